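// Event-driven core of the 2D lattice kinetic Monte Carlo model.
//
// State: N particles on an L x L square lattice, periodic in both axes,
// von Neumann (4-site) neighbourhoods.  Particles carry valency-limited
// specific bonds (with multiplicity) to adjacent particles and feel a
// non-specific attraction eps_ns per occupied neighbour site.
//
// Events and rates (per configuration, re-enumerated after every event):
//   monomer_move : per particle and empty target site,
//                  k_diff * exp(-(bonds_p * eps_sp + nbrs_p * eps_ns));
//                  the move severs every bond and contact of the mover.
//   cluster_move : per adjacency-connected cluster of size >= 2 and
//                  direction whose rigid translation lands all members on
//                  empty-or-same-cluster sites, at rate k_diff / S_clus.
//   bond_form    : per unordered adjacent pair with spare valency on both
//                  sides, at rate k_bond.
//   bond_break   : per existing bond (counting multiplicity), at rate
//                  k_bond * exp(-eps_sp).
//
// The Gillespie draw order is fixed: waiting time first (delta_t =
// -ln(z2)/r_total), then the event (z1), both from one mt19937_64 stream
// seeded per trajectory, so runs are bit-reproducible.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <array>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

namespace {

const int DR[4] = {-1, 1, 0, 0};   // N, S, E, W
const int DC[4] = {0, 0, 1, -1};

struct Engine {
  int L, N, lambda;
  double epsSp, epsNs, kDiff, kBond, kBreak, kD;  // kD = kDiff / divisor
  std::vector<int> prow, pcol;                    // particle -> coords (0-based)
  std::vector<int> site;                          // site -> particle index or -1
  std::vector<std::array<int, 4>> bPartner;       // bonded partners (or -1)
  std::vector<std::array<int, 4>> bMult;          // bond multiplicities
  std::vector<int> usedVal;
  double time;

  // scratch rebuilt by enumerate()
  std::vector<int> nbr;                        // occupied-neighbour count
  std::vector<int> parent, clustOf, clustSize; // union-find / compact clusters
  std::vector<int> memberStart, memberList;    // members grouped by cluster
  int nClusters;
  std::vector<double> boltz;    // exp(-(k*epsSp + m*epsNs)), k<=lambda, m<=4

  std::vector<int> nbrSite;  // site*4 + d -> neighbouring site index
  std::vector<int> psite;    // particle -> site index
  std::vector<int> nbq;      // particle*4 + d -> neighbouring occupant (or -1)

  int at(int r, int c) const { return site[r * L + c]; }
  int shiftR(int r, int d) const { int x = r + DR[d]; return x < 0 ? L - 1 : (x >= L ? 0 : x); }
  int shiftC(int c, int d) const { int x = c + DC[d]; return x < 0 ? L - 1 : (x >= L ? 0 : x); }

  void allocate() {
    site.assign((size_t)L * L, -1);
    nbrSite.assign((size_t)L * L * 4, 0);
    for (int r = 0; r < L; ++r)
      for (int c = 0; c < L; ++c)
        for (int d = 0; d < 4; ++d)
          nbrSite[((size_t)r * L + c) * 4 + d] = shiftR(r, d) * L + shiftC(c, d);
    psite.assign(N, -1);
    nbq.assign((size_t)N * 4, -1);
    bPartner.assign(N, {{-1, -1, -1, -1}});
    bMult.assign(N, {{0, 0, 0, 0}});
    usedVal.assign(N, 0);
    nbr.assign(N, 0);
    parent.assign(N, 0);
    clustOf.assign(N, 0);
    // escape exponent: usedVal can reach 4*lambda only if lambda small; the
    // bound on usedVal is lambda itself, so table is (lambda+1) x 5
    boltz.assign((size_t)(lambda + 1) * 5, 0.0);
    for (int k = 0; k <= lambda; ++k)
      for (int m = 0; m <= 4; ++m)
        boltz[(size_t)k * 5 + m] = std::exp(-(k * epsSp + m * epsNs));
  }

  void placeParticle(int p, int r, int c) {
    prow[p] = r; pcol[p] = c; psite[p] = r * L + c; site[psite[p]] = p;
  }

  int find(int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  }
  void unite(int a, int b) {
    a = find(a); b = find(b);
    if (a != b) parent[b] = a;
  }

  bool geomValid = false;  // nbq/nbr/clusters current? (bond events keep them)

  // Rebuild the adjacency geometry: neighbour cache, neighbour counts,
  // union-find clusters and member lists.  Only moves invalidate these;
  // bond formation/breakage leaves every position unchanged.
  void rebuildGeometry() {
    for (int p = 0; p < N; ++p) { parent[p] = p; nbr[p] = 0; }
    for (int p = 0; p < N; ++p) {
      const int *ns = &nbrSite[(size_t)psite[p] * 4];
      int cnt = 0;
      for (int d = 0; d < 4; ++d) {
        const int q = site[ns[d]];
        nbq[(size_t)p * 4 + d] = q;
        if (q >= 0) { ++cnt; if (d == 1 || d == 2) unite(p, q); }  // S,E once
      }
      nbr[p] = cnt;
    }
    // compact cluster ids in order of smallest member index
    nClusters = 0;
    std::fill(clustOf.begin(), clustOf.end(), -1);
    clustSize.clear();
    for (int p = 0; p < N; ++p) {
      const int r = find(p);
      if (clustOf[r] < 0) { clustOf[r] = nClusters++; clustSize.push_back(0); }
      clustOf[p] = clustOf[r];
      ++clustSize[clustOf[p]];
    }
    // member lists grouped by cluster (counting sort)
    memberStart.assign(nClusters + 1, 0);
    for (int ci = 0; ci < nClusters; ++ci) memberStart[ci + 1] = memberStart[ci] + clustSize[ci];
    memberList.assign(N, 0);
    {
      std::vector<int> fill(memberStart.begin(), memberStart.end() - 1);
      for (int p = 0; p < N; ++p) memberList[fill[clustOf[p]]++] = p;
    }
    geomValid = true;
  }

  // Single source of truth for the feasible-event enumeration.  The
  // visitor f(kind, a, b, mult, rate) is invoked for every feasible event
  // in canonical order (monomer moves, cluster moves, bond events per
  // S/E adjacency scan); a visitor returning true stops the walk.
  // Aggregated bond_break entries carry mult > 1 (rate = mult * kBreak).
  // Both the r_total pass and the event-pick pass traverse this exact
  // walk, so the sampled dynamics and the exported event list cannot
  // diverge.
  template <class F>
  bool walkEvents(F &&f) {
    if (!geomValid) rebuildGeometry();
    // (a) monomer moves
    for (int p = 0; p < N; ++p) {
      const double rate = kD * boltz[(size_t)usedVal[p] * 5 + nbr[p]];
      for (int d = 0; d < 4; ++d)
        if (nbq[(size_t)p * 4 + d] < 0 && f(0, p, d, 1, rate)) return true;
    }
    // (b) cluster moves (size >= 2)
    for (int ci = 0; ci < nClusters; ++ci) {
      const int S = clustSize[ci];
      if (S < 2) continue;
      const double rate = kD / S;
      for (int d = 0; d < 4; ++d) {
        bool ok = true;
        for (int k = memberStart[ci]; k < memberStart[ci + 1]; ++k) {
          const int q = nbq[(size_t)memberList[k] * 4 + d];
          if (q >= 0 && clustOf[q] != ci) { ok = false; break; }
        }
        if (ok && f(1, ci, d, 1, rate)) return true;
      }
    }
    // (c) bond formation and (d) breakage, one pass over S/E adjacencies
    for (int p = 0; p < N; ++p) {
      for (int d = 1; d <= 2; ++d) {  // each unordered pair once (L >= 3)
        const int q = nbq[(size_t)p * 4 + d];
        if (q >= 0 && usedVal[p] < lambda && usedVal[q] < lambda &&
            f(2, p, q, 1, kBond))
          return true;
      }
      for (int s = 0; s < 4; ++s) {
        const int q = bPartner[p][s];
        if (q > p && f(3, p, q, bMult[p][s], bMult[p][s] * kBreak))
          return true;
      }
    }
    return false;
  }

  double computeRTotal() {
    double s = 0;
    walkEvents([&](int, int, int, int, double r) { s += r; return false; });
    return s;
  }

  struct Picked { int kind, a, b; };

  // the Gillespie z1 draw: the event at the cumulative-rate interval
  // containing target; accumulation order matches computeRTotal exactly
  Picked pick(double target) {
    Picked out{-1, -1, -1};
    double acc = 0;
    walkEvents([&](int k, int a, int b, int, double r) {
      acc += r;
      out.kind = k; out.a = a; out.b = b;
      return target < acc;   // overrun falls through to the last event
    });
    return out;
  }

  int slotOf(int p, int q) const {
    for (int s = 0; s < 4; ++s) if (bPartner[p][s] == q) return s;
    return -1;
  }
  int freeSlot(int p) const {
    for (int s = 0; s < 4; ++s) if (bPartner[p][s] < 0) return s;
    return -1;
  }

  void addBond(int p, int q) {
    int s = slotOf(p, q);
    if (s < 0) { s = freeSlot(p); bPartner[p][s] = q; }
    ++bMult[p][s]; ++usedVal[p];
    s = slotOf(q, p);
    if (s < 0) { s = freeSlot(q); bPartner[q][s] = p; }
    ++bMult[q][s]; ++usedVal[q];
  }

  void dropBond(int p, int q) {
    int s = slotOf(p, q);
    if (--bMult[p][s] == 0) bPartner[p][s] = -1;
    --usedVal[p];
    s = slotOf(q, p);
    if (--bMult[q][s] == 0) bPartner[q][s] = -1;
    --usedVal[q];
  }

  void severAll(int p) {
    for (int s = 0; s < 4; ++s) {
      const int q = bPartner[p][s];
      if (q >= 0) {
        const int sq = slotOf(q, p);
        usedVal[q] -= bMult[q][sq];
        bPartner[q][sq] = -1; bMult[q][sq] = 0;
        usedVal[p] -= bMult[p][s];
        bPartner[p][s] = -1; bMult[p][s] = 0;
      }
    }
  }

  void apply(int kind, int a, int b) {
    if (kind == 0) {                       // monomer move: sever, relocate
      severAll(a);
      const int nr = shiftR(prow[a], b), nc = shiftC(pcol[a], b);
      site[psite[a]] = -1;
      placeParticle(a, nr, nc);
    } else if (kind == 1) {                // rigid cluster translation
      for (int k = memberStart[a]; k < memberStart[a + 1]; ++k)
        site[psite[memberList[k]]] = -1;
      for (int k = memberStart[a]; k < memberStart[a + 1]; ++k) {
        const int p = memberList[k];
        placeParticle(p, shiftR(prow[p], b), shiftC(pcol[p], b));
      }
    } else if (kind == 2) {
      addBond(a, b);
    } else {
      dropBond(a, b);
    }
    if (kind <= 1) geomValid = false;  // positions changed
  }

  int totalBonds() const {
    int s = 0;
    for (int p = 0; p < N; ++p) s += usedVal[p];
    return s / 2;
  }
};

// Partial Fisher-Yates draw of N distinct sites out of L*L.
std::vector<int> sampleSites(int L, int N, std::mt19937_64 &gen) {
  const int M = L * L;
  std::vector<int> pool(M);
  for (int i = 0; i < M; ++i) pool[i] = i;
  std::vector<int> out(N);
  for (int i = 0; i < N; ++i) {
    std::uniform_int_distribution<int> pick(i, M - 1);
    const int j = pick(gen);
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
  return out;
}

void loadBonds(Engine &eng, const IntegerMatrix &bonds) {
  for (int i = 0; i < bonds.nrow(); ++i) {
    const int p = bonds(i, 0) - 1, q = bonds(i, 1) - 1, m = bonds(i, 2);
    for (int k = 0; k < m; ++k) eng.addBond(p, q);
  }
}

IntegerMatrix extractBonds(const Engine &eng) {
  std::vector<int> bp, bq, bm;
  for (int p = 0; p < eng.N; ++p)
    for (int s = 0; s < 4; ++s)
      if (eng.bPartner[p][s] > p) {
        bp.push_back(p + 1); bq.push_back(eng.bPartner[p][s] + 1);
        bm.push_back(eng.bMult[p][s]);
      }
  IntegerMatrix out(bp.size(), 3);
  for (size_t i = 0; i < bp.size(); ++i) {
    out(i, 0) = bp[i]; out(i, 1) = bq[i]; out(i, 2) = bm[i];
  }
  colnames(out) = CharacterVector::create("p", "q", "mult");
  return out;
}

void setupEngine(Engine &eng, int L, int N, int lambda, double epsSp,
                 double epsNs, double kDiff, double kBond, double divisor) {
  eng.L = L; eng.N = N; eng.lambda = lambda;
  eng.epsSp = epsSp; eng.epsNs = epsNs;
  eng.kDiff = kDiff; eng.kBond = kBond;
  eng.kBreak = kBond * std::exp(-epsSp);
  eng.kD = kDiff / divisor;
  eng.prow.assign(N, 0); eng.pcol.assign(N, 0);
  eng.time = 0.0;
  eng.allocate();
}

} // namespace

// [[Rcpp::export]]
IntegerMatrix cpp_init_positions(int L, int N, double seed) {
  std::mt19937_64 gen((uint64_t)seed);
  std::vector<int> sites = sampleSites(L, N, gen);
  IntegerMatrix out(N, 2);
  for (int i = 0; i < N; ++i) {
    out(i, 0) = sites[i] / L;   // row, 0-based
    out(i, 1) = sites[i] % L;   // col
  }
  colnames(out) = CharacterVector::create("row", "col");
  return out;
}

// Hoshen-Kopelman / union-find labelling of occupied sites, canonicalized:
// labels 1..n ordered by decreasing size, ties broken by smallest member id.
// [[Rcpp::export]]
List cpp_label_clusters(IntegerVector row, IntegerVector col, int L) {
  const int N = row.size();
  Engine eng;
  setupEngine(eng, L, N, 0, 0.0, 0.0, 1.0, 0.0, 1.0);
  for (int p = 0; p < N; ++p) eng.placeParticle(p, row[p], col[p]);
  eng.rebuildGeometry();

  // canonical order: size desc, then smallest member (compact ids already
  // ascend by smallest member)
  std::vector<int> ord(eng.nClusters);
  for (int i = 0; i < eng.nClusters; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(), [&](int a, int b) {
    return eng.clustSize[a] > eng.clustSize[b];
  });
  std::vector<int> rank(eng.nClusters);
  for (int i = 0; i < eng.nClusters; ++i) rank[ord[i]] = i;

  IntegerVector labels(N), sizes(eng.nClusters);
  for (int p = 0; p < N; ++p) labels[p] = rank[eng.clustOf[p]] + 1;
  for (int i = 0; i < eng.nClusters; ++i) sizes[i] = eng.clustSize[ord[i]];
  return List::create(_["labels"] = labels, _["sizes"] = sizes,
                      _["nClusters"] = eng.nClusters);
}

// [[Rcpp::export]]
List cpp_enumerate_events(IntegerVector row, IntegerVector col,
                          IntegerMatrix bonds, int L, int lambda,
                          double epsSp, double epsNs, double kDiff,
                          double kBond, double divisor) {
  const int N = row.size();
  Engine eng;
  setupEngine(eng, L, N, lambda, epsSp, epsNs, kDiff, kBond, divisor);
  for (int p = 0; p < N; ++p) eng.placeParticle(p, row[p], col[p]);
  loadBonds(eng, bonds);

  std::vector<int> kindV, aV, bV, multV;
  std::vector<double> rateV;
  double rtot = 0;
  eng.walkEvents([&](int k, int a, int b, int m, double r) {
    kindV.push_back(k);
    // clusters reported by their smallest member id for stability
    aV.push_back(k == 1 ? eng.memberList[eng.memberStart[a]] : a);
    bV.push_back(b);
    multV.push_back(m);
    rateV.push_back(r);
    rtot += r;
    return false;
  });

  const size_t E = kindV.size();
  IntegerVector kind(E), a(E), b(E), mult(E);
  NumericVector rate(E);
  for (size_t e = 0; e < E; ++e) {
    kind[e] = kindV[e];
    a[e] = aV[e] + 1;
    b[e] = bV[e] + 1;
    mult[e] = multV[e];
    rate[e] = rateV[e];
  }
  return List::create(_["kind"] = kind, _["a"] = a, _["b"] = b,
                      _["mult"] = mult, _["rate"] = rate,
                      _["rTotal"] = rtot);
}

// Full Gillespie trajectory.  Returns snapshot summaries at multiples of
// snapInterval (plus t = 0 and t = tEnd), optional full snapshots, the
// monomer-exchange first-passage log, an optional event log, and the final
// state.
// [[Rcpp::export]]
List cpp_run_trajectory(int L, int N, int lambda, double epsSp, double epsNs,
                        double kDiff, double kBond, double tEnd, double seed,
                        double snapInterval, double divisor,
                        bool storeSnapshots, bool recordEvents,
                        Nullable<IntegerMatrix> initPositions,
                        Nullable<IntegerMatrix> initBonds,
                        double maxEvents) {
  std::mt19937_64 gen((uint64_t)seed);
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  Engine eng;
  setupEngine(eng, L, N, lambda, epsSp, epsNs, kDiff, kBond, divisor);
  if (initPositions.isNotNull()) {
    IntegerMatrix pos(initPositions);
    for (int p = 0; p < N; ++p) eng.placeParticle(p, pos(p, 0), pos(p, 1));
  } else {
    std::vector<int> sites = sampleSites(L, N, gen);
    for (int p = 0; p < N; ++p) eng.placeParticle(p, sites[p] / L, sites[p] % L);
  }
  if (initBonds.isNotNull()) loadBonds(eng, IntegerMatrix(initBonds));

  // exchange bookkeeping: interval opens when nbr reaches 4, closes at 0
  std::vector<double> openAt(N, -1.0);
  std::vector<int> nbrPrev(N, 0);
  std::vector<int> xId; std::vector<double> xOpen, xClose; std::vector<int> xCens;

  std::vector<double> sumT; std::vector<int> sumLc, sumNc, sumNb;
  List snapshots;
  std::vector<double> logT; std::vector<int> logKind, logA, logB;

  eng.rebuildGeometry();
  for (int p = 0; p < N; ++p) {
    nbrPrev[p] = eng.nbr[p];
    if (eng.nbr[p] == 4) openAt[p] = 0.0;
  }

  int largest = 0;
  for (int ci = 0; ci < eng.nClusters; ++ci)
    largest = std::max(largest, eng.clustSize[ci]);

  auto recordSummary = [&](double t) {
    if (!sumT.empty() && sumT.back() == t) return;  // horizon == tick
    sumT.push_back(t); sumLc.push_back(largest);
    sumNc.push_back(eng.nClusters); sumNb.push_back(eng.totalBonds());
    if (storeSnapshots) {
      IntegerMatrix pos(N, 2);
      for (int p = 0; p < N; ++p) { pos(p, 0) = eng.prow[p]; pos(p, 1) = eng.pcol[p]; }
      IntegerVector uv(N);
      for (int p = 0; p < N; ++p) uv[p] = eng.usedVal[p];
      snapshots.push_back(List::create(_["time"] = t, _["positions"] = pos,
                                       _["bonds"] = extractBonds(eng),
                                       _["usedValency"] = uv));
    }
  };
  recordSummary(0.0);

  double nextTick = snapInterval > 0 ? snapInterval : tEnd + 1.0;
  double nEvents = 0;
  bool earlyTermination = false, truncated = false;

  while (eng.time < tEnd) {
    const double rTotal = eng.computeRTotal();
    if (rTotal <= 0.0) {            // frozen: no feasible event, ever
      earlyTermination = true;
      while (nextTick <= tEnd) { recordSummary(nextTick); nextTick += snapInterval; }
      eng.time = tEnd;
      break;
    }
    const double z2 = 1.0 - unif(gen);        // (0, 1]
    const double dt = -std::log(z2) / rTotal; // waiting time first
    const double tNew = eng.time + dt;
    while (nextTick < tNew && nextTick <= tEnd) { // state holds on [t, t+dt)
      recordSummary(nextTick);
      nextTick += snapInterval;
    }
    if (tNew >= tEnd) { eng.time = tEnd; break; }

    // event draw (z1) over the same cumulative walk
    const double target = unif(gen) * rTotal;
    const Engine::Picked ev = eng.pick(target);
    const bool moved = ev.kind <= 1;
    if (recordEvents) {
      logT.push_back(tNew); logKind.push_back(ev.kind);
      // cluster events logged by smallest member id
      logA.push_back(ev.kind == 1
                       ? eng.memberList[eng.memberStart[ev.a]] + 1
                       : ev.a + 1);
      logB.push_back(ev.b + 1);
    }
    eng.apply(ev.kind, ev.a, ev.b);
    eng.time = tNew;
    nEvents += 1;

    if (moved) {  // bond events change neither clusters nor neighbour counts
      eng.rebuildGeometry();
      largest = 0;
      for (int ci = 0; ci < eng.nClusters; ++ci)
        largest = std::max(largest, eng.clustSize[ci]);

      for (int p = 0; p < N; ++p) {
        const int nb = eng.nbr[p];
        if (nb != nbrPrev[p]) {
          if (openAt[p] < 0 && nb == 4) {
            openAt[p] = tNew;
          } else if (openAt[p] >= 0 && nb == 0) {
            xId.push_back(p + 1); xOpen.push_back(openAt[p]);
            xClose.push_back(tNew); xCens.push_back(0);
            openAt[p] = -1.0;
          }
          nbrPrev[p] = nb;
        }
      }
    }
    if (nEvents >= maxEvents) { truncated = true; break; }
    if (((long long)nEvents & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  recordSummary(eng.time);
  for (int p = 0; p < N; ++p) {
    if (openAt[p] >= 0) {
      xId.push_back(p + 1); xOpen.push_back(openAt[p]);
      xClose.push_back(eng.time); xCens.push_back(1);
    }
  }

  IntegerMatrix finalPos(N, 2);
  for (int p = 0; p < N; ++p) { finalPos(p, 0) = eng.prow[p]; finalPos(p, 1) = eng.pcol[p]; }
  IntegerVector finalUv(N);
  for (int p = 0; p < N; ++p) finalUv[p] = eng.usedVal[p];

  List out = List::create(
    _["summaryTime"] = wrap(sumT), _["summaryLargest"] = wrap(sumLc),
    _["summaryNClusters"] = wrap(sumNc), _["summaryNBonds"] = wrap(sumNb),
    _["snapshots"] = snapshots,
    _["exchange"] = List::create(_["particle"] = wrap(xId),
                                 _["burial"] = wrap(xOpen),
                                 _["release"] = wrap(xClose),
                                 _["censored"] = wrap(xCens)),
    _["finalPositions"] = finalPos, _["finalBonds"] = extractBonds(eng),
    _["finalUsedValency"] = finalUv, _["finalTime"] = eng.time,
    _["nEvents"] = nEvents, _["earlyTermination"] = earlyTermination,
    _["truncated"] = truncated);
  if (recordEvents)
    out["eventLog"] = List::create(_["time"] = wrap(logT), _["kind"] = wrap(logKind),
                                   _["a"] = wrap(logA), _["b"] = wrap(logB));
  return out;
}
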