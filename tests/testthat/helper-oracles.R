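# Independent plain-R oracles for cluster labelling and event enumeration,
# plus random-state generators.  Everything here is written from the model
# definition directly, deliberately not reusing the package's compiled paths.

# build a LatticeState from explicit 0-based coordinates / bond rows
mkState <- function(L, coords, bonds = NULL, time = 0) {
  condensateKMC:::.newLatticeState(L, coords, bonds, time = time)
}

# wrap-around neighbour of (r, c) in direction d (1=N, 2=S, 3=E, 4=W)
.oDR <- c(-1L, 1L, 0L, 0L)
.oDC <- c(0L, 0L, 1L, -1L)
oracleNeighbor <- function(r, c, d, L) {
  c((r + .oDR[d]) %% L, (c + .oDC[d]) %% L)
}

# breadth-first-search partition of occupied sites into clusters;
# returns a list of sorted member-id vectors, unordered
bfsClusters <- function(state) {
  L <- latticeSize(state)
  pos <- positions(state)
  N <- nrow(pos)
  key <- pos[, 1] * L + pos[, 2]
  idOf <- new.env()
  for (i in seq_len(N)) assign(as.character(key[i]), i, envir = idOf)
  seen <- logical(N)
  comps <- list()
  for (root in seq_len(N)) {
    if (seen[root]) next
    comp <- integer(0)
    queue <- root
    seen[root] <- TRUE
    while (length(queue)) {
      i <- queue[1]; queue <- queue[-1]
      comp <- c(comp, i)
      for (d in 1:4) {
        nb <- oracleNeighbor(pos[i, 1], pos[i, 2], d, L)
        j <- mget(as.character(nb[1] * L + nb[2]), envir = idOf,
                  ifnotfound = list(NULL))[[1]]
        if (!is.null(j) && !seen[j]) { seen[j] <- TRUE; queue <- c(queue, j) }
      }
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}

# canonical string form of a partition (for set equality)
partitionKey <- function(comps) {
  paste(sort(vapply(comps, function(x) paste(x, collapse = ","), "")),
        collapse = ";")
}

# naive re-scan of every site, pair and cluster: the brute-force event
# enumeration oracle.  Returns a canonical sorted data.frame.
oracleEvents <- function(state, params) {
  L <- latticeSize(state)
  pos <- positions(state)
  N <- nrow(pos)
  lam <- valency(params)
  kD <- kDiff(params) / (if (params@rateConvention == "total") 4 else 1)
  kB <- kBond(params)
  occ <- matrix(FALSE, L, L)
  for (i in seq_len(N)) occ[pos[i, 1] + 1, pos[i, 2] + 1] <- TRUE
  b <- bonds(state)
  bondMult <- integer(N)
  for (i in seq_len(nrow(b))) {
    bondMult[b[i, 1]] <- bondMult[b[i, 1]] + b[i, 3]
    bondMult[b[i, 2]] <- bondMult[b[i, 2]] + b[i, 3]
  }
  rows <- list()
  add <- function(kind, a, bb, dir, rate)
    rows[[length(rows) + 1]] <<- data.frame(kind = kind, a = a, b = bb,
                                            direction = dir, rate = rate)
  dirName <- c("N", "S", "E", "W")
  # monomer moves
  for (p in seq_len(N)) {
    nNbr <- 0
    for (d in 1:4) {
      nb <- oracleNeighbor(pos[p, 1], pos[p, 2], d, L)
      if (occ[nb[1] + 1, nb[2] + 1]) nNbr <- nNbr + 1
    }
    rate <- kD * exp(-(bondMult[p] * epsSp(params) + nNbr * epsNs(params)))
    for (d in 1:4) {
      nb <- oracleNeighbor(pos[p, 1], pos[p, 2], d, L)
      if (!occ[nb[1] + 1, nb[2] + 1])
        add("monomer_move", p, NA_integer_, dirName[d], rate)
    }
  }
  # cluster moves
  for (comp in bfsClusters(state)) {
    S <- length(comp)
    if (S < 2) next
    for (d in 1:4) {
      ok <- TRUE
      for (p in comp) {
        nb <- oracleNeighbor(pos[p, 1], pos[p, 2], d, L)
        if (occ[nb[1] + 1, nb[2] + 1]) {
          tgt <- which(pos[, 1] == nb[1] & pos[, 2] == nb[2])
          if (!(tgt %in% comp)) { ok <- FALSE; break }
        }
      }
      if (ok) add("cluster_move", min(comp), NA_integer_, dirName[d], kD / S)
    }
  }
  # bond formation: every unordered adjacent pair with spare valency
  if (N >= 2) {
    for (p in seq_len(N - 1)) {
      for (q in seq(p + 1, N)) {
        dr <- abs(pos[p, 1] - pos[q, 1]); dr <- min(dr, L - dr)
        dc <- abs(pos[p, 2] - pos[q, 2]); dc <- min(dc, L - dc)
        if (dr + dc == 1 && bondMult[p] < lam && bondMult[q] < lam)
          add("bond_form", p, q, NA_character_, kB)
      }
    }
  }
  # bond breakage: one event per bond copy
  for (i in seq_len(nrow(b)))
    for (k in seq_len(b[i, 3]))
      add("bond_break", b[i, 1], b[i, 2], NA_character_,
          kB * exp(-epsSp(params)))
  if (!length(rows))
    return(data.frame(kind = character(0), a = integer(0), b = integer(0),
                      direction = character(0), rate = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$kind, out$a, out$b, out$direction, out$rate), , drop = FALSE]
}

canonicalEvents <- function(ev) {
  ev <- ev[order(ev$kind, ev$a, ev$b, ev$direction, ev$rate), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# random small states with valency-consistent random bonds
randomState <- function(L, maxN, lambda) {
  N <- sample.int(maxN, 1)
  sites <- sample.int(L^2, N) - 1L
  coords <- cbind(sites %/% L, sites %% L)
  st <- mkState(L, coords)
  if (lambda >= 1 && N >= 2) {
    params <- SimParams(latticeSize = L, nParticles = N, valency = lambda,
                        tEnd = 1, snapshotInterval = 1)
    for (p in seq_len(N - 1)) {
      for (q in seq(p + 1, N)) {
        if (!condensateKMC:::.areAdjacent(st, p, q)) next
        nAdd <- sample(0:lambda, 1)
        for (k in seq_len(nAdd)) {
          ok <- usedValency(st)[p] < lambda && usedValency(st)[q] < lambda
          if (ok && stats::runif(1) < 0.6) st <- placeBond(st, p, q, params)
        }
      }
    }
  }
  st
}

# default microphase study point at reduced lattice scale (shared by tests)
microParams <- function(L = 50, phi = 0.04, epsSp = 3, valency = 5,
                        tEnd = 7200, seed = 1,
                        snapshotInterval = tEnd) {
  SimParams(latticeSize = L, phi = phi, valency = valency, epsSp = epsSp,
            tEnd = tEnd, seed = seed, snapshotInterval = snapshotInterval)
}
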