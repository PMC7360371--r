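#' Parameters of one lattice kinetic Monte Carlo run
#'
#' `SimParams` bundles every model parameter and rate of a single kMC
#' trajectory: the lattice, particle number (or density), valency, the two
#' interaction strengths (in units of kT), the diffusion and bond-formation
#' rates, the simulated horizon and the RNG seed.  The bond-breakage rate is
#' never stored: it is always recomputed as
#' \eqn{k_{break} = k_{bond}\, e^{-\epsilon_{sp}}}, which ties bond kinetics
#' to detailed balance at strength \eqn{\epsilon_{sp}}.
#'
#' @details
#' The lattice is a 2D square grid with periodic boundaries and von Neumann
#' (4-site) neighbourhoods.  `rateConvention` controls how `kDiff` is read:
#' `"per_direction"` (default) makes each feasible direction an event at rate
#' `kDiff`; `"total"` divides by 4 so that `kDiff` is the total escape rate
#' of an isolated particle.
#'
#' @param latticeSize integer, sites per side (L).
#' @param nParticles integer, number of particles; alternatively give `phi`.
#' @param phi occupied-site fraction; `nParticles = round(phi * L^2)`.
#' @param valency maximum number of specific bonds per particle (lambda).
#' @param epsSp specific-bond strength, kT.
#' @param epsNs non-specific neighbour attraction, kT.
#' @param kDiff free-diffusion rate, 1/s.
#' @param kBond bond-formation rate per eligible neighbour pair, 1/s.
#' @param tEnd simulated duration, s.
#' @param seed integer RNG seed for the trajectory.
#' @param snapshotInterval simulated seconds between recorded snapshots.
#' @param rateConvention `"per_direction"` or `"total"` (see Details).
#'
#' @return A `SimParams` object.
#' @examples
#' p <- SimParams(latticeSize = 50, phi = 0.04, valency = 5, epsSp = 3)
#' kBreak(p)  # == kBond(p) * exp(-epsSp(p))
#' @aliases latticeSize nParticles valency epsSp epsNs kDiff kBond kBreak
#'   phiLattice tEnd simSeed
#' @export SimParams
#' @exportClass SimParams
setClass("SimParams",
  representation(
    latticeSize = "integer",
    nParticles = "integer",
    valency = "integer",
    epsSp = "numeric",
    epsNs = "numeric",
    kDiff = "numeric",
    kBond = "numeric",
    tEnd = "numeric",
    seed = "integer",
    snapshotInterval = "numeric",
    rateConvention = "character"
  )
)

setValidity("SimParams", function(object) {
  msg <- character()
  L <- object@latticeSize
  N <- object@nParticles
  if (length(L) != 1L || is.na(L) || L < 2L)
    msg <- c(msg, "latticeSize must be a single integer >= 2")
  if (length(N) != 1L || is.na(N) || N < 1L)
    msg <- c(msg, "nParticles must be a single integer >= 1 (empty systems are not allowed)")
  if (length(N) == 1L && length(L) == 1L && !is.na(N) && !is.na(L) && N > L^2)
    msg <- c(msg, sprintf("density > 1: nParticles (%d) exceeds lattice capacity L^2 = %d", N, L^2))
  if (object@valency < 0L) msg <- c(msg, "valency must be >= 0")
  if (object@epsSp < 0) msg <- c(msg, "epsSp must be >= 0 (kT)")
  if (object@epsNs < 0) msg <- c(msg, "epsNs must be >= 0 (kT)")
  if (!(object@kDiff > 0)) msg <- c(msg, "kDiff must be > 0")
  if (object@kBond < 0) msg <- c(msg, "kBond must be >= 0")
  if (object@tEnd < 0) msg <- c(msg, "tEnd must be >= 0")
  if (!(object@snapshotInterval > 0)) msg <- c(msg, "snapshotInterval must be > 0")
  if (!object@rateConvention %in% c("per_direction", "total"))
    msg <- c(msg, "rateConvention must be 'per_direction' or 'total'")
  if (length(msg)) msg else TRUE
})

SimParams <- function(latticeSize = 100L, nParticles = NULL, phi = NULL,
                      valency = 5L, epsSp = 3, epsNs = 0.35,
                      kDiff = 1, kBond = 1, tEnd = 7200, seed = 1L,
                      snapshotInterval = tEnd / 20,
                      rateConvention = c("per_direction", "total")) {
  latticeSize <- as.integer(latticeSize)
  if (is.null(nParticles)) {
    if (is.null(phi)) phi <- 0.04
    if (phi > 1) stop("density > 1: phi must lie in (0, 1]")
    nParticles <- as.integer(round(phi * latticeSize^2))
  } else if (!is.null(phi)) {
    stop("give either nParticles or phi, not both")
  }
  if (tEnd == 0) snapshotInterval <- 1
  new("SimParams",
      latticeSize = latticeSize, nParticles = as.integer(nParticles),
      valency = as.integer(valency), epsSp = as.numeric(epsSp),
      epsNs = as.numeric(epsNs), kDiff = as.numeric(kDiff),
      kBond = as.numeric(kBond), tEnd = as.numeric(tEnd),
      seed = as.integer(seed),
      snapshotInterval = as.numeric(snapshotInterval),
      rateConvention = match.arg(rateConvention))
}

#' Occupancy state of the lattice
#'
#' `LatticeState` holds the configuration of the kMC system at one instant:
#' particle coordinates (0-based `row`/`col`, periodic wrap), the multiset of
#' specific bonds (unordered particle pairs with multiplicity; a pair of
#' neighbours can share several bonds as long as both have spare valency),
#' the per-particle used valency, and the simulated time.
#'
#' Invariants enforced by the validity method: all occupied sites distinct
#' and in range; every bonded pair occupies nearest-neighbour sites (von
#' Neumann, periodic); `usedValency[p]` equals the sum of bond
#' multiplicities involving `p`.  The valency *cap* depends on the run
#' parameters and is enforced by [placeBond()] and the engine.
#'
#' @aliases positions bonds usedValency simTime occupancyGrid
#' @exportClass LatticeState
setClass("LatticeState",
  representation(
    latticeSize = "integer",
    positions = "matrix",
    bonds = "matrix",
    usedValency = "integer",
    time = "numeric"
  )
)

setValidity("LatticeState", function(object) {
  msg <- character()
  L <- object@latticeSize
  pos <- object@positions
  N <- nrow(pos)
  if (ncol(pos) != 2L) return("positions must be an N x 2 matrix (row, col)")
  if (any(pos < 0L) || any(pos >= L))
    msg <- c(msg, "coordinates must lie in [0, L-1]")
  sites <- pos[, 1L] * L + pos[, 2L]
  if (anyDuplicated(sites))
    msg <- c(msg, "two particles occupy the same site")
  b <- object@bonds
  if (ncol(b) != 3L) return("bonds must be a B x 3 matrix (p, q, mult)")
  uv <- integer(N)
  if (nrow(b) > 0) {
    if (any(b[, 1L] < 1L) || any(b[, 2L] < 1L) || any(b[, 1L] > N) || any(b[, 2L] > N))
      msg <- c(msg, "bond endpoints must be valid particle ids")
    else {
      if (any(b[, 1L] >= b[, 2L]))
        msg <- c(msg, "bond rows must have p < q")
      if (any(b[, 3L] < 1L))
        msg <- c(msg, "bond multiplicities must be >= 1")
      if (anyDuplicated(b[, 1L] * (N + 1) + b[, 2L]))
        msg <- c(msg, "duplicate bond rows (use the mult column)")
      dr <- abs(pos[b[, 1L], 1L] - pos[b[, 2L], 1L])
      dc <- abs(pos[b[, 1L], 2L] - pos[b[, 2L], 2L])
      dr <- pmin(dr, L - dr)
      dc <- pmin(dc, L - dc)
      if (any(dr + dc != 1L))
        msg <- c(msg, "a bond connects non-adjacent sites")
      for (i in seq_len(nrow(b))) {
        uv[b[i, 1L]] <- uv[b[i, 1L]] + b[i, 3L]
        uv[b[i, 2L]] <- uv[b[i, 2L]] + b[i, 3L]
      }
    }
  }
  if (length(object@usedValency) != N)
    msg <- c(msg, "usedValency must have one entry per particle")
  else if (!length(msg) && !identical(as.integer(uv), as.integer(object@usedValency)))
    msg <- c(msg, "usedValency inconsistent with the bond multiset")
  if (object@time < 0) msg <- c(msg, "time must be >= 0")
  if (length(msg)) msg else TRUE
})

.newLatticeState <- function(L, positions, bonds = NULL, usedValency = NULL,
                             time = 0) {
  positions <- matrix(as.integer(positions), ncol = 2L,
                      dimnames = list(NULL, c("row", "col")))
  if (is.null(bonds))
    bonds <- matrix(integer(0), ncol = 3L)
  bonds <- matrix(as.integer(bonds), ncol = 3L,
                  dimnames = list(NULL, c("p", "q", "mult")))
  if (is.null(usedValency)) {
    usedValency <- integer(nrow(positions))
    for (i in seq_len(nrow(bonds))) {
      usedValency[bonds[i, 1L]] <- usedValency[bonds[i, 1L]] + bonds[i, 3L]
      usedValency[bonds[i, 2L]] <- usedValency[bonds[i, 2L]] + bonds[i, 3L]
    }
  }
  new("LatticeState", latticeSize = as.integer(L), positions = positions,
      bonds = bonds, usedValency = as.integer(usedValency),
      time = as.numeric(time))
}

#' Feasible events of a configuration and their rates
#'
#' An ordered table of every feasible event in the current configuration —
#' monomer moves, rigid cluster translations, bond formations and bond
#' breakages — together with the total rate \eqn{r_{total}} used by the
#' Gillespie draw.  Blocked moves are never listed: a null event would
#' distort the stochastic time axis.
#'
#' @aliases eventTable rTotal
#' @exportClass EventSet
setClass("EventSet",
  representation(events = "data.frame", rTotal = "numeric")
)

setValidity("EventSet", function(object) {
  ev <- object@events
  need <- c("kind", "a", "b", "rate")
  if (!all(need %in% names(ev)))
    return("events must have columns kind, a, b, rate")
  if (any(ev$rate < 0)) return("negative event rate")
  s <- sum(ev$rate)
  if (abs(s - object@rTotal) > 1e-9 * max(1, s))
    return("rTotal does not match the sum of event rates")
  TRUE
})

#' Connected-component labelling of the occupied lattice
#'
#' Result of Hoshen-Kopelman (union-find) labelling of occupied sites under
#' von Neumann adjacency with periodic wrap.  Labels are canonical: cluster
#' 1 is the largest, ties broken by smallest member id, so identical
#' configurations always yield identical labellings.
#'
#' @aliases clusterLabels clusterSizes nClusters
#' @exportClass ClusterLabeling
setClass("ClusterLabeling",
  representation(labels = "integer", sizes = "integer", nClusters = "integer")
)

setValidity("ClusterLabeling", function(object) {
  if (sum(object@sizes) != length(object@labels))
    return("cluster sizes must sum to the particle count")
  if (length(object@sizes) != object@nClusters)
    return("nClusters inconsistent with sizes")
  TRUE
})

#' A simulated kMC trajectory
#'
#' Container for one Gillespie trajectory: the run parameters, a summary
#' table (time, largest-cluster size, cluster count, bond count) sampled at
#' `snapshotInterval`, optional full snapshots, the monomer-exchange
#' first-passage log (burial at 4 occupied neighbours, release at 0;
#' unresolved burials are censored at `tEnd`), an optional event log, and
#' the final [LatticeState-class].
#'
#' @aliases trajectorySummary snapshots finalState simParams
#' @exportClass Trajectory
setClass("Trajectory",
  representation(
    params = "SimParams",
    summary = "data.frame",
    snapshots = "list",
    exchangeLog = "data.frame",
    eventLog = "ANY",
    stats = "list",
    finalState = "LatticeState"
  )
)

#' Bead-spring chain topology
#'
#' Bead types and backbone connectivity of a coarse-grained sticker-spacer
#' chain: large adhesive domain beads (20 A diameter, types `"domainA"` /
#' `"domainB"` for the two complementary species) joined by flexible linker
#' beads (4.2 A).  Consecutive beads are bonded; each backbone bond carries
#' its own rest length (4.5 A linker-linker, 12.1 A linker-domain contact
#' distance by default).
#'
#' @exportClass ChainTopology
setClass("ChainTopology",
  representation(types = "character", r0 = "numeric", diameters = "numeric")
)

setValidity("ChainTopology", function(object) {
  msg <- character()
  if (!all(object@types %in% c("linker", "domainA", "domainB")))
    msg <- c(msg, "bead types must be linker, domainA or domainB")
  M <- length(object@types)
  if (M >= 2L && length(object@r0) != M - 1L)
    msg <- c(msg, "r0 must have one entry per backbone bond (M - 1)")
  if (length(object@diameters) != M)
    msg <- c(msg, "diameters must have one entry per bead")
  if (length(msg)) msg else TRUE
})

#' Bead coordinates plus active specific bonds
#'
#' A conformation of one or more concatenated chains: bead coordinates in
#' Angstrom and the set of active specific bonds between complementary
#' domain beads.  Each domain bead can hold at most one specific bond
#' (per-site valency of 1).
#'
#' @exportClass ChainConformation
setClass("ChainConformation",
  representation(coords = "matrix", topology = "ChainTopology",
                 specificBonds = "matrix")
)

setValidity("ChainConformation", function(object) {
  msg <- character()
  if (ncol(object@coords) != 3L) msg <- c(msg, "coords must be M x 3 (Angstrom)")
  if (nrow(object@coords) != length(object@topology@types))
    msg <- c(msg, "coords and topology disagree on bead count")
  sb <- object@specificBonds
  if (ncol(sb) != 2L) msg <- c(msg, "specificBonds must be K x 2")
  if (nrow(sb) > 0) {
    ids <- as.vector(sb)
    if (anyDuplicated(ids))
      msg <- c(msg, "a domain bead participates in more than one specific bond")
    ty <- object@topology@types[ids]
    if (any(ty == "linker"))
      msg <- c(msg, "specific bonds may only involve domain beads")
  }
  if (length(msg)) msg else TRUE
})

#' Force-field parameters for the bead-spring evaluators
#'
#' Constants of the bead-spring force field: harmonic stretching (`ks`),
#' cosine bending (`kappa`), truncated 12-6 Lennard-Jones (`epsNs`, per-pair
#' `sigma`, cutoff `cutoffMult * sigma`), and the stochastic specific-bond
#' rules (capture radius `rC`, breakage stretch `rBreakDelta`, formation
#' probability `pForm`).  All energies carry an explicit unit tag
#' (`energyUnit`), either `"kT"` or `"kcal/mol"`, interconverted at
#' T = 310 K (1 kT = 0.61596 kcal/mol); constructor inputs are converted to
#' `energyUnit` at build time so no untagged mixing can occur.
#'
#' @exportClass ForceFieldParams
setClass("ForceFieldParams",
  representation(
    ks = "numeric", kappa = "numeric", epsNs = "numeric",
    sigmaLinker = "numeric", sigmaDomain = "numeric", cutoffMult = "numeric",
    r0Specific = "numeric", rC = "numeric", rBreakDelta = "numeric",
    pForm = "numeric", halfPrefactor = "logical", irreversible = "logical",
    energyUnit = "character"
  )
)

setValidity("ForceFieldParams", function(object) {
  msg <- character()
  pos <- c(ks = object@ks, kappa = object@kappa, epsNs = object@epsNs,
           sigmaLinker = object@sigmaLinker, sigmaDomain = object@sigmaDomain,
           cutoffMult = object@cutoffMult, r0Specific = object@r0Specific,
           rC = object@rC, rBreakDelta = object@rBreakDelta)
  bad <- names(pos)[!(pos > 0)]
  if (length(bad)) msg <- c(msg, paste("must be positive:", paste(bad, collapse = ", ")))
  if (object@pForm < 0 || object@pForm > 1) msg <- c(msg, "pForm must lie in [0, 1]")
  if (!object@energyUnit %in% c("kT", "kcal/mol"))
    msg <- c(msg, "energyUnit must be 'kT' or 'kcal/mol'")
  if (length(msg)) msg else TRUE
})
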