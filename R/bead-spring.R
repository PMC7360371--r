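#' @include AllClasses.R
NULL

# kT <-> kcal/mol at T = 310 K
.KT_IN_KCAL <- 0.61596

#' Convert energies between kT and kcal/mol at T = 310 K
#'
#' 1 kT = 0.61596 kcal/mol at 310 K, the temperature of the underlying
#' Langevin simulations.
#'
#' @param x energy value(s).
#' @param from,to `"kT"` or `"kcal/mol"`.
#' @return Converted value(s).
#' @export
convertEnergy <- function(x, from, to) {
  units <- c("kT", "kcal/mol")
  if (!from %in% units || !to %in% units)
    stop("energy units must be 'kT' or 'kcal/mol'")
  if (from == to) return(x)
  if (from == "kT") x * .KT_IN_KCAL else x / .KT_IN_KCAL
}

#' Construct force-field parameters
#'
#' All defaults follow the bead-spring model of sticker-spacer chains:
#' backbone spring constant 5 kT/A^2, bending stiffness 2 kcal/mol,
#' LJ sigma 4.2 A (linker) / 20 A (domain) with a 2.5 sigma truncation,
#' specific-bond rest length 20 A, capture radius 22.5 A and breakage at
#' 2.2 A beyond rest.  Every energetic input carries an explicit unit tag
#' and is converted to `energyUnit` on construction.
#'
#' The stretching sum is implemented exactly as
#' \eqn{k_s \sum (r - r_0)^2}; `halfPrefactor = TRUE` switches to the
#' \eqn{\tfrac12 k_s} convention (both are in circulation; the breakage
#' energy "about 4 kT" at 2.2 A stretch with k_s = 2 kT/A^2 is only
#' consistent with the half convention, so the flag is exposed rather than
#' resolved).
#'
#' @param ks spring constant, in `ksUnit`/A^2.
#' @param ksUnit,kappaUnit,epsNsUnit unit tags of the three inputs.
#' @param kappa bending stiffness.
#' @param epsNs LJ well depth.
#' @param sigmaLinker,sigmaDomain LJ sigma per bead class, Angstrom.
#' @param cutoffMult LJ truncation radius in units of sigma.
#' @param r0Specific rest length of specific bonds, Angstrom.
#' @param rC specific-bond capture radius, Angstrom.
#' @param rBreakDelta breakage stretch beyond rest length, Angstrom.
#' @param pForm bond-formation probability per eligible pair and attempt.
#' @param halfPrefactor use the 1/2 k_s stretching convention.
#' @param irreversible if `TRUE`, bonds never break (stable-bond mode).
#' @param energyUnit unit in which energies are stored and returned.
#' @return A [ForceFieldParams-class].
#' @export
forceFieldParams <- function(ks = 5, ksUnit = "kT",
                             kappa = 2, kappaUnit = "kcal/mol",
                             epsNs = 1, epsNsUnit = "kcal/mol",
                             sigmaLinker = 4.2, sigmaDomain = 20,
                             cutoffMult = 2.5, r0Specific = 20,
                             rC = 22.5, rBreakDelta = 2.2, pForm = 1,
                             halfPrefactor = FALSE, irreversible = FALSE,
                             energyUnit = "kT") {
  new("ForceFieldParams",
      ks = convertEnergy(ks, ksUnit, energyUnit),
      kappa = convertEnergy(kappa, kappaUnit, energyUnit),
      epsNs = convertEnergy(epsNs, epsNsUnit, energyUnit),
      sigmaLinker = sigmaLinker, sigmaDomain = sigmaDomain,
      cutoffMult = cutoffMult, r0Specific = r0Specific, rC = rC,
      rBreakDelta = rBreakDelta, pForm = pForm,
      halfPrefactor = halfPrefactor, irreversible = irreversible,
      energyUnit = energyUnit)
}

#' Build a sticker-spacer chain topology and equilibrium conformation
#'
#' The default architecture carries `nDomains` adhesive domain beads
#' (20 A) separated by flexible linkers of `linkerLength` beads (4.2 A)
#' each — 5 domains with 35-bead linkers gives the 145-bead chain.
#' Backbone rest lengths default to 4.5 A between linker beads and the
#' contact distance (4.2 + 20)/2 = 12.1 A between a linker and a domain
#' bead.  `buildChain()` lays the chain along +x with every backbone bond
#' at its rest length, so its stretching energy is exactly zero.
#'
#' @param nDomains number of adhesive domain beads.
#' @param linkerLength linker beads between consecutive domains.
#' @param domainType `"domainA"` or `"domainB"` (the two complementary
#'   species).
#' @param r0Linker,r0Mixed backbone rest lengths (A).
#' @return `chainTopology()` a [ChainTopology-class]; `buildChain()` a
#'   [ChainConformation-class].
#' @export
chainTopology <- function(nDomains = 5L, linkerLength = 35L,
                          domainType = c("domainA", "domainB"),
                          r0Linker = 4.5, r0Mixed = (4.2 + 20) / 2) {
  domainType <- match.arg(domainType)
  stopifnot(nDomains >= 1L, linkerLength >= 0L)
  types <- character(0)
  for (i in seq_len(nDomains)) {
    types <- c(types, domainType)
    if (i < nDomains) types <- c(types, rep("linker", linkerLength))
  }
  M <- length(types)
  r0 <- numeric(max(M - 1L, 0L))
  if (M >= 2L) {
    for (i in seq_len(M - 1L)) {
      pair <- types[c(i, i + 1L)]
      r0[i] <- if (all(pair == "linker")) r0Linker else r0Mixed
    }
  }
  diam <- ifelse(types == "linker", 4.2, 20)
  new("ChainTopology", types = types, r0 = r0, diameters = diam)
}

#' @rdname chainTopology
#' @param topology a [ChainTopology-class]; built from the other arguments
#'   when missing.
#' @param ... passed on to `chainTopology()`.
#' @export
buildChain <- function(topology = chainTopology(...), ...) {
  M <- length(topology@types)
  x <- c(0, cumsum(topology@r0))
  coords <- cbind(x = x, y = numeric(M), z = numeric(M))
  new("ChainConformation", coords = coords, topology = topology,
      specificBonds = matrix(integer(0), ncol = 2L))
}

.bondVectors <- function(conformation) {
  xyz <- conformation@coords
  xyz[-1L, , drop = FALSE] - xyz[-nrow(xyz), , drop = FALSE]
}

#' Harmonic backbone stretching energy
#'
#' \eqn{E_{stretch} = k_s \sum_{i=1}^{M-1} (|r_i - r_{i+1}| - r_0)^2}
#' over consecutive beads, with the per-bond rest lengths of the topology
#' (optionally with the 1/2 prefactor, see [forceFieldParams()]).
#'
#' @param conformation a [ChainConformation-class].
#' @param params a [ForceFieldParams-class].
#' @return Energy in `params@energyUnit`.
#' @examples
#' ff <- forceFieldParams()
#' stretchEnergy(buildChain(chainTopology(2, 7)), ff)  # 0 at equilibrium
#' @export
stretchEnergy <- function(conformation, params) {
  M <- nrow(conformation@coords)
  if (M < 2L) {
    warning("fewer than 2 beads: stretching energy is 0")
    return(0)
  }
  bv <- .bondVectors(conformation)
  r <- sqrt(rowSums(bv^2))
  pref <- if (params@halfPrefactor) 0.5 else 1
  pref * params@ks * sum((r - conformation@topology@r0)^2)
}

#' Cosine bending energy
#'
#' \eqn{E_{bend} = \kappa \sum_{i=1}^{M-2} (1 - \cos\theta_i)} where
#' \eqn{\theta_i} is the angle between consecutive bond vectors: zero for a
#' collinear chain, \eqn{2\kappa} per full reversal.
#'
#' @inheritParams stretchEnergy
#' @return Energy in `params@energyUnit`.
#' @export
bendEnergy <- function(conformation, params) {
  M <- nrow(conformation@coords)
  if (M < 3L) stop("bending needs at least 3 beads")
  bv <- .bondVectors(conformation)
  r <- sqrt(rowSums(bv^2))
  if (any(r == 0)) stop("zero-length bond: bending angle undefined")
  nb <- nrow(bv)
  dots <- rowSums(bv[-nb, , drop = FALSE] * bv[-1L, , drop = FALSE])
  cosT <- pmin(1, pmax(-1, dots / (r[-nb] * r[-1L])))
  params@kappa * sum(1 - cosT)
}

.pairSigma <- function(types, params) {
  # Lorentz arithmetic mean for mixed linker-domain pairs
  s <- ifelse(types == "linker", params@sigmaLinker, params@sigmaDomain)
  outer(s, s, "+") / 2
}

#' Truncated 12-6 Lennard-Jones energy
#'
#' \eqn{E_{nb} = 4\epsilon_{ns} \sum_{i<j} [(\sigma/r_{ij})^{12} -
#' (\sigma/r_{ij})^6]} over all non-bonded pairs (directly bonded
#' consecutive beads are excluded) with per-pair sigma — 4.2 A
#' linker-linker, 20 A for domain pairs, arithmetic mean for mixed pairs —
#' truncated (not shifted) at `cutoffMult * sigma`; beyond the cutoff a
#' pair contributes exactly 0.
#'
#' @inheritParams stretchEnergy
#' @return Energy in `params@energyUnit`.
#' @export
ljEnergy <- function(conformation, params) {
  xyz <- conformation@coords
  M <- nrow(xyz)
  if (M < 2L) return(0)
  sig <- .pairSigma(conformation@topology@types, params)
  d <- as.matrix(stats::dist(xyz))
  E <- 0
  for (i in seq_len(M - 1L)) {
    for (j in seq((i + 1L), M)) {
      if (j == i + 1L) next  # bonded exclusion
      r <- d[i, j]
      if (r == 0) stop("coincident beads: r = 0 in the LJ sum")
      s <- sig[i, j]
      if (r < params@cutoffMult * s) {
        sr6 <- (s / r)^6
        E <- E + 4 * params@epsNs * (sr6^2 - sr6)
      }
    }
  }
  E
}

#' Total bead-spring energy breakdown
#'
#' @inheritParams stretchEnergy
#' @return A list `stretch`, `bend`, `lj`, `total` (all in
#'   `params@energyUnit`).
#' @export
chainEnergy <- function(conformation, params) {
  st <- stretchEnergy(conformation, params)
  bd <- if (nrow(conformation@coords) >= 3L) bendEnergy(conformation, params) else 0
  lj <- ljEnergy(conformation, params)
  list(stretch = st, bend = bd, lj = lj, total = st + bd + lj)
}

.domainDist <- function(conformation, i, j) {
  sqrt(sum((conformation@coords[i, ] - conformation@coords[j, ])^2))
}

#' Stochastic specific-bond formation
#'
#' Scans all complementary (domainA, domainB) pairs that are both free and
#' within the capture radius `rC` (22.5 A), in an order randomized by R's
#' RNG for tie-fairness, and forms each with probability `pForm`.  Every
#' domain bead ends with at most one specific bond (per-site valency 1).
#'
#' @param conformation a [ChainConformation-class].
#' @param params a [ForceFieldParams-class].
#' @return The updated conformation.
#' @export
tryFormSpecificBonds <- function(conformation, params) {
  ty <- conformation@topology@types
  a <- which(ty == "domainA")
  b <- which(ty == "domainB")
  if (!length(a) || !length(b)) return(conformation)
  bonded <- as.vector(conformation@specificBonds)
  pairs <- expand.grid(i = a, j = b)
  keep <- !(pairs$i %in% bonded) & !(pairs$j %in% bonded)
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs)) return(conformation)
  inRange <- vapply(seq_len(nrow(pairs)), function(k)
    .domainDist(conformation, pairs$i[k], pairs$j[k]) <= params@rC,
    logical(1))
  pairs <- pairs[inRange, , drop = FALSE]
  if (!nrow(pairs)) return(conformation)
  ord <- sample.int(nrow(pairs))
  sb <- conformation@specificBonds
  taken <- bonded
  for (k in ord) {
    i <- pairs$i[k]; j <- pairs$j[k]
    if (i %in% taken || j %in% taken) next
    if (stats::runif(1) <= params@pForm && params@pForm > 0) {
      sb <- rbind(sb, c(i, j))
      taken <- c(taken, i, j)
    }
  }
  initialize(conformation, specificBonds = sb)
}

#' Distance-triggered specific-bond breakage
#'
#' Every bond whose inter-domain separation exceeds
#' `r0Specific + rBreakDelta` (20 + 2.2 A) breaks with probability 1;
#' others are kept.  With `irreversible = TRUE` bonds never break — the
#' stable-bond mode of the underlying model.
#'
#' @inheritParams tryFormSpecificBonds
#' @return The updated conformation.
#' @export
tryBreakSpecificBonds <- function(conformation, params) {
  sb <- conformation@specificBonds
  if (!nrow(sb) || params@irreversible) return(conformation)
  rBreak <- params@r0Specific + params@rBreakDelta
  keep <- vapply(seq_len(nrow(sb)), function(k)
    .domainDist(conformation, sb[k, 1L], sb[k, 2L]) <= rBreak, logical(1))
  initialize(conformation, specificBonds = sb[keep, , drop = FALSE])
}

#' Read and write chain conformations as plain-text tables
#'
#' Tab-separated: a bead table (`id  type  x  y  z`, Angstrom) and, after a
#' `#bonds` marker line, an optional table of active specific bonds
#' (`i  j`).
#'
#' @param conformation a [ChainConformation-class].
#' @param path file path.
#' @param r0,... forwarded to [chainTopology()] when reading (`r0Linker`,
#'   `r0Mixed`).
#' @return `writeConformation()` returns `path` invisibly;
#'   `readConformation()` a [ChainConformation-class].
#' @export
writeConformation <- function(conformation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  xyz <- conformation@coords
  ty <- conformation@topology@types
  for (i in seq_len(nrow(xyz)))
    writeLines(sprintf("%d\t%s\t%.10g\t%.10g\t%.10g", i, ty[i],
                       xyz[i, 1L], xyz[i, 2L], xyz[i, 3L]), con)
  writeLines("#bonds", con)
  sb <- conformation@specificBonds
  for (k in seq_len(nrow(sb)))
    writeLines(sprintf("%d\t%d", sb[k, 1L], sb[k, 2L]), con)
  invisible(path)
}

#' @rdname writeConformation
#' @export
readConformation <- function(path, ...) {
  lines <- readLines(path)
  mark <- which(lines == "#bonds")
  if (!length(mark)) mark <- length(lines) + 1L
  beadLines <- strsplit(lines[seq_len(mark[1L] - 1L)], "\t", fixed = TRUE)
  ids <- vapply(beadLines, function(x) as.integer(x[1L]), integer(1))
  types <- vapply(beadLines, function(x) x[2L], character(1))
  xyz <- t(vapply(beadLines, function(x) as.numeric(x[3:5]), numeric(3)))
  ord <- order(ids)
  types <- types[ord]
  xyz <- xyz[ord, , drop = FALSE]
  colnames(xyz) <- c("x", "y", "z")
  # rebuild a topology consistent with the bead types
  topo <- new("ChainTopology", types = types,
              r0 = .defaultR0(types, ...),
              diameters = ifelse(types == "linker", 4.2, 20))
  sb <- matrix(integer(0), ncol = 2L)
  if (mark[1L] < length(lines)) {
    bl <- strsplit(lines[(mark[1L] + 1L):length(lines)], "\t", fixed = TRUE)
    bl <- bl[lengths(bl) == 2L]
    if (length(bl))
      sb <- matrix(as.integer(unlist(bl)), ncol = 2L, byrow = TRUE)
  }
  new("ChainConformation", coords = xyz, topology = topo, specificBonds = sb)
}

.defaultR0 <- function(types, r0Linker = 4.5, r0Mixed = (4.2 + 20) / 2) {
  M <- length(types)
  if (M < 2L) return(numeric(0))
  vapply(seq_len(M - 1L), function(i) {
    if (types[i] == "linker" && types[i + 1L] == "linker") r0Linker else r0Mixed
  }, numeric(1))
}
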