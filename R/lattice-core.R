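#' @include AllClasses.R AllGenerics.R
NULL

# ---- accessors -------------------------------------------------------------

#' @rdname SimParams-class
#' @param x,object an object of the documented class.
#' @export
setMethod("latticeSize", "SimParams", function(x) x@latticeSize)

#' @rdname LatticeState-class
#' @export
setMethod("latticeSize", "LatticeState", function(x) x@latticeSize)

#' @rdname SimParams-class
#' @export
setMethod("nParticles", "SimParams", function(x) x@nParticles)

#' @rdname LatticeState-class
#' @export
setMethod("nParticles", "LatticeState", function(x) nrow(x@positions))

#' @rdname SimParams-class
#' @export
setMethod("valency", "SimParams", function(x) x@valency)

#' @rdname SimParams-class
#' @export
setMethod("epsSp", "SimParams", function(x) x@epsSp)

#' @rdname SimParams-class
#' @export
setMethod("epsNs", "SimParams", function(x) x@epsNs)

#' @rdname SimParams-class
#' @export
setMethod("kDiff", "SimParams", function(x) x@kDiff)

#' @rdname SimParams-class
#' @export
setMethod("kBond", "SimParams", function(x) x@kBond)

#' @rdname SimParams-class
#' @export
setMethod("kBreak", "SimParams", function(x) x@kBond * exp(-x@epsSp))

#' @rdname SimParams-class
#' @export
setMethod("phiLattice", "SimParams", function(x) x@nParticles / x@latticeSize^2)

#' @rdname SimParams-class
#' @export
setMethod("tEnd", "SimParams", function(x) x@tEnd)

#' @rdname SimParams-class
#' @export
setMethod("simSeed", "SimParams", function(x) x@seed)

#' @rdname LatticeState-class
#' @export
setMethod("positions", "LatticeState", function(x) x@positions)

#' @rdname LatticeState-class
#' @export
setMethod("bonds", "LatticeState", function(x) x@bonds)

#' @rdname LatticeState-class
#' @export
setMethod("usedValency", "LatticeState", function(x) x@usedValency)

#' @rdname LatticeState-class
#' @export
setMethod("simTime", "LatticeState", function(x) x@time)

#' @rdname LatticeState-class
#' @export
setMethod("occupancyGrid", "LatticeState", function(x) {
  L <- x@latticeSize
  g <- matrix(NA_integer_, L, L)
  g[x@positions[, 1L] + 1L + L * x@positions[, 2L]] <- seq_len(nrow(x@positions))
  g
})

setMethod("show", "SimParams", function(object) {
  cat(sprintf(
    "SimParams: L=%d, N=%d (phi=%.4g), lambda=%d\n  epsSp=%.3g kT, epsNs=%.3g kT, kDiff=%.3g /s, kBond=%.3g /s (kBreak=%.4g /s)\n  tEnd=%.6g s, seed=%d, snapshotInterval=%.6g s, rateConvention=%s\n",
    object@latticeSize, object@nParticles, phiLattice(object),
    object@valency, object@epsSp, object@epsNs, object@kDiff, object@kBond,
    kBreak(object), object@tEnd, object@seed, object@snapshotInterval,
    object@rateConvention))
})

setMethod("show", "LatticeState", function(object) {
  cat(sprintf(
    "LatticeState: %d particles on a %d x %d periodic lattice at t=%.6g s\n  %d bond(s) (total multiplicity %d)\n",
    nrow(object@positions), object@latticeSize, object@latticeSize,
    object@time, nrow(object@bonds),
    if (nrow(object@bonds)) sum(object@bonds[, 3L]) else 0L))
})

# ---- geometry helpers ------------------------------------------------------

# minimal-image component difference on a periodic axis
.pbcDelta <- function(d, L) {
  d <- d %% L
  ifelse(d > L / 2, d - L, d)
}

.areAdjacent <- function(state, p, q) {
  L <- state@latticeSize
  dr <- abs(.pbcDelta(state@positions[p, 1L] - state@positions[q, 1L], L))
  dc <- abs(.pbcDelta(state@positions[p, 2L] - state@positions[q, 2L], L))
  dr + dc == 1
}

# occupied neighbours of particle p, counted per direction (N, S, E, W)
.neighborIds <- function(state, p) {
  L <- state@latticeSize
  g <- occupancyGrid(state)
  r <- state@positions[p, 1L]
  cc <- state@positions[p, 2L]
  dr <- c(-1L, 1L, 0L, 0L)
  dc <- c(0L, 0L, 1L, -1L)
  ids <- integer(0)
  for (d in 1:4) {
    q <- g[((r + dr[d]) %% L) + 1L, ((cc + dc[d]) %% L) + 1L]
    if (!is.na(q)) ids <- c(ids, q)
  }
  ids
}

.checkParticle <- function(state, p) {
  if (length(p) != 1L || is.na(p) || p < 1L || p > nrow(state@positions))
    stop("unknown particle id: ", p)
}

# ---- operations ------------------------------------------------------------

#' Place particles uniformly at random on the lattice
#'
#' Draws `nParticles(params)` distinct sites uniformly without replacement
#' (partial Fisher-Yates on a dedicated 64-bit generator, so the layout is
#' bit-identical across sessions for the same seed) and returns the bond-free
#' starting state at `time = 0`.
#'
#' @param params a [SimParams-class].
#' @param seed integer seed; defaults to the seed stored in `params`.
#' @return A [LatticeState-class] with no bonds.
#' @examples
#' s <- initLattice(SimParams(latticeSize = 50, phi = 0.04))
#' nParticles(s)  # 100
#' @export
initLattice <- function(params, seed = simSeed(params)) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  pos <- cpp_init_positions(params@latticeSize, params@nParticles,
                            as.numeric(seed))
  .newLatticeState(params@latticeSize, pos)
}

#' Net interaction energy of one particle
#'
#' The magnitude of all interactions particle `p` is engaged in:
#' \eqn{\sum \epsilon_{sp} + \epsilon_{ns}}, i.e. (total bond multiplicity
#' of `p`) x `epsSp` plus (occupied nearest-neighbour sites) x `epsNs`, in
#' kT.  This is the energy whose Boltzmann factor suppresses the particle's
#' diffusive escape.
#'
#' @param state a [LatticeState-class].
#' @param params a [SimParams-class].
#' @param p particle id.
#' @return Non-negative energy in kT.
#' @export
interactionEnergy <- function(state, params, p) {
  .checkParticle(state, p)
  b <- state@bonds
  bondMult <- 0L
  if (nrow(b))
    bondMult <- sum(b[b[, 1L] == p | b[, 2L] == p, 3L])
  nNbr <- length(.neighborIds(state, p))
  bondMult * params@epsSp + nNbr * params@epsNs
}

#' Form or remove one specific bond between neighbouring particles
#'
#' `placeBond()` adds one unit of multiplicity to the bond between adjacent
#' particles `p` and `q`, provided both still have unsatisfied valencies
#' (`usedValency < valency(params)`).  A pair of neighbours can accumulate
#' several bonds this way.  `removeBond()` removes one unit.
#'
#' @param state a [LatticeState-class].
#' @param p,q particle ids occupying nearest-neighbour sites.
#' @param params a [SimParams-class] (supplies the valency cap).
#' @return The updated [LatticeState-class].
#' @export
placeBond <- function(state, p, q, params) {
  .checkParticle(state, p); .checkParticle(state, q)
  if (p == q) stop("cannot bond a particle to itself")
  if (!.areAdjacent(state, p, q))
    stop("particles ", p, " and ", q, " are not nearest neighbours")
  if (state@usedValency[p] >= params@valency ||
      state@usedValency[q] >= params@valency)
    stop("valency exceeded: both particles need usedValency < ",
         params@valency)
  p <- as.integer(p); q <- as.integer(q)
  lo <- min(p, q); hi <- max(p, q)
  b <- state@bonds
  hit <- which(b[, 1L] == lo & b[, 2L] == hi)
  if (length(hit)) {
    b[hit, 3L] <- b[hit, 3L] + 1L
  } else {
    b <- rbind(b, c(lo, hi, 1L))
  }
  uv <- state@usedValency
  uv[p] <- uv[p] + 1L
  uv[q] <- uv[q] + 1L
  initialize(state, bonds = b, usedValency = uv)
}

#' @rdname placeBond
#' @export
removeBond <- function(state, p, q) {
  .checkParticle(state, p); .checkParticle(state, q)
  p <- as.integer(p); q <- as.integer(q)
  lo <- min(p, q); hi <- max(p, q)
  b <- state@bonds
  hit <- which(b[, 1L] == lo & b[, 2L] == hi)
  if (!length(hit))
    stop("no bond exists between particles ", p, " and ", q)
  b[hit, 3L] <- b[hit, 3L] - 1L
  if (b[hit, 3L] == 0L) b <- b[-hit, , drop = FALSE]
  uv <- state@usedValency
  uv[p] <- uv[p] - 1L
  uv[q] <- uv[q] - 1L
  initialize(state, bonds = b, usedValency = uv)
}

# ---- snapshot I/O ----------------------------------------------------------

#' Read and write plain-text lattice snapshots
#'
#' Deterministic plain-text format: header lines `#L <L>` and
#' `#time <seconds>`, then one line per particle
#' (`id  row  col  used_valency`, 0-based coordinates, ascending id), then
#' one line per bond (`p  q  multiplicity`, p < q, sorted).  Fields are
#' tab-separated; particle lines have 4 fields, bond lines 3.
#'
#' @param state a [LatticeState-class].
#' @param path file path.
#' @return `writeSnapshot()` returns `path` invisibly; `readSnapshot()`
#'   returns a [LatticeState-class].
#' @export
writeSnapshot <- function(state, path) {
  stopifnot(is(state, "LatticeState"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#L\t%d", state@latticeSize), con)
  writeLines(sprintf("#time\t%.15g", state@time), con)
  pos <- state@positions
  for (i in seq_len(nrow(pos)))
    writeLines(sprintf("%d\t%d\t%d\t%d", i, pos[i, 1L], pos[i, 2L],
                       state@usedValency[i]), con)
  b <- state@bonds
  if (nrow(b)) {
    b <- b[order(b[, 1L], b[, 2L]), , drop = FALSE]
    for (i in seq_len(nrow(b)))
      writeLines(sprintf("%d\t%d\t%d", b[i, 1L], b[i, 2L], b[i, 3L]), con)
  }
  invisible(path)
}

#' @rdname writeSnapshot
#' @export
readSnapshot <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  get <- function(key) {
    ln <- lines[hdr][startsWith(lines[hdr], paste0("#", key))]
    if (!length(ln)) stop("snapshot is missing header #", key)
    strsplit(ln[1L], "\t", fixed = TRUE)[[1L]][2L]
  }
  L <- as.integer(get("L"))
  time <- as.numeric(get("time"))
  body <- strsplit(lines[!hdr & nzchar(lines)], "\t", fixed = TRUE)
  nf <- lengths(body)
  pl <- body[nf == 4L]
  bl <- body[nf == 3L]
  if (!length(pl)) stop("snapshot contains no particles")
  pm <- matrix(as.integer(unlist(pl)), ncol = 4L, byrow = TRUE)
  pm <- pm[order(pm[, 1L]), , drop = FALSE]
  bonds <- if (length(bl))
    matrix(as.integer(unlist(bl)), ncol = 3L, byrow = TRUE) else NULL
  .newLatticeState(L, pm[, 2:3], bonds, pm[, 4L], time)
}
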