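#' @include AllClasses.R AllGenerics.R kmc-engine.R cluster-stats.R
NULL

#' Extract the monomer-exchange first-passage log
#'
#' An exchange event starts ("burial") when a particle's occupied-neighbour
#' count reaches 4 and completes ("release") when it next reaches 0 —
#' the lattice analogue of a molecule leaving a droplet, as probed by FRAP.
#' Burials still open at the end of the run are censored, never averaged
#' into the mean.  Double burial without an intervening release never nests:
#' one open interval per particle.
#'
#' The engine performs this bookkeeping during the run (`method =
#' "stored"`).  `method = "replay"` rebuilds the log in R by replaying the
#' trajectory's event log through [applyEvent()] (requires
#' `recordEvents = TRUE`), which is useful as an independent cross-check.
#'
#' @param trajectory a [Trajectory-class].
#' @param method `"stored"` (default) or `"replay"`.
#' @return A data.frame with columns `particle`, `burial`, `release`,
#'   `censored`.
#' @export
recordExchangeEvents <- function(trajectory, method = c("stored", "replay")) {
  stopifnot(is(trajectory, "Trajectory"))
  method <- match.arg(method)
  if (method == "stored") return(trajectory@exchangeLog)
  if (is.null(trajectory@eventLog))
    stop("replay needs an event log; rerun with recordEvents = TRUE")
  if (!length(trajectory@snapshots))
    stop("replay needs stored snapshots (the initial state)")
  params <- trajectory@params
  state <- trajectory@snapshots[[1L]]
  counts <- vapply(seq_len(nParticles(state)),
                   function(p) length(.neighborIds(state, p)), integer(1))
  openAt <- ifelse(counts == 4L, 0, NA_real_)
  log <- list()
  el <- trajectory@eventLog
  for (i in seq_len(nrow(el))) {
    ev <- data.frame(kind = el$kind[i], a = el$a[i], b = el$b[i],
                     direction = if (el$kind[i] %in% c("monomer_move", "cluster_move"))
                       .DIRS[el$b[i]] else NA_character_)
    state <- applyEvent(state, ev, params)
    t <- el$time[i]
    counts <- vapply(seq_len(nParticles(state)),
                     function(p) length(.neighborIds(state, p)), integer(1))
    for (p in seq_along(counts)) {
      if (is.na(openAt[p]) && counts[p] == 4L) {
        openAt[p] <- t
      } else if (!is.na(openAt[p]) && counts[p] == 0L) {
        log[[length(log) + 1L]] <- c(p, openAt[p], t, 0)
        openAt[p] <- NA_real_
      }
    }
  }
  tEnd <- tEnd(params)
  for (p in which(!is.na(openAt)))
    log[[length(log) + 1L]] <- c(p, openAt[p], tEnd, 1)
  if (!length(log))
    return(data.frame(particle = integer(0), burial = numeric(0),
                      release = numeric(0), censored = logical(0)))
  m <- do.call(rbind, log)
  data.frame(particle = as.integer(m[, 1L]), burial = m[, 2L],
             release = m[, 3L], censored = m[, 4L] == 1)
}

#' Build an exchange log from a scripted neighbour-count series
#'
#' Definition-level helper: given the times at which one particle's
#' occupied-neighbour count changes, produce its exchange intervals
#' (burial at count 4, release at count 0, censoring at `tEnd`).
#'
#' @param time times of the count changes (ascending).
#' @param count the neighbour count after each change.
#' @param tEnd end of observation.
#' @param particle id stored in the log.
#' @return A data.frame like [recordExchangeEvents()].
#' @export
exchangeEventsFromCounts <- function(time, count, tEnd, particle = 1L) {
  stopifnot(length(time) == length(count), !is.unsorted(time))
  openAt <- NA_real_
  out <- list()
  for (i in seq_along(time)) {
    if (is.na(openAt) && count[i] == 4L) openAt <- time[i]
    else if (!is.na(openAt) && count[i] == 0L) {
      out[[length(out) + 1L]] <- c(openAt, time[i], 0)
      openAt <- NA_real_
    }
  }
  if (!is.na(openAt)) out[[length(out) + 1L]] <- c(openAt, tEnd, 1)
  if (!length(out))
    return(data.frame(particle = integer(0), burial = numeric(0),
                      release = numeric(0), censored = logical(0)))
  m <- do.call(rbind, out)
  data.frame(particle = particle, burial = m[, 1L], release = m[, 2L],
             censored = m[, 3L] == 1)
}

#' Mean first-passage exchange time
#'
#' Arithmetic mean of the completed buried-to-free passage times, with the
#' censoring fraction always reported alongside.  `kmLowerBound` treats
#' censored durations as if they completed at the censoring instant — a
#' conservative lower bound on the true mean used as a cross-check that
#' censoring never biases the estimate downward silently.
#'
#' @param log an exchange log (see [recordExchangeEvents()]), possibly
#'   pooled over trajectories via `rbind`.
#' @return A list: `mean` (s; `NA` if no completed events), `sd`,
#'   `nCompleted`, `nCensored`, `censoringFraction`, `kmLowerBound`.
#' @examples
#' log <- data.frame(particle = 1:2, burial = c(3, 0), release = c(10, 3),
#'                   censored = c(FALSE, FALSE))
#' meanExchangeTime(log)$mean  # 5
#' @export
meanExchangeTime <- function(log) {
  stopifnot(all(c("burial", "release", "censored") %in% names(log)))
  dur <- log$release - log$burial
  done <- !log$censored
  n <- sum(done)
  ncen <- sum(log$censored)
  list(mean = if (n) mean(dur[done]) else NA_real_,
       sd = if (n > 1) stats::sd(dur[done]) else NA_real_,
       nCompleted = n,
       nCensored = ncen,
       censoringFraction = if (n + ncen) ncen / (n + ncen) else NA_real_,
       kmLowerBound = if (n + ncen) mean(dur) else NA_real_)
}

#' Fraction of free valencies inside and outside the largest cluster
#'
#' `1 - sum(usedValency) / (valency * count)`, computed separately for the
#' members of the single largest cluster and for everything else; tracks
#' how quickly adhesive valencies are exhausted inside a growing droplet.
#'
#' @param state a [LatticeState-class].
#' @param labeling a [ClusterLabeling-class] for `state`.
#' @param params a [SimParams-class] with `valency >= 1`.
#' @return Named numeric: `inside`, `outside` (NA when the group is empty).
#' @export
valencyUtilization <- function(state, labeling, params) {
  if (params@valency < 1L) stop("valency must be >= 1")
  inside <- which(labeling@labels == 1L)
  outside <- setdiff(seq_len(nParticles(state)), inside)
  frac <- function(ids) {
    if (!length(ids)) return(NA_real_)
    1 - sum(state@usedValency[ids]) / (params@valency * length(ids))
  }
  c(inside = frac(inside), outside = frac(outside))
}

#' Classify a phase point as NoPS, microphase or macrophase
#'
#' Operational criteria: *macrophase* when the mean largest-cluster
#' fraction reaches `macroThreshold` (0.5 — the largest cluster holds at
#' least half of all monomers); *NoPS* when the mean `L_clus` stays at the
#' monomer scale (`<= max(5/N_tot, 0.05)`) with negligible bonding
#' (< `nopsBonds` bonds per particle); everything else is the
#' multi-droplet *microphase*.
#'
#' @param meanLclus mean largest-cluster fraction over replicates.
#' @param meanBondsPerParticle mean bond multiplicity per particle.
#' @param nTot particle count.
#' @param macroThreshold,nopsLclus,nopsBonds the thresholds above.
#' @return One of `"NoPS"`, `"microphase"`, `"macrophase"`.
#' @export
classifyPhase <- function(meanLclus, meanBondsPerParticle, nTot,
                          macroThreshold = 0.5,
                          nopsLclus = max(5 / nTot, 0.05),
                          nopsBonds = 0.5) {
  if (is.na(meanLclus)) stop("meanLclus is missing (no replicates?)")
  if (meanLclus >= macroThreshold) return("macrophase")
  if (meanLclus <= nopsLclus && meanBondsPerParticle < nopsBonds)
    return("NoPS")
  "microphase"
}

.seedFor <- function(baseSeed, cell, replicate) {
  # deterministic, order-independent; keep well below 2^31
  (as.numeric(baseSeed) + 10000 * (cell - 1) + (replicate - 1)) %% 2147483647
}

.withParams <- function(template, row) {
  p <- template
  for (nm in names(row)) {
    val <- row[[nm]]
    switch(nm,
      valency = { p@valency <- as.integer(val) },
      epsSp = { p@epsSp <- as.numeric(val) },
      epsNs = { p@epsNs <- as.numeric(val) },
      kDiff = { p@kDiff <- as.numeric(val) },
      kBond = { p@kBond <- as.numeric(val) },
      tEnd = { p@tEnd <- as.numeric(val) },
      latticeSize = { p@latticeSize <- as.integer(val) },
      nParticles = { p@nParticles <- as.integer(val) },
      phiLattice = {
        p@nParticles <- as.integer(round(as.numeric(val) * p@latticeSize^2))
      },
      stop("unknown sweep parameter: ", nm))
  }
  validObject(p)
  p
}

# run replicates of one parameter set; returns per-replicate final L_clus
# and bond counts
.runCell <- function(params, replicates, baseSeed, cell) {
  lclus <- numeric(replicates)
  nclus <- numeric(replicates)
  bondsPer <- numeric(replicates)
  seeds <- integer(replicates)
  for (r in seq_len(replicates)) {
    seeds[r] <- as.integer(.seedFor(baseSeed, cell, r))
    tr <- runTrajectory(params, seed = seeds[r])
    n <- nrow(tr@summary)
    lclus[r] <- tr@summary$largestCluster[n] / params@nParticles
    nclus[r] <- tr@summary$nClusters[n]
    bondsPer[r] <- tr@summary$nBonds[n] / params@nParticles
  }
  list(lclus = lclus, nclus = nclus, bondsPer = bondsPer, seeds = seeds)
}

#' Kinetic phase-diagram sweep
#'
#' Runs seeded replicate trajectories over a Cartesian grid of model
#' parameters and classifies every grid cell.  Each replicate's seed is
#' derived deterministically from `(baseSeed, cell index, replicate
#' index)`, so results do not depend on execution order.  Failures in one
#' cell are recorded and the sweep continues.
#'
#' @param grid data.frame, one row per phase point; columns may be any of
#'   `valency`, `epsSp`, `epsNs`, `kDiff`, `kBond`, `phiLattice`,
#'   `nParticles`, `latticeSize`, `tEnd`.
#' @param template a [SimParams-class] providing every other parameter.
#' @param replicates independent trajectories per cell.
#' @param baseSeed base of the deterministic seed schedule.
#' @return `grid` augmented with `meanLclus`, `sdLclus`, `meanNClusters`,
#'   `meanBondsPerParticle`, `classification`, `replicates`, `error`.
#' @examples
#' tpl <- SimParams(latticeSize = 20, phi = 0.05, valency = 5, epsSp = 3,
#'                  tEnd = 60, snapshotInterval = 60)
#' phaseSweep(data.frame(epsSp = c(1, 3)), tpl, replicates = 2, baseSeed = 1)
#' @export
phaseSweep <- function(grid, template, replicates = 10L,
                       baseSeed = simSeed(template)) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L, replicates >= 1L)
  out <- grid
  out$meanLclus <- NA_real_
  out$sdLclus <- NA_real_
  out$meanNClusters <- NA_real_
  out$meanBondsPerParticle <- NA_real_
  out$classification <- NA_character_
  out$replicates <- as.integer(replicates)
  out$error <- NA_character_
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch({
      p <- .withParams(template, grid[i, , drop = FALSE])
      cell <- .runCell(p, replicates, baseSeed, i)
      list(p = p, cell = cell)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      out$error[i] <- conditionMessage(res)
      next
    }
    cell <- res$cell
    out$meanLclus[i] <- mean(cell$lclus)
    out$sdLclus[i] <- stats::sd(cell$lclus)
    out$meanNClusters[i] <- mean(cell$nclus)
    out$meanBondsPerParticle[i] <- mean(cell$bondsPer)
    out$classification[i] <- classifyPhase(out$meanLclus[i],
                                           out$meanBondsPerParticle[i],
                                           res$p@nParticles)
  }
  out
}

#' Critical specific-interaction strength
#'
#' The smallest grid value of `epsSp` at which the mean largest-cluster
#' fraction reaches `threshold` (default 0.5: the largest cluster holds at
#' least 50% of all monomers).  Returns `NA` if the row never crosses.
#'
#' @param epsSp ascending grid of specific-bond strengths (kT).
#' @param meanLclus mean largest-cluster fraction at each grid point.
#' @param threshold crossing criterion.
#' @return The critical strength in kT, or `NA_real_`.
#' @export
criticalEpsilon <- function(epsSp, meanLclus, threshold = 0.5) {
  stopifnot(length(epsSp) == length(meanLclus))
  if (is.unsorted(epsSp, strictly = TRUE))
    stop("epsSp grid must be sorted ascending")
  hit <- which(meanLclus >= threshold)
  if (!length(hit)) return(NA_real_)
  epsSp[hit[1L]]
}

#' Largest-cluster size as a function of the diffusion rate
#'
#' Reruns the model at fixed `kBond` and fixed simulated horizon while
#' varying `kDiff` (the kinetic analogue of changing solvent viscosity),
#' and reports the mean final `L_clus` per rate together with the Spearman
#' rank correlation between `kDiff` and the replicate means.
#'
#' @param kDiffValues diffusion rates to scan (1/s).
#' @param template a [SimParams-class]; its `kBond` stays fixed.
#' @param replicates trajectories per rate.
#' @param baseSeed deterministic seed schedule base.
#' @return A list: `table` (kDiff, meanLclus, sdLclus, replicates columns),
#'   `spearmanRho`, and the per-replicate matrix `lclus`.
#' @export
diffusionScan <- function(kDiffValues, template, replicates = 8L,
                          baseSeed = simSeed(template)) {
  stopifnot(length(kDiffValues) >= 1L, all(kDiffValues > 0))
  lclus <- matrix(NA_real_, nrow = replicates, ncol = length(kDiffValues))
  for (j in seq_along(kDiffValues)) {
    p <- template
    p@kDiff <- as.numeric(kDiffValues[j])
    cell <- .runCell(p, replicates, baseSeed, j)
    lclus[, j] <- cell$lclus
  }
  means <- colMeans(lclus)
  rho <- if (length(kDiffValues) > 2L)
    suppressWarnings(stats::cor(kDiffValues, means, method = "spearman"))
  else NA_real_
  list(table = data.frame(kDiff = kDiffValues, meanLclus = means,
                          sdLclus = apply(lclus, 2L, stats::sd),
                          replicates = replicates),
       spearmanRho = rho, lclus = lclus)
}

#' Pooled exchange-time experiment
#'
#' Runs independent seeded trajectories and pools their exchange logs,
#' the standard protocol for measuring monomer exchange MFPTs (the study
#' scale is 100 trajectories of 10 simulated hours each).
#'
#' @param params a [SimParams-class].
#' @param replicates number of independent trajectories.
#' @param baseSeed deterministic seed schedule base.
#' @param perParticle if `TRUE`, also return per-particle means instead of
#'   pooling only.
#' @return A list: `mfpt` (see [meanExchangeTime()]), `log` (pooled),
#'   `replicates`, and optionally `perParticleMeans`.
#' @export
measureExchangeTimes <- function(params, replicates = 100L,
                                 baseSeed = simSeed(params),
                                 perParticle = FALSE) {
  logs <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    tr <- runTrajectory(params, seed = as.integer(.seedFor(baseSeed, 1L, r)))
    lg <- tr@exchangeLog
    if (nrow(lg)) lg$replicate <- r
    logs[[r]] <- lg
  }
  pooled <- do.call(rbind, logs[vapply(logs, nrow, integer(1)) > 0])
  if (is.null(pooled))
    pooled <- data.frame(particle = integer(0), burial = numeric(0),
                         release = numeric(0), censored = logical(0),
                         replicate = integer(0))
  out <- list(mfpt = meanExchangeTime(pooled), log = pooled,
              replicates = replicates)
  if (perParticle && nrow(pooled)) {
    done <- pooled[!pooled$censored, ]
    out$perParticleMeans <- tapply(done$release - done$burial,
                                   interaction(done$replicate, done$particle,
                                               drop = TRUE), mean)
  }
  out
}
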