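#' @include AllClasses.R AllGenerics.R lattice-core.R
NULL

.DIRS <- c("N", "S", "E", "W")
.DR <- c(N = -1L, S = 1L, E = 0L, W = 0L)
.DC <- c(N = 0L, S = 0L, E = 1L, W = -1L)

.rateDivisor <- function(params)
  if (params@rateConvention == "total") 4 else 1

#' @rdname EventSet-class
#' @param x,object an `EventSet`.
#' @export
setMethod("eventTable", "EventSet", function(x) x@events)

#' @rdname EventSet-class
#' @export
setMethod("rTotal", "EventSet", function(x) x@rTotal)

setMethod("show", "EventSet", function(object) {
  tab <- table(object@events$kind)
  cat(sprintf("EventSet: %d feasible event(s), rTotal = %.6g\n",
              nrow(object@events), object@rTotal))
  if (length(tab))
    cat(paste(sprintf("  %s: %d", names(tab), as.integer(tab)),
              collapse = "\n"), "\n")
})

setMethod("show", "Trajectory", function(object) {
  n <- nrow(object@summary)
  cat(sprintf(
    "Trajectory: t = %.6g s, %.4g events, %d summary row(s), %d snapshot(s)\n",
    object@finalState@time, object@stats$nEvents, n,
    length(object@snapshots)))
  cat(sprintf("  final largest cluster: %d / %d particles; %d bond multiplicity\n",
              object@summary$largestCluster[n], nParticles(object@finalState),
              object@summary$nBonds[n]))
  if (isTRUE(object@stats$earlyTermination))
    cat("  NOTE: terminated early (no feasible events; frozen state)\n")
})

#' Enumerate every feasible event of a configuration
#'
#' Builds the complete event list of the current configuration:
#' \describe{
#'   \item{monomer_move}{per particle and empty target site, at rate
#'     `kDiff * exp(-interactionEnergy(p))`; executing it severs every bond
#'     and contact of the mover (`a` = particle, `b` = direction).}
#'   \item{cluster_move}{per adjacency-connected cluster of size >= 2 and
#'     direction whose rigid translation lands all members on
#'     empty-or-same-cluster sites, at rate `kDiff / S_clus`
#'     (`a` = smallest member id of the cluster, `b` = direction).}
#'   \item{bond_form}{per unordered adjacent pair with spare valency on
#'     both sides, at rate `kBond` (`a`, `b` = the pair).}
#'   \item{bond_break}{one event per existing bond, counting multiplicity,
#'     at rate `kBond * exp(-epsSp)`.}
#' }
#' Blocked moves are excluded rather than listed at rate 0.
#'
#' @param state a [LatticeState-class].
#' @param params a [SimParams-class].
#' @return An [EventSet-class].
#' @examples
#' p <- SimParams(latticeSize = 9, nParticles = 1, valency = 0, tEnd = 1)
#' ev <- enumerateEvents(initLattice(p), p)
#' rTotal(ev)  # 4 * kDiff
#' @export
enumerateEvents <- function(state, params) {
  stopifnot(is(state, "LatticeState"), is(params, "SimParams"))
  if (any(state@usedValency > params@valency))
    stop("state uses more valency than params allow")
  raw <- cpp_enumerate_events(
    state@positions[, 1L], state@positions[, 2L], state@bonds,
    state@latticeSize, params@valency, params@epsSp, params@epsNs,
    params@kDiff, params@kBond, .rateDivisor(params))
  kindName <- c("monomer_move", "cluster_move", "bond_form", "bond_break")
  # expand aggregated bond_break rows: one event per bond copy
  idx <- rep(seq_along(raw$kind), raw$mult)
  kind <- kindName[raw$kind[idx] + 1L]
  b <- raw$b[idx]
  mv <- kind %in% c("monomer_move", "cluster_move")
  rate <- raw$rate[idx]
  rate[kind == "bond_break"] <- params@kBond * exp(-params@epsSp)
  a <- raw$a[idx]
  ev <- data.frame(kind = kind, a = ifelse(mv, a, pmin(a, b)),
                   b = ifelse(mv, NA_integer_, pmax(a, b)),
                   direction = ifelse(mv, .DIRS[pmin(b, 4L)], NA_character_),
                   rate = rate, stringsAsFactors = FALSE)
  new("EventSet", events = ev, rTotal = sum(ev$rate))
}

#' Draw the next event by inverse transform on cumulative rates
#'
#' Returns the event at the cumulative-rate interval containing
#' `u * rTotal`, i.e. event `i` is chosen with probability
#' \eqn{r_i / r_{total}} — the Gillespie z1 draw.  Deterministic given the
#' event order and `u`.
#'
#' @param events an [EventSet-class] with `rTotal > 0`.
#' @param u a uniform(0,1) variate.
#' @return One row of the event table.
#' @export
drawEvent <- function(events, u) {
  stopifnot(is(events, "EventSet"))
  if (!(events@rTotal > 0)) stop("rTotal must be > 0 to draw an event")
  if (u < 0 || u >= 1) stop("u must lie in [0, 1)")
  cum <- cumsum(events@events$rate)
  i <- findInterval(u * events@rTotal, cum, left.open = FALSE) + 1L
  i <- min(i, nrow(events@events))
  events@events[i, , drop = FALSE]
}

#' Exponential waiting time of the Gillespie algorithm
#'
#' \eqn{\delta t = -\ln(z_2)/r_{total}}: the holding time of a
#' continuous-time Markov jump process whose total exit rate is
#' `rTotal`.
#'
#' @param rTotal total event rate (> 0).
#' @param u a uniform(0,1] variate (the z2 draw; `u = 0` diverges).
#' @return Waiting time in seconds.
#' @examples
#' waitingTime(2, exp(-1))  # 0.5
#' @export
waitingTime <- function(rTotal, u) {
  if (!(rTotal > 0)) stop("rTotal must be > 0")
  if (any(u <= 0) || any(u > 1)) stop("u must lie in (0, 1]")
  -log(u) / rTotal
}

#' Apply one event to a state
#'
#' Executes a single event row (as produced by [enumerateEvents()] /
#' [drawEvent()]): a monomer move relocates the particle and severs all its
#' bonds; a cluster move rigidly translates every member of the
#' adjacency-connected cluster, preserving internal bonds; bond events
#' adjust one unit of multiplicity.  The event must be feasible in `state`
#' (the engine re-enumerates after every event, so staleness cannot occur
#' there; stale events passed here raise an error).
#'
#' @param state a [LatticeState-class].
#' @param event one row of an event table.
#' @param params a [SimParams-class].
#' @return The updated [LatticeState-class].
#' @export
applyEvent <- function(state, event, params) {
  stopifnot(is(state, "LatticeState"), nrow(event) == 1L)
  L <- state@latticeSize
  kind <- event$kind
  if (kind == "monomer_move") {
    p <- event$a
    .checkParticle(state, p)
    d <- event$direction
    tgt <- c((state@positions[p, 1L] + .DR[[d]]) %% L,
             (state@positions[p, 2L] + .DC[[d]]) %% L)
    occ <- positions(state)
    if (any(occ[, 1L] == tgt[1L] & occ[, 2L] == tgt[2L]))
      stop("infeasible (stale) event: target site occupied")
    b <- state@bonds
    mine <- b[, 1L] == p | b[, 2L] == p
    uv <- state@usedValency
    if (any(mine)) {
      for (i in which(mine)) {
        uv[b[i, 1L]] <- uv[b[i, 1L]] - b[i, 3L]
        uv[b[i, 2L]] <- uv[b[i, 2L]] - b[i, 3L]
      }
      b <- b[!mine, , drop = FALSE]
    }
    pos <- state@positions
    pos[p, ] <- tgt
    initialize(state, positions = pos, bonds = b, usedValency = uv)
  } else if (kind == "cluster_move") {
    lab <- labelClusters(state)
    ci <- lab@labels[event$a]
    members <- which(lab@labels == ci)
    if (length(members) < 2L)
      stop("infeasible event: cluster of size 1 cannot cluster_move")
    d <- event$direction
    pos <- state@positions
    newpos <- pos
    newpos[members, 1L] <- (pos[members, 1L] + .DR[[d]]) %% L
    newpos[members, 2L] <- (pos[members, 2L] + .DC[[d]]) %% L
    others <- setdiff(seq_len(nrow(pos)), members)
    if (length(others)) {
      occ <- paste(pos[others, 1L], pos[others, 2L])
      tgt <- paste(newpos[members, 1L], newpos[members, 2L])
      if (any(tgt %in% occ))
        stop("infeasible (stale) event: cluster translation collides")
    }
    initialize(state, positions = newpos)
  } else if (kind == "bond_form") {
    placeBond(state, event$a, event$b, params)
  } else if (kind == "bond_break") {
    removeBond(state, event$a, event$b)
  } else {
    stop("unknown event kind: ", kind)
  }
}

#' Run one Gillespie kMC trajectory
#'
#' Iterates \{enumerate feasible events, draw the exponential waiting time
#' (z2), draw the event (z1), apply it\} until the simulated time reaches
#' `tEnd(params)`.  The full event loop runs in compiled code with complete
#' re-enumeration after every event; the waiting-time and event draws come,
#' in that fixed order, from one dedicated 64-bit generator seeded from
#' `seed`, so identical seeds give identical trajectories.
#'
#' Summary rows (time, largest-cluster size, cluster count, total bond
#' multiplicity) are recorded at every multiple of the snapshot interval
#' plus `t = 0` and `t = tEnd`.  Monomer-exchange first-passage bookkeeping
#' (burial when a particle's occupied-neighbour count reaches 4, release
#' when it next reaches 0; burials still open at `tEnd` are censored) is
#' always performed.
#'
#' If no event is feasible the state is frozen forever; the run fills in the
#' remaining summary ticks, flags `earlyTermination` and warns.
#'
#' @param params a [SimParams-class].
#' @param seed integer seed; defaults to `simSeed(params)`.
#' @param init optional [LatticeState-class] to start from instead of a
#'   random placement (its bonds are kept).
#' @param storeSnapshots keep full [LatticeState-class] snapshots at every
#'   summary tick (memory-heavy for long runs; default `FALSE`).
#' @param recordEvents keep a log of every executed event
#'   (time, kind, payload); intended for small diagnostic runs.
#' @param maxEvents safety cap on the number of executed events.
#' @return A [Trajectory-class].
#' @examples
#' p <- SimParams(latticeSize = 20, nParticles = 12, valency = 5,
#'                epsSp = 2, tEnd = 50, snapshotInterval = 10, seed = 7)
#' tr <- runTrajectory(p)
#' trajectorySummary(tr)
#' @export
runTrajectory <- function(params, seed = simSeed(params), init = NULL,
                          storeSnapshots = FALSE, recordEvents = FALSE,
                          maxEvents = Inf) {
  stopifnot(is(params, "SimParams"))
  validObject(params)
  initPos <- NULL
  initBonds <- NULL
  if (!is.null(init)) {
    stopifnot(is(init, "LatticeState"))
    validObject(init)
    if (init@latticeSize != params@latticeSize ||
        nrow(init@positions) != params@nParticles)
      stop("init state does not match params (lattice size or particle count)")
    if (any(init@usedValency > params@valency))
      stop("init state uses more valency than params allow")
    initPos <- init@positions
    initBonds <- init@bonds
  }
  res <- cpp_run_trajectory(
    params@latticeSize, params@nParticles, params@valency, params@epsSp,
    params@epsNs, params@kDiff, params@kBond, params@tEnd, as.numeric(seed),
    params@snapshotInterval, .rateDivisor(params), storeSnapshots,
    recordEvents, initPos, initBonds,
    if (is.finite(maxEvents)) maxEvents else 1e18)

  summ <- data.frame(time = res$summaryTime,
                     largestCluster = res$summaryLargest,
                     nClusters = res$summaryNClusters,
                     nBonds = res$summaryNBonds)
  snaps <- lapply(res$snapshots, function(s)
    .newLatticeState(params@latticeSize, s$positions, s$bonds,
                     s$usedValency, s$time))
  xl <- res$exchange
  exchangeLog <- data.frame(particle = as.integer(xl$particle),
                            burial = as.numeric(xl$burial),
                            release = as.numeric(xl$release),
                            censored = as.integer(xl$censored) == 1L)
  eventLog <- NULL
  if (recordEvents) {
    kindName <- c("monomer_move", "cluster_move", "bond_form", "bond_break")
    el <- res$eventLog
    eventLog <- data.frame(time = as.numeric(el$time),
                           kind = kindName[as.integer(el$kind) + 1L],
                           a = as.integer(el$a), b = as.integer(el$b))
  }
  final <- .newLatticeState(params@latticeSize, res$finalPositions,
                            res$finalBonds, res$finalUsedValency,
                            res$finalTime)
  if (isTRUE(res$earlyTermination))
    warning("no feasible events remained; trajectory frozen before tEnd")
  if (isTRUE(res$truncated))
    warning("maxEvents cap reached before tEnd; trajectory truncated")
  new("Trajectory", params = params, summary = summ, snapshots = snaps,
      exchangeLog = exchangeLog, eventLog = eventLog,
      stats = list(nEvents = res$nEvents,
                   earlyTermination = isTRUE(res$earlyTermination),
                   truncated = isTRUE(res$truncated),
                   seed = as.integer(seed)),
      finalState = final)
}

#' @rdname Trajectory-class
#' @param x,object a `Trajectory`.
#' @export
setMethod("trajectorySummary", "Trajectory", function(x) x@summary)

#' @rdname Trajectory-class
#' @export
setMethod("snapshots", "Trajectory", function(x) x@snapshots)

#' @rdname Trajectory-class
#' @export
setMethod("finalState", "Trajectory", function(x) x@finalState)

#' @rdname Trajectory-class
#' @export
setMethod("simParams", "Trajectory", function(x) x@params)
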