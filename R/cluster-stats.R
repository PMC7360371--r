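#' @include AllClasses.R AllGenerics.R lattice-core.R
NULL

#' @rdname ClusterLabeling-class
#' @param x,object a `ClusterLabeling`.
#' @export
setMethod("clusterLabels", "ClusterLabeling", function(x) x@labels)

#' @rdname ClusterLabeling-class
#' @export
setMethod("clusterSizes", "ClusterLabeling", function(x) x@sizes)

#' @rdname ClusterLabeling-class
#' @export
setMethod("nClusters", "ClusterLabeling", function(x) x@nClusters)

setMethod("show", "ClusterLabeling", function(object) {
  cat(sprintf("ClusterLabeling: %d cluster(s) over %d particle(s); largest = %d\n",
              object@nClusters, length(object@labels),
              if (object@nClusters) object@sizes[1L] else 0L))
})

#' Hoshen-Kopelman labelling of occupied sites
#'
#' Labels the adjacency-connected components of occupied sites (von Neumann
#' neighbourhood, periodic wrap) with a union-find / Hoshen-Kopelman pass in
#' compiled code.  Labels are canonicalized — decreasing size, ties broken
#' by smallest member id — so the partition is reproducible and invariant
#' under particle-id relabelling up to that convention.
#'
#' @param state a [LatticeState-class].
#' @return A [ClusterLabeling-class].
#' @examples
#' p <- SimParams(latticeSize = 10, nParticles = 8, tEnd = 1)
#' labelClusters(initLattice(p, seed = 3))
#' @export
labelClusters <- function(state) {
  stopifnot(is(state, "LatticeState"))
  res <- cpp_label_clusters(state@positions[, 1L], state@positions[, 2L],
                            state@latticeSize)
  new("ClusterLabeling", labels = as.integer(res$labels),
      sizes = as.integer(res$sizes), nClusters = as.integer(res$nClusters))
}

#' Largest-cluster fraction L_clus
#'
#' Size of the single largest cluster as a fraction of the total particle
#' count.  \eqn{L_{clus} \to 1} marks a system-spanning macrophase; many
#' coexisting clusters with \eqn{S_{clus} \ll N_{tot}} mark the metastable
#' microphase.
#'
#' @param labeling a [ClusterLabeling-class].
#' @param nTot total particle count (defaults to the labelled count).
#' @return A number in (0, 1].
#' @export
largestClusterFraction <- function(labeling, nTot = length(clusterLabels(labeling))) {
  stopifnot(is(labeling, "ClusterLabeling"), nTot > 0)
  max(labeling@sizes) / nTot
}

#' Pooled cluster-size distribution
#'
#' Histogram of normalized cluster sizes \eqn{S_{clus}/N_{tot}} pooled over
#' every snapshot (of every trajectory) whose time falls inside `tWindow`.
#' Each cluster present in a snapshot contributes one count; probabilities
#' sum to 1.
#'
#' @param trajectories a [Trajectory-class], a list of them, or a list of
#'   [LatticeState-class] snapshots.  Trajectories must have been run with
#'   `storeSnapshots = TRUE`.
#' @param tWindow numeric length-2 window `[t0, t1]` of simulated seconds.
#' @param nBins number of equal bins on (0, 1].
#' @return A data.frame with `binLow`, `binHigh`, `probability`.
#' @export
clusterSizeDistribution <- function(trajectories, tWindow = c(0, Inf),
                                    nBins = 20L) {
  if (is(trajectories, "Trajectory")) trajectories <- list(trajectories)
  states <- list()
  for (tr in trajectories) {
    if (is(tr, "Trajectory")) {
      if (!length(tr@snapshots))
        stop("trajectory has no stored snapshots; rerun with storeSnapshots = TRUE")
      states <- c(states, tr@snapshots)
    } else if (is(tr, "LatticeState")) {
      states <- c(states, list(tr))
    } else stop("unsupported input type")
  }
  keep <- vapply(states, function(s) {
    t <- simTime(s); t >= tWindow[1L] && t <= tWindow[2L]
  }, logical(1))
  states <- states[keep]
  if (!length(states)) stop("no snapshots fall inside the requested time window")
  frac <- unlist(lapply(states, function(s) {
    lab <- labelClusters(s)
    lab@sizes / nParticles(s)
  }))
  edges <- seq(0, 1, length.out = nBins + 1L)
  counts <- tabulate(findInterval(frac, edges, left.open = TRUE,
                                  rightmost.closed = TRUE), nbins = nBins)
  data.frame(binLow = edges[-length(edges)], binHigh = edges[-1L],
             probability = counts / sum(counts))
}

# unwrap one cluster across the periodic seam by BFS with minimal-image steps
.unwrapCluster <- function(state, members) {
  L <- state@latticeSize
  pos <- state@positions[members, , drop = FALSE]
  n <- nrow(pos)
  key <- pos[, 1L] * L + pos[, 2L]
  lookup <- seq_len(n)
  names(lookup) <- as.character(key)
  un <- matrix(NA_real_, n, 2L)
  un[1L, ] <- pos[1L, ]
  queue <- 1L
  visited <- c(TRUE, rep(FALSE, n - 1L))
  dr <- c(-1L, 1L, 0L, 0L)
  dc <- c(0L, 0L, 1L, -1L)
  while (length(queue)) {
    i <- queue[1L]; queue <- queue[-1L]
    for (d in 1:4) {
      nrw <- (pos[i, 1L] + dr[d]) %% L
      ncl <- (pos[i, 2L] + dc[d]) %% L
      j <- lookup[as.character(nrw * L + ncl)]
      if (!is.na(j) && !visited[j]) {
        visited[j] <- TRUE
        un[j, ] <- un[i, ] + c(dr[d], dc[d])
        queue <- c(queue, j)
      }
    }
  }
  un
}

#' Normalized intra-cluster density phi_clus / phi_lattice
#'
#' 2D density of one cluster via its gyration disk,
#' \eqn{\phi_{clus} = S_{clus} / (\pi R_g^2)} with \eqn{R_g} the radius of
#' gyration of the member sites (lattice constant 1), normalized by the
#' bulk density \eqn{\phi_{lattice} = N_{tot}/L^2}.  Values \eqn{\gg 1}
#' indicate dense droplets; system-spanning networks approach 1.  The
#' cluster is unwrapped across the periodic seam before the centroid is
#' taken, so the value is translation-invariant.
#'
#' Clusters of fewer than 4 particles return `NA` (degenerate gyration
#' radius), as do percolating clusters — those spanning at least L/2 along
#' either axis — which carry a `percolating` attribute.
#'
#' @param state a [LatticeState-class].
#' @param labeling a [ClusterLabeling-class] for `state`.
#' @param cluster canonical cluster label (1 = largest).
#' @return `phi_clus / phi_lattice`, or `NA` (see above).
#' @export
clusterDensity <- function(state, labeling, cluster) {
  stopifnot(is(state, "LatticeState"), is(labeling, "ClusterLabeling"))
  if (cluster < 1L || cluster > labeling@nClusters)
    stop("no such cluster label: ", cluster)
  members <- which(labeling@labels == cluster)
  if (length(members) < 4L) return(NA_real_)
  un <- .unwrapCluster(state, members)
  L <- state@latticeSize
  span <- apply(un, 2L, function(v) max(v) - min(v) + 1)
  if (any(span >= L / 2)) {
    out <- NA_real_
    attr(out, "percolating") <- TRUE
    return(out)
  }
  ctr <- colMeans(un)
  rg2 <- mean((un[, 1L] - ctr[1L])^2 + (un[, 2L] - ctr[2L])^2)
  phiClus <- length(members) / (pi * rg2)
  phiLat <- nParticles(state) / L^2
  phiClus / phiLat
}

#' @rdname clusterDensity
#' @return `clusterDensities()` returns the vector over all clusters.
#' @export
clusterDensities <- function(state, labeling = labelClusters(state)) {
  vapply(seq_len(labeling@nClusters),
         function(ci) as.numeric(clusterDensity(state, labeling, ci)),
         numeric(1))
}
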