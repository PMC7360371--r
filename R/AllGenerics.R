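#' @include AllClasses.R
NULL

#' @rdname SimParams-class
#' @export
setGeneric("latticeSize", function(x) standardGeneric("latticeSize"))

#' @rdname SimParams-class
#' @export
setGeneric("nParticles", function(x) standardGeneric("nParticles"))

#' @rdname SimParams-class
#' @export
setGeneric("valency", function(x) standardGeneric("valency"))

#' @rdname SimParams-class
#' @export
setGeneric("epsSp", function(x) standardGeneric("epsSp"))

#' @rdname SimParams-class
#' @export
setGeneric("epsNs", function(x) standardGeneric("epsNs"))

#' @rdname SimParams-class
#' @export
setGeneric("kDiff", function(x) standardGeneric("kDiff"))

#' @rdname SimParams-class
#' @export
setGeneric("kBond", function(x) standardGeneric("kBond"))

#' @rdname SimParams-class
#' @export
setGeneric("kBreak", function(x) standardGeneric("kBreak"))

#' @rdname SimParams-class
#' @export
setGeneric("phiLattice", function(x) standardGeneric("phiLattice"))

#' @rdname SimParams-class
#' @export
setGeneric("tEnd", function(x) standardGeneric("tEnd"))

#' @rdname SimParams-class
#' @export
setGeneric("simSeed", function(x) standardGeneric("simSeed"))

#' @rdname LatticeState-class
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname LatticeState-class
#' @export
setGeneric("bonds", function(x) standardGeneric("bonds"))

#' @rdname LatticeState-class
#' @export
setGeneric("usedValency", function(x) standardGeneric("usedValency"))

#' @rdname LatticeState-class
#' @export
setGeneric("simTime", function(x) standardGeneric("simTime"))

#' @rdname LatticeState-class
#' @export
setGeneric("occupancyGrid", function(x) standardGeneric("occupancyGrid"))

#' @rdname EventSet-class
#' @export
setGeneric("eventTable", function(x) standardGeneric("eventTable"))

#' @rdname EventSet-class
#' @export
setGeneric("rTotal", function(x) standardGeneric("rTotal"))

#' @rdname ClusterLabeling-class
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname ClusterLabeling-class
#' @export
setGeneric("clusterSizes", function(x) standardGeneric("clusterSizes"))

#' @rdname ClusterLabeling-class
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname Trajectory-class
#' @export
setGeneric("trajectorySummary", function(x) standardGeneric("trajectorySummary"))

#' @rdname Trajectory-class
#' @export
setGeneric("snapshots", function(x) standardGeneric("snapshots"))

#' @rdname Trajectory-class
#' @export
setGeneric("finalState", function(x) standardGeneric("finalState"))

#' @rdname Trajectory-class
#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))
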