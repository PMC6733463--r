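#' Number of regions of an object
#' @param object a PairwiseModel, StateSeries, StateDistribution or
#'   EnergyLandscape.
#' @return integer N.
#' @export
setGeneric("nRegions", function(object) standardGeneric("nRegions"))

#' Baseline sensitivities H of a model
#' @param object a PairwiseModel.
#' @return numeric vector of length N.
#' @export
setGeneric("biasField", function(object) standardGeneric("biasField"))

#' Pairwise coupling matrix J of a model
#' @param object a PairwiseModel.
#' @return N x N symmetric matrix.
#' @export
setGeneric("couplingMatrix", function(object) standardGeneric("couplingMatrix"))

#' Region labels
#' @param object a PairwiseModel or StateSeries.
#' @return character vector.
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))

#' Binary state matrix of a series
#' @param object a StateSeries.
#' @return T x N integer matrix.
#' @export
setGeneric("stateMatrix", function(object) standardGeneric("stateMatrix"))

#' State probabilities
#' @param object a StateDistribution.
#' @return numeric vector of length 2^N indexed by state code + 1.
#' @export
setGeneric("stateProbs", function(object) standardGeneric("stateProbs"))

#' Energies over the full state space
#' @param object an EnergyLandscape.
#' @return numeric vector of length 2^N indexed by state code + 1.
#' @export
setGeneric("energies", function(object) standardGeneric("energies"))

#' Local minima of a landscape
#' @param object an EnergyLandscape.
#' @return integer state codes sorted by energy (ascending).
#' @export
setGeneric("localMinima", function(object) standardGeneric("localMinima"))

#' Global minimum of a landscape
#' @param object an EnergyLandscape.
#' @return integer state code.
#' @export
setGeneric("globalMinimum", function(object) standardGeneric("globalMinimum"))

#' Underlying igraph of a transition network
#' @param object a TransitionNetwork.
#' @return an igraph object.
#' @export
setGeneric("networkGraph", function(object) standardGeneric("networkGraph"))

#' Pathways underlying a transition network
#' @param object a TransitionNetwork.
#' @return list of TransitionPath objects.
#' @export
setGeneric("pathList", function(object) standardGeneric("pathList"))

setMethod("nRegions", "PairwiseModel", function(object) object@nRegions)
setMethod("nRegions", "StateSeries", function(object) ncol(object@states))
setMethod("nRegions", "StateDistribution", function(object) object@nRegions)
setMethod("nRegions", "EnergyLandscape", function(object) object@nRegions)

setMethod("biasField", "PairwiseModel", function(object) object@h)
setMethod("couplingMatrix", "PairwiseModel", function(object) object@j)
setMethod("regionLabels", "PairwiseModel", function(object) object@regionLabels)
setMethod("regionLabels", "StateSeries", function(object) colnames(object@states))
setMethod("stateMatrix", "StateSeries", function(object) object@states)
setMethod("stateProbs", "StateDistribution", function(object) object@probs)
setMethod("energies", "EnergyLandscape", function(object) object@energies)
setMethod("localMinima", "EnergyLandscape", function(object) object@localMinima)
setMethod("globalMinimum", "EnergyLandscape", function(object) object@globalMinimum)
setMethod("networkGraph", "TransitionNetwork", function(object) object@graph)
setMethod("pathList", "TransitionNetwork", function(object) object@paths)
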