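#' @import methods
NULL

.MAX_ENUM_N <- 20L

#' PairwiseModel: a pairwise maximum-entropy (Ising) model on N binary regions
#'
#' The model assigns every N-bit activity pattern \eqn{V} an energy
#' \deqn{E(V) = -\sum_i H_i \sigma_i - \sum_{i<j} J_{ij} \sigma_i \sigma_j,}
#' where \eqn{\sigma_i \in \{0,1\}} is the activity of region i, \eqn{H_i} is
#' the baseline activation tendency of region i and \eqn{J_{ij}} the symmetric
#' pairwise interaction. State probabilities follow the Boltzmann distribution
#' \eqn{p(V) \propto e^{-E(V)}}.
#'
#' @slot nRegions integer, number of regions N.
#' @slot h numeric vector of N baseline sensitivities.
#' @slot j N x N symmetric numeric matrix of pairwise couplings, zero diagonal.
#' @slot regionLabels character vector of N region names.
#'
#' @exportClass PairwiseModel
setClass("PairwiseModel",
  representation(
    nRegions = "integer",
    h = "numeric",
    j = "matrix",
    regionLabels = "character"
  )
)

setValidity("PairwiseModel", function(object) {
  n <- object@nRegions
  if (length(n) != 1L || is.na(n) || n < 1L)
    return("nRegions must be a single positive integer")
  if (length(object@h) != n)
    return(sprintf("h must have length %d", n))
  j <- object@j
  if (!is.numeric(j) || !identical(dim(j), c(as.integer(n), as.integer(n))))
    return(sprintf("j must be a %d x %d numeric matrix", n, n))
  if (any(!is.finite(object@h)) || any(!is.finite(j)))
    return("model parameters must be finite")
  if (!isTRUE(all.equal(j, t(j), tolerance = 0)))
    return("j must be exactly symmetric")
  if (any(diag(j) != 0))
    return("diagonal of j must be exactly zero")
  if (length(object@regionLabels) != n)
    return(sprintf("regionLabels must have length %d", n))
  TRUE
})

#' Construct a PairwiseModel
#'
#' @param h numeric vector of baseline sensitivities H.
#' @param j symmetric numeric coupling matrix J with zero diagonal.
#' @param regionLabels optional character vector of region names; defaults to
#'   \code{R1..RN}.
#' @return A \linkS4class{PairwiseModel}.
#' @examples
#' m <- PairwiseModel(h = c(1, -1), j = matrix(c(0, 0.5, 0.5, 0), 2))
#' stateEnergy(m, c(1, 1))
#' @export
PairwiseModel <- function(h, j, regionLabels = NULL) {
  n <- length(h)
  j <- as.matrix(j)
  storage.mode(j) <- "double"
  if (is.null(regionLabels)) regionLabels <- paste0("R", seq_len(n))
  new("PairwiseModel", nRegions = as.integer(n), h = as.numeric(h), j = j,
      regionLabels = as.character(regionLabels))
}

setMethod("show", "PairwiseModel", function(object) {
  cat(sprintf("PairwiseModel with %d regions\n", object@nRegions))
  cat(sprintf("  mean |H| = %.4g, mean |J| (off-diag) = %.4g\n",
              mean(abs(object@h)),
              mean(abs(object@j[upper.tri(object@j)]))))
  cat("  regions:", paste(utils::head(object@regionLabels, 8L),
                          collapse = ", "),
      if (object@nRegions > 8L) "..." else "", "\n")
})

#' StateSeries: a binary multivariate time series
#'
#' Rows are time points, columns are regions; entries are 0 (deactive) or
#' 1 (active).
#'
#' @slot states T x N integer matrix with entries in {0, 1}.
#' @exportClass StateSeries
setClass("StateSeries", representation(states = "matrix"))

setValidity("StateSeries", function(object) {
  s <- object@states
  if (!is.numeric(s)) return("states must be a numeric/integer matrix")
  if (nrow(s) < 1L) return("series must contain at least one time point")
  if (any(is.na(s)) || any(s != 0L & s != 1L))
    return("all entries must be 0 or 1")
  TRUE
})

#' Construct a StateSeries from a binary matrix
#'
#' @param states T x N matrix of 0/1 values; column names are kept as region
#'   labels.
#' @return A \linkS4class{StateSeries}.
#' @export
StateSeries <- function(states) {
  states <- as.matrix(states)
  storage.mode(states) <- "integer"
  if (is.null(colnames(states)))
    colnames(states) <- paste0("R", seq_len(ncol(states)))
  new("StateSeries", states = states)
}

setMethod("show", "StateSeries", function(object) {
  cat(sprintf("StateSeries: %d time points x %d regions (activity rate %.3f)\n",
              nrow(object@states), ncol(object@states), mean(object@states)))
})

#' MomentSet: first and second moments of binary activity
#'
#' Holds the per-region activation rates \eqn{\langle\sigma_i\rangle} and the
#' pairwise co-activation rates \eqn{\langle\sigma_i\sigma_j\rangle}, either
#' empirical (time averages) or model-implied (Boltzmann expectations).
#'
#' @slot first numeric vector of N means.
#' @slot second N x N symmetric matrix of pairwise product expectations;
#'   the diagonal equals \code{first} (since \eqn{\sigma_i^2 = \sigma_i}).
#' @exportClass MomentSet
setClass("MomentSet", representation(first = "numeric", second = "matrix"))

setValidity("MomentSet", function(object) {
  n <- length(object@first)
  if (!identical(dim(object@second), c(n, n)))
    return("second must be an N x N matrix")
  if (any(object@first < 0 | object@first > 1))
    return("first moments must lie in [0, 1]")
  TRUE
})

#' StateDistribution: a probability distribution over all 2^N states
#'
#' @slot probs numeric vector of length 2^N indexed by state code + 1.
#' @slot nRegions integer N.
#' @exportClass StateDistribution
setClass("StateDistribution",
         representation(probs = "numeric", nRegions = "integer"))

setValidity("StateDistribution", function(object) {
  if (length(object@probs) != 2^object@nRegions)
    return("probs must have length 2^N")
  if (any(object@probs < 0)) return("probabilities must be non-negative")
  if (abs(sum(object@probs) - 1) > 1e-12)
    return("probabilities must sum to 1 within 1e-12")
  TRUE
})

setMethod("show", "StateDistribution", function(object) {
  cat(sprintf("StateDistribution over %d states (N = %d); max p = %.4g at code %d\n",
              length(object@probs), object@nRegions,
              max(object@probs), which.max(object@probs) - 1L))
})

#' FitResult: outcome of the gradient-ascent pairwise model fit
#'
#' @slot model the fitted \linkS4class{PairwiseModel}.
#' @slot nIterations number of update iterations performed.
#' @slot converged TRUE if the maximum absolute log-ratio term fell below the
#'   tolerance before the iteration cap.
#' @slot finalGradientNorm the maximum absolute log-ratio term at the last
#'   iteration.
#' @exportClass FitResult
setClass("FitResult",
  representation(model = "PairwiseModel", nIterations = "integer",
                 converged = "logical", finalGradientNorm = "numeric"))

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: %s after %d iterations (max |log ratio| = %.3g)\n",
              if (object@converged) "converged" else "NOT converged",
              object@nIterations, object@finalGradientNorm))
})

#' FitMetrics: accuracy and reliability of the pairwise fit
#'
#' Compares the first-order (independent) and second-order (pairwise) models
#' against the empirical state distribution: Kullback-Leibler divergences
#' \eqn{D_1, D_2}, entropies \eqn{S_1, S_2, S_N}, accuracy
#' \eqn{r_D = (D_1 - D_2)/D_1}, entropy ratio
#' \eqn{r_S = (S_1 - S_2)/(S_1 - S_N)} and reliability \eqn{ER}.
#'
#' @slot d1,d2 Kullback-Leibler divergences of the two model orders.
#' @slot s1,s2,sN entropies of the independent model, pairwise model and
#'   empirical distribution (natural log).
#' @slot rD,rS,er the derived accuracy, entropy-ratio and reliability metrics.
#' @exportClass FitMetrics
setClass("FitMetrics",
  representation(d1 = "numeric", d2 = "numeric", s1 = "numeric",
                 s2 = "numeric", sN = "numeric", rD = "numeric",
                 rS = "numeric", er = "numeric"))

setMethod("show", "FitMetrics", function(object) {
  cat(sprintf("FitMetrics: r_D = %.4f, r_S = %.4f, ER = %.4f\n",
              object@rD, object@rS, object@er))
  cat(sprintf("  D1 = %.4g, D2 = %.4g; S1 = %.4g, S2 = %.4g, SN = %.4g\n",
              object@d1, object@d2, object@s1, object@s2, object@sN))
})

#' GeneratorConfig: settings for the synthetic ground-truth generator
#'
#' @slot nRegions number of binary channels (2..20).
#' @slot structure one of "random", "two_community", "ferromagnetic".
#' @slot hScale standard deviation of the baseline-field noise.
#' @slot jScale scale of the coupling magnitudes.
#' @slot density probability that any given pair is coupled at all; values
#'   below 1 give the heterogeneous, weak-link landscapes on which multiple
#'   stable states coexist.
#' @slot communityAssignment integer vector of community ids (1 or 2) per
#'   region; only used by the two_community structure.
#' @slot seed RNG seed making the draw reproducible.
#' @exportClass GeneratorConfig
setClass("GeneratorConfig",
  representation(nRegions = "integer", structure = "character",
                 hScale = "numeric", jScale = "numeric",
                 density = "numeric",
                 communityAssignment = "integer", seed = "integer"))

setValidity("GeneratorConfig", function(object) {
  if (object@nRegions < 2L || object@nRegions > .MAX_ENUM_N)
    return("nRegions must be in [2, 20]")
  if (!object@structure %in% c("random", "two_community", "ferromagnetic"))
    return("structure must be random, two_community or ferromagnetic")
  if (object@hScale < 0 || object@jScale < 0)
    return("scales must be non-negative")
  if (object@density < 0 || object@density > 1)
    return("density must lie in [0, 1]")
  if (length(object@communityAssignment) &&
      length(object@communityAssignment) != object@nRegions)
    return("communityAssignment must have one entry per region")
  TRUE
})

#' Construct a GeneratorConfig
#'
#' Defaults describe the condition the synthetic module emulates: a system of
#' around ten binary channels whose couplings are organized into two
#' communities (positive within, negative between), producing a multistable
#' landscape whose local minima occur in complementary pairs.
#'
#' @param nRegions number of regions (default 10).
#' @param structure coupling topology: "two_community" (default), "random" or
#'   "ferromagnetic".
#' @param hScale sd of the baseline-field noise around the flip-symmetric
#'   point (default 0.05).
#' @param jScale scale of coupling magnitudes (default 0.5).
#' @param density probability that a pair is coupled (default 0.6); missing
#'   links create the weakly bound substructures that carry secondary stable
#'   states.
#' @param communityAssignment optional integer vector of 1/2 community labels;
#'   default splits the regions into two equal halves.
#' @param seed integer RNG seed (default 1).
#' @return A \linkS4class{GeneratorConfig}.
#' @export
generatorConfig <- function(nRegions = 10L,
                            structure = c("two_community", "random",
                                          "ferromagnetic"),
                            hScale = 0.05, jScale = 0.5, density = 0.6,
                            communityAssignment = NULL, seed = 1L) {
  structure <- match.arg(structure)
  if (is.null(communityAssignment)) {
    communityAssignment <- if (structure == "two_community")
      rep(1:2, c(ceiling(nRegions / 2), floor(nRegions / 2)))
    else integer(0)
  }
  new("GeneratorConfig", nRegions = as.integer(nRegions),
      structure = structure, hScale = hScale, jScale = jScale,
      density = density,
      communityAssignment = as.integer(communityAssignment),
      seed = as.integer(seed))
}

#' EnergyLandscape: energies of all states plus the local minima
#'
#' A state is a local minimum (stable state, attractor) when its energy is
#' strictly lower than the energies of all N single-bit-flip neighbors.
#'
#' @slot energies numeric vector of 2^N energies indexed by state code + 1.
#' @slot localMinima integer state codes of the local minima, sorted by
#'   energy (ascending).
#' @slot globalMinimum state code of the lowest-energy minimum.
#' @slot nRegions integer N.
#' @exportClass EnergyLandscape
setClass("EnergyLandscape",
  representation(energies = "numeric", localMinima = "integer",
                 globalMinimum = "integer", nRegions = "integer"))

setMethod("show", "EnergyLandscape", function(object) {
  cat(sprintf("EnergyLandscape: N = %d, %d local minima; global minimum code %d (E = %.4f)\n",
              object@nRegions, length(object@localMinima),
              object@globalMinimum,
              object@energies[object@globalMinimum + 1L]))
})

#' BarrierSet: pairwise threshold energies and barriers between local minima
#'
#' For minima i and j, the threshold \eqn{E_{th}(i,j)} is the minimax
#' (bottleneck) energy over all single-flip paths between them; the pair
#' barrier is \eqn{E_B = E_{th} - \max(E_i, E_j)} and the directed barrier
#' from i is \eqn{E_{th} - E_i}.
#'
#' @slot minima integer codes of the local minima (row/column order).
#' @slot minimaEnergies energies of those minima.
#' @slot thresholds symmetric matrix of E_th values (NA diagonal).
#' @slot barriers symmetric matrix of pair barriers.
#' @slot directedBarriers matrix with entry [i, j] = E_th(i,j) - E_i.
#' @exportClass BarrierSet
setClass("BarrierSet",
  representation(minima = "integer", minimaEnergies = "numeric",
                 thresholds = "matrix", barriers = "matrix",
                 directedBarriers = "matrix"))

setMethod("show", "BarrierSet", function(object) {
  m <- length(object@minima)
  cat(sprintf("BarrierSet over %d local minima (%d pairs)\n", m, choose(m, 2)))
  if (m >= 2L)
    cat(sprintf("  pair barriers: min %.4f, median %.4f, max %.4f\n",
                min(object@barriers[upper.tri(object@barriers)]),
                stats::median(object@barriers[upper.tri(object@barriers)]),
                max(object@barriers[upper.tri(object@barriers)])))
})

#' DisconnectivityTree: single-linkage merge structure of minima basins
#'
#' Summarizes the threshold energies at which the basins of local minima
#' become connected as the landscape is filled from below. Stored as an
#' hclust-compatible merge structure whose cophenetic heights reproduce the
#' pairwise thresholds exactly (bottleneck distances are ultrametric).
#'
#' @slot hclust the merge structure (a base-R \code{hclust} object in a list
#'   slot).
#' @slot leafEnergies energies of the minima at the leaves.
#' @slot minima integer codes of the leaves, in \code{hclust$labels} order.
#' @exportClass DisconnectivityTree
setClass("DisconnectivityTree",
  representation(hclust = "list", leafEnergies = "numeric",
                 minima = "integer"))

setMethod("show", "DisconnectivityTree", function(object) {
  cat(sprintf("DisconnectivityTree over %d minima; merge thresholds in [%.4f, %.4f]\n",
              length(object@minima), min(object@hclust$height),
              max(object@hclust$height)))
})

#' TransitionPath: a minimax single-flip path between two local minima
#'
#' The path connects the higher-energy minimum (source) to the lower-energy
#' one (target), flipping one bit per step, and attains the pair's bottleneck
#' threshold energy. The highest-energy state on the path is the
#' rate-determining transition state (TS); the barrier from the source is
#' \eqn{E_B = E_{th} - E(source)} and sets the transition rate
#' \eqn{e^{-E_B}}.
#'
#' @slot sourceLM,targetLM state codes of the endpoints (source has the
#'   higher energy).
#' @slot states integer codes along the path, consecutive states one bit
#'   apart.
#' @slot eTh threshold (maximum) energy along the path.
#' @slot eB barrier from the source.
#' @slot tsCode code of the rate-determining transition state.
#' @slot intermediates codes of local minima strictly inside the path.
#' @exportClass TransitionPath
setClass("TransitionPath",
  representation(sourceLM = "integer", targetLM = "integer",
                 states = "integer", eTh = "numeric", eB = "numeric",
                 tsCode = "integer", intermediates = "integer"))

setMethod("show", "TransitionPath", function(object) {
  cat(sprintf("TransitionPath %d -> %d: %d steps, E_th = %.4f, E_B = %.4f, TS = %d\n",
              object@sourceLM, object@targetLM,
              length(object@states) - 1L, object@eTh, object@eB,
              object@tsCode))
})

#' TransitionNetwork: a directed weighted state-transition network
#'
#' Three variants are built from the minimax pathways between local minima:
#' \describe{
#'   \item{FS}{all states on all pairwise pathways (full-state network);}
#'   \item{GM}{the subnetwork of pathways that terminate at the global
#'     minimum;}
#'   \item{LM}{local minima and rate-determining transition states only.}
#' }
#' Nodes carry a role (local_minimum, transition_state or transient) and
#' edges carry the pathway transition rate \eqn{e^{-E_B}}.
#'
#' @slot variant "FS", "GM" or "LM".
#' @slot graph the underlying \pkg{igraph} directed graph.
#' @slot paths list of the \linkS4class{TransitionPath} objects the network
#'   was assembled from.
#' @exportClass TransitionNetwork
setClass("TransitionNetwork",
  representation(variant = "character", graph = "ANY", paths = "list"))

setMethod("show", "TransitionNetwork", function(object) {
  g <- object@graph
  cat(sprintf("TransitionNetwork (STN-%s): %d nodes, %d edges, %d pathways\n",
              object@variant, igraph::vcount(g), igraph::ecount(g),
              length(object@paths)))
  roles <- table(igraph::V(g)$role)
  cat("  roles:", paste(names(roles), roles, sep = "=", collapse = ", "), "\n")
})

#' ClusterResult: UPGMA grouping of local minima
#'
#' @slot hclust the UPGMA merge structure (base-R \code{hclust} in a list
#'   slot).
#' @slot groups named integer vector mapping minimum code (name) to group id
#'   at the chosen cut.
#' @slot mode "barrier" or "rate" (which pairwise matrix fed the features).
#' @exportClass ClusterResult
setClass("ClusterResult",
  representation(hclust = "list", groups = "integer", mode = "character"))

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult (%s mode): %d minima in %d groups\n",
              object@mode, length(object@groups),
              length(unique(object@groups))))
})

#' PerturbationSweep: landscape and network summaries across coupling scales
#'
#' For each scale factor alpha, all couplings J are replaced by alpha * J and
#' the landscape and (when at least two minima survive) the full-state
#' transition network are recomputed.
#'
#' @slot alphas the scale grid.
#' @slot minimaCounts number of local minima per alpha.
#' @slot summaries data.frame with one row per alpha: nodes, edges, maxDegree
#'   (NA when fewer than two minima).
#' @slot eplHistograms list (per alpha) of effective-path-length frequency
#'   tables.
#' @exportClass PerturbationSweep
setClass("PerturbationSweep",
  representation(alphas = "numeric", minimaCounts = "integer",
                 summaries = "data.frame", eplHistograms = "list"))

setMethod("show", "PerturbationSweep", function(object) {
  cat(sprintf("PerturbationSweep over %d scale factors in [%.2f, %.2f]\n",
              length(object@alphas), min(object@alphas), max(object@alphas)))
  cat(sprintf("  minima counts: min %d, max %d (max at alpha = %s)\n",
              min(object@minimaCounts), max(object@minimaCounts),
              paste(object@alphas[object@minimaCounts ==
                                  max(object@minimaCounts)],
                    collapse = ", ")))
})
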