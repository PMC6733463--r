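# Synthetic ground-truth models and binary/continuous surrogate time series.
#
# The generator emulates the statistical structure the landscape analysis
# assumes: ~10-20 binary channels sampled from the Boltzmann distribution of
# a pairwise model whose couplings are mostly organized into two communities
# (positive within, negative between), which yields a multistable landscape
# whose local minima occur in complementary pairs.

#' Generate a ground-truth pairwise model
#'
#' Three coupling structures are available:
#' \describe{
#'   \item{two_community}{couplings are positive within each of two
#'     communities (\eqn{|N(0, jScale)|}) and negative between them
#'     (\eqn{-|N(0, jScale)|});}
#'   \item{ferromagnetic}{all couplings non-negative (\eqn{|N(0, jScale)|});}
#'   \item{random}{couplings of either sign (\eqn{N(0, jScale)}).}
#' }
#' In every structure each pair is coupled only with probability
#' \code{density}; a fully coupled two-community system is gauge-equivalent
#' to a homogeneous ferromagnet and supports only the two community ground
#' states, whereas missing and weak links carry the domain substructure on
#' which additional stable states (and their complements) appear.
#'
#' For the two structured topologies, the baseline field is centered on the
#' flip-symmetric point \eqn{H_i = -\frac{1}{2}\sum_j J_{ij}} (the point at
#' which the equivalent plus/minus-one spin system has zero external field)
#' plus \eqn{N(0, hScale)} noise. Near that point the landscape is nearly
#' invariant under global activity inversion, so local minima occur in
#' complementary pairs --- the phenomenology the downstream analyses probe.
#' For the random structure, \eqn{H_i \sim N(0, hScale)} directly.
#'
#' @param config a \linkS4class{GeneratorConfig}.
#' @return A \linkS4class{PairwiseModel}; deterministic given
#'   \code{config@seed}.
#' @examples
#' m <- makeModel(generatorConfig(nRegions = 8, seed = 1))
#' findLocalMinima(m)
#' @export
makeModel <- function(config) {
  stopifnot(is(config, "GeneratorConfig"))
  validObject(config)
  n <- config@nRegions
  .withSeed(config@seed, {
    j <- matrix(0, n, n)
    up <- which(upper.tri(j), arr.ind = TRUE)
    raw <- stats::rnorm(nrow(up), 0, config@jScale)
    vals <- switch(config@structure,
      random = raw,
      ferromagnetic = abs(raw),
      two_community = {
        comm <- config@communityAssignment
        same <- comm[up[, 1]] == comm[up[, 2]]
        ifelse(same, abs(raw), -abs(raw))
      })
    vals <- vals * stats::rbinom(nrow(up), 1L, config@density)
    j[upper.tri(j)] <- vals
    j <- j + t(j)
    h <- if (config@structure == "random")
      stats::rnorm(n, 0, config@hScale)
    else
      -0.5 * rowSums(j) + stats::rnorm(n, 0, config@hScale)
    PairwiseModel(h = h, j = j)
  })
}

#' Draw i.i.d. samples from a model's Boltzmann distribution
#'
#' Exact sampling by inversion over the enumerated state probabilities.
#'
#' @param model a \linkS4class{PairwiseModel} with N <= 20.
#' @param nSamples number of time points T.
#' @param seed RNG seed.
#' @return A \linkS4class{StateSeries} of T i.i.d. states.
#' @export
sampleExact <- function(model, nSamples, seed = 1L) {
  p <- boltzmannDistribution(model)@probs
  codes <- .withSeed(seed,
    sample.int(length(p), nSamples, replace = TRUE, prob = p) - 1L)
  .seriesFromCodes(codes, model@nRegions, model@regionLabels)
}

.seriesFromCodes <- function(codes, nRegions, labels = NULL) {
  s <- vapply(seq_len(nRegions),
              function(i) bitwAnd(bitwShiftR(codes, i - 1L), 1L),
              integer(length(codes)))
  if (length(codes) == 1L) s <- matrix(s, nrow = 1L)
  colnames(s) <- if (is.null(labels)) paste0("R", seq_len(nRegions)) else labels
  StateSeries(s)
}

# One Gibbs chain under the caller's current RNG state; sequential site
# sweeps, conditional p(sigma_i = 1 | rest) = logistic(H_i + sum_j J_ij s_j).
.gibbsChain <- function(model, nSamples, burnIn, thin) {
  n <- model@nRegions
  h <- model@h
  j <- model@j
  nSweeps <- burnIn + nSamples * thin
  state <- as.numeric(stats::runif(n) < 0.5)
  u <- matrix(stats::runif(nSweeps * n), nrow = n)
  out <- matrix(0L, nrow = nSamples, ncol = n)
  keep <- 0L
  for (sw in seq_len(nSweeps)) {
    for (i in seq_len(n)) {
      field <- h[i] + sum(j[, i] * state)
      state[i] <- as.numeric(u[i, sw] < 1 / (1 + exp(-field)))
    }
    if (sw > burnIn && (sw - burnIn) %% thin == 0L) {
      keep <- keep + 1L
      out[keep, ] <- as.integer(state)
    }
  }
  colnames(out) <- model@regionLabels
  out
}

#' Sample a temporally correlated series by single-site Gibbs sweeps
#'
#' Provides an autocorrelated surrogate for empirical state sequences (e.g.
#' slow imaging time series), in contrast to the i.i.d. draws of
#' [sampleExact()]. The chain's stationary distribution is the model's
#' Boltzmann distribution.
#'
#' @param model a \linkS4class{PairwiseModel}.
#' @param nSamples number of retained time points.
#' @param burnIn sweeps discarded before retention (default 1000).
#' @param thin retain every thin-th sweep (default 1).
#' @param seed RNG seed.
#' @return A \linkS4class{StateSeries}.
#' @export
sampleGibbs <- function(model, nSamples, burnIn = 1000L, thin = 1L,
                        seed = 1L) {
  stopifnot(is(model, "PairwiseModel"), burnIn >= 0L, thin >= 1L)
  StateSeries(.withSeed(seed, .gibbsChain(model, nSamples, burnIn, thin)))
}

#' Continuous surrogate signals with a recoverable binary ground truth
#'
#' Draws binary states by Gibbs sampling, maps them to plus/minus one and
#' adds centered Gaussian noise, so that thresholding the output at zero
#' recovers the underlying binary states whenever the noise is small. This
#' exercises the binarization path of the pipeline.
#'
#' @param model a \linkS4class{PairwiseModel}.
#' @param nSamples number of time points.
#' @param noiseSd standard deviation of the additive noise (> 0).
#' @param seed RNG seed.
#' @param burnIn,thin passed to the Gibbs chain.
#' @return list with \code{continuous} (T x N numeric matrix) and
#'   \code{states} (the underlying \linkS4class{StateSeries}).
#' @export
sampleSurrogateContinuous <- function(model, nSamples, noiseSd = 0.1,
                                      seed = 1L, burnIn = 1000L, thin = 1L) {
  stopifnot(noiseSd > 0)
  .withSeed(seed, {
    s <- .gibbsChain(model, nSamples, burnIn, thin)
    x <- (2 * s - 1) + matrix(stats::rnorm(length(s), 0, noiseSd),
                              nrow = nrow(s))
    colnames(x) <- colnames(s)
    list(continuous = x, states = StateSeries(s))
  })
}
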