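# Pairwise maximum-entropy model machinery: energies, Boltzmann
# distribution, empirical/model moments, and the exact gradient-ascent fit.

#' Energy of a single binary state under a pairwise model
#'
#' \eqn{E(V) = -\sum_i H_i \sigma_i - \sum_{i<j} J_{ij} \sigma_i \sigma_j};
#' each interacting pair is counted once.
#'
#' @param model a \linkS4class{PairwiseModel}.
#' @param bits binary state vector of length N.
#' @return numeric energy.
#' @examples
#' m <- PairwiseModel(c(1, -1), matrix(c(0, 0.5, 0.5, 0), 2))
#' stateEnergy(m, c(1, 1))  # -0.5
#' @export
stateEnergy <- function(model, bits) {
  stopifnot(is(model, "PairwiseModel"))
  bits <- as.numeric(bits)
  if (length(bits) != model@nRegions)
    stop("state length does not match the model's number of regions",
         call. = FALSE)
  .checkBits(bits)
  -sum(model@h * bits) - 0.5 * drop(bits %*% model@j %*% bits)
}

#' Energies of all 2^N states
#'
#' Enumerates the full state space (codes 0..2^N - 1, region 1 at the
#' least-significant bit) and evaluates the energy of every state.
#'
#' @param model a \linkS4class{PairwiseModel} with N <= 20.
#' @return numeric vector of length 2^N; element k + 1 is the energy of
#'   state code k.
#' @export
enumerateEnergies <- function(model) {
  stopifnot(is(model, "PairwiseModel"))
  s <- .stateSpace(model@nRegions)
  .energiesFromSpace(model, s)
}

# energies given a precomputed state-space matrix (J has zero diagonal, so
# the quadratic form double-counts each pair; halve it)
.energiesFromSpace <- function(model, s) {
  drop(-(s %*% model@h) - 0.5 * rowSums((s %*% model@j) * s))
}

#' Boltzmann distribution of a pairwise model
#'
#' \eqn{p(V_k) = e^{-E(V_k)} / \sum_l e^{-E(V_l)}}, computed with a
#' log-sum-exp shift so large |E| cannot overflow.
#'
#' @param model a \linkS4class{PairwiseModel} with N <= 20.
#' @return A \linkS4class{StateDistribution}.
#' @export
boltzmannDistribution <- function(model) {
  e <- enumerateEnergies(model)
  .distFromEnergies(e, model@nRegions)
}

.distFromEnergies <- function(e, nRegions) {
  le <- -e - max(-e)
  p <- exp(le)
  p <- p / sum(p)
  new("StateDistribution", probs = p, nRegions = as.integer(nRegions))
}

#' Empirical first and second moments of a binary series
#'
#' Time averages \eqn{\langle\sigma_i\rangle = T^{-1}\sum_t \sigma_i(t)} and
#' \eqn{\langle\sigma_i\sigma_j\rangle = T^{-1}\sum_t
#' \sigma_i(t)\sigma_j(t)}. These are the constraints the pairwise
#' maximum-entropy fit must reproduce.
#'
#' @param series a \linkS4class{StateSeries} or binary matrix.
#' @return A \linkS4class{MomentSet}.
#' @export
empiricalMoments <- function(series) {
  s <- .asStateMatrix(series)
  t <- nrow(s)
  s <- matrix(as.numeric(s), nrow = t)
  new("MomentSet", first = colMeans(s), second = crossprod(s) / t)
}

.asStateMatrix <- function(series) {
  if (is(series, "StateSeries")) return(series@states)
  s <- as.matrix(series)
  if (any(is.na(s)) || any(s != 0 & s != 1))
    stop("series entries must be 0 or 1", call. = FALSE)
  s
}

#' Empirical distribution of observed states
#'
#' Relative frequency of each state code over the series; unseen states have
#' probability exactly zero.
#'
#' @param series a \linkS4class{StateSeries} or binary matrix with N <= 20
#'   columns.
#' @return A \linkS4class{StateDistribution}.
#' @export
empiricalDistribution <- function(series) {
  s <- .asStateMatrix(series)
  n <- ncol(s)
  if (n > .MAX_ENUM_N)
    stop(sprintf("state histogram limited to N <= %d", .MAX_ENUM_N),
         call. = FALSE)
  codes <- as.integer(s %*% 2^(seq_len(n) - 1L))
  p <- tabulate(codes + 1L, nbins = 2^n) / nrow(s)
  new("StateDistribution", probs = p, nRegions = as.integer(n))
}

#' Exact model moments under the Boltzmann distribution
#'
#' \eqn{\langle\sigma_i\rangle_m = \sum_k \sigma_i(V_k) p(V_k)} and the
#' pairwise analogue, by full enumeration of the 2^N states.
#'
#' @param model a \linkS4class{PairwiseModel} with N <= 20.
#' @return A \linkS4class{MomentSet}.
#' @export
modelMoments <- function(model) {
  s <- .stateSpace(model@nRegions)
  p <- .distFromEnergies(.energiesFromSpace(model, s), model@nRegions)@probs
  .momentsFromSpace(s, p)
}

.momentsFromSpace <- function(s, p) {
  new("MomentSet", first = drop(crossprod(s, p)),
      second = crossprod(s, s * p))
}

#' Fit the independent (first-order) maximum-entropy model
#'
#' The maximum-entropy model constrained only by the first moments has
#' J = 0 and \eqn{H_i = \mathrm{logit}(\langle\sigma_i\rangle)}; it
#' reproduces the activation rates exactly and serves as the first-order
#' baseline for the fit-quality metrics.
#'
#' @param moments a \linkS4class{MomentSet} (only the first moments are
#'   used).
#' @param clipEps optional clipping bound: first moments are forced into
#'   [clipEps, 1 - clipEps] before the logit. When NULL (default), moments
#'   exactly 0 or 1 raise an error.
#' @return A \linkS4class{PairwiseModel} with zero couplings.
#' @export
fitIndependentMEM <- function(moments, clipEps = NULL) {
  stopifnot(is(moments, "MomentSet"))
  m1 <- moments@first
  if (!is.null(clipEps)) m1 <- pmin(pmax(m1, clipEps), 1 - clipEps)
  if (any(m1 <= 0 | m1 >= 1))
    stop("degenerate first moment (0 or 1); supply clipEps to proceed",
         call. = FALSE)
  n <- length(m1)
  PairwiseModel(h = log(m1 / (1 - m1)), j = matrix(0, n, n))
}

#' Clip moments away from the boundary of the feasible region
#'
#' Log-ratio gradient updates diverge when a target moment is exactly 0 or
#' 1; moments estimated from T samples are conventionally clipped to
#' [1/(2T), 1 - 1/(2T)].
#'
#' @param moments a \linkS4class{MomentSet}.
#' @param eps clipping bound, e.g. \code{1 / (2 * T)}.
#' @return A clipped \linkS4class{MomentSet}.
#' @export
clipMoments <- function(moments, eps) {
  stopifnot(is(moments, "MomentSet"), eps > 0, eps < 0.5)
  first <- pmin(pmax(moments@first, eps), 1 - eps)
  second <- pmin(pmax(moments@second, eps), 1 - eps)
  second <- (second + t(second)) / 2
  diag(second) <- first
  new("MomentSet", first = first, second = second)
}

#' Fit the pairwise maximum-entropy model by exact gradient ascent
#'
#' Iterates the multiplicative log-ratio updates
#' \deqn{H_i \leftarrow H_i + \alpha_g \log(\langle\sigma_i\rangle /
#'   \langle\sigma_i\rangle_m), \quad
#'   J_{ij} \leftarrow J_{ij} + \alpha_g \log(\langle\sigma_i\sigma_j\rangle
#'   / \langle\sigma_i\sigma_j\rangle_m),}
#' recomputing the model moments by full enumeration at every iteration.
#' Convergence is declared when the maximum absolute log-ratio term (the
#' gradient in these updates) falls below \code{tol}. Parameters start from
#' the independent solution (H at the logit of the first moments, J = 0).
#'
#' @param moments target \linkS4class{MomentSet} (empirical or exact).
#' @param aG learning rate (default 0.1).
#' @param tol convergence tolerance on the max absolute log-ratio term
#'   (default 1e-5).
#' @param maxIter iteration cap (default 5e5); hitting it flags
#'   non-convergence in the result rather than raising an error.
#' @param clipEps optional boundary clipping applied to the target moments
#'   (see [clipMoments()]); moments exactly 0 or 1 without clipping raise an
#'   error.
#' @param init optional \linkS4class{PairwiseModel} to start from (e.g. to
#'   resume a fit); a model whose moments already match the targets is left
#'   unchanged, since every log-ratio term is zero.
#' @param regionLabels optional region names for the fitted model.
#' @return A \linkS4class{FitResult}.
#' @export
fitPairwiseMEM <- function(moments, aG = 0.1, tol = 1e-5, maxIter = 5e5L,
                           clipEps = NULL, init = NULL,
                           regionLabels = NULL) {
  stopifnot(is(moments, "MomentSet"))
  if (!is.null(clipEps)) moments <- clipMoments(moments, clipEps)
  t1 <- moments@first
  t2 <- moments@second
  n <- length(t1)
  if (n > .MAX_ENUM_N)
    stop(sprintf("exact fitting limited to N <= %d", .MAX_ENUM_N),
         call. = FALSE)
  up <- upper.tri(t2)
  if (any(t1 <= 0 | t1 >= 1) || any(t2[up] <= 0 | t2[up] >= 1))
    stop("degenerate target moment (0 or 1); supply clipEps to proceed",
         call. = FALSE)

  s <- .stateSpace(n)
  if (is.null(init)) {
    h <- log(t1 / (1 - t1))
    j <- matrix(0, n, n)
  } else {
    stopifnot(is(init, "PairwiseModel"), init@nRegions == n)
    h <- init@h
    j <- init@j
  }
  lt1 <- log(t1)
  lt2up <- log(t2[up])

  grad <- Inf
  iter <- 0L
  while (iter < maxIter) {
    iter <- iter + 1L
    e <- drop(-(s %*% h)) - 0.5 * rowSums((s %*% j) * s)
    p <- exp(-e - max(-e))
    p <- p / sum(p)
    m1 <- drop(crossprod(s, p))
    m2 <- crossprod(s, s * p)
    g1 <- lt1 - log(m1)
    g2 <- lt2up - log(m2[up])
    grad <- max(abs(c(g1, g2)))
    if (grad < tol) break
    h <- h + aG * g1
    j[up] <- j[up] + aG * g2
    j[lower.tri(j)] <- t(j)[lower.tri(j)]
  }
  model <- PairwiseModel(h = h, j = j, regionLabels = regionLabels)
  new("FitResult", model = model, nIterations = iter,
      converged = grad < tol, finalGradientNorm = grad)
}

.entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

.klDivergence <- function(pEmp, pModel) {
  keep <- pEmp > 0
  if (any(pModel[keep] == 0))
    return(Inf)
  sum(pEmp[keep] * log(pEmp[keep] / pModel[keep]))
}

#' Accuracy and reliability metrics of the pairwise fit
#'
#' Evaluates how much of the empirical distribution's structure the pairwise
#' model captures beyond the independent model:
#' \deqn{D_k = \sum_l p_N(V_l)\log\frac{p_N(V_l)}{p_k(V_l)}, \quad
#'   r_D = \frac{D_1 - D_2}{D_1},}
#' \deqn{S_k = -\sum_l p_k \log p_k, \quad
#'   r_S = \frac{S_1 - S_2}{S_1 - S_N}, \quad ER = r_S / r_D,}
#' where k = 1 is the independent model, k = 2 the pairwise model and
#' \eqn{p_N}, \eqn{S_N} the empirical distribution and its entropy. Natural
#' logarithms are used throughout; every reported metric is a ratio of
#' same-base quantities, so the base cancels. When the empirical
#' distribution equals the pairwise model's Boltzmann distribution
#' (error-free estimation), ER = 1.
#'
#' @param empirical the empirical \linkS4class{StateDistribution}.
#' @param independent the first-order \linkS4class{PairwiseModel}.
#' @param pairwise the fitted second-order \linkS4class{PairwiseModel}.
#' @param erMode "ratio" (default) computes ER = r_S / r_D; "product"
#'   computes ER = r_S * r_D. Both equal 1 under error-free estimation.
#' @return A \linkS4class{FitMetrics}.
#' @export
fitMetrics <- function(empirical, independent, pairwise,
                       erMode = c("ratio", "product")) {
  erMode <- match.arg(erMode)
  stopifnot(is(empirical, "StateDistribution"),
            is(independent, "PairwiseModel"),
            is(pairwise, "PairwiseModel"))
  n <- empirical@nRegions
  if (independent@nRegions != n || pairwise@nRegions != n)
    stop("all three inputs must share the same number of regions",
         call. = FALSE)
  pN <- empirical@probs
  p1 <- boltzmannDistribution(independent)@probs
  p2 <- boltzmannDistribution(pairwise)@probs
  d1 <- .klDivergence(pN, p1)
  d2 <- .klDivergence(pN, p2)
  s1 <- .entropy(p1)
  s2 <- .entropy(p2)
  sN <- .entropy(pN)
  if (d1 == 0)
    stop("empirical distribution is already first-order (D1 = 0); r_D undefined",
         call. = FALSE)
  if (s1 == sN)
    stop("S1 equals the empirical entropy; r_S undefined", call. = FALSE)
  rD <- (d1 - d2) / d1
  rS <- (s1 - s2) / (s1 - sN)
  er <- if (erMode == "ratio") rS / rD else rS * rD
  new("FitMetrics", d1 = d1, d2 = d2, s1 = s1, s2 = s2, sN = sN,
      rD = rD, rS = rS, er = er)
}
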