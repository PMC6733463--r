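test_that("state energy matches direct substitution and the local-field form", {
  m <- toyModel()
  expect_equal(stateEnergy(m, c(1, 1)), -0.5)
  expect_equal(stateEnergy(m, c(0, 0)), 0)
  expect_error(stateEnergy(m, c(1, 0, 1)), "does not match")
  # flipping bit i changes E by -(+/-)(H_i + sum_j J_ij sigma_j)
  for (seed in 1:3) {
    m6 <- randomModel(6, seed)
    set.seed(seed + 100)
    bits <- sample(0:1, 6, replace = TRUE)
    for (i in 1:6) {
      flipped <- bits
      flipped[i] <- 1L - flipped[i]
      field <- biasField(m6)[i] + sum(couplingMatrix(m6)[i, ] * bits)
      delta <- if (bits[i] == 0) -field else field
      expect_equal(stateEnergy(m6, flipped) - stateEnergy(m6, bits), delta)
    }
  }
})

test_that("Boltzmann distribution is normalized and matches hand enumeration", {
  one <- PairwiseModel(h = 0, j = matrix(0, 1, 1))
  expect_equal(stateProbs(boltzmannDistribution(one)), c(0.5, 0.5))
  p <- stateProbs(boltzmannDistribution(toyModel()))
  # energies 0, -1, 1, -0.5 enumerated by hand
  expect_equal(p[2], exp(1) / (1 + exp(1) + exp(-1) + exp(0.5)),
               tolerance = 1e-12)
  for (seed in 1:5) {
    m <- randomModel(5, seed)
    d <- boltzmannDistribution(m)
    expect_equal(sum(stateProbs(d)), 1, tolerance = 1e-12)
    # -log p and E agree up to the shared log-partition constant
    lp <- -log(stateProbs(d))
    e <- enumerateEnergies(m)
    expect_equal(lp - min(lp), e - min(e), tolerance = 1e-9)
  }
})

test_that("log-sum-exp guard survives extreme energies", {
  m <- PairwiseModel(h = c(800, -800), j = matrix(0, 2, 2))
  p <- stateProbs(boltzmannDistribution(m))
  expect_false(any(is.nan(p)))
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(p[2], 1, tolerance = 1e-9)
})

test_that("empirical moments are time averages", {
  s <- StateSeries(rbind(c(1, 0), c(1, 1)))
  mo <- empiricalMoments(s)
  expect_equal(mo@first, c(1, 0.5))
  expect_equal(mo@second[1, 2], 0.5)
  ones <- StateSeries(matrix(1L, 10, 3))
  expect_true(all(empiricalMoments(ones)@first == 1))
  expect_true(all(empiricalMoments(ones)@second == 1))
})

test_that("empirical moments of exact samples converge to model moments", {
  m <- randomModel(5, seed = 7, lim = 0.8)
  truth <- modelMoments(m)
  s <- sampleExact(m, 1e5, seed = 11)
  est <- empiricalMoments(s)
  # binomial standard errors at T = 1e5
  se1 <- sqrt(truth@first * (1 - truth@first) / 1e5)
  expect_true(all(abs(est@first - truth@first) < 3 * se1 + 1e-12))
  up <- upper.tri(truth@second)
  se2 <- sqrt(truth@second[up] * (1 - truth@second[up]) / 1e5)
  expect_true(all(abs(est@second[up] - truth@second[up]) < 3 * se2 + 1e-12))
})

test_that("empirical distribution counts state frequencies", {
  s <- StateSeries(rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 0)))
  d <- empiricalDistribution(s)
  expect_equal(stateProbs(d), c(0.5, 0.25, 0, 0.25))
  set.seed(3)
  x <- matrix(sample(0:1, 400, replace = TRUE), ncol = 4)
  expect_equal(stateProbs(empiricalDistribution(StateSeries(x))),
               histogramOracle(x))
})

test_that("model moments factorize under independence and match sampling", {
  one <- PairwiseModel(h = 0, j = matrix(0, 1, 1))
  expect_equal(modelMoments(one)@first, 0.5)
  set.seed(2)
  indep <- PairwiseModel(h = rnorm(4), j = matrix(0, 4, 4))
  mo <- modelMoments(indep)
  up <- upper.tri(mo@second)
  expect_equal(mo@second[up], outer(mo@first, mo@first)[up],
               tolerance = 1e-12)
  # Monte-Carlo agreement for a coupled model
  m <- randomModel(4, seed = 5)
  truth <- modelMoments(m)
  est <- empiricalMoments(sampleExact(m, 1e5, seed = 6))
  se <- sqrt(truth@first * (1 - truth@first) / 1e5)
  expect_true(all(abs(est@first - truth@first) < 3 * se + 1e-12))
})

test_that("independent fit is the exact logit solution", {
  mo <- new("MomentSet", first = rep(0.5, 3), second = diag(0.5, 3))
  expect_equal(biasField(fitIndependentMEM(mo)), rep(0, 3))
  mo1 <- new("MomentSet", first = exp(1) / (1 + exp(1)),
             second = matrix(exp(1) / (1 + exp(1)), 1, 1))
  expect_equal(biasField(fitIndependentMEM(mo1)), 1)
  # round trip: fitted model reproduces arbitrary first moments exactly
  target <- c(0.12, 0.57, 0.983)
  fit <- fitIndependentMEM(new("MomentSet", first = target,
                               second = diag(target)))
  expect_equal(modelMoments(fit)@first, target, tolerance = 1e-12)
  expect_error(fitIndependentMEM(new("MomentSet", first = c(0, 0.5),
                                     second = diag(c(0, 0.5)))),
               "degenerate")
})

test_that("gradient ascent sits still at a fixed point and flags its cap", {
  truth <- randomModel(4, seed = 9, lim = 0.7)
  mo <- modelMoments(truth)
  fit <- fitPairwiseMEM(mo)
  expect_true(fit@converged)
  expect_true(fit@finalGradientNorm < 1e-5)
  # a model whose moments equal the targets is a fixed point of the update
  refit <- fitPairwiseMEM(modelMoments(fit@model), init = fit@model)
  expect_identical(refit@nIterations, 1L)
  expect_identical(biasField(refit@model), biasField(fit@model))
  expect_identical(couplingMatrix(refit@model), couplingMatrix(fit@model))
  capped <- fitPairwiseMEM(mo, maxIter = 3L)
  expect_false(capped@converged)
  expect_identical(capped@nIterations, 3L)
  expect_error(fitPairwiseMEM(new("MomentSet", first = c(1, 0.5),
                                  second = diag(c(1, 0.5)))),
               "degenerate")
})

test_that("pairwise fit recovers a known model from exact moments", {
  truth <- randomModel(6, seed = 21)
  fit <- fitPairwiseMEM(modelMoments(truth))
  expect_true(fit@converged)
  expect_lt(max(abs(biasField(fit@model) - biasField(truth))), 1e-3)
  expect_lt(max(abs(couplingMatrix(fit@model) - couplingMatrix(truth))),
            1e-3)
  # at convergence every log-ratio term is below the tolerance
  mo <- modelMoments(fit@model)
  tgt <- modelMoments(truth)
  up <- upper.tri(tgt@second)
  expect_true(max(abs(c(log(tgt@first / mo@first),
                        log(tgt@second[up] / mo@second[up])))) < 1e-5)
})

test_that("fit metrics satisfy the maximum-entropy hierarchy", {
  truth <- randomModel(4, seed = 31, lim = 0.9)
  emp <- boltzmannDistribution(truth)
  indep <- fitIndependentMEM(modelMoments(truth))
  met <- fitMetrics(emp, indep, truth)
  expect_equal(met@er, 1, tolerance = 1e-9)
  expect_equal(met@rD, 1, tolerance = 1e-9)
  expect_equal(met@rS, 1, tolerance = 1e-9)
  expect_true(met@d1 >= 0 && met@d2 >= 0)
  expect_true(met@sN <= met@s2 + 1e-9 && met@s2 <= met@s1 + 1e-9)
  expect_equal(fitMetrics(emp, indep, truth, erMode = "product")@er, 1,
               tolerance = 1e-9)
})

test_that("pairwise model explains a correlated distribution better than the independent one", {
  truth <- randomModel(4, seed = 41)
  # empirical distribution = exact samples, fitted models from its moments
  s <- sampleExact(truth, 2e4, seed = 42)
  emp <- empiricalDistribution(s)
  mo <- clipMoments(empiricalMoments(s), 1 / (4e4))
  indep <- fitIndependentMEM(mo)
  pair <- fitPairwiseMEM(mo)@model
  met <- fitMetrics(emp, indep, pair)
  expect_lt(met@d2, met@d1)
  expect_true(met@rD > 0 && met@rD <= 1)
})

test_that("degenerate metric inputs raise informative errors", {
  indep <- PairwiseModel(h = c(0, 0), j = matrix(0, 2, 2))
  emp <- boltzmannDistribution(indep)
  expect_error(fitMetrics(emp, indep, indep), "D1 = 0|undefined",
               ignore.case = TRUE)
})
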