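# Shared fixtures and independent oracles for the test suite.

# N=2 toy with a single minimum: H = (1, -1), J12 = 0.5
# energies over codes 0..3: 0, -1, 1, -0.5
toyModel <- function() {
  PairwiseModel(h = c(1, -1), j = matrix(c(0, 0.5, 0.5, 0), 2))
}

# N=2 "square" with two minima and a saddle at 00:
# H = (1.2, 1.0), J12 = -3; energies 00 -> 0, 10 -> -1.2, 01 -> -1.0,
# 11 -> 0.8
squareModel <- function() {
  PairwiseModel(h = c(1.2, 1.0), j = matrix(c(0, -3, -3, 0), 2))
}

# random dense model with parameters U[-lim, lim]
randomModel <- function(n, seed, lim = 1) {
  set.seed(seed)
  j <- matrix(0, n, n)
  j[upper.tri(j)] <- stats::runif(choose(n, 2), -lim, lim)
  j <- j + t(j)
  PairwiseModel(h = stats::runif(n, -lim, lim), j = j)
}

# brute-force local-minima scan, written independently of the package's
# vectorized path: per-state loop flipping each bit
bruteForceMinima <- function(model) {
  n <- nRegions(model)
  mins <- integer(0)
  for (code in 0:(2^n - 1)) {
    bits <- decodeState(code, n)
    e0 <- stateEnergy(model, bits)
    ok <- TRUE
    for (i in seq_len(n)) {
      nb <- bits
      nb[i] <- 1L - nb[i]
      if (stateEnergy(model, nb) <= e0) { ok <- FALSE; break }
    }
    if (ok) mins <- c(mins, code)
  }
  e <- enumerateEnergies(model)
  mins[order(e[mins + 1L], mins)]
}

# counting-pass histogram oracle for the empirical distribution
histogramOracle <- function(states) {
  n <- ncol(states)
  counts <- numeric(2^n)
  for (t in seq_len(nrow(states))) {
    code <- encodeState(states[t, ])
    counts[code + 1] <- counts[code + 1] + 1
  }
  counts / nrow(states)
}

# default two-community fixture used across the landscape/network tests
# (seed 2 of the generator defaults: 6 minima, 3 complementary pairs)
richFixture <- function() {
  model <- makeModel(generatorConfig(seed = 2))
  landscape <- findLocalMinima(model)
  list(model = model, landscape = landscape)
}

totalVariation <- function(p, q) 0.5 * sum(abs(p - q))
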