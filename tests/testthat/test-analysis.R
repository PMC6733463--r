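test_that("path-length decomposition separates the TS segments", {
  # hand-built 5-step path between states at Hamming distance 3
  p <- new("TransitionPath", sourceLM = 0L, targetLM = 11L,
           states = c(0L, 1L, 3L, 2L, 10L, 11L), eTh = 1, eB = 1,
           tsCode = 3L, intermediates = integer(0))
  pl <- pathLengths(p)
  expect_identical(pl$full, 5L)
  expect_identical(pl$toTS, 2L)
  expect_identical(pl$fromTS, 3L)
  expect_identical(pl$effective, 2L)
  # geodesic path: zero effective length
  m <- squareModel()
  ls <- findLocalMinima(m)
  plG <- pathLengths(minimaxPath(m, 1, 2, ls))
  expect_identical(plG$effective, 0L)
})

test_that("effective path lengths are even and non-negative on all fixture pathways", {
  for (seed in c(2, 5)) {
    m <- makeModel(generatorConfig(seed = seed))
    ls <- findLocalMinima(m)
    if (length(localMinima(ls)) < 2) next
    for (p in pathList(buildSTNFS(m, ls))) {
      pl <- pathLengths(p)
      expect_gte(pl$effective, 0L)
      expect_identical(pl$effective %% 2L, 0L)
      expect_identical(pl$toTS + pl$fromTS, pl$full)
    }
  }
})

test_that("degree profile follows the collapsed undirected graph", {
  m <- squareModel()
  ls <- findLocalMinima(m)
  stn <- buildSTNFS(m, ls)
  prof <- nodeDegreeProfile(stn)
  expect_identical(prof$degree[prof$code == 0L], 2L)
  expect_identical(prof$degree[prof$code == 1L], 1L)
  expect_identical(prof$degree[prof$code == 2L], 1L)
  fx <- richFixture()
  stnF <- buildSTNFS(fx$model, fx$landscape)
  profF <- nodeDegreeProfile(stnF)
  gU <- igraph::simplify(igraph::as_undirected(networkGraph(stnF),
                                               mode = "collapse"))
  expect_equal(sum(profF$degree), 2 * igraph::ecount(gU))
  expect_true(all(diff(profF$degree) <= 0))
})

test_that("UPGMA merges the closest feature rows first", {
  # direct-dissimilarity trace: d(A,B) = 2, d(A,C) = d(B,C) = 4
  d <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
              dimnames = list(c("1", "2", "3"), c("1", "2", "3")))
  bar <- new("BarrierSet", minima = c(1L, 2L, 3L),
             minimaEnergies = c(0, 0, 0), thresholds = d, barriers = d,
             directedBarriers = d)
  cl <- clusterLocalMinima(bar, mode = "barrier", directDissimilarity = TRUE)
  hc <- structure(cl@hclust, class = "hclust")
  expect_identical(sort(hc$merge[1, ]), c(-2L, -1L))   # A,B merge first
  expect_equal(hc$height, c(2, 4))
  # 2 minima: a single merge, two singleton groups
  m2 <- PairwiseModel(h = c(1, 1), j = matrix(c(0, -3, -3, 0), 2))
  ls2 <- suppressWarnings(findLocalMinima(m2))
  cl2 <- clusterLocalMinima(barrierMatrix(m2, ls2))
  expect_identical(sort(unique(cl2@groups)), c(1L, 2L))
})

test_that("complementary minima fall in opposite UPGMA groups on the fixture", {
  m <- makeModel(generatorConfig(seed = 1))
  ls <- findLocalMinima(m)
  lm <- localMinima(ls)
  cl <- clusterLocalMinima(barrierMatrix(m, ls))
  g <- cl@groups
  npairs <- 0L
  for (x in lm) {
    cx <- 2^10 - 1L - x
    if (cx %in% lm) {
      npairs <- npairs + 1L
      expect_false(g[[as.character(x)]] == g[[as.character(cx)]])
    }
  }
  expect_gte(npairs, 2L)
})

test_that("Pearson correlation matches closed forms", {
  x <- c(1, 2, 3, 4)
  r1 <- correlatePearson(x, 2 * x + 1)
  expect_equal(r1$r, 1)
  expect_equal(r1$p, 0)
  expect_equal(correlatePearson(x, -x)$r, -1)
  r0 <- correlatePearson(c(0, 1, 2), c(0, 1, 0))
  expect_equal(r0$r, 0)
  expect_equal(r0$p, 1)
  expect_identical(r0$n, 3L)
  expect_error(correlatePearson(c(1, 1, 1), x[1:3]), "constant")
  # p-value agrees with the t-test used by cor.test
  set.seed(1)
  a <- rnorm(20); b <- a + rnorm(20)
  ct <- stats::cor.test(a, b)
  rc <- correlatePearson(a, b)
  expect_equal(rc$r, unname(ct$estimate))
  expect_equal(rc$p, ct$p.value)
})

test_that("group-transition table covers both directions of every pair", {
  m <- squareModel()
  ls <- findLocalMinima(m)
  paths <- pathList(buildSTNFS(m, ls))
  cl <- clusterLocalMinima(barrierMatrix(m, ls))
  tab <- analyzeGroupTransitions(paths, cl, ls)
  expect_identical(nrow(tab), 2L)
  expect_setequal(tab$source, c(1L, 2L))
  fx <- richFixture()
  pathsF <- pathList(buildSTNFS(fx$model, fx$landscape))
  clF <- clusterLocalMinima(barrierMatrix(fx$model, fx$landscape))
  tabF <- analyzeGroupTransitions(pathsF, clF, fx$landscape)
  mN <- length(localMinima(fx$landscape))
  expect_equal(nrow(tabF), 2 * choose(mN, 2))
  e <- energies(fx$landscape)
  expect_equal(tabF$eB, tabF$eTh - e[tabF$source + 1L])
  expect_equal(tabF$rate, exp(-tabF$eB))
  expect_true(all(tabF$type %in% c("intra", "inter")))
})

test_that("barrier size grows with endpoint separation on the fixture", {
  fx <- richFixture()
  paths <- pathList(buildSTNFS(fx$model, fx$landscape))
  cl <- clusterLocalMinima(barrierMatrix(fx$model, fx$landscape))
  tab <- analyzeGroupTransitions(paths, cl, fx$landscape)
  expect_gt(correlatePearson(tab$hamming, tab$eB)$r, 0)
})

test_that("coupling scaling is linear and collapses the landscape at zero", {
  m <- randomModel(5, seed = 61)
  expect_equal(couplingMatrix(scaleInteractions(m, 1)), couplingMatrix(m))
  expect_identical(biasField(scaleInteractions(m, 3)), biasField(m))
  ls0 <- findLocalMinima(scaleInteractions(m, 0))
  expect_identical(length(localMinima(ls0)), 1L)
  # E(alpha) = E_H + alpha * E_J for any state
  bits <- decodeState(19, 5)
  eH <- stateEnergy(scaleInteractions(m, 0), bits)
  e1 <- stateEnergy(m, bits)
  expect_equal(stateEnergy(scaleInteractions(m, 2.5), bits),
               eH + 2.5 * (e1 - eH))
})

test_that("parameter randomization preserves multisets and symmetry", {
  m <- randomModel(6, seed = 71)
  for (mode in c("permute_h", "permute_j", "random_values")) {
    pm <- permuteParameters(m, mode, seed = 5)
    j <- couplingMatrix(pm)
    expect_identical(j, t(j))
    expect_true(all(diag(j) == 0))
    pm2 <- permuteParameters(m, mode, seed = 5)
    expect_identical(biasField(pm), biasField(pm2))
    expect_identical(couplingMatrix(pm), couplingMatrix(pm2))
  }
  expect_equal(sort(biasField(permuteParameters(m, "permute_h", 3))),
               sort(biasField(m)))
  jp <- permuteParameters(m, "permute_j", 3)
  expect_equal(sort(couplingMatrix(jp)[upper.tri(diag(6))]),
               sort(couplingMatrix(m)[upper.tri(diag(6))]))
})

test_that("alpha sweep aligns summaries with the grid", {
  m <- makeModel(generatorConfig(nRegions = 8, seed = 2))
  grid <- c(0, 0.5, 1, 2)
  sw <- sweepAlpha(m, grid)
  expect_identical(sw@alphas, grid)
  expect_length(sw@minimaCounts, 4L)
  expect_identical(nrow(sw@summaries), 4L)
  expect_identical(sw@minimaCounts[1], 1L)   # alpha = 0, generic fields
  big <- which(sw@minimaCounts >= 2)
  expect_true(all(!is.na(sw@summaries$nodes[big])))
})
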