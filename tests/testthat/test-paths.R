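# The "square" fixture (see helper): two minima 10 (code 1) and 01 (code 2)
# separated by the saddle 00 (code 0), with 11 (code 3) the high corner.

test_that("minimax path crosses the saddle with the correct barrier", {
  m <- squareModel()
  ls <- findLocalMinima(m)
  p <- minimaxPath(m, 1, 2, ls)
  expect_identical(p@sourceLM, 2L)      # 01 is the higher-energy minimum
  expect_identical(p@targetLM, 1L)
  expect_identical(p@states, c(2L, 0L, 1L))
  expect_equal(p@eTh, 0)
  expect_identical(p@tsCode, 0L)
  expect_equal(p@eB, 1.0)
  expect_identical(p@intermediates, integer(0))
})

test_that("paths step one bit at a time and attain the pair threshold", {
  fx <- richFixture()
  paths <- pathList(buildSTNFS(fx$model, fx$landscape))
  e <- energies(fx$landscape)
  for (p in paths) {
    s <- p@states
    steps <- length(s) - 1L
    for (i in seq_len(steps))
      expect_identical(hammingDistance(decodeState(s[i], 10),
                                       decodeState(s[i + 1], 10)), 1L)
    ham <- hammingDistance(decodeState(s[1], 10),
                           decodeState(s[steps + 1], 10))
    expect_gte(steps, ham)
    expect_identical((steps - ham) %% 2L, 0L)       # equal parity
    expect_equal(max(e[s + 1]), p@eTh)
    expect_equal(pairThreshold(fx$model, p@sourceLM, p@targetLM,
                               fx$landscape), p@eTh)
    expect_identical(s[which.max(e[s + 1])], p@tsCode)
    expect_gte(p@eB, 0)
  }
})

test_that("intermediate minima are interior path states only", {
  m <- squareModel()
  ls <- findLocalMinima(m)
  p <- minimaxPath(m, 1, 2, ls)
  expect_identical(locateIntermediates(p, ls), integer(0))
  fx <- richFixture()
  paths <- pathList(buildSTNFS(fx$model, fx$landscape))
  found <- 0L
  for (p in paths) {
    ints <- locateIntermediates(p, fx$landscape)
    expect_identical(ints, p@intermediates)
    expect_false(p@sourceLM %in% ints)
    expect_false(p@targetLM %in% ints)
    expect_true(all(ints %in% localMinima(fx$landscape)))
    # reported in path order
    expect_identical(ints, p@states[p@states %in% ints])
    found <- found + length(ints)
  }
  expect_gt(found, 0L)   # the rich fixture has multi-basin pathways
})

test_that("transition rates follow the barrier exponential", {
  expect_equal(transitionRate(0), 1)
  expect_equal(transitionRate(1), exp(-1))
  expect_equal(transitionRate(1), 0.36788, tolerance = 1e-4)
  expect_error(transitionRate(-0.1), "non-negative")
})

test_that("STN-FS stitches pathway steps into a directed network", {
  m <- squareModel()
  ls <- findLocalMinima(m)
  stn <- buildSTNFS(m, ls)
  g <- networkGraph(stn)
  expect_setequal(igraph::V(g)$code, c(0L, 1L, 2L))
  edges <- igraph::as_data_frame(g)
  expect_identical(nrow(edges), 2L)
  expect_setequal(paste(edges$from, edges$to), c("2 0", "0 1"))
  expect_equal(edges$rate, rep(exp(-1), 2))
  roles <- setNames(igraph::V(g)$role, igraph::V(g)$name)
  expect_identical(roles[["0"]], "transition_state")
  expect_identical(roles[["1"]], "local_minimum")
  fx <- richFixture()
  stnF <- buildSTNFS(fx$model, fx$landscape)
  expect_gte(igraph::vcount(networkGraph(stnF)),
             length(localMinima(fx$landscape)))
  # every step edge joins states at Hamming distance 1
  ef <- igraph::as_data_frame(networkGraph(stnF))
  for (k in seq_len(nrow(ef)))
    expect_identical(hammingDistance(
      decodeState(as.integer(ef$from[k]), 10),
      decodeState(as.integer(ef$to[k]), 10)), 1L)
})

test_that("STN-GM keeps exactly the pathways into the global minimum", {
  m <- squareModel()
  ls <- findLocalMinima(m)
  stnFS <- buildSTNFS(m, ls)
  stnGM <- buildSTNGM(stnFS, ls)
  expect_equal(igraph::vcount(networkGraph(stnGM)), 3)
  fx <- richFixture()
  fs <- buildSTNFS(fx$model, fx$landscape)
  gm <- buildSTNGM(fs, fx$landscape)
  expect_true(all(igraph::V(networkGraph(gm))$code %in%
                  igraph::V(networkGraph(fs))$code))
  expect_identical(length(pathList(gm)),
                   length(localMinima(fx$landscape)) - 1L)
  for (p in pathList(gm))
    expect_identical(p@targetLM, globalMinimum(fx$landscape))
})

test_that("STN-LM has minima and transition states with through-flow", {
  m <- squareModel()
  ls <- findLocalMinima(m)
  paths <- pathList(buildSTNFS(m, ls))
  lmNet <- buildSTNLM(paths, ls)
  g <- networkGraph(lmNet)
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), 2)
  fx <- richFixture()
  fsPaths <- pathList(buildSTNFS(fx$model, fx$landscape))
  net <- buildSTNLM(fsPaths, fx$landscape)
  gN <- networkGraph(net)
  nLM <- length(localMinima(fx$landscape))
  nTS <- length(setdiff(unique(vapply(fsPaths, function(p) p@tsCode,
                                      integer(1))),
                        localMinima(fx$landscape)))
  expect_equal(igraph::vcount(gN), nLM + nTS)
  tsNodes <- igraph::V(gN)[igraph::V(gN)$role == "transition_state"]
  expect_true(all(igraph::degree(gN, tsNodes, mode = "in") >= 1))
  expect_true(all(igraph::degree(gN, tsNodes, mode = "out") >= 1))
})

test_that("state removal reroutes pathways and can only raise thresholds", {
  m <- squareModel()
  ls <- findLocalMinima(m)
  rr <- removeStateAndReroute(m, ls, 0L)
  expect_identical(rr$paths[[1]]@states, c(2L, 3L, 1L))
  expect_equal(rr$summary$eTh, 0.8)
  expect_identical(rr$summary$tsCode, 3L)
  expect_false(rr$summary$disconnected)
  expect_error(removeStateAndReroute(m, ls, 1L), "local minimum")
  # on the rich fixture: remove the most shared TS; thresholds never drop
  fx <- richFixture()
  paths <- pathList(buildSTNFS(fx$model, fx$landscape))
  ts <- vapply(paths, function(p) p@tsCode, integer(1))
  hub <- as.integer(names(which.max(table(ts))))
  rrF <- removeStateAndReroute(fx$model, fx$landscape, hub)
  for (k in seq_along(paths)) {
    old <- paths[[k]]
    row <- rrF$summary[k, ]
    if (row$disconnected) next
    expect_gte(row$eTh, old@eTh - 1e-12)
    # rate ratio identity for the same source
    expect_equal(exp(-row$eB) / exp(-old@eB),
                 exp(-(row$eTh - old@eTh)), tolerance = 1e-12)
  }
})

test_that("network rebuilds are deterministic", {
  fx <- richFixture()
  f1 <- tempfile(fileext = ".graphml")
  f2 <- tempfile(fileext = ".graphml")
  writeNetwork(buildSTNFS(fx$model, fx$landscape), f1)
  writeNetwork(buildSTNFS(fx$model, fx$landscape), f2)
  expect_identical(readLines(f1), readLines(f2))
})
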