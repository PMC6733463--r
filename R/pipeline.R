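# End-to-end pipeline: data (read or simulate) -> binarize -> fit ->
# landscape -> transition networks -> analysis -> reports, plus the
# subcommand CLI entry point.

.writeProvenance <- function(outDir, step, params, seed) {
  prov <- list(step = step, seed = seed, params = params,
               package = "energyScape",
               version = as.character(utils::packageVersion("energyScape")),
               r_version = as.character(getRversion()),
               time = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.writeTable <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full landscape-analysis pipeline
#'
#' Stages: obtain a binary series (read from \code{input}, binarizing
#' continuous data at \code{threshold}, or simulate one from a generated
#' ground-truth model), fit the independent and pairwise maximum-entropy
#' models to its moments, compute the fit metrics, derive the energy
#' landscape, barriers and disconnectivity tree of the fitted model, build
#' the three transition networks, group the minima by UPGMA and tabulate
#' intra/inter-group transitions with the Hamming/barrier correlation, and
#' optionally sweep the coupling scale and re-route around a removed state.
#' All tabular and network outputs are deterministic given the same
#' configuration and seed.
#'
#' @param input optional TSV/CSV time-series path; when NULL a series is
#'   simulated from \code{simulateConfig}.
#' @param outDir output directory (created if needed).
#' @param seed integer seed controlling simulation.
#' @param threshold binarization threshold for continuous input (default 0).
#' @param simulateConfig a \linkS4class{GeneratorConfig} for the simulated
#'   branch; default \code{generatorConfig(seed = seed)}.
#' @param nSamples simulated series length (default 20000).
#' @param sampler "gibbs" (temporally correlated, default) or "exact"
#'   (i.i.d.) simulated sampling.
#' @param aG,tol,maxIter gradient-ascent fit hyperparameters.
#' @param clusterMode "barrier" or "rate" feature matrix for the UPGMA
#'   grouping.
#' @param alphaGrid optional numeric grid for the coupling-scale sweep
#'   (NULL skips the sweep).
#' @param removeState optional state code to delete and re-route around.
#' @return invisibly, a list with the main result objects.
#' @export
runPipeline <- function(input = NULL, outDir, seed = 1L, threshold = 0,
                        simulateConfig = NULL, nSamples = 20000L,
                        sampler = c("gibbs", "exact"),
                        aG = 0.1, tol = 1e-5, maxIter = 5e5L,
                        clusterMode = c("barrier", "rate"),
                        alphaGrid = NULL, removeState = NULL) {
  sampler <- match.arg(sampler)
  clusterMode <- match.arg(clusterMode)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  truthModel <- NULL
  if (is.null(input)) {
    if (is.null(simulateConfig))
      simulateConfig <- generatorConfig(seed = seed)
    truthModel <- makeModel(simulateConfig)
    series <- if (sampler == "gibbs")
      sampleGibbs(truthModel, nSamples, seed = seed)
    else sampleExact(truthModel, nSamples, seed = seed)
    writeModel(truthModel, file.path(outDir, "model_truth.json"))
    writeTimeSeries(series, file.path(outDir, "series.tsv"))
  } else {
    raw <- readTimeSeries(input)
    series <- if (is(raw, "StateSeries")) raw
              else binarizeSeries(raw, threshold)
  }

  tT <- nrow(stateMatrix(series))
  eps <- 1 / (2 * tT)
  moments <- empiricalMoments(series)
  pEmp <- empiricalDistribution(series)
  indep <- fitIndependentMEM(moments, clipEps = eps)
  fit <- fitPairwiseMEM(moments, aG = aG, tol = tol, maxIter = maxIter,
                        clipEps = eps,
                        regionLabels = regionLabels(series))
  metrics <- fitMetrics(pEmp, indep, fit@model)
  writeModel(fit@model, file.path(outDir, "model_fitted.json"))
  jsonlite::write_json(
    list(converged = fit@converged, n_iterations = fit@nIterations,
         final_gradient = fit@finalGradientNorm,
         d1 = metrics@d1, d2 = metrics@d2, s1 = metrics@s1,
         s2 = metrics@s2, sN = metrics@sN, r_d = metrics@rD,
         r_s = metrics@rS, er = metrics@er),
    file.path(outDir, "fit_metrics.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)

  ls <- findLocalMinima(fit@model)
  lm <- ls@localMinima
  minimaTable <- data.frame(
    label = paste0("LM", seq_along(lm)), code = lm,
    bitstring = .bitString(lm, ls@nRegions),
    energy = ls@energies[lm + 1L],
    isGlobal = lm == ls@globalMinimum)
  .writeTable(minimaTable, file.path(outDir, "minima.tsv"))

  out <- list(series = series, model = fit@model, fit = fit,
              metrics = metrics, landscape = ls, truthModel = truthModel,
              minima = minimaTable)

  if (length(lm) >= 2L) {
    bar <- barrierMatrix(fit@model, ls)
    .writeTable(as.data.frame(bar@thresholds),
                file.path(outDir, "thresholds.tsv"))
    .writeTable(as.data.frame(bar@barriers),
                file.path(outDir, "barriers.tsv"))
    tree <- buildDisconnectivityTree(bar, ls)
    writeNewick(tree, file.path(outDir, "disconnectivity.nwk"))

    stnFS <- buildSTNFS(fit@model, ls)
    stnGM <- buildSTNGM(stnFS, ls)
    stnLM <- suppressMessages(buildSTNLM(stnFS@paths, ls))
    for (v in list(FS = stnFS, GM = stnGM, LM = stnLM)) {
      base <- file.path(outDir, paste0("stn_", tolower(v@variant)))
      writeNetwork(v, paste0(base, ".graphml"), "graphml")
      writeNetwork(v, paste0(base, ".tsv"), "edgelist_tsv")
    }
    clusters <- clusterLocalMinima(bar, mode = clusterMode)
    writeNewick(clusters, file.path(outDir, "dendrogram_upgma.nwk"))
    trans <- analyzeGroupTransitions(stnFS@paths, clusters, ls)
    .writeTable(trans, file.path(outDir, "transitions.tsv"))
    corBH <- tryCatch(correlatePearson(trans$hamming, trans$eB),
                      error = function(e) list(r = NA, p = NA,
                                               n = nrow(trans)))
    jsonlite::write_json(
      list(hamming_vs_barrier = corBH,
           groups = as.list(stats::setNames(clusters@groups,
                                            names(clusters@groups)))),
      file.path(outDir, "analysis.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
    out <- c(out, list(barriers = bar, tree = tree, stnFS = stnFS,
                       stnGM = stnGM, stnLM = stnLM, clusters = clusters,
                       transitions = trans, corBH = corBH))

    if (!is.null(removeState)) {
      rr <- removeStateAndReroute(fit@model, ls, removeState)
      .writeTable(rr$summary, file.path(outDir, "reroute.tsv"))
      out$reroute <- rr
    }
  } else {
    warning("fitted landscape has a single local minimum; ",
            "transition-network stages skipped")
  }

  if (!is.null(alphaGrid)) {
    sw <- sweepAlpha(fit@model, alphaGrid)
    .writeTable(sw@summaries, file.path(outDir, "alpha_sweep.tsv"))
    out$sweep <- sw
  }

  .writeProvenance(outDir, "pipeline",
                   list(input = input, threshold = threshold,
                        nSamples = if (is.null(input)) nSamples else NA,
                        sampler = sampler, aG = aG, tol = tol,
                        maxIter = maxIter, clusterMode = clusterMode,
                        alphaGrid = alphaGrid, removeState = removeState),
                   seed)
  invisible(out)
}
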