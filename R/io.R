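# Readers and writers: TSV/CSV time series, JSON model parameter files,
# GraphML / edge-list network exports, Newick dendrograms.

#' Read a multivariate time series from TSV/CSV
#'
#' One row per time point, one column per region, header row of region
#' labels. Binary tables are returned as a \linkS4class{StateSeries};
#' continuous tables as a plain numeric matrix (binarize with
#' [binarizeSeries()]).
#'
#' @param path file path; tab- or comma-separated (chosen by extension,
#'   ".csv" means comma).
#' @return A \linkS4class{StateSeries} or a numeric matrix with column
#'   names.
#' @export
readTimeSeries <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "numeric")
  x <- as.matrix(df)
  if (any(is.na(x))) {
    bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing or non-numeric cell at row %d, column '%s'",
                 bad[1L], colnames(x)[bad[2L]]), call. = FALSE)
  }
  if (all(x == 0 | x == 1)) StateSeries(x) else x
}

#' Write a time series as TSV (or CSV)
#'
#' Continuous values are rendered with 17 significant digits so that a
#' write/read round trip is exact; binary series round-trip identically.
#'
#' @param series a \linkS4class{StateSeries} or numeric matrix.
#' @param path output file path (".csv" switches to comma separation).
#' @return invisibly, the path.
#' @export
writeTimeSeries <- function(series, path) {
  x <- if (is(series, "StateSeries")) series@states else as.matrix(series)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(x), collapse = sep), con)
  body <- apply(x, 1L, function(row)
    paste(formatC(row, format = if (is.integer(x)) "d" else "g",
                  digits = 17), collapse = sep))
  writeLines(body, con)
  invisible(path)
}

#' Read a pairwise model from a JSON parameter file
#'
#' Expected keys: \code{n_regions}, \code{region_labels}, \code{h} (length-N
#' array), \code{j} (N x N array). Symmetry and the zero diagonal are
#' validated on read.
#'
#' @param path JSON file path.
#' @return A \linkS4class{PairwiseModel}.
#' @export
readModel <- function(path) {
  obj <- jsonlite::fromJSON(path)
  for (key in c("n_regions", "h", "j")) {
    if (is.null(obj[[key]]))
      stop(sprintf("model file is missing required key '%s'", key),
           call. = FALSE)
  }
  j <- as.matrix(obj$j)
  if (!isTRUE(all.equal(j, t(j), tolerance = 0)))
    stop("coupling matrix in model file is not symmetric", call. = FALSE)
  if (any(diag(j) != 0))
    stop("coupling matrix in model file has a nonzero diagonal",
         call. = FALSE)
  labels <- obj$region_labels
  if (is.null(labels)) labels <- paste0("R", seq_len(obj$n_regions))
  m <- PairwiseModel(h = obj$h, j = j, regionLabels = labels)
  if (m@nRegions != obj$n_regions)
    stop("n_regions does not match the parameter dimensions", call. = FALSE)
  m
}

#' Write a pairwise model to JSON
#'
#' Values are serialized at full double precision (17 significant digits) so
#' the round trip through [readModel()] is exact.
#'
#' @param model a \linkS4class{PairwiseModel}.
#' @param path output JSON path.
#' @return invisibly, the path.
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "PairwiseModel"))
  obj <- list(n_regions = model@nRegions,
              region_labels = model@regionLabels,
              h = model@h, j = model@j)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Export a transition network
#'
#' GraphML carries node attributes (code, bitstring, role, energy) and edge
#' attributes (rate, e_b, pathway, multiplicity); the edge-list TSV has
#' columns from_code, to_code, rate, e_b, pathway. Nodes and edges are
#' ordered by state code, so re-export is byte-identical across runs.
#'
#' @param network a \linkS4class{TransitionNetwork}.
#' @param path output file path.
#' @param format "graphml" or "edgelist_tsv".
#' @return invisibly, the path.
#' @export
writeNetwork <- function(network, path,
                         format = c("graphml", "edgelist_tsv")) {
  format <- match.arg(format)
  stopifnot(is(network, "TransitionNetwork"))
  g <- network@graph
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    el <- igraph::as_data_frame(g, what = "edges")
    out <- data.frame(from_code = as.integer(el$from),
                      to_code = as.integer(el$to),
                      rate = el$rate, e_b = el$e_b, pathway = el$pathway)
    out <- out[order(out$from_code, out$to_code), , drop = FALSE]
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("from_code\tto_code\trate\te_b\tpathway", con)
    writeLines(sprintf("%d\t%d\t%.17g\t%.17g\t%d", out$from_code,
                       out$to_code, out$rate, out$e_b, out$pathway), con)
  }
  invisible(path)
}

#' Export a dendrogram or disconnectivity tree as Newick
#'
#' @param tree a \linkS4class{DisconnectivityTree} or
#'   \linkS4class{ClusterResult}.
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeNewick <- function(tree, path) {
  hc <- if (is(tree, "DisconnectivityTree") || is(tree, "ClusterResult")) {
    structure(tree@hclust, class = "hclust")
  } else stop("unsupported tree object", call. = FALSE)
  phy <- ape::as.phylo(hc)
  ape::write.tree(phy, file = path)
  invisible(path)
}
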