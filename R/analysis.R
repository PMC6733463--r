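# Graph-theoretic and statistical analysis of the transition networks:
# path-length decompositions, degree profiles, UPGMA grouping of minima,
# correlations, and coupling-scale perturbation sweeps.

#' Path-length decomposition of a transition pathway
#'
#' Full length (number of single-flip steps), segment lengths from the
#' source to the rate-determining transition state and from there to the
#' target, and the effective path length: full length minus the Hamming
#' distance of the endpoints (the excess detour beyond a geodesic; always
#' even and non-negative by parity).
#'
#' @param path a \linkS4class{TransitionPath}.
#' @return named list with \code{full}, \code{toTS}, \code{fromTS},
#'   \code{effective} (integers).
#' @export
pathLengths <- function(path) {
  stopifnot(is(path, "TransitionPath"))
  s <- path@states
  full <- length(s) - 1L
  tsPos <- match(path@tsCode, s)
  ham <- .hammingCodes(s[1L], s[length(s)])
  list(full = full, toTS = tsPos - 1L, fromTS = full - (tsPos - 1L),
       effective = full - ham)
}

#' Node degrees of a transition network
#'
#' Degrees are computed on the collapsed undirected simple graph (parallel
#' and reciprocal edges merged), the usual reading of a degree histogram for
#' a directed pathway network. Nodes whose degree exceeds the network mean
#' by more than two standard deviations are flagged as hub candidates
#' (reported, not asserted).
#'
#' @param network a \linkS4class{TransitionNetwork}.
#' @return data.frame (code, role, degree, hub) sorted by degree descending.
#' @export
nodeDegreeProfile <- function(network) {
  stopifnot(is(network, "TransitionNetwork"))
  g <- igraph::as_undirected(network@graph, mode = "collapse")
  g <- igraph::simplify(g)
  deg <- igraph::degree(g)
  out <- data.frame(code = igraph::V(network@graph)$code,
                    role = igraph::V(network@graph)$role,
                    degree = as.integer(deg[igraph::V(network@graph)$name]))
  out$hub <- out$degree > mean(out$degree) + 2 * stats::sd(out$degree)
  out[order(-out$degree, out$code), , drop = FALSE]
}

#' UPGMA grouping of local minima
#'
#' Each minimum is represented by its row of pairwise values (transition
#' rates in "rate" mode, energy barriers in "barrier" mode; self-entry 0);
#' average-linkage (UPGMA) clustering is applied to the Euclidean distances
#' between these feature vectors, and the tree is cut into \code{k} groups
#' (default 2). Alternatively the pairwise matrix can be used directly as a
#' dissimilarity (\code{directDissimilarity = TRUE}; rates are converted to
#' dissimilarities as 1 - rate).
#'
#' @param barriers a \linkS4class{BarrierSet}.
#' @param mode "barrier" or "rate": which pairwise matrix builds the
#'   features. Rates are \eqn{e^{-E_B}} of the symmetric pair barriers.
#' @param k number of groups at the cut (default 2).
#' @param directDissimilarity use the pairwise matrix itself as the
#'   dissimilarity instead of row-vector Euclidean distances.
#' @return A \linkS4class{ClusterResult}; group names are the minima codes.
#' @export
clusterLocalMinima <- function(barriers, mode = c("barrier", "rate"),
                               k = 2L, directDissimilarity = FALSE) {
  mode <- match.arg(mode)
  stopifnot(is(barriers, "BarrierSet"))
  m <- length(barriers@minima)
  if (m < 2L) stop("need at least two local minima", call. = FALSE)
  mat <- if (mode == "barrier") barriers@barriers else exp(-barriers@barriers)
  diag(mat) <- 0
  d <- if (directDissimilarity) {
    stats::as.dist(if (mode == "rate") 1 - mat else mat)
  } else {
    stats::dist(mat)
  }
  hc <- stats::hclust(d, method = "average")
  groups <- stats::setNames(as.integer(stats::cutree(hc, k = min(k, m))),
                            as.character(barriers@minima))
  new("ClusterResult", hclust = unclass(hc), groups = groups, mode = mode)
}

#' Pearson correlation with a t-distribution p-value
#'
#' @param x,y numeric vectors of equal length n >= 3; neither may be
#'   constant.
#' @return list with \code{r}, \code{p} (two-sided, t with n - 2 df) and
#'   \code{n}.
#' @export
correlatePearson <- function(x, y) {
  if (length(x) != length(y)) stop("inputs must have equal length",
                                   call. = FALSE)
  n <- length(x)
  if (n < 3L) stop("need at least three observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("degenerate (constant) input", call. = FALSE)
  r <- stats::cor(x, y)
  p <- if (abs(r) == 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Tabulate all pairwise transitions with group labels
#'
#' One record per ordered pair of local minima (both directions of every
#' pathway): source and target group at the cluster cut, Hamming distance of
#' the endpoints, directed barrier and rate, and the path-length
#' decomposition measured in that direction. Transitions are tagged intra
#' (same group) or inter (different groups); this table feeds the
#' Hamming/path-length correlation analyses.
#'
#' @param paths list of \linkS4class{TransitionPath} objects covering all
#'   minima pairs.
#' @param clusters a \linkS4class{ClusterResult} over the same minima.
#' @param landscape the matching \linkS4class{EnergyLandscape}.
#' @return data.frame with one row per ordered pair.
#' @export
analyzeGroupTransitions <- function(paths, clusters, landscape) {
  stopifnot(is(clusters, "ClusterResult"), is(landscape, "EnergyLandscape"))
  paths <- Filter(Negate(is.null), paths)
  e <- landscape@energies
  grp <- clusters@groups
  rows <- lapply(paths, function(p) {
    s <- p@states
    ham <- .hammingCodes(s[1L], s[length(s)])
    full <- length(s) - 1L
    tsPos <- match(p@tsCode, s)
    mk <- function(src, tgt, toTS, fromTS) {
      eB <- p@eTh - e[src + 1L]
      data.frame(source = src, target = tgt,
                 sourceGroup = grp[[as.character(src)]],
                 targetGroup = grp[[as.character(tgt)]],
                 type = if (grp[[as.character(src)]] ==
                            grp[[as.character(tgt)]]) "intra" else "inter",
                 hamming = ham, eTh = p@eTh, eB = eB, rate = exp(-eB),
                 full = full, toTS = toTS, fromTS = fromTS,
                 effective = full - ham, tsCode = p@tsCode)
    }
    rbind(mk(p@sourceLM, p@targetLM, tsPos - 1L, full - (tsPos - 1L)),
          mk(p@targetLM, p@sourceLM, full - (tsPos - 1L), tsPos - 1L))
  })
  do.call(rbind, rows)
}

#' Scale all pairwise couplings by a factor
#'
#' Replaces J by alpha * J while leaving H unchanged; the perturbation used
#' to probe how coupling strength shapes the landscape's multistability.
#'
#' @param model a \linkS4class{PairwiseModel}.
#' @param alpha non-negative scale factor.
#' @return A \linkS4class{PairwiseModel}.
#' @export
scaleInteractions <- function(model, alpha) {
  stopifnot(is(model, "PairwiseModel"), alpha >= 0)
  PairwiseModel(h = model@h, j = alpha * model@j,
                regionLabels = model@regionLabels)
}

#' Randomize model parameters
#'
#' Control systems for the landscape analysis: \code{permute_h} shuffles the
#' baseline sensitivities, \code{permute_j} shuffles the upper-triangle
#' couplings (then re-symmetrizes), and \code{random_values} redraws every
#' parameter uniformly from the range of the empirical values. All preserve
#' symmetry and the zero diagonal; deterministic given the seed.
#'
#' @param model a \linkS4class{PairwiseModel}.
#' @param mode "permute_h", "permute_j" or "random_values".
#' @param seed RNG seed.
#' @return A \linkS4class{PairwiseModel}.
#' @export
permuteParameters <- function(model, mode = c("permute_h", "permute_j",
                                              "random_values"), seed = 1L) {
  mode <- match.arg(mode)
  n <- model@nRegions
  .withSeed(seed, {
    h <- model@h
    j <- model@j
    if (mode == "permute_h") {
      h <- sample(h)
    } else if (mode == "permute_j") {
      up <- upper.tri(j)
      j[up] <- sample(j[up])
      j[lower.tri(j)] <- 0
      j <- j + t(j)
    } else {
      h <- stats::runif(n, min(model@h), max(model@h))
      up <- upper.tri(j)
      vals <- stats::runif(sum(up), min(model@j[up]), max(model@j[up]))
      j[] <- 0
      j[up] <- vals
      j <- j + t(j)
    }
    PairwiseModel(h = h, j = j, regionLabels = model@regionLabels)
  })
}

#' Sweep the coupling scale factor and summarize each perturbed landscape
#'
#' For each alpha on the grid, all couplings are scaled by alpha and the
#' landscape is recomputed; when at least two local minima survive, the
#' full-state transition network is rebuilt and summarized (node count, edge
#' count, maximum collapsed degree, effective-path-length histogram).
#'
#' @param model a \linkS4class{PairwiseModel}.
#' @param alphas grid of non-negative scale factors (default 0.0 to 5.0 in
#'   steps of 0.1).
#' @return A \linkS4class{PerturbationSweep}.
#' @export
sweepAlpha <- function(model, alphas = seq(0, 5, by = 0.1)) {
  stopifnot(all(alphas >= 0))
  counts <- integer(length(alphas))
  nodes <- edges <- maxDeg <- rep(NA_integer_, length(alphas))
  hists <- vector("list", length(alphas))
  for (k in seq_along(alphas)) {
    pm <- scaleInteractions(model, alphas[k])
    ls <- findLocalMinima(pm)
    counts[k] <- length(ls@localMinima)
    if (counts[k] >= 2L) {
      stn <- buildSTNFS(pm, ls)
      g <- stn@graph
      nodes[k] <- igraph::vcount(g)
      edges[k] <- igraph::ecount(g)
      maxDeg[k] <- max(nodeDegreeProfile(stn)$degree)
      epl <- vapply(stn@paths, function(p) pathLengths(p)$effective,
                    integer(1))
      hists[[k]] <- table(epl)
    }
  }
  new("PerturbationSweep", alphas = as.numeric(alphas),
      minimaCounts = counts,
      summaries = data.frame(alpha = alphas, minima = counts, nodes = nodes,
                             edges = edges, maxDegree = maxDeg),
      eplHistograms = hists)
}
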