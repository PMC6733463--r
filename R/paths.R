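# Minimax transition paths between local minima, rate-determining transition
# states, and the three state-transition network variants (FS, GM, LM).

# BFS distances from `from` over the alive subgraph (single-flip moves);
# NA where unreachable.
.distBFS <- function(alive, from, nRegions) {
  bits <- bitwShiftL(1L, seq_len(nRegions) - 1L)
  dist <- rep(NA_integer_, length(alive))
  dist[from] <- 0L
  queue <- from
  d <- 0L
  while (length(queue)) {
    d <- d + 1L
    nxt <- integer(0)
    for (s in queue) {
      for (b in bits) {
        nb <- bitwXor(s - 1L, b) + 1L
        if (!alive[nb] || !is.na(dist[nb])) next
        dist[nb] <- d
        nxt <- c(nxt, nb)
      }
    }
    queue <- nxt
  }
  dist
}

#' Minimax transition path between two local minima
#'
#' Returns a single-flip path achieving the pair's bottleneck threshold
#' \eqn{E_{th}}: among all paths confined to states with energy at most
#' \eqn{E_{th}}, the shortest one, with remaining ties broken by the
#' lexicographically smallest code sequence (deterministic). The path runs
#' from the higher-energy minimum (source) to the lower-energy one; the
#' highest-energy state on it is the rate-determining transition state (ties
#' resolved to the state closest to the source). Equal-energy endpoint pairs
#' are oriented smaller-code-first.
#'
#' @param model a \linkS4class{PairwiseModel}.
#' @param lmI,lmJ local-minimum state codes.
#' @param landscape optional precomputed \linkS4class{EnergyLandscape}.
#' @param excluded state codes removed from the landscape before pathfinding
#'   (must not include the endpoints).
#' @return A \linkS4class{TransitionPath}, or NULL when the exclusions
#'   disconnect the pair.
#' @export
minimaxPath <- function(model, lmI, lmJ, landscape = NULL,
                        excluded = integer(0)) {
  if (is.null(landscape)) landscape <- findLocalMinima(model)
  lm <- landscape@localMinima
  if (!(lmI %in% lm) || !(lmJ %in% lm))
    stop("both states must be local minima", call. = FALSE)
  e <- landscape@energies
  # orient: source is the higher-energy endpoint (ties: smaller code first)
  if (e[lmI + 1L] < e[lmJ + 1L] ||
      (e[lmI + 1L] == e[lmJ + 1L] && lmI > lmJ)) {
    tmp <- lmI; lmI <- lmJ; lmJ <- tmp
  }
  eTh <- .allPairThresholds(e, c(lmI, lmJ), landscape@nRegions,
                            excluded = excluded)[1L, 2L]
  if (!is.finite(eTh)) return(NULL)
  .pathFromThreshold(landscape, lmI, lmJ, eTh, excluded)
}

.pathFromThreshold <- function(landscape, source, target, eTh,
                               excluded = integer(0)) {
  e <- landscape@energies
  n <- landscape@nRegions
  alive <- e <= eTh
  if (length(excluded)) alive[excluded + 1L] <- FALSE
  dist <- .distBFS(alive, target + 1L, n)
  stopifnot(!is.na(dist[source + 1L]))
  bits <- bitwShiftL(1L, seq_len(n) - 1L)
  path <- source + 1L
  cur <- source + 1L
  while (cur != target + 1L) {
    nbs <- bitwXor(cur - 1L, bits) + 1L
    cand <- nbs[alive[nbs] & !is.na(dist[nbs]) & dist[nbs] == dist[cur] - 1L]
    cur <- min(cand)                      # lexicographically smallest
    path <- c(path, cur)
  }
  codes <- as.integer(path - 1L)
  pe <- e[path]
  ts <- codes[which.max(pe)]              # which.max = first tie -> nearest source
  interior <- codes[-c(1L, length(codes))]
  new("TransitionPath",
      sourceLM = as.integer(source), targetLM = as.integer(target),
      states = codes, eTh = eTh, eB = eTh - e[source + 1L],
      tsCode = as.integer(ts),
      intermediates = as.integer(interior[interior %in%
                                          landscape@localMinima]))
}

#' Local minima lying strictly inside a transition path
#'
#' Intermediate states: interior path states (endpoints excluded) that are
#' themselves local minima, in path order.
#'
#' @param path a \linkS4class{TransitionPath}.
#' @param landscape the matching \linkS4class{EnergyLandscape}.
#' @return integer vector of state codes (possibly empty).
#' @export
locateIntermediates <- function(path, landscape) {
  stopifnot(is(path, "TransitionPath"), is(landscape, "EnergyLandscape"))
  codes <- path@states
  if (length(codes) <= 2L) return(integer(0))
  interior <- codes[-c(1L, length(codes))]
  as.integer(interior[interior %in% landscape@localMinima])
}

#' Transition rate from an energy barrier
#'
#' Transition-state theory rate \eqn{\exp(-E_B)} for a barrier
#' \eqn{E_B \ge 0}.
#'
#' @param eB non-negative energy barrier(s).
#' @return numeric rate(s) in (0, 1].
#' @export
transitionRate <- function(eB) {
  if (any(eB < 0)) stop("energy barrier must be non-negative", call. = FALSE)
  exp(-eB)
}

# Minimax paths for every unordered pair of local minima (source = higher
# energy endpoint). With exclusions, disconnected pairs yield NULL entries.
.allMinimaxPaths <- function(model, landscape, excluded = integer(0)) {
  lm <- landscape@localMinima
  m <- length(lm)
  if (m < 2L) return(list())
  pairs <- utils::combn(m, 2L)
  lapply(seq_len(ncol(pairs)), function(k) {
    minimaxPath(model, lm[pairs[1L, k]], lm[pairs[2L, k]],
                landscape = landscape, excluded = excluded)
  })
}

# Assemble a transition network from pathway step edges (FS/GM variants).
.assembleSTN <- function(paths, landscape, variant) {
  paths <- Filter(Negate(is.null), paths)
  n <- landscape@nRegions
  e <- landscape@energies
  lm <- landscape@localMinima
  tsCodes <- unique(vapply(paths, function(p) p@tsCode, integer(1)))

  edgeKey <- character(0)
  from <- integer(0); to <- integer(0)
  rate <- numeric(0); barrier <- numeric(0)
  pathway <- integer(0); mult <- integer(0)
  for (k in seq_along(paths)) {
    p <- paths[[k]]
    r <- exp(-p@eB)
    s <- p@states
    for (i in seq_len(length(s) - 1L)) {
      key <- paste0(s[i], ">", s[i + 1L])
      hit <- match(key, edgeKey)
      if (is.na(hit)) {
        edgeKey <- c(edgeKey, key)
        from <- c(from, s[i]); to <- c(to, s[i + 1L])
        rate <- c(rate, r); barrier <- c(barrier, p@eB)
        pathway <- c(pathway, k); mult <- c(mult, 1L)
      } else {
        mult[hit] <- mult[hit] + 1L
        if (r > rate[hit]) {          # shared step edge keeps the max rate
          rate[hit] <- r; barrier[hit] <- p@eB; pathway[hit] <- k
        }
      }
    }
  }
  nodes <- sort(unique(c(from, to,
                         vapply(paths, function(p) p@sourceLM, integer(1)),
                         vapply(paths, function(p) p@targetLM, integer(1)))))
  role <- ifelse(nodes %in% lm, "local_minimum",
                 ifelse(nodes %in% tsCodes, "transition_state", "transient"))
  vdf <- data.frame(name = as.character(nodes), code = nodes,
                    bitstring = .bitString(nodes, n), role = role,
                    energy = e[nodes + 1L], stringsAsFactors = FALSE)
  ord <- order(from, to)
  edf <- data.frame(from = as.character(from[ord]), to = as.character(to[ord]),
                    rate = rate[ord], e_b = barrier[ord],
                    pathway = pathway[ord], multiplicity = mult[ord],
                    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
  new("TransitionNetwork", variant = variant, graph = g, paths = paths)
}

#' Build the full-state transition network (STN-FS)
#'
#' For every pair of local minima the minimax pathway is extracted (oriented
#' from the higher- to the lower-energy minimum); all states on all pathways
#' become nodes, and each consecutive state pair on a pathway becomes a
#' directed edge weighted by that pathway's overall rate \eqn{e^{-E_B}}.
#' When several pathways share a step edge the largest rate is kept and a
#' multiplicity counter records the sharing.
#'
#' @param model a \linkS4class{PairwiseModel}.
#' @param landscape optional precomputed \linkS4class{EnergyLandscape}.
#' @return A \linkS4class{TransitionNetwork} (variant "FS").
#' @export
buildSTNFS <- function(model, landscape = NULL) {
  if (is.null(landscape)) landscape <- findLocalMinima(model)
  if (length(landscape@localMinima) < 2L)
    stop("need at least two local minima to build a transition network",
         call. = FALSE)
  paths <- .allMinimaxPaths(model, landscape)
  .assembleSTN(paths, landscape, "FS")
}

#' Build the global-minimum transition network (STN-GM)
#'
#' Restriction of the STN-FS to the pathways whose target is the global
#' minimum: the m - 1 transition processes from every other local minimum
#' toward the most stable state.
#'
#' @param stnFS the \linkS4class{TransitionNetwork} from [buildSTNFS()].
#' @param landscape the matching \linkS4class{EnergyLandscape}.
#' @return A \linkS4class{TransitionNetwork} (variant "GM").
#' @export
buildSTNGM <- function(stnFS, landscape) {
  stopifnot(is(stnFS, "TransitionNetwork"), stnFS@variant == "FS")
  gm <- landscape@globalMinimum
  keep <- Filter(function(p) p@targetLM == gm, stnFS@paths)
  .assembleSTN(keep, landscape, "GM")
}

#' Build the minima/transition-state network (STN-LM)
#'
#' Nodes are the local minima plus the distinct rate-determining transition
#' states; each pathway contributes an inward edge source -> TS and an
#' outward edge TS -> target, both carrying the pathway rate. When two
#' minima are Hamming-1 adjacent the TS coincides with the source minimum
#' and a single direct edge source -> target is used (logged). Parallel
#' contributions to an edge keep the maximum rate.
#'
#' @param paths list of \linkS4class{TransitionPath} objects covering all
#'   minima pairs (e.g. \code{pathList(stnFS)}).
#' @param landscape the matching \linkS4class{EnergyLandscape}.
#' @return A \linkS4class{TransitionNetwork} (variant "LM").
#' @export
buildSTNLM <- function(paths, landscape) {
  paths <- Filter(Negate(is.null), paths)
  stopifnot(length(paths) >= 1L, is(landscape, "EnergyLandscape"))
  lm <- landscape@localMinima
  e <- landscape@energies
  n <- landscape@nRegions

  key <- character(0)
  from <- integer(0); to <- integer(0)
  rate <- numeric(0); barrier <- numeric(0); pathway <- integer(0)
  addEdge <- function(a, b, r, eb, k) {
    kk <- paste0(a, ">", b)
    hit <- match(kk, key)
    if (is.na(hit)) {
      key <<- c(key, kk)
      from <<- c(from, a); to <<- c(to, b)
      rate <<- c(rate, r); barrier <<- c(barrier, eb); pathway <<- c(pathway, k)
    } else if (r > rate[hit]) {
      rate[hit] <<- r; barrier[hit] <<- eb; pathway[hit] <<- k
    }
  }
  for (k in seq_along(paths)) {
    p <- paths[[k]]
    r <- exp(-p@eB)
    if (p@tsCode == p@sourceLM) {
      # adjacent minima: the source itself is the bottleneck
      message(sprintf("minima %d and %d are Hamming-1 adjacent; direct edge used",
                      p@sourceLM, p@targetLM))
      addEdge(p@sourceLM, p@targetLM, r, p@eB, k)
    } else {
      addEdge(p@sourceLM, p@tsCode, r, p@eB, k)
      addEdge(p@tsCode, p@targetLM, r, p@eB, k)
    }
  }
  nodes <- sort(unique(c(from, to, lm)))
  role <- ifelse(nodes %in% lm, "local_minimum", "transition_state")
  vdf <- data.frame(name = as.character(nodes), code = nodes,
                    bitstring = .bitString(nodes, n), role = role,
                    energy = e[nodes + 1L], stringsAsFactors = FALSE)
  ord <- order(from, to)
  edf <- data.frame(from = as.character(from[ord]), to = as.character(to[ord]),
                    rate = rate[ord], e_b = barrier[ord],
                    pathway = pathway[ord],
                    multiplicity = 1L, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edf, directed = TRUE, vertices = vdf)
  new("TransitionNetwork", variant = "LM", graph = g, paths = paths)
}

#' Recompute all pathways after removing a state from the landscape
#'
#' Deletes a single state code from the landscape and re-extracts the
#' minimax pathway for every pair of local minima over the remaining states.
#' Thresholds can only rise (the path set shrinks under deletion); pairs
#' left with no connecting path are flagged disconnected. Removal of one
#' state per call; iterative multi-removal is composed via
#' \code{additionalExcluded}.
#'
#' @param model a \linkS4class{PairwiseModel}.
#' @param landscape the \linkS4class{EnergyLandscape} of the model.
#' @param removed state code to delete; must not be a local minimum.
#' @param additionalExcluded further codes already removed (for composed
#'   multi-removal).
#' @return list with \code{paths} (list of \linkS4class{TransitionPath} or
#'   NULL where disconnected) and \code{summary} (data.frame with source,
#'   target, eTh, tsCode, eB, disconnected per pair).
#' @export
removeStateAndReroute <- function(model, landscape, removed,
                                  additionalExcluded = integer(0)) {
  stopifnot(is(landscape, "EnergyLandscape"))
  removed <- as.integer(removed)
  if (length(removed) != 1L)
    stop("exactly one state is removed per call", call. = FALSE)
  if (removed %in% landscape@localMinima)
    stop("cannot remove a state that is itself a local minimum",
         call. = FALSE)
  excl <- unique(c(removed, as.integer(additionalExcluded)))
  paths <- .allMinimaxPaths(model, landscape, excluded = excl)
  lm <- landscape@localMinima
  pairs <- utils::combn(length(lm), 2L)
  summary <- data.frame(
    source = integer(ncol(pairs)), target = integer(ncol(pairs)),
    eTh = NA_real_, tsCode = NA_integer_, eB = NA_real_,
    disconnected = FALSE)
  for (k in seq_len(ncol(pairs))) {
    p <- paths[[k]]
    if (is.null(p)) {
      a <- lm[pairs[1L, k]]; b <- lm[pairs[2L, k]]
      e <- landscape@energies
      hi <- if (e[a + 1L] > e[b + 1L] ||
                (e[a + 1L] == e[b + 1L] && a < b)) a else b
      summary[k, ] <- list(hi, setdiff(c(a, b), hi), NA_real_, NA_integer_,
                           NA_real_, TRUE)
    } else {
      summary[k, ] <- list(p@sourceLM, p@targetLM, p@eTh, p@tsCode, p@eB,
                           FALSE)
    }
  }
  list(paths = paths, summary = summary)
}
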