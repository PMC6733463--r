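# Energy landscape analysis: local minima, minimax barrier thresholds via an
# energy-ascending union-find filtration, and the disconnectivity tree.

#' Find the local minima of a model's energy landscape
#'
#' A state is a local minimum (stable state) when its energy is strictly
#' lower than the energies of all N Hamming-distance-1 neighbors. Minima are
#' returned sorted by energy (ascending, ties broken by smaller code with a
#' warning); the first is the global minimum.
#'
#' @param model a \linkS4class{PairwiseModel} with N <= 20.
#' @return An \linkS4class{EnergyLandscape}.
#' @export
findLocalMinima <- function(model) {
  n <- model@nRegions
  e <- enumerateEnergies(model)
  codes <- 0:(2^n - 1)
  isMin <- rep(TRUE, 2^n)
  anyTie <- FALSE
  for (i in seq_len(n)) {
    nbE <- e[bitwXor(codes, bitwShiftL(1L, i - 1L)) + 1L]
    if (!anyTie && any(e == nbE)) anyTie <- TRUE
    isMin <- isMin & (e < nbE)
  }
  if (anyTie)
    warning("exact energy ties between neighboring states detected; ",
            "minimum and barrier tie-breaking depends on code order")
  lm <- codes[isMin]
  ord <- order(e[lm + 1L], lm)
  lm <- lm[ord]
  if (length(lm) >= 2L && e[lm[1L] + 1L] == e[lm[2L] + 1L])
    warning("global minimum is tied; the smaller state code was chosen")
  new("EnergyLandscape", energies = e, localMinima = as.integer(lm),
      globalMinimum = as.integer(lm[1L]), nRegions = as.integer(n))
}

# --- union-find filtration ---------------------------------------------------
# States are added in increasing energy order (ties by code); two minima's
# components merge at the energy of the state whose addition connects them,
# which is exactly the minimax (bottleneck) threshold over single-flip paths.

# thresholds for all minima pairs; excluded codes are never added.
# Returns an m x m matrix (Inf where disconnected, NA diagonal).
.allPairThresholds <- function(energies, minima, nRegions,
                               excluded = integer(0)) {
  m <- length(minima)
  th <- matrix(Inf, m, m)
  diag(th) <- NA_real_
  if (m < 2L) return(th)
  nStates <- length(energies)
  minIndex <- integer(nStates)            # 1-based state -> minima position
  minIndex[minima + 1L] <- seq_len(m)
  if (any(minIndex[excluded + 1L] > 0L))
    stop("cannot exclude a state that is itself a queried local minimum",
         call. = FALSE)

  ord <- order(energies, seq_len(nStates))
  if (length(excluded))
    ord <- ord[!(ord %in% (excluded + 1L))]

  parent <- integer(nStates)              # 0 = not yet added
  minSets <- vector("list", nStates)      # minima positions per root
  bits <- bitwShiftL(1L, seq_len(nRegions) - 1L)
  left <- choose(m, 2)

  find <- function(x) {
    root <- x
    while (parent[root] != root) root <- parent[root]
    while (parent[x] != root) {
      nxt <- parent[x]
      parent[x] <<- root
      x <- nxt
    }
    root
  }

  for (s in ord) {
    parent[s] <- s
    mi <- minIndex[s]
    if (mi > 0L) minSets[[s]] <- mi
    for (b in bits) {
      nb <- bitwXor(s - 1L, b) + 1L
      if (parent[nb] == 0L) next
      ra <- find(s)
      rb <- find(nb)
      if (ra == rb) next
      sa <- minSets[[ra]]
      sb <- minSets[[rb]]
      if (length(sa) && length(sb)) {
        th[sa, sb] <- energies[s]
        th[sb, sa] <- energies[s]
        left <- left - length(sa) * length(sb)
      }
      # union by attaching ra under rb
      parent[ra] <- rb
      if (length(sa)) {
        minSets[[rb]] <- c(sb, sa)
        minSets[ra] <- list(NULL)
      }
    }
    if (left == 0L) break
  }
  th
}

#' Minimax threshold energy between two local minima
#'
#' The threshold \eqn{E_{th}} is the minimum over all single-flip paths of
#' the maximum state energy along the path (the bottleneck energy at which
#' the two basins first connect when the landscape is filled from below).
#' Computed by an energy-ascending union-find filtration, which yields the
#' same value as the iterative shortest-path/removal procedure implemented
#' in [pairThresholdOracle()].
#'
#' @param model a \linkS4class{PairwiseModel}.
#' @param lmI,lmJ state codes; both must be local minima of the model.
#' @param landscape optional precomputed \linkS4class{EnergyLandscape}.
#' @return numeric E_th (Inf if the minima are disconnected, which cannot
#'   happen without state exclusions).
#' @export
pairThreshold <- function(model, lmI, lmJ, landscape = NULL) {
  if (is.null(landscape)) landscape <- findLocalMinima(model)
  lm <- landscape@localMinima
  if (!(lmI %in% lm) || !(lmJ %in% lm))
    stop("both states must be local minima", call. = FALSE)
  th <- .allPairThresholds(landscape@energies, c(lmI, lmJ),
                           landscape@nRegions)
  th[1L, 2L]
}

# --- literal iterative-removal reference ------------------------------------

# BFS shortest path between two states over the alive subgraph; neighbors
# visited in ascending bit order. Returns 1-based state indices or NULL.
.bfsPath <- function(alive, from, to, nRegions) {
  bits <- bitwShiftL(1L, seq_len(nRegions) - 1L)
  prev <- integer(length(alive))
  prev[from] <- from
  queue <- from
  while (length(queue)) {
    nxt <- integer(0)
    for (s in queue) {
      for (b in bits) {
        nb <- bitwXor(s - 1L, b) + 1L
        if (!alive[nb] || prev[nb] != 0L) next
        prev[nb] <- s
        if (nb == to) {
          path <- nb
          while (path[1L] != from) path <- c(prev[path[1L]], path)
          return(path)
        }
        nxt <- c(nxt, nb)
      }
    }
    queue <- nxt
  }
  NULL
}

#' Reference implementation of the pair threshold (iterative removal)
#'
#' Literal transcription of the descriptive procedure: repeatedly find a
#' shortest single-flip path between the two minima, take its maximum energy
#' as the current threshold, delete all states with energy strictly above
#' that threshold, and stop when the minima are disconnected; the threshold
#' of the last connected path is E_th. (When a deletion pass removes
#' nothing, the states attaining the threshold -- never the minima
#' themselves -- are removed so the loop always terminates; energy ties make
#' this case reachable.) Kept as an independent cross-check of
#' [pairThreshold()]; quadratic in the worst case.
#'
#' @inheritParams pairThreshold
#' @return numeric E_th.
#' @export
pairThresholdOracle <- function(model, lmI, lmJ, landscape = NULL) {
  if (is.null(landscape)) landscape <- findLocalMinima(model)
  lm <- landscape@localMinima
  if (!(lmI %in% lm) || !(lmJ %in% lm))
    stop("both states must be local minima", call. = FALSE)
  e <- landscape@energies
  n <- landscape@nRegions
  alive <- rep(TRUE, length(e))
  from <- lmI + 1L
  to <- lmJ + 1L
  lastTh <- NA_real_
  repeat {
    path <- .bfsPath(alive, from, to, n)
    if (is.null(path)) return(lastTh)
    th <- max(e[path])
    lastTh <- th
    drop <- alive & e > th
    if (!any(drop)) {
      drop <- alive & e == th
      drop[c(from, to)] <- FALSE
    }
    alive[drop] <- FALSE
  }
}

#' Threshold and barrier matrices over all local-minima pairs
#'
#' For each pair of minima, the pair barrier is
#' \eqn{E_B(i,j) = E_{th}(i,j) - \max(E_i, E_j)} (the barrier seen from the
#' higher, i.e. less stable, minimum) and the directed barrier from i is
#' \eqn{E_{th}(i,j) - E_i}; the pair barrier equals the smaller of the two
#' directed barriers.
#'
#' @param model a \linkS4class{PairwiseModel}.
#' @param landscape optional precomputed \linkS4class{EnergyLandscape}.
#' @return A \linkS4class{BarrierSet}; with fewer than two minima an empty
#'   table is returned with a warning.
#' @export
barrierMatrix <- function(model, landscape = NULL) {
  if (is.null(landscape)) landscape <- findLocalMinima(model)
  lm <- landscape@localMinima
  eMin <- landscape@energies[lm + 1L]
  if (length(lm) < 2L) {
    warning("fewer than two local minima; barrier table is empty")
    empty <- matrix(numeric(0), 0, 0)
    return(new("BarrierSet", minima = lm, minimaEnergies = eMin,
               thresholds = empty, barriers = empty,
               directedBarriers = empty))
  }
  th <- .allPairThresholds(landscape@energies, lm, landscape@nRegions)
  pairMax <- outer(eMin, eMin, pmax)
  barriers <- th - pairMax
  directed <- th - matrix(eMin, length(lm), length(lm))
  dimnames(th) <- dimnames(barriers) <- dimnames(directed) <-
    list(as.character(lm), as.character(lm))
  new("BarrierSet", minima = lm, minimaEnergies = eMin, thresholds = th,
      barriers = barriers, directedBarriers = directed)
}

#' Disconnectivity tree of the local minima
#'
#' Single-linkage merge structure on the pairwise threshold energies: two
#' basins join at the energy at which they first become connected.
#' Bottleneck thresholds are ultrametric, so the tree's cophenetic heights
#' reproduce the threshold matrix exactly.
#'
#' @param barriers a \linkS4class{BarrierSet} (from [barrierMatrix()]).
#' @param landscape the matching \linkS4class{EnergyLandscape}.
#' @return A \linkS4class{DisconnectivityTree}.
#' @export
buildDisconnectivityTree <- function(barriers, landscape) {
  stopifnot(is(barriers, "BarrierSet"), is(landscape, "EnergyLandscape"))
  lm <- barriers@minima
  if (length(lm) < 2L)
    stop("need at least two local minima to build a tree", call. = FALSE)
  d <- barriers@thresholds
  hc <- stats::hclust(stats::as.dist(d), method = "single")
  new("DisconnectivityTree", hclust = unclass(hc),
      leafEnergies = barriers@minimaEnergies, minima = lm)
}
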