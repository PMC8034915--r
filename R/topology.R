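.asUndirectedGraph <- function(x) {
  if (is(x, "CeRNANetwork")) return(cernaGraph(x))
  if (inherits(x, "igraph")) return(x)
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop("edge table needs two id columns")
    return(igraph::graph_from_data_frame(x[, 1:2], directed = FALSE))
  }
  stop("cannot interpret 'x' as a network")
}

#' Node centralities of a ceRNA network
#'
#' Degree, betweenness and closeness for every node of an undirected simple
#' graph. Betweenness is the unnormalized shortest-path count
#' `sum over (s, t), s != v != t, of sigma_st(v) / sigma_st` (each unordered
#' pair counted once). Closeness follows the reciprocal-farness convention:
#' `1 / sum of d(v, u)` over the nodes `u` reachable from `v`, computed
#' within each connected component (cross-component distances are excluded
#' rather than treated as infinite), with 0 for isolated nodes. With
#' `normalized_closeness = TRUE` the within-component normalized variant
#' `(n_comp - 1) / sum d(v, u)` is reported instead.
#'
#' @param x a [CeRNANetwork-class], an igraph graph, or a two-column edge
#'   data.frame.
#' @param normalized_closeness logical(1), default `FALSE`.
#' @return data.frame with columns `node`, `partition` (`NA` when unknown),
#'   `degree`, `betweenness`, `closeness`.
#' @examples
#' path <- data.frame(from = c("A", "B"), to = c("B", "C"))
#' computeCentralities(path) # closeness(B) = 1/2, betweenness(B) = 1
#' @export
computeCentralities <- function(x, normalized_closeness = FALSE) {
  g <- .asUndirectedGraph(x)
  if (any(igraph::which_loop(g))) stop("self-loops are not allowed")
  g <- igraph::simplify(g)
  n <- igraph::vcount(g)
  nm <- igraph::V(g)$name
  if (is.null(nm)) nm <- as.character(seq_len(n))
  part <- igraph::vertex_attr(g, "partition")
  if (is.null(part)) part <- rep(NA_character_, n)

  deg <- as.integer(igraph::degree(g))
  btw <- if (n) as.numeric(igraph::betweenness(g, directed = FALSE, normalized = FALSE)) else numeric(0)
  d <- igraph::distances(g)
  clo <- vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    di <- di[is.finite(di)]
    if (!length(di)) return(0)
    if (normalized_closeness) length(di) / sum(di) else 1 / sum(di)
  }, numeric(1))
  data.frame(node = nm, partition = part, degree = deg,
             betweenness = btw, closeness = clo,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Log-log least-squares fit of the degree distribution
#'
#' Scale-free topology check: tabulates `N(k)`, the number of nodes with
#' degree `k`, over the observed degrees `k >= 1`, and fits
#' `log10 N(k) = intercept + slope * log10 k` by ordinary least squares.
#' Raw frequencies are used (no logarithmic binning); degrees with zero
#' count are absent by construction. An exact power law
#' `N(k) = c * k^(-gamma)` gives `slope = -gamma` and `r_squared = 1`.
#'
#' @param degrees integer vector of node degrees (zeros are ignored; at
#'   least two distinct positive degrees are required).
#' @return an object of class `PowerLawFit`: a list with `slope`,
#'   `intercept`, `r_squared` and the `points` data.frame
#'   (`k`, `count`, `log10_k`, `log10_count`).
#' @examples
#' deg <- rep(c(1, 2, 4, 8), c(64, 16, 4, 1)) # N(k) = 64 * k^-2
#' fitPowerLaw(deg)                            # slope -2, R^2 = 1
#' @export
fitPowerLaw <- function(degrees) {
  k <- degrees[degrees >= 1]
  if (!length(k)) stop("no positive degrees")
  tab <- table(k)
  kk <- as.numeric(names(tab))
  nk <- as.numeric(tab)
  if (length(kk) < 2L)
    stop("need at least two distinct positive degrees to fit")
  pts <- data.frame(k = kk, count = nk, log10_k = log10(kk),
                    log10_count = log10(nk))
  fit <- stats::lm(log10_count ~ log10_k, data = pts)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((pts$log10_count - mean(pts$log10_count))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = max(0, min(1, r2)),
                 points = pts),
            class = "PowerLawFit")
}

#' @export
print.PowerLawFit <- function(x, ...) {
  cat(sprintf("Power-law degree-distribution fit: slope %.4f, intercept %.4f, R^2 = %.4f (%d degree classes)\n",
              x$slope, x$intercept, x$r_squared, nrow(x$points)))
  invisible(x)
}

#' Key-node selection by top-k centrality intersection
#'
#' Ranks nodes in descending order by degree, betweenness and closeness,
#' takes the top `k` per measure with all boundary ties included (every node
#' tied with the k-th value is kept, so the result is order-independent),
#' and returns the three-way intersection together with the per-measure top
#' lists and rankings.
#'
#' @param centralities data.frame as returned by [computeCentralities()].
#' @param k integer(1). List depth per measure (default 10).
#' @param partition optional character(1); restrict ranking to nodes of this
#'   partition (e.g. `"lncRNA"`) before taking the top lists.
#' @return list with elements `key_nodes` (sorted character vector),
#'   `top_degree`, `top_betweenness`, `top_closeness`, and `rankings` (the
#'   filtered table with `rank_deg`, `rank_btw`, `rank_clo`; ties share the
#'   smallest rank).
#' @export
selectKeyNodes <- function(centralities, k = 10, partition = NULL) {
  if (k < 1) stop("k must be >= 1")
  tab <- centralities
  if (!is.null(partition)) tab <- tab[tab$partition %in% partition, , drop = FALSE]
  if (!nrow(tab)) stop("no nodes to rank (empty table after filtering)")
  topWithTies <- function(v) {
    ord <- sort(v, decreasing = TRUE)
    thr <- ord[min(k, length(ord))]
    tab$node[v >= thr]
  }
  rk <- function(v) as.integer(rank(-v, ties.method = "min"))
  tab$rank_deg <- rk(tab$degree)
  tab$rank_btw <- rk(tab$betweenness)
  tab$rank_clo <- rk(tab$closeness)
  td <- topWithTies(tab$degree)
  tb <- topWithTies(tab$betweenness)
  tc <- topWithTies(tab$closeness)
  list(key_nodes = sort(Reduce(intersect, list(td, tb, tc))),
       top_degree = td, top_betweenness = tb, top_closeness = tc,
       rankings = tab)
}
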