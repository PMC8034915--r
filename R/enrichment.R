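#' Read a GMT gene-set collection
#'
#' Parses a standard GMT file (set name, description, member gene ids,
#' tab-separated) into a named list of character vectors via
#' [fgsea::gmtPathways()], validating that set names are unique and every
#' set is nonempty.
#'
#' @param path path to a `.gmt` file.
#' @return named list of character vectors of gene ids.
#' @export
readGMT <- function(path) {
  sets <- fgsea::gmtPathways(path)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  if (any(!lengths(sets))) stop("empty gene set in GMT")
  sets
}

#' Over-representation tail probability
#'
#' Hypergeometric enrichment P value for a query of size `n` overlapping a
#' gene set of size `K` in `k` genes within a universe of `N` genes:
#' `P(X >= k)` with `X ~ Hypergeometric(N, K, n)`. The default reports the
#' over-representation (upper) tail; `alternative = "two.sided"` doubles the
#' smaller of the two tails, capped at 1.
#'
#' @param k,K,n,N integers: overlap, set size, query size, universe size
#'   (vectors are recycled).
#' @param alternative `"over"` (default) or `"two.sided"`.
#' @return numeric vector of P values.
#' @examples
#' oraPValue(3, 5, 5, 20) # 1126/15504
#' @export
oraPValue <- function(k, K, n, N, alternative = c("over", "two.sided")) {
  alternative <- match.arg(alternative)
  args <- cbind(k = k, K = K, n = n, N = N)
  bad <- args[, "k"] > pmin(args[, "K"], args[, "n"]) |
    pmax(args[, "K"], args[, "n"]) > args[, "N"] | args[, "k"] < 0
  if (any(is.na(bad)) || any(bad))
    stop("require 0 <= k <= min(K, n) and K, n <= N")
  upper <- vapply(seq_len(nrow(args)), function(i)
    .hyperUpperTail(args[i, "N"], args[i, "K"], args[i, "n"], args[i, "k"]),
    numeric(1))
  if (alternative == "over") return(upper)
  lower <- stats::phyper(args[, "k"], args[, "K"], args[, "N"] - args[, "K"],
                         args[, "n"])
  pmin(1, 2 * pmin(upper, lower))
}

#' Gene-set over-representation analysis
#'
#' Tests a query gene list against every set of a collection by the
#' hypergeometric upper tail within a fixed gene universe, with
#' Benjamini-Hochberg adjustment across all tested sets. Query (and set)
#' genes outside the universe are dropped; the number of dropped query genes
#' is attached as attribute `n_dropped`. Rows are sorted by ascending raw P.
#'
#' @param query character vector of gene ids.
#' @param collection named list of gene sets (see [readGMT()]).
#' @param universe character vector of background gene ids (for a ceRNA
#'   network analysis, typically all genes of the network).
#' @param alpha numeric(1). Significance threshold (default 0.05).
#' @param use_adjusted logical(1). Flag significance on `p_adj` instead of
#'   the default raw P (the raw-P convention mirrors reporting significance
#'   at p < 0.05 while still listing adjusted values).
#' @param alternative passed to [oraPValue()].
#' @return data.frame with one row per set intersected with the universe:
#'   `term`, `k` (overlap), `K` (set size in universe), `n` (query size in
#'   universe), `N` (universe size), `p_raw`, `p_adj`,
#'   `associated_gene_pct` (`100 * k / K`), `query_gene_pct`
#'   (`100 * k / n`), `genes` (comma-separated overlap), `significant`.
#' @examples
#' sets <- list(A = c("g1", "g2", "g3"), B = c("g4", "g5"))
#' enrichGeneSets(c("g1", "g2"), sets, paste0("g", 1:10))
#' @export
enrichGeneSets <- function(query, collection, universe, alpha = 0.05,
                           use_adjusted = FALSE,
                           alternative = c("over", "two.sided")) {
  alternative <- match.arg(alternative)
  universe <- unique(as.character(universe))
  if (!length(universe)) stop("empty universe")
  if (!length(collection)) stop("empty collection")
  if (is.null(names(collection)) || anyDuplicated(names(collection)))
    stop("collection must have unique set names")
  query0 <- unique(as.character(query))
  query <- intersect(query0, universe)
  n_dropped <- length(query0) - length(query)
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(collection), function(term) {
    set <- intersect(unique(collection[[term]]), universe)
    hit <- intersect(query, set)
    data.frame(term = term, k = length(hit), K = length(set), n = n, N = N,
               genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$K > 0, , drop = FALSE]
  if (!nrow(out)) stop("no set overlaps the universe")
  out$p_raw <- oraPValue(out$k, out$K, out$n, out$N, alternative = alternative)
  out$p_adj <- benjaminiHochberg(out$p_raw)
  out$associated_gene_pct <- ifelse(out$K > 0, 100 * out$k / out$K, NA_real_)
  out$query_gene_pct <- if (n > 0) 100 * out$k / n else NA_real_
  out$significant <- (if (use_adjusted) out$p_adj else out$p_raw) < alpha
  out <- out[order(out$p_raw, out$term),
             c("term", "k", "K", "n", "N", "p_raw", "p_adj",
               "associated_gene_pct", "query_gene_pct", "genes", "significant")]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- n_dropped
  out
}
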