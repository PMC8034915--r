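#' Probe re-annotation filtering
#'
#' Applies the three-rule probe filter used when re-annotating microarray
#' probes against coding and long non-coding transcript alignments:
#' (1) probes matching both a coding and a lncRNA transcript are deleted;
#' (2) probes matching more than one transcript are deleted;
#' (3) transcripts matched by at least `min_probes` surviving probes are
#' retained. The result is independent of the input row order.
#'
#' @param alignments data.frame with columns `probe_id`, `transcript_id`,
#'   `biotype` (`"coding"` or `"lncRNA"`).
#' @param min_probes integer(1). Minimum surviving probes per retained
#'   transcript (default 3).
#' @return data.frame with columns `transcript_id`, `biotype`, `n_probes`,
#'   one row per retained transcript, sorted by id. Empty input gives an
#'   empty result, not an error.
#' @examples
#' aln <- data.frame(
#'   probe_id = c("P1", "P2", "P3", "P4", "P4", "P5", "P5"),
#'   transcript_id = c("T1", "T1", "T1", "T1", "T2", "T3", "T2"),
#'   biotype = c(rep("lncRNA", 5), "coding", "lncRNA")
#' )
#' # P4 hits two transcripts (rule 2), P5 hits both biotypes (rule 1)
#' reannotateProbes(aln) # only T1 keeps three clean probes
#' @export
reannotateProbes <- function(alignments, min_probes = 3) {
  need <- c("probe_id", "transcript_id", "biotype")
  if (!all(need %in% names(alignments)))
    stop("alignments must have columns probe_id, transcript_id, biotype")
  empty <- data.frame(transcript_id = character(), biotype = character(),
                      n_probes = integer())
  if (!nrow(alignments)) return(empty)
  if (!all(alignments$biotype %in% c("coding", "lncRNA")))
    stop("biotype must be 'coding' or 'lncRNA'")
  aln <- unique(alignments[need])
  bt <- split(aln$biotype, aln$probe_id)
  crossBiotype <- names(bt)[vapply(bt, function(b) length(unique(b)) > 1L, logical(1))]
  aln <- aln[!aln$probe_id %in% crossBiotype, , drop = FALSE]
  multi <- names(which(table(aln$probe_id) > 1L))
  aln <- aln[!aln$probe_id %in% multi, , drop = FALSE]
  if (!nrow(aln)) return(empty)
  support <- stats::aggregate(probe_id ~ transcript_id + biotype, data = aln, FUN = length)
  names(support)[3] <- "n_probes"
  support <- support[support$n_probes >= min_probes, , drop = FALSE]
  support <- support[order(support$transcript_id), c("transcript_id", "biotype", "n_probes")]
  rownames(support) <- NULL
  support
}

#' Normalize an expression matrix
#'
#' Simple normalizers for pre-summarized expression matrices (samples in
#' columns): `log2` applies `log2(x + pseudocount)`; `quantile` equalizes the
#' per-sample empirical distributions (each column is replaced by the mean of
#' the sorted columns at its ranks, ties averaged, via
#' [limma::normalizeQuantiles()]); `none` is the identity.
#'
#' @param x numeric matrix, genes in rows, samples in columns.
#' @param method one of `"log2"`, `"quantile"`, `"none"`.
#' @param pseudocount numeric(1) added before the log2 transform (default 0;
#'   with 0, non-positive values are an error).
#' @return the normalized matrix (dimnames preserved).
#' @examples
#' m <- matrix(c(1, 5, 3, 7), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' normalizeMatrix(m, "quantile")
#' @export
normalizeMatrix <- function(x, method = c("log2", "quantile", "none"),
                            pseudocount = 0) {
  method <- match.arg(method)
  x <- as.matrix(x)
  switch(method,
    none = x,
    log2 = {
      if (any(x + pseudocount <= 0))
        stop("non-positive values under log2; supply a pseudocount")
      log2(x + pseudocount)
    },
    quantile = {
      out <- limma::normalizeQuantiles(x, ties = TRUE)
      dimnames(out) <- dimnames(x)
      out
    }
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment
#' `p_adj(i) = min_{j: rank(j) >= rank(i)} m * p(j) / rank(j)`, capped at 1,
#' returned in the input order. A thin validated front-end to
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p numeric vector of P values in `[0, 1]`.
#' @return adjusted P values, same length and order.
#' @examples
#' benjaminiHochberg(c(0.005, 0.011, 0.02, 0.04))
#' @export
benjaminiHochberg <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Two-group differential expression
#'
#' Per-gene two-group comparison on log2-scale data: the log2 fold change is
#' the case-group mean minus the control-group mean, the P value comes from a
#' two-sided t test (Welch by default, pooled-variance optionally), and P
#' values are Benjamini-Hochberg adjusted across all tested genes. A gene is
#' called differentially expressed when `|log2fc| > log2(fc_threshold)` and
#' `p_adj < alpha`. Genes with (near) zero variance in both groups get P = 1
#' when the group means are equal; otherwise their variances are floored at
#' `var_floor` and the gene is flagged in the `var_floored` column.
#'
#' @param x numeric matrix of log2 expression, genes in rows, samples in
#'   columns.
#' @param groups factor or character of length `ncol(x)` with exactly two
#'   levels; the second level (or `case`) is the case group.
#' @param fc_threshold numeric(1). Fold-change call threshold on the natural
#'   scale; the default 2 calls `|log2fc| > 1`. Use 4 for the stricter
#'   `|log2fc| > 2` reading.
#' @param alpha numeric(1). Adjusted-P call threshold (default 0.05).
#' @param case optional character(1) naming the case level.
#' @param statistic `"welch"` (default) or `"pooled"`.
#' @param var_floor numeric(1). Variance floor for degenerate genes
#'   (default 1e-8).
#' @return data.frame with columns `gene_id`, `log2fc`, `p_raw`, `p_adj`,
#'   `is_de`, `var_floored`, in the row order of `x`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(40, 8), 4, 10,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
#' x[1, 6:10] <- x[1, 6:10] + 3
#' differentialExpression(x, rep(c("ctrl", "case"), each = 5), case = "case")
#' @export
differentialExpression <- function(x, groups, fc_threshold = 2, alpha = 0.05,
                                   case = NULL,
                                   statistic = c("welch", "pooled"),
                                   var_floor = 1e-8) {
  statistic <- match.arg(statistic)
  x <- as.matrix(x)
  groups <- as.character(groups)
  if (length(groups) != ncol(x))
    stop("groups must have one label per sample column")
  lev <- unique(groups)
  if (length(lev) != 2L) stop("exactly two group labels are required")
  if (is.null(case)) case <- lev[2L]
  if (!case %in% lev) stop("case level '", case, "' not found in groups")
  ctrl <- setdiff(lev, case)
  ic <- groups == case; i0 <- groups == ctrl
  n1 <- sum(ic); n0 <- sum(i0)
  if (n1 < 2L || n0 < 2L) stop("need at least 2 samples per group")

  m1 <- rowMeans(x[, ic, drop = FALSE]); m0 <- rowMeans(x[, i0, drop = FALSE])
  v1 <- apply(x[, ic, drop = FALSE], 1, stats::var)
  v0 <- apply(x[, i0, drop = FALSE], 1, stats::var)
  log2fc <- m1 - m0

  degenerate <- v1 < var_floor & v0 < var_floor
  flat <- degenerate & abs(log2fc) < .Machine$double.eps^0.5
  floored <- degenerate & !flat
  v1f <- pmax(v1, ifelse(degenerate, var_floor, 0))
  v0f <- pmax(v0, ifelse(degenerate, var_floor, 0))

  if (statistic == "welch") {
    se2 <- v1f / n1 + v0f / n0
    tstat <- log2fc / sqrt(se2)
    df <- se2^2 / ((v1f / n1)^2 / (n1 - 1) + (v0f / n0)^2 / (n0 - 1))
  } else {
    sp2 <- ((n1 - 1) * v1f + (n0 - 1) * v0f) / (n1 + n0 - 2)
    tstat <- log2fc / sqrt(sp2 * (1 / n1 + 1 / n0))
    df <- rep(n1 + n0 - 2, length(tstat))
  }
  p_raw <- 2 * stats::pt(-abs(tstat), df)
  p_raw[flat] <- 1
  p_adj <- benjaminiHochberg(p_raw)

  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  data.frame(
    gene_id = ids,
    log2fc = log2fc,
    p_raw = p_raw,
    p_adj = p_adj,
    is_de = abs(log2fc) > log2(fc_threshold) & p_adj < alpha,
    var_floored = floored,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Hierarchical clustering with correlation distance
#'
#' Unsupervised average-linkage (UPGMA) agglomeration of the rows of a
#' matrix under the Pearson correlation distance `d = 1 - r`. Constant rows
#' make the correlation undefined and are an error.
#'
#' @param x numeric matrix with at least two rows, each with nonzero
#'   variance.
#' @return an object of class [stats::hclust] (merge tree, heights, leaf
#'   order).
#' @seealso [writeClusterNewick()] to export the tree.
#' @examples
#' m <- rbind(a = c(1, 2, 3, 4), b = c(2, 4, 6, 8.2), c = c(4, 3, 2, 1))
#' hc <- hierarchicalCluster(m)
#' hc$height  # a and b (r ~ 1) merge near height 0
#' @export
hierarchicalCluster <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least two rows to cluster")
  v <- apply(x, 1, stats::var)
  if (any(v == 0))
    stop("constant row(s): Pearson correlation undefined for ",
         paste(utils::head(rownames(x)[v == 0], 5L), collapse = ", "))
  d <- stats::as.dist(1 - stats::cor(t(x)))
  stats::hclust(d, method = "average")
}

#' Write a merge tree as Newick
#'
#' Exports a [stats::hclust] tree to a Newick file with branch lengths
#' derived from the merge heights (via [ape::as.phylo()]).
#'
#' @param hc an `hclust` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeClusterNewick <- function(hc, path) {
  ape::write.tree(ape::as.phylo(hc), file = path)
  invisible(path)
}
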