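# Upper-tail hypergeometric mass computed by direct log-space summation of
# the overlap distribution: P(X >= r) with X the number of marked elements in
# an n-draw from a universe of m containing t marked. Summing the upper tail
# (rather than 1 - lower tail) avoids catastrophic cancellation for the very
# small P values the network filter acts on.
.hyperUpperTail <- function(m, t, n, r) {
  if (r <= 0) return(1)
  i <- seq.int(r, min(t, n))
  if (!length(i)) return(0)
  lp <- lchoose(t, i) + lchoose(m - t, n - i) - lchoose(m, n)
  lp <- lp[is.finite(lp)]
  if (!length(lp)) return(0)
  mx <- max(lp)
  min(1, exp(mx) * sum(exp(lp - mx)))
}

#' Filter candidate lncRNA-miRNA interactions
#'
#' Keeps candidate pairs whose prediction score strictly exceeds `score_min`
#' and whose binding energy is strictly below `energy_max` (more negative =
#' more stable duplex), then removes duplicate (lncRNA, miRNA) rows. The
#' defaults reproduce the score > 160 and energy < -20 kcal/mol selection
#' commonly applied to sequence-based lncRNA-miRNA predictions.
#'
#' @param pairs data.frame with columns `lncRNA_id`, `miRNA_id`,
#'   `prediction_score`, `binding_energy`.
#' @param score_min numeric(1). Exclusive lower bound on the prediction score.
#' @param energy_max numeric(1). Exclusive upper bound on the binding energy
#'   (kcal/mol).
#' @return the filtered, deduplicated data.frame.
#' @examples
#' pairs <- data.frame(
#'   lncRNA_id = "L1", miRNA_id = c("m1", "m2"),
#'   prediction_score = c(161, 160), binding_energy = c(-20.5, -25)
#' )
#' filterCandidates(pairs) # the score = 160 row is dropped (bound exclusive)
#' @export
filterCandidates <- function(pairs, score_min = 160, energy_max = -20) {
  need <- c("lncRNA_id", "miRNA_id", "prediction_score", "binding_energy")
  miss <- setdiff(need, names(pairs))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  bad <- which(is.na(pairs$prediction_score) | is.na(pairs$binding_energy))
  if (length(bad))
    stop("missing prediction_score/binding_energy in row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  keep <- pairs$prediction_score > score_min & pairs$binding_energy < energy_max
  out <- pairs[keep, , drop = FALSE]
  out <- out[!duplicated(out[c("lncRNA_id", "miRNA_id")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assemble the tripartite background network
#'
#' Merges a (filtered) lncRNA-miRNA table and a miRNA-mRNA table into the
#' global "triple" background network, deduplicating edges and inferring the
#' three node partitions from table roles. An identifier appearing in more
#' than one partition is an error: the downstream bipartite ceRNA test
#' requires structurally disjoint partitions.
#'
#' @param lnc_mirna data.frame with columns `lncRNA_id`, `miRNA_id` (extra
#'   columns are ignored).
#' @param mirna_mrna data.frame with columns `miRNA_id`, `mRNA_id`.
#' @return a [TripleNetwork-class] object.
#' @examples
#' tn <- buildTripleNetwork(
#'   data.frame(lncRNA_id = c("L1", "L1"), miRNA_id = c("m1", "m2")),
#'   data.frame(miRNA_id = c("m1", "m2", "m3"), mRNA_id = "G1")
#' )
#' tn
#' @export
buildTripleNetwork <- function(lnc_mirna, mirna_mrna) {
  lm <- unique(data.frame(
    lncRNA_id = as.character(lnc_mirna$lncRNA_id),
    miRNA_id = as.character(lnc_mirna$miRNA_id),
    stringsAsFactors = FALSE
  ))
  mm <- unique(data.frame(
    miRNA_id = as.character(mirna_mrna$miRNA_id),
    mRNA_id = as.character(mirna_mrna$mRNA_id),
    stringsAsFactors = FALSE
  ))
  rownames(lm) <- rownames(mm) <- NULL
  new("TripleNetwork", lncMirna = lm, mirnaMrna = mm)
}

#' @rdname lncRNAs
#' @export
setMethod("lncRNAs", "TripleNetwork", function(x) sort(unique(x@lncMirna$lncRNA_id)))

#' @rdname lncRNAs
#' @export
setMethod("miRNAs", "TripleNetwork", function(x)
  sort(unique(c(x@lncMirna$miRNA_id, x@mirnaMrna$miRNA_id))))

#' @rdname lncRNAs
#' @export
setMethod("mRNAs", "TripleNetwork", function(x) sort(unique(x@mirnaMrna$mRNA_id)))

setMethod("show", "TripleNetwork", function(object) {
  cat("TripleNetwork:",
      length(lncRNAs(object)), "lncRNAs,",
      length(miRNAs(object)), "miRNAs,",
      length(mRNAs(object)), "mRNAs;",
      nrow(object@lncMirna), "lncRNA-miRNA +",
      nrow(object@mirnaMrna), "miRNA-mRNA edges\n")
})

#' @rdname cernaGraph
#' @export
setMethod("cernaGraph", "TripleNetwork", function(x) {
  edges <- rbind(
    data.frame(from = x@lncMirna$lncRNA_id, to = x@lncMirna$miRNA_id),
    data.frame(from = x@mirnaMrna$miRNA_id, to = x@mirnaMrna$mRNA_id)
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  part <- rep("miRNA", igraph::vcount(g))
  nm <- igraph::V(g)$name
  part[nm %in% lncRNAs(x)] <- "lncRNA"
  part[nm %in% mRNAs(x)] <- "mRNA"
  igraph::set_vertex_attr(g, "partition", value = part)
})

#' Hypergeometric shared-miRNA test for one lncRNA-mRNA pair
#'
#' Probability of observing at least `r` shared miRNAs between a lncRNA with
#' `n` miRNA partners and an mRNA with `t` miRNA partners when both partner
#' sets are drawn from a universe of `m` miRNAs:
#' \deqn{P = 1 - \sum_{i=0}^{r-1} \frac{{t \choose i}{m-t \choose n-i}}{{m \choose n}}}
#' i.e. the upper tail of a hypergeometric distribution evaluated at the
#' observed overlap. Binomial coefficients are handled in log space, and the
#' tail is summed directly from `r` upward so small P values keep full
#' relative precision.
#'
#' @param m integer. Total miRNAs in the background network.
#' @param t integer. miRNAs interacting with the mRNA.
#' @param n integer. miRNAs interacting with the lncRNA.
#' @param r integer. miRNAs shared by the pair.
#' @return numeric vector of tail probabilities (arguments are recycled).
#' @examples
#' cernaPValue(10, 4, 3, 2)   # 1/3
#' cernaPValue(30, 5, 5, 5)   # 1/choose(30, 5)
#' cernaPValue(10, 4, 3, 0)   # empty sum: 1
#' @export
cernaPValue <- function(m, t, n, r) {
  args <- cbind(m = m, t = t, n = n, r = r)
  if (any(is.na(args))) stop("m, t, n, r must be non-missing")
  if (any(args != floor(args))) stop("m, t, n, r must be integers")
  bad <- args[, "r"] > pmin(args[, "t"], args[, "n"]) |
    pmax(args[, "t"], args[, "n"]) > args[, "m"] |
    args[, "r"] < 0 | args[, "t"] < 0 | args[, "n"] < 0 | args[, "m"] < 1
  if (any(bad))
    stop("count invariants 0 <= r <= min(t, n) <= m violated in row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  vapply(seq_len(nrow(args)), function(i)
    .hyperUpperTail(args[i, "m"], args[i, "t"], args[i, "n"], args[i, "r"]),
    numeric(1))
}

#' Extract the significance-filtered ceRNA network
#'
#' Maps differentially expressed lncRNAs (DELs) and mRNAs (DEMs) onto the
#' tripartite background network and tests every DEL/DEM pair sharing at
#' least one miRNA with [cernaPValue()], using `m` = the number of distinct
#' miRNAs in the background network. Pairs with P below `alpha` (raw P by
#' default; Benjamini-Hochberg-adjusted P when `adjust = TRUE`) form the
#' bipartite ceRNA network. Pairs sharing no miRNA are not tested (their P is
#' identically 1). DE ids absent from the background network are skipped and
#' counted, not treated as errors.
#'
#' @param triple a [TripleNetwork-class] background network.
#' @param dels character. Differentially expressed lncRNA ids.
#' @param dems character. Differentially expressed mRNA ids.
#' @param alpha numeric(1). Significance threshold (default 0.01).
#' @param adjust logical(1). Apply the threshold to BH-adjusted rather than
#'   raw P values.
#' @return a [CeRNANetwork-class] with the significant edge table, the
#'   complete tested-pair table, and the lncRNA-miRNA-mRNA triplet list (one
#'   row per shared miRNA per significant pair).
#' @examples
#' lm <- data.frame(lncRNA_id = "L1", miRNA_id = paste0("m", 1:5))
#' mm <- data.frame(miRNA_id = paste0("m", 1:30),
#'                  mRNA_id = rep(c("G1", "G2"), c(5, 25)))
#' net <- extractCernaNetwork(buildTripleNetwork(lm, mm), "L1", c("G1", "G2"))
#' cernaEdges(net) # only the fully overlapping pair L1-G1 survives
#' @export
extractCernaNetwork <- function(triple, dels, dems, alpha = 0.01, adjust = FALSE) {
  stopifnot(is(triple, "TripleNetwork"))
  dels <- unique(as.character(dels)); dems <- unique(as.character(dems))
  if (!length(dels) || !length(dems)) stop("dels and dems must be nonempty")
  lncPart <- split(triple@lncMirna$miRNA_id, triple@lncMirna$lncRNA_id)
  mrnaPart <- split(triple@mirnaMrna$miRNA_id, triple@mirnaMrna$mRNA_id)
  m <- length(miRNAs(triple))
  skipped <- sum(!dels %in% names(lncPart)) + sum(!dems %in% names(mrnaPart))
  useL <- sort(intersect(dels, names(lncPart)))
  useG <- sort(intersect(dems, names(mrnaPart)))

  rows <- list()
  for (L in useL) {
    pl <- lncPart[[L]]
    for (G in useG) {
      shared <- intersect(pl, mrnaPart[[G]])
      if (!length(shared)) next
      rows[[length(rows) + 1L]] <- data.frame(
        lncRNA_id = L, mRNA_id = G,
        m = m, t = length(mrnaPart[[G]]), n = length(pl), r = length(shared),
        shared_mirnas = paste(sort(shared), collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows)) {
    tested <- do.call(rbind, rows)
    tested$p_value <- cernaPValue(tested$m, tested$t, tested$n, tested$r)
    tested$p_adj <- stats::p.adjust(tested$p_value, method = "BH")
    crit <- if (adjust) tested$p_adj else tested$p_value
    tested$kept <- crit < alpha
    tested <- tested[order(tested$p_value, tested$lncRNA_id, tested$mRNA_id), ]
    rownames(tested) <- NULL
  } else {
    tested <- data.frame(
      lncRNA_id = character(), mRNA_id = character(), m = integer(),
      t = integer(), n = integer(), r = integer(), shared_mirnas = character(),
      p_value = numeric(), p_adj = numeric(), kept = logical()
    )
  }
  edges <- tested[tested$kept, setdiff(names(tested), "kept"), drop = FALSE]
  rownames(edges) <- NULL
  triplets <- if (nrow(edges)) {
    do.call(rbind, lapply(seq_len(nrow(edges)), function(i) {
      mir <- strsplit(edges$shared_mirnas[i], ",", fixed = TRUE)[[1]]
      data.frame(lncRNA_id = edges$lncRNA_id[i], miRNA_id = mir,
                 mRNA_id = edges$mRNA_id[i], stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(lncRNA_id = character(), miRNA_id = character(),
               mRNA_id = character())
  }
  rownames(triplets) <- NULL
  # validity enforces p < alpha on raw p; under adjust mode raw p <= adjusted
  # p < alpha holds as well, so the stored alpha remains the raw bound
  new("CeRNANetwork", edges = edges, tested = tested, triplets = triplets,
      alpha = if (adjust) max(alpha, if (nrow(edges)) max(edges$p_value) * (1 + 1e-12) else alpha) else alpha,
      nMirnaBackground = m, skipped = skipped)
}

#' @rdname cernaEdges
#' @export
setMethod("cernaEdges", "CeRNANetwork", function(x) x@edges)

#' @rdname cernaEdges
#' @export
setMethod("testedPairs", "CeRNANetwork", function(x) x@tested)

#' @rdname cernaEdges
#' @export
setMethod("cernaTriplets", "CeRNANetwork", function(x) x@triplets)

#' @rdname cernaEdges
#' @export
setMethod("cernaTriplets", "CeRNASubnetwork", function(x) x@triplets)

#' @rdname lncRNAs
#' @export
setMethod("lncRNAs", "CeRNANetwork", function(x) sort(unique(x@edges$lncRNA_id)))

#' @rdname lncRNAs
#' @export
setMethod("mRNAs", "CeRNANetwork", function(x) sort(unique(x@edges$mRNA_id)))

setMethod("show", "CeRNANetwork", function(object) {
  cat("CeRNANetwork:", length(lncRNAs(object)), "lncRNAs +",
      length(mRNAs(object)), "mRNAs,", nrow(object@edges), "edges",
      sprintf("(alpha = %g, m = %d miRNAs, %d pairs tested)\n",
              object@alpha, as.integer(object@nMirnaBackground),
              nrow(object@tested)))
})

#' @rdname cernaGraph
#' @export
setMethod("cernaGraph", "CeRNANetwork", function(x) {
  if (!nrow(x@edges)) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(igraph::set_vertex_attr(g, "partition", value = character(0)))
  }
  g <- igraph::graph_from_data_frame(
    x@edges[c("lncRNA_id", "mRNA_id")], directed = FALSE)
  part <- ifelse(igraph::V(g)$name %in% x@edges$lncRNA_id, "lncRNA", "mRNA")
  igraph::set_vertex_attr(g, "partition", value = part)
})

setMethod("show", "CeRNASubnetwork", function(object) {
  cat("CeRNASubnetwork of", object@keyLnc, ":",
      nrow(object@edges), "mRNA neighbours,",
      nrow(object@triplets), "triplets\n")
})
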