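#' @import methods
NULL

#' Simulation configuration for synthetic ceRNA studies
#'
#' An S4 container holding every tunable of the synthetic-data generator:
#' the size of the miRNA universe, gene counts, interaction density, the
#' planted ceRNA structure (ordinary planted pairs and hub lncRNAs), and the
#' two-group expression design (samples per group, differential-expression
#' fraction, effect size and noise level on the log2 scale).
#'
#' @slot seed integer(1). Master seed; all sub-streams are derived from it.
#' @slot n_mirna integer(1). Number of miRNAs in the universe.
#' @slot n_lnc integer(1). Number of lncRNA genes.
#' @slot n_mrna integer(1). Number of mRNA genes.
#' @slot targets_per_gene numeric(1). Mean miRNA partners per gene; partner
#'   counts are Poisson with this mean, truncated at `n_mirna`.
#' @slot n_planted_pairs integer(1). Number of ordinary planted ceRNA
#'   lncRNA-mRNA pairs (each pair shares a common miRNA subset).
#' @slot planted_overlap integer(1). Minimum shared-miRNA count for planted
#'   pairs (and for hub lncRNA/mRNA pairs).
#' @slot n_hub_lnc integer(1). Number of planted hub lncRNAs; each hub is
#'   given `hub_n_mrna` planted mRNA partners sharing one common miRNA set,
#'   so hubs dominate degree, betweenness and closeness in the inferred
#'   network.
#' @slot hub_n_mrna integer(1). mRNA partners per hub lncRNA.
#' @slot n_samples_per_group integer(1). Samples per condition (the emulated
#'   study design profiled seven cases and seven controls).
#' @slot de_fraction numeric(1). Fraction of genes planted as differentially
#'   expressed in addition to the genes already involved in planted ceRNA
#'   structure (which are always differentially expressed so the planted
#'   network is recoverable downstream).
#' @slot log2fc_effect numeric(1). Planted effect size in log2 units.
#' @slot noise_sd numeric(1). Within-group standard deviation (log2 units).
#' @slot score_pass_frac numeric(1). Fraction of background lncRNA-miRNA rows
#'   drawn with prediction score above 160 (the candidate-filter threshold);
#'   planted rows always pass.
#' @slot energy_pass_frac numeric(1). Fraction of background lncRNA-miRNA rows
#'   drawn with binding energy below -20 kcal/mol; planted rows always pass.
#'
#' @seealso [simulationConfig()] for the user-facing constructor with
#'   validated defaults, [generateInteractions()], [generateExpression()].
#' @export
setClass("SimulationConfig",
  representation(
    seed = "integer",
    n_mirna = "integer",
    n_lnc = "integer",
    n_mrna = "integer",
    targets_per_gene = "numeric",
    n_planted_pairs = "integer",
    planted_overlap = "integer",
    n_hub_lnc = "integer",
    hub_n_mrna = "integer",
    n_samples_per_group = "integer",
    de_fraction = "numeric",
    log2fc_effect = "numeric",
    noise_sd = "numeric",
    score_pass_frac = "numeric",
    energy_pass_frac = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && !is.na(x)
  for (s in slotNames(object)) {
    if (!one(slot(object, s))) msg <- c(msg, sprintf("'%s' must be a single non-NA value", s))
  }
  if (length(msg)) return(msg)
  if (object@n_mirna < 1L) msg <- c(msg, "n_mirna must be >= 1")
  if (object@n_lnc < 1L) msg <- c(msg, "n_lnc must be >= 1")
  if (object@n_mrna < 1L) msg <- c(msg, "n_mrna must be >= 1")
  if (object@targets_per_gene < 0) msg <- c(msg, "targets_per_gene must be >= 0")
  if (object@n_planted_pairs < 0L) msg <- c(msg, "n_planted_pairs must be >= 0")
  if (object@planted_overlap < 1L) msg <- c(msg, "planted_overlap must be >= 1")
  if (object@planted_overlap > object@n_mirna)
    msg <- c(msg, "planted_overlap cannot exceed n_mirna")
  if (object@n_hub_lnc < 0L) msg <- c(msg, "n_hub_lnc must be >= 0")
  if (object@n_hub_lnc > 0L && object@hub_n_mrna < 1L)
    msg <- c(msg, "hub_n_mrna must be >= 1 when hubs are planted")
  if (object@n_samples_per_group < 1L) msg <- c(msg, "n_samples_per_group must be >= 1")
  if (object@de_fraction < 0 || object@de_fraction > 1)
    msg <- c(msg, "de_fraction must be in [0, 1]")
  if (object@noise_sd < 0) msg <- c(msg, "noise_sd must be >= 0")
  if (object@score_pass_frac < 0 || object@score_pass_frac > 1)
    msg <- c(msg, "score_pass_frac must be in [0, 1]")
  if (object@energy_pass_frac < 0 || object@energy_pass_frac > 1)
    msg <- c(msg, "energy_pass_frac must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Tripartite lncRNA-miRNA-mRNA background network
#'
#' The merged "triple" network used as the universe for the shared-miRNA
#' hypergeometric test: deduplicated lncRNA-miRNA and miRNA-mRNA edge tables
#' with disjoint node partitions. Every edge connects a miRNA to a non-miRNA
#' node; an identifier occurring in more than one partition is rejected by
#' the validity method because the downstream bipartite test requires the
#' partitions to be structural.
#'
#' @slot lncMirna data.frame with columns `lncRNA_id`, `miRNA_id`.
#' @slot mirnaMrna data.frame with columns `miRNA_id`, `mRNA_id`.
#'
#' @seealso [buildTripleNetwork()], [extractCernaNetwork()], [lncRNAs()],
#'   [miRNAs()], [mRNAs()]
#' @export
setClass("TripleNetwork",
  representation(lncMirna = "data.frame", mirnaMrna = "data.frame")
)

setValidity("TripleNetwork", function(object) {
  msg <- character()
  if (!all(c("lncRNA_id", "miRNA_id") %in% names(object@lncMirna)))
    msg <- c(msg, "lncMirna must have columns lncRNA_id, miRNA_id")
  if (!all(c("miRNA_id", "mRNA_id") %in% names(object@mirnaMrna)))
    msg <- c(msg, "mirnaMrna must have columns miRNA_id, mRNA_id")
  if (length(msg)) return(msg)
  if (anyDuplicated(object@lncMirna[c("lncRNA_id", "miRNA_id")]))
    msg <- c(msg, "duplicate lncRNA-miRNA edges")
  if (anyDuplicated(object@mirnaMrna[c("miRNA_id", "mRNA_id")]))
    msg <- c(msg, "duplicate miRNA-mRNA edges")
  lnc <- unique(object@lncMirna$lncRNA_id)
  mir <- unique(c(object@lncMirna$miRNA_id, object@mirnaMrna$miRNA_id))
  mrna <- unique(object@mirnaMrna$mRNA_id)
  clash <- c(intersect(lnc, mir), intersect(lnc, mrna), intersect(mir, mrna))
  if (length(clash))
    msg <- c(msg, paste0("identifiers present in more than one partition: ",
                         paste(utils::head(unique(clash), 5L), collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Significance-filtered bipartite ceRNA network
#'
#' The lncRNA-mRNA network obtained by testing every differentially expressed
#' lncRNA/mRNA pair of the background [TripleNetwork-class] for shared-miRNA
#' over-representation and keeping pairs below the significance threshold.
#' Carries the complete tested-pair table (for audit and calibration checks)
#' and the lncRNA-miRNA-mRNA triplet list (one row per shared miRNA per
#' significant pair).
#'
#' @slot edges data.frame of significant pairs with columns `lncRNA_id`,
#'   `mRNA_id`, `m`, `t`, `n`, `r`, `p_value`, `p_adj`, `shared_mirnas`
#'   (comma-separated miRNA ids).
#' @slot tested data.frame of all tested pairs (same statistic columns plus
#'   logical `kept`).
#' @slot triplets data.frame with columns `lncRNA_id`, `miRNA_id`, `mRNA_id`.
#' @slot alpha numeric(1). Significance threshold used for extraction.
#' @slot nMirnaBackground numeric(1). `m`, the number of distinct miRNAs in
#'   the background network.
#' @slot skipped numeric(1). Count of supplied DE gene ids absent from the
#'   background network (skipped, not an error).
#'
#' @seealso [extractCernaNetwork()], [cernaEdges()], [testedPairs()],
#'   [cernaTriplets()], [cernaGraph()], [computeCentralities()]
#' @export
setClass("CeRNANetwork",
  representation(
    edges = "data.frame",
    tested = "data.frame",
    triplets = "data.frame",
    alpha = "numeric",
    nMirnaBackground = "numeric",
    skipped = "numeric"
  )
)

setValidity("CeRNANetwork", function(object) {
  msg <- character()
  need <- c("lncRNA_id", "mRNA_id", "m", "t", "n", "r", "p_value")
  if (!all(need %in% names(object@edges)))
    msg <- c(msg, "edges must carry lncRNA_id, mRNA_id, m, t, n, r, p_value")
  if (length(msg)) return(msg)
  e <- object@edges
  if (nrow(e)) {
    if (any(e$p_value >= object@alpha))
      msg <- c(msg, "edge with p_value >= alpha")
    if (any(e$r > pmin(e$t, e$n)) || any(pmax(e$t, e$n) > e$m) || any(e$r < 0))
      msg <- c(msg, "count invariant 0 <= r <= min(t, n) <= m violated")
    if (length(intersect(e$lncRNA_id, e$mRNA_id)))
      msg <- c(msg, "network is not bipartite: id used as both lncRNA and mRNA")
  }
  if (length(msg)) msg else TRUE
})

#' Per-lncRNA ceRNA sub-network
#'
#' The induced star of one key lncRNA in a [CeRNANetwork-class]: its nearest
#' mRNA neighbours, the edge annotations carried over from the parent
#' network, and the lncRNA-miRNA-mRNA triplets restricted to the key lncRNA
#' (the miRNA layer of the sub-network).
#'
#' @slot keyLnc character(1). The key lncRNA id.
#' @slot edges data.frame. Parent-network edge rows incident to `keyLnc`.
#' @slot triplets data.frame. Triplet rows (`lncRNA_id`, `miRNA_id`,
#'   `mRNA_id`) with `lncRNA_id == keyLnc`.
#'
#' @seealso [extractSubnetwork()]
#' @export
setClass("CeRNASubnetwork",
  representation(keyLnc = "character", edges = "data.frame", triplets = "data.frame")
)

setValidity("CeRNASubnetwork", function(object) {
  msg <- character()
  if (length(object@keyLnc) != 1L) msg <- c(msg, "keyLnc must be a single id")
  if (nrow(object@edges) && !all(object@edges$lncRNA_id == object@keyLnc))
    msg <- c(msg, "all edges must be incident to the key lncRNA")
  if (nrow(object@triplets) && !all(object@triplets$lncRNA_id == object@keyLnc))
    msg <- c(msg, "all triplets must involve the key lncRNA")
  if (length(msg)) msg else TRUE
})
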