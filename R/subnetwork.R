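#' Extract the ceRNA sub-network of one key lncRNA
#'
#' Builds the induced star of a key lncRNA in a significance-filtered ceRNA
#' network: its nearest mRNA neighbours with the edge annotations from the
#' shared-miRNA test, plus the miRNA layer reconstructed from the triplet
#' table (one lncRNA-miRNA-mRNA row per shared miRNA). A key lncRNA without
#' significant edges yields an empty star, not an error; a lncRNA absent
#' from the parent network is an error.
#'
#' @param network a [CeRNANetwork-class].
#' @param key_lnc character(1). The key lncRNA id.
#' @param triplets optional triplet data.frame; defaults to
#'   `cernaTriplets(network)`.
#' @return a [CeRNASubnetwork-class].
#' @export
extractSubnetwork <- function(network, key_lnc, triplets = NULL) {
  stopifnot(is(network, "CeRNANetwork"))
  key_lnc <- as.character(key_lnc)
  tested <- testedPairs(network)
  known <- unique(c(tested$lncRNA_id, network@edges$lncRNA_id))
  if (!key_lnc %in% known)
    stop("lncRNA '", key_lnc, "' is not present in the network")
  if (is.null(triplets)) triplets <- cernaTriplets(network)
  edges <- network@edges[network@edges$lncRNA_id == key_lnc, , drop = FALSE]
  rownames(edges) <- NULL
  tri <- triplets[triplets$lncRNA_id == key_lnc, , drop = FALSE]
  rownames(tri) <- NULL
  new("CeRNASubnetwork", keyLnc = key_lnc, edges = edges, triplets = tri)
}

#' @describeIn extractSubnetwork mRNA neighbour ids of the key lncRNA.
#' @param x a [CeRNASubnetwork-class].
#' @export
subnetworkNeighbors <- function(x) {
  stopifnot(is(x, "CeRNASubnetwork"))
  sort(unique(x@edges$mRNA_id))
}

#' Intersect named regulator (or any gene-id) lists
#'
#' Computes the common set across two or more named gene-id lists together
#' with all single, pairwise and full intersection sizes — the counts needed
#' to draw a Venn diagram, e.g. of predicted transcription factors targeting
#' several key lncRNAs. Commutative and associative in its list arguments.
#'
#' @param lists named list (length >= 2) of character vectors.
#' @return list with `common` (sorted character vector of ids present in
#'   every list), `sizes` (per-list unique sizes), `pairwise` (data.frame
#'   `set_a`, `set_b`, `n_common`), and `n_common`.
#' @examples
#' intersectRegulators(list(a = c("TF1", "TF2"), b = c("TF2", "TF3")))
#' @export
intersectRegulators <- function(lists) {
  if (!is.list(lists) || length(lists) < 2L)
    stop("need at least two lists to intersect")
  if (is.null(names(lists)) || any(!nzchar(names(lists))))
    stop("lists must be named")
  lists <- lapply(lists, function(v) unique(as.character(v)))
  common <- sort(Reduce(intersect, lists))
  nm <- names(lists)
  pairs <- utils::combn(nm, 2)
  pairwise <- data.frame(
    set_a = pairs[1, ], set_b = pairs[2, ],
    n_common = apply(pairs, 2, function(p)
      length(intersect(lists[[p[1]]], lists[[p[2]]]))),
    stringsAsFactors = FALSE
  )
  list(common = common,
       sizes = lengths(lists),
       pairwise = pairwise,
       n_common = length(common))
}
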