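#' Node partitions of a network object
#'
#' Accessors for the three node partitions of a tripartite background network
#' or a bipartite ceRNA network.
#'
#' @param x a [TripleNetwork-class] or [CeRNANetwork-class] object.
#' @return character vector of node identifiers (sorted, unique).
#' @examples
#' tn <- buildTripleNetwork(
#'   data.frame(lncRNA_id = "L1", miRNA_id = c("m1", "m2")),
#'   data.frame(miRNA_id = c("m1", "m2"), mRNA_id = "G1")
#' )
#' lncRNAs(tn)
#' miRNAs(tn)
#' mRNAs(tn)
#' @export
setGeneric("lncRNAs", function(x) standardGeneric("lncRNAs"))

#' @rdname lncRNAs
#' @export
setGeneric("miRNAs", function(x) standardGeneric("miRNAs"))

#' @rdname lncRNAs
#' @export
setGeneric("mRNAs", function(x) standardGeneric("mRNAs"))

#' Edge and annotation tables of a ceRNA network
#'
#' `cernaEdges()` returns the significant lncRNA-mRNA pairs with their
#' shared-miRNA test statistics; `testedPairs()` the complete tested-pair
#' table (including non-significant pairs); `cernaTriplets()` the
#' lncRNA-miRNA-mRNA triplet list, one row per shared miRNA per significant
#' pair.
#'
#' @param x a [CeRNANetwork-class] object (for `cernaTriplets()` also a
#'   [CeRNASubnetwork-class]).
#' @return a data.frame.
#' @export
setGeneric("cernaEdges", function(x) standardGeneric("cernaEdges"))

#' @rdname cernaEdges
#' @export
setGeneric("testedPairs", function(x) standardGeneric("testedPairs"))

#' @rdname cernaEdges
#' @export
setGeneric("cernaTriplets", function(x) standardGeneric("cernaTriplets"))

#' Convert a network object to an igraph graph
#'
#' Builds the undirected simple graph of a network container: for a
#' [CeRNANetwork-class] the bipartite lncRNA-mRNA graph (vertex attribute
#' `partition` is `"lncRNA"` or `"mRNA"`), for a [TripleNetwork-class] the
#' tripartite graph with partitions `"lncRNA"`, `"miRNA"`, `"mRNA"`.
#'
#' @param x a network object.
#' @return an [igraph::igraph] object.
#' @export
setGeneric("cernaGraph", function(x) standardGeneric("cernaGraph"))
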