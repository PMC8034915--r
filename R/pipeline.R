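.pipelineDefaults <- function() {
  list(
    lnc_mirna = NULL, mirna_mrna = NULL, expression = NULL, groups = NULL,
    gmt = NULL,
    fc_threshold = 2, de_alpha = 0.05, case = "case",
    score_min = 160, energy_max = -20,
    cerna_alpha = 0.01, top_k = 10, partition = "lncRNA",
    mcode_node_score_cutoff = 0.2, mcode_haircut = TRUE, mcode_fluff = TRUE,
    mcode_fluff_density_cutoff = 0.2,
    enrich_alpha = 0.05,
    seed = 1
  )
}

#' Build a pipeline configuration
#'
#' Merges user settings over the pipeline defaults, which reproduce the
#' thresholds of the published ceRNA workflow: fold change > 2 with adjusted
#' P < 0.05 for differential expression, prediction score > 160 and binding
#' energy < -20 for candidate lncRNA-miRNA pairs, raw hypergeometric
#' P < 0.01 for network extraction, top-10 centrality lists, MCODE node
#' score cutoff 0.2 with haircut and fluff, and enrichment alpha 0.05.
#' Unknown keys are rejected.
#'
#' @param ... named settings overriding the defaults; alternatively a single
#'   named list (e.g. parsed from YAML).
#' @return a named list of settings (class `ceRNAPipelineConfig`).
#' @export
pipelineConfig <- function(...) {
  user <- list(...)
  # allow pipelineConfig(list(...)), e.g. a parsed YAML document
  if (length(user) == 1L && is.list(user[[1]]) && !is.data.frame(user[[1]]) &&
      (is.null(names(user)) || !nzchar(names(user)[1])))
    user <- user[[1]]
  cfg <- .pipelineDefaults()
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  cfg[names(user)] <- user
  structure(cfg, class = "ceRNAPipelineConfig")
}

.readTableMaybe <- function(x) {
  if (is.character(x) && length(x) == 1L)
    return(utils::read.delim(x, stringsAsFactors = FALSE, check.names = FALSE))
  x
}

# Accepts either the split lncRNA_id/miRNA_id layout or the combined
# source_id/target_id/interaction_type layout written by simulateCeRNAStudy().
.normalizeInteractions <- function(lnc_mirna, mirna_mrna) {
  if (!is.null(lnc_mirna) && "source_id" %in% names(lnc_mirna) &&
      "interaction_type" %in% names(lnc_mirna)) {
    tab <- lnc_mirna
    lm <- tab[tab$interaction_type == "lncRNA-miRNA", , drop = FALSE]
    mm <- tab[tab$interaction_type == "miRNA-mRNA", , drop = FALSE]
    lnc_mirna <- data.frame(lncRNA_id = lm$source_id, miRNA_id = lm$target_id,
                            prediction_score = lm$prediction_score,
                            binding_energy = lm$binding_energy,
                            stringsAsFactors = FALSE)
    if (is.null(mirna_mrna))
      mirna_mrna <- data.frame(miRNA_id = mm$source_id, mRNA_id = mm$target_id,
                               stringsAsFactors = FALSE)
  }
  list(lnc_mirna = lnc_mirna, mirna_mrna = mirna_mrna)
}

#' Run the full ceRNA network-inference workflow
#'
#' Orchestrates every stage end-to-end: two-group differential expression,
#' candidate lncRNA-miRNA filtering, background triple-network assembly,
#' hypergeometric extraction of the bipartite ceRNA network, hierarchical
#' clustering of the network genes, centrality computation with power-law
#' degree-distribution fit and key-lncRNA selection, MCODE functional-module
#' detection, optional gene-set enrichment of the network mRNAs, and
#' per-key-lncRNA sub-network extraction. With a fixed seed the run report
#' is identical across runs.
#'
#' @param config a list from [pipelineConfig()], a plain named list, or the
#'   path to a flat YAML file of settings. Input tables (`lnc_mirna`,
#'   `mirna_mrna`, `expression`, `groups`) may be data.frames/matrices or
#'   file paths to the TSV formats written by [simulateCeRNAStudy()].
#' @param outdir optional directory; when given, every stage's outputs
#'   (DE table, tested pairs, edge list, GraphML, centralities, key nodes,
#'   modules, sub-network tables, Newick tree, `report.json`) are written
#'   there.
#' @return list with `report` (all counts and key results), `de`,
#'   `triple`, `network`, `centralities`, `power_law`, `key_nodes`,
#'   `modules`, `enrichment` (NULL without a GMT), `subnetworks`, `hclust`.
#' @seealso [runSyntheticDemo()] for a one-call synthetic demonstration.
#' @export
runPipeline <- function(config, outdir = NULL) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!inherits(config, "ceRNAPipelineConfig"))
    config <- pipelineConfig(config)
  set.seed(config$seed)

  fail <- function(stage, e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE)
  tryStage <- function(stage, expr)
    tryCatch(expr, error = function(e) fail(stage, e))

  inp <- tryStage("input", {
    raw <- .normalizeInteractions(.readTableMaybe(config$lnc_mirna),
                                  .readTableMaybe(config$mirna_mrna))
    expr <- .readTableMaybe(config$expression)
    if (is.data.frame(expr) && "gene_id" %in% names(expr)) {
      m <- as.matrix(expr[setdiff(names(expr), "gene_id")])
      rownames(m) <- expr$gene_id
      expr <- m
    }
    groups <- .readTableMaybe(config$groups)
    if (is.data.frame(groups)) groups <- stats::setNames(groups$group, groups$sample_id)
    list(lnc_mirna = raw$lnc_mirna, mirna_mrna = raw$mirna_mrna,
         expression = as.matrix(expr), groups = groups)
  })
  groups <- inp$groups
  if (!is.null(names(groups)) && !is.null(colnames(inp$expression)))
    groups <- groups[colnames(inp$expression)]

  de <- tryStage("differential_expression",
    differentialExpression(inp$expression, groups,
                           fc_threshold = config$fc_threshold,
                           alpha = config$de_alpha, case = config$case))

  filtered <- tryStage("filter_candidates",
    filterCandidates(inp$lnc_mirna, score_min = config$score_min,
                     energy_max = config$energy_max))

  triple <- tryStage("triple_network",
    buildTripleNetwork(filtered, inp$mirna_mrna))

  deGenes <- de$gene_id[de$is_de]
  dels <- intersect(deGenes, unique(inp$lnc_mirna$lncRNA_id))
  dems <- intersect(deGenes, unique(inp$mirna_mrna$mRNA_id))
  network <- tryStage("cerna_extraction",
    extractCernaNetwork(triple, dels = dels, dems = dems,
                        alpha = config$cerna_alpha))

  netGenes <- sort(unique(c(lncRNAs(network), mRNAs(network))))
  hc <- NULL
  if (length(netGenes) >= 2L) {
    sub <- inp$expression[intersect(netGenes, rownames(inp$expression)), , drop = FALSE]
    v <- apply(sub, 1, stats::var)
    sub <- sub[v > 0, , drop = FALSE]
    if (nrow(sub) >= 2L)
      hc <- tryStage("hierarchical_clustering", hierarchicalCluster(sub))
  }

  centr <- NULL; plaw <- NULL; keys <- list(key_nodes = character(0))
  modules <- structure(list(), class = "MCODEModuleList")
  if (nrow(cernaEdges(network))) {
    centr <- tryStage("centralities", computeCentralities(network))
    plaw <- tryStage("power_law_fit", {
      if (length(unique(centr$degree[centr$degree >= 1])) >= 2L)
        fitPowerLaw(centr$degree) else NULL
    })
    keys <- tryStage("key_node_selection",
      selectKeyNodes(centr, k = config$top_k, partition = config$partition))
    modules <- tryStage("mcode",
      mcodeFindModules(network,
                       node_score_cutoff = config$mcode_node_score_cutoff,
                       haircut = config$mcode_haircut,
                       fluff = config$mcode_fluff,
                       fluff_density_cutoff = config$mcode_fluff_density_cutoff))
  }

  enr <- NULL
  if (!is.null(config$gmt) && length(mRNAs(network))) {
    collection <- if (is.character(config$gmt)) readGMT(config$gmt) else config$gmt
    enr <- tryStage("enrichment",
      enrichGeneSets(mRNAs(network), collection, universe = netGenes,
                     alpha = config$enrich_alpha))
  }

  subnets <- tryStage("subnetworks",
    stats::setNames(lapply(keys$key_nodes, function(L)
      extractSubnetwork(network, L)), keys$key_nodes))

  centrDeg <- if (!is.null(centr)) centr$degree else integer(0)
  report <- list(
    seed = config$seed,
    n_genes_tested = nrow(de),
    n_de = sum(de$is_de),
    n_del = length(dels),
    n_dem = length(dems),
    n_candidate_lnc_mirna = nrow(inp$lnc_mirna),
    n_filtered_lnc_mirna = nrow(filtered),
    n_background_edges = nrow(triple@lncMirna) + nrow(triple@mirnaMrna),
    n_background_mirnas = network@nMirnaBackground,
    n_skipped_de_ids = network@skipped,
    n_tested_pairs = nrow(testedPairs(network)),
    n_network_edges = nrow(cernaEdges(network)),
    n_lnc_nodes = length(lncRNAs(network)),
    n_mrna_nodes = length(mRNAs(network)),
    n_triplets = nrow(cernaTriplets(network)),
    sum_degree = sum(centrDeg),
    power_law_slope = if (!is.null(plaw)) plaw$slope else NA_real_,
    power_law_r_squared = if (!is.null(plaw)) plaw$r_squared else NA_real_,
    key_nodes = keys$key_nodes,
    n_modules = length(modules),
    modules = mcodeTable(modules),
    n_enriched = if (!is.null(enr)) sum(enr$significant) else NA_integer_
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    w <- function(d, f) utils::write.table(d, file.path(outdir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
    w(de, "de_results.tsv")
    w(testedPairs(network), "tested_pairs.tsv")
    w(cernaEdges(network), "network_edges.tsv")
    w(cernaTriplets(network), "triplets.tsv")
    if (nrow(cernaEdges(network)))
      igraph::write_graph(cernaGraph(network),
                          file.path(outdir, "network.graphml"),
                          format = "graphml")
    if (!is.null(centr)) {
      w(centr, "centralities.tsv")
      w(keys$rankings, "centrality_rankings.tsv")
    }
    if (length(keys$key_nodes))
      writeLines(keys$key_nodes, file.path(outdir, "key_lncRNAs.txt"))
    w(mcodeTable(modules), "mcode_modules.tsv")
    if (!is.null(enr)) w(enr, "enrichment.tsv")
    if (!is.null(hc)) writeClusterNewick(hc, file.path(outdir, "clustering.nwk"))
    for (L in names(subnets)) {
      w(subnets[[L]]@edges, paste0("subnetwork_", L, "_edges.tsv"))
      w(subnets[[L]]@triplets, paste0("subnetwork_", L, "_triplets.tsv"))
    }
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         dataframe = "columns", auto_unbox = TRUE, digits = NA)
  }

  list(report = report, de = de, triple = triple, network = network,
       centralities = centr, power_law = plaw, key_nodes = keys,
       modules = modules, enrichment = enr, subnetworks = subnets,
       hclust = hc)
}

#' One-command synthetic demonstration run
#'
#' Simulates a complete synthetic ceRNA study ([simulateCeRNAStudy()]) and
#' runs the full pipeline on it with the default thresholds, returning both
#' the simulation (with its ground truth) and the pipeline result, so
#' planted-structure recovery can be checked directly.
#'
#' @param seed integer master seed.
#' @param outdir optional output directory for all stage outputs.
#' @param config optional [SimulationConfig-class] (its seed wins over
#'   `seed`).
#' @param ... further settings passed to [pipelineConfig()].
#' @return list with `sim` (the synthetic study) and `result` (the pipeline
#'   output; see [runPipeline()]).
#' @examples
#' demo <- runSyntheticDemo(seed = 1,
#'   config = simulationConfig(seed = 1, n_mirna = 60, n_lnc = 12,
#'                             n_mrna = 15, n_planted_pairs = 2,
#'                             planted_overlap = 6, n_hub_lnc = 1,
#'                             hub_n_mrna = 4))
#' demo$result$report$n_network_edges
#' @export
runSyntheticDemo <- function(seed = 1, outdir = NULL, config = NULL, ...) {
  if (is.null(config)) config <- simulationConfig(seed = seed)
  sim <- simulateCeRNAStudy(config, outdir = if (is.null(outdir)) NULL else
    file.path(outdir, "simulated"))
  cfg <- pipelineConfig(lnc_mirna = sim$lnc_mirna, mirna_mrna = sim$mirna_mrna,
                        expression = sim$expression, groups = sim$groups,
                        seed = config@seed, ...)
  res <- runPipeline(cfg, outdir = outdir)
  list(sim = sim, result = res)
}
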