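# Deterministic sub-stream seeds: one master seed drives independent streams
# per generated table, so e.g. changing the sample count cannot perturb the
# interaction tables. Kept below 2^31 - 1.
.subSeed <- function(seed, k) as.integer((as.numeric(seed) + 104729 * k) %% (2^31 - 1))

.simIds <- function(config) {
  list(
    mirna = sprintf("miR-%04d", seq_len(config@n_mirna)),
    lnc = sprintf("LNC%04d", seq_len(config@n_lnc)),
    mrna = sprintf("MRNA%04d", seq_len(config@n_mrna))
  )
}

#' Construct a simulation configuration
#'
#' Validated constructor for [SimulationConfig-class]. The defaults define a
#' study-scale benchmark: a universe of 200 miRNAs, 60 lncRNAs and 80 mRNAs
#' with on average 10 miRNA partners per gene, 5 planted ceRNA pairs and 3
#' hub lncRNAs each sharing at least 8 miRNAs with their planted partners,
#' and a two-group design of 7 samples per condition with planted effects of
#' 2 log2 units over noise of 0.5 log2 units — the sample size mirrors the
#' emulated granulosa-cell profiling study (seven cases, seven controls).
#'
#' @param seed,n_mirna,n_lnc,n_mrna,targets_per_gene,n_planted_pairs
#'   see [SimulationConfig-class].
#' @param planted_overlap,n_hub_lnc,hub_n_mrna,n_samples_per_group see
#'   [SimulationConfig-class].
#' @param de_fraction,log2fc_effect,noise_sd,score_pass_frac,energy_pass_frac
#'   see [SimulationConfig-class].
#' @return a [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(seed = 1, n_mirna = 50, n_lnc = 10, n_mrna = 12,
#'                         n_planted_pairs = 3, planted_overlap = 5,
#'                         n_hub_lnc = 0)
#' cfg
#' @export
simulationConfig <- function(seed = 1, n_mirna = 200, n_lnc = 60, n_mrna = 80,
                             targets_per_gene = 10, n_planted_pairs = 5,
                             planted_overlap = 8, n_hub_lnc = 3,
                             hub_n_mrna = 12, n_samples_per_group = 7,
                             de_fraction = 0.15, log2fc_effect = 2,
                             noise_sd = 0.5, score_pass_frac = 0.5,
                             energy_pass_frac = 0.5) {
  new("SimulationConfig",
      seed = as.integer(seed), n_mirna = as.integer(n_mirna),
      n_lnc = as.integer(n_lnc), n_mrna = as.integer(n_mrna),
      targets_per_gene = as.numeric(targets_per_gene),
      n_planted_pairs = as.integer(n_planted_pairs),
      planted_overlap = as.integer(planted_overlap),
      n_hub_lnc = as.integer(n_hub_lnc), hub_n_mrna = as.integer(hub_n_mrna),
      n_samples_per_group = as.integer(n_samples_per_group),
      de_fraction = as.numeric(de_fraction),
      log2fc_effect = as.numeric(log2fc_effect),
      noise_sd = as.numeric(noise_sd),
      score_pass_frac = as.numeric(score_pass_frac),
      energy_pass_frac = as.numeric(energy_pass_frac))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(paste0(
    "SimulationConfig (seed %d): %d miRNAs, %d lncRNAs, %d mRNAs, ",
    "%.1f partners/gene;\n  %d planted pairs + %d hubs x %d mRNAs ",
    "(overlap >= %d); %d+%d samples, effect %.1f, sd %.2f\n"),
    object@seed, object@n_mirna, object@n_lnc, object@n_mrna,
    object@targets_per_gene, object@n_planted_pairs, object@n_hub_lnc,
    object@hub_n_mrna, object@planted_overlap, object@n_samples_per_group,
    object@n_samples_per_group, object@log2fc_effect, object@noise_sd))
})

#' Generate synthetic interaction tables with planted ceRNA structure
#'
#' Draws each gene's miRNA partner set from the universe (partner counts
#' Poisson with mean `targets_per_gene`, truncated at `n_mirna`), then
#' plants ceRNA structure: every ordinary planted lncRNA-mRNA pair receives
#' a common random miRNA subset of size `planted_overlap` added to both
#' partner sets, and every hub lncRNA shares one such subset with each of
#' its `hub_n_mrna` planted mRNA partners, so hubs dominate the inferred
#' network on all centralities. Prediction scores and binding energies of
#' background lncRNA-miRNA rows are drawn uniformly on intervals straddling
#' the 160 / -20 filter thresholds (pass fractions configurable); rows
#' belonging to planted shared sets always pass, so planting survives the
#' candidate filter. All genes involved in planted ceRNA structure are also
#' planted as differentially expressed (random sign), plus additional genes
#' up to `de_fraction` of all genes, drawn proportionally from the lncRNA
#' and mRNA pools.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements
#'   * `lnc_mirna`: data.frame `lncRNA_id`, `miRNA_id`, `prediction_score`,
#'     `binding_energy`;
#'   * `mirna_mrna`: data.frame `miRNA_id`, `mRNA_id`;
#'   * `truth`: list with `planted_pairs` (data.frame `lncRNA_id`,
#'     `mRNA_id`, `n_shared`, `is_hub_pair`), `hub_lnc`, `planted_de`
#'     (data.frame `gene_id`, `direction`), the id pools (`lncRNA_ids`,
#'     `mRNA_ids`, `miRNA_ids`) and the `seed`.
#' @export
generateInteractions <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  ids <- .simIds(config)
  nHubPairs <- config@n_hub_lnc * config@hub_n_mrna
  if (config@n_hub_lnc > config@n_lnc)
    stop("more hub lncRNAs than lncRNAs")
  if (nHubPairs > 0 && config@hub_n_mrna > config@n_mrna)
    stop("hub_n_mrna exceeds n_mrna")
  if (config@n_planted_pairs > config@n_lnc * config@n_mrna)
    stop("n_planted_pairs exceeds n_lnc * n_mrna")

  set.seed(.subSeed(config@seed, 1L))
  lncPartners <- lapply(stats::rpois(config@n_lnc, config@targets_per_gene),
                        function(k) sample(ids$mirna, min(k, config@n_mirna)))
  names(lncPartners) <- ids$lnc
  mrnaPartners <- lapply(stats::rpois(config@n_mrna, config@targets_per_gene),
                         function(k) sample(ids$mirna, min(k, config@n_mirna)))
  names(mrnaPartners) <- ids$mrna

  # hub structure first: hub lncRNAs and their mRNA partner blocks are kept
  # disjoint from each other and from the ordinary planted pairs
  hubLnc <- if (config@n_hub_lnc > 0) sample(ids$lnc, config@n_hub_lnc) else character(0)
  hubMrnaPool <- ids$mrna
  pairRows <- list()
  plantedEdges <- list() # lncRNA-miRNA rows that must survive the filter
  for (h in hubLnc) {
    if (length(hubMrnaPool) < config@hub_n_mrna)
      stop("not enough mRNAs for disjoint hub partner blocks")
    partners <- sample(hubMrnaPool, config@hub_n_mrna)
    hubMrnaPool <- setdiff(hubMrnaPool, partners)
    shared <- sample(ids$mirna, config@planted_overlap)
    lncPartners[[h]] <- union(lncPartners[[h]], shared)
    plantedEdges[[length(plantedEdges) + 1L]] <- data.frame(
      lncRNA_id = h, miRNA_id = shared, stringsAsFactors = FALSE)
    for (g in partners) {
      mrnaPartners[[g]] <- union(mrnaPartners[[g]], shared)
      pairRows[[length(pairRows) + 1L]] <- data.frame(
        lncRNA_id = h, mRNA_id = g, is_hub_pair = TRUE,
        stringsAsFactors = FALSE)
    }
  }

  if (config@n_planted_pairs > 0) {
    freeLnc <- setdiff(ids$lnc, hubLnc)
    freeMrna <- hubMrnaPool
    if (!length(freeLnc) || !length(freeMrna))
      stop("no free lncRNA/mRNA ids left for ordinary planted pairs")
    grid <- expand.grid(lncRNA_id = freeLnc, mRNA_id = freeMrna,
                        stringsAsFactors = FALSE)
    if (config@n_planted_pairs > nrow(grid))
      stop("n_planted_pairs exceeds the available lncRNA x mRNA grid")
    pick <- grid[sample(nrow(grid), config@n_planted_pairs), , drop = FALSE]
    for (i in seq_len(nrow(pick))) {
      L <- pick$lncRNA_id[i]; G <- pick$mRNA_id[i]
      shared <- sample(ids$mirna, config@planted_overlap)
      lncPartners[[L]] <- union(lncPartners[[L]], shared)
      mrnaPartners[[G]] <- union(mrnaPartners[[G]], shared)
      plantedEdges[[length(plantedEdges) + 1L]] <- data.frame(
        lncRNA_id = L, miRNA_id = shared, stringsAsFactors = FALSE)
      pairRows[[length(pairRows) + 1L]] <- data.frame(
        lncRNA_id = L, mRNA_id = G, is_hub_pair = FALSE,
        stringsAsFactors = FALSE)
    }
  }

  lncMirna <- data.frame(
    lncRNA_id = rep(names(lncPartners), lengths(lncPartners)),
    miRNA_id = unlist(lncPartners, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  mirnaMrna <- data.frame(
    miRNA_id = unlist(mrnaPartners, use.names = FALSE),
    mRNA_id = rep(names(mrnaPartners), lengths(mrnaPartners)),
    stringsAsFactors = FALSE
  )

  plantedKey <- if (length(plantedEdges)) {
    pe <- unique(do.call(rbind, plantedEdges))
    paste(pe$lncRNA_id, pe$miRNA_id)
  } else character(0)

  set.seed(.subSeed(config@seed, 2L))
  nr <- nrow(lncMirna)
  scorePass <- stats::runif(nr) < config@score_pass_frac
  energyPass <- stats::runif(nr) < config@energy_pass_frac
  isPlanted <- paste(lncMirna$lncRNA_id, lncMirna$miRNA_id) %in% plantedKey
  scorePass[isPlanted] <- TRUE
  energyPass[isPlanted] <- TRUE
  lncMirna$prediction_score <- ifelse(scorePass,
                                      stats::runif(nr, 160, 200),
                                      stats::runif(nr, 120, 160))
  lncMirna$binding_energy <- ifelse(energyPass,
                                    stats::runif(nr, -30, -20),
                                    stats::runif(nr, -20, -10))

  plantedPairs <- if (length(pairRows)) {
    pp <- do.call(rbind, pairRows)
    pp$n_shared <- vapply(seq_len(nrow(pp)), function(i)
      length(intersect(lncPartners[[pp$lncRNA_id[i]]],
                       mrnaPartners[[pp$mRNA_id[i]]])), integer(1))
    pp[c("lncRNA_id", "mRNA_id", "n_shared", "is_hub_pair")]
  } else {
    data.frame(lncRNA_id = character(), mRNA_id = character(),
               n_shared = integer(), is_hub_pair = logical())
  }

  # planted differential expression: every gene in the planted ceRNA
  # structure, then extra genes up to de_fraction of all genes
  set.seed(.subSeed(config@seed, 3L))
  mustDe <- unique(c(plantedPairs$lncRNA_id, plantedPairs$mRNA_id))
  allGenes <- c(ids$lnc, ids$mrna)
  nTarget <- round(config@de_fraction * length(allGenes))
  extra <- character(0)
  if (nTarget > length(mustDe)) {
    pool <- setdiff(allGenes, mustDe)
    extra <- sample(pool, min(nTarget - length(mustDe), length(pool)))
  }
  deGenes <- c(mustDe, extra)
  plantedDe <- data.frame(
    gene_id = deGenes,
    direction = sample(c(-1, 1), length(deGenes), replace = TRUE),
    stringsAsFactors = FALSE
  )

  truth <- list(planted_pairs = plantedPairs, hub_lnc = sort(hubLnc),
                planted_de = plantedDe,
                lncRNA_ids = ids$lnc, mRNA_ids = ids$mrna,
                miRNA_ids = ids$mirna, seed = config@seed)
  list(lnc_mirna = lncMirna, mirna_mrna = mirnaMrna, truth = truth)
}

#' Generate a synthetic two-group expression matrix
#'
#' Per-gene baseline log2 intensities are uniform on `[6, 10]`; every cell
#' adds Gaussian noise with standard deviation `noise_sd`; planted
#' differentially expressed genes (from the truth produced by
#' [generateInteractions()]) are shifted by `direction * log2fc_effect` in
#' the case group. The expression stream is seeded independently of the
#' interaction stream, so the same configuration always yields the same
#' tables regardless of which parts are generated.
#'
#' @param config a [SimulationConfig-class].
#' @param truth truth list from [generateInteractions()].
#' @return list with `matrix` (genes x samples, log2 scale) and `groups`
#'   (data.frame `sample_id`, `group` with levels `control`, `case`).
#' @export
generateExpression <- function(config, truth) {
  stopifnot(is(config, "SimulationConfig"))
  genes <- c(truth$lncRNA_ids, truth$mRNA_ids)
  ns <- config@n_samples_per_group
  samples <- c(sprintf("ctrl_%02d", seq_len(ns)), sprintf("case_%02d", seq_len(ns)))
  group <- rep(c("control", "case"), each = ns)

  set.seed(.subSeed(config@seed, 4L))
  mu <- stats::runif(length(genes), 6, 10)
  mat <- matrix(stats::rnorm(length(genes) * 2 * ns, sd = config@noise_sd),
                nrow = length(genes), ncol = 2 * ns,
                dimnames = list(genes, samples))
  mat <- mat + mu
  if (nrow(truth$planted_de)) {
    idx <- match(truth$planted_de$gene_id, genes)
    shift <- truth$planted_de$direction * config@log2fc_effect
    mat[idx, group == "case"] <- mat[idx, group == "case"] + shift
  }
  list(matrix = mat,
       groups = data.frame(sample_id = samples, group = group,
                           stringsAsFactors = FALSE))
}

#' Simulate a complete synthetic ceRNA study
#'
#' Convenience wrapper running [generateInteractions()] and
#' [generateExpression()], optionally writing everything to disk in the
#' pipeline's file formats: `interactions.tsv` (columns `source_id`,
#' `target_id`, `interaction_type`, `prediction_score`, `binding_energy`;
#' the last two are empty for miRNA-mRNA rows), `expression.tsv` (first
#' column `gene_id`), `groups.tsv`, and `truth.json`.
#'
#' @param config a [SimulationConfig-class].
#' @param outdir optional output directory (created if missing).
#' @return list with `lnc_mirna`, `mirna_mrna`, `truth`, `expression`,
#'   `groups`.
#' @export
simulateCeRNAStudy <- function(config = simulationConfig(), outdir = NULL) {
  inter <- generateInteractions(config)
  expr <- generateExpression(config, inter$truth)
  out <- list(lnc_mirna = inter$lnc_mirna, mirna_mrna = inter$mirna_mrna,
              truth = inter$truth, expression = expr$matrix,
              groups = expr$groups)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    inTab <- rbind(
      data.frame(source_id = inter$lnc_mirna$lncRNA_id,
                 target_id = inter$lnc_mirna$miRNA_id,
                 interaction_type = "lncRNA-miRNA",
                 prediction_score = inter$lnc_mirna$prediction_score,
                 binding_energy = inter$lnc_mirna$binding_energy),
      data.frame(source_id = inter$mirna_mrna$miRNA_id,
                 target_id = inter$mirna_mrna$mRNA_id,
                 interaction_type = "miRNA-mRNA",
                 prediction_score = NA_real_, binding_energy = NA_real_)
    )
    utils::write.table(inTab, file.path(outdir, "interactions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    exprTab <- data.frame(gene_id = rownames(expr$matrix), expr$matrix,
                          check.names = FALSE)
    utils::write.table(exprTab, file.path(outdir, "expression.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(expr$groups, file.path(outdir, "groups.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(inter$truth, file.path(outdir, "truth.json"),
                         dataframe = "columns", auto_unbox = TRUE, digits = NA)
  }
  out
}
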