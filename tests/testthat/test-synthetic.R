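test_that("generation is deterministic given the config", {
  cfg <- smallConfig(seed = 11)
  a <- generateInteractions(cfg)
  b <- generateInteractions(cfg)
  expect_identical(a, b)
  ea <- generateExpression(cfg, a$truth)
  eb <- generateExpression(cfg, b$truth)
  expect_identical(ea, eb)
})

test_that("interaction tables are unaffected by the expression design", {
  a <- generateInteractions(smallConfig(seed = 3, n_samples_per_group = 4))
  b <- generateInteractions(smallConfig(seed = 3, n_samples_per_group = 9))
  expect_identical(a$lnc_mirna, b$lnc_mirna)
  expect_identical(a$mirna_mrna, b$mirna_mrna)
})

test_that("no planted pairs means empty truth", {
  out <- generateInteractions(smallConfig(seed = 2, n_planted_pairs = 0))
  expect_equal(nrow(out$truth$planted_pairs), 0L)
  expect_length(out$truth$hub_lnc, 0L)
})

test_that("planted pairs share at least the configured miRNA overlap", {
  cfg <- smallConfig(seed = 1, n_mirna = 50, planted_overlap = 5,
                     n_planted_pairs = 3)
  out <- generateInteractions(cfg)
  pp <- out$truth$planted_pairs
  expect_equal(nrow(pp), 3L)
  for (i in seq_len(nrow(pp))) {
    lncSet <- out$lnc_mirna$miRNA_id[out$lnc_mirna$lncRNA_id == pp$lncRNA_id[i]]
    mrnaSet <- out$mirna_mrna$miRNA_id[out$mirna_mrna$mRNA_id == pp$mRNA_id[i]]
    shared <- intersect(lncSet, mrnaSet)
    expect_gte(length(shared), 5L)
    expect_equal(length(shared), pp$n_shared[i])
  }
})

test_that("planted lncRNA-miRNA edges survive the candidate filter", {
  cfg <- smallConfig(seed = 4, n_hub_lnc = 2, hub_n_mrna = 3)
  out <- generateInteractions(cfg)
  filtered <- filterCandidates(out$lnc_mirna)
  pp <- out$truth$planted_pairs
  for (i in seq_len(nrow(pp))) {
    lncSet <- filtered$miRNA_id[filtered$lncRNA_id == pp$lncRNA_id[i]]
    mrnaSet <- out$mirna_mrna$miRNA_id[out$mirna_mrna$mRNA_id == pp$mRNA_id[i]]
    expect_gte(length(intersect(lncSet, mrnaSet)), cfg@planted_overlap)
  }
})

test_that("oversized planting requests are rejected", {
  expect_error(generateInteractions(smallConfig(n_planted_pairs = 1000)),
               "exceeds")
  expect_error(simulationConfig(planted_overlap = 0), "planted_overlap")
  expect_error(simulationConfig(de_fraction = 1.5), "de_fraction")
})

test_that("noiseless expression reproduces the planted effect exactly", {
  cfg <- smallConfig(seed = 5, noise_sd = 0, log2fc_effect = 2,
                     de_fraction = 0.5)
  out <- generateInteractions(cfg)
  expr <- generateExpression(cfg, out$truth)
  grp <- expr$groups$group
  diff <- rowMeans(expr$matrix[, grp == "case"]) -
    rowMeans(expr$matrix[, grp == "control"])
  pd <- out$truth$planted_de
  expect_equal(unname(diff[pd$gene_id]), pd$direction * 2)
  others <- setdiff(rownames(expr$matrix), pd$gene_id)
  expect_equal(unname(diff[others]), rep(0, length(others)))
})

test_that("planted group-mean differences match the effect within noise", {
  cfg <- smallConfig(seed = 7, n_samples_per_group = 7, log2fc_effect = 2,
                     noise_sd = 0.5)
  out <- generateInteractions(cfg)
  expr <- generateExpression(cfg, out$truth)
  grp <- expr$groups$group
  diff <- rowMeans(expr$matrix[, grp == "case"]) -
    rowMeans(expr$matrix[, grp == "control"])
  pd <- out$truth$planted_de
  se <- 0.5 * sqrt(2 / 7)
  expect_true(all(abs(diff[pd$gene_id] - pd$direction * 2) < 3 * se))
})

test_that("zero de_fraction with no planting gives a null expression matrix", {
  cfg <- smallConfig(seed = 8, n_planted_pairs = 0, de_fraction = 0)
  out <- generateInteractions(cfg)
  expect_equal(nrow(out$truth$planted_de), 0L)
})

test_that("written study files round-trip through the pipeline readers", {
  dir <- withr::local_tempdir()
  cfg <- smallConfig(seed = 9, n_hub_lnc = 1, hub_n_mrna = 3)
  sim <- simulateCeRNAStudy(cfg, outdir = dir)
  expect_true(all(file.exists(file.path(
    dir, c("interactions.tsv", "expression.tsv", "groups.tsv", "truth.json")))))
  res <- runPipeline(pipelineConfig(
    lnc_mirna = file.path(dir, "interactions.tsv"),
    expression = file.path(dir, "expression.tsv"),
    groups = file.path(dir, "groups.tsv")))
  inMem <- runPipeline(pipelineConfig(
    lnc_mirna = sim$lnc_mirna, mirna_mrna = sim$mirna_mrna,
    expression = sim$expression, groups = sim$groups))
  expect_equal(res$report, inMem$report, tolerance = 1e-12)
})

test_that("null partner sets give super-uniform ceRNA P-values", {
  cfg <- smallConfig(seed = 13, n_planted_pairs = 0, n_lnc = 25, n_mrna = 25,
                     n_mirna = 60, targets_per_gene = 8)
  out <- generateInteractions(cfg)
  lncSets <- split(out$lnc_mirna$miRNA_id, out$lnc_mirna$lncRNA_id)
  mrnaSets <- split(out$mirna_mrna$miRNA_id, out$mirna_mrna$mRNA_id)
  m <- length(unique(c(out$lnc_mirna$miRNA_id, out$mirna_mrna$miRNA_id)))
  p <- c(outer(names(lncSets), names(mrnaSets), Vectorize(function(L, G) {
    cernaPValue(m, length(mrnaSets[[G]]), length(lncSets[[L]]),
                length(intersect(lncSets[[L]], mrnaSets[[G]])))
  })))
  grid <- seq(0.01, 0.99, by = 0.01)
  excess <- vapply(grid, function(a) mean(p <= a) - a, numeric(1))
  # super-uniformity of a valid discrete test, plus sampling slack
  expect_lt(max(excess), 0.05)
})
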