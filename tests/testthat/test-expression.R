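test_that("probe filter applies the three rules in order", {
  # P4 multi-maps within a biotype (rule 2); P5 spans biotypes (rule 1)
  aln <- data.frame(
    probe_id = c("P1", "P2", "P3", "P4", "P4", "P5", "P5"),
    transcript_id = c("T1", "T1", "T1", "T1", "T2", "T3", "T2"),
    biotype = c("lncRNA", "lncRNA", "lncRNA", "lncRNA", "lncRNA",
                "coding", "lncRNA")
  )
  out <- reannotateProbes(aln, min_probes = 3)
  expect_equal(out$transcript_id, "T1")
  expect_equal(out$n_probes, 3L)

  # invariant to row order
  perm <- aln[sample(nrow(aln)), ]
  expect_equal(reannotateProbes(perm, 3), out)
})

test_that("probe support threshold is a boundary at min_probes", {
  one <- data.frame(probe_id = "P1", transcript_id = "T1", biotype = "coding")
  expect_equal(nrow(reannotateProbes(one, 3)), 0L)
  three <- data.frame(probe_id = c("P1", "P2", "P3"), transcript_id = "T1",
                      biotype = "coding")
  expect_equal(reannotateProbes(three, 3)$transcript_id, "T1")
  expect_equal(nrow(reannotateProbes(three[0, ], 3)), 0L)
})

test_that("quantile normalization equalizes sample distributions", {
  m <- matrix(c(1, 5, 3, 7), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  # rank-and-average by hand: sorted columns (1,5) and (3,7), row means (2,6)
  out <- normalizeMatrix(m, "quantile")
  expect_equal(unname(out), matrix(c(2, 6, 2, 6), 2))

  same <- matrix(c(1, 4, 9, 4, 9, 1), 3, 2) # identical sorted values
  expect_equal(normalizeMatrix(same, "quantile"), same)
  expect_identical(normalizeMatrix(m, "none"), m)
  expect_equal(normalizeMatrix(m, "log2"), log2(m))
  expect_error(normalizeMatrix(matrix(c(-1, 1, 2, 3), 2), "log2"),
               "non-positive")
})

test_that("BH adjustment matches the step-up formula", {
  expect_equal(benjaminiHochberg(0.03), 0.03)
  expect_equal(benjaminiHochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(benjaminiHochberg(c(0.005, 0.011, 0.02, 0.04)),
               c(0.02, 0.022, 0.08 / 3, 0.04))
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(42)
  for (i in 1:25) {
    p <- runif(sample(2:40, 1))
    adj <- benjaminiHochberg(p)
    expect_equal(adj, bruteBH(p))
    perm <- sample(length(p))
    expect_equal(benjaminiHochberg(p[perm]), adj[perm])
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
    expect_true(all(adj >= p - 1e-12))
  }
})

test_that("Welch differential expression matches t.test and the call rule", {
  set.seed(7)
  x <- matrix(rnorm(60, 8, 1), 6, 10,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  x[1, 6:10] <- x[1, 6:10] + 3
  grp <- rep(c("control", "case"), each = 5)
  de <- differentialExpression(x, grp, case = "case")
  for (i in 1:6) {
    tt <- t.test(x[i, 6:10], x[i, 1:5])
    expect_equal(de$p_raw[i], tt$p.value, tolerance = 1e-12)
    expect_equal(de$log2fc[i], unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }
  expect_equal(de$p_adj, benjaminiHochberg(de$p_raw))
  expect_equal(de$is_de, abs(de$log2fc) > 1 & de$p_adj < 0.05)
})

test_that("hand-computed Welch statistic is reproduced", {
  case <- c(10.1, 9.9, 10.0); ctrl <- c(8.0, 8.2, 7.8)
  x <- rbind(g1 = c(ctrl, case))
  x <- rbind(x, g2 = rnorm(6, 8, 0.1))
  de <- differentialExpression(x, rep(c("c0", "c1"), each = 3), case = "c1")
  # direct Welch arithmetic
  v1 <- var(case); v0 <- var(ctrl); se2 <- v1 / 3 + v0 / 3
  tstat <- (mean(case) - mean(ctrl)) / sqrt(se2)
  df <- se2^2 / ((v1 / 3)^2 / 2 + (v0 / 3)^2 / 2)
  expect_equal(de$log2fc[1], 2, tolerance = 1e-12)
  expect_equal(de$p_raw[1], 2 * pt(-abs(tstat), df), tolerance = 1e-12)
})

test_that("degenerate zero-variance genes are handled and flagged", {
  x <- rbind(flat = rep(2, 8), shifted = rep(c(2, 4), each = 4))
  de <- differentialExpression(x, rep(c("a", "b"), each = 4), case = "b")
  expect_equal(de$p_raw[1], 1)
  expect_false(de$var_floored[1])
  expect_true(de$var_floored[2])
  expect_equal(de$log2fc[2], 2)
  expect_lt(de$p_raw[2], 1e-6)
  expect_equal(de$log2fc[1], 0)
  expect_false(de$is_de[1])
})

test_that("identical group means give no DE call", {
  set.seed(1)
  base <- rnorm(4)
  x <- rbind(g = c(base, base))
  x <- rbind(x, g2 = rnorm(8))
  de <- differentialExpression(x, rep(c("a", "b"), each = 4), case = "b")
  expect_equal(de$log2fc[1], 0)
  expect_false(de$is_de[1])
})

test_that("UPGMA clustering under correlation distance matches brute force", {
  # two identical rows merge first at height 0
  m <- rbind(a = c(1, 2, 3, 5), b = c(1, 2, 3, 5), c = c(9, 2, 7, 1))
  hc <- hierarchicalCluster(m)
  expect_equal(hc$height[1], 0, tolerance = 1e-12)
  expect_equal(sort(hc$merge[1, ]), c(-2, -1))

  # a row and its negation sit at distance 2
  n <- rbind(x = c(1, 2, 3), y = -c(1, 2, 3))
  expect_equal(hierarchicalCluster(n)$height, 2, tolerance = 1e-12)

  expect_error(hierarchicalCluster(rbind(a = rep(1, 4), b = 1:4)), "constant")

  set.seed(11)
  for (i in 1:20) {
    nr <- sample(3:8, 1)
    mm <- matrix(rnorm(nr * 6), nr)
    rownames(mm) <- paste0("r", seq_len(nr))
    hc <- hierarchicalCluster(mm)
    d <- 1 - cor(t(mm))
    expect_equal(sort(hc$height), bruteUPGMAHeights(d), tolerance = 1e-9)
  }
})

test_that("cluster trees export as Newick", {
  dir <- withr::local_tempdir()
  m <- matrix(rnorm(20), 4, dimnames = list(paste0("g", 1:4), NULL))
  path <- writeClusterNewick(hierarchicalCluster(m), file.path(dir, "t.nwk"))
  tr <- ape::read.tree(path)
  expect_setequal(tr$tip.label, paste0("g", 1:4))
})

test_that("synthetic DE recovery meets sensitivity and FDR expectations", {
  cfg <- smallConfig(seed = 21, n_lnc = 40, n_mrna = 60,
                     n_samples_per_group = 7, de_fraction = 0.2,
                     log2fc_effect = 2, noise_sd = 0.5)
  out <- generateInteractions(cfg)
  expr <- generateExpression(cfg, out$truth)
  de <- differentialExpression(expr$matrix, expr$groups$group, case = "case")
  truthDe <- out$truth$planted_de$gene_id
  called <- de$gene_id[de$is_de]
  expect_gte(mean(truthDe %in% called), 0.9)
  fdr <- if (length(called)) mean(!called %in% truthDe) else 0
  expect_lte(fdr, 0.1)
})
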