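test_that("candidate filter applies strict score and energy bounds", {
  p <- function(s, e) data.frame(lncRNA_id = "L1", miRNA_id = paste0("m", seq_along(s)),
                                 prediction_score = s, binding_energy = e)
  expect_equal(nrow(filterCandidates(p(161, -20.5))), 1L)
  expect_equal(nrow(filterCandidates(p(160, -25))), 0L)
  expect_equal(nrow(filterCandidates(p(161, -20))), 0L)

  grid <- expand.grid(prediction_score = c(150, 160, 161, 200),
                      binding_energy = c(-19, -21))
  tab <- data.frame(lncRNA_id = "L1", miRNA_id = paste0("m", seq_len(nrow(grid))),
                    grid)
  byHand <- sum(grid$prediction_score > 160 & grid$binding_energy < -20)
  expect_equal(nrow(filterCandidates(tab)), byHand)

  dup <- rbind(tab, tab)
  expect_equal(nrow(filterCandidates(dup)), byHand)

  bad <- p(c(170, NA), c(-25, -25))
  expect_error(filterCandidates(bad), "row")
  expect_error(filterCandidates(tab[, -3]), "missing column")
})

test_that("triple network merges, deduplicates and partitions", {
  lm <- data.frame(lncRNA_id = c("L1", "L1", "L2"), miRNA_id = c("m1", "m2", "m3"))
  mm <- data.frame(miRNA_id = c("m1", "m2", "m3", "m4"), mRNA_id = c("G1", "G1", "G2", "G2"))
  tn <- buildTripleNetwork(lm, mm)
  expect_equal(nrow(tn@lncMirna) + nrow(tn@mirnaMrna), 7L)
  expect_setequal(lncRNAs(tn), c("L1", "L2"))
  expect_setequal(miRNAs(tn), paste0("m", 1:4))
  expect_setequal(mRNAs(tn), c("G1", "G2"))

  tn2 <- buildTripleNetwork(rbind(lm, lm[1, ]), mm)
  expect_equal(nrow(tn2@lncMirna), 3L)

  # partition conflict: id plays lncRNA and mRNA
  expect_error(buildTripleNetwork(lm, data.frame(miRNA_id = "m1", mRNA_id = "L1")),
               "partition")

  set.seed(5)
  for (i in 1:10) {
    a <- data.frame(lncRNA_id = sample(paste0("L", 1:5), 30, TRUE),
                    miRNA_id = sample(paste0("m", 1:8), 30, TRUE))
    b <- data.frame(miRNA_id = sample(paste0("m", 1:8), 30, TRUE),
                    mRNA_id = sample(paste0("G", 1:5), 30, TRUE))
    tn3 <- buildTripleNetwork(a, b)
    expect_equal(nrow(tn3@lncMirna), nrow(unique(a)))
    expect_equal(nrow(tn3@mirnaMrna), nrow(unique(b)))
  }
})

test_that("ceRNA tail probability matches enumeration and closed forms", {
  expect_equal(cernaPValue(10, 4, 3, 0), 1)
  expect_equal(cernaPValue(10, 10, 3, 3), 1) # t = m: overlap certain
  expect_equal(cernaPValue(10, 4, 3, 2), 1 / 3, tolerance = 1e-14)
  expect_equal(cernaPValue(30, 5, 5, 5), 1 / choose(30, 5), tolerance = 1e-14)

  # closed-form cross-check: complement CDF of the hypergeometric
  set.seed(3)
  for (i in 1:50) {
    m <- sample(5:60, 1); t <- sample(0:m, 1); n <- sample(0:m, 1)
    r <- sample(0:min(t, n), 1)
    expect_equal(cernaPValue(m, t, n, r),
                 phyper(r - 1, t, m - t, n, lower.tail = FALSE),
                 tolerance = 1e-12)
  }

  # monotone non-increasing in r
  p <- cernaPValue(rep(40, 6), rep(12, 6), rep(9, 6), 0:5)
  expect_true(all(diff(p) <= 1e-15))

  expect_error(cernaPValue(10, 11, 3, 1), "invariant")
  expect_error(cernaPValue(10, 4, 3, 4), "invariant")
})

test_that("network extraction keeps planted signal and skips r = 0 pairs", {
  # one planted pair with t = n = r = 5 in a 30-miRNA background
  lm <- data.frame(lncRNA_id = "L1", miRNA_id = paste0("m", 1:5))
  mm <- data.frame(miRNA_id = paste0("m", 1:30),
                   mRNA_id = rep(c("G1", "G2"), c(5, 25)))
  net <- extractCernaNetwork(buildTripleNetwork(lm, mm), "L1", c("G1", "G2"))
  ed <- cernaEdges(net)
  expect_equal(nrow(ed), 1L)
  expect_equal(ed$mRNA_id, "G1")
  expect_equal(ed$p_value, 1 / choose(30, 5), tolerance = 1e-12)
  expect_equal(nrow(cernaTriplets(net)), 5L)
  # L1-G2 shares no miRNA: not tested
  expect_equal(nrow(testedPairs(net)), 1L)

  # weak overlap: P = 1/3 at alpha 0.01 is excluded but still tested
  lm2 <- data.frame(lncRNA_id = "L1", miRNA_id = paste0("m", 1:3))
  mm2 <- data.frame(miRNA_id = paste0("m", c(1, 2, 4, 5)),
                    mRNA_id = "G1")
  mm2 <- rbind(mm2, data.frame(miRNA_id = paste0("m", 1:10), mRNA_id = "G9"))
  net2 <- extractCernaNetwork(buildTripleNetwork(lm2, mm2), "L1", "G1")
  expect_equal(nrow(cernaEdges(net2)), 0L)
  te <- testedPairs(net2)
  expect_equal(te$r, 2L)
  expect_equal(te$p_value, 1 / 3, tolerance = 1e-12)
})

test_that("extraction is invariant to input row order and recomputes r", {
  cfg <- smallConfig(seed = 6, n_hub_lnc = 1, hub_n_mrna = 3)
  out <- generateInteractions(cfg)
  dels <- unique(out$lnc_mirna$lncRNA_id)
  dems <- unique(out$mirna_mrna$mRNA_id)
  tn <- buildTripleNetwork(out$lnc_mirna, out$mirna_mrna)
  net <- extractCernaNetwork(tn, dels, dems, alpha = 0.05)

  set.seed(1)
  shuf <- buildTripleNetwork(out$lnc_mirna[sample(nrow(out$lnc_mirna)), ],
                             out$mirna_mrna[sample(nrow(out$mirna_mrna)), ])
  net2 <- extractCernaNetwork(shuf, sample(dels), sample(dems), alpha = 0.05)
  expect_equal(cernaEdges(net), cernaEdges(net2))
  expect_equal(testedPairs(net), testedPairs(net2))

  # every reported r equals the brute-force partner-set intersection
  te <- testedPairs(net)
  for (i in seq_len(nrow(te))) {
    lncSet <- out$lnc_mirna$miRNA_id[out$lnc_mirna$lncRNA_id == te$lncRNA_id[i]]
    mrnaSet <- out$mirna_mrna$miRNA_id[out$mirna_mrna$mRNA_id == te$mRNA_id[i]]
    expect_equal(te$r[i], length(intersect(lncSet, mrnaSet)))
    expect_equal(sort(strsplit(te$shared_mirnas[i], ",")[[1]]),
                 sort(intersect(lncSet, mrnaSet)))
  }
})

test_that("unknown DE ids are skipped with a count, empty overlap gives empty net", {
  lm <- data.frame(lncRNA_id = "L1", miRNA_id = "m1")
  mm <- data.frame(miRNA_id = "m2", mRNA_id = "G1")
  net <- extractCernaNetwork(buildTripleNetwork(lm, mm),
                             c("L1", "Lmissing"), c("G1", "Gmissing"))
  expect_equal(net@skipped, 2)
  expect_equal(nrow(cernaEdges(net)), 0L)
  expect_error(extractCernaNetwork(buildTripleNetwork(lm, mm),
                                   character(0), "G1"), "nonempty")
})

test_that("BH-adjusted extraction mode thresholds on adjusted P", {
  cfg <- smallConfig(seed = 10, n_hub_lnc = 0)
  out <- generateInteractions(cfg)
  tn <- buildTripleNetwork(out$lnc_mirna, out$mirna_mrna)
  dels <- unique(out$lnc_mirna$lncRNA_id)
  dems <- unique(out$mirna_mrna$mRNA_id)
  net <- extractCernaNetwork(tn, dels, dems, alpha = 0.05, adjust = TRUE)
  te <- testedPairs(net)
  expect_equal(te$kept, te$p_adj < 0.05)
})
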