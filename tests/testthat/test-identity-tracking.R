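## shared low-noise simulation for identity tests
identitySim <- function(noise_cv = 0, seed = 19, ...) {
  generateDataset(simulationConfig(
    n_genes = 400, n_de_per_comparison = 20, de_fold = 4,
    frac_wound_shared = 0.5, n_stem_identity = 16, n_root_identity = 16,
    stem_decay_hpe = 72, root_rise_hpe = 72, noise_cv = noise_cv,
    seed = seed, ...))
}

test_that("wound-regulated genes recover the planted wound set", {
  sim <- identitySim(noise_cv = 0.05)
  res <- runComparison(sim$dataset, "leaf_wounded", "leaf_fresh",
                       n_permutations = 300, seed = 3)
  ws <- woundRegulatedGenes(res$de)
  expect_setequal(ws@genes, sim$truth@wound_genes)
  expect_equal(ws@provenance$comparison, "leaf_wounded_vs_leaf_fresh")
  # impossible thresholds give the empty set
  de_hard <- callDE(res$rp,
                    setNames(rowMeans(conditionColumns(sim$dataset, "leaf_wounded")),
                             rownames(sim$dataset)),
                    setNames(rowMeans(conditionColumns(sim$dataset, "leaf_fresh")),
                             rownames(sim$dataset)),
                    deThresholds(m_cut = 1e9))
  expect_length(woundRegulatedGenes(de_hard)@genes, 0)
})

test_that("wound calls on a null dataset stay near the nominal level", {
  x <- generateNullDataset(n_genes = 600, replicates = 3, noise_cv = 0.3,
                           seed = 23)
  res <- runComparison(x, "leaf_wounded", "leaf_fresh",
                       n_permutations = 300, seed = 5)
  ws <- woundRegulatedGenes(res$de)
  # joint rule (|M| > 1 AND p < 0.01) is far stricter than 2% of genes
  expect_lte(length(ws@genes), 0.02 * 600)
})

test_that("wound subtraction is plain set difference with provenance", {
  ar <- geneSet("ar", c("a", "b", "c"))
  w <- geneSet("wound", "b")
  expect_setequal(subtractWound(ar, w)@genes, c("a", "c"))
  expect_setequal(subtractWound(ar, geneSet("none"))@genes, ar@genes)
  expect_length(subtractWound(geneSet("sub", "b"), w)@genes, 0)
  # idempotent
  once <- subtractWound(ar, w)
  expect_setequal(subtractWound(once, w)@genes, once@genes)
  expect_equal(subtractWound(ar, w)@provenance$subtracted, "wound")
})

test_that("organ-specific genes recover planted identity sets", {
  sim <- identitySim(noise_cv = 0.05)
  stem <- organSpecificGenes(sim$dataset, "stem_base",
                             n_permutations = 300, seed = 7)
  root <- organSpecificGenes(sim$dataset, "root",
                             n_permutations = 300, seed = 7)
  expect_setequal(stem@genes, sim$truth@stem_identity$gene_id)
  expect_setequal(root@genes, sim$truth@root_identity$gene_id)
})

test_that("uniform or shared-high genes are not organ-specific", {
  # gene high in stem base AND leaf fails the higher-than-each rule;
  # uniform gene fails everywhere
  filler <- exp(seq(log(30), log(3000), length.out = 12))
  base <- c(sb_only = NA, sb_and_leaf = NA, root_only = NA, uniform = 600,
            setNames(filler, paste0("null", 1:12)))
  sb <- base; sb[1:3] <- c(2000, 2000, 100)
  leaf <- base; leaf[1:3] <- c(100, 2000, 100)
  root <- base; root[1:3] <- c(100, 500, 2000)
  m <- cbind(sb, sb, leaf, leaf, root, root)
  rownames(m) <- names(base)
  set.seed(1)
  m <- m * matrix(exp(rnorm(length(m), 0, 0.02)), nrow = nrow(m))
  d <- data.frame(sample_id = paste0("s", 1:6),
                  tissue = rep(c("stem_base", "leaf_fresh", "root"),
                               each = 2),
                  hpe = c(0, 0, 0, 0, NA, NA), replicate = rep(1:2, 3))
  x <- ExpressionDataset(m, d)
  stem <- organSpecificGenes(x, "stem_base", n_permutations = 500, seed = 2)
  expect_true("sb_only" %in% stem@genes)
  expect_false("sb_and_leaf" %in% stem@genes)
  expect_false("uniform" %in% stem@genes)
  # missing organ is an error
  expect_error(organSpecificGenes(tinyDataset(), "stem_base"), "leaf_fresh")
})

test_that("identity-shift table matches planted step trajectories exactly", {
  sim <- identitySim(noise_cv = 0)
  x <- sim$dataset
  tp <- stemTimepoints(x)[-1]
  de_list <- list()
  for (t in tp)
    de_list[[paste0("sb_", t, "_vs_sb_0")]] <-
      runComparison(x, paste0("sb_", t), "sb_0", n_permutations = 200,
                    seed = 3)$de
  stem <- geneSet("stem", sim$truth@stem_identity$gene_id)
  root <- geneSet("root", sim$truth@root_identity$gene_id)
  wound <- geneSet("wound", sim$truth@wound_genes)
  tbl <- identityShiftTable(x, stem, root, wound, de_list)
  # planted steps all cross at 72 hpe
  expect_equal(tbl$n_stem_repressed, ifelse(tbl$hpe >= 72, 16, 0))
  expect_equal(tbl$n_root_expressed, ifelse(tbl$hpe >= 72, 16, 0))
  # regulated counts: planted DE plus identity genes that have stepped
  for (i in seq_along(tp)) {
    t <- tp[i]
    tr <- trueRegulated(sim$truth, paste0("sb_", t), "sb_0")
    expect_equal(tbl$n_ar_regulated[i], length(c(tr$up, tr$down)))
    expect_equal(tbl$n_ar_minus_wound[i],
                 length(setdiff(c(tr$up, tr$down), sim$truth@wound_genes)))
  }
  # wound genes planted at 2 hpe are all subtracted there
  expect_lt(tbl$n_ar_minus_wound[1], tbl$n_ar_regulated[1])
})

test_that("largest shift interval follows the planted step", {
  tbl <- data.frame(hpe = c(2, 6, 24, 72, 96),
                    n_ar_regulated = 0, n_ar_minus_wound = 0,
                    n_stem_repressed = c(0, 0, 0, 30, 30),
                    n_root_expressed = c(0, 0, 0, 25, 25))
  got <- largestShiftInterval(tbl)
  expect_equal(c(got$from, got$to), c(24, 72))
  expect_equal(got$shift, 55)
  # constant counts: earliest interval, shift 0
  tbl0 <- tbl; tbl0$n_stem_repressed <- 5; tbl0$n_root_expressed <- 5
  got0 <- largestShiftInterval(tbl0)
  expect_equal(c(got0$from, got0$to), c(2, 6))
  expect_equal(got0$shift, 0)
  # monotone counts: agrees with brute force over intervals
  tbl2 <- tbl
  tbl2$n_stem_repressed <- c(1, 4, 9, 20, 22)
  tbl2$n_root_expressed <- c(0, 2, 6, 14, 30)
  brute <- which.max(abs(diff(tbl2$n_stem_repressed)) +
                       abs(diff(tbl2$n_root_expressed)))
  got2 <- largestShiftInterval(tbl2)
  expect_equal(got2$from, tbl2$hpe[brute])
  expect_error(largestShiftInterval(tbl[1, ]), "2 timepoints")
})

test_that("stricter thresholds never enlarge a gene set", {
  sim <- identitySim(noise_cv = 0.3, seed = 29)
  res <- runComparison(sim$dataset, "leaf_wounded", "leaf_fresh",
                       n_permutations = 200, seed = 5)
  loose <- woundRegulatedGenes(res$de)
  means_a <- setNames(rowMeans(conditionColumns(sim$dataset, "leaf_wounded")),
                      rownames(sim$dataset))
  means_b <- setNames(rowMeans(conditionColumns(sim$dataset, "leaf_fresh")),
                      rownames(sim$dataset))
  for (th in list(deThresholds(m_cut = 1.5), deThresholds(p_cut = 0.001),
                  deThresholds(m_cut = 2, p_cut = 0.005))) {
    strict <- woundRegulatedGenes(callDE(res$rp, means_a, means_b, th))
    expect_true(all(strict@genes %in% loose@genes))
  }
})
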