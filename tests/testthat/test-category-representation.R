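fakeDETable <- function(calls) {
  ids <- names(calls)
  n <- length(ids)
  tb <- S4Vectors::DataFrame(gene_id = ids, mean_a = rep(100, n),
                             mean_b = rep(100, n), m = rep(0, n),
                             p_up = rep(1, n), p_down = rep(1, n),
                             call = unname(calls))
  new("DETable", table = tb, thresholds = deThresholds(),
      comparison = "test")
}

test_that("the representation ratio follows the printed counts formula", {
  expect_equal(representationRatio(10, 100, 1000, 10000), 1)
  expect_equal(representationRatio(20, 100, 1000, 10000), 2)
  expect_equal(representationRatio(0, 100, 1000, 10000), 0)
  # scale invariance: common factor on all counts cancels
  set.seed(4)
  for (i in 1:10) {
    n_at <- sample(1000:10000, 1)
    n_xt <- sample(10:300, 1)
    n_ap <- sample(50:900, 1)
    n_xp <- sample(0:min(n_xt, n_ap), 1)
    r <- representationRatio(n_xp, n_xt, n_ap, n_at)
    expect_equal(representationRatio(3 * n_xp, 3 * n_xt, 3 * n_ap, 3 * n_at), r)
  }
  # distinct error per zero denominator
  expect_error(representationRatio(1, 10, 100, 0), "n_at")
  expect_error(representationRatio(0, 0, 100, 1000), "n_xt")
  expect_error(representationRatio(0, 10, 0, 1000), "n_ap")
})

test_that("category profile matches an independent recount", {
  set.seed(11)
  n <- 400
  ids <- sprintf("g%03d", 1:n)
  calls <- setNames(sample(c("up", "down", "ns"), n, replace = TRUE,
                           prob = c(0.15, 0.1, 0.75)), ids)
  ann <- data.frame(gene_id = ids,
                    category_code = sample(c("Ib", "VIa", "XIIa", "XV"),
                                           n, replace = TRUE),
                    category_name = "x", hormone_category = "none")
  prof <- categoryProfile(fakeDETable(calls), ann, min_category_size = 5)
  for (i in seq_len(nrow(prof))) {
    expect_equal(prof$ratio[i],
                 recountRatio(calls, ann, prof$category[i],
                              prof$direction[i]))
  }
  # conservation when every gene is annotated
  up <- prof[prof$direction == "up", ]
  expect_equal(sum(up$n_xp), unique(up$n_ap))
  expect_equal(sum(up$n_xt), unique(up$n_at))
  # weighted mean of ratios over disjoint full-coverage categories is 1
  w <- up$n_xt * (up$n_ap / up$n_at)
  expect_equal(sum(w * up$ratio) / sum(w), 1)
})

test_that("small categories are excluded and zero counts give -Inf m", {
  calls <- setNames(c(rep("ns", 90), rep("up", 10)),
                    sprintf("g%03d", 1:100))
  ann <- data.frame(gene_id = sprintf("g%03d", 1:100),
                    category_code = c(rep("tiny", 3), rep("quiet", 40),
                                      rep("big", 57)),
                    category_name = "x", hormone_category = "none")
  prof <- categoryProfile(fakeDETable(calls), ann, min_category_size = 10)
  tiny <- prof[prof$category == "tiny" & prof$direction == "up", ]
  expect_true(tiny$excluded)
  expect_equal(tiny$flag, "none")
  # the 'quiet' category has no up gene at all: ratio 0, m -Inf, under
  quiet <- prof[prof$category == "quiet" & prof$direction == "up", ]
  expect_equal(quiet$ratio, 0)
  expect_equal(quiet$m, -Inf)
  expect_equal(quiet$flag, "under")
  expect_error(categoryProfile(fakeDETable(calls), ann[0, ]), "empty")
})

test_that("unannotated genes count in the universe unless restricted", {
  calls <- setNames(c(rep("up", 20), rep("ns", 80)),
                    sprintf("g%03d", 1:100))
  ann <- data.frame(gene_id = sprintf("g%03d", 1:50),
                    category_code = "Ib", category_name = "x",
                    hormone_category = "none")
  all_u <- categoryProfile(fakeDETable(calls), ann, min_category_size = 5)
  ann_u <- categoryProfile(fakeDETable(calls), ann, min_category_size = 5,
                           universe = "annotated")
  expect_equal(all_u$n_at[1], 100)
  expect_equal(ann_u$n_at[1], 50)
})

test_that("planted category enrichment is recovered from called DE", {
  ratios <- c()
  for (seed in 1:3) {
    plan <- defaultCategoryPlan(2000)
    plan$ratio_up <- ifelse(plan$code == "XIb", 3, 1)
    sim <- generateDataset(simulationConfig(
      n_genes = 2000, n_de_per_comparison = 120, de_fold = 4,
      noise_cv = 0.2, n_stem_identity = 0, n_root_identity = 0,
      frac_wound_shared = 0, category_plan = plan, seed = seed))
    res <- runComparison(sim$dataset, "sb_72", "sb_0",
                         n_permutations = 200, seed = seed)
    prof <- categoryProfile(res$de, sim$annotation)
    ratios <- c(ratios,
                prof$ratio[prof$category == "XIb" & prof$direction == "up"])
  }
  expect_lt(abs(mean(ratios) - 3) / 3, 0.2)
})

test_that("uniform assignment yields ratios near 1 for large categories", {
  plan <- data.frame(code = c("A", "B", "C", "D"),
                     name = "x", hormone = "none",
                     size = rep(5000, 4), ratio_up = 1)
  sim <- generateDataset(simulationConfig(
    n_genes = 20000, n_de_per_comparison = 1000, de_fold = 4,
    noise_cv = 0.3, n_stem_identity = 0, n_root_identity = 0,
    frac_wound_shared = 0, category_plan = plan, seed = 41))
  # ratios from planted truth (no test statistic involved): pure check of
  # the assignment's uniformity, pooled over all baseline comparisons so
  # the counts are large
  calls <- setNames(rep("ns", 20000), sim$annotation$gene_id)
  for (cmp in sim$truth@de_genes) {
    calls[cmp$up] <- "up"; calls[cmp$down] <- "down"
  }
  prof <- categoryProfile(fakeDETable(calls), sim$annotation)
  big <- prof[prof$n_xt >= 200, ]
  expect_gte(min(big$n_xp), 200)
  expect_true(all(abs(big$m) < 0.3))
})

test_that("hormone time-course flags planted ethylene enrichment", {
  plan <- defaultCategoryPlan(2000)
  plan$size[plan$code == "XIb"] <- 200
  plan$ratio_up <- ifelse(plan$code == "XIb", 4, 1)
  sim <- generateDataset(simulationConfig(
    n_genes = 2000, n_de_per_comparison = 150, de_fold = 4,
    noise_cv = 0.15, n_stem_identity = 0, n_root_identity = 0,
    frac_wound_shared = 0, category_plan = plan, seed = 47))
  x <- sim$dataset
  de_list <- list()
  for (t in stemTimepoints(x)[-1]) {
    key <- paste0("sb_", t, "_vs_sb_0")
    de_list[[key]] <- runComparison(x, paste0("sb_", t), "sb_0",
                                    n_permutations = 150, seed = 7)$de
  }
  ht <- hormoneTimecourse(de_list, sim$annotation)
  eth_up <- ht[ht$category == "ethylene" & ht$direction == "up", ]
  expect_equal(nrow(eth_up), length(de_list))
  expect_true(all(eth_up$flag == "over"))
  # tiny hormone categories are excluded everywhere
  small <- ht[ht$category %in% c("cytokinin", "brassinosteroid",
                                 "salicylic_acid"), ]
  expect_true(all(small$excluded))
  expect_true(all(small$flag == "none"))
  # annotation without hormones is an error
  ann0 <- sim$annotation; ann0$hormone_category <- "none"
  expect_error(hormoneTimecourse(de_list, ann0), "hormone")
})
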