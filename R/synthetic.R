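#' Default functional-category plan for the generator
#'
#' Categories mirror a curated functional classification of a rooting
#' transcriptome (storage, mineral acquisition, anti-oxidative and secondary
#' metabolism, biotic stimuli) plus the eight phytohormone classes; the
#' cytokinin, brassinosteroid and salicylic-acid classes are deliberately
#' tiny so that the small-category exclusion rule is exercised. Sizes are
#' fractions of `n_genes`; `ratio_up` is the planted over-representation of
#' the category among genes up-regulated versus the pre-excision stem base
#' (ethylene- and jasmonate-related genes are planted over-represented, the
#' pattern the analysis is designed to detect).
#'
#' @param n_genes number of genes the plan is scaled to.
#' @return data.frame with columns `code`, `name`, `hormone`, `size`,
#'   `ratio_up`.
#' @export
defaultCategoryPlan <- function(n_genes) {
  plan <- data.frame(
    code = c("Ib", "IIIb", "Vg", "VIa", "XIIa",
             "XIa", "XIb", "XIc", "XId", "XIe", "XIf", "XIg", "XIh"),
    name = c("Storage", "Mineral nutrient responsive and acquisition",
             "Antioxidative metabolism and redox state",
             "Secondary metabolism", "Biotic stimuli",
             "Auxin", "Ethylene", "Jasmonate", "Abscisic acid",
             "Gibberellin", "Cytokinin", "Brassinosteroid",
             "Salicylic acid"),
    hormone = c("none", "none", "none", "none", "none",
                "auxin", "ethylene", "jasmonate", "abscisic_acid",
                "gibberellin", "cytokinin", "brassinosteroid",
                "salicylic_acid"),
    frac = c(0.030, 0.030, 0.030, 0.050, 0.040,
             0.040, 0.030, 0.020, 0.020, 0.015,
             0.004, 0.003, 0.003),
    ratio_up = c(1, 1, 1, 1, 1, 1, 3, 2, 1, 1, 1, 1, 1),
    stringsAsFactors = FALSE)
  plan$size <- pmax(2L, as.integer(round(plan$frac * n_genes)))
  plan$frac <- NULL
  plan
}

#' Configure the synthetic time-course generator
#'
#' Emulates the study design the package targets: stem-base samples at 0,
#' 2, 6, 24, 72, 96, 144 and 192 hours post-excision (hpe), fresh and
#' wounded leaves, and a fully developed root, with 3 biological replicates
#' per condition. Baseline intensities are log-normal (default median 500,
#' log-sd 1, i.e. spanning tens to thousands of fluorescence units) and
#' replicate noise is multiplicative log-normal with coefficient of
#' variation `noise_cv`, mean-unbiased (`mean * exp(N(-s^2/2, s^2))` with
#' `s^2 = log(1 + cv^2)`).
#'
#' Planted structure (the ground truth returned alongside the data):
#' \itemize{
#'   \item `n_de_per_comparison` genes per stem-base timepoint `t > 0` whose
#'     condition mean at `t` is multiplied (up) or divided (down) by
#'     `de_fold`, a fraction `de_frac_up` of them up.
#'   \item a fraction `frac_wound_shared` of the genes planted at the early
#'     timepoints (2 and 6 hpe) is additionally planted, same direction, in
#'     the wounded-vs-fresh leaf contrast — these form the wound-response
#'     set that the pipeline subtracts.
#'   \item `n_stem_identity` genes high (`identity_high`) in the stem base
#'     and low elsewhere, stepping down to `identity_low` at a decay
#'     timepoint (`stem_decay_hpe`, recycled over the planted genes);
#'     `n_root_identity` genes high in the root, stepping up in the stem
#'     base at `root_rise_hpe`. The steps cross the conventional 500
#'     expression cutoff, so identity-shift counts are exactly predictable
#'     at zero noise.
#'   \item category labels assigned so that each category of
#'     `category_plan` attains its planted `ratio_up` among the true
#'     up-regulated genes of every baseline comparison.
#' }
#'
#' @param n_genes number of genes (the emulated platform has ~25,000;
#'   simulations in this package scale that down).
#' @param timepoints_hpe stem-base sampling times, starting at 0.
#' @param replicates biological replicates per condition.
#' @param baseline_log_mean,baseline_log_sd natural-log mean and sd of the
#'   baseline intensity distribution.
#' @param noise_cv replicate coefficient of variation.
#' @param n_de_per_comparison planted DE genes per baseline comparison
#'   (default 3% of `n_genes`).
#' @param de_fold planted fold change (> 1).
#' @param de_frac_up fraction of planted DE genes that are up-regulated.
#' @param frac_wound_shared fraction of early (2 and 6 hpe) DE genes shared
#'   with the leaf-wounding response.
#' @param n_stem_identity,n_root_identity sizes of the organ-identity sets
#'   (defaults 1.4% and 1.9% of `n_genes`, the proportions of the emulated
#'   study's stem-base and root sets).
#' @param identity_high,identity_low step levels bracketing the 500 cutoff.
#' @param stem_decay_hpe,root_rise_hpe timepoints at which identity genes
#'   cross the cutoff; recycled across the genes of each set. `NULL` spreads
#'   them over all timepoints > 0.
#' @param category_plan data.frame as [defaultCategoryPlan()].
#' @param seed integer seed; same config + seed gives byte-identical output.
#' @return a validated [SimulationConfig-class].
#' @export
simulationConfig <- function(n_genes = 2000,
                             timepoints_hpe = c(0, 2, 6, 24, 72, 96, 144, 192),
                             replicates = 3,
                             baseline_log_mean = log(500),
                             baseline_log_sd = 1,
                             noise_cv = 0.3,
                             n_de_per_comparison = NULL,
                             de_fold = 4,
                             de_frac_up = 0.5,
                             frac_wound_shared = 0.3,
                             n_stem_identity = NULL,
                             n_root_identity = NULL,
                             identity_high = 2000,
                             identity_low = 100,
                             stem_decay_hpe = NULL,
                             root_rise_hpe = NULL,
                             category_plan = NULL,
                             seed = 1) {
  ## planted-set defaults scale with the platform size, keeping the
  ## proportions of the emulated study (identity sets of roughly 1.4% and
  ## 1.9% of genes, DE sets a few percent per comparison)
  if (is.null(n_de_per_comparison))
    n_de_per_comparison <- round(0.03 * n_genes)
  if (is.null(n_stem_identity)) n_stem_identity <- round(0.014 * n_genes)
  if (is.null(n_root_identity)) n_root_identity <- round(0.019 * n_genes)
  if (is.null(category_plan)) category_plan <- defaultCategoryPlan(n_genes)
  if (is.null(stem_decay_hpe)) stem_decay_hpe <- timepoints_hpe[-1]
  if (is.null(root_rise_hpe)) root_rise_hpe <- timepoints_hpe[-1]
  new("SimulationConfig",
      n_genes = as.integer(n_genes),
      timepoints_hpe = as.numeric(timepoints_hpe),
      replicates = as.integer(replicates),
      baseline_log_mean = baseline_log_mean,
      baseline_log_sd = baseline_log_sd,
      noise_cv = noise_cv,
      n_de_per_comparison = as.integer(n_de_per_comparison),
      de_fold = de_fold,
      de_frac_up = de_frac_up,
      frac_wound_shared = frac_wound_shared,
      n_stem_identity = as.integer(n_stem_identity),
      n_root_identity = as.integer(n_root_identity),
      identity_high = identity_high,
      identity_low = identity_low,
      stem_decay_hpe = as.numeric(stem_decay_hpe),
      root_rise_hpe = as.numeric(root_rise_hpe),
      category_plan = category_plan,
      seed = as.integer(seed))
}

simConditions <- function(config) {
  c(paste0("sb_", config@timepoints_hpe), "leaf_fresh", "leaf_wounded",
    "root")
}

simDesign <- function(config) {
  conds <- simConditions(config)
  tissue <- c(rep("stem_base", length(config@timepoints_hpe)),
              "leaf_fresh", "leaf_wounded", "root")
  hpe <- c(config@timepoints_hpe, 0, 2, NA)
  r <- config@replicates
  data.frame(
    sample_id = paste0(rep(conds, each = r), "_r", seq_len(r)),
    tissue = rep(tissue, each = r),
    hpe = rep(hpe, each = r),
    replicate = rep(seq_len(r), times = length(conds)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic time-course dataset with known ground truth
#'
#' @param config a [SimulationConfig-class] from [simulationConfig()].
#' @return list with elements `dataset` ([ExpressionDataset-class]),
#'   `annotation` (data.frame as [readAnnotation()]) and `truth`
#'   ([SyntheticTruth-class]).
#' @examples
#' sim <- generateDataset(simulationConfig(n_genes = 200, seed = 7))
#' sim$dataset
#' lengths(sim$truth@de_genes[["sb_24_vs_sb_0"]])
#' @export
generateDataset <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  withSeed(config@seed, generateDatasetImpl(config))
}

generateDatasetImpl <- function(config) {
  n <- config@n_genes
  tp <- config@timepoints_hpe
  ids <- sprintf("gene_%05d", seq_len(n))
  conds <- simConditions(config)

  baseline <- exp(rnorm(n, config@baseline_log_mean, config@baseline_log_sd))
  means <- matrix(baseline, nrow = n, ncol = length(conds),
                  dimnames = list(ids, conds))

  ## --- allocate disjoint planted gene pools -------------------------------
  cursor <- 0L
  take <- function(k) {
    if (k == 0L) return(character(0))
    out <- ids[(cursor + 1L):(cursor + k)]
    cursor <<- cursor + k
    out
  }
  stem_ids <- take(config@n_stem_identity)
  root_ids <- take(config@n_root_identity)

  de_genes <- list()
  for (t in tp[-1]) {
    g <- take(config@n_de_per_comparison)
    n_up <- round(config@de_frac_up * length(g))
    de_genes[[paste0("sb_", t, "_vs_sb_0")]] <-
      list(up = g[seq_len(n_up)],
           down = if (length(g) > n_up) g[(n_up + 1L):length(g)]
                  else character(0))
  }

  ## --- plant DE versus the pre-excision stem base -------------------------
  for (t in tp[-1]) {
    cmp <- de_genes[[paste0("sb_", t, "_vs_sb_0")]]
    col <- paste0("sb_", t)
    means[cmp$up, col] <- means[cmp$up, col] * config@de_fold
    means[cmp$down, col] <- means[cmp$down, col] / config@de_fold
  }

  ## --- wound-shared genes: early stem-base DE also responds in leaves -----
  wound <- character(0)
  early <- intersect(c(2, 6), tp[-1])
  for (t in early) {
    cmp <- de_genes[[paste0("sb_", t, "_vs_sb_0")]]
    for (dir in c("up", "down")) {
      g <- cmp[[dir]]
      k <- round(config@frac_wound_shared * length(g))
      if (k == 0) next
      shared <- g[seq_len(k)]
      means[shared, "leaf_wounded"] <-
        if (dir == "up") means[shared, "leaf_wounded"] * config@de_fold
        else means[shared, "leaf_wounded"] / config@de_fold
      wound <- c(wound, shared)
    }
  }
  wound_up <- wound[means[wound, "leaf_wounded"] >
                      means[wound, "leaf_fresh"]]
  de_genes[["leaf_wounded_vs_leaf_fresh"]] <-
    list(up = wound_up, down = setdiff(wound, wound_up))

  ## --- organ-identity step trajectories -----------------------------------
  stem_decay <- rep_len(config@stem_decay_hpe,
                        max(1L, length(stem_ids)))[seq_along(stem_ids)]
  if (length(stem_ids)) {
    means[stem_ids, ] <- config@identity_low
    for (i in seq_along(stem_ids)) {
      pre <- paste0("sb_", tp[tp < stem_decay[i]])
      means[stem_ids[i], pre] <- config@identity_high
    }
  }
  root_rise <- rep_len(config@root_rise_hpe,
                       max(1L, length(root_ids)))[seq_along(root_ids)]
  if (length(root_ids)) {
    means[root_ids, ] <- config@identity_low
    means[root_ids, "root"] <- config@identity_high
    for (i in seq_along(root_ids)) {
      post <- paste0("sb_", tp[tp >= root_rise[i] & tp > 0])
      means[root_ids[i], post] <- config@identity_high
    }
  }

  ## --- category assignment with planted enrichment ------------------------
  plan <- config@category_plan
  up_pools <- lapply(de_genes[paste0("sb_", tp[-1], "_vs_sb_0")],
                     function(x) x$up)
  all_up <- unique(unlist(up_pools))
  assigned <- setNames(rep(NA_character_, n), ids)
  enriched <- plan[plan$ratio_up != 1, , drop = FALSE]
  for (i in seq_len(nrow(enriched))) {
    row <- enriched[i, ]
    members <- character(0)
    for (pool in up_pools) {
      free <- pool[is.na(assigned[pool])]
      k <- min(length(free),
               round(row$ratio_up * row$size * length(pool) / n))
      members <- c(members, free[seq_len(k)])
    }
    non_up <- ids[is.na(assigned) & !(ids %in% all_up)]
    fill <- max(0L, row$size - length(members))
    members <- c(members, sample(non_up, min(fill, length(non_up))))
    assigned[members] <- row$code
  }
  neutral <- plan[plan$ratio_up == 1, , drop = FALSE]
  free <- sample(ids[is.na(assigned)])
  pos <- 0L
  for (i in seq_len(nrow(neutral))) {
    k <- min(neutral$size[i], length(free) - pos)
    if (k > 0) assigned[free[(pos + 1L):(pos + k)]] <- neutral$code[i]
    pos <- pos + k
  }
  assigned[is.na(assigned)] <- "XV"
  lookup <- rbind(plan[, c("code", "name", "hormone")],
                  data.frame(code = "XV", name = "Unclassified",
                             hormone = "none", stringsAsFactors = FALSE))
  idx <- match(assigned, lookup$code)
  annotation <- data.frame(gene_id = ids,
                           category_code = assigned,
                           category_name = lookup$name[idx],
                           hormone_category = lookup$hormone[idx],
                           stringsAsFactors = FALSE)

  ## --- replicate sampling --------------------------------------------------
  design <- simDesign(config)
  s2 <- log(1 + config@noise_cv^2)
  vals <- matrix(0, nrow = n, ncol = nrow(design),
                 dimnames = list(ids, design$sample_id))
  condcol <- conditionOf(design)
  for (j in seq_len(nrow(design))) {
    mu <- means[, condcol[j]]
    vals[, j] <- if (s2 == 0) mu
                 else mu * exp(rnorm(n, -s2 / 2, sqrt(s2)))
  }

  truth <- new("SyntheticTruth",
               de_genes = de_genes,
               wound_genes = unique(wound),
               stem_identity = data.frame(gene_id = stem_ids,
                                          decay_hpe = stem_decay,
                                          stringsAsFactors = FALSE),
               root_identity = data.frame(gene_id = root_ids,
                                          rise_hpe = root_rise,
                                          stringsAsFactors = FALSE),
               enriched_categories = setNames(enriched$ratio_up,
                                              enriched$code),
               condition_means = means)
  list(dataset = ExpressionDataset(vals, design),
       annotation = annotation, truth = truth)
}

#' Generate a null dataset (no planted effects)
#'
#' Every gene has identical condition means across the whole design; the
#' only variation is replicate noise. Used to calibrate the permutation
#' test: empirical p-values on this data should be approximately uniform.
#'
#' @param n_genes number of genes.
#' @param replicates replicates per condition.
#' @param noise_cv replicate coefficient of variation.
#' @param seed integer seed.
#' @param timepoints_hpe stem-base timepoints.
#' @return an [ExpressionDataset-class].
#' @export
generateNullDataset <- function(n_genes, replicates = 4, noise_cv = 0.3,
                                seed = 1,
                                timepoints_hpe = c(0, 2, 6, 24, 72, 96,
                                                   144, 192)) {
  config <- simulationConfig(n_genes = n_genes,
                             timepoints_hpe = timepoints_hpe,
                             replicates = replicates, noise_cv = noise_cv,
                             n_de_per_comparison = 0,
                             n_stem_identity = 0, n_root_identity = 0,
                             frac_wound_shared = 0, seed = seed)
  generateDataset(config)$dataset
}

#' True regulated genes of a contrast, from planted condition means
#'
#' @param truth a [SyntheticTruth-class].
#' @param a,b condition labels (columns of `truth@condition_means`).
#' @return list with `up` and `down` gene-id vectors: genes whose true mean
#'   in `a` differs from that in `b` in the given direction.
#' @export
trueRegulated <- function(truth, a, b) {
  m <- truth@condition_means
  list(up = rownames(m)[m[, a] > m[, b]],
       down = rownames(m)[m[, a] < m[, b]])
}
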