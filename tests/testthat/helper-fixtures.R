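## Shared fixtures and independent oracles for the test suite.

## A minimal hand-built dataset: 3 genes, stem base at 0/24 hpe plus root,
## 2 replicates each.
tinyDataset <- function() {
  m <- matrix(c(1000, 100, 500,   980, 110, 520,   # sb_0
                1020, 410, 490,  1005, 390, 515,   # sb_24
                90, 800, 505,     110, 820, 495),  # root
              nrow = 3,
              dimnames = list(c("gA", "gB", "gC"), NULL))
  d <- data.frame(sample_id = c("sb0_1", "sb0_2", "sb24_1", "sb24_2",
                                "root_1", "root_2"),
                  tissue = rep(c("stem_base", "stem_base", "root"), each = 2),
                  hpe = c(0, 0, 24, 24, NA, NA),
                  replicate = rep(1:2, 3))
  ExpressionDataset(m, d)
}

randomDesign <- function(n_cond = 3, reps = 2) {
  tissues <- c("stem_base", "stem_base", "root", "leaf_fresh")[seq_len(n_cond)]
  hpe <- c(0, 24, NA, 0)[seq_len(n_cond)]
  data.frame(sample_id = paste0("s", seq_len(n_cond * reps)),
             tissue = rep(tissues, each = reps),
             hpe = rep(hpe, each = reps),
             replicate = rep(seq_len(reps), n_cond))
}

## All permutations of a vector (list of orderings). n <= 6 only.
allPerms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in allPerms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}

## Independent exhaustive oracle for the pooled rank-product permutation
## p-value: enumerate every configuration of within-column rank
## permutations, recompute the statistic for all genes, and count how often
## a permuted value is <= each observed one. Brute force, usable for
## n <= 5 genes and K <= 2 columns.
exhaustiveRPPvalues <- function(ratios, direction) {
  n <- nrow(ratios)
  ranks <- apply(as.matrix(ratios), 2, function(col) {
    if (direction == "up") rank(-col, ties.method = "average")
    else rank(col, ties.method = "average")
  })
  ranks <- matrix(ranks, nrow = n)
  K <- ncol(ranks)
  obs <- exp(rowMeans(log(ranks)))
  col_perms <- lapply(seq_len(K), function(k) allPerms(ranks[, k]))
  grid <- do.call(expand.grid, c(lapply(col_perms, seq_along),
                                 KEEP.OUT.ATTRS = FALSE))
  counts <- numeric(n)
  total <- 0
  for (r in seq_len(nrow(grid))) {
    cfg <- vapply(seq_len(K), function(k)
      col_perms[[k]][[grid[r, k]]], numeric(n))
    cfg <- matrix(cfg, nrow = n)
    rp_perm <- exp(rowMeans(log(cfg)))
    for (g in seq_len(n)) counts[g] <- counts[g] + sum(rp_perm <= obs[g] + 1e-12)
    total <- total + n
  }
  counts / total
}

## Independent recount of a representation ratio from raw calls and
## annotation, written loop-wise (package code is vectorized).
recountRatio <- function(calls, annotation, category, direction) {
  n_at <- length(calls)
  n_ap <- 0L; n_xt <- 0L; n_xp <- 0L
  ann <- setNames(annotation$category_code, annotation$gene_id)
  for (g in names(calls)) {
    if (calls[[g]] == direction) n_ap <- n_ap + 1L
    in_cat <- !is.na(ann[g]) && ann[[g]] == category
    if (in_cat) {
      n_xt <- n_xt + 1L
      if (calls[[g]] == direction) n_xp <- n_xp + 1L
    }
  }
  (n_xp / n_xt) / (n_ap / n_at)
}

## Two-sided KS distance of values from Uniform(0, 1).
ksUniform <- function(p) {
  p <- sort(p)
  n <- length(p)
  max(abs(seq_len(n) / n - p), abs(p - (seq_len(n) - 1) / n))
}
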