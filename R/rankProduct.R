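#' All pairwise replicate ratio columns of a two-condition contrast
#'
#' The two-class rank-product construction compares every replicate of
#' condition A with every replicate of condition B: for `nA` and `nB`
#' replicates the result has `K = nA * nB` columns, with column `(i, j)`
#' holding the per-gene ratio `a[, i] / b[, j]`. Intensities are floored
#' (see [floorIntensity()]) so all ratios are finite and positive.
#'
#' @param a genes x replicates intensity matrix of condition A.
#' @param b genes x replicates intensity matrix of condition B.
#' @param floor intensity floor applied before the ratios.
#' @return genes x K matrix of ratios; columns named `"a<i>/b<j>"`.
#' @export
pairwiseRatioMatrix <- function(a, b, floor = 1) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (nrow(a) != nrow(b)) stop("'a' and 'b' must have the same genes")
  if (ncol(a) < 1L || ncol(b) < 1L)
    stop("each condition needs at least one replicate column")
  a <- floorIntensity(a, floor)
  b <- floorIntensity(b, floor)
  K <- ncol(a) * ncol(b)
  out <- matrix(0, nrow = nrow(a), ncol = K)
  cn <- character(K)
  k <- 0L
  for (i in seq_len(ncol(a))) for (j in seq_len(ncol(b))) {
    k <- k + 1L
    out[, k] <- a[, i] / b[, j]
    cn[k] <- sprintf("a%d/b%d", i, j)
  }
  dimnames(out) <- list(rownames(a), cn)
  out
}

rankColumns <- function(ratios, direction) {
  direction <- match.arg(direction, c("up", "down"))
  n <- nrow(ratios)
  if (n < 2L) stop("rank product needs at least 2 genes")
  apply(ratios, 2, function(col) {
    if (direction == "up") rank(-col, ties.method = "average")
    else rank(col, ties.method = "average")
  })
}

#' Per-gene rank product statistic
#'
#' Within each ratio column, genes are ranked by fold change (direction
#' `"up"`: the largest ratio gets rank 1; `"down"`: the smallest), with
#' average ranks on ties. The statistic is the geometric mean of a gene's
#' ranks across columns, so a small value marks consistently extreme
#' regulation.
#'
#' @param ratios genes x K ratio matrix from [pairwiseRatioMatrix()].
#' @param direction `"up"` or `"down"`.
#' @return numeric vector of rank products, in `[1, n_genes]`.
#' @export
rankProductStatistic <- function(ratios, direction = c("up", "down")) {
  ratios <- as.matrix(ratios)
  if (ncol(ratios) < 1L) stop("ratio matrix needs at least one column")
  r <- rankColumns(ratios, match.arg(direction))
  # K-th root of the rank product; exact for K = 1 (the rank itself)
  out <- apply(r, 1, prod)^(1 / ncol(r))
  names(out) <- rownames(ratios)
  out
}

#' Permutation significance of observed rank products
#'
#' For each permutation the rank values within every column are
#' independently shuffled and the rank product recomputed for all genes.
#' The p-value pools the permuted statistics over genes and permutations:
#' `p_g = (1 + #\{permuted rp <= rp_g\}) / (1 + n_permutations * n_genes)`
#' (the add-one form keeps p strictly positive). The percentage of false
#' positives at gene g's position is `pfp_g = p_g * n_genes / rank(rp_g)`.
#'
#' @param ratios ratio matrix the observed statistics came from.
#' @param rp observed rank products from [rankProductStatistic()] on the
#'   same matrix and direction.
#' @param direction `"up"` or `"down"`.
#' @param n_permutations number of permutations (>= 1).
#' @param seed integer seed; results are deterministic given the seed.
#' @return list with numeric vectors `p` and `pfp` (named by gene).
#' @export
permutationSignificance <- function(ratios, rp,
                                    direction = c("up", "down"),
                                    n_permutations = 1000, seed = 1) {
  ratios <- as.matrix(ratios)
  direction <- match.arg(direction)
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 1L) stop("n_permutations must be at least 1")
  n <- nrow(ratios)
  if (length(rp) != n)
    stop("'rp' must have one value per gene of the ratio matrix")
  lr <- log(rankColumns(ratios, direction))
  K <- ncol(lr)
  ## recompute the observed log statistic from the ranks: log(exp(x)) is
  ## not exact, and tied permuted values must count as <= observed
  obs <- rowMeans(lr)
  if (max(abs(exp(obs) - rp)) > 1e-8)
    stop("'rp' was not computed from this ratio matrix and direction")
  ord <- order(obs)
  obs_sorted <- obs[ord]
  counts_sorted <- numeric(n)
  ## draw permutations from the column-sorted rank values so the null
  ## stream is invariant to the gene order of the input
  lrs <- apply(lr, 2, sort)
  lrs <- matrix(lrs, nrow = n)
  withSeed(seed, {
    perm <- matrix(0, nrow = n, ncol = K)
    for (b in seq_len(n_permutations)) {
      for (k in seq_len(K)) perm[, k] <- lrs[sample.int(n), k]
      counts_sorted <- counts_sorted +
        findInterval(obs_sorted, sort(rowMeans(perm)))
    }
  })
  counts <- numeric(n)
  counts[ord] <- counts_sorted
  p <- (1 + counts) / (1 + as.numeric(n_permutations) * n)
  pos <- rank(rp, ties.method = "average")
  pfp <- p * n / pos
  names(p) <- names(pfp) <- rownames(ratios)
  list(p = p, pfp = pfp)
}

## Calibrated permutation null for the two-class pairwise-ratio design:
## random experiments are built by shuffling gene labels independently
## within each replicate array, then recomputing every pairwise ratio
## column and its ranks. Columns that share a replicate stay correlated in
## the null exactly as in the data, which keeps the pooled p-values
## uniform under no differential expression (a within-ratio-column rank
## shuffle would treat the K = nA*nB columns as independent and is
## anti-conservative for replicated designs).
arrayPermutationSignificance <- function(la, lb, obs_up, obs_down,
                                         n_permutations, seed) {
  n <- nrow(la)
  nA <- ncol(la); nB <- ncol(lb)
  K <- nA * nB
  ord_up <- order(obs_up); ord_down <- order(obs_down)
  cnt_up <- numeric(n); cnt_down <- numeric(n)
  ## shuffles draw from the sorted per-array values: same null (a shuffle
  ## of a multiset), but invariant to the gene order of the input
  la <- apply(la, 2, sort); la <- matrix(la, nrow = n)
  lb <- apply(lb, 2, sort); lb <- matrix(lb, nrow = n)
  withSeed(seed, {
    rk <- matrix(0, nrow = n, ncol = K)
    for (b in seq_len(n_permutations)) {
      pa <- lapply(seq_len(nA), function(i) la[sample.int(n), i])
      pb <- lapply(seq_len(nB), function(j) lb[sample.int(n), j])
      k <- 0L
      for (i in seq_len(nA)) for (j in seq_len(nB)) {
        k <- k + 1L
        rk[, k] <- rank(pb[[j]] - pa[[i]], ties.method = "average")
      }
      lrp_up <- rowMeans(log(rk))
      cnt_up[ord_up] <- cnt_up[ord_up] +
        findInterval(obs_up[ord_up], sort(lrp_up))
      ## down-direction ranks mirror the up ranks: n + 1 - r
      lrp_down <- rowMeans(log(n + 1 - rk))
      cnt_down[ord_down] <- cnt_down[ord_down] +
        findInterval(obs_down[ord_down], sort(lrp_down))
    }
  })
  denom <- 1 + as.numeric(n_permutations) * n
  list(p_up = (1 + cnt_up) / denom, p_down = (1 + cnt_down) / denom)
}

#' Rank Product test of one two-condition contrast
#'
#' Runs both directions of the rank-product test on all pairwise replicate
#' ratios of the contrast and attaches permutation p-values and pfp
#' estimates.
#'
#' Two permutation nulls are available. The default, `scheme = "array"`,
#' builds each random experiment by shuffling gene labels within every
#' replicate array and recomputing all pairwise ratio ranks; ratio columns
#' that share a replicate remain correlated, so the null matches the
#' dependence structure of the observed statistic and the p-values are
#' calibrated under no differential expression. `scheme = "column"`
#' shuffles rank values within each ratio column independently (see
#' [permutationSignificance()]); it is exactly enumerable on tiny
#' instances but treats the columns as independent, which is
#' anti-conservative when both conditions are replicated.
#'
#' @param a,b genes x replicates intensity matrices (condition A over B).
#' @param n_permutations permutations for significance (1000 by default).
#' @param seed integer seed; substreams are derived per direction/scheme.
#' @param floor intensity floor, shared with the M-value computation.
#' @param comparison label stored in the result.
#' @param scheme permutation null: `"array"` (calibrated, default) or
#'   `"column"` (independent within-column rank shuffles).
#' @return an [RPResult-class].
#' @examples
#' a <- matrix(c(800, 100, 120, 760, 90, 130), nrow = 3)
#' b <- matrix(c(100, 110, 100, 120, 100, 95), nrow = 3)
#' rownames(a) <- rownames(b) <- c("g1", "g2", "g3")
#' res <- rankProduct(a, b, n_permutations = 100, seed = 1)
#' rpStats(res)
#' @export
rankProduct <- function(a, b, n_permutations = 1000, seed = 1, floor = 1,
                        comparison = "A_vs_B",
                        scheme = c("array", "column")) {
  scheme <- match.arg(scheme)
  a <- as.matrix(a); b <- as.matrix(b)
  ratios <- pairwiseRatioMatrix(a, b, floor = floor)
  rp_up <- rankProductStatistic(ratios, "up")
  rp_down <- rankProductStatistic(ratios, "down")
  n <- nrow(ratios)
  if (scheme == "column") {
    sig_up <- permutationSignificance(ratios, rp_up, "up",
                                      n_permutations = n_permutations,
                                      seed = deriveSeed(seed, "rp_up"))
    sig_down <- permutationSignificance(ratios, rp_down, "down",
                                        n_permutations = n_permutations,
                                        seed = deriveSeed(seed, "rp_down"))
    p_up <- sig_up$p; pfp_up <- sig_up$pfp
    p_down <- sig_down$p; pfp_down <- sig_down$pfp
  } else {
    la <- log(floorIntensity(a, floor))
    lb <- log(floorIntensity(b, floor))
    obs_up <- rowMeans(log(rankColumns(ratios, "up")))
    obs_down <- rowMeans(log(rankColumns(ratios, "down")))
    sig <- arrayPermutationSignificance(la, lb, obs_up, obs_down,
                                        n_permutations = n_permutations,
                                        seed = deriveSeed(seed, "rp_array"))
    p_up <- sig$p_up; p_down <- sig$p_down
    pfp_up <- p_up * n / rank(rp_up, ties.method = "average")
    pfp_down <- p_down * n / rank(rp_down, ties.method = "average")
  }
  ids <- rownames(ratios)
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(ratios)))
  st <- S4Vectors::DataFrame(gene_id = ids,
                             rp_up = unname(rp_up), p_up = unname(p_up),
                             pfp_up = unname(pfp_up),
                             rp_down = unname(rp_down),
                             p_down = unname(p_down),
                             pfp_down = unname(pfp_down))
  new("RPResult", stats = st, k = ncol(ratios),
      nPermutations = as.integer(n_permutations), seed = as.integer(seed),
      comparison = comparison)
}

#' @rdname rankProduct
#' @param x an `RPResult`.
#' @export
rpStats <- function(x) {
  stopifnot(is(x, "RPResult"))
  x@stats
}

setMethod("show", "RPResult", function(object) {
  cat("RPResult '", object@comparison, "': ", nrow(object@stats),
      " genes, K=", object@k, ", ", object@nPermutations,
      " permutations\n", sep = "")
})

#' Write an RPResult as a tab-separated table
#'
#' @param x an [RPResult-class].
#' @param path output path.
#' @export
writeRPResult <- function(x, path) {
  df <- as.data.frame(rpStats(x))
  df$k <- x@k
  writeTsv(df, path)
  invisible(path)
}
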