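#' Significance thresholds of the joint DE rule
#'
#' The screening rule of the pipeline: a difference is significant when the
#' M-value is > `m_cut` or < `-m_cut` AND the rank-product significance
#' value is below `p_cut`. By default the raw permutation p-value is
#' thresholded; `threshold_on = "pfp"` thresholds the estimated percentage
#' of false positives instead (both readings of an "RP value < 0.01" rule
#' are supported; the p-value is the default).
#'
#' @param m_cut positive M-value cutoff (default 1, i.e. 2-fold).
#' @param p_cut significance cutoff in (0, 1) (default 0.01).
#' @param threshold_on `"p"` or `"pfp"`.
#' @return list of validated thresholds.
#' @export
deThresholds <- function(m_cut = 1, p_cut = 0.01,
                         threshold_on = c("p", "pfp")) {
  if (!is.numeric(m_cut) || m_cut <= 0) stop("m_cut must be positive")
  if (!is.numeric(p_cut) || p_cut <= 0 || p_cut >= 1)
    stop("p_cut must lie in (0, 1)")
  list(m_cut = m_cut, p_cut = p_cut,
       threshold_on = match.arg(threshold_on))
}

#' M-value: log2 ratio of mean expression
#'
#' @param mean_a,mean_b mean intensities of the two conditions (vectors of
#'   equal length are accepted).
#' @param floor intensity floor applied before the ratio.
#' @return `log2(mean_a / mean_b)` after flooring.
#' @examples
#' mValue(400, 100)  # 2
#' mValue(50, 100)   # -1
#' @export
mValue <- function(mean_a, mean_b, floor = 1) {
  a <- floorIntensity(mean_a, floor)
  b <- floorIntensity(mean_b, floor)
  # the quotient is taken larger-over-smaller and signed, so that
  # m(a, b) == -m(b, a) holds exactly in floating point
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  ifelse(a >= b, 1, -1) * log2(hi / lo)
}

#' Apply the joint M-value / rank-product significance rule
#'
#' A gene is called `up` when `m > m_cut` and its up-direction significance
#' value is below `p_cut`; `down` when `m < -m_cut` and the down-direction
#' value is below `p_cut`; otherwise `ns`. Exactly one call per gene.
#'
#' @param rp an [RPResult-class] for the comparison.
#' @param mean_a,mean_b named numeric vectors of condition means over the
#'   same genes as `rp` (names are checked).
#' @param thresholds see [deThresholds()].
#' @param floor intensity floor shared with the ratio computation.
#' @param comparison label; defaults to the one stored in `rp`.
#' @return a [DETable-class].
#' @export
callDE <- function(rp, mean_a, mean_b, thresholds = deThresholds(),
                   floor = 1, comparison = NULL) {
  stopifnot(is(rp, "RPResult"))
  st <- rpStats(rp)
  ids <- st$gene_id
  if (!is.null(names(mean_a))) {
    if (!setequal(names(mean_a), ids))
      stop("gene sets of rank-product result and condition means differ")
    mean_a <- mean_a[ids]
    mean_b <- mean_b[ids]
  } else if (length(mean_a) != length(ids)) {
    stop("gene sets of rank-product result and condition means differ")
  }
  m <- mValue(mean_a, mean_b, floor = floor)
  sig_up <- if (thresholds$threshold_on == "pfp") st$pfp_up else st$p_up
  sig_down <- if (thresholds$threshold_on == "pfp") st$pfp_down else st$p_down
  call <- rep("ns", length(ids))
  call[m > thresholds$m_cut & sig_up < thresholds$p_cut] <- "up"
  call[m < -thresholds$m_cut & sig_down < thresholds$p_cut] <- "down"
  tb <- S4Vectors::DataFrame(gene_id = ids, mean_a = unname(mean_a),
                             mean_b = unname(mean_b), m = unname(m),
                             p_up = st$p_up, p_down = st$p_down,
                             call = call)
  new("DETable", table = tb, thresholds = thresholds,
      comparison = if (is.null(comparison)) rp@comparison else comparison)
}

#' @rdname callDE
#' @param x a `DETable`.
#' @export
deCalls <- function(x) {
  stopifnot(is(x, "DETable"))
  setNames(x@table$call, x@table$gene_id)
}

#' @rdname callDE
#' @export
deTable <- function(x) {
  stopifnot(is(x, "DETable"))
  x@table
}

#' Genes called regulated in a DETable
#'
#' @param x a [DETable-class].
#' @param direction `"up"`, `"down"` or `"both"`.
#' @return character vector of gene identifiers.
#' @export
regulatedGenes <- function(x, direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  calls <- deCalls(x)
  keep <- if (direction == "both") calls != "ns" else calls == direction
  names(calls)[keep]
}

setMethod("show", "DETable", function(object) {
  calls <- table(factor(object@table$call, levels = c("up", "down", "ns")))
  cat("DETable '", object@comparison, "': ", nrow(object@table),
      " genes (", calls[["up"]], " up, ", calls[["down"]], " down)\n",
      sep = "")
})

#' Write a DETable as tab-separated text
#'
#' @param x a [DETable-class].
#' @param path output path.
#' @export
writeDETable <- function(x, path) {
  df <- as.data.frame(deTable(x))
  df <- cbind(gene_id = df$gene_id, comparison = x@comparison,
              df[, setdiff(colnames(df), "gene_id")])
  writeTsv(df, path)
  invisible(path)
}

#' Run the rank-product DE test for one comparison of a dataset
#'
#' Convenience wrapper: extracts the replicate columns of two conditions,
#' runs [rankProduct()], computes condition means and applies [callDE()].
#'
#' @param x an [ExpressionDataset-class].
#' @param a,b condition labels (see [conditionLabels()]); `a` is the
#'   numerator of the ratio, so `up` means higher in `a`.
#' @param n_permutations,seed,floor passed to [rankProduct()].
#' @param thresholds see [deThresholds()].
#' @return list with elements `rp` ([RPResult-class]) and `de`
#'   ([DETable-class]).
#' @export
runComparison <- function(x, a, b, n_permutations = 1000, seed = 1,
                          thresholds = deThresholds(), floor = 1) {
  ma <- conditionColumns(x, a)
  mb <- conditionColumns(x, b)
  label <- paste0(a, "_vs_", b)
  rp <- rankProduct(ma, mb, n_permutations = n_permutations,
                    seed = deriveSeed(seed, label), floor = floor,
                    comparison = label)
  de <- callDE(rp, setNames(rowMeans(ma), rownames(ma)),
               setNames(rowMeans(mb), rownames(mb)),
               thresholds = thresholds, floor = floor)
  list(rp = rp, de = de)
}

#' Standard comparisons of the rooting time-course design
#'
#' Enumerates the contrasts the analysis is built on: every stem-base
#' timepoint against the pre-excision stem base (0 hpe), consecutive
#' stem-base timepoints, wounded vs fresh leaves (the wound-response
#' contrast), and root vs stem base at 0 hpe (organ contrast).
#'
#' @param x an [ExpressionDataset-class].
#' @return data.frame with columns `comparison`, `a`, `b`, `type`.
#' @export
standardComparisons <- function(x) {
  labs <- conditionLabels(x)
  tp <- stemTimepoints(x)
  out <- data.frame(a = character(0), b = character(0), type = character(0),
                    stringsAsFactors = FALSE)
  if (length(tp) >= 2)
    out <- rbind(out,
      data.frame(a = paste0("sb_", tp[-1]), b = "sb_0",
                 type = "vs_baseline", stringsAsFactors = FALSE),
      data.frame(a = paste0("sb_", tp[-1][-1]),
                 b = paste0("sb_", tp[-1][-length(tp[-1])]),
                 type = "consecutive", stringsAsFactors = FALSE))
  if (all(c("leaf_wounded", "leaf_fresh") %in% labs))
    out <- rbind(out, data.frame(a = "leaf_wounded", b = "leaf_fresh",
                                 type = "wound", stringsAsFactors = FALSE))
  if (all(c("root", "sb_0") %in% labs))
    out <- rbind(out, data.frame(a = "root", b = "sb_0", type = "organ",
                                 stringsAsFactors = FALSE))
  out$comparison <- paste0(out$a, "_vs_", out$b)
  out[, c("comparison", "a", "b", "type")]
}

#' Relative expression from qPCR cycle thresholds
#'
#' `2^-(ct_target - ct_reference)`: the relative expression of a target
#' gene normalized to a reference gene, from their PCR cycle-threshold
#' values.
#'
#' @param ct_target,ct_reference finite CT values (cycles); vectorized.
#' @return relative expression, strictly positive.
#' @examples
#' qpcrRelativeExpression(25, 25)  # 1
#' qpcrRelativeExpression(26, 25)  # 0.5
#' @export
qpcrRelativeExpression <- function(ct_target, ct_reference) {
  if (any(!is.finite(ct_target)) || any(!is.finite(ct_reference)))
    stop("CT values must be finite")
  2^(-(ct_target - ct_reference))
}
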