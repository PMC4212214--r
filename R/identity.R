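#' Wound-regulated genes from the leaf contrast
#'
#' Genes called up or down between wounded and fresh leaves; subtracted
#' from the stem-base regulated sets to isolate wound-independent,
#' rooting-specific regulation.
#'
#' @param de a [DETable-class] for the wounded-vs-fresh leaf comparison.
#' @return a [GeneSet-class] named `"wound_regulated"` with the thresholds
#'   recorded in its provenance.
#' @export
woundRegulatedGenes <- function(de) {
  stopifnot(is(de, "DETable"))
  geneSet("wound_regulated", regulatedGenes(de, "both"),
          provenance = list(comparison = de@comparison,
                            m_cut = de@thresholds$m_cut,
                            p_cut = de@thresholds$p_cut,
                            threshold_on = de@thresholds$threshold_on))
}

#' Subtract a wound-response set from a regulated set
#'
#' Set difference `ar_set \ wound_set`; the provenance chains both parents.
#' Idempotent: subtracting the same wound set again changes nothing.
#'
#' @param ar_set a [GeneSet-class] of regulated genes.
#' @param wound_set a [GeneSet-class] to remove.
#' @return a [GeneSet-class].
#' @export
subtractWound <- function(ar_set, wound_set) {
  stopifnot(is(ar_set, "GeneSet"), is(wound_set, "GeneSet"))
  geneSet(paste0(ar_set@name, "_minus_", wound_set@name),
          setdiff(ar_set@genes, wound_set@genes),
          provenance = c(ar_set@provenance,
                         list(subtracted = wound_set@name,
                              subtracted_n = length(wound_set@genes))))
}

#' Organ-identity genes of one organ
#'
#' A gene is organ-specific when it is significantly higher (per the joint
#' M-value / rank-product rule) in the focal organ than in *each* of the
#' other two organs, and its mean intensity in the focal organ exceeds the
#' absolute expression cutoff. The organs compared are the stem base before
#' excision (`sb_0`), fresh leaf and root.
#'
#' @param x an [ExpressionDataset-class] containing all three organs.
#' @param organ `"stem_base"`, `"root"` or `"leaf_fresh"`.
#' @param thresholds see [deThresholds()].
#' @param cutoff absolute expression cutoff (default 500).
#' @param n_permutations,seed,floor passed to the rank-product test.
#' @return a [GeneSet-class] (e.g. `"stem_base_identity"`).
#' @export
organSpecificGenes <- function(x, organ = c("stem_base", "root",
                                            "leaf_fresh"),
                               thresholds = deThresholds(), cutoff = 500,
                               n_permutations = 1000, seed = 1, floor = 1) {
  organ <- match.arg(organ)
  organ_conds <- c(stem_base = "sb_0", leaf_fresh = "leaf_fresh",
                   root = "root")
  missing <- setdiff(organ_conds, conditionLabels(x))
  if (length(missing))
    stop(sprintf("organ condition(s) absent from dataset: %s",
                 paste(missing, collapse = ", ")))
  focal <- organ_conds[[organ]]
  others <- setdiff(unname(organ_conds), focal)
  keep <- NULL
  for (o in others) {
    res <- runComparison(x, focal, o, n_permutations = n_permutations,
                         seed = deriveSeed(seed, paste0("organ_", o)),
                         thresholds = thresholds, floor = floor)
    up <- regulatedGenes(res$de, "up")
    keep <- if (is.null(keep)) up else intersect(keep, up)
  }
  means <- rowMeans(conditionColumns(x, focal))
  keep <- keep[means[keep] > cutoff]
  geneSet(paste0(organ, "_identity"), keep,
          provenance = list(organ = organ, cutoff = cutoff,
                            m_cut = thresholds$m_cut,
                            p_cut = thresholds$p_cut,
                            rule = "higher than each other organ"))
}

#' Identity-shift table across the time course
#'
#' For every stem-base timepoint `t > 0`: the number of genes regulated
#' versus the pre-excision stem base (all, and minus the wound set), the
#' number of stem-base identity genes whose mean at `t` has dropped below
#' the cutoff (repressed), and the number of root-identity genes whose mean
#' at `t` exceeds the cutoff (expressed). The table quantifies the loss of
#' stem identity and gain of root identity in the rooting zone.
#'
#' @param x an [ExpressionDataset-class].
#' @param stem_set,root_set organ-identity [GeneSet-class]es.
#' @param wound_set wound-response [GeneSet-class] to subtract.
#' @param de_list named list of [DETable-class]es for the baseline
#'   comparisons (`"sb_<t>_vs_sb_0"`), one per timepoint > 0.
#' @param cutoff absolute expression cutoff (default 500).
#' @return data.frame with columns `hpe`, `n_ar_regulated`,
#'   `n_ar_minus_wound`, `n_stem_repressed`, `n_root_expressed`.
#' @export
identityShiftTable <- function(x, stem_set, root_set, wound_set, de_list,
                               cutoff = 500) {
  tp <- stemTimepoints(x)
  tp <- tp[tp > 0]
  if (length(tp) < 1L) stop("dataset has no post-excision stem-base timepoint")
  means <- conditionMeans(x)
  rows <- lapply(tp, function(t) {
    key <- sprintf("sb_%s_vs_sb_0", format(t, trim = TRUE))
    if (!key %in% names(de_list))
      stop(sprintf("DE table for comparison '%s' is missing", key))
    reg <- regulatedGenes(de_list[[key]], "both")
    col <- paste0("sb_", t)
    data.frame(
      hpe = t,
      n_ar_regulated = length(reg),
      n_ar_minus_wound = length(setdiff(reg, wound_set@genes)),
      n_stem_repressed = sum(means[stem_set@genes, col] < cutoff),
      n_root_expressed = sum(means[root_set@genes, col] > cutoff))
  })
  do.call(rbind, rows)
}

#' Interval of the largest stem-to-root identity shift
#'
#' Finds the consecutive timepoint pair of an identity-shift table with the
#' largest summed absolute change in the stem-repressed and root-expressed
#' counts; ties go to the earlier interval.
#'
#' @param tbl data.frame from [identityShiftTable()].
#' @return list with `from`, `to` (hpe) and `shift` (the summed change).
#' @export
largestShiftInterval <- function(tbl) {
  if (nrow(tbl) < 2L)
    stop("at least 2 timepoints are needed to find a shift interval")
  tbl <- tbl[order(tbl$hpe), ]
  d <- abs(diff(tbl$n_stem_repressed)) + abs(diff(tbl$n_root_expressed))
  i <- which.max(d)  # which.max takes the first maximum: earlier interval
  list(from = tbl$hpe[i], to = tbl$hpe[i + 1L], shift = d[i])
}
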