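#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' ExpressionDataset: a time-course intensity matrix with its sample design
#'
#' Container for a genes x samples matrix of normalized fluorescence
#' intensities together with the sample design (tissue, hours post-excision,
#' replicate). Extends [SummarizedExperiment::SummarizedExperiment]; the
#' single assay is named `"intensity"` and the design lives in `colData`.
#'
#' Intensities are kept on the absolute scale of the input: the organ-identity
#' analysis uses an absolute expression cutoff (500 by default) that is only
#' meaningful on that scale, so no re-normalization is ever applied.
#'
#' @slot ... see [SummarizedExperiment::SummarizedExperiment].
#' @seealso [ExpressionDataset()], [conditionMeans()], [sampleDesign()]
#' @exportClass ExpressionDataset
setClass("ExpressionDataset", contains = "SummarizedExperiment")

setValidity("ExpressionDataset", function(object) {
  msg <- character()
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    return("assay 'intensity' is missing")
  v <- SummarizedExperiment::assay(object, "intensity")
  ids <- rownames(object)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msg <- c(msg, "gene identifiers (rownames) must be present and non-empty")
  else if (anyDuplicated(ids))
    msg <- c(msg, sprintf("duplicate gene identifiers: %s",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  if (!is.numeric(v) || any(!is.finite(v)))
    msg <- c(msg, "intensities must be finite numbers")
  else if (any(v < 0))
    msg <- c(msg, "intensities must be non-negative")
  cd <- SummarizedExperiment::colData(object)
  need <- c("tissue", "hpe", "replicate")
  if (!all(need %in% colnames(cd)))
    return(c(msg, sprintf("colData must contain columns: %s",
                          paste(need, collapse = ", "))))
  tissue <- as.character(cd$tissue)
  if (!all(tissue %in% TISSUES))
    msg <- c(msg, sprintf("unknown tissue value(s): %s",
                          paste(setdiff(unique(tissue), TISSUES), collapse = ", ")))
  hpe <- cd$hpe
  if (any(tissue == "stem_base" & (is.na(hpe) | hpe < 0)))
    msg <- c(msg, "stem_base samples need a non-negative hpe")
  key <- paste(tissue, hpe, cd$replicate)
  if (anyDuplicated(key))
    msg <- c(msg, "duplicate (tissue, hpe, replicate) sample triples")
  cond <- paste(tissue, hpe)
  if (any(table(cond) < 2L))
    msg <- c(msg, "every (tissue, hpe) condition needs at least 2 replicates")
  if (length(msg)) msg else TRUE
})

#' RPResult: per-gene Rank Product statistics for one comparison
#'
#' Holds, for every gene, the up- and down-direction rank-product statistic
#' (geometric mean of fold-change ranks across all pairwise replicate
#' ratios), the pooled permutation p-value and the estimated percentage of
#' false positives (pfp) at the gene's rank position.
#'
#' @slot stats a [S4Vectors::DataFrame] with columns `gene_id`, `rp_up`,
#'   `p_up`, `pfp_up`, `rp_down`, `p_down`, `pfp_down`.
#' @slot k integer, number of pairwise ratio columns (nA * nB).
#' @slot nPermutations integer, permutations used for significance.
#' @slot seed integer seed that produced the permutation stream.
#' @slot comparison label of the comparison, e.g. `"sb_24_vs_sb_0"`.
#' @exportClass RPResult
setClass("RPResult",
         representation(stats = "DataFrame", k = "integer",
                        nPermutations = "integer", seed = "integer",
                        comparison = "character"))

setValidity("RPResult", function(object) {
  st <- object@stats
  need <- c("gene_id", "rp_up", "p_up", "pfp_up", "rp_down", "p_down",
            "pfp_down")
  if (!all(need %in% colnames(st)))
    return(sprintf("stats must contain columns: %s", paste(need, collapse = ", ")))
  for (p in c("p_up", "p_down"))
    if (any(st[[p]] <= 0 | st[[p]] > 1)) return(sprintf("%s must lie in (0, 1]", p))
  if (any(st$rp_up < 1) || any(st$rp_down < 1))
    return("rank products must be >= 1")
  TRUE
})

#' DETable: per-gene M-values and significance calls for one comparison
#'
#' The joint significance rule of the pipeline: a gene is called `up` when
#' its M-value (log2 ratio of condition means) exceeds `m_cut` and its
#' up-direction permutation p-value (or pfp, depending on `threshold_on`)
#' is below `p_cut`; symmetrically for `down`; otherwise `ns`.
#'
#' @slot table a [S4Vectors::DataFrame] with columns `gene_id`, `mean_a`,
#'   `mean_b`, `m`, `p_up`, `p_down`, `call`.
#' @slot thresholds list with `m_cut`, `p_cut`, `threshold_on`.
#' @slot comparison comparison label (`"<condA>_vs_<condB>"`).
#' @exportClass DETable
setClass("DETable",
         representation(table = "DataFrame", thresholds = "list",
                        comparison = "character"))

setValidity("DETable", function(object) {
  tb <- object@table
  need <- c("gene_id", "mean_a", "mean_b", "m", "p_up", "p_down", "call")
  if (!all(need %in% colnames(tb)))
    return(sprintf("table must contain columns: %s", paste(need, collapse = ", ")))
  if (!all(tb$call %in% c("up", "down", "ns")))
    return("call must be one of up/down/ns")
  th <- object@thresholds
  if (!all(c("m_cut", "p_cut") %in% names(th)))
    return("thresholds must contain m_cut and p_cut")
  if (th$m_cut <= 0) return("m_cut must be positive")
  if (th$p_cut <= 0 || th$p_cut >= 1) return("p_cut must lie in (0, 1)")
  TRUE
})

#' GeneSet: a named gene collection with provenance
#'
#' A plain set of gene identifiers plus a structured record of the
#' comparison and thresholds that produced it (so that e.g. a wound-response
#' set remembers which leaf contrast and which cutoffs defined it).
#'
#' @slot name short label of the set.
#' @slot genes character vector of unique gene identifiers.
#' @slot provenance named list describing how the set was derived.
#' @exportClass GeneSet
setClass("GeneSet",
         representation(name = "character", genes = "character",
                        provenance = "list"))

setValidity("GeneSet", function(object) {
  if (length(object@name) != 1L) return("name must be a single string")
  if (anyDuplicated(object@genes)) return("gene identifiers must be unique")
  TRUE
})

#' SimulationConfig: parameters of the synthetic time-course generator
#'
#' Describes a cutting experiment: stem-base samples over a time course
#' (hours post-excision), fresh and wounded leaves, and a developed root,
#' with planted differential expression, wound-shared genes, organ-identity
#' trajectories and functional-category enrichment. See [simulationConfig()]
#' for field semantics and defaults.
#'
#' @exportClass SimulationConfig
setClass("SimulationConfig",
         representation(n_genes = "integer", timepoints_hpe = "numeric",
                        replicates = "integer", baseline_log_mean = "numeric",
                        baseline_log_sd = "numeric", noise_cv = "numeric",
                        n_de_per_comparison = "integer", de_fold = "numeric",
                        de_frac_up = "numeric", frac_wound_shared = "numeric",
                        n_stem_identity = "integer", n_root_identity = "integer",
                        identity_high = "numeric", identity_low = "numeric",
                        stem_decay_hpe = "numeric", root_rise_hpe = "numeric",
                        category_plan = "data.frame", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@n_genes < 10L) msg <- c(msg, "n_genes must be at least 10")
  tp <- object@timepoints_hpe
  if (length(tp) < 2L || tp[1] != 0 || is.unsorted(tp, strictly = TRUE))
    msg <- c(msg, "timepoints_hpe must start at 0 and increase strictly")
  if (object@replicates < 2L) msg <- c(msg, "replicates must be >= 2")
  if (object@de_fold <= 1) msg <- c(msg, "de_fold must exceed 1")
  if (object@noise_cv < 0) msg <- c(msg, "noise_cv must be non-negative")
  for (f in c("de_frac_up", "frac_wound_shared")) {
    v <- slot(object, f)
    if (v < 0 || v > 1) msg <- c(msg, sprintf("%s must lie in [0, 1]", f))
  }
  if (!(object@identity_high > 500 && object@identity_low < 500))
    msg <- c(msg, "identity_high must exceed 500 and identity_low must be below 500")
  planted <- object@n_stem_identity + object@n_root_identity +
    object@n_de_per_comparison * (length(tp) - 1L)
  if (planted > object@n_genes)
    msg <- c(msg, "planted gene counts exceed n_genes")
  cp <- object@category_plan
  need <- c("code", "name", "hormone", "size", "ratio_up")
  if (!all(need %in% colnames(cp)))
    msg <- c(msg, sprintf("category_plan must have columns: %s",
                          paste(need, collapse = ", ")))
  else {
    if (!all(cp$hormone %in% HORMONES))
      msg <- c(msg, "unknown hormone in category_plan")
    if (sum(cp$size) > object@n_genes)
      msg <- c(msg, "category_plan sizes exceed n_genes")
    if (any(cp$ratio_up < 0)) msg <- c(msg, "ratio_up must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticTruth: planted ground truth of a generated dataset
#'
#' @slot de_genes named list, one entry per baseline comparison
#'   (`"sb_<t>_vs_sb_0"`) and for `"leaf_wounded_vs_leaf_fresh"`, each a
#'   list with `up` and `down` gene-id vectors.
#' @slot wound_genes genes planted as wound-responsive (shared between the
#'   leaf contrast and the early stem-base comparisons).
#' @slot stem_identity data.frame `gene_id`, `decay_hpe`: stem-base identity
#'   genes and the timepoint at which their mean steps below the cutoff.
#' @slot root_identity data.frame `gene_id`, `rise_hpe`.
#' @slot enriched_categories named numeric of planted up-direction
#'   enrichment ratios per category code.
#' @slot condition_means genes x conditions matrix of true (noise-free)
#'   condition means, from which the truth of any contrast is derivable.
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
         representation(de_genes = "list", wound_genes = "character",
                        stem_identity = "data.frame",
                        root_identity = "data.frame",
                        enriched_categories = "numeric",
                        condition_means = "matrix"))
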