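#' Construct an ExpressionDataset
#'
#' @param values numeric matrix of normalized intensities with gene
#'   identifiers as rownames (or supplied via `gene_ids`), one column per
#'   sample. Values are arbitrary fluorescence units on an absolute scale
#'   where ~500 marks meaningful expression.
#' @param design data.frame with one row per column of `values`, columns
#'   `sample_id`, `tissue` (one of `stem_base`, `leaf_fresh`,
#'   `leaf_wounded`, `root`), `hpe` (hours post-excision; `NA` for root)
#'   and `replicate`. Column order of `values` must follow `design`.
#' @param gene_ids optional character vector of gene identifiers,
#'   overriding rownames of `values`.
#' @return an [ExpressionDataset-class] object.
#' @examples
#' m <- matrix(100 * (1:12), nrow = 3,
#'             dimnames = list(c("g1", "g2", "g3"), NULL))
#' d <- data.frame(sample_id = paste0("s", 1:4),
#'                 tissue = rep(c("stem_base", "root"), each = 2),
#'                 hpe = c(0, 0, NA, NA), replicate = c(1, 2, 1, 2))
#' eds <- ExpressionDataset(m, d)
#' conditionLabels(eds)
#' @export
ExpressionDataset <- function(values, design, gene_ids = NULL) {
  values <- as.matrix(values)
  if (!is.null(gene_ids)) rownames(values) <- gene_ids
  design <- as.data.frame(design, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(design))
    design$sample_id <- paste0("s", seq_len(nrow(design)))
  if (nrow(design) != ncol(values))
    stop(sprintf("design has %d rows but matrix has %d sample columns",
                 nrow(design), ncol(values)))
  design$tissue <- as.character(design$tissue)
  design$hpe <- suppressWarnings(as.numeric(design$hpe))
  design$replicate <- as.integer(design$replicate)
  colnames(values) <- design$sample_id
  cd <- S4Vectors::DataFrame(design, row.names = design$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = values), colData = cd)
  new("ExpressionDataset", se)
}

#' @rdname ExpressionDataset
#' @param x an `ExpressionDataset`.
#' @export
intensities <- function(x) {
  stopifnot(is(x, "ExpressionDataset"))
  SummarizedExperiment::assay(x, "intensity")
}

#' @rdname ExpressionDataset
#' @export
sampleDesign <- function(x) {
  stopifnot(is(x, "ExpressionDataset"))
  as.data.frame(SummarizedExperiment::colData(x))[,
    c("sample_id", "tissue", "hpe", "replicate")]
}

#' @rdname ExpressionDataset
#' @export
geneIds <- function(x) {
  if (is(x, "GeneSet")) return(x@genes)
  rownames(x)
}

## condition label: stem_base keyed by timepoint, other organs by tissue
conditionOf <- function(design) {
  ifelse(design$tissue == "stem_base",
         paste0("sb_", design$hpe), design$tissue)
}

#' Condition labels of a dataset
#'
#' Samples are grouped into conditions by tissue, with stem-base samples
#' further keyed by their timepoint: `"sb_<hpe>"`, `"leaf_fresh"`,
#' `"leaf_wounded"`, `"root"`. Comparisons throughout the package are
#' expressed in these labels.
#'
#' @param x an [ExpressionDataset-class].
#' @return character vector of unique condition labels, in design order.
#' @export
conditionLabels <- function(x) {
  unique(conditionOf(sampleDesign(x)))
}

#' Replicate columns of one condition
#'
#' @param x an [ExpressionDataset-class].
#' @param condition a condition label, see [conditionLabels()].
#' @return intensity sub-matrix of the condition's replicate columns.
#' @export
conditionColumns <- function(x, condition) {
  labs <- conditionOf(sampleDesign(x))
  if (!condition %in% labs)
    stop(sprintf("condition '%s' not present in the dataset", condition))
  intensities(x)[, labs == condition, drop = FALSE]
}

#' Per-condition mean expression
#'
#' Arithmetic mean of replicate intensities per condition, the quantity on
#' which M-values and the absolute expression cutoff operate.
#'
#' @param x an [ExpressionDataset-class].
#' @return genes x conditions matrix of replicate means.
#' @export
conditionMeans <- function(x) {
  labs <- conditionOf(sampleDesign(x))
  v <- intensities(x)
  out <- vapply(unique(labs),
                function(l) rowMeans(v[, labs == l, drop = FALSE]),
                numeric(nrow(v)))
  rownames(out) <- rownames(v)
  out
}

#' Stem-base timepoints of a dataset
#'
#' @param x an [ExpressionDataset-class].
#' @return sorted numeric vector of hours post-excision with stem-base
#'   samples.
#' @export
stemTimepoints <- function(x) {
  d <- sampleDesign(x)
  sort(unique(d$hpe[d$tissue == "stem_base"]))
}

setMethod("show", "ExpressionDataset", function(object) {
  d <- sampleDesign(object)
  cat("ExpressionDataset:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  conditions:", paste(conditionLabels(object), collapse = ", "), "\n")
  reps <- table(conditionOf(d))
  cat("  replicates per condition:", paste(range(reps), collapse = "-"), "\n")
})
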