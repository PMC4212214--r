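#' Read an expression matrix and its sample design
#'
#' The matrix file is tab-separated with a header row of sample identifiers
#' and a first column of gene identifiers. The design file is tab-separated
#' with columns `sample_id`, `tissue`, `hpe`, `replicate`. Columns of the
#' returned dataset follow design-file order.
#'
#' @param path path to the expression matrix.
#' @param design_path path to the sample design table.
#' @return an [ExpressionDataset-class].
#' @export
readExpression <- function(path, design_path) {
  raw <- readTsv(path)
  if (ncol(raw) < 2L) stop("expression matrix needs gene ids plus samples")
  ids <- as.character(raw[[1]])
  if (anyDuplicated(ids))
    stop(sprintf("duplicate gene identifiers in '%s': %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  vals <- raw[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- suppressWarnings(as.numeric(vals[[j]]))
    bad <- which(is.na(col) | !is.finite(col) | col < 0)
    if (length(bad))
      stop(sprintf(
        "invalid intensity '%s' at gene '%s' (row %d), sample '%s'",
        as.character(vals[[j]][bad[1]]), ids[bad[1]], bad[1],
        colnames(vals)[j]))
    vals[[j]] <- col
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  design <- readTsv(design_path)
  need <- c("sample_id", "tissue", "hpe", "replicate")
  if (!all(need %in% colnames(design)))
    stop(sprintf("design must have columns: %s", paste(need, collapse = ", ")))
  missing_in_matrix <- setdiff(design$sample_id, colnames(m))
  if (length(missing_in_matrix))
    stop(sprintf("sample(s) in design but not in matrix: %s",
                 paste(missing_in_matrix, collapse = ", ")))
  extra_in_matrix <- setdiff(colnames(m), design$sample_id)
  if (length(extra_in_matrix))
    stop(sprintf("sample(s) in matrix but not in design: %s",
                 paste(extra_in_matrix, collapse = ", ")))
  ExpressionDataset(m[, design$sample_id, drop = FALSE], design)
}

#' Write an ExpressionDataset to tab-separated files
#'
#' Inverse of [readExpression()]: `readExpression(path, design_path)` on the
#' written files reproduces the dataset.
#'
#' @param x an [ExpressionDataset-class].
#' @param path output path for the matrix.
#' @param design_path output path for the design table.
#' @return the matrix path, invisibly.
#' @export
writeExpression <- function(x, path, design_path) {
  m <- intensities(x)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  writeTsv(df, path)
  writeTsv(sampleDesign(x), design_path)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-separated with columns `gene_id`, `category_code`, `category_name`,
#' `hormone_category`. Every gene carries exactly one functional category;
#' the hormone category is `"none"` for genes outside the phytohormone
#' classes. Exact duplicate rows are dropped silently; a gene annotated
#' twice with different content is an error.
#'
#' @param path path to the annotation file.
#' @return data.frame with one row per gene.
#' @export
readAnnotation <- function(path) {
  ann <- readTsv(path)
  need <- c("gene_id", "category_code", "category_name", "hormone_category")
  if (!all(need %in% colnames(ann)))
    stop(sprintf("annotation must have columns: %s",
                 paste(need, collapse = ", ")))
  ann <- unique(ann[, need])
  dup <- ann$gene_id[duplicated(ann$gene_id)]
  if (length(dup))
    stop(sprintf("gene(s) annotated with conflicting categories: %s",
                 paste(unique(dup), collapse = ", ")))
  bad <- setdiff(unique(ann$hormone_category), HORMONES)
  if (length(bad))
    stop(sprintf("unknown hormone_category value(s): %s (expected one of %s)",
                 paste(bad, collapse = ", "), paste(HORMONES, collapse = ", ")))
  rownames(ann) <- NULL
  ann
}

#' @rdname readAnnotation
#' @param ann annotation data.frame as returned by [readAnnotation()].
#' @export
writeAnnotation <- function(ann, path) {
  writeTsv(ann, path)
  invisible(path)
}

escapeField <- function(x) {
  gsub("\n", "\\\\n", gsub("\t", "\\\\t", gsub("\\\\", "\\\\\\\\", x)))
}
unescapeField <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- strsplit(x[i], "", fixed = TRUE)[[1]]
    res <- character(0); j <- 1
    while (j <= length(s)) {
      if (s[j] == "\\" && j < length(s)) {
        res <- c(res, switch(s[j + 1], t = "\t", n = "\n", "\\" = "\\",
                             paste0("\\", s[j + 1])))
        j <- j + 2
      } else { res <- c(res, s[j]); j <- j + 1 }
    }
    out[i] <- paste(res, collapse = "")
  }
  out
}

#' Write / read a gene set as a plain-text list
#'
#' One gene identifier per line, preceded by header comments carrying the
#' set name and its provenance (`# key<TAB-escaped>=value`). Reading a
#' written file reproduces the set exactly.
#'
#' @param set a [GeneSet-class].
#' @param path output path.
#' @return `writeGeneSet`: the path, invisibly; `readGeneSet`: a
#'   [GeneSet-class].
#' @export
writeGeneSet <- function(set, path) {
  stopifnot(is(set, "GeneSet"))
  hdr <- c(paste0("# name=", escapeField(set@name)),
           vapply(names(set@provenance), function(k)
             paste0("# ", escapeField(k), "=",
                    escapeField(as.character(set@provenance[[k]]))),
             character(1)))
  writeLines(c(hdr, set@genes), path)
  invisible(path)
}

#' @rdname writeGeneSet
#' @export
readGeneSet <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^# ?", lines)
  meta <- sub("^# ?", "", lines[hdr])
  kv <- regmatches(meta, regexpr("=", meta), invert = TRUE)
  keys <- unescapeField(vapply(kv, `[`, character(1), 1))
  vals <- unescapeField(vapply(kv, function(x)
    if (length(x) > 1) x[2] else "", character(1)))
  name <- if ("name" %in% keys) vals[keys == "name"][1] else "gene_set"
  prov <- as.list(vals[keys != "name"])
  names(prov) <- keys[keys != "name"]
  genes <- lines[!hdr]
  genes <- genes[genes != ""]
  geneSet(name, genes, prov)
}
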