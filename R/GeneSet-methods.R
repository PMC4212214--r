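#' Construct a GeneSet
#'
#' @param name short label for the set.
#' @param genes character vector of gene identifiers (deduplicated,
#'   order preserved).
#' @param provenance named list recording how the set was derived
#'   (comparison, thresholds, parent sets, ...).
#' @return a [GeneSet-class].
#' @export
geneSet <- function(name, genes = character(), provenance = list()) {
  new("GeneSet", name = as.character(name),
      genes = unique(as.character(genes)), provenance = provenance)
}

#' @rdname geneSet
#' @param x a `GeneSet`.
#' @export
provenance <- function(x) {
  stopifnot(is(x, "GeneSet"))
  x@provenance
}

#' @rdname geneSet
#' @export
setMethod("length", "GeneSet", function(x) length(x@genes))

setMethod("show", "GeneSet", function(object) {
  cat("GeneSet '", object@name, "': ", length(object@genes), " genes\n",
      sep = "")
  if (length(object@provenance))
    cat("  provenance:", paste(names(object@provenance), collapse = ", "),
        "\n")
})
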