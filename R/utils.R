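#' @importFrom stats rnorm setNames sd
#' @importFrom utils read.delim write.table packageVersion
NULL

TISSUES <- c("stem_base", "leaf_fresh", "leaf_wounded", "root")

HORMONES <- c("auxin", "ethylene", "jasmonate", "abscisic_acid",
              "gibberellin", "cytokinin", "brassinosteroid",
              "salicylic_acid", "none")

#' Floor intensities before ratio computation
#'
#' Raw intensities below `floor` are clamped to `floor` so that ratios and
#' log-ratios stay finite. The default of 1 is on the normalized absolute
#' fluorescence scale of the input data.
#'
#' @param x numeric vector or matrix of intensities.
#' @param floor positive lower bound applied before ratios.
#' @return `x` with all values below `floor` replaced by `floor`.
#' @export
floorIntensity <- function(x, floor = 1) {
  if (!is.numeric(floor) || length(floor) != 1L || !is.finite(floor))
    stop("'floor' must be a single finite number")
  out <- pmax(x, floor)
  if (any(out <= 0))
    stop("non-positive intensity remains after flooring; use floor > 0")
  out
}

## Deterministic per-stage seed derivation from one master seed.
## Keeps derived seeds inside 32-bit integer range.
deriveSeed <- function(seed, stage) {
  offs <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 7919 + offs * 104729) %% 2147483587)
}

## Run an expression with a local RNG state so package functions are
## reproducible from their 'seed' argument without clobbering the caller's
## random stream.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE)
  invisible(path)
}

readTsv <- function(path) {
  read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
             stringsAsFactors = FALSE, comment.char = "")
}
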