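#' Relative representation of a category among regulated genes
#'
#' The ratio of the category's share among regulated genes to its share
#' among all genes:
#' `(n_xp / n_xt) / (n_ap / n_at)`, where `n_xp` is the number of up- (or
#' down-) regulated genes of the category, `n_xt` the number of all genes
#' in the category, `n_ap` the number of all up- (or down-) regulated
#' genes, and `n_at` the number of all genes. A value of 1 means the
#' category is regulated exactly in proportion to its size.
#'
#' @param n_xp regulated genes in the category.
#' @param n_xt all genes in the category (> 0).
#' @param n_ap all regulated genes (> 0).
#' @param n_at all genes (> 0).
#' @return the representation ratio (>= 0).
#' @examples
#' representationRatio(20, 100, 1000, 10000)  # 2
#' @export
representationRatio <- function(n_xp, n_xt, n_ap, n_at) {
  if (any(n_at <= 0)) stop("n_at (number of all genes) must be positive")
  if (any(n_xt <= 0)) stop("n_xt (category size) must be positive")
  if (any(n_ap <= 0)) stop("n_ap (number of regulated genes) must be positive")
  if (any(n_xp < 0) || any(n_xp > pmin(n_xt, n_ap)))
    stop("n_xp must lie in [0, min(n_xt, n_ap)]")
  (n_xp / n_xt) / (n_ap / n_at)
}

#' Category over/under-representation profile of one comparison
#'
#' For every functional category and each direction (up, down), counts the
#' regulated genes of the category and computes the representation ratio
#' and its log2 (the category M-value). A category is flagged `over` when
#' the ratio reaches `fold_criterion` (2 by default, i.e. twice the number
#' of regulated genes expected by chance) and `under` when it falls below
#' `1 / fold_criterion`. Categories with fewer than `min_category_size`
#' genes are marked excluded (too small for a reliable ratio) and carry no
#' flag. A ratio of 0 gives `m = -Inf`, with the raw counts retained.
#'
#' @param de a [DETable-class].
#' @param annotation data.frame as [readAnnotation()]; genes of the
#'   comparison without an annotation row are allowed.
#' @param min_category_size smallest category size that is evaluated.
#' @param fold_criterion fold threshold for the over/under flags.
#' @param universe `"all"` counts unannotated genes in the totals (they are
#'   genes and can be regulated); `"annotated"` restricts the universe to
#'   annotated genes.
#' @param by annotation column to group by: `"category_code"` or
#'   `"hormone_category"`.
#' @return data.frame with one row per (category, direction): columns
#'   `category`, `direction`, `n_xp`, `n_xt`, `n_ap`, `n_at`, `ratio`, `m`,
#'   `flag`, `excluded`.
#' @export
categoryProfile <- function(de, annotation, min_category_size = 10,
                            fold_criterion = 2,
                            universe = c("all", "annotated"),
                            by = c("category_code", "hormone_category")) {
  stopifnot(is(de, "DETable"))
  universe <- match.arg(universe)
  by <- match.arg(by)
  if (is.null(annotation) || nrow(annotation) == 0)
    stop("annotation is empty")
  calls <- deCalls(de)
  genes <- names(calls)
  ann <- annotation[annotation$gene_id %in% genes, ]
  if (by == "hormone_category") ann <- ann[ann$hormone_category != "none", ]
  if (universe == "annotated") {
    keep <- genes %in% annotation$gene_id
    calls <- calls[keep]
    genes <- genes[keep]
  }
  n_at <- length(genes)
  cat_of <- setNames(ann[[by]], ann$gene_id)
  cats <- sort(unique(ann[[by]]))
  out <- list()
  for (direction in c("up", "down")) {
    n_ap <- sum(calls == direction)
    for (cc in cats) {
      members <- names(cat_of)[cat_of == cc]
      n_xt <- length(members)
      n_xp <- sum(calls[members] == direction)
      excluded <- n_xt < min_category_size
      if (n_ap == 0) {
        ratio <- NA_real_; m <- NA_real_; flag <- "none"
        excluded <- TRUE
      } else {
        ratio <- representationRatio(n_xp, n_xt, n_ap, n_at)
        m <- log2(ratio)
        flag <- if (excluded) "none"
                else if (ratio >= fold_criterion) "over"
                else if (ratio <= 1 / fold_criterion) "under"
                else "none"
      }
      out[[length(out) + 1L]] <- data.frame(
        category = cc, direction = direction, n_xp = n_xp, n_xt = n_xt,
        n_ap = n_ap, n_at = n_at, ratio = ratio, m = m, flag = flag,
        excluded = excluded, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hormone-category representation across the time course
#'
#' Category M-values (log2 representation ratio) for every phytohormone
#' category, per comparison and direction — the per-hormone time-course
#' profile of regulated genes. Small hormone categories (below
#' `min_category_size`) are excluded at every timepoint.
#'
#' @param de_list named list of [DETable-class]es, typically the baseline
#'   comparisons plus the root-vs-stem-base contrast.
#' @param annotation data.frame as [readAnnotation()]; needs at least one
#'   gene with a hormone category.
#' @param min_category_size,fold_criterion,universe see
#'   [categoryProfile()].
#' @return long data.frame: `comparison`, `category` (hormone),
#'   `direction`, counts, `ratio`, `m`, `flag`, `excluded`.
#' @export
hormoneTimecourse <- function(de_list, annotation, min_category_size = 10,
                              fold_criterion = 2,
                              universe = c("all", "annotated")) {
  universe <- match.arg(universe)
  if (is.null(annotation) || all(annotation$hormone_category == "none"))
    stop("annotation carries no hormone categories")
  out <- lapply(names(de_list), function(nm) {
    prof <- categoryProfile(de_list[[nm]], annotation,
                            min_category_size = min_category_size,
                            fold_criterion = fold_criterion,
                            universe = universe, by = "hormone_category")
    cbind(comparison = nm, prof, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
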