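# Fluorescence-signal granularity: coefficient of variation of pixel
# intensities within a traced cytoplasm region.

#' Coefficient of variation of masked pixel intensities
#'
#' Population standard deviation (divisor n, not n - 1; the difference is
#' negligible for masks of >= 100 pixels) of the intensities inside the
#' mask, divided by their mean. A perfectly uniform signal gives CV = 0;
#' signal concentrated in granules gives a high CV. CV is invariant to
#' uniform intensity scaling but not to additive offsets — background
#' subtraction, if wanted, is up to the caller.
#'
#' @param masked_image a `masked_image` list (`image`, `mask`, `label`), or
#'   a numeric matrix together with `mask`.
#' @param mask logical matrix when `masked_image` is a plain matrix.
#' @return the CV (>= 0).
#' @examples
#' img <- matrix(7, 20, 20)
#' cell_cv(img, matrix(TRUE, 20, 20))   # 0
#' @export
cell_cv <- function(masked_image, mask = NULL) {
  if (inherits(masked_image, "masked_image") || is.list(masked_image)) {
    img <- masked_image$image
    mask <- masked_image$mask
  } else img <- masked_image
  stopifnot(is.matrix(img), is.logical(mask), all(dim(img) == dim(mask)))
  v <- img[mask]
  if (length(v) < 1L) stop("empty mask")
  if (any(!is.finite(v)) || any(v < 0)) stop("intensities must be finite and nonnegative")
  mu <- mean(v)
  if (mu <= 0) stop("masked mean intensity is zero; CV undefined")
  sqrt(mean((v - mu)^2)) / mu
}

#' Per-group granularity summary over many cells
#'
#' Computes the CV of every cell and summarises per group (mean, SD, n).
#' Groups with fewer than `min_cells` cells are excluded with a warning.
#' An optional two-tailed t-test compares a designated pair of groups.
#'
#' @param cells list of `masked_image` objects (each with a `label`).
#' @param min_cells minimum cells per group (default 5).
#' @param test_pair optional character vector of two group labels to
#'   compare with a two-tailed t-test.
#' @return list with `cells` (data.frame `cell`, `label`, `cv` — the
#'   scatter-plot export), `groups` (data.frame `label`, `n`, `mean_cv`,
#'   `sd_cv`) and, when requested, `test` (htest).
#' @export
group_granularity <- function(cells, min_cells = 5L, test_pair = NULL) {
  cv <- vapply(cells, cell_cv, 0)
  lab <- vapply(cells, function(c) c$label, "")
  df <- data.frame(cell = seq_along(cells), label = lab, cv = cv,
                   stringsAsFactors = FALSE)
  sizes <- table(df$label)
  small <- names(sizes)[sizes < min_cells]
  if (length(small)) {
    warning("group(s) below ", min_cells, " cells excluded: ",
            paste(small, collapse = ", "))
    df <- df[!df$label %in% small, , drop = FALSE]
  }
  if (length(unique(df$label)) < 2L) {
    stop("need >= 2 groups with at least ", min_cells, " cells")
  }
  groups <- do.call(rbind, lapply(split(df, df$label), function(g) {
    data.frame(label = g$label[1L], n = nrow(g), mean_cv = mean(g$cv),
               sd_cv = sd(g$cv), stringsAsFactors = FALSE)
  }))
  rownames(groups) <- NULL
  out <- list(cells = df, groups = groups)
  if (!is.null(test_pair)) {
    stopifnot(length(test_pair) == 2L, all(test_pair %in% df$label))
    out$test <- t.test(df$cv[df$label == test_pair[1L]],
                       df$cv[df$label == test_pair[2L]])
  }
  out
}

#' Write per-cell granularity results to TSV
#'
#' @param result output of [group_granularity()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_granularity_tsv <- function(result, path) {
  write.table(result$cells, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
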