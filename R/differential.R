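# Condition comparisons across replicate libraries: miRNA normalisation,
# percent-change estimates and two-tailed t-tests with significance tiers.

#' Normalise raw counts to the library's miRNA content
#'
#' Reads per million miRNA reads: `raw * 1e6 / mirna_total`. Scale-free in
#' the sequencing depth, since the miRNA denominator scales with it.
#'
#' @param raw_counts numeric vector of raw counts.
#' @param mirna_total total miRNA count of the same library (> 0).
#' @return normalised counts.
#' @examples
#' normalize_library(50, 2e6)   # 25
#' @export
normalize_library <- function(raw_counts, mirna_total) {
  if (length(mirna_total) != 1L || is.na(mirna_total) || mirna_total <= 0) {
    stop("mirna_total must be a single positive number; library unusable")
  }
  raw_counts * 1e6 / mirna_total
}

#' Build a condition table from per-library category counts
#'
#' Assembles the long-format table that [compare_conditions()] consumes:
#' one row per (category, strand, condition, replicate) with
#' miRNA-normalised counts.
#'
#' @param count_tables list of data.frames from [count_by_category()], one
#'   per library.
#' @param conditions,replicates character/integer vectors parallel to
#'   `count_tables`.
#' @return a `condition_table` data.frame with columns `category`, `strand`,
#'   `condition`, `replicate`, `value`.
#' @export
condition_table <- function(count_tables, conditions, replicates) {
  stopifnot(length(count_tables) == length(conditions),
            length(count_tables) == length(replicates))
  rows <- lapply(seq_along(count_tables), function(i) {
    cc <- count_tables[[i]]
    mt <- cc$count[cc$category == "mirna"]
    if (length(mt) != 1L || mt <= 0) {
      stop("library ", i, " has no usable miRNA total")
    }
    sel <- cc[cc$category != "mirna", , drop = FALSE]
    data.frame(category = sel$category, strand = sel$strand,
               condition = conditions[i], replicate = replicates[i],
               value = normalize_library(sel$count, mt),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("condition_table", "data.frame")
  out
}

star_tier <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**",
                                  ifelse(p < 0.05, "*", "ns")))
}

#' Compare knockdown versus control across replicates
#'
#' For every (category, strand) row: means and SDs per condition, the
#' percent reduction `100 * (1 - mean_kd / mean_control)` (negative values
#' denote an increase) and a two-tailed two-sample t-test. The
#' equal-variance Student test is the default; Welch is available via
#' `var_equal = FALSE`. When both groups have zero variance the p-value is
#' 1 for equal means and a 0 sentinel (with a warning) otherwise. No
#' multiple-testing correction is applied across rows (per-row significance
#' tiers are reported); set `adjust = "BH"` for Benjamini-Hochberg.
#'
#' @param tab a `condition_table` from [condition_table()] (long format).
#' @param control,treatment condition labels.
#' @param var_equal use the pooled-variance Student t-test (default TRUE).
#' @param adjust `"none"` (default) or `"BH"`.
#' @return data.frame with columns `category`, `strand`, `mean_control`,
#'   `mean_kd`, `sd_control`, `sd_kd`, `percent_reduction`, `p_value`,
#'   `stars`.
#' @export
compare_conditions <- function(tab, control = "control",
                               treatment = "knockdown", var_equal = TRUE,
                               adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  stopifnot(all(c(control, treatment) %in% tab$condition))
  keys <- unique(tab[, c("category", "strand")])
  res <- lapply(seq_len(nrow(keys)), function(i) {
    sel <- tab[tab$category == keys$category[i] & tab$strand == keys$strand[i], ]
    x <- sel$value[sel$condition == control]
    y <- sel$value[sel$condition == treatment]
    if (length(x) < 2L || length(y) < 2L) {
      stop("need >= 2 replicates per condition for ",
           keys$category[i], "/", keys$strand[i])
    }
    if (sd(x) == 0 && sd(y) == 0) {
      p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else {
        warning("zero variance with unequal means: p = 0 sentinel for ",
                keys$category[i], "/", keys$strand[i])
        0
      }
    } else {
      p <- t.test(x, y, var.equal = var_equal)$p.value
    }
    data.frame(category = keys$category[i], strand = keys$strand[i],
               mean_control = mean(x), mean_kd = mean(y),
               sd_control = sd(x), sd_kd = sd(y),
               percent_reduction = 100 * (1 - mean(y) / mean(x)),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (adjust == "BH") out$p_value <- stats::p.adjust(out$p_value, "BH")
  out$stars <- star_tier(out$p_value)
  rownames(out) <- NULL
  out
}

#' Fold-change matrix relative to a control column
#'
#' Divides every cell by its row's control value, as in expression heat maps
#' normalised to a control sample. Rows with a nonpositive control value are
#' excluded and reported in the `excluded` attribute.
#'
#' @param expression_table numeric matrix or data.frame (genes x samples).
#' @param control_column name or index of the control column.
#' @param log2 return log2 ratios instead of ratios.
#' @return matrix of relative changes (control column all 1, or 0 on the
#'   log2 scale), with attribute `excluded` naming dropped rows.
#' @examples
#' m <- matrix(c(2, 4, 1, 8), 2, dimnames = list(c("g1", "g2"), c("ctl", "s")))
#' fold_change_heatmap(m, "ctl")
#' @export
fold_change_heatmap <- function(expression_table, control_column,
                                log2 = FALSE) {
  m <- as.matrix(expression_table)
  ctl <- m[, control_column]
  bad <- !is.finite(ctl) | ctl <= 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with nonpositive control value excluded")
  }
  out <- sweep(m[!bad, , drop = FALSE], 1L, ctl[!bad], "/")
  if (log2) out <- base::log2(out)
  attr(out, "excluded") <- rownames(m)[bad]
  out
}
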