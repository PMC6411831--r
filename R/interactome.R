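# LFQ bait-vs-control interactome enrichment: left-censored imputation,
# per-protein t-tests, permutation-based FDR, volcano classification.

#' Impute left-censored missing LFQ values
#'
#' Standard downshifted-Gaussian imputation: missing cells of each sample
#' are drawn from a normal centred `shift_sd` sample-SDs below that sample's
#' observed mean, with SD `width_sd` times the sample SD. This models values
#' missing because they fall below the detection limit.
#'
#' @param matrix an `lfq_matrix` (log2 scale, `NA` = missing).
#' @param shift_sd downshift in sample SDs (default 1.8).
#' @param width_sd imputation width in sample SDs (default 0.3).
#' @param seed integer seed.
#' @return the matrix with missing cells filled; the original missingness
#'   mask is kept in the `imputed_mask` attribute.
#' @export
impute_missing <- function(matrix, shift_sd = 1.8, width_sd = 0.3, seed = 1L) {
  x <- matrix
  mask <- is.na(x)
  if (!any(mask)) {
    attr(x, "imputed_mask") <- mask
    return(x)
  }
  set.seed(derive_seed(seed, "impute"))
  for (j in seq_len(ncol(x))) {
    obs <- x[!mask[, j], j]
    if (length(obs) == 0L) stop("sample ", colnames(x)[j], " is all-missing")
    if (length(obs) < 10L) {
      stop("sample ", colnames(x)[j], " has fewer than 10 observed values")
    }
    n_miss <- sum(mask[, j])
    if (n_miss > 0L) {
      x[mask[, j], j] <- rnorm(n_miss, mean(obs) - shift_sd * sd(obs),
                               width_sd * sd(obs))
    }
  }
  attr(x, "imputed_mask") <- mask
  x
}

# Vectorised two-sample Student t statistics for every row of a matrix.
row_tstats <- function(x, g1, g2) {
  moments <- function(g) {
    xs <- x[, g, drop = FALSE]
    n <- rowSums(!is.na(xs))
    m <- rowMeans(xs, na.rm = TRUE)
    # row variance via sums of squared deviations from the row mean
    v <- rowSums((xs - m)^2, na.rm = TRUE) / (n - 1)
    list(n = n, m = m, v = v)
  }
  a <- moments(g1); b <- moments(g2)
  sp2 <- ((a$n - 1) * a$v + (b$n - 1) * b$v) / (a$n + b$n - 2)
  t <- (a$m - b$m) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  list(t = t, df = a$n + b$n - 2, n1 = a$n, n2 = b$n, diff = a$m - b$m)
}

#' Permutation-FDR t-tests for bait-vs-control enrichment
#'
#' Per-protein two-sample Student t-tests with a permutation-based false
#' discovery rate: the null distribution is built by relabelling samples
#' (exhaustively when the number of distinct relabelings is at most 100 —
#' for 3v3 that is the 20 ways of choosing the bait triplet — otherwise by
#' `n_permutations` random relabelings). The q-value of a protein is the
#' mean number of permuted |t| values at least as extreme as its observed
#' |t|, divided by the observed count at that threshold, clipped to [0, 1]
#' and monotonised so that q never decreases as |t| decreases.
#'
#' @param matrix an `lfq_matrix` (ideally after [impute_missing()]).
#' @param groups factor of sample groups; defaults to the matrix's `groups`
#'   attribute.
#' @param n_permutations random relabelings when exhaustive enumeration is
#'   too large (>= 100).
#' @param seed integer seed for random relabelings.
#' @return data.frame with `protein`, `log2_fc` (bait minus control mean),
#'   `t`, `p_value` (Student reference distribution), `neg_log10_p`, `q`
#'   (permutation FDR), `tested` (FALSE for proteins with fewer than 2
#'   observed values per group, which are skipped).
#' @export
permutation_fdr_ttest <- function(matrix, groups = attr(matrix, "groups"),
                                  n_permutations = 250L, seed = 1L) {
  if (is.null(groups)) stop("groups must be supplied")
  groups <- as.factor(groups)
  if (nlevels(groups) != 2L) stop("exactly two groups required")
  if (n_permutations < 100L) stop("n_permutations must be >= 100")
  x <- unclass(matrix)
  attr(x, "groups") <- NULL; attr(x, "ground_truth") <- NULL
  lv <- levels(groups)
  g1 <- which(groups == lv[1L]); g2 <- which(groups == lv[2L])
  obs <- row_tstats(x, g1, g2)
  tested <- obs$n1 >= 2L & obs$n2 >= 2L & is.finite(obs$t)
  t_obs <- abs(obs$t[tested])

  n_s <- length(groups)
  all_sets <- combn(n_s, length(g1))
  if (ncol(all_sets) <= 100L) {
    perm_sets <- all_sets
  } else {
    set.seed(derive_seed(seed, "perm"))
    perm_sets <- all_sets[, sample(ncol(all_sets), n_permutations)]
  }
  # for each permutation, count exceedances of each observed |t|
  ord <- order(t_obs, decreasing = TRUE)
  t_sorted <- t_obs[ord]
  exceed_perm <- numeric(length(t_sorted))
  for (b in seq_len(ncol(perm_sets))) {
    p1 <- perm_sets[, b]
    p2 <- setdiff(seq_len(n_s), p1)
    tp <- abs(row_tstats(x, p1, p2)$t)
    tp <- sort(tp[is.finite(tp)])
    # #{ |t_perm| >= th } = n - #{ |t_perm| < th }, via a sorted scan
    exceed_perm <- exceed_perm +
      (length(tp) - findInterval(t_sorted, tp, left.open = TRUE))
  }
  mean_exceed <- exceed_perm / ncol(perm_sets)
  obs_exceed <- seq_along(t_sorted)   # observed |t| sorted decreasing
  q_sorted <- pmin(1, pmax(0, mean_exceed / obs_exceed))
  q_sorted <- cummax(q_sorted)        # monotone: q non-increasing in |t|
  q <- numeric(length(t_obs))
  q[ord] <- q_sorted

  out <- data.frame(protein = rownames(x),
                    log2_fc = obs$diff, t = obs$t,
                    p_value = NA_real_, neg_log10_p = NA_real_,
                    q = NA_real_, tested = tested,
                    stringsAsFactors = FALSE)
  p <- 2 * pt(-abs(obs$t[tested]), df = obs$df[tested])
  out$p_value[tested] <- p
  out$neg_log10_p[tested] <- -log10(p)
  out$q[tested] <- q
  rownames(out) <- NULL
  out
}

#' Classify proteins on the volcano plot
#'
#' A protein is called an interactor when it is bait-enriched and clears
#' both cutoffs strictly: `log2_fc > fc_cutoff` and `neg_log10_p >
#' p_cutoff`. Defaults follow the headline volcano rule (log2 fold change
#' > 4.3, -log10 P > 1.5). The bait protein itself, if named, is flagged
#' separately.
#'
#' @param records data.frame from [permutation_fdr_ttest()] (columns
#'   `protein`, `log2_fc`, `neg_log10_p`).
#' @param fc_cutoff,p_cutoff strict cutoffs (defaults 4.3 and 1.5).
#' @param bait optional bait protein id.
#' @return `records` with logical columns `is_interactor` and `is_bait`.
#' @examples
#' rec <- data.frame(protein = c("a", "b"), log2_fc = c(5, 4.3),
#'                   neg_log10_p = c(2, 2))
#' classify_volcano(rec)$is_interactor
#' @export
classify_volcano <- function(records, fc_cutoff = 4.3, p_cutoff = 1.5,
                             bait = NULL) {
  stopifnot(all(c("protein", "log2_fc", "neg_log10_p") %in% names(records)))
  records$is_interactor <- !is.na(records$log2_fc) &
    !is.na(records$neg_log10_p) &
    records$log2_fc > fc_cutoff & records$neg_log10_p > p_cutoff
  records$is_bait <- records$protein %in% bait
  records$is_interactor[records$is_bait] <- FALSE
  records
}
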