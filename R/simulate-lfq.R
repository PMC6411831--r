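#' Simulate a label-free quantification (LFQ) intensity matrix
#'
#' Emulates an affinity-purification mass-spectrometry experiment with
#' triplicate bait pulldowns versus triplicate control pulldowns. Background
#' proteins share a common log2-intensity distribution in both groups; true
#' interactors are shifted up by `effect_log2` in the bait columns. Values
#' are censored missing with an overall rate `missing_rate`, with the
#' missingness probability rising logistically as the underlying intensity
#' falls (left-censoring, as in real LFQ data where low-abundance peptides
#' drop below the detection limit — so control cells of true interactors go
#' missing most often).
#'
#' @param n_proteins total number of proteins.
#' @param n_true_interactors number of planted interactors (< n_proteins).
#' @param effect_log2 log2 shift of interactors in bait columns (> 0).
#' @param missing_rate overall expected fraction of missing cells in [0, 1).
#' @param seed integer seed.
#' @param n_replicates replicates per group (default 3).
#' @param baseline_mean,baseline_sd protein-level mean log2 intensity
#'   distribution.
#' @param rep_sd replicate-to-replicate log2 noise SD.
#' @return an `lfq_matrix`: numeric matrix (proteins x samples, log2 scale,
#'   `NA` = missing) with columns `bait_1..n` then `ctrl_1..n`, plus
#'   attributes `groups` (factor) and `ground_truth` (list with
#'   `interactors`, the planted protein ids).
#' @examples
#' m <- simulate_lfq_matrix(50, 5, effect_log2 = 6, missing_rate = 0, seed = 1)
#' attr(m, "ground_truth")$interactors
#' @export
simulate_lfq_matrix <- function(n_proteins, n_true_interactors, effect_log2,
                                missing_rate = 0.1, seed = 1L,
                                n_replicates = 3L,
                                baseline_mean = 25, baseline_sd = 2,
                                rep_sd = 0.5) {
  if (effect_log2 <= 0) stop("effect_log2 must be > 0")
  if (n_true_interactors >= n_proteins) {
    stop("n_true_interactors must be < n_proteins")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must lie in [0, 1)")
  }
  set.seed(derive_seed(seed, "lfq"))
  ids <- sprintf("P%04d", seq_len(n_proteins))
  interactors <- if (n_true_interactors > 0) {
    sort(sample(ids, n_true_interactors))
  } else character(0)
  base_mu <- rnorm(n_proteins, baseline_mean, baseline_sd)
  n_s <- 2L * n_replicates
  mu <- matrix(base_mu, n_proteins, n_s)
  mu[ids %in% interactors, seq_len(n_replicates)] <-
    mu[ids %in% interactors, seq_len(n_replicates)] + effect_log2
  x <- mu + matrix(rnorm(n_proteins * n_s, 0, rep_sd), n_proteins, n_s)
  dimnames(x) <- list(ids, c(sprintf("bait_%d", seq_len(n_replicates)),
                             sprintf("ctrl_%d", seq_len(n_replicates))))
  if (missing_rate > 0) {
    # logistic left-censoring: weight cells by how far below the global
    # median their true intensity lies, then scale to the target rate
    w <- plogis(-(mu - stats::median(mu)) / baseline_sd)
    p <- pmin(1, w * (missing_rate / mean(w)))
    x[matrix(runif(length(x)) < p, n_proteins, n_s)] <- NA_real_
  }
  attr(x, "groups") <- factor(rep(c("bait", "control"), each = n_replicates),
                              levels = c("bait", "control"))
  attr(x, "ground_truth") <- list(interactors = interactors,
                                  effect_log2 = effect_log2)
  class(x) <- c("lfq_matrix", class(x))
  x
}

#' Write / read an LFQ matrix as TSV
#'
#' The TSV carries a `protein` id column followed by sample columns; a
#' leading comment line records the group of each sample.
#'
#' @param x an `lfq_matrix` (or plain matrix with a `groups` attribute).
#' @param path file path.
#' @return `path` (write) or an `lfq_matrix` (read).
#' @export
write_lfq_tsv <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# groups\t",
                    paste(as.character(attr(x, "groups")), collapse = "\t")),
             con)
  df <- data.frame(protein = rownames(x), unclass(x), check.names = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_lfq_tsv
#' @export
read_lfq_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  groups <- strsplit(sub("^# groups\\t", "", first), "\t")[[1]]
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   check.names = FALSE)
  x <- as.matrix(df[, -1, drop = FALSE])
  rownames(x) <- df$protein
  attr(x, "groups") <- factor(groups, levels = c("bait", "control"))
  class(x) <- c("lfq_matrix", class(x))
  x
}
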