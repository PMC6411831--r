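# Ping-pong diagnostics: positional nucleotide bias, 5'-overlap probability
# with z-score, hotspot localisation, IP-vs-input enrichment.

#' Positional nucleotide bias matrix (1U/10A diagnostics)
#'
#' Frequency of each base at read positions 1--20, counted from each read's
#' own 5' end (never reference coordinates) and weighted by collapsed copy
#' count. T is reported as U, as small RNAs are RNA. Reads shorter than 20
#' nt contribute only to positions up to their length; positions with zero
#' coverage are zero-filled and flagged in the `uncovered` attribute rather
#' than emitted as NaN.
#'
#' @param aligned output of [align_reads()], already restricted to the reads
#'   of interest (e.g. one category, piRNA size class).
#' @param strand `"sense"` or `"antisense"`.
#' @return a 4 x 20 matrix (rows A, C, G, U) of per-position frequencies,
#'   columns summing to 1; attributes `n_reads` (weighted total) and
#'   `uncovered` (positions with no coverage).
#' @examples
#' aln <- data.frame(sequence = "AAAAAAAAAAAAAAAAAAAAAAAAA", strand = "sense",
#'                   count = 1L)
#' nucleotide_bias(aln, "sense")["A", ]
#' @export
nucleotide_bias <- function(aligned, strand = c("sense", "antisense")) {
  strand <- match.arg(strand)
  sel <- aligned[aligned$strand == strand, , drop = FALSE]
  if (nrow(sel) == 0L) stop("no reads on the ", strand,
                            " strand; nucleotide bias undefined")
  m <- matrix(0, 4L, 20L, dimnames = list(c("A", "C", "G", "U"), 1:20))
  for (k in 1:20) {
    b <- substring(sel$sequence, k, k)
    has <- b != ""
    if (!any(has)) next
    b <- chartr("T", "U", b[has])
    tab <- tapply(sel$count[has], b, sum)
    m[names(tab), k] <- tab
  }
  colsum <- colSums(m)
  uncovered <- which(colsum == 0)
  covered <- colsum > 0
  m[, covered] <- sweep(m[, covered, drop = FALSE], 2L, colsum[covered], "/")
  attr(m, "n_reads") <- sum(sel$count)
  attr(m, "uncovered") <- as.integer(uncovered)
  class(m) <- c("position_bias_matrix", class(m))
  m
}

#' 5'-overlap probability profile between opposite-strand piRNAs
#'
#' For each offset d in 1..30, sums the pair mass of sense/antisense read
#' pairs whose 5' ends satisfy `antisense_five_prime - sense_five_prime =
#' d - 1` (so d = 10 is the canonical ping-pong configuration, a 10-nt
#' overlap of 5' ends). Pair mass is the product of the two copy counts by
#' default (`weight = "product"`), or 1 per distinct pair
#' (`weight = "presence"`). Probabilities are the masses normalised to sum
#' to 1; the ping-pong z-score `z10` compares the probability at offset 10
#' with the mean and SD of all other offsets.
#'
#' The profile is computed via strand-wise 5'-position mass vectors and a
#' lagged cross-product, equivalent to (but far faster than) enumerating
#' all read pairs.
#'
#' @param sense_reads,antisense_reads aligned-read data.frames (columns
#'   `five_prime`, `count`) from the same reference.
#' @param max_offset largest offset considered (default 30, covering all
#'   read lengths).
#' @param weight `"product"` (default) or `"presence"`.
#' @return an `overlap_profile` list: `offsets`, `probability`, `mass`,
#'   `z10`. If no pair mass exists at any offset the profile is all zero
#'   and `z10` is `NA`.
#' @examples
#' s <- data.frame(five_prime = 0L, count = 1L)
#' a <- data.frame(five_prime = 9L, count = 1L)
#' overlap_probability(s, a)$probability[10]
#' @export
overlap_probability <- function(sense_reads, antisense_reads,
                                max_offset = 30L,
                                weight = c("product", "presence")) {
  weight <- match.arg(weight)
  if (nrow(sense_reads) == 0L || nrow(antisense_reads) == 0L) {
    stop("both strands must contribute reads; got ",
         nrow(sense_reads), " sense and ", nrow(antisense_reads),
         " antisense records")
  }
  if (weight == "presence") {
    sense_reads$count <- rep(1, nrow(sense_reads))
    antisense_reads$count <- rep(1, nrow(antisense_reads))
  }
  s_mass <- tapply(as.numeric(sense_reads$count), sense_reads$five_prime, sum)
  a_mass <- tapply(as.numeric(antisense_reads$count),
                   antisense_reads$five_prime, sum)
  s_pos <- as.integer(names(s_mass))
  a_pos <- as.integer(names(a_mass))
  mass <- numeric(max_offset)
  for (d in seq_len(max_offset)) {
    k <- match(s_pos + d - 1L, a_pos)
    ok <- !is.na(k)
    if (any(ok)) mass[d] <- sum(s_mass[ok] * a_mass[k[ok]])
  }
  tot <- sum(mass)
  prob <- if (tot > 0) mass / tot else mass
  z10 <- NA_real_
  if (tot > 0 && sum(mass > 0) >= 5L && 10L <= max_offset) {
    bg <- prob[-10L]
    if (sd(bg) > 0) z10 <- (prob[10L] - mean(bg)) / sd(bg)
  }
  structure(list(offsets = seq_len(max_offset), probability = prob,
                 mass = mass, z10 = z10),
            class = "overlap_profile")
}

#' @export
print.overlap_profile <- function(x, ...) {
  cat("overlap_profile: offsets 1..", length(x$offsets),
      ", peak at ", which.max(x$probability),
      " (p = ", signif(max(x$probability), 3),
      "), z10 = ", signif(x$z10, 4), "\n", sep = "")
  invisible(x)
}

#' Locate the piRNA production hotspot
#'
#' Slides a window of `window_nt` nt along the reference and returns the
#' half-open window maximising the contained 5'-end read mass, together
#' with the fraction of the strand total it contains. Ties are broken by
#' the smallest window start. A reference shorter than the window returns
#' the whole reference.
#'
#' @param aligned aligned reads on one reference and one strand (columns
#'   `five_prime`, `count`).
#' @param reference_length length of the reference in nt.
#' @param window_nt window width (default 200 nt).
#' @return list with `start`, `end` (0-based half-open) and `fraction`.
#' @export
hotspot <- function(aligned, reference_length, window_nt = 200L) {
  if (nrow(aligned) == 0L) stop("no reads supplied")
  if (length(unique(aligned$strand)) > 1L) {
    stop("hotspot expects reads from a single strand")
  }
  mass <- numeric(reference_length)
  agg <- tapply(as.numeric(aligned$count), aligned$five_prime, sum)
  mass[as.integer(names(agg)) + 1L] <- agg
  if (reference_length <= window_nt) {
    return(list(start = 0L, end = as.integer(reference_length), fraction = 1))
  }
  cs <- c(0, cumsum(mass))
  win <- cs[(window_nt + 1L):(reference_length + 1L)] -
    cs[1:(reference_length - window_nt + 1L)]
  best <- which.max(win)   # which.max takes the first maximum: smallest start
  list(start = as.integer(best - 1L),
       end = as.integer(best - 1L + window_nt),
       fraction = win[best] / sum(mass))
}

#' IP-versus-input enrichment of small RNAs, miRNA-normalised
#'
#' log2 of the miRNA-normalised IP count over the miRNA-normalised input
#' count, per (category, strand). Zero input counts give `+Inf`, zero IP
#' counts `-Inf`, both with a warning.
#'
#' @param ip_counts,input_counts data.frames from [count_by_category()]
#'   (columns `category`, `strand`, `count`) for the IP and input libraries.
#' @param mirna_ip,mirna_input miRNA totals of the two libraries (> 0).
#' @return data.frame with `category`, `strand`, `log2_enrichment`.
#' @examples
#' ip <- data.frame(category = "virus", strand = "sense", count = 800)
#' inp <- data.frame(category = "virus", strand = "sense", count = 400)
#' ip_enrichment(ip, inp, 1e6, 1e6)$log2_enrichment
#' @export
ip_enrichment <- function(ip_counts, input_counts, mirna_ip, mirna_input) {
  if (mirna_ip <= 0 || mirna_input <= 0) {
    stop("miRNA totals must be > 0 in both libraries")
  }
  key <- paste(ip_counts$category, ip_counts$strand)
  k <- match(key, paste(input_counts$category, input_counts$strand))
  if (anyNA(k)) stop("category/strand sets differ between IP and input")
  ipn <- ip_counts$count / mirna_ip
  inn <- input_counts$count[k] / mirna_input
  le <- log2(ipn / inn)
  if (any(!is.finite(le))) {
    warning("zero counts produced infinite enrichment sentinels")
  }
  data.frame(category = ip_counts$category, strand = ip_counts$strand,
             log2_enrichment = le)
}

#' Write a bias matrix or overlap profile as TSV
#'
#' @param x a `position_bias_matrix` or `overlap_profile`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_signature_tsv <- function(x, path) {
  if (inherits(x, "position_bias_matrix")) {
    df <- data.frame(base = rownames(x), unclass(x), check.names = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (inherits(x, "overlap_profile")) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("# z10\t", format(x$z10, digits = 10)), con)
    write.table(data.frame(offset = x$offsets, probability = x$probability),
                con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else stop("unsupported object")
  invisible(path)
}
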