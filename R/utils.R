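# Internal helpers shared across modules.

#' Reverse complement of DNA strings
#'
#' Thin vectorised wrapper around [Biostrings::reverseComplement()] operating
#' on plain character vectors of A/C/G/T(/N).
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @keywords internal
rc <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Derive a reproducible child seed from a parent seed and a stream label.
# Keeps the result strictly below 2^31 so set.seed() accepts it.
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (k in utf8ToInt(parts)) h <- (h * 31 + k) %% 2147483587
  as.integer(h + 1)
}

# Collapse a character vector of read sequences (with optional per-read
# counts) into a canonical collapsed-read data.frame, lexicographic order.
collapse_reads <- function(sequence, count = rep(1L, length(sequence))) {
  if (length(sequence) == 0L) {
    return(data.frame(sequence = character(0), count = integer(0),
                      stringsAsFactors = FALSE))
  }
  agg <- rowsum(as.numeric(count), sequence)   # C-level, sorted keys
  out <- data.frame(sequence = rownames(agg), count = as.integer(agg[, 1L]),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# Weighted sampling of one index per draw, vectorised.
sample_idx <- function(n, size, prob = NULL) {
  if (size == 0L) return(integer(0))
  sample.int(n, size, replace = TRUE, prob = prob)
}
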