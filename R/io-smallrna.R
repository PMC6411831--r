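#' Load small-RNA reads from FASTQ or collapsed FASTA
#'
#' Reads are collapsed to unique sequences with summed counts and returned
#' in deterministic lexicographic order. Collapsed FASTA headers follow the
#' `>id_count` convention (the integer after the final underscore is the
#' copy count). Reads shorter than 15 nt or longer than 40 nt are dropped
#' with a warning (inputs are assumed adapter-trimmed).
#'
#' @param path input file.
#' @param format `"collapsed_fasta"` or `"fastq"`.
#' @return a data.frame with columns `sequence` and `count`.
#' @examples
#' tmp <- tempfile(fileext = ".fa")
#' writeLines(c(">r1_17", "ACGTACGTACGTACGTACGTACGT"), tmp)
#' load_reads(tmp, "collapsed_fasta")
#' @export
load_reads <- function(path, format = c("collapsed_fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  xs <- tryCatch(
    Biostrings::readDNAStringSet(
      path, format = if (format == "fastq") "fastq" else "fasta"),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
  if (length(xs) == 0L) {
    warning("no reads in ", path)
    return(data.frame(sequence = character(0), count = integer(0)))
  }
  if (format == "collapsed_fasta") {
    heads <- sub("\\s.*$", "", names(xs))
    counts <- suppressWarnings(as.integer(sub("^.*_", "", heads)))
    bad <- which(is.na(counts) | counts < 1L | !grepl("_", heads))
    if (length(bad)) {
      stop("malformed collapsed FASTA header at record ", bad[1L],
           " (expected '>id_count'): ", heads[bad[1L]])
    }
  } else {
    counts <- rep(1L, length(xs))
  }
  seqs <- as.character(xs)
  len <- nchar(seqs)
  out_of_range <- len < 15L | len > 40L
  if (any(out_of_range)) {
    warning(sum(out_of_range), " read record(s) outside 15-40 nt dropped")
    seqs <- seqs[!out_of_range]
    counts <- counts[!out_of_range]
  }
  collapse_reads(seqs, counts)
}

#' Write collapsed reads to FASTA with `>id_count` headers
#'
#' @param reads data.frame with `sequence` and `count` columns.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(reads, path) {
  ids <- sprintf("r%06d_%d", seq_len(nrow(reads)), reads$count)
  xs <- Biostrings::DNAStringSet(setNames(reads$sequence, ids))
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}
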