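#' Generate a labelled synthetic reference set
#'
#' Builds the mapping targets a viral-infection small-RNA experiment needs:
#' a viral genome (`virus`), a ping-pong-processed transposon consensus
#' (`te_pingpong`), a phased-1U transposon consensus (`te_phased`), a short
#' host mRNA (`host_mrna`) and a panel of 22-nt miRNAs (`mirna_01`, ...).
#' All sequences are uniform-random DNA, deterministic in `config$seed`.
#'
#' @param config a [sim_config()] object.
#' @param n_mirnas number of distinct miRNA references (>= 10).
#' @return a `reference_set`: a data.frame with columns `id`, `category`
#'   (`virus`, `te_pingpong`, `te_phased`, `host_mrna`, `mirna`) and
#'   `sequence`.
#' @examples
#' refs <- make_references(sim_config(seed = 1, genome_length = 1000))
#' table(refs$category)
#' @export
make_references <- function(config, n_mirnas = 12L) {
  validate_sim_config(config)
  if (n_mirnas < 10L) stop("n_mirnas must be >= 10")
  set.seed(derive_seed(config$seed, "references"))
  rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
  repeat {
    ids <- c("virus", "te_pingpong", "te_phased", "host_mrna",
             sprintf("mirna_%02d", seq_len(n_mirnas)))
    seqs <- c(rand_dna(config$genome_length),
              rand_dna(4000L), rand_dna(4000L), rand_dna(400L),
              vapply(seq_len(n_mirnas), function(i) rand_dna(22L), ""))
    if (!anyDuplicated(seqs)) break
  }
  refs <- data.frame(
    id = ids,
    category = c("virus", "te_pingpong", "te_phased", "host_mrna",
                 rep("mirna", n_mirnas)),
    sequence = seqs, stringsAsFactors = FALSE)
  class(refs) <- c("reference_set", "data.frame")
  refs
}

validate_reference_set <- function(refs) {
  if (!all(c("id", "category", "sequence") %in% names(refs))) {
    stop("reference_set needs columns id, category, sequence")
  }
  if (anyDuplicated(refs$id)) stop("reference ids must be unique")
  if (any(nchar(refs$sequence) == 0L)) stop("reference sequences must be non-empty")
  if (any(grepl("[^ACGTN]", refs$sequence))) {
    stop("reference sequences must be uppercase ACGT (N allowed)")
  }
  invisible(refs)
}

#' Write a reference set (or any named sequences) to FASTA
#'
#' @param refs a `reference_set` or data.frame with `id` and `sequence`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(refs, path) {
  xs <- Biostrings::DNAStringSet(setNames(refs$sequence, refs$id))
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Read a reference set from FASTA
#'
#' Categories are recovered from the id prefix (`virus`, `te_pingpong`,
#' `te_phased`, `host_mrna`, `mirna_*`); anything else is labelled `other`.
#'
#' @param path FASTA file path.
#' @return a `reference_set` data.frame.
#' @export
read_reference_fasta <- function(path) {
  xs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(xs))
  cat_of <- function(id) {
    if (grepl("^mirna", id)) return("mirna")
    if (id %in% c("virus", "te_pingpong", "te_phased", "host_mrna")) return(id)
    "other"
  }
  refs <- data.frame(id = ids,
                     category = vapply(ids, cat_of, ""),
                     sequence = as.character(xs), stringsAsFactors = FALSE)
  rownames(refs) <- NULL
  validate_reference_set(refs)
  class(refs) <- c("reference_set", "data.frame")
  refs
}
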