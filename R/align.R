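# Read placement on reference sequences.
#
# Coordinate convention (0-based throughout): `five_prime` is the forward-
# axis coordinate of the read's 5'-most nucleotide. For a sense read this is
# the leftmost covered base; for an antisense read it is the rightmost
# covered base, so five_prime - length + 1 gives the leftmost base. All
# ping-pong offset arithmetic rests on this convention.

#' Place small-RNA reads on a reference set
#'
#' Reports every position on every reference where a read matches the
#' forward sequence (sense) or where its reverse complement matches
#' (antisense), with at most `max_mismatch` substitutions. In one-mismatch
#' mode a hit whose single mismatch falls at read position 1 or 10 is
#' rejected, so the 1U/10A signature positions are never diluted by
#' sequencing-error tolerance. A multi-mapping read contributes its full
#' count to every hit; categories are analysed independently downstream.
#' Reads containing N are discarded before alignment.
#'
#' @param reads data.frame with `sequence` and `count` (e.g. from
#'   [load_reads()] or [simulate_pingpong_library()]).
#' @param refs a `reference_set`.
#' @param max_mismatch 0 (exact, default) or 1.
#' @return data.frame of hits with columns `sequence`, `reference_id`,
#'   `category`, `strand`, `five_prime` (0-based, per the convention above),
#'   `length`, `count`, `n_mismatch`; attribute `unmapped` holds the total
#'   count of reads with no hit anywhere.
#' @examples
#' refs <- make_references(sim_config(seed = 1, genome_length = 1000))
#' rd <- data.frame(sequence = substring(refs$sequence[1], 101, 128),
#'                  count = 5L)
#' align_reads(rd, refs)[, c("strand", "five_prime", "length", "count")]
#' @export
align_reads <- function(reads, refs, max_mismatch = 0L) {
  if (!max_mismatch %in% c(0L, 1L)) stop("max_mismatch must be 0 or 1")
  validate_reference_set(refs)
  reads <- reads[!grepl("N", reads$sequence, fixed = TRUE), , drop = FALSE]
  empty <- data.frame(sequence = character(0), reference_id = character(0),
                      category = character(0), strand = character(0),
                      five_prime = integer(0), length = integer(0),
                      count = integer(0), n_mismatch = integer(0))
  if (nrow(reads) == 0L) {
    attr(empty, "unmapped") <- 0L
    return(empty)
  }
  seqs <- reads$sequence
  counts <- reads$count
  lens <- nchar(seqs)
  rc_seqs <- rc(seqs)
  hit_any <- logical(length(seqs))
  if (max_mismatch == 0L) {
    hits <- exact_hits_all(seqs, rc_seqs, lens, refs)
  } else {
    out <- list()
    for (r in seq_len(nrow(refs))) {
      h <- onemm_hits(seqs, rc_seqs, lens, refs$sequence[r])
      if (nrow(h)) { h$ref <- r; out[[length(out) + 1L]] <- h }
    }
    hits <- if (length(out)) do.call(rbind, out)
            else data.frame(read = integer(0), strand = character(0),
                            five_prime = integer(0), n_mismatch = integer(0),
                            ref = integer(0))
  }
  res <- empty
  if (nrow(hits)) {
    hit_any[hits$read] <- TRUE
    res <- data.frame(
      sequence = seqs[hits$read],
      reference_id = refs$id[hits$ref], category = refs$category[hits$ref],
      strand = hits$strand, five_prime = hits$five_prime,
      length = lens[hits$read], count = counts[hits$read],
      n_mismatch = hits$n_mismatch, stringsAsFactors = FALSE)
  }
  res <- res[order(res$reference_id, res$strand, res$five_prime, res$sequence), ,
             drop = FALSE]
  rownames(res) <- NULL
  attr(res, "unmapped") <- sum(counts[!hit_any])
  res
}

# Memoised substring tables: for a given reference set and read length L,
# one hash map from every length-L reference window to encoded
# (reference index, start) positions. Keyed by a content fingerprint so a
# modified reference set invalidates its entries.
.window_cache <- new.env(parent = emptyenv())

refset_fingerprint <- function(refs) {
  paste(refs$id, nchar(refs$sequence),
        substr(refs$sequence, 1L, 16L), collapse = ";")
}

global_pos_map <- function(refs, L, fp) {
  key <- paste(L, fp, sep = "|")
  hit <- .window_cache[[key]]
  if (!is.null(hit)) return(hit)
  enc <- integer(0)
  win <- character(0)
  for (r in seq_len(nrow(refs))) {
    Lr <- nchar(refs$sequence[r])
    if (L > Lr) next
    starts <- seq_len(Lr - L + 1L)
    win <- c(win, substring(refs$sequence[r], starts, starts + L - 1L))
    enc <- c(enc, r * 2^24 + starts)     # references stay << 16 Mb here
  }
  pos_map <- split(enc, win)
  .window_cache[[key]] <- pos_map
  pos_map
}

# Exact matching across the whole reference set at once.
exact_hits_all <- function(seqs, rc_seqs, lens, refs) {
  fp <- refset_fingerprint(refs)
  rows <- list()
  for (idx in split(seq_along(seqs), lens)) {
    L <- lens[idx[1L]]
    pos_map <- global_pos_map(refs, L, fp)
    for (pass in c("sense", "antisense")) {
      keys <- if (pass == "sense") seqs[idx] else rc_seqs[idx]
      hl <- pos_map[keys]
      nh <- lengths(hl)
      if (all(nh == 0L)) next
      read_i <- rep(idx, nh)
      enc <- unlist(hl, use.names = FALSE)
      ref_i <- enc %/% 2^24
      start1 <- enc - ref_i * 2^24
      fpos <- if (pass == "sense") start1 - 1L else start1 + L - 2L
      rows[[length(rows) + 1L]] <- data.frame(
        read = read_i, ref = ref_i, strand = pass, five_prime = fpos,
        n_mismatch = 0L, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(read = integer(0), ref = integer(0), strand = character(0),
                  five_prime = integer(0), n_mismatch = integer(0))
}

# One-mismatch matching via a vectorised position scan per read. Mismatches
# at read positions 1 and 10 disqualify a hit (exact hits always pass).
onemm_hits <- function(seqs, rc_seqs, lens, S) {
  refc <- strsplit(S, "")[[1]]
  Lr <- length(refc)
  rows <- list()
  for (i in seq_along(seqs)) {
    L <- lens[i]
    if (L > Lr) next
    starts <- seq_len(Lr - L + 1L)
    for (pass in c("sense", "antisense")) {
      q <- strsplit(if (pass == "sense") seqs[i] else rc_seqs[i], "")[[1]]
      # read position k sits at window offset k (sense) or L - k + 1
      # (antisense, because the query is the reverse complement)
      excl_k <- if (pass == "sense") c(1L, 10L) else c(L, L - 9L)
      mm <- integer(length(starts))
      excl <- logical(length(starts))
      for (k in seq_len(L)) {
        ne <- refc[starts + k - 1L] != q[k]
        mm <- mm + ne
        if (k %in% excl_k) excl <- excl | ne
      }
      ok <- which(mm == 0L | (mm == 1L & !excl))
      if (length(ok)) {
        fp <- if (pass == "sense") starts[ok] - 1L else starts[ok] + L - 2L
        rows[[length(rows) + 1L]] <- data.frame(
          read = i, strand = pass, five_prime = fp,
          n_mismatch = mm[ok], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(read = integer(0), strand = character(0),
                  five_prime = integer(0), n_mismatch = integer(0))
}

#' Export aligned reads as SAM
#'
#' Minimal SAM export: sense hits carry flag 0, antisense hits flag 16 with
#' the stored sequence reverse-complemented back to the forward strand, as
#' the SAM standard requires. The collapsed copy count is written to the
#' `XC:i` tag.
#'
#' @param aligned output of [align_reads()].
#' @param refs the `reference_set` the reads were aligned to (for `@SQ`
#'   header lines).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
export_sam <- function(aligned, refs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", refs$id, nchar(refs$sequence)), con)
  if (nrow(aligned)) {
    anti <- aligned$strand == "antisense"
    pos1 <- ifelse(anti, aligned$five_prime - aligned$length + 1L,
                   aligned$five_prime) + 1L
    seq_out <- aligned$sequence
    seq_out[anti] <- rc(seq_out[anti])
    writeLines(sprintf("r%06d\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t*\tXC:i:%d",
                       seq_len(nrow(aligned)), ifelse(anti, 16L, 0L),
                       aligned$reference_id, pos1, aligned$length,
                       seq_out, aligned$count), con)
  }
  invisible(path)
}
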