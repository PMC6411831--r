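# Independent brute-force oracles. These deliberately share no code with
# the package implementations they check.

# Quadratic position scan: try every start on every reference and strand,
# counting substitutions by direct character comparison against an index
# matrix of window positions.
brute_align <- function(reads, refs, max_mismatch = 0) {
  revcomp <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  rows <- list()
  for (r in seq_len(nrow(refs))) {
    refc <- strsplit(refs$sequence[r], "")[[1]]
    for (i in seq_len(nrow(reads))) {
      rd <- reads$sequence[i]
      if (grepl("N", rd)) next
      L <- nchar(rd)
      if (L > length(refc)) next
      starts <- 1:(length(refc) - L + 1)
      win_idx <- outer(starts, 0:(L - 1), "+")   # window x read position
      for (strand in c("sense", "antisense")) {
        q <- if (strand == "sense") rd else revcomp(rd)
        qc <- strsplit(q, "")[[1]]
        neq <- matrix(refc[win_idx] != rep(qc, each = length(starts)),
                      nrow = length(starts))
        mm <- rowSums(neq)
        keep <- which(mm <= max_mismatch)
        if (max_mismatch == 1) {
          one <- keep[mm[keep] == 1]
          if (length(one)) {
            # window offset of the single mismatch -> read position
            wp <- max.col(neq[one, , drop = FALSE], ties.method = "first")
            rp <- if (strand == "sense") wp else L - wp + 1
            keep <- setdiff(keep, one[rp %in% c(1, 10)])
          }
        }
        if (length(keep)) {
          fp <- if (strand == "sense") starts[keep] - 1
                else starts[keep] + L - 2
          rows[[length(rows) + 1]] <- data.frame(
            sequence = rd, reference_id = refs$id[r],
            strand = strand, five_prime = fp, length = L,
            count = reads$count[i], n_mismatch = mm[keep],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows)) do.call(rbind, rows)
  else data.frame(sequence = character(0), reference_id = character(0),
                  strand = character(0), five_prime = integer(0),
                  length = integer(0), count = integer(0),
                  n_mismatch = integer(0))
}

# Canonical sortable key for comparing hit sets.
hit_key <- function(df) {
  sort(sprintf("%s|%s|%s|%d|%d|%d|%d", df$sequence, df$reference_id,
               df$strand, df$five_prime, df$length, df$count, df$n_mismatch))
}

# O(n^2) pair enumeration for the 5'-overlap profile.
brute_overlap <- function(sense, antisense, max_offset = 30,
                          weight = "product") {
  mass <- numeric(max_offset)
  for (i in seq_len(nrow(sense))) {
    for (j in seq_len(nrow(antisense))) {
      d <- antisense$five_prime[j] - sense$five_prime[i] + 1
      if (d >= 1 && d <= max_offset) {
        w <- if (weight == "product") sense$count[i] * antisense$count[j] else 1
        mass[d] <- mass[d] + w
      }
    }
  }
  if (sum(mass) > 0) mass / sum(mass) else mass
}

# Random unrooted binary tree with positive branch lengths, as ape phylo.
random_additive_tree <- function(n_taxa, min_bl = 0.1, max_bl = 2) {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   br = function(n) runif(n, min_bl, max_bl))
  tr$tip.label <- sort(tr$tip.label)[sample(n_taxa)]
  tr
}
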