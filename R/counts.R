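#' Size-class definitions for small-RNA strata
#'
#' piRNAs occupy 25--30 nt and siRNAs exactly 21 nt by default; both bounds
#' are overridable.
#'
#' @param name `"piRNA"` or `"siRNA"` (or any label).
#' @param min_len,max_len inclusive length bounds in nt; defaults follow the
#'   named class.
#' @return a `size_class` list with `name`, `min_len`, `max_len`.
#' @examples
#' size_class("piRNA")
#' size_class("siRNA")
#' @export
size_class <- function(name = c("piRNA", "siRNA"), min_len = NULL,
                       max_len = NULL) {
  name <- match.arg(name)
  defaults <- list(piRNA = c(25L, 30L), siRNA = c(21L, 21L))[[name]]
  out <- list(name = name,
              min_len = if (is.null(min_len)) defaults[1] else as.integer(min_len),
              max_len = if (is.null(max_len)) defaults[2] else as.integer(max_len))
  if (out$min_len > out$max_len) stop("min_len must be <= max_len")
  class(out) <- "size_class"
  out
}

#' Per-length read-count profile for one reference category
#'
#' Sums collapsed counts per read length and strand, reporting both raw
#' counts and within-strand fractions (summing to 1 per strand).
#'
#' @param aligned output of [align_reads()].
#' @param category reference category to profile.
#' @return data.frame with columns `category`, `strand`, `length`, `count`,
#'   `fraction`; empty (with a warning) when the category has no hits.
#' @export
size_profile <- function(aligned, category) {
  sel <- aligned[aligned$category == category, , drop = FALSE]
  if (nrow(sel) == 0L) {
    warning("no aligned reads for category '", category, "'")
    return(data.frame(category = character(0), strand = character(0),
                      length = integer(0), count = numeric(0),
                      fraction = numeric(0)))
  }
  key <- sprintf("%s\t%03d", sel$strand, sel$length)
  agg <- rowsum(as.numeric(sel$count), key)
  parts <- do.call(rbind, strsplit(rownames(agg), "\t"))
  out <- data.frame(category = category, strand = parts[, 1L],
                    length = as.integer(parts[, 2L]), count = agg[, 1L])
  tot <- tapply(out$count, out$strand, sum)
  out$fraction <- out$count / as.numeric(tot[out$strand])
  rownames(out) <- NULL
  out
}

#' Count reads per (category, strand) within a size class
#'
#' Counts are weighted by collapsed-read copy numbers. The miRNA category is
#' special-cased: only sense-strand, mismatch-free, full-length matches to a
#' miRNA reference are counted (its total is the normalisation denominator
#' used downstream).
#'
#' @param aligned output of [align_reads()].
#' @param size_cls a [size_class()]; applied to all non-miRNA categories.
#' @param refs the `reference_set` (for miRNA reference lengths).
#' @return data.frame with columns `category`, `strand`, `count`, covering
#'   every (category, strand) present in `refs` (zero-filled).
#' @export
count_by_category <- function(aligned, size_cls, refs) {
  stopifnot(inherits(size_cls, "size_class"))
  cats <- unique(refs$category)
  grid <- expand.grid(category = setdiff(cats, "mirna"),
                      strand = c("sense", "antisense"),
                      stringsAsFactors = FALSE)
  if ("mirna" %in% cats) {
    grid <- rbind(grid, data.frame(category = "mirna", strand = "sense"))
  }
  grid$count <- 0
  sel <- aligned[aligned$category != "mirna" &
                 aligned$length >= size_cls$min_len &
                 aligned$length <= size_cls$max_len, , drop = FALSE]
  if (nrow(sel)) {
    agg <- rowsum(as.numeric(sel$count), paste(sel$category, sel$strand))
    k <- match(rownames(agg), paste(grid$category, grid$strand))
    grid$count[k] <- agg[, 1L]
  }
  if ("mirna" %in% cats) {
    ref_len <- setNames(nchar(refs$sequence), refs$id)
    msel <- aligned[aligned$category == "mirna" &
                    aligned$strand == "sense" &
                    aligned$n_mismatch == 0L &
                    aligned$five_prime == 0L &
                    aligned$length == ref_len[aligned$reference_id], ,
                    drop = FALSE]
    grid$count[grid$category == "mirna"] <- sum(msel$count)
  }
  rownames(grid) <- NULL
  grid
}

#' Total miRNA count of a library (normalisation denominator)
#'
#' @param aligned output of [align_reads()].
#' @param refs the `reference_set`.
#' @return the summed count of exact full-length sense miRNA matches.
#' @export
mirna_total <- function(aligned, refs) {
  cc <- count_by_category(aligned, size_class("piRNA"), refs)
  cc$count[cc$category == "mirna"]
}
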