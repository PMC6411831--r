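#' Retrieve the ground truth of a simulated object
#'
#' Every generator attaches the realized truth of its output (per-stratum
#' read totals, planted hotspot window, true interactor ids, IP sampling
#' factors, ...) as a `ground_truth` attribute; this accessor returns it.
#'
#' @param x an object produced by one of the `simulate_*` generators.
#' @return a list, or `NULL` when `x` carries no ground truth.
#' @export
ground_truth <- function(x) attr(x, "ground_truth")

#' Serialize a read library's ground truth as TSV
#'
#' @param lib a `read_library`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth_tsv <- function(lib, path) {
  gt <- ground_truth(lib)
  if (is.null(gt)) stop("object carries no ground truth")
  df <- data.frame(key = names(gt$counts), count = as.integer(gt$counts))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# hotspot\t%d\t%d", gt$hotspot[1], gt$hotspot[2]), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
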