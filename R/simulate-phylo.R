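#' Simulate a protein-domain alignment down a known tree
#'
#' Evolves alignment columns independently along a given tree under a
#' symmetric amino-acid substitution model: on a branch of length `b` each
#' site substitutes with probability `1 - exp(-rate * b)`, to one of the 19
#' other residues uniformly. Suited to short (~50-residue) domains such as
#' TUDOR domains, where fitting a richer substitution model is fragile.
#'
#' @param true_tree an [ape::phylo] object or a Newick string, >= 4 leaves,
#'   with branch lengths.
#' @param n_columns alignment length (>= 10; default 50, a typical TUDOR
#'   domain length).
#' @param substitution_rate expected substitutions per site per unit branch
#'   length.
#' @param seed integer seed.
#' @return a `domain_alignment`: named character vector of equal-length
#'   gapless sequences (leaf order randomised), with attribute `true_tree`.
#' @examples
#' tr <- ape::read.tree(text = "((A:0.3,B:0.3):0.2,(C:0.3,D:0.3):0.2);")
#' aln <- simulate_domain_alignment(tr, n_columns = 50,
#'                                  substitution_rate = 1, seed = 1)
#' nchar(aln[1])
#' @export
simulate_domain_alignment <- function(true_tree, n_columns = 50L,
                                      substitution_rate = 1, seed = 1L) {
  if (is.character(true_tree)) true_tree <- ape::read.tree(text = true_tree)
  if (!inherits(true_tree, "phylo")) stop("true_tree must be a phylo or Newick string")
  if (length(true_tree$tip.label) < 4L) stop("true_tree must have >= 4 leaves")
  if (is.null(true_tree$edge.length)) stop("true_tree must have branch lengths")
  if (n_columns < 10L) stop("n_columns must be >= 10")
  set.seed(derive_seed(seed, "domain_alignment"))
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  tr <- ape::reorder.phylo(true_tree, "cladewise")
  n_tip <- length(tr$tip.label)
  root <- n_tip + 1L
  n_node <- max(tr$edge)
  seqs <- matrix(NA_character_, n_node, n_columns)
  seqs[root, ] <- sample(aa, n_columns, replace = TRUE)
  for (e in seq_len(nrow(tr$edge))) {
    par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
    p_sub <- 1 - exp(-substitution_rate * tr$edge.length[e])
    s <- seqs[par, ]
    hit <- runif(n_columns) < p_sub
    if (any(hit)) {
      s[hit] <- vapply(s[hit], function(b) sample(setdiff(aa, b), 1L), "")
    }
    seqs[child, ] <- s
  }
  out <- apply(seqs[seq_len(n_tip), , drop = FALSE], 1L, paste, collapse = "")
  names(out) <- tr$tip.label
  out <- out[sample(n_tip)]
  attr(out, "true_tree") <- true_tree
  class(out) <- "domain_alignment"
  out
}

#' Read / write aligned FASTA as a domain alignment
#'
#' @param path aligned FASTA file.
#' @return `read_domain_alignment`: a `domain_alignment` named character
#'   vector; `write_domain_alignment`: `path`, invisibly.
#' @export
read_domain_alignment <- function(path) {
  xs <- Biostrings::readAAStringSet(path)
  out <- setNames(as.character(xs), sub("\\s.*$", "", names(xs)))
  if (length(unique(nchar(out))) != 1L) {
    stop("alignment sequences must have equal lengths")
  }
  class(out) <- "domain_alignment"
  out
}

#' @rdname read_domain_alignment
#' @param aln a `domain_alignment` or named character vector.
#' @export
write_domain_alignment <- function(aln, path) {
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(setNames(as.character(aln), names(aln))), path)
  invisible(path)
}
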