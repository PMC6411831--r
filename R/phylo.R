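# Distance-based phylogeny for protein-domain alignments: p-distances,
# Saitou-Nei neighbor joining with deterministic tie-breaking, bootstrap
# supports over bipartitions, and reciprocal-nearest-neighbor ortholog
# calling across two species.

aln_matrix <- function(alignment) {
  seqs <- as.character(alignment)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("alignment sequences must have equal lengths")
  }
  m <- do.call(rbind, strsplit(seqs, ""))
  rownames(m) <- names(alignment)
  m
}

#' Pairwise p-distance matrix from an alignment
#'
#' Proportion of mismatching residues over columns where both sequences
#' have a non-gap character (pairwise deletion — complete deletion would
#' discard too much of a ~50-residue domain). A Poisson correction
#' `-log(1 - p)` is available for multiple hits.
#'
#' @param alignment a `domain_alignment` or named character vector of
#'   equal-length aligned sequences; `-` and `.` are gaps.
#' @param model `"p"` (default) or `"poisson"`.
#' @return symmetric numeric matrix with zero diagonal.
#' @examples
#' p_distance_matrix(c(a = "AAAA", b = "AAAT"))["a", "b"]   # 0.25
#' @export
p_distance_matrix <- function(alignment, model = c("p", "poisson")) {
  model <- match.arg(model)
  m <- aln_matrix(alignment)
  n <- nrow(m)
  if (n < 2L) stop("need >= 2 sequences")
  gap <- m == "-" | m == "."
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- !gap[i, ] & !gap[j, ]
      if (!any(comp)) {
        stop("sequences ", rownames(m)[i], " and ", rownames(m)[j],
             " share no comparable columns")
      }
      p <- sum(m[i, comp] != m[j, comp]) / sum(comp)
      d[i, j] <- d[j, i] <- if (model == "poisson") {
        if (p >= 1) stop("saturated p-distance; Poisson correction undefined")
        -log(1 - p)
      } else p
    }
  }
  d
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Standard NJ agglomeration on a symmetric distance matrix with the
#' Q-criterion; ties in Q are broken by the smallest (row, column) index
#' pair, making the output deterministic on degenerate (e.g. star) inputs.
#' Negative branch-length estimates are clamped to zero and the total
#' clamped deficit is recorded in the `negative_deficit` attribute. On an
#' additive matrix the generating topology and branch lengths are recovered
#' exactly.
#'
#' @param distances symmetric numeric matrix with labelled rows, >= 4 taxa.
#' @return an unrooted [ape::phylo] tree.
#' @examples
#' tr <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
#' d <- ape::cophenetic.phylo(tr)
#' nj_tree(d)
#' @export
nj_tree <- function(distances) {
  d <- as.matrix(distances)
  n <- nrow(d)
  if (n < 4L) stop("need >= 4 taxa")
  if (max(abs(d - t(d))) > 1e-9) stop("distance matrix must be symmetric")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # active cluster node ids: tips 1..n, internal nodes numbered upward
  active <- seq_len(n)
  next_node <- n + 1L
  edges <- matrix(0L, 0L, 2L)
  lens <- numeric(0)
  deficit <- 0
  while (length(active) > 3L) {
    r <- length(active)
    rs <- rowSums(d)
    q <- (r - 2) * d - outer(rs, rs, "+")
    diag(q) <- Inf
    # smallest (row, col) pair among minima, scanning column-major with
    # i < j: order by (i, j)
    qmin <- min(q)
    cand <- which(q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    li <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lj <- d[i, j] - li
    if (li < 0) { deficit <- deficit - li; li <- 0 }
    if (lj < 0) { deficit <- deficit - lj; lj <- 0 }
    u <- next_node; next_node <- next_node + 1L
    edges <- rbind(edges, c(u, active[i]), c(u, active[j]))
    lens <- c(lens, li, lj)
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    active <- c(active[keep], u)
  }
  # final trifurcation joining the last three clusters
  u <- next_node
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  for (k in 1:3) {
    lk <- c(l1, l2, l3)[k]
    if (lk < 0) { deficit <- deficit - lk; lk <- 0 }
    edges <- rbind(edges, c(u, active[k]))
    lens <- c(lens, lk)
  }
  tree <- renumber_phylo(edges, lens, n, labels, root = u)
  attr(tree, "negative_deficit") <- deficit
  tree
}

# Rebuild edge/node numbering into ape's convention: tips 1..n, root n+1,
# internal nodes in preorder.
renumber_phylo <- function(edges, lens, n_tip, labels, root) {
  kids <- split(seq_len(nrow(edges)), edges[, 1L])
  new_id <- integer(max(edges))
  new_id[seq_len(n_tip)] <- seq_len(n_tip)
  counter <- n_tip
  edge_out <- matrix(0L, nrow(edges), 2L)
  len_out <- numeric(nrow(edges))
  k <- 0L
  visit <- function(node) {
    counter <<- counter + 1L
    new_id[node] <<- counter
    for (e in kids[[as.character(node)]]) {
      child <- edges[e, 2L]
      if (child > n_tip) visit(child)
    }
  }
  visit(root)
  emit <- function(node) {
    for (e in kids[[as.character(node)]]) {
      child <- edges[e, 2L]
      k <<- k + 1L
      edge_out[k, ] <<- c(new_id[node], new_id[child])
      len_out[k] <<- lens[e]
      if (child > n_tip) emit(child)
    }
  }
  emit(root)
  structure(list(edge = edge_out, edge.length = len_out,
                 tip.label = labels, Nnode = max(edge_out) - n_tip),
            class = "phylo", order = "cladewise")
}

# Canonical keys for the non-trivial bipartitions of an unrooted tree: for
# each internal edge, the sorted leaf set of the side not containing the
# first tip, pasted with "|".
bipartition_keys <- function(tree) {
  n_tip <- length(tree$tip.label)
  desc <- function(node) {
    out <- integer(0)
    for (child in tree$edge[tree$edge[, 1L] == node, 2L]) {
      out <- c(out, if (child <= n_tip) child else desc(child))
    }
    out
  }
  keys <- character(0)
  internal_children <- tree$edge[tree$edge[, 2L] > n_tip, 2L]
  for (node in internal_children) {
    side <- sort(tree$tip.label[desc(node)])
    if (length(side) < 2L || length(side) > n_tip - 2L) next
    other <- sort(setdiff(tree$tip.label, side))
    canon <- if (paste(side, collapse = ",") < paste(other, collapse = ","))
      side else other
    keys <- c(keys, paste(canon, collapse = "|"))
  }
  setNames(keys, internal_children)
}

#' Bootstrap supports for an NJ tree
#'
#' Resamples alignment columns with replacement to the original length,
#' recomputes distances and the NJ tree for each replicate, and scores each
#' internal edge of the original tree by the number of replicates whose
#' tree contains the same bipartition. Supports are counts out of
#' `n_bootstrap` (the conventional display filter keeps values > half the
#' replicates; filtering is left to rendering). Resampling is canonical in
#' column indices, so leaf input order does not affect the result for a
#' given seed.
#'
#' @param alignment a `domain_alignment` (or named character vector).
#' @param n_bootstrap number of replicates (default 1000).
#' @param seed integer seed.
#' @param model distance model passed to [p_distance_matrix()].
#' @return the NJ tree of the full alignment with `node.label` set to the
#'   support counts of internal nodes and a `bootstrap` attribute
#'   (data.frame of bipartition keys and supports).
#' @export
bootstrap_supports <- function(alignment, n_bootstrap = 1000L, seed = 1L,
                               model = "p") {
  seqs <- setNames(as.character(alignment), names(alignment))
  alignment <- seqs[order(names(seqs))]   # canonical leaf order
  tree <- nj_tree(p_distance_matrix(alignment, model))
  keys <- bipartition_keys(tree)
  support <- setNames(integer(length(keys)), keys)
  m <- aln_matrix(alignment)
  n_col <- ncol(m)
  set.seed(derive_seed(seed, "bootstrap"))
  for (b in seq_len(n_bootstrap)) {
    cols <- sample.int(n_col, n_col, replace = TRUE)
    mb <- m[, cols, drop = FALSE]
    ab <- setNames(apply(mb, 1L, paste, collapse = ""), rownames(m))
    tb <- nj_tree(p_distance_matrix(ab, model))
    kb <- bipartition_keys(tb)
    hit <- keys %in% kb
    support[hit] <- support[hit] + 1L
  }
  n_tip <- length(tree$tip.label)
  node_lab <- rep(NA_character_, tree$Nnode)
  node_lab[as.integer(names(keys)) - n_tip] <- as.character(support)
  tree$node.label <- node_lab
  attr(tree, "bootstrap") <- data.frame(bipartition = keys,
                                        support = as.integer(support),
                                        n_bootstrap = n_bootstrap)
  tree
}

#' Patristic distance matrix of a tree
#'
#' Sum of branch lengths along the path between every pair of leaves.
#'
#' @param tree a [ape::phylo] tree.
#' @return symmetric matrix over tip labels.
#' @export
patristic_distances <- function(tree) {
  dn <- ape::dist.nodes(tree)
  n_tip <- length(tree$tip.label)
  d <- dn[seq_len(n_tip), seq_len(n_tip)]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

#' Call one-to-one orthologs by reciprocal nearest neighbors
#'
#' For each leaf, finds its nearest cross-species leaf by patristic
#' distance; two leaves that are each other's nearest cross-species
#' neighbors form a one-to-one ortholog pair. Leaves whose nearest
#' neighbor is non-reciprocal (e.g. lineage-specific duplicates) are
#' reported unpaired with their nearest cross-species neighbor listed.
#'
#' @param tree a [ape::phylo] tree.
#' @param species_map named character vector mapping leaf id to species
#'   label (two species expected; with one species all leaves are
#'   unpaired).
#' @return list with `pairs` (data.frame `id_a`, `id_b`, `distance`) and
#'   `unpaired` (data.frame `id`, `nearest`, `distance`).
#' @export
call_orthologs <- function(tree, species_map) {
  stopifnot(all(tree$tip.label %in% names(species_map)))
  sp <- species_map[tree$tip.label]
  d <- patristic_distances(tree)
  species <- sort(unique(sp))
  nearest <- setNames(rep(NA_character_, length(tree$tip.label)),
                      tree$tip.label)
  for (leaf in tree$tip.label) {
    other <- tree$tip.label[sp != sp[leaf]]
    if (length(other)) {
      dd <- d[leaf, other]
      nearest[leaf] <- other[which.min(dd)]   # ties: first label in order
    }
  }
  paired <- character(0)
  pairs <- list()
  for (leaf in tree$tip.label) {
    mate <- nearest[leaf]
    if (!is.na(mate) && identical(nearest[[mate]], leaf) &&
        !(leaf %in% paired) && !(mate %in% paired)) {
      a <- sort(c(leaf, mate))
      pairs[[length(pairs) + 1L]] <- data.frame(
        id_a = a[1L], id_b = a[2L], distance = d[leaf, mate],
        stringsAsFactors = FALSE)
      paired <- c(paired, leaf, mate)
    }
  }
  un <- setdiff(tree$tip.label, paired)
  un_near <- unname(nearest[un])
  un_dist <- rep(NA_real_, length(un))
  has_near <- !is.na(un_near)
  if (any(has_near)) {
    un_dist[has_near] <- d[cbind(un[has_near], un_near[has_near])]
  }
  list(
    pairs = if (length(pairs)) do.call(rbind, pairs)
            else data.frame(id_a = character(0), id_b = character(0),
                            distance = numeric(0)),
    unpaired = data.frame(id = un, nearest = un_near, distance = un_dist,
                          stringsAsFactors = FALSE))
}
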