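test_that("p-distances count mismatches over comparable columns", {
  expect_equal(p_distance_matrix(c(a = "AAAA", b = "AAAT"))["a", "b"], 0.25)
  d <- p_distance_matrix(c(a = "ACGT", b = "ACGT", c = "TGCA"))
  expect_equal(unname(diag(d)), c(0, 0, 0))
  expect_equal(d["a", "b"], 0)
  expect_equal(d, t(d))
})

test_that("pairwise deletion handles gaps; zero-overlap pairs error", {
  # hand count: comparable columns exclude any gap in either sequence
  aln <- c(s1 = "AC-GTACGTAC-GTACGTAC",
           s2 = "ACTG--CGTACTGTACGAAC",
           s3 = "ACTGTACGTACTGTACGTAC",
           s4 = "TTTTTTTTTTTTTTTTTTTT",
           s5 = "ACTGTACGAACTGAACGTAC")
  d <- p_distance_matrix(aln)
  # s1 vs s2: gaps at columns 3,5,6,12 -> 16 comparable, 1 mismatch (col 18)
  expect_equal(d["s1", "s2"], 1 / 16)
  # s3 vs s5: 20 comparable, mismatches at cols 9 and 14
  expect_equal(d["s3", "s5"], 2 / 20)
  expect_error(p_distance_matrix(c(x = "AA--", y = "--AA")),
               "no comparable columns")
})

test_that("Poisson correction transforms p monotonically", {
  aln <- c(a = "AAAAAAAAAA", b = "AAAAAAAATT")
  expect_equal(p_distance_matrix(aln, model = "poisson")["a", "b"],
               -log(1 - 0.2))
})

test_that("NJ reconstructs a 4-taxon additive matrix exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)); hand distances
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(d)
  expect_s3_class(tr, "phylo")
  # topology AB|CD
  expect_equal(as.numeric(ape::dist.topo(
    tr, ape::unroot(ape::read.tree(text = "((A,B),(C,D));")))), 0)
  # branch lengths via patristic distances: must reproduce the input
  expect_equal(patristic_distances(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
  # terminal branch lengths exact
  tip_edge <- setNames(tr$edge.length[match(seq_len(4), tr$edge[, 2])],
                       tr$tip.label)
  expect_equal(unname(tip_edge[LETTERS[1:4]]), c(1, 2, 3, 4))
})

test_that("a 4-taxon star resolves deterministically with zero internal branch", {
  d <- matrix(2, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  t1 <- nj_tree(d)
  t2 <- nj_tree(d)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  internal <- t1$edge.length[t1$edge[, 2] > 4]
  expect_equal(internal, 0, tolerance = 1e-12)
  expect_error(nj_tree(matrix(c(0, 1, 2, 1, 0, 1, 1, 1, 0), 3, 3)), ">= 4")
  d_bad <- d; d_bad[1, 2] <- 5
  expect_error(nj_tree(d_bad), "symmetric")
})

test_that("NJ recovers random additive trees exactly (cross-checked vs ape)", {
  set.seed(6)
  for (i in 1:20) {
    tr0 <- random_additive_tree(sample(4:12, 1))
    d <- ape::cophenetic.phylo(tr0)
    tr <- nj_tree(d)
    expect_equal(as.numeric(ape::dist.topo(tr, tr0)), 0)
    expect_equal(patristic_distances(tr)[rownames(d), colnames(d)], d,
                 tolerance = 1e-9)
    # independent cross-check against ape's NJ implementation
    tr_ape <- ape::nj(d)
    expect_equal(as.numeric(ape::dist.topo(tr, tr_ape)), 0)
  }
})

test_that("NJ on simulated domain alignments recovers the generating topology", {
  tr0 <- ape::read.tree(text = "((A:0.25,B:0.25):0.15,(C:0.25,D:0.25):0.15);")
  ref <- ape::unroot(tr0)
  hits <- 0
  for (s in 1:20) {
    aln <- simulate_domain_alignment(tr0, n_columns = 500,
                                     substitution_rate = 1, seed = s)
    tr <- nj_tree(p_distance_matrix(aln))
    if (as.numeric(ape::dist.topo(tr, ref)) == 0) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("bootstrap gives full support to a conflict-free split and is reproducible", {
  # two cleanly separated clades: every column splits x* from y*, with a
  # couple of within-clade differences so distances are not all zero
  clade1 <- strrep("A", 30)
  clade2 <- paste0(strrep("C", 15), strrep("G", 15))
  aln <- c(x1 = clade1, x2 = clade1,
           x3 = paste0("TT", substr(clade1, 3, 30)),
           y1 = clade2, y2 = clade2,
           y3 = paste0("WW", substr(clade2, 3, 30)))
  tr <- bootstrap_supports(aln, n_bootstrap = 200, seed = 9)
  bs <- attr(tr, "bootstrap")
  sep <- grepl("^x1\\|x2\\|x3$|^y1\\|y2\\|y3$", bs$bipartition)
  expect_true(any(sep))
  expect_equal(bs$support[sep][1], 200)
  tr2 <- bootstrap_supports(aln, n_bootstrap = 200, seed = 9)
  expect_identical(attr(tr2, "bootstrap"), bs)
  # leaf input order does not change supports (same seed)
  tr3 <- bootstrap_supports(aln[c(4, 2, 6, 1, 3, 5)], n_bootstrap = 200,
                            seed = 9)
  bs3 <- attr(tr3, "bootstrap")
  expect_equal(bs3$support[match(bs$bipartition, bs3$bipartition)],
               bs$support)
})

test_that("bootstrap support tracks internal branch length in simulation", {
  tr0 <- ape::read.tree(text = paste0(
    "(((A:0.2,B:0.2):0.02,(C:0.2,D:0.2):0.1):0.05,",
    "((E:0.2,F:0.2):0.3,(G:0.2,H:0.2):0.6):0.05);"))
  aln <- simulate_domain_alignment(tr0, n_columns = 60,
                                   substitution_rate = 1, seed = 12)
  tr <- bootstrap_supports(aln, n_bootstrap = 100, seed = 12)
  bs <- attr(tr, "bootstrap")
  # planted internal branch length per recovered bipartition, keyed by the
  # same canonical rule as the implementation (lexicographically smaller
  # side string)
  canon <- function(side) {
    other <- sort(setdiff(LETTERS[1:8], side))
    if (paste(side, collapse = ",") < paste(other, collapse = ","))
      paste(side, collapse = "|") else paste(other, collapse = "|")
  }
  planted <- setNames(c(0.02, 0.1, 0.3, 0.6),
                      vapply(list(c("A", "B"), c("C", "D"),
                                  c("E", "F"), c("G", "H")), canon, ""))
  m <- match(names(planted), bs$bipartition)
  ok <- !is.na(m)
  expect_gte(sum(ok), 3)
  expect_gt(cor(planted[ok], bs$support[m[ok]], method = "spearman"), 0)
})

test_that("reciprocal nearest neighbors give one-to-one ortholog pairs", {
  tr <- ape::read.tree(text = "((a1:0.1,d1:0.1):0.5,(a2:0.1,d2:0.1):0.5);")
  sp <- c(a1 = "aegypti", a2 = "aegypti", d1 = "melanogaster",
          d2 = "melanogaster")
  oc <- call_orthologs(tr, sp)
  expect_equal(nrow(oc$pairs), 2)
  expect_setequal(paste(oc$pairs$id_a, oc$pairs$id_b),
                  c("a1 d1", "a2 d2"))
  expect_equal(nrow(oc$unpaired), 0)
})

test_that("duplications leave one copy unpaired with its nearest neighbor listed", {
  tr <- ape::read.tree(
    text = "(((a1:0.05,a2:0.1):0.2,d1:0.2):0.4,(a3:0.1,d2:0.1):0.4);")
  sp <- c(a1 = "aegypti", a2 = "aegypti", a3 = "aegypti",
          d1 = "melanogaster", d2 = "melanogaster")
  oc <- call_orthologs(tr, sp)
  # a1 and a2 both have d1 nearest; only one can be reciprocal
  expect_lte(sum(oc$pairs$id_a %in% c("a1", "a2") |
                 oc$pairs$id_b %in% c("a1", "a2")), 1)
  expect_true(any(oc$unpaired$id %in% c("a1", "a2")))
  expect_equal(unique(oc$unpaired$nearest[oc$unpaired$id %in% c("a1", "a2")]),
               "d1")
  # single-species tree: everything unpaired
  oc1 <- call_orthologs(tr, setNames(rep("aegypti", 5), names(sp)))
  expect_equal(nrow(oc1$pairs), 0)
  expect_equal(nrow(oc1$unpaired), 5)
})

test_that("ortholog calls agree with brute-force patristic arithmetic on 8 leaves", {
  nwk <- paste0("(((a1:1,d1:2):1,(a2:1,d2:1):3):1,",
                "((a3:2,d3:2):1,(a4:1,d4:10):1):1);")
  tr <- ape::read.tree(text = nwk)
  sp <- setNames(rep(c("aegypti", "melanogaster"), 4),
                 c("a1", "d1", "a2", "d2", "a3", "d3", "a4", "d4"))
  # brute force: path lengths summed by hand over the known topology
  hand <- patristic_distances(tr)
  expect_equal(hand["a1", "d1"], 3)
  expect_equal(hand["a1", "d2"], 6)
  expect_equal(hand["a4", "d4"], 11)
  expect_equal(hand["a4", "d3"], 5)
  oc <- call_orthologs(tr, sp)
  expect_true(all(c("a1 d1", "a2 d2", "a3 d3") %in%
                  paste(oc$pairs$id_a, oc$pairs$id_b)))
  # a4's nearest cross-species leaf is d3 (5 < 11), but d3 pairs
  # reciprocally with a3 (4), so a4 stays unpaired; d4's nearest is a4
  expect_true(all(c("a4", "d4") %in% oc$unpaired$id))
  expect_equal(oc$unpaired$nearest[oc$unpaired$id == "a4"], "d3")
  expect_equal(oc$unpaired$nearest[oc$unpaired$id == "d4"], "a4")
})

test_that("Newick export keeps supports in the internal-node label position", {
  clade1 <- strrep("A", 30)
  clade2 <- strrep("C", 30)
  aln <- c(p = clade1, q = clade1, r = clade2, s = clade2)
  tr <- bootstrap_supports(aln, n_bootstrap = 50, seed = 2)
  nwk <- ape::write.tree(tr)
  expect_match(nwk, "\\)50")   # full support on the separating edge
})
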