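test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(genome_length = 400), "genome_length")
  expect_error(sim_config(replicates = 1), "replicates")
  expect_error(sim_config(bias_10A = 1.2), "probabilities")
  expect_error(sim_config(knockdown_retention = list(virus_sense = -0.1)),
               "probabilities|retention")
  expect_error(
    sim_config(piRNA_length_distribution = c(`25` = 0.5, `26` = 0.4)),
    "sum to 1")
})

test_that("reference generation is deterministic and well-formed", {
  cfg <- sim_config(seed = 1, genome_length = 1000)
  refs <- make_references(cfg)
  expect_equal(nchar(refs$sequence[refs$id == "virus"]), 1000)
  expect_setequal(unique(refs$category),
                  c("virus", "te_pingpong", "te_phased", "host_mrna", "mirna"))
  mir <- refs$sequence[refs$category == "mirna"]
  expect_gte(length(mir), 10)
  expect_true(all(nchar(mir) == 22))
  expect_false(anyDuplicated(refs$sequence) > 0)

  # same seed twice -> byte-identical FASTA; different seed -> different virus
  f1 <- tempfile(); f2 <- tempfile()
  write_reference_fasta(refs, f1)
  write_reference_fasta(make_references(cfg), f2)
  expect_identical(readLines(f1), readLines(f2))
  refs2 <- make_references(sim_config(seed = 2, genome_length = 1000))
  expect_false(identical(refs$sequence[1], refs2$sequence[1]))
})

test_that("FASTA round trip preserves the reference set", {
  refs <- make_references(small_config())
  f <- tempfile(fileext = ".fa")
  write_reference_fasta(refs, f)
  back <- read_reference_fasta(f)
  expect_equal(back$id, refs$id)
  expect_equal(back$sequence, refs$sequence)
  expect_equal(back$category, refs$category)
})

test_that("library generation is deterministic and condition-checked", {
  cfg <- small_config()
  refs <- make_references(cfg)
  l1 <- simulate_pingpong_library(refs, cfg, "control", 1)
  l2 <- simulate_pingpong_library(refs, cfg, "control", 1)
  expect_identical(l1$sequence, l2$sequence)
  expect_identical(l1$count, l2$count)
  l3 <- simulate_pingpong_library(refs, cfg, "control", 2)
  expect_false(identical(l1$count, l3$count))
  expect_error(simulate_pingpong_library(refs, cfg, "dsVen", 1))
  cfg_bad <- cfg
  cfg_bad$knockdown_retention$virus_sense <- NULL
  expect_error(simulate_pingpong_library(refs, cfg_bad, "knockdown", 1),
               "virus_sense")
})

test_that("ground-truth totals equal the sums over emitted reads", {
  cfg <- small_config()
  refs <- make_references(cfg)
  for (cond in c("control", "knockdown")) {
    lib <- simulate_pingpong_library(refs, cfg, cond, 1)
    expect_identical(sum(lib$count), sum(ground_truth(lib)$counts))
  }
})

test_that("forced 10A bias places A at initiator position 10 and U at responder position 1", {
  cfg <- sim_config(seed = 5, genome_length = 3000, pingpong_pair_rate = 400,
                    bias_10A = 1, bias_1U = 1, sirna_count = 0,
                    mirna_count = 0, n_sites = 100)
  refs <- make_references(cfg)
  lib <- simulate_pingpong_library(refs, cfg, "control", 1)
  aln <- align_reads(lib, refs, 0)
  vs <- aln[aln$category == "virus" & aln$strand == "sense", ]
  va <- aln[aln$category == "virus" & aln$strand == "antisense", ]
  expect_true(all(substring(vs$sequence, 10, 10) == "A"))
  expect_true(all(substring(va$sequence, 1, 1) == "T"))
})

test_that("knockdown retention scales expected counts (Poisson sampling)", {
  cfg <- sim_config(seed = 31, genome_length = 3000,
                    pingpong_pair_rate = 10000, sirna_count = 100,
                    mirna_count = 1000)
  refs <- make_references(cfg)
  n_rep <- 50
  counts <- vapply(seq_len(n_rep), function(i) {
    gt <- ground_truth(simulate_pingpong_library(refs, cfg, "knockdown", i))
    gt$counts[["virus_sense"]]
  }, 0)
  expected <- 10000 * cfg$knockdown_retention$virus_sense   # 2500
  se <- sd(counts) / sqrt(n_rep)
  expect_lt(abs(mean(counts) - expected), 3 * se + 1e-9)
})

test_that("siRNA reads are 21-nt duplexes without ping-pong overlap", {
  cfg <- small_config()
  refs <- make_references(cfg)
  lib <- simulate_pingpong_library(refs, cfg, "control", 1)
  aln <- align_reads(lib, refs, 0)
  si <- aln[aln$category == "virus" & aln$length == 21, ]
  expect_gt(nrow(si), 0)
  op <- overlap_probability(si[si$strand == "sense", ],
                            si[si$strand == "antisense", ])
  # duplex geometry puts the 5'-overlap offset at 19, never 10
  expect_gt(op$probability[19], op$probability[10])
})

test_that("IP simulator plants strand-specific enrichment and biases", {
  cfg <- sim_config(seed = 77, genome_length = 6000,
                    pingpong_pair_rate = 10000, sirna_count = 100,
                    mirna_count = 20000)
  refs <- make_references(cfg)
  ips <- simulate_ip_libraries(refs, cfg, ago3_factor = 4, piwi5_factor = 4)
  expect_named(ips, c("Ago3IP", "Piwi5IP", "Input"))
  expect_equal(ground_truth(ips$Ago3IP)$ip_factors[["virus_sense"]], 4)
  pa <- align_reads(ips$Piwi5IP, refs, 0)
  va <- pa[pa$category == "virus" & pa$strand == "antisense" &
             pa$length >= 25, ]
  u1 <- sum(va$count[substring(va$sequence, 1, 1) == "T"]) / sum(va$count)
  expect_gte(u1, cfg$bias_1U - 0.05)
})

test_that("factor-1 IP is statistically indistinguishable from input", {
  cfg <- sim_config(seed = 12, genome_length = 6000,
                    pingpong_pair_rate = 5000, sirna_count = 100,
                    mirna_count = 1000)
  refs <- make_references(cfg)
  ips <- simulate_ip_libraries(refs, cfg, ago3_factor = 1, piwi5_factor = 1)
  strand_counts <- function(lib) {
    a <- align_reads(lib, refs, 0)
    cc <- count_by_category(a, size_class("piRNA"), refs)
    cc$count[cc$category == "virus"]
  }
  tab <- rbind(strand_counts(ips$Ago3IP), strand_counts(ips$Input))
  expect_gt(suppressWarnings(chisq.test(tab))$p.value, 0.01)
})

test_that("LFQ simulator plants recoverable interactor shifts", {
  m <- simulate_lfq_matrix(300, 10, effect_log2 = 6, missing_rate = 0,
                           seed = 3)
  gt <- ground_truth(m)
  expect_length(gt$interactors, 10)
  diffs <- rowMeans(m[gt$interactors, 1:3]) - rowMeans(m[gt$interactors, 4:6])
  expect_true(all(diffs >= 4 & diffs <= 8))
  expect_error(simulate_lfq_matrix(100, 5, effect_log2 = 0), "effect_log2")
  expect_error(simulate_lfq_matrix(100, 100, effect_log2 = 6),
               "n_true_interactors")
})

test_that("LFQ missingness is left-censored and round-trips through TSV", {
  m <- simulate_lfq_matrix(400, 20, effect_log2 = 6, missing_rate = 0.2,
                           seed = 9)
  expect_gt(sum(is.na(m)), 0)
  gt <- ground_truth(m)
  # interactors are high in bait, low in control: control side should lose
  # far more cells than the bait side
  na_bait <- mean(is.na(m[gt$interactors, 1:3]))
  na_ctrl <- mean(is.na(m[gt$interactors, 4:6]))
  expect_gt(na_ctrl, na_bait)
  f <- tempfile(fileext = ".tsv")
  write_lfq_tsv(m, f)
  back <- read_lfq_tsv(f)
  expect_equal(unclass(back)[, ], unclass(m)[, ], tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(as.character(attr(back, "groups")),
               as.character(attr(m, "groups")))
})

test_that("domain alignment simulator respects limits and randomises leaf order", {
  tr <- ape::read.tree(text = "((A:0.5,B:0.5):0.3,(C:0.5,D:0.5):0.3);")
  aln0 <- simulate_domain_alignment(tr, n_columns = 40,
                                    substitution_rate = 0, seed = 1)
  expect_length(unique(as.character(aln0)), 1)   # rate 0: all identical
  expect_setequal(names(aln0), c("A", "B", "C", "D"))
  expect_error(simulate_domain_alignment(tr, n_columns = 5,
                                         substitution_rate = 1), "n_columns")
  aln <- simulate_domain_alignment(tr, n_columns = 500,
                                   substitution_rate = 0.5, seed = 2)
  expect_true(all(nchar(aln) == 500))
  f <- tempfile(fileext = ".fa")
  write_domain_alignment(aln, f)
  back <- read_domain_alignment(f)
  expect_equal(as.character(back)[names(aln)], as.character(aln)[names(aln)])
})

test_that("image simulator separates granular from diffuse by construction", {
  cells <- simulate_images(5, 5, total_intensity = 1e5, seed = 4)
  labs <- vapply(cells, function(c) c$label, "")
  expect_equal(sum(labs == "granular"), 5)
  sums <- vapply(cells, function(c) sum(c$image[c$mask]), 0)
  expect_equal(max(sums) - min(sums), 0, tolerance = 1e-6)
  cvs <- vapply(cells, cell_cv, 0)
  expect_gt(min(cvs[labs == "granular"]), max(cvs[labs == "diffuse"]))
  # zero-noise diffuse cell is perfectly flat
  flat <- simulate_images(0, 1, total_intensity = 1e5, seed = 4,
                          noise_sd = 0)[[1]]
  expect_equal(cell_cv(flat), 0)
})
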