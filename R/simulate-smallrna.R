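# Synthetic small-RNA library generator.
#
# Ping-pong pairs are planted as anchor sites on each reference: a site is
# the 5' position of the initiator (sense) read; the responder (antisense)
# read starts 9 nt downstream on the forward axis, giving the canonical
# 10-nt 5' overlap. Because emitted reads are exact (reverse-complemented)
# substrings of the reference, the initiator's position-10 base and the
# responder's position-1 base are the same reference nucleotide: site pools
# are built with an exact fraction `bias_10A` of A-bearing sites, so both
# the 10A (sense) and 1U (antisense) biases are recovered with plain
# multinomial error as read counts grow.

# Pick `k` site entries (with replacement when candidates are scarce, as in
# a 200-nt hotspot) such that exactly round(frac * k) satisfy `is_target`.
pick_sites <- function(candidates, is_target, frac, k) {
  k_t <- round(frac * k)
  tgt <- candidates[is_target]
  oth <- candidates[!is_target]
  if (length(tgt) == 0L && k_t > 0L) stop("no target-base candidate sites")
  if (length(oth) == 0L && k_t < k) stop("no background candidate sites")
  c(if (k_t > 0L) sample(tgt, k_t, replace = TRUE),
    if (k - k_t > 0L) sample(oth, k - k_t, replace = TRUE))
}

# Apply per-base substitution noise to a character vector of reads.
add_read_noise <- function(seqs, noise_rate) {
  if (noise_rate <= 0 || length(seqs) == 0L) return(seqs)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- runif(length(ch)) < noise_rate
    if (any(hit)) {
      ch[hit] <- vapply(ch[hit], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    }
    paste(ch, collapse = "")
  }, "", USE.NAMES = FALSE)
}

# Anchor-site pools for one reference. Pair anchors p (0-based sense 5'
# coordinates) are kept away from the edges so that both mates of a pair
# with read lengths up to 30 nt fit on the reference.
pair_site_pools <- function(refseq, config, hotspot = NULL) {
  chars <- strsplit(refseq, "")[[1]]
  L <- length(chars)
  lo <- 21L
  hi <- L - 31L
  if (hi <= lo) stop("reference too short for ping-pong pair placement")
  cand <- lo:hi
  is_a <- chars[cand + 10L] == "A"   # initiator position 10 on forward axis
  if (is.null(hotspot)) {
    list(main = pick_sites(cand, is_a, config$bias_10A, config$n_sites))
  } else {
    in_hot <- cand >= hotspot[1] & cand <= hotspot[2] - 30L
    k_hot <- max(20L, round(config$n_sites / 4))
    list(hot = pick_sites(cand[in_hot], is_a[in_hot], config$bias_10A, k_hot),
         bg  = pick_sites(cand[!in_hot], is_a[!in_hot], config$bias_10A,
                          config$n_sites))
  }
}

# Draw n ping-pong reads on one strand from anchor pools.
draw_pair_reads <- function(refseq, pools, n, config, strand) {
  if (n == 0L) return(character(0))
  if (!is.null(pools$hot)) {
    use_hot <- runif(n) < config$hotspot_fraction
    p <- integer(n)
    p[use_hot] <- pools$hot[sample_idx(length(pools$hot), sum(use_hot))]
    p[!use_hot] <- pools$bg[sample_idx(length(pools$bg), sum(!use_hot))]
  } else {
    p <- pools$main[sample_idx(length(pools$main), n)]
  }
  ld <- config$piRNA_length_distribution
  len <- as.integer(names(ld))[sample_idx(length(ld), n, prob = ld)]
  if (strand == "sense") {
    substring(refseq, p + 1L, p + len)
  } else {
    a <- p + 9L                      # responder 5' on the forward axis
    rc(substring(refseq, a - len + 2L, a + 1L))
  }
}

# Draw n standalone 1U-biased reads (phased/primary-like, no overlap
# structure) on one strand.
draw_phased_reads <- function(refseq, n, config, strand) {
  if (n == 0L) return(character(0))
  chars <- strsplit(refseq, "")[[1]]
  L <- length(chars)
  if (strand == "sense") {
    cand <- 0:(L - 30L)
    is_u <- chars[cand + 1L] == "T"
  } else {
    cand <- 29L:(L - 1L)
    is_u <- chars[cand + 1L] == "A"  # read 5' base is the complement
  }
  pool <- pick_sites(cand, is_u, config$bias_1U, config$n_sites)
  p <- pool[sample_idx(length(pool), n)]
  ld <- config$piRNA_length_distribution
  len <- as.integer(names(ld))[sample_idx(length(ld), n, prob = ld)]
  if (strand == "sense") substring(refseq, p + 1L, p + len)
  else rc(substring(refseq, p - len + 2L, p + 1L))
}

# Draw n 21-nt siRNA reads on one strand from a shared duplex-site pool.
# Duplexes carry 2-nt 3' overhangs: the antisense guide 5' sits 18 nt
# downstream of the sense 5', so siRNA pairs put their 5'-overlap mass at
# offset 19, never at the ping-pong offset 10.
sirna_site_pool <- function(refseq, n_sites) {
  L <- nchar(refseq)
  sample_idx(L - 24L, n_sites) + 1L   # duplex sense 5' in [2, L-23], 0-based
}

draw_sirna_reads <- function(refseq, pool, n, strand) {
  if (n == 0L) return(character(0))
  d <- pool[sample_idx(length(pool), n)]
  if (strand == "sense") substring(refseq, d + 1L, d + 21L)
  else rc(substring(refseq, d - 1L, d + 19L))   # 5' at d + 18
}

ref_seq <- function(refs, id) refs$sequence[match(id, refs$id)]

# Core generator shared by condition libraries and IP libraries.
# `rate_scale` multiplies the expected piRNA read count per category_strand.
simulate_library_core <- function(refs, config, rate_scale, stream) {
  validate_reference_set(refs)
  set.seed(derive_seed(config$seed, "hotspot"))
  L <- nchar(ref_seq(refs, "virus"))
  w <- sample(21:(L - 31L - config$hotspot_width), 1L)
  hotspot <- c(w, w + config$hotspot_width)          # half-open, 0-based

  set.seed(derive_seed(config$seed, stream))
  size_factor <- exp(rnorm(1, 0, 0.05))              # library depth wobble
  parts <- list()                                    # collapsed per stratum
  truth <- list()
  emit <- function(seqs) {
    seqs <- add_read_noise(seqs, config$noise_rate)
    parts[[length(parts) + 1L]] <<- collapse_reads(seqs)
  }

  pp_cats <- c("virus", "te_pingpong", "host_mrna")
  for (cat in pp_cats) {
    rs <- ref_seq(refs, cat)
    pools <- pair_site_pools(rs, config,
                             hotspot = if (cat == "virus") hotspot else NULL)
    for (strand in c("sense", "antisense")) {
      key <- paste(cat, strand, sep = "_")
      sc <- if (is.null(rate_scale[[key]])) 1 else rate_scale[[key]]
      n <- rpois(1, config$pingpong_pair_rate * sc * size_factor)
      emit(draw_pair_reads(rs, pools, n, config, strand))
      truth[[key]] <- n
    }
  }
  rs <- ref_seq(refs, "te_phased")
  for (strand in c("sense", "antisense")) {
    key <- paste("te_phased", strand, sep = "_")
    sc <- if (is.null(rate_scale[[key]])) 1 else rate_scale[[key]]
    n <- rpois(1, config$pingpong_pair_rate * sc * size_factor)
    emit(draw_phased_reads(rs, n, config, strand))
    truth[[key]] <- n
  }
  for (cat in c("virus", "te_pingpong", "te_phased")) {
    rs <- ref_seq(refs, cat)
    si_pool <- sirna_site_pool(rs, config$n_sites)
    for (strand in c("sense", "antisense")) {
      key <- paste(cat, strand, "sirna", sep = "_")
      n <- rpois(1, config$sirna_count * size_factor)
      emit(draw_sirna_reads(rs, si_pool, n, strand))
      truth[[key]] <- n
    }
  }
  mir <- refs$sequence[refs$category == "mirna"]
  n_mir <- rpois(1, config$mirna_count * size_factor)
  mir_w <- rev(sort(rexp(length(mir)))); mir_w <- mir_w / sum(mir_w)
  mir_tab <- tabulate(sample_idx(length(mir), n_mir, prob = mir_w),
                      nbins = length(mir))
  if (config$noise_rate > 0) {
    emit(rep(mir, mir_tab))
  } else {
    parts[[length(parts) + 1L]] <- collapse_reads(mir[mir_tab > 0],
                                                  mir_tab[mir_tab > 0])
  }
  truth[["mirna"]] <- n_mir

  all_parts <- do.call(rbind, parts)
  lib <- collapse_reads(all_parts$sequence, all_parts$count)
  attr(lib, "ground_truth") <- list(counts = unlist(truth),
                                    hotspot = hotspot,
                                    size_factor = size_factor)
  class(lib) <- c("read_library", "data.frame")
  lib
}

#' Simulate one small-RNA library with planted ping-pong structure
#'
#' Emits a collapsed read library for one replicate of one condition:
#' ping-pong piRNA pairs with 10-nt 5' overlaps and 1U/10A biases on the
#' viral genome (with a 200-nt sense hotspot), a ping-pong transposon family
#' and a host mRNA; 1U-biased non-overlapping reads on the phased transposon
#' family; 21-nt siRNA duplexes; and verbatim miRNA background reads.
#' Per-stratum read counts are Poisson around their expectation; under
#' `knockdown` the expectation is multiplied by the configured retention
#' fraction.
#'
#' @param refs a `reference_set` from [make_references()].
#' @param config a [sim_config()].
#' @param condition `"control"` or `"knockdown"`.
#' @param replicate replicate index (>= 1); part of the RNG stream.
#' @return a `read_library`: data.frame with columns `sequence`, `count`
#'   (lexicographic order) and attribute `ground_truth` holding realized
#'   per-stratum read totals, the planted hotspot window (0-based,
#'   half-open) and the library size factor.
#' @examples
#' cfg <- sim_config(seed = 7, pingpong_pair_rate = 200,
#'                   sirna_count = 50, mirna_count = 500)
#' refs <- make_references(cfg)
#' lib <- simulate_pingpong_library(refs, cfg, "control", 1)
#' sum(lib$count)
#' @export
simulate_pingpong_library <- function(refs, config,
                                      condition = c("control", "knockdown"),
                                      replicate = 1L) {
  condition <- match.arg(condition)
  validate_sim_config(config)
  scale <- list()
  if (condition == "knockdown") {
    needed <- c(outer(c("virus", "te_pingpong", "te_phased", "host_mrna"),
                      c("sense", "antisense"), paste, sep = "_"))
    missing_keys <- setdiff(needed, names(config$knockdown_retention))
    if (length(missing_keys)) {
      stop("knockdown_retention missing for: ",
           paste(missing_keys, collapse = ", "))
    }
    scale <- config$knockdown_retention
  }
  lib <- simulate_library_core(refs, config, scale,
                               paste("lib", condition, replicate, sep = "/"))
  attr(lib, "condition") <- condition
  attr(lib, "replicate") <- as.integer(replicate)
  lib
}

#' Simulate immunoprecipitation (IP) and input small-RNA libraries
#'
#' Models PIWI-protein IP sequencing: the Ago3 IP oversamples virus
#' sense-strand (10A, initiator) piRNAs, the Piwi5 IP oversamples virus
#' antisense-strand (1U, responder) piRNAs, and the input library samples
#' both strands symmetrically. Sampling factors are recorded in the ground
#' truth of each library.
#'
#' @param refs a `reference_set`.
#' @param config a [sim_config()].
#' @param ago3_factor,piwi5_factor oversampling factor for the favoured
#'   virus strand in each IP (default 4, i.e. log2 enrichment 2).
#' @return named list of `read_library` objects: `Ago3IP`, `Piwi5IP`,
#'   `Input`.
#' @export
simulate_ip_libraries <- function(refs, config, ago3_factor = 4,
                                  piwi5_factor = 4) {
  validate_sim_config(config)
  mk <- function(scale, stream, factors) {
    lib <- simulate_library_core(refs, config, scale, stream)
    gt <- attr(lib, "ground_truth")
    gt$ip_factors <- factors
    attr(lib, "ground_truth") <- gt
    lib
  }
  list(
    Ago3IP = mk(list(virus_sense = ago3_factor), "ip/ago3",
                c(virus_sense = ago3_factor, virus_antisense = 1)),
    Piwi5IP = mk(list(virus_antisense = piwi5_factor), "ip/piwi5",
                 c(virus_sense = 1, virus_antisense = piwi5_factor)),
    Input = mk(list(), "ip/input",
               c(virus_sense = 1, virus_antisense = 1)))
}
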