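#' Simulation configuration for synthetic small-RNA experiments
#'
#' Bundles every tunable of the synthetic-data generators into one validated
#' object. The defaults describe a Sindbis-virus-like infection of mosquito
#' cells: an 11.7 kb viral genome producing ping-pong piRNA pairs with strong
#' 1U/10A biases, a ping-pong-driven transposon family (Ty3-gypsy-like), a
#' phased-1U transposon family (BEL-Pao-like), a short host mRNA target, a
#' 21-nt siRNA population and an abundant miRNA background, in a
#' control-versus-knockdown triplicate design.
#'
#' @param seed integer master seed; every generator derives its own stream
#'   from it, so identical configs give byte-identical outputs.
#' @param genome_length viral genome length in nt (default 11700).
#' @param pingpong_pair_rate expected ping-pong read count per strand per
#'   category in the control condition (Poisson mean).
#' @param bias_1U probability that a standalone (phased / primary-like) read
#'   starts with U. In planted ping-pong pairs the responder's first base is
#'   the complement of the initiator's tenth base, so pair reads inherit their
#'   1U frequency from `bias_10A`.
#' @param bias_10A probability that a ping-pong pair site carries an A at
#'   initiator position 10 (equivalently a U at responder position 1).
#' @param piRNA_length_distribution named numeric vector of probabilities over
#'   read lengths 25--30 nt.
#' @param sirna_count expected 21-nt siRNA read count per strand.
#' @param mirna_count expected total miRNA read count.
#' @param knockdown_retention named list/vector mapping category_strand keys
#'   (e.g. `virus_sense`) to the fraction of reads retained under knockdown.
#' @param replicates number of replicates per condition (>= 2).
#' @param noise_rate per-base substitution probability applied to emitted
#'   reads (default 0; reads then map back exactly).
#' @param hotspot_fraction fraction of virus-sense pair sites drawn from a
#'   single 200-nt hotspot window.
#' @param hotspot_width width of the hotspot window in nt.
#' @param n_sites number of distinct pair anchor sites per category; the
#'   fraction of A-bearing sites is fixed exactly at `bias_10A` so the planted
#'   bias is recovered with plain multinomial error.
#'
#' @return an object of class `sim_config` (a validated list).
#' @examples
#' cfg <- sim_config(seed = 1, genome_length = 1000)
#' cfg$bias_10A
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 11700L,
                       pingpong_pair_rate = 10000,
                       bias_1U = 0.9,
                       bias_10A = 0.9,
                       piRNA_length_distribution = c(
                         `25` = 0.08, `26` = 0.17, `27` = 0.25,
                         `28` = 0.25, `29` = 0.17, `30` = 0.08),
                       sirna_count = 4000,
                       mirna_count = 50000,
                       knockdown_retention = list(
                         virus_sense = 0.25, virus_antisense = 0.20,
                         te_pingpong_sense = 0.85, te_pingpong_antisense = 0.45,
                         te_phased_sense = 0.40, te_phased_antisense = 0.40,
                         host_mrna_sense = 0.80, host_mrna_antisense = 0.80),
                       replicates = 3L,
                       noise_rate = 0,
                       hotspot_fraction = 0.6,
                       hotspot_width = 200L,
                       n_sites = 400L) {
  cfg <- list(seed = as.integer(seed),
              genome_length = as.integer(genome_length),
              pingpong_pair_rate = pingpong_pair_rate,
              bias_1U = bias_1U, bias_10A = bias_10A,
              piRNA_length_distribution = piRNA_length_distribution,
              sirna_count = sirna_count, mirna_count = mirna_count,
              knockdown_retention = as.list(knockdown_retention),
              replicates = as.integer(replicates),
              noise_rate = noise_rate,
              hotspot_fraction = hotspot_fraction,
              hotspot_width = as.integer(hotspot_width),
              n_sites = as.integer(n_sites))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$bias_1U, cfg$bias_10A, cfg$noise_rate, cfg$hotspot_fraction,
             unlist(cfg$knockdown_retention))
  if (any(probs < 0 | probs > 1)) {
    stop("invalid config: all probabilities and retention fractions must lie in [0, 1]")
  }
  if (cfg$genome_length < 500L) {
    stop("invalid config: genome_length must be >= 500 nt")
  }
  if (cfg$replicates < 2L) {
    stop("invalid config: replicates must be >= 2")
  }
  ld <- cfg$piRNA_length_distribution
  if (is.null(names(ld)) || any(is.na(as.integer(names(ld)))) ||
      any(as.integer(names(ld)) < 25L) || any(as.integer(names(ld)) > 30L)) {
    stop("invalid config: piRNA_length_distribution must be named with lengths in 25..30")
  }
  if (abs(sum(ld) - 1) > 1e-8) {
    stop("invalid config: piRNA_length_distribution must sum to 1")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config: seed", x$seed,
      "| genome", x$genome_length, "nt",
      "| pair rate", x$pingpong_pair_rate,
      "| 10A", x$bias_10A, "| 1U", x$bias_1U,
      "| replicates", x$replicates, "\n")
  invisible(x)
}
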