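# pingpongr

Simulation and analysis of piRNA ping-pong signatures, small-RNA
differential abundance, protein interactome enrichment, TUDOR-domain
phylogeny, and fluorescence-signal granularity.

## The problem

In arbovirus-infected mosquito cells, viral RNA is processed into
PIWI-interacting RNAs (piRNAs, 25–30 nt) by the **ping-pong amplification
loop**: two PIWI proteins reciprocally cleave sense and antisense target
RNA. Because the responder piRNA starts with a uridine (1U) that pairs with
the adenosine at position 10 of the initiator (10A), ping-pong leaves two
sequence fingerprints in sequencing libraries — a 10-nt overlap of
opposite-strand 5' ends, and the 1U/10A positional nucleotide bias.
Perturbation experiments (knockdown of biogenesis factors, PIWI-protein
IPs, interactome pulldowns) then ask which proteins drive this loop.

`pingpongr` is the computational side of such a study, built for
researchers analysing small-RNA and LFQ proteomics data:

* **Synthetic data with ground truth** — a read simulator that plants
  ping-pong pairs, 1U/10A biases, a production hotspot, knockdown effect
  sizes, siRNA duplexes and miRNA background; plus generators for IP
  libraries, LFQ matrices, domain alignments down a known tree, and
  granular/diffuse cell images.
* **Small-RNA core** — read collapsing (FASTQ / collapsed FASTA),
  exact and 1-mismatch placement on references, size-class stratification,
  per-category strand-resolved counts, SAM export.
* **Signatures** — positional nucleotide-bias matrices; the 5'-overlap
  probability profile with ping-pong z-score

  $z_{10} = \dfrac{p(10) - \overline{p(d\neq10)}}{\mathrm{sd}\,p(d\neq10)}$;

  hotspot localisation; miRNA-normalised IP-versus-input log2 enrichment.
* **Differential analysis** — reads-per-million-miRNA normalisation,
  percent reduction with two-tailed Student t-tests and significance tiers.
* **Interactome** — left-censored imputation, permutation-FDR t-tests, and
  strict volcano classification (log2 FC > 4.3, −log10 P > 1.5 by default).
* **Phylogeny** — p-distances (pairwise gap deletion), Saitou–Nei
  neighbor joining with deterministic tie-breaks, column-bootstrap
  supports, reciprocal-nearest-neighbor ortholog calling.
* **Granularity** — per-cell coefficient of variation of masked pixel
  intensities, with group summaries.

See `vignettes/pingpong-methods.Rmd` for the models, assumptions, and
design decisions.

## Worked example

Simulate a 3+3 knockdown experiment, run the full pipeline, and measure
what was planted:

```r
library(pingpongr)

cfg  <- sim_config(seed = 7)      # pair rate 1e4, retentions 0.25/0.20, ...
refs <- make_references(cfg)

tabs <- list(); conds <- c(); reps <- c()
for (i in 1:3) for (cond in c("control", "knockdown")) {
  lib <- simulate_pingpong_library(refs, cfg, cond, i)
  aln <- align_reads(lib, refs)
  tabs[[length(tabs) + 1]] <- count_by_category(aln, size_class("piRNA"), refs)
  conds <- c(conds, cond); reps <- c(reps, i)
  if (cond == "control" && i == 1) ctl <- aln
}
res <- compare_conditions(condition_table(tabs, conds, reps))
subset(res, category == "virus",
       c(category, strand, percent_reduction, p_value, stars))
#>   category    strand percent_reduction  p_value stars
#> 1    virus     sense              74.6 7.93e-10   ***
#> 5    virus antisense              79.7 3.35e-08   ***

pir <- subset(ctl, length >= 25 & length <= 30 & category == "virus")
overlap_probability(subset(pir, strand == "sense"),
                    subset(pir, strand == "antisense"))
#> overlap_profile: offsets 1..30, peak at 10 (p = 0.172), z10 = 12.94

b <- nucleotide_bias(subset(pir, strand == "sense"), "sense")
b["A", 10]
#> [1] 0.9

hotspot(subset(pir, strand == "sense"), nchar(refs$sequence[1]))
#> $start 9035  $end 9235  $fraction 0.60
```

The configured 75%/80% sense/antisense knockdown retention is recovered
within a point, the overlap profile peaks at the ping-pong offset 10 with
z10 ≈ 13, the planted position-10 A bias (0.9) is recovered exactly at this
depth, and 60% of sense piRNA 5' ends fall in one 200-nt window — the
planted hotspot.

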