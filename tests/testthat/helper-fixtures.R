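# Shared simulated fixtures, memoised so expensive generation runs once
# per test session.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- force(expr)
  .fixture_env[[key]]
}

# Full-depth study-condition config and reference set.
fix_config <- function() memo("cfg", sim_config(seed = 424242))

fix_refs <- function() memo("refs", make_references(fix_config()))

# One control library at full depth (pair rate 1e4) and its alignment.
fix_aligned_lib <- function() {
  memo("lib", simulate_pingpong_library(fix_refs(), fix_config(),
                                        "control", 1))
}

fix_aligned <- function() {
  memo("aligned", align_reads(fix_aligned_lib(), fix_refs(), 0))
}

# Aligned piRNA-class subsets for a category/strand.
fix_subset <- function(category, strand, min_len = 25, max_len = 30) {
  a <- fix_aligned()
  a[a$category == category & a$strand == strand &
      a$length >= min_len & a$length <= max_len, , drop = FALSE]
}

# Small config for cheap structural tests.
small_config <- function(seed = 99) {
  sim_config(seed = seed, genome_length = 2000, pingpong_pair_rate = 300,
             sirna_count = 60, mirna_count = 600, n_sites = 80)
}
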