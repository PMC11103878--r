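# Small, fast study configurations and independent oracles used across tests.

tiny_config <- function(seed = 11, ...) {
  defaults <- list(seed = seed, n_chrom_per_subgenome = 1L, chrom_length = 2e6,
                   bin_size = 2e4, n_genes = 80L, n_tads_per_chrom = 5L,
                   n_fusion = 1L, n_neo = 1L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Closed-form Pearson chi-square for a 2x2 table (no correction):
# N (ad - bc)^2 / (r1 r2 c1 c2).
chisq_2x2_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# One-sided enrichment p by exhaustive hypergeometric summation.
hyper_tail_oracle <- function(overlap, term_size, universe, set_size) {
  i <- overlap:min(term_size, set_size)
  sum(choose(term_size, i) * choose(universe - term_size, set_size - i)) /
    choose(universe, set_size)
}

# Random tiling TAD partition of [0, L) on one chromosome (bin-aligned).
random_tad_set <- function(chrom, L, bin = 2e4, n_cuts = sample(2:8, 1)) {
  pos <- sort(sample(seq(bin, L - bin, by = bin), n_cuts))
  tads_from_boundaries(pos, setNames(L, chrom), chrom = chrom)
}

# Comparable signature of an event table for duality checks.
event_signature <- function(ev, type) {
  e <- ev[ev$type == type, c("chrom", "span_start", "span_end", "n_parts",
                             "changed_boundaries")]
  e <- e[order(e$chrom, e$span_start), ]
  rownames(e) <- NULL
  e
}
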