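---
title: "Methods: drought-induced transcriptome and 3D-chromatin analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: drought-induced transcriptome and 3D-chromatin analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromadapt)
```

`chromadapt` analyses how an allotetraploid genome (two subgenomes, here
labelled A and D) responds to progressive drought and re-watering, combining
expression, homoeolog bias, A/B compartments, TAD dynamics and a co-expression
target screen. This vignette documents the statistical model behind each
module, the parameters and their defaults, and the design decisions and
limitations a user should know before trusting the output.

## Study design and vocabulary

All functions assume a factorial design of two varieties (`sensitive`,
`tolerant`), two treatments (`C` control, `D` drought) and four stages (`ID`
initial, `MD` mild, `SD` severe drought, `RW` re-watering); the constants
`VARIETIES`, `TREATMENTS` and `STAGES` hold the canonical levels and
`sample_key()` builds the `variety.treatment.stage` keys used to index
per-condition results. Genomic intervals are 0-based half-open throughout, and
two intervals are "associated" when they overlap by at least 1 bp.

## Synthetic data generator

`sim_config()` + `simulate_study()` produce a complete synthetic study with
ground truth for every downstream module. The generator is not a fit to real
data; it is a minimal mechanism that plants each signal the pipeline is meant
to detect:

* **Genome.** `n_chrom_per_subgenome` chromosomes per subgenome, tiled by
  `n_tads_per_chrom` TADs whose boundaries are jittered on the bin grid. A/B
  compartment blocks are runs of `compartment_period_tads` whole TADs, so
  compartment edges coincide with TAD boundaries and never create spurious
  insulation minima. Genes are placed without overlap, 3:1 enriched in A
  blocks, and `homoeolog_fraction` of them form A/D homoeolog pairs.
* **Expression.** Counts are negative binomial with log-normal gene baselines
  (`baseline_log2_mean` ± `baseline_log2_sd`) and dispersion `dispersion`.
  Drought adds a signed log2 effect `base_lfc * stage_multiplier[stage]` to a
  planted fraction of genes (`frac_down`, `frac_up`; both homoeologs of a pair
  share the class), plus an extra `extra_dt_lfc` suppression on the D copy of
  down-regulated pairs — the planted subgenome asymmetry. At RW the effect
  shrinks by the variety's `recovery` fraction (defaults 0.4 sensitive, 0.9
  tolerant), so recovery differs by variety by construction. The default
  baseline and dispersion are deliberately low-noise: the internal DE caller
  is a two-replicate Welch test (see below), far weaker than the
  dispersion-sharing tools used on real data, and at higher noise it would
  detect nothing even though a real-data tool would.
* **Contact maps.** Each condition gets one dense symmetric matrix per
  chromosome: distance decay `(d + 1)^-decay_exponent`, times
  `1 ± compartment_amplitude` for same/different compartment, times
  `tad_enrichment` within TADs, times log-normal noise (`noise_sd`). Drought
  samples carry `n_fusion` boundary-removing fusions and `n_neo` TAD-splitting
  events, planted only on the first chromosome of each subgenome so the
  remaining chromosomes are negative controls; drought also flips the first A
  block per chromosome to B from MD onward, reverting at RW only in the
  tolerant variety.

All randomness derives from `seed` through independent per-family streams, so
identical configurations reproduce identical studies, and adding an output to
one family does not perturb another.

## Expression response

`call_differential()` is a deliberately simple stand-in for an external DE
tool: Welch t-test on `log2(x + 1)` between drought and control replicates of
one (variety, stage), BH correction, and a call only when `padj <= alpha`
(default 0.05) **and** `|log2fc| >= lfc_threshold` (default 1). With two
replicates its power is limited; consume externally computed DE tables via
`as_differential_calls()` whenever you have them.

A gene is **drought-induced** (`call_drought_induced()`) when it is
differential in at least one of ID/MD/SD and all its differential stages agree
in direction; RW is excluded and reserved for recovery.
`classify_recovery()` splits the induced set at RW into `recovered` (no longer
differential), `still_differential`, and `missing`, and `chi_square_2x2()`
tests the variety × recovery contingency (`correct = FALSE` by default; both
conventions are exposed because published tables may use either).

## Homoeolog bias

`call_bias()` codes each pair per condition as +1 (A-biased) when
`log2((At + eps)/(Dt + eps)) >= lfc_cut`, −1 when `<= -lfc_cut`, else 0, with
pairs below `min_expr` in both copies forced to 0. The **bias-change index**
(`bias_change_index()`) is drought state minus control state, in −2..+2, and
the **genome bias value** (`genome_bias_value()`) is its sum over pairs:
positive means a drought shift toward the A subgenome.
`classify_bias_dynamics()` labels a pair stable only when one homoeolog is
strictly higher at all four stages; ties count as "not higher", so exact ties
are `dynamic`. `classify_pair_direction()` gives the per-stage
common/single/opposite DE-direction taxonomy.

## A/B compartments

`compute_eigentrack()` implements the standard pipeline: per-distance
observed/expected normalisation, Pearson correlation matrix, first
eigenvector. Zero-coverage bins and bins constant after normalisation are
masked. The eigenvector's sign is arbitrary, so it is oriented by the sign of
its correlation with a gene-density track (A = gene-rich); note that negating
the orientation track flips every call. A `low_signal` flag is raised when the
leading eigenvalue explains less than `low_signal_varexp` of the variance
(e.g. a pure distance-decay matrix, which yields an all-masked track).
`call_compartments()` applies the strict sign rule: positive = A, negative =
B, exact zero = masked.

`switch_group()` maps each four-stage pattern (letters over {A, B}, stage
order ID MD SD RW) to `stable` (constant), `AB` (starts A ends B), `BA`
(starts B ends A), `ABA` (A at both ends with a B excursion) or `BAB`; the 16
strings partition 2/4/4/3/3. `classify_switch_patterns()` applies this per
bin, excluding bins masked at any stage, and
`associate_switches_with_genes()` tests the switch-region × differential 2×2
association.

## TAD dynamics

`separation_score()` is an insulation-style score: mean contact between the
windows flanking each bin, z-normalised per window size (defaults 40/60/100
kb) and averaged; `call_tad_boundaries()` takes local minima below `z_cut`.
The score is invariant to rescaling the matrix and identically zero on a
uniform one.

Boundary comparison uses the 40-kb-flank convention: each boundary becomes an
80-kb region and two boundaries are conserved when their regions overlap by at
least 1 bp, i.e. positions differ by less than 80 kb.  `match_boundaries()`
resolves one-to-many cases to a one-to-one matching (greedy on decreasing
overlap, then distance, then leftmost), so matched counts are symmetric.
On top of this sit `classify_drought_boundaries()` (conserved / drought-gain
`dg` / drought-loss `dl`), `build_pan_boundaries()` (iterative ID→MD→SD→RW
accretion with a final best-overlap presence assignment; the accretion order
is exposed for sensitivity checks), and the order-invariant
`build_cross_sample_pan()` over all sample keys (connected components of the
pairwise matchings).

`detect_tad_events()` finds **fusions** (a chain of ≥2 exactly consecutive
control TADs merged into one drought TAD whose outer boundaries are conserved
while ≥1 internal boundary is lost) and **Neo-TADs** (the symmetric split), by
running the same scanner with the roles swapped — which makes fusion(a, b) and
neo(b, a) dual by construction. `call_hotspots()` tiles chromosomes in
non-overlapping windows (10 Mb) and flags windows with strictly more than
`min_count` (8) changed boundaries, merging consecutive qualifying windows;
`percent_shared()` fixes the one-decimal reporting convention.

## Network integration

`coexpression_edges()` is a lightweight stand-in (signed soft-threshold:
`max(cor, 0)^power` on `log2(x + 1)`), and `assign_modules_components()` a
stand-in module detector (connected components of the filtered network,
labelled by decreasing size); both exist so fully synthetic runs can exercise
the downstream logic, and both should be replaced by external tool output on
real data. `filter_edges()` keeps weights **strictly** greater than the
threshold (default 0.2). `find_hubs()` ranks module members by intra-module
weight sums with a lexicographic tie-break; `module_expression_profile()`
averages per-gene z-scores (constant genes masked);
`fisher_enrichment()` is the one-sided hypergeometric test with BH across
terms. `screen_target_genes()` intersects, per variety, the drought-induced
set, a module gene set, and the genes near drought-changed TAD boundaries
(`genes_near_boundaries()`, 20 kb per side by default, 10 kb selectable), then
reports shared and variety-specific targets with per-gene evidence flags.

## Numerical and design choices

* Strict inequalities where a published convention says "greater than"
  (edge weights > 0.2, hotspot count > 8, compartment sign rule), with exact
  zeros masked rather than assigned.
* Chi-square and Fisher tests delegate to `stats`; BH via `p.adjust`. The
  2×2 chi-square validates marginals and non-negativity and errors rather
  than returning NaN.
* Boundary matching, pan construction and event detection are exact interval
  algebra on bp coordinates — no rounding to bins — so the 1-bp edge cases
  (e.g. positions 1,079,999 vs 1,080,000 under 40-kb flanks) behave as
  interval arithmetic dictates.
* Deterministic tie-breaks everywhere a ranking can tie (hub genes, boundary
  matching, module labels), so results are reproducible across platforms.

## Limitations

* The DE caller, co-expression builder and module detector are explicit
  stand-ins; at real-data scale use DESeq2-class tools, WGCNA-class networks
  and a dedicated Hi-C stack, importing their outputs.
* The generator plants block-constant compartments and sharp TADs on short
  chromosomes (4 Mb default); hotspots (10-Mb windows, > 8 changes) can never
  fire at that scale and are exercised on constructed inputs instead.
* Welch testing with two replicates has low power by construction; the
  generator's low default noise reflects the emulated design's
  high replicate agreement, not a claim about RNA-seq noise in general.
* Eigenvector orientation relies on gene density; on genomes where A
  compartments are not gene-rich, supply a different orientation track.
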