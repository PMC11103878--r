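#' Configuration for the synthetic allotetraploid drought study
#'
#' Builds and validates the parameter set driving the synthetic-data generator.
#' The generator emulates a two-variety (drought sensitive / tolerant), two
#' treatment (control C / drought D), four stage (ID, MD, SD, RW) design on an
#' allotetraploid genome with two subgenomes (A and D chromosomes), homoeolog
#' gene pairs, drought suppression that is stronger on the D subgenome, a
#' variety-dependent recovery after re-watering, and Hi-C contact matrices with
#' planted TADs, A/B compartment blocks and fusion / Neo-TAD events.
#'
#' @param seed master seed; three independent streams (genome, expression,
#'   contacts) are derived from it.
#' @param n_chrom_per_subgenome chromosomes per subgenome.
#' @param chrom_length chromosome length in bp.
#' @param bin_size Hi-C bin size in bp; must divide `chrom_length`.
#' @param n_genes total gene count (split evenly across subgenomes).
#' @param homoeolog_fraction fraction of genes belonging to a homoeolog pair.
#' @param n_replicates expression replicates per design cell.
#' @param baseline_log2_mean,baseline_log2_sd log2 scale of the log-normal
#'   gene baseline means. The default keeps typical genes well out of the
#'   count shot-noise regime so that the internal two-replicate t-test
#'   stand-in — far weaker than a dispersion-sharing external tool — can
#'   recover planted effects, matching the high between-replicate agreement
#'   of the emulated design.
#' @param dispersion negative-binomial dispersion (1/size); must be > 0. The
#'   default is low for the same reason.
#' @param base_lfc magnitude (log2) of the drought effect for affected genes
#'   at the MD stage.
#' @param stage_multiplier named multipliers of `base_lfc` for ID, MD, SD.
#' @param extra_dt_lfc additional log2 suppression applied to the D-subgenome
#'   copy of drought-suppressed genes under drought.
#' @param recovery named fractions (sensitive, tolerant) of the SD effect
#'   removed at RW; 1 means full recovery to the control state.
#' @param frac_down,frac_up fractions of genes planted as drought
#'   down-/up-regulated.
#' @param compartment_expr_boost log2 expression boost for genes in planted A
#'   compartment bins.
#' @param boundary_expr_boost log2 expression boost for genes within
#'   `boundary_expr_window` of a planted TAD boundary.
#' @param boundary_expr_window bp window used for `boundary_expr_boost`.
#' @param n_tads_per_chrom planted TADs per chromosome.
#' @param tad_enrichment intra-TAD contact enrichment factor (>= 1; the value
#'   1 disables TAD structure, useful for degenerate checks).
#' @param decay_exponent distance-decay exponent of the contact background.
#' @param compartment_period_tads number of consecutive TADs per A/B block
#'   (block edges therefore coincide with TAD boundaries).
#' @param compartment_amplitude checkerboard amplitude in (0, 1).
#' @param noise_sd sd of the multiplicative log-normal matrix noise.
#' @param n_fusion,n_neo planted fusion / Neo-TAD events per drought sample.
#' @param switch_blocks_per_chrom number of A blocks per chromosome flipped to
#'   B under drought from MD onward (restored at RW in the tolerant variety).
#'
#' @return an object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$n_genes
sim_config <- function(seed = 1L,
                       n_chrom_per_subgenome = 2L,
                       chrom_length = 4e6,
                       bin_size = 2e4,
                       n_genes = 400L,
                       homoeolog_fraction = 0.8,
                       n_replicates = 2L,
                       baseline_log2_mean = 10,
                       baseline_log2_sd = 1,
                       dispersion = 0.01,
                       base_lfc = 2,
                       stage_multiplier = c(ID = 0.5, MD = 1, SD = 1.5),
                       extra_dt_lfc = 1.5,
                       recovery = c(sensitive = 0.4, tolerant = 0.9),
                       frac_down = 0.30,
                       frac_up = 0.15,
                       compartment_expr_boost = 0.5,
                       boundary_expr_boost = 0.5,
                       boundary_expr_window = 2e4,
                       n_tads_per_chrom = 10L,
                       tad_enrichment = 3,
                       decay_exponent = 0.8,
                       compartment_period_tads = 2L,
                       compartment_amplitude = 0.3,
                       noise_sd = 0.1,
                       n_fusion = 2L,
                       n_neo = 2L,
                       switch_blocks_per_chrom = 1L) {
  check_number(seed, "seed")
  check_number(n_chrom_per_subgenome, "n_chrom_per_subgenome", 1)
  check_number(chrom_length, "chrom_length", 0, strict = TRUE)
  check_number(bin_size, "bin_size", 0, strict = TRUE)
  if (chrom_length %% bin_size != 0)
    stopf("bin_size (%g) must divide chrom_length (%g)", bin_size, chrom_length)
  check_number(n_genes, "n_genes", 0)
  if (n_genes %% 2 != 0) stopf("n_genes must be even (split across subgenomes)")
  check_fraction(homoeolog_fraction, "homoeolog_fraction")
  check_number(n_replicates, "n_replicates", 1)
  check_number(dispersion, "dispersion", 0, strict = TRUE)
  check_number(tad_enrichment, "tad_enrichment", 1)
  check_fraction(compartment_amplitude, "compartment_amplitude")
  check_number(noise_sd, "noise_sd", 0)
  check_fraction(frac_down, "frac_down")
  check_fraction(frac_up, "frac_up")
  if (frac_down + frac_up > 1) stopf("frac_down + frac_up must be <= 1")
  if (!all(c("ID", "MD", "SD") %in% names(stage_multiplier)))
    stopf("stage_multiplier must name ID, MD and SD")
  if (!all(VARIETIES %in% names(recovery)))
    stopf("recovery must name both varieties (sensitive, tolerant)")
  for (v in VARIETIES) check_fraction(recovery[[v]], paste0("recovery[", v, "]"))
  check_number(n_tads_per_chrom, "n_tads_per_chrom", 2)
  check_number(n_fusion, "n_fusion", 0)
  check_number(n_neo, "n_neo", 0)

  design <- expand.grid(variety = VARIETIES, treatment = TREATMENTS,
                        stage = STAGES, replicate = seq_len(n_replicates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  design <- design[order(design$variety, design$treatment,
                         match(design$stage, STAGES), design$replicate), ]
  design$sample_id <- sprintf("%s_%s_%s_r%d", design$variety, design$treatment,
                              design$stage, design$replicate)
  rownames(design) <- NULL

  cfg <- list(seed = as.integer(seed),
              n_chrom_per_subgenome = as.integer(n_chrom_per_subgenome),
              chrom_length = chrom_length, bin_size = bin_size,
              n_genes = as.integer(n_genes),
              homoeolog_fraction = homoeolog_fraction,
              n_replicates = as.integer(n_replicates), design = design,
              baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd,
              dispersion = dispersion, base_lfc = base_lfc,
              stage_multiplier = stage_multiplier,
              extra_dt_lfc = extra_dt_lfc, recovery = recovery,
              frac_down = frac_down, frac_up = frac_up,
              compartment_expr_boost = compartment_expr_boost,
              boundary_expr_boost = boundary_expr_boost,
              boundary_expr_window = boundary_expr_window,
              n_tads_per_chrom = as.integer(n_tads_per_chrom),
              tad_enrichment = tad_enrichment,
              decay_exponent = decay_exponent,
              compartment_period_tads = as.integer(compartment_period_tads),
              compartment_amplitude = compartment_amplitude,
              noise_sd = noise_sd,
              n_fusion = as.integer(n_fusion), n_neo = as.integer(n_neo),
              switch_blocks_per_chrom = as.integer(switch_blocks_per_chrom))
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic allotetraploid drought-study configuration\n")
  cat(sprintf("  seed %d | %d chromosomes x %g Mb | bin %g kb\n",
              x$seed, 2L * x$n_chrom_per_subgenome, x$chrom_length / 1e6,
              x$bin_size / 1e3))
  cat(sprintf("  %d genes (%.0f%% paired), %d samples\n", x$n_genes,
              100 * x$homoeolog_fraction, nrow(x$design)))
  cat(sprintf("  drought lfc %g (extra Dt %g), dispersion %g\n",
              x$base_lfc, x$extra_dt_lfc, x$dispersion))
  cat(sprintf("  %d TADs/chrom (enrichment %g), %d fusion + %d neo per drought sample\n",
              x$n_tads_per_chrom, x$tad_enrichment, x$n_fusion, x$n_neo))
  invisible(x)
}

#' Read / write a simulation configuration as YAML
#'
#' @param config a [sim_config()] object.
#' @param path file path.
#' @return `write_sim_config` returns `path` invisibly; `read_sim_config`
#'   returns a validated `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  scalar <- config[setdiff(names(config), c("design", "stage_multiplier", "recovery"))]
  scalar$stage_multiplier <- as.list(config$stage_multiplier)
  scalar$recovery <- as.list(config$recovery)
  yaml::write_yaml(scalar, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$stage_multiplier <- unlist(raw$stage_multiplier)
  raw$recovery <- unlist(raw$recovery)
  do.call(sim_config, raw)
}
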