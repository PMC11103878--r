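#' Simulate the drought-response expression experiment
#'
#' Draws negative-binomial counts for every gene and sample of the design.
#' The log2 mean of each gene is `baseline + planted drought effect`, where the
#' baseline is log-normal (plus boosts for genes in A-compartment bins and
#' genes near planted TAD boundaries) and the drought effect applies only to
#' drought (D) samples: down-/up-regulated genes move by
#' `base_lfc * stage_multiplier[stage]` log2 units, the D-subgenome copy of a
#' suppressed gene receives an extra `extra_dt_lfc * multiplier` suppression
#' (the subgenome asymmetry), and at RW the SD-sized effect is shrunk by the
#' variety's recovery fraction. Homoeolog pair members always share their
#' planted class. An FPKM-like matrix (counts / (gene length in kb x library
#' size in millions)) is emitted alongside the raw counts, and the truth set
#' records the planted per-stage DE direction and per-condition bias state.
#'
#' @param genome a [simulate_genome()] result.
#' @param config the same [sim_config()]; defaults to the one inside `genome`.
#' @return object of class `ca_expression`: `counts`, `fpkm` (genes x samples),
#'   `meta` (sample sheet), `genes`, and `truth` with elements `class`
#'   (per-gene planted class), `de` (gene, variety, stage, direction) and
#'   `bias` (pair_id, variety, treatment, stage, state from the planted means).
#' @export
simulate_expression <- function(genome, config = genome$config) {
  stopifnot(inherits(genome, "ca_genome"))
  if (config$dispersion <= 0) stopf("dispersion must be > 0")
  set.seed(stream_seed(config$seed, 2L))

  genes <- genome$genes
  ng <- nrow(genes)
  meta <- config$design

  # Planted class: shared within a homoeolog pair, independent otherwise.
  cls <- rep(NA_character_, ng)
  names(cls) <- genes$gene_id
  draw_class <- function(n) sample(c("down", "up", "null"), n, replace = TRUE,
                                   prob = c(config$frac_down, config$frac_up,
                                            1 - config$frac_down - config$frac_up))
  if (nrow(genome$pairs) > 0) {
    pc <- draw_class(nrow(genome$pairs))
    cls[genome$pairs$gene_At] <- pc
    cls[genome$pairs$gene_Dt] <- pc
  }
  unpaired <- is.na(cls)
  cls[unpaired] <- draw_class(sum(unpaired))

  # Baseline log2 mean with structural boosts.
  baseline <- rnorm(ng, config$baseline_log2_mean, config$baseline_log2_sd)
  mid <- (genes$start + genes$end) / 2
  bin_label <- character(ng)
  near_boundary <- logical(ng)
  for (ch in genome$chroms$chrom) {
    gi <- which(genes$chrom == ch)
    if (!length(gi)) next
    b <- genome$bins[genome$bins$chrom == ch, ]
    bin_label[gi] <- b$compartment[findInterval(mid[gi], b$start)]
    td <- genome$tads_base[genome$tads_base$chrom == ch, ]
    inner <- td$end[-nrow(td)]
    if (length(inner))
      near_boundary[gi] <- vapply(mid[gi], function(m)
        any(abs(m - inner) <= config$boundary_expr_window), logical(1))
  }
  baseline <- baseline +
    config$compartment_expr_boost * (bin_label == "A") +
    config$boundary_expr_boost * near_boundary

  eff_sign <- ifelse(cls == "up", 1, ifelse(cls == "down", -1, 0))

  # Planted log2 effect for one (variety, treatment, stage) condition.
  planted_effect <- function(variety, treatment, stage) {
    if (treatment != "D") return(numeric(ng))
    m <- if (stage == "RW") {
      config$stage_multiplier[["SD"]] * (1 - config$recovery[[variety]])
    } else config$stage_multiplier[[stage]]
    lfc <- eff_sign * config$base_lfc * m
    extra <- (cls == "down") * (genes$subgenome == "D") * config$extra_dt_lfc * m
    lfc - extra
  }

  counts <- matrix(0, ng, nrow(meta),
                   dimnames = list(genes$gene_id, meta$sample_id))
  size <- 1 / config$dispersion
  cond <- unique(meta[, c("variety", "treatment", "stage")])
  effects <- list()
  for (i in seq_len(nrow(cond))) {
    key <- sample_key(cond$variety[i], cond$treatment[i], cond$stage[i])
    effects[[key]] <- planted_effect(cond$variety[i], cond$treatment[i], cond$stage[i])
  }
  for (j in seq_len(nrow(meta))) {
    key <- sample_key(meta$variety[j], meta$treatment[j], meta$stage[j])
    mu <- 2^(baseline + effects[[key]])
    counts[, j] <- rnbinom(ng, mu = mu, size = size)
  }

  len_kb <- (genes$end - genes$start) / 1e3
  lib_m <- pmax(colSums(counts), 1) / 1e6
  fpkm <- sweep(counts / len_kb, 2, lib_m, "/")

  # Truth: planted DE direction per (variety, stage).
  de <- do.call(rbind, lapply(VARIETIES, function(v) {
    do.call(rbind, lapply(STAGES, function(s) {
      eff <- effects[[sample_key(v, "D", s)]] - effects[[sample_key(v, "C", s)]]
      data.frame(gene_id = genes$gene_id, variety = v, stage = s,
                 direction = ifelse(eff > 0, "up", ifelse(eff < 0, "down", "ns")),
                 lfc_planted = eff, stringsAsFactors = FALSE)
    }))
  }))
  rownames(de) <- NULL

  # Truth: bias state from planted means (noise-free), default bias criterion.
  bias <- NULL
  if (nrow(genome$pairs) > 0) {
    ia <- match(genome$pairs$gene_At, genes$gene_id)
    id <- match(genome$pairs$gene_Dt, genes$gene_id)
    bias <- do.call(rbind, lapply(names(effects), function(key) {
      parts <- strsplit(key, ".", fixed = TRUE)[[1]]
      lr <- (baseline[ia] + effects[[key]][ia]) - (baseline[id] + effects[[key]][id])
      data.frame(pair_id = genome$pairs$pair_id, variety = parts[1],
                 treatment = parts[2], stage = parts[3],
                 state = ifelse(lr >= 1, 1L, ifelse(lr <= -1, -1L, 0L)),
                 stringsAsFactors = FALSE)
    }))
    rownames(bias) <- NULL
  }

  out <- list(counts = counts, fpkm = fpkm, meta = meta, genes = genes,
              truth = list(class = cls, de = de, bias = bias),
              config = config)
  class(out) <- "ca_expression"
  out
}

#' @export
print.ca_expression <- function(x, ...) {
  cat(sprintf("Synthetic expression experiment: %d genes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  planted classes: %s\n",
              paste(sprintf("%s=%d", names(table(x$truth$class)),
                            table(x$truth$class)), collapse = ", ")))
  invisible(x)
}
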