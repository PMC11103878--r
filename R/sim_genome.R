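#' Generate the synthetic allotetraploid genome model
#'
#' Lays down chromosomes for the two subgenomes (named `A01..`, `D01..`),
#' places genes at non-overlapping intervals (0-based half-open), builds the
#' homoeolog pair map, and fixes the structural blueprint used by both the
#' expression and the contact-map simulators: a TAD partition per chromosome
#' and A/B compartment blocks made of whole TADs (so compartment edges
#' coincide with TAD boundaries, as they typically do in real maps). Genes are
#' placed preferentially in A-compartment bins, which makes the A compartment
#' gene-rich — the property the compartment caller's orientation rule relies
#' on.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `ca_genome`: a list with `chroms`, `genes`,
#'   `pairs`, `bins` (per-bin base compartment labels), `tads_base` and the
#'   `config` used.
#' @export
#' @examples
#' g <- simulate_genome(sim_config(seed = 1, n_genes = 100))
#' nrow(g$pairs)
simulate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stream_seed(config$seed, 1L))

  k <- config$n_chrom_per_subgenome
  chroms <- data.frame(
    chrom = c(sprintf("A%02d", seq_len(k)), sprintf("D%02d", seq_len(k))),
    subgenome = rep(c("A", "D"), each = k),
    length = config$chrom_length,
    stringsAsFactors = FALSE)

  nb <- as.integer(config$chrom_length / config$bin_size)

  # TAD partition: near-equal segments with a +-2 bin jitter, min width 4 bins.
  tads <- lapply(chroms$chrom, function(ch) {
    cuts <- round(seq(0, nb, length.out = config$n_tads_per_chrom + 1L))
    inner <- cuts[-c(1L, length(cuts))]
    jit <- inner + sample(-2:2, length(inner), replace = TRUE)
    jit <- pmin(pmax(jit, 4L), nb - 4L)
    jit <- sort(unique(jit))
    keep <- c(TRUE, diff(jit) >= 4L)
    edges <- c(0L, jit[keep], nb)
    data.frame(chrom = ch,
               start = edges[-length(edges)] * config$bin_size,
               end = edges[-1L] * config$bin_size,
               stringsAsFactors = FALSE)
  })
  tads_base <- do.call(rbind, tads)

  # Compartment blocks: runs of `compartment_period_tads` TADs, alternating
  # A, B, A, ... from the chromosome start.
  bins <- do.call(rbind, lapply(chroms$chrom, function(ch) {
    td <- tads_base[tads_base$chrom == ch, ]
    block <- ((seq_len(nrow(td)) - 1L) %/% config$compartment_period_tads)
    td_label <- ifelse(block %% 2L == 0L, "A", "B")
    start <- (seq_len(nb) - 1L) * config$bin_size
    idx <- findInterval(start, td$start)
    data.frame(chrom = ch, bin = seq_len(nb), start = start,
               end = start + config$bin_size,
               compartment = td_label[idx], stringsAsFactors = FALSE)
  }))

  # Gene placement: one gene per 5-kb slot, slots drawn with 3:1 preference
  # for A-compartment bins.
  slot_w <- 5000
  n_slots <- floor(config$chrom_length / slot_w)
  per_chrom <- distribute_counts(config$n_genes %/% 2L, k)
  genes <- list()
  for (i in seq_len(nrow(chroms))) {
    ch <- chroms$chrom[i]
    ng <- per_chrom[((i - 1L) %% k) + 1L]
    if (ng > n_slots)
      stopf("capacity error: %d genes requested on %s but only %d slots", ng, ch, n_slots)
    slot_start <- (seq_len(n_slots) - 1L) * slot_w
    slot_bin <- findInterval(slot_start, bins$start[bins$chrom == ch])
    w <- ifelse(bins$compartment[bins$chrom == ch][slot_bin] == "A", 3, 1)
    picked <- sort(sample.int(n_slots, ng, prob = w))
    gstart <- slot_start[picked] + sample(0:1000, ng, replace = TRUE)
    glen <- sample(1000:3800, ng, replace = TRUE)
    genes[[i]] <- data.frame(
      gene_id = sprintf("%sG%04d", ch, seq_len(ng)),
      chrom = ch, start = gstart, end = gstart + glen,
      subgenome = chroms$subgenome[i], stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  rownames(genes) <- NULL

  # Homoeolog pairs: rank j gene on A0i pairs with rank j gene on D0i.
  n_pairs <- round(config$homoeolog_fraction * config$n_genes / 2)
  pairs <- data.frame(pair_id = character(0), gene_At = character(0),
                      gene_Dt = character(0), stringsAsFactors = FALSE)
  if (n_pairs > 0) {
    per_chrom_pairs <- distribute_counts(n_pairs, k)
    rows <- list()
    for (i in seq_len(k)) {
      np <- min(per_chrom_pairs[i], per_chrom[i])
      if (np > 0)
        rows[[i]] <- data.frame(
          gene_At = sprintf("A%02dG%04d", i, seq_len(np)),
          gene_Dt = sprintf("D%02dG%04d", i, seq_len(np)),
          stringsAsFactors = FALSE)
    }
    pairs <- do.call(rbind, rows)
    pairs <- data.frame(pair_id = sprintf("P%04d", seq_len(nrow(pairs))), pairs,
                        stringsAsFactors = FALSE)
  }

  out <- list(chroms = chroms, genes = genes, pairs = pairs, bins = bins,
              tads_base = tads_base, config = config)
  class(out) <- "ca_genome"
  out
}

# Split n into k near-equal integer parts.
distribute_counts <- function(n, k) {
  base <- n %/% k
  extra <- n %% k
  base + (seq_len(k) <= extra)
}

#' @export
print.ca_genome <- function(x, ...) {
  cat(sprintf("Synthetic allotetraploid genome: %d chromosomes (%d per subgenome)\n",
              nrow(x$chroms), x$config$n_chrom_per_subgenome))
  cat(sprintf("  %d genes, %d homoeolog pairs, %d TADs\n",
              nrow(x$genes), nrow(x$pairs), nrow(x$tads_base)))
  invisible(x)
}

#' Per-bin gene density
#'
#' Counts genes whose interval overlaps each bin by at least 1 bp; used as the
#' orientation track for compartment calling.
#'
#' @param genes data frame with `chrom`, `start`, `end` (0-based half-open).
#' @param chrom chromosome id.
#' @param chrom_length chromosome length in bp.
#' @param bin_size bin size in bp.
#' @return numeric vector of length `chrom_length / bin_size`.
#' @export
gene_density <- function(genes, chrom, chrom_length, bin_size) {
  nb <- as.integer(chrom_length / bin_size)
  dens <- numeric(nb)
  g <- genes[genes$chrom == chrom, , drop = FALSE]
  if (nrow(g) == 0) return(dens)
  first <- pmax(floor(g$start / bin_size), 0) + 1L
  last <- pmin(ceiling(g$end / bin_size), nb)
  for (j in seq_len(nrow(g))) {
    idx <- first[j]:last[j]
    dens[idx] <- dens[idx] + 1
  }
  dens
}
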