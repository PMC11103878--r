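#' Simulate Hi-C contact maps with planted structures
#'
#' Builds one symmetric, non-negative contact matrix per chromosome for each
#' (variety, treatment, stage) condition (replicates are merged, as Hi-C
#' replicates were in the study design being emulated). Each matrix is
#' `distance-decay background x compartment checkerboard factor x intra-TAD
#' enrichment x multiplicative log-normal noise`. Drought samples carry planted
#' events: each fusion removes one internal TAD boundary (merging two adjacent
#' same-compartment TADs into one) and each Neo-TAD event inserts a boundary at
#' a TAD midpoint (splitting it in two). Events are planted only on the first
#' chromosome of each subgenome, leaving the remaining chromosomes as negative
#' controls. Under drought the first `switch_blocks_per_chrom` A-compartment
#' blocks per chromosome flip to B from MD onward; at RW the flip persists in
#' the sensitive variety and reverts in the tolerant one.
#'
#' @param genome a [simulate_genome()] result.
#' @param config the [sim_config()]; defaults to the one inside `genome`.
#' @return object of class `ca_contacts`: `samples`, a named list (key
#'   `variety.treatment.stage`) each holding `matrices` (per chromosome),
#'   `tads`, `compartments` (per-chromosome per-bin labels) and the design
#'   fields; and `truth` with per-sample TAD sets, compartment labels and the
#'   planted `events` table (sample key, type, chrom, changed boundary).
#' @export
simulate_contact_maps <- function(genome, config = genome$config) {
  stopifnot(inherits(genome, "ca_genome"))
  if (config$chrom_length %% config$bin_size != 0)
    stopf("bin_size must divide chrom_length")

  nb <- as.integer(config$chrom_length / config$bin_size)
  event_chroms <- genome$chroms$chrom[!duplicated(genome$chroms$subgenome)]
  cond <- unique(config$design[, c("variety", "treatment", "stage")])
  rownames(cond) <- NULL

  samples <- list()
  events <- list()
  for (i in seq_len(nrow(cond))) {
    v <- cond$variety[i]; tr <- cond$treatment[i]; st <- cond$stage[i]
    key <- sample_key(v, tr, st)
    set.seed(stream_seed(config$seed, 100L + i))

    tads <- genome$tads_base
    ev <- NULL
    if (tr == "D" && (config$n_fusion > 0 || config$n_neo > 0)) {
      planted <- plant_tad_events(tads, genome$bins, event_chroms, config)
      tads <- planted$tads
      if (nrow(planted$events)) {
        ev <- planted$events
        ev$sample <- key
        ev$variety <- v
        ev$stage <- st
      }
    }

    labels <- lapply(genome$chroms$chrom, function(ch)
      genome$bins$compartment[genome$bins$chrom == ch])
    names(labels) <- genome$chroms$chrom
    flipped <- tr == "D" && (st %in% c("MD", "SD") || (st == "RW" && v == "sensitive"))
    if (flipped && config$switch_blocks_per_chrom > 0) {
      nms <- names(labels)
      labels <- lapply(labels, flip_leading_a_blocks,
                       n_blocks = config$switch_blocks_per_chrom)
      names(labels) <- nms
    }

    mats <- lapply(genome$chroms$chrom, function(ch) {
      build_contact_matrix(nb, config,
                           tads[tads$chrom == ch, , drop = FALSE],
                           labels[[ch]])
    })
    names(mats) <- genome$chroms$chrom

    samples[[key]] <- list(variety = v, treatment = tr, stage = st, key = key,
                           matrices = mats, tads = tads, compartments = labels)
    if (!is.null(ev)) events[[key]] <- ev
  }

  events <- if (length(events)) do.call(rbind, events) else
    data.frame(type = character(0), chrom = character(0), boundary = numeric(0),
               span_start = numeric(0), span_end = numeric(0),
               sample = character(0), variety = character(0),
               stage = character(0), stringsAsFactors = FALSE)
  rownames(events) <- NULL

  out <- list(samples = samples,
              truth = list(
                tads = lapply(samples, `[[`, "tads"),
                compartments = lapply(samples, `[[`, "compartments"),
                events = events),
              config = config)
  class(out) <- "ca_contacts"
  out
}

# Flip the first n A-labelled blocks (maximal runs of "A") of a label vector.
flip_leading_a_blocks <- function(labels, n_blocks) {
  r <- rle(labels)
  a_idx <- which(r$values == "A")
  flip <- head(a_idx, n_blocks)
  r$values[flip] <- "B"
  inverse.rle(r)
}

# Choose and apply fusion / neo events on the eligible chromosomes.
# Fusions merge two adjacent TADs sharing a compartment label; neo events
# split a wide TAD (>= 6 bins) at its middle bin edge. TADs already used by
# an event are excluded from further events (leftmost-first tie-break after a
# random shuffle for variety across samples).
plant_tad_events <- function(tads, bins, event_chroms, config) {
  bs <- config$bin_size
  td <- tads[tads$chrom %in% event_chroms, , drop = FALSE]
  td <- td[order(td$chrom, td$start), ]
  td$label <- vapply(seq_len(nrow(td)), function(j) {
    b <- bins[bins$chrom == td$chrom[j], ]
    b$compartment[findInterval(td$start[j], b$start)]
  }, character(1))
  td$id <- seq_len(nrow(td))

  adj <- which(td$chrom[-nrow(td)] == td$chrom[-1] &
               td$end[-nrow(td)] == td$start[-1] &
               td$label[-nrow(td)] == td$label[-1])
  used <- logical(nrow(td))
  ev <- list()

  pick <- sample(adj)
  n_fused <- 0L
  fuse_rows <- integer(0)
  for (j in pick) {
    if (n_fused >= config$n_fusion) break
    if (used[j] || used[j + 1L]) next
    used[c(j, j + 1L)] <- TRUE
    fuse_rows <- c(fuse_rows, j)
    n_fused <- n_fused + 1L
    ev[[length(ev) + 1L]] <- data.frame(
      type = "fusion", chrom = td$chrom[j], boundary = td$end[j],
      span_start = td$start[j], span_end = td$end[j + 1L],
      stringsAsFactors = FALSE)
  }
  if (n_fused < config$n_fusion)
    stopf("capacity error: only %d fusable TAD pairs available (%d requested)",
          n_fused, config$n_fusion)

  wide <- which(!used & (td$end - td$start) >= 6 * bs)
  pick <- sample(wide)
  n_neo <- 0L
  neo_rows <- integer(0)
  neo_cut <- numeric(0)
  for (j in pick) {
    if (n_neo >= config$n_neo) break
    used[j] <- TRUE
    cut <- td$start[j] + floor(((td$end[j] - td$start[j]) / bs) / 2) * bs
    neo_rows <- c(neo_rows, j)
    neo_cut <- c(neo_cut, cut)
    n_neo <- n_neo + 1L
    ev[[length(ev) + 1L]] <- data.frame(
      type = "neo", chrom = td$chrom[j], boundary = cut,
      span_start = td$start[j], span_end = td$end[j],
      stringsAsFactors = FALSE)
  }
  if (n_neo < config$n_neo)
    stopf("capacity error: only %d splittable TADs available (%d requested)",
          n_neo, config$n_neo)

  # Apply: merge fusion pairs, split neo TADs.
  keep <- tads
  for (j in fuse_rows) {
    sel <- keep$chrom == td$chrom[j] & keep$start %in% c(td$start[j], td$start[j + 1L])
    keep <- keep[!sel, ]
    keep <- rbind(keep, data.frame(chrom = td$chrom[j], start = td$start[j],
                                   end = td$end[j + 1L], stringsAsFactors = FALSE))
  }
  for (idx in seq_along(neo_rows)) {
    j <- neo_rows[idx]
    sel <- keep$chrom == td$chrom[j] & keep$start == td$start[j] & keep$end == td$end[j]
    keep <- keep[!sel, ]
    keep <- rbind(keep,
                  data.frame(chrom = td$chrom[j], start = td$start[j],
                             end = neo_cut[idx], stringsAsFactors = FALSE),
                  data.frame(chrom = td$chrom[j], start = neo_cut[idx],
                             end = td$end[j], stringsAsFactors = FALSE))
  }
  keep <- keep[order(keep$chrom, keep$start), ]
  rownames(keep) <- NULL
  list(tads = keep, events = do.call(rbind, ev))
}

# Dense symmetric contact matrix for one chromosome.
build_contact_matrix <- function(nb, config, tads, labels) {
  bs <- config$bin_size
  idx <- seq_len(nb)
  d <- abs(outer(idx, idx, "-"))
  m <- (d + 1)^(-config$decay_exponent)

  same_comp <- outer(labels, labels, "==")
  m <- m * ifelse(same_comp, 1 + config$compartment_amplitude,
                  1 - config$compartment_amplitude)

  tad_id <- rep(NA_integer_, nb)
  start_bin <- tads$start / bs + 1L
  end_bin <- tads$end / bs
  for (j in seq_len(nrow(tads))) tad_id[start_bin[j]:end_bin[j]] <- j
  same_tad <- outer(tad_id, tad_id, "==") & !is.na(outer(tad_id, tad_id, "+"))
  m[same_tad] <- m[same_tad] * config$tad_enrichment

  if (config$noise_sd > 0) {
    e <- matrix(rnorm(nb * nb, 0, config$noise_sd), nb, nb)
    e[lower.tri(e)] <- t(e)[lower.tri(e)]
    m <- m * exp(e)
  }
  m <- (m + t(m)) / 2   # guard against numeric asymmetry
  attr(m, "bin_size") <- bs
  m
}

#' @export
print.ca_contacts <- function(x, ...) {
  cat(sprintf("Synthetic contact maps: %d samples x %d chromosomes (%d bins each)\n",
              length(x$samples), length(x$samples[[1]]$matrices),
              nrow(x$samples[[1]]$matrices[[1]])))
  cat(sprintf("  planted events: %d fusion, %d neo\n",
              sum(x$truth$events$type == "fusion"), sum(x$truth$events$type == "neo")))
  invisible(x)
}

#' Run the whole synthetic study
#'
#' Convenience wrapper generating genome, expression and contact maps from one
#' configuration.
#'
#' @param config a [sim_config()].
#' @return list with `genome`, `expression`, `contacts`.
#' @export
simulate_study <- function(config = sim_config()) {
  genome <- simulate_genome(config)
  list(genome = genome,
       expression = simulate_expression(genome, config),
       contacts = simulate_contact_maps(genome, config))
}
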