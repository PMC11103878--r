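#' First-eigenvector track of a contact matrix
#'
#' Standard A/B compartment pipeline: the matrix is normalised to
#' observed/expected using the per-distance mean as the expected value, the
#' Pearson correlation matrix of the normalised matrix is computed, and the
#' first principal component (leading eigenvector of the correlation matrix)
#' is extracted. Bins with zero coverage, or with zero variance after
#' normalisation, are masked. The eigenvector's sign is arbitrary, so it is
#' oriented with a gene-density track: the sign is chosen so that the
#' correlation between the track and the density is positive (A = gene rich);
#' negating the orientation track therefore flips every sign. When the leading
#' eigenvalue explains little of the total variance (no plaid pattern, e.g. a
#' pure distance-decay matrix) the result carries a `low_signal` flag.
#'
#' @param mat square symmetric contact matrix (non-negative).
#' @param orientation per-bin gene density (or any reference track where
#'   higher = A-like).
#' @param min_unmasked minimum number of unmasked bins required.
#' @param low_signal_varexp variance-explained threshold below which the
#'   low-signal flag is raised.
#' @return list of class `ca_eigentrack`: `values` (per-bin PC1, NA where
#'   masked), `valid` (logical), `varexp`, `low_signal`.
#' @export
compute_eigentrack <- function(mat, orientation, min_unmasked = 10,
                               low_signal_varexp = 0.1) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (ncol(mat) != n) stopf("contact matrix must be square")
  if (length(orientation) != n)
    stopf("orientation track length (%d) != bin count (%d)", length(orientation), n)
  if (all(mat == 0)) stopf("degenerate input: all-zero contact matrix")
  keep <- rowSums(mat) > 0
  if (sum(keep) < min_unmasked)
    stopf("fewer than %d unmasked bins", min_unmasked)

  m <- mat[keep, keep, drop = FALSE]
  nb <- nrow(m)
  d <- abs(outer(seq_len(nb), seq_len(nb), "-"))
  expected <- vapply(0:(nb - 1), function(k) mean(m[d == k]), numeric(1))
  oe <- m / expected[d + 1]
  oe[!is.finite(oe)] <- 0

  cc <- suppressWarnings(stats::cor(oe))
  const <- apply(oe, 2, function(x) stats::sd(x) == 0) | apply(is.na(cc), 2, all)
  if (all(const)) {
    # uniform observed/expected (e.g. pure distance decay): no plaid pattern,
    # no compartment information
    out <- list(values = rep(NA_real_, n), valid = rep(FALSE, n),
                varexp = NA_real_, low_signal = TRUE)
    class(out) <- "ca_eigentrack"
    return(out)
  }
  if (any(const)) {
    sub <- which(!const)
    if (length(sub) < min_unmasked) stopf("fewer than %d informative bins", min_unmasked)
    cc <- cc[sub, sub]
  } else sub <- seq_len(nb)
  cc[is.na(cc)] <- 0

  eg <- eigen(cc, symmetric = TRUE)
  v <- eg$vectors[, 1]
  varexp <- eg$values[1] / sum(pmax(eg$values, 0))

  values <- rep(NA_real_, n)
  values[which(keep)[sub]] <- v
  valid <- !is.na(values)

  orient_cor <- suppressWarnings(stats::cor(values[valid], orientation[valid]))
  if (!is.na(orient_cor) && orient_cor < 0) values <- -values

  out <- list(values = values, valid = valid, varexp = varexp,
              low_signal = is.na(varexp) || varexp < low_signal_varexp)
  class(out) <- "ca_eigentrack"
  out
}

#' Call A/B compartments from an eigenvector track
#'
#' Applies the sign rule: a bin is A when its eigenvector value is strictly
#' positive and B when strictly negative. A value of exactly zero carries no
#' compartment information under the strict-inequality rule, so it is masked,
#' as are bins masked in the track itself.
#'
#' @param track a [compute_eigentrack()] result, or a plain numeric vector.
#' @return character vector of per-bin labels `A`/`B`/`masked`.
#' @export
#' @examples
#' call_compartments(c(0.3, -0.2, 0, NA))
call_compartments <- function(track) {
  v <- if (inherits(track, "ca_eigentrack")) track$values else as.numeric(track)
  ifelse(is.na(v), "masked", ifelse(v > 0, "A", ifelse(v < 0, "B", "masked")))
}

#' Group of a four-stage compartment switch string
#'
#' Maps each four-letter string over `{A, B}` (stage order ID, MD, SD, RW) to
#' its switch group: `stable` (AAAA, BBBB), `AB` (ends B after starting A:
#' AAAB, ABAB, AABB, ABBB), `BA` (BAAA, BABA, BBAA, BBBA), `ABA` (starts and
#' ends A with a B excursion: ABBA, ABAA, AABA) and `BAB` (BAAB, BABB, BBAB).
#' The 16 strings partition as stable 2, AB 4, BA 4, ABA 3, BAB 3.
#'
#' @param pattern character vector of four-letter strings over `{A, B}`.
#' @return character vector of groups.
#' @export
#' @examples
#' switch_group(c("AAAA", "ABBA", "AABB"))
switch_group <- function(pattern) {
  if (any(nchar(pattern) != 4L) || any(grepl("[^AB]", pattern)))
    stopf("patterns must be four-letter strings over {A, B}")
  first <- substr(pattern, 1, 1)
  last <- substr(pattern, 4, 4)
  constant <- pattern %in% c("AAAA", "BBBB")
  ifelse(constant, "stable",
  ifelse(first == "A" & last == "B", "AB",
  ifelse(first == "B" & last == "A", "BA",
  ifelse(first == "A", "ABA", "BAB"))))
}

#' Classify four-stage compartment switch patterns
#'
#' Builds the per-bin four-letter string from compartment tracks of the four
#' stages (order ID, MD, SD, RW) and assigns each bin to its switch group.
#' Bins masked in any stage are excluded. Span totals per group are reported
#' in Mb.
#'
#' @param tracks list of four per-bin label vectors (`A`/`B`/`masked`) on
#'   identical binning, ordered ID, MD, SD, RW.
#' @param bin_size bin size in bp.
#' @return list with `bins` (data frame: `bin`, `pattern`, `group`) and
#'   `span_mb` (named numeric, total Mb per group).
#' @export
classify_switch_patterns <- function(tracks, bin_size) {
  if (length(tracks) != 4L) stopf("four stage tracks are required")
  n <- unique(vapply(tracks, length, integer(1)))
  if (length(n) != 1L) stopf("binning mismatch between stage tracks")
  ok <- Reduce(`&`, lapply(tracks, function(x) x %in% c("A", "B")))
  pattern <- paste0(tracks[[1]], tracks[[2]], tracks[[3]], tracks[[4]])[ok]
  bins <- data.frame(bin = which(ok), pattern = pattern,
                     group = switch_group(pattern), stringsAsFactors = FALSE)
  groups <- c("stable", "AB", "BA", "ABA", "BAB")
  span <- vapply(groups, function(g) sum(bins$group == g) * bin_size / 1e6,
                 numeric(1))
  list(bins = bins, span_mb = span)
}

#' Associate compartment-switching bins with genes and differential expression
#'
#' A gene belongs to a switch region when its interval overlaps a switching
#' bin by at least 1 bp (0-based half-open arithmetic). The association with
#' differential expression is tested with a 2x2 chi-square on (inside/outside
#' switch region) x (differential/ns).
#'
#' @param switch_bins data frame of switching bins: `chrom`, `start`, `end`,
#'   `group` (non-stable groups).
#' @param genes gene intervals: `gene_id`, `chrom`, `start`, `end`.
#' @param de_calls differential calls with `gene_id` and `direction`.
#' @param correct continuity correction for the chi-square.
#' @return list with `genes_by_group` (named list of gene ids), `table` (2x2),
#'   `chisq` ([chi_square_2x2()] result).
#' @export
associate_switches_with_genes <- function(switch_bins, genes, de_calls,
                                          correct = FALSE) {
  if (nrow(genes) == 0) stopf("empty gene set")
  in_group <- rep(NA_character_, nrow(genes))
  for (g in unique(switch_bins$group)) {
    sb <- switch_bins[switch_bins$group == g, , drop = FALSE]
    hit <- vapply(seq_len(nrow(genes)), function(i) {
      s <- sb[sb$chrom == genes$chrom[i], , drop = FALSE]
      nrow(s) > 0 && any(interval_overlap(genes$start[i], genes$end[i],
                                          s$start, s$end) >= 1)
    }, logical(1))
    in_group[hit & is.na(in_group)] <- g
  }
  genes_by_group <- split(genes$gene_id, in_group)

  de <- de_calls$direction[match(genes$gene_id, de_calls$gene_id)]
  de[is.na(de)] <- "ns"
  in_switch <- !is.na(in_group)
  tab <- rbind(inside  = c(sum(in_switch & de != "ns"), sum(in_switch & de == "ns")),
               outside = c(sum(!in_switch & de != "ns"), sum(!in_switch & de == "ns")))
  colnames(tab) <- c("differential", "ns")
  list(genes_by_group = genes_by_group, table = tab,
       chisq = chi_square_2x2(tab, correct = correct))
}
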