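#' Differential expression between drought and control arms
#'
#' Internal differential caller used for synthetic experiments: a Welch t-test
#' on log2(x + 1) across replicates, per gene, with Benjamini-Hochberg
#' correction. It is a deliberately minimal stand-in for a dedicated count
#' model — real studies should load their own differential tables with
#' [as_differential_calls()]; only the direction/threshold contract matters
#' downstream. A gene is called `up`/`down` when its adjusted p-value is at
#' most `alpha`, its |log2 fold change| reaches `lfc_threshold`, and the fold
#' change is non-zero; otherwise `ns`.
#'
#' @param mat genes x samples abundance matrix (FPKM-like or counts).
#' @param meta sample sheet with `sample_id`, `variety`, `treatment`, `stage`.
#' @param variety,stage the contrast cell: drought (D) vs control (C) at one
#'   stage within one variety.
#' @param alpha adjusted-p cutoff in (0, 1].
#' @param lfc_threshold minimum |log2 fold change|.
#' @return data frame: `gene_id`, `stage`, `log2fc`, `pvalue`, `padj`,
#'   `direction` in `up`/`down`/`ns`.
#' @export
call_differential <- function(mat, meta, variety, stage, alpha = 0.05,
                              lfc_threshold = 1) {
  check_stage(stage)
  if (alpha <= 0 || alpha > 1) stopf("alpha must be in (0, 1]")
  d_cols <- meta$sample_id[meta$variety == variety & meta$stage == stage &
                             meta$treatment == "D"]
  c_cols <- meta$sample_id[meta$variety == variety & meta$stage == stage &
                             meta$treatment == "C"]
  if (length(d_cols) == 0 || length(c_cols) == 0)
    stopf("contrast arm with zero samples for %s/%s", variety, stage)

  x <- log2(mat[, d_cols, drop = FALSE] + 1)
  y <- log2(mat[, c_cols, drop = FALSE] + 1)
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  lfc <- mx - my
  vx <- apply(x, 1, var); vy <- apply(y, 1, var)
  if (nx < 2 || ny < 2) { vx[] <- NA; vy[] <- NA }

  se2 <- vx / nx + vy / ny
  p <- rep(NA_real_, nrow(mat))
  zero_se <- !is.na(se2) & se2 == 0
  p[zero_se] <- ifelse(lfc[zero_se] == 0, 1, 0)   # degenerate noise-free limit
  ok <- !is.na(se2) & se2 > 0
  tt <- lfc[ok] / sqrt(se2[ok])
  df <- se2[ok]^2 / ((vx[ok] / nx)^2 / (nx - 1) + (vy[ok] / ny)^2 / (ny - 1))
  p[ok] <- 2 * pt(-abs(tt), df)
  p[is.na(p)] <- 1

  padj <- p.adjust(p, method = "BH")
  direction <- ifelse(padj <= alpha & abs(lfc) >= lfc_threshold & lfc != 0,
                      ifelse(lfc > 0, "up", "down"), "ns")
  data.frame(gene_id = rownames(mat), stage = stage, log2fc = lfc,
             pvalue = p, padj = padj, direction = direction,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Validate an externally produced differential table
#'
#' Checks the column contract (`gene_id`, `stage`, `log2fc`, `padj`,
#' `direction`) and the direction invariant: a non-`ns` call must have
#' `padj <= alpha` and a fold change of the matching sign.
#'
#' @param calls data frame of differential calls.
#' @param alpha the cutoff the table was produced with.
#' @return the validated data frame.
#' @export
as_differential_calls <- function(calls, alpha = 0.05) {
  need <- c("gene_id", "stage", "log2fc", "padj", "direction")
  if (!all(need %in% names(calls)))
    stopf("differential table must have columns: %s", paste(need, collapse = ", "))
  check_stage(unique(calls$stage))
  bad <- calls$direction != "ns" &
    (calls$padj > alpha |
       sign(calls$log2fc) != ifelse(calls$direction == "up", 1, -1))
  if (any(bad))
    stopf("%d rows violate the direction invariant (padj <= alpha, sign match)",
          sum(bad))
  calls
}

#' Call drought-induced genes
#'
#' A gene is drought-induced when it is differentially expressed in at least
#' one of the drought stages (ID, MD, SD) and every stage in which it is
#' called shares one direction (all up or all down). The RW stage is reserved
#' for the recovery analysis and is not consulted here.
#'
#' @param calls differential calls covering stages ID, MD and SD for one
#'   variety (rows with other stages are ignored).
#' @return data frame: `gene_id`, `direction`, `supporting` (comma-separated
#'   stages), `n_stages`.
#' @export
call_drought_induced <- function(calls) {
  drought_stages <- c("ID", "MD", "SD")
  missing <- setdiff(drought_stages, unique(calls$stage))
  if (length(missing))
    stopf("missing differential table for stage(s): %s",
          paste(missing, collapse = ", "))
  calls <- calls[calls$stage %in% drought_stages, ]
  sig <- calls[calls$direction != "ns", ]
  if (nrow(sig) == 0)
    return(data.frame(gene_id = character(0), direction = character(0),
                      supporting = character(0), n_stages = integer(0),
                      stringsAsFactors = FALSE))
  sp <- split(sig, sig$gene_id)
  rows <- lapply(sp, function(g) {
    if (length(unique(g$direction)) != 1L) return(NULL)
    st <- drought_stages[drought_stages %in% g$stage]
    data.frame(gene_id = g$gene_id[1], direction = g$direction[1],
               supporting = paste(st, collapse = ","),
               n_stages = length(st), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$gene_id), , drop = FALSE]
}

#' Classify post-rewatering recovery of drought-induced genes
#'
#' An induced gene counts as recovered when it is no longer differential
#' (`ns`) at the RW stage and as still-differential otherwise. Induced genes
#' absent from the RW table are reported as missing, never silently dropped;
#' recovered + still-differential + missing partitions the induced set.
#'
#' @param induced result of [call_drought_induced()].
#' @param rw_calls differential calls at the RW stage for the same variety.
#' @return list with `genes` (per-gene status), `recovered`,
#'   `still_differential`, `missing` counts.
#' @export
classify_recovery <- function(induced, rw_calls) {
  rw <- rw_calls[rw_calls$stage == "RW", ]
  if (nrow(rw) == 0) stopf("missing differential table for stage(s): RW")
  idx <- match(induced$gene_id, rw$gene_id)
  status <- ifelse(is.na(idx), "missing",
                   ifelse(rw$direction[idx] == "ns", "recovered",
                          "still_differential"))
  genes <- data.frame(gene_id = induced$gene_id, direction = induced$direction,
                      rw_status = status, stringsAsFactors = FALSE)
  list(genes = genes,
       recovered = sum(status == "recovered"),
       still_differential = sum(status == "still_differential"),
       missing = sum(status == "missing"))
}

#' Two-variety recovery contingency table
#'
#' Assembles the 2x2 table (variety x recovered/still-differential) compared
#' in the recovery analysis.
#'
#' @param rec_a,rec_b [classify_recovery()] results for the two varieties.
#' @param names row names for the table.
#' @return a 2x2 integer matrix.
#' @export
recovery_table <- function(rec_a, rec_b, names = c("variety_a", "variety_b")) {
  m <- rbind(c(rec_a$recovered, rec_a$still_differential),
             c(rec_b$recovered, rec_b$still_differential))
  dimnames(m) <- list(names, c("recovered", "still_differential"))
  m
}

#' Pearson chi-square test on a 2x2 table
#'
#' One degree of freedom, optional Yates continuity correction, upper-tail
#' p-value. Errors on a zero marginal (the statistic is undefined there).
#'
#' @param table 2x2 matrix of non-negative counts.
#' @param correct apply the Yates continuity correction.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
#' @examples
#' chi_square_2x2(rbind(c(8109, 14497), c(3326, 16226)))$p_value
chi_square_2x2 <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2L, 2L))) stopf("table must be 2x2")
  if (any(table < 0) || any(!is.finite(table))) stopf("cells must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stopf("undefined test: a marginal of the 2x2 table is zero")
  ht <- suppressWarnings(stats::chisq.test(table, correct = correct))
  list(statistic = unname(ht$statistic), p_value = unname(ht$p.value),
       df = unname(ht$parameter))
}

#' Count expressed genes
#'
#' Descriptive helper: genes whose abundance reaches `threshold` in at least
#' one sample of each column group.
#'
#' @param mat genes x samples abundance matrix.
#' @param threshold expressed-gene cutoff (default 1, FPKM-like scale).
#' @return integer count of expressed genes.
#' @export
count_expressed <- function(mat, threshold = 1) {
  sum(apply(mat, 1, function(x) any(x >= threshold)))
}
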