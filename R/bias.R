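#' Direction category of a homoeolog pair at one stage
#'
#' Classifies each pair by the differential-expression directions of its two
#' homoeologs (drought vs control): `common` when both are `ns` or both move
#' in the same direction, `single` when exactly one is differential, and
#' `opposite` when both are differential in opposing directions.
#'
#' @param dir_at,dir_dt direction calls (`up`/`down`/`ns`) of the A- and
#'   D-subgenome homoeologs; vectorized, equal length, no missing values.
#' @return character vector in `common`/`single`/`opposite`.
#' @export
#' @examples
#' classify_pair_direction(c("up", "up", "up"), c("up", "ns", "down"))
classify_pair_direction <- function(dir_at, dir_dt) {
  if (length(dir_at) != length(dir_dt))
    stopf("homoeolog call vectors must have equal length")
  if (anyNA(dir_at) || anyNA(dir_dt))
    stopf("missing homoeolog call")
  ok <- c("up", "down", "ns")
  if (!all(dir_at %in% ok) || !all(dir_dt %in% ok))
    stopf("directions must be up/down/ns")
  ifelse(dir_at == "ns" & dir_dt == "ns", "common",
  ifelse(dir_at == dir_dt, "common",
  ifelse(dir_at == "ns" | dir_dt == "ns", "single", "opposite")))
}

#' Call the subgenome bias state of homoeolog pairs
#'
#' For one condition, the bias state is +1 (A-subgenome biased) when
#' `log2((At + eps) / (Dt + eps)) >= lfc_cut`, -1 (D-biased) when it is at most
#' `-lfc_cut`, and 0 (no bias) otherwise. Pairs in which both homoeologs fall
#' below `min_expr` are set to 0. The criterion is a ratio cutoff — the three
#' knobs are deliberately explicit because published pair counts depend on
#' them.
#'
#' @param at,dt non-negative expression of the A- and D-subgenome homoeologs.
#' @param min_expr minimum expression required in at least one homoeolog.
#' @param lfc_cut |log2 ratio| threshold.
#' @param eps pseudocount.
#' @return integer vector of states in `{-1, 0, +1}`.
#' @export
#' @examples
#' call_bias(8, 2)          # +1
#' call_bias(5, 5)          # 0
call_bias <- function(at, dt, min_expr = 1, lfc_cut = 1, eps = 0.1) {
  if (any(at < 0) || any(dt < 0)) stopf("expression values must be non-negative")
  lr <- log2((at + eps) / (dt + eps))
  state <- ifelse(lr >= lfc_cut, 1L, ifelse(lr <= -lfc_cut, -1L, 0L))
  state[at < min_expr & dt < min_expr] <- 0L
  state
}

#' Classify bias dynamics across the four stages
#'
#' A pair is `stableAtbias` when the A homoeolog's expression is strictly
#' higher than the D homoeolog's in all four stages, `stableDtbias` in the
#' mirrored case, and `dynamic` otherwise. Exact ties count as "not higher",
#' so an all-tie pair is dynamic.
#'
#' @param at_by_stage,dt_by_stage numeric matrices (pairs x 4 stages, columns
#'   ordered ID, MD, SD, RW) of homoeolog expression in one (variety,
#'   treatment) context.
#' @return character vector in `stableAtbias`/`stableDtbias`/`dynamic`.
#' @export
classify_bias_dynamics <- function(at_by_stage, dt_by_stage) {
  at_by_stage <- as.matrix(at_by_stage)
  dt_by_stage <- as.matrix(dt_by_stage)
  if (ncol(at_by_stage) != 4L || ncol(dt_by_stage) != 4L)
    stopf("all four stages are required")
  if (!identical(dim(at_by_stage), dim(dt_by_stage)))
    stopf("homoeolog matrices must have identical shape")
  at_all <- rowSums(at_by_stage > dt_by_stage) == 4L
  dt_all <- rowSums(dt_by_stage > at_by_stage) == 4L
  ifelse(at_all, "stableAtbias", ifelse(dt_all, "stableDtbias", "dynamic"))
}

#' Bias-change index and genome-wide bias value
#'
#' The bias-change index of a pair is its drought bias state minus its control
#' bias state (states coded Atbias = +1, nobias = 0, Dtbias = -1), so each
#' index lies in -2..+2. The genome-wide bias value is the sum of the indices
#' over all pairs: positive means the genome shifted toward A-subgenome
#' expression under drought, negative toward the D subgenome, and the absolute
#' value measures the strength of the shift.
#'
#' @param control_state,drought_state integer bias states in `{-1, 0, +1}` for
#'   the same (variety, stage) condition.
#' @return `bias_change_index`: integer vector; `genome_bias_value`: a single
#'   integer sum.
#' @export
#' @examples
#' bias_change_index(c(1, -1, 0), c(0, 1, 0))
#' genome_bias_value(c(1, -1, 0), c(0, 1, 0))
bias_change_index <- function(control_state, drought_state) {
  if (length(control_state) != length(drought_state))
    stopf("mismatched condition keys: state vectors differ in length")
  ok <- c(-1L, 0L, 1L)
  if (!all(control_state %in% ok) || !all(drought_state %in% ok))
    stopf("bias states must be -1, 0 or +1")
  as.integer(drought_state) - as.integer(control_state)
}

#' @rdname bias_change_index
#' @export
genome_bias_value <- function(control_state, drought_state) {
  sum(bias_change_index(control_state, drought_state))
}

#' Per-condition bias table for a synthetic or real experiment
#'
#' Convenience wrapper: computes replicate-mean expression per condition for
#' each homoeolog pair and the resulting bias state, for every (variety,
#' treatment, stage) cell.
#'
#' @param pairs pair map (`pair_id`, `gene_At`, `gene_Dt`).
#' @param mat genes x samples abundance matrix.
#' @param meta sample sheet (`sample_id`, `variety`, `treatment`, `stage`).
#' @param ... passed to [call_bias()].
#' @return data frame: `pair_id`, `variety`, `treatment`, `stage`, `at`, `dt`,
#'   `state`. Pairs with a homoeolog absent from the matrix are excluded and
#'   reported via the `n_excluded` attribute.
#' @export
bias_table <- function(pairs, mat, meta, ...) {
  present <- pairs$gene_At %in% rownames(mat) & pairs$gene_Dt %in% rownames(mat)
  excluded <- sum(!present)
  pairs <- pairs[present, , drop = FALSE]
  cond <- unique(meta[, c("variety", "treatment", "stage")])
  out <- do.call(rbind, lapply(seq_len(nrow(cond)), function(i) {
    cols <- meta$sample_id[meta$variety == cond$variety[i] &
                             meta$treatment == cond$treatment[i] &
                             meta$stage == cond$stage[i]]
    at <- rowMeans(mat[pairs$gene_At, cols, drop = FALSE])
    dt <- rowMeans(mat[pairs$gene_Dt, cols, drop = FALSE])
    data.frame(pair_id = pairs$pair_id, variety = cond$variety[i],
               treatment = cond$treatment[i], stage = cond$stage[i],
               at = unname(at), dt = unname(dt),
               state = call_bias(at, dt, ...),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "n_excluded") <- excluded
  out
}
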