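# Internal helpers shared across modules.

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Derive an independent RNG stream seed from the master seed. Streams keep the
# genome / expression / contact families decoupled, so adding one output never
# perturbs another. Kept below 2^31 - 1 (R integer range).
stream_seed <- function(seed, stream) {
  s <- (as.double(seed) %% 2147483647) * 48271 + as.double(stream) * 10007
  as.integer(s %% 2147483629) + 1L
}

# Overlap length of two 0-based half-open intervals; <= 0 means no overlap.
interval_overlap <- function(s1, e1, s2, e2) {
  pmin(e1, e2) - pmax(s1, s2)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stopf("'%s' must be a single number", name)
  if (strict && x <= min) stopf("'%s' must be > %g", name, min)
  if (!strict && x < min) stopf("'%s' must be >= %g", name, min)
  invisible(x)
}

check_fraction <- function(x, name) {
  check_number(x, name)
  if (x < 0 || x > 1) stopf("'%s' must lie in [0, 1]", name)
  invisible(x)
}

#' Closed vocabularies of the study design
#'
#' Stage, treatment and variety levels used throughout: stages ID (initial
#' drought), MD (mild), SD (severe), RW (re-water); treatments C (control) and
#' D (drought); varieties sensitive and tolerant.
#' @name design_levels
#' @format `STAGES`, `TREATMENTS` and `VARIETIES` are character vectors of the
#'   design levels, in canonical order.
NULL

#' @rdname design_levels
#' @export
STAGES <- c("ID", "MD", "SD", "RW")

#' @rdname design_levels
#' @export
TREATMENTS <- c("C", "D")

#' @rdname design_levels
#' @export
VARIETIES <- c("sensitive", "tolerant")

check_stage <- function(stage) {
  if (!all(stage %in% STAGES)) stopf("unknown stage(s): %s",
                                     paste(setdiff(stage, STAGES), collapse = ", "))
  invisible(stage)
}

#' Canonical sample-condition key
#'
#' Builds the `variety.treatment.stage` key used to index per-condition
#' results (for example the sample lists of [simulate_contact_maps()]).
#'
#' @param variety,treatment,stage design levels (see [design_levels]).
#' @return character vector of keys.
#' @export
#' @examples
#' sample_key("sensitive", "D", "MD")
sample_key <- function(variety, treatment, stage) {
  paste(variety, treatment, stage, sep = ".")
}
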