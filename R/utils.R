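# Internal helpers shared across modules.

`%||%` <- rlang::`%||%`

assert_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

assert_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  as.numeric(x)
}

# Event-stream column contract used throughout: patient_id, date, code_type, code.
STREAM_COLS <- c("patient_id", "date", "code_type", "code")
CODE_TYPES <- c("DIAG", "MED", "LAB_ABN")

assert_stream <- function(stream, arg = "stream") {
  if (!is.data.frame(stream)) abort(sprintf("`%s` must be a data frame.", arg))
  missing <- setdiff(STREAM_COLS, names(stream))
  if (length(missing)) {
    abort(sprintf("`%s` is missing column(s): %s.", arg, paste(missing, collapse = ", ")))
  }
  invisible(stream)
}

#' Area under the ROC curve by the rank (Mann-Whitney) statistic
#'
#' Tie-aware AUROC: average ranks are used, so tied scores contribute 1/2.
#'
#' @param scores Numeric vector of predicted risks.
#' @param labels Binary vector (0/1 or logical) of outcomes, same length.
#' @return A single number in \[0, 1\].
#' @export
#' @examples
#' auroc(c(.9, .8, .7, .1), c(1, 1, 0, 0))
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) abort("`scores` and `labels` differ in length.")
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) abort("AUROC is undefined: both classes must be present.")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

sigmoid <- function(x) plogis(x)

# deterministic sub-seed derivation; keeps results < 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% .Machine$integer.max)
}
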