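#' @keywords internal
#' @importFrom Rcpp sourceCpp
#' @useDynLib dpdmicelle, .registration = TRUE
"_PACKAGE"

# Error helpers: validation errors are user-input problems, configuration
# errors are missing/mismatched setup (unknown species, absent records).
abort_validation <- function(msg, ...) {
  rlang::abort(msg, class = "dpdmicelle_validation_error", ...)
}

abort_config <- function(msg, ...) {
  rlang::abort(msg, class = "dpdmicelle_config_error", ...)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_validation(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) {
    abort_validation(sprintf("`%s` must be positive (got %g)", name, x))
  }
  invisible(x)
}

# Deterministic per-stage seed fan-out: one global seed maps to independent
# 31-bit stage seeds keyed by stage name, so each pipeline stage can be
# reproduced in isolation.
stage_seed <- function(seed, stage) {
  key <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + key) %% 2147483647)
}
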