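# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_if <- function(cond, ...) {
  if (isTRUE(cond)) stop(..., call. = FALSE)
  invisible(NULL)
}

#' Evaluate code under a temporary RNG state
#'
#' Seeds the RNG, runs `code`, and restores the caller's RNG state so that
#' library calls never perturb user-level reproducibility.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic per-subject substream seed; order-independent across subjects
# and kept well below .Machine$integer.max.
subject_seed <- function(seed, subject_id) {
  (as.integer(seed) %% 1009L) * 1250003L + as.integer(subject_id) * 7919L + 17L
}

is_binary <- function(x) all(x %in% c(0, 1))
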