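#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

# Classed errors so callers (and tests) can match on contract violations
# rather than message text.
sn_stop <- function(msg, class, call. = FALSE) {
  stop(errorCondition(msg, class = c(class, "strokenet_error", "error", "condition")))
}

sn_assert <- function(cond, msg, class = "invalid_parameter") {
  if (!isTRUE(cond)) sn_stop(msg, class)
  invisible(TRUE)
}

#' Evaluate code with a temporary RNG state
#'
#' Saves and restores `.Random.seed` so generators are reproducible without
#' clobbering the caller's RNG stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive independent sub-seeds from a master seed
#'
#' All randomness in the synthetic-cohort generator flows from a single cohort
#' seed through this splitter, so each subject (and each stage within a
#' subject) is reproducible in isolation.
#' @param seed master seed (integer).
#' @param n number of sub-seeds.
#' @return integer vector of length `n`, each in `[1, 2^31 - 1]`.
#' @export
derive_seeds <- function(seed, n) {
  sn_assert(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
            "seed must be a single finite number")
  sn_assert(n >= 1, "n must be >= 1")
  with_seed(seed, sample.int(.Machine$integer.max, n, replace = FALSE))
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x)
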