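# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a stream of reproducible sub-seeds from one master seed
#'
#' Stages of the pipeline (covariate sampling, event-time simulation,
#' censoring, replicate loops) each receive their own sub-seed so that any
#' stage can be re-run in isolation.  The rule is a fixed affine map modulo
#' a prime below 2^31, so sub-seeds are valid `set.seed()` inputs.
#'
#' @param seed master seed (single integer-valued number)
#' @param k stream index (vectorised; positive integers)
#' @return integer vector of sub-seeds, same length as `k`
#' @export
split_seed <- function(seed, k) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(k), all(k >= 1))
  # exact in double arithmetic: |seed| < 2^31 so products stay below 2^53
  as.integer((abs(seed) * 7919 + k * 104729) %% 2147483629)
}

stop_scr <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "semicompete_error", "error", "condition")))
}

is_binary01 <- function(x) all(x %in% c(0, 1))
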