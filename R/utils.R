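#' @importFrom rlang %||%
NULL

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

#' Derive a child seed from a global seed
#'
#' One global seed is expanded into independent per-stage, per-subject
#' streams by folding the stage name and an index into the seed with a
#' multiplicative hash modulo 2^31 - 1. Adding a subject therefore never
#' perturbs another subject's stream.
#'
#' @param seed Integer global seed.
#' @param stage Character stage tag (e.g. `"behavior"`, `"neural"`).
#' @param index Integer index within the stage (e.g. subject number).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stage, index = 0L) {
  m <- 2147483647 # 2^31 - 1
  h <- (as.numeric(seed) %% m)
  for (ch in utf8ToInt(stage)) h <- (h * 69069 + ch) %% m
  h <- (h * 69069 + as.numeric(index) + 1) %% m
  as.integer(h %% (m - 2) + 1)
}

# round-half-up to the nearest integer (base round() is banker's rounding)
round_half_up <- function(x) floor(x + 0.5)

trial_type_levels <- function() c("instruction", "GG", "GfSS", "GfFS", "SS", "FS")
feature_trial_types <- function() c("GfSS", "GfFS", "SS", "FS")
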