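# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so library code never perturbs the
#' caller's random-number stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env) else
      suppressWarnings(rm(".Random.seed", envir = env))
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible sub-seed (kept below 2^31) for stage `k` of a run.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 48271 + k) %% 2147483647L)
}

# Collect validation messages and abort once with all of them.
check_all <- function(errors, context) {
  errors <- errors[!vapply(errors, is.null, logical(1))]
  if (length(errors) > 0) {
    rlang::abort(c(paste0("invalid ", context, ":"),
                   stats::setNames(unlist(errors), rep("x", length(unlist(errors))))))
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
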