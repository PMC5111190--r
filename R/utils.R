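# Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is restored afterwards so package functions never perturb it.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## Derive a stage seed from a global seed; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) * 1009L + as.integer(offset)) %% 2147483647L
}

stop_invalid <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "septapk_error")))
}

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop_invalid(sprintf("`%s` must be a single positive finite number", name),
                 "septapk_invalid_parameter")
  }
  invisible(x)
}

check_nonnegative <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop_invalid(sprintf("`%s` must be nonnegative and finite", name),
                 "septapk_invalid_parameter")
  }
  invisible(x)
}

## meanlog/sdlog of a lognormal with the given arithmetic mean and sd.
lognormal_pars <- function(mean, sd) {
  stopifnot(mean > 0, sd >= 0)
  if (sd == 0) return(list(meanlog = log(mean), sdlog = 0))
  s2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}
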