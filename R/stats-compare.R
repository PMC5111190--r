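#' Normality-gated two-group comparison
#'
#' The two-group testing procedure applied to all non-PK continuous
#' endpoints: Shapiro--Wilk normality tests on each group decide the
#' comparison -- when both groups look normal (both p >= `alpha`) a
#' two-sided Student t test with pooled variance is used, otherwise a
#' two-sided Mann--Whitney (Wilcoxon rank-sum) test. The rank-sum test is
#' exact when both groups have 8 or fewer untied observations and uses the
#' tie-corrected normal approximation otherwise.
#'
#' @param a,b numeric samples (each n >= 3, the Shapiro--Wilk minimum).
#' @param alpha significance level for both the gate and the comparison.
#' @return A list of class `ctx_comparison`: `test_used`, `statistic`,
#'   `p_value`, `normality_p` (named pair), `alpha`.
#' @export
gated_compare <- function(a, b, alpha = 0.05) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 3 || length(b) < 3) {
    stop_invalid("each group needs at least 3 observations for the normality gate",
                 "septapk_insufficient_sample")
  }
  sw <- c(a = shapiro_p(a), b = shapiro_p(b))
  if (all(sw >= alpha)) {
    tt <- stats::t.test(a, b, var.equal = TRUE)
    res <- list(test_used = "student_t", statistic = unname(tt$statistic),
                p_value = tt$p.value)
  } else {
    exact <- length(a) <= 8 && length(b) <= 8 &&
      !any(duplicated(c(a, b)))
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = TRUE))
    res <- list(test_used = "mann_whitney", statistic = unname(wt$statistic),
                p_value = wt$p.value)
  }
  structure(c(res, list(normality_p = sw, alpha = alpha)),
            class = "ctx_comparison")
}

## Shapiro-Wilk p, treating a constant sample as decisively non-normal
## (shapiro.test() errors on zero range).
shapiro_p <- function(x) {
  if (stats::sd(x) == 0) return(0)
  stats::shapiro.test(x)$p.value
}

#' Welch's t test for PK parameter comparisons
#'
#' Welch statistic with Satterthwaite degrees of freedom, two-sided; the
#' procedure reserved for between-group comparison of pharmacokinetic
#' parameters.
#'
#' @param a,b numeric samples (each n >= 2).
#' @return A `ctx_comparison` list (`normality_p` is `NA`: no gate).
#' @export
welch_compare <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) {
    stop_invalid("each group needs at least 2 observations",
                 "septapk_insufficient_sample")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      stop_invalid("both groups constant with equal means: Welch statistic undefined",
                   "septapk_degenerate_input")
    }
  }
  tt <- stats::t.test(a, b)  # Welch is the t.test default
  structure(list(test_used = "welch_t", statistic = unname(tt$statistic),
                 p_value = tt$p.value, df = unname(tt$parameter),
                 normality_p = c(a = NA_real_, b = NA_real_), alpha = 0.05),
            class = "ctx_comparison")
}

#' @export
print.ctx_comparison <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n",
              x$test_used, x$statistic, x$p_value))
  if (!all(is.na(x$normality_p))) {
    cat(sprintf("  Shapiro-Wilk gate: p(a) = %.3g, p(b) = %.3g (alpha = %g)\n",
                x$normality_p[["a"]], x$normality_p[["b"]], x$alpha))
  }
  invisible(x)
}
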