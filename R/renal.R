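#' Total urinary drug loss over a collection interval
#'
#' Loss (mg) = urine volume (converted to L) x total urinary concentration
#' (mg/L). Vectorized over the rows of a urine record table.
#'
#' @param urine data frame with columns `volume_mL` and
#'   `conc_total_mg_L` (a `conc_bound_mg_L` column, when present, must not
#'   exceed the total).
#' @return Numeric vector of losses in mg.
#' @export
total_urinary_loss <- function(urine) {
  check_urine(urine)
  urine$volume_mL / 1000 * urine$conc_total_mg_L
}

#' Bound-to-total urinary concentration percentage
#'
#' `100 * conc_bound / conc_total`, the quantity whose elevation in septic
#' animals signals loss of glomerular perm-selectivity (protein-bound drug
#' appearing in urine).
#'
#' @param urine data frame with columns `conc_bound_mg_L`,
#'   `conc_total_mg_L` (all totals must be positive).
#' @return Percentages in `[0, 100]`.
#' @export
bound_fraction_pct <- function(urine) {
  check_urine(urine)
  if (!("conc_bound_mg_L" %in% names(urine))) {
    stop_invalid("urine table lacks a `conc_bound_mg_L` column",
                 "septapk_invalid_data")
  }
  if (any(urine$conc_total_mg_L <= 0)) {
    stop_invalid("bound fraction is undefined where `conc_total_mg_L` is zero",
                 "septapk_undefined_fraction")
  }
  100 * urine$conc_bound_mg_L / urine$conc_total_mg_L
}

check_urine <- function(urine) {
  need <- c("volume_mL", "conc_total_mg_L")
  if (!all(need %in% names(urine))) {
    stop_invalid(paste("urine table must contain columns:",
                       paste(need, collapse = ", ")),
                 "septapk_invalid_data")
  }
  check_nonnegative(urine$volume_mL, "volume_mL")
  check_nonnegative(urine$conc_total_mg_L, "conc_total_mg_L")
  if ("conc_bound_mg_L" %in% names(urine)) {
    check_nonnegative(urine$conc_bound_mg_L, "conc_bound_mg_L")
    if (any(urine$conc_bound_mg_L > urine$conc_total_mg_L + 1e-9)) {
      stop_invalid("`conc_bound_mg_L` exceeds `conc_total_mg_L`",
                   "septapk_invalid_data")
    }
  }
  invisible(urine)
}

#' Minimal glomerular sieving model
#'
#' A mechanistic stand-in for glomerular filtration-barrier
#' perm-selectivity: free drug crosses the barrier with sieving coefficient
#' `sieve_free` (about 1), protein-bound drug with `sieve_bound` (0 for an
#' intact barrier; positive once the glycocalyx sialic components are
#' lost). This model is a package extension used to back the synthetic
#' urine generator -- the underlying experiment demonstrates the phenomenon
#' but supplies no transport equation.
#'
#' @param sieve_free sieving coefficient of free drug, in `[0, 1]`.
#' @param sieve_bound sieving coefficient of bound drug, in `[0, 1]`.
#' @param gfr_mL_h glomerular filtration rate, mL/h.
#' @return An object of class `sieving_model`.
#' @export
sieving_model <- function(sieve_free = 1, sieve_bound = 0, gfr_mL_h = 6) {
  stopifnot(sieve_free >= 0, sieve_free <= 1,
            sieve_bound >= 0, sieve_bound <= 1)
  check_positive(gfr_mL_h, "gfr_mL_h")
  structure(list(sieve_free = sieve_free, sieve_bound = sieve_bound,
                 gfr_mL_h = gfr_mL_h), class = "sieving_model")
}

#' Expected urine record under the sieving model
#'
#' Expected excreted amounts over `[0, window]`:
#' \deqn{A = GFR \times sieve \times \int_0^{w} C(t)\,dt} for the free and
#' bound plasma curves respectively; urinary concentrations are the amounts
#' divided by the urine volume.
#'
#' @param s a [sieving_model()] object.
#' @param free_curve,bound_curve functions of time (h) returning plasma
#'   free and bound concentrations in mg/L.
#' @param window collection window, h.
#' @param volume_mL urine volume produced over the window, mL.
#' @return A one-row data frame: `volume_mL`, `amount_free_mg`,
#'   `amount_bound_mg`, `conc_bound_mg_L`, `conc_total_mg_L`.
#' @export
predict_urine <- function(s, free_curve, bound_curve, window = 6,
                          volume_mL = 2) {
  stopifnot(inherits(s, "sieving_model"))
  check_positive(window, "window")
  check_positive(volume_mL, "volume_mL")
  gfr_L_h <- s$gfr_mL_h / 1000
  auc_free <- stats::integrate(free_curve, 0, window)$value
  auc_bound <- stats::integrate(bound_curve, 0, window)$value
  amount_free <- gfr_L_h * s$sieve_free * auc_free
  amount_bound <- gfr_L_h * s$sieve_bound * auc_bound
  vol_L <- volume_mL / 1000
  data.frame(volume_mL = volume_mL,
             amount_free_mg = amount_free,
             amount_bound_mg = amount_bound,
             conc_bound_mg_L = amount_bound / vol_L,
             conc_total_mg_L = (amount_free + amount_bound) / vol_L)
}

#' Group summary of urine records
#'
#' @param urine urine table with a `group` column.
#' @return Data frame of group means and SDs for volume, bound fraction
#'   percentage and total loss.
#' @export
summarize_urine <- function(urine) {
  check_urine(urine)
  loss <- total_urinary_loss(urine)
  pct <- bound_fraction_pct(urine)
  groups <- unique(as.character(urine$group))
  do.call(rbind, lapply(groups, function(g) {
    i <- urine$group == g
    data.frame(group = g, n = sum(i),
               volume_mean_mL = mean(urine$volume_mL[i]),
               volume_sd_mL = stats::sd(urine$volume_mL[i]),
               bound_pct_mean = mean(pct[i]),
               bound_pct_sd = stats::sd(pct[i]),
               loss_mean_mg = mean(loss[i]),
               loss_sd_mg = stats::sd(loss[i]))
  }))
}
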