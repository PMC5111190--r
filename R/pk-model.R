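#' Structural one-compartment parameters
#'
#' Bundles the parameters of the closed-form one-compartment model with
#' first-order absorption used throughout the package,
#' \deqn{C(t) = \frac{D\,k_e\,k_a}{Cl\,(k_a-k_e)}\left[e^{-k_e t} - e^{-k_a t}\right],}
#' where \eqn{D} is the intraperitoneal dose (mg), \eqn{k_a} and \eqn{k_e}
#' are the absorption and elimination rate constants (1/h) and \eqn{Cl} is
#' the clearance (L/h). The implied volume of distribution is
#' \eqn{V = Cl/k_e}. Bioavailability is taken as 1 (the i.p. route is treated
#' as complete absorption).
#'
#' @param dose_mg dose administered, mg.
#' @param ka first-order absorption rate constant, 1/h.
#' @param ke first-order elimination rate constant, 1/h.
#' @param cl clearance, L/h.
#' @return An object of class `structural_params`.
#' @examples
#' p <- structural_params(dose_mg = 32.5, ka = 1, ke = 0.2, cl = 0.02)
#' conc_profile(p, c(0, 1, 2, 6))
#' @export
structural_params <- function(dose_mg, ka, ke, cl) {
  check_positive(dose_mg, "dose_mg")
  check_positive(ka, "ka")
  check_positive(ke, "ke")
  check_positive(cl, "cl")
  structure(list(dose_mg = dose_mg, ka = ka, ke = ke, cl = cl),
            class = "structural_params")
}

#' @export
print.structural_params <- function(x, ...) {
  cat(sprintf(
    "One-compartment parameters: D = %g mg, ka = %g /h, ke = %g /h, Cl = %g L/h (V = %g L)\n",
    x$dose_mg, x$ka, x$ke, x$cl, x$cl / x$ke))
  invisible(x)
}

#' Dosing regimen
#'
#' @param dose_per_kg dose in mg/kg (100 mg/kg corresponds to the human 1 g
#'   dose, 200 mg/kg to 2 g).
#' @param body_mass body mass in kg; default 0.325 kg, the midpoint of the
#'   320--330 g range of adult male Sprague--Dawley rats used in this model.
#' @param interval dosing interval in hours over which fT>MIC coverage is
#'   assessed; default 6 h, the experimental observation window.
#' @return A list of class `dose_regimen` with the absolute dose in
#'   `dose_mg`.
#' @export
dose_regimen <- function(dose_per_kg, body_mass = 0.325, interval = 6) {
  check_positive(dose_per_kg, "dose_per_kg")
  check_positive(body_mass, "body_mass")
  check_positive(interval, "interval")
  structure(list(dose_per_kg = dose_per_kg, body_mass = body_mass,
                 interval = interval, dose_mg = dose_per_kg * body_mass),
            class = "dose_regimen")
}

## Relative ka/ke gap below which the analytic ka -> ke limit is used,
## avoiding catastrophic cancellation in (exp(-ke t) - exp(-ka t))/(ka - ke).
.KA_KE_EPS <- 1e-6

#' Concentration-time profile of the structural model
#'
#' Evaluates the deterministic one-compartment curve at the requested times.
#' When \eqn{|k_a - k_e| < 10^{-6} k_e} the analytic limit
#' \eqn{D k_e^2 t\, e^{-k_e t} / Cl} is used so the evaluation is continuous
#' across the \eqn{k_a = k_e} degeneracy.
#'
#' @param p a [structural_params()] object.
#' @param t vector of times, h (nonnegative).
#' @return Concentrations in mg/L, same length as `t`.
#' @export
conc_profile <- function(p, t) {
  stopifnot(inherits(p, "structural_params"))
  check_nonnegative(t, "t")
  conc_eval(p$dose_mg, p$ka, p$ke, p$cl, t)
}

## Core evaluator, vectorized over t and (recycled) parameter vectors.
conc_eval <- function(dose, ka, ke, cl, t) {
  limit <- abs(ka - ke) < .KA_KE_EPS * ke
  limit[is.na(limit)] <- FALSE   # non-finite rates take the general branch
  if (all(!limit)) {
    dose * ke * ka / (cl * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
  } else if (all(limit)) {
    dose * ke^2 * t * exp(-ke * t) / cl
  } else {
    out <- dose * ke * ka / (cl * (ka - ke)) * (exp(-ke * t) - exp(-ka * t))
    lim <- dose * ke^2 * t * exp(-ke * t) / cl
    ifelse(limit, lim, out)
  }
}

#' Time and magnitude of the concentration peak
#'
#' @param p a [structural_params()] object.
#' @return A list with `tmax` (h) and `cmax` (mg/L). For the
#'   \eqn{k_a = k_e} degeneracy `tmax = 1/k_e`.
#' @export
tmax_cmax <- function(p) {
  stopifnot(inherits(p, "structural_params"))
  tmax <- if (abs(p$ka - p$ke) < .KA_KE_EPS * p$ke) {
    1 / p$ke
  } else {
    log(p$ka / p$ke) / (p$ka - p$ke)
  }
  list(tmax = tmax, cmax = conc_profile(p, tmax))
}

#' Area under the concentration-time curve
#'
#' Analytic integral of the structural curve; `auc_interval(p, 0, Inf)`
#' equals \eqn{D/Cl} exactly.
#'
#' @param p a [structural_params()] object.
#' @param t0,t1 integration limits in hours, `0 <= t0 < t1 <= Inf`.
#' @return AUC in mg h/L.
#' @export
auc_interval <- function(p, t0 = 0, t1 = Inf) {
  stopifnot(inherits(p, "structural_params"))
  check_nonnegative(t0, "t0")
  if (!(t1 > t0)) {
    stop_invalid("`t1` must be strictly greater than `t0`",
                 "septapk_invalid_interval")
  }
  D <- p$dose_mg; ka <- p$ka; ke <- p$ke; cl <- p$cl
  if (abs(ka - ke) < .KA_KE_EPS * ke) {
    ## integral of D ke^2 t exp(-ke t)/Cl
    prim <- function(t) {
      if (is.infinite(t)) return(0)
      -(t / ke + 1 / ke^2) * exp(-ke * t)
    }
    return(D * ke^2 / cl * (prim(t1) - prim(t0)))
  }
  K <- D * ke * ka / (cl * (ka - ke))
  prim <- function(t) {
    if (is.infinite(t)) return(0)
    -exp(-ke * t) / ke + exp(-ka * t) / ka
  }
  K * (prim(t1) - prim(t0))
}

#' Fraction of a dosing interval spent above a threshold
#'
#' Computes the fraction of `[0, interval]` during which the (optionally
#' transformed) concentration strictly exceeds `threshold`. The curve is
#' scanned on a dense grid (`interval / 1e4` step) and each threshold
#' crossing is refined by bisection to `1e-6` h; exact equality counts as
#' not above.
#'
#' The `transform` hook is how free-drug thresholds are handled: passing the
#' total-to-free binding conversion makes this the per-subject fT>MIC.
#'
#' @param p a [structural_params()] object.
#' @param threshold threshold concentration, mg/L (> 0).
#' @param interval length of the assessment window, h.
#' @param transform optional function mapping total concentration (mg/L) to
#'   the scale on which `threshold` lives; default identity.
#' @return Fraction in `[0, 1]`.
#' @export
time_above <- function(p, threshold, interval, transform = NULL) {
  stopifnot(inherits(p, "structural_params"))
  check_positive(threshold, "threshold")
  check_positive(interval, "interval")
  f <- if (is.null(transform)) {
    function(t) conc_profile(p, t)
  } else {
    function(t) transform(conc_profile(p, t))
  }
  n_grid <- 1e4L
  tt <- seq(0, interval, length.out = n_grid + 1L)
  above <- f(tt) > threshold
  refine <- function(lo, hi) {
    ## bisection on the indicator boundary to 1e-6 h
    flo <- above_at(f, lo, threshold)
    while (hi - lo > 1e-6) {
      mid <- (lo + hi) / 2
      if (above_at(f, mid, threshold) == flo) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  total <- 0
  i <- 1L
  while (i <= n_grid) {
    if (above[i + 1L] || above[i]) {
      ## locate entry
      t_in <- if (above[i]) tt[i] else refine(tt[i], tt[i + 1L])
      ## walk until the curve drops back
      j <- i + 1L
      while (j <= n_grid && above[j + 1L]) j <- j + 1L
      t_out <- if (j > n_grid) tt[n_grid + 1L] else refine(tt[j], tt[j + 1L])
      total <- total + (t_out - t_in)
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  min(max(total / interval, 0), 1)
}

above_at <- function(f, t, threshold) f(t) > threshold

#' Plasma anchor set for preset calibration
#'
#' The four printed plasma summaries used to pin the sham and CLP group
#' curves: the observed 1-h peaks in each group and the between-group
#' (CLP minus sham) differences at 2 h and 4 h. "Peak" is interpreted as
#' the model value at the first post-dose sampling time (1 h) because the
#' reported peaks are observed 1-h means, not continuous-time maxima.
#'
#' @param peak_sham,peak_clp observed 1-h concentrations, mg/L.
#' @param diff_2h,diff_4h CLP minus sham differences at 2 h and 4 h, mg/L.
#' @param t_peak sampling time at which the peaks were observed, h.
#' @return A list of class `ctx_anchors`.
#' @export
ctx_anchors <- function(peak_sham = 120.29, peak_clp = 132.48,
                        diff_2h = 47.3, diff_4h = 24.94, t_peak = 1) {
  structure(list(peak_sham = peak_sham, peak_clp = peak_clp,
                 diff_2h = diff_2h, diff_4h = diff_4h, t_peak = t_peak),
            class = "ctx_anchors")
}

#' Calibrate sham/CLP group presets to plasma anchors
#'
#' Least-squares fit of per-group structural parameters so that the two
#' group curves reproduce the plasma anchor set: each group's 1-h peak and
#' the between-group differences at 2 h and 4 h. With
#' `cl_policy = "free"` each group has free \eqn{(k_a, k_e, V)} and
#' \eqn{Cl = V k_e} is derived; with `cl_policy = "fixed"` the clearances
#' are pinned to `cl_fixed` and only \eqn{(k_a, k_e)} move. The fit is a
#' deterministic `nlminb` run from a fixed, documented starting point, so
#' repeated calls give identical presets.
#'
#' Four anchors with six free parameters leave the "free" problem
#' underdetermined; the fixed start selects a reproducible solution whose
#' curves interpolate the anchors (residual reported, near zero). The
#' reported group clearances are not used as anchors because they are not
#' jointly consistent with the reported peaks under a one-compartment model
#' at this dose (see the methods vignette).
#'
#' @param anchors a [ctx_anchors()] object.
#' @param cl_policy `"free"` (default) or `"fixed"`.
#' @param dose_mg dose used for both curves; default 32.5 mg
#'   (100 mg/kg x 0.325 kg).
#' @param cl_fixed named clearances (L/h) used when `cl_policy = "fixed"`;
#'   defaults are the reported sham/CLP values (0.32 and 0.21 mL/min).
#' @return A list of class `group_presets` with elements `sham` and `clp`
#'   (each a `group_preset` carrying `structural_params` and the shared
#'   root-mean-square anchor misfit) plus `residual_rms`.
#' @export
calibrate_presets <- function(anchors = ctx_anchors(),
                              cl_policy = c("free", "fixed"),
                              dose_mg = 32.5,
                              cl_fixed = c(sham = 0.0192, clp = 0.0126)) {
  stopifnot(inherits(anchors, "ctx_anchors"))
  cl_policy <- match.arg(cl_policy)
  check_positive(dose_mg, "dose_mg")
  a <- anchors

  curve <- function(ka, ke, V, t) conc_eval(dose_mg, ka, ke, V * ke, t)

  if (cl_policy == "free") {
    resid_fun <- function(lp) {
      s <- exp(lp[1:3]); k <- exp(lp[4:6])
      c(curve(s[1], s[2], s[3], a$t_peak) - a$peak_sham,
        curve(k[1], k[2], k[3], a$t_peak) - a$peak_clp,
        (curve(k[1], k[2], k[3], 2) - curve(s[1], s[2], s[3], 2)) - a$diff_2h,
        (curve(k[1], k[2], k[3], 4) - curve(s[1], s[2], s[3], 4)) - a$diff_4h)
    }
    ## fixed start: ka = 1/h, sham ke = 0.5/h, CLP ke = 0.25/h, V set so the
    ## starting curve passes through each group's observed peak
    v_init <- function(ka, ke, peak) {
      dose_mg * ka / (ka - ke) * (exp(-ke * a$t_peak) - exp(-ka * a$t_peak)) / peak
    }
    lp0 <- log(c(1, 0.5, v_init(1, 0.5, a$peak_sham),
                 1, 0.25, v_init(1, 0.25, a$peak_clp)))
    unpack <- function(lp) {
      s <- exp(lp[1:3]); k <- exp(lp[4:6])
      list(sham = structural_params(dose_mg, s[1], s[2], s[3] * s[2]),
           clp  = structural_params(dose_mg, k[1], k[2], k[3] * k[2]))
    }
  } else {
    resid_fun <- function(lp) {
      s <- exp(lp[1:2]); k <- exp(lp[3:4])
      Vs <- cl_fixed[["sham"]] / s[2]; Vk <- cl_fixed[["clp"]] / k[2]
      c(curve(s[1], s[2], Vs, a$t_peak) - a$peak_sham,
        curve(k[1], k[2], Vk, a$t_peak) - a$peak_clp,
        (curve(k[1], k[2], Vk, 2) - curve(s[1], s[2], Vs, 2)) - a$diff_2h,
        (curve(k[1], k[2], Vk, 4) - curve(s[1], s[2], Vs, 4)) - a$diff_4h)
    }
    lp0 <- log(c(1, 0.5, 1, 0.25))
    unpack <- function(lp) {
      s <- exp(lp[1:2]); k <- exp(lp[3:4])
      list(sham = structural_params(dose_mg, s[1], s[2], cl_fixed[["sham"]]),
           clp  = structural_params(dose_mg, k[1], k[2], cl_fixed[["clp"]]))
    }
  }

  obj <- function(lp) sum(resid_fun(lp)^2)
  fit <- stats::nlminb(lp0, obj,
                       control = list(iter.max = 2000, eval.max = 5000))
  rms <- sqrt(fit$objective / 4)
  pars <- unpack(fit$par)
  if (fit$convergence != 0 && rms > 1) {
    cond <- errorCondition(
      sprintf("preset calibration did not converge (message: %s, RMS %.3g mg/L)",
              fit$message, rms),
      class = c("septapk_calibration_failure", "septapk_error"))
    cond$best <- pars
    stop(cond)
  }
  presets <- list(
    sham = structure(list(label = "sham", params = pars$sham,
                          calibration_residual = rms), class = "group_preset"),
    clp = structure(list(label = "CLP", params = pars$clp,
                         calibration_residual = rms), class = "group_preset"),
    residual_rms = rms, cl_policy = cl_policy, anchors = a)
  class(presets) <- "group_presets"
  presets
}

#' @export
print.group_presets <- function(x, ...) {
  cat(sprintf("Calibrated group presets (cl_policy = %s, anchor RMS = %.3g mg/L)\n",
              x$cl_policy, x$residual_rms))
  for (g in c("sham", "clp")) {
    p <- x[[g]]$params
    cat(sprintf("  %-4s: ka = %.4g /h, ke = %.4g /h, Cl = %.4g L/h (%.3g mL/min)\n",
                x[[g]]$label, p$ka, p$ke, p$cl, p$cl / 0.06))
  }
  invisible(x)
}
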