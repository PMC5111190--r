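test_that("closed-form curve matches the absorption ODE system", {
  skip_if_not_installed("deSolve")
  ode_conc <- function(p, times) {
    V <- p$cl / p$ke
    out <- deSolve::lsoda(
      y = c(gut = p$dose_mg, conc = 0),
      times = c(0, times),
      func = function(t, y, parms) {
        list(c(-p$ka * y["gut"],
               p$ka * y["gut"] / V - p$ke * y["conc"]))
      },
      rtol = 1e-10, atol = 1e-10)
    out[-1, "conc"]
  }
  tt <- c(0.25, 0.5, 1, 2, 4, 8, 16, 24)
  set.seed(42)
  for (rep in 1:5) {
    p <- random_params()
    expect_equal(conc_profile(p, tt), unname(ode_conc(p, tt)),
                 tolerance = 1e-6)
  }
  ## frozen spot value (ODE oracle, D=32.5, ka=1, ke=0.2, Cl=0.02, t=2)
  expect_equal(conc_profile(ref_params(), 2), 217.34, tolerance = 1e-4)
})

test_that("curve starts at zero, decays to zero and rejects bad parameters", {
  p <- ref_params()
  expect_identical(conc_profile(p, 0), 0)
  expect_lt(conc_profile(p, 200), 1e-12)
  expect_error(structural_params(32.5, -1, 0.2, 0.02),
               class = "septapk_invalid_parameter")
  expect_error(structural_params(0, 1, 0.2, 0.02),
               class = "septapk_invalid_parameter")
})

test_that("tmax/cmax agree with a dense grid search and the curve is unimodal", {
  p <- ref_params()
  pk <- tmax_cmax(p)
  expect_equal(pk$tmax, 2.0118, tolerance = 1e-4)  # frozen from grid oracle
  tt <- seq(0, 24, by = 1e-3)
  cc <- conc_profile(p, tt)
  expect_equal(pk$cmax, max(cc), tolerance = 1e-6)
  expect_equal(tt[which.max(cc)], pk$tmax, tolerance = 1e-3)
  ## unimodal: nondecreasing before tmax, nonincreasing after
  set.seed(7)
  for (rep in 1:5) {
    q <- random_params()
    tm <- tmax_cmax(q)$tmax
    grid <- seq(0, 4 * tm, length.out = 2000)
    v <- conc_profile(q, grid)
    rising <- grid <= tm
    expect_true(all(diff(v[rising]) >= -1e-9))
    expect_true(all(diff(v[!rising]) <= 1e-9))
  }
})

test_that("AUC is analytic: D/Cl over (0, Inf) and trapezoid-consistent on (0, 6)", {
  set.seed(11)
  for (rep in 1:5) {
    p <- random_params()
    expect_equal(auc_interval(p, 0, Inf), p$dose_mg / p$cl, tolerance = 1e-12)
  }
  p <- ref_params()
  tt <- seq(0, 6, by = 1e-3)
  trap <- sum(diff(tt) * (head(conc_profile(p, tt), -1) +
                          tail(conc_profile(p, tt), -1)) / 2)
  expect_equal(auc_interval(p, 0, 6), trap, tolerance = 1e-6)
  expect_error(auc_interval(p, 2, 2), class = "septapk_invalid_interval")
  expect_error(auc_interval(p, 3, 1), class = "septapk_invalid_interval")
})

test_that("time_above matches an exhaustive grid and behaves monotonically", {
  p <- ref_params()
  ## brute-force fraction on a 1e-4 h grid (midpoint counting)
  grid_frac <- function(p, thr, interval, transform = identity) {
    tt <- seq(0, interval, by = 1e-4)
    mean(transform(conc_profile(p, tt)) > thr)
  }
  f <- time_above(p, 50, 6)
  expect_equal(f, grid_frac(p, 50, 6), tolerance = 1e-3)
  ## above the peak -> 0; far below the whole curve -> ~1
  cmax <- tmax_cmax(p)$cmax
  expect_identical(time_above(p, cmax * 1.01, 6), 0)
  expect_gt(time_above(p, 1e-6, 6), 0.999)
  ## nonincreasing in threshold
  thr <- c(5, 20, 50, 100, 200)
  fr <- vapply(thr, function(x) time_above(p, x, 6), numeric(1))
  expect_true(all(diff(fr) <= 0))
  ## nondecreasing in dose
  doses <- c(10, 32.5, 65, 130)
  fd <- vapply(doses, function(D) {
    time_above(structural_params(D, p$ka, p$ke, p$cl), 50, 6)
  }, numeric(1))
  expect_true(all(diff(fd) >= 0))
  ## transform hook is applied
  half <- time_above(p, 50, 6, transform = function(x) x / 2)
  expect_equal(half, time_above(p, 100, 6), tolerance = 1e-5)
})

test_that("evaluation is continuous across the ka = ke degeneracy", {
  ke <- 0.4
  t <- c(0.5, 1, 2, 5)
  limit <- 32.5 * ke^2 * t * exp(-ke * t) / 0.02
  for (eps in c(1e-3, 1e-5, 1e-7)) {
    p <- structural_params(32.5, ke * (1 + eps), ke, 0.02)
    expect_equal(conc_profile(p, t), limit, tolerance = 10 * eps + 1e-7)
  }
  p_eq <- structural_params(32.5, ke * (1 + 1e-9), ke, 0.02)
  expect_equal(conc_profile(p_eq, t), limit, tolerance = 1e-9)
  expect_equal(tmax_cmax(p_eq)$tmax, 1 / ke, tolerance = 1e-6)
  expect_equal(auc_interval(p_eq, 0, Inf), 32.5 / 0.02, tolerance = 1e-12)
})

test_that("preset calibration reproduces self-consistent anchors and reported ones", {
  ## anchors manufactured from known curves are interpolated with ~0 residual
  sham_true <- structural_params(32.5, 2, 0.6, 0.1)
  clp_true <- structural_params(32.5, 1, 0.4, 0.06)
  anch <- ctx_anchors(
    peak_sham = conc_profile(sham_true, 1),
    peak_clp = conc_profile(clp_true, 1),
    diff_2h = conc_profile(clp_true, 2) - conc_profile(sham_true, 2),
    diff_4h = conc_profile(clp_true, 4) - conc_profile(sham_true, 4))
  fit <- calibrate_presets(anch)
  expect_lt(fit$residual_rms, 1e-4)
  expect_equal(conc_profile(fit$sham$params, 1), anch$peak_sham,
               tolerance = 1e-5)
  ## the default (reported) anchor set
  def <- calibrate_presets()
  expect_lt(def$residual_rms, 1e-4)
  expect_equal(conc_profile(def$clp$params, 1), 132.48, tolerance = 1e-3)
  expect_equal(conc_profile(def$sham$params, 1), 120.29, tolerance = 1e-3)
  d2 <- conc_profile(def$clp$params, 2) - conc_profile(def$sham$params, 2)
  expect_equal(d2, 47.3, tolerance = 1e-3)
  ## deterministic across calls
  again <- calibrate_presets()
  expect_identical(def$clp$params, again$clp$params)
  ## residual is carried on both presets, never dropped
  expect_true(is.finite(def$sham$calibration_residual))
  expect_identical(def$sham$calibration_residual, def$clp$calibration_residual)
})

test_that("fixed-clearance calibration pins the printed clearances", {
  fit <- calibrate_presets(cl_policy = "fixed")
  expect_equal(fit$sham$params$cl, 0.0192)
  expect_equal(fit$clp$params$cl, 0.0126)
})
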