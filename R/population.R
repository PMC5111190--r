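#' Population PK parameters
#'
#' Fixed effects, random-effect covariance and residual error of the
#' population model
#' \deqn{Cl_i = e^{\beta_1 + b_{i1}},\quad k_{ei} = e^{\beta_2 + b_{i2}},\quad
#'       k_{ai} = e^{\beta_3},}
#' with \eqn{(b_{i1}, b_{i2}) \sim N(0, \Omega)} and additive Gaussian
#' residual error of standard deviation `sigma` on the concentration scale.
#' The absorption rate constant carries no random effect: the sparse
#' 1/2/4/6 h schedule does not identify between-subject variability in
#' absorption.
#'
#' @param beta1 log typical clearance (Cl in L/h).
#' @param beta2 log typical elimination rate constant (1/h).
#' @param beta3 log absorption rate constant (1/h), fixed effect only.
#' @param omega 2x2 symmetric positive-semidefinite covariance of
#'   `(b1, b2)`.
#' @param sigma residual standard deviation, mg/L.
#' @return An object of class `population_params`.
#' @export
population_params <- function(beta1, beta2, beta3,
                              omega = diag(c(0.09, 0.09)), sigma = 5) {
  stopifnot(is.numeric(beta1), is.numeric(beta2), is.numeric(beta3))
  omega <- as.matrix(omega)
  if (!isTRUE(all.equal(dim(omega), c(2L, 2L))) ||
      max(abs(omega - t(omega))) > 1e-12) {
    stop_invalid("`omega` must be a symmetric 2x2 matrix",
                 "septapk_invalid_parameter")
  }
  ev <- eigen(omega, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10) {
    stop_invalid("`omega` must be positive semidefinite",
                 "septapk_invalid_parameter")
  }
  check_positive(sigma, "sigma")
  structure(list(beta1 = beta1, beta2 = beta2, beta3 = beta3,
                 omega = omega, sigma = sigma),
            class = "population_params")
}

#' @export
print.population_params <- function(x, ...) {
  cat(sprintf("Population PK parameters\n  typical Cl = %.4g L/h (%.3g mL/min), ke = %.4g /h, ka = %.4g /h\n",
              exp(x$beta1), exp(x$beta1) / 0.06, exp(x$beta2), exp(x$beta3)))
  cat(sprintf("  omega diag = (%.3g, %.3g), sigma = %.3g mg/L\n",
              x$omega[1, 1], x$omega[2, 2], x$sigma))
  invisible(x)
}

#' Individual structural parameters from population parameters
#'
#' @param pop a [population_params()] object.
#' @param eff numeric vector `c(b1, b2)` of subject-level deviations on log
#'   clearance and log elimination rate.
#' @param dose_mg dose for this subject, mg.
#' @return A [structural_params()] object.
#' @export
individual_params <- function(pop, eff, dose_mg) {
  stopifnot(inherits(pop, "population_params"), length(eff) == 2L)
  structural_params(dose_mg,
                    ka = exp(pop$beta3),
                    ke = exp(pop$beta2 + eff[2]),
                    cl = exp(pop$beta1 + eff[1]))
}

#' Sample subject-level random effects
#'
#' Draws i.i.d. bivariate normal `(b1, b2)` deviations with covariance
#' `pop$omega`. Reproducible under `seed`; the caller's RNG state is left
#' untouched when a seed is given.
#'
#' @param pop a [population_params()] object.
#' @param n number of subjects.
#' @param seed optional integer seed.
#' @return A data frame with columns `b1`, `b2`.
#' @export
sample_population <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "population_params"), n >= 1)
  ## matrix square root via eigendecomposition: valid for singular omega too
  e <- eigen(pop$omega, symmetric = TRUE)
  A <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), 2L)
  z <- with_seed(seed, matrix(stats::rnorm(2L * n), nrow = n))
  b <- z %*% t(A)
  data.frame(b1 = b[, 1], b2 = b[, 2])
}

## ---- internal likelihood machinery ---------------------------------------

## Validate/standardize an observation data frame; returns the rows used for
## likelihood evaluation (post-dose, above LLOQ) in an indexed layout.
prepare_pk_data <- function(data, dose_mg) {
  required <- c("subject", "time_h", "conc_total_mg_L")
  if (!all(required %in% names(data))) {
    stop_invalid(paste("data must contain columns:",
                       paste(required, collapse = ", ")),
                 "septapk_invalid_data")
  }
  if (!("below_lloq" %in% names(data))) data$below_lloq <- FALSE
  if (!("dose_mg" %in% names(data))) data$dose_mg <- dose_mg
  keep <- data$time_h > 0 & !data$below_lloq
  d <- data[keep, , drop = FALSE]
  if (nrow(d) == 0L) {
    stop_invalid("no usable observations (post-dose, above LLOQ)",
                 "septapk_invalid_data")
  }
  subj <- factor(d$subject, levels = unique(d$subject))
  idx <- as.integer(subj)
  list(y = d$conc_total_mg_L, t = d$time_h, idx = idx,
       dose = d$dose_mg, n_subj = nlevels(subj),
       n_obs = as.vector(rowsum(rep(1, nrow(d)), idx)),
       subjects = levels(subj))
}

## Analytic derivatives of the structural curve wrt the log-scale random
## effects b1 (on Cl) and b2 (on ke). Returns f and the two partials,
## vectorized over observations.
conc_eval_grad <- function(dose, ka, ke, cl, t) {
  limit <- abs(ka - ke) < .KA_KE_EPS * ke
  limit[is.na(limit)] <- FALSE
  Ee <- exp(-ke * t); Ea <- exp(-ka * t)
  K <- dose * ka / cl
  f_gen <- K * ke / (ka - ke) * (Ee - Ea)
  ## d f / d ke, then chain through ke = exp(beta2 + b2)
  dfdke_gen <- K * (ka / (ka - ke)^2 * (Ee - Ea) - ke / (ka - ke) * t * Ee)
  f_lim <- dose * ke^2 * t * Ee / cl
  dfdb2_lim <- f_lim * (2 - ke * t)
  if (any(limit)) {
    f <- ifelse(limit, f_lim, f_gen)
    dfdb2 <- ifelse(limit, dfdb2_lim, ke * dfdke_gen)
  } else {
    f <- f_gen
    dfdb2 <- ke * dfdke_gen
  }
  list(f = f, dfdb1 = -f, dfdb2 = dfdb2)
}

## Per-subject joint negative log density g_i(b) = -log p(y_i | b) p(b),
## evaluated for all subjects at once. B is an n x 2 matrix.
make_gvec <- function(prep, pop) {
  om <- pop$omega
  det_om <- om[1, 1] * om[2, 2] - om[1, 2]^2
  if (det_om <= 0) {
    stop_invalid("`omega` must be positive definite for the Laplace/AGQ marginal (use omega = 0 for the degenerate case)",
                 "septapk_invalid_parameter")
  }
  oi11 <- om[2, 2] / det_om; oi22 <- om[1, 1] / det_om
  oi12 <- -om[1, 2] / det_om
  ldet <- log(det_om)
  ka <- exp(pop$beta3)
  sig2 <- pop$sigma^2
  const_obs <- 0.5 * log(2 * pi * sig2)
  idx <- prep$idx
  function(B) {
    cl <- exp(pop$beta1 + B[idx, 1L])
    ke <- exp(pop$beta2 + B[idx, 2L])
    f <- conc_eval(prep$dose, ka, ke, cl, prep$t)
    rss <- as.vector(rowsum((prep$y - f)^2, idx))
    quad <- B[, 1L]^2 * oi11 + 2 * B[, 1L] * B[, 2L] * oi12 + B[, 2L]^2 * oi22
    rss / (2 * sig2) + prep$n_obs * const_obs +
      0.5 * quad + log(2 * pi) + 0.5 * ldet
  }
}

## Analytic gradient of g_i wrt (b1, b2), all subjects at once (n x 2).
make_grad <- function(prep, pop) {
  om <- pop$omega
  det_om <- om[1, 1] * om[2, 2] - om[1, 2]^2
  oi11 <- om[2, 2] / det_om; oi22 <- om[1, 1] / det_om
  oi12 <- -om[1, 2] / det_om
  ka <- exp(pop$beta3)
  sig2 <- pop$sigma^2
  idx <- prep$idx
  function(B) {
    cl <- exp(pop$beta1 + B[idx, 1L])
    ke <- exp(pop$beta2 + B[idx, 2L])
    fd <- conc_eval_grad(prep$dose, ka, ke, cl, prep$t)
    r <- fd$f - prep$y
    g1 <- as.vector(rowsum(r * fd$dfdb1, idx)) / sig2 +
      B[, 1L] * oi11 + B[, 2L] * oi12
    g2 <- as.vector(rowsum(r * fd$dfdb2, idx)) / sig2 +
      B[, 1L] * oi12 + B[, 2L] * oi22
    cbind(g1, g2)
  }
}

## Vectorized Newton search for the per-subject posterior modes: analytic
## gradient, Hessian by forward differencing of the gradient (h = 1e-5),
## an eigenvalue ridge whenever the local Hessian is not positive definite,
## and Armijo backtracking on the per-subject objective.
find_modes <- function(gvec, grad, B, max_iter = 50L, tol = 1e-5, h = 1e-5) {
  n <- nrow(B)
  g0 <- gvec(B)
  H11 <- H22 <- rep(1, n); H12 <- rep(0, n)
  for (iter in seq_len(max_iter)) {
    gr <- grad(B)
    if (any(!is.finite(gr)) || any(!is.finite(g0))) {
      ## non-finite state (overflowed parameters): report failure and let
      ## the caller's finiteness guard reject this parameter vector
      return(list(B = B, g = g0, H11 = H11, H12 = H12, H22 = H22,
                  detH = H11 * H22 - H12^2, converged = FALSE, iter = iter))
    }
    zc <- rep(0, n); hc <- rep(h, n)
    grp1 <- grad(B + cbind(hc, zc))
    grp2 <- grad(B + cbind(zc, hc))
    H11 <- (grp1[, 1L] - gr[, 1L]) / h
    H22 <- (grp2[, 2L] - gr[, 2L]) / h
    H12 <- ((grp1[, 2L] - gr[, 2L]) + (grp2[, 1L] - gr[, 1L])) / (2 * h)
    ## ridge to enforce positive definiteness
    eig_min <- (H11 + H22) / 2 - sqrt(((H11 - H22) / 2)^2 + H12^2)
    ridge <- pmax(0, 1e-6 - eig_min)
    H11 <- H11 + ridge; H22 <- H22 + ridge
    detH <- H11 * H22 - H12^2
    s1 <- -(H22 * gr[, 1L] - H12 * gr[, 2L]) / detH
    s2 <- -(-H12 * gr[, 1L] + H11 * gr[, 2L]) / detH
    ## fall back to steepest descent where the curvature is non-finite
    bad <- !is.finite(s1) | !is.finite(s2)
    if (any(bad)) {
      s1[bad] <- -gr[bad, 1L]
      s2[bad] <- -gr[bad, 2L]
      H11[bad] <- 1; H22[bad] <- 1; H12[bad] <- 0
      detH <- H11 * H22 - H12^2
    }
    if (max(abs(gr)) < tol || max(abs(c(s1, s2))) < 1e-10) {
      return(list(B = B, g = g0, H11 = H11, H12 = H12, H22 = H22,
                  detH = detH, converged = TRUE, iter = iter))
    }
    ## random effects live on the log scale; cap the step length at 3 while
    ## preserving its direction (so the Armijo slope stays a descent slope)
    smax <- pmax(abs(s1), abs(s2))
    scale <- ifelse(smax > 3, 3 / smax, 1)
    s1 <- s1 * scale
    s2 <- s2 * scale
    slope <- gr[, 1L] * s1 + gr[, 2L] * s2
    alpha <- rep(1, n)
    ## hard clamp: |b| > 20 on the log scale is numerically meaningless
    Bn <- pmin(pmax(B + cbind(alpha * s1, alpha * s2), -20), 20)
    gn <- gvec(Bn)
    for (bt in 1:25) {
      worse <- !is.finite(gn) | gn > g0 + 1e-4 * alpha * slope
      if (!any(worse)) break
      alpha[worse] <- alpha[worse] / 2
      Bn <- pmin(pmax(B + cbind(alpha * s1, alpha * s2), -20), 20)
      gn <- gvec(Bn)
    }
    keep_old <- !is.finite(gn) | gn > g0
    if (any(keep_old)) {
      Bn[keep_old, ] <- B[keep_old, ]
      gn[keep_old] <- g0[keep_old]
    }
    stalled <- max(g0 - gn) < 1e-13
    B <- Bn
    g0 <- gn
    if (stalled) {
      ## objective at machine-precision floor: accept the current modes
      return(list(B = B, g = g0, H11 = H11, H12 = H12, H22 = H22,
                  detH = detH, converged = TRUE, iter = iter))
    }
  }
  ## final curvature at the last iterate
  list(B = B, g = g0, H11 = H11, H12 = H12, H22 = H22,
       detH = H11 * H22 - H12^2, converged = FALSE, iter = max_iter)
}

## Gauss-Hermite nodes/weights (physicists' convention) via Golub-Welsch.
gauss_hermite <- function(n) {
  if (n == 1L) return(list(x = 0, w = sqrt(pi)))
  i <- seq_len(n - 1L)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1L)] <- sqrt(i / 2)
  J[cbind(i + 1L, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = sqrt(pi) * (e$vectors[1, ord])^2)
}

#' Marginal log-likelihood of the population model
#'
#' Integrates the per-subject random effects out of the joint density. The
#' default is the Laplace approximation: for each subject the joint negative
#' log density is minimized over \eqn{(b_1, b_2)} (vectorized Newton with
#' backtracking) and the local Gaussian integral substitutes for the exact
#' one. `method = "agq"` instead applies adaptive Gauss--Hermite quadrature
#' centered and scaled at the same mode, which converges to the exact
#' marginal as `nodes` grows and serves as the validation mode.
#'
#' With `omega = 0` (all entries exactly zero) the random effects are
#' degenerate and the exact pooled Gaussian log-likelihood about the
#' typical-subject curve is returned.
#'
#' Observations at `time_h == 0` (pre-dose baseline) and rows flagged
#' `below_lloq` are excluded.
#'
#' @param pop a [population_params()] object.
#' @param data data frame with columns `subject`, `time_h`,
#'   `conc_total_mg_L`, optional `below_lloq` and `dose_mg`.
#' @param dose_mg dose applied to subjects lacking a `dose_mg` column.
#' @param method `"laplace"` (default) or `"agq"`.
#' @param nodes quadrature nodes per dimension for `"agq"`.
#' @return The marginal log-likelihood (scalar).
#' @export
marginal_loglik <- function(pop, data, dose_mg = 32.5,
                            method = c("laplace", "agq"), nodes = 9L) {
  stopifnot(inherits(pop, "population_params"))
  method <- match.arg(method)
  prep <- prepare_pk_data(data, dose_mg)
  if (all(pop$omega == 0)) {
    f <- conc_eval(prep$dose, exp(pop$beta3), exp(pop$beta2),
                   exp(pop$beta1), prep$t)
    return(sum(stats::dnorm(prep$y, f, pop$sigma, log = TRUE)))
  }
  gvec <- make_gvec(prep, pop)
  grad <- make_grad(prep, pop)
  modes <- find_modes(gvec, grad, matrix(0, prep$n_subj, 2L))
  if (method == "laplace") {
    return(sum(-modes$g + log(2 * pi) - 0.5 * log(modes$detH)))
  }
  agq_loglik(gvec, modes, nodes)
}

## Adaptive Gauss-Hermite built on the Laplace mode and curvature.
agq_loglik <- function(gvec, modes, nodes) {
  gh <- gauss_hermite(nodes)
  n <- nrow(modes$B)
  ## lower Cholesky factor of H^{-1} per subject
  hinv11 <- modes$H22 / modes$detH
  hinv22 <- modes$H11 / modes$detH
  hinv12 <- -modes$H12 / modes$detH
  l11 <- sqrt(hinv11)
  l21 <- hinv12 / l11
  l22 <- sqrt(pmax(hinv22 - l21^2, 1e-300))
  ## accumulate log-sum-exp over the node grid
  terms <- matrix(NA_real_, n, nodes * nodes)
  k <- 0L
  for (i in seq_len(nodes)) {
    for (j in seq_len(nodes)) {
      k <- k + 1L
      z1 <- gh$x[i]; z2 <- gh$x[j]
      b1 <- modes$B[, 1L] + sqrt(2) * l11 * z1
      b2 <- modes$B[, 2L] + sqrt(2) * (l21 * z1 + l22 * z2)
      g <- gvec(cbind(b1, b2))
      terms[, k] <- log(gh$w[i]) + log(gh$w[j]) + z1^2 + z2^2 - g
    }
  }
  m <- apply(terms, 1L, max)
  sum(log(2) - 0.5 * log(modes$detH) + m + log(rowSums(exp(terms - m))))
}

#' Empirical Bayes estimates of subject-level random effects
#'
#' Returns, for each subject present in `data`, the mode of the joint
#' density of observations and random effects at the supplied population
#' parameters (the same mode the Laplace approximation expands around).
#' Subjects with no usable observations get `(0, 0)`, the prior mode.
#'
#' @param pop a [population_params()] object.
#' @param data observation data frame (see [marginal_loglik()]).
#' @param dose_mg default dose, mg.
#' @return Data frame with columns `subject`, `b1`, `b2`.
#' @export
empirical_bayes <- function(pop, data, dose_mg = 32.5) {
  stopifnot(inherits(pop, "population_params"))
  all_subjects <- unique(data$subject)
  usable <- data$time_h > 0 &
    !(if ("below_lloq" %in% names(data)) data$below_lloq else FALSE)
  out <- data.frame(subject = all_subjects, b1 = 0, b2 = 0)
  if (!any(usable) || all(pop$omega == 0)) return(out)
  prep <- prepare_pk_data(data, dose_mg)
  gvec <- make_gvec(prep, pop)
  grad <- make_grad(prep, pop)
  modes <- find_modes(gvec, grad, matrix(0, prep$n_subj, 2L))
  m <- match(as.character(out$subject), prep$subjects)
  hit <- !is.na(m)
  out$b1[hit] <- modes$B[m[hit], 1L]
  out$b2[hit] <- modes$B[m[hit], 2L]
  out
}

## theta <-> parameter list mapping used by the fitter. omega is
## parameterized through its Cholesky factor [exp(t4) 0; t5 exp(t6)] so any
## theta yields a positive-definite omega; sigma through its log.
theta_to_pop <- function(theta, beta3_fixed = NULL) {
  if (is.null(beta3_fixed)) {
    b3 <- theta[3]; rest <- theta[4:7]
  } else {
    b3 <- beta3_fixed; rest <- theta[3:6]
  }
  L <- matrix(c(exp(rest[1]), rest[2], 0, exp(rest[3])), 2L, 2L)
  population_params(theta[1], theta[2], b3,
                    omega = L %*% t(L), sigma = exp(rest[4]))
}

pop_to_theta <- function(pop, fix_ka) {
  ch <- chol(pop$omega + diag(1e-10, 2L))  # upper; we store lower
  L <- t(ch)
  core <- c(pop$beta1, pop$beta2)
  if (!fix_ka) core <- c(core, pop$beta3)
  c(core, log(L[1, 1]), L[2, 1], log(L[2, 2]), log(pop$sigma))
}

## Moment-based starting values from pooled means (curve stripping).
init_from_data <- function(data, dose_mg) {
  prep <- prepare_pk_data(data, dose_mg)
  tm <- sort(unique(prep$t))
  mu <- vapply(tm, function(ti) mean(prep$y[prep$t == ti]), numeric(1))
  ## terminal slope from the last two pooled means
  k <- length(tm)
  ke0 <- if (k >= 2 && mu[k] > 0 && mu[k - 1] > mu[k]) {
    (log(mu[k - 1]) - log(mu[k])) / (tm[k] - tm[k - 1])
  } else 0.3
  ke0 <- min(max(ke0, 0.05), 3)
  ka0 <- max(1, 3 * ke0)
  t_pk <- tm[which.max(mu)]
  dose0 <- stats::median(prep$dose)
  V0 <- dose0 * ka0 / (ka0 - ke0) *
    (exp(-ke0 * t_pk) - exp(-ka0 * t_pk)) / max(mu)
  cl0 <- max(V0 * ke0, 1e-6)
  f0 <- conc_eval(prep$dose, ka0, ke0, cl0, prep$t)
  sig0 <- max(stats::sd(prep$y - f0), 0.5)
  population_params(log(cl0), log(ke0), log(ka0),
                    omega = diag(c(0.1, 0.1)), sigma = sig0)
}

#' Fit the population PK model by maximum marginal likelihood
#'
#' Quasi-Newton (BFGS) ascent of the Laplace-approximated marginal
#' log-likelihood. The random-effect covariance is parameterized through
#' its Cholesky factor, guaranteeing positive definiteness along the whole
#' optimization path, and the residual SD through its log. The per-subject
#' modes are warm-started between objective evaluations, so successive
#' inner Newton solves take only a few iterations.
#'
#' @param data observation data frame with columns `subject`, `time_h`,
#'   `conc_total_mg_L`, optional `below_lloq`, `group`, `dose_mg`.
#' @param init optional [population_params()] starting point; when `NULL`,
#'   starting values come from curve stripping on the pooled means with
#'   `omega = diag(0.1, 0.1)`.
#' @param fix_ka logical; freeze the absorption rate constant at its
#'   starting value (recommended for the sparse 1/2/4/6 h schedule, which
#'   poorly identifies absorption).
#' @param dose_mg default dose for rows lacking `dose_mg`.
#' @param control passed to [stats::optim()]; defaults set
#'   `maxit = 400`, `reltol = 1e-12`.
#' @return An object of class `population_fit` with elements `pop`
#'   (the estimates), `loglik`, `converged`, `counts`, `se_theta`
#'   (standard errors on the internal scale from the observed-information
#'   inverse, `NA` where the information is singular), `theta`, `fix_ka`.
#' @export
fit_population <- function(data, init = NULL, fix_ka = TRUE,
                           dose_mg = 32.5, control = list()) {
  if (is.null(init)) init <- init_from_data(data, dose_mg)
  stopifnot(inherits(init, "population_params"))
  prep <- prepare_pk_data(data, dose_mg)
  beta3_fixed <- if (fix_ka) init$beta3 else NULL
  theta0 <- pop_to_theta(init, fix_ka)

  ## warm-started objective: reuse the previous modes as the Newton start
  warm <- new.env(parent = emptyenv())
  warm$B <- matrix(0, prep$n_subj, 2L)
  negll <- function(theta) {
    ## wild line-search excursions (exp overflow/underflow) get a flat
    ## penalty instead of propagating non-finite arithmetic
    if (any(!is.finite(theta)) || max(abs(theta)) > 50) return(1e10)
    ll <- tryCatch(suppressWarnings({
      pop <- theta_to_pop(theta, beta3_fixed)
      gvec <- make_gvec(prep, pop)
      grad <- make_grad(prep, pop)
      modes <- find_modes(gvec, grad, warm$B)
      warm$B <- modes$B
      sum(-modes$g + log(2 * pi) - 0.5 * log(modes$detH))
    }), septapk_error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)
    -ll
  }

  ctrl <- utils::modifyList(list(maxit = 400, reltol = 1e-12), control)
  opt <- stats::optim(theta0, negll, method = "BFGS",
                      control = ctrl, hessian = TRUE)
  pop_hat <- theta_to_pop(opt$par, beta3_fixed)
  se <- rep(NA_real_, length(opt$par))
  info_ok <- FALSE
  ih <- try(solve(opt$hessian), silent = TRUE)
  if (!inherits(ih, "try-error")) {
    v <- diag(ih)
    info_ok <- all(is.finite(v)) && all(v > 0)
    if (info_ok) se <- sqrt(v)
  }
  if (!info_ok) {
    warning("observed information is singular or indefinite; standard errors unavailable")
  }
  converged <- opt$convergence == 0L
  if (!converged) {
    warning(sprintf("fit_population did not converge (optim code %d): returning the best iterate",
                    opt$convergence))
  }
  structure(list(pop = pop_hat, loglik = -opt$value, converged = converged,
                 counts = opt$counts, se_theta = se, theta = opt$par,
                 fix_ka = fix_ka, init = init,
                 n_subjects = prep$n_subj, n_obs = length(prep$y)),
            class = "population_fit")
}

#' @export
print.population_fit <- function(x, ...) {
  cat(sprintf("Population PK fit (%d subjects, %d observations)%s\n",
              x$n_subjects, x$n_obs,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  cat(sprintf("  log-likelihood: %.3f\n", x$loglik))
  print(x$pop)
  invisible(x)
}
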