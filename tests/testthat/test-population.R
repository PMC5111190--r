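ref_pop <- function(sigma = 3, omega = diag(c(0.09, 0.09))) {
  population_params(log(0.0126), log(0.4), log(1), omega = omega,
                    sigma = sigma)
}

test_that("individual parameters map random effects log-linearly", {
  pop <- ref_pop()
  p0 <- individual_params(pop, c(0, 0), 32.5)
  expect_equal(p0$cl, exp(pop$beta1))
  expect_equal(p0$cl, 0.0126)          # typical CLP clearance, 0.21 mL/min
  expect_equal(p0$cl / 0.06, 0.21)
  expect_equal(p0$ke, exp(pop$beta2))
  expect_equal(p0$ka, exp(pop$beta3))
  d <- 0.37
  p1 <- individual_params(pop, c(d, -d), 32.5)
  expect_equal(p1$cl, p0$cl * exp(d), tolerance = 1e-12)
  expect_equal(p1$ke, p0$ke * exp(-d), tolerance = 1e-12)
})

test_that("omega = 0 reduces the marginal to the pooled Gaussian log-likelihood", {
  pop0 <- ref_pop(omega = matrix(0, 2, 2))
  d <- simulate_plasma(ref_pop(), n = 12, seed = 3)
  typ <- individual_params(pop0, c(0, 0), 32.5)
  pooled <- sum(dnorm(d$conc_total_mg_L,
                      conc_profile(typ, d$time_h), pop0$sigma, log = TRUE))
  expect_identical(marginal_loglik(pop0, d), pooled)
})

test_that("AGQ marginal matches a dense brute-force integral (single subject)", {
  pop <- ref_pop()
  d1 <- data.frame(subject = "s1", time_h = 2, conc_total_mg_L = 100,
                   dose_mg = 32.5)
  ## vectorized Riemann sum over the random-effect plane
  bs <- seq(-3, 3, length.out = 2001); db <- bs[2] - bs[1]
  B1 <- matrix(bs, 2001, 2001); B2 <- t(B1)
  ke <- exp(pop$beta2 + B2); cl <- exp(pop$beta1 + B1); ka <- exp(pop$beta3)
  f <- 32.5 * ke * ka / (cl * (ka - ke)) * (exp(-2 * ke) - exp(-2 * ka))
  dens <- dnorm(100, f, pop$sigma) * dnorm(B1, 0, 0.3) * dnorm(B2, 0, 0.3)
  oracle <- log(sum(dens) * db^2)
  agq <- marginal_loglik(pop, d1, method = "agq", nodes = 40)
  expect_equal(agq, oracle, tolerance = 1e-4)
  ## Laplace is close but not exact for a single sparse subject
  expect_equal(marginal_loglik(pop, d1), oracle, tolerance = 5e-3)
})

test_that("Laplace tracks AGQ closely on informative data", {
  pop <- ref_pop(sigma = 1)
  d <- simulate_plasma(pop, n = 5, seed = 99)
  ll <- marginal_loglik(pop, d)
  la <- marginal_loglik(pop, d, method = "agq", nodes = 21)
  expect_lt(abs(ll - la) / 5, 1e-3)  # per-subject log-likelihood units
})

test_that("independent subjects contribute additively", {
  pop <- ref_pop()
  d <- simulate_plasma(pop, n = 1, seed = 5)
  d2 <- rbind(d, transform(d, subject = "dup"))
  expect_equal(marginal_loglik(pop, d2), 2 * marginal_loglik(pop, d),
               tolerance = 1e-9)
})

test_that("non-PSD omega is rejected", {
  expect_error(population_params(0, 0, 0, omega = matrix(c(1, 2, 2, 1), 2)),
               class = "septapk_invalid_parameter")
  expect_error(population_params(0, 0, 0, omega = diag(c(-0.1, 0.1))),
               class = "septapk_invalid_parameter")
})

test_that("sample_population is seeded, centered and matches omega", {
  pop <- ref_pop()
  a <- sample_population(pop, 100, seed = 7)
  b <- sample_population(pop, 100, seed = 7)
  expect_identical(a, b)
  big <- sample_population(pop, 1e5, seed = 8)
  emp <- cov(cbind(big$b1, big$b2))
  expect_lt(norm(emp - pop$omega, "F") / norm(pop$omega, "F"), 0.05)
  z <- sample_population(ref_pop(omega = matrix(0, 2, 2)), 10, seed = 9)
  expect_true(all(z$b1 == 0 & z$b2 == 0))
})

test_that("empirical Bayes recovers known effects and shrinks toward zero", {
  pop <- ref_pop(sigma = 0.1)
  b_true <- c(0.25, -0.3)
  ip <- individual_params(pop, b_true, 32.5)
  tt <- seq(0.25, 12, by = 0.25)
  dense <- data.frame(subject = "s1", time_h = tt,
                      conc_total_mg_L = conc_profile(ip, tt),
                      dose_mg = 32.5)
  eb <- empirical_bayes(pop, dense)
  expect_equal(c(eb$b1, eb$b2), b_true, tolerance = 1e-3)
  ## no observations -> prior mode
  none <- data.frame(subject = "s2", time_h = 0, conc_total_mg_L = 0,
                     dose_mg = 32.5)
  eb0 <- empirical_bayes(pop, none)
  expect_identical(c(eb0$b1, eb0$b2), c(0, 0))
  ## shrinkage: a sparse noisy subject's EB estimate is closer to zero than
  ## the (nearly) unpenalized per-subject mode
  pop_s <- ref_pop(sigma = 5)
  sparse <- simulate_plasma(population_params(pop_s$beta1 + 0.4,
                                              pop_s$beta2 - 0.4,
                                              pop_s$beta3,
                                              omega = matrix(0, 2, 2),
                                              sigma = 5),
                            n = 1, seed = 11)
  eb_s <- empirical_bayes(pop_s, sparse)
  flat <- population_params(pop_s$beta1, pop_s$beta2, pop_s$beta3,
                            omega = diag(c(100, 100)), sigma = 5)
  eb_f <- empirical_bayes(flat, sparse)
  expect_lt(sqrt(eb_s$b1^2 + eb_s$b2^2), sqrt(eb_f$b1^2 + eb_f$b2^2))
})

test_that("fit_population recovers generating parameters on one cohort", {
  truth <- ref_pop(sigma = 5)
  d <- simulate_plasma(truth, n = 60, seed = 21)
  init <- population_params(truth$beta1 + 0.3, truth$beta2 - 0.2,
                            truth$beta3, omega = diag(c(0.05, 0.05)),
                            sigma = 3)
  fit <- fit_population(d, init = init, fix_ka = TRUE)
  expect_true(fit$converged)
  expect_lt(abs(exp(fit$pop$beta1) / exp(truth$beta1) - 1), 0.15)
  expect_lt(abs(fit$pop$sigma / truth$sigma - 1), 0.35)
  ## likelihood at the optimum is no worse than at the start
  expect_gte(fit$loglik, marginal_loglik(init, d))
  ## deterministic: same data and init give bit-identical estimates
  fit2 <- fit_population(d, init = init, fix_ka = TRUE)
  expect_identical(fit$theta, fit2$theta)
})

test_that("omega collapses toward zero when subjects are exchangeable", {
  truth <- population_params(log(0.0126), log(0.4), log(1),
                             omega = matrix(0, 2, 2), sigma = 3)
  d <- simulate_plasma(truth, n = 50, seed = 31)
  init <- population_params(truth$beta1, truth$beta2, truth$beta3,
                            omega = diag(c(0.05, 0.05)), sigma = 3)
  fit <- fit_population(d, init = init, fix_ka = TRUE,
                        control = list(maxit = 600))
  expect_lt(max(diag(fit$pop$omega)), 0.01)
})
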