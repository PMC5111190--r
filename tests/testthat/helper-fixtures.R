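# Shared fixtures: canonical parameter sets and small simulated cohorts.

ref_params <- function() structural_params(dose_mg = 32.5, ka = 1, ke = 0.2,
                                           cl = 0.02)

ref_binding <- function() binding_params()

## Random valid structural parameters for property-style loops.
random_params <- function() {
  structural_params(dose_mg = runif(1, 5, 100),
                    ka = runif(1, 0.3, 4),
                    ke = runif(1, 0.05, 1.5),
                    cl = runif(1, 0.005, 0.3))
}

## Simulate a plasma data set directly from known population parameters
## (independent of the cohort generator) for fitter tests.
simulate_plasma <- function(pop, n, schedule = c(1, 2, 4, 6),
                            dose_mg = 32.5, seed = 1) {
  set.seed(seed)
  eff <- sample_population(pop, n)
  rows <- lapply(seq_len(n), function(i) {
    ip <- individual_params(pop, c(eff$b1[i], eff$b2[i]), dose_mg)
    conc <- conc_profile(ip, schedule) + rnorm(length(schedule), 0, pop$sigma)
    data.frame(subject = sprintf("s%03d", i), time_h = schedule,
               conc_total_mg_L = pmax(conc, 0), dose_mg = dose_mg)
  })
  do.call(rbind, rows)
}
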