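## Package-level cache (memoized preset calibration).
.septapk_cache <- new.env(parent = emptyenv())

#' Default calibrated sham/CLP presets
#'
#' The [calibrate_presets()] result for the default anchor set with
#' `cl_policy = "free"`, memoized for the session. Deterministic: repeated
#' calls return identical presets.
#'
#' @return A `group_presets` object.
#' @export
default_presets <- function() {
  if (is.null(.septapk_cache$presets)) {
    .septapk_cache$presets <- calibrate_presets(ctx_anchors(),
                                                cl_policy = "free")
  }
  .septapk_cache$presets
}

#' Specification of a synthetic sham/CLP rat cohort
#'
#' Collects every distributional assumption the generator uses. Defaults
#' emulate the reported study conditions: 18 rats per group, sampling at
#' baseline and 1/2/4/6 h, multiplicative assay noise with per-sample CV
#' uniform in the reported 1.5--6.8% intra-assay range, LLOQ 0.125 mg/L,
#' urine and densitometry distributions matched to the reported group
#' means and SDs, and colony counts spanning the reported sham/CLP ranges.
#'
#' @param n_per_group rats per group.
#' @param schedule sampling times, h (must include 0, the drug-free
#'   baseline).
#' @param presets a `group_presets` pair; default [default_presets()].
#' @param omega 2x2 between-subject covariance of `(log Cl, log ke)`
#'   deviations; default `diag(0.09, 0.09)` (about 30% CV on each).
#' @param assay_cv range of per-sample assay coefficients of variation.
#' @param lloq assay lower limit of quantification, mg/L.
#' @param urine_params per-group distributions (arithmetic mean, sd) of
#'   urine volume (mL), total drug loss (mg) and bound/total percentage.
#' @param cfu_ranges per-group colony count ranges (sham: uniform counts;
#'   CLP: log10-uniform).
#' @param od_params per lectin x group normalized-OD mean and sd, plus the
#'   background OD distribution.
#' @param seed integer seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 18,
                        schedule = c(0, 1, 2, 4, 6),
                        presets = NULL,
                        omega = diag(c(0.09, 0.09)),
                        assay_cv = c(0.015, 0.068),
                        lloq = 0.125,
                        urine_params = list(
                          sham = list(volume = c(2.25, 0.53),
                                      loss = c(3.34, 0.55),
                                      bound_pct = c(11, 4)),
                          clp = list(volume = c(1.24, 0.72),
                                     loss = c(1.85, 0.8),
                                     bound_pct = c(22, 6))),
                        cfu_ranges = list(sham = c(0, 10),
                                          clp = c(5e4, 1e5)),
                        od_params = list(
                          maa = list(sham = c(0.97, 0.07),
                                     clp = c(0.38, 0.06)),
                          sna = list(sham = c(1.09, 0.09),
                                     clp = c(0.41, 0.05)),
                          background = c(0.2, 0.02)),
                        seed = 1L) {
  problems <- character()
  if (!(0 %in% schedule)) {
    problems <- c(problems, "`schedule` must include the baseline time 0")
  }
  if (n_per_group < 1) problems <- c(problems, "`n_per_group` must be >= 1")
  if (length(assay_cv) != 2 || any(assay_cv < 0) || assay_cv[1] > assay_cv[2]) {
    problems <- c(problems, "`assay_cv` must be a nondecreasing pair of nonnegative CVs")
  }
  if (lloq <= 0) problems <- c(problems, "`lloq` must be positive")
  for (g in c("sham", "clp")) {
    up <- urine_params[[g]]
    if (is.null(up) || !all(c("volume", "loss", "bound_pct") %in% names(up))) {
      problems <- c(problems,
                    sprintf("`urine_params$%s` needs volume, loss and bound_pct entries", g))
    } else if (any(vapply(up, function(v) v[1] <= 0 || v[2] < 0, logical(1)))) {
      problems <- c(problems,
                    sprintf("`urine_params$%s` means must be positive and SDs nonnegative", g))
    }
  }
  if (length(problems) > 0) {
    stop_invalid(paste0("invalid cohort spec:\n  ",
                        paste(problems, collapse = "\n  ")),
                 "septapk_invalid_spec")
  }
  if (is.null(presets)) presets <- default_presets()
  structure(list(n_per_group = as.integer(n_per_group), schedule = schedule,
                 presets = presets, omega = omega, assay_cv = assay_cv,
                 lloq = lloq, urine_params = urine_params,
                 cfu_ranges = cfu_ranges, od_params = od_params,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate a complete synthetic sham/CLP cohort
#'
#' Produces, fully reproducibly under `spec$seed`, the four tables the
#' analysis pipeline consumes:
#'
#' * `plasma`: per rat, per scheduled time, the individual structural
#'   curve (group preset plus lognormal subject deviations with covariance
#'   `omega`) under multiplicative lognormal assay noise whose CV is drawn
#'   per sample from `assay_cv`; the pre-dose baseline is exactly zero and
#'   values below the LLOQ are reported as 0 with `below_lloq = TRUE`.
#' * `urine`: per rat, 0--6 h volume, total and bound concentrations drawn
#'   from group lognormals matched to the configured means/SDs (bound
#'   percentage capped at 100).
#' * `cfu`: peritoneal colony counts -- sham uniform on the configured
#'   count range, CLP log10-uniform across its range.
#' * `od`: lectin densitometry ROIs, 8 ROIs x 10 fields per lectin and
#'   group, normal around the configured normalized-OD means (truncated
#'   positive) over per-field backgrounds.
#'
#' @param spec a [cohort_spec()] object.
#' @return A list of class `ctx_cohort` with elements `plasma`, `urine`,
#'   `cfu`, `od` and the `spec` used.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  plasma <- with_seed(derive_seed(spec$seed, 11L), gen_plasma(spec))
  urine <- with_seed(derive_seed(spec$seed, 12L), gen_urine(spec))
  cfu <- with_seed(derive_seed(spec$seed, 13L), gen_cfu(spec))
  od <- with_seed(derive_seed(spec$seed, 14L), gen_od(spec))
  structure(list(plasma = plasma, urine = urine, cfu = cfu, od = od,
                 spec = spec), class = "ctx_cohort")
}

gen_plasma <- function(spec) {
  out <- list()
  for (g in c("sham", "clp")) {
    p <- spec$presets[[g]]$params
    pop <- population_params(log(p$cl), log(p$ke), log(p$ka),
                             omega = spec$omega, sigma = 1)
    eff <- sample_population(pop, spec$n_per_group)
    for (i in seq_len(spec$n_per_group)) {
      ip <- individual_params(pop, c(eff$b1[i], eff$b2[i]), p$dose_mg)
      conc <- conc_profile(ip, spec$schedule)
      cv <- stats::runif(length(conc), spec$assay_cv[1], spec$assay_cv[2])
      s2 <- log(1 + cv^2)
      noise <- exp(stats::rnorm(length(conc), -s2 / 2, sqrt(s2)))
      obs <- conc * noise           # multiplicative: baseline stays exactly 0
      censored <- obs < spec$lloq
      obs[censored] <- 0
      out[[length(out) + 1L]] <- data.frame(
        subject = sprintf("%s_%02d", g, i), group = g,
        time_h = spec$schedule, conc_total_mg_L = obs,
        below_lloq = censored, dose_mg = p$dose_mg)
    }
  }
  do.call(rbind, out)
}

rlnorm_ms <- function(n, mean, sd) {
  lp <- lognormal_pars(mean, sd)
  stats::rlnorm(n, lp$meanlog, lp$sdlog)
}

gen_urine <- function(spec) {
  out <- list()
  for (g in c("sham", "clp")) {
    up <- spec$urine_params[[g]]
    n <- spec$n_per_group
    volume <- rlnorm_ms(n, up$volume[1], up$volume[2])
    loss <- rlnorm_ms(n, up$loss[1], up$loss[2])
    pct <- pmin(rlnorm_ms(n, up$bound_pct[1], up$bound_pct[2]), 100)
    conc_total <- loss / (volume / 1000)
    out[[length(out) + 1L]] <- data.frame(
      subject = sprintf("%s_%02d", g, seq_len(n)), group = g,
      volume_mL = volume, conc_bound_mg_L = pct / 100 * conc_total,
      conc_total_mg_L = conc_total)
  }
  do.call(rbind, out)
}

gen_cfu <- function(spec) {
  n <- spec$n_per_group
  sham_rng <- spec$cfu_ranges$sham
  clp_rng <- log10(spec$cfu_ranges$clp)
  data.frame(
    subject = c(sprintf("sham_%02d", seq_len(n)),
                sprintf("clp_%02d", seq_len(n))),
    group = rep(c("sham", "clp"), each = n),
    cfu = c(sample(seq(sham_rng[1], sham_rng[2]), n, replace = TRUE),
            round(10^stats::runif(n, clp_rng[1], clp_rng[2]))))
}

gen_od <- function(spec, n_fields = 10L, n_roi = 8L) {
  bkg <- spec$od_params$background
  out <- list()
  for (lectin in c("maa", "sna")) {
    for (g in c("sham", "clp")) {
      ms <- spec$od_params[[lectin]][[g]]
      for (f in seq_len(n_fields)) {
        od_bkg <- max(stats::rnorm(1, bkg[1], bkg[2]), 0.01)
        norm <- pmax(stats::rnorm(n_roi, ms[1], ms[2]), 0)  # truncated positive
        out[[length(out) + 1L]] <- data.frame(
          lectin = toupper(lectin), group = g,
          field_id = sprintf("%s_%s_f%02d", lectin, g, f),
          roi_id = seq_len(n_roi),
          od = od_bkg * (1 + norm), od_bkg = od_bkg)
      }
    }
  }
  do.call(rbind, out)
}

#' Write a cohort to a dataset directory
#'
#' Emits `plasma.csv`, `urine.csv`, `cfu.csv`, `od.csv` and a
#' `manifest.json` recording the generating spec, seed and package
#' version. Identical specs produce byte-identical files.
#'
#' @param cohort a `ctx_cohort` from [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ctx_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in c("plasma", "urine", "cfu", "od")) {
    utils::write.csv(cohort[[nm]], file.path(dir, paste0(nm, ".csv")),
                     row.names = FALSE)
  }
  spec <- cohort$spec
  manifest <- list(
    seed = spec$seed, n_per_group = spec$n_per_group,
    schedule = spec$schedule, assay_cv = spec$assay_cv, lloq = spec$lloq,
    omega = as.vector(spec$omega),
    presets = lapply(spec$presets[c("sham", "clp")], function(gp) {
      p <- gp$params
      list(label = gp$label, dose_mg = p$dose_mg, ka = p$ka, ke = p$ke,
           cl = p$cl, calibration_residual = gp$calibration_residual)
    }),
    urine_params = spec$urine_params, cfu_ranges = spec$cfu_ranges,
    od_params = spec$od_params,
    package_version = as.character(utils::packageVersion("septapk")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort dataset directory
#'
#' @param dir directory written by [write_cohort()] (or hand-assembled
#'   CSVs with the same columns).
#' @return A list with `plasma`, `urine`, `cfu`, `od` data frames and the
#'   parsed `manifest` (NULL when absent).
#' @export
read_cohort <- function(dir) {
  out <- lapply(c(plasma = "plasma", urine = "urine",
                  cfu = "cfu", od = "od"), function(nm) {
    path <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(path)) utils::read.csv(path) else NULL
  })
  mpath <- file.path(dir, "manifest.json")
  out$manifest <- if (file.exists(mpath)) jsonlite::read_json(mpath) else NULL
  out
}
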