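---
title: "Population PK/PD of ceftriaxone in early experimental sepsis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population PK/PD of ceftriaxone in early experimental sepsis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septapk)
```

## The scientific problem

Early sepsis changes how the body handles antibiotics before any clinical
chemistry flags it. For ceftriaxone — a third-generation cephalosporin that
is about 95% bound to plasma protein and cleared almost entirely by
glomerular filtration — two mechanisms compete: altered clearance changes
total exposure, while loss of the glomerular filtration barrier (GFB)
glycocalyx lets *protein-bound* drug leak into urine, a route that simply
does not exist in health. septapk implements the quantitative machinery for
studying this in the rat cecal ligation and puncture (CLP) model: a
population pharmacokinetic model for sparse plasma sampling, a saturable
binding model linking total and free drug, a Monte Carlo
probability-of-target-attainment (PTA) engine for fT>MIC dosing targets,
urinary bound/free accounting, lectin-densitometry quantification of the
GFB sialic components, and the two-group statistical procedure used on all
of these endpoints.

Because the underlying animal study deposited no raw data — only summary
statistics — the package ships a seeded synthetic-cohort generator whose
defaults are calibrated to those summaries. Every stage of the pipeline is
therefore testable end to end, with the generator standing in for the raw
data.

## The structural and population model

Plasma concentration after an intraperitoneal dose \(D\) follows a
one-compartment model with first-order absorption,

\[
C(t) = \frac{D\,k_e\,k_a}{Cl\,(k_a - k_e)}
       \left[e^{-k_e t} - e^{-k_a t}\right],
\]

with absorption rate \(k_a\) (1/h), elimination rate \(k_e\) (1/h) and
clearance \(Cl\) (L/h); the implied volume is \(V = Cl/k_e\) and
bioavailability is taken as 1 (the formula carries no F term).
\(\mathrm{AUC}(0,\infty) = D/Cl\) exactly, which the tests use as a
conservation check. When \(|k_a - k_e| < 10^{-6} k_e\) evaluation switches
to the analytic limit \(D k_e^2 t\, e^{-k_e t}/Cl\), avoiding catastrophic
cancellation while keeping the curve continuous in the parameters.

Between-subject variability enters log-linearly:
\(Cl_i = e^{\beta_1 + b_{i1}}\), \(k_{ei} = e^{\beta_2 + b_{i2}}\),
\(k_{ai} = e^{\beta_3}\), with \((b_{i1}, b_{i2}) \sim N(0, \Omega)\) and
additive Gaussian residual error \(\sigma\) on the concentration scale.
Absorption carries no random effect: a 1/2/4/6 h schedule cannot identify
between-subject variability in \(k_a\), and `fit_population()` can freeze
\(\beta_3\) entirely (`fix_ka = TRUE`, recommended for this design).

`fit_population()` maximizes a Laplace-approximated marginal likelihood by
BFGS quasi-Newton ascent. The per-subject posterior modes are found by a
vectorized Newton search with analytic gradients, and \(\Omega\) is
parameterized through its Cholesky factor so every iterate is positive
definite; \(\sigma\) is parameterized on the log scale. Adaptive
Gauss–Hermite quadrature (`marginal_loglik(..., method = "agq")`) built on
the same modes serves as the validation mode: it converges to the exact
marginal as nodes grow, and the test suite checks it against a brute-force
two-dimensional Riemann integral. On informative data
(\(\sigma \approx 1\) mg/L) the Laplace and AGQ log-likelihoods agree to
about \(2\times10^{-4}\) per subject; the gap grows to a few \(10^{-3}\)
per subject at \(\sigma = 5\) mg/L, which is why AGQ stays available.

Observations below the assay quantification limit (0.125 mg/L) are excluded
from the likelihood (the simple "discard" strategy); a censoring-aware
likelihood is deliberately out of scope. Residual error is additive with a
single \(\sigma\); a proportional model would also be defensible, but the
study's assay precision (1.5–6.8% CV) acts on concentrations spanning two
decades and the additive choice keeps the marginal tractable and the
recovery experiments honest.

## Saturable protein binding

Free concentration comes from the single-site binding mass balance
\(C_{tot} = C_{free}\,(1 + nP\,K_{aff}/(1 + K_{aff}C_{free}))\), whose
closed-form solution is

\[
C_{free} = \tfrac12\Big[-(nP + 1/K_{aff} - C_{tot}) +
\sqrt{(nP + 1/K_{aff} - C_{tot})^2 + 4C_{tot}/K_{aff}}\Big],
\]

with \(nP = 517\) µmol/L of binding sites and affinity
\(K_{aff} = 0.0367\) L/µmol — the in-vivo ceftriaxone values. In the dilute
limit the unbound fraction is \(1/(1 + nP\,K_{aff}) \approx 5\%\),
consistent with the drug's >95% bound characterization, and it rises with
concentration as binding saturates. The formula is evaluated through a
conjugate rearrangement when \(C_{tot} \ll nP + 1/K_{aff}\), where the
direct form loses precision to cancellation; tests pin both branches to a
bisection solution of the mass balance at \(10^{-9}\) relative tolerance.

Two practical choices deserve note. First, the conversion is applied
*pointwise in time* to simulated curves — the stated equation, not a fixed
unbound fraction; a fixed fraction would overstate free drug at low totals
and understate it near the peak. Second, the mg/L\(\leftrightarrow\)µmol/L
conversion needs a molar mass and published mg/L values rarely state the
salt form; the default is the free acid (554.58 g/mol) with the disodium
salt (661.6 g/mol) available as a configuration parameter.

```{r binding}
b <- binding_params()
fraction_unbound(b, c(10, 100, 1000))   # saturable: rises with total
```

## Group presets and what "calibration" means here

No concentration-time records exist, so the sham and CLP group curves are
pinned to four reported plasma summaries: the 1-h peaks (120.29 and
132.48 mg/L) and the CLP-minus-sham differences at 2 h (47.3 mg/L) and 4 h
(24.94 mg/L). `calibrate_presets()` runs a deterministic least-squares fit
of per-group \((k_a, k_e, V)\) from a fixed, documented starting point.
"Peak" is interpreted as the model value at the 1-h sampling time, not the
continuous-time maximum, because the reported peaks are observed 1-h means.

Two caveats are documented rather than hidden. Four anchors with six free
parameters leave the problem underdetermined; the fixed start makes the
solution reproducible, and the anchor residual (reported on every preset,
near machine zero) tells you the curves interpolate the anchors whatever
else they do. More importantly, the reported group clearances
(0.21/0.32 mL/min) are *not jointly consistent* with the reported peaks
under this model at the 32.5 mg dose — \(D/Cl\) would imply an
\(\mathrm{AUC}(0,\infty)\) several times larger than the printed curves can
carry. Calibration therefore leaves \(Cl\) free by default
(`cl_policy = "free"`); `cl_policy = "fixed"` pins the printed clearances
and accepts anchor misfit instead. Relatedly, the study's summary text
gives the dose both as "100 mg" and as "100 mg/kg"; the package defaults to
100 mg/kg × 0.325 kg (the midpoint of the reported 320–330 g body masses)
= 32.5 mg, configurable.

```{r presets}
default_presets()
```

## Monte Carlo PTA

`run_pta()` draws `n_subjects` (default 10,000) virtual rats per dosing
regimen (100 and 200 mg/kg, the rat equivalents of 1 g and 2 g human
doses), builds each subject's total-concentration curve, and computes each
subject's fT>MIC — the fraction of the dosing interval with free
concentration strictly above the MIC. PTA at a given MIC and coverage
target is the proportion of subjects meeting the target; the default MIC
grid is the doubling sequence 0.03125–32 mg/L containing the EUCAST
Enterobacteriaceae breakpoint of 1 mg/L, and the default targets are 80%
and 100% of the interval with a 90% PTA adequacy threshold.

Implementation note: because the free concentration is strictly increasing
in the total, \(C_{free}(t) > \mathrm{MIC}\) exactly when
\(C_{tot}(t) > T(\mathrm{MIC})\) with \(T\) the algebraic inverse of the
binding solution. Each MIC is therefore converted to the total scale once,
and the threshold crossings of the unimodal total curve are located by
vectorized bisection — no per-subject grid scan. The generic
`time_above()` (dense grid plus bisection refinement, with the binding
conversion as a transform hook) computes the same quantity subject by
subject, and the tests require the two routes to agree.

Assumptions that matter:

* **Coverage interval**: 6 h by default — the experimental window, which
  the study design equates to a 24-h human interval on trough criteria; the
  interval is configurable because the original simulation never states
  which was used.
* **Between-subject variability**: \(\Omega = \mathrm{diag}(0.09, 0.09)\)
  (30% CV on clearance and elimination, uncorrelated) is a package
  assumption — the fitted covariance behind the original simulation was
  never published. PTA percentages at intermediate MICs move with this
  choice, which is exactly why the reported PTA percentages are checked as
  directional properties, not reproduced as exact targets.
* **Assay error is excluded** from simulated profiles: simulated rats have
  "true" curves; measurement noise belongs to the observation model.
* **The 100% target is structurally unattainable** after a first dose:
  absorption from a drug-free baseline means \(C(0) = 0\), so free
  concentration cannot exceed any positive MIC at \(t = 0\) and fT>MIC is
  always strictly below 1. The engine consequently reports PTA = 0 for the
  100% target at every MIC — in agreement with the reported simulation
  outcome, and worth knowing before interpreting 100%-coverage targets for
  any first-dose simulation.

```{r pta}
p <- default_presets()$clp$params
pop <- population_params(log(p$cl), log(p$ke), log(p$ka),
                         omega = diag(c(0.09, 0.09)), sigma = 1)
res <- run_pta(pop, pta_config(n_subjects = 2000, seed = 1),
               binding_params())
subset(as.data.frame(res), mic_mg_L == 1)
```

## Urinary accounting and the sieving model

Urinary loss over the 0–6 h collection is volume × total concentration
(mg = mg/L × L); the bound/total percentage,
\(100 \cdot C_{bound}/C_{tot}\), is the endpoint that rises when the GFB
loses perm-selectivity. `sieving_model()` is a deliberately minimal
mechanistic stand-in used by the generator: free drug crosses the barrier
with sieving coefficient ≈ 1, bound drug with a coefficient that is 0 for
an intact barrier and positive once the glycocalyx sialic components are
lost; expected amounts are GFR × sieving × plasma AUC. The underlying
experiment demonstrates the phenomenon but provides no transport equation,
so this model is labelled a package extension, property-tested
(linearity in GFR, monotonicity in sieving and exposure) rather than
calibrated mechanistically.

## Densitometry

Lectin reactivity (MAA for α2–3-, SNA for α2–6-linked sialic acids) is
quantified as background-normalized optical density,
\((\mathrm{OD} - \mathrm{OD}_{bkg})/\mathrm{OD}_{bkg}\), averaged over at
least eight 40 µm² regions of interest in each of ten optical fields.
The primary input is a pre-extracted OD table; a synthetic grayscale image
path (\(\mathrm{OD} = -\log_{10}(I/255)\), seeded uniform ROI placement
away from borders) exists purely to exercise the pipeline end to end, since
the original quantification used interactive software. One internal
inconsistency in the source summaries is worth flagging: the CLP MAA mean
appears as 0.38 ± 0.06 in the results text but as 0.28 in a figure legend;
the package defaults use 0.38.

## The synthetic cohort generator

`generate_cohort()` emulates the study design: 18 rats per group sampled at
baseline and 1/2/4/6 h, multiplicative lognormal assay noise with
per-sample CV uniform in the reported 1.5–6.8% intra-assay range,
censoring below the 0.125 mg/L LLOQ (reported as zero and flagged), urine
volume/total-loss/bound-percentage drawn from lognormals matched to the
reported group means and SDs (lognormal because the reported CLP bound
concentration has SD 689 > mean 553, i.e. strong right skew), colony counts
uniform 0–10 for sham and log10-uniform over 5×10⁴–10⁵ for CLP, and
densitometry ROIs normal around the reported normalized-OD means truncated
at zero. A single seed makes the whole cohort byte-reproducible.

What passing tests on generated data do **not** show: the generator draws
urine quantities from matched marginals rather than from a joint
physiological model, produces full per-rat profiles (the real study pooled
at least four rats per time point destructively — an option exists for the
sparse design), and contains no model misspecification, so parameter
recovery results certify the estimator, not robustness to wrong structural
assumptions.

## Numerical choices and problem sizes

* Inner Newton for posterior modes: analytic gradient, forward-difference
  Hessian (h = 10⁻⁵), eigenvalue ridge for indefiniteness, Armijo
  backtracking, step clamped to length 3 on the log scale, convergence at
  gradient < 10⁻⁵ or stagnation at the floating-point floor.
* Outer BFGS: relative tolerance 10⁻¹², overflow excursions penalized
  flatly; standard errors from the observed-information inverse, with a
  warning when the information is singular (common when \(\Omega\) hits
  the zero boundary).
* Threshold crossings: `time_above()` uses a grid of interval/10⁴ with
  bisection to 10⁻⁶ h; ties at exact equality count as *not* above
  (strict inequality).
* Attainment uses ≥: PTA exactly at the threshold counts as attained.
* Clearance unit bridge: printed mL/min × 0.06 = L/h at the I/O boundary;
  SI-per-hour internally.
* Recovery experiments (tests and the acceptance script) use 20 cohorts of
  100 rats per group; PTA property checks run the full 10,000-subject
  simulation (a seconds-scale job) plus a 500-subject consistency run
  compared at 4 binomial standard errors.

## Known limitations

Single-compartment disposition only; no censoring-aware likelihood; no
covariate modelling or inter-occasion variability; the sieving model is
phenomenological; PTA is first-dose (no accumulation, no steady state); no
human extrapolation — the package quantifies the rat model on its own
terms.
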