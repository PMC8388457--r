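---
title: "Naive pooled-sample pharmacokinetics: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Naive pooled-sample pharmacokinetics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pooledPK)
```

## The problem and the design

Classical pharmacokinetic studies draw a full concentration-time profile
from every subject. When repeated bleeding is impractical — client-owned
cats kept in their homes, welfare caps on draws per animal — a *sparse*
design is used instead: each subject contributes a baseline sample plus only
2–3 post-dose samples, arranged so that every scheduled time still carries a
fixed number of observations (here 5 at each of 1, 2, 4, 8, 12 and 24 h
across 14 cats). The **naive pooled** estimator merges all observed points
and analyses them as if they belonged to one individual. Its key assumption
is that the individual profile resembles the population profile; it yields a
single typical-animal parameter set and, unlike mixed-effects approaches, no
between-subject variance estimate. That lost variance matters again at the
PK/PD stage, where it must be re-introduced as an explicit assumption (see
*Monte Carlo PTA* below).

`pool()` implements the merge and the per-time summaries (mean, sample SD
with the n−1 denominator). The packaged study table (`enro_cats()`) is
reproduced cell-for-cell at 1-decimal rounding by
`summary_table(pool(enro_cats()))`, with one caveat: at 2 h the table as
published prints an SD of 0.4, while the sample SD of its own five printed
cells is 0.349, which rounds to 0.3. The package always reports the value it
computes; the test suite asserts the discrepancy rather than hiding it.
Display rounding is half-away-from-zero (`round_half_away()`), which matches
the published table's convention; internal values are never rounded.

Baseline (time-0) records with concentration 0 are retained in the data
model: they anchor trapezoidal integration at the dose time, but are always
excluded from log-domain computations (λz, the log-trapezoid), where zeros
are undefined.

## Noncompartmental analysis

`run_nca()` operates by default on the **per-time-mean basis** — one value
per scheduled time — because pooled raw points carry replicate observations
at the same time, which break the trapezoid's requirement of unique
abscissae; the raw-points basis remains available for peak detection.

**Terminal slope.** λz is the negative slope of an unweighted least-squares
line through (t, ln C). The study behind the fixture does not state its
regression window, so the default is the dominant convention: evaluate every
candidate window that ends at the last positive observation, excludes Tmax,
and has at least 3 points; keep the window with the highest adjusted R²
(ties broken toward more points); report the window, n and adjusted R² in
the result. A manual window (`lambda_selection = "manual_window"`) overrides
this. A profile that rises to its last observation has no terminal phase and
raises a classed error rather than returning a nonsensical positive slope.

**Integration.** The default AUC rule is linear-up/log-down: the ordinary
trapezoid on rising or flat segments and the log-trapezoid
\((t_2-t_1)(C_1-C_2)/\ln(C_1/C_2)\) on strictly decreasing positive
segments, which is exact when decline is exponential. The plain linear rule
is available (`rule = "linear"`) for comparison with older software.
Interval endpoints that fall inside a segment are interpolated with the same
interpolant as the segment's rule, which makes AUC exactly additive over
subintervals (a property the tests assert at 1e−10). AUMC uses the matching
first-moment integrals; under the log interpolant
\(\int tC\,dt = (t_1C_1 - t_2C_2)/k + (C_1-C_2)/k^2\) with
\(k = \ln(C_1/C_2)/(t_2-t_1)\). Tails beyond the last observation are
\(C_\text{last}/\lambda_z\) for AUC and
\(C_\text{last}t_\text{last}/\lambda_z + C_\text{last}/\lambda_z^2\) for
AUMC, with C_last observed (default) or predicted from the λz line.
MRT = AUMC₀₋∞/AUC₀₋∞ is reported as-is for the extravascular dose, with no
absorption correction.

**On the published parameter panel.** The study that the fixture reproduces
prints AUC₀₋₂₄ = 12.4 µg·h/mL, Tmax = 2.2 h and MRT = 12.5 h, but does not
state which analysis produced which value. No documented trapezoid on the
pooled table yields 12.4 (the linear rule gives 19.37, linear-up/log-down
18.88), and 2.2 h is not a sampling time, so at least part of the panel must
derive from an unstated model fit or settings. The package therefore treats
its own transparent computations as the result and validates the machinery
property-wise instead: NCA on dense noise-free one-compartment data must
match the closed-form AUC within 0.5% and λz within 1% of ke, the
compartmental fit must recover noise-free parameters to 1e−5, and the
synthetic recovery harness must keep median bias under 15% at the default
variability. All three are asserted in the test suite.

## The one-compartment model

`fit_onecomp()` fits
\(C(t) = \frac{D\,k_a}{V/F\,(k_a-k_e)}\left(e^{-k_e t} - e^{-k_a t}\right)\)
by weighted nonlinear least squares (Levenberg–Marquardt on log-parameters,
iteration cap 500, relative tolerance 1e−10). Weighting is uniform by
default — the conventional choice when nothing is stated — with 1/C and 1/C²
options. Starting values are deterministic: ke from the λz fit, ka by
numerically inverting \(t_\text{max} = \ln(k_a/k_e)/(k_a-k_e)\) at the
empirical peak, V/F by matching the empirical Cmax; a fit is therefore
reproducible without a random restart. The model has no lag time: the
profile shows a single peak and monophasic decline, and the data carry too
few absorption-phase points to support one.

The model is symmetric under \((k_a, k_e, V/F) \mapsto
(k_e, k_a, V/F \cdot k_e/k_a)\) — flip-flop kinetics. When the optimizer
converges on the branch with ka < ke, the equivalent conventional branch is
reported and flagged (`flip_flop = TRUE`), with the raw solution kept in the
result; for this drug and route absorption is faster than elimination, so
the convention is the physiologically sensible branch. At the exact
degeneracy ka = ke (relative difference below 1e−10) the limiting form
\(C(t) = D/(V/F)\,k_e t\,e^{-k_e t}\) is evaluated; the tests check
continuity against nearby ka.

## PK/PD targets and Monte Carlo PTA

Fluoroquinolone efficacy tracks Cmax/MIC ≥ 10 and AUC₀₋₂₄/MIC ≥ 125; the
AUC threshold of 120 that also circulates is accepted via
`pkpd_targets(auc24_over_mic_threshold = 120)`. Ratios are computed exactly
as parameter/MIC; attainment is inclusive at the boundary, implemented with
a 1e−9 relative tolerance so a ratio equal to the target up to
floating-point rounding counts.

`run_pta()` simulates a cohort of sham subjects (default n = 1000, explicit
seed, both recorded in the result) from correlated lognormal Cmax and
AUC₀₋₂₄ distributions parameterized by geometric mean and CV
(`sdlog = sqrt(log(1 + CV²))`). A pooled analysis provides no
between-subject variance, so the CV is a first-class input rather than a
hidden constant: the default of 0.30 with log-scale correlation 0.8 is a
typical magnitude for oral fluoroquinolone exposure in small-animal
populations, and sensitivity to it is one command-line flag away
(`--cv-cmax`, `--cv-auc`). Because one cohort of draws is reused across the
whole MIC grid, PTA is nonincreasing in MIC by construction, and the code
asserts this on every run. With CV = 0 the simulator degenerates to the
deterministic indicator of `assess_pkpd()`, and for any CV the simulated PTA
is testable against the closed-form lognormal exceedance
\(\Phi(\ln(\text{GM}/(\text{threshold}\cdot\text{MIC}))/\text{sdlog})\);
the tests require agreement within 3 binomial standard errors. Published
PTA percentages for this study (e.g. 65% at MIC 1 µg/mL) were generated
under variability assumptions that were never stated, so they serve as
qualitative guidance only, not as targets.

The MIC grid follows the microbiological doubling-dilution convention:
exact powers of two above 0.1 µg/mL, conventional two-decimal labels below
(0.03, 0.06, 0.125, …). The PK/PD cutoff is the largest grid MIC whose PTA
is at or above the adequacy level (default 0.90), reported per target and
jointly; joint PTA is computed on the same draws and is never above the
smaller single-target PTA.

## The synthetic-data generator

`generate_dataset()` emulates the study's statistical structure so the
whole pipeline is testable without animal data:

- subject parameters are lognormal around the typical values (geometric
  mean preserved); defaults ka 1.2 1/h, ke 0.12 1/h, V/F 3.0 L/kg at
  10 mg/kg, chosen to resemble the study profile (these defaults imply a
  typical Cmax of 2.58 µg/mL at 2.13 h);
- between-subject CVs default to 0.25/0.25/0.20 for ka/ke/V-over-F and the
  residual model is proportional CV 0.10 plus additive SD 0.02 µg/mL,
  truncated at zero — plausible magnitudes for a small-animal oral study,
  stated here because the pooled source data cannot identify them;
- sampling follows a randomized least-loaded allocation that covers every
  scheduled time with exactly `n_per_time` subjects while never exceeding
  `max_draws_per_subject` (infeasible designs are rejected up front with
  the binding constraint named); every subject gets a baseline zero, and
  unallocated cells are emitted as not-sampled markers so the output has
  the exact shape of the study table;
- observations below the LLOQ (default 0.01 µg/mL) are censored to
  not-sampled or set to zero, per configuration;
- one user seed drives cohort, allocation and noise through independent
  derived streams, so a dataset is reproducible from its manifest alone.

What the generator does **not** emulate: formulation release kinetics, food
effects, multi-dose accumulation, assay error structure beyond the
two-component residual, or any correlation between a subject's parameters
and its allocation. Passing tests therefore demonstrate that the estimators
recover the truth *under the stated generative model*, not that the model
is the truth about any real population.

`end_to_end_recovery()` chains generate → pool → NCA → fit over replicate
studies and reports median relative bias and relative RMSE per parameter.
NCA quantities computed on a 6-point grid carry discretization bias relative
to the continuous-curve truth even without noise (the peak of the means is
not the peak of the curve), so NCA and fit rows are labelled separately. The
shipped checks use 200 replicates of 14 subjects, which is ample for a
median-bias summary at these CVs while keeping the full suite fast.

## Numerical choices and limitations

- Rounding for display is half-away-from-zero; all internal computation is
  full precision.
- λz tie-breaks (equal adjusted R² within 1e−12) go to the wider window.
- `beads_required()` subtracts 1e−9 before the ceiling so exact divisions
  are not bumped up by floating-point representation.
- Degenerate inputs raise classed conditions (`pooledPK_input_error`,
  `_validation_error`, `_domain_error`, `_capacity_error`,
  `_convergence_error`, plus `_insufficient_data` and
  `_no_terminal_phase`), which the command-line wrapper maps to distinct
  exit codes.
- Single-dose extravascular analysis only: no urinary excretion,
  steady-state or multiple-dose NCA, no bioavailability estimate (there is
  no IV reference arm), no two-compartment or nonlinear-elimination models,
  and no MIC-distribution-weighted cumulative fraction of response — PTA is
  per-MIC, as the breakpoint question requires.
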