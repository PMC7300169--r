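---
title: "Optimal sampling schedules for radioligand-therapy dosimetry: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal sampling schedules for radioligand-therapy dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ossdosim)
```

## The problem

Individualized dosimetry in ¹⁷⁷Lu radioligand therapy requires the
time-integrated activity coefficient (TIAC) of each organ and lesion at
risk: the integral of the region's activity over time, normalized by the
injected activity, which is proportional to the self-absorbed dose.
Estimating TIACs accurately needs serial imaging over a week or more —
costly for patients and departments. `ossdosim` quantifies, by Monte-Carlo
simulation, how much accuracy and precision each candidate measurement
schedule buys, and identifies the schedule that jointly optimizes kidney
and tumour dosimetry.

The pipeline has five stages, each an exported module of the package:

1. **Schedule space** (`default_grid()`, `enumerate_*`): candidate planar
   imaging times on a 24-point grid from 1 to 192 h post injection,
   restricted to working hours. Two- and three-point subsets are
   unconstrained (276 and 2024 schedules); four-point subsets must place
   one or two points within the first 4 h (5700 schedules). Hybrid
   schedules add one SPECT/CT 0.5 h after one of the planar images; the
   single-time-point method uses each grid time as the lone SPECT/CT (24
   cases).
2. **Virtual cohort** (`sample_cohort()`): parametric ground-truth
   time–activity curves with closed-form true TIACs.
3. **Noise model** (`simulate_measurements()`): multiplicative log-normal
   perturbations of the true activities.
4. **Estimators** (`fit_monoexp()`, `tiac_planar()`, `tiac_hybrid()`,
   `tiac_single_tp()`): what a clinic would compute from the measurements.
5. **Search** (`schedule_metrics()`, `run_search()`, `find_oss()`,
   `constrained_search()`, `vary_last_two()`): pooled deviation statistics
   and exhaustive ranking.

## Ground-truth curves and what the generator emulates

The cohorts that motivated this design were derived from whole-body
physiologically based pharmacokinetic (PBPK) model fits to clinical
imaging of 13 patients. Those fits are not distributed; `ossdosim` instead
generates curves with the same *reported statistical structure*. Each
region follows a two-exponential uptake/washout form scaled by physical
decay,

$$A(t) = C\,\bigl(e^{-(\lambda_{bio}+\lambda_{phys})t} -
         e^{-(\lambda_{up}+\lambda_{phys})t}\bigr),
  \qquad \lambda_{phys} = \frac{\ln 2}{6.647 \cdot 24\ \mathrm h},$$

the simplest form with an uptake phase, a mono-exponential washout and an
analytic integral,

$$\mathrm{TIAC} = \frac{C}{A_0}\left(
    \frac{1}{\lambda_{bio}+\lambda_{phys}} -
    \frac{1}{\lambda_{up}+\lambda_{phys}}\right).$$

Sampled quantities (defaults in `cohort_config()`):

| Quantity | Distribution | Default |
|---|---|---|
| kidney effective half-life | triangular (min, mode, max) | 30 / 40 / 62 h |
| tumour effective half-life | triangular | 34 / 50 / 94 h |
| kidney time of maximum | uniform | 0.6–3 h |
| tumour time of maximum | uniform | 0.5–9 h |
| injected activity $A_0$ | normal | 7300 ± 300 MBq |
| peak kidney uptake | uniform fraction of $A_0$ | 1–3 % |
| peak lesion uptake | uniform fraction of $A_0$ | 0.05–2 % |

Triangular distributions are used because only medians and ranges of the
effective half-lives are reported; placing the mode at the median is the
least-committal choice that reproduces both. The uptake rate
$\lambda_{up}$ is solved numerically (bisection on the peak-time equation)
so the curve maximum lands at the drawn time; kidney draws are rejected
until at least 96.8 % of the curve maximum is reached 1 h post injection,
the reported early-uptake behaviour. Peak-uptake fractions are *not*
reported anywhere; they only set the curve scale, and since all error
metrics are relative TIAC deviations they cannot influence the headline
results — values were chosen once as plausible organ/lesion uptakes of a
PSMA ligand and never revisited.

What the generator does **not** emulate: inter-region correlations within
a patient (a PBPK model couples kidney and tumour kinetics through shared
physiology; here regions are independent), bi-exponential or more complex
washout, lesion volume (which would modulate measurement noise for small
lesions), and the "tumour rest" compartment. Conclusions drawn from
passing tests therefore concern the estimators and the schedule ranking
under the stated kinetic statistics — not any individual patient's
physiology.

## Noise model

Simulated activities are median-preserving log-normal perturbations of the
truth, i.e. multipliers $\exp(\sigma Z)$ with
$\sigma = \sqrt{\ln(1+\mathrm{CV}^2)}$. Planar values carry a total 20 %
coefficient of variation split into a systematic factor (drawn once per
patient, region and replicate, shared by all planar time points — the
signature of region overlap and attenuation errors in 2-D quantification)
and an independent stochastic factor per time point. The systematic
fraction `f_syst` is unknown in practice and is scanned over 25/50/75 %.
The SPECT/CT value carries a single independent 5 % error.

The exact published composition of the two log-normals is not available,
so the default split is linear in CV
($\mathrm{CV}_{syst} = f_{syst}\cdot 0.20$,
$\mathrm{CV}_{stoch} = (1-f_{syst})\cdot 0.20$) — the most literal reading
of "fraction of the total error" — with a log-variance split available as
`noise_config(syst_split = "variance")` for sensitivity analyses.

Noise CVs are time-independent. This is justified by a Poisson budget: a
planar sweep over a 3.1 MBq kidney at 9.4 cps/MBq sensitivity, 38.7 cm
axial field of view and 10 cm/min bed speed collects enough counts that
the Poisson contribution stays near
`planar_poisson_uncertainty(3.1, 9.4, 38.7, 10)` ≈ 1.2 %, negligible
against the 20 % quantification error. For sub-millilitre lesions this
argument weakens (Poisson noise up to ~10 % at late times), so late time
points are likely somewhat flattered for the smallest lesions — a known
limitation shared with the constant-CV design this package follows.

### Common random numbers

Every `(patient, region, measurement time)` triple owns its own
deterministic stream of standard-normal draws, seeded from the global seed
and those identifiers; replicate $i$ uses position $i$ of each stream.
Consequences:

* results are bitwise reproducible and independent of evaluation order
  (no state leaks between schedules, patients, or parallel chunks);
* two schedules sharing a measurement time see *identical* noise at that
  time, so schedule comparisons are paired. This is the classic
  common-random-numbers variance-reduction device for ranking and
  selection: with ~6000 candidate schedules whose true RMSE values differ
  by less than the Monte-Carlo error of independent runs at moderate
  replicate counts, independent streams would let sampling noise decide
  the top ranks, whereas paired comparisons leave the ranking stable at
  200 replicates;
* the `f_syst` and noise-level sweeps are also paired (same draws, scaled
  differently), which is why monotone trends can be asserted tightly in
  the tests.

## Estimators

**Planar fit.** Planar samples are fitted with
$f(t) = A_1 e^{-(\lambda_1+\lambda_{phys})t}$. The default fitting space
is ordinary least squares on $\ln$ activity versus time: under
multiplicative log-normal noise this is the maximum-likelihood estimator,
and for two points it is the exact interpolant. A linear-space
`nls()` fit is available via `fit_monoexp(space = "linear")` for
sensitivity checks. If the fitted slope implies $\lambda_1 < 0$
(biological buildup, divergent integral), $\lambda_1$ is clamped to zero
and the amplitude re-estimated with the slope fixed at
$-\lambda_{phys}$; the replicate is retained and flagged, and clamp counts
are reported per schedule (`n_clamped`), because discarding such
replicates would bias the pooled moments.

**Hybrid planar/SPECT.** $\mathrm{TIAC}_{hybrid} =
\frac{A_{SPECT}(t_{SPECT})}{f_{planar}(t_{SPECT})}\,
\mathrm{TIAC}_{planar}$. A shared multiplicative planar error scales $A_1$
but not $\lambda_1$, so it cancels exactly in the ratio — the property
that makes one quantitative 3-D measurement so valuable, and which the
test suite asserts to machine precision in the purely systematic limit.

**Single time point.** $\mathrm{TIAC}_{1TP} = \frac{2}{\ln 2}
A_{SPECT}(t_{ref})\, t_{ref} / A_0$. On a mono-exponential truth with
effective half-life $T_{eff}$ the estimate/truth ratio is exactly
$2\,x\,2^{-x}$ with $x = t_{ref}/T_{eff}$: exact at $x = 1$, below 1 for
$x < 1$, and at most $2/(e \ln 2) \approx 1.061$ near $x = 1.44$. Because
tumour half-lives spread widely (34–94 h), no single $t_{ref}$ can serve
both kidneys and tumours — the simulated tumour TIACs at the
kidney-oriented time are biased low, reproducing the qualitative clinical
finding.

## Pooling, scoring and ranking

For each schedule, relative deviations
$\Delta = 100\,(\widehat{\mathrm{TIAC}} - \mathrm{TIAC}) /
\mathrm{TIAC}$ are pooled over patients × replicates (kidneys; 13 000 at
the defaults) and lesions × patients × replicates (tumours; 26 000).
Moments use the population definition of $\sigma$ (the pooled sample is
the distribution of interest, and at $N \ge 13\,000$ the correction is
immaterial). The per-region score is
$\mathrm{RMSE} = \sqrt{\mu^2 + \sigma^2}$ and schedules are ranked by
$\mathrm{RMSE}_{joint} = w_K\,\mathrm{RMSE}_K + \mathrm{RMSE}_T$ with
$w_K = 2$, prioritizing the dose-limiting kidneys. Ties (not observed in
practice) break deterministically: earlier last planar time first, then
lexicographic schedule label.

Duration-constrained searches (`constrained_search()`) filter candidates
by their last *planar* time; the fixed 0.5 h SPECT offset may exceed the
limit, mirroring how a 96-h schedule carries its SPECT/CT at 96.5 h.

## Numerical choices and degenerate inputs

* Times are plain hours compared exactly on grid membership; the grid and
  all constraints are configurable (`default_run_config()`), defaults as
  above.
* $\lambda_{up}$ solving uses `uniroot` on the ratio
  $r = \lambda_{up,eff}/\lambda_{bio,eff} \in (1, 10^{12}]$ at tolerance
  $10^{-12}$; infeasible combinations (peak time beyond the washout
  curve's reach, effective half-life above the physical one) are rejected
  with explicit errors.
* `lambda_up = Inf` is supported as the exact mono-exponential limit, used
  heavily in tests where estimators must be exact.
* Fits require ≥ 2 distinct times and positive activities; non-positive
  effective decay rates are unreachable by construction (clamping).
* Cohorts serialize to JSON at 15 significant digits — round-trip accurate
  to ~1 ULP; downstream results from a *pinned file* are exactly
  reproducible since they depend only on the file contents and seeds.

## Problem sizes in the shipped tests and script

The test suite and `scripts/acceptance.R` run the full enumeration
(24-point grid) but scale Monte-Carlo depth to desk size: 200 replicates
per schedule for the exhaustive 3-TP hybrid search (6072 schedules;
common random numbers keep the ranking stable at this depth, and the
pooled per-schedule sample is still 2600/5200 deviations), 1000 replicates
for single-schedule summaries and the 24-case single-TP search, and an
independent 2×10⁵-draw brute-force oracle for the engine cross-check. The
full-depth setting (`n_reps = 1000` everywhere) is a flag away via
`search_config()`.

## Known limitations

* Population-level optimum only: the search minimizes cohort-pooled RMSE;
  per-patient optimal schedules are out of scope.
* The synthetic cohort reproduces reported marginal statistics, not joint
  PBPK physiology; absolute RMSE values on it are therefore *scale*
  plausible but not patient-data estimates — the package's value is in
  the estimator properties and schedule *ranking* structure.
* Mono-exponential fitting only; model-selection over richer fit functions
  would change the optimal schedules.
* No absorbed-dose (Gy) conversion, no image simulation or reconstruction,
  and no size-dependent lesion noise.
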