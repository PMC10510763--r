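---
title: "Delayed reactant labelling kinetics: models, noise, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Delayed reactant labelling kinetics: models, noise, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drlkin)
```

## The experiment and its observable

Delayed reactant labelling (DRL) turns ligand self-exchange — invisible to
most techniques — into a mass-spectrometric time course. The experiment has
three phases: (I) a host is equilibrated with unlabelled ligand while being
continuously infused into an ESI source; (II) at time `t_L` an isotopically
labelled ligand (a +5 Da isotopologue, say) is added; (III) the system
relaxes to a scrambled equilibrium in which the bound labelled fraction
equals the labelled fraction of the whole ligand pool.

Absolute ion currents drift with spray conditions, but the labelled and
unlabelled complexes are isotopologues with the same ionization efficiency,
so the *relative* intensities within the complex group are a clean solution
-phase observable. That common-mode cancellation is the design principle
behind everything downstream: fits consume fractions, never raw counts.

## Kinetic model

The single-site scheme is

```
host + L      <-- k_off / k_on -->  host·L
host + L*     <-- k_off / k_on -->  host·L*
```

with one shared pair of rate constants: the isotopologues are assumed
kinetically identical (no kinetic isotope effect — the label sits far from
the coordinating atom). `simulate_single_site()` integrates

```
dP/dt = k_on · F · [L]  − k_off · P
dL/dt = k_on · F · [L*] − k_off · L
```

with `F = host_total − P − L` eliminated algebraically and both free pools
obtained from conservation, so host mass balance holds to machine
precision by construction rather than to solver tolerance. Free-ligand
depletion is explicit: small-excess regimes are meaningful, and the
closed-form law below is recovered only as the large-excess limit.

In that limit the unlabelled bound fraction follows

p(t) = (1 − f) + f·exp(−k_off (t − t_L)),   t ≥ t_L,

with `f` the labelled pool fraction (`closed_form_relative()`). Note the
plateau is exact at any excess: with identical rate constants the bound
and free pools scramble to the same labelled fraction, so `f_eq = f` even
when the kinetics are not pseudo-first-order.

`predict_kms()` treats the simulated system exactly like an experiment:
simulate, normalize, fit. Two properties matter scientifically and are
enforced by tests: `k_MS` → `k_off` (from above) as the excess grows, and
`k_MS` is insensitive to `k_on` at ~100 equivalents — which is why the DRL
fit determines the dissociation rate without knowledge of the association
step.

### Two-site (bis-complex) variant

Hosts with two inequivalent sites (inside/outside a cage cavity) are
tracked through the four bound states (inner × outer, each
labelled/unlabelled). Each site exchanges independently at its own
`k_off`; the replacement ligand is drawn from the shared well-mixed pools
in proportion to their current fractions. This is the fast-rebinding
limit: the per-site `k_on` does not enter, every host stays doubly bound,
and at a 1:1 pool the long-time class fractions are binomial —
PP : PL : LL → 1/4 : 1/2 : 1/4.

The mixed (PL) class rises quickly when the outer site is much faster, so
the slow inner exchange is isolated by *renormalizing* the PP and LL
traces together (`renormalize_pair()`) and fitting them first-order. A
caution established analytically (independent-site product solution) and
reproduced by the simulator: this renormalized trace is single-exponential
only when the two rates are well separated. At a 10-fold separation the
fitted rate is within ~1% of the slow site's `k_off`; at equal rates the
trace is not exponential at all and a fixed-plateau fit lands near
0.61 × k_off. The renormalization is therefore reported as a slow-site
rate only in the separated regime, which is also the regime in which it is
used experimentally.

## Synthetic data generator

`generate_drl_dataset()` emulates what the instrument would record under
the study conditions: intensities proportional to simulated concentrations
(default scale 10^11 counts per mol/L, i.e. ~10^6 counts full scale for a
10 µM host), perturbed by

- a **log-normal common-mode drift** factor shared by all species at a
  time point (`spray_drift_sd`, default study value 10% — ESI spray
  fluctuation);
- **shot-like noise** with variance proportional to intensity
  (`shot_scale`);
- **additive baseline noise** (`additive_sd`; the reference noisy
  condition is 1% of full scale), clipped at the detector floor of zero.

Seeded runs are bit-reproducible. The reference noisy-recovery study uses
600 points over `5/k_off`, 10% drift and 1% additive noise, 100 seeds —
chosen as a realistic acquisition (a scan per ~15 s over five half-lives).

What the generator does *not* emulate: profile peak shapes, detector
saturation, chromatographic or mobility artefacts, and H/D scrambling
(deuterium is a distinct element `D` in formulas). Post-selection
fragmentation of bis-complexes into the 1:1 channels is available only as
a single cross-contamination fraction. Passing tests therefore demonstrate
correctness of the estimators under this noise family, not robustness to
every instrumental pathology.

Isotope envelopes use a fixed, compiled table of natural abundances
(IUPAC 2021 representative values) convolved per element at nominal
(unit) mass offsets. Fine isotopic structure is irrelevant here: the only
interference that matters for DRL is the light species' M+5 line under the
labelled monoisotopic peak, and that is captured exactly by unit-offset
aggregation. `overlap_matrix()`/`correct_overlap()` undo that bleed by
non-negative least squares per time point; the correction is off by
default, matching common practice when the M+5 abundance is negligible.

## Fitting and uncertainties

`fit_first_order()` fits both complementary fractions globally with shared
parameters — symmetric in the labelled/unlabelled roles. Because the two
traces of a two-species group are exact complements, the stacked
Gauss–Newton covariance would undercount the variance by a factor of two;
the reported standard error is rescaled to the effective single-trace
degrees of freedom. In the 100-seed reference study this yields ~95%
nominal-coverage intervals for the estimator's own noise-free limit (the
finite-excess `k_MS`, which at 100 equivalents sits 0.5% above `k_off` —
a deterministic feature of the conditions, not an estimator bias).

Defaults and their rationale:

- `f_eq` fixed to the known labelled fraction (stocks are weighed; the
  plateau is exact at any excess). Floating it is an option for imperfect
  stock ratios, and on model-generated data the floated value converges to
  the true fraction.
- `t_L` from metadata; floated only on request.
- Start value for `k` from the empirical half-decay; bounds `k ≥ 0`;
  Levenberg–Marquardt (minpack.lm) with tight `ftol`/`ptol` (1e-14).
- Data with a decaying-fraction range below 10^-3 are rejected as
  degenerate ("insufficient dynamic range") rather than returning an
  arbitrary rate.
- `check_quantitation_limit()` flags rates above 0.5 s⁻¹ (the dead time of
  manual addition plus infusion makes faster processes unquantifiable) and
  fits whose sampling puts fewer than 3 points within the first `1/k`.

`fit_competitive()` runs per-host fits with a shared `t_L` and isolates
failures, so one dead channel cannot abort a multi-host run; rate ratios
between hosts come from a single experiment.

## Eyring analysis

`eyring_fit()` regresses `ln(k/T)` on `1/T`; `ΔH‡ = −slope·R`,
`ΔS‡ = R·(intercept − ln(k_B/h))`. Physical constants are CODATA 2018
(`k_B = 1.380649e-23` J/K, `h = 6.62607015e-34` J·s,
`R = 1.98720425864083` cal mol⁻¹ K⁻¹) for bit-reproducible output.
Replicate spreads, when present, enter as inverse-variance weights on the
`ln(k/T)` scale via the delta method; without them the fit is unweighted.
Reported uncertainties are 1·SE from the regression, with the full
(ΔH, ΔS) covariance kept so that `gibbs_at()` propagates correctly —
the covariance term dominates, and ΔG‡ is most precise near the mean
experimental temperature. Mixed conventional units (kcal/mol for ΔH‡ and
ΔG‡, cal/mol/K for ΔS‡) are used in all reports; internally everything is
in calories.

Self-consistency of published (ΔH‡, ΔS‡, ΔG‡ at 25 °C) triples is checked
after rounding to the printed precision, since the inputs themselves are
printed at one decimal.

## Numerical choices

- **Integrator**: `deSolve::lsoda`, `rtol = 1e-8`,
  `atol = 1e-12 · host_total`. `k_on·[L]` and `k_off` can differ by many
  orders of magnitude, so a stiff-capable method with tight tolerances is
  the safe default.
- **Grids**: `predict_kms()` samples 1 point/s over `5/k_off` (capped at
  20 000 intervals for very slow exchange); fits use only `t ≥ t_L`.
- **Labelled addition**: an instantaneous concentration step at `t_L`; a
  first-order mixing reservoir (`mixing_tau`) is available when the
  dead-time of addition matters.
- **Degenerate inputs**: zero-signal time points are masked with a logged
  count, never silently dropped; all-flat groups raise a typed error;
  validation and numerical failures carry distinct condition classes that
  the CLI maps onto exit codes 2 and 3.
- **Equilibrium checks** run to 15–20 half-lives (the plateau criterion
  ±10⁻³ is only meaningful beyond ~10/k); fit windows use the
  conventional 5/k span.

## Known limitations

- The two-site model's fast-rebinding limit ignores transient vacancies;
  at very low free-ligand concentrations (rebinding no longer fast against
  dissociation) a vacancy-explicit model would be needed.
- The renormalized PP/LL rate is meaningful only for kinetically separated
  sites (see above).
- Mechanistic small-excess fitting to extract `k_on` is deliberately out
  of scope: `k_MS` is insensitive to it in the regime where the method is
  quantitative.
- Readers are CSV-based (long trace tables, centroided peak lists); vendor
  formats and profile spectra are upstream concerns.
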