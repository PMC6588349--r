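---
title: "Models and methods: subunit counting, FRET pharmacology, and quench kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: subunit counting, FRET pharmacology, and quench kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smpharm)
```

This vignette is the package's own account of the models it implements, the
assumptions they rest on, the tunable parameters that matter, and the places
where the design was genuinely open and a choice had to be made. Nothing
here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## 1. The scientific setting

Class C GPCRs such as the metabotropic glutamate receptors are obligate
dimers, and a central question is whether their transmembrane domains (TMDs)
dimerize on their own and how allosteric drugs (PAMs, NAMs, inverse
agonists) act on that interface. The measurements this package analyzes are:

- **single-molecule pulldown (SiMPull) photobleaching**: receptor complexes
  immobilized on passivated glass, imaged by TIRF at 20 Hz; each spot's
  intensity drops in discrete steps, one per fluorophore, so the step count
  reports the number of labeled subunits;
- **live-cell two-channel FRET**: donor- and acceptor-labeled constructs
  report inter-domain proximity as drugs wash in and out;
- **GIRK-current and dose–response pharmacology**: activation amplitudes,
  EC50s, 10–90% transition times, percent inverse agonism;
- **stopped-flow thallium quench assays**: gramicidin-channel-mediated Tl⁺
  influx into fluorophore-loaded vesicles, reporting bilayer modification by
  the drugs themselves.

## 2. Subunit counting

### 2.1 Step detection

A spot's trace is modeled as a piecewise-constant signal plus white Gaussian
read noise. `estimate_noise()` uses the median absolute deviation of first
differences scaled by $1/(\sqrt{2}\cdot 0.6745)$: differencing removes the
slowly-varying signal, the median ignores the sparse step outliers, and the
scaling makes the estimator consistent for Gaussian noise.

`detect_steps()` segments by recursive binary splitting: at each stage the
change point with the largest residual-sum-of-squares reduction is added,
and the model order $k$ is chosen to minimize

$$\mathrm{SSE}(k) + \lambda\, k\, \hat\sigma^2 \ln N,$$

a BIC-like criterion with `penalty_scale` $\lambda = 2$ by default. Two
refinements matter in practice:

- **Monotone constraint.** In photobleaching mode candidate splits that
  would create an up-step larger than $2\hat\sigma$ are rejected; true
  bleaching only goes down, and this suppresses noise-driven up-splits
  without forbidding the small rebounds that pure noise produces.
- **Boundary refinement.** After each split, every change point is
  re-placed at the optimal position between its neighbors (coordinate
  descent). Without this, a first split that lands a frame or two off the
  true step leaves enough residual structure that the criterion buys a
  spurious extra step — exactly the failure mode that inflates rejected
  spots. With refinement, detection on simulated cohorts at SNR 5 assigns
  the true step count to ≳98% of spots whose steps are at least one second
  apart (this is computed by the test suite).

The algorithm is deliberately swappable behind the single `detect_steps()`
interface; the original analysis this emulates used an unpublished
LabVIEW routine, so the segmentation here is this package's own, validated
against an exhaustive-search oracle on noiseless traces.

### 2.2 Acceptance rules

`classify_spot()` buckets fits into `1`, `2`, `3plus`, or `rejected`. A spot
is rejected when no step is found, when the final level is not within
$3\hat\sigma$ of zero (the molecule did not fully bleach within the movie),
or when any fitted step is smaller than $3\hat\sigma$ (indistinguishable
from noise). The source experiments did not publish their spot-acceptance
criteria, so these rules are this artifact's definition; percentages are
always computed among accepted spots, with rejected counts carried
alongside. The movie — not the spot — is the unit of replication for
condition comparisons (`aggregate_condition()`, `compare_conditions()`).

### 2.3 The binomial labeling model

With labeling efficiency $p$ (default 0.80, the SNAP-tag value), a monomer
is visible with probability $p$ and always bleaches in one step; a dimer is
visible with probability $2p - p^2$ and shows two steps with conditional
probability $p^2/(2p-p^2)$. Chance colocalization — two molecules within
one diffraction-limited spot, plus antibody/NeutrAvidin bivalency — is
lumped into a single background probability $b$ that attaches one extra
labeled monomer to a visible spot, shifting its category up by one
(1→2, 2→3plus). Higher coincidences are ignored: the empirical background
is only 5–10%, so double coincidences are second-order. The `3plus`
category arises *only* from background; higher-order oligomers are not a
free model class because no condition in this assay family changes the
>3-step fraction.

Inverting the two-step fraction $\theta_2$ at $b=0$ gives the closed form

$$\hat f = \frac{\theta_2}{p + \theta_2 (p - 1)},$$

so $\theta_2 = 0.45$ at $p = 0.8$ yields $\hat f = 63.4\%$ — "~60% dimers"
at ten-percent precision. Note the rounding asymmetry: a true $f = 0.60$
forward-predicts $\theta_2 = 42.9\%$, not 45%; the pair (45%, ~60%) is a
pair of rounded empirical values, and the package's tests use the exact
forward model as their oracle. `fit_ml()` generalizes the inversion to a
multinomial maximum-likelihood fit over all three categories with $p$ and
$b$ held fixed (a three-category table cannot identify $f$, $p$ and $b$
jointly) and reports 95% profile-likelihood intervals
($\Delta 2\log L = 3.84$). When $b = 0$ the `3plus` probability is zero, so
any observed `3plus` spots (rare detection artifacts) are dropped from the
likelihood with a warning. Default $b = 0.075$ (the midpoint of the
empirical 5–10% range) when modeling real backgrounds; $b = 0$ when
reproducing the closed-form arithmetic.

## 3. FRET responses

`compute_fret()` is the ratiometric definition $A/(D+A)$, computed
pointwise; samples with zero total intensity propagate as gaps (`NA`),
never as zeros, and are never interpolated. No bleed-through,
direct-excitation, or acceptor-artifact corrections are applied — the
analysis is confined to *relative* FRET changes, which is all the ratio
supports without calibration. Consequences: the ratio is invariant to
common-mode gain, and only baseline-normalized quantities
(`normalize_baseline()`, which maps the pre-drug mean to 1) are reported.

Response amplitude is the mean of the normalized ratio over the **last 25%
of a drug epoch**, minus 1. The plateau window is this package's choice:
the source recordings reach steady state well before washout and no window
convention was published. Responses are optionally re-expressed as a
fraction of a saturating reference epoch measured *within the same
recording*, which cancels expression level and labeling differences between
cells. `donor_recovery()` quantifies the energy-transfer control: for a
conserved-intensity donor/acceptor pair at FRET ratio $E$, complete
acceptor bleaching raises the donor by $E/(1-E)$.

## 4. Pharmacology metrics

- **Hill fits** (`fit_hill()`): $r(c) = E_{max} c^n / (c^n + EC_{50}^n)$
  with the baseline fixed at 0 by default, because responses are
  baseline-subtracted or reference-normalized upstream (an additive
  baseline can be freed). Initialization takes $EC_{50}$ from the
  concentration nearest half-max and $n = 1$; standard errors come from the
  curvature at the optimum; replicates are fitted unweighted, mirroring
  figure-legend presentation. EC50s outside the tested range are flagged
  extrapolated; flat data are flagged unidentifiable rather than fitted.
- **10–90% times** (`time_10_90()`): amplitude is plateau (mean of the
  final 10% of the epoch) minus baseline (mean of the final 10% of the
  pre-epoch span — symmetric with the plateau rule, and it makes OFF
  transitions measurable right after an ON epoch). The 10% and 90%
  crossings are the first crossings after epoch start, linearly
  interpolated between samples; smoothing is off by default since the
  statistic is computed on raw traces. For a single exponential the
  statistic equals $\tau \ln 9$, which ties the printed rise times
  (14.3 s and 1.9 s) to their time constants (6.51 s and 0.865 s).
  Amplitudes below $3\times$ the baseline s.d. raise a "no response" error
  instead of returning a meaningless time.
- **Percent inverse agonism**: $100\, I_{NAM}/(I_{NAM}+I_{Glu})$ on raw
  amplitudes; scale-invariant by construction.

## 5. Quench kinetics

Stopped-flow traces are fit over the **2–100 ms window** (the instrument
dead time is <2 ms) to the stretched exponential

$$F(t) = F_\infty + (F_0 - F_\infty)\, e^{-(t/\tau_0)^\beta},
\qquad 0 < \beta \le 1,$$

a compact surrogate for a sum of exponentials whose dispersion reflects the
vesicle size distribution ($\beta = 1$ is a homogeneous sample). Because
the window excludes $t \approx 0$, the four parameters are strongly
correlated and a naive first-sample start for $F_0$ finds local minima;
`fit_stretched_exp()` therefore initializes from a coarse
$(\tau_0, \beta)$ grid with the two linear parameters solved exactly at
each node, then polishes with box-constrained Levenberg–Marquardt.
Non-decaying traces (amplitude under $3\times$ the trace noise) are flagged
rather than fitted.

The quench rate is the decay rate evaluated at $t = 2$ ms,

$$\mathrm{Rate} = \frac{\beta}{\tau_0}\Big(\frac{t}{\tau_0}\Big)^{\beta-1}
\Bigg|_{2\,\mathrm{ms}},$$

averaged over the (by default nine) quencher trials of an experiment and
normalized to matched no-modulator controls, which cancels loading and
instrument factors; it obeys the exact scaling identity
$\mathrm{Rate}(k\tau_0) = \mathrm{Rate}(\tau_0)\,k^{-\beta}$.

Compound autofluorescence is removed as an **additive offset** estimated
from a compound-only reference. The source protocol only says the signals
were "normalized" for compound fluorescence; additive removal was chosen
because a fluorophore background free of inner-filter effects adds linearly
to the detected signal. This is the one place the correction convention is
genuinely underdetermined.

## 6. The synthetic-data generators

Every pipeline input can be generated with recorded ground truth:

- `gen_photobleach_cohort()` draws complex types from the stoichiometry
  model, labels subunits independently at $p$, discards invisible
  complexes, attaches a background monomer with probability $b$, and
  renders staircase traces with i.i.d. exponential bleach times
  (default mean 10 s), 20 Hz sampling, 60 s movies, and Gaussian read
  noise at SNR 5. SNR and unit spot intensity are fixture choices — the
  source experiments published neither — set once to values typical of
  sCMOS TIRF at these exposures. Fluorophores bleach independently and do
  not blink; blinking robustness is out of the default model.
- `gen_fret_series()` relaxes the true FRET ratio single-exponentially
  toward baseline + ΔFRET during epochs and back after; channels are
  anti-correlated with a constant total, plus independent Gaussian noise.
  Truth records per-epoch plateau ΔFRET and closed-form 10–90% times.
- `gen_dose_response()` and `gen_current_trace()` evaluate the Hill model
  and exponential responders; a preset bank carries the fitted parameters
  reported for this receptor system (e.g. GIRK LY48 EC50 0.23 µM; inter-TMD
  FRET LY48 1.2 µM, TASP 0.9 µM with 1.3× efficacy, Ro 64 2.1 µM) for
  regression-style use. Hill slopes were not published and default to 1.
- `gen_quench_trials()` inverts the stretched-exponential model: nine
  quencher trials, four flat controls, an additive compound offset, and a
  compound-only reference trace.

What the generators deliberately do **not** emulate: raw images or spot
localization (the pipeline starts from extracted traces), fluorophore
blinking, bleed-through and acceptor artifacts (off by default), drift, or
correlated noise. Passing tests therefore validate the *estimators* under
the stated noise model; they do not certify performance on traces whose
dominant artifacts are upstream of this pipeline's inputs.

## 7. Numerical choices and problem sizes

- Step-detection ties (noiseless data, zero penalty) resolve to the
  smallest model order within a $10^{-9}$ relative score tolerance.
- `fit_ml()` optimizes on $[0,1]$ with `stats::optimize` (tolerance
  $10^{-10}$), compares against both boundaries, and finds CI edges by
  `uniroot`; boundary estimates are flagged with one-sided intervals.
- Nonlinear fits run Levenberg–Marquardt (`minpack.lm::nlsLM`) with
  `ftol = ptol = 1e-15` so noiseless recovery is limited by arithmetic,
  not convergence.
- The test suite sizes simulations to validate each claim at desk scale:
  50,000-spot truth-only draws for distributional checks, 1,000–6,000
  rendered traces for detection accuracy, 200 replicates for CI coverage,
  and a 5,000-spot end-to-end recovery; the full suite runs in a few
  minutes on one CPU.

## 8. Known limitations

- Steps closer than roughly two frames merge at SNR 5; at 20 Hz and a
  10 s bleach constant this affects ~1% of dimers and biases the two-step
  fraction down by well under a percentage point, which the ML inversion
  does not correct.
- The `3plus` bucket does not resolve 3 vs 4+ steps (cap `max_steps = 6`),
  so the pipeline cannot quantify genuine higher-order oligomers; it can
  only detect their absence as a stable small `3plus` fraction.
- $p$ and $b$ are inputs, not estimands; a mis-stated labeling efficiency
  propagates directly into $\hat f$ (the closed form shows
  $\partial f/\partial p < 0$ near the operating point).
- Absolute FRET efficiencies, bleed-through-corrected ratios, and
  hidden-state single-molecule FRET analysis are out of scope.
- Stretched-exponential $\tau_0$ and $\beta$ are strongly anti-correlated
  over a 2–100 ms window; the 2-ms rate is the stable, reportable summary,
  which is why comparisons are made on control-normalized rates.
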