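# smpharm

Quantitative analysis pipeline for single-molecule fluorescence studies of
GPCR dimerization and allosteric pharmacology — the kind of study that asks
whether a receptor's transmembrane domains dimerize on their own, and how
positive and negative allosteric modulators reshape that interface.

The package covers four measurement families, each driven end-to-end by a
synthetic-data generator with recorded ground truth, so every stage is
testable without any external recordings:

1. **Photobleaching-step subunit counting.** Single-molecule pulldown spots
   bleach in discrete steps, one per fluorophore. `detect_steps()` segments
   each intensity trace by penalized binary change-point splitting
   (model order minimizes `SSE(k) + penalty * k * sigma^2 * log N`, with a
   monotone-decreasing level constraint), `classify_spot()` buckets spots
   into 1 / 2 / ≥3 steps or rejects them, and `summarize_movie()` /
   `aggregate_condition()` follow the movie-as-replicate convention.

2. **Stoichiometry under incomplete labeling.** With per-subunit labeling
   efficiency *p*, a dimer shows two steps only with probability
   `p² / (2p − p²)` among visible spots. The dimer fraction *f* follows in
   closed form from the observed two-step fraction θ₂,

   ```
   f = θ₂ / (p + θ₂ (p − 1))
   ```

   (`invert_dimer_fraction()`), or by multinomial maximum likelihood with
   profile-likelihood confidence intervals (`fit_ml()`), including a
   chance-colocalization background *b* that shifts categories up by one.
   With θ₂ = 0.45 and p = 0.80 the closed form gives f = 63.4%, i.e. ~60%
   dimers at ten-percent precision; a pure monomer with b = 0.10 shows 10%
   two-step bleaching.

3. **Ratiometric FRET and pharmacology.** `compute_fret()` implements
   `FRET = I_A / (I_D + I_A)` (no bleed-through corrections — only relative
   changes are meaningful), with baseline normalization, plateau response
   amplitudes referenced to a saturating in-recording control, Hill
   dose–response fits (`fit_hill()`), 10–90% transition times
   (`time_10_90()`, equal to `τ·ln 9` for exponential responses), and
   percent inverse agonism `100·I_NAM/(I_NAM + I_Glu)`.

4. **Stopped-flow thallium quench kinetics.** Gramicidin-based bilayer
   assays quench ANTS fluorescence with a stretched-exponential time course
   `F(t) = F∞ + (F0 − F∞)·exp{−(t/τ₀)^β}`; `fit_stretched_exp()` fits the
   2–100 ms window and `rate_at()` evaluates the quench rate
   `(β/τ₀)(t/τ₀)^(β−1)` at 2 ms, normalized to control experiments by
   `experiment_rate()`.

## Worked example

Simulate a pulldown cohort of 2,000 spots at a true dimer fraction of 0.60
with 80% labeling, count bleaching steps, and re-infer the dimer fraction:

```r
library(smpharm)
run <- run_pipeline(list(seed = 1,
  simpull = list(n_spots = 2000, f_dimer = 0.6, p = 0.8, b = 0, n_movies = 4)))
print(run)
#> smpharm pipeline run (seed 1, config 26c72690):
#>   4 movie(s), mean two-step 43.2%
#> Dimer fraction (ML): 0.605  [95% CI 0.571-0.640]  (~60% to the nearest ten percent), n = 1956 spots
```

The observed two-step percentage (43.2%) is far below the true dimer
fraction because ~36% of dimers carry only one functional label at
p = 0.80; the likelihood inversion corrects for this and recovers
f̂ = 0.605 with a 95% profile-likelihood interval covering the simulated
truth. 44 of the 2,000 spots were rejected (incomplete bleaching or steps
indistinguishable from noise) and are excluded from the percentages.

Fitting a noisy dose–response table from the generator:

```r
d <- gen_dose_response(ec50_uM = 1.2, hill_n = 1, emax = 1,
                       concentrations_uM = 10^seq(-2, 2, 0.5),
                       noise_sd = 0.05, n_replicates = 3, seed = 21)
fit_hill(d$concentration_uM, d$response)
#> Hill fit: EC50 = 1.08 +/- 0.1 uM, n = 1.17 +/- 0.11, Emax = 0.971 +/- 0.022
```

A thin command-line front end over the same functions ships in
`inst/cli/smpharm.R` (subcommands `run`, `count-steps`, `stoichiometry`,
`dose-response`, `kinetics`, `quench-rate`).

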