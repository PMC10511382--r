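# tvarousal

Visual attention parameters, pupillary unrest, and the statistics that link
them.

Studies of *hypoarousal* — for instance in post-COVID patients with brain fog
and fatigue — measure the same construct on three levels: **tonic alertness**
as the visual processing speed *C* of the theory of visual attention (TVA),
**central nervous activation** as the pupillary unrest index (PUI) of the
pupillographic sleepiness test, and **subjective mental fatigue** as
questionnaire totals. `tvarousal` implements that whole analysis chain as a
tested, reusable R pipeline, together with synthetic-data generators so every
stage can be exercised without access to patient data.

## The models at the core

**TVA whole report.** Six letters shown for a brief exposure race in
parallel for a capacity-limited short-term store. Each letter is encoded
with probability

    p = 1 − exp(−(C/6) · a),   a = max(0, τ + μ·[unmasked] − t0) / 1000

where *C* (letters/s) is the processing rate (the curve's initial slope),
*t0* (ms) the perceptual threshold (x-intercept), *μ* (ms) the visual
persistence gained by unmasked displays, and the report score is the number
of encoded letters capped at the vSTM capacity *K* (the asymptote; modelled
as a two-point mixture on adjacent integers so fractional estimates like
3.85 are meaningful). Parameters are estimated by maximum likelihood with a
multi-start bounded simplex search. Partial report adds the top-down control
parameter **α = wD/wT**, the distractor/target attentional weight ratio,
estimated from target-report counts in 16 display conditions.

**PUI.** Raw 25-Hz pupil diameter traces are cleaned (blinks interpolated
linearly, gaps > 3 s invalidate their segment), block-averaged over 16
samples (→ 1.5625 Hz), and the absolute successive differences are summed
per 82.5-s segment (127 differences) and normalized per minute:
PUI = Σ|Δ| · 60/82.5 mm/min, averaged over the 8 segments of an 11-min
recording. A perfectly stable pupil gives exactly 0.

**Statistics.** Wilcoxon rank-sum tests with effect size r = |z|/√N,
bootstrapped kernel-density non-overlap, Spearman matrices with
Benjamini–Hochberg FDR, multiple regression with percentile-bootstrap CIs
and Cohen's f² = R²adj/(1 − R²adj), nested-model F tests, and
percentile-bootstrap mediation (full mediation = direct CI covers 0,
indirect CI excludes it).

## Worked example

```r
library(tvarousal)

## fit a simulated whole-report session (7 conditions x 20 trials)
params <- tva_params(C = 33.8, t0 = 6, K = 3.85, mu = 150)
trials <- simulate_whole_report(params, seed = 42)
fit_whole_report(trials, seed = 42)
#> TVA parameters: C = 29.66 letters/s, t0 = 2.78 ms, K = 3.84 letters, mu = 178.2 ms
#> logLik = -135.79, R2 = 0.998, status = converged

## pupillary unrest from a synthetic 11-minute trace
trace <- simulate_pupil_trace(base_pd_mm = 6.9, oscillation_amplitude_mm = 0.3, seed = 42)
compute_pui(preprocess_trace(trace))
#> PUI: 7.703 mm/min over 7 segment(s) [flagged: segments excluded]; mean PD 6.63 mm

## the full battery over a synthetic 40 + 40 cohort
cohort <- simulate_cohort(cohort_config(), seed = 42)
analyze_cohort(cohort, seed = 42)
#> Group comparisons (one-tailed rank-sum, BH-FDR):
#>        variable      W     z        p    r p_adjusted significant
#>             vps 1021.0  2.12 1.69e-02 0.24   2.37e-02        TRUE
#>               k 1243.0  4.26 5.46e-06 0.48   1.27e-05        TRUE
#>           alpha  812.5  0.12 4.54e-01 0.01   4.54e-01       FALSE
#>              t0  660.5 -1.34 8.97e-02 0.15   1.05e-01       FALSE
#>  fatigue_mental   82.5 -6.92 2.34e-12 0.77   1.64e-11        TRUE
#>      depression  287.0 -4.96 3.60e-07 0.55   1.26e-06        TRUE
#>      sleepiness  490.5 -2.98 1.42e-03 0.33   2.48e-03        TRUE
#>
#> Distribution non-overlap:
#>   vps: 0.24
#>   k: 0.42
#>   t0: 0.23
#>   alpha: 0.18
#>
#> Model 1 (VPS ~ PUI + mental fatigue): R2 = 0.377 (adj. 0.343), f2 = 0.52, p = 0.0001593
#> Nested model F(4, 33) = 1.28, p = 0.297
#> Mediation pui -> vps -> k (n = 40)
#>   indirect = -0.0867, SE 0.0459, CI [-0.1818, -0.0090]
#>   direct   = -0.0456, CI [-0.1998, 0.1271]
#>   full mediation: TRUE
```

Reading the output: in this synthetic replicate, patients have significantly
lower processing speed (one-tailed, FDR-corrected) with a medium effect
(r = 0.24) and ~24% distribution non-overlap; pupillary unrest and mental
fatigue together explain 38% of processing-speed variance (a large effect,
f² = 0.52); adding covariates buys nothing (nested F p = 0.297); and the
unrest–capacity association is fully mediated by processing speed (indirect
CI excludes 0, direct CI covers it). The excluded PUI segment is a simulated
dropout longer than the 3-s blink rule. One synthetic trace/fit keeps no
segment count or parameter value fixed; rerun with another seed to see the
sampling variability.

`run_pipeline(pipeline_config(), seed = 1, out_dir = "out")` chains all
stages — cohort simulation, per-subject trial simulation and refitting,
trace simulation and PUI computation, and the statistical battery — and
writes CSV/JSON outputs plus a manifest of all stage seeds so a rerun is
byte-identical.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the package-level acceptance quantities from scratch with the
installed package (generating its own inputs) and writes them as JSON keyed
by target id.
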