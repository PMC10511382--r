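---
title: "Methods: visual attention parameters, pupillary unrest and the arousal battery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: visual attention parameters, pupillary unrest and the arousal battery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvarousal)
```

## Scope

`tvarousal` implements a complete analysis chain for studies that relate
*tonic alertness* (measured as visual processing speed under the theory of
visual attention, TVA), *central nervous activation* (measured as pupillary
unrest in darkness) and *subjective mental fatigue* (questionnaire totals).
It covers four layers:

1. a generative TVA race model for whole- and partial-report letter
   paradigms with maximum-likelihood parameter estimation;
2. the pupillary unrest index (PUI, mm/min) computed from raw 25-Hz pupil
   diameter traces;
3. synthetic-data generators for trials, traces and whole cohorts;
4. the statistical battery: rank-sum group tests with effect size *r*,
   bootstrapped kernel-density non-overlap, Spearman correlation matrices
   under Benjamini–Hochberg FDR control, bootstrap multiple regression with
   Cohen's *f²*, nested-model F tests, and percentile-bootstrap mediation.

## The TVA whole-report model

Six letters are briefly displayed and the participant reports all letters
recognized. Under TVA, the letters race in parallel for encoding into a
capacity-limited visual short-term memory (vSTM). With equal attentional
weights across the six positions, each letter is encoded during an effective
exposure $a$ with probability

$$p = 1 - \exp\!\left(-\tfrac{C}{6}\, a\right),$$

where $C$ (letters/s) is the total processing rate — the initial slope of the
performance curve and the quantity of interest as a proxy of tonic alertness.
The effective exposure is

$$a = \max(0,\; \tau + \mu\,[\text{unmasked}] - t_0)/1000,$$

with $\tau$ the nominal exposure (ms), $t_0$ the perceptual threshold (the
x-intercept of the curve) and $\mu$ the visual persistence that prolongs
processing on unmasked displays (masks terminate iconic persistence, so
masked trials gain nothing). The report score is the number of encoded
letters capped at the vSTM capacity $K$ — the curve's asymptote.

**Fractional capacity.** Group-level capacity estimates are routinely
non-integer (e.g. 3.85 letters). We represent $K$ as a two-point mixture on
adjacent integers: capacity $\lfloor K\rfloor$ with probability
$1-(K-\lfloor K\rfloor)$ and $\lfloor K\rfloor + 1$ otherwise. This is the
smallest capacity distribution that is identifiable from a 140-trial session
and reproduces fractional reported values; a free distribution over 0–6
would not be.

With capacity $k$, the score distribution is binomial below the cap with the
upper tail lumped at $k$:
$P(s \mid k) = \binom{6}{s}p^s(1-p)^{6-s}$ for $s < k$ and
$P(k \mid k) = P(\mathrm{Bin}(6,p) \ge k)$. The trial likelihood mixes over
the two capacities. Score probabilities of exactly zero (impossible scores
under a candidate parameter vector) contribute a floor of $10^{-12}$ per
trial so the optimizer never sees $-\infty$.

### Estimation

`fit_whole_report()` maximizes the likelihood over
$(\log C,\; t_0,\; K,\; \mu)$ with bounds $C \in (1, 200)$ letters/s,
$t_0 \in [0, 100]$ ms, $K \in [0.5, 6]$, $\mu \in [0, 500]$ ms. The search is
a derivative-free Nelder–Mead simplex on a logistic reparameterization of the
box, restarted from a seeded Latin-hypercube of starting points (8 by
default); the best restart is returned together with a convergence status.
When a dataset contains no unmasked trials $\mu$ is unidentifiable and is
fixed at 0. Goodness of fit is reported as the squared Pearson correlation
between observed and predicted mean scores across the (typically 7) exposure
conditions — the convention in the TVA literature for summarizing
whole-report fits. At the standard design (7 conditions × 20 trials) the
mean fit $R^2$ in simulation is ≈ 0.99, consistent with the high values
reported for real sessions.

### Partial report and top-down control

In partial report, one or two letters appear at the corners of an imaginary
square (never diagonally): a lone target, a target with a distractor, or two
targets; only targets (red letters) are to be reported. Item $x$ races with
rate $v_x = C\, w_x / \sum_z w_z$, summing over displayed items, with target
weight fixed at 1 and distractor weight $w_D = \alpha$. The top-down control
parameter $\alpha = w_D / w_T$ is 0 for perfect selection and 1 for none.
With at most two items the race probabilities are available in closed form;
e.g. with capacity 1 the target is reported iff it finishes first:
$P = \tfrac{v_T}{v_T + v_D}\left(1 - e^{-(v_T+v_D)a}\right)$. The likelihood
treats the per-condition count of reported targets as the observation;
positional sensory differences are deliberately not modelled (the 16
condition layouts are preserved in the data representation). `fit_partial_report()`
estimates $\alpha$ alone when whole-report parameters are supplied, or
$(\alpha, C, t_0)$ otherwise with $K$ held at 4 — with two-item displays any
capacity ≥ 2 is equivalent, so this choice is innocuous.

$\alpha$ estimates from 288 trials are noisy (the information about $\alpha$
sits in 144 binary target-report outcomes), so recovery is assessed on the
median over replicate sessions; the estimator's bias shrinks with trial
count, which the test suite checks by Monte-Carlo.

## The pupillary unrest index

The PUI quantifies slow "fatigue waves" of the dark-adapted pupil. The
computation follows the pupillographic sleepiness test convention exactly:

1. **Artifact handling.** Samples flagged by the device, outside plausible
   bounds (default 1.5–9 mm) or following a physiologically impossible jump
   (> 1 mm between consecutive 40-ms samples) become gaps; gaps are bridged
   by linear interpolation between the nearest valid neighbours. Blinks are
   brief; a gap longer than 3 s cannot be a blink, so any 82.5-s segment
   overlapping one is excluded (as is a segment with more than 25%
   interpolated samples). The bounds and the 25% rule are our own defaults —
   the source method names the artifact types but not thresholds.
2. **Block averaging.** Non-overlapping means of 16 consecutive samples act
   as a low-pass filter, decimating 25 Hz to 1.5625 Hz.
3. **Segment PUI.** Each 82.5-s segment holds 128 block means (127 absolute
   successive differences); their sum, normalized to one minute
   ($\times 60/82.5$), is the segment PUI in mm/min.
4. **Totals.** An 11-min recording yields 8 segments; the total PUI is the
   mean over valid segments and the mean pupil diameter (PD) is averaged over
   samples outside long gaps (post-interpolation).

One bookkeeping subtlety: 82.5 s at 25 Hz is 2062.5 samples. Each segment
uses its first 128 complete blocks (2048 samples) — reproducing the
127-difference convention — while segment origins advance by a full 82.5 s of
real time (start indices rounded to the nearest sample), so 660 s still
yields exactly 8 segments. Whether the vendor software overlaps segments or
skips the residual 14.5 samples is not documented; this is one defensible
reading, and a constant trace yields a PUI of exactly 0 under it.

## The synthetic cohort: a stated world

No patient data are distributed, so the generators emulate the study design:
40 post-COVID patients and 40 matched controls; per group the marginal
means/SDs of the attention parameters, pupillary measures and questionnaire
totals are taken from the study's descriptive tables. Two values are not
available there and were chosen once on plausibility grounds: control-group
PUI (3.2 ± 1.4 mm/min) and PD (7.4 ± 0.9 mm) — pupillography was not
performed in the study's control group — and a visual persistence
$\mu \sim N(150, 40)$ ms for trial-level simulation, a typical iconic-memory
scale. The depression score is clipped to the instrument's standard 0–21
range (the source text says 0–24, which does not match the instrument; the
bound is configurable).

**Correlation structure.** Within groups, variables follow a Gaussian copula
whose target rank-correlation matrix comes from a small path model: a latent
arousal factor loads positively on processing speed (0.75) and negatively on
pupillary unrest (−0.68) and mental fatigue (−0.72), reproducing the anchor
correlations $\rho(C,\mathrm{PUI}) \approx -0.51$,
$\rho(C,\mathrm{fatigue}) \approx -0.54$. A pupil-specific factor shared only
by PUI and PD gives $\rho(\mathrm{PUI},\mathrm{PD}) \approx -0.45$ without
tying PD to the cognitive measures; a fatigue-specific factor links
depression (≈ 0.50) and sleepiness (≈ 0.30) to fatigue. Capacity $K$ is
driven by processing speed alone ($\rho = 0.574$), which *encodes the
full-mediation structure*: $K$ is conditionally independent of PUI given
$C$, so the PUI–$K$ association is entirely indirect. Two consequences are
accepted rather than hidden: the implied $\rho(K,\mathrm{PUI}) \approx -0.29$
is weaker than the study's printed −0.433, and the implied
$\rho(\mathrm{PUI},\mathrm{fatigue}) \approx 0.49$ is stronger than the
printed 0.234 — the printed triple (−0.508, −0.535, 0.234) is in fact
inconsistent with any single-factor model (it would need a loading above 1),
so a compromise is unavoidable and we resolved it in favour of the anchors
the design prioritizes. Target Spearman correlations are converted to copula
(Pearson) correlations via $r = 2\sin(\pi\rho_s/6)$; marginals are normal
with group-specific location/scale, then clipped to scale bounds and rounded
where integer-valued.

The generators state what they do **not** emulate: letter confusability and
response bias, positional weight asymmetries, circadian or within-session
drift in the attention parameters, and mechanistic (locus-coeruleus) pupil
dynamics — the trace generator is phenomenological (baseline + drift + slow
random-phase oscillation + noise + blinks). A green test therefore
establishes that the pipeline recovers what this world contains, not that
the world exhausts real data.

## Statistical battery

* **Group tests** are Wilcoxon rank-sum with midrank ties. One-tailed
  directions follow the study hypotheses (patients lower on $C$, $K$,
  $\alpha$; higher on $t_0$, fatigue, depression, sleepiness); demographic
  matching checks are two-tailed and the sex ratio uses uncorrected Pearson
  $\chi^2$. The effect size is $r = |z|/\sqrt{N}$ with $z$ from the normal
  approximation with tie and continuity correction; p-values use the exact
  rank-sum distribution when samples are small and untied (as
  `stats::wilcox.test` does), otherwise the same approximation.
* **Non-overlap** of two group distributions is $1 - \int \min(f, g)$ for
  Gaussian-kernel densities (Silverman bandwidth) on a shared grid, averaged
  over nonparametric bootstrap resamples of both groups.
* **FDR control** is Benjamini–Hochberg, applied per result family (group
  battery, correlation matrix, regression model fits) — "among all tests"
  spans heterogeneous families, and per-family control is the interpretable
  reading; families are kept separate in the report.
* **Regression** reports unstandardized and standardized weights with
  case-resampling percentile bootstrap CIs (1000 replicates), $R^2$,
  adjusted $R^2$ and Cohen's $f^2 = R^2_{adj}/(1-R^2_{adj})$. Computing
  $f^2$ from the *adjusted* $R^2$ is deliberate: the study's own printed
  values (adj. $R^2 = 0.338$, $f^2 = 0.51$) are only consistent under this
  convention (the raw $R^2 = 0.373$ would give 0.595). Model comparison uses
  the standard extra-sum-of-squares F test; the implausible denominator df
  printed in the source for that test is treated as a typesetting artifact.
* **Mediation** fits the OLS paths $M \sim X$ and $Y \sim M + X$; the
  indirect effect $a\cdot b$ and the direct effect get percentile bootstrap
  CIs (1000 case resamples). *Full mediation* is flagged when the direct CI
  covers zero while the indirect CI excludes it. For linear models
  total = direct + indirect holds exactly, which the tests assert to
  machine precision. Percentile (not BCa) intervals match the referenced
  PROCESS convention; they are known to be mildly anti-conservative at
  $n = 40$, which is visible in the full-mediation replicate rate (≈ 84%
  rather than the ≈ 90% a perfectly calibrated interval would give).

## Numerical choices and degenerate inputs

* Optimizer convergence: relative tolerance $10^{-10}$ on the negative
  log-likelihood (tighter than the $10^{-6}$ needed), max 2000 simplex
  iterations per restart; non-convergence is flagged, never silent.
* Likelihood floor $10^{-12}$ per trial; all-tied rank tests return
  $z = 0, r = 0, p = 1$ flagged degenerate; zero-variance inputs to
  correlation/non-overlap/mediation raise errors naming the problem;
  rank-deficient regression designs name the collinear columns.
* All stochastic stages (generators, restarts, bootstraps) accept seeds and
  restore the caller's RNG state; the pipeline derives stage seeds from one
  master seed and records them in its run manifest.

## Limitations

* The partial-report likelihood ignores position effects and letter
  confusability; $\alpha$ from a single 288-trial session carries
  substantial sampling noise.
* The cohort copula matches target *pairwise* structure only; higher-order
  dependence is whatever the Gaussian copula implies.
* The PUI segment bookkeeping is one defensible reading of an
  under-documented vendor convention; absolute PUI values from other
  readings could differ at the percent level, though a constant trace is 0
  under all of them.
* Clipping marginals to scale bounds introduces small point masses at the
  bounds; for the default parameterization the effect on correlations is
  well under the Monte-Carlo tolerances the tests use.
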