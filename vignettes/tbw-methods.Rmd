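---
title: "Estimating temporal binding windows from simultaneity judgments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating temporal binding windows from simultaneity judgments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbwindow)
```

## The task and the quantity of interest

In an audiovisual simultaneity-judgment (SJ) experiment an observer is shown
paired auditory and visual stimuli separated by a signed stimulus onset
asynchrony (SOA; negative = auditory first) and reports, trial by trial,
whether the two appeared simultaneous. The probability of a "simultaneous"
response is high near true synchrony and falls off on both sides. The range
of SOAs over which it stays above a criterion — here an absolute 50% — is the
temporal binding window (TBW). A narrower window indicates more accurate
temporal integration of the two modalities.

The window is estimated side by side. Trials are split by SOA sign into an
audio-leading (AV) and a visual-leading (VA) half, and a binomial regression
with a logit link is fitted to each half separately:

$$\Pr(\text{simultaneous} \mid s) = \mathrm{logit}^{-1}(b_0 + b_1 s),$$

with $s$ the signed SOA in ms. The side's 50% crossing is the closed form
$|-b_0/b_1|$; the TBW width is the sum of the two crossings, the asymmetry is
their difference (positive = auditory-shifted window), and the peak
amplitude — a proxy for response confidence — is the larger of the two fitted
curves at $s = 0$, where each side's fitted sigmoid attains its supremum over
its own domain.

Splitting at zero by SOA sign (rather than into two equal-sized halves of the
data) keeps a side's fit unaffected when trials are lost asymmetrically, as
happens when an apparatus rejects individual trials. Per-side fitting is the
default and the tested path; `fit_side(include_other_side = TRUE)` fits a
side's monotone sigmoid to both sides' trials for sensitivity comparison,
with the result labeled accordingly. A zero-SOA level, if a design includes
one, enters both sides.

## Design arithmetic

A target SOA is realized by delaying both stimuli from a common event onset:
the leading modality gets the leading delay, the lagging one gets leading
delay plus $|$SOA$|$, so `audio - video == soa` always. The default design
uses the 14-level schedule ±67, 100, 167, 200, 267, 334, 400 ms, delays
constrained to 200–600 ms, 4 blocks × 4 trials per SOA per block = 16 trials
per SOA, i.e. 224 trials per condition and 448 for a two-condition session.
Because nothing fixes how a given SOA's two delays are chosen per trial, the
leading delay is drawn uniformly on the feasible integer interval
`[delay_min, delay_max - |soa|]`, reproducibly from the design seed.

Apparatus calibration (constant reproduction delays of 170 ms audio / 150 ms
video with 5 / 8 ms jitter by default) is treated as compensated at design
time: estimation always works on nominal SOA levels. The calibration enters
only the simulator's optional effective-onset path
(`simulate_session(use_effective_soa = TRUE)`), which perturbs the effective
SOA by the constant offset and jitter; it is off by default.

## The synthetic observer

No raw trial data accompany the reference study, so the package ships a
generative observer sufficient to exercise every downstream stage: a
piecewise logistic

$$p(s) = \gamma + (1 - \gamma - \lambda)\,\mathrm{logit}^{-1}\!\big(\beta_{AV}(s + c_{AV})\big) \quad (s < 0),$$

and mirrored with $(c_{VA}, \beta_{VA})$ for $s \ge 0$, with guess rate
$\gamma$ and lapse rate $\lambda$. With $\gamma = \lambda = 0$ (the default)
the generative crossings coincide exactly with the 50% estimation criterion,
which is what makes crossing-recovery tests well-posed; nonzero lapse is
exercised in robustness tests only.

The default population emulates a published talk-versus-listen SJ study with
17 participants: crossing means/SDs of 240.76/100.71 (active AV),
119.53/91.45 (active VA), 259/79.13 (passive AV) and 222.41/82.97 ms
(passive VA), and 7 participants losing 1–26 active-condition trials to
microphone failures. Choices the data could not dictate, made once:

* **Zero-truncated, moment-matched crossings.** Crossings must be positive,
  so they are drawn from a zero-truncated normal. Truncation shifts moments
  (truncating a normal with mean 119.53 and SD 91.45 at zero would push the
  realized mean to about 135 ms), so the parent parameters are solved
  numerically such that the *realized* mean and SD equal the stated values
  (for active VA the parent is $\mu \approx -12.9$, $\sigma \approx 155.5$).
  A consequence: a zero-truncated distribution cannot have SD ≥ mean, and
  `population_spec()` rejects such inputs.
* **Cross-condition coupling.** A participant's crossings in the two
  conditions are coupled through a Gaussian copula with correlation 0.5 over
  exact inverse-CDF truncated-normal margins. The copula leaves marginal
  moments exact at any correlation (joint rejection sampling would not).
  The value 0.5 affects paired-test power realism only, not marginal means;
  it is configurable via `rho`.
* **Slopes.** Slope distributions are never reported in SJ group tables. The
  default is lognormal with median 0.015/ms (SD of log 0.3): a logistic
  slope of 0.015/ms puts the 25–75% rise over roughly ±73 ms around the
  crossing, typical of speech-stimulus SJ curves measured over a ±400 ms
  range.
* **Rejection regime.** Rejected trials are drawn uniformly over the active
  condition's trials, since apparatus losses carry no stated SOA dependence;
  the per-participant loss counts are uniform on [1, 26] for
  `min(7, n_participants)` randomly chosen participants. This uniform choice
  is a stand-in — the real per-participant loss distribution is unknown.

What the simulator does **not** emulate: response times, sequential/order
effects within a session, SOA-dependent lapsing, drift across blocks, or any
acoustic/visual stimulus content. Passing recovery tests therefore show that
the estimation chain is correct *for this generative family*, not that real
observers are piecewise-logistic.

## Numerical choices in fitting

* Fits run on per-SOA aggregated counts; the binomial likelihood is
  identical to the trial-level fit (a property test asserts equality to
  1e-8), and aggregation makes large simulations cheap.
* **Separation.** With 16 trials per SOA, all-"simultaneous" (or all-"not")
  sides happen. Ordinary ML then diverges — sometimes silently, with `glm()`
  converging to an intercept near 27 (a fitted probability within 1e-12 of
  1). A fit is declared degenerate on the `glm` separation warning,
  non-convergence, $|b_0| > 15$, $|b_1| > 0.5$, or one-sided data, and is
  then redone with a Jeffreys-prior (Firth) penalty — Newton iterations on
  the hat-adjusted score — which is deterministic, needs no tuning, and
  always yields finite coefficients. Penalized estimates carry a
  `penalized` flag.
* **Minimum slope.** A side with $|b_1| < 10^{-4}$/ms (a 50-ms SOA change
  moving the rate by ~0.1% near the midpoint) has no usable crossing; it is
  flagged unusable (`tbw_no_crossing`) rather than extrapolated to an
  absurd value. Unusable sides propagate as missing estimates, and group
  analyses drop those participants listwise with an explicit count.
* **Extrapolation.** Crossings outside the measured 67–400 ms magnitude
  range are retained but flagged, supporting sensitivity reporting.

## Group statistics

The inferential battery mirrors standard SJ group analyses:

* **Paired t with dz.** `paired_t()` computes the classical paired t and
  Cohen's d as mean difference over SD of differences, so $t = d\sqrt{n}$
  holds identically; `cohens_d_from_t()` inverts it. The average-SD
  standardizer is deliberately not offered, to avoid two silently
  inconsistent "Cohen's d" values in one report.
* **2×2 within-subject ANOVA.** Each effect is tested against its own
  subject × effect interaction stratum (df 1 and n−1); with 2-level factors
  sphericity is trivially satisfied, so no correction machinery is included.
  Partial eta squared is $F/(F + n - 1)$. Degenerate strata (a sum of
  squares that is zero up to rounding) return F = 0 rather than 0/0.
* **Power.** `power_paired_t()` is the exact noncentral-t power
  (noncentrality $d\sqrt{n}$, df $n-1$); `required_n()` inverts it by scan
  plus bisection. Tails matter: at dz = 0.95, α = 0.05, target power 0.95,
  the one-tailed protocol needs **14** pairs and the two-tailed one 17. The
  default is one-tailed and every printed protocol states the tails.
* p-values are reported at full precision with no multiple-testing
  correction, matching how multiple paired tests are conventionally reported
  in this paradigm; users wanting Holm can apply `p.adjust` to the report's
  p column.

## Problem sizes used in the shipped tests

The package's own test suite simulates at sizes chosen to balance
Monte-Carlo error against runtime: moment checks at n = 10,000 draws;
crossing-recovery at 500 sessions each for 16 and 1,000 trials per SOA
(median absolute recovery error ≈ 13 ms and ≈ 1.5 ms respectively); and the
full-pipeline check at 30 cohorts of 17 participants, where pooled group
means sit within 20 ms (≈ 4.4 Monte-Carlo SEs) of the generative means, the
active window is narrower than the passive in (essentially) every replicate,
and the VA-side paired test rejects far more often than the AV-side test —
the qualitative pattern expected when the generative VA effect is large
(dz ≈ 1.2) and the AV effect small (dz ≈ 0.2).

## A worked example

```{r example, eval = FALSE}
cfg <- run_config(seed = 11)
res <- run_pipeline(cfg, outdir = "sj_demo")
res$group
res$analysis$tests[, c("comparison", "t", "df", "p", "cohens_d", "n")]
power_protocol(0.95, 0.05, 0.95, "one")
```

## Known limitations

* The generative model is piecewise-logistic with independent sides; fused
  single-curve models (e.g. Gaussian TBW shapes) and criterion drift are out
  of scope.
* Lapse rates are not estimated from data; a lapsing observer biases the
  50% crossing inward, which robustness tests quantify but the estimator
  does not correct.
* The probit link is available for side fits, but the separation penalty is
  implemented for the logit link only; probit fits on separated data raise
  an error instead.
* Group curves in `plot_tbw_curves()` average per-participant fitted curves;
  they are a display convention, not an estimator.
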