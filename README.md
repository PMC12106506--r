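# tbwindow

Estimation and inference for the **temporal binding window (TBW)** in
audiovisual **simultaneity-judgment (SJ)** experiments, plus a synthetic
observer for testing the whole chain when raw trial data are unavailable.

In an SJ task, an observer sees a visual and hears an auditory stimulus
separated by a signed stimulus onset asynchrony (SOA; negative = auditory
first) and reports whether they seemed simultaneous. The probability of a
"simultaneous" response peaks near synchrony; the SOA range where it exceeds
50% is the TBW. Each side of the window is estimated separately by a binomial
regression with logit link on the signed SOA,

    P(simultaneous | s) = logit^-1(b0 + b1 s),

fitted to the audio-leading trials (AV, s < 0) and the visual-leading trials
(VA, s > 0). The 50% crossing of a side is the closed form |-b0 / b1|; the
window width is the sum of the two crossings, the asymmetry their difference,
and the peak amplitude (a response-confidence proxy) the larger fitted value
at s = 0. Separated sides (all responses identical) are refitted with a
Jeffreys-prior penalty instead of letting the ML intercept diverge.

Group-level inference covers the battery standard in this paradigm: paired
t-tests with Cohen's d in the paired (dz) standardization, so t = d·sqrt(n);
the fully within-subject 2×2 ANOVA (condition × window side) with partial eta
squared F/(F + n − 1); and exact noncentral-t power analysis for paired
designs (`required_n(0.95, 0.05, 0.95, "one")` is 14; the two-tailed protocol
needs 17).

## Worked example

Simulate a 17-participant active/passive cohort from the default population
(whose crossing means/SDs emulate a published talk-versus-listen SJ study),
estimate every TBW, and run the inferential battery:

```r
library(tbwindow)
cfg <- run_config(seed = 11)
res <- run_pipeline(cfg, outdir = "sj_demo")

res$group
#>   condition  n av_mean  av_sd va_mean   va_sd width_mean width_sd peak_mean
#> 1    active 17  203.95 91.692  134.26  85.598     338.21   91.258   0.94843
#> 2   passive 17  216.78 75.401  237.51 118.358     454.29  123.683   0.97673

res$analysis$tests[, c("comparison", "t", "df", "p", "cohens_d", "n")]
#>                comparison       t df         p cohens_d  n
#> 1    av: active - passive -0.8680 16 0.3982501  -0.2105 17
#> 2    va: active - passive -4.1752 16 0.0007147  -1.0126 17
#> 3 width: active - passive -4.8849 16 0.0001652  -1.1848 17
#> 4  peak: active - passive -1.7244 16 0.1039042  -0.4182 17
#> 5   shift active: av - va  1.8889 16 0.0771658   0.4581 17
#> 6  shift passive: av - va -0.5507 16 0.5894210  -0.1336 17

as.data.frame(res$analysis$anova)
#>   effect       F df1 df2         p partial_eta_sq
#> 1      a 23.8621   1  16 0.0001652        0.59862
#> 2      b  0.5373   1  16 0.4741470        0.03249
#> 3    a:b  7.4634   1  16 0.0147728        0.31809
```

The pattern to read off: the active (self-generated) window is narrower than
the passive one, the difference is concentrated on the visual-leading (VA)
side, and the active window is auditory-shifted — while the audio-leading
(AV) sides barely differ. The ANOVA's `a` row is the condition effect, `b`
the side effect, `a:b` their interaction.

The a-priori power protocol prints a G*Power-style block:

```r
power_protocol(0.95, 0.05, 0.95, "one")
#> t test: difference between two dependent means (matched pairs)
#> Analysis: a priori (required sample size)
#>   Tails                 : one
#>   Effect size dz        : 0.95
#>   alpha                 : 0.05
#>   Target power          : 0.95
#>   Noncentrality (at N)  : 3.554575
#>   Critical t (df = 13)  : 1.770933
#>   Required N            : 14
#>   Achieved power        : 0.956946
```

A thin CLI over the same functions ships in
`inst/scripts/tbwindow-cli.R` (subcommands `simulate`, `fit`, `analyze`,
`power`, `report`; exit codes 0/1/2 for success/validation error/runtime
error).

See `vignettes/tbw-methods.Rmd` for the model, the synthetic-observer
population (zero-truncated moment-matched crossings, Gaussian-copula
cross-condition coupling), numerical choices (separation handling, minimum
usable slope, extrapolation flags), and known limitations.

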