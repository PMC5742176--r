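# blinkrv

Multifractal scaling analysis of eye-blink rate variability (BRV).

Spontaneous eye blinks form a point process whose inter-blink
intervals, stacked in order, behave like a colored-noise series.
`blinkrv` extracts blink events from frontopolar EEG (Fp1/Fp2),
builds the interval series, and summarizes its temporal structure by
the scale exponent α(q = 0) of a Gaussian sub-band variant of
multifractal detrended fluctuation analysis (MFDFA).  Resting-state α
turns out to track cognitive test performance, and the package ships
the cohort statistics (median split, one-way ANOVA, Pearson
correlation, Shapiro–Wilk) for exactly that analysis, along with a
bundled 24-subject reference cohort.

It is aimed at researchers in cognitive psychophysiology and
physiological time-series analysis who want a tested, scriptable
blink-dynamics pipeline.

## The estimator

For a series x₁…xₙ (intervals indexed by event number), the profile
Y = cumsum(x − x̄) is detrended at each scale l by subtracting a
Gaussian-smoothed copy (σ(l) = l/4) — a linear sub-band filter in
place of classical windowed polynomial fits.  Variances σ²ₖ(l) over
Nₗ = ⌊n/l⌋ − 1 half-overlapping windows of length 2l form the
partition function

    χ(q, l) = Σₖ [σ²ₖ(l)]^(q/2)  ∝  l^τ(q)

with weights μₖ = [σ²ₖ]^(q/2)/χ.  Least-squares slopes against ln l
over the scale ladder {8, 10, 12, 14, 16, 20, 22, 26, 32, 38, 46,
54, 64} give τ(q), the Holder exponents α(q) (from ½·Σμₖ ln σ²ₖ) and
the spectrum f(q) (from Σμₖ ln μₖ), satisfying f = qα − τ.  The
headline scalar α = α(0) locates the spectrum's peak: 0.5 for
white-noise-like, 1 for pink, 1.5 for brown dynamics, via
α = (γ+1)/2 for a 1/f^γ spectrum.  A classical polynomial-detrended
MFDFA (`method = "poly"`) is included as an independent cross-check,
and generators for colored noise, blink-interval series and
blink-bearing EEG make the whole chain testable without recordings.

## Worked example

```r
library(blinkrv)

# a known-exponent check: white noise should give alpha ~ 0.5
alpha0(colored_noise(4096, gamma = 0, seed = 1))
#> alpha(q=0) = 0.4984  (fit R^2 = 1.000, 13 scales)

# full chain on synthetic data: EEG -> blinks -> BRV -> alpha
truth <- cumsum(as.numeric(blink_intervals(300, 18, alpha_target = 1,
                                           seed = 2)))
rec <- synth_eeg(300, truth[truth < 299.8], seed = 3)   # 75000 samples @ 250 Hz
events <- detect_blinks(rec)                             # bilateral, 4xMAD
brv <- build_brv(events, session = "rest")
mfdfa(as.numeric(brv))

# cohort statistics on the bundled 24-subject table
cohort_report()
```

The report prints the per-group means/SDs, the median split, the
ANOVAs and the regression; on the bundled cohort:

```
BRV cohort report (n = 24 )
...
median split at 4: 9 high / 15 low
  rest_br    group ANOVA: F(1,22) = 0.139, p = 0.713
  rest_alpha group ANOVA: F(1,22) = 6.337, p = 0.020
  iq_br      group ANOVA: F(1,22) = 0.001, p = 0.981
  iq_alpha   group ANOVA: F(1,22) = 0.184, p = 0.672
  br         rest-vs-task ANOVA: F(1,46) = 0.078, p = 0.7807
  alpha      rest-vs-task ANOVA: F(1,46) = 9.339, p = 0.0037
  resting alpha vs score: Pearson r(22) = 0.429, p = 0.0365, R^2 = 0.184
```

Read: blink *rate* does not separate the high- and low-scoring
groups (F ≈ 0.14), but the resting-state scale exponent does
(F ≈ 6.3, p = 0.02), resting α correlates with the score
(r ≈ 0.43), and α drops from rest to task (p ≈ 0.004).

A thin CLI wraps the same functions
(`system.file("cli", "blinkrv", package = "blinkrv")`) with verbs
`simulate`, `detect`, `mfdfa`, `stats`/`reproduce` and
`simulate-cohort`.

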