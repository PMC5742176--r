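---
title: "Multifractal scaling of blink rate variability: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multifractal scaling of blink rate variability: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blinkrv)
```

## The measurement problem

Spontaneous eye blinks occur every few seconds, and the sequence of
intervals between consecutive blinks — blink rate variability (BRV),
by analogy with heart rate variability — is not a renewal process:
interval fluctuations carry structure across many time scales.  A
compact way to summarize such structure is a scale exponent
$\alpha$: the rate at which the magnitude of detrended fluctuations
grows with the window over which they are measured.  For a process
with power spectrum $S(f) \propto 1/f^{\gamma}$ the two descriptions
are linked by

$$\alpha = \frac{\gamma + 1}{2}, \qquad \gamma > -1,$$

so $\alpha = 0.5$, $1$ and $1.5$ correspond to white, pink and brown
noise.  `blinkrv` estimates $\alpha$ (and the full multifractal
spectrum around it) for BRV series extracted from frontopolar EEG,
and provides the cohort statistics used to relate resting-state
$\alpha$ to cognitive test scores.

A BRV series is analyzed **by event index**, not resampled in clock
time: the $i$-th sample is simply the $i$-th inter-blink interval.
This matches how the series is constructed (intervals stacked in
order) and avoids interpolation artifacts, but it means "scale"
is measured in events, not seconds.

## The estimator

The fitting function `mfdfa()` implements a sub-band variant of
multifractal detrended fluctuation analysis.  For a series
$x_1,\dots,x_n$:

1. **Profile.** $Y_t = \sum_{i\le t}(x_i - \bar x)$.  Classical DFA
   integrates before windowing, and the colored-noise taxonomy above
   ($\alpha=0.5$ for white input) is only consistent with an
   integrated profile, so integration is on by default
   (`integrate = TRUE`); it can be disabled for pre-integrated input.
2. **Sub-band detrending.**  For each scale $l$ the trend is the
   Gaussian-smoothed profile, and the fluctuation is
   $Y - G_{\sigma(l)} * Y$.  This is a *linear*, shift-invariant
   operator — unlike windowed polynomial fits it cannot create
   discontinuities at window boundaries, and its stop band tracks the
   analysis scale.  We take $\sigma(l) = l/4$ (kernel truncated at
   $\pm 4\sigma$), which puts the kernel's FWHM at $\approx 0.59\,l$
   so the suppressed band stays proportional to the window length.
   The mapping is exposed (`sigma_rule`) because only the
   proportionality, not the constant, is essential.
3. **Windowed variances.**  The fluctuation series is cut into
   $N_l = \lfloor n/l \rfloor - 1$ sub-windows of length $2l$
   advancing by $l$ (50 % overlap) and the population variance
   $\sigma^2_k(l)$ of each is recorded.  Half-overlap is the densest
   tiling that reuses no more than half of each window; the count
   identity $N_l = \lfloor n/l\rfloor - 1$ is tested exactly.
4. **Partition function and spectrum.**
   $$\chi(q, l) = \sum_{k=1}^{N_l} \left[\sigma^2_k(l)\right]^{q/2},
     \qquad \chi(q, l) \propto l^{\tau(q)},$$
   with weights $\mu_k(q,l) = [\sigma^2_k]^{q/2}/\chi(q,l)$ (the
   normalized summands of $\chi$, so $\sum_k \mu_k = 1$ by
   construction).  The Holder exponents and spectrum values are
   estimated as least-squares slopes against $\ln l$ over the
   retained scales:
   $\tau(q)$ from $\ln\chi$, $\alpha(q)$ from
   $\tfrac12\sum_k \mu_k \ln \sigma^2_k$, and $f(q)$ from
   $\sum_k \mu_k \ln \mu_k$ — the direct (Chhabra–Jensen style)
   estimation, with the $l\to 0$ limits replaced by regressions over
   the finite scale ladder.

Two conventions deserve a note.  First, the weights use the exponent
$q/2$, matching the summands of $\chi$; normalization to 1 forces
this choice, and with it the three regressions are linearly dependent,
so the Legendre relation $f(q) = q\,\alpha(q) - \tau(q)$ holds
*identically* on the estimates (the test suite asserts it to
$10^{-1}$, and it is in fact exact to machine precision).  Second,
because $\ln\sigma^2 = 2\ln\sigma$, the raw $\alpha(q)$ regression is
in log-variance units; the factor `calibration = 0.5` converts to
fluctuation units, the convention under which white noise yields
$\alpha(0)=0.5$.  Both are arguments, not constants, so the verbatim
log-variance slope is one `calibration = 1` away.

The headline scalar is $\alpha = \alpha(q=0)$, the peak position of
the multifractal spectrum $f(\alpha)$; `alpha0()` is a shortcut that
returns it with its fit $R^2$.

**Scale set and retention.**  The default ladder is
$\{8, 10, 12, 14, 16, 20, 22, 26, 32, 38, 46, 54, 64\}$ (half-window
lengths in events).  Scales with $N_l < 4$ are dropped — a variance
power-law fit on fewer than four windows per scale is noise — and
fewer than five surviving scales is an error rather than a silent
degraded fit.  For the ~90-interval series a 5-minute resting session
produces, this means the fit typically uses scales 8–16; series
shorter than 80 intervals cannot be fit at all with the default
ladder, which the pipeline reports as an exclusion (see below).

**Degenerate windows.**  A zero-variance window contributes
$0^{q/2}$, which diverges for $q<0$; such windows are excluded from
the weighted sums with a warning.  They cannot occur for continuous
noise, only for pathological constant segments.

**Classical oracle.**  `mfdfa(method = "poly")` is conventional
MFDFA — non-overlapping windows of length $2l$ taken from both ends
of the series, least-squares polynomial detrending (default order 1),
then the same partition machinery — kept as an independent
cross-check: the two methods agree on $\alpha(0)$ within 0.1 on
monofractal fractional noise (tested over ensembles at three Hurst
values).

## Synthetic data: what it emulates and what it does not

The generators exist so every downstream stage is testable without
recordings.

* `colored_noise(n, gamma)` uses spectral synthesis: complex Gaussian
  Fourier coefficients shaped by $|2\sin(\pi f)|^{-\gamma/2}$, the
  exact frequency response of fractional differencing (equal to
  $f^{-\gamma/2}$ at low frequency).  The discrete response makes the
  construction self-consistent on the grid — the first difference of
  a $\gamma=2$ series is exactly white — at $O(n\log n)$ cost.
  Output is normalized to zero mean and the requested SD.
* `blink_intervals(duration, mean_rate, alpha_target)` builds a BRV
  series with a prescribed exponent: colored noise with
  $\gamma = 2\alpha_{\rm target} - 1$ is exponentiated
  (lognormal intervals; positivity *without clipping*, which would
  distort small-interval scaling) and affinely rescaled so the mean
  interval is $60/\text{rate}$ and no interval falls below the
  refractory floor (default 0.25 s).  The log-scale SD is kept small
  (default 0.4) so the monotone transform approximately preserves the
  scaling; this is *verified*, not assumed: the recovery test
  regenerates 100 series of ~2000 intervals at
  $\alpha_{\rm target}=1$ and requires the ensemble-mean estimate
  within 0.1.  The lognormal construction is a stand-in for testing,
  not a claim about blink physiology.
* `synth_eeg()` renders blinks as raised-cosine pulses (default
  300 ms wide, 100 µV) identical on Fp1 and Fp2, over independent
  pink background noise (default $\gamma=1$, 15 µV) per channel at
  250 Hz.  Real blink waveforms are asymmetric and variable, real EEG
  is nonstationary and shares noise across channels, and saccades,
  EMG, line noise and electrode drift are absent by design — so
  passing detection benchmarks here shows the algorithm is correct
  under its stated model, not that it is robust to every recording
  artifact.  Session lengths default to the study protocol: 5 min
  rest, 10 min task.

## Blink detection

The extraction algorithm is deliberately simple and fully
parameterized: zero-phase Butterworth band-pass 0.5–10 Hz (order 2),
adaptive threshold $k\cdot\mathrm{MAD}$ of the filtered trace with
$k = 4$ (floored at 10 µV), local-maximum peak picking, 250 ms
refractory period resolved in favor of the larger peak, and —
default on — bilateral coincidence: an event must appear on both
Fp1 and Fp2 within 50 ms, since frontopolar blink deflections are
strongly bilateral while many artifacts are not.  The MAD-based
threshold makes detection equivariant under amplitude rescaling
(tested), and the event count is non-increasing in $k$ (tested).
The benchmark condition — 100 µV pulses over 15 µV pink noise —
requires a mean F1 of at least 0.95 at 100 ms matching tolerance,
with exact recovery in the noiseless case.

Manual and video verification of blinks, used in the original
protocol, is replaced by the QC report: a session passes if its BRV
has at least 30 intervals (configurable; boundary inclusive).  Thirty
intervals clear the blink-count floor yet still fall short of the
80 needed by the default scale ladder; `run_subject()` therefore has
a second exclusion path ("too short for scaling analysis") so such
sessions are flagged, never crashed on and never silently dropped.

## Cohort statistics

`cohort_report()` recomputes every statistic from the per-subject
table; no printed value is ever hard-coded.  Choices:

* Median split: high group strictly above the sample median (mean of
  the central order statistics for even $n$); on the bundled cohort
  the threshold is 4 with a 9/15 split.
* SDs use the $n-1$ denominator, matching the bundled table's summary
  row.
* One-way ANOVA is the classic equal-variance $F$
  (`oneway.test(var.equal = TRUE)`), identical to the squared pooled
  $t$; correlation p-values are two-sided via the $t$ transform; no
  multiple-testing correction is applied (none is part of the
  original design).
* Shapiro–Wilk is delegated to `stats::shapiro.test`.

The bundled 24-subject cohort table stores blink rates to one
decimal and exponents to two.  Statistics recomputed from it
therefore differ in the third digit from values computed on
unrounded per-subject data: the resting-$\alpha$ group ANOVA, for
instance, comes out at $F(1,22) = 6.34$ from the rounded table.  The
package reports what the data give and flags cohorts whose size is
not 24; it does not attempt to reconcile rounding.

## Simulation harness and problem sizes

`simulate_cohort()` generates a cohort with group-specific resting
exponents (defaults 0.94 for the 9 high scorers, 0.72 for the 15
low, task sessions 0.62 for all, rates 18 and 19 blinks/min) and
runs the median-split analysis — a recovery and power harness for
the design.  By default it works at the interval level;
`from_eeg = TRUE` renders EEG and re-detects blinks.  With a null
effect the rejection rate at $p<0.05$ is calibrated (0.045 over 200
replicates in the test suite); with the default contrast the same
harness rejects in 0.87 of replicates.

The test-suite ensembles are sized for precision at interactive
cost: 200 series of length 4096 for the white/brown calibration
(giving ensemble means 0.51 and 1.48 against targets 0.5 and 1.5),
50 seeds per $\gamma$ for the $\alpha$-vs-$(\gamma+1)/2$ regression
(slope within 0.1 of 1), 100 series per Hurst value for the
cross-method check, 50 end-to-end subjects and 20 detection-benchmark
seeds.  All seeds are fixed; every run is deterministic.

## Known limitations

* Event-index scaling ignores interval duration within the window;
  a subject with the same interval ordering but different absolute
  rates gets the same $\alpha$ (by design — the exponent is
  rate-free, and the blink rate is reported separately).
* The 5- vs 10-minute sessions yield BRV series of unequal length.
  Whether to truncate to a common length before comparing exponents
  is an open design question; the package analyzes full series by
  default, and truncation is a one-liner on the interval vector.
* $\alpha$ estimates from ~90 intervals carry sampling SDs around
  0.15–0.2; group statistics, not individual values, are the usable
  output at such lengths.
* Per-subject exponents computed from real recordings depend on
  detection settings and the $\sigma(l)$ rule; comparisons across
  software should fix both.
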