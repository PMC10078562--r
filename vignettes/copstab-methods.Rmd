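---
title: "Postural sway, local dynamic stability, and the copstab pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Postural sway, local dynamic stability, and the copstab pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(copstab)
```

## The measurement problem

Quiet standing is an actively controlled process: the centre of pressure
(COP) under the feet wanders continuously as the nervous system corrects
the body's position. Two complementary families of measures summarize a
30-s COP recording:

* **Sway path lengths** — the cumulative distance travelled by the COP,
  per axis and in the plane. For coordinate series $X_i$ (medio-lateral)
  and $Y_i$ (anterior–posterior), over $n$ increments,
  $$L_{ML} = \sum_i |X_{i+1}-X_i|, \quad
    L_{AP} = \sum_i |Y_{i+1}-Y_i|, \quad
    L_{tot} = \sum_i \sqrt{(\Delta X_i)^2 + (\Delta Y_i)^2}.$$
  A longer path indicates less economical postural control. The sums are
  taken over absolute increments: without the absolute values the per-axis
  sums would telescope to the net displacement $X_n - X_1$, which is not a
  path length. COP series enter this computation unfiltered — any
  smoothing stage removes exactly the high-frequency corrective activity
  the path length is meant to capture — and `compute_sway_paths()` refuses
  input flagged as filtered.

* **Local dynamic stability** — the largest Lyapunov exponent (LyE) of
  the sway dynamics, estimated per direction by the Rosenstein
  nearest-neighbor method. A larger exponent means faster divergence of
  neighboring state-space trajectories, i.e. less stable control.

The package computes both families, extracts breathing rate from a
respiration transducer trace, and carries all outcomes through the
two-way repeated-measures analysis used in a crossed
inhalation-type (normal air vs 7.5% CO~2~-enriched air) by
inhalation-time (5, 10, 15 min of inhalation, plus post-inhalation)
within-subject design.

## State-space reconstruction

A scalar series $x(t)$ is embedded by the method of time delays,
$$X(t) = [x(t),\, x(t+T),\, \dots,\, x(t+(d_E-1)T)],$$
with the delay $T$ and dimension $d_E$ chosen per trial.

**Delay: first minimum of the average mutual information (AMI).** AMI is
estimated from a joint histogram of $(x_t, x_{t+\tau})$ with equal-width
bins, in nats. Two numerical choices matter:

* *Bin count.* The histogram MI estimator carries a positive bias of
  roughly $(B-1)^2/2N$ nats for $B$ bins and $N$ samples. The default for
  long fixtures is 64 bins; for 1500-sample COP trials `trial_lye()` uses
  16 bins, because at $B = 64$ the bias (about 1.3 nats) and its
  lag-to-lag jitter dominate the tail of the AMI curve and the location
  of its first minimum becomes essentially random. With $B^2 \ll N$ the
  delay selection is stable.
* *Minimum detection.* The raw histogram AMI of near-deterministic
  signals has bin-boundary fine structure: shallow spurious dips one lag
  wide that the strict "first interior minimum" rule would latch onto.
  Detection therefore runs on a 3-point moving average of the curve (the
  reported AMI curve itself is unsmoothed). The classic sanity check —
  the delay of a periodic signal is a quarter period, where the lagged
  copy is maximally uninformative — holds in the estimator's operating
  regime, i.e. for an oscillation observed in measurement noise and long
  enough that estimation jitter is below the curvature of the AMI valley
  (the tests use a period-100 tone with noise SD 0.2 at $N = 5\times10^4$).
  A *noiseless, integer-period* sampled sine is a degenerate input for a
  histogram AMI — it takes only 100 distinct values, and the joint
  entropy saturates into a flat plateau rather than a well-defined
  valley — so no estimator of this family recovers the quarter period
  there.
* *Fallbacks.* If the series carries no lag-1 dependence
  (AMI(1) < 0.1 AMI(0), as for white noise) an interior minimum is
  meaningless and the 1/e rule is applied directly: the first lag with
  AMI below AMI(1)/e, else `max_lag` with a flag.

**Dimension: global false nearest neighbors.** For each candidate
dimension $d$ the nearest neighbor of every point is found in the
$d$-dimensional embedding; the pair is *false* if adding the
$(d+1)$-th coordinate inflates its distance by more than $r_{tol} = 15$,
or pushes it beyond $a_{tol} = 2$ sample standard deviations. The chosen
$d_E$ is the smallest $d$ with a false fraction below 1%; if none
qualifies (noise has no finite embedding dimension) the maximum is
returned with a saturation flag. Neighbor distances at rounding-noise
level (exactly repeating states, e.g. a commensurately sampled sine) make
the inflation *ratio* meaningless and are judged by the size criterion
alone. The cohort analysis itself uses a fixed $d_E = 6$ per direction,
the value appropriate for COP signals in this design; FNN selection is
available via `fixed_dE = "AUTO"`.

## The Rosenstein divergence curve

For every embedded point, the nearest neighbor with temporal separation
greater than the signal's mean period (the reciprocal of the
power-weighted mean frequency of the periodogram) is located — the
Theiler exclusion that prevents trivially correlated neighbors. The pair
distance $d_j(i)$ is then tracked $i$ steps forward, and
$\langle \ln d_j(i) \rangle$ is averaged over pairs at each step. The LyE
is the least-squares slope of this curve against time.

* COP trials use the fit window 0–0.75 s at 50 Hz, tracking pairs for
  1 s.
* Pairs with exactly zero initial separation carry no divergence
  information and are excluded; if every pair is excluded the input is
  degenerate and an error is raised.
* The stage is entirely deterministic: identical input gives bit-identical
  curves.
* Amplitude invariance holds by construction: scaling the series by $c$
  shifts the curve by $\ln c$ and leaves the slope unchanged.

**Validation against independent oracles.** Two fixtures with known
exponents validate the estimator end to end. The logistic map at $r = 4$
has the closed-form exponent $\ln 2$ per iteration; its divergence curve
is linear essentially from lag zero (nearest-neighbor separations are
$\sim 10^{-4}$ of the attractor size), and the fixture protocol fits
0–6 iterations. The Lorenz system at $(\sigma, \rho, \beta) =
(10, 28, 8/3)$ is checked against a tangent-space (Benettin) integration
— a fully independent code path that integrates the variational equations
with per-step renormalization ($\approx 0.906$ nats per time unit). The
Lorenz divergence curve shows the classic initial shoulder (fast
alignment of the neighbor vector with the unstable direction) before its
linear regime; the fixture protocol fits 1–3.5 time units, inside the
linear region and well before saturation. A strongly damped,
noise-driven oscillator serves as the negative control: its fitted slope
is two orders of magnitude below the chaotic values.

## Respiration processing

Raw respiration-transducer traces (2000 Hz) are downsampled to 100 Hz
with an anti-alias FIR low-pass (symmetric kernel applied as one centered
convolution, hence exactly zero-phase, with unit DC gain), then
optionally band-pass filtered with a linear-phase FIR: passband
0.5–1 Hz, 8000 coefficients, group delay fully compensated, edges flagged.
The filter's realized response is verified in the tests: unit gain at
0.75 Hz within 0.03%, 75 dB attenuation at 0.05 Hz.

Breathing rate is estimated by positive-peak detection with a hysteresis
threshold equal to 5% of the window's peak-to-peak range on a
25-ms-baseline-smoothed copy, discarding breath-to-breath intervals
outside 3–10 s (the 6–20 breaths/min physiological band) and returning
60 over the mean retained interval. Fewer than two peaks, or no retained
interval, is an explicit undefined-rate error, never a zero.

One pipeline decision deserves emphasis: **the rate detector runs on the
resampled trace, not the band-passed one.** A signal band-limited to
0.5–1 Hz oscillates at least once every 2 s, so it cannot present a
single peak per breath at breathing rates of 0.1–0.33 Hz — the breathing
fundamental lies in the filter's stopband, and what survives the filter
is harmonic ringing at 2–10 cycles per breath whose inter-peak intervals
the 3–10 s band rejects wholesale. Applying the documented detector to
the documented filter output is therefore mathematically incapable of
returning a physiological rate; the two documented components are only
mutually consistent if peak detection sees the unfiltered (resampled)
trace. The band-pass remains available, with its response validated, as
the 0.5–1 Hz isolation step. The acquisition software's `Q = 0.70700`
has no standard FIR interpretation and is carried as metadata only.

## Repeated-measures statistics

Each outcome is aggregated to one value per subject × inhalation-type ×
inhalation-time cell (the mean of up to five 30-s repetitions), screened
for outliers (a subject is dropped for that outcome if its value lies
strictly more than 2.5 sample SDs from the sample mean; single pass, no
re-screening), and analyzed with a fully within-subject two-way ANOVA:

* every effect is tested against its own effect-by-subject interaction;
* Greenhouse–Geisser $\varepsilon$ is estimated from the covariance of
  the orthonormalized contrasts, clipped to $[1/(k-1), 1]$, and applied
  to the degrees of freedom of any effect with more than one numerator
  df; both raw and corrected results are always reported. Under true
  sphericity the corrected test is conservative by construction
  ($\hat\varepsilon < 1$ even when $\varepsilon = 1$), which is why the
  type-I calibration checks evaluate the uncorrected test — exact under
  the compound-symmetric null — while the corrected one guards against
  sphericity violations;
* partial eta squared is $SS_{effect}/(SS_{effect}+SS_{error})$,
  algebraically $F\,df_1/(F\,df_1+df_2)$;
* ANOVA p-values are the standard upper-tail F probabilities (the F test
  is inherently directional, which is the only reading of a "one-tailed
  alpha" consistent with published F/p pairs); Pearson change-score
  correlations report one-tailed p in the observed direction and an
  Evans strength band on $|r|$;
* Bonferroni families: all level pairs for main effects (6 pairs for a
  4-level time factor), and the between-type contrast at each time level
  for the interaction (4 pairs).

The decomposition is verified against `aov()` with an `Error()` stratum
to $10^{-10}$, the 2-level case against the squared paired-t statistic,
and $\varepsilon$ against its closed-form anchors ($\varepsilon = 1$ at
$k = 2$; $\varepsilon = 1/(k-1)$ for rank-one covariance;
$\varepsilon \to 1$ under compound symmetry).

## The synthetic cohort

The deposited study data are not required by any test: a generator
produces balanced cohorts with known ground truth. Per axis, a COP trial
is
$$x(t) = m_s\,[\,u(t) + g\,\sigma_{stat}\,c(t)\,],$$
where $u$ is an exact-discretization Ornstein–Uhlenbeck process
(reversion $\theta$, diffusion $\sigma$ in mm/$\sqrt{s}$;
$\sigma_{stat} = \sigma/\sqrt{2\theta}$), $c$ is a standardized Lorenz
first coordinate with random initial state, $g$ is the dimensionless
chaotic blend ratio, and $m_s$ a log-normal subject multiplier. Design
rationale:

* *Two orthogonal dials.* The diffusion scale $\sigma$ sets sway path
  length; the blend ratio $g$ sets local dynamic stability. Expressing
  the chaotic amplitude *relative* to the stochastic amplitude keeps the
  dials orthogonal — raising $\sigma$ under one condition does not dilute
  that condition's injected stability effect.
* *Chaotic timescale.* The Lorenz component advances 0.04 time units per
  sample (2 tu/s at 50 Hz), so its divergence rate ($\approx 1.8$ nats/s)
  falls inside the 0–0.75 s fit window of the stability stage. A slower
  blend would change the series' appearance without measurably moving
  the fitted slope, leaving the dial ineffective.
* *Defaults.* 10 subjects × {AIR, CO2} × {T5, T10, T15, POST} × 5
  repetitions of 30 s at 50 Hz (1500 samples, 1499 increments);
  $\theta = 1$/s; $\sigma$ = 1.5 (AIR) vs 1.8 (CO2) mm/$\sqrt{s}$ — a
  1.2× multiplier; $g$ = 0.8 (AIR) vs 1.6 (CO2); subject SD 0.15 on the
  log scale. These produce total paths of roughly 400–1000 mm per 30-s
  trial and AP exponents near 0.5–0.7 s⁻¹, within the range reported for
  quiet standing, with both injected effects pointing the way the
  CO~2~-challenge literature reports: longer paths and higher exponents
  under CO~2~.
* *Respiration.* Quasi-periodic unit-amplitude cycles with relative
  cycle-length and amplitude jitter; condition × phase mean rates default
  to the published group means (12.10/10.96 breaths/min during/post for
  air; 15.00/10.71 for CO~2~).
* *Reproducibility.* Every trial is a pure function of the root seed
  (default 20221006) and its design coordinates, via an explicit integer
  seed-mixing function; replicate cohorts use a `seed_offset`.

What the generator does **not** emulate: postural drift and fatigue
trends within a trial, non-stationarity across the session, correlated
ML/AP coupling, sensor quantization, and any biomechanically detailed
(inverted-pendulum) dynamics. Passing recovery tests therefore
demonstrates that the estimators detect the modeled effect classes at
realistic magnitudes — not that the generator reproduces every feature
of force-plate data.

## Problem sizes and calibration checks

The test suite and acceptance script use these sizes, chosen so each
check resolves the property it targets:

* type-I calibration: 2000 null cohorts (n = 10, 2 × 4 design,
  compound-symmetric subject effect) generated at the cohort-table
  level, the stage the calibration claim concerns; rejection rates are
  compared with the 95% binomial interval around 0.05. A full-pipeline
  null (COP trials with identical parameters across conditions) runs at
  400 cohorts with the corresponding interval.
* parameter recovery: 240 trials (120 per condition) through the
  complete sway and stability stages.
* oracle checks: logistic map at $10^4$ samples, Lorenz at
  $3 \times 10^4$ samples (tolerances 5% and 15%), Benettin oracle at
  $2 \times 10^6$ steps.
* Monte-Carlo sway check: 500 replicate 1499-increment Gaussian walks
  against the closed-form Rayleigh step mean $n\sigma\sqrt{\pi/2}$,
  within 1%.
* breathing-rate round trips: 240–480 s windows, where breath-count
  sampling noise is below the 0.5 breaths/min tolerance.

## Known limitations

* The AMI delay estimator is histogram-based; for very short or strongly
  quantized series the delay is stable but estimator-specific, and
  kNN-based MI estimators could select somewhat different delays.
* The published mean embedding delays (tens of samples at the study's
  rate) and group means cannot be checked without the deposited data;
  the package reports its delays but asserts only their order of
  magnitude on synthetic cohorts.
* The rate detector matches the *documented* settings of the acquisition
  software, not the vendor implementation bit-for-bit; its proprietary
  baseline logic is unknown.
* The RM-ANOVA requires a complete crossed design after aggregation;
  missing cells abort with the cell named rather than being imputed.
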