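---
title: "Methods: sleep-window HRV analysis and the IPFM simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sleep-window HRV analysis and the IPFM simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caninehrv)
```

This vignette documents the models, conventions and numerical choices behind
`caninehrv`: what each stage computes, why the defaults are what they are, and
what the synthetic-data generator does and does not emulate.

## The analysis problem

Canine 48-h Holter recordings are reduced to a nocturnal ("sleep") window to
limit activity-driven nonstationarity, cleaned to normal-to-normal (NN)
intervals, and summarized by linear indices (SDNN, RMSSD, spectral band
powers with normalized HF and the LF/HF ratio) and nonlinear indices
(Poincaré SD1/SD2 ellipse descriptors, phase-rectified signal averaging
capacities). Paired pre/post conditions across a small cohort are compared
per index with the exact Wilcoxon signed-rank test. The scientific question
this serves: does an autonomic shift toward sympathetic predominance appear
in nonlinear HRV before conventional echocardiographic indices move?

## The IPFM generator

The simulator uses integral pulse frequency modulation: an instantaneous
rate signal (beats/s)

$$r(t) = \frac{1000}{\overline{RR}}\Big[1 + a_{LF}\sin(2\pi f_{LF}t+\phi_{LF})
 + a_{HF}\sin(2\pi f_{HF}t+\phi_{HF}) + \eta(t)\Big]$$

is integrated, and beat $k$ is emitted when $\int_0^t r$ crosses $k$. IPFM is
the standard way to synthesize RR series whose tachogram has controlled
spectral content: a sinusoidal modulation at $f_0$ produces tachogram power
concentrated at $f_0$, so band-level properties of the whole pipeline can be
checked against ground truth.

Numerics: the integral is evaluated by the trapezoidal rule on a fixed 4 ms
grid and crossing times are linearly interpolated, giving sub-0.01 ms beat
placement for these smooth rate signals (with zero modulation the generator
is an exact metronome, which the tests assert). The broadband term $\eta$ is
Gaussian white noise on the grid, smoothed by a 2-s moving average and
rescaled by $\sqrt{n}$ (the moving average over $n$ samples divides white
noise SD by $\sqrt{n}$) so its SD is exactly `noise_sd`. Smoothing keeps the
noise floor finite-variance and band-limited rather than aliasing
grid-frequency power into the HRV bands.

### Canine preset and the sympathovagal shift

The default configuration emulates a resting/nocturnal dog: mean RR 560 ms
(about 107 bpm, matching the heart rates reported for the population the
package targets), respiratory (HF) modulation at 0.30 Hz with amplitude 0.12
— dogs have marked respiratory sinus arrhythmia — LF modulation at 0.09 Hz
with amplitude 0.05, broadband SD 0.02, and 8-h duration. No quantitative
canine autonomic parameters are published for this design, so the amplitudes
are calibrated only to plausible heart-rate medians and to the qualitative
dominance of vagal over sympathetic modulation during sleep.

The shift parameter $\rho \in [0,1]$ models drug-induced sympathetic
predominance by rescaling before simulation:
$\overline{RR} \mapsto \overline{RR}(1-0.08\rho)$ (mild rate increase),
$a_{HF} \mapsto a_{HF}(1-0.6\rho)$ (vagal withdrawal),
$a_{LF} \mapsto a_{LF}(1+0.4\rho)$. These coefficients are package constants
chosen to reproduce the direction and rough magnitude of the pre/post
contrast of interest (lower SD1/SD2, higher SD2/SD1, faster rate); they are
configuration, not physiological claims. The pipeline-level consequence —
median SD1/SD2 non-increasing in $\rho$ — is asserted by a property test.

Cohorts draw independent Gaussian inter-individual factors (relative SD 5%)
on mean RR and both amplitudes, a mild heterogeneity consistent with a
homogeneous laboratory population, with distinct sub-seeds per subject and
condition.

### What the generator does not emulate

No closed-loop baroreflex (LF oscillations are imposed, not emergent), no
circadian drift within the window, no respiratory frequency wander, no ECG
waveforms (beat times only), and artifact contamination is limited to
premature (ectopic) shifts and missed beats. Passing tests therefore
demonstrate the correctness and calibration of the *analysis*, not that real
doxorubicin cardiotoxicity produces these effect sizes.

## Preprocessing

**Window.** Wall-clock, half-open $[\text{start}, \text{end})$, with day
indices counting midnights after record start; the conventional nocturnal
span for a 48-h record — midnight of the first night to 08:00 of the second
day — is the default (`start_day = 1`, `end_day = 2`). The literal 32-h span
is used rather than two separate 00:00–08:00 nights because the span is
defined in clock time; callers wanting per-night windows call
`select_window()` per night with `start_day = end_day`.

**NN filtering.** An interval is rejected when an endpoint beat is non-normal,
when it falls outside 200–2000 ms, or when it steps more than 25% from the
previously retained interval. The bounds are generous for dogs, whose
respiratory sinus arrhythmia legitimately swings successive intervals by
>10%; 25% still catches premature beats (a 40% early ectopic perturbs its
two flanking intervals by roughly ±40%). Rejected intervals leave *gaps* —
onset times are preserved and nothing is interpolated — so that downstream
modules never treat non-adjacent beats as successive: time-domain successive
differences, Poincaré pairs and PRSA windows all refuse to span a gap.
Filtering is idempotent, and the rules are configurable.

## Spectral analysis

The tachogram (onset, interval) points are cubic-spline interpolated onto a
uniform 4 Hz grid — comfortably above twice the 0.4 Hz analysis edge — and
linearly detrended. Gaps longer than 5 s are bridged linearly between their
bracketing points instead of splined, because spline overshoot across a long
gap injects spurious low-frequency power; bridge counts are recorded.

The default estimator is the full-record rectangular-window periodogram,
normalized so the discrete Parseval identity holds exactly
(`sum(density) * df = mean(x²)`, asserted at 1e-9): band powers then
partition the signal variance. A Welch option (600-s Hann segments, 50%
overlap) reduces variance for the upper bands; since 600-s segments cannot
resolve ULF (fundamental ≈ 3.5e-5 Hz over 8 h), Welch-mode results take ULF
from the full-record periodogram and are flagged `hybrid`.

Band powers integrate bins whose center lies in the half-open band
$[lo, hi)$, which resolves the shared edges at 0.04 and 0.15 Hz
deterministically and makes TP = ULF+VLF+LF+HF hold by construction. nHF,
nLF and LF/HF are reported dimensionless (they are ratios by definition,
whatever units appear alongside them in published tables) and are flagged
missing (`NA`) when their denominator is zero.

## Poincaré descriptors

SD1 is the population SD of the signed transverse distances
$(y_i - x_i)/\sqrt2$; SD2 the population SD of the longitudinal coordinates
$(x_i + y_i - 2m)/\sqrt2$ about the centroid $m$. Two deliberate choices:

* **Population (n) variance** rather than sample (n−1), so the projection
  form agrees *exactly* with the closed forms
  $SD1^2 = \tfrac12\mathrm{Var}(y-x)$, $SD2^2 = \tfrac12\mathrm{Var}(x+y)$
  and the decomposition $SD1^2 + SD2^2 = \mathrm{Var}(x) + \mathrm{Var}(y)$;
  at Holter scale (tens of thousands of pairs) the bias difference is
  negligible, and exact testability wins.
* **SD2 as dispersion along the identity direction** — the standard ellipse
  convention ("length of the ellipse") — rather than distance from the line
  $y = x + \overline{RR}$ sometimes quoted in descriptions of the method.
  Distance from any line *parallel to the identity* measures the transverse
  direction again and would duplicate SD1; the long-axis reading is the one
  consistent with the ellipse geometry, and it is what the package
  implements.

SD1 relates to RMSSD by $SD1 = RMSSD/\sqrt2$ when both use the same
(centered, population) convention; with the package's RMSSD denominator
(number of differences, uncentered) the relative discrepancy is bounded by
$1/n_{\text{pairs}}$ and is asserted at 1e-3 for $n \ge 10^4$.

## PRSA

Deceleration anchors are intervals longer than their predecessor by at most a
factor `rel_threshold` (default 1.05, excluding artifact-scale jumps);
acceleration anchors mirror this; ties anchor neither mode. Anchors need $L$
intervals before and $L-1$ after within one gap-free run (default $L = 5$),
because phase alignment across a filtering gap is meaningless. The averaged
curve is $X(k) = \langle NN_{i+k}\rangle_i$, $k = -L..L-1$, and the capacity
is the anchor-centered Haar-like contrast $[X(0)+X(1)-X(-1)-X(-2)]/4$ — the
standard single-scale form; no wavelet-scale sweep is provided. $L$, the
threshold and the mode are configurable. Note the ratio threshold makes the
*anchor set* scale-invariant but not translation-invariant; the capacity
contrast itself is translation-invariant for a fixed anchor set, which is
how the property is tested.

## Group statistics

Differences post − pre; zeros dropped (the classical exact convention —
stated explicitly because other software retains zeros Pratt-style and will
differ); midranks for ties; $W$ = sum of positive-difference ranks. For
$m \le 20$ the two-sided p is exact: both tails include the observed $W$, the
smaller tail is doubled and capped at 1. The null distribution is built by
dynamic programming over doubled (integer) midranks — arithmetically
identical to enumerating all $2^m$ sign assignments, which the tests verify
bit-for-bit against a literal enumeration oracle. For $m > 20$ a
tie-corrected normal approximation with continuity correction is used and
flagged.

With six subjects the smallest attainable two-sided p is $2/2^6 = 0.03125$;
with five it is 0.0625. Published p-values smaller than these attainable
levels for the stated n (e.g. p = 0.008 at n = 5–6) cannot arise from the
exact test as described and are not reproduction targets for this package.

Summaries use linear-interpolation percentiles (quantile type 7); the results
table renders `median (q25–q75)` by default, with a `(min–max)` option since
published tables sometimes label the parenthetical "range".

## Problem sizes used in the test suite

The packaged tests run the Monte-Carlo calibrations on 6-subject cohorts of
1-h records (100 seeds for the null false-positive check and for power
against shift 0.8; 50 seeds for contamination robustness; 20 seeds for
monotonicity in the shift). One hour at ~107 bpm gives ≈ 6400 NN intervals —
ample for stable SD1/SD2 and RMSSD — and keeps the full suite to minutes;
the 8-h preset is exercised end-to-end by `scripts/acceptance.R`.

## Known limitations

* The spectral estimator is periodogram/Welch only; no Lomb–Scargle,
  autoregressive or multitaper option, so unevenly sampled analysis always
  passes through the 4 Hz resampling.
* Absolute band powers depend on the (unpublished) estimator conventions of
  commercial Holter software; cross-package comparisons should rely on the
  normalized indices and ratios.
* Only lag-1 Poincaré maps; no ellipse area or lagged variants.
* The exact test enumerates up to $m = 20$; beyond that the normal
  approximation is flagged rather than exact.
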