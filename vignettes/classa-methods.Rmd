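---
title: "Classification Angle metrics for HRV: models, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classification Angle metrics for HRV: models, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(classa)
```

## The problem and the model

Heart rate variability (HRV) — the series of beat-to-beat (RR) interval
durations — carries the signature of both autonomic branches: the fast
(sub-second) parasympathetic (PNS) modulation and the slower (several-second)
sympathetic (SNS) drive. The classical route to separating them, the LF
(0.04–0.15 Hz) and HF (0.15–0.4 Hz) spectral band powers, rests on contested
assumptions about what each band represents, requires stationarity, and needs
5-min windows.

The Classification Angle (ClassA) family instead works on a
second-order-difference-plot (SODP) of the HRV signal: the scatter of
successive first-derivative estimates, where each point is

$$(d(n),\, d(n+1)), \qquad
  d(n) = \tfrac{1}{2}\left(4x(n{+}1) - 3x(n) - x(n{+}2)\right),$$

the three-point forward derivative estimate, more accurate than the plain
first difference. The quadrants of this plot admit a direct physiological
reading: quadrant 1 (two successive positive rates of change) is sustained
cardiac deceleration, quadrant 3 sustained acceleration, and quadrants 2 and
4 (a sign change) balanced variability. Four metrics summarize a window of
$N$ samples:

* **PQ1** — fraction of SODP points in quadrant 1, computed on the raw
  (scale-1) signal in short 10-s windows; an index of PNS dominance;
* **PQ2,4** — fraction in quadrants 2 and 4 together, same scale, an index
  of balanced HRV;
* **PQ3** — fraction in quadrant 3 of the *coarse-grained* signal
  ($\tau = 7$ block means of a 60-s window); SNS dynamics are slow, so they
  are read at the higher temporal scale;
* **RAS** (Real Angle Sum) — the per-window sum of each point's
  anti-clockwise angle with the positive abscissa, divided by $N$: a single
  trend number, in $(0°, 90°)$ for predominantly increasing (decelerating)
  windows and $(180°, 270°)$ for decreasing (accelerating) ones.

The two temporal scales are the point of the construction: no balance is
assumed between the branches, so coupled and uncoupled PNS/SNS changes can
be told apart.

## The processing chain and its tunables

`run_record()` executes the standard chain. Each step's default is the
conventional choice; every one is a `classa_config()` field.

| Step | Default | Why |
|---|---|---|
| Resampling | cubic spline onto a 4 Hz grid starting at the first beat | the common HRV convention; a 10-s window then holds exactly 40 samples and a 60-s window 240 |
| Outlier handling | per analysis window; values below $Q_1/1.5$ or above $1.5\,Q_3$ replaced by the median of the values inside $[Q_1, Q_3]$ | ratio fences suit strictly positive RR data; the replacement is a data-typical value, not an extrapolation |
| Short windows | 10 s, 1-s step | PNS resolution; RAS, PQ1, PQ2,4 |
| Long windows | 60 s, 1-s step, $\tau = 7$ | SNS resolution: 240 samples coarse-grain to 34, comparable to the 40 of the short window |
| Traditional windows | 300 s, 1-s step | the standard recommendation for HR, SDNN, spectra and entropies |
| Spectra | full-length Hamming taper, demeaned, density scaling | see below |
| Sample entropy | $m = 2$, $r = 0.15\,\mathrm{SD}$ | the conventional parameterization |
| Permutation entropy | $m = 6$, normalized by $\log m!$ | within the recommended 3–7 range; normalization maps to $[0,1]$ |

Three places the field's descriptions are genuinely ambiguous; each is a
documented, configurable choice here:

* **Interpolation kind** for resampling is rarely stated; we default to a
  cubic spline and expose `interp = "linear"` for sensitivity checks.
* **Outlier fences**: "1.5 times smaller than the 25th percentile" can be
  read multiplicatively ($x < Q_1/1.5$) or as Tukey fences
  ($Q_1 - 1.5\,\mathrm{IQR}$). The multiplicative reading is the default
  (`fence = "multiplicative"`); Tukey fences are available and are the right
  choice for data that can change sign. Quartiles are fixed to the
  linear-interpolation (type-7) convention so fences are bit-reproducible.
  Replacement happens after resampling, within each analysis window.
* **The RAS/proportion denominator**: the construction divides the angle sum
  and the quadrant counts by $N$, the window sample count, although the plot
  has only $N-3$ points. The literal $N$ is the default
  (`denominator = "n"`); `denominator = "points"` divides by $N-3$. Note the
  consequence: under the literal denominator every proportion and RAS carry
  a factor $(N-3)/N$ (0.925 at $N = 40$), so e.g. the trend bands for RAS
  hold exactly for the mean point angle and only approximately — tightly at
  these window sizes — for the $N$-normalized value.

## Numerical choices

* The derivative is evaluated as
  $d = \tfrac{1}{2}\left(3(x_{n+1}-x_n) + (x_{n+1}-x_{n+2})\right)$ —
  algebraically identical to the displayed form, but exact on constant
  windows in floating point (the direct $4x - 3x - x$ evaluation leaves a
  $\sim 10^{-17}$ residue that would mislabel origin points).
* Angles come from the two-argument arctangent mapped to $[0°, 360°)$;
  points with an exactly-zero coordinate receive the exact axis angle (0,
  90, 180 or 270°) and the label `BOUNDARY`: they join no quadrant (the
  quadrants are defined by strict sign patterns) but still contribute their
  angle to RAS. Points at the origin contribute nothing; a window whose
  points all sit at the origin reports RAS 0 with a degeneracy flag.
* Outlier replacement iterates flag-and-replace to its fixed point.
  Replacing a value shifts the quartiles, so a single pass is not
  idempotent; the fixed-point form is, by construction, and coincides with
  the single pass whenever the artifacts are isolated — the case the rule is
  meant for.
* The periodogram uses density scaling compensated for the Hamming taper
  energy, $P_k = 2\lvert X_k \rvert^2 / (f_s \sum_t w_t^2)$, so a sinusoid
  of amplitude $A$ integrates to $A^2/2$ regardless of the taper. The
  published pair of formulas, applied literally, would normalize by $N$
  twice; we implement the standard estimator instead. Demeaning before
  tapering is likewise unstated in most descriptions but essential: DC
  leakage through a Hamming window would otherwise swamp the LF band.
  Band powers integrate trapezoidally over the bins whose centers fall in
  the band; the shared 0.15 Hz edge belongs to HF. Absolute powers are in
  (input unit)² — seconds² here; normalized powers are percentages of the
  0.04–0.5 Hz power.
* Sample entropy follows the template-counting definition with Chebyshev
  distance and self-match exclusion, both template lengths drawn from the
  same $N - m$ templates. A zero tolerance (constant window) or an empty
  match count returns `NA` with a `flag` attribute — never a silent
  infinity. Permutation entropy breaks rank ties by order of occurrence
  (stable ranking); the logarithm base cancels in the $\log m!$
  normalization.
* Kruskal–Wallis tests are tie-corrected with chi-square p-values; an exact
  permutation null (full enumeration of group assignments) is available for
  totals up to 12 and is used as the small-sample cross-check. The pairwise
  epoch contrasts use a Bonferroni threshold of $0.05/2 = 0.025$ (two
  stress-vs-no-stress pairs); the ClassA-by-traditional Spearman family uses
  $0.05/32 \approx 0.0016$. For the correlation analysis the package pools
  per-record per-epoch means (one point per record and epoch); other
  poolings can be assembled from the windowed series directly.

## Epoch segmentation

A protocol (`protocol_config()`) is an ordered list of epochs with 1-min
gaps; the default is the five-epoch stress test (rest, mental arithmetic,
meditation, step exercise, meditation; 15 min each, 4740 s total). Windows
are assigned to the epoch containing their *start* time, and windows
starting inside a gap are discarded. Two caveats follow: a window near an
epoch's end extends into the following gap, and a 5-min traditional window
mixes epochs near every boundary — an unavoidable consequence of window
lengths commensurate with epoch margins. The start-time rule is the default;
summaries over strictly interior windows can be had by shrinking the epoch
intervals before segmentation. Block-averaged (30-s) trajectories of
(PQ1, PQ2,4, PQ3) for three-dimensional state plots are aligned to each
epoch's start.

## What the synthetic generator does and does not emulate

`simulate_rr()` draws beats sequentially: the interval at beat time $t$ is

$$RR(t) = \overline{RR} + \beta t + A_{LF}\sin(2\pi f_{LF} t)
        + A_{HF}\sin(2\pi f_{HF} t) + \varepsilon,
  \qquad \varepsilon \sim \mathcal N(0, \sigma^2),$$

clipped at a positivity floor, with the next beat at $t + RR(t)$. This is
deliberately the minimal model exposing each property the metrics measure:
one narrowband component per spectral band, a slow trend for sustained
acceleration or deceleration, white noise for irregularity. The default
five-epoch parameterization (`default_epoch_specs()`) encodes the canonical
stress physiology at typical resting magnitudes: baseline 0.80 s mean RR
(75 bpm) at rest against 0.65 s (~92 bpm) during exercise; stress epochs
with roughly halved HF amplitude (vagal withdrawal), moderately raised LF
amplitude (sympathetic activation) and a slow negative trend (progressive
cardiac acceleration). `simulate_cohort()` adds mild log-normal
between-subject scaling of the amplitudes and a Gaussian baseline shift,
held constant within a subject.

What this generator is *not*: real HRV has respiratory coupling with a
drifting rate, asymmetric accelerations and decelerations, transient
ectopy, $1/f$ background structure and nonstationary band powers. None of
these are present (autocorrelated noise is the only optional extra), so a
passing validation suite demonstrates that the implementation computes its
definitions correctly and that the chain separates the encoded contrasts —
not that any particular separation will be observed in recorded human data.

## Problem sizes used in the validation suite

The suite runs entirely on generated data: 1000 random windows (10–50
samples) for the SODP oracle and invariance checks; 300-sample windows for
the exact entropy oracles; 1000 null replicates (5 groups × 10) for the
Kruskal–Wallis calibration; and 20 seeded batches of 10 simulated subjects,
each a full 4740-s protocol record analyzed at the standard 1-s increment,
for the end-to-end stress-contrast check. These sizes are the package's
validation choices; all of them regenerate from fixed seeds at test time.

## Known limitations

* The choice $\tau = 7$ trades SNS bandwidth against the number of
  coarse-grained points; nothing in the construction selects it uniquely,
  and PQ3 is correspondingly the least sharply resolved of the four metrics.
* Boundary points (zero coordinates) are counted in no quadrant; with
  continuous-valued data they are measure-zero, but heavily quantized input
  can inflate the uncounted fraction.
* The multiplicative outlier fences presume positive data; use Tukey fences
  for anything sign-changing.
* Series from overlapping sliding windows are strongly autocorrelated;
  epoch summaries therefore use per-record means, and the statistical
  battery treats records, not windows, as the units of inference.
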