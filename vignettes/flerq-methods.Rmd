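---
title: "Quantifying dynamic ICG fluorescence angiography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dynamic ICG fluorescence angiography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flerq)
```

## The measurement problem

Intravenous indocyanine green (ICG) binds plasma proteins and re-emits
light under near-infrared excitation, so the arrival of an ICG bolus in
tissue can be filmed as a rising fluorescence signal. The *absolute*
intensity of that signal is a poor perfusion metric: it depends on the
camera distance, on excitation power, and — crucially for repeated
assessments — on dye left over from earlier injections. The *speed* of
the wash-in does not. `flerq` quantifies wash-in speed as the
**time-to-peak (TTP)**: the elapsed time between the normalized
fluorescence trace crossing 25% and crossing 75% of its within-window
range, evaluated per pixel inside the first 40 s after injection. The
per-pixel map, colour-coded and alpha-blended onto the recorded frame,
is the fluorescence-based enhanced reality (FLER) cartography.

The package reproduces, at desk scale, the analysis of a five-pig
protocol in which bowel perfusion was assessed five times per animal:
at baseline, under three escalating norepinephrine infusion rates
(0.1, 0.5, 1.0 µg/kg/min), and after discontinuation. Because no
recordings are deposited, a synthetic videography module generates
image stacks with the kinetic structure that analysis assumes, and the
published per-pig tables are embedded for the parts of the analysis
that are recomputable exactly.

## Wash-in model

A pixel in region $r$ follows the noiseless trace

$$I_r(t) = B_r + A_r \, S\!\left(\frac{t - t_{0,r}}{\tau_r}\right),
\qquad S(x) = \frac{1}{1 + e^{-x}},$$

with arrival (inflection) time $t_0$ (s), rise time constant $\tau$
(s), amplitude $A$ and accumulated baseline $B$ (detector units). The
logistic family is chosen because its 25–75% rise time has the closed
form $2\ln(3)\,\tau$, giving every downstream check an analytic oracle;
a gamma-variate bolus shape is available behind
`washInTrace(..., family = "gamma")` for sensitivity work. Between
injections a fraction `retention` of the amplitude stays in tissue:
`accumulateBaseline()` maps $B \mapsto B + \text{retention}\cdot A$, so
after $k$ injections with constant $A$, $B_k = A\,r\,(k-1)$.

Defaults, chosen once as plausible study conditions: per-region
$\tau \sim U(1.5, 2.5)$ s, so the baseline regional mean TTP is near
$2\ln 3 \cdot 2 \approx 4.4$ s, the magnitude the published tables
report; $t_0 \sim U(9, 12)$ s so both logistic tails are negligible
inside the 40-s window; $A \sim U(90, 130)$ so the baseline maximum
intensity sits near 100 of 255; `retention = 0.6`; Gaussian detector
noise $\sigma = 2$ detector units (8-bit readout scale); 10 Hz for
40 s. The retention value is illustrative, not fitted: it makes the
simulated minimum/maximum-intensity trajectory qualitatively track the
published accumulation pattern.

## Detector model

Recorded intensity is the ideal trace passed through a transfer
function and clipped to $[0, 255]$ (`detectorResponse()`). Two
responses are provided:

* `"linear"` — identity plus hard clip; the default for single
  sequences (`simulateSequence()`), where it keeps the recorded trace
  exactly equal to the model.
* `"saturating"` — the smooth compressor
  $f(x) = c\,(1 - e^{-x/c})$ with ceiling $c = 255$, followed by the
  hard clip; the default for full protocols (`simulateProtocol()`).

The compressor is the package's model of the empirical observation
that, as dye accumulates, the maximum intensity rises ever more slowly
while the floor keeps climbing, so their difference shrinks. It has an
exact and convenient property: since
$f(B + A S) - f(B) = c\,e^{-B/c}\bigl(1 - e^{-A S / c}\bigr)$, the
baseline $B$ scales the recorded wash-in excursion but cancels from
the min–max normalized trace. Under this detector, accumulation leaves
TTP *exactly* invariant while `fi_min` strictly increases and
`fi_diff` strictly decreases at every injection for any retention
> 0 — the qualitative pattern the published intensity trajectory
shows. A hard clip alone cannot produce that pattern: regional
differences stay constant until the ceiling is hit, and regions that do
hit it lose their trace shape entirely (eventually their whole trace
flattens and the rise time is undefined). Frames are finally rounded
to integer detector units by default (`quantize = TRUE`), which is both
8-bit videography realism and what makes the TIFF round trip
bit-exact.

## Rise-time analysis

Per pixel, `computeTTPMap()`:

1. restricts the trace to timestamps $\le$ 40 s (the analysis window);
2. applies a centred moving average (default 3 frames, truncated at
   the edges) — light smoothing suppresses spurious early threshold
   crossings caused by frame noise;
3. min–max normalizes using the within-window minimum and maximum
   (`normalizeTrace()`). The affine map makes the result invariant to
   detector gain and additive baseline — the distance- and
   accumulation-independence that motivates TTP in the first place. A
   flat trace is flagged degenerate, never divided by zero;
4. finds the *earliest* crossing of each threshold (0.25, 0.75),
   linearly interpolated between the last frame below and the first
   frame at or above the level (`crossingTime()`): sub-frame precision
   with no model assumption;
5. reports `ttp = t75 - t25`. Pixels that are degenerate, or whose
   normalized trace never reaches the upper threshold inside the
   window, are invalid and carry `NA` — not a sentinel value — so that
   ROI means are computed over valid pixels only and stay unbiased.

Two numerical properties are worth knowing. First, **window
truncation bias**: min–max normalization can only see the range the
window contains. For a logistic with both tails inside the window the
computed rise time equals $2\ln(3)\tau$ to within a few milliseconds,
but when $\tau$ is large the 40-s window cannot contain both tails
(that needs roughly $10.7\,\tau$ seconds) and the crossings contract.
At $\tau = 4$ s the best achievable placement ($t_0 = 20$ s) yields
$\approx 8.65$ s against the asymptotic $8.79$ s — a structural bias
of $\approx 0.14$ s, larger than one frame interval at 10 Hz. The
oracle-equivalence checks therefore pass cleanly for
$\tau \in \{0.5, 1, 2\}$ and document the $\tau = 4$ bias rather than
hide it. Second, **noise bias of the per-pixel map mean**: with an
earliest-crossing rule, frame noise inflates the normalized range and
drags `t25` early, so the mean of per-pixel rise times drifts upward
as the recorded excursion shrinks under heavy accumulation (about
+0.8 s by the fifth injection at default noise). The region-level
readout used for stability and recovery checks is therefore
`roiTraceTTP()` — the same analysis applied to the ROI-averaged trace,
where pixel averaging suppresses noise by roughly the square root of
the ROI size. This distinction is stated here precisely because a
naive average of a noisy rise-time map looks stable at baseline and is
not at high accumulation.

## ROI statistics

`roiStats()` reports, per region: the mean rise time over valid map
pixels; and the minimum and maximum over time (within the window) of
the ROI-averaged intensity trace, with `fi_diff = fi_max - fi_min`.
Temporal extrema of the ROI-mean trace — rather than spatial extrema
of single frames or single pixels — are used because at a dye-free
baseline the pre-arrival floor is genuinely 0, matching how the
published trajectory starts, and single-pixel extrema are
noise-dominated. `summarizeAssessment()` averages exactly four ROI
rows; by linearity the mean of per-ROI differences equals the
difference of means, so only one convention exists. An ROI with fewer
than half its pixels valid triggers a warning, not an error; zero
valid pixels is an error naming the ROI.

## Censored lactate

The point-of-care analyser reports local capillary lactate below
0.6 mmol/L only as "Low" (the interval 0.1–0.59 mmol/L). Summaries
substitute a fixed constant for censored readings before averaging to
avoid underestimation bias (`censoredMean()`). The default constant is
**0.6 mmol/L**, the analyser's reporting limit. The study text states
the substitution as 0.59, but the five published per-assessment means
(0.74, 0.82, 0.64, 0.60, 0.62) are reproducible only with 0.6 —
e.g. at the second assessment $(3 \times 0.6 + 1.3 + 1.0)/5 = 0.82$
exactly, whereas 0.59 gives 0.814. The constant is an explicit
parameter (`substitute`, `lactateSubstitute`, `censorConstant`)
so either convention is one argument away.

## Paired contrasts and table reproduction

`pairedTTest()` implements the two-sided paired Student test,
$t = \bar d / (s_d/\sqrt n)$ with the $n-1$ standard deviation, each
animal acting as its own control. Degenerate cases (zero variance of
the differences) are flagged rather than silently propagated. The sign
convention throughout is *assessment minus baseline*, so a faster
wash-in at a given dose appears as a negative mean difference. No
multiple-testing correction is applied across the four contrasts,
mirroring the study's analysis; with four uncorrected tests at
$n = 5$ this is a reporting convention, not an inferential
recommendation. Rounding (integers for hemodynamics, one decimal for
intensities, two for rise times and lactate) happens only at report
emission.

`reproduceTables()` recomputes the group summaries from per-animal
records. On the embedded table this reproduces the published weight
mean/SD, every per-time-point hemodynamic mean, 23 of the 24
hemodynamic SDs, and all five censored lactate means; the one
discrepant SD cell (diastolic at 10 min: data give 5.45, table prints
6) and three lactate range upper bounds are not recomputable from the
published per-pig values and are reported as computed. The published
per-assessment rise-time and intensity summaries are embedded
separately (`publishedSummaries()`) and drive the worked-example
arithmetic — baseline contrasts $-0.18, -0.51, +0.19, +1.58$ s and the
intensity percent changes — via `reproducePaper()`. Per-pig rise times
were never published, so the study's rise-time SDs and p-values cannot
be recomputed from in-paper data; on synthetic protocols the same code
path is exercised for plumbing correctness instead.

## What the generator does and does not emulate

Emulated: sigmoid wash-in to a plateau within the 40-s window;
additive dye accumulation over five injections; detector saturation,
noise and quantization; per-dose hemodynamics drawn from uniform
ranges bracketing the published per-time-point means ± SD (only
moments are recoverable, not the generating process), with diastolic
forced below systolic and the collapse after discontinuation
guaranteed by the ranges themselves; mostly-censored lactate draws.
Rise-time constants are held fixed within an animal across
assessments, encoding the study's conclusion that vasopressor dose
does not alter wash-in speed — the pipeline is meant to *detect*
stability, so the generator must not inject a dose effect.

Not emulated: camera motion, peristalsis or registration error (the
study fixed the camera on an articulated arm); specular reflection;
spatial texture within a region (kinetics are constant per region);
any receptor-level pharmacology (hemodynamics are phenomenological);
correlation between hemodynamics and wash-in kinetics. Passing tests
on this generator therefore demonstrate correctness of the
quantification given the kinetic model, not robustness to motion or
optical artefacts of real endoscopy.

## Problem sizes and determinism

The shipped checks run at desk scale: 64×64 noiseless stacks for
oracle equivalence, 48×48 five-animal protocols (four 12×12 ROIs,
10 Hz, 40 s) for accumulation and recovery properties, 20×20 frames
for pipeline smoke tests. Every stochastic step takes an explicit
seed; `simulateProtocol()` derives per-sequence sub-seeds from the
master seed, restores the caller's RNG state, and two runs with one
seed are bitwise identical at the tabular level and element-wise for
stacks. `runPipeline()` writes a manifest (configuration, versions,
checksums) sufficient to re-run any stage.

## Known limitations

* The 25–75% rise time is a *duration*, not a latency to peak; it is
  blind to arrival-time differences between regions.
* Window truncation biases rise times low once $\tau \gtrsim 3.3$ s
  at a 40-s window (see above); for slower kinetics the window, not
  the estimator, must grow.
* The per-pixel map mean is noise-biased upward at low recorded
  amplitude; prefer `roiTraceTTP()` for regional readouts.
* Absolute intensities are reported in detector units of a simulated
  8-bit camera; they are comparable within a protocol, not across
  devices.
* The embedded records are transcriptions of printed tables; cells the
  publication itself reports inconsistently are reproduced as computed
  from the per-pig values, with the discrepancies listed above.
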