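---
title: "Models and methods behind whiskertask"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind whiskertask}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(whiskertask)
```

whiskertask analyzes go/no-go whisker aperture-discrimination experiments:
freely moving mice on an 820 mm linear track palpate motorized apertures
(wide = 45 mm go, narrow = 25 mm no-go) and report their decision by licking
or withholding a lick. This vignette explains the statistical models the
package implements, the choices made where the procedure was genuinely open,
and what the synthetic-data tests do and do not demonstrate about real
recordings.

## Behavioral performance

Performance is the signal-detection discriminability

$$ d' = z(\text{hit rate}) - z(\text{false-alarm rate}), $$

computed over scored trials only (neutral-aperture and extinction trials
carry no score). Because the probit transform diverges at 0 and 1, a rate of
0 is clipped to $1/(2n)$ and a rate of 1 to $1 - 1/(2n)$, with $n$ the
number of go or no-go trials respectively. This bounds $|d'|$ at
$z(1 - 1/(2n_{go})) + z(1 - 1/(2n_{nogo}))$ — a ceiling the test suite
checks explicitly. The expert threshold is $z_{0.95}$, reported as 1.65
using the conventional half-up rounding of the tabulated 1.645.

The running d' at trial $i$ uses the half-open window $(i - 200, i]$ — "the
preceding 200 trials" — and leaves gaps where the window lacks either trial
class. Two criterion readouts exist because stage advancement and
learning-speed estimation answer different questions: `expert_criterion()`
works on per-session d' (≥ 4 sessions and ≥ 200 trials above 1.65), while
`first_sustained_crossing()` reads trials-to-expert off the running series.
A crossing is "sustained" when the series stays at or above threshold for
the next 100 defined values; 100 was chosen once as half the running window
so that a single lucky streak cannot qualify.

The moment of insight is the first session whose no-go success rate is at
least 5× the previous session's (zero denominators never qualify). For the
population moment, each animal's session index is rescaled to [0, 1] stage
progression and insights are averaged on that common axis — the natural
reading of aligning animals with different stage lengths.

Lick latencies over trials are fitted with $y = a + b e^{-cx}$ by
least squares with ≥ 20 random multistarts. The asymptote $a$ is a free
parameter initialized at the median latency by default; a flag pins it to
the median instead, since the description of $a$ as "the median lick
latency" and the least-squares fitting cannot both hold exactly.

## Kinematics

Whisker angles (240 Hz, 0° = full retraction, 180° = full protraction) are
band-passed at 2–30 Hz with a 4th-order Butterworth filter applied
forward-backward; only the band is dictated by the analysis, the filter
realization is a documented choice, and zero-phase filtering matters because
any phase lag would bias the Hilbert phase. Whisking phase is the
analytic-signal angle mapped to $[0, 2\pi)$ with $\pi$ at the protraction
peak. Whisking amplitude is peak-to-peak angle in a centered 100 ms window
(a 50 ms margin each side); a Hilbert-envelope alternative was considered
and rejected as the default because "amplitude" for a broadband signal is
most directly the observed angular excursion. Whisking requires amplitude
above 5°, quiescence below 3°, and the 3–5° band is deliberately excluded
from both states — the dead band makes the two labels unambiguous. Frames
within 100 ms of a touch are excluded from both.

Locomotion requires speed above 100 mm/s sustained for 200 ms, rest below
10 mm/s for 200 ms. Velocity is a centered 3-point finite difference at
60 Hz followed by a 50 ms median filter, which suppresses single-frame
tracking jumps without smearing run onsets. Occupancy maps count video
frames in 10 × 1 mm rectangles with half-open bins.

Whisk cycles per trial are full $2\pi$ progressions of the unwrapped phase
inside the trial window; increments from frames whose amplitude is below 3°
are discarded so that filtered noise during quiescence cannot rotate the
phase. Trial windows default to beam-crossing-to-resolution (the touch-to-
decision alternative is a parameter, since the analysis window was an open
question).

## Per-unit statistics

**QC and cell classes.** Units need isolation distance strictly greater
than 15 and an ISI-violation fraction (ISIs < 1.5 ms over all ISIs)
strictly below 3%. The RS/FS boundary is 350 µs trough-to-peak for cortex
and zona incerta and 300 µs for thalamus; RS units are kept in BC/VPM/POm
and FS units in ZIv.

**Onset latency.** Trial-summed PSTH counts in 1 ms bins; the baseline rate
comes from the −800 to −600 ms window, and the latency is the first bin in
the 200 ms search window whose count exceeds the Poisson expectation at
$p \le 0.05$, upper tail only. No correction across the 200 bins is applied
by default because the per-bin rule is the specified procedure; note that
under the null ~5–10 isolated bins per unit will clear an uncorrected 5%
threshold, so single-unit "latencies" without a real response are expected
— population medians are robust to them, and a Bonferroni flag exists for
single-unit use. If the baseline window is empty, a 0.1 Hz floor is applied
and flagged rather than dividing by zero.

**Touch modulation.** Per aperture, per-trial spike counts in the 200 ms
response window are compared against a 200 ms pre-touch baseline (length
chosen for symmetry; only "a baseline window" was specified) with a
two-sided Wilcoxon signed rank test; because the category of interest is an
*increase*, significance additionally requires a positive median paired
difference. Calcium touch modulation sums ΔF/F over ±400 ms (12 frames at
30 Hz, converted by time at other rates) and uses a paired two-tailed
t-test.

**Shuffle nulls.** All tuning significance uses circular-shift shuffles:
all spike times move by one uniform draw from $[0, T)$ and wrap, preserving
the spike count and the ISI structure (up to the single wrap interval)
while destroying the alignment to behavior. A shift of exactly 0 is not
excluded — the draw is uniform as stated, and the event has measure zero.

**Angle and head-angle tuning.** Rates in 5° bins (whisker: 0–180°; head:
−90 to 90°), spikes within 100 ms of touches excluded, modulation depth
$(r_{max} - r_{min})/r_{mean}$, significant above the shuffle 95th
percentile. Bins with less than 0.5 s occupancy are dropped: a rate from a
few dozen milliseconds of occupancy is numerically unstable and would
dominate the depth. The synthetic ground truth uses a von Mises bump on the
doubled angle (the generative form was unspecified; von Mises gives a
closed-form mode for recovery tests).

**Phase tuning.** Rates in 32 phase bins are fitted with
$\lambda(\phi) = \langle\lambda\rangle + Amp\cos(\phi - \phi_{pref})$ by
ordinary linear regression on $(\cos\phi, \sin\phi)$ — equivalently the
first circular Fourier coefficient, which the tests verify to $10^{-9}$.
$SNR = 2 \cdot Amp \sqrt{T/\langle\lambda\rangle}$ with $T = 0.111$ s, the
average whisk-cycle window. Significance is a Kuiper test (implemented in
the package: statistic $V = D^+ + D^-$ with the finite-sample stretch
factor $\sqrt{n} + 0.155 + 0.24/\sqrt{n}$) applied to the spike phases
against circular uniformity; a binned-rate variant sits behind a flag
because the original description ("applied to the firing rate distribution
across phase bins") is ambiguous. The spike-phase default is exact and
assumption-free; its caveat is that non-uniform *phase occupancy* also
registers, which is why phase extraction excludes non-whisking periods.

**Spatial tuning.** Rates in 100 ms time bins are averaged into 20 mm
position bins and modeled as
$A \exp(-(x-\mu)^2 / 2\sigma^2) + \beta_v v + c$, fitted by weighted
nonlinear least squares (weights ∝ time per bin) with a multistart over
$\mu$ (position quantiles) and $\sigma \in \{20, 40, 80\}$ mm, and $\sigma$
bounded below by the 20 mm bin width — a narrower field is unresolvable at
the binning resolution, and an unbounded $\sigma$ lets the Gaussian
collapse onto a single noisy bin. Classification requires three conditions:
(i) the occupancy-weighted variance of the binned rates exceeds its
circular-shift shuffle 95th percentile, (ii) 0 lies outside the amplitude's
95% CI, and (iii) 0 lies inside the speed coefficient's 95% CI. Condition
(i) exists because the linearized amplitude CI does not account for the
search over field position: on homogeneous Poisson units the CI rule alone
flags the majority of units at any recording length, while the gated
classification is calibrated at ~5%. A caveat of condition (iii): a genuine
place field whose position covaries with running speed (mid-track fields
are sampled mostly at speed) can acquire a small but significant speed
coefficient and be excluded — that is the rule working as stated, not a
detection failure, and the fitted $\mu$ remains accurate in those cases.

## Decoding

Spike decoding trains a linear-kernel SVM per 50 ms bin (bin width is a
package default; only the 10-fold cross-validation and the 0–400 ms summary
window were fixed by the procedure) under stratified folds, standardizing
features with training-fold statistics only. Whisker-angle decoding uses a
smooth additive logistic model: each of the 121 per-frame angles enters
through a 3-df natural-spline basis and the model is fitted with
elastic-net-penalized logistic regression, cross-validated on the 80%
training split. Penalization is what makes 121 additive terms identifiable
at realistic trial counts; any smooth additive binary classifier satisfies
the same contract. ROC curves on the held-out 20% carry pointwise 95%
bootstrap bands (100 resamples).

Calcium decoding uses a compact CNN on unit × 24-frame ΔF/F tensors
(12 frames before and after touch at 30 Hz): two blocks of 3×3 convolution
with same-padding, batch normalization, ReLU, and 2×2 max pooling, then a
fully connected layer with two outputs and a softmax, trained with SGD with
momentum 0.9 (the optimizer was named, its coefficient was not) for 100
epochs at learning rate 0.01. Filter counts (8, 16) and minibatch size (32)
are package choices. The network, including backpropagation, is implemented
in R with im2col convolutions; all randomness (weight init, stratified
split, batch order) derives from one seed, so accuracies reproduce exactly.
Inputs of fewer than 8 units or 40 trials are rejected — after two
poolings the spatial dimension would collapse and the split would leave too
few validation trials.

## The synthetic generator

The generator is first-class, tested code and defines the study conditions
under which everything else is validated. Sessions draw i.i.d. uniform
apertures from the stage's set and score them under the stage rules; the
parametric learner follows logistic lick-probability trajectories (defaults:
go 0.5 → 0.95, no-go 0.5 → 0.05) with an optional ≥5-fold insight step.
Inter-trial intervals default to 5–15 s uniform — trial-duration statistics
were never specified, so this is an arbitrary, configurable choice.
Whisker traces oscillate at 14.5 Hz (the reported mean whisking frequency)
with 20° peak-to-peak amplitude during bouts and sub-3° jitter otherwise,
plus exponential touch-locked deflections. Position traces alternate dwells
at the track ends with constant-speed runs (300 mm/s default). Spikes are
inhomogeneous-Poisson by Bernoulli thinning at 1 ms (matching the latency
PSTH bin, with a validity guard at rate·dt ≤ 0.1); the rate model is the
product of baseline, a rectangular 200 ms touch kernel, a locomotion gain,
a von Mises angle factor, a cosine phase factor, and a Gaussian place
factor, clipped at zero. Calcium is the spike train convolved with a
double-exponential kernel (rise 50 ms, decay 400 ms) plus white noise at
30 Hz. Every stream (events, whiskers, position, per-unit spikes, per-unit
noise) derives an independent sub-seed from the master seed, so modules are
individually reproducible.

What passing on this ground truth shows: the estimators recover known
parameters at realistic rates and durations, and the shuffle tests hold
their nominal false-positive rate under exchangeable nulls. What it does
not show: robustness to non-Poisson spiking (bursting, refractoriness),
slow non-stationarity, tracking artifacts, or correlated noise across
units — real recordings have all of these, and the synthetic traces have
none.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 200 homogeneous units ×
100 shuffles for null calibration at ~5 min recording length; 600 s at
10 Hz baseline for phase recovery (tolerance ±15°); 20 units × 50 touches
for latency recovery (median 8 ± 2 ms); 5 place units at σ = 40 mm and
amplitude 15 Hz over ~5 min for spatial recovery (center ± 20 mm); 200
trials × 6 units for spike decoding and 120 trials × 16 units for the CNN.
These sizes give stable statistics while keeping a full run in minutes on a
single core. Decoding demonstrations generate touch responses spanning the
full 0–400 ms summary window so that "separable" holds throughout the
analyzed window.

Ties and degenerate inputs: equal trajectory maxima take the earliest time
(turning is a reaction, so the first attainment matters); max-pooling ties
take the first element in a fixed order; all-zero traces yield an explicit
undefined-phase marker; empty success-rate denominators yield `NA`, never
0; a zero spatial-information matrix is ridge-regularized, which inflates
the CIs and classifies the unit as untuned rather than erroring.

## Known limitations

- The Kuiper p-value is asymptotic; below ~10 spikes the test is refused
  rather than approximated.
- The spatial amplitude CI is a linearization at the optimum; it is
  reported as fitted but should be read jointly with the shuffle gate.
- The phase-modulation amplitude recovered from band-passed real-like
  traces is attenuated (~10–15%) relative to the injected value because
  modulation only acts during whisking bouts and the filter removes some
  modulation power; preferred phase is unaffected.
- The CNN is deliberately minimal and CPU-bound; it is not a general deep
  learning facility.
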