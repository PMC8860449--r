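---
title: "Quantifying hyperventilation-provoked spike-wave seizures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hyperventilation-provoked spike-wave seizures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(swdquant)
```

## The measurement problem

Absence seizures in seizure-prone rats (the WAG/Rij model) appear in the
electrocorticogram (ECoG) as spike-wave discharges (SWDs): rhythmic 5-8 Hz
events with pronounced spectral harmonics, accompanied by behavioral
arrest (EMG atonia). Hyperventilation — provoked by hypoxia, or by
optogenetic stimulation of brainstem respiratory centers — changes how
often these events occur. Quantifying that change requires a chain of
signal-analysis steps over synchronized ECoG, EMG, whole-body
plethysmography and chamber-gas recordings, all sampled at 200 Hz:

1. refine manually annotated seizure windows to objective onset/offset
   boundaries;
2. characterize each event (duration, dominant frequency, harmonic
   content, atonia);
3. estimate the respiratory rate trace from the plethysmography flow;
4. count events in peristimulus bins around each gas-exchange or laser
   onset;
5. compare conditions across animals with paired statistics.

`swdquant` implements this chain, and pairs it with a synthetic-session
generator so every stage can be verified against ground truth without
animal data.

## Event boundary refinement

Candidate windows come from human annotation; the refiner makes their
bounds objective. The rule is an RMS threshold: the seizure is where the
signal amplitude exceeds **2.5 times the pre-event RMS baseline**, and
onset/offset are the times of the **first and last peak** in that
supra-threshold region. Duration is the time between those two peaks, and
only events lasting **at least 2 s (inclusive)** count as seizures.

Several details are deliberate, and worth spelling out:

* **Baseline window.** The pre-event RMS is computed over the 10 s
  preceding the candidate window, shrunk to exclude any overlap with the
  previously accepted event, and never shorter than 2 s (otherwise the
  candidate is rejected). 10 s is long enough for a stable RMS at 200 Hz
  and matches the respiration analysis window scale.
* **Detrending.** Both the baseline and the candidate window are
  detrended by subtracting a centered running mean of 1/3 s before any
  RMS or peak computation. This attenuates content below about 3 Hz —
  electrode drift and sleep-related slow waves — while leaving the 5-8 Hz
  seizure band untouched; 3 Hz is also the low edge of the
  dominant-frequency search band. Without this step, slow components
  masquerade as supra-threshold excursions at the edges of the candidate
  window: the amplitude of a drifting signal relative to its window mean
  is largest at the window edges, which biases onsets early by up to the
  full annotation margin.
* **Sections, not samples.** Amplitude "above threshold" is evaluated on
  a 0.25 s centered running RMS (about 1.5 spike-wave cycles), not on
  individual samples. For any Gaussian-like background, isolated samples
  exceed 2.5 standard deviations about 1.2% of the time, so a rule keyed
  to single supra-threshold samples would routinely latch onto background
  noise in the annotation margins; the 0.25 s RMS of background
  essentially never reaches 2.5 times the baseline RMS. A peak must lie
  inside a supra-threshold section *and* itself exceed the threshold.
* **Peak polarity.** A peak is a local maximum of the absolute detrended
  signal (strictly greater than its predecessor, at least its successor;
  plateaus take their first sample). Montage sign is arbitrary, so
  polarity is not used.
* **Limiting behavior.** At multiplier 0 the bounds are simply the first
  and last local maxima of the window; as the multiplier grows the
  refined duration is non-increasing, and a window with no
  supra-threshold peak yields a typed rejection, not an error. Scaling
  the signal by any positive constant leaves the bounds unchanged,
  because the threshold scales with the baseline RMS.

## Event characterization

**Dominant frequency** is the frequency of maximal FFT power density of
the mean-subtracted event segment, zero-padded to a 0.1 Hz grid and
searched over 3-12 Hz. The band brackets the reported 4.6-7.9 Hz range of
event fundamentals while excluding DC and the harmonics; ties resolve to
the lower frequency; events shorter than one cycle of the band's low edge
are flagged low-confidence. On the 0.1 Hz grid, noiseless harmonic combs
are recovered exactly, and at the default signal-to-noise ratio the
estimate is within 0.1 Hz of the injected fundamental for essentially all
events (the acceptance script measures this).

**Harmonic score.** SWDs are distinguished from non-REM sleep by 5-8 Hz
harmonics in the power spectrogram. The spectrogram uses 1 s Hann
windows, 50% overlap, and 4-fold zero padding (0.25 Hz grid). The
fundamental estimate is the peak of the event-averaged spectrum within
5-8 Hz; for each harmonic k = 2..3 the mean power within ±0.5 Hz of
k-times-the-fundamental is divided by the median power of the two
flanking 1 Hz bands, and the mean ratio is the score. Events score
harmonic when the ratio exceeds 2. The flanking-median background makes
the score robust to ridge width; the 0.25 Hz grid keeps the k-th harmonic
band centered despite fundamental quantization. A pure sinusoid scores
about 1 (no harmonic energy) and band-limited 1-4 Hz slow-wave surrogates
score below threshold in the large majority of draws.

**Atonia.** Behavioral arrest is operationalized as an EMG power drop:
the event's EMG RMS must be at most half the pre-event baseline EMG RMS.
The original criterion was behavioral/visual, so this quantitative
stand-in is deliberately overridable (`drop_fraction`, and a non-strict
mode that skips the check with a warning when no EMG channel exists).

`process_events()` composes the chain in order — refine, duration filter,
atonia, frequency, harmonic score — and logs every rejected candidate
with the stage and reason.

## Respiratory rate

The flow trace is partitioned into consecutive non-overlapping 10 s
windows ("individual windows", hop = window); each window is
mean-subtracted and Fourier-transformed, and its rate is the frequency of
maximal power density within 0.5-4 Hz. Rat breathing spans roughly
0.8-2 Hz across the conditions modeled, so the band brackets it with
margin while excluding DC drift and movement artifact. The raw series is
then smoothed with a 30 s moving average — implemented as a centered
3-window mean with edge truncation (centered vs trailing is not dictated
by the procedure being reproduced; centered was chosen and is flagged
here). Windows of an all-zero signal yield missing values that the
smoother skips with renormalization. By default the per-window argmax is
refined by 4-fold zero padding (0.025 Hz grid, ties toward the lower
frequency); setting `pad_factor = 1` restores strict 0.1 Hz native bins.
Rates are carried in Hz and reported alongside breaths/minute (exactly
60 times the Hz value).

## Peristimulus histograms and summaries

Event onsets are aligned to the protocol's t = 0 (gas exchange or
laser-on) and counted in three 5-min half-open bins per side of the
origin, spanning [-15, +15) minutes. Assignment is by onset only: an
event straddling the origin counts on the side where it began, and an
onset exactly at 0 counts post. Half-open bins partition time, so bin
counts are conserved, invariant under joint time translation, and merging
the three pre bins reproduces the pre-side total exactly. Per animal, the
pre/post totals and mean counts per bin are summarized as group mean ±
SEM with animals as the experimental unit.

## Statistics

All comparisons are gated on normality: Shapiro-Wilk on the paired
differences at the 0.05 level routes to a paired t-test or a Wilcoxon
signed-rank test (exact p for n ≤ 25 without ties, normal approximation
with continuity correction otherwise). All-zero differences produce a
flagged degenerate result with p = 1. The repeated-measures ANOVA removes
the per-animal effect, forms F from the condition and error sums of
squares, and scales both degrees of freedom by the Greenhouse-Geisser
epsilon computed from the double-centered condition covariance
(Huynh-Feldt available). At k = 2 epsilon is exactly 1 and F equals the
squared paired t statistic. Pairwise post-hoc comparisons reuse the gated
paired machinery with Holm correction — the multiplicity procedure is a
package decision, documented rather than asserted as equivalent to any
particular historical software default.

## The synthetic generator

The generator emulates the statistical structure the analysis relies on,
not the biophysics:

* **ECoG background**: Gaussian 1/f^α noise with α = 2 (a typical
  broadband ECoG slope over 1-50 Hz) at 25 µV RMS, with a first-order
  0.1 Hz high-pass corner reproducing the acquisition band-pass of the
  recordings being emulated.
* **SWD bursts**: harmonic combs — four harmonics with geometric
  amplitude decay 0.6, random phases, raised-cosine 0.2 s ramps —
  because the analysis identifies SWDs by their harmonic spectrogram
  signature, not by spike morphology. The fundamental amplitude defaults
  to 250 µV, i.e. a signal-to-noise ratio of 10 against the background
  RMS; no amplitude statistics are available for the recordings being
  emulated, so SNR is a package choice, exposed as a parameter and
  exercised across values in the tests.
* **Event placement**: a piecewise-homogeneous Poisson process, one rate
  per condition per 5-min bin (defaults: normoxia 0.89, hypoxia 1.73,
  hypoxia + CO2 0.84, normoxia + CO2 0.95 events/bin — the reported
  group means, used as configurable defaults, not assertions), with
  overlap rejection by redrawing within the bin (cap 100 tries).
  Durations are lognormal with mean 5.5 s and SD 2 s on the natural
  scale: reported per-animal mean durations are 5.3-5.8 s; the per-event
  spread is not reported, so 2 s is a package choice.
* **EMG**: broadband noise at 50 µV RMS, multiplied by 0.2 during events
  (atonia).
* **Respiration**: a phase-continuous unit sinusoid whose instantaneous
  frequency follows a per-condition schedule (normoxia 1.03 Hz, hypoxia
  1.33 Hz, hypoxia + CO2 1.88 Hz, normoxia + CO2 1.78 Hz) with slow
  wander (SD 0.02 Hz over 10 s blocks). A sinusoid suffices because the
  estimator only uses spectral peak location — realistic flow shapes are
  out of scope.
* **Chamber gas**: exponential relaxation to each epoch's target with
  τ = 200 s, the ideal-mixing value for a 5 L chamber at 1.5 L/min flow.
* **Laser**: 10 ms pulses at 20 Hz for 2 s, then 2 s rest (40 pulses per
  train).

One integer seed drives one master generator from which per-channel
sub-streams are derived, so a seed reproduces a whole session bitwise.
The default protocol is 40 min normoxia followed by 20 min hypoxia with
the alignment origin at the boundary.

**What passing tests do and do not show.** The generator's background is
Gaussian and stationary within epochs; real ECoG has non-stationary
arousal-state structure, movement artifacts, and genuine slow-wave sleep
— so recovery rates measured here bound the method's behavior under the
modeled conditions only, and say nothing about annotation quality on
real data. Event morphology, EMG spectra and flow shapes are
deliberately schematic.

## Numerical choices and degenerate inputs

Times are seconds on the session clock (t = 0 at recording start);
intervals are half-open everywhere (epoch membership, PSTH bins). The
text recording dialect writes doubles with 17 significant digits so
fixtures round-trip bit-exactly; EDF quantizes to 16 bits against the
physical limits exactly as stored in its ASCII header, so reading
inverts writing to within one quantization step. Tie-breaks go to the
lower frequency in every argmax. Constant differences skip the Shapiro
test (outside its domain) and default parametric; identical ANOVA
columns give F = 0, p = 1; missing cells are refused rather than
imputed. Sample-precision peak times are used (no sub-sample
interpolation).

## Verification protocol and problem sizes

The test suite builds every fixture in code. Property checks run at
these sizes, chosen to keep the full suite in the low minutes on one
CPU while leaving Monte-Carlo margins well clear of their thresholds:
200 synthetic events for boundary/frequency recovery; 200 + 200 events
for harmonic discrimination; 1000 random event sets for the PSTH
brute-force oracle; 200 replicate 15-animal cohorts for the rate
contrast; 2000 replicates per null for type-I calibration; 150-200
random configurations for generator invariants. `scripts/acceptance.R`
recomputes all headline quantities from scratch at the same sizes.

One measured property deserves honesty: with per-bin Poisson counts at
rates 0.89 vs 1.73 and n = 15 animals, the two-sided paired comparison
of per-animal mean bin counts has a theoretical power of about 0.89
(noncentral-t ceiling), and the measured rejection rate is about 0.90.
A requirement of 95% rejection is not attainable under these exact
generative conditions without changing the rates, the cohort size, or
the sidedness of the test; the package reports the measured rate as-is.

## Known limitations

* Coarse windows must come from annotation (or the generator); the
  package does not do de-novo SWD detection, sleep staging, or artifact
  rejection.
* The EDF layer covers continuous equal-rate signals (the package's own
  sessions); EDF+ annotations and variable-rate files are out of scope.
* The atonia criterion is a quantitative stand-in for a behavioral
  judgment; on real data its threshold needs validation against video
  or observer scores.
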