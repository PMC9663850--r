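---
title: "Sleep staging, spindle detection and cohort stratification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sleep staging, spindle detection and cohort stratification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(somnoblast)
```

somnoblast analyses longitudinal EEG/EMG telemetry from rodent
blast-injury studies: it scores the sleep/wake cycle in 5-s epochs,
detects NREM sleep spindles and their features, stratifies injured
animals by their delta/alpha-ratio trajectory, scores four behavioral
assays, and runs a nonparametric statistics battery. Because such
studies rarely deposit raw recordings, the package ships a synthetic
EEG/EMG/behavior generator with complete ground truth; every analysis
stage is validated against planted truth rather than against a
published dataset. This vignette explains the models, the tunable
parameters, and the design decisions a user or reviewer would want to
audit.

## Spectral estimation

Band powers are computed with Thomson's multitaper method: a sliding
window (default 5 s, advanced by 0.1 s) is tapered with discrete
prolate spheroidal sequences (time-bandwidth 3, 5 tapers, unweighted
average) and the one-sided PSD is integrated over five half-open
bands: delta [2, 4), theta [5, 8), alpha [8, 13), beta [16, 31) and
gamma [32, 100) Hz. The shared 8 Hz edge is assigned to alpha so the
bands never overlap. Band power is the *integral* of the PSD over the
band (uV^2), not the mean density; the choice only rescales ratios of
different-width bands and is fixed throughout.

Per-epoch powers average the spectrogram frames whose centers fall
inside each non-overlapping 5-s epoch. The pipeline driver
`stage_record()` steps the spectrogram by 2.5 s rather than 0.1 s:
within-epoch averaging makes the finer step 25-fold redundant for
staging, and the coarser step keeps a 24-h, 500 Hz record under half a
minute of spectral computation. `multitaper_spectrogram()` itself
retains the classical [5, 0.1] s default for users who want dense
time-frequency maps.

DPSS tapers come from the symmetric tridiagonal commuting matrix; for
windows longer than 1024 samples the sequences are computed on a
1024-point grid and spline-interpolated to full length, then
renormalized to unit energy. The interpolation error is orders of
magnitude below the chi-square fluctuation of any single frame, which
the white-noise oracle test confirms at the property level.

## Staging rules and their calibration

Epochs are classified by a strict precedence hierarchy of band-power
ratios:

1. **AWAKE** if gamma/delta exceeds its cut *and* EMG power exceeds
   the calibration-window median EMG power;
2. else **NREM** if delta/EMG exceeds its cut;
3. else **REM** if theta/(delta x EMG) exceeds its cut;
4. else **UNDETECTABLE** (also any epoch with missing powers —
   missing data are never interpolated).

Each cut is `median + k * s_med` of the corresponding ratio over a
calibration window, where `s_med = sqrt(mean((x - median)^2))` is the
standard deviation from the median; `k` is 0.5 for the awake
gamma/delta cut, 1.0 for the NREM delta/EMG cut, and 1.0 by default
for the REM cut (`rem_k`), which is exposed because this threshold is
the least standardized in practice. Denominators are floored at
1e-12 times their record median so degenerate all-zero epochs fall
through to UNDETECTABLE rather than producing spurious labels.

**Calibration window.** The classical recipe calibrates on a single
hour. A median-plus-spread statistic, however, is a *composition*
statistic: it moves with the state mix of the window, and one hour of
mouse sleep contains only a few dozen state episodes, so its
composition varies enormously from hour to hour. In simulation this
produced occasional catastrophic records (an hour that is mostly awake
pushes the gamma/delta median into the awake mode and the awake rule
above its own population). `stage_record()` therefore calibrates on
the whole record by default and takes `calibration_window_s = 3600`
as an option for the classical behavior. With whole-record
calibration the rules are stable whenever awake occupies less than
half the record — which also delimits what the automatic rules can do
on real data: a recording dominated by wake needs a manually chosen
reference window.

`staging_qc()` replaces interactive visual inspection with an
automated report (per-state fractions, fraction UNDETECTABLE,
transition matrix), keeping the pipeline reproducible.

## Spindle detection and features

EEG is band-passed to 10-20 Hz — deliberately wider than the classical
11-16 Hz because spindle frequency shifts with age and injury — with a
linear-phase FIR kernel (Hamming design, 801 taps at 500 Hz) applied
by FFT circular convolution with the kernel centered at lag zero:
exactly zero phase, output length equal to input length, and at least
40 dB of attenuation by 8 and 24 Hz (verified against the kernel's
frequency response in the tests).

"Peaks" are signed local extrema of the band-passed trace — the
amplitude definition (maximal positive minus minimal negative peak)
only exists for a signed trace, not an envelope. The trace is z-scored
against its whole-record mean and SD; extrema with |z| > 2 are
*selected peaks*. Consecutive selected peaks with successive gaps
below 0.16 s form a candidate, which is a spindle iff it has more than
five selected peaks *and* spans more than 0.2 s. Detection runs over
the whole record and events are then kept only if their midpoint lies
in a NREM epoch; this avoids truncating events at epoch boundaries.
Each emitted event stores its selected-peak list so the three rules
can be re-checked exactly (`check_spindle_rules()`).

Features per event: duration (first-to-last selected peak), amplitude
(max positive minus min negative extremum, uV, on the unnormalized
trace), cycles (positive local maxima in the span — all of them by
default, only supra-threshold ones with `cycles_all = FALSE`),
intra-spindle frequency (cycles/duration, exactly), and symmetry
(position of the largest positive peak relative to the span). Density
is events per second of NREM.

Two definitional ambiguities are settled by config switches with
documented defaults: the cycle count uses all positive maxima (so
intra-spindle frequency tracks the oscillation rate), and the 2-SD
reference is the band-passed trace (not the raw EEG). Note one
systematic property of the cycles/duration estimator: for an event
whose selected span is T seconds, the count-based frequency is biased
high by roughly 1/(2T); at the default 0.6-s bursts this is about
+1 Hz and it cancels in group comparisons, which is why group
contrasts are assessed as orderings and carrier recovery is validated
on longer bursts.

## Delta/alpha cohort stratification

For each subject and state (NREM, REM, AWAKE), the score is
mean(delta)/mean(alpha) over that state's epochs, divided by the same
statistic on the subject's pre-injury baseline record; 1.0 means
unchanged. K-means with k = 2 (50 seeded restarts, best
within-cluster sum of squares) runs on the three-dimensional scores of
all subjects, controls included. Injured subjects in the cluster
holding the majority of controls are labeled SBI-LD, the others
SBI-HD; ties break toward calling the smaller-ratio cluster LD. All
score vectors identical is a degenerate case: a warning, and every
injured subject is SBI-LD. Subjects missing any of the three state
scores (e.g. no REM in a short record) are excluded from clustering,
with a warning. The centroid separation and 90% of it (the plotting
radius of the control/LD cluster circle) are attached as attributes.

## Behavior scoring

The four assays use the published formulas and exclusion rules
verbatim: novel-object preference is `(time3/time4)/(time1/time2)`,
the day-2 novel/familiar ratio corrected for day-1 object bias (a
trial is excluded when summed day-2 exploration is under 10 s — the
rule is applied to day 2 by default, configurable per object); Y-maze
preference is new-arm time over familiar-arm time (excluded under 15 s
in either arm, under 7 total visits, or over 10% tracking loss);
rotarod run times and beam velocities are averaged per subject-day and
then per day with SEM (a single trial reports SEM 0). Rotarod values
are not baseline-normalized by default; everything else can be put in
relative units with `normalize_to_baseline()`.

## The synthetic generator

`sim_config()` fixes the study conditions. EEG is a sum of five
band-limited Gaussian noise components — white noise ideally band-pass
filtered in the frequency domain, unit RMS — multiplied by per-state
amplitude profiles, plus Hann-enveloped spindle bursts planted as a
Poisson process (0.05 events per NREM second, 12.5 Hz carrier, 0.6 s
mean duration) wholly inside NREM episodes; EMG is white noise scaled
by a muscle-tone profile. States follow a semi-Markov chain in 5-s
epochs with geometric dwells (awake 180 s, NREM 150 s, REM 120 s; REM
entered only from NREM; awake dwell times 1.15x longer in the dark
phase, 9:00-21:00 under the reverse light cycle). These defaults give
roughly 45% wake / 39% NREM / 16% REM with moderate circadian
modulation, sleep-state band signatures with strong contrast
(delta-dominant NREM at 2.8x baseline amplitude, theta-dominant REM,
high-gamma/high-EMG wake with prominent 10-20 Hz activity), and
realistic bout statistics.

Two quantitative conventions matter when reading the config. Injury
profiles express *power* ratios (HD: delta x1.5, alpha x0.7, gamma
x0.7, sleep dwell x1.2, carrier -0.4 Hz, spindle amplitude x0.8; LD:
carrier -0.3 Hz only), so they enter amplitudes as square roots — the
HD normalized delta/alpha score is then 1.5/0.7 ~ 2.14 by
construction. Planted spindle amplitude is expressed relative to the
expected whole-record SD of the 10-20 Hz band-passed trace, the same
reference the detector's z-score uses (default 4x; the high-SNR
validation preset `high_snr_spindles()` uses 8x with 1.5-s bursts).
Because awake EEG carries the strongest 10-20 Hz activity, the
whole-record SD sits well above the NREM background and the detector's
false-alarm rate inside NREM stays low — mirroring why the published
detection restricts itself to NREM in the first place.

What the generator does *not* emulate: 1/f broadband structure outside
the five bands, artifacts, epileptiform events, circadian drift beyond
the two-phase dwell modulation, or pharmacological dynamics (a sedative
effect is representable only as a carrier-frequency shift profile).
Passing recovery tests on this generator therefore demonstrates the
pipeline's correctness against its own definitions, not performance on
noisy real-world telemetry.

## Validation sizes and numerical choices

The validation suite exercises: staging recovery on one full 24-h
record (seed 1) plus ten 6-h records straddling the dark-light
transition for sensitivity/specificity; spindle recall/precision and
11/13/15 Hz carrier recovery on high-SNR records of 0.5-1 h; the
12.5 vs 12.1 Hz group contrast on ten batches of 8 + 8 quarter-hour
records; and cohort recovery (11 controls, 8 HD, 8 LD) on ten seeds of
half-hour record pairs. Short records are legitimate here because
state-mean band powers stabilize within a few dozen epochs and all
planted contrasts are multiplicative; they were chosen to keep the
suite fast, and the half-hour cohort records occasionally lack a REM
episode, which exercises the missing-state exclusion path of the
clustering contract.

Numerical conventions collected in one place: half-open band edges;
frame-center epoch assignment; denominator floors at 1e-12 x record
median; UNDETECTABLE for missing epochs; mid-ranks for all ties;
Bonferroni factors equal to the number of pairwise comparisons (3 in
the three-group design); exact Mann-Whitney p for tie-free samples
with min(n, m) <= 8, normal approximation with tie and continuity
correction otherwise; exact signed-rank p by full sign enumeration for
up to 16 non-zero differences (valid under ties); Jarque-Bera
statistic n(S^2/6 + (K-3)^2/24) against chi-square(2), with constant
samples routed to the nonparametric track. The 16-bit EDF writer
quantizes against the physical range exactly as written into its
8-character header field, so round trips are exact to half a
quantization step.

## Known limitations

Epochs at state transitions are intrinsically ambiguous: a 5-s
analysis window centered in a boundary epoch necessarily overlaps the
neighboring state, and a NREM epoch entered from wake inherits enough
wake EMG to fail the delta/EMG rule — such epochs are typically
UNDETECTABLE rather than mislabeled. Band-power fluctuation sets a
hard ceiling on rule-based staging: a 2-Hz-wide band integrated over
5 s has ~20 chi-square degrees of freedom (~30% power SD), so a few
percent of genuine NREM epochs fall below any threshold tied to the
population spread. Both effects are visible in the planted-truth
confusion matrices and bound the achievable epoch agreement in the low
90s; real recordings add artifacts on top. The K-means stratification
assumes exactly two injured phenotypes, as in the published design; it
will split a continuum arbitrarily.
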