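---
title: "Detecting local sleep-like theta events in wake EEG: models, parameters, and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting local sleep-like theta events in wake EEG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(thetawake)
```

## The problem

Sleep pressure builds with time awake and leaves measurable traces in the
waking EEG: theta-band (5–7 Hz) power rises, and brief, spatially
restricted negative waves resembling sleep slow waves — *local sleep-like
events* — appear. Their spatial extent across the scalp (*globality*)
and their trough-to-peak amplitude track how pressing the need for sleep
is, and larger events coincide with slower reaction times in visuomotor
tasks. `thetawake` implements the complete measurement chain on
multichannel scalp EEG, together with a synthetic-session generator that
makes every stage testable against ground truth. Real recordings of this
kind (e.g., long-duration mission studies) are typically access
restricted, so the package's validation is parameter recovery on
simulated sessions whose statistical structure mirrors the assumed
signal model.

## Signal model and detection procedure

**Geometry.** Electrode positions are constructed on a unit sphere from
the 10–20 system's own percentage rules (outer 10% ring at 72° from the
vertex, 18° midline steps, spherical interpolation of interior rows).
The default cap has 58 channels; `P5`/`P6` are excluded from analysis,
leaving 56. Two electrodes are neighbors below an angular distance of
25° (configurable), giving 4–8 neighbors per channel — the graph used by
interpolation, the involvement cluster rule, and cluster statistics.

**Preprocessing.** Band-pass 0.1–48 Hz (zero-phase: an order-2
Butterworth high-pass plus a cascaded order-3 low-pass, chosen over a
single high-order band-pass for numerical stability near DC; the mean is
subtracted exactly because a 0.1 Hz corner cannot settle on short
records), resampling to 512 Hz with conservative artifact-mask
propagation (an output sample is usable only if all source samples
were), earlobe→average re-referencing, and per-channel z-scoring with
moments taken over usable samples only. Channels whose log muscle-band
(20–30 Hz) power exceeds the channel median by 5 robust SDs are
rejected and rebuilt by inverse-distance weighting over good neighbors.
Independent-component artifact removal is out of scope; the pipeline
accepts an upstream artifact mask.

**Spectra.** Welch periodograms with 4 s Hamming windows at 50% overlap.
A 4 s window yields 0.25 Hz bins, yet the analysis convention states
0.125 Hz; the only self-consistent reading is zero-padding each segment
to 8 s, which is what `welch_psd()` does. Band power is the mean over
bins in [5, 7) Hz (closed-open boundary convention). Topographies are
normalised by the scalp-average power, so the channel mean is exactly 1;
a between-condition increase is *global* when strictly more than 50% of
channels increase. PRSA (anchor rule: samples decreasing relative to
their predecessor; half-window 2 s) is available as a
signal-to-noise-enhancing front end to the PSD; both paths are exposed
because the source procedure is ambiguous about whether spectra were
taken on PRSA curves or raw traces. Note one PRSA property relevant to
testing: the two samples that enter the anchor definition retain a
deterministic selection offset (about ∓1/√π on white noise), so noise
floors should be assessed away from the window centre.

**Detection.** Per area (frontal: Fp1, Fp2, AF3, AFz, AF4, F1, Fz, F2;
central: FC1, FCz, FC2, C1, CPz, CP2; parietal: CP1, CPz, CP2, P1, Pz,
P2, PO3, POz, PO4 — the central list shares CPz/CP2 with the parietal
list as printed in the source description of "non-overlapping" areas;
`default_areas(fix_overlap = TRUE)` substitutes Cz/C2 for the suspected
misprint), the channel mean is filtered with a zero-phase 2nd-order
Butterworth band-pass in 5–7 Hz. The threshold is
`median − 2 × median(|x − median|)` over usable samples — the raw median
deviation, no consistency constant, giving −1.349 on a standard-normal
signal. Candidates are interior minima between two consecutive local
maxima whose separation lies within one theta period (1/7–1/5 s, ±20%),
strictly below the threshold; this maxima-pair construction is immune to
slow drifts that plague zero-crossing detectors. Zero-phase filtering
matters here: event timing must not be phase-shifted before the trough
is localised.

**Involvement and globality.** For each candidate, the reference segment
is Pearson-correlated against every channel's theta trace over integer
lags within ±50 ms (a propagation-delay allowance: theta waves travel
across the scalp faster than slow waves), and channels exceeding
r = 0.95 (strict) are involved. The correlation segment is the
candidate's half-wave *padded by two theta cycles per side*
(`corr_pad_cycles = 2`). This padding is the package's one substantive
numerical choice: a 5–7 Hz band lies below the frequency resolution of a
bare one-period segment, so over that window every in-band snippet is
close to a pure sinusoid and the max-lag correlation of *independent*
theta-filtered noise exceeds 0.95 for the majority of channels (measured
~60%); with two cycles of padding the chance involvement drops below
~2% while channels genuinely carrying the event remain above the cut.
The unpadded literal reading stays available via `corr_pad_cycles = 0`.
Involved channels with no involved neighbor are unmarked (isolated
channels are likelier artifacts than one-electrode events), and
candidates whose involved set empties are discarded. Globality is the
involved fraction of analysed channels; amplitude is the
trough-to-following-peak excursion at the involved channel with the
median trough-to-peak slope (lower median on even counts).

**Behaviour and statistics.** Reaction times outside 100–500 ms are
invalid (false starts / outliers); the median split uses the pooled
across-session median with ties counting as "not above". Events are
linked to trials over the half-open window [stim − 250 ms,
stim + 500 ms) spanning motor planning through the maximal admissible
reaction time, and RT is regressed on the window's maximal globality by
OLS (adjusted R², F test of zero slope). Topographic condition effects
use per-channel paired t-tests (df = subjects − 1) corrected by
sign-flip permutation: all 2^n flips when feasible, cluster-forming
threshold at uncorrected two-sided p < 0.05, and a minimum significant
cluster size equal to the 95th percentile of the null max-cluster-size
distribution, floored at 3 neighboring electrodes. With five subjects
the observed assignment and its global mirror both sit in the 32-flip
null, so the achievable family-wise rate is 1/16 — marginally above the
nominal 5% and the reason acceptance allows 7%; simulation puts the
realised rate near 1–2% because of the size floor. The richer
mixed-effects modelling a full study would report is deliberately
summarised here as paired contrasts (`condition_contrast()`): the
bespoke content of this package is the measures, not the routine model
fitting, which standard tools (`lme4` and relatives) perform on the
exported tables.

## The synthetic generator

`gen_background()` produces 1/f (slope 1 by default, capped below
0.1 Hz) noise with a Gaussian alpha peak (9 Hz, twice the trend by
default — the analysis band 5–7 Hz deliberately stays clear of it),
mixed across channels with distance-decaying weights
(`exp(−d/30°)`, row-normalised) so that average referencing and
cross-correlation face realistic spatial correlation. Events are
Hann-windowed theta wavelets (default 1.5 cycles, trough at `t_neg`)
whose amplitude tapers as `cos(π·d/(2·radius))` from the centre channel
to zero at the radius — smooth, monotone, and positive throughout the
disc so that the involved-channel count grows monotonically with the
radius and recovery of the extent is well posed. On microvolt
recordings the trough depth is scaled by each channel's pre-injection
SD, making the specified amplitude a z-unit quantity; on standardised
recordings it is added directly. Trials sit on a jittered inter-stimulus
grid; RT = base + β·G + Gaussian noise, truncated to [50, 800] ms so the
100/500 ms exclusion rules are exercised on both tails, with G the
largest ground-truth globality in the peristimulus window and docking
outcomes assigned independently of events (matching the observed absence
of an outcome association).

**Ground truth for recovery.** Injected globality is the percentage of
analysed channels strictly within the radius. Injected amplitude is
reported through a forward model rather than the raw trough depth: the
clean wavelet is passed through the same 2nd-order theta filter (the
narrowband filter reshapes a 1.5-cycle transient substantially — the
trough-to-peak gain is about 0.5), scaled by the median in-radius taper
weight minus the scalp-mean taper (the average-reference subtraction).
Comparing the detector to this forward model tests the detector, not
the LTI algebra in front of it.

**Recovery harness conditions.** Recovery sessions
(`gen_recovery_session()`) are generated directly in z-units with a
quiet background (SD 0.08 z against trough depths near 3.5 z). This is
deliberate: the specified amplitude is a z-quantity, so literal
re-standardisation would fix the event-to-background ratio and make
"quiet" unexpressible; and the r > 0.95 involvement cut needs in-band
noise well below the tapered event amplitude before the outermost disc
channels are recoverable at all. Condition studies
(`gen_condition_pair()`) pair an "earth" and a "space" session per
subject, with a per-subject radius offset (SD 1°) providing
random-intercept structure, and the second condition's radius chosen by
`calibrate_radius_shift()` so the ground-truth mean globality shifts by
a stated number of percentage points (+4 in the packaged harness,
matching the magnitude such missions report).

**Problem sizes.** The packaged checks use 120 s sessions with 30 events
for single-session recovery (20 seeds), 45 s sessions at 0.8 events/s
for the 5-subject × 2-condition shift study (20 seeds), 237 valid-trial
regressions (20 recovery seeds; 1000 null seeds), and 500 simulated
null experiments for the cluster test — sizes at which every quantity's
Monte-Carlo error is well inside its acceptance band while the whole
suite runs on a laptop-class single core in minutes. The default
`background_spec()` session length of 60 min mirrors the cleaned
duration of typical real sessions; tests shorten it because nothing in
the contracts depends on duration beyond threshold stability.

## What passing tests do and do not show

The generator emulates the *assumed* structure: stationary 1/f + alpha
background, isolated stereotyped wavelet events, linear RT coupling. It
does not emulate non-stationary vigilance drift, ocular/cardiac
artifacts (only optional broadband bursts for mask testing), volume
conduction from deep sources, or electrode impedance drift. Recovery
results therefore validate the algorithmic chain — thresholds, peak
logic, correlation windows, cluster pruning, statistics — not the
biological identifiability of events in arbitrary real data.

Known behaviours worth keeping in mind on real recordings:

- **Average-reference bias.** Subtracting the scalp mean superimposes a
  negative ghost of each event on every channel; channels whose taper
  weight falls below the scalp-mean weight lose their positive
  deflection and cannot pass the correlation cut. Detected globality is
  therefore biased low by roughly the outermost ring of the true extent
  (about 1 channel at a 28° radius here), and between-condition shifts
  compress accordingly (the packaged +4-point study recovers ≈ +3.4).
  The same bias direction is acknowledged for real data by the source
  methodology; earlobe-referenced detection would avoid it at the cost
  of reference asymmetry.
- **Ringing echoes.** A narrowband filter turns a 1.5-cycle wavelet into
  a longer oscillation; side troughs of strong events cross the
  relative threshold and appear as additional low-amplitude events
  whose correlation windows overlap the true event. They inflate
  density but echo the true globality, so condition contrasts survive;
  amplitude-weighted analyses should deduplicate by refractory time if
  that matters.
- **Relative threshold.** `median − 2·MAD` adapts to the reference
  signal's own scale, so a fully quiet recording still yields
  threshold-crossing noise minima; density is only interpretable
  relative to a comparison condition, never absolutely. On
  realistic-noise synthetic hours the per-session event count lands in
  the several-thousand range, the same order as reported for real
  sessions — a plausibility diagnostic, not an asserted contract.
- **Degenerate inputs.** Zero-variance channels error in z-scoring
  (naming the channel); a flat reference signal cannot produce
  candidates (the threshold precondition fails and `detect_all()`
  reports zero events); topography is unavailable on zero-power input
  and the session report says so rather than failing.

## Parameter summary

| Parameter | Default | Units | Role |
|---|---|---|---|
| `bp_low`, `bp_high` | 0.1, 48 | Hz | analysis band |
| `fs_out` | 512 | Hz | working rate |
| `muscle_band`, `outlier_k` | 20–30, 5 | Hz, robust SDs | bad-channel rule |
| `welch_win`, `freq_res` | 4, 0.125 | s, Hz | PSD resolution |
| `theta_band` | 5–7 | Hz | marker band, below the alpha peak |
| `prsa_halfwin` | 2 | s | PRSA window |
| `thresh_factor` | 2 | × median deviation | detection depth |
| `corr_cut`, `lag_win_ms` | 0.95, 50 | –, ms | involvement rule |
| `corr_pad_cycles` | 2 | theta cycles | correlation segment extension |
| `min_involved_neighbors` | 1 | channels | isolated-channel pruning |
| `max_angle` | 25 | degrees | neighbor graph |
| `period_range_s`, `period_tol` | 1/7–1/5, 0.2 | s, fraction | theta-period gate |

All are explicit arguments of `preproc_params()`, `spectral_params()`,
`detection_params()` and `build_neighbors()`.
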