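# thetawake

Detection and statistics for **local sleep-like events** in multichannel
wake EEG, with a synthetic-session generator for parameter-recovery
validation.

During sustained wakefulness, brief theta-range (5–7 Hz) negative waves
resembling sleep slow waves intrude into the waking EEG of restricted
cortical territories. Their rate, amplitude, and above all their spatial
extent ("globality") are markers of homeostatic sleep pressure, and they
have been linked to lapses in visuomotor performance. `thetawake` packages
the full analysis chain a sleep/vigilance lab needs to quantify these
events and relate them to behaviour:

1. **Preprocessing** — zero-phase band-pass (0.1–48 Hz) and resampling to
   512 Hz, earlobe→average re-referencing, per-channel z-scoring over
   artifact-free samples, muscle-band (20–30 Hz) bad-channel rejection,
   neighbor-graph interpolation.
2. **Spectral markers** — Welch power spectra (4 s Hamming windows,
   0.125 Hz bins), optional phase-rectified signal averaging (PRSA),
   theta topographies normalised to a scalp mean of 1, and the
   strict ">50% of electrodes" global-increase criterion.
3. **Event detection** — per scalp area (frontal/central/parietal): the
   area-mean signal is theta-filtered (2nd-order Butterworth); a robust
   threshold is set at

   `thr = median(x) − 2 · median(|x − median(x)|)`

   and every interior minimum between two local maxima separated by one
   theta period that falls below `thr` is an event. A channel is
   *involved* in an event when the maximum lagged Pearson correlation
   (lags ≤ ±50 ms) between the reference segment and the channel's theta
   trace exceeds 0.95; isolated involved channels are unmarked (cluster
   rule). Globality = involved channels / analysed channels; amplitude =
   trough-to-following-peak excursion at the involved channel with the
   median slope.
4. **Statistics** — paired per-channel t-topographies with sign-flip
   permutation cluster correction (≥3 neighboring electrodes), paired
   condition contrasts, reaction-time validity rules (100–500 ms), the
   median-split RT analysis, and OLS regression of RT on peristimulus
   event globality.
5. **Synthetic sessions** — 1/f + alpha-peak background with
   distance-decaying cross-channel mixing, Hann-windowed theta wavelets
   with cosine spatial taper and full ground truth, and behavioral trials
   whose RTs are linearly coupled to event globality.

## Worked example

```r
library(thetawake)

montage <- build_neighbors(standard_montage(analysis_labels()))  # 56 ch

# one synthetic session: quiet background + 24 frontal theta events
sess <- gen_recovery_session(montage, duration = 60, event_rate = 0.4,
                             amplitude = 3.5, radius = 28, seed = 3)
rec <- average_reference(sess$rec)
det <- detect_all(rec, default_areas(warn_overlap = FALSE), montage)

det$thresholds["frontal"]
#>     frontal
#> -0.02366684
head(det$events[det$events$area == "frontal",
                c("t_neg_s", "amplitude_z", "globality_pct")], 3)
#>    t_neg_s amplitude_z globality_pct
#> 1 1.025391   0.3084144      14.28571
#> 2 1.193359   0.6543273      16.07143
#> 3 1.355469   0.7645845      16.07143
```

The frontal threshold is negative, in z-scale units of the quiet
reference signal. The third row is the first injected event: trough at
1.355 s (injected at 1.357 s), amplitude 0.76 z against a forward-model
ground truth of 0.72 z, and globality 16.1% (9 of 56 channels) against
an injected extent of 17.9% — the average-reference subtraction removes
the scalp-mean deflection, so the outermost taper channels fall below
the 0.95 correlation cut. The first two rows are side troughs of the
same wavelet after narrowband filtering (ringing); their correlation
windows overlap the event, so they echo its globality at lower
amplitude.

Condition comparison and behavioral linkage run the same way through
`gen_condition_pair()`, `run_session()` and `compare_conditions()`; see
the methods vignette (`vignettes/thetawake-methods.Rmd`).

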