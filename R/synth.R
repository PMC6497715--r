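# Synthetic EEG sessions with ground truth.
#
# Background: per-channel 1/f noise with an alpha peak, generated by spectral
# shaping of white noise and mixed across channels with distance-decaying
# weights (shared + private sources), so that average referencing and
# cross-correlation are nontrivial while every channel keeps the same
# spectral shape. Events: Hann-windowed theta wavelets whose trough depth
# tapers from the centre channel with a quarter-wave cosine, zero beyond the
# spatial radius. Trials: stimulus times on a jittered grid with reaction
# times linearly coupled to the globality of ground-truth events near the
# stimulus.

#' Background EEG specification
#'
#' @param n_channels Channel count.
#' @param fs Sampling rate in Hz (>= 128).
#' @param duration Seconds (> 0). The default session length of 60 min
#'   mirrors a typical cleaned wake recording.
#' @param psd_slope 1/f exponent of the background spectrum (power ~
#'   `f^-slope` above 0.1 Hz).
#' @param alpha_freq Alpha peak frequency in Hz.
#' @param alpha_power_ratio Height of the alpha peak relative to the 1/f
#'   trend at `alpha_freq` (0 disables the peak).
#' @param rms Per-channel RMS amplitude in the recording's units
#'   (microvolts for `"volts"` output).
#' @param mixing_lambda Spatial decay constant (degrees) of the cross-channel
#'   mixing weights.
#' @param seed Integer seed; the generator is a pure function of spec + seed.
#' @return A list of class `background_spec`.
#' @export
background_spec <- function(n_channels = 56, fs = 512, duration = 3600,
                            psd_slope = 1, alpha_freq = 9,
                            alpha_power_ratio = 2, rms = 20,
                            mixing_lambda = 30, seed = 1) {
  stopifnot(duration > 0, fs >= 128, psd_slope >= 0, n_channels >= 1,
            alpha_power_ratio >= 0, rms > 0, mixing_lambda > 0)
  structure(list(n_channels = n_channels, fs = fs, duration = duration,
                 psd_slope = psd_slope, alpha_freq = alpha_freq,
                 alpha_power_ratio = alpha_power_ratio, rms = rms,
                 mixing_lambda = mixing_lambda, seed = seed),
            class = "background_spec")
}

# One 1/f + alpha trace of length n at rate fs, unit SD.
shaped_noise <- function(n, fs, slope, alpha_freq, alpha_ratio) {
  freqs <- (0:(n - 1)) * fs / n
  half <- freqs > fs / 2
  freqs[half] <- fs - freqs[half]
  trend <- pmax(freqs, 0.1)^(-slope)
  trend[1] <- 0
  psd <- trend
  if (alpha_ratio > 0) {
    bump <- alpha_ratio * pmax(alpha_freq, 0.1)^(-slope) *
      exp(-(freqs - alpha_freq)^2 / (2 * 0.5^2))
    psd <- psd + bump
  }
  z <- complex(real = rnorm(n), imaginary = rnorm(n))
  x <- Re(fft(z * sqrt(psd), inverse = TRUE)) / n
  x / sd(x)
}

#' Generate background EEG
#'
#' @param spec [background_spec()].
#' @param montage An `eeg_montage` with at least `spec$n_channels` positions;
#'   the first `n_channels` labels are used.
#' @param unit_state Unit state of the produced recording. `"volts"` scales
#'   to `spec$rms` microvolts; `"zscored"` scales to `spec$rms` z-units
#'   (used by recovery harnesses that work directly on standardised data).
#' @return An earlobe-reference `eeg_recording`, deterministic per seed.
#' @export
gen_background <- function(spec, montage, unit_state = "volts") {
  stopifnot(inherits(spec, "background_spec"),
            inherits(montage, "eeg_montage"))
  if (length(montage$labels) < spec$n_channels)
    stopf("montage has %d positions; spec needs %d", length(montage$labels),
          spec$n_channels)
  n <- round(spec$duration * spec$fs)
  if (n * spec$n_channels > 5e8) stopf("duration x fs overflow guard")
  labels <- montage$labels[seq_len(spec$n_channels)]
  ang <- angular_distance(montage$pos3d[labels, , drop = FALSE],
                          montage$pos3d[labels, , drop = FALSE])
  dim(ang) <- c(spec$n_channels, spec$n_channels)
  W <- exp(-ang / spec$mixing_lambda)
  W <- W / sqrt(rowSums(W^2))
  data <- withr::with_seed(spec$seed, {
    S <- matrix(0, spec$n_channels, n)
    for (i in seq_len(spec$n_channels))
      S[i, ] <- shaped_noise(n, spec$fs, spec$psd_slope, spec$alpha_freq,
                             spec$alpha_power_ratio)
    (W %*% S) * spec$rms
  })
  new_recording(data, spec$fs, labels, reference = "earlobe",
                unit_state = unit_state)
}

#' Ground-truth event specifications
#'
#' @param t_neg Trough times in seconds from recording start.
#' @param center_channel Centre channel labels.
#' @param spatial_radius Spatial extent in degrees of arc.
#' @param amplitude Trough depth in z-units.
#' @param freq Oscillation frequency in Hz, within `[5, 7]`.
#' @param n_cycles Hann-window length in cycles.
#' @return Data frame of event specs (recycled to a common length).
#' @export
event_specs <- function(t_neg, center_channel, spatial_radius, amplitude,
                        freq = 6, n_cycles = 1.5) {
  df <- data.frame(t_neg = t_neg, center_channel = center_channel,
                   spatial_radius = spatial_radius, amplitude = amplitude,
                   freq = freq, n_cycles = n_cycles,
                   stringsAsFactors = FALSE)
  if (any(df$freq < 5 | df$freq > 7)) stopf("event freq must lie in [5, 7]")
  if (any(df$amplitude < 0)) stopf("event amplitude must be >= 0")
  df
}

# Trough-centred theta wavelet of unit trough depth.
unit_wavelet <- function(freq, n_cycles, fs) {
  len_s <- n_cycles / freq
  L <- round(len_s * fs)
  if (L %% 2 == 0) L <- L + 1L
  tt <- ((seq_len(L) - 1) - (L - 1) / 2) / fs
  hann <- 0.5 * (1 + cos(2 * pi * tt / len_s))
  -cos(2 * pi * freq * tt) * hann
}

# Quarter-wave cosine spatial taper: 1 at the centre, 0 at the radius,
# 0 beyond. Smooth and monotone so involved-channel counts grow
# monotonically with the radius.
spatial_taper <- function(ang, radius) {
  w <- cos(pi * ang / (2 * radius))
  w[ang >= radius] <- 0
  w
}

#' Inject theta events into a recording
#'
#' Each event adds a Hann-windowed theta wavelet (trough at `t_neg`) to all
#' channels within `spatial_radius` of the centre channel, with the
#' quarter-wave cosine taper; channels beyond the radius are untouched. On a
#' `"volts"` recording the trough depth is `amplitude` times the channel's
#' pre-injection SD (so the spec amplitude is in z-units); on a `"zscored"`
#' recording it is added directly in z-units.
#'
#' @param rec An `eeg_recording`.
#' @param specs Data frame from [event_specs()].
#' @param montage An `eeg_montage` covering the recording's labels.
#' @return List with the modified `rec` and the unchanged ground `truth`.
#' @export
inject_events <- function(rec, specs, montage) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(montage, "eeg_montage"))
  n <- ncol(rec$data)
  miss <- setdiff(specs$center_channel, rec$labels)
  if (length(miss) > 0)
    stopf("center channel(s) not in recording: %s",
          paste(unique(miss), collapse = ", "))
  scale <- if (rec$unit_state == "volts")
    apply(rec$data, 1, sd) else rep(1, nrow(rec$data))
  pos <- montage$pos3d[rec$labels, , drop = FALSE]
  for (k in seq_len(nrow(specs))) {
    s <- specs[k, ]
    g <- s$amplitude * unit_wavelet(s$freq, s$n_cycles, rec$fs)
    L <- length(g)
    i0 <- round(s$t_neg * rec$fs) + 1L
    a <- i0 - (L - 1L) %/% 2L
    b <- a + L - 1L
    if (a < 1L || b > n)
      stopf("event %d at t_neg=%.3f s falls outside the recording", k,
            s$t_neg)
    ang <- angular_distance(pos[s$center_channel, ], pos)
    w <- spatial_taper(ang, s$spatial_radius) * scale
    hit <- which(w > 0)
    if (length(hit) > 0)
      rec$data[hit, a:b] <- rec$data[hit, a:b] + outer(w[hit], g)
  }
  list(rec = rec, truth = specs)
}

#' Ground-truth globality of event specs
#'
#' Percentage of the analysed channels lying strictly within each event's
#' spatial radius of its centre channel.
#'
#' @param specs Event spec data frame.
#' @param montage An `eeg_montage`.
#' @param labels Analysed channel set.
#' @return Numeric vector of globality percentages.
#' @export
truth_globality <- function(specs, montage, labels) {
  pos <- montage$pos3d[labels, , drop = FALSE]
  vapply(seq_len(nrow(specs)), function(k) {
    ang <- angular_distance(pos[specs$center_channel[k], ], pos)
    100 * sum(ang < specs$spatial_radius[k]) / length(labels)
  }, 0)
}

#' Forward-model ground-truth amplitude of event specs
#'
#' What an ideal detector measures for an injected event: the trough depth is
#' scaled by the in-radius channel with the median taper weight (corrected
#' for the average-reference subtraction of the scalp-mean taper), and the
#' clean wavelet is passed through the detection band-pass so the
#' trough-to-following-peak excursion reflects the filter's gain.
#'
#' @param specs Event spec data frame.
#' @param montage An `eeg_montage`.
#' @param labels Analysed channel set.
#' @param fs Sampling rate used by the detector.
#' @param p [detection_params()].
#' @return Numeric vector of expected trough-to-peak amplitudes (z-units).
#' @export
truth_amplitude <- function(specs, montage, labels, fs = 512,
                            p = detection_params()) {
  pos <- montage$pos3d[labels, , drop = FALSE]
  bf <- theta_butter(fs, p)
  vapply(seq_len(nrow(specs)), function(k) {
    s <- specs[k, ]
    g <- unit_wavelet(s$freq, s$n_cycles, fs)
    padded <- c(numeric(2 * fs), g, numeric(2 * fs))
    fg <- signal::filtfilt(bf, padded)
    i_min <- which.min(fg)
    after <- fg[i_min:min(i_min + fs %/% 3, length(fg))]
    unit_amp <- max(after) - fg[i_min]
    ang <- angular_distance(pos[s$center_channel, ], pos)
    w <- spatial_taper(ang, s$spatial_radius)
    w_in <- w[ang < s$spatial_radius]
    w_med <- w_in[lower_median_index(w_in)]
    s$amplitude * (w_med - mean(w)) * unit_amp
  }, 0)
}

#' Trial-generation specification
#'
#' @param n_trials Trial count (>= 1).
#' @param base_rt Baseline reaction time in ms.
#' @param beta Coupling in ms per globality percentage point.
#' @param noise_sd Gaussian RT noise SD in ms.
#' @param iti Inter-stimulus interval in seconds.
#' @param p_success Probability of a successful docking outcome (assigned
#'   independently of events).
#' @param seed Integer seed.
#' @return A list of class `trial_gen_spec`.
#' @export
trial_gen_spec <- function(n_trials = 80, base_rt = 220, beta = 2,
                           noise_sd = 40, iti = 10, p_success = 0.66,
                           seed = 1) {
  stopifnot(n_trials >= 1, noise_sd >= 0, iti > 0, base_rt > 0,
            p_success >= 0, p_success <= 1)
  structure(list(n_trials = n_trials, base_rt = base_rt, beta = beta,
                 noise_sd = noise_sd, iti = iti, p_success = p_success,
                 seed = seed),
            class = "trial_gen_spec")
}

#' Generate behavioral trials coupled to ground-truth events
#'
#' Stimulus times sit on a regular `iti` grid with uniform jitter. Each
#' trial's reaction time is `base_rt + beta * G + noise`, where `G` is the
#' largest ground-truth globality among events whose trough falls in
#' `[stim - 0.25 s, stim + 0.5 s)` (0 when none), truncated to
#' `[50, 800] ms` so that downstream 100/500 ms exclusion rules are
#' exercised on both tails. Outcomes are assigned independently of events.
#'
#' @param truth Event spec data frame (ground truth).
#' @param spec [trial_gen_spec()].
#' @param session_dur Session duration in seconds
#'   (`iti * n_trials <= session_dur`).
#' @param montage,labels Montage and analysed channel set for globality.
#' @return Trial data frame (`trial_id`, `stim_time_s`, `rt_ms`, `outcome`,
#'   `valid = NA`, plus the ground-truth `truth_globality` regressor).
#' @export
gen_trials <- function(truth, spec, session_dur, montage, labels) {
  stopifnot(inherits(spec, "trial_gen_spec"))
  if (spec$iti * spec$n_trials > session_dur)
    stopf("iti * n_trials exceeds session duration")
  glob <- if (nrow(truth) > 0) truth_globality(truth, montage, labels)
          else numeric(0)
  withr::with_seed(spec$seed, {
    stim <- (seq_len(spec$n_trials) - 0.5) * spec$iti +
      runif(spec$n_trials, -0.2 * spec$iti, 0.2 * spec$iti)
    G <- vapply(stim, function(s0) {
      sel <- truth$t_neg >= s0 - 0.25 & truth$t_neg < s0 + 0.5
      if (any(sel)) max(glob[sel]) else 0
    }, 0)
    rt <- spec$base_rt + spec$beta * G + rnorm(spec$n_trials, 0, spec$noise_sd)
    rt <- pmin(pmax(rt, 50), 800)
    outcome <- ifelse(runif(spec$n_trials) < spec$p_success, "S", "F")
    data.frame(trial_id = seq_len(spec$n_trials), stim_time_s = stim,
               rt_ms = rt, outcome = outcome, valid = NA,
               truth_globality = G, stringsAsFactors = FALSE)
  })
}
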