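# Recovery-harness sessions and paired-condition study sets.
#
# Recovery sessions are generated directly in z-units with a quiet
# background (default SD 0.08 z against trough depths of ~3 z) so that
# parameter recovery isolates the detector's behaviour from noise-floor
# effects; realistic noise levels are exercised separately as diagnostics.

#' Generate a recovery session with ground truth
#'
#' A quiet background plus theta events centred on channels of one scalp
#' area, with troughs on a jittered grid. The recording is produced in
#' z-units (`unit_state = "zscored"`), earlobe-reference state so the
#' standard average-referencing step still applies.
#'
#' @param montage An `eeg_montage` covering `labels`.
#' @param labels Analysed channel set.
#' @param duration Session length in seconds.
#' @param event_rate Events per second.
#' @param amplitude Mean trough depth in z-units (per-event depths jittered
#'   by +-10%).
#' @param radius Spatial radius in degrees (scalar, or per-event vector).
#' @param centers Candidate centre channels (defaults to the frontal area).
#' @param background_sd Background SD in z-units.
#' @param freq_range Event frequency range in Hz.
#' @param fs Sampling rate.
#' @param seed Integer seed.
#' @return List with `rec` (events injected), `truth` (event specs with
#'   `truth_globality` and `truth_amplitude` columns), and `montage` echo.
#' @export
gen_recovery_session <- function(montage, labels = analysis_labels(),
                                 duration = 60, event_rate = 0.5,
                                 amplitude = 3.5, radius = 28,
                                 centers = NULL, background_sd = 0.08,
                                 freq_range = c(5.5, 6.5), fs = 512,
                                 seed = 1) {
  centers <- centers %||% default_areas(warn_overlap = FALSE)$frontal
  stopifnot(all(centers %in% labels))
  n_ev <- max(1L, round(event_rate * duration))
  bg_spec <- background_spec(n_channels = length(labels), fs = fs,
                             duration = duration, rms = background_sd,
                             seed = seed)
  sub <- standard_montage(labels)
  rec <- gen_background(bg_spec, sub, unit_state = "zscored")
  specs <- withr::with_seed(seed + 1L, {
    pitch <- duration / n_ev
    t_neg <- (seq_len(n_ev) - 0.5) * pitch +
      runif(n_ev, -0.25 * pitch, 0.25 * pitch)
    event_specs(
      t_neg = pmin(pmax(t_neg, 0.5), duration - 0.5),
      center_channel = sample(centers, n_ev, replace = TRUE),
      spatial_radius = rep_len(radius, n_ev),
      amplitude = amplitude * runif(n_ev, 0.9, 1.1),
      freq = runif(n_ev, freq_range[1], freq_range[2]))
  })
  inj <- inject_events(rec, specs, montage)
  truth <- inj$truth
  truth$truth_globality <- truth_globality(truth, montage, labels)
  truth$truth_amplitude <- truth_amplitude(truth, montage, labels, fs = fs)
  list(rec = inj$rec, truth = truth, montage = montage)
}

#' Mean ground-truth globality as a function of spatial radius
#'
#' Averages the within-radius channel percentage over the given centre
#' channels; used to choose condition radii that produce a stated globality
#' shift.
#'
#' @param montage An `eeg_montage`.
#' @param labels Analysed channel set.
#' @param centers Centre channels averaged over.
#' @param radius Vector of radii (degrees).
#' @return Mean globality percentage for each radius.
#' @export
mean_globality_at_radius <- function(montage, labels, centers, radius) {
  vapply(radius, function(r) {
    specs <- event_specs(t_neg = rep(1, length(centers)),
                         center_channel = centers, spatial_radius = r,
                         amplitude = 1)
    mean(truth_globality(specs, montage, labels))
  }, 0)
}

#' Radius producing a target globality shift
#'
#' Finds, by grid interpolation, the radius at which the mean ground-truth
#' globality over `centers` exceeds that at `base_radius` by `shift_pct`
#' percentage points.
#'
#' @param montage,labels,centers As in [mean_globality_at_radius()].
#' @param base_radius Reference radius in degrees.
#' @param shift_pct Target shift in percentage points.
#' @return The calibrated radius in degrees.
#' @export
calibrate_radius_shift <- function(montage, labels, centers, base_radius,
                                   shift_pct) {
  grid <- seq(base_radius * 0.5, base_radius * 2.5, by = 0.25)
  g <- mean_globality_at_radius(montage, labels, centers, grid)
  target <- mean_globality_at_radius(montage, labels, centers,
                                     base_radius) + shift_pct
  if (target > max(g) || target < min(g))
    stopf("target globality shift %.1f unreachable on the radius grid",
          shift_pct)
  stats::approx(g, grid, xout = target, ties = mean)$y
}

#' Generate a paired two-condition study set
#'
#' Per synthetic subject, one session per condition, with condition
#' parameters taken from the two spec lists (arguments of
#' [gen_recovery_session()]). A per-subject random radius offset (shared
#' across that subject's conditions) provides random-intercept structure.
#' Deterministic per seed.
#'
#' @param earth_spec,space_spec Named lists of [gen_recovery_session()]
#'   arguments; they should differ only in the stated parameters.
#' @param n_subjects Number of subjects (>= 2).
#' @param montage An `eeg_montage`.
#' @param subject_radius_sd SD of the per-subject radius offset in degrees.
#' @param seed Integer seed.
#' @return List of subjects, each a list with `earth` and `space` session
#'   objects from [gen_recovery_session()].
#' @export
gen_condition_pair <- function(earth_spec, space_spec, n_subjects, montage,
                               subject_radius_sd = 1, seed = 1) {
  if (n_subjects < 2) stopf("paired statistics need >= 2 subjects")
  offsets <- withr::with_seed(seed, rnorm(n_subjects, 0, subject_radius_sd))
  lapply(seq_len(n_subjects), function(s) {
    make <- function(spec, cond_off) {
      spec$montage <- montage
      spec$radius <- spec$radius + offsets[s]
      spec$seed <- seed + 1000L * s + cond_off
      do.call(gen_recovery_session, spec)
    }
    list(earth = make(earth_spec, 1L), space = make(space_spec, 2L))
  })
}
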