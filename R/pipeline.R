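# End-to-end orchestration: preprocess -> topography -> detection ->
# behaviour, and paired-condition comparison with cluster-corrected
# topographic statistics.

load_recording <- function(x) {
  if (inherits(x, "eeg_recording")) x
  else if (is.character(x)) read_edf(x)
  else stopf("recording must be an eeg_recording or an EDF path")
}

load_trials <- function(x) {
  if (is.null(x)) NULL
  else if (is.data.frame(x)) x
  else if (is.character(x)) read_trials(x)
  else stopf("trials must be a data frame or a CSV path")
}

config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  slim <- cfg[setdiff(names(cfg), c("recording", "trials", "montage",
                                    "sessions"))]
  jsonlite::write_json(slim, f, auto_unbox = TRUE, force = TRUE, digits = NA)
  unname(tools::md5sum(f))
}

#' Run the full single-session pipeline
#'
#' Stages: optional band-pass + resampling (applied to `"volts"` input),
#' muscle-band bad-channel rejection and interpolation, average
#' referencing, z-scoring, normalised theta topography, and event detection
#' with per-area thresholds and densities; behavioral linkage when trials
#' are provided. Deterministic given its inputs; each stage failure aborts
#' with the stage name.
#'
#' @param cfg List: `recording` (an `eeg_recording` or EDF path), `montage`
#'   (with neighbor graph), optional `trials` (data frame or CSV path),
#'   `areas` (default [default_areas()]), `preproc`, `spectral`, `detect`
#'   parameter objects, `reject_bad` flag (default `TRUE`), `use_prsa`
#'   flag.
#' @return Session report list: bookkeeping (usable minutes, rejected
#'   channels), per-area thresholds, densities, event table and summary
#'   statistics, theta topography, behavioral results (or `NULL`), and the
#'   configuration hash.
#' @export
run_session <- function(cfg) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
  }
  rec <- stage("load", load_recording(cfg$recording))
  montage <- cfg$montage %||% stopf("cfg$montage is required")
  areas <- cfg$areas %||% default_areas(warn_overlap = FALSE)
  pp <- cfg$preproc %||% preproc_params()
  sp <- cfg$spectral %||% spectral_params()
  dp <- cfg$detect %||% detection_params()
  rejected <- character()
  if (rec$unit_state == "volts") {
    rec <- stage("bandpass_resample", bandpass_resample(rec, pp))
    if (isTRUE(cfg$reject_bad %||% TRUE)) {
      rejected <- stage("detect_bad_channels", detect_bad_channels(rec, pp))
      if (length(rejected) > 0) {
        rec$bad_channels <- rejected
        rec <- stage("interpolate_channels",
                     interpolate_channels(rec, montage))
      }
    }
  }
  if (rec$reference == "earlobe")
    rec <- stage("average_reference", average_reference(rec))
  if (rec$unit_state == "volts")
    rec <- stage("zscore_channels", zscore_channels(rec))
  topo <- tryCatch(
    band_topography(rec, sp, use_prsa = isTRUE(cfg$use_prsa)),
    error = function(e) {
      warnf("theta topography unavailable: %s", conditionMessage(e))
      NULL
    })
  det <- stage("detect_all", detect_all(rec, areas, montage, dp))
  behav <- NULL
  trials <- stage("load_trials", load_trials(cfg$trials))
  if (!is.null(trials)) {
    trials <- stage("filter_rts", filter_rts(trials))
    summ <- stage("events_near_stimulus",
                  events_near_stimulus(det$events, trials))
    reg <- tryCatch(regress_rt_on_globality(summ, trials),
                    error = function(e) NULL)
    behav <- list(trials = trials, summaries = summ, regression = reg,
                  n_false_start = attr(trials, "n_false_start"),
                  n_outlier = attr(trials, "n_outlier"))
  }
  ev <- det$events
  list(usable_minutes = det$usable_minutes,
       rejected_channels = rejected,
       thresholds = det$thresholds,
       n_events = nrow(ev),
       n_discarded = det$n_discarded,
       density = det$density,
       mean_amplitude = if (nrow(ev)) mean(ev$amplitude_z) else NA_real_,
       mean_globality = if (nrow(ev)) mean(ev$globality_pct) else NA_real_,
       events = ev,
       theta_topography = topo,
       behavior = behav,
       config_hash = config_hash(cfg))
}

#' Compare two recording conditions across subjects
#'
#' Runs [run_session()] for every subject x condition cell and summarises:
#' paired contrasts of mean globality, mean amplitude and event density;
#' cluster-corrected paired theta-topography statistics; and, when trials
#' are present, the pooled-median reaction-time split and the pooled
#' RT-globality regression. Missing trials drop the RT section with a
#' warning; other imbalances are reported, not fatal.
#'
#' @param cfg List: `sessions` (list per subject, each a named list of
#'   per-condition session configs as for [run_session()]; every subject
#'   must hold the same condition names), `montage`, and optional shared
#'   parameter entries merged into each session config.
#' @return Study report list: `per_session` summaries, `contrasts` (by
#'   measure), `topo_stats` (per condition pair vs the first condition),
#'   and `rt` (or `NULL`).
#' @export
compare_conditions <- function(cfg) {
  sessions <- cfg$sessions %||% stopf("cfg$sessions is required")
  conds <- names(sessions[[1]])
  if (length(conds) < 2) stopf("need >= 2 conditions per subject")
  for (s in seq_along(sessions))
    if (!identical(names(sessions[[s]]), conds))
      warnf("subject %d has conditions (%s) unlike subject 1 (%s)", s,
            paste(names(sessions[[s]]), collapse = ","),
            paste(conds, collapse = ","))
  shared <- cfg[setdiff(names(cfg), "sessions")]
  reports <- lapply(sessions, function(subj)
    lapply(subj, function(sess) run_session(utils::modifyList(shared, sess))))
  measure <- function(field) {
    M <- do.call(rbind, lapply(reports, function(subj)
      vapply(subj, function(r) {
        v <- r[[field]]
        if (field == "density") mean(v) else v
      }, 0)))
    colnames(M) <- conds
    rownames(M) <- paste0("subj", seq_len(nrow(M)))
    M
  }
  contrasts <- list(
    globality = condition_contrast(measure("mean_globality")),
    amplitude = condition_contrast(measure("mean_amplitude")),
    density = condition_contrast(measure("density")))
  topo_of <- function(cond) lapply(reports, function(subj)
    subj[[cond]]$theta_topography)
  topo_stats <- list()
  for (cond in conds[-1]) {
    ts <- paired_topo_test(topo_of(conds[1]), topo_of(cond))
    topo_stats[[sprintf("%s-%s", cond, conds[1])]] <-
      permutation_cluster_correct(ts, cfg$montage)
  }
  rt <- NULL
  have_trials <- all(vapply(reports, function(subj)
    all(!vapply(subj, function(r) is.null(r$behavior), TRUE)), TRUE))
  if (have_trials) {
    all_sessions <- list()
    for (s in seq_along(reports)) for (cond in conds)
      all_sessions[[sprintf("subj%d_%s", s, cond)]] <-
        reports[[s]][[cond]]$behavior$trials
    med <- pooled_median_rt(all_sessions)
    pct <- percent_above_median(all_sessions, med)
    pct_mat <- matrix(pct, nrow = length(reports), byrow = TRUE,
                      dimnames = list(paste0("subj", seq_along(reports)),
                                      conds))
    rt <- list(pooled_median = med, percent_above = pct_mat,
               contrast = condition_contrast(pct_mat))
  } else {
    warnf("trials missing for some sessions; RT section omitted")
  }
  list(per_session = lapply(reports, function(subj) lapply(subj, function(r)
         r[setdiff(names(r), c("events", "behavior", "theta_topography"))])),
       contrasts = contrasts, topo_stats = topo_stats, rt = rt,
       conditions = conds, config_hash = config_hash(cfg))
}
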