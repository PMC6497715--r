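# Detector for local sleep-like theta events.
#
# Per scalp area: the area channels are averaged and band-pass filtered
# (2nd-order Butterworth, 5-7 Hz, zero-phase); a relative threshold is set at
# the median minus twice the median deviation from the median; every interior
# minimum between two local maxima separated by a theta period that falls
# below the threshold is an event candidate. Globality: the reference segment
# around the trough is correlated against every channel's theta-filtered
# trace over lags up to +-50 ms; channels exceeding r = 0.95 are involved;
# involved channels with no involved neighbor are unmarked (cluster rule),
# and candidates whose involved set empties are discarded. Amplitude is the
# trough-to-following-peak excursion at the involved channel with the median
# trough-to-peak slope.

#' Scalp areas used for event detection
#'
#' Default frontal/central/parietal channel lists along the
#' anterior-posterior axis. As printed in the source material the central
#' list shares `CPz`/`CP2` with the parietal list although the areas are
#' described as non-overlapping; `fix_overlap = TRUE` substitutes `Cz`/`C2`
#' for the suspected misprint.
#'
#' @param fix_overlap Replace `CPz`/`CP2` in the central list by `Cz`/`C2`.
#' @param warn_overlap Warn about the printed central/parietal overlap when
#'   it is kept.
#' @return Named list of channel-label vectors.
#' @export
default_areas <- function(fix_overlap = FALSE, warn_overlap = TRUE) {
  central <- if (fix_overlap) c("FC1", "FCz", "FC2", "C1", "Cz", "C2")
             else c("FC1", "FCz", "FC2", "C1", "CPz", "CP2")
  if (!fix_overlap && warn_overlap)
    warnf("central area shares CPz/CP2 with the parietal area as printed; use fix_overlap = TRUE for disjoint areas")
  list(frontal = c("Fp1", "Fp2", "AF3", "AFz", "AF4", "F1", "Fz", "F2"),
       central = central,
       parietal = c("CP1", "CPz", "CP2", "P1", "Pz", "P2", "PO3", "POz",
                    "PO4"))
}

#' Event-detection parameters
#'
#' @param band Theta band in Hz.
#' @param butter_order Butterworth band-pass order (per band edge).
#' @param thresh_factor Multiplier of the median deviation in the threshold.
#' @param corr_cut Involvement threshold on the Pearson correlation (strict).
#' @param lag_win_ms Maximum cross-correlation lag, in ms each way.
#' @param min_involved_neighbors Minimum involved neighbors a channel needs
#'   to stay marked (the isolated-channel cluster rule).
#' @param corr_pad_cycles Cycles of the band-centre period by which the
#'   correlation segment extends beyond the trough's flanking maxima on each
#'   side. `0` restricts the segment to the half-wave itself, which on
#'   narrowband signals leaves the correlation nearly unconstrained (the
#'   band falls below the segment's frequency resolution); the default of 2
#'   keeps chance involvement of independent channels below ~2%.
#' @param mad_type `"mad"` (median absolute deviation from the median) or
#'   `"mean_ad"` (mean absolute deviation from the median) in the threshold.
#' @param period_range_s Range of local-maxima separations counted as one
#'   theta period, in seconds.
#' @param period_tol Fractional tolerance widening `period_range_s`.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(band = c(5, 7), butter_order = 2,
                             thresh_factor = 2, corr_cut = 0.95,
                             lag_win_ms = 50, min_involved_neighbors = 1,
                             corr_pad_cycles = 2,
                             mad_type = c("mad", "mean_ad"),
                             period_range_s = c(1 / 7, 1 / 5),
                             period_tol = 0.2) {
  mad_type <- match.arg(mad_type)
  stopifnot(length(band) == 2, band[1] < band[2], corr_cut > 0, corr_cut < 1,
            lag_win_ms > 0, thresh_factor > 0, butter_order >= 1,
            corr_pad_cycles >= 0, period_tol >= 0,
            period_range_s[1] < period_range_s[2])
  structure(list(band = band, butter_order = butter_order,
                 thresh_factor = thresh_factor, corr_cut = corr_cut,
                 lag_win_ms = lag_win_ms,
                 min_involved_neighbors = min_involved_neighbors,
                 corr_pad_cycles = corr_pad_cycles, mad_type = mad_type,
                 period_range_s = period_range_s, period_tol = period_tol),
            class = "detection_params")
}

theta_butter <- function(fs, p) {
  signal::butter(p$butter_order, p$band / (fs / 2), type = "pass")
}

#' Theta-filter every channel of a recording
#'
#' @param rec An `eeg_recording`.
#' @param p [detection_params()].
#' @return Channels x samples matrix of band-filtered traces (zero-phase).
#' @export
theta_filter <- function(rec, p = detection_params()) {
  bf <- theta_butter(rec$fs, p)
  out <- t(apply(rec$data, 1, function(x) signal::filtfilt(bf, x)))
  rownames(out) <- rec$labels
  out
}

#' Area-averaged theta reference signal
#'
#' Mean over the area channels, then zero-phase 2nd-order Butterworth
#' band-pass in the theta band.
#'
#' @param rec A z-scored, average-referenced `eeg_recording` (bad channels
#'   already interpolated).
#' @param area Character vector of area channel labels.
#' @param p [detection_params()].
#' @return A `ref_signal` (trace + sampling rate + usability mask).
#' @export
area_reference <- function(rec, area, p = detection_params()) {
  stopifnot(inherits(rec, "eeg_recording"))
  missing <- setdiff(area, rec$labels)
  if (length(missing) > 0)
    stopf("area channel(s) missing from recording: %s",
          paste(missing, collapse = ", "))
  m <- colMeans(rec$data[area, , drop = FALSE])
  bf <- theta_butter(rec$fs, p)
  new_ref_signal(signal::filtfilt(bf, m), rec$fs, rec$artifact_mask)
}

#' Relative detection threshold
#'
#' `median(x) - thresh_factor * median(|x - median(x)|)` over usable samples
#' (mean absolute deviation instead of the median one with
#' `mad_type = "mean_ad"`). For a standard normal signal the default
#' threshold converges to `-2 * qnorm(0.75) = -1.349`.
#'
#' @param refsig A `ref_signal` from [area_reference()].
#' @param p [detection_params()].
#' @return The (negative) threshold in the signal's units.
#' @export
compute_threshold <- function(refsig, p = detection_params()) {
  stopifnot(inherits(refsig, "ref_signal"))
  x <- refsig$x[refsig$usable]
  med <- median(x)
  dev <- abs(x - med)
  md <- if (p$mad_type == "mad") median(dev) else mean(dev)
  med - p$thresh_factor * md
}

#' Detect candidate negative peaks between theta maxima
#'
#' For each pair of consecutive strict local maxima whose separation lies in
#' the theta-period range (widened by `period_tol`), the interior minimum is
#' a candidate iff its value is strictly below `thr` and all samples between
#' the maxima are usable.
#'
#' @param refsig A `ref_signal`.
#' @param thr Threshold from [compute_threshold()]; must lie below the
#'   signal's median.
#' @param p [detection_params()].
#' @return Data frame with sample indices (`i_prev`, `i_neg`, `i_next`),
#'   times in seconds (`t_pos_prev`, `t_neg`, `t_pos_next`; sample 0 is time
#'   0) and the trough `value`, sorted by `t_neg`. Possibly empty.
#' @export
detect_negative_peaks <- function(refsig, thr, p = detection_params()) {
  stopifnot(inherits(refsig, "ref_signal"))
  x <- refsig$x
  if (thr >= median(x[refsig$usable]))
    stopf("threshold must lie below the signal median")
  fs <- refsig$fs
  lo <- p$period_range_s[1] * (1 - p$period_tol)
  hi <- p$period_range_s[2] * (1 + p$period_tol)
  empty <- data.frame(i_prev = integer(), i_neg = integer(),
                      i_next = integer(), t_pos_prev = numeric(),
                      t_neg = numeric(), t_pos_next = numeric(),
                      value = numeric())
  mx <- local_maxima(x)
  if (length(mx) < 2) return(empty)
  sep <- diff(mx) / fs
  ok_pair <- which(sep >= lo & sep <= hi)
  if (length(ok_pair) == 0) return(empty)
  cum_bad <- cumsum(!refsig$usable)
  rows <- lapply(ok_pair, function(k) {
    a <- mx[k]; b <- mx[k + 1L]
    if ((cum_bad[b] - cum_bad[a - 1L]) > 0L) return(NULL)
    inner <- (a + 1L):(b - 1L)
    i_min <- inner[which.min(x[inner])]
    if (x[i_min] >= thr) return(NULL)
    data.frame(i_prev = a, i_neg = i_min, i_next = b,
               t_pos_prev = (a - 1L) / fs, t_neg = (i_min - 1L) / fs,
               t_pos_next = (b - 1L) / fs, value = x[i_min])
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out[order(out$t_neg), , drop = FALSE]
}

# Max-lag Pearson correlation of the reference segment against every channel,
# vectorised over channels and lags (one matrix product per candidate).
max_lag_correlation <- function(cand, rec_theta, refsig, p) {
  fs <- refsig$fs
  pad <- round(p$corr_pad_cycles * fs / mean(p$band))
  lagmax <- round(p$lag_win_ms / 1000 * fs)
  a <- cand$i_prev - pad
  b <- cand$i_next + pad
  n <- length(refsig$x)
  if (a - lagmax < 1L || b + lagmax > n) return(NULL)  # edge: drop candidate
  ref <- refsig$x[a:b]
  rc <- ref - mean(ref)
  len <- length(rc)
  ssr <- sum(rc^2)
  if (ssr == 0) return(rep(0, nrow(rec_theta)))
  wide <- rec_theta[, (a - lagmax):(b + lagmax), drop = FALSE]
  width <- ncol(wide)
  nlag <- 2L * lagmax + 1L
  # shifted copies of the centred reference as a sparse-ish dense matrix
  M <- matrix(0, width, nlag)
  M[cbind(rep(seq_len(len), nlag) + rep(0:(nlag - 1L), each = len),
          rep(seq_len(nlag), each = len))] <- rep(rc, nlag)
  num <- wide %*% M                            # channels x lags
  cs1 <- cbind(0, t(apply(wide, 1, cumsum)))
  cs2 <- cbind(0, t(apply(wide^2, 1, cumsum)))
  starts <- 0:(nlag - 1L)
  sums <- cs1[, starts + len + 1L, drop = FALSE] - cs1[, starts + 1L, drop = FALSE]
  sums2 <- cs2[, starts + len + 1L, drop = FALSE] - cs2[, starts + 1L, drop = FALSE]
  ssx <- pmax(sums2 - sums^2 / len, 0)
  r <- num / sqrt(ssx * ssr)
  r[ssx == 0] <- 0
  apply(r, 1, max)
}

#' Channels involved in one event
#'
#' The reference segment around the candidate trough (half-wave padded by
#' `corr_pad_cycles` theta cycles per side) is Pearson-correlated with every
#' channel's theta trace at every integer-sample lag within
#' `+-lag_win_ms`; channels whose maximum correlation strictly exceeds
#' `corr_cut` are involved. Involved channels with fewer than
#' `min_involved_neighbors` involved neighbors are then unmarked.
#'
#' @param cand One row of [detect_negative_peaks()] output.
#' @param rec_theta Matrix from [theta_filter()] (rows named by label).
#' @param refsig The area `ref_signal`.
#' @param montage An `eeg_montage` with a neighbor graph.
#' @param p [detection_params()].
#' @return Character vector of involved labels after pruning, or `NULL` when
#'   the correlation segment would extend past the recording edge.
#' @export
event_involvement <- function(cand, rec_theta, refsig, montage,
                              p = detection_params()) {
  stopifnot(inherits(montage, "eeg_montage"))
  if (is.null(montage$neighbor_map)) stopf("montage has no neighbor graph")
  maxr <- max_lag_correlation(cand, rec_theta, refsig, p)
  if (is.null(maxr)) return(NULL)
  labels <- rownames(rec_theta)
  involved <- labels[maxr > p$corr_cut]
  if (length(involved) == 0) return(character())
  keep <- vapply(involved, function(ch)
    length(intersect(montage$neighbor_map[[ch]], involved)) >=
      p$min_involved_neighbors, TRUE)
  involved[keep]
}

#' Event amplitude at the median-slope channel
#'
#' Per involved channel the trough-to-peak slope is
#' `(x[i_next] - x[i_neg]) / (t_pos_next - t_neg)` on its theta trace; the
#' channel with the median slope (lower median for even counts) is selected
#' and the amplitude is its value at the following positive peak minus its
#' trough value.
#'
#' @param cand One candidate row.
#' @param involved Nonempty character vector of involved labels.
#' @param rec_theta Matrix from [theta_filter()].
#' @return List with `amplitude` and the selected `channel`.
#' @export
event_amplitude <- function(cand, involved, rec_theta) {
  if (length(involved) == 0) stopf("involved set is empty")
  v_neg <- rec_theta[involved, cand$i_neg]
  v_pos <- rec_theta[involved, cand$i_next]
  slopes <- (v_pos - v_neg) / (cand$t_pos_next - cand$t_neg)
  pick <- lower_median_index(slopes)
  list(amplitude = unname(v_pos[pick] - v_neg[pick]),
       channel = involved[pick])
}

#' Detect local sleep-like events in all areas
#'
#' Runs the full per-area chain (reference, threshold, candidate troughs,
#' involvement, pruning, amplitude) and reports per-area event density per
#' usable minute. Candidates whose involved set empties after pruning, or
#' whose correlation segment leaves the recording, are discarded and counted.
#'
#' @param rec A preprocessed (z-scored, average-referenced, interpolated)
#'   `eeg_recording`.
#' @param areas Named list of channel-label vectors (see [default_areas()]).
#' @param montage An `eeg_montage` with a neighbor graph.
#' @param p [detection_params()].
#' @return List with `events` (data frame: `event_id`, `area`, `t_neg_s`,
#'   `t_pos_prev_s`, `t_pos_next_s`, `amplitude_z`, `globality_pct`,
#'   `involved_channels`), per-area `density` (events per usable minute),
#'   `thresholds`, `n_discarded`, and `usable_minutes`.
#' @export
detect_all <- function(rec, areas, montage, p = detection_params()) {
  stopifnot(inherits(rec, "eeg_recording"), is.list(areas))
  n_analyzed <- nrow(rec$data)
  rec_theta <- theta_filter(rec, p)
  minutes <- usable_minutes(rec)
  all_events <- list()
  density <- numeric(0)
  thresholds <- numeric(0)
  discarded <- 0L
  for (area_name in names(areas)) {
    refsig <- area_reference(rec, areas[[area_name]], p)
    thr <- compute_threshold(refsig, p)
    thresholds[area_name] <- thr
    cands <- tryCatch(detect_negative_peaks(refsig, thr, p),
                      error = function(e) NULL)
    kept <- list()
    if (!is.null(cands) && nrow(cands) > 0) {
      for (k in seq_len(nrow(cands))) {
        cand <- cands[k, ]
        involved <- event_involvement(cand, rec_theta, refsig, montage, p)
        if (is.null(involved) || length(involved) == 0) {
          discarded <- discarded + 1L
          next
        }
        amp <- event_amplitude(cand, involved, rec_theta)
        kept[[length(kept) + 1L]] <- data.frame(
          area = area_name, t_neg_s = cand$t_neg,
          t_pos_prev_s = cand$t_pos_prev, t_pos_next_s = cand$t_pos_next,
          amplitude_z = amp$amplitude,
          globality_pct = 100 * length(involved) / n_analyzed,
          involved_channels = paste(involved, collapse = ";"),
          stringsAsFactors = FALSE)
      }
    }
    n_kept <- length(kept)
    density[area_name] <- n_kept / minutes
    if (n_kept > 0) all_events <- c(all_events, kept)
  }
  events <- if (length(all_events) > 0) do.call(rbind, all_events) else
    data.frame(area = character(), t_neg_s = numeric(),
               t_pos_prev_s = numeric(), t_pos_next_s = numeric(),
               amplitude_z = numeric(), globality_pct = numeric(),
               involved_channels = character(), stringsAsFactors = FALSE)
  events <- cbind(event_id = seq_len(nrow(events)), events)
  list(events = events, density = density, thresholds = thresholds,
       n_discarded = discarded, usable_minutes = minutes)
}
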