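# Power spectra and normalised band topographies.
#
# Welch periodograms use a Hamming window of `welch_win` seconds with 50%
# overlap. The paper-style combination of a 4 s window with 0.125 Hz bin
# spacing is realised by zero-padding each segment to 1/freq_res seconds,
# the only self-consistent reading of those two numbers.

#' Spectral analysis parameters
#'
#' @param welch_win Welch segment length in seconds (Hamming window).
#' @param freq_res Spectral bin spacing in Hz (zero-padding when finer than
#'   `1/welch_win`).
#' @param theta_band Two-element Hz band, interpreted as closed-open
#'   `[lo, hi)` over bins.
#' @param prsa_halfwin PRSA half-window in seconds.
#' @param prsa_anchor Anchor rule; only `"decreasing"` (sample lower than its
#'   predecessor) is implemented.
#' @return A list of class `spectral_params`.
#' @export
spectral_params <- function(welch_win = 4, freq_res = 0.125,
                            theta_band = c(5, 7), prsa_halfwin = 2,
                            prsa_anchor = "decreasing") {
  stopifnot(welch_win > 0, freq_res > 0, length(theta_band) == 2,
            theta_band[1] < theta_band[2], prsa_halfwin > 0,
            prsa_anchor == "decreasing")
  structure(list(welch_win = welch_win, freq_res = freq_res,
                 theta_band = theta_band, prsa_halfwin = prsa_halfwin,
                 prsa_anchor = prsa_anchor),
            class = "spectral_params")
}

hamming_win <- function(n) 0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))

#' Welch power spectral density
#'
#' One-sided PSD from Hamming-windowed segments with 50% overlap, each
#' zero-padded to `1/freq_res` seconds. Segments containing unusable samples
#' are dropped.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param welch_win Segment length (s).
#' @param freq_res Bin spacing (Hz).
#' @param mask Optional logical usability mask.
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, welch_win = 4, freq_res = 0.125, mask = NULL) {
  wl <- round(welch_win * fs)
  if (length(x) < wl) stopf("signal shorter than one Welch window")
  if (is.null(mask)) mask <- rep(TRUE, length(x))
  if (sum(mask) < wl)
    stopf("usable duration < one Welch window (%g s)", welch_win)
  nfft <- max(wl, round(fs / freq_res))
  w <- hamming_win(wl)
  starts <- seq(1L, length(x) - wl + 1L, by = wl %/% 2L)
  acc <- numeric(nfft %/% 2 + 1)
  nseg <- 0L
  for (s in starts) {
    idx <- s:(s + wl - 1L)
    if (!all(mask[idx])) next
    seg <- c(x[idx] * w, numeric(nfft - wl))
    sp <- abs(fft(seg)[1:(nfft %/% 2 + 1)])^2
    acc <- acc + sp
    nseg <- nseg + 1L
  }
  if (nseg == 0L) stopf("no fully usable Welch segment")
  psd <- 2 * acc / nseg / (fs * sum(w^2))
  psd[1] <- psd[1] / 2
  psd[length(psd)] <- psd[length(psd)] / 2
  list(freq = (0:(nfft %/% 2)) * fs / nfft, psd = psd)
}

#' Phase-rectified signal averaging
#'
#' Averages signal windows centred on anchor samples (samples that decrease
#' relative to their predecessor), reinforcing quasi-periodic components
#' against incoherent noise. Windows that would extend past the signal edge,
#' or contain unusable samples, are dropped.
#'
#' @param x Single-channel numeric trace.
#' @param fs Sampling rate (Hz).
#' @param p [spectral_params()].
#' @param mask Optional logical usability mask.
#' @return List with `curve` (length `2 * prsa_halfwin * fs`), `n_anchors`,
#'   and `fs`. Fewer than 100 usable anchors is an error.
#' @export
prsa <- function(x, fs, p = spectral_params(), mask = NULL) {
  h <- round(p$prsa_halfwin * fs)
  if (length(x) < 10 * h) stopf("signal shorter than 10 PRSA half-windows")
  if (is.null(mask)) mask <- rep(TRUE, length(x))
  anchors <- which(diff(x) < 0) + 1L
  anchors <- anchors[anchors > h & anchors + h - 1L <= length(x)]
  if (length(anchors) > 0) {
    cum_bad <- cumsum(!mask)
    ok <- (cum_bad[anchors + h - 1L] - cum_bad[anchors - h]) == 0L
    anchors <- anchors[ok & mask[anchors]]
  }
  if (length(anchors) < 100)
    stopf("too few PRSA anchors (%d; need >= 100)", length(anchors))
  offs <- (-h):(h - 1L)
  curve <- numeric(2L * h)
  chunk <- 2000L
  for (s in seq(1L, length(anchors), by = chunk)) {
    a <- anchors[s:min(s + chunk - 1L, length(anchors))]
    idx <- outer(a, offs, `+`)
    curve <- curve + colSums(matrix(x[idx], nrow = length(a)))
  }
  list(curve = curve / length(anchors), n_anchors = length(anchors), fs = fs)
}

#' Normalised band-power topography
#'
#' Per channel: (optionally PRSA, then) Welch PSD; band power is the mean of
#' bins in the closed-open band; values are divided by their cross-channel
#' mean so that the scalp average is exactly 1.
#'
#' @param rec A z-scored, average-referenced `eeg_recording`.
#' @param p [spectral_params()].
#' @param use_prsa If `TRUE`, the PSD is computed on each channel's PRSA
#'   curve (Welch window shrunk to the curve length when needed).
#' @param band Band in Hz; defaults to `p$theta_band`.
#' @return Object of class `band_topography`: named `values` (scalp mean 1),
#'   `band`, `labels`, `n_channels`.
#' @export
band_topography <- function(rec, p = spectral_params(), use_prsa = FALSE,
                            band = NULL) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$unit_state != "zscored")
    stopf("band_topography expects a z-scored recording")
  if (rec$reference != "average")
    stopf("band_topography expects an average-referenced recording")
  band <- band %||% p$theta_band
  if (sum(rec$artifact_mask) / rec$fs < 2 * p$welch_win)
    stopf("usable duration < 2 Welch windows")
  pow <- vapply(seq_len(nrow(rec$data)), function(i) {
    x <- rec$data[i, ]
    mask <- rec$artifact_mask
    if (use_prsa) {
      pr <- prsa(x, rec$fs, p, mask)
      x <- pr$curve
      mask <- NULL
      wl <- min(p$welch_win, length(x) / rec$fs)
      ps <- welch_psd(x, rec$fs, welch_win = wl, freq_res = p$freq_res,
                      mask = NULL)
    } else {
      ps <- welch_psd(x, rec$fs, welch_win = p$welch_win,
                      freq_res = p$freq_res, mask = mask)
    }
    sel <- ps$freq >= band[1] & ps$freq < band[2]
    mean(ps$psd[sel])
  }, 0)
  if (any(pow <= 0)) stopf("non-positive band power in channel %s",
                           rec$labels[which(pow <= 0)[1]])
  values <- pow / mean(pow)
  names(values) <- rec$labels
  structure(list(values = values, band = band, labels = rec$labels,
                 n_channels = length(values)),
            class = "band_topography")
}

#' @export
print.band_topography <- function(x, ...) {
  cat(sprintf("<band_topography> %d channels, band %g-%g Hz, range %.3f-%.3f\n",
              x$n_channels, x$band[1], x$band[2], min(x$values),
              max(x$values)))
  invisible(x)
}

#' Global-increase criterion between two topographies
#'
#' The increase is global when strictly more than 50% of channels increase
#' from `topo_a` to `topo_b` (strict inequalities on both counts).
#'
#' @param topo_a,topo_b `band_topography` objects on the same channel set.
#' @return List with `fraction` (of channels with b > a) and `global` flag.
#' @export
global_increase <- function(topo_a, topo_b) {
  stopifnot(inherits(topo_a, "band_topography"),
            inherits(topo_b, "band_topography"))
  if (!identical(topo_a$labels, topo_b$labels))
    stopf("channel sets differ between topographies")
  frac <- mean(topo_b$values > topo_a$values)
  list(fraction = frac, global = frac > 0.5)
}
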