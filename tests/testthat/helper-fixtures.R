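# Shared fixtures, built in code.

montage56 <- build_neighbors(standard_montage(analysis_labels()))
areas_default <- default_areas(warn_overlap = FALSE)

# Single-channel recording from a waveform function of time.
wave_recording <- function(f, fs = 512, dur = 10, labels = "Cz",
                           unit_state = "volts", reference = "earlobe") {
  tt <- (seq_len(round(dur * fs)) - 1) / fs
  data <- matrix(rep(f(tt), length(labels)), nrow = length(labels),
                 byrow = TRUE)
  new_recording(data, fs, labels, reference = reference,
                unit_state = unit_state)
}

# Small multichannel noise recording.
noise_recording <- function(n_ch = 4, fs = 256, dur = 10, seed = 1,
                            labels = NULL, sd = 10) {
  labels <- labels %||% c("Fz", "Cz", "Pz", "Oz", "C3", "C4")[seq_len(n_ch)]
  data <- withr::with_seed(seed,
    matrix(rnorm(n_ch * round(dur * fs), sd = sd), n_ch))
  new_recording(data, fs, labels)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Independent brute-force oracle for negative-peak detection: literal scan
# over all strict local extrema, no shared code with the package path.
oracle_negative_peaks <- function(x, fs, thr, usable = NULL,
                                  lo = (1 / 7) * 0.8, hi = (1 / 5) * 1.2) {
  if (is.null(usable)) usable <- rep(TRUE, length(x))
  out <- list()
  n <- length(x)
  maxima <- c()
  for (i in 2:(n - 1)) {
    if (x[i] > x[i - 1] && x[i] > x[i + 1]) maxima <- c(maxima, i)
  }
  if (length(maxima) >= 2) {
    for (k in 1:(length(maxima) - 1)) {
      a <- maxima[k]; b <- maxima[k + 1]
      sep <- (b - a) / fs
      if (sep < lo || sep > hi) next
      if (!all(usable[a:b])) next
      seg <- x[(a + 1):(b - 1)]
      i_min <- a + which.min(seg)
      if (x[i_min] < thr)
        out[[length(out) + 1]] <- c(a, i_min, b)
    }
  }
  if (length(out) == 0) matrix(integer(), ncol = 3)
  else do.call(rbind, out)
}
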