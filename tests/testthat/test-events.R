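test_that("area reference averages then filters in the theta band", {
  fs <- 512
  labs <- areas_default$frontal
  tt <- (1:(10 * fs)) / fs
  s <- sin(2 * pi * 6 * tt)
  rec <- new_recording(matrix(rep(s, 8), 8, byrow = TRUE), fs, labs,
                       reference = "average", unit_state = "zscored")
  ref <- area_reference(rec, labs)
  mid <- (2 * fs):(8 * fs)
  expect_equal(max(abs(ref$x[mid])), 1, tolerance = 0.02)
  # antiphase channels cancel
  rec2 <- new_recording(rbind(s, -s), fs, c("Fz", "F1"),
                        reference = "average", unit_state = "zscored")
  expect_lt(max(abs(area_reference(rec2, c("Fz", "F1"))$x)), 1e-10)
  expect_error(area_reference(rec, c(labs, "Oz")), "Oz")
})

test_that("threshold follows median - 2 MAD and its scaling law", {
  mk <- function(x) thetawake:::new_ref_signal(x, 512)
  # median 0, median deviation 0.5 -> threshold -1
  x <- rep(c(-0.5, 0, 0.5), 100)
  expect_equal(compute_threshold(mk(x)), -1)
  expect_equal(compute_threshold(mk(3 * x)), -3)  # homogeneous of degree 1
  y <- c(rep(1, 6), rep(2, 3), rep(0, 3))  # median 1, deviations 0,1,1 pattern
  expect_equal(compute_threshold(mk(y)),
               median(y) - 2 * median(abs(y - median(y))))
  expect_equal(compute_threshold(mk(y), detection_params(mad_type = "mean_ad")),
               median(y) - 2 * mean(abs(y - median(y))))
})

test_that("negative-peak detection matches the brute-force oracle", {
  fs <- 512
  p <- detection_params()
  bf <- signal::butter(2, c(5, 7) / (fs / 2), type = "pass")
  for (seed in 1:10) {
    x <- withr::with_seed(seed, {
      n <- round(runif(1, 5, 20) * fs)
      sig <- signal::filtfilt(bf, rnorm(n)) +
        0.3 * sin(2 * pi * runif(1, 5, 7) * (1:n) / fs)
      sig
    })
    refsig <- thetawake:::new_ref_signal(x, fs)
    if (seed %% 3 == 0) refsig$usable[seq(fs, 2 * fs)] <- FALSE
    thr <- compute_threshold(refsig, p)
    got <- detect_negative_peaks(refsig, thr, p)
    want <- oracle_negative_peaks(x, fs, thr, refsig$usable)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want) > 0) {
      expect_equal(got$i_prev, unname(want[, 1]))
      expect_equal(got$i_neg, unname(want[, 2]))
      expect_equal(got$i_next, unname(want[, 3]))
    }
  }
})

test_that("sinusoid candidates appear once per cycle; boundaries strict", {
  fs <- 512
  tt <- (1:(10 * fs)) / fs
  x <- 3 * sin(2 * pi * 6 * tt)
  refsig <- thetawake:::new_ref_signal(x, fs)
  got <- detect_negative_peaks(refsig, -1, detection_params())
  expect_lte(abs(nrow(got) - 60), 2)          # one trough per 6 Hz cycle
  expect_true(all(diff(got$t_neg) > 0))
  # a trough exactly at the threshold is rejected (strict <)
  expect_equal(nrow(detect_negative_peaks(refsig, -3, detection_params())), 0)
  # flat signal: no candidates via threshold precondition
  flat <- thetawake:::new_ref_signal(rep(0, 10 * fs), fs)
  expect_error(detect_negative_peaks(flat, 0), "below the signal median")
  expect_equal(nrow(detect_negative_peaks(
    thetawake:::new_ref_signal(c(rep(0, 5 * fs), x[1:(5 * fs)]), fs), -10)),
    0)  # nothing ever crosses an unreachable threshold
})

test_that("involvement keeps matching channels and prunes isolated ones", {
  fs <- 512
  labs <- analysis_labels()
  dur <- 8
  bf <- signal::butter(2, c(5, 7) / (fs / 2), type = "pass")
  wav <- 3 * thetawake:::unit_wavelet(6, 1.5, fs)
  n <- dur * fs
  base <- withr::with_seed(42, matrix(rnorm(56 * n, sd = 0.05), 56))
  rownames(base) <- labs
  mid <- n / 2
  idx <- (mid - (length(wav) - 1) %/% 2):(mid + (length(wav) - 1) %/% 2)
  cluster <- c("Fz", "F1", "F2", "AFz", "FCz")
  distant <- "O2"
  for (ch in c(cluster, distant)) base[ch, idx] <- base[ch, idx] + wav
  rec_theta <- t(apply(base, 1, function(x) signal::filtfilt(bf, x)))
  rownames(rec_theta) <- labs
  refsig <- thetawake:::new_ref_signal(colMeans(rec_theta[cluster, ]), fs)
  thr <- compute_threshold(refsig)
  cands <- detect_negative_peaks(refsig, thr)
  cand <- cands[which.min(abs(cands$t_neg - (mid - 1) / fs)), ]
  p <- detection_params()
  inv <- event_involvement(cand, rec_theta, refsig, montage56, p)
  expect_true(all(cluster %in% inv))
  expect_false(distant %in% inv)   # isolated channel pruned by cluster rule
  # without pruning the distant copy is involved
  p0 <- detection_params(min_involved_neighbors = 0)
  inv0 <- event_involvement(cand, rec_theta, refsig, montage56, p0)
  expect_true(distant %in% inv0)
  # raising the cut never grows the involved set
  p99 <- detection_params(corr_cut = 0.99, min_involved_neighbors = 0)
  inv99 <- event_involvement(cand, rec_theta, refsig, montage56, p99)
  expect_true(all(inv99 %in% inv0))
})

test_that("independent noise channels are rarely involved", {
  fs <- 512
  labs <- analysis_labels()
  bf <- signal::butter(2, c(5, 7) / (fs / 2), type = "pass")
  wav <- 3 * thetawake:::unit_wavelet(6, 1.5, fs)
  n <- 8 * fs
  rates <- vapply(1:5, function(seed) {
    base <- withr::with_seed(seed, matrix(rnorm(56 * n), 56))
    rownames(base) <- labs
    mid <- n / 2
    idx <- (mid - (length(wav) - 1) %/% 2):(mid + (length(wav) - 1) %/% 2)
    area <- areas_default$frontal
    clean <- matrix(0, 56, n, dimnames = list(labs, NULL))
    clean[area[1], idx] <- wav * 50   # reference dominated by the event
    rec_theta <- t(apply(base, 1, function(x) signal::filtfilt(bf, x)))
    rownames(rec_theta) <- labs
    refsig <- thetawake:::new_ref_signal(
      signal::filtfilt(bf, colMeans(clean[area, ])), fs)
    cands <- detect_negative_peaks(refsig, -1)
    cand <- cands[which.min(abs(cands$t_neg - (mid - 1) / fs)), ]
    p0 <- detection_params(min_involved_neighbors = 0)
    mean(labs %in% event_involvement(cand, rec_theta, refsig, montage56, p0))
  }, 0)
  expect_lt(mean(rates), 0.05)  # pre-pruning chance involvement is rare
})

test_that("amplitude is read at the median-slope involved channel", {
  fs <- 512
  cand <- data.frame(i_prev = 1, i_neg = 2, i_next = 3,
                     t_pos_prev = 0, t_neg = 1 / fs, t_pos_next = 2 / fs,
                     value = -2)
  # three channels with slopes 1, 2, 9 -> median-slope channel is the second
  rec_theta <- rbind(c(0, -1, 1 * (2 - 1) / fs - 1),
                     c(0, -2, 2 * (2 - 1) / fs - 2),
                     c(0, -3, 9 * (2 - 1) / fs - 3))
  rownames(rec_theta) <- c("a", "b", "c")
  got <- event_amplitude(cand, c("a", "b", "c"), rec_theta)
  expect_identical(got$channel, "b")
  expect_equal(got$amplitude, unname(rec_theta["b", 3] - rec_theta["b", 2]))
  # identical wave on all channels, trough -2 to peak +1 -> amplitude 3
  rec2 <- rbind(c(0, -2, 1), c(0, -2, 1))
  rownames(rec2) <- c("a", "b")
  expect_equal(event_amplitude(cand, c("a", "b"), rec2)$amplitude, 3)
  # lower median for even counts
  rec4 <- rbind(c(0, -1, 0), c(0, -2, 1), c(0, -3, 3), c(0, -4, 6))
  rownames(rec4) <- letters[1:4]
  expect_identical(event_amplitude(cand, letters[1:4], rec4)$channel, "b")
  expect_error(event_amplitude(cand, character(0), rec_theta), "empty")
})

test_that("detection is silent on null input and shifts with translation", {
  labs <- analysis_labels()
  quiet <- new_recording(
    withr::with_seed(3, matrix(rnorm(56 * 512 * 70, sd = 1e-4), 56)),
    512, labs, reference = "average", unit_state = "zscored")
  det <- suppressWarnings(detect_all(quiet, areas_default, montage56))
  expect_true(all(det$events$globality_pct > 0 |
                    nrow(det$events) == 0))
  expect_named(det$density, names(areas_default))

  # translation invariance of candidate times
  fs <- 512
  x <- withr::with_seed(9, signal::filtfilt(
    signal::butter(2, c(5, 7) / 256, "pass"), rnorm(10 * fs)))
  k <- 321
  r1 <- thetawake:::new_ref_signal(c(x, numeric(k)), fs)
  r2 <- thetawake:::new_ref_signal(c(numeric(k), x), fs)
  thr <- compute_threshold(r1)
  t1 <- detect_negative_peaks(r1, thr)$t_neg
  t2 <- detect_negative_peaks(r2, thr)$t_neg
  interior <- t1[t1 > 0.5 & t1 < 9]
  expect_true(all(vapply(interior, function(t0)
    min(abs(t2 - (t0 + k / fs))) < 1e-9, TRUE)))

  # deepening the threshold never increases the candidate count
  expect_lte(nrow(detect_negative_peaks(r1, thr * 2)),
             nrow(detect_negative_peaks(r1, thr)))
})

test_that("injected frontal events are recovered with faithful properties", {
  sess <- gen_recovery_session(montage56, duration = 40, event_rate = 0.4,
                               amplitude = 3.5, radius = 28, seed = 23)
  rec <- average_reference(sess$rec)
  det <- detect_all(rec, list(frontal = areas_default$frontal), montage56)
  ev <- det$events
  hits <- vapply(sess$truth$t_neg, function(t0) {
    j <- which.min(abs(ev$t_neg_s - t0))
    c(err_ms = abs(ev$t_neg_s[j] - t0) * 1000,
      glob = ev$globality_pct[j], amp = ev$amplitude_z[j])
  }, c(0, 0, 0))
  detected <- hits["err_ms", ] <= 10
  expect_gte(mean(detected), 0.9)
  glob_mae_ch <- mean(abs(hits["glob", detected] -
                            sess$truth$truth_globality[detected])) / (100 / 56)
  expect_lte(glob_mae_ch, 2)
  amp_mae <- mean(abs(hits["amp", detected] -
                        sess$truth$truth_amplitude[detected]))
  expect_lte(amp_mae, 0.5)
  expect_equal(det$density[["frontal"]],
               sum(ev$area == "frontal") / det$usable_minutes)
})
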