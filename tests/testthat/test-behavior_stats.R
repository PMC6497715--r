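test_that("reaction-time validity rules use the 100/500 ms bounds", {
  tr <- data.frame(trial_id = 1:6, stim_time_s = 1:6,
                   rt_ms = c(244, 99, 501, 100, 500, 350),
                   outcome = "S", valid = NA)
  out <- filter_rts(tr)
  expect_identical(out$valid, c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(attr(out, "n_false_start"), 1)
  expect_equal(attr(out, "n_outlier"), 1)
})

test_that("percent above median is strict and per-session", {
  mk <- function(rts) data.frame(trial_id = seq_along(rts),
                                 stim_time_s = seq_along(rts),
                                 rt_ms = rts, outcome = "S",
                                 valid = rts >= 100 & rts <= 500)
  sessions <- list(a = mk(c(200, 300)), b = mk(rep(244, 4)))
  expect_equal(pooled_median_rt(list(mk(c(200, 244, 300)))), 244)
  pct <- percent_above_median(sessions, 244)
  expect_equal(pct[["a"]], 50)
  expect_equal(pct[["b"]], 0)   # ties are not above
  sessions$c <- mk(c(50, 600))  # no valid trials
  expect_warning(pct2 <- percent_above_median(sessions, 244), "c")
  expect_named(pct2, c("a", "b"))
  # pooled: strictly-above fraction of the pooled median is at most half
  pool <- mk(withr::with_seed(1, round(runif(101, 120, 480))))
  expect_lte(percent_above_median(list(p = pool),
                                  pooled_median_rt(list(pool)))[["p"]], 50)
})

test_that("peristimulus windows are half-open [-250 ms, +500 ms)", {
  ev <- data.frame(t_neg_s = c(9.75, 10.5, 10.2), globality_pct = c(10, 20, 30))
  tr <- data.frame(trial_id = 1:2, stim_time_s = c(10, 100),
                   rt_ms = 200, outcome = "S", valid = TRUE)
  s <- events_near_stimulus(ev, tr)
  expect_equal(s$n_events[1], 2)        # 9.75 included, 10.5 excluded
  expect_equal(s$max_globality[1], 30)
  expect_equal(s$mean_globality[1], 20)
  expect_true(s$eventless[2])
  expect_equal(s$max_globality[2], 0)
})

test_that("RT-globality regression reports slope, fit and F-test", {
  g <- seq(0, 30, length.out = 40)
  tr <- data.frame(trial_id = 1:40, stim_time_s = 1:40,
                   rt_ms = 200 + 2 * g, outcome = "S", valid = TRUE)
  s <- data.frame(max_globality = g)
  fit <- suppressWarnings(regress_rt_on_globality(s, tr))  # exact fit
  expect_equal(fit$slope, 2, tolerance = 1e-9)
  expect_equal(fit$r2_adj, 1, tolerance = 1e-9)
  expect_equal(fit$df, 38)
  expect_lt(fit$p, 1e-12)
  s0 <- data.frame(max_globality = rep(1, 40))
  expect_error(regress_rt_on_globality(s0, tr), "zero variance")
  expect_error(regress_rt_on_globality(s[1:5, , drop = FALSE], tr[1:5, ]),
               "10 valid")
})

test_that("permuted globality yields uniform regression p-values", {
  ps <- vapply(1:300, function(seed) withr::with_seed(seed, {
    g <- runif(200, 0, 30)
    rt <- 220 + 2 * sample(g) + rnorm(200, 0, 40)  # permuted coupling
    tr <- data.frame(trial_id = 1:200, stim_time_s = 1:200, rt_ms = rt,
                     outcome = "S", valid = TRUE)
    regress_rt_on_globality(data.frame(max_globality = g), tr)$p
  }), 0)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("paired topographic t-maps behave at the degenerate corners", {
  labs <- analysis_labels()
  A <- matrix(rnorm(5 * 56), 5, 56, dimnames = list(NULL, labs))
  same <- paired_topo_test(A, A)
  expect_true(all(same$t_map == 0))
  expect_equal(same$df, 4)   # five subjects
  B <- A
  B[, "Fz"] <- 0.5               # exact constant difference from zero below
  A2 <- A
  A2[, "Fz"] <- 0
  shift <- paired_topo_test(A2, B)
  expect_identical(unname(shift$t_map["Fz"]), Inf)
  expect_true(all(shift$t_map[setdiff(labs, "Fz")] == 0))
  expect_error(paired_topo_test(A, B[, 1:30]), "differ")
  expect_error(paired_topo_test(A[1:1, , drop = FALSE],
                                B[1:1, , drop = FALSE]), "2 subjects")
})

test_that("cluster correction enforces the three-neighbor floor", {
  labs <- analysis_labels()
  # background differences with exactly zero mean (t = 0 everywhere), plus
  # two neighboring channels with a consistent effect: below the cluster
  # floor, so never reported
  D <- matrix(rep(c(-2, -1, 0, 1, 2) * 0.01, 56), 5, 56,
              dimnames = list(NULL, labs))
  D[, c("Fz", "F1")] <- 5
  ts <- paired_topo_test(matrix(0, 5, 56, dimnames = list(NULL, labs)), D)
  res <- permutation_cluster_correct(ts, montage56, n_perm = 32)
  expect_gte(res$min_cluster, 3)
  expect_false(any(c("Fz", "F1") %in% res$sig_mask))
  # a compact ten-channel effect survives
  blob <- c("Fz", "F1", "F2", "AFz", "AF3", "AF4", "FCz", "FC1", "FC2", "Cz")
  D2 <- matrix(rnorm(5 * 56, sd = 0.3), 5, 56, dimnames = list(NULL, labs))
  D2[, blob] <- D2[, blob] + 4
  ts2 <- paired_topo_test(matrix(0, 5, 56, dimnames = list(NULL, labs)), D2)
  res2 <- permutation_cluster_correct(ts2, montage56, n_perm = 32)
  expect_gte(length(intersect(blob, res2$sig_mask)), 3)
  expect_true(all(res2$sig_mask %in% names(which(res2$p_map < 0.05))))
  expect_error(permutation_cluster_correct(ts2, montage56, n_perm = 64),
               "exceeds")
})

test_that("cluster statistics are invariant to a mirror relabeling", {
  labs <- analysis_labels()
  mirror <- vapply(labs, function(l) {
    digits <- regmatches(l, regexpr("[0-9]+", l))
    if (length(digits) == 0) return(l)
    d <- as.integer(digits)
    sub("[0-9]+", if (d %% 2 == 1) d + 1 else d - 1, l)
  }, "")
  expect_setequal(mirror, labs)   # left-right swap is a permutation
  D <- withr::with_seed(77, matrix(rnorm(5 * 56), 5, 56,
                                   dimnames = list(NULL, labs)))
  zero <- matrix(0, 5, 56, dimnames = list(NULL, labs))
  res <- permutation_cluster_correct(paired_topo_test(zero, D), montage56,
                                     32)
  Dm <- D
  colnames(Dm) <- mirror
  Dm <- Dm[, labs]
  resm <- permutation_cluster_correct(paired_topo_test(zero, Dm), montage56,
                                      32)
  expect_identical(sort(res$null_max), sort(resm$null_max))
  expect_identical(res$min_cluster, resm$min_cluster)
  expect_setequal(mirror[match(res$sig_mask, labs)], resm$sig_mask)
})

test_that("condition contrasts are paired, antisymmetric, and strict", {
  vals <- cbind(earth = c(10, 11, 12, 13, 14),
                space = c(14.2, 15.1, 15.9, 17.3, 18.0))
  cc <- condition_contrast(vals)
  expect_equal(cc$mean_diff, mean(vals[, 2] - vals[, 1]))
  expect_equal(cc$df, 4)
  expect_gt(cc$t, 0)
  swapped <- condition_contrast(vals[, c(2, 1)])
  expect_equal(swapped$mean_diff, -cc$mean_diff)
  expect_equal(swapped$t, -cc$t)
  same <- condition_contrast(cbind(a = vals[, 1], b = vals[, 1]))
  expect_equal(same$mean_diff, 0)
  long <- data.frame(subject = rep(1:3, each = 2),
                     condition = rep(c("a", "b"), 3),
                     value = c(1, 2, 1.5, 2.5, 0.5, 1.5))
  expect_equal(condition_contrast(long)$mean_diff, 1)
  expect_error(condition_contrast(long[-1, ]), "missing cell")
})
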