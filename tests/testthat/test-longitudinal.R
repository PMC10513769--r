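test_that("trend classification and pooled agreement", {
  expect_equal(classify_trend(10, 12), "increasing")
  expect_equal(classify_trend(12, 10), "decreasing")
  expect_equal(classify_trend(10, 10), "constant")
  expect_equal(classify_trend(0, 0), "constant")

  expect_equal(trend_agreement(c(1, 2, 3), c(1, 2, 3)), 100)
  expect_equal(trend_agreement(c(1, 2, 1, 2), c(1, 2, 3, 4)), 100 * 2 / 3,
               tolerance = 1e-12)
  expect_equal(trend_agreement(c(1, 2, 3), c(3, 2, 1)), 0)
  expect_error(trend_agreement(c(1, 2), c(1, 2, 3)), "mismatch")

  # pooling over patients: 2/3 and 3/3 pooled = 5/6
  a <- list(c(1, 2, 1, 2), c(1, 2, 3, 4))
  b <- list(c(1, 2, 3, 4), c(2, 3, 4, 5))
  expect_equal(trend_agreement(a, b), 100 * 5 / 6, tolerance = 1e-12)

  # scale invariance
  x <- c(3, 1, 4, 1, 5)
  expect_equal(trend_agreement(x, 7.3 * x), 100)
  expect_true(ranometry:::trend_labels(c(5, 5, 6))[1] == "constant")
})

test_that("Spearman rho on average ranks, with hand-computed tie case", {
  expect_equal(spearman_rho(1:5, c(2, 4, 8, 16, 32)), 1.0)
  expect_equal(spearman_rho(1:5, rev(1:5)), -1.0)
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(1, 3, 2, 4)), 4.5 / sqrt(22.5),
               tolerance = 1e-12)
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(1, 3, 2, 4)), 0.9487,
               tolerance = 1e-3)
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "undefined")
  # agrees with the stock implementation on random data
  for (seed in 1:3) {
    xy <- with_test_seed(seed, cbind(rnorm(20), rnorm(20)))
    expect_equal(spearman_rho(xy[, 1], xy[, 2]),
                 cor(xy[, 1], xy[, 2], method = "spearman"),
                 tolerance = 1e-12)
  }
})

test_that("consistency ICC: hand ANOVA value, offset invariance, noise", {
  expect_equal(icc_consistency(matrix(c(1, 2, 3, 2, 4, 6), ncol = 2)), 0.8,
               tolerance = 1e-12)
  r1 <- with_test_seed(5, rnorm(12, 10, 2))
  expect_equal(icc_consistency(cbind(r1, r1 + 5)), 1.0, tolerance = 1e-9)
  expect_equal(icc_consistency(cbind(r1, r1 + 5, r1 - 2)), 1.0,
               tolerance = 1e-9)
  noise <- with_test_seed(6, matrix(rnorm(400), 200, 2))
  expect_lt(abs(icc_consistency(noise)), 0.2)
  expect_error(icc_consistency(matrix(1:3, ncol = 1)), "at least 2")
  expect_error(icc_consistency(matrix(c(1, NA, 2, 3), 2, 2)), "complete")
})

test_that("nadir-referenced TTP follows the worked traces", {
  days <- c(60, 120, 180, 240)
  r <- compute_ttp(c(10, 8, 11, 11.3), metric = "volume", days = days,
                   os_days = 400)
  expect_true(r$progressed)
  expect_equal(r$ttp_days, 240)
  expect_equal(r$progression_index, 4L)
  expect_equal(r$nadir_trace, c(NA, 10, 8, 8))

  # threshold 0.30 catches the +37.5% step at day 180
  r30 <- compute_ttp(c(10, 8, 11, 11.3), metric = "volume", threshold = 0.30,
                     days = days, os_days = 400)
  expect_equal(r30$ttp_days, 180)

  # never progressing: TTP = OS
  rn <- compute_ttp(c(10, 9, 10.5, 11), metric = "volume", days = days,
                    os_days = 400)
  expect_false(rn$progressed)
  expect_equal(rn$ttp_days, 400)

  # baseline 10 -> 20 crosses the 25% SPD rule at the first follow-up
  rs <- compute_ttp(c(10, 20), metric = "spd2d", days = c(30, 100),
                    os_days = 300)
  expect_true(rs$progressed)
  expect_equal(rs$ttp_days, 100)

  # zero nadir followed by regrowth is called and flagged
  rz <- compute_ttp(c(5, 0, 3), metric = "volume", days = c(10, 50, 90),
                    os_days = 200)
  expect_true(rz$progressed && rz$zero_nadir_call)
  expect_equal(rz$ttp_days, 90)
})

test_that("expert nadir flags pin the reference time point", {
  tps <- list(
    timepoint_record(30, measurements = c(volume = 10)),
    timepoint_record(100, measurements = c(volume = 2),
                     expert_is_nadir = FALSE),  # under-segmented follow-up
    timepoint_record(170, measurements = c(volume = 9),
                     expert_is_nadir = TRUE),
    timepoint_record(240, measurements = c(volume = 13)))
  s <- patient_series("E", tps, os_days = 500)
  auto <- compute_ttp(s, "volume", nadir_mode = "auto")
  expect_equal(auto$ttp_days, 170)  # 9 >= 1.4 x 2: spurious call
  exp_r <- compute_ttp(s, "volume")  # expert flags present -> expert mode
  expect_equal(exp_r$ttp_days, 240)  # 13 >= 1.4 x 9, reference pinned at 9
})

test_that("TTP is weakly monotone in the threshold and recovers engineered
           crossing points exactly", {
  for (seed in 1:10) {
    vals <- with_test_seed(seed, abs(cumsum(rnorm(6, 0.1, 1))) + 0.5)
    days <- seq(30, by = 70, length.out = 6)
    tt <- vapply(c(0.1, 0.25, 0.4, 0.6, 1.0), function(th)
      as.numeric(compute_ttp(vals, metric = "volume", threshold = th,
                             days = days, os_days = 600)$ttp_days),
      numeric(1))
    expect_true(all(diff(tt) >= 0))
  }
  # engineered crossing at follow-up k for both metrics
  for (k in 2:5) {
    vals <- c(100, rep(100, k - 2), 100 * 1.45, rep(160, 6 - k))
    days <- seq(40, by = 80, length.out = 6)
    for (metric in c("volume", "spd2d")) {
      r <- compute_ttp(vals, metric = metric, days = days, os_days = 700)
      expect_equal(r$progression_index, k)
      expect_equal(r$ttp_days, days[k])
    }
  }
})

test_that("threshold sweep reproduces per-threshold mean differences and
           the TTP-OS correlation behaves", {
  mk_series <- function(id, vals, days, os, pd_at = NA) {
    ratings <- rep(NA_character_, length(days))
    if (!is.na(pd_at)) ratings[pd_at] <- "PD"
    tps <- lapply(seq_along(days), function(i)
      timepoint_record(days[i], measurements = c(volume = vals[i],
                                                 spd2d = vals[i],
                                                 spd25d = vals[i]),
                       expert_rating = ratings[i]))
    patient_series(id, tps, os)
  }
  s1 <- mk_series("A", c(10, 8, 11, 11.3), c(60, 120, 180, 240), 400,
                  pd_at = 4)
  s2 <- mk_series("B", c(5, 9, 9.5, 9.6), c(50, 110, 170, 230), 380,
                  pd_at = 2)
  sw <- threshold_sweep(list(s1, s2), "volume", thresholds = c(0.30, 0.40))
  # at 0.30: A -> 180 (diff -60), B -> 110 (diff 0); at 0.40: A -> 240, B -> 110
  expect_equal(sw$mean_diff_days, c(-30, 0))
  expect_equal(sw$n, c(2, 2))

  # cohort where the automated TTP equals the expert TTP exactly
  sw40 <- threshold_sweep(list(s1), "volume", thresholds = 0.40)
  expect_equal(sw40$mean_diff_days, 0)

  cohort <- lapply(1:6, function(i)
    mk_series(paste0("P", i), c(10, 10 * (1 + 0.5 * i)), c(30, 30 + 40 * i),
              200 + 50 * i))
  ct <- ttp_os_correlation(cohort, "volume", threshold = 0.25)
  expect_equal(ct$rho, 1.0)
  # n = 4 identical-rank pairs: exact permutation p = 1/12
  c4 <- lapply(1:4, function(i)
    mk_series(paste0("Q", i), c(10, 16), c(30, 30 + 40 * i), 200 + 50 * i))
  ct4 <- ttp_os_correlation(c4, "volume", threshold = 0.25)
  expect_equal(ct4$rho, 1.0)
  expect_equal(ct4$p_value, 1 / 12, tolerance = 1e-12)
  # independent TTP and OS: every series progresses at its (random) second
  # time point, drawn independently of the (random) survival time
  big <- with_test_seed(9, lapply(1:400, function(i) {
    os <- sample(300:1500, 1)
    mk_series(paste0("R", i), c(10, 16), c(30, sample(60:250, 1)), os)
  }))
  expect_lt(abs(ttp_os_correlation(big, "volume")$rho), 0.15)
})

test_that("invariances: ICC under rater offset, agreement and rho under
           positive scaling", {
  tab <- make_rater_table(40, 3, subject_sd = 2, noise_sd = 1, seed = 3)
  shifted <- tab
  shifted[, 2] <- shifted[, 2] + 100
  expect_equal(icc_consistency(tab), icc_consistency(shifted),
               tolerance = 1e-9)
  x <- c(5, 3, 8, 2, 9)
  y <- c(4, 4.5, 7, 3, 8)
  expect_equal(trend_agreement(x, y), trend_agreement(2.5 * x, 7 * y))
  expect_equal(spearman_rho(x, y), spearman_rho(3 * x, 0.1 * y))
  expect_equal(trend_agreement(x, y), trend_agreement(y, x))
})
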