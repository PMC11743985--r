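small_cfg <- function(...) {
  cohort_config(n_subjects_per_group = c(low = 3, high = 3),
                duration_s = 6, roi_list = c("PCC", "mPFC"),
                theta_effect_rois = "PCC", ...)
}

test_that("config validation enforces the generative invariants", {
  expect_error(cohort_config(fs = 0), class = "invalid_config")
  expect_error(cohort_config(duration_s = -1), class = "invalid_config")
  expect_error(cohort_config(alpha_center_by_group = c(low = 7, high = 10)),
               class = "invalid_config")
  expect_error(cohort_config(theta_effect_d = -0.5),
               class = "invalid_config")
  expect_error(cohort_config(n_subjects_per_group = c(low = 1, high = 5)),
               class = "invalid_config")
  expect_error(cohort_config(theta_effect_rois = "not_an_roi"),
               class = "invalid_config")
  expect_error(simulate_experience_sampling(1.2), class = "invalid_config")
  expect_error(simulate_ni_trials(1300, trials_per_block = 0),
               class = "invalid_config")
  expect_error(simulate_ni_trials(1300, n_blocks = 5),
               class = "invalid_config")
})

test_that("a fixed seed reproduces the cohort bit-identically", {
  co1 <- simulate_cohort(small_cfg(seed = 31), keep_series = TRUE)
  co2 <- simulate_cohort(small_cfg(seed = 31), keep_series = TRUE)
  expect_identical(co1$truth, co2$truth)
  expect_identical(co1$experience, co2$experience)
  expect_identical(co1$ni_trials, co2$ni_trials)
  expect_identical(co1$series, co2$series)
  # lazily regenerated series equal the stored ones
  co3 <- simulate_cohort(small_cfg(seed = 31))
  sid <- co1$truth$subject_id[1]
  expect_identical(subject_series_matrix(co3, sid), co1$series[[sid]])
  # a different seed gives a different cohort
  co4 <- simulate_cohort(small_cfg(seed = 32), keep_series = TRUE)
  expect_false(identical(co1$series[[sid]], co4$series[[sid]]))
})

test_that("latent attention endpoints pin the IAP score", {
  all_pain <- simulate_experience_sampling(1, 20, seed = 1)
  expect_true(all(all_pain$response == "only_pain"))
  expect_equal(compute_iap_score(all_pain)$iap_score, 2)
  none <- simulate_experience_sampling(0, 20, seed = 2)
  expect_true(all(none$response == "only_else"))
  expect_equal(compute_iap_score(none)$iap_score, -2)
})

test_that("an ambivalent latent propensity gives mean IAP near zero", {
  set.seed(33)
  scores <- vapply(1:1000, function(i)
    compute_iap_score(simulate_experience_sampling(0.5, 20))$iap_score,
    numeric(1))
  # E[score] = 2 * (2p - 1) = 0 at p = 0.5; MC standard error ~ 0.011
  expect_lt(abs(mean(scores)), 0.05)
})

test_that("NI simulation produces the alternating-block design", {
  ni <- simulate_ni_trials(1300, 48, seed = 34)
  expect_equal(nrow(ni), 6 * 24)
  blk <- unique(ni[, c("block", "condition")])
  expect_equal(blk$condition, rep(c("no_pain", "pain"), 3))
  expect_true(all(ni$rt_ms > 0))
})

test_that("noise-free pain shifts reproduce the worked delta-RT examples", {
  p <- compute_ap_type(filter_ni_trials(
    simulate_ni_trials(1216, 48, rt_sdlog = 0, seed = 35)))
  expect_equal(p$delta_rt_mean, 48)
  expect_equal(p$ap_type, "P")
  a <- compute_ap_type(filter_ni_trials(
    simulate_ni_trials(1344, -75, rt_sdlog = 0, seed = 36)))
  expect_equal(a$delta_rt_mean, -75)
  expect_equal(a$ap_type, "A")
})

test_that("an outlier rate of one empties every analysis block", {
  ni <- simulate_ni_trials(1300, 0, outlier_rate = 1, seed = 37)
  expect_true(all(ni$rt_ms < 200 | ni$rt_ms > 2500))
  filtered <- filter_ni_trials(ni)
  expect_equal(nrow(filtered), 0)
  expect_error(compute_ap_type(filtered), class = "empty_after_filter")
})

test_that("degenerate spectral config gives a flat white-noise spectrum", {
  cfg <- cohort_config(duration_s = 30, aperiodic_exponent = 0,
                       aperiodic_offset = 1, noise_sd = 0,
                       alpha_bump_power_by_group = c(low = 0, high = 0),
                       theta_power_by_group = c(low = 0, high = 0))
  ts <- simulate_roi_timeseries(cfg, seed = 38)
  ps <- welch_psd(ts)
  idx <- ps$freq >= 1 & ps$freq <= 100
  expect_lt(abs(mean(ps$power[idx]) - 1), 0.05)
  expect_lt(sd(ps$power[idx]) / mean(ps$power[idx]), 0.3)
})

test_that("a strong alpha bump is recovered at the configured frequency", {
  cfg <- cohort_config(duration_s = 20, noise_sd = 0.02,
                       alpha_bump_power_by_group = c(low = 3, high = 3),
                       theta_power_by_group = c(low = 0.2, high = 0.2))
  ts <- simulate_roi_timeseries(cfg, seed = 39, alpha_center = 10)
  # the synthesized signal's own PSD peaks where configured
  expect_equal(compute_band_metrics(ts)$paf_speed, 10, tolerance = 0.1)
})

test_that("log-log background slope matches the aperiodic exponent", {
  for (chi in c(0.8, 1.2)) {
    cfg <- cohort_config(duration_s = 40, aperiodic_exponent = chi,
                         noise_sd = 0,
                         alpha_bump_power_by_group = c(low = 0, high = 0),
                         theta_power_by_group = c(low = 0, high = 0))
    ts <- simulate_roi_timeseries(cfg, seed = 40)
    ps <- welch_psd(ts)
    idx <- ps$freq >= 20 & ps$freq <= 80
    fit <- lm(log10(ps$power[idx]) ~ log10(ps$freq[idx]))
    expect_equal(unname(coef(fit)[2]), -chi, tolerance = 0.1)
  }
})

test_that("the calibrated theta contrast recovers the target effect size", {
  cfg <- calibrate_theta_effect(cohort_config(
    n_subjects_per_group = c(low = 200, high = 200), duration_s = 20,
    roi_list = "PCC", theta_effect_rois = "PCC", seed = 5))
  expect_gt(cfg$theta_power_by_group[["low"]],
            cfg$theta_power_by_group[["high"]])
  co <- simulate_cohort(cfg)
  met <- compute_cohort_metrics(co)
  g <- co$truth$group[match(met$subject_id, co$truth$subject_id)]
  d <- cohens_d(met$total_theta_power[g == "low"],
                met$total_theta_power[g == "high"])
  expect_equal(d, 0.93, tolerance = 0.15)
})
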