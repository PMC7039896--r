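test_that("observed completion converts angles to lengths through the row's own model", {
  # choose an angle whose forward length is known, then complete and compare
  obs <- tibble::tibble(A_mm = 9.2, B_mm = 6.8, model = "eca",
                        actual_angular_c1_deg = 500)
  done <- complete_observed(obs)
  expect_equal(done$actual_linear_c1_mm, cdl_eca(9.2, 6.8, 500), tolerance = 1e-12)
  expect_equal(done$actual_linear_tip_mm, done$actual_linear_c1_mm + 1.2)
  expect_equal(cdl_eca(9.2, 6.8, done$actual_angular_tip_deg),
               done$actual_linear_tip_mm, tolerance = 1e-6)

  esc <- complete_observed(tibble::tibble(A_mm = 9.2, model = "escude",
                                          actual_angular_c1_deg = 500))
  expect_equal(esc$actual_linear_c1_mm, cdl_escude(9.2, 500), tolerance = 1e-12)
})

test_that("prediction errors are actual minus predicted, per subject", {
  meas <- tibble::tibble(subject_id = 1:3,
                         A_mm = c(9.2, 8.7, 9.6), B_mm = c(6.8, 6.5, 7.1))
  pred <- predict_insertion(meas, model = "eca")
  obs <- tibble::tibble(subject_id = 1:3,
                        actual_angular_c1_deg = pred$angular_c1_deg + c(-40, 0, 25))
  err <- prediction_error(pred, obs)
  # hand subtraction, record by record
  expect_equal(err$angular_error_deg, c(-40, 0, 25), tolerance = 1e-9)
  # linear error via the forward model at the observed angle
  expect_equal(err$linear_error_mm,
               cdl_eca(meas$A_mm, meas$B_mm, obs$actual_angular_c1_deg) - 26.8,
               tolerance = 1e-9)
  # negative error = prediction overestimated the achieved depth
  expect_lt(err$linear_error_mm[1], 0)
  expect_equal(err$linear_error_mm[2], 0, tolerance = 1e-9)
})

test_that("error summaries take absolute values per record with sample SDs", {
  err <- tibble::tibble(model = "eca",
                        angular_error_deg = c(-10, 10),
                        linear_error_mm = c(-0.5, 0.5))
  s <- summarize_errors(err, model)
  expect_equal(s$mean_abs_angular_deg, 10)
  expect_equal(s$mean_signed_angular_deg, 0)
  expect_equal(s$sd_abs_angular_deg, 0)  # |errors| are equal

  # spreadsheet-style hand computation on five records
  e5 <- c(-2.1, -0.4, 0.9, -1.5, 0.3)
  err5 <- tibble::tibble(model = "x", angular_error_deg = e5 * 30,
                         linear_error_mm = e5)
  s5 <- summarize_errors(err5, model)
  expect_equal(s5$mean_abs_linear_mm, mean(c(2.1, 0.4, 0.9, 1.5, 0.3)))
  expect_equal(s5$sd_abs_linear_mm, stats::sd(c(2.1, 0.4, 0.9, 1.5, 0.3)))
  expect_equal(s5$mean_signed_linear_mm, mean(e5))
  expect_gte(s5$mean_abs_linear_mm, abs(s5$mean_signed_linear_mm))

  # a single record has no sample SD
  s1 <- summarize_errors(err5[1, ], model)
  expect_true(is.na(s1$sd_abs_linear_mm))
  expect_error(summarize_errors(err5[0, ], model), "no finite error records")
})

test_that("cohort mean angles convert to turns by 360", {
  expect_equal(cohort_angle_summary(tibble::tibble(a = c(360, 360)), a)$mean_deg, 360)
  expect_equal(cohort_angle_summary(tibble::tibble(a = c(360, 360)), a)$turns, 1)
  s <- cohort_angle_summary(tibble::tibble(a = c(540, 580)), a)
  expect_equal(s$mean_deg, 560)
  expect_equal(s$turns, 560 / 360)
})

test_that("pooled mean equals the mean of per-observer means at equal group sizes", {
  coh <- generate_cohort(cohort_config(n_subjects = 20), seed = 11)
  pooled <- cohort_angle_summary(coh$observed, actual_angular_tip_deg)
  per_obs <- cohort_angle_summary(coh$observed, actual_angular_tip_deg, observer)
  expect_equal(pooled$mean_deg, mean(per_obs$mean_deg), tolerance = 1e-12)
})

test_that("exceedance report gives empirical fractions and normal tails", {
  all_neg <- c(-0.2, -1.1, -0.6)
  r <- exceedance_report(all_neg)
  expect_equal(r$frac_exceed_0, 0)

  toy <- c(-1.5, -0.8, -0.6, -0.3, -0.1, 0.2, 0.4, 0.9, -2.2, 0.05)
  r10 <- exceedance_report(toy, bound = 0.5)
  expect_equal(r10$frac_exceed_0, 4 / 10)   # hand count
  expect_equal(r10$frac_exceed_bound, 1 / 10)
  # fitted-normal tail probabilities against a direct CDF evaluation
  expect_equal(r10$p_exceed_0_normal,
               1 - stats::pnorm(0, mean(toy), stats::sd(toy)), tolerance = 1e-12)
  expect_equal(r10$p_exceed_bound_normal,
               1 - stats::pnorm(0.5, mean(toy), stats::sd(toy)), tolerance = 1e-12)
  # the conventional one- and two-SD planning tails (about 16% and 2.3%)
  expect_equal(r10$p_one_sd_tail, 1 - stats::pnorm(1), tolerance = 1e-12)
  expect_equal(r10$p_two_sd_tail, 1 - stats::pnorm(2), tolerance = 1e-12)
  expect_equal(round(100 * r10$p_one_sd_tail), 16)
  expect_error(exceedance_report(numeric(0)), "no finite")
})

test_that("zero observation noise and model-consistent truth gives zero error for the generating model", {
  cfg <- cohort_config(n_subjects = 6,
                       obs_noise_A = c(0, 0), obs_noise_B = c(0, 0),
                       session_sd_A = 0, session_sd_B = 0,
                       inter_observer_bias_A = c(0, 0),
                       inter_observer_bias_B = c(0, 0),
                       insertion_shortfall_mean = 0, insertion_shortfall_sd = 0,
                       actual_angle_noise_sd = 0,
                       generating_model = "eca")
  coh <- generate_cohort(cfg, seed = 3)
  pred <- predict_insertion(coh$measurements, model = "both")
  err <- prediction_error(pred, coh$observed)
  s <- summarize_errors(err, model)
  eca_row <- dplyr::filter(s, model == "eca")
  expect_lt(eca_row$mean_abs_angular_deg, 1e-6)
  expect_lt(eca_row$mean_abs_linear_mm, 1e-9)
  # the non-generating model keeps a genuine model-mismatch error
  expect_gt(dplyr::filter(s, model == "escude")$mean_abs_angular_deg, 1)
})

test_that("mean absolute error shrinks when observation noise shrinks", {
  mae_at <- function(noise_sd, seed) {
    cfg <- cohort_config(n_subjects = 500, n_observations = 1,
                         actual_angle_noise_sd = noise_sd,
                         generating_model = "eca")
    coh <- generate_cohort(cfg, seed = seed)
    pred <- suppressWarnings(predict_insertion(coh$measurements, model = "eca"))
    err <- suppressWarnings(prediction_error(pred, coh$observed))
    summarize_errors(err, model)$mean_abs_angular_deg
  }
  for (seed in c(1, 2)) {
    expect_lt(mae_at(4, seed), mae_at(16, seed))
  }
})
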