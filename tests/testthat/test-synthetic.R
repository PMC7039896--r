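test_that("cohorts are reproducible and respect the anatomical box", {
  cfg <- cohort_config(n_subjects = 30)
  a <- generate_cohort(cfg, seed = 14)
  b <- generate_cohort(cfg, seed = 14)
  expect_identical(a$truth, b$truth)
  expect_identical(a$measurements, b$measurements)
  expect_identical(a$observed, b$observed)
  c2 <- generate_cohort(cfg, seed = 15)
  expect_false(identical(a$truth$A_true_mm, c2$truth$A_true_mm))

  expect_true(all(a$truth$A_true_mm >= 7 & a$truth$A_true_mm <= 11))
  expect_true(all(a$truth$B_true_mm >= 5 & a$truth$B_true_mm <= 8))
  expect_true(all(a$truth$A_true_mm > a$truth$B_true_mm))
  expect_true(all(a$truth$shortfall_mm >= 0))
})

test_that("with all noise off, measurements equal truth and insertion is nominal", {
  cfg <- cohort_config(n_subjects = 5,
                       obs_noise_A = c(0, 0), obs_noise_B = c(0, 0),
                       session_sd_A = 0, session_sd_B = 0,
                       inter_observer_bias_A = c(0, 0),
                       inter_observer_bias_B = c(0, 0),
                       insertion_shortfall_mean = 0, insertion_shortfall_sd = 0,
                       actual_angle_noise_sd = 0)
  coh <- generate_cohort(cfg, seed = 1)
  joined <- dplyr::left_join(coh$measurements, coh$truth, by = "subject_id")
  expect_equal(joined$A_mm, joined$A_true_mm, tolerance = 1e-12)
  expect_equal(joined$B_mm, joined$B_true_mm, tolerance = 1e-12)
  expect_equal(coh$truth$actual_linear_c1_mm, rep(26.8, 5))
})

test_that("the default study configuration encodes the two-observer design", {
  cfg <- default_study_config()
  expect_equal(cfg$n_subjects, 46)
  expect_equal(cfg$n_observers, 2)
  expect_equal(cfg$n_observations, 2)
  # per-measurement noise is the intra-observer difference SD over sqrt(2)
  expect_equal(cfg$obs_noise_A, c(0.47, 0.53) / sqrt(2))
  expect_equal(cfg$obs_noise_B, c(0.40, 0.44) / sqrt(2))
  expect_equal(cfg$generating_model, "eca")
  expect_s3_class(cfg, "cohort_config")
})

test_that("intra-observer difference SD recovers sqrt(2) times the injected noise", {
  sigma <- 0.47 / sqrt(2)
  cfg <- cohort_config(n_subjects = 500,
                       obs_noise_A = c(sigma, sigma),
                       insertion_shortfall_sd = 0, actual_angle_noise_sd = 0)
  coh <- generate_cohort(cfg, seed = 8)
  wide <- tidyr::pivot_wider(
    dplyr::filter(coh$measurements, observer == 1)[
      c("subject_id", "observation", "A_mm")],
    names_from = "observation", values_from = "A_mm", names_prefix = "o")
  ba <- bland_altman(wide, o1, o2)
  expect_lt(abs(ba$sd_diff - 0.47) / 0.47, 0.15)
  expect_lt(abs(ba$sd_diff - sigma * sqrt(2)) / (sigma * sqrt(2)), 0.15)
})

test_that("session noise makes inter-observer differences tighter than intra-observer ones", {
  # session SDs solved from difference SDs of 0.47/0.53 (intra, A), 0.27
  # (inter, A) and 0.40/0.44 / 0.41 for B: the shared component cancels in
  # the inter-observer difference but not in the intra-observer one
  cfg <- cohort_config(n_subjects = 500,
                       session_sd_A = sqrt(0.47^2 / 2 -
                                             (0.27^2 - (0.53^2 - 0.47^2) / 2) / 2),
                       session_sd_B = sqrt(0.40^2 / 2 -
                                             (0.41^2 - (0.44^2 - 0.40^2) / 2) / 2),
                       insertion_shortfall_sd = 0, actual_angle_noise_sd = 0)
  coh <- generate_cohort(cfg, seed = 18)
  intra <- tidyr::pivot_wider(
    dplyr::filter(coh$measurements, observer == 1)[
      c("subject_id", "observation", "A_mm")],
    names_from = "observation", values_from = "A_mm", names_prefix = "o")
  sd_intra <- bland_altman(intra, o1, o2)$sd_diff
  inter <- tidyr::pivot_wider(
    dplyr::filter(coh$measurements, observation == 1)[
      c("subject_id", "observer", "A_mm")],
    names_from = "observer", values_from = "A_mm", names_prefix = "r")
  sd_inter <- bland_altman(inter, r1, r2)$sd_diff
  expect_lt(abs(sd_intra - 0.47) / 0.47, 0.15)
  expect_lt(abs(sd_inter - 0.27) / 0.27, 0.15)
  expect_lt(sd_inter, sd_intra)
})

test_that("injected inter-observer bias shows up as the Bland-Altman mean difference", {
  cfg <- cohort_config(n_subjects = 500, n_observations = 1,
                       insertion_shortfall_sd = 0, actual_angle_noise_sd = 0)
  coh <- generate_cohort(cfg, seed = 12)
  wide <- tidyr::pivot_wider(
    coh$measurements[c("subject_id", "observer", "A_mm")],
    names_from = "observer", values_from = "A_mm", names_prefix = "obs")
  ba <- bland_altman(wide, obs1, obs2)
  # observer 2 reads A higher by 0.12 mm, so observer1 - observer2 ~ -0.12;
  # difference SD is sqrt(sigma1^2 + sigma2^2), so SE = SD/sqrt(n)
  se <- ba$sd_diff / sqrt(ba$n)
  expect_lt(abs(ba$mean_diff - (-0.12)), 2 * se)
})

test_that("a positive shortfall makes predictions systematically overestimate", {
  coh <- generate_cohort(cohort_config(n_subjects = 60), seed = 4)
  # small cochleae that cannot seat the full array warn and drop to NA
  pred <- suppressWarnings(predict_insertion(coh$measurements, model = "both"))
  err <- suppressWarnings(prediction_error(pred, coh$observed))
  s <- summarize_errors(err, model)
  expect_true(all(s$mean_signed_linear_mm < 0))
  expect_true(all(s$mean_signed_angular_deg < 0))
})

test_that("cohorts roundtrip through the CSV writer", {
  coh <- generate_cohort(cohort_config(n_subjects = 6), seed = 2)
  stem <- file.path(withr::local_tempdir(), "coh")
  paths <- write_cohort(coh, stem)
  expect_true(all(file.exists(paths)))
  meas <- read_measurements(paths[1])
  expect_equal(as.numeric(meas$A_mm), coh$measurements$A_mm, tolerance = 1e-12)
  expect_equal(meas$observer, coh$measurements$observer)
})
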