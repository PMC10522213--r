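test_that("cohort generation is reproducible from the seed", {
  a <- generate_cohort(cohort_config(n_subjects = 30, seed = 77))
  b <- generate_cohort(cohort_config(n_subjects = 30, seed = 77))
  c_ <- generate_cohort(cohort_config(n_subjects = 30, seed = 78))
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$panels, b$panels)
  expect_false(identical(a$subjects, c_$subjects))
})

test_that("invalid cohort configurations are rejected", {
  expect_error(cohort_config(n_subjects = 2), ">= 3")
  expect_error(cohort_config(dxa_noise_sd = -1), ">= 0")
  bad_r <- matrix(0.99, 6, 6); diag(bad_r) <- 1; bad_r[1, 2] <- -0.99
  expect_error(cohort_config(site_correlation = bad_r), "positive definite")
  expect_error(observer_error_config(
    intra_noise_sd_mm = c(triceps = -0.1, suprailiac = 0.1, medial_thigh = 0.1)),
    ">= 0")
})

test_that("zero-noise, zero-offset cohorts make all four methods identical", {
  co <- generate_cohort(cohort_config(n_subjects = 25, seed = 2,
                                      dxa_offset = 0, bia_offset = 0,
                                      dxa_noise_sd = 0, bia_noise_sd = 0))
  expect_equal(co$panels$dxa, co$panels$sf_jpw, tolerance = 1e-12)
  expect_equal(co$panels$bia, co$panels$sf_jpw, tolerance = 1e-12)
  expect_warning(ccc <- lin_ccc(co$panels$bia, co$panels$dxa), "point mass")
  expect_equal(ccc$estimate, 1.0)
})

test_that("sample moments track the configured distribution", {
  # truncation-negligible configuration isolates the sampling machinery
  cfg <- cohort_config(
    n_subjects = 20000, seed = 99,
    site_means_mm = c(tsf_mm = 40, ssf_mm = 40, sisf_mm = 40, aasf_mm = 40,
                      mtsf_mm = 45, csf_mm = 40),
    site_sds_mm = c(tsf_mm = 6, ssf_mm = 6, sisf_mm = 6, aasf_mm = 6,
                    mtsf_mm = 6, csf_mm = 6))
  co <- generate_cohort(cfg)
  m <- colMeans(co$subjects[, names(cfg$site_means_mm)])
  expect_equal(unname(m), unname(cfg$site_means_mm), tolerance = 0.01)
  s <- apply(co$subjects[, names(cfg$site_means_mm)], 2, sd)
  expect_equal(unname(s), unname(cfg$site_sds_mm), tolerance = 0.015)
  r <- cor(co$subjects$tsf_mm, co$subjects$csf_mm)
  expect_equal(r, 0.6, tolerance = 0.02)
})

test_that("default cohort means land near their configured targets", {
  co <- generate_cohort(cohort_config(seed = 1))
  cfg <- co$config
  for (site in names(cfg$site_means_mm)) {
    se <- cfg$site_sds_mm[[site]] / sqrt(cfg$n_subjects)
    expect_lt(abs(mean(co$subjects[[site]]) - cfg$site_means_mm[[site]]),
              3 * se)
  }
  expect_true(all(co$subjects[, names(cfg$site_means_mm)] > 2))
  expect_gt(mean(co$panels$dxa), mean(co$panels$sf_jpw))
})

test_that("closed-form oracles match hand arithmetic", {
  expect_equal(closed_form_ccc(5, 5, 2, 2, 0.8), 0.8)
  expect_equal(closed_form_ccc(0, 1, 1, 1, 1), 2 / 3, tolerance = 1e-12)
  expect_equal(closed_form_ccc(0, 0, 1, 2, 0), 0)
  expect_error(closed_form_ccc(0, 0, -1, 1, 0.5))
  expect_error(closed_form_ccc(0, 0, 1, 1, 1.5))
  expect_equal(closed_form_st_laurent(6, 3), 36 / 45, tolerance = 1e-12)
  expect_equal(closed_form_st_laurent(1, 0, 0), 1)
  expect_error(closed_form_st_laurent(-1, 1))
})

test_that("sample coefficients converge to their closed forms", {
  set.seed(61)
  n <- 5000
  z1 <- rnorm(n); z2 <- 0.8 * z1 + sqrt(1 - 0.8^2) * rnorm(n)
  expect_equal(lin_ccc(10 + 3 * z1, 10 + 3 * z2)$estimate,
               closed_form_ccc(10, 10, 3, 3, 0.8), tolerance = 0.02)

  g <- rnorm(n, 30, 6)
  t_ <- g + rnorm(n, 0, 3)
  expect_equal(st_laurent_point(g, t_), closed_form_st_laurent(6, 3),
               tolerance = 0.02)
  t_bias <- g + 2 + rnorm(n, 0, 3)
  expect_equal(st_laurent_point(g, t_bias), closed_form_st_laurent(6, 3, 2),
               tolerance = 0.02)
})

test_that("observer sessions honour their error configuration", {
  subjects <- generate_cohort(reliability_cohort_config(n_subjects = 20,
                                                        seed = 8))$subjects
  silent <- observer_error_config(
    intra_noise_sd_mm = c(triceps = 0, suprailiac = 0, medial_thigh = 0),
    inter_bias_mm = c(triceps = 0, suprailiac = 0, medial_thigh = 0),
    inter_subject_sd_mm = c(triceps = 0, suprailiac = 0, medial_thigh = 0),
    seed = 3)
  ses <- generate_observer_sessions(subjects, silent)
  # all passes identical to the true site values
  for (pass in c("A1", "B", "A2")) {
    sub <- ses[ses$observer_pass == pass & ses$site == "triceps", ]
    expect_equal(sub$reading1_mm, subjects$tsf_mm, tolerance = 1e-12)
    expect_equal(sub$reading3_mm, subjects$tsf_mm, tolerance = 1e-12)
  }

  biased <- observer_error_config(
    intra_noise_sd_mm = c(triceps = 0, suprailiac = 0, medial_thigh = 0),
    inter_bias_mm = c(triceps = 0, suprailiac = 3.68, medial_thigh = 0),
    inter_subject_sd_mm = c(triceps = 0, suprailiac = 0, medial_thigh = 0),
    seed = 3)
  ses_b <- generate_observer_sessions(subjects, biased)
  b_si <- ses_b[ses_b$observer_pass == "B" & ses_b$site == "suprailiac", ]
  expect_equal(b_si$reading2_mm, subjects$sisf_mm + 3.68, tolerance = 1e-12)

  expect_identical(generate_observer_sessions(subjects, biased), ses_b)
  expect_error(generate_observer_sessions(subjects[, "subject_id", drop = FALSE],
                                          biased), "missing site")
})
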