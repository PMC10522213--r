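test_that("triplicate averaging is the arithmetic mean of 3 positive readings", {
  expect_equal(average_triplicate(c(10, 11, 12)), 11.0)
  expect_equal(average_triplicate(c(8, 8, 8)), 8.0)
  expect_equal(average_triplicate(c(19.0, 19.5, 20.2)), 19.5667, tolerance = 1e-4)
  expect_error(average_triplicate(c(10, 11)), "exactly 3")
  expect_error(average_triplicate(c(10, -1, 12)))
})

test_that("session derivatives chain sum -> density -> %BF", {
  sm <- c(triceps = 19.45, suprailiac = 25.59, medial_thigh = 34.37)
  der <- session_derivatives(sm, 29.28)
  expect_equal(der$sum3_mm, 79.41, tolerance = 1e-12)
  # frozen direct evaluation of the JPW equation at this sum and age
  expect_equal(der$density, 1.03107382, tolerance = 1e-6)
  expect_equal(der$percent_bf, 30.08202, tolerance = 1e-4)
  expect_equal(der$density, oracle_density_jpw(79.41, 29.28), tolerance = 1e-12)

  expect_error(session_derivatives(sm[c("triceps", "suprailiac")], 30),
               "medial_thigh")
  # duplicate session gives identical derivatives
  expect_identical(session_derivatives(sm, 29.28), session_derivatives(sm, 29.28))
})

test_that("perfect-duplicate sessions yield CCC 1 for every quantity", {
  ses <- perfect_sessions(n = 6)
  rep <- suppressWarnings(reliability_analysis(ses, subjects_for(ses)))
  expect_equal(nrow(rep), 10)  # 5 quantities x 2 comparisons
  expect_true(all(abs(rep$ccc - 1) < 1e-12))
  expect_equal(attr(rep, "n_subjects"), 6)
  expect_equal(attr(rep, "n_dropped"), 0)
})

test_that("subjects with incomplete passes are dropped and counted", {
  ses <- perfect_sessions(n = 5)
  broken <- ses[!(ses$subject_id == "S05" & ses$observer_pass == "A2"), ]
  expect_message(rep <- suppressWarnings(
    reliability_analysis(broken, subjects_for(ses))), "dropped 1 subject")
  expect_equal(attr(rep, "n_subjects"), 4)
  expect_equal(attr(rep, "n_dropped"), 1)
  expect_equal(attr(rep, "n_subjects") + attr(rep, "n_dropped"),
               length(unique(ses$subject_id)))

  two <- perfect_sessions(n = 2)
  expect_error(suppressWarnings(reliability_analysis(two, subjects_for(two))),
               "fewer than 3")
})

test_that("intra-observer CCC decreases as reading noise grows", {
  cfg0 <- reliability_cohort_config(n_subjects = 40, seed = 9)
  subjects <- generate_cohort(cfg0)$subjects
  ccc_at_noise <- function(sd) {
    err <- observer_error_config(
      intra_noise_sd_mm = c(triceps = sd, suprailiac = sd, medial_thigh = sd),
      inter_bias_mm = c(triceps = 0, suprailiac = 0, medial_thigh = 0),
      inter_subject_sd_mm = c(triceps = 0, suprailiac = 0, medial_thigh = 0),
      seed = 13)
    ses <- generate_observer_sessions(subjects, err)
    rep <- suppressWarnings(reliability_analysis(ses, subjects))
    mean(rep$ccc[rep$comparison == "intra" & rep$quantity == "sum_sf"])
  }
  cccs <- vapply(c(0.2, 1, 3, 8), ccc_at_noise, numeric(1))
  expect_true(all(diff(cccs) < 0))
})

test_that("calibrated observer error makes intra agreement beat inter agreement", {
  subjects <- generate_cohort(reliability_cohort_config(seed = 3))$subjects
  ses <- generate_observer_sessions(subjects, observer_error_config(seed = 4))
  rep <- reliability_analysis(ses, subjects)
  wide <- reshape(as.data.frame(rep)[, c("quantity", "comparison", "ccc")],
                  idvar = "quantity", timevar = "comparison", direction = "wide")
  expect_true(all(wide$ccc.intra > wide$ccc.inter))
  inter <- rep[rep$comparison == "inter", ]
  sites <- inter[inter$quantity %in% c("triceps", "suprailiac", "medial_thigh"), ]
  expect_equal(sites$quantity[which.max(sites$ccc)], "triceps")
})
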