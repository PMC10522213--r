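test_that("descriptive summaries use n-1 SD and median of central order stats", {
  d <- describe(c(1, 2, 3, 4))
  expect_equal(d$mean, 2.5)
  expect_equal(d$sd, sqrt(5 / 3), tolerance = 1e-12)
  expect_equal(d$sd, 1.2910, tolerance = 1e-4)
  expect_equal(c(d$minimum, d$median, d$maximum), c(1, 2.5, 4))

  expect_warning(one <- describe(5), "variance undefined")
  expect_equal(c(one$mean, one$sd, one$minimum, one$median, one$maximum),
               c(5, 0, 5, 5, 5))
  cst <- describe(c(2, 2, 2))
  expect_equal(cst$sd, 0)
  expect_equal(c(cst$minimum, cst$median, cst$maximum), c(2, 2, 2))
  expect_error(describe(numeric(0)), "empty")
})

test_that("pearson_r matches hand values and rejects degenerate input", {
  expect_equal(pearson_r(c(1, 2, 3), c(2, 3, 4)), 1.0)
  expect_equal(pearson_r(c(1, 2, 3), c(3, 2, 1)), -1.0)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8, tolerance = 1e-12)
  expect_error(pearson_r(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), ">= 3")
})

test_that("Lin CCC matches hand-computed cases", {
  expect_equal(lin_ccc(c(1, 2, 3), c(2, 3, 4))$estimate, 4 / 7,
               tolerance = 1e-12)
  expect_warning(perfect <- lin_ccc(1:10, 1:10), "point mass")
  expect_equal(perfect$estimate, 1.0)
  expect_equal(perfect$ci_lower, 1.0)
  expect_warning(anti <- lin_ccc(c(1, 2, 3), c(3, 2, 1)), "point mass")
  expect_equal(anti$estimate, -1.0)
  expect_error(lin_ccc(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("Lin CCC is symmetric, bounded by |r|, and equals the moment oracle", {
  set.seed(23)
  for (i in 1:300) {
    p <- random_pair(n = sample(5:60, 1))
    a <- lin_ccc(p$x, p$y)
    expect_equal(a$estimate, oracle_ccc(p$x, p$y), tolerance = 1e-12)
    expect_equal(a$estimate, lin_ccc(p$y, p$x)$estimate, tolerance = 1e-12)
    expect_lte(abs(a$estimate), abs(a$components$pearson_r) + 1e-12)
    expect_true(a$ci_lower <= a$estimate && a$estimate <= a$ci_upper)
    expect_lte(abs(a$estimate), 1)
  }
})

test_that("St. Laurent coefficient matches hand values and stays in [0, 1]", {
  expect_equal(st_laurent(gold = c(1, 2, 3), test = c(1, 2, 3),
                          boot = 200)$estimate, 1.0)
  expect_equal(st_laurent(gold = c(1, 2, 3), test = c(2, 3, 4),
                          boot = 200)$estimate, 0.4, tolerance = 1e-12)
  expect_equal(st_laurent(gold = c(1, 2, 3), test = c(1.1, 1.9, 3.0),
                          boot = 200)$estimate, 2 / 2.02, tolerance = 1e-12)
  expect_error(st_laurent(gold = c(1, 1, 1), test = c(1, 2, 3)),
               "zero gold-standard variance")

  set.seed(31)
  for (i in 1:100) {
    g <- rnorm(20, 30, 5)
    t_ <- g + rnorm(20, runif(1, -4, 4), runif(1, 0, 4))
    est <- st_laurent(g, t_, boot = 100)
    expect_equal(est$estimate, oracle_st_laurent(g, t_), tolerance = 1e-12)
    expect_gte(est$estimate, 0)
    expect_lte(est$estimate, 1)
    expect_true(est$ci_lower <= est$estimate && est$estimate <= est$ci_upper)
  }
})

test_that("added noise lowers expected St. Laurent agreement", {
  set.seed(5)
  g <- rnorm(200, 30, 6)
  clean <- mean(replicate(50, {
    t_ <- g + rnorm(200, 0, 1); sum((g - mean(g))^2) /
      (sum((g - mean(g))^2) + sum((t_ - g)^2))
  }))
  noisy <- mean(replicate(50, {
    t_ <- g + rnorm(200, 0, 4); sum((g - mean(g))^2) /
      (sum((g - mean(g))^2) + sum((t_ - g)^2))
  }))
  expect_gt(clean, noisy)
})

test_that("Bland-Altman bias and limits match hand computation", {
  ident <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(ident$bias, ident$sd_diff, ident$loa_lower, ident$loa_upper),
               c(0, 0, 0, 0))

  ba <- bland_altman(c(0, 0, 0), c(1, 2, 3))  # differences -1, -2, -3
  expect_equal(ba$bias, -2)
  expect_equal(ba$sd_diff, 1)
  expect_equal(c(ba$loa_lower, ba$loa_upper), c(-3.96, -0.04), tolerance = 1e-12)
  ba2 <- bland_altman(c(0, 0, 0), c(1, 2, 3), multiplier = 2)
  expect_equal(c(ba2$loa_lower, ba2$loa_upper), c(-4, 0), tolerance = 1e-12)

  expect_equal(ba$data$difference, c(-1, -2, -3))
  expect_equal(ba$data$average, c(0.5, 1, 1.5))
  expect_true(ba$loa_lower <= ba$bias && ba$bias <= ba$loa_upper)
  expect_error(bland_altman(1:2, 2:3), ">= 3")
})

test_that("paired difference test matches the t distribution", {
  pt <- paired_diff_test(c(0, 0, 0), c(1, 2, 3))
  expect_equal(pt$mean_diff, -2)
  expect_equal(pt$t_stat, -2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(pt$t_stat, -3.464, tolerance = 1e-3)
  expect_equal(pt$df, 2)
  expect_equal(pt$p_value, 0.0742, tolerance = 1e-3)

  sym <- paired_diff_test(c(-1, 0, 1), c(0, 0, 0))
  expect_equal(sym$t_stat, 0)
  expect_equal(sym$p_value, 1)
  expect_error(paired_diff_test(1:3, 1:3), "degenerate")
})

test_that("ICC precision sample sizes follow the planning formula", {
  expect_identical(icc_sample_size(0.70, 0.20, k = 2), 101L)
  expect_identical(icc_sample_size(0.70, 0.20, k = 3), 68L)
  rhos <- seq(0.05, 0.95, by = 0.05)
  sizes <- vapply(rhos, icc_sample_size, integer(1), ci_width = 0.20, k = 2)
  expect_true(all(diff(sizes) <= 0))          # monotone decrease in rho
  expect_lte(icc_sample_size(0.999, 0.20, k = 2), 2L)
  expect_error(icc_sample_size(1.2, 0.2))
  expect_error(icc_sample_size(0.7, 0))
  expect_error(icc_sample_size(0.7, 0.2, k = 1))
})

test_that("qualitative agreement labels are annotation-only bands", {
  expect_identical(agreement_label(c(0.3, 0.6, 0.8, 0.95)),
                   c("poor", "moderate", "good", "excellent"))
  expect_identical(agreement_label(0.6, bands = c(low = 0.5, high = 1)), "high")
})

test_that("incomplete pairs are dropped with a reported count", {
  expect_message(cp <- complete_pairs(c(1, NA, 3, 4), c(1, 2, NA, 4)),
                 "2 incomplete")
  expect_equal(cp$x, c(1, 4))
  expect_equal(cp$dropped, 2)
})
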