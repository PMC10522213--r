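#' Descriptive summary of a numeric variable
#'
#' Mean, standard deviation (n-1 denominator), minimum, median (average of
#' the central order statistics for even n) and maximum, as used in
#' cohort-characteristics tables.
#'
#' @param x Numeric vector, no missing values, length >= 1.
#' @return An object of class `"descriptive_summary"`: a list with
#'   `mean`, `sd`, `minimum`, `median`, `maximum`, `n`.
#' @export
describe <- function(x) {
  if (length(x) == 0L) stop("empty input", call. = FALSE)
  if (anyNA(x)) stop("missing values not allowed; drop them upstream", call. = FALSE)
  if (length(x) == 1L) warning("single observation: variance undefined, SD reported as 0",
                               call. = FALSE)
  out <- list(mean = mean(x),
              sd = if (length(x) == 1L) 0 else stats::sd(x),
              minimum = min(x), median = stats::median(x), maximum = max(x),
              n = length(x))
  class(out) <- "descriptive_summary"
  out
}

#' @export
print.descriptive_summary <- function(x, digits = 4, ...) {
  cat(sprintf("n = %d  mean = %s  sd = %s  min = %s  median = %s  max = %s\n",
              x$n, format(x$mean, digits = digits), format(x$sd, digits = digits),
              format(x$minimum, digits = digits), format(x$median, digits = digits),
              format(x$maximum, digits = digits)))
  invisible(x)
}

#' Drop incomplete pairs
#'
#' Pairwise deletion: pairs with any missing member are removed and the
#' number dropped is reported via a message (never silently).
#'
#' @param x,y Numeric vectors of equal length.
#' @return List with complete `x`, `y` and the `dropped` count.
#' @export
complete_pairs <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  dropped <- sum(!keep)
  if (dropped > 0L) message(sprintf("dropped %d incomplete pair(s)", dropped))
  list(x = x[keep], y = y[keep], dropped = dropped)
}

#' Pearson product-moment correlation
#'
#' Thin wrapper around [stats::cor()] that enforces the preconditions of
#' the agreement analyses: at least 3 pairs and positive variance in both
#' vectors (a zero-variance vector has no defined correlation).
#'
#' @param x,y Numeric vectors of equal length, n >= 3, no missing values.
#' @return Correlation in \[-1, 1\].
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need >= 3 complete pairs", call. = FALSE)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  stats::cor(x, y)
}

# n-denominator (biased) moments used by Lin's estimator
moments_n <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  list(mx = mx, my = my,
       sx2 = mean((x - mx)^2), sy2 = mean((y - my)^2),
       sxy = mean((x - mx) * (y - my)))
}

#' Lin's concordance correlation coefficient
#'
#' Measures agreement of paired measurements with the identity line,
#' combining precision (Pearson r) with an accuracy (bias-correction)
#' factor C_b:
#' \deqn{\hat\rho_c = \frac{2 s_{xy}}{s_x^2 + s_y^2 + (\bar x - \bar y)^2}}
#' with n-denominator moments, following Lin's original estimator. The
#' confidence interval uses the Fisher z-transform with Lin's corrected
#' asymptotic variance, back-transformed to the coefficient scale.
#'
#' @param x,y Numeric vectors of paired measurements (n >= 3, positive
#'   variance each). The coefficient is symmetric in x and y.
#' @param alpha Two-sided CI level is 1 - alpha (default 0.05).
#' @param labels Optional length-2 character vector naming the methods.
#' @return An object of class `c("lin_ccc", "agreement_estimate")`: a list
#'   with `estimate`, `ci_lower`, `ci_upper`, `n`, `alpha`, and
#'   `components` (`pearson_r`, `bias_correction`).
#' @references Lin LI (1989) A concordance correlation coefficient to
#'   evaluate reproducibility. Biometrics 45:255-268 (and the 2000 erratum
#'   for the variance of the z-transformed estimate).
#' @examples
#' lin_ccc(c(1, 2, 3), c(2, 3, 4))$estimate  # 4/7
#' @export
lin_ccc <- function(x, y, alpha = 0.05, labels = c("x", "y")) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need >= 3 complete pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values: use complete_pairs() first", call. = FALSE)
  m <- moments_n(x, y)
  if (m$sx2 == 0 || m$sy2 == 0) stop("zero variance: CCC undefined", call. = FALSE)
  n <- length(x)
  rho_c <- 2 * m$sxy / (m$sx2 + m$sy2 + (m$mx - m$my)^2)
  r <- m$sxy / sqrt(m$sx2 * m$sy2)
  cb <- rho_c / r

  if (abs(rho_c) >= 1 - .Machine$double.eps^0.5) {
    warning("degenerate CCC of +/-1: CI returned as a point mass", call. = FALSE)
    ci <- c(rho_c, rho_c)
  } else {
    u <- (m$mx - m$my) / sqrt(sqrt(m$sx2) * sqrt(m$sy2))
    var_z <- ((1 - r^2) * rho_c^2 / ((1 - rho_c^2) * r^2) +
                4 * rho_c^3 * (1 - rho_c) * u^2 / (r * (1 - rho_c^2)^2) -
                2 * rho_c^4 * u^4 / (r^2 * (1 - rho_c^2)^2)) / (n - 2)
    # collinear-but-biased samples cancel the variance exactly; guard the
    # tiny negative residue that cancellation leaves behind
    var_z <- max(var_z, 0)
    z <- atanh(rho_c)
    hw <- stats::qnorm(1 - alpha / 2) * sqrt(var_z)
    ci <- tanh(c(z - hw, z + hw))
  }
  structure(list(estimate = rho_c, ci_lower = ci[1], ci_upper = ci[2],
                 n = n, alpha = alpha, statistic = "lin_ccc",
                 labels = labels,
                 components = list(pearson_r = r, bias_correction = cb)),
            class = c("lin_ccc", "agreement_estimate"))
}

#' St. Laurent gold-standard agreement coefficient
#'
#' Agreement of an approximate method with a gold standard. With deviations
#' D_i = test_i - gold_i,
#' \deqn{\hat r_G = \frac{S_{GG}}{S_{GG} + S_{DD}},\quad
#'   S_{GG} = \sum_i (g_i - \bar g)^2,\ S_{DD} = \sum_i D_i^2.}
#' S_DD is left uncentred so that a systematic bias penalises agreement.
#' Under this estimator the coefficient lies in \[0, 1\]; 1 means the test
#' method reproduces the gold standard exactly. The CI is a seeded
#' percentile bootstrap over subject pairs.
#'
#' @param gold Gold-standard measurements (positive variance required).
#' @param test Test-method measurements, aligned with `gold`.
#' @param alpha CI level is 1 - alpha.
#' @param boot Number of bootstrap resamples (default 2000).
#' @param labels Optional method names, `(test, gold)` order.
#' @return An object of class `c("st_laurent", "agreement_estimate")`.
#' @references St-Laurent RT (1998) Evaluating agreement with a gold
#'   standard in method comparison studies. Biometrics 54:537-545.
#' @examples
#' st_laurent(gold = c(1, 2, 3), test = c(2, 3, 4), boot = 200)$estimate  # 0.4
#' @export
st_laurent <- function(gold, test, alpha = 0.05, boot = 2000,
                       labels = c("test", "gold")) {
  if (length(gold) != length(test) || length(gold) < 3L)
    stop("need >= 3 aligned pairs", call. = FALSE)
  if (anyNA(gold) || anyNA(test)) stop("missing values: use complete_pairs() first", call. = FALSE)
  if (stats::var(gold) == 0) stop("zero gold-standard variance", call. = FALSE)
  n <- length(gold)
  est <- st_laurent_point(gold, test)
  bs <- replicate(boot, {
    i <- sample.int(n, n, replace = TRUE)
    st_laurent_point(gold[i], test[i])
  })
  bs <- bs[is.finite(bs)]
  ci <- unname(stats::quantile(bs, c(alpha / 2, 1 - alpha / 2), type = 7))
  # percentile CIs need not bracket the plug-in estimate exactly, but keep
  # the invariant ci_lower <= estimate <= ci_upper by clamping
  ci <- c(min(ci[1], est), max(ci[2], est))
  structure(list(estimate = est, ci_lower = ci[1], ci_upper = ci[2],
                 n = n, alpha = alpha, statistic = "st_laurent",
                 labels = labels, boot = boot),
            class = c("st_laurent", "agreement_estimate"))
}

st_laurent_point <- function(gold, test) {
  sgg <- sum((gold - mean(gold))^2)
  sdd <- sum((test - gold)^2)
  sgg / (sgg + sdd)
}

#' @export
print.agreement_estimate <- function(x, digits = 3, ...) {
  kind <- switch(x$statistic,
                 lin_ccc = "Lin concordance correlation",
                 st_laurent = "St. Laurent gold-standard agreement",
                 x$statistic)
  cat(sprintf("%s: %s vs %s\n", kind, x$labels[1], x$labels[2]))
  cat(sprintf("  estimate %s  %d%% CI [%s, %s]  n = %d\n",
              format(round(x$estimate, digits), nsmall = digits),
              round(100 * (1 - x$alpha)),
              format(round(x$ci_lower, digits), nsmall = digits),
              format(round(x$ci_upper, digits), nsmall = digits), x$n))
  if (!is.null(x$components))
    cat(sprintf("  Pearson r %s  bias-correction C_b %s\n",
                format(round(x$components$pearson_r, digits), nsmall = digits),
                format(round(x$components$bias_correction, digits), nsmall = digits)))
  invisible(x)
}

#' Qualitative label for an agreement coefficient
#'
#' Annotation only (never used in computation): maps a coefficient to a
#' verbal band. The default bands follow common usage — below 0.50 "poor",
#' 0.50-0.75 "satisfactory/moderate", 0.75-0.90 "good", above 0.90
#' "excellent" — and can be replaced wholesale.
#'
#' @param estimate Coefficient value(s).
#' @param bands Named numeric vector of ascending upper bounds.
#' @return Character vector of labels.
#' @export
agreement_label <- function(estimate,
                            bands = c(poor = 0.50, moderate = 0.75,
                                      good = 0.90, excellent = 1.00)) {
  bands <- sort(bands)
  names(bands)[pmin(findInterval(estimate, bands, left.open = TRUE) + 1L,
                    length(bands))]
}

#' Bland-Altman analysis of paired measurements
#'
#' Computes the mean difference (bias), SD of differences, and limits of
#' agreement bias +/- multiplier * SD. The bias CI uses the t distribution;
#' LoA CIs use the standard approximation
#' SE = sd_diff * sqrt(1/n + multiplier^2 / (2(n-1))).
#' The per-pair (average, difference) table is returned for plotting.
#'
#' @param x,y Paired measurements; differences are x - y.
#' @param multiplier LoA multiplier (1.96 by convention; set 2 to reproduce
#'   "two SDs from the mean" figure captions).
#' @param alpha CI level is 1 - alpha.
#' @param labels Optional method names.
#' @return An object of class `"bland_altman"`: bias, sd_diff, `loa_lower`,
#'   `loa_upper`, CIs, `n` and a `data` data frame (average, difference).
#' @examples
#' ba <- bland_altman(c(1, 2, 3), c(2, 4, 6))
#' ba$bias
#' @export
bland_altman <- function(x, y, multiplier = 1.96, alpha = 0.05,
                         labels = c("x", "y")) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need >= 3 complete pairs", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values: use complete_pairs() first", call. = FALSE)
  d <- x - y
  n <- length(d)
  bias <- mean(d)
  sd_d <- stats::sd(d)
  loa <- bias + c(-1, 1) * multiplier * sd_d
  tq <- stats::qt(1 - alpha / 2, df = n - 1)
  se_bias <- sd_d / sqrt(n)
  se_loa <- sd_d * sqrt(1 / n + multiplier^2 / (2 * (n - 1)))
  structure(list(bias = bias, sd_diff = sd_d,
                 loa_lower = loa[1], loa_upper = loa[2],
                 multiplier = multiplier, alpha = alpha, n = n,
                 ci_bias = bias + c(-1, 1) * tq * se_bias,
                 ci_loa_lower = loa[1] + c(-1, 1) * tq * se_loa,
                 ci_loa_upper = loa[2] + c(-1, 1) * tq * se_loa,
                 labels = labels,
                 data = data.frame(average = (x + y) / 2, difference = d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 3, ...) {
  cat(sprintf("Bland-Altman: %s - %s (n = %d)\n", x$labels[1], x$labels[2], x$n))
  cat(sprintf("  bias %s (%d%% CI %s to %s), SD of differences %s\n",
              format(round(x$bias, digits)), round(100 * (1 - x$alpha)),
              format(round(x$ci_bias[1], digits)), format(round(x$ci_bias[2], digits)),
              format(round(x$sd_diff, digits))))
  cat(sprintf("  limits of agreement (bias +/- %g SD): %s to %s\n",
              x$multiplier, format(round(x$loa_lower, digits)),
              format(round(x$loa_upper, digits))))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$data$average, x$data$difference,
                 xlab = sprintf("average of %s and %s", x$labels[1], x$labels[2]),
                 ylab = sprintf("%s - %s", x$labels[1], x$labels[2]), ...)
  graphics::abline(h = c(x$bias, x$loa_lower, x$loa_upper),
                   lty = c(1, 2, 2))
  invisible(x)
}

#' Paired-difference t test
#'
#' Two-sided paired t test of x - y, refusing the degenerate case of
#' zero-variance differences (for which the t statistic is undefined).
#'
#' @param x,y Paired measurements, n >= 3.
#' @return A list with `mean_diff`, `sd_diff`, `t_stat`, `df`, `p_value`, `n`.
#' @export
paired_diff_test <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("need >= 3 complete pairs", call. = FALSE)
  d <- x - y
  if (stats::sd(d) == 0)
    stop("degenerate test: differences have zero variance", call. = FALSE)
  ht <- stats::t.test(d)
  list(mean_diff = mean(d), sd_diff = stats::sd(d),
       t_stat = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, n = length(d))
}

#' Sample size for ICC precision
#'
#' Number of subjects needed so that the 95% (or 1 - alpha) confidence
#' interval for an intraclass correlation of k raters has width at most
#' `ci_width`, by Bonett's precision formula
#' \deqn{n = \lceil 1 + 8 z^2 (1-\rho)^2 (1+(k-1)\rho)^2 / (k(k-1) w^2) \rceil.}
#' Rounded up: planned sample sizes are conservative integers.
#'
#' @param rho Planning value of the ICC, in (0, 1).
#' @param ci_width Target CI width w (> 0).
#' @param k Number of raters/measurements per subject (>= 2).
#' @param alpha CI level is 1 - alpha.
#' @return Integer sample size.
#' @references Bonett DG (2002) Sample size requirements for estimating
#'   intraclass correlations with desired precision. Stat Med 21:1331-1335.
#' @examples
#' icc_sample_size(0.70, 0.20, k = 2)  # 101
#' @export
icc_sample_size <- function(rho, ci_width, k = 2, alpha = 0.05) {
  if (!is.finite(rho) || rho <= 0 || rho >= 1) stop("rho must be in (0, 1)", call. = FALSE)
  if (!is.finite(ci_width) || ci_width <= 0) stop("ci_width must be > 0", call. = FALSE)
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  z <- stats::qnorm(1 - alpha / 2)
  as.integer(ceiling(1 + 8 * z^2 * (1 - rho)^2 * (1 + (k - 1) * rho)^2 /
                       (k * (k - 1) * ci_width^2)))
}
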