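#' Configuration for the synthetic cohort generator
#'
#' Defines the distributional conditions of a simulated method-comparison
#' cohort of adult women: age, anthropometry, the joint distribution of the
#' six skinfold sites, and how the BIA and DXA %BF panels relate to the
#' skinfold-derived latent %BF. The defaults emulate a cohort of Brazilian
#' women of reproductive age (n = 90, ages ~18-38, wide BMI range) in which
#' DXA reads about 5.4 %BF above the 3-site skinfold estimate and BIA sits
#' level with it.
#'
#' Skinfold sites are drawn from a truncated multivariate normal (every
#' site > 2 mm) with an exchangeable correlation (default 0.6) between
#' sites. The subscapular site is carried in the record but used by no
#' equation; its marginals are a chosen realistic default. BIA and DXA are
#' generated as latent (the subject's 3-site %BF) + offset + Gaussian
#' noise, which reproduces the mean ordering DXA > BIA ~ 3-site > 4-site
#' without asserting unavailable joint structure.
#'
#' @param n_subjects Cohort size (>= 3).
#' @param seed Integer seed; the generator is fully reproducible from it.
#' @param age `c(mean, sd, min, max)` in years (truncated normal).
#' @param height_m `c(mean, sd, min, max)` in metres.
#' @param bmi `c(mean, sd, min, max)` in kg/m^2; weight is derived as
#'   BMI * height^2.
#' @param site_means_mm,site_sds_mm Named vectors over the six schema sites.
#' @param site_correlation Either a single exchangeable correlation or a
#'   6x6 positive-definite correlation matrix.
#' @param dxa_offset,bia_offset Additive %BF offsets relative to the latent
#'   3-site %BF.
#' @param dxa_noise_sd,bia_noise_sd Gaussian noise SDs of the two panels.
#' @return An object of class `"cohort_config"` (validated list).
#' @export
cohort_config <- function(n_subjects = 90,
                          seed = 1L,
                          age = c(mean = 29.06, sd = 4.96, min = 18.33, max = 37.77),
                          height_m = c(mean = 1.61, sd = 0.05, min = 1.46, max = 1.75),
                          bmi = c(mean = 26.86, sd = 5.92, min = 16.08, max = 41.43),
                          site_means_mm = c(tsf_mm = 20.13, ssf_mm = 20.00,
                                            sisf_mm = 25.07, aasf_mm = 17.64,
                                            mtsf_mm = 35.08, csf_mm = 22.28),
                          site_sds_mm = c(tsf_mm = 6.81, ssf_mm = 7.50,
                                          sisf_mm = 10.04, aasf_mm = 7.92,
                                          mtsf_mm = 10.39, csf_mm = 7.42),
                          site_correlation = 0.6,
                          dxa_offset = 5.4, bia_offset = 0,
                          dxa_noise_sd = 6.8, bia_noise_sd = 4.0) {
  if (!is.numeric(n_subjects) || n_subjects < 3)
    stop("n_subjects must be >= 3", call. = FALSE)
  stopifnot(identical(names(site_means_mm), all_sites) ||
              setequal(names(site_means_mm), all_sites))
  site_means_mm <- site_means_mm[all_sites]
  site_sds_mm <- site_sds_mm[all_sites]
  if (any(site_sds_mm <= 0)) stop("site SDs must be > 0", call. = FALSE)
  if (any(c(dxa_noise_sd, bia_noise_sd) < 0))
    stop("method noise SDs must be >= 0", call. = FALSE)
  if (is.matrix(site_correlation)) {
    R <- site_correlation
  } else {
    R <- matrix(site_correlation, 6, 6)
    diag(R) <- 1
  }
  if (!isSymmetric(unname(R)) || any(eigen(R, symmetric = TRUE,
                                           only.values = TRUE)$values <= 1e-10))
    stop("site correlation matrix must be symmetric positive definite",
         call. = FALSE)
  structure(list(n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 age = age, height_m = height_m, bmi = bmi,
                 site_means_mm = site_means_mm, site_sds_mm = site_sds_mm,
                 site_correlation = R,
                 dxa_offset = dxa_offset, bia_offset = bia_offset,
                 dxa_noise_sd = dxa_noise_sd, bia_noise_sd = bia_noise_sd),
            class = "cohort_config")
}

#' Cohort conditions for the observer-reliability sample
#'
#' A [cohort_config()] preset for the smaller reliability cohort (default
#' n = 59): slightly leaner and narrower than the full method-comparison
#' cohort, with 3-site marginals matching its first observer pass.
#'
#' @param n_subjects Cohort size.
#' @param seed Integer seed.
#' @param ... Further overrides passed to [cohort_config()].
#' @export
reliability_cohort_config <- function(n_subjects = 59, seed = 1L, ...) {
  cohort_config(n_subjects = n_subjects, seed = seed,
                age = c(mean = 29.28, sd = 4.79, min = 19.78, max = 37.75),
                height_m = c(mean = 1.62, sd = 0.05, min = 1.51, max = 1.75),
                bmi = c(mean = 25.91, sd = 4.90, min = 16.08, max = 36.84),
                site_means_mm = c(tsf_mm = 19.45, ssf_mm = 20.00,
                                  sisf_mm = 25.59, aasf_mm = 17.64,
                                  mtsf_mm = 34.37, csf_mm = 22.28),
                site_sds_mm = c(tsf_mm = 6.46, ssf_mm = 7.50,
                                sisf_mm = 11.20, aasf_mm = 7.92,
                                mtsf_mm = 9.89, csf_mm = 7.42),
                ...)
}

rtruncnorm1 <- function(n, mean, sd, lo, hi, max_iter = 1000L) {
  out <- numeric(0)
  it <- 0L
  while (length(out) < n) {
    it <- it + 1L
    if (it > max_iter) stop("truncation rejection cap exceeded", call. = FALSE)
    draw <- stats::rnorm(n, mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic method-comparison cohort
#'
#' Draws a seeded cohort under a [cohort_config()]: ages, heights and BMI
#' from truncated normals, skinfold sites from a truncated multivariate
#' normal (rejection sampling, every site > 2 mm, capped iterations), then
#' computes the two skinfold %BF estimates through the prediction
#' equations and generates the BIA and DXA panels as latent + offset +
#' noise.
#'
#' @param config A [cohort_config()].
#' @return An object of class `"cohort"`: a list with
#'   \describe{
#'     \item{subjects}{data frame in the subject CSV schema
#'       (`subject_id`, `age_years`, `weight_kg`, `height_m`, six `*_mm`
#'       sites, `bia_pbf`, `dxa_pbf`).}
#'     \item{panels}{data frame of per-subject %BF by the four methods
#'       (`sf_jpw`, `sf_pet`, `bia`, `dxa`) plus the two skinfold sums.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_subjects

  age <- rtruncnorm1(n, config$age["mean"], config$age["sd"],
                     config$age["min"], config$age["max"])
  height <- rtruncnorm1(n, config$height_m["mean"], config$height_m["sd"],
                        config$height_m["min"], config$height_m["max"])
  bmi_v <- rtruncnorm1(n, config$bmi["mean"], config$bmi["sd"],
                       config$bmi["min"], config$bmi["max"])
  weight <- bmi_v * height^2

  D <- diag(config$site_sds_mm)
  Sigma <- D %*% config$site_correlation %*% D
  sites <- matrix(NA_real_, n, 6, dimnames = list(NULL, all_sites))
  filled <- 0L
  it <- 0L
  while (filled < n) {
    it <- it + 1L
    if (it > 1000L) stop("truncation rejection cap exceeded", call. = FALSE)
    draw <- MASS::mvrnorm(n, mu = config$site_means_mm, Sigma = Sigma)
    ok <- apply(draw, 1, function(r) all(r > 2 & r < 100))
    take <- min(sum(ok), n - filled)
    if (take > 0) {
      sites[(filled + 1):(filled + take), ] <- draw[which(ok)[seq_len(take)], ]
      filled <- filled + take
    }
  }

  profile <- as.data.frame(sites)
  sum_jpw <- skinfold_sum(profile, "JPW")
  sum_pet <- skinfold_sum(profile, "PET")
  pbf_jpw <- siri(density_jpw(sum_jpw, age))
  pbf_pet <- siri(density_pet(sum_pet, age))
  dxa <- pbf_jpw + config$dxa_offset + stats::rnorm(n, 0, config$dxa_noise_sd)
  bia <- pbf_jpw + config$bia_offset + stats::rnorm(n, 0, config$bia_noise_sd)

  id <- sprintf("S%03d", seq_len(n))
  subjects <- data.frame(subject_id = id, age_years = age,
                         weight_kg = weight, height_m = height,
                         profile, bia_pbf = bia, dxa_pbf = dxa,
                         stringsAsFactors = FALSE)
  panels <- data.frame(subject_id = id,
                       sum_sf_jpw = sum_jpw, sum_sf_pet = sum_pet,
                       sf_jpw = pbf_jpw, sf_pet = pbf_pet,
                       bia = bia, dxa = dxa, stringsAsFactors = FALSE)
  structure(list(subjects = subjects, panels = panels, config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects (seed %d)\n",
              nrow(x$subjects), x$config$seed))
  invisible(x)
}

#' Configuration for synthetic observer sessions
#'
#' Error model for the three-pass (A1, B, A2) triplicate skinfold design:
#' every individual caliper reading gets iid Gaussian noise
#' (`intra_noise_sd_mm`); observer B additionally reads with a fixed
#' site-specific bias (`inter_bias_mm`) plus a subject-level random
#' deviation (`inter_subject_sd_mm`) capturing between-subject variation in
#' how the second observer locates and pinches each site. Defaults are
#' calibrated so the suprailiac site shows the largest inter-observer bias
#' (about +3.7 mm) and the triceps the best inter-observer agreement,
#' with intra-observer agreement near-perfect.
#'
#' @param intra_noise_sd_mm Named per-site reading noise SDs (>= 0).
#' @param inter_bias_mm Named per-site fixed biases of observer B.
#' @param inter_subject_sd_mm Named per-site SDs of observer B's
#'   subject-level deviation (>= 0).
#' @param seed Integer seed.
#' @return An object of class `"observer_error_config"`.
#' @export
observer_error_config <- function(
    intra_noise_sd_mm = c(triceps = 0.5, suprailiac = 0.5, medial_thigh = 0.5),
    inter_bias_mm = c(triceps = -0.45, suprailiac = 3.68, medial_thigh = 0.19),
    inter_subject_sd_mm = c(triceps = 1.08, suprailiac = 5.08, medial_thigh = 5.59),
    seed = 1L) {
  for (v in list(intra_noise_sd_mm, inter_subject_sd_mm)) {
    if (any(!is.finite(v) | v < 0)) stop("noise SDs must be >= 0", call. = FALSE)
  }
  stopifnot(setequal(names(intra_noise_sd_mm), reliability_sites),
            setequal(names(inter_bias_mm), reliability_sites),
            setequal(names(inter_subject_sd_mm), reliability_sites))
  structure(list(intra_noise_sd_mm = intra_noise_sd_mm[reliability_sites],
                 inter_bias_mm = inter_bias_mm[reliability_sites],
                 inter_subject_sd_mm = inter_subject_sd_mm[reliability_sites],
                 seed = as.integer(seed)),
            class = "observer_error_config")
}

# schema column for each reliability site
site_schema_col <- c(triceps = "tsf_mm", suprailiac = "sisf_mm",
                     medial_thigh = "mtsf_mm")

#' Generate synthetic triplicate observer sessions
#'
#' For each subject in `subjects`, produces the three passes A1, B, A2 over
#' the triceps, suprailiac and medial thigh sites. Each reading is the
#' subject's true site value plus pass-level observer error (zero for A1
#' and A2; fixed bias + subject-level deviation for B) plus iid reading
#' noise. Readings are redrawn if non-positive (rare; capped).
#'
#' @param subjects A subject data frame (e.g. `generate_cohort()$subjects`)
#'   with the `tsf_mm`, `sisf_mm`, `mtsf_mm` columns as true site values.
#' @param config An [observer_error_config()].
#' @return Long-format sessions data frame: `subject_id`, `observer_pass`,
#'   `site`, `reading1_mm`, `reading2_mm`, `reading3_mm`.
#' @export
generate_observer_sessions <- function(subjects, config = observer_error_config()) {
  stopifnot(inherits(config, "observer_error_config"))
  missing_cols <- setdiff(unname(site_schema_col), names(subjects))
  if (length(missing_cols))
    stop(sprintf("subjects table missing site column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  set.seed(config$seed)
  n <- nrow(subjects)

  draw_triple <- function(center, sd) {
    r <- stats::rnorm(3, center, sd)
    for (it in seq_len(100)) {
      bad <- r <= 0
      if (!any(bad)) return(r)
      r[bad] <- stats::rnorm(sum(bad), center, sd)
    }
    stop("could not draw positive readings (center too close to zero)",
         call. = FALSE)
  }

  rows <- vector("list", n * 9L)
  k <- 0L
  for (i in seq_len(n)) {
    # subject-level deviation of observer B, one per site
    b_dev <- stats::rnorm(3, 0, config$inter_subject_sd_mm)
    for (s in seq_along(reliability_sites)) {
      site <- reliability_sites[s]
      true_val <- subjects[[site_schema_col[[site]]]][i]
      for (pass in observer_passes) {
        center <- true_val +
          if (pass == "B") config$inter_bias_mm[[site]] + b_dev[s] else 0
        center <- max(center, 0.5)  # keep the reading model in-range
        r <- draw_triple(center, config$intra_noise_sd_mm[[site]])
        k <- k + 1L
        rows[[k]] <- data.frame(subject_id = subjects$subject_id[i],
                                observer_pass = pass, site = site,
                                reading1_mm = r[1], reading2_mm = r[2],
                                reading3_mm = r[3], stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Population concordance correlation for a bivariate normal
#'
#' Closed-form value that the sample Lin CCC converges to under a
#' bivariate normal with means mu1, mu2, SDs sigma1, sigma2 and
#' correlation rho:
#' \deqn{\rho_c = \frac{2\rho\sigma_1\sigma_2}
#'   {\sigma_1^2+\sigma_2^2+(\mu_1-\mu_2)^2}.}
#' Used as the parameter-recovery oracle in tests.
#'
#' @param mu1,mu2 Population means.
#' @param sigma1,sigma2 Population SDs (> 0).
#' @param rho Population correlation in \[-1, 1\].
#' @export
closed_form_ccc <- function(mu1, mu2, sigma1, sigma2, rho) {
  if (any(c(sigma1, sigma2) <= 0)) stop("sigmas must be > 0", call. = FALSE)
  if (abs(rho) > 1) stop("|rho| must be <= 1", call. = FALSE)
  2 * rho * sigma1 * sigma2 / (sigma1^2 + sigma2^2 + (mu1 - mu2)^2)
}

#' Population St. Laurent coefficient for the additive gold-standard model
#'
#' Under test = gold + bias + noise with gold SD `sigma_g`, noise SD
#' `sigma_d` and mean bias `delta`, the sample coefficient converges to
#' sigma_g^2 / (sigma_g^2 + sigma_d^2 + delta^2).
#'
#' @param sigma_g Gold-standard SD (> 0).
#' @param sigma_d Deviation noise SD (>= 0).
#' @param delta Mean bias.
#' @export
closed_form_st_laurent <- function(sigma_g, sigma_d, delta = 0) {
  if (sigma_g <= 0) stop("sigma_g must be > 0", call. = FALSE)
  if (sigma_d < 0) stop("sigma_d must be >= 0", call. = FALSE)
  sigma_g^2 / (sigma_g^2 + sigma_d^2 + delta^2)
}
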