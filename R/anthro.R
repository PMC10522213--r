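#' Skinfold sites used by each prediction protocol
#'
#' Column names follow the subject CSV schema: `tsf_mm` (triceps),
#' `ssf_mm` (subscapular), `sisf_mm` (suprailiac), `aasf_mm`
#' (average axillary), `mtsf_mm` (medial thigh), `csf_mm` (medial calf).
#' The subscapular site is part of the measurement record but is not used
#' by either implemented equation.
#'
#' @format A named list with elements `JPW` and `PET`, each a character
#'   vector of required column names.
#' @export
protocol_sites <- list(
  JPW = c("tsf_mm", "sisf_mm", "mtsf_mm"),
  PET = c("aasf_mm", "sisf_mm", "mtsf_mm", "csf_mm")
)

all_sites <- c("tsf_mm", "ssf_mm", "sisf_mm", "aasf_mm", "mtsf_mm", "csf_mm")

check_positive <- function(x, name, upper = Inf) {
  if (!is.numeric(x)) stop(sprintf("'%s' must be numeric", name), call. = FALSE)
  bad <- !is.finite(x) | x <= 0 | x > upper
  if (any(bad)) {
    stop(sprintf("'%s' has %d missing/invalid value(s): must be > 0%s",
                 name, sum(bad),
                 if (is.finite(upper)) sprintf(" and <= %g", upper) else ""),
         call. = FALSE)
  }
  invisible(x)
}

#' Sum of skinfolds for a prediction protocol
#'
#' Computes the skinfold sum (ΣSF, mm) entering a body-density equation:
#' triceps + suprailiac + medial thigh for the 3-site Jackson-Pollock-Ward
#' protocol (`"JPW"`), or average axillary + suprailiac + medial thigh +
#' medial calf for the 4-site Petroski protocol (`"PET"`).
#'
#' @param profile A data frame (or named list of equal-length numeric
#'   vectors) holding per-subject site measurements in mm, using the
#'   schema names in [protocol_sites].
#' @param protocol `"JPW"` or `"PET"`.
#' @return Numeric vector of sums in mm, one per subject.
#' @examples
#' skinfold_sum(data.frame(tsf_mm = 20.13, sisf_mm = 25.07, mtsf_mm = 35.08), "JPW")
#' @export
skinfold_sum <- function(profile, protocol = c("JPW", "PET")) {
  protocol <- match.arg(protocol)
  need <- protocol_sites[[protocol]]
  missing_sites <- setdiff(need, names(profile))
  if (length(missing_sites)) {
    stop(sprintf("missing required skinfold site(s) for %s: %s",
                 protocol, paste(missing_sites, collapse = ", ")), call. = FALSE)
  }
  for (s in need) check_positive(profile[[s]], s, upper = 100)
  Reduce(`+`, lapply(need, function(s) as.numeric(profile[[s]])))
}

#' Body density from the 3-site Jackson-Pollock-Ward equation
#'
#' Predicts body density (g/cm^3 scale) for adult women from the sum of the
#' triceps, suprailiac and medial thigh skinfolds and age:
#' D = 1.0994921 - 0.0009929 S + 0.0000023 S^2 - 0.0001392 age.
#' The quadratic is decreasing in S up to its vertex at about 215.9 mm, well
#' above any plausible 3-site sum.
#'
#' @param sum3 Sum of the three skinfolds, mm (> 0).
#' @param age_years Age in years (> 0); fractional years allowed.
#' @return Numeric vector of predicted densities.
#' @seealso [density_pet()], [siri()]
#' @export
density_jpw <- function(sum3, age_years) {
  check_positive(sum3, "sum3")
  check_positive(age_years, "age_years")
  1.0994921 - 0.0009929 * sum3 + 0.0000023 * sum3^2 - 0.0001392 * age_years
}

#' Body density from the 4-site Petroski equation
#'
#' Predicts body density for adult women from the sum of the average
#' axillary, suprailiac, medial thigh and medial calf skinfolds and age:
#' D = 1.19547130 - 0.07513507 log10(S) - 0.00041072 age.
#'
#' @param sum4 Sum of the four skinfolds, mm (> 0; log10 domain).
#' @param age_years Age in years (> 0).
#' @return Numeric vector of predicted densities.
#' @export
density_pet <- function(sum4, age_years) {
  check_positive(sum4, "sum4")
  check_positive(age_years, "age_years")
  1.19547130 - 0.07513507 * log10(sum4) - 0.00041072 * age_years
}

#' Siri two-compartment conversion of body density to percent body fat
#'
#' %BF = 495 / D - 450. Strictly decreasing in density; returns exactly 0 at
#' D = 1.1. Values are returned as computed: very lean inputs can produce
#' negative %BF, which is flagged by [check_percent_fat()] rather than
#' clipped, since clipping would bias downstream agreement statistics.
#'
#' @param density Body density (> 0), e.g. from [density_jpw()].
#' @return Percent body fat.
#' @export
siri <- function(density) {
  check_positive(density, "density")
  495 / density - 450
}

#' Body mass index
#'
#' @param weight_kg Body mass, kg (> 0).
#' @param height_m Stature, m (> 0).
#' @return BMI in kg/m^2.
#' @export
bmi <- function(weight_kg, height_m) {
  check_positive(weight_kg, "weight_kg")
  check_positive(height_m, "height_m")
  weight_kg / height_m^2
}

#' Range checks for derived body-composition quantities
#'
#' Sanity screens used by the pipeline's validation stage. Values outside
#' the plausible window are flagged with a warning and returned unchanged —
#' never altered.
#'
#' `check_density` flags densities outside (0.90, 1.20); `check_percent_fat`
#' flags %BF outside (-10, 80).
#'
#' @param x Numeric vector of densities or %BF values.
#' @param label Label used in the warning message.
#' @return `x`, invisibly, with a logical `flagged` attribute.
#' @export
check_density <- function(x, label = "density") {
  flag_range(x, 0.90, 1.20, label)
}

#' @rdname check_density
#' @export
check_percent_fat <- function(x, label = "percent body fat") {
  flag_range(x, -10, 80, label)
}

flag_range <- function(x, lo, hi, label) {
  flagged <- is.finite(x) & (x <= lo | x >= hi)
  if (any(flagged)) {
    warning(sprintf("%d %s value(s) outside (%g, %g); returned as computed",
                    sum(flagged), label, lo, hi), call. = FALSE)
  }
  attr(x, "flagged") <- flagged
  invisible(x)
}
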