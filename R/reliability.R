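#' Sites required for the observer-reliability analysis
#'
#' The 3-site protocol drives the reliability chain (sum, density, %BF), so
#' each observer pass must include at least triceps, suprailiac and medial
#' thigh. Extra sites present in a session are carried through untouched.
#' @keywords internal
reliability_sites <- c("triceps", "suprailiac", "medial_thigh")

observer_passes <- c("A1", "B", "A2")

#' Average of a triplicate skinfold reading
#'
#' Each observer pass records three caliper readings per site; their
#' arithmetic mean is the value used in all downstream analysis.
#'
#' @param triple Numeric vector of exactly 3 positive readings (mm).
#' @return The mean reading in mm.
#' @export
average_triplicate <- function(triple) {
  if (length(triple) != 3L)
    stop("a triplicate must contain exactly 3 readings", call. = FALSE)
  check_positive(triple, "readings")
  mean(triple)
}

# long sessions table -> per (subject, pass, site) triplicate means
triplicate_means <- function(sessions) {
  need <- c("subject_id", "observer_pass", "site",
            "reading1_mm", "reading2_mm", "reading3_mm")
  missing_cols <- setdiff(need, names(sessions))
  if (length(missing_cols))
    stop(sprintf("sessions table missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  bad_pass <- setdiff(unique(sessions$observer_pass), observer_passes)
  if (length(bad_pass))
    stop(sprintf("unknown observer pass(es): %s", paste(bad_pass, collapse = ", ")),
         call. = FALSE)
  r <- as.matrix(sessions[, c("reading1_mm", "reading2_mm", "reading3_mm")])
  if (any(!is.finite(r) | r <= 0))
    stop("all triplicate readings must be positive and non-missing", call. = FALSE)
  data.frame(subject_id = sessions$subject_id,
             observer_pass = sessions$observer_pass,
             site = sessions$site,
             mean_mm = rowMeans(r),
             stringsAsFactors = FALSE)
}

#' Per-pass derived quantities for one observer session
#'
#' Chains the triplicate site means of one pass through the 3-site sum,
#' the Jackson-Pollock-Ward density equation and the Siri conversion.
#'
#' @param site_means_mm Named numeric vector of triplicate means (mm); must
#'   contain the names in `triceps`, `suprailiac`, `medial_thigh`.
#' @param age_years Subject age in years.
#' @return A list with `sum3_mm`, `density`, `percent_bf`.
#' @export
session_derivatives <- function(site_means_mm, age_years) {
  missing_sites <- setdiff(reliability_sites, names(site_means_mm))
  if (length(missing_sites))
    stop(sprintf("missing site(s): %s", paste(missing_sites, collapse = ", ")),
         call. = FALSE)
  s3 <- sum(site_means_mm[reliability_sites])
  d <- density_jpw(s3, age_years)
  list(sum3_mm = s3, density = d, percent_bf = siri(d))
}

#' Inter- and intra-observer reliability of skinfold measurement
#'
#' Two observers, three passes: observer A measures first (A1), observer B
#' second, observer A again third (A2). Inter-observer agreement
#' (reproducibility) compares A1 with B; intra-observer agreement
#' (repeatability) compares A1 with A2. For each quantity — the three sites'
#' triplicate means, their 3-site sum, and %BF derived through the
#' density chain — Lin's CCC is computed across subjects for both
#' comparisons.
#'
#' Subjects lacking any of the three passes (or any required site) are
#' dropped with a message; at least 3 complete subjects are required.
#'
#' @param sessions Long-format data frame: one row per (subject, pass,
#'   site) with columns `subject_id`, `observer_pass` (A1|B|A2), `site`,
#'   `reading1_mm`, `reading2_mm`, `reading3_mm`.
#' @param subjects Data frame with `subject_id` and `age_years` (shared
#'   across passes; all passes are taken the same day).
#' @param alpha CI level for the CCCs is 1 - alpha.
#' @return An object of class `"reliability_report"`: a data frame with
#'   columns `quantity`, `comparison` (`inter` = A1 vs B, `intra` = A1 vs
#'   A2), `n`, `ccc`, `ci_lower`, `ci_upper`, plus attributes `n_subjects`
#'   and `n_dropped`.
#' @export
reliability_analysis <- function(sessions, subjects, alpha = 0.05) {
  tm <- triplicate_means(sessions)
  if (!all(c("subject_id", "age_years") %in% names(subjects)))
    stop("subjects table needs columns subject_id, age_years", call. = FALSE)

  ids <- unique(tm$subject_id)
  complete <- vapply(ids, function(id) {
    sub <- tm[tm$subject_id == id, ]
    all(vapply(observer_passes, function(p) {
      all(reliability_sites %in% sub$site[sub$observer_pass == p])
    }, logical(1))) && id %in% subjects$subject_id
  }, logical(1))
  dropped <- sum(!complete)
  if (dropped > 0L)
    message(sprintf("dropped %d subject(s) with incomplete passes", dropped))
  ids <- ids[complete]
  if (length(ids) < 3L)
    stop("fewer than 3 subjects with all three complete passes", call. = FALSE)

  ages <- subjects$age_years[match(ids, subjects$subject_id)]

  # quantity matrix per pass: rows subjects, cols quantities
  quantity_matrix <- function(pass) {
    t(vapply(seq_along(ids), function(i) {
      sub <- tm[tm$subject_id == ids[i] & tm$observer_pass == pass, ]
      sm <- stats::setNames(sub$mean_mm, sub$site)[reliability_sites]
      der <- session_derivatives(sm, ages[i])
      c(sm, sum_sf = der$sum3_mm, percent_bf = der$percent_bf)
    }, numeric(5)))
  }
  qm <- lapply(stats::setNames(observer_passes, observer_passes), quantity_matrix)
  quantities <- c(reliability_sites, "sum_sf", "percent_bf")

  rows <- list()
  for (q in seq_along(quantities)) {
    for (cmp in c("inter", "intra")) {
      other <- if (cmp == "inter") "B" else "A2"
      est <- lin_ccc(qm$A1[, q], qm[[other]][, q], alpha = alpha,
                     labels = c("A1", other))
      rows[[length(rows) + 1L]] <- data.frame(
        quantity = quantities[q], comparison = cmp, n = est$n,
        ccc = est$estimate, ci_lower = est$ci_lower, ci_upper = est$ci_upper,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_subjects") <- length(ids)
  attr(out, "n_dropped") <- dropped
  class(out) <- c("reliability_report", "data.frame")
  out
}

#' @export
print.reliability_report <- function(x, digits = 3, ...) {
  cat(sprintf("Observer reliability (%d subjects, %d dropped)\n",
              attr(x, "n_subjects"), attr(x, "n_dropped")))
  cat("  inter = A1 vs B (reproducibility), intra = A1 vs A2 (repeatability)\n")
  df <- as.data.frame(x)
  df$ccc <- round(df$ccc, digits)
  df$ci_lower <- round(df$ci_lower, digits)
  df$ci_upper <- round(df$ci_upper, digits)
  print(df, row.names = FALSE)
  invisible(x)
}
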