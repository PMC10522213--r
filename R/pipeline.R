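subject_schema <- c("subject_id", "age_years", "weight_kg", "height_m",
                    "tsf_mm", "ssf_mm", "sisf_mm", "aasf_mm", "mtsf_mm",
                    "csf_mm", "bia_pbf", "dxa_pbf")

session_schema <- c("subject_id", "observer_pass", "site",
                    "reading1_mm", "reading2_mm", "reading3_mm")

#' Run configuration for the analysis pipeline
#'
#' Collects every statistical option in one place. `reproduction_mode`
#' switches on the settings matching the original figure conventions:
#' limits of agreement at 2 SD (instead of 1.96) and observer pass A1 for
#' the intra-method skinfold values.
#'
#' @param alpha Two-sided CI level is 1 - alpha; must lie in (0, 0.5).
#' @param ba_multiplier Bland-Altman LoA multiplier.
#' @param boot Bootstrap replicates for St. Laurent CIs (>= 100).
#' @param seed Optional integer seed for the bootstrap.
#' @param reproduction_mode Logical; see above.
#' @param paired_test `"t"` (paired t test, default) or `"wilcoxon"`.
#' @return An object of class `"run_config"`.
#' @export
run_config <- function(alpha = 0.05, ba_multiplier = 1.96, boot = 2000,
                       seed = NULL, reproduction_mode = FALSE,
                       paired_test = c("t", "wilcoxon")) {
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 0.5)
    stop("alpha must be in (0, 0.5)", call. = FALSE)
  if (boot < 100) stop("boot must be >= 100", call. = FALSE)
  paired_test <- match.arg(paired_test)
  if (reproduction_mode) ba_multiplier <- 2
  structure(list(alpha = alpha, ba_multiplier = ba_multiplier,
                 boot = as.integer(boot),
                 seed = if (!is.null(seed)) as.integer(seed),
                 reproduction_mode = reproduction_mode,
                 paired_test = paired_test),
            class = "run_config")
}

validate_rows <- function(df, checks) {
  issues <- data.frame(row = integer(), column = character(),
                       problem = character(), stringsAsFactors = FALSE)
  bad <- rep(FALSE, nrow(df))
  for (col in names(checks)) {
    v <- df[[col]]
    miss <- !is.finite(v)
    out <- !miss & !checks[[col]](v)
    for (i in which(miss)) issues[nrow(issues) + 1L, ] <-
        list(i, col, "missing or non-numeric")
    for (i in which(out)) issues[nrow(issues) + 1L, ] <-
        list(i, col, sprintf("out of range (%g)", v[i]))
    bad <- bad | miss | out
  }
  list(bad = bad, issues = issues)
}

#' Read and validate a subject-level CSV
#'
#' Schema (UTF-8, comma-separated, header, dot decimal): `subject_id`,
#' `age_years`, `weight_kg`, `height_m`, the six `*_mm` skinfold sites,
#' `bia_pbf`, `dxa_pbf`. A missing required column is fatal. Rows with
#' missing or out-of-range numeric cells are excluded from analysis and
#' logged with row numbers; a BMI outside 18-39.9 only raises a warning
#' (observed cohorts extend beyond the nominal inclusion window).
#'
#' @param path CSV file path.
#' @return A list with `records` (complete, in-range rows), `issues`
#'   (data frame row/column/problem), and `n_input`.
#' @export
read_subjects <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty subject file", call. = FALSE)
  missing_cols <- setdiff(subject_schema, names(df))
  if (length(missing_cols))
    stop(sprintf("subject CSV missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  num_cols <- setdiff(subject_schema, "subject_id")
  for (col in num_cols) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))

  site_ok <- function(v) v > 0 & v <= 100
  checks <- c(list(age_years = function(v) v > 10 & v < 90,
                   weight_kg = function(v) v > 0,
                   height_m = function(v) v > 1.0 & v < 2.5,
                   bia_pbf = function(v) v > -10 & v < 80,
                   dxa_pbf = function(v) v > -10 & v < 80),
              stats::setNames(rep(list(site_ok), 6), all_sites))
  val <- validate_rows(df, checks)
  records <- df[!val$bad, , drop = FALSE]
  if (nrow(records)) {
    b <- bmi(records$weight_kg, records$height_m)
    n_out <- sum(b < 18 | b > 39.9)
    if (n_out > 0)
      warning(sprintf("%d subject(s) with BMI outside 18-39.9 kg/m^2 (kept)",
                      n_out), call. = FALSE)
  }
  list(records = records, issues = val$issues, n_input = nrow(df))
}

#' Read and validate an observer-sessions CSV
#'
#' Long format, one row per (subject, pass, site): `subject_id`,
#' `observer_pass` (A1|B|A2), `site`, `reading1_mm..reading3_mm`.
#'
#' @param path CSV file path.
#' @return A list with `records`, `issues`, `n_input` as in
#'   [read_subjects()].
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(df) == 0L) stop("empty sessions file", call. = FALSE)
  missing_cols <- setdiff(session_schema, names(df))
  if (length(missing_cols))
    stop(sprintf("sessions CSV missing column(s): %s",
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  for (col in paste0("reading", 1:3, "_mm"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  reading_ok <- function(v) v > 0 & v <= 100
  checks <- stats::setNames(rep(list(reading_ok), 3), paste0("reading", 1:3, "_mm"))
  val <- validate_rows(df, checks)
  bad_pass <- !(df$observer_pass %in% observer_passes)
  for (i in which(bad_pass)) val$issues[nrow(val$issues) + 1L, ] <-
      list(i, "observer_pass", sprintf("unknown pass '%s'", df$observer_pass[i]))
  keep <- !val$bad & !bad_pass
  list(records = df[keep, , drop = FALSE], issues = val$issues, n_input = nrow(df))
}

# the seven inter-method pairs: four Lin comparisons among the indirect
# methods, three gold-standard comparisons against DXA
intermethod_pairs <- list(
  list(x = "sf_jpw", y = "sf_pet", stat = "lin_ccc", label = "%BF JPW vs PET"),
  list(x = "sum_sf_jpw", y = "sum_sf_pet", stat = "lin_ccc", label = "Sum SF JPW vs PET"),
  list(x = "sf_jpw", y = "bia", stat = "lin_ccc", label = "%BF JPW vs BIA"),
  list(x = "sf_pet", y = "bia", stat = "lin_ccc", label = "%BF PET vs BIA"),
  list(x = "sf_jpw", y = "dxa", stat = "st_laurent", label = "%BF JPW vs DXA"),
  list(x = "sf_pet", y = "dxa", stat = "st_laurent", label = "%BF PET vs DXA"),
  list(x = "bia", y = "dxa", stat = "st_laurent", label = "%BF BIA vs DXA"))

panels_from_subjects <- function(subjects) {
  sum_jpw <- skinfold_sum(subjects, "JPW")
  sum_pet <- skinfold_sum(subjects, "PET")
  d_jpw <- check_density(density_jpw(sum_jpw, subjects$age_years), "JPW density")
  d_pet <- check_density(density_pet(sum_pet, subjects$age_years), "PET density")
  data.frame(subject_id = subjects$subject_id,
             sum_sf_jpw = sum_jpw, sum_sf_pet = sum_pet,
             density_jpw = as.numeric(d_jpw), density_pet = as.numeric(d_pet),
             sf_jpw = as.numeric(check_percent_fat(siri(as.numeric(d_jpw)), "%BF (JPW)")),
             sf_pet = as.numeric(check_percent_fat(siri(as.numeric(d_pet)), "%BF (PET)")),
             bia = subjects$bia_pbf, dxa = subjects$dxa_pbf,
             stringsAsFactors = FALSE)
}

#' Inter-method agreement analysis
#'
#' The full method-comparison analysis over a validated subject table:
#' descriptive statistics for every variable, paired-difference tests of
#' each indirect method against DXA (differences reported as method - DXA,
#' so underestimation appears as a negative mean), Lin's CCC for the four
#' comparisons among indirect methods, the St. Laurent coefficient (gold =
#' DXA) for the three DXA-referenced comparisons, and a Bland-Altman
#' summary for all seven pairs.
#'
#' @param subjects Validated subject data frame (see [read_subjects()]).
#' @param config A [run_config()].
#' @return An object of class `"intermethod_report"` with elements
#'   `descriptives`, `paired_tests`, `agreement`, `bland_altman` (named
#'   list), `panels`, `n`, `config`.
#' @export
run_intermethod <- function(subjects, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  cc <- stats::complete.cases(subjects[, setdiff(subject_schema, "subject_id")])
  if (sum(!cc) > 0)
    message(sprintf("dropped %d incomplete subject(s)", sum(!cc)))
  subjects <- subjects[cc, , drop = FALSE]
  if (nrow(subjects) < 3L) stop("fewer than 3 complete cases", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed)

  panels <- panels_from_subjects(subjects)
  vars <- list(age_years = subjects$age_years, weight_kg = subjects$weight_kg,
               height_m = subjects$height_m,
               bmi_kg_m2 = bmi(subjects$weight_kg, subjects$height_m))
  for (s in all_sites) vars[[s]] <- subjects[[s]]
  for (v in c("sum_sf_jpw", "sum_sf_pet", "density_jpw", "density_pet",
              "sf_jpw", "sf_pet", "bia", "dxa")) vars[[v]] <- panels[[v]]
  descriptives <- do.call(rbind, lapply(names(vars), function(nm) {
    d <- describe(vars[[nm]])
    data.frame(variable = nm, n = d$n, mean = d$mean, sd = d$sd,
               minimum = d$minimum, median = d$median, maximum = d$maximum,
               stringsAsFactors = FALSE)
  }))

  test_fun <- function(x, y) {
    if (stats::sd(x - y) == 0) {
      # degenerate (e.g. noise-free synthetic data): no test statistic exists
      return(data.frame(mean_diff = mean(x - y), sd_diff = 0,
                        statistic = NA_real_, df = NA_real_,
                        p_value = NA_real_))
    }
    if (config$paired_test == "t") {
      pt <- paired_diff_test(x, y)
      data.frame(mean_diff = pt$mean_diff, sd_diff = pt$sd_diff,
                 statistic = pt$t_stat, df = pt$df, p_value = pt$p_value)
    } else {
      w <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)
      data.frame(mean_diff = mean(x - y), sd_diff = stats::sd(x - y),
                 statistic = unname(w$statistic), df = NA_real_,
                 p_value = w$p.value)
    }
  }
  paired_tests <- do.call(rbind, lapply(c("sf_jpw", "sf_pet", "bia"), function(m) {
    cbind(data.frame(comparison = sprintf("%s - dxa", m),
                     stringsAsFactors = FALSE),
          test_fun(panels[[m]], panels$dxa))
  }))

  agreement <- list()
  ba <- list()
  for (p in intermethod_pairs) {
    x <- panels[[p$x]]; y <- panels[[p$y]]
    est <- if (p$stat == "lin_ccc") {
      lin_ccc(x, y, alpha = config$alpha, labels = c(p$x, p$y))
    } else {
      st_laurent(gold = y, test = x, alpha = config$alpha, boot = config$boot,
                 labels = c(p$x, p$y))
    }
    agreement[[length(agreement) + 1L]] <- data.frame(
      statistic_kind = p$stat, pair_label = p$label, n = est$n,
      estimate = est$estimate, ci_lower = est$ci_lower,
      ci_upper = est$ci_upper,
      label = agreement_label(est$estimate), stringsAsFactors = FALSE)
    ba[[p$label]] <- bland_altman(x, y, multiplier = config$ba_multiplier,
                                  alpha = config$alpha, labels = c(p$x, p$y))
    ba[[p$label]]$data <- cbind(subject_id = panels$subject_id,
                                ba[[p$label]]$data)
  }

  structure(list(descriptives = descriptives, paired_tests = paired_tests,
                 agreement = do.call(rbind, agreement), bland_altman = ba,
                 panels = panels, n = nrow(subjects), config = config),
            class = "intermethod_report")
}

#' @export
print.intermethod_report <- function(x, digits = 3, ...) {
  cat(sprintf("Inter-method agreement analysis (n = %d complete cases)\n\n", x$n))
  cat("Paired differences vs DXA:\n")
  pt <- x$paired_tests
  pt[, -1] <- round(pt[, -1], digits)
  print(pt, row.names = FALSE)
  cat("\nAgreement coefficients:\n")
  ag <- x$agreement
  ag[, c("estimate", "ci_lower", "ci_upper")] <-
    round(ag[, c("estimate", "ci_lower", "ci_upper")], digits)
  print(ag, row.names = FALSE)
  invisible(x)
}

#' Observer-reliability analysis with session descriptives
#'
#' Wraps [reliability_analysis()] and adds the per-pass descriptive table
#' (each site's triplicate mean, the 3-site sum and derived %BF and
#' density, by observer pass).
#'
#' @param sessions Validated long sessions data frame.
#' @param subjects Subject table with `subject_id`, `age_years`.
#' @param config A [run_config()].
#' @return An object of class `"reliability_run"`: list with
#'   `descriptives`, `report`, `n`, `config`.
#' @export
run_reliability <- function(sessions, subjects, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  report <- reliability_analysis(sessions, subjects, alpha = config$alpha)
  tm <- triplicate_means(sessions)
  ids <- unique(tm$subject_id)
  rows <- list()
  for (pass in observer_passes) {
    per_subject <- lapply(ids, function(id) {
      sub <- tm[tm$subject_id == id & tm$observer_pass == pass, ]
      if (!all(reliability_sites %in% sub$site)) return(NULL)
      age <- subjects$age_years[match(id, subjects$subject_id)]
      if (!is.finite(age)) return(NULL)
      sm <- stats::setNames(sub$mean_mm, sub$site)[reliability_sites]
      der <- session_derivatives(sm, age)
      c(sm, sum_sf = der$sum3_mm, density = der$density,
        percent_bf = der$percent_bf)
    })
    per_subject <- do.call(rbind, per_subject)
    for (q in colnames(per_subject)) {
      d <- describe(per_subject[, q])
      rows[[length(rows) + 1L]] <- data.frame(
        quantity = q, observer_pass = pass, n = d$n, mean = d$mean, sd = d$sd,
        minimum = d$minimum, median = d$median, maximum = d$maximum,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(descriptives = do.call(rbind, rows), report = report,
                 n = attr(report, "n_subjects"), config = config),
            class = "reliability_run")
}

#' @export
print.reliability_run <- function(x, ...) {
  print(x$report, ...)
  invisible(x)
}

#' Write pipeline reports to disk
#'
#' Emits the CSV artifacts of a report plus a plain-text run manifest
#' (software version, seed, options, complete-case n). Output is
#' deterministic: rerunning with the same inputs and seed reproduces the
#' files byte for byte.
#'
#' For an inter-method report: `descriptives.csv`,
#' `paired_differences.csv`, `agreement.csv`, one
#' `bland_altman_<pair>.csv` of per-subject (average, difference) points
#' per pair plus `bland_altman_lines.csv` with the bias/LoA lines.
#' For a reliability run: `reliability_descriptives.csv`,
#' `reliability_agreement.csv`.
#'
#' @param report An `intermethod_report` or `reliability_run`.
#' @param outdir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_reports <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir) || file.access(outdir, 2) != 0)
    stop(sprintf("output directory not writable: %s", outdir), call. = FALSE)
  UseMethod("write_reports")
}

write_csv0 <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  path
}

manifest_lines <- function(report, extra = character()) {
  cfg <- report$config
  c(sprintf("package: bcagree %s", as.character(utils::packageVersion("bcagree"))),
    sprintf("n_complete_cases: %d", report$n),
    sprintf("alpha: %g", cfg$alpha),
    sprintf("ba_multiplier: %g", cfg$ba_multiplier),
    sprintf("bootstrap_replicates: %d", cfg$boot),
    sprintf("seed: %s", if (is.null(cfg$seed)) "none" else cfg$seed),
    sprintf("reproduction_mode: %s", cfg$reproduction_mode),
    extra)
}

#' @export
write_reports.intermethod_report <- function(report, outdir) {
  paths <- c(
    write_csv0(report$descriptives, file.path(outdir, "descriptives.csv")),
    write_csv0(report$paired_tests, file.path(outdir, "paired_differences.csv")),
    write_csv0(report$agreement, file.path(outdir, "agreement.csv")))
  lines <- list()
  for (label in names(report$bland_altman)) {
    ba <- report$bland_altman[[label]]
    slug <- gsub("[^a-z0-9]+", "_", tolower(label))
    paths <- c(paths, write_csv0(ba$data,
                                 file.path(outdir, sprintf("bland_altman_%s.csv", slug))))
    lines[[label]] <- data.frame(pair_label = label, n = ba$n, bias = ba$bias,
                                 sd_diff = ba$sd_diff, loa_lower = ba$loa_lower,
                                 loa_upper = ba$loa_upper,
                                 multiplier = ba$multiplier,
                                 stringsAsFactors = FALSE)
  }
  paths <- c(paths, write_csv0(do.call(rbind, lines),
                               file.path(outdir, "bland_altman_lines.csv")))
  mf <- file.path(outdir, "manifest.txt")
  writeLines(manifest_lines(report, "stage: intermethod"), mf)
  invisible(c(paths, mf))
}

#' @export
write_reports.reliability_run <- function(report, outdir) {
  paths <- c(
    write_csv0(report$descriptives,
               file.path(outdir, "reliability_descriptives.csv")),
    write_csv0(as.data.frame(report$report),
               file.path(outdir, "reliability_agreement.csv")))
  mf <- file.path(outdir, "manifest.txt")
  writeLines(manifest_lines(report,
                            c("stage: reliability",
                              sprintf("n_dropped: %d", attr(report$report, "n_dropped")))),
             mf)
  invisible(c(paths, mf))
}
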