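# Independently coded oracles: definition-level arithmetic kept separate
# from the package's own code paths.

# body-density equations re-evaluated term by term
oracle_density_jpw <- function(s, age) {
  terms <- c(1.0994921, -0.0009929 * s, 0.0000023 * s * s, -0.0001392 * age)
  sum(terms)
}

oracle_density_pet <- function(s, age) {
  1.19547130 - 0.07513507 * (log(s) / log(10)) - 0.00041072 * age
}

oracle_siri <- function(d) 495 / d - 450

# Lin CCC from the definition of the four moments, accumulated by loops
oracle_ccc <- function(x, y) {
  n <- length(x)
  mx <- 0; my <- 0
  for (i in seq_len(n)) { mx <- mx + x[i] / n; my <- my + y[i] / n }
  sx2 <- 0; sy2 <- 0; sxy <- 0
  for (i in seq_len(n)) {
    sx2 <- sx2 + (x[i] - mx)^2 / n
    sy2 <- sy2 + (y[i] - my)^2 / n
    sxy <- sxy + (x[i] - mx) * (y[i] - my) / n
  }
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# St. Laurent coefficient from its definition
oracle_st_laurent <- function(gold, test) {
  sgg <- 0
  for (g in gold) sgg <- sgg + (g - mean(gold))^2
  sdd <- 0
  for (i in seq_along(gold)) sdd <- sdd + (test[i] - gold[i])^2
  sgg / (sgg + sdd)
}

# random paired sample with varied location/scale/correlation
random_pair <- function(n = 30) {
  rho <- stats::runif(1, -0.95, 0.95)
  z1 <- stats::rnorm(n)
  z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
  list(x = stats::runif(1, -10, 40) + stats::runif(1, 0.5, 9) * z1,
       y = stats::runif(1, -10, 40) + stats::runif(1, 0.5, 9) * z2)
}

# minimal valid 3-subject session set where every pass equals A1
perfect_sessions <- function(n = 5, seed = 1) {
  set.seed(seed)
  rows <- list()
  for (i in seq_len(n)) {
    for (site in c("triceps", "suprailiac", "medial_thigh")) {
      v <- stats::runif(1, 8, 40)
      for (pass in c("A1", "B", "A2")) {
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = sprintf("S%02d", i), observer_pass = pass, site = site,
          reading1_mm = v, reading2_mm = v, reading3_mm = v,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

subjects_for <- function(sessions) {
  ids <- unique(sessions$subject_id)
  data.frame(subject_id = ids,
             age_years = seq(22, 38, length.out = length(ids)),
             stringsAsFactors = FALSE)
}
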