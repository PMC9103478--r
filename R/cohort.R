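# Synthetic cohort generation from published class-conditional summary
# statistics: truncated-normal numeric features, Bernoulli binary features,
# exact group sizes, optional Gaussian-copula dependence.

#' Truncated-normal helpers
#'
#' `rtruncnorm_inv()` samples by inverse-CDF; `truncated_normal_moments()`
#' returns the exact mean and SD of a normal(mean, sd) restricted to
#' \[lower, upper\]. `sd = 0` denotes a degenerate (constant) value.
#'
#' @param n Number of draws.
#' @param mean,sd Parameters of the parent (untruncated) normal.
#' @param lower,upper Truncation bounds.
#' @return `rtruncnorm_inv()`: numeric vector of draws.
#'   `truncated_normal_moments()`: list with elements `mean` and `sd`.
#' @keywords internal
rtruncnorm_inv <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) abort("`sd` must be >= 0")
  if (sd == 0) return(rep(mean, n))
  plo <- pnorm((lower - mean) / sd)
  phi <- pnorm((upper - mean) / sd)
  qtruncnorm_inv(runif(n), mean, sd, plo, phi)
}

qtruncnorm_inv <- function(u, mean, sd, plo, phi) {
  mean + sd * qnorm(plo + u * (phi - plo))
}

#' @rdname rtruncnorm_inv
#' @export
truncated_normal_moments <- function(mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) abort("`sd` must be >= 0")
  if (sd == 0) return(list(mean = mean, sd = 0))
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  z <- pnorm(b) - pnorm(a)
  if (z <= 0) abort("empty truncation interval")
  da <- dnorm(a)
  db <- dnorm(b)
  m <- mean + sd * (da - db) / z
  ta <- if (is.finite(a)) a * da else 0
  tb <- if (is.finite(b)) b * db else 0
  v <- sd^2 * (1 + (ta - tb) / z - ((da - db) / z)^2)
  list(mean = m, sd = sqrt(max(v, 0)))
}

#' Class-conditional generating distribution for one stone group
#'
#' Bundles the truncated-normal specs of the numeric features and the
#' Bernoulli proportions of the binary features for one stone class
#' (pure uric acid or non-uric acid) in one cohort.
#'
#' @param n Group size (number of patients).
#' @param numeric Named list over `age`, `bmi`, `urine_ph`, `egfr`; each
#'   element a list/vector with `mean`, `sd`, `lower`, `upper`. The mean/SD
#'   are the parameters of the parent normal before truncation.
#' @param binary Named proportions in \[0, 1\] for `male`, `dm`, `gout`,
#'   `bacteriuria`.
#' @return Object of class `ua_group_distribution`.
#' @export
group_distribution <- function(n, numeric, binary) {
  n <- as.integer(n)
  if (n < 0) abort("`n` must be non-negative")
  need_num <- c("age", "bmi", "urine_ph", "egfr")
  need_bin <- c("male", "dm", "gout", "bacteriuria")
  if (!setequal(names(numeric), need_num)) {
    abort("`numeric` must have entries age, bmi, urine_ph, egfr")
  }
  if (!setequal(names(binary), need_bin)) {
    abort("`binary` must have entries male, dm, gout, bacteriuria")
  }
  numeric <- lapply(numeric[need_num], function(spec) {
    spec <- as.list(spec)
    stopifnot(all(c("mean", "sd", "lower", "upper") %in% names(spec)))
    if (spec$sd < 0) abort("numeric `sd` must be >= 0")
    if (spec$lower >= spec$upper) abort("`lower` must be < `upper`")
    spec[c("mean", "sd", "lower", "upper")]
  })
  binary <- unlist(binary[need_bin])
  if (any(binary < 0 | binary > 1)) abort("proportions must lie in [0, 1]")
  structure(list(n = n, numeric = numeric, binary = binary),
            class = "ua_group_distribution")
}

# Physiologic truncation bounds shared by both cohorts.
ua_bounds <- function() {
  list(age = c(18, 95), bmi = c(14, 50), urine_ph = c(4.5, 8), egfr = c(2, 180))
}

num_spec <- function(mean, sd, feature) {
  b <- ua_bounds()[[feature]]
  list(mean = mean, sd = sd, lower = b[1], upper = b[2])
}

#' Default generating specification for study Cohort A or B
#'
#' Returns the class-conditional generating parameters matching the published
#' cohort composition: Cohort A with 146 pure uric acid (UA) and 952 non-UA
#' patients; Cohort B with 3 UA (all male, urine pH constant at 5.0) and 68
#' non-UA patients. Numeric features use the class-conditional means/SDs as
#' parent-normal parameters with physiologic truncation bounds (age
#' \[18, 95\], BMI \[14, 50\], pH \[4.5, 8\], eGFR \[2, 180\]); binary
#' features use the class-conditional proportions.
#'
#' @param cohort `"A"` or `"B"`.
#' @return Object of class `ua_cohort_spec` with elements `name`, `ua_group`
#'   and `non_ua_group`.
#' @examples
#' cohort_spec("A")$ua_group$n # 146
#' @export
cohort_spec <- function(cohort = c("A", "B")) {
  cohort <- arg_match(cohort)
  if (cohort == "A") {
    ua <- group_distribution(
      n = 146,
      numeric = list(age = num_spec(60.44, 12.52, "age"),
                     bmi = num_spec(25.63, 3.80, "bmi"),
                     urine_ph = num_spec(5.51, 0.54, "urine_ph"),
                     egfr = num_spec(55.13, 29.45, "egfr")),
      binary = c(male = 110 / 146, dm = 42 / 146, gout = 14 / 146,
                 bacteriuria = 13 / 146)
    )
    non_ua <- group_distribution(
      n = 952,
      numeric = list(age = num_spec(52.75, 12.69, "age"),
                     bmi = num_spec(25.38, 3.53, "bmi"),
                     urine_ph = num_spec(6.09, 0.77, "urine_ph"),
                     egfr = num_spec(80.14, 29.37, "egfr")),
      binary = c(male = 638 / 952, dm = 122 / 952, gout = 21 / 952,
                 bacteriuria = 164 / 952)
    )
  } else {
    ua <- group_distribution(
      n = 3,
      numeric = list(age = num_spec(56.67, 14.01, "age"),
                     bmi = num_spec(28.77, 6.11, "bmi"),
                     urine_ph = num_spec(5.0, 0, "urine_ph"),
                     egfr = num_spec(65.20, 18.55, "egfr")),
      binary = c(male = 1, dm = 2 / 3, gout = 1 / 3, bacteriuria = 0)
    )
    non_ua <- group_distribution(
      n = 68,
      numeric = list(age = num_spec(54.72, 13.78, "age"),
                     bmi = num_spec(26.80, 4.75, "bmi"),
                     urine_ph = num_spec(6.24, 0.88, "urine_ph"),
                     egfr = num_spec(76.91, 32.07, "egfr")),
      binary = c(male = 41 / 68, dm = 16 / 68, gout = 3 / 68,
                 bacteriuria = 5 / 68)
    )
  }
  structure(list(name = cohort, ua_group = ua, non_ua_group = non_ua),
            class = "ua_cohort_spec")
}

# Feature order used by the copula correlation matrix (CSV column order).
copula_feature_order <- function() {
  c("male", "age", "bmi", "dm", "gout", "bacteriuria", "urine_ph", "egfr")
}

#' Generate one class group of synthetic patients
#'
#' Draws exactly `dist$n` records. By default features are independent within
#' the class: numerics from truncated normals, binaries as Bernoulli draws.
#' An optional Gaussian copula induces rank dependence between features while
#' preserving every marginal.
#'
#' @param dist A [group_distribution()].
#' @param seed Integer seed; the same seed reproduces the group exactly.
#' @param n Override of the group size (used for large-sample checks).
#' @param copula Optional 8x8 Spearman rank-correlation matrix with
#'   rows/columns ordered `male, age, bmi, dm, gout, bacteriuria, urine_ph,
#'   egfr`; `NULL` (default) means independence.
#' @return Tibble with columns `sex, age, bmi, dm, gout, bacteriuria,
#'   urine_ph, egfr` (no label).
#' @export
generate_group <- function(dist, seed = NULL, n = NULL, copula = NULL) {
  stopifnot(inherits(dist, "ua_group_distribution"))
  n <- if (is.null(n)) dist$n else as.integer(n)
  local_seed(seed, {
    u <- copula_uniforms(n, copula)
    num <- lapply(names(dist$numeric), function(f) {
      spec <- dist$numeric[[f]]
      if (spec$sd == 0) return(rep(spec$mean, n))
      plo <- pnorm((spec$lower - spec$mean) / spec$sd)
      phi <- pnorm((spec$upper - spec$mean) / spec$sd)
      qtruncnorm_inv(u[[f]], spec$mean, spec$sd, plo, phi)
    })
    names(num) <- names(dist$numeric)
    bin_feats <- c("male", "dm", "gout", "bacteriuria")
    bin <- lapply(bin_feats, function(f) as.numeric(u[[f]] < dist$binary[[f]]))
    names(bin) <- bin_feats
    tibble(
      sex = bin$male,
      age = num$age,
      bmi = num$bmi,
      dm = bin$dm,
      gout = bin$gout,
      bacteriuria = bin$bacteriuria,
      urine_ph = num$urine_ph,
      egfr = num$egfr
    )
  })
}

# n independent (or copula-coupled) U(0,1) vectors per feature.
copula_uniforms <- function(n, copula) {
  feats <- copula_feature_order()
  if (is.null(copula)) {
    u <- lapply(feats, function(f) runif(n))
  } else {
    copula <- as.matrix(copula)
    stopifnot(nrow(copula) == 8, ncol(copula) == 8)
    # Spearman rho -> Pearson correlation of the Gaussian latent.
    r <- 2 * sin(pi * copula / 6)
    diag(r) <- 1
    cl <- chol(r)
    z <- matrix(rnorm(n * 8), nrow = n) %*% cl
    u <- lapply(seq_len(8), function(j) pnorm(z[, j]))
  }
  names(u) <- feats
  u
}

#' Generate a labelled synthetic cohort
#'
#' Group sizes are exact (not sampled): the UA group receives label 1, the
#' non-UA group label 0, and the rows are shuffled deterministically under
#' the seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed controlling all randomness.
#' @param n_scale Multiplier applied to both group sizes (rounded), for
#'   large-sample moment checks.
#' @param copula Optional Spearman correlation matrix; see [generate_group()].
#' @return Tibble of patient records with a binary `label` column
#'   (1 = pure uric acid stone).
#' @export
generate_cohort <- function(spec, seed = NULL, n_scale = 1, copula = NULL) {
  stopifnot(inherits(spec, "ua_cohort_spec"))
  n_ua <- as.integer(round(spec$ua_group$n * n_scale))
  n_non <- as.integer(round(spec$non_ua_group$n * n_scale))
  local_seed(seed, {
    ua <- generate_group(spec$ua_group, seed = NULL, n = n_ua, copula = copula)
    non <- generate_group(spec$non_ua_group, seed = NULL, n = n_non,
                          copula = copula)
    ua$label <- rep(1, n_ua)
    non$label <- rep(0, n_non)
    out <- bind_rows(ua, non)
    if (nrow(out) > 0) out <- out[sample.int(nrow(out)), ]
    out
  })
}

#' Convenience wrapper: simulate a default study cohort
#'
#' @param cohort `"A"` or `"B"`.
#' @inheritParams generate_cohort
#' @return Labelled cohort tibble; see [generate_cohort()].
#' @examples
#' a <- simulate_cohort("A", seed = 1)
#' table(a$label) # 952 non-UA, 146 UA
#' @export
simulate_cohort <- function(cohort = c("A", "B"), seed = NULL, n_scale = 1,
                            copula = NULL) {
  generate_cohort(cohort_spec(cohort), seed = seed, n_scale = n_scale,
                  copula = copula)
}

#' Split a cohort into training and validation sets
#'
#' The training set receives `floor(fraction * n)` records (the study's 60/40
#' split of 1098 gives 658/440). The default draw is a simple random
#' partition; `stratified = TRUE` preserves the class proportions to within
#' rounding while keeping the same total training size.
#'
#' @param data Labelled cohort (needs a binary `label` column).
#' @param fraction Training fraction in (0, 1); default 0.6.
#' @param seed Integer seed.
#' @param stratified Preserve per-class proportions.
#' @return Named list with tibbles `train` and `validation` forming a
#'   disjoint, exhaustive partition of `data`.
#' @export
split_cohort <- function(data, fraction = 0.6, seed = NULL,
                         stratified = FALSE) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1) {
    abort("`fraction` must lie strictly between 0 and 1")
  }
  data <- as_tibble(data)
  n <- nrow(data)
  n_train <- floor(fraction * n)
  local_seed(seed, {
    if (!stratified) {
      idx <- sample.int(n, n_train)
    } else {
      if (!"label" %in% names(data)) abort("stratified split needs `label`")
      by_class <- split(seq_len(n), data$label)
      raw <- vapply(by_class, length, integer(1)) * fraction
      take <- floor(raw)
      short <- n_train - sum(take)
      if (short > 0) {
        order_frac <- order(raw - floor(raw), decreasing = TRUE)
        take[order_frac[seq_len(short)]] <- take[order_frac[seq_len(short)]] + 1
      }
      idx <- unlist(lapply(seq_along(by_class), function(k) {
        sample(by_class[[k]], take[k])
      }), use.names = FALSE)
    }
    list(train = data[sort(idx), ], validation = data[-sort(idx), ])
  })
}

#' Class-conditional summary of a cohort
#'
#' Per-class sample means/SDs of the numeric features and proportions of the
#' binary features, plus the age-band composition (<=45, 45-65, >65) used as
#' a descriptive validation report.
#'
#' @param data Labelled cohort.
#' @return Named list of tibbles `numeric`, `binary` and `age_bands`.
#' @export
cohort_summary <- function(data) {
  data <- as_tibble(data)
  stopifnot("label" %in% names(data))
  num <- data |>
    tidyr::pivot_longer(all_of(ua_numeric_features()),
                        names_to = "feature", values_to = "value") |>
    group_by(.data$label, .data$feature) |>
    summarise(n = n(), mean = mean(.data$value),
              sd = stats::sd(.data$value), .groups = "drop")
  bin <- data |>
    tidyr::pivot_longer(all_of(ua_binary_features()),
                        names_to = "feature", values_to = "value") |>
    group_by(.data$label, .data$feature) |>
    summarise(n = n(), proportion = mean(.data$value), .groups = "drop")
  bands <- data |>
    mutate(age_band = cut(.data$age, breaks = c(-Inf, 45, 65, Inf),
                          labels = c("<=45", "45-65", ">65"))) |>
    dplyr::count(.data$label, .data$age_band)
  list(numeric = num, binary = bin, age_bands = bands)
}
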