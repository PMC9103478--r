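# Programmatic fixtures shared across the suite.

# Small table of valid random patient records.
make_patients <- function(n, seed = 1, label = NULL) {
  withr::with_seed(seed, {
    out <- tibble::tibble(
      sex = rbinom(n, 1, 0.6),
      age = round(runif(n, 20, 90), 1),
      bmi = round(runif(n, 17, 40), 1),
      dm = rbinom(n, 1, 0.2),
      gout = rbinom(n, 1, 0.1),
      bacteriuria = rbinom(n, 1, 0.15),
      urine_ph = round(runif(n, 4.8, 7.8), 1),
      egfr = round(runif(n, 10, 140), 1)
    )
    if (!is.null(label)) out$label <- label
    out
  })
}

# Linearly separable toy problem routed through the 8-feature template:
# the two classes differ only in urine pH (two well-separated Gaussians).
toy_separable_cohort <- function(n_per_class = 60, seed = 42, gap = 6) {
  withr::with_seed(seed, {
    base <- make_patients(2 * n_per_class, seed = seed + 1)
    base$label <- rep(c(1, 0), each = n_per_class)
    base$urine_ph <- ifelse(base$label == 1,
                            rnorm(2 * n_per_class, 5.0, 0.15),
                            rnorm(2 * n_per_class, 5.0 + gap / 4, 0.15))
    base$urine_ph <- pmin(pmax(base$urine_ph, 4.2), 8.8)
    base
  })
}

# Tiny cohort spec for pipeline smoke tests (~20 patients).
micro_cohort_spec <- function(n_ua = 6, n_non = 14) {
  num <- list(
    age = list(mean = 55, sd = 10, lower = 18, upper = 95),
    bmi = list(mean = 26, sd = 3, lower = 14, upper = 50),
    urine_ph = list(mean = 5.6, sd = 0.5, lower = 4.5, upper = 8),
    egfr = list(mean = 70, sd = 25, lower = 2, upper = 180)
  )
  structure(list(
    name = "micro",
    ua_group = group_distribution(n_ua, num,
                                  c(male = 0.7, dm = 0.3, gout = 0.1,
                                    bacteriuria = 0.1)),
    non_ua_group = group_distribution(n_non, num,
                                      c(male = 0.6, dm = 0.15, gout = 0.05,
                                        bacteriuria = 0.2))
  ), class = "ua_cohort_spec")
}

# Flatten a parameter structure to one numeric vector (for finite differences).
flatten_params <- function(p) {
  c(p$a, p$b, as.vector(p$A1), as.vector(p$A2), p$B2)
}

unflatten_params <- function(v, template) {
  h <- nrow(template$A1)
  a <- v[1:6]
  b <- v[7]
  i <- 7
  A1 <- matrix(v[(i + 1):(i + 8 * h)], nrow = h,
               dimnames = dimnames(template$A1))
  i <- i + 8 * h
  A2 <- matrix(v[(i + 1):(i + 6 * h)], nrow = h)
  i <- i + 6 * h
  B2 <- v[(i + 1):(i + 6)]
  structure(list(a = a, b = b, A1 = A1, A2 = A2, B2 = B2),
            class = "ua_parameters")
}

# Central finite-difference gradient of the weighted BCE.
numeric_gradient <- function(params, x, y, config, w_pos, w_neg, h = 1e-5) {
  v <- flatten_params(params)
  vapply(seq_along(v), function(k) {
    vp <- v; vp[k] <- vp[k] + h
    vm <- v; vm[k] <- vm[k] - h
    lp <- uastone:::ua_loss_grad(unflatten_params(vp, params), x, y, config,
                                 w_pos, w_neg)$loss
    lm <- uastone:::ua_loss_grad(unflatten_params(vm, params), x, y, config,
                                 w_pos, w_neg)$loss
    (lp - lm) / (2 * h)
  }, numeric(1))
}

# Exhaustive Youden search oracle: tries every midpoint/extreme cutoff by
# direct thresholding, smallest cutoff wins ties.
youden_oracle <- function(scores, labels) {
  s <- sort(unique(scores))
  cand <- if (length(s) == 1) s else c(s[1], (s[-1] + s[-length(s)]) / 2)
  cand <- c(cand, Inf)
  best <- -Inf
  best_t <- NA
  for (t in cand) {
    sens <- mean(scores[labels == 1] >= t)
    spec <- mean(scores[labels == 0] < t)
    if (sens + spec - 1 > best + 1e-12) {
      best <- sens + spec - 1
      best_t <- t
    }
  }
  list(cutoff = best_t, j = best)
}

# Pairwise-comparison AUC oracle (brute force, ties one half).
auc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}
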