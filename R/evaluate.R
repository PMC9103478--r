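# ROC analysis, Youden-index cutoff selection, confusion-matrix metrics with
# Wald confidence intervals, DeLong / bootstrap AUC intervals, and the
# random-guess baseline. Scores are oriented so that HIGHER score = more
# likely uric acid; the prediction rule at a cutoff is `score >= cutoff`.

check_two_classes <- function(labels) {
  if (!all(labels %in% c(0, 1))) abort("`labels` must be binary 0/1")
  if (length(unique(labels)) < 2) {
    abort("both classes must be present for ROC analysis")
  }
}

#' ROC curve points
#'
#' One operating point per unique score (decision rule `score >= threshold`)
#' plus both endpoints (-Inf: everything positive; +Inf: nothing positive).
#'
#' @param scores Numeric ranking scores; higher = more likely uric acid.
#' @param labels Binary labels (1 = pure uric acid stone).
#' @return Tibble of class `ua_roc` with columns `threshold`, `sensitivity`,
#'   `specificity`; attributes `n_pos`, `n_neg`.
#' @export
roc_points <- function(scores, labels) {
  if (length(scores) != length(labels)) abort("length mismatch")
  if (any(!is.finite(scores))) abort("`scores` must be finite")
  check_two_classes(labels)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  thr <- c(-Inf, sort(unique(scores)), Inf)
  sens <- vapply(thr, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg < t), numeric(1))
  out <- tibble(threshold = thr, sensitivity = sens, specificity = spec)
  structure(out, class = c("ua_roc", class(out)),
            n_pos = length(pos), n_neg = length(neg))
}

#' Area under the ROC curve (trapezoidal)
#'
#' Trapezoidal area under the ROC curve; numerically identical to the
#' Mann-Whitney U statistic with ties counted one half (see
#' [auc_mann_whitney()], kept as an independent construction for
#' cross-checking).
#'
#' @param x Either a `ua_roc` curve or a numeric score vector.
#' @param labels Binary labels when `x` is a score vector.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(x, labels = NULL) {
  curve <- if (inherits(x, "ua_roc")) x else roc_points(x, labels)
  fpr <- 1 - curve$specificity
  tpr <- curve$sensitivity
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]
  tpr <- tpr[ord]
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' Mann-Whitney AUC
#'
#' Probability that a random positive outscores a random negative, ties
#' counted 1/2. Independent of the trapezoidal construction.
#'
#' @inheritParams roc_points
#' @return AUC in \[0, 1\].
#' @export
auc_mann_whitney <- function(scores, labels) {
  check_two_classes(labels)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Youden-index optimal cutoff
#'
#' Maximizes J = sensitivity + specificity - 1 over all decision rules
#' `score >= t`. Candidate cutoffs are midpoints between adjacent distinct
#' scores (the minimum score for the all-positive rule, +Inf for the
#' none-positive rule); ties in J are broken toward the smallest cutoff,
#' favoring sensitivity.
#'
#' @inheritParams roc_points
#' @return One-row tibble: `cutoff`, `youden_j`, `sensitivity`,
#'   `specificity`.
#' @export
youden_cutoff <- function(scores, labels) {
  check_two_classes(labels)
  s <- sort(unique(scores))
  cand <- if (length(s) == 1) s else c(s[1], (s[-1] + s[-length(s)]) / 2)
  cand <- c(cand, Inf)
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  sens <- vapply(cand, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(cand, function(t) mean(neg < t), numeric(1))
  j <- sens + spec - 1
  k <- which(j >= max(j) - 1e-12)[1] # candidates ascend: first max = smallest cutoff
  tibble(cutoff = cand[k], youden_j = j[k], sensitivity = sens[k],
         specificity = spec[k])
}

#' Confusion counts at a cutoff
#'
#' @inheritParams roc_points
#' @param cutoff Decision threshold; `score >= cutoff` predicts uric acid.
#' @return List of class `ua_confusion`: `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(scores, labels, cutoff) {
  if (!all(labels %in% c(0, 1))) abort("`labels` must be binary 0/1")
  pred <- scores >= cutoff
  structure(list(tp = sum(pred & labels == 1), fp = sum(pred & labels == 0),
                 tn = sum(!pred & labels == 0), fn = sum(!pred & labels == 1)),
            class = "ua_confusion")
}

wald_ci <- function(p, n, z = 1.96) {
  half <- z * sqrt(p * (1 - p) / n)
  c(max(0, p - half), min(1, p + half))
}

wilson_ci <- function(p, n, z = 1.96) {
  denom <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(max(0, centre - half), min(1, centre + half))
}

#' Diagnostic metrics from confusion counts
#'
#' Sensitivity, specificity, PPV, NPV and accuracy (the "overall correction
#' ratio") with 95% confidence intervals — Wald `p +/- 1.96 sqrt(p(1-p)/n)`
#' by default (matching the published intervals), Wilson by flag. A metric
#' with a zero denominator is reported as `NA` (undefined), never as 0.
#'
#' @param counts A `ua_confusion` from [confusion_counts()], or a list with
#'   `tp`, `fp`, `tn`, `fn`.
#' @param ci `"wald"` or `"wilson"`.
#' @param conf_z Normal quantile for the interval (default 1.96 for 95%).
#' @return Tibble with columns `metric`, `estimate`, `conf_low`, `conf_high`,
#'   `n` (the metric's denominator).
#' @export
confusion_metrics <- function(counts, ci = c("wald", "wilson"),
                              conf_z = 1.96) {
  ci <- arg_match(ci)
  ci_fun <- if (ci == "wald") wald_ci else wilson_ci
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (any(c(tp, fp, tn, fn) < 0)) abort("counts must be non-negative")
  one <- function(metric, num, den) {
    if (den == 0) {
      return(tibble(metric = metric, estimate = NA_real_,
                    conf_low = NA_real_, conf_high = NA_real_, n = 0L))
    }
    p <- num / den
    iv <- ci_fun(p, den, conf_z)
    tibble(metric = metric, estimate = p, conf_low = iv[1], conf_high = iv[2],
           n = as.integer(den))
  }
  bind_rows(
    one("sensitivity", tp, tp + fn),
    one("specificity", tn, tn + fp),
    one("ppv", tp, tp + fp),
    one("npv", tn, tn + fn),
    one("accuracy", tp + tn, tp + fp + tn + fn)
  )
}

#' DeLong or bootstrap confidence interval for the AUC
#'
#' DeLong's asymptotic interval by default; a stratified nonparametric
#' bootstrap (percentile) by flag. Both clipped to \[0, 1\].
#'
#' @inheritParams roc_points
#' @param method `"delong"` or `"bootstrap"`.
#' @param conf_z Normal quantile (default 1.96).
#' @param n_boot Bootstrap replicates.
#' @param seed Seed for the bootstrap.
#' @return Named numeric vector `c(low, high)`.
#' @export
auc_ci <- function(scores, labels, method = c("delong", "bootstrap"),
                   conf_z = 1.96, n_boot = 2000, seed = NULL) {
  method <- arg_match(method)
  check_two_classes(labels)
  if (method == "delong") {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    psi <- function(x, y) (x > y) + 0.5 * (x == y)
    v10 <- vapply(pos, function(x) mean(psi(x, neg)), numeric(1))
    v01 <- vapply(neg, function(y) mean(psi(pos, y)), numeric(1))
    a <- mean(v10)
    se <- sqrt(var(v10) / length(pos) + var(v01) / length(neg))
    if (!is.finite(se)) se <- 0
    low <- max(0, a - conf_z * se)
    high <- min(1, a + conf_z * se)
  } else {
    ipos <- which(labels == 1)
    ineg <- which(labels == 0)
    alpha <- 2 * (1 - pnorm(conf_z))
    reps <- local_seed(seed, {
      vapply(seq_len(n_boot), function(r) {
        idx <- c(sample(ipos, replace = TRUE), sample(ineg, replace = TRUE))
        auc_mann_whitney(scores[idx], labels[idx])
      }, numeric(1))
    })
    qs <- quantile(reps, c(alpha / 2, 1 - alpha / 2), names = FALSE)
    low <- max(0, qs[1])
    high <- min(1, qs[2])
  }
  c(low = low, high = high)
}

#' Random-guess predictive-value baseline
#'
#' With 50% sensitivity and 50% specificity the predictive values collapse to
#' the prevalence: PPV = n_pos / n, NPV = 1 - PPV.
#'
#' @param n_pos,n_neg Class sizes.
#' @return One-row tibble with `ppv` and `npv`.
#' @examples
#' random_guess_baseline(59, 381) # ppv 0.1341, npv 0.8659
#' @export
random_guess_baseline <- function(n_pos, n_neg) {
  if (n_pos + n_neg <= 0) abort("empty input")
  prev <- n_pos / (n_pos + n_neg)
  tibble(ppv = prev, npv = 1 - prev)
}

#' Full metrics report at a cutoff
#'
#' Thresholds the scores (`score >= cutoff` predicts uric acid), assembles the
#' confusion counts and delegates to [confusion_metrics()], [roc_auc()] and
#' [auc_ci()].
#'
#' @inheritParams confusion_counts
#' @param ci,auc_method Interval flavors; see [confusion_metrics()] and
#'   [auc_ci()].
#' @param seed Seed for the bootstrap AUC interval, if selected.
#' @return Object of class `ua_metrics`: list with `cutoff`, `counts`,
#'   `metrics` (tibble), `auc`, `auc_ci`, `roc`, `n_pos`, `n_neg`. `tidy()`
#'   returns the metric tibble with the AUC appended.
#' @export
evaluate_at_cutoff <- function(scores, labels, cutoff, ci = "wald",
                               auc_method = "delong", seed = NULL) {
  check_two_classes(labels)
  counts <- confusion_counts(scores, labels, cutoff)
  curve <- roc_points(scores, labels)
  structure(list(
    cutoff = cutoff,
    counts = counts,
    metrics = confusion_metrics(counts, ci = ci),
    auc = roc_auc(curve),
    auc_ci = auc_ci(scores, labels, method = auc_method, seed = seed),
    roc = curve,
    n_pos = sum(labels == 1),
    n_neg = sum(labels == 0)
  ), class = "ua_metrics")
}

#' Evaluate a fitted model on labelled records
#'
#' Scores the records with the model's uric acid probability and evaluates at
#' the Youden-optimal cutoff (default) or at a fixed cutoff such as one
#' carried over from another cohort.
#'
#' @param data Labelled patient records.
#' @param model A fitted `ua_nam`.
#' @param cutoff `"youden"` or a numeric probability cutoff.
#' @param ... Passed to [evaluate_at_cutoff()].
#' @return A `ua_metrics` report.
#' @export
evaluate_model <- function(data, model, cutoff = "youden", ...) {
  data <- validate_patients(data, require_label = TRUE)
  scores <- predict(model, data)
  if (identical(cutoff, "youden")) {
    cutoff <- youden_cutoff(scores, data$label)$cutoff
  }
  evaluate_at_cutoff(scores, data$label, cutoff, ...)
}

#' @export
print.ua_metrics <- function(x, ...) {
  cat(sprintf("Evaluation at cutoff %.4g (%d positive / %d negative)\n",
              x$cutoff, x$n_pos, x$n_neg))
  cat(sprintf("  AUC %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$auc_ci[["low"]],
              x$auc_ci[["high"]]))
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    cat(sprintf("  %-12s %.3f (%.3f-%.3f)\n", m$metric[i], m$estimate[i],
                m$conf_low[i], m$conf_high[i]))
  }
  invisible(x)
}

#' @method tidy ua_metrics
#' @export
tidy.ua_metrics <- function(x, ...) {
  bind_rows(
    x$metrics,
    tibble(metric = "auc", estimate = x$auc, conf_low = x$auc_ci[["low"]],
           conf_high = x$auc_ci[["high"]], n = x$n_pos + x$n_neg)
  )
}

#' @method glance ua_metrics
#' @export
glance.ua_metrics <- function(x, ...) {
  wide <- setNames(x$metrics$estimate, x$metrics$metric)
  tibble(cutoff = x$cutoff, auc = x$auc,
         sensitivity = wide[["sensitivity"]],
         specificity = wide[["specificity"]],
         ppv = wide[["ppv"]], npv = wide[["npv"]],
         accuracy = wide[["accuracy"]])
}
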