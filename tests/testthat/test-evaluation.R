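# ROC analysis, Youden cutoffs, confusion metrics with Wald intervals,
# DeLong/bootstrap AUC intervals, random-guess baseline.

test_that("ROC points have the required endpoints and monotone sensitivity", {
  scores <- c(0.1, 0.4, 0.35, 0.8)
  labels <- c(0, 0, 1, 1)
  curve <- roc_points(scores, labels)
  expect_equal(curve$sensitivity[1], 1) # permissive extreme
  expect_equal(curve$specificity[1], 0)
  expect_equal(curve$sensitivity[nrow(curve)], 0) # strict extreme
  expect_equal(curve$specificity[nrow(curve)], 1)
  expect_true(all(diff(curve$sensitivity) <= 0))
  expect_true(all(diff(curve$specificity) >= 0))
  # perfectly separated scores pass through (sens 1, spec 1)
  perf <- roc_points(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1))
  expect_true(any(perf$sensitivity == 1 & perf$specificity == 1))
  # all-identical scores give the degenerate two-corner curve
  deg <- roc_points(rep(0.7, 6), c(1, 0, 1, 0, 0, 0))
  expect_true(all(deg$sensitivity %in% c(0, 1) & deg$specificity %in% c(0, 1)))
  expect_error(roc_points(1:3, c(1, 1, 1)), "both classes")
})

test_that("trapezoidal AUC matches the pairwise oracle on the worked example", {
  scores <- c(0.1, 0.4, 0.35, 0.8)
  labels <- c(0, 0, 1, 1)
  expect_equal(roc_auc(scores, labels), 0.75, tolerance = 1e-12)
  expect_equal(auc_oracle(scores, labels), 0.75)
  expect_equal(roc_auc(c(1, 2, 3), c(0, 0, 1)), 1)
  # constant scores: tie convention gives 0.5
  expect_equal(roc_auc(rep(1, 10), rep(c(0, 1), 5)), 0.5, tolerance = 1e-12)
})

test_that("trapezoidal AUC equals Mann-Whitney on random tied instances", {
  withr::with_seed(101, {
    for (r in 1:300) {
      n <- sample(4:30, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # many ties
      a1 <- roc_auc(scores, labels)
      a2 <- auc_mann_whitney(scores, labels)
      expect_lt(abs(a1 - a2), 1e-12)
    }
  })
})

test_that("Youden cutoff maximizes J, breaking ties toward sensitivity", {
  scores <- c(0.1, 0.4, 0.35, 0.8)
  labels <- c(0, 0, 1, 1)
  yc <- youden_cutoff(scores, labels)
  orc <- youden_oracle(scores, labels)
  expect_equal(yc$youden_j, 0.5)
  expect_equal(orc$j, 0.5)
  expect_equal(yc$cutoff, orc$cutoff)
  # smallest-threshold tie-break: the midpoint below the lowest positive
  expect_equal(yc$cutoff, (0.1 + 0.35) / 2)
  expect_equal(yc$sensitivity, 1)
  # perfect separation: midpoint of the gap, J = 1
  yc2 <- youden_cutoff(c(1, 2, 10, 11), c(0, 0, 1, 1))
  expect_equal(yc2$youden_j, 1)
  expect_equal(yc2$cutoff, 6)
  # all scores equal: J = 0
  expect_equal(youden_cutoff(rep(2, 6), c(1, 0, 1, 0, 0, 1))$youden_j, 0)
})

test_that("Youden cutoff equals the exhaustive-search oracle on random instances", {
  withr::with_seed(202, {
    for (r in 1:300) {
      n <- sample(4:30, 1)
      labels <- c(0, 1, rbinom(n - 2, 1, 0.4))
      scores <- round(runif(n), sample(1:2, 1))
      got <- youden_cutoff(scores, labels)
      want <- youden_oracle(scores, labels)
      expect_equal(got$cutoff, want$cutoff)
      expect_equal(got$youden_j, want$j, tolerance = 1e-12)
    }
  })
})

test_that("confusion metrics reproduce brute-force counting and handle zeros", {
  withr::with_seed(303, {
    scores <- runif(50)
    labels <- rbinom(50, 1, 0.3)
    cutoff <- 0.4
    cc <- confusion_counts(scores, labels, cutoff)
    expect_equal(cc$tp, sum(scores >= cutoff & labels == 1))
    expect_equal(cc$fn, sum(scores < cutoff & labels == 1))
    expect_equal(cc$tp + cc$fn, sum(labels == 1))
    expect_equal(cc$tn + cc$fp, sum(labels == 0))
    m <- confusion_metrics(cc)
    expect_equal(m$estimate[m$metric == "accuracy"],
                 mean((scores >= cutoff) == labels))
    expect_true(all(m$conf_low <= m$estimate & m$estimate <= m$conf_high))
    expect_true(all(m$conf_low >= 0 & m$conf_high <= 1))
  })
  # perfect classification
  perfect <- confusion_metrics(list(tp = 7, fp = 0, tn = 13, fn = 0))
  expect_equal(perfect$estimate, rep(1, 5))
  # zero denominator -> undefined, not zero
  nopos <- confusion_metrics(list(tp = 0, fp = 0, tn = 10, fn = 0))
  expect_true(is.na(nopos$estimate[nopos$metric == "sensitivity"]))
  expect_true(is.na(nopos$estimate[nopos$metric == "ppv"]))
})

test_that("Wilson intervals are available by flag and differ from Wald", {
  m_wald <- confusion_metrics(list(tp = 3, fp = 6, tn = 62, fn = 0))
  m_wilson <- confusion_metrics(list(tp = 3, fp = 6, tn = 62, fn = 0),
                                ci = "wilson")
  sens_wald <- m_wald[m_wald$metric == "sensitivity", ]
  sens_wilson <- m_wilson[m_wilson$metric == "sensitivity", ]
  expect_equal(sens_wald$conf_low, 1) # Wald degenerates at p = 1
  expect_lt(sens_wilson$conf_low, 1) # Wilson does not
  expect_equal(sens_wald$estimate, sens_wilson$estimate)
})

test_that("DeLong interval contains the AUC and approximates the bootstrap", {
  # perfect separation: degenerate (1, 1)
  ci <- auc_ci(c(1, 2, 10, 11), c(0, 0, 1, 1))
  expect_equal(unname(ci), c(1, 1))
  withr::with_seed(404, {
    scores <- c(rnorm(300, 1), rnorm(100, 2))
    labels <- rep(c(0, 1), c(300, 100))
  })
  a <- roc_auc(scores, labels)
  dl <- auc_ci(scores, labels, method = "delong")
  expect_true(dl[["low"]] <= a && a <= dl[["high"]])
  bs <- auc_ci(scores, labels, method = "bootstrap", seed = 7, n_boot = 2000)
  expect_lt(max(abs(dl - bs)), 0.02)
})

test_that("DeLong interval agrees with the pROC reference implementation", {
  withr::with_seed(505, {
    scores <- c(rnorm(80, 0.8), rnorm(40, 1.6))
    labels <- rep(c(0, 1), c(80, 40))
  })
  got <- auc_ci(scores, labels, method = "delong", conf_z = qnorm(0.975))
  ref <- suppressMessages(
    as.numeric(pROC::ci.auc(pROC::roc(labels, scores, quiet = TRUE),
                            method = "delong"))
  )
  expect_equal(roc_auc(scores, labels), ref[2], tolerance = 1e-12)
  expect_equal(unname(got), ref[c(1, 3)], tolerance = 1e-9)
})

test_that("random-guess baseline equals the prevalence", {
  rg <- random_guess_baseline(59, 381)
  expect_equal(rg$ppv, 59 / 440, tolerance = 1e-12)
  expect_equal(rg$npv, 381 / 440, tolerance = 1e-12)
  expect_equal(unlist(random_guess_baseline(10, 10)), c(ppv = 0.5, npv = 0.5))
  expect_error(random_guess_baseline(0, 0), "empty")
})

test_that("evaluate_at_cutoff thresholds inclusively and matches hand counts", {
  scores <- c(0.2, 0.5, 0.5, 0.9, 0.1, 0.7)
  labels <- c(0, 1, 0, 1, 0, 1)
  r <- evaluate_at_cutoff(scores, labels, 0.5)
  expect_equal(unclass(r$counts)[c("tp", "fp", "tn", "fn")],
               list(tp = 3L, fp = 1L, tn = 2L, fn = 0L))
  # cutoff below the minimum: everything positive
  lo <- evaluate_at_cutoff(scores, labels, 0)
  expect_equal(lo$metrics$estimate[lo$metrics$metric == "sensitivity"], 1)
  expect_equal(lo$metrics$estimate[lo$metrics$metric == "specificity"], 0)
  # cutoff above the maximum: nothing positive
  hi <- evaluate_at_cutoff(scores, labels, 2)
  expect_equal(hi$metrics$estimate[hi$metrics$metric == "sensitivity"], 0)
  expect_equal(hi$metrics$estimate[hi$metrics$metric == "specificity"], 1)
  td <- tidy(r)
  expect_true("auc" %in% td$metric)
  gl <- glance(r)
  expect_equal(gl$auc, roc_auc(scores, labels))
})

test_that("metrics are invariant under strictly monotone score transforms", {
  withr::with_seed(606, {
    scores <- runif(60)
    labels <- rbinom(60, 1, 0.4)
  })
  trans <- function(s) plogis(3 * s - 1) # strictly increasing
  expect_equal(roc_auc(scores, labels), roc_auc(trans(scores), labels),
               tolerance = 1e-12)
  y1 <- youden_cutoff(scores, labels)
  y2 <- youden_cutoff(trans(scores), labels)
  expect_equal(y1$youden_j, y2$youden_j, tolerance = 1e-12)
  # the selected operating point is the same set of predictions
  expect_equal(scores >= y1$cutoff, trans(scores) >= y2$cutoff)
})

test_that("autoplot produces ggplot objects", {
  curve <- roc_points(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1))
  expect_s3_class(autoplot(curve), "ggplot")
  cohort <- toy_separable_cohort(20, seed = 81)
  m <- fit_ua_model(cohort,
                    training_config = ua_training_config(max_epochs = 5,
                                                         seed = 1))
  expect_s3_class(autoplot(m, cohort), "ggplot")
  expect_s3_class(plot_training_history(m), "ggplot")
})
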