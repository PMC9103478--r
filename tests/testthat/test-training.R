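# Loss, analytic gradients vs finite differences, optimization behaviour.

test_that("weighted binary cross-entropy matches hand arithmetic", {
  expect_equal(weighted_bce(rep(0.5, 6), c(1, 0, 1, 0, 1, 0)), log(2),
               tolerance = 1e-12)
  # hand-computed weighted case
  expect_equal(weighted_bce(c(0.9, 0.2), c(1, 0), w_pos = 2, w_neg = 1),
               (2 * (-log(0.9)) + (-log(0.8))) / 2, tolerance = 1e-12)
  expect_equal(weighted_bce(c(0.9, 0.2), c(1, 0), w_pos = 2, w_neg = 1),
               0.2169323, tolerance = 1e-6)
  # perfect predictions cost only the clipping epsilon
  expect_lt(weighted_bce(c(1, 0, 1), c(1, 0, 1)), 1.1e-7)
  # reduces to standard BCE at unit weights
  p <- c(0.3, 0.8, 0.6)
  y <- c(0, 1, 1)
  expect_equal(weighted_bce(p, y),
               -mean(y * log(p) + (1 - y) * log(1 - p)), tolerance = 1e-12)
  expect_error(weighted_bce(c(0.5, 0.5), 1), "length")
  expect_error(weighted_bce(0.5, 1, w_pos = 0), "positive")
})

test_that("balanced class weights make the constant predictor optimum 0.5", {
  # w_pos = n/(2 n_pos), w_neg = n/(2 n_neg): minimizing over a constant
  # probability lands at 0.5 regardless of imbalance
  for (n_pos in c(5, 20, 90)) {
    y <- rep(c(1, 0), c(n_pos, 100 - n_pos))
    w <- uastone:::resolve_class_weights("balanced", y)
    opt <- optimize(function(p) weighted_bce(rep(p, 100), y, w[["pos"]],
                                             w[["neg"]]),
                    interval = c(0.01, 0.99))
    expect_equal(opt$minimum, 0.5, tolerance = 1e-4)
  }
})

test_that("analytic gradients match central finite differences", {
  x_raw <- make_patients(8, seed = 31)
  sc <- fit_scaler(x_raw)
  x <- apply_scaler(sc, encode_features(x_raw))
  y <- c(1, 0, 0, 1, 0, 1, 0, 0)
  for (acts in list(c("relu", "tanh"), c("tanh", "tanh"),
                    c("tanh", "sigmoid"))) {
    cfg <- ua_model_config(hidden_width = 4, hidden_activation = acts[1],
                           output_activation = acts[2])
    p <- init_parameters(cfg, seed = 32)
    got <- uastone:::ua_loss_grad(p, x, y, cfg, w_pos = 1.7, w_neg = 0.8)
    want <- numeric_gradient(p, x, y, cfg, w_pos = 1.7, w_neg = 0.8)
    rel <- sqrt(sum((flatten_params(got$grads) - want)^2)) /
      sqrt(sum(want^2))
    expect_lt(rel, 1e-4)
  }
  # also at the default width (full 293-parameter structure)
  cfg <- ua_model_config()
  p <- init_parameters(cfg, seed = 33)
  got <- uastone:::ua_loss_grad(p, x, y, cfg, 1, 1)
  want <- numeric_gradient(p, x, y, cfg, 1, 1)
  rel <- sqrt(sum((flatten_params(got$grads) - want)^2)) / sqrt(sum(want^2))
  expect_lt(rel, 1e-4)
})

test_that("a linearly separable toy problem is fit to near-perfect AUC", {
  cohort <- toy_separable_cohort(60, seed = 42)
  m <- fit_ua_model(cohort,
                    training_config = ua_training_config(max_epochs = 200,
                                                         patience = 200,
                                                         seed = 9))
  p <- predict(m, cohort)
  expect_gte(roc_auc(p, cohort$label), 0.99)
})

test_that("training is reproducible: identical seeds give identical histories", {
  cohort <- toy_separable_cohort(30, seed = 17)
  sp <- split_cohort(cohort, fraction = 0.6, seed = 1, stratified = TRUE)
  tc <- ua_training_config(max_epochs = 15, seed = 77)
  m1 <- fit_ua_model(sp$train, sp$validation, training_config = tc)
  m2 <- fit_ua_model(sp$train, sp$validation, training_config = tc)
  expect_identical(m1$history, m2$history)
  expect_equal(m1$parameters, m2$parameters, tolerance = 1e-15)
  tc2 <- ua_training_config(max_epochs = 15, seed = 78)
  m3 <- fit_ua_model(sp$train, sp$validation, training_config = tc2)
  expect_false(identical(m1$history, m3$history))
})

test_that("flipping all labels anti-correlates the fitted scores", {
  cohort <- toy_separable_cohort(40, seed = 23)
  tc <- ua_training_config(max_epochs = 60, patience = 60, seed = 5)
  m_pos <- fit_ua_model(cohort, training_config = tc)
  flipped <- cohort
  flipped$label <- 1 - flipped$label
  m_neg <- fit_ua_model(flipped, training_config = tc)
  probe <- make_patients(100, seed = 24)
  probe$urine_ph <- seq(4.6, 7.9, length.out = 100)
  rc <- cor(predict(m_pos, probe), predict(m_neg, probe), method = "spearman")
  expect_lt(rc, 0)
})

test_that("full-batch training loss is non-increasing at a small learning rate", {
  cohort <- toy_separable_cohort(30, seed = 55)
  tc <- ua_training_config(learning_rate = 1e-3, max_epochs = 60,
                           patience = 60, batch_size = nrow(cohort), seed = 3)
  m <- fit_ua_model(cohort, training_config = tc)
  increases <- diff(m$history$train_loss) > 1e-9
  expect_lte(mean(increases), 0.05)
})

test_that("degenerate training inputs raise informative errors", {
  one_class <- make_patients(10, seed = 61, label = rep(1, 10))
  expect_error(fit_ua_model(one_class), "both stone classes")
  no_label <- make_patients(10, seed = 62)
  expect_error(fit_ua_model(no_label), "label")
  # divergence aborts with the epoch in the diagnostic
  cohort <- toy_separable_cohort(20, seed = 63)
  expect_error(
    fit_ua_model(cohort,
                 model_config = ua_model_config(hidden_width = 4,
                                                hidden_activation = "identity",
                                                output_activation = "identity"),
                 training_config = ua_training_config(learning_rate = 1e155,
                                                      max_epochs = 3, seed = 1)),
    "diverged")
})

test_that("augment and broom methods expose the fit in tidy form", {
  cohort <- toy_separable_cohort(25, seed = 71)
  sp <- split_cohort(cohort, fraction = 0.6, seed = 2, stratified = TRUE)
  m <- fit_ua_model(sp$train, sp$validation,
                    training_config = ua_training_config(max_epochs = 10,
                                                         seed = 4))
  td <- tidy(m)
  expect_equal(nrow(td), 7)
  expect_identical(td$term[7], "(Intercept)")
  gl <- glance(m)
  expect_equal(gl$n_parameters, 293L)
  expect_true(gl$val_auc >= 0 && gl$val_auc <= 1)
  au <- augment(m, sp$validation)
  expect_true(all(au$.pred_ua > 0 & au$.pred_ua < 1))
  expect_equal(nrow(au), nrow(sp$validation))
})
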