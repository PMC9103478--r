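# Training: class-weighted binary cross-entropy minimized by Adam, with
# hand-derived backpropagation through the six subnetworks and early stopping
# on validation loss.

#' Class-weighted binary cross-entropy
#'
#' Mean over samples of `-[w_pos * y * log(p) + w_neg * (1 - y) * log(1 - p)]`
#' with predictions clipped to \[eps, 1 - eps\]. Equals the standard
#' cross-entropy when both weights are 1.
#'
#' @param predictions Probabilities of the positive (uric acid) class.
#' @param labels Binary labels (1 = pure uric acid stone).
#' @param w_pos,w_neg Positive / negative class weights (> 0).
#' @param eps Clipping constant (default 1e-7).
#' @return Scalar loss.
#' @examples
#' weighted_bce(rep(0.5, 4), c(1, 0, 1, 0)) # log(2)
#' @export
weighted_bce <- function(predictions, labels, w_pos = 1, w_neg = 1,
                         eps = 1e-7) {
  if (length(predictions) != length(labels)) {
    abort("`predictions` and `labels` must have equal length")
  }
  if (w_pos <= 0 || w_neg <= 0) abort("class weights must be positive")
  if (!all(labels %in% c(0, 1))) abort("`labels` must be binary 0/1")
  p <- pmin(pmax(predictions, eps), 1 - eps)
  mean(-(w_pos * labels * log(p) + w_neg * (1 - labels) * log(1 - p)))
}

#' Training configuration
#'
#' @param learning_rate Adam step size (default 1e-3).
#' @param max_epochs Maximum number of passes over the training data.
#' @param batch_size Mini-batch size (default 32).
#' @param class_weights `"balanced"` for inverse-prevalence weights
#'   `w_pos = n / (2 n_pos)`, `w_neg = n / (2 n_neg)`; or a numeric
#'   `c(pos, neg)` pair; or `"none"`.
#' @param patience Early-stopping patience in epochs on the monitored loss
#'   (validation loss when a validation set is supplied, else training loss).
#' @param seed Master seed for initialization and shuffling.
#' @return Object of class `ua_training_config`.
#' @export
ua_training_config <- function(learning_rate = 1e-3, max_epochs = 500,
                               batch_size = 32, class_weights = "balanced",
                               patience = 25, seed = NULL) {
  if (learning_rate <= 0) abort("`learning_rate` must be > 0")
  if (max_epochs < 1) abort("`max_epochs` must be >= 1")
  if (patience < 0) abort("`patience` must be >= 0")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 class_weights = class_weights,
                 patience = as.integer(patience),
                 seed = seed),
            class = "ua_training_config")
}

resolve_class_weights <- function(spec, labels) {
  n <- length(labels)
  n_pos <- sum(labels == 1)
  n_neg <- n - n_pos
  if (is.character(spec) && identical(spec, "balanced")) {
    c(pos = n / (2 * n_pos), neg = n / (2 * n_neg))
  } else if (is.character(spec) && identical(spec, "none")) {
    c(pos = 1, neg = 1)
  } else if (is.numeric(spec) && length(spec) == 2) {
    c(pos = spec[1], neg = spec[2])
  } else {
    abort("`class_weights` must be \"balanced\", \"none\" or c(pos, neg)")
  }
}

# Loss and analytic gradient of the weighted BCE w.r.t. every parameter.
# Gradients use the unclipped probability (the clip only guards the log in
# the reported loss). Returns list(loss, grads) with grads shaped like params.
ua_loss_grad <- function(params, x, y, config, w_pos = 1, w_neg = 1) {
  fwd <- ua_forward(params, x, config, keep = TRUE)
  n <- length(fwd$f)
  p <- score_to_probability(fwd$f, config)
  loss <- weighted_bce(p, y, w_pos, w_neg)
  sgn <- if (config$probability == "inverse") -1 else 1
  # dL/df per sample
  g <- sgn * (w_neg * (1 - y) * p - w_pos * y * (1 - p)) / n
  act1 <- activation_fns(config$hidden_activation)
  act2 <- activation_fns(config$output_activation)
  grads <- list(a = drop(crossprod(fwd$F, g)), b = sum(g),
                A1 = params$A1 * 0, A2 = params$A2 * 0, B2 = rep(0, 6))
  for (i in 1:6) {
    gz <- g * params$a[i] * act2$grad(fwd$z[, i])        # n
    grads$B2[i] <- sum(gz)
    grads$A2[, i] <- drop(crossprod(fwd$hidden[[i]], gz)) # h
    gpre <- outer(gz, params$A2[, i]) * act1$grad(fwd$pre[[i]]) # n x h
    if (i <= 5) {
      grads$A1[, i] <- drop(crossprod(gpre, fwd$x[, i]))
    } else {
      for (j in 6:8) grads$A1[, j] <- drop(crossprod(gpre, fwd$x[, j]))
    }
  }
  list(loss = loss, grads = grads)
}

adam_init <- function(params) {
  zero <- lapply(params[c("a", "b", "A1", "A2", "B2")], function(p) p * 0)
  list(m = zero, v = zero, t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (k in c("a", "b", "A1", "A2", "B2")) {
    state$m[[k]] <- beta1 * state$m[[k]] + (1 - beta1) * grads[[k]]
    state$v[[k]] <- beta2 * state$v[[k]] + (1 - beta2) * grads[[k]]^2
    mhat <- state$m[[k]] / (1 - beta1^state$t)
    vhat <- state$v[[k]] / (1 - beta2^state$t)
    params[[k]] <- params[[k]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

new_ua_nam <- function(parameters, model_config, scaler, training_config,
                       history, best_epoch, class_weights) {
  structure(list(parameters = parameters, model_config = model_config,
                 scaler = scaler, training_config = training_config,
                 history = history, best_epoch = best_epoch,
                 class_weights = class_weights),
            class = "ua_nam")
}

#' Fit the additive neural stone classifier
#'
#' Standardizes the numeric features with a scaler fitted on the training
#' records only, initializes the 14h + 13 parameters, and minimizes the
#' class-weighted binary cross-entropy by mini-batch Adam. When a validation
#' set is given, training stops early after `patience` epochs without
#' improvement in validation loss and the best-validation snapshot is
#' returned. All randomness flows from `training_config$seed`.
#'
#' @param train Labelled training records (must contain both classes).
#' @param validation Optional labelled validation records.
#' @param model_config A [ua_model_config()].
#' @param training_config A [ua_training_config()].
#' @return Object of class `ua_nam` with elements `parameters`, `scaler`,
#'   `model_config`, `training_config`, `history` (tibble of per-epoch
#'   training loss, validation loss and validation AUC) and `best_epoch`.
#'   Supports `predict()`, `tidy()`, `glance()`, `augment()` and
#'   `autoplot()`.
#' @export
fit_ua_model <- function(train, validation = NULL,
                         model_config = ua_model_config(),
                         training_config = ua_training_config()) {
  train <- validate_patients(train, require_label = TRUE)
  y <- train$label
  if (length(unique(y)) < 2) {
    abort("training data must contain both stone classes")
  }
  scaler <- fit_scaler(train)
  x <- apply_scaler(scaler, encode_features(train))
  has_val <- !is.null(validation)
  if (has_val) {
    validation <- validate_patients(validation, require_label = TRUE)
    xv <- apply_scaler(scaler, encode_features(validation))
    yv <- validation$label
  }
  w <- resolve_class_weights(training_config$class_weights, y)
  seed <- training_config$seed
  params <- init_parameters(model_config,
                            seed = if (is.null(seed)) NULL else derive_seed(seed, 1))
  state <- adam_init(params)
  n <- nrow(x)
  bs <- min(training_config$batch_size, n)
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- vector("list", training_config$max_epochs)
  wait <- 0L

  run_epochs <- function() {
    for (epoch in seq_len(training_config$max_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1, n, by = bs)) {
        idx <- ord[start:min(start + bs - 1, n)]
        lg <- ua_loss_grad(params, x[idx, , drop = FALSE], y[idx],
                           model_config, w[["pos"]], w[["neg"]])
        if (!is.finite(lg$loss)) {
          abort(sprintf("training diverged at epoch %d (non-finite loss)", epoch))
        }
        upd <- adam_step(params, lg$grads, state, training_config$learning_rate)
        params <<- upd$params
        state <<- upd$state
      }
      if (any(!vapply(params[c("a", "b", "A1", "A2", "B2")],
                      function(p) all(is.finite(p)), logical(1)))) {
        abort(sprintf("training diverged at epoch %d (non-finite parameters)",
                      epoch))
      }
      train_loss <- weighted_bce(
        score_to_probability(ua_forward(params, x, model_config)$f, model_config),
        y, w[["pos"]], w[["neg"]])
      if (!is.finite(train_loss)) {
        abort(sprintf("training diverged at epoch %d (non-finite loss)", epoch))
      }
      if (has_val) {
        pv <- score_to_probability(ua_forward(params, xv, model_config)$f,
                                   model_config)
        val_loss <- weighted_bce(pv, yv, w[["pos"]], w[["neg"]])
        val_auc <- roc_auc(pv, yv)
      } else {
        val_loss <- NA_real_
        val_auc <- NA_real_
      }
      hist[[epoch]] <<- tibble(epoch = epoch, train_loss = train_loss,
                               val_loss = val_loss, val_auc = val_auc)
      monitored <- if (has_val) val_loss else train_loss
      if (monitored < best$loss - 1e-12) {
        best <<- list(loss = monitored, params = params, epoch = epoch)
        wait <<- 0L
      } else {
        wait <<- wait + 1L
        if (wait > training_config$patience) break
      }
    }
  }
  local_seed(if (is.null(seed)) NULL else derive_seed(seed, 2), run_epochs())

  new_ua_nam(parameters = best$params, model_config = model_config,
             scaler = scaler, training_config = training_config,
             history = bind_rows(hist[!vapply(hist, is.null, logical(1))]),
             best_epoch = best$epoch, class_weights = w)
}

#' Predict uric acid stone probability for new patients
#'
#' @param object A fitted `ua_nam` model.
#' @param newdata Patient records.
#' @param type `"prob"` for the probability of a pure uric acid stone (the
#'   ranking score used for ROC analysis and cutoffs), `"score"` for the raw
#'   additive score f(x).
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.ua_nam <- function(object, newdata, type = c("prob", "score"), ...) {
  type <- arg_match(type)
  x <- apply_scaler(object$scaler, encode_features(newdata))
  f <- additive_score(object$parameters, x, object$model_config)
  if (type == "score") f else score_to_probability(f, object$model_config)
}

#' Per-patient additive contributions of a fitted model
#'
#' @param model A fitted `ua_nam`.
#' @param newdata Patient records.
#' @return Tibble with `row`, `term`, `contribution`; per patient the seven
#'   terms sum to the additive score f(x).
#' @export
feature_contributions <- function(model, newdata) {
  stopifnot(inherits(model, "ua_nam"))
  x <- apply_scaler(model$scaler, encode_features(newdata))
  contribution_report(model$parameters, x, model$model_config)
}

#' @export
print.ua_nam <- function(x, ...) {
  h <- x$model_config$hidden_width
  cat("Additive neural uric acid stone classifier\n")
  cat(sprintf("  hidden width %d (%d trainable parameters)\n", h,
              count_parameters(x$model_config)))
  if (!is.null(x$history) && nrow(x$history) > 0) {
    cat(sprintf("  trained %d epochs (best epoch %d)\n",
                nrow(x$history), x$best_epoch))
    last <- x$history[x$best_epoch, ]
    if (is.finite(last$val_auc)) {
      cat(sprintf("  validation loss %.4f, validation AUC %.3f\n",
                  last$val_loss, last$val_auc))
    }
  }
  invisible(x)
}

#' Tidy the combination layer of a fitted model
#'
#' @param x A fitted `ua_nam`.
#' @param ... Unused.
#' @return Tibble with one row per additive term: the combination
#'   coefficients a1..a6 and the intercept b.
#' @method tidy ua_nam
#' @export
tidy.ua_nam <- function(x, ...) {
  tibble(
    term = c("sex", "age", "egfr", "urine_ph", "bmi",
             "dm+gout+bacteriuria", "(Intercept)"),
    estimate = c(x$parameters$a, x$parameters$b)
  )
}

#' One-row model summary
#'
#' @param x A fitted `ua_nam`.
#' @param ... Unused.
#' @return Tibble with parameter count, epochs run, best epoch and the
#'   training/validation losses and validation AUC at the best epoch.
#' @method glance ua_nam
#' @export
glance.ua_nam <- function(x, ...) {
  best <- if (!is.null(x$history) && nrow(x$history) > 0) {
    x$history[x$best_epoch, ]
  } else {
    tibble(train_loss = NA_real_, val_loss = NA_real_, val_auc = NA_real_)
  }
  tibble(
    n_parameters = count_parameters(x$model_config),
    epochs = if (is.null(x$history)) NA_integer_ else nrow(x$history),
    best_epoch = x$best_epoch,
    train_loss = best$train_loss,
    val_loss = best$val_loss,
    val_auc = best$val_auc
  )
}

#' Augment patient records with model predictions
#'
#' @param x A fitted `ua_nam`.
#' @param data Patient records.
#' @param ... Unused.
#' @return `data` with a `.pred_ua` probability column.
#' @method augment ua_nam
#' @export
augment.ua_nam <- function(x, data, ...) {
  data <- as_tibble(data)
  data$.pred_ua <- predict(x, data)
  data
}
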