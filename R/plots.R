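# ggplot2 methods for the result types.

#' Plot a ROC curve
#'
#' @param object A `ua_roc` from [roc_points()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ua_roc
#' @export
autoplot.ua_roc <- function(object, ...) {
  df <- tibble(fpr = 1 - object$specificity, tpr = object$sensitivity)
  df <- df[order(df$fpr, df$tpr), ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_path() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity",
                  title = sprintf("ROC curve (AUC = %.3f)", roc_auc(object))) +
    ggplot2::theme_minimal()
}

#' Plot the learned shape functions of a fitted model
#'
#' Shows each weighted subnetwork contribution a_i f_i over the observed range
#' of its feature — the additive model's per-feature risk shapes on the score
#' scale (a NEGATIVE contribution pushes the uric acid probability UP under
#' the published convention y = 1/(1 + e^f)).
#'
#' @param object A fitted `ua_nam`.
#' @param data Patient records giving the feature ranges (e.g. the training
#'   set).
#' @param n_grid Grid points per numeric feature.
#' @param ... Unused.
#' @return A ggplot, faceted by feature.
#' @method autoplot ua_nam
#' @export
autoplot.ua_nam <- function(object, data, n_grid = 101, ...) {
  data <- validate_patients(data)
  shapes <- purrr::map_dfr(seq_len(5), function(i) {
    feat <- ua_feature_names()[i]
    vals <- if (feat %in% ua_binary_features()) c(0, 1) else {
      seq(min(data[[feat]]), max(data[[feat]]), length.out = n_grid)
    }
    z <- (vals - object$scaler$center[[feat]]) / object$scaler$scale[[feat]]
    x <- matrix(0, length(z), 8)
    x[, i] <- z
    fi <- subnetwork_value(object$parameters, i, x, object$model_config)
    tibble(feature = feat, value = vals,
           contribution = object$parameters$a[i] * fi)
  })
  ggplot2::ggplot(shapes,
                  ggplot2::aes(x = .data$value, y = .data$contribution)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~feature, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "contribution to score f(x)",
                  title = "Additive shape functions") +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' @param model A fitted `ua_nam`.
#' @return A ggplot of training/validation loss and validation AUC by epoch.
#' @export
plot_training_history <- function(model) {
  stopifnot(inherits(model, "ua_nam"))
  hist <- model$history |>
    tidyr::pivot_longer(c("train_loss", "val_loss", "val_auc"),
                        names_to = "series", values_to = "value")
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$epoch, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = model$best_epoch, linetype = "dotted") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}
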