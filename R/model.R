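# Additive neural classifier over the eight clinical features.
#
# Five per-feature subnetworks f1..f5 (sex, age, eGFR, urine pH, BMI) and one
# grouped subnetwork f6 over (DM, gout, bacteriuria). Each subnetwork is a
# two-layer net: hidden layer of width h WITHOUT bias, scalar output with
# bias. The score is f(x) = a1 f1 + ... + a6 f6 + b, mapped to a probability
# by y = 1 / (1 + e^f) — note y is DECREASING in f, the published sign
# convention; larger y means more likely uric acid.

activation_fns <- function(name) {
  switch(name,
    relu = list(f = function(z) pmax(z, 0), grad = function(z) (z > 0) * 1),
    tanh = list(f = tanh, grad = function(z) 1 - tanh(z)^2),
    sigmoid = list(f = plogis, grad = function(z) plogis(z) * (1 - plogis(z))),
    identity = list(f = identity, grad = function(z) rep(1, length(z)) + 0 * z),
    abort(paste0("unknown activation `", name, "`"))
  )
}

#' Model architecture configuration
#'
#' @param hidden_width Width h of each subnetwork's hidden layer (default 20,
#'   giving 293 trainable parameters).
#' @param hidden_activation,output_activation Activation names among
#'   `"relu"`, `"tanh"`, `"sigmoid"`, `"identity"`. Defaults: ReLU hidden,
#'   tanh output (bounded per-term contributions).
#' @param init_scale Multiplier on the 1/sqrt(fan-in) initialization SD.
#' @param probability `"inverse"` keeps the published convention
#'   y = 1/(1 + e^f) (decreasing in f); `"sigmoid"` uses the conventional
#'   y = 1/(1 + e^-f).
#' @return Object of class `ua_model_config`.
#' @export
ua_model_config <- function(hidden_width = 20, hidden_activation = "relu",
                            output_activation = "tanh", init_scale = 1,
                            probability = c("inverse", "sigmoid")) {
  hidden_width <- as.integer(hidden_width)
  if (hidden_width < 1) abort("`hidden_width` must be >= 1")
  activation_fns(hidden_activation)
  activation_fns(output_activation)
  structure(list(
    n_features = 8L,
    grouped_indices = c(6L, 7L, 8L),
    hidden_width = hidden_width,
    hidden_activation = hidden_activation,
    output_activation = output_activation,
    init_scale = init_scale,
    probability = arg_match(probability)
  ), class = "ua_model_config")
}

#' Number of trainable parameters of the additive network
#'
#' Five univariate subnetworks contribute 2h + 1 parameters each (h first- and
#' h second-layer weights plus the output bias), the grouped subnetwork
#' 4h + 1, and the combination layer 7 (a1..a6 and b): 14h + 13 in total, 293
#' at the default width h = 20.
#'
#' @param config A [ua_model_config()].
#' @return Integer parameter count.
#' @examples
#' count_parameters(ua_model_config(hidden_width = 20)) # 293
#' @export
count_parameters <- function(config) {
  h <- config$hidden_width
  5L * (2L * h + 1L) + (4L * h + 1L) + 7L
}

#' Initialize the trainable parameters
#'
#' First-layer weight vectors A_{1,1}..A_{8,1} (length h each, no bias) and
#' second-layer weight vectors A_{1,2}..A_{6,2} are drawn from zero-mean
#' normals with SD `init_scale / sqrt(fan-in)` (fan-in 1 for the first layer,
#' h for the second); output biases B_{1,2}..B_{6,2} start at 0; the
#' combination coefficients a1..a6 and intercept b start at small nonzero
#' values.
#'
#' @param config A [ua_model_config()].
#' @param seed Integer seed for reproducible initialization.
#' @return Object of class `ua_parameters`: list with `a` (6), `b` (scalar),
#'   `A1` (h x 8 matrix, first-layer vectors by feature), `A2` (h x 6 matrix,
#'   second-layer vectors by subnetwork), `B2` (6 output biases).
#' @export
init_parameters <- function(config, seed = NULL) {
  h <- config$hidden_width
  s <- config$init_scale
  local_seed(seed, {
    A1 <- matrix(rnorm(h * 8, sd = s), nrow = h,
                 dimnames = list(NULL, ua_feature_names()))
    A2 <- matrix(rnorm(h * 6, sd = s / sqrt(h)), nrow = h)
    B2 <- rep(0, 6)
    a <- rnorm(6, mean = 0.1, sd = 0.02)
    b <- rnorm(1, mean = 0.01, sd = 0.005)
    structure(list(a = a, b = b, A1 = A1, A2 = A2, B2 = B2),
              class = "ua_parameters")
  })
}

# Exhaustive count of the scalars held in a parameter structure.
n_parameters <- function(params) {
  length(params$a) + length(params$b) + length(params$A1) +
    length(params$A2) + length(params$B2)
}

as_feature_matrix <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) == 8)
    x <- matrix(as.numeric(x), nrow = 1)
  }
  stopifnot(ncol(x) == 8)
  x
}

# Forward pass. Returns f plus, when keep = TRUE, every intermediate needed
# by backprop: pre-activations (list of n x h), hidden activations, z (n x 6)
# and the subnetwork outputs F (n x 6).
ua_forward <- function(params, x, config, keep = FALSE) {
  x <- as_feature_matrix(x)
  act1 <- activation_fns(config$hidden_activation)
  act2 <- activation_fns(config$output_activation)
  n <- nrow(x)
  h <- config$hidden_width
  pre <- vector("list", 6)
  hid <- vector("list", 6)
  for (i in 1:5) pre[[i]] <- outer(x[, i], params$A1[, i])
  pre[[6]] <- outer(x[, 6], params$A1[, 6]) + outer(x[, 7], params$A1[, 7]) +
    outer(x[, 8], params$A1[, 8])
  z <- matrix(0, n, 6)
  Fm <- matrix(0, n, 6)
  for (i in 1:6) {
    hid[[i]] <- act1$f(pre[[i]])
    z[, i] <- hid[[i]] %*% params$A2[, i] + params$B2[i]
    Fm[, i] <- act2$f(z[, i])
  }
  f <- drop(Fm %*% params$a) + params$b
  if (!keep) return(list(f = f, F = Fm))
  list(f = f, F = Fm, z = z, hidden = hid, pre = pre, x = x)
}

#' Value of one subnetwork
#'
#' Subnetworks 1-5 depend only on their own feature; subnetwork 6 depends
#' only on the grouped features (DM, gout, bacteriuria).
#'
#' @param params A `ua_parameters` object.
#' @param i Subnetwork index, 1..6.
#' @param x Encoded 8-vector or n x 8 matrix.
#' @param config The matching [ua_model_config()].
#' @return Numeric vector of f_i values.
#' @export
subnetwork_value <- function(params, i, x, config) {
  if (!is.numeric(i) || length(i) != 1 || i < 1 || i > 6) {
    abort("`i` must be a single index in 1..6")
  }
  ua_forward(params, x, config)$F[, as.integer(i)]
}

#' Additive score f(x)
#'
#' `f(x) = a1 f1(x1) + ... + a5 f5(x5) + a6 f6(x6, x7, x8) + b`.
#'
#' @inheritParams subnetwork_value
#' @return Numeric vector of scores.
#' @export
additive_score <- function(params, x, config) {
  x <- as_feature_matrix(x)
  if (any(!is.finite(x))) abort("non-finite feature values")
  ua_forward(params, x, config)$f
}

#' Predicted probability of a pure uric acid stone
#'
#' Published convention: `y = 1 / (1 + e^{f(x)})`, strictly decreasing in the
#' score f (`probability = "sigmoid"` in the config flips to the conventional
#' orientation). Computed via `plogis` for numerical stability at large |f|.
#'
#' @inheritParams subnetwork_value
#' @return Probabilities in (0, 1).
#' @export
predict_probability <- function(params, x, config) {
  f <- additive_score(params, x, config)
  score_to_probability(f, config)
}

score_to_probability <- function(f, config) {
  if (config$probability == "inverse") plogis(-f) else plogis(f)
}

#' Per-term contribution report
#'
#' Decomposes the additive score into the six weighted subnetwork
#' contributions `a_i f_i` plus the intercept; the terms sum to f(x) exactly
#' (to floating tolerance).
#'
#' @inheritParams subnetwork_value
#' @return Tibble with one row per record and term: `row`, `term`,
#'   `contribution`.
#' @export
contribution_report <- function(params, x, config) {
  x <- as_feature_matrix(x)
  fwd <- ua_forward(params, x, config)
  terms <- c("sex", "age", "egfr", "urine_ph", "bmi",
             "dm+gout+bacteriuria", "(Intercept)")
  contrib <- cbind(sweep(fwd$F, 2, params$a, "*"), params$b)
  tibble(
    row = rep(seq_len(nrow(x)), times = 7),
    term = rep(terms, each = nrow(x)),
    contribution = as.vector(contrib)
  )
}

# --- serialization ---------------------------------------------------------

UA_MODEL_FORMAT <- "uastone-model/1"

params_to_list <- function(params) {
  list(a = params$a, b = params$b,
       A_first = lapply(seq_len(ncol(params$A1)), function(j) params$A1[, j]),
       A_second = lapply(seq_len(ncol(params$A2)), function(j) params$A2[, j]),
       B_second = params$B2)
}

params_from_list <- function(lst) {
  A1 <- do.call(cbind, lapply(lst$A_first, as.numeric))
  colnames(A1) <- ua_feature_names()
  structure(list(a = as.numeric(lst$a), b = as.numeric(lst$b),
                 A1 = A1,
                 A2 = do.call(cbind, lapply(lst$A_second, as.numeric)),
                 B2 = as.numeric(lst$B_second)),
            class = "ua_parameters")
}

#' Write / read a fitted model as JSON
#'
#' Flat JSON with named arrays: the architecture config, the parameter blocks
#' (`a`, `b`, `A_first`, `A_second`, `B_second`), the training-set scaler and
#' a format-version string.
#'
#' @param model A fitted `ua_nam` object (see [fit_ua_model()]).
#' @param path Output / input JSON path.
#' @return `write_ua_model()`: `path` invisibly. `read_ua_model()`: a
#'   `ua_nam` model usable with `predict()`.
#' @export
write_ua_model <- function(model, path) {
  stopifnot(inherits(model, "ua_nam"))
  cfg <- unclass(model$model_config)
  payload <- c(
    list(format_version = UA_MODEL_FORMAT, config = cfg),
    params_to_list(model$parameters),
    list(scaler = list(center = as.list(model$scaler$center),
                       scale = as.list(model$scaler$scale)))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ua_model
#' @export
read_ua_model <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(lst$format_version, UA_MODEL_FORMAT)) {
    abort(paste0("unrecognized model format: ", lst$format_version))
  }
  cfg <- ua_model_config(
    hidden_width = lst$config$hidden_width,
    hidden_activation = lst$config$hidden_activation,
    output_activation = lst$config$output_activation,
    init_scale = lst$config$init_scale,
    probability = lst$config$probability
  )
  params <- params_from_list(list(
    a = lst$a, b = lst$b,
    A_first = if (is.matrix(lst$A_first)) {
      lapply(seq_len(nrow(lst$A_first)), function(i) lst$A_first[i, ])
    } else lst$A_first,
    A_second = if (is.matrix(lst$A_second)) {
      lapply(seq_len(nrow(lst$A_second)), function(i) lst$A_second[i, ])
    } else lst$A_second,
    B_second = lst$B_second
  ))
  scaler <- structure(list(center = unlist(lst$scaler$center),
                           scale = unlist(lst$scaler$scale)),
                      class = "ua_scaler")
  new_ua_nam(parameters = params, model_config = cfg, scaler = scaler,
             training_config = NULL, history = NULL, best_epoch = NA_integer_,
             class_weights = NULL)
}
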