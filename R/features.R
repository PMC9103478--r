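# Patient-record encoding, validation, standardization and CSV I/O.
#
# The model consumes an ordered eight-column matrix:
#   x1 sex, x2 age, x3 eGFR, x4 urine pH, x5 BMI, x6 DM, x7 gout,
#   x8 bacteriuria.
# CSV files use the column order sex,age,bmi,dm,gout,bacteriuria,urine_ph,
# egfr[,scr][,label].

#' Model feature names in network input order
#'
#' @return Character vector of the eight predictor names, in the order the
#'   additive network consumes them (sex, age, egfr, urine_ph, bmi, dm, gout,
#'   bacteriuria).
#' @export
ua_feature_names <- function() {
  c("sex", "age", "egfr", "urine_ph", "bmi", "dm", "gout", "bacteriuria")
}

ua_numeric_features <- function() c("age", "egfr", "urine_ph", "bmi")
ua_binary_features <- function() c("sex", "dm", "gout", "bacteriuria")
ua_csv_columns <- function() {
  c("sex", "age", "bmi", "dm", "gout", "bacteriuria", "urine_ph", "egfr")
}

#' Validate a patient-record data frame
#'
#' Checks the clinical invariants of a record table: adult ages, urine pH in
#' \[4, 9\], positive BMI and eGFR, binary flags in \{0, 1\}, optional binary
#' `label`, and no missing values in any used column (records with missing
#' fields are rejected, never imputed).
#'
#' @param data Data frame with columns `sex`, `age`, `bmi`, `dm`, `gout`,
#'   `bacteriuria`, `urine_ph`, `egfr` and optionally `label`.
#' @param require_label Require a `label` column (`TRUE` for training data).
#' @return `data` as a tibble, invisibly usable downstream.
#' @export
validate_patients <- function(data, require_label = FALSE) {
  data <- as_tibble(data)
  needed <- ua_csv_columns()
  if (require_label) needed <- c(needed, "label")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  check <- intersect(c(needed, "label"), names(data))
  for (col in check) {
    if (anyNA(data[[col]])) {
      abort(paste0("missing values in column `", col,
                   "`; records with missing fields are rejected, not imputed"))
    }
  }
  binaries <- intersect(c(ua_binary_features(), "label"), names(data))
  for (col in binaries) {
    if (!all(data[[col]] %in% c(0, 1))) {
      abort(paste0("column `", col, "` must be binary 0/1"))
    }
  }
  if (nrow(data) > 0) {
    if (any(data$age < 18)) abort("`age` must be >= 18 (adult cohort)")
    if (any(data$urine_ph < 4 | data$urine_ph > 9)) {
      abort("`urine_ph` must lie in [4, 9]")
    }
    if (any(data$bmi <= 0)) abort("`bmi` must be positive")
    if (any(data$egfr <= 0)) abort("`egfr` must be positive")
  }
  data
}

#' Encode patient records as the model's ordered input matrix
#'
#' Maps a record table to the n-by-8 numeric matrix the additive network
#' consumes, with columns exactly in the order sex, age, eGFR, urine pH, BMI,
#' DM, gout, bacteriuria. Missing values raise an error.
#'
#' @param data Patient records (see [validate_patients()]).
#' @return Numeric matrix with one row per record and the eight ordered
#'   feature columns.
#' @examples
#' rec <- tibble::tibble(sex = 1, age = 60, bmi = 25.6, dm = 1, gout = 0,
#'                       bacteriuria = 0, urine_ph = 5.5, egfr = 55)
#' encode_features(rec)
#' @export
encode_features <- function(data) {
  data <- validate_patients(data)
  out <- as.matrix(data[, ua_feature_names()])
  storage.mode(out) <- "double"
  rownames(out) <- NULL
  out
}

#' Fit a training-set standardizer for the numeric features
#'
#' Computes per-feature z-score parameters (population standard deviation)
#' for the four numeric features (age, eGFR, urine pH, BMI); the binary
#' features pass through unchanged. Fit this on the training split only and
#' reuse it unchanged on validation or new data.
#'
#' @param data Training patient records.
#' @return An object of class `ua_scaler`: centers and scales for the eight
#'   ordered features (0/1 for binaries).
#' @export
fit_scaler <- function(data) {
  x <- encode_features(data)
  feats <- ua_feature_names()
  center <- setNames(rep(0, length(feats)), feats)
  scale <- setNames(rep(1, length(feats)), feats)
  for (f in ua_numeric_features()) {
    v <- x[, f]
    if (length(unique(v)) < 2) {
      abort(paste0("numeric feature `", f,
                   "` has zero variance in the training data; cannot standardize"))
    }
    m <- mean(v)
    s <- sqrt(mean((v - m)^2)) # population SD
    center[f] <- m
    scale[f] <- s
  }
  structure(list(center = center, scale = scale), class = "ua_scaler")
}

#' Apply a fitted standardizer to an encoded feature matrix
#'
#' @param scaler A `ua_scaler` from [fit_scaler()].
#' @param x Encoded matrix from [encode_features()] (or a single 8-vector).
#' @return Matrix (or vector) with numeric features standardized and binary
#'   features untouched.
#' @export
apply_scaler <- function(scaler, x) {
  stopifnot(inherits(scaler, "ua_scaler"))
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1, dimnames = list(NULL, ua_feature_names()))
  stopifnot(ncol(x) == 8)
  out <- sweep(sweep(x, 2, scaler$center, "-"), 2, scaler$scale, "/")
  if (vec) out[1, ] else out
}

#' Standardize the numeric columns of a patient table
#'
#' Data-frame-first companion to [apply_scaler()]: returns the table with
#' `age`, `egfr`, `urine_ph` and `bmi` replaced by their training z-scores.
#'
#' @inheritParams apply_scaler
#' @param data Patient records.
#' @return Tibble with standardized numeric columns.
#' @export
scale_features <- function(data, scaler) {
  data <- as_tibble(data)
  for (f in ua_numeric_features()) {
    data[[f]] <- (data[[f]] - scaler$center[[f]]) / scaler$scale[[f]]
  }
  data
}

#' Read patient records from CSV
#'
#' Expects the header `sex,age,bmi,dm,gout,bacteriuria,urine_ph,egfr[,scr][,label]`
#' (UTF-8, dot decimal separator). When an `egfr` column is present it is used
#' as-is; when only `scr` (serum creatinine, mg/dL) is present, eGFR is
#' computed with [compute_egfr_mdrd()]. Missing values are an error.
#'
#' @param path CSV file path.
#' @return Tibble of validated patient records.
#' @export
read_patients <- function(path) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!"egfr" %in% names(data)) {
    if (!"scr" %in% names(data)) {
      abort("CSV must contain an `egfr` column or an `scr` column")
    }
    if (anyNA(data$scr)) abort("missing values in column `scr`")
    data$egfr <- compute_egfr_mdrd(data$scr, data$age, 1 - data$sex)
  }
  validate_patients(data)
}

#' Write patient records to CSV
#'
#' @param data Patient records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_patients <- function(data, path) {
  data <- validate_patients(data)
  cols <- intersect(c(ua_csv_columns(), "scr", "label"), names(data))
  readr::write_csv(data[, cols], path, progress = FALSE)
  invisible(path)
}
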