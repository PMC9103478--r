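#' Estimated glomerular filtration rate (MDRD study equation)
#'
#' Computes eGFR from serum creatinine, age and sex using the IDMS-traceable
#' four-variable MDRD equation:
#' \deqn{eGFR = 175 \times Scr^{-1.154} \times Age^{-0.203} \times 0.742^{[female]}}
#' in mL/min/1.73 m^2. The race coefficient is not used (all-Asian cohorts).
#'
#' @param scr Serum creatinine in mg/dL. Must be strictly positive.
#' @param age Age in years. Adults only (>= 18).
#' @param female Binary flag (1 or `TRUE` = female, 0 or `FALSE` = male).
#' @return Numeric vector of eGFR values in mL/min/1.73 m^2.
#' @examples
#' compute_egfr_mdrd(scr = 1.0, age = 60, female = 0) # ~76.2
#' compute_egfr_mdrd(scr = 1.0, age = 60, female = 1) # 0.742 x male value
#' @export
compute_egfr_mdrd <- function(scr, age, female) {
  if (any(!is.finite(scr)) || any(scr <= 0)) {
    abort("`scr` must be strictly positive serum creatinine in mg/dL.")
  }
  if (any(!is.finite(age)) || any(age < 18)) {
    abort("`age` must be >= 18 years (adult cohort).")
  }
  female <- as.numeric(female)
  if (any(!female %in% c(0, 1))) {
    abort("`female` must be 0/1 (or FALSE/TRUE).")
  }
  175 * scr^(-1.154) * age^(-0.203) * ifelse(female == 1, 0.742, 1)
}
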