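# Lognormal accelerated failure time (AFT) models of years past age 40 to the
# final menstrual period: log(T_i - 40) = row_i' (alpha, theta) + eps_i,
# eps_i ~ N(0, sigma^2). Candidate designs M0-M4 add trajectory features
# (class membership D_i, log within-subject variance omega_i, and class-gated
# fitted FSH level/rate at ages 40 and 45); "Mfinal" is the simplified
# prediction model (no BMI, race or omega_i; AMH collapsed to two levels).

AFT_MODELS <- c("M0", "M1", "M2", "M3", "M4", "Mfinal")

# design dimension per model id
aft_dim <- function(model_id) {
  switch(model_id,
         M0 = 7L, M1 = 9L, M2 = 11L, M3 = 11L, M4 = 13L, Mfinal = 6L,
         stop("unknown model_id: ", model_id))
}

aft_coef_names <- function(model_id) {
  x_full <- c("Adj log BMI", "AMH Q2", "AMH Q3", "AMH Q4", "Smoker", "Race")
  switch(model_id,
         M0 = c("(Intercept)", x_full),
         M1 = c("(Intercept)", "Class 2 vs 1", "Within-subject variability", x_full),
         M2 = c("(Intercept)", "Class 2 vs 1", "Within-subject variability",
                "Class 1: mu(40)", "Class 2: mu(45)", x_full),
         M3 = c("(Intercept)", "Class 2 vs 1", "Within-subject variability",
                "Class 1: nu(40)", "Class 2: nu(45)", x_full),
         M4 = c("(Intercept)", "Class 2 vs 1", "Within-subject variability",
                "Class 1: mu(40)", "Class 2: mu(45)",
                "Class 1: nu(40)", "Class 2: nu(45)", x_full),
         Mfinal = c("(Intercept)", "Class 2 vs 1",
                    "Class 1: mu(40)", "Class 2: mu(45)",
                    "AMH > 0.83", "Smoker"),
         stop("unknown model_id: ", model_id))
}

#' AFT design row for one subject
#'
#' Builds the linear-predictor row of the requested model. Class-1 features
#' (level/rate at age 40) are gated by \eqn{(1 - D_i)} and class-2 features
#' (at age 45) by \eqn{D_i}, where \eqn{D_i = 0} labels the early-rise class 1
#' and \eqn{D_i = 1} the late-rise class 2.
#'
#' @param model_id one of \code{"M0"}, \code{"M1"}, \code{"M2"}, \code{"M3"},
#'   \code{"M4"}, \code{"Mfinal"}.
#' @param feats named list/vector of trajectory features: \code{D} (0/1...,
#'   collapsed to "class 2+" indicator for K > 2), \code{mu40}, \code{mu45},
#'   \code{nu40}, \code{nu45}, \code{omega}.
#' @param x named covariate vector with elements \code{bmi_log} (adjusted log
#'   BMI at 40), \code{amh_q2}, \code{amh_q3}, \code{amh_q4} (quartile
#'   indicators), \code{amh_high} (> 0.83 ng/mL indicator), \code{smoker},
#'   \code{race}.
#' @return named numeric design row; length 7 (M0), 9 (M1), 11 (M2/M3),
#'   13 (M4) or 6 (Mfinal).
#' @examples
#' feats <- list(D = 1, mu40 = 2.1, mu45 = 2.6, nu40 = 0.1, nu45 = 0.3,
#'               omega = -2.2)
#' x <- c(bmi_log = log(28), amh_q2 = 1, amh_q3 = 0, amh_q4 = 0,
#'        amh_high = 0, smoker = 0, race = 1)
#' design_row("M2", feats, x)
#' @export
design_row <- function(model_id, feats, x) {
  model_id <- match.arg(model_id, AFT_MODELS)
  D <- as.numeric(feats$D >= 1)  # late-class indicator
  g1 <- 1 - D; g2 <- D
  x_full <- c(x[["bmi_log"]], x[["amh_q2"]], x[["amh_q3"]], x[["amh_q4"]],
              x[["smoker"]], x[["race"]])
  row <- switch(model_id,
    M0 = c(1, x_full),
    M1 = c(1, D, feats$omega, x_full),
    M2 = c(1, D, feats$omega, feats$mu40 * g1, feats$mu45 * g2, x_full),
    M3 = c(1, D, feats$omega, feats$nu40 * g1, feats$nu45 * g2, x_full),
    M4 = c(1, D, feats$omega, feats$mu40 * g1, feats$mu45 * g2,
           feats$nu40 * g1, feats$nu45 * g2, x_full),
    Mfinal = c(1, D, feats$mu40 * g1, feats$mu45 * g2, x[["amh_high"]],
               x[["smoker"]]))
  stats::setNames(row, aft_coef_names(model_id))
}

#' AFT log-likelihood contribution of one subject
#'
#' \eqn{\log N(\log(T_i - 40);\ row \cdot coefs,\ \sigma^2)}. \code{T_i} must
#' be resolved (imputed for censored subjects) and exceed 40.
#'
#' @param T_i FMP age in years (> 40).
#' @param spec list with \code{coef} (vector matching \code{row}) and
#'   \code{sigma2} (> 0).
#' @param row design row from \code{\link{design_row}}.
#' @return scalar log-likelihood.
#' @export
aft_loglik <- function(T_i, spec, row) {
  if (any(T_i <= 40)) stop("T_i must exceed 40 years")
  if (length(row) != length(spec$coef)) stop("design/coefficient length mismatch")
  stats::dnorm(log(T_i - 40), sum(row * spec$coef), sqrt(spec$sigma2), log = TRUE)
}

#' Impute a censored FMP age from its truncated-normal conditional
#'
#' Draws \eqn{z \sim N(m, \sigma^2)} truncated below at
#' \eqn{\log(C_i - 40)} and returns \eqn{40 + e^z}, so the imputed FMP age
#' always exceeds the censoring age.
#'
#' @param C_i censoring age(s) in years (> 40).
#' @param mean linear predictor(s) \eqn{m} on the log(years past 40) scale.
#' @param sigma2 AFT residual variance.
#' @return imputed FMP age(s), each \code{> C_i}.
#' @export
impute_censored_fmp <- function(C_i, mean, sigma2) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  if (any(C_i <= 40)) stop("censoring age must exceed 40")
  a <- log(C_i - 40)
  if (any(!is.finite(a))) stop("non-finite truncation point")
  40 + exp(rtnorm_lower(length(C_i), mean = mean, sd = sqrt(sigma2), lower = a))
}

#' Time ratio of an AFT coefficient
#'
#' \eqn{e^{coef}}: the multiplicative factor on years past age 40 to FMP for
#' a one-unit covariate difference (e.g. late-rise vs early-rise class).
#'
#' @param coef AFT coefficient(s) on the log-time scale.
#' @return \code{exp(coef)}.
#' @examples
#' time_ratio(0.424)  # ~1.53x additional years past 40
#' @export
time_ratio <- function(coef) {
  if (any(!is.finite(coef))) stop("coef must be finite")
  exp(coef)
}

#' Cox-Snell residuals of a fitted lognormal AFT model
#'
#' \eqn{r_i = -\log S(T_i)} with \eqn{S} the fitted lognormal survival; if the
#' model is correct the \eqn{r_i} behave like unit-exponential (censored)
#' data, so their Nelson-Aalen cumulative hazard should follow the 45-degree
#' line. The returned flag passes when the maximum absolute deviation of the
#' cumulative hazard from the identity over residuals in \code{[0, window]}
#' stays below \code{threshold}.
#'
#' @param time observed time (FMP age if event, censoring age otherwise).
#' @param event logical/0-1 event indicators.
#' @param lp fitted linear predictors (per subject).
#' @param sigma2 fitted residual variance.
#' @param threshold maximum tolerated deviation (default 0.2).
#' @param window upper end of the residual range assessed (default 2).
#' @return list with \code{residuals}, \code{event}, \code{max_dev},
#'   \code{pass}.
#' @export
cox_snell_residuals <- function(time, event, lp, sigma2, threshold = 0.2,
                                window = 2) {
  if (!any(event)) stop("no events: cannot assess Cox-Snell residuals")
  z <- (log(time - 40) - lp) / sqrt(sigma2)
  r <- -stats::pnorm(z, lower.tail = FALSE, log.p = TRUE)  # -log S(t)
  sf <- survival::survfit(survival::Surv(r, as.integer(event)) ~ 1,
                          ctype = 1)
  H <- sf$cumhaz
  tt <- sf$time
  keep <- tt <= window & sf$n.event > 0
  max_dev <- if (any(keep)) max(abs(H[keep] - tt[keep])) else NA_real_
  list(residuals = r, event = as.logical(event), max_dev = max_dev,
       pass = is.finite(max_dev) && max_dev < threshold)
}
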