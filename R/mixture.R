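# Generalized growth mixture model (GGMM) likelihood pieces: latent trajectory
# classes, class-mean penalized splines plus subject random intercept/slope,
# Student-t(4) residuals as a Gamma(2,2) normal scale mixture, and lognormal
# subject-specific within-subject variances.
#
# Lightweight containers used throughout:
#   params: list(K, pi, beta [dim x K], lambda2 [K], eta [K], tau2,
#                psi2 = c(psi0^2, psi1^2), nu = 4)
#   state : per-subject list(D [0-based class], b = c(b0, b1), sigma2, omega,
#                w [per-visit t scale weights], T_imp)

#' Reference age for subject-level centering
#'
#' Subject deviations are a random intercept and slope centered at age 40, the
#' a-priori reference age of the outcome model.
#' @keywords internal
T_REF <- 40

#' Subject-specific mean trajectory
#'
#' \eqn{\mu_i(t) = X(t)\beta_{D_i} + b_{i0} + b_{i1}(t - 40)}; with
#' \code{what = "rate"} returns \eqn{\nu_i(t)}, the class-curve derivative plus
#' the subject slope \eqn{b_{i1}}.
#'
#' @param params GGMM parameter list (see package internals); needs
#'   \code{beta}, a \code{basis$dim x K} coefficient matrix.
#' @param state subject latent state: \code{D} (0-based class index) and
#'   \code{b = c(intercept, slope)}.
#' @param basis an \code{\link{fmp_basis}}.
#' @param t ages at which to evaluate.
#' @param what \code{"level"} or \code{"rate"}.
#' @return numeric vector of subject means (or rates) at \code{t}.
#' @export
subject_mean <- function(params, state, basis, t, what = c("level", "rate")) {
  what <- match.arg(what)
  beta_k <- params$beta[, state$D + 1L]
  if (what == "level")
    drop(basis_row(basis, t, 0) %*% beta_k) + state$b[1] + state$b[2] * (t - T_REF)
  else
    drop(basis_row(basis, t, 1) %*% beta_k) + state$b[2]
}

#' Longitudinal log-likelihood of one subject's visit series
#'
#' With \code{marginal = TRUE}, the Student-t(4) log density of each residual
#' (robust to outlying hormone values); otherwise the conditional normal form
#' given the latent scale weights \code{state$w}, i.e.
#' \eqn{N(y_{ij}; \mu_i(t_{ij}), \sigma_i^2 / w_{ij})}. The two agree after
#' integrating \eqn{w_{ij} \sim Gamma(2, 2)}.
#'
#' @param series list with \code{ages} and \code{y} (log FSH by default).
#' @param params,state,basis as in \code{\link{subject_mean}}.
#' @param marginal logical; marginalize the scale weights analytically.
#' @return scalar log-likelihood.
#' @export
longitudinal_loglik <- function(series, params, state, basis, marginal = TRUE) {
  if (state$sigma2 <= 0) stop("sigma2 must be positive")
  mu <- subject_mean(params, state, basis, series$ages)
  r <- series$y - mu
  if (marginal) {
    sum(dt_ls(r, 0, sqrt(state$sigma2), df = params$nu))
  } else {
    sum(stats::dnorm(r, 0, sqrt(state$sigma2 / state$w), log = TRUE))
  }
}

#' Posterior class-membership probabilities for one subject
#'
#' \eqn{p_k \propto \pi_k \exp\{\ell_{long}(k) + \ell_{AFT}(k) +
#' \log N(\omega_i; \eta_k, \tau^2)\}}, normalized with max-subtraction so
#' log-likelihood differences up to several hundred do not overflow. The
#' within-subject-variance prior term is part of the class definition because
#' the classes carry their own mean log-variance \eqn{\eta_k}.
#'
#' @param series visit series (list with \code{ages}, \code{y}).
#' @param outcome_loglik_by_class numeric vector of length K: the AFT
#'   log-likelihood of this subject evaluated under each candidate class
#'   (trajectory features recomputed per class). Zeros for outcome-free use.
#' @param params,state,basis as in \code{\link{subject_mean}}.
#' @param conditional logical; use the conditional-on-weights normal
#'   longitudinal likelihood (the form required inside the Gibbs sweep).
#' @return probability vector over classes summing to 1.
#' @export
class_responsibilities <- function(series, outcome_loglik_by_class, params,
                                   state, basis, conditional = FALSE) {
  K <- params$K
  if (length(outcome_loglik_by_class) != K)
    stop("outcome_loglik_by_class must have length K")
  lp <- numeric(K)
  for (k in seq_len(K)) {
    st_k <- state
    st_k$D <- k - 1L
    lp[k] <- log(params$pi[k]) +
      longitudinal_loglik(series, params, st_k, basis,
                          marginal = !conditional) +
      outcome_loglik_by_class[k] +
      stats::dnorm(state$omega, params$eta[k], sqrt(params$tau2), log = TRUE)
  }
  if (all(!is.finite(lp))) stop("all class log-likelihoods are -Inf")
  p <- exp(lp - logsumexp(lp))
  p / sum(p)
}
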