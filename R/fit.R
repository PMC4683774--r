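# User-facing model fit: wraps the MCMC engine, relabels draws, and exposes
# the classic modelling-object surface (print, summary, coef, predict, plot,
# residuals, simulate).

#' Fit the Bayesian joint FSH-trajectory / FMP-age model
#'
#' Jointly estimates a generalized growth mixture model for longitudinal
#' log-FSH (latent trajectory classes, penalized cubic class-mean splines,
#' subject random intercept/slope, t(4) residuals, lognormal within-subject
#' variances) and a lognormal accelerated failure time model for age at
#' final menstrual period, by MCMC.
#'
#' @param visits long-format longitudinal table (columns subject_id, age,
#'   fsh), or an \code{"fmp_cohort"} from \code{\link{simulate_cohort}} (in
#'   which case \code{outcomes} is taken from the cohort).
#' @param outcomes one-row-per-subject outcome table (subject_id, fmp_age,
#'   censor_age, event, bmi, amh, smoker, race).
#' @param model AFT model id: "M0", "M1", "M2", "M3", "M4" or "Mfinal".
#' @param K number of latent trajectory classes (default 2).
#' @param n_knots interior spline knots (default 10).
#' @param priors see \code{\link{fmp_priors}}.
#' @param control see \code{\link{fmp_control}}.
#' @param min_visits inclusion criterion: minimum measurements per subject.
#' @param mask_outcomes optional ids whose outcomes are masked (used by CV).
#' @param amh_cutpoints optional fixed AMH quartile cutpoints.
#' @param ... passed to \code{\link{run_mcmc}} (e.g. \code{fix}).
#' @return an object of class \code{"fmp_joint"}; see
#'   \code{\link{summary.fmp_joint}}, \code{\link{predict.fmp_joint}}.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(list(n_subjects = 80), seed = 7)
#' fit <- fmp_joint(coh, model = "M1",
#'                  control = fmp_control(n_burnin = 200, n_draws = 300))
#' summary(fit)
#' }
#' @export
fmp_joint <- function(visits, outcomes = NULL, model = "M2", K = 2,
                      n_knots = 10, priors = fmp_priors(),
                      control = fmp_control(), min_visits = 6,
                      mask_outcomes = NULL, amh_cutpoints = NULL, ...) {
  cohort_config <- NULL
  if (inherits(visits, "fmp_cohort")) {
    cohort_config <- visits$config
    outcomes <- visits$outcomes
    visits <- visits$visits
  }
  if (is.null(outcomes)) stop("outcomes table is required")
  raw <- run_mcmc(visits, outcomes, model_id = model, K = K, priors = priors,
                  control = control, n_knots = n_knots,
                  min_visits = min_visits, mask_outcomes = mask_outcomes,
                  amh_cutpoints = amh_cutpoints, ...)
  fit <- relabel_draws(raw)
  n <- fit$fd$n
  # posterior modal class per subject
  map_class <- integer(n)
  for (i in seq_len(n)) {
    tab <- tabulate(fit$draws$D[, i] + 1L, K)
    map_class[i] <- which.max(tab) - 1L
  }
  fit$map_class <- map_class
  fit$subjects <- data.frame(subject_id = fit$fd$ids,
                             class = map_class + 1L,
                             p_class1 = colMeans(fit$draws$D == 0L),
                             omega = colMeans(fit$draws$omega))
  fit$cohort_config <- cohort_config
  class(fit) <- c("fmp_joint", "fmp_draws")
  fit
}

# coefficient summary: posterior mean, central 95% interval, significance
summary_table <- function(fit, prob = 0.95) {
  g <- fit$draws$gamma
  lo <- (1 - prob) / 2
  qs <- apply(g, 2, stats::quantile, probs = c(lo, 1 - lo), names = FALSE)
  out <- cbind(mean = colMeans(g), lower = qs[1, ], upper = qs[2, ])
  rownames(out) <- colnames(g)
  out
}

#' @export
print.fmp_joint <- function(x, ...) {
  cat(sprintf("Joint GGMM/AFT fit: model %s, K = %d, %d subjects, %d draws (seed %d)\n",
              x$model, x$K, x$fd$n, x$n_stored, x$seed))
  cat(sprintf("  class sizes (modal): %s\n",
              paste(tabulate(x$map_class + 1L, x$K), collapse = " / ")))
  cat("  AFT coefficients (posterior means):\n")
  print(round(coef(x), 3))
  invisible(x)
}

#' Posterior coefficient summary of a joint fit
#'
#' Per-coefficient posterior mean, central 95% credible interval and a
#' significance flag (interval excludes 0), plus the AFT residual SD and
#' class-weight summary.
#'
#' @param object an \code{"fmp_joint"} fit.
#' @param dic compute the deviance information criterion (adds a pass over
#'   all draws; default FALSE).
#' @param ... unused.
#' @return an object of class \code{"summary.fmp_joint"}.
#' @export
summary.fmp_joint <- function(object, dic = FALSE, ...) {
  tab <- summary_table(object)
  sig <- tab[, "lower"] > 0 | tab[, "upper"] < 0
  out <- list(model = object$model, K = object$K,
              n = object$fd$n, n_events = sum(object$fd$event),
              n_draws = object$n_stored,
              coef = cbind(tab, significant = as.numeric(sig)),
              sigma_aft = mean(sqrt(object$draws$sigma2_aft)),
              pi = colMeans(object$draws$pi),
              dic = if (dic) compute_dic(object) else NULL)
  class(out) <- "summary.fmp_joint"
  out
}

#' @export
print.summary.fmp_joint <- function(x, digits = 3, ...) {
  cat(sprintf("Lognormal AFT model %s jointly fit with a %d-class GGMM\n",
              x$model, x$K))
  cat(sprintf("  %d subjects (%d FMP events), %d posterior draws\n",
              x$n, x$n_events, x$n_draws))
  cat(sprintf("  class weights: %s\n",
              paste(sprintf("%.2f", x$pi), collapse = " / ")))
  tab <- x$coef
  fmt <- cbind(
    Value = sprintf(paste0("%.", digits, "f"), tab[, "mean"]),
    `95% CI` = sprintf(paste0("%.", digits, "f, %.", digits, "f"),
                       tab[, "lower"], tab[, "upper"]),
    ` ` = ifelse(tab[, "significant"] > 0, "*", ""))
  rownames(fmt) <- rownames(tab)
  print(fmt, quote = FALSE)
  cat(sprintf("  AFT residual SD: %.3f\n", x$sigma_aft))
  if (!is.null(x$dic))
    cat(sprintf("  DIC: %.1f (p_D = %.1f)\n", x$dic[["DIC"]], x$dic[["p_D"]]))
  invisible(x)
}

#' @export
coef.fmp_joint <- function(object, ...) {
  colMeans(object$draws$gamma)
}

#' Predict FMP age for new subjects
#'
#' Builds the AFT design row per subject from supplied trajectory features
#' and covariates, forms the per-draw linear predictor, and reports the
#' posterior-median-scale prediction \eqn{40 + \exp(\overline{lp})} with a
#' 95\% credible interval from the per-draw predictions
#' \eqn{40 + \exp(lp^{(d)})}.
#'
#' @param object an \code{"fmp_joint"} fit.
#' @param newdata data.frame with columns as required by the fitted model:
#'   \code{class} (1 = early riser, 2 = late riser); \code{fsh} (FSH level in
#'   mIU/mL at the class reference age: 40 for class 1, 45 for class 2) or
#'   explicit \code{mu40}/\code{mu45} on the log scale; \code{nu40},
#'   \code{nu45}, \code{omega} when the model uses them; \code{bmi},
#'   \code{amh}, \code{smoker}, \code{race} as required.
#' @param ... unused.
#' @return data.frame with \code{fit} (predicted FMP age, years),
#'   \code{lower}, \code{upper}.
#' @export
predict.fmp_joint <- function(object, newdata, ...) {
  nd <- as.data.frame(newdata)
  m <- nrow(nd)
  getcol <- function(nm, default = NA_real_) {
    if (nm %in% names(nd)) nd[[nm]] else rep(default, m)
  }
  D <- as.numeric(getcol("class", 2) >= 2)
  mu40 <- getcol("mu40"); mu45 <- getcol("mu45")
  if ("fsh" %in% names(nd)) {
    lf <- log(nd$fsh)
    mu40 <- ifelse(is.na(mu40) & D == 0, lf, mu40)
    mu45 <- ifelse(is.na(mu45) & D == 1, lf, mu45)
  }
  feats <- list(D = D,
                mu40 = ifelse(is.na(mu40), 0, mu40),
                mu45 = ifelse(is.na(mu45), 0, mu45),
                nu40 = getcol("nu40", 0), nu45 = getcol("nu45", 0),
                omega = getcol("omega", 0))
  amh <- getcol("amh", NA)
  x <- cbind(bmi_log = log(getcol("bmi", exp(mean(log(28))))),
             amh_q2 = getcol("amh_q2", 0), amh_q3 = getcol("amh_q3", 0),
             amh_q4 = getcol("amh_q4", 0),
             amh_high = if (all(is.na(amh))) getcol("amh_high", 0)
                        else as.numeric(amh > 0.83),
             smoker = getcol("smoker", 0), race = getcol("race", 0))
  out <- matrix(NA_real_, m, 3,
                dimnames = list(NULL, c("fit", "lower", "upper")))
  for (j in seq_len(m)) {
    row <- design_row(object$model,
                      lapply(feats, `[`, j),
                      x[j, ])
    lp <- drop(object$draws$gamma %*% row)
    out[j, ] <- c(40 + exp(mean(lp)),
                  40 + exp(stats::quantile(lp, 0.025, names = FALSE)),
                  40 + exp(stats::quantile(lp, 0.975, names = FALSE)))
  }
  as.data.frame(out)
}

#' Cox-Snell residual diagnostic of the fitted AFT submodel
#'
#' Evaluates residuals at the posterior means; censored subjects contribute
#' censored residuals at their censoring age.
#'
#' @param object an \code{"fmp_joint"} fit.
#' @param threshold,window passed to \code{\link{cox_snell_residuals}}.
#' @param ... unused.
#' @return list from \code{\link{cox_snell_residuals}}.
#' @export
residuals.fmp_joint <- function(object, threshold = 0.2, window = 2, ...) {
  fd <- object$fd
  lp <- posterior_mean_lp(object)
  time <- ifelse(fd$event, fd$T_obs, fd$C_obs)
  cox_snell_residuals(time, fd$event, lp, mean(object$draws$sigma2_aft),
                      threshold = threshold, window = window)
}

# posterior mean AFT linear predictor per fitted subject
posterior_mean_lp <- function(fit) {
  fd <- fit$fd
  S <- fit$n_stored
  lp <- matrix(0, S, fd$n)
  for (sidx in seq_len(S)) {
    st <- draw_state(fit, sidx)
    lp[sidx, ] <- aft_lp_full(st, fd, fit$model, NULL)
  }
  colMeans(lp)
}

# reconstruct a sampler-state view of stored draw sidx
draw_state <- function(fit, sidx) {
  d <- fit$draws
  list(D = d$D[sidx, ], beta = matrix(d$beta[sidx, , ], ncol = fit$K),
       b = cbind(d$b0[sidx, ], d$b1[sidx, ]),
       omega = d$omega[sidx, ], sigma2_i = exp(d$omega[sidx, ]),
       pi = d$pi[sidx, ], eta = d$eta[sidx, ], tau2 = d$tau2[sidx],
       psi2 = d$psi2[sidx, ], w = d$w[sidx, ],
       gamma = d$gamma[sidx, ], sigma2_aft = d$sigma2_aft[sidx],
       logT = d$logT[sidx, ])
}

#' Simulate FMP ages from the fitted AFT submodel
#'
#' Draws outcome times for the fitted subjects from randomly chosen posterior
#' draws (features and coefficients of the same draw), i.e. from the
#' posterior predictive of the outcome submodel.
#'
#' @param object an \code{"fmp_joint"} fit.
#' @param nsim number of replicate outcome vectors.
#' @param seed optional RNG seed.
#' @param ... unused.
#' @return matrix \code{n_subjects x nsim} of simulated FMP ages.
#' @export
simulate.fmp_joint <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  fd <- object$fd
  out <- matrix(NA_real_, fd$n, nsim)
  picks <- sample.int(object$n_stored, nsim, replace = TRUE)
  for (j in seq_len(nsim)) {
    st <- draw_state(object, picks[j])
    lp <- aft_lp_full(st, fd, object$model, NULL)
    out[, j] <- 40 + exp(stats::rnorm(fd$n, lp, sqrt(st$sigma2_aft)))
  }
  out
}

#' Plot fitted class-mean trajectories
#'
#' Observed log-FSH measurements (grey) overlaid with the posterior-mean
#' class trajectories and pointwise 95\% credible bands.
#'
#' @param x an \code{"fmp_joint"} fit.
#' @param ages evaluation grid (default: range of observed ages).
#' @param ... passed to \code{matplot}.
#' @export
plot.fmp_joint <- function(x, ages = NULL, ...) {
  fd <- x$fd
  if (is.null(ages)) ages <- seq(min(fd$t), max(fd$t), length.out = 100)
  B <- basis_row(x$basis, ages, 0)
  graphics::plot(fd$t, fd$y, pch = 16, cex = 0.3, col = "grey70",
                 xlab = "Age (years)", ylab = "log FSH (mIU/mL)", ...)
  cols <- seq_len(x$K) + 1
  for (k in seq_len(x$K)) {
    curves <- B %*% t(x$draws$beta[, , k])
    graphics::lines(ages, rowMeans(curves), col = cols[k], lwd = 2)
    graphics::lines(ages, apply(curves, 1, stats::quantile, 0.025),
                    col = cols[k], lty = 2)
    graphics::lines(ages, apply(curves, 1, stats::quantile, 0.975),
                    col = cols[k], lty = 2)
  }
  graphics::legend("topleft", bty = "n", lwd = 2, col = cols,
                   legend = sprintf("class %d", seq_len(x$K)))
  invisible(x)
}
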