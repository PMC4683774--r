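# Model evaluation: DIC for choosing the number of trajectory classes,
# 10-fold cross-validated root PMSE of predicted FMP age for comparing the
# AFT designs, and comparison-table helpers.

# Gauss-Hermite nodes/weights (physicists' convention) via Golub-Welsch
gauss_hermite <- function(n) {
  i <- seq_len(n - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- J[cbind(i + 1, i)] <- sqrt(i / 2)
  e <- eigen(J, symmetric = TRUE)
  list(nodes = e$values, weights = sqrt(pi) * e$vectors[1, ]^2)
}

# Observed-data (class-marginalized) log-likelihood per subject for one
# parameter configuration. The latent class, the subject random
# intercept/slope and the within-subject log-variance omega are integrated
# out: conditional on the per-iteration t scale weights the visit vector is
# multivariate normal with covariance Z Psi Z' + diag(e^omega / w), so the
# random effects integrate analytically (rank-2 Woodbury) and omega is
# handled by Gauss-Hermite quadrature against N(eta_k, tau^2), with the AFT
# omega covariate inside the integral. Conditioning on the scale weights
# keeps the heavy-tailed t(4) residual representation exact -- replacing it
# with a plain Gaussian form lets extra mixture components soak up the tails
# and biases class-number selection upward -- while their large count makes
# their contribution to the deviance stable across K. A deviance
# conditioned on per-subject random effects, in contrast, cannot select the
# class count at all: plug-in effects absorb the class gap subject by
# subject.
marginal_loglik_subjects <- function(fit, st, gh_points = 13) {
  fd <- fit$fd
  n <- fd$n; K <- fit$K
  gh <- gauss_hermite(gh_points)
  pos <- aft_positions(fit$model)
  sd_a <- sqrt(st$sigma2_aft)
  evs <- fd$event & fd$observed
  cns <- !fd$event & fd$observed
  w <- rep_len(st$w, length(fd$y))
  # omega-independent per-subject sufficient statistics
  c1 <- as.numeric(fd$n_i)
  cw <- rowsum_vec(w, fd$s, n)
  cwz <- rowsum_vec(w * fd$zt, fd$s, n)
  cwzz <- rowsum_vec(w * fd$zt^2, fd$s, n)
  clogw <- rowsum_vec(log(w), fd$s, n)
  ll <- matrix(0, n, K)
  for (k in seq_len(K)) {
    ek <- fd$y - drop(fd$X %*% st$beta[, k])
    q0 <- rowsum_vec(w * ek^2, fd$s, n)
    S0 <- rowsum_vec(w * ek, fd$s, n)
    S1 <- rowsum_vec(w * ek * fd$zt, fd$s, n)
    # class-level AFT linear predictor at b = 0, without the omega term
    lp0 <- aft_lp_for_class(list(beta = st$beta,
                                 b = matrix(0, n, 2),
                                 omega = rep(0, n), D = rep(k - 1L, n),
                                 gamma = st$gamma), fd, fit$model, pos, k)
    node_ll <- matrix(-Inf, n, gh_points)
    for (j in seq_len(gh_points)) {
      om <- st$eta[k] + sqrt(2 * st$tau2) * gh$nodes[j]
      if (om < -600 || om > 600) next  # degenerate node (empty-class prior draw)
      ai <- exp(-om)
      m00 <- ai * cw + 1 / st$psi2[1]
      m01 <- ai * cwz
      m11 <- ai * cwzz + 1 / st$psi2[2]
      detM <- m00 * m11 - m01^2
      logdetS <- c1 * om - clogw + log(detM * st$psi2[1] * st$psi2[2])
      s0 <- ai * S0; s1 <- ai * S1
      quad <- ai * q0 - (m11 * s0^2 - 2 * m01 * s0 * s1 + m00 * s1^2) / detM
      lj <- -0.5 * (c1 * log(2 * pi) + logdetS + quad)
      lp_k <- lp0 + (if (pos$omega) st$gamma[pos$omega] * om else 0)
      if (any(evs))
        lj[evs] <- lj[evs] + stats::dnorm(log(fd$T_obs[evs] - 40),
                                          lp_k[evs], sd_a, log = TRUE)
      if (any(cns))  # censored subjects contribute Pr(T > C)
        lj[cns] <- lj[cns] + stats::pnorm(log(fd$C_obs[cns] - 40),
                                          lp_k[cns], sd_a,
                                          lower.tail = FALSE, log.p = TRUE)
      node_ll[, j] <- lj + log(gh$weights[j] / sqrt(pi))
    }
    mx <- apply(node_ll, 1, max)
    ll[, k] <- ifelse(is.finite(mx),
                      log(st$pi[k]) + mx + log(rowSums(exp(node_ll - mx))),
                      -Inf)
  }
  apply(ll, 1, logsumexp)
}

#' Deviance information criterion of a joint fit
#'
#' Observed-data DIC with latent classes marginalized and subject random
#' effects integrated out analytically (given the per-iteration scale
#' weights and within-subject variances):
#' \eqn{D^{(s)} = -2\sum_i \log \sum_k \pi_k f_{long}(y_i|k) f_{AFT}(T_i|k)},
#' \eqn{p_D = \bar D - D(\hat\theta)} with \eqn{\hat\theta} the
#' posterior means (guarded below by the best sampled deviance, so weakly
#' occupied mixture components cannot drive \eqn{p_D} negative), and
#' \eqn{DIC = \bar D + p_D}. Censored subjects contribute the lognormal
#' survival probability. Marginalizing the random intercept/slope is
#' essential for class-number selection: conditioned on per-subject effects,
#' a one-class fit can absorb the class gap subject by subject and the
#' deviance barely distinguishes K. The class-marginalized form is invariant
#' to coherent label permutation. The plug-in deviance \code{Dhat} is
#' returned for diagnostics.
#'
#' @param fit an \code{"fmp_joint"} (or \code{"fmp_draws"}) object.
#' @param every use every \code{every}-th stored draw (default 1 = all).
#' @return named vector with \code{DIC}, \code{p_D}, \code{Dbar},
#'   \code{Dhat}.
#' @export
compute_dic <- function(fit, every = 1) {
  stopifnot(inherits(fit, "fmp_draws"))
  idx <- seq(1, fit$n_stored, by = every)
  dev <- vapply(idx, function(sidx) {
    -2 * sum(marginal_loglik_subjects(fit, draw_state(fit, sidx)))
  }, numeric(1))
  d <- fit$draws
  st_bar <- list(
    D = d$D[fit$n_stored, ],   # unused by the marginalized form
    beta = matrix(apply(d$beta, c(2, 3), mean), ncol = fit$K),
    b = cbind(colMeans(d$b0), colMeans(d$b1)),
    omega = colMeans(d$omega),
    sigma2_i = colMeans(exp(d$omega)),
    pi = colMeans(d$pi), eta = colMeans(d$eta), tau2 = mean(d$tau2),
    psi2 = colMeans(d$psi2), w = colMeans(d$w),
    gamma = colMeans(d$gamma), sigma2_aft = mean(d$sigma2_aft),
    logT = colMeans(d$logT))
  dhat <- -2 * sum(marginal_loglik_subjects(fit, st_bar))
  # Guard against atypical plug-ins: with weakly occupied or role-swapping
  # mixture components the posterior-mean state can fit worse than sampled
  # states, driving p_D negative and spuriously rewarding extra classes.
  # The plug-in deviance is capped at the best sampled deviance.
  dhat <- min(dhat, min(dev))
  dbar <- mean(dev)
  p_d <- dbar - dhat
  c(DIC = dbar + p_d, p_D = p_d, Dbar = dbar, Dhat = dhat)
}

#' Choose the number of trajectory classes by DIC
#'
#' Fits the joint model for each candidate K and tabulates DIC.
#'
#' @param visits,outcomes data tables (or \code{visits} an
#'   \code{"fmp_cohort"}).
#' @param K_values candidate class counts (default 1:3).
#' @param model AFT model id.
#' @param ... passed to \code{\link{fmp_joint}}.
#' @return data.frame with K, DIC, p_D; attribute \code{"best"} holds the
#'   DIC-minimizing K.
#' @export
select_classes <- function(visits, outcomes = NULL, K_values = 1:3,
                           model = "M2", ...) {
  rows <- lapply(K_values, function(k) {
    fit <- fmp_joint(visits, outcomes, model = model, K = k, ...)
    dic <- compute_dic(fit)
    data.frame(K = k, DIC = dic[["DIC"]], p_D = dic[["p_D"]])
  })
  out <- do.call(rbind, rows)
  attr(out, "best") <- out$K[which.min(out$DIC)]
  out
}

#' Cross-validated root prediction error of FMP age
#'
#' Subjects with an observed FMP are partitioned into folds (seeded). For
#' each fold the joint model is refit with the held-out subjects' outcomes
#' masked: their longitudinal data stay in and their class membership is
#' driven by the longitudinal likelihood only, mimicking prospective
#' prediction. Predicted FMP age is \eqn{40 + \exp(\overline{lp_i})} (the
#' posterior mean linear predictor, i.e. the lognormal median); PMSE is the
#' mean squared error over all events on the year scale, with a 95\% interval
#' from the per-draw PMSE.
#'
#' @param visits,outcomes data tables (or \code{visits} an
#'   \code{"fmp_cohort"}).
#' @param model AFT model id.
#' @param K number of classes.
#' @param folds number of CV folds (default 10).
#' @param control sampler control (shorter chains than a final fit are
#'   customary here).
#' @param ... passed to \code{\link{fmp_joint}}.
#' @return list with \code{root_pmse}, \code{interval} (95\% from per-draw
#'   PMSE), \code{pmse}, \code{n_events}, \code{predictions} (per held-out
#'   event subject).
#' @export
cv_root_pmse <- function(visits, outcomes = NULL, model = "M2", K = 2,
                         folds = 10, control = fmp_control(), ...) {
  if (inherits(visits, "fmp_cohort")) {
    outcomes <- visits$outcomes
    visits <- visits$visits
  }
  ev_ids <- outcomes$subject_id[outcomes$event == 1]
  if (length(ev_ids) < folds)
    stop("need at least as many event subjects as folds")
  set.seed(control$seed)
  fold_of <- sample(rep_len(seq_len(folds), length(ev_ids)))
  sq_err <- numeric(0)
  pred_rows <- list()
  per_draw_sse <- NULL
  n_total <- 0
  for (f in seq_len(folds)) {
    held <- ev_ids[fold_of == f]
    fit <- fmp_joint(visits, outcomes, model = model, K = K,
                     control = control, mask_outcomes = held, ...)
    pos_held <- match(as.character(held), fit$fd$ids)
    pos_held <- pos_held[!is.na(pos_held)]   # held-out id may have < 6 visits
    if (!length(pos_held)) next
    S <- fit$n_stored
    lp <- matrix(0, S, length(pos_held))
    for (sidx in seq_len(S)) {
      st <- draw_state(fit, sidx)
      lp[sidx, ] <- aft_lp_full(st, fit$fd, fit$model, NULL)[pos_held]
    }
    T_true <- fit$fd$T_obs[pos_held]
    pred <- 40 + exp(colMeans(lp))
    sq_err <- c(sq_err, (T_true - pred)^2)
    pd <- (40 + exp(lp) - rep(T_true, each = S))^2
    sse <- rowSums(pd)
    per_draw_sse <- if (is.null(per_draw_sse)) sse else per_draw_sse + sse
    n_total <- n_total + length(pos_held)
    pred_rows[[f]] <- data.frame(subject_id = fit$fd$ids[pos_held],
                                 fold = f, observed = T_true,
                                 predicted = pred)
  }
  pmse <- mean(sq_err)
  per_draw_pmse <- per_draw_sse / n_total
  list(root_pmse = sqrt(pmse), pmse = pmse,
       interval = sqrt(stats::quantile(per_draw_pmse, c(0.025, 0.975),
                                       names = FALSE)),
       n_events = n_total,
       predictions = do.call(rbind, pred_rows))
}

#' Percentage PMSE reduction relative to a reference model
#'
#' \eqn{100 (PMSE_{ref} - PMSE_{model}) / PMSE_{ref}}.
#'
#' @param pmse_ref reference-model PMSE (e.g. the covariate-only model M0).
#' @param pmse_model comparison-model PMSE.
#' @return percentage reduction.
#' @export
pmse_reduction <- function(pmse_ref, pmse_model) {
  100 * (pmse_ref - pmse_model) / pmse_ref
}

#' Compare AFT designs by cross-validated prediction error
#'
#' @param visits,outcomes data (or \code{visits} an \code{"fmp_cohort"}).
#' @param models AFT model ids to compare.
#' @param ... passed to \code{\link{cv_root_pmse}}.
#' @return data.frame (model, root_pmse, lower, upper, pct_reduction_vs_first).
#' @export
compare_models_cv <- function(visits, outcomes = NULL, models = c("M0", "M2"),
                              ...) {
  res <- lapply(models, function(m)
    cv_root_pmse(visits, outcomes, model = m, ...))
  data.frame(model = models,
             root_pmse = vapply(res, `[[`, numeric(1), "root_pmse"),
             lower = vapply(res, function(r) r$interval[1], numeric(1)),
             upper = vapply(res, function(r) r$interval[2], numeric(1)),
             pct_reduction = vapply(res, function(r)
               pmse_reduction(res[[1]]$pmse, r$pmse), numeric(1)))
}
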