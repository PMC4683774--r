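# Joint MCMC sampler: systematic-scan Gibbs over the GGMM (scale weights,
# class spline coefficients, subject effects, within-subject log-variances,
# hierarchy parameters, class labels, class weights) and the AFT outcome
# model (censored-age imputation, regression coefficients, residual
# variance). The AFT likelihood feeds back into every update that moves a
# quantity appearing in its design row (omega_i via Metropolis; beta_k and
# b_i via Gaussian pseudo-observations, since the gated mu/nu features are
# linear in both).

#' Prior settings for the joint model
#'
#' Diffuse normals for spline polynomial coefficients, AFT coefficients and
#' class log-variance means; inverse-gamma(shape, rate) for all variances;
#' symmetric Dirichlet for class weights; hinge coefficients are
#' \eqn{N(0, \lambda_k^2)} with \eqn{\lambda_k^2} sampled (the smoothing
#' penalty).
#'
#' @param coef_var prior variance of unpenalized coefficients (default 1e6).
#' @param ig_shape,ig_rate inverse-gamma hyperparameters (default 0.01, 0.01).
#' @param dirichlet Dirichlet concentration for class weights (default 1).
#' @return named list of prior settings.
#' @export
fmp_priors <- function(coef_var = 1e6, ig_shape = 0.01, ig_rate = 0.01,
                       dirichlet = 1) {
  list(coef_var = coef_var, ig_shape = ig_shape, ig_rate = ig_rate,
       dirichlet = dirichlet)
}

#' Sampler run settings
#'
#' Production defaults are 25000 draws after 10000 burn-in; tests and
#' cross-validation use much shorter chains.
#'
#' @param n_burnin burn-in sweeps (default 10000).
#' @param n_draws stored post-burn-in sweeps before thinning (default 25000).
#' @param thin thinning interval (default 1).
#' @param seed RNG seed.
#' @param proposal_sd initial random-walk SD for the log sigma_i^2 step.
#' @param adapt adapt the proposal during burn-in toward 30-50% acceptance.
#' @param relabel_reference_age age at which class mean levels are ordered to
#'   fix label switching (default 42; the early-rise class is higher there).
#' @param verbose print progress with the current log-posterior every 1000
#'   sweeps.
#' @return named list of control settings.
#' @export
fmp_control <- function(n_burnin = 10000, n_draws = 25000, thin = 1,
                        seed = 1, proposal_sd = 0.5, adapt = TRUE,
                        relabel_reference_age = 42, verbose = FALSE) {
  stopifnot(n_burnin >= 0, n_draws > 0, thin >= 1, proposal_sd > 0)
  list(n_burnin = as.integer(n_burnin), n_draws = as.integer(n_draws),
       thin = as.integer(thin), seed = as.integer(seed),
       proposal_sd = proposal_sd, adapt = isTRUE(adapt),
       relabel_reference_age = relabel_reference_age,
       verbose = isTRUE(verbose))
}

# gamma-coefficient positions of the trajectory features per model id
aft_positions <- function(model_id) {
  switch(model_id,
         M0 = list(D = 0L, omega = 0L, mu40 = 0L, mu45 = 0L, nu40 = 0L, nu45 = 0L),
         M1 = list(D = 2L, omega = 3L, mu40 = 0L, mu45 = 0L, nu40 = 0L, nu45 = 0L),
         M2 = list(D = 2L, omega = 3L, mu40 = 4L, mu45 = 5L, nu40 = 0L, nu45 = 0L),
         M3 = list(D = 2L, omega = 3L, mu40 = 0L, mu45 = 0L, nu40 = 4L, nu45 = 5L),
         M4 = list(D = 2L, omega = 3L, mu40 = 4L, mu45 = 5L, nu40 = 6L, nu45 = 7L),
         Mfinal = list(D = 2L, omega = 0L, mu40 = 3L, mu45 = 4L, nu40 = 0L, nu45 = 0L),
         stop("unknown model_id: ", model_id))
}

# vectorized AFT design matrix (one row per subject)
build_design_matrix <- function(model_id, Dlate, omega, mu40, mu45, nu40,
                                nu45, xmat, amh_high, smoker) {
  g1 <- 1 - Dlate; g2 <- Dlate
  m <- switch(model_id,
    M0 = cbind(1, xmat),
    M1 = cbind(1, Dlate, omega, xmat),
    M2 = cbind(1, Dlate, omega, mu40 * g1, mu45 * g2, xmat),
    M3 = cbind(1, Dlate, omega, nu40 * g1, nu45 * g2, xmat),
    M4 = cbind(1, Dlate, omega, mu40 * g1, mu45 * g2, nu40 * g1, nu45 * g2,
               xmat),
    Mfinal = cbind(1, Dlate, mu40 * g1, mu45 * g2, amh_high, smoker),
    stop("unknown model_id: ", model_id))
  colnames(m) <- aft_coef_names(model_id)
  m
}

# Assemble the flat per-observation / per-subject structures the sampler
# iterates over. `visits` long table (subject_id, age, fsh), `outcomes` one
# row per subject. Subjects with fewer than min_visits visits are dropped
# with a message (study inclusion criterion).
prepare_fit_data <- function(visits, outcomes, n_knots = 10, min_visits = 6,
                             log_scale = TRUE, amh_cutpoints = NULL,
                             mask_outcomes = NULL) {
  need_v <- c("subject_id", "age", "fsh")
  miss <- setdiff(need_v, names(visits))
  if (length(miss)) stop("longitudinal table missing column(s): ",
                         paste(miss, collapse = ", "))
  need_o <- c("subject_id", "fmp_age", "censor_age", "event", "bmi", "amh",
              "smoker", "race")
  miss <- setdiff(need_o, names(outcomes))
  if (length(miss)) stop("outcome table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(!is.finite(visits$age)) || any(!is.finite(visits$fsh)))
    stop("non-finite age or fsh in longitudinal table")

  counts <- table(visits$subject_id)
  keep_ids <- names(counts)[counts >= min_visits]
  keep_ids <- keep_ids[keep_ids %in% as.character(outcomes$subject_id)]
  dropped <- length(counts) - length(keep_ids)
  if (dropped > 0)
    message(sprintf("dropping %d subject(s) with fewer than %d visits",
                    dropped, min_visits))
  if (length(keep_ids) < 2) stop("fewer than 2 usable subjects")

  v <- visits[as.character(visits$subject_id) %in% keep_ids, ]
  v <- v[order(match(as.character(v$subject_id), keep_ids), v$age), ]
  o <- outcomes[match(keep_ids, as.character(outcomes$subject_id)), ]
  n <- length(keep_ids)
  s <- match(as.character(v$subject_id), keep_ids)
  if (any(duplicated(paste(s, v$age)))) stop("duplicate visit ages within subject")

  y <- if (log_scale) log(v$fsh) else v$fsh
  # centered/decade-scaled time axis: identical function space, far better
  # conditioned normal equations
  basis <- fmp_basis(v$age, n_interior_knots = n_knots, center = 40,
                     scale = 10)
  X <- basis_row(basis, v$age, 0)
  zt <- v$age - T_REF

  ev <- as.logical(o$event)
  T_obs <- ifelse(ev, o$fmp_age, NA_real_)
  C_obs <- ifelse(ev, NA_real_, o$censor_age)
  if (any(ev & !(T_obs > 40))) stop("observed FMP ages must exceed 40")
  if (any(!ev & !(C_obs > 40))) stop("censoring ages must exceed 40")

  amh_q <- bin_amh(o$amh, "quartiles", cutpoints = amh_cutpoints)
  xmat <- cbind(bmi_log = log(o$bmi),
                amh_q2 = as.numeric(amh_q == 2),
                amh_q3 = as.numeric(amh_q == 3),
                amh_q4 = as.numeric(amh_q == 4),
                smoker = as.numeric(o$smoker),
                race = as.numeric(o$race))
  observed <- rep(TRUE, n)
  if (!is.null(mask_outcomes))
    observed[keep_ids %in% as.character(mask_outcomes)] <- FALSE

  list(ids = keep_ids, n = n, s = s, t = v$age, y = y, zt = zt,
       X = X, basis = basis,
       x40 = drop(basis_row(basis, 40, 0)), x45 = drop(basis_row(basis, 45, 0)),
       d40 = drop(basis_row(basis, 40, 1)), d45 = drop(basis_row(basis, 45, 1)),
       n_i = as.integer(tabulate(s, n)),
       event = ev, T_obs = T_obs, C_obs = C_obs,
       xmat = xmat, amh_high = as.numeric(o$amh > 0.83),
       smoker = as.numeric(o$smoker), observed = observed,
       outcomes = o)
}

#' Initialize sampler state
#'
#' Class labels from k-means clustering of each subject's least-squares FSH
#' slope over ages at or below 45 (subjects with fewer than 2 such visits are
#' assigned by overall-level distance); class spline coefficients from
#' per-cluster ridge fits; within-subject variances from per-subject residual
#' variances floored at 1e-4; scale weights at 1; censored FMP ages imputed
#' at censoring age + 1.
#'
#' @param fd prepared fit data (internal; from the fitting entry points).
#' @param K number of classes.
#' @param model_id AFT model id.
#' @param seed RNG seed for the k-means start.
#' @return list of initial state components.
#' @keywords internal
initialize_state <- function(fd, K, model_id, seed = 1) {
  set.seed(seed)
  n <- fd$n; p <- fd$basis$dim
  # Per-subject discriminating feature: mean log-FSH over the 41-46 window,
  # where an early rise has already happened but a late rise has not. For
  # subjects without two visits there, fall back to the least-squares slope
  # over ages <= 45 (an early riser climbs sooner), then to overall level.
  slope <- rep(NA_real_, n); level <- numeric(n); win <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    idx <- which(fd$s == i)
    level[i] <- mean(fd$y[idx])
    inw <- idx[fd$t[idx] >= 41 & fd$t[idx] <= 46]
    if (length(inw) >= 2) win[i] <- mean(fd$y[inw])
    pre <- idx[fd$t[idx] <= 45]
    if (length(pre) >= 2)
      slope[i] <- stats::cov(fd$t[pre], fd$y[pre]) / stats::var(fd$t[pre])
  }
  if (K == 1) {
    D <- rep(0L, n)
  } else {
    feat <- win
    miss <- !is.finite(feat)
    if (any(miss) && any(!miss)) {
      # map the fallback features onto the window-mean scale by rank matching
      fb <- ifelse(is.finite(slope), level + 2 * slope, level)
      feat[miss] <- stats::quantile(feat[!miss],
                                    probs = rank(fb[miss]) / (sum(miss) + 1),
                                    names = FALSE)
    } else if (all(miss)) feat <- level
    km <- stats::kmeans(feat, centers = K, nstart = 10)
    D <- km$cluster - 1L
  }
  beta <- matrix(0, p, K)
  for (k in seq_len(K)) {
    idx <- which(fd$s %in% which(D == k - 1L))
    if (length(idx) < p) idx <- seq_along(fd$s)
    Xk <- fd$X[idx, , drop = FALSE]
    beta[, k] <- solve(crossprod(Xk) + diag(0.1, p), crossprod(Xk, fd$y[idx]))
  }
  # order initial clusters so index 0 is the early riser (higher level at 42)
  lev42 <- drop(basis_row(fd$basis, 42, 0) %*% beta)
  ord <- order(lev42, decreasing = TRUE)
  beta <- beta[, ord, drop = FALSE]
  D <- match(D + 1L, ord) - 1L
  sigma2_i <- numeric(n)
  for (i in seq_len(n)) {
    idx <- which(fd$s == i)
    r <- fd$y[idx] - drop(fd$X[idx, , drop = FALSE] %*% beta[, D[i] + 1L])
    sigma2_i[i] <- max(stats::var(r) * (length(r) - 1) / length(r), 1e-4)
    if (!is.finite(sigma2_i[i])) sigma2_i[i] <- 1e-4
  }
  omega <- log(sigma2_i)
  counts <- tabulate(D + 1L, K)
  logT <- ifelse(fd$event, log(fd$T_obs - 40), log(fd$C_obs + 1 - 40))
  q <- aft_dim(model_id)
  gamma <- numeric(q)
  gamma[1] <- mean(logT[fd$observed])
  list(D = D, beta = beta, b = matrix(0, n, 2), omega = omega,
       sigma2_i = sigma2_i, w = rep(1, length(fd$y)),
       pi = pmax(counts, 1) / sum(pmax(counts, 1)),
       lambda2 = rep(1, K), eta = rep(mean(omega), K),
       tau2 = max(stats::var(omega), 0.01),
       psi2 = c(0.04, 0.0025),
       gamma = gamma, sigma2_aft = max(stats::var(logT[fd$observed]), 0.01),
       logT = logT)
}

# per-subject trajectory features under each subject's CURRENT class
current_features <- function(fd, st) {
  xb40 <- drop(crossprod(fd$x40, st$beta))  # K-vector
  xb45 <- drop(crossprod(fd$x45, st$beta))
  db40 <- drop(crossprod(fd$d40, st$beta))
  db45 <- drop(crossprod(fd$d45, st$beta))
  k <- st$D + 1L
  list(mu40 = xb40[k] + st$b[, 1],
       mu45 = xb45[k] + st$b[, 1] + 5 * st$b[, 2],
       nu40 = db40[k] + st$b[, 2],
       nu45 = db45[k] + st$b[, 2])
}

# observation-level class mean (no subject effects)
obs_class_mean <- function(fd, beta, D, s) {
  mu <- numeric(length(fd$y))
  for (k in seq_len(ncol(beta))) {
    idx <- which(D[s] == k - 1L)
    if (length(idx))
      mu[idx] <- drop(fd$X[idx, , drop = FALSE] %*% beta[, k])
  }
  mu
}

#' Run the joint MCMC sampler
#'
#' Executes the systematic-scan Gibbs sweep described in the package
#' vignette: (1) t scale weights; (2) class spline coefficients and smoothing
#' variances; (3) subject random effects; (4) log within-subject variances by
#' adaptive random-walk Metropolis whose acceptance ratio includes both the
#' longitudinal and the AFT likelihood; (5) variance-hierarchy parameters;
#' (6) class labels from full joint responsibilities; (7) class weights;
#' (8) truncated-normal imputation of censored FMP ages; (9) AFT
#' coefficients; (10) AFT residual variance.
#'
#' Most users should call \code{\link{fmp_joint}} instead; this is the raw
#' engine returning unrelabelled draws.
#'
#' @param visits long-format longitudinal table (subject_id, age, fsh).
#' @param outcomes one-row-per-subject outcome table (subject_id, fmp_age,
#'   censor_age, event, bmi, amh, smoker, race).
#' @param model_id AFT model: "M0".."M4" or "Mfinal".
#' @param K number of latent trajectory classes.
#' @param priors from \code{\link{fmp_priors}}.
#' @param control from \code{\link{fmp_control}}.
#' @param n_knots number of interior spline knots (default 10).
#' @param min_visits inclusion criterion (default 6 measurements).
#' @param mask_outcomes optional subject ids whose outcomes are treated as
#'   unobserved (used by cross-validation; their longitudinal data stay in).
#' @param fix named list of state components to hold fixed (testing hook):
#'   any of \code{w}, \code{sigma2_i}, \code{lambda2}, \code{sigma2_aft},
#'   \code{beta}, \code{b}, \code{D}, \code{pi}, \code{psi2}, \code{eta},
#'   \code{tau2}.
#' @param amh_cutpoints optional fixed AMH quartile cutpoints.
#' @return object of class \code{"fmp_draws"}: stored chains of all
#'   parameters and per-subject latent summaries, acceptance rates, and
#'   config/seed provenance.
#' @export
run_mcmc <- function(visits, outcomes, model_id = "M2", K = 2,
                     priors = fmp_priors(), control = fmp_control(),
                     n_knots = 10, min_visits = 6, mask_outcomes = NULL,
                     fix = list(), amh_cutpoints = NULL) {
  model_id <- match.arg(model_id, AFT_MODELS)
  fd <- prepare_fit_data(visits, outcomes, n_knots = n_knots,
                         min_visits = min_visits,
                         amh_cutpoints = amh_cutpoints,
                         mask_outcomes = mask_outcomes)
  set.seed(control$seed)
  st <- initialize_state(fd, K, model_id, seed = control$seed)
  for (nm in names(fix)) st[[nm]] <- fix[[nm]]
  if (!is.null(fix$sigma2_i)) st$omega <- log(st$sigma2_i)
  st$sigma2_i <- exp(st$omega)

  n <- fd$n; p <- fd$basis$dim; N <- length(fd$y)
  q <- aft_dim(model_id)
  pos <- aft_positions(model_id)
  nu <- 4
  pc <- priors$coef_var
  a0 <- priors$ig_shape; b0 <- priors$ig_rate
  obs_sub <- which(fd$observed)
  cens_sub <- which(!fd$event & fd$observed)
  n_out <- length(obs_sub)

  # initial sanity: finite likelihood
  mu0 <- obs_class_mean(fd, st$beta, st$D, fd$s) + st$b[fd$s, 1] +
    st$b[fd$s, 2] * fd$zt
  if (any(!is.finite(mu0)) || any(!is.finite(st$logT)))
    stop("non-finite likelihood at initialization")

  S <- control$n_draws %/% control$thin
  out <- list(
    pi = matrix(NA_real_, S, K),
    beta = array(NA_real_, c(S, p, K)),
    lambda2 = matrix(NA_real_, S, K),
    eta = matrix(NA_real_, S, K), tau2 = numeric(S),
    psi2 = matrix(NA_real_, S, 2),
    gamma = matrix(NA_real_, S, q,
                   dimnames = list(NULL, aft_coef_names(model_id))),
    sigma2_aft = numeric(S),
    D = matrix(NA_integer_, S, n), omega = matrix(NA_real_, S, n),
    b0 = matrix(NA_real_, S, n), b1 = matrix(NA_real_, S, n),
    logT = matrix(NA_real_, S, n), w = matrix(NA_real_, S, N)
  )
  step <- control$proposal_sd
  acc_cnt <- 0; acc_tot <- 0; acc_window <- 0; acc_window_n <- 0
  empty_streak <- 0L
  total <- control$n_burnin + control$n_draws
  stored <- 0L

  for (sw in seq_len(total)) {
    k_of_obs <- st$D[fd$s] + 1L

    ## (1) t scale weights w_ij
    mu_obs <- obs_class_mean(fd, st$beta, st$D, fd$s) + st$b[fd$s, 1] +
      st$b[fd$s, 2] * fd$zt
    r <- fd$y - mu_obs
    if (is.null(fix$w))
      st$w <- stats::rgamma(N, (nu + 1) / 2,
                            rate = (nu + r^2 / st$sigma2_i[fd$s]) / 2)

    u <- st$w / st$sigma2_i[fd$s]       # per-observation precision weight

    ## (2) class spline coefficients + smoothing variances
    if (is.null(fix$beta)) {
      e_sub <- fd$y - st$b[fd$s, 1] - st$b[fd$s, 2] * fd$zt
      for (k in seq_len(K)) {
        sub_k <- which(st$D == k - 1L)
        idx <- which(k_of_obs == k)
        prior_prec <- c(rep(1 / pc, 4), rep(1 / st$lambda2[k], p - 4))
        A <- diag(prior_prec, p)
        rhs <- numeric(p)
        if (length(idx)) {
          Xk <- fd$X[idx, , drop = FALSE]
          A <- A + crossprod(Xk, Xk * u[idx])
          rhs <- rhs + drop(crossprod(Xk, u[idx] * e_sub[idx]))
        }
        # AFT pseudo-observations: gated features are linear in beta_k
        ok_sub <- intersect(sub_k, obs_sub)
        if (length(ok_sub) && (pos$mu40 || pos$mu45 || pos$nu40 || pos$nu45)) {
          early <- st$D[ok_sub] == 0L
          cmu <- ifelse(early, if (pos$mu40) st$gamma[pos$mu40] else 0,
                        if (pos$mu45) st$gamma[pos$mu45] else 0)
          cnu <- ifelse(early, if (pos$nu40) st$gamma[pos$nu40] else 0,
                        if (pos$nu45) st$gamma[pos$nu45] else 0)
          # rows: early -> cmu*x40 + cnu*d40 ; late -> cmu*x45 + cnu*d45
          arows <- outer(ifelse(early, cmu, 0), fd$x40) +
            outer(ifelse(early, 0, cmu), fd$x45) +
            outer(ifelse(early, cnu, 0), fd$d40) +
            outer(ifelse(early, 0, cnu), fd$d45)
          lp_all <- aft_lp_full(st, fd, model_id, pos)
          beta_part <- drop(arows %*% st$beta[, k])
          v <- st$logT[ok_sub] - (lp_all[ok_sub] - beta_part)
          A <- A + crossprod(arows) / st$sigma2_aft
          rhs <- rhs + drop(crossprod(arows, v)) / st$sigma2_aft
        }
        ch <- chol(A)
        m <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
        st$beta[, k] <- m + backsolve(ch, stats::rnorm(p))
      }
    }
    if (is.null(fix$lambda2) && p > 4) {
      for (k in seq_len(K)) {
        hinge <- st$beta[5:p, k]
        st$lambda2[k] <- rinvgamma1(1, a0 + (p - 4) / 2,
                                    b0 + sum(hinge^2) / 2)
      }
    }

    ## (3) subject random effects b_i (longitudinal + AFT pseudo-obs)
    if (is.null(fix$b)) {
      mu_cls <- obs_class_mean(fd, st$beta, st$D, fd$s)
      e <- fd$y - mu_cls
      S11 <- rowsum_vec(u, fd$s, n) + 1 / st$psi2[1]
      S12 <- rowsum_vec(u * fd$zt, fd$s, n)
      S22 <- rowsum_vec(u * fd$zt^2, fd$s, n) + 1 / st$psi2[2]
      r1 <- rowsum_vec(u * e, fd$s, n)
      r2 <- rowsum_vec(u * e * fd$zt, fd$s, n)
      if (pos$mu40 || pos$mu45 || pos$nu40 || pos$nu45) {
        early <- st$D == 0L
        cmu <- ifelse(early, if (pos$mu40) st$gamma[pos$mu40] else 0,
                      if (pos$mu45) st$gamma[pos$mu45] else 0)
        cnu <- ifelse(early, if (pos$nu40) st$gamma[pos$nu40] else 0,
                      if (pos$nu45) st$gamma[pos$nu45] else 0)
        c1 <- cmu                                   # d lp / d b0
        c2 <- ifelse(early, cnu, 5 * cmu + cnu)     # d lp / d b1
        lp_all <- aft_lp_full(st, fd, model_id, pos)
        v <- st$logT - (lp_all - c1 * st$b[, 1] - c2 * st$b[, 2])
        use <- fd$observed
        S11 <- S11 + use * c1^2 / st$sigma2_aft
        S12 <- S12 + use * c1 * c2 / st$sigma2_aft
        S22 <- S22 + use * c2^2 / st$sigma2_aft
        r1 <- r1 + use * c1 * v / st$sigma2_aft
        r2 <- r2 + use * c2 * v / st$sigma2_aft
      }
      det <- S11 * S22 - S12^2
      V11 <- S22 / det; V22 <- S11 / det; V12 <- -S12 / det
      m1 <- V11 * r1 + V12 * r2
      m2 <- V12 * r1 + V22 * r2
      l11 <- sqrt(V11); l21 <- V12 / l11; l22 <- sqrt(pmax(V22 - V12^2 / V11, 1e-300))
      z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
      st$b <- cbind(m1 + l11 * z1, m2 + l21 * z1 + l22 * z2)
    }

    ## (4) log within-subject variances: adaptive random-walk Metropolis
    if (is.null(fix$sigma2_i)) {
      mu_obs <- obs_class_mean(fd, st$beta, st$D, fd$s) + st$b[fd$s, 1] +
        st$b[fd$s, 2] * fd$zt
      ssr_w <- rowsum_vec(st$w * (fd$y - mu_obs)^2, fd$s, n)
      om_new <- st$omega + stats::rnorm(n, 0, step)
      ll_old <- -0.5 * fd$n_i * st$omega - 0.5 * exp(-st$omega) * ssr_w
      ll_new <- -0.5 * fd$n_i * om_new - 0.5 * exp(-om_new) * ssr_w
      pr_old <- stats::dnorm(st$omega, st$eta[st$D + 1L], sqrt(st$tau2), log = TRUE)
      pr_new <- stats::dnorm(om_new, st$eta[st$D + 1L], sqrt(st$tau2), log = TRUE)
      lr <- ll_new - ll_old + pr_new - pr_old
      if (pos$omega) {   # omega is an AFT covariate: include outcome term
        lp <- aft_lp_full(st, fd, model_id, pos)
        lp_new <- lp + st$gamma[pos$omega] * (om_new - st$omega)
        lr <- lr + fd$observed *
          (stats::dnorm(st$logT, lp_new, sqrt(st$sigma2_aft), log = TRUE) -
           stats::dnorm(st$logT, lp, sqrt(st$sigma2_aft), log = TRUE))
      }
      acc <- log(stats::runif(n)) < lr
      st$omega[acc] <- om_new[acc]
      st$sigma2_i <- exp(st$omega)
      acc_cnt <- acc_cnt + sum(acc); acc_tot <- acc_tot + n
      acc_window <- acc_window + sum(acc); acc_window_n <- acc_window_n + n
      if (control$adapt && sw <= control$n_burnin && sw %% 100 == 0) {
        rate <- acc_window / acc_window_n
        step <- min(max(step * exp(rate - 0.4), 1e-3), 5)
        acc_window <- 0; acc_window_n <- 0
      }
    }

    ## (5) variance hierarchy: eta_k, tau2, psi2
    if (is.null(fix$eta)) {
      for (k in seq_len(K)) {
        omk <- st$omega[st$D == k - 1L]
        prec <- length(omk) / st$tau2 + 1 / pc
        m <- (sum(omk) / st$tau2) / prec
        st$eta[k] <- stats::rnorm(1, m, sqrt(1 / prec))
      }
    }
    if (is.null(fix$tau2))
      st$tau2 <- rinvgamma1(1, a0 + n / 2,
                            b0 + sum((st$omega - st$eta[st$D + 1L])^2) / 2)
    if (is.null(fix$psi2)) {
      st$psi2[1] <- rinvgamma1(1, a0 + n / 2, b0 + sum(st$b[, 1]^2) / 2)
      st$psi2[2] <- rinvgamma1(1, a0 + n / 2, b0 + sum(st$b[, 2]^2) / 2)
    }

    ## (6) class labels from joint responsibilities. The t scale weights are
    ## collapsed out (marginal t(4) likelihood): they are regenerated from
    ## their full conditional at the start of the next sweep before any
    ## other use, so this is a valid partially-collapsed move and mixes far
    ## better than conditioning on weights adapted to the current class.
    if (is.null(fix$D) && K > 1) {
      lp_mat <- matrix(0, n, K)
      e_sub <- fd$y - st$b[fd$s, 1] - st$b[fd$s, 2] * fd$zt
      sig_obs <- sqrt(st$sigma2_i[fd$s])
      for (k in seq_len(K)) {
        ek <- e_sub - drop(fd$X %*% st$beta[, k])
        lp_mat[, k] <- log(st$pi[k]) +
          rowsum_vec(dt_ls(ek, 0, sig_obs, df = nu), fd$s, n) +
          stats::dnorm(st$omega, st$eta[k], sqrt(st$tau2), log = TRUE)
        # AFT term with features recomputed under candidate class k
        lp_aft <- aft_lp_for_class(st, fd, model_id, pos, k)
        lp_mat[, k] <- lp_mat[, k] + fd$observed *
          stats::dnorm(st$logT, lp_aft, sqrt(st$sigma2_aft), log = TRUE)
      }
      mx <- lp_mat[cbind(seq_len(n), max.col(lp_mat))]
      pr <- exp(lp_mat - mx)
      pr <- pr / rowSums(pr)
      cp <- t(apply(pr, 1, cumsum))
      uu <- stats::runif(n)
      st$D <- as.integer(rowSums(uu > cp))
      counts <- tabulate(st$D + 1L, K)
      if (any(counts == 0)) {
        empty_streak <- empty_streak + 1L
        if (empty_streak == 50L)
          warning("a class has been empty for 50 consecutive sweeps")
      } else empty_streak <- 0L
    }

    ## (7) class weights
    if (is.null(fix$pi)) {
      counts <- tabulate(st$D + 1L, K)
      g <- stats::rgamma(K, priors$dirichlet + counts, 1)
      st$pi <- g / sum(g)
    }

    ## (8) impute censored FMP ages (truncated normal on the log scale)
    if (length(cens_sub)) {
      lp <- aft_lp_full(st, fd, model_id, pos)
      st$logT[cens_sub] <- rtnorm_lower(length(cens_sub),
                                        mean = lp[cens_sub],
                                        sd = sqrt(st$sigma2_aft),
                                        lower = log(fd$C_obs[cens_sub] - 40))
    }

    ## (9) AFT coefficients, joint conjugate normal
    fe <- current_features(fd, st)
    R <- build_design_matrix(model_id, as.numeric(st$D >= 1L), st$omega,
                             fe$mu40, fe$mu45, fe$nu40, fe$nu45,
                             fd$xmat, fd$amh_high, fd$smoker)
    Ro <- R[obs_sub, , drop = FALSE]
    if (is.null(fix$gamma)) {
      A <- crossprod(Ro) / st$sigma2_aft + diag(1 / pc, q)
      rhs <- drop(crossprod(Ro, st$logT[obs_sub])) / st$sigma2_aft
      ch <- chol(A)
      m <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
      st$gamma <- m + backsolve(ch, stats::rnorm(q))
    }

    ## (10) AFT residual variance
    if (is.null(fix$sigma2_aft)) {
      rss <- sum((st$logT[obs_sub] - drop(Ro %*% st$gamma))^2)
      st$sigma2_aft <- rinvgamma1(1, a0 + n_out / 2, b0 + rss / 2)
    }

    if (control$verbose && sw %% 1000 == 0)
      message(sprintf("sweep %d/%d  log-post(long lik) ~ %.1f  acc %.2f",
                      sw, total,
                      sum(dt_ls(r, 0, sqrt(st$sigma2_i[fd$s]))),
                      if (acc_tot) acc_cnt / acc_tot else NA))

    if (sw > control$n_burnin &&
        (sw - control$n_burnin) %% control$thin == 0) {
      stored <- stored + 1L
      out$pi[stored, ] <- st$pi
      out$beta[stored, , ] <- st$beta
      out$lambda2[stored, ] <- st$lambda2
      out$eta[stored, ] <- st$eta
      out$tau2[stored] <- st$tau2
      out$psi2[stored, ] <- st$psi2
      out$gamma[stored, ] <- st$gamma
      out$sigma2_aft[stored] <- st$sigma2_aft
      out$D[stored, ] <- st$D
      out$omega[stored, ] <- st$omega
      out$b0[stored, ] <- st$b[, 1]
      out$b1[stored, ] <- st$b[, 2]
      out$logT[stored, ] <- st$logT
      out$w[stored, ] <- rep_len(st$w, N)
    }
  }

  structure(list(
    draws = out, n_stored = stored, model = model_id, K = K,
    basis = fd$basis, fd = fd, priors = priors, control = control,
    acceptance_rate = if (acc_tot) acc_cnt / acc_tot else NA_real_,
    proposal_sd_final = step, seed = control$seed
  ), class = "fmp_draws")
}

#' Relabel stored draws to a canonical class order
#'
#' Mixture posteriors are invariant to permuting class indices ("label
#' switching"). Each stored iteration is re-indexed so classes are ordered by
#' decreasing class-mean level at the reference age (the early-rise class has
#' higher FSH at 42), with ties broken by the class-mean derivative and then
#' the original index. \code{D_i}, \code{pi}, \code{beta_k}, \code{lambda_k^2}
#' and \code{eta_k} are permuted coherently; the AFT design itself breaks the
#' label symmetry in a joint fit, so in practice this is a safeguard.
#'
#' @param fit an \code{"fmp_draws"} object from \code{\link{run_mcmc}}.
#' @param reference_age ordering age (default: the control setting, 42).
#' @return the \code{"fmp_draws"} object with classes in canonical order.
#' @export
relabel_draws <- function(fit, reference_age = NULL) {
  stopifnot(inherits(fit, "fmp_draws"))
  K <- fit$K
  if (K < 2) return(fit)
  if (is.null(reference_age)) reference_age <- fit$control$relabel_reference_age
  xr <- drop(basis_row(fit$basis, reference_age, 0))
  dr <- drop(basis_row(fit$basis, reference_age, 1))
  d <- fit$draws
  for (sidx in seq_len(fit$n_stored)) {
    B <- d$beta[sidx, , ]
    lev <- drop(crossprod(xr, B))
    rate <- drop(crossprod(dr, B))
    # empty classes carry prior-drawn (arbitrary) curves; keep them after the
    # occupied classes so they cannot scramble the canonical order
    occupied <- tabulate(d$D[sidx, ] + 1L, K) > 0
    ord <- order(-occupied, -lev, -rate, seq_len(K))
    if (identical(ord, seq_len(K))) next
    d$beta[sidx, , ] <- B[, ord]
    d$pi[sidx, ] <- d$pi[sidx, ord]
    d$lambda2[sidx, ] <- d$lambda2[sidx, ord]
    d$eta[sidx, ] <- d$eta[sidx, ord]
    d$D[sidx, ] <- match(d$D[sidx, ] + 1L, ord) - 1L
  }
  fit$draws <- d
  fit$relabelled <- TRUE
  fit
}

#' @export
print.fmp_draws <- function(x, ...) {
  cat(sprintf("Joint GGMM/AFT posterior draws: model %s, K = %d, %d stored draws (seed %d)\n",
              x$model, x$K, x$n_stored, x$seed))
  cat(sprintf("  subjects: %d;  omega Metropolis acceptance: %.2f\n",
              x$fd$n, x$acceptance_rate))
  invisible(x)
}

# sum of v by subject index, guaranteeing length n
rowsum_vec <- function(v, s, n) {
  out <- numeric(n)
  agg <- rowsum(v, s)
  out[as.integer(rownames(agg))] <- agg
  out
}

# linear predictor of the AFT model for all subjects at current state
aft_lp_full <- function(st, fd, model_id, pos) {
  fe <- current_features(fd, st)
  R <- build_design_matrix(model_id, as.numeric(st$D >= 1L), st$omega,
                           fe$mu40, fe$mu45, fe$nu40, fe$nu45,
                           fd$xmat, fd$amh_high, fd$smoker)
  drop(R %*% st$gamma)
}

# linear predictor if every subject were in class k (features recomputed)
aft_lp_for_class <- function(st, fd, model_id, pos, k) {
  n <- fd$n
  xb40 <- sum(fd$x40 * st$beta[, k]); xb45 <- sum(fd$x45 * st$beta[, k])
  db40 <- sum(fd$d40 * st$beta[, k]); db45 <- sum(fd$d45 * st$beta[, k])
  mu40 <- xb40 + st$b[, 1]
  mu45 <- xb45 + st$b[, 1] + 5 * st$b[, 2]
  nu40 <- db40 + st$b[, 2]
  nu45 <- db45 + st$b[, 2]
  R <- build_design_matrix(model_id, rep(as.numeric(k >= 2), n), st$omega,
                           mu40, mu45, nu40, nu45,
                           fd$xmat, fd$amh_high, fd$smoker)
  drop(R %*% st$gamma)
}

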