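# Joint MCMC sampler: determinism, initialization, draw-level invariants,
# relabelling, and exactness checks against closed forms / brute force.

test_that("identical seed and config give bit-identical draws", {
  co <- small_cohort(n = 60, seed = 1)
  f1 <- suppressMessages(run_mcmc(co$visits, co$outcomes, "M1", K = 2,
                                  control = quick_control(seed = 3,
                                                          n_burnin = 50,
                                                          n_draws = 80)))
  f2 <- suppressMessages(run_mcmc(co$visits, co$outcomes, "M1", K = 2,
                                  control = quick_control(seed = 3,
                                                          n_burnin = 50,
                                                          n_draws = 80)))
  expect_identical(f1$draws$gamma, f2$draws$gamma)
  expect_identical(f1$draws$beta, f2$draws$beta)
  expect_identical(f1$draws$D, f2$draws$D)
})

test_that("initialization recovers labels under constructed separation", {
  # two groups with clearly different pre-45 slopes, exact curves
  mk <- function(i, slope) {
    ages <- seq(38, 46, by = 1)
    data.frame(subject_id = i, age = ages,
               fsh = exp(2 + slope * (ages - 38) + rnorm(9, 0, 0.01)))
  }
  set.seed(2)
  visits <- do.call(rbind, c(lapply(1:8, mk, slope = 0.3),
                             lapply(9:20, mk, slope = 0.0)))
  outcomes <- data.frame(subject_id = 1:20, fmp_age = 50, censor_age = NA,
                         event = 1, bmi = 28, amh = runif(20, 0.2, 2),
                         smoker = 0, race = 0)
  fd <- fmpjoint:::prepare_fit_data(visits, outcomes, n_knots = 4)
  st <- fmpjoint:::initialize_state(fd, K = 2, "M1", seed = 1)
  # steep-slope group ends up in the early-riser slot (higher level at 42)
  expect_true(all(st$D[1:8] == st$D[1]))
  expect_true(all(st$D[9:20] == st$D[9]))
  expect_true(st$D[1] != st$D[9])
  expect_true(all(st$sigma2_i >= 1e-4))
  # K = 1: everyone in class 0
  st1 <- fmpjoint:::initialize_state(fd, K = 1, "M1", seed = 1)
  expect_true(all(st1$D == 0L))
  # imputed starting outcome for censored subjects sits above C
  outcomes2 <- outcomes
  outcomes2$event[1:5] <- 0
  outcomes2$censor_age[1:5] <- 48
  outcomes2$fmp_age[1:5] <- NA
  fd2 <- fmpjoint:::prepare_fit_data(visits, outcomes2, n_knots = 4)
  st2 <- fmpjoint:::initialize_state(fd2, K = 2, "M1", seed = 1)
  expect_true(all(exp(st2$logT[1:5]) + 40 > 48))
})

test_that("every stored draw satisfies the parameter-domain invariants", {
  co <- small_cohort(n = 80, seed = 6)
  fit <- suppressMessages(run_mcmc(co$visits, co$outcomes, "M2", K = 2,
                                   control = quick_control(seed = 2)))
  d <- fit$draws
  expect_true(all(abs(rowSums(d$pi) - 1) < 1e-12))
  expect_true(all(d$pi > 0))
  expect_true(all(d$lambda2 > 0) && all(d$tau2 > 0) && all(d$psi2 > 0))
  expect_true(all(d$sigma2_aft > 0))
  expect_true(all(d$D %in% 0:1))
  # imputed FMP ages exceed the censoring age in every draw
  cens <- which(!fit$fd$event)
  for (i in cens)
    expect_true(all(40 + exp(d$logT[, i]) > fit$fd$C_obs[i]))
})

test_that("relabelling orders classes by level at the reference age", {
  co <- small_cohort(n = 100, seed = 8)
  fit <- suppressMessages(run_mcmc(co$visits, co$outcomes, "M1", K = 2,
                                   control = quick_control(seed = 4)))
  rl <- relabel_draws(fit)
  xr <- fmpjoint:::basis_row(fit$basis, 42, 0)
  lev_diff <- vapply(seq_len(rl$n_stored), function(s)
    sum(xr * rl$draws$beta[s, , 1]) - sum(xr * rl$draws$beta[s, , 2]),
    numeric(1))
  expect_true(all(lev_diff > 0))
  # idempotence: already-canonical draws are unchanged
  rl2 <- relabel_draws(rl)
  expect_identical(rl2$draws$beta, rl$draws$beta)
  expect_identical(rl2$draws$D, rl$draws$D)
  # an artificially swapped iteration is restored
  sw <- rl
  sw$draws$beta[5, , ] <- sw$draws$beta[5, , 2:1]
  sw$draws$pi[5, ] <- sw$draws$pi[5, 2:1]
  sw$draws$eta[5, ] <- sw$draws$eta[5, 2:1]
  sw$draws$lambda2[5, ] <- sw$draws$lambda2[5, 2:1]
  sw$draws$D[5, ] <- 1L - sw$draws$D[5, ]
  fixed <- relabel_draws(sw)
  expect_equal(fixed$draws$beta[5, , ], rl$draws$beta[5, , ])
  expect_equal(fixed$draws$D[5, ], rl$draws$D[5, ])
})

test_that("with fixed variances the AFT posterior matches the GLS closed form", {
  # K = 1, M0 (fixed design), no censoring: gamma draws are iid from the
  # exact conjugate posterior, so the chain mean must sit within Monte Carlo
  # error of the closed-form posterior mean.
  co <- small_cohort(n = 120, seed = 10)
  outcomes <- co$outcomes
  outcomes$event <- 1
  outcomes$fmp_age <- co$truth$T_true[match(outcomes$subject_id,
                                            co$truth$subject_id)]
  outcomes$censor_age <- NA
  s2 <- 0.35^2
  fit <- suppressMessages(run_mcmc(co$visits, outcomes, "M0", K = 1,
                                   control = quick_control(seed = 5,
                                                           n_burnin = 100,
                                                           n_draws = 1500),
                                   fix = list(w = 1, sigma2_aft = s2,
                                              lambda2 = rep(1, 1))))
  fd <- fit$fd
  R <- cbind(1, fd$xmat)
  prec <- crossprod(R) / s2 + diag(1e-6, ncol(R))
  m_cf <- solve(prec, crossprod(R, log(fd$T_obs - 40)) / s2)
  pm <- colMeans(fit$draws$gamma)
  mcse <- apply(fit$draws$gamma, 2, sd) / sqrt(fit$n_stored)
  expect_true(all(abs(pm - drop(m_cf)) < 3.5 * mcse))
})

test_that("outcome feedback shifts the within-subject variance posterior", {
  # Two subjects with identical longitudinal data but opposite outcome
  # residuals; everything fixed except omega, with a nonzero AFT
  # coefficient on omega. The sampler's omega posterior must match a dense
  # quadrature of the exact 1-D conditional, and shift between subjects.
  ages <- seq(38, 48, by = 1)
  set.seed(77)
  y <- 2 + rnorm(length(ages), 0, 0.3)
  visits <- rbind(data.frame(subject_id = 1, age = ages, fsh = exp(y)),
                  data.frame(subject_id = 2, age = ages, fsh = exp(y)))
  outcomes <- data.frame(subject_id = 1:2,
                         fmp_age = c(40 + exp(2.6), 40 + exp(1.0)),
                         censor_age = NA, event = 1, bmi = 28, amh = 1,
                         smoker = 0, race = 0)
  alpha_om <- 1.2
  gamma_fixed <- c(1.8, 0, alpha_om, rep(0, 6))   # M1: intercept, D, omega, x
  p <- 8  # 4 knots + 4
  fit <- suppressMessages(run_mcmc(
    visits, outcomes, "M1", K = 1, min_visits = 6, n_knots = 4,
    control = quick_control(seed = 1, n_burnin = 500, n_draws = 4000,
                            proposal_sd = 0.6),
    fix = list(w = 1, beta = matrix(c(2, rep(0, p - 1)), p, 1),
               b = matrix(0, 2, 2), gamma = gamma_fixed,
               sigma2_aft = 0.25, lambda2 = 1, pi = 1, D = c(0L, 0L),
               eta = -2, tau2 = 0.5, psi2 = c(1, 1))))
  # exact 1-D posterior by quadrature (independent oracle)
  fd <- fit$fd
  post_mean <- function(i) {
    r2 <- sum((fd$y[fd$s == i] - 2)^2)
    n_i <- sum(fd$s == i)
    lt <- log(fd$T_obs[i] - 40)
    lp <- function(om) dnorm(om, -2, sqrt(0.5), log = TRUE) -
      0.5 * n_i * om - 0.5 * exp(-om) * r2 +
      dnorm(lt, 1.8 + alpha_om * om, 0.5, log = TRUE)
    og <- seq(-8, 4, by = 0.002)
    wts <- exp(lp(og) - max(lp(og)))
    sum(og * wts) / sum(wts)
  }
  m1 <- mean(fit$draws$omega[, 1]); m2 <- mean(fit$draws$omega[, 2])
  expect_equal(m1, post_mean(1), tolerance = 0.05)
  expect_equal(m2, post_mean(2), tolerance = 0.05)
  # larger outcome residual (given alpha_om > 0) pulls omega upward
  expect_gt(m1, m2)
})

test_that("credible intervals for the class effect attain nominal coverage", {
  # 20 seed-varied cohorts, short chains; the M1 class contrast has a known
  # implied truth under the generator. Binomial(20, 0.95) band: >= 16.
  hits <- 0
  truth <- fmpjoint:::generator_aft_truth("M1", cohort_config())[["Class 2 vs 1"]]
  for (s in 1:20) {
    co <- simulate_cohort(list(n_subjects = 200), seed = 500 + s)
    fit <- suppressMessages(fmp_joint(co, model = "M1", K = 2,
                                      control = quick_control(seed = s,
                                                              n_burnin = 300,
                                                              n_draws = 500)))
    ci <- quantile(fit$draws$gamma[, "Class 2 vs 1"], c(0.025, 0.975))
    hits <- hits + (truth >= ci[1] && truth <= ci[2])
  }
  expect_gte(hits, 16)
})

test_that("schema violations and degenerate inputs error clearly", {
  co <- small_cohort(n = 40, seed = 3)
  bad <- co$visits; names(bad)[3] <- "value"
  expect_error(suppressMessages(run_mcmc(bad, co$outcomes, "M1", 2,
                                         control = quick_control())),
               "fsh")
  bad_o <- co$outcomes; bad_o$bmi <- NULL
  expect_error(suppressMessages(run_mcmc(co$visits, bad_o, "M1", 2,
                                         control = quick_control())),
               "bmi")
})
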