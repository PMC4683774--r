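# DIC, cross-validated PMSE and posterior summaries.

test_that("a degenerate chain has zero effective parameters", {
  # everything fixed, no censoring: every stored draw is identical
  co <- small_cohort(n = 50, seed = 20)
  outcomes <- co$outcomes
  outcomes$event <- 1
  outcomes$fmp_age <- co$truth$T_true[match(outcomes$subject_id,
                                            co$truth$subject_id)]
  outcomes$censor_age <- NA
  p <- 14
  n_fit <- sum(table(co$visits$subject_id) >= 6)
  fit <- suppressMessages(fmp_joint(
    co$visits, outcomes, model = "M0", K = 1,
    control = quick_control(seed = 2, n_burnin = 10, n_draws = 50),
    fix = list(w = 1, sigma2_i = rep(0.1, n_fit), lambda2 = 1,
               sigma2_aft = 0.1, beta = matrix(c(2, rep(0, p - 1)), p, 1),
               b = matrix(0, n_fit, 2), D = rep(0L, n_fit), pi = 1,
               psi2 = c(1, 1), eta = -2.3, tau2 = 0.5,
               gamma = c(2, rep(0, 6)))))
  dic <- compute_dic(fit)
  expect_equal(dic[["p_D"]], 0, tolerance = 1e-8)
  expect_equal(dic[["DIC"]], dic[["Dbar"]], tolerance = 1e-8)
})

test_that("p_D approximates the free-parameter count in a conjugate toy", {
  # only the 7 AFT coefficients are free (known variance, no censoring):
  # classic DIC calibration gives p_D close to 7
  co <- small_cohort(n = 150, seed = 21)
  outcomes <- co$outcomes
  outcomes$event <- 1
  outcomes$fmp_age <- co$truth$T_true[match(outcomes$subject_id,
                                            co$truth$subject_id)]
  outcomes$censor_age <- NA
  n_fit <- sum(table(co$visits$subject_id) >= 6)
  p <- 14
  fit <- suppressMessages(fmp_joint(
    co$visits, outcomes, model = "M0", K = 1,
    control = quick_control(seed = 3, n_burnin = 100, n_draws = 2000),
    fix = list(w = 1, sigma2_i = rep(0.1, n_fit), lambda2 = 1,
               sigma2_aft = 0.35^2,
               beta = matrix(c(2, rep(0, p - 1)), p, 1),
               b = matrix(0, n_fit, 2), D = rep(0L, n_fit), pi = 1,
               psi2 = c(1, 1), eta = -2.3, tau2 = 0.5)))
  dic <- compute_dic(fit)
  expect_lt(abs(dic[["p_D"]] - 7) / 7, 0.2)
})

test_that("DIC is invariant to class relabelling", {
  co <- small_cohort(n = 80, seed = 22)
  fit <- suppressMessages(fmp_joint(co, model = "M1", K = 2,
                                    control = quick_control(seed = 4)))
  dic1 <- compute_dic(fit)
  # coherently permute the class indices of a block of iterations by hand;
  # for M1 the AFT side transforms as (a0, a1) -> (a0 + a1, -a1) because the
  # late-class indicator flips
  sw <- fit
  idx <- 1:20
  sw$draws$beta[idx, , ] <- sw$draws$beta[idx, , 2:1]
  sw$draws$pi[idx, ] <- sw$draws$pi[idx, 2:1]
  sw$draws$eta[idx, ] <- sw$draws$eta[idx, 2:1]
  sw$draws$lambda2[idx, ] <- sw$draws$lambda2[idx, 2:1]
  sw$draws$D[idx, ] <- 1L - sw$draws$D[idx, ]
  a1 <- sw$draws$gamma[idx, "Class 2 vs 1"]
  sw$draws$gamma[idx, "(Intercept)"] <-
    sw$draws$gamma[idx, "(Intercept)"] + a1
  sw$draws$gamma[idx, "Class 2 vs 1"] <- -a1
  dic2 <- compute_dic(sw)
  expect_equal(dic1[["Dbar"]], dic2[["Dbar"]], tolerance = 1e-8)
})

test_that("cross-validation partitions event subjects exactly once", {
  co <- small_cohort(n = 100, seed = 23)
  cv <- suppressMessages(cv_root_pmse(co, model = "M0", K = 1, folds = 5,
                                      control = quick_control(seed = 7,
                                                              n_burnin = 60,
                                                              n_draws = 100)))
  preds <- cv$predictions
  expect_false(any(duplicated(preds$subject_id)))
  fit_ids <- suppressMessages(
    fmpjoint:::prepare_fit_data(co$visits, co$outcomes))$ids
  ev_fit <- co$outcomes$subject_id[co$outcomes$event == 1 &
                                     co$outcomes$subject_id %in% as.numeric(fit_ids)]
  expect_setequal(preds$subject_id, ev_fit)
  expect_true(is.finite(cv$root_pmse) && cv$root_pmse > 0)
  expect_true(cv$interval[1] <= cv$interval[2])
})

test_that("PMSE is computed on back-transformed years (degenerate noise ~ 0)", {
  # outcome driven by covariates only, with vanishing residual noise; AMH
  # quartile effects are zeroed because cutpoints are recomputed on the
  # analysis subset and a re-binned subject would add spurious error
  co <- simulate_cohort(list(n_subjects = 150,
                             alpha = c(2.2, 0, 0, 0, 0),
                             theta = c(bmi_log = 0.1, amh_q2 = 0,
                                       amh_q3 = 0, amh_q4 = 0,
                                       smoker = -0.16, race = 0.05),
                             sigma_aft = 1e-3), seed = 24)
  cv <- suppressMessages(cv_root_pmse(co, model = "M0", K = 1, folds = 10,
                                      control = quick_control(seed = 8,
                                                              n_burnin = 100,
                                                              n_draws = 200)))
  expect_lt(cv$root_pmse, 0.1)
})

test_that("summaries match a direct percentile computation", {
  set.seed(30)
  chains <- cbind(a = rnorm(4000, 0, 1), b = rnorm(4000, 3, 0.1))
  fit <- fake_fit(chains, D_map = c(0L, 1L), model = "M0", K = 2)
  tab <- fmpjoint:::summary_table(fit)
  expect_equal(tab["a", "mean"], mean(chains[, "a"]))
  expect_equal(tab["a", "lower"], quantile(chains[, "a"], 0.025, names = FALSE))
  expect_equal(tab["b", "upper"], quantile(chains[, "b"], 0.975, names = FALSE))
  sm <- summary(fit)
  # symmetric posterior centered at 0: not significant; tight one at 3: is
  expect_equal(unname(sm$coef["a", "significant"]), 0)
  expect_equal(unname(sm$coef["b", "significant"]), 1)
  # constant chain: interval collapses to the constant
  fitc <- fake_fit(cbind(c = rep(1.7, 100)), D_map = 0L, model = "M0", K = 1)
  tc <- fmpjoint:::summary_table(fitc)
  expect_equal(unname(tc["c", ]), c(1.7, 1.7, 1.7))
})

test_that("percentage PMSE reduction is exposed as a derived field", {
  expect_equal(pmse_reduction(4, 3), 25)
  expect_equal(pmse_reduction(10, 10), 0)
})
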