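# Lognormal AFT designs M0-M4/Mfinal, censored-age imputation, effect
# transforms, Cox-Snell diagnostics.

feats_example <- function(D = 0) {
  list(D = D, mu40 = 2.1, mu45 = 2.6, nu40 = 0.12, nu45 = 0.31, omega = -2.2)
}
x_example <- c(bmi_log = log(28), amh_q2 = 1, amh_q3 = 0, amh_q4 = 0,
               amh_high = 0, smoker = 1, race = 0)

test_that("design rows have the documented dimensions and gating", {
  dims <- c(M0 = 7L, M1 = 9L, M2 = 11L, M3 = 11L, M4 = 13L, Mfinal = 6L)
  for (m in names(dims))
    expect_length(design_row(m, feats_example(), x_example), dims[[m]])

  # M0 is intercept + covariates
  expect_equal(unname(design_row("M0", feats_example(), x_example)),
               c(1, log(28), 1, 0, 0, 1, 0))

  # class gating: late-class subject zeroes the class-1 feature and vice versa
  r1 <- design_row("M2", feats_example(D = 1), x_example)
  expect_equal(unname(r1[["Class 1: mu(40)"]]), 0)
  expect_equal(unname(r1[["Class 2: mu(45)"]]), 2.6)
  r0 <- design_row("M2", feats_example(D = 0), x_example)
  expect_equal(unname(r0[["Class 1: mu(40)"]]), 2.1)
  expect_equal(unname(r0[["Class 2: mu(45)"]]), 0)

  expect_error(design_row("M9", feats_example(), x_example))
})

test_that("aft_loglik is the lognormal density on years past 40", {
  spec <- list(coef = c(1.5, rep(0, 6)), sigma2 = 1)
  row <- design_row("M0", feats_example(),
                    c(bmi_log = 0, amh_q2 = 0, amh_q3 = 0, amh_q4 = 0,
                      amh_high = 0, smoker = 0, race = 0))
  T_at_mode <- 40 + exp(1.5)
  expect_equal(aft_loglik(T_at_mode, spec, row), -0.5 * log(2 * pi))
  spec2 <- spec; spec2$sigma2 <- 4
  expect_equal(aft_loglik(T_at_mode, spec, row) -
                 aft_loglik(T_at_mode, spec2, row), log(2))
  # density oracle for an arbitrary case
  spec3 <- list(coef = rnorm(7), sigma2 = 0.35^2)
  row3 <- design_row("M0", feats_example(), x_example)
  T3 <- 51.2
  expect_equal(aft_loglik(T3, spec3, row3),
               dnorm(log(T3 - 40), sum(row3 * spec3$coef), 0.35, log = TRUE))
  expect_error(aft_loglik(39.5, spec, row), "exceed 40")
})

test_that("censored-age imputation respects truncation and closed-form moments", {
  set.seed(31)
  n <- 1e5
  C <- 48; m <- 1.8; s2 <- 0.35^2
  draws <- impute_censored_fmp(rep(C, n), m, s2)
  expect_true(all(draws > C))
  z <- log(draws - 40)
  mu_cf <- fmpjoint:::tnorm_lower_mean(m, sqrt(s2), log(C - 40))
  expect_lt(abs(mean(z) - mu_cf), 3 * sd(z) / sqrt(n))

  # degenerate truncation: C just above 40 leaves the normal untouched
  d0 <- impute_censored_fmp(rep(40 + 1e-12, n), m, s2)
  z0 <- log(d0 - 40)
  expect_lt(abs(mean(z0) - m), 3 * sqrt(s2 / n))
  expect_lt(abs(sd(z0) - sqrt(s2)), 3 * sqrt(s2 / (2 * n)))

  expect_error(impute_censored_fmp(39, m, s2), "exceed 40")
  expect_error(impute_censored_fmp(48, m, -1), "positive")
})

test_that("imputation draws pass a KS test against the analytic CDF", {
  set.seed(17)
  n <- 1e5
  C <- 50; m <- 1.9; s <- 0.4
  a <- log(C - 40)
  z <- log(impute_censored_fmp(rep(C, n), m, s^2) - 40)
  cdf <- function(q) (pnorm((q - m) / s) - pnorm((a - m) / s)) /
    pnorm((a - m) / s, lower.tail = FALSE)
  ks <- suppressWarnings(ks.test(z, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("far-tail truncation switches to rejection sampling and stays exact", {
  set.seed(23)
  m <- 0; s <- 0.2
  C <- 40 + exp(m + 6 * s)  # standardized truncation point = 6 > 5
  z <- log(impute_censored_fmp(rep(C, 2e4), m, s^2) - 40)
  expect_true(all(z > log(C - 40)))
  mu_cf <- fmpjoint:::tnorm_lower_mean(m, s, log(C - 40))
  expect_lt(abs(mean(z) - mu_cf), 4 * sd(z) / sqrt(2e4))
})

test_that("time ratios reproduce the printed worked-example transforms", {
  expect_equal(round(time_ratio(0.424), 2), 1.53)
  expect_equal(round(time_ratio(0.288), 2), 1.33)
  expect_equal(round(time_ratio(0.570), 2), 1.77)
  expect_equal(time_ratio(0), 1)
})

test_that("a positive class coefficient raises the predicted median FMP age", {
  spec <- list(coef = c(1.2, 0.424, 0, rep(0.1, 6)), sigma2 = 0.1)
  row0 <- design_row("M1", feats_example(D = 0), x_example)
  row1 <- design_row("M1", feats_example(D = 1), x_example)
  med <- function(row) 40 + exp(sum(row * spec$coef))
  expect_gt(med(row1), med(row0))
  # and the gap is exactly the time ratio on the years-past-40 scale
  expect_equal((med(row1) - 40) / (med(row0) - 40), time_ratio(0.424))
})

test_that("Cox-Snell residuals are exact at known survival and calibrate under the null", {
  # S(T) = e^{-1} exactly -> residual 1
  sigma2 <- 0.25
  lp <- 2
  z_star <- qnorm(exp(-1), lower.tail = FALSE)
  T_star <- 40 + exp(lp + sqrt(sigma2) * z_star)
  cs <- cox_snell_residuals(c(T_star, 50), c(TRUE, TRUE), c(lp, lp), sigma2)
  expect_equal(cs$residuals[1], 1, tolerance = 1e-10)

  # null calibration: data simulated from the fitted model passes >= 95/100.
  # Sample size chosen so the Nelson-Aalen sampling noise over [0, 2] sits
  # well inside the 0.2 deviation threshold.
  set.seed(61)
  n <- 1200
  pass <- logical(100)
  for (r in 1:100) {
    lp_i <- rnorm(n, 2, 0.3)
    T_i <- 40 + exp(rnorm(n, lp_i, 0.35))
    pass[r] <- cox_snell_residuals(T_i, rep(TRUE, n), lp_i, 0.35^2)$pass
  }
  expect_gte(mean(pass), 0.95)

  # censored subjects contribute censored residuals without breaking the check
  set.seed(63)
  lp_i <- rnorm(n, 2, 0.3)
  T_i <- 40 + exp(rnorm(n, lp_i, 0.35))
  C_i <- 40 + exp(rnorm(n, 2.6, 0.5))
  ev <- T_i <= C_i
  cs_c <- cox_snell_residuals(pmin(T_i, C_i), ev, lp_i, 0.35^2)
  expect_length(cs_c$residuals, n)
  expect_true(is.finite(cs_c$max_dev))

  # power: grossly mis-specified scale (x5) fails >= 90/100
  set.seed(62)
  fail <- logical(100)
  for (r in 1:100) {
    lp_i <- rnorm(n, 2, 0.3)
    T_i <- 40 + exp(rnorm(n, lp_i, 0.35))
    fail[r] <- !cox_snell_residuals(T_i, rep(TRUE, n), lp_i,
                                    (5 * 0.35)^2)$pass
  }
  expect_gte(mean(fail), 0.90)

  expect_error(cox_snell_residuals(c(50, 51), c(FALSE, FALSE), c(2, 2), 0.1),
               "no events")
})
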