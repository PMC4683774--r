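# Shared fixtures: small cohorts and short sampler controls keep the default
# test run fast; the acceptance tests use the full study-scale conditions.

quick_control <- function(seed = 1, n_burnin = 150, n_draws = 250, ...) {
  fmp_control(n_burnin = n_burnin, n_draws = n_draws, seed = seed, ...)
}

small_cohort <- function(n = 120, seed = 42, ...) {
  simulate_cohort(list(n_subjects = n, ...), seed = seed)
}

# tiny deterministic params/state for likelihood-level tests
toy_params <- function(K = 2, basis_dim = 4) {
  col <- c(2, 0.1, rep(0, basis_dim - 2))
  list(K = K, pi = rep(1 / K, K),
       beta = matrix(col, basis_dim, K),
       lambda2 = rep(1, K), eta = rep(-2.3, K), tau2 = 0.25,
       psi2 = c(0.0625, 0.0025), nu = 4)
}

toy_state <- function(D = 0L, b = c(0, 0), sigma2 = 0.1, w = 1) {
  list(D = D, b = b, sigma2 = sigma2,
       omega = if (sigma2 > 0) log(sigma2) else NA_real_, w = w)
}

# construct a minimal fmp_joint-shaped object from fixed chains (degenerate
# or fixture posteriors) for summary/report tests
fake_fit <- function(gamma_draws, D_map, model = "M2", K = 2,
                     subject_ids = seq_along(D_map), cohort_config = NULL) {
  S <- nrow(gamma_draws)
  structure(list(
    draws = list(gamma = gamma_draws,
                 D = matrix(rep(D_map, each = S), S, length(D_map)),
                 sigma2_aft = rep(0.1, S),
                 pi = matrix(1 / K, S, K)),
    n_stored = S, model = model, K = K,
    map_class = D_map,
    fd = list(n = length(D_map), event = rep(TRUE, length(D_map))),
    subjects = data.frame(subject_id = subject_ids, class = D_map + 1L),
    cohort_config = cohort_config
  ), class = c("fmp_joint", "fmp_draws"))
}
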