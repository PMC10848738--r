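test_that("time-constant cost is zero for a perfect fit and follows the formula", {
  p <- krill_params("RK")
  n <- 4
  sim <- simulate_krill(p, years = n, jan1_only = TRUE)
  obs <- sim$jan1[, c("year", "L", "J", "A")]
  cc <- cost_config()
  expect_lt(timeconstant_cost(p, obs, cc), 1e-8)

  # adults off by a factor e in one of two years, priors at the truth:
  # cost = alpha_A * 1 / n
  obs2 <- sim$jan1[1:2, c("year", "L", "J", "A")]
  obs2$A[1] <- obs2$A[1] * exp(1)
  expect_equal(timeconstant_cost(p, obs2, cc), cc$alpha_A * 1 / 2,
    tolerance = 1e-6)

  # two-year toy with all cohorts off by known factors: compare against a
  # direct spreadsheet-style evaluation of the weighted sum
  fac <- matrix(c(1.3, 0.7, 2.0, 0.9, 1.1, 0.5), 2, 3)
  obs3 <- sim$jan1[1:2, c("year", "L", "J", "A")]
  obs3$L <- obs3$L * fac[, 1]
  obs3$J <- obs3$J * fac[, 2]
  obs3$A <- obs3$A * fac[, 3]
  manual <- mean(
    cc$alpha_L * log(fac[, 1])^2 + cc$alpha_J * log(fac[, 2])^2 +
      cc$alpha_A * log(fac[, 3])^2
  )
  expect_equal(timeconstant_cost(p, obs3, cc), manual, tolerance = 1e-5)

  # prior penalty term
  p2 <- krill_params("RK", m_A = 0.51 * 1.1)
  expect_equal(
    timeconstant_cost(p2, obs, cc) -
      .01 * (0.1)^2 -
      timeconstant_cost(p2, obs, cost_config(lambda_prior = 1e-12)),
    0,
    tolerance = 1e-4
  )
  obs_bad <- obs
  obs_bad$L[2] <- 0
  expect_error(timeconstant_cost(p, obs_bad, cc), "year 2")
})

test_that("anomaly cost adds the ridge penalty on the loss anomalies", {
  p <- krill_params("RK")
  n <- 4
  an <- tibble::tibble(year = 1:n, delta_L = c(0, 0.5, 0, 0), delta_J = 0)
  sim <- simulate_krill(p, years = n, anomalies = an, jan1_only = TRUE)
  obs <- sim$jan1[, c("year", "L", "J", "A")]
  cc <- cost_config(lambda_anomaly = 0.01)
  # perfect data fit: only the penalty remains
  expect_equal(anomaly_cost(an, p, obs, cc), 0.01 * 0.25, tolerance = 1e-5)
  # zero anomalies equal the bare data term
  an0 <- tibble::tibble(year = 1:n, delta_L = 0, delta_J = 0)
  sim0 <- simulate_krill(p, years = n, jan1_only = TRUE)
  expect_equal(
    anomaly_cost(an0, p, obs, cc),
    krillab:::.data_term(sim0$jan1, obs, cc),
    tolerance = 1e-5
  )
  # arithmetic oracle on a toy: data term + lambda * sum of squares
  an2 <- tibble::tibble(year = 1:n, delta_L = c(0.2, -0.1, 0, 0.3),
    delta_J = c(0, 0.1, -0.2, 0))
  sim2 <- simulate_krill(p, years = n, anomalies = an2, jan1_only = TRUE)
  expect_equal(
    anomaly_cost(an2, p, obs, cc),
    krillab:::.data_term(sim2$jan1, obs, cc) +
      0.01 * sum(an2$delta_L^2 + an2$delta_J^2),
    tolerance = 1e-5
  )
})

test_that("sign-consistency significance applies the inclusive 95 percent rule", {
  mk <- function(n_neg, n_tot) {
    matrix(c(rep(-1, n_neg), rep(1, n_tot - n_neg)), ncol = 1)
  }
  best <- -0.5
  expect_true(classify_significance(mk(300, 300), best = best))
  expect_false(classify_significance(mk(280, 300), best = best))  # 93.3%
  expect_true(classify_significance(mk(285, 300), best = best))   # exactly 95%
  # zeros count against significance: 284 same-sign + 16 zeros is 94.7%
  m <- matrix(c(rep(-1, 284), rep(0, 16)), ncol = 1)
  expect_false(classify_significance(m, best = best))
  # a best value of zero is never significant
  expect_false(classify_significance(mk(300, 300), best = 0))
  expect_error(classify_significance(matrix(numeric(0), 0, 1)), "non-empty")
  expect_warning(classify_significance(mk(10, 10), best = best), "20 cycles")
})

test_that("time-constant fit recovers generating parameters", {
  p <- krill_params("RK")
  sim <- simulate_krill(p, years = 12, jan1_only = TRUE)
  obs <- sim$jan1[, c("year", "L", "J", "A")]
  fit <- fit_timeconstant(obs, "RK", seed = 1, n_starts = 2)
  est <- unlist(fit$params[krillab:::.FITTED_PARS])
  tru <- unlist(p[krillab:::.FITTED_PARS])
  expect_lt(max(abs(est - tru) / tru), 0.05)   # noise-free: within 5%
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(glance(fit)$n_years, 12)

  # a dominant prior pins the parameters to the priors
  obs_j <- obs
  obs_j$A <- obs_j$A * exp(c(0.3, -0.2, rep(0.1, 10)))
  fit_pin <- fit_timeconstant(obs_j, "RK", seed = 1, n_starts = 1,
    config = cost_config(lambda_prior = 1e6))
  est_pin <- unlist(fit_pin$params[krillab:::.FITTED_PARS])
  expect_lt(max(abs(est_pin - tru) / tru), 1e-3)
  expect_error(fit_timeconstant(obs[1:2, ], "RK"), "3 observation years")
})

test_that("anomaly fit recovers a small-instance optimum and reproduces its cost", {
  study <- toy_study(seed = 42, n_years = 8, obs_noise_sd = 0)
  p <- study$cfg$params
  cc <- cost_config(lambda_anomaly = 0.01)
  fit <- suppressWarnings(fit_anomalies(
    study$observations, p, config = cc,
    n_primary = 2, n_final = 8, evals_per_cycle = 2000, seed = 1
  ))
  # stored best cost is reproducible from the stored anomalies + ICs
  p_fit <- p
  p_fit[c("L0", "J0", "A0")] <- as.list(fit$init)
  expect_equal(
    anomaly_cost(fit$anomalies, p_fit, study$observations, cc,
      method = "rk4"),
    fit$cost, tolerance = 1e-12
  )
  # small-instance oracle: a deep local descent started from the truth
  # does not beat the two-stage search by more than 1%
  n <- 8
  x_true <- c(study$anomalies$delta_L, study$anomalies$delta_J,
    log(unlist(p[c("L0", "J0", "A0")])))
  obj <- function(x) {
    anomaly_cost(
      tibble::tibble(year = 1:n, delta_L = x[1:n], delta_J = x[n + 1:n]),
      {
        pp <- p
        pp[c("L0", "J0", "A0")] <- as.list(exp(x[2 * n + 1:3]))
        pp
      },
      study$observations, cc, method = "rk4"
    )
  }
  oracle <- stats::optim(x_true, obj, method = "L-BFGS-B",
    lower = c(rep(-3, 2 * n), log(c(0.01, 0.01, 0.01))),
    upper = c(rep(3, 2 * n), log(c(100, 100, 100))),
    control = list(maxit = 500))
  expect_lt(fit$cost, oracle$value * 1.01)
  # the retained cycles all sit within 2% of the best cost
  expect_true(all(fit$cycle_costs <= fit$cost * 1.02))
})

test_that("stronger anomaly regularization shrinks the fitted anomalies", {
  study <- toy_study(seed = 43, n_years = 8, obs_noise_sd = 0.1)
  p <- study$cfg$params
  mean_abs <- vapply(lambda_anomaly_grid(), function(lam) {
    fit <- suppressWarnings(fit_anomalies(
      study$observations, p,
      config = cost_config(lambda_anomaly = lam),
      n_primary = 1, n_final = 3, evals_per_cycle = 1500, seed = 7
    ))
    mean(abs(c(fit$anomalies$delta_L, fit$anomalies$delta_J)))
  }, numeric(1))
  expect_true(all(diff(mean_abs) <= 1e-8))
  # the ridge limit pushes the anomalies toward zero
  expect_lt(mean_abs[length(mean_abs)], 0.6 * mean_abs[1])
})

test_that("anomaly estimates are invariant under cycle relabeling", {
  # significance flags depend on the set of retained cycles, not their order
  set.seed(1)
  cycles <- matrix(rnorm(50 * 4, mean = c(1, -1, 0.02, 0)), 50, 4,
    byrow = TRUE)
  best <- c(1, -1, 0.02, 0)
  flags <- classify_significance(cycles, best)
  perm <- sample(50)
  expect_identical(flags, classify_significance(cycles[perm, ], best))
})
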