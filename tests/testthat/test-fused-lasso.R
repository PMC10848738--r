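test_that("the fused-LASSO objective matches hand arithmetic", {
  d <- manual_design(4, c(3), seed = 1, beta = c(1, 0, -1))
  a <- c(0.5, -0.2, 0.1)
  lam <- 0.05
  tau <- 0.03
  manual <- sum((d$y - 0.2 - drop(d$X %*% a))^2) / (2 * 4) +
    lam * sum(abs(a)) +
    tau * ((a[2] - a[1])^2 + (a[3] - a[2])^2)
  expect_equal(
    fused_lasso_objective(a, d, lam, tau, intercept = 0.2), manual
  )
  # all-zero coefficients with a centered response leave only the data term
  yc <- d$y - mean(d$y)
  d2 <- d
  d2$y <- yc
  expect_equal(fused_lasso_objective(numeric(3), d2, lam, tau),
    sum(yc^2) / 8)
  # both penalties off: the ordinary least-squares objective
  expect_equal(fused_lasso_objective(a, d, 0, 0, intercept = 0),
    sum((d$y - drop(d$X %*% a))^2) / 8)
})

test_that("fusion penalty couples only adjacent months within a block", {
  d <- manual_design(6, c(3, 3), seed = 2)
  a <- c(1, 2, 4, 8, 16, 32)
  # swapping whole blocks leaves the penalty structure intact
  d_swap <- d
  ord <- c(4:6, 1:3)
  d_swap$X <- d$X[, ord]
  d_swap$X_raw <- d$X_raw[, ord]
  d_swap$factor <- d$factor[ord]
  obj1 <- fused_lasso_objective(a, d, 0, 1)
  obj2 <- fused_lasso_objective(a[ord], d_swap, 0, 1)
  expect_equal(obj1, obj2)
  # permuting months inside a block changes the fusion penalty
  a_perm <- c(4, 1, 2, 8, 16, 32)
  expect_false(isTRUE(all.equal(
    fused_lasso_objective(a, d, 0, 1) - fused_lasso_objective(a, d, 0, 0),
    fused_lasso_objective(a_perm, d, 0, 1) -
      fused_lasso_objective(a_perm, d, 0, 0)
  )))
})

test_that("penalty limits: large lambda kills slopes, large tau fuses blocks", {
  d <- manual_design(20, c(4, 4), seed = 3,
    beta = c(1, 0.8, 0.6, 0.4, 0, 0, 0, 0), noise_sd = 0.3)
  f_big <- fused_lasso(d, lambda_l1 = 100, tau_fuse = 0)
  expect_equal(f_big$coefficients$estimate, rep(0, 8))
  expect_equal(f_big$intercept, mean(d$y))
  f_fuse <- fused_lasso(d, lambda_l1 = 1e-4, tau_fuse = 1e4)
  est <- f_fuse$coefficients$estimate
  expect_lt(max(abs(est[1:4] - mean(est[1:4]))), 1e-3)
  expect_lt(max(abs(est[5:8] - mean(est[5:8]))), 1e-3)
})

test_that("vanishing penalties reproduce ordinary least squares", {
  d <- manual_design(30, c(3, 3), seed = 4,
    beta = c(0.5, -0.5, 0.2, 0, 0.3, 0), noise_sd = 0.1)
  fit <- fused_lasso(d, lambda_l1 = 1e-8, tau_fuse = 0)
  ols <- stats::lm(d$y ~ d$X)
  expect_equal(fit$coefficients$estimate, unname(coef(ols)[-1]),
    tolerance = 1e-4)
  expect_equal(fit$intercept, unname(coef(ols)[1]), tolerance = 1e-4)
  # objective at the solution beats both the zero vector and the OLS point
  obj_fit <- fused_lasso_objective(fit$coefficients$estimate, d,
    1e-8, 0, fit$intercept)
  expect_lte(obj_fit,
    fused_lasso_objective(numeric(6), d, 1e-8, 0, mean(d$y)))
  expect_lte(obj_fit,
    fused_lasso_objective(unname(coef(ols)[-1]), d, 1e-8, 0,
      unname(coef(ols)[1])) + 1e-10)
})

test_that("solver matches an independent convex-programming oracle", {
  # the quadratic fusion term folds into an augmented LASSO, which an
  # independent coordinate-descent solver (glmnet) handles exactly
  d <- manual_design(10, c(3, 3), seed = 5,
    beta = c(1, 0.8, 0, 0, -0.5, 0), noise_sd = 0.2)
  lam <- 0.05
  tau <- 0.02
  fit <- fused_lasso(d, lam, tau)
  m <- 10
  D <- krillab:::.fusion_matrix(d$factor)
  Xa <- rbind(as.matrix(d$X), sqrt(2 * m * tau) * D)
  ya <- c(d$y - mean(d$y), rep(0, nrow(D)))
  g <- glmnet::glmnet(Xa, ya, alpha = 1, lambda = lam * m / (m + nrow(D)),
    standardize = FALSE, intercept = FALSE, thresh = 1e-14)
  oracle <- as.numeric(stats::coef(g))[-1]
  expect_equal(fit$coefficients$estimate, oracle, tolerance = 1e-4)
  expect_equal(
    fused_lasso_objective(fit$coefficients$estimate, d, lam, tau,
      fit$intercept),
    fused_lasso_objective(oracle, d, lam, tau, fit$intercept),
    tolerance = 1e-4
  )
})

test_that("solution path is stable under a small lambda perturbation", {
  d <- manual_design(25, c(4, 4), seed = 6,
    beta = c(1, 1, 0.5, 0, 0, 0, 0, 0), noise_sd = 0.2)
  f1 <- fused_lasso(d, 0.05, 0.01)
  f2 <- fused_lasso(d, 0.05 * 1.01, 0.01)
  rel <- sqrt(sum((f1$coefficients$estimate - f2$coefficients$estimate)^2)) /
    sqrt(sum(f1$coefficients$estimate^2))
  expect_lt(rel, 0.05)
})

test_that("prediction uses training standardization and is affine-invariant", {
  d <- manual_design(20, c(4), seed = 7, beta = c(1, 0.5, 0, -0.5),
    noise_sd = 0.1)
  fit <- fused_lasso(d, 0.01, 0.01)
  # rows at the training mean predict the intercept
  d_mean <- d
  d_mean$X_raw <- matrix(rep(d$center, each = 2), 2)
  colnames(d_mean$X_raw) <- colnames(d$X_raw)
  expect_equal(unname(predict(fit, d_mean)), rep(fit$intercept, 2))
  # rescaling raw inputs (and refitting) leaves predictions unchanged
  d_resc <- d
  d_resc$X_raw <- sweep(sweep(d$X_raw, 2, c(2, 3, 4, 5), "*"), 2,
    c(-1, 0, 1, 2), "+")
  d_resc$center <- colMeans(d_resc$X_raw)
  d_resc$scale <- apply(d_resc$X_raw, 2, sd)
  d_resc$X <- sweep(sweep(d_resc$X_raw, 2, d_resc$center), 2,
    d_resc$scale, "/")
  fit2 <- fused_lasso(d_resc, 0.01, 0.01)
  expect_equal(predict(fit2, d_resc), predict(fit, d), tolerance = 1e-6)
  # full-rank unpenalized training fit explains everything
  f0 <- fused_lasso(d, 1e-10, 0)
  sc <- predict_and_score(f0, d)
  expect_equal(sc$r_squared, summary(stats::lm(d$y ~ d$X))$r.squared,
    tolerance = 1e-4)
})

test_that("cross-validation bookkeeping and diagnostics behave", {
  d <- manual_design(12, c(3), seed = 8, beta = c(1, 1, 1), noise_sd = 0.1)
  folds <- krillab:::.make_folds(12, 12)
  expect_equal(length(folds), 12)            # K = m is leave-one-out
  expect_true(all(lengths(folds) == 1))
  expect_error(krillab:::.make_folds(5, 6), "K must satisfy")
  cv <- cv_fused_lasso(d, lambda_grid = 10^seq(-3, 0, length.out = 4),
    tau_grid = c(0.001, 0.1), K = 4)
  expect_equal(nrow(cv$surface), 8)
  expect_false(cv$no_signal)   # strong signal present
  # strong signal: the selected model beats the intercept-only limit
  best <- min(cv$surface$cv_error)
  intercept_only <- cv$surface$cv_error[
    cv$surface$lambda_l1 == max(cv$surface$lambda_l1)]
  expect_lt(best, min(intercept_only))
})

test_that("pure-noise responses trigger the no-signal diagnostic most of the time", {
  fires <- vapply(1:10, function(s) {
    d <- manual_design(20, c(4, 4), seed = 100 + s, beta = rep(0, 8),
      noise_sd = 1)
    cv_fused_lasso(d, lambda_grid = 10^seq(-3, 0.5, length.out = 5),
      tau_grid = c(0.01), K = 5)$no_signal
  }, logical(1))
  expect_gte(mean(fires), 0.6)
})

test_that("subset enumeration covers all 15 models and prefers parsimony", {
  study <- toy_study(seed = 45, n_years = 15)
  an <- tibble::tibble(year = study$anomalies$year,
    delta = study$anomalies$delta_L)
  sel <- select_factor_subset(an, study$env,
    lambda_grid = 10^seq(-2, 0, length.out = 3),
    tau_grid = c(0.01, 0.3), K = 5)
  expect_equal(nrow(sel$table), 15)
  expect_equal(anyDuplicated(sel$table$subset), 0)
  expect_equal(sum(sel$table$n_factors == 1), 4)
  expect_equal(sum(sel$table$selected), 1)
  # a duplicated driver column cannot justify a two-factor model: ties
  # break toward fewer factors
  env_dup <- study$env
  dup <- env_dup[env_dup$factor == "SAM", ]
  dup$factor <- "SAM2"
  env_dup <- rbind(env_dup, dup)
  sel2 <- select_factor_subset(an, env_dup, factors = c("SAM", "SAM2"),
    lambda_grid = 10^seq(-2, 0, length.out = 3),
    tau_grid = c(0.01), K = 5,
    smooth_factors = c("SAM", "SAM2"))
  expect_equal(sel2$table$n_factors[sel2$table$selected], 1)
})

test_that("factor importance ranks the generating driver first", {
  study <- toy_study(seed = 46, n_years = 20)
  an <- tibble::tibble(year = study$anomalies$year,
    delta = study$anomalies$delta_L)    # SAM-driven by construction
  sel <- select_factor_subset(an, study$env,
    lambda_grid = 10^seq(-2, 0, length.out = 3),
    tau_grid = c(0.01, 0.3), K = 5)
  imp <- factor_importance(sel)
  expect_equal(imp$factor[1], "SAM")
  expect_true(grepl("SAM", sel$selected_subset))
  # all-zero coefficient ensemble gives zero importance
  sel_zero <- sel
  sel_zero$models <- lapply(sel$models, function(m) {
    m$coefficients$estimate[] <- 0
    m
  })
  expect_true(all(factor_importance(sel_zero)$importance == 0))
})

test_that("bootstrap bands shrink to the truth on exact linear data", {
  set.seed(9)
  m <- 30
  X <- matrix(rnorm(m * 3), m, 3)
  colnames(X) <- paste0("A_m", 1:3)
  beta <- c(1, 0.6, -0.4)
  d <- manual_design(m, c(3))
  d$X_raw <- X
  d$center <- colMeans(X)
  d$scale <- apply(X, 2, sd)
  d$X <- sweep(sweep(X, 2, d$center), 2, d$scale, "/")
  d$y <- drop(d$X %*% beta)             # noise-free
  bb <- bootstrap_bands(d, lambda_l1 = 1e-8, tau_fuse = 0, B = 200,
    seed = 1)
  expect_true(all(bb$ci_low <= beta + 1e-6 & beta - 1e-6 <= bb$ci_high))
  expect_lt(max(bb$ci_high - bb$ci_low), 1e-4)
  expect_error(
    bootstrap_bands(d, 1e-8, 0, B = 1),
    "at least 200"
  )
})
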