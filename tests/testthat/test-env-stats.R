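test_that("outlier cleaning removes strictly above 5000 ind/1000 m^3", {
  s <- tibble::tibble(density = c(10, 4999, 5001))
  out <- suppressMessages(clean_samples(s))
  expect_equal(nrow(out), 2)
  expect_equal(attr(out, "n_removed"), 1)
  s2 <- tibble::tibble(density = 5000)
  expect_equal(nrow(clean_samples(s2)), 1)   # exactly 5000 is kept
  empty <- tibble::tibble(density = numeric(0))
  out3 <- clean_samples(empty)
  expect_equal(nrow(out3), 0)
  expect_equal(attr(out3, "n_removed"), 0)
  expect_error(clean_samples(tibble::tibble(density = -1)), "negative")
})

test_that("column abundance converts volumetric density by sampling depth", {
  s <- tibble::tibble(density = c(100, 0), depth = c(120, 80))
  out <- column_abundance(s)
  expect_equal(out$abundance, c(12, 0))
  # arithmetic oracle on a small table
  s5 <- tibble::tibble(density = c(5, 50, 500, 1000, 2500),
    depth = c(100, 150, 60, 120, 200))
  expect_equal(column_abundance(s5)$abundance, s5$density / 1000 * s5$depth)
  s_na <- tibble::tibble(density = c(1, 2), depth = c(NA, 50))
  expect_warning(out_na <- column_abundance(s_na), "missing depth")
  expect_equal(nrow(out_na), 1)
})

test_that("two-stage spatial binning de-weights resampled stations", {
  base <- tibble::tibble(
    year = 1, latitude = c(-65.01, -65.02, -65.03, -65.6),
    longitude = c(-70.1, -70.15, -70.2, -71.3),
    density = c(1, 2, 3, 10) * 1000, depth = 1,
    juvenile_fraction = 0
  )
  out <- bin_and_average(base)
  expect_equal(out$A, (2 + 10) / 2)   # bin means (2, 10), not pooled mean 4
  # singleton bins reduce to the simple mean
  spread <- base
  spread$latitude <- c(-64, -65, -66, -67)
  expect_equal(bin_and_average(spread)$A, mean(c(1, 2, 3, 10)))
  # juvenile fraction splits the areal abundance
  jf <- tibble::tibble(year = 2, latitude = -65, longitude = -70,
    density = 8000, depth = 1, juvenile_fraction = 0.25)
  out_jf <- bin_and_average(jf)
  expect_equal(out_jf$J, 2)
  expect_equal(out_jf$A, 6)
})

test_that("trailing moving average matches direct convolution", {
  expect_equal(moving_average(rep(3, 20))[9:20], rep(3, 12))
  expect_true(all(is.na(moving_average(rep(3, 20))[1:8])))
  x <- rep(0, 30)
  x[12] <- 1
  ma <- moving_average(x)
  expect_equal(ma[12:20], rep(1 / 9, 9))
  expect_equal(ma[c(9:11, 21:30)], rep(0, 13))
  expect_equal(moving_average(1:5, window = 1), as.numeric(1:5))
  expect_error(moving_average(1:5, window = 0), "window")
  # adding a constant commutes; white-noise variance drops by ~1/9
  set.seed(1)
  z <- rnorm(3000)
  expect_equal(moving_average(z + 5), moving_average(z) + 5)
  expect_equal(var(moving_average(z), na.rm = TRUE) / var(z), 1 / 9,
    tolerance = 0.15)
  # missing-value rule: >= 7 of 9 present
  z2 <- rep(1, 24)
  z2[c(10, 11, 12)] <- NA
  ma2 <- moving_average(z2)
  expect_true(all(is.na(ma2[12:18])))  # at most 6 of 9 present
  expect_false(is.na(ma2[19]))         # 7 of 9 present
  expect_equal(ma2[19], 1)
})

test_that("the 16-month cycle alignment runs Sep(Y-1) through Dec(Y)", {
  cm <- cycle_months()
  expect_equal(nrow(cm), 16)
  expect_equal(cm$month[c(1, 4, 5, 16)], c(9, 12, 1, 12))
  expect_equal(cm$year_offset[c(1, 4, 5, 16)], c(-1L, -1L, 0L, 0L))
  env <- tidyr::expand_grid(year = 0:3, month = 1:12)
  env$factor <- "X"
  env$value <- env$year * 100 + env$month
  M <- env_cycle_matrix(env, "X", years = 1:3)
  expect_equal(M[1, 1], 0 * 100 + 9)    # Sep of year 0
  expect_equal(M[1, 5], 1 * 100 + 1)    # Jan of year 1
  expect_equal(M[2, 16], 2 * 100 + 12)  # Dec of year 2
})

test_that("correlation screen flags a perfectly matching cell and respects scaling", {
  set.seed(2)
  env <- tidyr::expand_grid(year = 0:10, month = 1:12)
  env$factor <- "Chl"
  env$value <- rnorm(nrow(env))
  # anomalies equal to the standardized November values of each year
  nov <- env$value[env$month == 11 & env$year >= 1]
  an <- tibble::tibble(year = 1:10, delta = as.numeric(scale(nov)))
  scr <- correlation_screen(an, env, smooth_factors = character(0))
  cell <- scr[scr$label == "Nov", ]
  expect_equal(cell$r, 1, tolerance = 1e-12)
  expect_true(cell$significant)
  # affine rescaling of the factor leaves every correlation unchanged
  env2 <- env
  env2$value <- 3 * env2$value - 7
  scr2 <- correlation_screen(an, env2, smooth_factors = character(0))
  expect_equal(scr$r, scr2$r, tolerance = 1e-12)
  # too few overlapping years: cell not assessed
  an_short <- an[1:4, ]
  scr3 <- correlation_screen(an_short, env, smooth_factors = character(0))
  expect_true(all(is.na(scr3$r)))
  expect_s3_class(ggplot2::autoplot(scr), "ggplot")
})

test_that("a single-month driver is recovered as the column maximum", {
  cfg <- synthetic_config(seed = 5, n_years = 20,
    anomaly_coefficients = list(
      delta_L = tibble::tibble(factor = "Chl", cycle_month = 6, coef = 0.8),
      delta_J = tibble::tibble(factor = "T", cycle_month = 2, coef = 0.5)
    ),
    anomaly_noise_sd = 0.05)
  env <- gen_environment(cfg)
  an <- gen_anomalies(env, cfg)
  scr <- correlation_screen(
    tibble::tibble(year = an$year, delta = an$delta_L), env)
  chl <- scr[scr$factor == "Chl", ]
  expect_equal(chl$cycle_month[which.max(abs(chl$r))], 6)
})

test_that("recruit-versus-adult pairing and degenerate cases behave", {
  df <- tibble::tibble(year = 1:5, J = c(2, 4, 8, 16, 32),
    A = c(1, 2, 4, 8, 16))
  ra <- recruit_vs_adult(df)
  expect_equal(ra$n, 4)                 # overlap only
  expect_equal(ra$pairs$J_next, df$J[-1])
  expect_equal(ra$r, 1)
  const <- tibble::tibble(year = 1:4, J = c(1, 2, 3, 4), A = rep(2, 4))
  expect_true(is.na(recruit_vs_adult(const)$r))
  expect_error(recruit_vs_adult(df[1:2, ]), "3 years")
})

test_that("identity permutation reproduces the unpermuted stock-recruit correlation", {
  study <- toy_study(seed = 44, n_years = 8)
  pe <- permuted_anomaly_experiment(study$anomalies, study$cfg$params,
    n_permutations = 5, seed = 3)
  sim <- simulate_krill(study$cfg$params, years = 8,
    anomalies = study$anomalies, jan1_only = TRUE)
  expect_equal(attr(pe, "unpermuted_r"), recruit_vs_adult(sim$jan1)$r)
  expect_equal(nrow(pe), 5)
  expect_true(all(abs(pe$r) <= 1))
})
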