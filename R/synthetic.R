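#' Configuration of the synthetic study generator
#'
#' Bundles every choice the synthetic generators need: study length,
#' model preset, monthly environmental factor structure (seasonal cycle,
#' interannual AR(1) persistence, monthly noise), the sparse linear model
#' generating "true" loss anomalies from the environment, and the
#' multiplicative observation noise. Defaults emulate a 27-year Antarctic
#' coastal monitoring series: chlorophyll, temperature and ice follow
#' seasonal cycles with autocorrelated interannual anomalies; the
#' SAM-like climate index has no seasonal component; larval anomalies are
#' driven by a smooth run of winter-spring SAM months and juvenile
#' anomalies by autumn-winter temperature, mimicking coefficient runs that
#' are piecewise-smooth over adjacent months; observation noise is
#' lognormal with sd 0.3 on the log scale, echoing order-of-magnitude
#' abundance scatter.
#'
#' @param n_years number of observation years (>= 5; default 27).
#' @param seed integer seed; all generators are pure functions of
#'   `(config, seed)`.
#' @param preset model preset for the forward simulation.
#' @param factor_specs tibble with one row per factor: `factor`, `mean`,
#'   `seasonal_amp`, `peak_month`, `ar_coef`, `ar_sd`, `noise_sd`.
#' @param anomaly_coefficients list with elements `delta_L`, `delta_J`,
#'   each a tibble `factor`, `cycle_month`, `coef` on standardized
#'   predictors.
#' @param anomaly_intercepts named vector `c(L = , J = )`.
#' @param anomaly_noise_sd sd of the Gaussian noise added to the linear
#'   anomaly model.
#' @param obs_noise_sd sd of the lognormal observation noise on log
#'   abundance.
#' @param params model parameters (default the preset's).
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_years = 27, seed = 1,
                             preset = c("RK", "BH"),
                             factor_specs = default_factor_specs(),
                             anomaly_coefficients = default_anomaly_coefficients(),
                             anomaly_intercepts = c(L = 0, J = 0),
                             anomaly_noise_sd = 0.15,
                             obs_noise_sd = 0.3,
                             params = NULL) {
  preset <- match.arg(preset)
  stopifnot(
    n_years >= 5, anomaly_noise_sd >= 0, obs_noise_sd >= 0,
    all(abs(factor_specs$ar_coef) < 1)
  )
  if (is.null(params)) params <- krill_params(preset)
  structure(
    list(
      n_years = n_years, seed = seed, preset = preset,
      factor_specs = factor_specs,
      anomaly_coefficients = anomaly_coefficients,
      anomaly_intercepts = anomaly_intercepts,
      anomaly_noise_sd = anomaly_noise_sd,
      obs_noise_sd = obs_noise_sd, params = params
    ),
    class = "synthetic_config"
  )
}

#' @rdname synthetic_config
#' @export
default_factor_specs <- function() {
  tibble::tibble(
    factor = c("Chl", "T", "Ice", "SAM"),
    mean = c(1.5, 0.5, 0.5, 0),
    seasonal_amp = c(1.2, 1.5, 0.45, 0),
    peak_month = c(1, 2, 9, 1),
    ar_coef = c(0.5, 0.5, 0.5, 0.5),
    ar_sd = c(0.4, 0.3, 0.15, 0.8),
    noise_sd = c(0.2, 0.1, 0.05, 0.5)
  )
}

#' @rdname synthetic_config
#' @export
default_anomaly_coefficients <- function() {
  list(
    delta_L = tibble::tibble(factor = "SAM", cycle_month = 5:9, coef = 0.15),
    delta_J = tibble::tibble(factor = "T", cycle_month = 9:12, coef = 0.15)
  )
}

#' Generate a synthetic monthly environment table
#'
#' Per factor, the monthly value is a seasonal sinusoid (peaking at the
#' configured month) plus an interannual AR(1) anomaly shared by all
#' months of a year plus monthly white noise. Calendar years `0` through
#' `n_years` are produced so that the 16-month cycle of every anomaly
#' year (including year 1) is fully covered.
#'
#' @param config a [synthetic_config()].
#' @param seed seed override (default `config$seed`).
#' @return long tibble `year`, `month`, `factor`, `value`.
#' @export
gen_environment <- function(config, seed = config$seed) {
  set.seed(seed)
  years <- 0:config$n_years
  purrr::map_dfr(seq_len(nrow(config$factor_specs)), function(i) {
    sp <- config$factor_specs[i, ]
    ann <- numeric(length(years))
    innov <- stats::rnorm(length(years), 0, sp$ar_sd)
    ann[1] <- innov[1] / sqrt(max(1 - sp$ar_coef^2, 1e-12))
    for (k in seq_along(years)[-1]) {
      ann[k] <- sp$ar_coef * ann[k - 1] + innov[k]
    }
    grid <- expand.grid(month = 1:12, year = years)
    seasonal <- sp$mean +
      sp$seasonal_amp * cos(2 * pi * (grid$month - sp$peak_month) / 12)
    tibble::tibble(
      year = grid$year, month = grid$month, factor = sp$factor,
      value = seasonal + ann[match(grid$year, years)] +
        stats::rnorm(nrow(grid), 0, sp$noise_sd)
    )
  })
}

#' Generate "true" loss anomalies from the environment
#'
#' Forward application of the linear anomaly model: for each cohort the
#' anomaly of year `Y` is the intercept plus the configured coefficients
#' times the standardized environmental values on the 16-month cycle
#' (climate indices smoothed exactly as in [factor_design()]), plus
#' Gaussian noise.
#'
#' @param env environment table from [gen_environment()].
#' @param config a [synthetic_config()] (coefficients, intercepts, noise).
#' @param seed seed override.
#' @return anomaly tibble `year`, `delta_L`, `delta_J`; the deterministic
#'   (noise-free) parts are attached as attribute `linear_part`.
#' @export
gen_anomalies <- function(env, config, seed = config$seed) {
  n <- config$n_years
  years <- seq_len(n)
  smooth_factors <- c("SAM", "AAO", "SOI", "Nino3.4")
  lin <- lapply(c(L = "delta_L", J = "delta_J"), function(slot) {
    coefs <- config$anomaly_coefficients[[slot]]
    contrib <- rep(0, n)
    for (f in unique(coefs$factor)) {
      X <- env_cycle_matrix(env, f, years, smooth = f %in% smooth_factors)
      if (anyNA(X)) stop("environment does not cover the anomaly windows")
      Xs <- scale(X)
      sub <- coefs[coefs$factor == f, ]
      contrib <- contrib +
        as.numeric(Xs[, sub$cycle_month, drop = FALSE] %*% sub$coef)
    }
    contrib
  })
  set.seed(seed + 1L)
  out <- tibble::tibble(
    year = years,
    delta_L = config$anomaly_intercepts[["L"]] + lin$L +
      stats::rnorm(n, 0, config$anomaly_noise_sd),
    delta_J = config$anomaly_intercepts[["J"]] + lin$J +
      stats::rnorm(n, 0, config$anomaly_noise_sd)
  )
  attr(out, "linear_part") <- tibble::tibble(
    year = years, delta_L = lin$L, delta_J = lin$J
  )
  out
}

#' Generate noisy annual abundance observations
#'
#' Simulates the model under the true anomalies and multiplies each
#' 1 January sample by independent lognormal noise
#' `exp(N(0, obs_noise_sd^2))` per cohort and year.
#'
#' @param config a [synthetic_config()].
#' @param anomalies true anomaly table (e.g. from [gen_anomalies()]).
#' @param seed seed override.
#' @param obs_noise_sd noise sd override.
#' @return tibble `year`, `L`, `J`, `A`; the noise-free 1 January samples
#'   are attached as attribute `truth`.
#' @export
gen_observations <- function(config, anomalies, seed = config$seed,
                             obs_noise_sd = config$obs_noise_sd) {
  sim <- simulate_krill(config$params, years = config$n_years,
    anomalies = anomalies, jan1_only = TRUE)
  set.seed(seed + 2L)
  n <- config$n_years
  noise <- matrix(stats::rnorm(3 * n, 0, obs_noise_sd), n, 3)
  out <- tibble::tibble(
    year = seq_len(n),
    L = sim$jan1$L * exp(noise[, 1]),
    J = sim$jan1$J * exp(noise[, 2]),
    A = sim$jan1$A * exp(noise[, 3])
  )
  attr(out, "truth") <- sim$jan1[, c("year", "L", "J", "A")]
  out
}

#' Generate station-level sample tables
#'
#' Per year, stations on a latitude/longitude grid receive lognormally
#' overdispersed volumetric densities consistent with the annual mean
#' areal abundance (`density = abundance / depth * 1000`), sampling
#' depths, per-station juvenile fractions around the annual cohort split,
#' and (optionally) a fraction of extreme-density outliers above
#' 5000 ind/1000 m^3. With zero dispersion and no outliers, two-stage bin
#' averaging of the cleaned table recovers the annual truth exactly.
#'
#' @param annual tibble `year`, `J`, `A` (ind/m^2).
#' @param stations_per_year number of stations per year.
#' @param dispersion sd of the per-station lognormal factor (log scale).
#' @param outlier_rate probability that a station is replaced by an
#'   extreme-density outlier.
#' @param seed integer seed.
#' @param depth_range sampling depth range (m).
#' @return tibble `latitude`, `longitude`, `date`, `year`, `density`
#'   (ind/1000 m^3), `depth` (m), `juvenile_fraction`.
#' @export
gen_station_samples <- function(annual, stations_per_year = 50,
                                dispersion = 0.5, outlier_rate = 0,
                                seed = 1, depth_range = c(60, 160)) {
  set.seed(seed)
  purrr::map_dfr(seq_len(nrow(annual)), function(i) {
    yr <- annual$year[i]
    total <- annual$J[i] + annual$A[i]
    jf <- annual$J[i] / max(total, 1e-12)
    lat <- -68 + (seq_len(stations_per_year) %% 10) * 0.25 +
      stats::runif(stations_per_year, 0, 0.05)
    lon <- -78 + (seq_len(stations_per_year) %/% 10) * 0.5 +
      stats::runif(stations_per_year, 0, 0.05)
    depth <- stats::runif(stations_per_year, depth_range[1], depth_range[2])
    lnf <- if (dispersion > 0) {
      exp(stats::rnorm(stations_per_year, -dispersion^2 / 2, dispersion))
    } else {
      rep(1, stations_per_year)
    }
    density <- total / depth * 1000 * lnf
    out <- stats::runif(stations_per_year) < outlier_rate
    density[out] <- stats::runif(sum(out), 5001, 20000)
    jf_st <- if (dispersion > 0) {
      pmin(pmax(jf + stats::rnorm(stations_per_year, 0, 0.05), 0), 1)
    } else {
      rep(jf, stations_per_year)
    }
    tibble::tibble(
      latitude = lat, longitude = lon,
      date = as.Date(sprintf("%04d-01-15", yr)), year = yr,
      density = density, depth = depth, juvenile_fraction = jf_st
    )
  })
}

#' Write a complete synthetic toy study to a directory
#'
#' Generates environment, true anomalies, noisy observations, station
#' samples and the parameter set for one seeded configuration, and writes
#' them as the CSV schemas consumed by the analysis functions.
#'
#' @param dir output directory (created if needed).
#' @param config a [synthetic_config()].
#' @return invisibly, the vector of written file paths.
#' @export
make_fixtures <- function(dir, config = synthetic_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  env <- gen_environment(config)
  anoms <- gen_anomalies(env, config)
  obs <- gen_observations(config, anoms)
  stations <- gen_station_samples(obs[, c("year", "J", "A")],
    seed = config$seed)
  paths <- file.path(dir, c(
    "environment.csv", "anomalies_true.csv", "observations.csv",
    "stations.csv", "params.csv"
  ))
  utils::write.csv(env, paths[1], row.names = FALSE)
  utils::write.csv(anoms, paths[2], row.names = FALSE)
  utils::write.csv(obs, paths[3], row.names = FALSE)
  utils::write.csv(stations, paths[4], row.names = FALSE)
  write_params(config$params, paths[5])
  invisible(paths)
}
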