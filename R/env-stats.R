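#' Remove extreme-density outlier stations
#'
#' Drops station samples with krill density strictly greater than
#' 5000 ind/1000 m^3, the screening rule for implausibly dense net hauls.
#'
#' @param samples tibble with (at least) a `density` column, in individuals
#'   per 1000 m^3.
#' @param threshold removal threshold (strict).
#' @return the filtered tibble; the number of removed rows is attached as
#'   attribute `n_removed` and reported via a message.
#' @export
clean_samples <- function(samples, threshold = 5000) {
  if (any(samples$density < 0, na.rm = TRUE)) {
    stop("negative krill density in input")
  }
  keep <- !(samples$density > threshold) | is.na(samples$density)
  out <- samples[keep, , drop = FALSE]
  n_removed <- sum(!keep)
  if (n_removed > 0) {
    message("removed ", n_removed, " outlier sample(s) with density > ",
      threshold, " ind/1000 m^3")
  }
  attr(out, "n_removed") <- n_removed
  out
}

#' Convert volumetric density to water-column areal abundance
#'
#' Station densities in individuals per 1000 m^3 are converted to
#' individuals per m^2 by multiplying by the sampling depth:
#' `abundance = density / 1000 * depth`.
#'
#' @param samples tibble with columns `density` (ind/1000 m^3) and `depth`
#'   (m).
#' @return the tibble with an added `abundance` column (ind/m^2); rows with
#'   missing depth are dropped with a warning.
#' @export
column_abundance <- function(samples) {
  miss <- is.na(samples$depth)
  if (any(miss)) {
    warning(sum(miss), " sample(s) with missing depth excluded")
    samples <- samples[!miss, , drop = FALSE]
  }
  dplyr::mutate(samples, abundance = .data$density / 1000 * .data$depth)
}

#' Spatially binned annual cohort abundances
#'
#' Two-stage averaging that de-weights stations sampled repeatedly at the
#' same location: samples are first averaged within longitude/latitude bins
#' (default 0.5 deg x 0.25 deg), then the bin means are averaged per year.
#' Each sample is split into juvenile and adult abundance via its juvenile
#' fraction (body size <= 35 mm counts as juvenile).
#'
#' @param samples cleaned tibble with columns `year` (or `date`),
#'   `latitude`, `longitude`, `density`, `depth`, `juvenile_fraction`.
#' @param lon_step,lat_step bin widths in degrees.
#' @return tibble `year`, `J`, `A` (ind/m^2).
#' @export
bin_and_average <- function(samples, lon_step = 0.5, lat_step = 0.25) {
  if (!"year" %in% names(samples)) {
    samples$year <- as.integer(format(as.Date(samples$date), "%Y"))
  }
  if (!"abundance" %in% names(samples)) {
    samples <- column_abundance(samples)
  }
  samples |>
    dplyr::mutate(
      J_ab = .data$abundance * .data$juvenile_fraction,
      A_ab = .data$abundance * (1 - .data$juvenile_fraction),
      lon_bin = floor(.data$longitude / lon_step),
      lat_bin = floor(.data$latitude / lat_step)
    ) |>
    dplyr::group_by(.data$year, .data$lon_bin, .data$lat_bin) |>
    dplyr::summarise(
      J_ab = mean(.data$J_ab), A_ab = mean(.data$A_ab), .groups = "drop"
    ) |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(
      J = mean(.data$J_ab), A = mean(.data$A_ab), .groups = "drop"
    )
}

#' Trailing moving average
#'
#' Value at position `t` is the mean of positions `t - window + 1` through
#' `t`. Positions whose window extends before the start of the series are
#' missing; inside the series, a window is evaluated when at least
#' `min_obs` of its values are present (mean of the present values),
#' otherwise missing.
#'
#' @param x time-ordered numeric series (may contain `NA`).
#' @param window window length (default 9, the smoothing used for rapidly
#'   oscillating climate indices).
#' @param min_obs minimum non-missing values required inside a full window
#'   (default `window - 2`, i.e. 7 of 9).
#' @return numeric vector, same length as `x`.
#' @export
moving_average <- function(x, window = 9, min_obs = max(1, window - 2)) {
  if (window < 1) stop("window must be >= 1")
  n <- length(x)
  out <- rep(NA_real_, n)
  for (t in seq_len(n)) {
    if (t < window) next
    w <- x[(t - window + 1):t]
    if (sum(!is.na(w)) >= min_obs) out[t] <- mean(w, na.rm = TRUE)
  }
  out
}

#' The 16-month analysis cycle aligned to an anomaly year
#'
#' The monthly window over which environmental drivers act on the cohort of
#' anomaly year `Y` runs from September of calendar year `Y - 1` through
#' December of year `Y` (16 months), spanning the larval mortality window
#' (November of `Y - 1` to October of `Y`). This single table constant
#' encodes the alignment used by both the correlation screen and the fused
#' LASSO design.
#'
#' @return tibble with columns `cycle_month` (1..16), `month` (calendar
#'   month), `year_offset` (-1 or 0 relative to the anomaly year), and
#'   `label`.
#' @export
cycle_months <- function() {
  tibble::tibble(
    cycle_month = 1:16,
    month = c(9:12, 1:12),
    year_offset = c(rep(-1L, 4), rep(0L, 12)),
    label = c(paste0(month.abb[9:12], "*"), month.abb)
  )
}

#' Year-by-cycle-month matrix of an environmental factor
#'
#' Extracts, for each anomaly year, the 16 monthly values of one factor
#' along the [cycle_months()] alignment. Rapidly oscillating climate
#' indices are smoothed with a trailing [moving_average()] over the whole
#' monthly series before extraction; local factors enter as raw monthly
#' values.
#'
#' @param env long environment table: columns `year`, `month`, `factor`,
#'   `value` (at most one value per key).
#' @param factor_name factor to extract.
#' @param years anomaly years (rows of the result).
#' @param smooth apply the trailing moving average first?
#' @param ma_window moving-average window.
#' @return numeric matrix `length(years)` x 16 (NA where missing).
#' @export
env_cycle_matrix <- function(env, factor_name, years, smooth = FALSE,
                             ma_window = 9) {
  sub <- env[env$factor == factor_name, c("year", "month", "value")]
  if (anyDuplicated(sub[, c("year", "month")])) {
    stop("duplicate (year, month) values for factor ", factor_name)
  }
  full <- tidyr::complete(sub,
    year = seq(min(sub$year), max(sub$year)), month = 1:12
  )
  full <- dplyr::arrange(full, .data$year, .data$month)
  if (smooth) full$value <- moving_average(full$value, ma_window)
  cm <- cycle_months()
  out <- matrix(NA_real_, length(years), 16,
    dimnames = list(years, cm$label)
  )
  key <- paste(full$year, full$month)
  for (i in seq_along(years)) {
    idx <- match(paste(years[i] + cm$year_offset, cm$month), key)
    out[i, ] <- full$value[idx]
  }
  out
}

#' Correlation screen of loss anomalies against monthly environment
#'
#' Pearson correlations between the per-year anomalies of one cohort and
#' each environmental factor at each month of the 16-month cycle
#' ([cycle_months()]). Climate indices enter as 9-month trailing moving
#' averages, local factors as raw monthly values. Two-sided p-values come
#' from the t-distribution; cells are flagged at `p < 0.05` with no
#' multiple-testing correction (an exploratory screen).
#'
#' @param anomalies tibble with columns `year` and `delta`.
#' @param env long environment table (`year`, `month`, `factor`, `value`).
#' @param smooth_factors factors to smooth with the moving average
#'   (climate indices).
#' @param min_pairs minimum complete pairs per cell; cells with fewer are
#'   returned with `NA` (not assessed).
#' @param ma_window moving-average window for the smoothed factors.
#' @return tibble of class `correlation_screen`: `factor`, `cycle_month`,
#'   `label`, `r`, `p`, `n`, `significant`.
#' @export
correlation_screen <- function(anomalies, env,
                               smooth_factors = c("SAM", "AAO", "SOI", "Nino3.4"),
                               min_pairs = 5, ma_window = 9) {
  factors <- unique(env$factor)
  cm <- cycle_months()
  res <- purrr::map_dfr(factors, function(f) {
    X <- env_cycle_matrix(env, f, anomalies$year,
      smooth = f %in% smooth_factors, ma_window = ma_window
    )
    purrr::map_dfr(1:16, function(i) {
      x <- X[, i]
      y <- anomalies$delta
      ok <- stats::complete.cases(x, y)
      n <- sum(ok)
      if (n < min_pairs || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
        return(tibble::tibble(
          factor = f, cycle_month = i, label = cm$label[i],
          r = NA_real_, p = NA_real_, n = n, significant = NA
        ))
      }
      r <- stats::cor(x[ok], y[ok])
      tstat <- r * sqrt((n - 2) / max(1 - r^2, 1e-300))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
      tibble::tibble(
        factor = f, cycle_month = i, label = cm$label[i],
        r = r, p = p, n = n, significant = p < 0.05
      )
    })
  })
  class(res) <- c("correlation_screen", class(res))
  res
}

#' Plot a correlation screen
#'
#' Month-by-factor tile map of Pearson correlations, with significant cells
#' (p < 0.05) dotted.
#'
#' @param object a [correlation_screen()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.correlation_screen <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- factor(df$label, levels = rev(cycle_months()$label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor, y = .data$label)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$r)) +
    ggplot2::geom_point(
      data = df[!is.na(df$significant) & df$significant, ],
      colour = "yellow", size = 1.5
    ) +
    ggplot2::scale_fill_gradient2(
      low = "blue", mid = "white", high = "red", limits = c(-1, 1)
    ) +
    ggplot2::labs(x = NULL, y = "month of cycle", fill = "r")
}

#' Lag-1 relation between adult stock and next-year recruits
#'
#' Pairs adult abundance in year `Y` with juvenile abundance in year
#' `Y + 1` and reports their Pearson correlation on log abundances. A
#' negative correlation is the signature of overcompensating
#' (Ricker-type) recruitment.
#'
#' @param df tibble with columns `year`, `J`, `A` (observations or the
#'   `jan1` element of a simulation).
#' @return list of class `recruit_adult`: `pairs` (tibble `year`, `A`,
#'   `J_next`), `r`, `n`. `r` is `NA` when either series is constant.
#' @export
recruit_vs_adult <- function(df) {
  df <- dplyr::arrange(as.data.frame(df), .data$year)
  if (nrow(df) < 3) stop("need at least 3 years")
  n <- nrow(df)
  pairs <- tibble::tibble(
    year = df$year[-n], A = df$A[-n], J_next = df$J[-1]
  )
  lA <- log(pairs$A)
  lJ <- log(pairs$J_next)
  r <- if (stats::sd(lA) == 0 || stats::sd(lJ) == 0) NA_real_ else
    stats::cor(lA, lJ)
  structure(list(pairs = pairs, r = r, n = nrow(pairs)),
    class = "recruit_adult"
  )
}

#' @export
print.recruit_adult <- function(x, ...) {
  cat("<recruit_adult> n =", x$n, " Pearson r (log scale) =",
    format(x$r, digits = 3), "\n")
  invisible(x)
}

#' Permuted-anomaly experiment
#'
#' Re-simulates the model after randomly permuting the year order of the
#' fitted loss anomalies (larval and juvenile anomalies shuffled jointly,
#' keeping within-year pairing), and records the adult-versus-next-year
#' recruit correlation of each run. Under overcompensating recruitment the
#' negative stock-recruit relation survives arbitrary reshuffling of
#' favorable and unfavorable years; under saturating recruitment it
#' disappears.
#'
#' @param anomalies anomaly table (columns `year`, `delta_L`, `delta_J`).
#' @param params a [krill_params()] object.
#' @param n_permutations number of random permutations.
#' @param seed integer seed.
#' @param years simulated years (default: the anomaly span).
#' @return tibble of class `permutation_experiment` with columns
#'   `permutation`, `r`; attributes `median_r` and `unpermuted_r`.
#' @export
permuted_anomaly_experiment <- function(anomalies, params,
                                        n_permutations = 200, seed = 1,
                                        years = nrow(anomalies)) {
  anomalies <- validate_anomalies(anomalies)
  base_sim <- simulate_krill(params, years = years, anomalies = anomalies,
    jan1_only = TRUE)
  r0 <- recruit_vs_adult(base_sim$jan1)$r
  set.seed(seed)
  rs <- vapply(seq_len(n_permutations), function(b) {
    ord <- sample.int(nrow(anomalies))
    perm <- anomalies
    perm$delta_L <- anomalies$delta_L[ord]
    perm$delta_J <- anomalies$delta_J[ord]
    sim <- simulate_krill(params, years = years, anomalies = perm,
      jan1_only = TRUE)
    recruit_vs_adult(sim$jan1)$r
  }, numeric(1))
  out <- tibble::tibble(permutation = seq_len(n_permutations), r = rs)
  attr(out, "median_r") <- stats::median(rs, na.rm = TRUE)
  attr(out, "unpermuted_r") <- r0
  class(out) <- c("permutation_experiment", class(out))
  out
}
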