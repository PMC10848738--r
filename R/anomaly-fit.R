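#' Cost-function configuration
#'
#' Weights and regularization constants shared by the time-constant and
#' annually-varying cost functions. The cohort weights (`alpha_L = 2/3`,
#' `alpha_J = 1`, `alpha_A = 2`) equalize the contribution of the three
#' abundance scales to the weighted log-scale deviation. `lambda_prior`
#' penalizes relative deviations of fitted standard parameters from their
#' priors; `lambda_anomaly` penalizes the mean square of the annual loss
#' anomalies (its grid `0.001, 0.003, 0.01, 0.03, 0.1` spans under- to
#' over-smoothing).
#'
#' @param alpha_L,alpha_J,alpha_A cohort weights (> 0).
#' @param lambda_prior parameter-prior regularization constant.
#' @param lambda_anomaly anomaly regularization constant.
#' @param priors named list/vector of prior parameter values `theta_k0` for
#'   the fitted parameters; `NULL` means "use the preset values".
#' @return a list of class `cost_config`.
#' @export
cost_config <- function(alpha_L = 2 / 3, alpha_J = 1, alpha_A = 2,
                        lambda_prior = 0.01, lambda_anomaly = 0.01,
                        priors = NULL) {
  stopifnot(
    alpha_L > 0, alpha_J > 0, alpha_A > 0,
    lambda_prior > 0, lambda_anomaly > 0
  )
  structure(
    list(
      alpha_L = alpha_L, alpha_J = alpha_J, alpha_A = alpha_A,
      lambda_prior = lambda_prior, lambda_anomaly = lambda_anomaly,
      priors = priors
    ),
    class = "cost_config"
  )
}

#' Regularization grid for the anomaly penalty
#' @return the default `lambda_anomaly` grid.
#' @export
lambda_anomaly_grid <- function() c(0.001, 0.003, 0.01, 0.03, 0.1)

.FITTED_PARS <- c("L_max", "G_max", "m_L", "m_J", "m_A", "L0", "J0", "A0")

.data_term <- function(model_jan1, observations, config) {
  if (is.matrix(model_jan1)) model_jan1 <- as.data.frame(model_jan1)
  obs <- as.data.frame(observations)
  if (any(obs$L <= 0 | obs$J <= 0 | obs$A <= 0)) {
    bad <- which(obs$L <= 0 | obs$J <= 0 | obs$A <= 0)[1]
    stop("non-positive observation in year ", obs$year[bad])
  }
  n <- nrow(obs)
  m <- model_jan1[seq_len(n), ]
  eps <- 1e-12   # guard against exact zeros in degenerate simulations
  mean(
    config$alpha_L * (log(obs$L) - log(pmax(m$L, eps)))^2 +
      config$alpha_J * (log(obs$J) - log(pmax(m$J, eps)))^2 +
      config$alpha_A * (log(obs$A) - log(pmax(m$A, eps)))^2
  )
}

#' Cost of the time-constant model
#'
#' Weighted mean square deviation between the logarithms of observed and
#' modelled 1 January abundances, plus a penalty on relative deviations of
#' the fitted parameters from their priors:
#' \deqn{C = \frac{1}{n}\sum_Y\left[\alpha_L \Delta_L^2 + \alpha_J
#'   \Delta_J^2 + \alpha_A \Delta_A^2\right] + \lambda \sum_k
#'   \left(\frac{\theta_k - \theta_{k0}}{\theta_{k0}}\right)^2}
#'
#' @param params a [krill_params()] object (includes initial conditions).
#' @param observations tibble with columns `year`, `L`, `J`, `A`
#'   (strictly positive abundances).
#' @param config a [cost_config()]; its `priors` default to the preset
#'   values of `params`.
#' @param rtol,atol solver tolerances for the embedded simulation
#'   (`method = "lsoda"`).
#' @param method integrator for the embedded simulation: `"lsoda"`
#'   (adaptive, default) or `"rk4"` (the fixed-step fast path the fitting
#'   drivers use; `steps` per year).
#' @param steps steps per year for `method = "rk4"`.
#' @return scalar cost.
#' @export
timeconstant_cost <- function(params, observations, config = cost_config(),
                              rtol = 1e-6, atol = 1e-8,
                              method = c("lsoda", "rk4"), steps = 72L) {
  method <- match.arg(method)
  n <- nrow(observations)
  jan1 <- if (method == "rk4") {
    .jan1_fast(params, NULL, n, steps)
  } else {
    simulate_krill(params, years = n, jan1_only = TRUE,
      rtol = rtol, atol = atol)$jan1
  }
  priors <- config$priors
  if (is.null(priors)) {
    priors <- unlist(krill_params(params$preset)[.FITTED_PARS])
  }
  theta <- unlist(params[names(priors)])
  .data_term(jan1, observations, config) +
    config$lambda_prior * sum(((theta - priors) / priors)^2)
}

#' Cost of the annually varying model
#'
#' Same weighted log-scale data term as [timeconstant_cost()], with the
#' simulation run under annual loss anomalies, plus the anomaly penalty
#' \eqn{\lambda_r \sum_Y (\delta_{L,Y}^2 + \delta_{J,Y}^2)}. The standard
#' parameters are held fixed at their time-constant values; only the
#' anomalies (and, in the fit, the initial conditions) vary.
#'
#' @param anomalies anomaly table (columns `year`, `delta_L`, `delta_J`).
#' @param params fixed time-constant parameters (initial conditions in
#'   `L0`, `J0`, `A0`).
#' @param observations tibble `year`, `L`, `J`, `A`.
#' @param config a [cost_config()].
#' @param rtol,atol solver tolerances (`method = "lsoda"`).
#' @param method,steps integrator choice, see [timeconstant_cost()].
#' @return scalar cost.
#' @export
anomaly_cost <- function(anomalies, params, observations,
                         config = cost_config(), rtol = 1e-6, atol = 1e-8,
                         method = c("lsoda", "rk4"), steps = 72L) {
  method <- match.arg(method)
  n <- nrow(observations)
  jan1 <- if (method == "rk4") {
    .jan1_fast(params, anomalies, n, steps)
  } else {
    simulate_krill(params, years = n, anomalies = anomalies,
      jan1_only = TRUE, rtol = rtol, atol = atol)$jan1
  }
  .data_term(jan1, observations, config) +
    config$lambda_anomaly *
      sum(anomalies$delta_L^2 + anomalies$delta_J^2)
}

#' Fit the time-constant model to annual observations
#'
#' Minimizes [timeconstant_cost()] over the eight free quantities
#' (`L_max`, `G_max`, `m_L`, `m_J`, `m_A`, `L0`, `J0`, `A0`) with the
#' recruitment shape `gamma`, transition rate `r` and window duration
#' `tau_window` fixed by the preset. The search runs in log-parameter
#' space (positivity by construction) with box bounds of a factor `100`
#' around the priors, using bounded quasi-Newton iterations from the prior
#' values plus seeded jittered restarts.
#'
#' @param observations tibble `year`, `L`, `J`, `A` (>= 3 years).
#' @param preset `"RK"` or `"BH"`.
#' @param config a [cost_config()].
#' @param seed integer seed for the restart jitter.
#' @param n_starts number of optimization starts (first start is at the
#'   priors).
#' @param maxit iteration cap per start.
#' @return An object of class `krill_fit`: list with `params` (fitted
#'   [krill_params()]), `cost`, `starts` (per-start tibble of costs),
#'   `convergence`, `observations`, `config`.
#' @export
fit_timeconstant <- function(observations, preset = c("RK", "BH"),
                             config = cost_config(), seed = 1,
                             n_starts = 3, maxit = 200) {
  preset <- match.arg(preset)
  if (nrow(observations) < 3) stop("need at least 3 observation years")
  base <- krill_params(preset)
  priors <- config$priors
  if (is.null(priors)) priors <- unlist(base[.FITTED_PARS])
  config$priors <- priors

  # lean objective: direct fast-path evaluation, no intermediate tibbles
  obs <- as.data.frame(observations)
  n <- nrow(obs)
  if (any(obs$L <= 0 | obs$J <= 0 | obs$A <= 0)) {
    stop("non-positive observation in input")
  }
  logobs <- cbind(log(obs$L), log(obs$J), log(obs$A))
  w <- c(config$alpha_L, config$alpha_J, config$alpha_A)
  pv <- .pack_parms(base, NULL)
  par_idx <- match(c("L_max", "G_max", "m_L", "m_J", "m_A"), names(priors))
  ic_idx <- match(c("L0", "J0", "A0"), names(priors))
  obj <- function(logtheta) {
    theta <- exp(logtheta)
    pv[5:9] <- theta[par_idx]
    dat <- .C("krill_cost", as.double(pv), as.double(theta[ic_idx]),
      as.integer(n), 72L, as.double(logobs), as.double(w),
      cost = double(1), PACKAGE = "krillab"
    )$cost
    dat + config$lambda_prior * sum(((theta - priors) / priors)^2)
  }
  lp0 <- log(priors)
  lower <- lp0 - log(100)
  upper <- lp0 + log(100)

  set.seed(seed)
  starts <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    start <- if (s == 1) lp0 else lp0 + stats::rnorm(length(lp0), 0, 0.3)
    start <- pmin(pmax(start, lower), upper)
    opt <- stats::optim(start, obj,
      method = "L-BFGS-B", lower = lower, upper = upper,
      control = list(maxit = maxit)
    )
    starts[[s]] <- list(par = opt$par, cost = opt$value, conv = opt$convergence)
  }
  costs <- vapply(starts, `[[`, numeric(1), "cost")
  best <- starts[[which.min(costs)]]
  if (best$conv != 0) {
    warning("optimizer did not report convergence; returning best found")
  }
  fitted <- base
  fitted[names(priors)] <- as.list(exp(best$par))
  structure(
    list(
      params = fitted, cost = best$cost,
      starts = tibble::tibble(start = seq_len(n_starts), cost = costs),
      convergence = best$conv,
      observations = observations, config = config
    ),
    class = "krill_fit"
  )
}

#' @export
print.krill_fit <- function(x, ...) {
  cat("<krill_fit>", x$params$preset, "preset, cost", format(x$cost), "\n")
  print(x$params)
  invisible(x)
}

#' @export
tidy.krill_fit <- function(x, ...) {
  prior <- x$config$priors
  tibble::tibble(
    parameter = names(prior),
    estimate = unlist(x$params[names(prior)], use.names = FALSE),
    prior = unname(prior)
  )
}

#' @export
glance.krill_fit <- function(x, ...) {
  tibble::tibble(
    preset = x$params$preset, cost = x$cost,
    n_years = nrow(x$observations), convergence = x$convergence
  )
}

#' Sign-consistency significance of fitted anomalies
#'
#' An anomaly is called significant when at least `level` of the retained
#' optimization cycles place it on the same side of zero as the best-cycle
#' value; exact zeros count against significance. This turns the spread of
#' near-optimal solutions across restart cycles into a confidence
#' statement.
#'
#' @param cycle_matrix numeric matrix, one row per retained cycle, one
#'   column per anomaly (>= 20 rows).
#' @param best numeric vector: the best-cycle anomaly values (default the
#'   first row).
#' @param level required same-sign fraction (default 0.95, inclusive).
#' @return logical vector, one flag per column.
#' @export
classify_significance <- function(cycle_matrix, best = cycle_matrix[1, ],
                                  level = 0.95) {
  if (is.null(dim(cycle_matrix)) || nrow(cycle_matrix) == 0) {
    stop("cycle_matrix must be a non-empty matrix")
  }
  if (nrow(cycle_matrix) < 20) {
    warning("fewer than 20 cycles; significance flags are unreliable")
  }
  vapply(seq_len(ncol(cycle_matrix)), function(j) {
    s <- sign(best[j])
    if (s == 0) return(FALSE)
    mean(sign(cycle_matrix[, j]) == s) >= level
  }, logical(1))
}

#' Fit annual loss anomalies by regularized inversion
#'
#' Estimates the larval and juvenile loss anomalies (2n values) and the
#' three initial abundances that minimize [anomaly_cost()], holding the
#' standard time-constant parameters fixed. The search follows a two-stage
#' multi-cycle scheme: primary cycles recenter a sliding search region on
#' the best solution found so far (bounded quasi-Newton descent from the
#' recentered start), then independent restart cycles perturb the
#' stabilized optimum and re-descend. Cycles whose cost exceeds the best
#' by more than `retain_tol` are discarded; the retained per-cycle anomaly
#' vectors feed [classify_significance()].
#'
#' @param observations tibble `year`, `L`, `J`, `A`.
#' @param params fixed time-constant parameters (a [krill_params()] or the
#'   `params` element of a [fit_timeconstant()] result).
#' @param config a [cost_config()] (anomaly penalty `lambda_anomaly`).
#' @param n_primary,n_final numbers of primary (sliding-window) and final
#'   (independent restart) cycles.
#' @param evals_per_cycle approximate cost-evaluation budget per cycle;
#'   translated into an iteration cap for the bounded descent.
#' @param seed integer; cycle `c` uses `seed + c`.
#' @param bounds search bounds for each anomaly (mortality scale factors
#'   `exp(bounds)`).
#' @param jitter_sd standard deviation of the restart perturbations.
#' @param retain_tol relative cost excess above the best at which a cycle
#'   is dropped from the significance matrix (default 0.02).
#' @param level significance level for [classify_significance()].
#' @param steps integration steps per year for the fast-path cost (the
#'   stored best cost is reproducible via
#'   `anomaly_cost(..., method = "rk4", steps = steps)`).
#' @param rtol,atol solver tolerances for the embedded simulations.
#' @return An object of class `krill_anomaly_fit`: list with `anomalies`
#'   (tibble `year`, `delta_L`, `delta_L_significant`, `delta_J`,
#'   `delta_J_significant`), `init` (fitted `L0`, `J0`, `A0`), `cost`,
#'   `cycles` (retained cycle x anomaly matrix), `cycle_costs`, `params`,
#'   `config`.
#' @export
fit_anomalies <- function(observations, params, config = cost_config(),
                          n_primary = 300, n_final = 300,
                          evals_per_cycle = 30000, seed = 1,
                          bounds = c(-3, 3), jitter_sd = 0.15,
                          retain_tol = 0.02, level = 0.95,
                          steps = 72L, rtol = 1e-6, atol = 1e-8) {
  n <- nrow(observations)
  p <- 2L * n + 3L
  maxit <- max(5L, as.integer(round(evals_per_cycle / (p + 3))))
  ic0 <- log(unlist(params[c("L0", "J0", "A0")]))
  lower <- c(rep(bounds[1], 2 * n), ic0 - log(100))
  upper <- c(rep(bounds[2], 2 * n), ic0 + log(100))

  unpack <- function(x) {
    list(
      anomalies = tibble::tibble(
        year = seq_len(n), delta_L = x[seq_len(n)],
        delta_J = x[n + seq_len(n)]
      ),
      ic = exp(x[2 * n + 1:3])
    )
  }
  # lean objective on the compiled fixed-step fast path
  obs <- as.data.frame(observations)
  if (any(obs$L <= 0 | obs$J <= 0 | obs$A <= 0)) {
    stop("non-positive observation in input")
  }
  logobs <- cbind(log(obs$L), log(obs$J), log(obs$A))
  w <- c(config$alpha_L, config$alpha_J, config$alpha_A)
  pv <- .pack_parms(params, NULL)
  pv[10] <- n
  iL <- 10 + seq_len(n)
  iJ <- 10 + .NMAX_ANOM + seq_len(n)
  obj <- function(x) {
    pv[iL] <- x[seq_len(n)]
    pv[iJ] <- x[n + seq_len(n)]
    dat <- .C("krill_cost", as.double(pv), as.double(exp(x[2 * n + 1:3])),
      as.integer(n), as.integer(steps), as.double(logobs), as.double(w),
      cost = double(1), PACKAGE = "krillab"
    )$cost
    dat + config$lambda_anomaly * sum(x[seq_len(2 * n)]^2)
  }
  # forward-difference gradient (the cost is smooth and deterministic)
  grad <- function(x) {
    f0 <- obj(x)
    h <- 1e-6
    vapply(seq_along(x), function(i) {
      xi <- x
      xi[i] <- xi[i] + h
      (obj(xi) - f0) / h
    }, numeric(1))
  }
  run_cycle <- function(start, it = maxit) {
    start <- pmin(pmax(start, lower), upper)
    stats::optim(start, obj, gr = grad,
      method = "L-BFGS-B", lower = lower, upper = upper,
      control = list(maxit = it)
    )
  }

  # stage 1: sliding-window search, recentred on the running optimum
  centre <- c(rep(0, 2 * n), ic0)
  best_par <- centre
  best_cost <- Inf
  for (cyc in seq_len(n_primary)) {
    set.seed(seed + cyc)
    start <- best_par + stats::rnorm(p, 0, jitter_sd)
    if (cyc == 1) start <- centre
    # the first descent from the cold start gets a deeper budget
    opt <- run_cycle(start, it = if (cyc == 1) 3L * maxit else maxit)
    if (opt$value < best_cost) {
      best_cost <- opt$value
      best_par <- opt$par
    }
  }

  # stage 2: independent restart cycles around the stabilized optimum
  cycles <- matrix(NA_real_, n_final, p)
  cycle_costs <- numeric(n_final)
  for (cyc in seq_len(n_final)) {
    set.seed(seed + n_primary + cyc)
    start <- best_par + stats::rnorm(p, 0, jitter_sd)
    opt <- run_cycle(start)
    cycles[cyc, ] <- opt$par
    cycle_costs[cyc] <- opt$value
  }
  if (min(cycle_costs) < best_cost) {
    k <- which.min(cycle_costs)
    best_cost <- cycle_costs[k]
    best_par <- cycles[k, ]
  }

  retained <- cycle_costs <= best_cost * (1 + retain_tol)
  anom_cols <- seq_len(2 * n)
  sig <- classify_significance(
    cycles[retained, anom_cols, drop = FALSE],
    best = best_par[anom_cols], level = level
  )
  u <- unpack(best_par)
  anomalies <- tibble::tibble(
    year = seq_len(n),
    delta_L = u$anomalies$delta_L,
    delta_L_significant = sig[seq_len(n)],
    delta_J = u$anomalies$delta_J,
    delta_J_significant = sig[n + seq_len(n)]
  )
  structure(
    list(
      anomalies = anomalies,
      init = stats::setNames(u$ic, c("L0", "J0", "A0")),
      cost = best_cost,
      cycles = cycles[retained, anom_cols, drop = FALSE],
      cycle_costs = cycle_costs[retained],
      n_retained = sum(retained),
      params = params, config = config,
      observations = observations
    ),
    class = "krill_anomaly_fit"
  )
}

#' @export
print.krill_anomaly_fit <- function(x, ...) {
  cat(
    "<krill_anomaly_fit>", nrow(x$anomalies), "years, cost",
    format(x$cost), "(", x$n_retained, "retained cycles )\n"
  )
  print(x$anomalies, n = 6)
  invisible(x)
}

#' @export
tidy.krill_anomaly_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(
      year = x$anomalies$year, cohort = "L",
      delta = x$anomalies$delta_L,
      significant = x$anomalies$delta_L_significant
    ),
    tibble::tibble(
      year = x$anomalies$year, cohort = "J",
      delta = x$anomalies$delta_J,
      significant = x$anomalies$delta_J_significant
    )
  )
}

#' @export
glance.krill_anomaly_fit <- function(x, ...) {
  tibble::tibble(
    cost = x$cost, n_years = nrow(x$anomalies),
    n_retained = x$n_retained,
    mean_abs_delta = mean(abs(c(x$anomalies$delta_L, x$anomalies$delta_J)))
  )
}

#' Plot fitted loss anomalies with their cycle spread
#'
#' Best-cycle anomalies (filled where significant) over the cloud of
#' retained-cycle solutions.
#'
#' @param object a `krill_anomaly_fit`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.krill_anomaly_fit <- function(object, ...) {
  n <- nrow(object$anomalies)
  cloud <- tibble::as_tibble(
    expand.grid(cycle = seq_len(nrow(object$cycles)), col = seq_len(2 * n))
  )
  cloud$delta <- object$cycles[cbind(cloud$cycle, cloud$col)]
  cloud$cohort <- ifelse(cloud$col <= n, "L", "J")
  cloud$year <- ifelse(cloud$col <= n, cloud$col, cloud$col - n)
  best <- tidy.krill_anomaly_fit(object)
  ggplot2::ggplot(cloud, ggplot2::aes(x = .data$year, y = .data$delta)) +
    ggplot2::geom_point(alpha = 0.15, size = 0.6, colour = "steelblue") +
    ggplot2::geom_point(
      data = best,
      ggplot2::aes(y = .data$delta, shape = .data$significant),
      colour = "red", size = 2
    ) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::facet_wrap(~cohort, ncol = 1) +
    ggplot2::labs(x = "year", y = expression(delta))
}

#' Export fitted anomalies as CSV
#'
#' @param fit a `krill_anomaly_fit`.
#' @param path output CSV (year, delta_L, delta_L_significant, delta_J,
#'   delta_J_significant).
#' @param cycles_path optional CSV for the retained per-cycle matrix.
#' @return `path`, invisibly.
#' @export
write_anomalies <- function(fit, path, cycles_path = NULL) {
  utils::write.csv(fit$anomalies, path, row.names = FALSE)
  if (!is.null(cycles_path)) {
    utils::write.csv(fit$cycles, cycles_path, row.names = FALSE)
  }
  invisible(path)
}
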