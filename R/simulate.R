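#' Cohort-specific mortality with annual loss anomalies applied
#'
#' Annual loss anomalies `delta_k,Y` modulate the background mortality of
#' cohort `k` multiplicatively, `m_k' = m_k exp(delta_k,Y)`, inside a
#' cohort-specific application window aligned to the lifespan of the cohort
#' that spends most of year `Y` in that stage: the larval anomaly of year
#' `Y` applies from 1 November of year `Y - 1` through 31 October of year
#' `Y`; the juvenile anomaly from 1 August of year `Y - 1` through 31 July
#' of year `Y`. Adult mortality is never modulated. Outside every window
#' (or when `anomalies` is `NULL`) the base mortality is returned.
#'
#' Model time `t` is continuous in years with `t = 0` at 1 January of year
#' 1; month `k` of year `Y` maps to `t` in `[Y - 1 + (k-1)/12, Y - 1 + k/12)`.
#'
#' @param t time in years (vectorized).
#' @param cohort `"L"` or `"J"`.
#' @param base base (background) mortality, 1/year.
#' @param anomalies a data frame with columns `year` (1-based, consecutive),
#'   `delta_L`, `delta_J`, or `NULL`.
#' @return mortality at `t` (1/year), same length as `t`.
#' @export
mortality_at <- function(t, cohort = c("L", "J"), base, anomalies = NULL) {
  cohort <- match.arg(cohort)
  if (is.null(anomalies)) {
    return(rep_len(base, length(t)))
  }
  anomalies <- validate_anomalies(anomalies)
  shift <- if (cohort == "L") 2 / 12 else 5 / 12
  idx <- floor(t + shift + 1e-12) + 1   # anomaly year containing t
  delta <- rep(0, length(t))
  inside <- idx >= 1 & idx <= nrow(anomalies)
  col <- if (cohort == "L") "delta_L" else "delta_J"
  delta[inside] <- anomalies[[col]][idx[inside]]
  base * exp(delta)
}

validate_anomalies <- function(anomalies) {
  anomalies <- as.data.frame(anomalies)
  need <- c("year", "delta_L", "delta_J")
  if (!all(need %in% names(anomalies))) {
    stop("anomalies must have columns year, delta_L, delta_J")
  }
  anomalies <- anomalies[order(anomalies$year), ]
  if (!identical(as.integer(anomalies$year), seq_len(nrow(anomalies)))) {
    stop("anomaly years must be consecutive integers 1..n (one entry per year)")
  }
  anomalies
}

#' Time derivatives of the stage-structured krill model
#'
#' The life-history labyrinth right-hand side. Larvae are produced at rate
#' `R(A)` ([recruitment()]) during the summer spawning window, move to the
#' juvenile stage through the spring window, and juveniles move to the
#' adult stage through the winter window; each stage decays at its
#' (possibly anomaly-modulated) mortality:
#' \deqn{dL/dt = R(A) f_{sum}(t) - r f_{spr}(t) L - m_L L}
#' \deqn{dJ/dt = r f_{spr}(t) L - r f_{wnt}(t) J - m_J J}
#' \deqn{dA/dt = r f_{wnt}(t) J - m_A A}
#' with window centres `f_sum` at phase 0 (mid-summer, 1 January),
#' `f_spr` at 9/12 (1 October) and `f_wnt` at 1/2 (1 July). With
#' `tau_window = 0.2` the three windows do not overlap, so no cohort can
#' shortcut two stages within one season. Negative state components are
#' clipped to zero inside the evaluation (smooth negativity guard).
#'
#' @param t time in years (scalar).
#' @param state named numeric vector `c(L = , J = , A = )`.
#' @param params a [krill_params()] object.
#' @param anomalies optional anomaly table, see [mortality_at()].
#' @return named numeric vector of derivatives `(L, J, A)`.
#' @export
krill_rhs <- function(t, state, params, anomalies = NULL) {
  L <- max(state[["L"]], 0)
  J <- max(state[["J"]], 0)
  A <- max(state[["A"]], 0)
  f_sum <- activation(t, 0, params$tau_window, params$m_exp)
  f_spr <- activation(t, 9 / 12, params$tau_window, params$m_exp)
  f_wnt <- activation(t, 1 / 2, params$tau_window, params$m_exp)
  m_L <- mortality_at(t, "L", params$m_L, anomalies)
  m_J <- mortality_at(t, "J", params$m_J, anomalies)
  R <- recruitment(A, params)
  c(
    L = R * f_sum - params$r * f_spr * L - m_L * L,
    J = params$r * f_spr * L - params$r * f_wnt * J - m_J * J,
    A = params$r * f_wnt * J - params$m_A * A
  )
}

.NMAX_ANOM <- 64L

.pack_parms <- function(params, anomalies = NULL) {
  dL <- dJ <- numeric(.NMAX_ANOM)
  n <- 0L
  if (!is.null(anomalies)) {
    anomalies <- validate_anomalies(anomalies)
    n <- nrow(anomalies)
    if (n > .NMAX_ANOM) {
      stop("at most ", .NMAX_ANOM, " anomaly years supported by the compiled model")
    }
    dL[seq_len(n)] <- anomalies$delta_L
    dJ[seq_len(n)] <- anomalies$delta_J
  }
  c(
    params$gamma, params$r, params$tau_window, params$m_exp,
    params$L_max, params$G_max, params$m_L, params$m_J, params$m_A,
    n, dL, dJ
  )
}

# compiled fixed-step fast path: 1 January samples only (used by the
# fitting drivers; agrees with lsoda to ~1e-5 relative at 72 steps/year)
.jan1_fast <- function(params, anomalies, years, steps = 72L) {
  res <- .C("krill_jan1",
    as.double(.pack_parms(params, anomalies)),
    as.double(c(params$L0, params$J0, params$A0)),
    as.integer(years), as.integer(steps),
    out = double(3 * years), PACKAGE = "krillab"
  )$out
  matrix(res, years, 3, dimnames = list(NULL, c("L", "J", "A")))
}

#' Simulate the stage-structured krill model
#'
#' Integrates [krill_rhs()] from 1 January of year 1 (`t = 0`) over the
#' requested number of years with an adaptive solver (`deSolve::lsoda`,
#' default relative tolerance `1e-8`, absolute `1e-10`) and records the
#' trajectory together with the 1 January samples used to compare the model
#' with annual field estimates.
#'
#' @param params a [krill_params()] object; initial abundances are taken
#'   from its `L0`, `J0`, `A0` entries.
#' @param years number of simulated years (>= 1); 1 January samples are
#'   taken at `t = 0, 1, ..., years - 1` (one per simulated year).
#' @param anomalies optional annual loss-anomaly table (columns `year`,
#'   `delta_L`, `delta_J`), see [mortality_at()].
#' @param dt trajectory output step in years (solver steps are adaptive and
#'   independent of this).
#' @param rtol,atol solver tolerances.
#' @param engine `"compiled"` (C right-hand side, fast) or `"R"` (reference
#'   implementation via [krill_rhs()]); both give the same solution to
#'   solver tolerance.
#' @param jan1_only if `TRUE`, only the 1 January samples are computed
#'   (fast path used by the fitting routines).
#' @return An object of class `krill_sim`: list with `trajectory`
#'   (tibble `t`, `L`, `J`, `A`), `jan1` (tibble `year`, `t`, `L`, `J`,
#'   `A`), `params`, and `anomalies`.
#' @examples
#' sim <- simulate_krill(krill_params("RK"), years = 10)
#' sim$jan1
#' @export
simulate_krill <- function(params, years = 27, anomalies = NULL, dt = 1 / 36,
                           rtol = 1e-8, atol = 1e-10,
                           engine = c("compiled", "R"), jan1_only = FALSE) {
  engine <- match.arg(engine)
  stopifnot(years >= 1)
  validate_krill_params(params)
  y0 <- c(L = params$L0, J = params$J0, A = params$A0)
  if (jan1_only) {
    times <- as.numeric(seq_len(years) - 1)
  } else {
    nstep <- max(1L, round(1 / dt))
    times <- (0:(years * nstep)) / nstep
  }

  if (engine == "compiled") {
    out <- deSolve::ode(
      y = y0, times = times, func = "krill_derivs",
      parms = .pack_parms(params, anomalies),
      dllname = "krillab", initfunc = "krill_init",
      rtol = rtol, atol = atol, method = "lsoda"
    )
  } else {
    rhs <- function(t, y, p) list(krill_rhs(t, y, params, anomalies))
    out <- deSolve::ode(
      y = y0, times = times, func = rhs, parms = NULL,
      rtol = rtol, atol = atol, method = "lsoda"
    )
  }
  if (attr(out, "istate")[1] < 0) {
    stop(
      "ODE integration failed; last valid time t = ",
      max(out[stats::complete.cases(out), "time"])
    )
  }
  traj <- tibble::tibble(
    t = out[, "time"],
    L = pmax(out[, "L"], 0),
    J = pmax(out[, "J"], 0),
    A = pmax(out[, "A"], 0)
  )
  jan_t <- as.numeric(seq_len(years) - 1)
  jan1 <- traj[match(jan_t, traj$t), ]
  jan1 <- tibble::tibble(year = seq_len(years), jan1)
  structure(
    list(trajectory = traj, jan1 = jan1, params = params, anomalies = anomalies),
    class = "krill_sim"
  )
}

#' @export
print.krill_sim <- function(x, ...) {
  cat(
    "<krill_sim>", nrow(x$jan1), "years,", x$params$preset, "preset,",
    if (is.null(x$anomalies)) "no anomalies" else "with loss anomalies", "\n"
  )
  print(x$jan1, n = 5)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.krill_sim <- function(x, what = c("jan1", "trajectory"), ...) {
  what <- match.arg(what)
  df <- x[[what]]
  tidyr::pivot_longer(df, cols = c("L", "J", "A"),
    names_to = "cohort", values_to = "abundance"
  )
}

#' Plot a simulated trajectory
#'
#' Stage abundances over time on a log scale, with the 1 January samples
#' overlaid as points.
#'
#' @param object a `krill_sim` object.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.krill_sim <- function(object, ...) {
  traj <- tidy.krill_sim(object, "trajectory")
  jan <- tidy.krill_sim(object, "jan1")
  ggplot2::ggplot(traj, ggplot2::aes(
    x = .data$t, y = .data$abundance, colour = .data$cohort
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point(
      data = jan, ggplot2::aes(x = .data$t), size = 0.8
    ) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "time (years)", y = expression(abundance ~ (ind / m^2)),
      colour = "cohort"
    )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Export a simulation as tidy CSV files
#'
#' Writes the continuous trajectory (`t`, `L`, `J`, `A`) and the 1 January
#' samples (`year`, `L`, `J`, `A`) to two CSV files.
#'
#' @param sim a `krill_sim` object.
#' @param traj_path,jan1_path output file paths.
#' @return invisibly, the two paths.
#' @export
write_trajectory <- function(sim, traj_path, jan1_path) {
  utils::write.csv(sim$trajectory, traj_path, row.names = FALSE)
  utils::write.csv(
    sim$jan1[, c("year", "L", "J", "A")], jan1_path, row.names = FALSE
  )
  invisible(c(traj_path, jan1_path))
}
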