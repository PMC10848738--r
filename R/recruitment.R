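#' Seasonal transition-window activation function
#'
#' Smooth dome-shaped function with period 1 year that opens the transition
#' windows of the life-history labyrinth model:
#' \deqn{f(t, t_0) = \exp\!\left(-\left[\frac{\sin \pi (t - t_0)}
#'   {\sin(\pi \tau / 2)}\right]^{2m} \ln 2\right)}
#' It equals 1 at `t = t0 + integer`, drops to 1/2 at `t0 +- tau_window/2`,
#' and with growing steepness exponent `m_exp` approaches a rectangular
#' pulse of width `tau_window` (its integral over one period tends to
#' `tau_window` as `m_exp` grows — the role of the `ln 2` normalization).
#'
#' @param t time in years (vectorized). The integer part is the calendar
#'   year; `t = 0` is 1 January of the first modelled year.
#' @param t0 window-centre phase in years.
#' @param tau_window window duration in years, in (0, 1).
#' @param m_exp steepness exponent (integer >= 1); default 5.
#' @return values in (0, 1].
#' @examples
#' activation(0.1, 0, 0.2, 5)   # half-maximum at tau/2 from the centre
#' @export
activation <- function(t, t0, tau_window = 0.2, m_exp = 5) {
  if (tau_window <= 0 || tau_window >= 1) {
    stop("tau_window must lie strictly between 0 and 1")
  }
  if (m_exp < 1) stop("m_exp must be >= 1")
  s <- sin(pi * (t - t0)) / sin(pi * tau_window / 2)
  exp(-(s^2)^m_exp * log(2))
}

#' Deriso-Schnute normalizing constant
#'
#' The constant \eqn{\beta_\gamma = \gamma / (\gamma + 1)^{1 + 1/\gamma}}
#' that makes the habitat capacity `G_max` an independent parameter of the
#' generalized recruitment function: with this normalization
#' \eqn{\sup_A R(A) = G_{max}} for every shape \eqn{\gamma \in [-1, 0)}.
#' The endpoint values are taken as analytic limits:
#' \eqn{\beta_{-1} = -1} and \eqn{\beta_\gamma \to \gamma/e} as
#' \eqn{\gamma \to 0^-}.
#'
#' @param gamma recruitment shape in `[-1, 0)`; `-1` is Beverton-Holt,
#'   `gamma -> 0` the Ricker limit.
#' @return the (negative) normalizing constant.
#' @export
beta_gamma <- function(gamma) {
  if (any(gamma < -1 | gamma >= 0)) stop("gamma must lie in [-1, 0)")
  ifelse(
    abs(gamma + 1) < 1e-8, -1,
    ifelse(abs(gamma) < 1e-4, gamma / exp(1),
      gamma / (gamma + 1)^(1 + 1 / gamma)
    )
  )
}

#' Generalized Deriso-Schnute stock-recruitment function
#'
#' Egg production rate as a function of adult abundance,
#' \deqn{R(A) = L_{max} A \left(1 - \beta_\gamma \frac{L_{max} A}
#'   {G_{max}}\right)^{1/\gamma}}
#' with [beta_gamma()] normalization. `L_max` is the initial slope
#' (eggs/year per adult at vanishing density) and `G_max` the habitat
#' capacity: the supremum of `R` over `A` equals `G_max` for every
#' `gamma`. At `gamma = -1` this is the saturating Beverton-Holt form
#' `L_max A / (1 + L_max A / G_max)`; as `gamma -> 0` it approaches the
#' dome-shaped Ricker form `L_max A exp(-L_max A / (e G_max))`
#' (overcompensation: recruitment declines once adults exceed a critical
#' density). The Ricker limit expression is used when `|gamma| < 1e-4`.
#'
#' @param A adult abundance (ind/m^2), non-negative; vectorized.
#' @param params a [krill_params()] object, or `NULL` when the three scalar
#'   parameters are given directly.
#' @param L_max,G_max,gamma scalar overrides of the corresponding entries
#'   in `params`.
#' @return egg production rate (eggs/year per m^2).
#' @examples
#' recruitment(1, krill_params("RK"))
#' @export
recruitment <- function(A, params = NULL, L_max = params$L_max,
                        G_max = params$G_max, gamma = params$gamma) {
  if (any(A < 0)) stop("adult abundance A must be non-negative")
  if (any(gamma < -1 | gamma >= 0)) stop("gamma must lie in [-1, 0)")
  x <- L_max * A
  if (abs(gamma) < 1e-4) {
    x * exp(-x / (exp(1) * G_max))
  } else if (abs(gamma + 1) < 1e-8) {
    x / (1 + x / G_max)
  } else {
    b <- beta_gamma(gamma)
    x * (1 - b * x / G_max)^(1 / gamma)
  }
}

#' Fraction of individuals failing to transit a stage window
#'
#' The stage transition at rate `r` acts over a window of duration
#' `tau_window`; the transit is exponential, so the proportion left behind
#' is `exp(-r * tau_window)`. Small leakage is the design goal of the
#' windowed-transition construction: it makes the model nearly insensitive
#' to the exact value of `r`.
#'
#' @param r transition rate (1/year), positive.
#' @param tau_window window duration (year), positive.
#' @return leakage fraction in (0, 1).
#' @examples
#' leakage_fraction(30, 0.2)
#' @export
leakage_fraction <- function(r, tau_window) {
  stopifnot(r > 0, tau_window > 0)
  exp(-r * tau_window)
}
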