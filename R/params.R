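#' Model parameters for the stage-structured krill model
#'
#' Constructs the full parameter set of the life-history labyrinth model:
#' recruitment shape and scale, stage-transition rate and window duration,
#' background mortalities and initial abundances. Two presets are provided,
#' corresponding to the Beverton-Holt (`"BH"`, `gamma = -1`) and Ricker
#' (`"RK"`, `gamma = -0.09`) regimes of the generalized Deriso-Schnute
#' stock-recruitment function, with fitted standard parameters and initial
#' conditions for the 27-year Western Antarctic Peninsula series.
#'
#' @param preset `"RK"` (Ricker-like, intercohort competition) or `"BH"`
#'   (Beverton-Holt, saturating recruitment).
#' @param ... named overrides for any parameter, e.g. `m_L = 2`, `L0 = 1`.
#'
#' @return An object of class `krill_params`: a named list with elements
#'   `gamma` (recruitment shape, in `[-1, 0)`), `r` (transition rate,
#'   1/year), `tau_window` (window duration, year), `m_exp` (window
#'   steepness exponent), `L_max` (initial recruitment slope, eggs/year per
#'   individual), `G_max` (habitat capacity, eggs/year per m^2), `m_L`,
#'   `m_J`, `m_A` (background mortalities, 1/year), and initial abundances
#'   `L0`, `J0`, `A0` (ind/m^2).
#' @examples
#' p <- krill_params("RK")
#' p$gamma
#' krill_params("BH", m_A = 0.7)$m_A
#' @export
krill_params <- function(preset = c("RK", "BH"), ...) {
  preset <- match.arg(preset)
  base <- switch(preset,
    BH = list(
      gamma = -1, r = 30, tau_window = 0.2, m_exp = 5,
      L_max = 3368, G_max = 101,
      m_L = 2.6, m_J = 1.31, m_A = 0.6,
      L0 = 1.9, J0 = 2.94, A0 = 5.07
    ),
    RK = list(
      gamma = -0.09, r = 30, tau_window = 0.2, m_exp = 5,
      L_max = 2481, G_max = 353,
      m_L = 1.76, m_J = 1.13, m_A = 0.51,
      L0 = 0.75, J0 = 2.6, A0 = 3.9
    )
  )
  dots <- list(...)
  if (length(dots)) {
    unknown <- setdiff(names(dots), names(base))
    if (length(unknown)) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    }
    base[names(dots)] <- dots
  }
  base$preset <- preset
  validate_krill_params(base)
  structure(base, class = "krill_params")
}

validate_krill_params <- function(p) {
  stopifnot(
    p$gamma >= -1, p$gamma < 0,
    p$r > 0,
    p$tau_window > 0, p$tau_window < 1,
    p$m_exp >= 1,
    p$L_max > 0, p$G_max > 0,
    p$m_L > 0, p$m_J > 0, p$m_A > 0,
    p$L0 >= 0, p$J0 >= 0, p$A0 >= 0
  )
  invisible(p)
}

#' @export
print.krill_params <- function(x, ...) {
  cat("<krill_params> preset:", x$preset, "\n")
  flds <- setdiff(names(x), "preset")
  vals <- vapply(flds, function(f) format(x[[f]]), character(1))
  cat(paste0("  ", format(flds), " = ", vals), sep = "\n")
  invisible(x)
}

#' @export
as_tibble.krill_params <- function(x, ...) {
  tibble::tibble(
    parameter = setdiff(names(x), "preset"),
    value = unlist(x[setdiff(names(x), "preset")], use.names = FALSE)
  )
}

#' Read or write a parameter table
#'
#' Flat CSV round-trip for [krill_params()] objects (columns `parameter`,
#' `value`), so fitted parameter sets can be archived alongside run outputs.
#'
#' @param params a `krill_params` object.
#' @param path file path.
#' @param preset preset label to attach on reading (affects nothing but the
#'   stored tag).
#' @return `write_params()` returns `path` invisibly; `read_params()` a
#'   `krill_params` object.
#' @export
write_params <- function(params, path) {
  utils::write.csv(as_tibble.krill_params(params), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path, preset = "RK") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  args <- as.list(stats::setNames(df$value, df$parameter))
  do.call(krill_params, c(list(preset = preset), args))
}
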