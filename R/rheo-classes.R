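#' Rheometer sweep record
#'
#' Container for one oscillatory rheometer test: an abscissa (time in
#' minutes, frequency in Hz, stress amplitude in Pa, or seconds for the
#' three-interval recovery protocol) with paired storage (\eqn{G'}) and
#' loss (\eqn{G''}) moduli in Pa.
#'
#' @param test_type one of `"time_sweep"`, `"freq_sweep"`,
#'   `"amplitude_sweep"`, `"recovery"`.
#' @param abscissa numeric vector, strictly increasing. Units depend on
#'   `test_type`: minutes, Hz, Pa or seconds respectively.
#' @param Gp,Gpp storage and loss moduli, Pa, same length as `abscissa`,
#'   non-negative.
#' @param temperature test temperature, degrees C (carried, not modeled).
#' @return an object of class `rheo_sweep`.
#' @export
rheo_sweep <- function(test_type, abscissa, Gp, Gpp, temperature = 37) {
  test_type <- match.arg(test_type,
                         c("time_sweep", "freq_sweep", "amplitude_sweep", "recovery"))
  abscissa <- as.numeric(abscissa)
  Gp <- as.numeric(Gp)
  Gpp <- as.numeric(Gpp)
  if (length(abscissa) != length(Gp) || length(abscissa) != length(Gpp))
    stop("abscissa, Gp and Gpp must have equal lengths")
  if (length(abscissa) == 0L) stop("empty sweep")
  if (any(!is.finite(abscissa)) || any(!is.finite(Gp)) || any(!is.finite(Gpp)))
    stop("non-finite values in sweep")
  if (any(diff(abscissa) <= 0)) stop("abscissa must be strictly increasing")
  if (any(Gp < 0) || any(Gpp < 0)) stop("moduli must be non-negative")
  structure(
    list(test_type = test_type, abscissa = abscissa, Gp = Gp, Gpp = Gpp,
         temperature = temperature),
    class = "rheo_sweep"
  )
}

#' @export
print.rheo_sweep <- function(x, ...) {
  units <- c(time_sweep = "min", freq_sweep = "Hz",
             amplitude_sweep = "Pa", recovery = "s")[x$test_type]
  cat(sprintf("<rheo_sweep: %s, %d points, %.4g-%.4g %s, %.3g C>\n",
              x$test_type, length(x$abscissa),
              min(x$abscissa), max(x$abscissa), units, x$temperature))
  invisible(x)
}

#' Loss tangent of a sweep
#'
#' tan delta = G''/G', computed pointwise.
#' @param sweep a [rheo_sweep()].
#' @return numeric vector.
#' @export
tan_delta <- function(sweep) {
  stopifnot(inherits(sweep, "rheo_sweep"))
  sweep$Gpp / sweep$Gp
}

#' Steady-shear flow curve
#'
#' Shear rate versus viscosity record used for shear-thinning power-law
#' fits (\eqn{\eta = K \dot\gamma^{n-1}}).
#'
#' @param shear_rate strictly increasing, positive, 1/s.
#' @param viscosity positive, Pa s, same length.
#' @return an object of class `flow_curve`.
#' @export
flow_curve <- function(shear_rate, viscosity) {
  shear_rate <- as.numeric(shear_rate)
  viscosity <- as.numeric(viscosity)
  if (length(shear_rate) != length(viscosity))
    stop("shear_rate and viscosity must have equal lengths")
  if (length(shear_rate) == 0L) stop("empty flow curve")
  if (any(!is.finite(shear_rate)) || any(!is.finite(viscosity)))
    stop("non-finite values in flow curve")
  if (any(shear_rate <= 0) || any(viscosity <= 0))
    stop("flow curve entries must be positive")
  if (any(diff(shear_rate) <= 0))
    stop("shear_rate must be strictly increasing")
  structure(list(shear_rate = shear_rate, viscosity = viscosity),
            class = "flow_curve")
}

#' @export
print.flow_curve <- function(x, ...) {
  cat(sprintf("<flow_curve: %d points, %.4g-%.4g 1/s>\n",
              length(x$shear_rate), min(x$shear_rate), max(x$shear_rate)))
  invisible(x)
}
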