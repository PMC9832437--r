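# Scalar characterizations from rheometer sweeps: gel point, yield point,
# power-law viscosity parameters, three-interval recovery, LVE summary.

# First sustained sign change of d from negative to positive.
# Returns the bracketing index i (d[i] <= 0 < d[i + 1]) or the tie index
# (d[i] == 0), or NA if no sustained crossing exists.
.find_crossing <- function(d, sustain = 2L) {
  n <- length(d)
  for (i in seq_len(n - 1L)) {
    if (d[i] == 0) {
      # tie: accept if the positive regime is sustained afterwards
      after <- d[seq(i + 1L, min(n, i + sustain))]
      if (all(after > 0)) return(list(index = i, tie = TRUE))
      next
    }
    if (d[i] < 0 && d[i + 1L] >= 0) {
      if (d[i + 1L] == 0) {
        after <- d[seq(min(n, i + 2L), min(n, i + 1L + sustain))]
        if (i + 2L <= n && all(after > 0))
          return(list(index = i + 1L, tie = TRUE))
        next
      }
      upto <- min(n, i + sustain)
      if (all(d[seq(i + 1L, upto)] > 0)) return(list(index = i, tie = FALSE))
    }
  }
  NULL
}

#' Detect the gel point of a time sweep
#'
#' The gel point is the time at which the storage modulus G' first
#' (sustainedly) exceeds the loss modulus G'': the onset of solid-like
#' behavior. The crossing is located by interpolating log-modulus
#' linearly in time between the two bracketing samples; a single-point
#' sign flip that immediately reverts is rejected as noise
#' (`sustain` consecutive samples must hold the new sign). When a sample
#' has G' exactly equal to G'', that sample's time is reported.
#'
#' @param sweep a [rheo_sweep()] with `test_type = "time_sweep"`, at
#'   least 4 points.
#' @param sustain number of consecutive post-crossing samples that must
#'   keep G' > G''. Default 2.
#' @return an object of class `gel_point_result` with fields
#'   `crossover_time` (minutes, `NA` if the material never gels in the
#'   window), `method` and `bracketing_indices`.
#' @export
detect_gel_point <- function(sweep, sustain = 2L) {
  stopifnot(inherits(sweep, "rheo_sweep"))
  if (sweep$test_type != "time_sweep")
    stop("detect_gel_point requires a time sweep")
  if (length(sweep$abscissa) < 4L) stop("need at least 4 points")
  res <- .interp_crossing(sweep$abscissa, sweep$Gp, sweep$Gpp,
                          logx = FALSE, sustain = sustain)
  structure(list(crossover_time = res$where, method = "crossover",
                 bracketing_indices = res$bracket),
            class = "gel_point_result")
}

# Shared crossing + interpolation logic. logx: interpolate in log(abscissa)
# (amplitude sweeps) or linear abscissa (time sweeps). Moduli are always
# interpolated on the log scale since they span decades; if a bracketing
# modulus is zero, falls back to linear-modulus interpolation.
.interp_crossing <- function(x, Gp, Gpp, logx, sustain) {
  d <- Gp - Gpp
  cr <- .find_crossing(d, sustain = sustain)
  if (is.null(cr)) return(list(where = NA_real_, bracket = c(NA_integer_, NA_integer_)))
  i <- cr$index
  if (cr$tie) return(list(where = x[i], bracket = c(i, i)))
  xi <- if (logx) log(x[c(i, i + 1L)]) else x[c(i, i + 1L)]
  if (all(Gp[c(i, i + 1L)] > 0) && all(Gpp[c(i, i + 1L)] > 0)) {
    dd <- log(Gp[c(i, i + 1L)]) - log(Gpp[c(i, i + 1L)])
  } else {
    dd <- d[c(i, i + 1L)]
  }
  w <- xi[1] - dd[1] * diff(xi) / diff(dd)
  list(where = if (logx) exp(w) else w, bracket = c(i, i + 1L))
}

#' @export
print.gel_point_result <- function(x, ...) {
  if (is.na(x$crossover_time)) {
    cat("<gel_point: no G'-G'' crossover in window>\n")
  } else {
    cat(sprintf("<gel_point: %.4g min (samples %d-%d, %s)>\n",
                x$crossover_time, x$bracketing_indices[1],
                x$bracketing_indices[2], x$method))
  }
  invisible(x)
}

#' Detect the yield point of an amplitude sweep
#'
#' The yield point is the oscillatory stress amplitude at which G''
#' starts to prevail over G' -- the stress above which the gel flows.
#' The crossing is located by log-log interpolation between the
#' bracketing samples. A sweep whose lowest amplitude already has
#' G' <= G'' carries no solid regime at all; that is signaled as an
#' error of class `"no_solid_regime"`, distinct from a solid sweep with
#' no crossing in range (which returns `sigma_y = NA`).
#'
#' @param sweep a [rheo_sweep()] with `test_type = "amplitude_sweep"`.
#' @param sustain consecutive post-crossing samples required to keep
#'   G'' > G'. Default 2.
#' @return an object of class `yield_point_result` with fields `sigma_y`
#'   (Pa or `NA`) and `bracketing_indices`.
#' @export
detect_yield_point <- function(sweep, sustain = 2L) {
  stopifnot(inherits(sweep, "rheo_sweep"))
  if (sweep$test_type != "amplitude_sweep")
    stop("detect_yield_point requires an amplitude sweep")
  if (length(sweep$abscissa) < 4L) stop("need at least 4 points")
  if (sweep$Gp[1] <= sweep$Gpp[1])
    stop(errorCondition(
      "G' <= G'' at the lowest amplitude: no solid regime to yield from",
      class = c("no_solid_regime", "error", "condition")))
  # crossing of (Gpp - Gp) from negative to positive
  res <- .interp_crossing(sweep$abscissa, sweep$Gpp, sweep$Gp,
                          logx = TRUE, sustain = sustain)
  structure(list(sigma_y = res$where, bracketing_indices = res$bracket),
            class = "yield_point_result")
}

#' @export
print.yield_point_result <- function(x, ...) {
  if (is.na(x$sigma_y)) {
    cat("<yield_point: no G'-G'' crossing in range>\n")
  } else {
    cat(sprintf("<yield_point: %.4g Pa (samples %d-%d)>\n", x$sigma_y,
                x$bracketing_indices[1], x$bracketing_indices[2]))
  }
  invisible(x)
}

#' Fit a power-law (Ostwald-de Waele) model to a flow curve
#'
#' Least squares of log viscosity on log shear rate: the slope is
#' \eqn{n - 1} and the intercept \eqn{\log K}, so
#' \eqn{\eta = K \dot\gamma^{n-1}}. Exact on noiseless power-law data.
#'
#' @param curve a [flow_curve()], at least 3 points, all positive.
#' @return an object of class `power_law_fit` with fields `K` (Pa s^n),
#'   `n`, `r_squared`, and the underlying `lm` fit in `$fit`.
#' @export
fit_power_law <- function(curve) {
  stopifnot(inherits(curve, "flow_curve"))
  if (length(curve$shear_rate) < 3L) stop("need at least 3 points")
  lx <- log(curve$shear_rate)
  ly <- log(curve$viscosity)
  fit <- stats::lm(ly ~ lx)
  co <- stats::coef(fit)
  rss <- sum(stats::residuals(fit)^2)
  tss <- sum((ly - mean(ly))^2)
  r2 <- if (tss <= .Machine$double.eps * sum(ly^2) + 1e-300) 1 else 1 - rss / tss
  structure(list(K = exp(unname(co[1])), n = unname(co[2]) + 1,
                 r_squared = r2, fit = fit),
            class = "power_law_fit")
}

#' @export
print.power_law_fit <- function(x, ...) {
  cat(sprintf("<power_law_fit: K = %.4g Pa.s^n, n = %.4g, R^2 = %.4f>\n",
              x$K, x$n, x$r_squared))
  invisible(x)
}

#' @export
coef.power_law_fit <- function(object, ...) {
  c(K = object$K, n = object$n)
}

#' Predicted viscosity from a power-law fit
#' @param object a `power_law_fit`.
#' @param shear_rate shear rates, 1/s.
#' @param ... unused.
#' @return viscosities, Pa s.
#' @export
predict.power_law_fit <- function(object, shear_rate, ...) {
  object$K * shear_rate^(object$n - 1)
}

#' Structural recovery from a three-interval trace
#'
#' For the protocol of three strain amplitudes (low, high, low) applied
#' for 100, 200 and 100 s, the recovery fraction is the median G' over
#' the last half of interval 3 divided by the median G' over the last
#' half of interval 1.
#'
#' @param trace a [rheo_sweep()] with `test_type = "recovery"`, abscissa
#'   in seconds from the start of interval 1.
#' @param interval_bounds end times of the three intervals, seconds.
#'   Default `c(100, 300, 400)`.
#' @return an object of class `recovery_result` with fields `recovery`,
#'   `plateau_initial` and `plateau_final` (Pa).
#' @export
compute_recovery <- function(trace, interval_bounds = c(100, 300, 400)) {
  stopifnot(inherits(trace, "rheo_sweep"))
  if (trace$test_type != "recovery")
    stop("compute_recovery requires a recovery trace")
  b <- as.numeric(interval_bounds)
  if (length(b) != 3L || any(diff(b) <= 0) || b[1] <= 0)
    stop("interval_bounds must be three increasing positive times")
  t <- trace$abscissa
  in2 <- t > b[1] & t <= b[2]
  lh1 <- t > b[1] / 2 & t <= b[1]
  lh3 <- t > (b[2] + b[3]) / 2 & t <= b[3]
  if (!any(in2)) stop("no samples cover interval 2 (protocol violation)")
  if (!any(lh1) || !any(lh3))
    stop("intervals 1 and 3 must each be sampled over their last half")
  p1 <- stats::median(trace$Gp[lh1])
  p3 <- stats::median(trace$Gp[lh3])
  structure(list(recovery = p3 / p1, plateau_initial = p1,
                 plateau_final = p3),
            class = "recovery_result")
}

#' @export
print.recovery_result <- function(x, ...) {
  cat(sprintf("<recovery: %.3f (G' %.4g -> %.4g Pa)>\n",
              x$recovery, x$plateau_initial, x$plateau_final))
  invisible(x)
}

#' Summarize the linear viscoelastic region of a frequency sweep
#'
#' Arithmetic means of G', G'' and the pointwise loss tangent
#' tan delta = G''/G' over a frequency band.
#'
#' @param sweep a [rheo_sweep()] with `test_type = "freq_sweep"`.
#' @param band numeric length-2 frequency interval, Hz, inside the sweep
#'   range.
#' @return list with `mean_Gp`, `mean_Gpp`, `mean_tan_delta`, `n_points`,
#'   `band`.
#' @export
summarize_lve <- function(sweep, band = range(sweep$abscissa)) {
  stopifnot(inherits(sweep, "rheo_sweep"))
  if (sweep$test_type != "freq_sweep")
    stop("summarize_lve requires a frequency sweep")
  band <- as.numeric(band)
  if (length(band) != 2L || band[1] >= band[2]) stop("band must be an interval")
  rng <- range(sweep$abscissa)
  if (band[1] < rng[1] || band[2] > rng[2])
    stop("band lies outside the sweep's frequency range")
  idx <- sweep$abscissa >= band[1] & sweep$abscissa <= band[2]
  if (!any(idx)) stop("no samples inside band")
  list(mean_Gp = mean(sweep$Gp[idx]), mean_Gpp = mean(sweep$Gpp[idx]),
       mean_tan_delta = mean(sweep$Gpp[idx] / sweep$Gp[idx]),
       n_points = sum(idx), band = band)
}
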