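# Drop-spreading geometry: spreading ratio and spherical-cap minimum
# layer height. Units: volume in microliters (1 uL = 1 mm^3), lengths mm.

#' Drop observation record
#'
#' @param volume_ul dispensed volume, microliters (> 0).
#' @param deq_mm equilibrium contact diameter, mm (>= 0).
#' @param time_min minutes since the beginning of crosslinking (optional).
#' @return a `drop_record` list.
#' @export
drop_record <- function(volume_ul, deq_mm, time_min = NA_real_) {
  if (volume_ul <= 0) stop("volume must be > 0")
  if (deq_mm < 0) stop("D_eq must be >= 0")
  structure(list(volume_ul = volume_ul, deq_mm = deq_mm,
                 time_min = time_min),
            class = "drop_record")
}

#' Diameter of the non-spreading (spherical) drop
#'
#' The diameter of a sphere of the dispensed volume,
#' \eqn{D_{ideal} = (6V/\pi)^{1/3}} with V in mm^3.
#'
#' @param volume_ul volume, microliters, > 0.
#' @return diameter, mm.
#' @export
ideal_drop_diameter <- function(volume_ul) {
  if (any(volume_ul <= 0)) stop("volume must be > 0")
  (6 * volume_ul / pi)^(1 / 3)
}

#' Spreading ratio
#'
#' \eqn{S_0 = D_{eq} / D_{ideal}}: the equilibrium contact diameter over
#' the equal-volume sphere diameter. Values above one indicate outward
#' flow (self-spreading); exactly one is a non-spreading spherical drop.
#' A zero contact diameter returns 0 with attribute `non_wetting = TRUE`.
#'
#' @param rec a [drop_record()].
#' @return numeric S0 (dimensionless).
#' @export
spreading_ratio <- function(rec) {
  stopifnot(inherits(rec, "drop_record"))
  s0 <- rec$deq_mm / ideal_drop_diameter(rec$volume_ul)
  if (rec$deq_mm == 0) {
    attr(s0, "non_wetting") <- TRUE
    warning("zero contact diameter: non-wetting drop")
  }
  s0
}

# Spherical-cap volume from height h and contact radius a (mm -> mm^3).
.cap_volume <- function(h, a) pi * h / 6 * (3 * a^2 + h^2)

#' Minimum layer height of a spread drop
#'
#' A drop spread on a flat surface is modeled as a spherical cap of
#' contact radius \eqn{a = D_{eq}/2} and height h satisfying
#' \eqn{V = (\pi h/6)(3a^2 + h^2)}. The unique positive root is found by
#' bisection on (0, D_eq/2 + D_ideal] to `tol` mm; it is the minimum
#' layer height obtainable with the material at that time point.
#' Requires the spread regime, `D_eq >= D_ideal`.
#'
#' @param volume_ul volume, microliters, > 0.
#' @param deq_mm equilibrium contact diameter, mm.
#' @param tol absolute bisection tolerance on h, mm.
#' @return cap height, mm.
#' @export
cap_height <- function(volume_ul, deq_mm, tol = 1e-12) {
  if (volume_ul <= 0) stop("volume must be > 0")
  d_ideal <- ideal_drop_diameter(volume_ul)
  if (deq_mm < d_ideal * (1 - 1e-12))
    stop("D_eq below the equal-volume sphere diameter: cap model invalid ",
         "(non-spread drop)")
  a <- deq_mm / 2
  f <- function(h) .cap_volume(h, a) - volume_ul
  lo <- 0
  hi <- deq_mm / 2 + d_ideal
  if (f(hi) < 0) stop("no cap root in bracket")  # cannot happen for valid input
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) < 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Characterize one drop observation
#'
#' Combines [ideal_drop_diameter()], [spreading_ratio()] and (in the
#' spread regime) [cap_height()].
#'
#' @param rec a [drop_record()].
#' @return an object of class `spread_result` with fields `D_ideal` (mm),
#'   `S0`, `h_min` (mm, `NA` when `D_eq < D_ideal`) and `regime`
#'   (`"spread"` or `"non_spread"`).
#' @export
characterize_drop <- function(rec) {
  stopifnot(inherits(rec, "drop_record"))
  d_ideal <- ideal_drop_diameter(rec$volume_ul)
  s0 <- rec$deq_mm / d_ideal
  spread <- rec$deq_mm >= d_ideal * (1 - 1e-12)
  h <- if (spread) cap_height(rec$volume_ul, rec$deq_mm) else NA_real_
  structure(list(D_ideal = d_ideal, S0 = s0, h_min = h,
                 regime = if (spread) "spread" else "non_spread",
                 volume_ul = rec$volume_ul, deq_mm = rec$deq_mm),
            class = "spread_result")
}

#' @export
print.spread_result <- function(x, ...) {
  cat(sprintf("<spread_result: S0 = %.3f, D_ideal = %.3f mm, h_min = %s>\n",
              x$S0, x$D_ideal,
              if (is.na(x$h_min)) "NA (non-spread)"
              else sprintf("%.3f mm", x$h_min)))
  invisible(x)
}

#' Spreading time course and processability window
#'
#' Labels each observation as `self_spreading` (before the gel point) or
#' `shape_retaining` (at or after the gel point -- the gel point is when
#' solid behavior starts, so the boundary is closed on the gel side),
#' and computes S0 and the minimum layer height per time point.
#' Self-spreading ability decays as crosslinking advances, so S0 should
#' be non-increasing in time; violations are flagged with a warning and
#' in the `monotone_ok` attribute.
#'
#' @param records list of [drop_record()]s, sorted by `time_min`.
#' @param gel_point_min gel point, minutes (may be `NA`: all records are
#'   then labeled `self_spreading`).
#' @return data.frame with columns `time_min`, `deq_mm`, `S0`, `h_min`,
#'   `window`; attribute `monotone_ok`.
#' @export
spreading_timecourse <- function(records, gel_point_min = NA_real_) {
  if (!length(records)) stop("no records")
  stopifnot(all(vapply(records, inherits, logical(1), "drop_record")))
  times <- vapply(records, function(r) r$time_min, numeric(1))
  if (any(is.na(times))) stop("all records need time_since_crosslink")
  if (is.unsorted(times, strictly = TRUE))
    stop("records must be sorted by time (strictly increasing)")
  res <- lapply(records, characterize_drop)
  s0 <- vapply(res, function(r) r$S0, numeric(1))
  h <- vapply(res, function(r) r$h_min, numeric(1))
  window <- if (is.na(gel_point_min)) rep("self_spreading", length(times))
            else ifelse(times < gel_point_min, "self_spreading", "shape_retaining")
  monotone_ok <- !any(diff(s0) > 0)
  if (!monotone_ok)
    warning("S0 increases between consecutive time points; ",
            "expected non-increasing as crosslinking advances")
  out <- data.frame(time_min = times,
                    deq_mm = vapply(records, function(r) r$deq_mm, numeric(1)),
                    S0 = s0, h_min = h, window = window)
  attr(out, "monotone_ok") <- monotone_ok
  out
}
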