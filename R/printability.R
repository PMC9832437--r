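# Shape-fidelity scores for extrusion-based bioprinting: spreading factor
# S, uniformity U, perimeter Pe, pore Pr, printability P, and a capillary
# wall-stress estimate of the minimum extrusion pressure. Unity (100% for
# S) is the ideal print for every score.

#' Needle geometry
#'
#' @param inner_diameter_mm needle inner diameter, mm (> 0). The 22G
#'   standard is 0.41 mm; see [gauge_inner_diameter()].
#' @param length_mm needle length, mm (> 0).
#' @return a `needle_geometry` list.
#' @export
needle_geometry <- function(inner_diameter_mm = 0.41, length_mm = 12.5) {
  if (inner_diameter_mm <= 0 || length_mm <= 0)
    stop("needle geometry must be positive")
  structure(list(inner_diameter_mm = inner_diameter_mm,
                 length_mm = length_mm),
            class = "needle_geometry")
}

#' Inner diameter of a standard dispensing-needle gauge
#'
#' Nominal inner diameters (mm) of common blunt dispensing needles.
#'
#' @param gauge string such as `"22G"`.
#' @return inner diameter, mm.
#' @export
gauge_inner_diameter <- function(gauge) {
  tbl <- c("18G" = 0.84, "20G" = 0.60, "21G" = 0.51, "22G" = 0.41,
           "23G" = 0.34, "25G" = 0.26, "27G" = 0.20)
  g <- toupper(gauge)
  if (!g %in% names(tbl)) stop("unknown gauge: ", gauge)
  unname(tbl[[g]])
}

#' Fiber diameter measurements
#'
#' @param diameters_mm vector of local fiber diameters, mm, all > 0.
#'   Protocol default: 10 random points on each of 5 fibers.
#' @param n_fibers number of fibers measured.
#' @param points_per_fiber points sampled per fiber.
#' @return a `fiber_measurement` list.
#' @export
fiber_measurement <- function(diameters_mm, n_fibers = 5L,
                              points_per_fiber = 10L) {
  diameters_mm <- as.numeric(diameters_mm)
  if (!length(diameters_mm)) stop("empty diameter list")
  if (any(!is.finite(diameters_mm)) || any(diameters_mm <= 0))
    stop("diameters must be positive and finite")
  structure(list(diameters_mm = diameters_mm,
                 n_fibers = as.integer(n_fibers),
                 points_per_fiber = as.integer(points_per_fiber)),
            class = "fiber_measurement")
}

#' Grid side-length measurements
#'
#' @param cad_side_x,cad_side_y theoretical side lengths as provided to
#'   the printer (L0x, L0y), mm > 0.
#' @param sides_x,sides_y measured printed side lengths per axis, mm,
#'   non-empty, all > 0.
#' @return a `grid_measurement` list.
#' @export
grid_measurement <- function(cad_side_x, cad_side_y, sides_x, sides_y) {
  if (cad_side_x <= 0 || cad_side_y <= 0) stop("CAD sides must be > 0")
  sides_x <- as.numeric(sides_x); sides_y <- as.numeric(sides_y)
  if (!length(sides_x) || !length(sides_y))
    stop("printed side arrays must be non-empty")
  if (any(sides_x <= 0) || any(sides_y <= 0))
    stop("printed side lengths must be > 0")
  structure(list(cad_side_x = cad_side_x, cad_side_y = cad_side_y,
                 sides_x = sides_x, sides_y = sides_y),
            class = "grid_measurement")
}

# sd() that is 0 (with optional warning) for a single observation
.sd0 <- function(x, warn_msg = NULL) {
  if (length(x) < 2L) {
    if (!is.null(warn_msg)) warning(warn_msg)
    return(0)
  }
  stats::sd(x)
}

#' Spreading factor S
#'
#' \eqn{S = 100 \, L_{real} / D_{needle}} percent, where L_real is the
#' mean measured fiber diameter. S quantifies the relaxation of the
#' fiber after extrusion; 100% means no relaxation.
#'
#' @param fm a [fiber_measurement()].
#' @param ng a [needle_geometry()].
#' @return S, percent.
#' @export
spreading_factor <- function(fm, ng) {
  stopifnot(inherits(fm, "fiber_measurement"), inherits(ng, "needle_geometry"))
  100 * mean(fm$diameters_mm) / ng$inner_diameter_mm
}

#' Uniformity coefficient U
#'
#' The ideal fiber is straight and homogeneous with diameter
#' \eqn{L_{ideal} = D_{needle} \times S} (S as a fraction, so L_ideal
#' equals the mean measured diameter). U penalizes the dispersion of the
#' local diameters around it:
#' \eqn{U = 1 - SD(L_i) / L_{ideal}}. U = 1 for a perfectly uniform
#' fiber; a single measurement point has undefined dispersion and
#' returns 1 with a warning.
#'
#' @param fm a [fiber_measurement()].
#' @param ng a [needle_geometry()].
#' @return U, dimensionless.
#' @export
uniformity_coefficient <- function(fm, ng) {
  stopifnot(inherits(fm, "fiber_measurement"), inherits(ng, "needle_geometry"))
  l_ideal <- ng$inner_diameter_mm * spreading_factor(fm, ng) / 100
  sd_l <- .sd0(fm$diameters_mm,
               "single measurement point: dispersion undefined, U = 1")
  1 - sd_l / l_ideal
}

#' Perimeter coefficient Pe
#'
#' Ratio of the printed to the CAD perimeter, with the per-axis standard
#' deviations of the printed sides subtracted so irregular sides are
#' penalized:
#' \eqn{P_e = (L_{bx} - SD_{bx} + L_{by} - SD_{by}) / (L_{0x} + L_{0y})}.
#' Pe = 1 when the print adheres perfectly to the CAD perimeter.
#'
#' @param gm a [grid_measurement()].
#' @return Pe, dimensionless.
#' @export
perimeter_coefficient <- function(gm) {
  stopifnot(inherits(gm, "grid_measurement"))
  lbx <- mean(gm$sides_x); lby <- mean(gm$sides_y)
  sdx <- .sd0(gm$sides_x); sdy <- .sd0(gm$sides_y)
  (lbx - sdx + lby - sdy) / (gm$cad_side_x + gm$cad_side_y)
}

#' Pore coefficient Pr
#'
#' Ratio of the printed to the CAD enclosed area,
#' \eqn{P_r = (L_{bx} L_{by}) / (L_{0x} L_{0y})}. Pr = 1 for
#' well-structured, superimposed layers whose pores match the design.
#'
#' @param gm a [grid_measurement()].
#' @return Pr, dimensionless.
#' @export
pore_coefficient <- function(gm) {
  stopifnot(inherits(gm, "grid_measurement"))
  (mean(gm$sides_x) * mean(gm$sides_y)) / (gm$cad_side_x * gm$cad_side_y)
}

#' Printability coefficient P
#'
#' Single-number combination of the average shape-fidelity scores:
#' \eqn{P = U \times P_e \times P_r}. P = 1 when the printed structure
#' is perfectly adherent to the CAD geometry (U = Pe = Pr = 1).
#'
#' @param U,Pe,Pr component coefficients, finite.
#' @return P, dimensionless.
#' @export
printability_coefficient <- function(U, Pe, Pr) {
  if (!all(is.finite(c(U, Pe, Pr))))
    stop("all component scores must be finite")
  U * Pe * Pr
}

#' Minimum extrusion pressure from the yield stress
#'
#' For pressure-driven flow through a cylindrical needle of length L and
#' radius R, the wall shear stress is \eqn{\tau_w = \Delta P R / (2 L)}
#' independently of the constitutive law, so the pressure at which the
#' wall stress reaches the yield stress is
#' \eqn{\Delta P = 2 L \tau_y / R} (`variant = "wall_stress"`, default).
#' With a power-law fit supplied, `variant = "power_law"` additionally
#' applies the Rabinowitsch shear-rate correction factor
#' \eqn{(3n + 1) / (4n)}, which reduces to the Newtonian closed form at
#' n = 1. The result carries the model variant in its `model` attribute.
#'
#' @param yield_stress_pa yield stress, Pa > 0.
#' @param ng a [needle_geometry()].
#' @param flow optional [fit_power_law()] result; selects the power-law
#'   variant.
#' @return pressure, kPa, with attribute `model`.
#' @export
estimate_extrusion_pressure <- function(yield_stress_pa, ng, flow = NULL) {
  stopifnot(inherits(ng, "needle_geometry"))
  if (yield_stress_pa <= 0) stop("yield stress must be > 0")
  R_m <- ng$inner_diameter_mm / 2 / 1000
  L_m <- ng$length_mm / 1000
  dp <- 2 * L_m * yield_stress_pa / R_m
  model <- "wall_stress"
  if (!is.null(flow)) {
    stopifnot(inherits(flow, "power_law_fit"))
    if (flow$n <= 0) stop("flow index must be positive")
    dp <- dp * (3 * flow$n + 1) / (4 * flow$n)
    model <- "power_law"
  }
  structure(dp / 1000, model = model)
}

#' Score one print
#'
#' Computes the full shape-fidelity score set from fiber and grid
#' measurements: S (percent), U, Pe, Pr and P, with the measurement
#' provenance that produced them.
#'
#' @param fm a [fiber_measurement()].
#' @param gm a [grid_measurement()].
#' @param ng a [needle_geometry()].
#' @return an object of class `score_set`.
#' @export
score_print <- function(fm, gm, ng) {
  S <- spreading_factor(fm, ng)
  U <- uniformity_coefficient(fm, ng)
  Pe <- perimeter_coefficient(gm)
  Pr <- pore_coefficient(gm)
  P <- printability_coefficient(U, Pe, Pr)
  structure(list(
    S = S, U = U, Pe = Pe, Pr = Pr, P = P,
    provenance = list(
      n_fiber_points = length(fm$diameters_mm),
      n_fibers = fm$n_fibers, points_per_fiber = fm$points_per_fiber,
      n_sides_x = length(gm$sides_x), n_sides_y = length(gm$sides_y),
      cad_side_x = gm$cad_side_x, cad_side_y = gm$cad_side_y,
      needle_inner_diameter_mm = ng$inner_diameter_mm,
      needle_length_mm = ng$length_mm)
  ), class = "score_set")
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf(
    "<score_set: S = %.1f%%, U = %.4f, Pe = %.4f, Pr = %.4f, P = %.4f>\n",
    x$S, x$U, x$Pe, x$Pr, x$P))
  invisible(x)
}
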