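# Image measurements: drop diameter, fiber width profiles, grid sides,
# particle granulometry, cell area fraction. Segmentation is Otsu by
# default (a deterministic stand-in for manual threshold adjustment),
# with a fixed-value override. Connected components via EBImage::bwlabel.

#' Segmentation configuration
#'
#' @param threshold `"otsu"` (default) or `"fixed"`.
#' @param fixed_value threshold on the 8-bit scale (0-255), required for
#'   `"fixed"`; pixels strictly above it are foreground.
#' @param min_object_area smallest connected component kept, px^2.
#' @param invert treat dark pixels as foreground.
#' @return a `segmentation_config` list.
#' @export
segmentation_config <- function(threshold = c("otsu", "fixed"),
                                fixed_value = NULL, min_object_area = 9,
                                invert = FALSE) {
  threshold <- match.arg(threshold)
  if (threshold == "fixed") {
    if (is.null(fixed_value)) stop("fixed threshold needs fixed_value")
    if (fixed_value < 0 || fixed_value > 255)
      stop("fixed_value must be within the 8-bit range 0-255")
  }
  structure(list(threshold = threshold, fixed_value = fixed_value,
                 min_object_area = min_object_area, invert = invert),
            class = "segmentation_config")
}

# Convert to 8-bit, threshold, return logical foreground matrix.
.binarize <- function(img, cfg) {
  stopifnot(inherits(img, "image_field"),
            inherits(cfg, "segmentation_config"))
  q <- round(img$pixels * 255)               # 8-bit conversion
  if (cfg$threshold == "otsu") {
    thr <- EBImage::otsu(EBImage::Image(q / 255), range = c(0, 1),
                         levels = 256) * 255
  } else {
    thr <- cfg$fixed_value
  }
  fg <- q > thr
  if (cfg$invert) fg <- !fg
  fg
}

# Label foreground, dropping components below min_object_area.
# Returns integer matrix (0 = background) and a table of areas.
.label <- function(fg, min_area) {
  lab <- EBImage::bwlabel(fg * 1)
  lab <- matrix(as.integer(lab), nrow(fg), ncol(fg))
  if (max(lab) == 0L) return(list(labels = lab, areas = integer(0)))
  areas <- tabulate(lab[lab > 0L])
  keep <- which(areas >= min_area)
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  list(labels = lab, areas = areas[keep])
}

#' Measure the contact diameter of a spread drop
#'
#' Equivalent-area circle diameter of the largest foreground component,
#' converted to mm via the image scale. If several objects are present
#' the largest is reported with a warning.
#'
#' @param img an [image_field()].
#' @param cfg a [segmentation_config()].
#' @return diameter, mm.
#' @export
measure_drop_diameter <- function(img, cfg = segmentation_config()) {
  lab <- .label(.binarize(img, cfg), cfg$min_object_area)
  if (!length(lab$areas)) stop("no object found in image")
  if (length(lab$areas) > 1L)
    warning(length(lab$areas), " objects found; reporting the largest")
  d_px <- 2 * sqrt(max(lab$areas) / pi)
  d_px * img$um_per_px / 1000
}

#' Measure fiber diameters at random centerline points
#'
#' Segments the fibers (one connected component each), then samples
#' `n_points` rows per fiber away from the fiber ends and takes the
#' local width as twice the Euclidean distance from the centerline (the
#' row's distance-transform maximum) to the background. Sampling is
#' seeded and reproducible.
#'
#' @param img an [image_field()] of near-vertical fibers.
#' @param n_points measurement points per fiber (protocol default 10).
#' @param seed integer seed for the sampled point set.
#' @param cfg a [segmentation_config()].
#' @return a [fiber_measurement()] with diameters in mm.
#' @export
measure_fiber_profile <- function(img, n_points = 10L, seed = 1L,
                                  cfg = segmentation_config()) {
  if (n_points < 1L) stop("n_points must be >= 1")
  fg <- .binarize(img, cfg)
  lab <- .label(fg, cfg$min_object_area)
  nf <- length(lab$areas)
  if (!nf) stop("no fibers found")
  dm <- matrix(as.numeric(EBImage::distmap(fg * 1)), nrow(fg), ncol(fg))
  # order fibers left to right by centroid x
  cx <- vapply(seq_len(nf), function(k) {
    mean(which(lab$labels == k, arr.ind = TRUE)[, 2])
  }, numeric(1))
  widths <- withr::with_seed(seed, {
    lapply(order(cx), function(k) {
      pix <- which(lab$labels == k, arr.ind = TRUE)
      rows <- range(pix[, 1])
      guard <- ceiling(2 * max(dm[lab$labels == k]))
      lo <- rows[1] + guard; hi <- rows[2] - guard
      if (lo > hi) { lo <- rows[1]; hi <- rows[2] }
      rs <- sample(seq(lo, hi), n_points, replace = (hi - lo + 1) < n_points)
      vapply(rs, function(r) {
        sel <- pix[, 1] == r
        if (!any(sel)) return(NA_real_)
        2 * max(dm[cbind(r, pix[sel, 2])])
      }, numeric(1))
    })
  })
  w_px <- unlist(widths)
  w_px <- w_px[!is.na(w_px)]
  if (max(w_px) < 3) stop("fiber thinner than 3 px: below resolution floor")
  fiber_measurement(w_px * img$um_per_px / 1000,
                    n_fibers = nf, points_per_fiber = n_points)
}

# Cluster sorted 1-d positions into groups separated by gaps > gap_min.
.cluster_1d <- function(x, gap_min) {
  o <- order(x)
  xs <- x[o]
  grp <- cumsum(c(1, diff(xs) > gap_min))
  split(o, grp)
}

#' Measure printed grid side lengths
#'
#' Detects the grid pores as background components fully enclosed by
#' foreground, groups them into pore rows and columns, and measures the
#' printed side length at each pore row (the foreground x-extent along a
#' scanline through the row's center) and each pore column (y-extent).
#'
#' @param img an [image_field()] of a printed grid.
#' @param cfg a [segmentation_config()].
#' @param cad_side_x,cad_side_y CAD side lengths to attach to the result,
#'   mm; default the measured means (so the fidelity scores are 1 unless
#'   real CAD values are supplied).
#' @return a [grid_measurement()] with sides in mm.
#' @export
measure_grid <- function(img, cfg = segmentation_config(),
                         cad_side_x = NULL, cad_side_y = NULL) {
  fg <- .binarize(img, cfg)
  # pores: background components not touching the border
  bg_lab <- EBImage::bwlabel((!fg) * 1)
  bg_lab <- matrix(as.integer(bg_lab), nrow(fg), ncol(fg))
  border <- unique(c(bg_lab[1, ], bg_lab[nrow(fg), ],
                     bg_lab[, 1], bg_lab[, ncol(fg)]))
  pores <- setdiff(unique(bg_lab[bg_lab > 0L]), border)
  if (!length(pores)) stop("no enclosed pores detected")
  cent <- t(vapply(pores, function(k) {
    pix <- which(bg_lab == k, arr.ind = TRUE)
    c(mean(pix[, 1]), mean(pix[, 2]), nrow(pix))
  }, numeric(3)))
  pore_size <- sqrt(stats::median(cent[, 3]))
  rows <- .cluster_1d(cent[, 1], pore_size / 2)
  cols <- .cluster_1d(cent[, 2], pore_size / 2)
  scale_mm <- img$um_per_px / 1000
  sides_x <- vapply(rows, function(idx) {
    y <- round(stats::median(cent[idx, 1]))
    run <- which(fg[y, ])
    (max(run) - min(run) + 1)
  }, numeric(1)) * scale_mm
  sides_y <- vapply(cols, function(idx) {
    x <- round(stats::median(cent[idx, 2]))
    run <- which(fg[, x])
    (max(run) - min(run) + 1)
  }, numeric(1)) * scale_mm
  if (is.null(cad_side_x)) cad_side_x <- mean(sides_x)
  if (is.null(cad_side_y)) cad_side_y <- mean(sides_y)
  grid_measurement(cad_side_x, cad_side_y, unname(sides_x), unname(sides_y))
}

#' Particle granulometry
#'
#' Equivalent-area diameters of all connected foreground components
#' after minimum-area filtering.
#'
#' @param img an [image_field()] of a particle field.
#' @param cfg a [segmentation_config()].
#' @return list with `diameters_um`, `mean_um`, `sd_um`, `n`; an empty
#'   field gives `n = 0` and `NA` summary values with the `empty` flag.
#' @export
measure_granulometry <- function(img, cfg = segmentation_config()) {
  lab <- .label(.binarize(img, cfg), cfg$min_object_area)
  if (!length(lab$areas)) {
    return(list(diameters_um = numeric(0), mean_um = NA_real_,
                sd_um = NA_real_, n = 0L, empty = TRUE))
  }
  d <- 2 * sqrt(lab$areas / pi) * img$um_per_px
  list(diameters_um = d, mean_um = mean(d),
       sd_um = if (length(d) > 1) stats::sd(d) else NA_real_,
       n = length(d), empty = FALSE)
}

#' Cell area fraction of one plane
#'
#' Converts the image to 8-bit, thresholds it so cells are white and
#' matrix black, measures the black (background) fraction and reports
#' one minus that value: the fraction of the plane occupied by cells.
#'
#' @param img an [image_field()] with a `plane_label`.
#' @param cfg a [segmentation_config()].
#' @return an object of class `plane_coverage` with `plane_label` and
#'   `cell_area_fraction`.
#' @export
cell_area_fraction <- function(img, cfg = segmentation_config()) {
  fg <- .binarize(img, cfg)
  black_fraction <- mean(!fg)
  structure(list(plane_label = img$plane_label,
                 cell_area_fraction = 1 - black_fraction),
            class = "plane_coverage")
}

#' @export
print.plane_coverage <- function(x, ...) {
  cat(sprintf("<plane_coverage: %s, %.2f%% cells>\n", x$plane_label,
              100 * x$cell_area_fraction))
  invisible(x)
}

#' Compare plane coverages before and after the gel point
#'
#' Per-plane absolute and relative changes, plus a homogeneity flag per
#' time point: a triplet is homogeneous when the spread across planes,
#' (max - min) / mean, is below `tol_rel`. A markedly higher bottom
#' plane is the sedimentation signature.
#'
#' @param before,after lists of three [cell_area_fraction()] results
#'   with matching plane labels.
#' @param tol_rel relative spread below which planes count as
#'   homogeneous (default 0.2).
#' @return list with `table` (data.frame: plane, before, after,
#'   abs_diff, rel_diff), `homogeneous_before`, `homogeneous_after`.
#' @export
compare_plane_coverage <- function(before, after, tol_rel = 0.2) {
  lab_b <- vapply(before, function(x) x$plane_label, character(1))
  lab_a <- vapply(after, function(x) x$plane_label, character(1))
  if (!identical(sort(lab_b), sort(lab_a)))
    stop("plane labels do not match between time points")
  fb <- vapply(before, function(x) x$cell_area_fraction, numeric(1))
  fa <- vapply(after, function(x) x$cell_area_fraction, numeric(1))[match(lab_b, lab_a)]
  spread_rel <- function(f) {
    m <- mean(f)
    if (m == 0) 0 else (max(f) - min(f)) / m
  }
  tab <- data.frame(plane = lab_b, before = fb, after = fa,
                    abs_diff = fa - fb,
                    rel_diff = ifelse(fb == 0, ifelse(fa == 0, 0, Inf),
                                      (fa - fb) / fb))
  list(table = tab,
       homogeneous_before = spread_rel(fb) < tol_rel,
       homogeneous_after = spread_rel(fa) < tol_rel)
}
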