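# Synthetic micrographs with known ground truth. Images are numeric
# matrices in [0, 1] (8-bit on disk), m[row = y, col = x], pixel centers
# at integer coordinates, origin top-left. Rendering is binary; an
# optional Gaussian blur can be layered on by callers before writing.

#' Grayscale image with a physical scale
#'
#' @param pixels numeric matrix in `[0, 1]`, rows = y, cols = x.
#' @param um_per_px physical scale, micrometers per pixel, > 0.
#' @param plane_label one of `"top"`, `"middle"`, `"bottom"`, `"none"`.
#' @return an object of class `image_field`.
#' @export
image_field <- function(pixels, um_per_px, plane_label = "none") {
  plane_label <- match.arg(plane_label, c("top", "middle", "bottom", "none"))
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (um_per_px <= 0) stop("um_per_px must be > 0")
  if (any(pixels < 0) || any(pixels > 1))
    stop("pixel values must lie in [0, 1]")
  structure(list(pixels = pixels, um_per_px = um_per_px,
                 plane_label = plane_label),
            class = "image_field")
}

#' @export
print.image_field <- function(x, ...) {
  cat(sprintf("<image_field: %d x %d px, %.3g um/px, plane %s>\n",
              nrow(x$pixels), ncol(x$pixels), x$um_per_px, x$plane_label))
  invisible(x)
}

# Render a filled disk (pixel-center criterion) into matrix m.
.draw_disk <- function(m, cy, cx, r_px) {
  ylo <- max(1L, floor(cy - r_px)); yhi <- min(nrow(m), ceiling(cy + r_px))
  xlo <- max(1L, floor(cx - r_px)); xhi <- min(ncol(m), ceiling(cx + r_px))
  if (ylo > yhi || xlo > xhi) return(m)
  ys <- ylo:yhi; xs <- xlo:xhi
  dy2 <- (ys - cy)^2
  dx2 <- (xs - cx)^2
  m[ys, xs] <- pmax(m[ys, xs], outer(dy2, dx2, "+") <= r_px^2)
  m
}

#' Ground truth of a synthetic print job
#'
#' @param needle_inner_diameter,needle_length needle geometry, mm.
#' @param cad_side_x,cad_side_y CAD square side lengths, mm.
#' @param true_fiber_diameter rendered fiber diameter, mm.
#' @param fiber_waviness_amp sinusoidal centerline amplitude, mm; must be
#'   smaller than the fiber diameter.
#' @param side_jitter_sd Gaussian sd of the printed-side jitter, mm.
#' @param pores_per_side number of pores along each grid axis.
#' @param seed integer seed.
#' @return a `print_job_truth` list.
#' @export
print_job_truth <- function(needle_inner_diameter = 0.41,
                            needle_length = 12.5,
                            cad_side_x = 20, cad_side_y = 20,
                            true_fiber_diameter = 0.41,
                            fiber_waviness_amp = 0,
                            side_jitter_sd = 0,
                            pores_per_side = 5L,
                            seed = 1L) {
  lens <- c(needle_inner_diameter, needle_length, cad_side_x, cad_side_y,
            true_fiber_diameter)
  if (any(lens <= 0)) stop("all lengths must be > 0")
  if (fiber_waviness_amp < 0 || side_jitter_sd < 0)
    stop("waviness and jitter must be >= 0")
  if (fiber_waviness_amp >= true_fiber_diameter)
    stop("waviness amplitude must be smaller than the fiber diameter")
  if (pores_per_side < 1L) stop("need at least one pore per side")
  structure(list(needle_inner_diameter = needle_inner_diameter,
                 needle_length = needle_length,
                 cad_side_x = cad_side_x, cad_side_y = cad_side_y,
                 true_fiber_diameter = true_fiber_diameter,
                 fiber_waviness_amp = fiber_waviness_amp,
                 side_jitter_sd = side_jitter_sd,
                 pores_per_side = as.integer(pores_per_side),
                 seed = as.integer(seed)),
            class = "print_job_truth")
}

#' Simulate fiber and grid micrographs of a print
#'
#' Renders (1) five vertical fibers whose centerlines follow a sinusoid
#' of amplitude `fiber_waviness_amp` (period 2 mm, random phase per
#' fiber) and (2) one square grid whose per-cell side extents are
#' jittered by `side_jitter_sd`. The grid outline is drawn so that its
#' outer extent equals the CAD side; strokes have the fiber diameter.
#' The returned truth records the exact pre-rasterization side lengths,
#' so image measurements can be validated to pixel resolution.
#'
#' @param truth a [print_job_truth()].
#' @param um_per_px rendering scale; the fiber must be at least 3 px
#'   wide (error) and should be at least 10 px (warning below that).
#' @param fiber_length_mm rendered fiber segment length.
#' @return list with elements `fiber` and `grid` ([image_field()]s);
#'   each carries a `truth` attribute (the grid truth adds `sides_x`,
#'   `sides_y` in mm).
#' @export
simulate_print_images <- function(truth, um_per_px = 25,
                                  fiber_length_mm = 6) {
  stopifnot(inherits(truth, "print_job_truth"))
  px_mm <- 1000 / um_per_px              # pixels per mm
  w_px <- truth$true_fiber_diameter * px_mm
  if (w_px < 3) stop("fiber thinner than 3 px at this scale")
  if (w_px < 10) warning("fiber thinner than 10 px; width recovery degrades")

  withr::with_seed(truth$seed, {
    ## ---- fibers -------------------------------------------------------
    n_fib <- 5L
    H <- round(fiber_length_mm * px_mm)
    spacing <- ceiling(w_px + 2 * truth$fiber_waviness_amp * px_mm + 3 * w_px)
    W <- as.integer(n_fib * spacing + spacing)
    fib <- matrix(0, H, W)
    phases <- stats::runif(n_fib, 0, 2 * pi)
    period_px <- 2 * px_mm
    amp_px <- truth$fiber_waviness_amp * px_mm
    ys <- seq_len(H)
    for (k in seq_len(n_fib)) {
      cx0 <- spacing * k
      cx <- cx0 + amp_px * sin(2 * pi * ys / period_px + phases[k])
      for (y in ys) {
        # half-open [cx - w/2, cx + w/2): run length is w_px +- 1 at most
        xlo <- ceiling(cx[y] - w_px / 2)
        xhi <- ceiling(cx[y] + w_px / 2) - 1L
        if (xhi >= xlo) fib[y, max(1L, xlo):min(W, xhi)] <- 1
      }
    }
    fiber_img <- image_field(fib, um_per_px)
    attr(fiber_img, "truth") <- truth

    ## ---- grid ---------------------------------------------------------
    m <- truth$pores_per_side
    Lx <- truth$cad_side_x * px_mm
    Ly <- truth$cad_side_y * px_mm
    margin <- ceiling(w_px * 2 + 4 * truth$side_jitter_sd * px_mm) + 8L
    GW <- as.integer(ceiling(Lx) + 2L * margin)
    GH <- as.integer(ceiling(Ly) + 2L * margin)
    grd <- matrix(0, GH, GW)
    jit_px <- truth$side_jitter_sd * px_mm
    pitch_x <- Lx / m
    pitch_y <- Ly / m
    # outer edge stroke centers: w/2 in from the CAD outline, jittered
    # per pore row (left/right edges) and per pore column (top/bottom)
    lx <- margin + w_px / 2 + stats::rnorm(m, 0, jit_px)
    rx <- margin + Lx - w_px / 2 + stats::rnorm(m, 0, jit_px)
    ty <- margin + w_px / 2 + stats::rnorm(m, 0, jit_px)
    by <- margin + Ly - w_px / 2 + stats::rnorm(m, 0, jit_px)
    hw <- w_px / 2
    band_y <- function(i) {                 # y range of pore row i
      c(margin + (i - 1) * pitch_y, margin + i * pitch_y)
    }
    band_x <- function(j) {
      c(margin + (j - 1) * pitch_x, margin + j * pitch_x)
    }
    fill <- function(m, y0, y1, x0, x1) {
      ys <- max(1L, ceiling(y0)):min(GH, floor(y1))
      xs <- max(1L, ceiling(x0)):min(GW, floor(x1))
      m[ys, xs] <- 1
      m
    }
    # left/right edges per pore row
    for (i in seq_len(m)) {
      byr <- band_y(i)
      grd <- fill(grd, byr[1], byr[2], lx[i] - hw, lx[i] + hw)
      grd <- fill(grd, byr[1], byr[2], rx[i] - hw, rx[i] + hw)
    }
    # top/bottom edges per pore column
    for (j in seq_len(m)) {
      bxr <- band_x(j)
      grd <- fill(grd, ty[j] - hw, ty[j] + hw, bxr[1], bxr[2])
      grd <- fill(grd, by[j] - hw, by[j] + hw, bxr[1], bxr[2])
    }
    # internal grid lines, spanning the full outline
    xspan <- c(min(lx) - hw, max(rx) + hw)
    yspan <- c(min(ty) - hw, max(by) + hw)
    if (m > 1L) {
      for (k in seq_len(m - 1L)) {
        xc <- margin + k * pitch_x
        grd <- fill(grd, yspan[1], yspan[2], xc - hw, xc + hw)
        yc <- margin + k * pitch_y
        grd <- fill(grd, yc - hw, yc + hw, xspan[1], xspan[2])
      }
    }
    grid_img <- image_field(grd, um_per_px)
    gt <- truth
    gt$sides_x <- (rx - lx + w_px) / px_mm   # exact pre-raster side lengths
    gt$sides_y <- (by - ty + w_px) / px_mm
    attr(grid_img, "truth") <- gt
  })
  list(fiber = fiber_img, grid = grid_img)
}

#' Simulate frames of a spreading drop
#'
#' Circular footprint growing monotonically (saturating exponential)
#' from the equal-volume sphere diameter toward `deq_mm`; the final
#' frame's diameter is exactly `deq_mm`.
#'
#' @param volume_ul drop volume, microliters.
#' @param deq_mm equilibrium contact diameter, mm; must be at least the
#'   equal-volume sphere diameter (the no-spreading footprint).
#' @param n_frames number of frames (1 = equilibrium frame only).
#' @param seed integer seed (reserved for optional appearance noise).
#' @param um_per_px rendering scale.
#' @return list of [image_field()]s with attribute `truth` (the frame
#'   diameters in mm).
#' @export
simulate_drop_frames <- function(volume_ul, deq_mm, n_frames = 8L,
                                 seed = 1L, um_per_px = 25) {
  if (volume_ul <= 0) stop("volume must be > 0")
  d0 <- ideal_drop_diameter(volume_ul)
  if (deq_mm < d0 * (1 - 1e-12))
    stop("D_eq below the no-spreading (equal-volume sphere) diameter")
  if (n_frames < 1L) stop("need at least one frame")
  px_mm <- 1000 / um_per_px
  if (n_frames == 1L) {
    diams <- deq_mm
  } else {
    k <- seq_len(n_frames)
    diams <- deq_mm - (deq_mm - d0) * exp(-3 * (k - 1) / (n_frames - 1))
    diams[n_frames] <- deq_mm
  }
  side <- as.integer(ceiling(deq_mm * px_mm) + 16L)
  c0 <- (side + 1) / 2
  frames <- lapply(diams, function(d) {
    m <- .draw_disk(matrix(0, side, side), c0, c0, d * px_mm / 2)
    image_field(m, um_per_px)
  })
  attr(frames, "truth") <- list(volume_ul = volume_ul, deq_mm = deq_mm,
                                diameters_mm = diams)
  frames
}

#' Simulate a powder-particle field
#'
#' Non-overlapping disks with the requested equivalent diameters,
#' placed by seeded rejection sampling.
#'
#' @param diameters_um particle equivalent diameters, micrometers (may
#'   be empty: an empty field is returned).
#' @param um_per_px rendering scale.
#' @param seed integer seed.
#' @param min_gap_px minimum background gap between particles.
#' @return an [image_field()] with attribute `truth` (the diameters).
#' @export
simulate_particle_field <- function(diameters_um, um_per_px = 2,
                                    seed = 1L, min_gap_px = 3) {
  diameters_um <- as.numeric(diameters_um)
  if (any(diameters_um <= 0)) stop("diameters must be > 0")
  radii_px <- diameters_um / 2 / um_per_px
  if (length(radii_px) && any(radii_px * 2 < 3))
    stop("particles must be at least 3 px in diameter at this scale")
  side <- max(64L, as.integer(ceiling(4 * sqrt(sum(pi * radii_px^2) + 1))))
  m <- matrix(0, side, side)
  if (!length(diameters_um)) {
    out <- image_field(m, um_per_px)
    attr(out, "truth") <- list(diameters_um = numeric(0))
    return(out)
  }
  withr::with_seed(seed, {
    centers <- matrix(NA_real_, length(radii_px), 2)
    for (i in order(radii_px, decreasing = TRUE)) {
      r <- radii_px[i]
      placed <- FALSE
      for (try in seq_len(2000L)) {
        cy <- stats::runif(1, r + 2, side - r - 1)
        cx <- stats::runif(1, r + 2, side - r - 1)
        ok <- TRUE
        for (j in seq_len(nrow(centers))) {
          if (is.na(centers[j, 1])) next
          if (sqrt((cy - centers[j, 1])^2 + (cx - centers[j, 2])^2) <
              r + radii_px[j] + min_gap_px) { ok <- FALSE; break }
        }
        if (ok) { centers[i, ] <- c(cy, cx); placed <- TRUE; break }
      }
      if (!placed) stop("could not place particles without overlap; ",
                        "requested density too high")
      m <- .draw_disk(m, centers[i, 1], centers[i, 2], r)
    }
  })
  out <- image_field(m, um_per_px)
  attr(out, "truth") <- list(diameters_um = diameters_um)
  out
}

#' Simulate nuclei images for three focal planes
#'
#' Places non-overlapping circular spots on each plane until the
#' foreground area fraction reaches the requested value (the rendered
#' fraction is within half a spot area, well inside 0.5 percentage
#' points for the default spot size). The exact rendered fraction per
#' plane is returned as truth.
#'
#' @param area_fraction_per_plane three values in `[0, 0.3)`, for the
#'   top, middle and bottom planes.
#' @param spot_radius_px spot radius, px.
#' @param seed integer seed.
#' @param side image side, px.
#' @return named list of three [image_field()]s (`top`, `middle`,
#'   `bottom`) with attribute `truth` (requested and rendered fractions).
#' @export
simulate_nuclei_planes <- function(area_fraction_per_plane,
                                   spot_radius_px = 4, seed = 1L,
                                   side = 256L) {
  f <- as.numeric(area_fraction_per_plane)
  if (length(f) != 3L) stop("need three plane fractions")
  if (any(f < 0) || any(f >= 0.3))
    stop("fractions must be in [0, 0.3) to avoid overlap saturation")
  labels <- c("top", "middle", "bottom")
  planes <- vector("list", 3L)
  rendered <- numeric(3L)
  withr::with_seed(seed, {
    for (p in 1:3) {
      m <- matrix(0, side, side)
      r <- spot_radius_px
      total <- side^2
      if (f[p] > 0) {
        centers <- NULL
        misses <- 0L
        while (sum(m) / total < f[p] && misses < 5000L) {
          cy <- stats::runif(1, r + 1, side - r)
          cx <- stats::runif(1, r + 1, side - r)
          ok <- is.null(centers) ||
            all(sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2) > 2 * r + 1)
          if (ok) {
            m <- .draw_disk(m, cy, cx, r)
            centers <- rbind(centers, c(cy, cx))
          } else misses <- misses + 1L
        }
        if (sum(m) / total < f[p])
          stop("could not reach requested area fraction without overlap")
      }
      rendered[p] <- sum(m) / total
      planes[[p]] <- image_field(m, 1, plane_label = labels[p])
    }
  })
  names(planes) <- labels
  attr(planes, "truth") <- list(requested = f, rendered = rendered)
  planes
}

#' Write an image and its scale sidecar
#'
#' 8-bit grayscale TIFF plus a JSON sidecar
#' `{"um_per_px": <float>, "plane_label": "<label>"}` at `<path>.json`.
#'
#' @param img an [image_field()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_tiff <- function(img, path) {
  stopifnot(inherits(img, "image_field"))
  q <- round(img$pixels * 255) / 255
  tiff::writeTIFF(q, path, bits.per.sample = 8L)
  jsonlite::write_json(list(um_per_px = img$um_per_px,
                            plane_label = img$plane_label),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an image written by [write_image_tiff()]
#'
#' @param path TIFF path; the scale sidecar is read from `<path>.json`.
#' @return an [image_field()].
#' @export
read_image_tiff <- function(path) {
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1]
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing scale sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar)
  image_field(px, meta$um_per_px,
              plane_label = if (is.null(meta$plane_label)) "none"
                            else meta$plane_label)
}
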