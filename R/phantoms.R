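#' Skull slice container
#'
#' A 2D raster of Hounsfield units (HU) with pixel spacing and a bone mask.
#' Rows run top to bottom; the transducer side is row 1. The bone mask is
#' derived from the HU grid by thresholding, so it is always consistent
#' with the raster.
#'
#' @param hu_grid Numeric matrix of Hounsfield units.
#' @param pixel_spacing_mm Pixel spacing in mm (scalar > 0).
#' @param bone_threshold_hu HU threshold above which a pixel is bone.
#' @param provenance_seed Integer seed that generated the slice (or `NA`).
#' @return An object of class `skull_slice` with fields `hu_grid`,
#'   `pixel_spacing_mm`, `skull_mask`, `bone_threshold_hu`,
#'   `provenance_seed`.
#' @export
skull_slice <- function(hu_grid, pixel_spacing_mm, bone_threshold_hu = 150,
                        provenance_seed = NA_integer_) {
  if (!is.matrix(hu_grid) || !is.numeric(hu_grid))
    stop("`hu_grid` must be a numeric matrix", call. = FALSE)
  if (any(!is.finite(hu_grid)))
    stop("`hu_grid` contains non-finite values", call. = FALSE)
  stopifnot_scalar(pixel_spacing_mm, "pixel_spacing_mm", positive = TRUE)
  structure(list(
    hu_grid = hu_grid,
    pixel_spacing_mm = pixel_spacing_mm,
    skull_mask = (hu_grid > bone_threshold_hu) * 1L,
    bone_threshold_hu = bone_threshold_hu,
    provenance_seed = provenance_seed
  ), class = "skull_slice")
}

#' @export
print.skull_slice <- function(x, ...) {
  cat(sprintf("<skull_slice> %dx%d @ %.4g mm/px, bone fraction %.3f, seed %s\n",
              nrow(x$hu_grid), ncol(x$hu_grid), x$pixel_spacing_mm,
              mean(x$skull_mask), as.character(x$provenance_seed)))
  invisible(x)
}

#' Phantom generator specification
#'
#' Parameter ranges for the procedural curved-plate skull phantom: an arc
#' of bone with outer and inner cortical tables at high HU and a noisy
#' trabecular core, emulating parietal/temporal calvarial segments. Each
#' range is sampled uniformly per phantom.
#'
#' @param grid_size_native Native raster size in pixels (square).
#' @param pixel_spacing_mm Native pixel spacing, mm/pixel.
#' @param curvature_radius_mm Range of outer-table curvature radii, mm.
#' @param total_thickness_mm Range of total plate thickness, mm.
#' @param cortical_fraction Range in (0,1): fraction of the thickness taken
#'   by the two cortical tables combined.
#' @param cortical_hu Range of cortical HU.
#' @param trabecular_hu Range of mean trabecular HU.
#' @param trabecular_noise_scale Gaussian HU noise sd in the trabecular
#'   core; the noise is spatially smoothed to emulate mm-scale diploic
#'   structure.
#' @param thickness_variation Range of the relative amplitude of the
#'   lateral thickness modulation along the plate (real calvaria vary in
#'   thickness by a few mm across an aperture).
#' @param thickness_lobes Integer range of modulation periods across the
#'   plate width.
#' @param apex_depth_mm Range of the outer-table apex depth below the top
#'   edge, mm.
#' @param plate_halfwidth_mm Lateral half-extent of the bone plate from
#'   the grid center line, mm (`Inf` spans the window).
#' @param bone_threshold_hu HU threshold defining the skull mask.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_size_native = 128L,
                         pixel_spacing_mm = 0.625,
                         curvature_radius_mm = c(60, 120),
                         total_thickness_mm = c(4, 9),
                         cortical_fraction = c(0.25, 0.45),
                         cortical_hu = c(1200, 1900),
                         trabecular_hu = c(400, 900),
                         trabecular_noise_scale = 150,
                         thickness_variation = c(0.1, 0.3),
                         thickness_lobes = c(1L, 3L),
                         apex_depth_mm = c(4.5, 7.5),
                         plate_halfwidth_mm = Inf,
                         bone_threshold_hu = 150) {
  spec <- list(grid_size_native = as.integer(grid_size_native),
               pixel_spacing_mm = pixel_spacing_mm,
               curvature_radius_mm = sort(curvature_radius_mm),
               total_thickness_mm = sort(total_thickness_mm),
               cortical_fraction = sort(cortical_fraction),
               cortical_hu = sort(cortical_hu),
               trabecular_hu = sort(trabecular_hu),
               trabecular_noise_scale = trabecular_noise_scale,
               thickness_variation = sort(thickness_variation),
               thickness_lobes = sort(as.integer(thickness_lobes)),
               apex_depth_mm = sort(apex_depth_mm),
               plate_halfwidth_mm = plate_halfwidth_mm,
               bone_threshold_hu = bone_threshold_hu)
  if (spec$grid_size_native < 8L) stop("grid too small", call. = FALSE)
  stopifnot_scalar(spec$pixel_spacing_mm, "pixel_spacing_mm", positive = TRUE)
  if (min(spec$total_thickness_mm) <= 0)
    stop("thickness range must be positive", call. = FALSE)
  if (min(spec$cortical_fraction) <= 0 || max(spec$cortical_fraction) >= 1)
    stop("cortical_fraction must lie in (0, 1)", call. = FALSE)
  if (min(spec$cortical_hu) < min(spec$trabecular_hu))
    stop("cortical HU must not fall below the trabecular lower bound",
         call. = FALSE)
  if (spec$trabecular_noise_scale < 0)
    stop("trabecular_noise_scale must be >= 0", call. = FALSE)
  if (min(spec$thickness_variation) < 0 || max(spec$thickness_variation) >= 1)
    stop("thickness_variation must lie in [0, 1)", call. = FALSE)
  grid_mm <- spec$grid_size_native * spec$pixel_spacing_mm
  if (max(spec$total_thickness_mm) * (1 + max(spec$thickness_variation)) +
      max(spec$apex_depth_mm) >= grid_mm)
    stop("plate thickness exceeds the grid extent", call. = FALSE)
  class(spec) <- "phantom_spec"
  spec
}

#' Reduced-scale phantom family used by the test and benchmark suites
#'
#' A phantom specification matched to the 128 x 128 / 6 cm simulation
#' window: a finite temporal/parietal-like plate (44 mm wide) of
#' adult-typical 5-7 mm thickness with 15-30% lateral thickness
#' modulation and spatially correlated diploic heterogeneity, sitting
#' 2.5-3.5 mm below the array so that focal targets at about 15 mm
#' depth clear the inner table.
#'
#' @param ... Overrides forwarded to [phantom_spec()].
#' @export
reduced_phantom_spec <- function(...) {
  args <- utils::modifyList(list(
    grid_size_native = 128L,
    pixel_spacing_mm = 60 / 128,
    curvature_radius_mm = c(100, 160),
    total_thickness_mm = c(5, 7),
    trabecular_hu = c(450, 900),
    trabecular_noise_scale = 250,
    thickness_variation = c(0.15, 0.3),
    thickness_lobes = c(2L, 5L),
    apex_depth_mm = c(2.5, 3.5),
    plate_halfwidth_mm = 22
  ), list(...))
  do.call(phantom_spec, args)
}

# 3x3 box blur with edge replication (for correlated trabecular noise)
box_blur3 <- function(m) {
  n_r <- nrow(m); n_c <- ncol(m)
  ri <- cbind(c(1L, seq_len(n_r - 1L)), seq_len(n_r),
              c(seq_len(n_r - 1L) + 1L, n_r))
  acc <- m[ri[, 1L], ] + m[ri[, 2L], ] + m[ri[, 3L], ]
  ci <- cbind(c(1L, seq_len(n_c - 1L)), seq_len(n_c),
              c(seq_len(n_c - 1L) + 1L, n_c))
  (acc[, ci[, 1L]] + acc[, ci[, 2L]] + acc[, ci[, 3L]]) / 9
}

#' Generate a procedural skull phantom
#'
#' Draws one curved two-table plate with a noisy trabecular interior from
#' the ranges in `spec`. Deterministic for a fixed seed. Background
#' (non-bone) HU is 0.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed.
#' @return A [skull_slice()].
#' @export
generate_skull_phantom <- function(spec = phantom_spec(), seed = 1L) {
  if (!inherits(spec, "phantom_spec")) stop("`spec` must be a phantom_spec")
  n <- spec$grid_size_native
  sp <- spec$pixel_spacing_mm
  with_seed(seed, {
    R  <- draw_range(spec$curvature_radius_mm)
    th <- draw_range(spec$total_thickness_mm)
    cf <- draw_range(spec$cortical_fraction)
    hu_c <- draw_range(spec$cortical_hu)
    hu_t <- draw_range(spec$trabecular_hu)
    apex <- draw_range(spec$apex_depth_mm)
    tvar <- draw_range(spec$thickness_variation)
    lobes <- if (spec$thickness_lobes[1L] == spec$thickness_lobes[2L])
      spec$thickness_lobes[1L]
    else sample(spec$thickness_lobes[1L]:spec$thickness_lobes[2L], 1L)
    tphase <- stats::runif(1L, 0, 2 * pi)

    # mm coordinates of pixel centers; row 1 is the top (transducer) side
    y <- (seq_len(n) - 0.5) * sp
    x <- (seq_len(n) - 0.5) * sp
    xc <- n * sp / 2
    yc <- apex + R                       # circle center, below the grid
    d <- sqrt(outer(y - yc, x - xc, function(a, b) a^2 + b^2))
    upper <- outer(y, x, function(a, b) a < yc)
    # lateral thickness modulation: inner surface moves, outer arc fixed
    th_col <- th * (1 + tvar * sin(2 * pi * lobes * x / (n * sp) + tphase))
    th_m <- matrix(th_col, n, n, byrow = TRUE)
    in_band <- d <= R & d > (R - th_m) & upper
    if (is.finite(spec$plate_halfwidth_mm)) {
      lat <- matrix(abs(x - xc), n, n, byrow = TRUE)
      in_band <- in_band & lat <= spec$plate_halfwidth_mm
    }

    t_cort <- cf * th_m / 2             # each cortical table
    outer_cort <- in_band & d > (R - t_cort)
    inner_cort <- in_band & d <= (R - th_m + t_cort)
    trab <- in_band & !outer_cort & !inner_cort

    hu <- matrix(0, n, n)
    hu[outer_cort | inner_cort] <- hu_c
    if (any(trab)) {
      # spatially correlated diploic noise: smoothed white field
      noise <- matrix(stats::rnorm(n * n), n, n)
      noise <- box_blur3(box_blur3(noise))
      noise <- noise / stats::sd(noise) * spec$trabecular_noise_scale
      hu[trab] <- hu_t + noise[trab]
    }
    skull_slice(hu, sp, bone_threshold_hu = spec$bone_threshold_hu,
                provenance_seed = as.integer(seed))
  })
}

#' Nearest-neighbor upsampling of a skull slice
#'
#' Each source pixel becomes a `factor` x `factor` block; the pixel spacing
#' is divided by `factor`.
#'
#' @param slice A [skull_slice()].
#' @param factor Positive integer upsampling factor.
#' @return A [skull_slice()] with `factor`-times larger rasters.
#' @export
upsample_nearest <- function(slice, factor) {
  if (!inherits(slice, "skull_slice")) stop("`slice` must be a skull_slice")
  if (length(factor) != 1L || !is.finite(factor) || factor < 1 ||
      factor != round(factor))
    stop("`factor` must be a positive integer", call. = FALSE)
  factor <- as.integer(factor)
  if (factor == 1L) return(slice)
  idx_r <- rep(seq_len(nrow(slice$hu_grid)), each = factor)
  idx_c <- rep(seq_len(ncol(slice$hu_grid)), each = factor)
  skull_slice(slice$hu_grid[idx_r, idx_c, drop = FALSE],
              slice$pixel_spacing_mm / factor,
              bone_threshold_hu = slice$bone_threshold_hu,
              provenance_seed = slice$provenance_seed)
}

#' Greedy diversity filter over a phantom corpus
#'
#' Retains a slice only if its mean squared HU error to every
#' already-retained slice exceeds `mse_threshold`. The pass is greedy in
#' input order, so the output is an order-stable subset of the input.
#'
#' @param slices List of [skull_slice()] objects of identical shape.
#' @param mse_threshold Minimum pairwise MSE (HU^2) for retention.
#' @return The retained sublist.
#' @export
diversity_filter <- function(slices, mse_threshold) {
  if (length(slices) == 0L) return(slices)
  shp <- dim(slices[[1L]]$hu_grid)
  for (s in slices)
    if (!identical(dim(s$hu_grid), shp))
      stop("all slices must share one shape", call. = FALSE)
  kept <- list()
  for (s in slices) {
    ok <- TRUE
    for (k in kept) {
      if (mean((s$hu_grid - k$hu_grid)^2) <= mse_threshold) { ok <- FALSE; break }
    }
    if (ok) kept[[length(kept) + 1L]] <- s
  }
  kept
}

#' Rigid perturbation of a skull slice
#'
#' Applies a rotation about the grid center followed by a translation,
#' resampling with nearest neighbors. Pixels mapped from outside the
#' source grid become background (HU 0); content can therefore be clipped
#' at the borders. The mask is re-derived from the transformed HU raster,
#' which is identical to transforming the mask itself under
#' nearest-neighbor resampling.
#'
#' @param slice A [skull_slice()].
#' @param rotation_deg Rotation in degrees, |rotation| <= 45. Positive
#'   rotates the content counterclockwise in (x right, y down) display.
#' @param shift_mm Length-2 numeric `(dx, dy)` in mm: column and row
#'   translation of the content.
#' @return A transformed [skull_slice()].
#' @export
perturb_slice <- function(slice, rotation_deg = 0, shift_mm = c(0, 0)) {
  if (!inherits(slice, "skull_slice")) stop("`slice` must be a skull_slice")
  if (abs(rotation_deg) > 45)
    stop("|rotation_deg| must be <= 45", call. = FALSE)
  sp <- slice$pixel_spacing_mm
  n_r <- nrow(slice$hu_grid); n_c <- ncol(slice$hu_grid)
  th <- rotation_deg * pi / 180
  shift_px <- shift_mm / sp                     # (dcol, drow)
  cr <- (n_r + 1) / 2; cc <- (n_c + 1) / 2
  # inverse map: output pixel -> source pixel
  rows <- matrix(seq_len(n_r), n_r, n_c)
  cols <- matrix(seq_len(n_c), n_r, n_c, byrow = TRUE)
  yr <- rows - cr - shift_px[2L]
  xc <- cols - cc - shift_px[1L]
  src_r <- round(cr + (-sin(th)) * xc + cos(th) * yr)
  src_c <- round(cc + cos(th) * xc + sin(th) * yr)
  ok <- src_r >= 1 & src_r <= n_r & src_c >= 1 & src_c <= n_c
  hu <- matrix(0, n_r, n_c)
  hu[ok] <- slice$hu_grid[cbind(src_r[ok], src_c[ok])]
  skull_slice(hu, sp, bone_threshold_hu = slice$bone_threshold_hu,
              provenance_seed = slice$provenance_seed)
}

#' Regular lattice of focal targets
#'
#' Builds an `n_rows` x `n_cols` lattice of (row, col) target pixels
#' anchored at `anchor_rc`, spaced `pitch_mm` apart. The default layout
#' contains 56 points.
#'
#' @param layout Integer pair `(n_rows, n_cols)`.
#' @param pitch_mm Lattice pitch in mm.
#' @param anchor_rc Top-left lattice point, 1-based (row, col).
#' @param pixel_spacing_mm Pixel spacing of the host grid, mm.
#' @param grid_dim Integer pair: host grid dimensions (rows, cols).
#' @param min_row Optional: all points must lie strictly below this row
#'   (e.g. the deepest skull row).
#' @return Object of class `target_grid` with `points` (matrix, one row
#'   per target), `pitch_mm`, `layout`.
#' @export
make_target_grid <- function(layout = c(7L, 8L), pitch_mm = 3.74,
                             anchor_rc, pixel_spacing_mm, grid_dim,
                             min_row = NULL) {
  layout <- as.integer(layout)
  stopifnot_scalar(pitch_mm, "pitch_mm", positive = TRUE)
  pitch_px <- pitch_mm / pixel_spacing_mm
  pts <- expand.grid(i = seq_len(layout[1L]) - 1L,
                     j = seq_len(layout[2L]) - 1L)
  rows <- round(anchor_rc[1L] + pts$i * pitch_px)
  cols <- round(anchor_rc[2L] + pts$j * pitch_px)
  if (any(rows < 1 | rows > grid_dim[1L] | cols < 1 | cols > grid_dim[2L]))
    stop("target lattice exceeds the grid bounds", call. = FALSE)
  if (!is.null(min_row) && any(rows <= min_row))
    stop("target lattice must lie strictly below the skull", call. = FALSE)
  structure(list(points = cbind(row = rows, col = cols),
                 pitch_mm = pitch_mm, layout = layout),
            class = "target_grid")
}
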