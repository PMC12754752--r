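#' Transducer element pixel positions
#'
#' Computes the canvas pixels marking the array elements: a single row at
#' the standoff depth, columns centered on the grid and spaced at the
#' element pitch.
#'
#' @param array An [array_spec()].
#' @param grid_dim Integer pair (rows, cols) of the host grid.
#' @param pixel_spacing_mm Pixel spacing, mm.
#' @return Integer matrix with columns `row`, `col`, one row per element
#'   (left to right).
#' @export
element_positions <- function(array, grid_dim, pixel_spacing_mm) {
  n <- array$n_elements
  row <- 1L + round(array$standoff_mm / pixel_spacing_mm)
  center <- (grid_dim[2L] + 1) / 2
  pitch_px <- array$pitch_mm / pixel_spacing_mm
  cols <- round(center + (seq_len(n) - (n + 1) / 2) * pitch_px)
  if (any(cols < 1 | cols > grid_dim[2L]))
    stop("array aperture does not fit inside the grid", call. = FALSE)
  cbind(row = rep.int(row, n), col = as.integer(cols))
}

# Xiaolin-Wu-style anti-aliased line between integer pixel endpoints.
# Per column (or row, when steep) the line deposits intensity (1 - f) and
# f on the two pixels straddling its exact position. Returns a data.frame
# of (row, col, intensity); zero-intensity entries are dropped.
wu_line <- function(r0, c0, r1, c1) {
  # work in (x, y) = (col, row)
  x0 <- c0; y0 <- r0; x1 <- c1; y1 <- r1
  steep <- abs(y1 - y0) > abs(x1 - x0)
  if (steep) { tmp <- x0; x0 <- y0; y0 <- tmp; tmp <- x1; x1 <- y1; y1 <- tmp }
  if (x0 > x1) { tmp <- x0; x0 <- x1; x1 <- tmp; tmp <- y0; y0 <- y1; y1 <- tmp }
  if (x1 == x0) {
    xs <- x0; ys <- y0; w <- 1
  } else {
    grad <- (y1 - y0) / (x1 - x0)
    xs <- x0:x1
    y <- y0 + grad * (xs - x0)
    fy <- floor(y)
    f <- y - fy
    xs <- c(xs, xs); ys <- c(fy, fy + 1); w <- c(1 - f, f)
  }
  keep <- w > 0
  xs <- xs[keep]; ys <- ys[keep]; w <- w[keep]
  if (steep) data.frame(row = xs, col = ys, intensity = w)
  else       data.frame(row = ys, col = xs, intensity = w)
}

#' Build a normalized network input canvas
#'
#' The canvas is the skull HU raster clipped below at zero and divided by
#' `dataset_max_hu` (the corpus-wide maximum), with the element pixels and
#' target pixel overwritten to exactly 1, and optionally two anti-aliased
#' waveguide lines from the two outermost elements to the target marking
#' the unaberrated propagation cone.
#'
#' @param slice A [skull_slice()].
#' @param array An [array_spec()].
#' @param target_rc Target pixel, 1-based (row, col).
#' @param dataset_max_hu Corpus-wide maximum HU used for normalization.
#' @param waveguides_enabled Draw the waveguide lines?
#' @return Object of class `canvas` with `image` in [0,1], `target_rc`,
#'   `element_rcs`, `dataset_max_hu`, `waveguides_enabled`,
#'   `pixel_spacing_mm`.
#' @export
build_canvas <- function(slice, array, target_rc, dataset_max_hu,
                         waveguides_enabled = TRUE) {
  if (!inherits(slice, "skull_slice")) stop("`slice` must be a skull_slice")
  stopifnot_scalar(dataset_max_hu, "dataset_max_hu", positive = TRUE)
  hu <- slice$hu_grid
  if (dataset_max_hu < max(hu))
    stop("`dataset_max_hu` is smaller than the slice maximum (stale normalizer)",
         call. = FALSE)
  nr <- nrow(hu); nc <- ncol(hu)
  target_rc <- as.integer(target_rc)
  if (target_rc[1L] < 1 || target_rc[1L] > nr ||
      target_rc[2L] < 1 || target_rc[2L] > nc)
    stop("target outside the grid", call. = FALSE)
  skull_rows <- which(rowSums(slice$skull_mask) > 0)
  if (length(skull_rows) && target_rc[1L] <= max(skull_rows))
    stop("target must lie below the skull", call. = FALSE)

  img <- pmax(hu, 0) / dataset_max_hu
  el <- element_positions(array, c(nr, nc), slice$pixel_spacing_mm)
  cv <- structure(list(image = img, target_rc = target_rc,
                       element_rcs = el, dataset_max_hu = dataset_max_hu,
                       waveguides_enabled = waveguides_enabled,
                       pixel_spacing_mm = slice$pixel_spacing_mm),
                  class = "canvas")
  if (waveguides_enabled) cv <- rasterize_waveguides(cv)
  cv$image[el] <- 1
  cv$image[target_rc[1L], target_rc[2L]] <- 1
  cv
}

#' Draw the waveguide lines onto a canvas
#'
#' Rasterizes two anti-aliased lines from the two outermost element pixels
#' to the target pixel. Lines are composited with `pmax`, so the
#' operation is idempotent and never lowers existing canvas intensity.
#'
#' @param canvas A [build_canvas()] result (or partially built canvas with
#'   `element_rcs` and `target_rc` set).
#' @return The canvas with waveguides drawn.
#' @export
rasterize_waveguides <- function(canvas) {
  el <- canvas$element_rcs
  tg <- canvas$target_rc
  if (tg[1L] == el[1L, "row"])
    stop("target lies on the element row; waveguides are undefined",
         call. = FALSE)
  for (k in c(1L, nrow(el))) {
    seg <- wu_line(el[k, "row"], el[k, "col"], tg[1L], tg[2L])
    ok <- seg$row >= 1 & seg$row <= nrow(canvas$image) &
          seg$col >= 1 & seg$col <= ncol(canvas$image)
    seg <- seg[ok, , drop = FALSE]
    idx <- cbind(seg$row, seg$col)
    canvas$image[idx] <- pmax(canvas$image[idx], seg$intensity)
  }
  canvas$waveguides_enabled <- TRUE
  canvas
}
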