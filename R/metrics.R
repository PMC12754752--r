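#' Full-width-at-half-maximum focal mask
#'
#' Binary mask of pixels whose pressure is at least half the field peak;
#' ties at exactly half the peak are included.
#'
#' @param field A [pressure_field()] or numeric matrix.
#' @return Object of class `focal_mask`: `mask` (0/1 matrix),
#'   `source_peak_pa`.
#' @export
half_max_mask <- function(field) {
  f <- if (inherits(field, "pressure_field")) field$field else field
  pk <- max(f)
  if (pk <= 0) stop("all-zero field has no half-maximum mask", call. = FALSE)
  structure(list(mask = (f >= 0.5 * pk) * 1L, source_peak_pa = pk),
            class = "focal_mask")
}

# 8-connected component labeling (iterative flood fill).
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  cur <- 0L
  fg <- which(mask > 0)
  for (start in fg) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    stack <- start
    lab[start] <- cur
    while (length(stack)) {
      px <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- (px - 1L) %% nr + 1L
      cl <- (px - 1L) %/% nr + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc <- cl + dc
        if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
        q <- (cc - 1L) * nr + rr
        if (mask[q] > 0 && lab[q] == 0L) { lab[q] <- cur; stack <- c(stack, q) }
      }
    }
  }
  lab
}

# Largest 8-connected component of a binary mask, as a logical matrix.
largest_component <- function(mask) {
  lab <- label_components(mask)
  if (max(lab) == 0L) stop("empty mask", call. = FALSE)
  sizes <- tabulate(lab[lab > 0L])
  lab == which.max(sizes)
}

#' Fit an ellipse to the largest connected focal component
#'
#' Selects the largest 8-connected component of the mask and fits an
#' ellipse by second-order image moments (semi-axes `2 sqrt(eigenvalue)`
#' of the pixel covariance). The tilt `theta_deg` is measured from the
#' array normal (the vertical/row axis): tilts toward the right of the
#' normal are negative, toward the left positive, `theta in (-90, 90]`.
#' Near-circular components (axis ratio < 1.05) report `theta = 0`.
#'
#' @param mask A [half_max_mask()] result or 0/1 matrix.
#' @return Object of class `focal_ellipse`: `center_rc` (sub-pixel),
#'   `major_px`, `minor_px` (full axis lengths in pixels), `theta_deg`,
#'   and `component` (logical matrix of the fitted component).
#' @export
largest_component_ellipse <- function(mask) {
  m <- if (inherits(mask, "focal_mask")) mask$mask else mask
  comp <- largest_component(m)
  idx <- which(comp, arr.ind = TRUE)
  ctr <- colMeans(idx)
  n <- nrow(idx)
  dr <- idx[, 1L] - ctr[1L]; dc <- idx[, 2L] - ctr[2L]
  # pixel covariance with the 1/12 variance of a unit pixel
  crr <- mean(dr * dr) + 1 / 12
  ccc <- mean(dc * dc) + 1 / 12
  crc <- mean(dr * dc)
  tr2 <- (crr + ccc) / 2
  det_ <- crr * ccc - crc^2
  disc <- sqrt(max(tr2^2 - det_, 0))
  l1 <- tr2 + disc; l2 <- max(tr2 - disc, 0)
  major <- 4 * sqrt(l1); minor <- 4 * sqrt(l2)
  # eigenvector of the major eigenvalue, oriented downward (vr >= 0)
  if (abs(crc) < 1e-12 && crr >= ccc) v <- c(1, 0)
  else if (abs(crc) < 1e-12) v <- c(0, 1)
  else v <- c(l1 - ccc, crc)
  if (v[1L] < 0) v <- -v
  theta <- -atan2(v[2L], v[1L]) * 180 / pi
  if (theta <= -90) theta <- theta + 180
  if (minor > 0 && major / minor < 1.05) theta <- 0
  structure(list(center_rc = ctr, major_px = major, minor_px = minor,
                 theta_deg = theta, component = comp,
                 n_pixels = n),
            class = "focal_ellipse")
}

#' Rasterize a fitted focal ellipse to a binary mask
#'
#' @param ellipse A [largest_component_ellipse()] result.
#' @param dim_out Output matrix dimensions (rows, cols).
#' @return 0/1 matrix of pixels whose centers fall inside the ellipse.
#' @export
rasterize_ellipse <- function(ellipse, dim_out) {
  a <- ellipse$major_px / 2; b <- ellipse$minor_px / 2
  th <- -ellipse$theta_deg * pi / 180
  v <- c(cos(th), sin(th))            # major axis direction (row, col)
  w <- c(-sin(th), cos(th))
  rows <- matrix(seq_len(dim_out[1L]), dim_out[1L], dim_out[2L])
  cols <- matrix(seq_len(dim_out[2L]), dim_out[1L], dim_out[2L], byrow = TRUE)
  dr <- rows - ellipse$center_rc[1L]
  dc <- cols - ellipse$center_rc[2L]
  u1 <- dr * v[1L] + dc * v[2L]
  u2 <- dr * w[1L] + dc * w[2L]
  a <- max(a, 1e-9); b <- max(b, 1e-9)
  ((u1 / a)^2 + (u2 / b)^2 <= 1) * 1L
}

as_mask_matrix <- function(m) {
  if (inherits(m, "focal_mask")) m$mask else (m > 0) * 1L
}

#' Focal area error (percent)
#'
#' Absolute difference in area between predicted and ground-truth masks,
#' normalized by the ground-truth area.
#' @param m_pred,m_gt Binary masks (matrix or [half_max_mask()]).
#' @return Percent error (scalar, >= 0).
#' @export
focal_area_error <- function(m_pred, m_gt) {
  a_p <- sum(as_mask_matrix(m_pred)); a_g <- sum(as_mask_matrix(m_gt))
  if (a_g == 0) stop("empty ground-truth mask", call. = FALSE)
  abs(a_p - a_g) / a_g * 100
}

#' Intersection over union of two focal masks (percent)
#' @param m_pred,m_gt Binary masks.
#' @return IoU in `[0, 100]`.
#' @export
iou <- function(m_pred, m_gt) {
  p <- as_mask_matrix(m_pred) > 0; g <- as_mask_matrix(m_gt) > 0
  u <- sum(p | g)
  if (u == 0) stop("both masks empty", call. = FALSE)
  sum(p & g) / u * 100
}

#' Peak pressure error (percent)
#'
#' Compares the maximum pressure anywhere in the simulation window.
#' @param pred,gt [pressure_field()]s or matrices.
#' @return Percent error.
#' @export
peak_pressure_error <- function(pred, gt) {
  pp <- if (inherits(pred, "pressure_field")) pred$peak_pa else max(pred)
  pg <- if (inherits(gt, "pressure_field")) gt$peak_pa else max(gt)
  if (pg <= 0) stop("zero ground-truth pressure", call. = FALSE)
  abs(pp - pg) / pg * 100
}

#' Focal pressure error (percent)
#'
#' Compares pressures at the location of the ground-truth focus (the
#' intended target pixel).
#' @param pred,gt [pressure_field()]s or matrices.
#' @param gt_focus_rc Ground-truth focus pixel, 1-based (row, col).
#' @return Percent error.
#' @export
focal_pressure_error <- function(pred, gt, gt_focus_rc) {
  fp <- if (inherits(pred, "pressure_field")) pred$field else pred
  fg <- if (inherits(gt, "pressure_field")) gt$field else gt
  pg <- fg[gt_focus_rc[1L], gt_focus_rc[2L]]
  if (pg <= 0) stop("zero ground-truth pressure at the focus", call. = FALSE)
  abs(fp[gt_focus_rc[1L], gt_focus_rc[2L]] - pg) / pg * 100
}

#' Euclidean distance between two foci, in mm
#' @param pred_peak_rc,gt_peak_rc (row, col) pixel pairs.
#' @param pixel_spacing_mm Pixel spacing, mm.
#' @return Distance in mm.
#' @export
euclidean_mm <- function(pred_peak_rc, gt_peak_rc, pixel_spacing_mm) {
  sqrt(sum((as.numeric(pred_peak_rc) - as.numeric(gt_peak_rc))^2)) *
    pixel_spacing_mm
}

# Boundary pixels of a logical component: pixels with at least one
# 4-neighbor outside the component (grid edges count as outside).
component_boundary <- function(comp) {
  nr <- nrow(comp); nc <- ncol(comp)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- comp
  inner <- pad[1:nr, 2:(nc + 1L)] & pad[3:(nr + 2L), 2:(nc + 1L)] &
           pad[2:(nr + 1L), 1:nc] & pad[2:(nr + 1L), 3:(nc + 2L)]
  which(comp & !inner, arr.ind = TRUE)
}

#' Modified Hausdorff distance between focal boundaries, in mm
#'
#' The maximum of the two mean nearest-neighbor distances between the
#' boundary point sets of the largest 8-connected components of the two
#' masks.
#'
#' @param b_pred,b_gt Binary masks (their largest components' boundaries
#'   are extracted), or two-column (row, col) matrices of boundary points.
#' @param pixel_spacing_mm Pixel spacing, mm.
#' @return MHD in mm.
#' @export
modified_hausdorff_mm <- function(b_pred, b_gt, pixel_spacing_mm) {
  pts <- function(b) {
    if (is.matrix(b) && ncol(b) == 2L && !all(b %in% c(0, 1)))
      return(b)
    component_boundary(largest_component(as_mask_matrix(b)))
  }
  A <- pts(b_pred); B <- pts(b_gt)
  d2 <- outer(A[, 1L], B[, 1L], "-")^2 + outer(A[, 2L], B[, 2L], "-")^2
  d_ab <- mean(sqrt(apply(d2, 1L, min)))
  d_ba <- mean(sqrt(apply(d2, 2L, min)))
  max(d_ab, d_ba) * pixel_spacing_mm
}

#' Axial and lateral projections of a focal displacement
#'
#' Projects the Cartesian displacement `(dx, dy)` (lateral/column and
#' axial/row offsets, mm) onto the major and minor axes of the predicted
#' focal ellipse with tilt `theta` (degrees, signed; right of the normal
#' negative): axial = `dy cos(theta) - dx sin(theta)`, lateral =
#' `dy sin(theta) + dx cos(theta)`.
#'
#' @param dx,dy Displacement components in mm.
#' @param theta_deg Predicted ellipse tilt, degrees.
#' @return Named vector `c(axial =, lateral =)`, signed.
#' @export
axial_lateral_mm <- function(dx, dy, theta_deg) {
  th <- theta_deg * pi / 180
  c(axial = dy * cos(th) - dx * sin(th),
    lateral = dy * sin(th) + dx * cos(th))
}

#' Complete metrics report for a prediction / ground-truth field pair
#'
#' Computes the full focal-spot evaluation suite: focal area error and
#' IoU on the rasterized FWHM ellipses (or the raw half-maximum masks),
#' peak and focal pressure errors, Euclidean focal distance, modified
#' Hausdorff distance between focal boundaries, and the signed
#' axial/lateral projections of the focal displacement.
#'
#' @param pred,gt [pressure_field()] objects.
#' @param gt_focus_rc Intended target pixel; defaults to the ground-truth
#'   peak location.
#' @param use_ellipse Compute area/IoU on rasterized fitted ellipses
#'   (default) rather than the raw threshold masks.
#' @return One-row `data.frame` with columns `focal_area_error_pct`,
#'   `iou_pct`, `peak_pressure_error_pct`, `focal_pressure_error_pct`,
#'   `euclidean_mm`, `mhd_mm`, `axial_mm`, `lateral_mm`.
#' @export
metrics_report <- function(pred, gt, gt_focus_rc = NULL,
                           use_ellipse = TRUE) {
  sp <- gt$pixel_spacing_mm
  if (is.null(gt_focus_rc)) gt_focus_rc <- gt$peak_rc
  mp <- half_max_mask(pred); mg <- half_max_mask(gt)
  ep <- largest_component_ellipse(mp); eg <- largest_component_ellipse(mg)
  if (use_ellipse) {
    rp <- rasterize_ellipse(ep, dim(pred$field))
    rg <- rasterize_ellipse(eg, dim(gt$field))
  } else {
    rp <- mp$mask; rg <- mg$mask
  }
  dxy <- (pred$peak_rc - gt$peak_rc) * sp
  al <- axial_lateral_mm(dx = dxy[2L], dy = dxy[1L], theta_deg = ep$theta_deg)
  data.frame(
    focal_area_error_pct = focal_area_error(rp, rg),
    iou_pct = iou(rp, rg),
    peak_pressure_error_pct = peak_pressure_error(pred, gt),
    focal_pressure_error_pct = focal_pressure_error(pred, gt, gt_focus_rc),
    euclidean_mm = euclidean_mm(pred$peak_rc, gt$peak_rc, sp),
    mhd_mm = modified_hausdorff_mm(mp$mask, mg$mask, sp),
    axial_mm = unname(al["axial"]),
    lateral_mm = unname(al["lateral"])
  )
}
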