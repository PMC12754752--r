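test_that("half-maximum masks follow the threshold definition exactly", {
  const <- pressure_field(matrix(2, 8, 8), 0.5)
  expect_true(all(half_max_mask(const)$mask == 1))
  single <- matrix(0, 8, 8); single[3, 5] <- 7
  expect_equal(sum(half_max_mask(pressure_field(single, 0.5))$mask), 1L)
  set.seed(11)
  f <- matrix(runif(400), 20, 20)
  m <- half_max_mask(f)$mask
  # brute-force reference
  ref <- matrix(0L, 20, 20)
  for (i in 1:20) for (j in 1:20)
    if (f[i, j] >= 0.5 * max(f)) ref[i, j] <- 1L
  expect_identical(m, ref)
  expect_error(half_max_mask(matrix(0, 4, 4)), "all-zero")
})

test_that("moment ellipses recover shape and orientation", {
  # tall filled rectangle: vertical major axis, zero tilt
  r <- matrix(0L, 32, 32); r[6:26, 14:18] <- 1L
  e <- largest_component_ellipse(r)
  expect_equal(e$theta_deg, 0)
  expect_gt(e$major_px, e$minor_px)
  # disk: near-equal axes, tilt reported as zero by the tie rule
  g <- gaussian_field(64, c(32, 32), 6, 6)
  ec <- largest_component_ellipse(half_max_mask(g))
  expect_lt(abs(ec$major_px / ec$minor_px - 1), 0.02)
  expect_equal(ec$theta_deg, 0)
  # tilted anisotropic blob at a known 20-degree tilt
  gt <- gaussian_field(64, c(32, 32), 10, 3, theta_deg = 20)
  et <- largest_component_ellipse(half_max_mask(gt))
  expect_lt(abs(et$theta_deg - 20), 2)
  expect_error(largest_component_ellipse(matrix(0L, 4, 4)), "empty")
})

test_that("the fitted ellipse selects the largest connected component", {
  m <- matrix(0L, 32, 32)
  m[4:6, 4:6] <- 1L                     # 9 px
  m[15:25, 15:20] <- 1L                 # 66 px
  e <- largest_component_ellipse(m)
  expect_true(all(which(e$component, arr.ind = TRUE)[, 1L] >= 15))
  expect_equal(e$n_pixels, 66L)
})

test_that("area, overlap, and distance metrics satisfy their defining identities", {
  a <- matrix(0L, 16, 16); a[4:8, 4:8] <- 1L
  expect_equal(focal_area_error(a, a), 0)
  expect_equal(iou(a, a), 100)
  expect_equal(modified_hausdorff_mm(a, a, 0.5), 0)
  # disjoint equal-area masks: area error 0 (it measures area difference,
  # not overlap), IoU 0
  b <- matrix(0L, 16, 16); b[10:14, 10:14] <- 1L
  expect_equal(focal_area_error(b, a), 0)
  expect_equal(iou(b, a), 0)
  # 3-4-5 triangle in pixels at the paper grid spacing
  expect_equal(euclidean_mm(c(10, 10), c(13, 14), 0.117), 5 * 0.117)
  # zero tilt leaves the projections untouched
  al <- axial_lateral_mm(dx = 1.3, dy = -2.1, theta_deg = 0)
  expect_equal(unname(al), c(-2.1, 1.3))
  expect_error(focal_area_error(a, matrix(0L, 16, 16)), "empty")
})

test_that("modified Hausdorff distance equals a brute-force double loop on random masks", {
  brute_mhd <- function(ma, mb, sp) {
    bpts <- function(m) {
      comp <- tfus:::largest_component(m)
      pts <- which(comp, arr.ind = TRUE)
      keep <- logical(nrow(pts))
      for (k in seq_len(nrow(pts))) {
        r <- pts[k, 1]; cc <- pts[k, 2]
        nb <- c(if (r > 1) comp[r - 1, cc] else FALSE,
                if (r < nrow(m)) comp[r + 1, cc] else FALSE,
                if (cc > 1) comp[r, cc - 1] else FALSE,
                if (cc < ncol(m)) comp[r, cc + 1] else FALSE)
        keep[k] <- !all(nb)
      }
      pts[keep, , drop = FALSE]
    }
    A <- bpts(ma); B <- bpts(mb)
    dmin <- function(P, Q) vapply(seq_len(nrow(P)), function(i)
      min(sqrt((Q[, 1] - P[i, 1])^2 + (Q[, 2] - P[i, 2])^2)), numeric(1))
    max(mean(dmin(A, B)), mean(dmin(B, A))) * sp
  }
  set.seed(42)
  for (rep in 1:25) {
    ma <- random_mask(); mb <- random_mask()
    expect_equal(modified_hausdorff_mm(ma, mb, 0.117),
                 brute_mhd(ma, mb, 0.117), tolerance = 1e-12)
  }
})

test_that("IoU and MHD are symmetric; projections preserve length", {
  set.seed(7)
  for (rep in 1:10) {
    ma <- random_mask(); mb <- random_mask()
    expect_equal(iou(ma, mb), iou(mb, ma))
    expect_equal(modified_hausdorff_mm(ma, mb, 1),
                 modified_hausdorff_mm(mb, ma, 1))
    dx <- rnorm(1); dy <- rnorm(1); th <- runif(1, -90, 90)
    al <- axial_lateral_mm(dx, dy, th)
    expect_equal(al[["axial"]]^2 + al[["lateral"]]^2, dx^2 + dy^2,
                 tolerance = 1e-9)
  }
})

test_that("scale-invariant metrics agree between normalized and absolute fields", {
  g1 <- gaussian_field(48, c(22, 25), 6, 3, theta_deg = -10)
  g2 <- gaussian_field(48, c(25, 24), 5, 3.5, theta_deg = 5)
  abs1 <- pressure_field(g1$field * 8.3e5, 0.5)
  abs2 <- pressure_field(g2$field * 1.7e6, 0.5)
  rep_n <- metrics_report(g1, g2)
  rep_a <- metrics_report(abs1, abs2)
  for (m in c("focal_area_error_pct", "iou_pct", "euclidean_mm", "mhd_mm",
              "axial_mm", "lateral_mm"))
    expect_equal(rep_n[[m]], rep_a[[m]], tolerance = 1e-9)
})

test_that("peak and focal pressure errors follow the percent-error formulas", {
  g <- gaussian_field(32, c(16, 16), 4, 3)
  p <- pressure_field(g$field * 0.9, 0.5)
  expect_equal(peak_pressure_error(p, g), 10, tolerance = 1e-9)
  expect_equal(focal_pressure_error(p, g, c(16L, 16L)), 10, tolerance = 1e-9)
  # the window peak need not sit at the focus
  f2 <- g$field; f2[30, 30] <- 2
  p2 <- pressure_field(f2, 0.5)
  expect_equal(p2$peak_rc, c(30L, 30L))
  expect_equal(focal_pressure_error(p2, g, c(16L, 16L)), 0, tolerance = 1e-9)
  expect_error(peak_pressure_error(p, matrix(0, 32, 32)), "zero")
})

test_that("peak location ties resolve to the first row-major occurrence", {
  f <- matrix(0, 6, 6); f[4, 2] <- 1; f[2, 5] <- 1
  expect_equal(pressure_field(f, 1)$peak_rc, c(2L, 5L))
})
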