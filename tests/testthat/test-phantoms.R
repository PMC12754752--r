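test_that("phantom generation is bit-identical for a fixed seed", {
  spec <- phantom_spec()
  a <- generate_skull_phantom(spec, 7L)
  b <- generate_skull_phantom(spec, 7L)
  expect_identical(a$hu_grid, b$hu_grid)
  expect_identical(a$skull_mask, b$skull_mask)
  # and does not disturb the session RNG
  set.seed(123); before <- runif(3)
  set.seed(123); invisible(generate_skull_phantom(spec, 1L))
  expect_identical(runif(3), before)
})

test_that("zero trabecular noise yields a constant interior", {
  spec <- phantom_spec(trabecular_noise_scale = 0)
  s <- generate_skull_phantom(spec, 3L)
  pos <- s$hu_grid[s$hu_grid > 0]
  # two tissue classes only: cortical and trabecular
  expect_lte(length(unique(pos)), 2L)
  expect_true(all(s$hu_grid[s$skull_mask == 0] <= s$bone_threshold_hu))
})

test_that("mean bone fraction lies within the analytic plate-area bounds", {
  spec <- phantom_spec()
  n <- spec$grid_size_native
  w_mm <- n * spec$pixel_spacing_mm
  # closed-form area between concentric arcs of radius R and R - t over
  # the full grid width (antiderivative of sqrt(R^2 - x^2))
  Fa <- function(x, R) (x * sqrt(pmax(R^2 - x^2, 0)) + R^2 * asin(x / R)) / 2
  band_area <- function(R, t) 2 * (Fa(w_mm / 2, R) - Fa(w_mm / 2, R - t))
  tv <- max(spec$thickness_variation)
  corners <- expand.grid(R = spec$curvature_radius_mm,
                         t = c(min(spec$total_thickness_mm) * (1 - tv),
                               max(spec$total_thickness_mm) * (1 + tv)))
  areas <- mapply(band_area, corners$R, corners$t)
  lo <- 0.80 * min(areas) / w_mm^2    # noise can punch sub-threshold holes
  hi <- 1.05 * max(areas) / w_mm^2
  fr <- vapply(1:60, function(s)
    mean(generate_skull_phantom(spec, s)$skull_mask), numeric(1L))
  expect_gt(mean(fr), lo)
  expect_lt(mean(fr), hi)
})

test_that("thickness exceeding the grid is rejected", {
  expect_error(phantom_spec(grid_size_native = 32L, pixel_spacing_mm = 0.25,
                            total_thickness_mm = c(6, 9)),
               "exceeds the grid")
})

test_that("nearest-neighbor upsampling expands pixels into blocks", {
  s <- skull_slice(matrix(c(100, 300, 500, 700), 2, 2), 0.625)
  u <- upsample_nearest(s, 2L)
  expect_equal(dim(u$hu_grid), c(4L, 4L))
  expect_equal(u$hu_grid[1:2, 1:2], matrix(100, 2, 2))
  expect_equal(u$hu_grid[3:4, 3:4], matrix(700, 2, 2))
  expect_equal(u$pixel_spacing_mm, 0.3125)
  # factor 1 is the identity
  expect_identical(upsample_nearest(s, 1L), s)
  expect_error(upsample_nearest(s, 2.5), "positive integer")
})

test_that("a 128-pixel slice at 0.625 mm upsamples 4x to 512 at 0.15625 mm", {
  s <- generate_skull_phantom(phantom_spec(), 1L)
  u <- upsample_nearest(s, 4L)
  expect_equal(dim(u$hu_grid), c(512L, 512L))
  expect_equal(u$pixel_spacing_mm, 0.15625)
})

test_that("diversity filter keeps one of identical slices and matches a brute-force pass", {
  mk <- function(seed) generate_skull_phantom(phantom_spec(grid_size_native = 32L,
                                                          pixel_spacing_mm = 1.5),
                                              seed)
  s1 <- mk(1L)
  expect_length(diversity_filter(list(s1, s1), 10), 1L)
  slices <- lapply(1:10, mk)
  # distinct slices all pass a zero threshold
  expect_length(diversity_filter(slices, 0), 10L)
  # threshold at the median pairwise MSE: compare against an independent
  # brute-force greedy enumeration
  mse <- function(a, b) mean((a$hu_grid - b$hu_grid)^2)
  pair_mse <- c()
  for (i in 1:9) for (j in (i + 1):10)
    pair_mse <- c(pair_mse, mse(slices[[i]], slices[[j]]))
  thr <- stats::median(pair_mse)
  keep <- c()
  for (i in seq_along(slices)) {
    ok <- TRUE
    for (j in keep) if (mse(slices[[i]], slices[[j]]) <= thr) { ok <- FALSE; break }
    if (ok) keep <- c(keep, i)
  }
  got <- diversity_filter(slices, thr)
  expect_length(got, length(keep))
  for (k in seq_along(keep))
    expect_identical(got[[k]]$hu_grid, slices[[keep[k]]]$hu_grid)
  # retained set property: no surviving pair at or below the threshold
  for (i in seq_along(got)) for (j in seq_len(i - 1L))
    expect_gt(mse(got[[i]], got[[j]]), thr)
  expect_length(diversity_filter(list(), 1), 0L)
})

test_that("rigid perturbations behave as exact pixel maps", {
  s <- skull64(4L)
  expect_identical(perturb_slice(s, 0, c(0, 0))$hu_grid, s$hu_grid)
  # one-pixel shift moves the raster by one index
  sh <- perturb_slice(s, 0, c(sp64, 0))       # dx = one pixel to the right
  expect_equal(sh$hu_grid[, 2:64], s$hu_grid[, 1:63])
  # rotation forth and back agrees on at least 95% of mask pixels
  rot <- perturb_slice(perturb_slice(s, 5, c(0, 0)), -5, c(0, 0))
  inter <- sum(rot$skull_mask & s$skull_mask)
  expect_gte(inter / sum(s$skull_mask), 0.95)
  expect_error(perturb_slice(s, 50, c(0, 0)), "45")
})

test_that("target grids form the documented lattices", {
  g1 <- make_target_grid(c(1L, 1L), 3.74, c(40L, 40L), 0.117, c(512L, 512L))
  expect_equal(nrow(g1$points), 1L)
  expect_equal(unname(g1$points[1L, ]), c(40L, 40L))
  # 3.74 mm at 0.117 mm/px is a 32-pixel lattice spacing
  g2 <- make_target_grid(c(2L, 1L), 3.74, c(200L, 256L), 0.117, c(512L, 512L))
  expect_equal(diff(g2$points[, "row"]), 32)
  # the default layout provides 56 targets
  g3 <- make_target_grid(c(7L, 8L), 3.74, c(200L, 150L), 0.117, c(512L, 512L))
  expect_equal(nrow(g3$points), 56L)
  expect_error(make_target_grid(c(7L, 8L), 3.74, c(500L, 150L), 0.117,
                                c(512L, 512L)), "bounds")
  expect_error(make_target_grid(c(1L, 1L), 3.74, c(40L, 40L), 0.117,
                                c(512L, 512L), min_row = 60L), "below the skull")
})
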