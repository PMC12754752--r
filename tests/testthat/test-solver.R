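test_that("configuration contracts are enforced", {
  med <- water64()
  expect_error(simulate_forward(med, arr40, rep(0, 10), cfg64), "length")
  expect_error(simulate_forward(med, arr40, NULL, sim_config(grid_n = 128L)),
               "grid")
  bad <- med; bad$pixel_spacing_mm <- 1.1 * med$pixel_spacing_mm
  expect_error(simulate_forward(bad, arr40, NULL, cfg64), "spacing")
  # the time step divides the carrier period into an integer number
  run <- record_at_elements(med, c(40L, 32L), cfg64, arr40)
  ratio <- (1 / arr40$f0_hz) / run$dt_s
  expect_equal(ratio, round(ratio), tolerance = 1e-9)
})

test_that("the solver is linear in the source amplitude", {
  wf <- water_focus_sim64()
  arr_x2 <- reduced_array_spec(element_pressure_pa = 2e6)
  pf2 <- simulate_forward(water64(), arr_x2, wf$phases, cfg64)
  expect_lt(max(abs(pf2$field - 2 * wf$field$field)) / pf2$peak_pa, 1e-6)
})

test_that("analytic focusing lands the peak near the target in water", {
  wf <- water_focus_sim64()
  lambda_mm <- 1492.68 / arr40$f0_hz * 1000
  err_mm <- euclidean_mm(wf$field$peak_rc, wf$target, sp64)
  expect_lt(err_mm, lambda_mm / 2)
})

test_that("mirroring the scene and the delays mirrors the field", {
  s <- skull64(2L)
  med <- map_hu_to_medium(s)
  pv <- ray_trace_phases(med, arr40, c(40L, 27L))
  pf <- simulate_forward(med, arr40, pv, cfg64)
  medm <- med
  for (f in c("density", "speed", "attenuation_coeff", "skull_mask"))
    medm[[f]] <- med[[f]][, 64:1]
  pfm <- simulate_forward(medm, arr40, rev(pv$delays_s), cfg64)
  expect_lt(max(abs(pfm$field[, 64:1] - pf$field)) / pf$peak_pa, 1e-9)
})

test_that("skull attenuation lowers the transmitted focal peak", {
  s <- skull64(3L)
  med <- map_hu_to_medium(s)
  med0 <- med; med0$attenuation_coeff <- med$attenuation_coeff * 0
  pv <- ray_trace_phases(med, arr40, c(40L, 32L))
  reg <- brain_region(s$skull_mask, cfg64)
  pk <- function(m) max(simulate_forward(m, arr40, pv, cfg64)$field[reg$rows,
                                                                    reg$cols])
  expect_lt(pk(med), pk(med0))
})

test_that("point-source traces respect symmetry, causality, and reciprocity", {
  # odd grid so the source can sit exactly on the array axis
  n <- 65L; sp <- 60 / n
  cfg <- sim_config(grid_n = n, pml_px = 10L)
  medo <- water_medium(n, sp)
  tro <- record_at_elements(medo, c(41L, 33L), cfg, arr40)
  expect_equal(dim(tro$traces)[2L], 40L)
  expect_lt(max(abs(tro$traces[, 1L] - tro$traces[, 40L])),
            1e-6 * max(abs(tro$traces)))
  # relative arrival structure matches the straight-line transit oracle
  # (tolerance: two time steps plus half a pixel of transit quantization)
  tr <- record_at_elements(water64(), c(40L, 32L), cfg64, arr40)
  tau <- tfus:::arrival_delays(tr, method = "xcorr")
  el <- element_positions(arr40, c(64L, 64L), sp64)
  d_s <- sqrt((el[, 1L] - 40)^2 + (el[, 2L] - 32)^2) * sp64 / 1000 / 1492.68
  tol <- 2 * tr$dt_s + 0.5 * sp64 / 1000 / 1492.68
  expect_lt(max(abs((tau - tau[20L]) - (d_s - d_s[20L]))), tol)
  # reciprocity: A -> B transit equals B -> A transit
  A <- c(40L, 32L); B <- c(20L, 45L)
  trAB <- record_at_elements(water64(), A, cfg64, arr40, trace_rcs = rbind(B))
  trBA <- record_at_elements(water64(), B, cfg64, arr40, trace_rcs = rbind(A))
  tAB <- tfus:::arrival_delays(trAB, method = "xcorr")
  tBA <- tfus:::arrival_delays(trBA, method = "xcorr")
  expect_lt(abs(tAB - tBA), 2 * trAB$dt_s)
  # zero-amplitude source emits nothing
  tr0 <- record_at_elements(water64(), c(40L, 32L), cfg64, arr40,
                            amplitude_pa = 0)
  expect_true(all(tr0$traces == 0))
})

test_that("halving the grid spacing moves the water focal peak by less than one coarse pixel", {
  wf <- water_focus_sim64()
  cfg128 <- sim_config(grid_n = 128L)
  med128 <- water_medium(128L, 60 / 128)
  tgt128 <- wf$target * 2L - 1L
  pv128 <- geometric_focus_phases(1492.68, arr40, tgt128, 60 / 128,
                                  c(128L, 128L))
  pf128 <- simulate_forward(med128, arr40, pv128, cfg128)
  # compare positions in mm on the shared window
  pos64 <- (wf$field$peak_rc - 0.5) * sp64
  pos128 <- (pf128$peak_rc - 0.5) * 60 / 128
  expect_lt(sqrt(sum((pos64 - pos128)^2)), sp64)
})

test_that("pressure fields expose a consistent normalized form", {
  wf <- water_focus_sim64()$field
  expect_equal(max(wf$normalized), 1)
  expect_equal(wf$normalized * wf$peak_pa, wf$field, tolerance = 1e-12)
  expect_equal(wf$field[wf$peak_rc[1L], wf$peak_rc[2L]], wf$peak_pa)
})
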