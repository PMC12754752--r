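test_that("phase vectors normalize delays and wrap phases consistently", {
  f0 <- 250e3; T0 <- 1 / f0
  v <- phase_vector(c(3e-6, 1e-6, 9e-6), f0)
  expect_equal(min(v$delays_s), 0)
  expect_equal(v$phases_rad, (2 * pi * f0 * v$delays_s) %% (2 * pi))
  expect_true(all(v$phases_rad >= 0 & v$phases_rad < 2 * pi))
  # one full period wraps to phase zero, as does zero delay
  w <- wrap_phase(phase_vector(c(0, T0), f0))
  expect_equal(w$phases_rad, c(0, 0), tolerance = 1e-9)
  # round trips: exact on phases, modulo one period on delays
  set.seed(5)
  x <- phase_vector(runif(16, 0, 5 * T0), f0)
  wx <- wrap_phase(x)
  rt <- wrap_phase(delay_from_phase(wx))
  expect_equal(rt$phases_rad, wx$phases_rad, tolerance = 1e-9)
  expect_equal(rt$delays_s, x$delays_s %% T0, tolerance = 1e-15)
  expect_true(all(phase_fractions(x) >= 0 & phase_fractions(x) < 1))
})

test_that("geometric focusing delays follow the closed form", {
  # 3-4-5 geometry: element 40 mm lateral of a 30 mm-deep target at
  # c = 1500 m/s gives a 33.33 us time of flight
  arr2 <- array_spec(n_elements = 2L, pitch_mm = 80, standoff_mm = 0,
                     f0_hz = 500e3)
  pv <- geometric_focus_phases(1500, arr2, c(31L, 51L), 1, c(101L, 101L))
  el <- element_positions(arr2, c(101L, 101L), 1)
  d_mm <- sqrt(rowSums((el - matrix(c(31, 51), 2, 2, byrow = TRUE))^2))
  expect_equal(max(d_mm) / 1000 / 1500, 50 / 1000 / 1500 + pv$delays_s[2])
  expect_equal(sqrt(40^2 + 30^2), 50)
  expect_equal(50 / 1000 / 1500, 33.33e-6, tolerance = 1e-3)
  # on-axis target (odd grid, integer axis): symmetric delays with zeros
  # at the outermost elements
  arr11 <- array_spec(n_elements = 11L, pitch_mm = 4, standoff_mm = 2,
                      f0_hz = 500e3)
  pvs <- geometric_focus_phases(1500, arr11, c(41L, 51L), 1, c(101L, 101L))
  expect_equal(pvs$delays_s, rev(pvs$delays_s), tolerance = 1e-12)
  expect_equal(pvs$delays_s[1L], 0)
})

test_that("straight-ray integration reduces to the closed form in uniform media", {
  pv_ray <- ray_trace_phases(water64(), arr40, c(40L, 30L))
  pv_geo <- geometric_focus_phases(unique(as.vector(water64()$speed)),
                                   arr40, c(40L, 30L), sp64, c(64L, 64L))
  expect_equal(pv_ray$delays_s, pv_geo$delays_s, tolerance = 1e-9)
})

test_that("wedge-thickness slabs order ray delays like a brute-force integral", {
  # slab thickness grows with column: rays through the thicker side gain
  # more high-speed path and arrive earlier
  hu <- matrix(0, 64, 64)
  for (j in 1:64) {
    th_px <- 2L + round(6 * j / 64)
    hu[10:(10 + th_px), j] <- 1500
  }
  s <- skull_slice(hu, sp64)
  med <- map_hu_to_medium(s)
  tgt <- c(45L, 32L)
  pv <- ray_trace_phases(med, arr40, tgt)
  el <- element_positions(arr40, c(64L, 64L), sp64)
  # independent oracle: dense nearest-neighbor sampled line integral
  t_oracle <- vapply(seq_len(nrow(el)), function(k) {
    n_s <- 4000L
    rr <- seq(el[k, "row"], tgt[1L], length.out = n_s)
    cc <- seq(el[k, "col"], tgt[2L], length.out = n_s)
    sp_m <- sp64 / 1000
    len <- sqrt(sum((c(rr[n_s], cc[n_s]) - c(rr[1L], cc[1L]))^2)) * sp_m
    slo <- 1 / med$speed[cbind(pmin(pmax(round(rr), 1L), 64L),
                               pmin(pmax(round(cc), 1L), 64L))]
    mean(slo) * len
  }, numeric(1L))
  d_oracle <- max(t_oracle) - t_oracle
  expect_gt(cor(pv$delays_s, d_oracle, method = "spearman"), 0.98)
  expect_lt(max(abs(pv$delays_s - d_oracle)), 0.15e-6)
})

test_that("time reversal reproduces analytic focusing in water", {
  tgt <- c(39L, 32L)
  pv_tr <- time_reversal_phases(water64(), arr40, tgt, cfg64)
  pv_geo <- geometric_focus_phases(unique(as.vector(water64()$speed)),
                                   arr40, tgt, sp64, c(64L, 64L))
  # the dominant error is sub-pixel source/receiver quantization: half a
  # pixel of water transit
  half_px <- 0.5 * sp64 / 1000 / 1492.68
  expect_lt(max(abs(pv_tr$delays_s - pv_geo$delays_s)), half_px)
})

test_that("a centered target in a symmetric medium gives a palindromic vector", {
  # odd grid so the array axis falls on an integer column
  n <- 65L; sp <- 60 / n
  cfg <- sim_config(grid_n = n, pml_px = 10L)
  med <- water_medium(n, sp)
  pv_c <- time_reversal_phases(med, arr40, c(41L, 33L), cfg)
  half_px <- 0.5 * sp / 1000 / 1492.68
  expect_lt(max(abs(pv_c$delays_s - rev(pv_c$delays_s))), half_px)
})

test_that("time-reversal delays are invariant to source amplitude", {
  med <- map_hu_to_medium(skull64(1L))
  tr1 <- record_at_elements(med, c(45L, 32L), cfg64, arr40,
                            amplitude_pa = 1e6)
  tr2 <- record_at_elements(med, c(45L, 32L), cfg64, arr40,
                            amplitude_pa = 3e6)
  expect_equal(tfus:::arrival_delays(tr1), tfus:::arrival_delays(tr2),
               tolerance = 1e-12)
})
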