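# Shared fixtures, memoized so expensive simulations run once per suite.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, expr, envir = .fixtures)
  get(key, envir = .fixtures)
}

# 64 x 64 scene over the 6 cm window: fast enough for unit tests
sp64 <- 60 / 64
cfg64 <- sim_config(grid_n = 64L, pml_px = 10L)
arr40 <- reduced_array_spec()

spec64 <- reduced_phantom_spec(grid_size_native = 64L, pixel_spacing_mm = sp64)

water64 <- function() memo("water64", water_medium(64L, sp64))

skull64 <- function(seed = 2L) memo(paste0("skull64_", seed), {
  generate_skull_phantom(spec64, seed)
})

# water forward simulation with analytic focusing delays (64 grid)
water_focus_sim64 <- function() memo("water_focus_sim64", {
  tgt <- c(20L, 32L)
  pv <- geometric_focus_phases(1492.68, arr40, tgt, sp64, c(64L, 64L))
  list(target = tgt, phases = pv,
       field = simulate_forward(water64(), arr40, pv, cfg64))
})

# a smooth two-blob field pair for metric tests
gaussian_field <- function(n, center, sigma_r, sigma_c, theta_deg = 0,
                           spacing = 0.5) {
  th <- theta_deg * pi / 180
  v <- c(cos(th), -sin(th)); w <- c(sin(th), cos(th))
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  dr <- rows - center[1L]; dc <- cols - center[2L]
  u1 <- dr * v[1L] + dc * v[2L]
  u2 <- dr * w[1L] + dc * w[2L]
  pressure_field(exp(-(u1^2 / (2 * sigma_r^2) + u2^2 / (2 * sigma_c^2))),
                 spacing)
}

random_mask <- function(n = 16L, p = 0.35) {
  m <- matrix(stats::rbinom(n * n, 1L, p), n, n)
  if (sum(m) == 0L) m[sample(n * n, 1L)] <- 1L
  m
}
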