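#' Phased-array specification
#'
#' Geometry and drive parameters of the flat transducer array. Full-scale
#' defaults: 80 elements at 0.7 mm pitch (55.3 mm aperture), 3 mm
#' standoff from the top row, 500 kHz, 5-cycle burst, 1 MPa drive per
#' element.
#'
#' @param n_elements Number of elements (>= 2).
#' @param pitch_mm Element pitch, mm.
#' @param standoff_mm Distance of the element row from the top edge, mm.
#' @param f0_hz Center frequency, Hz.
#' @param n_cycles Cycles in the emitted tone burst.
#' @param element_pressure_pa Drive amplitude per element, Pa.
#' @param element_width_mm Physical source width per element, mm.
#' @return Object of class `array_spec`.
#' @export
array_spec <- function(n_elements = 80L, pitch_mm = 0.7, standoff_mm = 3,
                       f0_hz = 500e3, n_cycles = 5L,
                       element_pressure_pa = 1e6, element_width_mm = 0.35) {
  if (n_elements < 2L) stop("need at least 2 elements", call. = FALSE)
  stopifnot_scalar(f0_hz, "f0_hz", positive = TRUE)
  structure(list(n_elements = as.integer(n_elements), pitch_mm = pitch_mm,
                 standoff_mm = standoff_mm, f0_hz = f0_hz,
                 n_cycles = as.integer(n_cycles),
                 element_pressure_pa = element_pressure_pa,
                 element_width_mm = element_width_mm),
            class = "array_spec")
}

#' Reduced-scale array used throughout the test suites
#'
#' 40 elements at 250 kHz; all other parameters as [array_spec()].
#' @param ... Overrides forwarded to [array_spec()].
#' @export
reduced_array_spec <- function(...) {
  args <- utils::modifyList(list(n_elements = 40L, f0_hz = 250e3), list(...))
  do.call(array_spec, args)
}

#' Simulation configuration
#'
#' @param window_mm Physical window size (square), mm. Default 60 mm.
#' @param grid_n Grid points per side. Default 512 (0.117 mm spacing).
#' @param cfl CFL number; the time step is `cfl * dx / max(c)`, then
#'   rounded down so one carrier period holds an integer number of steps.
#' @param pml_px Perfectly-matched-layer thickness, pixels.
#' @param total_time_s Total integrated time; `NULL` selects burst
#'   duration + diagonal transit at the minimum speed + 20% margin.
#' @param record_mode One of "max_amplitude", "traces", "both".
#' @param cw_mode If `TRUE` the burst envelope is held at 1 after ramp-up
#'   (continuous-wave excitation) instead of ending after `n_cycles`.
#' @param seed Integer seed recorded with outputs.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(window_mm = 60, grid_n = 512L, cfl = 0.3,
                       pml_px = 20L, total_time_s = NULL,
                       record_mode = c("max_amplitude", "traces", "both"),
                       cw_mode = FALSE, seed = 0L) {
  record_mode <- match.arg(record_mode)
  structure(list(window_mm = window_mm, grid_n = as.integer(grid_n),
                 cfl = cfl, pml_px = as.integer(pml_px),
                 total_time_s = total_time_s, record_mode = record_mode,
                 cw_mode = cw_mode, seed = as.integer(seed)),
            class = "sim_config")
}

#' Reduced-scale simulation configuration (128 x 128 over 6 cm)
#' @param ... Overrides forwarded to [sim_config()].
#' @export
reduced_sim_config <- function(...) {
  args <- utils::modifyList(list(grid_n = 128L), list(...))
  do.call(sim_config, args)
}

#' Maximum-amplitude pressure field container
#'
#' @param field Matrix of per-pixel maximum |pressure| in Pa.
#' @param pixel_spacing_mm Pixel spacing, mm.
#' @return Object of class `pressure_field` with `field`, `peak_pa`,
#'   `peak_rc` (first occurrence scanning rows top-down, left-to-right),
#'   and `normalized` = `field / peak_pa`.
#' @export
pressure_field <- function(field, pixel_spacing_mm) {
  pk <- max(field)
  if (pk <= 0) stop("all-zero pressure field", call. = FALSE)
  # row-major first occurrence of the maximum
  idx <- which(t(field) == pk)[1L] - 1L
  rc <- c(idx %/% ncol(field) + 1L, idx %% ncol(field) + 1L)
  structure(list(field = field, peak_pa = pk,
                 peak_rc = as.integer(rc),
                 normalized = field / pk,
                 pixel_spacing_mm = pixel_spacing_mm),
            class = "pressure_field")
}

# Hann-windowed tone burst, zero outside [0, n_cycles/f0]. `t` vectorized.
tone_burst <- function(t, f0, n_cycles, cw = FALSE) {
  tb <- n_cycles / f0
  inside <- t >= 0 & (cw | t <= tb)
  env <- ifelse(cw & t > tb / 2, 1, 0.5 * (1 - cos(2 * pi * clamp(t, 0, tb) / tb)))
  ifelse(inside, sin(2 * pi * f0 * t) * env, 0)
}

# Shared grid setup for both propagation entry points.
fdtd_setup <- function(medium, config) {
  n <- config$grid_n
  if (!identical(dim(medium$density), c(n, n)))
    stop("medium grid does not match `config$grid_n`", call. = FALSE)
  dx <- config$window_mm / n / 1000
  sp_m <- medium$pixel_spacing_mm / 1000
  if (abs(sp_m - dx) > 1e-9 * max(dx, sp_m))
    stop("medium pixel spacing disagrees with the simulation window",
         call. = FALSE)
  rho <- medium$density
  cc <- medium$speed
  list(n = n, dx = dx, rho = rho, c = cc, K = rho * cc^2,
       cmax = max(cc), cmin = min(cc))
}

# PML damping profile (1/s) at (possibly staggered) pixel coordinates
# `pos` in 1..n; quadratic ramp over `pml_px` cells at both edges.
pml_profile <- function(pos, n, pml_px, sigma_max) {
  d_left <- (pml_px + 0.5) - pos
  d_right <- pos - (n - pml_px + 0.5)
  d <- pmax(d_left, d_right, 0) / pml_px
  sigma_max * d^2
}

# Core split-field staggered-grid FDTD integrator.
#
# sources: list(idx = linear indices into the p grid, element = element id
# per index, scale = per-index injection scale, delays_s = per-element
# onset delay). Records running max |p| and/or traces at `trace_idx`.
fdtd_run <- function(medium, config, sources, f0, n_cycles,
                     trace_idx = NULL, record_max = TRUE,
                     record_from_s = 0) {
  g <- fdtd_setup(medium, config)
  n <- g$n; dx <- g$dx
  dt0 <- config$cfl * dx / g$cmax
  steps_per_cycle <- ceiling(1 / (f0 * dt0))
  dt <- 1 / (f0 * steps_per_cycle)
  ttot <- config$total_time_s
  if (is.null(ttot))
    ttot <- 1.2 * (n_cycles / f0 + sqrt(2) * n * dx / g$cmin)
  nsteps <- as.integer(ceiling(ttot / dt))

  # PML sigma (quadratic, reflection coefficient 1e-4)
  sig_max <- 3 * g$cmax * log(1e4) / (2 * config$pml_px * dx)
  sx_p <- pml_profile(seq_len(n), n, config$pml_px, sig_max)
  sy_p <- sx_p
  sx_u <- pml_profile(seq_len(n - 1) + 0.5, n, config$pml_px, sig_max)
  sy_u <- sx_u

  # power-law absorption (y = 1) evaluated at f0, as a pressure loss rate
  alpha_np_m <- medium$attenuation_coeff * (f0 / 1e6) * 100 / 8.6858896
  a_rate <- alpha_np_m * g$c                      # 1/s

  Sx <- matrix(sx_p, n, n, byrow = TRUE) + a_rate
  Sy <- matrix(sy_p, n, n) + a_rate
  Apx <- (1 - 0.5 * dt * Sx) / (1 + 0.5 * dt * Sx)
  Bpx <- (dt / (1 + 0.5 * dt * Sx)) * g$K
  Apy <- (1 - 0.5 * dt * Sy) / (1 + 0.5 * dt * Sy)
  Bpy <- (dt / (1 + 0.5 * dt * Sy)) * g$K

  rho_x <- 0.5 * (g$rho[, -1] + g$rho[, -n])
  rho_y <- 0.5 * (g$rho[-1, ] + g$rho[-n, ])
  Sxu <- matrix(sx_u, n, n - 1, byrow = TRUE)
  Syu <- matrix(sy_u, n - 1, n)
  Aux <- (1 - 0.5 * dt * Sxu) / (1 + 0.5 * dt * Sxu)
  Bux <- (dt / (1 + 0.5 * dt * Sxu)) / rho_x
  Auy <- (1 - 0.5 * dt * Syu) / (1 + 0.5 * dt * Syu)
  Buy <- (dt / (1 + 0.5 * dt * Syu)) / rho_y

  px <- matrix(0, n, n); py <- matrix(0, n, n)
  ux <- matrix(0, n, n - 1); uy <- matrix(0, n - 1, n)
  p <- px
  fmax <- if (record_max) matrix(0, n, n) else NULL
  traces <- if (!is.null(trace_idx)) matrix(0, nsteps, length(trace_idx)) else NULL

  inv_dx <- 1 / dx
  src_scale <- sources$scale * 0.5          # split equally between px, py
  dudx <- matrix(0, n, n); dudy <- matrix(0, n, n)

  for (s in seq_len(nsteps)) {
    t_now <- (s - 1) * dt
    # velocity update
    ux <- Aux * ux - Bux * ((p[, -1] - p[, -n]) * inv_dx)
    uy <- Auy * uy - Buy * ((p[-1, ] - p[-n, ]) * inv_dx)
    # pressure update
    dudx[, 1] <- ux[, 1]
    dudx[, 2:(n - 1)] <- ux[, -1] - ux[, -(n - 1)]
    dudx[, n] <- -ux[, n - 1]
    dudy[1, ] <- uy[1, ]
    dudy[2:(n - 1), ] <- uy[-1, ] - uy[-(n - 1), ]
    dudy[n, ] <- -uy[n - 1, ]
    px <- Apx * px - Bpx * (dudx * inv_dx)
    py <- Apy * py - Bpy * (dudy * inv_dx)
    # additive (soft) source
    amp <- tone_burst(t_now - sources$delays_s[sources$element], f0,
                      n_cycles, cw = config$cw_mode)
    if (any(amp != 0)) {
      inj <- src_scale * amp
      px[sources$idx] <- px[sources$idx] + inj
      py[sources$idx] <- py[sources$idx] + inj
    }
    p <- px + py
    if (record_max && t_now >= record_from_s) fmax <- pmax(fmax, abs(p))
    if (!is.null(traces)) traces[s, ] <- p[trace_idx]
    if (s %% 500L == 0L && !all(is.finite(p[1L])))
      stop("pressure field blew up (unstable configuration)", call. = FALSE)
  }
  if (!all(is.finite(p)))
    stop("pressure field blew up (unstable configuration)", call. = FALSE)
  list(fmax = fmax, traces = traces, dt_s = dt, nsteps = nsteps)
}

# Source bookkeeping for the full array: each element occupies
# `element_width_mm` worth of pixels centered on its canvas column.
array_sources <- function(medium, array, delays_s, config) {
  n <- config$grid_n
  sp <- medium$pixel_spacing_mm
  el <- element_positions(array, c(n, n), sp)
  w_px <- max(1L, round(array$element_width_mm / sp))
  offs <- seq_len(w_px) - 1L - (w_px - 1L) %/% 2L
  rows <- rep(el[, "row"], each = length(offs))
  cols <- as.integer(rep(el[, "col"], each = length(offs)) +
                       rep(offs, times = nrow(el)))
  cols <- clamp(cols, 1L, n)
  element <- rep(seq_len(nrow(el)), each = length(offs))
  idx <- (cols - 1L) * n + rows               # column-major linear index
  list(idx = idx, element = element,
       scale = rep(array$element_pressure_pa, length(idx)),
       delays_s = delays_s, el = el)
}

#' Forward simulation of the phased array through a medium
#'
#' Injects a Hann-windowed tone burst from every element with its
#' per-element emission delay and integrates the 2D linear acoustic
#' equations, returning the per-pixel maximum-amplitude pressure field.
#' The additive source drive is calibrated so one element in free water
#' radiates on the order of `element_pressure_pa`; only relative
#' pressures enter the downstream metrics.
#'
#' @param medium An [map_hu_to_medium()] result.
#' @param array An [array_spec()].
#' @param phases A [phase_vector()], or a numeric vector of per-element
#'   emission delays in seconds, or `NULL` for zero delays.
#' @param config A [sim_config()]. Maximum-amplitude recording starts
#'   once every element has finished emitting (burst duration plus the
#'   largest delay), so the per-pixel maximum describes the propagating
#'   field rather than the drive amplitude at the source pixels.
#' @return A [pressure_field()].
#' @export
simulate_forward <- function(medium, array, phases = NULL,
                             config = sim_config()) {
  delays <- phase_delays(phases, array)
  src <- array_sources(medium, array, delays, config)
  rec_from <- array$n_cycles / array$f0_hz + max(delays)
  run <- fdtd_run(medium, config, src, array$f0_hz, array$n_cycles,
                  record_max = TRUE, record_from_s = rec_from)
  pressure_field(run$fmax, medium$pixel_spacing_mm)
}

#' Record a test pulse from the target at the array elements
#'
#' Emits the same tone burst from a point source at `source_rc` and
#' samples the pressure at every element pixel each time step: the
#' receive leg of time-reversal aberration correction.
#'
#' @param medium An acoustic medium.
#' @param source_rc Source pixel, 1-based (row, col); must lie below the
#'   skull.
#' @param config A [sim_config()].
#' @param array The [array_spec()] whose element positions are sampled.
#' @param amplitude_pa Source drive amplitude.
#' @param trace_rcs Optional (row, col) matrix of sampling pixels;
#'   defaults to the array element positions.
#' @return Object of class `element_traces`: `traces` (steps x elements),
#'   `dt_s`, `t0_s`.
#' @export
record_at_elements <- function(medium, source_rc, config = sim_config(),
                               array = array_spec(), amplitude_pa = 1e6,
                               trace_rcs = NULL) {
  n <- config$grid_n
  source_rc <- as.integer(source_rc)
  if (any(source_rc < 1) || any(source_rc > n))
    stop("source outside the grid", call. = FALSE)
  skull_rows <- which(rowSums(medium$skull_mask) > 0)
  if (length(skull_rows) && source_rc[1L] <= max(skull_rows))
    stop("source must lie below the skull", call. = FALSE)
  el <- if (is.null(trace_rcs))
    element_positions(array, c(n, n), medium$pixel_spacing_mm)
  else matrix(as.integer(trace_rcs), ncol = 2L,
              dimnames = list(NULL, c("row", "col")))
  trace_idx <- (el[, "col"] - 1L) * n + el[, "row"]
  src <- list(idx = (source_rc[2L] - 1L) * n + source_rc[1L],
              element = 1L, scale = amplitude_pa, delays_s = 0)
  run <- fdtd_run(medium, config, src, array$f0_hz, array$n_cycles,
                  trace_idx = trace_idx, record_max = FALSE)
  structure(list(traces = run$traces, dt_s = run$dt_s, t0_s = 0,
                 element_rcs = el, f0_hz = array$f0_hz,
                 n_cycles = array$n_cycles),
            class = "element_traces")
}
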