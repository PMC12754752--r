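#' Per-element phase correction vector
#'
#' Stores per-element emission delays in seconds, normalized so the
#' smallest delay is zero, together with the wrapped phases at the
#' carrier frequency: `phases_rad = (2 pi f0 delays_s) mod 2 pi`.
#'
#' @param delays_s Numeric vector of per-element delays, seconds.
#' @param f0_hz Carrier frequency, Hz.
#' @return Object of class `phase_vector` with `delays_s` (min 0),
#'   `phases_rad` in `[0, 2 pi)`, `f0_hz`.
#' @export
phase_vector <- function(delays_s, f0_hz) {
  stopifnot_scalar(f0_hz, "f0_hz", positive = TRUE)
  if (any(!is.finite(delays_s))) stop("non-finite delays", call. = FALSE)
  d <- delays_s - min(delays_s)
  structure(list(delays_s = d,
                 phases_rad = (2 * pi * f0_hz * d) %% (2 * pi),
                 f0_hz = f0_hz),
            class = "phase_vector")
}

#' @export
print.phase_vector <- function(x, ...) {
  cat(sprintf("<phase_vector> %d elements @ %.3g Hz, delay span %.3g us\n",
              length(x$delays_s), x$f0_hz, 1e6 * max(x$delays_s)))
  invisible(x)
}

# Accept a phase_vector, a bare numeric delay vector, or NULL (zeros).
phase_delays <- function(phases, array) {
  d <- if (is.null(phases)) rep(0, array$n_elements)
       else if (inherits(phases, "phase_vector")) phases$delays_s
       else as.numeric(phases)
  if (length(d) != array$n_elements)
    stop("phase vector length does not match the element count", call. = FALSE)
  d
}

#' Delays as fractions of a carrier period
#'
#' The surrogate network's phase targets: wrapped delays normalized to
#' `[0, 1)` fractions of one period at `f0`.
#' @param v A [phase_vector()].
#' @return Numeric vector in `[0, 1)`.
#' @export
phase_fractions <- function(v) (v$delays_s * v$f0_hz) %% 1

#' Wrap a phase vector onto one carrier period
#'
#' Reduces the stored delays modulo one period; the wrapped phases are
#' unchanged. `delay_from_phase()` is the inverse map from wrapped phases
#' back to delays in `[0, T)`; the two round-trip exactly on phases and
#' modulo one period on delays.
#'
#' @param v A [phase_vector()].
#' @return A [phase_vector()].
#' @export
wrap_phase <- function(v) {
  period <- 1 / v$f0_hz
  pv <- phase_vector(v$delays_s %% period, v$f0_hz)
  # keep sub-period values verbatim (no re-anchoring to min)
  pv$delays_s <- v$delays_s %% period
  pv$phases_rad <- (2 * pi * v$f0_hz * pv$delays_s) %% (2 * pi)
  pv
}

#' @rdname wrap_phase
#' @export
delay_from_phase <- function(v) {
  pv <- phase_vector(rep(0, length(v$phases_rad)), v$f0_hz)
  pv$delays_s <- v$phases_rad / (2 * pi * v$f0_hz)
  pv$phases_rad <- v$phases_rad %% (2 * pi)
  pv
}

#' Analytic geometric-focusing delays in a homogeneous medium
#'
#' Closed-form focusing law: per-element time of flight
#' `t_k = |x_k - x_target| / c0`, emission delays `max(t_k) - t_k`.
#'
#' @param c0 Sound speed, m/s.
#' @param array An [array_spec()].
#' @param target_rc Target pixel, 1-based (row, col).
#' @param pixel_spacing_mm Pixel spacing, mm.
#' @param grid_dim Host grid dimensions (rows, cols).
#' @return A [phase_vector()].
#' @export
geometric_focus_phases <- function(c0, array, target_rc, pixel_spacing_mm,
                                   grid_dim) {
  stopifnot_scalar(c0, "c0", positive = TRUE)
  el <- element_positions(array, grid_dim, pixel_spacing_mm)
  d_mm <- sqrt((el[, "row"] - target_rc[1L])^2 +
               (el[, "col"] - target_rc[2L])^2) * pixel_spacing_mm
  t_k <- d_mm / 1000 / c0
  phase_vector(max(t_k) - t_k, array$f0_hz)
}

#' Straight-ray time-of-flight correction delays
#'
#' For each element, integrates travel time along the straight segment
#' from the element to the target through the heterogeneous speed map
#' (sub-pixel sampling with bilinear speed lookup; refraction is
#' deliberately ignored). Emission delays are `max(t_k) - t_k`.
#'
#' @param medium An acoustic medium.
#' @param array An [array_spec()].
#' @param target_rc Target pixel, 1-based (row, col).
#' @param step_frac Sampling step as a fraction of the pixel spacing.
#' @return A [phase_vector()].
#' @export
ray_trace_phases <- function(medium, array, target_rc, step_frac = 0.25) {
  el <- element_positions(array, dim(medium$density), medium$pixel_spacing_mm)
  ds_px <- step_frac
  t_k <- vapply(seq_len(nrow(el)), function(k) {
    dr <- target_rc[1L] - el[k, "row"]
    dc <- target_rc[2L] - el[k, "col"]
    len_px <- sqrt(dr^2 + dc^2)
    m <- max(2L, ceiling(len_px / ds_px) + 1L)
    s <- seq(0, 1, length.out = m)
    rr <- el[k, "row"] + s * dr
    cc <- el[k, "col"] + s * dc
    slo <- 1 / bilinear_at(medium$speed, rr, cc)
    seg <- len_px * medium$pixel_spacing_mm / 1000 / (m - 1)
    # trapezoid rule over the slowness samples
    sum((slo[-1] + slo[-m]) / 2) * seg
  }, numeric(1L))
  phase_vector(max(t_k) - t_k, array$f0_hz)
}

# Arrival delay per element from recorded traces.
#
# method "fourier" (default): delays from the phase of each trace's DFT
# component at the carrier f0. If `ref_delays_s` (e.g. the straight
# water time of flight to each element) is supplied, the carrier phase
# is measured relative to that reference; the skull-induced residuals
# span well under one period, so they are recovered without any
# unwrapping by circular re-centering around the mean residual.
# Without a reference the phases are unwrapped across the array by
# nearest-neighbor continuity.
# method "xcorr": lag of the envelope peak of the cross-correlation
# with the emitted burst (coarse, but period-unambiguous).
arrival_delays <- function(traces, method = c("fourier", "xcorr"),
                           ref_delays_s = NULL, weak_rel = 1e-3) {
  method <- match.arg(method)
  tr <- traces$traces
  dt <- traces$dt_s
  f0 <- traces$f0_hz
  nt <- nrow(tr)
  t_axis <- (seq_len(nt) - 1) * dt
  ph <- exp(-2i * pi * f0 * t_axis)
  amp_c <- as.vector(ph %*% tr) * dt           # complex amplitude at f0
  amp <- Mod(amp_c)
  weak <- amp < weak_rel * max(amp)

  if (method == "fourier") {
    if (!is.null(ref_delays_s)) {
      # residual rotation beyond the reference time of flight
      res <- amp_c * exp(2i * pi * f0 * ref_delays_s)
      ctr <- Arg(mean(res / Mod(res)))
      dev <- Arg(res * exp(-1i * ctr))        # in (-pi, pi]
      tau <- ref_delays_s - (dev + ctr) / (2 * pi * f0)
    } else {
      phi <- Arg(amp_c)
      dphi <- diff(phi)
      dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
      phi_u <- cumsum(c(phi[1L], dphi))
      tau <- -phi_u / (2 * pi * f0)
    }
  } else {
    burst_i <- tone_burst(t_axis, f0, traces$n_cycles)
    burst_q <- tone_burst(t_axis - 1 / (4 * f0), f0, traces$n_cycles)
    xc_env <- function(x) {
      ci <- stats::convolve(x, rev(burst_i), type = "open")
      cq <- stats::convolve(x, rev(burst_q), type = "open")
      sqrt(ci^2 + cq^2)
    }
    lag0 <- which.max(xc_env(burst_i))   # zero-lag calibration
    tau <- vapply(seq_len(ncol(tr)), function(k)
      (which.max(xc_env(tr[, k])) - lag0) * dt, numeric(1L))
  }

  if (any(weak)) {
    warning(sprintf("%d element(s) below the arrival-detection threshold; delays interpolated from neighbors",
                    sum(weak)))
    good <- which(!weak)
    if (length(good) < 2L) stop("too few usable element traces", call. = FALSE)
    tau[weak] <- stats::approx(good, tau[good], xout = which(weak),
                               rule = 2)$y
  }
  tau
}

#' Time-reversal phase aberration correction
#'
#' Ground-truth correction procedure: a test pulse is emitted from the
#' target, the arrival delay at every element is estimated from the
#' recorded traces, and the conjugated delays `max(tau) - tau` are
#' returned as emission delays. Elements whose received amplitude falls
#' below the detection threshold are flagged and their delay
#' interpolated from neighboring elements (with a warning).
#'
#' @param medium An acoustic medium.
#' @param array An [array_spec()].
#' @param target_rc Target pixel, 1-based (row, col), below the skull.
#' @param config A [sim_config()].
#' @param method Arrival estimator: `"fourier"` (phase of the carrier
#'   DFT component, unwrapped across the array) or `"xcorr"` (envelope
#'   peak of the cross-correlation with the emitted burst).
#' @return A [phase_vector()].
#' @export
time_reversal_phases <- function(medium, array, target_rc,
                                 config = sim_config(),
                                 method = c("fourier", "xcorr")) {
  method <- match.arg(method)
  traces <- record_at_elements(medium, target_rc, config, array)
  # reference water time of flight anchors the carrier phase to the
  # correct period (background speed = minimum speed in the medium)
  el <- element_positions(array, dim(medium$density),
                          medium$pixel_spacing_mm)
  d_m <- sqrt((el[, "row"] - target_rc[1L])^2 +
              (el[, "col"] - target_rc[2L])^2) *
         medium$pixel_spacing_mm / 1000
  ref <- d_m / min(medium$speed)
  tau <- arrival_delays(traces, method = method, ref_delays_s = ref)
  phase_vector(max(tau) - tau, array$f0_hz)
}
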