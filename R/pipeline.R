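#' Build a supervised dataset of phase-corrected simulations
#'
#' For every (skull, target) pair: computes time-reversal correction
#' delays, runs the corrected forward simulation, and stores the
#' normalized field (maximum exactly 1), its peak in Pa, the phase
#' targets as period fractions, and the input canvas normalized by the
#' corpus-wide maximum HU. Splits are assigned per skull so no skull
#' appears in more than one split.
#'
#' @param slices List of [skull_slice()] phantoms (one grid, matching
#'   the simulation window).
#' @param targets A [make_target_grid()] or a matrix of (row, col)
#'   targets applied to every skull.
#' @param array An [array_spec()].
#' @param config A [sim_config()] matching the slice grids.
#' @param waveguides_enabled Draw waveguides on the canvases?
#' @param split_fracs Named fractions for the per-skull train/val/test
#'   split.
#' @param seed Seed for the split assignment.
#' @return Object of class `tus_dataset`: `records` (list), and
#'   `dataset_max_hu`. Each record holds `canvas`, `normalized_field`,
#'   `absolute_peak_pa`, `phase_vector`, `phase_frac`, `skull_id`,
#'   `target_rc`, `split_tag`.
#' @export
build_dataset <- function(slices, targets, array = reduced_array_spec(),
                          config = reduced_sim_config(),
                          waveguides_enabled = TRUE,
                          split_fracs = c(train = 0.7, val = 0.15,
                                          test = 0.15),
                          seed = 1L) {
  if (!length(slices)) stop("phantom corpus is empty", call. = FALSE)
  tg <- if (inherits(targets, "target_grid")) targets$points else targets
  dataset_max_hu <- max(vapply(slices, function(s) max(s$hu_grid),
                               numeric(1L)))
  n_sk <- length(slices)
  split_tag <- with_seed(seed, {
    tags <- rep(names(split_fracs),
                times = diff(round(cumsum(c(0, split_fracs)) * n_sk)))
    if (length(tags) < n_sk)
      tags <- c(tags, rep(names(split_fracs)[1L], n_sk - length(tags)))
    sample(tags)
  })
  records <- list()
  n_failed <- 0L
  for (si in seq_along(slices)) {
    sl <- slices[[si]]
    med <- map_hu_to_medium(sl)
    for (ti in seq_len(nrow(tg))) {
      rc <- tg[ti, ]
      rec <- tryCatch({
        pv <- time_reversal_phases(med, array, rc, config)
        pf <- simulate_forward(med, array, pv, config)
        cv <- build_canvas(sl, array, rc, dataset_max_hu,
                           waveguides_enabled)
        list(canvas = cv,
             normalized_field = pf$normalized,
             absolute_peak_pa = pf$peak_pa,
             phase_vector = pv,
             phase_frac = phase_fractions(pv),
             skull_id = si,
             target_rc = as.integer(rc),
             split_tag = split_tag[si])
      }, error = function(e) e)
      if (inherits(rec, "error")) {
        n_failed <- n_failed + 1L
        message(sprintf("skipping skull %d target %d: %s", si, ti,
                        conditionMessage(rec)))
      } else {
        records[[length(records) + 1L]] <- rec
      }
    }
  }
  structure(list(records = records, dataset_max_hu = dataset_max_hu,
                 n_failed = n_failed, array = array, config = config,
                 config_digest = weights_digest(list(array, config,
                                                     split_fracs, seed))),
            class = "tus_dataset")
}

#' @export
print.tus_dataset <- function(x, ...) {
  tags <- vapply(x$records, function(r) r$split_tag, character(1L))
  cat(sprintf("<tus_dataset> %d records (%s), %d failed, max HU %.0f\n",
              length(x$records),
              paste(sprintf("%s=%d", names(table(tags)), table(tags)),
                    collapse = ", "),
              x$n_failed, x$dataset_max_hu))
  invisible(x)
}

#' Transcranial evaluation region of a scene
#'
#' The brain region below the skull, clear of the absorbing boundary
#' layer: rows from a margin below the deepest skull row down to the
#' PML, columns between the PMLs. At desk scale the near-array
#' reverberation between transducer and outer table can exceed the
#' focal amplitude, so focal metrics are evaluated on this region.
#'
#' @param skull_mask Binary skull mask of the scene.
#' @param config The [sim_config()] used (for the PML width).
#' @param margin_px Rows of clearance below the deepest skull row.
#' @return List with integer vectors `rows` and `cols`.
#' @export
brain_region <- function(skull_mask, config, margin_px = 4L) {
  n <- nrow(skull_mask)
  bottom <- if (any(skull_mask > 0)) max(which(rowSums(skull_mask) > 0))
            else 0L
  rows <- (bottom + margin_px + 1L):(n - config$pml_px - 2L)
  cols <- (config$pml_px + 2L):(n - config$pml_px - 2L)
  list(rows = rows, cols = cols)
}

#' Crop a pressure field to an evaluation region
#'
#' @param pf A [pressure_field()].
#' @param region A [brain_region()] result.
#' @return A [pressure_field()] over the cropped window; the attribute
#'   `offset_rc` maps cropped (row, col) back to the parent grid.
#' @export
crop_pressure_field <- function(pf, region) {
  out <- pressure_field(pf$field[region$rows, region$cols, drop = FALSE],
                        pf$pixel_spacing_mm)
  attr(out, "offset_rc") <- c(region$rows[1L] - 1L, region$cols[1L] - 1L)
  out
}

# Candidate correction delays for one benchmark method.
method_phases <- function(method, medium, array, target_rc, config,
                          model = NULL, slice = NULL, dataset_max_hu = NULL) {
  switch(method,
    none = phase_vector(rep(0, array$n_elements), array$f0_hz),
    ray = ray_trace_phases(medium, array, target_rc),
    tr = time_reversal_phases(medium, array, target_rc, config),
    surrogate = {
      if (is.null(model)) stop("surrogate method needs a model")
      cv <- build_canvas(slice, array, target_rc, dataset_max_hu)
      fr <- predict_tusnet(model, cv)$phase_frac
      phase_vector(fr / array$f0_hz, array$f0_hz)
    },
    stop("unknown method: ", method))
}

#' Benchmark correction methods against time-reversal ground truth
#'
#' For every (skull, target) pair the time-reversal-corrected field is
#' the ground truth; each candidate method's delays are re-simulated
#' through the same medium and scored with the full metric suite.
#'
#' @param slices List of [skull_slice()] phantoms.
#' @param targets Target matrix or [make_target_grid()].
#' @param methods Subset of `c("none", "ray", "tr", "surrogate")`.
#' @param array,config Simulation setup shared by all methods.
#' @param model Optional [tusnet()] for the surrogate method.
#' @param dataset_max_hu Canvas normalizer for the surrogate method.
#' @param use_ellipse Passed to [metrics_report()].
#' @param eval_region Evaluation window for the focal metrics; `NULL`
#'   derives the [brain_region()] of each skull.
#' @return Object of class `benchmark_table`: `per_sample` (data.frame
#'   with one row per method x sample) and `summary` (mean and sd per
#'   method x metric).
#' @export
benchmark <- function(slices, targets, methods = c("none", "ray", "tr"),
                      array = reduced_array_spec(),
                      config = reduced_sim_config(), model = NULL,
                      dataset_max_hu = NULL, use_ellipse = TRUE,
                      eval_region = NULL) {
  tg <- if (inherits(targets, "target_grid")) targets$points else targets
  rows <- list()
  for (si in seq_along(slices)) {
    sl <- slices[[si]]
    med <- map_hu_to_medium(sl)
    region <- if (is.null(eval_region)) brain_region(sl$skull_mask, config)
              else eval_region
    for (ti in seq_len(nrow(tg))) {
      rc <- tg[ti, ]
      rc_crop <- c(rc[1L] - region$rows[1L] + 1L,
                   rc[2L] - region$cols[1L] + 1L)
      gt_pv <- time_reversal_phases(med, array, rc, config)
      gt <- crop_pressure_field(
        simulate_forward(med, array, gt_pv, config), region)
      for (mth in methods) {
        pv <- if (mth == "tr") gt_pv
              else method_phases(mth, med, array, rc, config, model, sl,
                                 dataset_max_hu)
        pf <- if (mth == "tr") gt
              else crop_pressure_field(
                simulate_forward(med, array, pv, config), region)
        rep_ <- metrics_report(pf, gt, gt_focus_rc = rc_crop,
                               use_ellipse = use_ellipse)
        rep_$focal_pressure_at_target_pa <- pf$field[rc_crop[1L],
                                                     rc_crop[2L]]
        rep_$method <- mth
        rep_$skull_id <- si
        rep_$target_id <- ti
        rows[[length(rows) + 1L]] <- rep_
      }
    }
  }
  per_sample <- do.call(rbind, rows)
  metric_cols <- setdiff(names(per_sample),
                         c("method", "skull_id", "target_id"))
  summ <- do.call(rbind, lapply(split(per_sample, per_sample$method),
    function(d) {
      data.frame(method = d$method[1L],
                 metric = metric_cols,
                 mean = vapply(metric_cols, function(m) mean(d[[m]]),
                               numeric(1L)),
                 sd = vapply(metric_cols, function(m) stats::sd(d[[m]]),
                             numeric(1L)),
                 row.names = NULL)
    }))
  structure(list(per_sample = per_sample, summary = summ,
                 config_digest = weights_digest(list(array, config,
                                                     methods))),
            class = "benchmark_table")
}

#' Surrogate error versus distance from the training-target lattice
#'
#' Samples random targets below the skull, measures each one's distance
#' to the nearest training-grid point, evaluates the chosen correction
#' method against time-reversal ground truth, and summarizes the error
#' metrics in radial annuli. Reports the Spearman correlation between
#' annulus center and mean focal pressure error.
#'
#' @param slices List of phantoms.
#' @param train_grid A [make_target_grid()]: the training lattice.
#' @param n_random_targets Random targets per skull.
#' @param method `"surrogate"` (requires `model`) or `"ray"`.
#' @param model Optional [tusnet()].
#' @param array,config Simulation setup.
#' @param dataset_max_hu Canvas normalizer for the surrogate.
#' @param bin_edges_mm Annulus edges in mm (default 5 annuli to the
#'   half-lattice pitch and beyond).
#' @param margin_px Keep random targets this far from the grid border.
#' @param seed Seed for target sampling.
#' @return List with `per_target` (data.frame), `by_bin` (data.frame of
#'   per-annulus means), and `spearman_rho`.
#' @export
radial_error_analysis <- function(slices, train_grid, n_random_targets = 10L,
                                  method = c("ray", "surrogate"),
                                  model = NULL,
                                  array = reduced_array_spec(),
                                  config = reduced_sim_config(),
                                  dataset_max_hu = NULL,
                                  bin_edges_mm = NULL, margin_px = 12L,
                                  seed = 1L) {
  method <- match.arg(method)
  pts <- train_grid$points
  if (is.null(bin_edges_mm))
    bin_edges_mm <- seq(0, train_grid$pitch_mm, length.out = 6L)
  rows <- list()
  with_seed(seed, {
    for (si in seq_along(slices)) {
      sl <- slices[[si]]
      med <- map_hu_to_medium(sl)
      sp <- sl$pixel_spacing_mm
      n <- nrow(sl$hu_grid)
      skull_bottom <- max(which(rowSums(sl$skull_mask) > 0), 1L)
      region <- brain_region(sl$skull_mask, config)
      lo_r <- max(min(pts[, 1L]), skull_bottom + margin_px,
                  region$rows[1L])
      hi_r <- min(max(pts[, 1L]) + 2L, n - margin_px,
                  region$rows[length(region$rows)])
      lo_c <- max(min(pts[, 2L]) - 2L, margin_px, region$cols[1L])
      hi_c <- min(max(pts[, 2L]) + 2L, n - margin_px,
                  region$cols[length(region$cols)])
      if (hi_r < lo_r || hi_c < lo_c)
        stop("no admissible random-target region below the skull",
             call. = FALSE)
      for (k in seq_len(n_random_targets)) {
        rc <- c(sample(lo_r:hi_r, 1L), sample(lo_c:hi_c, 1L))
        d_mm <- min(sqrt((pts[, 1L] - rc[1L])^2 +
                         (pts[, 2L] - rc[2L])^2)) * sp
        rc_crop <- c(rc[1L] - region$rows[1L] + 1L,
                     rc[2L] - region$cols[1L] + 1L)
        gt_pv <- time_reversal_phases(med, array, rc, config)
        gt <- crop_pressure_field(
          simulate_forward(med, array, gt_pv, config), region)
        pv <- method_phases(method, med, array, rc, config, model, sl,
                            dataset_max_hu)
        pf <- crop_pressure_field(
          simulate_forward(med, array, pv, config), region)
        rep_ <- metrics_report(pf, gt, gt_focus_rc = rc_crop)
        rep_$dist_mm <- d_mm
        rep_$skull_id <- si
        rows[[length(rows) + 1L]] <- rep_
      }
    }
  })
  per_target <- do.call(rbind, rows)
  bin <- cut(per_target$dist_mm, breaks = c(bin_edges_mm, Inf),
             include.lowest = TRUE, right = FALSE)
  per_target$bin <- bin
  metric_cols <- setdiff(names(per_target), c("bin", "skull_id"))
  by_bin <- do.call(rbind, lapply(levels(bin), function(b) {
    d <- per_target[per_target$bin == b, , drop = FALSE]
    if (!nrow(d)) return(NULL)
    out <- data.frame(bin = b, n = nrow(d))
    for (m in metric_cols) out[[paste0("mean_", m)]] <- mean(d[[m]])
    out
  }))
  rho <- if (nrow(per_target) >= 3L)
    suppressWarnings(stats::cor(per_target$dist_mm,
                                per_target$focal_pressure_error_pct,
                                method = "spearman"))
  else NA_real_
  list(per_target = per_target, by_bin = by_bin, spearman_rho = rho)
}
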