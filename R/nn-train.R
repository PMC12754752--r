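#' Adaptive field-loss weights
#'
#' Epoch schedule of the spatial weighting in the field loss: the skull
#' region (rows above the split) carries weight `lambda_skull(t) = 0.5`
#' for epochs `t < 5` and `0.5^(t-4)` for `t >= 5` (1-based epochs); the
#' focal region carries `1 - lambda_skull(t)`, so the emphasis shifts
#' from the whole window toward the focal region as training proceeds.
#'
#' @param epoch 1-based epoch index.
#' @return List with `skull` and `focus` weights (they sum to 1).
#' @export
adaptive_loss_weights <- function(epoch) {
  if (epoch < 1) stop("`epoch` is 1-based", call. = FALSE)
  skull <- if (epoch < 5) 0.5 else 0.5^(epoch - 4)
  list(skull = skull, focus = 1 - skull)
}

#' Weighted mean-squared field loss
#'
#' Mean over all pixels of `W * (pred - gt)^2` where `W` is
#' `lambda_skull(epoch)` on rows `1..split_row` and
#' `lambda_focus(epoch)` below.
#'
#' @param pred,gt `(B, H, W)` arrays (or matrices) of normalized fields.
#' @param epoch 1-based epoch index.
#' @param split_row Last row of the skull-weighted region.
#' @return List with `loss` (scalar) and `grad` (array like `pred`).
#' @export
loss_field <- function(pred, gt, epoch, split_row) {
  pred <- as_batch(pred); gt <- as_batch(gt)
  if (!identical(dim(pred), dim(gt))) stop("shape mismatch", call. = FALSE)
  w <- adaptive_loss_weights(epoch)
  H <- dim(pred)[2L]
  wrow <- ifelse(seq_len(H) <= split_row, w$skull, w$focus)
  W <- array(rep(wrow, each = dim(pred)[1L]), dim(pred))
  diff <- pred - gt
  list(loss = mean(W * diff^2),
       grad = 2 * W * diff / length(diff))
}

#' L1 loss on the absolute peak pressure
#' @param pred,gt Numeric vectors (Pa).
#' @return List with `loss` (mean absolute error) and `grad`.
#' @export
loss_abs <- function(pred, gt) {
  d <- pred - gt
  list(loss = mean(abs(d)), grad = sign(d) / length(d))
}

#' Mean L1 loss on the phase vector
#' @param pred,gt `(B, K)` matrices of period-fraction delays.
#' @return List with `loss` and `grad`.
#' @export
loss_phase <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt))) stop("shape mismatch", call. = FALSE)
  d <- pred - gt
  list(loss = mean(abs(d)), grad = sign(d) / length(d))
}

## ---- Adam optimizer over layer environments ----

adam_step <- function(layers, lr, t, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  for (l in layers) {
    if (isTRUE(l$frozen) || is.null(l$params) || !length(l$params)) next
    if (is.null(l$adam_m)) {
      l$adam_m <- lapply(l$grads, function(g) g * 0)
      l$adam_v <- lapply(l$grads, function(g) g * 0)
    }
    for (nm in names(l$params)) {
      g <- l$grads[[nm]]
      l$adam_m[[nm]] <- beta1 * l$adam_m[[nm]] + (1 - beta1) * g
      l$adam_v[[nm]] <- beta2 * l$adam_v[[nm]] + (1 - beta2) * g^2
      mhat <- l$adam_m[[nm]] / (1 - beta1^t)
      vhat <- l$adam_v[[nm]] / (1 - beta2^t)
      l$params[[nm]] <- l$params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  invisible(NULL)
}

#' Training configuration
#'
#' Adam with initial learning rate 2e-4 and a reduce-on-plateau schedule
#' (factor 0.1, patience 2 epochs, relative threshold 1e-3), mirrored
#' for all three stages. Stage 1 trains the encoder, decoder, and field
#' head on the weighted field loss; stages 2 and 3 train the phase and
#' absolute-pressure decoders with the encoder frozen.
#'
#' @param lr Initial learning rate.
#' @param batch_size Minibatch size.
#' @param epochs_field,epochs_phase,epochs_abs Epochs per stage.
#' @param plateau_factor,plateau_patience,plateau_threshold Learning-rate
#'   schedule parameters (relative improvement threshold).
#' @param early_stop_patience Stop a stage after this many epochs without
#'   improvement of the monitored loss (`Inf` disables).
#' @param restore_best Restore each stage's best-monitored-loss weights
#'   when the stage ends (checkpointed early stopping).
#' @param seed Seed controlling shuffling and dropout.
#' @return Object of class `train_config`.
#' @export
train_config <- function(lr = 2e-4, batch_size = 16L, epochs_field = 10L,
                         epochs_phase = 10L, epochs_abs = 10L,
                         plateau_factor = 0.1, plateau_patience = 2L,
                         plateau_threshold = 1e-3,
                         early_stop_patience = Inf, restore_best = TRUE,
                         seed = 1L) {
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs_field = as.integer(epochs_field),
                 epochs_phase = as.integer(epochs_phase),
                 epochs_abs = as.integer(epochs_abs),
                 plateau_factor = plateau_factor,
                 plateau_patience = as.integer(plateau_patience),
                 plateau_threshold = plateau_threshold,
                 early_stop_patience = early_stop_patience,
                 restore_best = isTRUE(restore_best),
                 seed = as.integer(seed)),
            class = "train_config")
}

# Coerce a dataset (as produced by build_dataset, or a plain list with
# $canvas/$field/$peak_pa/$phase arrays) to training tensors.
as_training_arrays <- function(dataset) {
  if (!is.null(dataset$canvas)) return(dataset)
  recs <- if (!is.null(dataset$records)) dataset$records else dataset
  N <- length(recs)
  H <- nrow(recs[[1L]]$canvas$image)
  K <- length(recs[[1L]]$phase_frac)
  canvas <- array(0, c(N, H, H)); field <- array(0, c(N, H, H))
  peak <- numeric(N); phase <- matrix(0, N, K)
  for (i in seq_len(N)) {
    canvas[i, , ] <- recs[[i]]$canvas$image
    field[i, , ] <- recs[[i]]$normalized_field
    peak[i] <- recs[[i]]$absolute_peak_pa
    phase[i, ] <- recs[[i]]$phase_frac
  }
  list(canvas = canvas, field = field, peak_pa = peak, phase = phase)
}

# Deep-copy / restore of everything an optimizer step mutates
# (parameters and batch-norm running statistics).
snapshot_layers <- function(layers) {
  lapply(layers, function(l)
    list(params = l$params,
         run_mean = if (!is.null(l$run_mean)) l$run_mean,
         run_var = if (!is.null(l$run_var)) l$run_var))
}

restore_layers <- function(layers, snap) {
  for (i in seq_along(layers)) {
    layers[[i]]$params <- snap[[i]]$params
    if (!is.null(snap[[i]]$run_mean)) {
      layers[[i]]$run_mean <- snap[[i]]$run_mean
      layers[[i]]$run_var <- snap[[i]]$run_var
    }
  }
  invisible(NULL)
}

# One training stage over `epochs`: `step_fn(idx, epoch)` returns the
# minibatch loss after accumulating gradients; `eval_fn(idx)` returns
# the validation loss. Implements plateau scheduling, early stopping,
# and best-checkpoint restoration on the monitored loss.
run_stage <- function(stage, n_train, val_idx, layers, step_fn, eval_fn,
                      epochs, config, history, adam_t0 = 0L) {
  lr <- config$lr
  best <- Inf; wait <- 0L; stop_wait <- 0L
  best_snap <- NULL
  adam_t <- adam_t0
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n_train)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    tr_loss <- 0
    for (bi in batches) {
      zero_grads(layers)
      tr_loss <- tr_loss + step_fn(bi, ep) * length(bi)
      adam_t <- adam_t + 1L
      adam_step(layers, lr, adam_t)
    }
    tr_loss <- tr_loss / n_train
    va_loss <- if (length(val_idx)) eval_fn(val_idx) else NA_real_
    monitored <- if (is.na(va_loss)) tr_loss else va_loss
    history[[length(history) + 1L]] <- data.frame(
      stage = stage, epoch = ep, train_loss = tr_loss,
      val_loss = va_loss, lr = lr)
    if (monitored < best) {
      if (config$restore_best) best_snap <- snapshot_layers(layers)
    }
    if (monitored < best * (1 - config$plateau_threshold)) {
      best <- monitored; wait <- 0L; stop_wait <- 0L
    } else {
      best <- min(best, monitored)
      wait <- wait + 1L; stop_wait <- stop_wait + 1L
      if (wait >= config$plateau_patience) {
        lr <- lr * config$plateau_factor
        wait <- 0L
      }
      if (stop_wait >= config$early_stop_patience) break
    }
  }
  if (config$restore_best && !is.null(best_snap))
    restore_layers(layers, best_snap)
  list(history = history, adam_t = adam_t)
}

#' Staged training of the surrogate
#'
#' Stage 1 trains encoder + decoder + field head on the adaptive
#' weighted MSE; stage 2 freezes the encoder and trains the phase
#' decoder on mean L1 over period fractions; stage 3 trains the
#' absolute-pressure decoder on L1, also with the encoder frozen.
#' Encoder immutability across stages 2-3 is verified by digesting the
#' encoder weights before and after.
#'
#' @param model A [tusnet()].
#' @param dataset Dataset from [build_dataset()] or a list of arrays
#'   (`canvas`, `field`, `peak_pa`, `phase`).
#' @param config A [train_config()].
#' @param val_idx Indices of held-out validation samples (may be empty).
#' @return List with the trained `model`, `history` (data.frame), and
#'   `encoder_digest` (before/after stages 2-3, identical by
#'   construction).
#' @export
train_tusnet <- function(model, dataset, config = train_config(),
                         val_idx = integer(0)) {
  da <- as_training_arrays(dataset)
  N <- dim(da$canvas)[1L]
  train_idx <- setdiff(seq_len(N), val_idx)
  history <- list()
  set.seed(config$seed)

  enc_l <- encoder_layers(model)
  # --- stage 1: field ---
  fl <- c(enc_l, field_layers(model))
  step_field <- function(bi, ep) {
    idx <- train_idx[bi]
    res <- forward_field(model, da$canvas[idx, , , drop = FALSE], train = TRUE)
    L <- loss_field(res$field, da$field[idx, , , drop = FALSE], ep,
                    model$split_row)
    backward_field(model, L$grad)
    L$loss
  }
  eval_field <- function(idx) {
    res <- forward_field(model, da$canvas[idx, , , drop = FALSE],
                         train = FALSE)
    # schedule-free monitoring: plain MSE
    mean((res$field - da$field[idx, , , drop = FALSE])^2)
  }
  st <- run_stage("field", length(train_idx), val_idx, fl, step_field,
                  eval_field, config$epochs_field, config, history)
  history <- st$history

  # --- freeze the encoder for stages 2-3 ---
  for (l in enc_l) l$frozen <- TRUE
  dig_before <- weights_digest(lapply(enc_l, function(l) l$params))

  pl <- phase_layers(model)
  step_phase <- function(bi, ep) {
    idx <- train_idx[bi]
    res <- forward_field(model, da$canvas[idx, , , drop = FALSE],
                         train = FALSE)
    ph <- forward_phase(model, res$first_cell_output, train = TRUE)
    L <- loss_phase(ph, da$phase[idx, , drop = FALSE])
    backward_phase(model, L$grad)
    L$loss
  }
  eval_phase <- function(idx) {
    res <- forward_field(model, da$canvas[idx, , , drop = FALSE],
                         train = FALSE)
    ph <- forward_phase(model, res$first_cell_output, train = FALSE)
    loss_phase(ph, da$phase[idx, , drop = FALSE])$loss
  }
  st <- run_stage("phase", length(train_idx), val_idx, pl, step_phase,
                  eval_phase, config$epochs_phase, config, history)
  history <- st$history

  al <- abs_layers(model)
  step_abs <- function(bi, ep) {
    idx <- train_idx[bi]
    res <- forward_field(model, da$canvas[idx, , , drop = FALSE],
                         train = FALSE)
    ap <- forward_abs_pressure(model, res$reduced_embedding, train = TRUE)
    L <- loss_abs(ap / model$pressure_scale,
                  da$peak_pa[idx] / model$pressure_scale)
    backward_abs_pressure(model, L$grad / model$pressure_scale)
    L$loss
  }
  eval_abs <- function(idx) {
    res <- forward_field(model, da$canvas[idx, , , drop = FALSE],
                         train = FALSE)
    ap <- forward_abs_pressure(model, res$reduced_embedding, train = FALSE)
    loss_abs(ap / model$pressure_scale,
             da$peak_pa[idx] / model$pressure_scale)$loss
  }
  st <- run_stage("abs", length(train_idx), val_idx, al, step_abs,
                  eval_abs, config$epochs_abs, config, history)
  history <- st$history

  dig_after <- weights_digest(lapply(enc_l, function(l) l$params))
  list(model = model,
       history = do.call(rbind, history),
       encoder_digest = c(before = dig_before, after = dig_after))
}

#' Transfer weights between surrogates of different LSTM depth
#'
#' Copies every parameter whose shape matches from `src` into `dst`
#' (e.g. a converged 1-layer-LSTM model initializing the first LSTM
#' layer of a 4-layer model); parameters without a shape match keep
#' their fresh initialization.
#'
#' @param src,dst [tusnet()] models with identical grid and head sizes.
#' @return `dst`, modified in place (and invisibly returned).
#' @export
transfer_weights <- function(src, dst) {
  ls <- all_layers(src); ld <- all_layers(dst)
  if (length(ls) != length(ld))
    stop("models have different layer structure", call. = FALSE)
  n_copied <- 0L
  for (i in seq_along(ls)) {
    for (nm in names(ls[[i]]$params)) {
      ps <- ls[[i]]$params[[nm]]
      pd <- ld[[i]]$params[[nm]]
      if (!is.null(pd) &&
          identical(dim(as.array(pd)), dim(as.array(ps))) &&
          length(pd) == length(ps)) {
        ld[[i]]$params[[nm]] <- ps
        n_copied <- n_copied + 1L
      }
    }
  }
  dst$transferred <- n_copied
  invisible(dst)
}
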