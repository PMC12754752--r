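# The LSTM-Conv cell: four directional LSTM scans concatenated along the
# channel axis, an 8-channel same-size convolution, a 16-channel
# convolution that down- or up-samples by 2, and a 1x1 pooling
# convolution back to one channel, each followed by batch normalization
# and ReLU; dropout (rate 0.2) follows the 16-channel stage.

DIRECTIONS <- c("tb", "bt", "lr", "rl")

new_lstm_conv_cell <- function(S, mode = c("down", "up"),
                               n_lstm_layers = 1L, dropout = 0.2,
                               tie_dirs = FALSE) {
  mode <- match.arg(mode)
  e <- new.env(parent = emptyenv())
  e$S <- as.integer(S)
  e$mode <- mode
  dirs <- list()
  dirs[[1L]] <- new_lstm_scan(S, "tb", n_lstm_layers)
  for (d in 2:4)
    dirs[[d]] <- new_lstm_scan(S, DIRECTIONS[d], n_lstm_layers,
                               share = if (tie_dirs) dirs[[1L]] else NULL)
  e$dirs <- dirs
  e$conv1 <- new_conv(3L, 4L, 8L, "same"); e$bn1 <- new_bn(8L)
  e$relu1 <- new_relu()
  e$conv2 <- new_conv(3L, 8L, 16L, mode); e$bn2 <- new_bn(16L)
  e$relu2 <- new_relu()
  e$drop <- new_dropout(dropout)
  e$conv3 <- new_conv(1L, 16L, 1L, "same"); e$bn3 <- new_bn(1L)
  e$relu3 <- new_relu()
  class(e) <- "lstm_conv_cell"
  e
}

# Layer environments holding parameters (unique: tied scans appear once).
cell_layers <- function(cell) {
  scans <- Filter(function(d) is.null(d$shared), cell$dirs)
  c(scans, list(cell$conv1, cell$bn1, cell$conv2, cell$bn2,
                cell$conv3, cell$bn3))
}

# Linear map taking a width-S_old state vector to width S_new
# (average pooling when shrinking, nearest repetition when growing);
# identity is returned as NULL.
resize_P <- function(S_old, S_new) {
  if (S_old == S_new) return(NULL)
  P <- matrix(0, S_old, S_new)
  if (S_old > S_new) {
    f <- S_old %/% S_new
    P[cbind(seq_len(S_old), rep(seq_len(S_new), each = f))] <- 1 / f
  } else {
    f <- S_new %/% S_old
    P[cbind(rep(seq_len(S_old), each = f), seq_len(S_new))] <- 1
  }
  P
}

# Forward pass. `state` is the previous cell's per-direction final
# (h, c), resized to this cell's width; gradients flow back through the
# resize map in cell_backward.
cell_forward <- function(cell, x, state = NULL, train = FALSE) {
  B <- dim(x)[1L]; S <- cell$S
  cell$had_state <- !is.null(state)
  cell$state_P <- if (!is.null(state)) resize_P(ncol(state[[1L]]$h), S)
                  else NULL
  ys <- array(0, c(B, S, S, 4L))
  for (d in 1:4) {
    dir <- cell$dirs[[d]]
    if (!is.null(state)) {
      P <- cell$state_P
      dir$h0 <- if (is.null(P)) state[[d]]$h else state[[d]]$h %*% P
      dir$c0 <- if (is.null(P)) state[[d]]$c else state[[d]]$c %*% P
    } else { dir$h0 <- NULL; dir$c0 <- NULL }
    ys[, , , d] <- nn_forward(dir, x, train)
  }
  z <- nn_forward(cell$conv1, ys, train)
  z <- nn_forward(cell$bn1, z, train)
  z <- nn_forward(cell$relu1, z, train)
  z <- nn_forward(cell$conv2, z, train)
  z <- nn_forward(cell$bn2, z, train)
  z <- nn_forward(cell$relu2, z, train)
  z <- nn_forward(cell$drop, z, train)
  z <- nn_forward(cell$conv3, z, train)
  z <- nn_forward(cell$bn3, z, train)
  z <- nn_forward(cell$relu3, z, train)
  So <- dim(z)[2L]
  st <- lapply(cell$dirs, function(d) list(h = d$final_h, c = d$final_c))
  list(y = array(z, c(B, So, So)), state = st)
}

# Backward pass. `dstate` optionally carries the loss gradient w.r.t.
# this cell's handed-off final states (from the consuming cell).
# Returns list(dx, dstate): `dstate` is the gradient w.r.t. the
# previous cell's final states (through the resize map), or NULL if no
# state was handed in.
cell_backward <- function(cell, dy, dstate = NULL) {
  B <- dim(dy)[1L]; So <- dim(dy)[2L]
  for (d in 1:4) {
    cell$dirs[[d]]$dfinal_h <- if (is.null(dstate)) NULL else dstate[[d]]$h
    cell$dirs[[d]]$dfinal_c <- if (is.null(dstate)) NULL else dstate[[d]]$c
  }
  dz <- array(dy, c(B, So, So, 1L))
  dz <- nn_backward(cell$relu3, dz)
  dz <- nn_backward(cell$bn3, dz)
  dz <- nn_backward(cell$conv3, dz)
  dz <- nn_backward(cell$drop, dz)
  dz <- nn_backward(cell$relu2, dz)
  dz <- nn_backward(cell$bn2, dz)
  dz <- nn_backward(cell$conv2, dz)
  dz <- nn_backward(cell$relu1, dz)
  dz <- nn_backward(cell$bn1, dz)
  dcat <- nn_backward(cell$conv1, dz)
  S <- cell$S
  dx <- array(0, c(B, S, S))
  for (d in 1:4)
    dx <- dx + nn_backward(cell$dirs[[d]],
                           array(dcat[, , , d, drop = FALSE], c(B, S, S)))
  dstate_prev <- NULL
  if (isTRUE(cell$had_state)) {
    P <- cell$state_P
    dstate_prev <- lapply(cell$dirs, function(dir) {
      if (is.null(P)) list(h = dir$dh0, c = dir$dc0)
      else list(h = dir$dh0 %*% t(P), c = dir$dc0 %*% t(P))
    })
  }
  list(dx = dx, dstate = dstate_prev)
}
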