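# Minimal reverse-mode neural-network layers.
#
# Layers are environments holding `params` and `grads` (named lists of
# arrays), a `frozen` flag, and per-call caches. `nn_forward()` runs the
# layer and caches what the backward pass needs; `nn_backward()` returns
# the input gradient and accumulates parameter gradients. All activations
# for image data are 4D arrays (batch, height, width, channel).

new_layer <- function(class, params, extra = list()) {
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$grads <- lapply(params, function(p) array(0, dim(as.array(p))))
  e$frozen <- FALSE
  for (nm in names(extra)) assign(nm, extra[[nm]], envir = e)
  class(e) <- c(class, "nn_layer")
  e
}

nn_forward <- function(layer, x, train = FALSE) UseMethod("nn_forward")
nn_backward <- function(layer, dy) UseMethod("nn_backward")

zero_grads <- function(layers) {
  for (l in layers) l$grads <- lapply(l$grads, function(g) g * 0)
  invisible(NULL)
}

runif_init <- function(dims, fan_in) {
  k <- 1 / sqrt(fan_in)
  array(stats::runif(prod(dims), -k, k), dims)
}

sigm <- function(x) 1 / (1 + exp(-x))

## ---- fully connected ----

new_fc <- function(d_in, d_out) {
  new_layer("nn_fc", list(W = runif_init(c(d_in, d_out), d_in),
                          b = numeric(d_out)))
}

#' @export
nn_forward.nn_fc <- function(layer, x, train = FALSE) {
  layer$x <- x
  sweep(x %*% layer$params$W, 2L, layer$params$b, "+")
}

#' @export
nn_backward.nn_fc <- function(layer, dy) {
  layer$grads$W <- layer$grads$W + crossprod(layer$x, dy)
  layer$grads$b <- layer$grads$b + colSums(dy)
  dy %*% t(layer$params$W)
}

## ---- elementwise activations ----

new_relu <- function() new_layer("nn_relu", list())
#' @export
nn_forward.nn_relu <- function(layer, x, train = FALSE) {
  layer$mask <- x > 0
  x * layer$mask
}
#' @export
nn_backward.nn_relu <- function(layer, dy) dy * layer$mask

new_sigmoid <- function() new_layer("nn_sigmoid", list())
#' @export
nn_forward.nn_sigmoid <- function(layer, x, train = FALSE) {
  layer$y <- sigm(x)
  layer$y
}
#' @export
nn_backward.nn_sigmoid <- function(layer, dy) dy * layer$y * (1 - layer$y)

new_dropout <- function(rate = 0.2) new_layer("nn_dropout", list(),
                                              list(rate = rate))
#' @export
nn_forward.nn_dropout <- function(layer, x, train = FALSE) {
  if (!train || layer$rate <= 0) { layer$mask <- NULL; return(x) }
  keep <- 1 - layer$rate
  layer$mask <- array(stats::rbinom(length(x), 1L, keep), dim(x)) / keep
  x * layer$mask
}
#' @export
nn_backward.nn_dropout <- function(layer, dy) {
  if (is.null(layer$mask)) dy else dy * layer$mask
}

## ---- batch normalization (per channel of a 4D activation) ----

new_bn <- function(channels, momentum = 0.1, eps = 1e-5) {
  new_layer("nn_bn",
            list(gamma = rep(1, channels), beta = rep(0, channels)),
            list(momentum = momentum, eps = eps,
                 run_mean = rep(0, channels), run_var = rep(1, channels)))
}

#' @export
nn_forward.nn_bn <- function(layer, x, train = FALSE) {
  d <- dim(x); C <- d[length(d)]
  xm <- matrix(x, ncol = C)
  if (train) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2L, mu)
    va <- colMeans(xc^2)
    layer$run_mean <- (1 - layer$momentum) * layer$run_mean + layer$momentum * mu
    layer$run_var <- (1 - layer$momentum) * layer$run_var + layer$momentum * va
  } else {
    mu <- layer$run_mean
    xc <- sweep(xm, 2L, mu)
    va <- layer$run_var
  }
  ivar <- 1 / sqrt(va + layer$eps)
  xhat <- sweep(xc, 2L, ivar, "*")
  layer$xhat <- xhat; layer$ivar <- ivar; layer$train <- train
  ym <- sweep(sweep(xhat, 2L, layer$params$gamma, "*"), 2L,
              layer$params$beta, "+")
  array(ym, d)
}

#' @export
nn_backward.nn_bn <- function(layer, dy) {
  d <- dim(dy); C <- d[length(d)]
  dym <- matrix(dy, ncol = C)
  layer$grads$gamma <- layer$grads$gamma + colSums(dym * layer$xhat)
  layer$grads$beta <- layer$grads$beta + colSums(dym)
  if (!layer$train) {
    dxm <- sweep(dym, 2L, layer$params$gamma * layer$ivar, "*")
    return(array(dxm, d))
  }
  N <- nrow(dym)
  s1 <- colSums(dym)
  s2 <- colSums(dym * layer$xhat)
  dxm <- sweep(dym, 2L, s1 / N) - sweep(layer$xhat, 2L, s2 / N, "*")
  dxm <- sweep(dxm, 2L, layer$params$gamma * layer$ivar, "*")
  array(dxm, d)
}

## ---- 2D convolution (same / stride-2 down / nearest-up then conv) ----

upsample2 <- function(x) {
  d <- dim(x)
  x[, rep(seq_len(d[2L]), each = 2L), rep(seq_len(d[3L]), each = 2L), ,
    drop = FALSE]
}

downsum2 <- function(dx) {
  d <- dim(dx)
  i1 <- seq(1L, d[2L], 2L); i2 <- i1 + 1L
  j1 <- seq(1L, d[3L], 2L); j2 <- j1 + 1L
  dx[, i1, j1, , drop = FALSE] + dx[, i2, j1, , drop = FALSE] +
    dx[, i1, j2, , drop = FALSE] + dx[, i2, j2, , drop = FALSE]
}

pad_hw <- function(x, p) {
  if (p == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1L], d[2L] + 2L * p, d[3L] + 2L * p, d[4L]))
  out[, p + seq_len(d[2L]), p + seq_len(d[3L]), ] <- x
  out
}

# mode: "same" (stride 1), "down" (stride 2), "up" (nearest x2 then conv)
new_conv <- function(k, c_in, c_out, mode = "same") {
  new_layer("nn_conv",
            list(W = runif_init(c(k, k, c_in, c_out), k * k * c_in),
                 b = numeric(c_out)),
            list(k = k, mode = mode, pad = (k - 1L) %/% 2L))
}

#' @export
nn_forward.nn_conv <- function(layer, x, train = FALSE) {
  if (layer$mode == "up") x <- upsample2(x)
  stride <- if (layer$mode == "down") 2L else 1L
  d <- dim(x); B <- d[1L]; H <- d[2L]; Wd <- d[3L]; Cin <- d[4L]
  k <- layer$k; p <- layer$pad
  Ho <- H %/% stride; Wo <- Wd %/% stride
  xp <- pad_hw(x, p)
  layer$xp <- xp; layer$dims <- c(B, Ho, Wo, H, Wd)
  rows0 <- seq(1L, by = stride, length.out = Ho)
  cols0 <- seq(1L, by = stride, length.out = Wo)
  Cout <- length(layer$params$b)
  Ym <- matrix(rep(layer$params$b, each = B * Ho * Wo), ncol = Cout)
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    xs <- xp[, rows0 + di - 1L, cols0 + dj - 1L, , drop = FALSE]
    Ym <- Ym + matrix(xs, ncol = Cin) %*%
      matrix(layer$params$W[di, dj, , ], Cin, Cout)
  }
  array(Ym, c(B, Ho, Wo, Cout))
}

#' @export
nn_backward.nn_conv <- function(layer, dy) {
  stride <- if (layer$mode == "down") 2L else 1L
  k <- layer$k; p <- layer$pad
  B <- layer$dims[1L]; Ho <- layer$dims[2L]; Wo <- layer$dims[3L]
  H <- layer$dims[4L]; Wd <- layer$dims[5L]
  Cin <- dim(layer$xp)[4L]; Cout <- dim(dy)[4L]
  dym <- matrix(dy, ncol = Cout)
  layer$grads$b <- layer$grads$b + colSums(dym)
  rows0 <- seq(1L, by = stride, length.out = Ho)
  cols0 <- seq(1L, by = stride, length.out = Wo)
  dxp <- array(0, dim(layer$xp))
  for (di in seq_len(k)) for (dj in seq_len(k)) {
    rs <- rows0 + di - 1L; cs <- cols0 + dj - 1L
    xs <- matrix(layer$xp[, rs, cs, , drop = FALSE], ncol = Cin)
    layer$grads$W[di, dj, , ] <- layer$grads$W[di, dj, , ] +
      crossprod(xs, dym)
    dxs <- dym %*% t(matrix(layer$params$W[di, dj, , ], Cin, Cout))
    dxp[, rs, cs, ] <- dxp[, rs, cs, , drop = FALSE] +
      array(dxs, c(B, Ho, Wo, Cin))
  }
  dx <- if (p > 0L)
    dxp[, p + seq_len(H), p + seq_len(Wd), , drop = FALSE]
  else dxp
  if (layer$mode == "up") dx <- downsum2(dx)
  dx
}

## ---- directional LSTM scan ----

# Scans a square 1-channel image (B, S, S) with a (possibly stacked)
# LSTM along one of four directions; the orthogonal axis is the feature
# axis, the hidden size equals the input size S, and the full hidden
# sequence forms the output map (same shape as the input).
#
# `share` optionally points at another scan layer whose parameters (and
# gradients) are reused: the weight-tying contract for reverse scans.
new_lstm_scan <- function(S, direction, n_layers = 1L, share = NULL) {
  params <- list()
  if (is.null(share)) {
    for (l in seq_len(n_layers)) {
      params[[paste0("Wx", l)]] <- runif_init(c(S, 4L * S), S)
      params[[paste0("Wh", l)]] <- runif_init(c(S, 4L * S), S)
      b <- numeric(4L * S)
      b[S + seq_len(S)] <- 1            # forget-gate bias
      params[[paste0("b", l)]] <- b
    }
  }
  e <- new_layer("nn_lstm_scan", params,
                 list(S = S, direction = direction, n_layers = n_layers,
                      shared = share))
  if (!is.null(share)) { e$params <- NULL; e$grads <- NULL }
  e
}

lstm_param_env <- function(layer) {
  if (is.null(layer$shared)) layer else layer$shared
}

# map (B,S,S) into scan order: time along dim 2, features along dim 3
scan_canon <- function(x, direction) {
  S <- dim(x)[2L]
  switch(direction,
         tb = x,
         bt = x[, S:1, , drop = FALSE],
         lr = aperm(x, c(1L, 3L, 2L)),
         rl = aperm(x, c(1L, 3L, 2L))[, S:1, , drop = FALSE])
}

scan_uncanon <- function(y, direction) {
  S <- dim(y)[2L]
  switch(direction,
         tb = y,
         bt = y[, S:1, , drop = FALSE],
         lr = aperm(y, c(1L, 3L, 2L)),
         rl = aperm(y[, S:1, , drop = FALSE], c(1L, 3L, 2L)))
}

#' @export
nn_forward.nn_lstm_scan <- function(layer, x, train = FALSE) {
  pe <- lstm_param_env(layer)
  S <- layer$S
  xc <- scan_canon(x, layer$direction)
  B <- dim(xc)[1L]
  h0 <- layer$h0; c0 <- layer$c0       # optional handed-in state (constant)
  caches <- vector("list", layer$n_layers)
  inp <- xc
  for (l in seq_len(layer$n_layers)) {
    Wx <- pe$params[[paste0("Wx", l)]]
    Wh <- pe$params[[paste0("Wh", l)]]
    b <- pe$params[[paste0("b", l)]]
    h <- if (l == 1L && !is.null(h0)) h0 else matrix(0, B, S)
    cs <- if (l == 1L && !is.null(c0)) c0 else matrix(0, B, S)
    G <- array(0, c(B, 4L * S, S))     # activated gates per step
    Cc <- array(0, c(B, S, S)); HC <- array(0, c(B, S, S))
    Hp <- array(0, c(B, S, S)); Cp <- array(0, c(B, S, S))
    Y <- array(0, c(B, S, S))
    for (t in seq_len(S)) {
      xt <- matrix(inp[, t, ], B, S)
      Hp[, , t] <- h; Cp[, , t] <- cs
      g <- xt %*% Wx + h %*% Wh
      g <- sweep(g, 2L, b, "+")
      i <- sigm(g[, seq_len(S), drop = FALSE])
      f <- sigm(g[, S + seq_len(S), drop = FALSE])
      gg <- tanh(g[, 2L * S + seq_len(S), drop = FALSE])
      o <- sigm(g[, 3L * S + seq_len(S), drop = FALSE])
      cs <- f * cs + i * gg
      hc <- tanh(cs)
      h <- o * hc
      G[, , t] <- cbind(i, f, gg, o)
      Cc[, , t] <- cs; HC[, , t] <- hc
      Y[, , t] <- h
    }
    caches[[l]] <- list(G = G, Cc = Cc, HC = HC, Hp = Hp, Cp = Cp,
                        inp = inp)
    Y <- aperm(Y, c(1L, 3L, 2L))       # back to (B, T, S)
    inp <- Y
  }
  layer$caches <- caches
  layer$B <- B
  layer$final_h <- h                   # top layer final states
  layer$final_c <- cs
  scan_uncanon(inp, layer$direction)
}

#' @export
nn_backward.nn_lstm_scan <- function(layer, dy) {
  pe <- lstm_param_env(layer)
  S <- layer$S; B <- layer$B
  dinp <- scan_canon(dy, layer$direction)
  for (l in rev(seq_len(layer$n_layers))) {
    ch <- layer$caches[[l]]
    Wx <- pe$params[[paste0("Wx", l)]]
    Wh <- pe$params[[paste0("Wh", l)]]
    dWx <- array(0, dim(Wx)); dWh <- array(0, dim(Wh)); db <- numeric(4L * S)
    dX <- array(0, c(B, S, S))
    # gradient injected into the final (handed-off) state of the top layer
    if (l == layer$n_layers && !is.null(layer$dfinal_h)) {
      dh_next <- layer$dfinal_h; dc_next <- layer$dfinal_c
    } else {
      dh_next <- matrix(0, B, S); dc_next <- matrix(0, B, S)
    }
    for (t in rev(seq_len(S))) {
      dh <- matrix(dinp[, t, ], B, S) + dh_next
      i <- matrix(ch$G[, seq_len(S), t], B, S)
      f <- matrix(ch$G[, S + seq_len(S), t], B, S)
      gg <- matrix(ch$G[, 2L * S + seq_len(S), t], B, S)
      o <- matrix(ch$G[, 3L * S + seq_len(S), t], B, S)
      hc <- matrix(ch$HC[, , t], B, S)
      cp <- matrix(ch$Cp[, , t], B, S)
      do_ <- dh * hc
      dc <- dh * o * (1 - hc^2) + dc_next
      di <- dc * gg; dgg <- dc * i; df <- dc * cp
      dc_next <- dc * f
      dg <- cbind(di * i * (1 - i), df * f * (1 - f),
                  dgg * (1 - gg^2), do_ * o * (1 - o))
      xt <- matrix(ch$inp[, t, ], B, S)
      hp <- matrix(ch$Hp[, , t], B, S)
      dWx <- dWx + crossprod(xt, dg)
      dWh <- dWh + crossprod(hp, dg)
      db <- db + colSums(dg)
      dX[, , t] <- dg %*% t(Wx)
      dh_next <- dg %*% t(Wh)
    }
    pe$grads[[paste0("Wx", l)]] <- pe$grads[[paste0("Wx", l)]] + dWx
    pe$grads[[paste0("Wh", l)]] <- pe$grads[[paste0("Wh", l)]] + dWh
    pe$grads[[paste0("b", l)]] <- pe$grads[[paste0("b", l)]] + db
    if (l == 1L) {                      # gradient w.r.t. the handed-in state
      layer$dh0 <- dh_next; layer$dc0 <- dc_next
    }
    dinp <- aperm(dX, c(1L, 3L, 2L))
  }
  layer$dfinal_h <- NULL; layer$dfinal_c <- NULL
  scan_uncanon(dinp, layer$direction)
}
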