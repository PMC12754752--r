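#' Multi-task LSTM-Conv surrogate network
#'
#' Builds the surrogate: a five-cell LSTM-Conv encoder that halves the
#' resolution at every cell, a symmetric five-cell decoder with
#' per-level skip connections (channel concatenation followed by a 1x1
#' convolution), a sigmoid-bounded field head producing the normalized
#' pressure field, a phase decoder (three further LSTM-Conv cells on the
#' first encoder cell's output followed by fully connected layers and a
#' sigmoid, yielding per-element delays as fractions of a period), and
#' an absolute-pressure decoder (convolution plus fully connected layers
#' on the reduced embedding, yielding the peak pressure in Pa).
#'
#' @param grid_n Input raster size; must be divisible by 32.
#' @param n_elements Length of the phase output vector.
#' @param n_lstm_layers Stacked LSTM layers per directional scan (1 or 4).
#' @param dropout Dropout rate inside each cell.
#' @param tie_dirs Share scan weights across the four directions.
#' @param phase_hidden,abs_hidden Hidden widths of the two head MLPs.
#' @param pressure_scale Output scale of the absolute-pressure head, Pa.
#' @param split_row Last row (1-based) of the skull-weighted region in
#'   the field loss; defaults to `round(180/512 * grid_n)`.
#' @param seed Seed for weight initialization.
#' @return Object of class `tusnet`.
#' @export
tusnet <- function(grid_n = 128L, n_elements = 40L, n_lstm_layers = 1L,
                   dropout = 0.2, tie_dirs = FALSE, phase_hidden = 64L,
                   abs_hidden = 32L, pressure_scale = 1e6,
                   split_row = NULL, seed = 1L) {
  grid_n <- as.integer(grid_n)
  if (grid_n %% 32L != 0L)
    stop("`grid_n` must be divisible by 32", call. = FALSE)
  if (!n_lstm_layers %in% c(1L, 4L))
    stop("`n_lstm_layers` must be 1 or 4", call. = FALSE)
  m <- new.env(parent = emptyenv())
  m$grid_n <- grid_n
  m$n_elements <- as.integer(n_elements)
  m$n_lstm_layers <- as.integer(n_lstm_layers)
  m$pressure_scale <- pressure_scale
  m$split_row <- if (is.null(split_row)) round(180 / 512 * grid_n)
                 else as.integer(split_row)
  m$seed <- as.integer(seed)
  with_seed(seed, {
    s <- grid_n
    m$enc <- lapply(1:5, function(k) {
      cell <- new_lstm_conv_cell(s %/% 2L^(k - 1L), "down", n_lstm_layers,
                                 dropout, tie_dirs)
      cell
    })
    m$dec <- lapply(1:5, function(k)
      new_lstm_conv_cell(s %/% 2L^(6L - k), "up", n_lstm_layers,
                         dropout, tie_dirs))
    m$skip <- lapply(1:4, function(k) new_conv(1L, 2L, 1L, "same"))
    # 3x3 linear projection ahead of the bounded activation: a wider
    # head lets locally inactive (post-ReLU zero) pixels borrow from
    # neighbors, which a 1x1 head cannot
    m$field_head <- new_conv(3L, 1L, 1L, "same")
    m$field_act <- new_sigmoid()
    m$phase_cells <- lapply(1:3, function(k)
      new_lstm_conv_cell(s %/% 2L^k, "down", n_lstm_layers, dropout,
                         tie_dirs))
    phase_in <- (s %/% 16L)^2L
    m$phase_fc1 <- new_fc(phase_in, phase_hidden)
    m$phase_relu <- new_relu()
    m$phase_fc2 <- new_fc(phase_hidden, n_elements)
    m$phase_act <- new_sigmoid()
    m$abs_conv <- new_conv(3L, 1L, 8L, "same")
    m$abs_relu1 <- new_relu()
    m$abs_fc1 <- new_fc((s %/% 32L)^2L * 8L, abs_hidden)
    m$abs_relu2 <- new_relu()
    m$abs_fc2 <- new_fc(abs_hidden, 1L)
  })
  class(m) <- "tusnet"
  m
}

# Parameter-holding layer groups.
encoder_layers <- function(m) unlist(lapply(m$enc, cell_layers))
field_layers <- function(m)
  c(unlist(lapply(m$dec, cell_layers)), m$skip,
    list(m$field_head))
phase_layers <- function(m)
  c(unlist(lapply(m$phase_cells, cell_layers)),
    list(m$phase_fc1, m$phase_fc2))
abs_layers <- function(m)
  list(m$abs_conv, m$abs_fc1, m$abs_fc2)
all_layers <- function(m)
  c(encoder_layers(m), field_layers(m), phase_layers(m), abs_layers(m))

as_batch <- function(x) {
  if (length(dim(x)) == 2L) array(x, c(1L, dim(x))) else x
}

#' Forward pass of the field branch
#'
#' Runs the encoder and decoder on a batch of canvases and returns the
#' normalized pressure field in `[0, 1]`, the reduced embedding (the
#' bottleneck between encoder and decoder), and the first encoder
#' cell's output (the phase decoder's input).
#'
#' @param model A [tusnet()].
#' @param x Batch array `(B, grid_n, grid_n)` or a single matrix.
#' @param train Training mode (batch statistics, dropout active)?
#' @return List with `field` `(B, grid_n, grid_n)`, `reduced_embedding`,
#'   `first_cell_output`.
#' @export
forward_field <- function(model, x, train = FALSE) {
  x <- as_batch(x)
  enc_out <- vector("list", 5L)
  state <- NULL
  h <- x
  for (k in 1:5) {
    res <- cell_forward(model$enc[[k]], h, state, train)
    enc_out[[k]] <- res$y; state <- res$state; h <- res$y
  }
  re <- h
  for (k in 1:5) {
    res <- cell_forward(model$dec[[k]], h, state, train)
    state <- res$state
    h <- res$y
    if (k < 5L) {
      eo <- enc_out[[5L - k]]
      cat2 <- array(0, c(dim(h), 2L))
      cat2[, , , 1L] <- h; cat2[, , , 2L] <- eo
      h <- nn_forward(model$skip[[k]], cat2, train)
      h <- array(h, dim(h)[1:3])
    }
  }
  B <- dim(h)[1L]; S <- dim(h)[2L]
  z <- nn_forward(model$field_head, array(h, c(B, S, S, 1L)), train)
  y <- nn_forward(model$field_act, z, train)
  model$cache_enc_out <- enc_out
  list(field = array(y, c(B, S, S)),
       reduced_embedding = re,
       first_cell_output = enc_out[[1L]])
}

# Backward through head, decoder, skips, and encoder. `dfield` matches
# the field output. Inter-cell LSTM state hand-offs are
# gradient-truncated, so gradients flow only along the activation path.
backward_field <- function(model, dfield) {
  B <- dim(dfield)[1L]; S <- dim(dfield)[2L]
  g4 <- nn_backward(model$field_act, array(dfield, c(B, S, S, 1L)))
  g4 <- nn_backward(model$field_head, g4)
  g <- array(g4, c(B, S, S))
  denc <- lapply(model$cache_enc_out, function(e) array(0, dim(e)))
  dstate <- NULL                        # threads the state-chain gradient
  for (k in 5:1) {
    res <- cell_backward(model$dec[[k]], g, dstate)
    g <- res$dx; dstate <- res$dstate
    if (k > 1L) {
      # g sits at the output of skip merge (k-1), which consumed the
      # decoder cell (k-1) output and encoder output (6-k)
      dcat <- nn_backward(model$skip[[k - 1L]], array(g, c(dim(g), 1L)))
      g <- array(dcat[, , , 1L], dim(g))
      je <- 6L - k
      denc[[je]] <- denc[[je]] + array(dcat[, , , 2L], dim(denc[[je]]))
    }
  }
  denc[[5L]] <- denc[[5L]] + g          # gradient into the reduced embedding
  g_acc <- denc[[5L]]
  for (k in 5:1) {
    res <- cell_backward(model$enc[[k]], g_acc, dstate)
    dstate <- res$dstate
    if (k > 1L) g_acc <- denc[[k - 1L]] + res$dx
  }
  invisible(res$dx)
}

#' Forward pass of the phase decoder
#'
#' Maps the first encoder cell's output through three further LSTM-Conv
#' cells, flattens, and applies fully connected layers with a sigmoid,
#' yielding per-element correction delays as fractions of one carrier
#' period in `[0, 1)`.
#'
#' @param model A [tusnet()].
#' @param first_cell_output `(B, grid_n/2, grid_n/2)` array from
#'   [forward_field()].
#' @param train Training mode?
#' @return `(B, n_elements)` matrix.
#' @export
forward_phase <- function(model, first_cell_output, train = FALSE) {
  h <- as_batch(first_cell_output)
  state <- NULL
  for (k in 1:3) {
    res <- cell_forward(model$phase_cells[[k]], h, state, train)
    state <- res$state; h <- res$y
  }
  B <- dim(h)[1L]
  model$cache_phase_flat_dim <- dim(h)
  z <- matrix(h, B)                     # (B, (grid_n/16)^2)
  z <- nn_forward(model$phase_fc1, z, train)
  z <- nn_forward(model$phase_relu, z, train)
  z <- nn_forward(model$phase_fc2, z, train)
  nn_forward(model$phase_act, z, train)
}

backward_phase <- function(model, dout) {
  g <- nn_backward(model$phase_act, dout)
  g <- nn_backward(model$phase_fc2, g)
  g <- nn_backward(model$phase_relu, g)
  g <- nn_backward(model$phase_fc1, g)
  g <- array(g, model$cache_phase_flat_dim)
  dstate <- NULL
  for (k in 3:1) {
    res <- cell_backward(model$phase_cells[[k]], g, dstate)
    g <- res$dx; dstate <- res$dstate
  }
  invisible(g)
}

#' Forward pass of the absolute-pressure decoder
#'
#' Decodes the scalar peak pressure (Pa) from the reduced embedding via
#' a convolution and fully connected layers; the linear output is scaled
#' by `model$pressure_scale`.
#'
#' @param model A [tusnet()].
#' @param reduced_embedding `(B, grid_n/32, grid_n/32)` array.
#' @param train Training mode?
#' @return Numeric vector of length B, peak pressures in Pa.
#' @export
forward_abs_pressure <- function(model, reduced_embedding, train = FALSE) {
  h <- as_batch(reduced_embedding)
  B <- dim(h)[1L]; S <- dim(h)[2L]
  z <- nn_forward(model$abs_conv, array(h, c(B, S, S, 1L)), train)
  z <- nn_forward(model$abs_relu1, z, train)
  model$cache_abs_conv_dim <- dim(z)
  z <- matrix(z, B)
  z <- nn_forward(model$abs_fc1, z, train)
  z <- nn_forward(model$abs_relu2, z, train)
  z <- nn_forward(model$abs_fc2, z, train)
  as.vector(z) * model$pressure_scale
}

backward_abs_pressure <- function(model, dout) {
  B <- length(dout)
  g <- matrix(dout * model$pressure_scale, B, 1L)
  g <- nn_backward(model$abs_fc2, g)
  g <- nn_backward(model$abs_relu2, g)
  g <- nn_backward(model$abs_fc1, g)
  g <- array(g, model$cache_abs_conv_dim)
  g <- nn_backward(model$abs_relu1, g)
  g <- nn_backward(model$abs_conv, g)
  invisible(g)
}

#' End-to-end surrogate prediction for one canvas
#'
#' Runs all three branches in evaluation mode and reconstructs the
#' absolute pressure field as normalized field times predicted peak.
#'
#' @param model A [tusnet()].
#' @param canvas A [build_canvas()] result or `grid_n` x `grid_n` matrix.
#' @return List with `normalized_field` (matrix), `absolute_peak_pa`
#'   (scalar), `absolute_field` (matrix, Pa), and `phase_frac`
#'   (per-element delays as period fractions in `[0, 1)`).
#' @export
predict_tusnet <- function(model, canvas) {
  x <- if (inherits(canvas, "canvas")) canvas$image else canvas
  res <- forward_field(model, x, train = FALSE)
  ph <- forward_phase(model, res$first_cell_output, train = FALSE)
  ap <- forward_abs_pressure(model, res$reduced_embedding, train = FALSE)
  nf <- res$field[1L, , ]
  list(normalized_field = nf,
       absolute_peak_pa = ap[1L],
       absolute_field = nf * ap[1L],
       phase_frac = as.vector(ph[1L, ]) %% 1)
}
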