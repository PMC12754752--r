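test_that("LSTM-Conv cells resample by a factor of two with one output channel", {
  down <- tfus:::new_lstm_conv_cell(16L, "down", dropout = 0)
  up <- tfus:::new_lstm_conv_cell(8L, "up", dropout = 0)
  x <- array(runif(2 * 16 * 16), c(2L, 16L, 16L))
  rd <- tfus:::cell_forward(down, x, NULL, train = FALSE)
  expect_equal(dim(rd$y), c(2L, 8L, 8L))
  ru <- tfus:::cell_forward(up, rd$y, rd$state, train = FALSE)
  expect_equal(dim(ru$y), c(2L, 16L, 16L))
  # four directional states, each batch x width
  expect_length(rd$state, 4L)
  expect_equal(dim(rd$state[[1L]]$h), c(2L, 16L))
})

test_that("evaluation-mode forward passes are deterministic", {
  m <- tusnet(grid_n = 32L, n_elements = 8L, seed = 3L)
  x <- array(runif(32 * 32), c(1L, 32L, 32L))
  a <- forward_field(m, x, train = FALSE)
  b <- forward_field(m, x, train = FALSE)
  expect_identical(a$field, b$field)
  expect_identical(forward_phase(m, a$first_cell_output),
                   forward_phase(m, b$first_cell_output))
})

test_that("forward branches produce the contracted shapes and ranges", {
  m <- tusnet(grid_n = 32L, n_elements = 8L, seed = 1L)
  x <- array(runif(3 * 32 * 32), c(3L, 32L, 32L))
  r <- forward_field(m, x)
  expect_equal(dim(r$field), c(3L, 32L, 32L))
  expect_true(all(r$field >= 0 & r$field <= 1))
  expect_equal(dim(r$reduced_embedding), c(3L, 1L, 1L))
  expect_equal(dim(r$first_cell_output), c(3L, 16L, 16L))
  ph <- forward_phase(m, r$first_cell_output)
  expect_equal(dim(ph), c(3L, 8L))
  expect_true(all(ph >= 0 & ph <= 1))
  ap <- forward_abs_pressure(m, r$reduced_embedding)
  expect_length(ap, 3L)
  # the absolute field is the normalized field times the scalar, exactly
  pred <- predict_tusnet(m, matrix(runif(32 * 32), 32, 32))
  expect_identical(pred$absolute_field,
                   pred$normalized_field * pred$absolute_peak_pa)
})

test_that("reverse scans mirror forward scans under weight tying", {
  cell <- tfus:::new_lstm_conv_cell(12L, "down", tie_dirs = TRUE)
  x <- array(runif(2 * 12 * 12), c(2L, 12L, 12L))
  y_lr <- tfus:::nn_forward(cell$dirs[[3L]], x)
  y_rl_flip <- tfus:::nn_forward(cell$dirs[[4L]], x[, , 12:1, drop = FALSE])
  expect_equal(y_lr, y_rl_flip[, , 12:1, drop = FALSE], tolerance = 1e-12)
  y_tb <- tfus:::nn_forward(cell$dirs[[1L]], x)
  y_bt_flip <- tfus:::nn_forward(cell$dirs[[2L]], x[, 12:1, , drop = FALSE])
  expect_equal(y_tb, y_bt_flip[, 12:1, , drop = FALSE], tolerance = 1e-12)
})

test_that("the adaptive loss schedule shifts weight from skull to focus", {
  w3 <- adaptive_loss_weights(3)
  expect_equal(w3$skull, 0.5)
  expect_equal(w3$focus, 0.5)
  w6 <- adaptive_loss_weights(6)
  expect_equal(w6$skull, 0.25)
  expect_equal(w6$focus, 0.75)
  ws <- vapply(1:12, function(t) adaptive_loss_weights(t)$skull, numeric(1L))
  expect_true(all(diff(ws) <= 0))
  expect_equal(ws + vapply(1:12, function(t) adaptive_loss_weights(t)$focus,
                           numeric(1L)), rep(1, 12L))
})

test_that("the three losses evaluate their formulas", {
  set.seed(8)
  p <- array(runif(2 * 16 * 16), c(2L, 16L, 16L))
  g <- array(runif(2 * 16 * 16), c(2L, 16L, 16L))
  # early epochs reduce to half the plain MSE
  expect_equal(loss_field(p, g, epoch = 3, split_row = 6L)$loss,
               0.5 * mean((p - g)^2))
  expect_equal(loss_field(p, p, epoch = 9, split_row = 6L)$loss, 0)
  # later epochs weight the regions differently
  L6 <- loss_field(p, g, epoch = 6, split_row = 6L)$loss
  W <- array(rep(ifelse(seq_len(16) <= 6, 0.25, 0.75), each = 2),
             c(2L, 16L, 16L))
  expect_equal(L6, mean(W * (p - g)^2))
  expect_equal(loss_abs(5, 5)$loss, 0)
  expect_equal(loss_abs(6.2, 5.2)$loss, 1)
  a <- runif(8); b <- runif(8)
  expect_equal(loss_abs(a, b)$loss, mean(abs(a - b)))
  P <- matrix(runif(12), 3L); G <- matrix(runif(12), 3L)
  expect_equal(loss_phase(P, G)$loss, mean(abs(P - G)))
  expect_equal(loss_phase(P, P + 0.3)$loss, 0.3, tolerance = 1e-12)
  expect_error(loss_phase(P, matrix(0, 2, 4)), "mismatch")
})

test_that("analytic gradients agree with finite differences through a cell chain", {
  set.seed(14)
  c1 <- tfus:::new_lstm_conv_cell(8L, "down", dropout = 0)
  c2 <- tfus:::new_lstm_conv_cell(4L, "up", dropout = 0)
  x <- array(runif(2 * 8 * 8), c(2L, 8L, 8L))
  tgt <- array(runif(2 * 8 * 8), c(2L, 8L, 8L))
  fwd <- function() {
    r1 <- tfus:::cell_forward(c1, x, NULL, train = TRUE)
    r2 <- tfus:::cell_forward(c2, r1$y, r1$state, train = TRUE)
    sum((r2$y - tgt)^2)
  }
  layers <- c(tfus:::cell_layers(c1), tfus:::cell_layers(c2))
  tfus:::zero_grads(layers)
  r1 <- tfus:::cell_forward(c1, x, NULL, train = TRUE)
  r2 <- tfus:::cell_forward(c2, r1$y, r1$state, train = TRUE)
  res2 <- tfus:::cell_backward(c2, 2 * (r2$y - tgt), NULL)
  invisible(tfus:::cell_backward(c1, res2$dx, res2$dstate))
  eps <- 1e-6
  probes <- list(list(c1$dirs[[1L]], "Wx1", 3L), list(c1$dirs[[4L]], "Wh1", 7L),
                 list(c1$conv2, "W", 20L), list(c2$dirs[[2L]], "b1", 5L),
                 list(c2$conv1, "W", 9L), list(c2$bn2, "gamma", 3L))
  for (pr in probes) {
    layer <- pr[[1L]]; nm <- pr[[2L]]; idx <- pr[[3L]]
    g_ana <- layer$grads[[nm]][idx]
    p0 <- layer$params[[nm]][idx]
    layer$params[[nm]][idx] <- p0 + eps; L1 <- fwd()
    layer$params[[nm]][idx] <- p0 - eps; L2 <- fwd()
    layer$params[[nm]][idx] <- p0
    g_num <- (L1 - L2) / (2 * eps)
    expect_equal(g_ana, g_num, tolerance = 1e-4)
  }
})

test_that("one optimizer step lowers the loss and respects frozen layers", {
  set.seed(2)
  m <- tusnet(grid_n = 32L, n_elements = 8L, dropout = 0, seed = 6L)
  x <- array(runif(2 * 32 * 32), c(2L, 32L, 32L))
  g <- array(runif(2 * 32 * 32) * 0.2, c(2L, 32L, 32L))
  layers <- c(tfus:::encoder_layers(m), tfus:::field_layers(m))
  step <- function() {
    tfus:::zero_grads(layers)
    r <- forward_field(m, x, train = TRUE)
    L <- loss_field(r$field, g, 1, m$split_row)
    tfus:::backward_field(m, L$grad)
    L$loss
  }
  l0 <- step()
  tfus:::adam_step(layers, 5e-3, 1L)
  l1 <- step()
  expect_lt(l1, l0)
  # frozen layers are untouched by further steps
  enc1 <- m$enc[[1L]]$conv1
  enc1$frozen <- TRUE
  w_before <- enc1$params$W
  tfus:::adam_step(layers, 5e-3, 2L)
  expect_identical(enc1$params$W, w_before)
})

test_that("weight transfer seeds a 4-layer model from a 1-layer model", {
  m1 <- tusnet(grid_n = 32L, n_elements = 8L, n_lstm_layers = 1L, seed = 4L)
  m4 <- tusnet(grid_n = 32L, n_elements = 8L, n_lstm_layers = 4L, seed = 5L)
  transfer_weights(m1, m4)
  expect_identical(m4$enc[[1L]]$dirs[[1L]]$params$Wx1,
                   m1$enc[[1L]]$dirs[[1L]]$params$Wx1)
  expect_identical(m4$field_head$params$W, m1$field_head$params$W)
  expect_gt(m4$transferred, 0L)
  # deeper layers keep their own initialization and the model still runs
  x <- array(runif(32 * 32), c(1L, 32L, 32L))
  expect_equal(dim(forward_field(m4, x)$field), c(1L, 32L, 32L))
})
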