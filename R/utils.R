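# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so generators never perturb the session stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Draw one value uniformly from a length-2 range (or return a scalar as is).
draw_range <- function(rng) {
  if (length(rng) == 1L) return(rng)
  stats::runif(1L, min(rng), max(rng))
}

clamp <- function(x, lo = -Inf, hi = Inf) pmin(pmax(x, lo), hi)

# Bilinear interpolation of matrix `z` at fractional (row, col) positions.
# Positions are clamped to the grid; used by the ray tracer.
bilinear_at <- function(z, r, c) {
  nr <- nrow(z); nc <- ncol(z)
  r <- clamp(r, 1, nr); c <- clamp(c, 1, nc)
  r0 <- pmin(floor(r), nr - 1L); c0 <- pmin(floor(c), nc - 1L)
  fr <- r - r0; fc <- c - c0
  z[cbind(r0, c0)]     * (1 - fr) * (1 - fc) +
  z[cbind(r0 + 1, c0)] * fr       * (1 - fc) +
  z[cbind(r0, c0 + 1)] * (1 - fr) * fc +
  z[cbind(r0 + 1, c0 + 1)] * fr   * fc
}

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

# Cheap content digest used for frozen-weight audits: polynomial hash over
# the serialized bytes, reported with the byte count to make collisions
# easy to spot in logs.
weights_digest <- function(x) {
  r <- as.integer(serialize(x, NULL, xdr = TRUE))
  w <- (seq_along(r) - 1L) %% 9973L + 1L
  paste0(format(sum(as.double(r) * w), digits = 22), ":", length(r))
}
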