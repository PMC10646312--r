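# Shared fixtures: rasterized shapes and small constructed inputs.

disc_mask <- function(r, cx = 128, cy = 128, n = 256) {
  x <- matrix(rep(seq_len(n), each = n), n)
  y <- matrix(rep(seq_len(n), times = n), n)
  (x - cx)^2 + (y - cy)^2 <= r^2
}

ellipse_mask <- function(a, b, cx = 128, cy = 128, n = 256) {
  x <- matrix(rep(seq_len(n), each = n), n)
  y <- matrix(rep(seq_len(n), times = n), n)
  ((x - cx) / a)^2 + ((y - cy) / b)^2 <= 1
}

square_mask <- function(half, cx = 64, cy = 64, n = 128) {
  m <- matrix(FALSE, n, n)
  m[(cy - half):(cy + half), (cx - half):(cx + half)] <- TRUE
  m
}

# trajectory data frame from a positions matrix (single cell)
traj_from_xy <- function(xy, dt = 1, cell_id = 1) {
  d <- data.frame(cell_id = cell_id,
                  t_s = (seq_len(nrow(xy)) - 1) * dt,
                  x_um = xy[, 1], y_um = xy[, 2])
  attr(d, "delta_t") <- dt
  d
}

table1_params <- function(noise = FALSE) {
  gle_reference_params(if (noise) "gle_noise" else "gle")
}

# random admissible (stationary) GLE parameter sets for property loops
random_gle_params <- function(n, seed = 42) {
  set.seed(seed)
  out <- list()
  while (length(out) < n) {
    a <- runif(1, 0.02, 0.2); b <- runif(1, 0.05, 0.5)
    g <- runif(1, 0.01, 0.2); s <- runif(1, 0.1, 0.6)
    if (b * g > a^2 * 1.1)
      out[[length(out) + 1]] <- gle_params(a, b, g, s)
  }
  out
}
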