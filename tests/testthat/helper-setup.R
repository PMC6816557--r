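# Small, fast configurations shared across tests.

small_params <- function(...) {
  args <- utils::modifyList(list(n_cells = 20, domain_size = c(200, 200),
                                 grid_shape = c(20, 20), duration = 1),
                            list(...))
  do.call(sim_params, args)
}

# Hand-made two-cell (or n-cell) state for crafted scenarios.
manual_state <- function(params, x, y, theta, speed = NULL) {
  n <- length(x)
  stopifnot(params$n_cells == n)
  if (is.null(speed)) speed <- rep(params$speed_mean, n)
  grid <- new_fiber_grid(params$grid_shape[1], params$grid_shape[2],
                         params$n_bins,
                         spacing = params$domain_size[1] / params$grid_shape[1])
  st <- list(x = x, y = y, theta = theta, speed = speed, ux = x, uy = y,
             grid = grid,
             last_selected = rep(-1L,
                                 params$grid_shape[1] * params$grid_shape[2]),
             time_min = 0)
  class(st) <- "sim_state"
  st
}

# Brute-force oracle for the apolar representative: minimise circular
# distance over {other, other - pi, other + pi}.
oracle_nematic <- function(ref, other) {
  cand <- c(other, other - pi, other + pi)
  circ <- function(a, b) {
    d <- abs((a - b) %% (2 * pi))
    pmin(d, 2 * pi - d)
  }
  d <- circ(cand, ref)
  best <- cand[order(d, c(1, 2, 3))[1]] # ties keep `other`
  best %% (2 * pi)
}

# Straight-line image of given size with `k` horizontal lines.
line_image <- function(n = 256, rows = round(n / 2)) {
  img <- matrix(0, n, n)
  img[rows, ] <- 1
  img
}
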