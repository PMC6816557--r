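#' Initialize a simulation state
#'
#' Places `n_cells` cells uniformly at random over the domain with uniform
#' random headings and per-cell constant speeds drawn from a Gaussian
#' truncated at zero, over an empty fiber grid.
#'
#' @param params A `"sim_params"` object.
#' @param seed Optional integer seed (calls `set.seed()`).
#' @return A list of class `"sim_state"` with elements `x`, `y`, `theta`,
#'   `speed`, unwrapped coordinates `ux`, `uy`, the fiber `grid`, the
#'   per-point `last_selected` bin (0 when never selected), and `time_min`.
#' @export
initialize_state <- function(params, seed = NULL) {
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  n <- params$n_cells
  speed <- numeric(n)
  if (n > 0) {
    speed <- rnorm(n, params$speed_mean, params$speed_sd)
    while (any(bad <- speed <= 0))
      speed[bad] <- rnorm(sum(bad), params$speed_mean, params$speed_sd)
  }
  x <- runif(n, 0, params$domain_size[1])
  y <- runif(n, 0, params$domain_size[2])
  theta <- runif(n, 0, 2 * pi)
  grid <- new_fiber_grid(params$grid_shape[1], params$grid_shape[2],
                         params$n_bins,
                         spacing = params$domain_size[1] / params$grid_shape[1])
  st <- list(x = x, y = y, theta = theta, speed = speed, ux = x, uy = y,
             grid = grid,
             last_selected = rep(-1L, params$grid_shape[1] * params$grid_shape[2]),
             time_min = 0)
  class(st) <- "sim_state"
  st
}

cpp_par <- function(params) {
  geo <- bead_geometry(params$cell_shape, params$cell_area)
  list(W = params$domain_size[1], H = params$domain_size[2],
       sd_eta = sqrt(params$noise_variance),
       w_c = params$w_c, w_m = params$w_m,
       dep = params$deposition_rate, deg = params$degradation_rate,
       rea = params$rearrangement_rate,
       fb = params$density_feedback, d_lo = params$d_lo, d_hi = params$d_hi,
       ve = params$v_e_factor, ovf = params$overlap_fraction,
       off = geo$offsets, rad = geo$radii,
       nx = as.integer(params$grid_shape[1]),
       ny = as.integer(params$grid_shape[2]),
       nbins = as.integer(params$n_bins),
       periodic = params$boundary == "periodic")
}

#' Run the simulation
#'
#' Advances a state by a number of steps (or simulated days). Each step
#' executes, in order: (1) all new headings computed synchronously from the
#' current state; (2) matrix deposition, degradation and rearrangement at
#' each cell's head grid point using the new heading; (3) position updates
#' with volume exclusion.
#'
#' @param params A `"sim_params"` object.
#' @param state Optional starting `"sim_state"`; a fresh one is initialized
#'   when `NULL` (matrix remodeling experiments restart phase 2 from a saved
#'   state this way).
#' @param days,steps Duration; give one of them (default `params$duration`
#'   days).
#' @param seed Optional integer seed.
#' @param record_tracks Record cell positions for persistence analysis?
#' @param record_every Record every this-many steps.
#' @return The advanced `"sim_state"`; when `record_tracks = TRUE` it carries
#'   a `tracks` tibble (`time_min`, `cell`, `x`, `y`, unwrapped coordinates).
#' @examples
#' p <- sim_params(n_cells = 20, domain_size = c(200, 200),
#'                 grid_shape = c(20, 20), duration = 1)
#' st <- run_simulation(p, seed = 1)
#' total_fibers(st$grid) # 20 cells x 96 steps x deposition rate 1
#' @export
run_simulation <- function(params, state = NULL, days = NULL, steps = NULL,
                           seed = NULL, record_tracks = FALSE,
                           record_every = 1) {
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(state)) state <- initialize_state(params)
  if (is.null(steps)) steps <- n_steps(params, if (is.null(days)) params$duration else days)
  stopifnot(steps >= 0)
  if (steps == 0) return(state)

  res <- cpp_run(state$x, state$y, state$theta, state$speed,
                 state$ux, state$uy, as.numeric(state$grid),
                 as.integer(state$last_selected), cpp_par(params),
                 as.integer(steps),
                 if (record_tracks) as.integer(record_every) else 0L)

  grid <- array(res$grid, dim = dim(state$grid))
  attr(grid, "spacing") <- attr(state$grid, "spacing")
  class(grid) <- class(state$grid)

  out <- state
  out$x <- res$x; out$y <- res$y; out$theta <- res$theta
  out$ux <- res$ux; out$uy <- res$uy
  out$grid <- grid
  out$last_selected <- res$last_selected
  t0 <- state$time_min
  out$time_min <- t0 + steps * params$dt
  if (record_tracks) {
    n <- params$n_cells
    times <- c(t0, t0 + res$rec_step * params$dt)
    xs <- rbind(state$ux, res$rec_x)
    ys <- rbind(state$uy, res$rec_y)
    out$tracks <- tibble::tibble(
      time_min = rep(times, each = n),
      cell = rep(seq_len(n), times = length(times)),
      x = as.vector(t(xs)), y = as.vector(t(ys)))
  }
  out
}

#' Advance a state by a few steps
#'
#' Thin wrapper over [run_simulation()] for unit-sized updates.
#'
#' @param state A `"sim_state"`.
#' @param params A `"sim_params"` object.
#' @param n Number of steps.
#' @return The advanced state.
#' @export
step_simulation <- function(state, params, n = 1) {
  run_simulation(params, state = state, steps = n)
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("<sim_state> %d cells, t = %g min, %.0f fibers on a %dx%d grid\n",
              length(x$x), x$time_min, sum(x$grid), dim(x$grid)[2],
              dim(x$grid)[3]))
  invisible(x)
}
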