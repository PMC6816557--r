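#' Simulation parameters
#'
#' Builds and validates the full parameter set of the two-layer model: a top
#' layer of self-propelled, nematically interacting cells and a bottom layer
#' of binned fiber orientations that the cells deposit, degrade, rearrange
#' and are guided by.
#'
#' The heading of a cell is updated each step as a convex combination of three
#' unit-vector terms: persistent migratory noise (weight `w_p = 1 - w_c -
#' w_m`), nematic guidance from contacting cells (`w_c`) and nematic guidance
#' from the fiber bin selected under the cell's head (`w_m`). When
#' `density_feedback = TRUE` the matrix term is scaled by the piecewise-linear
#' density response [density_feedback_scale()], so sparse matrix exerts no
#' guidance.
#'
#' @param noise_variance Variance of the per-step Gaussian heading
#'   perturbation, radians^2/step. Figure-style values 0-0.21.
#' @param w_c Cell-cell guidance weight in `[0, 1]`.
#' @param w_m Matrix feedback weight in `[0, 1]`; `w_c + w_m <= 1`.
#' @param speed_mean,speed_sd Gaussian parameters of the per-cell constant
#'   speed, micrometres/step (truncated at zero).
#' @param n_cells Number of cells.
#' @param domain_size Width and height of the domain, micrometres.
#' @param dt Minutes of real time per step.
#' @param duration Simulated days (used by [run_simulation()] when no explicit
#'   step count is given).
#' @param deposition_rate,degradation_rate,rearrangement_rate Fibers per step
#'   deposited into the heading bin, removed from every bin, and moved from
#'   each neighbouring bin into the heading bin, at the grid point under a
#'   cell's head.
#' @param density_feedback Scale `w_m` by the fiber-density response `f(d)`?
#' @param d_lo,d_hi Density way-points of `f(d)`: `f(d_lo) = 0`,
#'   `f(d_hi) = 1`.
#' @param cell_shape One of `"elongated"` (default 4-bead, 3:1 aspect),
#'   `"teardrop"`, `"rounded"`.
#' @param cell_area Projected cell area, square micrometres; sets the bead
#'   radii.
#' @param overlap_fraction Fraction of the combined bead radii below which the
#'   head bead counts as overlapping another cell (volume exclusion trigger).
#' @param v_e_factor Speed multiplier applied while the head bead overlaps
#'   another cell.
#' @param grid_shape Number of fiber grid points in x and y.
#' @param n_bins Apolar orientation bins per grid point; bin `b` covers
#'   `[(b-1)*pi/n_bins, b*pi/n_bins)`.
#' @param boundary `"periodic"` (default) or `"reflecting"`.
#'
#' @return A list of class `"sim_params"`.
#' @examples
#' p <- sim_params(n_cells = 50, noise_variance = 0.14)
#' n_steps(p)
#' @export
sim_params <- function(noise_variance = 0.14,
                       w_c = 0.03,
                       w_m = 0,
                       speed_mean = 10,
                       speed_sd = 2,
                       n_cells = 800,
                       domain_size = c(1000, 1000),
                       dt = 15,
                       duration = 7,
                       deposition_rate = 1,
                       degradation_rate = 0,
                       rearrangement_rate = 0,
                       density_feedback = FALSE,
                       d_lo = 5,
                       d_hi = 10,
                       cell_shape = c("elongated", "teardrop", "rounded"),
                       cell_area = 500,
                       overlap_fraction = 0.75,
                       v_e_factor = 0.25,
                       grid_shape = c(100, 100),
                       n_bins = 8,
                       boundary = c("periodic", "reflecting")) {
  cell_shape <- match.arg(cell_shape)
  boundary <- match.arg(boundary)
  p <- list(
    noise_variance = noise_variance, w_c = w_c, w_m = w_m,
    speed_mean = speed_mean, speed_sd = speed_sd,
    n_cells = n_cells, domain_size = domain_size,
    dt = dt, duration = duration,
    deposition_rate = deposition_rate,
    degradation_rate = degradation_rate,
    rearrangement_rate = rearrangement_rate,
    density_feedback = density_feedback, d_lo = d_lo, d_hi = d_hi,
    cell_shape = cell_shape, cell_area = cell_area,
    overlap_fraction = overlap_fraction, v_e_factor = v_e_factor,
    grid_shape = grid_shape, n_bins = n_bins, boundary = boundary
  )
  class(p) <- "sim_params"
  validate_params(p)
}

#' Validate a parameter set
#'
#' Checks the invariants of the model configuration and returns the object
#' invisibly unchanged on success.
#'
#' @param p A `"sim_params"` object.
#' @return `p`, invisibly on success; otherwise an error.
#' @export
validate_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(p$w_c >= 0 && p$w_m >= 0, "w_c and w_m must be non-negative")
  chk(p$w_c + p$w_m <= 1 + 1e-12,
      sprintf("w_c + w_m = %.3f exceeds 1; the persistence weight w_p = 1 - w_c - w_m would be negative. Lower w_c and/or w_m.",
              p$w_c + p$w_m))
  chk(p$noise_variance >= 0, "noise_variance must be >= 0")
  chk(all(c(p$deposition_rate, p$degradation_rate, p$rearrangement_rate) >= 0),
      "matrix rates must be >= 0")
  chk(p$n_cells >= 0 && p$n_cells == round(p$n_cells),
      "n_cells must be a non-negative integer")
  chk(length(p$domain_size) == 2 && all(p$domain_size > 0),
      "domain_size must be two positive lengths")
  chk(p$dt > 0 && p$duration > 0, "dt and duration must be positive")
  chk(p$n_bins >= 2 && p$n_bins == round(p$n_bins), "n_bins must be >= 2")
  chk(p$d_lo < p$d_hi, "d_lo must be below d_hi")
  chk(p$v_e_factor > 0 && p$v_e_factor <= 1, "v_e_factor must be in (0, 1]")
  chk(p$overlap_fraction > 0 && p$overlap_fraction <= 1,
      "overlap_fraction must be in (0, 1]")
  chk(length(p$grid_shape) == 2 && all(p$grid_shape >= 1),
      "grid_shape must be two positive counts")
  chk(p$speed_mean >= 0 && p$speed_sd >= 0,
      "speed_mean and speed_sd must be >= 0")
  invisible(p)
}

#' Number of steps in a simulated run
#'
#' @param p A `"sim_params"` object.
#' @param days Simulated days; defaults to `p$duration`.
#' @return Integer step count, `days * 24 * 60 / dt`.
#' @export
n_steps <- function(p, days = p$duration) {
  as.integer(round(days * 24 * 60 / p$dt))
}

# Bead geometry tables. Radii/offsets are along the cell axis, head first.
# The elongated default is four tangent beads (r, 2r, 2r, r): length 12r,
# width 4r, aspect 3:1; r is set so the summed bead area matches cell_area.
bead_geometry <- function(shape, area) {
  unit <- switch(shape,
    elongated = list(radii = c(1, 2, 2, 1), offsets = c(5, 2, -2, -5)),
    teardrop = list(radii = c(2, 1.6, 1.2, 0.9), offsets = NULL),
    rounded = list(radii = c(1.6, 1.6, 1.6, 1.6), offsets = c(2.4, 0.8, -0.8, -2.4))
  )
  if (is.null(unit$offsets)) { # tangent chain, centred on its extremes
    r <- unit$radii
    pos <- c(0, -cumsum(r[-length(r)] + r[-1]))
    unit$offsets <- pos - (max(pos + r) + min(pos - r)) / 2
  }
  scale <- sqrt(area / (pi * sum(unit$radii^2)))
  list(radii = unit$radii * scale, offsets = unit$offsets * scale)
}

#' Tissue parameter presets
#'
#' Parameter sets that generate matrix patterns resembling dermis, liver,
#' spleen and stomach: per-tissue noise variance, cell-cell guidance and
#' matrix feedback, with 200 cells in a 1 mm^2 domain (about 10% confluence)
#' and density-scaled matrix feedback enabled.
#'
#' @param tissue One of `"dermis"`, `"liver"`, `"spleen"`, `"stomach"`.
#' @param fine_grid Use a twice-as-fine fiber grid (200 x 200) and halved cell
#'   speed for higher-precision fiber placement. Default `FALSE`.
#' @param ... Overrides passed on to [sim_params()].
#' @return A `"sim_params"` object.
#' @examples
#' tissue_preset("liver")$w_m
#' @export
tissue_preset <- function(tissue = c("dermis", "liver", "spleen", "stomach"),
                          fine_grid = FALSE, ...) {
  tissue <- match.arg(tissue)
  tab <- list(
    dermis  = list(noise_variance = 0.1,  w_c = 0.03, w_m = 0.4),
    liver   = list(noise_variance = 0.1,  w_c = 0.03, w_m = 0.8),
    spleen  = list(noise_variance = 0.01, w_c = 0,    w_m = 0.01),
    stomach = list(noise_variance = 0.02, w_c = 0.03, w_m = 0)
  )[[tissue]]
  base <- c(tab, list(n_cells = 200, domain_size = c(1000, 1000),
                      density_feedback = TRUE))
  if (fine_grid) base <- c(base, list(grid_shape = c(200, 200), speed_mean = 5))
  do.call(sim_params, modifyList(base, list(...)))
}

#' Rescale a configuration to a smaller domain at fixed confluence
#'
#' Shrinks the domain edge by `factor` and scales the cell count and fiber
#' grid with the domain area so that confluence and grid spacing are
#' preserved. Useful for desk-scale replicates of large runs.
#'
#' @param p A `"sim_params"` object.
#' @param factor Edge scale factor in (0, 1].
#' @return A rescaled `"sim_params"` object.
#' @export
scale_params <- function(p, factor) {
  stopifnot(inherits(p, "sim_params"), factor > 0, factor <= 1)
  p$domain_size <- p$domain_size * factor
  p$n_cells <- max(1L, as.integer(round(p$n_cells * factor^2)))
  p$grid_shape <- pmax(1L, as.integer(round(p$grid_shape * factor)))
  validate_params(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  cat(sprintf("  cells: %d in %g x %g um (%s, %s boundary)\n", x$n_cells,
              x$domain_size[1], x$domain_size[2], x$cell_shape, x$boundary))
  cat(sprintf("  weights: Var(eta)=%g  w_c=%g  w_m=%g%s\n", x$noise_variance,
              x$w_c, x$w_m,
              if (x$density_feedback) sprintf(" (density-scaled, f(%g)=0, f(%g)=1)",
                                              x$d_lo, x$d_hi) else ""))
  cat(sprintf("  matrix: %dx%d grid, %d bins; dep/deg/rearr = %g/%g/%g per step\n",
              x$grid_shape[1], x$grid_shape[2], x$n_bins, x$deposition_rate,
              x$degradation_rate, x$rearrangement_rate))
  cat(sprintf("  time: dt=%g min, %g days (%d steps); speed %g +/- %g um/step\n",
              x$dt, x$duration, n_steps(x), x$speed_mean, x$speed_sd))
  invisible(x)
}
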