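#' Create an empty fiber grid
#'
#' The matrix layer is a lattice of grid points, each holding `n_bins`
#' non-negative fiber counts in apolar orientation bins: bin `b` covers
#' orientations `[(b-1)*pi/n_bins, b*pi/n_bins)` and its left bound
#' `(b-1)*pi/n_bins` is the orientation a guided cell flocks with.
#'
#' @param nx,ny Grid points in x and y.
#' @param n_bins Orientation bins per grid point.
#' @param spacing Distance between neighbouring grid points, micrometres.
#' @return A numeric array of dimension `c(n_bins, nx, ny)` with class
#'   `"fiber_grid"` and a `spacing` attribute.
#' @export
new_fiber_grid <- function(nx, ny, n_bins = 8, spacing = 10) {
  g <- array(0, dim = c(n_bins, nx, ny))
  attr(g, "spacing") <- spacing
  class(g) <- c("fiber_grid", "array")
  g
}

#' Orientation bin of a heading
#'
#' Folds a heading into `[0, pi)` (fibers are apolar, so `theta` and
#' `theta + pi` land in the same bin) and returns its 1-based bin index.
#'
#' @param theta Heading(s), radians.
#' @param n_bins Number of bins over `[0, pi)`.
#' @return Integer bin index in `1:n_bins`.
#' @examples
#' bin_of(0)            # 1
#' bin_of(9 * pi / 8)   # 2
#' @export
bin_of <- function(theta, n_bins = 8) {
  vapply(theta, cpp_bin_of, integer(1), nbins = as.integer(n_bins))
}

#' Deposit fibers into the heading bin
#'
#' @param bins Numeric vector of bin counts at one grid point.
#' @param theta Depositing cell's heading, radians.
#' @param rate Fibers deposited per call.
#' @return Updated bin counts.
#' @export
deposit_fibers <- function(bins, theta, rate) {
  stopifnot(rate >= 0)
  b <- bin_of(theta, length(bins))
  bins[b] <- bins[b] + rate
  bins
}

#' Degrade all bins at a grid point
#'
#' Every bin loses `rate` fibers, floored at zero.
#'
#' @inheritParams deposit_fibers
#' @return Updated bin counts.
#' @export
degrade_fibers <- function(bins, rate) {
  stopifnot(rate >= 0)
  pmax(0, bins - rate)
}

#' Rearrange fibers into the heading bin
#'
#' Moves up to `rate` fibers from each of the two cyclic neighbours of the
#' heading bin into the heading bin; the total count is conserved.
#'
#' @inheritParams deposit_fibers
#' @return Updated bin counts.
#' @export
rearrange_fibers <- function(bins, theta, rate) {
  stopifnot(rate >= 0)
  n <- length(bins)
  b <- bin_of(theta, n)
  for (nb in c((b - 2) %% n + 1, b %% n + 1)) {
    m <- min(rate, bins[nb])
    bins[nb] <- bins[nb] - m
    bins[b] <- bins[b] + m
  }
  bins
}

#' Gillespie selection of a guidance bin
#'
#' Samples a bin with probability proportional to its fiber count, so the
#' densest bins are most likely to guide the cell. Returns `NA` when the grid
#' point is empty (no matrix guidance).
#'
#' @param bins Numeric vector of bin counts at one grid point.
#' @return Integer bin index, or `NA_integer_` when all bins are empty.
#' @export
select_guidance_bin <- function(bins) {
  tot <- sum(bins)
  if (tot <= 0) return(NA_integer_)
  u <- runif(1) * tot
  as.integer(findInterval(u, cumsum(bins), left.open = FALSE) + 1L)
}

#' Density response of matrix feedback
#'
#' Piecewise-linear scaling of the matrix feedback weight by the fiber count
#' `d` of the selected bin: 0 at or below `d_lo`, 1 at or above `d_hi`,
#' linear in between. Sparse, freshly deposited matrix therefore exerts no
#' guidance, while established matrix exerts the full `w_m`.
#'
#' @param d Fiber count(s), `>= 0`.
#' @param d_lo,d_hi Lower and upper density way-points.
#' @return Value(s) in `[0, 1]`.
#' @examples
#' density_feedback_scale(c(5, 7.5, 10))
#' @export
density_feedback_scale <- function(d, d_lo = 5, d_hi = 10) {
  stopifnot(d_lo < d_hi, all(d >= 0))
  pmin(1, pmax(0, (d - d_lo) / (d_hi - d_lo)))
}

#' Bin left-bound orientations of a grid
#'
#' @param n_bins Number of bins.
#' @return Orientations `(0:(n_bins-1)) * pi / n_bins`.
#' @export
bin_orientations <- function(n_bins = 8) {
  (seq_len(n_bins) - 1) * pi / n_bins
}

#' Total fiber count of a grid
#'
#' @param grid A `"fiber_grid"` array.
#' @return Total fibers over all points and bins.
#' @export
total_fibers <- function(grid) sum(grid)
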