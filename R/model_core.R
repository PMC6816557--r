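#' Nematic representative of an orientation
#'
#' Fibers and cell axes are apolar: a direction and its opposite are
#' equivalent. This returns whichever of `theta_other` or `theta_other + pi`
#' lies within a quarter turn of `theta_ref` (ties keep `theta_other`), so an
#' antiparallel neighbour reinforces rather than cancels alignment.
#'
#' @param theta_ref Reference heading, radians.
#' @param theta_other Heading to represent, radians.
#' @return Angle in `[0, 2*pi)`.
#' @examples
#' nematic_representative(0, pi)       # 0: antiparallel maps onto parallel
#' nematic_representative(0, 3 * pi / 4) # 7*pi/4
#' @export
nematic_representative <- function(theta_ref, theta_other) {
  stopifnot(is.finite(theta_ref), all(is.finite(theta_other)))
  vapply(theta_other, function(o) cpp_nematic_rep(theta_ref, o), numeric(1))
}

#' Migratory noise term
#'
#' Unit vector along the perturbed heading `theta + eta`, with
#' `eta ~ N(0, noise_variance)`; the persistent-random-walk component of the
#' heading update.
#'
#' @param theta Current heading, radians.
#' @param noise_variance Variance of the Gaussian perturbation,
#'   radians^2/step.
#' @return Named vector `c(xp, yp)` of unit magnitude.
#' @export
noise_term <- function(theta, noise_variance) {
  stopifnot(noise_variance >= 0)
  eta <- rnorm(1, 0, sqrt(noise_variance))
  c(xp = cos(theta + eta), yp = sin(theta + eta))
}

#' Cell-cell guidance term
#'
#' Mean unit vector of the nematic representatives of all contacting cells'
#' headings, relative to the focal heading. The guidance weight does not grow
#' with the number of contacts; with no contacts the term is undefined and
#' the caller zeroes its weight.
#'
#' @param theta_i Focal cell heading, radians.
#' @param contact_thetas Headings of contacting cells (may be empty).
#' @return Named vector `c(xc, yc)`, or `NULL` when there are no contacts.
#' @export
cell_guidance_term <- function(theta_i, contact_thetas) {
  if (length(contact_thetas) == 0) return(NULL)
  rep_ <- nematic_representative(theta_i, contact_thetas)
  c(xc = mean(cos(rep_)), yc = mean(sin(rep_)))
}

#' Matrix guidance term
#'
#' Gillespie-selects a fiber bin under the cell's head (probability
#' proportional to fiber count), takes the left bound of that bin as the
#' fiber orientation, and returns its nematic representative relative to the
#' focal heading together with the selected bin's density.
#'
#' @param theta_i Focal cell heading, radians.
#' @param bins Fiber counts of the grid point under the head.
#' @return List with `xm`, `ym`, `d` (selected-bin fiber count) and `bin`, or
#'   `NULL` when every bin is empty.
#' @export
matrix_guidance_term <- function(theta_i, bins) {
  b <- select_guidance_bin(bins)
  if (is.na(b)) return(NULL)
  phi <- (b - 1) * pi / length(bins)
  rep_ <- nematic_representative(theta_i, phi)
  list(xm = cos(rep_), ym = sin(rep_), d = bins[b], bin = b)
}

#' Combine guidance terms into a new heading
#'
#' Weighted combination of the noise, cell-guidance and matrix-guidance unit
#' vectors with weights `w_p = 1 - w_c - w_m`, `w_c`, `w_m`. Absent terms
#' (`NULL`) have their weight zeroed; with density feedback the matrix weight
#' becomes `f(d) * w_m`. The applied weights are renormalised by their own
#' sum, and the new heading is the angle of the combined vector, wrapped to
#' `[0, 2*pi)`. A numerically zero combination keeps the previous heading.
#'
#' @param theta_prev Previous heading (returned if the combination vanishes).
#' @param noise Vector `c(xp, yp)` from [noise_term()].
#' @param cell Vector `c(xc, yc)` or `NULL`.
#' @param matrix List from [matrix_guidance_term()] or `NULL`.
#' @param w_c,w_m Guidance weights.
#' @param f_d Density-response scale applied to `w_m` (1 when density
#'   feedback is off).
#' @return List with `theta`, the combined components `xi`, `yi`, and the
#'   applied `effective_wc`, `effective_wm`.
#' @export
combine_direction <- function(theta_prev, noise, cell = NULL, matrix = NULL,
                              w_c = 0, w_m = 0, f_d = 1) {
  wp <- 1 - w_c - w_m
  wce <- if (is.null(cell)) 0 else w_c
  wme <- if (is.null(matrix)) 0 else w_m * f_d
  s <- wp + wce + wme
  xi <- yi <- 0
  if (s > 0) {
    xi <- (wp * noise[[1]] + wce * (if (wce > 0) cell[[1]] else 0) +
             wme * (if (wme > 0) matrix$xm else 0)) / s
    yi <- (wp * noise[[2]] + wce * (if (wce > 0) cell[[2]] else 0) +
             wme * (if (wme > 0) matrix$ym else 0)) / s
  }
  theta <- if (abs(xi) < 1e-15 && abs(yi) < 1e-15) theta_prev else
    atan2(yi, xi) %% (2 * pi)
  list(theta = theta, xi = xi, yi = yi,
       effective_wc = wce, effective_wm = wme)
}
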