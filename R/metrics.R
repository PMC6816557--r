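#' Extract the oriented fiber field of a grid
#'
#' One entry per non-empty orientation bin per grid point: position of the
#' grid point (micrometres, cell centres), orientation = the bin's left
#' bound, weight = the fiber count.
#'
#' @param grid A `"fiber_grid"` array.
#' @return A tibble with columns `x`, `y`, `theta` (in `[0, pi)`), `weight`.
#' @export
fiber_field <- function(grid) {
  nb <- dim(grid)[1]; nx <- dim(grid)[2]; ny <- dim(grid)[3]
  sp <- attr(grid, "spacing")
  idx <- which(grid > 0)
  b <- (idx - 1) %% nb + 1
  ix <- ((idx - 1) %/% nb) %% nx + 1
  iy <- (idx - 1) %/% (nb * nx) + 1
  tibble::tibble(x = (ix - 0.5) * sp, y = (iy - 0.5) * sp,
                 theta = (b - 1) * pi / nb, weight = grid[idx])
}

#' Alignment score of an oriented fiber field
#'
#' For each fiber, the weighted median of the acute angular deviation (in
#' `[0, pi/2]`) to every other fiber within `radius`; the field-level
#' deviation is the weight-averaged per-fiber median, and the reported score
#' is `1 - mean_deviation / (pi/2)`, so 1 is perfect alignment and 0.5 the
#' expectation for isotropic random orientations. Use [lra()] and [sra()]
#' for the standard long/short neighbourhoods.
#'
#' On a `"fiber_grid"` the computation runs directly on the binned lattice
#' (each non-empty point/bin is one fiber bundle of weight = count); on a
#' data frame field it runs pairwise.
#'
#' @param x A `"fiber_grid"` or a data frame with columns `x`, `y`, `theta`
#'   and optionally `weight`.
#' @param radius Neighbourhood length, micrometres.
#' @param periodic Wrap distances around the domain? Defaults to `TRUE` for
#'   grids (periodic simulations) and `FALSE` for point fields.
#' @param domain Domain size (width, height) when `periodic = TRUE` for a
#'   point field.
#' @param raw Return the mean deviation in radians instead of the score?
#' @return Alignment score in `[0, 1]` (or mean deviation when `raw`), `NA`
#'   when fewer than two fibers or no fiber has a neighbour.
#' @export
alignment_score <- function(x, radius, ...) UseMethod("alignment_score")

#' @rdname alignment_score
#' @param ... Passed between methods.
#' @export
alignment_score.fiber_grid <- function(x, radius, periodic = TRUE,
                                       raw = FALSE, ...) {
  stopifnot(radius > 0)
  res <- cpp_grid_align(as.numeric(x), dim(x)[2], dim(x)[3], dim(x)[1],
                        attr(x, "spacing"), radius, periodic)
  if (res$weight <= 0 || is.na(res$mean_dev)) return(NA_real_)
  if (raw) res$mean_dev else 1 - res$mean_dev / (pi / 2)
}

#' @rdname alignment_score
#' @export
alignment_score.data.frame <- function(x, radius, periodic = FALSE,
                                       domain = NULL, raw = FALSE, ...) {
  stopifnot(radius > 0, all(c("x", "y", "theta") %in% names(x)))
  if (nrow(x) < 2) return(NA_real_)
  w <- if ("weight" %in% names(x)) x$weight else rep(1, nrow(x))
  if (periodic && is.null(domain))
    stop("periodic point fields need an explicit domain size")
  W <- if (is.null(domain)) 0 else domain[1]
  H <- if (is.null(domain)) 0 else domain[length(domain)]
  med <- cpp_field_median_dev(x$x, x$y, x$theta, w, radius, periodic, W, H)
  ok <- !is.na(med)
  if (!any(ok)) return(NA_real_)
  d <- sum(med[ok] * w[ok]) / sum(w[ok])
  if (raw) d else 1 - d / (pi / 2)
}

#' Long-range alignment (LRA)
#'
#' [alignment_score()] with a long neighbourhood (default 200 micrometres).
#'
#' @inheritParams alignment_score
#' @param ... Passed to [alignment_score()].
#' @return Score in `[0, 1]` or `NA`.
#' @export
lra <- function(x, radius = 200, ...) alignment_score(x, radius, ...)

#' Short-range alignment (SRA)
#'
#' [alignment_score()] with a short neighbourhood (default 20 micrometres).
#'
#' @inheritParams alignment_score
#' @param ... Passed to [alignment_score()].
#' @return Score in `[0, 1]` or `NA`.
#' @export
sra <- function(x, radius = 20, ...) alignment_score(x, radius, ...)

#' Otsu threshold of a grayscale image
#'
#' @param image Numeric matrix with values in `[0, 1]`.
#' @return Threshold value.
#' @export
otsu_threshold <- function(image) {
  as.numeric(EBImage::otsu(EBImage::Image(image), range = c(0, 1)))
}

#' Percentage of high-density matrix (HDM)
#'
#' Percentage of pixels whose intensity exceeds a threshold; those pixels are
#' taken to be fibers.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param threshold Intensity threshold; `NULL` uses Otsu's method. Rendered
#'   simulation matrices use a fixed threshold (see
#'   [compute_metric_set()]).
#' @return Percentage in `[0, 100]`.
#' @export
hdm <- function(image, threshold = NULL) {
  if (length(image) == 0) stop("empty image")
  if (is.null(threshold)) threshold <- otsu_threshold(image)
  100 * mean(image > threshold)
}

#' Mean fiber curvature (Curv)
#'
#' Blurs the image with a large-radius Gaussian, thresholds it to a mask of
#' the principal fiber structure, thins the mask to a one-pixel skeleton,
#' and traverses each skeleton path in increments of `window` pixels; the
#' curvature at a sample is the absolute change of direction between one
#' chord and the next, and the metric is the average over the whole image.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param window Chord length in pixels.
#' @param blur_sigma Gaussian sigma of the structure mask, pixels.
#' @param threshold Mask threshold; `NULL` uses Otsu on the blurred image.
#' @return Mean absolute turning angle in degrees per window, `NA` when the
#'   mask has no traceable structure.
#' @export
curvature <- function(image, window = 10, blur_sigma = 8, threshold = NULL) {
  stopifnot(length(image) > 0, window >= 2)
  bl <- EBImage::gblur(image, sigma = blur_sigma)
  if (is.null(threshold)) {
    if (max(bl) <= min(bl)) return(NA_real_)
    threshold <- otsu_threshold(pmax(pmin(bl, 1), 0))
  }
  mask <- matrix(as.integer(bl > threshold), nrow(image), ncol(image))
  if (sum(mask) == 0) return(NA_real_)
  skel <- cpp_thin(mask)
  turns <- cpp_trace_turning(skel, window)
  if (length(turns) == 0) return(NA_real_)
  mean(turns) * 180 / pi
}

box_counts <- function(mask, sizes) {
  n <- nrow(mask)
  vapply(sizes, function(s) {
    idx <- rep(seq_len(n / s), each = s)
    m <- rowsum(mask + 0, idx)
    m <- rowsum(t(m), idx)
    sum(m > 0)
  }, numeric(1))
}

#' Box-counting fractal dimension (Frac)
#'
#' Blurs the image with a small-radius Gaussian, thresholds it to a detail
#' mask, and counts the boxes needed to cover the mask at dyadic box sizes
#' from the (padded) image size down to 2 px. The dimension is minus the
#' least-squares slope of log(count) against log(box size).
#'
#' @param image Numeric matrix in `[0, 1]`, or a logical/0-1 mask when
#'   `blur_sigma = 0`.
#' @param blur_sigma Gaussian sigma of the detail mask, pixels; 0 skips
#'   blurring and thresholds at 0.5.
#' @param threshold Mask threshold; `NULL` uses Otsu on the blurred image.
#' @return Dimension estimate (about 1 for a line, 2 for a filled plane),
#'   `NA` for an empty mask.
#' @export
fractal_dimension <- function(image, blur_sigma = 2, threshold = NULL) {
  stopifnot(length(image) > 0)
  if (blur_sigma > 0) {
    bl <- EBImage::gblur(image, sigma = blur_sigma)
    if (is.null(threshold)) {
      if (max(bl) <= min(bl)) return(NA_real_)
      threshold <- otsu_threshold(pmax(pmin(bl, 1), 0))
    }
    mask <- bl > threshold
  } else {
    mask <- image > if (is.null(threshold)) 0.5 else threshold
  }
  if (!any(mask)) return(NA_real_)
  npad <- 2^ceiling(log2(max(dim(mask))))
  pad <- matrix(FALSE, npad, npad)
  pad[seq_len(nrow(mask)), seq_len(ncol(mask))] <- mask
  sizes <- 2^seq(log2(npad), 1)
  counts <- box_counts(pad, sizes)
  fit <- stats::lm(log(counts) ~ log(sizes))
  -unname(stats::coef(fit)[2])
}

#' Render a fiber grid as a grayscale image
#'
#' Each grid point is drawn as a line segment spanning its pixel block at the
#' orientation of its most recently selected bin (the densest bin where no
#' selection has happened), with intensity `min(density / cutoff, 1)`: a
#' density at the cut-off renders fully black (here, intensity 1 on a zero
#' background).
#'
#' @param grid A `"fiber_grid"` array.
#' @param last_selected Optional integer vector of 0-based last-selected bins
#'   per grid point (-1 where never selected), as carried by a
#'   `"sim_state"`.
#' @param pixels_per_point Edge of the square pixel block per grid point.
#' @param cutoff Density rendered at full intensity.
#' @param halfwidth Segment half-width, pixels.
#' @return Numeric matrix in `[0, 1]`, rows indexing y.
#' @export
render_matrix <- function(grid, last_selected = NULL, pixels_per_point = 5,
                          cutoff = 25, halfwidth = 1) {
  nb <- dim(grid)[1]; nx <- dim(grid)[2]; ny <- dim(grid)[3]
  P <- as.integer(pixels_per_point)
  img <- matrix(0, ny * P, nx * P)
  np <- nx * ny
  gm <- matrix(as.numeric(grid), nb, np)
  sel <- max.col(t(gm), ties.method = "first")
  if (!is.null(last_selected)) {
    ls <- as.integer(last_selected)
    sel[ls >= 0] <- ls[ls >= 0] + 1L
  }
  dens <- gm[cbind(sel, seq_len(np))]
  val <- pmin(dens / cutoff, 1)

  ctr <- (P + 1) / 2
  sr <- rep(seq_len(P), times = P)
  sc <- rep(seq_len(P), each = P)
  for (b in seq_len(nb)) {
    pts <- which(sel == b & val > 0)
    if (length(pts) == 0) next
    a <- (b - 1) * pi / nb
    # pixel (row=y, col=x) centre offsets; segment along (cos a, sin a)
    dx <- sc - ctr; dy <- sr - ctr
    perp <- abs(-sin(a) * dx + cos(a) * dy)
    lon <- abs(cos(a) * dx + sin(a) * dy)
    hit <- which(perp <= halfwidth & lon <= P / 2)
    ix <- (pts - 1) %% nx
    iy <- (pts - 1) %/% nx
    rr <- rep(iy * P, each = length(hit)) + sr[hit]
    cc <- rep(ix * P, each = length(hit)) + sc[hit]
    vv <- rep(val[pts], each = length(hit))
    flat <- rr + (cc - 1) * nrow(img)
    img[flat] <- pmax(img[flat], vv)
  }
  img
}

#' Estimate an oriented fiber field from a grayscale image
#'
#' Thresholds the image and assigns each retained fiber pixel a local apolar
#' orientation from the smoothed structure tensor of the intensity
#' gradients. A deterministic, evenly spaced subsample caps the field size.
#'
#' @param image Numeric matrix in `[0, 1]`.
#' @param pixel_size Micrometres per pixel.
#' @param threshold Fiber threshold; `NULL` uses Otsu.
#' @param tensor_sigma Gaussian sigma smoothing the structure tensor, pixels.
#' @param max_fibers Upper bound on returned fibers.
#' @return A tibble with columns `x`, `y` (micrometres), `theta`, `weight`.
#' @export
field_from_image <- function(image, pixel_size = 1, threshold = NULL,
                             tensor_sigma = 2, max_fibers = 5000) {
  if (is.null(threshold)) threshold <- otsu_threshold(image)
  gxm <- (cbind(image[, -1], image[, ncol(image)]) -
            cbind(image[, 1], image[, -ncol(image)])) / 2
  gym <- (rbind(image[-1, ], image[nrow(image), ]) -
            rbind(image[1, ], image[-nrow(image), ])) / 2
  jxx <- EBImage::gblur(gxm * gxm, sigma = tensor_sigma)
  jyy <- EBImage::gblur(gym * gym, sigma = tensor_sigma)
  jxy <- EBImage::gblur(gxm * gym, sigma = tensor_sigma)
  # dominant gradient direction + pi/2 = fiber direction, folded apolar
  ori <- (0.5 * atan2(2 * jxy, jxx - jyy) + pi / 2) %% pi
  idx <- which(image > threshold)
  if (length(idx) > max_fibers)
    idx <- idx[round(seq(1, length(idx), length.out = max_fibers))]
  rr <- (idx - 1) %% nrow(image) + 1
  cc <- (idx - 1) %/% nrow(image) + 1
  tibble::tibble(x = (cc - 0.5) * pixel_size, y = (rr - 0.5) * pixel_size,
                 theta = ori[idx], weight = 1)
}

#' Compute the five matrix-topology metrics
#'
#' Long- and short-range alignment are computed on the oriented fiber field
#' (directly from the lattice for simulated grids, via [field_from_image()]
#' for images); high-density matrix, curvature and fractal dimension on the
#' (rendered) grayscale image. Rendered simulation matrices use a fixed HDM
#' threshold of `d_hi / cutoff` (density 10 of cut-off 25, i.e. intensity
#' 0.4) so that density contrasts between conditions are preserved; external
#' images default to Otsu.
#'
#' @param x A `"fiber_grid"`, a `"sim_state"`, or a grayscale image matrix.
#' @param ... Passed between methods.
#' @return A one-row tibble with columns `lra`, `sra`, `hdm`, `curv`,
#'   `frac`; metrics that are undefined on the input are `NA`.
#' @export
compute_metric_set <- function(x, ...) UseMethod("compute_metric_set")

#' @rdname compute_metric_set
#' @param last_selected Optional last-selected bin vector for rendering.
#' @param lra_radius,sra_radius Neighbourhood lengths, micrometres.
#' @param curvature_window Chord length, pixels.
#' @param sigma_large,sigma_small Gaussian sigmas of the curvature and
#'   fractal masks, pixels.
#' @param hdm_threshold Fixed HDM threshold for rendered matrices.
#' @param pixels_per_point,cutoff,halfwidth Rendering parameters, see
#'   [render_matrix()].
#' @param periodic Periodic distances for the alignment metrics.
#' @export
compute_metric_set.fiber_grid <- function(x, last_selected = NULL,
                                          lra_radius = 200, sra_radius = 20,
                                          curvature_window = 10,
                                          sigma_large = 8, sigma_small = 2,
                                          hdm_threshold = 0.4,
                                          pixels_per_point = 5, cutoff = 25,
                                          halfwidth = 1, periodic = TRUE,
                                          ...) {
  img <- render_matrix(x, last_selected, pixels_per_point, cutoff, halfwidth)
  tibble::tibble(
    lra = alignment_score(x, lra_radius, periodic = periodic),
    sra = alignment_score(x, sra_radius, periodic = periodic),
    hdm = hdm(img, hdm_threshold),
    curv = curvature(img, curvature_window, sigma_large),
    frac = fractal_dimension(img, sigma_small))
}

#' @rdname compute_metric_set
#' @export
compute_metric_set.sim_state <- function(x, ...) {
  compute_metric_set(x$grid, last_selected = x$last_selected, ...)
}

#' @rdname compute_metric_set
#' @param pixel_size Micrometres per pixel for image inputs.
#' @export
compute_metric_set.matrix <- function(x, pixel_size = 1, lra_radius = 200,
                                      sra_radius = 20, curvature_window = 10,
                                      sigma_large = 8, sigma_small = 2,
                                      hdm_threshold = NULL, ...) {
  field <- field_from_image(x, pixel_size = pixel_size)
  tibble::tibble(
    lra = alignment_score(field, lra_radius),
    sra = alignment_score(field, sra_radius),
    hdm = hdm(x, hdm_threshold),
    curv = curvature(x, curvature_window, sigma_large),
    frac = fractal_dimension(x, sigma_small))
}

#' Min-max normalization of metric sets for starplots
#'
#' Rescales each metric column to `[0, 1]` over the compared collection;
#' columns that are constant across the collection map to 0.5.
#'
#' @param metric_sets Data frame of metric sets (rows = matrices).
#' @param metrics Columns to normalize; defaults to the five standard
#'   metrics present.
#' @return The data frame with normalized metric columns.
#' @export
starplot_normalize <- function(metric_sets,
                               metrics = intersect(names(metric_sets),
                                                   c("lra", "sra", "hdm",
                                                     "curv", "frac"))) {
  stopifnot(nrow(metric_sets) >= 2)
  out <- metric_sets
  for (m in metrics) {
    v <- out[[m]]
    rng <- range(v, na.rm = TRUE)
    out[[m]] <- if (diff(rng) == 0) rep(0.5, length(v)) else
      (v - rng[1]) / diff(rng)
  }
  out
}

#' Read a grayscale image
#'
#' Reads PNG (or TIFF when the tiff package is installed) into a numeric
#' matrix in `[0, 1]`; colour channels are averaged.
#'
#' @param path File path.
#' @return Numeric matrix.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("reading TIFF needs the 'tiff' package")
    tiff::readTIFF(path)
  } else {
    png::readPNG(path)
  }
  if (length(dim(img)) == 3) img <- apply(img[, , seq_len(min(3, dim(img)[3])),
                                              drop = FALSE], c(1, 2), mean)
  img
}

#' Write a grayscale image as PNG
#'
#' @param image Numeric matrix; values are clamped to `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gray_png <- function(image, path) {
  png::writePNG(pmax(pmin(image, 1), 0), path)
  invisible(path)
}
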