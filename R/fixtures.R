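# Deterministic synthetic patterns with analytically known metric values;
# these are the ground truth the metric implementations are validated
# against.

draw_segments <- function(img, x0, y0, x1, y1, value = 1) {
  nr <- nrow(img); ncol_ <- ncol(img)
  for (k in seq_along(x0)) {
    len <- sqrt((x1[k] - x0[k])^2 + (y1[k] - y0[k])^2)
    t <- seq(0, 1, length.out = max(2, ceiling(len / 0.4)))
    cc <- round(x0[k] + t * (x1[k] - x0[k]))
    rr <- round(y0[k] + t * (y1[k] - y0[k]))
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= ncol_
    img[cbind(rr[ok], cc[ok])] <- value
  }
  img
}

#' Hilbert curve vertex coordinates
#'
#' 0-based integer coordinates of the `4^order` vertices of the Hilbert
#' space-filling curve on a `2^order` square lattice, in traversal order.
#'
#' @param order Curve order (>= 1).
#' @return A two-column matrix of `x`, `y` coordinates.
#' @export
hilbert_curve <- function(order) {
  stopifnot(order >= 1)
  n <- 2L^order
  t <- 0:(n * n - 1)
  x <- y <- integer(n * n)
  s <- 1L
  while (s < n) {
    rx <- bitwAnd(1L, t %/% 2L)
    ry <- bitwAnd(1L, bitwXor(t, rx))
    flip <- ry == 0L & rx == 1L
    x[flip] <- s - 1L - x[flip]
    y[flip] <- s - 1L - y[flip]
    swap <- ry == 0L
    tmp <- x[swap]; x[swap] <- y[swap]; y[swap] <- tmp
    x <- x + s * rx
    y <- y + s * ry
    t <- t %/% 4L
    s <- s * 2L
  }
  cbind(x = x, y = y)
}

#' Generate a synthetic test pattern
#'
#' Deterministic fixture generator returning an oriented fiber field, a
#' rasterized grayscale image and, where they exist, analytically known
#' metric expectations (with tolerances). Regeneration with identical
#' arguments is bit-identical.
#'
#' @param kind One of `"aligned_stripes"`, `"isotropic"`, `"swirl"`,
#'   `"checkerboard_domains"`, `"circle_arcs"`, `"hilbert_raster"`,
#'   `"blank"`, `"filled"`.
#' @param domain Square domain edge, micrometres.
#' @param pixel_size Micrometres per image pixel.
#' @param n_fibers Fiber count for `"isotropic"`.
#' @param spacing Stripe spacing for `"aligned_stripes"`, micrometres.
#' @param radius Circle radius for `"circle_arcs"`, micrometres.
#' @param order Curve order for `"hilbert_raster"`.
#' @param seed RNG seed used by the random kinds.
#' @return A list with `kind`, `field` (tibble or `NULL`), `image` (matrix),
#'   `expected` (named list of expectations and tolerances), `pixel_size`,
#'   `domain`.
#' @examples
#' fx <- generate_fixture("aligned_stripes")
#' fx$expected$lra
#' @export
generate_fixture <- function(kind = c("aligned_stripes", "isotropic", "swirl",
                                      "checkerboard_domains", "circle_arcs",
                                      "hilbert_raster", "blank", "filled"),
                             domain = 500, pixel_size = 2, n_fibers = 10000,
                             spacing = 20, radius = 120, order = 6,
                             seed = 1) {
  kind <- match.arg(kind)
  npx <- round(domain / pixel_size)
  img <- matrix(0, npx, npx)
  field <- NULL
  expected <- list()
  to_px <- function(u) u / pixel_size

  if (kind == "aligned_stripes") {
    ys <- seq(spacing / 2, domain - spacing / 2, by = spacing)
    xs <- seq(2.5, domain - 2.5, by = 5)
    field <- tibble::tibble(x = rep(xs, times = length(ys)),
                            y = rep(ys, each = length(xs)),
                            theta = 0, weight = 1)
    img <- draw_segments(img, to_px(rep(0, length(ys))), to_px(ys),
                         to_px(rep(domain, length(ys))), to_px(ys))
    expected <- list(lra = 1, sra = 1, tol_align = 1e-9,
                     curv = 0, tol_curv = 2)
  } else if (kind == "isotropic") {
    set.seed(seed)
    field <- tibble::tibble(x = runif(n_fibers, 0, domain),
                            y = runif(n_fibers, 0, domain),
                            theta = runif(n_fibers, 0, pi), weight = 1)
    seg <- 4 # half-length, um
    img <- draw_segments(img,
                         to_px(field$x - seg * cos(field$theta)),
                         to_px(field$y - seg * sin(field$theta)),
                         to_px(field$x + seg * cos(field$theta)),
                         to_px(field$y + seg * sin(field$theta)))
    expected <- list(lra = 0.5, sra = 0.5, tol_align = 0.03)
  } else if (kind == "swirl") {
    ctr <- domain / 2
    radii <- seq(40, domain / 2 - 20, by = 15)
    parts <- lapply(radii, function(r) {
      ang <- seq(0, 2 * pi, length.out = max(16, ceiling(2 * pi * r / 5)))
      ang <- ang[-length(ang)]
      tibble::tibble(x = ctr + r * cos(ang), y = ctr + r * sin(ang),
                     theta = (ang + pi / 2) %% pi, weight = 1)
    })
    field <- do.call(rbind, parts)
    for (r in radii) {
      ang <- seq(0, 2 * pi, length.out = ceiling(2 * pi * r / pixel_size) * 2)
      img <- draw_segments(img,
                           to_px(ctr + r * cos(ang[-length(ang)])),
                           to_px(ctr + r * sin(ang[-length(ang)])),
                           to_px(ctr + r * cos(ang[-1])),
                           to_px(ctr + r * sin(ang[-1])))
    }
    expected <- list(sra_gt_lra = TRUE)
  } else if (kind == "checkerboard_domains") {
    block <- 100
    xs <- seq(2.5, domain - 2.5, by = 5)
    gridpts <- expand.grid(x = xs, y = xs)
    th <- ifelse((floor(gridpts$x / block) + floor(gridpts$y / block)) %% 2 == 0,
                 0, pi / 2)
    field <- tibble::tibble(x = gridpts$x, y = gridpts$y, theta = th,
                            weight = 1)
    seg <- 2.4
    img <- draw_segments(img, to_px(field$x - seg * cos(th)),
                         to_px(field$y - seg * sin(th)),
                         to_px(field$x + seg * cos(th)),
                         to_px(field$y + seg * sin(th)))
    expected <- list(sra_gt_lra = TRUE)
  } else if (kind == "circle_arcs") {
    ctr <- domain / 2
    ang <- seq(0, 2 * pi, length.out = ceiling(2 * pi * radius / pixel_size) * 2)
    img <- draw_segments(img, to_px(ctr + radius * cos(ang[-length(ang)])),
                         to_px(ctr + radius * sin(ang[-length(ang)])),
                         to_px(ctr + radius * cos(ang[-1])),
                         to_px(ctr + radius * sin(ang[-1])))
    pts <- seq(0, 2 * pi, length.out = 200)[-1]
    field <- tibble::tibble(x = ctr + radius * cos(pts),
                            y = ctr + radius * sin(pts),
                            theta = (pts + pi / 2) %% pi, weight = 1)
    # chord of length w on a circle of radius R turns by 2*asin(w / (2R))
    expected <- list(curv_of_window = function(window_px)
      2 * asin(pmin(1, window_px / (2 * to_px(radius)))) * 180 / pi,
      radius_px = to_px(radius), tol_curv_rel = 0.1)
  } else if (kind == "hilbert_raster") {
    xy <- hilbert_curve(order)
    n <- 2^order
    sc <- (npx - 8) / (n - 1)
    px <- 4 + xy[, 1] * sc
    py <- 4 + xy[, 2] * sc
    m <- nrow(xy)
    img <- draw_segments(img, px[-m], py[-m], px[-1], py[-1])
    expected <- list(frac = 2, tol_frac = 0.1)
  } else if (kind == "blank") {
    expected <- list(hdm = 0)
  } else if (kind == "filled") {
    img[] <- 1
    expected <- list(hdm = 100, frac = 2, tol_frac = 0.05)
  }

  list(kind = kind, field = field, image = img, expected = expected,
       pixel_size = pixel_size, domain = domain)
}
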