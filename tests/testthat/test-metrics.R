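test_that("alignment is 1 for identical orientations and 0 for perpendicular neighbours", {
  f <- tibble::tibble(x = runif(50, 0, 100), y = runif(50, 0, 100),
                      theta = 0.8, weight = 1)
  expect_equal(alignment_score(f, 50), 1)
  # perpendicular 4-neighbour lattice: radius catches only cross-oriented cells
  g <- expand.grid(x = seq(5, 95, by = 10), y = seq(5, 95, by = 10))
  g$theta <- ifelse((g$x + g$y) %/% 10 %% 2 == 0, 0, pi / 2)
  g$weight <- 1
  expect_equal(alignment_score(g, 10.5), 0)
})

test_that("uniform random apolar orientations score one half", {
  set.seed(10)
  n <- 8000
  f <- tibble::tibble(x = runif(n, 0, 500), y = runif(n, 0, 500),
                      theta = runif(n, 0, pi), weight = 1)
  expect_equal(alignment_score(f, 30), 0.5, tolerance = 0.03)
})

test_that("alignment is invariant to apolar flips and global rotation", {
  set.seed(11)
  f <- tibble::tibble(x = runif(300, 0, 200), y = runif(300, 0, 200),
                      theta = runif(300, 0, pi), weight = runif(300, 0.5, 2))
  s0 <- alignment_score(f, 60)
  flip <- f
  pick <- sample(300, 120)
  flip$theta[pick] <- flip$theta[pick] + pi
  expect_equal(alignment_score(flip, 60), s0, tolerance = 1e-12)
  rot <- f
  rot$theta <- (rot$theta + 0.71) # acute deviations are rotation-invariant
  expect_equal(alignment_score(rot, 60), s0, tolerance = 1e-12)
})

test_that("the lattice fast path agrees with the brute-force field path", {
  set.seed(12)
  g <- new_fiber_grid(8, 8, 8, spacing = 10)
  g[sample(length(g), 120)] <- runif(120, 0, 5)
  fast <- alignment_score(g, 25, periodic = TRUE)
  field <- fiber_field(g)
  slow <- alignment_score(as.data.frame(field), 25, periodic = TRUE,
                          domain = c(80, 80))
  expect_equal(fast, slow, tolerance = 1e-12)
  # and on the short neighbourhood too
  expect_equal(alignment_score(g, 12, periodic = TRUE),
               alignment_score(as.data.frame(field), 12, periodic = TRUE,
                               domain = c(80, 80)),
               tolerance = 1e-12)
})

test_that("alignment degrades monotonically as random fibers are mixed in", {
  set.seed(13)
  n <- 1500
  base <- tibble::tibble(x = runif(n, 0, 300), y = runif(n, 0, 300),
                         theta = 0.4, weight = 1)
  noise <- runif(n, 0, pi)
  scores <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(q) {
    f <- base
    k <- round(q * n)
    if (k > 0) f$theta[seq_len(k)] <- noise[seq_len(k)]
    alignment_score(f, 50)
  }, numeric(1))
  expect_true(all(diff(scores) < 0))
  expect_equal(scores[1], 1)
  expect_equal(scores[5], 0.5, tolerance = 0.05)
})

test_that("HDM equals a brute-force pixel count at any threshold", {
  expect_equal(hdm(matrix(0, 16, 16), 0.5), 0)
  expect_equal(hdm(matrix(1, 16, 16), 0.5), 100)
  cb <- matrix(rep(c(0, 1), 128), 16, 16)
  expect_equal(hdm(cb, 0.5), 50)
  set.seed(14)
  img <- matrix(runif(400), 20, 20)
  expect_equal(hdm(img, 0.3), 100 * sum(img > 0.3) / 400)
  expect_error(hdm(matrix(numeric(0), 0, 0)), "empty")
  # Otsu default separates a bimodal image
  bim <- matrix(c(rep(0.1, 200), rep(0.9, 200)), 20, 20)
  expect_equal(hdm(bim), 50)
})

test_that("curvature is near zero for straight fibers and follows the chord formula on circles", {
  stripes <- generate_fixture("aligned_stripes")
  expect_lt(curvature(stripes$image, window = 10), 2)
  circ <- generate_fixture("circle_arcs", radius = 120) # 60 px at 2 um/px
  expected <- circ$expected$curv_of_window(10)
  got <- curvature(circ$image, window = 10)
  expect_equal(got, expected, tolerance = 0.1)
  # tighter circles curve more
  small <- generate_fixture("circle_arcs", radius = 70)
  expect_gt(curvature(small$image, window = 10),
            curvature(circ$image, window = 10))
})

test_that("curvature and fractal dimension are translation invariant", {
  img <- matrix(0, 200, 200)
  ang <- seq(0, 2 * pi, length.out = 600)
  img[cbind(round(100 + 50 * sin(ang)), round(100 + 50 * cos(ang)))] <- 1
  img2 <- matrix(0, 200, 200)
  img2[cbind(round(113 + 50 * sin(ang)), round(93 + 50 * cos(ang)))] <- 1
  expect_equal(curvature(img2, 10), curvature(img, 10), tolerance = 0.1)
  expect_equal(fractal_dimension(img2), fractal_dimension(img),
               tolerance = 0.05)
})

test_that("box-counting dimension hits the analytic values", {
  expect_equal(fractal_dimension(line_image(256), blur_sigma = 0), 1,
               tolerance = 0.05)
  expect_equal(fractal_dimension(matrix(1, 256, 256), blur_sigma = 0), 2,
               tolerance = 0.05)
  hb <- generate_fixture("hilbert_raster", order = 6)
  expect_equal(fractal_dimension(hb$image), 2, tolerance = 0.1)
  expect_true(is.na(fractal_dimension(matrix(0, 64, 64), blur_sigma = 0)))
})

test_that("rendering maps density to intensity with the configured cut-off", {
  g <- new_fiber_grid(4, 4, 8, spacing = 10)
  expect_equal(sum(render_matrix(g)), 0) # empty grid -> blank image
  g[1, 2, 3] <- 25
  img <- render_matrix(g)
  expect_equal(max(img), 1) # cut-off density renders at full intensity
  g[1, 2, 3] <- 12.5
  expect_equal(max(render_matrix(g)), 0.5)
  g[1, 2, 3] <- 100
  expect_equal(max(render_matrix(g)), 1) # clamped above the cut-off
  # the segment lives inside its own grid-point block
  blk <- render_matrix(g)
  blk[(2 * 5 + 1):(3 * 5), (1 * 5 + 1):(2 * 5)] <- 0
  expect_equal(sum(blk), 0)
})

test_that("rendering honours the last-selected bin over the densest", {
  g <- new_fiber_grid(2, 1, 8, spacing = 10)
  g[1, 1, 1] <- 20 # horizontal, dense
  g[5, 1, 1] <- 5  # vertical, sparse but most recently selected
  ls <- c(4L, -1L) # 0-based bin 4 = bin 5
  img_sel <- render_matrix(g, last_selected = ls)
  img_max <- render_matrix(g)
  expect_equal(max(img_sel), 5 / 25)
  expect_equal(max(img_max), 20 / 25)
})

test_that("starplot normalization is per-axis min-max with the constant rule", {
  two <- tibble::tibble(lra = c(0.2, 0.8), sra = c(0.5, 0.5),
                        hdm = c(10, 40), curv = c(3, 1), frac = c(1.2, 1.9))
  n <- starplot_normalize(two)
  expect_equal(n$lra, c(0, 1))
  expect_equal(n$sra, c(0.5, 0.5))
  expect_equal(n$curv, c(1, 0))
  three <- tibble::tibble(lra = c(0, 0.25, 1), sra = 1:3, hdm = 1:3,
                          curv = 1:3, frac = 1:3)
  expect_equal(starplot_normalize(three)$lra, c(0, 0.25, 1))
  same <- tibble::tibble(lra = c(1, 1), sra = c(1, 1), hdm = c(1, 1),
                         curv = c(1, 1), frac = c(1, 1))
  expect_true(all(unlist(starplot_normalize(same)[, 1:5]) == 0.5))
})

test_that("image-derived fiber fields recover stripe orientation", {
  stripes <- generate_fixture("aligned_stripes")
  f <- field_from_image(stripes$image, pixel_size = stripes$pixel_size)
  expect_gt(nrow(f), 100)
  # estimated orientations hug 0 (mod pi)
  dev <- pmin(f$theta, pi - f$theta)
  expect_lt(median(dev), 0.2)
})

test_that("metric sets dispatch on grids, states and images", {
  p <- small_params(w_c = 0.05, noise_variance = 0)
  st <- run_simulation(p, steps = 150, seed = 31)
  ms <- compute_metric_set(st)
  expect_named(ms, c("lra", "sra", "hdm", "curv", "frac"))
  expect_true(all(vapply(ms, is.numeric, logical(1))))
  empty <- new_fiber_grid(10, 10, 8, 10)
  ms0 <- compute_metric_set(empty)
  expect_true(is.na(ms0$lra))
  expect_equal(ms0$hdm, 0)
  iso <- generate_fixture("isotropic", n_fibers = 2000)
  msi <- compute_metric_set(iso$image, pixel_size = iso$pixel_size)
  expect_named(msi, c("lra", "sra", "hdm", "curv", "frac"))
})

test_that("grayscale PNG round-trips through the image helpers", {
  img <- matrix(runif(64), 8, 8)
  path <- tempfile(fileext = ".png")
  write_gray_png(img, path)
  back <- read_gray_image(path)
  expect_equal(dim(back), c(8, 8))
  expect_equal(back, img, tolerance = 1 / 255)
})
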