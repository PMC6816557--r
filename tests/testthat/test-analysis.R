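test_that("persistence is exact on canonical geometries", {
  straight <- tibble::tibble(time_min = 0:10 * 15, x = 0:10 * 3, y = 0)
  expect_equal(persistence(straight, window = 5), 1)
  expect_equal(persistence(straight, window = 5, smooth = TRUE), 1,
               tolerance = 1e-6)
  # two equal legs at a right angle
  lpath <- tibble::tibble(time_min = 0:2, x = c(0, 4, 4), y = c(0, 0, 4))
  expect_equal(persistence(lpath, window = 2), sqrt(2) / 2)
  # closed square loop
  loop <- tibble::tibble(time_min = 0:4,
                         x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0))
  expect_equal(persistence(loop, window = 4), 0)
  # stationary track: degenerate convention
  still <- tibble::tibble(time_min = 0:3, x = 0, y = 0)
  expect_equal(persistence(still, window = 3), 1)
  # the literal printed denominator sums net displacements at every lag
  expect_equal(persistence(lpath, window = 2, literal = TRUE),
               4 * sqrt(2) / (4 + 4 * sqrt(2)))
})

test_that("population persistence averages per-cell medians", {
  tr <- rbind(tibble::tibble(time_min = 0:4, cell = 1, x = 0:4, y = 0),
              tibble::tibble(time_min = 0:4, cell = 2,
                             x = c(0, 1, 1, 0, 0), y = c(0, 0, 1, 1, 0)))
  expect_equal(mean_persistence(tr, window = 4), 0.5)
})

test_that("zero-noise lone cells migrate with persistence exactly one", {
  p <- sim_params(n_cells = 5, domain_size = c(2000, 2000),
                  grid_shape = c(20, 20), noise_variance = 0, w_c = 0,
                  w_m = 0)
  st <- run_simulation(p, steps = 30, seed = 8, record_tracks = TRUE)
  expect_equal(mean_persistence(st$tracks, window = 10), 1)
})

test_that("sweeps are deterministic, tidy and skip invalid points", {
  g <- data.frame(noise_variance = 0.1)
  a <- run_sweep(g, base_params = small_params(), reps = 1, base_seed = 5)
  expect_equal(nrow(a), 1)
  b <- run_sweep(g, base_params = small_params(), reps = 1, base_seed = 5)
  expect_identical(a, b)
  g2 <- data.frame(w_c = c(0.03, 0.6), w_m = c(0, 0.6))
  expect_warning(tab <- run_sweep(g2, base_params = small_params(), reps = 1,
                                  base_seed = 5),
                 "skipping")
  expect_equal(nrow(tab), 1)
  expect_error(run_sweep(data.frame(bogus = 1), base_params = small_params()),
               "unknown parameter")
})

test_that("PCA summary matches known covariance structures", {
  tab <- tibble::tibble(lra = 1:30, sra = 2 * (1:30), hdm = -3 * (1:30),
                        curv = 1:30 + 0.5, frac = 0.1 * (1:30))
  expect_equal(pca_summary(tab)$cumulative[1], 1)
  set.seed(15)
  iso <- as.data.frame(matrix(rnorm(5 * 3000), ncol = 5))
  names(iso) <- c("lra", "sra", "hdm", "curv", "frac")
  vf <- pca_summary(iso)$variance_fraction
  expect_equal(unname(vf), rep(0.2, 5), tolerance = 0.06)
  const <- tibble::tibble(lra = rep(1, 10), sra = rnorm(10), hdm = rnorm(10),
                          curv = rnorm(10), frac = rnorm(10))
  expect_warning(res <- pca_summary(const), "constant")
  expect_equal(nrow(res$loadings), 4)
})

test_that("noise calibration recovers the generating variance", {
  p <- sim_params(n_cells = 20, w_c = 0, w_m = 0,
                  domain_size = c(1000, 1000), grid_shape = c(50, 50))
  p$noise_variance <- 0.13
  obs <- simulated_persistence(p, c(60, 120), seed = 99)
  cand <- c(0.01, 0.05, 0.09, 0.13, 0.17, 0.21, 0.25)
  fit <- calibrate_noise(obs, candidates = cand, base_params = p, seed = 1)
  expect_true(fit$estimate %in% c(0.09, 0.13, 0.17)) # within one grid step
  # perfect persistence selects zero noise
  fit0 <- calibrate_noise(c(1, 1), candidates = c(0, 0.1, 0.2),
                          base_params = p, seed = 1)
  expect_equal(fit0$estimate, 0)
  # a one-candidate grid returns that candidate
  one <- calibrate_noise(c(0.8, 0.7), candidates = 0.12, base_params = p,
                         seed = 1)
  expect_equal(one$estimate, 0.12)
})

test_that("feedback calibration recovers w_m and persistence grows with it", {
  p <- sim_params(n_cells = 20, w_c = 0, domain_size = c(1000, 1000),
                  grid_shape = c(50, 50), noise_variance = 0.13)
  sub <- aligned_substrate(50, 50, 8, density = 25, spacing = 20)
  truth <- p
  truth$w_m <- 0.27
  set.seed(55)
  st <- initialize_state(truth)
  st$grid <- sub
  obs <- simulated_persistence(truth, c(60, 120), seed = 55, state = st)
  grid <- c(0.07, 0.17, 0.27, 0.37, 0.47)
  fit <- calibrate_feedback(obs, noise_variance = 0.13, w_m_grid = grid,
                            substrate = sub, base_params = p, seed = 2)
  expect_true(fit$estimate %in% c(0.17, 0.27, 0.37)) # within one grid step
  # on an aligned substrate persistence is non-decreasing in w_m
  sims <- fit$table$sim_120min[match(c(0.07, 0.27, 0.47), fit$table$w_m)]
  expect_true(all(diff(sims) > -0.02))
})

test_that("a null phenotype switch leaves the alignment trend unchanged", {
  p1 <- small_params(n_cells = 20, w_c = 0.03, noise_variance = 0.05,
                     density_feedback = TRUE)
  same <- tibble::tibble(name = "null", noise_variance = 0.05, w_m = p1$w_m,
                         deposition_rate = p1$deposition_rate,
                         degradation_rate = 0, rearrangement_rate = 0)
  res <- remodeling_experiment(phase1_params = p1, conditions = same,
                               phase2_days = 1, reps = 4, seed = 6,
                               metric_days = c(0, 1))
  ts <- res$time_series
  d0 <- ts$lra[ts$day == 0]
  d1 <- ts$lra[ts$day == 1]
  expect_lt(abs(mean(d1) - mean(d0)), 0.15)
  expect_error(remodeling_experiment(phase1_params = p1, conditions = same,
                                     phase2_days = 1, reps = 2,
                                     metric_days = 5),
               "phase2_days")
})
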