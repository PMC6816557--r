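#' Migratory persistence of a track
#'
#' Directionality ratio over sliding windows of `window` steps: net
#' displacement across the window divided by the path length travelled
#' within it (1 for a straight path, 0 for a closed loop). The per-cell
#' value is the median over all sliding windows. Optionally the track is
#' first smoothed with a local-regression spline to suppress small
#' intracellular fluctuations; smoothing is used in the calibration
#' workflows.
#'
#' The printed-form denominator `sum_k |p(t) - p(t-k)|` (a sum of net
#' displacements at every lag, not a path length) is available via
#' `literal = TRUE` for comparison.
#'
#' @param track Data frame with columns `time_min`, `x`, `y` for one cell,
#'   in time order.
#' @param window Window length in steps (samples); the track needs at least
#'   `window + 1` samples.
#' @param smooth Smooth the track first with [stats::loess()]?
#' @param span Loess span.
#' @param literal Use the printed-form denominator instead of path length.
#' @return Median directionality ratio; 1 for a degenerate zero-path window.
#' @examples
#' tr <- tibble::tibble(time_min = 0:10 * 15, x = 0:10 * 5, y = 0)
#' persistence(tr, window = 5) # straight line: 1
#' @export
persistence <- function(track, window, smooth = FALSE, span = 0.5,
                        literal = FALSE) {
  stopifnot(window >= 1, nrow(track) >= window + 1,
            all(diff(track$time_min) > 0))
  x <- track$x
  y <- track$y
  if (smooth && nrow(track) >= 8) {
    t <- track$time_min
    x <- stats::fitted(stats::loess(x ~ t, span = span))
    y <- stats::fitted(stats::loess(y ~ t, span = span))
  }
  n <- length(x)
  steps <- sqrt(diff(x)^2 + diff(y)^2)
  ratios <- vapply((window + 1):n, function(t2) {
    t1 <- t2 - window
    net <- sqrt((x[t2] - x[t1])^2 + (y[t2] - y[t1])^2)
    den <- if (literal) {
      sum(sqrt((x[t2] - x[t1:(t2 - 1)])^2 + (y[t2] - y[t1:(t2 - 1)])^2))
    } else {
      sum(steps[t1:(t2 - 1)])
    }
    if (den <= 0) 1 else net / den
  }, numeric(1))
  stats::median(ratios)
}

#' Population persistence of a track table
#'
#' Mean over cells of the per-cell median directionality ratio.
#'
#' @param tracks Data frame with columns `time_min`, `cell`, `x`, `y` (as
#'   recorded by [run_simulation()]).
#' @param window Window length in steps.
#' @param ... Passed to [persistence()].
#' @return Mean persistence over cells.
#' @export
mean_persistence <- function(tracks, window, ...) {
  vals <- vapply(split(tracks, tracks$cell), function(tr) {
    tr <- tr[order(tr$time_min), ]
    persistence(tr, window, ...)
  }, numeric(1))
  mean(vals)
}

#' Run a parameter sweep
#'
#' Runs `reps` independently seeded simulations for every row of
#' `param_grid` (columns named after [sim_params()] fields override the base
#' configuration) and computes the five matrix metrics at the final frame.
#' Rows whose parameters fail validation (for example `w_c + w_m > 1`) are
#' skipped with a warning. Seeds derive deterministically from `base_seed`,
#' so the whole table is reproducible.
#'
#' @param param_grid Data frame of parameter overrides, one row per point in
#'   parameter space.
#' @param base_params Baseline `"sim_params"` configuration.
#' @param reps Replicate simulations per point.
#' @param base_seed Master seed.
#' @param metric_args List of extra arguments for [compute_metric_set()].
#' @return Long-format tibble: the override columns, `rep`, `seed` and the
#'   five metric columns.
#' @export
run_sweep <- function(param_grid, base_params = sim_params(), reps = 3,
                      base_seed = 1, metric_args = list()) {
  param_grid <- as.data.frame(param_grid)
  stopifnot(nrow(param_grid) >= 1, reps >= 1)
  unknown <- setdiff(names(param_grid), names(unclass(base_params)))
  if (length(unknown) > 0)
    stop("unknown parameter columns: ", paste(unknown, collapse = ", "))
  set.seed(base_seed)
  seeds <- matrix(sample.int(2^31 - 2, nrow(param_grid) * reps),
                  nrow(param_grid), reps)
  rows <- list()
  for (i in seq_len(nrow(param_grid))) {
    p <- base_params
    for (nm in names(param_grid)) p[[nm]] <- param_grid[i, nm]
    p <- tryCatch(validate_params(p), error = function(e) {
      warning(sprintf("skipping sweep row %d: %s", i, conditionMessage(e)),
              call. = FALSE)
      NULL
    })
    if (is.null(p)) next
    for (r in seq_len(reps)) {
      st <- run_simulation(p, seed = seeds[i, r])
      ms <- do.call(compute_metric_set, c(list(st), metric_args))
      rows[[length(rows) + 1]] <-
        tibble::as_tibble(c(as.list(param_grid[i, , drop = FALSE]),
                            list(rep = r, seed = seeds[i, r]), as.list(ms)))
    }
  }
  do.call(rbind, rows)
}

#' PCA summary of a metric table
#'
#' Z-scores the metric columns and runs a principal component analysis;
#' constant columns are dropped with a warning, rows with missing metrics
#' are removed.
#'
#' @param metric_table Data frame containing the metric columns.
#' @param metrics Metric columns to use.
#' @return List with `variance_fraction` (per component), `cumulative`,
#'   `loadings`, `scores` and `n` (rows used).
#' @examples
#' tab <- tibble::tibble(lra = 1:10, sra = (1:10) * 2, hdm = 11:20,
#'                       curv = 10:1, frac = 1:10 * -1)
#' pca_summary(tab)$cumulative[1] # perfectly correlated: PC1 = 100%
#' @export
pca_summary <- function(metric_table,
                        metrics = c("lra", "sra", "hdm", "curv", "frac")) {
  m <- as.data.frame(metric_table)[, metrics, drop = FALSE]
  m <- m[stats::complete.cases(m), , drop = FALSE]
  stopifnot(nrow(m) >= 3)
  const <- vapply(m, function(v) stats::sd(v) == 0, logical(1))
  if (any(const)) {
    warning("dropping constant metric column(s): ",
            paste(names(m)[const], collapse = ", "), call. = FALSE)
    m <- m[, !const, drop = FALSE]
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(variance_fraction = vf, cumulative = cumsum(vf),
       loadings = pc$rotation, scores = pc$x, n = nrow(m))
}

#' Simulated persistence at given window lengths
#'
#' Runs one tracked simulation and returns the population persistence at
#' each window (in minutes of simulated time). Used by the calibration
#' routines.
#'
#' @param params A `"sim_params"` object.
#' @param windows_min Window lengths, minutes.
#' @param seed Integer seed.
#' @param steps Steps to simulate; defaults to six of the longest window.
#' @param smooth Smooth tracks before computing persistence.
#' @param state Optional prepared starting state (e.g. cells on a
#'   substrate).
#' @return Numeric vector of persistences, one per window.
#' @export
simulated_persistence <- function(params, windows_min = c(60, 120), seed = 1,
                                  steps = NULL, smooth = TRUE, state = NULL) {
  if (is.null(steps))
    steps <- as.integer(round(6 * max(windows_min) / params$dt))
  set.seed(seed)
  if (is.null(state)) state <- initialize_state(params)
  st <- run_simulation(params, state = state, steps = steps,
                       record_tracks = TRUE)
  vapply(windows_min, function(wm) {
    w <- max(1L, as.integer(round(wm / params$dt)))
    mean_persistence(st$tracks, w, smooth = smooth)
  }, numeric(1))
}

#' Calibrate the migratory noise variance from persistence
#'
#' Scans candidate values of the per-step noise variance, simulating
#' sub-confluent cells with no cell-cell or matrix guidance, and returns the
#' candidate whose simulated persistence best matches the observed values in
#' the least-squares sense. Common random numbers (one seed for every
#' candidate) keep the objective smooth.
#'
#' @param observed Observed persistence values, one per window.
#' @param windows_min Window lengths, minutes.
#' @param candidates Candidate noise variances.
#' @param base_params Baseline configuration; guidance weights are forced to
#'   zero. `NULL` uses a 30-cell sub-confluent default.
#' @param seed Integer seed.
#' @param smooth Smooth simulated tracks (as tracked-cell data would be).
#' @return List with `estimate` and the candidate `table` (candidate, sse,
#'   simulated persistences).
#' @export
calibrate_noise <- function(observed, windows_min = c(60, 120),
                            candidates = seq(0, 0.3, by = 0.01),
                            base_params = NULL, seed = 1, smooth = TRUE) {
  stopifnot(length(observed) == length(windows_min), length(candidates) >= 1)
  if (is.null(base_params))
    base_params <- sim_params(n_cells = 30, w_c = 0, w_m = 0,
                              domain_size = c(1000, 1000))
  base_params$w_c <- 0
  base_params$w_m <- 0
  sim <- t(vapply(candidates, function(v) {
    p <- base_params
    p$noise_variance <- v
    simulated_persistence(p, windows_min, seed = seed, smooth = smooth)
  }, numeric(length(windows_min))))
  sse <- rowSums((sim - matrix(observed, nrow(sim), length(observed),
                               byrow = TRUE))^2)
  tab <- tibble::tibble(candidate = candidates, sse = sse)
  for (k in seq_along(windows_min))
    tab[[paste0("sim_", windows_min[k], "min")]] <- sim[, k]
  list(estimate = candidates[which.min(sse)], table = tab)
}

#' A uniformly aligned fiber substrate
#'
#' Fiber grid with every point carrying `density` fibers in one bin —
#' the in-silico analogue of a thick pre-aligned matrix.
#'
#' @param nx,ny Grid points.
#' @param n_bins Bins per point.
#' @param density Fibers in the aligned bin.
#' @param bin The aligned bin (1 = orientation 0).
#' @param spacing Grid spacing, micrometres.
#' @return A `"fiber_grid"`.
#' @export
aligned_substrate <- function(nx, ny, n_bins = 8, density = 25, bin = 1,
                              spacing = 10) {
  g <- new_fiber_grid(nx, ny, n_bins, spacing)
  g[bin, , ] <- density
  g
}

#' Calibrate the matrix feedback weight from persistence on a substrate
#'
#' Scans `w_m` candidates for cells of fixed noise variance moving over a
#' thick aligned substrate and returns the least-squares match to the
#' observed persistence values.
#'
#' @param observed Observed persistence values, one per window.
#' @param noise_variance Fixed (previously calibrated) noise variance.
#' @param windows_min Window lengths, minutes.
#' @param w_m_grid Candidate matrix feedback weights.
#' @param substrate A `"fiber_grid"` substrate; `NULL` builds an aligned one
#'   matching `base_params`.
#' @param base_params Baseline configuration; `w_c` is forced to zero.
#'   `NULL` uses a 30-cell sub-confluent default.
#' @param seed Integer seed.
#' @param smooth Smooth simulated tracks.
#' @return List with `estimate` and candidate `table`.
#' @export
calibrate_feedback <- function(observed, noise_variance,
                               windows_min = c(60, 120),
                               w_m_grid = seq(0, 1, by = 0.05),
                               substrate = NULL, base_params = NULL,
                               seed = 1, smooth = TRUE) {
  stopifnot(length(observed) == length(windows_min))
  if (is.null(base_params))
    base_params <- sim_params(n_cells = 30, w_c = 0,
                              domain_size = c(1000, 1000))
  base_params$w_c <- 0
  base_params$noise_variance <- noise_variance
  if (is.null(substrate))
    substrate <- aligned_substrate(base_params$grid_shape[1],
                                   base_params$grid_shape[2],
                                   base_params$n_bins,
                                   spacing = base_params$domain_size[1] /
                                     base_params$grid_shape[1])
  sim <- t(vapply(w_m_grid, function(v) {
    p <- base_params
    p$w_m <- v
    set.seed(seed)
    st <- initialize_state(p)
    st$grid <- substrate
    simulated_persistence(p, windows_min, seed = seed, smooth = smooth,
                          state = st)
  }, numeric(length(windows_min))))
  sse <- rowSums((sim - matrix(observed, nrow(sim), length(observed),
                               byrow = TRUE))^2)
  tab <- tibble::tibble(w_m = w_m_grid, sse = sse)
  for (k in seq_along(windows_min))
    tab[[paste0("sim_", windows_min[k], "min")]] <- sim[, k]
  list(estimate = w_m_grid[which.min(sse)], table = tab)
}

#' Default remodeling phase-2 conditions
#'
#' Zero-noise fibroblasts at three matrix-feedback levels, deposition rate
#' 10, with ("remodel") and without ("static") degradation and
#' rearrangement at rate 5.
#'
#' @return Tibble of phase-2 parameter overrides.
#' @export
remodel_conditions <- function() {
  tibble::tibble(
    name = c("wm0_static", "wm0_remodel", "wm0.2_static", "wm0.2_remodel",
             "wm0.4_static", "wm0.4_remodel"),
    noise_variance = 0,
    w_m = rep(c(0, 0.2, 0.4), each = 2),
    deposition_rate = 10,
    degradation_rate = rep(c(0, 5), 3),
    rearrangement_rate = rep(c(0, 5), 3))
}

#' Two-phase matrix remodeling experiment
#'
#' Phase 1 deposits an initial matrix (dermis-like by default); phase 2
#' re-seeds fresh cells with altered properties on the retained matrix and
#' follows long-range alignment over time. Finishes with a two-tailed
#' Welch t-test of final-day LRA between a chosen pair of conditions
#' (default: remodeling-on vs remodeling-off at `w_m = 0.2`).
#'
#' @param phase1_params Phase-1 configuration.
#' @param conditions Tibble of phase-2 overrides (see
#'   [remodel_conditions()]); must contain a `name` column.
#' @param phase2_days Days simulated after the switch.
#' @param reps Replicates per condition (each with its own phase-1 matrix).
#' @param seed Master seed.
#' @param metric_days Phase-2 days at which LRA is measured (0 = at the
#'   switch).
#' @param test_pair Condition names compared by the final-day t-test.
#' @param lra_radius Neighbourhood length of the LRA metric.
#' @return List with `time_series` (condition, rep, day, lra), `test`
#'   (htest) and `final_day`.
#' @export
remodeling_experiment <- function(phase1_params = tissue_preset("dermis"),
                                  conditions = remodel_conditions(),
                                  phase2_days = 10, reps = 25, seed = 1,
                                  metric_days = c(5, 10),
                                  test_pair = c("wm0.2_remodel",
                                                "wm0.2_static"),
                                  lra_radius = 200) {
  stopifnot("name" %in% names(conditions), phase2_days >= max(metric_days))
  set.seed(seed)
  s1 <- matrix(sample.int(2^31 - 2, reps * nrow(conditions)), reps)
  s2 <- matrix(sample.int(2^31 - 2, reps * nrow(conditions)), reps)
  rows <- list()
  for (r in seq_len(reps)) {
    for (ci in seq_len(nrow(conditions))) {
      st1 <- run_simulation(phase1_params, seed = s1[r, ci])
      p2 <- phase1_params
      for (nm in setdiff(names(conditions), "name"))
        p2[[nm]] <- conditions[[nm]][ci]
      validate_params(p2)
      set.seed(s2[r, ci])
      st <- initialize_state(p2)
      st$grid <- st1$grid
      st$last_selected <- st1$last_selected
      prev <- 0
      for (d in sort(unique(metric_days))) {
        if (d > prev)
          st <- run_simulation(p2, state = st, days = d - prev)
        prev <- d
        rows[[length(rows) + 1]] <- tibble::tibble(
          condition = conditions$name[ci], rep = r, day = d,
          lra = alignment_score(st$grid, lra_radius,
                                periodic = p2$boundary == "periodic"))
      }
    }
  }
  ts <- do.call(rbind, rows)
  final_day <- max(metric_days)
  a <- ts$lra[ts$condition == test_pair[1] & ts$day == final_day]
  b <- ts$lra[ts$condition == test_pair[2] & ts$day == final_day]
  test <- if (length(a) >= 2 && length(b) >= 2)
    stats::t.test(a, b, alternative = "two.sided") else NULL
  list(time_series = ts, test = test, final_day = final_day)
}
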