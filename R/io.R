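STATE_FORMAT_VERSION <- 1L

fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Load a simulation configuration file
#'
#' Reads a YAML configuration whose keys are [sim_params()] arguments (plus
#' an optional `preset` naming a tissue preset to start from) and returns a
#' validated parameter set with defaults filled in. Unknown keys are an
#' error, as is any invalid combination such as `w_c + w_m > 1`.
#'
#' @param path Path to a YAML file.
#' @return A `"sim_params"` object.
#' @export
load_config <- function(path) {
  stopifnot(file.exists(path))
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  preset <- cfg$preset
  cfg$preset <- NULL
  known <- names(formals(sim_params))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0)
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!is.null(preset)) {
    do.call(tissue_preset, c(list(tissue = preset), cfg))
  } else {
    do.call(sim_params, cfg)
  }
}

#' Save a simulation state as plain text
#'
#' Writes `cells.csv` (one row per cell), `grid.tsv` (one row per grid point
#' in row-major order, one column per orientation bin) and `meta.json`
#' (grid geometry, simulated time, last-selected bins and the RNG state) so
#' that a run can be resumed bit-identically.
#'
#' @param state A `"sim_state"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_state <- function(state, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cells <- data.frame(cell = seq_along(state$x), x = fmt_num(state$x),
                      y = fmt_num(state$y), theta = fmt_num(state$theta),
                      speed = fmt_num(state$speed), ux = fmt_num(state$ux),
                      uy = fmt_num(state$uy))
  write.csv(cells, file.path(dir, "cells.csv"), row.names = FALSE,
            quote = FALSE)
  nb <- dim(state$grid)[1]
  gm <- t(matrix(as.numeric(state$grid), nrow = nb))
  utils::write.table(matrix(fmt_num(gm), nrow = nrow(gm)),
                     file.path(dir, "grid.tsv"), sep = "\t",
                     row.names = FALSE, col.names = paste0("bin", seq_len(nb)),
                     quote = FALSE)
  meta <- list(format_version = STATE_FORMAT_VERSION,
               time_min = state$time_min,
               nx = dim(state$grid)[2], ny = dim(state$grid)[3],
               n_bins = nb, spacing = attr(state$grid, "spacing"),
               last_selected = as.integer(state$last_selected),
               rng_state = if (exists(".Random.seed", globalenv()))
                 get(".Random.seed", globalenv()) else NULL)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' Load a saved simulation state
#'
#' Restores a state written by [save_state()], including the RNG stream
#' position, so that a resumed run continues exactly as the uninterrupted
#' one would have.
#'
#' @param dir Directory written by [save_state()].
#' @return A `"sim_state"`.
#' @export
load_state <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  if (is.null(meta$format_version) ||
      meta$format_version != STATE_FORMAT_VERSION)
    stop("state format version mismatch", call. = FALSE)
  cells <- read.csv(file.path(dir, "cells.csv"))
  gm <- as.matrix(utils::read.table(file.path(dir, "grid.tsv"), sep = "\t",
                                    header = TRUE))
  grid <- array(as.numeric(t(gm)), dim = c(meta$n_bins, meta$nx, meta$ny))
  attr(grid, "spacing") <- meta$spacing
  class(grid) <- c("fiber_grid", "array")
  if (!is.null(meta$rng_state))
    assign(".Random.seed", as.integer(meta$rng_state), envir = globalenv())
  st <- list(x = as.numeric(cells$x), y = as.numeric(cells$y),
             theta = as.numeric(cells$theta),
             speed = as.numeric(cells$speed), ux = as.numeric(cells$ux),
             uy = as.numeric(cells$uy), grid = grid,
             last_selected = as.integer(meta$last_selected),
             time_min = meta$time_min)
  class(st) <- "sim_state"
  st
}

#' Write a run manifest
#'
#' JSON inventory of a run: configuration snapshot, seed, package version,
#' simulated time span, files written and wall-clock seconds. Written last,
#' so its presence marks a complete output directory.
#'
#' @param dir Output directory.
#' @param params The `"sim_params"` used (or `NULL`).
#' @param seed Seed used.
#' @param outputs Character vector of files written (relative to `dir`).
#' @param started `Sys.time()` at run start.
#' @param time_min Simulated minutes covered.
#' @return Path of the manifest, invisibly.
#' @export
write_manifest <- function(dir, params, seed, outputs, started,
                           time_min = NA) {
  man <- list(package = "matrixflock",
              version = as.character(utils::packageVersion("matrixflock")),
              seed = seed, config = unclass(params),
              simulated_minutes = time_min, outputs = outputs,
              wall_clock_s = as.numeric(difftime(Sys.time(), started,
                                                 units = "secs")))
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
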