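#' Run configuration
#'
#' A run is described by a YAML file with the sections below; unknown keys
#' are rejected and model parameters default to the packaged values.
#'
#' ```yaml
#' model: fhn            # heat | cubic_cable | fhn
#' geometry:
#'   kind: grid          # grid | irregular | ventricle | file
#'   bounds: [[0,0,0],[60,60,60]]
#'   counts: [10,10,10]
#' mls: {d_max: 2.0, weight: cubic, basis: linear}
#' quadrature: {cells_per_axis: 9, points_per_axis: 2}
#' diffusion: {sigma_f: 4.0, sigma_cf: 1.0, isotropic: false}
#' integrator: {method: rk4, t_end: 300, rtol: 1.0e-5, atol: 1.0e-7}
#' stimulus: {mode: initial_value, amplitude: 0.5, face_axis: 1}
#' output: {dir: out, snapshot_times: [47, 95, 176, 236]}
#' seed: 1
#' ```
#'
#' @name config
#' @keywords internal
NULL

config_schema <- function() {
  list(
    model = c("heat", "cubic_cable", "fhn"),
    geometry = c("kind", "bounds", "counts", "n", "min_spacing", "path",
                 "epi_axes", "endo_axes", "base_z", "helix_range"),
    mls = c("d_max", "weight", "basis"),
    quadrature = c("cells_per_axis", "points_per_axis"),
    diffusion = c("sigma_f", "sigma_cf", "isotropic"),
    ionic = c("g", "v_th", "v_p", "C_m", "A_m", "v_rest",
              "a", "b", "c1", "c2", "d", "sigma_f", "sigma_cf"),
    integrator = c("method", "dt", "n_steps", "t_end", "rtol", "atol"),
    stimulus = c("mode", "nodes", "amplitude", "onset", "duration",
                 "face_axis", "fraction"),
    output = c("dir", "snapshot_times"),
    seed = NULL)
}

#' Load and validate a run configuration
#'
#' @param path YAML file path.
#' @return validated `run_config` list with model defaults filled in.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("load_config: no such file: ", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname load_config
#' @param cfg configuration list (as parsed from YAML).
#' @export
validate_config <- function(cfg) {
  schema <- config_schema()
  unknown <- setdiff(names(cfg), names(schema))
  if (length(unknown))
    stop("config: unknown key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$model) || !cfg$model %in% schema$model)
    stop("config: 'model' must be one of ", paste(schema$model, collapse = ", "))
  for (sec in c("geometry", "mls", "quadrature", "diffusion", "ionic",
                "integrator", "stimulus", "output")) {
    bad <- setdiff(names(cfg[[sec]]), schema[[sec]])
    if (length(bad))
      stop(sprintf("config: unknown key(s) in '%s': %s", sec,
                   paste(bad, collapse = ", ")))
  }
  mls <- cfg$mls %||% list()
  mls$d_max <- mls$d_max %||% 2.0
  if (!is.numeric(mls$d_max) || mls$d_max <= 0)
    stop("config: 'd_max' must be a positive number")
  mls$weight <- mls$weight %||% "cubic"
  if (!mls$weight %in% c("cubic", "quartic"))
    stop("config: 'weight' must be cubic or quartic")
  mls$basis <- mls$basis %||% "linear"
  if (!mls$basis %in% c("linear", "quadratic"))
    stop("config: 'basis' must be linear or quadratic")
  cfg$mls <- mls
  quad <- cfg$quadrature %||% list()
  quad$points_per_axis <- quad$points_per_axis %||% 2L
  if (!quad$points_per_axis %in% 1:4)
    stop("config: 'points_per_axis' must be in 1..4")
  cfg$quadrature <- quad
  ion <- cfg$ionic %||% list()
  cfg$ionic <- if (cfg$model == "fhn") {
    utils::modifyList(unclass(fhn_params()), ion)
  } else if (cfg$model == "cubic_cable") {
    utils::modifyList(unclass(cubic_ionic_params()), ion)
  } else ion
  diff <- cfg$diffusion %||% list()
  diff$sigma_f <- diff$sigma_f %||% (if (cfg$model == "fhn") 4.0 else 0.5)
  diff$sigma_cf <- diff$sigma_cf %||% (if (cfg$model == "fhn") 1.0 else diff$sigma_f)
  diff$isotropic <- isTRUE(diff$isotropic)
  if (diff$sigma_f <= 0 || diff$sigma_cf <= 0)
    stop("config: 'sigma_f'/'sigma_cf' must be positive")
  cfg$diffusion <- diff
  stim <- cfg$stimulus %||% list()
  if (!is.null(stim$duration) && stim$duration < 0)
    stop("config: stimulus 'duration' must be >= 0")
  stim$mode <- stim$mode %||% "initial_value"
  stim$amplitude <- stim$amplitude %||% (if (cfg$model == "fhn") 0.5 else 100)
  cfg$stimulus <- stim
  cfg$integrator <- cfg$integrator %||% list()
  cfg$integrator$method <- cfg$integrator$method %||%
    (if (cfg$model == "fhn") "rk4" else "euler")
  cfg$seed <- cfg$seed %||% 1L
  structure(cfg, class = "run_config")
}

#' @rdname load_config
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Write a point cloud with data as a legacy VTK (ASCII) file
#'
#' POLYDATA point set with optional per-node scalar fields and vector
#' fields; readable by ParaView for Fig-style snapshot rendering.
#'
#' @param path output file.
#' @param cloud a [node_cloud()]
#' @param scalars named list of numeric vectors (per node).
#' @param vectors named list of n x 3 matrices.
#' @param title dataset title line.
#' @export
write_vtk_points <- function(path, cloud, scalars = list(), vectors = list(),
                             title = "efgm point cloud") {
  pos <- cloud$positions
  if (ncol(pos) < 3) pos <- cbind(pos, matrix(0, nrow(pos), 3 - ncol(pos)))
  n <- nrow(pos)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", title, "ASCII",
               "DATASET POLYDATA", sprintf("POINTS %d float", n)), con)
  utils::write.table(format(pos, scientific = TRUE, digits = 8), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("VERTICES %d %d", n, 2 * n), con)
  utils::write.table(cbind(1L, seq_len(n) - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  if (length(scalars) || length(vectors))
    writeLines(sprintf("POINT_DATA %d", n), con)
  for (nm in names(scalars)) {
    writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(format(scalars[[nm]], scientific = TRUE, digits = 8), con)
  }
  for (nm in names(vectors)) {
    writeLines(sprintf("VECTORS %s float", nm), con)
    utils::write.table(format(vectors[[nm]], scientific = TRUE, digits = 8),
                       con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write snapshot frames of a trace as VTK files
#'
#' @param trace a `sim_trace` with a `snapshots` attribute (from
#'   [integrate_rk4_adaptive()]) or recorded samples.
#' @param cloud the [node_cloud()]
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return written paths.
#' @export
write_snapshots <- function(trace, cloud, dir, prefix = "frame") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  snaps <- attr(trace, "snapshots")
  if (is.null(snaps))
    snaps <- lapply(seq_along(trace$times), function(k)
      list(time = trace$times[k], v = trace$V[k, ]))
  paths <- character(0)
  for (s in snaps) {
    p <- file.path(dir, sprintf("%s_t%07.2fms.vtk", prefix, s$time))
    write_vtk_points(p, cloud, scalars = list(vm = s$v),
                     title = sprintf("v_m at t = %.2f ms", s$time))
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Export an activation map as CSV
#' @param map an [activation_times()] result.
#' @param cloud the [node_cloud()]
#' @param path output CSV.
#' @export
write_activation_csv <- function(map, cloud, path) {
  d <- cloud$dim
  tab <- data.frame(id = cloud$ids)
  cn <- c("x", "y", "z")[seq_len(d)]
  for (k in seq_len(d)) tab[[cn[k]]] <- cloud$positions[, k]
  tab$activation_time_ms <- map$time
  tab$not_activated <- map$not_activated
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest
#'
#' Records the configuration echo, package version and seed so a
#' deterministic run can be reproduced byte-identically.
#'
#' @param config configuration list.
#' @param dir output directory.
#' @param seed RNG seed used.
#' @export
write_manifest <- function(config, dir, seed = config$seed %||% NA) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(package = "efgm",
         version = as.character(utils::packageVersion("efgm")),
         seed = seed, config = unclass(config)),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  invisible(file.path(dir, "manifest.json"))
}
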