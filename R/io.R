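#' Load and validate a configuration file
#'
#' Reads a JSON or YAML configuration with up to three sections --
#' `geometry`, `simulation`, and `sweep` -- whose keys are exactly the
#' arguments of [geometry_params()], [simulation_config()], and
#' [sweep_spec()] (the sweep's base config and geometry come from the
#' other two sections). Missing keys take the documented defaults;
#' unknown keys are rejected with their paths.
#'
#' @param path Path to a `.json`, `.yaml`, or `.yml` file.
#' @return List with validated `geometry`, `simulation`, and (if present)
#'   `sweep` objects, plus `raw`, the normalized key-value content (all
#'   defaults applied) that [dump_config()] writes back.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config format '.", ext, "' (use JSON or YAML)"))
  if (!is.list(raw)) stop("config must be a mapping of sections")
  unknown <- setdiff(names(raw), c("geometry", "simulation", "sweep"))
  if (length(unknown))
    stop("unknown top-level section(s): ", paste(unknown, collapse = ", "))

  norm_section <- function(section, fn, drop = character()) {
    given <- raw[[section]]
    if (is.null(given)) given <- list()
    allowed <- setdiff(names(formals(fn)), drop)
    bad <- setdiff(names(given), allowed)
    if (length(bad))
      stop("unknown key(s) in '", section, "': ",
           paste(paste0(section, ".", bad), collapse = ", "))
    defaults <- lapply(formals(fn)[allowed], function(d)
      if (is.call(d) || is.symbol(d)) eval(d) else d)
    modifyList(defaults[!vapply(defaults, is.null, logical(1))], given)
  }

  geo_raw <- norm_section("geometry", geometry_params)
  sim_raw <- norm_section("simulation", simulation_config)
  out <- list(
    geometry = do.call(geometry_params, geo_raw),
    simulation = do.call(simulation_config, sim_raw),
    raw = list(geometry = geo_raw, simulation = sim_raw)
  )
  if (!is.null(raw$sweep)) {
    sw_raw <- norm_section("sweep", sweep_spec,
                           drop = c("base_config", "base_geometry_params"))
    out$sweep <- do.call(sweep_spec, c(sw_raw, list(
      base_config = out$simulation, base_geometry_params = out$geometry)))
    out$raw$sweep <- sw_raw
  }
  out
}

#' Write a normalized configuration back to disk
#'
#' Writes the `raw` element of a [load_config()] result (all defaults
#' applied) as JSON, so that `load_config(dump_config(cfg, f))` is a
#' fixed point.
#'
#' @param config A [load_config()] result (or any list with a `raw`
#'   element of the same shape).
#' @param path Output path (JSON).
#' @return `path`, invisibly.
#' @export
dump_config <- function(config, path) {
  raw <- if (!is.null(config$raw)) config$raw else config
  jsonlite::write_json(raw, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Write a geometry to CSV (with a JSON sidecar)
#'
#' The CSV holds one sphere per row (`x,y,z,radius,kind`, lengths in um,
#' kind `neuronal`/`astroglial`); the `<path>.json` sidecar holds the
#' parameters, seed, and realized fractions needed to rebuild the object.
#'
#' @param geometry A `neuropil_geometry`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_geometry_csv <- function(geometry, path) {
  stopifnot(inherits(geometry, "neuropil_geometry"))
  df <- data.frame(
    x = geometry$centers[, 1], y = geometry$centers[, 2],
    z = geometry$centers[, 3], radius = geometry$radii,
    kind = c("neuronal", "astroglial")[geometry$kinds])
  write.csv(df, path, row.names = FALSE)
  side <- list(params = unclass(geometry$params), seed = geometry$seed,
               realized_alpha = geometry$realized_alpha,
               realized_astro_fraction = geometry$realized_astro_fraction,
               se_alpha = geometry$se_alpha, n_spheres = geometry$n_spheres)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a geometry written by [write_geometry_csv()]
#'
#' @param path CSV path (the `<path>.json` sidecar must sit beside it).
#' @return A `neuropil_geometry`.
#' @export
read_geometry_csv <- function(path) {
  df <- read.csv(path)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  params <- structure(side$params, class = "geometry_params")
  structure(list(
    params = params,
    centers = unname(as.matrix(df[, c("x", "y", "z")])),
    radii = df$radius,
    kinds = ifelse(df$kind == "astroglial", 2L, 1L),
    cleft = list(center = c(0, 0, 0), radius = params$cleft_radius,
                 half_height = params$cleft_half_height, axis = c(0, 0, 1)),
    realized_alpha = side$realized_alpha,
    realized_astro_fraction = side$realized_astro_fraction,
    realized_neuronal_fraction =
      1 - side$realized_alpha - side$realized_astro_fraction,
    se_alpha = side$se_alpha,
    n_spheres = nrow(df),
    seed = side$seed,
    cell_edge = .cell_edge(params)
  ), class = "neuropil_geometry")
}

#' Write a particle snapshot as CSV
#'
#' Columns `x,y,z` (um) and `state` (`free`/`bound`).
#'
#' @param snapshot A `particle_ensemble`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_snapshot_csv <- function(snapshot, path) {
  stopifnot(inherits(snapshot, "particle_ensemble"))
  df <- data.frame(x = snapshot$positions[, 1], y = snapshot$positions[, 2],
                   z = snapshot$positions[, 3],
                   state = c("free", "bound")[snapshot$state + 1L])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a particle snapshot as an XYZ point cloud
#'
#' Plain XYZ text (count, comment, then `LABEL x y z` lines, labels `GLF`
#' for free and `GLB` for bound), loadable by common point-cloud viewers.
#'
#' @param snapshot A `particle_ensemble`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snapshot_xyz <- function(snapshot, path) {
  stopifnot(inherits(snapshot, "particle_ensemble"))
  n <- nrow(snapshot$positions)
  lab <- c("GLF", "GLB")[snapshot$state + 1L]
  lines <- c(as.character(n),
             sprintf("glutamate snapshot t=%g ms (um)", snapshot$time),
             sprintf("%s %.6f %.6f %.6f", lab, snapshot$positions[, 1],
                     snapshot$positions[, 2], snapshot$positions[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Write a concentration profile as tidy CSV
#'
#' Columns: `time_ms`, `r_um`, `dist_um`, `free_uM`, `bound_uM`, `ratio`,
#' `free_se`, `bound_se`.
#'
#' @param profile A `concentration_profile`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  stopifnot(inherits(profile, "concentration_profile"))
  df <- data.frame(
    time_ms = attr(profile, "time"),
    r_um = profile$r_mid, dist_um = profile$dist,
    free_uM = profile$free_uM, bound_uM = profile$bound_uM,
    ratio = profile$free_uM / profile$bound_uM,
    free_se = if (!is.null(profile$free_se)) profile$free_se else NA_real_,
    bound_se = if (!is.null(profile$bound_se)) profile$bound_se else NA_real_)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a sweep result as long-format CSV
#'
#' @param sweep A `psi_alpha_sweep`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "psi_alpha_sweep"))
  write.csv(sweep$table, path, row.names = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON provenance record referencing every output of a run: package
#' version, timestamp, seed, config file checksum, and output paths.
#'
#' @param path Manifest path (JSON).
#' @param seed Seed(s) used.
#' @param config_path Optional path of the config file (an md5 checksum is
#'   recorded).
#' @param outputs Character vector of produced files.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, seed, config_path = NULL,
                           outputs = character()) {
  m <- list(
    package = "neuropilsim",
    version = as.character(utils::packageVersion("neuropilsim")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = if (!is.null(config_path))
      list(path = config_path,
           md5 = unname(tools::md5sum(config_path))),
    outputs = outputs)
  jsonlite::write_json(m[!vapply(m, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
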