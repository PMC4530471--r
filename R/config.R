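#' Run configuration
#'
#' A flat record of the knobs shared across pipeline stages, echoed
#' into every run log so results can be regenerated.
#'
#' @param random_seed integer seed.
#' @param angular_step docking orientation spacing, degrees.
#' @param voxel_size map grid spacing, Angstrom.
#' @param resolution blurring resolution, Angstrom.
#' @param forster_radius Forster distance R0, Angstrom (default 59,
#'   the AF488/Cy3NTA pair).
#' @param grid_step_locus trilateration locus voxel, Angstrom.
#' @param output_dir directory for artifacts.
#' @return An object of class `run_config`.
#' @export
run_config <- function(random_seed = 1L, angular_step = 20,
                       voxel_size = 1.5, resolution = 6,
                       forster_radius = 59, grid_step_locus = 2,
                       output_dir = ".") {
  num <- c(angular_step = angular_step, voxel_size = voxel_size,
           resolution = resolution, forster_radius = forster_radius,
           grid_step_locus = grid_step_locus)
  if (any(num <= 0)) stop("all step/size fields must be > 0")
  structure(list(random_seed = as.integer(random_seed),
                 angular_step = angular_step, voxel_size = voxel_size,
                 resolution = resolution, forster_radius = forster_radius,
                 grid_step_locus = grid_step_locus,
                 output_dir = output_dir),
            class = "run_config")
}

#' Read a run configuration from JSON
#' @param path JSON file mirroring the [run_config()] fields.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, x[intersect(names(x), names(formals(run_config)))])
}

#' Write a run log
#'
#' Records the configuration, package version, and R version alongside
#' each analysis artifact.
#'
#' @param config a `run_config`.
#' @param path output JSON file.
#' @param extra optional named list merged into the log.
#' @return The path, invisibly.
#' @export
write_run_log <- function(config, path, extra = list()) {
  log <- c(unclass(config),
           list(package_version =
                  as.character(utils::packageVersion("fretdock")),
                r_version = R.version.string,
                timestamp = format(Sys.time(), tz = "UTC")),
           extra)
  jsonlite::write_json(log, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
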