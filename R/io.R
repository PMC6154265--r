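# format doubles with 17 significant digits so the CSV round-trips to the
# exact binary value
.lossless <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      df[[nm]] <- sprintf("%.17g", df[[nm]])
    }
  }
  df
}

# serialise a simulation_config to plain lists (JSON-ready)
config_to_list <- function(cfg) {
  g <- cfg$geometry
  list(
    geometry = list(R1 = g$R1, R_int = g$R_int, R2 = g$R2,
                    n_inner = length(g$xi_in), n_outer = length(g$xi_out)),
    material = unclass(cfg$material),
    rates = unclass(cfg$rates),
    stimuli = unclass(cfg$stimuli),
    protocol = list(event_times = cfg$protocol$event_times,
                    sigma = cfg$protocol$sigma, d = cfg$protocol$d,
                    challenge_window = cfg$protocol$challenge_window,
                    horizon = cfg$protocol$horizon),
    loads = unclass(cfg$loads),
    mode = cfg$mode,
    sbm_thickening = cfg$sbm_thickening,
    dt = cfg$dt,
    closure_radius = cfg$closure_radius,
    snapshot_days = cfg$snapshot_days,
    store_every = cfg$store_every
  )
}

config_from_list <- function(x, source = "config") {
  known <- c("geometry", "material", "rates", "stimuli", "protocol", "loads",
             "mode", "sbm_thickening", "dt", "closure_radius",
             "snapshot_days", "store_every")
  extra <- setdiff(names(x), known)
  if (length(extra)) {
    rlang::abort(sprintf("Unknown key(s) in %s: %s", source,
                         paste(extra, collapse = ", ")),
                 class = "airwaymorph_config_error")
  }
  check_block <- function(block, fn_formals, label) {
    extra <- setdiff(names(block), fn_formals)
    if (length(extra)) {
      rlang::abort(sprintf("Unknown key(s) in %s$%s: %s", source, label,
                           paste(extra, collapse = ", ")),
                   class = "airwaymorph_config_error")
    }
    block
  }
  args <- list()
  if (!is.null(x$geometry)) {
    gb <- check_block(x$geometry,
                      c("R1", "R_int", "R2", "n_inner", "n_outer"), "geometry")
    args$geometry <- do.call(grown_geometry, gb)
  }
  build <- function(name, ctor, drop = character(0)) {
    if (is.null(x[[name]])) return(NULL)
    b <- x[[name]]
    b <- b[setdiff(names(b), drop)]
    b <- check_block(b, names(formals(ctor)), name)
    do.call(ctor, b)
  }
  if (!is.null(x$material)) args$material <- build("material", material_params)
  if (!is.null(x$rates)) args$rates <- build("rates", rate_params)
  if (!is.null(x$stimuli)) args$stimuli <- build("stimuli", stimulus_params)
  if (!is.null(x$protocol)) args$protocol <- build("protocol", challenge_protocol)
  if (!is.null(x$loads)) args$loads <- build("loads", load_case)
  for (nm in c("mode", "sbm_thickening", "dt", "closure_radius",
               "snapshot_days", "store_every")) {
    if (!is.null(x[[nm]])) args[[nm]] <- x[[nm]]
  }
  do.call(simulation_config, args)
}

#' Load a simulation configuration from JSON
#'
#' Reads and validates a run configuration. Missing blocks are filled with
#' package defaults; unknown keys, unit-incompatible values or invariant
#' violations (e.g. `c_pc <= c_p0`) fail hard with a message naming the
#' offending key.
#'
#' @param path Path to a JSON file.
#' @return A validated [simulation_config()].
#' @seealso [save_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Config file not found: %s", path),
                 class = "airwaymorph_config_error")
  }
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  config_from_list(x, source = basename(path))
}

#' Save a simulation configuration to JSON
#'
#' @param cfg A [simulation_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(config_to_list(cfg), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Write simulation results to disk
#'
#' Writes the time series and the transmural snapshots as CSV (full
#' double precision; readable back losslessly) plus a JSON run manifest
#' sufficient to reproduce the run: the full configuration, package
#' version, flags and the output file index.
#'
#' @param result An `airway_sim` result.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  f_series <- file.path(dir, "series.csv")
  readr::write_csv(.lossless(result$series), f_series)
  files <- c(files, f_series)
  if (nrow(result$snapshots %||% tibble::tibble())) {
    for (d in unique(result$snapshots$day)) {
      f <- file.path(dir, sprintf("snapshot_day_%g.csv", d))
      readr::write_csv(.lossless(result$snapshots[result$snapshots$day == d, ]), f)
      files <- c(files, f)
    }
  }
  manifest <- list(
    package = "airwaymorph",
    version = as.character(utils::packageVersion("airwaymorph")),
    config = config_to_list(result$config),
    closed = result$closed,
    aborted = result$aborted,
    diagnostic = result$diagnostic,
    last_event_time = result$last_event_time,
    files = basename(files),
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  f_manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, f_manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, f_manifest))
}
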