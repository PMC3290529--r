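#' Load an experiment configuration from YAML or JSON
#'
#' Any subset of [experiment_config()] fields may be given; missing fields
#' take the model defaults, so an empty file yields the default
#' configuration.  Unknown or ill-typed fields are reported with their
#' names.
#'
#' @param path path to a `.yaml`/`.yml`/`.json` file.
#' @return An [experiment_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  # YAML 1.1 would read the bare grid-side key `N` as boolean; keep single
  # letters literal
  keep_letters <- list(
    "bool#no" = function(x) if (x %in% c("n", "N")) x else FALSE,
    "bool#yes" = function(x) if (x %in% c("y", "Y")) x else TRUE)
  x <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path, handlers = keep_letters)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported config format: ", ext)
  if (is.null(x)) x <- list()
  if (!is.list(x)) stop("config must be a mapping of fields to values")
  neuron_fields <- c("a", "b", "c", "d", "v_peak", "capacitance")
  known <- setdiff(names(formals(experiment_config)), "params")
  bad <- setdiff(names(x), c(known, "params", neuron_fields))
  if (length(bad))
    stop("unknown config fields: ", paste(bad, collapse = ", "))
  pargs <- x[names(x) %in% neuron_fields]
  if (!is.null(x$params)) pargs <- utils::modifyList(pargs, x$params)
  x <- x[names(x) %in% known]
  x$params <- do.call(izhikevich_params, pargs)
  tryCatch(do.call(experiment_config, x),
           error = function(e) stop("invalid config (", path, "): ",
                                    conditionMessage(e)))
}

#' Write / read experiment result tables
#'
#' Plain CSV round-trip of the tidy result tables the `run_*` experiment
#' functions produce.  An empty table writes a header-only file.
#'
#' @param result a data.frame.
#' @param path CSV path.
#' @return `write_results()` returns the path invisibly; `read_results()`
#'   the data.frame.
#' @export
write_results <- function(result, path) {
  utils::write.csv(as.data.frame(result), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read a spike raster as a CSV event list
#'
#' The raster is stored as one row per spike (`t_ms`, `channel`, `layer`,
#' `row`, `col`) with the grid geometry in a JSON sidecar (`<path>.meta.json`)
#' so the round-trip is lossless.  A `.gz` suffix compresses the event list.
#'
#' @param raster a `spike_raster` from [run_network()].
#' @param path output CSV path (optionally ending `.gz`).
#' @return `write_raster()` returns the path invisibly; `read_raster()` the
#'   `spike_raster`.
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  df <- data.frame(t_ms = raster$t_ms, channel = raster$channel,
                   layer = raster$layer, row = raster$row, col = raster$col)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  meta <- list(N = attr(raster, "N"), dt = attr(raster, "dt"),
               n_steps = attr(raster, "n_steps"),
               n_channels = attr(raster, "n_channels"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  df <- utils::read.csv(con)
  df$step <- as.integer(round(df$t_ms / meta$dt)) + 1L
  df <- df[, c("step", "t_ms", "channel", "layer", "row", "col")]
  structure(df, N = meta$N, dt = meta$dt, n_steps = meta$n_steps,
            n_channels = meta$n_channels,
            class = c("spike_raster", "data.frame"))
}

#' Run manifest
#'
#' A reproducibility record for a batch of runs: the configuration snapshot,
#' the derived per-condition seeds, output paths and timing.  Every
#' stochastic result row is traceable to a seed listed here.
#'
#' @param config the [experiment_config()] used.
#' @param seeds named list/vector of seeds actually used.
#' @param outputs named list of output paths.
#' @param wall_time_s elapsed wall time in seconds.
#' @return An object of class `run_manifest`.
#' @export
run_manifest <- function(config, seeds = list(), outputs = list(),
                         wall_time_s = NA_real_) {
  snap <- unclass(config)
  snap$params <- unclass(snap$params)
  structure(list(config = snap, seeds = seeds, outputs = outputs,
                 wall_time_s = wall_time_s,
                 package_version = as.character(utils::packageVersion("spikemask")),
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
            class = "run_manifest")
}

#' @rdname run_manifest
#' @param manifest a `run_manifest`.
#' @param path JSON output path.
#' @export
write_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "run_manifest"))
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
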