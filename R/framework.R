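# Shared plumbing: run configs, seeded fixtures, raster IO, sidecars.

run_config_schema <- function(model) {
  params <- switch(model,
    mito = c(as.list(mito_params()), unclass(energy_budget())),
    account = list(theta_ret = 0.15, theta_fet = -0.15, refractory = 5,
                   baseline_cost = 0.01, q = 0.3, q_kernel_duration = 20,
                   c_bar = 0.05, c_max = 0.1, tau_atp = 50,
                   tau_ros = 100, ros_min = 0.1, v_slope = 20),
    channel = c(unclass(channel_params()), list(rho = 0)),
    net = unclass(reduced_network_config()),
    aval = list(bin_ms = 1, min_obs = 50, min_tail = 50,
                gof_cutoff = 0.03),
    stop("unknown model `", model, "`; expected one of ",
         "mito, account, channel, net, aval", call. = FALSE))
  params
}

#' Default run configuration for a model
#'
#' @param model one of `"mito"`, `"account"`, `"channel"`, `"net"`,
#'   `"aval"`.
#' @return A list of class `"run_config"` with fields `model`,
#'   `params`, `duration`, `dt`, `seed`, `out_dir`, `record_every`.
#' @export
default_config <- function(model) {
  structure(list(model = model, params = run_config_schema(model),
                 duration = 1000, dt = 0.1, seed = 1L, out_dir = ".",
                 record_every = 10L),
            class = "run_config")
}

validate_config <- function(cfg) {
  top <- c("model", "params", "duration", "dt", "seed", "out_dir",
           "record_every")
  extra <- setdiff(names(cfg), top)
  if (length(extra))
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  if (is.null(cfg$model)) stop("config must name a `model`", call. = FALSE)
  defaults <- default_config(cfg$model)
  schema <- defaults$params
  if (!is.null(cfg$params)) {
    bad <- setdiff(names(cfg$params), names(schema))
    if (length(bad))
      stop("unknown config key(s) under params: ",
           paste0("params.", bad, collapse = ", "), call. = FALSE)
    for (nm in names(cfg$params)) {
      tmpl <- schema[[nm]]
      val <- cfg$params[[nm]]
      if (is.numeric(tmpl) && !is.numeric(val))
        stop("config key params.", nm, " must be numeric", call. = FALSE)
      schema[[nm]] <- val
    }
  }
  out <- defaults
  for (nm in setdiff(top, c("model", "params")))
    if (!is.null(cfg[[nm]])) out[[nm]] <- cfg[[nm]]
  out$params <- schema
  if (out$dt <= 0) stop("config: dt must be > 0", call. = FALSE)
  if (!is.numeric(out$seed) || out$seed < 0 || out$seed != round(out$seed))
    stop("config: seed must be a nonnegative integer", call. = FALSE)
  out$seed <- as.integer(out$seed)
  out$record_every <- as.integer(out$record_every)
  out
}

#' Load and validate a run configuration
#'
#' YAML key/value file with a mandatory `model` and optional overrides;
#' unknown keys are rejected with the offending key path, defaults are
#' filled in, and the result round-trips through [save_config()].
#'
#' @param path YAML file path.
#' @return A `"run_config"` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  validate_config(yaml::read_yaml(path))
}

#' @rdname load_config
#' @param config a `"run_config"`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Derive a per-component seed from a run seed
#'
#' Deterministic 32-bit splitting so subsystems draw from independent
#' streams regardless of execution order.
#'
#' @param seed nonnegative integer run seed.
#' @param stream small nonnegative integer component index.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stream = 0L) {
  as.integer((as.double(seed) * 48271 + stream * 10007) %% 2147483647)
}

#' Homogeneous Poisson spike trains
#'
#' Independent trains at a common rate; deterministic per seed.
#'
#' @param rate_hz event rate, `>= 0`.
#' @param duration_ms train length (ms).
#' @param n_trains number of independent trains.
#' @param seed optional RNG seed.
#' @return Tibble `train, time_ms`, times sorted within train.
#' @export
#' @examples
#' poisson_fixture(10, 1000, n_trains = 2, seed = 42)
poisson_fixture <- function(rate_hz, duration_ms, n_trains = 1,
                            seed = NULL) {
  if (rate_hz < 0) stop("rate_hz must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  purrr::map_dfr(seq_len(n_trains), function(i) {
    n <- rpois(1, rate_hz * duration_ms / 1000)
    tibble::tibble(train = i, time_ms = sort(runif(n, 0, duration_ms)))
  })
}

fmt9 <- function(x) {
  ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
         formatC(x, digits = 9, format = "g"))
}

config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  yaml::write_yaml(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}

write_sidecar <- function(path, seed = NA, config = NULL) {
  meta <- list(seed = seed, config_hash = config_hash(config),
               package = "metaspike",
               version = as.character(utils::packageVersion("metaspike")))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

#' Write / read a spike raster as two-column text
#'
#' The interchange format is plain whitespace-separated text with a
#' header line and one `(neuron_id, time_ms)` pair per row, sorted by
#' neuron then time, times printed to 9 significant digits. A JSON
#' metadata sidecar (`<path>.meta.json`) records the seed, the config
#' hash and the package version.
#'
#' @param spikes tibble with columns `neuron_id`, `time_ms` (a
#'   [poisson_fixture()] `train` column is accepted too).
#' @param path output file.
#' @param seed,config recorded in the sidecar.
#' @return `write_raster` returns `path` invisibly; `read_raster`
#'   returns the tibble.
#' @export
write_raster <- function(spikes, path, seed = NA, config = NULL) {
  if ("train" %in% names(spikes) && !("neuron_id" %in% names(spikes)))
    spikes <- dplyr::rename(spikes, neuron_id = "train")
  spikes <- dplyr::arrange(spikes, .data$neuron_id, .data$time_ms)
  lines <- c("neuron_id\ttime_ms",
             paste(spikes$neuron_id, fmt9(spikes$time_ms), sep = "\t"))
  writeLines(lines, path)
  write_sidecar(path, seed = seed, config = config)
  invisible(path)
}

#' @rdname write_raster
#' @export
read_raster <- function(path) {
  lines <- readLines(path)
  if (!length(lines))
    stop("read_raster: empty file ", path, call. = FALSE)
  body <- lines[-1]
  body <- body[nzchar(body)]
  if (!length(body))
    return(tibble::tibble(neuron_id = integer(), time_ms = numeric()))
  parts <- strsplit(body, "[\t ]+")
  for (i in seq_along(parts)) {
    p <- suppressWarnings(as.numeric(parts[[i]]))
    if (length(p) != 2 || anyNA(p))
      stop("read_raster: malformed line ", i + 1, " in ", path,
           call. = FALSE)
  }
  m <- matrix(as.numeric(unlist(parts)), ncol = 2, byrow = TRUE)
  tibble::tibble(neuron_id = as.integer(m[, 1]), time_ms = m[, 2]) |>
    dplyr::arrange(.data$neuron_id, .data$time_ms)
}

#' Write a trace table as CSV with fixed precision
#'
#' Numeric columns are printed to 9 significant digits so repeated runs
#' with the same seed produce byte-identical files; a JSON sidecar
#' records provenance.
#'
#' @param df data frame of traces.
#' @param path output CSV.
#' @param seed,config recorded in the sidecar.
#' @export
write_trace_csv <- function(df, path, seed = NA, config = NULL) {
  out <- as.data.frame(lapply(df, function(col) {
    if (is.numeric(col)) fmt9(col) else col
  }))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  write_sidecar(path, seed = seed, config = config)
  invisible(path)
}
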