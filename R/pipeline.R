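# Configuration, orchestration and plain-text I/O glue. One JSON config
# with per-stage blocks drives the whole chain:
# phantom -> extract -> radiality -> rp -> simulate -> thermal -> compare.

#' Build and validate a run configuration
#'
#' Accepts a path to a JSON file or an equivalent nested list. Blocks:
#' `geometry` (see [scan_geometry()]), `phantom` ([phantom_spec()] plus
#' `thickness` constructor arguments), `physics` (constant overrides),
#' `simulate` ([simulation_config()]), `thermal` ([thermal_camera_spec()]),
#' plus top-level `seed` and `stages`. Validation happens before any
#' compute and names the offending field.
#'
#' @param config path to a JSON file, or a named list.
#' @return object of class `run_config`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- jsonlite::read_json(config, simplifyVector = TRUE)
  if (!is.list(config)) stop("config must be a list or a JSON file path")
  need <- function(block, field) {
    if (is.null(config[[block]]) || is.null(config[[block]][[field]]))
      stop(sprintf("config validation: missing required field `%s.%s`", block, field))
  }
  for (f in c("voxel_size", "dims", "n_radial", "n_phi", "n_h",
              "r_vial", "h_vial")) need("geometry", f)
  cfg <- list(
    seed = if (is.null(config$seed)) 1L else as.integer(config$seed),
    stages = config$stages %||% c("phantom", "extract", "radiality", "rp",
                                  "simulate", "thermal", "compare"),
    geometry = do.call(scan_geometry, config$geometry),
    constants = constants_from_config(config$physics),
    thickness = config$thickness %||% list(base = 2e-3),
    phantom = config$phantom %||% list(),
    true_rp = config$true_rp %||% list(constant = 1e5),
    simulate = do.call(simulation_config,
                       c(config$simulate %||% list(),
                         list(constants = constants_from_config(config$physics)))),
    thermal = do.call(thermal_camera_spec, config$thermal %||% list()),
    n_scans = config$n_scans %||% NULL
  )
  structure(cfg, class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ground-truth resistance profile from a config block
true_rp_fun <- function(block) {
  if (!is.null(block$constant)) {
    val <- block$constant
    return(function(L) rep(val, length(L)))
  }
  if (!is.null(block$linear)) {
    a <- block$linear[[1]]; b <- block$linear[[2]]
    return(function(L) a + b * L)
  }
  stop("config validation: `true_rp` must define `constant` or `linear`")
}

#' Run the pipeline
#'
#' Executes the selected stages in dependency order, writing every artifact
#' (CSV tables, JSON metadata) to a fresh run directory. Re-running with
#' the same config and seed reproduces identical tabular payloads. No stage
#' mutates its inputs.
#'
#' @param config a [run_config()], list, or JSON path.
#' @param outdir output directory (created; must not be an existing
#'   non-empty run).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory stage results and the
#'   output paths.
#' @export
run_pipeline <- function(config, outdir = tempfile("spinlyo_run_"),
                         quiet = FALSE) {
  if (!inherits(config, "run_config")) config <- run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  geom <- config$geometry
  res <- list(outdir = outdir)

  say("stage phantom: rendering synthetic scan series")
  th0 <- do.call(thickness_field, c(list(geometry = geom), config$thickness))
  pspec <- do.call(phantom_spec, c(list(seed = config$seed), config$phantom))
  truth <- ground_truth(true_rp_fun(config$true_rp), th0, geom)
  sim <- simulate_series(pspec, geom, truth, config$simulate,
                         n_scans = config$n_scans)
  res$series_truth <- sim$truth

  say("stage extract: layer series from %d frames", length(sim$frames))
  series <- extract_layer_series(sim$frames, geom)
  res$series <- series
  write_layer_series_csv(series, file.path(outdir, "layer_series.csv"))

  say("stage radiality: sublimation-direction diagnostic")
  nt <- length(series$t)
  rad <- radiality_map(matrix(series$L_ice[nt %/% 2L, , ], geom$n_phi),
                       matrix(series$L_ice_prime[nt %/% 2L, , ], geom$n_phi))
  res$radiality <- rad
  write_map_csv(rad$rel_diff, file.path(outdir, "radiality.csv"), "rel_diff")

  say("stage rp: resistance regression")
  trace <- process_trace(sim$truth$T_i_trace$t, sim$truth$T_i_trace$T_i,
                         P_c = config$simulate$P_c)
  prof <- resistance_profile(series, trace, geom, config$constants)
  binned <- bin_profiles(prof)
  res$profiles <- binned
  write_profiles_csv(binned, file.path(outdir, "rp_profiles.csv"))

  say("stage simulate: endpoint prediction")
  L0 <- prof$L_ice0
  em <- predict_endpoints(binned, L0, config$simulate, geom)
  res$endpoints <- em
  write_map_csv(em$t_end_h, file.path(outdir, "endpoints_predicted.csv"),
                "t_end_h")
  utils::write.csv(em$history, file.path(outdir, "step_history.csv"),
                   row.names = FALSE)

  say("stage thermal: verification movie + detection")
  cam <- config$thermal
  t_end_cam <- resample_map(sim$truth$endpoints,
                            c(cam$frames_per_rev, geom$n_h))
  movie <- make_thermal_movie(t_end_cam, cam, seed = config$seed + 1L)
  detected <- detect_endpoint_map(unwrap_movie(movie))
  res$thermal_endpoints <- detected
  write_map_csv(detected, file.path(outdir, "endpoints_thermal.csv"),
                "t_end_h")

  say("stage compare: predicted vs thermal endpoint distributions")
  cmp <- compare_endpoint_maps(em$t_end_h, detected)
  res$comparison <- cmp
  utils::write.csv(cmp$histogram, file.path(outdir, "endpoint_histograms.csv"),
                   row.names = FALSE)

  meta <- list(package = "spinlyo",
               version = as.character(utils::packageVersion("spinlyo")),
               seed = config$seed,
               config_hash = unname(config_hash(config)),
               r_version = R.version.string,
               correlation = cmp$correlation,
               max_cdf_distance = cmp$max_cdf_distance)
  jsonlite::write_json(meta, file.path(outdir, "metadata.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::serializeJSON(unclass(config)), f)
  tools::md5sum(f)
}

# plain-text writers --------------------------------------------------------

#' Write a layer series as long-format CSV
#'
#' Columns: `t`, `phi_index`, `h_index`, `L_ice`, `L_ice_prime`, `r_p`
#' (SI units). The matching reader is [read_layer_series_csv()].
#'
#' @param series a `layer_series`.
#' @param path output file.
#' @export
write_layer_series_csv <- function(series, path) {
  nt <- length(series$t)
  n <- dim(series$L_ice)[2L]; m <- dim(series$L_ice)[3L]
  df <- data.frame(
    t = rep(series$t, times = n * m),
    phi_index = rep(rep(seq_len(n), each = nt), times = m),
    h_index = rep(seq_len(m), each = nt * n),
    L_ice = as.vector(series$L_ice),
    L_ice_prime = as.vector(series$L_ice_prime),
    r_p = as.vector(series$r_p))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a layer series written by [write_layer_series_csv()]
#'
#' @param path CSV file.
#' @param geometry the [scan_geometry()] the series was extracted with.
#' @return a `layer_series`.
#' @export
read_layer_series_csv <- function(path, geometry) {
  df <- utils::read.csv(path)
  t <- sort(unique(df$t))
  nt <- length(t); n <- max(df$phi_index); m <- max(df$h_index)
  o <- order(df$h_index, df$phi_index, df$t)
  df <- df[o, ]
  shape <- function(x) array(x, c(nt, n, m))
  structure(list(t = t, L_ice = shape(df$L_ice),
                 L_ice_prime = shape(df$L_ice_prime),
                 r_p = shape(df$r_p),
                 r_vial = geometry$r_vial, geometry = geometry),
            class = "layer_series")
}

write_map_csv <- function(map, path, value_name = "value") {
  df <- data.frame(phi_index = rep(seq_len(nrow(map)), ncol(map)),
                   h_index = rep(seq_len(ncol(map)), each = nrow(map)),
                   value = as.vector(map))
  names(df)[3L] <- value_name
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

write_profiles_csv <- function(binned, path) {
  stopifnot(isTRUE(binned$binned))
  nb <- dim(binned$R_p)[1L]; n <- dim(binned$R_p)[2L]; m <- dim(binned$R_p)[3L]
  df <- data.frame(
    phi_index = rep(rep(seq_len(n), each = nb), times = m),
    h_index = rep(seq_len(m), each = nb * n),
    bin_center_mm = rep(binned$bin_centers * 1e3, times = n * m),
    Rp_m_per_s = as.vector(binned$R_p),
    count = as.vector(binned$count))
  utils::write.csv(df[df$count > 0, ], path, row.names = FALSE)
  invisible(path)
}

#' Command-line entry point
#'
#' Thin wrapper so the pipeline can be driven from `Rscript`:
#' `Rscript -e 'spinlyo::lyo_cli()' --args --config cfg.json --outdir out`.
#' Subcommand selection is via the config's `stages` field.
#'
#' @param args character vector of CLI arguments (default
#'   `commandArgs(trailingOnly = TRUE)`).
#' @return exit status, invisibly.
#' @export
lyo_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  take <- function(flag, default = NULL) {
    i <- which(args == flag)
    if (length(i)) args[i[1L] + 1L] else default
  }
  cfg_path <- take("--config")
  if (is.null(cfg_path)) {
    message("usage: --config <json> [--outdir <dir>] [--seed <int>]")
    return(invisible(1L))
  }
  cfg <- jsonlite::read_json(cfg_path, simplifyVector = TRUE)
  seed <- take("--seed"); if (!is.null(seed)) cfg$seed <- as.integer(seed)
  outdir <- take("--outdir", tempfile("spinlyo_run_"))
  run_pipeline(run_config(cfg), outdir)
  message("run complete: ", outdir)
  invisible(0L)
}
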