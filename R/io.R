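# Configuration files, tabular output and run manifests.

#' Read a run configuration
#'
#' Configurations are JSON (or YAML when the `yaml` package is installed)
#' with exactly one of a `dimensional` or `nondimensional` parameter block,
#' plus optional `domain`, `protocol` and `solver` blocks and a `seed`. A
#' stochastic run (`protocol$eta > 0`) must carry a seed.
#'
#' @param path config file path.
#' @return A validated named list with a `params` element
#'   ([nondim_params()]) resolved from whichever block was given, and a
#'   `hash` of the canonicalised config.
#' @export
read_run_config <- function(path) {
  txt <- readLines(path, warn = FALSE)
  cfg <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("yaml package not available; use JSON")
    yaml::yaml.load(paste(txt, collapse = "\n"))
  } else jsonlite::fromJSON(paste(txt, collapse = "\n"),
                            simplifyVector = TRUE)
  has_dim <- !is.null(cfg$dimensional)
  has_nd <- !is.null(cfg$nondimensional)
  if (has_dim && has_nd)
    stop("config error at dimensional/nondimensional: give exactly one ",
         "parameter block, not both")
  if (!has_dim && !has_nd)
    stop("config error: one of 'dimensional' or 'nondimensional' required")
  cfg$params <- if (has_nd) do.call(nondim_params, as.list(cfg$nondimensional))
  else nondimensionalise(do.call(dimensional_params,
                                 as.list(cfg$dimensional)))$params
  eta <- cfg$protocol$eta
  if (!is.null(eta) && eta > 0 && is.null(cfg$seed))
    stop("config error at seed: stochastic runs (eta > 0) require a seed")
  cfg$hash <- config_hash(cfg[setdiff(names(cfg), c("params", "hash"))])
  cfg
}

#' Deterministic hash of a configuration
#'
#' @param cfg a list.
#' @return Character scalar (31-bit polynomial rolling hash of the canonical
#'   JSON, hex).
#' @export
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a region-label scan as long-format CSV
#'
#' @param scan a matrix from [scan_stability_plane()] or
#'   [scan_turing_plane()].
#' @param path output CSV path.
#' @return The long-format data frame, invisibly.
#' @export
write_scan_csv <- function(scan, path) {
  su <- attr(scan, "sigma_u"); sw <- attr(scan, "sigma_w")
  df <- data.frame(sigma_u = rep(su, times = length(sw)),
                   sigma_w = rep(sw, each = length(su)),
                   label = as.vector(scan))
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Export a kymograph
#'
#' Writes the 1D tumour-density space-time array (rows = save times,
#' columns = nodes) as CSV.
#'
#' @param traj a 1D `trajectory` object.
#' @param path output CSV path.
#' @return The kymograph matrix, invisibly.
#' @export
export_kymograph <- function(traj, path) {
  if (is.null(traj$dom) || traj$dom$dim != 1L)
    stop("kymograph export requires a 1D trajectory")
  kymo <- summarise_trajectory(traj)$kymograph
  df <- data.frame(time = traj$times, kymo)
  names(df) <- c("time", sprintf("x%03d", seq_len(ncol(kymo))))
  write.csv(df, path, row.names = FALSE)
  invisible(kymo)
}

#' Read a kymograph CSV back
#'
#' @param path CSV written by [export_kymograph()].
#' @return A list with `times` and the `kymograph` matrix.
#' @export
read_kymograph <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  list(times = df[[1]], kymograph = as.matrix(df[, -1, drop = FALSE]))
}

#' Save a branch summary as CSV
#'
#' @param branch a `branch` object.
#' @param path output CSV path.
#' @return The summary data frame, invisibly.
#' @export
write_branch_csv <- function(branch, path) {
  df <- branch$points
  df$param_name <- branch$param_name
  write.csv(df, path, row.names = FALSE)
  invisible(df)
}

#' Write a run manifest
#'
#' Records inputs, seed, package version and the config hash next to a
#' run's outputs so every output file is traceable to its configuration.
#'
#' @param cfg a config list (see [read_run_config()]).
#' @param outputs character vector of files written.
#' @param path manifest path (JSON).
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(cfg, outputs, path) {
  man <- list(
    config_hash = if (!is.null(cfg$hash)) cfg$hash else
      config_hash(cfg[setdiff(names(cfg), c("params", "hash"))]),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("turimm")),
    outputs = outputs,
    written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(man)
}
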