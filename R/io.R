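# Configuration files, result serialization and logging.

#' Load a run configuration from YAML or JSON
#'
#' The file must contain a \code{mode} field (one of \code{"classify"},
#' \code{"census"}, \code{"run-wellmixed"}, \code{"run-group"}) plus the
#' parameters of that mode; missing parameters take the package
#' defaults.  Unknown keys and out-of-range values raise descriptive
#' errors before any computation.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return a validated config: for the run modes a
#'   [well_mixed_config()]/[group_config()] carrying the mode as
#'   attribute; for classify/census a plain validated list.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    # quote bare keys that YAML 1.1 would parse as booleans (the group
    # size is called N, which yaml reads as FALSE otherwise)
    lines <- sub("^(\\s*)(y|Y|n|N|yes|no|true|false|on|off)(\\s*):",
                 '\\1"\\2"\\3:', readLines(path))
    yaml::yaml.load(paste(lines, collapse = "\n"))
  } else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be a .yaml or .json file: ", path)
  if (is.null(raw$mode))
    stop("config must contain a `mode` field")
  mode <- match.arg(raw$mode,
                    c("classify", "census", "run-wellmixed", "run-group"))
  pars <- raw[setdiff(names(raw), "mode")]
  allowed <- switch(mode,
    "classify" = "strategy",
    "census" = c("m1", "m2", "n_samples", "e", "threshold"),
    "run-wellmixed" = names(formals(well_mixed_config)),
    "run-group" = names(formals(group_config)))
  bad <- setdiff(names(pars), allowed)
  if (length(bad))
    stop("unknown config key(s) for mode ", mode, ": ",
         paste(bad, collapse = ", "))
  cfg <- switch(mode,
    "classify" = {
      if (is.null(pars$strategy)) stop("classify mode needs `strategy`")
      pars
    },
    "census" = {
      if (is.null(pars$m1) || is.null(pars$m2))
        stop("census mode needs `m1` and `m2`")
      pars
    },
    "run-wellmixed" = do.call(well_mixed_config, pars),
    "run-group" = do.call(group_config, pars))
  attr(cfg, "mode") <- mode
  cfg
}

#' Write run results to an output directory
#'
#' Writes \code{summary.json} (the observables, plus the config and seed
#' echoed verbatim; floats at full precision), \code{timeseries.csv}
#' (columns t, cooperation, frac_fr, frac_eff, frac_rival, mean_m1,
#' mean_m2) and \code{run.log}.  Re-running with the recorded seed and
#' config reproduces the files bit-identically.
#'
#' @param run an \code{"fr_run"} object.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_run_results <- function(run, dir) {
  stopifnot(inherits(run, "fr_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("summary.json", "timeseries.csv", "run.log"))
  summary <- list(mode = run$mode,
                  seed = run$seed,
                  config = unclass(run$config),
                  observables = run$observables)
  jsonlite::write_json(summary, paths[1], auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  utils::write.csv(run$series, paths[2], row.names = FALSE)
  writeLines(c(
    sprintf("frsim %s", as.character(utils::packageVersion("frsim"))),
    sprintf("mode: %s", run$mode),
    sprintf("seed: %d", run$seed),
    sprintf("config: %s",
            jsonlite::toJSON(unclass(run$config), auto_unbox = TRUE))),
    paths[3])
  invisible(paths)
}
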