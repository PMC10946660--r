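# ---- observation tables -----------------------------------------------------

# CSV writer preserving doubles exactly (17 significant digits round-trip)
.write_csv17 <- function(df, path) {
  out <- df
  for (cl in names(out))
    if (is.double(out[[cl]]))
      out[[cl]] <- formatC(out[[cl]], digits = 17, format = "g")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
}

#' Read an observation table
#'
#' CSV with header `time_h, od660[, lum]`; dot decimal separator, UTF-8.
#'
#' @param path File path.
#' @return data.frame with the validated columns.
#' @export
read_observations <- function(path) {
  d <- read.csv(path)
  if (!"time_h" %in% names(d)) stop("read_observations: missing time_h column")
  if (!any(c("od660", "lum") %in% names(d)))
    stop("read_observations: need at least one of od660, lum")
  if (any(diff(d$time_h) <= 0))
    stop("read_observations: time_h must be strictly increasing")
  d
}

#' Write an observation table
#'
#' @param tab data.frame with `time_h` and `od660`/`lum`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(tab, path) {
  .write_csv17(tab, path)
  invisible(path)
}

# ---- trajectories -----------------------------------------------------------

#' Write a simulated trajectory with a provenance sidecar
#'
#' The trajectory CSV has columns `time_h, S, N, a, A, R, L, I`. When
#' `sidecar = TRUE`, a JSON file next to it echoes the full parameter set,
#' configuration and scenario.
#'
#' @param traj A `qs_trajectory`.
#' @param path Output CSV path.
#' @param sidecar Write `<path>.json` provenance (default TRUE).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, sidecar = TRUE) {
  stopifnot(inherits(traj, "qs_trajectory"))
  .write_csv17(as.data.frame(traj), path)
  if (sidecar) {
    meta <- list(params = params_to_list(attr(traj, "params")),
                 energy_config = unclass(attr(traj, "cfg")),
                 scenario = if (!is.null(attr(traj, "scenario")))
                   unclass(attr(traj, "scenario")) else NULL,
                 package_version = as.character(utils::packageVersion("qslum")))
    jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, null = "null")
  }
  invisible(path)
}

#' Read a trajectory CSV
#'
#' @param path CSV written by [write_trajectory()].
#' @return data.frame (without the original attributes).
#' @export
read_trajectory <- function(path) read.csv(path)

# ---- parameter serialization ------------------------------------------------

#' Convert parameters to a plain nested list
#'
#' @param p A [full_params()] object.
#' @return Nested list keyed by block with exact field names.
#' @export
params_to_list <- function(p) {
  stopifnot(inherits(p, "full_params"))
  lapply(unclass(p), function(b) lapply(unclass(b), identity))
}

#' Rebuild parameters from a nested list
#'
#' @param x Nested list as produced by [params_to_list()] (missing fields
#'   fall back to the defaults).
#' @return A [full_params()] object.
#' @export
params_from_list <- function(x) {
  # leaf values may arrive as strings (full-precision YAML); coerce
  blk <- function(ctor, nm) {
    fields <- if (is.null(x[[nm]])) list() else lapply(x[[nm]], function(v)
      if (is.character(v)) as.numeric(v) else v)
    do.call(ctor, fields)
  }
  full_params(growth = blk(growth_params, "growth"),
              energy = blk(energy_params, "energy"),
              qs = blk(qs_params, "qs"),
              lum = blk(lum_params, "lum"),
              scale = blk(scale_params, "scale"))
}

#' Write parameters to JSON or YAML
#'
#' Round-trips losslessly (17 significant digits for YAML, unrounded JSON).
#'
#' @param p A [full_params()] object.
#' @param path Output path; format chosen by extension (`.json`, `.yaml`,
#'   `.yml`).
#' @return `path`, invisibly.
#' @export
write_params <- function(p, path) {
  x <- params_to_list(p)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = I(17))
  else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    # yaml's own precision caps below a double's 17 significant digits;
    # format values as %.17g strings, coerced back on read
    xs <- lapply(x, function(b) lapply(b, formatC, digits = 17, format = "g"))
    writeLines(yaml::as.yaml(xs), path)
  } else stop("write_params: use a .json or .yaml/.yml extension")
  invisible(path)
}

#' Read parameters from JSON or YAML
#'
#' @param path Path written by [write_params()] (or hand-edited with the
#'   same field names).
#' @return A [full_params()] object.
#' @export
read_params <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else stop("read_params: use a .json or .yaml/.yml extension")
  params_from_list(x)
}

#' Serialize a regime-scan report to JSON
#'
#' @param scan An `energy_scan` from [regime_scan()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_regime_scan <- function(scan, path) {
  stopifnot(inherits(scan, "energy_scan"))
  jsonlite::write_json(list(per_S = scan$per_S, summary = scan$summary),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
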