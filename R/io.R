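## CSV / JSON writers with run manifests. Output is deterministic: fixed
## column order, 9 significant digits, no quoting; re-running the same
## configuration and seed yields byte-identical files.

fmt9 <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], 9)
  df
}

## small deterministic content hash (djb2) so manifests can fingerprint a
## configuration without a cryptographic dependency
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

write_manifest <- function(path, command, config = NULL, seed = NULL) {
  manifest <- list(command = command,
                   config_hash = if (is.null(config)) NA else config_hash(config),
                   seed = if (is.null(seed)) NA else seed,
                   tool = "magbior",
                   version = as.character(packageVersion("magbior")),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write simulation and field results to CSV with a run manifest
#'
#' Dispatches on the result type: [plane_field_map()] output gets columns
#' `x_m, y_m, z_m, bx_T, by_T, bz_T, bmag_T`; [axis_profile()] output
#' `z_m, bz_T, saturated`; [bm_sim] time series `t_s, value, actuator, mode`.
#' Doubles are written at 9 significant digits in a fixed column order, and a
#' `<path>.manifest.json` (command, config hash, seed, version, timestamp) is
#' placed alongside.
#'
#' @param result a `field_map`, `axis_profile` or `bm_sim`.
#' @param path output CSV path.
#' @param command free-text provenance string recorded in the manifest.
#' @param config optional configuration object to fingerprint.
#' @param seed seed recorded in the manifest (NA for deterministic outputs).
#' @return `path`, invisibly.
#' @export
write_outputs <- function(result, path, command = "write_outputs",
                          config = NULL, seed = NULL) {
  df <- if (inherits(result, "field_map")) {
    as.data.frame(result)
  } else if (inherits(result, "axis_profile")) {
    as.data.frame(result)
  } else if (inherits(result, "bm_sim")) {
    d <- as.data.frame(result)
    names(d)[1] <- "t_s"
    d
  } else stop_config("write_outputs: unsupported result class ",
                     paste(class(result), collapse = "/"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  ok <- tryCatch({
    write.csv(fmt9(df), path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop_config("failed writing ", path, ": ", conditionMessage(ok))
  write_manifest(path, command, config, seed)
  invisible(path)
}

#' @rdname write_outputs
#' @export
write_field_map <- function(result, path, ...) write_outputs(result, path, ...)

#' @rdname write_outputs
#' @export
write_axis_profile <- function(result, path, ...) write_outputs(result, path, ...)

#' @rdname write_outputs
#' @export
write_timeseries <- function(result, path, ...) write_outputs(result, path, ...)

#' Export a field map as a PNG heat map
#'
#' @param fm a `field_map`.
#' @param path output PNG path.
#' @param width,height image size in pixels.
#' @return `path`, invisibly.
#' @export
export_heatmap <- function(fm, path, width = 800, height = 700) {
  stopifnot(inherits(fm, "field_map"))
  png(path, width = width, height = height)
  on.exit(dev.off())
  plot(fm)
  invisible(path)
}
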