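#' Write a dataset as CSV traces plus a JSON manifest
#'
#' Each series goes to `<id>.csv` (columns `time_s`, `V_mV`); the manifest
#' records ids, files, condition labels, stimulant levels, routes, sigma
#' values and any step-artifact annotations.
#'
#' @param dataset `mp_dataset`.
#' @param dir output directory (created if needed).
#' @param description free-text dataset description.
#' @param seed seed provenance to record.
#' @return Invisibly, the manifest path.
#' @export
write_dataset <- function(dataset, dir, description = "", seed = NA) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- lapply(dataset$series, function(s) {
    f <- paste0(s$series_id, ".csv")
    write.csv(data.frame(time_s = seq_along(s$values) - 1, V_mV = s$values),
              file.path(dir, f), row.names = FALSE)
    list(file = f, series_id = s$series_id,
         condition_label = s$condition_label,
         stimulant_uM = s$condition$S_max, route = s$condition$route,
         pkg_active = s$condition$pkg_active, sigma = s$sigma,
         annotations = if (is.null(s$annotations)) list() else s$annotations)
  })
  manifest <- list(schema_version = "1.0", description = description,
                   seed = seed, series = entries)
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Load a dataset from a manifest
#'
#' Reads every series referenced by the JSON manifest, validating that each
#' file exists and sits on the uniform 1 s grid, and parsing condition
#' labels into blocker flags.
#'
#' @param manifest_path path to `manifest.json`.
#' @return `mp_dataset`.
#' @export
load_dataset <- function(manifest_path) {
  if (!file.exists(manifest_path))
    stop("load-error: manifest not found: ", manifest_path)
  man <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  series <- lapply(man$series, function(e) {
    f <- file.path(dir, e$file)
    if (!file.exists(f))
      stop("load-error: series '", e$series_id, "' file missing: ", f)
    d <- read.csv(f)
    if (!all(c("time_s", "V_mV") %in% names(d)))
      stop("load-error: series '", e$series_id,
           "' needs columns time_s, V_mV")
    if (nrow(d) > 1 && any(abs(diff(d$time_s) - 1) > 1e-9))
      stop("load-error: series '", e$series_id, "' is not on a 1 s grid")
    cond <- condition_from_label(e$condition_label,
                                 S_max = e$stimulant_uM %||% 10,
                                 route = e$route %||% "PIPETTE")
    if (!is.null(e$pkg_active)) cond$pkg_active <- e$pkg_active
    ann <- if (length(e$annotations)) e$annotations else NULL
    mp_series(d$V_mV, e$condition_label, e$series_id, cond,
              sigma = e$sigma %||% NA_real_, annotations = ann)
  })
  mp_dataset(series)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Hash of a configuration object
#'
#' MD5 of the canonical JSON serialization; changes whenever any config
#' field changes.  Recorded in result files for provenance.
#'
#' @param x any serializable list.
#' @return Character MD5 hash.
#' @export
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"), f)
  unname(tools::md5sum(f))
}

#' Save a result object
#'
#' JSON (with schema version and config hash) for structured results;
#' evidence matrices additionally get a flat CSV (81 rows: model index,
#' signs, log evidence, MC s.e., group) and a 9x9 grid CSV next to it.
#'
#' @param result a result object (`evidence_result`, `evidence_matrix`,
#'   `loo_result`, `fit_result`, `prediction_result`, or any list).
#' @param path output path (`.json`).
#' @return Invisibly, `path`.
#' @export
save_results <- function(result, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  payload <- unclass(result)
  payload$layout <- NULL                   # drop bulky internals
  out <- list(schema_version = "1.0",
              class = class(result)[1],
              config_hash = config_hash(payload),
              result = payload)
  ok <- tryCatch({
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, force = TRUE, null = "null")
    TRUE
  }, error = function(e) stop("io-error: cannot write ", path, ": ",
                              conditionMessage(e)))
  if (inherits(result, "evidence_matrix")) {
    base <- sub("\\.json$", "", path)
    write.csv(result$table, paste0(base, "_table.csv"), row.names = FALSE)
    write.csv(result$grid, paste0(base, "_grid.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read back a saved result
#'
#' @param path path written by [save_results()].
#' @return The `result` payload as a list.
#' @export
load_results <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)$result
}
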