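#' Write a trace to CSV with a JSON sidecar
#'
#' The CSV holds `time_ms, voltage_mV` (fixed decimal format, so a
#' read/write cycle reproduces the text exactly); the sidecar
#' (`<path>.json`) holds the sampling step, stimulus descriptor and
#' identifiers.
#'
#' @param trace a [cc_trace()]
#' @param path CSV file path
#' @return `path`, invisibly
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cc_trace"))
  t <- trace_time(trace)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("time_ms,voltage_mV", con)
  writeLines(sprintf("%.4f,%.5f", t, trace$voltage), con)
  side <- list(dt = trace$dt,
               stimulus = unclass(trace$stimulus),
               cell_id = trace$cell_id, group_label = trace$group_label,
               sweep_id = trace$sweep_id, i_hold = trace$i_hold)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path CSV file path; `<path>.json` must exist
#' @return a [cc_trace()]
#' @export
read_trace <- function(path) {
  side_path <- paste0(path, ".json")
  if (!file.exists(side_path))
    stop("missing trace sidecar: expected ", side_path)
  side <- jsonlite::fromJSON(side_path)
  d <- read.csv(path)
  if (!all(c("time_ms", "voltage_mV") %in% names(d)))
    stop("trace CSV must have columns time_ms, voltage_mV: ", path)
  dt <- side$dt
  steps <- diff(d$time_ms)
  if (length(steps) > 0 && any(abs(steps - dt) > 1e-3 * dt))
    stop("non-uniform time grid in ", path, " (first offending line ",
         which(abs(steps - dt) > 1e-3 * dt)[1] + 1, ")")
  st <- side$stimulus
  holding <- if (is.null(st$holding) || is.na(st$holding)) NA_real_ else st$holding
  cc_trace(d$voltage_mV, dt,
           stim_step(st$amplitude, onset = st$onset,
                     duration = st$duration, holding = holding,
                     post = st$post),
           cell_id = side$cell_id %||% NA_character_,
           group_label = side$group_label %||% NA_character_,
           sweep_id = side$sweep_id %||% NA_character_,
           i_hold = side$i_hold %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a) || (length(a) == 1 && is.na(a))) b else a

#' Write / read a feature table
#'
#' @param ft feature table data.frame
#' @param path file path (`.csv` or `.json`)
#' @return `path` (write) or the table (read)
#' @export
write_feature_table <- function(ft, path) {
  if (grepl("\\.json$", path))
    jsonlite::write_json(ft, path, dataframe = "rows", digits = NA,
                         na = "null")
  else
    write.csv(ft, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  if (grepl("\\.json$", path)) as.data.frame(jsonlite::fromJSON(path))
  else read.csv(path, stringsAsFactors = FALSE)
}

.spec_to_list <- function(spec) {
  list(groups = lapply(spec$groups, unclass),
       amplitudes = spec$amplitudes, dt = spec$dt, seed = spec$seed)
}

.spec_from_list <- function(sl) {
  groups <- lapply(sl$groups, function(g) {
    do.call(group_spec, g[c("label", "n_cells", "params", "cv", "v_sd",
                            "noise_sd", "rheobase", "fi_slope",
                            "adapt_ratio", "ap_width", "ap_amp", "ap_rise",
                            "area")])
  })
  cohort_spec(groups, amplitudes = sl$amplitudes, dt = sl$dt,
              seed = sl$seed)
}

#' Write a cohort bundle to a directory
#'
#' Layout: `cohort_spec.json`, `manifest.json` (ground truth), and one
#' CSV + sidecar per sweep under `traces/<cell_id>/`.
#'
#' @param cohort an `ih_cohort` from [generate_cohort()]
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "ih_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(.spec_to_list(cohort$spec),
                       file.path(dir, "cohort_spec.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  jsonlite::write_json(cohort$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  for (id in names(cohort$cells)) {
    cdir <- file.path(dir, "traces", id)
    dir.create(cdir, recursive = TRUE, showWarnings = FALSE)
    sw <- cohort$cells[[id]]
    for (nm in names(sw))
      write_trace(sw[[nm]], file.path(cdir, paste0(nm, ".csv")))
  }
  invisible(dir)
}

#' Read a cohort bundle written by [write_cohort()]
#'
#' @param dir bundle directory
#' @return an `ih_cohort` (trace voltages at the stored text precision)
#' @export
read_cohort <- function(dir) {
  spec <- .spec_from_list(jsonlite::fromJSON(
    file.path(dir, "cohort_spec.json"), simplifyVector = TRUE))
  manifest <- jsonlite::fromJSON(file.path(dir, "manifest.json"),
                                 simplifyVector = FALSE)
  cells <- list()
  for (id in list.dirs(file.path(dir, "traces"), recursive = FALSE,
                       full.names = FALSE)) {
    cdir <- file.path(dir, "traces", id)
    files <- list.files(cdir, pattern = "\\.csv$", full.names = TRUE)
    sw <- lapply(files, read_trace)
    names(sw) <- sub("\\.csv$", "", basename(files))
    # protocol order: amplitudes first, rmp sweep last
    ord <- c(as.character(spec$amplitudes), "rmp")
    cells[[id]] <- sw[ord[ord %in% names(sw)]]
  }
  structure(list(cells = cells, manifest = manifest, spec = spec),
            class = "ih_cohort")
}
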