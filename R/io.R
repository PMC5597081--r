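# Plain-text persistence for fields, truth tables, traces and event tables.
#
# The environment provides no TIFF reader/writer, so fields are stored as
# one whitespace-separated matrix per channel plus a small JSON sidecar; the
# per-field truth table uses the documented CSV schema.  This is a
# documented narrowing of the OME-TIFF interface to text formats.

#' Write a field of view to a directory of plain-text channels
#'
#' Creates `<dir>/<CHANNEL>.txt` per channel, `<dir>/field.json` metadata
#' and, when truth is given, `<dir>/truth.csv` with columns puncta_id, row,
#' col, diameter_px, compartment, cell_label, transfected.
#'
#' @param iset a [image_set()].
#' @param dir output directory (created if needed).
#' @param truth optional `gj_ground_truth` from [make_monolayer()].
#' @return `dir`, invisibly.
#' @export
write_field <- function(iset, dir, truth = NULL) {
  stopifnot(inherits(iset, "gj_image_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(iset$channels))
    write_matrix_txt(iset$channels[[nm]], file.path(dir, paste0(nm, ".txt")))
  meta <- sprintf(
    '{"channels": [%s], "pixel_size_um": %.10g, "well_id": "%s", "site_id": %s}',
    paste(sprintf('"%s"', names(iset$channels)), collapse = ", "),
    iset$pixel_size_um, iset$well_id,
    if (is.na(iset$site_id)) "null" else iset$site_id)
  writeLines(meta, file.path(dir, "field.json"))
  if (!is.null(truth)) {
    tr <- truth$puncta[, c("puncta_id", "row", "col", "diameter_px",
                           "compartment", "cell_label", "transfected")]
    utils::write.csv(tr, file.path(dir, "truth.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a field written by [write_field()]
#'
#' @param dir field directory.
#' @return a [image_set()].
#' @export
read_field <- function(dir) {
  meta <- paste(readLines(file.path(dir, "field.json")), collapse = "")
  chans <- regmatches(meta, gregexpr('"[A-Z0-9]+"(?=[,\\]])', meta,
                                     perl = TRUE))[[1]]
  chans <- gsub('"', "", chans)
  px <- as.numeric(sub('.*"pixel_size_um": *([0-9.eE+-]+).*', "\\1", meta))
  mats <- lapply(chans, function(nm)
    read_matrix_txt(file.path(dir, paste0(nm, ".txt"))))
  names(mats) <- chans
  image_set(mats, pixel_size_um = px)
}

write_matrix_txt <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(apply(m, 1, paste, collapse = " "), con)
}

read_matrix_txt <- function(path) {
  rows <- strsplit(readLines(path), " ", fixed = TRUE)
  matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
}

#' Read an intracellular trace from CSV
#'
#' @param path CSV with columns `time_ms`, `voltage_mV` (case-insensitive).
#' @param stim_times_ms stimulus markers, or path to a one-column CSV.
#' @return a `gj_trace`.
#' @export
read_trace_csv <- function(path, stim_times_ms = numeric(0)) {
  d <- utils::read.csv(path)
  names(d) <- tolower(names(d))
  stopifnot(all(c("time_ms", "voltage_mv") %in% names(d)))
  if (is.character(stim_times_ms))
    stim_times_ms <- utils::read.csv(stim_times_ms)[[1]]
  dt <- diff(d$time_ms)
  if (max(dt) - min(dt) > 1e-6 * mean(dt)) stop("trace is not uniformly sampled")
  structure(list(time_ms = d$time_ms, voltage_mv = d$voltage_mv,
                 sampling_rate_hz = 1000 / mean(dt),
                 stim_times_ms = stim_times_ms, true_latency_ms = NA_real_),
            class = "gj_trace")
}

#' Write a trace to CSV
#' @param trace a `gj_trace`.
#' @param path output CSV path.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(data.frame(time_ms = trace$time_ms,
                              voltage_mV = trace$voltage_mv),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read ROI polygons from a CSV vertex list
#'
#' @param path CSV with columns `roi`, `row`, `col` (0-based pixel
#'   coordinates).
#' @return list of vertex matrices, one per ROI, in roi order.
#' @export
read_rois_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("roi", "row", "col") %in% names(d)))
  lapply(split(d, d$roi), function(p) cbind(row = p$row, col = p$col))
}
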