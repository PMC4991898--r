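#' Map file columns to anatomical channels
#'
#' Recordings arrive as delimited text with arbitrary column names; a
#' channel map states which file column is which `<side>_<muscle>` channel.
#' The mapping must be injective and cover at least one channel.
#'
#' @param ... Named arguments `file_column = "channel"`, e.g.
#'   `R_TA = "right_TA"`, or a single named character vector.
#' @param time_column Name of a time column to ignore on read (`NULL` if
#'   none; the sampling rate is authoritative, the time column is not).
#' @return A tibble of class `channel_map` with columns `column`,
#'   `channel`, plus a `time_column` attribute.
#' @export
#' @examples
#' channel_map(R_TA = "right_TA", L_TA = "left_TA", time_column = "t")
channel_map <- function(..., time_column = NULL) {
  dots <- c(...)
  if (length(dots) == 1L && is.null(names(dots)) && !is.null(names(c(...)))) {
    dots <- c(...)
  }
  if (is.null(names(dots)) || any(names(dots) == "")) {
    abort("Every entry must be named: file_column = \"channel\".")
  }
  channels <- unname(unlist(dots))
  bad <- setdiff(channels, canonical_channels())
  if (length(bad)) {
    abort(paste0("Unknown channel target(s): ", paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(channels)) {
    abort("Channel map must be injective: duplicate channel targets.")
  }
  if (length(channels) < 1L) abort("Channel map must cover >= 1 channel.")
  structure(tibble::tibble(column = names(dots), channel = channels),
            time_column = time_column,
            class = c("channel_map", class(tibble::tibble())))
}

#' Default channel map for files already using canonical names
#'
#' @param channels Channels to include (default all eight).
#' @param time_column Passed to [channel_map()] (default `"time"`).
#' @return A `channel_map`.
#' @export
default_channel_map <- function(channels = canonical_channels(),
                                time_column = "time") {
  channel_map(setNames(channels, channels), time_column = time_column)
}

#' Read a multi-channel sEMG recording from delimited text
#'
#' Accepts comma- or tab-separated text (delimiter sniffed from the first
#' line) with one numeric column per channel. Channels are reordered into
#' canonical order regardless of file column order; any time column named
#' in the map is dropped and rebuilt from `fs`.
#'
#' @param path File path.
#' @param map A [channel_map()].
#' @param fs Sampling rate in Hz.
#' @param condition `"static"` or treadmill speed (km/h).
#' @param subject_id Optional subject label.
#' @return An [emg_recording()].
#' @export
read_recording <- function(path, map, fs, condition = "static",
                           subject_id = NA_character_) {
  stopifnot(inherits(map, "channel_map"))
  if (!file.exists(path)) abort(paste0("Cannot read file: ", path))
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  missing <- setdiff(map$column, names(df))
  if (length(missing)) {
    abort(paste0("Mapped column(s) absent from file: ",
                 paste(missing, collapse = ", ")))
  }
  for (col in map$column) {
    if (!is.numeric(df[[col]])) {
      abort(paste0("Column ", col, " contains non-numeric cells."))
    }
  }
  samples <- df[, map$column]
  names(samples) <- map$channel
  emg_recording(samples, fs = fs, condition = condition,
                subject_id = subject_id)
}

#' Write a recording to CSV
#'
#' One `time` column (s) plus one column per channel, in canonical order;
#' the file round-trips through [read_recording()] with
#' [default_channel_map()] up to float formatting.
#'
#' @param rec An [emg_recording()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  readr::write_csv(tibble::as_tibble(rec), path, progress = FALSE)
  invisible(path)
}

report_columns <- function() {
  c("muscle", "condition", "n_left", "n_right", "mean_left", "mean_right",
    "delta_d", "ratio", "w", "p_value", "method", "significant",
    "sampen_left", "sampen_right")
}

#' Write an asymmetry report as a tab-separated table
#'
#' One row per (muscle, condition) with a stable column order: side means,
#' the absolute mean difference, the activity ratio, rank-sum statistic and
#' p-value, and the left/right sample entropies. Values are written at full
#' precision; an empty report produces a header-only file.
#'
#' @param report An `asymmetry_report` tibble (see [analyze_static()] /
#'   [analyze_dynamic()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(report, path) {
  stopifnot(is.data.frame(report))
  cols <- intersect(report_columns(), names(report))
  missing <- setdiff(report_columns(), names(report))
  out <- report
  for (col in missing) out[[col]] <- NA
  out <- out[, report_columns()]
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
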