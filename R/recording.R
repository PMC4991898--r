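#' Anatomical channel vocabulary
#'
#' The package works with four bilateral shank muscles: tibialis anterior
#' (TA), soleus (SOL), lateral gastrocnemius (LG) and medial gastrocnemius
#' (MG). Channels are named `<side>_<muscle>`, e.g. `"right_TA"`, and are
#' always ordered left/right within muscle, muscles in the order TA, SOL,
#' LG, MG.
#'
#' @return `emg_muscles()` and `emg_sides()` return character vectors;
#'   `canonical_channels()` returns the eight channel names in canonical
#'   order.
#' @export
#' @examples
#' canonical_channels()
emg_muscles <- function() c("TA", "SOL", "LG", "MG")

#' @rdname emg_muscles
#' @export
emg_sides <- function() c("left", "right")

#' @rdname emg_muscles
#' @export
canonical_channels <- function() {
  as.vector(t(outer(emg_muscles(), emg_sides(),
                    function(m, s) paste(s, m, sep = "_"))))
}

channel_side <- function(channel) sub("_.*$", "", channel)
channel_muscle <- function(channel) sub("^.*_", "", channel)

#' Construct a multi-channel sEMG recording
#'
#' An `emg_recording` is a tibble with a `time` column (seconds) and one
#' numeric column per channel, carrying the sampling rate, the recording
#' condition and a subject identifier as attributes. Channel columns are
#' reordered into canonical order (see [canonical_channels()]).
#'
#' @param samples A data frame or named list of equal-length numeric vectors,
#'   one per channel; names must be valid channel names such as `"left_TA"`.
#' @param fs Sampling rate in Hz (> 0).
#' @param condition Either the string `"static"` (quiet standing) or a
#'   positive treadmill speed in km/h.
#' @param subject_id Optional subject label.
#' @return A tibble of class `emg_recording`.
#' @export
#' @examples
#' rec <- emg_recording(list(left_TA = rnorm(100), right_TA = rnorm(100)),
#'                      fs = 2000, condition = "static")
#' emg_channels(rec)
emg_recording <- function(samples, fs, condition = "static",
                          subject_id = NA_character_) {
  samples <- tibble::as_tibble(samples)
  chans <- setdiff(names(samples), "time")
  if (length(chans) < 1L) {
    abort("`samples` must contain at least one channel column.")
  }
  bad <- setdiff(chans, canonical_channels())
  if (length(bad) > 0L) {
    abort(paste0("Unknown channel name(s): ", paste(bad, collapse = ", "),
                 ". Use <side>_<muscle> with side in {left, right} and ",
                 "muscle in {TA, SOL, LG, MG}."))
  }
  if (anyDuplicated(chans)) abort("Duplicate channel columns.")
  if (!all(vapply(samples[chans], is.numeric, logical(1)))) {
    abort("All channel columns must be numeric.")
  }
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0) {
    abort("`fs` must be a single positive number (Hz).")
  }
  n <- nrow(samples)
  if (!"time" %in% names(samples)) {
    samples$time <- (seq_len(n) - 1) / fs
  }
  ord <- intersect(canonical_channels(), chans)
  out <- samples[, c("time", ord)]
  condition <- validate_condition(condition)
  structure(out,
            fs = fs, condition = condition, subject_id = subject_id,
            class = c("emg_recording", class(tibble::tibble())))
}

validate_condition <- function(condition) {
  if (is.character(condition)) {
    if (length(condition) != 1L || condition != "static") {
      abort("`condition` must be \"static\" or a positive speed in km/h.")
    }
    return("static")
  }
  if (!is.numeric(condition) || length(condition) != 1L ||
      !is.finite(condition) || condition <= 0) {
    abort("`condition` must be \"static\" or a positive speed in km/h.")
  }
  condition
}

#' Accessors for recording and envelope metadata
#'
#' @param x An `emg_recording` or `emg_envelope`.
#' @return `emg_fs()` the sampling rate in Hz; `emg_condition()` `"static"`
#'   or the treadmill speed (km/h); `emg_subject()` the subject label;
#'   `emg_channels()` the channel names present, in canonical order.
#' @export
emg_fs <- function(x) attr(x, "fs")

#' @rdname emg_fs
#' @export
emg_condition <- function(x) attr(x, "condition")

#' @rdname emg_fs
#' @export
emg_subject <- function(x) attr(x, "subject_id")

#' @rdname emg_fs
#' @export
emg_channels <- function(x) setdiff(names(x), "time")

#' @export
print.emg_recording <- function(x, ...) {
  cond <- emg_condition(x)
  cond <- if (identical(cond, "static")) "static standing" else
    paste0("treadmill ", cond, " km/h")
  cat(sprintf("<emg_recording> %d channels x %d samples @ %g Hz (%s)\n",
              length(emg_channels(x)), nrow(x), emg_fs(x), cond))
  NextMethod()
}

# carry recording attributes onto a derived object
copy_emg_meta <- function(to, from) {
  attr(to, "condition") <- attr(from, "condition")
  attr(to, "subject_id") <- attr(from, "subject_id")
  to
}
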