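#' Zero-phase band-pass and power-line notch filtering
#'
#' Applies a 4th-order Butterworth band-pass (forward-backward, so zero
#' phase lag) followed by a biquad notch (quality factor 30) at the mains
#' frequency, channel by channel. Hardware front-ends typically band-limit
#' sEMG at acquisition; this stage exists so that synthetic signals and any
#' raw re-analysis pass through one shared path.
#'
#' @param rec An [emg_recording()].
#' @param low,high Band edges in Hz; must satisfy `0 < low < high < fs/2`.
#' @param notch Mains frequency in Hz, or `NULL` to skip the notch.
#' @param notch_q Notch quality factor (centre frequency / -3 dB width).
#' @return The filtered [emg_recording()], same length and channel order.
#' @export
#' @examples
#' rec <- synth_static_emg(synth_params(duration = 2, muscles = "TA"))
#' filt <- bandpass_notch(rec)
bandpass_notch <- function(rec, low = 10, high = 500, notch = 50,
                           notch_q = 30) {
  stopifnot(inherits(rec, "emg_recording"))
  fs <- emg_fs(rec)
  if (!(low > 0 && high > low && high < fs / 2)) {
    abort("Band edges must satisfy 0 < low < high < fs/2.")
  }
  n <- nrow(rec)
  if (n < 24L) abort("Signal too short to filter (needs >= 24 samples).")
  bf <- signal::butter(4, c(low, high) / (fs / 2), type = "pass")
  notch_ba <- NULL
  if (!is.null(notch)) {
    if (notch <= 0 || notch >= fs / 2) abort("`notch` must lie in (0, fs/2).")
    w0 <- 2 * pi * notch / fs
    alpha <- sin(w0) / (2 * notch_q)
    b <- c(1, -2 * cos(w0), 1)
    a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
    notch_ba <- list(b = b / a[1], a = a / a[1])
  }
  # odd-reflection padding long enough for the high-Q notch's ringing to
  # decay, so edge transients do not leak into the signal
  pad <- min(n - 1L, as.integer(fs))
  out <- rec
  for (ch in emg_channels(rec)) {
    x <- rec[[ch]]
    xp <- c(2 * x[1] - x[(pad + 1L):2], x, 2 * x[n] - x[(n - 1L):(n - pad)])
    y <- signal::filtfilt(bf, xp)
    if (!is.null(notch_ba)) {
      y <- signal::filtfilt(notch_ba$b, notch_ba$a, y)
    }
    out[[ch]] <- y[(pad + 1L):(pad + n)]
  }
  out
}

new_envelope <- function(values, fs_env, window, overlap, normalized, src) {
  structure(values,
            fs = fs_env, window = window, overlap = overlap,
            normalized = normalized,
            condition = attr(src, "condition"),
            subject_id = attr(src, "subject_id"),
            class = c("emg_envelope", class(tibble::tibble())))
}

#' Sliding-window RMS envelope
#'
#' Converts each channel to its root-mean-square amplitude over windows of
#' `window` seconds advancing by `window * (1 - overlap)`. The envelope is
#' the smooth, non-negative amplitude estimate all later stages work on;
#' its sampling rate (`emg_fs()` of the result) is `fs / hop`.
#'
#' @param rec An [emg_recording()].
#' @param window Window length in s; `window * fs` must be >= 2 samples.
#' @param overlap Fractional window overlap in `[0, 1)`. The default
#'   125 ms / 50% follows common practice for gait sEMG; use `overlap = 0`
#'   when downstream statistics require (approximately) independent frames.
#' @return A tibble of class `emg_envelope` with a `time` column (window
#'   centres, s) and one column per channel.
#' @export
#' @examples
#' rec <- emg_recording(list(right_TA = rep(3, 1000)), fs = 1000)
#' env <- rms_envelope(rec)
#' all(abs(env$right_TA - 3) < 1e-12)
rms_envelope <- function(rec, window = 0.125, overlap = 0.5) {
  stopifnot(inherits(rec, "emg_recording"))
  if (overlap < 0 || overlap >= 1) abort("`overlap` must lie in [0, 1).")
  fs <- emg_fs(rec)
  len <- round(window * fs)
  if (len < 2L) abort("`window * fs` must be at least 2 samples.")
  n <- nrow(rec)
  if (len > n) abort("Window longer than the signal.")
  hop <- max(1L, round(len * (1 - overlap)))
  starts <- seq.int(1L, n - len + 1L, by = hop)
  vals <- tibble::tibble(time = (starts - 1 + (len - 1) / 2) / fs)
  for (ch in emg_channels(rec)) {
    cs <- c(0, cumsum(rec[[ch]]^2))
    vals[[ch]] <- sqrt((cs[starts + len] - cs[starts]) / len)
  }
  new_envelope(vals, fs_env = fs / hop, window = window, overlap = overlap,
               normalized = FALSE, src = rec)
}

#' @export
print.emg_envelope <- function(x, ...) {
  units <- if (isTRUE(attr(x, "normalized"))) "%MVC" else "mV"
  cat(sprintf("<emg_envelope> %d channels x %d frames @ %g Hz (%s)\n",
              length(emg_channels(x)), nrow(x), emg_fs(x), units))
  NextMethod()
}

#' Extract MVC reference values from a reference-trial envelope
#'
#' The reference for each channel is the maximum of a 1 s moving average of
#' the RMS envelope, a peak estimate robust to single-frame spikes (a raw
#' maximum would be dominated by them).
#'
#' @param env An `emg_envelope` of an MVC trial (>= 1 s long).
#' @param smooth Moving-average length in s.
#' @return A tibble with columns `side`, `muscle`, `mvc` (mV), one row per
#'   channel of `env`. An all-zero channel is an error: normalization by a
#'   zero MVC is impossible.
#' @export
extract_mvc <- function(env, smooth = 1) {
  stopifnot(inherits(env, "emg_envelope"))
  if (isTRUE(attr(env, "normalized"))) {
    abort("`env` must be a raw (non-normalized) envelope.")
  }
  fs_env <- emg_fs(env)
  if (nrow(env) / fs_env < smooth) {
    abort("MVC trial shorter than the smoothing window (needs >= 1 s).")
  }
  k <- max(1L, round(smooth * fs_env))
  rows <- purrr::map(emg_channels(env), function(ch) {
    x <- env[[ch]]
    m <- if (k == 1L) x else {
      cs <- c(0, cumsum(x))
      (cs[(k + 1):(length(x) + 1)] - cs[1:(length(x) - k + 1)]) / k
    }
    peak <- max(m)
    if (peak <= 0) {
      abort(paste0("Channel ", ch, " has zero MVC amplitude; ",
                   "normalization is impossible."))
    }
    tibble::tibble(side = channel_side(ch), muscle = channel_muscle(ch),
                   mvc = peak)
  })
  dplyr::bind_rows(rows)
}

#' Normalize an envelope to percent MVC
#'
#' Each channel is rescaled to `100 * value / mvc`, with the per-channel
#' reference taken from `ref`. Normalizing an already-normalized envelope is
#' refused.
#'
#' @param env A raw `emg_envelope`.
#' @param ref A reference tibble with columns `side`, `muscle`, `mvc`
#'   covering every channel of `env`, all `mvc > 0` (see [extract_mvc()]).
#' @return The envelope in %MVC units (`normalized` attribute set).
#' @export
mvc_normalize <- function(env, ref) {
  stopifnot(inherits(env, "emg_envelope"))
  if (isTRUE(attr(env, "normalized"))) {
    abort("Envelope is already normalized to %MVC.")
  }
  stopifnot(is.data.frame(ref), all(c("side", "muscle", "mvc") %in% names(ref)))
  out <- env
  for (ch in emg_channels(env)) {
    r <- ref$mvc[ref$side == channel_side(ch) &
                   ref$muscle == channel_muscle(ch)]
    if (length(r) != 1L) {
      abort(paste0("No MVC reference for channel ", ch, "."))
    }
    if (!is.finite(r) || r <= 0) {
      abort(paste0("MVC reference for ", ch, " must be positive."))
    }
    out[[ch]] <- 100 * env[[ch]] / r
  }
  attr(out, "normalized") <- TRUE
  out
}
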