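#' Detect muscle activation onsets in an envelope channel
#'
#' An onset is an upward crossing of an amplitude threshold that stays
#' above threshold for at least `min_active` seconds, with a refractory
#' separation of `min_separation` seconds from the previous onset. The
#' threshold is baseline-relative, so uniform rescaling of the envelope
#' leaves onset indices unchanged:
#' `threshold = baseline_level + threshold_k * spread`, where the baseline
#' level is the mean of the channel's lowest-decile frames and the spread
#' is a robust SD (1.4826 * MAD) of the whole channel, which tolerates up
#' to about half the frames being active bursts. A signal that begins above
#' threshold does not fire an onset at frame 1 -- only crossings count.
#'
#' A constant envelope has no definable crossing and returns zero onsets.
#'
#' @param env An `emg_envelope`.
#' @param channel Channel to detect on; segmentation of a gait recording
#'   uses `"right_TA"`, whose contraction defines the start of a cycle.
#' @param threshold_k Threshold height in robust-SD units above baseline.
#' @param min_active Minimum supra-threshold duration (s).
#' @param min_separation Refractory period between onsets (s). The default
#'   0.45 s is longer than the dip between the TA swing burst and the
#'   swing-to-stance transition burst at the slowest cadence considered
#'   (about 0.33 s at a 1.1 s cycle), and shorter than the shortest cycle
#'   at fast walking, so each cycle fires exactly one onset.
#' @return Integer vector of envelope frame indices (strictly increasing).
#' @export
detect_onsets <- function(env, channel = "right_TA", threshold_k = 3,
                          min_active = 0.05, min_separation = 0.45) {
  stopifnot(inherits(env, "emg_envelope"))
  if (!channel %in% emg_channels(env)) {
    abort(paste0("Channel ", channel, " not present in envelope."))
  }
  fs_env <- emg_fs(env)
  x <- env[[channel]]
  need <- max(2L, ceiling(2 * min_active * fs_env))
  if (length(x) < need) abort("Envelope too short for onset detection.")
  base_level <- mean(x[x <= quantile(x, 0.10)])
  spread <- mad(x)
  if (spread == 0 && sd(x) == 0) {
    return(integer(0))                      # constant envelope: no crossings
  }
  thr <- base_level + threshold_k * spread
  above <- x > thr
  k_active <- max(1L, ceiling(min_active * fs_env))
  sep_frames <- ceiling(min_separation * fs_env)
  crossings <- which(diff(c(FALSE, above)) == 1L)
  crossings <- crossings[crossings > 1L]    # starting above is not an onset
  onsets <- integer(0)
  last <- -Inf
  for (i in crossings) {
    if (i - last < sep_frames) next
    run_end <- min(length(x), i + k_active - 1L)
    if (all(above[i:run_end]) && (run_end - i + 1L) >= k_active) {
      onsets <- c(onsets, i)
      last <- i
    }
  }
  onsets
}

#' Cut gait cycles from onset indices
#'
#' Each gait cycle runs from one right-TA onset to (but not including) the
#' next, so N onsets induce N - 1 half-open, contiguous, non-overlapping
#' cycles. Both limbs are cut on this single cycle clock.
#'
#' @param onsets Strictly increasing integer frame indices.
#' @return A tibble of class `gait_cycles` with columns `cycle`, `start`,
#'   `end` (half-open `[start, end)`); zero rows (with a warning) when
#'   fewer than two onsets are supplied.
#' @export
#' @examples
#' segment_cycles(c(100, 600, 1100))
segment_cycles <- function(onsets) {
  if (length(onsets) > 1L && any(diff(onsets) <= 0)) {
    abort("`onsets` must be strictly increasing (no duplicates).")
  }
  if (length(onsets) < 2L) {
    warn("Fewer than two onsets: no complete gait cycle.")
    out <- tibble::tibble(cycle = integer(0), start = integer(0),
                          end = integer(0))
  } else {
    out <- tibble::tibble(cycle = seq_len(length(onsets) - 1L),
                          start = as.integer(onsets[-length(onsets)]),
                          end = as.integer(onsets[-1]))
  }
  structure(out, onsets = as.integer(onsets),
            class = c("gait_cycles", class(tibble::tibble())))
}

#' Phase-normalize envelope cycles to a fixed number of points
#'
#' Resamples every channel of the envelope over each cycle at phases
#' k/n, k = 0..n-1, by linear interpolation -- the "one hundred points at
#' equal intervals" representation that makes cycles of different duration
#' comparable. The grid is half-open: point n would coincide with the next
#' cycle's point 0. A cycle spanning exactly n frames reproduces its frames
#' verbatim.
#'
#' @param env An `emg_envelope` (normally in %MVC).
#' @param cycles A [segment_cycles()] result (or tibble with `cycle`,
#'   `start`, `end`).
#' @param n_points Points per cycle (default 100).
#' @return A tibble of class `cycle_curves` with columns `cycle`, `side`,
#'   `muscle`, `phase` (k/n), `value`.
#' @export
time_normalize <- function(env, cycles, n_points = 100) {
  stopifnot(inherits(env, "emg_envelope"), is.data.frame(cycles))
  if (nrow(cycles) == 0L) {
    return(structure(
      tibble::tibble(cycle = integer(0), side = character(0),
                     muscle = character(0), phase = numeric(0),
                     value = numeric(0)),
      n_points = n_points, normalized = attr(env, "normalized"),
      class = c("cycle_curves", class(tibble::tibble()))))
  }
  if (any(cycles$end - cycles$start < 2)) {
    abort("Degenerate cycle: fewer than 2 frames.")
  }
  if (max(cycles$end) > nrow(env)) {
    abort("Cycle indices exceed envelope length.")
  }
  phases <- (seq_len(n_points) - 1) / n_points
  chans <- emg_channels(env)
  out <- purrr::map(seq_len(nrow(cycles)), function(i) {
    s <- cycles$start[i]; e <- cycles$end[i]
    pos <- s + (e - s) * phases
    purrr::map(chans, function(ch) {
      v <- approx(x = s:e, y = env[[ch]][s:e], xout = pos)$y
      tibble::tibble(cycle = cycles$cycle[i], side = channel_side(ch),
                     muscle = channel_muscle(ch), phase = phases, value = v)
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()
  structure(out, n_points = n_points, normalized = attr(env, "normalized"),
            class = c("cycle_curves", class(tibble::tibble())))
}

#' Ensemble-average cycle curves
#'
#' Pointwise mean and population SD across cycles, per side and muscle --
#' the ensemble curve that summarizes a muscle's activation profile over
#' the gait cycle.
#'
#' @param curves A [time_normalize()] result (possibly pooled over
#'   subjects); must contain at least one curve.
#' @return A tibble of class `emg_ensemble` with columns `side`, `muscle`,
#'   `phase`, `mean`, `sd`, `n_cycles`.
#' @export
ensemble_average <- function(curves) {
  stopifnot(is.data.frame(curves))
  if (nrow(curves) == 0L) abort("No cycle curves to average.")
  out <- curves |>
    dplyr::group_by(.data$side, .data$muscle, .data$phase) |>
    dplyr::summarise(
      n_cycles = dplyr::n(),
      sd = sqrt(mean((.data$value - mean(.data$value))^2)),
      mean = mean(.data$value),
      .groups = "drop") |>
    dplyr::select("side", "muscle", "phase", "mean", "sd", "n_cycles") |>
    dplyr::arrange(match(.data$muscle, emg_muscles()), .data$side,
                   .data$phase)
  structure(out, class = c("emg_ensemble", class(tibble::tibble())))
}

#' Label gait-cycle phases as stance or swing
#'
#' Adds a `phase_label` column splitting the cycle at `stance_fraction`:
#' phases in `[0, stance_fraction)` are stance, the rest swing. At normal
#' walking the stance phase occupies about 60% of the cycle and swing about
#' 40%, hence the default split of 0.6.
#'
#' @param curves A `cycle_curves` or `emg_ensemble` tibble with a `phase`
#'   column.
#' @param stance_fraction Split point in (0, 1).
#' @return The input with a `phase_label` factor column.
#' @export
phase_annotation <- function(curves, stance_fraction = 0.6) {
  stopifnot(is.data.frame(curves), "phase" %in% names(curves))
  if (stance_fraction <= 0 || stance_fraction >= 1) {
    abort("`stance_fraction` must lie strictly inside (0, 1).")
  }
  curves$phase_label <- factor(
    ifelse(curves$phase < stance_fraction, "stance", "swing"),
    levels = c("stance", "swing"))
  curves
}
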