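new_asymmetry_report <- function(df, ensembles = NULL, issues = character(0)) {
  structure(df, ensembles = ensembles, issues = issues,
            class = c("asymmetry_report", class(tibble::tibble())))
}

as_recording_list <- function(recordings) {
  if (inherits(recordings, "emg_recording")) return(list(recordings))
  if (!is.list(recordings) ||
      !all(vapply(recordings, inherits, logical(1), "emg_recording"))) {
    abort("`recordings` must be an emg_recording or a list of them.")
  }
  recordings
}

muscle_pairs <- function(channels) {
  present <- unique(channel_muscle(channels))
  present[vapply(present, function(m) {
    all(paste(emg_sides(), m, sep = "_") %in% channels)
  }, logical(1))]
}

preprocess_recording <- function(rec, mvc_ref, window, overlap,
                                 low, high, notch, filter) {
  if (filter) rec <- bandpass_notch(rec, low = low, high = high,
                                    notch = notch)
  env <- rms_envelope(rec, window = window, overlap = overlap)
  mvc_normalize(env, mvc_ref)
}

#' Static steady-state left/right comparison
#'
#' Analyzes quiet-standing recordings: band-pass + notch filtering, RMS
#' envelope, %MVC normalization, then per muscle a Wilcoxon rank-sum test
#' of the pooled left-side envelope frames against the right-side frames,
#' with mean activations, their absolute difference ([delta_d()]) and the
#' left/right [activity_ratio()]. No gait segmentation is applied --
#' standing has no cycles.
#'
#' The envelope uses non-overlapping windows here (`overlap = 0`) so that
#' the frames entering the rank-sum test are approximately independent.
#'
#' @param recordings An [emg_recording()] or list of them (one per
#'   subject), condition `"static"`; frames are pooled across subjects.
#' @param mvc_ref MVC reference tibble (`side`, `muscle`, `mvc`).
#' @param window RMS window (s).
#' @param overlap RMS window overlap.
#' @param low,high,notch Filter settings, see [bandpass_notch()].
#' @param filter Apply [bandpass_notch()] first (set `FALSE` for data that
#'   is already band-limited and mains-free).
#' @param alpha Significance level.
#' @return An `asymmetry_report` tibble: one row per muscle with columns
#'   `muscle`, `condition`, `n_left`, `n_right`, `mean_left`, `mean_right`,
#'   `delta_d`, `ratio`, `w`, `p_value`, `method`, `significant`,
#'   `sampen_left`, `sampen_right` (the last two `NA` for static rows).
#' @export
analyze_static <- function(recordings, mvc_ref, window = 0.125, overlap = 0,
                           low = 10, high = 500, notch = 50, filter = TRUE,
                           alpha = 0.05) {
  recordings <- as_recording_list(recordings)
  envs <- purrr::map(recordings, preprocess_recording, mvc_ref = mvc_ref,
                     window = window, overlap = overlap, low = low,
                     high = high, notch = notch, filter = filter)
  chans <- emg_channels(envs[[1]])
  muscles <- muscle_pairs(chans)
  if (length(muscles) == 0L) {
    abort("No muscle has both left and right channels present.")
  }
  rows <- purrr::map(muscles, function(mus) {
    lft <- unlist(purrr::map(envs, ~ .x[[paste0("left_", mus)]]))
    rgt <- unlist(purrr::map(envs, ~ .x[[paste0("right_", mus)]]))
    ht <- rank_sum_test(lft, rgt, alpha = alpha)
    ml <- mean(lft); mr <- mean(rgt)
    tibble::tibble(muscle = mus, condition = "static",
                   n_left = length(lft), n_right = length(rgt),
                   mean_left = ml, mean_right = mr,
                   delta_d = delta_d(ml, mr),
                   ratio = activity_ratio(ml, mr),
                   w = ht$w, p_value = ht$p_value, method = ht$method,
                   significant = ht$significant,
                   sampen_left = NA_real_, sampen_right = NA_real_)
  })
  new_asymmetry_report(
    dplyr::arrange(dplyr::bind_rows(rows), match(.data$muscle, emg_muscles())))
}

#' Dynamic steady-state left/right comparison across treadmill speeds
#'
#' Runs the full walking pipeline per speed: filtering, RMS envelope, %MVC
#' normalization, gait-cycle segmentation by right-TA activation onsets
#' ([detect_onsets()]), 100-point phase normalization of every cycle for
#' every channel ([time_normalize()]), pooling of cycles across subjects,
#' ensemble averaging, and then per muscle a Wilcoxon rank-sum test of the
#' left vs right 100-point ensemble curves, the mean %MVC per side, their
#' absolute difference ([delta_d()]), and the sample entropy of each
#' side's ensemble curve.
#'
#' Only left and right of the same muscle are ever compared -- never two
#' different muscles.
#'
#' @param recordings A list of [emg_recording()]s, each with a numeric
#'   (speed) condition; several subjects per speed are pooled at the cycle
#'   level (or averaged per subject first, see `pool`).
#' @inheritParams analyze_static
#' @param overlap RMS window overlap (50% here: curves benefit from the
#'   denser envelope sampling).
#' @param n_points Points per phase-normalized cycle.
#' @param threshold_k,min_active,min_separation Onset-detector settings.
#' @param sampen_m,sampen_r Sample-entropy parameters (embedding dimension
#'   and tolerance in SD units).
#' @param pool `"cycles"` pools all cycles of all subjects per speed;
#'   `"subjects"` averages each subject's cycles first and ensembles the
#'   per-subject means.
#' @return An `asymmetry_report` tibble, one row per (muscle, speed), with
#'   the same columns as [analyze_static()] plus `n_cycles`; `condition`
#'   holds the speed as character, and a `speed` column holds it as a
#'   number. The full ensemble curves are attached as the `"ensembles"`
#'   attribute; per-speed segmentation problems (fewer than two onsets)
#'   are collected in the `"issues"` attribute rather than raised.
#' @export
analyze_dynamic <- function(recordings, mvc_ref, window = 0.125,
                            overlap = 0.5, low = 10, high = 500, notch = 50,
                            filter = TRUE, n_points = 100, threshold_k = 3,
                            min_active = 0.05, min_separation = 0.45,
                            sampen_m = 2, sampen_r = 0.2, alpha = 0.05,
                            pool = c("cycles", "subjects")) {
  pool <- match.arg(pool)
  recordings <- as_recording_list(recordings)
  speeds <- vapply(recordings, function(r) {
    cond <- emg_condition(r)
    if (!is.numeric(cond)) {
      abort("Dynamic analysis needs numeric (speed) conditions.")
    }
    cond
  }, numeric(1))
  issues <- character(0)
  all_rows <- list()
  all_ens <- list()
  for (sp in sort(unique(speeds))) {
    recs <- recordings[speeds == sp]
    curves <- purrr::imap(recs, function(rec, i) {
      subj <- emg_subject(rec)
      if (is.null(subj) || is.na(subj)) subj <- paste0("subject", i)
      env <- preprocess_recording(rec, mvc_ref, window, overlap,
                                  low, high, notch, filter)
      onsets <- detect_onsets(env, "right_TA", threshold_k = threshold_k,
                              min_active = min_active,
                              min_separation = min_separation)
      if (length(onsets) < 2L) {
        issues <<- c(issues, sprintf(
          "speed %g km/h, subject %s: %d onset(s), no complete cycle",
          sp, subj, length(onsets)))
        return(NULL)
      }
      cyc <- suppressWarnings(segment_cycles(onsets))
      cc <- time_normalize(env, cyc, n_points = n_points)
      cc$subject <- subj
      cc
    })
    curves <- dplyr::bind_rows(purrr::compact(curves))
    if (nrow(curves) == 0L) next
    if (pool == "subjects") {
      curves <- curves |>
        dplyr::group_by(.data$subject, .data$side, .data$muscle,
                        .data$phase) |>
        dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
        dplyr::mutate(cycle = as.integer(factor(.data$subject)))
    }
    ens <- ensemble_average(curves)
    ens$speed <- sp
    all_ens[[length(all_ens) + 1L]] <- ens
    for (mus in muscle_pairs(unique(paste(curves$side, curves$muscle,
                                          sep = "_")))) {
      lc <- ens$mean[ens$side == "left" & ens$muscle == mus]
      rc <- ens$mean[ens$side == "right" & ens$muscle == mus]
      nc <- max(ens$n_cycles[ens$muscle == mus])
      ht <- rank_sum_test(lc, rc, alpha = alpha)
      ml <- mean(lc); mr <- mean(rc)
      sl <- sample_entropy(lc, m = sampen_m, r = sampen_r)
      sr <- sample_entropy(rc, m = sampen_m, r = sampen_r)
      all_rows[[length(all_rows) + 1L]] <- tibble::tibble(
        muscle = mus, condition = format(sp), speed = sp, n_cycles = nc,
        n_left = length(lc), n_right = length(rc),
        mean_left = ml, mean_right = mr,
        delta_d = delta_d(ml, mr), ratio = activity_ratio(ml, mr),
        w = ht$w, p_value = ht$p_value, method = ht$method,
        significant = ht$significant,
        sampen_left = sl$value, sampen_right = sr$value)
    }
  }
  df <- dplyr::bind_rows(all_rows)
  if (nrow(df) > 0L) {
    df <- dplyr::arrange(df, match(.data$muscle, emg_muscles()),
                         .data$speed)
  }
  new_asymmetry_report(df, ensembles = dplyr::bind_rows(all_ens),
                       issues = issues)
}

#' Ensemble curves attached to a dynamic asymmetry report
#'
#' @param report An `asymmetry_report` from [analyze_dynamic()].
#' @return A tibble of ensemble curves with a `speed` column, or `NULL`
#'   for static reports.
#' @export
report_ensembles <- function(report) {
  ens <- attr(report, "ensembles")
  if (!is.null(ens) && !inherits(ens, "emg_ensemble")) {
    class(ens) <- c("emg_ensemble", class(ens))
  }
  ens
}

#' @rdname report_ensembles
#' @export
report_issues <- function(report) attr(report, "issues")

fmt_p <- function(p) sprintf("%.3f", p)

#' Write the result tables and run manifest of an analysis
#'
#' Produces, inside `outdir`:
#' \itemize{
#'   \item `report.tsv` -- the full asymmetry report ([write_table()]).
#'   \item `p_grid.tsv` -- muscles x speeds grid of rank-sum p-values
#'     (three-decimal formatting, so very small values print as `0.000`),
#'     for dynamic rows.
#'   \item `sampen_grid.tsv` -- side/muscle x speeds grid of sample
#'     entropies, for dynamic rows.
#'   \item `means_by_speed.tsv` -- per muscle, speed and side the mean and
#'     SD of the ensemble curve.
#'   \item `manifest.json` -- configuration, seed, package version and the
#'     full-precision report, for reproducibility.
#' }
#' Re-running with the same inputs writes byte-identical files.
#'
#' @param report A non-empty `asymmetry_report` (static, dynamic, or a
#'   row-bound combination).
#' @param outdir Output directory (created if needed).
#' @param config Optional named list recorded in the manifest.
#' @param seed Optional seed recorded in the manifest.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(report, outdir, config = NULL, seed = NULL) {
  stopifnot(is.data.frame(report))
  if (nrow(report) == 0L) abort("Report is empty; nothing to write.")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(outdir, "report.tsv")
  write_table(report, paths[1])
  dyn <- if ("speed" %in% names(report)) {
    report[!is.na(report$speed) & report$condition != "static", ]
  } else report[0, ]
  if (nrow(dyn) > 0L) {
    p_grid <- dyn |>
      dplyr::mutate(p = fmt_p(.data$p_value)) |>
      dplyr::select("muscle", "speed", "p") |>
      tidyr::pivot_wider(names_from = "speed", values_from = "p") |>
      dplyr::arrange(match(.data$muscle, emg_muscles()))
    f <- file.path(outdir, "p_grid.tsv")
    readr::write_tsv(p_grid, f, progress = FALSE)
    paths <- c(paths, f)

    sampen_grid <- dyn |>
      dplyr::select("muscle", "speed", left = "sampen_left",
                    right = "sampen_right") |>
      tidyr::pivot_longer(c("left", "right"), names_to = "side",
                          values_to = "sampen") |>
      dplyr::mutate(sampen = sprintf("%.4f", .data$sampen)) |>
      tidyr::pivot_wider(names_from = "speed", values_from = "sampen") |>
      dplyr::arrange(.data$side, match(.data$muscle, emg_muscles()))
    f <- file.path(outdir, "sampen_grid.tsv")
    readr::write_tsv(sampen_grid, f, progress = FALSE)
    paths <- c(paths, f)

    ens <- report_ensembles(report)
    if (!is.null(ens) && nrow(ens) > 0L) {
      means <- ens |>
        dplyr::group_by(.data$muscle, .data$speed, .data$side) |>
        dplyr::summarise(mean_pct_mvc = mean(.data$mean),
                         sd_pct_mvc = sd(.data$mean),
                         n_cycles = max(.data$n_cycles),
                         .groups = "drop") |>
        dplyr::arrange(match(.data$muscle, emg_muscles()), .data$speed,
                       .data$side)
      f <- file.path(outdir, "means_by_speed.tsv")
      readr::write_tsv(means, f, progress = FALSE)
      paths <- c(paths, f)
    }
  }
  manifest <- list(
    package = "gaitsemg",
    version = as.character(utils::packageVersion("gaitsemg")),
    seed = seed,
    config = config,
    report = report[, intersect(report_columns(), names(report))])
  f <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, f, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  paths <- c(paths, f)
  invisible(paths)
}
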