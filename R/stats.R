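#' Wilcoxon rank-sum comparison of two samples
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) test with midranks for ties.
#' The p-value is exact (full enumeration of the rank-sum null
#' distribution) when the combined sample size is at most 20 and there are
#' no ties; otherwise a normal approximation with tie-corrected variance
#' and continuity correction is used.
#'
#' @param x,y Non-empty numeric samples (left and right limb, typically).
#' @param alpha Significance level for the `significant` flag.
#' @return An object of class `rank_sum`: a list with `w` (rank sum of
#'   `x`), `statistic` (Mann-Whitney U), `p_value`, `method`
#'   (`"exact"` or `"normal"`), `tie_corrected`, `n_x`, `n_y`, `alpha`,
#'   `significant`.
#' @export
#' @examples
#' rank_sum_test(c(1, 2, 3), c(4, 5, 6))$p_value  # 0.1
rank_sum_test <- function(x, y, alpha = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0L || length(y) == 0L) {
    abort("Both samples must be non-empty.")
  }
  if (anyNA(x) || anyNA(y)) abort("Samples must not contain NA.")
  n <- length(x); m <- length(y)
  rk <- rank(c(x, y))                        # midranks
  w <- sum(rk[seq_len(n)])
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- (n + m) <= 20L && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = use_exact, correct = TRUE,
                       alternative = "two.sided"))
  p <- min(1, ht$p.value)
  structure(list(w = w, statistic = unname(ht$statistic), p_value = p,
                 method = if (use_exact) "exact" else "normal",
                 tie_corrected = !use_exact && ties,
                 n_x = n, n_y = m, alpha = alpha,
                 significant = p < alpha),
            class = "rank_sum")
}

#' @export
print.rank_sum <- function(x, ...) {
  cat(sprintf("Wilcoxon rank-sum: W = %g, p = %.4g (%s%s), n = %d vs %d\n",
              x$w, x$p_value, x$method,
              if (x$tie_corrected) ", tie-corrected" else "",
              x$n_x, x$n_y))
  invisible(x)
}

#' @rdname rank_sum_test
#' @param ... Unused.
#' @export
tidy.rank_sum <- function(x, ...) {
  tibble::tibble(w = x$w, statistic = x$statistic, p.value = x$p_value,
                 method = x$method, tie_corrected = x$tie_corrected,
                 n_x = x$n_x, n_y = x$n_y, significant = x$significant)
}

#' @rdname rank_sum_test
#' @export
glance.rank_sum <- function(x, ...) tidy(x)

#' Absolute left/right mean difference
#'
#' The asymmetry descriptor for a muscle at one condition: the absolute
#' difference between the left and right mean activation in %MVC
#' percentage points. Symmetric under limb swap.
#'
#' @param mean_left,mean_right Mean activations (%MVC), vectorized over
#'   conditions.
#' @return Absolute differences (percentage points).
#' @export
#' @examples
#' delta_d(30, 25)  # 5
delta_d <- function(mean_left, mean_right) {
  if (any(mean_left < 0, na.rm = TRUE) || any(mean_right < 0, na.rm = TRUE)) {
    abort("Mean activations must be non-negative.")
  }
  abs(mean_left - mean_right)
}

#' Range of the asymmetry descriptor across speeds
#'
#' Summarizes per-speed values of [delta_d()] into their maximum and
#' minimum, per muscle when applied to an asymmetry report.
#'
#' @param x Either a numeric vector of per-speed differences or an
#'   `asymmetry_report` tibble with `muscle` and `delta_d` columns.
#' @return A tibble with `delta_d_max` and `delta_d_min` (and `muscle`
#'   when summarizing a report).
#' @export
#' @examples
#' delta_d_summary(c(2, 7, 4))
delta_d_summary <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("muscle", "delta_d") %in% names(x)))
    x |>
      dplyr::group_by(.data$muscle) |>
      dplyr::summarise(delta_d_max = max(.data$delta_d, na.rm = TRUE),
                       delta_d_min = min(.data$delta_d, na.rm = TRUE),
                       .groups = "drop")
  } else {
    tibble::tibble(delta_d_max = max(x, na.rm = TRUE),
                   delta_d_min = min(x, na.rm = TRUE))
  }
}

#' Ratio of two mean activations
#'
#' @param mean_a,mean_b Mean activations; `mean_b` must be positive.
#' @return `mean_a / mean_b` (dimensionless); inverts under limb swap.
#' @export
#' @examples
#' activity_ratio(2.9, 1.0)
activity_ratio <- function(mean_a, mean_b) {
  if (any(mean_b <= 0, na.rm = TRUE)) {
    abort("Denominator mean must be positive.")
  }
  mean_a / mean_b
}
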