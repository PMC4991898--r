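#' Standardize a series to zero mean and unit variance
#'
#' Sample entropy is computed on standardized series so that the tolerance
#' `r` is expressed in SD units of the data; this also makes the entropy
#' invariant to affine rescaling of the input.
#'
#' @param x Numeric series of length >= 2 with non-zero variance.
#' @return The standardized series (mean 0, SD 1).
#' @export
#' @examples
#' z <- standardize_series(c(1, 2, 3))
#' c(mean(z), sd(z))
standardize_series <- function(x) {
  if (length(x) < 2L) abort("Series must have at least 2 points.")
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort("Series has zero variance; sample entropy is undefined.")
  }
  (x - mean(x)) / s
}

# ordered-pair match count among the first `n_templates` length-m templates,
# Chebyshev distance strictly below r
count_template_matches <- function(x, m, r, n_templates) {
  n <- length(x)
  if (n_templates < 2L) abort("Series too short: fewer than 2 templates.")
  # running Chebyshev distance, one vectorized pass per template
  count <- 0L
  idx <- seq_len(n_templates)
  for (i in idx) {
    d <- abs(x[idx] - x[i])
    if (m > 1L) {
      for (k in 1:(m - 1L)) {
        d <- pmax(d, abs(x[idx + k] - x[i + k]))
      }
    }
    count <- count + sum(d < r) - as.integer(d[i] < r)
  }
  count
}

#' Count matching template pairs
#'
#' Counts ordered pairs (i, j), i != j, of length-`m` subsequences
#' (templates) whose Chebyshev (maximum-norm) distance is strictly below
#' `r`. By default all `N - m + 1` templates are used.
#'
#' @param x Numeric series (standardize first if `r` is meant in SD units).
#' @param m Template length (embedding dimension), >= 1.
#' @param r Tolerance (strict inequality).
#' @param n_templates Number of leading templates to compare (defaults to
#'   all `N - m + 1`).
#' @return Integer count of ordered matching pairs.
#' @export
#' @examples
#' match_counts(c(0, 1, 0, 1, 0), m = 2, r = 0.5)  # 4
match_counts <- function(x, m, r, n_templates = NULL) {
  if (m < 1L) abort("`m` must be a positive integer.")
  if (r <= 0) abort("`r` must be positive.")
  n <- length(x)
  t_all <- n - m + 1L
  if (t_all < 2L) abort("Series too short for the requested `m`.")
  n_templates <- n_templates %||% t_all
  if (n_templates > t_all) abort("`n_templates` exceeds available templates.")
  count_template_matches(x, m, r, n_templates)
}

#' Sample entropy of a time series
#'
#' Sample entropy (SampEn) measures the irregularity of a series as the
#' negative log of the conditional probability that subsequences matching
#' for `m` points (within tolerance `r`, maximum norm, strict inequality)
#' still match at length `m + 1`. Lower values indicate a more
#' self-similar (regular) series; higher values a more random one.
#'
#' Two formulations are provided:
#' \describe{
#'   \item{`"standard"`}{The Richman-Moorman convention: the same
#'     `N - m` templates are used at both lengths, so
#'     `SampEn = -log(A / B)` with `A` and `B` the ordered-pair match
#'     counts at lengths `m + 1` and `m`. Always >= 0 when defined; this
#'     is the default and the formulation behind reported values.}
#'   \item{`"binomial"`}{A step-by-step formulation that circulates in
#'     parts of the applied literature: all `N - m + 1` templates at
#'     length `m` (and `N - m` at `m + 1`), each ordered-pair count
#'     divided by the unordered-pair binomial coefficient
#'     `choose(T, 2)`, and the ratio orientated as
#'     `-log(phi_m / phi_{m+1})`. Because `phi_m >= phi_{m+1}` in
#'     practice this yields non-positive values; it is provided for
#'     auditing published numbers, not as a default.}
#' }
#'
#' When no template pair still matches at length `m + 1` the conditional
#' probability is zero and the entropy is unbounded: the standard mode
#' returns `Inf` with the `undefined` flag set.
#'
#' @param x Numeric series with `length(x) > m + 1` and non-zero variance.
#' @param m Embedding dimension (default 2).
#' @param r Tolerance in SD units of the series (default 0.2, i.e. 0.2 SD
#'   after standardization).
#' @param mode `"standard"` or `"binomial"`.
#' @param scale Standardize the series first (default `TRUE`).
#' @return An object of class `sampen`: a list with `value` (nats),
#'   `phi_m`, `phi_m1`, `n_templates_m`, `n_templates_m1`, `m`, `r`,
#'   `mode`, `n`, `undefined`.
#' @export
#' @examples
#' set.seed(1)
#' sample_entropy(rnorm(100))$value
sample_entropy <- function(x, m = 2, r = 0.2,
                           mode = c("standard", "binomial"),
                           scale = TRUE) {
  mode <- match.arg(mode)
  n <- length(x)
  if (n <= m + 1L) abort("Series too short: need length > m + 1.")
  if (scale) x <- standardize_series(x)
  undefined <- FALSE
  if (mode == "standard") {
    t_m <- n - m                  # equalized template counts
    b_count <- count_template_matches(x, m, r, t_m)
    a_count <- count_template_matches(x, m + 1L, r, t_m)
    denom <- t_m * (t_m - 1)
    phi_m <- b_count / denom
    phi_m1 <- a_count / denom
    if (b_count == 0) abort("No template matches at length m; increase r.")
    if (a_count == 0) {
      value <- Inf                # conditional probability 0: unbounded
      undefined <- TRUE
    } else {
      value <- -log(a_count / b_count)
    }
    nt <- c(t_m, t_m)
  } else {
    t_m <- n - m + 1L
    t_m1 <- n - m
    num_m <- count_template_matches(x, m, r, t_m)
    num_m1 <- count_template_matches(x, m + 1L, r, t_m1)
    phi_m <- num_m / choose(t_m, 2)
    phi_m1 <- num_m1 / choose(t_m1, 2)
    if (phi_m == 0) abort("No template matches at length m; increase r.")
    if (phi_m1 == 0) {
      value <- -Inf
      undefined <- TRUE
    } else {
      value <- -log(phi_m / phi_m1)
    }
    nt <- c(t_m, t_m1)
  }
  structure(list(value = value, phi_m = phi_m, phi_m1 = phi_m1,
                 n_templates_m = nt[1], n_templates_m1 = nt[2],
                 m = m, r = r, mode = mode, n = n, undefined = undefined),
            class = "sampen")
}

#' @export
print.sampen <- function(x, ...) {
  cat(sprintf("Sample entropy (%s): %.4f  [m = %d, r = %g, N = %d]\n",
              x$mode, x$value, x$m, x$r, x$n))
  invisible(x)
}

#' @rdname sample_entropy
#' @param x A `sampen` object.
#' @param ... Unused.
#' @export
tidy.sampen <- function(x, ...) {
  tibble::tibble(value = x$value, phi_m = x$phi_m, phi_m1 = x$phi_m1,
                 m = x$m, r = x$r, mode = x$mode, n = x$n,
                 undefined = x$undefined)
}

#' @rdname sample_entropy
#' @export
glance.sampen <- function(x, ...) tidy(x)[, c("value", "m", "r", "mode", "n")]

#' Sample entropy of a phase-normalized curve
#'
#' Applies [sample_entropy()] to the value series of a single cycle or
#' ensemble curve (e.g. the 100-point ensemble mean of one muscle/side). A
#' flat curve has no variance and is an error.
#'
#' @param curve A tibble with a `value` column (cycle curve) or a `mean`
#'   column (ensemble curve), holding a single curve.
#' @inheritParams sample_entropy
#' @return A `sampen` object.
#' @export
sampen_curve <- function(curve, m = 2, r = 0.2,
                         mode = c("standard", "binomial")) {
  stopifnot(is.data.frame(curve))
  col <- if ("value" %in% names(curve)) "value" else if
    ("mean" %in% names(curve)) "mean" else
    abort("`curve` needs a `value` or `mean` column.")
  if (all(c("side", "muscle") %in% names(curve))) {
    if (nrow(dplyr::distinct(curve[, c("side", "muscle")])) != 1L) {
      abort("`curve` must hold a single side/muscle curve.")
    }
  }
  sample_entropy(curve[[col]], m = m, r = r, mode = match.arg(mode))
}
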