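test_that("standardization centres and scales, and refuses constants", {
  z <- standardize_series(c(1, 2, 3))
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_equal(standardize_series(z), z, tolerance = 1e-12)
  expect_error(standardize_series(c(5, 5, 5)), "zero variance")
  expect_error(standardize_series(5), "at least 2")
})

test_that("template match counting agrees with hand enumeration", {
  # templates (0,1),(1,0),(0,1),(1,0): two identical pairs, counted twice
  expect_equal(match_counts(c(0, 1, 0, 1, 0), m = 2, r = 0.5), 4)
  # r -> Inf: every ordered pair matches
  set.seed(2)
  x <- rnorm(20)
  t_all <- 20 - 2 + 1
  expect_equal(match_counts(x, m = 2, r = Inf), t_all * (t_all - 1))
  # huge gaps, small r: nothing matches
  expect_equal(match_counts(cumsum(rep(10, 10)), m = 2, r = 0.5), 0)
})

test_that("all-match limit gives zero entropy", {
  set.seed(3)
  res <- sample_entropy(rnorm(50), m = 2, r = 1e6)
  expect_equal(res$value, 0)
  expect_equal(res$phi_m, 1)
  expect_equal(res$phi_m1, 1)
})

test_that("both modes equal the brute-force oracle on seeded series", {
  for (seed in 1:4) {
    set.seed(seed)
    x <- rnorm(60 + 20 * seed)
    for (mode in c("standard", "binomial")) {
      expect_equal(sample_entropy(x, 2, 0.2, mode = mode)$value,
                   oracle_sampen(x, 2, 0.2, mode), tolerance = 1e-12)
    }
  }
  set.seed(99)
  x <- rnorm(100)
  expect_equal(sample_entropy(x, 2, 0.2)$value, oracle_sampen(x, 2, 0.2),
               tolerance = 1e-12)
})

test_that("a periodic series is more regular than white noise", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- 150
    noisy <- rnorm(n)
    periodic <- periodic_series(n) + rnorm(n, sd = 0.02)
    expect_lt(sample_entropy(periodic, 2, 0.2)$value,
              sample_entropy(noisy, 2, 0.2)$value)
  }
})

test_that("match fractions rise with r, and entropy falls over a wide r gap", {
  # the match fractions are non-decreasing in r by construction; the
  # entropy value itself can fluctuate upward between nearby r in finite
  # samples, but falls clearly between widely separated tolerances
  rs <- c(0.1, 0.15, 0.2, 0.3, 0.5)
  for (seed in 11:20) {
    set.seed(seed)
    x <- rnorm(120)
    fits <- lapply(rs, function(r) sample_entropy(x, 2, r))
    phi_m <- vapply(fits, `[[`, numeric(1), "phi_m")
    phi_m1 <- vapply(fits, `[[`, numeric(1), "phi_m1")
    vals <- vapply(fits, `[[`, numeric(1), "value")
    expect_true(all(diff(phi_m) >= 0))
    expect_true(all(diff(phi_m1) >= 0))
    expect_gt(vals[1], vals[length(vals)])
  }
})

test_that("entropy is invariant to affine rescaling and non-negative", {
  for (seed in 5:9) {
    set.seed(seed)
    x <- rnorm(80)
    base <- sample_entropy(x, 2, 0.2)$value
    expect_gte(base, 0)
    expect_equal(sample_entropy(3.7 * x - 11, 2, 0.2)$value, base,
                 tolerance = 1e-10)
  }
})

test_that("unmatchable continuations are flagged as unbounded", {
  x <- c(0, 1, 0, 1, 2)          # m-matches exist, no (m+1)-match
  res <- sample_entropy(x, m = 2, r = 0.5, scale = FALSE)
  expect_true(is.infinite(res$value) && res$value > 0)
  expect_true(res$undefined)
  expect_error(sample_entropy(cumsum(rep(10, 10)), 2, r = 0.01,
                              scale = FALSE), "increase r")
  expect_error(sample_entropy(rnorm(3), m = 2), "too short")
})

test_that("the audit mode reports the inverted-ratio convention", {
  set.seed(41)
  x <- rnorm(100)
  res <- sample_entropy(x, 2, 0.2, mode = "binomial")
  expect_lte(res$value, 0)                  # phi_m >= phi_{m+1}
  expect_gt(res$phi_m, 0)
  expect_lte(res$phi_m, 2)                  # ordered pairs over C(T, 2)
  expect_equal(res$n_templates_m, 99)
  expect_equal(res$n_templates_m1, 98)
})

test_that("curve entropy rejects flat curves and sees injected ripple", {
  flat <- tibble::tibble(side = "left", muscle = "MG",
                         phase = (0:99) / 100, value = rep(1, 100))
  expect_error(sampen_curve(flat), "zero variance")
  ph <- (0:99) / 100
  base <- exp(-0.5 * ((ph - 0.45) / 0.08)^2) + 0.15
  left <- tibble::tibble(side = "left", muscle = "MG", phase = ph,
                         value = base)
  right <- dplyr::mutate(left, side = "right",
                         value = base * (1 + 0.3 * sin(2 * pi * 4 * ph)))
  expect_gt(sampen_curve(right)$value, sampen_curve(left)$value)
  # identical curves give identical entropy
  expect_identical(sampen_curve(left)$value, sampen_curve(left)$value)
})

test_that("tidy and glance expose the fitted quantities", {
  set.seed(1)
  res <- sample_entropy(rnorm(60))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$value, res$value)
  expect_equal(td$m, 2)
  gl <- glance(res)
  expect_named(gl, c("value", "m", "r", "mode", "n"))
})
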