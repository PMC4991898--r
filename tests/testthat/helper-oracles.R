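# Independent brute-force oracles, deliberately written as plain loops /
# full enumerations so they share no code path with the implementation.

# ordered-pair template match count, triple loop
oracle_count <- function(x, m, r, n_templates) {
  cnt <- 0L
  for (i in seq_len(n_templates)) {
    for (j in seq_len(n_templates)) {
      if (i == j) next
      d <- 0
      for (k in 0:(m - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
      if (d < r) cnt <- cnt + 1L
    }
  }
  cnt
}

oracle_sampen <- function(x, m, r, mode = "standard") {
  x <- (x - mean(x)) / sd(x)
  n <- length(x)
  if (mode == "standard") {
    b <- oracle_count(x, m, r, n - m)
    a <- oracle_count(x, m + 1, r, n - m)
    if (a == 0) return(Inf)
    -log(a / b)
  } else {
    phi_m <- oracle_count(x, m, r, n - m + 1) / choose(n - m + 1, 2)
    phi_m1 <- oracle_count(x, m + 1, r, n - m) / choose(n - m, 2)
    if (phi_m1 == 0) return(-Inf)
    -log(phi_m / phi_m1)
  }
}

# exact two-sided rank-sum p by enumerating every size-n subset of ranks
oracle_ranksum_p <- function(x, y) {
  n <- length(x)
  total <- n + length(y)
  rk <- rank(c(x, y))
  w_obs <- sum(rk[seq_len(n)])
  subsets <- utils::combn(total, n)
  ws <- colSums(matrix(seq_len(total)[subsets], nrow = n))
  mu <- n * (total + 1) / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# a strictly periodic series with a long repeated motif
periodic_series <- function(n, motif_len = 20) {
  motif <- sin(2 * pi * seq_len(motif_len) / motif_len)
  rep_len(motif, n)
}
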