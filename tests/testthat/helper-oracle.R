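# Independent brute-force reference for the peak screens.
#
# Deliberately avoids the package's internals *and* base rank():
# average ranks come from the counting formula
#   R_i = #{j : a_j < a_i} + (#{j : a_j == a_i} + 1) / 2,
# circular windows from an explicitly extended vector, and the argmax
# from a plain loop keeping the first maximum.

oracle_ranks <- function(a) {
  vapply(seq_along(a), function(i) {
    sum(a < a[i]) + (sum(a == a[i]) + 1) / 2
  }, numeric(1L))
}

oracle_window <- function(a, n, h) {
  N <- length(a)
  ext <- c(a[N - 1L], a[N], a, a[1L], a[2L])  # positions -1..N+2 at offset +2
  ext[(n - h):(n + h) + 2L]
}

oracle_eval <- function(a, r3_min, r5_min, k3_min = 0.3, k5_min = 0.6) {
  N <- length(a)
  R <- oracle_ranks(a)

  best3 <- -Inf; n3 <- NA_integer_
  for (n in 1:N) {
    s <- sum(oracle_window(a, n, 1L))
    if (s > best3) { best3 <- s; n3 <- n }
  }
  r3 <- sum(oracle_window(R, n3, 1L))
  k3 <- if (best3 > 0) a[n3] / best3 else 0
  pass1 <- (r3 > r3_min) && (k3 > k3_min)

  best5 <- -Inf; n5 <- NA_integer_
  for (n in 1:N) {
    s <- sum(oracle_window(a, n, 2L))
    if (s > best5) { best5 <- s; n5 <- n }
  }
  r5 <- sum(oracle_window(R, n5, 2L))
  inner <- sum(oracle_window(a, n5, 1L))
  k5 <- if (best5 > 0) inner / best5 else 0
  k3b <- if (inner > 0) a[n5] / inner else 0
  pass2 <- (r5 > r5_min) && (k5 > k5_min) && (k3b > k3_min)

  list(n3 = n3, S3 = best3, r3 = r3, k3 = k3, part1_pass = pass1,
       n5 = n5, S5 = best5, r5 = r5, k5 = k5, k3_part2 = k3b,
       part2_pass = pass2, is_periodic = pass1 || pass2,
       peak_index = if (pass1) n3 else if (pass2) n5 else n3)
}

has_window_tie <- function(a, N = length(a), tol = 1e-9) {
  s3 <- vapply(1:N, function(n) sum(oracle_window(a, n, 1L)), numeric(1L))
  s5 <- vapply(1:N, function(n) sum(oracle_window(a, n, 2L)), numeric(1L))
  sum(max(s3) - s3 < tol) > 1L || sum(max(s5) - s5 < tol) > 1L
}

# Random non-negative series mixing smooth bumps, noise and ties.
random_series <- function(N) {
  kind <- sample(3L, 1L)
  if (kind == 1L) {
    round(stats::rlnorm(N, log(3), 1), sample(c(0, 1, 3), 1L))  # ties likely
  } else if (kind == 2L) {
    p <- sample(N, 1L)
    d <- pmin(abs(1:N - p), N - abs(1:N - p))
    (stats::runif(1, 0.5, 5) + stats::runif(1, 2, 30) * exp(-d^2 / 2)) *
      exp(stats::rnorm(N, 0, 0.2))
  } else {
    stats::runif(N, 0, 10)
  }
}
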