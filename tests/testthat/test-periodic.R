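test_that("rank_series ranks larger values higher and handles ties", {
  expect_equal(rank_series(1:8), as.numeric(1:8))
  expect_equal(rank_series(rep(5, 8)), rep(4.5, 8))
  expect_equal(rank_series(c(0, 0, 0, 10, 0, 0, 0, 0)),
               c(4, 4, 4, 8, 4, 4, 4, 4))
  expect_equal(rank_series(rep(5, 8), tie_method = "ordinal"), as.numeric(1:8))
  # conservation: averaged ranks always sum to N(N+1)/2
  set.seed(11)
  for (N in c(8L, 10L)) {
    for (rep in 1:25) {
      a <- random_series(N)
      expect_equal(sum(rank_series(a)), N * (N + 1) / 2)
    }
  }
})

test_that("circular window sums wrap around the time course", {
  a <- as.numeric(1:8)
  expect_equal(circular_window_sum(a, 8, 1), 7 + 8 + 1)
  expect_equal(circular_window_sum(a, 1, 2), 7 + 8 + 1 + 2 + 3)
  expect_equal(circular_window_sum(rep(2.5, 8), 3, 1), 7.5)
  expect_error(circular_window_sum(a, 9, 1), "out of range")
  expect_error(circular_window_sum(a, 0, 2), "out of range")
})

test_that("locate_peak finds the maximal window, smallest index on ties", {
  expect_equal(locate_peak(as.numeric(1:8), 1), list(n = 7L, S = 21))
  expect_equal(locate_peak(rep(3, 8), 1)$n, 1L)
  expect_equal(locate_peak(c(1, 2, 4, 8, 4, 2, 1, 1), 2), list(n = 4L, S = 20))
})

test_that("default thresholds reproduce the documented screen floors", {
  t8 <- default_thresholds(8)
  expect_equal(t8$r3_min, 18); expect_equal(t8$r5_min, 25)
  expect_equal(t8$k3_min, 0.3); expect_equal(t8$k5_min, 0.6)
  t10 <- default_thresholds(10)
  expect_equal(t10$r3_min, 24); expect_equal(t10$r5_min, 35)
  t12 <- default_thresholds(12)
  expect_equal(t12$r3_min, 30); expect_equal(t12$r5_min, 45)
  expect_error(default_thresholds(4), "at least 5 samples")
})

test_that("part-1 screen matches hand-evaluated cases", {
  ramp <- evaluate_part1(as.numeric(1:8))
  expect_equal(ramp[c("n3", "S3", "r3")], list(n3 = 7L, S3 = 21, r3 = 21))
  expect_equal(ramp$k3, 7 / 21)
  expect_true(ramp$part1_pass)

  spike <- evaluate_part1(c(0, 0, 0, 10, 0, 0, 0, 0))
  expect_equal(spike$r3, 16)          # 4 + 8 + 4 with averaged ties
  expect_false(spike$part1_pass)

  flat <- evaluate_part1(rep(2, 8))
  expect_equal(flat$r3, 13.5)
  expect_false(flat$part1_pass)
})

test_that("part-2 screen matches hand-evaluated cases", {
  tent <- evaluate_part2(c(1, 2, 4, 8, 4, 2, 1, 1))
  expect_equal(tent[c("n5", "S5", "r5")], list(n5 = 4L, S5 = 20, r5 = 30))
  expect_equal(tent$k5, 16 / 20)
  expect_equal(tent$k3_part2, 8 / 16)
  expect_true(tent$part2_pass)

  spike <- evaluate_part2(c(0, 0, 0, 10, 0, 0, 0, 0))
  expect_equal(spike$r5, 24)
  expect_false(spike$part2_pass)

  flat <- evaluate_part2(rep(2, 8))
  expect_equal(flat$r5, 22.5)
  expect_false(flat$part2_pass)
})

test_that("classification combines the two screens per policy", {
  ramp <- classify_transcript(as.numeric(1:8))
  expect_true(ramp$is_periodic)
  expect_equal(ramp$peak_index, 7L)

  tent <- classify_transcript(c(1, 2, 4, 8, 4, 2, 1, 1), combine = "part2_only")
  expect_true(tent$is_periodic)
  expect_equal(tent$peak_index, 4L)

  for (policy in c("union", "part1_only", "part2_only", "intersection")) {
    expect_false(classify_transcript(rep(7, 8), combine = policy)$is_periodic)
    expect_false(classify_transcript(rep(0, 8), combine = policy)$is_periodic)
  }
})

test_that("zero-expression windows give zero concentration, not NaN", {
  a <- c(0, 0, 0, 0, 0, 0, 0, 1e-12)
  p1 <- evaluate_part1(c(rep(0, 8)))
  expect_identical(p1$k3, 0)
  p2 <- evaluate_part2(rep(0, 8))
  expect_identical(p2$k5, 0)
  expect_identical(p2$k3_part2, 0)
  expect_false(classify_transcript(a)$is_periodic)
})

test_that("detect_matrix evaluates every row in order", {
  calls <- detect_matrix(fixture_three_transcripts())
  expect_identical(calls$transcript_id, c("ramp", "spike", "flat"))
  expect_identical(calls$is_periodic, c(TRUE, FALSE, FALSE))
  expect_equal(calls$peak_index[1], 7L)

  empty <- detect_matrix(fixture_three_transcripts()[0, , drop = FALSE])
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("r3", "k5", "is_periodic", "peak_index") %in% colnames(empty)))

  sim <- simulate_cycle_matrix(cycle_sim_spec(N = 8, n_periodic = 100,
                                              n_aperiodic = 400,
                                              noise_sd = 0, seed = 3))
  calls0 <- detect_matrix(sim$matrix)
  merged <- merge(calls0, sim$truth, by = "transcript_id")
  expect_true(all(merged$is_periodic.x[merged$is_periodic.y]))       # all bumps found
  expect_false(any(merged$is_periodic.x[!merged$is_periodic.y]))     # no flat false calls
})

test_that("min-fpkm floor suppresses calls on weakly expressed transcripts", {
  m <- rbind(strong = as.numeric(1:8), weak = as.numeric(1:8) / 100)
  colnames(m) <- paste0("s", 1:8)
  calls <- detect_matrix(m, min_fpkm = 0.5)
  expect_identical(calls$is_periodic, c(TRUE, FALSE))
})

test_that("statistics are invariant to rotation and positive scaling", {
  set.seed(23)
  stats_cols <- c("S3", "r3", "k3", "S5", "r5", "k5", "k3_part2",
                  "part1_pass", "part2_pass", "is_periodic")
  for (N in c(8L, 10L)) {
    for (rep in 1:20) {
      a <- random_series(N)
      base <- classify_transcript(a)
      s <- sample(N - 1L, 1L)
      # rotation by s moves indices back by s (mod N), statistics unchanged;
      # only well-posed when the maximal window is unique (ties resolve by
      # smallest index, which is not rotation-equivariant)
      if (!has_window_tie(a, N)) {
        rotated <- classify_transcript(c(a[(s + 1):N], a[1:s]))
        expect_equal(rotated$n3, (base$n3 - s - 1) %% N + 1)
        expect_equal(rotated$n5, (base$n5 - s - 1) %% N + 1)
        expect_equal(rotated$peak_index, (base$peak_index - s - 1) %% N + 1)
        expect_equal(rotated[stats_cols], base[stats_cols])
      }
      scaled <- classify_transcript(a * runif(1, 0.01, 100))
      expect_equal(scaled$n3, base$n3)
      expect_equal(scaled$n5, base$n5)
      expect_equal(scaled[setdiff(stats_cols, c("S3", "S5"))],
                   base[setdiff(stats_cols, c("S3", "S5"))])
    }
  }
})

test_that("rank sums respect their attainable bounds", {
  set.seed(31)
  for (N in c(8L, 10L)) {
    for (rep in 1:50) {
      ev <- classify_transcript(random_series(N))
      expect_lte(ev$r3, 3 * N - 3)
      expect_gte(ev$r3, 3)
      expect_lte(ev$r5, 5 * N - 10)
      expect_gte(ev$r5, 10)
    }
  }
})

test_that("screens agree exactly with the brute-force oracle", {
  set.seed(7)
  fields <- c("n3", "S3", "r3", "k3", "part1_pass",
              "n5", "S5", "r5", "k5", "k3_part2", "part2_pass",
              "is_periodic", "peak_index")
  for (N in c(8L, 10L)) {
    t <- default_thresholds(N)
    for (rep in 1:100) {
      a <- random_series(N)
      got <- classify_transcript(a, t)
      want <- oracle_eval(a, t$r3_min, t$r5_min, t$k3_min, t$k5_min)
      expect_equal(got[fields], want[fields], info = paste(a, collapse = ","))
    }
  }
})
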