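#' Screening thresholds for the periodicity screens
#'
#' Bundles the four thresholds of the rank-based peak screens: the 3-window
#' rank-sum floor `r3_min`, the 5-window rank-sum floor `r5_min`, the peak
#' concentration floor `k3_min` (fraction of the 3-window sum carried by its
#' centre) and the inner-window concentration floor `k5_min` (fraction of
#' the 5-window sum carried by its inner 3 samples). A series passes a
#' screen only by exceeding the floors strictly.
#'
#' @param r3_min Rank-sum floor for the 3-sample window.
#' @param r5_min Rank-sum floor for the 5-sample window.
#' @param k3_min Concentration floor for the window centre, in (0, 1].
#' @param k5_min Concentration floor for the inner 3-window, in (0, 1].
#' @return An object of class `threshold_set`.
#' @seealso [default_thresholds()] for the sample-count-dependent defaults.
#' @export
threshold_set <- function(r3_min, r5_min, k3_min = 0.3, k5_min = 0.6) {
  stopifnot(is.numeric(r3_min), length(r3_min) == 1L, is.finite(r3_min),
            is.numeric(r5_min), length(r5_min) == 1L, is.finite(r5_min))
  if (!(k3_min > 0 && k3_min <= 1)) stop("k3_min must lie in (0, 1]")
  if (!(k5_min > 0 && k5_min <= 1)) stop("k5_min must lie in (0, 1]")
  structure(list(r3_min = r3_min, r5_min = r5_min,
                 k3_min = k3_min, k5_min = k5_min),
            class = "threshold_set")
}

#' Default thresholds as a function of sample count
#'
#' `r3_min = 3N - 6` and `r5_min = 5N - 15`, which give r3 > 18 / r5 > 25
#' for N = 8 samples and r3 > 24 / r5 > 35 for N = 10 samples; the closed
#' forms extend the same screening stringency to other time-course lengths.
#' Concentration floors are k3 > 0.3 and k5 > 0.6 irrespective of N.
#'
#' @param N Number of ordered samples in the time course (>= 5).
#' @return A [threshold_set()].
#' @export
default_thresholds <- function(N) {
  stopifnot(is.numeric(N), length(N) == 1L)
  if (is.na(N) || N < 5) stop("at least 5 samples are required; got N = ", N)
  t <- threshold_set(r3_min = 3 * N - 6, r5_min = 5 * N - 15,
                     k3_min = 0.3, k5_min = 0.6)
  # sanity: floors must be attainable (r3 can reach 3N - 3, r5 can reach 5N - 10)
  stopifnot(t$r3_min < 3 * N - 3, t$r5_min < 5 * N - 10)
  t
}

check_series <- function(a) {
  if (!is.numeric(a)) stop("expression series must be numeric")
  if (length(a) < 5L) stop("expression series must have at least 5 samples; got ", length(a))
  if (any(!is.finite(a))) stop("expression series contains non-finite values")
  if (any(a < 0)) stop("expression series contains negative values")
  invisible(a)
}

#' Rank the samples of an expression series
#'
#' Ranks within one transcript's series, largest value receiving the
#' largest rank. Ties are averaged by default, so the ranks always sum to
#' N(N+1)/2; `"ordinal"` breaks ties by position, yielding a strict
#' permutation of 1..N.
#'
#' @param a Numeric series of FPKM values.
#' @param tie_method `"average"` (default) or `"ordinal"`.
#' @return Numeric vector of ranks R_1..R_N.
#' @export
rank_series <- function(a, tie_method = c("average", "ordinal")) {
  check_series(a)
  tie_method <- match.arg(tie_method)
  rank(a, ties.method = if (tie_method == "average") "average" else "first")
}

circular_index <- function(n, N) (n - 1L) %% N + 1L

#' Circular window sum
#'
#' Sum of a series over the window `n - halfwidth .. n + halfwidth` with
#' circular index wrap (the time course is treated as one full cycle, so
#' a_0 = a_N, a_{N+1} = a_1, etc.).
#'
#' @param a Numeric series.
#' @param n Centre index, 1-based.
#' @param halfwidth 1 (3-sample window) or 2 (5-sample window).
#' @return The window sum.
#' @export
circular_window_sum <- function(a, n, halfwidth) {
  check_series(a)
  N <- length(a)
  if (!halfwidth %in% c(1L, 2L)) stop("halfwidth must be 1 or 2")
  if (n < 1L || n > N) stop("window centre out of range: n = ", n, ", N = ", N)
  sum(a[circular_index((n - halfwidth):(n + halfwidth), N)])
}

#' Locate the maximal circular window
#'
#' Finds the centre index maximizing the circular window sum; on ties the
#' smallest index wins, so the result is deterministic and independent of
#' evaluation order.
#'
#' @param a Numeric series.
#' @param halfwidth 1 or 2.
#' @return List with `n` (centre of the maximal window) and `S` (its sum).
#' @export
locate_peak <- function(a, halfwidth) {
  check_series(a)
  N <- length(a)
  sums <- vapply(seq_len(N), function(n) circular_window_sum(a, n, halfwidth), numeric(1L))
  n <- which.max(sums)   # ties: smallest index
  list(n = n, S = sums[n])
}

#' First-part screen: 3-sample window
#'
#' Locates the maximal 3-sample circular window, then requires (i) the
#' rank sum r3 of the window's samples to exceed `r3_min` — the window must
#' hold the series' largest observations — and (ii) the peak concentration
#' k3 = a_n / S3 to exceed `k3_min`, guarding against collapse in the
#' middle of the peak. k3 is defined as 0 when S3 = 0.
#'
#' @param a Numeric series.
#' @param thresholds A [threshold_set()].
#' @param tie_method Rank tie handling, see [rank_series()].
#' @return List with `n3`, `S3`, `r3`, `k3`, `part1_pass`.
#' @export
evaluate_part1 <- function(a, thresholds = default_thresholds(length(a)),
                           tie_method = c("average", "ordinal")) {
  tie_method <- match.arg(tie_method)
  R <- rank_series(a, tie_method)
  N <- length(a)
  pk <- locate_peak(a, 1L)
  w <- circular_index((pk$n - 1L):(pk$n + 1L), N)
  r3 <- sum(R[w])
  k3 <- if (pk$S > 0) a[pk$n] / pk$S else 0
  list(n3 = pk$n, S3 = pk$S, r3 = r3, k3 = k3,
       part1_pass = r3 > thresholds$r3_min && k3 > thresholds$k3_min)
}

#' Second-part screen: 5-sample window
#'
#' Widens the window to 5 samples for fault tolerance to broader peaks.
#' Requires the 5-window rank sum r5 > `r5_min`, the inner-window share
#' k5 = (a_{n-1}+a_n+a_{n+1}) / S5 > `k5_min`, and the centre share of the
#' inner window a_n / (a_{n-1}+a_n+a_{n+1}) > `k3_min`. Ratios with zero
#' denominators are defined as 0 (an unexpressed window cannot be a peak).
#'
#' @inheritParams evaluate_part1
#' @return List with `n5`, `S5`, `r5`, `k5`, `k3_part2`, `part2_pass`.
#' @export
evaluate_part2 <- function(a, thresholds = default_thresholds(length(a)),
                           tie_method = c("average", "ordinal")) {
  tie_method <- match.arg(tie_method)
  R <- rank_series(a, tie_method)
  N <- length(a)
  pk <- locate_peak(a, 2L)
  w5 <- circular_index((pk$n - 2L):(pk$n + 2L), N)
  r5 <- sum(R[w5])
  inner <- circular_window_sum(a, pk$n, 1L)
  k5 <- if (pk$S > 0) inner / pk$S else 0
  k3b <- if (inner > 0) a[pk$n] / inner else 0
  list(n5 = pk$n, S5 = pk$S, r5 = r5, k5 = k5, k3_part2 = k3b,
       part2_pass = r5 > thresholds$r5_min && k5 > thresholds$k5_min &&
         k3b > thresholds$k3_min)
}

#' Classify one expression series as periodic or not
#'
#' Runs both screens and combines their verdicts. The default `"union"`
#' policy calls a transcript periodic if either screen passes (the
#' 5-window part exists to tolerate broader waveforms that the 3-window
#' part misses). The reported `peak_index` is the 3-window peak when part 1
#' passes, else the 5-window peak when part 2 passes, else the 3-window
#' peak.
#'
#' @param a Numeric series (>= 5 samples, finite, non-negative).
#' @param thresholds A [threshold_set()].
#' @param combine `"union"`, `"part1_only"`, `"part2_only"` or
#'   `"intersection"`.
#' @param tie_method Rank tie handling.
#' @return Named list with all six statistics, both verdicts,
#'   `is_periodic` and `peak_index`.
#' @export
classify_transcript <- function(a, thresholds = default_thresholds(length(a)),
                                combine = c("union", "part1_only", "part2_only", "intersection"),
                                tie_method = c("average", "ordinal")) {
  combine <- match.arg(combine)
  tie_method <- match.arg(tie_method)
  p1 <- evaluate_part1(a, thresholds, tie_method)
  p2 <- evaluate_part2(a, thresholds, tie_method)
  is_periodic <- switch(combine,
    union        = p1$part1_pass || p2$part2_pass,
    part1_only   = p1$part1_pass,
    part2_only   = p2$part2_pass,
    intersection = p1$part1_pass && p2$part2_pass)
  peak_index <- if (p1$part1_pass) p1$n3 else if (p2$part2_pass) p2$n5 else p1$n3
  c(p1, p2, list(is_periodic = is_periodic, peak_index = peak_index))
}

#' Detect periodic transcripts across a whole matrix
#'
#' Applies [classify_transcript()] to every row of an ordered FPKM matrix
#' and returns one row of statistics and verdicts per transcript, in the
#' input row order. Deterministic given its inputs.
#'
#' @param m Numeric matrix, transcripts x ordered samples (5-30 samples
#'   supported), with rownames and colnames; or a matrix read by
#'   [read_expression_matrix()].
#' @param thresholds A [threshold_set()]; defaults to
#'   [default_thresholds()] at the matrix's sample count.
#' @param combine Verdict combination policy, see [classify_transcript()].
#' @param tie_method Rank tie handling.
#' @param min_fpkm Optional expression floor: transcripts whose maximum
#'   FPKM is below this value are reported but never called periodic.
#'   Default 0 (no pre-filter).
#' @return data.frame with columns `transcript_id`, `n3`, `S3`, `r3`,
#'   `k3`, `part1_pass`, `n5`, `S5`, `r5`, `k5`, `k3_part2`, `part2_pass`,
#'   `is_periodic`, `peak_index`.
#' @export
detect_matrix <- function(m, thresholds = NULL,
                          combine = c("union", "part1_only", "part2_only", "intersection"),
                          tie_method = c("average", "ordinal"),
                          min_fpkm = 0) {
  combine <- match.arg(combine)
  tie_method <- match.arg(tie_method)
  validate_expression_matrix(m)
  N <- ncol(m)
  if (N < 5L || N > 30L) stop("detect_matrix supports 5 to 30 ordered samples; got ", N)
  if (is.null(thresholds)) thresholds <- default_thresholds(N)
  stopifnot(inherits(thresholds, "threshold_set"))
  cols <- c("n3", "S3", "r3", "k3", "part1_pass", "n5", "S5", "r5", "k5",
            "k3_part2", "part2_pass", "is_periodic", "peak_index")
  if (nrow(m) == 0L) {
    out <- c(list(transcript_id = character(0)),
             stats::setNames(rep(list(numeric(0)), length(cols)), cols))
    out$part1_pass <- out$part2_pass <- out$is_periodic <- logical(0)
    return(as.data.frame(out, stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(m)), function(i) {
    res <- classify_transcript(m[i, ], thresholds, combine, tie_method)
    if (min_fpkm > 0 && max(m[i, ]) < min_fpkm) res$is_periodic <- FALSE
    res
  })
  out <- data.frame(transcript_id = rownames(m), stringsAsFactors = FALSE)
  for (col in cols) out[[col]] <- vapply(rows, function(r) as.numeric(r[[col]]), numeric(1L))
  for (col in c("part1_pass", "part2_pass", "is_periodic")) out[[col]] <- as.logical(out[[col]])
  out$n3 <- as.integer(out$n3); out$n5 <- as.integer(out$n5)
  out$peak_index <- as.integer(out$peak_index)
  out
}
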