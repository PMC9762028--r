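#' Cell-cycle phase ring
#'
#' An ordered set of phase labels treated as a ring, so that the last
#' phase (M-G1) is adjacent to the first (G1/S), following the cyclic
#' biology of cell division.
#'
#' @param labels Character vector of distinct phase labels, in cycle
#'   order. Default: the package's phase vocabulary [PHASE_LEVELS].
#' @return An object of class `phase_cycle`.
#' @export
phase_cycle <- function(labels = PHASE_LEVELS) {
  labels <- as.character(labels)
  if (length(labels) < 2L) stop("a phase cycle needs at least 2 labels")
  if (anyDuplicated(labels)) {
    stop("duplicate phase label: ", labels[duplicated(labels)][1L])
  }
  structure(labels, class = "phase_cycle")
}

#' Circular distance between phases
#'
#' Number of steps separating two phases on the ring, taking the shorter
#' direction; symmetric and wraparound-aware (on the default ring, M-G1
#' and G1/S are at distance 1).
#'
#' @param cycle A [phase_cycle()].
#' @param p,q Phase labels (vectorized, recycled).
#' @return Integer vector of ring distances.
#' @export
phase_distance <- function(cycle, p, q) {
  stopifnot(inherits(cycle, "phase_cycle"))
  L <- length(cycle)
  i <- match(p, cycle); j <- match(q, cycle)
  if (anyNA(i)) stop("unknown phase label: ", p[is.na(i)][1L])
  if (anyNA(j)) stop("unknown phase label: ", q[is.na(j)][1L])
  d <- abs(i - j)
  as.integer(pmin(d, L - d))
}

#' Assign each peak to its cell-cycle phase
#'
#' Looks up the phase of the sample at which each transcript's expression
#' peaks, using the sample panel of the dataset the calls came from.
#'
#' @param calls A calls table from [detect_matrix()] (or any data.frame
#'   with `transcript_id` and `peak_index`).
#' @param panel Sample panel from [read_sample_sheet()]; must have one row
#'   per time-course sample, in order.
#' @param dataset_id Optional label recorded alongside the assignments.
#' @return data.frame with columns `transcript_id`, `dataset_id`,
#'   `peak_index`, `phase`.
#' @export
assign_phase <- function(calls, panel, dataset_id = NA_character_) {
  stopifnot(is.data.frame(calls),
            all(c("transcript_id", "peak_index") %in% colnames(calls)))
  panel <- validate_sample_panel(panel)
  if (nrow(calls) > 0L &&
      (min(calls$peak_index) < 1L || max(calls$peak_index) > nrow(panel))) {
    stop("peak_index outside the sample panel (panel has ", nrow(panel),
         " samples)")
  }
  data.frame(transcript_id = calls$transcript_id,
             dataset_id = dataset_id,
             peak_index = as.integer(calls$peak_index),
             phase = panel$phase[calls$peak_index],
             stringsAsFactors = FALSE)
}

#' Order periodic transcripts by peak position
#'
#' Stable sort of the periodic calls by ascending peak sample, the order
#' used to lay out heatmap rows so that transcripts peaking in successive
#' phases appear top to bottom. Ties keep the input order.
#'
#' @param calls Calls table restricted to (or containing) periodic
#'   transcripts; rows with `is_periodic == FALSE` are dropped if the
#'   column is present.
#' @return Character vector of transcript ids in display order.
#' @export
order_by_peak <- function(calls) {
  stopifnot(is.data.frame(calls),
            all(c("transcript_id", "peak_index") %in% colnames(calls)))
  if ("is_periodic" %in% colnames(calls)) {
    calls <- calls[calls$is_periodic, , drop = FALSE]
  }
  calls$transcript_id[order(calls$peak_index)]   # order() is stable
}

#' Intersect periodic calls across datasets
#'
#' Plain set intersection of the periodic transcript identifiers of two
#' or more call tables (one per cell line / dataset).
#'
#' @param ... Two or more calls tables from [detect_matrix()], or a single
#'   list of them.
#' @return Character vector of transcript ids periodic in every dataset.
#' @export
intersect_datasets <- function(...) {
  tables <- list(...)
  if (length(tables) == 1L && is.list(tables[[1L]]) && !is.data.frame(tables[[1L]])) {
    tables <- tables[[1L]]
  }
  if (length(tables) < 2L) stop("need at least two call tables to intersect")
  sets <- lapply(tables, function(tb) {
    stopifnot(is.data.frame(tb), "transcript_id" %in% colnames(tb))
    if (anyDuplicated(tb$transcript_id)) {
      stop("duplicate transcript_id in calls table: ",
           tb$transcript_id[duplicated(tb$transcript_id)][1L])
    }
    if ("is_periodic" %in% colnames(tb)) tb <- tb[tb$is_periodic, , drop = FALSE]
    tb$transcript_id
  })
  Reduce(intersect, sets)
}

#' Restrict shared transcripts to same-or-adjacent-phase peaks
#'
#' Given per-dataset phase assignments for transcripts shared across
#' datasets, keeps those whose peak phases agree up to `max_distance`
#' steps on the phase ring for every pair of datasets — "restricted
#' parallel expression". The default `max_distance = 1` keeps transcripts
#' peaking in the same or adjacent phases everywhere.
#'
#' @param assignments Named list of data.frames (one per dataset) with
#'   columns `transcript_id` and `phase`, e.g. from [assign_phase()].
#' @param cycle A [phase_cycle()].
#' @param max_distance Maximum pairwise ring distance, default 1.
#' @param transcripts Transcripts to evaluate; default: the intersection
#'   of the assignment tables. Every requested transcript must have one
#'   assignment per dataset.
#' @return data.frame with one row per evaluated transcript: its phase in
#'   each dataset and a logical `kept`.
#' @export
common_phase_restricted <- function(assignments, cycle = phase_cycle(),
                                    max_distance = 1L, transcripts = NULL) {
  stopifnot(is.list(assignments), length(assignments) >= 2L,
            inherits(cycle, "phase_cycle"))
  if (is.null(names(assignments)) || any(names(assignments) == "")) {
    names(assignments) <- paste0("dataset", seq_along(assignments))
  }
  ids_per <- lapply(assignments, function(df) {
    stopifnot(is.data.frame(df), all(c("transcript_id", "phase") %in% colnames(df)))
    df$transcript_id
  })
  if (is.null(transcripts)) transcripts <- Reduce(intersect, ids_per)
  phases <- matrix(NA_character_, nrow = length(transcripts),
                   ncol = length(assignments),
                   dimnames = list(transcripts, names(assignments)))
  for (ds in names(assignments)) {
    df <- assignments[[ds]]
    hit <- match(transcripts, df$transcript_id)
    if (anyNA(hit)) {
      stop("transcript '", transcripts[is.na(hit)][1L],
           "' has no phase assignment in dataset '", ds, "'")
    }
    phases[, ds] <- df$phase[hit]
  }
  kept <- rep(TRUE, length(transcripts))
  if (length(transcripts) > 0L) {
    pairs <- utils::combn(seq_along(assignments), 2L)
    for (k in seq_len(ncol(pairs))) {
      d <- phase_distance(cycle, phases[, pairs[1L, k]], phases[, pairs[2L, k]])
      kept <- kept & (d <= max_distance)
    }
  }
  out <- data.frame(transcript_id = transcripts, stringsAsFactors = FALSE)
  for (ds in names(assignments)) out[[paste0("phase_", ds)]] <- phases[, ds]
  out$kept <- kept
  out
}
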