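#' Specification for a simulated cell-cycle time course
#'
#' Describes a synthetic transcripts x samples FPKM matrix emulating a
#' synchronized cell-cycle experiment: periodic transcripts carry one
#' circular Gaussian expression bump per cycle at a planted peak sample;
#' aperiodic transcripts are flat. Both are multiplied by log-normal
#' noise, preserving non-negativity.
#'
#' @param N Samples per cycle; 8 and 10 mirror the two common panel
#'   designs (8-sample HeLa/HCT116-style, 10-sample MDA-MB-231-style).
#' @param n_periodic,n_aperiodic Transcript counts of each class.
#' @param amplitude_range Uniform range of bump amplitudes (FPKM).
#' @param bump_sd Circular Gaussian bump width, in samples.
#' @param noise_sd Standard deviation of the log-normal multiplicative
#'   noise on the log scale; 0 disables noise.
#' @param baseline_range Uniform range of baseline expression (FPKM).
#' @param seed Integer seed; the simulation is deterministic given it.
#' @return An object of class `cycle_sim_spec`.
#' @export
cycle_sim_spec <- function(N = 8L, n_periodic = 100L, n_aperiodic = 400L,
                           amplitude_range = c(5, 50), bump_sd = 1,
                           noise_sd = 0.1, baseline_range = c(0.5, 5),
                           seed = 1L) {
  stopifnot(N >= 5L, n_periodic >= 0L, n_aperiodic >= 0L,
            length(amplitude_range) == 2L, all(amplitude_range > 0),
            diff(amplitude_range) >= 0,
            bump_sd > 0, noise_sd >= 0,
            length(baseline_range) == 2L, all(baseline_range > 0),
            diff(baseline_range) >= 0)
  structure(list(N = as.integer(N), n_periodic = as.integer(n_periodic),
                 n_aperiodic = as.integer(n_aperiodic),
                 amplitude_range = amplitude_range, bump_sd = bump_sd,
                 noise_sd = noise_sd, baseline_range = baseline_range,
                 seed = as.integer(seed)),
            class = "cycle_sim_spec")
}

circular_sample_distance <- function(i, p, N) pmin(abs(i - p), N - abs(i - p))

#' Simulate a cell-cycle expression matrix with ground truth
#'
#' Periodic transcripts follow
#' `baseline + A * exp(-d(i, p)^2 / (2 * bump_sd^2))`, with `d` the
#' circular sample distance to the planted peak `p`, multiplied by
#' log-normal noise `exp(rnorm(0, noise_sd))` per value. Aperiodic
#' transcripts are a constant baseline under the same noise.
#'
#' @param spec A [cycle_sim_spec()].
#' @return List with `matrix` (transcripts x samples, rownames
#'   `PT...`/`AT...`, colnames `s1..sN`) and `truth` (data.frame
#'   `transcript_id`, `is_periodic`, `true_peak`; NA peak for aperiodic
#'   transcripts).
#' @export
simulate_cycle_matrix <- function(spec) {
  stopifnot(inherits(spec, "cycle_sim_spec"))
  set.seed(spec$seed)
  N <- spec$N
  n_tot <- spec$n_periodic + spec$n_aperiodic
  ids <- c(sprintf("PT%04d", seq_len(spec$n_periodic)),
           sprintf("AT%04d", seq_len(spec$n_aperiodic)))
  peaks <- if (spec$n_periodic > 0L) sample.int(N, spec$n_periodic, replace = TRUE) else integer(0)
  baselines <- stats::runif(n_tot, spec$baseline_range[1L], spec$baseline_range[2L])
  amps <- if (spec$n_periodic > 0L)
    stats::runif(spec$n_periodic, spec$amplitude_range[1L], spec$amplitude_range[2L]) else numeric(0)
  m <- matrix(0, nrow = n_tot, ncol = N,
              dimnames = list(ids, paste0("s", seq_len(N))))
  for (t in seq_len(spec$n_periodic)) {
    d <- circular_sample_distance(seq_len(N), peaks[t], N)
    m[t, ] <- baselines[t] + amps[t] * exp(-d^2 / (2 * spec$bump_sd^2))
  }
  if (spec$n_aperiodic > 0L) {
    m[spec$n_periodic + seq_len(spec$n_aperiodic), ] <-
      baselines[spec$n_periodic + seq_len(spec$n_aperiodic)]
  }
  if (spec$noise_sd > 0) {
    m <- m * exp(matrix(stats::rnorm(n_tot * N, 0, spec$noise_sd), n_tot, N))
  }
  truth <- data.frame(
    transcript_id = ids,
    is_periodic = rep(c(TRUE, FALSE), c(spec$n_periodic, spec$n_aperiodic)),
    true_peak = c(peaks, rep(NA_integer_, spec$n_aperiodic)),
    stringsAsFactors = FALSE)
  list(matrix = m, truth = truth)
}

#' Specification for a simulated drug-response panel
#'
#' Describes a panel emulating matched GDSC-style IC50 and CCLE-style
#' expression exports for one drug and its single target gene: one
#' "driver" isoform determines log-IC50 linearly, several inert isoforms
#' add unrelated expression, and the gene-level value is the sum of its
#' isoforms — so the driver's signal is diluted at gene level.
#'
#' @param n_cells Number of cell lines.
#' @param n_inert Inert isoforms per gene (the gene has `n_inert + 1`
#'   isoforms in total).
#' @param effect_slope Slope linking driver-isoform expression (FPKM) to
#'   log-IC50; positive means higher driver expression confers
#'   resistance.
#' @param noise_sd SD of the additive Gaussian noise on log-IC50.
#' @param tissues Optional character vector of tissue labels; cell lines
#'   are assigned to tissues in round-robin order.
#' @param effect_in With `tissues`: labels in which the driver effect is
#'   active (slope 0 elsewhere). Default: all tissues.
#' @param expr_meanlog,expr_sdlog Log-normal parameters of isoform
#'   expression across cell lines.
#' @param seed Integer seed.
#' @return An object of class `drug_sim_spec`.
#' @export
drug_sim_spec <- function(n_cells = 50L, n_inert = 3L, effect_slope = 1,
                          noise_sd = 0.3, tissues = NULL, effect_in = NULL,
                          expr_meanlog = log(5), expr_sdlog = 0.8,
                          seed = 1L) {
  stopifnot(n_cells >= 5L, n_inert >= 0L, noise_sd >= 0, expr_sdlog > 0)
  if (!is.null(tissues)) {
    stopifnot(length(tissues) >= 1L, !anyDuplicated(tissues))
    if (is.null(effect_in)) effect_in <- tissues
    stopifnot(all(effect_in %in% tissues))
  }
  structure(list(n_cells = as.integer(n_cells), n_inert = as.integer(n_inert),
                 effect_slope = effect_slope, noise_sd = noise_sd,
                 tissues = tissues, effect_in = effect_in,
                 expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
                 seed = as.integer(seed)),
            class = "drug_sim_spec")
}

#' Simulate a drug-response panel with ground truth
#'
#' Isoform expression is drawn iid log-normal per cell line; log-IC50 of
#' the single simulated drug is `effect_slope * driver + N(0, noise_sd)`
#' (slope applied only in `effect_in` tissues when tissues are defined);
#' gene expression is the sum of the gene's isoform expression values.
#'
#' @param spec A [drug_sim_spec()].
#' @return List with `ic50` (cells x drugs matrix), `gene_expr` (gene x
#'   cells), `tx_expr` (transcripts x cells), `annotation`
#'   (transcript/gene/biotype data.frame), `target_sets` (drug -> gene
#'   list, single-target), `tissue_map` (named vector, NULL without
#'   tissues) and `truth` (list naming the driver transcript, gene, drug
#'   and effect tissues).
#' @export
simulate_drug_panel <- function(spec) {
  stopifnot(inherits(spec, "drug_sim_spec"))
  set.seed(spec$seed)
  cells <- sprintf("CL%03d", seq_len(spec$n_cells))
  n_iso <- spec$n_inert + 1L
  txs <- c("T_driver", if (spec$n_inert > 0L) sprintf("T_inert%d", seq_len(spec$n_inert)))
  tx_expr <- matrix(stats::rlnorm(n_iso * spec$n_cells, spec$expr_meanlog, spec$expr_sdlog),
                    nrow = n_iso, ncol = spec$n_cells,
                    dimnames = list(txs, cells))
  gene_expr <- matrix(colSums(tx_expr), nrow = 1L,
                      dimnames = list("G1", cells))
  slope <- rep(spec$effect_slope, spec$n_cells)
  tissue_map <- NULL
  if (!is.null(spec$tissues)) {
    tissue_map <- stats::setNames(
      rep(spec$tissues, length.out = spec$n_cells), cells)
    slope[!tissue_map %in% spec$effect_in] <- 0
  }
  log_ic50 <- slope * tx_expr["T_driver", ] +
    stats::rnorm(spec$n_cells, 0, spec$noise_sd)
  ic50 <- matrix(log_ic50, ncol = 1L, dimnames = list(cells, "drug1"))
  annotation <- data.frame(transcript_id = txs,
                           gene_id = "G1",
                           biotype = "protein_coding",
                           stringsAsFactors = FALSE)
  list(ic50 = ic50, gene_expr = gene_expr, tx_expr = tx_expr,
       annotation = annotation,
       target_sets = list(drug1 = "G1"),
       tissue_map = tissue_map,
       truth = list(driver_transcript = "T_driver", gene = "G1",
                    drug = "drug1", effect_in = spec$effect_in))
}
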