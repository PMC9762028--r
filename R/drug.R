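#' Collapse a drug-target table to single-target drugs
#'
#' Drugs annotated with more than one target gene are excluded (reported
#' via `message()`), avoiding ambiguous drug-gene attribution in the
#' correlation scan; the remainder map each drug to its single target.
#'
#' @param target_sets Named list drug -> character vector of target genes,
#'   as returned by [read_drug_target_table()].
#' @return Named character vector: one target gene per retained drug.
#' @export
build_target_map <- function(target_sets) {
  stopifnot(is.list(target_sets), length(target_sets) > 0L)
  n_targets <- lengths(target_sets)
  multi <- names(target_sets)[n_targets > 1L]
  for (d in multi) {
    message("excluding multitarget drug '", d, "' (targets: ",
            paste(target_sets[[d]], collapse = ", "), ")")
  }
  keep <- target_sets[n_targets == 1L]
  if (length(keep) == 0L) stop("no single-target drugs left after multitarget exclusion")
  vapply(keep, identity, character(1L))
}

#' Match cell lines between response and expression panels
#'
#' Cell lines present in both the IC50 table and the expression panel, in
#' lexicographic order; lines without drug evaluations or without
#' expression are dropped.
#'
#' @param ic50 Cell x drug IC50 matrix ([read_ic50_matrix()]).
#' @param expr Feature x cell expression matrix ([read_cell_expression()]).
#' @return Character vector of matched cell-line ids.
#' @export
align_panels <- function(ic50, expr) {
  stopifnot(is.matrix(ic50), is.matrix(expr))
  shared <- sort(intersect(rownames(ic50), colnames(expr)))
  if (length(shared) == 0L) stop("no cell lines shared between IC50 and expression panels")
  shared
}

#' Spearman correlation with a pair floor
#'
#' Rank correlation of the complete pairs of `x` and `y`: Pearson
#' correlation of average-tied ranks, with the two-sided p-value from the
#' large-sample t approximation. With fewer than `min_n` complete pairs
#' the result is marked unavailable rather than raising an error.
#'
#' @param x,y Paired numeric vectors; NAs allowed and dropped pairwise.
#' @param min_n Minimum number of complete pairs, default 10.
#' @return List with `rho`, `p`, `n`, `available`.
#' @export
spearman_cor <- function(x, y, min_n = 10L) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < min_n) {
    return(list(rho = NA_real_, p = NA_real_, n = n, available = FALSE))
  }
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    # degenerate: constant vector has no rank ordering
    return(list(rho = NA_real_, p = NA_real_, n = n, available = FALSE))
  }
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n, available = TRUE)
}

#' Correlate IC50 with target genes and their isoforms
#'
#' For every retained drug, pairs its IC50 profile across matched cell
#' lines with the expression of its target gene and of each transcript
#' isoform of that gene, computing both Spearman correlations on the
#' identical cell-line subset (the lines with an IC50 evaluation for that
#' drug). Emits one record per (drug, gene, isoform).
#'
#' @param ic50 Cell x drug IC50 matrix.
#' @param gene_expr Gene x cell expression matrix.
#' @param tx_expr Transcript x cell expression matrix.
#' @param target_map Named vector drug -> gene from [build_target_map()].
#' @param annotation Transcript-to-gene table ([read_feature_annotation()]).
#' @param min_n Minimum complete pairs per correlation, default 10.
#' @param delta_min,direction Flagging rule, see
#'   [flag_sensitivity_related()]; applied to populate the `flagged`
#'   column.
#' @param tissue Optional tissue label recorded on every record.
#' @return data.frame with columns `drug`, `gene`, `transcript`,
#'   `rho_gene`, `p_gene`, `rho_transcript`, `p_transcript`, `n_cells`,
#'   `tissue`, `delta`, `flagged`, plus Benjamini-Hochberg-adjusted
#'   `p_gene_bh` / `p_transcript_bh` (informational; flagging never uses
#'   p-values).
#' @export
gene_vs_transcript_scan <- function(ic50, gene_expr, tx_expr, target_map,
                                    annotation, min_n = 10L,
                                    delta_min = 0.1,
                                    direction = c("higher", "both"),
                                    tissue = NA_character_) {
  direction <- match.arg(direction)
  stopifnot(is.matrix(ic50), is.matrix(gene_expr), is.matrix(tx_expr),
            is.character(target_map), !is.null(names(target_map)),
            is.data.frame(annotation))
  cells <- align_panels(ic50, gene_expr)
  cells <- sort(intersect(cells, colnames(tx_expr)))
  if (length(cells) == 0L) stop("no cell lines shared across all three panels")
  records <- list()
  for (drug in names(target_map)) {
    gene <- target_map[[drug]]
    if (!drug %in% colnames(ic50)) {
      message("drug '", drug, "' absent from IC50 table; skipped")
      next
    }
    if (!gene %in% rownames(gene_expr)) {
      message("target gene '", gene, "' of drug '", drug,
              "' absent from gene panel; skipped")
      next
    }
    isoforms <- annotation$transcript_id[annotation$gene_id == gene]
    isoforms <- isoforms[isoforms %in% rownames(tx_expr)]
    if (length(isoforms) == 0L) {
      message("no isoforms of gene '", gene, "' in transcript panel; drug '",
              drug, "' skipped")
      next
    }
    y <- ic50[cells, drug]
    complete <- is.finite(y)   # identical subset for gene and every isoform
    g <- spearman_cor(gene_expr[gene, cells][complete], y[complete], min_n)
    for (tx in isoforms) {
      tc <- spearman_cor(tx_expr[tx, cells][complete], y[complete], min_n)
      if (!g$available || !tc$available) {
        message("correlation unavailable for drug '", drug, "', transcript '",
                tx, "' (", tc$n, " complete pairs)")
      }
      records[[length(records) + 1L]] <- data.frame(
        drug = drug, gene = gene, transcript = tx,
        rho_gene = g$rho, p_gene = g$p,
        rho_transcript = tc$rho, p_transcript = tc$p,
        n_cells = tc$n, tissue = tissue,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(records) > 0L) do.call(rbind, records) else
    data.frame(drug = character(0), gene = character(0),
               transcript = character(0), rho_gene = numeric(0),
               p_gene = numeric(0), rho_transcript = numeric(0),
               p_transcript = numeric(0), n_cells = integer(0),
               tissue = character(0), stringsAsFactors = FALSE)
  out$delta <- abs(out$rho_transcript) - abs(out$rho_gene)
  out$flagged <- apply_flag_rule(out, delta_min, direction)
  # Benjamini-Hochberg columns are informational only; flagging uses the
  # correlation gap, never a p-value.
  out$p_gene_bh <- stats::p.adjust(out$p_gene, method = "BH")
  out$p_transcript_bh <- stats::p.adjust(out$p_transcript, method = "BH")
  rownames(out) <- NULL
  out
}

apply_flag_rule <- function(records, delta_min, direction) {
  d <- abs(records$rho_transcript) - abs(records$rho_gene)
  f <- switch(direction,
              higher = d >= delta_min,
              both   = abs(d) >= delta_min)
  f & !is.na(d)
}

#' Flag drug-sensitivity-related transcript isoforms
#'
#' An isoform is drug-sensitivity-related when the absolute value of its
#' Spearman correlation with IC50 exceeds that of its parent gene by at
#' least `delta_min` (default 0.1, inclusive). Direction `"both"` also
#' keeps isoforms at least `delta_min` *lower*, matching a
#' "higher or lower" listing.
#'
#' @param records Scan records from [gene_vs_transcript_scan()] (rows with
#'   unavailable correlations are never flagged).
#' @param delta_min Minimum absolute-correlation gap, default 0.1.
#' @param direction `"higher"` (default) or `"both"`.
#' @return The flagged subset of `records`, with `flagged` recomputed.
#' @export
flag_sensitivity_related <- function(records, delta_min = 0.1,
                                     direction = c("higher", "both")) {
  direction <- match.arg(direction)
  stopifnot(is.data.frame(records),
            all(c("rho_gene", "rho_transcript") %in% colnames(records)))
  records$delta <- abs(records$rho_transcript) - abs(records$rho_gene)
  records$flagged <- apply_flag_rule(records, delta_min, direction)
  records[records$flagged, , drop = FALSE]
}

#' Rerun the correlation scan within each tissue
#'
#' Stratifies the matched cell lines by tissue and reruns
#' [gene_vs_transcript_scan()] inside every tissue with at least `min_n`
#' lines; smaller tissues are skipped with a message. Correlations are
#' therefore computed only among lines of the same cancer type.
#'
#' @inheritParams gene_vs_transcript_scan
#' @param tissue_map Named character vector cell line -> tissue
#'   ([read_tissue_map()]); every matched line must be labelled.
#' @return data.frame of per-tissue records (column `tissue` filled in).
#' @export
stratify_by_tissue <- function(ic50, gene_expr, tx_expr, target_map,
                               annotation, tissue_map, min_n = 10L,
                               delta_min = 0.1,
                               direction = c("higher", "both")) {
  direction <- match.arg(direction)
  cells <- align_panels(ic50, gene_expr)
  cells <- sort(intersect(cells, colnames(tx_expr)))
  unlabelled <- setdiff(cells, names(tissue_map))
  if (length(unlabelled) > 0L) {
    stop("cell line(s) without tissue label: ", paste(unlabelled, collapse = ", "))
  }
  out <- list()
  for (tis in sort(unique(tissue_map[cells]))) {
    sub <- cells[tissue_map[cells] == tis]
    if (length(sub) < min_n) {
      message("tissue '", tis, "' has only ", length(sub),
              " matched cell lines (< ", min_n, "); skipped")
      next
    }
    out[[tis]] <- gene_vs_transcript_scan(
      ic50[sub, , drop = FALSE],
      gene_expr[, sub, drop = FALSE],
      tx_expr[, sub, drop = FALSE],
      target_map, annotation, min_n = min_n,
      delta_min = delta_min, direction = direction, tissue = tis)
  }
  if (length(out) == 0L) {
    return(data.frame(drug = character(0), gene = character(0),
                      transcript = character(0), rho_gene = numeric(0),
                      p_gene = numeric(0), rho_transcript = numeric(0),
                      p_transcript = numeric(0), n_cells = integer(0),
                      tissue = character(0), delta = numeric(0),
                      flagged = logical(0), p_gene_bh = numeric(0),
                      p_transcript_bh = numeric(0), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
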