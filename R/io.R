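#' Allowed cell-cycle phase labels
#'
#' The fixed phase vocabulary used throughout the package, in cycle order:
#' G1/S boundary (synchronization release point), S, G2/M, and the M-to-G1
#' transition. Sample sheets must label every sample with one of these.
#'
#' @export
PHASE_LEVELS <- c("G1/S", "S", "G2/M", "M-G1")

#' Read an ordered expression matrix from TSV
#'
#' Reads a feature x sample FPKM matrix. The first column holds feature
#' identifiers, the header row holds sample identifiers, and the column
#' order is taken as the time-course order and preserved exactly.
#'
#' @param path Path to a delimited text file.
#' @param delimiter Field delimiter, default tab.
#' @return A numeric matrix with feature ids as rownames and sample ids as
#'   colnames. All values are finite and non-negative; missing values are
#'   not allowed in time-course matrices.
#' @export
read_expression_matrix <- function(path, delimiter = "\t") {
  if (!file.exists(path)) {
    stop("expression matrix file not found: ", path)
  }
  df <- utils::read.delim(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) {
    stop("expression matrix must have a feature id column and at least one sample column: ", path)
  }
  ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  vals <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  m <- matrix(vals, nrow = length(ids), ncol = length(sample_ids),
              dimnames = list(ids, sample_ids))
  bad <- which(!is.finite(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf(
      "invalid expression value at feature '%s', sample '%s' (row %d, column %d): must be a finite number >= 0",
      ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]], bad[1L, 1L], bad[1L, 2L]))
  }
  validate_expression_matrix(m)
  m
}

validate_expression_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m)) stop("expression matrix must be a numeric matrix")
  ids <- rownames(m); samples <- colnames(m)
  if ((nrow(m) > 0L && is.null(ids)) || (ncol(m) > 0L && is.null(samples))) {
    stop("expression matrix must carry feature and sample identifiers")
  }
  if (anyDuplicated(ids)) {
    stop("duplicate feature id: ", ids[duplicated(ids)][1L])
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample id: ", samples[duplicated(samples)][1L])
  }
  if (any(!is.finite(m))) stop("expression matrix contains non-finite values")
  if (any(m < 0)) stop("expression matrix contains negative values")
  invisible(m)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: `read(write(M)) == M` for values
#' representable in plain decimal text (17 significant digits are written,
#' enough to round-trip doubles exactly).
#'
#' @param m Numeric matrix with feature rownames and sample colnames.
#' @param path Output file path.
#' @param id_column Header for the feature id column.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(m, path, id_column = "feature_id") {
  validate_expression_matrix(m)
  df <- data.frame(id = rownames(m),
                   format(m, digits = 17, trim = TRUE, scientific = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c(id_column, colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a sample sheet describing the ordered time course
#'
#' The sheet must contain columns `sample`, `time_h` (hours since G1/S
#' release) and `phase` (one of [PHASE_LEVELS]). Row order is the
#' time-course order; `time_h` must be non-decreasing.
#'
#' @param path Path to a TSV file.
#' @return A data.frame with columns `sample`, `time_h`, `phase`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("sample sheet not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  validate_sample_panel(df)
}

validate_sample_panel <- function(df) {
  need <- c("sample", "time_h", "phase")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols) > 0L) {
    stop("sample sheet is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, need]
  df$sample <- as.character(df$sample)
  df$time_h <- as.numeric(df$time_h)
  df$phase <- as.character(df$phase)
  if (anyDuplicated(df$sample)) {
    stop("duplicate sample id in sample sheet: ", df$sample[duplicated(df$sample)][1L])
  }
  if (any(!is.finite(df$time_h)) || any(df$time_h < 0)) {
    stop("time_h must be finite and non-negative")
  }
  if (is.unsorted(df$time_h)) {
    stop("time_h must be non-decreasing: rows must follow the time-course order")
  }
  unknown <- setdiff(unique(df$phase), PHASE_LEVELS)
  if (length(unknown) > 0L) {
    stop("unknown phase label(s) ", paste(sQuote(unknown), collapse = ", "),
         "; allowed labels are: ", paste(PHASE_LEVELS, collapse = ", "))
  }
  df
}

#' Check that a sample panel matches a matrix's columns
#'
#' @param m Expression matrix.
#' @param panel Sample panel from [read_sample_sheet()].
#' @return The panel, invisibly, if samples agree in set and order.
#' @export
match_panel <- function(m, panel) {
  if (!identical(colnames(m), panel$sample)) {
    stop("sample sheet does not match matrix columns; matrix has [",
         paste(colnames(m), collapse = ", "), "], sheet has [",
         paste(panel$sample, collapse = ", "), "]")
  }
  invisible(panel)
}

#' Read a drug-to-target-gene table
#'
#' Expects columns `drug` and `target_gene`; duplicate (drug, gene) rows
#' are collapsed. Returns the full drug -> set-of-genes mapping; use
#' [build_target_map()] to apply the multitarget-drug exclusion.
#'
#' @param path Path to a TSV file.
#' @return Named list: one character vector of target genes per drug.
#' @export
read_drug_target_table <- function(path) {
  if (!file.exists(path)) stop("drug target table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("drug", "target_gene")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols) > 0L) {
    stop("drug target table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[!is.na(df$drug) & !is.na(df$target_gene), , drop = FALSE]
  if (nrow(df) == 0L) stop("drug target table is empty")
  lapply(split(as.character(df$target_gene), as.character(df$drug)),
         function(g) sort(unique(g)))
}

#' Read a transcript-to-gene annotation table
#'
#' Expects columns `transcript_id` and `gene_id`; `biotype` is optional.
#' Each transcript must map to exactly one gene.
#'
#' @param path Path to a TSV file.
#' @return data.frame with columns `transcript_id`, `gene_id`, `biotype`.
#' @export
read_feature_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_id")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols) > 0L) {
    stop("annotation table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$transcript_id)) {
    stop("duplicate transcript_id in annotation: ",
         df$transcript_id[duplicated(df$transcript_id)][1L])
  }
  if (!"biotype" %in% colnames(df)) df$biotype <- NA_character_
  df[, c("transcript_id", "gene_id", "biotype")]
}

#' Read a cell-line x drug IC50 table
#'
#' Rows are cell lines (first column `cell_line`), remaining columns are
#' drugs. Missing evaluations are encoded as `NA` and allowed here (unlike
#' time-course matrices); every retained drug must have at least one
#' non-missing value.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, cell lines x drugs, possibly with NAs.
#' @export
read_ic50_matrix <- function(path) {
  if (!file.exists(path)) stop("IC50 table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("IC50 table must have a cell_line column and at least one drug column")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) stop("duplicate cell line id: ", ids[duplicated(ids)][1L])
  m <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "double")
  dimnames(m) <- list(ids, colnames(df)[-1L])
  if (any(is.infinite(m), na.rm = TRUE)) stop("IC50 values must be finite where present")
  empty <- colnames(m)[colSums(!is.na(m)) == 0L]
  if (length(empty) > 0L) {
    stop("drug(s) with no IC50 evaluations: ", paste(empty, collapse = ", "))
  }
  m
}

#' Read a cell-line expression panel (gene- or transcript-level)
#'
#' Features x cell lines, first column the feature id. Values must be
#' finite and non-negative (FPKM-like).
#'
#' @param path Path to a TSV file.
#' @param delimiter Field delimiter.
#' @return Numeric matrix, features x cell lines.
#' @export
read_cell_expression <- function(path, delimiter = "\t") {
  read_expression_matrix(path, delimiter = delimiter)
}

#' Read a cell-line to tissue map
#'
#' Expects columns `cell_line` and `tissue`.
#'
#' @param path Path to a TSV file.
#' @return Named character vector: tissue per cell line.
#' @export
read_tissue_map <- function(path) {
  if (!file.exists(path)) stop("tissue table not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("cell_line", "tissue")
  missing_cols <- setdiff(need, colnames(df))
  if (length(missing_cols) > 0L) {
    stop("tissue table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$cell_line)) {
    stop("duplicate cell line in tissue table: ", df$cell_line[duplicated(df$cell_line)][1L])
  }
  stats::setNames(as.character(df$tissue), as.character(df$cell_line))
}

# Generic TSV writer used by the CLI for calls/results tables.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
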