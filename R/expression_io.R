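# I/O: expression matrices (TSV, genes in rows), gene sets (GMT), and
# result tables (TSV). Row/column order is preserved exactly.

#' Read a genes-by-samples expression matrix from TSV
#'
#' Expects a tab-separated file with gene identifiers in the first column
#' and sample identifiers in the header row. Identifiers are matched
#' case-sensitively and must be unique. The matrix must have at least 2
#' genes and 9 samples (the minimum for non-degenerate tertiles).
#'
#' Missing or non-numeric cells are handled by `missing_policy`:
#' `"error"` (default — MI estimates are rank-sensitive, so imputation is
#' opt-in), `"drop_gene"` (drop rows containing any missing cell), or
#' `"impute_row_median"` (fill with the median of the gene's remaining
#' values). Zero-variance genes are retained but logged.
#'
#' @param path Path to the TSV file.
#' @param missing_policy One of `"error"`, `"drop_gene"`,
#'   `"impute_row_median"`.
#' @param transpose Set `TRUE` for samples-in-rows files.
#' @return A numeric matrix, genes in rows (rownames = gene ids, colnames =
#'   sample ids).
#' @export
read_expression_matrix <- function(path,
                                   missing_policy = c("error", "drop_gene",
                                                      "impute_row_median"),
                                   transpose = FALSE) {
  missing_policy <- match.arg(missing_policy)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        show_col_types = FALSE, progress = FALSE)
  if (ncol(df) < 2L) stop("expression file needs id column plus data columns", call. = FALSE)
  ids <- df[[1]]
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate gene id(s): ", paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  vals <- suppressWarnings(
    vapply(df[-1], as.numeric, numeric(nrow(df)))
  )
  if (nrow(df) == 1L) vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, names(df)[-1]))
  rownames(vals) <- ids
  if (transpose) vals <- t(vals)
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)
    if (missing_policy == "error") {
      stop(sprintf("missing/non-numeric cell at gene '%s', sample '%s'",
                   rownames(vals)[bad[1, 1]], colnames(vals)[bad[1, 2]]),
           call. = FALSE)
    } else if (missing_policy == "drop_gene") {
      drop <- unique(bad[, 1])
      mindy_log("dropping ", length(drop), " gene(s) with missing values")
      vals <- vals[-drop, , drop = FALSE]
    } else {
      for (i in unique(bad[, 1])) {
        row <- vals[i, ]
        vals[i, is.na(row)] <- median(row, na.rm = TRUE)
      }
      mindy_log("imputed missing cells in ", length(unique(bad[, 1])), " gene(s)")
    }
  }
  validate_expression_matrix(vals)
  vals
}

validate_expression_matrix <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression matrix must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix needs gene rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(expr))) stop("duplicate gene ids", call. = FALSE)
  if (anyDuplicated(colnames(expr))) stop("duplicate sample ids", call. = FALSE)
  if (nrow(expr) < 2L) stop("need at least 2 genes", call. = FALSE)
  if (ncol(expr) < 9L) {
    stop("need at least 9 samples (non-degenerate tertiles)", call. = FALSE)
  }
  if (anyNA(expr)) stop("expression matrix contains missing values", call. = FALSE)
  nzv <- sum(apply(expr, 1L, sd) == 0)
  if (nzv > 0) mindy_log(nzv, " zero-variance gene(s) retained")
  invisible(expr)
}

#' Write an expression matrix to TSV
#'
#' Inverse of [read_expression_matrix()]: gene ids in the first column
#' (`gene`), sample ids as the header.
#'
#' @param expr Numeric matrix, genes in rows.
#' @param path Output path.
#' @export
write_expression_matrix <- function(expr, path) {
  df <- tibble::as_tibble(expr, rownames = "gene")
  readr::write_tsv(df, path, progress = FALSE)
  mindy_log("wrote ", nrow(expr), " genes x ", ncol(expr), " samples to ", path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' One set per line: name, description, then member identifiers,
#' tab-separated. Set names must be unique; empty member lists are
#' rejected. Members may be absent from a given expression matrix — that is
#' resolved when the set is used.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop(sprintf("malformed GMT line %d: fewer than 3 fields", i), call. = FALSE)
    }
    nm <- fields[1]
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    if (length(members) == 0L) {
      stop(sprintf("GMT line %d ('%s'): empty member list", i, nm), call. = FALSE)
    }
    if (nm %in% names(sets)) {
      stop("duplicate gene-set name: ", nm, call. = FALSE)
    }
    sets[[nm]] <- members
  }
  mindy_log("read ", length(sets), " gene set(s) from ", path)
  sets
}

#' Write gene sets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Description field written to every line.
#' @export
write_gene_sets <- function(sets, path, description = "na") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a result table to TSV
#'
#' Writes any result tibble (conditional records, modulator summaries,
#' in-modulator calls) with a fixed column order, floats serialised to 6
#' significant digits, and deterministic row order (sorted by whichever of
#' `tf`, `modulator`, `target` are present). An empty table produces a
#' header-only file.
#'
#' @param records A data frame of results.
#' @param path Output path.
#' @export
write_results_table <- function(records, path) {
  records <- tibble::as_tibble(records)
  keys <- intersect(c("tf", "modulator", "target"), names(records))
  if (length(keys) > 0 && nrow(records) > 0) {
    records <- dplyr::arrange(records, dplyr::across(dplyr::all_of(keys)))
  }
  records <- dplyr::mutate(records, dplyr::across(dplyr::where(is.double), ~ signif(.x, 6)))
  readr::write_tsv(records, path, progress = FALSE)
  mindy_log("wrote ", nrow(records), " row(s) to ", path)
  invisible(path)
}

#' Read a result table written by [write_results_table()]
#'
#' @param path Path to the TSV.
#' @return A tibble.
#' @export
read_results_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
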