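#' Read a gene-by-timepoint expression table
#'
#' Loads an expression table in which each row is a gene and each column a
#' timepoint of a synchronised time course (for a *Caulobacter* cell-cycle
#' series, minutes post-synchrony: 0, 30, 60, 90, 120). The layout matches
#' what transcript-quantification tools such as Rockhopper emit in their
#' "verbose" transcripts table: a gene-identifier column plus one numeric
#' expression column per timepoint. Column mapping makes that layout directly
#' consumable without reshaping.
#'
#' @param path Path to a tab- or comma-delimited file with a header row.
#' @param gene_col Name (or position) of the gene-identifier column.
#'   Default `"gene_id"`.
#' @param expr_cols Character vector naming the expression columns, in
#'   timepoint order. `NULL` (default) takes every column except `gene_col`,
#'   in file order.
#' @param delim Field delimiter; `NULL` guesses from the file extension
#'   (`.csv` is comma, anything else tab).
#'
#' @return A tibble with column `gene_id` followed by one non-negative
#'   numeric column per timepoint, in the order given by the header.
#'   Timepoint labels are metadata only; all downstream computation uses
#'   column order.
#'
#' @details Negative expression values and duplicated gene identifiers are
#'   rejected with an error naming the offending gene.
#'
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines(c("gene_id\tt0\tt30", "geneA\t1\t3", "geneB\t2\t2"), tf)
#' read_expression_table(tf)
#' @export
read_expression_table <- function(path, gene_col = "gene_id",
                                  expr_cols = NULL, delim = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  delim <- delim %||% if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (is.numeric(gene_col)) gene_col <- names(raw)[gene_col]
  if (!gene_col %in% names(raw)) {
    abort(paste0("gene column '", gene_col, "' not found"))
  }
  expr_cols <- expr_cols %||% setdiff(names(raw), gene_col)
  missing_cols <- setdiff(expr_cols, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("expression columns not found: ",
                 paste(missing_cols, collapse = ", ")))
  }
  tab <- tibble(gene_id = as.character(raw[[gene_col]]))
  for (cc in expr_cols) tab[[cc]] <- as.numeric(raw[[cc]])
  validate_expression_table(tab)
}

#' Validate an expression table
#'
#' Checks the invariants every downstream step assumes: a `gene_id` column,
#' at least two timepoint columns, all values finite and non-negative, and
#' exactly one row per gene.
#'
#' @param table A data frame as returned by [read_expression_table()].
#' @return The table, invisibly coerced to a tibble, if valid; otherwise an
#'   error identifying the offending gene or column.
#' @export
validate_expression_table <- function(table) {
  table <- as_tibble(table)
  if (!"gene_id" %in% names(table)) abort("expression table needs a 'gene_id' column")
  tp <- expression_timepoints(table)
  if (length(tp) < 2) abort("expression table needs at least 2 timepoint columns")
  dup <- unique(table$gene_id[duplicated(table$gene_id)])
  if (length(dup) > 0) {
    abort(paste0("duplicated gene_id: ", paste(head(dup, 5), collapse = ", ")))
  }
  for (cc in tp) {
    v <- table[[cc]]
    if (!is.numeric(v)) abort(paste0("column '", cc, "' is not numeric"))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad) > 0) {
      abort(paste0("negative or non-finite expression for gene '",
                   table$gene_id[bad[1]], "' in column '", cc, "'"))
    }
  }
  table
}

# timepoint (value) columns of an expression/profile tibble
expression_timepoints <- function(table) {
  setdiff(names(table), c("gene_id", "degenerate"))
}

#' Normalize expression profiles to per-gene fractions
#'
#' Converts each gene's expression series into the fraction of its total
#' expression observed at each timepoint: every value is divided by the
#' gene's row sum, so a non-degenerate profile sums to 1 and captures only
#' the *shape* of the expression trajectory, not its magnitude. These
#' normalized profiles are the input to all co-expression computation.
#'
#' Genes whose expression is zero at every timepoint carry no shape
#' information and the fraction is undefined; they are flagged
#' `degenerate = TRUE`, their normalized values are `NA`, and downstream
#' network construction excludes them.
#'
#' @param table An expression table (see [read_expression_table()]).
#' @return A tibble with `gene_id`, the normalized timepoint columns, and a
#'   logical `degenerate` column.
#' @examples
#' tab <- tibble::tibble(gene_id = c("a", "b"), t0 = c(1, 0), t1 = c(3, 0))
#' normalize_profiles(tab)
#' @export
normalize_profiles <- function(table) {
  table <- validate_expression_table(table)
  tp <- expression_timepoints(table)
  m <- as.matrix(table[tp])
  rs <- rowSums(m)
  degenerate <- rs == 0
  norm <- m / ifelse(degenerate, NA_real_, rs)
  out <- tibble(gene_id = table$gene_id)
  for (j in seq_along(tp)) out[[tp[j]]] <- norm[, j]
  out$degenerate <- degenerate
  out
}

#' Write and re-read normalized profiles
#'
#' Round-trip serialisation of profile tables as TSV (`gene_id` plus one
#' column per timepoint). Degenerate genes are written with empty cells.
#'
#' @param profiles A tibble from [normalize_profiles()].
#' @param path Output file path.
#' @return `path`, invisibly (writer); a profiles tibble (reader).
#' @export
write_profiles <- function(profiles, path) {
  readr::write_tsv(profiles[setdiff(names(profiles), "degenerate")], path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_profiles
#' @export
read_profiles <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  tp <- setdiff(names(raw), "gene_id")
  out <- tibble(gene_id = as.character(raw$gene_id))
  for (cc in tp) out[[cc]] <- as.numeric(raw[[cc]])
  out$degenerate <- !stats::complete.cases(out[tp])
  out
}

#' Write an expression table as TSV
#'
#' @param table An expression table.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(table, path) {
  readr::write_tsv(as_tibble(table), path, progress = FALSE)
  invisible(path)
}
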