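#' Tidy a ranking result
#'
#' @param x A `rank_result`.
#' @param ... Unused.
#' @return A tibble with one row per gene: `gene_id`, `weight`, `rank`
#'   (1 = heaviest, ties broken lexicographically) and `seed`.
#' @exportS3Method generics::tidy
tidy.rank_result <- function(x, ...) {
  out <- tibble(gene_id = names(x$weights),
                weight = unname(x$weights),
                rank = unname(x$ranks),
                seed = names(x$weights) %in% (x$seeds %||% character()))
  dplyr::arrange(out, .data$rank)
}

#' Summarise a ranking run
#'
#' @param x A `rank_result`.
#' @param ... Unused.
#' @return A one-row tibble: `n_genes`, `alpha`, `cutoff`, `method`,
#'   `iterations`, `converged`.
#' @exportS3Method generics::glance
glance.rank_result <- function(x, ...) {
  tibble(n_genes = length(x$weights), alpha = x$alpha,
         cutoff = x$cutoff %||% NA_real_, method = x$method,
         iterations = x$iterations, converged = x$converged)
}

#' Tidy a tuning grid
#'
#' @param x A `tuning_result`.
#' @param ... Unused.
#' @return The grid as a plain tibble (alpha, cutoff, held-out ranks).
#' @exportS3Method generics::tidy
tidy.tuning_result <- function(x, ...) as_tibble(x)

#' Summarise a tuning grid
#'
#' @param x A `tuning_result`.
#' @param ... Unused.
#' @return A one-row tibble with the held-out gene, grid size, and the
#'   best cell's alpha, cutoff and rank.
#' @exportS3Method generics::glance
glance.tuning_result <- function(x, ...) {
  best <- tune_argmin(x)
  tibble(held_out = attr(x, "held_out"), n_cells = nrow(x),
         best_alpha = best$alpha[1], best_cutoff = best$cutoff[1],
         best_rank = best$rank_all[1])
}

#' Write a ranked gene list as TSV
#'
#' @param result A `rank_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rank_tsv <- function(result, path) {
  readr::write_tsv(tidy(result), path, progress = FALSE)
  invisible(path)
}
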