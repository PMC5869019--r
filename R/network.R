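#' Clipped-correlation co-expression network
#'
#' `pairwise_correlation()` computes Pearson's correlation between the
#' normalized expression profiles of every pair of genes and stores the
#' result as the network's weighted adjacency: negative correlations carry
#' no meaning as co-expression edges and are clipped to 0, the diagonal is
#' 1, and genes whose normalized profile is constant across timepoints (so
#' that the correlation is undefined) are assigned weight 0 against every
#' other gene.
#'
#' @param profiles A profiles tibble from [normalize_profiles()]. Degenerate
#'   genes are dropped before correlation.
#' @return A `rho_matrix`: a symmetric gene-by-gene matrix with entries in
#'   \[0, 1\], unit diagonal, gene ids as dimnames, and a `cutoff` attribute
#'   (`NA` until [threshold_edges()] is applied).
#' @examples
#' tab <- tibble::tibble(gene_id = c("a", "b", "c"),
#'                       t0 = c(1, 2, 9), t1 = c(2, 4, 3), t2 = c(3, 6, 1))
#' pairwise_correlation(normalize_profiles(tab))
#' @export
pairwise_correlation <- function(profiles) {
  profiles <- as_tibble(profiles)
  if ("degenerate" %in% names(profiles)) {
    profiles <- dplyr::filter(profiles, !.data$degenerate)
  }
  tp <- expression_timepoints(profiles)
  if (length(tp) < 2) abort("need at least 2 timepoints to correlate")
  if (nrow(profiles) < 2) abort("need at least 2 non-degenerate genes")
  m <- t(as.matrix(profiles[tp]))          # timepoints x genes
  colnames(m) <- profiles$gene_id
  suppressWarnings(r <- cor(m))            # constant columns give NA
  r[is.na(r)] <- 0
  r[r < 0] <- 0
  diag(r) <- 1
  new_rho_matrix(r, cutoff = NA_real_)
}

new_rho_matrix <- function(w, cutoff = NA_real_) {
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  structure(w, cutoff = cutoff, class = c("rho_matrix", "matrix", "array"))
}

#' Build a network adjacency from an existing matrix
#'
#' Coerces a square weight matrix (for example one computed elsewhere and
#' read from disk) into a `rho_matrix`, validating the invariants the
#' pipeline assumes: symmetry, entries in \[0, 1\], and gene ids as
#' dimnames (generated when absent).
#'
#' @param w Square numeric matrix of non-negative edge weights.
#' @param cutoff Edge-reduction cutoff already applied to `w`, if any.
#' @return A `rho_matrix`.
#' @export
as_rho_matrix <- function(w, cutoff = NA_real_) {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) abort("weight matrix must be square")
  if (max(abs(w - t(w))) > 1e-12) abort("weight matrix must be symmetric")
  if (any(w < 0) || any(w > 1)) abort("weights must lie in [0, 1]")
  if (is.null(rownames(w))) {
    rownames(w) <- colnames(w) <- sprintf("gene_%04d", seq_len(nrow(w)))
  }
  new_rho_matrix(w, cutoff = cutoff)
}

#' @export
print.rho_matrix <- function(x, ...) {
  cat(sprintf("<rho_matrix> %d genes, %d edges, cutoff %s\n",
              nrow(x), count_edges(x),
              ifelse(is.na(attr(x, "cutoff")), "none",
                     format(attr(x, "cutoff")))))
  invisible(x)
}

#' Gene identifiers of a network object
#'
#' @param x A `rho_matrix` or `transition_matrix`.
#' @return Character vector of gene ids in matrix order.
#' @export
network_genes <- function(x) rownames(x)

#' Edge reduction by correlation cutoff
#'
#' Zeroes every off-diagonal edge whose weight is less than or equal to
#' `cutoff`; only strictly greater weights survive, so a cutoff of 0.9
#' retains edges with correlation > 0.9. The diagonal is untouched.
#'
#' @param rho A `rho_matrix`.
#' @param cutoff Correlation cutoff in \[0, 1).
#' @return The thresholded `rho_matrix`, with its `cutoff` attribute set.
#' @export
threshold_edges <- function(rho, cutoff) {
  stopifnot(inherits(rho, "rho_matrix"))
  if (!is.numeric(cutoff) || length(cutoff) != 1 || is.na(cutoff) ||
      cutoff < 0 || cutoff >= 1) {
    abort("cutoff must be a single number in [0, 1)")
  }
  w <- unclass(rho)
  d <- diag(w)
  w[w <= cutoff] <- 0
  diag(w) <- d
  new_rho_matrix(w, cutoff = cutoff)
}

#' Count network edges
#'
#' An edge is an unordered gene pair with positive weight; the diagonal is
#' excluded.
#'
#' @param rho A `rho_matrix`.
#' @return Integer count of edges.
#' @export
count_edges <- function(rho) {
  w <- unclass(rho)
  sum(w[upper.tri(w)] > 0)
}

#' Genes with no network edges
#'
#' @param rho A `rho_matrix`, usually after [threshold_edges()].
#' @return Character vector of gene ids whose every off-diagonal weight
#'   is zero.
#' @export
disconnected_nodes <- function(rho) {
  w <- unclass(rho)
  diag(w) <- 0
  rownames(w)[rowSums(w > 0) == 0]
}

#' Column-then-row normalized transition matrix
#'
#' Produces the propagation operator P used by the iterative ranking: the
#' adjacency is normalized so each column sums to one, and the result is
#' then normalized so each row sums to one. Each normalization is applied
#' exactly once, in that order; applying the pair twice gives a different
#' matrix, and the pipeline never does. Columns or rows that are entirely
#' zero (isolated genes) are left zero.
#'
#' The unit diagonal (self-loop) is retained by default, since the network's
#' adjacency carries it; `keep_diagonal = FALSE` zeroes it before
#' normalizing.
#'
#' @param rho A `rho_matrix` (thresholded or not).
#' @param keep_diagonal Keep the self-loop weights? Default `TRUE`.
#' @return A `transition_matrix`: same gene order, every row summing to 1
#'   or entirely zero.
#' @export
normalize_transition <- function(rho, keep_diagonal = TRUE) {
  stopifnot(inherits(rho, "rho_matrix"))
  w <- unclass(rho)
  if (!keep_diagonal) diag(w) <- 0
  cs <- colSums(w)
  w <- sweep(w, 2, ifelse(cs == 0, 1, cs), "/")
  rs <- rowSums(w)
  w <- sweep(w, 1, ifelse(rs == 0, 1, rs), "/")
  structure(w, class = c("transition_matrix", "matrix", "array"))
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> %d genes\n", nrow(x)))
  invisible(x)
}

#' Network serialisation
#'
#' `write_edge_list()` emits the network as a three-column TSV of unordered
#' positive-weight pairs (`gene_i`, `gene_j`, `weight`), `gene_i` < `gene_j`
#' lexicographically; `read_edge_list()` rebuilds the symmetric matrix from
#' it (genes absent from any edge must be supplied via `genes` to survive
#' the round trip). `write_rho_matrix()`/`read_rho_matrix()` use a dense
#' TSV with a `gene_id` column.
#'
#' @param rho A `rho_matrix`.
#' @param path File path.
#' @param genes Gene order for reconstruction; default is those seen in the
#'   edge list.
#' @return Writers return `path` invisibly; readers return a `rho_matrix`.
#' @export
write_edge_list <- function(rho, path) {
  w <- unclass(rho)
  idx <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  edges <- tibble(gene_i = rownames(w)[idx[, 1]],
                  gene_j = colnames(w)[idx[, 2]],
                  weight = w[idx])
  swap <- edges$gene_i > edges$gene_j
  tmp <- edges$gene_i[swap]
  edges$gene_i[swap] <- edges$gene_j[swap]
  edges$gene_j[swap] <- tmp
  readr::write_tsv(dplyr::arrange(edges, .data$gene_i, .data$gene_j), path,
                   progress = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, genes = NULL) {
  edges <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  genes <- genes %||% sort(unique(c(edges$gene_i, edges$gene_j)))
  w <- matrix(0, length(genes), length(genes), dimnames = list(genes, genes))
  w[cbind(edges$gene_i, edges$gene_j)] <- edges$weight
  w[cbind(edges$gene_j, edges$gene_i)] <- edges$weight
  diag(w) <- 1
  new_rho_matrix(w, cutoff = NA_real_)
}

#' @rdname write_edge_list
#' @export
write_rho_matrix <- function(rho, path) {
  w <- unclass(rho)
  out <- as_tibble(w)
  out <- dplyr::bind_cols(tibble(gene_id = rownames(w)), out)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_rho_matrix <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  w <- as.matrix(raw[setdiff(names(raw), "gene_id")])
  rownames(w) <- raw$gene_id
  new_rho_matrix(w, cutoff = NA_real_)
}
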