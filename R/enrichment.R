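#' High-variance replicate correction
#'
#' One bait replicate of the pull-down showed systematic inflation relative
#' to the other two, so a per-window guard is applied before any testing:
#' for each window, if the mean RPKM of all three bait replicates exceeds
#' 1.5 times the mean of the two non-suspect replicates, the suspect
#' replicate is taken to have artificially raised the signal and the window
#' is dropped from the analysis entirely (no sample's data in that window
#' is used). All other windows are retained.
#'
#' Degenerate windows: when the two non-suspect replicates average zero,
#' the window is removed if the overall mean is positive (all the signal is
#' the suspect replicate's) and retained if all three values are zero.
#'
#' @param bait_rpkm Tibble with `window_id` and one RPKM column per bait
#'   replicate.
#' @param bait_cols Names of the three bait replicate columns; default all
#'   columns except `window_id`.
#' @param outlier_col Name (or index within `bait_cols`) of the suspect
#'   replicate. Default the first.
#' @param ratio Inflation ratio that triggers removal. Default 1.5.
#' @return A removal log: tibble with `window_id`, `mean_all`,
#'   `mean_others`, and logical `removed`. Retained window ids are
#'   `window_id[!removed]`.
#' @examples
#' remove_high_variance_windows(
#'   tibble::tibble(window_id = 1:2, r1 = c(100, 12), r2 = c(10, 10),
#'                  r3 = c(10, 10)))
#' @export
remove_high_variance_windows <- function(bait_rpkm, bait_cols = NULL,
                                         outlier_col = 1, ratio = 1.5) {
  bait_rpkm <- as_tibble(bait_rpkm)
  bait_cols <- bait_cols %||% setdiff(names(bait_rpkm), "window_id")
  if (length(bait_cols) != 3) abort("exactly three bait replicates expected")
  if (is.numeric(outlier_col)) outlier_col <- bait_cols[outlier_col]
  if (!outlier_col %in% bait_cols) abort("outlier_col must be a bait column")
  m <- as.matrix(bait_rpkm[bait_cols])
  if (any(!is.finite(m))) abort("missing replicate value in bait RPKM")
  others <- setdiff(bait_cols, outlier_col)
  mean_all <- rowMeans(m)
  mean_others <- rowMeans(m[, others, drop = FALSE])
  removed <- ifelse(mean_others == 0, mean_all > 0,
                    mean_all > ratio * mean_others)
  tibble(window_id = bait_rpkm$window_id, mean_all = mean_all,
         mean_others = mean_others, removed = removed)
}

# DESeq-style median-of-ratios size factors; columns of K are samples
size_factors <- function(K) {
  logK <- log(K)
  logK[!is.finite(logK)] <- NA
  log_geo <- rowMeans(logK)
  usable <- is.finite(log_geo)
  if (!any(usable)) {
    # no window has counts in every sample; fall back to total-count scaling
    tot <- colSums(K)
    return(tot / exp(mean(log(tot[tot > 0]))))
  }
  apply(logK, 2, function(lc) exp(median(lc[usable] - log_geo[usable],
                                         na.rm = TRUE)))
}

# pooled method-of-moments dispersion per window, over replicate groups.
# For NB counts K with mean mu_j = s_j q, Var(K_j/s_j) = q/s_j + alpha q^2,
# so alpha_hat = sum_g (n_g-1)(v_g - q_g zbar_g) / sum_g (n_g-1) q_g^2.
mom_dispersion <- function(norm, sf, groups) {
  num <- 0
  den <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    sub <- norm[, idx, drop = FALSE]
    q <- rowMeans(sub)
    v <- apply(sub, 1, var)
    zbar <- mean(1 / sf[idx])
    num <- num + (length(idx) - 1) * (v - q * zbar)
    den <- den + (length(idx) - 1) * q^2
  }
  ifelse(den > 0, num / den, NA_real_)
}

#' Negative-binomial window enrichment test
#'
#' Tests each genome window for enrichment of bait (aptamer pull-down)
#' counts over control counts under a negative-binomial model, in the style
#' of count-based differential expression:
#'
#' * library-depth differences are removed by median-of-ratios size
#'   factors computed over windows detected in every sample;
#' * a per-window method-of-moments dispersion (variance = mu + alpha mu^2)
#'   is pooled across replicate groups, a mean-dispersion trend
#'   alpha(mu) = a0 + a1/mu is fitted across all windows, and each window's
#'   working dispersion is the trend value unless its own estimate exceeds
#'   `outlier_mult` times the trend (such windows keep their larger
#'   estimate, guarding against underestimating noisy windows);
#' * the test statistic is a Wald-style contrast of log bait vs log control
#'   concentration with a delta-method standard error, giving a two-sided
#'   normal p-value.
#'
#' Auxiliary samples (`condition == "aux"`, e.g. wild-type total-RNA
#' libraries added to stabilise the dispersion fit) contribute to size
#' factors and the mean-dispersion trend but never to the contrast.
#' Windows with zero counts everywhere get p = 1 and zero base means.
#'
#' @param counts Window-count tibble (`window_id` plus one column per
#'   sample), e.g. from [count_reads_in_windows()] after the
#'   high-variance correction.
#' @param design Tibble with columns `sample` and `condition`
#'   (`"bait"`, `"control"` or `"aux"`).
#' @param outlier_mult Dispersion outlier guard multiplier. Default 4.
#' @return A `window_stats` tibble: `window_id`, `base_mean_bait`,
#'   `base_mean_control` (means of size-factor-normalized counts per
#'   condition), `log2_fold`, `p_value`, `dispersion`.
#' @export
window_enrichment_test <- function(counts, design, outlier_mult = 4) {
  counts <- as_tibble(counts)
  design <- as_tibble(design)
  stopifnot(all(c("sample", "condition") %in% names(design)))
  miss <- setdiff(design$sample, names(counts))
  if (length(miss) > 0) {
    abort(paste0("samples missing from counts: ", paste(miss, collapse = ", ")))
  }
  bait <- design$sample[design$condition == "bait"]
  ctrl <- design$sample[design$condition == "control"]
  if (length(bait) < 2 || length(ctrl) < 2) {
    abort("at least two bait and two control samples are required")
  }
  all_samples <- design$sample
  K <- as.matrix(counts[all_samples])
  if (any(K < 0) || any(K != floor(K))) abort("counts must be non-negative integers")

  sf <- size_factors(K)
  norm <- sweep(K, 2, sf, "/")
  groups <- design$condition[match(all_samples, design$sample)]

  alpha_hat <- mom_dispersion(norm, sf, groups)
  mu_bar <- rowMeans(norm)
  usable <- is.finite(alpha_hat) & mu_bar > 0
  trend <- function(mu) rep(1e-8, length(mu))
  if (sum(usable) >= 10) {
    fit <- lm(alpha_hat[usable] ~ I(1 / mu_bar[usable]))
    cf <- coef(fit)
    cf[is.na(cf)] <- 0          # constant 1/mu makes the slope inestimable
    a0 <- max(cf[1], 0)
    a1 <- max(cf[2], 0)
    if (a0 == 0 && a1 == 0) a0 <- max(mean(alpha_hat[usable]), 1e-8)
    trend <- function(mu) pmax(a0 + a1 / pmax(mu, 1e-8), 1e-8)
  } else if (any(usable)) {
    a0 <- max(mean(alpha_hat[usable]), 1e-8)
    trend <- function(mu) rep(a0, length(mu))
  }
  disp <- trend(mu_bar)
  own <- is.finite(alpha_hat) & alpha_hat > outlier_mult * disp
  disp[own] <- alpha_hat[own]

  bi <- match(bait, all_samples)
  ci <- match(ctrl, all_samples)
  qb <- rowMeans(norm[, bi, drop = FALSE])
  qc <- rowMeans(norm[, ci, drop = FALSE])
  pseudo <- 0.5 / exp(mean(log(sf)))     # half a count at reference depth
  qb_ <- pmax(qb, pseudo)
  qc_ <- pmax(qc, pseudo)
  var_log <- function(q, idx) {
    (sum(q / sf[idx] + disp * q^2) / length(idx)^2) / q^2
  }
  vb <- vapply(seq_along(qb_), function(i) {
    (sum(qb_[i] / sf[bi] + disp[i] * qb_[i]^2) / length(bi)^2) / qb_[i]^2
  }, numeric(1))
  vc <- vapply(seq_along(qc_), function(i) {
    (sum(qc_[i] / sf[ci] + disp[i] * qc_[i]^2) / length(ci)^2) / qc_[i]^2
  }, numeric(1))
  wald <- (log(qb_) - log(qc_)) / sqrt(vb + vc)
  p <- 2 * pnorm(-abs(wald))
  zero <- qb == 0 & qc == 0
  p[zero] <- 1
  lfc <- log2(qb_ / qc_)
  lfc[zero] <- 0

  out <- tibble(window_id = counts$window_id,
                base_mean_bait = qb, base_mean_control = qc,
                log2_fold = lfc, p_value = p, dispersion = disp)
  structure(out, class = c("window_stats", class(out)),
            size_factors = sf)
}

#' Select significantly enriched windows
#'
#' Applies the enrichment cut used for the pull-down candidates: keep a
#' window when its p-value is below `p_max`, its bait base mean exceeds its
#' control base mean, and its bait base mean exceeds `basemean_min`.
#'
#' @param stats A `window_stats` tibble from [window_enrichment_test()].
#' @param p_max P-value ceiling. Default 0.10.
#' @param basemean_min Bait base-mean floor. Default 1000.
#' @return Integer vector of significant window ids.
#' @export
filter_significant_windows <- function(stats, p_max = 0.10,
                                       basemean_min = 1000) {
  stats <- as_tibble(stats)
  keep <- stats$p_value < p_max &
    stats$base_mean_bait > stats$base_mean_control &
    stats$base_mean_bait > basemean_min
  stats$window_id[keep]
}

#' Merge adjacent significant windows
#'
#' Combines maximal runs of coordinate-adjacent significant windows on the
#' same replicon into single enriched regions; windows separated by any
#' non-significant gap stay in separate regions.
#'
#' @param significant Vector of significant window ids.
#' @param windows Window tibble from [make_windows()].
#' @return A tibble of regions: `region_id`, `replicon`, `start`, `end`,
#'   `n_windows`, and a `window_ids` list-column.
#' @export
merge_adjacent_windows <- function(significant, windows) {
  windows <- as_tibble(windows)
  if (!all(significant %in% windows$window_id)) {
    abort("significant ids must come from the window set")
  }
  sig <- dplyr::arrange(windows[windows$window_id %in% significant, ],
                        .data$replicon, .data$start)
  if (nrow(sig) == 0) {
    return(tibble(region_id = integer(), replicon = character(),
                  start = numeric(), end = numeric(), n_windows = integer(),
                  window_ids = list()))
  }
  new_run <- c(TRUE, sig$replicon[-1] != sig$replicon[-nrow(sig)] |
                 sig$start[-1] != sig$end[-nrow(sig)])
  sig$run <- cumsum(new_run)
  out <- dplyr::summarise(dplyr::group_by(sig, .data$run),
                          replicon = .data$replicon[1],
                          start = min(.data$start), end = max(.data$end),
                          n_windows = dplyr::n(),
                          window_ids = list(.data$window_id),
                          .groups = "drop")
  dplyr::mutate(dplyr::select(out, -"run"),
                region_id = dplyr::row_number(), .before = 1)
}

#' Majority-vote strand call for a region
#'
#' Window counting is strand-blind, so the strand of an enriched region is
#' recovered from the raw alignments: the call is the majority strand of
#' reads overlapping the region; an exact tie, or no overlapping read at
#' all, yields `"ambiguous"` rather than an arbitrary call.
#'
#' @param regions Region tibble (needs `replicon`, `start`, `end`).
#' @param alignments Stranded alignment tibble.
#' @return The regions with `strand`, `reads_plus` and `reads_minus`
#'   columns added.
#' @export
assign_region_strand <- function(regions, alignments) {
  regions <- as_tibble(regions)
  alignments <- as_tibble(alignments)
  votes <- purrr::pmap(regions[c("replicon", "start", "end")],
                       function(replicon, start, end) {
    ov <- alignments$replicon == replicon &
      alignments$start < end & alignments$end > start
    c(plus = sum(alignments$strand[ov] == "+"),
      minus = sum(alignments$strand[ov] == "-"))
  })
  plus <- purrr::map_dbl(votes, "plus")
  minus <- purrr::map_dbl(votes, "minus")
  dplyr::mutate(regions,
                strand = dplyr::case_when(plus > minus ~ "+",
                                          minus > plus ~ "-",
                                          TRUE ~ "ambiguous"),
                reads_plus = plus, reads_minus = minus)
}

#' Annotate enriched regions against gene coordinates
#'
#' Assigns each region the two-letter code used in the pull-down target
#' table. The first letter places the region relative to annotated gene
#' coordinates: `I` when it overlaps a single gene body, `O` when it spans
#' two or more genes (reported as "geneA-geneB"), `U`/`D` when it lies
#' within `upstream_margin` nt upstream/downstream of the nearest gene
#' (relative to that gene's strand), and `NA` otherwise. The second letter
#' gives the read orientation relative to the gene: `S` (sense) when the
#' region's strand call equals the gene's strand, `A` (anti-sense)
#' otherwise; an ambiguous strand call leaves it `NA`.
#'
#' @param regions Region tibble with `replicon`, `start`, `end` (0-based
#'   half-open) and optionally `strand` from [assign_region_strand()].
#' @param genes Annotation tibble with `gene_id`, `replicon`, `start`,
#'   `end` (1-based inclusive), `strand`.
#' @param upstream_margin Margin in nt for the U/D codes. Default 100.
#' @return The regions with `gene`, `position_code` and `orientation_code`
#'   columns added.
#' @export
annotate_region <- function(regions, genes, upstream_margin = 100) {
  regions <- as_tibble(regions)
  genes <- as_tibble(genes)
  stopifnot(all(c("gene_id", "replicon", "start", "end", "strand") %in%
                  names(genes)))
  g0 <- dplyr::mutate(genes, start0 = .data$start - 1, end0 = .data$end)
  ann <- purrr::pmap(regions[c("replicon", "start", "end")],
                     function(replicon, start, end) {
    gg <- g0[g0$replicon == replicon, ]
    ov <- gg[gg$start0 < end & gg$end0 > start, ]
    if (nrow(ov) >= 2) {
      ov <- dplyr::arrange(ov, .data$start0)
      overlap_len <- pmin(ov$end0, end) - pmax(ov$start0, start)
      main <- ov[which.max(overlap_len), ]
      return(list(gene = paste(ov$gene_id, collapse = "-"), code = "O",
                  gene_strand = main$strand))
    }
    if (nrow(ov) == 1) {
      return(list(gene = ov$gene_id, code = "I", gene_strand = ov$strand))
    }
    # upstream gap: between region and gene start, on the gene's 5' side
    up_gap <- ifelse(gg$strand == "+", gg$start0 - end, start - gg$end0)
    dn_gap <- ifelse(gg$strand == "+", start - gg$end0, gg$start0 - end)
    cand <- tibble(gene_id = gg$gene_id, strand = gg$strand,
                   gap = pmin(ifelse(up_gap >= 0, up_gap, Inf),
                              ifelse(dn_gap >= 0, dn_gap, Inf)),
                   code = ifelse(up_gap >= 0 & (dn_gap < 0 | up_gap <= dn_gap),
                                 "U", "D"))
    cand <- cand[is.finite(cand$gap) & cand$gap <= upstream_margin, ]
    if (nrow(cand) == 0) {
      return(list(gene = NA_character_, code = NA_character_,
                  gene_strand = NA_character_))
    }
    best <- cand[which.min(cand$gap), ]
    list(gene = best$gene_id, code = best$code, gene_strand = best$strand)
  })
  out <- dplyr::mutate(regions,
                       gene = purrr::map_chr(ann, "gene"),
                       position_code = purrr::map_chr(ann, "code"),
                       gene_strand = purrr::map_chr(ann, "gene_strand"))
  if ("strand" %in% names(regions)) {
    out$orientation_code <- dplyr::case_when(
      !out$strand %in% c("+", "-") | is.na(out$gene_strand) ~ NA_character_,
      out$strand == out$gene_strand ~ "S",
      TRUE ~ "A")
  }
  dplyr::select(out, -"gene_strand")
}

#' Gene-level pull-down candidate filter
#'
#' The first-pass, annotation-based screen on a gene-level quantification
#' table (the "verbose" transcripts layout): keep genes with an
#' FDR-corrected p-value (qValue) below `q_max`, bait expression above
#' control expression, and bait expression above `expr_min`.
#'
#' @param records Tibble with `gene_id`, `bait_expr`, `control_expr`,
#'   `q_value` (see [read_rockhopper_transcripts()]).
#' @param q_max qValue ceiling. Default 0.05.
#' @param expr_min Bait expression floor. Default 1000.
#' @return The retained records, as a tibble.
#' @export
rockhopper_gene_filter <- function(records, q_max = 0.05, expr_min = 1000) {
  records <- as_tibble(records)
  need <- c("gene_id", "bait_expr", "control_expr", "q_value")
  miss <- setdiff(need, names(records))
  if (length(miss) > 0) {
    abort(paste0("records lack columns: ", paste(miss, collapse = ", ")))
  }
  bad <- which(!is.finite(records$q_value) | records$q_value < 0 |
                 records$q_value > 1 | !is.finite(records$bait_expr) |
                 records$bait_expr < 0 | !is.finite(records$control_expr) |
                 records$control_expr < 0)
  if (length(bad) > 0) {
    abort(paste0("malformed record for gene '", records$gene_id[bad[1]], "'"))
  }
  dplyr::filter(records, .data$q_value < q_max,
                .data$bait_expr > .data$control_expr,
                .data$bait_expr > expr_min)
}

#' Read a gene-level transcripts table
#'
#' Loads a transcript-quantification table in the "verbose" transcripts
#' layout and maps its columns onto the fields the candidate filter needs.
#'
#' @param path TSV file path.
#' @param gene_col,bait_col,control_col,q_col Column names in the file for
#'   the gene identifier, bait expression, control expression and qValue.
#' @return A tibble with `gene_id`, `bait_expr`, `control_expr`, `q_value`.
#' @export
read_rockhopper_transcripts <- function(path, gene_col, bait_col,
                                        control_col, q_col) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  miss <- setdiff(c(gene_col, bait_col, control_col, q_col), names(raw))
  if (length(miss) > 0) {
    abort(paste0("columns not found: ", paste(miss, collapse = ", ")))
  }
  tibble(gene_id = as.character(raw[[gene_col]]),
         bait_expr = as.numeric(raw[[bait_col]]),
         control_expr = as.numeric(raw[[control_col]]),
         q_value = as.numeric(raw[[q_col]]))
}

#' Run the full sliding-window pull-down pipeline
#'
#' Convenience wrapper chaining the per-step functions: RPKM conversion of
#' the bait replicates, the high-variance window correction, the
#' negative-binomial enrichment test on the retained windows, significance
#' filtering, adjacent-window merging, and (when alignments are supplied)
#' strand assignment and gene annotation.
#'
#' @param counts Window-count tibble with a `library_sizes` attribute or
#'   accompanied by `library_sizes`.
#' @param design Design tibble (`sample`, `condition`).
#' @param windows Window tibble from [make_windows()].
#' @param library_sizes Optional named vector of per-sample mapped-read
#'   totals.
#' @param outlier_rep Suspect bait replicate for the variance filter.
#' @param p_max,basemean_min Significance cuts
#'   (see [filter_significant_windows()]).
#' @param alignments Optional stranded alignments for strand calls.
#' @param genes Optional gene annotation for position/orientation codes.
#' @param upstream_margin Margin for the U/D codes. Default 100.
#' @return A list with `stats` (window_stats on retained windows),
#'   `variance_log`, `significant` (window ids) and `regions` (merged,
#'   possibly stranded and annotated).
#' @export
pulldown_pipeline <- function(counts, design, windows, library_sizes = NULL,
                              outlier_rep = 1, p_max = 0.10,
                              basemean_min = 1000, alignments = NULL,
                              genes = NULL, upstream_margin = 100) {
  library_sizes <- library_sizes %||% attr(counts, "library_sizes")
  bait <- design$sample[design$condition == "bait"]
  if (is.null(library_sizes)) {
    library_sizes <- setNames(colSums(as.matrix(counts[design$sample])),
                              design$sample)
  }
  bait_rpkm <- window_rpkm(counts[c("window_id", "width", bait)],
                           library_sizes[bait])
  vlog <- remove_high_variance_windows(bait_rpkm[c("window_id", bait)],
                                       bait_cols = bait,
                                       outlier_col = outlier_rep)
  retained <- vlog$window_id[!vlog$removed]
  stats <- window_enrichment_test(counts[counts$window_id %in% retained, ],
                                  design)
  sig <- filter_significant_windows(stats, p_max = p_max,
                                    basemean_min = basemean_min)
  regions <- merge_adjacent_windows(sig, windows)
  if (!is.null(alignments) && nrow(regions) > 0) {
    regions <- assign_region_strand(regions, alignments)
  }
  if (!is.null(genes) && nrow(regions) > 0) {
    regions <- annotate_region(regions, genes,
                               upstream_margin = upstream_margin)
  }
  list(stats = stats, variance_log = vlog, significant = sig,
       regions = regions)
}
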