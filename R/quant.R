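#' Relative colony-forming units after stress
#'
#' Survival relative to an untreated culture from spot-titer dilution
#' series: (treated CFU x 10^x) / (untreated CFU x 10^y), where x and y are
#' the countable (resolvable) dilution exponents of the treated and
#' untreated series.
#'
#' @param data Data frame with columns `treated_cfu`, `treated_dilution`
#'   (exponent x), `untreated_cfu`, `untreated_dilution` (exponent y).
#' @return The data as a tibble with a `relative_cfu` column appended.
#' @examples
#' relative_cfu(tibble::tibble(treated_cfu = 10, treated_dilution = 2,
#'                             untreated_cfu = 10, untreated_dilution = 5))
#' @export
relative_cfu <- function(data) {
  data <- as_tibble(data)
  need <- c("treated_cfu", "treated_dilution", "untreated_cfu",
            "untreated_dilution")
  check_columns(data, need)
  if (any(data$untreated_cfu <= 0)) abort("untreated_cfu must be positive")
  if (any(data$treated_cfu < 0)) abort("counts must be non-negative")
  ex <- c(data$treated_dilution, data$untreated_dilution)
  if (any(ex < 0) || any(ex != floor(ex))) {
    abort("dilution exponents must be non-negative integers")
  }
  dplyr::mutate(data, relative_cfu =
    (.data$treated_cfu * 10^.data$treated_dilution) /
    (.data$untreated_cfu * 10^.data$untreated_dilution))
}

#' Miller units from a beta-galactosidase assay
#'
#' MU = A420 x 1000 / (A660 x t x v): A420 is the absorbance of the
#' quenched reaction, A660 the optical density of the assayed culture, t
#' the reaction time in minutes and v the culture volume in millilitres.
#'
#' @param data Data frame with columns `a420`, `a660`, `t`, `v`.
#' @return The data as a tibble with a `miller_units` column appended.
#' @export
miller_units <- function(data) {
  data <- as_tibble(data)
  check_columns(data, c("a420", "a660", "t", "v"))
  if (any(data$a660 <= 0) || any(data$t <= 0) || any(data$v <= 0)) {
    abort("a660, t and v must all be positive")
  }
  dplyr::mutate(data, miller_units =
    .data$a420 * 1000 / (.data$a660 * .data$t * .data$v))
}

#' Blot signal normalization
#'
#' `blot_normalize()` scales a probe's signal volume (CNT mm^2 units) by
#' the loading-control (5S rRNA) probe volume in the same lane;
#' `percent = TRUE` additionally multiplies by 100 for the percent-scale
#' variant. `timepoint_normalize()` then expresses a decay series relative
#' to its time-zero value, so the untreated timepoint is exactly 1.
#'
#' @param data Data frame with columns `volume` and `reference`
#'   (`blot_normalize`), or `normalized_volume` and `timepoint`
#'   (`timepoint_normalize`).
#' @param percent Multiply the ratio by 100? Default `FALSE`.
#' @return The data as a tibble with `normalized_volume`
#'   (`blot_normalize`) or `relative_volume` (`timepoint_normalize`)
#'   appended.
#' @export
blot_normalize <- function(data, percent = FALSE) {
  data <- as_tibble(data)
  check_columns(data, c("volume", "reference"))
  if (any(data$reference <= 0)) abort("reference volume must be positive")
  if (any(data$volume < 0)) abort("volumes must be non-negative")
  scale <- if (percent) 100 else 1
  dplyr::mutate(data, normalized_volume =
    scale * .data$volume / .data$reference)
}

#' @rdname blot_normalize
#' @param reference Time-zero normalized volume; `NULL` (default) takes the
#'   `normalized_volume` at `timepoint == 0`.
#' @export
timepoint_normalize <- function(data, reference = NULL) {
  data <- as_tibble(data)
  check_columns(data, "normalized_volume")
  if (is.null(reference)) {
    check_columns(data, "timepoint")
    at0 <- data$normalized_volume[data$timepoint == 0]
    if (length(at0) != 1) abort("need exactly one timepoint == 0 row")
    reference <- at0
  }
  if (reference <= 0) abort("time-zero reference must be positive")
  dplyr::mutate(data, relative_volume = .data$normalized_volume / reference)
}

#' Western blot lane and wild-type normalization
#'
#' The target band doublet is first normalized within its lane against a
#' non-specific band: lane value = (top + bottom) / nonspecific. When a
#' wild-type untreated lane value is supplied, each lane value is further
#' divided by it, so the wild-type untreated lane normalizes to exactly 1.
#'
#' @param data Data frame with columns `top`, `bottom`, `nonspecific`.
#' @param wt_reference Lane value of the wild-type untreated sample on the
#'   same gel; `NULL` (default) skips the second normalization.
#' @return The data as a tibble with `lane_volume` (and `wt_normalized`
#'   when `wt_reference` is given) appended.
#' @export
western_normalize <- function(data, wt_reference = NULL) {
  data <- as_tibble(data)
  check_columns(data, c("top", "bottom", "nonspecific"))
  if (any(data$nonspecific <= 0)) abort("nonspecific volume must be positive")
  if (any(data$top < 0) || any(data$bottom < 0)) {
    abort("band volumes must be non-negative")
  }
  out <- dplyr::mutate(data, lane_volume =
    (.data$top + .data$bottom) / .data$nonspecific)
  if (!is.null(wt_reference)) {
    if (wt_reference <= 0) abort("wt_reference must be positive")
    out <- dplyr::mutate(out, wt_normalized = .data$lane_volume / wt_reference)
  }
  out
}

#' Label-free quantification fold changes
#'
#' Aggregates per-run LFQ intensities of each protein group into a
#' per-strain average and a between-strain log2 fold change. An average is
#' only formed when at least `min_values` runs detected the protein in that
#' strain (missing values are absent, never zero); the fold change is
#' defined only when both strains have an average. log2 fold =
#' log2(average A / average B).
#'
#' @param data Long-format tibble with columns `protein_id`, `strain`,
#'   `intensity` (one row per run; missing runs may be absent rows or `NA`).
#' @param strain_a,strain_b The two strains to compare (A over B).
#' @param min_values Minimum detected runs required per strain. Default 3.
#' @return A tibble with one row per protein: `protein_id`, `n_a`, `n_b`,
#'   `avg_a`, `avg_b`, `log2_fold` (`NA` where undefined).
#' @export
lfq_fold_change <- function(data, strain_a, strain_b, min_values = 3) {
  data <- as_tibble(data)
  check_columns(data, c("protein_id", "strain", "intensity"))
  if (any(data$intensity <= 0, na.rm = TRUE)) {
    abort("LFQ intensities must be positive where present")
  }
  per <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(data, .data$strain %in% c(strain_a, strain_b)),
                    .data$protein_id, .data$strain),
    n = sum(!is.na(.data$intensity)),
    avg = ifelse(sum(!is.na(.data$intensity)) >= min_values,
                 mean(.data$intensity, na.rm = TRUE), NA_real_),
    .groups = "drop")
  wide <- tidyr::pivot_wider(per, names_from = "strain",
                             values_from = c("n", "avg"))
  na_col <- paste0("n_", strain_a); nb_col <- paste0("n_", strain_b)
  aa_col <- paste0("avg_", strain_a); ab_col <- paste0("avg_", strain_b)
  for (cc in c(na_col, nb_col)) if (!cc %in% names(wide)) wide[[cc]] <- 0L
  for (cc in c(aa_col, ab_col)) if (!cc %in% names(wide)) wide[[cc]] <- NA_real_
  tibble(protein_id = wide$protein_id,
         n_a = tidyr::replace_na(wide[[na_col]], 0L),
         n_b = tidyr::replace_na(wide[[nb_col]], 0L),
         avg_a = wide[[aa_col]], avg_b = wide[[ab_col]],
         log2_fold = log2(wide[[aa_col]] / wide[[ab_col]]))
}

check_columns <- function(data, cols) {
  miss <- setdiff(cols, names(data))
  if (length(miss) > 0) {
    abort(paste0("missing column(s): ", paste(miss, collapse = ", ")))
  }
  invisible(data)
}
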