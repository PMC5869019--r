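#' Tile a genome into fixed-width windows
#'
#' Fragments each replicon in silico into contiguous, non-overlapping
#' windows of `width` base pairs (25 bp for the pull-down analysis); the
#' final window is truncated when the replicon length is not a multiple of
#' the width, so the windows tile \[0, length) exactly.
#'
#' @param replicon_lengths Named numeric vector of replicon lengths.
#' @param width Window width in bp. Default 25.
#' @return A tibble with `replicon`, `window_id` (sequential across
#'   replicons), `start`, `end` in 0-based half-open coordinates, and
#'   `width`.
#' @examples
#' make_windows(c(chr = 103), width = 25)
#' @export
make_windows <- function(replicon_lengths, width = 25) {
  if (!is.numeric(width) || length(width) != 1 || width <= 0) {
    abort("width must be a single positive number")
  }
  if (is.null(names(replicon_lengths)) || any(replicon_lengths <= 0)) {
    abort("replicon_lengths must be a named vector of positive lengths")
  }
  per <- purrr::imap(replicon_lengths, function(L, nm) {
    starts <- seq(0, L - 1, by = width)
    tibble(replicon = nm, start = starts, end = pmin(starts + width, L))
  })
  out <- dplyr::bind_rows(per)
  dplyr::mutate(out, window_id = dplyr::row_number(),
                width = .data$end - .data$start,
                .after = "replicon")
}

#' Read and write the simplified tabular alignment format
#'
#' A plain-TSV interchange for stranded alignment records: one row per
#' aligned read with columns `replicon`, `start`, `end` (0-based half-open
#' span on the reference), `strand` (`+`/`-`) and `sample`.
#' `read_alignments_sam()` reads the same records from a SAM file (via
#' Rsamtools), taking the sample name from an argument since SAM carries
#' none.
#'
#' @param path File path.
#' @return A tibble of alignment records (readers); `path` invisibly
#'   (writer).
#' @export
read_alignments_tsv <- function(path) {
  aln <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("replicon", "start", "end", "strand", "sample")
  miss <- setdiff(need, names(aln))
  if (length(miss) > 0) {
    abort(paste0("alignment table lacks columns: ", paste(miss, collapse = ", ")))
  }
  aln[need]
}

#' @rdname read_alignments_tsv
#' @param alignments Alignment tibble.
#' @export
write_alignments_tsv <- function(alignments, path) {
  readr::write_tsv(as_tibble(alignments), path, progress = FALSE)
  invisible(path)
}

#' @rdname read_alignments_tsv
#' @param sample Sample name attached to every record read from SAM.
#' @export
read_alignments_sam <- function(path, sample) {
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    abort("Rsamtools is required to read SAM files")
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  rec <- Rsamtools::scanBam(bam,
    param = Rsamtools::ScanBamParam(what = c("rname", "pos", "qwidth",
                                             "strand")))[[1]]
  keep <- !is.na(rec$pos)
  tibble(replicon = as.character(rec$rname)[keep],
         start = rec$pos[keep] - 1L,
         end = rec$pos[keep] - 1L + rec$qwidth[keep],
         strand = as.character(rec$strand)[keep],
         sample = sample)
}

#' Count reads in genome windows
#'
#' Assigns each aligned read to every window its span overlaps by at least
#' one base, ignoring strand — mirroring how window-based quantification of
#' the pull-down libraries attributed reads (the quantifier discarded
#' strand information; strand is recovered later from the raw alignments by
#' [assign_region_strand()]). A 50-nt read therefore increments two or
#' three 25-bp windows. `strand_aware = TRUE` instead restricts counting to
#' reads on `strand`.
#'
#' The per-sample library size (total mapped reads, used for RPKM) is
#' attached as attribute `"library_sizes"`.
#'
#' @param alignments Alignment tibble (see [read_alignments_tsv()]).
#' @param windows Window tibble from [make_windows()].
#' @param samples Sample columns to emit; default those present in
#'   `alignments`.
#' @param strand_aware,strand Optional strand-restricted counting mode
#'   (off by default).
#' @return A tibble of windows with one integer count column per sample.
#' @export
count_reads_in_windows <- function(alignments, windows, samples = NULL,
                                   strand_aware = FALSE, strand = "+") {
  alignments <- as_tibble(alignments)
  windows <- as_tibble(windows)
  samples <- samples %||% sort(unique(alignments$sample))
  bad <- setdiff(unique(alignments$replicon), unique(windows$replicon))
  if (length(bad) > 0) {
    abort(paste0("alignment references unknown replicon(s): ",
                 paste(bad, collapse = ", ")))
  }
  if (strand_aware) alignments <- alignments[alignments$strand == strand, ]
  lib <- setNames(numeric(length(samples)), samples)
  tab <- table(alignments$sample)
  lib[names(tab)] <- as.numeric(tab)

  counts <- matrix(0L, nrow = nrow(windows), ncol = length(samples),
                   dimnames = list(NULL, samples))
  for (rep_id in unique(windows$replicon)) {
    w <- windows[windows$replicon == rep_id, ]
    a <- alignments[alignments$replicon == rep_id, ]
    if (nrow(a) == 0) next
    L <- max(w$end)
    if (any(a$start < 0 | a$end > L | a$end <= a$start)) {
      abort(paste0("alignment span outside replicon '", rep_id, "'"))
    }
    width <- w$width[1]
    # contiguous fixed-width tiling: overlapped windows are an index range
    first <- pmin(floor(a$start / width), nrow(w) - 1) + 1
    last <- pmin(floor((a$end - 1) / width), nrow(w) - 1) + 1
    span <- last - first + 1
    widx <- sequence(span, from = first)
    sidx <- rep(match(a$sample, samples), span)
    inc <- table(factor(widx, levels = seq_len(nrow(w))),
                 factor(sidx, levels = seq_along(samples)))
    counts[w$window_id, ] <- counts[w$window_id, ] + as.integer(inc)
  }
  out <- windows
  for (s in samples) out[[s]] <- counts[, s]
  attr(out, "library_sizes") <- lib
  out
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm()` is the plain scalar formula,
#' count / ((length / 1000) * (library_size / 1e6)); `window_rpkm()`
#' applies it to every sample column of a window-count table.
#'
#' @param count Read count(s).
#' @param window_length Feature length in nt.
#' @param library_size Total mapped reads in the sample.
#' @return Numeric RPKM value(s).
#' @export
rpkm <- function(count, window_length, library_size) {
  if (any(library_size <= 0)) abort("library_size must be positive")
  if (any(window_length <= 0)) abort("window_length must be positive")
  count / ((window_length / 1000) * (library_size / 1e6))
}

#' @rdname rpkm
#' @param counts Window-count tibble from [count_reads_in_windows()].
#' @param library_sizes Named vector of per-sample mapped-read totals;
#'   defaults to the attribute attached by [count_reads_in_windows()].
#' @export
window_rpkm <- function(counts, library_sizes = NULL) {
  library_sizes <- library_sizes %||% attr(counts, "library_sizes")
  if (is.null(library_sizes)) abort("library_sizes are required")
  samples <- intersect(names(library_sizes), names(counts))
  out <- counts
  for (s in samples) {
    out[[s]] <- rpkm(counts[[s]], counts$width, library_sizes[[s]])
  }
  out
}

#' Per-million coverage normalization
#'
#' Scales a per-nucleotide read-depth vector to depth per million mapped
#' reads: depth * 1e6 / mapped_reads, elementwise.
#'
#' @param per_base_depth Numeric depth vector.
#' @param mapped_reads Total mapped reads in the library.
#' @return Normalized depth vector.
#' @export
normalize_coverage <- function(per_base_depth, mapped_reads) {
  if (length(mapped_reads) != 1 || mapped_reads <= 0) {
    abort("mapped_reads must be a single positive number")
  }
  per_base_depth * 1e6 / mapped_reads
}

#' Write intervals as BED
#'
#' Emits windows or merged regions in BED format (0-based half-open), the
#' coordinate convention the tables already use internally. Columns beyond
#' the first three are `name`, `score` (0) and `strand` when available.
#'
#' @param intervals Tibble with `replicon`, `start`, `end` and optionally
#'   `name`/`region_id` and `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  intervals <- as_tibble(intervals)
  name <- if ("name" %in% names(intervals)) intervals[["name"]]
    else if ("region_id" %in% names(intervals)) intervals[["region_id"]]
    else as.character(seq_len(nrow(intervals)))
  strand <- if ("strand" %in% names(intervals)) intervals[["strand"]]
    else rep(".", nrow(intervals))
  strand[!strand %in% c("+", "-")] <- "."
  bed <- tibble(chrom = intervals$replicon,
                chromStart = as.integer(intervals$start),
                chromEnd = as.integer(intervals$end),
                name = as.character(name), score = 0L, strand = strand)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}
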