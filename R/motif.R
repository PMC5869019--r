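#' Read and write genome FASTA
#'
#' Thin wrappers around Biostrings that hand sequences around as a named
#' character vector (one element per replicon), the representation the rest
#' of the motif module uses.
#'
#' @param path FASTA file path.
#' @return `read_genome_fasta()`: named character vector of upper-case
#'   sequences. `write_genome_fasta()`: `path`, invisibly.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(ss))
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @rdname read_genome_fasta
#' @param genome Named character vector of replicon sequences.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome)
  names(ss) <- names(genome)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract upstream promoter regions
#'
#' For each annotated anchor (a mapped transcriptional start site when
#' available, otherwise the translation start) extracts the `length`
#' nucleotides directly upstream, reported 5'->3' on the gene's strand: for
#' a + strand gene the bases ending immediately before the anchor, for a -
#' strand gene the reverse complement of the bases immediately following
#' it. Regions running off a replicon end are truncated, not wrapped;
#' `circular = TRUE` wraps around instead, for circular chromosomes.
#'
#' @param genome Named character vector of replicon sequences (see
#'   [read_genome_fasta()]).
#' @param annotations Data frame with columns `gene_id`, `replicon`,
#'   `anchor` (1-based coordinate of the anchor base), `strand` ("+"/"-"),
#'   and optionally `anchor_kind` ("TSS" or "start").
#' @param length Upstream window size in nucleotides. Default 200.
#' @param circular Wrap around replicon ends? Default `FALSE`.
#' @return A tibble of promoter regions: `gene_id`, `replicon`, `anchor`,
#'   `strand`, `anchor_kind`, `sequence`, `length`, `truncated`.
#' @export
extract_upstream <- function(genome, annotations, length = 200,
                             circular = FALSE) {
  annotations <- as_tibble(annotations)
  need <- c("gene_id", "replicon", "anchor", "strand")
  miss <- setdiff(need, names(annotations))
  if (length(miss) > 0) {
    abort(paste0("annotation table lacks columns: ", paste(miss, collapse = ", ")))
  }
  if (!all(annotations$strand %in% c("+", "-"))) {
    abort("strand must be '+' or '-'")
  }
  if (!all(annotations$replicon %in% names(genome))) {
    abort("annotation references a replicon absent from the genome")
  }
  rows <- purrr::pmap(annotations[need], function(gene_id, replicon, anchor,
                                                  strand) {
    chrom <- genome[[replicon]]
    L <- nchar(chrom)
    if (anchor < 1 || anchor > L) {
      abort(paste0("anchor for gene '", gene_id, "' outside replicon"))
    }
    if (strand == "+") {
      from <- anchor - length
      to <- anchor - 1
    } else {
      from <- anchor + 1
      to <- anchor + length
    }
    if (circular) {
      pos <- ((seq(from, to) - 1) %% L) + 1
      seq_chr <- paste(strsplit(chrom, "")[[1]][pos], collapse = "")
      truncated <- FALSE
    } else {
      from_c <- max(from, 1)
      to_c <- min(to, L)
      truncated <- from_c > from || to_c < to
      seq_chr <- if (from_c > to_c) "" else substr(chrom, from_c, to_c)
    }
    if (strand == "-") seq_chr <- reverse_complement(seq_chr)
    tibble(gene_id = gene_id, replicon = replicon, anchor = anchor,
           strand = strand, sequence = seq_chr, length = nchar(seq_chr),
           truncated = truncated)
  })
  out <- dplyr::bind_rows(rows)
  if ("anchor_kind" %in% names(annotations)) {
    out <- dplyr::mutate(out, anchor_kind = annotations$anchor_kind,
                         .after = "strand")
  }
  out
}

# all (possibly overlapping) start offsets of a fixed pattern, 1-based
pattern_starts <- function(seq, pattern) {
  if (nchar(seq) < nchar(pattern)) return(integer(0))
  hits <- gregexpr(paste0("(?=", pattern, ")"), seq, perl = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits)
}

#' Scan for strict sigma-T promoter element pairs
#'
#' Reports every pairing of a -35 element (consensus `GGAAC`) with a
#' downstream -10 element (consensus `CGTT`) whose spacer falls within the
#' configured range. Only strict, exact matches count: ambiguity characters
#' such as `N` never match. Overlapping element occurrences are all
#' considered.
#'
#' The spacer is, by default, the number of bases strictly between the last
#' base of the -35 element and the first base of the -10 element
#' (`spacer_measure = "gap"`, the 15-17 nt window of the sigma-T
#' consensus); `"start_to_start"` measures between the two elements' start
#' positions instead, for scripts that counted that way.
#'
#' @param regions A promoter-region tibble from [extract_upstream()], or a
#'   character vector of sequences (names become region ids).
#' @param spacer_min,spacer_max Inclusive spacer bounds. Defaults 15 and 17.
#' @param motif_35,motif_10 Element consensus strings. Defaults `GGAAC`
#'   and `CGTT`.
#' @param spacer_measure `"gap"` (default) or `"start_to_start"`.
#' @return A tibble of sites: `region`, `m35_start`, `m10_start` (1-based
#'   offsets from the region's 5' end), `spacer`.
#' @examples
#' scan_sigt_promoter(c(p1 = paste0("GGAAC", strrep("A", 16), "CGTT")))
#' @export
scan_sigt_promoter <- function(regions, spacer_min = 15, spacer_max = 17,
                               motif_35 = "GGAAC", motif_10 = "CGTT",
                               spacer_measure = c("gap", "start_to_start")) {
  spacer_measure <- match.arg(spacer_measure)
  if (is.character(regions)) {
    ids <- names(regions) %||% as.character(seq_along(regions))
    regions <- tibble(gene_id = ids, sequence = unname(regions))
  }
  regions <- as_tibble(regions)
  stopifnot(all(c("gene_id", "sequence") %in% names(regions)))
  if (spacer_min > spacer_max) abort("spacer_min must be <= spacer_max")
  rows <- purrr::map2(regions$gene_id, toupper(regions$sequence),
                      function(id, seq) {
    p35 <- pattern_starts(seq, motif_35)
    p10 <- pattern_starts(seq, motif_10)
    if (length(p35) == 0 || length(p10) == 0) return(NULL)
    pairs <- tidyr::expand_grid(m35_start = p35, m10_start = p10)
    spacer <- if (spacer_measure == "gap") {
      pairs$m10_start - (pairs$m35_start + nchar(motif_35))
    } else {
      pairs$m10_start - pairs$m35_start
    }
    keep <- spacer >= spacer_min & spacer <= spacer_max
    if (!any(keep)) return(NULL)
    tibble(region = id, m35_start = pairs$m35_start[keep],
           m10_start = pairs$m10_start[keep], spacer = spacer[keep])
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(region = character(), m35_start = integer(),
                  m10_start = integer(), spacer = integer())
  }
  dplyr::arrange(out, .data$region, .data$m35_start, .data$m10_start)
}

#' Annotation table I/O
#'
#' Reads and writes the minimal gene/TSS annotation layout used by
#' [extract_upstream()] and the pull-down region annotator: `gene_id`,
#' `replicon`, coordinates, `strand`, and optional `anchor`/`anchor_kind`.
#'
#' @param path TSV file path.
#' @return A tibble (reader) or `path` invisibly (writer).
#' @export
read_annotation_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_annotation_tsv
#' @param annotations Annotation data frame.
#' @export
write_annotation_tsv <- function(annotations, path) {
  readr::write_tsv(as_tibble(annotations), path, progress = FALSE)
  invisible(path)
}
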