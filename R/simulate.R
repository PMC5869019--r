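#' Seeded generator streams
#'
#' Each generator draws from its own RNG stream derived from the user seed
#' and the generator's name, so adding or re-running one generator never
#' perturbs another's output for the same seed.
#'
#' @param seed Integer user seed.
#' @param name Generator name.
#' @return An integer stream seed below 2^31.
#' @keywords internal
stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 2654435761) %% 1e9
  as.integer((abs(seed) * 7919 + h) %% .Machine$integer.max)
}

#' Simulate a cell-cycle expression table with a correlated regulon
#'
#' Emulates a synchronised time-course expression matrix in which a small
#' regulon of co-regulated genes shares one smooth, positive, unimodal
#' latent trajectory (peaking mid-series, like a cell-cycle-activated
#' program over a 0-120 minute series) plus Gaussian noise, while
#' background genes fluctuate independently. The noise standard deviation
#' is scaled so the expected pairwise Pearson correlation between regulon
#' members is approximately `regulon_cor`; values are clipped at zero.
#'
#' @param n_genes Total genes. Default 200.
#' @param n_timepoints Timepoints in the series. Default 5.
#' @param regulon_size Regulon members. Default 20.
#' @param regulon_cor Target pairwise correlation within the regulon.
#'   Default 0.95.
#' @param background_mean,background_sd Background gene expression level
#'   and spread. Defaults 500 and 200.
#' @param seed Integer seed; identical seeds give identical tables.
#' @return A list with `table` (expression tibble: `gene_id` + one column
#'   per timepoint) and `truth` (tibble `gene_id`, `role`).
#' @export
simulate_expression <- function(n_genes = 200, n_timepoints = 5,
                                regulon_size = 20, regulon_cor = 0.95,
                                background_mean = 500, background_sd = 200,
                                seed = 1) {
  stopifnot(n_genes >= 2, n_timepoints >= 2, regulon_size >= 2,
            regulon_size <= n_genes, regulon_cor > 0, regulon_cor <= 1)
  set.seed(stream_seed(seed, "expression"))
  tt <- seq_len(n_timepoints)
  mid <- (n_timepoints + 1) / 2
  latent <- 400 + 800 * exp(-(tt - mid)^2 / (2 * (n_timepoints / 4)^2))
  # Var over timepoints of the shared curve fixes the noise scale:
  # r ~ Var(latent) / (Var(latent) + sigma^2)  =>  sigma for target r
  sigma <- if (regulon_cor == 1) 0 else {
    sqrt(var(latent) * (1 / regulon_cor - 1))
  }
  ids <- sprintf("gene_%04d", seq_len(n_genes))
  regulon <- sort(sample(ids, regulon_size))
  m <- matrix(0, n_genes, n_timepoints)
  is_reg <- ids %in% regulon
  m[is_reg, ] <- rep(latent, each = sum(is_reg)) +
    rnorm(sum(is_reg) * n_timepoints, 0, sigma)
  m[!is_reg, ] <- rnorm(sum(!is_reg) * n_timepoints,
                        background_mean, background_sd)
  m[m < 0] <- 0
  tab <- tibble(gene_id = ids)
  for (j in tt) tab[[paste0("t", (j - 1) * 30)]] <- m[, j]
  truth <- tibble(gene_id = ids,
                  role = ifelse(is_reg, "regulon", "background"))
  list(table = tab, truth = truth)
}

# background sequence with no strict occurrence of any motif in `avoid`
motif_free_sequence <- function(n, avoid) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    if (all(vapply(avoid, function(p) length(pattern_starts(s, p)) == 0,
                   logical(1)))) {
      return(s)
    }
  }
}

#' Simulate a genome with planted sigma-T promoter sites
#'
#' Builds a single-replicon genome carrying genes on both strands, each
#' with an upstream region of `upstream_length` nt. Selected genes get a
#' strict -35/-10 element pair (`GGAAC` ... `CGTT`) planted at a recorded
#' offset with a recorded spacer; every upstream region's background is
#' rejection-sampled to be free of accidental strict matches, so the
#' planted sites are exactly the sites present. Minus-strand regions are
#' written into the genome as their reverse complement, exercising the
#' strand logic of [extract_upstream()].
#'
#' @param n_genes Genes in the genome. Default 10.
#' @param n_planted Genes receiving a planted site (the first `n_planted`
#'   after strand assignment). Default 5.
#' @param spacers Spacer lengths to cycle through for planted sites.
#'   Default `15:17`.
#' @param upstream_length Upstream region length. Default 200.
#' @param gene_length Gene body length. Default 300.
#' @param gap Gap between gene slots. Default 100.
#' @param seed Integer seed.
#' @return A list with `genome` (named character), `annotations` (tibble
#'   for [extract_upstream()]) and `truth` (tibble: `gene_id`, `strand`,
#'   `m35_start`, `m10_start`, `spacer`, offsets 1-based within the
#'   upstream region).
#' @export
simulate_genome_with_promoters <- function(n_genes = 10, n_planted = 5,
                                           spacers = 15:17,
                                           upstream_length = 200,
                                           gene_length = 300, gap = 100,
                                           seed = 1) {
  stopifnot(n_genes >= 1, n_planted <= n_genes)
  motif_35 <- "GGAAC"
  motif_10 <- "CGTT"
  avoid <- c(motif_35, motif_10)
  set.seed(stream_seed(seed, "genome"))
  spacers <- as.integer(spacers)
  slot <- upstream_length + gene_length + gap
  L <- n_genes * slot
  chrom <- strsplit(motif_free_sequence(L, character(0)), "")[[1]]
  ids <- sprintf("gene_%02d", seq_len(n_genes))
  strands <- rep(c("+", "-"), length.out = n_genes)
  anchors <- integer(n_genes)
  truth_rows <- list()
  for (i in seq_len(n_genes)) {
    s0 <- (i - 1) * slot                  # slot offset, 0-based
    planted <- i <= n_planted
    spacer <- spacers[((i - 1) %% length(spacers)) + 1]
    site_len <- nchar(motif_35) + spacer + nchar(motif_10)
    repeat {
      region <- motif_free_sequence(upstream_length, avoid)
      if (planted) {
        off <- sample(seq_len(upstream_length - site_len + 1), 1)
        site <- paste0(motif_35, substr(region, off + nchar(motif_35),
                                        off + nchar(motif_35) + spacer - 1),
                       motif_10)
        region <- paste0(substr(region, 1, off - 1), site,
                         substr(region, off + site_len, upstream_length))
        # junctions may create extra strict matches; resample if so
        p35 <- pattern_starts(region, motif_35)
        p10 <- pattern_starts(region, motif_10)
        ok <- length(p35) == 1 && p35 == off &&
          length(p10) == 1 && p10 == off + nchar(motif_35) + spacer
        if (!ok) next
      }
      break
    }
    if (strands[i] == "+") {
      anchors[i] <- s0 + upstream_length + 1
      chrom[(s0 + 1):(s0 + upstream_length)] <- strsplit(region, "")[[1]]
    } else {
      # gene body occupies the slot start; upstream lies after the anchor
      anchors[i] <- s0 + gene_length
      genome_slice <- reverse_complement(region)
      chrom[(s0 + gene_length + 1):(s0 + gene_length + upstream_length)] <-
        strsplit(genome_slice, "")[[1]]
    }
    if (planted) {
      off <- pattern_starts(region, motif_35)
      truth_rows[[length(truth_rows) + 1]] <-
        tibble(gene_id = ids[i], strand = strands[i], m35_start = off,
               m10_start = off + nchar(motif_35) + spacer, spacer = spacer)
    }
  }
  genome <- c(chr = paste(chrom, collapse = ""))
  annotations <- tibble(gene_id = ids, replicon = "chr", anchor = anchors,
                        strand = strands, anchor_kind = "TSS")
  truth <- if (length(truth_rows) > 0) dplyr::bind_rows(truth_rows) else {
    tibble(gene_id = character(), strand = character(),
           m35_start = integer(), m10_start = integer(), spacer = integer())
  }
  list(genome = genome, annotations = annotations, truth = truth)
}

#' Simulate negative-binomial window counts with planted enrichment
#'
#' Emulates the pull-down window-count design: three bait replicates, two
#' control replicates and optional auxiliary (wild-type total RNA)
#' dispersion samples, all drawn from a negative binomial with
#' variance = mu + dispersion * mu^2. Planted enriched regions are runs of
#' `region_width` adjacent windows whose bait means are multiplied by
#' `fold`; regions are separated by at least two windows so they never
#' merge. To exercise the high-variance correction, a configured fraction
#' of background windows has the designated outlier bait replicate's
#' counts inflated by `outlier_factor`.
#'
#' @param n_windows Number of windows. Default 400.
#' @param width Window width in bp. Default 25.
#' @param bait_reps,control_reps,aux_reps Replicate counts.
#'   Defaults 3, 2, 2.
#' @param nb_mean Baseline NB mean. Default 200.
#' @param dispersion NB dispersion alpha. Default 0.1.
#' @param n_regions Planted enriched regions. Default 3.
#' @param region_width Windows per planted region. Default 3.
#' @param fold Bait enrichment fold in planted regions. Default 8.
#' @param outlier_rep Index of the suspect bait replicate. Default 1.
#' @param outlier_fraction Fraction of background windows corrupted.
#'   Default 0.1.
#' @param outlier_factor Count inflation factor for corrupted windows.
#'   Default 10.
#' @param seed Integer seed.
#' @return A list with `counts` (window tibble + one column per sample,
#'   `library_sizes` attribute attached), `design`, `windows`, and `truth`
#'   (tibble of planted regions: `region_id`, `start`, `end`, window id
#'   range, `fold`; plus attribute `corrupted` with corrupted window ids).
#' @export
simulate_window_counts <- function(n_windows = 400, width = 25,
                                   bait_reps = 3, control_reps = 2,
                                   aux_reps = 2, nb_mean = 200,
                                   dispersion = 0.1, n_regions = 3,
                                   region_width = 3, fold = 8,
                                   outlier_rep = 1, outlier_fraction = 0.1,
                                   outlier_factor = 10, seed = 1) {
  stopifnot(n_windows >= 1, dispersion > 0, fold > 0, region_width >= 1)
  set.seed(stream_seed(seed, "counts"))
  windows <- make_windows(c(chr = n_windows * width), width = width)
  samples <- c(paste0("bait_", seq_len(bait_reps)),
               paste0("control_", seq_len(control_reps)),
               if (aux_reps > 0) paste0("aux_", seq_len(aux_reps)))
  design <- tibble(sample = samples,
                   condition = c(rep("bait", bait_reps),
                                 rep("control", control_reps),
                                 rep("aux", aux_reps)))
  # place planted regions on a grid with >= 2 spacer windows between them
  planted <- integer(0)
  truth <- tibble(region_id = integer(), start_window = integer(),
                  end_window = integer(), start = numeric(), end = numeric(),
                  fold = numeric())
  if (n_regions > 0) {
    stride <- region_width + 2
    avail <- seq(2, n_windows - region_width - 1, by = stride)
    if (length(avail) < n_regions) abort("planted regions do not fit")
    starts <- sort(sample(avail, n_regions))
    truth <- tibble(region_id = seq_len(n_regions), start_window = starts,
                    end_window = starts + region_width - 1L,
                    start = windows$start[starts],
                    end = windows$end[starts + region_width - 1L],
                    fold = fold)
    planted <- unlist(purrr::map2(truth$start_window, truth$end_window, seq))
  }
  mu_bait <- rep(nb_mean, n_windows)
  mu_bait[planted] <- nb_mean * fold
  counts <- windows
  for (s in samples) {
    cond <- design$condition[design$sample == s]
    mu <- if (cond == "bait") mu_bait else rep(nb_mean, n_windows)
    counts[[s]] <- rnbinom(n_windows, mu = mu, size = 1 / dispersion)
  }
  corrupted <- integer(0)
  if (outlier_fraction > 0 && bait_reps >= outlier_rep) {
    background <- setdiff(seq_len(n_windows), planted)
    corrupted <- sort(sample(background,
                             round(outlier_fraction * length(background))))
    out_col <- paste0("bait_", outlier_rep)
    counts[[out_col]][corrupted] <- counts[[out_col]][corrupted] * outlier_factor
  }
  attr(counts, "library_sizes") <- setNames(
    vapply(samples, function(s) sum(counts[[s]]), numeric(1)), samples)
  attr(truth, "corrupted") <- corrupted
  list(counts = counts, design = design, windows = windows, truth = truth)
}

#' Simulate stranded alignment records over regions
#'
#' Places reads uniformly within each region and draws each read's strand
#' to match the region's true strand with probability `strand_fraction`,
#' producing input for [assign_region_strand()] and
#' [count_reads_in_windows()].
#'
#' @param regions Tibble with `replicon`, `start`, `end` and `strand` (the
#'   true strand of the transcript the reads derive from).
#' @param reads_per_region Reads placed in each region. Default 200.
#' @param read_length Read length in nt. Default 50.
#' @param strand_fraction Probability a read maps to the true strand.
#'   Default 0.9.
#' @param sample Sample name attached to the records. Default `"bait_1"`.
#' @param seed Integer seed.
#' @return A list with `alignments` (tibble in the simplified tabular
#'   format) and `truth` (the regions with their true strands).
#' @export
simulate_stranded_alignments <- function(regions, reads_per_region = 200,
                                         read_length = 50,
                                         strand_fraction = 0.9,
                                         sample = "bait_1", seed = 1) {
  regions <- as_tibble(regions)
  stopifnot(all(c("replicon", "start", "end", "strand") %in% names(regions)))
  set.seed(stream_seed(seed, "alignments"))
  rows <- purrr::pmap(regions[c("replicon", "start", "end", "strand")],
                      function(replicon, start, end, strand) {
    if (reads_per_region == 0) return(NULL)
    span <- max(end - start - read_length, 0)
    starts <- start + floor(runif(reads_per_region) * (span + 1))
    flip <- runif(reads_per_region) >= strand_fraction
    other <- if (strand == "+") "-" else "+"
    tibble(replicon = replicon, start = starts,
           end = starts + read_length,
           strand = ifelse(flip, other, strand), sample = sample)
  })
  aln <- dplyr::bind_rows(rows)
  if (nrow(aln) == 0) {
    aln <- tibble(replicon = character(), start = numeric(),
                  end = numeric(), strand = character(), sample = character())
  }
  list(alignments = aln, truth = regions)
}
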