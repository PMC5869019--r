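test_that("high-variance filter applies the 1.5x inequality literally", {
  rp <- tibble::tibble(window_id = 1:5,
                       r1 = c(100, 12, 10, 30, 0),
                       r2 = c(10, 10, 10, 0, 0),
                       r3 = c(10, 10, 10, 0, 0))
  log <- remove_high_variance_windows(rp)
  # (100,10,10): mean 40 > 1.5 * 10 -> removed
  expect_true(log$removed[1])
  # (12,10,10): mean 10.67 <= 15 -> retained
  expect_false(log$removed[2])
  # symmetric case retained
  expect_false(log$removed[3])
  # all suspect-replicate signal, others zero -> removed
  expect_true(log$removed[4])
  # all-zero window retained
  expect_false(log$removed[5])
  expect_error(remove_high_variance_windows(
    tibble::tibble(window_id = 1, r1 = NA_real_, r2 = 1, r3 = 1)),
    "missing")
})

test_that("filter decision ignores the order of the non-suspect replicates", {
  set.seed(6)
  rp <- tibble::tibble(window_id = 1:200,
                       r1 = runif(200, 0, 100),
                       r2 = runif(200, 0, 100),
                       r3 = runif(200, 0, 100))
  a <- remove_high_variance_windows(rp, outlier_col = "r1")
  swapped <- dplyr::rename(rp, r2 = "r3", r3 = "r2")
  b <- remove_high_variance_windows(swapped[c("window_id", "r1", "r2", "r3")],
                                    outlier_col = "r1")
  expect_equal(a$removed, b$removed)
  # and the decision matches the stated inequality on every window
  direct <- (rp$r1 + rp$r2 + rp$r3) / 3 > 1.5 * (rp$r2 + rp$r3) / 2
  expect_equal(a$removed, direct)
})

test_that("identical counts in every sample show no enrichment", {
  windows <- make_windows(c(chr = 50 * 25))
  counts <- windows
  for (s in c("bait_1", "bait_2", "bait_3", "control_1", "control_2")) {
    counts[[s]] <- rep(100L, 50)
  }
  design <- tibble::tibble(
    sample = c("bait_1", "bait_2", "bait_3", "control_1", "control_2"),
    condition = c("bait", "bait", "bait", "control", "control"))
  st <- window_enrichment_test(counts, design)
  expect_true(all(st$log2_fold == 0))
  expect_true(all(st$p_value > 0.999))
  expect_equal(st$base_mean_bait, st$base_mean_control)
})

test_that("all-zero windows get p = 1 and zero base means", {
  sim <- simulate_window_counts(n_windows = 60, n_regions = 0,
                                outlier_fraction = 0, seed = 3)
  counts <- sim$counts
  for (s in sim$design$sample) counts[[s]][1:3] <- 0L
  st <- window_enrichment_test(counts, sim$design)
  expect_equal(st$p_value[1:3], rep(1, 3))
  expect_equal(st$base_mean_bait[1:3], rep(0, 3))
  expect_equal(st$log2_fold[1:3], rep(0, 3))
})

test_that("planted 8-fold windows are detected with high power", {
  sim <- simulate_window_counts(n_windows = 1000, n_regions = 50,
                                region_width = 1, fold = 8,
                                outlier_fraction = 0, seed = 17)
  st <- window_enrichment_test(sim$counts, sim$design)
  planted <- sim$truth$start_window
  expect_gte(mean(st$p_value[planted] < 0.10), 0.9)
  expect_true(all(st$log2_fold[planted] > 0))
})

test_that("significance filter is a row-wise predicate and is monotone", {
  set.seed(4)
  st <- tibble::tibble(window_id = 1:500,
                       base_mean_bait = runif(500, 0, 3000),
                       base_mean_control = runif(500, 0, 3000),
                       log2_fold = rnorm(500),
                       p_value = runif(500),
                       dispersion = 0.1)
  got <- filter_significant_windows(st, p_max = 0.10, basemean_min = 1000)
  oracle <- st$window_id[st$p_value < 0.10 &
                           st$base_mean_bait > st$base_mean_control &
                           st$base_mean_bait > 1000]
  expect_equal(got, oracle)
  expect_equal(filter_significant_windows(
    tibble::tibble(window_id = 1:2, base_mean_bait = c(2000, 900),
                   base_mean_control = c(100, 100), log2_fold = 1,
                   p_value = 0.05, dispersion = 0.1)), 1L)
  # stricter cuts never add windows
  tighter_p <- filter_significant_windows(st, p_max = 0.05,
                                          basemean_min = 1000)
  higher_bm <- filter_significant_windows(st, p_max = 0.10,
                                          basemean_min = 2000)
  expect_true(all(tighter_p %in% got))
  expect_true(all(higher_bm %in% got))
})

test_that("adjacent significant windows merge; gaps split regions", {
  windows <- make_windows(c(chr = 3000), width = 25)
  ids <- windows$window_id[windows$start %in% c(1000, 1025)]
  merged <- merge_adjacent_windows(ids, windows)
  expect_equal(nrow(merged), 1)
  expect_equal(c(merged$start, merged$end), c(1000, 1050))

  ids2 <- windows$window_id[windows$start %in% c(0, 50)]
  merged2 <- merge_adjacent_windows(ids2, windows)
  expect_equal(nrow(merged2), 2)

  # random sets: regions partition the significant windows into runs
  set.seed(23)
  for (k in 1:10) {
    sig <- sort(sample(windows$window_id, 30))
    mm <- merge_adjacent_windows(sig, windows)
    expect_setequal(unlist(mm$window_ids), sig)
    runs <- split(sig, cumsum(c(1, diff(sig) != 1)))
    expect_equal(nrow(mm), length(runs))
  }
  expect_error(merge_adjacent_windows(99999, windows), "window set")
})

test_that("strand calls are majority votes with honest ties", {
  region <- tibble::tibble(replicon = "chr", start = 100, end = 200)
  mk <- function(nplus, nminus) tibble::tibble(
    replicon = "chr", start = 120, end = 170,
    strand = c(rep("+", nplus), rep("-", nminus)), sample = "s")
  expect_equal(assign_region_strand(region, mk(10, 2))$strand, "+")
  expect_equal(assign_region_strand(region, mk(5, 5))$strand, "ambiguous")
  expect_equal(assign_region_strand(region, mk(0, 0))$strand, "ambiguous")
  # reads outside the region do not vote
  outside <- tibble::tibble(replicon = "chr", start = 300, end = 350,
                            strand = "-", sample = "s")
  expect_equal(assign_region_strand(region, dplyr::bind_rows(mk(3, 0),
                                                             outside))$strand,
               "+")
})

test_that("strand recovery succeeds on simulated stranded reads", {
  regions <- tibble::tibble(replicon = "chr", start = c(0, 500),
                            end = c(300, 900), strand = c("+", "-"))
  correct <- 0
  for (s in 1:100) {
    sim <- simulate_stranded_alignments(regions, reads_per_region = 200,
                                        strand_fraction = 0.9, seed = s)
    calls <- assign_region_strand(regions, sim$alignments)
    correct <- correct + all(calls$strand == regions$strand)
  }
  expect_gte(correct, 99)
})

test_that("regions get position and orientation codes from annotation", {
  genes <- tibble::tibble(gene_id = c("gA", "gB", "gC"),
                          replicon = "chr",
                          start = c(1001, 2001, 3001),
                          end = c(1500, 2500, 3500),
                          strand = c("+", "+", "-"))
  reg <- tibble::tibble(replicon = "chr",
                        start = c(1100, 1100, 1460, 2500, 940, 1520, 3510),
                        end = c(1200, 1200, 1480, 2510, 960, 1540, 3530),
                        strand = c("+", "-", "+", "+", "+", "-", "-"))
  ann <- annotate_region(reg, genes, upstream_margin = 100)
  # inside gA, sense then anti-sense
  expect_equal(ann$position_code[1:2], c("I", "I"))
  expect_equal(ann$orientation_code[1:2], c("S", "A"))
  expect_equal(ann$gene[1], "gA")
  # still internal near the edge
  expect_equal(ann$position_code[3], "I")
  # region starting exactly at gB's 3' boundary no longer overlaps it
  expect_equal(ann$position_code[4], "D")
  # 40-60 nt 5' of gA start, within margin -> upstream
  expect_equal(ann$position_code[5], "U")
  expect_equal(ann$gene[5], "gA")
  # just 3' of gA on its strand -> downstream
  expect_equal(ann$position_code[6], "D")
  # 5' side of the minus-strand gene gC is at its high-coordinate end
  expect_equal(ann$position_code[7], "U")
  expect_equal(ann$gene[7], "gC")
  expect_equal(ann$orientation_code[7], "S")
})

test_that("regions spanning two genes get the overlapping-pair code", {
  genes <- tibble::tibble(gene_id = c("nepR", "sigT"), replicon = "chr",
                          start = c(100, 301), end = c(300, 700),
                          strand = "+")
  reg <- tibble::tibble(replicon = "chr", start = 250, end = 350,
                        strand = "+")
  ann <- annotate_region(reg, genes)
  expect_equal(ann$position_code, "O")
  expect_equal(ann$gene, "nepR-sigT")
  expect_equal(ann$orientation_code, "S")
})

test_that("gene-level candidate filter matches its predicate oracle", {
  expect_equal(rockhopper_gene_filter(tibble::tibble(
    gene_id = "g", bait_expr = 5000, control_expr = 100,
    q_value = 0.01))$gene_id, "g")
  expect_equal(nrow(rockhopper_gene_filter(tibble::tibble(
    gene_id = "g", bait_expr = 5000, control_expr = 6000,
    q_value = 0.01))), 0)
  set.seed(31)
  rec <- tibble::tibble(gene_id = sprintf("g%03d", 1:300),
                        bait_expr = runif(300, 0, 3000),
                        control_expr = runif(300, 0, 3000),
                        q_value = runif(300))
  got <- rockhopper_gene_filter(rec)$gene_id
  oracle <- rec$gene_id[rec$q_value < 0.05 &
                          rec$bait_expr > rec$control_expr &
                          rec$bait_expr > 1000]
  expect_equal(got, oracle)
  expect_error(rockhopper_gene_filter(tibble::tibble(
    gene_id = "bad", bait_expr = -1, control_expr = 1, q_value = 0.5)),
    "bad")
})

test_that("transcripts tables load through column mapping", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(paste("Synonym", "Expression GsrN(37)-PP7hp",
                     "Expression PP7hp", "qValue", sep = "\t"),
               paste("CCNA_03107", "5000", "120", "0.001", sep = "\t"),
               paste("CCNA_00001", "80", "90", "0.8", sep = "\t")), tf)
  rec <- read_rockhopper_transcripts(tf, "Synonym",
                                     "Expression GsrN(37)-PP7hp",
                                     "Expression PP7hp", "qValue")
  expect_equal(rec$gene_id, c("CCNA_03107", "CCNA_00001"))
  expect_equal(rockhopper_gene_filter(rec)$gene_id, "CCNA_03107")
})

test_that("fold estimates track an independent NB implementation", {
  sim <- simulate_window_counts(n_windows = 200, n_regions = 10,
                                region_width = 1, fold = 8, aux_reps = 0,
                                outlier_fraction = 0, seed = 29)
  st <- window_enrichment_test(sim$counts, sim$design)
  samples <- sim$design$sample
  mat <- as.matrix(sim$counts[samples])
  rownames(mat) <- sim$counts$window_id
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      mat, S4Vectors::DataFrame(condition = factor(sim$design$condition,
                                                   levels = c("control", "bait"))),
      ~condition)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    res <- DESeq2::results(dds)
  })
  ok <- is.finite(res$log2FoldChange)
  expect_gt(cor(st$log2_fold[ok], res$log2FoldChange[ok]), 0.9)
  # both routes rank the planted windows at the top
  top_ours <- order(st$p_value)[1:10]
  expect_gte(length(intersect(st$window_id[top_ours],
                              sim$truth$start_window)), 8)
})

test_that("the whole pipeline writes BED and report output", {
  sim <- simulate_window_counts(seed = 8)
  genes <- tibble::tibble(gene_id = "gX", replicon = "chr",
                          start = sim$truth$start[1] + 1,
                          end = sim$truth$end[1], strand = "+")
  aln <- simulate_stranded_alignments(
    dplyr::mutate(sim$truth, replicon = "chr", strand = "+"),
    sample = "bait_1", seed = 2)$alignments
  out <- pulldown_pipeline(sim$counts, sim$design, sim$windows,
                           alignments = aln, genes = genes)
  expect_equal(nrow(out$regions), nrow(sim$truth))
  expect_true(all(c("strand", "position_code", "orientation_code") %in%
                    names(out$regions)))
  bed <- withr::local_tempfile(fileext = ".bed")
  write_bed(out$regions, bed)
  lines <- readLines(bed)
  expect_equal(length(lines), nrow(out$regions))
  expect_equal(length(strsplit(lines[1], "\t")[[1]]), 6)
})
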