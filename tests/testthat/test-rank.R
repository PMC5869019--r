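two_node_P <- function() {
  normalize_transition(as_rho_matrix(
    matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))),
    keep_diagonal = FALSE)
}

test_that("alpha = 1 returns the seed vector exactly", {
  P <- random_transition(10)
  f0 <- seed_vector(network_genes(P), network_genes(P)[1:2])
  for (fun in list(iterate_rank, closed_form_rank)) {
    res <- fun(P, f0, alpha = 1)
    expect_identical(unname(res$weights), unname(as.numeric(f0)))
    expect_true(res$converged)
  }
})

test_that("iteration converges within the contraction bound", {
  set.seed(11)
  P <- random_transition(25)
  f0 <- seed_vector(network_genes(P), sample(network_genes(P), 3))
  for (alpha in c(0.3, 0.5, 0.85)) {
    tol <- 1e-10
    res <- iterate_rank(P, f0, alpha, tol = tol)
    expect_true(res$converged)
    expect_lte(res$iterations, ceiling(log(tol) / log(1 - alpha)) + 1)
    closed <- closed_form_rank(P, f0, alpha)
    expect_lt(max(abs(res$weights - closed$weights)), 1e-8)
  }
})

test_that("isolated nodes keep alpha-scaled seed weight, zero otherwise", {
  # without self-loops an isolated node has an all-zero row in P
  w <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  w[1, 2] <- w[2, 1] <- 0.8
  diag(w) <- 1
  P <- normalize_transition(as_rho_matrix(w), keep_diagonal = FALSE)
  f0 <- seed_vector(c("a", "b", "c"), c("a", "c"))
  res <- closed_form_rank(P, f0, alpha = 0.4)
  expect_equal(unname(res$weights["c"]), 0.4)   # isolated seed
  f0b <- seed_vector(c("a", "b", "c"), "a")
  resb <- closed_form_rank(P, f0b, alpha = 0.4)
  expect_equal(unname(resb$weights["c"]), 0)    # isolated non-seed
  # with self-loops retained an isolated seed keeps its full weight
  Pd <- normalize_transition(as_rho_matrix(w), keep_diagonal = TRUE)
  resd <- closed_form_rank(Pd, f0, alpha = 0.4)
  expect_equal(unname(resd$weights["c"]), 1)
})

test_that("adding a seed never decreases any final weight", {
  set.seed(21)
  for (k in 1:5) {
    P <- random_transition(15)
    genes <- network_genes(P)
    base_seeds <- sample(genes, 2)
    extra <- sample(setdiff(genes, base_seeds), 1)
    f_small <- closed_form_rank(P, seed_vector(genes, base_seeds), 0.5)
    f_big <- closed_form_rank(P, seed_vector(genes, c(base_seeds, extra)),
                              0.5)
    expect_true(all(f_big$weights - f_small$weights >= -1e-12))
  }
})

test_that("gene ordering breaks ties lexicographically and honours exclusions", {
  res <- structure(list(
    weights = c(gA = 0.5, gC = 0.2, gB = 0.2),
    ranks = setNames(c(1L, 3L, 2L), c("gA", "gC", "gB")),
    alpha = 0.5, cutoff = NA, iterations = 0L, converged = TRUE,
    method = "closed_form", seeds = "gA"), class = "rank_result")
  expect_equal(rank_genes(res), c("gA", "gB", "gC"))
  expect_equal(rank_genes(res, exclude = "gA"), c("gB", "gC"))
  expect_equal(gene_rank(res, "gC"), 3)
  # random weights agree with an explicit sort-then-filter oracle
  set.seed(5)
  P <- random_transition(20)
  f0 <- seed_vector(network_genes(P), sample(network_genes(P), 4))
  rr <- closed_form_rank(P, f0, 0.6)
  ord <- names(sort(rank(-rr$weights, ties.method = "min")))
  oracle <- names(rr$weights)[order(-rr$weights, names(rr$weights))]
  expect_equal(rank_genes(rr), oracle)
  expect_equal(rank_genes(rr, exclude = attr(f0, "seeds")),
               setdiff(oracle, attr(f0, "seeds")))
})

test_that("ranks are a permutation and tidiers expose them", {
  P <- random_transition(12)
  f0 <- seed_vector(network_genes(P), network_genes(P)[1:3])
  res <- iterate_rank(P, f0, 0.5)
  expect_setequal(res$ranks, seq_along(res$weights))
  td <- tidy(res)
  expect_equal(names(td), c("gene_id", "weight", "rank", "seed"))
  expect_equal(td$rank, seq_len(nrow(td)))
  expect_equal(sum(td$seed), 3)
  gl <- glance(res)
  expect_equal(gl$n_genes, 12)
  expect_true(gl$converged)
})

test_that("input validation rejects mismatched or invalid arguments", {
  P <- random_transition(5)
  f0 <- seed_vector(rev(network_genes(P)), network_genes(P)[1])
  expect_error(iterate_rank(P, f0, 0.5), "gene order")
  f0_ok <- seed_vector(network_genes(P), network_genes(P)[1])
  expect_error(iterate_rank(P, f0_ok, 0), "alpha")
  expect_error(iterate_rank(P, f0_ok, 1.2), "alpha")
  expect_error(seed_vector(c("a", "b"), "zz"), "absent")
})

test_that("self-predictability tuning recovers a planted regulon structure", {
  # held-out gene tightly correlated with all seeds, background independent
  # a long series makes chance background correlations above 0.9 negligible
  sim <- simulate_expression(n_genes = 60, n_timepoints = 12,
                             regulon_size = 8, regulon_cor = 0.99,
                             seed = 31)
  reg <- sim$truth$gene_id[sim$truth$role == "regulon"]
  tu <- tune_parameters(normalize_profiles(sim$table), seeds = reg[-1],
                        held_out = reg[1],
                        alpha_grid = c(0.3, 0.85), cutoff_grid = c(0, 0.9))
  expect_equal(nrow(tidy(tu)), 4)
  at_09 <- dplyr::filter(tidy(tu), cutoff == 0.9)
  expect_true(all(at_09$rank_nonseed == 1))
  expect_error(tune_parameters(normalize_profiles(sim$table), reg, reg[1]),
               "held_out")
})
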