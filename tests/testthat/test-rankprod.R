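make_em <- function(values, gene_ids, sample_ids) {
  matrix(values, nrow = length(gene_ids), byrow = TRUE,
         dimnames = list(gene_ids, sample_ids))
}

test_that("pairwise log ratios enumerate all single-origin comparisons", {
  ss <- factorial_sheet()
  spec <- contrast_spec("BC_vs_CC",
                        group_samples(ss, "hippocampus", "BC"),
                        group_samples(ss, "hippocampus", "CC"))
  em <- factorial_expression(
    ss, matrix(rnorm(40), 10L, 4L,
               dimnames = list(NULL, c("CC", "BC", "CB", "BB"))),
    noise_sd = 0.3, seed = 2)
  ratios <- pairwise_log_ratios(em, spec)
  expect_equal(ncol(ratios), 9L)
  # class1-major order: first three columns share class1 replicate 1
  expect_equal(ratios[, 1L],
               em[, spec$class1_samples[1L]] - em[, spec$class2_samples[1L]],
               ignore_attr = TRUE)
  expect_equal(ratios[, 3L],
               em[, spec$class1_samples[1L]] - em[, spec$class2_samples[3L]],
               ignore_attr = TRUE)

  # equal expression across all involved samples gives an all-zero matrix
  em2 <- em
  for (s in c(spec$class1_samples, spec$class2_samples)) {
    em2[, s] <- em[, spec$class1_samples[1L]]
  }
  expect_true(all(pairwise_log_ratios(em2, spec) == 0))

  # single gene, singleton classes
  em3 <- make_em(c(6, 5), "g1", c("a", "b"))[1L, , drop = FALSE]
  sp3 <- contrast_spec("a_vs_b", "a", "b")
  expect_equal(as.vector(pairwise_log_ratios(em3, sp3)), 1)

  expect_error(pairwise_log_ratios(em[, 1:3], spec), "missing")
  expect_error(contrast_spec("x", c("a", "b"), c("b", "c")), "disjoint")
})

test_that("the rank product is the geometric mean of extreme-first ranks", {
  # a gene largest in every comparison has rp 1 in the up direction
  em <- make_em(c(9, 1, 1, 9, 2, 3, 4, 2), c("hi", "lo", "m1", "m2"),
                c("a", "b"))
  sp <- contrast_spec("a_vs_b", "a", "b")
  r <- pairwise_log_ratios(em, sp)
  expect_equal(rank_product_statistic(r, "up")[["hi"]], 1)
  expect_equal(rank_product_statistic(r, "down")[["lo"]], 1)

  # geometric mean: ranks (2, 8) over two comparisons give rp 4
  vals <- cbind(10 - 1:10, c(2, 9, rep(0, 8)) - (1:10) / 100)
  colnames(vals) <- c("k1", "k2")
  rownames(vals) <- paste0("g", 1:10)
  # build ranks directly: column k1 ranks gene g2 second, column k2 eighth
  ranks_oracle <- apply(-vals, 2L, rank, ties.method = "first")
  rp_oracle <- apply(ranks_oracle, 1L, function(x) prod(x)^(1 / length(x)))
  expect_equal(unname(rank_product_statistic(vals, "up")),
               unname(rp_oracle))

  # brute-force oracle on random small matrices with distinct values
  for (seed in 1:10) {
    set.seed(seed)
    m <- matrix(sample(seq(-50, 50), 15L) / 7, nrow = 5L, ncol = 3L,
                dimnames = list(paste0("g", 1:5), NULL))
    for (dir in c("up", "down")) {
      ranks <- apply(if (dir == "up") -m else m, 2L, rank,
                     ties.method = "first")
      oracle <- apply(ranks, 1L, function(x) prod(x)^(1 / 3))
      expect_equal(unname(rank_product_statistic(m, dir)), unname(oracle))
    }
  }
})

test_that("rank products are invariant to shifting and positive scaling", {
  set.seed(3)
  m <- matrix(rnorm(60), 20L, 3L, dimnames = list(paste0("g", 1:20), NULL))
  base <- rank_product_statistic(m, "up")
  expect_equal(rank_product_statistic(m + 5.3, "up"), base)
  expect_equal(rank_product_statistic(m * 2.7, "up"), base)
})

test_that("rank-permutation pfp is seeded, tie-coherent and monotone", {
  set.seed(4)
  m <- matrix(rnorm(100), 50L, 2L, dimnames = list(paste0("g", 1:50), NULL))
  a <- permutation_pfp(m, "up", B = 200L, seed = 9L)
  b <- permutation_pfp(m, "up", B = 200L, seed = 9L)
  expect_identical(a, b)
  expect_true(all(diff(a$pfp[order(a$rank_position)]) >= 0))
  expect_true(all(a$pfp >= a$pfp_raw - 1e-12))
  expect_equal(a$pfp_raw, a$e_value / a$rank_position)
  expect_identical(sort(a$rank_position), 1:50)

  # all genes tied: deterministic index tie-break gives rp_g = g and,
  # with one comparison, e_value_g = g exactly, so raw pfp is 1
  tied <- matrix(1, 30L, 1L, dimnames = list(paste0("g", 1:30), NULL))
  r <- permutation_pfp(tied, "up", B = 500L, seed = 1L)
  expect_equal(r$rp, 1:30)
  expect_equal(r$pfp_raw, rep(1, 30L))
})

test_that("contrast runs are antisymmetric under class swap", {
  ss <- factorial_sheet()
  gm <- matrix(rnorm(200), 50L, 4L,
               dimnames = list(NULL, c("CC", "BC", "CB", "BB")))
  em <- factorial_expression(ss, gm, noise_sd = 0.2, seed = 5)
  cfg <- quick_config(seed = 8L)
  fwd <- contrast_spec("BC_vs_CC", group_samples(ss, "hippocampus", "BC"),
                       group_samples(ss, "hippocampus", "CC"))
  rev <- contrast_spec("CC_vs_BC", group_samples(ss, "hippocampus", "CC"),
                       group_samples(ss, "hippocampus", "BC"))
  rf <- run_contrast(em, fwd, cfg, seed = 31L)
  rr <- run_contrast(em, rev, cfg, seed = 31L)
  expect_equal(rf$up$rp, rr$down$rp)
  expect_equal(rf$up$gene_id, rr$down$gene_id)
  expect_equal(rf$down$rp, rr$up$rp)
  expect_equal(rf$n_up, rr$n_down)

  # adding a constant or scaling all expression values leaves pfp intact
  r2 <- run_contrast(em + 3, fwd, cfg, seed = 31L)
  expect_equal(r2$up$pfp, rf$up$pfp)
  r3 <- run_contrast(em * 1.8, fwd, cfg, seed = 31L)
  expect_equal(r3$up$pfp, rf$up$pfp)
})

test_that("six_contrasts covers the factorial contrasts in fixed order", {
  sim <- simulate_counts(sim_params(n_genes = 400L, seed = 12L,
                                    n_per_category = c(III = 40L),
                                    sign_fraction_up = 1,
                                    effect_size = 2.5))
  cfg <- quick_config(seed = 12L)
  em <- expression_matrix(sim$counts, cfg)
  six <- six_contrasts(em, sim$samples, "hippocampus", cfg)
  expect_equal(six$summary$contrast,
               c("BC_vs_CC", "CB_vs_CC", "BB_vs_CC",
                 "CB_vs_BC", "BB_vs_BC", "BB_vs_CB"))
  expect_equal(nrow(six$summary), 6L)

  # pre-natal-only up-planting: BC_vs_CC and BB_vs_CC dominate up counts,
  # CB_vs_CC stays near zero
  s <- six$summary
  up <- stats::setNames(s$n_up, s$contrast)
  expect_gt(up[["BC_vs_CC"]], 10L)
  expect_gt(up[["BB_vs_CC"]], 10L)
  expect_lte(up[["CB_vs_CC"]], 2L)

  # a gene can be significant in at most one direction per contrast
  for (res in six$contrasts) {
    both <- intersect(res$up$gene_id[res$up$significant],
                      res$down$gene_id[res$down$significant])
    expect_length(both, 0L)
  }

  # missing group is a hard error naming the group
  keep <- sim$samples[sample_groups(sim$samples) != "BB", ]
  expect_error(six_contrasts(em[, keep$sample_id], keep,
                             "hippocampus", cfg), "BB")
})

test_that("gene universe is the union over all six contrasts", {
  sim <- simulate_counts(sim_params(n_genes = 400L, seed = 13L,
                                    n_per_category = c(III = 30L),
                                    effect_size = 2.5))
  cfg <- quick_config(seed = 13L)
  em <- expression_matrix(sim$counts, cfg)
  six <- six_contrasts(em, sim$samples, "hippocampus", cfg)
  u <- gene_universe(six, cfg)
  per_contrast <- lapply(six$contrasts, function(res) {
    union(res$up$gene_id[res$up$significant],
          res$down$gene_id[res$down$significant])
  })
  expect_setequal(u, unique(unlist(per_contrast)))
  expect_lte(length(u), sum(lengths(per_contrast)))
})
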