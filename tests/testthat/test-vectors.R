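vector_env <- function(group_means, noise_sd = 0, seed = 1, n_rep = 3L) {
  ss <- factorial_sheet(n_rep = n_rep)
  em <- factorial_expression(ss, group_means, noise_sd = noise_sd,
                             seed = seed)
  list(ss = ss, em = em)
}

flat_means <- function(n_genes = 4L) {
  matrix(5, n_genes, 4L, dimnames = list(NULL, c("CC", "BC", "CB", "BB")))
}

test_that("between-replicate vectors form the full cross product", {
  env <- vector_env(flat_means(), noise_sd = 0.1, seed = 3)
  spec <- vector_analysis_spec("postnatal_response", env$ss, "hippocampus")
  v <- between_replicate_vectors(env$em, spec, "g001")
  expect_equal(nrow(v), 81L)

  # replicates identical within groups: all 81 vectors identical
  env0 <- vector_env(flat_means() + c(0, 1, 2, 3), noise_sd = 0)
  v0 <- between_replicate_vectors(env0$em, spec, "g001")
  expect_equal(nrow(unique(as.data.frame(v0))), 1L)

  # n = 1 gives the single vector (delta0, delta1)
  env1 <- vector_env(matrix(c(1, 2, 4, 8), 1L, 4L,
                            dimnames = list(NULL, c("CC", "BC", "CB", "BB"))),
                     n_rep = 1L)
  spec1 <- vector_analysis_spec("postnatal_response", env1$ss, "hippocampus")
  v1 <- between_replicate_vectors(env1$em, spec1, "g001")
  expect_equal(nrow(v1), 1L)
  expect_equal(unname(v1[1L, ]), c(4 - 1, 8 - 2))  # CB-CC, BB-BC
})

test_that("vector summation matches a brute-force oracle", {
  ones <- matrix(1, 81L, 2L)
  s <- vector_sum(ones)
  expect_equal(unname(s), c(81, 81, 81 * sqrt(2)))

  sym <- rbind(c(3, 1), c(-3, -1), c(0.5, -2), c(-0.5, 2))
  expect_equal(unname(vector_sum(sym)), c(0, 0, 0))

  set.seed(8)
  v <- matrix(rnorm(20), 10L, 2L)
  sx <- 0; sy <- 0
  for (i in 1:10) { sx <- sx + v[i, 1L]; sy <- sy + v[i, 2L] }
  expect_equal(unname(vector_sum(v)), c(sx, sy, sqrt(sx^2 + sy^2)))

  # |Vsum| scales linearly with a common fold-change scaling
  expect_equal(vector_sum(3.7 * v)[["vsum_mag"]],
               3.7 * vector_sum(v)[["vsum_mag"]])

  # unit-normalized mode measures consistency only
  expect_equal(vector_sum(rbind(c(10, 0), c(0.1, 0)),
                          normalize = TRUE)[["vsum_mag"]], 2)
})

test_that("sector classification follows the eight 45-degree sectors", {
  cfg <- run_config()
  cls <- function(x, y, p = 0.01) classify_sector(x, y, p, cfg)
  expect_equal(cls(50, 50), "both_up")
  expect_equal(cls(50, 0), "only0_up")
  expect_equal(cls(0, 50), "only1_up")
  expect_equal(cls(-50, 50), "opposite_0down_1up")
  expect_equal(cls(-50, 0), "only0_down")
  expect_equal(cls(-50, -50), "both_down")
  expect_equal(cls(0, -50), "only1_down")
  expect_equal(cls(50, -50), "opposite_0up_1down")

  # threshold rule: (30, 30) has |Vsum| ~ 42.4 >= 40, (25, 25) ~ 35.4 < 40;
  # small-and-non-significant is unchanged, the mixed zones (significant
  # but small, or large but non-significant) are indeterminate
  expect_equal(cls(30, 30), "both_up")
  expect_equal(cls(25, 25, p = 0.5), "unchanged")
  expect_equal(cls(25, 25, p = 0.01), "indeterminate")
  expect_equal(cls(50, 50, p = 0.2), "indeterminate")
  # a boundary angle (exactly 22.5 degrees) goes to the counterclockwise
  # sector, and p exactly at the cut-off still passes
  expect_equal(cls(60 * cos(pi / 8), 60 * sin(pi / 8), p = 0.05), "both_up")
  expect_equal(cls(60 * cos(3 * pi / 8), 60 * sin(3 * pi / 8)), "only1_up")
})

test_that("class labels obey the symmetry involutions", {
  angles <- seq(5, 355, by = 10)
  x <- 60 * cospi(angles / 180)
  y <- 60 * sinpi(angles / 180)
  cfg <- run_config()
  base <- classify_sector(x, y, rep(0.01, length(x)), cfg)
  neg <- classify_sector(-x, -y, rep(0.01, length(x)), cfg)
  swap_ud <- c(both_up = "both_down", both_down = "both_up",
               only0_up = "only0_down", only0_down = "only0_up",
               only1_up = "only1_down", only1_down = "only1_up",
               opposite_0up_1down = "opposite_0down_1up",
               opposite_0down_1up = "opposite_0up_1down",
               unchanged = "unchanged")
  expect_equal(neg, unname(swap_ud[base]))

  # exchanging the axes reflects about the diagonal: only0 <-> only1,
  # both_* fixed
  refl <- classify_sector(y, x, rep(0.01, length(x)), cfg)
  swap_axes <- c(both_up = "both_up", both_down = "both_down",
                 only0_up = "only1_up", only1_up = "only0_up",
                 only0_down = "only1_down", only1_down = "only0_down",
                 opposite_0up_1down = "opposite_0down_1up",
                 opposite_0down_1up = "opposite_0up_1down",
                 unchanged = "unchanged")
  expect_equal(refl, unname(swap_axes[base]))
})

test_that("permutation p-values are exact, reproducible and honest at null", {
  # a gene with all-equal expression: |Vsum| = 0 and p = 1
  env <- vector_env(flat_means(), noise_sd = 0)
  spec <- vector_analysis_spec("postnatal_response", env$ss, "hippocampus")
  r <- vector_permutation_p(env$em, spec, c("g001", "g002"), B = 1000L,
                            seed = 2L)
  expect_equal(r$vsum_mag, c(0, 0))
  expect_equal(r$p_value, c(1, 1))

  # exact enumeration is deterministic regardless of seed
  env2 <- vector_env(flat_means(), noise_sd = 0.5, seed = 9)
  a <- vector_permutation_p(env2$em, spec, "g001", B = 1000L, seed = 1L)
  b <- vector_permutation_p(env2$em, spec, "g001", B = 1000L, seed = 99L)
  expect_identical(a, b)

  # Monte-Carlo fallback (B below the 400 exact combos) is seeded
  a <- vector_permutation_p(env2$em, spec, "g001", B = 199L, seed = 5L)
  b <- vector_permutation_p(env2$em, spec, "g001", B = 199L, seed = 5L)
  expect_identical(a, b)
})

test_that("planted strong both-up genes are detected", {
  detected <- 0L
  for (seed in 1:40) {
    gm <- flat_means(2L)
    gm[1L, c("BC", "CB")] <- 5 + 2
    gm[1L, "BB"] <- 5 + 4   # cumulative: both axes shift by 2
    env <- vector_env(gm, noise_sd = 0.3, seed = seed)
    spec <- vector_analysis_spec("postnatal_response", env$ss,
                                 "hippocampus")
    r <- vector_permutation_p(env$em, spec, "g001", B = 1000L, seed = seed)
    detected <- detected + (r$p_value <= 0.05 && r$vsum_mag >= 40)
  }
  expect_gte(detected / 40, 0.95)
})

test_that("the vector analyses use the contrasts of their environments", {
  ss <- factorial_sheet()
  post <- vector_analysis_spec("postnatal_response", ss, "hippocampus")
  expect_equal(post$axis0$name, "CB_vs_CC")
  expect_equal(post$axis1$name, "BB_vs_BC")
  pre <- vector_analysis_spec("prenatal_response", ss, "hippocampus")
  expect_equal(pre$axis0$name, "BC_vs_CC")
  expect_equal(pre$axis1$name, "BB_vs_CB")
})
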