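# Shared fixtures for the test suite; everything is built in code.

# A tiny valid count matrix with named dimensions.
tiny_counts <- function(values = c(0L, 5L, 10L, 0L, 3L, 3L),
                        n_genes = 3L, n_samples = 2L) {
  m <- matrix(values, nrow = n_genes, byrow = TRUE,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  count_matrix(m)
}

# Random valid count matrix for property tests.
random_counts <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  m <- matrix(rnbinom(n_genes * n_samples, mu = 50, size = 5),
              nrow = n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(n_samples))))
  count_matrix(m)
}

# A full 2x2 factorial sample sheet for one tissue.
factorial_sheet <- function(tissue = "hippocampus", n_rep = 3L) {
  groups <- c("CC", "BC", "CB", "BB")
  sample_sheet(data.frame(
    sample_id = paste0(tissue, "_", rep(groups, each = n_rep), "_",
                       rep(seq_len(n_rep), 4L)),
    tissue = tissue,
    prenatal = substr(rep(groups, each = n_rep), 1L, 1L),
    postnatal = substr(rep(groups, each = n_rep), 2L, 2L),
    replicate = rep(seq_len(n_rep), 4L),
    stringsAsFactors = FALSE
  ))
}

# Log-scale expression matrix with specified per-group means plus
# Gaussian noise, matching a factorial sheet.
factorial_expression <- function(ss, group_means, n_genes = nrow(group_means),
                                 noise_sd = 0, seed = 1) {
  set.seed(seed)
  grp <- sample_groups(ss)
  em <- matrix(0, nrow = n_genes, ncol = nrow(ss),
               dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                               ss$sample_id))
  for (j in seq_len(ncol(em))) {
    em[, j] <- group_means[, grp[j]] + rnorm(n_genes, 0, noise_sd)
  }
  em
}

# Quick configuration for cheap test runs.
quick_config <- function(...) {
  run_config(n_permutations_rp = 100L, n_permutations_vector = 1000L, ...)
}
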