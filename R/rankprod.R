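# RankProducts two-class differential expression with a permutation
# percentage-of-false-positives (pfp) estimate of the FDR, run over the
# six pairwise contrasts of the 2x2 factorial design.

CONTRAST_ORDER <- c("BC_vs_CC", "CB_vs_CC", "BB_vs_CC",
                    "CB_vs_BC", "BB_vs_BC", "BB_vs_CB")

#' Define a two-class contrast
#'
#' @param name contrast name, conventionally `"<class1>_vs_<class2>"`;
#'   class 1 is the first-named class and directions (up/down) refer to
#'   regulation in class 1 relative to class 2.
#' @param class1_samples,class2_samples disjoint non-empty sample-id
#'   vectors drawn from one tissue.
#' @return list of class `rpvec_contrast_spec`.
#' @export
contrast_spec <- function(name, class1_samples, class2_samples) {
  class1_samples <- as.character(class1_samples)
  class2_samples <- as.character(class2_samples)
  if (!length(class1_samples) || !length(class2_samples)) {
    stop("both classes must be non-empty")
  }
  if (length(intersect(class1_samples, class2_samples))) {
    stop("classes must be disjoint in contrast ", name)
  }
  structure(list(name = name, class1_samples = class1_samples,
                 class2_samples = class2_samples),
            class = "rpvec_contrast_spec")
}

#' All pairwise log ratios for a contrast
#'
#' Builds the single-origin comparison matrix: one column per
#' (class1 sample, class2 sample) pair holding, for every gene, the
#' difference class1 minus class2 on the log2 expression scale. Columns
#' are in deterministic class1-major order.
#'
#' @param em expression matrix (genes x samples, log2 scale).
#' @param spec contrast from [contrast_spec()].
#' @return numeric matrix, genes x (n1 * n2).
#' @export
pairwise_log_ratios <- function(em, spec) {
  stopifnot(inherits(spec, "rpvec_contrast_spec"))
  missing <- setdiff(c(spec$class1_samples, spec$class2_samples),
                     colnames(em))
  if (length(missing)) {
    stop("sample(s) missing from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  n1 <- length(spec$class1_samples)
  n2 <- length(spec$class2_samples)
  left <- em[, rep(spec$class1_samples, each = n2), drop = FALSE]
  right <- em[, rep(spec$class2_samples, times = n1), drop = FALSE]
  ratios <- left - right
  colnames(ratios) <- paste0(rep(spec$class1_samples, each = n2), ".vs.",
                             rep(spec$class2_samples, times = n1))
  ratios
}

# Per-column ranks with rank 1 the most extreme value in the requested
# direction (largest difference for "up", smallest for "down"); ties
# broken deterministically by ascending gene index.
rank_columns <- function(ratios, direction = c("up", "down")) {
  direction <- match.arg(direction)
  G <- nrow(ratios)
  idx <- seq_len(G)
  ranks <- matrix(0L, nrow = G, ncol = ncol(ratios))
  for (k in seq_len(ncol(ratios))) {
    key <- if (direction == "up") -ratios[, k] else ratios[, k]
    o <- order(key, idx)
    ranks[o, k] <- idx
  }
  ranks
}

#' Rank product statistic
#'
#' The geometric mean, across all pairwise comparisons, of each gene's
#' rank, where rank 1 is the most up-regulated (direction `"up"`) or most
#' down-regulated (direction `"down"`) gene in that comparison. Values lie
#' in `[1, G]`; small values indicate consistent extreme regulation.
#'
#' @param ratios pairwise log-ratio matrix from [pairwise_log_ratios()].
#' @param direction `"up"` or `"down"`.
#' @return numeric vector of per-gene rank products.
#' @export
rank_product_statistic <- function(ratios, direction = c("up", "down")) {
  if (nrow(ratios) < 2L) stop("rank products need at least 2 genes")
  ranks <- rank_columns(ratios, direction)
  stats::setNames(exp(rowMeans(log(ranks))), rownames(ratios))
}

#' Null distribution of the rank product
#'
#' Generates `B` independent randomizations in which every comparison
#' column receives an independent uniform permutation of the ranks
#' `1..n_genes`, and pools the resulting `B * n_genes` null rank products.
#' The null depends only on the dimensions, so one object can be shared by
#' all contrasts of the same shape and by both directions.
#'
#' @param n_genes number of genes.
#' @param n_comparisons number of pairwise comparison columns.
#' @param B number of randomizations.
#' @param seed integer seed.
#' @return list of class `rpvec_rp_null` holding the sorted pooled null
#'   log rank products and the generation parameters.
#' @export
rp_null_distribution <- function(n_genes, n_comparisons, B, seed) {
  n_genes <- as.integer(n_genes)
  K <- as.integer(n_comparisons)
  B <- as.integer(B)
  if (B < 1L) stop("B must be at least 1")
  log_rank <- log(seq_len(n_genes))
  null_log_rp <- local_seed(seed, {
    out <- numeric(B * n_genes)
    for (b in seq_len(B)) {
      acc <- log_rank[sample.int(n_genes)]
      if (K > 1L) {
        for (k in seq.int(2L, K)) acc <- acc + log_rank[sample.int(n_genes)]
      }
      out[((b - 1L) * n_genes + 1L):(b * n_genes)] <- acc / K
    }
    out
  })
  structure(list(sorted_log_rp = sort(null_log_rp), n_genes = n_genes,
                 n_comparisons = K, B = B, seed = as.integer(seed)),
            class = "rpvec_rp_null")
}

# Expected number of null gene instances per randomization at or below
# each observed rank product (the RankProducts E-value).
rp_evalue <- function(rp, null) {
  stopifnot(inherits(null, "rpvec_rp_null"))
  findInterval(log(rp) + 1e-9, null$sorted_log_rp) / null$B
}

# Sample-label permutation null for the rank product. The class labels of
# the involved samples are re-assigned (the same re-assignment for every
# gene), the full pairwise-comparison rank machinery is recomputed, and
# null rank products are pooled over genes; this respects the correlation
# between comparison columns that share samples, which the independent
# rank-randomization null ignores. The rank product is invariant to
# sample order within a class, so the null has only choose(n1+n2, n1)
# distinct splits; when that count is within the permutation budget B the
# null is enumerated exactly (deterministically), otherwise B random
# splits are drawn. Returns the per-split null log rank products (one
# vector per split and direction) for reuse across pool re-estimates.
label_null_ranks <- function(em_sub, n1, n2, B, seed) {
  G <- nrow(em_sub)
  K <- n1 * n2
  n <- n1 + n2
  idx <- seq_len(G)
  log_rank <- log(idx)
  n_splits <- choose(n, n1)
  exact <- n_splits <= B
  splits <- if (exact) {
    utils::combn(n, n1, simplify = FALSE)
  } else {
    local_seed(seed, {
      replicate(B, sort(sample.int(n, n1)), simplify = FALSE)
    })
  }
  up <- vector("list", length(splits))
  down <- vector("list", length(splits))
  for (s in seq_along(splits)) {
    c1 <- splits[[s]]
    c2 <- setdiff(seq_len(n), c1)
    ratios <- em_sub[, rep(c1, each = n2), drop = FALSE] -
      em_sub[, rep(c2, times = n1), drop = FALSE]
    acc_up <- numeric(G)
    acc_down <- numeric(G)
    for (k in seq_len(K)) {
      col <- ratios[, k]
      o <- order(-col, idx)
      acc_up[o] <- acc_up[o] + log_rank
      o <- order(col, idx)
      acc_down[o] <- acc_down[o] + log_rank
    }
    up[[s]] <- acc_up / K
    down[[s]] <- acc_down / K
  }
  list(up = up, down = down, exact = exact, n_rounds = length(splits))
}

# E-values against the label-permutation null, counting pool genes
# flagged in `keep`; genes provisionally called significant are excluded
# from the pool (but never from the ranking) so that abundant true
# effects do not contaminate the null and mask one another. A gene's own
# null instances always count against it even when it is excluded from
# the shared pool, preserving the permutation-test guarantee that a
# gene cannot certify itself by being removed from its own null.
label_null_evalues <- function(null_ranks, log_rp_up, log_rp_down, keep) {
  G <- length(log_rp_up)
  cnt_up <- numeric(G)
  cnt_down <- numeric(G)
  own_up <- numeric(G)
  own_down <- numeric(G)
  for (s in seq_len(null_ranks$n_rounds)) {
    cnt_up <- cnt_up +
      findInterval(log_rp_up + 1e-9, sort(null_ranks$up[[s]][keep]))
    cnt_down <- cnt_down +
      findInterval(log_rp_down + 1e-9, sort(null_ranks$down[[s]][keep]))
    own_up <- own_up + (null_ranks$up[[s]] <= log_rp_up + 1e-9)
    own_down <- own_down + (null_ranks$down[[s]] <= log_rp_down + 1e-9)
  }
  e_up <- cnt_up / null_ranks$n_rounds
  e_down <- cnt_down / null_ranks$n_rounds
  e_up[!keep] <- e_up[!keep] + own_up[!keep] / null_ranks$n_rounds
  e_down[!keep] <- e_down[!keep] + own_down[!keep] / null_ranks$n_rounds
  list(up = e_up, down = e_down)
}

# Rank positions and monotone pfp from rank products and E-values.
pfp_from_evalue <- function(rp, e_value) {
  G <- length(rp)
  pos <- integer(G)
  pos[order(rp, seq_len(G))] <- seq_len(G)
  pfp_raw <- e_value / pos
  ord <- order(pos)
  pfp <- numeric(G)
  pfp[ord] <- cummax(pfp_raw[ord])
  data.frame(rp = rp, rank_position = pos, e_value = e_value,
             pfp_raw = pfp_raw, pfp = pfp)
}

#' Permutation E-values and pfp for one direction
#'
#' For each gene, `e_value` is the expected number of null genes with a
#' rank product at or below the gene's observed value (estimated from `B`
#' rank randomizations), and `pfp = e_value / rank_position` estimates the
#' false discovery rate incurred by calling every gene up to that rank.
#' Reported pfp values are made monotone non-decreasing in rank order by a
#' running maximum so that thresholding yields a coherent call set.
#'
#' @param ratios pairwise log-ratio matrix.
#' @param direction `"up"` or `"down"`.
#' @param B number of randomizations (used when `null` is not supplied).
#' @param seed seed for the null stream (used when `null` is not
#'   supplied).
#' @param null optional pre-computed [rp_null_distribution()] of matching
#'   shape, shared across directions and contrasts.
#' @return data frame with `rp`, `rank_position`, `e_value`, `pfp_raw`
#'   and monotone `pfp`, in gene order.
#' @export
permutation_pfp <- function(ratios, direction = c("up", "down"),
                            B = 1000L, seed = 1L, null = NULL) {
  direction <- match.arg(direction)
  G <- nrow(ratios)
  if (is.null(null)) {
    null <- rp_null_distribution(G, ncol(ratios), B, seed)
  }
  if (null$n_genes != G || null$n_comparisons != ncol(ratios)) {
    stop("null distribution shape does not match the ratio matrix")
  }
  rp <- rank_product_statistic(ratios, direction)
  pfp_from_evalue(rp, rp_evalue(rp, null))
}

#' Run RankProducts for one contrast
#'
#' Computes both one-sided analyses (up- and down-regulation in class 1
#' relative to class 2) sharing one null distribution, flags genes with
#' `pfp <= config$fdr_threshold`, and resolves the pathological case of a
#' gene significant in both directions by keeping the direction with the
#' smaller pfp (ties go to up). Also reports the mean log2 fold change
#' over all pairwise comparisons and, separately labelled, a signed linear
#' ratio of group-mean normalized counts (`linear_fc`; computed by
#' back-transforming the expression values and using a pseudo-count of 1,
#' positive when class 1 is higher, negative reciprocal when lower).
#'
#' Because the pairwise comparison columns share samples and are
#' therefore correlated, the default null permutes the class labels of
#' the involved samples and recomputes the full rank machinery
#' (`null_method = "label_permutation"`), which keeps the pfp estimate
#' calibrated. Because genes carrying real effects would otherwise
#' contaminate a data-derived null (their permuted fold changes retain
#' partial signal) and mask one another, genes provisionally significant
#' at the pfp threshold are excluded from the null pool and the E-values
#' re-estimated until the call set stabilises; the pool never shrinks
#' below half the genes. `"rank_permutation"` selects the plain
#' independent
#' rank-randomization null of [rp_null_distribution()] instead, which is
#' anticonservative for correlated columns and is retained for
#' comparison and for the small-sample enumeration checks.
#'
#' @param em expression matrix (log2 scale).
#' @param spec contrast from [contrast_spec()].
#' @param config run configuration ([run_config()]).
#' @param null optional shared [rp_null_distribution()]; supplying one
#'   implies `null_method = "rank_permutation"`.
#' @param null_method how to build the null distribution (see Details).
#' @param seed seed for the null stream; defaults to a stream derived
#'   from `config$seed`.
#' @return list of class `rpvec_contrast_result` with `name`, `up` and
#'   `down` data frames (ordered by rank position; columns `gene_id`,
#'   `direction`, `rp`, `e_value`, `pfp`, `mean_log2fc`, `linear_fc`,
#'   `rank_position`, `significant`), and significant counts `n_up`,
#'   `n_down`.
#' @export
run_contrast <- function(em, spec, config = run_config(), null = NULL,
                         null_method = c("label_permutation",
                                         "rank_permutation"),
                         seed = derive_seed(config$seed, 17L)) {
  null_method <- match.arg(null_method)
  ratios <- pairwise_log_ratios(em, spec)
  G <- nrow(ratios)
  mean_log2fc <- rowMeans(ratios)
  norm_counts <- pmax(2^em - config$log_offset, 0)
  m1 <- rowMeans(norm_counts[, spec$class1_samples, drop = FALSE])
  m2 <- rowMeans(norm_counts[, spec$class2_samples, drop = FALSE])
  ratio <- (m1 + 1) / (m2 + 1)
  linear_fc <- ifelse(ratio >= 1, ratio, -1 / ratio)

  if (!is.null(null) || null_method == "rank_permutation") {
    if (is.null(null)) {
      null <- rp_null_distribution(G, ncol(ratios),
                                   config$n_permutations_rp, seed)
    }
    side <- lapply(c(up = "up", down = "down"), function(d) {
      permutation_pfp(ratios, d, null = null)
    })
  } else {
    log_rp_up <- rowMeans(log(rank_columns(ratios, "up")))
    log_rp_down <- rowMeans(log(rank_columns(ratios, "down")))
    null_ranks <- label_null_ranks(
      em[, c(spec$class1_samples, spec$class2_samples), drop = FALSE],
      length(spec$class1_samples), length(spec$class2_samples),
      config$n_permutations_rp, seed)
    # Iteratively purge provisionally significant genes from the null
    # pool (never below half the genes) until the call set stabilises.
    keep <- rep(TRUE, G)
    for (it in seq_len(10L)) {
      e <- label_null_evalues(null_ranks, log_rp_up, log_rp_down, keep)
      side <- list(up = pfp_from_evalue(exp(log_rp_up), e$up),
                   down = pfp_from_evalue(exp(log_rp_down), e$down))
      sig <- side$up$pfp <= config$fdr_threshold |
        side$down$pfp <= config$fdr_threshold
      if (sum(!sig) < G / 2 || identical(!sig, keep)) break
      keep <- !sig
    }
  }
  side <- lapply(side, function(res) {
    res$significant <- res$pfp <= config$fdr_threshold
    res
  })
  both <- side$up$significant & side$down$significant
  if (any(both)) {
    keep_up <- side$up$pfp[both] <= side$down$pfp[both]
    side$up$significant[both][!keep_up] <- FALSE
    side$down$significant[both][keep_up] <- FALSE
  }
  tables <- lapply(c(up = "up", down = "down"), function(d) {
    res <- side[[d]]
    df <- data.frame(
      gene_id = rownames(em),
      direction = d,
      rp = res$rp,
      e_value = res$e_value,
      pfp = res$pfp,
      mean_log2fc = mean_log2fc,
      linear_fc = linear_fc,
      rank_position = res$rank_position,
      significant = res$significant,
      stringsAsFactors = FALSE
    )
    df[order(df$rank_position), , drop = FALSE]
  })
  structure(list(
    name = spec$name,
    spec = spec,
    up = tables$up,
    down = tables$down,
    n_up = sum(tables$up$significant),
    n_down = sum(tables$down$significant)
  ), class = "rpvec_contrast_result")
}

#' Build the six factorial contrast specs for one tissue
#'
#' @param ss sample sheet.
#' @param tissue tissue name.
#' @return named list of [contrast_spec()] objects in the fixed order
#'   BC_vs_CC, CB_vs_CC, BB_vs_CC, CB_vs_BC, BB_vs_BC, BB_vs_CB.
#' @export
six_contrast_specs <- function(ss, tissue) {
  specs <- lapply(CONTRAST_ORDER, function(nm) {
    parts <- strsplit(nm, "_vs_")[[1L]]
    contrast_spec(nm, group_samples(ss, tissue, parts[1L]),
                  group_samples(ss, tissue, parts[2L]))
  })
  stats::setNames(specs, CONTRAST_ORDER)
}

#' RankProducts over all six factorial contrasts of one tissue
#'
#' Runs [run_contrast()] for the six pairwise group comparisons in a fixed
#' order, sharing one null distribution per comparison-matrix shape, and
#' summarises the number of significant up- and down-regulated genes per
#' contrast.
#'
#' @param em expression matrix for the tissue's samples.
#' @param ss sample sheet.
#' @param tissue tissue name; all four groups must be present.
#' @param config run configuration.
#' @return list of class `rpvec_six_contrasts` with `tissue`, `contrasts`
#'   (named list of contrast results) and `summary` (data frame with
#'   columns contrast, n_up, n_down; six rows).
#' @export
six_contrasts <- function(em, ss, tissue, config = run_config()) {
  sub <- ss[ss$tissue == tissue, , drop = FALSE]
  if (!nrow(sub)) stop("no samples for tissue: ", tissue)
  grp <- sample_groups(sub)
  n_rep <- vapply(GROUPS, function(g) sum(grp == g), integer(1L))
  if (any(n_rep == 0L)) {
    stop("group(s) absent for tissue ", tissue, ": ",
         paste(GROUPS[n_rep == 0L], collapse = ", "))
  }
  absent <- setdiff(sub$sample_id, colnames(em))
  if (length(absent)) {
    stop("sample(s) missing from expression matrix: ",
         paste(absent, collapse = ", "))
  }
  specs <- six_contrast_specs(ss, tissue)
  results <- lapply(seq_along(specs), function(i) {
    run_contrast(em, specs[[i]], config,
                 seed = derive_seed(config$seed, 17L + i))
  })
  names(results) <- names(specs)
  summary <- data.frame(
    contrast = CONTRAST_ORDER,
    n_up = vapply(results, `[[`, integer(1L), "n_up"),
    n_down = vapply(results, `[[`, integer(1L), "n_down"),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(list(tissue = tissue, contrasts = results, summary = summary),
            class = "rpvec_six_contrasts")
}
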