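# Vector analysis: each gene's response to one exposure is represented as
# a 2-D vector whose coordinates are log2 fold changes measured in the two
# states of the other exposure ("environment 0" = carrier-only, plotted on
# the horizontal axis; "environment 1" = B-exposed, vertical axis).
# Summation over all between-replicate fold-change pairs gives |Vsum|,
# which encodes both magnitude and replicate consistency; significance
# comes from group-label permutation, and direction is classified into
# eight 45-degree sectors.

VECTOR_ANALYSES <- c("postnatal_response", "prenatal_response")

CLASS_LABELS <- c("unchanged", "indeterminate", "both_up", "both_down",
                  "opposite_0up_1down", "opposite_0down_1up",
                  "only0_up", "only0_down", "only1_up", "only1_down")

# Sector order counterclockwise starting at the sector centered on the
# positive horizontal axis; boundaries at odd multiples of 22.5 degrees,
# half-open with ties going to the counterclockwise sector.
SECTOR_LABELS <- c("only0_up", "both_up", "only1_up", "opposite_0down_1up",
                   "only0_down", "both_down", "only1_down",
                   "opposite_0up_1down")

#' Define one of the two vector analyses
#'
#' `postnatal_response` interrogates the response to post-natal exposure
#' given each pre-natal environment: axis 0 (carrier-only pre-natal
#' environment) is the contrast CB vs CC and axis 1 (B-exposed pre-natal
#' environment) is BB vs BC. `prenatal_response` interrogates the response
#' to pre-natal exposure given each post-natal environment: axis 0 is
#' BC vs CC and axis 1 is BB vs CB.
#'
#' @param name `"postnatal_response"` or `"prenatal_response"`.
#' @param ss sample sheet.
#' @param tissue tissue name.
#' @return list of class `rpvec_vector_spec` with `name`, `axis0` and
#'   `axis1` contrast specs.
#' @export
vector_analysis_spec <- function(name = VECTOR_ANALYSES, ss, tissue) {
  name <- match.arg(name)
  groups <- if (name == "postnatal_response") {
    list(axis0 = c("CB", "CC"), axis1 = c("BB", "BC"))
  } else {
    list(axis0 = c("BC", "CC"), axis1 = c("BB", "CB"))
  }
  make <- function(g) {
    contrast_spec(paste0(g[1L], "_vs_", g[2L]),
                  group_samples(ss, tissue, g[1L]),
                  group_samples(ss, tissue, g[2L]))
  }
  structure(list(name = name, axis0 = make(groups$axis0),
                 axis1 = make(groups$axis1)),
            class = "rpvec_vector_spec")
}

#' Gene universe for the vector analyses
#'
#' The union of genes significant (in either direction) in at least one of
#' the six RankProducts contrasts at `config$fdr_threshold`.
#'
#' @param six result of [six_contrasts()].
#' @param config run configuration.
#' @return sorted character vector of gene ids.
#' @export
gene_universe <- function(six, config = run_config()) {
  stopifnot(inherits(six, "rpvec_six_contrasts"))
  hits <- unlist(lapply(six$contrasts, function(res) {
    c(res$up$gene_id[res$up$pfp <= config$fdr_threshold],
      res$down$gene_id[res$down$pfp <= config$fdr_threshold])
  }), use.names = FALSE)
  sort(unique(hits))
}

#' Between-replicate fold-change vectors for one gene
#'
#' Axis 0 values are all `n1 x n2` between-replicate log2 differences for
#' the axis-0 contrast (class 1 replicate minus class 2 replicate), axis 1
#' values likewise; the vectors are the full cross product of the two
#' difference sets in deterministic axis-0-major order (n = 3 replicates
#' everywhere gives 9 x 9 = 81 vectors).
#'
#' @param em expression matrix.
#' @param spec vector-analysis spec from [vector_analysis_spec()].
#' @param gene gene id.
#' @return two-column matrix (x, y), one row per vector.
#' @export
between_replicate_vectors <- function(em, spec, gene) {
  stopifnot(inherits(spec, "rpvec_vector_spec"))
  if (!gene %in% rownames(em)) stop("gene not in expression matrix: ", gene)
  row <- em[gene, , drop = TRUE]
  diffs <- function(cs) {
    missing <- setdiff(c(cs$class1_samples, cs$class2_samples), colnames(em))
    if (length(missing)) {
      stop("replicate(s) missing from expression matrix: ",
           paste(missing, collapse = ", "))
    }
    a <- row[cs$class1_samples]
    b <- row[cs$class2_samples]
    as.vector(t(outer(a, b, "-")))  # class1-major order
  }
  xd <- diffs(spec$axis0)
  yd <- diffs(spec$axis1)
  cbind(x = rep(xd, each = length(yd)), y = rep(yd, times = length(xd)))
}

#' Sum a set of fold-change vectors
#'
#' @param vectors two-column matrix of (x, y) vectors.
#' @param normalize if `TRUE`, each vector is scaled to unit length before
#'   summation (zero vectors are left as zero), so the sum measures pure
#'   directional consistency.
#' @return named numeric vector with `vsum_x`, `vsum_y` and the Euclidean
#'   magnitude `vsum_mag`.
#' @export
vector_sum <- function(vectors, normalize = FALSE) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 1L) stop("vector_sum needs at least one vector")
  if (normalize) {
    r <- sqrt(vectors[, 1L]^2 + vectors[, 2L]^2)
    r[r == 0] <- 1
    vectors <- vectors / r
  }
  x <- sum(vectors[, 1L])
  y <- sum(vectors[, 2L])
  c(vsum_x = x, vsum_y = y, vsum_mag = sqrt(x^2 + y^2))
}

# Summed vectors for many genes at once. X is the expression submatrix
# (genes x involved samples); idx* are column indices of the four class
# slots (axis0 class1/class2, axis1 class1/class2). In the raw mode the
# cross-product sum collapses to a closed form in the group sums; the
# normalized mode materialises all pairs per gene.
vsum_matrix <- function(X, idx0a, idx0b, idx1a, idx1b, normalize = FALSE) {
  n0a <- length(idx0a); n0b <- length(idx0b)
  n1a <- length(idx1a); n1b <- length(idx1b)
  n_x <- n0a * n0b
  n_y <- n1a * n1b
  if (!normalize) {
    sum_x <- n0b * rowSums(X[, idx0a, drop = FALSE]) -
      n0a * rowSums(X[, idx0b, drop = FALSE])
    sum_y <- n1b * rowSums(X[, idx1a, drop = FALSE]) -
      n1a * rowSums(X[, idx1b, drop = FALSE])
    x <- n_y * sum_x
    y <- n_x * sum_y
  } else {
    G <- nrow(X)
    x <- numeric(G)
    y <- numeric(G)
    for (g in seq_len(G)) {
      xd <- as.vector(t(outer(X[g, idx0a], X[g, idx0b], "-")))
      yd <- as.vector(t(outer(X[g, idx1a], X[g, idx1b], "-")))
      vx <- rep(xd, each = n_y)
      vy <- rep(yd, times = n_x)
      r <- sqrt(vx^2 + vy^2)
      r[r == 0] <- 1
      x[g] <- sum(vx / r)
      y[g] <- sum(vy / r)
    }
  }
  cbind(vsum_x = x, vsum_y = y, vsum_mag = sqrt(x^2 + y^2))
}

#' Permutation P-values for summed vectors
#'
#' Builds the null by permuting group labels (the same permutation
#' applied to every gene within a round) and recomputing |Vsum|;
#' `p = (1 + #{permuted |Vsum| >= observed}) / (B + 1)`.
#'
#' With the default `permute = "within_axis"`, labels are permuted
#' independently within each axis's own two-group contrast, so each axis
#' fold change is tested against exchangeability of exactly the samples
#' it is computed from. |Vsum| is invariant to sample order within a
#' class, so the within-axis null has only
#' `choose(2n, n)^2` distinct split combinations (400 at n = 3); when
#' that count is within the budget `B` the null is enumerated exactly
#' and `p = #{split combinations with |Vsum| >= observed} / N`
#' (deterministic, no seed consumed), otherwise `B` random rounds are
#' drawn. The alternative `"across_axes"` permutes all
#' involved samples in one pool; it is retained for comparison but loses
#' power for genes whose four group means span more than one effect step
#' (a cumulative gene's own BB-vs-CC spread, reassigned to a single axis
#' by the permutation, then exceeds the observed |Vsum|).
#'
#' @param em expression matrix.
#' @param spec vector-analysis spec.
#' @param gene_ids genes to test.
#' @param B number of permutations.
#' @param seed integer seed.
#' @param normalize unit-normalize vectors before summation.
#' @param permute label-permutation scheme (see Details).
#' @return data frame with `gene_id`, `vsum_x`, `vsum_y`, `vsum_mag` and
#'   `p_value`.
#' @export
vector_permutation_p <- function(em, spec, gene_ids, B = 1000L, seed = 1L,
                                 normalize = FALSE,
                                 permute = c("within_axis",
                                             "across_axes")) {
  permute <- match.arg(permute)
  stopifnot(inherits(spec, "rpvec_vector_spec"))
  B <- as.integer(B)
  if (B < 1L) stop("B must be at least 1")
  slots <- list(spec$axis0$class1_samples, spec$axis0$class2_samples,
                spec$axis1$class1_samples, spec$axis1$class2_samples)
  samples <- unique(unlist(slots))
  missing <- setdiff(samples, colnames(em))
  if (length(missing)) {
    stop("sample(s) missing from expression matrix: ",
         paste(missing, collapse = ", "))
  }
  absent <- setdiff(gene_ids, rownames(em))
  if (length(absent)) {
    stop("gene(s) missing from expression matrix: ",
         paste(utils::head(absent, 3L), collapse = ", "))
  }
  X <- em[gene_ids, samples, drop = FALSE]
  idx <- lapply(slots, function(s) match(s, samples))
  sizes <- lengths(idx)
  obs <- vsum_matrix(X, idx[[1L]], idx[[2L]], idx[[3L]], idx[[4L]],
                     normalize)
  exceed <- integer(length(gene_ids))
  axis0_cols <- c(idx[[1L]], idx[[2L]])
  axis1_cols <- c(idx[[3L]], idx[[4L]])
  n_combos <- choose(length(axis0_cols), sizes[1L]) *
    choose(length(axis1_cols), sizes[3L])
  exact <- permute == "within_axis" && n_combos <= B

  if (exact) {
    splits0 <- utils::combn(length(axis0_cols), sizes[1L],
                            simplify = FALSE)
    splits1 <- utils::combn(length(axis1_cols), sizes[3L],
                            simplify = FALSE)
    for (s0 in splits0) {
      c0a <- axis0_cols[s0]
      c0b <- axis0_cols[-s0]
      for (s1 in splits1) {
        null <- vsum_matrix(X, c0a, c0b, axis1_cols[s1], axis1_cols[-s1],
                            normalize)
        exceed <- exceed + (null[, "vsum_mag"] >= obs[, "vsum_mag"])
      }
    }
    p_value <- exceed / n_combos
  } else {
    local_seed(seed, {
      for (b in seq_len(B)) {
        if (permute == "within_axis") {
          p0 <- axis0_cols[sample.int(length(axis0_cols))]
          p1 <- axis1_cols[sample.int(length(axis1_cols))]
          pidx <- list(p0[seq_len(sizes[1L])],
                       p0[sizes[1L] + seq_len(sizes[2L])],
                       p1[seq_len(sizes[3L])],
                       p1[sizes[3L] + seq_len(sizes[4L])])
        } else {
          perm <- sample.int(ncol(X))
          ends <- cumsum(sizes)
          starts <- c(1L, utils::head(ends, -1L) + 1L)
          pidx <- lapply(seq_along(slots),
                         function(i) perm[starts[i]:ends[i]])
        }
        null <- vsum_matrix(X, pidx[[1L]], pidx[[2L]], pidx[[3L]],
                            pidx[[4L]], normalize)
        exceed <- exceed + (null[, "vsum_mag"] >= obs[, "vsum_mag"])
      }
    })
    p_value <- (1 + exceed) / (B + 1)
  }
  data.frame(
    gene_id = gene_ids,
    vsum_x = obs[, "vsum_x"],
    vsum_y = obs[, "vsum_y"],
    vsum_mag = obs[, "vsum_mag"],
    p_value = p_value,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Classify summed vectors into behaviour sectors
#'
#' A gene is assigned a directional class only when its summed vector
#' passes both cut-offs (`vsum_mag >= vsum_threshold` and `p_value <=
#' vector_p_threshold`); it is `unchanged` when it fails both
#' (`vsum_mag < vsum_threshold` and `p_value > vector_p_threshold`,
#' i.e. genuinely small and non-significant); and it is `indeterminate`
#' in the mixed zone -- a large vector that misses significance, or a
#' significant but small one -- where the evidence supports neither a
#' response nor its absence. For directional classes
#' the angle `theta = atan2(vsum_y, vsum_x)` falls into one of
#' eight 45-degree sectors centered on the four semi-axes and the four
#' diagonals: near the positive x axis `only0_up` (response in the
#' carrier-only environment alone), the first diagonal `both_up`, the
#' positive y axis `only1_up`, and so on around the plane. Sector
#' boundaries sit at odd multiples of 22.5 degrees and are half-open with
#' ties going to the counterclockwise sector.
#'
#' @param vsum_x,vsum_y summed vector components.
#' @param p_value permutation P-values.
#' @param config run configuration supplying the two cut-offs.
#' @return character vector of class labels.
#' @export
classify_sector <- function(vsum_x, vsum_y, p_value,
                            config = run_config()) {
  mag <- sqrt(vsum_x^2 + vsum_y^2)
  theta <- atan2(vsum_y, vsum_x) * 180 / pi
  sector <- floor(((theta + 22.5) %% 360) / 45) + 1L
  labels <- SECTOR_LABELS[sector]
  small <- mag < config$vsum_threshold
  nonsig <- p_value > config$vector_p_threshold
  labels[small | nonsig] <- "indeterminate"
  labels[small & nonsig] <- "unchanged"
  labels
}

#' Run one complete vector analysis
#'
#' Computes summed vectors, permutation P-values and sector classes for a
#' gene universe (typically from [gene_universe()]).
#'
#' @param em expression matrix.
#' @param ss sample sheet.
#' @param tissue tissue name.
#' @param name which analysis (`"postnatal_response"` or
#'   `"prenatal_response"`).
#' @param gene_ids gene universe to analyse.
#' @param config run configuration.
#' @param permute label-permutation scheme, see [vector_permutation_p()].
#' @return data frame of class `rpvec_vector_result` with one row per
#'   gene: `gene_id`, `vsum_x`, `vsum_y`, `vsum_mag`, `p_value`, `class`,
#'   `n_vectors`.
#' @export
run_vector_analysis <- function(em, ss, tissue, name = VECTOR_ANALYSES,
                                gene_ids, config = run_config(),
                                permute = c("within_axis",
                                            "across_axes")) {
  permute <- match.arg(permute)
  name <- match.arg(name)
  spec <- vector_analysis_spec(name, ss, tissue)
  n_vec <- length(spec$axis0$class1_samples) *
    length(spec$axis0$class2_samples) *
    length(spec$axis1$class1_samples) *
    length(spec$axis1$class2_samples)
  if (length(gene_ids) == 0L) {
    out <- data.frame(gene_id = character(0L), vsum_x = numeric(0L),
                      vsum_y = numeric(0L), vsum_mag = numeric(0L),
                      p_value = numeric(0L), class = character(0L),
                      n_vectors = integer(0L), stringsAsFactors = FALSE)
    class(out) <- c("rpvec_vector_result", class(out))
    attr(out, "analysis") <- name
    return(out)
  }
  seed <- derive_seed(config$seed, 300L + match(name, VECTOR_ANALYSES))
  res <- vector_permutation_p(em, spec, gene_ids,
                              B = config$n_permutations_vector,
                              seed = seed,
                              normalize = config$normalize_vectors,
                              permute = permute)
  res$class <- classify_sector(res$vsum_x, res$vsum_y, res$p_value, config)
  res$n_vectors <- n_vec
  class(res) <- c("rpvec_vector_result", class(res))
  attr(res, "analysis") <- name
  res
}
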