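# Seeded negative-binomial simulator for the 2x2 factorial design
# (pre-natal x post-natal exposure, groups CC/BC/CB/BB), with planted
# category I-IV effects so every downstream stage can be exercised and
# calibrated without external data.

CATEGORIES <- c("I", "II", "III", "IV")

#' Simulation parameters
#'
#' Describes one synthetic experiment: per-gene log2 baseline means drawn
#' from a normal distribution, log-normal per-sample library-size factors,
#' negative-binomial counts, and planted treatment effects of four kinds
#' mirroring the factorial response categories:
#' category I, a common non-additive response (all exposed groups shifted
#' equally); II, a cumulative response (single exposure shifts by delta,
#' double exposure by 2*delta); III, a pre-natal-specific response; and
#' IV, a post-natal-specific response.
#'
#' Defaults emulate a pooled-replicate bulk RNA-seq study: 15,000 genes,
#' 3 biological replicates per group, baseline log2 mean 8 +/- 2 (median
#' gene around 256 expected counts, as in libraries of tens of millions
#' of reads spread over ~15k genes), NB size
#' 20 (squared biological coefficient of variation 0.05: each replicate
#' is a pool of four individuals, which divides individual-level
#' biological variance of ~0.2 by the pool size), library-size spread
#' 0.15 on the natural-log scale, effect size 1.5 log2 units, and 100
#' planted genes per category of which half are up- and half
#' down-regulated.
#'
#' @param n_genes number of genes.
#' @param n_replicates biological replicates per group.
#' @param baseline_logmean_mu,baseline_logmean_sd mean and sd of the
#'   per-gene baseline expression on the log2 scale of expected counts.
#' @param dispersion negative-binomial size (shape) parameter, scalar or
#'   per-gene vector; larger values approach Poisson noise.
#' @param libsize_sd sd of per-sample log library-size factors
#'   (natural-log scale); 0 gives equal library sizes.
#' @param effect_size planted effect delta in log2 units.
#' @param n_per_category named vector giving the number of planted genes in
#'   each of categories I-IV (missing names mean 0).
#' @param sign_fraction_up fraction of planted genes per category that are
#'   up-regulated; the rest are down-regulated.
#' @param seed integer seed making the simulation fully reproducible.
#' @return list of class `rpvec_sim_params`.
#' @export
sim_params <- function(n_genes = 15000L,
                       n_replicates = 3L,
                       baseline_logmean_mu = 8,
                       baseline_logmean_sd = 2,
                       dispersion = 20,
                       libsize_sd = 0.15,
                       effect_size = 1.5,
                       n_per_category = c(I = 100L, II = 100L,
                                          III = 100L, IV = 100L),
                       sign_fraction_up = 0.5,
                       seed = 1L) {
  n_cat <- stats::setNames(integer(4L), CATEGORIES)
  if (length(n_per_category)) {
    if (is.null(names(n_per_category))) {
      stop("n_per_category must be a named vector over categories I-IV")
    }
    bad <- setdiff(names(n_per_category), CATEGORIES)
    if (length(bad)) stop("unknown category in n_per_category: ", bad[1L])
    n_cat[names(n_per_category)] <- as.integer(n_per_category)
  }
  p <- list(
    n_genes = as.integer(n_genes),
    n_replicates = as.integer(n_replicates),
    baseline_logmean_mu = as.numeric(baseline_logmean_mu),
    baseline_logmean_sd = as.numeric(baseline_logmean_sd),
    dispersion = as.numeric(dispersion),
    libsize_sd = as.numeric(libsize_sd),
    effect_size = as.numeric(effect_size),
    n_per_category = n_cat,
    sign_fraction_up = as.numeric(sign_fraction_up),
    seed = as.integer(seed)
  )
  if (p$n_genes < 1L) stop("n_genes must be positive")
  if (p$n_replicates < 1L) stop("n_replicates must be positive")
  if (any(p$dispersion <= 0)) stop("dispersion must be positive")
  if (p$libsize_sd < 0) stop("libsize_sd must be non-negative")
  if (p$effect_size <= 0) stop("effect_size must be positive")
  if (any(p$n_per_category < 0L)) stop("n_per_category must be non-negative")
  if (sum(p$n_per_category) > p$n_genes) {
    stop("sum of planted genes exceeds n_genes")
  }
  if (p$sign_fraction_up < 0 || p$sign_fraction_up > 1) {
    stop("sign_fraction_up must lie in [0, 1]")
  }
  structure(p, class = "rpvec_sim_params")
}

#' Group offsets encoding a planted factorial effect
#'
#' Translates a response category and a sign into the quadruple of log2
#' offsets applied to the four treatment groups (CC, BC, CB, BB). With
#' `s = +delta` (up) or `-delta` (down):
#' category I gives `(0, s, s, s)` (every exposed group shifted equally,
#' no cumulative effect), II gives `(0, s, s, 2s)` (additive/cumulative),
#' III gives `(0, s, 0, s)` (pre-natal exposure only) and IV gives
#' `(0, 0, s, s)` (post-natal exposure only). Category `"none"` gives all
#' zeros.
#'
#' @param category one of `"I"`, `"II"`, `"III"`, `"IV"`, `"none"`.
#' @param sign `"up"` or `"down"` (ignored for `"none"`).
#' @param delta positive effect size in log2 units.
#' @return named numeric vector of offsets over CC, BC, CB, BB.
#' @export
plant_group_effects <- function(category, sign = c("up", "down"), delta = 1) {
  category <- as.character(category)
  if (category == "none") {
    return(stats::setNames(c(0, 0, 0, 0), GROUPS))
  }
  if (!category %in% CATEGORIES) stop("unknown category: ", category)
  sign <- match.arg(sign)
  if (delta <= 0) stop("delta must be positive")
  s <- if (sign == "up") delta else -delta
  offsets <- switch(category,
    I = c(0, s, s, s),
    II = c(0, s, s, 2 * s),
    III = c(0, s, 0, s),
    IV = c(0, 0, s, s)
  )
  stats::setNames(offsets, GROUPS)
}

# Build the truth table (which genes carry which planted effect) from the
# parameters; the gene order is randomized so planted genes are scattered.
build_truth <- function(params, gene_ids) {
  n_planted <- sum(params$n_per_category)
  planted_idx <- if (n_planted > 0L) {
    sample.int(params$n_genes, n_planted)
  } else {
    integer(0L)
  }
  category <- rep("none", params$n_genes)
  sign <- rep("n/a", params$n_genes)
  effect <- rep(0, params$n_genes)
  pos <- 0L
  for (cat in CATEGORIES) {
    k <- params$n_per_category[[cat]]
    if (k == 0L) next
    idx <- planted_idx[pos + seq_len(k)]
    pos <- pos + k
    n_up <- round(k * params$sign_fraction_up)
    category[idx] <- cat
    sign[idx] <- c(rep("up", n_up), rep("down", k - n_up))
    effect[idx] <- params$effect_size
  }
  data.frame(
    gene_id = gene_ids,
    category = category,
    sign = sign,
    effect_size = effect,
    stringsAsFactors = FALSE
  )
}

#' Simulate counts for one tissue
#'
#' Draws counts `NB(mean = s_j * 2^(m_g + offset_{group(j),g}), size =
#' dispersion)` where `m_g ~ Normal(baseline_logmean_mu,
#' baseline_logmean_sd)` is the per-gene baseline and `s_j ~
#' logNormal(0, libsize_sd)` is the per-sample library-size factor.
#' Group offsets come from [plant_group_effects()] according to the truth
#' table drawn from `n_per_category`. Fully reproducible from the seed.
#'
#' @param params simulation parameters from [sim_params()].
#' @param tissue tissue label written into the sample sheet; also offsets
#'   the random stream so the two tissues are generated independently.
#' @param truth optional pre-built truth table (as returned in a previous
#'   simulation) to reuse the same planted genes; default draws a new one.
#' @return list of class `rpvec_simulation` with elements `counts`
#'   (integer matrix), `samples` (sample sheet), `truth` (gene_id,
#'   category, sign, effect_size) and `params`.
#' @export
simulate_counts <- function(params, tissue = "hippocampus", truth = NULL) {
  stopifnot(inherits(params, "rpvec_sim_params"))
  tissue <- match.arg(tissue, TISSUES)
  G <- params$n_genes
  n <- params$n_replicates
  gene_ids <- sprintf("gene%05d", seq_len(G))
  seed <- derive_seed(params$seed, match(tissue, TISSUES) * 1000L)

  sim <- local_seed(seed, {
    if (is.null(truth)) truth <- build_truth(params, gene_ids)
    m_g <- stats::rnorm(G, params$baseline_logmean_mu,
                        params$baseline_logmean_sd)
    s_j <- exp(stats::rnorm(4L * n, 0, params$libsize_sd))
    offsets <- matrix(0, nrow = G, ncol = 4L, dimnames = list(NULL, GROUPS))
    planted <- which(truth$category != "none")
    for (i in planted) {
      offsets[i, ] <- plant_group_effects(truth$category[i], truth$sign[i],
                                          truth$effect_size[i])
    }
    size <- rep_len(params$dispersion, G)
    counts <- matrix(0L, nrow = G, ncol = 4L * n)
    j <- 0L
    for (g in seq_along(GROUPS)) {
      for (r in seq_len(n)) {
        j <- j + 1L
        mu <- s_j[j] * 2^(m_g + offsets[, g])
        counts[, j] <- stats::rnbinom(G, mu = mu, size = size)
      }
    }
    list(counts = counts, truth = truth)
  })

  prefix <- substr(tissue, 1L, 4L)
  group <- rep(GROUPS, each = n)
  replicate <- rep(seq_len(n), times = 4L)
  sample_ids <- sprintf("%s_%s_%d", prefix, group, replicate)
  dimnames(sim$counts) <- list(gene_ids, sample_ids)
  samples <- sample_sheet(data.frame(
    sample_id = sample_ids,
    tissue = tissue,
    prenatal = substr(group, 1L, 1L),
    postnatal = substr(group, 2L, 2L),
    replicate = replicate,
    stringsAsFactors = FALSE
  ))
  structure(
    list(counts = count_matrix(sim$counts), samples = samples,
         truth = sim$truth, params = params),
    class = "rpvec_simulation"
  )
}

#' Simulate a full two-tissue experiment
#'
#' Runs [simulate_counts()] once per tissue with independent random
#' streams (independent baselines, library sizes and noise) and binds the
#' results into a single count matrix and sample sheet. The planted truth
#' (which genes carry which category effect) is shared across tissues so
#' each tissue's recovery can be scored against the same table.
#'
#' @param params simulation parameters from [sim_params()].
#' @param tissues tissues to simulate.
#' @return list of class `rpvec_simulation` with combined `counts`,
#'   `samples`, the shared `truth` and `params`.
#' @export
simulate_experiment <- function(params, tissues = TISSUES) {
  tissues <- match.arg(tissues, TISSUES, several.ok = TRUE)
  first <- simulate_counts(params, tissues[1L])
  sims <- list(first)
  for (t in tissues[-1L]) {
    sims <- c(sims, list(simulate_counts(params, t, truth = first$truth)))
  }
  counts <- do.call(cbind, lapply(sims, `[[`, "counts"))
  samples <- do.call(rbind, lapply(sims, `[[`, "samples"))
  structure(
    list(counts = count_matrix(counts), samples = sample_sheet(samples),
         truth = first$truth, params = params),
    class = "rpvec_simulation"
  )
}

#' Write a simulation to an output directory
#'
#' Writes `counts.tsv`, `samples.tsv` and `truth.tsv`.
#'
#' @param sim simulation from [simulate_counts()] or
#'   [simulate_experiment()].
#' @param outdir output directory (created if needed).
#' @return named character vector of the written paths, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "rpvec_simulation"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = file.path(outdir, "counts.tsv"),
    samples = file.path(outdir, "samples.tsv"),
    truth = file.path(outdir, "truth.tsv")
  )
  write_count_matrix(sim$counts, paths[["counts"]])
  write_sample_sheet(sim$samples, paths[["samples"]])
  utils::write.table(sim$truth, paths[["truth"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}
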