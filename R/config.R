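# Run configuration: analysis thresholds, permutation counts and the master
# seed, with defaults matching the published workflow cut-offs.

#' Create a run configuration
#'
#' Bundles all tunable analysis parameters. Defaults follow the published
#' workflow this pipeline implements: FDR (percentage of false positives)
#' cut-off 0.10 for the RankProducts stage, vector-analysis cut-offs
#' |Vsum| >= 40 and P <= 0.05, 1000 permutations for both permutation
#' tests, a log2(x + 32) transform and 75th-percentile normalization.
#'
#' @param fdr_threshold pfp cut-off declaring a gene significant in a
#'   contrast (fraction in (0, 1)).
#' @param vsum_threshold minimum summed-vector magnitude |Vsum| for a gene
#'   to be classified as changed (log2-fold-change units summed over all
#'   between-replicate comparisons).
#' @param vector_p_threshold permutation P cut-off for the vector analysis.
#' @param n_permutations_rp number of rank randomizations for the
#'   RankProducts null.
#' @param n_permutations_vector number of group-label permutations for the
#'   vector-analysis null.
#' @param log_offset pseudo-count added before the log2 transform.
#' @param quantile quantile of the nonzero count distribution used for
#'   normalization (0.75 = upper quartile).
#' @param normalize_vectors if `TRUE`, unit-normalize each fold-change
#'   vector before summation (so |Vsum| measures pure directional
#'   consistency); default `FALSE` keeps raw magnitudes.
#' @param seed master integer seed; per-stage streams are derived from it.
#' @return list of class `rpvec_config`.
#' @export
run_config <- function(fdr_threshold = 0.10,
                       vsum_threshold = 40,
                       vector_p_threshold = 0.05,
                       n_permutations_rp = 1000L,
                       n_permutations_vector = 1000L,
                       log_offset = 32,
                       quantile = 0.75,
                       normalize_vectors = FALSE,
                       seed = 1L) {
  cfg <- list(
    fdr_threshold = as.numeric(fdr_threshold),
    vsum_threshold = as.numeric(vsum_threshold),
    vector_p_threshold = as.numeric(vector_p_threshold),
    n_permutations_rp = as.integer(n_permutations_rp),
    n_permutations_vector = as.integer(n_permutations_vector),
    log_offset = as.numeric(log_offset),
    quantile = as.numeric(quantile),
    normalize_vectors = isTRUE(normalize_vectors),
    seed = as.integer(seed)
  )
  if (!(cfg$fdr_threshold > 0 && cfg$fdr_threshold < 1)) {
    stop("fdr_threshold must lie in (0, 1)")
  }
  if (!(cfg$vector_p_threshold > 0 && cfg$vector_p_threshold < 1)) {
    stop("vector_p_threshold must lie in (0, 1)")
  }
  if (!(cfg$quantile > 0 && cfg$quantile < 1)) {
    stop("quantile must lie in (0, 1)")
  }
  if (cfg$vsum_threshold < 0) stop("vsum_threshold must be non-negative")
  if (cfg$n_permutations_rp < 1L || cfg$n_permutations_vector < 1L) {
    stop("permutation counts must be positive")
  }
  if (cfg$log_offset <= 0) stop("log_offset must be positive")
  structure(cfg, class = "rpvec_config")
}

#' Read a run configuration from a JSON or YAML file
#'
#' Every field is optional; unspecified fields take the [run_config()]
#' defaults. Arguments passed through `...` override file values (used by
#' the command-line wrapper to let flags win over the config file).
#'
#' @param path path to a `.json`, `.yaml` or `.yml` file.
#' @param ... overrides forwarded to [run_config()].
#' @return list of class `rpvec_config`.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  vals <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yaml = ,
    yml = yaml::read_yaml(path),
    stop("unsupported config format: .", ext, " (use JSON or YAML)")
  )
  if (is.null(vals)) vals <- list()
  known <- names(formals(run_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  do.call(run_config, vals)
}
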