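# End-to-end orchestration: simulate (or load) counts, normalize, run the
# six RankProducts contrasts, the two vector analyses and the category
# assignment per tissue, writing every stage's tables plus a manifest.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Either simulates a synthetic experiment (when `counts` is `NULL`) or
#' consumes a count matrix and sample sheet, then runs, per tissue:
#' upper-quartile normalization and the log2 transform, PCA QC, the six
#' RankProducts contrasts with their significant-count summary, the two
#' vector analyses on the filtered gene universe, and the category
#' assignment with its count summary (plus a planted-truth confusion
#' matrix when truth is available). All randomness derives from
#' `config$seed`, so a rerun with the same configuration reproduces every
#' output file byte for byte.
#'
#' @param outdir output directory (created if needed).
#' @param config run configuration from [run_config()].
#' @param counts count matrix, or path to a counts TSV, or `NULL` to
#'   simulate.
#' @param samples sample sheet, or path to a samples TSV (required when
#'   `counts` is given).
#' @param sim_parameters [sim_params()] used when simulating; defaults to
#'   `sim_params(seed = config$seed)`.
#' @param truth optional truth table (data frame or TSV path) for
#'   confusion reporting when `counts` is supplied from a synthetic file.
#' @param tissues tissues to analyse; default, all tissues in the sample
#'   sheet.
#' @return the manifest, invisibly: configuration snapshot, seeds,
#'   per-file md5 checksums, stage timings and package version.
#' @export
run_all <- function(outdir, config = run_config(), counts = NULL,
                    samples = NULL, sim_parameters = NULL, truth = NULL,
                    tissues = NULL) {
  outdir <- sub("/+$", "", outdir)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- expr
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  files <- character(0L)
  add_file <- function(path) files <<- c(files, path)

  if (is.null(counts)) {
    params <- sim_parameters %||% sim_params(seed = config$seed)
    sim <- clock("simulate", simulate_experiment(params))
    cm <- sim$counts
    ss <- sim$samples
    truth <- sim$truth
    for (p in write_simulation(sim, outdir)) add_file(p)
  } else {
    if (is.character(counts)) counts <- read_count_matrix(counts)
    if (is.null(samples)) stop("samples must accompany counts")
    if (is.character(samples)) samples <- read_sample_sheet(samples)
    if (is.character(truth)) {
      truth <- utils::read.delim(truth, stringsAsFactors = FALSE)
    }
    cm <- count_matrix(counts)
    ss <- pair_inputs(cm, sample_sheet(samples))
  }

  tissues <- tissues %||% unique(ss$tissue)
  for (tissue in tissues) {
    tdir <- file.path(outdir, tissue)
    dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
    sub_ss <- ss[ss$tissue == tissue, , drop = FALSE]
    sub_cm <- cm[, sub_ss$sample_id, drop = FALSE]

    em <- clock(paste0(tissue, ".normalize"), expression_matrix(sub_cm, config))
    add_file(write_count_matrix(round(em, 6), file.path(tdir, "expr.tsv")))

    pca <- clock(paste0(tissue, ".pca"),
                 pca_qc(em, min(3L, ncol(em) - 1L)))
    pca_df <- data.frame(sample_id = rownames(pca$coordinates),
                         round(pca$coordinates, 6),
                         check.names = FALSE, stringsAsFactors = FALSE)
    add_file(write_tsv(pca_df, file.path(tdir, "pca.tsv")))
    add_file(write_tsv(
      data.frame(component = colnames(pca$coordinates),
                 variance_explained = round(pca$variance_explained, 6)),
      file.path(tdir, "pca_variance.tsv")))

    six <- clock(paste0(tissue, ".rankprod"),
                 six_contrasts(em, sub_ss, tissue, config))
    for (nm in names(six$contrasts)) {
      res <- six$contrasts[[nm]]
      tab <- rbind(res$up, res$down)
      num <- vapply(tab, is.numeric, logical(1L))
      tab[num] <- lapply(tab[num], function(x) round(x, 6))
      add_file(write_tsv(tab, file.path(tdir, paste0("contrast_", nm, ".tsv"))))
    }
    add_file(write_tsv(six$summary, file.path(tdir, "summary_table1.tsv")))

    universe <- gene_universe(six, config)
    vres <- clock(paste0(tissue, ".vectors"), {
      lapply(stats::setNames(VECTOR_ANALYSES, VECTOR_ANALYSES),
             function(nm) run_vector_analysis(em, sub_ss, tissue, nm,
                                              universe, config))
    })
    for (nm in VECTOR_ANALYSES) {
      tab <- vres[[nm]]
      num <- vapply(tab, is.numeric, logical(1L))
      tab[num] <- lapply(tab[num], function(x) round(x, 6))
      short <- sub("_response$", "", nm)
      add_file(write_tsv(tab, file.path(tdir, paste0("vectors_", short, ".tsv"))))
    }

    cats <- clock(paste0(tissue, ".categories"),
                  categorize_tissue(vres$postnatal_response,
                                    vres$prenatal_response, tissue))
    add_file(write_tsv(cats$assignments, file.path(tdir, "assignments.tsv")))
    add_file(write_tsv(
      data.frame(category = names(cats$summary),
                 n_genes = as.integer(cats$summary)),
      file.path(tdir, "summary_table2.tsv")))

    if (!is.null(truth)) {
      conf <- truth_confusion(cats$assignments, truth,
                              all_genes = rownames(cm))
      conf_df <- data.frame(planted = rownames(conf), conf,
                            check.names = FALSE, stringsAsFactors = FALSE)
      add_file(write_tsv(conf_df, file.path(tdir, "confusion.tsv")))
    }
  }

  manifest <- list(
    package = "rpvec",
    version = as.character(utils::packageVersion("rpvec")),
    config = unclass(config),
    seed = config$seed,
    tissues = tissues,
    files = {
      sums <- tools::md5sum(files)
      names(sums) <- substring(names(sums), nchar(outdir) + 2L)
      as.list(sums)
    },
    timings = timings
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}
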