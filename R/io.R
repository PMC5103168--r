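# Readers, writers and validators for the package's tabular inputs:
# gene x sample count matrices and factorial sample sheets, both plain TSV.

TISSUES <- c("hippocampus", "hypothalamus")
TREATMENTS <- c("C", "B")
GROUPS <- c("CC", "BC", "CB", "BB")

#' Validate a count matrix
#'
#' Checks that `counts` is a numeric matrix of non-negative integral values
#' with unique, non-empty gene (row) and sample (column) identifiers.
#'
#' @param counts numeric matrix, genes in rows, samples in columns, with
#'   `rownames` (gene ids) and `colnames` (sample ids).
#' @return the validated matrix, in integer storage mode, invisibly usable
#'   as the package's canonical count container.
#' @export
count_matrix <- function(counts) {
  if (!is.matrix(counts)) stop("counts must be a matrix")
  gene_ids <- rownames(counts)
  sample_ids <- colnames(counts)
  if (is.null(gene_ids) || any(!nzchar(gene_ids))) {
    stop("count matrix must have non-empty gene ids as rownames")
  }
  if (is.null(sample_ids) || any(!nzchar(sample_ids))) {
    stop("count matrix must have non-empty sample ids as colnames")
  }
  dup <- gene_ids[duplicated(gene_ids)]
  if (length(dup)) stop("duplicate gene id: ", dup[1L])
  dup <- sample_ids[duplicated(sample_ids)]
  if (length(dup)) stop("duplicate sample id: ", dup[1L])
  if (!is.numeric(counts)) stop("counts must be numeric")
  bad <- which(is.na(counts) | counts < 0 | counts %% 1 != 0)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(counts))
    stop(sprintf(
      "invalid count at gene '%s', sample '%s': must be a non-negative integer",
      gene_ids[i[1L]], sample_ids[i[2L]]
    ))
  }
  storage.mode(counts) <- "integer"
  counts
}

#' Read a count matrix from a TSV file
#'
#' The canonical format is tab-separated UTF-8 text with a header row of
#' sample identifiers and gene identifiers in the first column, as written
#' by standard read-counting tools. Row and column order are preserved.
#'
#' @param path path to the TSV file.
#' @return validated integer matrix (genes x samples) with dimnames.
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "")
  if (ncol(df) < 2L) stop("count matrix must have at least one sample column")
  gene_ids <- df[[1L]]
  sample_ids <- colnames(df)[-1L]
  body <- as.matrix(df[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(body), nrow = nrow(body)))
  bad <- which(is.na(num) | num < 0 | num %% 1 != 0)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(num))
    stop(sprintf(
      "invalid count '%s' at gene '%s', sample '%s' (row %d, column %d)",
      body[bad[1L]], gene_ids[i[1L]], sample_ids[i[2L]], i[1L], i[2L]
    ))
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  count_matrix(num)
}

#' Write a count matrix to a TSV file
#'
#' @param cm count matrix as returned by [count_matrix()].
#' @param path destination path.
#' @param id_column name used for the gene-id column header.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(cm, path, id_column = "gene_id") {
  df <- data.frame(rownames(cm), cm, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a sample sheet
#'
#' A sample sheet is a data frame with columns `sample_id`, `tissue`
#' (`hippocampus` or `hypothalamus`), `prenatal` and `postnatal` (each `C`
#' for carrier control or `B` for corticosterone) and a positive integer
#' `replicate`. The treatment group is always derived, never stored:
#' `group = paste0(prenatal, postnatal)`, one of CC, BC, CB, BB.
#'
#' @param ss data frame with the columns above.
#' @return validated data frame with character columns and an integer
#'   `replicate` column.
#' @export
sample_sheet <- function(ss) {
  required <- c("sample_id", "tissue", "prenatal", "postnatal", "replicate")
  missing <- setdiff(required, colnames(ss))
  if (length(missing)) {
    stop("sample sheet is missing column(s): ", paste(missing, collapse = ", "))
  }
  ss <- as.data.frame(ss, stringsAsFactors = FALSE)
  ss$sample_id <- as.character(ss$sample_id)
  ss$tissue <- as.character(ss$tissue)
  ss$prenatal <- as.character(ss$prenatal)
  ss$postnatal <- as.character(ss$postnatal)
  if (any(duplicated(ss$sample_id))) {
    stop("duplicate sample_id: ", ss$sample_id[duplicated(ss$sample_id)][1L])
  }
  bad <- setdiff(unique(ss$tissue), TISSUES)
  if (length(bad)) stop("unknown tissue: ", bad[1L])
  bad <- setdiff(unique(ss$prenatal), TREATMENTS)
  if (length(bad)) stop("unknown prenatal treatment: ", bad[1L])
  bad <- setdiff(unique(ss$postnatal), TREATMENTS)
  if (length(bad)) stop("unknown postnatal treatment: ", bad[1L])
  rep_num <- suppressWarnings(as.numeric(ss$replicate))
  if (any(is.na(rep_num) | rep_num < 1 | rep_num %% 1 != 0)) {
    stop("replicate must be a positive integer")
  }
  ss$replicate <- as.integer(rep_num)
  rownames(ss) <- NULL
  ss[required]
}

#' Derive treatment group labels from a sample sheet
#'
#' @param ss validated sample sheet.
#' @return character vector of group labels (CC/BC/CB/BB), one per row.
#' @export
sample_groups <- function(ss) paste0(ss$prenatal, ss$postnatal)

#' Read a sample sheet from a TSV file
#'
#' @param path path to the TSV file.
#' @return validated sample sheet (see [sample_sheet()]).
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character",
                          quote = "")
  sample_sheet(df)
}

#' Write a sample sheet to a TSV file
#'
#' @param ss validated sample sheet.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(ss, path) {
  utils::write.table(ss, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pair a count matrix with a sample sheet
#'
#' Validates that the sample sheet describes exactly the samples present in
#' the count matrix.
#'
#' @param cm count matrix.
#' @param ss sample sheet.
#' @return the sample sheet reordered to match the matrix columns.
#' @export
pair_inputs <- function(cm, ss) {
  extra <- setdiff(ss$sample_id, colnames(cm))
  absent <- setdiff(colnames(cm), ss$sample_id)
  if (length(extra) || length(absent)) {
    stop("sample sheet and count matrix disagree on samples; ",
         if (length(extra)) paste0("not in matrix: ",
                                   paste(extra, collapse = ", "), "; ") else "",
         if (length(absent)) paste0("not in sheet: ",
                                    paste(absent, collapse = ", ")) else "")
  }
  ss[match(colnames(cm), ss$sample_id), , drop = FALSE]
}

#' Summarise the factorial design for one tissue
#'
#' Reports which of the four treatment groups are present and how many
#' replicates each has, and flags groups with fewer than two replicates
#' (the permutation machinery needs at least two).
#'
#' @param cm count matrix.
#' @param ss sample sheet paired with `cm`.
#' @param tissue tissue to summarise.
#' @return list with `tissue`, `replicates` (named integer vector over
#'   CC/BC/CB/BB; absent groups are 0), `missing_groups` and
#'   `low_replicate_groups` character vectors.
#' @export
validate_design <- function(cm, ss, tissue) {
  tissue <- match.arg(tissue, TISSUES)
  ss <- pair_inputs(cm, ss)
  sub <- ss[ss$tissue == tissue, , drop = FALSE]
  if (nrow(sub) == 0L) stop("no samples for tissue: ", tissue)
  grp <- sample_groups(sub)
  n <- vapply(GROUPS, function(g) sum(grp == g), integer(1L))
  list(
    tissue = tissue,
    replicates = n,
    missing_groups = GROUPS[n == 0L],
    low_replicate_groups = GROUPS[n > 0L & n < 2L]
  )
}

#' Sample ids for one tissue/group cell of the design
#'
#' @param ss sample sheet.
#' @param tissue tissue name.
#' @param group group label (CC/BC/CB/BB).
#' @return character vector of sample ids, ordered by replicate index.
#' @export
group_samples <- function(ss, tissue, group) {
  tissue <- match.arg(tissue, TISSUES)
  group <- match.arg(group, GROUPS)
  sub <- ss[ss$tissue == tissue & sample_groups(ss) == group, , drop = FALSE]
  if (nrow(sub) == 0L) {
    stop(sprintf("group %s absent for tissue %s", group, tissue))
  }
  sub$sample_id[order(sub$replicate)]
}
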