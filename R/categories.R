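# Combine the two vector analyses into the four factorial response
# categories: I common non-additive response, II cumulative/additive
# response, III pre-natal-specific, IV post-natal-specific.

CATEGORY_LEVELS <- c("I", "II", "III", "IV", "none")

#' Default class-combination rules for category assignment
#'
#' Each row maps a pair of sector classes -- from the postnatal-response
#' and prenatal-response analyses respectively -- to a category and sign.
#' The logic follows the category definitions: a category-I gene (every
#' exposed group shifted equally, no cumulative effect) responds to each
#' exposure only in the carrier-only other-stage environment, hence
#' `only0` in both analyses; a category-II gene (cumulative) responds in
#' both environments of both analyses (`both`/`both`); category III
#' responds to the pre-natal exposure only (`unchanged`/`both`); category
#' IV to the post-natal exposure only (`both`/`unchanged`). Any pair not
#' listed -- mixed signs, `opposite_*`, `only1_*` (a response present only
#' in the already-exposed environment, which no category claims), or
#' `unchanged`/`unchanged` -- maps to `none`. The table is data, not
#' code: pass an edited copy to [assign_category()] to change the rules.
#'
#' @return data frame with columns `class_postnatal`, `class_prenatal`,
#'   `category`, `sign`.
#' @export
default_category_rules <- function() {
  rules <- rbind(
    c("only0_up", "only0_up", "I", "up"),
    c("only0_down", "only0_down", "I", "down"),
    c("both_up", "both_up", "II", "up"),
    c("both_down", "both_down", "II", "down"),
    c("unchanged", "both_up", "III", "up"),
    c("unchanged", "both_down", "III", "down"),
    c("both_up", "unchanged", "IV", "up"),
    c("both_down", "unchanged", "IV", "down")
  )
  stats::setNames(as.data.frame(rules, stringsAsFactors = FALSE),
                  c("class_postnatal", "class_prenatal", "category", "sign"))
}

#' Assign factorial categories from sector-class pairs
#'
#' Pure, total and vectorised: every (postnatal class, prenatal class)
#' pair maps to exactly one of categories I-IV with a sign, or to
#' (`none`, `n/a`).
#'
#' @param cls_post sector classes from the postnatal-response analysis.
#' @param cls_pre sector classes from the prenatal-response analysis.
#' @param rules rules table, by default [default_category_rules()].
#' @return data frame with columns `category` and `sign`.
#' @export
assign_category <- function(cls_post, cls_pre,
                            rules = default_category_rules()) {
  cls_post <- as.character(cls_post)
  cls_pre <- as.character(cls_pre)
  if (length(cls_post) != length(cls_pre)) {
    stop("class vectors must have equal length")
  }
  bad <- setdiff(unique(c(cls_post, cls_pre)), CLASS_LABELS)
  if (length(bad)) stop("unknown class label: ", bad[1L])
  key <- paste(cls_post, cls_pre, sep = "|")
  rule_key <- paste(rules$class_postnatal, rules$class_prenatal, sep = "|")
  hit <- match(key, rule_key)
  data.frame(
    category = ifelse(is.na(hit), "none", rules$category[hit]),
    sign = ifelse(is.na(hit), "n/a", rules$sign[hit]),
    stringsAsFactors = FALSE
  )
}

#' Categorise the gene universe of one tissue
#'
#' Joins the two vector-analysis results (which must cover the same gene
#' universe), assigns each gene a category, and tabulates the counts per
#' category.
#'
#' @param post result of [run_vector_analysis()] for
#'   `"postnatal_response"`.
#' @param pre result of [run_vector_analysis()] for `"prenatal_response"`.
#' @param tissue tissue label recorded in the output.
#' @param rules rules table for [assign_category()].
#' @return list of class `rpvec_categories` with `assignments` (gene_id,
#'   tissue, category, sign, class_postnatal, class_prenatal) and
#'   `summary` (named integer counts over categories I-IV).
#' @export
categorize_tissue <- function(post, pre, tissue,
                              rules = default_category_rules()) {
  if (!setequal(post$gene_id, pre$gene_id) ||
      nrow(post) != nrow(pre)) {
    stop("the two vector analyses cover different gene universes")
  }
  pre <- pre[match(post$gene_id, pre$gene_id), , drop = FALSE]
  assigned <- assign_category(post$class, pre$class, rules)
  assignments <- data.frame(
    gene_id = post$gene_id,
    tissue = tissue,
    category = assigned$category,
    sign = assigned$sign,
    class_postnatal = post$class,
    class_prenatal = pre$class,
    stringsAsFactors = FALSE
  )
  counts <- vapply(c("I", "II", "III", "IV"),
                   function(k) sum(assignments$category == k), integer(1L))
  list(assignments = assignments, summary = counts) |>
    structure(class = "rpvec_categories")
}

#' Confusion matrix of planted versus assigned categories
#'
#' For synthetic runs: rows are the planted categories from the truth
#' table, columns the assigned categories plus a `not_in_universe` column
#' for genes that never passed the RankProducts filter. Row sums equal the
#' planted counts.
#'
#' @param assignments assignment data frame from [categorize_tissue()].
#' @param truth truth table from the simulator (gene_id, category, sign,
#'   effect_size); genes absent from it count as planted `none`.
#' @param all_genes optional complete gene-id vector; defaults to the
#'   truth table's genes.
#' @return integer matrix, planted x assigned.
#' @export
truth_confusion <- function(assignments, truth, all_genes = truth$gene_id) {
  planted <- rep("none", length(all_genes))
  hit <- match(all_genes, truth$gene_id)
  planted[!is.na(hit)] <- truth$category[hit[!is.na(hit)]]
  assigned <- rep("not_in_universe", length(all_genes))
  in_univ <- match(all_genes, assignments$gene_id)
  assigned[!is.na(in_univ)] <- assignments$category[in_univ[!is.na(in_univ)]]
  tab <- table(
    factor(planted, levels = CATEGORY_LEVELS),
    factor(assigned, levels = c(CATEGORY_LEVELS, "not_in_universe"))
  )
  m <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  names(dimnames(m)) <- c("planted", "assigned")
  m
}
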