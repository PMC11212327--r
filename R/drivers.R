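# Driver curation: canonical cancer-gene mutations distilled from the F2
# set (pathogenic amino-acid changes in oncogenes, truncating mutations in
# tumor suppressors), plus gene-level association tests.

TRUNCATING <- c("stop_gain", "splice", "frameshift")

#' Curate canonical cancer-gene (driver) mutations
#'
#' Keeps exactly the variants satisfying one of two rationales:
#' `oncogene_pathogenic` (gene role oncogene or both, with a pathogenic
#' amino-acid change, non-synonymous) or `tsg_truncating` (gene role tsg or
#' both, with a truncating consequence: stop-gain, splice or frameshift).
#' Genes absent from the role table count as role `none` and are excluded.
#'
#' @param f2_variants annotated variant data.frame (typically the F2 subset
#'   of a [categorize()] result) with tumor_id, gene, consequence,
#'   gene_role, pathogenic_aa_change and key columns.
#' @param gene_role_table optional data.frame with `gene` and `gene_role`
#'   overriding the per-variant roles; if NULL the variant annotations are
#'   used directly.
#' @return data.frame of driver calls: tumor_id, gene, consequence,
#'   rationale, key.
#' @export
curate_drivers <- function(f2_variants, gene_role_table = NULL) {
  v <- f2_variants
  role <- if (!is.null(gene_role_table)) {
    idx <- match(v$gene, gene_role_table$gene)
    miss <- sum(is.na(idx))
    if (miss > 0) {
      message("curate_drivers: ", miss,
              " variants in genes absent from the role table (excluded)")
    }
    r <- gene_role_table$gene_role[idx]
    r[is.na(r)] <- "none"
    r
  } else {
    v$gene_role
  }
  onc <- role %in% c("oncogene", "both") & v$pathogenic_aa_change &
    v$consequence != "synonymous"
  tsg <- role %in% c("tsg", "both") & v$consequence %in% TRUNCATING
  keep <- onc | tsg
  rationale <- ifelse(tsg, "tsg_truncating", "oncogene_pathogenic")
  out <- data.frame(tumor_id = v$tumor_id[keep], gene = v$gene[keep],
                    consequence = v$consequence[keep],
                    rationale = rationale[keep], key = v$key[keep],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Gene x tumor mutation matrix and prevalence
#'
#' @param driver_calls data.frame from [curate_drivers()].
#' @param tumor_ids full cohort tumor ids (the prevalence denominator).
#' @return list with `matrix` (binary gene x tumor, rows sorted by
#'   descending prevalence) and `prevalence` (named numeric).
#' @export
mutation_matrix <- function(driver_calls, tumor_ids) {
  genes <- unique(driver_calls$gene)
  m <- matrix(0L, nrow = length(genes), ncol = length(tumor_ids),
              dimnames = list(genes, tumor_ids))
  if (nrow(driver_calls) > 0) {
    ok <- driver_calls$tumor_id %in% tumor_ids
    m[cbind(match(driver_calls$gene[ok], genes),
            match(driver_calls$tumor_id[ok], tumor_ids))] <- 1L
  }
  prev <- rowSums(m) / max(length(tumor_ids), 1L)
  if (nrow(m) > 0) {
    ord <- order(-prev, rownames(m))
    m <- m[ord, , drop = FALSE]
    prev <- prev[ord]
  }
  list(matrix = m, prevalence = prev)
}

#' Mutual-exclusivity test for two gene mutation sets
#'
#' Two-sided Fisher's exact test on the 2x2 co-occurrence table of two
#' genes across the cohort. An odds ratio of 0 indicates perfect
#' exclusivity; Inf perfect co-occurrence.
#'
#' @param gene_a_tumors,gene_b_tumors vectors of tumor ids mutated in each
#'   gene.
#' @param n_tumors cohort size; must be at least the size of the union.
#' @return list with `odds_ratio` (conditional MLE from the exact test),
#'   `p_value` and `table`.
#' @export
mutual_exclusivity_test <- function(gene_a_tumors, gene_b_tumors, n_tumors) {
  a <- unique(gene_a_tumors)
  b <- unique(gene_b_tumors)
  if (n_tumors < length(union(a, b))) {
    stop("mutual_exclusivity_test: n_tumors smaller than the union of ",
         "mutated tumors", call. = FALSE)
  }
  n11 <- length(intersect(a, b))
  n10 <- length(setdiff(a, b))
  n01 <- length(setdiff(b, a))
  n00 <- n_tumors - n11 - n10 - n01
  tab <- matrix(c(n11, n10, n01, n00), nrow = 2,
                dimnames = list(gene_a = c("mut", "wt"),
                                gene_b = c("mut", "wt")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value, table = tab)
}

#' Mutation-outcome association (chi-squared)
#'
#' Pearson chi-squared on the 2x2 table of mutation status versus a binary
#' outcome, without continuity correction by default (a flag enables the
#' Yates correction). Tables with a zero margin are rejected.
#'
#' @param mutation_status logical/binary vector per patient.
#' @param outcome_labels binary vector per patient (e.g. recurrence).
#' @param correct apply the Yates continuity correction.
#' @return list with `chi_squared`, `p_value`, `table` and `expected`.
#' @export
mutation_outcome_association <- function(mutation_status, outcome_labels,
                                         correct = FALSE) {
  tab <- table(factor(as.integer(as.logical(mutation_status)),
                      levels = c(0, 1)),
               factor(as.integer(as.logical(outcome_labels)),
                      levels = c(0, 1)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("mutation_outcome_association: table has a zero margin; ",
         "the chi-squared test is undefined", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(chi_squared = unname(ct$statistic), p_value = ct$p.value,
       table = tab, expected = ct$expected)
}
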