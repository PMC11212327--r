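# End-to-end orchestration: read a cohort directory (as written by
# simulate_cohort), run consensus filtering, driver curation, clonal
# reconstruction, transcriptomic subtyping and survival association, and
# write deterministic per-stage outputs.

#' Run the full analysis pipeline on a cohort directory
#'
#' @param cohort_dir directory produced by [simulate_cohort()] (three
#'   caller VCFs per tumor under `vcf/`, `vcf/pooled_normal.vcf`,
#'   `annotations.tsv`, `counts.tsv`, `clinical.tsv`, `signatures.gmt`,
#'   `cell_markers.gmt`).
#' @param out_dir output directory for stage results; NULL to skip writing.
#' @param seed integer seed for the stochastic stages (CCF clustering, NMF,
#'   SAM permutations).
#' @param vaf_threshold strand VAF threshold for F1/F2.
#' @param target_mb TMB denominator in Mb.
#' @param ranks,n_restarts,n_top,n_perm subtyping stage controls (see
#'   [subtype_pipeline()]).
#' @param max_k maximum CCF cluster count per tumor.
#' @param min_clonal_variants minimum retained variants for clonal
#'   reconstruction of a tumor.
#' @return list with `consensus` (per tumor), `tmb`, `drivers`,
#'   `driver_matrix`, `exclusivity`, `clonal` (per tumor), `branched_fraction`,
#'   `subtyping`, `survival_rfs`, `survival_os` and `summary`.
#' @export
run_pipeline <- function(cohort_dir, out_dir = NULL, seed = 1L,
                         vaf_threshold = 0.05, target_mb = 50,
                         ranks = 2:6, n_restarts = 30, n_top = 1500,
                         n_perm = 500, max_k = 4, min_clonal_variants = 10) {
  vcf_dir <- file.path(cohort_dir, "vcf")
  vcfs <- list.files(vcf_dir, pattern = "\\.vcf$", full.names = FALSE)
  vcfs <- setdiff(vcfs, "pooled_normal.vcf")
  meta <- do.call(rbind, lapply(vcfs, function(f) {
    parts <- strsplit(sub("\\.vcf$", "", f), "_")[[1]]
    data.frame(file = f, tumor = parts[1],
               caller = paste(parts[-1], collapse = "_"),
               stringsAsFactors = FALSE)
  }))
  pooled <- read_pooled_normal_vcf(file.path(vcf_dir, "pooled_normal.vcf"))
  annotations <- utils::read.delim(file.path(cohort_dir, "annotations.tsv"),
                                   stringsAsFactors = FALSE)
  tumor_ids <- sort(unique(meta$tumor))

  consensus <- list()
  clonal <- list()
  tmb <- stats::setNames(numeric(length(tumor_ids)), tumor_ids)
  f2_rows <- list()
  for (tid in tumor_ids) {
    rows <- meta[meta$tumor == tid, , drop = FALSE]
    obs <- lapply(seq_len(nrow(rows)), function(i) {
      read_caller_vcf(file.path(vcf_dir, rows$file[i]),
                      caller_id = rows$caller[i], tumor_id = tid)
    })
    names(obs) <- rows$caller
    res <- consensus_pipeline(obs, pooled, annotations,
                              vaf_threshold = vaf_threshold,
                              target_mb = target_mb)
    res$variants$tumor_id <- tid
    res$retained$tumor_id <- if (nrow(res$retained) > 0) tid else character(0)
    consensus[[tid]] <- res
    tmb[tid] <- res$tmb
    f2 <- res$variants[res$variants$f2, , drop = FALSE]
    if (nrow(f2) > 0) f2_rows[[tid]] <- f2

    ret <- res$retained
    if (nrow(ret) >= min_clonal_variants) {
      ret$vaf <- (ret$fwd_alt + ret$rev_alt) /
        pmax(ret$fwd_depth + ret$rev_depth, 1)
      drv_keys <- ret$key[ret$gene %in% names(DRIVER_LOCI)]
      clonal[[tid]] <- reconstruct_clones(
        ret, purity = NULL, max_k = max_k,
        seed = derive_seed(seed, paste0("clonal_", tid)),
        driver_keys = drv_keys)
    }
  }

  f2_all <- if (length(f2_rows) > 0) {
    do.call(rbind, c(f2_rows, list(make.row.names = FALSE)))
  } else {
    NULL
  }
  drivers <- if (!is.null(f2_all)) curate_drivers(f2_all) else
    data.frame(tumor_id = character(0), gene = character(0),
               consequence = character(0), rationale = character(0),
               key = character(0), stringsAsFactors = FALSE)
  dmat <- mutation_matrix(drivers, tumor_ids)
  exclusivity <- if (all(c("MET", "TP53") %in% drivers$gene) ||
                     all(c("MET", "KRAS") %in% drivers$gene)) {
    mutual_exclusivity_test(
      drivers$tumor_id[drivers$gene == "MET"],
      drivers$tumor_id[drivers$gene %in% c("TP53", "KRAS")],
      length(tumor_ids))
  } else {
    NULL
  }
  convergent <- detect_convergent(drivers)
  branched_fraction <- if (length(clonal) > 0) {
    mean(vapply(clonal, function(x) x$branching == "branched", logical(1)))
  } else {
    NA_real_
  }

  counts <- read_counts_tsv(file.path(cohort_dir, "counts.tsv"))
  gene_sets <- read_gmt(file.path(cohort_dir, "signatures.gmt"))
  marker_sets <- read_gmt(file.path(cohort_dir, "cell_markers.gmt"))
  subtyping <- if (ncol(counts) >= 4) {
    subtype_pipeline(counts, gene_sets$IMMUNE_SIGNATURE,
                     gene_sets$STROMAL_SIGNATURE, ranks = ranks,
                     n_restarts = n_restarts, n_top = n_top,
                     n_perm = n_perm, seed = derive_seed(seed, "subtype"))
  } else {
    NULL
  }
  markers <- if (!is.null(subtyping)) {
    marker_score(subtyping$normalization$logcpm, marker_sets)
  } else {
    NULL
  }

  clinical <- utils::read.delim(file.path(cohort_dir, "clinical.tsv"),
                                stringsAsFactors = FALSE)
  survival_rfs <- survival_os <- NULL
  if (!is.null(subtyping)) {
    labels <- stats::setNames(subtyping$subtypes$label,
                              subtyping$subtypes$sample)
    survival_rfs <- subtype_survival(clinical, labels, "rfs_time",
                                     "rfs_event")
    survival_os <- subtype_survival(clinical, labels, "os_time", "os_event")
  }

  summary <- list(
    n_tumors = length(tumor_ids),
    n_retained_mutations = sum(vapply(consensus,
                                      function(x) nrow(x$retained),
                                      numeric(1))),
    mean_tmb = mean(tmb),
    n_driver_calls = nrow(drivers),
    driver_prevalence = as.list(dmat$prevalence),
    branched_fraction = branched_fraction,
    chosen_rank = if (!is.null(subtyping)) subtyping$chosen_rank else NA,
    n_sam_significant = if (!is.null(subtyping))
      sum(subtyping$sam$significant) else NA,
    n_imh = if (!is.null(subtyping))
      sum(subtyping$subtypes$label == "IM-H") else NA,
    logrank_p_rfs = if (!is.null(survival_rfs))
      survival_rfs$logrank$p_value else NA,
    hr_rfs = if (!is.null(survival_rfs))
      survival_rfs$cox_univariate$table$hr[1] else NA)

  result <- list(consensus = consensus, tmb = tmb, drivers = drivers,
                 driver_matrix = dmat, exclusivity = exclusivity,
                 convergent = convergent, clonal = clonal,
                 branched_fraction = branched_fraction,
                 subtyping = subtyping, marker_scores = markers,
                 survival_rfs = survival_rfs, survival_os = survival_os,
                 summary = summary)
  if (!is.null(out_dir)) {
    write_pipeline_outputs(result, out_dir, tumor_ids)
  }
  result
}

write_pipeline_outputs <- function(result, out_dir, tumor_ids) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cons <- do.call(rbind, c(lapply(result$consensus, function(x) x$variants),
                           list(make.row.names = FALSE)))
  num_cols <- vapply(cons, is.numeric, logical(1))
  cons[num_cols] <- lapply(cons[num_cols], function(v) fmt_num(v, 8))
  write_tsv(cons, file.path(out_dir, "consensus_variants.tsv"))
  write_tsv(result$drivers, file.path(out_dir, "drivers.tsv"))
  write_tsv(data.frame(gene = rownames(result$driver_matrix$matrix),
                       result$driver_matrix$matrix, check.names = FALSE),
            file.path(out_dir, "driver_matrix.tsv"))
  trees <- lapply(result$clonal, function(x) {
    list(purity = x$purity, k = x$clusters$k, means = x$clusters$means,
         sizes = x$clusters$sizes, parent = x$tree$parent,
         branching = x$branching)
  })
  writeLines(jsonlite::toJSON(trees, digits = 10, auto_unbox = TRUE,
                              pretty = TRUE, na = "null"),
             file.path(out_dir, "clonal_trees.json"))
  if (!is.null(result$subtyping)) {
    st <- result$subtyping$subtypes
    st_num <- vapply(st, is.numeric, logical(1)) & names(st) != "cluster"
    st[st_num] <- lapply(st[st_num], function(v) fmt_num(v, 8))
    write_tsv(st, file.path(out_dir, "subtypes.tsv"))
    sam <- result$subtyping$sam
    samn <- vapply(sam, is.numeric, logical(1))
    sam[samn] <- lapply(sam[samn], function(v) fmt_num(v, 8))
    write_tsv(sam, file.path(out_dir, "sam_ranking.tsv"))
    writeLines(jsonlite::toJSON(result$subtyping$nmf$diagnostics,
                                digits = 10, pretty = TRUE),
               file.path(out_dir, "nmf_diagnostics.json"))
    if (!is.null(result$subtyping$centroids)) {
      write_tsv(data.frame(gene = rownames(result$subtyping$centroids),
                           apply(result$subtyping$centroids, 2, fmt_num, 8),
                           check.names = FALSE),
                file.path(out_dir, "centroids.tsv"))
    }
  }
  surv <- list(rfs = survival_export(result$survival_rfs),
               os = survival_export(result$survival_os))
  writeLines(jsonlite::toJSON(surv, digits = 10, auto_unbox = TRUE,
                              pretty = TRUE, na = "null"),
             file.path(out_dir, "survival.json"))
  writeLines(jsonlite::toJSON(result$summary, digits = 10,
                              auto_unbox = TRUE, pretty = TRUE,
                              na = "null"),
             file.path(out_dir, "summary.json"))
  invisible(out_dir)
}

survival_export <- function(sv) {
  if (is.null(sv)) {
    return(NULL)
  }
  list(logrank_chisq = sv$logrank$chi_squared,
       logrank_p = sv$logrank$p_value,
       cox_univariate = sv$cox_univariate$table,
       cox_univariate_converged = sv$cox_univariate$converged,
       cox_adjusted = if (!is.null(sv$cox_adjusted)) sv$cox_adjusted$table
       else NULL)
}
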