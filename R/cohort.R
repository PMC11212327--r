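# Cohort orchestration: draws ground truth for every tumor, simulates the
# three callers, expression and survival, and writes all pipeline inputs
# plus the serialized ground truth.

#' Simulate a complete synthetic cohort
#'
#' Generates ground truth (subclone trees, planted drivers, subtype labels,
#' survival hazard groups) and every file the analysis pipeline consumes:
#' three per-tumor caller VCFs, a pooled-normal VCF of recurrent artifact
#' loci, a variant annotation TSV, a gene x sample count TSV, gene set GMT
#' files, a clinical TSV and the ground truth as JSON. Deterministic for a
#' fixed seed: two runs with the same config produce byte-identical files.
#'
#' @param config a [cohort_config()] object.
#' @param out_dir output directory (created if missing). Set to `NULL` to
#'   skip writing files and return in-memory objects only.
#' @return (invisibly) a list with `truth`, `observations` (per tumor, per
#'   caller), `pooled_normal` (data.frame of artifact loci), `annotations`,
#'   `counts`, `clinical`, `gene_sets` and `paths` (NULL if `out_dir` is).
#' @export
#' @examples
#' cfg <- cohort_config(n_tumors = 2, n_true_variants_mean = 20,
#'                      expr_spec = list(n_genes = 200, n_expr_samples = 2,
#'                                       n_immune_genes = 20,
#'                                       immune_effect_log2fc = 1.5,
#'                                       dispersion = 0.3, baseline_mean = 50,
#'                                       libsize_spread = 3,
#'                                       p_immune_high = 0.5),
#'                      seed = 11)
#' cohort <- simulate_cohort(cfg, out_dir = NULL)
#' names(cohort$truth$tumors)
simulate_cohort <- function(config, out_dir = tempfile("psc_cohort_")) {
  validate_cohort_config(config)
  seed <- config$seed
  n <- as.integer(config$n_tumors)
  tumor_ids <- if (n > 0) sprintf("PSC%02d", seq_len(n)) else character(0)

  # --- per-tumor genomic ground truth -------------------------------------
  artifacts <- with_rng(derive_seed(seed, "artifacts"), {
    m <- config$n_artifact_loci
    if (m > 0) {
      al <- random_snv_alleles(m)
      data.frame(chrom = paste0("chr", sample(1:22, m, replace = TRUE)),
                 pos = sample.int(100000000L, m) + 200000000L,
                 ref = al$ref, alt = al$alt, stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0),
                 stringsAsFactors = FALSE)
    }
  })

  tumors <- list()
  observations <- list()
  for (i in seq_len(n)) {
    tid <- tumor_ids[i]
    tseed <- derive_seed(seed, paste0("tumor_", tid))
    structure <- simulate_subclone_structure(config$subclone_spec,
                                             derive_seed(tseed, "tree"))
    truth_i <- with_rng(derive_seed(tseed, "variants"), {
      purity <- stats::runif(1, config$subclone_spec$purity_range[1],
                             config$subclone_spec$purity_range[2])
      drivers <- plant_drivers(config$driver_prevalence,
                               config$subclone_spec$convergent_tp53_prob)
      drv <- driver_variant_rows(drivers, i)
      n_pass <- stats::rpois(1, config$n_true_variants_mean)
      pas <- passenger_variant_rows(n_pass, i)
      vars <- rbind(drv, pas)
      if (is.null(vars)) {
        vars <- data.frame(chrom = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           gene = character(0), consequence = character(0),
                           driver = logical(0), stringsAsFactors = FALSE)
      }
      vars <- vars[!duplicated(paste(vars$chrom, vars$pos)), , drop = FALSE]
      k <- length(structure$ccf)
      cluster <- integer(nrow(vars))
      if (nrow(vars) > 0) {
        if (k == 1L) {
          cluster[] <- 1L
        } else {
          tf <- config$subclone_spec$trunk_fraction
          w <- c(tf, (1 - tf) * structure$ccf[-1] / sum(structure$ccf[-1]))
          cluster <- sample.int(k, nrow(vars), replace = TRUE, prob = w)
          is_drv <- vars$driver
          trunked <- stats::runif(sum(is_drv)) <
            config$subclone_spec$trunk_driver_prob
          subcl <- (2:k)[sample.int(k - 1L, sum(is_drv), replace = TRUE)]
          cluster[is_drv] <- ifelse(trunked, 1L, subcl)
        }
      }
      vars$subclone <- cluster
      vars$ccf <- structure$ccf[cluster]
      vars$vaf <- vars$ccf * purity / 2
      vars$tumor_id <- tid
      list(purity = purity, variants = vars)
    })
    tumors[[tid]] <- list(id = tid,
                          purity = truth_i$purity,
                          tree = list(parent = structure$parent,
                                      ccf = structure$ccf),
                          branched = structure$branched,
                          variants = truth_i$variants)
    art_i <- if (nrow(artifacts) > 0) {
      with_rng(derive_seed(tseed, "artifact_vaf"), {
        data.frame(chrom = artifacts$chrom, pos = artifacts$pos,
                   ref = artifacts$ref, alt = artifacts$alt,
                   gene = ".", consequence = "other", driver = FALSE,
                   subclone = NA_integer_, ccf = NA_real_,
                   vaf = stats::runif(nrow(artifacts), 0.2, 0.45),
                   tumor_id = tid, always_detected = TRUE,
                   stringsAsFactors = FALSE)
      })
    } else {
      NULL
    }
    tv <- tumors[[tid]]$variants
    if (nrow(tv) > 0) tv$always_detected <- FALSE
    caller_input <- rbind(tv, art_i)
    observations[[tid]] <- simulate_caller_observations(
      caller_input, config$caller_profiles,
      seed = derive_seed(tseed, "callers"),
      mean_depth = config$mean_depth, target_mb = config$target_mb)
  }

  annotations <- build_annotation_table(tumors, artifacts, config,
                                        derive_seed(seed, "annotations"))

  # --- expression + subtypes ---------------------------------------------
  es <- config$expr_spec
  n_expr <- min(es$n_expr_samples, n)
  expr_ids <- tumor_ids[seq_len(n_expr)]
  subtype_all <- with_rng(derive_seed(seed, "subtypes"), {
    s <- ifelse(stats::runif(n) < es$p_immune_high, "IM-H", "IM-L")
    names(s) <- tumor_ids
    s
  })
  gene_sets <- list(
    IMMUNE_SIGNATURE = paste0("IMM", sprintf("%04d", seq_len(es$n_immune_genes))),
    STROMAL_SIGNATURE = paste0("STR", sprintf("%04d",
                                              seq_len(max(es$n_immune_genes %/% 2, 5))))
  )
  marker_sets <- list(
    Neutrophils = gene_sets$IMMUNE_SIGNATURE[seq_len(min(10, es$n_immune_genes))],
    B_cells = gene_sets$IMMUNE_SIGNATURE[seq_len(min(20, es$n_immune_genes))][-seq_len(min(10, es$n_immune_genes))],
    Endothelial = gene_sets$STROMAL_SIGNATURE[seq_len(min(10, length(gene_sets$STROMAL_SIGNATURE)))]
  )
  counts <- if (n_expr > 0) {
    simulate_expression(es, subtype_all[expr_ids],
                        immune_geneset = gene_sets$IMMUNE_SIGNATURE,
                        seed = derive_seed(seed, "expression"),
                        stromal_geneset = gene_sets$STROMAL_SIGNATURE)
  } else {
    matrix(integer(0), nrow = 0, ncol = 0)
  }

  # --- survival + clinical -------------------------------------------------
  rfs <- simulate_survival(subtype_all, config$surv_spec,
                           derive_seed(seed, "rfs"))
  os <- simulate_survival(subtype_all, config$surv_spec,
                          derive_seed(seed, "os"),
                          hazard_scale = config$surv_spec$os_hazard_scale)
  clinical <- with_rng(derive_seed(seed, "clinical"), {
    stage <- sample(1:7, n, replace = TRUE,
                    prob = c(0.143, 0.333, 0.048, 0.286, 0.095, 0.048, 0.047))
    gender <- sample(c("male", "female"), n, replace = TRUE,
                     prob = c(2 / 3, 1 / 3))
    smoking <- sample(c("ever", "never"), n, replace = TRUE,
                      prob = c(0.95, 0.05))
    data.frame(tumor_id = tumor_ids,
               rfs_time = rfs$time, rfs_event = rfs$event,
               os_time = os$time, os_event = os$event,
               recurrence = rfs$event,
               stage = if (n > 0) stage else integer(0),
               gender = if (n > 0) gender else character(0),
               smoking = if (n > 0) smoking else character(0),
               stringsAsFactors = FALSE)
  })

  truth <- list(config_seed = seed,
                tumor_ids = tumor_ids,
                tumors = tumors,
                purity = vapply(tumors, function(t) t$purity, numeric(1)),
                subtype = as.list(subtype_all),
                expr_samples = expr_ids,
                artifact_loci = artifacts,
                gene_sets = gene_sets,
                marker_sets = marker_sets)

  paths <- NULL
  if (!is.null(out_dir)) {
    paths <- write_cohort_files(out_dir, tumor_ids, observations, artifacts,
                                annotations, counts, clinical, gene_sets,
                                marker_sets, truth)
  }
  invisible(list(truth = truth, observations = observations,
                 pooled_normal = artifacts, annotations = annotations,
                 counts = counts, clinical = clinical,
                 gene_sets = gene_sets, marker_sets = marker_sets,
                 paths = paths))
}

# One annotation row per distinct true-variant or artifact locus. Driver
# loci carry hotspot-grade evidence; a small share of passengers carries
# database evidence so the hotspot-rescue category is populated.
build_annotation_table <- function(tumors, artifacts, config, seed) {
  vars <- if (length(tumors) > 0) {
    do.call(rbind, c(lapply(tumors, function(t) t$variants),
                     list(make.row.names = FALSE)))
  } else {
    NULL
  }
  if (is.null(vars) || nrow(vars) == 0) {
    vars <- data.frame(chrom = character(0), pos = integer(0),
                       ref = character(0), alt = character(0),
                       gene = character(0), consequence = character(0),
                       driver = logical(0), stringsAsFactors = FALSE)
  }
  art <- if (nrow(artifacts) > 0) {
    data.frame(chrom = artifacts$chrom, pos = artifacts$pos,
               ref = artifacts$ref, alt = artifacts$alt, gene = ".",
               consequence = "other", driver = FALSE,
               stringsAsFactors = FALSE)
  } else {
    NULL
  }
  all <- rbind(vars[, c("chrom", "pos", "ref", "alt", "gene", "consequence",
                        "driver")], art)
  key <- locus_key(all$chrom, all$pos, all$ref, all$alt)
  all <- all[!duplicated(key), , drop = FALSE]
  with_rng(seed, {
    m <- nrow(all)
    pan <- integer(m)
    clinvar <- logical(m)
    tier <- rep("none", m)
    role <- rep("none", m)
    patho <- logical(m)
    drv <- all$driver
    pan[drv] <- sample(4:60, sum(drv), replace = TRUE)
    clinvar[drv] <- TRUE
    tier[drv] <- sample(c("1", "2"), sum(drv), replace = TRUE)
    patho[drv] <- TRUE
    role[all$gene == "TP53"] <- "tsg"
    role[all$gene %in% c("KRAS", "MET")] <- "oncogene"
    # database evidence on a small share of passengers (hotspot rescue pool)
    pas <- which(!drv)
    hot <- pas[stats::runif(length(pas)) < 0.04]
    pan[hot] <- sample(4:20, length(hot), replace = TRUE)
    clin_extra <- pas[stats::runif(length(pas)) < 0.02]
    clinvar[clin_extra] <- TRUE
    pan[setdiff(pas, hot)] <- sample(0:3, length(setdiff(pas, hot)),
                                     replace = TRUE,
                                     prob = c(0.7, 0.15, 0.1, 0.05))
    data.frame(chrom = all$chrom, pos = all$pos, ref = all$ref, alt = all$alt,
               gene = all$gene, consequence = all$consequence,
               pan_cancer_count = pan, in_clinvar = clinvar, acmg_tier = tier,
               gene_role = role, pathogenic_aa_change = patho,
               stringsAsFactors = FALSE)
  })
}

write_cohort_files <- function(out_dir, tumor_ids, observations, artifacts,
                               annotations, counts, clinical, gene_sets,
                               marker_sets, truth) {
  dir.create(file.path(out_dir, "vcf"), recursive = TRUE, showWarnings = FALSE)
  vcf_paths <- list()
  for (tid in tumor_ids) {
    vcf_paths[[tid]] <- vapply(names(observations[[tid]]), function(cname) {
      p <- file.path(out_dir, "vcf", paste0(tid, "_", cname, ".vcf"))
      write_caller_vcf(observations[[tid]][[cname]], p)
      p
    }, character(1))
  }
  pooled_path <- file.path(out_dir, "vcf", "pooled_normal.vcf")
  write_pooled_normal_vcf(artifacts, pooled_path)
  ann_path <- file.path(out_dir, "annotations.tsv")
  write_tsv(annotations, ann_path)
  counts_path <- file.path(out_dir, "counts.tsv")
  write_counts_tsv(counts, counts_path)
  clin_path <- file.path(out_dir, "clinical.tsv")
  write_tsv(clinical, clin_path)
  gmt_path <- file.path(out_dir, "signatures.gmt")
  write_gmt(gene_sets, gmt_path)
  markers_path <- file.path(out_dir, "cell_markers.gmt")
  write_gmt(marker_sets, markers_path)
  truth_path <- file.path(out_dir, "ground_truth.json")
  write_ground_truth(truth, truth_path)
  list(dir = out_dir, vcf = vcf_paths, pooled_normal = pooled_path,
       annotations = ann_path, counts = counts_path, clinical = clin_path,
       gene_sets = gmt_path, markers = markers_path, truth = truth_path)
}

#' Serialize / restore ground truth
#'
#' Ground truth round-trips losslessly through JSON (full numeric
#' precision).
#'
#' @param truth ground-truth list from [simulate_cohort()].
#' @param path file path.
#' @return `read_ground_truth` returns the restored list.
#' @export
write_ground_truth <- function(truth, path) {
  json <- jsonlite::toJSON(truth, digits = NA, auto_unbox = TRUE,
                           pretty = TRUE, na = "null")
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = TRUE)
  invisible(path)
}

write_counts_tsv <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a gene x sample count matrix from TSV
#'
#' @param path TSV with a leading `gene` column.
#' @return integer matrix with gene rownames.
#' @export
read_counts_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' Write / read gene sets in GMT format
#'
#' @param sets named list of character vectors.
#' @param path file path.
#' @return `read_gmt` returns a named list of character vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "synthetic", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-c(1, 2)]
  })
  names(sets) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  sets
}
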