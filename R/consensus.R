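# Multi-caller consensus filtering: allele normalization, caller merging,
# pooled-normal subtraction, the strand-aware F1/F2 filter rules,
# categorization and tumor mutational burden.
#
# F1: PASS by at least two of the three callers AND forward and reverse
#     strand VAF each strictly greater than the threshold (default 5%).
# F2: forward and reverse strand VAF strictly greater than the threshold
#     AND database evidence (pan-cancer recurrence count strictly greater
#     than 3, a ClinVar entry, or ACMG/ICMG tier 1 or 2).
# Categories: both = F1 & F2; hotspot_rescue = F2 only; other_somatic =
# F1 only; rejected = neither. The retained (F1/F2) list feeds TMB.

#' Normalize a variant to a minimal representation
#'
#' Trims the shared suffix, then the shared prefix (advancing the
#' position), of REF/ALT so that the same event reported with different
#' padding by different callers maps to one locus key. Idempotent.
#'
#' @param chrom chromosome.
#' @param pos 1-based position (VCF convention).
#' @param ref,alt non-empty uppercase allele strings.
#' @return list with normalized `chrom`, `pos`, `ref`, `alt` and `key`
#'   ("chrom:pos:ref:alt").
#' @export
#' @examples
#' normalize_variant("chr1", 100, "AT", "AC")$key  # "chr1:101:T:C"
normalize_variant <- function(chrom, pos, ref, alt) {
  if (is.na(ref) || is.na(alt) || !nzchar(ref) || !nzchar(alt)) {
    stop("normalize_variant: ref and alt must be non-empty", call. = FALSE)
  }
  if (ref == alt) {
    stop("normalize_variant: ref equals alt at ", chrom, ":", pos,
         " - not a variant", call. = FALSE)
  }
  r <- strsplit(ref, "", fixed = TRUE)[[1]]
  a <- strsplit(alt, "", fixed = TRUE)[[1]]
  # shared suffix
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]
    a <- a[-length(a)]
  }
  # shared prefix
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]
    a <- a[-1]
    pos <- pos + 1
  }
  ref2 <- paste(r, collapse = "")
  alt2 <- paste(a, collapse = "")
  list(chrom = chrom, pos = as.integer(pos), ref = ref2, alt = alt2,
       key = locus_key(chrom, pos, ref2, alt2))
}

normalize_keys <- function(chrom, pos, ref, alt) {
  n <- length(chrom)
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- normalize_variant(chrom[i], pos[i], ref[i], alt[i])$key
  }
  out
}

#' Merge per-caller observations into consensus variants
#'
#' One row per distinct normalized locus across all callers, with per-caller
#' observed/PASS verdicts and strand-split counts taken from the designated
#' primary caller (falling back to the first caller reporting the locus).
#'
#' @param observations named list (one element per caller, at most 3) of
#'   observation data.frames with the VariantObservation columns.
#' @param primary_caller name of the caller whose strand counts feed the
#'   strand-VAF test; default `"ionreporter"`.
#' @return data.frame with one row per locus: key, chrom, pos, ref, alt,
#'   per-caller `observed.<caller>` / `passed.<caller>` columns, n_observed,
#'   n_passed, fwd_alt, rev_alt, fwd_depth, rev_depth, fwd_vaf, rev_vaf and
#'   vaf_source (the caller whose counts were used).
#' @export
merge_callers <- function(observations, primary_caller = "ionreporter") {
  callers <- names(observations)
  if (length(callers) > 3L) {
    stop("merge_callers: at most 3 callers supported", call. = FALSE)
  }
  norm <- lapply(callers, function(cname) {
    obs <- observations[[cname]]
    if (nrow(obs) == 0) {
      obs$key <- character(0)
      return(obs)
    }
    keys <- normalize_keys(obs$chrom, obs$pos, obs$ref, obs$alt)
    if (anyDuplicated(keys)) {
      dup <- keys[duplicated(keys)][1]
      stop("merge_callers: duplicate record for caller ", cname,
           " at locus ", dup, call. = FALSE)
    }
    obs$key <- keys
    obs
  })
  names(norm) <- callers
  all_keys <- sort(unique(unlist(lapply(norm, function(o) o$key))))
  n <- length(all_keys)
  res <- data.frame(key = all_keys, stringsAsFactors = FALSE)
  first <- rep(NA_integer_, n)  # index of first caller observing each locus
  for (ci in seq_along(callers)) {
    o <- norm[[ci]]
    idx <- match(all_keys, o$key)
    res[[paste0("observed.", callers[ci])]] <- !is.na(idx)
    res[[paste0("passed.", callers[ci])]] <- !is.na(idx) & o$passed[pmax(idx, 1)]
    res[[paste0("passed.", callers[ci])]][is.na(idx)] <- FALSE
    first[is.na(first) & !is.na(idx)] <- ci
  }
  obs_cols <- paste0("observed.", callers)
  pass_cols <- paste0("passed.", callers)
  res$n_observed <- rowSums(as.matrix(res[, obs_cols, drop = FALSE]))
  res$n_passed <- rowSums(as.matrix(res[, pass_cols, drop = FALSE]))
  # strand counts from the primary caller where it observed the locus
  src_idx <- if (primary_caller %in% callers) {
    ifelse(res[[paste0("observed.", primary_caller)]],
           match(primary_caller, callers), first)
  } else {
    first
  }
  pick <- function(field) {
    vapply(seq_len(n), function(i) {
      o <- norm[[src_idx[i]]]
      o[[field]][match(all_keys[i], o$key)]
    }, numeric(1))
  }
  if (n > 0) {
    res$vaf_source <- callers[src_idx]
    res$chrom <- as.character(pick_chr(norm, src_idx, all_keys, "chrom"))
    res$pos <- as.integer(pick_chr(norm, src_idx, all_keys, "pos"))
    res$ref <- as.character(pick_chr(norm, src_idx, all_keys, "ref"))
    res$alt <- as.character(pick_chr(norm, src_idx, all_keys, "alt"))
    res$fwd_alt <- pick("fwd_alt")
    res$rev_alt <- pick("rev_alt")
    res$fwd_depth <- pick("fwd_depth")
    res$rev_depth <- pick("rev_depth")
    vafs <- strand_vafs(res)
    res$fwd_vaf <- vafs$fwd_vaf
    res$rev_vaf <- vafs$rev_vaf
  } else {
    res$vaf_source <- character(0)
    res$chrom <- character(0)
    res$pos <- integer(0)
    res$ref <- character(0)
    res$alt <- character(0)
    res$fwd_alt <- res$rev_alt <- res$fwd_depth <- res$rev_depth <- numeric(0)
    res$fwd_vaf <- res$rev_vaf <- numeric(0)
  }
  rownames(res) <- NULL
  res
}

pick_chr <- function(norm, src_idx, keys, field) {
  vapply(seq_along(keys), function(i) {
    o <- norm[[src_idx[i]]]
    j <- match(keys[i], o$key)
    # report the normalized coordinates, not the caller's padded ones
    if (field %in% c("chrom", "pos", "ref", "alt")) {
      nv <- normalize_variant(o$chrom[j], o$pos[j], o$ref[j], o$alt[j])
      as.character(nv[[field]])
    } else {
      as.character(o[[field]][j])
    }
  }, character(1))
}

#' Strand-split variant allele frequencies
#'
#' `fwd_vaf = fwd_alt / fwd_depth` and likewise for the reverse strand; a
#' zero-depth strand yields VAF 0 (which fails the >5% strand test, the
#' conservative convention).
#'
#' @param observation data.frame (or list) with fwd_alt, rev_alt,
#'   fwd_depth, rev_depth.
#' @return list with numeric vectors `fwd_vaf` and `rev_vaf`.
#' @export
#' @examples
#' strand_vafs(list(fwd_alt = 6, fwd_depth = 100, rev_alt = 3, rev_depth = 80))
strand_vafs <- function(observation) {
  fwd <- ifelse(observation$fwd_depth > 0,
                observation$fwd_alt / observation$fwd_depth, 0)
  rev <- ifelse(observation$rev_depth > 0,
                observation$rev_alt / observation$rev_depth, 0)
  list(fwd_vaf = as.numeric(fwd), rev_vaf = as.numeric(rev))
}

#' Attach annotations to consensus variants
#'
#' Joins the annotation table by normalized locus key. Loci without an
#' annotation row get the conservative defaults (pan-cancer count 0, not in
#' ClinVar, tier none, role none); the number of such loci is messaged.
#'
#' @param consensus output of [merge_callers()].
#' @param annotations data.frame with chrom, pos, ref, alt, gene,
#'   consequence, pan_cancer_count, in_clinvar, acmg_tier, gene_role,
#'   pathogenic_aa_change.
#' @return consensus with annotation columns appended.
#' @export
annotate_consensus <- function(consensus, annotations) {
  if (nrow(annotations) > 0) {
    akey <- normalize_keys(annotations$chrom, annotations$pos,
                           annotations$ref, annotations$alt)
  } else {
    akey <- character(0)
  }
  idx <- match(consensus$key, akey)
  missing <- sum(is.na(idx))
  if (missing > 0) {
    message("annotate_consensus: ", missing,
            " loci without annotation; using defaults")
  }
  take <- function(field, default) {
    v <- annotations[[field]][idx]
    v[is.na(idx)] <- default
    v
  }
  consensus$gene <- take("gene", ".")
  consensus$consequence <- take("consequence", "other")
  consensus$pan_cancer_count <- {
    v <- take("pan_cancer_count", 0L)
    v[is.na(v)] <- 0L
    v
  }
  consensus$in_clinvar <- {
    v <- take("in_clinvar", FALSE)
    v[is.na(v)] <- FALSE
    v
  }
  consensus$acmg_tier <- take("acmg_tier", "none")
  consensus$gene_role <- take("gene_role", "none")
  consensus$pathogenic_aa_change <- {
    v <- take("pathogenic_aa_change", FALSE)
    v[is.na(v)] <- FALSE
    v
  }
  consensus
}

#' Filter 1: consensus PASS plus strand support
#'
#' TRUE iff the variant was PASSed by at least two callers and both strand
#' VAFs strictly exceed the threshold.
#'
#' @param consensus_variant consensus row(s) with n_passed, fwd_vaf,
#'   rev_vaf.
#' @param vaf_threshold strand VAF threshold (strict), default 0.05.
#' @return logical vector.
#' @export
apply_filter1 <- function(consensus_variant, vaf_threshold = 0.05) {
  consensus_variant$n_passed >= 2 &
    consensus_variant$fwd_vaf > vaf_threshold &
    consensus_variant$rev_vaf > vaf_threshold
}

#' Filter 2: strand support plus database evidence
#'
#' TRUE iff both strand VAFs strictly exceed the threshold and the variant
#' has a pan-cancer recurrence count strictly greater than 3, a ClinVar
#' entry, or ACMG/ICMG tier 1 or 2.
#'
#' @inheritParams apply_filter1
#' @return logical vector.
#' @export
apply_filter2 <- function(consensus_variant, vaf_threshold = 0.05) {
  evidence <- consensus_variant$pan_cancer_count > 3 |
    consensus_variant$in_clinvar |
    consensus_variant$acmg_tier %in% c("1", "2", 1, 2)
  consensus_variant$fwd_vaf > vaf_threshold &
    consensus_variant$rev_vaf > vaf_threshold &
    evidence
}

#' Remove pooled-normal loci
#'
#' Drops consensus variants whose normalized locus appears in the
#' pooled-normal call set (germline variants and recurrent sequencing
#' artifacts), before F1/F2 evaluation.
#'
#' @param consensus_variants consensus data.frame with a `key` column.
#' @param pooled_normal_loci character vector of normalized locus keys.
#' @return filtered data.frame; the removal count is messaged.
#' @export
pooled_normal_filter <- function(consensus_variants, pooled_normal_loci) {
  drop <- consensus_variants$key %in% pooled_normal_loci
  if (any(drop)) {
    message("pooled_normal_filter: removed ", sum(drop),
            " pooled-normal loci")
  }
  consensus_variants[!drop, , drop = FALSE]
}

#' Categorize consensus variants by the F1/F2 rules
#'
#' Evaluates both filters and partitions variants into `both` (F1 and F2),
#' `hotspot_rescue` (F2 only: hotspot/known oncogenic mutations failing the
#' strict F1 criterion), `other_somatic` (F1 only) and `rejected`. The
#' retained F1/F2 list is their union minus `rejected`.
#'
#' @param consensus_variants annotated consensus data.frame.
#' @param vaf_threshold strand VAF threshold.
#' @return list with `variants` (input plus f1, f2, category), `retained`
#'   (the F1/F2 list) and `summary` (named counts and their total).
#' @export
categorize <- function(consensus_variants, vaf_threshold = 0.05) {
  f1 <- apply_filter1(consensus_variants, vaf_threshold)
  f2 <- apply_filter2(consensus_variants, vaf_threshold)
  category <- ifelse(f1 & f2, "both",
                     ifelse(f2, "hotspot_rescue",
                            ifelse(f1, "other_somatic", "rejected")))
  out <- consensus_variants
  out$f1 <- f1
  out$f2 <- f2
  out$category <- category
  retained <- out[out$category != "rejected", , drop = FALSE]
  summary <- c(both = sum(category == "both"),
               hotspot_rescue = sum(category == "hotspot_rescue"),
               other_somatic = sum(category == "other_somatic"))
  summary <- c(summary, total = sum(summary))
  list(variants = out, retained = retained, summary = summary)
}

#' Tumor mutational burden
#'
#' Retained (F1/F2) mutations per megabase of sequenced target.
#'
#' @param f1f2_variants data.frame of retained variants, or a single count.
#' @param target_size_mb target size in Mb; must be positive.
#' @return mutations per Mb.
#' @export
#' @examples
#' compute_tmb(285, 50)  # 5.7
compute_tmb <- function(f1f2_variants, target_size_mb) {
  if (!is.numeric(target_size_mb) || length(target_size_mb) != 1 ||
      is.na(target_size_mb) || target_size_mb <= 0) {
    stop("compute_tmb: target_size_mb must be positive", call. = FALSE)
  }
  n <- if (is.data.frame(f1f2_variants)) nrow(f1f2_variants) else f1f2_variants
  n / target_size_mb
}

#' Run the consensus stage for one tumor
#'
#' Merge, pooled-normal-filter, annotate and categorize one tumor's caller
#' observations.
#'
#' @param observations named list of per-caller observation data.frames.
#' @param pooled_normal_loci character vector of normalized pooled-normal
#'   locus keys.
#' @param annotations annotation data.frame.
#' @param vaf_threshold strand VAF threshold.
#' @param target_mb target size for TMB.
#' @param primary_caller caller supplying strand counts.
#' @return list as [categorize()] plus `tmb`.
#' @export
consensus_pipeline <- function(observations, pooled_normal_loci, annotations,
                               vaf_threshold = 0.05, target_mb = 50,
                               primary_caller = "ionreporter") {
  merged <- merge_callers(observations, primary_caller = primary_caller)
  merged <- pooled_normal_filter(merged, pooled_normal_loci)
  merged <- annotate_consensus(merged, annotations)
  cat <- categorize(merged, vaf_threshold)
  cat$tmb <- compute_tmb(cat$retained, target_mb)
  cat
}
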