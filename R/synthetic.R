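# Synthetic multiomics cohort generator. Produces, with known ground truth,
# every input the analysis stages consume: three per-tumor caller VCFs, a
# pooled-normal VCF of recurrent artifacts, a variant annotation table, a
# gene x sample count matrix, gene sets, and a clinical table.

DRIVER_LOCI <- list(
  TP53 = list(chrom = "chr17", base = 7577000L,
              consequence = "stop_gain", role = "tsg", pathogenic = TRUE),
  KRAS = list(chrom = "chr12", base = 25398000L,
              consequence = "missense", role = "oncogene", pathogenic = TRUE),
  MET  = list(chrom = "chr7", base = 116411000L,
              consequence = "splice", role = "oncogene", pathogenic = TRUE)
)

PASSENGER_CONSEQUENCES <- c(missense = 0.40, synonymous = 0.20, other = 0.20,
                            stop_gain = 0.05, splice = 0.05,
                            frameshift = 0.05, inframe = 0.05)

#' Simulate one tumor's subclonal architecture
#'
#' Draws a rooted clone tree: a clonal trunk (cancer cell fraction 1) plus
#' either a linear chain of 0-2 nested subclones or, with probability
#' `p_branched`, two or more sibling subclones under the trunk. Subclone
#' CCFs respect the pigeonhole sum rule (sibling CCFs sum to at most the
#' parent's) and are kept at least `min_ccf_gap` apart so clusters are
#' identifiable.
#'
#' @param subclone_spec list with `p_branched` and `max_branches` (see
#'   [cohort_config()]).
#' @param seed integer seed.
#' @param min_ccf_gap minimum CCF separation between any two clusters.
#' @return list with `parent` (0 for the trunk), `ccf` per cluster
#'   (cluster 1 is the trunk at CCF 1) and `branched` (logical).
#' @export
simulate_subclone_structure <- function(subclone_spec, seed, min_ccf_gap = 0.1) {
  p_branched <- subclone_spec$p_branched
  max_branches <- max(1L, as.integer(subclone_spec$max_branches))
  with_rng(seed, {
    branched <- max_branches >= 2L && stats::runif(1) < p_branched
    if (branched) {
      nb <- if (max_branches == 2L) 2L else sample(2:max_branches, 1L)
      w <- NULL
      for (attempt in seq_len(500L)) {
        cand <- sort(stats::runif(nb, 0.15, 0.75), decreasing = TRUE)
        gaps_ok <- nb == 1L || min(-diff(cand)) >= min_ccf_gap
        if (sum(cand) <= 0.9 && gaps_ok && (1 - cand[1]) >= min_ccf_gap) {
          w <- cand
          break
        }
      }
      if (is.null(w) && nb > 2L) {
        # dense sibling sets can be infeasible under the sum rule; fall back
        for (attempt in seq_len(500L)) {
          cand <- sort(stats::runif(2L, 0.15, 0.75), decreasing = TRUE)
          if (sum(cand) <= 0.9 && (cand[1] - cand[2]) >= min_ccf_gap &&
              (1 - cand[1]) >= min_ccf_gap) {
            w <- cand
            break
          }
        }
      }
      if (is.null(w)) w <- c(0.5, 0.25)
      list(parent = c(0L, rep(1L, length(w))),
           ccf = c(1, w),
           branched = TRUE)
    } else {
      # Linear chains are drawn "heavy": nested subclone CCFs sum above the
      # trunk, so sibling placement is infeasible under the sum rule and the
      # nested topology is identifiable from the CCFs alone.
      nc <- sample(0:2, 1L)
      trunk_gap <- min(min_ccf_gap, 0.2)
      ccf <- 1
      parent <- 0L
      if (nc >= 1L) {
        if (nc == 2L) {
          lo1 <- max(0.3, (1.15 + min_ccf_gap) / 2)
          hi1 <- 1 - trunk_gap
          if (lo1 < hi1) {
            c1 <- stats::runif(1, lo1, hi1)
            c2 <- stats::runif(1, max(0.15, 1.15 - c1), c1 - min_ccf_gap)
            ccf <- c(1, c1, c2)
            parent <- c(0L, 1L, 2L)
          } else {
            nc <- 1L
          }
        }
        if (nc == 1L) {
          c1 <- stats::runif(1, 0.3, 1 - trunk_gap)
          ccf <- c(1, c1)
          parent <- c(0L, 1L)
        }
      }
      list(parent = as.integer(parent), ccf = ccf, branched = FALSE)
    }
  })
}

#' Draw noisy mutation CCFs from a planted subclone structure
#'
#' Assigns `n_per_cluster` mutations to each cluster of a structure from
#' [simulate_subclone_structure()] and perturbs each mutation's CCF with
#' Gaussian noise, clamped to (0, 1.2].
#'
#' @param structure list with `ccf` per cluster.
#' @param n_per_cluster mutations per cluster (recycled).
#' @param sd Gaussian noise standard deviation on the CCF scale.
#' @param seed integer seed.
#' @return data.frame with columns `cluster` (true cluster index, clusters
#'   ordered by descending CCF as generated) and `ccf`.
#' @export
simulate_mutation_ccfs <- function(structure, n_per_cluster, sd, seed) {
  k <- length(structure$ccf)
  n_per_cluster <- rep_len(n_per_cluster, k)
  with_rng(seed, {
    cl <- rep(seq_len(k), times = n_per_cluster)
    ccf <- stats::rnorm(length(cl), mean = structure$ccf[cl], sd = sd)
    ccf <- pmin(pmax(ccf, 0.01), 1.2)
    data.frame(cluster = cl, ccf = ccf)
  })
}

random_snv_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  list(ref = ref, alt = unname(alt))
}

# Plant driver mutations for one tumor. MET exon-14 splice drivers are kept
# mutually exclusive with TP53/KRAS unless a prevalence of 1 forces the gene.
plant_drivers <- function(driver_prevalence, convergent_tp53_prob) {
  genes <- names(driver_prevalence)
  planted <- stats::runif(length(genes)) < driver_prevalence
  names(planted) <- genes
  guaranteed <- driver_prevalence >= 1
  if (isTRUE(planted["MET"]) && !isTRUE(guaranteed["MET"])) {
    others <- intersect(c("TP53", "KRAS"), genes)
    if (any(planted[others])) planted["MET"] <- FALSE
  } else if (isTRUE(planted["MET"]) && isTRUE(guaranteed["MET"])) {
    others <- intersect(c("TP53", "KRAS"), genes)
    drop <- others[planted[others] & !guaranteed[others]]
    planted[drop] <- FALSE
  }
  out <- genes[planted]
  if ("TP53" %in% out && stats::runif(1) < convergent_tp53_prob) {
    out <- c(out, "TP53")  # second, distinct TP53 hit: convergent evolution
  }
  out
}

driver_variant_rows <- function(driver_genes, tumor_idx) {
  if (length(driver_genes) == 0L) {
    return(NULL)
  }
  rows <- lapply(seq_along(driver_genes), function(i) {
    g <- driver_genes[i]
    info <- DRIVER_LOCI[[g]]
    if (is.null(info)) {
      info <- list(chrom = "chr9", base = 5000000L, consequence = "missense",
                   role = "oncogene", pathogenic = TRUE)
    }
    # second hit on the same gene gets a distinct locus and consequence
    second <- duplicated(driver_genes)[i]
    cons <- if (second) "missense" else info$consequence
    pos <- info$base + tumor_idx * 97L + i * 13L
    al <- random_snv_alleles(1L)
    data.frame(chrom = info$chrom, pos = pos, ref = al$ref, alt = al$alt,
               gene = g, consequence = cons, driver = TRUE,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

passenger_variant_rows <- function(n, tumor_idx) {
  if (n == 0L) {
    return(NULL)
  }
  chrom <- paste0("chr", sample(1:22, n, replace = TRUE))
  pos <- sample.int(100000000L, n)
  al <- random_snv_alleles(n)
  gene <- paste0("GENE", sprintf("%05d", sample.int(19000L, n, replace = TRUE)))
  cons <- sample(names(PASSENGER_CONSEQUENCES), n, replace = TRUE,
                 prob = PASSENGER_CONSEQUENCES)
  data.frame(chrom = chrom, pos = pos, ref = al$ref, alt = al$alt,
             gene = gene, consequence = cons, driver = FALSE,
             stringsAsFactors = FALSE)
}

#' Simulate per-caller observations of a tumor's true variants
#'
#' Each true variant is detected by a caller with that caller's sensitivity;
#' detected variants get strand-split read counts drawn binomially at the
#' configured mean depth with expected VAF as supplied. With the caller's
#' strand-bias probability a variant's alt reads collapse onto the forward
#' strand (reverse-strand VAF 0). Caller-specific false positives are added
#' at `fp_rate` per Mb of target.
#'
#' @param true_variants data.frame with columns chrom, pos, ref, alt, vaf and
#'   optionally `always_detected` (logical) and `tumor_id`.
#' @param caller_profiles named list of exactly three caller profiles.
#' @param seed integer seed.
#' @param mean_depth mean total depth per site.
#' @param target_mb target size in Mb (scales false-positive counts).
#' @return named list (one per caller) of observation data.frames with
#'   columns tumor_id, caller_id, chrom, pos, ref, alt, passed, fwd_alt,
#'   rev_alt, fwd_depth, rev_depth.
#' @export
simulate_caller_observations <- function(true_variants, caller_profiles, seed,
                                         mean_depth = 225, target_mb = 50) {
  if (length(caller_profiles) != 3L) {
    stop("exactly 3 caller profiles are required, got ",
         length(caller_profiles), call. = FALSE)
  }
  tumor_id <- if (!is.null(true_variants$tumor_id) &&
                  nrow(true_variants) > 0) {
    true_variants$tumor_id[1]
  } else {
    "tumor"
  }
  always <- if (is.null(true_variants$always_detected)) {
    rep(FALSE, nrow(true_variants))
  } else {
    true_variants$always_detected
  }
  out <- list()
  for (cname in names(caller_profiles)) {
    prof <- caller_profiles[[cname]]
    obs <- with_rng(derive_seed(seed, paste0("caller_", cname)), {
      n <- nrow(true_variants)
      det <- if (n > 0) {
        stats::runif(n) < prof$sensitivity | always
      } else {
        logical(0)
      }
      tv <- true_variants[det, , drop = FALSE]
      rows <- draw_read_counts(tv$vaf, mean_depth, prof$strand_bias_prob)
      true_obs <- if (nrow(tv) > 0) {
        data.frame(tumor_id = tumor_id, caller_id = cname,
                   chrom = tv$chrom, pos = tv$pos, ref = tv$ref, alt = tv$alt,
                   passed = TRUE, rows, stringsAsFactors = FALSE)
      } else {
        NULL
      }
      n_fp <- stats::rpois(1, prof$fp_rate * target_mb)
      fp_obs <- if (n_fp > 0) {
        chrom <- paste0("chr", sample(1:22, n_fp, replace = TRUE))
        pos <- sample.int(100000000L, n_fp) + 100000000L
        al <- random_snv_alleles(n_fp)
        vaf <- stats::runif(n_fp, 0.03, 0.25)
        rows_fp <- draw_read_counts(vaf, mean_depth,
                                    max(prof$strand_bias_prob, 0.3))
        data.frame(tumor_id = tumor_id, caller_id = cname,
                   chrom = chrom, pos = pos, ref = al$ref, alt = al$alt,
                   passed = TRUE, rows_fp, stringsAsFactors = FALSE)
      } else {
        NULL
      }
      res <- rbind(true_obs, fp_obs)
      if (is.null(res)) {
        res <- data.frame(tumor_id = character(0), caller_id = character(0),
                          chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          passed = logical(0), fwd_alt = integer(0),
                          rev_alt = integer(0), fwd_depth = integer(0),
                          rev_depth = integer(0), stringsAsFactors = FALSE)
      }
      res
    })
    out[[cname]] <- obs
  }
  out
}

# Strand-split read-count draws: total depth Poisson around mean_depth,
# strands split evenly, alt reads binomial at the expected VAF per strand.
# A strand-bias event moves all alt reads to the forward strand.
draw_read_counts <- function(vaf, mean_depth, strand_bias_prob) {
  n <- length(vaf)
  if (n == 0) {
    return(data.frame(fwd_alt = integer(0), rev_alt = integer(0),
                      fwd_depth = integer(0), rev_depth = integer(0)))
  }
  depth <- pmax(stats::rpois(n, mean_depth), 4L)
  fwd_depth <- stats::rbinom(n, depth, 0.5)
  rev_depth <- depth - fwd_depth
  fwd_alt <- stats::rbinom(n, fwd_depth, pmin(vaf, 1))
  rev_alt <- stats::rbinom(n, rev_depth, pmin(vaf, 1))
  biased <- stats::runif(n) < strand_bias_prob
  fwd_alt[biased] <- pmin(fwd_depth[biased], fwd_alt[biased] + rev_alt[biased])
  rev_alt[biased] <- 0L
  data.frame(fwd_alt = as.integer(fwd_alt), rev_alt = as.integer(rev_alt),
             fwd_depth = as.integer(fwd_depth),
             rev_depth = as.integer(rev_depth))
}

#' Simulate a two-subtype RNA count matrix
#'
#' Negative-binomial counts with log-normal baseline means. Each gene's
#' baseline mean is a deterministic function of its identifier, so separately
#' simulated cohorts that share gene ids also share gene-level baseline
#' expression (as real cohorts do); sampling noise and library sizes are
#' driven by `seed`. Genes in the immune (and optionally stromal) signature
#' have their mean multiplied by `2^immune_effect_log2fc` (resp. half that
#' effect on the log2 scale) in immune-high samples. Library-size factors
#' span exactly `libsize_spread`-fold so between-sample normalization is
#' non-trivial.
#'
#' @param expr_spec list, see [cohort_config()].
#' @param subtype_labels character vector of "IM-H"/"IM-L" per sample; names
#'   (if present) become column names.
#' @param immune_geneset character vector of immune signature gene ids.
#' @param seed integer seed.
#' @param stromal_geneset optional character vector of stromal gene ids.
#' @return integer matrix, genes x samples.
#' @export
# Per-gene baseline means are a deterministic function of the gene id alone,
# so that independently simulated cohorts sharing gene identifiers also share
# gene-level baseline expression, as real cohorts do (a gene's typical
# abundance is a property of the gene, not of the cohort). Each id is hashed
# and the hash seeds a one-draw lognormal; the caller's RNG stream is
# preserved.
gene_baselines <- function(ids, baseline_mean) {
  with_rng(0, vapply(ids, function(id) {
    h <- 0
    for (k in utf8ToInt(id)) h <- (h * 131 + k) %% 2147483647
    set.seed(as.integer(h))
    stats::rlnorm(1, meanlog = log(baseline_mean), sdlog = 1)
  }, numeric(1), USE.NAMES = FALSE))
}

simulate_expression <- function(expr_spec, subtype_labels, immune_geneset,
                                seed, stromal_geneset = NULL) {
  n_genes <- as.integer(expr_spec$n_genes)
  n_samples <- length(subtype_labels)
  special <- unique(c(immune_geneset, stromal_geneset))
  if (length(special) > n_genes) {
    stop("expr_spec$n_genes smaller than the supplied gene sets", call. = FALSE)
  }
  filler <- paste0("G", sprintf("%05d", seq_len(n_genes)))
  genes <- c(special, setdiff(filler, special))[seq_len(n_genes)]
  base <- gene_baselines(genes, expr_spec$baseline_mean)
  with_rng(seed, {
    mu <- matrix(base, nrow = n_genes, ncol = n_samples)
    imh <- subtype_labels == "IM-H"
    if (any(imh)) {
      fc_imm <- 2^expr_spec$immune_effect_log2fc
      mu[genes %in% immune_geneset, imh] <-
        mu[genes %in% immune_geneset, imh, drop = FALSE] * fc_imm
      if (length(stromal_geneset) > 0) {
        fc_str <- 2^(expr_spec$immune_effect_log2fc / 2)
        str_only <- genes %in% setdiff(stromal_geneset, immune_geneset)
        mu[str_only, imh] <- mu[str_only, imh, drop = FALSE] * fc_str
      }
    }
    spread <- max(expr_spec$libsize_spread, 1)
    lf <- stats::runif(n_samples)
    if (n_samples >= 2 && diff(range(lf)) > 0) {
      lf <- 1 + (lf - min(lf)) / (max(lf) - min(lf)) * (spread - 1)
    } else {
      lf <- rep(1, n_samples)
    }
    mu <- sweep(mu, 2, lf, `*`)
    size <- 1 / expr_spec$dispersion
    counts <- matrix(stats::rnbinom(n_genes * n_samples,
                                    mu = as.numeric(mu), size = size),
                     nrow = n_genes, ncol = n_samples)
    storage.mode(counts) <- "integer"
    rownames(counts) <- genes
    colnames(counts) <- if (!is.null(names(subtype_labels))) {
      names(subtype_labels)
    } else {
      paste0("S", sprintf("%02d", seq_len(n_samples)))
    }
    counts
  })
}

#' Simulate survival records with a subtype-dependent hazard
#'
#' Exponential event times with hazard
#' `baseline_hazard * exp(log_hr_subtype)` for immune-low samples and
#' `baseline_hazard` otherwise, under independent uniform administrative
#' censoring calibrated to the requested overall censoring fraction.
#'
#' @param subtype_labels character vector ("IM-H"/"IM-L"); names used as ids.
#' @param surv_spec list with `baseline_hazard`, `log_hr_subtype`,
#'   `censor_rate` (see [cohort_config()]).
#' @param seed integer seed.
#' @param hazard_scale multiplier on the baseline hazard (used for the
#'   overall-survival endpoint).
#' @return data.frame with sample_id, group, time, event.
#' @export
simulate_survival <- function(subtype_labels, surv_spec, seed,
                              hazard_scale = 1) {
  n <- length(subtype_labels)
  ids <- if (!is.null(names(subtype_labels))) {
    names(subtype_labels)
  } else {
    paste0("S", sprintf("%02d", seq_len(n)))
  }
  lambda <- surv_spec$baseline_hazard * hazard_scale *
    exp(surv_spec$log_hr_subtype * (subtype_labels == "IM-L"))
  with_rng(seed, {
    t_event <- stats::rexp(n, rate = lambda)
    if (surv_spec$censor_rate > 0 && n > 0) {
      u <- censoring_horizon(lambda, surv_spec$censor_rate)
      c_time <- stats::runif(n, 0, u)
      event <- as.integer(t_event <= c_time)
      time <- pmin(t_event, c_time)
    } else {
      event <- rep(1L, n)
      time <- t_event
    }
    data.frame(sample_id = ids, group = unname(subtype_labels),
               time = time, event = event, stringsAsFactors = FALSE)
  })
}

# Upper bound u of the Uniform(0, u) censoring time such that the expected
# censored fraction P(C < T) matches `censor_rate`:
# P(T > C) = (1 - exp(-lambda u)) / (lambda u) for exponential T.
censoring_horizon <- function(lambda, censor_rate) {
  f <- function(u) mean((1 - exp(-lambda * u)) / (lambda * u)) - censor_rate
  # f decreases from 1 - censor_rate at u -> 0 to -censor_rate as u -> Inf
  lo <- 1e-8
  hi <- 1
  while (f(hi) > 0 && hi < 1e12) hi <- hi * 10
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}
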