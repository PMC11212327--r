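# Independent oracles used by the test suite. These deliberately avoid the
# package's own code paths: direct formulas, full enumeration, or a second
# implementation from the published method description.

# Two-sided Fisher exact p by full hypergeometric enumeration over the
# 2x2 tables with the observed margins.
oracle_fisher_2x2 <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  n <- sum(tab)
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Textbook two-group log-rank statistic: observed minus expected with the
# hypergeometric variance at each distinct event time.
oracle_logrank <- function(time, event, group) {
  g <- as.integer(factor(group)) == 1L
  times <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & g)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) {
      V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  chisq <- (O - E)^2 / V
  list(chi_squared = chisq,
       p_value = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Hand product-limit estimator over distinct event times.
oracle_km <- function(time, event) {
  times <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = numeric(0), surv = numeric(0))
  for (t in times) {
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
    out <- rbind(out, data.frame(time = t, surv = s))
  }
  out
}

# Independent implementation of trimmed-mean-of-M-values normalization from
# the published method description (doubly trimmed, precision-weighted).
oracle_tmm <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  lib <- colSums(counts)
  f75 <- apply(counts, 2, function(x) stats::quantile(x, 0.75)) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  pair_factor <- function(obs_col, ref_col, lib_o, lib_r) {
    keep0 <- obs_col > 0 & ref_col > 0
    o <- obs_col[keep0] / lib_o
    r <- ref_col[keep0] / lib_r
    M <- log2(o / r)
    A <- 0.5 * log2(o * r)
    w <- (lib_o - obs_col[keep0]) / (lib_o * obs_col[keep0]) +
      (lib_r - ref_col[keep0]) / (lib_r * ref_col[keep0])
    n <- length(M)
    loM <- floor(n * trim_m) + 1
    hiM <- n + 1 - loM
    loA <- floor(n * trim_a) + 1
    hiA <- n + 1 - loA
    rM <- rank(M)
    rA <- rank(A)
    keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (max(abs(M[keep])) < 1e-6) return(1)
    2^(sum(w[keep] * M[keep]) / sum(w[keep]))
  }
  f <- vapply(seq_len(ncol(counts)), function(j) {
    pair_factor(counts[, j], counts[, ref], lib[j], lib[ref])
  }, numeric(1))
  f / exp(mean(log(f)))
}

# Brute-force per-variant F1/F2 predicate evaluation by direct substitution.
oracle_categorize <- function(df, thr = 0.05) {
  vapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    strands <- r$fwd_vaf > thr && r$rev_vaf > thr
    f1 <- r$n_passed >= 2 && strands
    f2 <- strands && (r$pan_cancer_count > 3 || r$in_clinvar ||
                        r$acmg_tier %in% c("1", "2"))
    if (f1 && f2) "both" else if (f2) "hotspot_rescue"
    else if (f1) "other_somatic" else "rejected"
  }, character(1))
}

# Random consensus-variant table generator for filter-oracle tests.
random_consensus_table <- function(n, seed) {
  withr::with_seed(seed, {
    data.frame(
      key = paste0("chr1:", seq_len(n), ":A:T"),
      n_passed = sample(0:3, n, replace = TRUE),
      fwd_vaf = round(stats::runif(n, 0, 0.3), 3),
      rev_vaf = round(stats::runif(n, 0, 0.3), 3),
      pan_cancer_count = sample(0:10, n, replace = TRUE),
      in_clinvar = sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(.2, .8)),
      acmg_tier = sample(c("1", "2", "none"), n, replace = TRUE,
                         prob = c(.1, .1, .8)),
      stringsAsFactors = FALSE)
  })
}

# Small expression spec used across subtyping tests.
small_expr_spec <- function(n_genes = 600, lfc = 2) {
  list(n_genes = n_genes, immune_effect_log2fc = lfc, dispersion = 0.3,
       baseline_mean = 80, libsize_spread = 3)
}

# Observation row constructor for consensus unit tests.
obs_row <- function(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                    passed = TRUE, fwd_alt = 20L, rev_alt = 20L,
                    fwd_depth = 100L, rev_depth = 100L,
                    caller_id = "mutect", tumor_id = "T1") {
  data.frame(tumor_id = tumor_id, caller_id = caller_id, chrom = chrom,
             pos = pos, ref = ref, alt = alt, passed = passed,
             fwd_alt = fwd_alt, rev_alt = rev_alt, fwd_depth = fwd_depth,
             rev_depth = rev_depth, stringsAsFactors = FALSE)
}

empty_obs <- function(caller_id = "mutect") {
  obs_row(caller_id = caller_id)[0, ]
}

# Tiny cohort config for fast end-to-end tests.
tiny_cohort_config <- function(seed = 1, n_tumors = 3,
                               n_variants = 40, n_artifact_loci = 10, ...) {
  cohort_config(
    n_tumors = n_tumors, n_true_variants_mean = n_variants,
    n_artifact_loci = n_artifact_loci,
    expr_spec = list(n_genes = 300, n_expr_samples = min(n_tumors, 6),
                     n_immune_genes = 40, immune_effect_log2fc = 2,
                     dispersion = 0.3, baseline_mean = 80,
                     libsize_spread = 3, p_immune_high = 0.5),
    seed = seed, ...)
}

noiseless_profiles <- function() {
  list(mutect = list(sensitivity = 1, fp_rate = 0, strand_bias_prob = 0),
       mutect2 = list(sensitivity = 1, fp_rate = 0, strand_bias_prob = 0),
       ionreporter = list(sensitivity = 1, fp_rate = 0, strand_bias_prob = 0))
}
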