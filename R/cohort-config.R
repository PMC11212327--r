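#' Cohort simulation configuration
#'
#' Builds and validates the configuration object consumed by
#' [simulate_cohort()]. Defaults emulate the 21-tumor pulmonary sarcomatoid
#' carcinoma study cohort that the pipeline was designed around: an average
#' of 285 true somatic mutations per tumor over a 50 Mb exome target at a
#' mean depth of 225x, driver prevalences of 57% TP53, 28% KRAS and 14%
#' MET exon-14 skipping (mutually exclusive with TP53/KRAS), roughly half
#' the tumors with branched subclonal architecture, a 17-sample two-subtype
#' expression cohort with an immune-signature effect, and exponential
#' survival with a ten-fold hazard ratio disfavouring the immune-low group.
#'
#' @param n_tumors number of tumors in the cohort.
#' @param n_true_variants_mean mean number of planted true somatic variants
#'   per tumor (Poisson).
#' @param driver_prevalence named numeric vector of per-tumor planting
#'   probabilities for driver genes. A gene named `"MET"` is treated as the
#'   exon-14-skipping splice driver and kept mutually exclusive with
#'   `TP53`/`KRAS` unless a prevalence of 1 forces co-occurrence.
#' @param caller_profiles named list of exactly three caller profiles, each
#'   a list with `sensitivity` (detection probability per true variant),
#'   `fp_rate` (false positives per Mb of target) and `strand_bias_prob`
#'   (probability that a reported variant's alt reads collapse onto one
#'   strand).
#' @param mean_depth mean sequencing depth used for read-count draws.
#' @param target_mb sequencing target size in megabases (TMB denominator
#'   and false-positive scaling).
#' @param n_artifact_loci number of recurrent pooled-normal artifact loci
#'   injected into every tumor's call sets (removed by the pooled-normal
#'   filter downstream).
#' @param subclone_spec list with `p_branched`, `max_branches`,
#'   `purity_range` (within (0,1]), `trunk_fraction` (share of mutations on
#'   the trunk), `trunk_driver_prob` (probability a driver maps to the
#'   trunk) and `convergent_tp53_prob` (probability of planting a second,
#'   distinct TP53 driver in a TP53-mutant tumor).
#' @param expr_spec list with `n_genes`, `n_expr_samples`, `n_immune_genes`,
#'   `immune_effect_log2fc` (>= 0), `dispersion` (> 0, negative-binomial),
#'   `baseline_mean` (> 0), `libsize_spread` (max/min library-size factor,
#'   >= 2 so normalization is non-trivial) and `p_immune_high`.
#' @param surv_spec list with `baseline_hazard` (> 0, events per month for
#'   the reference immune-high group), `log_hr_subtype` (log hazard ratio
#'   of the immune-low group), `censor_rate` (in [0,1)) and
#'   `os_hazard_scale` (overall-survival baseline relative to
#'   recurrence-free survival).
#' @param seed integer master seed; all stage seeds are derived from it.
#'
#' @return an object of class `cohort_config` (a validated list).
#' @export
#' @examples
#' cfg <- cohort_config(n_tumors = 4, n_true_variants_mean = 30, seed = 7)
#' cfg$n_tumors
cohort_config <- function(n_tumors = 21,
                          n_true_variants_mean = 285,
                          driver_prevalence = c(TP53 = 12 / 21,
                                                KRAS = 6 / 21,
                                                MET = 3 / 21),
                          caller_profiles = default_caller_profiles(),
                          mean_depth = 225,
                          target_mb = 50,
                          n_artifact_loci = 30,
                          subclone_spec = list(p_branched = 0.5,
                                               max_branches = 3,
                                               purity_range = c(0.3, 0.9),
                                               trunk_fraction = 0.6,
                                               trunk_driver_prob = 0.8,
                                               convergent_tp53_prob = 0.05),
                          expr_spec = list(n_genes = 2000,
                                           n_expr_samples = 17,
                                           n_immune_genes = 100,
                                           immune_effect_log2fc = 1.5,
                                           dispersion = 0.3,
                                           baseline_mean = 100,
                                           libsize_spread = 3,
                                           p_immune_high = 10 / 17),
                          surv_spec = list(baseline_hazard = 0.01,
                                           log_hr_subtype = log(10),
                                           censor_rate = 0.45,
                                           os_hazard_scale = 0.5),
                          seed = 1L) {
  cfg <- list(n_tumors = n_tumors,
              n_true_variants_mean = n_true_variants_mean,
              driver_prevalence = driver_prevalence,
              caller_profiles = caller_profiles,
              mean_depth = mean_depth,
              target_mb = target_mb,
              n_artifact_loci = n_artifact_loci,
              subclone_spec = subclone_spec,
              expr_spec = expr_spec,
              surv_spec = surv_spec,
              seed = seed)
  validate_cohort_config(cfg)
  class(cfg) <- "cohort_config"
  cfg
}

#' Default three-caller observation profiles
#'
#' Sensitivity, false-positive rate (per Mb) and strand-bias probability for
#' the three emulated somatic callers. Slot `ionreporter` is the designated
#' primary caller whose strand-split depths feed the strand-VAF filter.
#'
#' @return named list of three caller profiles.
#' @export
default_caller_profiles <- function() {
  list(
    mutect      = list(sensitivity = 0.95, fp_rate = 0.5, strand_bias_prob = 0.02),
    mutect2     = list(sensitivity = 0.90, fp_rate = 1.0, strand_bias_prob = 0.02),
    ionreporter = list(sensitivity = 0.90, fp_rate = 1.5, strand_bias_prob = 0.05)
  )
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop("invalid cohort_config: `", field, "` must be a probability in [0, 1]",
         call. = FALSE)
  }
}

check_pos <- function(x, field, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop("invalid cohort_config: `", field, "` must be ",
         if (strict) "a positive number" else "a non-negative number",
         call. = FALSE)
  }
}

validate_cohort_config <- function(cfg) {
  check_pos(cfg$n_tumors, "n_tumors", strict = FALSE)
  if (cfg$n_tumors != floor(cfg$n_tumors)) {
    stop("invalid cohort_config: `n_tumors` must be an integer count",
         call. = FALSE)
  }
  check_pos(cfg$n_true_variants_mean, "n_true_variants_mean")
  check_prob(cfg$driver_prevalence, "driver_prevalence")
  if (length(cfg$caller_profiles) != 3L) {
    stop("invalid cohort_config: `caller_profiles` must name exactly 3 callers",
         call. = FALSE)
  }
  for (nm in names(cfg$caller_profiles)) {
    p <- cfg$caller_profiles[[nm]]
    check_prob(p$sensitivity, paste0("caller_profiles$", nm, "$sensitivity"))
    check_pos(p$fp_rate, paste0("caller_profiles$", nm, "$fp_rate"), strict = FALSE)
    check_prob(p$strand_bias_prob,
               paste0("caller_profiles$", nm, "$strand_bias_prob"))
  }
  check_pos(cfg$mean_depth, "mean_depth")
  check_pos(cfg$target_mb, "target_mb")
  ss <- cfg$subclone_spec
  check_prob(ss$p_branched, "subclone_spec$p_branched")
  check_pos(ss$max_branches, "subclone_spec$max_branches", strict = FALSE)
  pr <- ss$purity_range
  if (!is.numeric(pr) || length(pr) != 2L || any(pr <= 0) || any(pr > 1) ||
      pr[1] > pr[2]) {
    stop("invalid cohort_config: `subclone_spec$purity_range` must lie within (0, 1]",
         call. = FALSE)
  }
  check_prob(ss$trunk_driver_prob, "subclone_spec$trunk_driver_prob")
  es <- cfg$expr_spec
  check_pos(es$n_genes, "expr_spec$n_genes", strict = FALSE)
  check_pos(es$dispersion, "expr_spec$dispersion")
  check_pos(es$baseline_mean, "expr_spec$baseline_mean")
  if (!is.numeric(es$immune_effect_log2fc) || es$immune_effect_log2fc < 0) {
    stop("invalid cohort_config: `expr_spec$immune_effect_log2fc` must be >= 0",
         call. = FALSE)
  }
  sv <- cfg$surv_spec
  check_pos(sv$baseline_hazard, "surv_spec$baseline_hazard")
  if (!is.numeric(sv$censor_rate) || sv$censor_rate < 0 || sv$censor_rate >= 1) {
    stop("invalid cohort_config: `surv_spec$censor_rate` must be in [0, 1)",
         call. = FALSE)
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || !is.finite(cfg$seed)) {
    stop("invalid cohort_config: `seed` must be a single integer", call. = FALSE)
  }
  invisible(cfg)
}
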