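test_that("cohort_config validates fields with informative errors", {
  expect_error(cohort_config(n_tumors = -1), "n_tumors")
  expect_error(cohort_config(n_true_variants_mean = 0), "n_true_variants_mean")
  expect_error(cohort_config(driver_prevalence = c(TP53 = 1.5)),
               "driver_prevalence")
  expect_error(cohort_config(caller_profiles = noiseless_profiles()[1:2]),
               "exactly 3")
  expect_error(
    cohort_config(subclone_spec = list(p_branched = 0.5, max_branches = 3,
                                       purity_range = c(0, 1),
                                       trunk_fraction = 0.6,
                                       trunk_driver_prob = 0.8,
                                       convergent_tp53_prob = 0.05)),
    "purity_range")
  expect_s3_class(cohort_config(n_tumors = 2), "cohort_config")
})

test_that("subclone structures respect the pigeonhole and gap constraints", {
  spec <- list(p_branched = 0.5, max_branches = 3)
  for (s in 1:60) {
    st <- simulate_subclone_structure(spec, seed = 1000 + s,
                                      min_ccf_gap = 0.1)
    expect_equal(st$ccf[1], 1)
    expect_equal(st$parent[1], 0L)
    k <- length(st$ccf)
    if (st$branched) {
      expect_gte(k, 3L)
      sib <- st$ccf[st$parent == 1L]
      expect_lte(sum(sib), 0.9 + 1e-12)
      # all pairwise cluster gaps at least min_ccf_gap
      expect_gte(min(abs(diff(sort(st$ccf)))), 0.1 - 1e-12)
    } else if (k == 3L) {
      # heavy linear chains: nested CCFs sum above the trunk so sibling
      # placement is infeasible and the chain is identifiable
      expect_gt(sum(st$ccf[2:3]), 1.1)
      expect_true(all(diff(st$ccf) < 0))
    }
  }
})

test_that("mutation CCFs stay in (0, 1.2] and track their clusters", {
  st <- list(parent = c(0L, 1L), ccf = c(1, 0.4), branched = FALSE)
  m <- simulate_mutation_ccfs(st, n_per_cluster = c(30, 20), sd = 0.03,
                              seed = 9)
  expect_equal(nrow(m), 50L)
  expect_equal(as.integer(table(m$cluster)), c(30L, 20L))
  expect_true(all(m$ccf > 0 & m$ccf <= 1.2))
  expect_equal(mean(m$ccf[m$cluster == 2]), 0.4, tolerance = 0.03)
})

test_that("driver planting honours prevalence bounds and MET exclusivity", {
  prev <- c(TP53 = 0.6, KRAS = 0.3, MET = 0.5)
  draws <- with_rng(314, {
    replicate(400, plant_drivers(prev, convergent_tp53_prob = 0),
              simplify = FALSE)
  })
  for (d in draws) {
    if ("MET" %in% d) expect_false(any(c("TP53", "KRAS") %in% d))
  }
  # TP53 frequency near its prevalence (MET exclusion removes a few)
  tp53_rate <- mean(vapply(draws, function(d) "TP53" %in% d, logical(1)))
  expect_gt(tp53_rate, 0.4)
  # prevalence 1 forces the gene even against the exclusivity rule
  forced <- with_rng(7, {
    replicate(50, plant_drivers(c(TP53 = 1, MET = 1),
                                convergent_tp53_prob = 0), simplify = FALSE)
  })
  expect_true(all(vapply(forced, function(d) {
    all(c("TP53", "MET") %in% d)
  }, logical(1))))
  # convergent probability 1 always yields a second TP53 hit
  conv <- with_rng(8, plant_drivers(c(TP53 = 1), convergent_tp53_prob = 1))
  expect_equal(sum(conv == "TP53"), 2L)
})

test_that("caller sensitivity controls the detection rate", {
  n <- 1500
  al <- random_snv_alleles(n)
  tv <- data.frame(chrom = "chr1", pos = seq_len(n), ref = al$ref,
                   alt = al$alt, vaf = 0.3, tumor_id = "T1",
                   stringsAsFactors = FALSE)
  profiles <- list(
    mutect = list(sensitivity = 0.8, fp_rate = 0, strand_bias_prob = 0),
    mutect2 = list(sensitivity = 1, fp_rate = 0, strand_bias_prob = 0),
    ionreporter = list(sensitivity = 0, fp_rate = 0, strand_bias_prob = 0))
  obs <- simulate_caller_observations(tv, profiles, seed = 55)
  # detection fraction within the binomial 99.9% interval around 0.8
  rate <- nrow(obs$mutect) / n
  expect_lt(abs(rate - 0.8), 3.29 * sqrt(0.8 * 0.2 / n))
  expect_equal(nrow(obs$mutect2), n)
  expect_equal(nrow(obs$ionreporter), 0L)
  expect_error(simulate_caller_observations(tv, profiles[1:2], seed = 1),
               "exactly 3")
})

test_that("false positives appear at the configured per-Mb rate", {
  tv <- data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                   alt = character(0), vaf = numeric(0),
                   stringsAsFactors = FALSE)
  profiles <- list(
    mutect = list(sensitivity = 1, fp_rate = 2, strand_bias_prob = 0),
    mutect2 = list(sensitivity = 1, fp_rate = 0, strand_bias_prob = 0),
    ionreporter = list(sensitivity = 1, fp_rate = 0, strand_bias_prob = 0))
  counts <- vapply(1:40, function(s) {
    obs <- simulate_caller_observations(tv, profiles, seed = 9000 + s,
                                        target_mb = 50)
    nrow(obs$mutect)
  }, numeric(1))
  # Poisson mean 100: the average of 40 draws sits within 5 sd of the mean
  expect_lt(abs(mean(counts) - 100), 5 * sqrt(100 / 40))
  expect_equal(sum(vapply(1:5, function(s) {
    nrow(simulate_caller_observations(tv, profiles, seed = s)$mutect2)
  }, numeric(1))), 0)
})

test_that("strand bias collapses alt reads onto the forward strand", {
  n <- 300
  al <- random_snv_alleles(n)
  tv <- data.frame(chrom = "chr1", pos = seq_len(n), ref = al$ref,
                   alt = al$alt, vaf = 0.4, stringsAsFactors = FALSE)
  profiles <- list(
    mutect = list(sensitivity = 1, fp_rate = 0, strand_bias_prob = 1),
    mutect2 = list(sensitivity = 1, fp_rate = 0, strand_bias_prob = 0),
    ionreporter = list(sensitivity = 1, fp_rate = 0, strand_bias_prob = 0))
  obs <- simulate_caller_observations(tv, profiles, seed = 12)
  expect_true(all(obs$mutect$rev_alt == 0))
  # depth conservation: alt counts never exceed strand depths
  for (cn in names(obs)) {
    o <- obs[[cn]]
    expect_true(all(o$fwd_alt <= o$fwd_depth))
    expect_true(all(o$rev_alt <= o$rev_depth))
    expect_true(all(o$fwd_depth + o$rev_depth >= 4))
  }
})

test_that("expression simulation plants the immune effect and library spread", {
  imm <- paste0("IMM", sprintf("%04d", 1:50))
  spec <- list(n_genes = 800, immune_effect_log2fc = 2, dispersion = 0.3,
               baseline_mean = 80, libsize_spread = 3)
  labels <- stats::setNames(rep(c("IM-H", "IM-L"), each = 8),
                            paste0("S", 1:16))
  counts <- simulate_expression(spec, labels, imm, seed = 3)
  expect_equal(dim(counts), c(800L, 16L))
  expect_true(is.integer(counts))
  expect_true(all(counts >= 0))
  expect_equal(rownames(counts)[1:50], imm)
  # library-size-corrected immune fold change near the planted 4x
  cpm <- sweep(counts, 2, colSums(counts), `/`) * 1e6
  ratio <- rowMeans(cpm[imm, labels == "IM-H"]) /
    pmax(rowMeans(cpm[imm, labels == "IM-L"]), 1e-9)
  expect_equal(median(log2(ratio)), 2, tolerance = 0.4)
  # non-signature genes show no systematic effect
  others <- setdiff(rownames(counts), imm)
  ratio0 <- rowMeans(cpm[others, labels == "IM-H"]) /
    pmax(rowMeans(cpm[others, labels == "IM-L"]), 1e-9)
  expect_equal(median(log2(ratio0)), 0, tolerance = 0.3)
  # zero planted effect removes the immune difference
  spec0 <- spec
  spec0$immune_effect_log2fc <- 0
  counts0 <- simulate_expression(spec0, labels, imm, seed = 3)
  cpm0 <- sweep(counts0, 2, colSums(counts0), `/`) * 1e6
  r0 <- rowMeans(cpm0[imm, labels == "IM-H"]) /
    pmax(rowMeans(cpm0[imm, labels == "IM-L"]), 1e-9)
  expect_equal(median(log2(r0)), 0, tolerance = 0.3)
  expect_error(simulate_expression(list(n_genes = 10,
                                        immune_effect_log2fc = 1,
                                        dispersion = 0.3, baseline_mean = 50,
                                        libsize_spread = 2),
                                   labels, imm, seed = 1),
               "smaller than the supplied gene sets")
})

test_that("survival simulation hits the planted hazard ratio and censoring", {
  labels <- rep(c("IM-H", "IM-L"), each = 400)
  spec <- list(baseline_hazard = 0.01, log_hr_subtype = log(10),
               censor_rate = 0, os_hazard_scale = 0.5)
  d <- simulate_survival(labels, spec, seed = 21)
  expect_true(all(d$event == 1))
  # exponential means: 1/lambda per group
  expect_equal(mean(d$time[d$group == "IM-H"]), 100, tolerance = 0.15)
  expect_equal(mean(d$time[d$group == "IM-L"]), 10, tolerance = 0.15)
  # requested censoring fraction is achieved on average
  spec$censor_rate <- 0.45
  cens <- mean(1 - simulate_survival(labels, spec, seed = 22)$event)
  expect_equal(cens, 0.45, tolerance = 0.06)
  expect_true(all(simulate_survival(labels, spec, seed = 23)$time > 0))
})

test_that("simulate_cohort is deterministic and writes consistent files", {
  cfg <- tiny_cohort_config(seed = 505, n_tumors = 3)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_cohort(cfg, out_dir = d1)
  simulate_cohort(cfg, out_dir = d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = paste("file", f))
  }
  # a different seed changes the data
  cfg2 <- tiny_cohort_config(seed = 506, n_tumors = 3)
  d3 <- withr::local_tempdir()
  simulate_cohort(cfg2, out_dir = d3)
  expect_false(identical(readLines(file.path(d1, "annotations.tsv")),
                         readLines(file.path(d3, "annotations.tsv"))))
})

test_that("cohort ground truth is internally consistent and round-trips", {
  cfg <- tiny_cohort_config(seed = 71, n_tumors = 4)
  dir <- withr::local_tempdir()
  cohort <- simulate_cohort(cfg, out_dir = dir)
  truth <- cohort$truth
  expect_equal(length(truth$tumors), 4L)
  for (t in truth$tumors) {
    expect_true(t$purity > 0 && t$purity <= 1)
    expect_equal(t$tree$ccf[1], 1)
    # every variant's CCF equals its subclone's CCF; VAF = ccf*purity/2
    v <- t$variants
    expect_equal(v$ccf, t$tree$ccf[v$subclone])
    expect_equal(v$vaf, v$ccf * t$purity / 2)
  }
  # all subtype labels valid; expression only for the configured samples
  expect_true(all(unlist(truth$subtype) %in% c("IM-H", "IM-L")))
  expect_equal(colnames(cohort$counts), truth$expr_samples)
  # JSON round-trip preserves purity at full precision
  back <- read_ground_truth(file.path(dir, "ground_truth.json"))
  expect_equal(unname(unlist(back$purity)), unname(truth$purity),
               tolerance = 1e-12)
  # counts and gene sets round-trip through their file formats
  expect_identical(read_counts_tsv(file.path(dir, "counts.tsv")),
                   cohort$counts)
  expect_identical(read_gmt(file.path(dir, "signatures.gmt")),
                   cohort$gene_sets)
})

test_that("an empty cohort simulates without error", {
  cfg <- tiny_cohort_config(seed = 1, n_tumors = 0)
  cohort <- simulate_cohort(cfg, out_dir = NULL)
  expect_equal(length(cohort$truth$tumors), 0L)
  expect_equal(nrow(cohort$clinical), 0L)
})
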