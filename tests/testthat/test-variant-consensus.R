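test_that("normalize_variant trims shared suffix then prefix", {
  nv <- normalize_variant("chr1", 100, "AT", "AC")
  expect_equal(nv$pos, 101L)
  expect_equal(nv$ref, "T")
  expect_equal(nv$alt, "C")
  expect_equal(nv$key, "chr1:101:T:C")
  # multi-base with both shared prefix and suffix
  nv2 <- normalize_variant("chr2", 500, "CAT", "CGT")
  expect_equal(nv2$pos, 501L)
  expect_equal(nv2$ref, "A")
  expect_equal(nv2$alt, "G")
  # deletion keeps the anchor base (alt cannot shrink below 1)
  nv3 <- normalize_variant("chr3", 100, "ATG", "A")
  expect_equal(nv3$pos, 100L)
  expect_equal(nv3$ref, "ATG")
  expect_equal(nv3$alt, "A")
})

test_that("normalize_variant is idempotent", {
  cases <- list(c("chr1", "100", "AT", "AC"), c("chr1", "7", "GGGT", "GGCT"),
                c("chrX", "42", "T", "G"), c("chr5", "9", "TTA", "T"))
  for (cs in cases) {
    n1 <- normalize_variant(cs[1], as.integer(cs[2]), cs[3], cs[4])
    n2 <- normalize_variant(n1$chrom, n1$pos, n1$ref, n1$alt)
    expect_identical(n1, n2)
  }
})

test_that("normalize_variant rejects degenerate input", {
  expect_error(normalize_variant("chr1", 1, "A", "A"), "not a variant")
  expect_error(normalize_variant("chr1", 1, "", "T"), "non-empty")
  expect_error(normalize_variant("chr1", 1, "A", NA), "non-empty")
})

test_that("padded SNVs normalize back to the unpadded representation", {
  withr::with_seed(41, {
    for (i in 1:200) {
      al <- random_snv_alleles(1)
      pos <- sample.int(1e6, 1)
      want <- locus_key("chr1", pos, al$ref, al$alt)
      pre <- paste(sample(c("A", "C", "G", "T"), sample(0:3, 1),
                          replace = TRUE), collapse = "")
      suf <- paste(sample(c("A", "C", "G", "T"), sample(0:3, 1),
                          replace = TRUE), collapse = "")
      nv <- normalize_variant("chr1", pos - nchar(pre),
                              paste0(pre, al$ref, suf),
                              paste0(pre, al$alt, suf))
      expect_identical(nv$key, want)
    }
  })
})

test_that("merge_callers unifies padded representations of one event", {
  obs <- list(
    mutect = obs_row(pos = 100L, ref = "AT", alt = "AC"),
    mutect2 = obs_row(pos = 101L, ref = "T", alt = "C",
                      caller_id = "mutect2"),
    ionreporter = obs_row(pos = 99L, ref = "GAT", alt = "GAC",
                          caller_id = "ionreporter",
                          fwd_alt = 7L, rev_alt = 9L))
  m <- merge_callers(obs)
  expect_equal(nrow(m), 1L)
  expect_equal(m$key, "chr1:101:T:C")
  expect_equal(m$n_observed, 3)
  expect_equal(m$n_passed, 3)
  # strand counts come from the primary caller and report normalized alleles
  expect_equal(m$fwd_alt, 7)
  expect_equal(m$rev_alt, 9)
  expect_equal(m$vaf_source, "ionreporter")
  expect_equal(m$ref, "T")
  expect_equal(m$pos, 101L)
})

test_that("merge_callers falls back to the first observer for strand counts", {
  obs <- list(mutect = obs_row(fwd_alt = 11L),
              mutect2 = obs_row(caller_id = "mutect2", fwd_alt = 22L),
              ionreporter = empty_obs("ionreporter"))
  m <- merge_callers(obs)
  expect_equal(m$vaf_source, "mutect")
  expect_equal(m$fwd_alt, 11)
})

test_that("merge_callers errors on duplicate normalized loci within a caller", {
  dup <- rbind(obs_row(pos = 100L, ref = "AT", alt = "AC"),
               obs_row(pos = 101L, ref = "T", alt = "C"))
  expect_error(merge_callers(list(mutect = dup)), "chr1:101:T:C")
})

test_that("merge_callers rejects more than three callers", {
  obs <- stats::setNames(replicate(4, empty_obs(), simplify = FALSE),
                         paste0("c", 1:4))
  expect_error(merge_callers(obs), "at most 3")
})

test_that("merged loci equal the set union across callers (oracle)", {
  withr::with_seed(99, {
    make_obs <- function(cid) {
      n <- sample(20:40, 1)
      pos <- sample.int(5000, n)
      al <- random_snv_alleles(n)
      data.frame(tumor_id = "T1", caller_id = cid, chrom = "chr1", pos = pos,
                 ref = al$ref, alt = al$alt,
                 passed = sample(c(TRUE, FALSE), n, replace = TRUE),
                 fwd_alt = 10L, rev_alt = 10L, fwd_depth = 100L,
                 rev_depth = 100L, stringsAsFactors = FALSE)
    }
    obs <- list(mutect = make_obs("mutect"), mutect2 = make_obs("mutect2"),
                ionreporter = make_obs("ionreporter"))
    m <- merge_callers(obs)
    want <- sort(unique(unlist(lapply(obs, function(o) {
      locus_key(o$chrom, o$pos, o$ref, o$alt)
    }))))
    expect_identical(m$key, want)
    # per-caller verdict counts agree with direct membership checks
    for (cn in names(obs)) {
      ok <- locus_key(obs[[cn]]$chrom, obs[[cn]]$pos, obs[[cn]]$ref,
                      obs[[cn]]$alt)
      expect_identical(m[[paste0("observed.", cn)]], m$key %in% ok)
    }
  })
})

test_that("merge_callers is invariant to row order within a caller", {
  withr::with_seed(7, {
    n <- 30
    al <- random_snv_alleles(n)
    o <- data.frame(tumor_id = "T1", caller_id = "mutect", chrom = "chr1",
                    pos = sample.int(1e5, n), ref = al$ref, alt = al$alt,
                    passed = TRUE, fwd_alt = sample(5:30, n, replace = TRUE),
                    rev_alt = 10L, fwd_depth = 100L, rev_depth = 100L,
                    stringsAsFactors = FALSE)
    m1 <- merge_callers(list(mutect = o))
    m2 <- merge_callers(list(mutect = o[sample.int(n), ]))
    expect_identical(m1, m2)
  })
})

test_that("strand VAFs follow the per-strand ratio with a zero-depth guard", {
  v <- strand_vafs(list(fwd_alt = 6, fwd_depth = 100, rev_alt = 3,
                        rev_depth = 80))
  expect_equal(v$fwd_vaf, 0.06)
  expect_equal(v$rev_vaf, 0.0375)
  z <- strand_vafs(list(fwd_alt = 0, fwd_depth = 0, rev_alt = 5,
                        rev_depth = 50))
  expect_equal(z$fwd_vaf, 0)
  expect_equal(z$rev_vaf, 0.1)
})

test_that("F1/F2 worked examples behave per the filter definitions", {
  base <- data.frame(n_passed = 2, fwd_vaf = 0.06, rev_vaf = 0.06,
                     pan_cancer_count = 0L, in_clinvar = FALSE,
                     acmg_tier = "none")
  expect_true(apply_filter1(base))
  expect_false(apply_filter2(base))
  # strict threshold: exactly 5% fails both
  at_thr <- transform(base, fwd_vaf = 0.05)
  expect_false(apply_filter1(at_thr))
  expect_false(apply_filter2(at_thr))
  # single-caller hotspot: rescued by F2 only
  hot <- transform(base, n_passed = 1, pan_cancer_count = 10L)
  expect_false(apply_filter1(hot))
  expect_true(apply_filter2(hot))
  # ClinVar or tier evidence suffices for F2
  expect_true(apply_filter2(transform(base, in_clinvar = TRUE)))
  expect_true(apply_filter2(transform(base, acmg_tier = "2")))
  expect_false(apply_filter2(transform(base, pan_cancer_count = 3L)))
})

test_that("categorize matches the brute-force predicate oracle", {
  df <- random_consensus_table(400, seed = 12)
  res <- categorize(df)
  expect_identical(res$variants$category, oracle_categorize(df))
  expect_equal(unname(res$summary["total"]),
               sum(res$variants$category != "rejected"))
  expect_equal(nrow(res$retained), unname(res$summary["total"]))
})

test_that("pooled-normal filter removes exactly the listed loci", {
  df <- random_consensus_table(50, seed = 3)
  drop <- df$key[c(5, 10, 40)]
  expect_message(out <- pooled_normal_filter(df, drop), "removed 3")
  expect_identical(out$key, setdiff(df$key, drop))
  expect_silent(unchanged <- pooled_normal_filter(df, character(0)))
  expect_identical(unchanged, df)
})

test_that("annotate_consensus joins by key and defaults missing loci", {
  cons <- data.frame(key = c("chr1:10:A:T", "chr1:20:C:G"),
                     stringsAsFactors = FALSE)
  ann <- data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "T",
                    gene = "TP53", consequence = "stop_gain",
                    pan_cancer_count = 12L, in_clinvar = TRUE,
                    acmg_tier = "1", gene_role = "tsg",
                    pathogenic_aa_change = TRUE, stringsAsFactors = FALSE)
  expect_message(out <- annotate_consensus(cons, ann), "1 loci without")
  expect_equal(out$gene, c("TP53", "."))
  expect_equal(out$pan_cancer_count, c(12L, 0L))
  expect_equal(out$in_clinvar, c(TRUE, FALSE))
  expect_equal(out$acmg_tier, c("1", "none"))
})

test_that("TMB reproduces the worked value and scales linearly", {
  expect_equal(compute_tmb(285, 50), 5.7)
  expect_equal(compute_tmb(0, 50), 0)
  expect_equal(compute_tmb(570, 50), 2 * compute_tmb(285, 50))
  expect_equal(compute_tmb(data.frame(key = letters[1:10]), 50), 0.2)
  expect_error(compute_tmb(10, 0), "positive")
  expect_error(compute_tmb(10, -1), "positive")
})

test_that("caller VCFs round-trip through write/read", {
  obs <- rbind(obs_row(pos = 100L, fwd_alt = 12L, rev_alt = 8L,
                       fwd_depth = 110L, rev_depth = 90L),
               obs_row(pos = 250L, ref = "G", alt = "C", passed = FALSE,
                       fwd_alt = 3L, rev_alt = 0L, fwd_depth = 50L,
                       rev_depth = 60L))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_caller_vcf(obs, path)
  back <- read_caller_vcf(path, caller_id = "mutect", tumor_id = "T1")
  expect_equal(back[order(back$pos), c("chrom", "pos", "ref", "alt", "passed",
                                       "fwd_alt", "rev_alt", "fwd_depth",
                                       "rev_depth")],
               obs[order(obs$pos), c("chrom", "pos", "ref", "alt", "passed",
                                     "fwd_alt", "rev_alt", "fwd_depth",
                                     "rev_depth")],
               ignore_attr = TRUE)
  # pooled normal round-trip yields normalized keys
  pn <- data.frame(chrom = "chr2", pos = 77L, ref = "AT", alt = "AC",
                   stringsAsFactors = FALSE)
  pnp <- withr::local_tempfile(fileext = ".vcf")
  write_pooled_normal_vcf(pn, pnp)
  expect_identical(read_pooled_normal_vcf(pnp), "chr2:78:T:C")
})

test_that("consensus_pipeline computes TMB over the retained list", {
  obs <- list(
    mutect = rbind(obs_row(pos = 100L), obs_row(pos = 200L, ref = "G",
                                                alt = "A")),
    mutect2 = rbind(obs_row(pos = 100L, caller_id = "mutect2"),
                    obs_row(pos = 200L, ref = "G", alt = "A",
                            caller_id = "mutect2")),
    ionreporter = empty_obs("ionreporter"))
  ann <- data.frame(chrom = "chr1", pos = 100L, ref = "A", alt = "T",
                    gene = "TP53", consequence = "stop_gain",
                    pan_cancer_count = 12L, in_clinvar = TRUE,
                    acmg_tier = "1", gene_role = "tsg",
                    pathogenic_aa_change = TRUE, stringsAsFactors = FALSE)
  res <- suppressMessages(
    consensus_pipeline(obs, pooled_normal_loci = character(0),
                       annotations = ann, target_mb = 50))
  expect_equal(unname(res$summary["both"]), 1)
  expect_equal(unname(res$summary["other_somatic"]), 1)
  expect_equal(res$tmb, 2 / 50)
})
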