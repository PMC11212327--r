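#' @keywords internal
"_PACKAGE"

# Deterministic sub-seed derivation. Every stochastic stage draws its own
# seed from the user-facing seed plus a stage tag, so stages can be re-run
# independently and adding a stage never perturbs the streams of the others.
# Result always fits a 32-bit signed integer.
derive_seed <- function(seed, tag) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  chars <- utf8ToInt(as.character(tag))
  h <- sum(chars * seq_along(chars)) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h * 1009 + 1) %% 2147483647)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.
with_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Locus keys are plain strings "chrom:pos:ref:alt" over normalized alleles.
locus_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# Consistent number formatting for file output so runs are byte-identical
# across platforms.
fmt_num <- function(x, digits = 6) {
  formatC(x, digits = digits, format = "g")
}
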