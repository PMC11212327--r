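# VCF 4.2 I/O. The generator writes plain-text VCFs with strand-split
# observation counts in FreeBayes-style INFO keys (SAF/SAR alt, SRF/SRR
# ref); the consensus stage reads them back through vcfR.

vcf_header <- function(source) {
  c("##fileformat=VCFv4.2",
    paste0("##source=", source),
    "##INFO=<ID=SAF,Number=1,Type=Integer,Description=\"Alt observations on the forward strand\">",
    "##INFO=<ID=SAR,Number=1,Type=Integer,Description=\"Alt observations on the reverse strand\">",
    "##INFO=<ID=SRF,Number=1,Type=Integer,Description=\"Ref observations on the forward strand\">",
    "##INFO=<ID=SRR,Number=1,Type=Integer,Description=\"Ref observations on the reverse strand\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
}

#' Write one caller's observations as VCF 4.2
#'
#' @param obs observation data.frame (see
#'   [simulate_caller_observations()]).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_caller_vcf <- function(obs, path) {
  header <- vcf_header(if (nrow(obs) > 0) obs$caller_id[1] else "caller")
  ord <- order(obs$chrom, obs$pos, obs$ref, obs$alt)
  obs <- obs[ord, , drop = FALSE]
  body <- if (nrow(obs) > 0) {
    info <- paste0("SAF=", obs$fwd_alt, ";SAR=", obs$rev_alt,
                   ";SRF=", obs$fwd_depth - obs$fwd_alt,
                   ";SRR=", obs$rev_depth - obs$rev_alt)
    filter <- ifelse(obs$passed, "PASS", "FAIL")
    paste(obs$chrom, obs$pos, ".", obs$ref, obs$alt, ".", filter, info,
          sep = "\t")
  } else {
    character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write the pooled-normal artifact loci as VCF 4.2
#'
#' @param loci data.frame with chrom, pos, ref, alt.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_pooled_normal_vcf <- function(loci, path) {
  header <- c("##fileformat=VCFv4.2",
              "##source=pooled_normal",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  ord <- order(loci$chrom, loci$pos, loci$ref, loci$alt)
  loci <- loci[ord, , drop = FALSE]
  body <- if (nrow(loci) > 0) {
    paste(loci$chrom, loci$pos, ".", loci$ref, loci$alt, ".", "PASS", ".",
          sep = "\t")
  } else {
    character(0)
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read one caller's VCF into an observation table
#'
#' Parses a VCF 4.2 file via vcfR and extracts strand-split read counts
#' from the configured INFO keys (defaults SAF/SAR/SRF/SRR: forward/reverse
#' alt and ref observation counts).
#'
#' @param path VCF file.
#' @param caller_id caller label to attach.
#' @param tumor_id tumor label to attach.
#' @param info_keys named character vector mapping the four count roles
#'   `fwd_alt`, `rev_alt`, `fwd_ref`, `rev_ref` to INFO keys.
#' @return observation data.frame with the VariantObservation columns.
#' @export
read_caller_vcf <- function(path, caller_id = NA_character_,
                            tumor_id = NA_character_,
                            info_keys = c(fwd_alt = "SAF", rev_alt = "SAR",
                                          fwd_ref = "SRF", rev_ref = "SRR")) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) {
    return(data.frame(tumor_id = character(0), caller_id = character(0),
                      chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      passed = logical(0), fwd_alt = integer(0),
                      rev_alt = integer(0), fwd_depth = integer(0),
                      rev_depth = integer(0), stringsAsFactors = FALSE))
  }
  get_info <- function(key) {
    as.integer(vcfR::extract.info(v, element = key))
  }
  fa <- get_info(info_keys[["fwd_alt"]])
  ra <- get_info(info_keys[["rev_alt"]])
  fr <- get_info(info_keys[["fwd_ref"]])
  rr <- get_info(info_keys[["rev_ref"]])
  filt <- fix[, "FILTER"]
  data.frame(tumor_id = tumor_id, caller_id = caller_id,
             chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
             ref = fix[, "REF"], alt = fix[, "ALT"],
             passed = !is.na(filt) & filt == "PASS",
             fwd_alt = fa, rev_alt = ra,
             fwd_depth = fa + fr, rev_depth = ra + rr,
             stringsAsFactors = FALSE)
}

#' Read pooled-normal loci from VCF
#'
#' @param path VCF file.
#' @return character vector of normalized locus keys.
#' @export
read_pooled_normal_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0) {
    return(character(0))
  }
  vapply(seq_len(nrow(fix)), function(i) {
    nv <- normalize_variant(fix[i, "CHROM"], as.integer(fix[i, "POS"]),
                            fix[i, "REF"], fix[i, "ALT"])
    nv$key
  }, character(1))
}
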