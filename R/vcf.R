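#' Read a multi-sample VCF into site records
#'
#' Thin wrapper over `vcfR` extracting the fields the filtering step uses:
#' position, REF/ALT, site QUAL, per-sample depth (DP) and missingness
#' (GT of `./.` or absent).
#'
#' @param path VCF path (plain or bgzipped).
#' @return A list of class `vcf_records`: `sites` (data frame chrom, pos,
#'   ref, alt, qual, n_alt), `dp` (sites x samples integer matrix),
#'   `missing` (logical matrix), `samples`.
#' @export
read_vcf_records <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  alt <- fix$ALT
  n_alt <- ifelse(is.na(alt) | alt == ".", 0L,
                  lengths(strsplit(alt, ",", fixed = TRUE)))
  gt <- vcfR::extract.gt(v, element = "GT")
  dp <- suppressWarnings(vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
  miss <- is.na(gt) | gt %in% c("./.", ".|.", ".")
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = fix$REF, alt = alt,
                      qual = suppressWarnings(as.numeric(fix$QUAL)),
                      n_alt = n_alt, stringsAsFactors = FALSE)
  dimnames(dp) <- NULL; dimnames(miss) <- NULL
  structure(list(sites = sites, dp = matrix(dp, nrow = nrow(sites)),
                 missing = matrix(miss, nrow = nrow(sites)),
                 samples = colnames(v@gt)[-1]),
            class = "vcf_records")
}

#' Filter VCF site records
#'
#' Applies the site-level filters used for matriline variant sets: only
#' biallelic sites are kept; a sample whose depth falls outside
#' `[min_depth, max_depth]` is treated as missing for that site; sites
#' missing in `max_missing_frac` or more of the samples (strict: exactly
#' 10% missing is removed) are dropped, as are sites below the quality
#' threshold.  No minor-allele-frequency floor is applied, so singleton
#' (putative de novo) variants survive.
#'
#' @param records A `vcf_records` object.
#' @param max_missing_frac Maximum tolerated missing-sample fraction
#'   (strict upper bound).
#' @param min_depth,max_depth Per-sample depth bounds in reads.
#' @param min_qual Minimum Phred-scaled site quality (30 and 90 are the
#'   conventional permissive/conservative choices).
#' @return A filtered `vcf_records`; attribute `"log"` records per-rule
#'   attrition counts.
#' @export
filter_vcf <- function(records, max_missing_frac = 0.10, min_depth = 10,
                       max_depth = 500, min_qual = 30) {
  stopifnot(inherits(records, "vcf_records"),
            min_depth > 0, max_depth >= min_depth, min_qual >= 0)
  s <- records$sites
  n_samp <- length(records$samples)
  biallelic <- s$n_alt == 1L
  qual_ok <- !is.na(s$qual) & s$qual >= min_qual
  eff_missing <- records$missing |
    is.na(records$dp) | records$dp < min_depth | records$dp > max_depth
  miss_frac <- rowSums(eff_missing) / n_samp
  miss_ok <- miss_frac < max_missing_frac
  keep <- biallelic & qual_ok & miss_ok
  out <- structure(list(sites = s[keep, , drop = FALSE],
                        dp = records$dp[keep, , drop = FALSE],
                        missing = records$missing[keep, , drop = FALSE],
                        samples = records$samples),
                   class = "vcf_records")
  attr(out, "log") <- c(n_input = nrow(s),
                        fail_biallelic = sum(!biallelic),
                        fail_qual = sum(!qual_ok),
                        fail_missing = sum(!miss_ok),
                        n_retained = sum(keep))
  out
}

#' Write site records as a minimal VCF
#'
#' @param records A `vcf_records`.
#' @param path Output path.
#' @export
write_vcf_records <- function(records, path) {
  s <- records$sites
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", records$samples), collapse = "\t"))
  lines <- vapply(seq_len(nrow(s)), function(i) {
    gt <- ifelse(records$missing[i, ], "./.", "0/1")
    dp <- ifelse(is.na(records$dp[i, ]), ".", records$dp[i, ])
    paste(c(s$chrom[i], s$pos[i], ".", s$ref[i], s$alt[i],
            format(s$qual[i], trim = TRUE), "PASS", ".", "GT:DP",
            paste0(gt, ":", dp)), collapse = "\t")
  }, "")
  writeLines(c(header, lines), path)
  invisible(path)
}
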