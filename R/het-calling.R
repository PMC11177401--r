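#' Read a per-site allele-count table
#'
#' Reads the package's primary tab-delimited count dialect: header line
#' with columns chrom, pos, ref, depth, count_A, count_C, count_G, count_T.
#'
#' @param path File path.
#' @param individual Individual id to attach; defaults to the file name
#'   without the `.counts.tsv` / `.tsv` suffix.
#' @return A count data frame (individual, chrom, pos, ref, depth,
#'   count_A..count_T).
#' @export
read_readcount_tsv <- function(path, individual = NULL) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "depth", "count_A", "count_C",
            "count_G", "count_T")
  if (!all(need %in% names(d)))
    stopf("%s is missing columns: %s", path,
          paste(setdiff(need, names(d)), collapse = ", "))
  if (any(!d$ref %in% BASES)) stopf("malformed reference base in %s", path)
  id <- individual %||% sub("\\.counts\\.tsv$|\\.tsv$", "", basename(path))
  cbind(data.frame(individual = id, stringsAsFactors = FALSE), d[, need])
}

#' Read native bam-readcount output
#'
#' Parses the colon-delimited per-site line format emitted by bam-readcount
#' (tab-separated fields: chrom, position, reference base, depth, then one
#' `base:count:...` block per base).  Only the base and count of each block
#' are consumed; N/indel blocks are ignored.
#'
#' @param path File path.
#' @param individual Individual id to attach (defaults from file name).
#' @return A count data frame in the package's primary dialect.
#' @export
read_bam_readcount <- function(path, individual = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 5L)) stopf("malformed bam-readcount line in %s", path)
  n <- length(parts)
  counts <- matrix(0L, nrow = n, ncol = 4, dimnames = list(NULL, BASES))
  for (i in seq_len(n)) {
    for (block in parts[[i]][-(1:4)]) {
      bits <- strsplit(block, ":", fixed = TRUE)[[1]]
      if (length(bits) >= 2L && toupper(bits[1]) %in% BASES)
        counts[i, toupper(bits[1])] <- as.integer(bits[2])
    }
  }
  ref <- toupper(vapply(parts, `[[`, "", 3))
  if (any(!ref %in% BASES)) stopf("malformed reference base in %s", path)
  id <- individual %||% sub("\\.[^.]*$", "", basename(path))
  data.frame(individual = id,
             chrom = vapply(parts, `[[`, "", 1),
             pos = as.integer(vapply(parts, `[[`, "", 2)),
             ref = ref,
             depth = as.integer(vapply(parts, `[[`, "", 4)),
             count_A = counts[, "A"], count_C = counts[, "C"],
             count_G = counts[, "G"], count_T = counts[, "T"],
             stringsAsFactors = FALSE)
}

#' Call heteroplasmic sites from allele counts
#'
#' A site is heteroplasmic in an individual when the highest-count
#' non-reference base reaches the frequency threshold (default 2% of the
#' row's stated depth, the filter used to separate real low-frequency
#' variation from sequencing error; 5% is a common stricter check) at
#' sufficient depth.  Multiallelic rows collapse to the top alternative
#' base, ties broken in fixed base order A < C < G < T.  Depth-0 rows are
#' skipped; their number is reported via a message.
#'
#' @param counts Count data frame (one or many individuals).
#' @param min_freq Minimum alternative-allele frequency, in (0, 1).
#' @param min_depth Minimum site depth in reads.
#' @return A data frame of called sites: individual, position, ref, alt,
#'   alt_freq (fraction of depth), depth.
#' @export
call_het_sites <- function(counts, min_freq = 0.02, min_depth = 10L) {
  if (!(min_freq > 0 && min_freq < 1)) stopf("min_freq must be in (0, 1)")
  if (!"individual" %in% names(counts))
    counts$individual <- "sample"
  if (any(!counts$ref %in% BASES)) stopf("malformed reference base in counts")
  cm <- as.matrix(counts[, c("count_A", "count_C", "count_G", "count_T")])
  zero_depth <- counts$depth == 0
  if (any(zero_depth))
    message(sum(zero_depth), " depth-0 rows skipped")
  # mask the reference base, then take the top remaining count
  cm[cbind(seq_len(nrow(cm)), match(counts$ref, BASES))] <- -1L
  top <- max.col(cm, ties.method = "first")
  top_count <- cm[cbind(seq_len(nrow(cm)), top)]
  freq <- ifelse(counts$depth > 0, top_count / counts$depth, 0)
  keep <- !zero_depth & counts$depth >= min_depth & top_count > 0 &
    freq >= min_freq
  data.frame(individual = counts$individual[keep],
             position = counts$pos[keep],
             ref = counts$ref[keep],
             alt = BASES[top[keep]],
             alt_freq = freq[keep],
             depth = counts$depth[keep],
             stringsAsFactors = FALSE)
}

#' Per-individual heteroplasmy summary
#'
#' Summarises called sites for one individual: the number of variable
#' sites, the percentage of the genome variable, and the mean
#' alternative-allele frequency both excluding zeros (over called sites
#' only) and including zeros (over all assayed positions).  Both means are
#' reported in percent.  With no called sites the excluding-zeros mean is
#' undefined (NA), never 0.
#'
#' @param sites Called sites for a single individual ([call_het_sites()]).
#' @param L_mt Genome length in bases.
#' @param n_assayed Number of positions assayed (defaults to `L_mt`).
#' @return One-row data frame: individual, n_variable, pct_sites_variable,
#'   mean_freq_excl_zero, mean_freq_incl_zero.
#' @export
summarize_individual <- function(sites, L_mt, n_assayed = L_mt) {
  stopifnot(L_mt > 0)
  id <- if (nrow(sites) > 0) sites$individual[1] else NA_character_
  n <- nrow(sites)
  data.frame(
    individual = id,
    n_variable = n,
    pct_sites_variable = 100 * n / L_mt,
    mean_freq_excl_zero = if (n > 0) 100 * mean(sites$alt_freq) else NA_real_,
    mean_freq_incl_zero = 100 * sum(sites$alt_freq) / n_assayed,
    stringsAsFactors = FALSE)
}

#' @rdname summarize_individual
#' @param individuals Optional vector of ids to summarise (defaults to the
#'   ids present in `sites`); ids with no called sites get zero rows.
#' @export
summarize_individuals <- function(sites, L_mt, n_assayed = L_mt,
                                  individuals = NULL) {
  ids <- individuals %||% sort(unique(sites$individual))
  out <- do.call(rbind, lapply(ids, function(id)
    summarize_individual(sites[sites$individual == id, , drop = FALSE],
                         L_mt, n_assayed)))
  out$individual <- ids
  out
}

#' Concordance of two frequency tables
#'
#' Pearson correlation between two per-key frequency tables (keys are sites
#' or individuals), used e.g. to compare sequencing batches or
#' technologies.  Keys present in only one table are treated as frequency 0
#' in the other, rather than dropped: dropping would inflate the
#' correlation by discarding exactly the discordant keys.
#'
#' @param freqs_a,freqs_b Named numeric vectors (names are the keys).
#' @return A list: `r`, `r_squared`, `p`, `n`.  With fewer than 3 keys or
#'   zero variance in either vector, `r` is NA and `reason` says why.
#' @export
concordance <- function(freqs_a, freqs_b) {
  keys <- union(names(freqs_a), names(freqs_b))
  a <- ifelse(is.na(freqs_a[keys]), 0, freqs_a[keys])
  b <- ifelse(is.na(freqs_b[keys]), 0, freqs_b[keys])
  n <- length(keys)
  if (n < 3L)
    return(list(r = NA_real_, r_squared = NA_real_, p = NA_real_, n = n,
                reason = "fewer than 3 shared keys"))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(list(r = NA_real_, r_squared = NA_real_, p = NA_real_, n = n,
                reason = "zero variance"))
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n = n)
}
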