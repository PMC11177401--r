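#' Fraction of reads that are mitochondrial
#'
#' @param mt_reads Number of reads mapping to the mitogenome.
#' @param total_reads Total reads generated for the individual.
#' @return `mt_reads / total_reads`.
#' @export
mt_read_fraction <- function(mt_reads, total_reads) {
  if (any(total_reads <= 0)) stopf("total_reads must be positive")
  if (any(mt_reads < 0) || any(mt_reads > total_reads))
    stopf("mt_reads must be in [0, total_reads]")
  mt_reads / total_reads
}

#' mtDNA copies per nuclear genome copy
#'
#' Converts a mitochondrial read fraction into a relative copy number:
#' assuming reads sample the cell's DNA content uniformly, the expected
#' fraction of mitochondrial reads is `R * L_mt / G_nuc` for `R` mtDNA
#' copies per haploid nuclear genome equivalent, so `R = f_mt * G_nuc /
#' L_mt`.  The small mitochondrial fraction (well under 0.1% in snail WGS)
#' makes the denominator correction `1 - f_mt` negligible and it is not
#' applied.
#'
#' @param f_mt Mitochondrial read fraction, in `[0, 1)`.
#' @param G_nuc Haploid nuclear genome size in bases.
#' @param L_mt Mitogenome length in bases.
#' @return The copy ratio `R`.
#' @export
copy_ratio <- function(f_mt, G_nuc, L_mt) {
  if (any(G_nuc <= 0) || any(L_mt <= 0)) stopf("G_nuc and L_mt must be positive")
  if (any(f_mt < 0) || any(f_mt >= 1)) stopf("f_mt must be in [0, 1)")
  f_mt * G_nuc / L_mt
}

#' Copy-ratio table from read totals
#'
#' @param totals Data frame with columns individual, mt_reads, total_reads,
#'   G_nuc, L_mt (the read-totals TSV layout).
#' @return The same rows with added `mt_fraction` and `ratio` columns.
#' @export
copy_ratio_table <- function(totals) {
  totals$mt_fraction <- mt_read_fraction(totals$mt_reads, totals$total_reads)
  totals$ratio <- copy_ratio(totals$mt_fraction, totals$G_nuc, totals$L_mt)
  totals
}

#' Read a read-totals TSV
#'
#' Columns: individual, mt_reads, total_reads, G_nuc, L_mt.
#'
#' @param path File path.
#' @export
read_totals_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  need <- c("individual", "mt_reads", "total_reads", "G_nuc", "L_mt")
  if (!all(need %in% names(d)))
    stopf("%s is missing columns: %s", path,
          paste(setdiff(need, names(d)), collapse = ", "))
  d
}

#' Read a per-base depth table
#'
#' Accepts either the 2-column (pos, depth) TSV or a BED-like 4-column
#' windows file (chrom, start0, end, depth) as written by mosdepth; the
#' BED form is expanded to per-base depth.
#'
#' @param path File path.
#' @return Numeric per-base depth vector.
#' @export
read_depth_tsv <- function(path) {
  first <- strsplit(readLines(path, n = 1L), "\t")[[1]]
  header <- suppressWarnings(any(is.na(as.numeric(first[-1])))) ||
    any(grepl("[A-Za-z]", first[-1]))
  d <- utils::read.table(path, sep = "\t", header = header,
                         stringsAsFactors = FALSE)
  if (ncol(d) == 2L) {
    depth <- numeric(max(d[[1]]))
    depth[d[[1]]] <- d[[2]]
    depth
  } else if (ncol(d) >= 4L) {
    depth <- numeric(max(d[[3]]))
    for (i in seq_len(nrow(d))) depth[(d[[2]][i] + 1L):d[[3]][i]] <- d[[4]][i]
    depth
  } else stopf("unrecognised depth table layout in %s", path)
}

#' Windowed mean depth
#'
#' Non-overlapping windows of `window_size` bases (default 25, the usual
#' mosdepth setting for small genomes); the last window may be short.
#'
#' @param per_base_depth Numeric per-base depth vector.
#' @param window_size Window size in bases (>= 1).
#' @return A list of class `depth_profile`: `window_size`, `start`, `end`,
#'   `depth` (per-window means), `genome_length`.
#' @export
windowed_depth <- function(per_base_depth, window_size = 25L) {
  if (length(per_base_depth) == 0L) stopf("empty depth vector")
  if (window_size < 1L) stopf("window_size must be >= 1")
  L <- length(per_base_depth)
  starts <- seq.int(1L, L, by = window_size)
  ends <- pmin(starts + window_size - 1L, L)
  means <- vapply(seq_along(starts), function(k)
    mean(per_base_depth[starts[k]:ends[k]]), numeric(1))
  structure(list(window_size = as.integer(window_size), start = starts,
                 end = ends, depth = means, genome_length = L),
            class = "depth_profile")
}

#' Repeat copy number from depth ratios
#'
#' Estimates the per-genome copy number of a repeat assembled as a single
#' copy, as the mean read depth over the repeat divided by the mean depth
#' of the flanking sequence (default 1 kb immediately upstream and
#' downstream, pooled).  Flanks wrap around the origin on circular genomes
#' and are truncated, never overlapped, where the genome is too short.
#'
#' @param per_base_depth Numeric per-base depth vector.
#' @param repeat_region Two-element (start, end), 1-based inclusive.
#' @param flank Flank length in bases on each side.
#' @param circular Whether flanks may wrap the coordinate origin.
#' @return A list: `copies` (the depth ratio; NA with `reason` if the
#'   flank mean is 0), `repeat_mean`, `flank_mean`, `n_flank`.
#' @export
repeat_copy_number <- function(per_base_depth, repeat_region, flank = 1000L,
                               circular = TRUE) {
  L <- length(per_base_depth)
  r1 <- repeat_region[1]; r2 <- repeat_region[2]
  if (r1 < 1L || r2 > L || r1 > r2) stopf("repeat_region outside genome")
  rep_idx <- r1:r2
  non_rep <- L - length(rep_idx)
  flank <- min(flank, non_rep %/% 2L)
  if (flank < 1L) stopf("no flanking sequence available")
  up <- r1 - seq_len(flank)
  down <- r2 + seq_len(flank)
  if (circular) {
    up <- ((up - 1L) %% L) + 1L
    down <- ((down - 1L) %% L) + 1L
  } else {
    up <- up[up >= 1L]
    down <- down[down <= L]
    if (length(up) + length(down) == 0L) stopf("no flanking sequence available")
  }
  flank_idx <- c(up, down)
  fm <- mean(per_base_depth[flank_idx])
  rm_ <- mean(per_base_depth[rep_idx])
  if (fm == 0)
    return(list(copies = NA_real_, repeat_mean = rm_, flank_mean = 0,
                n_flank = length(flank_idx), reason = "flank mean depth is 0"))
  list(copies = rm_ / fm, repeat_mean = rm_, flank_mean = fm,
       n_flank = length(flank_idx))
}

#' Copy ratio versus heteroplasmy association
#'
#' Ordinary least-squares regression of a per-individual heteroplasmy
#' measure on the mtDNA copy ratio, the test for the negative coupling
#' between variant load and copy number.
#'
#' @param ratios Data frame with columns individual and ratio (e.g. from
#'   [copy_ratio_table()]).
#' @param summaries Data frame from [summarize_individuals()].
#' @param measure Which heteroplasmy measure to regress:
#'   `"n_variable"` (count of heteroplasmic sites) or `"mean_freq"`
#'   (mean alternative-allele frequency excluding zeros).
#' @return A list: `slope`, `intercept`, `r_squared`, `p` (two-sided slope
#'   test), `n`; NA with `reason` on a degenerate predictor.
#' @export
ratio_vs_het_association <- function(ratios, summaries,
                                     measure = c("n_variable", "mean_freq")) {
  measure <- match.arg(measure)
  m <- merge(ratios[, c("individual", "ratio")], summaries, by = "individual")
  if (nrow(m) < 3L) stopf("need at least 3 matched individuals")
  y <- if (measure == "n_variable") m$n_variable else m$mean_freq_excl_zero
  keep <- !is.na(y) & !is.na(m$ratio)
  y <- y[keep]; x <- m$ratio[keep]
  if (length(x) < 3L || stats::sd(x) == 0)
    return(list(slope = NA_real_, intercept = NA_real_, r_squared = NA_real_,
                p = NA_real_, n = length(x), reason = "degenerate predictor"))
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit))   # perfect fits are legitimate inputs
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p = sm$coefficients[2, 4],
       n = length(x))
}
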