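# File formats emitted by the simulator and consumed by the analysis
# stages: per-individual read-count TSVs, pedigree TSV, truth tables,
# a minimal multi-sample VCF 4.2, and a flat key: value config file.

#' Write per-individual read-count tables
#'
#' One TSV per individual (columns chrom, pos, ref, depth, count_A,
#' count_C, count_G, count_T), named `<id>.counts.tsv`.
#'
#' @param counts Long count data frame from [simulate_readcounts()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_readcount_tables <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(split(counts, counts$individual), function(d) {
    p <- file.path(dir, paste0(d$individual[1], ".counts.tsv"))
    utils::write.table(d[, c("chrom", "pos", "ref", "depth", "count_A",
                             "count_C", "count_G", "count_T")],
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }, "")
  invisible(unname(paths))
}

#' Write / read a pedigree table
#'
#' Tab-delimited columns id, mother, father, generation; unknown parents
#' are written as `"."`.
#'
#' @param pedigree Data frame with id, mother, father, generation.
#' @param path File path.
#' @export
write_pedigree <- function(pedigree, path) {
  out <- pedigree[, c("id", "mother", "father", "generation")]
  out$mother[is.na(out$mother)] <- "."
  out$father[is.na(out$father)] <- "."
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  ped <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = c("character", "character",
                                          "character", "integer"))
  ped$mother[ped$mother == "."] <- NA_character_
  ped$father[ped$father == "."] <- NA_character_
  ped
}

#' Write simulation truth tables
#'
#' Two TSVs: `<prefix>.individuals.tsv` (per-individual truth: copy ratio,
#' repeat copies, de novo count) and `<prefix>.freqs.tsv` (long table of
#' non-zero true frequencies: individual, pos, freq).
#'
#' @param state A `matriline_state`.
#' @param prefix Output path prefix.
#' @export
write_truth_tables <- function(state, prefix) {
  utils::write.table(state$individuals, paste0(prefix, ".individuals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  nz <- which(state$freqs > 0, arr.ind = TRUE)
  long <- data.frame(individual = rownames(state$freqs)[nz[, 1]],
                     pos = nz[, 2], freq = state$freqs[nz],
                     stringsAsFactors = FALSE)
  long <- long[order(long$individual, long$pos), ]
  utils::write.table(long, paste0(prefix, ".freqs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}

#' Write a minimal multi-sample VCF of simulated heteroplasmic sites
#'
#' Emits VCF 4.2 with one record per site where any individual has true
#' alternative-allele frequency > 0.  QUAL is a stated monotone map of the
#' maximum individual frequency at the site, `QUAL = round(1000 * max_f,
#' 1)`, so a site at 3% maps to 30 and at 9% to 90.  Per-sample fields are
#' GT (0/1 where the individual carries the allele, 0/0 otherwise), DP and
#' AD; depths are the expected sequencing depth unless a count table is
#' supplied.
#'
#' @param state A `matriline_state`.
#' @param genome The simulated genome.
#' @param path Output path.
#' @param counts Optional long count data frame; if given, DP/AD are the
#'   realised per-site counts.
#' @export
write_sim_vcf <- function(state, genome, path, counts = NULL) {
  ids <- state$individuals$id
  f <- state$freqs
  variable <- which(colSums(f > 0) > 0)
  refs <- genome_base(genome, variable)
  alts <- state$alt[variable]
  maxf <- apply(f[, variable, drop = FALSE], 2, max)
  qual <- round(1000 * maxf, 1)

  depth <- matrix(as.integer(round(state$config$mean_depth)),
                  nrow = length(ids), ncol = length(variable),
                  dimnames = list(ids, NULL))
  altd <- NULL
  if (!is.null(counts)) {
    cnt <- counts[counts$pos %in% variable & counts$individual %in% ids, ]
    ii <- match(cnt$individual, ids)
    jj <- match(cnt$pos, variable)
    depth[cbind(ii, jj)] <- cnt$depth
    cmat <- as.matrix(cnt[, c("count_A", "count_C", "count_G", "count_T")])
    altd <- matrix(0L, nrow = length(ids), ncol = length(variable),
                   dimnames = list(ids, NULL))
    altd[cbind(ii, jj)] <- cmat[cbind(seq_len(nrow(cnt)),
                                      match(alts[jj], BASES))]
  }

  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", genome$id, genome$length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", ids), collapse = "\t"))
  records <- vapply(seq_along(variable), function(j) {
    gt <- ifelse(f[ids, variable[j]] > 0, "0/1", "0/0")
    dp <- depth[, j]
    ad_alt <- if (is.null(altd)) as.integer(round(dp * f[ids, variable[j]]))
              else altd[, j]
    samp <- sprintf("%s:%d:%d,%d", gt, dp, dp - ad_alt, ad_alt)
    paste(c(genome$id, variable[j], ".", refs[j], alts[j],
            format(qual[j], trim = TRUE), "PASS", ".", "GT:DP:AD", samp),
          collapse = "\t")
  }, "")
  writeLines(c(header, records), path)
  invisible(path)
}

#' Read / write a flat simulator configuration file
#'
#' Scalar fields of [sim_config()] round-trip through a flat `key: value`
#' (YAML-compatible) file; the gene layout is carried by the package
#' default and not serialised.
#'
#' @param config A `sim_config`.
#' @param path File path.
#' @export
write_sim_config <- function(config, path) {
  scalars <- config[!(names(config) %in% "gene_layout")]
  yaml::write_yaml(scalars, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals <- vals[names(vals) %in% setdiff(names(formals(sim_config)), "gene_layout")]
  do.call(sim_config, vals)
}
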