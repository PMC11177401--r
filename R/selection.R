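#' Tabulate heteroplasmic sites by gene, codon position and effect
#'
#' Pools called heteroplasmic sites across individuals into unique
#' (position, alt) pairs — a site segregating in 40 individuals counts once
#' — classifies each against the annotation, and tallies counts per gene by
#' codon position (n1, n2, n3) and effect (n_syn, n_nonsyn).  Sites in two
#' overlapping protein-coding genes count once per gene; sites in
#' tRNA/rRNA features are tallied under the feature, and sites outside any
#' feature under `"intergenic"`.
#'
#' @param sites Called sites ([call_het_sites()]) pooled over individuals.
#' @param genome,annotation,code The reference model.
#' @param per_individual If TRUE, count (individual, position, alt) entries
#'   instead of unique (position, alt) pairs.
#' @return A list: `per_gene` (data frame gene, kind, n_sites, n1, n2, n3,
#'   n_syn, n_nonsyn), `pooled` (named totals over PCG-classified sites),
#'   `n_unique_sites`.
#' @export
tabulate_positions <- function(sites, genome, annotation,
                               code = genetic_code(), per_individual = FALSE) {
  if (nrow(sites) == 0L)
    return(list(per_gene = data.frame(gene = character(0), kind = character(0),
                                      n_sites = numeric(0), n1 = numeric(0),
                                      n2 = numeric(0), n3 = numeric(0),
                                      n_syn = numeric(0), n_nonsyn = numeric(0)),
                pooled = c(n1 = 0, n2 = 0, n3 = 0, n_syn = 0, n_nonsyn = 0,
                           nonsyn1 = 0, nonsyn2 = 0, nonsyn3 = 0),
                n_unique_sites = 0L))
  pair_key <- paste(sites$position, sites$alt)
  uniq <- sites[!duplicated(pair_key), , drop = FALSE]
  uniq_key <- paste(uniq$position, uniq$alt)
  cls_list <- lapply(seq_len(nrow(uniq)), function(k)
    classify_substitution(genome, annotation, code, uniq$position[k],
                          uniq$alt[k]))
  # weight 1 per unique pair, or its multiplicity across individuals
  w_pair <- if (per_individual)
    as.numeric(table(pair_key)[uniq_key]) else rep(1, nrow(uniq))
  cls <- do.call(rbind, cls_list)
  cls$w <- rep(w_pair, times = vapply(cls_list, nrow, 0L))
  cls$gene[is.na(cls$gene)] <- "intergenic"
  kinds <- c(stats::setNames(annotation$kind, annotation$name),
             intergenic = "other")
  genes <- unique(cls$gene)
  per_gene <- do.call(rbind, lapply(genes, function(g) {
    d <- cls[cls$gene == g, , drop = FALSE]
    data.frame(gene = g, kind = unname(kinds[g]),
               n_sites = sum(d$w),
               n1 = sum(d$w[d$codon_position %in% 1L]),
               n2 = sum(d$w[d$codon_position %in% 2L]),
               n3 = sum(d$w[d$codon_position %in% 3L]),
               n_syn = sum(d$w[d$effect == "synonymous"]),
               n_nonsyn = sum(d$w[d$effect == "nonsynonymous"]),
               stringsAsFactors = FALSE)
  }))
  coding <- cls[!is.na(cls$codon_position), , drop = FALSE]
  pooled <- c(n1 = sum(coding$w[coding$codon_position == 1L]),
              n2 = sum(coding$w[coding$codon_position == 2L]),
              n3 = sum(coding$w[coding$codon_position == 3L]),
              n_syn = sum(coding$w[coding$effect == "synonymous"]),
              n_nonsyn = sum(coding$w[coding$effect == "nonsynonymous"]),
              nonsyn1 = sum(coding$w[coding$effect == "nonsynonymous" &
                                       coding$codon_position == 1L]),
              nonsyn2 = sum(coding$w[coding$effect == "nonsynonymous" &
                                       coding$codon_position == 2L]),
              nonsyn3 = sum(coding$w[coding$effect == "nonsynonymous" &
                                       coding$codon_position == 3L]))
  list(per_gene = per_gene, pooled = pooled, n_unique_sites = nrow(uniq))
}

#' Codon-position chi-squared test
#'
#' Compares the observed numbers of heteroplasmic sites at two codon
#' positions against the neutral expectation of equal numbers (each codon
#' contributes one site of each position), by Pearson chi-squared with 1
#' degree of freedom and no continuity correction.
#'
#' @param nA,nB Observed site counts at the two codon positions.
#' @return A list: `statistic`, `p`, `df`, `expected`, and
#'   `valid_asymptotic` (FALSE when `nA + nB < 5`, flagging that the
#'   asymptotic p-value is unreliable).
#' @export
chisq_positions <- function(nA, nB) {
  if (nA < 0 || nB < 0 || nA + nB == 0) stopf("need non-negative counts, nA + nB > 0")
  e <- (nA + nB) / 2
  stat <- (nA - e)^2 / e + (nB - e)^2 / e
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE),
       df = 1L, expected = e,
       valid_asymptotic = (nA + nB) >= 5)
}

#' McDonald-Kreitman test
#'
#' Two-sided Fisher exact test on the 2x2 table of polymorphic (within the
#' matriline) versus fixed (against the outgroup) counts, split by
#' synonymous/non-synonymous effect; reports the neutrality index
#' `NI = (Pn/Ps) / (Dn/Ds)` and `alpha = 1 - NI`, the inferred fraction of
#' adaptive substitutions.  NI and alpha are undefined (NA) when `Ps = 0`
#' or `Dn = 0`, never silently zero.
#'
#' @param Pn,Ps Polymorphic non-synonymous / synonymous site counts.
#' @param Dn,Ds Fixed non-synonymous / synonymous differences.
#' @param gene Optional gene label carried through.
#' @return A list: `gene`, `table`, `fisher_p`, `NI`, `alpha`.
#' @export
mk_test <- function(Pn, Ps, Dn, Ds, gene = NA_character_) {
  if (any(c(Pn, Ps, Dn, Ds) < 0)) stopf("counts must be non-negative")
  tab <- matrix(c(Pn, Ps, Dn, Ds), nrow = 2, byrow = TRUE,
                dimnames = list(c("polymorphic", "fixed"),
                                c("nonsynonymous", "synonymous")))
  p <- stats::fisher.test(tab)$p.value
  if (Ps == 0 || Dn == 0) {
    ni <- NA_real_; alpha <- NA_real_
  } else {
    ni <- (Pn / Ps) / (Dn / Ds)
    alpha <- 1 - ni
  }
  list(gene = gene, table = tab, fisher_p = p, NI = ni, alpha = alpha)
}

#' Sliding-window nucleotide diversity (Pi)
#'
#' Average pairwise difference per site among aligned sequences, in
#' sliding windows (defaults: 500-site window, 100-site step, the usual
#' DnaSP-style setting).  Sites where either sequence of a pair has a gap
#' (`-`) or `N` are excluded pairwise; the final partial window is
#' included.
#'
#' @param sequences Character vector of aligned equal-length sequences
#'   (or a `Biostrings::DNAStringSet`).
#' @param window Window length in alignment sites.
#' @param step Step between window starts.
#' @return A data frame: window_start, window_end, midpoint, pi.
#' @export
sliding_pi <- function(sequences, window = 500L, step = 100L) {
  if (inherits(sequences, "DNAStringSet")) sequences <- as.character(sequences)
  n <- length(sequences)
  if (n < 2L) stopf("need at least 2 sequences")
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) stopf("sequences must be aligned (equal length)")
  len <- lens[1]
  if (window > len) {
    warning("window longer than alignment; using a single whole-alignment window")
    window <- len
  }
  m <- do.call(rbind, strsplit(toupper(sequences), ""))
  valid <- m %in% c("A", "C", "G", "T")
  dim(valid) <- dim(m)

  # per-pair cumulative difference / comparable-site counts, so each window
  # sum is O(1)
  pairs <- utils::combn(n, 2)
  n_pair <- ncol(pairs)
  cum_diff <- matrix(0, nrow = n_pair, ncol = len + 1L)
  cum_comp <- matrix(0, nrow = n_pair, ncol = len + 1L)
  for (k in seq_len(n_pair)) {
    i <- pairs[1, k]; j <- pairs[2, k]
    comp <- valid[i, ] & valid[j, ]
    diff <- comp & (m[i, ] != m[j, ])
    cum_diff[k, ] <- c(0, cumsum(diff))
    cum_comp[k, ] <- c(0, cumsum(comp))
  }

  starts <- seq.int(1L, max(1L, len), by = step)
  full <- starts[starts + window - 1L <= len]
  partial <- setdiff(starts, full)
  starts <- c(full, if (length(partial)) partial[1])
  ends <- pmin(starts + window - 1L, len)

  pi <- vapply(seq_along(starts), function(w) {
    d <- cum_diff[, ends[w] + 1L] - cum_diff[, starts[w]]
    cc <- cum_comp[, ends[w] + 1L] - cum_comp[, starts[w]]
    ok <- cc > 0
    if (!any(ok)) return(NA_real_)
    mean(d[ok] / cc[ok])
  }, numeric(1))
  data.frame(window_start = starts, window_end = ends,
             midpoint = (starts + ends) / 2, pi = pi)
}

#' Fixed differences between a focal consensus and an outgroup
#'
#' Counts synonymous and non-synonymous fixed differences per
#' protein-coding gene between two aligned equal-length sequences.  Codons
#' differing at one position are classified directly; codons differing at
#' several positions are counted along the stepwise substitution pathways,
#' averaged over the orderings (pathways passing through a stop codon are
#' excluded unless all do).  Codons containing a gap or `N` in either
#' sequence are skipped.
#'
#' @param consensus,outgroup Aligned equal-length sequences (character).
#' @param annotation A `mito_annotation` giving gene coordinates on the
#'   alignment.
#' @param code A [genetic_code()].
#' @return A data frame: gene, Dn, Ds (possibly fractional from pathway
#'   averaging), n_codons_compared.
#' @export
fixed_differences <- function(consensus, outgroup, annotation,
                              code = genetic_code()) {
  stopifnot(nchar(consensus) == nchar(outgroup))
  consensus <- toupper(consensus); outgroup <- toupper(outgroup)
  pcg <- annotation[annotation$kind == "PCG", , drop = FALSE]
  L <- nchar(consensus)
  out <- lapply(seq_len(nrow(pcg)), function(k) {
    feat <- pcg[k, ]
    pos <- unroll_span(feat$start, feat$end, L)
    if (feat$strand == "-") pos <- rev(pos)
    s1 <- substring(consensus, pos, pos)
    s2 <- substring(outgroup, pos, pos)
    if (feat$strand == "-") {
      ok <- s1 %in% BASES
      s1[ok] <- comp_base(s1[ok])
      ok <- s2 %in% BASES
      s2[ok] <- comp_base(s2[ok])
    }
    n_full <- (length(pos) %/% 3L) * 3L  # drop an abbreviated-stop tail
    if (n_full == 0L) stopf("gene '%s' shorter than one codon", feat$name)
    s1 <- s1[seq_len(n_full)]; s2 <- s2[seq_len(n_full)]
    dn <- 0; ds <- 0; n_comp <- 0L
    for (c0 in seq.int(1L, n_full, by = 3L)) {
      c1 <- s1[c0 + 0:2]; c2 <- s2[c0 + 0:2]
      if (!all(c(c1, c2) %in% BASES)) next
      n_comp <- n_comp + 1L
      if (all(c1 == c2)) next
      path <- codon_pathway(paste0(c1, collapse = ""),
                            paste0(c2, collapse = ""), code)
      dn <- dn + path["nonsyn"]; ds <- ds + path["syn"]
    }
    data.frame(gene = feat$name, Dn = unname(dn), Ds = unname(ds),
               n_codons_compared = n_comp, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Average syn/nonsyn step counts over substitution orderings between two
# codons (Nei-Gojobori pathway counting).
codon_pathway <- function(codon_a, codon_b, code) {
  diff_pos <- which(strsplit(codon_a, "")[[1]] != strsplit(codon_b, "")[[1]])
  orders <- if (length(diff_pos) == 1L) list(diff_pos) else
    apply(permutations_of(diff_pos), 1, identity, simplify = FALSE)
  a_chars <- strsplit(codon_a, "")[[1]]
  b_chars <- strsplit(codon_b, "")[[1]]
  tally <- lapply(orders, function(ord) {
    cur <- a_chars
    syn <- 0; nonsyn <- 0; via_stop <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- b_chars[p]
      aa1 <- code$codons[[paste0(cur, collapse = "")]]
      aa2 <- code$codons[[paste0(nxt, collapse = "")]]
      if (aa2 == "*" && !identical(paste0(nxt, collapse = ""), codon_b))
        via_stop <- TRUE
      if (aa1 == aa2) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    c(syn = syn, nonsyn = nonsyn, via_stop = as.numeric(via_stop))
  })
  tl <- do.call(rbind, tally)
  keep <- tl[, "via_stop"] == 0
  if (!any(keep)) keep <- rep(TRUE, nrow(tl))
  c(syn = mean(tl[keep, "syn"]), nonsyn = mean(tl[keep, "nonsyn"]))
}

permutations_of <- function(x) {
  if (length(x) == 1L) return(matrix(x, 1))
  out <- NULL
  for (i in seq_along(x))
    out <- rbind(out, cbind(x[i], permutations_of(x[-i])))
  out
}

#' Per-gene selection report
#'
#' Combines the codon-position tabulation, the 1-vs-3 and 2-vs-3
#' chi-squared tests and (when an outgroup is supplied) the
#' McDonald-Kreitman test into one per-gene table.  Per-gene tests are
#' reported uncorrected, with a Bonferroni-adjusted column alongside for
#' transparency.
#'
#' @param sites Pooled called sites.
#' @param genome,annotation,code Reference model.
#' @param outgroup Optional aligned outgroup sequence for fixed
#'   differences.
#' @return A data frame, one row per protein-coding gene: codon-position
#'   counts, chi-squared statistics and p-values, and MK columns (Pn, Ps,
#'   Dn, Ds, fisher_p, NI, alpha) when an outgroup is given.
#' @export
selection_report <- function(sites, genome, annotation,
                             code = genetic_code(), outgroup = NULL) {
  tab <- tabulate_positions(sites, genome, annotation, code)
  pg <- tab$per_gene[tab$per_gene$kind == "PCG", , drop = FALSE]
  res <- do.call(rbind, lapply(seq_len(nrow(pg)), function(k) {
    r <- pg[k, ]
    c13 <- if (r$n1 + r$n3 > 0) chisq_positions(r$n1, r$n3) else
      list(statistic = NA_real_, p = NA_real_)
    c23 <- if (r$n2 + r$n3 > 0) chisq_positions(r$n2, r$n3) else
      list(statistic = NA_real_, p = NA_real_)
    data.frame(r, chi2_13 = c13$statistic, p_13 = c13$p,
               chi2_23 = c23$statistic, p_23 = c23$p,
               stringsAsFactors = FALSE)
  }))
  res$p_13_bonferroni <- pmin(1, res$p_13 * nrow(res))
  res$p_23_bonferroni <- pmin(1, res$p_23 * nrow(res))
  if (!is.null(outgroup)) {
    fd <- fixed_differences(genome$sequence, outgroup, annotation, code)
    res <- merge(res, fd, by = "gene", all.x = TRUE, sort = FALSE)
    mk <- lapply(seq_len(nrow(res)), function(k) {
      m <- mk_test(res$n_nonsyn[k], res$n_syn[k],
                   round(res$Dn[k]), round(res$Ds[k]), gene = res$gene[k])
      c(fisher_p = m$fisher_p, NI = m$NI, alpha = m$alpha)
    })
    mk <- do.call(rbind, mk)
    res$Pn <- res$n_nonsyn; res$Ps <- res$n_syn
    res$fisher_p <- mk[, "fisher_p"]; res$NI <- mk[, "NI"]
    res$alpha <- mk[, "alpha"]
  }
  res
}
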