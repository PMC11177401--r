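#' Classify a substitution by gene, codon position and synonymy
#'
#' Locates a 1-based genome position within the annotation and, for
#' protein-coding genes, reports the codon position (1-3) relative to the
#' polished reading frame and whether substituting `alt` for the reference
#' base is synonymous or non-synonymous under the genetic code.  Minus-strand
#' genes are classified on the reverse complement.  A position inside two
#' overlapping protein-coding genes (different frames) yields one row per
#' gene; positions in tRNA/rRNA features or between genes are `noncoding`.
#'
#' Genes with an abbreviated stop codon (length not divisible by 3) have
#' their terminal partial codon completed with A's, the poly-A tail that
#' restores the stop in the mature transcript.
#'
#' @param genome A [mito_genome()].
#' @param annotation A `mito_annotation` (ideally polished).
#' @param code A [genetic_code()].
#' @param position 1-based genome position.
#' @param alt Alternative base (on the plus/reference strand).
#' @return A data frame with columns `position`, `gene`, `codon_position`,
#'   `effect` (`synonymous`, `nonsynonymous`, `noncoding`), `ref_codon`,
#'   `alt_codon`; one row per overlapping PCG, or a single noncoding row.
#' @export
classify_substitution <- function(genome, annotation, code = genetic_code(),
                                  position, alt) {
  stopifnot(inherits(genome, "mito_genome"))
  position <- as.integer(position)
  alt <- toupper(alt)
  if (position < 1L || position > genome$length)
    stopf("position %d outside genome of length %d", position, genome$length)
  if (!alt %in% BASES) stopf("alt must be one of A,C,G,T")
  ref <- genome_base(genome, position)
  if (alt == ref)
    stopf("alt equals the reference base '%s' at position %d", ref, position)

  hits <- features_at(annotation, position, genome$length, genome$circular)
  pcg <- hits[hits$kind == "PCG", , drop = FALSE]
  if (nrow(pcg) == 0L) {
    gene <- if (nrow(hits) > 0L) hits$name[1] else NA_character_
    return(classification_row(position, gene, NA_integer_, "noncoding",
                              NA_character_, NA_character_))
  }
  rows <- lapply(seq_len(nrow(pcg)), function(k)
    classify_in_pcg(genome, pcg[k, ], code, position, alt))
  do.call(rbind, rows)
}

features_at <- function(annotation, position, L, circular = TRUE) {
  if (nrow(annotation) == 0L)
    return(annotation)
  hit <- vapply(seq_len(nrow(annotation)), function(k) {
    f <- annotation[k, ]
    if (f$start <= f$end) position >= f$start && position <= f$end
    else circular && (position >= f$start || position <= f$end)
  }, logical(1))
  annotation[hit, , drop = FALSE]
}

classification_row <- function(position, gene, codon_position, effect,
                               ref_codon, alt_codon) {
  data.frame(position = position, gene = gene,
             codon_position = codon_position, effect = effect,
             ref_codon = ref_codon, alt_codon = alt_codon,
             stringsAsFactors = FALSE)
}

classify_in_pcg <- function(genome, feat, code, position, alt) {
  L <- genome$length
  pos5to3 <- feature_span(feat, L)
  if (feat$strand == "-") pos5to3 <- rev(pos5to3)
  i <- match(position, pos5to3) - 1L        # 0-based offset in coding frame
  codon_position <- (i %% 3L) + 1L
  codon_start <- i - (i %% 3L)
  codon_pos_genomic <- pos5to3[codon_start + 1:3]   # may contain NA at 3' tail
  bases <- ifelse(is.na(codon_pos_genomic), "A",
                  genome_base(genome, ifelse(is.na(codon_pos_genomic), 1L,
                                             codon_pos_genomic)))
  if (feat$strand == "-") {
    bases <- ifelse(is.na(codon_pos_genomic), "A", comp_base(bases))
  }
  ref_codon <- paste0(bases, collapse = "")
  alt_coding <- if (feat$strand == "-") comp_base(alt) else alt
  alt_bases <- bases
  alt_bases[codon_position] <- alt_coding
  alt_codon <- paste0(alt_bases, collapse = "")
  effect <- if (translate_codon(ref_codon, code) ==
                translate_codon(alt_codon, code)) "synonymous" else "nonsynonymous"
  classification_row(position, feat$name, codon_position, effect,
                     ref_codon, alt_codon)
}

#' Classify many (position, alt) pairs at once
#'
#' Vectorised wrapper around [classify_substitution()]; returns the stacked
#' classification rows.  Used by the site-tabulation and simulation code.
#'
#' @inheritParams classify_substitution
#' @param positions Integer vector of 1-based positions.
#' @param alts Character vector of alternative bases, same length.
#' @return A data frame as in [classify_substitution()] with one or more
#'   rows per input pair.
#' @export
classify_sites <- function(genome, annotation, code = genetic_code(),
                           positions, alts) {
  stopifnot(length(positions) == length(alts))
  if (length(positions) == 0L)
    return(classification_row(integer(0), character(0), integer(0),
                              character(0), character(0), character(0)))
  do.call(rbind, lapply(seq_along(positions), function(k)
    classify_substitution(genome, annotation, code, positions[k], alts[k])))
}

#' Genome-wide substitution-effect lookup
#'
#' For a fixed alternative base per position, computes the effect
#' (`synonymous` / `nonsynonymous` / `noncoding`) of substituting it at
#' every position of the genome in one vectorised pass per gene.  A position
#' covered by two protein-coding genes in different frames is marked
#' `nonsynonymous` if the change is non-synonymous in either frame.  Also
#' returns the codon position (NA outside protein-coding genes; for
#' overlapping genes, that of the first gene encountered).
#'
#' @inheritParams classify_substitution
#' @param alts Character vector of length `L_mt` giving the alternative base
#'   at each position (entries equal to the reference are ignored and
#'   reported as NA effect).
#' @return A list with character vector `effect` and integer vector
#'   `codon_position`, each of length `L_mt`.
#' @export
effect_profile <- function(genome, annotation, code = genetic_code(), alts) {
  L <- genome$length
  stopifnot(length(alts) == L)
  refs <- genome_base(genome, seq_len(L))
  effect <- rep("noncoding", L)
  codon_position <- rep(NA_integer_, L)
  syn_seen <- logical(L); nonsyn_seen <- logical(L)

  pcg <- annotation[annotation$kind == "PCG", , drop = FALSE]
  for (k in seq_len(nrow(pcg))) {
    feat <- pcg[k, ]
    pos <- feature_span(feat, L)
    if (feat$strand == "-") pos <- rev(pos)
    bases <- genome_base(genome, pos)
    a <- alts[pos]
    if (feat$strand == "-") { bases <- comp_base(bases); a <- comp_base(a) }
    n <- length(pos)
    pad <- (3L - n %% 3L) %% 3L
    if (pad > 0L) { bases <- c(bases, rep("A", pad)); a <- c(a, rep("A", pad)) }
    m <- matrix(bases, nrow = 3L)
    ref_cod <- paste0(m[1, ], m[2, ], m[3, ])
    ref_aa <- code$codons[ref_cod]
    cp <- rep_len(1:3, n)
    idx_cod <- (seq_len(n) - 1L) %/% 3L + 1L
    alt_aa <- character(n)
    for (cpos in 1:3) {
      sel <- which(cp == cpos)
      mm <- m[, idx_cod[sel], drop = FALSE]
      mm[cpos, ] <- a[sel]
      alt_aa[sel] <- code$codons[paste0(mm[1, ], mm[2, ], mm[3, ])]
    }
    is_syn <- alt_aa == ref_aa[idx_cod]
    syn_seen[pos][is_syn] <- TRUE
    nonsyn_seen[pos][!is_syn] <- TRUE
    blank <- is.na(codon_position[pos])
    codon_position[pos][blank] <- cp[blank]
  }
  in_pcg <- syn_seen | nonsyn_seen
  effect[in_pcg] <- ifelse(nonsyn_seen[in_pcg], "nonsynonymous", "synonymous")
  same <- alts == refs
  effect[same] <- NA_character_
  list(effect = effect, codon_position = codon_position)
}
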