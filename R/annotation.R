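#' Gene feature table
#'
#' Builds a validated annotation table for a mitochondrial genome.  Features
#' are typed as protein-coding genes (`PCG`), `tRNA`, `rRNA` or `other`,
#' with 1-based inclusive coordinates.  On a circular genome a feature may
#' wrap the origin, stored as `start > end`.
#'
#' @param name Feature names.
#' @param kind One of `"PCG"`, `"tRNA"`, `"rRNA"`, `"other"` per feature.
#' @param start,end 1-based inclusive coordinates.
#' @param strand `"+"` or `"-"`.
#' @param notes Free-text notes (default empty).
#' @param L_mt Genome length for bounds checking (optional).
#' @param circular Whether wrap-around (`start > end`) features are allowed.
#' @return A data frame of class `mito_annotation`.
#' @export
gene_features <- function(name, kind, start, end, strand = "+",
                          notes = "", L_mt = NULL, circular = TRUE) {
  kinds <- c("PCG", "tRNA", "rRNA", "other")
  if (!all(kind %in% kinds))
    stopf("feature kind must be one of %s", paste(kinds, collapse = ", "))
  if (!all(strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  start <- as.integer(start); end <- as.integer(end)
  if (any(start < 1L) || any(end < 1L)) stopf("coordinates must be >= 1")
  if (!is.null(L_mt) && (any(start > L_mt) || any(end > L_mt)))
    stopf("feature coordinates exceed genome length %d", L_mt)
  if (!circular && any(start > end))
    stopf("start > end only permitted on a circular genome")
  df <- data.frame(name = as.character(name), kind = kind,
                   start = start, end = end,
                   strand = rep_len(strand, length(name)),
                   notes = rep_len(as.character(notes), length(name)),
                   stringsAsFactors = FALSE)
  class(df) <- c("mito_annotation", "data.frame")
  df
}

feature_span <- function(feat, L, circular = TRUE) {
  unroll_span(feat$start, feat$end, L, circular)
}

#' Read a GFF3-style feature table
#'
#' Accepts the tab-delimited 9-column GFF3 layout (seqid, source, type,
#' start, end, score, strand, phase, attributes).  The feature name is taken
#' from a `Name=` attribute (falling back to `ID=`, then the type).  GFF
#' types `CDS`/`gene` map to `PCG`, `tRNA` and `rRNA` to themselves,
#' anything else to `other`.
#'
#' @param path File path.
#' @param L_mt Optional genome length for bounds checking.
#' @return A `mito_annotation` data frame.
#' @export
read_feature_table <- function(path, L_mt = NULL) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(lines) == 0L) stopf("no features in %s", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 9L)) stopf("malformed GFF line (need 9 columns)")
  get <- function(i) vapply(parts, `[[`, "", i)
  type <- get(3)
  kind <- ifelse(type %in% c("CDS", "gene", "PCG"), "PCG",
          ifelse(type == "tRNA", "tRNA",
          ifelse(type == "rRNA", "rRNA", "other")))
  attrs <- get(9)
  name <- vapply(seq_along(attrs), function(i) {
    m <- regmatches(attrs[i], regexec("(?:^|;)\\s*Name=([^;]+)", attrs[i]))[[1]]
    if (length(m) == 2L) return(m[2])
    m <- regmatches(attrs[i], regexec("(?:^|;)\\s*ID=([^;]+)", attrs[i]))[[1]]
    if (length(m) == 2L) return(m[2])
    type[i]
  }, "")
  gene_features(name, kind, as.integer(get(4)), as.integer(get(5)),
                strand = get(7), L_mt = L_mt)
}

#' Write a feature table in GFF3-like format
#'
#' @param annotation A `mito_annotation`.
#' @param path Output path.
#' @param seqid Sequence id for column 1.
#' @export
write_feature_table <- function(annotation, path, seqid = "mtDNA") {
  type <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", other = "region")[annotation$kind]
  attr_col <- sprintf("Name=%s%s", annotation$name,
                      ifelse(nzchar(annotation$notes),
                             sprintf(";note=%s", annotation$notes), ""))
  lines <- sprintf("%s\tmitohet\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   seqid, type, annotation$start, annotation$end,
                   annotation$strand, attr_col)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}

# ---- annotation polishing ---------------------------------------------------

#' Polish a draft annotation
#'
#' Applies the manual curation rules used for mitochondrial genomes to a
#' draft annotation, in order: (1) tRNA predictions are trusted and returned
#' unchanged; (2) each protein-coding gene is assumed to begin at the first
#' eligible in-frame start codon nearest to the preceding gene, without
#' overlapping it; (3) protein-coding genes never overlap tRNAs, so their
#' ends are truncated to abut them; (4) two protein-coding genes may overlap
#' only in different reading frames, otherwise the upstream gene is
#' truncated; (5) truncation may leave an abbreviated stop (a terminal T or
#' TA completed by polyadenylation), recorded in `notes`; (6) start-codon
#' eligibility uses the code's start set (ATG, ATA, ATT, ATC, TTG, GTG);
#' (7) rRNA boundaries are returned as given, never extended.
#'
#' Wrap-around features on a circular genome are handled by unrolling the
#' circle into a linear coordinate frame around each gene.
#'
#' @param genome A [mito_genome()].
#' @param draft A `mito_annotation` of draft features.
#' @param code A [genetic_code()].
#' @return A polished `mito_annotation` (same rows, same order).
#' @export
polish_annotation <- function(genome, draft, code = genetic_code()) {
  stopifnot(inherits(genome, "mito_genome"), inherits(draft, "data.frame"))
  L <- genome$length
  out <- draft
  pcg_idx <- which(draft$kind == "PCG")

  for (i in pcg_idx) {
    out[i, ] <- polish_one_pcg(genome, out, i, code)
  }
  # rule 4: same-frame PCG-PCG overlap -> truncate the upstream gene
  for (i in pcg_idx) {
    for (j in pcg_idx) {
      if (i == j) next
      out[i, ] <- truncate_same_frame_overlap(genome, out[i, ], out[j, ])
    }
  }
  for (i in pcg_idx) out[i, ] <- flag_abbreviated_stop(genome, out[i, ])
  class(out) <- c("mito_annotation", "data.frame")
  out
}

# Linearized view of a gene and its neighbours: offsets relative to an
# unrolled coordinate c = start .. start + len - 1 mapped to ((c-1) mod L)+1.
lin_pos <- function(p, ref_start, L) {
  ((p - ref_start) %% L)
}

polish_one_pcg <- function(genome, ann, i, code) {
  feat <- ann[i, ]
  L <- genome$length
  len <- span_length(feat$start, feat$end, L)
  others <- ann[-i, , drop = FALSE]

  # Work in a coding-oriented frame: position 0 = 5' end of the gene.
  if (feat$strand == "+") {
    five_prime <- feat$start
  } else {
    five_prime <- feat$end
  }

  # Distance (bases) from the gene 5' end to the nearest upstream feature
  # boundary, measured against the coding direction.
  gap <- upstream_gap(genome, feat, others)

  # rule 2: candidate 5' extensions/contractions in steps of 3; scan from the
  # outermost in-frame position (nearest the preceding gene) inward, take the
  # first eligible start codon.
  max_ext <- (gap %/% 3L) * 3L
  offsets <- seq.int(-max_ext, len - 3L, by = 3L)
  chosen <- NA_integer_
  for (off in offsets) {
    codon <- coding_codon_at(genome, feat, off)
    if (codon %in% code$start_codons) { chosen <- off; break }
  }
  if (is.na(chosen))
    stopf("no eligible start codon for gene '%s' within its span", feat$name)
  feat <- shift_five_prime(feat, chosen, L)

  # rule 3: truncate 3' end so the gene does not overlap any tRNA
  feat <- truncate_to_trnas(genome, feat, others)
  feat
}

# Gap in bases between this gene's 5' end and the closest other feature lying
# upstream of it (in coding orientation), not counting wrap beyond one turn.
upstream_gap <- function(genome, feat, others) {
  L <- genome$length
  if (nrow(others) == 0L) return(0L)
  if (feat$strand == "+") {
    # distance from each other-feature 3'-most base to feat$start, going left
    d <- (feat$start - others$end - 1L) %% L
  } else {
    d <- (others$start - feat$end - 1L) %% L
  }
  # features "upstream" within half a genome; guard against self-ish overlaps
  as.integer(min(d))
}

# Codon at coding-frame offset `off` (0 = current 5' end; negative = upstream).
coding_codon_at <- function(genome, feat, off) {
  L <- genome$length
  if (feat$strand == "+") {
    p <- ((feat$start - 1L + off + 0:2) %% L) + 1L
    paste0(genome_base(genome, p), collapse = "")
  } else {
    p <- ((feat$end - 1L - off - 0:2) %% L) + 1L
    paste0(comp_base(genome_base(genome, p)), collapse = "")
  }
}

shift_five_prime <- function(feat, off, L) {
  if (off == 0L) return(feat)
  if (feat$strand == "+") {
    feat$start <- as.integer(((feat$start - 1L + off) %% L) + 1L)
  } else {
    feat$end <- as.integer(((feat$end - 1L - off) %% L) + 1L)
  }
  feat
}

truncate_to_trnas <- function(genome, feat, others) {
  L <- genome$length
  trnas <- others[others$kind == "tRNA", , drop = FALSE]
  if (nrow(trnas) == 0L) return(feat)
  len <- span_length(feat$start, feat$end, L)
  gene_pos <- feature_span(feat, L)
  trna_pos <- unique(unlist(lapply(seq_len(nrow(trnas)), function(k)
    feature_span(trnas[k, ], L))))
  hit <- gene_pos %in% trna_pos
  if (!any(hit)) return(feat)
  # truncate at the first overlapped base from the 3' side of the gene
  if (feat$strand == "+") {
    cut <- min(which(hit))          # index within gene_pos (5'->3')
    if (cut == 1L) stopf("gene '%s' entirely within a tRNA", feat$name)
    feat$end <- as.integer(gene_pos[cut - 1L])
  } else {
    ord <- rev(gene_pos)            # coding order for minus strand
    hit2 <- ord %in% trna_pos
    cut <- min(which(hit2))
    if (cut == 1L) stopf("gene '%s' entirely within a tRNA", feat$name)
    feat$start <- as.integer(ord[cut - 1L])
  }
  feat
}

truncate_same_frame_overlap <- function(genome, up, down) {
  L <- genome$length
  if (up$strand != down$strand) return(up)   # different strands: frames differ
  up_pos <- feature_span(up, L)
  down_pos <- feature_span(down, L)
  ov <- intersect(up_pos, down_pos)
  if (length(ov) == 0L) return(up)
  # same reading frame iff 5' ends are congruent mod 3 along the strand
  if (up$strand == "+") {
    same_frame <- (up$start %% 3L) == (down$start %% 3L)
  } else {
    same_frame <- (up$end %% 3L) == (down$end %% 3L)
  }
  if (!same_frame) return(up)
  # truncate `up` only when `down` starts inside it (i.e. up is the upstream
  # gene); otherwise leave it for the reciprocal call.
  if (up$strand == "+") {
    if (!(down$start %in% up_pos) || down$start == up$start) return(up)
    idx <- match(down$start, up_pos)
    up$end <- as.integer(up_pos[idx - 1L])
  } else {
    if (!(down$end %in% up_pos) || down$end == up$end) return(up)
    ord <- rev(up_pos)
    idx <- match(down$end, ord)
    up$start <- as.integer(ord[idx - 1L])
  }
  up
}

flag_abbreviated_stop <- function(genome, feat) {
  L <- genome$length
  len <- span_length(feat$start, feat$end, L)
  rem <- len %% 3L
  if (rem == 0L || grepl("abbreviated_stop", feat$notes)) return(feat)
  pos <- feature_span(feat, L)
  ord <- if (feat$strand == "+") pos else rev(pos)
  tail_pos <- ord[(len - rem + 1L):len]
  bases <- genome_base(genome, tail_pos)
  if (feat$strand == "-") bases <- comp_base(bases)
  partial <- paste0(bases, collapse = "")
  note <- sprintf("abbreviated_stop:%s", partial)
  feat$notes <- if (nzchar(feat$notes) && !grepl("abbreviated_stop", feat$notes))
    paste(feat$notes, note, sep = ";") else note
  feat
}
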