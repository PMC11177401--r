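#' Mitochondrial genome container
#'
#' Holds a single circular (or linear) mitochondrial reference sequence.
#' The sequence alphabet is restricted to A, C, G, T: ambiguity codes are
#' rejected at construction so that downstream codon arithmetic never has to
#' handle them.
#'
#' @param id Sequence identifier.
#' @param sequence Nucleotide string over ACGT (case-insensitive).
#' @param circular Logical; circular genomes wrap position arithmetic
#'   modulo the genome length.
#' @return An object of class `mito_genome` with fields `id`, `sequence`,
#'   `length` and `circular`.
#' @export
mito_genome <- function(id, sequence, circular = TRUE) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0L) stopf("empty genome sequence")
  if (grepl("[^ACGT]", sequence))
    stopf("genome sequence contains characters outside {A,C,G,T}")
  structure(
    list(id = id, sequence = sequence, length = nchar(sequence),
         circular = isTRUE(circular)),
    class = "mito_genome"
  )
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s: %d bp, %s\n", x$id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

# Bases at (possibly wrapped) positions, as a character vector.
genome_base <- function(genome, positions) {
  if (genome$circular) positions <- ((positions - 1L) %% genome$length) + 1L
  if (any(positions < 1L | positions > genome$length))
    stopf("position out of genome bounds")
  substring(genome$sequence, positions, positions)
}

#' Read a mitochondrial genome from FASTA
#'
#' Reads the first record of a FASTA file into a [mito_genome()].
#'
#' @param path FASTA file path.
#' @param circular Whether to treat the sequence as circular.
#' @return A `mito_genome`.
#' @export
read_mito_fasta <- function(path, circular = TRUE) {
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0L) stopf("no sequences in %s", path)
  id <- sub("\\s.*$", "", names(ss)[1])
  mito_genome(id, as.character(ss[[1]]), circular = circular)
}

#' Write a mitochondrial genome to FASTA
#'
#' @param genome A `mito_genome`.
#' @param path Output path.
#' @export
write_mito_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$sequence)
  names(ss) <- genome$id
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Genetic code for mitochondrial translation
#'
#' Wraps an NCBI translation table (default 5, invertebrate mitochondrial)
#' together with the start-codon set used for annotation polishing.  Besides
#' ATG, mitochondrial protein-coding genes may start at ATA (Met), ATT/ATC
#' (Ile), TTG (Leu) or GTG (Val).
#'
#' @param table_id NCBI translation table number (default 5).
#' @return An object of class `genetic_code` with the 64-entry codon table
#'   (`codons`, stop = `"*"`) and `start_codons`.
#' @export
genetic_code <- function(table_id = 5L) {
  tab <- Biostrings::getGeneticCode(as.character(table_id))
  codons <- as.character(tab)
  names(codons) <- names(tab)
  stopifnot(length(codons) == 64L)
  structure(
    list(table_id = as.integer(table_id), codons = codons,
         start_codons = c("ATG", "ATA", "ATT", "ATC", "TTG", "GTG")),
    class = "genetic_code"
  )
}

#' Translate a single codon
#'
#' @param codon A 3-letter codon over ACGT.
#' @param code A [genetic_code()].
#' @return One-letter amino-acid symbol; `"*"` for stop.
#' @export
translate_codon <- function(codon, code = genetic_code()) {
  codon <- toupper(codon)
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L ||
      grepl("[^ACGT]", codon))
    stopf("codon must be a 3-mer over {A,C,G,T}, got '%s'", codon)
  unname(code$codons[[codon]])
}
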