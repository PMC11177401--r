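# Fixtures are built in code; nothing is read from disk.

# A tiny hand-crafted genome: one plus-strand PCG of 4 codons (ATG AAA GGA
# TAA) at 1..12, a tRNA at 16..30, and a minus-strand PCG at 34..45 whose
# coding sequence is also ATG AAA GGA TAA.
toy_genome <- function() {
  pcg1 <- "ATGAAAGGATAA"
  spacer1 <- "CCC"
  trna <- paste(rep("T", 15), collapse = "")
  spacer2 <- "CCC"
  pcg2 <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString("ATGAAAGGATAA")))
  tail <- "CCCCC"
  genome <- mito_genome("toy", paste0(pcg1, spacer1, trna, spacer2, pcg2, tail))
  ann <- gene_features(
    name = c("pcgA", "trnX", "pcgB"),
    kind = c("PCG", "tRNA", "PCG"),
    start = c(1L, 16L, 34L),
    end = c(12L, 30L, 45L),
    strand = c("+", "+", "-"),
    L_mt = genome$length)
  list(genome = genome, annotation = ann)
}

# Small, fast simulation settings used across test files.  Smaller genome and
# sibships than the package defaults, same model.
small_layout <- function() {
  data.frame(name = c("g1", "trnA", "g2", "g3", "trnB"),
             kind = c("PCG", "tRNA", "PCG", "PCG", "tRNA"),
             length = c(300L, 60L, 300L, 300L, 60L),
             strand = c("+", "+", "-", "+", "+"),
             stringsAsFactors = FALSE)
}

small_cfg <- function(seed = 1L, ...) {
  args <- utils::modifyList(
    list(seed = seed, L_mt = 2000L, gene_layout = small_layout(),
         offspring_per_cross = 12L, founder_het_sites = 80L),
    list(...))
  do.call(sim_config, args)
}

# Build a count-table row in the primary dialect.
count_row <- function(pos, ref, depth, A = 0L, C = 0L, G = 0L, T = 0L,
                      individual = "s1") {
  data.frame(individual = individual, chrom = "mt", pos = pos, ref = ref,
             depth = depth, count_A = A, count_C = C, count_G = G,
             count_T = T, stringsAsFactors = FALSE)
}

# Minimal hand-built matriline state around a given frequency matrix, for
# driving simulate_readcounts with exact ground truth.
manual_state <- function(freqs, genome, config, mothers = NA_character_) {
  ids <- rownames(freqs)
  set.seed(sub_seed_for_tests(config$seed))
  alt <- vapply(genome_base_for_tests(genome), function(r)
    sample(setdiff(c("A", "C", "G", "T"), r), 1L), "")
  individuals <- data.frame(
    id = ids, mother = rep_len(mothers, length(ids)),
    father = NA_character_,
    generation = ifelse(is.na(rep_len(mothers, length(ids))), 1L, 2L),
    copy_ratio = 30, repeat_copies = 3, n_denovo = 0L,
    stringsAsFactors = FALSE)
  structure(list(individuals = individuals, freqs = freqs, alt = alt,
                 effect = NULL, focal_parents = ids[1:2],
                 focal_offspring = ids[-(1:2)], config = config),
            class = "matriline_state")
}

# test-side access to internal helpers without ::: noise everywhere
sub_seed_for_tests <- function(seed) seed + 77L
genome_base_for_tests <- function(genome)
  strsplit(genome$sequence, "")[[1]]
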