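#' Simulation configuration for a synthetic matriline
#'
#' Bundles all parameters of the forward matriline simulator.  Defaults
#' describe the study system the package targets: a compact ~14.2 kb
#' circular mitogenome with 13 protein-coding genes, 2 rRNAs and 22 tRNAs; a
#' five-generation pedigree of about 90 snails culminating in a focal cross
#' with 76 offspring; heteroplasmy transmitted through a germline bottleneck
#' of 100 genome copies with de novo mutation and selection against
#' non-synonymous alleles; per-individual mtDNA-to-nuclear copy ratios
#' log-uniform on 5-80, with de novo mutation intensity inversely coupled to
#' copy ratio (a narrower effective bottleneck and more replication error at
#' low copy number); and Poisson/binomial short-read sequencing with a small
#' per-base error rate.
#'
#' @param seed Integer seed; identical seeds give bit-identical simulations.
#' @param L_mt Mitogenome length in bases.
#' @param gene_layout Data frame (name, kind, length, strand) laid out in
#'   order along the genome; see [default_gene_layout()].
#' @param n_generations Pedigree depth (founder = generation 1).
#' @param offspring_per_cross Offspring in the final focal cross.
#' @param side_sibs Sibship size in the intermediate generations.
#' @param bottleneck Germline bottleneck size `N_b` (genome copies).
#' @param mu De novo heteroplasmy seeding probability per site per
#'   generation, at the reference copy ratio (geometric mean of
#'   `copy_ratio_bounds`).
#' @param founder_het_sites Number of heteroplasmic sites in the founder.
#' @param founder_freq_mean Mean of the (exponential, truncated at 0.5)
#'   founder allele-frequency distribution.
#' @param selection_s Per-generation multiplicative penalty on
#'   non-synonymous alternative-allele frequencies, in `[0, 1]`.
#' @param copy_ratio_bounds Log-uniform bounds for the per-individual
#'   mtDNA-copies-per-nuclear-genome ratio.
#' @param kappa Exponent coupling de novo intensity to copy ratio
#'   (intensity proportional to `ratio^-kappa`); 0 switches coupling off.
#' @param error Per-base sequencing error rate.
#' @param mean_depth Mean sequencing depth over the mitogenome.
#' @param depth_model `"poisson"` (default) or `"fixed"` per-site depth.
#' @param G_nuc Haploid nuclear genome size in bases.
#' @param total_reads_target Approximate total read count per individual,
#'   used when back-constructing read totals from the true copy ratio.
#' @param repeat_region Two-element interval (start, end) of the tandem
#'   repeat used for depth simulation.
#' @param repeat_copies_range Uniform bounds for the true per-genome repeat
#'   copy number.
#' @param prob_mother_p1 Probability that a focal-cross offspring's true
#'   mother is the first focal parent.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       L_mt = 14202L,
                       gene_layout = default_gene_layout(),
                       n_generations = 5L,
                       offspring_per_cross = 76L,
                       side_sibs = 4L,
                       bottleneck = 100L,
                       mu = 0.01,
                       founder_het_sites = 520L,
                       founder_freq_mean = 0.026,
                       selection_s = 0.8,
                       copy_ratio_bounds = c(5, 80),
                       kappa = 1,
                       error = 0.001,
                       mean_depth = 100,
                       depth_model = c("poisson", "fixed"),
                       G_nuc = 3.5e9,
                       total_reads_target = 2.3e8,
                       repeat_region = c(1510L, 1833L),
                       repeat_copies_range = c(2, 4),
                       prob_mother_p1 = 0.5) {
  depth_model <- match.arg(depth_model)
  cfg <- list(seed = as.integer(seed), L_mt = as.integer(L_mt),
              gene_layout = gene_layout,
              n_generations = as.integer(n_generations),
              offspring_per_cross = as.integer(offspring_per_cross),
              side_sibs = as.integer(side_sibs),
              bottleneck = as.integer(bottleneck),
              mu = mu, founder_het_sites = as.integer(founder_het_sites),
              founder_freq_mean = founder_freq_mean,
              selection_s = selection_s,
              copy_ratio_bounds = as.numeric(copy_ratio_bounds),
              kappa = kappa, error = error, mean_depth = mean_depth,
              depth_model = depth_model, G_nuc = G_nuc,
              total_reads_target = total_reads_target,
              repeat_region = as.integer(repeat_region),
              repeat_copies_range = as.numeric(repeat_copies_range),
              prob_mother_p1 = prob_mother_p1)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(mu = cfg$mu, selection_s = cfg$selection_s, error = cfg$error,
             prob_mother_p1 = cfg$prob_mother_p1)
  bad <- probs < 0 | probs > 1
  if (any(bad))
    stopf("probabilities outside [0,1]: %s", paste(names(probs)[bad], collapse = ", "))
  if (cfg$bottleneck < 1L) stopf("bottleneck must be >= 1")
  if (cfg$L_mt < 1L) stopf("L_mt must be positive")
  if (any(cfg$copy_ratio_bounds <= 0) ||
      cfg$copy_ratio_bounds[1] > cfg$copy_ratio_bounds[2])
    stopf("copy_ratio_bounds must be positive and ordered")
  if (cfg$founder_freq_mean <= 0 || cfg$founder_freq_mean > 0.5)
    stopf("founder_freq_mean must be in (0, 0.5]")
  invisible(cfg)
}

#' Default mitogenome gene layout
#'
#' A snail-like complement of 13 protein-coding genes (typical metazoan
#' mitochondrial lengths), 2 rRNAs and 22 tRNAs, laid end to end; it sums to
#' just under the default genome length of 14,202 bases, leaving a short
#' non-coding remainder.  One gene (ND6) and three tRNAs are placed on the
#' minus strand so that strand-aware classification is exercised.
#'
#' @return A data frame with columns `name`, `kind`, `length`, `strand`.
#' @export
default_gene_layout <- function() {
  pcg <- data.frame(
    name = c("COX1", "COX2", "ATP8", "ATP6", "COX3", "ND3", "ND5", "ND1",
             "ND4L", "CYTB", "ND6", "ND4", "ND2"),
    kind = "PCG",
    length = c(1530L, 690L, 159L, 660L, 780L, 354L, 1716L, 900L,
               297L, 1140L, 480L, 1380L, 960L),
    strand = c(rep("+", 10), "-", "+", "+"),
    stringsAsFactors = FALSE)
  rrna <- data.frame(name = c("rrnL", "rrnS"), kind = "rRNA",
                     length = c(1050L, 780L), strand = "+",
                     stringsAsFactors = FALSE)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L1", "L2",
          "M", "N", "P", "Q", "R", "S1", "S2", "T", "V", "W", "Y")
  trna <- data.frame(name = paste0("trn", aa), kind = "tRNA",
                     length = 60L,
                     strand = ifelse(aa %in% c("C", "Q", "Y"), "-", "+"),
                     stringsAsFactors = FALSE)
  # interleave: a few tRNAs between the larger genes, mirroring compact
  # molluscan gene orders
  big <- rbind(pcg, rrna)
  out <- NULL
  ti <- 1L
  for (k in seq_len(nrow(big))) {
    out <- rbind(out, big[k, ])
    n_t <- if (ti <= nrow(trna)) min(2L, nrow(trna) - ti + 1L) else 0L
    if (n_t > 0L && k %% 1L == 0L) {
      take <- seq.int(ti, length.out = min(n_t, max(0L, nrow(trna) - ti + 1L)))
      if (length(take) > 0L) {
        out <- rbind(out, trna[take, ])
        ti <- ti + length(take)
      }
    }
  }
  if (ti <= nrow(trna)) out <- rbind(out, trna[seq.int(ti, nrow(trna)), ])
  rownames(out) <- NULL
  out
}

sub_seed <- function(seed, id, salt = "") {
  as.integer((as.numeric(seed) * 69069 + stable_hash(paste0(salt, id))) %%
               2147483629)
}

# ---- genome -----------------------------------------------------------------

#' Simulate a mitogenome and its annotation
#'
#' Generates a random circular genome realising `config$gene_layout`:
#' features are laid end to end from position 1 in layout order, each
#' protein-coding gene given a valid start codon, stop-free internal
#' codons and a full stop codon; any remaining bases form a trailing
#' non-coding stretch.
#'
#' @param config A [sim_config()].
#' @return A list with elements `genome` ([mito_genome()]) and `annotation`
#'   (`mito_annotation`).
#' @export
simulate_genome <- function(config) {
  layout <- config$gene_layout
  L <- config$L_mt
  if (any(layout$length[layout$kind == "PCG"] %% 3L != 0L))
    stopf("PCG lengths must be divisible by 3")
  if (sum(layout$length) > L)
    stopf("gene layout (%d bases) does not fit in genome of length %d",
          sum(layout$length), L)
  set.seed(sub_seed(config$seed, "genome"))
  seq_chars <- sample(BASES, L, replace = TRUE)

  code <- genetic_code()
  nonstop <- names(code$codons)[code$codons != "*"]
  starts <- integer(nrow(layout)); ends <- integer(nrow(layout))
  at <- 1L
  for (k in seq_len(nrow(layout))) {
    len <- layout$length[k]
    starts[k] <- at; ends[k] <- at + len - 1L
    if (layout$kind[k] == "PCG") {
      n_codon <- len %/% 3L
      codons <- c("ATG",
                  sample(nonstop, n_codon - 2L, replace = TRUE),
                  "TAA")
      coding <- unlist(strsplit(paste0(codons, collapse = ""), ""))
      if (layout$strand[k] == "-")
        coding <- rev(comp_base(coding))
      seq_chars[at:(at + len - 1L)] <- coding
    }
    at <- at + len
  }
  genome <- mito_genome("simulated_mt", paste0(seq_chars, collapse = ""))
  annotation <- gene_features(layout$name, layout$kind, starts, ends,
                              strand = layout$strand, L_mt = L)
  list(genome = genome, annotation = annotation)
}

# ---- matriline --------------------------------------------------------------

#' Simulate heteroplasmy transmission through a matriline
#'
#' Builds a pedigree (founder, intermediate sibships, and a final focal
#' cross between two full-sib parents) and propagates per-site heteroplasmy
#' frequencies down the maternal line.  Each offspring's frequency at a site
#' is `B / N_b` with `B ~ Binomial(N_b, f_mother)`; de novo events arrive
#' with per-site probability `mu * (R / R_ref)^-kappa` (where `R` is the
#' individual's copy ratio and `R_ref` the geometric mean of the configured
#' bounds) and seed frequency `1 / N_b`; after transmission, non-synonymous
#' alternative frequencies are multiplied by `1 - selection_s`.  Every
#' individual draws its own copy ratio (log-uniform) and true repeat copy
#' number.  Randomness is routed through per-individual sub-streams derived
#' by stable hashing of the individual id, so enlarging the pedigree never
#' perturbs existing individuals.
#'
#' @param config A [sim_config()].
#' @param genome,annotation Output of [simulate_genome()] (or compatible).
#' @return A list of class `matriline_state`: `individuals` (data frame with
#'   id, mother, father, generation, copy_ratio, repeat_copies, n_denovo),
#'   `freqs` (individuals x sites matrix of true alternative-allele
#'   frequencies), `alt` (per-site alternative base), `effect` (per-site
#'   substitution effect), `focal_parents`, `focal_offspring`, `config`.
#' @export
simulate_matriline <- function(config, genome, annotation) {
  validate_sim_config(config)
  L <- config$L_mt
  stopifnot(genome$length == L)
  ped <- build_pedigree(config)

  # fixed per-site alternative base and its effect, shared by the whole run
  set.seed(sub_seed(config$seed, "sites"))
  refs <- genome_base(genome, seq_len(L))
  alt <- vapply(refs, function(r) sample(setdiff(BASES, r), 1L), "")
  names(alt) <- NULL
  eff <- effect_profile(genome, annotation, genetic_code(), alt)
  nonsyn <- !is.na(eff$effect) & eff$effect == "nonsynonymous"

  n <- nrow(ped)
  freqs <- matrix(0, nrow = n, ncol = L, dimnames = list(ped$id, NULL))
  copy_ratio <- numeric(n); repeat_copies <- numeric(n); n_denovo <- integer(n)
  r_ref <- exp(mean(log(config$copy_ratio_bounds)))
  lb <- log(config$copy_ratio_bounds)

  for (i in seq_len(n)) {
    id <- ped$id[i]
    set.seed(sub_seed(config$seed, id, "indiv"))
    copy_ratio[i] <- exp(stats::runif(1, lb[1], lb[2]))
    repeat_copies[i] <- stats::runif(1, config$repeat_copies_range[1],
                                     config$repeat_copies_range[2])
    lambda <- min(1, config$mu * (copy_ratio[i] / r_ref)^(-config$kappa))
    if (is.na(ped$mother[i])) {             # founder
      f <- numeric(L)
      sites <- sample.int(L, config$founder_het_sites)
      f[sites] <- pmin(0.5, stats::rexp(length(sites), 1 / config$founder_freq_mean))
      f[sites] <- pmax(f[sites], 1 / config$bottleneck)
      freqs[i, ] <- f
      next
    }
    fm <- freqs[ped$mother[i], ]
    f <- stats::rbinom(L, config$bottleneck, fm) / config$bottleneck
    dn <- which(stats::runif(L) < lambda)
    n_denovo[i] <- length(dn)
    f[dn] <- pmax(f[dn], 1 / config$bottleneck)
    f[nonsyn] <- f[nonsyn] * (1 - config$selection_s)
    freqs[i, ] <- f
  }

  ped$copy_ratio <- copy_ratio
  ped$repeat_copies <- repeat_copies
  ped$n_denovo <- n_denovo
  structure(
    list(individuals = ped, freqs = freqs, alt = alt, effect = eff,
         focal_parents = attr(ped, "focal_parents"),
         focal_offspring = attr(ped, "focal_offspring"),
         config = config),
    class = "matriline_state"
  )
}

# Pedigree: founder (gen 1); sibships of side_sibs in gens 2..(G-2); the
# parental generation (G-1) holds the two focal parents plus side sibs; the
# final generation is the focal cross.  Fathers are outside the matriline
# and recorded as unknown.
build_pedigree <- function(config) {
  G <- config$n_generations
  if (G < 2L) stopf("n_generations must be >= 2")
  rows <- list()
  rows[[1]] <- data.frame(id = "F1", mother = NA_character_,
                          father = NA_character_, generation = 1L,
                          stringsAsFactors = FALSE)
  mother_id <- "F1"
  if (G > 2L) {
    for (g in 2:(G - 1L)) {
      n_sib <- if (g == G - 1L) max(2L, config$side_sibs + 1L) else config$side_sibs
      ids <- sprintf("G%d_%02d", g, seq_len(n_sib))
      rows[[g]] <- data.frame(id = ids, mother = mother_id,
                              father = NA_character_, generation = g,
                              stringsAsFactors = FALSE)
      mother_id <- ids[1]
    }
  }
  if (G == 2L) {
    parents <- c("F1", "F1")   # degenerate two-generation pedigree
  } else {
    parents <- rows[[G - 1L]]$id[1:2]
  }
  set.seed(sub_seed(config$seed, "pedigree"))
  mothers <- ifelse(stats::runif(config$offspring_per_cross) < config$prob_mother_p1,
                    parents[1], parents[2])
  off_ids <- sprintf("O%03d", seq_len(config$offspring_per_cross))
  rows[[G]] <- data.frame(id = off_ids, mother = mothers,
                          father = rev(parents)[match(mothers, parents)],
                          generation = G, stringsAsFactors = FALSE)
  ped <- do.call(rbind, rows)
  rownames(ped) <- NULL
  attr(ped, "focal_parents") <- unique(parents)
  attr(ped, "focal_offspring") <- off_ids
  ped
}

# ---- sequencing emulation ---------------------------------------------------

#' Simulate per-site allele-count tables
#'
#' Emulates short-read sequencing of each individual: per-site depth is
#' Poisson (or fixed) around `mean_depth`; reads supporting the designated
#' alternative base are `Binomial(depth, f (1 - e) + (1 - f) e / 3)`, and
#' the remaining error reads are split between the two other non-reference
#' bases (sequential multinomial decomposition, so counts always sum to
#' depth).  Read totals are back-constructed so that
#' `mt_reads / total_reads * G_nuc / L_mt` recovers the true copy ratio to
#' within rounding of the read counts.
#'
#' @param state A `matriline_state` from [simulate_matriline()].
#' @param genome The simulated [mito_genome()].
#' @param config The [sim_config()] used.
#' @param individuals Optional subset of individual ids.
#' @return A list with `counts` (long data frame: individual, chrom, pos,
#'   ref, depth, count_A..count_T) and `totals` (data frame: individual,
#'   mt_reads, total_reads, G_nuc, L_mt).
#' @export
simulate_readcounts <- function(state, genome, config = state$config,
                                individuals = NULL) {
  ids <- individuals %||% state$individuals$id
  L <- config$L_mt
  refs <- genome_base(genome, seq_len(L))
  alt <- state$alt
  eps <- config$error
  per_ind <- vector("list", length(ids))
  mt_reads <- integer(length(ids)); total_reads <- numeric(length(ids))

  ref_idx <- match(refs, BASES)
  alt_idx <- match(alt, BASES)
  # the two non-ref, non-alt base indices per position (vectorised over the
  # 12 possible ref/alt pairs)
  other <- matrix(0L, nrow = L, ncol = 2)
  for (r in 1:4) for (a in setdiff(1:4, r)) {
    sel <- ref_idx == r & alt_idx == a
    if (any(sel)) other[sel, ] <- matrix(setdiff(1:4, c(r, a)),
                                         nrow = sum(sel), ncol = 2, byrow = TRUE)
  }

  for (k in seq_along(ids)) {
    id <- ids[k]
    set.seed(sub_seed(config$seed, id, "reads"))
    f <- state$freqs[id, ]
    depth <- if (config$depth_model == "poisson")
      stats::rpois(L, config$mean_depth) else rep(as.integer(config$mean_depth), L)
    p_alt <- f * (1 - eps) + (1 - f) * eps / 3
    n_alt <- stats::rbinom(L, depth, p_alt)
    rest <- depth - n_alt
    p_e <- (1 - f) * eps / 3 + f * eps / 3   # error reads to each other base
    q1 <- ifelse(p_alt >= 1, 0, p_e / (1 - p_alt))
    n_e1 <- stats::rbinom(L, rest, pmin(1, q1))
    rest2 <- rest - n_e1
    q2 <- ifelse(p_alt + p_e >= 1, 0, p_e / (1 - p_alt - p_e))
    n_e2 <- stats::rbinom(L, rest2, pmin(1, q2))
    n_ref <- rest2 - n_e2

    cm <- matrix(0L, nrow = L, ncol = 4)
    cm[cbind(seq_len(L), ref_idx)] <- n_ref
    cm[cbind(seq_len(L), alt_idx)] <- cm[cbind(seq_len(L), alt_idx)] + n_alt
    cm[cbind(seq_len(L), other[, 1])] <- cm[cbind(seq_len(L), other[, 1])] + n_e1
    cm[cbind(seq_len(L), other[, 2])] <- cm[cbind(seq_len(L), other[, 2])] + n_e2

    per_ind[[k]] <- data.frame(individual = id, chrom = genome$id,
                               pos = seq_len(L), ref = refs, depth = depth,
                               count_A = cm[, 1], count_C = cm[, 2],
                               count_G = cm[, 3], count_T = cm[, 4],
                               stringsAsFactors = FALSE)

    r_true <- state$individuals$copy_ratio[state$individuals$id == id]
    f_mt <- r_true * L / config$G_nuc
    mt <- max(1L, as.integer(round(f_mt * config$total_reads_target)))
    mt_reads[k] <- mt
    total_reads[k] <- round(mt / f_mt)
  }
  list(counts = do.call(rbind, per_ind),
       totals = data.frame(individual = ids, mt_reads = mt_reads,
                           total_reads = total_reads, G_nuc = config$G_nuc,
                           L_mt = L, stringsAsFactors = FALSE))
}

#' Simulate a per-base depth profile with a tandem repeat
#'
#' Depth is Poisson with mean `flank_depth` outside the repeat interval and
#' `r_true * flank_depth` inside it, emulating the elevated coverage of a
#' collapsed multi-copy repeat in a single-copy assembly.
#'
#' @param r_true True per-genome repeat copy number (>= 0).
#' @param flank_depth Mean depth of single-copy sequence.
#' @param repeat_region Two-element (start, end) interval, 1-based inclusive.
#' @param L_mt Genome length.
#' @return Integer vector of per-base depths, length `L_mt`.
#' @export
simulate_depth_profile <- function(r_true, flank_depth, repeat_region, L_mt) {
  stopifnot(is_scalar_number(r_true), is_scalar_number(flank_depth))
  if (length(repeat_region) != 2L || repeat_region[1] > repeat_region[2])
    stopf("repeat_region must be a non-empty (start, end) interval")
  if (repeat_region[1] < 1L || repeat_region[2] > L_mt)
    stopf("repeat_region outside genome bounds")
  mu <- rep(flank_depth, L_mt)
  mu[repeat_region[1]:repeat_region[2]] <- r_true * flank_depth
  stats::rpois(L_mt, mu)
}
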