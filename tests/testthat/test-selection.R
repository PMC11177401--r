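test_that("site tabulation counts unique variants by codon position", {
  fx <- toy_genome()
  code <- genetic_code()
  # three third-position variants in pcgA (positions 3, 6, 9), the middle
  # one shared by many individuals, counted once when pooled
  sites <- data.frame(
    individual = c("a", "a", rep(letters[1:20], each = 1), "b"),
    position = c(3L, 6L, rep(6L, 20), 9L),
    ref = "A", alt = "G", alt_freq = 0.1, depth = 100,
    stringsAsFactors = FALSE)
  sites$ref <- substring(fx$genome$sequence, sites$position, sites$position)
  sites$alt <- ifelse(sites$ref == "G", "T", "G")
  tab <- tabulate_positions(sites, fx$genome, fx$annotation, code)
  g <- tab$per_gene[tab$per_gene$gene == "pcgA", ]
  expect_equal(g$n3, 3)
  expect_equal(g$n1, 0)
  expect_equal(g$n2, 0)
  expect_equal(tab$n_unique_sites, 3L)

  # per-individual counting weights the shared site by its carriers
  tab_pi <- tabulate_positions(sites, fx$genome, fx$annotation, code,
                               per_individual = TRUE)
  g_pi <- tab_pi$per_gene[tab_pi$per_gene$gene == "pcgA", ]
  expect_equal(g_pi$n3, 23)

  # empty input yields empty, well-formed output
  empty <- tabulate_positions(sites[0, ], fx$genome, fx$annotation, code)
  expect_equal(empty$n_unique_sites, 0L)
  expect_equal(unname(empty$pooled["n3"]), 0)
})

test_that("codon-position chi-squared matches the hand formula", {
  null <- chisq_positions(45, 45)
  expect_equal(null$statistic, 0)
  expect_equal(null$p, 1)

  # a strong third-position excess: 6 first-position vs 84 third-position
  cox1 <- chisq_positions(6, 84)
  expect_equal(cox1$statistic, (6 - 45)^2 / 45 + (84 - 45)^2 / 45)
  expect_equal(cox1$statistic, 67.6)
  expect_lt(cox1$p, 1e-15)

  expect_equal(chisq_positions(0, 84)$statistic, 84)
  expect_false(chisq_positions(1, 3)$valid_asymptotic)
  expect_error(chisq_positions(0, 0), "nA \\+ nB")

  # generic contingency-test oracle on random count pairs
  set.seed(7)
  for (k in 1:100) {
    a <- rpois(1, 30); b <- rpois(1, 30)
    if (a + b == 0) next
    ours <- chisq_positions(a, b)
    ref <- suppressWarnings(stats::chisq.test(c(a, b), p = c(0.5, 0.5)))
    expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-9)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("the McDonald-Kreitman test reports NI, alpha and exact p", {
  neutral <- mk_test(10, 10, 10, 10)
  expect_equal(neutral$NI, 1)
  expect_equal(neutral$alpha, 0)
  expect_equal(neutral$fisher_p, 1)

  m <- mk_test(2, 20, 10, 20)
  expect_equal(m$NI, 0.2)
  expect_equal(m$alpha, 0.8)
  # hypergeometric enumeration oracle: sum of point probabilities <= observed
  p_obs <- stats::dhyper(2, 12, 40, 22)
  p_enum <- sum(stats::dhyper(0:12, 12, 40, 22)[
    stats::dhyper(0:12, 12, 40, 22) <= p_obs + 1e-12])
  expect_equal(m$fisher_p, p_enum, tolerance = 1e-9)

  # undefined markers, never silent zeros
  expect_true(is.na(mk_test(5, 0, 3, 7)$alpha))
  expect_true(is.na(mk_test(5, 3, 0, 7)$NI))
  expect_error(mk_test(-1, 1, 1, 1), "non-negative")

  # Fisher p is symmetric under swapping rows and under swapping columns
  set.seed(9)
  for (k in 1:20) {
    v <- rpois(4, 8)
    p0 <- mk_test(v[1], v[2], v[3], v[4])$fisher_p
    expect_equal(mk_test(v[3], v[4], v[1], v[2])$fisher_p, p0, tolerance = 1e-12)
    expect_equal(mk_test(v[2], v[1], v[4], v[3])$fisher_p, p0, tolerance = 1e-12)
  }
})

test_that("sliding Pi equals the brute-force pairwise average", {
  s <- strrep("ACGT", 250)   # 1000 bases
  expect_true(all(sliding_pi(c(s, s), window = 500)$pi == 0))

  s2 <- paste0(substr(s, 1, 100), "T", substr(s, 102, 1000))  # A101 -> T
  pw <- sliding_pi(c(s, s2), window = 500, step = 100)
  expect_equal(pw$pi[1], 1 / 500)
  expect_equal(pw$pi[pw$window_start == 201], 0)

  # random alignment vs direct pairwise loop
  set.seed(14)
  seqs <- vapply(1:4, function(i)
    paste0(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = ""),
    "")
  prof <- sliding_pi(seqs, window = 500, step = 100)
  mats <- do.call(rbind, strsplit(seqs, ""))
  for (w in seq_len(nrow(prof))) {
    idx <- prof$window_start[w]:prof$window_end[w]
    vals <- utils::combn(4, 2, FUN = function(p)
      mean(mats[p[1], idx] != mats[p[2], idx]))
    expect_equal(prof$pi[w], mean(vals), tolerance = 1e-12)
  }

  # pairwise gap exclusion
  g1 <- "AAAA-AAAAA"
  g2 <- "AAAT-TAAAA"
  expect_equal(sliding_pi(c(g1, g2), window = 10)$pi, 2 / 9)

  expect_warning(p1 <- sliding_pi(c("ACGT", "ACGA"), window = 500),
                 "window longer")
  expect_equal(p1$pi, 0.25)
  expect_error(sliding_pi("ACGT"), "at least 2")
  expect_error(sliding_pi(c("ACGT", "ACG")), "equal length")
})

test_that("fixed differences use pathway-averaged codon comparison", {
  code <- genetic_code()
  ann <- gene_features("g", "PCG", 1L, 12L, "+", L_mt = 12L, circular = FALSE)
  expect_equal(fixed_differences("ATGAAAGGATAA", "ATGAAAGGATAA", ann, code)$Dn, 0)

  # single synonymous codon difference: GGA -> GGC
  fd <- fixed_differences("ATGAAAGGATAA", "ATGAAAGGCTAA", ann, code)
  expect_equal(fd$Ds, 1)
  expect_equal(fd$Dn, 0)

  # two-position difference GGA -> AGC: average over both substitution orders
  # order 1: GGA->AGA (G->S, nonsyn), AGA->AGC (S->S, syn)
  # order 2: GGA->GGC (syn), GGC->AGC (G->S, nonsyn)
  fd2 <- fixed_differences("ATGAAAGGATAA", "ATGAAAAGCTAA", ann, code)
  expect_equal(fd2$Dn, 1)
  expect_equal(fd2$Ds, 1)

  # minus-strand genes are compared on the coding strand
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(x)))
  ann_m <- gene_features("g", "PCG", 1L, 12L, "-", L_mt = 12L, circular = FALSE)
  fdm <- fixed_differences(rc("ATGAAAGGATAA"), rc("ATGAAAGGCTAA"), ann_m, code)
  expect_equal(fdm$Ds, 1)
  expect_equal(fdm$Dn, 0)

  expect_error(fixed_differences("ACGT", "ACG", ann, code), "nchar")
})

test_that("selection against nonsynonymous change leaves a position-3 excess", {
  cfg <- small_cfg(seed = 33, selection_s = 0.9, error = 0,
                   founder_het_sites = 200L)
  fx <- simulate_genome(cfg)
  st <- simulate_matriline(cfg, fx$genome, fx$annotation)
  rc <- simulate_readcounts(st, fx$genome, cfg)
  sites <- call_het_sites(rc$counts)
  # restrict to non-founder carriers: the founder never felt selection
  founder <- st$individuals$id[is.na(st$individuals$mother)]
  sites <- sites[sites$individual != founder, ]
  tab <- tabulate_positions(sites, fx$genome, fx$annotation)
  pooled <- tab$pooled
  # positions 1+2 (mostly nonsynonymous) depleted relative to position 3
  expect_lt(chisq_positions(pooled["n2"], pooled["n3"])$p, 0.01)
  expect_lt(pooled["n2"], pooled["n3"])
  # and the nonsynonymous fraction at position 2 is 1 wherever sites exist
  if (pooled["n2"] > 0)
    expect_equal(unname(pooled["nonsyn2"] / pooled["n2"]), 1)
})

test_that("with no selection the codon positions are uniform", {
  pooled <- c(n1 = 0, n2 = 0, n3 = 0)
  for (s in 1:3) {
    cfg <- small_cfg(seed = 200 + s, selection_s = 0)
    fx <- simulate_genome(cfg)
    st <- simulate_matriline(cfg, fx$genome, fx$annotation)
    rc <- simulate_readcounts(st, fx$genome, cfg)
    tab <- tabulate_positions(call_het_sites(rc$counts), fx$genome,
                              fx$annotation)
    pooled <- pooled + tab$pooled[c("n1", "n2", "n3")]
  }
  gof <- suppressWarnings(stats::chisq.test(pooled))
  expect_gt(gof$p.value, 0.001)
})

test_that("the per-gene selection report assembles all columns", {
  cfg <- small_cfg(seed = 37)
  fx <- simulate_genome(cfg)
  st <- simulate_matriline(cfg, fx$genome, fx$annotation)
  rc <- simulate_readcounts(st, fx$genome, cfg)
  sites <- call_het_sites(rc$counts)
  outg_cfg <- small_cfg(seed = 38)
  outg <- simulate_genome(outg_cfg)$genome$sequence  # same layout, divergent
  rep_ <- selection_report(sites, fx$genome, fx$annotation, outgroup = outg)
  expect_setequal(rep_$gene, c("g1", "g2", "g3"))
  expect_true(all(c("chi2_13", "p_23", "Pn", "Ps", "Dn", "Ds", "fisher_p",
                    "NI", "alpha", "p_13_bonferroni") %in% names(rep_)))
  expect_true(all(rep_$p_13_bonferroni >= rep_$p_13, na.rm = TRUE))
  expect_true(all(rep_$Dn + rep_$Ds <= rep_$n_codons_compared * 3))
})
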