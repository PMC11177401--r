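test_that("the simulated genome realises its layout deterministically", {
  cfg <- small_cfg(seed = 9)
  a <- simulate_genome(cfg)
  b <- simulate_genome(cfg)
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_identical(a$annotation, b$annotation)
  expect_equal(nrow(a$annotation), nrow(cfg$gene_layout))
  # PCGs start with an eligible start codon and contain no internal stop
  code <- genetic_code()
  for (k in which(a$annotation$kind == "PCG")) {
    f <- a$annotation[k, ]
    pos <- if (f$strand == "+") f$start:f$end else f$end:f$start
    ch <- strsplit(a$genome$sequence, "")[[1]][pos]
    if (f$strand == "-") ch <- c(A = "T", C = "G", G = "C", T = "A")[ch]
    codons <- apply(matrix(ch, nrow = 3), 2, paste0, collapse = "")
    expect_true(codons[1] %in% code$start_codons)
    expect_false(any(code$codons[codons[-length(codons)]] == "*"))
    expect_equal(unname(code$codons[codons[length(codons)]]), "*")
  }
})

test_that("infeasible layouts are rejected", {
  bad <- small_layout(); bad$length[1] <- 301L
  expect_error(simulate_genome(sim_config(L_mt = 2000L, gene_layout = bad)),
               "divisible by 3")
  big <- small_layout(); big$length[1] <- 5001L
  expect_error(simulate_genome(sim_config(L_mt = 2000L, gene_layout = big)),
               "does not fit")
  expect_error(sim_config(mu = 1.5), "probabilities")
  expect_error(sim_config(bottleneck = 0), "bottleneck")
})

test_that("matriline transmission follows the bottleneck model", {
  # enormous bottleneck, no mutation, no selection: offspring equal mother
  cfg <- small_cfg(seed = 4, bottleneck = 1000000L, mu = 0,
                   selection_s = 0)
  fx <- simulate_genome(cfg)
  st <- simulate_matriline(cfg, fx$genome, fx$annotation)
  ped <- st$individuals
  kid <- ped$id[ped$generation == 2][1]
  fm <- st$freqs[ped$mother[ped$id == kid], ]
  fk <- st$freqs[kid, ]
  expect_true(all(fk[fm == 0] == 0))
  sdv <- sqrt(fm * (1 - fm) / cfg$bottleneck)
  expect_true(all(abs(fk - fm) <= 5 * sdv + 1e-12))

  # absorbing selection: every nonsynonymous alternative is 0 in non-founders
  cfg2 <- small_cfg(seed = 4, selection_s = 1)
  fx2 <- simulate_genome(cfg2)
  st2 <- simulate_matriline(cfg2, fx2$genome, fx2$annotation)
  nonsyn <- !is.na(st2$effect$effect) & st2$effect$effect == "nonsynonymous"
  nonfounder <- !is.na(st2$individuals$mother)
  expect_true(all(st2$freqs[nonfounder, nonsyn] == 0))
  expect_true(any(nonsyn))

  # all frequencies are proper and the pedigree is generation-consistent
  expect_true(all(st2$freqs >= 0 & st2$freqs <= 1))
  ped2 <- st2$individuals
  for (i in which(!is.na(ped2$mother)))
    expect_equal(ped2$generation[match(ped2$mother[i], ped2$id)] + 1L,
                 ped2$generation[i])
})

test_that("without de novo mutation every offspring variant is maternal", {
  cfg <- small_cfg(seed = 21, mu = 0)
  fx <- simulate_genome(cfg)
  st <- simulate_matriline(cfg, fx$genome, fx$annotation)
  ped <- st$individuals
  for (i in which(!is.na(ped$mother))) {
    fm <- st$freqs[ped$mother[i], ]
    expect_true(all(st$freqs[i, fm == 0] == 0), info = ped$id[i])
  }
})

test_that("de novo intensity decouples from copy ratio at kappa = 0", {
  rs <- numeric(0); dn <- integer(0)
  for (s in 1:10) {
    cfg <- small_cfg(seed = 100 + s, kappa = 0)
    fx <- simulate_genome(cfg)
    st <- simulate_matriline(cfg, fx$genome, fx$annotation)
    keep <- !is.na(st$individuals$mother)
    rs <- c(rs, st$individuals$copy_ratio[keep])
    dn <- c(dn, st$individuals$n_denovo[keep])
  }
  expect_gt(stats::cor.test(rs, dn)$p.value, 0.01)
})

test_that("per-individual sub-streams are stable under pedigree growth", {
  cfg_a <- small_cfg(seed = 31, offspring_per_cross = 10L)
  cfg_b <- small_cfg(seed = 31, offspring_per_cross = 14L)
  fx <- simulate_genome(cfg_a)
  st_a <- simulate_matriline(cfg_a, fx$genome, fx$annotation)
  st_b <- simulate_matriline(cfg_b, fx$genome, fx$annotation)
  shared <- intersect(rownames(st_a$freqs), rownames(st_b$freqs))
  expect_gt(length(shared), 10)
  expect_identical(st_a$freqs[shared, ], st_b$freqs[shared, ])
})

test_that("read-count emulation conserves depth and inverts copy ratios", {
  cfg <- small_cfg(seed = 6)
  fx <- simulate_genome(cfg)
  st <- simulate_matriline(cfg, fx$genome, fx$annotation)
  rc <- simulate_readcounts(st, fx$genome, cfg)
  cm <- rc$counts[, c("count_A", "count_C", "count_G", "count_T")]
  expect_true(all(rowSums(cm) == rc$counts$depth))
  expect_true(all(rc$counts$depth >= 0))
  # copy_ratio . read-total construction recovers the truth to 6 decimals
  rt <- copy_ratio_table(rc$totals)
  truth <- st$individuals$copy_ratio[match(rt$individual, st$individuals$id)]
  expect_true(all(abs(rt$ratio - truth) < 1e-6))
  # determinism of the full sequencing emulation
  rc2 <- simulate_readcounts(st, fx$genome, cfg)
  expect_identical(rc, rc2)
})

test_that("error-free sequencing of an invariant genome yields no calls", {
  cfg <- small_cfg(seed = 2, error = 0, founder_het_sites = 1L)
  fx <- simulate_genome(cfg)
  st <- simulate_matriline(cfg, fx$genome, fx$annotation)
  st$freqs[] <- 0
  rc <- simulate_readcounts(st, fx$genome, cfg)
  cm <- as.matrix(rc$counts[, c("count_A", "count_C", "count_G", "count_T")])
  ref_n <- cm[cbind(seq_len(nrow(cm)), match(rc$counts$ref, c("A", "C", "G", "T")))]
  expect_true(all(ref_n == rc$counts$depth))
  expect_equal(nrow(call_het_sites(rc$counts)), 0L)
})

test_that("a 50% heteroplasmy at high depth is recovered near 50%", {
  cfg <- small_cfg(seed = 13, error = 0, mean_depth = 10000)
  fx <- simulate_genome(cfg)
  st <- simulate_matriline(cfg, fx$genome, fx$annotation)
  st$freqs[] <- 0
  st$freqs[, 1000] <- 0.5
  rc <- simulate_readcounts(st, fx$genome, cfg,
                            individuals = st$individuals$id[1])
  row <- rc$counts[rc$counts$pos == 1000, ]
  altn <- row[[paste0("count_", st$alt[1000])]]
  expect_gt(altn / row$depth, 0.48)
  expect_lt(altn / row$depth, 0.52)
})

test_that("depth profiles show the repeat plateau and nothing else", {
  set.seed(1)
  flat <- simulate_depth_profile(1, 100, c(401L, 700L), 2000L)
  wd <- windowed_depth(flat, 100L)
  se <- sqrt(100 / 100)
  expect_true(all(abs(wd$depth - 100) < 4 * se))

  prof <- simulate_depth_profile(3, 100, c(401L, 700L), 2000L)
  est <- repeat_copy_number(prof, c(401L, 700L), flank = 400L)
  expect_gt(est$copies, 2.7)
  expect_lt(est$copies, 3.3)

  expect_error(simulate_depth_profile(3, 100, c(700L, 401L), 2000L),
               "interval")
  expect_error(simulate_depth_profile(3, 100, c(1, 3000L), 2000L), "bounds")
})

test_that("simulation outputs round-trip through their file formats", {
  cfg <- small_cfg(seed = 17)
  fx <- simulate_genome(cfg)
  st <- simulate_matriline(cfg, fx$genome, fx$annotation)
  dir <- tempfile("simio_")
  dir.create(dir)

  write_pedigree(st$individuals, file.path(dir, "ped.tsv"))
  ped <- read_pedigree(file.path(dir, "ped.tsv"))
  expect_equal(ped$id, st$individuals$id)
  expect_equal(ped$mother, st$individuals$mother)
  expect_true(is.na(ped$mother[1]))

  rc <- simulate_readcounts(st, fx$genome, cfg,
                            individuals = st$individuals$id[1:2])
  paths <- write_readcount_tables(rc$counts, file.path(dir, "counts"))
  back <- read_readcount_tsv(paths[1])
  orig <- rc$counts[rc$counts$individual == back$individual[1], ]
  rownames(orig) <- NULL
  expect_equal(back$depth, orig$depth)
  expect_equal(back$count_G, orig$count_G)

  write_sim_config(cfg, file.path(dir, "cfg.yaml"))
  cfg2 <- read_sim_config(file.path(dir, "cfg.yaml"))
  for (nm in setdiff(names(cfg), "gene_layout"))
    expect_equal(cfg2[[nm]], cfg[[nm]], info = nm)

  write_sim_vcf(st, fx$genome, file.path(dir, "sim.vcf"), counts = rc$counts)
  v <- read_vcf_records(file.path(dir, "sim.vcf"))
  expect_equal(nrow(v$sites), sum(colSums(st$freqs > 0) > 0))
  expect_equal(v$samples, st$individuals$id)
  # QUAL is the stated monotone map of the maximum individual frequency
  maxf <- apply(st$freqs[, colSums(st$freqs > 0) > 0, drop = FALSE], 2, max)
  expect_equal(v$sites$qual, round(1000 * unname(maxf), 1))
})
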