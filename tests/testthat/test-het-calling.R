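test_that("the frequency threshold separates calls exactly at the boundary", {
  rows <- rbind(count_row(1, "A", 100, A = 99, G = 1),    # 1%: below
                count_row(2, "A", 100, A = 98, G = 2),    # 2%: at threshold
                count_row(3, "A", 100, A = 95, G = 5),    # 5%
                count_row(4, "A", 9, A = 7, G = 2),       # under min depth
                count_row(5, "A", 0))                     # depth 0, skipped
  expect_message(s2 <- call_het_sites(rows, min_freq = 0.02), "depth-0")
  expect_equal(s2$position, c(2L, 3L))
  expect_equal(s2$alt_freq, c(0.02, 0.05))
  s5 <- suppressMessages(call_het_sites(rows, min_freq = 0.05))
  expect_equal(s5$position, 3L)
  expect_error(call_het_sites(rows, min_freq = 0), "min_freq")
})

test_that("multiallelic rows collapse to the top alternative, ties by base order", {
  rows <- rbind(count_row(1, "A", 100, A = 90, C = 4, G = 6),
                count_row(2, "A", 100, A = 92, C = 4, T = 4),
                count_row(3, "G", 100, G = 90, A = 3, T = 7))
  s <- call_het_sites(rows)
  expect_equal(s$alt, c("G", "C", "T"))
  expect_equal(s$alt_freq, c(0.06, 0.04, 0.07))
})

test_that("frequency uses the stated row depth, not the count sum", {
  row <- count_row(1, "A", 200, A = 90, G = 4)
  s <- call_het_sites(row)
  expect_equal(s$alt_freq, 4 / 200)
})

test_that("raising the frequency threshold never adds calls", {
  set.seed(8)
  n <- 400
  depth <- rpois(n, 80)
  alt_n <- rbinom(n, depth, runif(n, 0, 0.1))
  rows <- count_row(seq_len(n), "A", depth, A = depth - alt_n, G = alt_n)
  thresholds <- c(0.01, 0.02, 0.03, 0.05, 0.1, 0.2)
  n_called <- vapply(thresholds, function(t)
    nrow(suppressMessages(call_het_sites(rows, min_freq = t))), 0L)
  expect_true(all(diff(n_called) <= 0))
})

test_that("per-individual summaries report both frequency conventions", {
  # the reference-scale example: 1888 variable sites in a 14202-base genome
  sites <- data.frame(individual = "C854", position = seq_len(1888),
                      ref = "A", alt = "G", alt_freq = 0.011, depth = 100)
  sm <- summarize_individual(sites, L_mt = 14202)
  expect_equal(sm$n_variable, 1888L)
  expect_equal(sm$pct_sites_variable, 100 * 1888 / 14202)
  expect_equal(round(sm$pct_sites_variable), 13)

  # 2 sites at 10% and 30% over 10 assayed positions
  s2 <- data.frame(individual = "x", position = 1:2, ref = "A", alt = "G",
                   alt_freq = c(0.1, 0.3), depth = 100)
  sm2 <- summarize_individual(s2, L_mt = 10, n_assayed = 10)
  expect_equal(sm2$mean_freq_excl_zero, 20)
  expect_equal(sm2$mean_freq_incl_zero, 4)
  expect_true(sm2$mean_freq_incl_zero <= sm2$mean_freq_excl_zero)

  # empty: percentage 0 and an undefined (not zero) excluding-zeros mean
  sm0 <- summarize_individual(s2[0, ], L_mt = 10)
  expect_equal(sm0$n_variable, 0L)
  expect_equal(sm0$pct_sites_variable, 0)
  expect_true(is.na(sm0$mean_freq_excl_zero))
  expect_equal(sm0$mean_freq_incl_zero, 0)
})

test_that("calling on exact simulator truth recovers the variable sites", {
  cfg <- small_cfg(seed = 19, error = 0, mean_depth = 300,
                   depth_model = "fixed")
  fx <- simulate_genome(cfg)
  st <- simulate_matriline(cfg, fx$genome, fx$annotation)
  # plant well-separated frequencies so sampling noise cannot cross the
  # threshold in 300 fixed-depth reads
  st$freqs[] <- 0
  set.seed(40)
  for (i in seq_len(nrow(st$freqs)))
    st$freqs[i, sample.int(cfg$L_mt, 30)] <- runif(30, 0.3, 0.6)
  rc <- simulate_readcounts(st, fx$genome, cfg)
  sites <- call_het_sites(rc$counts, min_freq = 0.02)
  sm <- summarize_individuals(sites, cfg$L_mt,
                              individuals = st$individuals$id)
  expect_equal(sm$n_variable, rowSums(st$freqs > 0)[sm$individual],
               ignore_attr = TRUE)
})

test_that("the native bam-readcount line format is parsed", {
  lines <- c(
    "mt\t1\tA\t100\t=:0:...\tA:97:x\tC:0:x\tG:2:x\tT:1:x\tN:0:x",
    "mt\t2\tC\t50\t=:0:...\tA:0:x\tC:50:x\tG:0:x\tT:0:x\tN:0:x")
  p <- tempfile(fileext = ".brc")
  writeLines(lines, p)
  d <- read_bam_readcount(p, individual = "s1")
  expect_equal(d$pos, 1:2)
  expect_equal(d$count_G, c(2L, 0L))
  expect_equal(d$depth, c(100L, 50L))
  s <- call_het_sites(d)
  expect_equal(s$position, 1L)
  expect_equal(s$alt, "G")
})

test_that("concordance pools keys with zero imputation and matches Pearson", {
  a <- c("1" = 0.1, "2" = 0.2, "3" = 0.3, "4" = 0.4)
  expect_equal(concordance(a, a)$r_squared, 1)
  expect_equal(concordance(a, -a)$r, -1)
  expect_equal(concordance(a, -a)$r_squared, 1)

  # hand-computed Pearson on a 10-point table, via the covariance formula
  set.seed(5)
  b1 <- stats::setNames(runif(10), 1:10)
  b2 <- stats::setNames(runif(10), 1:10)
  r_hand <- sum((b1 - mean(b1)) * (b2 - mean(b2))) /
    sqrt(sum((b1 - mean(b1))^2) * sum((b2 - mean(b2))^2))
  expect_equal(concordance(b1, b2)$r, r_hand, tolerance = 1e-12)

  # a key absent from one batch enters as frequency 0, not dropped
  c1 <- c("1" = 0.5, "2" = 0.5, "3" = 0.5)
  c2 <- c("1" = 0.5, "2" = 0.5, "4" = 0.5)
  expect_equal(concordance(c1, c2)$n, 4L)

  expect_true(is.na(concordance(c("1" = 1, "2" = 1, "3" = 1), c1)$r))
  expect_true(is.na(concordance(a[1:2], a[1:2])$r))
})

test_that("batch concordance is high on resequenced simulated individuals", {
  cfg <- small_cfg(seed = 23)
  fx <- simulate_genome(cfg)
  st <- simulate_matriline(cfg, fx$genome, fx$annotation)
  cfg_b <- cfg; cfg_b$seed <- cfg$seed + 500L   # second run of the sequencer
  rc1 <- simulate_readcounts(st, fx$genome, cfg)
  rc2 <- simulate_readcounts(st, fx$genome, cfg_b)
  s1 <- summarize_individuals(call_het_sites(rc1$counts), cfg$L_mt,
                              individuals = st$individuals$id)
  s2 <- summarize_individuals(call_het_sites(rc2$counts), cfg$L_mt,
                              individuals = st$individuals$id)
  cc <- concordance(stats::setNames(s1$mean_freq_incl_zero, s1$individual),
                    stats::setNames(s2$mean_freq_incl_zero, s2$individual))
  expect_gt(cc$r, 0.7)
  expect_lt(cc$p, 1e-6)
})

test_that("VCF filtering applies each rule and their intersection", {
  cfg <- small_cfg(seed = 29)
  fx <- simulate_genome(cfg)
  st <- simulate_matriline(cfg, fx$genome, fx$annotation)
  path <- tempfile(fileext = ".vcf")
  write_sim_vcf(st, fx$genome, path)
  v <- read_vcf_records(path)

  # boundary: quality exactly at the threshold survives, just below fails
  qs <- v$sites$qual
  keep30 <- filter_vcf(v, min_qual = 30)
  expect_true(all(keep30$sites$qual >= 30))
  expect_equal(nrow(keep30$sites), sum(qs >= 30))

  # monotonicity: the stricter quality filter never retains more sites
  keep90 <- filter_vcf(v, min_qual = 90)
  expect_lte(nrow(keep90$sites), nrow(keep30$sites))

  # hand-built 20-site set, 6 sites each violating exactly one rule,
  # checked against an independent per-rule oracle intersection
  n_samp <- length(v$samples)
  v2 <- v
  v2$sites <- v$sites[rep(1, 20), ]
  v2$sites$pos <- 1:20
  v2$sites$qual <- 50
  v2$sites$n_alt <- 1L
  v2$dp <- matrix(100, nrow = 20, ncol = n_samp)
  v2$missing <- matrix(FALSE, nrow = 20, ncol = n_samp)
  v2$sites$n_alt[1:2] <- 2L                         # not biallelic
  v2$sites$qual[3:4] <- 29                          # below quality
  n_bad <- ceiling(0.10 * n_samp)
  v2$missing[5, seq_len(n_bad)] <- TRUE             # >= 10% missing
  v2$dp[6, seq_len(n_bad)] <- 5                     # depth-masked to missing
  out <- filter_vcf(v2, min_qual = 30)
  expect_equal(nrow(out$sites), 14L)
  # oracle: each rule applied separately, then intersected
  r_bi <- v2$sites$n_alt == 1L
  r_q <- v2$sites$qual >= 30
  eff_miss <- v2$missing | v2$dp < 10 | v2$dp > 500
  r_miss <- rowSums(eff_miss) / n_samp < 0.10
  expect_equal(out$sites$pos, v2$sites$pos[r_bi & r_q & r_miss])
  expect_equal(unname(attr(out, "log")["n_retained"]), 14)

  # filtered records survive a write/read round trip
  p2 <- tempfile(fileext = ".vcf")
  write_vcf_records(out, p2)
  back <- read_vcf_records(p2)
  expect_equal(back$sites$pos, out$sites$pos)
})
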