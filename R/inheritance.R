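#' Sharing of heteroplasmic sites among siblings
#'
#' For each position variable in at least one individual, computes the
#' fraction of individuals variable there; returns the mean and population
#' standard deviation of these fractions (in percent).  High mean sharing
#' among siblings is the signature of inherited (rather than somatic or
#' artefactual) heteroplasmy.
#'
#' @param het_matrix Logical matrix, individuals x positions, TRUE where
#'   the individual is heteroplasmic at the position.
#' @return A list: `n_siblings`, `fractions` (per variable position),
#'   `mean_fraction` and `sd_fraction` (percent); NA markers with no
#'   variable positions.
#' @export
shared_site_stats <- function(het_matrix) {
  stopifnot(is.matrix(het_matrix), nrow(het_matrix) >= 2L)
  het_matrix <- het_matrix > 0
  variable <- colSums(het_matrix) > 0
  if (!any(variable))
    return(list(n_siblings = nrow(het_matrix), fractions = numeric(0),
                mean_fraction = NA_real_, sd_fraction = NA_real_))
  frac <- colMeans(het_matrix[, variable, drop = FALSE])
  list(n_siblings = nrow(het_matrix),
       fractions = 100 * frac,
       mean_fraction = 100 * mean(frac),
       sd_fraction = 100 * sqrt(mean((frac - mean(frac))^2)))
}

#' Parent-offspring heteroplasmy correlation
#'
#' Pearson correlation between the per-site alternative-allele frequencies
#' of a candidate parent and an offspring.  Under the default `union`
#' policy the correlation runs over sites heteroplasmic in either member,
#' with absent sites imputed as frequency 0 — conservative against
#' spuriously perfect correlations on tiny intersections; `intersection`
#' restricts to sites called in both.
#'
#' @param parent_freqs,offspring_freqs Named numeric vectors of
#'   alternative-allele frequencies, names are positions.
#' @param site_policy `"union"` (default) or `"intersection"`.
#' @return A list: `r`, `r_squared`, `p`, `n`; NA with `reason` when fewer
#'   than 3 sites or zero variance.
#' @export
parent_offspring_correlation <- function(parent_freqs, offspring_freqs,
                                         site_policy = c("union", "intersection")) {
  site_policy <- match.arg(site_policy)
  keys <- if (site_policy == "union")
    union(names(parent_freqs), names(offspring_freqs)) else
    intersect(names(parent_freqs), names(offspring_freqs))
  undefined <- function(reason, n)
    list(r = NA_real_, r_squared = NA_real_, p = NA_real_, n = n,
         reason = reason)
  if (length(keys) < 3L) return(undefined("fewer than 3 sites", length(keys)))
  a <- ifelse(is.na(parent_freqs[keys]), 0, parent_freqs[keys])
  b <- ifelse(is.na(offspring_freqs[keys]), 0, offspring_freqs[keys])
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    return(undefined("zero variance", length(keys)))
  ct <- stats::cor.test(a, b, method = "pearson")
  list(r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
       p = ct$p.value, n = length(keys))
}

#' Assign the maternal parent of an offspring
#'
#' Given correlation reports against the two candidate parents, a parent
#' qualifies when its correlation is positive and significant (two-sided
#' `p < alpha_sig`).  Under the strict criterion the offspring is assigned
#' only when exactly one parent qualifies; under the loose criterion the
#' qualifying parent with the lower p-value wins, ties broken by higher
#' R-squared.  Undefined correlations never qualify.
#'
#' @param stats_p1,stats_p2 Reports from [parent_offspring_correlation()].
#' @param alpha_sig Significance level.
#' @param parents Labels of the two candidate parents.
#' @param offspring Offspring label carried through.
#' @return One-row data frame: offspring, r1, R2_1, p1, n1, r2, R2_2, p2,
#'   n2, strict_mother, loose_mother (NA when unassigned).
#' @export
assign_mother <- function(stats_p1, stats_p2, alpha_sig = 0.05,
                          parents = c("P1", "P2"),
                          offspring = NA_character_) {
  q <- function(s) !is.na(s$r) && s$r > 0 && !is.na(s$p) && s$p < alpha_sig
  q1 <- q(stats_p1); q2 <- q(stats_p2)
  strict <- if (xor(q1, q2)) parents[c(q1, q2)] else NA_character_
  loose <- if (q1 && q2) {
    if (stats_p1$p < stats_p2$p) parents[1]
    else if (stats_p2$p < stats_p1$p) parents[2]
    else if (stats_p1$r_squared >= stats_p2$r_squared) parents[1] else parents[2]
  } else if (q1 || q2) parents[c(q1, q2)] else NA_character_
  data.frame(offspring = offspring,
             r1 = stats_p1$r, R2_1 = stats_p1$r_squared, p1 = stats_p1$p,
             n1 = stats_p1$n,
             r2 = stats_p2$r, R2_2 = stats_p2$r_squared, p2 = stats_p2$p,
             n2 = stats_p2$n,
             strict_mother = strict, loose_mother = loose,
             stringsAsFactors = FALSE)
}

#' Assign mothers for a set of offspring from called sites
#'
#' Convenience driver for the two-candidate maternity procedure: builds
#' per-individual frequency vectors from a called-site table, correlates
#' each offspring against both candidate parents and applies
#' [assign_mother()].  A Benjamini-Hochberg adjusted column for the
#' winning parent's p-value is appended alongside the unadjusted decision
#' (the decision itself is deliberately per-offspring and uncorrected).
#'
#' @param sites Called sites ([call_het_sites()]) covering parents and
#'   offspring.
#' @param parents Character vector of the two candidate parent ids.
#' @param offspring Character vector of offspring ids.
#' @param alpha_sig Significance level.
#' @param site_policy Site policy for the correlations.
#' @return A data frame with one row per offspring, as [assign_mother()],
#'   plus `p_min_bh`.
#' @export
assign_mothers <- function(sites, parents, offspring, alpha_sig = 0.05,
                           site_policy = "union") {
  stopifnot(length(parents) == 2L)
  fv <- function(id) {
    d <- sites[sites$individual == id, ]
    stats::setNames(d$alt_freq, d$position)
  }
  f1 <- fv(parents[1]); f2 <- fv(parents[2])
  res <- do.call(rbind, lapply(offspring, function(o) {
    fo <- fv(o)
    assign_mother(parent_offspring_correlation(f1, fo, site_policy),
                  parent_offspring_correlation(f2, fo, site_policy),
                  alpha_sig = alpha_sig, parents = parents, offspring = o)
  }))
  res$p_min_bh <- stats::p.adjust(pmin(res$p1, res$p2, na.rm = TRUE), "BH")
  res
}

#' Compare offspring heteroplasmy between assigned-mother groups
#'
#' Two-sample pooled-variance Student t-test (two-sided) on a
#' per-offspring heteroplasmy measure split by assigned mother.
#'
#' @param x,y Numeric vectors for the two groups (each of size >= 2).
#' @return A list: group means, SDs and sizes, `t`, `df`, `p`.
#' @export
group_comparison <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stopf("each group needs >= 2 values")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(mean_x = mean(x), mean_y = mean(y),
       sd_x = stats::sd(x), sd_y = stats::sd(y),
       n_x = length(x), n_y = length(y),
       t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Pooled t-test from group summary statistics
#'
#' Closed-form pooled-variance two-sample t-test from printed group
#' summaries (n, mean, SD per group), for reproducing reported comparisons
#' without the raw values.
#'
#' @param n1,mean1,sd1 First group summary.
#' @param n2,mean2,sd2 Second group summary.
#' @return A list: `t`, `df`, `p` (two-sided).
#' @export
pooled_t_summary <- function(n1, mean1, sd1, n2, mean2, sd2) {
  stopifnot(n1 >= 2, n2 >= 2)
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (mean1 - mean2) / se
  df <- n1 + n2 - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Pedigree mutation-rate estimate
#'
#' The simple direct estimate: mutations observed to reach majority in the
#' pedigree, divided by (individuals screened x genome length), in
#' mutations per base per generation.
#'
#' @param n_fixed Count of de novo mutations treated as fixed.
#' @param n_individuals Individuals screened.
#' @param L_mt Genome length in bases.
#' @return A list: `rate` (full precision), `rate_2sf` (two significant
#'   figures), and the inputs.
#' @export
pedigree_mutation_rate <- function(n_fixed, n_individuals, L_mt) {
  if (n_individuals <= 0 || L_mt <= 0) stopf("denominator must be positive")
  if (n_fixed < 0) stopf("n_fixed must be >= 0")
  rate <- n_fixed / (n_individuals * L_mt)
  list(rate = rate, rate_2sf = signif(rate, 2), n_fixed = n_fixed,
       n_individuals = n_individuals, L_mt = L_mt)
}

#' Count majority (>50%) alternative alleles
#'
#' Counts distinct (individual, position) entries whose alternative-allele
#' frequency exceeds the threshold; these candidate-fixation events feed
#' the numerator of [pedigree_mutation_rate()].
#'
#' @param sites Called sites over the matriline.
#' @param threshold Frequency threshold (strict `>`), default 0.5.
#' @return A list: `n` and `sites` (the qualifying rows).
#' @export
count_majority_variants <- function(sites, threshold = 0.5) {
  keep <- sites$alt_freq > threshold
  hits <- sites[keep, , drop = FALSE]
  hits <- hits[!duplicated(paste(hits$individual, hits$position)), , drop = FALSE]
  list(n = nrow(hits), sites = hits)
}
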