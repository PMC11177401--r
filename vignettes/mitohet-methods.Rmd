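---
title: "Heteroplasmy, copy number and inheritance in a snail matriline: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heteroplasmy, copy number and inheritance in a snail matriline: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitohet)
```

## The scientific setting

Land snails carry unusually variable mitochondrial genomes. Deep short-read
sequencing of a multigenerational laboratory matriline makes three linked
phenomena measurable within single individuals:

* **SNP heteroplasmy** — at many positions a minority base segregates within
  an individual's mtDNA pool, detectable as a stable fraction of the reads.
* **Copy-number variation** — the number of mtDNA genome copies per nuclear
  genome copy varies widely (roughly 5–80 in the matriline this package
  models), and individuals with fewer mtDNA copies show *more* heteroplasmic
  sites.
* **Length heteroplasmy** — a tandemly repeated tRNA region is present in a
  variable number of copies per genome, visible as a plateau of elevated
  read depth over the collapsed repeat in a single-copy assembly.

`mitohet` implements the analysis chain for these observations — calling
heteroplasmic sites from per-site allele counts, copy-ratio estimation from
read fractions, repeat quantification from windowed depth, selection tests on
the called sites, maternity inference from parent–offspring frequency
correlations, and a direct pedigree mutation-rate estimate — together with a
forward simulator of the whole system, so that every stage can be validated
on data with known ground truth and no external downloads.

## Heteroplasmy calling

The caller consumes per-individual, per-site base counts (the package's
tab-delimited dialect, or native `bam-readcount` lines). A site is
heteroplasmic when the highest-count non-reference base reaches a frequency
threshold of the row's stated depth:

* `min_freq = 0.02` (2%) by default — the conventional filter that separates
  real low-frequency variation from sequencing error at ~100× depth; 5% is
  offered as the stricter check (`strict_freq` in the pipeline
  configuration).
* `min_depth = 10` reads. The count-table path has no canonical depth floor
  in the literature we follow; we adopt the same floor as the VCF filter and
  expose it as an argument.

Multiallelic rows collapse to the top alternative (ties broken A<C<G<T),
because the downstream analyses treat sites as biallelic. Frequencies use
the stated depth, not the sum of the four base counts, so dropped N/indel
reads still count toward coverage. Per-individual summaries report the mean
alternative-allele frequency both **excluding zeros** (over called sites)
and **including zeros** (over all assayed positions); published per-site
percentages are ambiguous between the two conventions, so both are always
emitted. With no called sites the excluding-zeros mean is `NA`, never 0.

VCF-level filtering keeps biallelic sites with quality ≥ 30 (or ≥ 90 for
the conservative variant), treats samples with depth outside 10–500 as
missing at that site, and drops sites missing in ≥ 10% of samples (the
bound is strict). No minor-allele-frequency floor is applied: de novo
variants present in one individual are the object of study.

## Copy ratio

With reads sampled uniformly from a cell's DNA, the expected mitochondrial
read fraction is $f_{mt} = R\,L_{mt}/G_{nuc}$ for $R$ mtDNA copies per
haploid nuclear genome equivalent, so

$$R = f_{mt}\, \frac{G_{nuc}}{L_{mt}}.$$

Two deliberate simplifications: the ratio is per *haploid* genome
equivalent (no ×2 ploidy correction — the published range of 5–80 is
consistent with the haploid-equivalent formula), and no $(1-f_{mt})$
denominator correction is applied since $f_{mt} \le 10^{-3}$ throughout the
data this models.

Repeat copy number is the mean depth over the repeat divided by the mean
depth of 1 kb of flanking sequence on each side, pooled. Flanks wrap across
the origin on circular genomes and are truncated (never overlapped) on
short genomes. Windowed depth uses non-overlapping 25 bp windows, the usual
mosdepth setting at mitogenome scale.

The copy-ratio–heteroplasmy association is an ordinary least-squares
regression of a per-individual heteroplasmy measure (site count by default,
mean frequency as an alternative) on the copy ratio, with a two-sided slope
test.

## Selection analyses

Heteroplasmic sites are pooled across individuals as unique (position,
alternative-base) pairs — a site segregating in 40 individuals counts once.
Published pooled counts are tallied this way by implication rather than
statement, so a `per_individual` flag offers the carrier-weighted
alternative. Each pair is classified against the annotation: gene, codon
position relative to the polished reading frame (minus-strand genes on the
reverse complement), and synonymous/non-synonymous status under NCBI
translation table 5. A useful theorem of that code — verified exhaustively
in the test suite — is that *every* codon-position-2 substitution is
non-synonymous, which makes the position-2 versus position-3 contrast a
clean selection probe.

The codon-position test is a Pearson chi-squared (df = 1, no continuity
correction) of observed counts at two positions against equal expectation;
totals under 5 are flagged as asymptotically unreliable. The
McDonald–Kreitman test is a two-sided Fisher exact test on
[[Pn, Ps], [Dn, Ds]], with neutrality index $NI = (P_n/P_s)/(D_n/D_s)$ and
$\alpha = 1 - NI$; $NI$ and $\alpha$ are undefined (never silently zero)
when $P_s = 0$ or $D_n = 0$. Fisher's exact test was chosen over a G-test
to match the convention of DnaSP, whose sliding-window nucleotide diversity
(Pi, 500-site window, 100-site step, last partial window included) is also
mirrored. Pi is computed over a supplied set of aligned sequences (e.g.
per-individual consensus); heteroplasmy-weighted diversity is out of scope.
Fixed differences against an outgroup are counted per codon; multi-position
codon differences are averaged over substitution orderings, excluding
pathways through a stop codon unless all orderings pass through one.
Within-matriline polymorphism enters the MK table as unique polymorphic
site counts by effect ("assuming fixed differences" in the source
convention). Per-gene tests are reported uncorrected — matching how such
tables are published — with a Bonferroni column alongside for transparency.

## Maternity inference

In a hermaphroditic cross neither parent is known to be the mother, but
only the mother transmits mtDNA. For each offspring the package computes
the Pearson correlation between its per-site heteroplasmy frequencies and
each candidate parent's, over the **union** of sites variable in either
member (absent sites imputed as 0). The union policy is deliberate:
restricting to the intersection can manufacture near-perfect correlations
from a handful of shared sites. Intersection is available as a flag.

Assignment criteria:

* **strict** — assigned only when exactly one parent shows a positive,
  significant (two-sided p < 0.05) correlation. When both qualify the
  offspring is left unassigned: the wording of the published procedure
  leaves this case open, and we read "both significant" as ambiguous
  evidence under the strict rule.
* **loose** — among qualifying parents, the lower p-value wins, ties broken
  by higher R².

Significance is per-offspring with no multiple-testing correction (matching
the published per-offspring procedure); a Benjamini–Hochberg column is
emitted alongside. A documented caveat: when the two candidate parents are
full sibs they share maternal heteroplasmy, so an offspring may correlate
weakly with its father too. This confound is not modelled in the
assignment; it is visible in the simulator (parent–parent frequency
correlations around 0.85) and the procedure still recovers ≥ 90% of true
mothers there.

Group comparisons of offspring heteroplasmy by assigned mother use the
pooled-variance Student t-test: only the pooled form reproduces published
group comparisons computed from printed summary statistics, and
`pooled_t_summary()` provides exactly that closed form.

The pedigree mutation rate is the direct estimate
$\hat\mu = n_{fixed} / (n_{individuals} \times L_{mt})$, with
`count_majority_variants()` (frequency strictly > 50%) supplying the
numerator. It is a *pedigree* rate: selection has not yet purged these
variants, so it should exceed phylogenetic substitution rates by design.

## The simulator

`sim_config()` defaults describe the study conditions the package targets;
they are fixed choices, not tuning knobs:

| parameter | default | meaning |
|---|---|---|
| `L_mt` | 14,202 | mitogenome length (bases) |
| `gene_layout` | 13 PCGs + 2 rRNA + 22 tRNA | compact snail-like complement; one PCG and three tRNAs on the minus strand |
| `n_generations` | 5 | founder → focal cross depth; ~90 individuals |
| `offspring_per_cross` | 76 | focal-cross sibship |
| `bottleneck` | 100 | germline genome copies `N_b` |
| `mu` | 0.01 | de novo heteroplasmy seeding probability per site per generation at the reference copy ratio |
| `founder_het_sites` | 520 | founder heteroplasmic sites |
| `founder_freq_mean` | 0.026 | exponential mean founder frequency (truncated at 0.5) |
| `selection_s` | 0.8 | per-generation penalty on non-synonymous frequencies |
| `copy_ratio_bounds` | 5–80 | log-uniform per-individual copy ratio |
| `kappa` | 1 | de novo intensity ∝ ratio^−κ |
| `error` | 0.001 | per-base sequencing error |
| `mean_depth` | 100 | Poisson depth over the mitogenome |

Transmission resamples each site through the bottleneck
($f' = B/N_b$, $B \sim \mathrm{Binomial}(N_b, f)$), de novo events arrive
at per-site probability $\mu\,(R/R_{ref})^{-\kappa}$ (with $R_{ref}$ the
geometric mean of the copy-ratio bounds) and seed frequency $1/N_b$, and
selection multiplies non-synonymous frequencies by $1-s$ after
transmission. Selection as a deterministic frequency penalty — rather than
viability sampling — is the simplest model that produces the empirical
signature (non-synonymous depletion at codon positions 1–2). The
ratio→mutation coupling is modelled causally from copy ratio to mutational
input while acknowledging that in real data the association is
correlational only.

Where the literature gives no distributional information (founder
frequency distribution, de novo seeding rate), values were chosen once for
realism: the founder figures mirror a real parent with 2.6% mean frequency
across 520 sites, and `mu = 0.01` yields per-individual variable-site
loads in the low hundreds and an association strength (median R² ≈ 0.25 at
n = 90) of the same order as reported in the field (R² ≈ 0.2). Sequencing
is emulated site-wise: Poisson depth, binomial alternative reads at
$f(1-\varepsilon) + (1-f)\varepsilon/3$, remaining error reads split over
the other two bases by a sequential multinomial decomposition so counts
always sum to depth. Read totals are constructed to invert exactly back to
the true copy ratio through `copy_ratio()`.

Randomness is routed through per-individual sub-streams derived by stable
hashing of individual ids, so enlarging a pedigree never changes existing
individuals' draws, and a seed fixes every output byte.

What the simulator does *not* emulate — and what passing tests therefore do
not establish about real data: NUMT contamination, alignment and mapping
artefacts, batch effects beyond resampled sequencing noise, linked sites
and recombination-free haplotype structure, tissue heterogeneity, and any
dependence of depth on base composition. The false-positive control is
purely the binomial error model.

## Numerical and degenerate-input choices

* Coordinates are 1-based inclusive throughout; circular features may wrap
  (`start > end`) and are unrolled internally. How start-codon polishing
  should interact with a gene spanning the origin is undocumented in the
  annotation conventions we follow; unrolling the circle is our reading.
* Annotation polishing applies the curation rules in order (trust tRNAs;
  first eligible in-frame start nearest the preceding gene; no PCG–tRNA
  overlap; PCG–PCG overlap only in different frames; abbreviated stops
  flagged; start set ATG/ATA/ATT/ATC/TTG/GTG; rRNA bounds untouched) and is
  idempotent. A PCG with no eligible start codon in its span is an error
  naming the gene.
* Abbreviated-stop partial codons are completed with A (polyadenylation)
  for classification.
* Correlation and regression degeneracies (fewer than 3 points, zero
  variance) return `NA` markers with a reason, and assignments treat them
  as non-qualifying.
* Sites in two overlapping protein-coding genes are classified once per
  frame and tabulated once per gene.
* Test problem sizes: property suites run the full 90-individual,
  14.2 kb configuration where the claim is about the study scale (50-seed
  association power), and a 2 kb, 26-individual configuration for
  calibration loops (200-seed type-I) and module tests.

## Known limitations

* The copy ratio assumes uniform read sampling; GC and mappability biases
  in real data shift the proportionality constant.
* The MK polymorphism counts treat every within-matriline heteroplasmic
  site equally regardless of frequency.
* Maternity assignment is the two-candidate correlation procedure only; no
  likelihood model, no more-than-two-candidate support.
* The pedigree mutation-rate numerator relies on a fixed majority
  threshold; variants hovering near 50% make it knife-edge by construction.
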