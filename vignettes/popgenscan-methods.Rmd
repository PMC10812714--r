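---
title: "Methods and design notes for popgenscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for popgenscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the statistical models behind each stage of the
package, the defaults and why they were chosen, the behaviour of the
synthetic-data generator used for validation, and the numerical
conventions that matter when comparing output across tools.

## Data model

All statistics operate on an allele-dosage matrix (loci × samples, with
entries 0/1/2 counting copies of the non-reference allele and `NA` for
missing calls), a variant table (contig, 1-based position, single-base
ref/alt), and a sample→population map. VCF positions are 1-based; every
interval the package emits (windows, BED output, sweep truth) is 0-based
half-open, following the BED convention. Phased (`|`) and unphased (`/`)
genotype separators are treated identically because none of the
statistics here use phase.

## Variant filtering

`apply_filters()` applies rules in a fixed order — (1) contig
whitelist / biallelic SNP structure, (2) mean-depth bounds (only when
per-site depth is present in the VCF; the simulator emits none, and the
rule then passes vacuously), (3) call rate, (4) missing rate, (5) pooled
minor allele frequency, (6) exact Hardy–Weinberg — and attributes each
removed locus to the *first* rule it fails. The fixed order makes
reports reproducible, and first-fail attribution guarantees the
conservation identity `input = retained + Σ removed` that the report
class enforces.

Two conventions deserve a note:

* *Call rate vs missing rate.* The two rules are numerically redundant
  at the defaults (call rate ≥ 0.90 and missing rate ≤ 0.10 are the same
  constraint), but they are kept as distinct, separately configurable
  rules because workflows in this field commonly report removals for
  both. At default settings the call-rate rule, being applied first,
  absorbs the removals.
* *HWE on pooled genotypes.* The exact test (sum of probabilities of all
  heterozygote configurations no more probable than the observed one,
  conditional on allele counts) is applied to genotype counts pooled
  over all samples, mirroring a single filtering pass over the combined
  panel. Pooling samples from differentiated populations induces a
  Wahlund-style heterozygote deficit, so the default threshold is
  deliberately extreme (p < 1e-5) to remove only gross artefacts.

The default thresholds are: MAF ≥ 0.05, missing rate ≤ 0.1, call rate
≥ 0.90, HWE p ≥ 1e-5, mean depth strictly between 3× and 30×, biallelic
SNPs only. `ld_prune()` implements the classic windowed pruning (50-SNP
windows advanced by 10 SNPs, r² > 0.2): within a window, pairs are
scanned in position order and the *later* member of an offending pair is
dropped. The which-of-the-pair tie-break varies between tools; dropping
the later locus keeps the pass deterministic.

## Diversity statistics

Within a population with per-locus alt-allele frequency $\hat p$
estimated from $n$ non-missing diploid calls:

* $H_E$ uses the unbiased gene diversity
  $2\hat p\hat q \cdot \frac{2n}{2n-1}$; the correction matters at the
  sample sizes this package targets (5–12 diploids per population).
* $P_N$, $H_O$ and $H_E$ are averaged over the *full filtered locus
  set*, not per-population segregating subsets, so values are comparable
  across populations.
* Mean MAF averages $\min(\hat p, 1-\hat p)$ over loci segregating in
  the pooled sample.
* $F_{IS}$ is the method-of-moments estimate per individual,
  $F_i = (O_{hom,i} - E_{hom,i})/(L_i - E_{hom,i})$, with the expected
  homozygote count built from the corrected gene diversity at the loci
  the individual was genotyped at; the population value is the mean of
  the $F_i$. Individuals with a degenerate denominator are excluded
  with a warning rather than contributing ±Inf.

## Differentiation

Per-site differentiation uses the Weir–Cockerham (1984) variance
components for two groups of diploids: $a$ (among populations), $b$
(among individuals within populations), $c$ (within individuals), and
$\theta = a/(a+b+c)$. A locus is usable when both groups have at least
two non-missing calls; loci monomorphic across both groups have an
undefined $\theta$ and are excluded from averages (they contribute zero
to sums regardless). The genome-wide estimate is the *ratio of sums*
$\sum a / \sum (a+b+c)$ — the standard combination for this estimator —
clamped at zero for reporting with the raw value retained as an
attribute. Negative per-site values are *not* clamped before window
averaging: clamping would bias window means upward.

Reynolds' distance is computed from allele frequencies with a
finite-sample correction: per locus the squared frequency difference is
debiased by the binomial sampling variance $\hat p\hat q/(2n-1)$ of each
frequency, the denominator adds the unbiased within-population gene
diversities, and the ratio of sums estimates the drift-model coancestry
$\theta_R$, mapped to $D = -\ln(1-\theta_R)$. Negative $\theta_R$ is
truncated to zero before the log; complete fixed differences give
$\theta_R = 1$ and an infinite distance, flagged with a warning. For
small divergence $D \approx \theta_R$ to first order, which the tests
verify.

## The sweep scan

The scan contrasts one test population against all remaining samples
pooled into a single control group. Geometry: 100-kb windows advanced by
50 kb (defaults), emitted only when fully contained in the contig, and
retained only with ≥ 50 SNPs carrying a defined per-site $\theta$.
Within retained windows:

* window F_ST is the arithmetic *mean of per-site θ* (a ratio-of-sums
  alternative is a one-line change via `site_fst()`, but the mean is the
  default because window averaging of per-SNP values is the convention
  this scan follows);
* Z(F_ST) standardizes the window means to mean 0, sd 1 (sample sd)
  across all retained windows genome-wide;
* nucleotide diversity per site is the unbiased
  $\frac{m}{m-1}2\hat p\hat q$ with $m$ non-missing allele copies —
  exactly the mean pairwise difference among the sampled copies, which
  the tests verify against literal pairwise counting — summed over
  variant sites and divided by window length (per-bp). Since all windows
  share one length, the log2 ratio
  $\log_2(\pi_{control}/\pi_{test})$ is identical under per-bp or
  per-window-total scaling;
* Tajima's D per group uses $S$ segregating sites and total window
  $\hat\pi$, with the standard constants evaluated at the rounded mean
  number of non-missing allele copies across the window's genotyped
  sites (a per-site-constants variant would be possible, but a single
  $n$ keeps D interpretable and matches common practice with modest
  missingness). D is reported as missing — never zero — when $S = 0$,
  so downstream means are not dragged toward zero.

Outliers are called by *rank*: the top $\lfloor(1-q)W\rfloor$ windows by
each statistic ($q = 0.95$ by default over $W$ retained windows), ties
broken by genomic order, joint outliers being the intersection. The
rank rule makes the flagged count deterministic; the realized cutoffs
(minimum flagged Z(F_ST) and log2 ratio) are reported so runs can be
compared on the value scale. A structural consequence worth keeping in
mind: the joint set can never exceed $\lfloor(1-q)W\rfloor$ windows, so
when the truly swept fraction of the genome is larger than $1-q$, a
top-5% scan *cannot* flag every swept window — it identifies the
strongest signals, not the full extent of the swept territory. With the
validation generator's defaults (five 200-kb sweeps on 10 Mb ≈ 12.5% of
windows swept, 199 windows, 9 slots per statistic) the ceiling binds:
what the tests therefore assert is that the joint outliers that *are*
called fall overwhelmingly inside planted sweeps and that the
directional signatures (π depletion, elevated F_ST, negative test-group
Tajima's D) hold.

## LD decay and effective population size

r² is the squared Pearson correlation of dosages over samples
non-missing at both loci (the composite estimator — the natural choice
for unphased genotypes; haplotype-EM r² would require phase
information this package does not model), restricted to same-contig
pairs within 1 Mb. Pairs with a monomorphic member are skipped. An
optional minimum pair separation in SNPs and a per-locus partner cap
(random subsample; seed the RNG for reproducibility) keep the pair count
tractable. Distance bins of 20 kb are averaged arithmetically, and
`estimate_ne()` inverts $E(r^2) = (1+4N_ec)^{-1}$ per bin with the bin
midpoint converted to Morgans at 1 cM/Mb (configurable): the
finite-sample adjustment subtracts $1/(2n)$ from mean r² (on by
default), $\alpha$ defaults to 1 (2.2 is the usual
mutation-adjusted alternative), and each bin maps to
$t = 1/(2c)$ generations ago. Bins whose adjusted r² or Ne is
non-positive are flagged undefined rather than floored, because a
floored value would masquerade as an estimate. The forward–inverse
identity (bins synthesized from the model equation invert to the exact
Ne) is checked to machine precision in the tests.

## The synthetic-data generator

`simulate_dataset()` draws, per locus, an ancestral frequency uniform on
$[0.05, 0.95]$ and per-population frequencies from the Balding–Nichols
Beta distribution with drift parameter F — the canonical model in which
F *is* the true F_ST, which turns differentiation estimation into a
parameter-recovery problem with a known answer. Genotypes are two
Bernoulli allele draws, duplicated with probability $F_{sim}$ to plant
within-population inbreeding; sweeps override the test population's
frequency to $1-(1-s)u$ (near fixation for strength $s \to 1$);
missingness is i.i.d. All draws come from one seeded Mersenne–Twister
stream in documented order, so output is byte-identical per seed.

Defaults emulate a small two-group resequencing contrast: 12-diploid
test population vs 33-diploid pooled control, F = 0.05 on both branches,
50,000 SNPs on one 10-Mb contig, 2% missingness, five 200-kb sweeps at
strength 0.95 placed at regular 1.8-Mb intervals. These sizes keep the
full simulate–filter–scan cycle in a few seconds while leaving ~250
SNPs per 100-kb window, comfortably above the 50-SNP retention floor.

What the generator deliberately does **not** emulate — and hence what
passing tests do *not* establish about real data:

* **No linkage.** Loci are drawn independently, so the simulated data
  contain no LD decay; background r² sits near the finite-sample
  expectation at all distances. The LD module is therefore validated
  with construction-based fixtures (a Markov-copied genotype matrix with
  known index-decaying correlation) and the exact forward–inverse Ne
  identity, not with the Balding–Nichols output.
* **No selection dynamics.** Sweeps are imposed on frequencies, not
  simulated through time with recombination; the generator produces
  exactly the signal pattern the scan targets (local differentiation +
  diversity depletion + rare-variant excess), which is ideal for
  recovery testing but cannot probe the scan's power against partial or
  soft sweeps.
* **No demography.** Single-F drift per population; no bottlenecks,
  migration or growth, so simulated Tajima's D backgrounds are milder
  than in real populations.
* **No sequencing error or depth structure**, so the depth filter is
  exercised only via explicitly supplied depth vectors in tests.

## Validation problem sizes

The test suite and the acceptance script use: 100–150 randomized small
fixtures per estimator against independent brute-force oracles (π exact
to 1e-12 with complete data; exhaustive enumeration for the HWE test up
to 10 individuals); 20,000 loci × 2 × 50 diploids for drift recovery
(tolerance ±0.02 on θ, monotonicity over F = 0.01–0.30); the default
generator (50,000 × 45) for the sweep scan, missingness calibration
(±0.005) and pipeline byte-reproducibility; and 10,000 loci × 50
diploids for F_IS recovery (±0.05). These sizes were chosen so the whole
suite completes in about a minute while leaving Monte-Carlo noise well
inside each tolerance.

## Known limitations

* Only two-group Weir–Cockerham components are implemented; multi-way
  θ across k > 2 populations is composed pairwise in
  `pairwise_matrix()`.
* Tajima's D with heavy, uneven missingness leans on the rounded-mean
  allele-copy approximation for the constants.
* The exact HWE test is two-sided by probability mass; mid-p variants
  are not offered.
* `ld_prune()` recomputes pairwise correlations per window without
  caching, which is fine at panel scale (tens of samples, overlapping
  windows of 50 SNPs) but not tuned for biobank-size data.
* No haplotype statistics (iHS, XP-EHH), no phasing or imputation, no
  enrichment analysis of annotated genes.
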