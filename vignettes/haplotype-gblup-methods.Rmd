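---
title: "Haplotype-block GBLUP: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haplotype-block GBLUP: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
what is computed, under which assumptions, and why the genuinely open design
choices were resolved the way they were. Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## 1. Quality control

Input is a phased, biallelic VCF (GT fields with `|` separators) and a
delimited phenotype table (id, sex, slaughter age, birth date, carcass
traits). Filters, with defaults: minor allele frequency < 0.01, SNP
genotype call rate < 0.95, Hardy–Weinberg equilibrium p < 0.001 (one-df
chi-square against expectations from the sample allele frequency),
duplicated (chromosome, position) records (first kept), individual call
rate < 0.95. Phenotypes and the age covariate are screened by the
two-sided Grubbs test at α = 0.05, applied iteratively — remove the flagged
value, re-test — until no test is significant.

Open points resolved here, as package choices rather than reconstructions
of anyone's intent:

* **Filter order** is fixed and logged — individual call rate, then
  duplicates, SNP call rate, MAF, HWE — because the order changes the
  per-filter counts.
* **MAF is haplotype-based** (mean of the phased alleles, missing entries
  excluded): genotypes arrive phased, so the haplotype frequency is the
  natural estimator.
* **HWE uses the chi-square test**; no source dictates a particular test,
  and the chi-square is the field default at these sample sizes.
* Unphased *heterozygous* calls are an error in strict mode (they cannot be
  assigned to haplotypes); unphased homozygotes are unambiguous and always
  accepted.

## 2. Linkage disequilibrium and block construction

For two loci with alternate-allele frequencies $p_A$, $p_B$ and haplotype
frequency $p_{AB}$,

$$D = p_{AB} - p_A p_B, \qquad
D_{\max} = \begin{cases} \min\{p_A(1-p_B),\,(1-p_A)p_B\} & D > 0\\
\max\{-p_A p_B,\,-(1-p_A)(1-p_B)\} & D < 0 \end{cases}, \qquad
D' = D / D_{\max}.$$

Conventions: $D' = 0$ when $D = 0$ or a locus is monomorphic (so stray
fixed alleles cannot crash clustering); haplotypes with a missing value at
either locus are deleted pairwise (minimum two informative haplotypes).

The clustering distance between SNPs is $1 - |D'|$ by default. The sign of
$D'$ flips under arbitrary ref/alt relabelling, so a signed $1 - D'$
distance would depend on strand/label conventions that carry no biology; a
`"signed"` mode preserves the literal definition for comparison. This is a
deliberate, documented divergence, not an interpretation.

Three block definitions, calibrated to an average of $k \in \{5,10,20,50\}$
SNPs per block:

* **count** — runs of exactly $k$ SNPs per chromosome. The trailing
  remainder is kept as a short block by default; `drop` (excluded, listed)
  and `merge_last` policies are available. `drop` reproduces the accounting
  where block totals are exact multiples of per-chromosome $\lfloor n/k
  \rfloor$.
* **length** — half-open windows of (genome length / SNP count) × $k$ bp,
  anchored at each chromosome's first SNP (anchoring at coordinate zero
  would only create leading empty windows). Genome length is the sum of
  per-chromosome spans.
* **ld_cluster** — agglomerative complete-linkage clustering in which only
  physically adjacent SNPs or clusters may merge. A linear list of
  adjacent-cluster distances is the source of truth: each merge removes the
  three affected entries and inserts two distances recomputed directly by
  the complete-linkage rule (max of $1-|D'|$ over cross pairs). Merging
  stops at the cluster-count threshold K = round(total SNPs / $k$).

Because adjacency makes cross-chromosome merging impossible, the
genome-wide K must be apportioned: proportionally to chromosome SNP counts
by largest remainder, minimum one per chromosome. Ties in the minimum
search break to the leftmost pair so runs are exactly reproducible. Merge
distances under this constrained update scheme need not be monotone
non-decreasing — complete linkage guarantees monotonicity only for
unconstrained merging — so the suite instead verifies that every logged
merge distance is reproduced by direct recomputation, and that the whole
merge sequence matches a quadratic-time reference that rebuilds the full
distance list at every step.

## 3. Haplotype alleles, diplotype dosages, GBLUP

Per block, the distinct phased strings among the 2N haplotypes are the
alleles (ordered by descending frequency, ties by string, so column order
is deterministic). Individual i is coded by dosage $x_{ij} \in \{0,1,2\}$;
within every block an individual's dosages sum to exactly 2. Haplotypes
with residual missing entries are assigned to the most frequent compatible
complete haplotype at encoding time only (a strict mode errors instead);
the stored genotypes are never imputed.

The relationship matrix is
$$G = \frac{M_c M_c'}{2\sum_j p_j (1-p_j)}$$
with $M_c$ the *centered-only* design $x_{ij} - 2p_j$. A `paper_literal`
mode divides the centered-and-scaled design by the same constant — a
combination that double-scales relative to either standard construction but
is retained for faithfulness to sources that print it. Two related
ambiguities are resolved the same way: $p_j$ is the allele's *own*
frequency, not the folded minor-allele frequency, because folding breaks
the zero-mean property of centered columns; and the marker back-solution
$\hat u = s\,M'G^{-1}\hat g$ uses $s = 1/2\sum p_j(1-p_j)$ so that
$M\hat u = \hat g$ exactly (an `/N` variant is provided, as the divisor is
dimensionally ambiguous in print). Fixed alleles ($p_j \in \{0,1\}$) are
dropped with a logged count. Centered GRMs have the ones vector in their
null space, so the back-solution uses an eigenvalue-thresholded
pseudo-inverse; $\hat g$ lies in the range of G, so the reconstruction
identities hold to 1e-8 regardless.

REML for $y \sim N(Xb,\, G\sigma^2_g + I\sigma^2_e)$ exploits the single
genomic component: after eigendecomposition of G the restricted likelihood
profiles to one dimension in $\lambda = \sigma^2_g/\sigma^2_e$, searched by
staged grid refinement (best log-likelihood non-decreasing by construction)
and polished by Brent's method to |Δ log-lik| < 1e-8. Boundary estimates
clamp at $\sigma^2_g = 0$. Standard errors come from the observed
information of the two-parameter restricted likelihood; $h^2 =
\sigma^2_g/(\sigma^2_g+\sigma^2_e)$. Numerically negative eigenvalues are
clamped at zero, and a 1e-6 ridge is added to G only when its smallest
eigenvalue falls below 1e-8 (always recorded). The suite cross-checks this
fit against `lme4` on an equivalent random-intercept model ($G = ZZ'$) and
against a dense-matrix likelihood evaluated with `solve()`.

## 4. Validation

Accuracy is the Pearson correlation between predicted GEBVs and phenotypes
pre-corrected for sex and slaughter age (OLS residuals), over 5×5
cross-validation and a forward split (test = born on/after the cutoff,
inclusive). Within each fold, allele frequencies, centering, REML and — by
default — the pre-correction coefficients are estimated on the training
side only; a `whole_data` pre-correction mode mirrors the literal reading
in which correction precedes validation. Block boundaries and allele
catalogs are built on the full genotype panel: genotypes are not the
predicted quantity, and fold-specific boundaries would make the design
matrices incomparable across folds. Both choices are the package's own.
Test GEBVs come from $G_{new} G^{-1}\hat g$ (computed as $G_{new}\alpha$
without inverting G), which equals $M_{new}\hat u$. A boundary fit
($\sigma^2_g = 0$) predicts a constant; its accuracy is recorded as 0
rather than NA. Paired t-tests compare methods on the 25 (repeat, fold)
accuracy pairs — the pairing unit is a package choice; all-zero differences
return (t = 0, p = 1) as a flagged degenerate case.

## 5. The simulator: what it emulates and what it does not

`simulate_genotypes()` is a founder-mosaic generator: each chromosome is
partitioned into LD segments (geometric lengths, mean 8 SNPs, minimum 3);
each segment carries a pool of founder haplotype patterns (default 3, every
SNP segregating in the pool); each individual haplotype picks one founder
per segment, keeping the previous segment's founder with probability 0.5.
A founder-mosaic design was preferred over a coalescent simulator because
it is dependency-free and gives direct control over block-level allelic
structure — the quantity the haplotype methods exploit.

Default conditions: 1,000 individuals, two chromosomes of 2,500 SNPs at
~4 kb mean spacing (exponential gaps), heritability 0.4 (within the 0.3–0.5
range typical of carcass traits), sex ~ Bernoulli(0.5) with effect 0.5,
slaughter age ~ U(24, 36) months with slope 0.05, unit genetic-plus-residual
variance, birth dates uniform over 2010–2013 so the 2012-01-01 forward
split is meaningful. The segment/founder defaults were calibrated once, at
design time, to two qualitative features of dense cattle panels: mean
adjacent-SNP r² near 0.4, and total haplotype-allele counts that *grow*
with block size for every method (longer founder segments cap within-block
allele counts at the pool size and invert that direction). Validation
experiments in the tests and the acceptance script use genomes of 2,500
SNPs (2 × 1,250) and 60 QTL so that complete runs finish in minutes; these
sizes are stated here as the package's documented problem sizes.

Two QTL architectures: `snp_additive` draws effects for random SNPs;
`haplotype_allelic` attaches effects to the founder string of a short (≤5
SNP) window chosen so that, at every window SNP, some non-carrier founder
shares the causal allele's value — hence no single SNP can tag the allele
(the suite asserts max single-SNP r² < 0.9). True breeding values are
rescaled to variance $h^2$, residuals drawn with variance $1-h^2$. An
optional founder-drift parameter tilts founder sampling weights along the
birth-cohort axis, producing the allele-frequency drift that degrades
forward validation relative to cross-validation.

What the generator does **not** emulate: demographic history and pedigree
structure, selection, genotyping error, imputation/phasing error, MAF
spectra skewed toward rare variants, LD decay within segments. Passing
tests therefore demonstrate the correctness of the algorithms and the
direction of the haplotype-vs-SNP comparison under a favourable, controlled
architecture — not the magnitude of any gain on real cattle data.

## 6. Known limitations

* Single genomic variance component only (no dominance, no multi-kernel
  GREML, no single-step H).
* The constrained clustering is exact but quadratic in the worst case;
  panels far beyond ~100k SNPs per chromosome would need a smarter
  minimum-search structure (any such structure must reproduce the linear
  scan's merge sequence bit-identically).
* `read_phased_genotypes()` assumes biallelic records after its
  multiallelic skip; structural variants are not handled.
* Grubbs screening assumes approximately Gaussian traits; heavy-tailed
  traits will over-flag.
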