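---
title: "Quantifying intratumoral heterogeneity and treatment-driven subclonal dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intratumoral heterogeneity and treatment-driven subclonal dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(itgh)
```

## The problem

A solid tumor is rarely one genetic entity: it is a founder clone plus
subclones at varying cancer-cell fractions (CCFs). This intratumoral genetic
heterogeneity (ITGH) matters clinically — more heterogeneous tumors carry
more raw material for progression and therapy resistance — and it changes
under treatment, when therapy acts as a selective pressure on coexisting
subpopulations.

With single-region sequencing, the accessible footprint of ITGH is the
distribution of mutant-allele frequencies (MAFs): for each somatic SNV,
`maf = alt_count / (ref_count + alt_count)`. A homogeneous tumor piles its
MAFs near one value (half the purity, for heterozygous diploid variants); a
heterogeneous tumor spreads them out. `itgh` implements the analysis built
on that observation: per-sample MAF dispersion (the MATH score), per-variant
MAF-shift tests between matched samples (enriched mutations), substitution
spectra, and the cohort statistics that relate heterogeneity to clinical
covariates.

## The MATH score

For a sample's MAF vector the MATH (mutant-allele tumor heterogeneity)
score is

$$\mathrm{MATH} = 100 \times \frac{1.4826 \cdot
\mathrm{median}_i\,|\mathrm{MAF}_i - \mathrm{median}(\mathrm{MAF})|}
{\mathrm{median}(\mathrm{MAF})}$$

i.e. the width of the MAF distribution relative to its center, with the
median absolute deviation scaled by the usual 1.4826 normal-consistency
constant so that it estimates a standard deviation under normality. Two
properties motivate the ratio form:

* **Purity robustness.** Contaminating normal tissue rescales every MAF by
  the same factor; a ratio of a dispersion to a location statistic is
  invariant under joint rescaling. The suite verifies this to 1e-9 relative
  tolerance.
* **Robustness to outliers.** Median and MAD ignore a handful of extreme
  MAFs (e.g. variants on copy-number-altered segments), which is why the
  score tolerates moderate CNV burden.

Choices that the score's original definition leaves open, and how this
package fixes them: even-length medians are the arithmetic midpoint of the
two central order statistics; MAFs are **not** purity-corrected before
scoring (purity association is checked separately at the cohort level);
samples with fewer than `min_variants` MAFs (default 5) or a zero median
get a flagged `NA` score rather than an error, and flagged samples stay in
cohort tables. Defaults `min_depth = 10` and `min_variants = 5` stabilize
the median on shallow or mutation-poor samples; both are arguments
everywhere they matter.

```{r math-example}
mathScore(c(0.1, 0.2, 0.3), min_variants = 3)
```

## Enriched mutations: exact binomial MAF-shift tests

To monitor subclonal dynamics between a reference sample A (e.g.
pre-treatment) and a matched sample B (post-treatment), each shared variant
is tested with an exact binomial test: under the null of no compositional
change, B's mutant reads are `Binomial(depth_b, p0)` with `p0` equal to the
MAF observed in A. Variants whose adjusted p-value falls below `alpha` are
*enriched* — in B if the MAF rose, in A if it fell. The default correction
is Bonferroni at `alpha = 0.05`, with Benjamini–Hochberg available; the
default two-sided convention is minimum-likelihood (sum of all outcome
probabilities no larger than the observed one), with a central doubled-tail
option exposed because two-sided exact conventions differ between tools.

Three deliberate design points:

* **Directionality.** The test conditions on A's observed MAF and treats
  only B's counts as random. A two-proportion exact test would treat both
  as random; the single-direction form mirrors the positive-control /
  reference-timepoint structure of a paired design (PRE as reference for
  PRE/POST, blood as reference for blood/mucosa) and is recorded in the
  output metadata.
* **Anti-conservativeness under the null.** Because `p0` is itself an
  estimate from finite reads, the null distribution of the test statistic
  is wider than the binomial assumed (by roughly $\sqrt{2}$ in standard
  errors at equal depths). Bonferroni therefore does not deliver strict
  family-wise control here: in a 500-variant null simulation a few calls
  per family are expected. What does hold — and what the acceptance suite
  checks — is that the *fraction* of variants called enriched under the
  null stays well below 5% (measured ≈ 0.6% at 100× depth). Interpreting
  a single enriched call in real data therefore warrants caution;
  interpreting dozens (as in a strong selection signal) does not.
* **Untestable variants.** A reference MAF of exactly 0 or 1 admits no
  binomial null; such variants are excluded with a logged count.

By default tumor-pair comparisons restrict to coding and splice-site
variants (the set most likely to carry functional impact, and the one used
for selection inference); germline comparisons should disable the
restriction. The N/S ratio (nonsynonymous over synonymous counts) among
variants enriched on one side, and a Fisher exact contrast of the
N/S-by-side table, summarize whether selection favored protein-altering
changes. Fisher tests are two-sided by default; the one-sided variant is
exposed since published contrasts of this kind are sometimes directional.

## Substitution spectra and signature refitting

Spectra collapse each SNV to the pyrimidine-reference representation (G>T
counts as C>A via reverse complement), either into 6 classes or into the 96
trinucleotide-context bins in the conventional COSMIC ordering. Contexts
are caller-supplied — the simulator emits them, and real data should derive
them from a reference genome upstream — so the package performs no genome
lookups. Exposure refitting against a user-supplied signature matrix is
non-negative least squares on the normalized spectrum with exposures
renormalized to sum 1 and the residual norm reported; de novo signature
extraction is deliberately out of scope.

## Cohort statistics

Group contrasts of MATH scores use Wilcoxon tests: exact when both groups
have at most 25 observations and no ties, otherwise the normal
approximation with continuity correction; the same rule applies to the
signed-rank test on non-zero paired differences, and an all-zero difference
vector is reported degenerate with p = 1. The standard battery
([associateMath()]) contrasts stage I+II vs III+IV and N0 vs N1+N2 and
correlates MATH with CNV count and purity (Pearson, t-based p). One
deliberate deviation from common practice in the literature this package
follows: nodal contrasts across *independent* patients are necessarily
unpaired, so the rank-sum test is used there, and the paired signed-rank
test is reserved for within-patient timepoint contrasts; the report notes
this. No multiple-testing correction is applied across the (few) cohort
tests, matching how such panels are conventionally presented.

## The simulator: what it emulates and what it does not

`simulatePair()` generates matched variant tables from a known clonal
architecture, so every stage of the pipeline can be tested against ground
truth without external data. The model:

* one founder clone (CCF 1 at both timepoints) plus mutually exclusive
  subclones whose CCFs may shift between timepoints (a CCF increase marks
  the clone's private mutations as selected);
* heterozygous, diploid, copy-number-neutral mutations: expected MAF is
  `purity × CCF / 2` ([expectedMaf()]);
* per-variant depth `Poisson(mean_depth)` truncated at 1, mutant reads
  `Binomial(depth, expected MAF)`;
* a detection rule (`alt >= min_alt`, default 1) that drops undetected
  variants from a sample's table — this alone produces the realistic
  partial sharing of mutation complements between timepoints;
* optional de novo post-treatment mutations on a dedicated clone;
* per-(sample, clone) seeded random substreams, so enlarging one clone
  never perturbs another clone's reads.

Defaults encode the observational setting the package targets: purity 0.8
at both timepoints (tumor samples admitted at ≥ 80% tumor nuclei), mean
depth 100×, exome-like effect classes (90% coding, 75% of coding
nonsynonymous). The germline generator draws the same sites in both samples
with a 1/3 homozygous-alternate fraction (the familiar ~2:1 het:hom ratio);
that het/hom mix provides the between-site MAF variance that makes two
same-individual samples strongly concordant (R² ≈ 0.94 at 100×, 2,000
sites) — an all-heterozygous model would have no between-site variance and
therefore near-zero MAF correlation, which is not how germline variant sets
behave.

Not modeled, by design: sequencing error, mapping artifacts, CNV/LOH and
mutation multiplicity, nested clone phylogenies, indels. Passing tests on
simulated data therefore demonstrate the statistical machinery under the
diploid read-sampling model, not robustness to those real-data
complications; in particular, purity *differences* between timepoints shift
all MAFs jointly and can masquerade as widespread enrichment, which is why
microdissection-style purity control matters for the real analysis.

## Verification problem sizes

The test and acceptance suites run: MATH oracle equivalence on 1,000 random
vectors; binomial-test enumeration equality for all depths ≤ 30 at p0 ∈
{0.1, 0.25, 0.5}; null calibration over 20 replicates of 500-variant pairs
at 100× (enriched fraction ≈ 0.006, bound 0.05); selection recovery for a
0.10 → 0.60 subclone at purity 0.8 and 100× (≥ 80% of its private
mutations flagged POST-enriched, zero founder mutations flagged at the
default seed); MATH monotonicity of four dispersed subclones vs a single
clone over 20 replicates; and per-clone mean MAF within 3 standard errors
of `purity × CCF / 2`. These sizes give stable statistics at sub-minute
runtimes; all are parameters, not constants, if larger experiments are
wanted.

## Known limitations

MATH compresses heterogeneity to one number and cannot count clones;
enrichment calls inherit the anti-conservativeness discussed above and are
blind to purity shifts; spectra require caller-supplied contexts; the
cohort battery assumes the metadata dialect documented in
[associateMath()]. The simulator's omissions are listed above. Reproducing
published cohort-level numbers requires the corresponding per-sample
mutation tables, which ship with the respective studies, not with this
package.
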