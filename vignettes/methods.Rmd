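---
title: "Models and methods: population structure across replicated elevational gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: population structure across replicated elevational gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chickpop)
```

## The problem

Mountain-bird populations sampled at paired high- and low-elevation sites
along several geographic transects pose a classic landscape-genomics
question: does elevation structure genetic variation, either genome-wide
(restricted gene flow) or at individual loci (parallel divergent selection)?
chickpop implements the full analysis chain for such designs, starting from
genotype *likelihoods* — the natural currency of low-coverage
genotyping-by-sequencing (GBS) data — rather than called genotypes: a
hierarchical Bayesian genotype-probability model, SNP retention filters,
genome-wide and locus-specific differentiation statistics with permutation
nulls, multivariate ordination, hierarchical AMOVA, distance-matrix
regression, and a permutation test for *parallel* locus-specific divergence
across replicated elevational contrasts.

The package assumes the canonical design used throughout: six sites arranged
as three transects, each with one `high` and one `low` site.

## Genotype model

At each biallelic locus, individual $i$ contributes a likelihood triple
$L_i(g) = P(\text{reads}_i \mid g)$ for $g \in \{0, 1, 2\}$ copies of the
non-reference allele. Triples are stored max-normalised (likelihoods are
defined only up to a constant). Within each group (by default each sampling
site) the model places a Hardy–Weinberg prior on genotypes given the group
allele frequency $p$ and a flat $\mathrm{Beta}(1,1)$ prior on $p$, and runs a
Gibbs sampler per locus:

1. $g_i \sim P(g \mid \cdot) \propto L_i(g) \cdot
   \{(1-p)^2,\, 2p(1-p),\, p^2\}_g$,
2. $p \sim \mathrm{Beta}(1 + \textstyle\sum_i g_i,\; 1 + 2n - \sum_i g_i)$.

Defaults are 10 000 steps, 6 000 burn-in, and retention of every 2nd step
(2 000 posterior draws). Posterior genotype probabilities are the plain
retained-sample indicator means; the *composite genotype* is their
$[0, 2]$-scale mean, and group allele frequencies are the retained-sample
mean of $p$. Individuals with little coverage at a locus are thereby shrunk
toward their group's Hardy–Weinberg expectation, while deep loci are driven
by the likelihood. Initialisation (likelihood-weighted naive frequency,
argmax genotypes) only affects burn-in speed; there is no label-switching
issue. The sampler is implemented in compiled code; a one-locus testing
oracle integrates the joint posterior over $p$ on a $10^{-4}$ grid and the
two agree to better than 0.01.

Two modelling choices were genuinely open and are exposed as options:

* **Grouping of the frequency prior** (`grouping`): `per_site` (default, the
  most conservative reading of "population allele frequencies") or `pooled`.
  This choice matters more than it may appear — see *Known behaviours* below.
* **Certainty mask**: downstream analyses that require hard genotypes
  (AMOVA) keep only composites within 0.1 of 0, 1 or 2 (boundary inclusive)
  and treat the rest as missing.

## SNP filters

Defaults mirror standard GBS practice for this design: a locus is retained
when at least 90% of individuals have at least one read and the naive
minor-allele frequency (from likelihood-weighted expected genotypes) is at
least 0.05; one SNP is kept per contig (uniformly at random, seeded); locus
mean depth must lie in [4, 15] and individual mean depth across retained
loci in [3, 10], all bounds inclusive, loci filtered before individuals.
"Per-locus" and "per-individual" depth are interpreted as *means* — the
conventional GBS aggregation; alternatives (median, min/max) are not
implemented. Where retention wordings conflict at exactly the MAF boundary,
the rule is retain iff MAF ≥ 0.05.

## Differentiation statistics

Locus-specific $F_{ST}$ uses the Hudson method-of-moments estimator with
finite-sample corrections,

$$\hat F_{ST} = \frac{(p_1 - p_2)^2 - \frac{p_1(1-p_1)}{n_1 - 1}
  - \frac{p_2(1-p_2)}{n_2 - 1}}{p_1(1 - p_2) + p_2(1 - p_1)},$$

with allele frequencies taken from composite genotypes
($\hat p = \overline{\text{composite}}/2$) and allele counts $n = 2N$.
Genome-wide values combine loci as the **ratio of averages** (sum of
numerators over sum of denominators), the recommended aggregation for this
estimator; loci monomorphic for the same allele in both samples are skipped
pair-by-pair. Negative estimates are retained — the pairwise permutation
test is two-sided. Nei's standard distance $D = -\ln(J_{xy}/\sqrt{J_x J_y})$
is computed from the same frequencies.

Pairwise significance follows the published protocol: 100 permutations of
site identity (group sizes preserved), empirical 2.5/97.5 percentiles as the
null band (normal-approximation bounds are reported alongside, since the
published table does not state the method), verdict `greater`/`smaller`/`ns`.

## Ordination, PERMANOVA and DAPC

PCA is a centred, unscaled SVD of the composite matrix (PCA on the genotype
covariance matrix). PERMANOVA on the first two axes uses the standard
distance-based sums of squares with pseudo-$F$ and free label permutation;
the observed statistic is included in the null set
($p = (1 + \#\{F^\ast \ge F\})/(1 + B)$). The implementation is checked in
the test suite against an independent distance-based ANOVA (vegan's
`adonis2`) to $10^{-10}$.

DAPC proceeds in two steps. The cluster search runs k-means (10 restarts,
300-iteration cap) for $k = 1..k_{max}$ and scores each solution with
$\mathrm{BIC} = N \ln(\mathrm{WSS}/N) + k \ln N$. This BIC is only
discriminating when k-means operates in a reasonably high-dimensional score
space: in 1–2 dimensions, splitting even pure Gaussian noise reduces WSS by
a large factor (36% in 1D) and always defeats the $k \ln N$ penalty. The
pipeline therefore feeds the cluster search many PCs
(`n_pcs_cluster_search`, default 60) while the discriminant step retains the
configured `n_pcs_dapc` (default 1, matching the published analysis).
Assignment probabilities come from the equal-covariance Gaussian model in
discriminant space (ridge-regularised if the pooled covariance is singular);
they agree with MASS's LDA posteriors to $10^{-6}$ in the tests.

## Hierarchical AMOVA

Variance in certainty-masked composite genotypes is partitioned among
transects, among elevation sites within transects, and within sites, from
squared Euclidean inter-individual distances (pairwise-complete over
non-missing loci, rescaled by the fraction of loci compared — the source
protocol does not state its missing-data rule) and the standard nested
moment equations with unequal-sample-size coefficients. Individuals, not
alleles, are the lowest unit: composites are continuous, so no
within-individual stratum is modelled and "within samples" maps to
within-site. $\phi_{CT} = \sigma^2_a/\sigma^2_{tot}$,
$\phi_{SC} = \sigma^2_b/(\sigma^2_b + \sigma^2_c)$,
$\phi_{ST} = (\sigma^2_a + \sigma^2_b)/\sigma^2_{tot}$. Negative components
are reported as-is with a flag; truncation would bias the percentages.
Permutations follow the standard level-specific schemes: individuals across
all sites ($\phi_{ST}$), individuals among sites within transects
($\phi_{SC}$), whole sites among transects ($\phi_{CT}$). With six sites
there are only a handful of distinct site-to-transect arrangements, so
$p_{CT}$ has a coarse attainable floor — the tests assert ranking rather
than tiny p-values.

## Distance-matrix regression

Geographic distances are great-circle (Haversine, mean Earth radius
6371.0 km); elevational distance is $|\Delta$elevation$|$ in metres. MRM
regresses the unfolded lower triangle of the genetic distance matrix
(Nei's $D$ by default; genome-wide $F_{ST}$ optionally) on the predictor
triangles by OLS, with inference from jointly permuting rows and columns of
the response matrix — labels, never pairs, so every permuted response is
itself a valid distance matrix. Coefficient tests are two-sided on absolute
values. Because the published summary labels its statistics "Mantel
$R^2$" while describing a two-predictor regression, the wrapper reports
both the two-predictor MRM and the two single-predictor Mantel regressions.

## Parallel divergence across contrasts

For each transect, the high-vs-low locus $F_{ST}$ vector defines outlier
sets: loci strictly above the interpolated empirical quantile (rank
$1 + (L-1)q$; R's type-7) at $q = 0.97, 0.98, 0.99$, computed over the loci
defined in all three contrasts. Sharing counts are `exactly2` (loci extreme
in exactly two contrasts) and `exactly3`; "exactly" rather than "at least"
is used because the closed-form exactly-2 expectation reproduces all three
published expected values within their intervals while the at-least-2 form
does not at $q = 0.97$. The null permutes locus labels independently within
each contrast — equivalently, draws three independent uniform subsets of the
observed sizes — 10 000 times. A closed-form oracle
$$E[\text{exactly3}] = \frac{m_1 m_2 m_3}{L^2}, \qquad
E[\text{exactly2}] = \frac{m_1 m_2 (L - m_3) + m_1 m_3 (L - m_2)
 + m_2 m_3 (L - m_1)}{L^2}$$
is checked against the permutation means to three Monte-Carlo standard
errors; at the study scale ($L = 18\,073$) the permutation means also land
inside the published intervals for all six count summaries.

## The synthetic-data generator

The generator emulates the study conditions so the whole pipeline runs and
is testable without external data: ancestral allele frequencies uniform on
$(0.05, 0.95)$; per-site frequencies Balding–Nichols
($\mathrm{Beta}$ with mean $p$ and variance $F p(1-p)$, default $F = 0.02$,
the genome-wide differentiation regime reported for this design); genotypes
$\mathrm{Binomial}(2, p_{site})$ (HWE, unrelated individuals — consistent
with the genotype model's prior, not asserted of real birds); read depths
negative binomial (mean 8, dispersion 5 — GBS coverage is overdispersed
relative to Poisson); non-reference read counts binomial with a symmetric
single-parameter error rate (default 0.01, no base-quality stratification);
likelihoods the corresponding binomial pmfs. Optionally, a chosen number of
outlier loci get parallel frequency shifts: $+\delta$ at every high site,
$-\delta$ at every low site (clipped to $[0.01, 0.99]$), matching the
alternative hypothesis of the parallelism test. Balding–Nichols was chosen
over coalescent simulation because the analysis consumes only
allele-frequency structure; there is no linkage disequilibrium, selection
dynamics, or read-sequence simulation. All randomness flows from one seed;
identical configurations reproduce bit-identical outputs.

What passing tests on these data do and do not show: they validate the
estimators, the permutation machinery and parameter recovery under the
model's own assumptions; they cannot validate robustness to LD, relatedness,
batch effects, or reference bias, none of which the generator emulates.

## Problem sizes and numerical choices

Tests and the acceptance script run at desk scale, chosen as the smallest
sizes at which the statistical claims are informative: genotype-model
recovery at 6×25 individuals × 500 loci; Balding–Nichols recovery at 5 000
loci; permutation-size (type-I) studies at 500–800 replicates; the
end-to-end regime run at 1 000 loci × 150 birds — approximately the study's
sample size with a down-sampled locus count. Permutation counts follow the
published protocol (100 pairwise, 999 multivariate, 10 000 parallel). The
size study of the pairwise verdict uses 999 permutations: with 100, the
interpolated empirical 95% band has a discrete two-sided size near 6.9%
by order-statistics arithmetic, which is a property of the published
protocol itself, not of this implementation. Degenerate inputs are handled
explicitly: zero-depth likelihood triples are forced uninformative; loci
monomorphic in both samples are flagged undefined for $F_{ST}$; an
all-identical AMOVA input is flagged degenerate rather than divided by zero;
certainty tolerances of 0.5 or more are rejected because the bands would
touch.

## Known behaviours and limitations

* **Per-site priors create a correlation floor at low coverage.** With
  `grouping = "per_site"`, low-coverage genotypes within a site shrink
  toward the same (noisily estimated) site frequency. This induces apparent
  site-level differentiation even when none exists: at $F = 0$ and mean
  depth 8, pairwise $F_{ST}$ of about 0.015 and clearly significant
  PERMANOVA are observed, while pooled grouping shows neither. Real
  low-coverage studies using population priors share this floor — their
  permuted-label null $F_{ST}$ sits near the observed value for exactly this
  reason. Users comparing sites should either use pooled priors or lean on
  the permutation nulls, never on raw $F_{ST}$ magnitudes.
* **A Balding–Nichols $F$ of 0.02 is real drift, and the tests detect it.**
  When the generator is calibrated so that *true* among-site drift equals
  the *measured* genome-wide $F_{ST}$ of a study whose measured value is
  largely an estimation floor, PERMANOVA and AMOVA at 150 individuals
  correctly reject "no structure" (within-site variance lands near 93–96%,
  not >99%). The published no-structure regime is therefore reproduced only
  in its transect-level conclusions ($\phi_{CT}$ not significant, no
  site-aligned DAPC clusters), not in the site-level tests; the acceptance
  suite records this honestly rather than recalibrating the generator
  toward the published conclusion.
* AMOVA supports exactly three hierarchy levels; no allele-level
  (haplotypic) variant is implemented.
* The VCF reader consumes a deliberate subset (CHROM, POS, REF, ALT, GL/PL,
  DP/AD); it never writes VCF and skips non-biallelic records with a count.
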