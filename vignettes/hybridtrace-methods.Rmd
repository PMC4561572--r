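---
title: "Models and methods behind hybridtrace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind hybridtrace}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridtrace)
```

# The problem

Two sibling fly taxa — an introduced, hawthorn-infesting taxon and a native,
snowberry-infesting one — co-occur at paired field sites along an
environmental transect. Diploid microsatellite genotypes (fragment-length
alleles at ~19 loci) are scored for larvae reared from each host at each
site. Three questions drive the analysis:

1. **Are the taxa hybridizing, and how often?** Individual flies are
   classified into ancestry classes (pure resident, pure migrant from the
   other host, F1 hybrid, backcross), and per-generation hybridization and
   migration rates are computed from the class counts.
2. **Are alleles introgressing clinally?** If alleles from the native taxon
   are favoured in the introduced taxon near one end of the transect, the
   between-taxon allele-frequency difference at paired sites should shrink
   with proximity to that focal site — a pattern tested against a
   genotype-permutation null.
3. **Is differentiation structured as expected?** Nei-distance
   neighbor-joining trees with locus bootstraps, Mantel/partial-Mantel
   isolation-by-distance tests, and private-allele accounting describe the
   background differentiation against which hybridization is judged.

Everything is exercisable on synthetic data from a generator that emulates
the study design, so the whole pipeline is testable without any external
data.

# The genotype-class classifier

For an individual sampled from host/taxon $N$ (its *natal* taxon; $O$ the
other), five classes are considered, each a pair of gamete distributions
over alleles at each locus:

| class | gametes |
|---|---|
| pure natal | $(p_N, p_N)$ |
| pure non-natal (migrant) | $(p_O, p_O)$ |
| F1 | $(p_N, p_O)$ |
| backcross into natal | $(p_N, (p_N + p_O)/2)$ |
| backcross into non-natal | $(p_O, (p_N + p_O)/2)$ |

The probability of an unordered genotype $\{x,y\}$ under gametes
$(q_1, q_2)$ is $q_1(x)q_2(y) + q_1(y)q_2(x)$ for $x \ne y$ and
$q_1(x)q_2(x)$ otherwise; per-locus probabilities are multiplied across
non-missing loci in log space. The prior puts $1-\nu$ on pure natal and
$\nu/4$ on each other class, where $\nu$ is the prior migration rate
(default 0.01; 0.05 and 0.1 are conventional alternatives, and clear
assignments are insensitive to the choice). The "generations back" depth is
fixed at two, so F2 and backcross genotypes fall into a single
backcross/later-generation class per direction — they are not
distinguishable from two generations of microsatellite data anyway.

This is a *fixed-frequency* (empirical Bayes) classifier: reference allele
frequencies for the two taxa are estimated from the sampled individuals —
per paired site by default, matching per-site supervised runs, or pooled by
taxon via `pool = TRUE` — with Dirichlet smoothing $(\text{count} +
\lambda)/(2n + \lambda K)$ over the union allele set of the whole dataset at
the locus ($K$ alleles, $\lambda = 1/K$ by default). Smoothing over the
dataset-wide union guarantees strictly positive likelihoods even for
alleles unseen in a local reference. A full MCMC over reference frequencies
would propagate their uncertainty but at the cost of determinism; with
19 loci and tens of reference individuals per site the posterior class
calls consume only the frequency point estimates, and the fixed-frequency
form makes every number in the package reproducible bit-for-bit from a
seed.

`leave_one_out = TRUE` removes an individual's own two alleles from its
natal reference counts before smoothing. With small per-site references
(~30 diploids) self-assignment bias is material: an F1's alleles inflate
the natal reference exactly where it is unusual, dragging its posterior
toward "pure natal". Leave-one-out is therefore the recommended setting for
hybrid detection and is what the package's recovery tests use.

A technical note on an idealized case: between *fixed-difference* parents an
F1 is heterozygous everywhere, and the pure classes have zero likelihood —
but a backcross still produces a heterozygote with probability $1/2$ per
locus, so the F1 posterior is $1/(1 + 2^{1-L})$ for $L$ loci, approaching 1
only as loci accumulate. Single-locus intuition ("only the F1 can produce a
het") is wrong once backcross classes exist.

**Rates.** With argmax class calls in a host sample of size $N$:
hybridization rate $= \#F1 / N$ per generation; migration into that host's
taxon $= (\#\text{migrants} + \tfrac12 \#F1)/N$ — each F1 carries one
immigrant gamete. Ties in the argmax resolve to pure natal (conservative);
full posteriors are always reported so users can impose thresholds instead.

# The clinal-introgression test

The per-locus divergence between the two taxa at a paired site is the
total-variation distance $\tfrac12\sum_a |p_A(a) - p_B(a)|$ over the union
allele set — bounded in $[0,1]$, 0 for identical frequencies, 1 for
disjoint allele sets, and a metric. The site-level statistic is its mean
over the loci scored in both members of the pair (a pair missing a locus
simply contributes fewer loci). The cline statistic is the Pearson $r$ of
this divergence on the great-circle distance (haversine, radius
6371.0088 km) from the pair's midpoint to the focal site.

Significance comes from a permutation null that shuffles individuals among
sites *within each species*, preserving every per-site sample size, then
recomputes frequencies, divergences and $r$. The test is one-tailed for
positive $r$ (divergence growing away from the focal site, i.e.
convergence toward it), with the add-one convention
$p = (1 + \#\{r^\ast \ge r_{\text{obs}}\})/(1 + B)$ so $p \ge 1/(B+1)$ and
never 0. Under the null the individuals are exchangeable within species, so
the test is exact; the package verifies a 5% type-I error rate by
simulation. $B$ defaults to 9999.

Climate covariates (July–October precipitation, July high and January low
temperature) are user-supplied columns of the site table; their association
with the mean divergence is a plain Pearson correlation across paired
sites. Mantel and partial Mantel tests (Pearson form, label permutations of
the first matrix, add-one one-tailed p) relate Nei distances to geographic
distance and binary species identity; the partial form correlates the
residuals of both matrices on the conditioning matrix and permutes the
residual matrix of the first. When the conditioning matrix explains the
second matrix exactly the partial correlation is reported as 0.

# Distances, trees and bootstrap

Nei's (1972) standard distance is
$D = -\ln\left(\bar J_{xy} / \sqrt{\bar J_x \bar J_y}\right)$ with the
$\bar J$ arithmetic means over loci of $\sum_a p_A p_B$, $\sum_a p_A^2$,
$\sum_a p_B^2$; loci unscored in either population are deleted pairwise
(mirroring real surveys where one population may lack a locus or two), and
$D = +\infty$ when the mean cross-identity is zero. The neighbor-joining
implementation fixes two conventions for determinism: Q-matrix ties break
toward the lowest (row, column) pair, and a negative branch-length estimate
is clamped to zero with the excess moved to its sister so path lengths are
preserved; additive matrices are recovered exactly. Bootstrap supports
resample *loci* with replacement (the natural unit when loci are few and
individuals many), recompute distances and the tree, and report the
fraction of replicates containing each original bipartition; replicates
producing non-finite distances are dropped and counted, with a warning past
1%.

# Private alleles

An allele is private to a taxon when observed (frequency > 0) in at least
one of its populations and in none of the other taxon's — presence/absence
with no minimum-frequency filter. The report also tallies alleles by the
number of carrier populations $k$; alleles with $k = 2$ are checked for
whether their two carriers form a designated sympatric cross-taxon pair, a
fingerprint of very local introgression. Whether the count of such
sympatric sharings is low is judged against a null expectation; the package
implements the simple printed form with denominator $n(n-1)$ (ordered
pairs), the combinatorially consistent $\binom{n}{2}$ form (exactly twice
the former — the two are both reported so the discrepancy is visible), and
a Monte Carlo placement null that converges to the combinatorial value. The
taxon imbalance in private-allele counts is tested by a df-1 goodness-of-fit
$\chi^2$ against an equal split.

# The synthetic-data generator

`sim_config()` defaults encode the emulated study design: 2 taxa × 9 paired
sites on a ~320 km linear transect (40 km spacing, both members of a pair
co-located), 19 loci on 5 linkage groups, 8 ancestral alleles per locus, 30
diploids per population, 2% missing calls.

Divergence follows the Balding–Nichols model: ancestral frequencies
$p \sim \text{Dirichlet}(1,\dots,1)$ per locus, taxon frequencies
$\sim \text{Dirichlet}(p(1-F)/F)$ independently per taxon with $F = 0.15$ —
strong differentiation that nonetheless leaves no fixed differences, the
regime the analysis is designed for. The realized between-taxon FST
(Hudson ratio-of-averages form) matches $F$ closely, which the tests verify
over replicates.

A fraction 7/19 of loci carry an introgression cline, applied to taxon A
only (the introduced-like taxon, matching the asymmetric-introgression
hypothesis): site frequencies are $(1-\alpha_s)p_A + \alpha_s p_B$ with
$\alpha_s = \alpha_{\max} e^{-d_s/\lambda}$, $d_s$ the distance to the focal
site, $\alpha_{\max} = 0.4$. The decay length $\lambda$ is set to 150 km so
that mixing falls from 0.4 at the focal site to ~0.05 at the far end of the
transect — a visible but not caricatured cline at the transect's scale.
Hybrid individuals are injected per taxon sample at the roughly observed
study rates (F1 at 1.5% of the taxon-A sample, migrants at 0.3% of taxon
B's, backcrosses off by default): F1s take one gamete from each taxon's
site-level frequencies, migrants are pure draws from the opposite taxon
labelled with the natal host, backcrosses use the classifier's own gamete
model. `exact_counts = TRUE` plants `round(rate * N)` individuals
deterministically, which is how the study's 4-of-278 arithmetic is
reproduced exactly in tests.

What the generator does **not** emulate: stepwise microsatellite mutation
(alleles are exchangeable labels, so size homoplasy and allele-length
constraints are absent), linkage between loci, site-level drift unless
`site_drift > 0` is set, null alleles, and temporal structure of the
invasion. Passing tests therefore demonstrate correctness of the estimators
under the model's assumptions — HWE within classes, independent loci,
known references — not robustness to those real-data complications.

# Numerical and design choices

- **Inbreeding coefficient:** $f = 1 - H_o/H_e$ with the unbiased
  $H_e = \frac{2n}{2n-1}(1 - \sum p^2)$, reported missing at monomorphic
  loci and excluded from the across-locus mean. The Weir–Cockerham
  variance-component $F_{IS}$ is deliberately not implemented; users
  comparing to it should expect small differences at small $n$.
- **Frequency difference statistic:** total-variation distance was chosen
  because it is bounded, metric, and insensitive to how the allele
  spectrum is partitioned; published "allele frequency difference"
  statistics are often left undefined, so per-locus $r$ values from other
  software are not directly comparable.
- **Permutation conventions:** add-one p-values everywhere; seeds are
  explicit arguments; all permutations preserve group sizes.
- **Problem sizes in the test suite** (the package's own choice of
  desk-scale validation): type-I calibration with 500 null replicates of a
  reduced design (5 loci, 15 per population, 99 permutations); power at the
  default cline with 40 replicates of the full design and 999 permutations,
  asserted at the nominal 80% minus the binomial Monte Carlo margin;
  FST calibration over 200 frequency replicates; classifier recovery at the
  study's n = 278 with leave-one-out. Per-locus power at desk scale is low
  (~50% for a single introgressed locus over 9 sites), so power is asserted
  for the across-loci statistic, the analysis's headline test.
- **Degenerate inputs:** zero-variance variables yield `NA` correlations
  rather than errors; populations unscored at a locus are flagged empty,
  never zero-filled; individuals with no scored locus are reported
  unclassified rather than dropped silently.

# Known limitations

- The classifier conditions on point-estimated reference frequencies;
  posterior probabilities are slightly overconfident relative to a full
  hierarchical treatment, most visibly with references under ~20
  individuals.
- Rates are computed from argmax calls, so a sample with many borderline
  posteriors can bias rates downward; inspect the posterior table when the
  F1 column mass is spread.
- The bootstrap resamples loci only; with 19 loci the support resolution is
  coarse and supports near 1 should be read as "all replicates", not as a
  probability with two-digit precision.
- Genepop encoding caps allele labels at 999 (three digits); longer
  fragment lengths must round-trip through the STRUCTURE-format writer.
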