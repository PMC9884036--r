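---
title: "Dual-marker population genetics for island archipelagos: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-marker population genetics: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(archipop)
```

# Scope

`archipop` implements the complete analysis a conservation geneticist runs
on a species sampled across an island archipelago with two marker systems:
a maternally inherited mitochondrial sequence (here a 657-bp COI fragment)
and a panel of nuclear microsatellites. The motivating system is an
endangered island bat sampled on four islands at very uneven sizes
(roughly 131/102/49/16 individuals), but every routine is generic over
demes, loci and sample sizes. The stages are: sequence and microsatellite
diversity, equilibrium testing and marker QC, F-statistics and AMOVA,
multivariate ordination, isolation by distance, sex-biased dispersal,
contemporary and long-term effective population size, and bottleneck
inference. A forward-time island-model simulator with known truth stands
in for the original samples, so every estimator is validated by parameter
recovery rather than by fiat.

# Sequence statistics

Diversity follows the classical summaries. For $n$ sequences with $S$
segregating sites, haplotype frequencies $p_i$ and mean pairwise
difference $\pi_{seq}$:

* $H_d = \frac{n}{n-1}\left(1-\sum p_i^2\right)$, with Nei's sampling
  variance for the reported standard deviation;
* $\pi$ per site uses the unbiased $\binom{n}{2}$ pairwise denominator;
* Watterson's $\hat\theta_{seq} = S/a_1$, $a_1 = \sum_{i=1}^{n-1} 1/i$,
  and $\hat\theta_{site} = \hat\theta_{seq}/L$.

**Complete deletion.** Any site carrying a gap, `N`, or an IUPAC ambiguity
code in any sequence is removed before computing $S$, $\pi$ and $\theta$,
and the effective length is reported. This matches the defaults of the
standard sequence-analysis software in this field and is the main reason
published per-site and per-sequence values can disagree with naive
recomputation from printed $n$ and $S$.

**Heteroplasmy screening.** Sequences containing ambiguity codes are
flagged as heteroplasmy candidates. They are excluded from network
construction by default but both inclusion modes are exposed, because
published practice varies and the choice visibly changes network topology.

Tajima's $D$ is evaluated from $(n, S, \pi_{seq})$ with the standard
constants; its sign always equals the sign of $\pi - S/a_1$, which the
test suite asserts as an invariant. Fu's $F_s$ uses the Ewens sampling
distribution of the number of alleles, computed from unsigned Stirling
numbers of the first kind in log space with $\theta$ set to $\pi_{seq}$:
$S' = P(K \ge k_{obs})$ and $F_s = \ln(S'/(1-S'))$. The Stirling-number
route is exact and is cross-checked in the tests against brute-force
enumeration of permutation cycles.

The haplotype network is a tie-retaining minimum spanning network over
pairwise difference counts. Edges are admitted in increasing step order;
within a step class, every edge joining two components as they stood when
the class opened is kept, so all tied alternatives appear. The exact
cascade-joining of the classical statistical-parsimony implementation is
deliberately not replicated: at the divergences involved here the MSN
topology is equivalent, and the cascade adds only tie-breaking detail.
The 95% connection limit uses a uniform-mutation multiple-hit
("birthday") model: $j$ mutations on $L$ sites are all distinct with
probability $\prod_{i<j}(1-i/L)$, and the limit is the largest $j$ keeping
this at or above 0.95 (8 steps at $L = 657$). Deep inter-clade edges are
flagged, not removed.

# Microsatellite statistics

Observed heterozygosity, Nei's unbiased expected heterozygosity
$H_e = \frac{2n}{2n-1}(1-\sum p^2)$, gene diversity and
$F_{IS} = 1 - H_o/H_e$ are computed per locus and group with pairwise
deletion of missing genotypes. Hardy-Weinberg testing uses the
heterozygote count as statistic under the conditional (Levene)
distribution given allele counts: exact enumeration for biallelic loci,
seeded Monte-Carlo reshuffling of gene copies otherwise, with a
probability-ordering two-sided p-value. Genotypic linkage disequilibrium
uses the likelihood-ratio $G$ statistic on the joint two-locus genotype
table with permutation of one locus across individuals. Null alleles are
screened with the two standard homozygote-excess moment estimators
(Chakraborty; Brookfield eq. 1), floored at zero.

Rarefied allelic richness uses exact hypergeometric rarefaction at $g$
gene copies, $E[A] = \sum_a (1 - \binom{N-N_a}{g}/\binom{N}{g})$; private
richness multiplies each allele's presence probability by its absence
probability in every other group's independent rarefied draw. The default
$g = 32$ corresponds to the smallest island sample (16 diploids). For
$N \le 12$ the implementation is tested against exhaustive enumeration of
all $\binom{N}{g}$ subsamples.

# Structure and isolation by distance

Global and pairwise $F$-statistics are Weir & Cockerham (1984) variance
components, accumulated per allele per locus and combined as
ratio-of-sums; confidence intervals bootstrap over loci (1000 replicates).
Mitochondrial pairwise structure uses $\Phi_{ST}$ from the two-level
AMOVA over pairwise difference counts; significance for both markers is by
permutation of sample labels. The ENA null-allele correction first fits,
per locus and group, an EM model in which observed homozygote classes are
mixtures of true homozygotes and null heterozygotes (untyped individuals
count as null homozygotes, the standard assumption of this estimator
family), then recomputes pairwise $F_{ST}$ from the unconditional
corrected visible-allele frequencies with the null size class excluded
from the allele sums. Renormalizing the visible frequencies instead would
re-inflate the between-group variance by $1/(1-p_{null})^2$ and undo the
correction; simulations in the test suite confirm the corrected estimate
falls between the naive and null-free values.

AMOVA follows the squared-distance formulation: two levels for sequences,
three levels over gene copies for diploid genotypes (allele non-identity
per locus by default; squared repeat-unit difference exposed as an
$R_{ST}$-style alternative - which distance the original analyses used is
not documented, so identity is the default). Negative variance components
are reported as estimated; percentages are also given after truncation at
zero.

PCA operates on 0/1/2 allele-dosage columns, column-centered, missing
values mean-imputed (ordination only; estimators never impute). DAPC is
linear discriminant analysis on the leading principal components; the
retained-PC default is the smallest number explaining 80% of variance,
a choice the original study leaves unstated.

Isolation by distance is tested two ways: a one-sided Mantel test between
Edwards' chord distance and great-circle distance across collection sites
(minimum 2 samples per site by default; the original used 59 sites without
stating a minimum), and OLS regression of $F_{ST}/(1-F_{ST})$ on
$\ln(\mathrm{km})$ with a locus-bootstrap CI for the slope.

# Sex-biased dispersal

The corrected assignment index AIc of each individual is the log10
Hardy-Weinberg likelihood of its multilocus genotype in its own group,
computed with leave-one-out allele frequencies and centered to group mean
zero - so AIc sums to zero within every group by construction, an
identity asserted to $10^{-9}$ in the tests. Alleles unseen in the rest
of the group receive pseudo-frequency $1/(2n_g+1)$; the reference
implementation in the field does not document its zero-frequency
correction, so this explicit choice is stated here. The test suite
reports, per sex: mAIc, vAIc, Weir-Cockerham $F_{ST}$ and $F_{IS}$,
group-referenced Queller-Goodnight relatedness over within-group dyads,
$H_o$ and $H_s$. One-sided p-values come from randomizing sex labels
within groups, oriented a priori toward the dispersing-sex signature
(lower mAIc, higher vAIc, lower $F_{ST}$, higher $F_{IS}$, lower
relatedness, higher $H_s$). Under sex permutation the AIc values
themselves are fixed, so the assignment-index tests are cheap; the
frequency-based metrics are recomputed per randomization and capped at
1000 randomizations by default.

# Effective population size

**Contemporary (LD method).** Burrows composite disequilibrium
correlations between allele dosages at locus pairs, $n/(n-1)$-corrected,
screened at minor-allele frequency 0.05, averaged within locus pairs and
combined with sample-size weights. The no-drift sampling expectation is
subtracted before inverting to Ne, and because Ne is extremely sensitive
to this term (at $S = 50$ a shift of 0.001 in mean $r^2$ moves a true
Ne of 100 by tens of percent), the expectation must match the exact
$r^2$ construction used. For the dosage-correlation form implemented
here the null expectation, calibrated on simulations of unlinked loci at
Hardy-Weinberg proportions across $S$ = 20-80, is
$1/(S-1) + 1.1/S^2$ ($S$ the weighted harmonic-mean sample size); this
plays the role of the published $1/S + 3.19/S^2$ coefficient set, which
was fitted by the same route to a slightly different $r^2$. Ne then
follows from the random-mating quadratic ($n > 29$ coefficient set);
non-positive drift signal reports infinity, the standard convention. CIs: jackknife over locus pairs, and parametric
chi-square with degrees of freedom equal to the number of allele
comparisons. Parameter recovery (true $N_e = 100$, $n = 50$, 18 loci)
returns a median estimate within [70, 140] over 50 replicates in the
acceptance suite.

**Long-term.** From mean expected heterozygosity under mutation-drift
equilibrium: $N_e^{SMM} = ((1/(1-H))^2-1)/(8\mu)$ and
$N_e^{IAM} = H/(4\mu(1-H))$, bracketed at $\mu = 10^{-3}$ and $10^{-5}$;
the SMM inversion is exact and tested. The maternal long-term female size
inverts $\theta = 2 N_{ef} u$ with the two literature substitution rates
($8.061\times10^{-6}$ and $1.089\times10^{-4}$ per sequence per
generation).

# Bottleneck inference

The modified Garza-Williamson M-ratio converts allele sizes to repeat
units via each locus's motif length: $M = k/(r+1)$ with $k$ occupied size
classes and $r$ the unit range; monomorphic loci carry no range
information and are excluded by default. The critical value $M_c$ is
simulated: per locus a Kingman coalescent genealogy of $n$ gene copies,
Poisson mutations at rate $\theta/2$ per unit branch length, each a
one-unit step with probability 0.8 or a geometric multi-step (conditioned
$\ge 2$, mean 3.5 units); $M_c$ is the 5th percentile of replicate mean
$M$. **Each simulated locus is conditioned on polymorphism** (redrawn
until at least two size classes), mirroring the empirical $M$ being taken
over observed polymorphic loci. This conditioning is what reproduces both
published anchor behaviors - $M_c \approx 0.80$ in the $\theta \to 0$
limit and $M_c \approx 0.58$ at $\theta = 10$ with 32 genes and 15 loci -
whereas including monomorphic loci drives $M_c$ to ~1 at small $\theta$.
The geometric multi-step is conditioned to $\ge 2$ units per the
two-phase convention; the source description is silent on this point.

# The synthetic-data generator

The generator is a discrete-generation, individual-based Wright-Fisher
island model with balanced sexes, chosen over a coalescent so that
sex-biased migration, bottlenecks and maternal mitochondrial transmission
co-segregate in one model (a coalescent oracle is used only to calibrate
the neutrality tests). Migration is individual natal dispersal: each
offspring is assigned a sex first and then, with the sex-specific
probability, occupies a slot in a different deme while carrying its full
natal genotype. This matters for the sex-biased dispersal tests - under
the gametic alternative (drawing single parents across demes) foreign
alleles never attach to individuals of the dispersing sex and the
assignment-index signature vanishes by construction. Defaults emulate the
study conditions:

* 4 demes of 250 diploids; per-pair migration 0.004 per generation
  (total emigration 0.012, $Nm = 3$), placing equilibrium pairwise
  $F_{ST} \approx 1/(1+4Nm) \approx 0.077$, inside the observed
  0.05-0.10 band;
* samples of 131/102/49/16 with a 60:40 male:female ratio;
* 18 dinucleotide loci under the two-phase model
  ($\mu = 10^{-3}$, $p_{multistep} = 0.2$, mean step 3.5), initialized
  from an 8-allele ladder (or a coalescent equilibrium draw when
  requested); the sampled allele-count spectrum overlaps the observed
  2-24 alleles per locus;
* a 657-bp maternal marker at $2\times10^{-6}$ per site per generation,
  seeded with two founder clades 18 substitutions apart (deme 1 nearly
  fixed for one, deme 2 for the other), mirroring the observed deep
  mitochondrial split;
* collection sites jittered around island centroids spanning ~500 km,
  with offspring inheriting their mother's site with probability 0.5
  (a weak within-island spatial signal for the site-level IBD tests);
* burn-in of 10 x the largest deme size (2500 generations at defaults),
  enough to approach migration-drift equilibrium at these sizes.

Sex-specific migration multiplies the male rate by
`sex_migration_multiplier` and scales both rates so their mean matches
the nominal rate. Same seed gives byte-identical output; the RNG state of
the caller is restored afterwards, so embedding the generator in a larger
seeded workflow does not shift other draws.

What the generator does *not* emulate: overlapping generations and age
structure (a known caveat of the LD-Ne method for long-lived species),
selection, mutation-rate heterogeneity across loci beyond the shared
two-phase model, genotyping error and allele dropout, and temporal
structure in sampling years (years are drawn uniformly). Passing tests on
synthetic data therefore validate the estimators under the stated model,
not robustness to these real-data complications.

# Problem sizes, determinism and numerics

Simulation-based tests are sized to stay informative while keeping the
full suite quick: calibration checks use 500 null replicates (the 95%
binomial band around a 5% level is then 3.1-6.9%), parameter-recovery
checks use 25-50 replicates, and the critical-M acceptance run uses 2000
replicates. One master seed expands into per-stage substreams via a
stable string hash, so toggling one analysis stage never shifts another
stage's draws, and every permutation procedure is reproducible from its
seed. Permutation p-values use the $(x+1)/(N+1)$ convention. Degenerate
inputs follow explicit conventions rather than NaN: monomorphic loci give
HWE and LD p = 1 and are excluded from M-ratio means; pairs with no
variation give an undefined (NA) pairwise $F_{ST}$; a non-positive LD
drift signal gives an infinite Ne, serialized as `"inf"` in text output;
AMOVA variance components may be negative and are reported both raw and
truncated.

# Known limitations

* The LD-Ne jackknife is over locus pairs, which are not independent;
  the parametric chi-square CI shares the usual anti-conservatism of
  treating allele comparisons as independent degrees of freedom.
* The ENA correction assumes within-group Hardy-Weinberg equilibrium
  apart from the null allele, and treats all missing genotypes as null
  homozygotes; technical dropout inflates its null-frequency estimates.
* The statistical-parsimony limit uses an idealized uniform-mutation
  model; it is a flagging heuristic, not a probability statement about
  the true genealogy.
* Tests of sex-biased dispersal have limited power when dispersal is
  rare; the simulation-based power checks use a 10:1 rate ratio at
  moderate overall migration, where the assignment-index tests are
  expected to respond.
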