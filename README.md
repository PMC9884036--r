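# archipop

Dual-marker population genetics for island archipelagos.

`archipop` implements, as one tested R package, the complete analysis a
conservation geneticist runs on a species sampled across an island chain
with two marker systems: a maternally inherited mitochondrial sequence
(e.g., a 657-bp COI fragment) and a panel of nuclear microsatellites. The
motivating system is an endangered island bat sampled on four Hawaiian
islands at very uneven sizes, but every routine is generic over demes,
loci and samples. It is aimed at researchers who need the classical
dual-marker toolkit - diversity, structure, dispersal, effective size,
bottlenecks - in one scriptable, reproducible place, with every estimator
validated against simulations with known truth.

## What it computes

**Sequence marker** - haplotype diversity Hd = n(1 - Σp²)/(n-1),
nucleotide diversity π, Watterson's θ̂ = S/a₁ (per site and per
sequence), within/between-group divergence Dxy, Tajima's D, Fu's Fs via
the Ewens sampling distribution (exact Stirling-number computation),
tie-retaining minimum-spanning haplotype networks with a 95%
statistical-parsimony step limit, and heteroplasmy screening.

**Microsatellites** - Ho, Nei's unbiased He, Fis; exact/Monte-Carlo
Hardy-Weinberg tests (Levene's conditional distribution); genotypic LD
G-tests; null-allele estimators; hypergeometric rarefied allelic and
private richness; Weir-Cockerham F-statistics (a, b, c variance
components, ratio-of-sums over loci, locus bootstrap CIs); ENA
null-allele-corrected Fst (EM over homozygote classes); AMOVA (two-level
for sequences, three-level over gene copies for diploids); PCA and DAPC
on allele dosages; Mantel and Fst/(1-Fst) ~ ln(km) isolation-by-distance
tests; sex-biased dispersal via corrected assignment indices (mAIc,
vAIc) and per-sex Fst/Fis/relatedness/Ho/Hs with one-sided
randomization; LD effective population size (Burrows composite r²,
Waples bias correction, jackknife and parametric CIs); long-term Ne
under SMM, Ne = ((1/(1-H))² - 1)/(8μ), and IAM, Ne = H/(4μ(1-H));
maternal Ne from θ = 2Nu; and the modified Garza-Williamson M-ratio
M = k/(r+1) with coalescent critical-M simulation under the two-phase
mutation model.

**Simulator** - a forward-time Wright-Fisher island model with balanced
sexes, individual sex-specific natal dispersal, two-phase microsatellite
mutation, maternal sequence transmission with two founder clades,
optional bottlenecks, and collection-site geography; same seed, same
dataset, byte for byte.

## A worked example

```r
library(archipop)

cfg <- sim_config(deme_sizes = rep(120, 4),
                  sample_sizes = c(50, 40, 30, 16),
                  sites_per_deme = c(4, 4, 3, 2), seed = 7)
sim <- simulate_dataset(cfg)
validate_dataset(sim$genotypes, sim$alignment, sim$metadata)
#> metadata: 136 samples, 4 demes, sexes F=54 M=82
#> genotypes: 136 samples x 18 loci, alleles/locus 3-8, 100.0% complete
#> mtDNA: 136 sequences x 657 bp, 0 with ambiguity codes

wc_f_statistics(sim$genotypes, sim$partition, seed = 7)$estimates
#>   Fis   Fst   Fit
#> 0.003 0.095 0.098

ld_ne_estimate(sim$genotypes, sim$partition, "demeA")
#> LD-Ne (demeA): 196 (jackknife 95% CI 83-inf, parametric 99-1568;
#>                S=50.0, 153 locus pairs)

m_ratio(sim$genotypes, sim$partition, "demeD")
#> M-ratio (demeD): 0.667 +/- 0.227 over 17 polymorphic loci

critical_m(32, 18, c(1, 10), reps = 500, seed = 7)[, 1:2]
#>   theta    Mc
#> 1     1 0.724
#> 2    10 0.582
```

Reading the output: the global multilocus Fst of 0.095 sits near the
island-model expectation for these deme sizes and migration rates
(truth is carried in `sim$truth`); the contemporary LD-Ne point estimate
of 196 for a deme of true size 120 has, as usual for this estimator, a
wide upper tail (the jackknife interval reaches infinity); and the
smallest deme's M-ratio of 0.667 sits just above the simulated critical
value 0.582 at θ = 10 - no bottleneck signal, as expected for an
equilibrium simulation.

## The analysis workflow

The `analysis/` directory holds the study pipeline as numbered thin
drivers over the package functions; each writes its tables under
`results/`:

```sh
Rscript analysis/01_simulate.R 1       # synthetic four-island study
Rscript analysis/02_diversity.R 1      # Hd, pi, theta, Dxy, richness
Rscript analysis/03_structure_ibd.R 1  # Fst, ENA, AMOVA, PCA/DAPC, IBD
Rscript analysis/04_dispersal.R 1      # sex-biased dispersal suite
Rscript analysis/05_effective_size.R 1 # LD-Ne, SMM/IAM Ne, maternal Ne
Rscript analysis/06_bottlenecks.R 1    # M-ratio vs critical M, D, Fs
```

The trailing integer is the master seed; every stage derives its own
substream from it. `run_pipeline()` performs the same stages in one call
with stage isolation and a run log.

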