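# trdtrio

Bayesian genome scans for **transmission ratio distortion (TRD)** in
parent–offspring trios, built for the half-sib family structure of
dairy-cattle genotype databases (one bull, many one-offspring dams) and for
hunting recessive lethal alleles.

TRD is a departure of offspring allele/genotype frequencies from Mendelian
expectation given the parental genotypes. `trdtrio` fits three models to the
offspring-genotype counts of the five informative mating types at each locus:

* **allelic, parent-unspecific** — a heterozygous parent transmits allele A
  with probability 0.5 + α, flat prior on α ∈ [−0.5, 0.5];
* **allelic, parent-specific** — separate sire and dam effects α_s, α_d;
* **genotypic** — additive + dominance distortion of the offspring genotype:
  from AB×AB, P(AA, AB, BB) = ((1+α_g−δ_g)/4, (1+δ_g)/2, (1−α_g−δ_g)/4),
  renormalized in het×hom matings; flat prior on the probability simplex
  δ_g ≤ 1 − |α_g|. A complete recessive lethal (of AA) is the boundary point
  (α_g, δ_g) = (−2/3, +1/3).

Inference is deterministic grid quadrature (reference) or adaptive Metropolis
MCMC. Significance is the Bayes factor against the point Mendelian null
(BF ≥ 100 decisive; equals the Savage–Dickey ratio under the flat prior),
model choice is DIC with a 3-unit parsimony rule, and selected fits are
labelled (overall/sire/dam/sire+dam TRD, recessive, heterosis
excess/deficiency, homozygote advantage/disadvantage). The pipeline adds
sliding-window biallelic haplotype recoding (each haplotype allele H_j vs the
pooled rest H_−j), a four-stage filtering ledger (informative parents,
fully-skewed-sire robustness, empirical-null exceedance at 10⁻⁵, posterior
CV ≤ 20%), best-BF deduplication, Gaussian-kernel smoothing of BF along the
genome (σ = 500 kb / 2 Mb / 5 Mb) and core-region extraction with
significance spans of ±980 kb / ±1.29 Mb / ±1.645 Mb (95/99/99.9% at
σ = 500 kb). A gene-drop simulator with planted distortion mechanisms
(`sim_trios()`, `make_fixture()`) generates validation data with known truth.

## Worked example: recovering a recessive lethal

Simulate a half-sib cohort (300 sires × 200 offspring) segregating a
complete recessive lethal at ~3% carrier frequency, and fit the genotypic
model at the planted locus:

```r
library(trdtrio)

sim <- sim_trios(sim_config(
  n_sires = 300, offspring_per_sire = 200, n_chrom = 1, snps_per_chrom = 3,
  freq_b = 0.97,   # lethal allele A segregates at ~3%
  loci = list(list(chrom = 1, snp = 2, mechanism = "recessive_lethal")),
  seed = 1))

trios  <- assemble_trios(sim$gt, sim$ped, "c1_s2")
counts <- tabulate_matings(trios)
counts
#> mating_counts: 6766 informative offspring; 17 het sires, 3546 het dams
#>       AA   AB   BB
#> ABxAA  0    1    0
#> ABxBB  0 1581 1638
#> AAxAB  0    0    0
#> BBxAB  0 1684 1682
#> ABxAB  0  128   52

fit <- grid_fit(counts, "genotypic", resolution = 1001)
posterior_summary(fit)
#>     param       mean         sd median  lower  upper         cv
#> 1 alpha_g -0.6582296 0.01792012 -0.660 -0.686 -0.616 0.02722473
#> 2 delta_g  0.3212386 0.01293283  0.322  0.294  0.344 0.04025925

bayes_factor(counts, fit)
#> [1] 1.417383e+19
classify_pattern("genotypic", posterior_summary(fit))
#> [1] "recessive"
```

Reading the output: no AA offspring survive anywhere; the het×hom matings
stay Mendelian (≈1:1) while AB×AB offspring split ≈2:1 AB:BB — the
classical recessive signature. The posterior means land on the
complete-lethality point (−2/3, +1/3) and the Bayes factor is decisive.
`missing_homozygotes(counts, -0.66)` estimates `round(180/4) − 0 = 45`
non-observed homozygous offspring from carrier×carrier matings.

The full pipeline on a synthetic genome lives in `analysis/`:
`01_simulate.R` (planted three-signal cohort) → `02_scan.R` (SNP-by-SNP
scan) → `03_filter.R` (null table + filtering ledger) → `04_integrate.R`
(dedup, smoothing, core-region BED/bedGraph) → `05_window_demo.R`
(haplotype-window scan of a planted lethal haplotype). Each script prints
what it found and writes tables under `results/`.

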