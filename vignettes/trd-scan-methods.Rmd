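---
title: "Detecting transmission ratio distortion in half-sib trio data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting transmission ratio distortion in half-sib trio data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trdtrio)
```

## The problem

Transmission ratio distortion (TRD) is a departure of offspring allele or
genotype frequencies from Mendelian expectation given the parental
genotypes. In livestock, persistent TRD at a locus is a strong signal of a
deleterious or lethal allele: carrier-by-carrier matings produce fewer (or
no) homozygous offspring, and distorted transmission from carriers depresses
fertility. Dairy-cattle populations are ideal for scanning for such loci —
genotyped parent–offspring trios number in the hundreds of thousands,
structured in very large paternal half-sib families (one bull, many
one-offspring dams).

`trdtrio` implements a Bayesian TRD genome scan for such data: model fitting
per SNP or per haplotype window, Bayes-factor significance, model choice and
inheritance-pattern labelling, quality filters, and kernel-smoothed
integration into core regions. A gene-drop simulator with known planted
mechanisms makes every stage testable without access-restricted industry
data.

## Models

The unit of observation is the trio (sire, dam, offspring) at one biallelic
locus. Only matings with at least one heterozygous parent are informative;
the data per locus are offspring-genotype counts cross-classified by the
five informative mating types (AB×AA, AB×BB, AA×AB, BB×AB, AB×AB, sire
listed first), with a multinomial likelihood per mating.

**Allelic (gametic) models.** A heterozygous parent transmits allele A with
probability 0.5 + α. The parent-unspecific model uses one α for both
parents; the parent-specific model splits it into a sire effect α~s~ and a
dam effect α~d~. All allelic parameters have flat priors on [−0.5, 0.5].
For AB×AB matings the two transmissions are independent, so e.g.
P(offspring AA) = (0.5 + α~s~)(0.5 + α~d~).

**Genotypic (zygotic) model.** Distortion acts on the offspring genotype
after fertilization, with an additive parameter α~g~ and a dominance
parameter δ~g~. From AB×AB the offspring probabilities are
(1 + α~g~ − δ~g~)/4, (1 + δ~g~)/2 and (1 − α~g~ − δ~g~)/4 for AA, AB, BB.
In heterozygous-by-homozygous matings only two genotypes are possible and
the same quantities are renormalized for the overall loss of individuals
(division by 2(1 ± α~g~/2)). A complete recessive lethal (say of AA) is the
boundary point α~g~ = −2/3, δ~g~ = +1/3, at which P(AA) = 0 in every mating
while het×hom matings remain exactly Mendelian — which is why
carrier-by-carrier matings are indispensable for separating recessive
(genotypic) from allelic patterns.

**Parametric space of the genotypic model.** We take the admissible region
to be the probability simplex of the AB×AB kernel: α~g~ ∈ [−1, 1] and
δ~g~ ∈ [−1, 1 − |α~g~|], with a flat prior normalized over that region.
This is the minimal space in which every offspring probability lies in
[0, 1]; narrower published supports exclude parameter pairs (such as
α~g~ ≈ 0.05 with δ~g~ ≈ 0.25) that arise naturally under heterozygote
excess, so the simplex is the space this package uses throughout. Users
comparing against other TRD software should be aware of this choice.

## Inference

Every model is 1- or 2-dimensional, so the *reference* inference path is
deterministic grid quadrature: a regular grid per dimension (default 201
points; 1001 for reported estimates), trapezoid weights, flat prior
normalized numerically, exact posterior masses, and the marginal likelihood
by quadrature. An adaptive random-walk Metropolis sampler (defaults 110,000
iterations, 10,000 burn-in, proposals reflected at the box bounds and
rejected outside the genotypic simplex) reproduces the grid results within
Monte-Carlo error and is provided for protocol fidelity; the scan itself
uses the grid for speed and determinism.

**Significance.** The Bayes factor compares each TRD model with the point
Mendelian null: BF = m(y) / p(y | θ = 0). Under a flat prior this equals the
Savage–Dickey density ratio at the null point, which the package computes by
an independent route (local quadratic fit to the log posterior density near
the null) as a cross-check; the two agree to three significant digits at
grid resolution 1001. BF ≥ 100 ("decisive" on Jeffreys' scale) is the scan's
significance threshold.

**Model choice and patterns.** Models are compared by DIC
(Spiegelhalter's form, posterior-mean point estimate; multinomial constants
cancel in differences). Differences under 3 DIC units are not considered
relevant, and ties resolve toward the simpler model. The selected model is
labelled: overall-TRD; sire-TRD / dam-TRD / sire+dam-TRD by which 95%
credible intervals exclude zero; and for the genotypic model, *recessive*
when δ~g~ > 0 and the surviving fraction of the disadvantaged homozygote
(1 − |α~g~| − δ~g~) falls below 0.5, otherwise heterosis excess/deficiency
(|δ~g~| ≥ 0.10) or homozygote disadvantage/advantage (0 < |δ~g~| < 0.10).
The 0.5 lethality margin and 0.10 dominance split are configurable; the
defaults reproduce the canonical labels of all five reference parameter
pairs used in the tests.

These labels have intrinsically fuzzy boundaries. The credible-interval rule
carries the usual 5% per-parameter false-exclusion rate, and a locus where
both parents distort equally sits on the overall/sire+dam boundary: a finite
replicate *realizes* slightly different sire and dam transmission rates, and
with tens of thousands of offspring the parent-specific model can genuinely
fit that realization better. The validation suite therefore scores labels at
mechanism level (allelic vs genotypic channel, sire involvement, recessive),
while detection itself — core regions found, none invented — is scored
strictly.

## The filtering ledger

Scan records pass four independent screens, mirroring standard practice for
separating real TRD from genotyping artifacts and sampling noise:

1. **Informative parents** — at least 20 heterozygous sires and/or 100
   heterozygous dams.
2. **Sire robustness** — a decisive signal must survive removing, one at a
   time, each of the k (default 2) largest *fully-skewed* heterozygous-sire
   families (a het sire whose every unambiguous transmission is the same
   allele — the archetypal sample-mixup signature).
3. **Empirical null** — the estimate must exceed the chance-level TRD
   magnitude for its informative-offspring bin: thresholds are the smallest
   magnitudes with two-sided exceedance probability ≤ 10^−5^ ("< 0.001%
   margin error") under Mendelian sampling, simulated with 10^6^ replicates
   per bin. The allelic estimator is the transmission proportion
   k/n − 0.5; the genotypic thresholds use the moment estimators from
   AB×AB offspring (α̂~g~ = 2(p̂~AA~ − p̂~BB~), δ̂~g~ = 2p̂~AB~ − 1), since
   refitting a posterior per replicate is both unnecessary and prohibitive.
   At n = 20 the simulated allelic threshold equals exact binomial
   enumeration (0.5).
4. **Stability** — posterior coefficient of variation (sd/|mean|) of the
   selected model's primary parameter at most 20%.

## Integration

Overlapping records on a chromosome are collapsed to the highest-BF record
(ties: smaller interval, then leftmost). Bayes factors are then smoothed
along each chromosome with a Gaussian kernel,
ŷ~i~ = Σ~j~ (2πσ²)^−1/2^ exp(−(κ~i~ − κ~j~)²/(2σ²)) · BF~j~, with
bandwidths σ of 500 kb, 2 Mb or 5 Mb and record anchors at interval
midpoints. The track is rescaled by √(2πσ²) so an isolated record's peak
equals its BF (max-normalization is available by flag); this is the
definition of "rescaled smoothed BF" the package adopts, since
isolated-peak preservation makes the decisive threshold directly readable
off the track. Core regions are separated local maxima (two peaks merge
unless the valley between them drops below half the smaller peak), each with
a significance span of ± z·σ, where z is the two-sided normal quantile
rounded to two decimals — ±980,000 bp (95%), ±1,290,000 bp (99%) and
±1,645,000 bp (99.9%) at σ = 500 kb. The number of under-represented
(missing) offspring behind an allelic signal is n~informative~ × 2|α̂|; for
genotypic fits the shortfall of disadvantaged homozygotes from AB×AB
matings, round(n~AB×AB~/4) − observed, is reported as well.

## The gene-drop simulator

`sim_trios()` emulates the structure of the real data the method was built
for: paternal half-sib families (configurable sizes from tens to
thousands; each dam produces one offspring, matching dam counts ≈ offspring
counts in such data), biallelic SNPs at a regular spacing (default 50 kb, a
50K-array order of density), founder haplotypes drawn SNP-wise from
configured frequencies, within-chromosome recombination at 1 cM/Mb, phased
output, and optional genotyping error (flip to a random different code,
losing phase) and missingness. Planted mechanisms:

* **allelic(α~s~, α~d~)** — a heterozygous parent's transmitted focal
  allele is redrawn with P(A) = 0.5 + α;
* **genotypic(α~g~, δ~g~)** — the offspring's focal genotype is
  accept/reject sampled so survivors follow the genotypic kernel exactly;
  rejected zygotes are tallied as removed (non-viable) offspring in the
  truth table;
* **recessive_lethal** — shorthand for the complete-lethality point
  (−2/3, +1/3);
* any mechanism may sit on a multi-SNP carrier haplotype planted at a
  target founder frequency.

Because mechanisms are applied to the focal locus (or focal haplotype
segment) of the transmitted gametes only, flanking markers segregate
Mendelian-ly: the simulator deliberately does **not** emulate hitchhiking
of linked markers through within-family coupling, nor population LD between
founder SNPs (founder alleles are drawn independently). Passing tests
therefore demonstrate recovery of *localized* signals under realistic family
structure and sample sizes — not the LD-spread signal clusters real data
produce, which the dedup-and-smooth integration stage exists to handle. Real
ascertainment wrinkles (multi-density genotyping arrays, offspring
pre-selection) are likewise reduced to a global error/missingness rate.

## Numerical choices and problem sizes

* Grid resolution 201 per dimension in the scan, 1001 for headline
  estimates; quadrature masses sum to 1 within 10^−10^.
* Bayes factors beyond double range enter smoothing as 10^300^; on the log
  scale nothing is lost.
* The genotypic kernel clamps roundoff-negative probabilities (≥ −10^−12^)
  at the simplex boundary to zero.
* Validation problem sizes were chosen to exercise the method at realistic
  scale while staying desk-runnable: the planted-signal genome is 5
  chromosomes × 200 SNPs with 300 sires × 50 offspring (15,000 trios); the
  recessive-lethal recovery cohort has ~48,000 offspring yielding ≥ 5,000
  informative trios at 3% carrier frequency; null calibration uses 1,000
  loci of 1,000 informative offspring; empirical-null tables use 10^6^
  replicates per bin.
* Degenerate inputs are legal where the mathematics is: an all-zero count
  table has marginal likelihood 1 and BF 1 under every model; a cell with
  observations where a model puts probability zero gives log-likelihood
  −∞ and BF behaves accordingly.

## Known limitations

* Unphased input disables window mode (no on-the-fly phasing); imputation
  and phasing are upstream concerns.
* One-generation pedigrees only; no kinship correction, no X-chromosome
  matings, no per-family random-TRD models.
* The empirical-null moment estimators for the genotypic model ignore
  het×hom matings (which carry no information at the complete-lethality
  point anyway, but do constrain milder distortions).
* Manual curation of genotyping-error regions — unavoidable in real data —
  is replaced by the automated ledger plus the per-locus
  Mendelian-inconsistency tally.
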