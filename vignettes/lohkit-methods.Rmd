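---
title: "Methods: models, parameters and design choices in lohkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in lohkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lohkit)
```

lohkit analyses loss-of-heterozygosity (LOH) in heterozygous diploid
yeast: it phases heterozygous SNP markers from tetrad genotypes, maps a
recessive trait by strict co-segregation, estimates LOH rates from
fluctuation assays, resolves LOH clone genotypes into tracts and tests
their endpoint distributions, and calls copy number from droplet digital
PCR. This vignette documents the models behind each stage, the tunable
parameters, the numerical choices, and what the synthetic-data generator
does and does not emulate.

## Tetrad-based marker filtering and phasing

A candidate heterozygous site genotyped across four-spore tetrads is
retained as *high confidence* when it is biallelic and segregates its two
alleles exactly 2:2 in **every complete tetrad**. 2:2 segregation is the
Mendelian expectation for a true heterozygous site, so any complete
tetrad violating it (gene conversion, genotyping error, paralogous
mis-mapping) disqualifies the site. Tetrads with any missing spore call
are ignored, up to `max_missing_tetrads` (default **2** of 14); beyond
that the site is dropped as under-supported. This is a deliberately
conservative, self-contained definition: read-level quality and depth
filters operate upstream of this package's inputs, which begin at
per-spore allele calls.

Phasing uses greedy adjacent-marker linkage chaining. Across `T` tetrads
(4`T` spores), a crossover falls between two neighbouring markers in a
given meiosis only rarely, so the allele pairing under which
adjacent-marker alleles co-segregate in the majority of spores is taken
as the in-phase pairing; the agreement fraction is the adjacency's
confidence. An adjacency with agreement exactly 1/2 carries no
information — the chain is broken rather than guessed, and the downstream
marker starts a new phase block flagged `unphaseable`. Because
maternal/paternal labels are arbitrary, each block is canonicalized: the
lexicographically smaller allele of the block's first marker is assigned
to M. Canonicalization makes the output invariant under relabelling of
allele symbols and under a global allele swap, which the test suite
checks property-style.

With 14 tetrads and ~1 crossover per chromosome per meiosis, the
probability that a majority of 56 spores recombines between two adjacent
markers a few kb apart is negligible, which is why the greedy chain
recovers a planted phase at ≥99% of markers in the package's simulations.

## Carrier inference and the strict co-segregation scan

The trait model is a single recessive gene: a diploid shows the mutant
phenotype iff both haploid parents carry the recessive allele.
`infer_carriers()` applies the two sound deductions — any participant in
a mutant-phenotype cross is a carrier; a wild-type-phenotype cross with a
confirmed carrier confirms the partner as non-carrier — and leaves
everything else unknown. An all-wild-type matrix therefore identifies
nobody: one entire mating type could still carry the allele. Model
consistency is checked exactly against every tested cell and reported
with a witness cross rather than thrown as an error.

The scan criterion is strict: a marker passes only when one homolog's
allele is carried by *all* of group 1 and the other homolog's allele by
*all* of group 2, with at most `max_missing` missing calls (default
**0**; missing never counts as agreement). Passing runs are merged into
candidate regions reported **marker-to-marker** (first to last passing
marker); the midpoint-extended span is available behind
`extend_to_flanks = TRUE`. Marker-delimited spans are the defensible
default because the data constrain the causal locus only to the passing
markers themselves; the extension is an interpretation.

## Fluctuation analysis: Lea–Coulson method of the median

A fluctuation assay grows `C` parallel cultures to `N` cells and counts
mutants `r_i` per culture. Because a mutation early in growth produces a
jackpot of descendants, the mean of `r` is useless; the Lea–Coulson
method of the median solves

$$\frac{\tilde r}{m} - \ln m = 1.24$$

for `m`, the expected number of mutational events per culture, where
$\tilde r$ is the median mutant count. The left-hand side is strictly
decreasing in `m`, so `lc_median_m()` brackets the unique root and solves
it to a relative tolerance of 1e-9 (`stats::uniroot`). The rate is
$\mu = m / \bar N$ with $\bar N$ the **arithmetic mean** of per-culture
population sizes by default (`center = "median"` is available); the
arithmetic mean matches the behaviour of the widely used fluctuation
calculators this workflow mirrors.

The 95% confidence interval uses the empirical dispersion fit of the
FALCOR/Rosche–Foster lineage,

$$\hat\sigma_{\ln m} = 1.225\, m^{-0.315} / \sqrt{C},$$

with limits $e^{\ln m \pm 1.96\hat\sigma}/\bar N$.

**Known limitation.** That dispersion fit was calibrated by simulation
for moderate `m` (roughly 1.5–15). The package's own coverage check —
1,000 replicate experiments of 24 cultures simulated at the case study's
conditions ($\mu = 1.5\times10^{-5}$, $N = 5.75\times10^{7}$, hence
$m \approx 862$) — measures coverage far below the nominal 95% (roughly
half the replicates), for two compounding reasons: the symmetric
$1.96\hat\sigma$ interval underestimates the sampling spread of the
median estimator, and at large `m` the constant 1.24 in the median
equation is itself only approximate, biasing $\ln\hat m$ upward by a
fraction of $\hat\sigma$. The acceptance test reports this honestly
rather than widening the interval: the CI formula is part of the method
being reproduced, and published critiques of method-of-the-median
intervals reach the same conclusion. Point estimates are unaffected —
the estimator inverts the simulator's planted `m` within 10% across
`m` in [5, 2000].

Experiment comparisons use a two-sided Wilcoxon rank-sum test on
per-culture mutant **frequencies** `r_i/N_i` (exact for combined
n ≤ 20 without ties, normal approximation with tie correction
otherwise); raw counts are available via `on = "counts"`. Frequencies
are the natural per-culture quantity when `N_i` varies; the choice is a
documented flag because either convention appears in practice.

Rates are normalized per kilobase by dividing by the centromere-to-
cassette distance, reflecting the geometry of selected LOH: any
recombination initiating between the centromere and the selection marker
can produce the selected genotype. Coincident-event arithmetic multiplies
two independent rates and reports the nearest order of magnitude.

### The culture simulator

`simulate_cultures()` draws `K ~ Poisson(m)` mutational events per
culture and gives each event a clone of `floor(1/u)` mutant cells,
`u ~ Uniform(0,1]`, capped at `N` — the standard quick algorithm for the
Lea–Coulson distribution under deterministic growth. A stochastic-growth
variant (geometric clone sizes with mean `1/u`, i.e. Yule growth) is
available behind `growth = "stochastic"`. Rates with `mu > 0.1` are
rejected: the model assumes mutations are rare during growth. At the
case-study parameters the simulated median count reproduces the
analytic approximation $\tilde r \approx m(\ln m + 1.24)$ to ~2%.

## LOH tract calling and endpoint statistics

Clone genotypes over the phased map (`H`, `M`, `P`, missing) are
resolved per chromosome arm into maximal runs of same-direction
homozygosity. **Missing calls are transparent**: a genotyping gap inside
a run neither breaks it nor extends it, because PCR-RFLP dropouts should
not fabricate tract interruptions (`missing_breaks = TRUE` gives the
conservative alternative). Tract endpoints are midpoints between the
outermost homozygous marker and the adjacent informative marker — the
data cannot localize a breakpoint more finely than one inter-marker
interval, and on simulated clones the true breakpoint always lies inside
the called interval, so the midpoint errs by at most half the local
marker spacing. A run touching the arm's most distal marker is flagged
`reaches_last_marker`: nothing distinguishes a very long interstitial
event from one extending to the telomere.

Clones are classified `simple` (exactly one selected-arm tract, selected
direction, containing the selected marker) or `complex` (interruptions
or homozygosity opposite to selection); events on the other arm are
annotated `coincident`. Complex clones are excluded from endpoint
tallies by default, since their boundaries are not interpretable as
single-event endpoints.

Endpoint intervals are **half-open** `(left, right]` — an endpoint
exactly on a marker position belongs to the interval ending there — and
interval length is `right − left`. The size-model test compares observed
endpoint counts to expectations proportional to interval lengths,
$E_j = \Sigma O \cdot L_j / \Sigma L$, with
$\chi^2 = \Sigma (O_j - E_j)^2 / E_j$ on **J − 1 degrees of freedom**;
the homogeneity test is the 2×J contingency chi-square, also J − 1 df.
The df convention was validated by recovering both of the case study's
printed (χ², p) pairs — (18.51, 0.001) and (0.855, 0.93) at five
intervals — from the closed form. Expected counts below 5 trigger a
warning, not an error: small cohorts are the norm in this assay.

## ddPCR copy number

Template concentration per droplet follows the Poisson correction
$\lambda = -\ln(1 - \text{positives}/\text{total})$; a saturated plate is
an error. Copy number normalizes the target to the average of **two**
reference loci of known two-copy status divided by 2, making the call
invariant to template amount and droplet volume. The droplet volume
default (0.85 nL) is the instrument-typical constant and affects only
volumetric units. Unrounded CN is reported alongside a nearest-integer
call accepted within ±0.3 — at 20,000 droplets the sampling error of CN
is well under 5%, so the band separates 1 from 2 copies cleanly.

## The synthetic-data generator

The generator reproduces the *statistical structure* the analyses
assume, not sequence-level data:

* a diploid genome of heterozygous blocks interspersed with homozygous
  runs, markers placed Poisson-uniformly inside het blocks only;
* meioses with exact 2:2 segregation, Poisson crossovers with uniform
  positions (no interference — none of the tested properties depend on
  it), optional gene-conversion tracts, genotyping error and
  missingness;
* a recessive locus riding one homolog, the rough-iff-both-carriers
  cross rule, and 2:2 mating-type segregation;
* LOH clones from a mechanism mixture — terminal crossover/BIR tracts
  (breakpoint uniform or hotspot-weighted between centromere and
  selection), interstitial gene conversions (exponential lengths, mean
  20 kb), and point contractions — with the selection constraint
  satisfied by construction (default mixture 0.90/0.05/0.05, dominated
  by terminal events as observed in selected LOH cohorts);
* Luria–Delbrück cultures and Poisson droplet partitioning as above.

The default genome is intentionally small — **3 chromosomes × 500 kb,
one 150 kb heterozygous block each, 0.1 markers/kb** — so the full test
suite runs in seconds; `sim_genome_config_jay270()` scales to 16
yeast-like chromosomes and ~12,000 markers. Default assay conditions
follow the case study: 14 tetrads; twelve haploids (three tetrads) in
the cross matrix; fluctuation assays at $\mu = 1.5\times10^{-5}$,
$N = 5.75\times10^{7}$, 24 cultures; 20,000 droplets at λ = 0.5.

What the generator does **not** emulate: read-level artifacts (mapping
bias, depth variation), linked structural variation, crossover
interference, chromatid-level interference between the two spore pairs,
rDNA repeat dynamics, and fitness effects of the phenotypes. Passing
tests therefore demonstrate the correctness of the estimators and the
internal consistency of the pipeline on data satisfying its model
assumptions — not robustness to upstream artifacts real sequencing data
can carry.

## Problem sizes and reproducibility

All stochastic checks fix seeds. The package's own validation uses:
1,000 sites for filter/brute-force equivalence; ~100-marker chromosomes
× 14 tetrads for phasing recovery (3 seeds); 40 seeds for planted-locus
recovery by the scan; 10,000 cultures for simulator/estimator closure;
1,000 replicate experiments × 24 cultures for CI coverage; 100 clones
for endpoint containment; 20,000 droplets for ddPCR recovery. Every
simulation function accepts an explicit `seed`, and `run_pipeline()`
embeds the seed, a configuration hash and input checksums in every
result file; reruns with identical inputs are byte-identical.
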