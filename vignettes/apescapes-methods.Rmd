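---
title: "Correlated landscapes of diversity and divergence: models and methods"
author: "apescapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlated landscapes of diversity and divergence: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apescapes)
```

## The problem

Nucleotide diversity ($\pi$, mean pairwise differences per site within a
population) and absolute divergence ($d_{XY}$, mean pairwise differences per
site between two populations), computed in non-overlapping windows along a
chromosome, form *landscapes*. In a clade of closely related species such as
the great apes, these landscapes are strikingly correlated with one another —
often more strongly than diversity correlates with classic covariates like
exon density. Several processes can produce such correlations:

* **Incomplete lineage sorting (ILS).** Two populations that split $T$
  generations ago share ancestral variation; two samples from a population of
  diploid size $N_e$ coalesce before a split with probability
  $1 - e^{-T/(2N_e)}$ (`coalesceBeforeSplit()`), so correlations between
  landscapes should decay with the phylogenetic distance between them.
* **Shared mutation-rate variation.** If the map of local mutation rate is
  conserved, high-rate windows are high in every species, inducing
  correlations that *grow* with time as divergence accumulates.
* **GC-biased gene conversion (gBGC)** favouring strong (G/C) over weak
  (A/T) alleles, concentrated where recombination is high.
* **Linked selection** (background selection and sweeps) tied to the shared
  landscape of functional sites.

The package provides the full machinery to measure these correlations in
data, simulate the competing explanations at desk scale, and compare
simulations to data.

## Phylogenetic distance between statistics

Each landscape statistic maps to a node of the dated species tree: a
diversity to its tip, a divergence to the MRCA of its pair. `phyloDistance()`
returns the path length in generations between the two nodes ($d_T$); for a
diversity of population $W$ against a divergence whose MRCA is the deeper
node $VWXY$ this equals $2T_{VWXY} - T_{XY}$. Two divergences may share tree
branches *by definition* (their defining tip-to-tip paths intersect), in
which case $d_T$ is a poor proxy for their expected correlation;
`sharesBranches()` flags such pairs and `allPairwiseCorrelations()` can drop
them. The defining edge set of a divergence is operationalized here as the
branches on the tip-to-tip path through the MRCA, and that of a diversity as
its terminal branch; this is our concrete reading of a rule that is usually
stated qualitatively.

The default `greatApesTree()` encodes a ten-population panel with the
published sample sizes (human 9, bonobo 13, Nigeria–Cameroon chimpanzee 10,
eastern chimpanzee 6, central chimpanzee 4, western chimpanzee 4, eastern
gorilla 3, western gorilla 27, Sumatran orangutan 5, Bornean orangutan 5).
Split times use literature-standard dates (clade root 12 Mya, gorilla 8 Mya,
human–chimp 6 Mya, chimp–bonobo 2 Mya; 25-year generations). Two branch
sizes are fixed by published estimates — 125,089 diploids for the great-apes
ancestor and 7,672 for the human branch — and the intermediate sizes on the
human lineage interpolate geometrically between them; remaining tip sizes
are plausible defaults chosen once, satisfying the constraint that bonobos,
western chimpanzees and eastern gorillas fall below the low-$N_e$ threshold
of $8\times10^3$. Every value is configurable through `speciesTree()`.

## Windowed statistics

`windowedDiversity()` and `windowedDivergence()` work from an `AlleleTable`
(per-site alternate-allele counts `ac` and called-allele numbers `an` per
population, read from VCF by `readVcfAlleles()`). Per site,

$$\pi_{\text{site}} = \frac{ac\,(an-ac)}{\binom{an}{2}}, \qquad
  d_{XY,\text{site}} = \frac{ac_A(an_B-ac_B) + (an_A-ac_A)\,ac_B}{an_A\,an_B},$$

summed over sites in a window and divided by the number of jointly callable
sites. Key conventions, decided here because the choice is genuinely open:

* Masks are intersected across **all** populations before any statistic
  ("callable in all populations"); monomorphic callable sites enter
  denominators only.
* Diversity counts all allele pairs including the two alleles of one
  diploid individual (the standard unbiased estimator); statistics are
  computed on allele counts, so phased haplotypes and unphased genotypes
  are treated identically.
* Windows with a callable fraction strictly below the threshold are
  dropped (`applyWindowFilter()`; 0.40 for the main analyses, 0.05 for the
  site-class-partitioned divergences). A fraction exactly at the threshold
  is kept.

For gBGC analyses, `classifySiteType()` classifies a site from one
representative nucleotide per species: two observed states both weak (A/T)
or both strong (G/C) imply a W–W/S–S change; one weak and one strong state a
W–S change; three or more states imply multiple mutations and exclusion.
The representative allele is the species' majority allele at the site, with
ties excluding the site — the published rule classifies "by the 4 species"
without specifying how within-species polymorphism is collapsed, so this is
our operationalization. `polarizeByOutgroup()` implements the complementary
outgroup-polarization route, with sites lacking an outgroup allele excluded.

## Forward simulation with rescaling

`simulateForward()` is a diploid Wright–Fisher simulation of the species
tree: a burn-in of 10 rescaled root-$N_e$ generations in the ancestral
population (standing in for coalescent recapitation — same stationary-state
intent, no ancestry recording), then a pre-order traversal in which each
split copies the parent population into both daughters in a single
generation (no post-split contact) and each branch evolves at its constant
size. Mutations arise at total rate $\mu$ ($2\times10^{-8}$ by default);
within exons a `DFEConfig` fraction is deleterious (gamma, shape
$\alpha = 0.16$, mean $\bar s \in \{-0.015, -0.03\}$) and a fraction
beneficial (exponential, mean $\bar s \in \{0.01, 0.005\}$), the rest
neutral, so the total rate is constant along the genome. Crossovers follow
a piecewise-constant recombination map.

Fitness is multiplicative across sites and additive within a site with
genotype fitnesses $1$, $1+s$, $1+2s$: $s$ is the per-allele-copy effect,
the convention under which a new beneficial mutation fixes with probability
$\approx 2s$ and which matches the diffusion formula used throughout
(`fixationProbability()`). Any variant reaching frequency 1 within a branch
is recorded as a `FixationRecord` and removed from the segregating pool;
fixed differences re-enter the tip allele table so that divergence includes
the substitution process.

Chromosome-scale runs of this model take weeks, so desk-scale work uses
**Q-rescaling** (`rescaleConfig()`): $N_e \to N_e/Q$, branch lengths and
burn-in $\to /Q$, while $\mu$, $r$ and (at draw time) $s$ are multiplied by
$Q$, preserving $4N_e\mu$, $4N_e r$ and $4N_e s$. Rescaling is exact only
while $2sQ \ll 1$; at $Q = 50$ the exponential beneficial tail violates
this, biasing beneficial fixation rates downward by roughly a quarter. For
this reason the acceptance tests compare rescaled forward runs against the
diffusion oracle evaluated at the *matched rescaled* parameters, while the
printed-value reproduction uses the oracle at the unrescaled parameters.

## Neutral mode and mutation-rate maps

`simulateNeutralWindows()` replaces the forward engine under neutrality
with the multispecies coalescent: per window it simulates
$k = \max(1, \text{round}(10 \times \text{map length in cM}))$ independent
recombination-free genealogies (so a 1 cM window gets 10 loci) and stores
mean pairwise coalescence times for every statistic. This reproduces the
higher coalescent variance of low-recombination windows without a full
coalescent-with-recombination. `overlayMutations()` then converts stored
times into landscapes under any `MutationRateMap`: expected per-site value
$2\,\text{rate}_w\,\bar T$, Poisson-sampled over the window's callable
length — so one set of genealogies is reused across maps, mirroring the
add-neutral-mutations-after-the-fact design of the original pipeline.

`buildMutationMap()` draws window rates i.i.d. from
$\mathcal N(\mu, \sigma_{\text{rel}}\mu)$ on the published
$\sigma_{\text{rel}}$ grid $\{0.005, \dots, 0.150\}$, truncated below at
zero (whether negative draws were truncated or redrawn is unstated in the
source; at these $\sigma$ values truncation essentially never triggers).
Exon-overlapping intervals carry the window rate minus the non-neutral
exonic rate, floored at zero with a warning. One map is shared identically
by all branches.

## Correlation, covariance and PCA analyses

`spearmanRho()` uses rank correlation with average ranks for ties and
pairwise deletion of missing windows (undefined below 3 complete pairs).
`allPairwiseCorrelations()` emits one record per unordered landscape pair
with $d_T$, comparison type, shared-branch flag and a low-$N_e$ flag
(threshold $8\times10^3$, overridable). For ten populations this yields
$\binom{55}{2} = 1485$ pairs; published pair counts depend on an unstated
subsetting rule, so no particular count is hard-coded.

`covarianceSeries()` implements the decomposition
$D_i(t) = \pi_i(t) + R_i t + \varepsilon_i$, which gives
$\mathrm{Cov}(D(t), X) = \mathrm{Cov}(\pi(t), X) + t\,\mathrm{Cov}(R, X) +
\mathrm{Cov}(\varepsilon, X)$ for any per-window feature $X$ (exon density,
mean recombination rate): the OLS slope of covariance on split time
estimates $\mathrm{Cov}(R, X)$, the coupling between substitution rates and
the feature. The optional "middle half" restriction keeps the interior 50%
of windows by index (the exact tail-exclusion boundary being unstated, this
is our choice), which removes chromosome-end effects such as gBGC
hotspots.

`pcaEmbedding()` takes the runs-by-correlations matrix, centers columns but
does **not** scale them (correlations already share a scale; the source does
not state its scaling), imputes missing entries by column means, and
returns top-2 coordinates plus full-space Euclidean distances from the data
row to every run. Runs with beneficial mutation rate
$\mu_p \ge 10^{-10}$ can be excluded, since strong positive selection
induces negative correlations that dominate low-order components.

## Substitution-rate oracle

`fixationProbability()` evaluates the diffusion result
$u(s) = (1 - e^{-2s})/(1 - e^{-4Ns})$ with $u(0) = 1/(2N)$, switching to
$e^{(4N-2)s}$ asymptotics when $-4Ns$ is large so strongly deleterious
values underflow to zero instead of overflowing.
`expectedSubstitutionRates()` integrates $2N\,u(s)$ over the DFE in
log-space (the gamma with $\alpha < 1$ concentrates its mass at $s \to 0$,
where naive quadrature misses it), giving per-class substitution rates; the
neutral class substitutes at its mutation rate. A lineage whose size
changes through time is handled as a `(N, duration)` schedule with
duration-weighted averaging; `humanLineageSchedule()` extracts the
root-to-human path of a tree. With the best-fit parameters (deleterious
$1.2\times10^{-8}$, beneficial $10^{-12}$ of a $2\times10^{-8}$ total) this
machinery yields a beneficial share of exonic substitutions near 8%, an
exon/neutral rate ratio near 59% and a beneficial substitution rate near
$9\times10^{-10}$ per exon bp per generation — the quantities
`scripts/acceptance.R` recomputes. Their uncertainty is dominated by the
unpublished intermediate-branch sizes, hence the interpolation described
above.

## Synthetic data

`generateDataset()` produces a self-contained stand-in for the empirical
inputs: neutral multispecies-coalescent genealogies on the default
ten-population tree, genotype-level mutation dropping, nucleotides assigned
uniformly over ordered (ancestral, derived) pairs, an outgroup (ancestral)
allele planted at a configurable fraction of sites (default 0.7, to
exercise the excluded path of polarization), per-population callable masks
engineered so a chosen fraction of windows falls below the 40% threshold,
heterogeneous exon-density and recombination profiles, and a truth JSON
with the internally computed landscapes for recovery tests. Output is
byte-identical for a fixed seed. The uniform nucleotide model has no
transition bias and no CpG structure — it is deliberately the simplest
model that exercises the weak/strong machinery, and nothing about real
hg18 chromosome 12 annotation or callability is emulated. Consequently the
round-trip tests validate the *pipeline*, not the biological realism of
any particular rate.

## Problem sizes and what the tests show

The package's test and acceptance runs use deliberately small problems,
chosen once as the smallest sizes at which each property has clear
statistical power: forward calibrations at $N = 100$–$5000$ diploids over
20–50 kb; the rescaling sweep at $Q \in \{10, 25, 50\}$ against
$4N_e\mu$; neutral-mode calibrations over 250 one-Mb windows; the
human-lineage forward cross-check at $Q = 50$ over 30 kb of exon;
selection-induced correlation runs over 30 windows of 10 kb with exons
concentrated in alternating windows. Passing these shows the machinery is
internally consistent and calibrated against coalescent and diffusion
theory at those scales; it does not re-demonstrate the published
chromosome-scale empirical results, which would require the original data
download and month-scale simulations.

## Known limitations

* No migration or post-split contact; constant size within a branch; no
  sex chromosomes.
* gBGC is classified in data but not simulated as a force.
* The neutral mode's $k$-loci-per-window device approximates, but is not,
  a coalescent with recombination; within-window linkage structure is not
  reproduced.
* Rescaling distorts the strong-$s$ tail at large $Q$ (quantified above).
* Mutation maps are static in time and perfectly shared across species.
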