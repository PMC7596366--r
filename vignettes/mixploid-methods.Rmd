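---
title: "Methods: ploidy, clonality and demography from GBS read counts"
author: "mixploid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ploidy, clonality and demography from GBS read counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mixploid)
```

## The problem

Vegetatively propagated crops such as greater yam accumulate collections in
which the same clone appears under many names, ploidy varies (diploid,
triploid, tetraploid — polyploids arising through unreduced gametes), and
genotyping is done by reduced-representation sequencing (GBS) with modest,
variable depth. Before any population-genetic statement can be made, three
nuisances must be resolved in order: each accession's ploidy, the clonal
redundancy of the panel, and only then diversity and demographic history on
the independent diploid genotypes. `mixploid` implements that pipeline, and
a synthetic GBS generator with full truth (dosage, ploidy, clone membership,
demographic history) so every stage is testable without raw sequencing data.

## Synthetic GBS generator

Founders are diploids drawn from gene pools that diverged by drift: a pool
with split time $t$ generations and diploid size $N$ receives allele
frequencies from a Balding–Nichols beta distribution around the ancestral
frequency with divergence $F = (1 - e^{-t/2N})/(1 + 4Nm)$, where $m$ is a
symmetric migration rate. $F$ equals the expected pairwise Weir–Cockerham
Fst between pools drifting on branches of length $t$, which is what the
generator's tests check; at $t = 0$ or $m \to \infty$ pools are
exchangeable. Ancestral frequencies default to a U-shaped Beta(0.5, 0.5),
a reasonable shape for a post-discovery SNP panel; tests pin them where
closed forms need it.

Polyploids follow the unreduced-gamete route: a triploid is one reduced
gamete (one allele sampled per site) plus the full somatic dosage of a
second parent from the same pool; a tetraploid is the full dosage of both
parents. Clonal ramets differ from their founder at
$\mathrm{Poisson}(\mu \cdot L)$ sites; a somatic mutation moves the dosage
by one copy, reflected at 0 and at the ploidy — a minimal model of
somaclonal variation that preserves dosage bounds. Reads are binomial: with
per-read error $e$, a cell of dosage $d$ and ploidy $p$ at depth $D$ yields
alternate reads $\sim \mathrm{Binomial}(D,\ (1-e)\,d/p + e\,(1-d/p))$.
Depth is fixed or Poisson; a missing cell has depth 0. The synthetic
genotype call is heterozygous when both alleles are seen with at least two
reads — a documented stand-in for an unspecified caller rule, and the one
knob downstream het-dependent stages inherit. What the generator does *not*
emulate: linkage disequilibrium along chromosomes (sites are exchangeable),
selection, allele-specific biases, paralogy, or index hopping. Passing
tests therefore demonstrate algorithmic correctness under clean GBS noise,
not robustness to every artefact of real libraries.

## Ploidy from allele balance

At a heterozygous site, the fraction of alternate reads concentrates near
$d/p$: a diploid's heterozygous sites pile up near $1/2$; a triploid's near
$1/3$ and $2/3$; a tetraploid's near $1/4$, $1/2$ and $3/4$. Per accession
we histogram the alternate-read fraction at heterozygous calls with depth
at least `min_site_depth` (default 30, the value a training grid selects at
realistic depth — low-depth fractions blur the modes), using 100, 250 or
500 equal classes, then fit an even-degree least-squares polynomial through
the class heights with no prior on its mode count, and count interior local
maxima of the fitted curve: one maps to diploid, two to triploid, three to
tetraploid, zero or more than three to unknown. Accessions with fewer than
`min_het_sites` (default 100) usable sites are unknown.

Numerical choices that matter, all exposed in `ploidy_params()`:

* **Degree 10** (not 8). A cubic-modal histogram needs at least seven
  extrema of the fitted curve to carry three humps with their shoulders;
  empirically degree 8 recovers tetraploids in under a quarter of seeded
  runs at 60x / 2000 heterozygous sites while degree 10 recovers all three
  ploidies in 90/90 runs across 100/250/500 classes. The degree stays in
  the training grid.
* **Maxima window (0.1, 0.9)** suppresses edge artefacts from sequencing
  error and residual homozygote leakage.
* **Relative peak floor** `min_peak_frac = 0.1`: a least-squares polynomial
  rings over the long empty tails of the histogram, producing spurious
  low-amplitude maxima; peaks below a tenth of the tallest fitted value are
  discarded.
* **Merge tolerance 0.08**: maxima closer than this are one mode split by
  noise; the higher is kept.

`train_parameters()` evaluates every combination of a user grid (depth
threshold, class count, degree, site floor) against labelled accessions —
the in-silico counterpart of calibrating against a flow-cytometry panel —
scoring unknowns as errors, with ties broken toward the stricter depth
threshold and then fewer classes.

## Clonal structure

Two relatedness measures serve the two distinct decisions the pipeline has
to make:

* **Manhattan kinship** on the mean-imputed 012 matrix,
  $k_{ij} = 1 - \sum_\ell |M_{i\ell} - M_{j\ell}| / 2L$ — the fraction of
  shared allele copies. Mean imputation happens on the 012 scale (imputed
  cells are fractional), which keeps the distance well defined with missing
  data. Significance is a normal law fitted to the kinship of independent
  pairs (`fitdistrplus`), thresholded at its upper 5% point; edges above it
  are exported as TSV and GraphML for external layout.
* **Method-of-moments IBD** ($\hat\pi = P_1/2 + P_2$) from
  identity-by-state counts and panel allele frequencies, the classical
  moment estimator without small-sample correction (frequencies come from
  the full filtered panel). Clipping the three probabilities to $[0,1]$ and
  renormalising biases $\hat\pi$ of truly unrelated pairs slightly upward
  (a few hundredths) — visible in the tests' tolerances and inherent to the
  estimator.

The clone threshold is the valley of a kernel density of all pairwise
$\hat\pi$ between the clone peak (near 1) and the nearest lower peak — with
sib cohorts in the panel, the parent–offspring peak near 0.5. Cohort labels,
when supplied, bound the search above the median within-cohort $\hat\pi$;
twin peaks within 0.1 are merged before the valley is taken; a unimodal
density falls back to the normal-law threshold. Clone clusters are
connected components of the above-threshold graph — deliberately not
cliques, because chains of somatic mutants of one ancestor can be mutually
distant while each link stays clone-like. Components of two or more samples
are multi-locus lineages (MLLs), singletons unique genotypes (UGs);
genotypic richness is $R = (G-1)/(N-1)$ on its conventional 0–1 scale, and
per-group $F_{IS} = 1 - H_o/H_e$ averaged over polymorphic loci is negative
in clonal groups, whose heterozygosity is frozen.

## Diversity statistics

Statistics are averaged over 100-kb bins holding at least three SNPs.
Per-site diversity is the unbiased $\pi_s = \frac{m}{m-1} 2\hat p \hat q$
over the $m$ observed allele copies (equal to the mean pairwise difference
among copies; missing genotypes are excluded site by site). Bin values are
reported per analyzed SNP by default — synthetic data carry no
invariant-site track — with a per-bp mode (dividing by the bin width) to
echo genome-scale conventions. Tajima's D uses the classical constants at
the rounded mean copy number over segregating sites; it is undefined (NA)
rather than zero when a bin has no segregating site. Weir–Cockerham Fst is
the two-population variance-components estimator with observed
heterozygosities, combined across sites as the ratio of component sums;
negative per-site values are retained.

## Joint SFS and demographic scenarios

The SFS-grade filter keeps rare variants (no MAF cut). To absorb missing
data, each site's allele count is projected to a fixed number of copies per
population by the hypergeometric expectation over subsamples —
deterministic and lower-variance than resampling once; sites observed with
fewer copies than the target are dropped and counted. The alternate allele
is treated as derived (the reference genome is an outgroup); a folded mode
is provided.

Scenarios are split-and-migration histories: backwards in time, lineages
coalesce within populations at rate $\binom{n}{2}/2N$, migrate at
per-generation per-lineage rates, and merge at split times (strictly
increasing, validated). The simulator (C++, event-driven) accumulates, per
joint allele-count bin, the branch length subtending that configuration;
with mutations uniform on the tree the normalized lengths are the expected
SFS, and an observed spectrum is a multinomial draw of sites over the
accumulated lengths (so longer trees carry more sites). The composite
log-likelihood is multinomial over SFS entries with expected proportions
floored at $10^{-10}$ (no renormalisation), monomorphic corners excluded by
default since SNP-only input carries no invariant-site information; for
multi-population observations it is summed over all pairwise 2-D marginals.
Fitting maximises this by golden-section search for one free parameter or
multi-restart Nelder–Mead otherwise, on log-scaled parameters, with each
evaluation re-simulating under a fixed seed (common random numbers make the
surface deterministic). Models are ranked by $AIC = 2k - 2\log L$.

Built-in templates cover a four-gene-pool crop dispersal history: three
3-population topologies for the Mainland-Southeast-Asia / Indian-Peninsula /
Pacific pools with and
without InP–Pac migration, and three Africa-origin scenarios on the winning
backbone (Pacific splits first, MSEA/InP later): A — Africa from InP; B —
Africa from Pac; C — A plus Afr–Pac gene flow. Migration rates are fixed at
0.005 per generation per lineage — a conventional value for weakly connected
crop gene pools — and the Africa divergence time is the free parameter.
Absent calibrated times or sizes, template sizes and times are desk-scale
choices made once — $N = 100$ diploids everywhere and splits at 100/200/400
generations — deep enough that 5000 SNPs separate the topologies, shallow
enough that everything runs on one CPU in minutes; parameters are reported
in generations and diploid sizes, not years.

## Problem sizes used in the checks

The shipped tests and the acceptance script run at sizes chosen to exercise
the statistics well inside a desk budget: 2000 heterozygous sites at 60x
(Poisson) and error 0.005 per simulated accession for mode recovery and the
60-accession classifier check; a 300-accession panel (40 planted clone
groups, 53 singletons, two 15-member sib cohorts) at 5000 loci and 30x for
clone recovery; 10 000 loci for the neutral-spectrum check at 8 copies; and
5000 observed sites against 4000 simulated loci per likelihood evaluation,
ten seeded replicates, for the scenario-recovery experiment. The collection-scale
quantities these mirror (hundreds of accessions, hundreds of thousands of
SNPs, millions of coalescent simulations) change precision, not the
algorithms.

## Known limitations

* Ploidy is capped at tetraploid and inferred only from mode counts; mode
  positions are reported but unused in classification.
* The IBD moment estimator assumes diploids; polyploid clone detection
  falls back on kinship.
* No linkage model: windowed statistics on synthetic data tile positions
  that are exchangeable within chromosomes.
* The coalescent simulator targets expected spectra, not sequence output;
  it supports at most eight populations.
* Composite-likelihood AIC ranks scenarios but its absolute differences
  overstate evidence when sites are linked, as in any SFS composite
  likelihood.
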