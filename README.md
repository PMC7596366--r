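# mixploid

Population genomics for mixed-ploidy, clonally propagated crop collections
genotyped by sequencing (GBS). Collections of crops like greater yam are
riddled with duplicated clones under different names, contain diploids,
triploids and tetraploids side by side (polyploids arise through unreduced
gametes), and are genotyped at modest read depth. `mixploid` implements the
analysis chain that turns such a panel into population-genetic results, plus
a synthetic GBS generator with known truth so the whole chain runs and is
tested without any raw sequencing data:

1. **Variant filtering** — depth ≥ 8 masks cells; biallelic sites with
   minor-allele count ≥ 3, MAF ≥ 0.05 and ≤ 10% missing are kept (the
   SFS-grade regime drops the MAF cut to keep rare variants); 012 encoding
   with per-locus mean imputation.
2. **Ploidy inference from allele balance** — at heterozygous sites the
   alternate-read fraction concentrates near *d/p* for dosage *d* and
   ploidy *p*: one mode at ½ for diploids, modes at ⅓ and ⅔ for triploids,
   at ¼, ½, ¾ for tetraploids. A polynomial is fitted to the fraction
   histogram with no prior on its mode count; the number of interior local
   maxima (1 / 2 / 3, else unknown) is the call. A training grid over depth
   thresholds and class counts calibrates the parameters on labelled
   accessions.
3. **Clone detection** — Manhattan kinship `1 − Σ|Mi − Mj| / 2L` with a
   normal-law significance threshold for the relatedness network, and
   method-of-moments IBD sharing (π̂ = P₁/2 + P₂) with a valley threshold
   between the parent–offspring and clone peaks for clone calls;
   multi-locus lineages (MLLs) are connected components above the
   threshold, with genotypic richness R = (G−1)/(N−1) and per-group Fis.
4. **Diversity statistics** — per-site nucleotide diversity, Tajima's D and
   Weir–Cockerham Fst on 100-kb bins holding ≥ 3 SNPs.
5. **Demography** — downsized joint site-frequency spectra via exact
   hypergeometric projection, an event-driven structured coalescent
   simulator (C++), multinomial composite likelihood, and AIC comparison of
   split-and-migration scenario templates.

## Worked example

Simulate a triploid accession (2000 heterozygous sites, Poisson 60x depth,
0.5% read error) and call its ploidy, then recover a planted clonal
structure:

```r
library(mixploid)

rct  <- simulate_ploidy_accession(3, n_het_sites = 2000,
                                  dm = depth_model(60, "poisson", 0.005),
                                  seed = 42)
fr   <- het_site_fractions(rct, "acc1")
call <- classify_ploidy(fit_distribution(fr), "acc1")
# accession acc1: 2000 usable het sites, 2 maxima at {0.327, 0.67} -> ploidy 3

panel <- simulate_clonal_panel(n_mlls = 8, n_ugs = 10, n_clone_members = 40,
                               n_sites = 3000, seed = 7)
m   <- geno012(panel$rct)
ph  <- ibd_pihat(m)$pihat[panel$panel_ids, panel$panel_ids]
thr <- clone_threshold_from_cohorts(ph[upper.tri(ph)])
mll_partition(ph, thr$threshold)
# mll_partition: N = 50, G = 18 (8 MLLs + 10 UGs), R = 0.347, threshold = 0.866
```

The two detected maxima sit at the triploid theory values ⅓ and ⅔, and the
partition recovers exactly the 8 planted clone groups and 10 unique
genotypes (18 distinct genotypes among 50 ramets).

## Analysis workflow

`analysis/` holds the numbered end-to-end workflow on synthetic data; each
stage reads the previous stage's outputs from `results/`:

| script | does |
| --- | --- |
| `01_simulate_collection.R` | mixed-ploidy collection (3 gene pools, polyploids, clones) → VCF + truth |
| `02_filter_variants.R` | both filter regimes, imputed 012 matrix |
| `03_infer_ploidy.R` | parameter training on a labelled subset, ploidy calls vs truth |
| `04_clonal_structure.R` | kinship network, π̂ clone partition, R, Fis |
| `05_diversity_stats.R` | binned π / Tajima's D, pairwise Fst matrix |
| `06_demography.R` | joint SFS, AIC comparison of the Africa-origin scenario templates |

Run them in order with `Rscript analysis/01_simulate_collection.R` etc.

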