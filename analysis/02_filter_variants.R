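#!/usr/bin/env Rscript
# Stage 2 - load the simulated VCF and apply the two filtering regimes.
#
# The full regime (depth >= 8, minor-allele count >= 3, MAF >= 0.05,
# biallelic only, <= 10% missing) feeds the ploidy and clonality stages;
# the SFS regime keeps rare variants (no MAF filter) for demography.

suppressPackageStartupMessages(library(mixploid))

rct <- load_vcf("results/collection.vcf")
cat(sprintf("loaded %d sites x %d samples\n", nrow(rct$sites),
            length(rct$samples)))

full <- apply_site_filters(rct, filter_params())
cat("full regime removals:\n")
print(attr(full, "removed"))
cat(sprintf("-> %d sites retained\n", nrow(full$sites)))

sfs <- apply_site_filters(rct, sfs_filter_params())
cat(sprintf("SFS regime (no MAF filter) -> %d sites retained\n",
            nrow(sfs$sites)))

m <- encode_012_impute(geno012(full))
write.table(round(m, 4), "results/geno012_imputed.tsv", sep = "\t",
            quote = FALSE)
write_vcf(full, "results/collection_filtered.vcf")
write_vcf(sfs, "results/collection_sfs_grade.vcf")
cat("wrote results/geno012_imputed.tsv and filtered VCFs\n")
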