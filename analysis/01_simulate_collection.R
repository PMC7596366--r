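#!/usr/bin/env Rscript
# Stage 1 - simulate a mixed-ploidy, clonally propagated GBS collection.
#
# Builds the synthetic collection used by every later stage: diploid
# founders from three diverged gene pools, triploids/tetraploids formed by
# unreduced gametes within pools, clonal expansion of a subset of diploids,
# and binomial read sampling at GBS-like depth. Writes a VCF, the truth
# table, and a population-assignment table under results/.

suppressPackageStartupMessages(library(mixploid))
dir.create("results", showWarnings = FALSE)
set.seed(101)

cfg <- pop_config(n_pops = 3, split_times = c(200, 400, 600),
                  pop_sizes = 1000, migration_rate = 0, n_sites = 3000,
                  n_chroms = 20, seed = 101)
acc <- simulate_founders(cfg, n_per_pop = 40)
acc <- make_polyploids(acc, triploid_fraction = 0.15,
                       tetraploid_fraction = 0.05, seed = 102)
# clonally expand ten diploid founders (3-6 ramets each)
set.seed(103)
for (id in sample(acc$truth$sample_id[acc$truth$ploidy == 2], 10)) {
  acc <- clonal_expand(acc, id, sample(3:6, 1), somatic_mu = 2e-4,
                       seed = sum(utf8ToInt(id)))
}
rct <- sample_reads(acc, depth_model(60, "poisson", 0.005,
                                     missing_rate = 0.03), seed = 104)

write_vcf(rct, "results/collection.vcf")
write_truth(acc, "results/collection_truth.tsv")
write.table(acc$truth[, c("sample_id", "pop")], "results/pop_table.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf("simulated %d accessions (%s) x %d sites -> results/collection.vcf\n",
            nrow(acc$truth),
            paste(sprintf("%sx: %d", names(table(acc$truth$ploidy)),
                          table(acc$truth$ploidy)), collapse = ", "),
            nrow(acc$sites)))
cat(sprintf("%d clonal lineages planted; mean depth 60x, 3%% missing cells\n",
            sum(table(acc$truth$clone_id) > 1)))
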