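#!/usr/bin/env Rscript
# Stage 5 - windowed diversity statistics on the unique-genotype panel.
#
# One representative per MLL plus the unique genotypes form the independent
# diploid panel; nucleotide diversity and Tajima's D are averaged over
# 100-kb bins holding at least three SNPs, and Weir-Cockerham Fst is
# computed for every gene-pool pair.

suppressPackageStartupMessages(library(mixploid))

rct <- load_vcf("results/collection_filtered.vcf")
truth <- read.delim("results/collection_truth.tsv", stringsAsFactors = FALSE)
part <- read.delim("results/mll_partition.tsv", stringsAsFactors = FALSE)
reps <- read.delim("results/mll_representatives.tsv",
                   stringsAsFactors = FALSE)
panel <- sort(unique(reps$representative))
cat(sprintf("independent diploid panel: %d genotypes\n", length(panel)))

m <- geno012(rct)[panel, ]
pop <- setNames(truth$pop, truth$sample_id)[panel]
bins <- make_bins(rct$sites)
cat(sprintf("%d bins of 100 kb with >= 3 SNPs\n", nrow(bins)))

per_pop <- lapply(sort(unique(pop)), function(p) {
  mp <- m[pop == p, , drop = FALSE]
  b <- nucleotide_diversity(mp, bins, per_bp = TRUE)
  b <- binned_tajimas_d(mp, b)
  data.frame(pop = p, chrom = b$chrom, start = b$start, end = b$end,
             n_snps = b$n_snps, pi_per_bp = b$pi, tajima_d = b$tajima_d)
})
bin_tab <- do.call(rbind, per_pop)
write.table(bin_tab, "results/diversity_bins.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

summ <- do.call(rbind, lapply(split(bin_tab, bin_tab$pop), function(d) {
  data.frame(pop = d$pop[1],
             pi_median = median(d$pi_per_bp, na.rm = TRUE),
             pi_iqr = IQR(d$pi_per_bp, na.rm = TRUE),
             d_median = median(d$tajima_d, na.rm = TRUE),
             d_iqr = IQR(d$tajima_d, na.rm = TRUE))
}))
print(summ, row.names = FALSE)

pops <- sort(unique(pop))
fst_mat <- matrix(NA_real_, length(pops), length(pops),
                  dimnames = list(pops, pops))
for (i in seq_along(pops)) for (j in seq_len(i - 1)) {
  fst_mat[i, j] <- fst_mat[j, i] <-
    weir_cockerham_fst(m[pop == pops[i], , drop = FALSE],
                       m[pop == pops[j], , drop = FALSE])$mean
}
cat("pairwise Weir-Cockerham Fst:\n")
print(round(fst_mat, 4))
write.table(summ, "results/diversity_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(round(fst_mat, 6), "results/fst_matrix.tsv", sep = "\t",
            quote = FALSE)
cat("wrote results/diversity_{bins,summary}.tsv and results/fst_matrix.tsv\n")
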