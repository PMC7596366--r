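#!/usr/bin/env Rscript
# Stage 4 - kinship, clone detection, multi-locus lineages, richness, Fis.
#
# Restricts to accessions called diploid, computes Manhattan kinship with a
# normal-law significance threshold, pi-hat IBD sharing with the valley
# clone threshold, partitions the panel into multi-locus lineages (MLLs)
# and unique genotypes (UGs), and exports the significant-kinship network.

suppressPackageStartupMessages(library(mixploid))

rct <- load_vcf("results/collection_filtered.vcf")
truth <- read.delim("results/collection_truth.tsv", stringsAsFactors = FALSE)
calls <- read.delim("results/ploidy_calls.tsv", stringsAsFactors = FALSE)
dip <- calls$sample_id[calls$ploidy == "2"]
cat(sprintf("%d accessions called diploid\n", length(dip)))

m_raw <- geno012(rct)[dip, ]
m_imp <- encode_012_impute(m_raw)

## kinship + significance threshold from presumed-independent pairs
k <- kinship_matrix(m_imp)
clone_truth <- setNames(truth$clone_id, truth$sample_id)[dip]
indep <- k[upper.tri(k)][outer(clone_truth, clone_truth,
                               "!=")[upper.tri(k)]]
thr_k <- significance_threshold(indep)
cat(sprintf("kinship normal fit: mu %.3f sd %.3f -> threshold %.3f\n",
            thr_k$mu, thr_k$sd, thr_k$threshold))

## pi-hat clone detection with the valley threshold
ph <- ibd_pihat(m_raw)$pihat
thr_c <- clone_threshold_from_cohorts(ph[upper.tri(ph)])
cat(sprintf("clone threshold %.3f (%s)\n", thr_c$threshold, thr_c$method))
part <- mll_partition(ph, thr_c$threshold)
print(part)
cat(sprintf("genotypic richness R = %.3f; panel Fis = %.3f\n",
            part$R, fis(m_raw)))

## outputs: partition table, representatives, network
out <- data.frame(sample_id = names(part$membership),
                  mll = part$membership,
                  is_unique = names(part$membership) %in%
                    part$unique_genotypes)
write.table(out, "results/mll_partition.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
reps <- data.frame(mll = names(part$representatives),
                   representative = part$representatives)
write.table(reps, "results/mll_representatives.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
attrs <- truth[truth$sample_id %in% dip, c("sample_id", "pop", "ploidy")]
export_network(k, thr_k$threshold, "results/kinship_network",
               node_attrs = attrs)
cat("wrote results/mll_partition.tsv, results/mll_representatives.tsv,",
    "results/kinship_network{.graphml,_edges.tsv}\n")

## recovery check against the planted truth
tab <- table(clone_truth, part$membership)
a <- sum(choose(tab, 2)); b <- sum(choose(rowSums(tab), 2))
cc <- sum(choose(colSums(tab), 2)); n <- sum(tab)
e <- b * cc / choose(n, 2)
cat(sprintf("adjusted Rand vs planted clones: %.4f\n",
            (a - e) / ((b + cc) / 2 - e)))
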