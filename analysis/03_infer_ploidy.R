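#!/usr/bin/env Rscript
# Stage 3 - infer each accession's ploidy from allele-balance histograms.
#
# Trains the depth/class parameters on a labelled subset (the flow-cytometry
# surrogate: truth table entries), then calls ploidy for the whole
# collection and reports the confusion against the simulated truth.

suppressPackageStartupMessages(library(mixploid))

rct <- load_vcf("results/collection_filtered.vcf")
truth <- read.delim("results/collection_truth.tsv", stringsAsFactors = FALSE)

# training subset mirroring a small flow-cytometry panel: 15 diploids,
# 8 triploids, 10 tetraploids (or as many as the collection holds)
set.seed(31)
pick <- function(pl, n) {
  ids <- truth$sample_id[truth$ploidy == pl]
  sample(ids, min(n, length(ids)))
}
train_ids <- c(pick(2, 15), pick(3, 8), pick(4, 10))
labels <- setNames(as.character(truth$ploidy[match(train_ids,
                                                   truth$sample_id)]),
                   train_ids)
trained <- train_parameters(rct, labels,
                            grid = list(min_site_depth = c(8L, 30L),
                                        n_classes = c(100L, 250L, 500L)))
cat(sprintf("training accuracy %.1f%% with min_site_depth %d, %d classes\n",
            100 * trained$accuracy, trained$best$min_site_depth,
            trained$best$n_classes))
print(trained$confusion)

calls <- call_ploidy(rct, trained$best)
calls$true_ploidy <- truth$ploidy[match(calls$sample_id, truth$sample_id)]
write.table(calls, "results/ploidy_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

known <- calls$ploidy != "unknown"
cat(sprintf("called %d/%d accessions (%.1f%% unknown)\n", sum(known),
            nrow(calls), 100 * mean(!known)))
cat(sprintf("accuracy on called accessions: %.1f%%\n",
            100 * mean(calls$ploidy[known] ==
                         as.character(calls$true_ploidy[known]))))
cat("per-ploidy tally of calls:\n")
print(table(true = calls$true_ploidy, called = calls$ploidy))
cat("wrote results/ploidy_calls.tsv\n")
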