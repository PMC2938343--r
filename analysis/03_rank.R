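#!/usr/bin/env Rscript
# Step 3: mRMR ranking.
#
# Genes are discretized to three levels at mean +/- sd and ranked greedily by
# relevance (mutual information with the four-group label) minus mean
# redundancy with the genes already picked. The top of this list is the
# candidate pool the incremental search works through.

library(unisig)

x <- read_expression("results/expression_preprocessed.tsv")
ph <- read_phenotype("results/data/phenotype.tsv")
truth <- read.delim("results/data/truth.tsv")

ranked <- rank_features(x, phenotype_groups(ph), n_select = 100)
write.table(format(ranked, digits = 12), "results/ranked_features.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

hits40 <- mean(truth$gene_id %in% ranked$gene_id[1:40])
cat("ranked", nrow(ranked), "candidate genes\n")
cat(sprintf("top-40 contains %.0f%% of the %d planted informative genes\n",
            100 * hits40, nrow(truth)))
print(head(ranked, 10))
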