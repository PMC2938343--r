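#!/usr/bin/env Rscript
# Step 4: incremental feature selection.
#
# For every k, the top-k ranked genes feed a four-group nearest-neighbour
# classifier (cosine-derived distance) under leave-one-out cross-validation.
# The four-group predictions are merged two ways: by subtype (ABC vs GCB,
# scored as overall accuracy) and by risk (dead- vs alive-labelled
# predictions, scored by the log-rank test on observed survival).

library(unisig)

x <- read_expression("results/expression_preprocessed.tsv")
ph <- read_phenotype("results/data/phenotype.tsv")
ranked <- read.delim("results/ranked_features.tsv")

curve <- ifs_run(x, ranked$gene_id, ph, k_max = 100)
write.table(format(curve, digits = 12), "results/ifs_curve.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

best_acc <- curve$k[which.max(curve$subtype_accuracy)]
best_p <- curve$k[which.max(curve$neg_log10_p)]
cat("IFS curve over k = 1..", nrow(curve), "\n", sep = "")
cat(sprintf("best subtype accuracy %.3f at k = %d\n",
            max(curve$subtype_accuracy), best_acc))
cat(sprintf("smallest log-rank p %.3g at k = %d\n",
            min(curve$logrank_p), best_p))
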