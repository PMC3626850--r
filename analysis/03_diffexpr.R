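#!/usr/bin/env Rscript
# ATRA differential expression on the expressed transcripts: per-repeat and
# per-line folds, the 1.5-fold / 2-of-3-lines / 4-of-6-repeats cascade, and
# the paired Student t-test across the six matched sample pairs (raw
# p < 0.05). Calls are compared against the planted ground truth.

library(tucrtile)

ds <- read_dataset("results/dataset")
prep <- preprocess_intensities(ds$intensity, ds$probes, ds$regions,
                               ds$samples)
de <- build_de_table(prep$tucr_expressed, ds$samples)
write.table(de, "results/de_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

truth_de <- ds$truth$transcript_id[ds$truth$de_label != "null"]
recall <- mean(truth_de %in% de$transcript_id)
fdp <- if (nrow(de)) mean(!de$transcript_id %in% truth_de) else 0

cat(nrow(de), "transcripts called differentially expressed (",
    sum(de$direction == "up"), "up /", sum(de$direction == "down"),
    "down ) of", sum(ds$truth$de_label != "null"), "planted.\n")
cat(sprintf("Recall of the planted DE set: %.2f; false-discovery proportion: %.2f\n",
            recall, fdp))
cat("Top calls by p-value:\n")
print(head(de[, c("transcript_id", "direction", "p_value")], 5),
      row.names = FALSE)
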