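#!/usr/bin/env Rscript
# Unsupervised analysis of intragenic T-UCR expression: reorient each
# region's two strand profiles relative to the host gene (sense block S,
# antisense block A), merge to one region x 2F matrix, cluster with Ward's
# criterion on Spearman rank-correlation distance (k = 3), and test each
# cluster for annotation over/under-representation.

library(tucrtile)

ds <- read_dataset("results/dataset")
prep <- preprocess_intensities(ds$intensity, ds$probes, ds$regions,
                               ds$samples)
info <- prep$tucr$info
intra <- info[info$region_class %in% c("intronic", "exonic", "partly_exonic"), ]
reo <- reorient_merge(prep$tucr$mat[intra$transcript_id, ], intra)
d <- spearman_distance(reo)
cl <- ward_cluster(d, k = 3)

ann_sets <- list(
  exonic = ds$regions$id[ds$regions$region_class %in%
                           c("exonic", "partly_exonic")],
  intronic = ds$regions$id[ds$regions$region_class == "intronic"])
enr <- cluster_enrichment(cl$labels, ann_sets)

write.table(data.frame(region = names(cl$labels), cluster = cl$labels),
            "results/clusters.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(order = cl$order, region = rownames(reo)[cl$order]),
            "results/dendrogram_order.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(enr, "results/enrichment.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Reoriented", nrow(intra), "strand profiles into", nrow(reo),
    "regions x", ncol(reo), "features.\n")
cat("Cluster sizes at k = 3:", as.vector(table(cl$labels)), "\n")
cat("Annotation enrichment (one-sided hypergeometric):\n")
print(enr, row.names = FALSE)
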