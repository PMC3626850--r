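#!/usr/bin/env Rscript
# Generate the synthetic study dataset: 200 UCR loci tiled on both strand
# containers, 12 arrays (3 neuroblastoma lines x untreated/ATRA x 2 repeats),
# with 16 up- and 16 down-regulated transcripts planted among the expressed
# ones and class-wise transcript/host correlations planted at the emulated
# study levels (0.68 sense-exonic, 0.13 antisense-intronic).

library(tucrtile)

dir.create("results", showWarnings = FALSE)
cfg <- sim_config(seed = 1)
sim <- simulate_dataset(cfg)
write_dataset(sim, "results/dataset")

cat("Simulated", nrow(sim$regions), "regions /", nrow(sim$truth),
    "transcripts on", ncol(sim$intensity), "arrays;",
    nrow(sim$probes), "probes;",
    sum(sim$truth$de_label != "null"), "planted DE transcripts;",
    nrow(sim$outliers), "planted outlier spikes.\n")
cat("Dataset written under results/dataset/\n")
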