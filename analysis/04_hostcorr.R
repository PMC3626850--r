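#!/usr/bin/env Rscript
# Host-gene correlation of intragenic T-UCRs: Pearson r between the
# transcript summary and the mean exonic probe expression of the host gene
# over the 12 arrays, with exact t-based significance, per-class summaries,
# and the anti-correlation (transcriptional interference) screen.

library(tucrtile)

ds <- read_dataset("results/dataset")
prep <- preprocess_intensities(ds$intensity, ds$probes, ds$regions,
                               ds$samples)
emap <- exon_probe_map(ds$probes, ds$exons, ds$regions)
host <- host_exon_expression(prep$probe_mat, emap)
screen <- correlation_screen(prep$tucr, host)
smry <- summarize_hostcorr(screen)
anti <- anticorrelation_screen(screen)

write.table(screen, "results/hostcorr.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(smry, "results/hostcorr_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(anti, "results/anticorrelated.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat("Scored", sum(screen$flag != "no_data"), "intragenic transcripts (",
    sum(screen$flag == "no_data"), "without host exons in the window ).\n")
cat("Per-class median correlation and % significant (planted: 0.68",
    "sense-exonic, 0.13 antisense-intronic):\n")
print(smry, row.names = FALSE)
cat(nrow(anti), "transcripts significantly anti-correlated with their host",
    "gene (interference candidates).\n")
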