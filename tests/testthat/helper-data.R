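# Small in-code fixtures shared across test files.

toy_regions <- function() {
  validate_regions(data.frame(
    chrom = "chr1",
    start = c(10000, 30000, 50000, 70000),
    end = c(10300, 30250, 50400, 70220),
    id = c("uc.A", "uc.B", "uc.C", "uc.D"),
    region_class = c("intergenic", "intronic", "exonic", "intronic"),
    host_gene = c(NA, "HGB", "HGC", "HGD"),
    host_strand = c(NA, "+", "-", "+"),
    orientation = NA_character_,
    stringsAsFactors = FALSE))
}

toy_exons <- function() {
  data.frame(gene = c("HGB", "HGC"), chrom = "chr1",
             start = c(28000, 50600), end = c(28400, 51000),
             strand = c("+", "-"), stringsAsFactors = FALSE)
}

# minimal noiseless simulation shared by several files
quiet_sim <- function(...) {
  cfg <- sim_config(...)
  suppressMessages(simulate_dataset(cfg))
}

quiet_preprocess <- function(sim, ...) {
  suppressWarnings(suppressMessages(
    preprocess_intensities(sim$intensity, sim$probes, sim$regions,
                           sim$samples, ...)))
}

noiseless_args <- list(noise_sd = 0, probe_affinity_sd = 0, line_sd = 0,
                       repeat_sd = 0, array_bio_sd = 0, array_effect_sd = 0,
                       outlier_prob = 0)
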