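#' Run the full analysis pipeline on a simulated dataset
#'
#' Executes simulate -> preprocess -> differential expression -> host-gene
#' correlation -> reorientation/clustering/enrichment -> gene-list overlap,
#' end to end, optionally writing per-stage TSVs plus a JSON summary (with
#' the seed and package version for provenance) under `out_dir`. If a stage
#' fails, partial outputs are retained and a `FAILED` marker file names the
#' stage.
#'
#' @param config a [sim_config()]; its seed drives every random draw.
#' @param de_cfg a [de_config()].
#' @param k number of clusters for the unsupervised stage.
#' @param out_dir optional output directory.
#' @return (invisibly) list with all stage results and a `summary` list.
#' @export
run_pipeline <- function(config = sim_config(), de_cfg = de_config(), k = 3,
                         out_dir = NULL) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create output directory: ", out_dir, call. = FALSE)
  stage <- "simulate"
  res <- tryCatch({
    sim <- simulate_dataset(config)

    stage <- "preprocess"
    prep <- preprocess_intensities(sim$intensity, sim$probes, sim$regions,
                                   sim$samples)

    stage <- "diffexpr"
    de <- build_de_table(prep$tucr_expressed, sim$samples, de_cfg)

    stage <- "hostcorr"
    emap <- exon_probe_map(sim$probes, sim$exons, sim$regions)
    host <- host_exon_expression(prep$probe_mat, emap)
    screen <- correlation_screen(prep$tucr, host, alpha = de_cfg$alpha)
    corr_summary <- summarize_hostcorr(screen, alpha = de_cfg$alpha)
    anticorr <- anticorrelation_screen(screen)

    stage <- "cluster"
    info <- prep$tucr$info
    intra <- info[info$region_class %in% INTRAGENIC_CLASSES, , drop = FALSE]
    reoriented <- reorient_merge(prep$tucr$mat[intra$transcript_id, ,
                                               drop = FALSE], intra)
    dist_mat <- spearman_distance(reoriented)
    clustering <- ward_cluster(dist_mat, k = k)
    ann_sets <- list(
      exonic = sim$regions$id[sim$regions$region_class %in%
                                c("exonic", "partly_exonic")],
      intronic = sim$regions$id[sim$regions$region_class == "intronic"])
    enrichment <- cluster_enrichment(clustering$labels, ann_sets)

    stage <- "overlap"
    ov_sim <- simulate_overlap_experiments(seed = config$seed)
    calls_a <- gene_de(ov_sim$expr_a, ov_sim$samples)
    calls_b <- gene_de(ov_sim$expr_b, ov_sim$samples)
    ov <- overlap_lists(calls_a, calls_b)

    summary <- list(
      seed = config$seed,
      package_version = as.character(utils::packageVersion("tucrtile")),
      n_regions = nrow(sim$regions),
      n_transcripts = nrow(prep$tucr$mat),
      n_expressed = nrow(prep$tucr_expressed$mat),
      n_de = nrow(de),
      n_de_up = sum(de$direction == "up"),
      n_de_down = sum(de$direction == "down"),
      n_anticorrelated = nrow(anticorr),
      n_clusters = k,
      n_up_overlap = ov$n_up_overlap,
      n_down_overlap = ov$n_down_overlap)

    list(sim = sim, prep = prep, de = de, hostcorr = screen,
         hostcorr_summary = corr_summary, anticorr = anticorr,
         reoriented = reoriented, clustering = clustering,
         enrichment = enrichment, overlap = ov, summary = summary)
  }, error = function(e) {
    if (!is.null(out_dir))
      writeLines(paste("FAILED at stage:", stage, "-", conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
    stop(e)
  })

  if (!is.null(out_dir)) {
    write_tsv_file(res$de, file.path(out_dir, "de_table.tsv"))
    write_tsv_file(res$hostcorr, file.path(out_dir, "hostcorr.tsv"))
    write_tsv_file(res$hostcorr_summary,
                   file.path(out_dir, "hostcorr_summary.tsv"))
    write_tsv_file(res$anticorr, file.path(out_dir, "anticorrelated.tsv"))
    write_matrix_tsv(res$reoriented, file.path(out_dir, "reoriented.tsv"),
                     id_col = "region")
    write_tsv_file(data.frame(region = names(res$clustering$labels),
                              cluster = unname(res$clustering$labels)),
                   file.path(out_dir, "clusters.tsv"))
    write_tsv_file(res$enrichment, file.path(out_dir, "enrichment.tsv"))
    jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(res)
}
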