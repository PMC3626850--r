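#' @title Synthetic tiling-array generator with planted ground truth
#' @name synthetic_data
#' @description
#' Emulates the study design the pipeline targets: three retinoid-sensitive
#' neuroblastoma cell lines (SK-N-BE, LAN-5, SH-SY5Y), each untreated and
#' ATRA-treated, with two biological repeats, i.e. 12 arrays. Probe
#' intensities follow a log-normal model on the log2 scale:
#'
#'   log2 I(p, s) = mu_t + beta(t, line) + delta_t 1\[ATRA\] + u(t, line, rep)
#'                  + w(t, s) + a_p + eps(p, s)
#'
#' with transcript baseline mu_t, transcript-by-line baseline shifts beta,
#' planted treatment log2 fold delta_t, repeat-level biological variation u
#' shared by the treated/untreated arrays of one repeat, array-level
#' biological variation w, probe affinity a_p constant across arrays, and
#' technical noise eps. Host-gene exon signal is generated jointly with the
#' T-UCR signal through a shared latent factor, so the transcript/host
#' correlation is planted per class. Isolated probes are spiked
#' multiplicatively with probability `outlier_prob` — exactly the artifact
#' window-3 median smoothing is meant to remove.
NULL

CELL_LINES <- c("SKNBE", "LAN5", "SHSY5Y")

#' Simulation configuration
#'
#' Defaults encode the emulated study conditions: 200 regions with the
#' genome-wide class mix (39% intergenic, 43% intronic, 15% exonic including
#' partly exonic, 3% unclassified), 16 up- and 16 down-regulated transcripts
#' with linear folds between 1.5 and 4, and planted transcript/host
#' correlations of 0.68 for sense exonic and 0.13 for antisense intronic
#' T-UCRs (0.4 for the remaining intragenic classes).
#'
#' @param n_regions number of UCR loci to simulate.
#' @param class_fractions named fractions over region classes (sum to 1).
#' @param n_de_up,n_de_down planted differentially expressed transcript counts.
#' @param de_log2fold_range absolute planted log2 fold range.
#' @param rho_by_class named target transcript/host correlations in \[-1, 1\]
#'   for classes exonic_sense, exonic_antisense, intronic_sense,
#'   intronic_antisense.
#' @param probe_affinity_sd sd of per-probe affinity (log2 units).
#' @param noise_sd sd of per-probe technical noise (log2 units).
#' @param line_sd sd of transcript-by-cell-line baseline shifts.
#' @param repeat_sd sd of repeat-level biological variation (shared by the
#'   treated and untreated arrays of a biological repeat; this is the latent
#'   channel through which host correlation is planted).
#' @param array_bio_sd sd of array-level biological variation (also
#'   correlation-coupled).
#' @param array_effect_sd sd of global per-array shifts (what quantile
#'   normalization removes).
#' @param baseline_mean,baseline_sd transcript baseline distribution (log2).
#'   DE labels are planted only on transcripts whose baseline clears the
#'   population median by at least 1 log2 unit, because the screen by
#'   construction only labels expressed transcripts.
#' @param host_exon_prob probability that an intragenic region's host gene
#'   has an exon inside the tiled window (others come out as `no_data`).
#' @param outlier_prob per-(probe, array) probability of a multiplicative
#'   intensity spike.
#' @param outlier_scale multiplicative spike factor on the intensity scale.
#' @param step,tm_target probe tiling parameters (see [tile_region()]).
#' @param ucr_length_range UCR core length range in bases.
#' @param seed integer seed; everything downstream is reproducible from it.
#' @return validated config list of class `sim_config`.
#' @export
sim_config <- function(n_regions = 200,
                       class_fractions = c(intergenic = 0.39, intronic = 0.43,
                                           exonic = 0.12, partly_exonic = 0.03,
                                           unclassified = 0.03),
                       n_de_up = 16, n_de_down = 16,
                       de_log2fold_range = c(log2(1.5), 2),
                       rho_by_class = c(exonic_sense = 0.68,
                                        exonic_antisense = 0.40,
                                        intronic_sense = 0.40,
                                        intronic_antisense = 0.13),
                       probe_affinity_sd = 0.5, noise_sd = 0.3,
                       line_sd = 0.12, repeat_sd = 0.8, array_bio_sd = 0.2,
                       array_effect_sd = 0.3,
                       baseline_mean = 8, baseline_sd = 1.5,
                       host_exon_prob = 0.8,
                       outlier_prob = 0.01, outlier_scale = 8,
                       step = 45, tm_target = 76,
                       ucr_length_range = c(200, 600),
                       seed = 1) {
  cfg <- as.list(environment())
  if (abs(sum(class_fractions) - 1) > 1e-8)
    stop("class_fractions must sum to 1", call. = FALSE)
  if (!all(names(class_fractions) %in% REGION_CLASSES))
    stop("unknown class in class_fractions", call. = FALSE)
  if (any(rho_by_class < -1 | rho_by_class > 1))
    stop("rho_by_class values must lie in [-1, 1]", call. = FALSE)
  sds <- c(probe_affinity_sd, noise_sd, line_sd, repeat_sd, array_bio_sd,
           array_effect_sd, baseline_sd)
  if (any(sds < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  if (n_de_up + n_de_down > n_regions)
    stop("n_de_up + n_de_down must not exceed n_regions", call. = FALSE)
  if (outlier_prob < 0 || outlier_prob > 1)
    stop("outlier_prob must lie in [0, 1]", call. = FALSE)
  if (diff(de_log2fold_range) < 0 || de_log2fold_range[1] < 0)
    stop("de_log2fold_range must be a non-negative increasing interval",
         call. = FALSE)
  structure(cfg, class = "sim_config")
}

#' Sample sheet of the emulated design
#'
#' @return 12-row data.frame: array_id, cell_line, treatment, repeat.
#' @export
study_sample_sheet <- function() {
  grid <- expand.grid(rep = 1:2, treatment = c("untreated", "ATRA"),
                      cell_line = CELL_LINES, stringsAsFactors = FALSE)
  out <- data.frame(
    array_id = sprintf("%s_%s_r%d", grid$cell_line,
                       ifelse(grid$treatment == "ATRA", "atra", "untr"),
                       grid$rep),
    cell_line = grid$cell_line, treatment = grid$treatment,
    check.names = FALSE, stringsAsFactors = FALSE)
  out[["repeat"]] <- grid$rep
  out
}

hostcorr_class <- function(region_class, orientation) {
  base <- ifelse(region_class %in% c("exonic", "partly_exonic"), "exonic",
                 ifelse(region_class == "intronic", "intronic", NA))
  ifelse(is.na(base) | is.na(orientation), NA_character_,
         paste0(base, "_", ifelse(orientation == "sense",
                                  "sense", "antisense")))
}

#' Simulate a full probe-level dataset with ground truth
#'
#' @param config a [sim_config()].
#' @return list of class `tucr_sim` with elements `regions`, `exons`,
#'   `probes`, `intensity` (linear-scale probes x arrays matrix), `samples`,
#'   `truth` (per-transcript planted fold, DE label, planted correlation) and
#'   `outliers` (spiked probe/array pairs).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_regions
  samples <- study_sample_sheet()

  # --- regions ------------------------------------------------------------
  counts <- diff(round(cumsum(c(0, config$class_fractions)) * n))
  classes <- sample(rep(names(config$class_fractions), counts))
  len <- round(stats::runif(n, config$ucr_length_range[1],
                            config$ucr_length_range[2]))
  gap <- 10000
  start <- 5000 + cumsum(c(0, utils::head(len, -1) + gap))
  intragenic <- classes %in% INTRAGENIC_CLASSES
  host_gene <- ifelse(intragenic, sprintf("GENE%04d", seq_len(n)), NA)
  host_strand <- ifelse(intragenic, sample(c("+", "-"), n, replace = TRUE), NA)
  regions <- data.frame(
    chrom = "chr1", start = start, end = start + len,
    id = sprintf("ucr%04d", seq_len(n)), region_class = classes,
    host_gene = host_gene, host_strand = host_strand,
    orientation = NA_character_, short = FALSE, stringsAsFactors = FALSE)

  # --- probes (synthetic GC tracks drive the Tm-matched lengths) ----------
  gc_list <- lapply(seq_len(n), function(i) {
    stats::runif(len[i] + 3000) < 0.5
  })
  names(gc_list) <- regions$id
  probes <- tile_regions(regions, step = config$step,
                         tm_target = config$tm_target, gc_list = gc_list)

  # --- host-gene exons in the upstream flank ------------------------------
  has_exon <- intragenic & stats::runif(n) < config$host_exon_prob
  ex_idx <- which(has_exon)
  exons <- if (length(ex_idx)) do.call(rbind, lapply(ex_idx, function(i) {
    r <- regions[i, ]
    if (r$host_strand == "+") es <- r$start - 2400 else es <- r$end + 2000
    data.frame(gene = r$host_gene, chrom = r$chrom, start = es,
               end = es + 400, strand = r$host_strand,
               stringsAsFactors = FALSE)
  })) else data.frame(gene = character(0), chrom = character(0),
                      start = numeric(0), end = numeric(0),
                      strand = character(0), stringsAsFactors = FALSE)

  # --- transcripts and planted DE -----------------------------------------
  tinfo <- transcript_table(regions)
  nt <- nrow(tinfo)
  tinfo$corr_class <- hostcorr_class(tinfo$region_class, tinfo$orientation)
  mu <- stats::rnorm(nt, config$baseline_mean, config$baseline_sd)
  # DE labels are planted on unambiguously expressed transcripts (baseline
  # at least 1 log2 unit above the population median): transcripts near the
  # array background have no well-defined DE status under the expression
  # filter, so they stay null.
  n_de <- config$n_de_up + config$n_de_down
  eligible <- which(mu >= stats::median(mu) + 1)
  if (length(eligible) < n_de)
    eligible <- order(mu, decreasing = TRUE)[seq_len(n_de)]
  de_idx <- eligible[sample.int(length(eligible), n_de)]
  de_label <- rep("null", nt)
  de_label[de_idx[seq_len(config$n_de_up)]] <- "up"
  de_label[de_idx[seq_len(config$n_de_down) + config$n_de_up]] <- "down"
  delta <- numeric(nt)
  fold_mag <- stats::runif(length(de_idx), config$de_log2fold_range[1],
                           config$de_log2fold_range[2])
  delta[de_idx] <- fold_mag * ifelse(de_label[de_idx] == "up", 1, -1)

  rho <- config$rho_by_class[tinfo$corr_class]
  rho[is.na(rho)] <- 0

  # --- latent biological structure ----------------------------------------
  ns <- nrow(samples)
  pair_id <- paste(samples$cell_line, samples[["repeat"]], sep = "_r")
  pairs <- unique(pair_id)                   # 6 biological repeats
  line_of <- samples$cell_line
  treated <- samples$treatment == "ATRA"

  # host latents (per region): repeat-level and array-level standard normals
  zh_rep <- matrix(stats::rnorm(n * length(pairs)), n)     # regions x 6
  zh_arr <- matrix(stats::rnorm(n * ns), n)                # regions x 12
  reg_i <- match(tinfo$region, regions$id)
  # transcript latents share the host latent with weight rho
  mix <- function(zh, own) rho * zh + sqrt(1 - rho^2) * own
  zt_rep <- mix(zh_rep[reg_i, , drop = FALSE],
                matrix(stats::rnorm(nt * length(pairs)), nt))
  zt_arr <- mix(zh_arr[reg_i, , drop = FALSE],
                matrix(stats::rnorm(nt * ns), nt))
  beta_line <- matrix(stats::rnorm(nt * 3, 0, config$line_sd), nt,
                      dimnames = list(NULL, CELL_LINES))

  # transcript log2 signal per array
  sig <- matrix(mu, nt, ns) +
    beta_line[, line_of] +
    outer(delta, as.numeric(treated)) +
    config$repeat_sd * zt_rep[, match(pair_id, pairs)] +
    config$array_bio_sd * zt_arr

  # host-gene log2 signal per array (one host per region)
  mu_host <- stats::rnorm(n, config$baseline_mean + 1, config$baseline_sd)
  beta_host <- matrix(stats::rnorm(n * 3, 0, config$line_sd), n,
                      dimnames = list(NULL, CELL_LINES))
  hsig <- matrix(mu_host, n, ns) + beta_host[, line_of] +
    config$repeat_sd * zh_rep[, match(pair_id, pairs)] +
    config$array_bio_sd * zh_arr

  # --- probe-level matrix --------------------------------------------------
  emap <- exon_probe_map(probes, exons, regions)
  is_exonic_probe <- probes$probe_id %in% emap$probe_id
  tr_of_probe <- paste0(probes$region, "_", probes$container)
  t_i <- match(tr_of_probe, tinfo$transcript_id)
  r_i <- match(probes$region, regions$id)
  np <- nrow(probes)

  base <- matrix(0, np, ns, dimnames = list(probes$probe_id, samples$array_id))
  core <- probes$zone == "core"
  base[core, ] <- sig[t_i[core], , drop = FALSE]
  base[is_exonic_probe, ] <- hsig[r_i[is_exonic_probe], , drop = FALSE]
  flank_bg <- !core & !is_exonic_probe
  base[flank_bg, ] <- config$baseline_mean - 2   # untranscribed background

  affinity <- stats::rnorm(np, 0, config$probe_affinity_sd)
  eps <- matrix(stats::rnorm(np * ns, 0, config$noise_sd), np)
  garr <- stats::rnorm(ns, 0, config$array_effect_sd)
  log2_mat <- base + affinity + eps + matrix(garr, np, ns, byrow = TRUE)

  spike <- matrix(stats::runif(np * ns) < config$outlier_prob, np)
  intensity <- 2^log2_mat * ifelse(spike, config$outlier_scale, 1)

  outliers <- data.frame(
    probe_id = probes$probe_id[row(spike)[spike]],
    array_id = samples$array_id[col(spike)[spike]],
    stringsAsFactors = FALSE)

  truth <- data.frame(
    transcript_id = tinfo$transcript_id, region = tinfo$region,
    container = tinfo$container, region_class = tinfo$region_class,
    orientation = tinfo$orientation, host_gene = tinfo$host_gene,
    corr_class = tinfo$corr_class,
    planted_log2fold = delta, de_label = de_label,
    planted_rho = ifelse(is.na(tinfo$corr_class), NA, rho),
    host_exons = !is.na(tinfo$host_gene) &
      tinfo$host_gene %in% exons$gene,
    baseline = mu, stringsAsFactors = FALSE)

  structure(list(regions = regions, exons = exons, probes = probes,
                 intensity = intensity, samples = samples, truth = truth,
                 outliers = outliers, config = config),
            class = "tucr_sim")
}

#' Write a simulated dataset to TSV files
#'
#' Writes regions.tsv, exons.tsv, probes.tsv, intensities.tsv, samples.tsv,
#' truth.tsv and outliers.tsv under `out_dir`; all re-readable with
#' [read_dataset()].
#'
#' @param dataset a `tucr_sim` list.
#' @param out_dir output directory (created if needed).
#' @export
write_dataset <- function(dataset, out_dir) {
  if (!dir.exists(out_dir))
    if (!dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
      stop("cannot create directory: ", out_dir, call. = FALSE)
  write_regions(dataset$regions, file.path(out_dir, "regions.tsv"))
  write_tsv_file(dataset$exons, file.path(out_dir, "exons.tsv"))
  write_tsv_file(dataset$probes[, c("probe_id", "region", "container",
                                    "start", "length", "zone", "tm")],
                 file.path(out_dir, "probes.tsv"))
  write_matrix_tsv(dataset$intensity, file.path(out_dir, "intensities.tsv"),
                   id_col = "probe_id")
  write_tsv_file(dataset$samples, file.path(out_dir, "samples.tsv"))
  write_tsv_file(dataset$truth, file.path(out_dir, "truth.tsv"))
  write_tsv_file(dataset$outliers, file.path(out_dir, "outliers.tsv"))
  invisible(out_dir)
}

#' Read back a dataset written by [write_dataset()]
#'
#' @param dir directory holding the TSV files.
#' @return list with the same tabular elements as [simulate_dataset()]
#'   (minus the config).
#' @export
read_dataset <- function(dir) {
  regions <- read_regions(file.path(dir, "regions.tsv"))
  probes <- read_tsv_file(file.path(dir, "probes.tsv"))
  win <- t(vapply(seq_len(nrow(regions)), function(i)
    tiled_window(regions[i, ]), numeric(2)))
  probes$window_start <- win[match(probes$region, regions$id), 1]
  probes$window_end <- win[match(probes$region, regions$id), 2]
  list(regions = regions,
       exons = read_tsv_file(file.path(dir, "exons.tsv")),
       probes = probes,
       intensity = read_matrix_tsv(file.path(dir, "intensities.tsv")),
       samples = read_tsv_file(file.path(dir, "samples.tsv")),
       truth = read_tsv_file(file.path(dir, "truth.tsv")),
       outliers = read_tsv_file(file.path(dir, "outliers.tsv")))
}

#' Simulate a reoriented matrix with two planted expression blocks
#'
#' Builds a region-by-2F matrix of the kind produced by [reorient_merge()],
#' with two planted groups mirroring the sense/antisense expression clusters:
#' group 1 is high in the sense block and low in the antisense block, group 2
#' the reverse. Used to verify that Spearman-distance/Ward clustering
#' recovers planted structure.
#'
#' @param n_regions regions per matrix (split evenly between groups).
#' @param n_arrays number of arrays F (matrix has 2F columns).
#' @param delta between-block log2 separation.
#' @param noise_sd additive noise sd.
#' @param seed integer seed.
#' @return list with `mat` (n_regions x 2F) and `labels` (planted group).
#' @export
simulate_cluster_blocks <- function(n_regions = 40, n_arrays = 12, delta = 2,
                                    noise_sd = 0.5, seed = 1) {
  set.seed(seed)
  g <- rep(1:2, length.out = n_regions)
  s_mean <- ifelse(g == 1, delta, 0)
  a_mean <- ifelse(g == 1, 0, delta)
  mat <- cbind(matrix(s_mean, n_regions, n_arrays),
               matrix(a_mean, n_regions, n_arrays)) +
    matrix(stats::rnorm(n_regions * 2 * n_arrays, 0, noise_sd), n_regions)
  rownames(mat) <- sprintf("ucr%04d", seq_len(n_regions))
  colnames(mat) <- c(paste0("arr", seq_len(n_arrays), "_S"),
                     paste0("arr", seq_len(n_arrays), "_A"))
  list(mat = mat, labels = g)
}

#' Simulate paired gene-expression experiments with a planted overlap
#'
#' Generates two gene-level two-repeat experiments over one gene universe —
#' an siRNA knockdown and an ATRA treatment — with planted up/down gene sets
#' whose direction-matched intersections are fixed. Defaults mirror the
#' emulated study: 150 up and 123 down after knockdown, of which 46 and 23
#' are shared with the ATRA response.
#'
#' @param n_genes size of the gene universe.
#' @param n_up_a,n_down_a planted counts in experiment A (knockdown).
#' @param n_up_b,n_down_b planted counts in experiment B (ATRA).
#' @param n_shared_up,n_shared_down planted direction-matched intersections.
#' @param log2fold_range planted absolute log2 fold range (linear 2 to 4).
#' @param noise_sd per-measurement log2 noise sd (0 gives exact recovery).
#' @param seed integer seed.
#' @return list with per-experiment expression matrices (`expr_a`, `expr_b`),
#'   a shared `samples` sheet (ctrl/test x 2 repeats) and `truth` labels.
#' @export
simulate_overlap_experiments <- function(n_genes = 2000,
                                         n_up_a = 150, n_down_a = 123,
                                         n_up_b = 300, n_down_b = 300,
                                         n_shared_up = 46, n_shared_down = 23,
                                         log2fold_range = c(1, 2),
                                         noise_sd = 0.1, seed = 1) {
  stopifnot(n_shared_up <= min(n_up_a, n_up_b),
            n_shared_down <= min(n_down_a, n_down_b),
            n_up_a + n_down_a + (n_up_b - n_shared_up) +
              (n_down_b - n_shared_down) <= n_genes)
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(n_genes))
  pool <- sample(genes)
  take <- function(k) {
    out <- pool[seq_len(k)]
    pool <<- pool[-seq_len(k)]
    out
  }
  up_a <- take(n_up_a); down_a <- take(n_down_a)
  up_b <- c(sample(up_a, n_shared_up), take(n_up_b - n_shared_up))
  down_b <- c(sample(down_a, n_shared_down), take(n_down_b - n_shared_down))

  samples <- data.frame(
    array_id = c("ctrl_r1", "ctrl_r2", "test_r1", "test_r2"),
    condition = c("ctrl", "ctrl", "test", "test"),
    check.names = FALSE, stringsAsFactors = FALSE)
  samples[["repeat"]] <- c(1L, 2L, 1L, 2L)

  build <- function(up, down) {
    delta <- numeric(n_genes)
    names(delta) <- genes
    delta[up] <- stats::runif(length(up), log2fold_range[1], log2fold_range[2])
    delta[down] <- -stats::runif(length(down), log2fold_range[1],
                                 log2fold_range[2])
    base <- stats::rnorm(n_genes, 8, 1)
    log2m <- cbind(base, base, base + delta, base + delta) +
      matrix(stats::rnorm(n_genes * 4, 0, noise_sd), n_genes)
    dimnames(log2m) <- list(genes, samples$array_id)
    2^log2m
  }
  truth <- data.frame(gene = genes,
                      label_a = ifelse(genes %in% up_a, "up",
                                       ifelse(genes %in% down_a, "down", "null")),
                      label_b = ifelse(genes %in% up_b, "up",
                                       ifelse(genes %in% down_b, "down", "null")),
                      stringsAsFactors = FALSE)
  list(expr_a = build(up_a, down_a), expr_b = build(up_b, down_b),
       samples = samples, truth = truth)
}
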