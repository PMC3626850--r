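#' @title Strand reorientation, clustering and annotation enrichment
#' @name cluster_enrich
#' @description
#' For unsupervised analysis the two strand-level expression profiles of
#' each region are relabeled relative to the host gene — sense (S) for the
#' container transcribed with the host gene, antisense (A) for the opposite
#' container — and concatenated, turning a 2R x F transcript matrix into an
#' R x 2F region matrix. Regions are then clustered hierarchically with
#' Ward's criterion on a Spearman rank-correlation distance, and cluster
#' membership is tested for annotation over/under-representation with
#' one-sided hypergeometric tails.
NULL

#' Reorient strand profiles and merge per region
#'
#' The S block is the container matching the host-gene strand (plus
#' container for intergenic/unclassified regions); the A block is the other
#' container. Output columns are the input arrays suffixed `_S` then `_A`,
#' so every input value appears exactly once in the output.
#'
#' @param mat transcripts x arrays matrix (2 rows per region).
#' @param info transcript annotation with transcript_id, region, container,
#'   region_class, host_strand (e.g. the `info` of a `tucr_summary`).
#' @return regions x 2F matrix.
#' @export
reorient_merge <- function(mat, info) {
  stopifnot(all(info$transcript_id %in% rownames(mat)))
  regions <- unique(info$region)
  intragenic <- info$region_class %in% INTRAGENIC_CLASSES
  bad <- intragenic & is.na(info$host_strand)
  if (any(bad))
    stop("missing host strand for intragenic region(s): ",
         paste(unique(info$region[bad]), collapse = ", "), call. = FALSE)
  sense_cont <- ifelse(intragenic,
                       ifelse(info$host_strand == "+", "plus", "minus"),
                       "plus")
  s_id <- info$transcript_id[info$container == sense_cont]
  names(s_id) <- info$region[info$container == sense_cont]
  a_id <- info$transcript_id[info$container != sense_cont]
  names(a_id) <- info$region[info$container != sense_cont]
  if (!all(regions %in% names(s_id)) || !all(regions %in% names(a_id)))
    stop("every region needs both strand containers", call. = FALSE)
  out <- cbind(mat[s_id[regions], , drop = FALSE],
               mat[a_id[regions], , drop = FALSE])
  dimnames(out) <- list(regions,
                        c(paste0(colnames(mat), "_S"),
                          paste0(colnames(mat), "_A")))
  out
}

#' Spearman rank-correlation distance between regions
#'
#' `d(i, j) = 1 - rho_spearman(row_i, row_j)`, symmetric with zero diagonal,
#' values in \[0, 2\].
#'
#' @param mat regions x features matrix (>= 2 rows).
#' @return regions x regions distance matrix.
#' @export
spearman_distance <- function(mat) {
  if (nrow(mat) < 2) stop("need at least 2 regions", call. = FALSE)
  const <- apply(mat, 1, function(x) length(unique(x)) == 1L)
  if (any(const))
    stop("constant row(s): ",
         paste(rownames(mat)[const] %||% which(const), collapse = ", "),
         call. = FALSE)
  d <- 1 - stats::cor(t(mat), method = "spearman")
  diag(d) <- 0
  d
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering under the classical Ward criterion applied
#' directly to the supplied distances (`stats::hclust`, method `ward.D`),
#' with labels from cutting the tree at `k` clusters. Cluster ids follow
#' first appearance in region order, so the partition is deterministic.
#'
#' @param dist_mat symmetric distance matrix (e.g. [spearman_distance()]).
#' @param k number of clusters.
#' @param method `"ward.D"` (default, Ward-on-distances) or `"ward.D2"`.
#' @return list of class `ucr_clustering`: `hclust`, `labels`, `k`, `order`.
#' @export
ward_cluster <- function(dist_mat, k = 3, method = c("ward.D", "ward.D2")) {
  method <- match.arg(method)
  n <- nrow(dist_mat)
  if (k > n) stop("k must not exceed the number of regions", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(dist_mat), method = method)
  labels <- stats::cutree(hc, k = k)
  structure(list(hclust = hc, labels = labels, k = k, order = hc$order),
            class = "ucr_clustering")
}

#' Hypergeometric annotation enrichment per cluster
#'
#' For each (cluster, annotation) pair, one-sided hypergeometric tail
#' probabilities for over- and under-representation of annotated regions in
#' the cluster. The urn is the clustered region universe; draws are the
#' cluster members; successes are the annotated regions.
#'
#' @param labels named cluster labels (names = region ids).
#' @param annotation_sets named list of region-id vectors.
#' @return data.frame: cluster, annotation, cluster_size, annotated_total,
#'   overlap, p_over, p_under.
#' @export
cluster_enrichment <- function(labels, annotation_sets) {
  universe <- names(labels)
  if (is.null(universe)) stop("labels must be named by region id",
                              call. = FALSE)
  N <- length(universe)
  rows <- list()
  for (ann in names(annotation_sets)) {
    A <- intersect(annotation_sets[[ann]], universe)
    if (length(A) == 0L) {
      warning("annotation '", ann, "' is disjoint from the universe; skipped")
      next
    }
    K <- length(A)
    for (cl in sort(unique(labels))) {
      members <- universe[labels == cl]
      n_draw <- length(members)
      k <- length(intersect(members, A))
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, annotation = ann, cluster_size = n_draw,
        annotated_total = K, overlap = k,
        p_over = stats::phyper(k - 1, K, N - K, n_draw, lower.tail = FALSE),
        p_under = stats::phyper(k, K, N - K, n_draw),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(cluster = integer(0), annotation = character(0),
               cluster_size = integer(0), annotated_total = integer(0),
               overlap = integer(0), p_over = numeric(0),
               p_under = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
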