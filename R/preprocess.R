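#' @title Probe-level preprocessing for strand-specific tiling arrays
#' @name preprocess
#' @description
#' The preprocessing chain runs, in order: log2 transform, quantile
#' normalization across arrays, window-3 median smoothing along each
#' region/strand-container probe track, mean-of-core-probe summarization to
#' transcript level, and expression calling against the array background
#' (median expression of the array). Tracks stay in log2 from normalization
#' onward so downstream fold changes are simple differences.
NULL

#' Quantile normalization
#'
#' Forces every array column onto the common reference distribution (the
#' mean of the column-wise sorted values) while preserving within-column
#' ranks. Ties within a column receive the mean of the reference values over
#' the tie's rank span.
#'
#' @param mat numeric matrix, probes x arrays, at least 2 columns.
#' @return matrix of the same shape; the sorted values of every column are
#'   identical afterwards.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) stop("need at least 2 arrays", call. = FALSE)
  if (anyNA(mat)) stop("matrix contains missing values", call. = FALSE)
  const <- apply(mat, 2, function(x) length(unique(x)) == 1L)
  if (any(const))
    stop("all-constant column(s) (rank undefined): ",
         paste(colnames(mat)[const] %||% which(const), collapse = ", "),
         call. = FALSE)
  ref <- rowMeans(apply(mat, 2, sort))
  out <- mat
  for (j in seq_len(ncol(mat))) {
    ord <- order(mat[, j])
    vals <- ref
    x_sorted <- mat[ord, j]
    # ties: average the reference values across the tied rank span
    grp <- cumsum(c(TRUE, x_sorted[-1] != x_sorted[-length(x_sorted)]))
    vals <- stats::ave(ref, grp)
    out[ord, j] <- vals
  }
  out
}

#' Median smoothing along a probe track
#'
#' Replaces each value with the median of a centered window (default 3
#' probes) along the track; the window is truncated at the track boundaries,
#' and truncated even-sized windows use the midpoint average. Accepts a
#' vector or a track-by-array matrix (smoothed per column).
#'
#' @param x numeric vector, or matrix with track positions in rows.
#' @param window odd window size.
#' @return smoothed object of the same shape.
#' @export
median_smooth <- function(x, window = 3) {
  if (window %% 2 != 1 || window < 1)
    stop("window must be odd and >= 1", call. = FALSE)
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, ncol = 1) else as.matrix(x)
  n <- nrow(m)
  if (n == 0L) return(x)
  out <- m
  if (window == 3 && n >= 3) {
    a <- m[1:(n - 2), , drop = FALSE]
    b <- m[2:(n - 1), , drop = FALSE]
    c_ <- m[3:n, , drop = FALSE]
    out[2:(n - 1), ] <- a + b + c_ - pmax(a, b, c_) - pmin(a, b, c_)
    out[1, ] <- (m[1, ] + m[2, ]) / 2
    out[n, ] <- (m[n - 1, ] + m[n, ]) / 2
  } else {
    h <- (window - 1) / 2
    for (i in seq_len(n)) {
      idx <- max(1, i - h):min(n, i + h)
      out[i, ] <- apply(m[idx, , drop = FALSE], 2, stats::median)
    }
  }
  if (vec) drop(out) else out
}

#' Smooth every region/container probe track of a matrix
#'
#' @param mat probes x arrays matrix (log2, quantile-normalized).
#' @param probes probe data.frame; tracks are formed per (region, container)
#'   and ordered by genomic start.
#' @param window odd smoothing window.
#' @return smoothed matrix with rows in the original order.
#' @export
smooth_tracks <- function(mat, probes, window = 3) {
  stopifnot(all(probes$probe_id %in% rownames(mat)))
  out <- mat
  for (idx in split(seq_len(nrow(probes)),
                    paste(probes$region, probes$container))) {
    ord <- idx[order(probes$start[idx])]
    out[probes$probe_id[ord], ] <-
      median_smooth(mat[probes$probe_id[ord], , drop = FALSE], window)
  }
  out
}

#' Summarize probes to T-UCR transcripts
#'
#' A transcript is one (region, strand container) pair; its summary on each
#' array is the mean of the smoothed core-zone probe values of the matching
#' container. Flank probes never enter the transcript summary (they are kept
#' for host-exon expression). Transcripts whose region has no core probe are
#' flagged missing and excluded.
#'
#' @param mat smoothed log2 probes x arrays matrix.
#' @param probes probe data.frame with zones assigned.
#' @param regions region data.frame.
#' @return list of class `tucr_summary`: `mat` (transcripts x arrays),
#'   `info` (transcript annotation), `missing` (transcript ids without core
#'   probes).
#' @export
summarize_tucrs <- function(mat, probes, regions) {
  tinfo <- transcript_table(regions)
  core <- probes[probes$zone == "core", , drop = FALSE]
  key <- paste0(core$region, "_", core$container)
  sums <- rowsum(mat[core$probe_id, , drop = FALSE], key)
  cnt <- as.vector(table(key)[rownames(sums)])
  smat <- sums / cnt
  missing <- setdiff(tinfo$transcript_id, rownames(smat))
  tinfo <- tinfo[tinfo$transcript_id %in% rownames(smat), , drop = FALSE]
  smat <- smat[tinfo$transcript_id, , drop = FALSE]
  if (length(missing))
    warning("transcript(s) without core probes excluded: ",
            paste(missing, collapse = ", "))
  structure(list(mat = smat, info = tinfo, missing = missing),
            class = "tucr_summary")
}

#' Call expressed transcripts against the array background
#'
#' The background of an array is its median expression — by default the
#' median over transcript summaries (configurable to the probe-level
#' median). A transcript is expressed in a cell line iff its summary exceeds
#' the background on at least one of that line's arrays (configurable to
#' all arrays), and is retained iff expressed in all three cell lines.
#'
#' @param tucr a `tucr_summary`.
#' @param samples sample sheet with array_id, cell_line columns.
#' @param background `"transcript"` or `"probe"`; probe-level background
#'   requires `probe_mat`.
#' @param probe_mat optional smoothed probe matrix for probe-level background.
#' @param per_line_rule `"any"` (default) or `"all"` arrays of a line.
#' @return list: `expressed` (transcripts x lines logical), `keep` (logical
#'   per transcript), `tucr` (filtered `tucr_summary`), `background`
#'   (per-array background values).
#' @export
call_expressed <- function(tucr, samples, background = c("transcript", "probe"),
                           probe_mat = NULL, per_line_rule = c("any", "all")) {
  background <- match.arg(background)
  per_line_rule <- match.arg(per_line_rule)
  lines <- unique(samples$cell_line)
  if (length(lines) < 3)
    stop("need at least 3 cell lines in the sample sheet", call. = FALSE)
  bg <- if (background == "transcript") {
    apply(tucr$mat, 2, stats::median)
  } else {
    if (is.null(probe_mat))
      stop("probe_mat required for probe-level background", call. = FALSE)
    apply(probe_mat, 2, stats::median)
  }
  bg <- bg[colnames(tucr$mat)]
  above <- sweep(tucr$mat, 2, bg, ">")
  agg <- if (per_line_rule == "any") any else all
  expressed <- vapply(lines, function(l) {
    cols <- samples$array_id[samples$cell_line == l]
    apply(above[, cols, drop = FALSE], 1, agg)
  }, logical(nrow(tucr$mat)))
  keep <- rowSums(expressed) == length(lines)
  filtered <- structure(list(mat = tucr$mat[keep, , drop = FALSE],
                             info = tucr$info[keep, , drop = FALSE],
                             missing = tucr$missing),
                        class = "tucr_summary")
  list(expressed = expressed, keep = keep, tucr = filtered, background = bg)
}

#' Run the full probe-level preprocessing chain
#'
#' log2 transform, quantile normalization, window-3 median smoothing per
#' track, transcript summarization and expression calling.
#'
#' @param intensity linear-scale probes x arrays intensity matrix.
#' @param probes probe data.frame with zones assigned.
#' @param regions region data.frame.
#' @param samples sample sheet.
#' @param window smoothing window.
#' @param ... passed to [call_expressed()].
#' @return list: `probe_mat` (normalized smoothed log2 matrix), `tucr` (all
#'   transcript summaries), `expressed_call` (result of [call_expressed()]),
#'   `tucr_expressed` (summaries restricted to retained transcripts),
#'   `state` (processing flags).
#' @export
preprocess_intensities <- function(intensity, probes, regions, samples,
                                   window = 3, ...) {
  if (any(intensity < 0)) stop("negative intensities", call. = FALSE)
  mat <- log2(intensity)
  mat <- quantile_normalize(mat)
  mat <- smooth_tracks(mat, probes, window)
  tucr <- summarize_tucrs(mat, probes, regions)
  call <- call_expressed(tucr, samples, ...)
  list(probe_mat = mat, tucr = tucr, expressed_call = call,
       tucr_expressed = call$tucr,
       state = c(raw = FALSE, quantile_normalized = TRUE, smoothed = TRUE))
}
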