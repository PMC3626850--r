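#' @title T-UCR / host-gene correlation analysis
#' @name hostcorr
#' @description
#' Intragenic T-UCRs are scored for co-expression with their host gene:
#' Pearson correlation between the transcript summary (mean core-probe
#' value) and the host-gene expression (mean of exonic probe values inside
#' the tiled window) over the experimental arrays. Significance comes from
#' the exact t transform of r on n - 2 degrees of freedom, the closed-form
#' equivalent of a critical-value table. Transcripts whose window contains
#' no host exon probe are reported as `no_data`. The anti-correlation screen
#' (transcriptional-interference candidates) keeps significantly negative
#' correlations.
NULL

#' Host-gene expression from exonic probes
#'
#' @param probe_mat normalized smoothed log2 probe matrix.
#' @param exon_map probe-to-gene map from [exon_probe_map()].
#' @return genes x arrays matrix of mean exonic probe values; genes without
#'   exonic probes are simply absent (callers flag them `no_data`).
#' @export
host_exon_expression <- function(probe_mat, exon_map) {
  if (nrow(exon_map) == 0L)
    return(matrix(numeric(0), 0, ncol(probe_mat),
                  dimnames = list(NULL, colnames(probe_mat))))
  sums <- rowsum(probe_mat[exon_map$probe_id, , drop = FALSE], exon_map$gene)
  cnt <- as.vector(table(exon_map$gene)[rownames(sums)])
  sums / cnt
}

#' Pearson correlation with exact significance
#'
#' `t = r sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom, two-tailed.
#'
#' @param x,y numeric vectors of equal length n >= 3 with nonzero variance.
#' @return list with elements `r`, `p`, `n`.
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance series", call. = FALSE)
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Correlation screen over intragenic transcripts
#'
#' @param tucr a `tucr_summary` (typically the expressed subset or all
#'   transcripts; intergenic and unclassified transcripts are excluded).
#' @param host_expr genes x arrays matrix from [host_exon_expression()].
#' @param alpha two-tailed significance threshold.
#' @return data.frame: transcript_id, host_gene, corr_class, r, n, p, flag
#'   (`sig_correlated`, `sig_anticorrelated`, `not_correlated`, `no_data`).
#' @export
correlation_screen <- function(tucr, host_expr, alpha = 0.05) {
  info <- tucr$info
  idx <- which(info$region_class %in% INTRAGENIC_CLASSES)
  if (!length(idx))
    return(data.frame(transcript_id = character(0), host_gene = character(0),
                      corr_class = character(0), r = numeric(0),
                      n = integer(0), p = numeric(0), flag = character(0),
                      stringsAsFactors = FALSE))
  rows <- lapply(idx, function(i) {
    g <- info$host_gene[i]
    cls <- hostcorr_class(info$region_class[i], info$orientation[i])
    if (!g %in% rownames(host_expr)) {
      return(data.frame(transcript_id = info$transcript_id[i], host_gene = g,
                        corr_class = cls, r = NA_real_, n = NA_integer_,
                        p = NA_real_, flag = "no_data",
                        stringsAsFactors = FALSE))
    }
    x <- tucr$mat[info$transcript_id[i], ]
    y <- host_expr[g, colnames(tucr$mat)]
    res <- pearson_with_p(x, y)
    flag <- if (res$p < alpha && res$r > 0) "sig_correlated"
    else if (res$p < alpha && res$r < 0) "sig_anticorrelated"
    else "not_correlated"
    data.frame(transcript_id = info$transcript_id[i], host_gene = g,
               corr_class = cls, r = res$r, n = res$n, p = res$p,
               flag = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-class summaries of the correlation screen
#'
#' Median correlation and fraction significant (p < alpha) per class;
#' classes with no scored transcript are absent from the output rather than
#' reported as zero.
#'
#' @param results data.frame from [correlation_screen()].
#' @param alpha significance threshold used for the fraction.
#' @return data.frame: corr_class, n, median_r, pct_significant (percent).
#' @export
summarize_hostcorr <- function(results, alpha = 0.05) {
  scored <- results[results$flag != "no_data", , drop = FALSE]
  if (nrow(scored) == 0L)
    return(data.frame(corr_class = character(0), n = integer(0),
                      median_r = numeric(0), pct_significant = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(split(scored, scored$corr_class), function(g)
    data.frame(corr_class = g$corr_class[1], n = nrow(g),
               median_r = stats::median(g$r),
               pct_significant = 100 * mean(g$p < alpha),
               stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Anti-correlation (transcriptional interference) screen
#'
#' @param results data.frame from [correlation_screen()].
#' @return rows with flag `sig_anticorrelated`, sorted by r ascending.
#' @export
anticorrelation_screen <- function(results) {
  out <- results[results$flag == "sig_anticorrelated", , drop = FALSE]
  out <- out[order(out$r), , drop = FALSE]
  rownames(out) <- NULL
  out
}
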