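#' @title ATRA differential-expression calling for T-UCRs
#' @name diffexpr
#' @description
#' Fold changes are computed per biological repeat (treated over untreated
#' within the matched repeat of a cell line), summarized per line as the
#' geometric mean of the two repeat folds, and passed through the filter
#' cascade: at least 1.5-fold in the same direction in 2 of 3 cell lines and
#' in at least 4 of the 6 repeat-level folds, with a two-tailed Student
#' t-test across the six matched sample pairs below alpha. No multiple-
#' testing correction is applied by default (raw p < 0.05), with a
#' Benjamini-Hochberg option behind the config.
NULL

#' Differential-expression configuration
#'
#' @param fold_threshold linear fold threshold (> 1).
#' @param min_lines cell lines that must pass (of 3).
#' @param min_repeats repeat-level folds that must pass (of 6).
#' @param alpha t-test significance level.
#' @param paired paired (within-repeat) or unpaired equal-variance t-test.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @export
de_config <- function(fold_threshold = 1.5, min_lines = 2, min_repeats = 4,
                      alpha = 0.05, paired = TRUE, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(fold_threshold > 1, min_lines >= 1, min_lines <= 3,
            alpha > 0, alpha < 1)
  structure(list(fold_threshold = fold_threshold, min_lines = min_lines,
                 min_repeats = min_repeats, alpha = alpha, paired = paired,
                 p_adjust = p_adjust), class = "de_config")
}

match_pairs <- function(samples) {
  key <- paste(samples$cell_line, samples[["repeat"]], sep = "_r")
  out <- lapply(unique(key), function(k) {
    s <- samples[key == k, , drop = FALSE]
    tr <- s$array_id[s$treatment == "ATRA"]
    un <- s$array_id[s$treatment == "untreated"]
    if (length(tr) != 1L || length(un) != 1L)
      stop("repeat ", k, " must have exactly one treated and one untreated ",
           "array", call. = FALSE)
    data.frame(pair = k, cell_line = s$cell_line[1], treated = tr,
               untreated = un, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-repeat fold changes
#'
#' Linear fold of a transcript in one biological repeat:
#' `2^(log2 treated - log2 untreated)` within the matched repeat.
#'
#' @param tucr a `tucr_summary` (log2 values).
#' @param samples sample sheet.
#' @return transcripts x 6 matrix of linear folds, columns named by
#'   line/repeat.
#' @export
per_repeat_folds <- function(tucr, samples) {
  pairs <- match_pairs(samples)
  folds <- 2^(tucr$mat[, pairs$treated, drop = FALSE] -
                tucr$mat[, pairs$untreated, drop = FALSE])
  colnames(folds) <- pairs$pair
  folds
}

#' Per-line fold changes
#'
#' The line fold is the geometric mean of that line's two repeat folds
#' (equivalently the mean on the log scale, matching multiplicative data).
#'
#' @param repeat_folds matrix from [per_repeat_folds()].
#' @param samples sample sheet (maps repeat columns to lines).
#' @return transcripts x lines matrix of linear folds.
#' @export
per_line_folds <- function(repeat_folds, samples) {
  if (any(repeat_folds <= 0)) stop("nonpositive fold", call. = FALSE)
  pairs <- match_pairs(samples)
  lines <- unique(pairs$cell_line)
  out <- vapply(lines, function(l) {
    cols <- pairs$pair[pairs$cell_line == l]
    exp(rowMeans(log(repeat_folds[, cols, drop = FALSE])))
  }, numeric(nrow(repeat_folds)))
  out
}

#' Fold-change filter cascade
#'
#' A line passes "up" iff its fold is at or above the threshold, "down" iff
#' at or below its reciprocal; the call direction is the majority direction
#' among passing lines (ambiguous rows fail). A transcript passes iff at
#' least `min_lines` lines and `min_repeats` repeat folds pass in the call
#' direction.
#'
#' @param line_folds transcripts x 3 matrix.
#' @param repeat_folds transcripts x 6 matrix.
#' @param config a [de_config()].
#' @return data.frame: transcript, direction, lines_passing,
#'   repeats_passing, passes_filter, ambiguous.
#' @export
de_filter <- function(line_folds, repeat_folds, config = de_config()) {
  if (any(line_folds <= 0) || any(repeat_folds <= 0))
    stop("folds must be positive", call. = FALSE)
  thr <- config$fold_threshold
  up_l <- rowSums(line_folds >= thr)
  dn_l <- rowSums(line_folds <= 1 / thr)
  direction <- ifelse(up_l > dn_l, "up", ifelse(dn_l > up_l, "down", NA))
  ambiguous <- up_l == dn_l & (up_l + dn_l) > 0
  up_r <- rowSums(repeat_folds >= thr)
  dn_r <- rowSums(repeat_folds <= 1 / thr)
  lines_passing <- ifelse(is.na(direction), 0L,
                          ifelse(direction == "up", up_l, dn_l))
  repeats_passing <- ifelse(is.na(direction), 0L,
                            ifelse(direction == "up", up_r, dn_r))
  passes <- !is.na(direction) & lines_passing >= config$min_lines &
    repeats_passing >= config$min_repeats
  data.frame(transcript_id = rownames(line_folds) %||%
               seq_len(nrow(line_folds)),
             direction = direction, lines_passing = lines_passing,
             repeats_passing = repeats_passing, passes_filter = passes,
             ambiguous = ambiguous, stringsAsFactors = FALSE)
}

#' Student's t-test, treated versus untreated
#'
#' Two-tailed test on the six matched (treated, untreated) log2 pairs of
#' each transcript; paired by default (matching the repeat structure), with
#' an unpaired equal-variance option. Degenerate zero-variance differences
#' are reported as p = 1 when all differences are zero and as the limit 0
#' otherwise, with a warning.
#'
#' @param tucr a `tucr_summary` (log2 values).
#' @param samples sample sheet.
#' @param paired paired or unpaired equal-variance test.
#' @return named numeric vector of p-values in (0, 1].
#' @export
ttest_treated_vs_untreated <- function(tucr, samples, paired = TRUE) {
  pairs <- match_pairs(samples)
  tr <- tucr$mat[, pairs$treated, drop = FALSE]
  un <- tucr$mat[, pairs$untreated, drop = FALSE]
  degenerate <- FALSE
  p <- vapply(seq_len(nrow(tr)), function(i) {
    x <- tr[i, ]; y <- un[i, ]
    if (paired) {
      d <- x - y
      if (stats::sd(d) == 0) {
        degenerate <<- TRUE
        return(if (all(d == 0)) 1 else 0)
      }
      stats::t.test(x, y, paired = TRUE)$p.value
    } else {
      if (stats::sd(x) == 0 && stats::sd(y) == 0) {
        degenerate <<- TRUE
        return(if (all(x == y)) 1 else 0)
      }
      stats::t.test(x, y, var.equal = TRUE)$p.value
    }
  }, numeric(1))
  if (degenerate)
    warning("zero-variance transcript(s): degenerate p reported as 0/1")
  names(p) <- rownames(tr)
  p
}

#' Build the ranked differential-expression table
#'
#' Combines folds, filter and t-test into a table shaped like the published
#' result: rows passing the cascade at p below alpha, up-regulated block
#' first, ascending p within block.
#'
#' @param tucr a `tucr_summary` of expressed transcripts (log2 values).
#' @param samples sample sheet.
#' @param config a [de_config()].
#' @return data.frame with per-line folds, annotation, direction, filter
#'   counts and p-value; one row per passing transcript.
#' @export
build_de_table <- function(tucr, samples, config = de_config()) {
  rf <- per_repeat_folds(tucr, samples)
  lf <- per_line_folds(rf, samples)
  filt <- de_filter(lf, rf, config)
  p <- ttest_treated_vs_untreated(tucr, samples, paired = config$paired)
  if (config$p_adjust == "BH") p <- stats::p.adjust(p, "BH")
  info <- tucr$info
  out <- data.frame(transcript_id = info$transcript_id,
                    lf,
                    region_class = info$region_class,
                    orientation = info$orientation,
                    host_gene = info$host_gene,
                    direction = filt$direction,
                    lines_passing = filt$lines_passing,
                    repeats_passing = filt$repeats_passing,
                    p_value = unname(p[info$transcript_id]),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out <- out[filt$passes_filter & out$p_value < config$alpha, , drop = FALSE]
  out <- out[order(match(out$direction, c("up", "down")), out$p_value), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
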