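#' @title Gene-level differential expression and list overlap
#' @name overlap
#' @description
#' Gene expression arrays use a stricter two-repeat rule: a gene is called
#' up (down) iff its fold change is at least 1.5 (at most 1/1.5) in both
#' biological repeats. The overlap stage intersects two such call tables
#' direction-matched (up/up and down/down), optionally with a hypergeometric
#' enrichment p against a stated gene universe.
NULL

#' Gene-level differential-expression calls
#'
#' @param expr genes x arrays matrix (linear scale, or log2 with
#'   `log2 = TRUE`).
#' @param samples sample sheet with array_id, condition (`ctrl`/`test`) and
#'   `repeat` columns; each repeat needs exactly one ctrl and one test array.
#' @param threshold linear fold threshold.
#' @param log2 whether `expr` is already log2.
#' @return data.frame: gene, per-repeat folds, mean_fold (geometric mean),
#'   direction, passes.
#' @export
gene_de <- function(expr, samples, threshold = 1.5, log2 = FALSE) {
  reps <- sort(unique(samples[["repeat"]]))
  folds <- vapply(reps, function(r) {
    s <- samples[samples[["repeat"]] == r, , drop = FALSE]
    te <- s$array_id[s$condition == "test"]
    ct <- s$array_id[s$condition == "ctrl"]
    if (length(te) != 1L || length(ct) != 1L)
      stop("repeat ", r, " must have exactly one ctrl and one test array",
           call. = FALSE)
    if (log2) 2^(expr[, te] - expr[, ct]) else expr[, te] / expr[, ct]
  }, numeric(nrow(expr)))
  colnames(folds) <- paste0("fold_r", reps)
  up <- rowSums(folds >= threshold) == length(reps)
  down <- rowSums(folds <= 1 / threshold) == length(reps)
  data.frame(gene = rownames(expr), folds,
             mean_fold = exp(rowMeans(log(folds))),
             direction = ifelse(up, "up", ifelse(down, "down", NA)),
             passes = up | down, stringsAsFactors = FALSE)
}

#' Direction-matched overlap of two gene call tables
#'
#' @param a,b data.frames from [gene_de()].
#' @param universe optional gene-universe size for hypergeometric p-values
#'   (must be at least the union of called genes).
#' @return list: per-list up/down sizes, intersection gene vectors and
#'   counts, and (if `universe` given) hypergeometric p for each direction.
#' @export
overlap_lists <- function(a, b, universe = NULL) {
  pick <- function(tbl, dir) tbl$gene[!is.na(tbl$direction) &
                                        tbl$direction == dir]
  a_up <- pick(a, "up"); a_down <- pick(a, "down")
  b_up <- pick(b, "up"); b_down <- pick(b, "down")
  up_common <- intersect(a_up, b_up)
  down_common <- intersect(a_down, b_down)
  out <- list(n_a_up = length(a_up), n_a_down = length(a_down),
              n_b_up = length(b_up), n_b_down = length(b_down),
              up_overlap = up_common, down_overlap = down_common,
              n_up_overlap = length(up_common),
              n_down_overlap = length(down_common))
  if (!is.null(universe)) {
    union_n <- length(unique(c(a_up, a_down, b_up, b_down)))
    if (universe < union_n)
      stop("universe smaller than the union of called genes", call. = FALSE)
    hyper <- function(k, K, n)
      stats::phyper(k - 1, K, universe - K, n, lower.tail = FALSE)
    out$p_up <- hyper(length(up_common), length(b_up), length(a_up))
    out$p_down <- hyper(length(down_common), length(b_down), length(a_down))
  }
  out
}
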