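test_that("quantile normalization matches hand-computed and brute-force oracles", {
  m <- cbind(a = c(2, 4, 6), b = c(1, 3, 5))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, "a"]), c(1.5, 3.5, 5.5))
  expect_equal(unname(qn[, "b"]), c(1.5, 3.5, 5.5))

  # identical column multisets are left unchanged (up to reordering ranks)
  m2 <- cbind(x = c(3, 1, 2), y = c(1, 2, 3))
  expect_equal(quantile_normalize(m2), m2)

  set.seed(1)
  r <- matrix(rnorm(20 * 6), 20, 6)
  qr <- quantile_normalize(r)
  expect_equal(qr, oracle_quantile_normalize(r), tolerance = 1e-9)
  # all columns share the same sorted values and equal means
  sorted <- apply(qr, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-12))
  expect_equal(max(colMeans(qr)) - min(colMeans(qr)), 0, tolerance = 1e-12)
  # ranks preserved within each column
  for (j in 1:6) expect_equal(rank(qr[, j]), rank(r[, j]))

  # ties receive the mean of the reference values over their rank span
  mt <- cbind(c(1, 2, 2, 5), c(1, 2, 3, 4))
  expect_equal(quantile_normalize(mt), oracle_quantile_normalize(mt),
               tolerance = 1e-12)

  expect_error(quantile_normalize(matrix(1:3)), "at least 2")
  expect_error(quantile_normalize(cbind(c(1, 1, 1), c(1, 2, 3))),
               "all-constant")
})

test_that("quantile normalization is idempotent and agrees with limma on tie-free input", {
  set.seed(7)
  r <- matrix(rexp(15 * 4), 15, 4)
  once <- quantile_normalize(r)
  expect_equal(quantile_normalize(once), once, tolerance = 1e-12)
  skip_if_not_installed("limma")
  expect_equal(unname(once), unname(limma::normalizeQuantiles(r)),
               tolerance = 1e-9)
})

test_that("median smoothing applies the truncated-window boundary rule", {
  expect_equal(median_smooth(c(5, 5, 5, 5)), c(5, 5, 5, 5))
  expect_equal(median_smooth(c(1, 100, 2, 3)), c(50.5, 2, 3, 2.5))

  # brute-force: an isolated spike in a constant track is removed everywhere
  # except possibly the boundary positions
  for (pos in 1:10) {
    x <- rep(2, 10); x[pos] <- 50
    sm <- median_smooth(x)
    interior <- setdiff(seq_len(10), c(1, 10))
    expect_true(all(sm[interior] == 2))
  }

  # oracle equivalence on random tracks, vector and matrix paths
  set.seed(3)
  for (n in c(1, 2, 3, 7, 12)) {
    x <- rnorm(n)
    expect_equal(median_smooth(x), oracle_median_smooth(x), tolerance = 1e-12)
  }
  m <- matrix(rnorm(12 * 4), 12, 4)
  sm <- median_smooth(m)
  for (j in 1:4) expect_equal(sm[, j], oracle_median_smooth(m[, j]),
                              tolerance = 1e-12)
  # window-5 generic path
  x <- rnorm(9)
  expect_equal(median_smooth(x, 5), oracle_median_smooth(x, 5),
               tolerance = 1e-12)

  # smoothing never widens the value range
  expect_true(all(sm >= min(m) & sm <= max(m)))
  expect_equal(median_smooth(numeric(0)), numeric(0))
  expect_error(median_smooth(1:5, window = 4), "odd")
})

test_that("track smoothing respects genomic order within region and container", {
  regions <- toy_regions()[1, , drop = FALSE]
  probes <- assign_zones(tile_region(regions, gc = 0.5), regions)
  mat <- matrix(rnorm(nrow(probes) * 2), nrow(probes), 2,
                dimnames = list(probes$probe_id, c("a1", "a2")))
  sm <- smooth_tracks(mat, probes)
  for (cont in c("plus", "minus")) {
    sel <- probes$container == cont
    ord <- order(probes$start[sel])
    ids <- probes$probe_id[sel][ord]
    expect_equal(sm[ids, 1], stats::setNames(
      oracle_median_smooth(mat[ids, 1]), ids), tolerance = 1e-12)
  }
})

test_that("transcript summaries average core probes of the matching container", {
  sim <- quiet_sim(n_regions = 6, n_de_up = 0, n_de_down = 0, seed = 1)
  mat <- log2(sim$intensity)
  tucr <- summarize_tucrs(mat, sim$probes, sim$regions)
  expect_equal(nrow(tucr$mat), 2 * nrow(sim$regions))
  # manual check for one transcript
  t1 <- tucr$info$transcript_id[1]
  p1 <- sim$probes[sim$probes$region == tucr$info$region[1] &
                     sim$probes$container == tucr$info$container[1] &
                     sim$probes$zone == "core", "probe_id"]
  expect_equal(unname(tucr$mat[t1, ]), unname(colMeans(mat[p1, ])),
               tolerance = 1e-12)
  # constant core values summarize to that constant
  mat2 <- mat; mat2[p1, ] <- 7
  tucr2 <- summarize_tucrs(mat2, sim$probes, sim$regions)
  expect_equal(unname(tucr2$mat[t1, ]), rep(7, 12))
  # summaries are invariant to probe row order
  perm <- sample(nrow(sim$probes))
  tucr3 <- summarize_tucrs(mat, sim$probes[perm, ], sim$regions)
  expect_equal(tucr3$mat[rownames(tucr$mat), ], tucr$mat, tolerance = 1e-12)
})

test_that("expression calling uses the per-array median background and the all-lines rule", {
  samples <- study_sample_sheet()
  n <- 11
  base <- matrix(rep(seq_len(n), 12), n, 12,
                 dimnames = list(paste0("t", seq_len(n)), samples$array_id))
  info <- data.frame(transcript_id = paste0("t", seq_len(n)))
  tucr <- structure(list(mat = base, info = info, missing = character(0)),
                    class = "tucr_summary")
  call <- call_expressed(tucr, samples)
  expect_equal(unname(call$background), rep(6, 12))
  # transcripts strictly above the median on every array are retained,
  # those at or below on all arrays are dropped
  expect_true(all(call$keep[7:11]))
  expect_false(any(call$keep[1:6]))

  # expressed in only 2 of 3 lines -> dropped
  m2 <- base
  m2["t7", samples$array_id[samples$cell_line == "SHSY5Y"]] <- 1
  tucr2 <- structure(list(mat = m2, info = info, missing = character(0)),
                     class = "tucr_summary")
  call2 <- call_expressed(tucr2, samples)
  expect_false(call2$keep["t7"])
  # ... but a single above-background array in that line rescues it ("any")
  m3 <- m2
  m3["t7", samples$array_id[samples$cell_line == "SHSY5Y"][1]] <- 10
  tucr3 <- structure(list(mat = m3, info = info, missing = character(0)),
                     class = "tucr_summary")
  expect_true(call_expressed(tucr3, samples)$keep["t7"])
  # under the "all" rule it stays dropped
  expect_false(call_expressed(tucr3, samples, per_line_rule = "all")$keep["t7"])

  expect_error(call_expressed(tucr, samples[samples$cell_line != "LAN5", ]),
               "3 cell lines")
})
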