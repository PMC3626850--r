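test_that("host exon expression averages exonic probe values per gene and array", {
  mat <- matrix(1:12, 3, 4,
                dimnames = list(c("p1", "p2", "p3"), paste0("a", 1:4)))
  emap <- data.frame(probe_id = c("p1", "p3"), gene = "G1",
                     stringsAsFactors = FALSE)
  h <- host_exon_expression(mat, emap)
  expect_equal(unname(h["G1", ]), unname(colMeans(mat[c("p1", "p3"), ])))
  # two probes with values 1 and 3 average to 2
  m2 <- matrix(c(1, 3), 2, 1, dimnames = list(c("p1", "p2"), "a1"))
  e2 <- data.frame(probe_id = c("p1", "p2"), gene = "G")
  expect_equal(unname(host_exon_expression(m2, e2)["G", ]), 2)
  # no exonic probes -> empty matrix
  expect_equal(nrow(host_exon_expression(mat, e2[0, ])), 0)
})

test_that("pearson_with_p matches cor.test and respects its invariants", {
  set.seed(21)
  x <- rnorm(12); y <- rnorm(12)
  res <- pearson_with_p(x, y)
  ct <- cor.test(x, y)
  expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res$p, ct$p.value, tolerance = 1e-9)

  expect_equal(pearson_with_p(x, x)$r, 1)
  expect_equal(pearson_with_p(x, -x)$r, -1)
  expect_equal(pearson_with_p(x, -x)$p, 0)

  # n = 12, r = 0.576 sits at the p = 0.05 critical boundary
  r_target <- 0.576
  u <- as.numeric(scale(1:12))
  v <- as.numeric(scale(resid(lm(rnorm(12) ~ u))))  # orthogonal to u
  yy <- r_target * u / sd(u) + sqrt(1 - r_target^2) * v / sd(v)
  res2 <- pearson_with_p(u, yy)
  expect_equal(res2$r, r_target, tolerance = 1e-9)
  expect_equal(res2$p, 0.0500, tolerance = 5e-3)

  # symmetry and positive-affine invariance
  expect_equal(pearson_with_p(x, y)$r, pearson_with_p(y, x)$r)
  expect_equal(pearson_with_p(2 * x + 3, y)$r, res$r, tolerance = 1e-12)
  expect_equal(pearson_with_p(2 * x + 3, y)$p, res$p, tolerance = 1e-12)

  # p decreases monotonically in |r| at fixed n
  rs <- seq(0.1, 0.9, by = 0.1)
  ps <- sapply(rs, function(r) {
    t <- r * sqrt(10 / (1 - r^2)); 2 * pt(-abs(t), 10)
  })
  expect_true(all(diff(ps) < 0))

  expect_error(pearson_with_p(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_with_p(rnorm(2), rnorm(2)), "n >= 3")
  expect_error(pearson_with_p(rnorm(5), rnorm(4)), "equal length")
})

test_that("the correlation screen recovers planted class structure", {
  sim <- quiet_sim(n_regions = 150, n_de_up = 0, n_de_down = 0, seed = 31,
                   host_exon_prob = 1)
  prep <- quiet_preprocess(sim)
  emap <- suppressMessages(exon_probe_map(sim$probes, sim$exons, sim$regions))
  host <- host_exon_expression(prep$probe_mat, emap)
  scr <- correlation_screen(prep$tucr, host)
  # only intragenic transcripts are scored, intergenic never appear
  expect_true(all(scr$transcript_id %in% sim$truth$transcript_id[
    sim$truth$region_class %in% c("intronic", "exonic", "partly_exonic")]))
  sm <- summarize_hostcorr(scr)
  es <- sm$median_r[sm$corr_class == "exonic_sense"]
  ia <- sm$median_r[sm$corr_class == "intronic_antisense"]
  # planted ordering: sense exonic correlates far more than antisense intronic
  expect_gt(es, ia + 0.2)
  expect_gt(sm$pct_significant[sm$corr_class == "exonic_sense"],
            sm$pct_significant[sm$corr_class == "intronic_antisense"])
})

test_that("transcripts without host exon coverage are flagged no_data", {
  sim <- quiet_sim(n_regions = 40, n_de_up = 0, n_de_down = 0, seed = 32,
                   host_exon_prob = 0)
  prep <- quiet_preprocess(sim)
  emap <- suppressMessages(exon_probe_map(sim$probes, sim$exons, sim$regions))
  host <- host_exon_expression(prep$probe_mat, emap)
  scr <- correlation_screen(prep$tucr, host)
  expect_true(all(scr$flag == "no_data"))
  expect_equal(nrow(summarize_hostcorr(scr)), 0)
  expect_equal(nrow(anticorrelation_screen(scr)), 0)
})

test_that("the anti-correlation screen detects planted negative correlation", {
  sim <- quiet_sim(n_regions = 60, n_de_up = 0, n_de_down = 0, seed = 33,
                   host_exon_prob = 1, noise_sd = 0.05, line_sd = 0.02,
                   rho_by_class = c(exonic_sense = -0.95,
                                    exonic_antisense = -0.95,
                                    intronic_sense = -0.95,
                                    intronic_antisense = -0.95))
  prep <- quiet_preprocess(sim)
  emap <- suppressMessages(exon_probe_map(sim$probes, sim$exons, sim$regions))
  host <- host_exon_expression(prep$probe_mat, emap)
  scr <- correlation_screen(prep$tucr, host)
  anti <- anticorrelation_screen(scr)
  scored <- scr[scr$flag != "no_data", ]
  expect_gt(nrow(anti) / nrow(scored), 0.9)
  expect_true(all(anti$r < 0 & anti$p < 0.05))
  expect_true(all(diff(anti$r) >= 0))   # sorted ascending by r
})

test_that("null host correlation yields roughly the nominal anti-correlated rate", {
  hits <- total <- 0
  for (s in 1:3) {
    sim <- quiet_sim(n_regions = 80, n_de_up = 0, n_de_down = 0, seed = 40 + s,
                     host_exon_prob = 1,
                     rho_by_class = c(exonic_sense = 0, exonic_antisense = 0,
                                      intronic_sense = 0,
                                      intronic_antisense = 0))
    prep <- quiet_preprocess(sim)
    emap <- suppressMessages(exon_probe_map(sim$probes, sim$exons, sim$regions))
    host <- host_exon_expression(prep$probe_mat, emap)
    scr <- correlation_screen(prep$tucr, host)
    scored <- scr[scr$flag != "no_data", ]
    hits <- hits + sum(scored$flag == "sig_anticorrelated")
    total <- total + nrow(scored)
  }
  # two-sided alpha = 0.05 leaves ~2.5% in the negative tail; allow slack for
  # the reduced effective sample size of the repeat-shared design
  expect_lt(hits / total, 0.09)
  expect_gt(total, 200)
})
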