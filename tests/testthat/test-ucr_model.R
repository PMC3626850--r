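test_that("region reading validates, round-trips, and flags problems", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "chrom\tstart\tend\tid\tregion_class\thost_gene\thost_strand\torientation",
    "chr10\t102505468\t102505940\tuc.300a\tintronic\tPAX2\t+\tanti-sense",
    "chr1\t1000\t1400\tuc.1\tintergenic\t0\t0\t0"), f)
  r <- read_regions(f)
  expect_equal(nrow(r), 2)
  expect_equal(r$id[1], "uc.300a")
  expect_equal(r$region_class[1], "intronic")
  expect_equal(r$host_gene[1], "PAX2")
  expect_true(is.na(r$host_gene[2]))

  # round trip is bit-exact on coordinates and classes
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_regions(r, f2)
  r2 <- read_regions(f2)
  expect_identical(r2[, c("chrom", "start", "end", "id", "region_class")],
                   r[, c("chrom", "start", "end", "id", "region_class")])

  # empty file -> empty result with a warning
  writeLines(character(0), f2)
  expect_warning(r0 <- read_regions(f2), "no region rows")
  expect_equal(nrow(r0), 0)

  # degenerate interval and duplicate ids are rejected by name
  bad <- r; bad$end[1] <- bad$start[1]
  expect_error(validate_regions(bad), "uc\\.300a")
  dup <- rbind(r, r[1, ])
  expect_error(validate_regions(dup), "duplicate.*uc\\.300a")

  # short regions warn but survive, flagged
  short <- r; short$end[2] <- short$start[2] + 150
  expect_warning(rs <- validate_regions(short), "shorter than 200")
  expect_true(rs$short[2])
})

test_that("tiling covers the window with Tm-matched probes in both containers", {
  reg <- toy_regions()[2, ]       # length 250 -> window 3250
  reg$end <- reg$start + 200      # length 200 -> window 3200
  probes <- tile_region(reg, step = 45, tm_target = 76, gc = 0.5)
  per_cont <- split(probes, probes$container)
  expect_equal(nrow(per_cont$plus), ceiling(3200 / 45) + 1)
  expect_equal(nrow(per_cont$minus), nrow(per_cont$plus))
  expect_true(all(probes$length >= 50 & probes$length <= 72))
  # identical coordinates in both containers
  expect_equal(per_cont$plus$start, per_cont$minus$start)
  expect_equal(per_cont$plus$length, per_cont$minus$length)
  # uniform GC -> constant length (Tm depends on length only)
  expect_equal(length(unique(probes$length)), 1)
  # probes stay inside the window
  expect_true(all(probes$start >= probes$window_start))
  expect_true(all(probes$start + probes$length <= probes$window_end))
  # brute-force coverage: every core base covered by >= 1 probe per container
  for (p in per_cont) {
    covered <- rep(FALSE, reg$end - reg$start)
    for (i in seq_len(nrow(p))) {
      rel <- seq(p$start[i], p$start[i] + p$length[i] - 1) - reg$start + 1
      rel <- rel[rel >= 1 & rel <= length(covered)]
      covered[rel] <- TRUE
    }
    expect_true(all(covered))
  }
  # determinism
  expect_identical(probes, tile_region(reg, step = 45, tm_target = 76, gc = 0.5))
})

test_that("Tm model selects lengths that approach the target", {
  reg <- toy_regions()[1, ]
  set.seed(42)
  gc <- runif(reg$end - reg$start + 3000) < 0.7
  probes <- tile_region(reg, step = 45, tm_target = 76, gc = gc)
  expect_true(all(probes$length >= 50 & probes$length <= 72))
  # chosen Tm must be the closest achievable at the probe's start
  p1 <- probes[5, ]
  cs <- c(0, cumsum(as.numeric(gc)))
  cand <- sapply(50:72, function(L) {
    s <- min(p1$start - p1$window_start, (p1$window_end - p1$window_start) - L)
    probe_tm(cs[s + L + 1] - cs[s + 1], L)
  })
  expect_equal(abs(p1$tm - 76), min(abs(cand - 76)), tolerance = 1e-9)
})

test_that("zone assignment follows the midpoint rule, oriented by host strand", {
  reg <- toy_regions()[2, ]   # host strand +
  probes <- tile_region(reg, gc = 0.5)
  probes <- assign_zones(probes, reg)
  mid <- probes$start + probes$length / 2
  expect_true(all((probes$zone == "core") ==
                    (mid >= reg$start & mid < reg$end)))
  expect_true(all(probes$zone[mid < reg$start] == "upstream_flank"))
  expect_true(all(probes$zone[mid >= reg$end] == "downstream_flank"))

  # minus host strand flips the flank labels
  regm <- toy_regions()[3, ]
  pm <- assign_zones(tile_region(regm, gc = 0.5), regm)
  midm <- pm$start + pm$length / 2
  expect_true(all(pm$zone[midm < regm$start] == "downstream_flank"))
  expect_true(all(pm$zone[midm >= regm$end] == "upstream_flank"))

  # zero flank -> every probe is core
  reg0 <- toy_regions()[1, ]
  p0 <- assign_zones(tile_region(reg0, gc = 0.5, upstream = 0, downstream = 0),
                     reg0)
  expect_true(all(p0$zone == "core"))

  # probe outside the window is an error
  bad <- probes; bad$start[1] <- bad$window_start[1] - 100
  expect_error(assign_zones(bad, reg), "outside tiled window")
})

test_that("exon-probe mapping requires >=1 bp overlap on the host strand", {
  regions <- toy_regions()
  probes <- tile_regions(regions, gc = 0.5)
  emap <- suppressMessages(exon_probe_map(probes, toy_exons(), regions))
  expect_true(all(emap$gene %in% c("HGB", "HGC")))
  p <- probes[match(emap$probe_id, probes$probe_id), ]
  # overlap >= 1 base with the gene's exon
  ex <- toy_exons()
  for (i in seq_len(nrow(p))) {
    e <- ex[ex$gene == emap$gene[i], ]
    expect_true(p$start[i] < e$end && p$start[i] + p$length[i] > e$start)
  }
  # container matches the host strand: HGC is on "-", so all its probes minus
  expect_true(all(p$container[emap$gene == "HGC"] == "minus"))
  expect_true(all(p$container[emap$gene == "HGB"] == "plus"))
  # antisense-container probes over the exon are never mapped
  anti <- probes$probe_id[probes$container == "minus" & probes$region == "uc.B"]
  expect_false(any(anti %in% emap$probe_id))
  # gene absent from the annotation -> logged, empty mapping for it
  expect_message(
    emap2 <- exon_probe_map(probes, toy_exons()[1, , drop = FALSE], regions),
    "HGC")
  expect_false("HGC" %in% emap2$gene)
})

test_that("exon validation merges overlapping exons per gene", {
  ex <- data.frame(gene = "G", chrom = "chr1", strand = "+",
                   start = c(100, 150, 500), end = c(200, 250, 600),
                   stringsAsFactors = FALSE)
  m <- validate_exons(ex)
  expect_equal(nrow(m), 2)
  expect_equal(m$start, c(100, 500))
  expect_equal(m$end, c(250, 600))
})

test_that("transcript table derives orientation from container and host strand", {
  tt <- transcript_table(toy_regions())
  expect_equal(nrow(tt), 8)
  expect_equal(tt$orientation[tt$region == "uc.B" & tt$container == "plus"],
               "sense")
  expect_equal(tt$orientation[tt$region == "uc.C" & tt$container == "plus"],
               "anti-sense")
  expect_true(all(is.na(tt$orientation[tt$region == "uc.A"])))
})
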