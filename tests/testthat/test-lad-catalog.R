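test_that("LAD partition handles degenerate timecourses", {
  g <- c(chr = 1000)
  s <- interval_set("chr", c(100, 500), c(200, 700), g)
  p <- derive_lad_partition(list(D0 = s, D1 = s, D3 = s))
  expect_equal(iv_as_bed_df(p$clads), iv_as_bed_df(s))
  expect_length(p$vlads, 0)
  d0 <- interval_set("chr", 0, 100, g)
  d1 <- interval_set("chr", 300, 400, g)
  p2 <- derive_lad_partition(list(d0, d1))
  expect_length(p2$clads, 0)
  expect_equal(iv_base_coverage(p2$vlads), 200)
  expect_error(derive_lad_partition(list(s)), "at least 2 timepoints")
})

test_that("LAD partition matches the boolean AND/OR oracle and tiles the genome", {
  set.seed(21)
  for (rep in 1:20) {
    sets <- lapply(1:3, function(i) iv_normalize(rand_intervals(toy_genome)))
    p <- derive_lad_partition(sets)
    bools <- lapply(sets, bool_of)
    all_and <- Reduce(function(x, y) Map(`&`, x, y), bools)
    any_or <- Reduce(function(x, y) Map(`|`, x, y), bools)
    expect_identical(bool_of(p$clads), all_and)
    expect_identical(bool_of(p$vlads), Map(function(o, a) o & !a, any_or, all_and))
    # conservation: the three classes tile the genome
    expect_equal(iv_base_coverage(p$clads) + iv_base_coverage(p$vlads) +
                   iv_base_coverage(p$ilads), sum(toy_genome))
    # monotonicity: one more timepoint can only shrink or keep cLADs
    extra <- iv_normalize(rand_intervals(toy_genome))
    p4 <- derive_lad_partition(c(sets, list(extra)))
    expect_true(iv_base_coverage(p4$clads) <= iv_base_coverage(p$clads))
  }
})

test_that("K4 regions are peak clusters clipped to cLADs", {
  g <- c(chr = 10000)
  clads <- interval_set("chr", 0, 1000, g)
  peaks <- interval_set("chr", 100, 200, g)
  ann <- annotate_clad_regions(clads, peaks, merge_gap = 0)
  expect_equal(iv_as_bed_df(ann$k4_regions),
               data.frame(chrom = "chr", start = 100L, end = 200L))
  expect_equal(iv_as_bed_df(ann$nonk4_regions),
               data.frame(chrom = "chr", start = c(0L, 200L), end = c(100L, 1000L)))
  # a cLAD without peaks is entirely non-K4
  clads2 <- interval_set("chr", c(0, 5000), c(1000, 6000), g)
  ann2 <- annotate_clad_regions(clads2, peaks, merge_gap = 0)
  expect_true(any(iv_as_bed_df(ann2$nonk4_regions)$start == 5000))
  # peaks 5 kb apart merge into one region under a 10 kb gap
  peaks3 <- interval_set("chr", c(1000, 6200), c(1200, 6400), g)
  clads3 <- interval_set("chr", 0, 10000, g)
  ann3 <- annotate_clad_regions(clads3, peaks3, merge_gap = 10000)
  expect_equal(iv_as_bed_df(ann3$k4_regions),
               data.frame(chrom = "chr", start = 1000L, end = 6400L))
  expect_error(annotate_clad_regions(clads, peaks, merge_gap = -1), "non-negative")
})

test_that("region means are length-weighted and respect missing bins", {
  g <- c(chr = 1000)
  tr <- coverage_track(list(chr = rep(2, 10)), g, 100)
  regions <- interval_set("chr", c(0, 250), c(100, 900), g)
  expect_equal(region_mean_signal(tr, regions), c(2, 2))
  # half over a 0-valued bin, half over a 4-valued bin
  tr2 <- coverage_track(list(chr = c(0, 4, rep(NA, 8))), g, 100)
  expect_equal(region_mean_signal(tr2, interval_set("chr", 50, 150, g)), 2)
  # missing bins drop out of the weighting instead of counting as zero
  expect_equal(region_mean_signal(tr2, interval_set("chr", 100, 300, g)), 4)
  expect_true(is.na(region_mean_signal(tr2, interval_set("chr", 300, 500, g))))
  expect_length(region_mean_signal(tr, regions[0]), 0)
})

test_that("region means agree with a per-base averaging oracle", {
  set.seed(5)
  g <- c(chr = 2000)
  vals <- runif(20)
  vals[sample(20, 4)] <- NA
  tr <- coverage_track(list(chr = vals), g, 100)
  per_base <- rep(vals, each = 100)
  for (rep in 1:20) {
    s <- sample(1900, 1)
    e <- s + sample(100, 1)
    expected <- mean(per_base[(s + 1):e], na.rm = TRUE)
    got <- region_mean_signal(tr, interval_set("chr", s, e, g))
    if (is.nan(expected)) expect_true(is.na(got)) else expect_equal(got, expected)
  }
})

test_that("Welch test matches hand evaluation and degenerates correctly", {
  r <- welch_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$t_statistic, -3.674235, tolerance = 1e-6)
  expect_equal(r$dof, 4)
  expect_equal(r$p_value, 0.021312, tolerance = 1e-4)
  same <- c(1, 2, 3, 4)
  r0 <- welch_test(same, same)
  expect_equal(r0$t_statistic, 0)
  expect_equal(r0$p_value, 1)
  set.seed(9)
  a <- rnorm(40); b <- rnorm(35, 0.3)
  h <- welch_hand(a, b)
  r2 <- welch_test(a, b)
  expect_equal(r2$t_statistic, h$t, tolerance = 1e-10)
  expect_equal(r2$dof, h$dof, tolerance = 1e-10)
  expect_equal(r2$p_value, h$p, tolerance = 1e-10)
  expect_error(welch_test(c(1, 1), c(1, 1)), "degenerate")
  expect_error(welch_test(1, c(1, 2)), "n >= 2")
})

test_that("lamin contrast between K4 and non-K4 cLAD regions is recovered", {
  truth <- shared_truth()
  ann <- annotate_clad_regions(truth$partition$clads, truth$peaks$H3K4me1)
  m_k4 <- region_mean_signal(truth$lamin_track, ann$k4_regions)
  m_non <- region_mean_signal(truth$lamin_track, ann$nonk4_regions)
  w <- welch_test(m_k4, m_non)
  expect_lt(w$group_means[1], w$group_means[2])  # K4 regions are lamin-low
  expect_lt(w$p_value, 1e-4)
  # the two region classes tile the cLADs
  expect_equal(iv_base_coverage(ann$k4_regions) + iv_base_coverage(ann$nonk4_regions),
               iv_base_coverage(truth$partition$clads))
})
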