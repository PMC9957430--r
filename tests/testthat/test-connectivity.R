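conn_row <- function(bs, be, ts, te, p, tp = "D0", bc = "chr", tc = "chr") {
  data.frame(bait_chrom = bc, bait_start = bs, bait_end = be,
             target_chrom = tc, target_start = ts, target_end = te,
             p_value = p, timepoint = tp)
}

test_that("connection loading filters on an inclusive p threshold and pools timepoints", {
  g <- c(chr = 10000)
  tab <- rbind(conn_row(0, 100, 500, 600, 0.005),
               conn_row(0, 100, 700, 800, 0.01, tp = "D1"),
               conn_row(200, 300, 900, 1000, 0.02))
  lc <- load_connections(tab, g)
  expect_equal(nrow(lc$connections), 2)  # p = 0.02 dropped, p = 0.01 kept
  expect_length(lc$baits, 1)             # same bait at two timepoints
  expect_equal(sort(lc$connections$timepoint), c("D0", "D1"))
  bad <- conn_row(0, 100, "oops", 600, 0.001)
  expect_error(load_connections(bad, g), "malformed coordinate.*line 1")
})

test_that("cLAD bait selection needs a shared base", {
  g <- c(chr = 10000)
  lads <- lapply(1:2, function(i) interval_set("chr", 1000, 2000, g))
  p <- derive_lad_partition(lads)
  baits <- interval_set("chr", c(1500, 2000, 990), c(1600, 2100, 1001), g)
  S4Vectors::mcols(baits)$bait_id <- c("in", "abut", "edge")
  kept <- baits_in_clads(baits, p)
  # fully inside kept; book-ended at the boundary excluded; 1 bp overlap kept
  expect_setequal(S4Vectors::mcols(kept)$bait_id, c("in", "edge"))
})

test_that("bait classification uses >= 1 bp overlap with peaks inside cLADs", {
  g <- c(chr = 10000)
  clads <- interval_set("chr", 0, 5000, g)
  baits <- interval_set("chr", c(100, 1000, 3000), c(200, 1100, 3100), g)
  S4Vectors::mcols(baits)$bait_id <- c("b1", "b2", "b3")
  # peak overlapping b1 by exactly 1 bp; a peak outside cLADs must not count
  peaks <- interval_set("chr", c(199, 6000), c(250, 6100), g)
  cls <- classify_baits(baits, peaks, clads)
  expect_equal(unname(cls$class_of[c("b1", "b2", "b3")]),
               c("K4", "nonK4", "nonK4"))
  no_peaks <- classify_baits(baits, peaks[0], clads)
  expect_true(all(no_peaks$class_of == "nonK4"))
  expect_equal(length(cls$class_of), 3)  # every cLAD bait classified once
})

test_that("connection density counts zero-connection baits and contrasts classes", {
  g <- c(chr = 10000)
  baits <- interval_set("chr", c(0, 200, 400, 600), c(100, 300, 500, 700), g)
  S4Vectors::mcols(baits)$bait_id <- paste0("b", 1:4)
  cls <- structure(list(class_of = c(b1 = "K4", b2 = "K4", b3 = "nonK4",
                                     b4 = "nonK4"), baits = baits),
                   class = "bait_classification")
  conns <- data.frame(bait_id = c("b1", "b1", "b1", "b2", "b3"),
                      chrom = "chr", start = seq(1000, 5000, 1000),
                      end = seq(1100, 5100, 1000), p_value = 0.001,
                      timepoint = "D0")
  cd <- connection_density(conns, cls)
  expect_equal(cd$per_bait$n_connections, c(3L, 1L, 1L, 0L))
  k4 <- cd$class_stats[cd$class_stats$class == "K4", ]
  expect_equal(k4$mean_connections, 2)
  expect_equal(k4$total_connections, 5 - 1)
  # duplicated targets counted once under the unique-target rule
  conns2 <- rbind(conns, conns[1, ])
  cd2 <- connection_density(conns2, cls)
  expect_equal(cd2$per_bait$n_connections[1], 4L)
  expect_equal(cd2$per_bait$n_unique_targets[1], 3L)
})

test_that("target annotation resolves LAD class by largest overlap with cLAD precedence", {
  g <- c(chr = 10000)
  lads <- list(interval_set("chr", c(0, 2000), c(1000, 3000), g),
               interval_set("chr", c(0, 2000), c(1000, 2500), g))
  p <- derive_lad_partition(lads)  # cLAD [0,1000)+[2000,2500), vLAD [2500,3000)
  peaks <- interval_set("chr", 100, 200, g)
  conns <- data.frame(
    bait_id = "b1", chrom = "chr",
    start = c(5000, 600, 2400, 2450, 150),
    end = c(5100, 1600, 2900, 2550, 250),
    p_value = 0.001, timepoint = "D0")
  ann <- annotate_targets(conns, p, peaks)
  # wholly inter-LAD; 40% cLAD / 60% iLAD -> iLAD; 100/400 cLAD -> vLAD;
  # 50/50 cLAD-vLAD tie -> cLAD precedence; peak overlap -> in_K4_peak
  expect_equal(ann$lad_class, c("iLAD", "iLAD", "vLAD", "cLAD", "cLAD"))
  expect_equal(ann$k4_status, c(rep("outside_K4_peak", 4), "in_K4_peak"))
  ann2 <- annotate_targets(conns, p, peaks, strategy = "any_overlap_priority")
  expect_equal(ann2$lad_class, c("iLAD", "cLAD", "cLAD", "cLAD", "cLAD"))
})

test_that("proportion summary sums to one within bait class", {
  g <- c(chr = 10000)
  baits <- interval_set("chr", 0, 100, g)
  S4Vectors::mcols(baits)$bait_id <- "b1"
  cls <- structure(list(class_of = c(b1 = "K4"), baits = baits),
                   class = "bait_classification")
  ann <- data.frame(bait_id = "b1", chrom = "chr", start = 1, end = 2,
                    p_value = 0, timepoint = "D0",
                    lad_class = "cLAD", k4_status = "in_K4_peak")
  sp <- summarize_proportions(ann, cls)
  expect_equal(sp$prop[sp$class == "K4" & sp$lad_class == "cLAD" &
                         sp$k4_status == "in_K4_peak"], 1)
  expect_equal(sum(sp$n[sp$class == "nonK4"]), 0)
  expect_true(all(is.na(sp$prop[sp$class == "nonK4"])))
})

test_that("generator placement fractions and class rates are recovered", {
  truth <- shared_truth()
  genome <- truth$genome
  lc <- load_connections(truth$connections[, 1:8], genome,
                         p_threshold = truth$config$p_threshold)
  # noise rows above the threshold are exactly the ones filtered out
  expect_equal(nrow(lc$connections), sum(!truth$connections$is_noise))
  cb <- baits_in_clads(lc$baits, truth$partition)
  cls <- classify_baits(cb, truth$peaks$H3K4me1, truth$partition$clads)
  tb <- table(cls$class_of)
  expect_equal(unname(tb[["K4"]]), truth$config$n_k4_baits)
  expect_equal(unname(tb[["nonK4"]]), truth$config$n_nonk4_baits)
  expect_equal(length(cls$class_of), length(cb))
  cd <- connection_density(lc$connections, cls)
  # per-bait totals add up to the retained connections
  expect_equal(sum(cd$per_bait$n_connections), nrow(lc$connections))
  st <- cd$class_stats
  expect_gt(st$mean_connections[st$class == "K4"],
            st$mean_connections[st$class == "nonK4"])
  ann <- annotate_targets(lc$connections, truth$partition, truth$peaks$H3K4me1)
  sp <- summarize_proportions(ann, cls)
  for (cl in c("K4", "nonK4")) {
    frac <- if (cl == "K4") truth$config$frac_k4 else truth$config$frac_nonk4
    n_cl <- sum(sp$n[sp$class == cl])
    for (lad in names(frac)) {
      got <- sum(sp$prop[sp$class == cl & sp$lad_class == lad])
      se <- sqrt(frac[[lad]] * (1 - frac[[lad]]) / n_cl)
      expect_lt(abs(got - frac[[lad]]), 3 * se + 1e-12)
    }
  }
})

test_that("equal connection rates give matching class means", {
  cfg <- small_config(lambda_k4 = 10, lambda_nonk4 = 10, noise_frac = 0)
  truth <- generate_synthetic(cfg, seed = 5)
  lc <- load_connections(truth$connections[, 1:8], truth$genome)
  cb <- baits_in_clads(lc$baits, truth$partition)
  cls <- classify_baits(cb, truth$peaks$H3K4me1, truth$partition$clads)
  cd <- connection_density(lc$connections, cls)
  expect_gt(cd$welch$p_value, 0.01)
})
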