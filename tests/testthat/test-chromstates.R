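toy_model <- function(e_hi = 0.9, e_lo = 0.1, self = 0.95) {
  bernoulli_hmm(matrix(c(e_hi, e_lo), 2, 1,
                       dimnames = list(NULL, "m1")),
                matrix(c(self, 1 - self, 1 - self, self), 2, 2))
}

test_that("binarization thresholds counts by the Poisson upper tail", {
  g <- c(chr = 2000)
  low <- coverage_track(list(chr = rep(1, 10)), g, 200)
  bt <- binarize_tracks(list(m = low))
  expect_true(all(bt$calls$chr == 0))
  spike <- coverage_track(list(chr = c(rep(1, 9), 50)), g, 200)
  bt2 <- binarize_tracks(list(m = spike))
  expect_equal(sum(bt2$calls$chr), 1)
  expect_equal(unname(bt2$calls$chr[10, "m"]), 1)
  expect_warning(binarize_tracks(list(m = coverage_track(list(chr = rep(0, 10)), g, 200))),
                 "all-zero")
})

test_that("minimal called count matches an independent Poisson CDF scan", {
  for (lambda in c(0.5, 5, 20)) {
    # oracle: accumulate the Poisson pmf directly
    x <- 0; upper <- 1
    while (upper >= 1e-4) {
      upper <- 1 - sum(dpois(0:x, lambda))
      x <- x + 1
    }
    expect_equal(binarize_min_count(lambda, 1e-4), x)
    # and the rule behaves as a sharp threshold on a constructed track
    g <- c(chr = 200 * 50)
    v <- rep(lambda, 50)  # mean stays ~lambda
    v[1] <- x; v[2] <- x - 1
    bt <- binarize_tracks(list(m = coverage_track(list(chr = v), g, 200)))
    lam_hat <- mean(v)
    expect_equal(unname(bt$calls$chr[1, "m"]),
                 as.numeric(ppois(x - 1, lam_hat, lower.tail = FALSE) < 1e-4))
  }
})

test_that("forward likelihood equals exhaustive path enumeration on 6-bin chains", {
  set.seed(17)
  for (K in 2:3) {
    for (rep in 1:5) {
      E <- matrix(runif(K * 2, 0.05, 0.95), K, 2)
      A <- matrix(runif(K * K), K, K)
      A <- A / rowSums(A)
      init <- runif(K); init <- init / sum(init)
      model <- bernoulli_hmm(E, A, init)
      X <- matrix(rbinom(12, 1, 0.5), 6, 2)
      expect_equal(hmm_loglik(model, X), enum_loglik(model, X),
                   tolerance = 1e-8)
    }
  }
})

test_that("Baum-Welch log-likelihood is monotone and reaches convergence", {
  sim <- simulate_bernoulli_hmm(toy_model(), 3000, seed = 8)
  fit <- baum_welch(sim$calls, n_states = 2, seed = 3, max_iter = 100)
  expect_true(all(diff(fit$loglik) >= -1e-8))
  expect_true(all(abs(rowSums(fit$transition) - 1) < 1e-9))
  expect_equal(sum(fit$initial), 1, tolerance = 1e-9)
  # fitted model scores the data at least as well as the start
  expect_gt(fit$loglik[fit$n_iter], fit$loglik[1])
})

test_that("a single-state fit recovers the empirical mark frequency", {
  set.seed(2)
  X <- matrix(rbinom(600, 1, c(0.3, 0.7)), 300, 2, byrow = TRUE)
  fit <- baum_welch(X, n_states = 1, seed = 1, max_iter = 10)
  expect_equal(as.numeric(fit$emission), colMeans(X), tolerance = 1e-8)
})

test_that("two-state parameters are recovered within 0.05 at 10k bins", {
  sim <- simulate_bernoulli_hmm(toy_model(), 10000, seed = 11)
  fit <- baum_welch(sim$calls, n_states = 2, seed = 4, max_iter = 200)
  em <- sort(as.numeric(fit$emission))
  expect_lt(abs(em[1] - 0.1), 0.05)
  expect_lt(abs(em[2] - 0.9), 0.05)
  self_tr <- diag(fit$transition)[order(as.numeric(fit$emission))]
  expect_lt(max(abs(self_tr - 0.95)), 0.05)
})

test_that("training is deterministic given the seed and label-stable across seeds", {
  sim <- simulate_bernoulli_hmm(toy_model(), 4000, seed = 13)
  f1 <- baum_welch(sim$calls, n_states = 2, seed = 7, max_iter = 100)
  f2 <- baum_welch(sim$calls, n_states = 2, seed = 7, max_iter = 100)
  expect_identical(f1$emission, f2$emission)
  # different seeds agree up to state relabelling
  f3 <- baum_welch(sim$calls, n_states = 2, seed = 99, max_iter = 100)
  d_direct <- max(abs(f1$emission - f3$emission))
  d_swapped <- max(abs(f1$emission - f3$emission[2:1, , drop = FALSE]))
  expect_lt(min(d_direct, d_swapped), 0.05)
})

test_that("posterior decoding recovers a well-separated path and normalizes", {
  model <- bernoulli_hmm(matrix(c(0.99, 0.01), 2, 1), toy_model()$transition)
  sim <- simulate_bernoulli_hmm(model, 2000, seed = 21)
  seg <- decode_states(model, sim$calls)
  expect_gt(mean(seg$states[[1]] == sim$states), 0.97)
  post <- state_posteriors(model, sim$calls)[[1]]
  expect_equal(rowSums(post), rep(1, 2000), tolerance = 1e-9)
  # symmetric model on all-zero data decodes to one constant state
  sym <- bernoulli_hmm(matrix(c(0.5, 0.5), 2, 1),
                       matrix(0.5, 2, 2))
  seg0 <- decode_states(sym, matrix(0, 50, 1))
  expect_length(unique(seg0$states[[1]]), 1)
  vit <- decode_states(model, sim$calls, method = "viterbi")
  expect_gt(mean(vit$states[[1]] == sim$states), 0.97)
})

test_that("fold-enrichment applies the printed formula", {
  g <- c(chr = 10000)
  seg_gr <- interval_set("chr", c(0, 1000), c(1000, 10000), g)
  S4Vectors::mcols(seg_gr)$state <- c("S1", "S2")
  # state 1000 bp, annotation 500 bp, overlap 100 bp, genome 10 kb -> 2.0
  ann <- interval_set("chr", c(900, 5000), c(1000, 5400), g)
  fe <- fold_enrichment(seg_gr, ann)
  expect_equal(fe$fold_enrichment[fe$state == "S1"], (100 / 1000) / (500 / 10000))
  # annotation = whole genome -> every state 1.0
  whole <- interval_set("chr", 0, 10000, g)
  expect_equal(fold_enrichment(seg_gr, whole)$fold_enrichment, c(1, 1))
  # disjoint annotation -> 0
  far <- interval_set("chr", 5000, 5500, g)
  expect_equal(fold_enrichment(seg_gr, far)$fold_enrichment[1], 0)
  expect_error(fold_enrichment(seg_gr, whole[0]), "empty annotation")
})

test_that("fold-enrichment equals a per-base brute-force computation", {
  set.seed(31)
  for (rep in 1:10) {
    states <- sample(1:3, 20, replace = TRUE)
    seg_gr <- interval_set(rep("cA", 20), seq(0, 5700, 300), seq(300, 6000, 300),
                           c(cA = 6000))
    S4Vectors::mcols(seg_gr)$state <- paste0("S", states)
    ann <- iv_normalize(rand_intervals(c(cA = 6000), n = 5))
    fe <- fold_enrichment(seg_gr, ann)
    ann_bool <- bool_of(ann)$cA
    state_per_base <- rep(states, each = 300)
    for (s in unique(states)) {
      in_state <- state_per_base == s
      expected <- (sum(in_state & ann_bool) / sum(in_state)) /
        (sum(ann_bool) / 6000)
      expect_equal(fe$fold_enrichment[fe$state == paste0("S", s)], expected)
    }
  }
})

test_that("targets are attributed to every overlapped state", {
  g <- c(chr = 10000)
  seg_gr <- interval_set("chr", c(0, 1000), c(1000, 10000), g)
  S4Vectors::mcols(seg_gr)$state <- c("EnhA", "Quies")
  inside <- interval_set("chr", 100, 200, g)
  att1 <- attribute_targets(inside, seg_gr)
  expect_equal(nrow(att1$attributions), 1)
  spanning <- interval_set("chr", 900, 1100, g)
  att2 <- attribute_targets(spanning, seg_gr)
  expect_equal(sort(att2$attributions$state), c("EnhA", "Quies"))
  # exclusion and suppression flags
  att3 <- attribute_targets(c(inside, spanning), seg_gr,
                            exclude_states = "Quies")
  expect_equal(att3$proportions$state, "EnhA")
  expect_equal(att3$proportions$prop, 1)
  att4 <- attribute_targets(c(inside, spanning), seg_gr, min_prop = 0.4)
  expect_true(att4$proportions$suppressed[att4$proportions$state == "Quies"])
})

test_that("segmentation round-trips through genomic intervals", {
  truth <- shared_truth()
  seg <- decode_states(truth$hmm$model, truth$hmm$calls)
  gr <- segmentation_granges(seg)
  expect_equal(iv_base_coverage(gr), sum(as.numeric(truth$genome)))
  expect_gt(mean(seg$states$chr1 == truth$hmm$states$chr1), 0.9)
  # targets dropped into single-state runs come back with exactly that state
  set.seed(51)
  runs <- gr[GenomicRanges::width(gr) >= 1000]
  pick <- runs[sample(length(runs), 100, replace = TRUE)]
  t_start <- GenomicRanges::start(pick) - 1 + 200
  targets <- interval_set(as.character(GenomicRanges::seqnames(pick)),
                          t_start, t_start + 400, truth$genome)
  att <- attribute_targets(targets, gr)
  expect_equal(nrow(att$attributions), 100)  # one state each
  expect_equal(att$attributions$state[order(att$attributions$target)],
               S4Vectors::mcols(pick)$state)
})
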