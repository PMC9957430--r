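# Independent brute-force oracles and shared fixtures.

toy_genome <- c(cA = 6000, cB = 4000)

# random interval set on a toy genome (possibly overlapping before normalize)
rand_intervals <- function(genome, n = 8, max_len = 800) {
  chrom <- sample(names(genome), n, replace = TRUE)
  start <- floor(runif(n) * (genome[chrom] - max_len))
  len <- 1 + floor(runif(n) * max_len)
  interval_set(chrom, start, start + len, genome)
}

# per-base boolean membership vectors, the reference representation
bool_of <- function(gr) {
  genome <- iv_genome(gr)
  out <- lapply(genome, function(L) rep(FALSE, L))
  df <- iv_as_bed_df(gr)
  for (i in seq_len(nrow(df))) {
    out[[df$chrom[i]]][(df$start[i] + 1):df$end[i]] <- TRUE
  }
  out
}

# exact HMM log-likelihood by exhaustive enumeration of all state paths
enum_loglik <- function(model, X) {
  K <- model$n_states
  Tn <- nrow(X)
  emis <- function(k, t) {
    prod(model$emission[k, ]^X[t, ] * (1 - model$emission[k, ])^(1 - X[t, ]))
  }
  paths <- expand.grid(rep(list(seq_len(K)), Tn))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    p <- as.integer(paths[r, ])
    pr <- model$initial[p[1]] * emis(p[1], 1)
    for (t in seq_len(Tn)[-1]) {
      pr <- pr * model$transition[p[t - 1], p[t]] * emis(p[t], t)
    }
    total <- total + pr
  }
  log(total)
}

# distance from an interior point to an ellipsoid surface by dense sampling
surface_min_dist <- function(p, semi_axes, n_theta = 600, n_phi = 300) {
  th <- seq(0, 2 * pi, length.out = n_theta)
  ph <- seq(0, pi, length.out = n_phi)
  grid <- expand.grid(th = th, ph = ph)
  sx <- semi_axes[1] * sin(grid$ph) * cos(grid$th)
  sy <- semi_axes[2] * sin(grid$ph) * sin(grid$th)
  sz <- semi_axes[3] * cos(grid$ph)
  min(sqrt((sx - p[1])^2 + (sy - p[2])^2 + (sz - p[3])^2))
}

# hand evaluation of the Welch statistic
welch_hand <- function(a, b) {
  va <- var(a) / length(a); vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  dof <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), dof)
  list(t = t, dof = dof, p = p)
}

# scaled-down generator configuration for fast per-module tests
small_config <- function(...) {
  synthetic_config(
    genome = c(chr1 = 6e5, chr2 = 6e5), cores_per_chrom = 2,
    core_length = c(8e4, 1e5), flank_max = 1e4, vlad_blocks_per_chrom = 1,
    vlad_length = 4e4, gaps_per_chrom = 2, gap_length = 2e4, peaks_per_gap = 4,
    stray_k4_per_chrom = 2, n_expressed_genes = 30, n_nonexpressed_genes = 40,
    n_k4_baits = 40, n_nonk4_baits = 80, fish_nuclei = 10, ...
  )
}

# one dataset shared across test files (generated once per test run)
shared_truth <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_synthetic(seed = 42)
    cache
  }
})
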