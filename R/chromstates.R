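#' Binarize count tracks for chromatin-state modelling
#'
#' Per mark, a bin is called present (1) when the upper-tail Poisson
#' probability of its count under the genome-wide mean rate is below
#' `p_cut`, i.e. `P(X >= x | lambda = mean) < p_cut` — the ChromHMM-style
#' signal test.
#'
#' @param tracks named list of count-valued `coverage_track`s, one per mark,
#'   sharing genome and bin grid
#' @param p_cut Poisson tail threshold (default 1e-4)
#' @return object of class `binarized_tracks`: list with `genome`,
#'   `bin_size`, `marks` and `calls` (per chromosome, a bins x marks 0/1
#'   matrix)
#' @export
binarize_tracks <- function(tracks, p_cut = 1e-4) {
  if (is.null(names(tracks))) stop("tracks must be a named list (mark names)")
  for (tr in tracks[-1]) check_same_grid(tracks[[1]], tr)
  genome <- tracks[[1]]$genome
  marks <- names(tracks)
  calls <- lapply(names(genome), function(ch) {
    m <- sapply(marks, function(mk) {
      v <- tracks[[mk]]$values[[ch]]
      v[is.na(v)] <- 0
      v
    })
    matrix(m, ncol = length(marks), dimnames = list(NULL, marks))
  })
  names(calls) <- names(genome)
  for (mk in marks) {
    allv <- unlist(lapply(calls, function(m) m[, mk]), use.names = FALSE)
    lambda <- mean(allv)
    if (lambda == 0) {
      warning(sprintf("mark %s: all-zero track, no bins called", mk))
      for (ch in names(calls)) calls[[ch]][, mk] <- 0
      next
    }
    for (ch in names(calls)) {
      x <- calls[[ch]][, mk]
      p_up <- stats::ppois(x - 1, lambda, lower.tail = FALSE)  # P(X >= x)
      calls[[ch]][, mk] <- as.integer(p_up < p_cut)
    }
  }
  structure(list(genome = genome, bin_size = tracks[[1]]$bin_size,
                 marks = marks, calls = calls),
            class = "binarized_tracks")
}

#' Minimal count called present under the Poisson binarization rule
#' @param lambda genome-wide mean rate
#' @param p_cut tail threshold
#' @return smallest integer count x with `P(X >= x) < p_cut`
#' @export
binarize_min_count <- function(lambda, p_cut = 1e-4) {
  x <- 0
  while (stats::ppois(x - 1, lambda, lower.tail = FALSE) >= p_cut) x <- x + 1
  x
}

as_call_list <- function(x) {
  if (inherits(x, "binarized_tracks")) return(x$calls)
  if (is.matrix(x)) return(list(x))
  if (is.list(x)) return(x)
  stop("expected binarized_tracks, a 0/1 matrix, or a list of matrices")
}

# Per-bin Bernoulli emission likelihoods: T x K matrix of
# prod_m e[k,m]^x (1-e[k,m])^(1-x), computed in log space.
emission_lik <- function(X, emission) {
  logB <- X %*% t(log(emission)) + (1 - X) %*% t(log(1 - emission))
  exp(logB)
}

# Scaled forward-backward (Rabiner scaling). Returns per-bin posteriors,
# expected transition counts and the exact log-likelihood.
forward_backward <- function(X, model) {
  K <- model$n_states
  Tn <- nrow(X)
  B <- emission_lik(X, model$emission)
  A <- model$transition
  alpha <- matrix(0, Tn, K)
  cvec <- numeric(Tn)
  a <- model$initial * B[1, ]
  cvec[1] <- sum(a)
  alpha[1, ] <- a / cvec[1]
  for (t in 2:Tn) {
    a <- (alpha[t - 1, ] %*% A) * B[t, ]
    cvec[t] <- sum(a)
    alpha[t, ] <- a / cvec[t]
  }
  beta <- matrix(0, Tn, K)
  beta[Tn, ] <- 1
  xi_sum <- matrix(0, K, K)
  for (t in (Tn - 1):1) {
    bb <- B[t + 1, ] * beta[t + 1, ]
    beta[t, ] <- (A %*% bb) / cvec[t + 1]
    xi_sum <- xi_sum + (alpha[t, ] %o% bb) * A / cvec[t + 1]
  }
  gamma <- alpha * beta
  gamma <- gamma / rowSums(gamma)
  list(gamma = gamma, xi_sum = xi_sum, loglik = sum(log(cvec)))
}

#' Log-likelihood of binarized tracks under a Bernoulli HMM
#' @param model `bernoulli_hmm`
#' @param calls `binarized_tracks`, matrix, or list of matrices
#' @return total log-likelihood over sequences
#' @export
hmm_loglik <- function(model, calls) {
  seqs <- as_call_list(calls)
  sum(vapply(seqs, function(X) forward_backward(X, model)$loglik, numeric(1)))
}

#' Construct a Bernoulli hidden Markov model
#' @param emission K x M matrix of per-state per-mark Bernoulli probabilities
#' @param transition K x K row-stochastic matrix
#' @param initial initial state distribution (default uniform)
#' @param state_names optional labels
#' @return object of class `bernoulli_hmm`
#' @export
bernoulli_hmm <- function(emission, transition, initial = NULL,
                          state_names = NULL) {
  emission <- as.matrix(emission)
  transition <- as.matrix(transition)
  K <- nrow(emission)
  if (!all(dim(transition) == K)) stop("transition must be K x K")
  if (any(abs(rowSums(transition) - 1) > 1e-9)) {
    stop("transition rows must sum to 1")
  }
  if (is.null(initial)) initial <- rep(1 / K, K)
  if (abs(sum(initial) - 1) > 1e-9) stop("initial must sum to 1")
  if (any(emission <= 0 | emission >= 1)) {
    stop("emission probabilities must lie strictly in (0, 1)")
  }
  if (is.null(state_names)) state_names <- paste0("S", seq_len(K))
  structure(list(n_states = K, marks = colnames(emission),
                 emission = emission, transition = transition,
                 initial = as.numeric(initial), state_names = state_names),
            class = "bernoulli_hmm")
}

#' @export
print.bernoulli_hmm <- function(x, ...) {
  cat(sprintf("Bernoulli HMM: %d states, %d marks\n",
              x$n_states, ncol(x$emission)))
  print(round(x$emission, 3))
  invisible(x)
}

#' Train a Bernoulli HMM by Baum-Welch
#'
#' Expectation-maximisation on a hidden Markov chain with independent
#' Bernoulli emissions per mark (the ChromHMM emission model). Emissions are
#' initialised from per-mark empirical frequencies with seeded jitter;
#' transitions start near-uniform with a sticky diagonal. Underflow is
#' handled by per-bin scaling, so the reported log-likelihood is exact. The
#' log-likelihood is checked to be non-decreasing at every iteration.
#'
#' @param calls `binarized_tracks`, a 0/1 matrix (bins x marks), or a list of
#'   such matrices (independent sequences, e.g. chromosomes)
#' @param n_states number of hidden states (>= 2; default 15)
#' @param seed RNG seed for the emission jitter (training is deterministic
#'   given the seed)
#' @param max_iter maximum EM iterations (default 200)
#' @param tol stop when the log-likelihood gain drops below this (default 1e-4)
#' @param state_names optional labels attached to the fitted model
#' @return `bernoulli_hmm` with a `loglik` attribute (per-iteration trace)
#' @export
baum_welch <- function(calls, n_states = 15, seed = 1, max_iter = 200,
                       tol = 1e-4, state_names = NULL) {
  seqs <- as_call_list(calls)
  seqs <- lapply(seqs, function(X) {
    X <- as.matrix(X)
    storage.mode(X) <- "double"
    X
  })
  M <- ncol(seqs[[1]])
  total_bins <- sum(vapply(seqs, nrow, 0L))
  if (n_states < 1) stop("n_states must be >= 1")
  if (n_states > total_bins) stop("more states than bins")
  marks <- colnames(seqs[[1]])
  freq <- colMeans(do.call(rbind, seqs))
  old_seed <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  emission <- matrix(rep(freq, each = n_states), n_states, M) +
    matrix(stats::runif(n_states * M, -0.15, 0.15), n_states, M)
  emission <- pmin(pmax(emission, 0.02), 0.98)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  transition <- if (n_states == 1) matrix(1, 1, 1) else {
    tr <- matrix((1 - 0.9) / (n_states - 1), n_states, n_states)
    diag(tr) <- 0.9
    tr
  }
  initial <- rep(1 / n_states, n_states)
  model <- bernoulli_hmm(emission, transition, initial, state_names)
  model$marks <- marks
  colnames(model$emission) <- marks
  ll_trace <- numeric(0)
  prev_ll <- -Inf
  for (iter in seq_len(max_iter)) {
    gamma1 <- numeric(n_states)
    xi_sum <- matrix(0, n_states, n_states)
    gsum <- numeric(n_states)
    gx <- matrix(0, n_states, M)
    ll <- 0
    for (X in seqs) {
      fb <- forward_backward(X, model)
      gamma1 <- gamma1 + fb$gamma[1, ]
      xi_sum <- xi_sum + fb$xi_sum
      gsum <- gsum + colSums(fb$gamma)
      gx <- gx + t(fb$gamma) %*% X
      ll <- ll + fb$loglik
    }
    if (ll < prev_ll - 1e-8) {
      stop(sprintf("EM log-likelihood decreased at iteration %d (%.10g -> %.10g)",
                   iter, prev_ll, ll))
    }
    ll_trace <- c(ll_trace, ll)
    converged <- is.finite(prev_ll) && (ll - prev_ll) < tol
    prev_ll <- ll
    if (converged) break
    model$initial <- gamma1 / sum(gamma1)
    model$transition <- xi_sum / rowSums(xi_sum)
    model$emission <- pmin(pmax(gx / gsum, 1e-6), 1 - 1e-6)
  }
  model$loglik <- ll_trace
  model$n_iter <- length(ll_trace)
  model
}

#' Simulate a state path and binarized calls from a Bernoulli HMM
#' @param model `bernoulli_hmm`
#' @param n_bins chain length
#' @param seed optional RNG seed
#' @return list with `states` (integer path) and `calls` (bins x marks 0/1
#'   matrix)
#' @export
simulate_bernoulli_hmm <- function(model, n_bins, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  K <- model$n_states
  M <- ncol(model$emission)
  st <- integer(n_bins)
  st[1] <- sample.int(K, 1, prob = model$initial)
  for (t in seq_len(n_bins)[-1]) {
    st[t] <- sample.int(K, 1, prob = model$transition[st[t - 1], ])
  }
  calls <- matrix(stats::rbinom(n_bins * M, 1, model$emission[st, ]),
                  n_bins, M, dimnames = list(NULL, colnames(model$emission)))
  list(states = st, calls = calls)
}

#' Decode per-bin chromatin states
#'
#' Default decoding assigns each bin the state of maximal forward-backward
#' posterior probability; `method = "viterbi"` returns the jointly most
#' probable path instead.
#'
#' @param model `bernoulli_hmm`
#' @param calls `binarized_tracks` (or matrix / list of matrices)
#' @param method `"posterior"` (default) or `"viterbi"`
#' @return object of class `segmentation`: list with `states` (per-sequence
#'   integer vectors), `state_names`, `bin_size`, `genome` (the latter two
#'   when `calls` is a `binarized_tracks`)
#' @export
decode_states <- function(model, calls, method = c("posterior", "viterbi")) {
  method <- match.arg(method)
  seqs <- as_call_list(calls)
  states <- lapply(seqs, function(X) {
    if (method == "posterior") {
      fb <- forward_backward(X, model)
      max.col(fb$gamma, ties.method = "first")
    } else {
      viterbi_path(X, model)
    }
  })
  names(states) <- names(seqs)
  structure(list(states = states, state_names = model$state_names,
                 bin_size = if (inherits(calls, "binarized_tracks")) calls$bin_size else NULL,
                 genome = if (inherits(calls, "binarized_tracks")) calls$genome else NULL),
            class = "segmentation")
}

viterbi_path <- function(X, model) {
  K <- model$n_states
  Tn <- nrow(X)
  logB <- log(emission_lik(X, model$emission))
  logA <- log(model$transition)
  delta <- matrix(-Inf, Tn, K)
  psi <- matrix(0L, Tn, K)
  delta[1, ] <- log(model$initial) + logB[1, ]
  for (t in 2:Tn) {
    m <- delta[t - 1, ] + logA  # K x K: from-state rows
    psi[t, ] <- max.col(t(m), ties.method = "first")
    delta[t, ] <- m[cbind(psi[t, ], seq_len(K))] + logB[t, ]
  }
  path <- integer(Tn)
  path[Tn] <- which.max(delta[Tn, ])
  for (t in (Tn - 1):1) path[t] <- psi[t + 1, path[t + 1]]
  path
}

#' Per-bin state posterior probabilities
#' @param model `bernoulli_hmm`
#' @param calls binarized tracks / matrix / list
#' @return list of bins x states posterior matrices (rows sum to 1)
#' @export
state_posteriors <- function(model, calls) {
  seqs <- as_call_list(calls)
  lapply(seqs, function(X) forward_backward(X, model)$gamma)
}

#' Convert a segmentation to genomic intervals
#' @param seg `segmentation` with `genome` and `bin_size`
#' @return `GRanges` with a `state` column (one range per run of equal-state
#'   bins, clipped to chromosome ends)
#' @export
segmentation_granges <- function(seg) {
  if (is.null(seg$genome)) stop("segmentation lacks genome information")
  bs <- seg$bin_size
  parts <- lapply(names(seg$states), function(ch) {
    r <- rle(seg$states[[ch]])
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1
    data.frame(chrom = ch,
               start = (starts_idx - 1) * bs,
               end = pmin(ends_idx * bs, seg$genome[[ch]]),
               state = r$values)
  })
  df <- do.call(rbind, parts)
  gr <- interval_set(df$chrom, df$start, df$end, seg$genome)
  S4Vectors::mcols(gr)$state <- seg$state_names[df$state]
  gr
}

#' Fold-enrichment of an annotation over chromatin states
#'
#' Per state: `((bases in state and annotation) / (bases in state)) /
#' ((bases in annotation) / (genome size))`. States absent from the
#' segmentation are reported with `NA` fold-enrichment.
#'
#' @param seg `segmentation` (with genome) or a `GRanges` with a `state`
#'   column
#' @param annotation normalized non-empty `GRanges` (e.g. connection targets)
#' @return data.frame: `state`, `bases_in_state`, `bases_overlap`,
#'   `fold_enrichment`, plus attributes `bases_in_annotation`, `genome_size`
#' @export
fold_enrichment <- function(seg, annotation) {
  gr <- if (inherits(seg, "segmentation")) segmentation_granges(seg) else seg
  if (length(annotation) == 0) stop("empty annotation")
  annotation <- iv_normalize(annotation)
  genome_size <- sum(as.numeric(iv_genome(gr)))
  ann_bases <- iv_base_coverage(annotation)
  state_levels <- if (inherits(seg, "segmentation")) seg$state_names else
    unique(S4Vectors::mcols(gr)$state)
  rows <- lapply(state_levels, function(st) {
    sgr <- gr[S4Vectors::mcols(gr)$state == st]
    bs <- iv_base_coverage(sgr)
    if (bs == 0) {
      return(data.frame(state = st, bases_in_state = 0, bases_overlap = 0,
                        fold_enrichment = NA_real_))
    }
    ov <- iv_base_coverage(iv_intersect(sgr, annotation))
    data.frame(state = st, bases_in_state = bs, bases_overlap = ov,
               fold_enrichment = (ov / bs) / (ann_bases / genome_size))
  })
  out <- do.call(rbind, rows)
  attr(out, "bases_in_annotation") <- ann_bases
  attr(out, "genome_size") <- genome_size
  out
}

#' Attribute connection targets to chromatin states
#'
#' A target is attributed to every state it overlaps by >= 1 bp, so a target
#' spanning a state boundary is counted in each state (multi-counting by
#' design). Proportions are computed over attributions; states can be
#' excluded (e.g. the Quiescent state) and rare states suppressed from the
#' report.
#'
#' @param targets `GRanges`
#' @param seg `segmentation` or state-labelled `GRanges`
#' @param exclude_states state names dropped before computing proportions
#' @param min_prop proportions below this are flagged `suppressed` in the
#'   output (default 0 = show everything); e.g. 0.003 hides cells under 0.3%
#' @return list: `attributions` (data.frame target index -> state) and
#'   `proportions` (state, n, prop, suppressed)
#' @export
attribute_targets <- function(targets, seg, exclude_states = NULL,
                              min_prop = 0) {
  gr <- if (inherits(seg, "segmentation")) segmentation_granges(seg) else seg
  hits <- GenomicRanges::findOverlaps(granges_unstranded(targets), gr,
                                      minoverlap = 1L, ignore.strand = TRUE)
  att <- unique(data.frame(
    target = S4Vectors::queryHits(hits),
    state = S4Vectors::mcols(gr)$state[S4Vectors::subjectHits(hits)],
    stringsAsFactors = FALSE
  ))
  keep <- !(att$state %in% exclude_states)
  kept <- att[keep, , drop = FALSE]
  levels <- setdiff(unique(S4Vectors::mcols(gr)$state), exclude_states)
  n <- table(factor(kept$state, levels = levels))
  prop <- as.numeric(n) / sum(n)
  proportions <- data.frame(state = levels, n = as.integer(n), prop = prop,
                            suppressed = prop < min_prop)
  list(attributions = att, proportions = proportions)
}

#' Write a fitted HMM as JSON
#' @param model `bernoulli_hmm`
#' @param path output path
#' @export
write_hmm_json <- function(model, path) {
  jsonlite::write_json(list(
    n_states = model$n_states,
    marks = model$marks,
    state_names = model$state_names,
    emission = model$emission,
    transition = model$transition,
    initial = model$initial
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
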