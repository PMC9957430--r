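#' Configuration for the synthetic-data generator
#'
#' Defaults encode the study conditions the pipeline is exercised under:
#' a 3 x 2 Mb toy genome; three differentiation timepoints whose LAD sets
#' share constitutive cores with variable flanks; euchromatic H3K4me1 gaps
#' inside cLADs with lower lamin signal (effect size 1.0 log2 units);
#' 225 K4 and 543 nonK4 cLAD baits with per-bait connection rates 27.5 and
#' 14.7; K4-bait target placement 0.7/0.2/0.1 over cLAD/vLAD/iLAD with one
#' third of cLAD targets inside H3K4me1 peaks; binarized chromatin-mark
#' tracks emitted by a known sticky Bernoulli HMM over 200-bp bins; gene
#' expression split around the >= 15 normalized-read-count threshold; and
#' two-condition FISH coordinate sets with +-0.5 um probe-probe shifts at
#' sigma = 0.8 um, 50 nuclei (100 alleles) per condition.
#'
#' @param ... named overrides of any default listed above (see the source for
#'   the complete set)
#' @return named list of generator parameters
#' @export
synthetic_config <- function(...) {
  cfg <- list(
    genome = c(chr1 = 2e6, chr2 = 2e6, chr3 = 2e6),
    timepoints = c("D0", "D1", "D3"),
    cores_per_chrom = 4,
    core_length = c(150e3, 210e3),
    flank_max = 40e3,
    vlad_blocks_per_chrom = 2,
    vlad_length = 80e3,
    gaps_per_chrom = 3,
    gap_length = 30e3,
    peaks_per_gap = 6,
    peak_length = c(1000, 2000),
    stray_k4_per_chrom = 3,
    lamin_bin = 1000,
    lamin_mean = c(ilad = -0.5, clad = 1.0, gap = 0.0, vlad = 0.5),
    lamin_sd = 0.3,
    lamin_region_sd = 0.1,
    n_expressed_genes = 120,
    n_nonexpressed_genes = 180,
    expression_threshold = 15,
    expr_meanlog = log(150),
    expr_sdlog = 0.6,
    nonexpr_max = 12,
    tss_bin = 50,
    tss_amp = 4,
    tss_width = 250,
    hmm_bin = 200,
    hmm_marks = c("H3K4me1", "H3K9me3"),
    hmm_emission = matrix(c(0.9, 0.05, 0.05, 0.05, 0.9, 0.05), ncol = 2,
                          dimnames = list(c("Enh", "Het", "Quies"),
                                          c("H3K4me1", "H3K9me3"))),
    hmm_self = 0.98,
    hmm_lambda_low = 0.5,
    hmm_lambda_high = 40,
    n_k4_baits = 225,
    n_nonk4_baits = 543,
    lambda_k4 = 27.5,
    lambda_nonk4 = 14.7,
    frac_k4 = c(cLAD = 0.7, vLAD = 0.2, iLAD = 0.1),
    frac_nonk4 = c(cLAD = 0.75, vLAD = 0.10, iLAD = 0.15),
    peak_frac_k4 = 1 / 3,
    peak_frac_nonk4 = 0.05,
    bait_length = 5e3,
    target_length = 5e3,
    noise_frac = 0.1,
    p_threshold = 0.01,
    fish_loci = list(CMKLR1like = c(D0 = 1.5, D3 = 2.0),
                     OTUD1like = c(D0 = 2.0, D3 = 1.5)),
    fish_nuclei = 50,
    fish_sd = 0.8,
    fish_axes = c(7, 5, 3),
    fish_axes_sd = 0.3
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) stop("unknown config fields: ",
                                paste(unknown, collapse = ", "))
  utils::modifyList(cfg, over)
}

validate_config <- function(cfg) {
  for (f in c("frac_k4", "frac_nonk4")) {
    if (abs(sum(cfg[[f]]) - 1) > 1e-9) stop(f, " must sum to 1")
  }
  if (cfg$lambda_k4 <= 0 || cfg$lambda_nonk4 <= 0) stop("lambdas must be positive")
  if (length(cfg$timepoints) < 2) stop("need >= 2 timepoints")
  if (nrow(cfg$hmm_emission) < 1 || ncol(cfg$hmm_emission) != length(cfg$hmm_marks)) {
    stop("hmm_emission must have one column per mark")
  }
  slot <- min(cfg$genome) / cfg$cores_per_chrom
  if (cfg$core_length[2] + 2 * cfg$flank_max > 0.6 * slot) {
    stop("core_length + flanks exceed the per-core slot; shrink them or the core count")
  }
  if (cfg$vlad_length > 0.16 * slot) stop("vlad_length too large for the slot layout")
  if (cfg$core_length[1] < cfg$gap_length + 4e4 + 1e3) {
    stop("cores too short to hold an interior euchromatic gap")
  }
  invisible(cfg)
}

# one RNG stream per file type, derived from the master seed, so adding a
# generator component does not perturb the others
sub_seed <- function(seed, k) {
  as.integer(((as.numeric(seed) %% 1e6) * 1009 + k) %% 2147483647)
}

with_stream <- function(seed, k, expr) {
  set.seed(sub_seed(seed, k))
  expr
}

sample_position_in <- function(gr, width, n) {
  w <- GenomicRanges::width(gr)
  usable <- pmax(w - width + 1, 0)
  ok <- which(usable > 0)
  if (length(ok) == 0) stop("no interval can hold a placement of this width")
  idx <- ok[sample.int(length(ok), n, replace = TRUE, prob = usable[ok])]
  off <- floor(stats::runif(n) * usable[idx])
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr))[idx],
             start = GenomicRanges::start(gr)[idx] - 1 + off,
             end = GenomicRanges::start(gr)[idx] - 1 + off + width,
             stringsAsFactors = FALSE)
}

runif_int <- function(n, lo, hi) floor(stats::runif(n, lo, hi + 1))

#' Generate the full synthetic input suite with known ground truth
#'
#' Emits every input the pipeline consumes — per-timepoint LAD sets, histone
#' peak sets, a lamin log2-ratio track, gene models, a TSS-enrichment track,
#' count tracks sampled from a known Bernoulli HMM, a bait-target connection
#' table, and two-condition FISH coordinates — together with the ground
#' truth used to produce them. Regeneration from the same `(config, seed)`
#' is deterministic.
#'
#' @param config list from [synthetic_config()]
#' @param seed master seed; each component draws from its own derived stream
#' @param outdir optional directory; when given, all inputs are written as
#'   plain-text BED/bedGraph/TSV files plus `truth.json`
#' @return list of class `synthetic_truth` (see the vignette for the layout)
#' @export
generate_synthetic <- function(config = synthetic_config(), seed = 1,
                               outdir = NULL) {
  cfg <- validate_config(config)
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  genome <- cfg$genome
  tps <- cfg$timepoints

  ## --- LAD architecture (stream 1) -----------------------------------------
  arch <- with_stream(seed, 1, {
    cores <- list(); gaps <- list(); vblocks <- list()
    for (ch in names(genome)) {
      slot <- genome[[ch]] / cfg$cores_per_chrom
      for (i in seq_len(cfg$cores_per_chrom)) {
        s0 <- (i - 1) * slot
        len <- runif_int(1, cfg$core_length[1], cfg$core_length[2])
        # core zone: central 60% of the slot, flank_max margin kept inside it
        zone_lo <- s0 + 0.2 * slot + cfg$flank_max
        zone_hi <- s0 + 0.8 * slot - cfg$flank_max - len
        start <- runif_int(1, zone_lo, zone_hi)
        cores[[length(cores) + 1]] <- data.frame(
          chrom = ch, start = start, end = start + len, slot = i)
      }
      # vLAD blocks in the leading free zone of the first slots
      for (i in seq_len(cfg$vlad_blocks_per_chrom)) {
        s0 <- (i - 1) * slot
        start <- s0 + runif_int(1, 0.01 * slot, 0.03 * slot)
        member <- rep(FALSE, length(tps))
        while (all(member) || !any(member)) {
          member <- stats::runif(length(tps)) < 0.5
        }
        vblocks[[length(vblocks) + 1]] <- cbind(
          data.frame(chrom = ch, start = start,
                     end = start + cfg$vlad_length),
          stats::setNames(as.data.frame(t(member)), tps))
      }
    }
    cores <- do.call(rbind, cores)
    vblocks <- do.call(rbind, vblocks)
    # euchromatic H3K4me1 gaps strictly interior to a subset of cores
    for (ch in names(genome)) {
      rows <- which(cores$chrom == ch)
      pick <- sort(sample(rows, cfg$gaps_per_chrom))
      for (r in pick) {
        glo <- cores$start[r] + 2e4
        ghi <- cores$end[r] - 2e4 - cfg$gap_length
        gs <- runif_int(1, glo, ghi)
        gaps[[length(gaps) + 1]] <- data.frame(
          chrom = ch, start = gs, end = gs + cfg$gap_length, core = r)
      }
    }
    gaps <- do.call(rbind, gaps)
    # per-timepoint flank extensions
    flanks <- array(runif_int(nrow(cores) * length(tps) * 2, 0, cfg$flank_max),
                    dim = c(nrow(cores), length(tps), 2))
    list(cores = cores, gaps = gaps, vblocks = vblocks, flanks = flanks)
  })
  cores_gr <- interval_set(arch$cores, genome = genome)
  gaps_gr <- interval_set(arch$gaps, genome = genome)
  lad_sets <- stats::setNames(lapply(seq_along(tps), function(j) {
    ext <- data.frame(chrom = arch$cores$chrom,
                      start = arch$cores$start - arch$flanks[, j, 1],
                      end = arch$cores$end + arch$flanks[, j, 2])
    vb <- arch$vblocks[arch$vblocks[[tps[j]]], c("chrom", "start", "end")]
    iv_normalize(interval_set(rbind(ext, vb), genome = genome))
  }), tps)
  partition <- derive_lad_partition(lad_sets)

  ## --- histone peaks (stream 2) --------------------------------------------
  peaks <- with_stream(seed, 2, {
    k4 <- list(); k27 <- list(); k9 <- list()
    for (g in seq_len(nrow(arch$gaps))) {
      grow <- arch$gaps[g, ]
      sub <- (grow$end - grow$start) / cfg$peaks_per_gap
      for (i in seq_len(cfg$peaks_per_gap)) {
        len <- runif_int(1, cfg$peak_length[1], cfg$peak_length[2])
        s <- grow$start + (i - 1) * sub + runif_int(1, 0, sub - len)
        k4[[length(k4) + 1]] <- data.frame(chrom = grow$chrom, start = s,
                                           end = s + len, gap = g)
      }
      if (g %% 2 == 0) {  # active (H3K27ac-marked) gaps: half of them
        for (i in seq_len(3)) {
          len <- runif_int(1, cfg$peak_length[1], cfg$peak_length[2])
          s <- grow$start + runif_int(1, 0, grow$end - grow$start - len)
          k27[[length(k27) + 1]] <- data.frame(chrom = grow$chrom, start = s,
                                               end = s + len)
        }
      }
    }
    # stray H3K4me1 peaks outside LADs (in the trailing free zones)
    for (ch in names(genome)) {
      slot <- genome[[ch]] / cfg$cores_per_chrom
      for (i in seq_len(cfg$stray_k4_per_chrom)) {
        s0 <- ((i - 1) %% cfg$cores_per_chrom) * slot + 0.82 * slot
        len <- runif_int(1, cfg$peak_length[1], cfg$peak_length[2])
        s <- floor(s0) + runif_int(1, 0, 0.15 * slot)
        k4[[length(k4) + 1]] <- data.frame(chrom = ch, start = s,
                                           end = s + len, gap = NA)
      }
    }
    # H3K9me3 blocks tiling the heterochromatic (non-gap) core interior
    for (r in seq_len(nrow(arch$cores))) {
      crow <- arch$cores[r, ]
      pos <- seq(crow$start, crow$end - 5e3, by = 1e4)
      for (s0 in pos) {
        s <- s0 + runif_int(1, 0, 1e3)
        grow <- arch$gaps[!is.na(arch$gaps$core) & arch$gaps$core == r, ]
        if (nrow(grow) == 1 && s + 4e3 > grow$start && s < grow$end) next
        k9[[length(k9) + 1]] <- data.frame(chrom = crow$chrom, start = s,
                                           end = s + 4e3)
      }
    }
    list(k4 = do.call(rbind, k4), k27 = do.call(rbind, k27),
         k9 = do.call(rbind, k9))
  })
  k4_gr <- interval_set(peaks$k4[, c("chrom", "start", "end")], genome = genome)
  k27_gr <- interval_set(peaks$k27, genome = genome)
  k9_gr <- iv_normalize(interval_set(peaks$k9, genome = genome))
  gap_peaks <- peaks$k4[!is.na(peaks$k4$gap), , drop = FALSE]

  ## --- lamin log2 track (stream 3) -----------------------------------------
  lamin_track <- with_stream(seed, 3, {
    bs <- cfg$lamin_bin
    core_shift <- stats::rnorm(nrow(arch$cores), 0, cfg$lamin_region_sd)
    gap_shift <- stats::rnorm(nrow(arch$gaps), 0, cfg$lamin_region_sd)
    values <- lapply(names(genome), function(ch) {
      nb <- ceiling(genome[[ch]] / bs)
      mid <- (seq_len(nb) - 0.5) * bs
      v <- rep(cfg$lamin_mean[["ilad"]], nb)
      for (r in which(arch$vblocks$chrom == ch)) {
        sel <- mid >= arch$vblocks$start[r] & mid < arch$vblocks$end[r]
        v[sel] <- cfg$lamin_mean[["vlad"]]
      }
      for (r in which(arch$cores$chrom == ch)) {
        sel <- mid >= arch$cores$start[r] - cfg$flank_max &
          mid < arch$cores$end[r] + cfg$flank_max
        v[sel] <- cfg$lamin_mean[["clad"]] + core_shift[r]
      }
      for (r in which(arch$gaps$chrom == ch)) {
        sel <- mid >= arch$gaps$start[r] & mid < arch$gaps$end[r]
        v[sel] <- cfg$lamin_mean[["gap"]] + gap_shift[r]
      }
      v + stats::rnorm(nb, 0, cfg$lamin_sd)
    })
    names(values) <- names(genome)
    coverage_track(values, genome, bs)
  })

  ## --- gene models (stream 4) ----------------------------------------------
  genes <- with_stream(seed, 4, {
    ex_pos <- sample_position_in(
      GenomicRanges::resize(gaps_gr, GenomicRanges::width(gaps_gr) - 4e3,
                            fix = "center"), 1, cfg$n_expressed_genes)
    non_gap_zone <- iv_complement(iv_normalize(GenomicRanges::resize(
      gaps_gr, GenomicRanges::width(gaps_gr) + 1e4, fix = "center")))
    ne_pos <- sample_position_in(non_gap_zone, 1, cfg$n_nonexpressed_genes)
    n <- cfg$n_expressed_genes + cfg$n_nonexpressed_genes
    data.frame(
      gene_id = sprintf("gene_%04d", seq_len(n)),
      chrom = c(ex_pos$chrom, ne_pos$chrom),
      tss = as.integer(c(ex_pos$start, ne_pos$start)),
      strand = sample(c("+", "-"), n, replace = TRUE),
      expression = c(stats::rlnorm(cfg$n_expressed_genes, cfg$expr_meanlog,
                                   cfg$expr_sdlog),
                     stats::runif(cfg$n_nonexpressed_genes, 0, cfg$nonexpr_max)),
      true_class = rep(c("expressed", "non_expressed"),
                       c(cfg$n_expressed_genes, cfg$n_nonexpressed_genes)),
      stringsAsFactors = FALSE
    )
  })

  ## --- TSS-enrichment coverage track (stream 5) ----------------------------
  tss_track <- with_stream(seed, 5, {
    bs <- cfg$tss_bin
    values <- lapply(names(genome), function(ch) {
      nb <- ceiling(genome[[ch]] / bs)
      stats::rgamma(nb, shape = 2, rate = 2)
    })
    names(values) <- names(genome)
    win <- ceiling(4 * cfg$tss_width / bs)
    for (i in which(genes$true_class == "expressed")) {
      ch <- genes$chrom[i]
      b0 <- floor(genes$tss[i] / bs) + 1
      idx <- max(1, b0 - win):min(length(values[[ch]]), b0 + win)
      d <- ((idx - 0.5) * bs - genes$tss[i])
      values[[ch]][idx] <- values[[ch]][idx] +
        cfg$tss_amp * exp(-d^2 / (2 * cfg$tss_width^2))
    }
    coverage_track(values, genome, bs)
  })

  ## --- chromatin-state tracks from a known HMM (stream 6) ------------------
  hmm <- with_stream(seed, 6, {
    E <- cfg$hmm_emission
    K <- nrow(E)
    A <- matrix((1 - cfg$hmm_self) / (K - 1), K, K)
    diag(A) <- cfg$hmm_self
    model <- bernoulli_hmm(E, A, state_names = rownames(E))
    model$marks <- colnames(E)
    bs <- cfg$hmm_bin
    states <- list(); calls <- list(); counts <- list()
    for (ch in names(genome)) {
      nb <- ceiling(genome[[ch]] / bs)
      st <- integer(nb)
      st[1] <- sample.int(K, 1)
      r <- stats::runif(nb)
      for (t in 2:nb) {
        st[t] <- sample.int(K, 1, prob = A[st[t - 1], ])
      }
      X <- matrix(stats::rbinom(nb * ncol(E), 1, E[st, ]), nb, ncol(E),
                  dimnames = list(NULL, colnames(E)))
      C <- matrix(stats::rpois(nb * ncol(E),
                               ifelse(X == 1, cfg$hmm_lambda_high,
                                      cfg$hmm_lambda_low)),
                  nb, ncol(E), dimnames = list(NULL, colnames(E)))
      states[[ch]] <- st
      calls[[ch]] <- X
      counts[[ch]] <- C
    }
    count_tracks <- lapply(colnames(E), function(mk) {
      coverage_track(lapply(counts, function(m) as.numeric(m[, mk])),
                     genome, bs)
    })
    names(count_tracks) <- colnames(E)
    list(model = model, states = states,
         calls = structure(list(genome = genome, bin_size = bs,
                                marks = colnames(E), calls = calls),
                           class = "binarized_tracks"),
         count_tracks = count_tracks)
  })

  ## --- bait-target connections (stream 7) ----------------------------------
  conn <- with_stream(seed, 7, {
    bl <- cfg$bait_length
    # K4 baits: anchored on a gap peak so the >= 1 bp overlap is guaranteed
    pk <- gap_peaks[sample.int(nrow(gap_peaks), cfg$n_k4_baits,
                               replace = TRUE), ]
    mid <- floor((pk$start + pk$end) / 2)
    bstart <- mid - runif_int(cfg$n_k4_baits, round(0.2 * bl), round(0.8 * bl))
    k4_baits <- data.frame(chrom = pk$chrom, start = bstart,
                           end = bstart + bl, true_class = "K4")
    # nonK4 baits: inside cores, clear of every gap by a bait length
    gap_clear <- iv_setdiff(cores_gr, iv_normalize(GenomicRanges::resize(
      gaps_gr, GenomicRanges::width(gaps_gr) + 2 * bl, fix = "center")))
    np <- sample_position_in(gap_clear, bl, cfg$n_nonk4_baits)
    nonk4_baits <- data.frame(chrom = np$chrom, start = np$start,
                              end = np$end, true_class = "nonK4")
    baits <- rbind(k4_baits, nonk4_baits)
    # exact-coordinate dedup guard: nudge clashes so every bait is distinct
    key <- paste(baits$chrom, baits$start)
    while (any(duplicated(key))) {
      i <- which(duplicated(key))
      baits$start[i] <- baits$start[i] + 1
      baits$end[i] <- baits$end[i] + 1
      key <- paste(baits$chrom, baits$start)
    }
    baits$bait_id <- sprintf("tb_%04d", seq_len(nrow(baits)))
    tl <- cfg$target_length
    compart <- list(cLAD = iv_setdiff(partition$clads, iv_normalize(
      GenomicRanges::resize(k4_gr, GenomicRanges::width(k4_gr) + 2 * tl,
                            fix = "center"))),
      vLAD = partition$vlads, iLAD = partition$ilads)
    is_k4 <- baits$true_class == "K4"
    nconn_vec <- stats::rpois(nrow(baits),
                              ifelse(is_k4, cfg$lambda_k4, cfg$lambda_nonk4))
    bidx <- rep(seq_len(nrow(baits)), nconn_vec)
    n_total <- length(bidx)
    k4_row <- is_k4[bidx]
    cls <- character(n_total)
    cls[k4_row] <- sample(names(cfg$frac_k4), sum(k4_row), replace = TRUE,
                          prob = cfg$frac_k4)
    cls[!k4_row] <- sample(names(cfg$frac_nonk4), sum(!k4_row), replace = TRUE,
                           prob = cfg$frac_nonk4)
    in_peak <- cls == "cLAD" & stats::runif(n_total) <
      ifelse(k4_row, cfg$peak_frac_k4, cfg$peak_frac_nonk4)
    tg_chrom <- character(n_total)
    tg_start <- numeric(n_total)
    ip <- which(in_peak)
    if (length(ip) > 0) {
      p <- gap_peaks[sample.int(nrow(gap_peaks), length(ip), replace = TRUE), ]
      pm <- floor((p$start + p$end) / 2)
      tg_chrom[ip] <- p$chrom
      tg_start[ip] <- pm - runif_int(length(ip), round(0.2 * tl),
                                     round(0.8 * tl))
    }
    for (cl in names(compart)) {
      sel <- which(cls == cl & !in_peak)
      if (length(sel) == 0) next
      pos <- sample_position_in(compart[[cl]], tl, length(sel))
      tg_chrom[sel] <- pos$chrom
      tg_start[sel] <- pos$start
    }
    signif <- data.frame(
      bait_chrom = baits$chrom[bidx], bait_start = baits$start[bidx],
      bait_end = baits$end[bidx],
      target_chrom = tg_chrom, target_start = tg_start,
      target_end = tg_start + tl,
      p_value = stats::runif(n_total, 0, cfg$p_threshold),
      timepoint = sample(tps, n_total, replace = TRUE),
      true_class = baits$true_class[bidx], true_lad_class = cls,
      true_in_peak = in_peak, is_noise = FALSE,
      stringsAsFactors = FALSE)
    n_noise <- round(cfg$noise_frac * nrow(signif))
    if (n_noise > 0) {
      bi <- sample.int(nrow(baits), n_noise, replace = TRUE)
      tp <- sample_position_in(interval_set(
        data.frame(chrom = names(genome), start = 0, end = unname(genome)),
        genome = genome), tl, n_noise)
      noise <- data.frame(
        bait_chrom = baits$chrom[bi], bait_start = baits$start[bi],
        bait_end = baits$end[bi],
        target_chrom = tp$chrom, target_start = tp$start, target_end = tp$end,
        p_value = stats::runif(n_noise, cfg$p_threshold * 1.01, 0.5),
        timepoint = sample(tps, n_noise, replace = TRUE),
        true_class = baits$true_class[bi], true_lad_class = NA,
        true_in_peak = NA, is_noise = TRUE, stringsAsFactors = FALSE)
      signif <- rbind(signif, noise)
    }
    list(baits = baits, table = signif)
  })

  ## --- FISH coordinates (stream 8) -----------------------------------------
  fish <- with_stream(seed, 8, {
    sigs <- list(); geoms <- list()
    for (locus in names(cfg$fish_loci)) {
      shifts <- cfg$fish_loci[[locus]]
      for (cond in names(shifts)) {
        mu <- shifts[[cond]]
        for (i in seq_len(cfg$fish_nuclei)) {
          nid <- sprintf("%s_%s_n%03d", locus, cond, i)
          ax <- pmax(abs(cfg$fish_axes + stats::rnorm(3, 0, cfg$fish_axes_sd)),
                     1.5)
          geoms[[length(geoms) + 1]] <- data.frame(
            nucleus_id = nid, locus = locus, condition = cond,
            cx = 0, cy = 0, cz = 0, ax = ax[1], ay = ax[2], az = ax[3])
          for (allele in 1:2) {
            # red (gene) probe: near the periphery
            u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
            surf <- u / sqrt(sum(u^2 / ax^2))
            red <- surf * (1 - stats::runif(1, 0.05, 0.3))
            # green (enhancer) probe at the condition's shifted distance
            d <- abs(stats::rnorm(1, mu, cfg$fish_sd))
            green <- NULL
            for (try in 1:100) {
              v <- stats::rnorm(3); v <- v / sqrt(sum(v^2))
              g <- red + d * v
              if (sum(g^2 / ax^2) < 1) { green <- g; break }
            }
            if (is.null(green)) {  # point back toward the centre
              g <- red - d * red / sqrt(sum(red^2))
              if (sum(g^2 / ax^2) >= 1) g <- g * 0.99 / sqrt(sum(g^2 / ax^2))
              green <- g
            }
            sigs[[length(sigs) + 1]] <- data.frame(
              nucleus_id = nid, locus = locus, condition = cond,
              channel = c("red", "green"),
              x = c(red[1], green[1]), y = c(red[2], green[2]),
              z = c(red[3], green[3]))
          }
        }
      }
    }
    list(signals = do.call(rbind, sigs), geometry = do.call(rbind, geoms))
  })

  truth <- structure(list(
    config = cfg, seed = seed, genome = genome,
    lad_sets = lad_sets, partition = partition,
    cores = cores_gr, gaps = gaps_gr,
    peaks = list(H3K4me1 = k4_gr, H3K27ac = k27_gr, H3K9me3 = k9_gr),
    lamin_track = lamin_track,
    genes = genes, tss_track = tss_track,
    hmm = hmm,
    baits = conn$baits, connections = conn$table,
    fish = c(fish, list(shifts = cfg$fish_loci))
  ), class = "synthetic_truth")

  if (!is.null(outdir)) write_synthetic(truth, outdir)
  truth
}

#' Write all synthetic inputs as plain-text files
#' @param truth a `synthetic_truth`
#' @param outdir output directory (created if absent)
#' @return `outdir`, invisibly
#' @export
write_synthetic <- function(truth, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(outdir, ...)
  write_genome(truth$genome, fp("genome.tsv"))
  for (tp in names(truth$lad_sets)) {
    write_bed(truth$lad_sets[[tp]], fp(sprintf("lads_%s.bed", tp)))
  }
  for (mk in names(truth$peaks)) {
    write_bed(truth$peaks[[mk]], fp(sprintf("peaks_%s.bed", mk)))
  }
  write_bedgraph(truth$lamin_track, fp("lamin_log2.bedGraph"))
  write_genes(truth$genes[, c("gene_id", "chrom", "tss", "strand",
                              "expression")], fp("genes.tsv"))
  write_bedgraph(truth$tss_track, fp("tss_signal.bedGraph"))
  for (mk in names(truth$hmm$count_tracks)) {
    write_bedgraph(truth$hmm$count_tracks[[mk]],
                   fp(sprintf("counts_%s.bedGraph", mk)))
  }
  cols <- c("bait_chrom", "bait_start", "bait_end", "target_chrom",
            "target_start", "target_end", "p_value", "timepoint")
  write_connections(truth$connections[, cols], fp("connections.tsv"))
  utils::write.table(truth$fish$signals, fp("fish_signals.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$fish$geometry, fp("fish_geometry.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_report(truth, fp("truth.json"))
  invisible(outdir)
}

#' Machine-readable ground-truth report
#'
#' Collects every configured parameter of a synthetic dataset — rates,
#' placement fractions, effect sizes, the generating HMM — into one list,
#' optionally written as JSON, for use in recovery tests.
#'
#' @param truth a `synthetic_truth`
#' @param path optional JSON output path
#' @return the report list, invisibly when writing
#' @export
truth_report <- function(truth, path = NULL) {
  cfg <- truth$config
  rep <- list(
    seed = truth$seed,
    genome = as.list(truth$genome),
    timepoints = cfg$timepoints,
    n_k4_baits = cfg$n_k4_baits,
    n_nonk4_baits = cfg$n_nonk4_baits,
    lambda_k4 = cfg$lambda_k4,
    lambda_nonk4 = cfg$lambda_nonk4,
    frac_k4 = as.list(cfg$frac_k4),
    frac_nonk4 = as.list(cfg$frac_nonk4),
    peak_frac_k4 = cfg$peak_frac_k4,
    peak_frac_nonk4 = cfg$peak_frac_nonk4,
    p_threshold = cfg$p_threshold,
    expression_threshold = cfg$expression_threshold,
    lamin_mean = as.list(cfg$lamin_mean),
    lamin_sd = cfg$lamin_sd,
    hmm_states = rownames(cfg$hmm_emission),
    hmm_marks = cfg$hmm_marks,
    hmm_emission = cfg$hmm_emission,
    hmm_self_transition = cfg$hmm_self,
    fish_shifts = lapply(cfg$fish_loci, as.list),
    fish_sd = cfg$fish_sd,
    fish_nuclei = cfg$fish_nuclei
  )
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
    return(invisible(rep))
  }
  rep
}
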