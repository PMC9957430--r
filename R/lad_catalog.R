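#' Partition the genome into cLADs, vLADs and inter-LADs
#'
#' Constitutive LADs (cLADs) are the base-level intersection of the LAD sets
#' across all timepoints; variable LADs (vLADs) are bases covered at some but
#' not all timepoints (union minus intersection); inter-LADs (iLADs) are the
#' rest of the genome. The three classes are pairwise disjoint and tile the
#' genome.
#'
#' @param lad_sets list of >= 2 normalized `GRanges` (one per timepoint),
#'   all on the same genome. Names are taken as timepoint labels.
#' @param vlads optional externally supplied vLAD set (`GRanges`); when given
#'   it replaces the union-minus-intersection definition (bases it shares
#'   with the derived cLADs stay cLAD; iLADs absorb the remainder).
#' @return object of class `lad_partition`: list with `clads`, `vlads`,
#'   `ilads` (`GRanges`) and `genome`.
#' @export
derive_lad_partition <- function(lad_sets, vlads = NULL) {
  if (length(lad_sets) < 2) stop("need at least 2 timepoints of LAD calls")
  lad_sets <- lapply(lad_sets, iv_normalize)
  for (s in lad_sets[-1]) check_same_genome(lad_sets[[1]], s)
  genome <- iv_genome(lad_sets[[1]])
  clads <- Reduce(iv_intersect, lad_sets)
  union_all <- iv_normalize(do.call(c, unname(lapply(lad_sets, granges_unstranded))))
  if (is.null(vlads)) {
    vlads <- iv_setdiff(union_all, clads)
    ilads <- iv_complement(union_all)
  } else {
    vlads <- iv_setdiff(iv_normalize(vlads), clads)
    ilads <- iv_complement(iv_normalize(c(granges_unstranded(clads),
                                          granges_unstranded(vlads))))
  }
  structure(list(clads = clads, vlads = vlads, ilads = ilads, genome = genome),
            class = "lad_partition")
}

#' @export
print.lad_partition <- function(x, ...) {
  gs <- sum(as.numeric(x$genome))
  cat(sprintf("LAD partition of %.3g bp genome:\n", gs))
  for (k in c("clads", "vlads", "ilads")) {
    cat(sprintf("  %-6s %6d intervals, %12.0f bp (%.1f%%)\n", k,
                length(x[[k]]), iv_base_coverage(x[[k]]),
                100 * iv_base_coverage(x[[k]]) / gs))
  }
  invisible(x)
}

#' Annotate H3K4me1 regions within cLADs
#'
#' A "K4 region" is a cLAD subregion owning at least one H3K4me1 peak: peaks
#' closer than `merge_gap` are clustered, and clusters are clipped to cLAD
#' bounds. The remaining cLAD bases form the non-K4 regions.
#'
#' @param clads normalized `GRanges` of constitutive LADs
#' @param k4_peaks normalized `GRanges` of H3K4me1 peaks
#' @param merge_gap peaks separated by fewer than this many bases are merged
#'   into one region (default 10 kb)
#' @return list with `k4_regions` and `nonk4_regions` (`GRanges`), disjoint,
#'   jointly covering the cLADs
#' @export
annotate_clad_regions <- function(clads, k4_peaks, merge_gap = 10000) {
  if (merge_gap < 0) stop("merge_gap must be non-negative")
  clusters <- GenomicRanges::reduce(granges_unstranded(k4_peaks),
                                    min.gapwidth = max(1L, as.integer(merge_gap)))
  k4_regions <- iv_intersect(clusters, clads)
  nonk4_regions <- iv_setdiff(clads, k4_regions)
  list(k4_regions = k4_regions, nonk4_regions = nonk4_regions)
}

#' Length-weighted mean signal per region
#'
#' For each region, the mean of overlapping track bins weighted by the number
#' of region bases each bin contributes. Bins with missing data are excluded
#' from the weighting; a region overlapping no data at all gets `NA`.
#'
#' @param track `coverage_track`
#' @param regions `GRanges`
#' @return numeric vector, one mean per region
#' @export
region_mean_signal <- function(track, regions) {
  if (length(regions) == 0) return(numeric(0))
  bs <- track$bin_size
  chroms <- as.character(GenomicRanges::seqnames(regions))
  starts <- GenomicRanges::start(regions) - 1L  # 0-based
  ends <- GenomicRanges::end(regions)
  vapply(seq_along(regions), function(i) {
    v <- track$values[[chroms[i]]]
    if (is.null(v)) return(NA_real_)
    b0 <- floor(starts[i] / bs)
    b1 <- floor((ends[i] - 1) / bs)
    idx <- (b0:b1) + 1
    bin_lo <- (b0:b1) * bs
    bin_hi <- bin_lo + bs
    w <- pmin(bin_hi, ends[i]) - pmax(bin_lo, starts[i])
    vals <- v[idx]
    ok <- !is.na(vals)
    if (!any(ok)) return(NA_real_)
    sum(w[ok] * vals[ok]) / sum(w[ok])
  }, numeric(1))
}

#' Welch's unpaired two-tailed t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom,
#' as used for all group contrasts in the pipeline (lamin enrichment between
#' region classes, per-bait connection counts, FISH distances).
#'
#' @param a,b numeric vectors (each n >= 2)
#' @return object of class `welch_test`: list with `t_statistic`, `dof`,
#'   `p_value`, `group_means`
#' @export
welch_test <- function(a, b) {
  a <- a[!is.na(a)]
  b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each group needs n >= 2")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("degenerate variance: both groups are constant")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(t_statistic = unname(ht$statistic),
                 dof = unname(ht$parameter),
                 p_value = ht$p.value,
                 group_means = c(mean(a), mean(b))),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t = %.4g, df = %.3g, p = %.4g (means %.4g vs %.4g)\n",
              x$t_statistic, x$dof, x$p_value,
              x$group_means[1], x$group_means[2]))
  invisible(x)
}
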