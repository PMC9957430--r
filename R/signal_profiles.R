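#' Per-bin log2(ChIP/input) ratio track
#'
#' A pseudocount stabilises low-coverage bins. Bins where both signals are
#' zero (or either is missing) are reported as missing rather than zero.
#'
#' @param chip,input `coverage_track`s on the same genome and bin grid
#' @param pseudocount added to both numerator and denominator (default 1)
#' @return `coverage_track` of log2 ratios
#' @export
log2_ratio_track <- function(chip, input, pseudocount = 1) {
  check_same_grid(chip, input)
  values <- lapply(names(chip$genome), function(ch) {
    x <- chip$values[[ch]]
    y <- input$values[[ch]]
    r <- log2((x + pseudocount) / (y + pseudocount))
    r[(!is.na(x) & !is.na(y) & x == 0 & y == 0)] <- NA_real_
    r
  })
  names(values) <- names(chip$genome)
  coverage_track(values, chip$genome, chip$bin_size)
}

#' Meta-profile of signal around transcription start sites
#'
#' Averages a coverage track across genes at fixed offsets from the TSS.
#' Offsets run from `-flank` to `+flank` in steps of `bin`; for minus-strand
#' genes, offsets are mirrored so positive offsets always point downstream of
#' transcription. Genes whose window extends past a chromosome end contribute
#' only their covered positions.
#'
#' @param track `coverage_track`
#' @param genes data.frame with columns `gene_id`, `chrom`, `tss` (0-based),
#'   `strand` (`+`/`-`), `expression`
#' @param flank half-window in bases (default 4000), a multiple of `bin`
#' @param bin profile step in bases (default 50)
#' @return data.frame of class `tss_profile`: `offset`, `mean_signal`,
#'   `n_genes`
#' @export
tss_metaprofile <- function(track, genes, flank = 4000, bin = 50) {
  if (nrow(genes) == 0) stop("empty gene list")
  if (flank %% bin != 0) stop("flank must be a multiple of bin")
  offsets <- seq(-flank, flank, by = bin)
  sums <- numeric(length(offsets))
  ns <- integer(length(offsets))
  for (i in seq_len(nrow(genes))) {
    sgn <- if (genes$strand[i] == "-") -1 else 1
    pos <- genes$tss[i] + sgn * offsets
    vals <- track_value_at(track, rep(genes$chrom[i], length(pos)), pos)
    ok <- !is.na(vals)
    sums[ok] <- sums[ok] + vals[ok]
    ns[ok] <- ns[ok] + 1L
  }
  out <- data.frame(offset = offsets,
                    mean_signal = ifelse(ns > 0, sums / ns, NA_real_),
                    n_genes = ns)
  class(out) <- c("tss_profile", "data.frame")
  out
}

#' Split genes into expressed and non-expressed classes
#'
#' A gene is expressed when its normalized read count reaches the threshold
#' (boundary inclusive, default >= 15).
#'
#' @param genes data.frame with an `expression` column
#' @param threshold minimum normalized read count (default 15)
#' @return list with `expressed` and `non_expressed` data.frames
#' @export
filter_expressed <- function(genes, threshold = 15) {
  if (threshold < 0) stop("threshold must be non-negative")
  keep <- genes$expression >= threshold
  list(expressed = genes[keep, , drop = FALSE],
       non_expressed = genes[!keep, , drop = FALSE])
}

#' Relative expression by the 2^-ddCt method
#'
#' Fold change of a target gene relative to a reference gene (e.g. SF3A1),
#' normalized to a calibrator condition:
#' `2^-((ct_target - ct_ref) - (ct_target_cal - ct_ref_cal))`.
#'
#' @param ct_target,ct_ref Ct values in the test condition
#' @param ct_target_cal,ct_ref_cal Ct values in the calibrator condition
#' @return fold change (1 = no change)
#' @export
relative_expression <- function(ct_target, ct_ref, ct_target_cal, ct_ref_cal) {
  ddct <- (ct_target - ct_ref) - (ct_target_cal - ct_ref_cal)
  2^(-ddct)
}

#' Read a gene-model table
#' @param path TSV with columns gene_id, chrom, tss, strand, expression
#' @return data.frame
#' @export
read_genes <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    colClasses = c(gene_id = "character", chrom = "character",
                                   tss = "integer", strand = "character",
                                   expression = "numeric"))
}

#' Write a gene-model table
#' @param genes data.frame
#' @param path output TSV
#' @export
write_genes <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
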