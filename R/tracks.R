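#' Construct a binned coverage track
#'
#' A coverage track stores one real value per fixed-width bin per chromosome.
#' Bin `i` (1-based) of a chromosome covers bases `[(i-1)*bin_size,
#' i*bin_size)` in 0-based half-open coordinates; the last bin may be partial.
#' `NA` marks bins with no data — missing is distinct from zero throughout.
#'
#' @param values named list (one numeric vector per chromosome) or NULL to
#'   create an all-NA track.
#' @param genome named chromosome-length vector.
#' @param bin_size bin width in bases (>= 1).
#' @return object of class `coverage_track`
#' @export
coverage_track <- function(values = NULL, genome, bin_size) {
  if (bin_size < 1) stop("bin_size must be >= 1")
  nbins <- ceiling(genome / bin_size)
  if (is.null(values)) {
    values <- lapply(nbins, function(n) rep(NA_real_, n))
  }
  if (!setequal(names(values), names(genome))) {
    stop("track chromosomes do not match genome")
  }
  values <- values[names(genome)]
  for (ch in names(genome)) {
    if (length(values[[ch]]) != nbins[[ch]]) {
      stop(sprintf("chromosome %s: expected %d bins, got %d",
                   ch, nbins[[ch]], length(values[[ch]])))
    }
  }
  structure(list(genome = genome, bin_size = as.integer(bin_size),
                 values = values),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d chromosomes, bin_size %d, %d bins (%d missing)\n",
              length(x$genome), x$bin_size,
              sum(lengths(x$values)), sum(vapply(x$values, function(v) sum(is.na(v)), 0))))
  invisible(x)
}

n_bins <- function(track) lengths(track$values)

check_same_grid <- function(a, b) {
  if (!identical(a$genome[sort(names(a$genome))], b$genome[sort(names(b$genome))]) ||
      a$bin_size != b$bin_size) {
    stop("tracks are on different bin grids")
  }
}

#' Look up track values at genomic positions
#' @param track a `coverage_track`
#' @param chrom chromosome names
#' @param pos 0-based base offsets
#' @return numeric vector (NA outside the genome or in missing bins)
#' @export
track_value_at <- function(track, chrom, pos) {
  out <- rep(NA_real_, length(pos))
  for (ch in unique(chrom)) {
    sel <- which(chrom == ch)
    v <- track$values[[ch]]
    if (is.null(v)) next
    idx <- floor(pos[sel] / track$bin_size) + 1
    ok <- pos[sel] >= 0 & pos[sel] < track$genome[[ch]]
    out[sel[ok]] <- v[idx[ok]]
  }
  out
}

#' Project bedGraph records onto a bin grid
#'
#' Each bin receives the coverage-weighted mean of the record values
#' overlapping it; bins touched by no record are `NA`.
#'
#' @param x a `GRanges` with a numeric `score` column (e.g. from
#'   [read_bedgraph()]), or a path to a bedGraph file.
#' @param genome named chromosome-length vector
#' @param bin_size bin width (bases)
#' @return `coverage_track`
#' @export
track_from_bedgraph <- function(x, genome, bin_size) {
  if (is.character(x)) x <- read_bedgraph(x, genome)
  score_rle <- GenomicRanges::coverage(x, weight = x$score)
  hit_rle <- GenomicRanges::coverage(x)
  values <- list()
  for (ch in names(genome)) {
    len <- genome[[ch]]
    nb <- ceiling(len / bin_size)
    starts <- seq.int(1L, by = bin_size, length.out = nb)
    ends <- pmin(starts + bin_size - 1L, len)
    if (ch %in% names(score_rle)) {
      sv <- IRanges::Views(score_rle[[ch]], start = starts, end = ends)
      hv <- IRanges::Views(hit_rle[[ch]], start = starts, end = ends)
      ssum <- IRanges::viewSums(sv)
      hsum <- IRanges::viewSums(hv)
      vals <- ifelse(hsum > 0, ssum / hsum, NA_real_)
    } else {
      vals <- rep(NA_real_, nb)
    }
    values[[ch]] <- as.numeric(vals)
  }
  coverage_track(values, genome, bin_size)
}

#' Read a bedGraph file
#' @param path bedGraph file (chrom, start, end, value)
#' @param genome named chromosome-length vector
#' @return `GRanges` with `score`
#' @export
read_bedgraph <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  attach_genome(gr, genome, path)
}

#' Write a coverage track as bedGraph
#'
#' Missing bins are omitted; runs of equal-valued adjacent bins are merged
#' into single records.
#'
#' @param track `coverage_track`
#' @param path output path
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bs <- track$bin_size
  for (ch in names(track$genome)) {
    v <- track$values[[ch]]
    if (all(is.na(v))) next
    r <- rle(v)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1
    vals <- v[starts_idx]
    keep <- !is.na(vals)
    starts <- (starts_idx[keep] - 1) * bs
    ends <- pmin(ends_idx[keep] * bs, track$genome[[ch]])
    writeLines(sprintf("%s\t%d\t%d\t%.6g", ch, starts, ends, vals[keep]), con)
  }
  invisible(path)
}
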