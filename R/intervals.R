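#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqlevels seqlevels<- seqnames
#'   Seqinfo seqinfo seqinfo<- sortSeqlevels
NULL

#' Construct an interval set on a fixed genome
#'
#' Interval sets are `GRanges` objects carrying the genome (chromosome sizes)
#' in their `seqinfo`. Input coordinates follow the BED convention: 0-based
#' starts, exclusive ends, so an interval `[start, end)` covers
#' `end - start` bases. Internally the 1-based closed convention of
#' `GenomicRanges` is used; conversion happens here, at the boundary, and in
#' the BED readers/writers.
#'
#' @param chrom character vector of chromosome names, or a data.frame with
#'   columns `chrom`, `start`, `end` (and optionally `name`, `strand`).
#' @param start,end integer vectors, 0-based half-open.
#' @param genome named integer vector of chromosome lengths (bases).
#' @param strand optional strand vector (`"+"`, `"-"`, `"*"`); strand is
#'   carried but ignored by all overlap operations.
#' @param name optional labels stored in `mcols()$name`.
#' @return a `GRanges` with `seqlengths` set.
#' @export
interval_set <- function(chrom, start = NULL, end = NULL, genome,
                         strand = NULL, name = NULL) {
  if (is.data.frame(chrom)) {
    df <- chrom
    strand <- if ("strand" %in% names(df)) df$strand else NULL
    name <- if ("name" %in% names(df)) df$name else NULL
    start <- df$start
    end <- df$end
    chrom <- df$chrom
  }
  if (is.null(genome) || is.null(names(genome))) {
    stop("'genome' must be a named vector of chromosome lengths")
  }
  chrom <- as.character(chrom)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start < 0)) stop("negative start coordinate")
  if (any(end <= start)) {
    i <- which(end <= start)[1]
    stop(sprintf("empty or inverted interval %s:%d-%d", chrom[i], start[i], end[i]))
  }
  unknown <- setdiff(unique(chrom), names(genome))
  if (length(unknown) > 0) {
    stop("chromosomes absent from genome: ", paste(unknown, collapse = ", "))
  }
  over <- which(end > genome[chrom])
  if (length(over) > 0) {
    i <- over[1]
    stop(sprintf("interval %s:%d-%d exceeds chromosome length %d",
                 chrom[i], start[i], end[i], genome[chrom[i]]))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = if (is.null(strand)) "*" else strand,
    seqinfo = genome_seqinfo(genome)
  )
  if (!is.null(name)) S4Vectors::mcols(gr)$name <- name
  gr
}

genome_seqinfo <- function(genome) {
  GenomeInfoDb::Seqinfo(seqnames = names(genome),
                        seqlengths = as.integer(genome))
}

#' Extract the genome (chrom sizes) from an interval set
#' @param x a `GRanges`
#' @return named integer vector
#' @export
iv_genome <- function(x) {
  sl <- GenomeInfoDb::seqlengths(x)
  if (any(is.na(sl))) stop("interval set has no genome (missing seqlengths)")
  sl
}

check_same_genome <- function(a, b) {
  ga <- iv_genome(a)
  gb <- iv_genome(b)
  if (!identical(ga[sort(names(ga))], gb[sort(names(gb))])) {
    stop("interval sets are on different genomes")
  }
}

#' Normalize an interval set
#'
#' Sorts and merges overlapping and book-ended intervals, so that per
#' chromosome the set is disjoint and sorted. Strand is dropped (overlap
#' operations are strand-blind throughout).
#'
#' @param x a `GRanges` from [interval_set()] or a reader.
#' @return normalized `GRanges`
#' @export
iv_normalize <- function(x) {
  x <- granges_unstranded(x)
  GenomicRanges::reduce(x, min.gapwidth = 1L)
}

granges_unstranded <- function(x) {
  GenomicRanges::strand(x) <- "*"
  S4Vectors::mcols(x) <- NULL
  x
}

#' Base-level intersection of two interval sets
#'
#' An overlap exists iff the shared length is at least 1 bp; book-ended
#' intervals (half-open coordinates touching) share zero bases and do not
#' intersect.
#'
#' @param a,b normalized `GRanges` on the same genome
#' @return `GRanges` covering exactly the bases present in both
#' @export
iv_intersect <- function(a, b) {
  check_same_genome(a, b)
  GenomicRanges::intersect(granges_unstranded(a), granges_unstranded(b))
}

#' Complement of an interval set over its genome
#' @param x normalized `GRanges` with seqlengths
#' @return `GRanges` covering every base not in `x`
#' @export
iv_complement <- function(x) {
  iv_genome(x)  # errors when genome missing
  g <- GenomicRanges::gaps(granges_unstranded(x))
  g[GenomicRanges::strand(g) == "*"]
}

#' Total bases covered by an interval set
#' @param x normalized `GRanges`
#' @return number of covered bases
#' @export
iv_base_coverage <- function(x) {
  sum(as.numeric(GenomicRanges::width(x)))
}

#' Set difference (bases in `a` not in `b`)
#' @param a,b normalized `GRanges` on the same genome
#' @return `GRanges`
#' @export
iv_setdiff <- function(a, b) {
  check_same_genome(a, b)
  GenomicRanges::setdiff(granges_unstranded(a), granges_unstranded(b))
}

#' Convert an interval set to a BED-convention data.frame
#' @param x a `GRanges`
#' @return data.frame with `chrom`, `start` (0-based), `end` (exclusive)
#' @export
iv_as_bed_df <- function(x) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(x)),
    start = GenomicRanges::start(x) - 1L,
    end = GenomicRanges::end(x),
    stringsAsFactors = FALSE
  )
  if (!is.null(S4Vectors::mcols(x)$name)) df$name <- S4Vectors::mcols(x)$name
  df
}

# ---- I/O --------------------------------------------------------------------

#' Read a two-column chromosome-sizes file
#' @param path TSV with columns chrom, length
#' @return named integer vector
#' @export
read_genome <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "integer"))
  stats::setNames(df$length, df$chrom)
}

#' Write a chromosome-sizes file
#' @param genome named integer vector
#' @param path output path
#' @export
write_genome <- function(genome, path) {
  utils::write.table(data.frame(names(genome), as.integer(genome)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a BED3/BED6 file as an interval set
#'
#' Uses `rtracklayer`, which performs the 0-based half-open to 1-based closed
#' conversion. Chromosome names are matched exactly against the genome; a
#' mismatch in the name sets is reported rather than silently aliased.
#'
#' @param path BED file
#' @param genome named chromosome-length vector
#' @return `GRanges` with seqlengths set
#' @export
read_bed <- function(path, genome) {
  gr <- rtracklayer::import(path, format = "BED")
  attach_genome(gr, genome, path)
}

attach_genome <- function(gr, genome, path) {
  unknown <- setdiff(GenomeInfoDb::seqlevels(gr), names(genome))
  if (length(unknown) > 0) {
    stop(sprintf("%s: chromosome names not in genome: %s",
                 path, paste(unknown, collapse = ", ")))
  }
  GenomeInfoDb::seqlevels(gr) <- names(genome)
  GenomeInfoDb::seqinfo(gr) <- genome_seqinfo(genome)
  bad <- which(GenomicRanges::end(gr) > GenomeInfoDb::seqlengths(gr)[
    as.character(GenomicRanges::seqnames(gr))])
  if (length(bad) > 0) {
    stop(sprintf("%s: interval %s:%d-%d exceeds chromosome length", path,
                 as.character(GenomicRanges::seqnames(gr))[bad[1]],
                 GenomicRanges::start(gr)[bad[1]] - 1L,
                 GenomicRanges::end(gr)[bad[1]]))
  }
  gr
}

#' Write an interval set as BED
#' @param x `GRanges`
#' @param path output path
#' @export
write_bed <- function(x, path) {
  rtracklayer::export(x, path, format = "BED")
  invisible(path)
}
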