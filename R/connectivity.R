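#' Load enhancer-capture Hi-C bait-target connections
#'
#' Reads a connection table (one row per bait-target link with a significance
#' p-value and a timepoint label), keeps significant rows (p <= threshold,
#' boundary inclusive), pools all timepoints, and deduplicates baits on exact
#' coordinates. Connection multiplicity across timepoints is retained.
#'
#' @param x data.frame or path to a TSV with columns `bait_chrom`,
#'   `bait_start`, `bait_end`, `target_chrom`, `target_start`, `target_end`,
#'   `p_value`, `timepoint` (BED-style 0-based half-open coordinates)
#' @param genome named chromosome-length vector
#' @param p_threshold significance cutoff (default 0.01)
#' @return list with `baits` (`GRanges` with `bait_id`) and `connections`
#'   (data.frame: `bait_id`, `chrom`, `start`, `end`, `p_value`, `timepoint`)
#' @export
load_connections <- function(x, genome, p_threshold = 0.01) {
  if (is.character(x)) {
    x <- utils::read.table(x, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  }
  need <- c("bait_chrom", "bait_start", "bait_end", "target_chrom",
            "target_start", "target_end", "p_value", "timepoint")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols) > 0) {
    stop("connection table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  coord_cols <- c("bait_start", "bait_end", "target_start", "target_end")
  for (cc in coord_cols) {
    v <- suppressWarnings(as.numeric(x[[cc]]))
    bad <- which(is.na(v))
    if (length(bad) > 0) {
      stop(sprintf("malformed coordinate in column %s at line %d", cc, bad[1]))
    }
    x[[cc]] <- v
  }
  bad <- which(x$bait_end <= x$bait_start | x$target_end <= x$target_start)
  if (length(bad) > 0) {
    stop(sprintf("malformed coordinate (empty interval) at line %d", bad[1]))
  }
  x <- x[x$p_value <= p_threshold, , drop = FALSE]
  key <- paste(x$bait_chrom, x$bait_start, x$bait_end, sep = ":")
  ukey <- unique(key)
  bait_id <- paste0("bait_", formatC(seq_along(ukey), width = 5, flag = "0"))
  names(bait_id) <- ukey
  first <- x[!duplicated(key), , drop = FALSE]
  baits <- interval_set(chrom = first$bait_chrom, start = first$bait_start,
                        end = first$bait_end, genome = genome)
  S4Vectors::mcols(baits)$bait_id <- bait_id[paste(
    first$bait_chrom, first$bait_start, first$bait_end, sep = ":")]
  connections <- data.frame(
    bait_id = unname(bait_id[key]),
    chrom = x$target_chrom,
    start = x$target_start,
    end = x$target_end,
    p_value = x$p_value,
    timepoint = as.character(x$timepoint),
    stringsAsFactors = FALSE
  )
  list(baits = baits, connections = connections)
}

targets_granges <- function(connections, genome) {
  interval_set(chrom = connections$chrom, start = connections$start,
               end = connections$end, genome = genome)
}

#' Baits overlapping constitutive LADs
#'
#' Keeps baits sharing at least 1 bp with the cLAD footprint; a bait merely
#' abutting a cLAD boundary (zero shared bases) is excluded.
#'
#' @param baits `GRanges` with `bait_id`
#' @param partition `lad_partition`
#' @return `GRanges` subset
#' @export
baits_in_clads <- function(baits, partition) {
  hits <- GenomicRanges::countOverlaps(baits, partition$clads, minoverlap = 1L,
                                       ignore.strand = TRUE)
  baits[hits > 0]
}

#' Classify cLAD baits as K4 or nonK4
#'
#' A bait is a "K4 bait" iff it overlaps by >= 1 bp an H3K4me1 peak lying in
#' a cLAD; otherwise it is a "nonK4 bait". Peaks are clipped to cLADs first,
#' so peak bases outside cLADs never confer K4 status.
#'
#' @param clad_baits `GRanges` with `bait_id` (from [baits_in_clads()])
#' @param k4_peaks normalized `GRanges` of H3K4me1 peaks
#' @param clads normalized `GRanges` of cLADs
#' @return object of class `bait_classification`: list with `class_of`
#'   (named character vector, bait_id -> "K4"/"nonK4") and `baits`
#' @export
classify_baits <- function(clad_baits, k4_peaks, clads) {
  peaks_in_clads <- iv_intersect(iv_normalize(k4_peaks), clads)
  hits <- GenomicRanges::countOverlaps(clad_baits, peaks_in_clads,
                                       minoverlap = 1L, ignore.strand = TRUE)
  cls <- ifelse(hits > 0, "K4", "nonK4")
  names(cls) <- S4Vectors::mcols(clad_baits)$bait_id
  structure(list(class_of = cls, baits = clad_baits),
            class = "bait_classification")
}

#' @export
print.bait_classification <- function(x, ...) {
  tb <- table(factor(x$class_of, levels = c("K4", "nonK4")))
  cat(sprintf("%d cLAD baits: %d K4, %d nonK4\n",
              length(x$class_of), tb[["K4"]], tb[["nonK4"]]))
  invisible(x)
}

#' Per-bait connection counts and class contrast
#'
#' Counts significant connections per classified bait (baits with no
#' connection count as 0, not dropped), summarises per class, and contrasts
#' classes with Welch's t-test. Because the per-bait mean can be computed
#' over connections (with multiplicity across timepoints) or over unique
#' target coordinates, both statistics are reported.
#'
#' @param connections connection data.frame (see [load_connections()])
#' @param classification `bait_classification`
#' @return list: `per_bait` (bait_id, class, n_connections, n_unique_targets),
#'   `class_stats` (per class mean/median/total for both counting rules),
#'   `welch` and `welch_unique` (`welch_test` results)
#' @export
connection_density <- function(connections, classification) {
  ids <- names(classification$class_of)
  conn <- connections[connections$bait_id %in% ids, , drop = FALSE]
  n_conn <- table(factor(conn$bait_id, levels = ids))
  tkey <- paste(conn$bait_id, conn$chrom, conn$start, conn$end, sep = ":")
  uconn <- conn[!duplicated(tkey), , drop = FALSE]
  n_uniq <- table(factor(uconn$bait_id, levels = ids))
  per_bait <- data.frame(
    bait_id = ids,
    class = unname(classification$class_of[ids]),
    n_connections = as.integer(n_conn),
    n_unique_targets = as.integer(n_uniq),
    stringsAsFactors = FALSE
  )
  agg <- function(col) {
    do.call(rbind, lapply(split(per_bait[[col]], per_bait$class), function(v) {
      data.frame(mean = mean(v), median = stats::median(v), total = sum(v),
                 n_baits = length(v))
    }))
  }
  cs <- agg("n_connections")
  cs_u <- agg("n_unique_targets")
  class_stats <- data.frame(
    class = rownames(cs),
    n_baits = cs$n_baits,
    mean_connections = cs$mean, median_connections = cs$median,
    total_connections = cs$total,
    mean_unique_targets = cs_u$mean, median_unique_targets = cs_u$median,
    total_unique_targets = cs_u$total,
    stringsAsFactors = FALSE
  )
  rownames(class_stats) <- NULL
  k4 <- per_bait$class == "K4"
  safe_welch <- function(a, b) {
    if (length(a) < 2 || length(b) < 2) return(NULL)
    tryCatch(welch_test(a, b), error = function(e) NULL)
  }
  w <- safe_welch(per_bait$n_connections[k4], per_bait$n_connections[!k4])
  wu <- safe_welch(per_bait$n_unique_targets[k4],
                   per_bait$n_unique_targets[!k4])
  list(per_bait = per_bait, class_stats = class_stats,
       welch = w, welch_unique = wu)
}

#' Annotate connection targets by LAD class and H3K4me1 status
#'
#' Each target receives exactly one LAD class. Under the default
#' `largest_overlap` strategy this is the class contributing the most bases
#' (ties broken cLAD > vLAD > iLAD); under `any_overlap_priority` a target
#' touching a cLAD by >= 1 bp is cLAD, else vLAD on any overlap, else iLAD.
#' K4 status is >= 1 bp overlap with any H3K4me1 peak.
#'
#' @param connections connection data.frame
#' @param partition `lad_partition`
#' @param k4_peaks normalized `GRanges` of H3K4me1 peaks
#' @param strategy `"largest_overlap"` (default) or `"any_overlap_priority"`
#' @return the connection data.frame with `lad_class` (`cLAD`/`vLAD`/`iLAD`)
#'   and `k4_status` (`in_K4_peak`/`outside_K4_peak`) columns added
#' @export
annotate_targets <- function(connections, partition, k4_peaks,
                             strategy = c("largest_overlap",
                                          "any_overlap_priority")) {
  strategy <- match.arg(strategy)
  tg <- targets_granges(connections, partition$genome)
  classes <- c("cLAD", "vLAD", "iLAD")
  sets <- list(cLAD = partition$clads, vLAD = partition$vlads,
               iLAD = partition$ilads)
  ovl <- sapply(sets, function(s) {
    hits <- GenomicRanges::findOverlaps(tg, s, ignore.strand = TRUE)
    w <- GenomicRanges::width(IRanges::pintersect(
      tg[S4Vectors::queryHits(hits)], s[S4Vectors::subjectHits(hits)]))
    out <- numeric(length(tg))
    acc <- tapply(w, S4Vectors::queryHits(hits), sum)
    out[as.integer(names(acc))] <- acc
    out
  })
  ovl <- matrix(ovl, ncol = 3, dimnames = list(NULL, classes))
  lad_class <- if (strategy == "largest_overlap") {
    # max.col with ties.method "first" implements the cLAD > vLAD > iLAD
    # precedence because columns are ordered that way
    classes[max.col(ovl, ties.method = "first")]
  } else {
    ifelse(ovl[, "cLAD"] > 0, "cLAD",
           ifelse(ovl[, "vLAD"] > 0, "vLAD", "iLAD"))
  }
  k4_hits <- GenomicRanges::countOverlaps(tg, iv_normalize(k4_peaks),
                                          minoverlap = 1L, ignore.strand = TRUE)
  connections$lad_class <- lad_class
  connections$k4_status <- ifelse(k4_hits > 0, "in_K4_peak", "outside_K4_peak")
  connections
}

#' Target-category proportions per bait class
#'
#' Fraction of a bait class's targets in each of the six (LAD class x K4
#' status) cells; proportions within a class sum to 1. A class with zero
#' annotated connections yields rows with `n = 0` and `NA` proportions.
#'
#' @param annotation annotated connection data.frame (see
#'   [annotate_targets()])
#' @param classification `bait_classification`
#' @return data.frame: `class`, `lad_class`, `k4_status`, `n`, `prop`
#' @export
summarize_proportions <- function(annotation, classification) {
  annotation$class <- unname(classification$class_of[annotation$bait_id])
  cells <- expand.grid(class = c("K4", "nonK4"),
                       lad_class = c("cLAD", "vLAD", "iLAD"),
                       k4_status = c("in_K4_peak", "outside_K4_peak"),
                       stringsAsFactors = FALSE)
  counts <- mapply(function(cl, lc, ks) {
    sum(annotation$class == cl & annotation$lad_class == lc &
          annotation$k4_status == ks, na.rm = TRUE)
  }, cells$class, cells$lad_class, cells$k4_status)
  cells$n <- as.integer(counts)
  totals <- tapply(cells$n, cells$class, sum)
  cells$prop <- ifelse(totals[cells$class] > 0,
                       cells$n / totals[cells$class], NA_real_)
  cells <- cells[order(cells$class, cells$lad_class, cells$k4_status), ]
  rownames(cells) <- NULL
  cells
}

#' Write a connection table
#' @param connections data.frame (target coordinates 0-based half-open)
#' @param path output TSV
#' @export
write_connections <- function(connections, path) {
  utils::write.table(connections, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
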