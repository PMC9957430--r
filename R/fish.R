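#' Pair red and green FISH signals into alleles
#'
#' An analyzable nucleus carries exactly two red (gene) and two green
#' (enhancer) signals — one per allele. Signals are matched one-to-one by
#' minimising the total red-green distance over the two possible pairings;
#' ties keep the input order. Nuclei with the wrong signal multiplicity are
#' excluded and listed in the `excluded` attribute.
#'
#' @param signals data.frame with columns `nucleus_id`, `channel`
#'   (`"red"`/`"green"`), `x`, `y`, `z` (micrometres), and optionally
#'   `condition`
#' @return data.frame with one row per allele: `nucleus_id`, `allele`,
#'   red and green coordinates, `condition` (if present); excluded nucleus
#'   ids in `attr(, "excluded")`
#' @export
pair_alleles <- function(signals) {
  out <- list()
  excluded <- character(0)
  for (nid in unique(signals$nucleus_id)) {
    s <- signals[signals$nucleus_id == nid, , drop = FALSE]
    red <- s[s$channel == "red", , drop = FALSE]
    green <- s[s$channel == "green", , drop = FALSE]
    if (nrow(red) != 2 || nrow(green) != 2) {
      excluded <- c(excluded, as.character(nid))
      next
    }
    d <- function(i, j) sqrt(sum((as.numeric(red[i, c("x", "y", "z")]) -
                                    as.numeric(green[j, c("x", "y", "z")]))^2))
    straight <- d(1, 1) + d(2, 2)
    crossed <- d(1, 2) + d(2, 1)
    gidx <- if (crossed < straight) c(2, 1) else c(1, 2)
    rows <- data.frame(
      nucleus_id = nid, allele = 1:2,
      red_x = red$x, red_y = red$y, red_z = red$z,
      green_x = green$x[gidx], green_y = green$y[gidx], green_z = green$z[gidx]
    )
    if ("condition" %in% names(s)) rows$condition <- s$condition[1]
    out[[length(out) + 1]] <- rows
  }
  res <- if (length(out) > 0) do.call(rbind, out) else
    data.frame(nucleus_id = character(0), allele = integer(0))
  attr(res, "excluded") <- excluded
  res
}

#' Euclidean 3D probe-probe distance
#' @param p,q numeric length-3 vectors, or matrices with 3 columns
#'   (rowwise distances)
#' @return distance(s) in the input units (micrometres)
#' @export
probe_distance <- function(p, q) {
  if (is.null(dim(p))) p <- matrix(p, ncol = 3)
  if (is.null(dim(q))) q <- matrix(q, ncol = 3)
  sqrt(rowSums((p - q)^2))
}

#' Distance from an interior point to an ellipsoid surface
#'
#' The nuclear boundary is modelled as an axis-aligned ellipsoid (the sphere
#' is the special case of equal semi-axes). For an interior point the
#' closest surface point is found from the unique largest root of the
#' Lagrange condition `sum(a_i^2 p_i^2 / (a_i^2 + t)^2) = 1`; probes outside
#' the boundary get distance 0 with a warning.
#'
#' @param p probe position (length 3), same frame as `center`
#' @param center ellipsoid centre (length 3)
#' @param semi_axes positive semi-axis lengths (length 3), micrometres
#' @param tol root-finding tolerance on the distance (default 1e-6 um)
#' @return distance to the surface in micrometres
#' @export
periphery_distance <- function(p, center, semi_axes, tol = 1e-6) {
  if (any(semi_axes <= 0)) stop("semi-axes must be positive")
  u <- as.numeric(p) - as.numeric(center)
  a2 <- semi_axes^2
  if (sum(u^2 / a2) > 1) {
    warning("probe lies outside the nuclear boundary; distance set to 0")
    return(0)
  }
  if (all(abs(u) < tol)) return(min(semi_axes))  # centre: nearest along shortest axis
  # perturb exact-zero components off the degenerate axis planes; the induced
  # distance error is far below tol
  eps <- 1e-9 * min(semi_axes)
  u[u == 0] <- eps
  f <- function(t) sum(a2 * u^2 / (a2 + t)^2) - 1
  # f is monotone decreasing on (-min(a2), Inf), diverges at the left end and
  # is <= 0 at t = 0 for interior points, so the root lies in (-min(a2), 0]
  lo <- -min(a2)
  delta <- 1e-9 * min(a2)
  lower <- lo + delta
  while (f(lower) < 0) {
    delta <- delta / 10
    lower <- lo + delta
  }
  root <- stats::uniroot(f, c(lower, 0), tol = 1e-12 * min(a2))$root
  q <- a2 * u / (a2 + root)
  sqrt(sum((u - q)^2))
}

#' Assemble FISH distance records from paired signals and nucleus geometry
#'
#' Computes, per allele, the probe-probe 3D distance and each probe's
#' distance to the nuclear periphery.
#'
#' @param pairs paired alleles from [pair_alleles()]
#' @param geometry data.frame with `nucleus_id`, ellipsoid centre `cx`, `cy`,
#'   `cz` and semi-axes `ax`, `ay`, `az` (micrometres)
#' @return data.frame: `nucleus_id`, `allele`, `condition` (if present),
#'   `probe_probe_um`, `periphery_red_um`, `periphery_green_um`
#' @export
fish_distance_records <- function(pairs, geometry) {
  geom <- geometry[match(pairs$nucleus_id, geometry$nucleus_id), , drop = FALSE]
  if (any(is.na(geom$ax))) stop("geometry missing for some nuclei")
  n <- nrow(pairs)
  red <- as.matrix(pairs[, c("red_x", "red_y", "red_z")])
  green <- as.matrix(pairs[, c("green_x", "green_y", "green_z")])
  out <- data.frame(
    nucleus_id = pairs$nucleus_id,
    allele = pairs$allele,
    probe_probe_um = probe_distance(red, green),
    periphery_red_um = vapply(seq_len(n), function(i) {
      periphery_distance(red[i, ], c(geom$cx[i], geom$cy[i], geom$cz[i]),
                         c(geom$ax[i], geom$ay[i], geom$az[i]))
    }, numeric(1)),
    periphery_green_um = vapply(seq_len(n), function(i) {
      periphery_distance(green[i, ], c(geom$cx[i], geom$cy[i], geom$cz[i]),
                         c(geom$ax[i], geom$ay[i], geom$az[i]))
    }, numeric(1))
  )
  if ("condition" %in% names(pairs)) out$condition <- pairs$condition
  out
}

#' Fraction of probes at the nuclear periphery
#'
#' A probe is peripheral when its distance to the boundary is at most
#' `cutoff` (boundary inclusive; default 2 um).
#'
#' @param periphery_um numeric distances to the periphery
#' @param cutoff micrometres (default 2.0)
#' @return fraction in `[0, 1]`
#' @export
peripheral_fraction <- function(periphery_um, cutoff = 2.0) {
  if (length(periphery_um) == 0) stop("no records")
  mean(periphery_um <= cutoff)
}

#' Compare FISH distances between two conditions
#'
#' Unpaired two-tailed Welch t-tests on the probe-probe distance and on the
#' probe-periphery distances (per channel); the sampling unit is the allele.
#'
#' @param records_a,records_b distance-record data.frames (see
#'   [fish_distance_records()]); pre-measured tables with the same columns
#'   are accepted directly
#' @return list of `welch_test` results: `probe_probe`, `periphery_red`,
#'   `periphery_green` (the latter two `NULL` when columns are absent)
#' @export
compare_conditions <- function(records_a, records_b) {
  res <- list(probe_probe = welch_test(records_a$probe_probe_um,
                                       records_b$probe_probe_um))
  for (ch in c("red", "green")) {
    col <- paste0("periphery_", ch, "_um")
    res[[paste0("periphery_", ch)]] <-
      if (col %in% names(records_a) && col %in% names(records_b)) {
        welch_test(records_a[[col]], records_b[[col]])
      } else NULL
  }
  res
}
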