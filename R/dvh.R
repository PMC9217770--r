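#' Organs at risk evaluated by the pipeline
#'
#' The six organ labels used throughout: contralateral breast, both lungs
#' (union), ipsilateral lung, contralateral lung, thyroid and esophagus,
#' in the fixed reporting order of the comparison table.
#'
#' @return Character vector of organ labels.
#' @export
oar_organs <- function() {
  c("breast_contralateral", "lungs_both", "lung_ipsilateral",
    "lung_contralateral", "thyroid", "esophagus")
}

#' Treatment group labels
#'
#' Partial breast irradiation at the 1.5 T MR-linac (`PBI_MRL`), partial
#' breast irradiation at the conventional linac (`PBI_CTL`) and whole breast
#' irradiation at the conventional linac (`WBI_CTL`).
#'
#' @return Character vector of the three group labels.
#' @export
treatment_groups <- function() c("PBI_MRL", "PBI_CTL", "WBI_CTL")

# prescription dose used by the synthetic cohort: 40.05 Gy in 15 fractions
PRESCRIPTION_GY <- 40.05
N_FRACTIONS <- 15L

# numerical-zero volume below which a bin does not count for max dose
VOLUME_FLOOR_CM3 <- 1e-9

#' Differential dose-volume histogram
#'
#' A differential DVH tabulates organ volume (cm^3) per dose bin. Bins are
#' half-open `[edge_i, edge_{i+1})` on an ascending grid of edges (Gy);
#' every integral over the DVH (mean dose, OED) uses the bin centers.
#'
#' @param organ Organ label.
#' @param bin_edges Ascending numeric vector of bin edges in Gy, length B+1,
#'   first edge >= 0.
#' @param bin_volumes Non-negative volumes in cm^3, length B.
#' @return An object of class `c("dvh_differential", "dvh")` with fields
#'   `organ`, `bin_edges`, `bin_volumes`, `total_volume`.
#' @examples
#' d <- dvh_differential("thyroid", c(0, 1, 2), c(60, 40))
#' mean_dose(d)
#' @export
dvh_differential <- function(organ, bin_edges, bin_volumes) {
  x <- structure(
    list(organ = as.character(organ),
         bin_edges = as.numeric(bin_edges),
         bin_volumes = as.numeric(bin_volumes),
         total_volume = sum(as.numeric(bin_volumes))),
    class = c("dvh_differential", "dvh"))
  validate_dvh(x)
  x
}

#' Cumulative dose-volume histogram
#'
#' A cumulative DVH tabulates the volume receiving at least each dose level:
#' `volume_at_or_above[i]` is the organ volume (cm^3) receiving a dose of
#' `dose_points[i]` or more. The curve is monotone non-increasing and starts
#' at the total organ volume at dose 0.
#'
#' @param organ Organ label.
#' @param dose_points Ascending dose grid in Gy, starting at 0.
#' @param volume_at_or_above Monotone non-increasing volumes in cm^3.
#' @return An object of class `c("dvh_cumulative", "dvh")`.
#' @export
dvh_cumulative <- function(organ, dose_points, volume_at_or_above) {
  x <- structure(
    list(organ = as.character(organ),
         dose_points = as.numeric(dose_points),
         volume_at_or_above = as.numeric(volume_at_or_above),
         total_volume = as.numeric(volume_at_or_above)[1L]),
    class = c("dvh_cumulative", "dvh"))
  validate_dvh(x)
  x
}

#' Validate a DVH object
#'
#' Checks the class invariants: ascending grids, non-negative volumes,
#' volume bookkeeping within 1e-6 relative, monotone cumulative curves.
#' Called by every constructor and transform; exported so that externally
#' assembled objects can be checked too.
#'
#' @param x A `dvh_differential` or `dvh_cumulative`.
#' @return `x`, invisibly, or an error.
#' @export
validate_dvh <- function(x) {
  if (inherits(x, "dvh_differential")) {
    e <- x$bin_edges; v <- x$bin_volumes
    if (length(e) != length(v) + 1L)
      stop("bin_edges must have length(bin_volumes) + 1", call. = FALSE)
    if (anyNA(e) || anyNA(v)) stop("DVH contains NA values", call. = FALSE)
    if (e[1L] < 0) stop("bin_edges[1] must be >= 0", call. = FALSE)
    if (any(diff(e) <= 0))
      stop("bin_edges must be strictly increasing", call. = FALSE)
    if (any(v < 0)) stop("bin_volumes must be non-negative", call. = FALSE)
    if (x$total_volume > 0 &&
        abs(sum(v) - x$total_volume) / x$total_volume > 1e-6)
      stop("sum(bin_volumes) does not match total_volume", call. = FALSE)
  } else if (inherits(x, "dvh_cumulative")) {
    d <- x$dose_points; v <- x$volume_at_or_above
    if (length(d) != length(v))
      stop("dose_points and volume_at_or_above lengths differ", call. = FALSE)
    if (anyNA(d) || anyNA(v)) stop("DVH contains NA values", call. = FALSE)
    if (d[1L] != 0)
      stop("cumulative DVH must start at dose 0", call. = FALSE)
    if (any(diff(d) <= 0))
      stop("dose_points must be strictly increasing", call. = FALSE)
    if (any(v < 0)) stop("volumes must be non-negative", call. = FALSE)
    if (any(diff(v) > 1e-9 * max(v[1L], 1)))
      stop("volume_at_or_above must be monotone non-increasing", call. = FALSE)
  } else {
    stop("not a dvh object", call. = FALSE)
  }
  invisible(x)
}

#' @export
print.dvh <- function(x, ...) {
  if (inherits(x, "dvh_differential")) {
    cat(sprintf("Differential DVH: %s\n", x$organ))
    cat(sprintf("  %d bins over [%.3g, %.3g] Gy, total volume %.4g cm^3\n",
                length(x$bin_volumes), x$bin_edges[1L],
                x$bin_edges[length(x$bin_edges)], x$total_volume))
    cat(sprintf("  mean dose %.4g Gy, max dose %.4g Gy\n",
                mean_dose(x), max_dose(x)))
  } else {
    cat(sprintf("Cumulative DVH: %s\n", x$organ))
    cat(sprintf("  %d dose points up to %.3g Gy, total volume %.4g cm^3\n",
                length(x$dose_points), max(x$dose_points), x$total_volume))
  }
  invisible(x)
}

#' Bin centers of a differential DVH
#' @param d A `dvh_differential`.
#' @return Numeric vector of bin-center doses in Gy.
#' @export
bin_centers <- function(d) {
  stopifnot(inherits(d, "dvh_differential"))
  e <- d$bin_edges
  (e[-length(e)] + e[-1L]) / 2
}

#' Convert a cumulative DVH to differential form
#'
#' Successive differences of the cumulative curve: the volume in bin
#' `[dose_points[i], dose_points[i+1])` is
#' `volume_at_or_above[i] - volume_at_or_above[i+1]`. Any volume still at or
#' above the last dose point is appended as a final bin of the same width as
#' the preceding one (zero for a curve that closes at 0).
#'
#' @param c A `dvh_cumulative`.
#' @return A `dvh_differential` with the total volume preserved exactly.
#' @export
cumulative_to_differential <- function(c) {
  stopifnot(inherits(c, "dvh_cumulative"))
  validate_dvh(c)
  d <- c$dose_points; v <- c$volume_at_or_above
  vols <- -diff(v)
  edges <- d
  tail_vol <- v[length(v)]
  if (tail_vol > 0) {
    w <- if (length(d) > 1L) d[length(d)] - d[length(d) - 1L] else 1
    edges <- c(edges, d[length(d)] + w)
    vols <- c(vols, tail_vol)
  }
  dvh_differential(c$organ, edges, vols)
}

#' Convert a differential DVH to cumulative form
#'
#' Reverse cumulative sum over the bins: the volume at or above each bin's
#' lower edge. The curve starts at the total volume and closes at 0 at the
#' upper edge of the last bin.
#'
#' @param d A `dvh_differential`.
#' @return A `dvh_cumulative` on the grid of bin edges.
#' @export
differential_to_cumulative <- function(d) {
  stopifnot(inherits(d, "dvh_differential"))
  validate_dvh(d)
  v <- rev(cumsum(rev(d$bin_volumes)))
  doses <- d$bin_edges
  vols <- c(v, 0)
  if (doses[1L] > 0) {  # curve always starts at dose 0 with the full volume
    doses <- c(0, doses)
    vols <- c(vols[1L], vols)
  }
  dvh_cumulative(d$organ, doses, vols)
}

#' Rebin a differential DVH onto a uniform grid
#'
#' Volume in each old bin is assumed uniformly distributed over the bin and
#' split among the overlapping new bins in proportion to overlap length, so
#' total volume is conserved exactly and the mean dose moves by at most half
#' of the coarser bin width.
#'
#' @param d A `dvh_differential`.
#' @param new_width New bin width in Gy (> 0). The new grid starts at
#'   `floor(min_edge / new_width) * new_width` and covers the old support.
#' @return A `dvh_differential` on the new grid.
#' @export
rebin_dvh <- function(d, new_width) {
  stopifnot(inherits(d, "dvh_differential"))
  validate_dvh(d)
  if (!is.numeric(new_width) || length(new_width) != 1L || new_width <= 0)
    stop("new_width must be a positive number", call. = FALSE)
  lo <- floor(d$bin_edges[1L] / new_width) * new_width
  hi <- d$bin_edges[length(d$bin_edges)]
  n_new <- ceiling((hi - lo) / new_width - 1e-12)
  n_new <- max(n_new, 1L)
  new_edges <- lo + new_width * (0:n_new)
  new_vols <- numeric(n_new)
  old_lo <- d$bin_edges[-length(d$bin_edges)]
  old_hi <- d$bin_edges[-1L]
  for (i in seq_along(d$bin_volumes)) {
    if (d$bin_volumes[i] == 0) next
    j <- seq.int(max(1L, floor((old_lo[i] - lo) / new_width) + 1L),
                 min(n_new, ceiling((old_hi[i] - lo) / new_width + 1e-12)))
    ov <- pmin(old_hi[i], new_edges[j + 1L]) - pmax(old_lo[i], new_edges[j])
    ov[ov < 0] <- 0
    w <- ov / (old_hi[i] - old_lo[i])
    # push any clipping residue into the last overlapped bin so volume is exact
    w[length(w)] <- w[length(w)] + (1 - sum(w))
    new_vols[j] <- new_vols[j] + d$bin_volumes[i] * w
  }
  dvh_differential(d$organ, new_edges, new_vols)
}

#' Volume-weighted mean dose
#'
#' `sum(v_i * D_i) / V_T` with `D_i` the bin centers. For a cumulative DVH
#' the curve is converted to differential form first, so both representations
#' agree exactly.
#'
#' @param d A DVH object.
#' @return Mean dose in Gy.
#' @export
mean_dose <- function(d) UseMethod("mean_dose")

#' @export
mean_dose.dvh_differential <- function(d) {
  validate_dvh(d)
  if (d$total_volume <= 0) stop("zero total volume", call. = FALSE)
  sum(d$bin_volumes * bin_centers(d)) / d$total_volume
}

#' @export
mean_dose.dvh_cumulative <- function(d) {
  mean_dose(cumulative_to_differential(d))
}

#' Maximum dose
#'
#' Upper edge of the highest dose bin holding more than a numerical-zero
#' volume (1e-9 cm^3); planning systems report Dmax without a volume
#' criterion, so the floor only guards against floating-point dust.
#'
#' @param d A DVH object.
#' @return Maximum dose in Gy.
#' @export
max_dose <- function(d) UseMethod("max_dose")

#' @export
max_dose.dvh_differential <- function(d) {
  validate_dvh(d)
  occ <- which(d$bin_volumes > VOLUME_FLOOR_CM3)
  if (length(occ) == 0L) stop("all bin volumes are zero", call. = FALSE)
  d$bin_edges[max(occ) + 1L]
}

#' @export
max_dose.dvh_cumulative <- function(d) {
  max_dose(cumulative_to_differential(d))
}

#' Combine two differential DVHs into the DVH of the union structure
#'
#' Bin volumes are added on a common grid (the union of both edge grids,
#' assuming each input is on a subset of a shared uniform grid this is exact).
#' Used to form the both-lungs DVH from the two single-lung DVHs.
#'
#' @param a,b `dvh_differential` objects.
#' @param organ Organ label for the combined structure.
#' @return A `dvh_differential` with `total_volume` equal to the sum.
#' @export
combine_dvh <- function(a, b, organ = a$organ) {
  stopifnot(inherits(a, "dvh_differential"), inherits(b, "dvh_differential"))
  edges <- sort(unique(c(a$bin_edges, b$bin_edges)))
  vols <- numeric(length(edges) - 1L)
  spread <- function(d) {
    lo <- d$bin_edges[-length(d$bin_edges)]
    hi <- d$bin_edges[-1L]
    for (i in seq_along(d$bin_volumes)) {
      if (d$bin_volumes[i] == 0) next
      j <- which(edges >= lo[i] - 1e-12 & edges < hi[i] - 1e-12)
      frac <- (pmin(edges[j + 1L], hi[i]) - edges[j]) -
        (pmax(edges[j], lo[i]) - edges[j])
      frac <- frac / (hi[i] - lo[i])
      vols[j] <<- vols[j] + d$bin_volumes[i] * frac
    }
  }
  spread(a); spread(b)
  dvh_differential(organ, edges, vols)
}
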