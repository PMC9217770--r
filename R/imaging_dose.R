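#' Cone-beam CT imaging protocol
#'
#' Describes the organ-level mean-dose increment contributed by image
#' guidance: the total increment (Gy) each organ accrues over a reference
#' number of CBCT acquisitions. Per-scan dose is obtained by linear division
#' of the reference total; the spatial dose pattern of the scan is not
#' modelled — the increment is applied as a uniform organ-dose shift, which
#' reproduces the organ mean dose exactly.
#'
#' @param name Protocol label.
#' @param reference_cbct_count Number of CBCTs over which
#'   `organ_increment_total` was accumulated (>= 1).
#' @param organ_increment_total Named numeric vector, organ label -> total
#'   mean-dose increment in Gy at the reference count (>= 0).
#' @return An object of class `imaging_protocol`.
#' @export
imaging_protocol <- function(name, reference_cbct_count, organ_increment_total) {
  if (!is.numeric(reference_cbct_count) || reference_cbct_count < 1)
    stop("reference_cbct_count must be >= 1", call. = FALSE)
  if (is.null(names(organ_increment_total)) || any(organ_increment_total < 0))
    stop("organ_increment_total must be a named vector of non-negative Gy",
         call. = FALSE)
  structure(list(name = name,
                 reference_cbct_count = as.integer(reference_cbct_count),
                 organ_increment_total = organ_increment_total),
            class = "imaging_protocol")
}

#' @export
print.imaging_protocol <- function(x, ...) {
  cat(sprintf("Imaging protocol '%s' (reference: %d CBCTs)\n",
              x$name, x$reference_cbct_count))
  for (o in names(x$organ_increment_total))
    cat(sprintf("  %-22s %.3g Gy\n", o, x$organ_increment_total[[o]]))
  invisible(x)
}

#' Shipped CBCT imaging protocols
#'
#' Two protocols with Monte-Carlo-derived organ mean-dose increments:
#' \itemize{
#'   \item `PBI_CTL`: daily CBCT over 15 fractions (reference 15 scans) —
#'     contralateral breast 0.55, both lungs 0.52, ipsilateral lung 0.66,
#'     contralateral lung 0.36, thyroid 0.51, esophagus 0.45 Gy;
#'   \item `WBI`: 6 scans total — 0.22, 0.23, 0.26, 0.15, 0.15, 0.20 Gy
#'     respectively.
#' }
#' The two tables are kept independent (per-scan doses differ because the
#' imaged anatomy and fields differ between PBI and WBI patients).
#'
#' @return Named list of [imaging_protocol()] objects.
#' @export
imaging_protocols <- function() {
  list(
    PBI_CTL = imaging_protocol("PBI_CTL", 15L, c(
      breast_contralateral = 0.55, lungs_both = 0.52,
      lung_ipsilateral = 0.66, lung_contralateral = 0.36,
      thyroid = 0.51, esophagus = 0.45)),
    WBI = imaging_protocol("WBI", 6L, c(
      breast_contralateral = 0.22, lungs_both = 0.23,
      lung_ipsilateral = 0.26, lung_contralateral = 0.15,
      thyroid = 0.15, esophagus = 0.20)))
}

#' Organ mean-dose increment for a number of CBCTs
#'
#' Linear in the scan count:
#' `total_increment x n_cbct / reference_cbct_count`.
#'
#' @param protocol An [imaging_protocol()].
#' @param organ Organ label present in the protocol.
#' @param n_cbct Number of CBCT scans (>= 0).
#' @return Increment in Gy.
#' @export
organ_increment <- function(protocol, organ, n_cbct) {
  stopifnot(inherits(protocol, "imaging_protocol"))
  if (n_cbct < 0) stop("n_cbct must be >= 0", call. = FALSE)
  if (!organ %in% names(protocol$organ_increment_total))
    stop(sprintf("protocol '%s' has no increment for organ '%s'",
                 protocol$name, organ), call. = FALSE)
  protocol$organ_increment_total[[organ]] * n_cbct /
    protocol$reference_cbct_count
}

#' Shift a DVH by a uniform dose
#'
#' Adds `delta` Gy to every bin's dose coordinates, leaving the volumes
#' untouched: the mean and maximum dose each increase by exactly `delta`.
#' This is the organ-level approximation used to add image-guidance dose.
#'
#' @param d A `dvh_differential`.
#' @param delta Uniform dose shift in Gy (>= 0).
#' @return The shifted `dvh_differential`.
#' @export
apply_uniform_dose <- function(d, delta) {
  stopifnot(inherits(d, "dvh_differential"))
  if (!is.numeric(delta) || length(delta) != 1L || delta < 0)
    stop("delta must be a non-negative number", call. = FALSE)
  if (delta == 0) return(d)
  dvh_differential(d$organ, d$bin_edges + delta, d$bin_volumes)
}

#' Add CBCT imaging dose to a patient record
#'
#' Shifts every organ DVH of the record by its protocol increment at
#' `n_cbct` scans. Returns a new record (the input is unchanged); the group
#' label gains a `_CBCT` suffix so the dosed cohort can act as a
#' pseudo-group in comparisons.
#'
#' @param p A [patient_record()].
#' @param protocol An [imaging_protocol()] covering all organs of `p`.
#' @param n_cbct Number of CBCT scans.
#' @param relabel Append `_CBCT` to the group label (default `TRUE` when
#'   `n_cbct > 0`).
#' @return A new [patient_record()].
#' @export
with_imaging_dose <- function(p, protocol, n_cbct,
                              relabel = n_cbct > 0) {
  stopifnot(inherits(p, "patient_record"))
  if (n_cbct == 0 && !relabel) return(p)
  dvhs <- p$dvhs
  for (o in names(dvhs))
    dvhs[[o]] <- apply_uniform_dose(dvhs[[o]],
                                    organ_increment(protocol, o, n_cbct))
  grp <- if (relabel) paste0(sub("_CBCT$", "", p$group), "_CBCT") else p$group
  rec <- p
  rec$dvhs <- dvhs
  rec$group <- grp
  rec
}
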