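#' Per-patient treatment record
#'
#' Bundles a patient id, a treatment group and the per-organ differential
#' DVHs. When all three lung structures are present, the both-lungs volume
#' must equal the sum of the single-lung volumes within 1%.
#'
#' @param patient_id Character id.
#' @param group One of [treatment_groups()] (a pseudo-group suffix such as
#'   `PBI_CTL_CBCT` is also accepted downstream of imaging-dose addition).
#' @param dvhs Named list of `dvh_differential` objects, names are organ
#'   labels from [oar_organs()].
#' @return An object of class `patient_record`.
#' @export
patient_record <- function(patient_id, group, dvhs) {
  known <- c(treatment_groups(), paste0(treatment_groups(), "_CBCT"))
  if (!is.character(group) || length(group) != 1L || !(group %in% known))
    stop(sprintf("unknown group label '%s' (expected one of %s)",
                 group, paste(treatment_groups(), collapse = ", ")),
         call. = FALSE)
  if (is.null(names(dvhs)) || any(names(dvhs) == ""))
    stop("dvhs must be a named list of organ DVHs", call. = FALSE)
  bad <- setdiff(names(dvhs), oar_organs())
  if (length(bad))
    stop(sprintf("unknown organ label(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  for (d in dvhs) validate_dvh(d)
  lungs <- c("lungs_both", "lung_ipsilateral", "lung_contralateral")
  if (all(lungs %in% names(dvhs))) {
    vb <- dvhs$lungs_both$total_volume
    vs <- dvhs$lung_ipsilateral$total_volume +
      dvhs$lung_contralateral$total_volume
    if (abs(vb - vs) / vs > 0.01)
      stop(sprintf(
        "patient %s: both-lungs volume (%.4g) differs from ipsi+contra (%.4g) by more than 1%%",
        patient_id, vb, vs), call. = FALSE)
  }
  structure(list(patient_id = as.character(patient_id),
                 group = group, dvhs = dvhs),
            class = "patient_record")
}

#' @export
print.patient_record <- function(x, ...) {
  cat(sprintf("Patient %s (%s): %d organ DVH(s)\n",
              x$patient_id, x$group, length(x$dvhs)))
  for (o in names(x$dvhs))
    cat(sprintf("  %-22s V = %8.4g cm^3, Dmean = %7.4g Gy\n",
                o, x$dvhs[[o]]$total_volume, mean_dose(x$dvhs[[o]])))
  invisible(x)
}

#' Read a DVH file
#'
#' Parses the plain-text DVH dialect: blocks separated by blank lines, each
#' block headed by `# patient <id>`, `# group <label>`, `# organ <name>`,
#' `# type <cumulative|differential>`, `# volume_cm3 <number>` and optional
#' `# units percent`, followed by two tab-separated columns
#' `dose_gy<TAB>volume`. Differential rows give the volume of the bin whose
#' lower edge is `dose_gy` (edges taken from successive rows, the last bin
#' closed with the same width as its predecessor). Cumulative blocks are
#' converted to differential form on load. Relative (% of total) volumes are
#' rescaled with the mandatory `volume_cm3` header.
#'
#' @param path File path.
#' @return List of [patient_record()] objects, one per patient.
#' @export
read_dvh <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  blocks <- list(); cur <- integer(0)
  for (i in seq_along(lines)) {
    if (grepl("^\\s*$", lines[i])) {
      if (length(cur)) blocks[[length(blocks) + 1L]] <- cur
      cur <- integer(0)
    } else cur <- c(cur, i)
  }
  if (length(cur)) blocks[[length(blocks) + 1L]] <- cur

  patients <- list()   # id -> list(group=, dvhs=list())
  for (blk in blocks) {
    hdr <- list(); data_lines <- integer(0)
    for (i in blk) {
      ln <- lines[i]
      if (startsWith(ln, "#")) {
        m <- regmatches(ln, regexec("^#\\s*(\\S+)\\s*(.*)$", ln))[[1]]
        if (length(m) < 2L)
          stop(sprintf("line %d: malformed header '%s'", i, ln), call. = FALSE)
        hdr[[m[2]]] <- trimws(m[3])
      } else data_lines <- c(data_lines, i)
    }
    need <- c("patient", "group", "organ", "type")
    miss <- setdiff(need, names(hdr))
    if (length(miss))
      stop(sprintf("line %d: block missing header field(s): %s",
                   blk[1], paste(miss, collapse = ", ")), call. = FALSE)
    if (!hdr$type %in% c("cumulative", "differential"))
      stop(sprintf("line %d: unknown type '%s'", blk[1], hdr$type),
           call. = FALSE)
    if (!hdr$group %in% treatment_groups())
      stop(sprintf("line %d: unknown group label '%s'", blk[1], hdr$group),
           call. = FALSE)
    percent <- identical(hdr$units, "percent")
    total <- if (!is.null(hdr$volume_cm3)) as.numeric(hdr$volume_cm3) else NA_real_
    if (percent && (is.na(total) || total <= 0))
      stop(sprintf(
        "line %d: percent units require a positive '# volume_cm3' header",
        blk[1]), call. = FALSE)

    dose <- numeric(length(data_lines)); vol <- numeric(length(data_lines))
    for (k in seq_along(data_lines)) {
      i <- data_lines[k]
      parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(parts) != 2L)
        stop(sprintf("line %d: expected 2 tab-separated columns", i),
             call. = FALSE)
      dose[k] <- suppressWarnings(as.numeric(parts[1]))
      vol[k] <- suppressWarnings(as.numeric(parts[2]))
      if (is.na(dose[k]) || is.na(vol[k]))
        stop(sprintf("line %d: non-numeric value", i), call. = FALSE)
      if (vol[k] < 0)
        stop(sprintf("line %d: negative volume", i), call. = FALSE)
    }
    if (length(dose) < 2L)
      stop(sprintf("line %d: block needs at least 2 data rows", blk[1]),
           call. = FALSE)
    if (any(diff(dose) <= 0))
      stop(sprintf("line %d: dose column must be strictly increasing",
                   data_lines[which(diff(dose) <= 0)[1] + 1L]), call. = FALSE)
    if (percent) vol <- vol * total / 100

    d <- if (hdr$type == "cumulative") {
      if (any(diff(vol) > 1e-9 * max(vol[1], 1)))
        stop(sprintf("line %d: cumulative volumes must be non-increasing",
                     data_lines[which(diff(vol) > 0)[1] + 1L]), call. = FALSE)
      cumulative_to_differential(dvh_cumulative(hdr$organ, dose, vol))
    } else {
      w <- if (length(dose) > 1L) dose[length(dose)] - dose[length(dose) - 1L] else 1
      dvh_differential(hdr$organ, c(dose, dose[length(dose)] + w), vol)
    }
    id <- hdr$patient
    if (is.null(patients[[id]]))
      patients[[id]] <- list(group = hdr$group, dvhs = list())
    patients[[id]]$dvhs[[hdr$organ]] <- d
  }
  lapply(names(patients), function(id)
    patient_record(id, patients[[id]]$group, patients[[id]]$dvhs))
}

#' Write patient records to a DVH file
#'
#' Inverse of [read_dvh()]: one differential block per patient x organ,
#' numbers formatted at 6 significant digits so a read/write roundtrip is
#' lossless at that precision.
#'
#' @param records List of [patient_record()] objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dvh <- function(records, path) {
  if (inherits(records, "patient_record")) records <- list(records)
  con <- file(path, "w"); on.exit(close(con))
  fmt <- function(x) sprintf("%.6g", x)
  for (p in records) {
    for (o in names(p$dvhs)) {
      d <- p$dvhs[[o]]
      writeLines(c(sprintf("# patient %s", p$patient_id),
                   sprintf("# group %s", sub("_CBCT$", "", p$group)),
                   sprintf("# organ %s", o),
                   "# type differential",
                   sprintf("# volume_cm3 %s", fmt(d$total_volume))), con)
      lo <- d$bin_edges[-length(d$bin_edges)]
      writeLines(paste(fmt(lo), fmt(d$bin_volumes), sep = "\t"), con)
      writeLines("", con)
    }
  }
  invisible(path)
}
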