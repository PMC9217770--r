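#' Shapiro-Wilk normality screen
#'
#' Wrapper around [stats::shapiro.test()] used as an advisory screen before
#' the group comparisons; its outcome never gates the t-test (no
#' non-parametric fallback is applied downstream).
#'
#' @param values Numeric sample, 3 <= n <= 5000.
#' @return List with `statistic` (W) and `p`.
#' @export
normality_check <- function(values) {
  n <- length(values)
  if (n < 3L) stop("normality check needs at least 3 values", call. = FALSE)
  if (n > 5000L) stop("normality check supports at most 5000 values", call. = FALSE)
  if (stats::sd(values) == 0)
    stop("sample has zero variance; normality test is degenerate", call. = FALSE)
  s <- stats::shapiro.test(values)
  list(statistic = unname(s$statistic), p = unname(s$p.value))
}

#' Welch two-sample t-test from summary statistics
#'
#' Unequal-variance t-test computed directly from group means, sample
#' standard deviations (n-1 denominator) and sizes:
#' `t = (mean_a - mean_b) / sqrt(sd_a^2/n_a + sd_b^2/n_b)`, degrees of
#' freedom by Welch-Satterthwaite, p two-sided.
#'
#' @param mean_a,sd_a,n_a Summary of group a.
#' @param mean_b,sd_b,n_b Summary of group b.
#' @return List with `t`, `df`, `p_raw`.
#' @examples
#' welch_from_summary(12.441, 2.276, 11, 12.423, 3.987, 11)
#' @export
welch_from_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b) {
  if (n_a < 2L || n_b < 2L) stop("each group needs n >= 2", call. = FALSE)
  if (sd_a < 0 || sd_b < 0) stop("standard deviations must be >= 0", call. = FALSE)
  if (sd_a == 0 && sd_b == 0)
    stop("both group variances are zero; t-test undefined", call. = FALSE)
  va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
  se2 <- va + vb
  t <- (mean_a - mean_b) / sqrt(se2)
  df <- se2^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p_raw = p)
}

#' Welch two-sample t-test from raw samples
#'
#' Definitionally identical to [welch_from_summary()] applied to the
#' samples' means and n-1 standard deviations.
#'
#' @param a,b Numeric samples, each n >= 2.
#' @return List with `t`, `df`, `p_raw`.
#' @export
welch_from_samples <- function(a, b) {
  welch_from_summary(mean(a), stats::sd(a), length(a),
                     mean(b), stats::sd(b), length(b))
}

#' Uncapped Bonferroni adjustment
#'
#' Multiplies a raw p-value by the family size `m` WITHOUT truncating at 1,
#' so non-significant adjusted values above 1 remain informative about the
#' raw p (e.g. an adjusted value of 3.96 reports a raw p of 0.99 under
#' m = 4). [stats::p.adjust()] caps at 1 and is deliberately not used.
#'
#' @param p_raw Raw p-value(s) in (0, 1].
#' @param m Family size (>= 1).
#' @return `m * p_raw`, possibly > 1.
#' @export
bonferroni_uncapped <- function(p_raw, m) {
  if (any(p_raw <= 0 | p_raw > 1)) stop("p_raw must be in (0, 1]", call. = FALSE)
  if (any(m < 1)) stop("m must be >= 1", call. = FALSE)
  m * p_raw
}

#' Default comparison plan
#'
#' The four group pairs compared per organ, in reporting order: PBI at the
#' conventional linac vs at the MR-linac; PBI vs WBI at the conventional
#' linac; WBI at the conventional linac vs PBI at the MR-linac; and PBI at
#' the conventional linac including CBCT dose vs PBI at the MR-linac.
#'
#' @return List of length-2 character vectors `(group_a, group_b)`.
#' @export
default_pairs <- function() {
  list(c("PBI_CTL", "PBI_MRL"),
       c("PBI_CTL", "WBI_CTL"),
       c("WBI_CTL", "PBI_MRL"),
       c("PBI_CTL_CBCT", "PBI_MRL"))
}

#' Per-organ cohort comparison table
#'
#' For each organ: one summary (n, mean, sample SD) per group and one Welch
#' comparison per requested group pair, Bonferroni-adjusted (uncapped) with
#' multiplier `m` = number of pairs. A Shapiro-Wilk screen per organ x group
#' is attached as advisory information. Ordering is deterministic: organs in
#' [oar_organs()] order, pairs as listed.
#'
#' @param ear_table data.frame with columns `patient_id`, `group`, `organ`,
#'   `ear` (as produced by [cohort_ear_table()], possibly row-bound with a
#'   `_CBCT` pseudo-group).
#' @param pairs List of group pairs, default [default_pairs()] restricted to
#'   groups present.
#' @param m Bonferroni multiplier, default `length(pairs)`.
#' @param alpha_sig Significance threshold on adjusted values (default 0.05).
#' @return An object of class `ear_comparison`: list with data.frames
#'   `summaries` (`organ`, `group`, `n`, `mean`, `sd`, `shapiro_p`) and
#'   `comparisons` (`organ`, `group_a`, `group_b`, `t`, `df`, `p_raw`,
#'   `p_adjusted`, `m`, `significant`).
#' @export
build_comparison_table <- function(ear_table, pairs = NULL, m = NULL,
                                   alpha_sig = 0.05) {
  need <- c("patient_id", "group", "organ", "ear")
  if (!all(need %in% names(ear_table)))
    stop("ear_table must have columns patient_id, group, organ, ear",
         call. = FALSE)
  if (is.null(pairs)) {
    pairs <- Filter(function(p) all(p %in% ear_table$group), default_pairs())
    if (!length(pairs)) stop("no default pair has both groups present", call. = FALSE)
  }
  groups <- unique(unlist(pairs))
  miss <- setdiff(groups, ear_table$group)
  if (length(miss))
    stop(sprintf("group(s) absent from ear_table: %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  if (is.null(m)) m <- length(pairs)
  organs <- intersect(oar_organs(), unique(ear_table$organ))

  pull <- function(o, g) ear_table$ear[ear_table$organ == o & ear_table$group == g]
  summaries <- do.call(rbind, lapply(organs, function(o) {
    do.call(rbind, lapply(groups, function(g) {
      v <- pull(o, g)
      if (length(v) < 2L)
        stop(sprintf("group %s has fewer than 2 patients for organ %s", g, o),
             call. = FALSE)
      sp <- if (length(v) >= 3L && stats::sd(v) > 0)
        normality_check(v)$p else NA_real_
      data.frame(organ = o, group = g, n = length(v), mean = mean(v),
                 sd = stats::sd(v), shapiro_p = sp, stringsAsFactors = FALSE)
    }))
  }))
  comparisons <- do.call(rbind, lapply(organs, function(o) {
    do.call(rbind, lapply(pairs, function(pr) {
      w <- welch_from_samples(pull(o, pr[1]), pull(o, pr[2]))
      padj <- bonferroni_uncapped(w$p_raw, m)
      data.frame(organ = o, group_a = pr[1], group_b = pr[2],
                 t = w$t, df = w$df, p_raw = w$p_raw, p_adjusted = padj,
                 m = m, significant = padj < alpha_sig,
                 stringsAsFactors = FALSE)
    }))
  }))
  structure(list(summaries = summaries, comparisons = comparisons,
                 pairs = pairs, m = m, alpha_sig = alpha_sig),
            class = "ear_comparison")
}

#' Comparison table from published summary statistics
#'
#' Runs the same Welch + uncapped-Bonferroni machinery directly on group
#' means/SDs/sizes (no patient-level data), e.g. to recompute a published
#' comparison table from its printed M +/- SD columns.
#'
#' @param summaries data.frame with columns `organ`, `group`, `n`, `mean`,
#'   `sd`.
#' @inheritParams build_comparison_table
#' @return An `ear_comparison` object (without Shapiro screens).
#' @export
compare_from_summaries <- function(summaries, pairs = default_pairs(),
                                   m = length(pairs), alpha_sig = 0.05) {
  organs <- intersect(oar_organs(), unique(summaries$organ))
  comparisons <- do.call(rbind, lapply(organs, function(o) {
    do.call(rbind, lapply(pairs, function(pr) {
      sa <- summaries[summaries$organ == o & summaries$group == pr[1], ]
      sb <- summaries[summaries$organ == o & summaries$group == pr[2], ]
      if (nrow(sa) != 1L || nrow(sb) != 1L)
        stop(sprintf("missing summary for organ %s, pair %s vs %s",
                     o, pr[1], pr[2]), call. = FALSE)
      w <- welch_from_summary(sa$mean, sa$sd, sa$n, sb$mean, sb$sd, sb$n)
      padj <- bonferroni_uncapped(w$p_raw, m)
      data.frame(organ = o, group_a = pr[1], group_b = pr[2],
                 t = w$t, df = w$df, p_raw = w$p_raw, p_adjusted = padj,
                 m = m, significant = padj < alpha_sig,
                 stringsAsFactors = FALSE)
    }))
  }))
  s <- summaries[order(match(summaries$organ, oar_organs())), ]
  s$shapiro_p <- NA_real_
  structure(list(summaries = s, comparisons = comparisons,
                 pairs = pairs, m = m, alpha_sig = alpha_sig),
            class = "ear_comparison")
}

#' Auxiliary two-group comparison
#'
#' Welch t-test between two raw samples with a configurable Bonferroni
#' multiplier, for side comparisons outside the per-organ EAR family (e.g.
#' target-volume sizes with m = 1, or maximum contralateral-breast dose
#' across three group pairs with m = 3).
#'
#' @param values_a,values_b Numeric samples.
#' @param m Correction multiplier (default 1 = no correction).
#' @param alpha_sig Significance threshold on the adjusted value.
#' @return List with `t`, `df`, `p_raw`, `p_adjusted`, `m`, `significant`.
#' @export
auxiliary_compare <- function(values_a, values_b, m = 1, alpha_sig = 0.05) {
  w <- welch_from_samples(values_a, values_b)
  padj <- bonferroni_uncapped(w$p_raw, m)
  c(w, list(p_adjusted = padj, m = m, significant = padj < alpha_sig))
}

#' @export
print.ear_comparison <- function(x, ...) {
  cat(format_comparison(x), sep = "\n")
  invisible(x)
}

#' @export
summary.ear_comparison <- function(object, ...) {
  nsig <- sum(object$comparisons$significant)
  cat(sprintf(
    "EAR comparison: %d organs, %d pairs (Bonferroni x%d, uncapped), %d significant at %.2g\n",
    length(unique(object$comparisons$organ)), length(object$pairs),
    object$m, nsig, object$alpha_sig))
  invisible(object)
}

# fixed-width text rendering shared by print and the report writer
format_comparison <- function(x) {
  organs <- unique(x$comparisons$organ)
  groups <- unique(x$summaries$group)
  hdr <- c(sprintf("%-22s", "organ"),
           sprintf("%-17s", paste0(groups, " M+/-SD")),
           sprintf("%-12s", vapply(x$pairs, paste, "", collapse = " vs ")))
  out <- paste(hdr, collapse = " ")
  for (o in organs) {
    cells <- vapply(groups, function(g) {
      s <- x$summaries[x$summaries$organ == o & x$summaries$group == g, ]
      if (nrow(s)) sprintf("%-17s", sprintf("%.3f +/- %.3f", s$mean, s$sd))
      else sprintf("%-17s", "-")
    }, "")
    ps <- vapply(seq_along(x$pairs), function(k) {
      cm <- x$comparisons[x$comparisons$organ == o &
                            x$comparisons$group_a == x$pairs[[k]][1] &
                            x$comparisons$group_b == x$pairs[[k]][2], ]
      sprintf("%-12s", paste0(format_pval(cm$p_adjusted),
                              if (cm$significant) " *" else ""))
    }, "")
    out <- c(out, paste(c(sprintf("%-22s", o), cells, ps), collapse = " "))
  }
  out
}

# p-value formatting matching the reporting convention: 2-4 significant
# digits, "<0.0001" below that resolution
format_pval <- function(p) {
  if (p < 1e-4) "<0.0001" else formatC(signif(p, 3), format = "fg", digits = 3)
}
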