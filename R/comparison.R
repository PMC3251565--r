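#' Percent by which a exceeds b
#'
#' 100 * (a - b) / b, the convention used when quoting "a was X% higher
#' than b". Rendered reports round to integer percent.
#'
#' @param a,b positive values in the same units.
#' @return percentage (full precision).
#' @examples
#' percentHigher(8.32, 5.98)  # ~39
#' @export
percentHigher <- function(a, b) {
  if (any(b <= 0)) stop("reference value b must be positive")
  100 * (a - b) / b
}

#' Percent by which b falls below a
#'
#' 100 * (a - b) / a, the convention used when quoting "b was X% lower
#' than a".
#'
#' @param a reference (positive); b the compared value.
#' @inheritParams percentHigher
#' @return percentage (full precision).
#' @examples
#' percentLower(0.75, 0.53)  # ~29
#' @export
percentLower <- function(a, b) {
  if (any(a <= 0)) stop("reference value a must be positive")
  100 * (a - b) / a
}

#' Fold ratio between two positive values
#'
#' max(a, b) / min(a, b), always >= 1 and symmetric in its arguments;
#' reports round to one decimal.
#'
#' @inheritParams percentHigher
#' @return dimensionless fold change.
#' @examples
#' foldRatio(0.11, 1.04)  # ~9.5
#' @export
foldRatio <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) stop("fold ratio requires positive values")
  pmax(a, b) / pmin(a, b)
}

#' Classify an effective internal correlation time into flexibility bands
#'
#' Half-open bands: "slow" for tau_e > 500 ps, "intermediate" for
#' 50 ps < tau_e <= 500 ps, "fast" for tau_e <= 50 ps (the boundaries
#' belong to the slower-index band by convention).
#'
#' @param te effective internal correlation time, seconds (vectorized).
#' @return character vector in \{"fast", "intermediate", "slow"\}.
#' @examples
#' classifyTauE(c(1.04e-9, 0.11e-9, 50e-12))
#' @export
classifyTauE <- function(te) {
  if (any(te < 0)) stop("tau_e must be non-negative")
  ifelse(te > 500e-12, "slow", ifelse(te > 50e-12, "intermediate", "fast"))
}

#' Composite amide chemical-shift difference
#'
#' Standard 1H/15N weighting \eqn{\sqrt{\Delta\delta_H^2 +
#' (\Delta\delta_N / w)^2}} with nitrogen weight w = 5 by default.
#'
#' @param d_h,d_n proton and nitrogen chemical-shift differences, ppm.
#' @param nitrogen_weight divisor applied to the nitrogen difference.
#' @return composite shift difference in ppm.
#' @examples
#' compositeShiftDifference(0.2, 1.0)
#' @export
compositeShiftDifference <- function(d_h, d_n, nitrogen_weight = 5) {
  if (any(!is.finite(d_h)) || any(!is.finite(d_n)))
    stop("shift differences must be finite")
  sqrt(d_h^2 + (d_n / nitrogen_weight)^2)
}

#' Flag residues with large composite shift perturbations
#'
#' @param shifts data.frame with columns residue, dH_ppm, dN_ppm.
#' @param threshold flagging threshold in ppm (default 0.3).
#' @inheritParams compositeShiftDifference
#' @return the input with added columns composite_ppm and flagged.
#' @export
flagShiftPerturbations <- function(shifts, threshold = 0.3,
                                   nitrogen_weight = 5) {
  shifts$composite_ppm <- compositeShiftDifference(shifts$dH_ppm,
                                                   shifts$dN_ppm,
                                                   nitrogen_weight)
  shifts$flagged <- shifts$composite_ppm > threshold
  shifts
}

#' Residue-by-residue comparison of two dynamics result sets
#'
#' Builds one row per shared residue and quantity (R1, R2, NOE from the rate
#' columns if present; S2, te, rex from the model-free columns), with both
#' values, the percent-higher/percent-lower pair and the fold ratio.
#' Residues present on only one side are listed with a missing-data flag
#' rather than dropped. Percentages use side A as the reference of
#' `pct_lower_b_under_a` and side B as the reference of
#' `pct_higher_a_over_b`; fold ratios are only computed when both values are
#' positive.
#'
#' @param fits_a,fits_b data.frames keyed by a `residue` column, carrying any
#'   of the columns R1, R2, NOE, S2, te_ns, rex (e.g. output of
#'   [modelfreeAnalysis()], optionally merged with the rate table).
#' @param label_a,label_b names of the two sides used in rendered reports.
#' @return data.frame of comparisons (class "dynamics_comparison").
#' @export
buildComparisonTable <- function(fits_a, fits_b, label_a = "A", label_b = "B") {
  stopifnot(!is.null(fits_a$residue), !is.null(fits_b$residue))
  shared <- intersect(fits_a$residue, fits_b$residue)
  if (length(shared) == 0) stop("no shared residues between the two sides")
  all_res <- sort(union(fits_a$residue, fits_b$residue))
  quantities <- intersect(c("R1", "R2", "NOE", "S2", "te_ns", "rex"),
                          intersect(names(fits_a), names(fits_b)))
  if (length(quantities) == 0)
    stop("no comparable quantity columns shared by the two sides")
  rows <- list()
  for (rid in all_res) {
    ia <- match(rid, fits_a$residue)
    ib <- match(rid, fits_b$residue)
    for (q in quantities) {
      va <- if (is.na(ia)) NA_real_ else fits_a[[q]][ia]
      vb <- if (is.na(ib)) NA_real_ else fits_b[[q]][ib]
      missing <- is.na(va) || is.na(vb)
      both_pos <- !missing && va > 0 && vb > 0
      rows[[length(rows) + 1]] <- data.frame(
        residue = rid, quantity = q, value_a = va, value_b = vb,
        pct_higher_a_over_b = if (both_pos) percentHigher(va, vb) else NA_real_,
        pct_lower_b_under_a = if (both_pos) percentLower(va, vb) else NA_real_,
        fold_ratio = if (both_pos) foldRatio(va, vb) else NA_real_,
        missing = missing)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "labels") <- c(a = label_a, b = label_b)
  class(out) <- c("dynamics_comparison", class(out))
  out
}

#' Render a comparison table as a plain-text report
#'
#' Percentages are rounded to integers and fold ratios to one decimal, the
#' usual style of published dynamics comparisons; the underlying table
#' retains full precision. A pure function of its inputs: identical inputs
#' produce identical bytes.
#'
#' @param comparison output of [buildComparisonTable()].
#' @return character vector of report lines.
#' @export
renderComparisonReport <- function(comparison) {
  lab <- attr(comparison, "labels")
  lines <- c(sprintf("Dynamics comparison: %s (A) vs %s (B)", lab[["a"]],
                     lab[["b"]]),
             sprintf("%-8s %-6s %10s %10s %8s %8s %6s", "residue", "qty",
                     "A", "B", "A>B(%)", "B<A(%)", "fold"))
  for (i in seq_len(nrow(comparison))) {
    r <- comparison[i, ]
    if (r$missing) {
      lines <- c(lines, sprintf("%-8d %-6s %10s %10s   [missing data]",
                                r$residue, r$quantity,
                                ifelse(is.na(r$value_a), "-", format(signif(r$value_a, 4))),
                                ifelse(is.na(r$value_b), "-", format(signif(r$value_b, 4)))))
    } else {
      lines <- c(lines, sprintf("%-8d %-6s %10.4g %10.4g %8.0f %8.0f %6.1f",
                                r$residue, r$quantity, r$value_a, r$value_b,
                                round(r$pct_higher_a_over_b),
                                round(r$pct_lower_b_under_a), r$fold_ratio))
    }
  }
  lines
}
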