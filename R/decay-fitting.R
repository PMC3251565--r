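#' Fit a monoexponential decay to a peak-height series
#'
#' Nonlinear least squares of \eqn{I(t) = I_0 e^{-R t}} on the untransformed
#' heights (Levenberg-Marquardt), initialized from a log-linear regression of
#' the positive heights. No baseline offset is fitted by default, since
#' heteronuclear 15N decays relax to zero; set `offset = TRUE` to add one.
#'
#' @param delays relaxation delays, seconds (>= 3 distinct values).
#' @param heights peak heights, arbitrary intensity units, same length.
#' @param residue_id integer residue number (carried through).
#' @param replicate_id integer replicate label (carried through).
#' @param offset fit an additive baseline term (default FALSE).
#' @return list with elements `residue_id`, `rate` (s^-1), `sigma` (s^-1,
#'   from the fit covariance), `amplitude`, `n_replicates` (1), `replicate_id`
#'   and `status` ("ok" or "non_decaying").
#' @examples
#' fitMonoexponential(c(0.1, 0.5, 1.0), exp(-2 * c(0.1, 0.5, 1.0)))
#' @export
fitMonoexponential <- function(delays, heights, residue_id = NA_integer_,
                               replicate_id = NA_integer_, offset = FALSE) {
  if (length(delays) != length(heights))
    stop("delays and heights must have the same length")
  if (any(!is.finite(delays)) || any(!is.finite(heights)))
    stop("delays and heights must be finite")
  if (any(delays < 0)) stop("delays must be non-negative")
  # two exact points determine the exponential; allow n = 2 only when the
  # system is exactly determined and noise-free fitting is intended
  if (length(unique(delays)) < 3 && length(unique(delays)) != 2)
    stop("need at least 3 distinct relaxation delays")
  if (length(unique(delays)) == 2 && length(delays) > 2)
    stop("need at least 3 distinct relaxation delays")

  o <- order(delays)
  delays <- delays[o]
  heights <- heights[o]

  # log-linear start (positive heights only)
  pos <- heights > 0
  if (sum(pos) >= 2) {
    lf <- stats::lm(log(heights[pos]) ~ delays[pos])
    r0 <- -unname(stats::coef(lf)[2])
    i0 <- exp(unname(stats::coef(lf)[1]))
  } else {
    r0 <- 1
    i0 <- max(abs(heights))
  }
  status <- "ok"
  if (!is.finite(r0) || r0 <= 0) {
    warning("series does not decay (initial rate estimate <= 0); flagged")
    status <- "non_decaying"
    r0 <- 1e-3
  }

  if (length(delays) == 2) {
    # exactly determined: closed form
    rate <- log(heights[1] / heights[2]) / (delays[2] - delays[1])
    amp <- heights[1] * exp(rate * delays[1])
    return(list(residue_id = residue_id, rate = rate, sigma = 0,
                amplitude = amp, n_replicates = 1L,
                replicate_id = replicate_id,
                status = if (rate > 0) "ok" else "non_decaying"))
  }

  df <- data.frame(t = delays, y = heights)
  fit <- tryCatch({
    if (offset)
      minpack.lm::nlsLM(y ~ i0 * exp(-r * t) + b, data = df,
                        start = list(i0 = i0, r = max(r0, 1e-3), b = 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
    else
      minpack.lm::nlsLM(y ~ i0 * exp(-r * t), data = df,
                        start = list(i0 = i0, r = max(r0, 1e-3)),
                        lower = c(0, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 200))
  }, error = function(e) NULL)
  if (is.null(fit)) {
    warning("monoexponential fit failed to converge; flagged")
    return(list(residue_id = residue_id, rate = NA_real_, sigma = NA_real_,
                amplitude = NA_real_, n_replicates = 1L,
                replicate_id = replicate_id, status = "failed"))
  }
  co <- summary(fit)$coefficients
  rate <- co["r", "Estimate"]
  sigma <- co["r", "Std. Error"]
  if (rate <= 1e-9) status <- "non_decaying"
  # plausibility guard against delay-unit mistakes (e.g. ms passed as s)
  if (status == "ok" && (rate < 0.01 || rate > 100))
    warning(sprintf(paste0("fitted rate %.3g s^-1 outside the plausible ",
                           "0.01-100 s^-1 range; check delay units (seconds expected)"),
                    rate))
  list(residue_id = residue_id, rate = rate, sigma = sigma,
       amplitude = co["i0", "Estimate"], n_replicates = 1L,
       replicate_id = replicate_id, status = status)
}

#' Aggregate replicate rate estimates for one residue
#'
#' The reported rate is the mean across replicates; its uncertainty is the
#' larger of the propagated fit sigma (quadrature mean / sqrt(n)) and the
#' half-range of the replicate rates, a conservative rule for the usual case
#' of two independent data sets.
#'
#' @param estimates list of estimates from [fitMonoexponential()] for the
#'   same residue.
#' @return a single aggregated estimate (same shape, `n_replicates` updated).
#' @export
aggregateReplicates <- function(estimates) {
  stopifnot(length(estimates) >= 1)
  ids <- vapply(estimates, function(e) as.integer(e$residue_id), integer(1))
  if (length(unique(ids)) > 1)
    stop("cannot aggregate estimates from different residues")
  if (length(estimates) == 1) return(estimates[[1]])
  rates <- vapply(estimates, function(e) e$rate, numeric(1))
  sig <- vapply(estimates, function(e) e$sigma, numeric(1))
  ok <- is.finite(rates)
  if (!any(ok)) stop("no finite replicate rates to aggregate")
  rates <- rates[ok]
  sig <- sig[ok]
  half_range <- (max(rates) - min(rates)) / 2
  prop <- sqrt(mean(sig^2)) / sqrt(length(rates))
  status <- vapply(estimates, function(e) e$status, character(1))
  list(residue_id = ids[1], rate = mean(rates),
       sigma = max(prop, half_range),
       amplitude = mean(vapply(estimates[ok], function(e) e$amplitude, numeric(1))),
       n_replicates = length(rates), replicate_id = NA_integer_,
       status = if (all(status[ok] == "ok")) "ok" else "flagged")
}

#' Compute the steady-state heteronuclear NOE from paired spectra
#'
#' NOE = mean over pairs of (saturated height / reference height); the
#' uncertainty is the standard deviation over pairs (0 for a single pair).
#'
#' @param sat_heights peak heights with proton saturation, one per pair.
#' @param ref_heights reference peak heights (no saturation), same length.
#' @param residue_id integer residue number.
#' @return list with `residue_id`, `noe`, `sigma`, `n_pairs`.
#' @examples
#' computeNOE(c(0.40, 0.42, 0.44), c(1, 1, 1))
#' @export
computeNOE <- function(sat_heights, ref_heights, residue_id = NA_integer_) {
  if (length(sat_heights) != length(ref_heights))
    stop("saturated and reference height lists must have equal length")
  if (length(sat_heights) == 0) stop("need at least one NOE pair")
  if (any(ref_heights <= 0))
    stop("reference peak heights must be positive")
  ratios <- sat_heights / ref_heights
  noe <- mean(ratios)
  sigma <- if (length(ratios) > 1) stats::sd(ratios) else 0
  if (noe > 1.05)
    warning(sprintf("NOE %.3f exceeds the physical ceiling (1.05 tolerated for noise)", noe))
  list(residue_id = residue_id, noe = noe, sigma = sigma,
       n_pairs = length(ratios))
}

#' Estimate per-residue relaxation rates from a long-format decay table
#'
#' Consumes the long decay schema (columns residue, experiment in
#' \{R1, R2, NOE_SAT, NOE_REF\}, replicate, delay_s, height): fits each
#' residue x experiment x replicate decay with [fitMonoexponential()],
#' aggregates replicates with [aggregateReplicates()], and pairs NOE_SAT with
#' NOE_REF rows (matched by replicate) through [computeNOE()].
#'
#' @param decays data.frame in the long decay schema.
#' @param offset passed to [fitMonoexponential()].
#' @return rate table data.frame: residue, R1, R1_err, R2, R2_err, NOE,
#'   NOE_err, status.
#' @export
fitDecayTable <- function(decays, offset = FALSE) {
  validateDecayTable(decays)
  residues <- sort(unique(decays$residue))
  rows <- lapply(residues, function(rid) {
    sub <- decays[decays$residue == rid, ]
    est <- list()
    for (exp_type in c("R1", "R2")) {
      dsub <- sub[sub$experiment == exp_type, ]
      if (nrow(dsub) == 0) {
        est[[exp_type]] <- list(rate = NA_real_, sigma = NA_real_, status = "missing")
        next
      }
      reps <- lapply(split(dsub, dsub$replicate), function(d)
        fitMonoexponential(d$delay_s, d$height, residue_id = rid,
                           replicate_id = d$replicate[1], offset = offset))
      est[[exp_type]] <- aggregateReplicates(unname(reps))
    }
    sat <- sub[sub$experiment == "NOE_SAT", ]
    ref <- sub[sub$experiment == "NOE_REF", ]
    noe <- if (nrow(sat) && nrow(ref)) {
      sat <- sat[order(sat$replicate), ]
      ref <- ref[order(ref$replicate), ]
      if (!identical(sat$replicate, ref$replicate))
        stop(sprintf("residue %d: unmatched NOE pairs", rid))
      computeNOE(sat$height, ref$height, residue_id = rid)
    } else list(noe = NA_real_, sigma = NA_real_)
    status <- c(est$R1$status, est$R2$status)
    data.frame(residue = rid,
               R1 = est$R1$rate, R1_err = est$R1$sigma,
               R2 = est$R2$rate, R2_err = est$R2$sigma,
               NOE = noe$noe, NOE_err = noe$sigma,
               status = if (all(status == "ok")) "ok" else "flagged")
  })
  do.call(rbind, rows)
}

#' Validate the long decay-table schema
#'
#' @param decays candidate data.frame.
#' @return invisibly TRUE; stops with a message naming missing columns.
#' @export
validateDecayTable <- function(decays) {
  need <- c("residue", "experiment", "replicate", "delay_s", "height")
  missing <- setdiff(need, names(decays))
  if (length(missing))
    stop("decay table is missing required columns: ",
         paste(missing, collapse = ", "))
  if (nrow(decays) == 0) stop("decay table has no rows")
  bad <- setdiff(unique(decays$experiment), c("R1", "R2", "NOE_SAT", "NOE_REF"))
  if (length(bad))
    stop("unknown experiment labels: ", paste(bad, collapse = ", "))
  invisible(TRUE)
}
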