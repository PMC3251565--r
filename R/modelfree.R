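#' Build a per-residue relaxation record table
#'
#' Validates and normalizes a table of per-residue relaxation observables
#' (R1, R2, NOE with uncertainties) as consumed by the model-free fitting
#' functions. Zero or sub-floor uncertainties are raised to a relative floor
#' (default 0.5% of the value) so that no single observable can dominate the
#' chi-square through an unrealistically small error bar.
#'
#' @param records data.frame with columns residue, R1, R1_err, R2, R2_err,
#'   NOE, NOE_err and optionally residue_name and field_mhz.
#' @param sigma_floor relative uncertainty floor (fraction of the value).
#' @return validated data.frame with floored uncertainties.
#' @export
relaxationRecords <- function(records, sigma_floor = 0.005) {
  need <- c("residue", "R1", "R1_err", "R2", "R2_err", "NOE", "NOE_err")
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("record table is missing required columns: ",
         paste(missing, collapse = ", "))
  if (nrow(records) == 0) stop("record table has no rows")
  if (any(records$R1 <= 0 | records$R2 <= 0))
    stop("relaxation rates must be positive")
  for (q in c("R1", "R2", "NOE")) {
    ec <- paste0(q, "_err")
    records[[ec]] <- pmax(records[[ec]], sigma_floor * abs(records[[q]]))
  }
  if (is.null(records$residue_name)) records$residue_name <- NA_character_
  records
}

# Precompute everything the hot rate evaluation needs from (diffusion,
# context): the five sampling frequencies, interaction constants and, for the
# axial model, the three correlation times and orientation amplitudes.
.precompute <- function(diffusion, context) {
  wh <- omegaH(context)
  wn <- omegaN(context)
  ic <- interactionConstants(context)
  pre <- list(freqs = c(0, wn, wh - wn, wh, wh + wn),
              d2 = ic[["d2"]], c2 = ic[["c2"]],
              gr = context@gyromagnetic_ratio_ratio,
              tm = diffusion@tm, axial = diffusion@kind == "axially_symmetric")
  if (pre$axial) {
    if (!is.finite(diffusion@nh_axis_angle))
      stop("axial diffusion model requires N-H bond orientations (nh_axis_angle)")
    rho <- diffusion@anisotropy_ratio
    diso <- 1 / (6 * diffusion@tm)
    dperp <- 3 * diso / (2 + rho)
    dpar <- rho * dperp
    pre$taus <- c(1 / (6 * dperp), 1 / (5 * dperp + dpar),
                  1 / (2 * dperp + 4 * dpar))
    pre$amps <- axialAmplitudes(diffusion@nh_axis_angle)
  }
  pre
}

.jPre <- function(w, pre, s2, te, s2f) {
  if (!pre$axial) {
    j <- s2 * pre$tm / (1 + (w * pre$tm)^2)
    if (te > 0 && s2f != s2) {
      tp <- pre$tm * te / (pre$tm + te)
      j <- j + (s2f - s2) * tp / (1 + (w * tp)^2)
    }
    return(0.4 * j)
  }
  j <- 0
  for (k in 1:3) {
    tk <- pre$taus[k]
    term <- s2 * tk / (1 + (w * tk)^2)
    if (te > 0 && s2f != s2) {
      tpk <- tk * te / (tk + te)
      term <- term + (s2f - s2) * tpk / (1 + (w * tpk)^2)
    }
    j <- j + pre$amps[k] * term
  }
  0.4 * j
}

.ratesPre <- function(pre, s2, te, rex, s2f = 1) {
  jj <- .jPre(pre$freqs, pre, s2, te, s2f)
  r1 <- pre$d2 / 4 * (jj[3] + 3 * jj[2] + 6 * jj[5]) + pre$c2 * jj[2]
  r2 <- pre$d2 / 8 * (4 * jj[1] + jj[3] + 3 * jj[2] + 6 * jj[4] + 6 * jj[5]) +
    pre$c2 / 6 * (4 * jj[1] + 3 * jj[2]) + rex
  noe <- 1 + pre$d2 / 4 * pre$gr / r1 * (6 * jj[5] - jj[3])
  c(r1, r2, noe)
}

.chi2Pre <- function(pre, obs, sig, s2, te, rex, s2f = 1) {
  p <- .ratesPre(pre, s2, te, rex, s2f)
  sum(((p - obs) / sig)^2)
}

#' Chi-square of a model-free parameter set against a relaxation record
#'
#' \eqn{\chi^2 = \sum_{X \in \{R_1, R_2, NOE\}}
#'   \left(\frac{X_{obs} - X_{pred}}{\sigma_X}\right)^2}
#'
#' @param record one-row data.frame (or named list) with R1, R1_err, R2,
#'   R2_err, NOE, NOE_err.
#' @param params a [DynamicsParams-class].
#' @param diffusion a [DiffusionModel-class].
#' @param context a [SpectrometerContext-class].
#' @return chi-square value (numeric scalar).
#' @export
chiSquare <- function(record, params, diffusion, context) {
  sig <- c(record$R1_err, record$R2_err, record$NOE_err)
  if (any(!is.finite(sig)) || any(sig <= 0))
    stop("all observable uncertainties must be positive")
  pre <- .precompute(diffusion, context)
  .chi2Pre(pre, c(record$R1, record$R2, record$NOE), sig,
           params@s2, params@te, params@rex, params@s2f)
}

# model parameterizations: free parameter names, bounds (te in ns) and starts
.modelSpec <- function(model_id, tm_ns) {
  switch(model_id,
    list(free = "s2", lower = 0, upper = 1,
         starts = matrix(c(0.3, 0.6, 0.9), ncol = 1)),
    list(free = c("s2", "te_ns"), lower = c(0, 0), upper = c(1, tm_ns),
         starts = as.matrix(expand.grid(c(0.3, 0.6, 0.9), c(0.01, 0.1, 1)))),
    list(free = c("s2", "rex"), lower = c(0, 0), upper = c(1, 20),
         starts = as.matrix(expand.grid(c(0.3, 0.6, 0.9), c(0, 2)))),
    list(free = c("s2", "te_ns", "rex"), lower = c(0, 0, 0),
         upper = c(1, tm_ns, 20),
         starts = as.matrix(expand.grid(c(0.3, 0.6, 0.9), c(0.01, 0.1, 1),
                                        c(0, 2)))),
    list(free = c("s2f", "s2s", "te_ns"), lower = c(0, 0, 0),
         upper = c(1, 1, tm_ns),
         starts = as.matrix(expand.grid(c(0.6, 0.9), c(0.3, 0.6, 0.9),
                                        c(0.01, 0.1, 1)))))
}

.paramsFromVector <- function(model_id, p) {
  switch(model_id,
         list(s2 = p[1], te = 0, rex = 0, s2f = 1),
         list(s2 = p[1], te = p[2] * 1e-9, rex = 0, s2f = 1),
         list(s2 = p[1], te = 0, rex = p[2], s2f = 1),
         list(s2 = p[1], te = p[2] * 1e-9, rex = p[3], s2f = 1),
         list(s2 = p[1] * p[2], te = p[3] * 1e-9, rex = 0, s2f = p[1]))
}

.fitModelPre <- function(pre, obs, sig, model_id, tm_ns,
                         starts = NULL, residue_id = NA_integer_,
                         coarse = FALSE) {
  ms <- .modelSpec(model_id, tm_ns)
  if (is.null(starts)) starts <- ms$starts
  obj <- function(p) {
    pp <- .paramsFromVector(model_id, p)
    v <- .chi2Pre(pre, obs, sig, pp$s2, pp$te, pp$rex, pp$s2f)
    # at s2 = s2f = 0 all spectral densities vanish and the NOE (which
    # divides by R1) is undefined; a large finite penalty keeps the bounded
    # optimizer away without derailing it
    if (!is.finite(v)) 1e12 else v
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(as.numeric(starts[i, ]), ms$lower), ms$upper)
    res <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B", lower = ms$lower,
                   upper = ms$upper,
                   control = list(factr = if (coarse) 1e7 else 1e4,
                                  maxit = if (coarse) 100 else 500)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$value < best$value)) best <- res
  }
  if (is.null(best)) {
    return(new("ModelFit", residue_id = as.integer(residue_id),
               params = do.call(dynamicsParams,
                                c(list(model_id = model_id),
                                  if (model_id == 5) list(s2f = 1, s2s = 1)
                                  else list(s2 = 1))),
               chi2 = Inf, dof = as.integer(3 - length(ms$free)),
               mc_sigmas = numeric(), status = "failed"))
  }
  # polish from the best start so the result is start-independent to tolerance
  polished <- if (coarse) NULL else tryCatch(
    stats::optim(best$par, obj, method = "L-BFGS-B", lower = ms$lower,
                 upper = ms$upper, control = list(factr = 10, maxit = 1000)),
    error = function(e) NULL)
  if (!is.null(polished) && polished$value <= best$value) best <- polished
  p <- pmin(pmax(best$par, ms$lower), ms$upper)
  tolb <- 1e-6 * pmax(ms$upper - ms$lower, 1)
  at_bound <- any(p - ms$lower < tolb | ms$upper - p < tolb)
  pp <- .paramsFromVector(model_id, p)
  params <- if (model_id == 5)
    dynamicsParams(5, te_ns = pp$te * 1e9, s2f = p[1], s2s = p[2])
  else
    dynamicsParams(model_id, s2 = pp$s2, te_ns = pp$te * 1e9, rex = pp$rex)
  new("ModelFit", residue_id = as.integer(residue_id), params = params,
      chi2 = max(best$value, 0), dof = as.integer(3 - length(ms$free)),
      mc_sigmas = numeric(),
      status = if (at_bound) "boundary" else "converged")
}

#' Fit one model-free model to one residue's relaxation record
#'
#' Minimizes [chiSquare()] over the model's free parameters by bounded
#' quasi-Newton optimization from a grid of starting points (S2 in
#' \{0.3, 0.6, 0.9\}, tau_e in \{10 ps, 100 ps, 1 ns\}, Rex in \{0, 2\} s^-1;
#' bounds S2 in [0,1], tau_e in [0, tau_m], Rex in [0, 20] s^-1), followed by
#' a high-precision polish from the best start. The chi-square surface is
#' multimodal in tau_e, hence the multi-start.
#'
#' @param record one-row relaxation record (see [relaxationRecords()]).
#' @param model_id model-free model 1-5.
#' @param diffusion a [DiffusionModel-class] (tau_m fixed during the fit).
#' @param context a [SpectrometerContext-class].
#' @return a [ModelFit-class].
#' @examples
#' rec <- relaxationRecords(data.frame(residue = 49, R1 = 1.63, R1_err = 0.04,
#'   R2 = 5.98, R2_err = 0.01, NOE = 0.42, NOE_err = 0.01))
#' fitModel(rec[1, ], 2, diffusionModel(6.38), spectrometerContext(600.13))
#' @export
fitModel <- function(record, model_id, diffusion, context) {
  model_id <- as.integer(model_id)
  if (!model_id %in% 1:5) stop("model_id must be in 1..5")
  sig <- c(record$R1_err, record$R2_err, record$NOE_err)
  if (any(!is.finite(sig)) || any(sig <= 0))
    stop("all observable uncertainties must be positive")
  pre <- .precompute(diffusion, context)
  .fitModelPre(pre, c(record$R1, record$R2, record$NOE), sig, model_id,
               diffusion@tm * 1e9, residue_id = record$residue)
}

#' Selection settings for stepwise model-free model choice
#'
#' @param gof_level goodness-of-fit confidence level (default 0.90).
#' @param ftest_level F-test confidence level for added parameters (0.80).
#' @param n_sims Monte Carlo simulations per record used to build the
#'   chi-square critical value (default 500).
#' @param gof_method "monte_carlo" (simulate the chi-square null
#'   distribution around the back-calculated rates) or "chisq" (analytic
#'   chi-square quantile; faster, used internally for tau_m grids).
#' @param seed base seed; each record/model derives its own stream from it.
#' @return list of class "selection_config".
#' @export
selectionConfig <- function(gof_level = 0.90, ftest_level = 0.80,
                            n_sims = 500,
                            gof_method = c("monte_carlo", "chisq"),
                            seed = 20210915) {
  structure(list(gof_level = gof_level, ftest_level = ftest_level,
                 n_sims = n_sims, gof_method = match.arg(gof_method),
                 seed = as.integer(seed %% .Machine$integer.max)),
            class = "selection_config")
}

# Monte Carlo chi-square critical value: simulate records consistent with the
# fitted model (Gaussian noise with the record's sigmas around the
# back-calculated rates), refit the same model from the fitted parameters,
# and take the gof_level quantile of the simulated chi-squares.
.mcCriticalValue <- function(pre, fit, sig, model_id, tm_ns, config,
                             residue_id) {
  pp <- fit@params
  back <- .ratesPre(pre, pp@s2, pp@te, pp@rex, pp@s2f)
  ms <- .modelSpec(model_id, tm_ns)
  start <- switch(model_id,
                  pp@s2, c(pp@s2, pp@te * 1e9), c(pp@s2, pp@rex),
                  c(pp@s2, pp@te * 1e9, pp@rex),
                  c(pp@s2f, pp@s2s, pp@te * 1e9))
  seed <- (config$seed + 7919L * as.integer(residue_id %% 10000) +
             104729L * model_id) %% .Machine$integer.max
  chi2s <- withSeed(seed, {
    vapply(seq_len(config$n_sims), function(i) {
      obs_i <- back + stats::rnorm(3, 0, sig)
      f <- .fitModelPre(pre, obs_i, sig, model_id, tm_ns,
                        starts = matrix(start, nrow = 1), coarse = TRUE)
      f@chi2
    }, numeric(1))
  })
  stats::quantile(chi2s, config$gof_level, names = FALSE, type = 7)
}

#' Stepwise model-free model selection for one residue
#'
#' Implements the standard stepwise hierarchy: accept model 1 if it passes a
#' chi-square goodness-of-fit test at `gof_level`; otherwise consider models
#' 2 and 3, each accepted if it passes its own goodness-of-fit test and
#' improves on model 1 by an F-test at `ftest_level`; otherwise consider the
#' three-parameter models 4 and 5, which fit three observables exactly
#' (zero residual degrees of freedom), accepted when their chi-square drop
#' relative to the best simpler model exceeds the `ftest_level` chi-square
#' quantile for the added parameters (a likelihood-ratio-style rule, since
#' the F denominator has zero degrees of freedom there). Ties go to the lower
#' model id. Goodness-of-fit critical values come from `n_sims` Monte Carlo
#' simulations per record (or analytic chi-square quantiles with
#' `gof_method = "chisq"`). Deterministic given the config and seed.
#'
#' @inheritParams fitModel
#' @param config a [selectionConfig()].
#' @return the accepted [ModelFit-class] (all candidate fits attached as
#'   attribute "candidates").
#' @export
selectModel <- function(record, diffusion, context,
                        config = selectionConfig()) {
  sig <- c(record$R1_err, record$R2_err, record$NOE_err)
  if (any(!is.finite(sig)) || any(sig <= 0))
    stop("all observable uncertainties must be positive")
  pre <- .precompute(diffusion, context)
  obs <- c(record$R1, record$R2, record$NOE)
  tm_ns <- diffusion@tm * 1e9
  rid <- record$residue
  fits <- lapply(1:5, function(m)
    .fitModelPre(pre, obs, sig, m, tm_ns, residue_id = rid))
  chi2 <- vapply(fits, function(f) f@chi2, numeric(1))
  npar <- c(1, 2, 2, 3, 3)

  crit <- function(m) {
    dof <- 3 - npar[m]
    if (config$gof_method == "chisq")
      stats::qchisq(config$gof_level, dof)
    else
      .mcCriticalValue(pre, fits[[m]], sig, m, tm_ns, config, rid)
  }

  pick <- function(m) {
    fit <- fits[[m]]
    attr(fit, "candidates") <- fits
    fit
  }

  if (fits[[1]]@status != "failed" && chi2[1] <= crit(1)) return(pick(1))

  for (m in 2:3) {
    if (fits[[m]]@status == "failed") next
    dof1 <- 2; dofm <- 1
    fstat <- if (chi2[m] <= 0) Inf
             else ((chi2[1] - chi2[m]) / (dof1 - dofm)) / (chi2[m] / dofm)
    if (fstat > stats::qf(config$ftest_level, dof1 - dofm, dofm) &&
        chi2[m] <= crit(m)) return(pick(m))
  }

  simpler <- which.min(chi2[1:3])   # which.min already ties to the lower id
  for (m in 4:5) {
    if (fits[[m]]@status == "failed") next
    extra <- npar[m] - npar[simpler]
    drop <- chi2[simpler] - chi2[m]
    if (drop > stats::qchisq(config$ftest_level, max(extra, 1L)))
      return(pick(m))
  }

  pick(which.min(chi2))
}

#' Monte Carlo parameter uncertainties for a model-free fit
#'
#' Draws `n_draws` synthetic records Gaussian-distributed around the fit's
#' back-calculated rates with the record's uncertainties, refits the same
#' model (starting from the fitted parameters), and reports the standard
#' deviation of each refitted parameter. Reproducible under a fixed seed.
#'
#' @param fit a converged [ModelFit-class].
#' @inheritParams fitModel
#' @param n_draws number of synthetic records (default 500).
#' @param seed integer seed.
#' @return the fit with its `mc_sigmas` slot filled (named: s2, te_ns, rex,
#'   and s2f/s2s for model 5).
#' @export
monteCarloErrors <- function(fit, record, diffusion, context, n_draws = 500,
                             seed = 1) {
  if (fit@status == "failed")
    stop("cannot estimate Monte Carlo errors for a failed fit")
  pre <- .precompute(diffusion, context)
  sig <- c(record$R1_err, record$R2_err, record$NOE_err)
  pp <- fit@params
  m <- pp@model_id
  tm_ns <- diffusion@tm * 1e9
  back <- .ratesPre(pre, pp@s2, pp@te, pp@rex, pp@s2f)
  start <- switch(m, pp@s2, c(pp@s2, pp@te * 1e9), c(pp@s2, pp@rex),
                  c(pp@s2, pp@te * 1e9, pp@rex),
                  c(pp@s2f, pp@s2s, pp@te * 1e9))
  draws <- withSeed(seed, {
    t(vapply(seq_len(n_draws), function(i) {
      obs_i <- back + stats::rnorm(3, 0, sig)
      f <- .fitModelPre(pre, obs_i, sig, m, tm_ns,
                        starts = matrix(start, nrow = 1))
      p <- f@params
      c(s2 = p@s2, te_ns = p@te * 1e9, rex = p@rex, s2f = p@s2f, s2s = p@s2s)
    }, numeric(5)))
  })
  keep <- switch(m, "s2", c("s2", "te_ns"), c("s2", "rex"),
                 c("s2", "te_ns", "rex"), c("s2", "s2f", "s2s", "te_ns"))
  fit@mc_sigmas <- apply(draws[, keep, drop = FALSE], 2, stats::sd)
  fit
}

#' Run a seeded expression and restore the RNG state
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
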