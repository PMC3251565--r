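# Context lookup for record tables that may mix static fields. `context` is
# either a single SpectrometerContext (applied to every record) or a named
# list keyed by proton frequency in MHz, matched against a field_mhz column.
.contextFor <- function(record, context) {
  if (is(context, "SpectrometerContext")) return(context)
  stopifnot(is.list(context))
  key <- as.character(record$field_mhz)
  if (is.null(record$field_mhz) || is.na(record$field_mhz))
    stop("records with multiple contexts need a field_mhz column")
  ctx <- context[[key]]
  if (is.null(ctx))
    stop("no spectrometer context supplied for field ", key, " MHz")
  ctx
}

.contextList <- function(records, context) {
  lapply(seq_len(nrow(records)), function(i) .contextFor(records[i, ], context))
}

# rigid-body R2/R1 ratio at a given tm (seconds) for one context
.rigidRatio <- function(tm, context) {
  pre <- .precompute(new("DiffusionModel", kind = "isotropic", tm = tm,
                         anisotropy_ratio = 1, nh_axis_angle = NA_real_),
                     context)
  r <- .ratesPre(pre, 1, 0, 0)
  r[2] / r[1]
}

.invertRigidRatio <- function(target, context, interval = c(0.3e-9, 30e-9)) {
  f <- function(tm) .rigidRatio(tm, context) - target
  if (f(interval[1]) > 0) return(interval[1])
  if (f(interval[2]) < 0) return(interval[2])
  stats::uniroot(f, interval, tol = 1e-13)$root
}

#' Initial tau_m estimate from the R2/R1 ratio
#'
#' For a rigid residue the R2/R1 ratio is a monotone function of the overall
#' correlation time and independent of the dipolar/CSA magnitudes' common
#' scale; inverting it numerically gives a robust tau_m initializer. The
#' estimate uses the 10%-trimmed mean ratio over records with NOE > 0.65
#' (flexible residues bias the ratio); if none qualify, the untrimmed full
#' set is used with a warning.
#'
#' @param records relaxation record table (see [relaxationRecords()]).
#' @param context a [SpectrometerContext-class], or a named list of contexts
#'   keyed by field (MHz) when `records$field_mhz` is present.
#' @return tau_m estimate in seconds.
#' @export
estimateTmR2R1 <- function(records, context) {
  stopifnot(nrow(records) >= 1)
  sel <- records$NOE > 0.65
  if (!any(sel)) {
    warning("no records with NOE > 0.65; using the untrimmed full set")
    sel <- rep(TRUE, nrow(records))
  }
  sub <- records[sel, ]
  if (is(context, "SpectrometerContext")) {
    target <- mean(sub$R2 / sub$R1, trim = 0.1)
    .invertRigidRatio(target, context)
  } else {
    # mixed fields: the ratio is field-dependent, so invert per record and
    # trim-average the field-independent tau_m instead
    tms <- vapply(seq_len(nrow(sub)), function(i)
      .invertRigidRatio(sub$R2[i] / sub$R1[i], .contextFor(sub[i, ], context)),
      numeric(1))
    mean(tms, trim = 0.1)
  }
}

# Flag residues whose R2/R1 ratio suggests exchange broadening: ratio more
# than one standard deviation above the 10%-trimmed mean of the NOE > 0.65
# subset.
flagExchange <- function(records) {
  ratio <- records$R2 / records$R1
  base <- ratio[records$NOE > 0.65]
  if (length(base) < 3) base <- ratio
  ratio > mean(base, trim = 0.1) + stats::sd(base)
}

#' Core-residue subset used for tau_m optimization
#'
#' Residues with NOE > 0.65 and no exchange flag (R2/R1 not elevated above
#' the trimmed-mean ratio by more than one standard deviation); flexible and
#' exchanging residues bias the overall correlation time.
#'
#' @inheritParams estimateTmR2R1
#' @return logical vector over rows of `records`.
#' @export
coreSubset <- function(records) {
  records$NOE > 0.65 & !flagExchange(records)
}

# Fast per-residue objective at fixed tm: cheap stepwise re-selection among
# models 1-3 (model 1 kept when adequate by analytic GOF; otherwise the best
# of models 1-3 under an AIC-style penalty of 2 per added parameter). The
# penalty matters: with a free tau_e a rigid record can be fitted exactly at
# ANY tm above the true value, so an unpenalized objective is flat in tm and
# the optimum undefined; parsimony restores a unique minimum. Light
# single/dual starts keep the tm grid affordable.
.residueChi2AtTm <- function(pre, obs, sig, tm_ns, gof_level = 0.90) {
  f1 <- .fitModelPre(pre, obs, sig, 1L, tm_ns,
                     starts = matrix(0.8, nrow = 1), coarse = TRUE)
  if (f1@chi2 <= stats::qchisq(gof_level, 2)) return(f1@chi2)
  s2_1 <- f1@params@s2
  f2 <- .fitModelPre(pre, obs, sig, 2L, tm_ns,
                     starts = matrix(c(s2_1, s2_1, 0.05, 0.8), ncol = 2),
                     coarse = TRUE)
  f3 <- .fitModelPre(pre, obs, sig, 3L, tm_ns,
                     starts = matrix(c(s2_1, 1), nrow = 1), coarse = TRUE)
  min(f1@chi2, f2@chi2 + 2, f3@chi2 + 2)
}

#' Optimize the overall rotational correlation time
#'
#' Two-stage tau_m fit mirroring the usual model-free workflow: the total
#' chi-square over the core-residue subset (see [coreSubset()]) is minimized
#' over tau_m, with a cheap per-residue model re-selection at each candidate
#' tau_m. A 1-15 ns grid at 0.1 ns spacing brackets the optimum, which is
#' then refined by golden-section search. The resulting diffusion model is
#' fixed for the final per-residue fits.
#'
#' @inheritParams estimateTmR2R1
#' @param kind diffusion model kind; the axial model additionally requires
#'   `anisotropy_ratio` and per-record `nh_axis_angle` values.
#' @param anisotropy_ratio D_parallel/D_perpendicular for the axial model.
#' @param grid_ns candidate tau_m grid in ns.
#' @return the optimized [DiffusionModel-class].
#' @export
optimizeTm <- function(records, context,
                       kind = c("isotropic", "axially_symmetric"),
                       anisotropy_ratio = 1.25,
                       grid_ns = seq(1, 15, by = 0.1)) {
  kind <- match.arg(kind)
  if (nrow(records) < 5)
    stop("tau_m optimization needs at least 5 records (underdetermined)")
  core <- coreSubset(records)
  if (sum(core) < 3) {
    warning("fewer than 3 core residues; using all records for tau_m")
    core <- rep(TRUE, nrow(records))
  }
  sub <- records[core, ]
  ctxs <- .contextList(sub, context)
  obs <- lapply(seq_len(nrow(sub)), function(i)
    c(sub$R1[i], sub$R2[i], sub$NOE[i]))
  sig <- lapply(seq_len(nrow(sub)), function(i)
    c(sub$R1_err[i], sub$R2_err[i], sub$NOE_err[i]))
  angles <- if (kind == "axially_symmetric") {
    if (is.null(sub$nh_axis_angle))
      stop("axial model requires an nh_axis_angle column (degrees)")
    sub$nh_axis_angle
  } else rep(NA_real_, nrow(sub))

  total <- function(tm_ns) {
    tot <- 0
    for (i in seq_along(obs)) {
      diff <- new("DiffusionModel", kind = kind, tm = tm_ns * 1e-9,
                  anisotropy_ratio = if (kind == "isotropic") 1 else anisotropy_ratio,
                  nh_axis_angle = angles[i])
      pre <- .precompute(diff, ctxs[[i]])
      tot <- tot + .residueChi2AtTm(pre, obs[[i]], sig[[i]], tm_ns)
    }
    tot
  }
  vals <- vapply(grid_ns, total, numeric(1))
  i <- which.min(vals)
  lo <- grid_ns[max(i - 1, 1)]
  hi <- grid_ns[min(i + 1, length(grid_ns))]
  refined <- stats::optimize(total, interval = c(lo, hi), tol = 1e-4)
  diffusionModel(refined$minimum, kind = kind,
                 anisotropy_ratio = if (kind == "isotropic") NA_real_ else anisotropy_ratio)
}

#' Model-free analysis of a relaxation record table
#'
#' Per-residue stepwise model selection (see [selectModel()]) at a fixed
#' diffusion model, with optional Monte Carlo parameter uncertainties,
#' returning the tabular results layout (one row per residue).
#'
#' @inheritParams estimateTmR2R1
#' @param diffusion a [DiffusionModel-class]; if NULL, tau_m is optimized
#'   from the records first via [optimizeTm()].
#' @param config a [selectionConfig()].
#' @param mc_draws Monte Carlo error draws per residue (0 to skip).
#' @param mc_seed seed for the Monte Carlo error estimation.
#' @return data.frame: residue, model, S2, S2_err, te_ns, te_err, rex,
#'   rex_err, chi2, status; the diffusion model used is attached as
#'   attribute "diffusion".
#' @export
modelfreeAnalysis <- function(records, context, diffusion = NULL,
                              config = selectionConfig(), mc_draws = 0,
                              mc_seed = 1) {
  records <- relaxationRecords(records)
  if (is.null(diffusion)) diffusion <- optimizeTm(records, context)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    ctx <- .contextFor(rec, context)
    fit <- selectModel(rec, diffusion, ctx, config)
    err <- c(s2 = NA_real_, te_ns = NA_real_, rex = NA_real_)
    if (mc_draws > 0 && fit@status != "failed") {
      fit <- monteCarloErrors(fit, rec, diffusion, ctx, n_draws = mc_draws,
                              seed = mc_seed + i)
      ms <- fit@mc_sigmas
      for (nm in intersect(names(err), names(ms))) err[nm] <- ms[nm]
    }
    p <- fit@params
    data.frame(residue = rec$residue, model = p@model_id,
               S2 = p@s2, S2_err = err[["s2"]],
               te_ns = p@te * 1e9, te_err = err[["te_ns"]],
               rex = p@rex, rex_err = err[["rex"]],
               chi2 = fit@chi2, status = fit@status)
  })
  out <- do.call(rbind, rows)
  attr(out, "diffusion") <- diffusion
  out
}
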