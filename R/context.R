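#' Create a spectrometer context
#'
#' The context fixes the interaction constants of backbone amide 15N
#' relaxation: the dipolar coupling \eqn{d = \mu_0 h \gamma_H \gamma_N /
#' (8 \pi^2 r_{NH}^3)} and the CSA coupling \eqn{c = \omega_N \Delta\sigma /
#' \sqrt{3}}. Defaults are the community values of the model-free literature:
#' r(N-H) = 1.02 Angstrom, \eqn{\Delta\sigma} = -160 ppm, \eqn{\gamma_H/\gamma_N}
#' = -9.8656, and "600 MHz" read as a 600.13 MHz proton frequency.
#'
#' @param proton_frequency_mhz 1H Larmor frequency, MHz.
#' @param r_nh_angstrom N-H bond length, Angstrom.
#' @param csa_ppm 15N chemical-shift anisotropy, ppm.
#' @param gamma_ratio signed gamma_H/gamma_N.
#' @return A [SpectrometerContext-class] object.
#' @examples
#' ctx <- spectrometerContext(600.13)
#' omegaN(ctx) / (2 * pi) / 1e6   # 15N Larmor frequency in MHz
#' @export
spectrometerContext <- function(proton_frequency_mhz = 600.13,
                                r_nh_angstrom = 1.02,
                                csa_ppm = -160,
                                gamma_ratio = -9.8656) {
  new("SpectrometerContext",
      proton_frequency = proton_frequency_mhz,
      nh_bond_length = r_nh_angstrom,
      csa_delta = csa_ppm,
      gyromagnetic_ratio_ratio = gamma_ratio)
}

#' Read a spectrometer context from a JSON or YAML-like config list
#'
#' Accepts a named list (e.g. parsed from JSON) with keys
#' `proton_frequency_mhz`, `r_nh_angstrom`, `csa_ppm`, `gamma_ratio`;
#' missing keys take the standard defaults.
#'
#' @param config named list of configuration values.
#' @return A [SpectrometerContext-class].
#' @export
contextFromConfig <- function(config) {
  stopifnot(is.list(config))
  get <- function(key, default) if (!is.null(config[[key]])) config[[key]] else default
  spectrometerContext(
    proton_frequency_mhz = get("proton_frequency_mhz", 600.13),
    r_nh_angstrom = get("r_nh_angstrom", 1.02),
    csa_ppm = get("csa_ppm", -160),
    gamma_ratio = get("gamma_ratio", -9.8656))
}

#' @rdname spectrometerContext
#' @param object,context a [SpectrometerContext-class].
#' @export
omegaH <- function(context) 2 * pi * context@proton_frequency * 1e6

#' @rdname spectrometerContext
#' @export
omegaN <- function(context) omegaH(context) / abs(context@gyromagnetic_ratio_ratio)

#' Dipolar and CSA interaction magnitudes
#'
#' Returns the squared interaction constants d^2 (dipolar) and c^2 (CSA),
#' in (rad/s)^2, entering the standard R1/R2/NOE expressions.
#'
#' @param context a [SpectrometerContext-class].
#' @return named numeric vector `c(d2 = ..., c2 = ...)`.
#' @export
interactionConstants <- function(context) {
  hbar <- .constants$h / (2 * pi)
  gh <- .constants$gamma_h
  gn <- gh / context@gyromagnetic_ratio_ratio
  r <- context@nh_bond_length * 1e-10
  d <- .constants$mu0 * hbar * gh * abs(gn) / (4 * pi * r^3)
  c_ <- omegaN(context) * abs(context@csa_delta) * 1e-6 / sqrt(3)
  c(d2 = d * d, c2 = c_ * c_)
}

setMethod("show", "SpectrometerContext", function(object) {
  cat("SpectrometerContext\n")
  cat(sprintf("  1H frequency : %.2f MHz (omega_H = %.4e rad/s)\n",
              object@proton_frequency, omegaH(object)))
  cat(sprintf("  15N frequency: %.2f MHz\n", omegaN(object) / (2 * pi) / 1e6))
  cat(sprintf("  r(N-H) = %.3f A, CSA = %.1f ppm, gammaH/gammaN = %.4f\n",
              object@nh_bond_length, object@csa_delta,
              object@gyromagnetic_ratio_ratio))
})

#' Create a rotational diffusion model
#'
#' @param tm_ns overall rotational correlation time, nanoseconds.
#' @param kind "isotropic" or "axially_symmetric".
#' @param anisotropy_ratio D_parallel/D_perpendicular (axial only).
#' @param nh_axis_angle_deg angle between the N-H bond vector and the unique
#'   diffusion axis, degrees (axial only).
#' @return A [DiffusionModel-class].
#' @examples
#' diffusionModel(6.38)
#' @export
diffusionModel <- function(tm_ns, kind = c("isotropic", "axially_symmetric"),
                           anisotropy_ratio = NA_real_,
                           nh_axis_angle_deg = NA_real_) {
  kind <- match.arg(kind)
  new("DiffusionModel", kind = kind, tm = tm_ns * 1e-9,
      anisotropy_ratio = if (kind == "isotropic") 1 else anisotropy_ratio,
      nh_axis_angle = nh_axis_angle_deg)
}

#' @export
tauM <- function(diffusion) diffusion@tm

setMethod("show", "DiffusionModel", function(object) {
  cat(sprintf("DiffusionModel (%s): tau_m = %.3f ns", object@kind,
              object@tm * 1e9))
  if (object@kind == "axially_symmetric")
    cat(sprintf(", D_par/D_perp = %.3f, NH angle = %s deg",
                object@anisotropy_ratio,
                format(object@nh_axis_angle)))
  cat("\n")
})

#' Create a model-free dynamics parameter set
#'
#' @param model_id model-free model, 1-5 (m1 S2; m2 S2+tau_e; m3 S2+Rex;
#'   m4 S2+tau_e+Rex; m5 S2f+S2s+tau_e).
#' @param s2 generalized order parameter squared (for model 5 this is derived
#'   as s2f*s2s and must not be supplied).
#' @param te_ns effective internal correlation time, nanoseconds.
#' @param rex conformational exchange broadening, s^-1.
#' @param s2f,s2s fast/slow order parameters (model 5 only).
#' @return A [DynamicsParams-class].
#' @examples
#' dynamicsParams(2, s2 = 0.53, te_ns = 1.04)
#' @export
dynamicsParams <- function(model_id, s2 = NA_real_, te_ns = 0, rex = 0,
                           s2f = NA_real_, s2s = NA_real_) {
  model_id <- as.integer(model_id)
  if (model_id == 5L) {
    if (is.na(s2f) || is.na(s2s))
      stop("model 5 requires s2f and s2s")
    s2 <- s2f * s2s
  } else {
    if (is.na(s2)) stop("s2 is required for models 1-4")
    s2f <- 1
    s2s <- s2
  }
  new("DynamicsParams", model_id = model_id, s2 = s2, te = te_ns * 1e-9,
      rex = rex, s2f = s2f, s2s = s2s)
}

#' @export
orderParameter <- function(params) params@s2

#' @export
tauE <- function(params) params@te

#' @export
rexValue <- function(params) params@rex

setMethod("show", "DynamicsParams", function(object) {
  cat(sprintf("DynamicsParams (model %d): S2 = %.3f, tau_e = %.3f ns, Rex = %.2f s^-1",
              object@model_id, object@s2, object@te * 1e9, object@rex))
  if (object@model_id == 5L)
    cat(sprintf(" (S2f = %.3f, S2s = %.3f)", object@s2f, object@s2s))
  cat("\n")
})

setMethod("show", "ModelFit", function(object) {
  cat(sprintf("ModelFit residue %d [%s]: model %d, chi2 = %.4g (dof %d)\n",
              object@residue_id, object@status, object@params@model_id,
              object@chi2, object@dof))
  show(object@params)
  if (length(object@mc_sigmas))
    cat("  MC sigmas:", paste(names(object@mc_sigmas),
                              signif(object@mc_sigmas, 3),
                              sep = "=", collapse = ", "), "\n")
})

#' @export
fittedParams <- function(fit) fit@params

#' @export
fitChi2 <- function(fit) fit@chi2

#' @export
fitStatus <- function(fit) fit@status
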