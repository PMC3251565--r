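#' @import methods
NULL

# Physical constants used to build the dipolar and CSA interaction strengths.
# gamma_h is the 1H gyromagnetic ratio (rad s^-1 T^-1); mu0 and h are exact SI.
.constants <- list(
  mu0     = 4e-7 * pi,
  h       = 6.62607015e-34,
  gamma_h = 2.6752218744e8
)

#' Spectrometer context for 15N relaxation calculations
#'
#' Holds the static-field and interaction parameters from which the dipolar
#' (\eqn{d^2}) and chemical-shift-anisotropy (\eqn{c^2}) interaction
#' magnitudes, and the angular frequencies \eqn{\omega_H}, \eqn{\omega_N},
#' \eqn{\omega_H \pm \omega_N}, are derived. All internal computation is in SI
#' units (s, rad/s); the constructor takes the conventional spectroscopist
#' units (MHz, Angstrom, ppm).
#'
#' @slot proton_frequency 1H Larmor frequency in MHz.
#' @slot nh_bond_length N-H bond length in Angstrom.
#' @slot csa_delta 15N chemical-shift anisotropy \eqn{\Delta\sigma} in ppm
#'   (conventionally negative for backbone amides).
#' @slot gyromagnetic_ratio_ratio signed ratio \eqn{\gamma_H/\gamma_N}
#'   (negative, since \eqn{\gamma_N < 0}).
#' @export
setClass("SpectrometerContext", representation(
  proton_frequency         = "numeric",
  nh_bond_length           = "numeric",
  csa_delta                = "numeric",
  gyromagnetic_ratio_ratio = "numeric"
))

setValidity("SpectrometerContext", function(object) {
  msg <- character()
  if (!is.finite(object@proton_frequency) || object@proton_frequency <= 0)
    msg <- c(msg, "proton_frequency must be a positive finite number (MHz)")
  if (!is.finite(object@nh_bond_length) || object@nh_bond_length <= 0)
    msg <- c(msg, "nh_bond_length must be a positive finite number (Angstrom)")
  if (!is.finite(object@csa_delta))
    msg <- c(msg, "csa_delta must be finite (ppm)")
  if (!is.finite(object@gyromagnetic_ratio_ratio) ||
      abs(object@gyromagnetic_ratio_ratio) <= 1)
    msg <- c(msg, "|gamma_H/gamma_N| must exceed 1")
  if (length(msg)) msg else TRUE
})

#' Rotational diffusion model
#'
#' Describes the overall tumbling of the molecule: either isotropic (a single
#' correlation time tau_m) or axially symmetric (tau_m plus the anisotropy
#' D_parallel/D_perpendicular and, per residue, the angle between the N-H bond
#' vector and the unique diffusion axis).
#'
#' @slot kind "isotropic" or "axially_symmetric".
#' @slot tm overall rotational correlation time, seconds.
#' @slot anisotropy_ratio D_parallel / D_perpendicular (axial only).
#' @slot nh_axis_angle angle between the N-H vector and the symmetry axis,
#'   degrees (axial only; NA when unset).
#' @export
setClass("DiffusionModel", representation(
  kind             = "character",
  tm               = "numeric",
  anisotropy_ratio = "numeric",
  nh_axis_angle    = "numeric"
))

setValidity("DiffusionModel", function(object) {
  msg <- character()
  if (!object@kind %in% c("isotropic", "axially_symmetric"))
    msg <- c(msg, "kind must be 'isotropic' or 'axially_symmetric'")
  if (!is.finite(object@tm) || object@tm <= 0)
    msg <- c(msg, "tm must be a positive finite time in seconds")
  if (object@kind == "axially_symmetric" &&
      (!is.finite(object@anisotropy_ratio) || object@anisotropy_ratio <= 0))
    msg <- c(msg, "anisotropy_ratio must be positive for the axial model")
  if (length(msg)) msg else TRUE
})

#' Lipari-Szabo model-free parameter set
#'
#' One residue's internal-motion parameters under one of the five standard
#' model-free models: m1 \{S2\}, m2 \{S2, tau_e\}, m3 \{S2, Rex\},
#' m4 \{S2, tau_e, Rex\}, m5 \{S2f, S2s, tau_e\}. For model 5 the generalized
#' order parameter is the product S2 = S2f * S2s; for models 1-4 the fast
#' order parameter S2f is 1.
#'
#' @slot model_id integer 1-5.
#' @slot s2 generalized order parameter squared, in [0, 1].
#' @slot te effective internal correlation time, seconds (0 in models 1, 3).
#' @slot rex conformational exchange broadening, s^-1, additive to R2
#'   (0 in models 1, 2, 5).
#' @slot s2f,s2s fast/slow order parameters (model 5; otherwise s2f = 1,
#'   s2s = s2).
#' @export
setClass("DynamicsParams", representation(
  model_id = "integer",
  s2       = "numeric",
  te       = "numeric",
  rex      = "numeric",
  s2f      = "numeric",
  s2s      = "numeric"
))

setValidity("DynamicsParams", function(object) {
  msg <- character()
  m <- object@model_id
  if (!m %in% 1:5) msg <- c(msg, "model_id must be in 1..5")
  bad <- function(x) !is.finite(x)
  if (bad(object@s2) || object@s2 < 0 || object@s2 > 1)
    msg <- c(msg, "s2 must lie in [0, 1]")
  if (bad(object@te) || object@te < 0) msg <- c(msg, "te must be >= 0 seconds")
  if (bad(object@rex) || object@rex < 0) msg <- c(msg, "rex must be >= 0 s^-1")
  if (length(m) == 1 && m %in% c(1L, 3L) && object@te != 0)
    msg <- c(msg, "models 1 and 3 fix te = 0")
  if (length(m) == 1 && m %in% c(1L, 2L, 5L) && object@rex != 0)
    msg <- c(msg, "models 1, 2 and 5 fix rex = 0")
  if (length(m) == 1 && m == 5L) {
    if (bad(object@s2f) || object@s2f < 0 || object@s2f > 1 ||
        bad(object@s2s) || object@s2s < 0 || object@s2s > 1)
      msg <- c(msg, "s2f and s2s must lie in [0, 1]")
    else if (abs(object@s2 - object@s2f * object@s2s) > 1e-8)
      msg <- c(msg, "model 5 requires s2 = s2f * s2s")
  }
  if (length(msg)) msg else TRUE
})

#' Result of fitting one model-free model to one residue
#'
#' @slot residue_id integer residue number.
#' @slot params fitted [DynamicsParams-class].
#' @slot chi2 chi-square of the fit.
#' @slot dof residual degrees of freedom (observables minus parameters).
#' @slot mc_sigmas named numeric vector of Monte Carlo parameter
#'   uncertainties (empty until [monteCarloErrors()] is run).
#' @slot status "converged", "boundary" (a parameter sits at a bound) or
#'   "failed".
#' @export
setClass("ModelFit", representation(
  residue_id = "integer",
  params     = "DynamicsParams",
  chi2       = "numeric",
  dof        = "integer",
  mc_sigmas  = "numeric",
  status     = "character"
))

setValidity("ModelFit", function(object) {
  msg <- character()
  if (object@status != "failed" && (!is.finite(object@chi2) || object@chi2 < -1e-9))
    msg <- c(msg, "chi2 must be non-negative")
  if (!object@status %in% c("converged", "boundary", "failed"))
    msg <- c(msg, "status must be converged, boundary or failed")
  if (length(msg)) msg else TRUE
})

#' Ground-truth dynamics profile for the synthetic-data generator
#'
#' Per-residue true model-free parameters plus the diffusion model used to
#' generate synthetic relaxation data, with region annotations
#' (core/loop/terminus) and the proline positions that carry no backbone
#' amide and are therefore withheld from observable output.
#'
#' @slot residues data.frame with columns residue, residue_name, region,
#'   model, s2, s2f, s2s, te, rex (times in seconds).
#' @slot diffusion the [DiffusionModel-class] of the overall tumbling.
#' @slot proline_positions integer positions excluded from observables.
#' @slot preset name of the generating preset.
#' @slot seed integer seed the profile was drawn with.
#' @export
setClass("GroundTruthProfile", representation(
  residues          = "data.frame",
  diffusion         = "DiffusionModel",
  proline_positions = "integer",
  preset            = "character",
  seed              = "integer"
))

setValidity("GroundTruthProfile", function(object) {
  df <- object@residues
  need <- c("residue", "residue_name", "region", "model", "s2", "s2f", "s2s",
            "te", "rex")
  msg <- character()
  if (!all(need %in% names(df)))
    msg <- c(msg, paste("residues must have columns:", paste(need, collapse = ", ")))
  else {
    if (any(df$s2 < 0 | df$s2 > 1)) msg <- c(msg, "all s2 must lie in [0, 1]")
    if (any(df$te < 0) || any(df$rex < 0))
      msg <- c(msg, "te and rex must be non-negative")
    core <- df$region == "core"
    if (any(core) && any(df$s2[core] < 0.7))
      msg <- c(msg, "core residues must have s2 >= 0.7")
  }
  if (length(msg)) msg else TRUE
})
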