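#' Lipari-Szabo spectral density function
#'
#' Evaluates the extended model-free spectral density for isotropic overall
#' tumbling,
#' \deqn{J(\omega) = \frac{2}{5}\left[\frac{S^2 \tau_m}{1+(\omega\tau_m)^2} +
#'   \frac{(S_f^2 - S^2)\,\tau'}{1+(\omega\tau')^2}\right],\qquad
#'   \frac{1}{\tau'} = \frac{1}{\tau_m} + \frac{1}{\tau_e},}
#' the simple (single-timescale) form being the \eqn{S_f^2 = 1} case. When
#' the diffusion model is axially symmetric, dispatches to
#' [spectralDensityAxial()].
#'
#' @param omega angular frequency, rad/s (vectorized; must be >= 0).
#' @param diffusion a [DiffusionModel-class].
#' @param params a [DynamicsParams-class].
#' @return spectral density J(omega) in s/rad, same length as `omega`.
#' @examples
#' d <- diffusionModel(6.38)
#' p <- dynamicsParams(1, s2 = 1)
#' spectralDensity(0, d, p)   # rigid-body limit 0.4 * tau_m
#' @export
spectralDensity <- function(omega, diffusion, params) {
  stopifnot(is(diffusion, "DiffusionModel"), is(params, "DynamicsParams"))
  validObject(params)
  if (any(!is.finite(omega)) || any(omega < 0))
    stop("omega must be finite and non-negative (rad/s)")
  if (diffusion@kind == "axially_symmetric")
    return(spectralDensityAxial(omega, diffusion, params))
  .jiso(omega, diffusion@tm, params@s2, params@te, params@s2f)
}

# scalar-core isotropic J; vectorized over omega
.jiso <- function(omega, tm, s2, te, s2f = 1) {
  j <- s2 * tm / (1 + (omega * tm)^2)
  # internal-motion term vanishes when te = 0 or the motional amplitude
  # (s2f - s2) is zero; guard avoids 0/0 in tau'
  if (te > 0 && abs(s2f - s2) > 0) {
    tp <- tm * te / (tm + te)
    j <- j + (s2f - s2) * tp / (1 + (omega * tp)^2)
  }
  0.4 * j
}

#' Spectral density under axially symmetric rotational diffusion
#'
#' Three-Lorentzian extension of the model-free spectral density for a
#' molecule tumbling as an axially symmetric rotor. The three correlation
#' times derive from \eqn{D_\parallel} and \eqn{D_\perp} (with
#' \eqn{\tau_m = 1/(6 D_{iso})}, \eqn{D_{iso} = (D_\parallel + 2D_\perp)/3}),
#' and the amplitudes from the angle \eqn{\theta} between the N-H bond vector
#' and the unique axis:
#' \eqn{A_1 = ((3\cos^2\theta - 1)/2)^2}, \eqn{A_2 = 3\sin^2\theta\cos^2\theta},
#' \eqn{A_3 = (3/4)\sin^4\theta}, which sum to 1. Reduces exactly to the
#' isotropic form when the anisotropy ratio is 1.
#'
#' @inheritParams spectralDensity
#' @return J(omega) in s/rad.
#' @export
spectralDensityAxial <- function(omega, diffusion, params) {
  stopifnot(is(diffusion, "DiffusionModel"), is(params, "DynamicsParams"))
  if (any(!is.finite(omega)) || any(omega < 0))
    stop("omega must be finite and non-negative (rad/s)")
  if (!is.finite(diffusion@anisotropy_ratio))
    stop("axial model requires anisotropy_ratio")
  if (!is.finite(diffusion@nh_axis_angle))
    stop("axial spectral density requires N-H bond orientations (nh_axis_angle)")
  rho <- diffusion@anisotropy_ratio
  diso <- 1 / (6 * diffusion@tm)
  dperp <- 3 * diso / (2 + rho)
  dpar <- rho * dperp
  taus <- c(1 / (6 * dperp), 1 / (5 * dperp + dpar), 1 / (2 * dperp + 4 * dpar))
  th <- diffusion@nh_axis_angle * pi / 180
  ct2 <- cos(th)^2
  st2 <- 1 - ct2
  amps <- c(((3 * ct2 - 1) / 2)^2, 3 * st2 * ct2, 0.75 * st2^2)
  s2 <- params@s2
  s2f <- params@s2f
  te <- params@te
  j <- 0
  for (k in 1:3) {
    tk <- taus[k]
    term <- s2 * tk / (1 + (omega * tk)^2)
    if (te > 0 && abs(s2f - s2) > 0) {
      tpk <- tk * te / (tk + te)
      term <- term + (s2f - s2) * tpk / (1 + (omega * tpk)^2)
    }
    j <- j + amps[k] * term
  }
  0.4 * j
}

#' Orientation amplitudes of the axially symmetric spectral density
#'
#' @param angle_deg angle between the N-H vector and the unique axis, degrees.
#' @return numeric(3) amplitudes summing to 1.
#' @export
axialAmplitudes <- function(angle_deg) {
  th <- angle_deg * pi / 180
  ct2 <- cos(th)^2
  st2 <- 1 - ct2
  c(((3 * ct2 - 1) / 2)^2, 3 * st2 * ct2, 0.75 * st2^2)
}

#' Predict R1, R2 and the heteronuclear NOE from dynamics parameters
#'
#' Standard dipolar + CSA expressions of the model-free literature:
#' \deqn{R_1 = \frac{d^2}{4}[J(\omega_H-\omega_N) + 3J(\omega_N) +
#'   6J(\omega_H+\omega_N)] + c^2 J(\omega_N)}
#' \deqn{R_2 = \frac{d^2}{8}[4J(0) + J(\omega_H-\omega_N) + 3J(\omega_N) +
#'   6J(\omega_H) + 6J(\omega_H+\omega_N)] + \frac{c^2}{6}[4J(0) +
#'   3J(\omega_N)] + R_{ex}}
#' \deqn{NOE = 1 + \frac{d^2}{4}\frac{\gamma_H}{\gamma_N}\frac{1}{R_1}
#'   [6J(\omega_H+\omega_N) - J(\omega_H-\omega_N)]}
#' with \eqn{d = \mu_0 h \gamma_H\gamma_N/(8\pi^2 r_{NH}^3)} and
#' \eqn{c = \omega_N \Delta\sigma/\sqrt{3}}. The exchange term enters R2
#' only, additively.
#'
#' @param params a [DynamicsParams-class].
#' @param diffusion a [DiffusionModel-class].
#' @param context a [SpectrometerContext-class].
#' @return named numeric vector `c(R1 = , R2 = , NOE = )`, rates in s^-1.
#' @examples
#' ctx <- spectrometerContext(600.13)
#' predictRates(dynamicsParams(2, s2 = 0.53, te_ns = 1.04),
#'              diffusionModel(6.38), ctx)
#' @export
predictRates <- function(params, diffusion, context) {
  stopifnot(is(context, "SpectrometerContext"))
  validObject(context)
  validObject(params)
  validObject(diffusion)
  wh <- omegaH(context)
  wn <- omegaN(context)
  ic <- interactionConstants(context)
  jj <- spectralDensity(c(0, wn, wh - wn, wh, wh + wn), diffusion, params)
  j0 <- jj[1]; jn <- jj[2]; jhmn <- jj[3]; jh <- jj[4]; jhpn <- jj[5]
  d2 <- ic[["d2"]]; c2 <- ic[["c2"]]
  r1 <- d2 / 4 * (jhmn + 3 * jn + 6 * jhpn) + c2 * jn
  r2 <- d2 / 8 * (4 * j0 + jhmn + 3 * jn + 6 * jh + 6 * jhpn) +
    c2 / 6 * (4 * j0 + 3 * jn) + params@rex
  noe <- 1 + d2 / 4 * context@gyromagnetic_ratio_ratio / r1 *
    (6 * jhpn - jhmn)
  c(R1 = unname(r1), R2 = unname(r2), NOE = unname(noe))
}
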