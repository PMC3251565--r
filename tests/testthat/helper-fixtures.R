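# Shared fixtures: the standard 600-MHz context, the tau_m = 6.38 ns
# isotropic diffusion model, and the printed 600-MHz per-residue relaxation
# values for the wild-type and P48A RGD-loop residues.

ctx600 <- spectrometerContext(600.13)
dm638 <- diffusionModel(6.38)

makeRecord <- function(residue, r1, r1e, r2, r2e, noe, noee) {
  relaxationRecords(data.frame(residue = residue, R1 = r1, R1_err = r1e,
                               R2 = r2, R2_err = r2e, NOE = noe,
                               NOE_err = noee))
}

# published 600-MHz relaxation values for the RGD residues of the two
# variants (uncertainty floor applied by relaxationRecords)
loopRecords <- function(variant = c("wt", "p48a")) {
  variant <- match.arg(variant)
  if (variant == "wt")
    relaxationRecords(data.frame(
      residue = c(49, 50, 51),
      R1 = c(1.69, 1.55, 1.72), R1_err = c(0.08, 0.02, 0.03),
      R2 = c(8.32, 5.09, 10.03), R2_err = c(0.13, 0.03, 0.02),
      NOE = c(0.48, 0.32, 0.50), NOE_err = c(0.01, 0.02, 0.02)))
  else
    relaxationRecords(data.frame(
      residue = c(49, 50, 51),
      R1 = c(1.63, 1.51, 1.68), R1_err = c(0.04, 0.02, 0.02),
      R2 = c(5.98, 4.90, 6.50), R2_err = c(0.01, 0.01, 0.02),
      NOE = c(0.42, 0.28, 0.47), NOE_err = c(0.01, 0.01, 0.02)))
}

# record with observables forward-computed from known parameters
syntheticRecord <- function(s2, te_ns, rex = 0, residue = 1,
                            diffusion = dm638, context = ctx600,
                            rel_err = 0.005) {
  r <- predictRates(dynamicsParams(if (rex > 0 && te_ns > 0) 4
                                   else if (rex > 0) 3
                                   else if (te_ns > 0) 2 else 1,
                                   s2 = s2, te_ns = te_ns, rex = rex),
                    diffusion, context)
  makeRecord(residue, r[["R1"]], rel_err * r[["R1"]],
             r[["R2"]], rel_err * r[["R2"]],
             r[["NOE"]], rel_err * abs(r[["NOE"]]))
}

# total spectral power of J(omega) over [0, Inf), by quadrature under the
# substitution omega = s * x / (1 - x) (s ~ 1/tau_m scales the Lorentzian
# widths into the unit interval); independent of the closed-form integral
spectralPower <- function(diffusion, params) {
  s <- 1 / tauM(diffusion)
  stats::integrate(function(x) {
    x <- pmin(x, 1 - 1e-9)
    spectralDensity(s * x / (1 - x), diffusion, params) * s / (1 - x)^2
  }, 0, 1, rel.tol = 1e-10, subdivisions = 1000L)$value
}
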