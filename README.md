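# spinrelax

Model-free analysis of protein backbone dynamics from heteronuclear ¹⁵N NMR
relaxation data, built for comparing the internal motions of two protein
variants residue by residue — the typical question being whether a point
mutation changes what a functional loop *does* (its motions) rather than
what it *looks like* (its structure). The motivating system is a small
disulfide-bonded disintegrin whose integrin-binding RGD loop changes its
ps–ns flexibility and µs–ms exchange behaviour upon mutation of the residue
preceding the RGD motif, while the mean structure stays put.

The package covers the full analysis chain:

1. **Rate estimation** — monoexponential fits `I(t) = I₀·e^(−R·t)` of
   peak-height decay series for R₁ and R₂ (Levenberg–Marquardt on the
   untransformed heights, log-linear initialization, replicate averaging),
   and steady-state ¹H-¹⁵N NOEs as ratios of saturated/reference peak
   heights averaged over experiment pairs.
2. **Model-free inference** — per-residue Lipari–Szabo parameters from
   (R₁, R₂, NOE) by χ² minimization. The spectral density is the extended
   isotropic form

   ```
   J(ω) = (2/5) [ S²·τm / (1 + (ωτm)²) + (Sf² − S²)·τ′ / (1 + (ωτ′)²) ],
   1/τ′ = 1/τm + 1/τe
   ```

   mapped to observables through the standard dipolar + CSA expressions
   (d² and c² built from r(N–H) = 1.02 Å, Δσ = −160 ppm, γH/γN = −9.8656 by
   default, all configurable). Five models are fitted — m1 {S²},
   m2 {S², τe}, m3 {S², Rex}, m4 {S², τe, Rex}, m5 {Sf², Ss², τe} — and
   chosen by the standard stepwise rule: χ² goodness-of-fit at the 90%
   level (Monte Carlo critical values), F-tests at the 80% level for added
   parameters. The overall correlation time τm is optimized on a rigid core
   subset (NOE > 0.65, no exchange flag) by grid search plus golden-section
   refinement, with per-residue model re-selection at each candidate τm.
   Parameter uncertainties come from Monte Carlo resampling of the
   back-calculated rates. An axially symmetric diffusion variant
   (D∥/D⊥, per-residue N–H axis angles) is available alongside the
   isotropic model.
3. **Comparison reporting** — percent differences, fold ratios and τe
   flexibility bands (fast ≤ 50 ps < intermediate ≤ 500 ps < slow) between
   two variants, plus composite amide chemical-shift perturbations
   √(ΔδH² + (ΔδN/5)²).
4. **Synthetic data** — a generator emulating a 68-residue disintegrin
   tumbling at τm = 6.38 ns with a rigid disulfide-bonded core, a flexible
   RGD loop, proline gaps, two replicate decay series per rate, three NOE
   pairs and multiplicative peak-height noise, so the entire pipeline is
   testable against known ground truth.

## Worked example

Fit the two-parameter model to a published 600-MHz relaxation triplet of
the mutant's R49 (R₁ = 1.63 s⁻¹, R₂ = 5.98 s⁻¹, NOE = 0.42) at
τm = 6.38 ns:

```r
library(spinrelax)
ctx <- spectrometerContext(600.13)
dm  <- diffusionModel(6.38)
rec <- relaxationRecords(data.frame(residue = 49,
  R1 = 1.63, R1_err = 0.04, R2 = 5.98, R2_err = 0.01,
  NOE = 0.42, NOE_err = 0.01))
fit <- fitModel(rec[1, ], 2, dm, ctx)
fit <- monteCarloErrors(fit, rec[1, ], dm, ctx, n_draws = 500, seed = 1)
show(fit)
#> ModelFit residue 49 [converged]: model 2, chi2 = 6.878 (dof 1)
#> DynamicsParams (model 2): S2 = 0.530, tau_e = 0.682 ns, Rex = 0.00 s^-1
#>   MC sigmas: s2=0.00461, te_ns=0.018
```

The fitted order parameter S² = 0.530 says the R49 amide N–H vector is
substantially disordered on the ps–ns timescale (S² = 1 would be rigid);
χ² = 6.9 on 1 degree of freedom signals that two parameters do not fully
absorb the triplet, which is why stepwise selection promotes such residues
to a three-parameter model.

Comparing the two variants' loop dynamics from their per-residue tables:

```r
wt  <- data.frame(residue = 49:51, R2 = c(8.32, 5.09, 10.03),
                  S2 = c(0.75, 0.50, 0.85), te_ns = c(0.11, 0.84, 0.19))
mut <- data.frame(residue = 49:51, R2 = c(5.98, 4.90, 6.50),
                  S2 = c(0.53, 0.43, 0.61), te_ns = c(1.04, 0.93, 0.98))
cat(renderComparisonReport(buildComparisonTable(wt, mut, "Rho", "P48A")),
    sep = "\n")
#> Dynamics comparison: Rho (A) vs P48A (B)
#> residue  qty             A          B   A>B(%)   B<A(%)   fold
#> 49       R2           8.32       5.98       39       28    1.4
#> 49       S2           0.75       0.53       42       29    1.4
#> 49       te_ns        0.11       1.04      -89     -845    9.5
#> 50       R2           5.09        4.9        4        4    1.0
#> 50       S2            0.5       0.43       16       14    1.2
#> 50       te_ns        0.84       0.93      -10      -11    1.1
#> 51       R2          10.03        6.5       54       35    1.5
#> 51       S2           0.85       0.61       39       28    1.4
#> 51       te_ns        0.19       0.98      -81     -416    5.2
```

Reading the table: wild-type R₂ is 39% and 54% higher at R49/D51, mutant
S² is 29% and 28% lower relative to wild type, and the internal correlation
times differ 9.5- and 5.2-fold — the mutation trades exchange broadening
for slower, larger-amplitude loop motion.

A complete simulate → rates → modelfree → compare pipeline is available
through `runPipeline()` or the thin command-line wrapper
`inst/cli/nmrdyn.R` (subcommands `simulate`, `rates`, `modelfree`,
`compare`, `config show`; every output directory carries a JSON manifest
with the merged configuration, input digests and seed).

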