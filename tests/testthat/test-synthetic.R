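test_that("presets encode the intended ground truth", {
  rigid <- profileResidues(makeProfile("rigid", seed = 1))
  expect_true(all(rigid$s2 == 0.85 & rigid$te == 0 & rigid$rex == 0))

  p48a <- profileResidues(makeProfile("p48a_like", seed = 1))
  r49 <- p48a[p48a$residue == 49, ]
  expect_equal(r49$s2, 0.53)
  expect_equal(r49$te * 1e9, 1.04)
  expect_equal(r49$rex, 0)

  wt <- makeProfile("rho_like", seed = 1)
  r49wt <- profileResidues(wt)[49, ]
  expect_equal(unlist(r49wt[c("s2", "rex")], use.names = FALSE), c(0.75, 0.91))
  # core invariant
  core <- profileResidues(wt)$region == "core"
  expect_true(all(profileResidues(wt)$s2[core] >= 0.7))
})

test_that("profiles are deterministic in the seed", {
  p1 <- makeProfile("rho_like", seed = 42)
  p2 <- makeProfile("rho_like", seed = 42)
  expect_identical(profileResidues(p1), profileResidues(p2))
  p3 <- makeProfile("rho_like", seed = 43)
  expect_false(identical(profileResidues(p1), profileResidues(p3)))
})

test_that("prolines are generated but withheld from observables", {
  wt <- makeProfile("rho_like", seed = 1)
  expect_setequal(wt@proline_positions, c(48L, 53L))
  expect_true(all(c(48, 53) %in% profileResidues(wt)$residue))
  obs <- observableResidues(wt)
  expect_false(any(c(48, 53) %in% obs$residue))
  recs <- simulateRates(wt, ctx600)
  expect_false(48 %in% recs$residue)

  p48a <- makeProfile("p48a_like", seed = 1)
  expect_true(48 %in% observableResidues(p48a)$residue)
})

test_that("profile overrides are applied and validated", {
  ov <- data.frame(residue = 10, s2 = 0.33, te_ns = 0.7, rex = 2)
  prof <- makeProfile("rigid", seed = 1, overrides = ov)
  row <- profileResidues(prof)[10, ]
  expect_equal(unlist(row[c("s2", "rex")], use.names = FALSE), c(0.33, 2))
  bad <- data.frame(residue = 10, s2 = 1.4, te_ns = 0, rex = 0)
  expect_error(makeProfile("rigid", seed = 1, overrides = bad), "invariants")
})

test_that("noiseless rates: homogeneity and mutant loop consistency", {
  rigid <- makeProfile("rigid", seed = 1)
  recs <- simulateRates(rigid, ctx600)
  expect_lt(max(recs$R1) - min(recs$R1), 1e-12)
  expect_lt(max(recs$R2) - min(recs$R2), 1e-12)
  expect_lt(max(recs$NOE) - min(recs$NOE), 1e-12)

  p48a <- simulateRates(makeProfile("p48a_like", seed = 1), ctx600)
  r49 <- p48a[p48a$residue == 49, ]
  # forward-computed observables sit in the physically expected window
  # around the published row (1.63, 5.98, 0.42); agreement is qualitative
  # because the published parameters carry their own fit/rounding error
  expect_equal(r49$R1, 1.63, tolerance = 0.2)
  expect_equal(r49$R2, 5.98, tolerance = 0.2)
  expect_equal(r49$NOE, 0.42, tolerance = 0.5)
})

test_that("simulated decays validate, reproduce, and round-trip at zero noise", {
  prof <- makeProfile("p48a_like", n_residues = 15, seed = 5)
  sim0 <- simulateDecays(prof, ctx600, noiseModel(height_cv = 0, seed = 5))
  expect_true(validateDecayTable(sim0$decays))
  rates0 <- fitDecayTable(sim0$decays)
  m <- merge(rates0, sim0$rates, by = "residue", suffixes = c("_fit", "_true"))
  expect_equal(m$R1_fit, m$R1_true, tolerance = 1e-7)
  expect_equal(m$R2_fit, m$R2_true, tolerance = 1e-7)
  expect_equal(m$NOE_fit, m$NOE_true, tolerance = 1e-10)

  simA <- simulateDecays(prof, ctx600, noiseModel(seed = 5))
  simB <- simulateDecays(prof, ctx600, noiseModel(seed = 5))
  expect_identical(simA$decays, simB$decays)
  simC <- simulateDecays(prof, ctx600, noiseModel(seed = 6))
  expect_false(identical(simA$decays$height, simC$decays$height))
  expect_identical(dim(simA$decays), dim(simC$decays))
  expect_identical(simA$manifest$run_id, simB$manifest$run_id)
})

test_that("parameter recovery degrades monotonically with height noise", {
  prof <- makeProfile("p48a_like", n_residues = 16, seed = 8)
  truth <- observableResidues(prof)
  med_err <- vapply(c(0.005, 0.02, 0.05), function(cv) {
    errs <- unlist(lapply(c(8, 9), function(sd) {
      sim <- simulateDecays(prof, ctx600, noiseModel(height_cv = cv, seed = sd))
      rates <- suppressWarnings(fitDecayTable(sim$decays))
      recs <- relaxationRecords(rates)
      vapply(seq_len(nrow(truth)), function(i) {
        rec <- recs[recs$residue == truth$residue[i], ]
        fit <- fitModel(rec, truth$model[i], profileDiffusion(prof), ctx600)
        abs(orderParameter(fittedParams(fit)) - truth$s2[i])
      }, numeric(1))
    }))
    median(errs)
  }, numeric(1))
  expect_true(all(diff(med_err) > 0))
})
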