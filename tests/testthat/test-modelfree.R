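test_that("chi-square: perfect fit, scaling law, hand evaluation", {
  p <- dynamicsParams(2, s2 = 0.6, te_ns = 0.4)
  r <- predictRates(p, dm638, ctx600)
  rec <- data.frame(residue = 1, R1 = r[["R1"]], R1_err = 0.02,
                    R2 = r[["R2"]], R2_err = 0.05, NOE = r[["NOE"]],
                    NOE_err = 0.01)
  expect_equal(chiSquare(rec, p, dm638, ctx600), 0, tolerance = 1e-18)

  rec2 <- rec
  rec2$R1 <- rec$R1 + 0.1
  chi <- chiSquare(rec2, p, dm638, ctx600)
  rec2_wide <- rec2
  for (q in c("R1_err", "R2_err", "NOE_err")) rec2_wide[[q]] <- 2 * rec2[[q]]
  expect_equal(chiSquare(rec2_wide, p, dm638, ctx600), chi / 4)

  # hand evaluation against the frozen rigid-rate values
  rigid <- dynamicsParams(1, s2 = 1)
  rec3 <- data.frame(residue = 1, R1 = 2, R1_err = 0.1, R2 = 10, R2_err = 0.1,
                     NOE = 0.8, NOE_err = 0.1)
  expected <- ((1.92533026534585 - 2) / 0.1)^2 +
    ((9.73191138177278 - 10) / 0.1)^2 + ((0.891275372425232 - 0.8) / 0.1)^2
  expect_equal(chiSquare(rec3, rigid, dm638, ctx600), expected,
               tolerance = 1e-8)

  rec_bad <- rec
  rec_bad$R2_err <- 0
  expect_error(chiSquare(rec_bad, p, dm638, ctx600), "positive")
})

test_that("two-parameter fits of the published mutant loop rows recover S2", {
  p48a <- loopRecords("p48a")
  f49 <- fitModel(p48a[p48a$residue == 49, ], 2, dm638, ctx600)
  expect_equal(orderParameter(fittedParams(f49)), 0.53, tolerance = 0.05)
  f51 <- fitModel(p48a[p48a$residue == 51, ], 2, dm638, ctx600)
  expect_equal(orderParameter(fittedParams(f51)), 0.61, tolerance = 0.05)
  expect_true(all(c(fitStatus(f49), fitStatus(f51)) != "failed"))
})

test_that("noiseless three-parameter round trip is exact to tolerance", {
  rec <- syntheticRecord(0.75, 0.11, rex = 0.91)
  fit <- fitModel(rec[1, ], 4, dm638, ctx600)
  p <- fittedParams(fit)
  expect_equal(orderParameter(p), 0.75, tolerance = 1e-4)
  expect_equal(tauE(p) * 1e9, 0.11, tolerance = 1e-3)
  expect_equal(rexValue(p), 0.91, tolerance = 1e-3)
})

test_that("model-2 fit agrees with an exhaustive grid search", {
  recs <- list(loopRecords("p48a")[1, ], loopRecords("p48a")[3, ],
               syntheticRecord(0.66, 0.45))
  s2_grid <- seq(0.005, 1, by = 0.005)
  te_grid <- exp(seq(log(1e-3), log(10), length.out = 240))  # ns, 1 ps-10 ns
  for (rec in recs) {
    chi <- outer(s2_grid, te_grid, Vectorize(function(s2, te) {
      chiSquare(rec, dynamicsParams(2, s2 = s2, te_ns = te), dm638, ctx600)
    }))
    best <- arrayInd(which.min(chi), dim(chi))
    fit <- fitModel(rec, 2, dm638, ctx600)
    p <- fittedParams(fit)
    expect_lte(abs(orderParameter(p) - s2_grid[best[1]]), 0.005 + 1e-9)
    log_step <- diff(log(te_grid))[1]
    expect_lte(abs(log(tauE(p) * 1e9) - log(te_grid[best[2]])),
               log_step + 1e-9)
  }
})

test_that("nested models dominate in chi-square", {
  recs <- rbind(loopRecords("wt"), loopRecords("p48a"))
  recs$residue <- seq_len(nrow(recs))
  set.seed(5)
  extra <- do.call(rbind, lapply(1:4, function(i)
    syntheticRecord(runif(1, 0.4, 0.95), runif(1, 0.01, 1),
                    residue = 100 + i, rel_err = 0.02)))
  recs <- rbind(recs, extra)
  for (i in seq_len(nrow(recs))) {
    chi <- vapply(c(1, 2, 4), function(m)
      fitChi2(fitModel(recs[i, ], m, dm638, ctx600)), numeric(1))
    tol <- 1e-6 * max(chi[1], 1)
    expect_lte(chi[2], chi[1] + tol)
    expect_lte(chi[3], chi[2] + tol)
  }
})

test_that("stepwise selection identifies rigid residues as model 1", {
  cfg <- selectionConfig(gof_method = "chisq")
  truth <- predictRates(dynamicsParams(1, s2 = 0.85), dm638, ctx600)
  picks <- vapply(1:100, function(trial) {
    set.seed(1000 + trial)
    obs <- truth * (1 + rnorm(3, 0, 0.02))
    rec <- makeRecord(1, obs[1], 0.02 * obs[1], obs[2], 0.02 * obs[2],
                      obs[3], 0.02 * abs(obs[3]))
    fittedParams(selectModel(rec[1, ], dm638, ctx600, cfg))@model_id
  }, integer(1))
  expect_gte(mean(picks == 1L), 0.90)
})

test_that("stepwise selection finds exchange when it is present", {
  cfg <- selectionConfig(gof_method = "chisq")
  truth <- predictRates(dynamicsParams(3, s2 = 0.85, rex = 1.4), dm638, ctx600)
  has_rex <- vapply(1:40, function(trial) {
    set.seed(2000 + trial)
    obs <- truth * (1 + rnorm(3, 0, 0.02))
    rec <- makeRecord(1, obs[1], 0.02 * obs[1], obs[2], 0.02 * obs[2],
                      obs[3], 0.02 * abs(obs[3]))
    rexValue(fittedParams(selectModel(rec[1, ], dm638, ctx600, cfg))) > 0
  }, logical(1))
  expect_gt(mean(has_rex), 0.5)
})

test_that("selection on the published mutant rows is tau_e-only", {
  p48a <- loopRecords("p48a")
  for (i in c(1, 3)) {
    fit <- selectModel(p48a[i, ], dm638, ctx600,
                       selectionConfig(n_sims = 200))
    p <- fittedParams(fit)
    expect_gt(tauE(p), 0)
    expect_identical(rexValue(p), 0)
  }
})

test_that("Monte Carlo errors: scale, limit and determinism", {
  p48a <- loopRecords("p48a")
  rec <- p48a[1, ]
  fit <- fitModel(rec, 2, dm638, ctx600)
  fit_mc <- monteCarloErrors(fit, rec, dm638, ctx600, n_draws = 500, seed = 9)
  # S2 uncertainty of the same order as the published +/- 0.02
  expect_gt(fit_mc@mc_sigmas[["s2"]], 0.002)
  expect_lt(fit_mc@mc_sigmas[["s2"]], 0.2)

  fit_mc2 <- monteCarloErrors(fit, rec, dm638, ctx600, n_draws = 500, seed = 9)
  expect_identical(fit_mc@mc_sigmas, fit_mc2@mc_sigmas)

  tiny <- rec
  for (q in c("R1_err", "R2_err", "NOE_err")) tiny[[q]] <- rec[[q]] * 1e-6
  fit_tiny <- monteCarloErrors(fit, tiny, dm638, ctx600, n_draws = 100,
                               seed = 9)
  expect_lt(max(fit_tiny@mc_sigmas), 1e-4)

  failed <- new("ModelFit", residue_id = 1L,
                params = dynamicsParams(1, s2 = 1), chi2 = Inf, dof = 2L,
                mc_sigmas = numeric(), status = "failed")
  expect_error(monteCarloErrors(failed, rec, dm638, ctx600), "failed")
})
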