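test_that("two exact points determine the exponential", {
  f <- fitMonoexponential(c(0.1, 0.5), c(exp(-0.2), exp(-1.0)))
  expect_equal(f$rate, 2.0, tolerance = 1e-12)
  expect_equal(f$amplitude, 1.0, tolerance = 1e-12)
})

test_that("noiseless series on the standard schedules recover their rates", {
  sched <- delaySchedules()
  for (case in list(c(rate = 8.32, exp = "R2"), c(rate = 1.69, exp = "R1"),
                    c(rate = 5.98, exp = "R2"))) {
    rate <- as.numeric(case[["rate"]])
    d <- sched[[case[["exp"]]]]
    f <- fitMonoexponential(d, 1e6 * exp(-rate * d))
    expect_equal(f$rate, rate, tolerance = 1e-8)
  }
})

test_that("fitted rate is invariant to overall intensity scale", {
  set.seed(7)
  d <- delaySchedules()$R1
  for (i in 1:5) {
    h <- exp(-2.5 * d) * (1 + rnorm(length(d), 0, 0.02))
    f1 <- fitMonoexponential(d, h)
    f2 <- fitMonoexponential(d, h * 10^runif(1, -3, 6))
    expect_equal(f1$rate, f2$rate, tolerance = 1e-8)
  }
})

test_that("estimator bias shrinks along a noise ladder", {
  d <- delaySchedules()$R2
  err <- vapply(c(0.05, 0.02, 0.005), function(cv) {
    set.seed(101)
    median(abs(vapply(1:60, function(i) {
      h <- exp(-5.98 * d) * (1 + rnorm(length(d), 0, cv))
      fitMonoexponential(d, h)$rate
    }, numeric(1)) - 5.98))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
})

test_that("degenerate and implausible inputs are flagged", {
  expect_error(fitMonoexponential(c(0.1, 0.2), c(1, 0.9, 0.8)), "delays")
  expect_error(fitMonoexponential(0.1, 1), "3 distinct")
  expect_warning(f <- fitMonoexponential(c(0.1, 0.3, 0.6, 1), c(1, 1.1, 1.2, 1.4)),
                 "does not decay")
  expect_equal(f$status, "non_decaying")
  # delays passed in ms instead of s give an implausibly large rate
  d_ms <- delaySchedules()$R2 * 1000
  expect_warning(fitMonoexponential(d_ms, exp(-5.98 * d_ms / 1000)),
                 "delay units")
})

test_that("replicate aggregation: identity, mean/half-range, mixed residues", {
  e1 <- list(residue_id = 5L, rate = 8.0, sigma = 1e-4, amplitude = 1,
             n_replicates = 1L, replicate_id = 1L, status = "ok")
  expect_identical(aggregateReplicates(list(e1)), e1)
  e2 <- modifyList(e1, list(rate = 8.4, replicate_id = 2L))
  agg <- aggregateReplicates(list(e1, e2))
  expect_equal(agg$rate, 8.2)
  expect_equal(agg$sigma, 0.2)
  expect_equal(agg$n_replicates, 2L)
  e3 <- modifyList(e1, list(residue_id = 6L))
  expect_error(aggregateReplicates(list(e1, e3)), "different residues")
})

test_that("aggregate sigma covers replicate sampling scatter", {
  d <- delaySchedules()$R2
  covered <- vapply(1:40, function(trial) {
    set.seed(300 + trial)
    reps <- lapply(1:2, function(r) {
      h <- exp(-5.98 * d) * (1 + rnorm(length(d), 0, 0.02))
      fitMonoexponential(d, h, residue_id = 1L, replicate_id = r)
    })
    agg <- aggregateReplicates(reps)
    agg$sigma >= max(vapply(reps, function(e) e$sigma, numeric(1))) * 0.5
  }, logical(1))
  expect_gte(mean(covered), 0.95)
})

test_that("NOE ratios: mean, spread and input validation", {
  same <- computeNOE(c(2, 5, 9), c(2, 5, 9))
  expect_equal(same$noe, 1.0)
  expect_equal(same$sigma, 0)
  flat <- computeNOE(0.42 * c(1, 2, 3), c(1, 2, 3))
  expect_equal(flat$noe, 0.42)
  expect_equal(flat$sigma, 0)
  spread <- computeNOE(c(0.40, 0.42, 0.44), c(1, 1, 1))
  expect_equal(spread$noe, 0.42)
  expect_equal(spread$sigma, 0.02)
  expect_equal(spread$n_pairs, 3L)
  expect_error(computeNOE(c(0.4, 0.4), c(1, 0)), "positive")
  expect_error(computeNOE(c(0.4), c(1, 1)), "equal length")
})

test_that("decay-table fitting enforces its schema", {
  expect_error(fitDecayTable(data.frame(residue = 1, height = 1)),
               "experiment.*delay_s|missing required columns")
  bad <- data.frame(residue = 1, experiment = "T1", replicate = 1,
                    delay_s = 0.1, height = 1)
  expect_error(fitDecayTable(bad), "unknown experiment")
})
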