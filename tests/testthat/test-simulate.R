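test_that("simulated trials are pure functions of their arguments", {
  a <- simulate_continuous_trial(50, 60, 0.3, seed = 9)
  b <- simulate_continuous_trial(50, 60, 0.3, seed = 9)
  expect_identical(a, b)
  c <- simulate_continuous_trial(50, 60, 0.3, seed = 10)
  expect_false(identical(a$raw$arm1, c$raw$arm1))

  expect_identical(simulate_binary_trial(100, 100, 0.1, 0.2, seed = 3),
                   simulate_binary_trial(100, 100, 0.1, 0.2, seed = 3))
  expect_identical(
    simulate_recovery_trial(100, 100, 10, 12, 0.5, 40, seed = 3),
    simulate_recovery_trial(100, 100, 10, 12, 0.5, 40, seed = 3))
})

test_that("continuous trials have the stated effect-size structure", {
  # under the null at large n the reconstructed t is a plain t statistic
  tr <- simulate_continuous_trial(10000, 10000, 0, seed = 4)
  cmp <- t_from_arm_summaries(tr$summaries$moments$arm1,
                              tr$summaries$moments$arm2)
  expect_lt(abs(cmp$t), 4)

  # Monte-Carlo recovery of the true standardized effect
  d <- vapply(1:1000, function(k) {
    trk <- simulate_continuous_trial(100, 100, 0.5, seed = k)
    t_from_arm_summaries(trk$summaries$moments$arm1,
                         trk$summaries$moments$arm2)$t / sqrt(50)
  }, numeric(1))
  expect_lt(abs(mean(d) - 0.5), 0.03)

  # summaries are recomputable from the raw samples
  expect_equal(tr$summaries$moments$arm1$mean, mean(tr$raw$arm1))
  expect_equal(tr$summaries$quartiles$arm2$median,
               unname(quantile(tr$raw$arm2, 0.5, type = 7)))
})

test_that("binary trials follow the stated event probabilities", {
  tr0 <- simulate_binary_trial(50, 50, 0, 0, seed = 1)
  expect_identical(tr0$table$y1, 0L)
  expect_identical(tr0$table$y2, 0L)

  rate <- vapply(1:500, function(k) {
    simulate_binary_trial(500, 500, 0.1, 0.1, seed = k)$table$y1 / 500
  }, numeric(1))
  expect_lt(abs(mean(rate) - 0.1), 0.01)
})

test_that("a Solidarity-scale mortality difference is detectable", {
  bf <- vapply(1:500, function(k) {
    tab <- simulate_binary_trial(2700, 2700, 0.08, 0.12, seed = k)$table
    indep_binomial_bf01(tab)$bf01
  }, numeric(1))
  expect_lt(median(bf), 1 / 3)
})

test_that("recovery trials emit censored-aware quartile summaries", {
  tr <- simulate_recovery_trial(500, 500, 11, 15, 0.6, 28, seed = 5)
  expect_identical(names(tr$summaries), "quartiles")
  expect_gt(tr$censoring$n_censored2, 0)  # median-15 arm hits the cutoff
  expect_true(all(tr$raw$observed1 <= 28))

  # equal medians: the reconstructed t is centered on zero with roughly
  # unit-t spread (the statistic keeps its null distribution no matter how
  # small sigma is, since numerator and denominator shrink together)
  tnull <- vapply(1:200, function(k) {
    trk <- simulate_recovery_trial(200, 200, 12, 12, 0.1, 28, seed = k)
    t_from_arm_summaries(trk$summaries$quartiles$arm1,
                         trk$summaries$quartiles$arm2)$t
  }, numeric(1))
  expect_lt(abs(mean(tnull)), 0.25)
  expect_gte(mean(abs(tnull) < 4), 0.99)

  # degenerate distribution: observed medians equal the specified medians
  trd <- simulate_recovery_trial(101, 101, 10, 14, 0, 1000, seed = 6)
  expect_equal(trd$summaries$quartiles$arm1$median, 10)
  expect_equal(trd$summaries$quartiles$arm2$median, 14)

  # censoring so heavy a quartile is unidentified must error
  expect_error(simulate_recovery_trial(200, 200, 20, 25, 1.5, 26, seed = 7),
               "censoring too heavy")
  expect_error(simulate_recovery_trial(100, 100, 10, 30, 0.5, 28, seed = 7),
               "exceed both medians")
})

test_that("an ACTT-1-style recovery contrast yields pro-treatment evidence", {
  bf <- vapply(1:100, function(k) {
    trk <- simulate_recovery_trial(500, 500, 11, 15, 0.6, 28, seed = k)
    cmp <- t_from_arm_summaries(trk$summaries$quartiles$arm1,
                                trk$summaries$quartiles$arm2)
    jzs_bf01(cmp)$bf01
  }, numeric(1))
  expect_gte(mean(bf < 1 / 3), 0.9)
})

test_that("evidence calibration tabulates the full chain reproducibly", {
  scen <- list(kind = "continuous", n1 = 50, n2 = 50, delta = 0)
  one <- evidence_calibration(scen, reps = 1, seed = 21)
  expect_identical(nrow(one$replicates), 1L)
  expect_identical(one, evidence_calibration(scen, reps = 1, seed = 21))
  expect_equal(sum(one$frequencies), 1)

  cal <- evidence_calibration(scen, reps = 50, seed = 22)
  expect_identical(names(cal$frequencies), evidence_categories())
  expect_equal(sum(cal$frequencies), 1)
  expect_identical(cal$replicates$category, categorize(cal$replicates$bf01))
  # replicate k is reproducible in isolation through its own stream
  k <- 17
  tr_direct <- simulate_continuous_trial(50, 50, 0,
                                         seed = trialbf:::.stream_seed(22, k - 1L))
  cmp <- t_from_arm_summaries(tr_direct$summaries$moments$arm1,
                              tr_direct$summaries$moments$arm2)
  expect_equal(cal$replicates$bf01[k], jzs_bf01(cmp)$bf01)

  # binary and recovery scenarios run through the same interface
  calb <- evidence_calibration(list(kind = "binary", n1 = 200, n2 = 200,
                                    p1 = 0.1, p2 = 0.1), reps = 20, seed = 1)
  expect_equal(sum(calb$frequencies), 1)
  calr <- evidence_calibration(list(kind = "recovery", n1 = 100, n2 = 100,
                                    median1 = 10, median2 = 12,
                                    sigma_log = 0.5, censor_day = 40),
                               reps = 10, seed = 2)
  expect_equal(sum(calr$frequencies), 1)
  expect_error(evidence_calibration(list(kind = "weibull"), reps = 2, seed = 1),
               "unknown scenario kind")
})

test_that("median bf01 moves with n in the direction consistency requires", {
  med_bf <- function(delta, n) {
    cal <- evidence_calibration(list(kind = "continuous", n1 = n, n2 = n,
                                     delta = delta), reps = 500, seed = 33)
    median(cal$replicates$bf01)
  }
  null_track <- vapply(c(50, 200, 1000), function(n) med_bf(0, n), numeric(1))
  expect_true(all(diff(null_track) >= 0))
  eff_track <- vapply(c(50, 200, 1000), function(n) med_bf(0.8, n), numeric(1))
  expect_true(all(diff(eff_track) <= 0))
})
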