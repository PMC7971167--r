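test_that("observer model: guess floor, threshold anchor, monotonicity", {
  obs0 <- observer_model(300, slope = 4)
  expect_equal(observer_prob(obs0, 0), 0)
  expect_equal(observer_prob(obs0, 300), 0.5)
  amps <- seq(0, 1500, by = 25)
  expect_true(all(diff(observer_prob(obs0, amps)) >= 0))
  # gamma = 0, amplitude 0: always no
  set.seed(1)
  expect_false(any(observer_response(obs0, rep(0, 500))))
  # Monte-Carlo anchors of the defined p
  set.seed(2)
  expect_equal(mean(observer_response(obs0, rep(300, 10000))), 0.5,
               tolerance = 0.04)
  obsg <- observer_model(300, slope = 4, guess_rate = 0.245)
  set.seed(3)
  expect_equal(mean(observer_response(obsg, rep(0, 10000))), 0.245,
               tolerance = 0.041)
})

test_that("hybrid estimator recovers thresholds; catch bookkeeping is exact", {
  # noiseless steep observer at the experimental threshold scale
  obs <- observer_model(259, slope = 30)
  s <- run_hybrid_threshold(obs, "E1", seed = 2, n_trials = 120)
  expect_lt(abs(s$estimates$threshold_uA - 259) / 259, 0.05)

  # catch trials with gamma = 0: block FPR identically zero
  s6 <- run_hybrid_threshold(observer_model(300, slope = 4),
                             paste0("E", 1:6), seed = 5, n_trials = 200,
                             n_catch = 32)
  expect_equal(sum(s6$trials$catch), 32L)
  expect_true(all(s6$trials$amplitude_uA[s6$trials$catch] == 0))
  expect_equal(s6$fpr, 0)
  # two electrodes with identical observers agree within sampling error
  expect_lt(abs(diff(range(s6$estimates$threshold_uA))) / 300, 0.45)
  # determinism per seed
  s6b <- run_hybrid_threshold(observer_model(300, slope = 4),
                              paste0("E", 1:6), seed = 5, n_trials = 200,
                              n_catch = 32)
  expect_identical(s6$trials, s6b$trials)
})

test_that("estimator recovery and false-positive bias (scaled-down sweeps)", {
  # gamma = 0: median relative error < 10% across random observers
  set.seed(11)
  errs <- vapply(1:40, function(i) {
    tru <- stats::runif(1, 100, 600)
    s <- run_hybrid_threshold(observer_model(tru, slope = 4), "E1",
                              seed = 300 + i, n_trials = 90)
    abs(s$estimates$threshold_uA - tru) / tru
  }, numeric(1))
  expect_lt(stats::median(errs), 0.10)

  # gamma = 0.25 skews the psychometric fit leftward (sign test p < 0.01)
  below <- vapply(1:50, function(i) {
    s <- run_hybrid_threshold(observer_model(300, slope = 4,
                                             guess_rate = 0.25),
                              "E1", seed = 700 + i, n_trials = 70)
    s$estimates$threshold_uA < 300
  }, logical(1))
  p_sign <- stats::binom.test(sum(below), length(below),
                              alternative = "greater")$p.value
  expect_lt(p_sign, 0.01)
})

test_that("block audit applies the strict >25% rule", {
  mk <- function(n_yes, n_catch = 32) data.frame(
    catch = rep(TRUE, n_catch),
    response = c(rep(TRUE, n_yes), rep(FALSE, n_catch - n_yes)))
  a9 <- audit_block(mk(9))
  expect_equal(a9$fpr, 9 / 32)
  expect_true(a9$exclude)                  # 28.1% > 25%
  expect_false(audit_block(mk(0))$exclude)
  expect_false(audit_block(mk(8))$exclude) # exactly 25.0%: keep
  no_catch <- audit_block(data.frame(catch = logical(0),
                                     response = logical(0)))
  expect_true(is.na(no_catch$exclude))
  # a gamma = 0.35 observer's block is excluded with probability > 0.8:
  # catch responses are iid Bernoulli(0.35) over 32 trials, so the exact
  # operating characteristic is 1 - pbinom(8, 32, 0.35)
  p_exact <- 1 - stats::pbinom(8, 32, 0.35)
  expect_gt(p_exact, 0.8)
  excl <- vapply(1:40, function(i) {
    s <- run_hybrid_threshold(observer_model(300, slope = 4,
                                             guess_rate = 0.35),
                              paste0("E", 1:2), seed = 40 + i,
                              n_trials = 40, n_catch = 32)
    audit_block(s)$exclude
  }, logical(1))
  expect_lt(abs(mean(excl) - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 40))
})

test_that("model-observed comparison: exact cases, filter, MC oracle", {
  x <- c(380, 400, 455, 290, 350, 500)
  ex <- compare_thresholds(x, x)
  expect_equal(ex$r, 1)
  expect_equal(ex$slope, 1)
  expect_equal(ex$intercept, 0, tolerance = 1e-9)
  expect_equal(compare_thresholds(x, -x)$r, -1)
  expect_error(compare_thresholds(x[1:2], x[1:2]), "at least 3")
  deg <- compare_thresholds(x, rep(100, 6))
  expect_true(is.na(deg$r))
  # the observed-threshold floor drops low pairs
  y <- x + 10
  y[2] <- 50
  expect_equal(compare_thresholds(x, y, min_observed_uA = 100)$n, 5L)

  # synthetic pairs at rho = 0.5, n = 24: estimate falls inside the exact
  # sampling distribution's 95% interval (simulated oracle)
  set.seed(9)
  n <- 24
  sim_r <- replicate(2000, {
    a <- stats::rnorm(n); b <- 0.5 * a + sqrt(1 - 0.25) * stats::rnorm(n)
    stats::cor(a, b)
  })
  ci <- stats::quantile(sim_r, c(0.025, 0.975))
  a <- stats::rnorm(n); b <- 0.5 * a + sqrt(1 - 0.25) * stats::rnorm(n)
  r_hat <- compare_thresholds(200 + 100 * a, 200 + 100 * b)$r
  expect_gt(r_hat, ci[1]); expect_lt(r_hat, ci[2])
})

test_that("block ANOVA: exact zero, null calibration, power", {
  expect_equal(block_anova(list(c(1, 2, 3), c(1, 2, 3)))$F, 0)
  deg <- block_anova(list(c(2, 2), c(2, 2)))
  expect_equal(deg$F, 0)
  expect_error(block_anova(list(1:3)), "length")
  set.seed(13)
  p_null <- replicate(200, {
    blocks <- lapply(1:3, function(i) stats::rnorm(20, mean = 300, sd = 60))
    block_anova(blocks)$p_value
  })
  expect_gt(mean(p_null), 0.40)     # roughly uniform null p-values
  expect_lt(mean(p_null), 0.60)
  expect_gt(mean(p_null > 0.5), 0.35)
  shifted <- block_anova(list(stats::rnorm(20, 300, 10),
                              stats::rnorm(20, 400, 10)))
  expect_lt(shifted$p_value, 1e-3)
})
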