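test_that("posterior intervals and directional probabilities behave", {
  set.seed(20)
  pos <- abs(rnorm(1000)) + 0.01
  iv <- posterior_interval(pos, 0.95)
  expect_equal(iv$pd, 1)
  expect_gt(iv$lower, 0)
  expect_identical(decide_group_difference(iv), "positive")

  sym <- c(rnorm(5000))
  ivs <- posterior_interval(sym, 0.89)
  expect_lt(ivs$pd, 0.55)
  expect_gte(ivs$pd, 0.5)
  expect_true(ivs$lower <= ivs$point && ivs$point <= ivs$upper)
  expect_error(posterior_interval(rnorm(50)), "100")

  # decision examples and sign symmetry
  mk <- function(lo, up) structure(list(point = (lo + up) / 2, lower = lo,
                                        upper = up, level = 0.95, pd = 0.9),
                                   class = "interval_estimate")
  expect_identical(decide_group_difference(mk(0.02, 0.30)), "positive")
  expect_identical(decide_group_difference(mk(-0.10, 0.20)), "none")
  expect_identical(decide_group_difference(mk(-0.30, -0.02)), "negative")
  draws <- rnorm(500, 2)
  iv1 <- posterior_interval(draws, 0.95)
  iv2 <- posterior_interval(-draws, 0.95)
  expect_equal(iv1$pd, iv2$pd)
  d1 <- decide_group_difference(iv1); d2 <- decide_group_difference(iv2)
  expect_true((d1 == "positive") == (d2 == "negative"))
})

test_that("comparator tests reject separated groups and not identical ones", {
  tr <- sample_truth(smoke_config(n_per_group = 5, seed = 23))
  out <- truth_outcomes(tr)
  # identical outcome vectors in both groups: t = 0, p = 1
  half <- out[out$group == 1, ]
  mirror <- half
  mirror$group <- 2
  mirror$subject <- paste0("m", mirror$subject)
  ct0 <- suppressMessages(comparator_tests(rbind(half, mirror)))
  expect_true(all(abs(ct0$t_tests$p - 1) < 1e-9))
  expect_false(any(ct0$t_tests$reject))

  # five-SD separation: everything rejects
  out2 <- out
  sdv <- stats::sd(out2$value)
  out2$value[out2$group == 2] <- out2$value[out2$group == 2] + 5 * sdv
  ct2 <- suppressMessages(comparator_tests(out2))
  expect_true(all(ct2$t_tests$reject))
  expect_true(ct2$lme$reject)
  expect_error(comparator_tests(out[out$subject %in% c("s01", "s06"), ]),
               "at least 2")
})

test_that("LME type-I error is nominal on null simulations", {
  rejections <- 0
  for (r in 1:200) {
    tr <- sample_truth(simulation_config(n_per_group = 20,
                                         regions = smoke_regions(),
                                         effect_log_bpnd = 0, seed = 3000 + r))
    ct <- suppressMessages(comparator_tests(truth_outcomes(tr)))
    rejections <- rejections + ct$lme$reject
  }
  # exact binomial 95% interval around 5% of 200
  expect_gte(rejections, qbinom(0.025, 200, 0.05))
  expect_lte(rejections, qbinom(0.975, 200, 0.05))
})

test_that("logspline power matches the analytic normal answer", {
  set.seed(8)
  lower <- rnorm(50, 0.1, 0.2)
  upper <- lower + 0.8
  pe <- power_logspline(lower, upper, B = 300)
  expect_equal(pe$power, pnorm(0.5), tolerance = 0.05)
  expect_gte(pe$ci_upper, pe$power)
  expect_lte(pe$ci_lower, pe$power)
  expect_identical(pe$method, "logspline")

  # converges to the empirical proportion
  lower2 <- rnorm(5000, 0.1, 0.2)
  pe2 <- power_logspline(lower2, lower2 + 0.8, B = 40)
  expect_lt(abs(pe2$power - pe2$empirical), 0.02)

  # saturated case
  set.seed(9)
  pe3 <- power_logspline(abs(rnorm(50)) + 0.01, abs(rnorm(50)) + 2, B = 100)
  expect_gte(pe3$power, 0.95)
  expect_equal(pe3$empirical, 1)

  expect_warning(pe4 <- power_logspline(rep(0.2, 25), rep(0.9, 25), B = 20),
                 "degenerate")
  expect_identical(pe4$method, "empirical")
  expect_error(power_logspline(rnorm(10), rnorm(10)), "at least 20")
})

test_that("recovery metrics measure absolute and relative accuracy", {
  x <- rnorm(100, 3)
  rm0 <- recovery_metrics(x, x)
  expect_equal(rm0$rmse, 0)
  expect_equal(rm0$r, 1)
  rm1 <- recovery_metrics(x, x + 0.5)
  expect_equal(rm1$rmse, 0.5)
  expect_equal(rm1$r, 1)
  set.seed(24)
  z <- rnorm(1000)
  rm2 <- recovery_metrics(z, sample(z))
  expect_lt(abs(rm2$r), 0.1)
  expect_true(is.na(recovery_metrics(rep(1, 5), rnorm(5))$r))
})

test_that("bias summaries and the exceedance identity agree with theory", {
  est <- c(0.2, 0.2, 0.2)
  bs <- bias_sd_summary(est, 0.2)
  expect_equal(bs$bias, 0)
  expect_equal(bs$sd, 0)
  bs2 <- bias_sd_summary(est - 0.05, 0.2)
  expect_equal(bs2$bias, -0.05)
  # an estimator biased low by 53% of its SD still exceeds the truth with
  # probability ~30%
  expect_equal(exceedance_given_bias(0.53), pnorm(-0.53))
  expect_equal(exceedance_given_bias(0.53), 0.298, tolerance = 0.002)
})

test_that("Cohen's d matches its definition and the configured effect", {
  x <- rnorm(50)
  expect_equal(cohens_d(x, x), 0)
  set.seed(25)
  a <- rnorm(2000); b <- rnorm(2000) + 1
  expect_equal(cohens_d(a, b), 1, tolerance = 0.06)
  expect_true(is.na(cohens_d(rep(1, 5), rep(1, 5))))
  # a 20% difference over the between-subject binding SD is a moderate effect
  sd_bpnd <- default_population_parameters()$sd_subject["BPND"]
  expect_equal(unname(0.182 / sd_bpnd), 0.55, tolerance = 0.01)
})
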