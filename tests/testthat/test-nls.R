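test_that("frame weights implement the configured schemes", {
  sched <- frame_schedule(start = c(0, 1, 2), end = c(1, 2, 5))
  expect_equal(as.numeric(compute_weights(sched, "uniform")), rep(1, 3))
  wd <- as.numeric(compute_weights(sched, "duration"))
  expect_equal(wd[3] / wd[1], 3)  # 3-min vs 1-min frame
  expect_equal(mean(wd), 1)
  sds <- c(2, 1, 0.5)
  wo <- as.numeric(compute_weights(sched, "oracle", noise_sds = sds))
  expect_equal(wo / wo[1], (1 / sds^2) / (1 / sds[1]^2))
  # the implied per-frame SD scales as 1/sqrt(w): doubling a weight divides
  # its implied SD by sqrt(2)
  implied_sd <- 1 / sqrt(wo)
  implied_sd2 <- 1 / sqrt(2 * wo)
  expect_equal(implied_sd / implied_sd2, rep(sqrt(2), 3))
  expect_error(compute_weights(sched, "oracle"), "noise_sds")
})

test_that("noiseless multi-start NLS recovers all five parameters", {
  set.seed(5)
  sched <- smoke_schedule()
  aif <- fixture_aif()
  cb <- parametric_frame_means(petpool:::whole_blood_curve(aif), sched)
  for (r in 1:50) {
    truth <- c(K1 = exp(runif(1, log(0.05), log(0.25))),
               VND = exp(runif(1, log(0.5), log(2.5))),
               BPND = exp(runif(1, log(0.4), log(6))),
               k4 = exp(runif(1, log(0.02), log(0.12))),
               vB = exp(runif(1, log(0.02), log(0.1))))
    rc <- outcomes_to_rates(truth["K1"], truth["VND"], truth["BPND"],
                            truth["k4"], truth["vB"])
    y <- predict_tac(rc, aif, cb, sched)$values
    fit <- fit_nls_tac(y, aif, cb, sched, n_starts = 10, seed = r)
    expect_lt(max(abs(fit$estimates - truth) / truth), 0.01)
  }
})

test_that("NLS honours its structural contracts", {
  set.seed(6)
  sched <- smoke_schedule()
  aif <- fixture_aif()
  cb <- parametric_frame_means(petpool:::whole_blood_curve(aif), sched)
  rc <- outcomes_to_rates(0.12, 1, 2, 0.05, 0.05)
  y <- predict_tac(rc, aif, cb, sched)$values + rnorm(12, 0, 0.3)

  # best-of-n RSS is non-increasing in the number of starts
  rss <- vapply(c(1, 3, 10), function(ns)
    fit_nls_tac(y, aif, cb, sched, n_starts = ns, seed = 9)$rss, numeric(1))
  expect_true(all(diff(rss) <= 1e-9))

  fit <- fit_nls_tac(y, aif, cb, sched, n_starts = 10, seed = 9)
  # direct binding potential is exactly k3/k4 of the fitted rates
  expect_equal(fit$estimates[["BPND"]], fit$rates$k3 / fit$rates$k4)
  # estimates respect the configured bounds
  b <- default_nls_bounds()
  expect_true(all(fit$estimates >= b["lower", ] - 1e-12))
  expect_true(all(fit$estimates <= b["upper", ] + 1e-12))
  # optimiser sanity: weighted RSS at the estimate beats the truth
  mu_true <- predict_tac(rc, aif, cb, sched)$values
  expect_lte(fit$rss, sum((y - mu_true)^2) + 1e-9)

  expect_error(fit_nls_tac(c(y[-1], NA), aif, cb, sched), "non-finite")
})

test_that("study-level NLS returns a complete outcome table", {
  st <- simulate_study(smoke_config(n_per_group = 2, seed = 14))
  fits <- fit_nls_study(st, weight_scheme = "oracle", n_starts = 6, seed = 2)
  expect_equal(nrow(fits), 12)
  expect_true(all(c("K1", "VND", "BPND", "BPP", "VT", "k4", "vB", "rss",
                    "converged", "group") %in% names(fits)))
  expect_equal(fits$BPP, fits$VND * fits$BPND, tolerance = 1e-10)
  expect_true(all(fits$rss >= 0))
})
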