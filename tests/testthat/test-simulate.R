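test_that("a degenerate hierarchy reproduces the population exactly", {
  pop <- default_population_parameters()
  pop$sd_subject[] <- 0; pop$sd_tac[] <- 0
  pop$sd_vB_subject <- 0; pop$sd_sigma_subject <- 0
  tr <- sample_truth(smoke_config(n_per_group = 2, effect = 0), pop)
  prof <- pop$regional_profile
  for (r in seq_len(nrow(tr$tacs))) {
    k <- match(tr$tacs$region[r], prof$region)
    expect_equal(tr$tacs$logK1[r], unname(pop$alpha["K1"] + prof$dK1[k]))
    expect_equal(tr$tacs$logBPND[r], unname(pop$alpha["BPND"] + prof$dBPND[k]))
  }
})

test_that("the group effect converges to the configured log difference", {
  tr <- sample_truth(simulation_config(n_per_group = 3000,
                                       regions = "DLPFC",
                                       effect_log_bpnd = 0.182, seed = 9))
  g2 <- tr$tacs$group == 2
  diff <- mean(tr$tacs$logBPND[g2]) - mean(tr$tacs$logBPND[!g2])
  expect_lt(abs(diff - 0.182), 0.02)
})

test_that("group distributions differ only by the binding shift", {
  tr <- sample_truth(simulation_config(n_per_group = 4000, regions = "DLPFC",
                                       effect_log_bpnd = 0.3, seed = 10))
  g2 <- tr$tacs$group == 2
  for (col in c("logK1", "logVND", "logk4", "logvB")) {
    expect_lt(abs(mean(tr$tacs[[col]][g2]) - mean(tr$tacs[[col]][!g2])), 0.03)
  }
  expect_gt(mean(tr$tacs$logBPND[g2]) - mean(tr$tacs$logBPND[!g2]), 0.25)
})

test_that("study generation is seeded and counts its TACs", {
  cfg <- smoke_config(n_per_group = 4, seed = 3)
  t1 <- sample_truth(cfg); t2 <- sample_truth(cfg)
  expect_identical(t1$tacs, t2$tacs)
  t3 <- sample_truth(smoke_config(n_per_group = 4, seed = 4))
  expect_false(isTRUE(all.equal(t1$tacs$logK1, t3$tacs$logK1)))

  cfg10 <- simulation_config(n_per_group = 10, seed = 5)
  tr <- sample_truth(cfg10)
  expect_equal(nrow(tr$tacs), 10 * 2 * 9)

  st1 <- generate_study(t1, noise_seed = 7)
  st2 <- generate_study(t1, noise_seed = 7)
  expect_identical(st1$tacs, st2$tacs)
  expect_equal(nrow(st1$tacs), 24 * 12)
})

test_that("zero error scale yields exact noise-free curves", {
  cfg <- smoke_config(n_per_group = 2, seed = 6, error_scale = 0)
  st <- generate_study(sample_truth(cfg))
  expect_equal(st$tacs$value, as.vector(t(st$noise_free)))
})

test_that("the noise model produces the specified per-frame SDs", {
  expect_equal(noise_sd(0.10, 100), 10)
  expect_equal(noise_sd(0.10, 100, tau_sigma = log(2)), 20)
  f <- c(-0.2, 0, 0.3)
  expect_true(all(diff(noise_sd(0.1, 50, f_t = f)) > 0))
  expect_error(noise_sd(-0.1, 100), "error_scale")

  # Monte-Carlo: empirical frame SDs of replicate noisy TACs match the model
  tr <- sample_truth(smoke_config(n_per_group = 1, seed = 12))
  aifs <- sample_aif_parameters(2, seed = 13)
  reps <- vapply(1:400, function(i) {
    st <- generate_study(tr, aifs = aifs, noise_seed = 5000 + i)
    st$tacs$value[st$tacs$subject == "s01" & st$tacs$region == "DLPFC"][6]
  }, numeric(1))
  st0 <- generate_study(tr, aifs = aifs, noise_seed = 1)
  expected_sd <- st0$noise_sd[which(st0$truth$tacs$subject == "s01" &
                                      st0$truth$tacs$region == "DLPFC"), 6]
  expect_equal(stats::sd(reps), expected_sd, tolerance = 0.1)
})

test_that("sampled AIF parameters are valid and reproducible", {
  draws <- sample_aif_parameters(1000, seed = 42)
  for (a in draws[1:50]) expect_s3_class(a, "aif_parameters")
  peaks <- vapply(draws, function(a) a$b * (a$tp - a$t0), numeric(1))
  late <- vapply(draws, function(a) aif_value(a, 90), numeric(1))
  expect_true(all(peaks > late))
  t0s <- vapply(draws, `[[`, numeric(1), "t0")
  expect_true(all(t0s >= 0.3 & t0s <= 1.0))
  a1 <- sample_aif_parameters(1, seed = 99)
  a2 <- sample_aif_parameters(1, seed = 99)
  expect_identical(a1, a2)
})

test_that("subject deviations reproduce the configured covariance", {
  pop <- default_population_parameters()
  tr <- sample_truth(simulation_config(n_per_group = 5000, regions = "DLPFC",
                                       seed = 21), pop)
  S_target <- diag(pop$sd_subject) %*% pop$corr_subject %*% diag(pop$sd_subject)
  S_emp <- stats::cov(tr$tau)
  expect_lt(norm(S_emp - S_target, "F") / norm(S_target, "F"), 0.08)

  # with correlations off the draws are independent
  tr0 <- sample_truth(simulation_config(n_per_group = 5000, regions = "DLPFC",
                                        seed = 22, correlations_on = FALSE), pop)
  C <- stats::cor(tr0$tau)
  expect_lt(max(abs(C[upper.tri(C)])), 0.05)
})
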