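test_that("design construction encodes regions, groups and indices", {
  cfg <- simulation_config(n_per_group = 2, seed = 1)  # all 9 regions
  st <- simulate_study(cfg)
  tac_tab <- unique(st$tacs[, c("subject", "region")])
  design <- build_design(tac_tab, st$covariates, covariate_spec())
  expect_equal(ncol(design$X$K1), 8)    # 9 regions, reference-coded
  expect_equal(ncol(design$X$BPND), 9)  # 8 dummies + group
  expect_true("group2" %in% colnames(design$X$BPND))
  expect_equal(ncol(design$X$k4), 0)    # no covariates on k4
  expect_equal(nrow(design$X$BPND), nrow(tac_tab))
  expect_equal(length(design$subj), nrow(tac_tab))
  expect_equal(sort(unique(design$reg)), 0:8)

  # continuous covariates are centred, categorical treatment-coded
  design2 <- build_design(tac_tab, st$covariates,
                          covariate_spec(K1 = c("age", "sex")))
  expect_lt(abs(mean(unique(design2$X$K1[, "age"]))), 25)
  expect_true(all(design2$X$K1[, "sexM"] %in% c(0, 1)))

  covs <- st$covariates
  covs$age[2] <- NA
  expect_error(build_design(tac_tab, covs, covariate_spec(K1 = "age")),
               "missing values.*s02")
  expect_error(build_design(tac_tab, st$covariates[-1, ], covariate_spec()),
               "absent")
})

test_that("the C++ joint log density matches an independent R replica", {
  st <- simulate_study(smoke_config(n_per_group = 3, effect = 0.182, seed = 7))
  fit <- fit_hier_2tc(st, sampler = smoke_sampler(warmup = 30, iter = 10))
  nm <- colnames(fit$draws)
  set.seed(101)
  for (rep in 1:3) {
    par <- petpool:::init_vector(nm, fit$data$prior)
    cpp <- petpool:::cpp_log_posterior(fit$data, par)
    rr <- replica_log_density(fit$data, par, nm)
    expect_equal(cpp$loglik + cpp$logprior, rr, tolerance = 1e-8)
  }
  # a retained draw must also evaluate identically
  par <- fit$draws[nrow(fit$draws), ]
  cpp <- petpool:::cpp_log_posterior(fit$data, par)
  expect_equal(cpp$loglik + cpp$logprior, replica_log_density(fit$data, par, nm),
               tolerance = 1e-8)
})

test_that("the values-mode joint density matches the replica too", {
  tr <- sample_truth(smoke_config(n_per_group = 5, effect = 0.182, seed = 8))
  vals <- tr$tacs[, c("subject", "region", "logK1", "logVND", "logBPND", "logk4")]
  covs <- tr$subjects; covs$group <- as.character(covs$group)
  fit <- fit_hier_values(vals, covs, sampler = smoke_sampler(warmup = 30, iter = 10))
  nm <- colnames(fit$draws)
  set.seed(102)
  for (rep in 1:2) {
    par <- petpool:::init_vector(nm, fit$data$prior)
    cpp <- petpool:::cpp_log_posterior(fit$data, par)
    expect_equal(cpp$loglik + cpp$logprior,
                 replica_log_density(fit$data, par, nm), tolerance = 1e-8)
  }
})

test_that("convergence rule matches its definition", {
  expect_true(check_convergence(rep(1.00, 200)))
  r <- rep(1.00, 200); r[1] <- 1.30
  expect_false(check_convergence(r))          # a single parameter above 1.25
  r2 <- rep(1.00, 200); r2[1:6] <- 1.06       # 3% above 1.05, max below 1.25
  expect_false(check_convergence(r2))
  r3 <- rep(1.00, 200); r3[1:4] <- 1.06       # exactly 2% above 1.05 passes
  expect_true(check_convergence(r3))
  expect_error(check_convergence(c(1, NA)), "missing")
})

test_that("split-Rhat separates mixed from unmixed chains", {
  set.seed(11)
  same <- cbind(rnorm(400), rnorm(400))
  expect_lt(split_rhat(same), 1.05)
  apart <- cbind(rnorm(400), rnorm(400) + 5)
  expect_gt(split_rhat(apart), 2)
  stuck <- cbind(rep(1, 400), rep(2, 400))
  expect_identical(split_rhat(stuck), Inf)
  expect_identical(split_rhat(cbind(rep(1, 400), rep(1, 400))), 1)
})

test_that("a smoke-scale fit recovers the population parameters", {
  cfg <- smoke_config(n_per_group = 4, effect = 0.182, seed = 42)
  st <- simulate_study(cfg)
  fit <- fit_hier_2tc(st, sampler = smoke_sampler(seed = 1, warmup = 1200,
                                                  iter = 800))
  pop <- st$truth$population
  prof <- pop$regional_profile
  ksel <- match(smoke_regions(), prof$region)
  # reference-coded intercepts absorb the first region's deviation for K1 and
  # BPND, and the mean regional deviation for the partially pooled VND / k4
  truth <- c(alpha_K1 = unname(pop$alpha["K1"] + prof$dK1[ksel[1]]),
             alpha_VND = unname(pop$alpha["VND"] + mean(prof$dVND[ksel])),
             alpha_BPND = unname(pop$alpha["BPND"] + prof$dBPND[ksel[1]]),
             alpha_k4 = unname(pop$alpha["k4"] + mean(prof$dk4[ksel])))
  for (nm in names(truth)) {
    qs <- stats::quantile(fit$draws[, nm], c(0.025, 0.975))
    expect_gt(truth[[nm]], qs[1])
    expect_lt(truth[[nm]], qs[2])
  }
  eff <- effect_draws(fit, "BPND", "group2")
  expect_lt(abs(mean(eff) - 0.182), 2 * sd(eff) + 0.05)
  expect_true(all(is.finite(fit$rhat)))
  expect_length(fit$rhat, ncol(fit$draws))
})

test_that("the univariate variant carries no correlation parameters", {
  st <- simulate_study(smoke_config(n_per_group = 2, seed = 15))
  fit <- fit_hier_2tc(st, sampler = smoke_sampler(warmup = 40, iter = 20),
                      multivariate = FALSE)
  expect_false(any(grepl("^ycor", colnames(fit$draws))))
  fit2 <- fit_hier_2tc(st, sampler = smoke_sampler(warmup = 40, iter = 20),
                       multivariate = TRUE)
  expect_equal(sum(grepl("^ycor", colnames(fit2$draws))), 13)
})

test_that("prior-implied kinetic parameters are automatically positive", {
  # the log parameterisation guarantees positive rates and vB in (0, 1)
  pr <- prior_config()
  set.seed(16)
  for (i in 1:200) {
    draws <- rnorm(5, pr$alpha_loc[1:5], pr$alpha_scale[1:5])
    rc <- outcomes_to_rates(exp(draws[1]), exp(draws[2]), exp(draws[3]),
                            exp(draws[4]), vB = min(exp(draws[5]), 0.99))
    expect_true(rc$K1 > 0 && rc$k2 > 0 && rc$k4 > 0 && rc$vB >= 0 && rc$vB < 1)
  }
})

test_that("zero inter-regional variance shrinks the regional SD", {
  pop <- default_population_parameters()
  pop$regional_profile$dVND[] <- 0
  pop$regional_profile$dk4[] <- 0
  cfg <- simulation_config(n_per_group = 3, schedule = smoke_schedule(),
                           seed = 18)  # all nine regions: strong evidence
  st <- generate_study(sample_truth(cfg, pop))
  fit <- fit_hier_2tc(st, sampler = smoke_sampler(seed = 3, warmup = 1000,
                                                  iter = 600))
  post_med <- stats::median(exp(fit$draws[, "lsd_region_VND"]))
  prior_med <- prior_config()$sd_scale_region[1] * stats::qt(0.75, df = 3)
  expect_lt(post_med, prior_med)
})

test_that("relabelling subjects leaves population inference unchanged", {
  cfg <- smoke_config(n_per_group = 3, effect = 0.182, seed = 19)
  st <- simulate_study(cfg)
  st2 <- st
  perm <- c(3, 1, 2, 6, 4, 5)  # permute within groups
  old <- unique(st$tacs$subject)
  map <- stats::setNames(old[perm], old)
  st2$tacs$subject <- unname(map[st2$tacs$subject])
  st2$tacs <- st2$tacs[order(match(st2$tacs$subject, old)), ]
  st2$covariates$subject <- unname(map[st2$covariates$subject])
  st2$covariates <- st2$covariates[order(match(st2$covariates$subject, old)), ]
  names(st2$aifs) <- unname(map[names(st2$aifs)])
  st2$aifs <- st2$aifs[old]
  rownames(st2$blood) <- unname(map[rownames(st2$blood)])
  st2$blood <- st2$blood[old, ]
  s <- smoke_sampler(seed = 5, warmup = 800, iter = 500)
  f1 <- fit_hier_2tc(st, sampler = s)
  f2 <- fit_hier_2tc(st2, sampler = s)
  e1 <- effect_draws(f1, "BPND", "group2")
  e2 <- effect_draws(f2, "BPND", "group2")
  expect_lt(abs(mean(e1) - mean(e2)), 2 * sqrt(sd(e1)^2 + sd(e2)^2))
  expect_lt(abs(mean(f1$draws[, "alpha_K1"]) - mean(f2$draws[, "alpha_K1"])),
            0.1)
})

test_that("uncorrelated data yield near-zero posterior TAC correlations", {
  cors <- c()
  for (r in 1:3) {
    cfg <- smoke_config(n_per_group = 4, seed = 60 + r, correlations_on = FALSE)
    st <- simulate_study(cfg)
    fit <- fit_hier_2tc(st, sampler = smoke_sampler(seed = r, warmup = 600,
                                                    iter = 400))
    ytac <- fit$draws[, grepl("^ycor_tac", colnames(fit$draws)), drop = FALSE]
    cors <- c(cors, colMeans(tanh(ytac)))
  }
  # centred near zero across replicates and pairs
  expect_lt(abs(mean(cors)), 0.15)
  expect_lt(max(abs(cors)), 0.5)
})

test_that("parameter counting identities hold for the full-scale design", {
  expect_identical(count_nls_parameters(97, 9), 4365L)
  expect_identical(count_phi_vb_omitted(97, 9), 873L)
})
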