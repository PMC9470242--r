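test_that("the parametric AIF follows its piecewise definition", {
  aif <- aif_parameters(t0 = 0.5, b = 60, tp = 1.2, A = c(30, 8, 1.5),
                       lambda = c(3, 0.3, 0.02))
  expect_equal(aif_value(aif, 0.4), 0)
  expect_equal(aif_value(aif, 1.2), 60 * 0.7)
  expect_equal(aif_value(aif, 0.5), 0)  # continuous at onset
  # far tail decays at the slowest rate
  lt <- log(aif_value(aif, c(80, 100)))
  slope <- (lt[2] - lt[1]) / 20
  expect_equal(slope, -0.02, tolerance = 1e-3)
  expect_error(aif_parameters(1, 1, 0.5, c(1, 1, 1), c(1, 2, 3)), "tp")
  expect_error(aif_parameters(0, 1, 1, c(1, 1, 1), c(1, 1, 3)), "distinct")
})

test_that("AIF fitting recovers known parameters from noiseless samples", {
  tt <- c(seq(0.05, 3, by = 0.05), seq(3.5, 10, by = 0.75),
          seq(12, 100, by = 6))
  for (s in c(21, 27, 34)) {
    aif <- sample_aif_parameters(1, seed = s)
    y <- aif_value(aif, tt)
    fit <- fit_aif(blood_samples(tt, y), n_starts = 10, seed = s)
    expect_equal(sort(fit$A), sort(aif$A), tolerance = 0.01)
    expect_equal(sort(fit$lambda), sort(aif$lambda), tolerance = 0.01)
  }
})

test_that("AIF fitting handles noise, scaling and degenerate inputs", {
  tt <- c(seq(0.05, 3, by = 0.05), seq(3.5, 10, by = 0.75),
          seq(12, 100, by = 6))
  aif <- sample_aif_parameters(1, seed = 33)
  y <- aif_value(aif, tt)
  set.seed(3)
  noise_sd <- 0.02 * max(y)
  fit <- fit_aif(blood_samples(tt, y + rnorm(length(y), 0, noise_sd)),
                 n_starts = 10, seed = 4)
  rmse <- sqrt(mean((aif_value(fit, tt) - y)^2))
  expect_lte(rmse, 2 * noise_sd)

  # scale equivariance: amplitudes and gradient scale, rates do not
  f1 <- fit_aif(blood_samples(tt, y), seed = 2)
  f2 <- fit_aif(blood_samples(tt, 10 * y), seed = 2)
  expect_equal(f2$A / f1$A, rep(10, 3), tolerance = 1e-3)
  expect_equal(f2$b / f1$b, 10, tolerance = 1e-3)
  expect_equal(f2$lambda, f1$lambda, tolerance = 1e-6)
  expect_equal(c(f2$t0, f2$tp), c(f1$t0, f1$tp), tolerance = 0.02)

  expect_error(fit_aif(blood_samples(1:5, rep(1, 5))), "at least 9")
  expect_error(fit_aif(blood_samples(1:10, rep(0, 10))), "degenerate")
})

test_that("whole-blood frame means average the interpolated curve", {
  sched <- smoke_schedule()
  # constant samples reproduce the constant
  bs <- blood_samples(seq(0, 110, by = 2), rep(7.5, 56), kind = "whole-blood")
  expect_equal(whole_blood_frame_means(bs, sched), rep(7.5, 12),
               tolerance = 1e-8)
  # linear samples: frame mean equals the midpoint value
  bs2 <- blood_samples(seq(0, 110, by = 2), 3 + 0.5 * seq(0, 110, by = 2),
                       kind = "whole-blood")
  expect_equal(whole_blood_frame_means(bs2, sched), 3 + 0.5 * sched$midpoint,
               tolerance = 1e-6)
  # dense smooth samples match fine-grid numerical averaging
  tt <- seq(0, 110, by = 0.25)
  bs3 <- blood_samples(tt, 10 + 3 * sin(tt / 7), kind = "whole-blood")
  means <- whole_blood_frame_means(bs3, sched)
  ref <- vapply(seq_len(12), function(i) {
    g <- seq(sched$start[i], sched$end[i], length.out = 2001)
    mean(10 + 3 * sin(g / 7))
  }, numeric(1))
  expect_equal(means, ref, tolerance = 1e-3)
  expect_error(whole_blood_frame_means(blood_samples(numeric(0), numeric(0)),
                                       sched))
})

test_that("parametric frame means agree with numerical integration", {
  sched <- smoke_schedule()
  aif <- fixture_aif()
  means <- parametric_frame_means(aif, sched)
  ref <- vapply(seq_len(12), function(i) {
    stats::integrate(function(t) aif_value(aif, t), sched$start[i],
                     sched$end[i], subdivisions = 500)$value / sched$duration[i]
  }, numeric(1))
  expect_equal(means, ref, tolerance = 1e-6)
})
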