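test_that("binding outcomes follow from rate constants and invert exactly", {
  rc <- rate_constants(K1 = 0.2, k2 = 0.1, k3 = 0.05, k4 = 0.025, vB = 0.05)
  bo <- rates_to_outcomes(rc)
  expect_equal(bo$VND, 2)
  expect_equal(bo$BPND, 2)
  expect_equal(bo$BPP, 4)
  expect_equal(bo$VT, 6)

  # no specific binding collapses VT to VND
  bo0 <- rates_to_outcomes(rate_constants(0.2, 0.1, 0, 0.025))
  expect_equal(bo0$BPND, 0)
  expect_equal(bo0$VT, bo0$VND)
  expect_equal(bo0$VT, 2)

  # inversion examples
  rc2 <- outcomes_to_rates(K1 = 0.2, VND = 2, BPND = 2, k4 = 0.025, vB = 0.05)
  expect_equal(rc2$k2, 0.1)
  expect_equal(rc2$k3, 0.05)
  rc3 <- outcomes_to_rates(K1 = 0.1, VND = 1, BPND = 0, k4 = 0.01)
  expect_equal(rc3$k2, 0.1)
  expect_equal(rc3$k3, 0)

  # roundtrips exact for 100 random parameter sets
  set.seed(1)
  for (i in 1:100) {
    rc <- random_rc()
    bo <- rates_to_outcomes(rc)
    back <- outcomes_to_rates(rc$K1, bo$VND, bo$BPND, rc$k4, rc$vB)
    expect_equal(unclass(back), unclass(rc), tolerance = 1e-12)
    expect_equal(bo$VT, bo$VND * (1 + bo$BPND), tolerance = 1e-10)
    expect_equal(bo$VT, bo$VND + bo$BPP, tolerance = 1e-10)
  }

  expect_error(rates_to_outcomes(rate_constants(0.2, 0, 0.05, 0.025)), "k2")
  expect_error(outcomes_to_rates(0.2, -1, 2, 0.025), "VND")
  expect_error(rate_constants(0.2, 0.1, 0.05, 0), "k4")
})

test_that("impulse response decomposes the 2TC kinetics", {
  # k3 = 0 collapses to one-tissue kinetics
  irf <- impulse_response(rate_constants(0.2, 0.1, 0, 0.025))
  expect_equal(irf$phi1, 0.2)
  expect_equal(irf$phi2, 0, tolerance = 1e-12)
  expect_equal(irf$theta1, 0.1)
  expect_equal(irf$theta2, 0.025)

  set.seed(2)
  for (i in 1:100) {
    rc <- random_rc()
    irf <- impulse_response(rc)
    expect_equal(irf$phi1 + irf$phi2, rc$K1, tolerance = 1e-10)
    expect_equal(irf$theta1 * irf$theta2, rc$k2 * rc$k4, tolerance = 1e-10)
    expect_equal(irf$theta1 + irf$theta2, rc$k2 + rc$k3 + rc$k4,
                 tolerance = 1e-10)
    expect_gte(irf$theta1, irf$theta2)
  }
})

test_that("impulse response matches a stiff ODE integrator", {
  skip_if_not_installed("deSolve")
  set.seed(3)
  tt <- c(0.1, 0.5, 1, 2, 5, 10, 30, 60, 100)
  for (i in 1:20) {
    rc <- random_rc()
    irf <- impulse_response(rc)
    analytic <- irf$phi1 * exp(-irf$theta1 * tt) + irf$phi2 * exp(-irf$theta2 * tt)
    # unit-bolus response of the 2TC ODE system:
    # dC1/dt = -(k2+k3) C1 + k4 C2, dC2/dt = k3 C1 - k4 C2, C1(0) = K1
    deriv <- function(t, y, p) {
      list(c(-(p$k2 + p$k3) * y[1] + p$k4 * y[2],
             p$k3 * y[1] - p$k4 * y[2]))
    }
    sol <- deSolve::lsoda(y = c(rc$K1, 0), times = c(0, tt), func = deriv,
                          parms = rc, rtol = 1e-10, atol = 1e-12)
    numeric <- rowSums(sol[-1, 2:3, drop = FALSE])
    expect_equal(analytic, unname(numeric), tolerance = 1e-6)
  }
})

test_that("analytic convolution matches textbook cases and the limit", {
  # degenerate AIF: single exponential, no rise
  aif1 <- aif_parameters(t0 = 0, b = 1e-9 + 1, tp = 0, A = c(1, 0, 0),
                         lambda = c(2, 5, 9))
  expect_equal(convolve_exponential(aif1, 1, 1), exp(-1) - exp(-2),
               tolerance = 1e-10)
  aif2 <- aif_parameters(t0 = 0, b = 1, tp = 0, A = c(1, 0, 0),
                         lambda = c(1, 5, 9))
  expect_equal(convolve_exponential(aif2, 1, 1), exp(-1), tolerance = 1e-6)
})

test_that("analytic convolution matches trapezoidal quadrature", {
  set.seed(4)
  aifs <- sample_aif_parameters(5, seed = 40)
  for (aif in aifs) {
    for (theta in c(0.02, 0.3, 2)) {
      for (t in c(2.2, 8, 40, 115)) {
        a <- convolve_exponential(aif, theta, t)
        n <- trapz_conv(aif, theta, t)
        expect_equal(a, n, tolerance = 1e-4)
      }
    }
  }
})

test_that("frame schedules validate their geometry", {
  sched <- default_schedule()
  expect_length(sched$start, 20)
  expect_equal(sched$end[20], 110)
  expect_equal(sched$midpoint, (sched$start + sched$end) / 2)
  expect_error(frame_schedule(c(0, 1), c(2, 3)), "overlap")
  expect_error(frame_schedule(0, 0), "duration")
})

test_that("predicted TACs satisfy structural limits", {
  sched <- smoke_schedule()
  aif <- fixture_aif()
  cb <- parametric_frame_means(aif, sched)
  rc <- outcomes_to_rates(0.1, 1, 2, 0.05, vB = 0.999999)
  # all-blood voxel reproduces the whole-blood curve
  pt <- predict_tac(rc, aif, cb, sched)
  expect_equal(pt$values, cb, tolerance = 1e-5)
  # no delivery, no blood: identically zero
  rc0 <- rate_constants(0, 0.1, 0.05, 0.025, vB = 0)
  expect_equal(predict_tac(rc0, aif, cb, sched)$values, rep(0, 12))
  expect_error(predict_tac(rc0, aif, cb[-1], sched), "per frame")
})

test_that("predicted TACs agree with a full numerical convolution", {
  set.seed(5)
  sched <- smoke_schedule()
  aifs <- sample_aif_parameters(4, seed = 50)
  for (aif in aifs) {
    cb <- parametric_frame_means(aif, sched)
    rc <- random_rc()
    pt <- predict_tac(rc, aif, cb, sched)$values
    irf <- impulse_response(rc)
    for (i in c(2, 5, 9, 12)) {
      t <- sched$midpoint[i]
      num <- (1 - rc$vB) *
        (irf$phi1 * trapz_conv(aif, irf$theta1, t) +
           irf$phi2 * trapz_conv(aif, irf$theta2, t)) + rc$vB * cb[i]
      expect_equal(pt[i], num, tolerance = 1e-4)
    }
  }
})

test_that("with k3 = 0 the 2TC prediction equals one-tissue kinetics", {
  sched <- smoke_schedule()
  aif <- fixture_aif()
  cb <- parametric_frame_means(aif, sched)
  rc <- rate_constants(0.15, 0.08, 0, 0.05, vB = 0.04)
  pt <- predict_tac(rc, aif, cb, sched)$values
  onetc <- (1 - rc$vB) * rc$K1 *
    petpool:::cpp_conv_exp(petpool:::as_aif_vector(aif), rc$k2, sched$midpoint) +
    rc$vB * cb
  expect_equal(pt, as.numeric(onetc), tolerance = 1e-10)
})

test_that("prediction moves monotonically toward blood as vB grows", {
  sched <- smoke_schedule()
  aif <- fixture_aif()
  cb <- parametric_frame_means(aif, sched)
  base <- outcomes_to_rates(0.1, 1, 2, 0.05, vB = 0)
  dist <- vapply(c(0, 0.3, 0.6, 0.9), function(v) {
    rc <- outcomes_to_rates(0.1, 1, 2, 0.05, vB = v)
    mean(abs(predict_tac(rc, aif, cb, sched)$values - cb))
  }, numeric(1))
  expect_true(all(diff(dist) < 0))
})
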