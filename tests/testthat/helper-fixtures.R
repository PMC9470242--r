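# Shared fixtures: a short 12-frame schedule and small study builders used
# across the suite. Everything is generated in code; seeds are fixed so the
# suite is deterministic.

smoke_schedule <- function() {
  frame_schedule(start = c(0, 0.5, 1, 2, 4, 8, 12, 20, 30, 45, 60, 80),
                 end = c(0.5, 1, 2, 4, 8, 12, 20, 30, 45, 60, 80, 100))
}

smoke_regions <- function() c("DLPFC", "Hippocampus", "DRN")

smoke_config <- function(n_per_group = 4, effect = 0, seed = 1,
                         correlations_on = TRUE, error_scale = 0.10) {
  simulation_config(n_per_group = n_per_group, regions = smoke_regions(),
                    schedule = smoke_schedule(), effect_log_bpnd = effect,
                    error_scale = error_scale,
                    correlations_on = correlations_on, seed = seed)
}

smoke_sampler <- function(seed = 1, warmup = 800, iter = 500) {
  sampler_config(chains = 2, warmup = warmup, iter = iter, seed = seed,
                 max_retries = 0)
}

fixture_aif <- function(seed = 11) sample_aif_parameters(1, seed = seed)

# fine-grid trapezoidal convolution of the parametric AIF with e^{-theta s}
trapz_conv <- function(aif, theta, t, dt = 0.001) {
  s <- seq(0, t, by = dt)
  f <- aif_value(aif, s) * exp(-theta * (t - s))
  sum((f[-1] + f[-length(f)]) / 2) * dt
}

# random valid rate constants in tracer-plausible ranges
random_rc <- function() {
  outcomes_to_rates(K1 = exp(stats::runif(1, log(0.05), log(0.3))),
                    VND = exp(stats::runif(1, log(0.4), log(3))),
                    BPND = exp(stats::runif(1, log(0.3), log(8))),
                    k4 = exp(stats::runif(1, log(0.01), log(0.2))),
                    vB = exp(stats::runif(1, log(0.01), log(0.1))))
}

# log outcomes table from a simulation truth, for comparator tests
truth_outcomes <- function(truth, column = "logBPND") {
  data.frame(subject = truth$tacs$subject, region = truth$tacs$region,
             group = truth$tacs$group, value = truth$tacs[[column]],
             stringsAsFactors = FALSE)
}
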