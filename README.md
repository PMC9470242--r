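# petpool

Hierarchical multifactor Bayesian modelling of PET time-activity curves.

## The problem

Quantitative PET estimates regional binding of a radiotracer by fitting a
pharmacokinetic model to each time-activity curve (TAC): the radioactivity
concentration of a brain region across acquisition frames. The conventional
workflow fits the two-tissue compartment (2TC) model to every TAC
independently by weighted nonlinear least squares and then compares the
resulting binding estimates between groups in a second stage. Because PET
samples are small (radiation exposure and cost cap recruitment) and each TAC
carries limited information about five kinetic parameters, that two-stage
approach is noisy and underpowered.

`petpool` implements the alternative: one joint hierarchical model for all
TACs of a study that partially pools kinetic parameters across subjects,
regions, and subject-by-region curves simultaneously, and performs the group
comparison inside the same posterior. Borrowing strength across the whole
dataset — including across *parameters*, through estimated correlation
matrices — stabilises each curve's estimates and substantially improves
power without inflating the false positive rate.

## The model

Measured frame values follow

    C_T(t) = (1 - vB) * (IRF (x) C_P)(t) + vB * C_B(t)

where `C_P` is the metabolite-corrected arterial input function (AIF),
modelled as a linear rise followed by a tri-exponential decay so that the
convolution with the bi-exponential 2TC impulse response is available in
closed form, `C_B` is whole blood, and `vB` the fractional blood volume.
The kinetic parameters are expressed as (K1, V_ND, BP_ND, k4, vB), with

    V_T = (K1/k2)(1 + k3/k4),  V_ND = K1/k2,  BP_P = V_ND * BP_ND,
    BP_ND = k3/k4,

all modelled on the log scale. For subject j, region k:

    log K1[j,k]    = a_K1   + X b_K1   + tau_K1[j]              + theta-level residual
    log V_ND[j,k]  = a_VND  + X b_VND  + tau_VND[j]  + ups_VND[k]  + ...
    log BP_ND[j,k] = a_BPND + X b_BPND + tau_BPND[j]             + ...
    log k4[j,k]    = a_k4            + tau_k4[j]   + ups_k4[k]   + ...

with multivariate-normal pooling of the subject deviations
(tau ~ MVN(0, Sigma_Subject) over the four log parameters), of regional
deviations for V_ND and k4 (regional differences in K1 and BP_ND are
unpooled fixed effects), and of TAC-level deviations; `vB` and the
measurement-error scale are pooled univariately with no TAC-level term. The
error SD follows a log-linear model with subject and region deviations plus
a penalised thin-plate smooth over frame time. Correlation matrices carry
LKJ priors, hierarchy SDs half-Student-t(3) priors with scales decreasing
from subject to region to TAC level.

Posterior sampling uses the package's own blockwise MCMC (see the methods
vignette): covariance-adapted Metropolis updates for the per-TAC kinetic
parameters, exact Gibbs draws for the linear-Gaussian layer, and interweaved
scale and ridge moves for the hierarchical degeneracies. A conventional
multi-start weighted NLS baseline, a full synthetic-study generator, and a
power/false-positive evaluation harness (Welch t-tests, mixed-effects
comparator, logspline power estimation with bootstrap intervals) round out
the package.

## Worked example

Simulate a two-group study (6 subjects per group, three regions, a 20%
group difference in BP_ND, frame noise at 10% of the mean TAC value), fit
the hierarchical model, and compare with the conventional analyses:

```r
library(petpool)

cfg <- simulation_config(
  n_per_group = 6,
  regions = c("DLPFC", "Hippocampus", "DRN"),
  schedule = frame_schedule(
    start = c(0, 0.5, 1, 2, 4, 8, 12, 20, 30, 45, 60, 80),
    end   = c(0.5, 1, 2, 4, 8, 12, 20, 30, 45, 60, 80, 100)),
  effect_log_bpnd = effect_from_percent(0.20),   # 0.1823
  seed = 701)
study <- simulate_study(cfg)

fit <- fit_hier_2tc(study,
                    sampler = sampler_config(chains = 2, warmup = 800,
                                             iter = 500, seed = 5,
                                             max_retries = 0))
eff <- effect_draws(fit, "BPND", "group2")
iv89 <- posterior_interval(eff, level = 0.89)
decide_group_difference(posterior_interval(eff, level = 0.95))
```

The posterior summary this produces (89% credible interval on the log
scale, with the directional probability Pd):

    effect (log): point 0.379, 89% CrI [0.113, 0.680], Pd 0.990
    effect (%BPND): 46.1%, 89% CrI [12.0%, 97.4%]
    95% decision: positive

so the model detects the group difference (the point estimate overshoots
the true 20% in this particular draw; across replicates the estimates
centre near the truth). The conventional analyses on the *same* study miss
it — LME on NLS log BP_P gives p = 0.405 and the per-region Welch t-tests
give p = 0.98, 0.65, 0.25:

```r
nls <- fit_nls_study(study, weight_scheme = "oracle", seed = 1)
comparator_tests(data.frame(subject = nls$subject, region = nls$region,
                            group = nls$group, value = log(nls$BPP)))
```

A command-line front end over the same functions is provided at
`inst/cli/petpool.R` (`simulate`, `fit-nls`, `fit-simba`, `evaluate`).

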