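#' Default ground-truth population parameters for study simulation
#'
#' A documented configuration standing in for posterior-mean population values
#' of a serotonergic tracer study: log-scale global means (alpha) for
#' \code{K1}, \code{VND}, \code{BPND}, \code{k4}, \code{vB}; a fixed regional
#' deviation profile for nine brain regions; between-subject and
#' between-TAC standard deviations and correlation matrices for the four
#' multivariately pooled log parameters (\code{K1}, \code{VND}, \code{BPND},
#' \code{k4}); univariate subject-level deviations for \code{vB} and the
#' measurement-error scale; and a smooth time component for the error model
#' derived from frame durations (error SD proportional to
#' 1/sqrt(duration), centred on the log scale).
#'
#' The between-subject SD of log \code{BPND} (0.331) is chosen so that a 20%
#' group difference (0.182 in log units) corresponds to a standardised mean
#' difference (Cohen's d) of 0.55. All values are overridable.
#'
#' @return A list of class \code{"population_parameters"}.
#' @export
default_population_parameters <- function() {
  regions <- c("DLPFC", "MPFC", "Hippocampus", "Amygdala", "Parahippocampus",
               "Insula", "ACC", "PCC", "DRN")
  profile <- data.frame(
    region = regions,
    dK1   = c(0.15, 0.10, 0.05, 0.00, -0.05, 0.10, 0.05, 0.00, -0.35),
    dVND  = c(0.05, 0.02, 0.00, -0.03, 0.01, -0.02, 0.03, 0.00, -0.06),
    dBPND = c(0.40, 0.30, 0.50, 0.20, 0.10, 0.00, -0.20, -0.40, -0.90),
    dk4   = c(0.02, 0.01, -0.02, 0.03, 0.00, -0.01, 0.02, -0.03, -0.02),
    dvB   = c(0.05, 0.02, -0.05, 0.00, -0.02, 0.08, 0.05, 0.02, 0.15),
    dsigma = c(0.00, -0.05, 0.05, 0.10, 0.00, -0.05, -0.10, -0.05, 0.60),
    stringsAsFactors = FALSE
  )
  corr_subject <- matrix(c(
    1.00, 0.50, 0.30, 0.20,
    0.50, 1.00, 0.60, 0.30,
    0.30, 0.60, 1.00, 0.20,
    0.20, 0.30, 0.20, 1.00), 4, 4,
    dimnames = list(c("K1", "VND", "BPND", "k4"), c("K1", "VND", "BPND", "k4")))
  corr_tac <- matrix(c(
    1.00, 0.40, 0.25, 0.20,
    0.40, 1.00, 0.45, 0.25,
    0.25, 0.45, 1.00, 0.15,
    0.20, 0.25, 0.15, 1.00), 4, 4,
    dimnames = dimnames(corr_subject))
  structure(list(
    alpha = c(K1 = log(0.10), VND = log(1.0), BPND = log(2.0),
              k4 = log(0.05), vB = log(0.05)),
    regional_profile = profile,
    sd_subject = c(K1 = 0.15, VND = 0.20, BPND = 0.331, k4 = 0.10),
    corr_subject = corr_subject,
    sd_tac = c(K1 = 0.10, VND = 0.10, BPND = 0.15, k4 = 0.10),
    corr_tac = corr_tac,
    sd_vB_subject = 0.25,
    sd_sigma_subject = 0.20
  ), class = "population_parameters")
}

#' Simulation configuration
#'
#' @param n_per_group Subjects per group (two groups are always generated).
#' @param regions Character vector of region names; must be a subset of the
#'   population regional profile.
#' @param schedule A \code{frame_schedule}; default \code{\link{default_schedule}}.
#' @param effect_log_bpnd Group difference added to log \code{BPND} of group 2
#'   (0.182 corresponds to a 20\% difference).
#' @param error_scale Global measurement-error SD as a fraction of the mean
#'   TAC value (default 0.10).
#' @param correlations_on If \code{FALSE}, subject- and TAC-level deviations
#'   are drawn from independent normals instead of the multivariate normals.
#' @param seed Integer seed; the full study generation is reproducible from
#'   the configuration alone.
#' @return A list of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_per_group, regions = NULL,
                              schedule = default_schedule(),
                              effect_log_bpnd = 0, error_scale = 0.10,
                              correlations_on = TRUE, seed = 1L) {
  stopifnot(n_per_group >= 1, error_scale >= 0,
            inherits(schedule, "frame_schedule"))
  structure(list(n_per_group = as.integer(n_per_group), regions = regions,
                 schedule = schedule, effect_log_bpnd = effect_log_bpnd,
                 error_scale = error_scale,
                 correlations_on = isTRUE(correlations_on),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Convert a proportional group difference to a log-scale effect
#'
#' A multiplicative difference of \code{pct} (e.g. 0.20 for 20\%) in
#' \code{BPND} corresponds to an additive difference of \code{log(1 + pct)}
#' on the log scale.
#'
#' @param pct Proportional difference.
#' @return Log-scale effect size.
#' @export
effect_from_percent <- function(pct) log(1 + pct)

chol_or_stop <- function(S, what) {
  if (all(S == 0)) return(matrix(0, nrow(S), ncol(S)))  # degenerate hierarchy
  out <- try(chol(S), silent = TRUE)
  if (inherits(out, "try-error"))
    stop(what, " covariance matrix is not positive definite")
  out
}

#' Sample the ground truth of a simulated study
#'
#' Draws subject-level deviations (multivariate normal across log \code{K1},
#' \code{VND}, \code{BPND}, \code{k4}, plus univariate \code{vB} and error
#' terms) and TAC-level deviations for every subject-by-region curve, holds
#' the regional deviations fixed at the configured profile, adds the group
#' effect to log \code{BPND} of group 2, and assembles per-TAC rate constants
#' and binding outcomes.
#'
#' @param cfg A \code{simulation_config}.
#' @param pop A \code{population_parameters} list (default
#'   \code{\link{default_population_parameters}}).
#' @return A list of class \code{"simulation_truth"}: subject table, regional
#'   profile, deviation draws, and a per-TAC parameter table with true rate
#'   constants and outcomes.
#' @export
sample_truth <- function(cfg, pop = default_population_parameters()) {
  stopifnot(inherits(cfg, "simulation_config"))
  regions <- if (is.null(cfg$regions)) pop$regional_profile$region else cfg$regions
  if (!all(regions %in% pop$regional_profile$region))
    stop("unknown region(s): ",
         paste(setdiff(regions, pop$regional_profile$region), collapse = ", "))
  prof <- pop$regional_profile[match(regions, pop$regional_profile$region), ]
  J <- 2L * cfg$n_per_group; K <- length(regions)
  set.seed(cfg$seed)

  S_subj <- diag(pop$sd_subject) %*% pop$corr_subject %*% diag(pop$sd_subject)
  S_tac <- diag(pop$sd_tac) %*% pop$corr_tac %*% diag(pop$sd_tac)
  if (!cfg$correlations_on) {
    S_subj <- diag(pop$sd_subject^2); S_tac <- diag(pop$sd_tac^2)
  }
  U_subj <- chol_or_stop(S_subj, "subject"); U_tac <- chol_or_stop(S_tac, "TAC")

  subjects <- data.frame(
    subject = sprintf("s%02d", seq_len(J)),
    group = rep(c(1L, 2L), each = cfg$n_per_group),
    stringsAsFactors = FALSE)
  tau <- matrix(stats::rnorm(J * 4), J, 4) %*% U_subj
  colnames(tau) <- c("K1", "VND", "BPND", "k4")
  tau_vB <- stats::rnorm(J, 0, pop$sd_vB_subject)
  tau_sigma <- stats::rnorm(J, 0, pop$sd_sigma_subject)
  phi <- matrix(stats::rnorm(J * K * 4), J * K, 4) %*% U_tac
  colnames(phi) <- colnames(tau)

  idx <- expand.grid(k = seq_len(K), j = seq_len(J))[, c("j", "k")]
  eff <- ifelse(subjects$group[idx$j] == 2L, cfg$effect_log_bpnd, 0)
  tacs <- data.frame(
    subject = subjects$subject[idx$j], region = regions[idx$k],
    group = subjects$group[idx$j],
    logK1 = pop$alpha["K1"] + prof$dK1[idx$k] + tau[idx$j, "K1"] + phi[, "K1"],
    logVND = pop$alpha["VND"] + prof$dVND[idx$k] + tau[idx$j, "VND"] + phi[, "VND"],
    logBPND = pop$alpha["BPND"] + prof$dBPND[idx$k] + eff +
      tau[idx$j, "BPND"] + phi[, "BPND"],
    logk4 = pop$alpha["k4"] + prof$dk4[idx$k] + tau[idx$j, "k4"] + phi[, "k4"],
    logvB = pop$alpha["vB"] + prof$dvB[idx$k] + tau_vB[idx$j],
    log_sigma_dev = tau_sigma[idx$j] + prof$dsigma[idx$k],
    stringsAsFactors = FALSE, row.names = NULL)
  tacs$K1 <- exp(tacs$logK1); tacs$VND <- exp(tacs$logVND)
  tacs$BPND <- exp(tacs$logBPND); tacs$k4 <- exp(tacs$logk4)
  tacs$vB <- exp(tacs$logvB)
  tacs$k2 <- tacs$K1 / tacs$VND; tacs$k3 <- tacs$BPND * tacs$k4
  tacs$VT <- tacs$VND * (1 + tacs$BPND); tacs$BPP <- tacs$VND * tacs$BPND

  structure(list(config = cfg, population = pop, regions = regions,
                 subjects = subjects, tau = tau, tau_vB = tau_vB,
                 tau_sigma = tau_sigma, phi = phi, tacs = tacs,
                 f_t = smooth_time_component(cfg$schedule)),
            class = "simulation_truth")
}

#' Smooth time component of the measurement-error model
#'
#' The generator's "true" smooth function over frame time: error SD scales
#' with 1/sqrt(frame duration), expressed as a centred log-scale offset per
#' frame. Longer frames accumulate more counts and are less noisy.
#'
#' @param sched A \code{frame_schedule}.
#' @return Numeric vector, one centred log-SD offset per frame.
#' @export
smooth_time_component <- function(sched) {
  f <- -0.5 * log(sched$duration)
  f - mean(f)
}

#' Per-frame measurement-error standard deviation
#'
#' \deqn{SD = \exp(\log(\textrm{error\_scale} \times \textrm{mean\_tac}) +
#'   \tau_\sigma + \upsilon_\sigma + f(t))}
#' where \code{tau_sigma} and \code{upsilon_sigma} are subject- and
#' region-level log-SD deviations and \code{f} the smooth time component.
#'
#' @param error_scale Global SD as a fraction of \code{mean_tac} (>= 0).
#' @param mean_tac Mean TAC value of the study (kBq/mL).
#' @param tau_sigma,upsilon_sigma Log-scale deviations (scalars).
#' @param f_t Smooth time component value(s); vectorised over frames.
#' @return Per-frame SD(s), kBq/mL.
#' @export
noise_sd <- function(error_scale, mean_tac, tau_sigma = 0, upsilon_sigma = 0,
                     f_t = 0) {
  if (error_scale < 0) stop("error_scale must be >= 0")
  if (error_scale == 0) return(rep(0, length(f_t)))
  exp(log(error_scale * mean_tac) + tau_sigma + upsilon_sigma + f_t)
}

#' Draw random arterial input function parameters
#'
#' Parametric stand-in for resampling measured blood curves: draws AIF
#' parameters from documented ranges (onset 0.3-1 min, rise 0.3-1.5 min,
#' decay rates spread over fast/medium/slow decades, peak 25-80 kBq/mL) with
#' the rise gradient set so the curve is continuous at the peak.
#'
#' @param n Number of AIFs to draw.
#' @param seed Optional integer seed.
#' @return A list of \code{aif_parameters} (length \code{n}), or a single
#'   object if \code{n = 1}.
#' @export
sample_aif_parameters <- function(n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  runiflog <- function(lo, hi) exp(stats::runif(1, log(lo), log(hi)))
  out <- lapply(seq_len(n), function(i) {
    t0 <- stats::runif(1, 0.3, 1.0)
    rise <- stats::runif(1, 0.3, 1.5)
    tp <- t0 + rise
    lambda <- c(runiflog(1.5, 6), runiflog(0.1, 0.5), runiflog(0.005, 0.03))
    peak <- runiflog(25, 80)
    # proportions of the peak carried by each exponential at tp
    p1 <- stats::runif(1, 0.70, 0.85)
    p2 <- stats::runif(1, 0.10, min(0.20, 1 - p1 - 0.02))
    p <- c(p1, p2, 1 - p1 - p2)
    A <- peak * p * exp(lambda * rise)  # continuous at tp by construction
    aif_parameters(t0 = t0, b = peak / rise, tp = tp, A = A, lambda = lambda)
  })
  if (n == 1) out[[1]] else out
}

# Whole-blood curve for a subject: the plasma AIF without metabolite
# correction has a heavier slow tail; modelled by inflating the slower
# exponential amplitudes.
whole_blood_curve <- function(aif, tail_mult = c(1, 1.5, 3)) {
  aif_parameters(t0 = aif$t0, b = aif$b, tp = aif$tp,
                 A = aif$A * tail_mult, lambda = aif$lambda)
}

#' Generate a full synthetic study
#'
#' Simulates every TAC of a two-group study: noise-free curves from the 2TC
#' forward model at the true per-TAC parameters, plus Gaussian noise whose
#' per-frame SD follows the structured error model (global scale a fraction
#' of the study mean TAC value, log-additive subject and region deviations,
#' smooth time component). Whole-blood frame means are derived from a
#' heavier-tailed variant of each subject's AIF.
#'
#' @param truth A \code{simulation_truth} from \code{\link{sample_truth}}.
#' @param aifs A list of per-subject \code{aif_parameters} (length = number
#'   of subjects), or \code{NULL} to draw them from
#'   \code{\link{sample_aif_parameters}}.
#' @param noise_seed Integer seed for the measurement noise (and AIF draws if
#'   \code{aifs} is \code{NULL}); default derives from the configuration seed.
#' @return A list of class \code{"study_dataset"}: \code{tacs} long table
#'   (subject, region, frame_start, frame_end, value), \code{schedule},
#'   \code{aifs}, \code{blood} (subject x frame whole-blood means),
#'   \code{covariates} (subject, group), and the \code{truth} block.
#' @export
generate_study <- function(truth, aifs = NULL, noise_seed = NULL) {
  stopifnot(inherits(truth, "simulation_truth"))
  cfg <- truth$config
  sched <- cfg$schedule
  J <- nrow(truth$subjects)
  if (is.null(noise_seed)) noise_seed <- cfg$seed + 1000L
  set.seed(noise_seed)
  if (is.null(aifs)) {
    aifs <- sample_aif_parameters(J)
  }
  if (length(aifs) != J) stop("need one AIF per subject (", J, ")")
  names(aifs) <- truth$subjects$subject

  cb <- t(vapply(aifs, function(a)
    parametric_frame_means(whole_blood_curve(a), sched), numeric(length(sched$midpoint))))
  rownames(cb) <- truth$subjects$subject

  nI <- length(sched$midpoint)
  tt <- truth$tacs
  mu <- matrix(0, nrow(tt), nI)
  for (r in seq_len(nrow(tt))) {
    j <- match(tt$subject[r], truth$subjects$subject)
    rc <- rate_constants(tt$K1[r], tt$k2[r], tt$k3[r], tt$k4[r], tt$vB[r])
    mu[r, ] <- predict_tac(rc, aifs[[j]], cb[j, ], sched)$values
  }
  mean_tac <- mean(mu)
  sds <- t(vapply(seq_len(nrow(tt)), function(r)
    noise_sd(cfg$error_scale, mean_tac, tau_sigma = tt$log_sigma_dev[r],
             f_t = truth$f_t), numeric(nI)))
  if (cfg$error_scale == 0) sds[] <- 0
  y <- mu + matrix(stats::rnorm(length(mu), 0, 1), nrow(mu), nI) * sds

  tacs_long <- data.frame(
    subject = rep(tt$subject, each = nI), region = rep(tt$region, each = nI),
    frame_start = rep(sched$start, nrow(tt)),
    frame_end = rep(sched$end, nrow(tt)),
    value = as.vector(t(y)), stringsAsFactors = FALSE)

  covariates <- truth$subjects
  covariates$group <- as.character(covariates$group)
  covariates$age <- round(stats::runif(J, 20, 65), 1)
  covariates$sex <- sample(c("F", "M"), J, replace = TRUE)

  structure(list(tacs = tacs_long, schedule = sched, aifs = aifs, blood = cb,
                 covariates = covariates, truth = truth, mean_tac = mean_tac,
                 noise_free = mu, noise_sd = sds),
            class = "study_dataset")
}

#' Simulate a study in one call
#'
#' Convenience wrapper: \code{\link{sample_truth}} then
#' \code{\link{generate_study}}.
#'
#' @inheritParams sample_truth
#' @inheritParams generate_study
#' @return A \code{study_dataset}.
#' @export
simulate_study <- function(cfg, pop = default_population_parameters(),
                           aifs = NULL, noise_seed = NULL) {
  generate_study(sample_truth(cfg, pop), aifs = aifs, noise_seed = noise_seed)
}
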