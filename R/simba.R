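#' Covariate specification for the hierarchical model
#'
#' Names the covariate terms entering the linear predictor of each log
#' parameter. The term \code{"region"} expands to reference-coded region
#' dummies (first region absorbed into the intercept) and is how the
#' unpooled regional differences in \code{K1} and \code{BPND} are expressed;
#' other terms name columns of the study covariate table (categorical
#' columns are treatment-coded, continuous columns centred).
#'
#' @param K1,VND,BPND,k4,vB,sigma Character vectors of term names (or
#'   \code{NULL} for an intercept-only predictor).
#' @return A list of class \code{"covariate_spec"}.
#' @export
covariate_spec <- function(K1 = "region", VND = NULL,
                           BPND = c("region", "group"), k4 = NULL,
                           vB = NULL, sigma = NULL) {
  structure(list(K1 = K1, VND = VND, BPND = BPND, k4 = k4, vB = vB,
                 sigma = sigma), class = "covariate_spec")
}

#' Prior configuration
#'
#' Weakly-informative defaults: normal priors on the log-scale global
#' intercepts centred at plausible tracer values; zero-centred normal priors
#' on covariate coefficients (wider for the unpooled regional differences);
#' zero-centred half-Student-t (3 df) priors on hierarchy SDs with scales
#' decreasing from subject to region to TAC level; LKJ priors on the
#' correlation matrices with \code{eta = 1} (subject) and \code{eta = 2}
#' (region, TAC).
#'
#' @param alpha_loc,alpha_scale Named length-6 vectors (K1, VND, BPND, k4,
#'   vB, sigma) of normal prior locations/scales for the intercepts; the
#'   sigma location may be \code{NA} to be centred on the data at fit time.
#' @param beta_scale Default SD of coefficient priors.
#' @param beta_scale_region SD for unpooled regional-difference coefficients.
#' @param sd_scale_subject,sd_scale_region,sd_scale_tac Half-t scales for the
#'   multivariate hierarchy SDs (lengths 4, 2, 4).
#' @param sd_scale_vB,sd_scale_sigma Half-t scales (subject, region) for the
#'   univariate hierarchies.
#' @param sd_scale_f Half-t scale of the smooth-term SD.
#' @param lkj_eta LKJ shapes for (subject, region, TAC) correlation matrices.
#' @return A list of class \code{"prior_config"}.
#' @export
prior_config <- function(
    alpha_loc = c(K1 = log(0.10), VND = log(1.0), BPND = log(2.0),
                  k4 = log(0.05), vB = log(0.05), sigma = NA),
    alpha_scale = c(K1 = 0.25, VND = 0.5, BPND = 0.5, k4 = 0.25,
                    vB = 0.5, sigma = 1.0),
    beta_scale = 0.5, beta_scale_region = 1.5,
    sd_scale_subject = rep(0.3, 4), sd_scale_region = rep(0.15, 2),
    sd_scale_tac = rep(0.1, 4), sd_scale_vB = c(0.3, 0.15),
    sd_scale_sigma = c(0.3, 0.15), sd_scale_f = 0.5,
    lkj_eta = c(subject = 1, region = 2, tac = 2)) {
  stopifnot(all(alpha_scale > 0), all(sd_scale_subject > 0), all(lkj_eta > 0))
  structure(list(alpha_loc = alpha_loc, alpha_scale = alpha_scale,
                 beta_scale = beta_scale, beta_scale_region = beta_scale_region,
                 sd_scale_subject = sd_scale_subject,
                 sd_scale_region = sd_scale_region,
                 sd_scale_tac = sd_scale_tac, sd_scale_vB = sd_scale_vB,
                 sd_scale_sigma = sd_scale_sigma, sd_scale_f = sd_scale_f,
                 lkj_eta = lkj_eta), class = "prior_config")
}

#' Sampler configuration
#'
#' @param chains Number of MCMC chains (>= 2).
#' @param warmup,iter Warmup (adaptation) and retained iterations per chain.
#' @param seed Integer seed.
#' @param max_retries Maximum reseeded refits on non-convergence.
#' @return A list of class \code{"sampler_config"}.
#' @export
sampler_config <- function(chains = 2, warmup = 500, iter = 500, seed = 1L,
                           max_retries = 3) {
  stopifnot(chains >= 2, warmup >= 1, iter >= 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 iter = as.integer(iter), seed = as.integer(seed),
                 max_retries = as.integer(max_retries)),
            class = "sampler_config")
}

# expand one parameter's covariate terms into a design matrix at TAC level
expand_terms <- function(terms, tac_tab, covariates, region_levels) {
  if (is.null(terms) || length(terms) == 0)
    return(matrix(0, nrow(tac_tab), 0))
  cols <- list()
  cov_row <- match(tac_tab$subject, covariates$subject)
  for (tm in terms) {
    if (tm == "region") {
      for (rl in region_levels[-1]) {
        x <- as.numeric(tac_tab$region == rl)
        cols[[paste0("region", rl)]] <- x
      }
    } else {
      if (!tm %in% names(covariates))
        stop("covariate '", tm, "' not found in the covariate table")
      v <- covariates[[tm]][cov_row]
      if (any(is.na(v)))
        stop("missing values in covariate '", tm, "' for subject(s): ",
             paste(unique(tac_tab$subject[is.na(v)]), collapse = ", "))
      if (is.numeric(v)) {
        cols[[tm]] <- v - mean(covariates[[tm]])
      } else {
        f <- factor(v)
        for (lv in levels(f)[-1]) cols[[paste0(tm, lv)]] <- as.numeric(f == lv)
      }
    }
  }
  out <- do.call(cbind, cols)
  colnames(out) <- names(cols)
  out
}

#' Build design matrices and index maps for the hierarchical model
#'
#' Expands the covariate specification into per-parameter design matrices at
#' the TAC level, with reference-coded region dummies for the unpooled
#' regional differences, and constructs the subject/region index vectors.
#'
#' @param tac_tab Data frame with one row per TAC: columns \code{subject},
#'   \code{region}.
#' @param covariates Covariate table with one row per subject.
#' @param spec A \code{covariate_spec}.
#' @return A list: \code{X} (list of six design matrices in parameter order
#'   K1, VND, BPND, k4, vB, sigma), \code{subj}/\code{reg} (0-based index
#'   vectors), \code{subjects}, \code{regions} (level vectors).
#' @export
build_design <- function(tac_tab, covariates, spec = covariate_spec()) {
  stopifnot(inherits(spec, "covariate_spec"))
  if (!all(tac_tab$subject %in% covariates$subject))
    stop("subject(s) absent from covariates: ",
         paste(setdiff(tac_tab$subject, covariates$subject), collapse = ", "))
  subjects <- unique(covariates$subject)
  regions <- unique(tac_tab$region)
  X <- lapply(spec, expand_terms, tac_tab = tac_tab, covariates = covariates,
              region_levels = regions)
  list(X = X, subj = match(tac_tab$subject, subjects) - 1L,
       reg = match(tac_tab$region, regions) - 1L,
       subjects = subjects, regions = regions, tac_tab = tac_tab)
}

# Parameter layout mirroring the C++ sampler; returns named index vector.
build_layout <- function(J, K, nT, nbf, pvec, mode, multivariate) {
  nm <- character(0)
  pk <- c("K1", "VND", "BPND", "k4", "vB", "sigma")
  na <- if (mode == 0) 6 else 4
  nm <- c(nm, paste0("alpha_", pk[seq_len(na)]))
  for (m in seq_len(na))
    if (pvec$p[m] > 0) nm <- c(nm, paste0("beta_", pk[m], "_", pvec$names[[m]]))
  nm <- c(nm, paste0("lsd_subject_", pk[1:4]), paste0("lsd_region_", pk[c(2, 4)]),
          paste0("lsd_tac_", pk[1:4]))
  if (mode == 0)
    nm <- c(nm, "lsd_vB_subject", "lsd_vB_region", "lsd_sigma_subject",
            "lsd_sigma_region", "lsd_f")
  pair_names <- function(d, vars) {
    out <- character(0)
    for (j in seq_len(d - 1)) for (i in (j + 1):d)
      out <- c(out, paste0(vars[i], ".", vars[j]))
    out
  }
  if (multivariate)
    nm <- c(nm, paste0("ycor_subject_", pair_names(4, pk[1:4])),
            paste0("ycor_region_", pair_names(2, pk[c(2, 4)])),
            paste0("ycor_tac_", pair_names(4, pk[1:4])))
  for (m in 1:4) nm <- c(nm, paste0("tau_", pk[m], "_", seq_len(J)))
  if (mode == 0) nm <- c(nm, paste0("tau_vB_", seq_len(J)),
                         paste0("tau_sigma_", seq_len(J)))
  for (m in 1:2) nm <- c(nm, paste0("up_", pk[c(2, 4)][m], "_", seq_len(K)))
  if (mode == 0) nm <- c(nm, paste0("up_vB_", seq_len(K)),
                         paste0("up_sigma_", seq_len(K)))
  if (mode == 0) for (m in 1:4) nm <- c(nm, paste0("theta_", pk[m], "_", seq_len(nT)))
  if (mode == 0 && nbf > 0) nm <- c(nm, paste0("c_f_", seq_len(nbf)))
  nm
}

# thin-plate smooth basis over frame midpoints (sum-to-zero constraint
# absorbed, diagonalised penalty; k basis functions before the constraint)
smooth_basis <- function(tmid, k = 8) {
  df <- data.frame(t = tmid)
  sm <- mgcv::smoothCon(mgcv::s(t, k = k, bs = "tp"), data = df,
                        absorb.cons = TRUE, diagonal.penalty = TRUE)[[1]]
  sm$X
}

assemble_priors <- function(priors, pvec, y = NULL) {
  aloc <- priors$alpha_loc
  if (is.na(aloc["sigma"])) {
    if (is.null(y)) aloc["sigma"] <- 0
    else aloc["sigma"] <- log(0.1 * mean(abs(y), na.rm = TRUE) + 1e-12)
  }
  bscale <- lapply(seq_along(pvec$names), function(m) {
    nms <- pvec$names[[m]]
    if (length(nms) == 0) return(numeric(0))
    ifelse(grepl("^region", nms), priors$beta_scale_region, priors$beta_scale)
  })
  list(alpha_loc = unname(aloc), alpha_scale = unname(priors$alpha_scale),
       beta_scale = bscale,
       sd_scale_subject = priors$sd_scale_subject,
       sd_scale_region = priors$sd_scale_region,
       sd_scale_tac = priors$sd_scale_tac,
       sd_scale_vB = priors$sd_scale_vB,
       sd_scale_sigma = priors$sd_scale_sigma,
       sd_scale_f = priors$sd_scale_f,
       lkj_eta = unname(priors$lkj_eta))
}

init_vector <- function(names, prior) {
  pk <- c("K1", "VND", "BPND", "k4", "vB", "sigma")
  x <- numeric(length(names))
  for (i in seq_along(names)) {
    nm <- names[i]
    x[i] <- if (startsWith(nm, "alpha_")) {
      m <- match(sub("alpha_", "", nm), pk)
      prior$alpha_loc[m] + 0.1 * stats::rnorm(1)
    } else if (startsWith(nm, "theta_")) {
      m <- match(sub("_[0-9]+$", "", sub("theta_", "", nm)), pk)
      prior$alpha_loc[m] + 0.3 * stats::rnorm(1)
    } else if (startsWith(nm, "lsd_")) {
      log(0.1) + 0.1 * stats::rnorm(1)
    } else if (startsWith(nm, "ycor_")) {
      0.02 * stats::rnorm(1)
    } else if (startsWith(nm, "beta_")) {
      0.05 * stats::rnorm(1)
    } else if (startsWith(nm, "tau_") || startsWith(nm, "up_")) {
      0.05 * stats::rnorm(1)
    } else {
      0.05 * stats::rnorm(1)
    }
  }
  x
}

#' Split-chain potential scale reduction factor
#'
#' Classic split-\eqn{\hat R}: each chain is halved, and the between/within
#' variance ratio computed over the resulting half-chains.
#'
#' @param x Iterations x chains matrix of draws for one parameter.
#' @return Scalar \eqn{\hat R} (1 when within-variance is zero everywhere and
#'   the halves agree; \code{Inf} when a zero-variance parameter differs
#'   across halves).
#' @export
split_rhat <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x) %/% 2L
  if (n < 2L) return(NA_real_)
  halves <- do.call(cbind, lapply(seq_len(ncol(x)), function(c)
    cbind(x[seq_len(n), c], x[n + seq_len(n), c])))
  mns <- colMeans(halves)
  vars <- apply(halves, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(mns)
  if (W < 1e-300) return(if (B < 1e-300) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence rule for a fitted model
#'
#' A fit is converged when no parameter has \eqn{\hat R} above 1.25 and at
#' most 2\% of parameters have \eqn{\hat R} above 1.05.
#'
#' @param rhat Named numeric vector of \eqn{\hat R} values (or a
#'   \code{hier_fit} object).
#' @return Logical flag.
#' @export
check_convergence <- function(rhat) {
  if (inherits(rhat, "hier_fit")) rhat <- rhat$rhat
  if (any(is.na(rhat))) stop("missing Rhat values")
  max(rhat) <= 1.25 && mean(rhat > 1.05) <= 0.02
}

run_chains <- function(data, par_names, prior, sampler, seed) {
  draws <- vector("list", sampler$chains)
  accept <- NULL
  for (ch in seq_len(sampler$chains)) {
    set.seed(seed + 7919L * ch)
    init <- init_vector(par_names, prior)
    out <- cpp_run_chain(data, init, sampler$warmup, sampler$iter)
    stopifnot(out$npar == length(par_names))
    d <- out$draws
    colnames(d) <- par_names
    draws[[ch]] <- d
    accept <- out$accept
  }
  rhat <- vapply(seq_along(par_names), function(i)
    split_rhat(sapply(draws, function(d) d[, i])), numeric(1))
  names(rhat) <- par_names
  list(draws = draws, rhat = rhat, accept = accept)
}

finish_fit <- function(runs, design, sampler, priors, multivariate, mode,
                       seeds_used, data) {
  draws <- do.call(rbind, runs$draws)
  chain <- rep(seq_along(runs$draws), each = sampler$iter)
  structure(list(draws = draws, chain = chain, rhat = runs$rhat,
                 converged = check_convergence(runs$rhat),
                 seeds = seeds_used, design = design, sampler = sampler,
                 priors = priors, multivariate = multivariate, mode = mode,
                 accept = runs$accept, data = data),
            class = "hier_fit")
}

#' Fit the hierarchical multifactor model to a study's TACs
#'
#' Samples the joint posterior of the population parameters and all hierarchy
#' deviations under the 2TC forward model: log-scale linear predictors for
#' \code{K1}, \code{VND}, \code{BPND}, \code{k4}, \code{vB} and the
#' measurement-error SD; multivariate partial pooling across subjects
#' (\code{K1}, \code{VND}, \code{BPND}, \code{k4}), regions (\code{VND},
#' \code{k4}) and TACs (all four); univariate pooling for \code{vB} and the
#' error scale (no TAC-level terms for either); and a penalised thin-plate
#' smooth over frame time in the error model. On non-convergence the model
#' is refit with a fresh seed, up to \code{max_retries} times; data and
#' priors are never altered between retries.
#'
#' @param study A \code{study_dataset}.
#' @param spec A \code{covariate_spec} (default: regional differences for
#'   \code{K1} and \code{BPND}, group membership on \code{BPND}).
#' @param priors A \code{prior_config}.
#' @param sampler A \code{sampler_config}.
#' @param multivariate If \code{FALSE}, all multivariate normal pooling
#'   distributions are replaced by independent normals with the same priors,
#'   and the fit contains no correlation parameters.
#' @param n_basis Number of thin-plate basis functions for the smooth time
#'   component of the error model.
#' @return A \code{hier_fit}: posterior \code{draws} (iterations x
#'   parameters, with chain index), per-parameter \code{rhat},
#'   \code{converged} flag, seeds used, and the design.
#' @export
fit_hier_2tc <- function(study, spec = covariate_spec(),
                         priors = prior_config(),
                         sampler = sampler_config(), multivariate = TRUE,
                         n_basis = 8) {
  stopifnot(inherits(study, "study_dataset"))
  sched <- study$schedule
  nI <- length(sched$midpoint)
  tac_tab <- unique(study$tacs[, c("subject", "region")])
  rownames(tac_tab) <- NULL
  design <- build_design(tac_tab, study$covariates, spec)
  nT <- nrow(tac_tab)
  J <- length(design$subjects); K <- length(design$regions)

  y <- matrix(NA_real_, nT, nI)
  for (r in seq_len(nT)) {
    sel <- study$tacs$subject == tac_tab$subject[r] &
      study$tacs$region == tac_tab$region[r]
    stopifnot(sum(sel) == nI)
    y[r, ] <- study$tacs$value[sel]
  }
  aifm <- vapply(design$subjects, function(s)
    as_aif_vector(study$aifs[[s]]), numeric(9))  # 9 x J, subjects in columns
  cb <- study$blood[design$subjects, , drop = FALSE]
  Bf <- smooth_basis(sched$midpoint, k = n_basis)

  pvec <- list(p = vapply(design$X, ncol, integer(1)),
               names = lapply(design$X, colnames))
  prior <- assemble_priors(priors, pvec, y = y)
  par_names <- build_layout(J, K, nT, ncol(Bf), pvec, 0L, multivariate)

  data <- list(mode = 0L, multivariate = multivariate, J = J, K = K, nT = nT,
               nI = nI, y = y, cb = cb, aif = aifm, tmid = sched$midpoint,
               Bf = Bf, wstar = rep(0, nI), subj = as.integer(design$subj),
               reg = as.integer(design$reg),
               X = lapply(design$X, function(x) as.matrix(x)), prior = prior)

  seeds_used <- integer(0)
  for (attempt in 0:sampler$max_retries) {
    seed <- sampler$seed + 104729L * attempt
    seeds_used <- c(seeds_used, seed)
    runs <- run_chains(data, par_names, prior, sampler, seed)
    if (check_convergence(runs$rhat) || attempt == sampler$max_retries)
      return(finish_fit(runs, design, sampler, priors, multivariate, 0L,
                        seeds_used, data))
  }
}

#' Fit the multifactor model to true (or estimated) parameter values
#'
#' The parameter-level variant: the observations are per-TAC log parameter
#' vectors (\code{K1}, \code{VND}, \code{BPND}, \code{k4}) rather than TACs,
#' with the TAC-level covariance acting as the residual covariance, the same
#' pooling structure across subjects and regions, and the same priors. Used
#' to quantify how much of the power advantage is attributable to the
#' multivariate specification rather than to TAC modelling.
#'
#' @param values Data frame with columns \code{subject}, \code{region},
#'   \code{logK1}, \code{logVND}, \code{logBPND}, \code{logk4}.
#' @param covariates Covariate table (one row per subject, including
#'   \code{group}).
#' @param spec A \code{covariate_spec} (vB/sigma terms are ignored).
#' @param priors,sampler,multivariate As in \code{\link{fit_hier_2tc}}.
#' @return A \code{hier_fit}.
#' @export
fit_hier_values <- function(values, covariates, spec = covariate_spec(),
                            priors = prior_config(),
                            sampler = sampler_config(), multivariate = TRUE) {
  tac_tab <- values[, c("subject", "region")]
  rownames(tac_tab) <- NULL
  design <- build_design(tac_tab, covariates, spec)
  nT <- nrow(tac_tab)
  J <- length(design$subjects); K <- length(design$regions)
  obs <- as.matrix(values[, c("logK1", "logVND", "logBPND", "logk4")])

  X4 <- design$X[1:4]
  pvec <- list(p = vapply(X4, ncol, integer(1)), names = lapply(X4, colnames))
  prior <- assemble_priors(priors, pvec)
  prior$alpha_loc <- prior$alpha_loc[1:4]
  prior$alpha_scale <- prior$alpha_scale[1:4]
  par_names <- build_layout(J, K, nT, 0L, pvec, 1L, multivariate)

  data <- list(mode = 1L, multivariate = multivariate, J = J, K = K, nT = nT,
               nI = 0L, obs = obs, subj = as.integer(design$subj),
               reg = as.integer(design$reg),
               X = lapply(X4, function(x) as.matrix(x)), prior = prior)

  seeds_used <- integer(0)
  for (attempt in 0:sampler$max_retries) {
    seed <- sampler$seed + 104729L * attempt
    seeds_used <- c(seeds_used, seed)
    runs <- run_chains(data, par_names, prior, sampler, seed)
    if (check_convergence(runs$rhat) || attempt == sampler$max_retries)
      return(finish_fit(runs, design, sampler, priors, multivariate, 1L,
                        seeds_used, data))
  }
}

#' Extract posterior draws of a coefficient
#'
#' @param fit A \code{hier_fit}.
#' @param parameter One of \code{"K1"}, \code{"VND"}, \code{"BPND"},
#'   \code{"k4"}, \code{"vB"}, \code{"sigma"}.
#' @param term Coefficient name as produced by \code{\link{build_design}}
#'   (e.g. \code{"group2"} for the group-2 effect).
#' @return Numeric vector of posterior draws (log-scale effect).
#' @export
effect_draws <- function(fit, parameter = "BPND", term = "group2") {
  stopifnot(inherits(fit, "hier_fit"))
  nm <- paste0("beta_", parameter, "_", term)
  if (!nm %in% colnames(fit$draws))
    stop("no such coefficient: ", nm)
  fit$draws[, nm]
}

#' Number of free parameters of the conventional per-TAC NLS analysis
#'
#' Five parameters (\code{K1}, \code{VND}, \code{BPND}, \code{k4},
#' \code{vB}) independently per TAC.
#'
#' @param n_subjects,n_regions Study dimensions.
#' @return Integer count.
#' @export
count_nls_parameters <- function(n_subjects, n_regions) {
  5L * as.integer(n_subjects) * as.integer(n_regions)
}

#' Number of TAC-level blood-volume parameters omitted by the model
#'
#' The hierarchical model estimates no TAC-level (subject-by-region)
#' deviations for \code{vB}; one parameter per TAC is thereby omitted.
#'
#' @param n_subjects,n_regions Study dimensions.
#' @return Integer count.
#' @export
count_phi_vb_omitted <- function(n_subjects, n_regions) {
  as.integer(n_subjects) * as.integer(n_regions)
}
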