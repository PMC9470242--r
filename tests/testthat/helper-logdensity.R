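# Independent R reimplementation of the hierarchical model's joint log
# density (likelihood + priors, same additive constants as the sampler).
# Used to verify the C++ density assembly at arbitrary parameter vectors.

replica_corr_chol <- function(yv, d) {
  z <- matrix(0, d, d); q <- 1
  for (j in seq_len(d - 1)) for (i in (j + 1):d) {
    z[i, j] <- tanh(yv[q]); q <- q + 1
  }
  L <- matrix(0, d, d); L[1, 1] <- 1
  for (i in 2:d) {
    s <- 0
    for (j in seq_len(i - 1)) {
      v <- z[i, j] * sqrt(max(0, 1 - s)); L[i, j] <- v; s <- s + v^2
    }
    L[i, i] <- sqrt(max(1e-12, 1 - s))
  }
  L
}

replica_mvn0 <- function(x, sd, Lr) {
  d <- length(x)
  L <- diag(sd) %*% Lr
  w <- forwardsolve(L, x)
  sum(-0.5 * w^2) - sum(log(diag(L)))
}

replica_half_t <- function(lsd, scale) {
  sd <- exp(lsd)
  -2 * log1p((sd / scale)^2 / 3) + lsd
}

replica_log_density <- function(data, par, par_names, study = NULL) {
  g <- function(nm) unname(par[par_names == nm])
  gs <- function(pref) unname(par[startsWith(par_names, pref)])
  pk <- c("K1", "VND", "BPND", "k4", "vB", "sigma")
  mode <- data$mode
  J <- data$J; K <- data$K; nT <- data$nT
  prior <- data$prior
  na <- if (mode == 0) 6 else 4

  alpha <- vapply(pk[seq_len(na)], function(p) g(paste0("alpha_", p)), numeric(1))
  betas <- lapply(pk[seq_len(na)], function(p) gs(paste0("beta_", p, "_")))
  sd_subj <- exp(gs("lsd_subject_")); sd_reg <- exp(gs("lsd_region_"))
  sd_tac <- exp(gs("lsd_tac_"))
  multivariate <- any(startsWith(par_names, "ycor_"))
  Lsu <- if (multivariate) replica_corr_chol(gs("ycor_subject_"), 4) else diag(4)
  Lre <- if (multivariate) replica_corr_chol(gs("ycor_region_"), 2) else diag(2)
  Lta <- if (multivariate) replica_corr_chol(gs("ycor_tac_"), 4) else diag(4)
  tau <- cbind(gs("tau_K1_"), gs("tau_VND_"), gs("tau_BPND_"), gs("tau_k4_"))
  up <- cbind(gs("up_VND_"), gs("up_k4_"))

  xb <- function(m, t) {
    if (length(betas[[m]]) == 0) return(0)
    sum(data$X[[m]][t, ] * betas[[m]])
  }
  layer_mean <- function(t) {
    j <- data$subj[t] + 1; k <- data$reg[t] + 1
    c(alpha[1] + xb(1, t) + tau[j, 1],
      alpha[2] + xb(2, t) + tau[j, 2] + up[k, 1],
      alpha[3] + xb(3, t) + tau[j, 3],
      alpha[4] + xb(4, t) + tau[j, 4] + up[k, 2])
  }

  ll <- 0
  if (mode == 0) {
    sd_vB <- exp(c(g("lsd_vB_subject"), g("lsd_vB_region")))
    sd_sig <- exp(c(g("lsd_sigma_subject"), g("lsd_sigma_region")))
    sd_f <- exp(g("lsd_f"))
    tauvB <- gs("tau_vB_"); tausig <- gs("tau_sigma_")
    upvB <- gs("up_vB_"); upsig <- gs("up_sigma_")
    cf <- gs("c_f_")
    fv <- as.vector(data$Bf %*% cf) + data$wstar
    theta <- cbind(gs("theta_K1_"), gs("theta_VND_"), gs("theta_BPND_"),
                   gs("theta_k4_"))
    for (t in seq_len(nT)) {
      j <- data$subj[t] + 1; k <- data$reg[t] + 1
      rc <- outcomes_to_rates(exp(theta[t, 1]), exp(theta[t, 2]),
                              exp(theta[t, 3]), exp(theta[t, 4]),
                              vB = exp(alpha[5] + xb(5, t) + tauvB[j] + upvB[k]))
      aif <- aif_parameters(data$aif[1, j], data$aif[2, j], data$aif[3, j],
                            A = data$aif[4:6, j], lambda = data$aif[7:9, j])
      # evaluate the forward model directly at the midpoints
      mu <- petpool:::cpp_predict_tac(rc$K1, rc$k2, rc$k3, rc$k4, rc$vB,
                                      data$aif[, j], data$cb[j, ], data$tmid, 0)
      lsig <- alpha[6] + xb(6, t) + tausig[j] + upsig[k] + fv
      ok <- is.finite(data$y[t, ])
      ll <- ll + sum(-0.5 * ((data$y[t, ok] - mu[ok]) / exp(lsig[ok]))^2 -
                       lsig[ok])
      ll <- ll + replica_mvn0(theta[t, ] - layer_mean(t), sd_tac, Lta)
    }
    for (j in seq_len(J))
      ll <- ll + sum(-0.5 * (tauvB[j] / sd_vB[1])^2 - log(sd_vB[1]),
                     -0.5 * (tausig[j] / sd_sig[1])^2 - log(sd_sig[1]))
    for (k in seq_len(K))
      ll <- ll + sum(-0.5 * (upvB[k] / sd_vB[2])^2 - log(sd_vB[2]),
                     -0.5 * (upsig[k] / sd_sig[2])^2 - log(sd_sig[2]))
    ll <- ll + sum(-0.5 * (cf / sd_f)^2 - log(sd_f))
    ll <- ll + replica_half_t(g("lsd_vB_subject"), prior$sd_scale_vB[1]) +
      replica_half_t(g("lsd_vB_region"), prior$sd_scale_vB[2]) +
      replica_half_t(g("lsd_sigma_subject"), prior$sd_scale_sigma[1]) +
      replica_half_t(g("lsd_sigma_region"), prior$sd_scale_sigma[2]) +
      replica_half_t(g("lsd_f"), prior$sd_scale_f)
  } else {
    for (t in seq_len(nT))
      ll <- ll + replica_mvn0(data$obs[t, ] - layer_mean(t), sd_tac, Lta)
  }
  for (j in seq_len(J)) ll <- ll + replica_mvn0(tau[j, ], sd_subj, Lsu)
  for (k in seq_len(K)) ll <- ll + replica_mvn0(up[k, ], sd_reg, Lre)

  ll <- ll + sum(-0.5 * ((alpha - prior$alpha_loc) / prior$alpha_scale)^2)
  for (m in seq_len(na))
    if (length(betas[[m]]))
      ll <- ll + sum(-0.5 * (betas[[m]] / prior$beta_scale[[m]])^2)
  ll <- ll + sum(mapply(replica_half_t, log(sd_subj), prior$sd_scale_subject)) +
    sum(mapply(replica_half_t, log(sd_reg), prior$sd_scale_region)) +
    sum(mapply(replica_half_t, log(sd_tac), prior$sd_scale_tac))
  if (multivariate) {
    lkj <- function(yv, d, eta) {
      q <- 1; s <- 0
      for (j in seq_len(d - 1)) for (i in (j + 1):d) {
        a <- eta + (d - 2 - (j - 1)) / 2
        s <- s - 2 * a * log(cosh(yv[q])); q <- q + 1
      }
      s
    }
    ll <- ll + lkj(gs("ycor_subject_"), 4, prior$lkj_eta[1]) +
      lkj(gs("ycor_region_"), 2, prior$lkj_eta[2]) +
      lkj(gs("ycor_tac_"), 4, prior$lkj_eta[3])
  }
  ll
}
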