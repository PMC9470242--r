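// Blockwise adaptive random-walk Metropolis sampler for the hierarchical
// multifactor 2TC model, in a centred parameterisation:
//
//   data layer:   y[t,i] ~ N(mu[t,i], sigma[t,i]^2), mu from the analytic
//                 2TC forward model at theta[t] = (logK1, logVND, logBPND,
//                 logk4) with blood volume and the structured error model;
//   TAC layer:    theta[t] ~ MVN(alpha + X beta + tau[j] + upsilon[k],
//                 Sigma_TAC)  (no upsilon for K1 and BPND);
//   hierarchies:  tau[j] ~ MVN(0, Sigma_Subject), upsilon[k] ~
//                 MVN(0, Sigma_Region); univariate normals for the vB and
//                 error-scale deviations (no TAC-level terms for either);
//   priors:       normals on alpha and beta, half-Student-t (3 df) on all
//                 hierarchy SDs, LKJ on correlation matrices via canonical
//                 partial correlations (tanh-transformed), N(0, sd_f^2) on
//                 the smooth-term coefficients.
//
// The centred parameterisation makes the expensive forward model local to
// per-TAC blocks: population, covariance and deviation updates touch only
// Gaussian layers (with cached tissue curves for the blood-volume and
// error-model blocks), so they cost almost nothing and are iterated more
// often per sweep.
//
// Two likelihood modes:
//   mode 0 ("tac"):    full model above.
//   mode 1 ("values"): theta is observed data (fitting the multifactor
//                      model directly to per-TAC parameter values); the
//                      TAC-level covariance acts as residual covariance and
//                      the vB / error-model components are absent.
#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

double conv_exp_one(const double* p, double theta, double t);
void tissue_predict(double K1, double k2, double k3, double k4,
                    const double* aif, const double* t, int n, double delay,
                    double* out);

namespace {

const double LOG_BAD = -1e10;

// Cholesky factor (column-major, d x d) of a correlation matrix from
// canonical partial correlations z = tanh(y), y over the strict lower
// triangle in column-major order.
void corr_chol_from_y(const double* y, int d, double* L) {
  std::vector<double> z(d * d, 0.0);
  int q = 0;
  for (int j = 0; j < d - 1; ++j)
    for (int i = j + 1; i < d; ++i) z[i + d * j] = std::tanh(y[q++]);
  for (int i = 0; i < d * d; ++i) L[i] = 0.0;
  for (int i = 0; i < d; ++i) {
    double sum = 0.0;
    for (int j = 0; j < i; ++j) {
      double v = z[i + d * j] * std::sqrt(std::max(0.0, 1.0 - sum));
      L[i + d * j] = v;
      sum += v * v;
    }
    L[i + d * i] = std::sqrt(std::max(1e-12, 1.0 - sum));
  }
}

// log MVN(x | 0, (diag(sd) Lr) (diag(sd) Lr)') up to the -d/2 log(2pi)
double mvn0_ll(const double* x, const double* sd, const double* Lr, int d) {
  double work[8], lp = 0.0;
  for (int i = 0; i < d; ++i) work[i] = x[i] / sd[i];
  for (int i = 0; i < d; ++i) {
    double s = work[i];
    for (int j = 0; j < i; ++j) s -= Lr[i + d * j] * work[j];
    const double dii = Lr[i + d * i];
    work[i] = s / dii;
    lp += -0.5 * work[i] * work[i] - std::log(dii * sd[i]);
  }
  return lp;
}

enum Kind {
  K_THETA,     // per-TAC theta block: forward model + TAC layer
  K_LAYER,     // population alpha/beta for PK parameters: TAC layer only
  K_TAU,       // subject PK deviations: TAC layer (subject) + tau density
  K_UP,        // region PK deviations: TAC layer (region) + upsilon density
  K_SIG_TAC,   // Sigma_TAC parameters: TAC layer, all TACs
  K_SIG_SUBJ,  // Sigma_Subject parameters: tau densities only
  K_SIG_REG,   // Sigma_Region parameters: upsilon densities only
  K_VBSIG_G,   // alpha/beta for vB and error scale: data layer, all TACs
  K_VBSIG_J,   // subject vB/error deviations: data layer (subject) + priors
  K_VBSIG_K,   // region vB/error deviations: data layer (region) + priors
  K_SMOOTH,    // smooth-term coefficients: data layer, all TACs (sigma only)
  K_HYPER,     // scale hyperparameters with closed Gaussian dependents
  K_ASIS,      // interweaved scale move: rescales one hierarchy SD together
               // with its deviations (non-centred coordinates held fixed),
               // breaking the funnel when a variance component collapses
  K_SPLIT,     // global V_T-preserving move along the weakly identified
               // V_ND / BP_ND split direction: shifts every log V_ND by
               // delta and adjusts every log BP_ND to keep each TAC's V_T
               // fixed (with the matching Jacobian)
  K_SHIFT,     // coherent translation moves along hierarchical location
               // redundancies: alpha_m with every theta_m (layer-invariant,
               // data decides) or alpha_m against every tau_m / upsilon_m
               // (likelihood-invariant, priors decide)
  K_GIBBS      // exact Gaussian full-conditional draws for the linear layer:
               // id 0 = tau (all subjects), 1 = upsilon (all regions),
               // 2 = (alpha, beta) jointly for the four PK parameters
};

// tiny in-place Cholesky for proposal covariances (d <= 8)
inline bool small_chol(const double* A, int d, double* L) {
  for (int i = 0; i < d * d; ++i) L[i] = 0.0;
  for (int j = 0; j < d; ++j) {
    double s = A[j + d * j];
    for (int k = 0; k < j; ++k) s -= L[j + d * k] * L[j + d * k];
    if (s <= 0.0) return false;
    L[j + d * j] = std::sqrt(s);
    for (int i = j + 1; i < d; ++i) {
      double v = A[i + d * j];
      for (int k = 0; k < j; ++k) v -= L[i + d * k] * L[j + d * k];
      L[i + d * j] = v / L[j + d * j];
    }
  }
  return true;
}

struct Block {
  std::vector<int> idx;
  Kind kind;
  int id;        // subject / region / TAC index where applicable
  int tm, tc;    // extra coordinates for translation moves
  int reps;      // updates per sweep
  double log_s;
  std::vector<double> mean, m2;   // m2 holds the d x d scatter matrix
  std::vector<double> prop_L;     // Cholesky of the adapted proposal shape
  bool have_L;
  long n_mom, ph_trials, ph_accepts, trials, accepts;
};

struct Sampler {
  bool last_accept;
  int mode, J, K, nT, nI, nbf;
  bool multivariate;
  NumericMatrix y, cb, aifm, Bf, obs;
  NumericVector tmid, wstar;
  std::vector<int> subj, reg;
  NumericMatrix X[6];
  int p[6];

  double a_loc[6], a_scale[6];
  std::vector<double> beta_scale[6];
  double sdsc_subj[4], sdsc_region[2], sdsc_tac[4];
  double sdsc_vB[2], sdsc_sig[2], sdsc_f;
  double eta[3];

  // layout
  int na;
  int i_alpha, i_beta[6], i_lsd_subj, i_lsd_region, i_lsd_tac, i_lsd_vB,
      i_lsd_sig, i_lsd_f, i_y_subj, i_y_region, i_y_tac, i_tau, i_tauvB,
      i_tausig, i_up, i_upvB, i_upsig, i_theta, i_cf;
  int n_y_subj, n_y_region, n_y_tac, npar;
  std::vector<double> y_shape;

  std::vector<double> par;

  // derived caches
  double Ls[16], Lr[4], Lt[16];
  double sd_subj[4], sd_region[2], sd_tac[4], sd_vB[2], sd_sig[2], sd_f;
  std::vector<double> xb;                    // nT x 6 linear predictors
  std::vector<double> f;                     // smooth + wstar per frame
  std::vector<double> tissue, mu;            // nT x nI forward-model caches
  std::vector<double> lsigb;                 // per-TAC error-model intercept
  std::vector<double> ll_data, ll_layer;     // per-TAC likelihood pieces
  std::vector<std::vector<int> > tacs_of_subj, tacs_of_reg;

  std::vector<Block> blocks;

  // ---- layout ---------------------------------------------------------
  void build_layout() {
    na = (mode == 0) ? 6 : 4;
    int off = 0;
    i_alpha = off; off += na;
    for (int m = 0; m < 6; ++m) {
      p[m] = (m < na) ? X[m].ncol() : 0;
      i_beta[m] = off; off += p[m];
    }
    i_lsd_subj = off; off += 4;
    i_lsd_region = off; off += 2;
    i_lsd_tac = off; off += 4;
    i_lsd_vB = off; off += (mode == 0) ? 2 : 0;
    i_lsd_sig = off; off += (mode == 0) ? 2 : 0;
    i_lsd_f = off; off += (mode == 0) ? 1 : 0;
    n_y_subj = multivariate ? 6 : 0;
    n_y_region = multivariate ? 1 : 0;
    n_y_tac = multivariate ? 6 : 0;
    i_y_subj = off; off += n_y_subj;
    i_y_region = off; off += n_y_region;
    i_y_tac = off; off += n_y_tac;
    i_tau = off; off += J * 4;
    i_tauvB = off; off += (mode == 0) ? J : 0;
    i_tausig = off; off += (mode == 0) ? J : 0;
    i_up = off; off += K * 2;
    i_upvB = off; off += (mode == 0) ? K : 0;
    i_upsig = off; off += (mode == 0) ? K : 0;
    i_theta = off; off += (mode == 0) ? nT * 4 : 0;
    i_cf = off; off += (mode == 0) ? nbf : 0;
    npar = off;

    y_shape.assign(npar, 0.0);
    if (multivariate) {
      fill_shape(i_y_subj, 4, eta[0]);
      fill_shape(i_y_region, 2, eta[1]);
      fill_shape(i_y_tac, 4, eta[2]);
    }
  }

  void fill_shape(int base, int d, double e) {
    int q = 0;
    for (int j = 0; j < d - 1; ++j)
      for (int i = j + 1; i < d; ++i)
        y_shape[base + q++] = e + 0.5 * (d - 2 - j);
  }

  // ---- derived caches --------------------------------------------------
  void derive_chols() {
    double yzero[6] = {0, 0, 0, 0, 0, 0};
    corr_chol_from_y(multivariate ? &par[i_y_subj] : yzero, 4, Ls);
    corr_chol_from_y(multivariate ? &par[i_y_region] : yzero, 2, Lr);
    corr_chol_from_y(multivariate ? &par[i_y_tac] : yzero, 4, Lt);
    for (int m = 0; m < 4; ++m) sd_subj[m] = std::exp(par[i_lsd_subj + m]);
    for (int m = 0; m < 2; ++m) sd_region[m] = std::exp(par[i_lsd_region + m]);
    for (int m = 0; m < 4; ++m) sd_tac[m] = std::exp(par[i_lsd_tac + m]);
    if (mode == 0) {
      for (int m = 0; m < 2; ++m) {
        sd_vB[m] = std::exp(par[i_lsd_vB + m]);
        sd_sig[m] = std::exp(par[i_lsd_sig + m]);
      }
      sd_f = std::exp(par[i_lsd_f]);
    }
  }

  void derive_xb() {
    for (int m = 0; m < na; ++m)
      for (int t = 0; t < nT; ++t) {
        double s = 0.0;
        for (int c = 0; c < p[m]; ++c) s += X[m](t, c) * par[i_beta[m] + c];
        xb[m * nT + t] = s;
      }
  }

  void derive_f() {
    if (mode != 0) return;
    for (int i = 0; i < nI; ++i) {
      double s = wstar[i];
      for (int c = 0; c < nbf; ++c) s += Bf(i, c) * par[i_cf + c];
      f[i] = s;
    }
  }

  // tissue curve for one TAC from its theta; returns false on overflow
  bool derive_tissue(int t) {
    const double lk1 = par[i_theta + 0 * nT + t];
    const double lvnd = par[i_theta + 1 * nT + t];
    const double lbp = par[i_theta + 2 * nT + t];
    const double lk4 = par[i_theta + 3 * nT + t];
    if (lk1 > 3 || lvnd > 6 || lbp > 6 || lk4 > 3 ||
        lk1 < -12 || lvnd < -8 || lbp < -12 || lk4 < -10)
      return false;
    const double K1 = std::exp(lk1), VND = std::exp(lvnd);
    const double BPND = std::exp(lbp), k4 = std::exp(lk4);
    tissue_predict(K1, K1 / VND, BPND * k4, k4, &aifm(0, subj[t]), &tmid[0],
                   nI, 0.0, &tissue[t * nI]);
    return true;
  }

  double logvB(int t) const {
    return par[i_alpha + 4] + xb[4 * nT + t] + par[i_tauvB + subj[t]] +
           par[i_upvB + reg[t]];
  }

  void derive_mu(int t) {
    const double lvB = logvB(t);
    const double vB = (lvB < -1e-3) ? std::exp(lvB) : 2.0;  // >=1 flags bad
    const int j = subj[t];
    for (int i = 0; i < nI; ++i)
      mu[t * nI + i] = (vB > 1.0) ? NA_REAL
        : (1.0 - vB) * tissue[t * nI + i] + vB * cb(j, i);
  }

  void derive_lsigb(int t) {
    lsigb[t] = par[i_alpha + 5] + xb[5 * nT + t] + par[i_tausig + subj[t]] +
               par[i_upsig + reg[t]];
  }

  // ---- likelihood pieces ----------------------------------------------
  double data_ll(int t) {
    if (mode == 1) return 0.0;
    const double lb = lsigb[t];
    if (lb > 20 || lb < -20) return LOG_BAD;
    double lp = 0.0;
    for (int i = 0; i < nI; ++i) {
      const double yi = y(t, i);
      if (!R_finite(yi)) continue;
      const double m = mu[t * nI + i];
      if (!R_finite(m)) return LOG_BAD;
      const double lsig = lb + f[i];
      const double sig = std::exp(lsig);
      const double z = (yi - m) / sig;
      lp += -0.5 * z * z - lsig;
    }
    return R_finite(lp) ? lp : LOG_BAD;
  }

  double layer_ll(int t) {
    const int j = subj[t], k = reg[t];
    double r[4];
    const double* th = (mode == 0) ? &par[i_theta] : NULL;
    for (int m = 0; m < 4; ++m) {
      const double obs_m = (mode == 0) ? th[m * nT + t] : obs(t, m);
      double mean = par[i_alpha + m] + xb[m * nT + t] + par[i_tau + m * J + j];
      if (m == 1) mean += par[i_up + 0 * K + k];
      if (m == 3) mean += par[i_up + 1 * K + k];
      r[m] = obs_m - mean;
    }
    return mvn0_ll(r, sd_tac, Lt, 4);
  }

  double tau_density(int j) {
    double x[4];
    for (int m = 0; m < 4; ++m) x[m] = par[i_tau + m * J + j];
    double lp = mvn0_ll(x, sd_subj, Ls, 4);
    if (mode == 0) {
      const double zv = par[i_tauvB + j] / sd_vB[0];
      const double zs = par[i_tausig + j] / sd_sig[0];
      lp += -0.5 * zv * zv - std::log(sd_vB[0]);
      lp += -0.5 * zs * zs - std::log(sd_sig[0]);
    }
    return lp;
  }

  double up_density(int k) {
    double x[2];
    for (int m = 0; m < 2; ++m) x[m] = par[i_up + m * K + k];
    double lp = mvn0_ll(x, sd_region, Lr, 2);
    if (mode == 0) {
      const double zv = par[i_upvB + k] / sd_vB[1];
      const double zs = par[i_upsig + k] / sd_sig[1];
      lp += -0.5 * zv * zv - std::log(sd_vB[1]);
      lp += -0.5 * zs * zs - std::log(sd_sig[1]);
    }
    return lp;
  }

  double cf_density() {
    if (mode != 0) return 0.0;
    double lp = 0.0;
    for (int c = 0; c < nbf; ++c) {
      const double z = par[i_cf + c] / sd_f;
      lp += -0.5 * z * z - std::log(sd_f);
    }
    return lp;
  }

  // ---- fixed priors ----------------------------------------------------
  static double log_cosh(double x) {
    const double a = std::fabs(x);
    return a + std::log1p(std::exp(-2.0 * a)) - M_LN2;
  }

  static double half_t_lp(double lsd, double scale) {
    const double sd = std::exp(lsd);
    const double r = sd / scale;
    return -2.0 * std::log1p(r * r / 3.0) + lsd;
  }

  // prior for the raw hyperparameters / coefficients; the Gaussian layers
  // (theta, tau, upsilon, c_f) are handled as densities above
  double prior_component(int i) const {
    const double v = par[i];
    if (i < i_alpha + na) {
      const double z = (v - a_loc[i - i_alpha]) / a_scale[i - i_alpha];
      return -0.5 * z * z;
    }
    for (int m = 0; m < 6; ++m)
      if (p[m] > 0 && i >= i_beta[m] && i < i_beta[m] + p[m]) {
        const double s = beta_scale[m][i - i_beta[m]];
        return -0.5 * (v / s) * (v / s);
      }
    if (i >= i_lsd_subj && i < i_lsd_subj + 4)
      return half_t_lp(v, sdsc_subj[i - i_lsd_subj]);
    if (i >= i_lsd_region && i < i_lsd_region + 2)
      return half_t_lp(v, sdsc_region[i - i_lsd_region]);
    if (i >= i_lsd_tac && i < i_lsd_tac + 4)
      return half_t_lp(v, sdsc_tac[i - i_lsd_tac]);
    if (mode == 0) {
      if (i >= i_lsd_vB && i < i_lsd_vB + 2) return half_t_lp(v, sdsc_vB[i - i_lsd_vB]);
      if (i >= i_lsd_sig && i < i_lsd_sig + 2) return half_t_lp(v, sdsc_sig[i - i_lsd_sig]);
      if (i == i_lsd_f) return half_t_lp(v, sdsc_f);
    }
    if (multivariate && i >= i_y_subj && i < i_y_tac + n_y_tac)
      return -2.0 * y_shape[i] * log_cosh(v);
    return 0.0;  // Gaussian-layer parameters: density handled elsewhere
  }

  // ---- full joint (for verification and initial state) -----------------
  void derive_all() {
    derive_chols();
    derive_xb();
    derive_f();
    if (mode == 0)
      for (int t = 0; t < nT; ++t) {
        derive_lsigb(t);
        if (!derive_tissue(t)) {
          for (int i = 0; i < nI; ++i) mu[t * nI + i] = NA_REAL;
        } else {
          derive_mu(t);
        }
      }
    for (int t = 0; t < nT; ++t) {
      ll_data[t] = data_ll(t);
      ll_layer[t] = layer_ll(t);
    }
  }

  double joint_log_density() {
    double lp = 0.0;
    for (int t = 0; t < nT; ++t) lp += ll_data[t] + ll_layer[t];
    for (int j = 0; j < J; ++j) lp += tau_density(j);
    for (int k = 0; k < K; ++k) lp += up_density(k);
    lp += cf_density();
    for (int i = 0; i < npar; ++i) lp += prior_component(i);
    return lp;
  }

  // ---- blocks ----------------------------------------------------------
  void add_block(const std::vector<int>& idx, Kind kind, int id, int reps = 1) {
    if (idx.empty()) return;
    Block b;
    b.idx = idx; b.kind = kind; b.id = id; b.tm = -1; b.tc = -1; b.reps = reps;
    b.log_s = std::log(2.38 / std::sqrt((double)idx.size())) - 0.7;
    b.mean.assign(idx.size(), 0.0);
    b.m2.assign(idx.size() * idx.size(), 0.0);
    b.prop_L.assign(idx.size() * idx.size(), 0.0);
    b.have_L = false;
    b.n_mom = 0; b.ph_trials = 0; b.ph_accepts = 0; b.trials = 0; b.accepts = 0;
    blocks.push_back(b);
  }

  void reset_adaptation() {
    for (size_t bi = 0; bi < blocks.size(); ++bi) {
      Block& b = blocks[bi];
      b.n_mom = 0;
      std::fill(b.mean.begin(), b.mean.end(), 0.0);
      std::fill(b.m2.begin(), b.m2.end(), 0.0);
      // keep prop_L: the last adapted shape remains a good starting shape
      if (b.ph_trials > 20) {
        const double acc = (double)b.ph_accepts / b.ph_trials;
        if (acc < 0.05) b.log_s -= 1.0;
        else if (acc > 0.7) b.log_s += 0.5;
      }
      b.ph_trials = 0; b.ph_accepts = 0;
    }
  }

  static std::vector<int> seq_idx(int from, int n) {
    std::vector<int> v(n);
    for (int i = 0; i < n; ++i) v[i] = from + i;
    return v;
  }

  void build_blocks() {
    if (mode == 0)
      for (int t = 0; t < nT; ++t) {
        std::vector<int> v(4);
        for (int m = 0; m < 4; ++m) v[m] = i_theta + m * nT + t;
        add_block(v, K_THETA, t, 5);
      }
    for (int j = 0; j < J; ++j) {
      std::vector<int> v;
      for (int m = 0; m < 4; ++m) v.push_back(i_tau + m * J + j);
      add_block(v, K_TAU, j, 2);
      if (mode == 0) {
        std::vector<int> w;
        w.push_back(i_tauvB + j); w.push_back(i_tausig + j);
        add_block(w, K_VBSIG_J, j, 1);
      }
    }
    for (int k = 0; k < K; ++k) {
      std::vector<int> v;
      for (int m = 0; m < 2; ++m) v.push_back(i_up + m * K + k);
      add_block(v, K_UP, k, 2);
      if (mode == 0) {
        std::vector<int> w;
        w.push_back(i_upvB + k); w.push_back(i_upsig + k);
        add_block(w, K_VBSIG_K, k, 1);
      }
    }
    add_block(seq_idx(i_alpha, 4), K_LAYER, -1, 3);
    for (int m = 0; m < 4; ++m)
      if (p[m] > 0) add_block(seq_idx(i_beta[m], p[m]), K_LAYER, -1, 3);
    if (mode == 0) {
      std::vector<int> v;
      v.push_back(i_alpha + 4); v.push_back(i_alpha + 5);
      for (int m = 4; m < 6; ++m)
        for (int c = 0; c < p[m]; ++c) v.push_back(i_beta[m] + c);
      add_block(v, K_VBSIG_G, -1, 1);
    }
    add_block(seq_idx(i_lsd_tac, 4), K_SIG_TAC, -1, 3);
    if (multivariate) add_block(seq_idx(i_y_tac, 6), K_SIG_TAC, -1, 3);
    add_block(seq_idx(i_lsd_subj, 4), K_SIG_SUBJ, -1, 3);
    if (multivariate) add_block(seq_idx(i_y_subj, 6), K_SIG_SUBJ, -1, 3);
    add_block(seq_idx(i_lsd_region, 2), K_SIG_REG, -1, 3);
    if (multivariate) add_block(seq_idx(i_y_region, 1), K_SIG_REG, -1, 3);
    if (mode == 0) {
      add_block(seq_idx(i_lsd_vB, 2), K_HYPER, -1, 2);
      add_block(seq_idx(i_lsd_sig, 2), K_HYPER, -1, 2);
      add_block(seq_idx(i_cf, nbf), K_SMOOTH, -1, 2);
      add_block(seq_idx(i_lsd_f, 1), K_HYPER, -1, 2);
    }
    // interweaved scale moves, one per hierarchy SD (id encodes the target)
    if (mode == 0)
      for (int m = 0; m < 4; ++m) add_block(seq_idx(i_lsd_tac + m, 1), K_ASIS, m);
    for (int m = 0; m < 4; ++m) add_block(seq_idx(i_lsd_subj + m, 1), K_ASIS, 10 + m);
    for (int m = 0; m < 2; ++m) add_block(seq_idx(i_lsd_region + m, 1), K_ASIS, 20 + m);
    if (mode == 0) {
      add_block(seq_idx(i_lsd_vB + 0, 1), K_ASIS, 30);
      add_block(seq_idx(i_lsd_vB + 1, 1), K_ASIS, 31);
      add_block(seq_idx(i_lsd_sig + 0, 1), K_ASIS, 40);
      add_block(seq_idx(i_lsd_sig + 1, 1), K_ASIS, 41);
      add_block(seq_idx(i_lsd_f, 1), K_ASIS, 50);
    }
    if (mode == 0) {
      add_block(seq_idx(i_alpha + 1, 1), K_SPLIT, 60, 3);
      for (int j = 0; j < J; ++j) {
        add_block(seq_idx(i_tau + 1 * J + j, 1), K_SPLIT, 61, 2);
        blocks.back().tc = j;
      }
      for (int k = 0; k < K; ++k) {
        add_block(seq_idx(i_up + 0 * K + k, 1), K_SPLIT, 62, 2);
        blocks.back().tc = k;
      }
    }
    if (mode == 0)
      for (int m = 0; m < 4; ++m) add_block(seq_idx(i_alpha + m, 1), K_SHIFT, m, 2);
    for (int m = 0; m < 4; ++m) add_block(seq_idx(i_alpha + m, 1), K_SHIFT, 10 + m, 2);
    for (int m = 0; m < 2; ++m) add_block(seq_idx(i_alpha + (m == 0 ? 1 : 3), 1), K_SHIFT, 20 + m, 2);
    if (mode == 0) {
      // per-coefficient, per-subject and per-region translations against theta
      for (int m = 0; m < 4; ++m)
        for (int c = 0; c < p[m]; ++c) {
          add_block(seq_idx(i_beta[m] + c, 1), K_SHIFT, 30, 2);
          blocks.back().tm = m; blocks.back().tc = c;
        }
      for (int m = 0; m < 4; ++m)
        for (int j = 0; j < J; ++j) {
          add_block(seq_idx(i_tau + m * J + j, 1), K_SHIFT, 40, 1);
          blocks.back().tm = m; blocks.back().tc = j;
        }
      for (int m = 0; m < 2; ++m)
        for (int k = 0; k < K; ++k) {
          add_block(seq_idx(i_up + m * K + k, 1), K_SHIFT, 50, 1);
          blocks.back().tm = m; blocks.back().tc = k;
        }
    }
    if (mode == 0)
      for (int q = 0; q < 4; ++q) add_block(seq_idx(i_alpha + 4 + q / 2, 1), K_SHIFT, 70 + q, 2);
    add_block(seq_idx(i_tau, 1), K_GIBBS, 0, 1);
    add_block(seq_idx(i_up, 1), K_GIBBS, 1, 1);
    add_block(seq_idx(i_alpha, 1), K_GIBBS, 2, 1);
  }

  void refresh_data_rows(const std::vector<int>& rows) {
    for (size_t a = 0; a < rows.size(); ++a) {
      const int t = rows[a];
      if (!derive_tissue(t)) {
        for (int i = 0; i < nI; ++i) mu[t * nI + i] = NA_REAL;
        ll_data[t] = LOG_BAD;
        continue;
      }
      derive_mu(t);
      ll_data[t] = data_ll(t);
    }
  }

  // coherent translation moves (Jacobian-free)
  void update_shift(Block& b, bool adapt) {
    asis_par = par;
    asis_tissue = tissue; asis_mu = mu; asis_lsigb = lsigb; asis_f = f;
    asis_lld = ll_data; asis_lll = ll_layer;
    const double old_joint = joint_from_caches();
    const double delta = std::exp(b.log_s) * norm_rand();
    const int id = b.id;
    if (id < 4) {
      // alpha_m and every theta_m together: layer residuals unchanged,
      // the data level decides
      const int m = id;
      par[i_alpha + m] += delta;
      for (int t = 0; t < nT; ++t) par[i_theta + m * nT + t] += delta;
      refresh_data_all();
      for (int t = 0; t < nT; ++t) ll_layer[t] = layer_ll(t);
    } else if (id < 20) {
      // alpha_m against every tau_m: likelihood and layer unchanged,
      // the tau prior decides
      const int m = id - 10;
      par[i_alpha + m] += delta;
      for (int j = 0; j < J; ++j) par[i_tau + m * J + j] -= delta;
      if (mode == 1) for (int t = 0; t < nT; ++t) ll_layer[t] = layer_ll(t);
      else for (int t = 0; t < nT; ++t) ll_layer[t] = layer_ll(t);
    } else if (id < 30) {
      // alpha (VND or k4) against every regional upsilon
      const int m = id - 20;  // 0 -> VND, 1 -> k4
      par[i_alpha + (m == 0 ? 1 : 3)] += delta;
      for (int k = 0; k < K; ++k) par[i_up + m * K + k] -= delta;
      for (int t = 0; t < nT; ++t) ll_layer[t] = layer_ll(t);
    } else if (id >= 70 && id < 74) {
      // vB / error-scale intercept against its subject or region deviations:
      // the linear predictors are unchanged, only the priors decide
      const int q = id - 70;           // 0,1: vB subj/region; 2,3: sigma
      const int ia = i_alpha + (q < 2 ? 4 : 5);
      par[ia] += delta;
      if (q == 0) for (int j = 0; j < J; ++j) par[i_tauvB + j] -= delta;
      if (q == 1) for (int k = 0; k < K; ++k) par[i_upvB + k] -= delta;
      if (q == 2) for (int j = 0; j < J; ++j) par[i_tausig + j] -= delta;
      if (q == 3) for (int k = 0; k < K; ++k) par[i_upsig + k] -= delta;
      derive_xb();
      for (int t = 0; t < nT; ++t) { derive_mu(t); derive_lsigb(t); }
    } else if (id == 30) {
      // coefficient c of parameter m with theta shifted by delta * X[t,c]:
      // layer-invariant, the data decide
      const int m = b.tm, c = b.tc;
      par[i_beta[m] + c] += delta;
      for (int t = 0; t < nT; ++t)
        par[i_theta + m * nT + t] += delta * X[m](t, c);
      derive_xb();
      refresh_data_all();
      for (int t = 0; t < nT; ++t) ll_layer[t] = layer_ll(t);
    } else if (id == 40) {
      // tau_m[j] with that subject's theta_m: layer-invariant locally
      const int m = b.tm, j = b.tc;
      par[i_tau + m * J + j] += delta;
      const std::vector<int>& tt = tacs_of_subj[j];
      for (size_t a = 0; a < tt.size(); ++a)
        par[i_theta + m * nT + tt[a]] += delta;
      refresh_data_rows(tt);
      for (size_t a = 0; a < tt.size(); ++a) ll_layer[tt[a]] = layer_ll(tt[a]);
    } else {
      // upsilon_m[k] with that region's theta: tm 0 -> VND, 1 -> k4
      const int m = b.tm, k = b.tc;
      const int mth = (m == 0) ? 1 : 3;
      par[i_up + m * K + k] += delta;
      const std::vector<int>& tt = tacs_of_reg[k];
      for (size_t a = 0; a < tt.size(); ++a)
        par[i_theta + mth * nT + tt[a]] += delta;
      refresh_data_rows(tt);
      for (size_t a = 0; a < tt.size(); ++a) ll_layer[tt[a]] = layer_ll(tt[a]);
    }
    const double new_joint = joint_from_caches();
    const double logr = new_joint - old_joint;
    const bool accept = new_joint > 0.5 * LOG_BAD && R_finite(logr) &&
                        (logr >= 0 || unif_rand() < std::exp(logr));
    b.trials++;
    if (accept) {
      b.accepts++;
    } else {
      par = asis_par;
      tissue = asis_tissue; mu = asis_mu; lsigb = asis_lsigb; f = asis_f;
      ll_data = asis_lld; ll_layer = asis_lll;
    }
    if (adapt) {
      b.ph_trials++; if (accept) b.ph_accepts++;
      b.log_s += (2.0 / std::sqrt((double)(b.ph_trials + 10))) *
                 ((accept ? 1.0 : 0.0) - 0.44);
      b.log_s = std::min(std::max(b.log_s, -6.0), 1.5);
    }
  }

  // V_T-preserving split move: log V_ND shifts by delta everywhere, each
  // log BP_ND compensates so V_T of every TAC is unchanged.  The BP_ND
  // transform lbp -> log((1 + e^lbp) e^-delta - 1) carries a Jacobian
  // term (lbp - delta - lbp') per transformed value.
  void update_split(Block& b, bool adapt) {
    asis_par = par;
    asis_tissue = tissue; asis_mu = mu; asis_lsigb = lsigb; asis_f = f;
    asis_lld = ll_data; asis_lll = ll_layer;
    const double old_joint = joint_from_caches();
    const double delta = std::exp(b.log_s) * norm_rand();

    double jac = 0.0;
    bool ok = true;
    // the set of TACs whose theta is transformed depends on the level
    static std::vector<int> rows;
    if (b.id == 60) {
      rows.resize(nT);
      for (int t = 0; t < nT; ++t) rows[t] = t;
    } else if (b.id == 61) rows = tacs_of_subj[b.tc];
    else rows = tacs_of_reg[b.tc];

    for (size_t a = 0; a < rows.size() && ok; ++a) {
      const int t = rows[a];
      const double lbp = par[i_theta + 2 * nT + t];
      const double v = (1.0 + std::exp(lbp)) * std::exp(-delta) - 1.0;
      if (v <= 1e-10) { ok = false; break; }
      const double lbp2 = std::log(v);
      jac += lbp - delta - lbp2;
      par[i_theta + 2 * nT + t] = lbp2;
      par[i_theta + 1 * nT + t] += delta;
    }
    if (ok && b.id == 60) {
      const double abp = par[i_alpha + 2];
      const double va = (1.0 + std::exp(abp)) * std::exp(-delta) - 1.0;
      if (va <= 1e-10) ok = false;
      else {
        const double abp2 = std::log(va);
        jac += abp - delta - abp2;
        par[i_alpha + 2] = abp2;
        par[i_alpha + 1] += delta;
      }
    } else if (ok && b.id == 61) {
      par[i_tau + 1 * J + b.tc] += delta;  // tau_VND tracks its thetas
    } else if (ok && b.id == 62) {
      par[i_up + 0 * K + b.tc] += delta;   // upsilon_VND tracks its thetas
    }
    bool accept = false;
    if (ok) {
      refresh_data_rows(rows);
      for (int t = 0; t < nT; ++t) ll_layer[t] = layer_ll(t);
      const double new_joint = joint_from_caches();
      const double logr = new_joint - old_joint + jac;
      accept = new_joint > 0.5 * LOG_BAD && R_finite(logr) &&
               (logr >= 0 || unif_rand() < std::exp(logr));
    }
    b.trials++;
    if (accept) {
      b.accepts++;
    } else {
      par = asis_par;
      tissue = asis_tissue; mu = asis_mu; lsigb = asis_lsigb; f = asis_f;
      ll_data = asis_lld; ll_layer = asis_lll;
    }
    if (adapt) {
      b.ph_trials++; if (accept) b.ph_accepts++;
      b.log_s += (2.0 / std::sqrt((double)(b.ph_trials + 10))) *
                 ((accept ? 1.0 : 0.0) - 0.44);
      b.log_s = std::min(std::max(b.log_s, -6.0), 1.0);
    }
  }

  // ---- interweaved scale move -----------------------------------------
  // Snapshot-everything state for ASIS moves (parameters are few).
  std::vector<double> asis_par, asis_tissue, asis_mu, asis_lsigb, asis_f,
      asis_lld, asis_lll;

  double joint_from_caches() {
    double lp = 0.0;
    for (int t = 0; t < nT; ++t) lp += ll_data[t] + ll_layer[t];
    for (int j = 0; j < J; ++j) lp += tau_density(j);
    for (int k = 0; k < K; ++k) lp += up_density(k);
    lp += cf_density();
    for (int i = 0; i < npar; ++i) lp += prior_component(i);
    return lp;
  }

  double theta_mean(int m, int t) const {
    const int j = subj[t], k = reg[t];
    double mean = par[i_alpha + m] + xb[m * nT + t] + par[i_tau + m * J + j];
    if (m == 1) mean += par[i_up + 0 * K + k];
    if (m == 3) mean += par[i_up + 1 * K + k];
    return mean;
  }

  void refresh_data_all() {
    for (int t = 0; t < nT; ++t) {
      if (!derive_tissue(t)) {
        for (int i = 0; i < nI; ++i) mu[t * nI + i] = NA_REAL;
        ll_data[t] = LOG_BAD;
        continue;
      }
      derive_mu(t);
      ll_data[t] = data_ll(t);
    }
  }

  void update_asis(Block& b, bool adapt) {
    asis_par = par;
    asis_tissue = tissue; asis_mu = mu; asis_lsigb = lsigb; asis_f = f;
    asis_lld = ll_data; asis_lll = ll_layer;
    const double old_joint = joint_from_caches();

    const double delta = std::exp(b.log_s) * norm_rand();
    const double c = std::exp(delta);
    const int id = b.id;
    double n_scaled = 0.0;
    if (id < 4) {                    // TAC-level SD m with theta residuals
      const int m = id;
      for (int t = 0; t < nT; ++t) {
        const double mean = theta_mean(m, t);
        par[i_theta + m * nT + t] = mean + c * (par[i_theta + m * nT + t] - mean);
      }
      par[i_lsd_tac + m] += delta;
      derive_chols();
      refresh_data_all();
      for (int t = 0; t < nT; ++t) ll_layer[t] = layer_ll(t);
      n_scaled = nT;
    } else if (id < 20) {            // subject-level SD m with tau
      const int m = id - 10;
      for (int j = 0; j < J; ++j) par[i_tau + m * J + j] *= c;
      par[i_lsd_subj + m] += delta;
      derive_chols();
      for (int t = 0; t < nT; ++t) ll_layer[t] = layer_ll(t);
      n_scaled = J;
    } else if (id < 30) {            // region-level SD m with upsilon
      const int m = id - 20;
      for (int k = 0; k < K; ++k) par[i_up + m * K + k] *= c;
      par[i_lsd_region + m] += delta;
      derive_chols();
      for (int t = 0; t < nT; ++t) ll_layer[t] = layer_ll(t);
      n_scaled = K;
    } else if (id == 30 || id == 31) {  // vB subject / region SD
      if (id == 30) { for (int j = 0; j < J; ++j) par[i_tauvB + j] *= c; par[i_lsd_vB] += delta; n_scaled = J; }
      else { for (int k = 0; k < K; ++k) par[i_upvB + k] *= c; par[i_lsd_vB + 1] += delta; n_scaled = K; }
      derive_chols();
      for (int t = 0; t < nT; ++t) { derive_mu(t); ll_data[t] = data_ll(t); }
    } else if (id == 40 || id == 41) {  // error-scale subject / region SD
      if (id == 40) { for (int j = 0; j < J; ++j) par[i_tausig + j] *= c; par[i_lsd_sig] += delta; n_scaled = J; }
      else { for (int k = 0; k < K; ++k) par[i_upsig + k] *= c; par[i_lsd_sig + 1] += delta; n_scaled = K; }
      derive_chols();
      for (int t = 0; t < nT; ++t) { derive_lsigb(t); ll_data[t] = data_ll(t); }
    } else {                         // smooth-term SD with coefficients
      for (int q = 0; q < nbf; ++q) par[i_cf + q] *= c;
      par[i_lsd_f] += delta;
      derive_chols();
      derive_f();
      for (int t = 0; t < nT; ++t) ll_data[t] = data_ll(t);
      n_scaled = nbf;
    }
    const double new_joint = joint_from_caches();
    const double logr = new_joint - old_joint + n_scaled * delta;
    const bool accept = new_joint > 0.5 * LOG_BAD && R_finite(logr) &&
                        (logr >= 0 || unif_rand() < std::exp(logr));
    b.trials++;
    if (accept) {
      b.accepts++;
    } else {
      par = asis_par;
      tissue = asis_tissue; mu = asis_mu; lsigb = asis_lsigb; f = asis_f;
      ll_data = asis_lld; ll_layer = asis_lll;
      derive_chols();
    }
    if (adapt) {
      b.ph_trials++; if (accept) b.ph_accepts++;
      b.log_s += (2.0 / std::sqrt((double)(b.ph_trials + 10))) *
                 ((accept ? 1.0 : 0.0) - 0.44);
      b.log_s = std::min(std::max(b.log_s, -6.0), 1.5);
    }
  }

  // ---- exact Gibbs draws for the Gaussian layer ------------------------
  // dense inverse of (diag(sd) Lr)(diag(sd) Lr)'
  static void cov_inverse(const double* sd, const double* Lr, int d, double* inv) {
    std::vector<double> L(d * d, 0.0), Li(d * d, 0.0);
    for (int j = 0; j < d; ++j)
      for (int i = j; i < d; ++i) L[i + d * j] = sd[i] * Lr[i + d * j];
    for (int j = 0; j < d; ++j) {
      Li[j + d * j] = 1.0 / L[j + d * j];
      for (int i = j + 1; i < d; ++i) {
        double sum = 0.0;
        for (int k = j; k < i; ++k) sum += L[i + d * k] * Li[k + d * j];
        Li[i + d * j] = -sum / L[i + d * i];
      }
    }
    for (int i = 0; i < d; ++i)
      for (int j = 0; j < d; ++j) {
        double sum = 0.0;
        for (int k = std::max(i, j); k < d; ++k) sum += Li[k + d * i] * Li[k + d * j];
        inv[i + d * j] = sum;
      }
  }

  // draw x ~ N(P^-1 b, P^-1); false if P is not positive definite
  static bool mvn_prec_draw(std::vector<double>& P, std::vector<double>& b,
                            int d, std::vector<double>& out) {
    std::vector<double> L(d * d, 0.0);
    if (!small_chol(&P[0], d, &L[0])) return false;
    std::vector<double> w(d);
    for (int i = 0; i < d; ++i) {
      double sum = b[i];
      for (int k = 0; k < i; ++k) sum -= L[i + d * k] * w[k];
      w[i] = sum / L[i + d * i];
    }
    out.assign(d, 0.0);
    for (int i = d - 1; i >= 0; --i) {
      double sum = w[i];
      for (int k = i + 1; k < d; ++k) sum -= L[k + d * i] * out[k];
      out[i] = sum / L[i + d * i];
    }
    std::vector<double> z(d);
    for (int i = 0; i < d; ++i) z[i] = norm_rand();
    for (int i = d - 1; i >= 0; --i) {
      double sum = z[i];
      for (int k = i + 1; k < d; ++k) sum -= L[k + d * i] * z[k];
      z[i] = sum / L[i + d * i];
      out[i] += z[i];
    }
    return true;
  }

  double theta_obs(int m, int t) const {
    return (mode == 0) ? par[i_theta + m * nT + t] : obs(t, m);
  }

  void gibbs_layer(int which) {
    double Wt[16], Ws[16], Wr[4];
    cov_inverse(sd_tac, Lt, 4, Wt);
    if (which == 0) {
      cov_inverse(sd_subj, Ls, 4, Ws);
      for (int j = 0; j < J; ++j) {
        const std::vector<int>& tt = tacs_of_subj[j];
        std::vector<double> P(16), b(4, 0.0), out;
        for (int q = 0; q < 16; ++q) P[q] = Ws[q] + tt.size() * Wt[q];
        double rsum[4] = {0, 0, 0, 0};
        for (size_t a = 0; a < tt.size(); ++a) {
          const int t = tt[a], k = reg[t];
          for (int m = 0; m < 4; ++m) {
            double r = theta_obs(m, t) - (par[i_alpha + m] + xb[m * nT + t]);
            if (m == 1) r -= par[i_up + 0 * K + k];
            if (m == 3) r -= par[i_up + 1 * K + k];
            rsum[m] += r;
          }
        }
        for (int m = 0; m < 4; ++m)
          for (int q = 0; q < 4; ++q) b[m] += Wt[m + 4 * q] * rsum[q];
        if (mvn_prec_draw(P, b, 4, out))
          for (int m = 0; m < 4; ++m) par[i_tau + m * J + j] = out[m];
        for (size_t a = 0; a < tt.size(); ++a) ll_layer[tt[a]] = layer_ll(tt[a]);
      }
    } else if (which == 1) {
      cov_inverse(sd_region, Lr, 2, Wr);
      const int sel[2] = {1, 3};  // upsilon acts on (VND, k4)
      for (int k = 0; k < K; ++k) {
        const std::vector<int>& tt = tacs_of_reg[k];
        std::vector<double> P(4), b(2, 0.0), out;
        for (int a2 = 0; a2 < 2; ++a2)
          for (int b2 = 0; b2 < 2; ++b2)
            P[a2 + 2 * b2] = Wr[a2 + 2 * b2] +
                             tt.size() * Wt[sel[a2] + 4 * sel[b2]];
        double rsum[4] = {0, 0, 0, 0};
        for (size_t a = 0; a < tt.size(); ++a) {
          const int t = tt[a], j = subj[t];
          for (int m = 0; m < 4; ++m)
            rsum[m] += theta_obs(m, t) -
                       (par[i_alpha + m] + xb[m * nT + t] + par[i_tau + m * J + j]);
        }
        for (int a2 = 0; a2 < 2; ++a2)
          for (int q = 0; q < 4; ++q) b[a2] += Wt[sel[a2] + 4 * q] * rsum[q];
        if (mvn_prec_draw(P, b, 2, out))
          for (int m = 0; m < 2; ++m) par[i_up + m * K + k] = out[m];
        for (size_t a = 0; a < tt.size(); ++a) ll_layer[tt[a]] = layer_ll(tt[a]);
      }
    } else {
      const int d = 4 + p[0] + p[1] + p[2] + p[3];
      std::vector<double> P(d * d, 0.0), b(d, 0.0), out;
      std::vector<int> base(4);
      base[0] = 4; for (int m = 1; m < 4; ++m) base[m] = base[m - 1] + p[m - 1];
      for (int m = 0; m < 4; ++m) {
        const double pr = 1.0 / (a_scale[m] * a_scale[m]);
        P[m + d * m] += pr;
        b[m] += pr * a_loc[m];
        for (int c = 0; c < p[m]; ++c) {
          const double sb = beta_scale[m][c];
          P[(base[m] + c) + d * (base[m] + c)] += 1.0 / (sb * sb);
        }
      }
      std::vector<double> A(4 * d), WA(4 * d);
      for (int t = 0; t < nT; ++t) {
        const int j = subj[t], k = reg[t];
        std::fill(A.begin(), A.end(), 0.0);
        double r[4], Wr4[4];
        for (int m = 0; m < 4; ++m) {
          A[m + 4 * m] = 1.0;
          for (int c = 0; c < p[m]; ++c) A[m + 4 * (base[m] + c)] = X[m](t, c);
          r[m] = theta_obs(m, t) - par[i_tau + m * J + j];
          if (m == 1) r[m] -= par[i_up + 0 * K + k];
          if (m == 3) r[m] -= par[i_up + 1 * K + k];
        }
        for (int m = 0; m < 4; ++m)
          for (int c2 = 0; c2 < d; ++c2) {
            double sum = 0.0;
            for (int q = 0; q < 4; ++q) sum += Wt[m + 4 * q] * A[q + 4 * c2];
            WA[m + 4 * c2] = sum;
          }
        for (int c1 = 0; c1 < d; ++c1)
          for (int c2 = 0; c2 < d; ++c2) {
            double sum = 0.0;
            for (int m = 0; m < 4; ++m) sum += A[m + 4 * c1] * WA[m + 4 * c2];
            P[c1 + d * c2] += sum;
          }
        for (int m = 0; m < 4; ++m) {
          double sum = 0.0;
          for (int q = 0; q < 4; ++q) sum += Wt[m + 4 * q] * r[q];
          Wr4[m] = sum;
        }
        for (int c1 = 0; c1 < d; ++c1) {
          double sum = 0.0;
          for (int m = 0; m < 4; ++m) sum += A[m + 4 * c1] * Wr4[m];
          b[c1] += sum;
        }
      }
      if (mvn_prec_draw(P, b, d, out)) {
        for (int m = 0; m < 4; ++m) {
          par[i_alpha + m] = out[m];
          for (int c = 0; c < p[m]; ++c) par[i_beta[m] + c] = out[base[m] + c];
        }
        derive_xb();
        for (int t = 0; t < nT; ++t) ll_layer[t] = layer_ll(t);
      }
    }
  }

  // ---- posterior delta machinery ---------------------------------------
  // Evaluates the terms affected by a block; called before and after the
  // proposal. "refresh" recomputes the caches the block invalidates.
  double block_terms(const Block& b, bool refresh) {
    double lp = 0.0;
    for (size_t m = 0; m < b.idx.size(); ++m) lp += prior_component(b.idx[m]);
    switch (b.kind) {
      case K_THETA: {
        const int t = b.id;
        if (refresh) {
          if (!derive_tissue(t)) {
            // invalid kinetic parameters: flag the whole TAC coherently
            for (int i = 0; i < nI; ++i) mu[t * nI + i] = NA_REAL;
            ll_data[t] = LOG_BAD;
          } else {
            derive_mu(t);
            ll_data[t] = data_ll(t);
          }
          ll_layer[t] = layer_ll(t);
        }
        return lp + ll_data[t] + ll_layer[t];
      }
      case K_LAYER: {
        if (refresh) {
          derive_xb();
          for (int t = 0; t < nT; ++t) ll_layer[t] = layer_ll(t);
        }
        for (int t = 0; t < nT; ++t) lp += ll_layer[t];
        return lp;
      }
      case K_TAU: {
        const std::vector<int>& tt = tacs_of_subj[b.id];
        if (refresh)
          for (size_t a = 0; a < tt.size(); ++a) ll_layer[tt[a]] = layer_ll(tt[a]);
        for (size_t a = 0; a < tt.size(); ++a) lp += ll_layer[tt[a]];
        return lp + tau_density(b.id);
      }
      case K_UP: {
        const std::vector<int>& tt = tacs_of_reg[b.id];
        if (refresh)
          for (size_t a = 0; a < tt.size(); ++a) ll_layer[tt[a]] = layer_ll(tt[a]);
        for (size_t a = 0; a < tt.size(); ++a) lp += ll_layer[tt[a]];
        return lp + up_density(b.id);
      }
      case K_SIG_TAC: {
        if (refresh) {
          derive_chols();
          for (int t = 0; t < nT; ++t) ll_layer[t] = layer_ll(t);
        }
        for (int t = 0; t < nT; ++t) lp += ll_layer[t];
        return lp;
      }
      case K_SIG_SUBJ: {
        if (refresh) derive_chols();
        for (int j = 0; j < J; ++j) lp += tau_density(j);
        return lp;
      }
      case K_SIG_REG: {
        if (refresh) derive_chols();
        for (int k = 0; k < K; ++k) lp += up_density(k);
        return lp;
      }
      case K_VBSIG_G: {
        if (refresh) {
          derive_xb();
          for (int t = 0; t < nT; ++t) {
            derive_mu(t);
            derive_lsigb(t);
            ll_data[t] = data_ll(t);
          }
        }
        for (int t = 0; t < nT; ++t) lp += ll_data[t];
        return lp;
      }
      case K_VBSIG_J: {
        const std::vector<int>& tt = tacs_of_subj[b.id];
        if (refresh)
          for (size_t a = 0; a < tt.size(); ++a) {
            derive_mu(tt[a]);
            derive_lsigb(tt[a]);
            ll_data[tt[a]] = data_ll(tt[a]);
          }
        for (size_t a = 0; a < tt.size(); ++a) lp += ll_data[tt[a]];
        return lp + tau_density(b.id);
      }
      case K_VBSIG_K: {
        const std::vector<int>& tt = tacs_of_reg[b.id];
        if (refresh)
          for (size_t a = 0; a < tt.size(); ++a) {
            derive_mu(tt[a]);
            derive_lsigb(tt[a]);
            ll_data[tt[a]] = data_ll(tt[a]);
          }
        for (size_t a = 0; a < tt.size(); ++a) lp += ll_data[tt[a]];
        return lp + up_density(b.id);
      }
      case K_SMOOTH: {
        if (refresh) {
          derive_f();
          for (int t = 0; t < nT; ++t) ll_data[t] = data_ll(t);
        }
        for (int t = 0; t < nT; ++t) lp += ll_data[t];
        return lp + cf_density();
      }
      case K_HYPER: {
        if (refresh) derive_chols();
        // scale parameters whose dependents are cheap Gaussian densities
        for (int j = 0; j < J && mode == 0; ++j) lp += tau_density(j);
        for (int k = 0; k < K && mode == 0; ++k) lp += up_density(k);
        return lp + cf_density();
      }
    }
    return lp;
  }

  // snapshot of caches a block can invalidate, for cheap restore
  struct Snapshot {
    std::vector<double> ll_data, ll_layer, tissue_row, mu_rows, lsigb_v, f_v;
    std::vector<int> rows;
  };

  void snapshot_block(const Block& b, Snapshot& s) {
    s.rows.clear();
    s.mu_rows.clear(); s.lsigb_v.clear(); s.tissue_row.clear(); s.f_v.clear();
    switch (b.kind) {
      case K_THETA: s.rows.push_back(b.id); break;
      case K_TAU: s.rows = tacs_of_subj[b.id]; break;
      case K_UP: s.rows = tacs_of_reg[b.id]; break;
      case K_VBSIG_J: s.rows = tacs_of_subj[b.id]; break;
      case K_VBSIG_K: s.rows = tacs_of_reg[b.id]; break;
      default:
        s.rows.resize(nT);
        for (int t = 0; t < nT; ++t) s.rows[t] = t;
    }
    const size_t n = s.rows.size();
    s.ll_data.resize(n); s.ll_layer.resize(n);
    for (size_t a = 0; a < n; ++a) {
      s.ll_data[a] = ll_data[s.rows[a]];
      s.ll_layer[a] = ll_layer[s.rows[a]];
    }
    if (b.kind == K_THETA && mode == 0) {
      s.tissue_row.assign(tissue.begin() + b.id * nI,
                          tissue.begin() + (b.id + 1) * nI);
    }
    if (mode == 0 && (b.kind == K_THETA || b.kind == K_VBSIG_G ||
                      b.kind == K_VBSIG_J || b.kind == K_VBSIG_K)) {
      s.mu_rows.resize(n * nI);
      s.lsigb_v.resize(n);
      for (size_t a = 0; a < n; ++a) {
        std::copy(mu.begin() + s.rows[a] * nI, mu.begin() + (s.rows[a] + 1) * nI,
                  s.mu_rows.begin() + a * nI);
        s.lsigb_v[a] = lsigb[s.rows[a]];
      }
    }
    if (b.kind == K_SMOOTH) s.f_v = f;
  }

  void restore_block(const Block& b, const Snapshot& s) {
    for (size_t a = 0; a < s.rows.size(); ++a) {
      ll_data[s.rows[a]] = s.ll_data[a];
      ll_layer[s.rows[a]] = s.ll_layer[a];
    }
    if (b.kind == K_THETA && mode == 0)
      std::copy(s.tissue_row.begin(), s.tissue_row.end(),
                tissue.begin() + b.id * nI);
    if (!s.mu_rows.empty()) {
      for (size_t a = 0; a < s.rows.size(); ++a) {
        std::copy(s.mu_rows.begin() + a * nI, s.mu_rows.begin() + (a + 1) * nI,
                  mu.begin() + s.rows[a] * nI);
        lsigb[s.rows[a]] = s.lsigb_v[a];
      }
    }
    if (b.kind == K_SMOOTH) f = s.f_v;
    // recompute cheap derived quantities from the restored parameters
    switch (b.kind) {
      case K_SIG_TAC: case K_SIG_SUBJ: case K_SIG_REG: case K_HYPER:
        derive_chols(); break;
      case K_LAYER: case K_VBSIG_G: derive_xb(); break;
      default: break;
    }
  }

  Snapshot snap;

  void update_block(Block& b, bool adapt) {
    if (b.kind == K_ASIS) { update_asis(b, adapt); return; }
    if (b.kind == K_SPLIT) { update_split(b, adapt); return; }
    if (b.kind == K_SHIFT) { update_shift(b, adapt); return; }
    if (b.kind == K_GIBBS) { gibbs_layer(b.id); b.trials++; b.accepts++; return; }
    const int d = b.idx.size();
    const double old_terms = block_terms(b, false);
    snapshot_block(b, snap);
    std::vector<double> old_par(d);
    for (int m = 0; m < d; ++m) old_par[m] = par[b.idx[m]];

    const double s = std::exp(b.log_s);
    if (b.have_L && d > 1) {
      std::vector<double> z(d);
      for (int m = 0; m < d; ++m) z[m] = norm_rand();
      for (int m = 0; m < d; ++m) {
        double step = 0.0;
        for (int q = 0; q <= m; ++q) step += b.prop_L[m + d * q] * z[q];
        par[b.idx[m]] = old_par[m] + s * step;
      }
    } else {
      for (int m = 0; m < d; ++m) {
        double psd = 1.0;
        if (b.n_mom > 20) psd = std::sqrt(b.m2[m + d * m] / (b.n_mom - 1) + 1e-8);
        par[b.idx[m]] = old_par[m] + s * psd * norm_rand();
      }
    }
    const double new_terms = block_terms(b, true);
    const double logr = new_terms - old_terms;
    const bool accept = new_terms > 0.5 * LOG_BAD && R_finite(logr) &&
                        (logr >= 0 || unif_rand() < std::exp(logr));
    last_accept = accept;
    b.trials++;
    if (accept) {
      b.accepts++;
    } else {
      for (int m = 0; m < d; ++m) par[b.idx[m]] = old_par[m];
      restore_block(b, snap);
    }
    if (adapt) {
      const double target = (d == 1) ? 0.44 : 0.25;
      b.ph_trials++; if (accept) b.ph_accepts++;
      b.log_s += (2.0 / std::sqrt((double)(b.ph_trials + 10))) *
                 ((accept ? 1.0 : 0.0) - target);
      b.log_s = std::min(std::max(b.log_s, -8.0), 3.0);
      b.n_mom++;
      std::vector<double> dlt(d);
      for (int m = 0; m < d; ++m) {
        dlt[m] = par[b.idx[m]] - b.mean[m];
        b.mean[m] += dlt[m] / b.n_mom;
      }
      for (int m = 0; m < d; ++m)
        for (int q = 0; q < d; ++q)
          b.m2[m + d * q] += dlt[m] * (par[b.idx[q]] - b.mean[q]);
      if (d > 1 && b.n_mom > 10 * d && b.n_mom % 25 == 0) {
        std::vector<double> cov(d * d), L(d * d);
        for (int m = 0; m < d * d; ++m) cov[m] = b.m2[m] / (b.n_mom - 1);
        for (int m = 0; m < d; ++m) cov[m + d * m] += 1e-8;
        if (small_chol(&cov[0], d, &L[0])) {
          std::copy(L.begin(), L.end(), b.prop_L.begin());
          b.have_L = true;
        }
      }
    }
  }
};

void sampler_setup(Sampler& S, List data) {
  S.mode = as<int>(data["mode"]);
  S.multivariate = as<bool>(data["multivariate"]);
  S.J = as<int>(data["J"]); S.K = as<int>(data["K"]);
  S.nT = as<int>(data["nT"]); S.nI = as<int>(data["nI"]);
  if (S.mode == 0) {
    S.y = as<NumericMatrix>(data["y"]);
    S.cb = as<NumericMatrix>(data["cb"]);
    S.aifm = as<NumericMatrix>(data["aif"]);  // 9 x J, subjects in columns
    S.tmid = as<NumericVector>(data["tmid"]);
    S.Bf = as<NumericMatrix>(data["Bf"]);
    S.wstar = as<NumericVector>(data["wstar"]);
    S.nbf = S.Bf.ncol();
  } else {
    S.obs = as<NumericMatrix>(data["obs"]);
    S.nbf = 0;
    S.tmid = NumericVector(1);
    S.wstar = NumericVector(1);
  }
  IntegerVector sj = data["subj"], rg = data["reg"];
  S.subj.assign(sj.begin(), sj.end());
  S.reg.assign(rg.begin(), rg.end());
  List XL = data["X"];
  for (int m = 0; m < 6; ++m)
    S.X[m] = (m < XL.size()) ? as<NumericMatrix>(XL[m]) : NumericMatrix(S.nT, 0);

  List pr = data["prior"];
  NumericVector al = pr["alpha_loc"], as_ = pr["alpha_scale"];
  for (int m = 0; m < al.size(); ++m) { S.a_loc[m] = al[m]; S.a_scale[m] = as_[m]; }
  List bs = pr["beta_scale"];
  for (int m = 0; m < 6; ++m)
    if (m < bs.size()) {
      NumericVector v = bs[m];
      S.beta_scale[m].assign(v.begin(), v.end());
    }
  NumericVector v1 = pr["sd_scale_subject"], v2 = pr["sd_scale_region"],
                v3 = pr["sd_scale_tac"], v4 = pr["sd_scale_vB"],
                v5 = pr["sd_scale_sigma"], et = pr["lkj_eta"];
  for (int m = 0; m < 4; ++m) S.sdsc_subj[m] = v1[m];
  for (int m = 0; m < 2; ++m) S.sdsc_region[m] = v2[m];
  for (int m = 0; m < 4; ++m) S.sdsc_tac[m] = v3[m];
  for (int m = 0; m < 2; ++m) { S.sdsc_vB[m] = v4[m]; S.sdsc_sig[m] = v5[m]; }
  S.sdsc_f = as<double>(pr["sd_scale_f"]);
  for (int m = 0; m < 3; ++m) S.eta[m] = et[m];

  S.build_layout();
  S.xb.assign(S.nT * 6, 0.0);
  S.f.assign(std::max(S.nI, 1), 0.0);
  S.tissue.assign(std::max(S.nT * S.nI, 1), 0.0);
  S.mu.assign(std::max(S.nT * S.nI, 1), 0.0);
  S.lsigb.assign(S.nT, 0.0);
  S.ll_data.assign(S.nT, 0.0);
  S.ll_layer.assign(S.nT, 0.0);
  S.tacs_of_subj.assign(S.J, std::vector<int>());
  S.tacs_of_reg.assign(S.K, std::vector<int>());
  for (int t = 0; t < S.nT; ++t) {
    S.tacs_of_subj[S.subj[t]].push_back(t);
    S.tacs_of_reg[S.reg[t]].push_back(t);
  }
  S.build_blocks();
}

}  // namespace

// Joint log density (likelihood + all priors, up to additive constants) at
// a full parameter vector; used for independent verification in tests.
// [[Rcpp::export]]
List cpp_log_posterior(List data, NumericVector par) {
  Sampler S;
  sampler_setup(S, data);
  if (par.size() != S.npar) stop("par length mismatch: need %d", S.npar);
  S.par.assign(par.begin(), par.end());
  S.derive_all();
  double ll = 0.0;
  for (int t = 0; t < S.nT; ++t) ll += S.ll_data[t] + S.ll_layer[t];
  double lp = S.joint_log_density() - ll;
  return List::create(_["loglik"] = ll, _["logprior"] = lp,
                      _["npar"] = S.npar);
}

// Per-TAC diagnostic breakdown of the joint density at a parameter vector.
// [[Rcpp::export]]
List cpp_diagnose(List data, NumericVector par) {
  Sampler S;
  sampler_setup(S, data);
  if (par.size() != S.npar) stop("par length mismatch: need %d", S.npar);
  S.par.assign(par.begin(), par.end());
  S.derive_all();
  NumericVector lvB(S.nT), lsb(S.nT);
  if (S.mode == 0)
    for (int t = 0; t < S.nT; ++t) { lvB[t] = S.logvB(t); lsb[t] = S.lsigb[t]; }
  return List::create(_["ll_data"] = NumericVector(S.ll_data.begin(), S.ll_data.end()),
                      _["ll_layer"] = NumericVector(S.ll_layer.begin(), S.ll_layer.end()),
                      _["logvB"] = lvB, _["lsigb"] = lsb);
}

// [[Rcpp::export]]
List cpp_run_chain(List data, NumericVector init, int n_warmup, int n_iter) {
  Sampler S;
  sampler_setup(S, data);
  if (init.size() != S.npar)
    stop("init length %d does not match parameter count %d", init.size(), S.npar);
  S.par.assign(init.begin(), init.end());

  RNGScope rng;
  S.derive_all();

  const bool debug_check = data.containsElementNamed("debug_check") &&
                           as<bool>(data["debug_check"]);
  NumericMatrix draws(n_iter, S.npar);
  NumericVector lpdraws(n_iter);
  const int reset1 = n_warmup / 3, reset2 = (2 * n_warmup) / 3;
  for (int it = 0; it < n_warmup + n_iter; ++it) {
    const bool adapt = it < n_warmup;
    if (it == reset1 || it == reset2) S.reset_adaptation();
    for (size_t bi = 0; bi < S.blocks.size(); ++bi)
      for (int r = 0; r < S.blocks[bi].reps; ++r) {
        S.update_block(S.blocks[bi], adapt);
        if (debug_check) {
          // verify without perturbing the trajectory: save all caches,
          // recompute from par, compare, then put the caches back
          std::vector<double> lld = S.ll_data, lll = S.ll_layer,
              sv_tis = S.tissue, sv_mu = S.mu, sv_lsb = S.lsigb,
              sv_f = S.f, sv_xb = S.xb;
          S.derive_all();
          double d1 = 0, d2 = 0;
          for (int t = 0; t < S.nT; ++t) {
            d1 += std::fabs(lld[t] - S.ll_data[t]);
            d2 += std::fabs(lll[t] - S.ll_layer[t]);
          }
          double d3 = 0, d4 = 0, d5 = 0;
          for (int t = 0; t < S.nT; ++t) d3 += std::fabs(sv_lsb[t] - S.lsigb[t]);
          for (size_t q = 0; q < S.mu.size(); ++q) {
            const bool na1 = !R_finite(sv_mu[q]), na2 = !R_finite(S.mu[q]);
            if (na1 != na2) d4 += 1.0;
            else if (!na1) d4 += std::fabs(sv_mu[q] - S.mu[q]);
          }
          for (int i = 0; i < S.nI; ++i) d5 += std::fabs(sv_f[i] - S.f[i]);
          const bool bad = d1 + d2 + d3 + d4 + d5 > 1e-6;
          int worst = -1; double wd = 0, wmu = 0, wtis = 0, cfresh = 0, ccache = 0;
          double mu0c = 0, mu0f = 0, lsbc = 0, lsbf = 0;
          if (bad) {
            for (int t = 0; t < S.nT; ++t)
              if (std::fabs(lld[t] - S.ll_data[t]) > wd) {
                wd = std::fabs(lld[t] - S.ll_data[t]); worst = t;
              }
            if (worst >= 0) {
              ccache = lld[worst]; cfresh = S.ll_data[worst];
              mu0c = sv_mu[worst * S.nI]; mu0f = S.mu[worst * S.nI];
              lsbc = sv_lsb[worst]; lsbf = S.lsigb[worst];
              for (int i = 0; i < S.nI; ++i) {
                wmu += std::fabs(sv_mu[worst * S.nI + i] - S.mu[worst * S.nI + i]);
                wtis += std::fabs(sv_tis[worst * S.nI + i] - S.tissue[worst * S.nI + i]);
              }
            }
          }
          S.ll_data = lld; S.ll_layer = lll;
          S.tissue = sv_tis; S.mu = sv_mu; S.lsigb = sv_lsb;
          S.f = sv_f; S.xb = sv_xb;
          S.derive_chols();
          if (bad)
            stop("cache drift after block %d (kind %d id %d acc %d) at iter %d: data %g layer %g worstTAC %d cached %g fresh %g mu0 %g/%g lsb %g/%g mudiff %g tisdiff %g",
                 (int)bi, (int)S.blocks[bi].kind, S.blocks[bi].id,
                 (int)S.last_accept, it, d1, d2,
                 worst, ccache, cfresh, mu0c, mu0f, lsbc, lsbf, d3, d4);
        }
      }
    if (it >= n_warmup) {
      const int r = it - n_warmup;
      for (int i = 0; i < S.npar; ++i) draws(r, i) = S.par[i];
      double tot = 0.0;
      for (int t = 0; t < S.nT; ++t) tot += S.ll_data[t];
      lpdraws[r] = tot;
    }
    if (it % 200 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector acc(S.blocks.size());
  for (size_t bi = 0; bi < S.blocks.size(); ++bi)
    acc[bi] = S.blocks[bi].trials ? (double)S.blocks[bi].accepts / S.blocks[bi].trials : NA_REAL;
  return List::create(_["draws"] = draws, _["loglik"] = lpdraws,
                      _["accept"] = acc, _["npar"] = S.npar);
}
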