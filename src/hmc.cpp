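// Hamiltonian Monte Carlo for GLMMs with multi-membership / correlated
// random intercepts. Likelihoods: beta (logit link, mean-precision),
// poisson (log link), gaussian (identity link).
//
// Unconstrained parameter vector layout:
//   [ beta (p) | z_1 (q_1) ... z_B (q_B) | log_sigma_1 ... log_sigma_B | aux ]
// where z_b are standardized random effects (non-centred parameterization,
// effect_b = sigma_b * L_b * z_b; L_b lower Cholesky of a correlation
// matrix, identity when absent) and aux is log(phi) for the beta
// likelihood or log(sigma_res) for the gaussian one.
//
// Priors: slopes N(0,5); intercept student-t(3,0,2.5); sigma_b and
// sigma_res half-t(3,0,2.5); phi Gamma(0.01, 0.01). All RNG draws come
// from R's generator so set.seed() in R gives bit-reproducible chains.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct REBlock {
  arma::imat idx;   // n x m, 0-based membership indices, -1 = absent
  arma::mat L;      // q x q lower Cholesky, empty => identity
  int q;
  bool has_L;
  bool center;      // sum-to-zero constraint (identifies the intercept)
  bool cp;          // centered parameterization (effect stored directly;
                    // preferable when each level is strongly informed)
};

struct ModelData {
  arma::vec y;
  arma::mat X;
  int likelihood;     // 0 beta, 1 poisson, 2 gaussian
  bool has_intercept; // first column of X is the intercept
  std::vector<REBlock> blocks;
  int p, n, n_aux, P;
  int cached_totq;
  arma::vec logy, log1my; // cached for beta likelihood
  int totq() const { return cached_totq; }
};

const double T_NU = 3.0, T_S = 2.5, T_S2 = 2.5 * 2.5;
const double PHI_A = 0.01, PHI_B = 0.01;

// fast lgamma/digamma for strictly positive arguments: upward recurrence
// into the asymptotic (Stirling) regime; |err| < 1e-12 for x > 0
inline double fast_lgamma(double x) {
  double s = 0.0;
  while (x < 8.0) { s -= std::log(x); x += 1.0; }
  const double x2 = 1.0 / (x * x);
  return s + (x - 0.5) * std::log(x) - x + 0.9189385332046727 +
         (1.0 / 12.0 - (1.0 / 360.0 - x2 / 1260.0) * x2) / x;
}
inline double fast_digamma(double x) {
  double s = 0.0;
  while (x < 6.0) { s -= 1.0 / x; x += 1.0; }
  const double x2 = 1.0 / (x * x);
  return s + std::log(x) - 0.5 / x -
         x2 * (1.0 / 12.0 - x2 * (1.0 / 120.0 - x2 / 252.0));
}

// log half-t(3,0,2.5) on sigma plus log-Jacobian of sigma = exp(ls)
inline double lp_half_t(double sigma, double ls) {
  return -0.5 * (T_NU + 1.0) * std::log1p(sigma * sigma / (T_NU * T_S2)) + ls;
}
inline double grad_half_t(double sigma) {
  return -(T_NU + 1.0) * sigma * sigma / (T_NU * T_S2 + sigma * sigma) + 1.0;
}

// Joint log posterior and gradient; returns -inf on numerical failure.
double lp_grad(const ModelData& d, const arma::vec& theta, arma::vec& grad) {
  grad.zeros(d.P);
  const int p = d.p, B = (int)d.blocks.size();
  arma::vec beta = theta.subvec(0, p - 1);
  double lp = 0.0;

  // fixed-effect priors
  for (int j = 0; j < p; ++j) {
    double b = beta[j];
    if (j == 0 && d.has_intercept) {
      lp += -0.5 * (T_NU + 1.0) * std::log1p(b * b / (T_NU * T_S2));
      grad[j] += -(T_NU + 1.0) * b / (T_NU * T_S2 + b * b);
    } else {
      lp += -b * b / 50.0;
      grad[j] += -b / 25.0;
    }
  }

  arma::vec eta = d.X * beta;
  std::vector<arma::vec> w(B);
  std::vector<double> sig(B);
  int off = p;
  for (int b = 0; b < B; ++b) {
    const REBlock& blk = d.blocks[b];
    arma::vec z = theta.subvec(off, off + blk.q - 1);
    double ls = theta[p + d.totq() + b];
    sig[b] = std::exp(ls);
    lp += lp_half_t(sig[b], ls);
    if (blk.cp) {
      // u ~ N(0, sigma^2 I), stored directly
      lp += -0.5 * arma::dot(z, z) / (sig[b] * sig[b]) - blk.q * ls;
      w[b] = z;
    } else {
      lp += -0.5 * arma::dot(z, z); // z ~ N(0,1), effect = sigma * L * z
      w[b] = blk.has_L ? arma::vec(blk.L * z) : z;
    }
    if (blk.center) w[b] -= arma::mean(w[b]);
    double scale = blk.cp ? 1.0 : sig[b];
    for (int i = 0; i < d.n; ++i)
      for (arma::uword c = 0; c < blk.idx.n_cols; ++c) {
        int j = blk.idx(i, c);
        if (j >= 0) eta[i] += scale * w[b][j];
      }
    off += blk.q;
  }

  // likelihood and d(loglik)/d(eta)
  arma::vec g(d.n);
  double aux_grad = 0.0;
  if (d.likelihood == 0) {
    double logphi = theta[d.P - 1];
    if (logphi > 25.0 || logphi < -25.0) return -INFINITY;
    double phi = std::exp(logphi);
    double dphi_sum = 0.0;
    const double lg_phi = fast_lgamma(phi), dg_phi = fast_digamma(phi);
    for (int i = 0; i < d.n; ++i) {
      double mu = 1.0 / (1.0 + std::exp(-eta[i]));
      mu = std::min(1.0 - 1e-10, std::max(1e-10, mu));
      double a = mu * phi, bb = (1.0 - mu) * phi;
      lp += lg_phi - fast_lgamma(a) - fast_lgamma(bb) +
            (a - 1.0) * d.logy[i] + (bb - 1.0) * d.log1my[i];
      double da = fast_digamma(a), db = fast_digamma(bb);
      double dmu = phi * (-da + db + d.logy[i] - d.log1my[i]);
      g[i] = dmu * mu * (1.0 - mu);
      dphi_sum += dg_phi - mu * da - (1.0 - mu) * db +
                  mu * d.logy[i] + (1.0 - mu) * d.log1my[i];
    }
    lp += PHI_A * logphi - PHI_B * phi; // Gamma prior + Jacobian
    aux_grad = phi * dphi_sum + PHI_A - PHI_B * phi;
  } else if (d.likelihood == 1) {
    for (int i = 0; i < d.n; ++i) {
      double e = std::min(eta[i], 30.0);
      double lam = std::exp(e);
      lp += d.y[i] * eta[i] - lam - R::lgammafn(d.y[i] + 1.0);
      g[i] = d.y[i] - lam;
    }
  } else {
    double ls = theta[d.P - 1];
    if (ls > 25.0 || ls < -25.0) return -INFINITY;
    double s = std::exp(ls), s2 = s * s, rss = 0.0;
    for (int i = 0; i < d.n; ++i) {
      double r = d.y[i] - eta[i];
      rss += r * r;
      g[i] = r / s2;
    }
    lp += -d.n * ls - rss / (2.0 * s2);
    aux_grad = -d.n + rss / s2 + grad_half_t(s);
    lp += lp_half_t(s, ls);
  }
  if (!std::isfinite(lp)) return -INFINITY;

  grad.subvec(0, p - 1) += d.X.t() * g;
  off = p;
  for (int b = 0; b < B; ++b) {
    const REBlock& blk = d.blocks[b];
    arma::vec ge(blk.q, arma::fill::zeros);
    for (int i = 0; i < d.n; ++i)
      for (arma::uword c = 0; c < blk.idx.n_cols; ++c) {
        int j = blk.idx(i, c);
        if (j >= 0) ge[j] += g[i];
      }
    arma::vec gec = blk.center ? arma::vec(ge - arma::mean(ge)) : ge;
    arma::vec z = theta.subvec(off, off + blk.q - 1);
    if (blk.cp) {
      double s2 = sig[b] * sig[b];
      grad.subvec(off, off + blk.q - 1) += gec - z / s2;
      grad[p + d.totq() + b] += arma::dot(z, z) / s2 - blk.q +
          grad_half_t(sig[b]);
    } else {
      arma::vec gz = blk.has_L ? arma::vec(blk.L.t() * gec) : gec;
      grad.subvec(off, off + blk.q - 1) += sig[b] * gz - z;
      grad[p + d.totq() + b] += sig[b] * arma::dot(w[b], ge) +
          grad_half_t(sig[b]);
    }
    off += blk.q;
  }
  if (d.n_aux == 1) grad[d.P - 1] += aux_grad;
  return lp;
}

// log-likelihood only, for interweaved scale updates
double lik_only(const ModelData& d, const arma::vec& eta, double aux) {
  double lp = 0.0;
  if (d.likelihood == 0) {
    double phi = std::exp(aux);
    const double lg_phi = fast_lgamma(phi);
    for (int i = 0; i < d.n; ++i) {
      double mu = 1.0 / (1.0 + std::exp(-eta[i]));
      mu = std::min(1.0 - 1e-10, std::max(1e-10, mu));
      double a = mu * phi, bb = (1.0 - mu) * phi;
      lp += lg_phi - fast_lgamma(a) - fast_lgamma(bb) +
            (a - 1.0) * d.logy[i] + (bb - 1.0) * d.log1my[i];
    }
  } else if (d.likelihood == 1) {
    for (int i = 0; i < d.n; ++i)
      lp += d.y[i] * eta[i] - std::exp(std::min(eta[i], 30.0));
  } else {
    double sg = std::exp(aux), s2 = sg * sg, rss = 0.0;
    for (int i = 0; i < d.n; ++i) {
      double r = d.y[i] - eta[i];
      rss += r * r;
    }
    lp += -d.n * aux - rss / (2.0 * s2);
  }
  return lp;
}

// Conditional log-density of log(sigma) for a centered block given its
// effects u: -q*ls - 0.5*ssq/sigma^2 + half-t prior (with Jacobian).
inline double lp_ls_cond(double ls, double ssq, int q) {
  double sigma = std::exp(ls);
  return -q * ls - 0.5 * ssq / (sigma * sigma) + lp_half_t(sigma, ls);
}

// Univariate slice sampler (stepping out + shrinkage, Neal 2003)
template <class F>
double slice_sample_1d(double x0, F target) {
  const double w = 0.5;
  const int m = 50;
  double f0 = target(x0);
  double logy = f0 + std::log(unif_rand());
  double L = x0 - w * unif_rand(), R = L + w;
  int j = (int)std::floor(m * unif_rand()), k = m - 1 - j;
  while (j-- > 0 && target(L) > logy) L -= w;
  while (k-- > 0 && target(R) > logy) R += w;
  for (int it = 0; it < 100; ++it) {
    double x1 = L + unif_rand() * (R - L);
    if (target(x1) > logy) return x1;
    if (x1 < x0) L = x1; else R = x1;
  }
  return x0;
}

} // namespace

// -- Rcpp entry ------------------------------------------------------------

// [[Rcpp::export(name = ".hmc_run")]]
List hmc_run(NumericVector y, NumericMatrix X, List blocks, int likelihood,
             bool has_intercept, NumericMatrix inits, int warmup, int iter,
             double target_accept, int max_steps, double traj_len,
             List nest) {
  ModelData d;
  d.y = as<arma::vec>(y);
  d.X = as<arma::mat>(X);
  d.likelihood = likelihood;
  d.has_intercept = has_intercept;
  d.n = d.X.n_rows;
  d.p = d.X.n_cols;
  for (int b = 0; b < blocks.size(); ++b) {
    List bl = blocks[b];
    REBlock blk;
    blk.idx = as<arma::imat>(as<IntegerMatrix>(bl["idx"]));
    blk.q = as<int>(bl["q"]);
    blk.center = bl.containsElementNamed("center") ?
        as<bool>(bl["center"]) : false;
    blk.cp = bl.containsElementNamed("cp") ? as<bool>(bl["cp"]) : false;
    if (blk.cp && bl.containsElementNamed("L") && !Rf_isNull(bl["L"]))
      stop("centered parameterization does not support a Cholesky factor");
    if (bl.containsElementNamed("L") && !Rf_isNull(bl["L"])) {
      blk.L = as<arma::mat>(as<NumericMatrix>(bl["L"]));
      blk.has_L = true;
    } else {
      blk.has_L = false;
    }
    d.blocks.push_back(blk);
  }
  d.n_aux = (likelihood == 1) ? 0 : 1;
  int totq = 0;
  for (auto& b : d.blocks) totq += b.q;
  d.cached_totq = totq;
  d.P = d.p + totq + (int)d.blocks.size() + d.n_aux;
  if (likelihood == 0) {
    d.logy = arma::log(d.y);
    d.log1my = arma::log(1.0 - d.y);
  }

  const int chains = inits.ncol();
  arma::mat draws(iter * chains, d.P);
  IntegerVector chain_id(iter * chains), divergences(chains);
  IntegerVector div_nonfinite(chains), div_energy(chains);
  NumericVector step_sizes(chains), accept_stat(chains);

  const double gamma_da = 0.05, t0 = 10.0, kappa = 0.75;
  const int w_lo = std::max(1, (int)std::floor(0.25 * warmup));
  const int w_hi = std::max(w_lo + 2, (int)std::floor(0.75 * warmup));

  // nested-split Gibbs: when child levels (e.g. samples) map many-to-one
  // onto parent levels (individuals) the likelihood depends only on
  // t = u_child + v_parent; the split is redrawn from its exact Gaussian
  // conditional each iteration.
  bool has_nest = nest.size() > 0;
  int nest_child = 0, nest_parent = 0;
  arma::ivec nest_map;
  if (has_nest) {
    nest_child = as<int>(nest["child"]);
    nest_parent = as<int>(nest["parent"]);
    nest_map = as<arma::ivec>(as<IntegerVector>(nest["map"]));
  }

  // indices of log-sigma parameters updated by slice sampling (cp blocks)
  std::vector<int> gibbs_ls, frozen_ls;
  {
    int off = d.p;
    for (auto& b : d.blocks) off += b.q;
    for (size_t b = 0; b < d.blocks.size(); ++b) {
      frozen_ls.push_back(off + (int)b); // all sigmas move by slice only
      if (d.blocks[b].cp) gibbs_ls.push_back(off + (int)b);
    }
  }

  for (int c = 0; c < chains; ++c) {
    arma::vec theta(d.P);
    for (int j = 0; j < d.P; ++j) theta[j] = inits(j, c);
    arma::vec minv(d.P, arma::fill::ones); // inverse mass (posterior var)
    for (int j : frozen_ls) minv[j] = 0.0; // frozen during leapfrog
    // the nested parent's effects are redrawn by exact Gibbs each
    // iteration; freezing them in the leapfrog avoids the stiff prior
    // direction at small sigma (the child alone moves the sum t)
    if (has_nest) {
      int offp = d.p;
      for (int b = 0; b < nest_parent; ++b) offp += d.blocks[b].q;
      for (int j = 0; j < d.blocks[nest_parent].q; ++j) minv[offp + j] = 0.0;
    }
    arma::vec grad(d.P), grad_prop(d.P);
    double lp = lp_grad(d, theta, grad);
    if (!std::isfinite(lp)) stop("non-finite log posterior at initial values");

    double eps = 0.1 / std::sqrt((double)d.P);
    double mu_da = std::log(10.0 * eps), hbar = 0.0, log_eps_bar = std::log(eps);
    int m_da = 0;
    // Welford accumulators for mass-matrix window
    arma::vec acc_m(d.P, arma::fill::zeros), acc_s(d.P, arma::fill::zeros);
    int acc_n = 0;
    int ndiv = 0;
    double asum = 0.0;
    int a_n = 0;

    for (int it = 0; it < warmup + iter; ++it) {
      bool adapting = it < warmup;
      // momentum p ~ N(0, M), M = 1/minv
      arma::vec pm(d.P);
      for (int j = 0; j < d.P; ++j)
        pm[j] = minv[j] > 0 ? norm_rand() / std::sqrt(minv[j]) : 0.0;
      double H0 = -lp;
      for (int j = 0; j < d.P; ++j) H0 += 0.5 * pm[j] * pm[j] * minv[j];

      int Lbase = std::max(1, std::min(max_steps,
                     (int)std::ceil(traj_len / eps)));
      // +/-25% length jitter breaks resonances without the efficiency
      // loss of uniform-over-[1, L] trajectory lengths
      int steps = std::max(1, (int)std::lround(Lbase * (0.75 + 0.5 * unif_rand())));

      arma::vec th = theta, gr = grad, pv = pm;
      double lp_prop = lp;
      bool div = false;
      for (int s = 0; s < steps; ++s) {
        pv += 0.5 * eps * gr;
        th += eps * (minv % pv);
        lp_prop = lp_grad(d, th, gr);
        if (!std::isfinite(lp_prop)) { div = true; break; }
        pv += 0.5 * eps * gr;
      }
      double alpha;
      bool nonfin = div;
      if (div) {
        alpha = 0.0;
        if (!adapting) ++div_nonfinite[c];
      } else {
        double H1 = -lp_prop;
        for (int j = 0; j < d.P; ++j) H1 += 0.5 * pv[j] * pv[j] * minv[j];
        double dH = H1 - H0;
        if (!std::isfinite(dH) || dH > 1000.0) {
          div = true;
          alpha = 0.0;
          if (!adapting) ++div_energy[c];
        } else {
          alpha = dH < 0 ? 1.0 : std::exp(-dH);
          if (unif_rand() < alpha) {
            theta = th;
            lp = lp_prop;
            grad = gr;
          }
        }
      }
      if (div && !adapting) ++ndiv;

      if (has_nest) {
        int offc = d.p, offp = d.p;
        for (int b = 0; b < nest_child; ++b) offc += d.blocks[b].q;
        for (int b = 0; b < nest_parent; ++b) offp += d.blocks[b].q;
        int qc = d.blocks[nest_child].q, qp = d.blocks[nest_parent].q;
        int lsu_i = d.p + d.totq() + nest_child;
        int lsv_i = d.p + d.totq() + nest_parent;
        // t = u + v[map]; the likelihood depends on the blocks only via t
        arma::vec t(qc);
        for (int sdx = 0; sdx < qc; ++sdx)
          t[sdx] = theta[offc + sdx] + theta[offp + nest_map[sdx]];
        arma::vec S1(qp, arma::fill::zeros), S2(qp, arma::fill::zeros),
                  kc(qp, arma::fill::zeros);
        for (int sdx = 0; sdx < qc; ++sdx) {
          int i2 = nest_map[sdx];
          S1[i2] += t[sdx];
          S2[i2] += t[sdx] * t[sdx];
          kc[i2] += 1.0;
        }
        // collapsed conditional of (log sigma_u, log sigma_v) given t,
        // with u and v integrated out analytically per parent level
        auto lp_coll = [&](double lsu, double lsv) {
          double su2 = std::exp(2.0 * lsu), sv2 = std::exp(2.0 * lsv);
          double lp2 = lp_half_t(std::exp(lsu), lsu) +
                       lp_half_t(std::exp(lsv), lsv);
          for (int i2 = 0; i2 < qp; ++i2) {
            double k = kc[i2];
            if (k == 0) continue;
            double den = su2 + k * sv2;
            lp2 += -0.5 * ((k - 1.0) * std::log(su2) + std::log(den));
            lp2 += -0.5 * (S2[i2] / su2 -
                           sv2 * S1[i2] * S1[i2] / (su2 * den));
          }
          return lp2;
        };
        for (int sweep = 0; sweep < 2; ++sweep) {
          theta[lsu_i] = slice_sample_1d(theta[lsu_i], [&](double x) {
            return lp_coll(x, theta[lsv_i]);
          });
          theta[lsv_i] = slice_sample_1d(theta[lsv_i], [&](double x) {
            return lp_coll(theta[lsu_i], x);
          });
        }
        // redraw the split v | t, sigmas from its exact conditional
        double su = std::exp(theta[lsu_i]), sv = std::exp(theta[lsv_i]);
        double pu = 1.0 / (su * su), pv = 1.0 / (sv * sv);
        for (int i2 = 0; i2 < qp; ++i2) {
          double prec = pv + kc[i2] * pu;
          double mean = S1[i2] * pu / prec;
          theta[offp + i2] = mean + norm_rand() / std::sqrt(prec);
        }
        for (int sdx = 0; sdx < qc; ++sdx)
          theta[offc + sdx] = t[sdx] - theta[offp + nest_map[sdx]];
      }

      // Interweaved (ASIS) update of centered blocks' log-sigma: first in
      // the sufficient parameterization (closed form given u), then in the
      // ancillary one (u rescaled with sigma; requires likelihood evals).
      if (!d.blocks.empty()) {
        // current eta and per-block centered contributions
        arma::vec beta_cur = theta.subvec(0, d.p - 1);
        arma::vec eta = d.X * beta_cur;
        std::vector<arma::vec> contrib(d.blocks.size());
        int off = d.p;
        for (size_t b = 0; b < d.blocks.size(); ++b) {
          const REBlock& blk = d.blocks[b];
          arma::vec z = theta.subvec(off, off + blk.q - 1);
          double sg = std::exp(theta[d.p + d.totq() + (int)b]);
          arma::vec wv = blk.cp ? z :
            (blk.has_L ? arma::vec(blk.L * z) : z);
          if (blk.center) wv -= arma::mean(wv);
          double scale = blk.cp ? 1.0 : sg;
          arma::vec cb(d.n, arma::fill::zeros);
          for (int i = 0; i < d.n; ++i)
            for (arma::uword cc = 0; cc < blk.idx.n_cols; ++cc) {
              int jj = blk.idx(i, cc);
              if (jj >= 0) cb[i] += scale * wv[jj];
            }
          contrib[b] = cb;
          eta += cb;
          off += blk.q;
        }
        double aux = d.n_aux == 1 ? theta[d.P - 1] : 0.0;
        off = d.p;
        size_t gi = 0;
        for (size_t b = 0; b < d.blocks.size(); ++b) {
          int q = d.blocks[b].q;
          if (d.blocks[b].cp &&
              has_nest && ((int)b == nest_child || (int)b == nest_parent)) {
            ++gi;
            off += q;
            continue;
          }
          if (!d.blocks[b].cp) {
            // sufficient-parameterization interweaving for non-centred
            // blocks: hold u = sigma * L * z fixed, slice log sigma, and
            // rescale z; breaks the funnel when levels are weakly informed
            int li = d.p + d.totq() + (int)b;
            double s0 = std::exp(theta[li]);
            double c2 = arma::dot(theta.subvec(off, off + q - 1),
                                  theta.subvec(off, off + q - 1));
            double ls1 = slice_sample_1d(theta[li], [&](double ls) {
              return -q * ls - 0.5 * s0 * s0 * c2 * std::exp(-2.0 * ls) +
                     lp_half_t(std::exp(ls), ls);
            });
            theta[li] = ls1;
            theta.subvec(off, off + q - 1) *= s0 / std::exp(ls1);
            // ancillary step: hold z fixed, move sigma (likelihood evals)
            double s1 = std::exp(ls1);
            arma::vec eta_other = eta - contrib[b];
            double ls2 = slice_sample_1d(ls1, [&](double ls) {
              double r = std::exp(ls) / s1;
              return lik_only(d, eta_other + r * contrib[b], aux) +
                     lp_half_t(std::exp(ls), ls);
            });
            theta[li] = ls2;
            double r2 = std::exp(ls2) / s1;
            contrib[b] *= r2;
            eta = eta_other + contrib[b];
            off += q;
            continue;
          }
          if (d.blocks[b].cp) {
            int li = gibbs_ls[gi];
            double ssq = arma::dot(theta.subvec(off, off + q - 1),
                                   theta.subvec(off, off + q - 1));
            theta[li] = slice_sample_1d(theta[li], [&](double ls) {
              return lp_ls_cond(ls, ssq, q);
            });
            // ancillary step: hold z = u / sigma fixed, move sigma
            double ls0 = theta[li];
            double s0 = std::exp(ls0);
            arma::vec eta_other = eta - contrib[b];
            theta[li] = slice_sample_1d(ls0, [&](double ls) {
              double r = std::exp(ls) / s0;
              return lik_only(d, eta_other + r * contrib[b], aux) +
                     lp_half_t(std::exp(ls), ls);
            });
            double r = std::exp(theta[li]) / s0;
            theta.subvec(off, off + q - 1) *= r;
            contrib[b] *= r;
            eta = eta_other + contrib[b];
            ++gi;
          }
          off += q;
        }
        lp = lp_grad(d, theta, grad);
      }

      if (adapting) {
        // dual averaging of the step size
        ++m_da;
        hbar = (1.0 - 1.0 / (m_da + t0)) * hbar +
               (target_accept - alpha) / (m_da + t0);
        double log_eps = mu_da - std::sqrt((double)m_da) / gamma_da * hbar;
        double w_da = std::pow((double)m_da, -kappa);
        log_eps_bar = w_da * log_eps + (1.0 - w_da) * log_eps_bar;
        eps = std::exp(log_eps);
        // mass window
        if (it >= w_lo && it < w_hi) {
          ++acc_n;
          arma::vec delta = theta - acc_m;
          acc_m += delta / acc_n;
          acc_s += delta % (theta - acc_m);
        }
        if (it == w_hi - 1 && acc_n > 4) {
          arma::vec v = acc_s / (acc_n - 1);
          // Stan-style regularization toward unit variance
          minv = (double)acc_n / (acc_n + 5.0) * v +
                 1e-3 * (5.0 / (acc_n + 5.0)) * arma::ones(d.P);
          minv.elem(arma::find(minv < 1e-8)).fill(1e-8);
          for (int j : frozen_ls) minv[j] = 0.0;
          if (has_nest) {
            int offp = d.p;
            for (int b = 0; b < nest_parent; ++b) offp += d.blocks[b].q;
            for (int j = 0; j < d.blocks[nest_parent].q; ++j)
              minv[offp + j] = 0.0;
          }
          mu_da = std::log(10.0 * std::exp(log_eps_bar));
          hbar = 0.0;
          m_da = 0;
        }
        if (it == warmup - 1) eps = std::exp(log_eps_bar);
      } else {
        asum += alpha;
        ++a_n;
        int row = c * iter + (it - warmup);
        for (int j = 0; j < d.P; ++j) draws(row, j) = theta[j];
        chain_id[row] = c + 1;
      }
    }
    divergences[c] = ndiv;
    step_sizes[c] = eps;
    accept_stat[c] = a_n > 0 ? asum / a_n : NA_REAL;
  }

  return List::create(_["draws"] = draws, _["chain"] = chain_id,
                      _["divergences"] = divergences,
                      _["step_size"] = step_sizes,
                      _["accept_stat"] = accept_stat,
                      _["n_par"] = d.P,
                      _["div_nonfinite"] = div_nonfinite,
                      _["div_energy"] = div_energy);
}
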