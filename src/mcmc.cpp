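// Metropolis-within-Gibbs sampler for hierarchical spatio-temporal count
// models: y[i,t] ~ Poisson(E[i,t] * r[i,t]) or NB(mean E*r, dispersion kappa),
// log r = alpha + beta_t + beta_lang + beta_urb + phi_i (+ theta_i),
// phi ~ intrinsic CAR (sum-to-zero per component), theta ~ N(0, sigma_theta^2).
//
// Random-walk Metropolis on every scalar; proposal scales adapt toward a
// 0.44 acceptance rate during burn-in only, so the post-burn-in kernel is a
// fixed Markov kernel (detailed balance preserved). R's RNG is used
// throughout, so chains are reproducible from set.seed() on the R side.
#include <Rcpp.h>
using namespace Rcpp;

namespace {

struct Subset {
  // cells over which a scalar shift acts: either whole rows or one column
  std::vector<int> rows;  // row indices; empty + col >= 0 means one column
  int col = -1;           // -1 means all columns of the listed rows
};

struct Sampler {
  int n, T, family;  // family: 0 Poisson, 1 negative binomial
  bool use_phi, use_theta;
  NumericMatrix y, E;
  IntegerVector lang, urb, comp;
  std::vector<std::vector<int>> nbr;
  // priors
  double beta_sd, sphi_scale, stheta_scale, kappa_meanlog, kappa_sdlog;
  // state
  double alpha, log_sphi, log_stheta, log_kappa;
  std::vector<double> beta_t, beta_l, beta_u, phi, theta;
  NumericMatrix mu;  // E * exp(eta), kept in sync
  // precomputed sufficient statistics (Poisson shifts)
  double sumY_all;
  std::vector<double> sumY_col, sumY_lang, rowY;
  double sumY_urb;
  int icar_rank;                 // sum over components >=2 of (size-1)
  std::vector<int> comp_size;

  double kappa() const { return std::exp(log_kappa); }

  void recompute_mu() {
    for (int i = 0; i < n; ++i) {
      double base = alpha + beta_l[lang[i]] + beta_u[urb[i]] + phi[i] + theta[i];
      for (int t = 0; t < T; ++t) {
        mu(i, t) = (E(i, t) > 0.0) ? E(i, t) * std::exp(base + beta_t[t]) : 0.0;
      }
    }
  }

  // log-likelihood change if eta is shifted by delta on the subset
  double delta_ll(double delta, const Subset& s) {
    if (family == 0) {
      double sy = 0.0, sm = 0.0;
      if (s.col >= 0 && s.rows.empty()) {
        sy = sumY_col[s.col];
        for (int i = 0; i < n; ++i) sm += mu(i, s.col);
      } else {
        for (int i : s.rows) {
          sy += rowY[i];
          for (int t = 0; t < T; ++t) sm += mu(i, t);
        }
      }
      return delta * sy - (std::exp(delta) - 1.0) * sm;
    }
    // negative binomial: per-cell evaluation
    double k = kappa(), ed = std::exp(delta), d = 0.0;
    auto cell = [&](int i, int t) {
      double m = mu(i, t);
      if (m <= 0.0) return;
      d += R::dnbinom_mu(y(i, t), k, m * ed, 1) - R::dnbinom_mu(y(i, t), k, m, 1);
    };
    if (s.col >= 0 && s.rows.empty()) {
      for (int i = 0; i < n; ++i) cell(i, s.col);
    } else {
      for (int i : s.rows) for (int t = 0; t < T; ++t) cell(i, t);
    }
    return d;
  }

  void apply_shift(double delta, const Subset& s) {
    double ed = std::exp(delta);
    if (s.col >= 0 && s.rows.empty()) {
      for (int i = 0; i < n; ++i) mu(i, s.col) *= ed;
    } else {
      for (int i : s.rows) for (int t = 0; t < T; ++t) mu(i, t) *= ed;
    }
  }

  double pairwise_ss() const {  // sum over adjacent pairs (i<j) of (phi_i-phi_j)^2
    double ss = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j : nbr[i])
        if (j > i) { double d = phi[i] - phi[j]; ss += d * d; }
    return ss;
  }

  double deviance() const {
    double ll = 0.0;
    double k = (family == 1) ? kappa() : 0.0;
    for (int i = 0; i < n; ++i) for (int t = 0; t < T; ++t) {
      double m = mu(i, t);
      if (m <= 0.0) continue;  // E = 0 forces y = 0; contributes 0
      ll += (family == 0) ? R::dpois(y(i, t), m, 1)
                          : R::dnbinom_mu(y(i, t), k, m, 1);
    }
    return -2.0 * ll;
  }
};

struct Adapt {
  std::vector<double> ls;   // log proposal sd
  std::vector<int> acc, tries;
  explicit Adapt(int m, double s0 = 0.1)
      : ls(m, std::log(s0)), acc(m, 0), tries(m, 0) {}
  void update() {
    for (size_t k = 0; k < ls.size(); ++k) {
      if (tries[k] == 0) continue;
      double rate = double(acc[k]) / tries[k];
      ls[k] += (rate - 0.44);
      if (ls[k] < -10.0) ls[k] = -10.0;
      if (ls[k] > 3.0) ls[k] = 3.0;
      acc[k] = 0; tries[k] = 0;
    }
  }
};

inline bool mh_accept(double log_ratio) {
  return std::log(R::runif(0.0, 1.0)) < log_ratio;
}

}  // namespace

// [[Rcpp::export]]
List run_chain_cpp(NumericMatrix y, NumericMatrix E,
                   IntegerVector lang, IntegerVector urb,
                   List nbr_list, IntegerVector comp,
                   int family, bool use_phi, bool use_theta,
                   List priors, List init,
                   int n_iter, int burn_in, int thin, int adapt_interval) {
  Sampler S;
  S.n = y.nrow(); S.T = y.ncol();
  S.family = family; S.use_phi = use_phi; S.use_theta = use_theta;
  S.y = y; S.E = E; S.lang = lang; S.urb = urb; S.comp = comp;
  S.nbr.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    IntegerVector v = nbr_list[i];
    S.nbr[i] = std::vector<int>(v.begin(), v.end());
  }
  S.beta_sd = as<double>(priors["beta_sd"]);
  S.sphi_scale = as<double>(priors["sigma_phi_scale"]);
  S.stheta_scale = as<double>(priors["sigma_theta_scale"]);
  S.kappa_meanlog = as<double>(priors["kappa_meanlog"]);
  S.kappa_sdlog = as<double>(priors["kappa_sdlog"]);

  S.alpha = as<double>(init["alpha"]);
  S.beta_t = as<std::vector<double>>(init["beta_t"]);
  S.beta_l = as<std::vector<double>>(init["beta_l"]);
  S.beta_u = as<std::vector<double>>(init["beta_u"]);
  S.phi = as<std::vector<double>>(init["phi"]);
  S.theta = as<std::vector<double>>(init["theta"]);
  S.log_sphi = as<double>(init["log_sigma_phi"]);
  S.log_stheta = as<double>(init["log_sigma_theta"]);
  S.log_kappa = as<double>(init["log_kappa"]);

  S.mu = NumericMatrix(S.n, S.T);
  S.recompute_mu();

  // sufficient statistics of y (cells with E = 0 are excluded everywhere)
  S.sumY_all = 0.0; S.sumY_urb = 0.0;
  S.sumY_col.assign(S.T, 0.0); S.sumY_lang.assign(3, 0.0);
  S.rowY.assign(S.n, 0.0);
  for (int i = 0; i < S.n; ++i) for (int t = 0; t < S.T; ++t) {
    if (S.E(i, t) <= 0.0) continue;
    double v = y(i, t);
    S.sumY_all += v; S.sumY_col[t] += v; S.rowY[i] += v;
    S.sumY_lang[lang[i]] += v;
    if (urb[i] == 1) S.sumY_urb += v;
  }

  int n_comp = 0;
  for (int i = 0; i < S.n; ++i) n_comp = std::max(n_comp, comp[i]);
  S.comp_size.assign(n_comp, 0);
  for (int i = 0; i < S.n; ++i) S.comp_size[comp[i] - 1]++;
  S.icar_rank = 0;
  for (int c = 0; c < n_comp; ++c)
    if (S.comp_size[c] >= 2) S.icar_rank += S.comp_size[c] - 1;

  // subsets for the fixed effects
  Subset all_cells;  // all rows, all columns
  for (int i = 0; i < S.n; ++i) all_cells.rows.push_back(i);
  std::vector<Subset> lang_rows(3), urb_rows(2), unit_rows(S.n);
  for (int i = 0; i < S.n; ++i) {
    lang_rows[lang[i]].rows.push_back(i);
    urb_rows[urb[i]].rows.push_back(i);
    unit_rows[i].rows.push_back(i);
  }

  // adaptation blocks: 0 alpha, 1..T-1 beta_t, T..T+1 beta_l(1,2),
  // T+2 beta_u, T+3 sigma_phi, T+4 sigma_theta, T+5 kappa,
  // T+6 joint phi/sigma_phi rescaling
  Adapt ada_g(S.T + 7);
  Adapt ada_phi(S.n), ada_theta(S.n);

  int n_keep = 0;
  for (int it = burn_in + 1; it <= n_iter; ++it)
    if ((it - burn_in) % thin == 0) ++n_keep;
  int P = 1 + (S.T - 1) + 2 + 1 +
          (use_phi ? 1 + S.n : 0) + (use_theta ? 1 + S.n : 0) +
          (family == 1 ? 1 : 0);
  NumericMatrix draws(n_keep, P);
  NumericVector dev(n_keep);

  int keep_row = 0;
  for (int it = 1; it <= n_iter; ++it) {
    bool adapting = (it <= burn_in);

    // --- alpha ---
    {
      double sd = std::exp(ada_g.ls[0]);
      double d = R::rnorm(0.0, sd);
      double lr = S.delta_ll(d, all_cells) +
                  (S.alpha * S.alpha -
                   (S.alpha + d) * (S.alpha + d)) / (2.0 * S.beta_sd * S.beta_sd);
      ada_g.tries[0]++;
      if (mh_accept(lr)) {
        S.apply_shift(d, all_cells); S.alpha += d; ada_g.acc[0]++;
      }
    }
    // --- period effects (reference t = 0 fixed at 0) ---
    for (int t = 1; t < S.T; ++t) {
      Subset s; s.col = t;
      double sd = std::exp(ada_g.ls[t]);
      double d = R::rnorm(0.0, sd);
      double b = S.beta_t[t];
      double lr = S.delta_ll(d, s) +
                  (b * b - (b + d) * (b + d)) / (2.0 * S.beta_sd * S.beta_sd);
      ada_g.tries[t]++;
      if (mh_accept(lr)) { S.apply_shift(d, s); S.beta_t[t] += d; ada_g.acc[t]++; }
    }
    // --- language effects (reference level 0) ---
    for (int l = 1; l < 3; ++l) {
      int blk = S.T - 1 + l;
      double sd = std::exp(ada_g.ls[blk]);
      double d = R::rnorm(0.0, sd);
      double b = S.beta_l[l];
      double lr = S.delta_ll(d, lang_rows[l]) +
                  (b * b - (b + d) * (b + d)) / (2.0 * S.beta_sd * S.beta_sd);
      ada_g.tries[blk]++;
      if (mh_accept(lr)) {
        S.apply_shift(d, lang_rows[l]); S.beta_l[l] += d; ada_g.acc[blk]++;
      }
    }
    // --- urbanisation effect ---
    {
      int blk = S.T + 2;
      double sd = std::exp(ada_g.ls[blk]);
      double d = R::rnorm(0.0, sd);
      double b = S.beta_u[1];
      double lr = S.delta_ll(d, urb_rows[1]) +
                  (b * b - (b + d) * (b + d)) / (2.0 * S.beta_sd * S.beta_sd);
      ada_g.tries[blk]++;
      if (mh_accept(lr)) {
        S.apply_shift(d, urb_rows[1]); S.beta_u[1] += d; ada_g.acc[blk]++;
      }
    }
    // --- spatial field ---
    if (use_phi) {
      double sphi = std::exp(S.log_sphi);
      double pv = sphi * sphi;
      for (int i = 0; i < S.n; ++i) {
        int deg = (int)S.nbr[i].size();
        if (deg == 0) continue;  // island: phi pinned at 0
        double nm = 0.0;
        for (int j : S.nbr[i]) nm += S.phi[j];
        nm /= deg;
        double sd = std::exp(ada_phi.ls[i]);
        double d = R::rnorm(0.0, sd);
        double p0 = S.phi[i] - nm, p1 = S.phi[i] + d - nm;
        double lr = S.delta_ll(d, unit_rows[i]) +
                    deg * (p0 * p0 - p1 * p1) / (2.0 * pv);
        ada_phi.tries[i]++;
        if (mh_accept(lr)) {
          S.apply_shift(d, unit_rows[i]); S.phi[i] += d; ada_phi.acc[i]++;
        }
      }
      // sigma_phi: random walk on the log scale, half-normal prior on sigma
      {
        int blk = S.T + 3;
        double sd = std::exp(ada_g.ls[blk]);
        double x0 = S.log_sphi, x1 = x0 + R::rnorm(0.0, sd);
        double s0 = std::exp(x0), s1 = std::exp(x1);
        double ss = S.pairwise_ss();
        double lr = -S.icar_rank * (x1 - x0) -
                    0.5 * ss * (1.0 / (s1 * s1) - 1.0 / (s0 * s0)) -
                    (s1 * s1 - s0 * s0) / (2.0 * S.sphi_scale * S.sphi_scale) +
                    (x1 - x0);  // Jacobian of sigma -> log sigma
        ada_g.tries[blk]++;
        if (mh_accept(lr)) { S.log_sphi = x1; ada_g.acc[blk]++; }
      }
      // joint rescaling (phi, sigma_phi) -> (c phi, c sigma_phi): breaks the
      // strong field-scale coupling that slows single-site mixing. The ICAR
      // prior term cancels against the phi part of the Jacobian, leaving
      // the likelihood ratio, the half-normal prior and one factor of c.
      {
        int blk = S.T + 6;
        double sd = std::exp(ada_g.ls[blk]);
        double s = R::rnorm(0.0, sd);
        double c = std::exp(s);
        double sig0 = std::exp(S.log_sphi);
        double dll = 0.0;
        if (S.family == 0) {
          for (int i = 0; i < S.n; ++i) {
            if (S.nbr[i].empty()) continue;
            double di = (c - 1.0) * S.phi[i];
            double sm = 0.0;
            for (int t = 0; t < S.T; ++t) sm += S.mu(i, t);
            dll += di * S.rowY[i] - (std::exp(di) - 1.0) * sm;
          }
        } else {
          double k = S.kappa();
          for (int i = 0; i < S.n; ++i) {
            if (S.nbr[i].empty()) continue;
            double ed = std::exp((c - 1.0) * S.phi[i]);
            for (int t = 0; t < S.T; ++t) {
              double m = S.mu(i, t);
              if (m <= 0.0) continue;
              dll += R::dnbinom_mu(S.y(i, t), k, m * ed, 1) -
                     R::dnbinom_mu(S.y(i, t), k, m, 1);
            }
          }
        }
        double lr = dll -
                    (c * c - 1.0) * sig0 * sig0 /
                        (2.0 * S.sphi_scale * S.sphi_scale) +
                    s;
        ada_g.tries[blk]++;
        if (mh_accept(lr)) {
          for (int i = 0; i < S.n; ++i) {
            if (S.nbr[i].empty()) continue;
            double ed = std::exp((c - 1.0) * S.phi[i]);
            S.phi[i] *= c;
            for (int t = 0; t < S.T; ++t) S.mu(i, t) *= ed;
          }
          S.log_sphi += s;
          ada_g.acc[blk]++;
        }
      }
    }
    // --- unstructured field ---
    if (use_theta) {
      double st = std::exp(S.log_stheta);
      double tv = st * st;
      for (int i = 0; i < S.n; ++i) {
        double sd = std::exp(ada_theta.ls[i]);
        double d = R::rnorm(0.0, sd);
        double t0 = S.theta[i], t1 = t0 + d;
        double lr = S.delta_ll(d, unit_rows[i]) +
                    (t0 * t0 - t1 * t1) / (2.0 * tv);
        ada_theta.tries[i]++;
        if (mh_accept(lr)) {
          S.apply_shift(d, unit_rows[i]); S.theta[i] += d; ada_theta.acc[i]++;
        }
      }
      {
        int blk = S.T + 4;
        double sd = std::exp(ada_g.ls[blk]);
        double x0 = S.log_stheta, x1 = x0 + R::rnorm(0.0, sd);
        double s0 = std::exp(x0), s1 = std::exp(x1);
        double sq = 0.0;
        for (int i = 0; i < S.n; ++i) sq += S.theta[i] * S.theta[i];
        double lr = -S.n * (x1 - x0) -
                    0.5 * sq * (1.0 / (s1 * s1) - 1.0 / (s0 * s0)) -
                    (s1 * s1 - s0 * s0) /
                        (2.0 * S.stheta_scale * S.stheta_scale) +
                    (x1 - x0);
        ada_g.tries[blk]++;
        if (mh_accept(lr)) { S.log_stheta = x1; ada_g.acc[blk]++; }
      }
    }
    // --- NB dispersion ---
    if (family == 1) {
      int blk = S.T + 5;
      double sd = std::exp(ada_g.ls[blk]);
      double x0 = S.log_kappa, x1 = x0 + R::rnorm(0.0, sd);
      double k0 = std::exp(x0), k1 = std::exp(x1);
      double d = 0.0;
      for (int i = 0; i < S.n; ++i) for (int t = 0; t < S.T; ++t) {
        double m = S.mu(i, t);
        if (m <= 0.0) continue;
        d += R::dnbinom_mu(S.y(i, t), k1, m, 1) -
             R::dnbinom_mu(S.y(i, t), k0, m, 1);
      }
      double z0 = (x0 - S.kappa_meanlog) / S.kappa_sdlog;
      double z1 = (x1 - S.kappa_meanlog) / S.kappa_sdlog;
      double lr = d + 0.5 * (z0 * z0 - z1 * z1);
      ada_g.tries[blk]++;
      if (mh_accept(lr)) { S.log_kappa = x1; ada_g.acc[blk]++; }
    }

    // --- per-component re-centering of phi, level absorbed by alpha ---
    if (use_phi) {
      int n_comp_sz = (int)S.comp_size.size();
      std::vector<double> msum(n_comp_sz, 0.0);
      for (int i = 0; i < S.n; ++i) msum[S.comp[i] - 1] += S.phi[i];
      std::vector<double> m(n_comp_sz, 0.0);
      double mbar = 0.0;
      for (int c = 0; c < n_comp_sz; ++c) {
        if (S.comp_size[c] >= 2) m[c] = msum[c] / S.comp_size[c];
        mbar += m[c] * S.comp_size[c];
      }
      mbar /= S.n;
      for (int i = 0; i < S.n; ++i) {
        if ((int)S.nbr[i].size() == 0) continue;
        S.phi[i] -= m[S.comp[i] - 1];
      }
      S.alpha += mbar;
      for (int i = 0; i < S.n; ++i) {
        double shift = mbar - ((int)S.nbr[i].size() == 0 ? 0.0
                                                         : m[S.comp[i] - 1]);
        if (shift != 0.0) {
          double es = std::exp(shift);
          for (int t = 0; t < S.T; ++t) S.mu(i, t) *= es;
        }
      }
    }

    if (adapting && it % adapt_interval == 0) {
      ada_g.update();
      if (use_phi) ada_phi.update();
      if (use_theta) ada_theta.update();
    }

    // periodic exact refresh guards against multiplicative drift in mu
    if (it % 200 == 0) S.recompute_mu();

    if (it > burn_in && (it - burn_in) % thin == 0) {
      S.recompute_mu();
      int col = 0;
      draws(keep_row, col++) = S.alpha;
      for (int t = 1; t < S.T; ++t) draws(keep_row, col++) = S.beta_t[t];
      draws(keep_row, col++) = S.beta_l[1];
      draws(keep_row, col++) = S.beta_l[2];
      draws(keep_row, col++) = S.beta_u[1];
      if (use_phi) {
        draws(keep_row, col++) = std::exp(S.log_sphi);
        for (int i = 0; i < S.n; ++i) draws(keep_row, col++) = S.phi[i];
      }
      if (use_theta) {
        draws(keep_row, col++) = std::exp(S.log_stheta);
        for (int i = 0; i < S.n; ++i) draws(keep_row, col++) = S.theta[i];
      }
      if (family == 1) draws(keep_row, col++) = S.kappa();
      dev[keep_row] = S.deviance();
      ++keep_row;
    }
  }

  return List::create(_["draws"] = draws, _["deviance"] = dev);
}
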