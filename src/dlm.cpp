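// Gaussian state-space machinery for the per-biomarker dynamic linear model.
//
// State per day t: level mu_t (random walk, variance Wmu), short-term
// fluctuation s_t (AR(1) with coefficient phi, innovation variance Ws), and
// device-batch offset b_t (constant within a batch, random-walk innovation
// variance Wb injected only where the batch id changes).
// Observation: y_t = mu_t + s_t + b_t + eps_t, eps_t ~ N(0, V), on the
// log10-concentration scale.  Missing y_t: the update step is skipped.
//
// All random draws go through R's RNG so set.seed() governs reproducibility.

#include <RcppArmadillo.h>
using namespace Rcpp;

static double rinvgamma(double shape, double scale) {
  // X ~ Gamma(shape, rate = scale)  =>  1/X ~ InvGamma(shape, scale)
  return 1.0 / R::rgamma(shape, 1.0 / scale);
}

// draw N(mu, S) for a 2x2 PSD matrix S, tolerant of zero eigenvalues
static arma::vec mvn2(const arma::vec& mu, arma::mat S) {
  S = 0.5 * (S + S.t());
  arma::vec eval;
  arma::mat evec;
  arma::eig_sym(eval, evec, S);
  arma::vec z(mu.n_elem);
  for (arma::uword i = 0; i < z.n_elem; ++i) z(i) = norm_rand();
  arma::vec sd = eval;
  sd.transform([](double v) { return v > 0.0 ? std::sqrt(v) : 0.0; });
  return mu + evec * (sd % z);
}

// Strictly causal filter.  Returns per-day posterior means of the state,
// the filtered mean/variance of (mu + s) and of (mu + s + b), and the
// log-likelihood from the prediction-error decomposition.
// [[Rcpp::export]]
List kalman_filter_cpp(const arma::vec& y, const arma::ivec& batch,
                       double V, double Wmu, double Ws, double Wb,
                       double phi, double m0, double C0mu) {
  const int T = y.n_elem;
  arma::mat m(T, 3);
  arma::vec f_ls(T), q_ls(T), f_all(T), q_all(T), q_mu(T), q_s(T);
  arma::ivec obs(T);

  arma::vec mc(3, arma::fill::zeros);
  mc(0) = m0;
  arma::mat Cc(3, 3, arma::fill::zeros);
  Cc(0, 0) = C0mu;
  if (Ws > 0.0 && std::abs(phi) < 1.0) Cc(1, 1) = Ws / (1.0 - phi * phi);

  arma::mat G(3, 3, arma::fill::eye);
  G(1, 1) = phi;
  const arma::vec F = {1.0, 1.0, 1.0};
  double loglik = 0.0;

  for (int t = 0; t < T; ++t) {
    arma::vec a = G * mc;
    arma::mat R = G * Cc * G.t();
    R(0, 0) += Wmu;
    R(1, 1) += Ws;
    if (t > 0 && batch(t) != batch(t - 1)) R(2, 2) += Wb;

    double f = arma::as_scalar(F.t() * a);
    double Q = arma::accu(R) + V;
    bool have = arma::is_finite(y(t));
    obs(t) = have ? 1 : 0;
    if (have && Q > 0.0) {
      double e = y(t) - f;
      arma::vec K = (R * F) / Q;
      mc = a + K * e;
      Cc = R - Q * (K * K.t());
      loglik += -0.5 * (std::log(2.0 * M_PI * Q) + e * e / Q);
    } else {
      mc = a;
      Cc = R;
    }
    m.row(t) = mc.t();
    f_ls(t) = mc(0) + mc(1);
    q_ls(t) = Cc(0, 0) + Cc(1, 1) + 2.0 * Cc(0, 1);
    f_all(t) = mc(0) + mc(1) + mc(2);
    q_all(t) = arma::accu(Cc);
    q_mu(t) = Cc(0, 0);
    q_s(t) = Cc(1, 1);
  }

  return List::create(_["state_mean"] = m,
                      _["filtered"] = f_ls, _["filtered_var"] = q_ls,
                      _["filtered_with_batch"] = f_all,
                      _["filtered_with_batch_var"] = q_all,
                      _["level_var"] = q_mu, _["fluct_var"] = q_s,
                      _["observed"] = obs, _["loglik"] = loglik);
}

// Gibbs sampler.  Blocks: (a) FFBS for the (mu, s) path given batch offsets;
// (b) joint conjugate draw of the batch step innovations; (c) inverse-gamma
// updates for V, Wmu, Ws, Wb; (d) random-walk Metropolis for phi on its
// uniform support; (e) imputation of missing observations from their
// conditional normal.  `fixed` has entries (V, Wmu, Ws, Wb, phi); NA = free.
// [[Rcpp::export]]
List dlm_gibbs_cpp(const arma::vec& y_in, const arma::ivec& batch,
                   const arma::vec& prior_shape, const arma::vec& prior_scale,
                   double phi_lo, double phi_hi,
                   const arma::vec& fixed,
                   double m0, double C0mu,
                   int n_iter, int n_burn, int thin,
                   double phi_prop_sd, bool store_states) {
  const int T = y_in.n_elem;
  arma::vec y = y_in;

  // missing indices; initialise imputations at the observed mean
  std::vector<int> miss;
  double ysum = 0.0;
  int nobs = 0;
  for (int t = 0; t < T; ++t) {
    if (arma::is_finite(y(t))) { ysum += y(t); ++nobs; }
    else miss.push_back(t);
  }
  const double ybar = nobs > 0 ? ysum / nobs : 0.0;
  for (size_t i = 0; i < miss.size(); ++i) y(miss[i]) = ybar;

  // batch boundaries (day index where a new batch starts)
  std::vector<int> bd;
  for (int t = 1; t < T; ++t)
    if (batch(t) != batch(t - 1)) bd.push_back(t);
  const int K = static_cast<int>(bd.size());

  auto prior_mean = [&](int i) {
    return prior_shape(i) > 1.0 ? prior_scale(i) / (prior_shape(i) - 1.0)
                                : prior_scale(i);
  };
  const bool fV = arma::is_finite(fixed(0)), fWmu = arma::is_finite(fixed(1)),
             fWs = arma::is_finite(fixed(2)), fWb = arma::is_finite(fixed(3)),
             fphi = arma::is_finite(fixed(4));
  double V   = fV   ? fixed(0) : prior_mean(0);
  double Wmu = fWmu ? fixed(1) : prior_mean(1);
  double Ws  = fWs  ? fixed(2) : prior_mean(2);
  double Wb  = fWb  ? fixed(3) : prior_mean(3);
  double phi = fphi ? fixed(4) : 0.5 * (phi_lo + phi_hi);

  arma::vec delta(std::max(K, 1), arma::fill::zeros);
  arma::vec b(T, arma::fill::zeros);

  int n_keep = 0;
  for (int it = 0; it < n_iter; ++it)
    if (it >= n_burn && (it - n_burn) % thin == 0) ++n_keep;
  arma::mat par_draws(n_keep, 5);
  arma::mat state_draws(store_states ? n_keep : 0, store_states ? T : 0);
  arma::mat imp_draws(n_keep, std::max<size_t>(miss.size(), 0));
  int keep = 0, phi_acc = 0, phi_try = 0;

  // FFBS workspaces over states 0..T (row 0 = pre-sample state)
  arma::mat mf(T + 1, 2), aa(T + 1, 2);
  arma::cube Cf(2, 2, T + 1), RR(2, 2, T + 1);
  arma::mat theta(T + 1, 2);

  for (int it = 0; it < n_iter; ++it) {
    // (a) FFBS for (mu, s)
    arma::mat G(2, 2, arma::fill::eye);
    G(1, 1) = phi;
    mf.row(0) = arma::rowvec({m0, 0.0});
    arma::mat C0(2, 2, arma::fill::zeros);
    C0(0, 0) = C0mu;
    if (Ws > 0.0 && std::abs(phi) < 1.0) C0(1, 1) = Ws / (1.0 - phi * phi);
    Cf.slice(0) = C0;
    for (int t = 1; t <= T; ++t) {
      arma::vec a = G * mf.row(t - 1).t();
      arma::mat R = G * Cf.slice(t - 1) * G.t();
      R(0, 0) += Wmu;
      R(1, 1) += Ws;
      aa.row(t) = a.t();
      RR.slice(t) = R;
      double f = a(0) + a(1);
      double Q = arma::accu(R) + V;
      double e = (y(t - 1) - b(t - 1)) - f;
      if (Q > 0.0) {
        arma::vec Kg = arma::sum(R, 1) / Q;  // R * (1,1)' / Q
        mf.row(t) = (a + Kg * e).t();
        Cf.slice(t) = R - Q * (Kg * Kg.t());
      } else {
        mf.row(t) = a.t();
        Cf.slice(t) = R;
      }
    }
    theta.row(T) = mvn2(mf.row(T).t(), Cf.slice(T)).t();
    for (int t = T - 1; t >= 0; --t) {
      arma::mat Rinv = arma::pinv(RR.slice(t + 1));
      arma::mat J = Cf.slice(t) * G.t() * Rinv;
      arma::vec h = mf.row(t).t() +
                    J * (theta.row(t + 1).t() - aa.row(t + 1).t());
      arma::mat H = Cf.slice(t) - J * RR.slice(t + 1) * J.t();
      theta.row(t) = mvn2(h, H).t();
    }
    arma::vec mu = theta.col(0).subvec(1, T);
    arma::vec s = theta.col(1).subvec(1, T);
    const double mu0 = theta(0, 0), s0 = theta(0, 1);

    // (b) batch step innovations: r_t = y_t - mu_t - s_t = X delta + eps
    if (K > 0) {
      if (Wb > 0.0) {
        arma::vec r = y - mu - s;
        arma::mat XtX(K, K);
        arma::vec Xtr(K);
        for (int j = 0; j < K; ++j) {
          Xtr(j) = arma::accu(r.subvec(bd[j], T - 1));
          for (int k = 0; k < K; ++k)
            XtX(j, k) = T - std::max(bd[j], bd[k]);
        }
        arma::mat A = XtX / V + arma::eye(K, K) / Wb;
        arma::vec mu_d = arma::solve(A, Xtr / V);
        arma::mat U = arma::chol(A);  // A = U'U ; cov = U^{-1} U^{-T}
        arma::vec z(K);
        for (int j = 0; j < K; ++j) z(j) = norm_rand();
        delta.head(K) = mu_d + arma::solve(arma::trimatu(U), z);
      } else {
        delta.zeros();
      }
      b.zeros();
      for (int j = 0; j < K; ++j)
        for (int t = bd[j]; t < T; ++t) b(t) += delta(j);
    }

    // (c) variances
    if (!fV) {
      double rss = 0.0;
      for (int t = 0; t < T; ++t) {
        double e = y(t) - mu(t) - s(t) - b(t);
        rss += e * e;
      }
      V = rinvgamma(prior_shape(0) + 0.5 * T, prior_scale(0) + 0.5 * rss);
    }
    if (!fWmu) {
      double ss = (mu(0) - mu0) * (mu(0) - mu0);
      for (int t = 1; t < T; ++t) ss += (mu(t) - mu(t - 1)) * (mu(t) - mu(t - 1));
      Wmu = rinvgamma(prior_shape(1) + 0.5 * T, prior_scale(1) + 0.5 * ss);
    }
    if (!fWs) {
      double ss = s0 * s0 * (1.0 - phi * phi);
      double prev = s0;
      for (int t = 0; t < T; ++t) {
        double e = s(t) - phi * prev;
        ss += e * e;
        prev = s(t);
      }
      Ws = rinvgamma(prior_shape(2) + 0.5 * (T + 1), prior_scale(2) + 0.5 * ss);
    }
    if (!fWb) {
      double ss = 0.0;
      for (int j = 0; j < K; ++j) ss += delta(j) * delta(j);
      // K = 0: no likelihood contribution, posterior = prior
      Wb = rinvgamma(prior_shape(3) + 0.5 * K, prior_scale(3) + 0.5 * ss);
    }

    // (d) phi: random-walk Metropolis on Uniform(phi_lo, phi_hi)
    if (!fphi && Ws > 0.0) {
      ++phi_try;
      double prop = phi + phi_prop_sd * norm_rand();
      if (prop > phi_lo && prop < phi_hi && std::abs(prop) < 1.0) {
        auto logpost = [&](double p) {
          double lp = 0.5 * std::log(1.0 - p * p) -
                      s0 * s0 * (1.0 - p * p) / (2.0 * Ws);
          double prev = s0;
          for (int t = 0; t < T; ++t) {
            double e = s(t) - p * prev;
            lp -= e * e / (2.0 * Ws);
            prev = s(t);
          }
          return lp;
        };
        if (std::log(unif_rand()) < logpost(prop) - logpost(phi)) {
          phi = prop;
          ++phi_acc;
        }
      }
    }

    // (e) impute missing observations
    for (size_t i = 0; i < miss.size(); ++i) {
      int t = miss[i];
      y(t) = mu(t) + s(t) + b(t) + std::sqrt(V) * norm_rand();
    }

    if (it >= n_burn && (it - n_burn) % thin == 0) {
      par_draws(keep, 0) = V;
      par_draws(keep, 1) = Wmu;
      par_draws(keep, 2) = Ws;
      par_draws(keep, 3) = Wb;
      par_draws(keep, 4) = phi;
      if (store_states) state_draws.row(keep) = (mu + s).t();
      for (size_t i = 0; i < miss.size(); ++i)
        imp_draws(keep, i) = y(miss[i]);
      ++keep;
    }
  }

  IntegerVector miss_out(miss.size());
  for (size_t i = 0; i < miss.size(); ++i) miss_out[i] = miss[i] + 1;
  return List::create(_["draws"] = par_draws,
                      _["states"] = state_draws,
                      _["imputed"] = imp_draws,
                      _["missing_days"] = miss_out,
                      _["phi_accept_rate"] =
                          phi_try > 0 ? (double)phi_acc / phi_try : NA_REAL);
}
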