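// MH-within-Gibbs sampler for the two-class mixture IRT model
// (gPCM-m class vs two-node IRTree class).
//
// Sweep order: class indicators -> person traits -> item parameter blocks
// -> mixing weight -> latent covariance -> rescaling to the identified
// unit-variance scale -> record. All likelihood arithmetic is in log space.
// Uses R's RNG throughout, so results are reproducible from set.seed() in R.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int MAX_CAT = 32;

// log gPCM probability of category x (1-based) with cumulative intercepts
// Cb[0..ncat-1]; numerically safe via max subtraction.
static inline double log_gpcm(double a, const double* Cb, int ncat,
                              double th, int x) {
  double at = a * th;
  double s[MAX_CAT];
  double mx = -HUGE_VAL;
  for (int k = 0; k < ncat; ++k) {
    s[k] = Cb[k] + at * (k + 1);
    if (s[k] > mx) mx = s[k];
  }
  double sum = 0.0;
  for (int k = 0; k < ncat; ++k) sum += std::exp(s[k] - mx);
  return s[x - 1] - mx - std::log(sum);
}

static inline double log_sigmoid(double u) {
  // log(1/(1+exp(-u))), stable for both signs
  if (u > 0) return -std::log1p(std::exp(-u));
  return u - std::log1p(std::exp(u));
}

struct Sampler {
  int N, K, m, D1;
  arma::imat X;      // N x K, -1 missing (column per item is contiguous)
  arma::imat Xss;    // N x K informative category, -1 if midpoint/missing
  arma::ivec dcol;   // K: theta column index (1..D) of each item's dimension

  arma::mat theta;   // N x D1 (column 0 = skip trait)
  arma::ivec z;
  arma::vec aR, aS, bS, aT;
  arma::mat bR;      // K x m   (first column fixed 0)
  arma::mat bT;      // K x (m-1)
  arma::mat CbRt;    // m x K cumulative intercepts (transposed for access)
  arma::mat CbTt;    // (m-1) x K
  arma::mat sigma, omega;
  double pi_;

  void refresh_cum(int i) {
    double c = 0.0;
    for (int k = 0; k < m; ++k) { c += bR(i, k); CbRt(k, i) = c; }
    c = 0.0;
    for (int k = 0; k < m - 1; ++k) { c += bT(i, k); CbTt(k, i) = c; }
  }

  // full response-vector log-likelihood of person p under the gPCM class,
  // at trait vector th (length D1)
  double person_ll_g(int p, const double* th) const {
    double ll = 0.0;
    for (int i = 0; i < K; ++i) {
      int x = X(p, i);
      if (x < 0) continue;
      ll += log_gpcm(aR[i], CbRt.colptr(i), m, th[dcol[i]], x);
    }
    return ll;
  }

  // ... and under the IRTree class
  double person_ll_h(int p, const double* th) const {
    double ll = 0.0;
    for (int i = 0; i < K; ++i) {
      int x = X(p, i);
      if (x < 0) continue;
      double u = aS[i] * th[0] + bS[i];
      int xss = Xss(p, i);
      if (xss < 0) {              // midpoint chosen: skip node terminates
        ll += log_sigmoid(u);
      } else {
        ll += log_sigmoid(-u) +
          log_gpcm(aT[i], CbTt.colptr(i), m - 1, th[dcol[i]], xss);
      }
    }
    return ll;
  }

  double person_ll(int p, const double* th, int zp) const {
    return zp == 1 ? person_ll_g(p, th) : person_ll_h(p, th);
  }

  // item-specific log-likelihoods for the three parameter blocks
  double item_ll_R(int i, double a, const double* Cb) const {
    double ll = 0.0;
    const arma::sword* xc = X.colptr(i);
    int dc = dcol[i];
    for (int p = 0; p < N; ++p) {
      if (z[p] == 1 && xc[p] > 0)
        ll += log_gpcm(a, Cb, m, theta(p, dc), (int)xc[p]);
    }
    return ll;
  }
  double item_ll_S(int i, double a, double b) const {
    double ll = 0.0;
    const arma::sword* xc = X.colptr(i);
    const arma::sword* sc = Xss.colptr(i);
    for (int p = 0; p < N; ++p) {
      if (z[p] == 0 && xc[p] > 0) {
        double u = a * theta(p, 0) + b;
        ll += (sc[p] < 0) ? log_sigmoid(u) : log_sigmoid(-u);
      }
    }
    return ll;
  }
  double item_ll_T(int i, double a, const double* Cb) const {
    double ll = 0.0;
    const arma::sword* sc = Xss.colptr(i);
    int dc = dcol[i];
    for (int p = 0; p < N; ++p) {
      if (z[p] == 0 && sc[p] > 0)
        ll += log_gpcm(a, Cb, m - 1, theta(p, dc), (int)sc[p]);
    }
    return ll;
  }
};

// [[Rcpp::export]]
List run_chain_cpp(IntegerMatrix X_, IntegerVector dims_, int m,
                   NumericMatrix theta_, IntegerVector z_,
                   NumericVector aR_, NumericMatrix bR_,
                   NumericVector aS_, NumericVector bS_,
                   NumericVector aT_, NumericMatrix bT_,
                   NumericMatrix sigma_, double pi0,
                   double sigma_df, NumericMatrix sigma_scale_,
                   double log_slope_mean, double log_slope_var,
                   double intercept_var, double skip_intercept_var,
                   NumericVector pi_beta, List ctrl) {
  if (m > MAX_CAT) stop("category count exceeds supported maximum");
  Sampler S;
  S.N = X_.nrow(); S.K = X_.ncol(); S.m = m;
  S.D1 = theta_.ncol();
  const int N = S.N, K = S.K, D1 = S.D1;
  const int mid = (m + 1) / 2;

  S.X.set_size(N, K);
  S.Xss.set_size(N, K);
  for (int i = 0; i < K; ++i)
    for (int p = 0; p < N; ++p) {
      int x = X_(p, i);
      if (x == NA_INTEGER || x < 1) { S.X(p, i) = -1; S.Xss(p, i) = -1; }
      else {
        S.X(p, i) = x;
        S.Xss(p, i) = (x == mid) ? -1 : (x > mid ? x - 1 : x);
      }
    }
  S.dcol.set_size(K);
  for (int i = 0; i < K; ++i) S.dcol[i] = dims_[i];  // theta col 1..D

  S.theta = as<arma::mat>(theta_);
  S.z = as<arma::ivec>(z_);
  S.aR = as<arma::vec>(aR_); S.bR = as<arma::mat>(bR_);
  S.aS = as<arma::vec>(aS_); S.bS = as<arma::vec>(bS_);
  S.aT = as<arma::vec>(aT_); S.bT = as<arma::mat>(bT_);
  S.sigma = as<arma::mat>(sigma_);
  S.omega = arma::inv_sympd(S.sigma);
  S.pi_ = pi0;
  S.CbRt.set_size(m, K);
  S.CbTt.set_size(m - 1, K);
  for (int i = 0; i < K; ++i) S.refresh_cum(i);

  arma::mat scale_prior = as<arma::mat>(sigma_scale_);

  const int n_iter = as<int>(ctrl["n_iter"]);
  const int n_burnin = as<int>(ctrl["n_burnin"]);
  const bool sample_z = as<bool>(ctrl["sample_z"]);
  const bool sample_items = as<bool>(ctrl["sample_items"]);
  const bool sample_sigma = as<bool>(ctrl["sample_sigma"]);
  const bool sample_pi = as<bool>(ctrl["sample_pi"]);
  const bool store_persons = as<bool>(ctrl["store_persons"]);
  const bool adapt_burnin_only = as<bool>(ctrl["adapt_burnin_only"]);
  const double target_acc = as<double>(ctrl["target_acc"]);
  const int T = n_iter - n_burnin;

  // proposal scales (log), adapted by Robbins-Monro during burn-in
  arma::vec ls_theta(N); ls_theta.fill(std::log(as<double>(ctrl["step_theta"])));
  arma::vec ls_R(K), ls_S(K), ls_T(K);
  ls_R.fill(std::log(as<double>(ctrl["step_item"])));
  ls_S = ls_R; ls_T = ls_R;

  const double sd_la = std::sqrt(log_slope_var);
  const double v_b = intercept_var, v_s = skip_intercept_var;

  // draw storage
  arma::cube thetaDraws;
  arma::mat theta_sum(N, D1, arma::fill::zeros),
    theta_sumsq(N, D1, arma::fill::zeros);
  if (store_persons) thetaDraws.set_size(T, N, D1);
  IntegerMatrix zDraws(T, N);
  arma::mat aRd(T, K), aSd(T, K), bSd(T, K), aTd(T, K);
  arma::cube bRd(T, K, m), bTd(T, K, m - 1), sigmaDraws(T, D1, D1);
  arma::vec piDraws(T), loglikDraws(T);

  double n_acc_theta = 0, n_prop_theta = 0, n_acc_item = 0, n_prop_item = 0;

  std::vector<double> th_cur(D1), th_prop(D1), blk_prop(MAX_CAT + 1),
    Cb_prop(MAX_CAT);

  arma::vec cur_ll(N);           // per-person class loglik cache
  for (int p = 0; p < N; ++p) {
    for (int j = 0; j < D1; ++j) th_cur[j] = S.theta(p, j);
    cur_ll[p] = S.person_ll(p, th_cur.data(), S.z[p]);
  }

  for (int iter = 1; iter <= n_iter; ++iter) {
    const bool adapting = !adapt_burnin_only || iter <= n_burnin;
    const double gamma = std::min(0.5, 1.0 / std::sqrt((double)iter));

    // --- class indicators -------------------------------------------------
    if (sample_z) {
      double lodds0 = std::log(S.pi_) - std::log1p(-S.pi_);
      for (int p = 0; p < N; ++p) {
        for (int j = 0; j < D1; ++j) th_cur[j] = S.theta(p, j);
        double lg = S.person_ll_g(p, th_cur.data());
        double lh = S.person_ll_h(p, th_cur.data());
        double pz = 1.0 / (1.0 + std::exp(-(lodds0 + lg - lh)));
        S.z[p] = (unif_rand() < pz) ? 1 : 0;
        cur_ll[p] = S.z[p] == 1 ? lg : lh;
      }
    }

    // --- person traits (random-walk MH) -----------------------------------
    for (int p = 0; p < N; ++p) {
      double step = std::exp(ls_theta[p]);
      for (int j = 0; j < D1; ++j) {
        th_cur[j] = S.theta(p, j);
        th_prop[j] = th_cur[j] + step * norm_rand();
      }
      // MVN(0, Sigma) prior quadratic forms
      double q_cur = 0, q_prop = 0;
      for (int a = 0; a < D1; ++a)
        for (int b = 0; b < D1; ++b) {
          q_cur += th_cur[a] * S.omega(a, b) * th_cur[b];
          q_prop += th_prop[a] * S.omega(a, b) * th_prop[b];
        }
      double ll_prop = S.person_ll(p, th_prop.data(), S.z[p]);
      double lr = (ll_prop - 0.5 * q_prop) - (cur_ll[p] - 0.5 * q_cur);
      bool acc = std::log(unif_rand()) < lr;
      if (acc) {
        for (int j = 0; j < D1; ++j) S.theta(p, j) = th_prop[j];
        cur_ll[p] = ll_prop;
      }
      if (adapting)
        ls_theta[p] += gamma * ((acc ? 1.0 : 0.0) - target_acc);
      if (iter > n_burnin) { n_prop_theta += 1; if (acc) n_acc_theta += 1; }
    }

    // --- item parameter blocks --------------------------------------------
    if (sample_items) {
      for (int i = 0; i < K; ++i) {
        // R family: (log alpha_R, beta_R[2..m])
        {
          double step = std::exp(ls_R[i]);
          double la_cur = std::log(S.aR[i]);
          double la_prop = la_cur + step * norm_rand();
          double lp = -0.5 * (la_prop * la_prop - la_cur * la_cur +
                              2.0 * log_slope_mean * (la_cur - la_prop)) /
                      (sd_la * sd_la);
          Cb_prop[0] = 0.0;
          double c = 0.0;
          blk_prop[0] = 0.0;
          for (int k = 1; k < m; ++k) {
            double b_cur = S.bR(i, k);
            double b_prop = b_cur + step * norm_rand();
            blk_prop[k] = b_prop;
            lp += -0.5 * (b_prop * b_prop - b_cur * b_cur) / v_b;
          }
          c = 0.0;
          for (int k = 0; k < m; ++k) { c += blk_prop[k]; Cb_prop[k] = c; }
          double lr = S.item_ll_R(i, std::exp(la_prop), Cb_prop.data()) -
            S.item_ll_R(i, S.aR[i], S.CbRt.colptr(i)) + lp;
          bool acc = std::log(unif_rand()) < lr;
          if (acc) {
            S.aR[i] = std::exp(la_prop);
            for (int k = 1; k < m; ++k) S.bR(i, k) = blk_prop[k];
            S.refresh_cum(i);
          }
          if (adapting) ls_R[i] += gamma * ((acc ? 1.0 : 0.0) - target_acc);
          if (iter > n_burnin) { n_prop_item += 1; if (acc) n_acc_item += 1; }
        }
        // S node: (log alpha_S, beta_S)
        {
          double step = std::exp(ls_S[i]);
          double la_cur = std::log(S.aS[i]);
          double la_prop = la_cur + step * norm_rand();
          double b_cur = S.bS[i];
          double b_prop = b_cur + step * norm_rand();
          double lp = -0.5 * (la_prop * la_prop - la_cur * la_cur +
                              2.0 * log_slope_mean * (la_cur - la_prop)) /
                      (sd_la * sd_la) -
                      0.5 * (b_prop * b_prop - b_cur * b_cur) / v_s;
          double lr = S.item_ll_S(i, std::exp(la_prop), b_prop) -
            S.item_ll_S(i, S.aS[i], b_cur) + lp;
          bool acc = std::log(unif_rand()) < lr;
          if (acc) { S.aS[i] = std::exp(la_prop); S.bS[i] = b_prop; }
          if (adapting) ls_S[i] += gamma * ((acc ? 1.0 : 0.0) - target_acc);
          if (iter > n_burnin) { n_prop_item += 1; if (acc) n_acc_item += 1; }
        }
        // T family: (log alpha_T, beta_T[2..m-1])
        {
          double step = std::exp(ls_T[i]);
          double la_cur = std::log(S.aT[i]);
          double la_prop = la_cur + step * norm_rand();
          double lp = -0.5 * (la_prop * la_prop - la_cur * la_cur +
                              2.0 * log_slope_mean * (la_cur - la_prop)) /
                      (sd_la * sd_la);
          blk_prop[0] = 0.0;
          for (int k = 1; k < m - 1; ++k) {
            double b_cur = S.bT(i, k);
            double b_prop = b_cur + step * norm_rand();
            blk_prop[k] = b_prop;
            lp += -0.5 * (b_prop * b_prop - b_cur * b_cur) / v_b;
          }
          double c = 0.0;
          for (int k = 0; k < m - 1; ++k) { c += blk_prop[k]; Cb_prop[k] = c; }
          double lr = S.item_ll_T(i, std::exp(la_prop), Cb_prop.data()) -
            S.item_ll_T(i, S.aT[i], S.CbTt.colptr(i)) + lp;
          bool acc = std::log(unif_rand()) < lr;
          if (acc) {
            S.aT[i] = std::exp(la_prop);
            for (int k = 1; k < m - 1; ++k) S.bT(i, k) = blk_prop[k];
            S.refresh_cum(i);
          }
          if (adapting) ls_T[i] += gamma * ((acc ? 1.0 : 0.0) - target_acc);
          if (iter > n_burnin) { n_prop_item += 1; if (acc) n_acc_item += 1; }
        }
      }
    }

    // --- mixing weight -----------------------------------------------------
    if (sample_pi) {
      double sz = (double)arma::accu(S.z);
      S.pi_ = R::rbeta(pi_beta[0] + sz, pi_beta[1] + N - sz);
    }

    // --- latent covariance (conjugate inverse-Wishart) ---------------------
    if (sample_sigma) {
      arma::mat Spost = scale_prior + S.theta.t() * S.theta;
      double df = sigma_df + N;
      arma::mat L = arma::chol(arma::inv_sympd(Spost), "lower");
      arma::mat A(D1, D1, arma::fill::zeros);
      for (int j = 0; j < D1; ++j) {
        A(j, j) = std::sqrt(R::rchisq(df - j));
        for (int r = j + 1; r < D1; ++r) A(r, j) = norm_rand();
      }
      arma::mat LA = L * A;
      arma::mat W = LA * LA.t();      // Wishart(df, Spost^-1) = Sigma^-1
      S.sigma = arma::inv_sympd(W);
      S.sigma = 0.5 * (S.sigma + S.sigma.t());

      // rescale to unit latent variances; likelihood invariant because
      // intercepts are held fixed and slopes absorb the scale
      arma::vec sdg = arma::sqrt(S.sigma.diag());
      for (int j = 0; j < D1; ++j) S.theta.col(j) /= sdg[j];
      S.aS *= sdg[0];
      for (int i = 0; i < K; ++i) {
        S.aR[i] *= sdg[S.dcol[i]];
        S.aT[i] *= sdg[S.dcol[i]];
      }
      S.sigma = S.sigma / (sdg * sdg.t());
      S.sigma.diag().ones();
      S.omega = arma::inv_sympd(S.sigma);
    }

    // --- record (full likelihood recompute refreshes the cache) -----------
    double total_ll = 0.0;
    for (int p = 0; p < N; ++p) {
      for (int j = 0; j < D1; ++j) th_cur[j] = S.theta(p, j);
      cur_ll[p] = S.person_ll(p, th_cur.data(), S.z[p]);
      total_ll += cur_ll[p];
    }
    if (iter > n_burnin) {
      int t = iter - n_burnin - 1;
      if (store_persons)
        for (int j = 0; j < D1; ++j)
          for (int p = 0; p < N; ++p) thetaDraws(t, p, j) = S.theta(p, j);
      theta_sum += S.theta;
      theta_sumsq += arma::square(S.theta);
      for (int p = 0; p < N; ++p) zDraws(t, p) = S.z[p];
      for (int i = 0; i < K; ++i) {
        aRd(t, i) = S.aR[i]; aSd(t, i) = S.aS[i];
        bSd(t, i) = S.bS[i]; aTd(t, i) = S.aT[i];
        for (int k = 0; k < m; ++k) bRd(t, i, k) = S.bR(i, k);
        for (int k = 0; k < m - 1; ++k) bTd(t, i, k) = S.bT(i, k);
      }
      for (int a = 0; a < D1; ++a)
        for (int b = 0; b < D1; ++b) sigmaDraws(t, a, b) = S.sigma(a, b);
      piDraws[t] = S.pi_;
      loglikDraws[t] = total_ll;
    }
  }

  List out = List::create(
    _["z"] = wrap(zDraws),
    _["alpha_R"] = wrap(aRd), _["beta_R"] = wrap(bRd),
    _["alpha_S"] = wrap(aSd), _["beta_S"] = wrap(bSd),
    _["alpha_T"] = wrap(aTd), _["beta_T"] = wrap(bTd),
    _["sigma"] = wrap(sigmaDraws), _["pi"] = wrap(piDraws),
    _["loglik"] = wrap(loglikDraws),
    _["theta_sum"] = wrap(theta_sum), _["theta_sumsq"] = wrap(theta_sumsq),
    _["acc_theta"] = n_prop_theta > 0 ? n_acc_theta / n_prop_theta : NA_REAL,
    _["acc_item"] = n_prop_item > 0 ? n_acc_item / n_prop_item : NA_REAL);
  if (store_persons) out["theta"] = wrap(thetaDraws);
  return out;
}
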