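#include <Rcpp.h>
using namespace Rcpp;

// Metropolis-within-Gibbs samplers for the two growth models.
// Location parameters use component-wise Gaussian random-walk proposals
// whose scales adapt in batches during burn-in only (factor exp(+-0.1)
// toward a 0.4 acceptance rate), then freeze.  The error precision tau is
// conjugate given the mean function and is drawn exactly from its
// conditional Gamma.  All randomness comes from R's RNG, so set.seed()
// makes a run bit-reproducible.

static const double ADAPT_TARGET = 0.4;
static const double ADAPT_STEP = 0.1;

static inline double gibbs_tau(double shape0, double rate0, int n, double rss) {
  // R::rgamma takes shape and *scale*
  return R::rgamma(shape0 + 0.5 * n, 1.0 / (rate0 + 0.5 * rss));
}

// [[Rcpp::export]]
List mcmc_linear_cpp(NumericVector y, NumericVector lx, NumericVector w,
                     double prior_prec, double tau_shape, double tau_rate,
                     int burn_in, int n_samples, int adapt_batch) {
  const int n = y.size();
  // design columns: intercept, log-age, weight
  std::vector<NumericVector> X(3);
  X[0] = NumericVector(n, 1.0);
  X[1] = lx;
  X[2] = w;
  double sumsq[3];
  for (int j = 0; j < 3; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X[j][i] * X[j][i];
    sumsq[j] = s;
  }

  double b[3] = {Rcpp::mean(y), 0.0, 0.0};
  double tau = 100.0;
  NumericVector resid(n);
  double rss = 0.0;
  for (int i = 0; i < n; ++i) {
    resid[i] = y[i] - (b[0] + b[1] * lx[i] + b[2] * w[i]);
    rss += resid[i] * resid[i];
  }

  double sd[3] = {0.1, 0.1, 0.1};
  int batch_acc[3] = {0, 0, 0};
  long post_acc[3] = {0, 0, 0};

  NumericMatrix draws(n_samples, 4);
  const int total = burn_in + n_samples;
  for (int it = 0; it < total; ++it) {
    for (int j = 0; j < 3; ++j) {
      double delta = sd[j] * R::norm_rand();
      double bj_new = b[j] + delta;
      // change in RSS if b_j moves by delta: -2*delta*sum(r*x_j) + delta^2*sum(x_j^2)
      double rx = 0.0;
      for (int i = 0; i < n; ++i) rx += resid[i] * X[j][i];
      double d_rss = -2.0 * delta * rx + delta * delta * sumsq[j];
      double log_alpha = -0.5 * tau * d_rss
        - 0.5 * prior_prec * (bj_new * bj_new - b[j] * b[j]);
      if (log(R::unif_rand()) < log_alpha) {
        b[j] = bj_new;
        for (int i = 0; i < n; ++i) resid[i] -= delta * X[j][i];
        rss += d_rss;
        if (it < burn_in) ++batch_acc[j]; else ++post_acc[j];
      }
    }
    tau = gibbs_tau(tau_shape, tau_rate, n, rss);

    if (it < burn_in && (it + 1) % adapt_batch == 0) {
      for (int j = 0; j < 3; ++j) {
        double rate = (double)batch_acc[j] / adapt_batch;
        sd[j] *= exp(rate > ADAPT_TARGET ? ADAPT_STEP : -ADAPT_STEP);
        batch_acc[j] = 0;
      }
    }
    if (it >= burn_in) {
      int k = it - burn_in;
      draws(k, 0) = b[0];
      draws(k, 1) = b[1];
      draws(k, 2) = b[2];
      draws(k, 3) = tau;
    }
  }
  NumericVector acc(3);
  for (int j = 0; j < 3; ++j) acc[j] = (double)post_acc[j] / n_samples;
  return List::create(_["draws"] = draws, _["accept_rate"] = acc,
                      _["proposal_sd"] = NumericVector::create(sd[0], sd[1], sd[2]));
}

// [[Rcpp::export]]
List mcmc_nonlinear_cpp(NumericVector y, NumericVector x,
                        double prior_prec, double tau_shape, double tau_rate,
                        int burn_in, int n_samples, int adapt_batch) {
  const int n = y.size();
  double a = Rcpp::max(y);
  double b3 = std::max(Rcpp::max(y) - Rcpp::min(y), 0.1);
  double g = 0.5;
  double tau = 100.0;

  NumericVector gx(n), resid(n);
  double rss = 0.0;
  for (int i = 0; i < n; ++i) {
    gx[i] = std::pow(g, x[i]);
    resid[i] = y[i] - (a - b3 * gx[i]);
    rss += resid[i] * resid[i];
  }

  double sd[3] = {0.1, 0.1, 0.05};  // a, b3, g
  int batch_acc[3] = {0, 0, 0};
  long post_acc[3] = {0, 0, 0};

  NumericMatrix draws(n_samples, 4);
  const int total = burn_in + n_samples;
  for (int it = 0; it < total; ++it) {
    // alpha: mean shifts by +delta, residual by -delta
    {
      double delta = sd[0] * R::norm_rand();
      double a_new = a + delta;
      double rsum = 0.0;
      for (int i = 0; i < n; ++i) rsum += resid[i];
      double d_rss = -2.0 * delta * rsum + delta * delta * n;
      double log_alpha = -0.5 * tau * d_rss
        - 0.5 * prior_prec * (a_new * a_new - a * a);
      if (log(R::unif_rand()) < log_alpha) {
        a = a_new;
        for (int i = 0; i < n; ++i) resid[i] -= delta;
        rss += d_rss;
        if (it < burn_in) ++batch_acc[0]; else ++post_acc[0];
      }
    }
    // beta3: mean shifts by -delta*g^x, residual by +delta*g^x
    {
      double delta = sd[1] * R::norm_rand();
      double b3_new = b3 + delta;
      double rgx = 0.0, gx2 = 0.0;
      for (int i = 0; i < n; ++i) { rgx += resid[i] * gx[i]; gx2 += gx[i] * gx[i]; }
      double d_rss = 2.0 * delta * rgx + delta * delta * gx2;
      double log_alpha = -0.5 * tau * d_rss
        - 0.5 * prior_prec * (b3_new * b3_new - b3 * b3);
      if (log(R::unif_rand()) < log_alpha) {
        b3 = b3_new;
        for (int i = 0; i < n; ++i) resid[i] += delta * gx[i];
        rss += d_rss;
        if (it < burn_in) ++batch_acc[1]; else ++post_acc[1];
      }
    }
    // gamma: Uniform(0,1) prior; proposals outside the support are rejected
    {
      double g_new = g + sd[2] * R::norm_rand();
      if (g_new > 0.0 && g_new < 1.0) {
        double rss_new = 0.0;
        NumericVector gx_new(n), resid_new(n);
        for (int i = 0; i < n; ++i) {
          gx_new[i] = std::pow(g_new, x[i]);
          resid_new[i] = y[i] - (a - b3 * gx_new[i]);
          rss_new += resid_new[i] * resid_new[i];
        }
        double log_alpha = -0.5 * tau * (rss_new - rss);
        if (log(R::unif_rand()) < log_alpha) {
          g = g_new;
          gx = gx_new;
          resid = resid_new;
          rss = rss_new;
          if (it < burn_in) ++batch_acc[2]; else ++post_acc[2];
        }
      }
    }
    tau = gibbs_tau(tau_shape, tau_rate, n, rss);

    if (it < burn_in && (it + 1) % adapt_batch == 0) {
      for (int j = 0; j < 3; ++j) {
        double rate = (double)batch_acc[j] / adapt_batch;
        sd[j] *= exp(rate > ADAPT_TARGET ? ADAPT_STEP : -ADAPT_STEP);
        batch_acc[j] = 0;
      }
    }
    if (it >= burn_in) {
      int k = it - burn_in;
      draws(k, 0) = a;
      draws(k, 1) = b3;
      draws(k, 2) = g;
      draws(k, 3) = tau;
    }
  }
  NumericVector acc(3);
  for (int j = 0; j < 3; ++j) acc[j] = (double)post_acc[j] / n_samples;
  return List::create(_["draws"] = draws, _["accept_rate"] = acc,
                      _["proposal_sd"] = NumericVector::create(sd[0], sd[1], sd[2]));
}
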