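#include <Rcpp.h>
using namespace Rcpp;

// Weighted Fine-Gray partial likelihood, score, information, Breslow
// baseline increments and (optionally) per-subject score residuals.
//
// Subjects must be pre-sorted by ascending follow-up time.  Risk-set rule
// (censoring-complete weighting): a subject contributes weight ipw_i while
// event-free and uncensored (T_i >= t); a cause-2 failure with T_i < t
// contributes ipw_i * G(t-) / G(T_i-); censored subjects leave at their
// censoring time.  G is the Kaplan-Meier estimate of the censoring
// survival function, supplied as left limits at the cause-1 event times
// (gtev) and at each subject's own time (gden, used for cause-2 rows).
//
// Linear predictors are centred at their maximum before exponentiation;
// all returned quantities are on the natural (uncentred) scale.
//
// [[Rcpp::export]]
List fg_core(NumericMatrix X, NumericVector time, IntegerVector status,
             NumericVector ipw, NumericVector tev, NumericVector gtev,
             NumericVector gden, NumericVector beta, bool want_resid) {
  const int n = X.nrow(), p = X.ncol(), K = tev.size();
  const double geps = 1e-12;

  std::vector<double> eta(n);
  double m = R_NegInf;
  for (int i = 0; i < n; ++i) {
    double e = 0.0;
    for (int j = 0; j < p; ++j) e += X(i, j) * beta[j];
    eta[i] = e;
    if (e > m) m = e;
  }
  if (!R_finite(m)) m = 0.0;
  std::vector<double> a(n);  // ipw_i * exp(eta_i - m)
  for (int i = 0; i < n; ++i) a[i] = ipw[i] * std::exp(eta[i] - m);

  // running sums over the natural risk set (A*) and the weighted
  // cause-2 tail set (B*)
  double A0 = 0.0, B0 = 0.0;
  std::vector<double> A1(p, 0.0), B1(p, 0.0);
  std::vector<double> A2(p * p, 0.0), B2(p * p, 0.0);
  for (int i = 0; i < n; ++i) {
    A0 += a[i];
    for (int j = 0; j < p; ++j) {
      A1[j] += a[i] * X(i, j);
      for (int l = 0; l <= j; ++l) A2[j * p + l] += a[i] * X(i, j) * X(i, l);
    }
  }

  double loglik = 0.0;
  NumericVector score(p);
  NumericMatrix info(p, p);
  NumericVector haz(K);        // Breslow increments D_k / S0(t_k)
  NumericVector s0_out(K);     // S0(t_k) on the natural scale
  NumericMatrix xbar(K, p);
  // prefix sums for residuals
  NumericVector c0(K), d0g(K);
  NumericMatrix c1(K, p), d1g(K, p);

  std::vector<double> S1(p), xb(p);
  int idx = 0;  // first subject with time >= current event time
  double cum_c0 = 0.0, cum_d0g = 0.0;
  std::vector<double> cum_c1(p, 0.0), cum_d1g(p, 0.0);

  for (int k = 0; k < K; ++k) {
    const double t = tev[k];
    while (idx < n && time[idx] < t) {
      const int i = idx;
      A0 -= a[i];
      for (int j = 0; j < p; ++j) {
        A1[j] -= a[i] * X(i, j);
        for (int l = 0; l <= j; ++l) A2[j * p + l] -= a[i] * X(i, j) * X(i, l);
      }
      if (status[i] == 2) {
        const double gd = (gden[i] > geps) ? gden[i] : geps;
        const double v = a[i] / gd;
        B0 += v;
        for (int j = 0; j < p; ++j) {
          B1[j] += v * X(i, j);
          for (int l = 0; l <= j; ++l) B2[j * p + l] += v * X(i, j) * X(i, l);
        }
      }
      ++idx;
    }
    const double g = gtev[k];
    const double S0 = A0 + g * B0;
    for (int j = 0; j < p; ++j) S1[j] = A1[j] + g * B1[j];
    for (int j = 0; j < p; ++j) xb[j] = S1[j] / S0;

    // events at this time (Breslow tie handling)
    double Dk = 0.0;
    for (int i = idx; i < n && time[i] == t; ++i) {
      if (status[i] != 1) continue;
      Dk += ipw[i];
      loglik += ipw[i] * (eta[i] - std::log(S0) - m);
      for (int j = 0; j < p; ++j) score[j] += ipw[i] * (X(i, j) - xb[j]);
    }
    const double dk = Dk / S0;
    for (int j = 0; j < p; ++j) {
      for (int l = 0; l <= j; ++l) {
        const double S2jl = A2[j * p + l] + g * B2[j * p + l];
        const double v = Dk * (S2jl / S0 - xb[j] * xb[l]);
        info(j, l) += v;
        if (l != j) info(l, j) += v;
      }
    }
    haz[k] = dk * std::exp(-m);
    s0_out[k] = S0 * std::exp(m);
    cum_c0 += dk;
    cum_d0g += g * dk;
    for (int j = 0; j < p; ++j) {
      xbar(k, j) = xb[j];
      cum_c1[j] += dk * xb[j];
      cum_d1g[j] += g * dk * xb[j];
      c1(k, j) = cum_c1[j];
      d1g(k, j) = cum_d1g[j];
    }
    c0[k] = cum_c0;
    d0g[k] = cum_d0g;
  }

  List out = List::create(
    _["loglik"] = loglik, _["score"] = score, _["info"] = info,
    _["haz"] = haz, _["s0"] = s0_out, _["xbar"] = xbar);

  if (want_resid) {
    NumericMatrix U(n, p);
    const double tot_d0g = (K > 0) ? d0g[K - 1] : 0.0;
    std::vector<double> tot_d1g(p, 0.0);
    if (K > 0) for (int j = 0; j < p; ++j) tot_d1g[j] = d1g(K - 1, j);
    // ki = index of last event time <= T_i (two-pointer over sorted times)
    int k = -1;
    for (int i = 0; i < n; ++i) {
      while (k + 1 < K && tev[k + 1] <= time[i]) ++k;
      for (int j = 0; j < p; ++j) {
        double u = 0.0;
        if (status[i] == 1) u += ipw[i] * (X(i, j) - xbar(k, j));
        if (k >= 0) u -= a[i] * (X(i, j) * c0[k] - c1(k, j));
        if (status[i] == 2) {
          const double gd = (gden[i] > geps) ? gden[i] : geps;
          const double tail0 = tot_d0g - (k >= 0 ? d0g[k] : 0.0);
          const double tail1 = tot_d1g[j] - (k >= 0 ? d1g(k, j) : 0.0);
          u -= (a[i] / gd) * (X(i, j) * tail0 - tail1);
        }
        U(i, j) = u;
      }
    }
    out["resid"] = U;
  }
  return out;
}
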