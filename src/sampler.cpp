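// Metropolis-within-Gibbs sampler for the hierarchical truncated-normal
// rating model. Conjugate Gibbs steps are used only where the conditional
// is exactly normal/gamma (beta0 and the between-study precision); every
// other scalar is slice-sampled (stepping out + shrinkage), because the
// (0,1) truncation normalizers and the theta-dependent variance function
// break conjugacy for theta, gamma, beta1, beta2, sigma2 and tau2.
//
// Slice targets drop terms that are constant within their own block
// (slice sampling is invariant to constant shifts of the log density);
// the exported .cpp_log_posterior keeps every term and is tested against
// the plain-R likelihood + prior.
#include <Rcpp.h>
#include <cmath>
#include <functional>
using namespace Rcpp;

static const double LOG_SQRT_2PI = 0.918938533204672741780329736406;

// upper-tail normal probability, good relative accuracy for x >= 0
static inline double upper_Q(double x) {
  return 0.5 * std::erfc(x * M_SQRT1_2);
}

// log Phi(x) over the whole real line (asymptotic series in the far tail)
static inline double log_Phi(double x) {
  if (x > -37.0) return std::log(0.5 * std::erfc(-x * M_SQRT1_2));
  double x2 = x * x;
  return -0.5 * x2 - std::log(-x) - LOG_SQRT_2PI +
         std::log1p(-1.0 / x2 + 3.0 / (x2 * x2));
}

// log(Phi(b) - Phi(a)) for a < b, stable in both tails.
static double log_phi_diff(double a, double b) {
  if (a + b > 0.0) { double t = a; a = -b; b = -t; }  // reflect: a + b <= 0
  double d = b - a;
  if (d < 1e-10)                       // pencil-thin interval: midpoint rule
    return -LOG_SQRT_2PI - 0.125 * (a + b) * (a + b) +
           std::log(d > 0 ? d : 1e-300);
  double dd = (b <= 0.0)
    ? upper_Q(-b) - upper_Q(-a)        // both bounds in the lower tail
    : 1.0 - upper_Q(b) - upper_Q(-a);  // straddling zero, no cancellation
  if (dd > 1e-290) return std::log(dd);
  double la = log_Phi(a), lb = log_Phi(b);   // far-tail fallback
  return lb + std::log1p(-std::exp(la - lb));
}

// log density of N(mu, sd^2) truncated to (0,1), evaluated at x in (0,1)
static inline double ldtnorm01(double x, double mu, double sd) {
  double z = (x - mu) / sd;
  return -LOG_SQRT_2PI - std::log(sd) - 0.5 * z * z -
         log_phi_diff(-mu / sd, (1.0 - mu) / sd);
}

// Univariate slice sampler (Neal 2003), stepping out + shrinkage.
static double slice1(double x0, const std::function<double(double)>& lf,
                     double w, int mmax, const char* block) {
  double f0 = lf(x0);
  if (!R_finite(f0))
    stop("sampler error: non-finite posterior at current state in block '%s'",
         std::string(block).c_str());
  double logy = f0 - R::exp_rand();
  double u = R::unif_rand();
  double L = x0 - w * u, Rt = L + w;
  int j = (int)std::floor(mmax * R::unif_rand());
  int k = mmax - 1 - j;
  while (j-- > 0 && lf(L) > logy) L -= w;
  while (k-- > 0 && lf(Rt) > logy) Rt += w;
  for (int it = 0; it < 1000; ++it) {
    double x1 = L + R::unif_rand() * (Rt - L);
    double f1 = lf(x1);
    if (f1 >= logy) return x1;
    if (x1 < x0) L = x1; else Rt = x1;
  }
  return x0;  // shrinkage exhausted: keep current state
}

struct MData {
  NumericVector y, rc, xc;          // per record: score, rater code, X - Xbar
  IntegerVector enc;                // per record: encounter index (0-based)
  IntegerVector enc_study;          // per encounter: study (0-based)
  IntegerVector enc_start, enc_len; // record block of each encounter
  IntegerVector srec_start, srec_len; // record block of each study
  IntegerVector senc_start, senc_len; // encounter block of each study
  int M, E, n, variant;             // 0 full, 1 hom binomial, 2 hom constant
};

static MData unpack(const List& md) {
  MData d;
  d.y = md["y"]; d.rc = md["rater_code"]; d.xc = md["x_centered"];
  d.enc = md["enc0"]; d.enc_study = md["enc_study0"];
  d.enc_start = md["enc_start"]; d.enc_len = md["enc_len"];
  d.srec_start = md["srec_start"]; d.srec_len = md["srec_len"];
  d.senc_start = md["senc_start"]; d.senc_len = md["senc_len"];
  d.M = md["M"]; d.E = md["E"]; d.n = d.y.size(); d.variant = md["variant"];
  return d;
}

// joint unnormalized log posterior (variance-scale parameterization),
// used by the exported cross-check; the updates never call it
static double joint_log_post(const MData& d,
                             const NumericVector& theta,
                             const NumericVector& gamma,
                             double b0, double b1, double b2,
                             const NumericVector& sig2,
                             const NumericVector& tau2, double om2,
                             double pb0, double pB2,
                             double v1, double v2, double v3) {
  int Ms = sig2.size();
  double lp = 0.0;
  for (int e = 0; e < d.E; ++e) {
    if (!(theta[e] > 0.0 && theta[e] < 1.0)) return R_NegInf;
    int s = d.enc_study[e];
    lp += ldtnorm01(theta[e], gamma[s], std::sqrt(tau2[Ms == 1 ? 0 : s]));
  }
  for (int s = 0; s < d.M; ++s)
    lp += R::dnorm(gamma[s], b0, std::sqrt(om2), 1);
  lp += R::dnorm(b0, pb0, std::sqrt(pB2), 1);
  lp += R::dnorm(b1, 0.0, std::sqrt(pB2), 1);
  lp += R::dnorm(b2, 0.0, std::sqrt(pB2), 1);
  for (int s = 0; s < Ms; ++s) {
    if (sig2[s] <= 0 || tau2[s] <= 0) return R_NegInf;
    lp += R::dgamma(1.0 / sig2[s], v1, 1.0 / v1, 1) - 2.0 * std::log(sig2[s]);
    lp += R::dgamma(1.0 / tau2[s], v2, 1.0 / v2, 1) - 2.0 * std::log(tau2[s]);
  }
  if (om2 <= 0) return R_NegInf;
  lp += R::dgamma(1.0 / om2, v3, 1.0 / v3, 1) - 2.0 * std::log(om2);
  for (int r = 0; r < d.n; ++r) {
    int e = d.enc[r], s = d.enc_study[e];
    double th = theta[e];
    double mu = th + b1 * d.rc[r] + b2 * d.xc[r];
    double var = (d.variant == 2) ? sig2[0]
                                  : sig2[Ms == 1 ? 0 : s] * th * (1.0 - th);
    lp += ldtnorm01(d.y[r], mu, std::sqrt(var));
  }
  return lp;
}

// [[Rcpp::export(".cpp_log_posterior")]]
double cpp_log_posterior(List md, List prior,
                         NumericVector theta, NumericVector gamma,
                         double beta0, double beta1, double beta2,
                         NumericVector sigma2, NumericVector tau2,
                         double omega2) {
  MData d = unpack(md);
  return joint_log_post(d, theta, gamma, beta0, beta1, beta2,
                        sigma2, tau2, omega2,
                        prior["b0"], prior["B2"],
                        prior["v1"], prior["v2"], prior["v3"]);
}

// [[Rcpp::export(".run_chain")]]
NumericMatrix run_chain(List md, List prior, List init,
                        int n_iter, int n_warmup, int thin, bool keep_theta) {
  MData d = unpack(md);
  const int Ms = (d.variant == 0) ? d.M : 1;
  const double pb0 = prior["b0"], pB2 = prior["B2"];
  const double v1 = prior["v1"], v2 = prior["v2"], v3 = prior["v3"];

  NumericVector theta = clone(as<NumericVector>(init["theta"]));
  NumericVector gamma = clone(as<NumericVector>(init["gamma"]));
  double b0 = init["beta0"], b1 = init["beta1"], b2 = init["beta2"];
  NumericVector sig2 = clone(as<NumericVector>(init["sigma2"]));
  NumericVector tau2 = clone(as<NumericVector>(init["tau2"]));
  double om2 = init["omega2"];
  if ((int)sig2.size() != Ms || (int)tau2.size() != Ms)
    stop("init variance vectors have wrong length for this variant");

  const int n_kept = (n_iter - n_warmup + thin - 1) / thin;
  const int P = 3 + d.M + 2 * Ms + 1 + (keep_theta ? d.E : 0);
  NumericMatrix out(n_kept, P);

  std::vector<double> off(d.n);    // beta1*rc + beta2*xc per record
  std::vector<double> sdrec(d.n);  // per-record sd given theta, sigma2
  RNGScope scope;

  auto refresh_off = [&]() {
    for (int r = 0; r < d.n; ++r) off[r] = b1 * d.rc[r] + b2 * d.xc[r];
  };
  auto rec_var = [&](int r) {
    int e = d.enc[r];
    return (d.variant == 2)
      ? sig2[0]
      : sig2[Ms == 1 ? 0 : d.enc_study[e]] * theta[e] * (1.0 - theta[e]);
  };

  int row = 0;
  for (int it = 0; it < n_iter; ++it) {
    if (it % 256 == 0) Rcpp::checkUserInterrupt();

    // --- theta_e | rest: slice on the logit scale -----------------------
    refresh_off();
    for (int e = 0; e < d.E; ++e) {
      int s = d.enc_study[e];
      double g = gamma[s];
      double tsd = std::sqrt(tau2[Ms == 1 ? 0 : s]);
      double s2 = sig2[Ms == 1 ? 0 : s];
      int r0 = d.enc_start[e], nr = d.enc_len[e];
      auto lf = [&](double z) {
        double th = 1.0 / (1.0 + std::exp(-z));
        if (th <= 0.0 || th >= 1.0) return R_NegInf;
        double res = std::log(th) + std::log1p(-th);   // Jacobian d theta/dz
        double zp = (th - g) / tsd;                    // prior (normalizer
        res += -0.5 * zp * zp;                         //  constant in theta)
        double var = (d.variant == 2) ? s2 : s2 * th * (1.0 - th);
        double sd = std::sqrt(var);
        res -= 0.5 * nr * std::log(var);
        for (int r = r0; r < r0 + nr; ++r) {
          double mu = th + off[r];
          double zz = (d.y[r] - mu) / sd;
          res += -0.5 * zz * zz - log_phi_diff(-mu / sd, (1.0 - mu) / sd);
        }
        return res;
      };
      double z0 = std::log(theta[e] / (1.0 - theta[e]));
      double z1 = slice1(z0, lf, 1.0, 12, "theta");
      double th1 = 1.0 / (1.0 + std::exp(-z1));
      theta[e] = std::min(std::max(th1, 1e-12), 1.0 - 1e-12);
    }

    // --- beta1, beta2 | rest: slice over the full likelihood ------------
    for (int r = 0; r < d.n; ++r) sdrec[r] = std::sqrt(rec_var(r));
    {
      auto lik_beta = [&](double bb1, double bb2) {
        double res = 0.0;
        for (int r = 0; r < d.n; ++r) {
          double mu = theta[d.enc[r]] + bb1 * d.rc[r] + bb2 * d.xc[r];
          double sd = sdrec[r];
          double zz = (d.y[r] - mu) / sd;
          res += -0.5 * zz * zz - log_phi_diff(-mu / sd, (1.0 - mu) / sd);
        }
        return res;
      };
      auto lf1 = [&](double b) {
        return -0.5 * b * b / pB2 + lik_beta(b, b2);
      };
      b1 = slice1(b1, lf1, 0.05, 12, "beta1");
      auto lf2 = [&](double b) {
        return -0.5 * b * b / pB2 + lik_beta(b1, b);
      };
      b2 = slice1(b2, lf2, 0.05, 12, "beta2");
    }
    refresh_off();

    // --- gamma_h | rest: slice; O(1) via sufficient statistics ----------
    for (int s = 0; s < d.M; ++s) {
      double t2 = tau2[Ms == 1 ? 0 : s];
      double tsd = std::sqrt(t2);
      int e0 = d.senc_start[s], ne = d.senc_len[s];
      double sum_th = 0.0, sum_th2 = 0.0;
      for (int e = e0; e < e0 + ne; ++e) {
        sum_th += theta[e]; sum_th2 += theta[e] * theta[e];
      }
      auto lf = [&](double g) {
        double res = -0.5 * (g - b0) * (g - b0) / om2;
        double ss = sum_th2 - 2.0 * g * sum_th + ne * g * g;
        res += -0.5 * ss / t2
               - ne * log_phi_diff(-g / tsd, (1.0 - g) / tsd);
        return res;
      };
      gamma[s] = slice1(gamma[s], lf, 0.2, 12, "gamma");
    }

    // --- sigma2 blocks | rest: slice on log(sigma2) ---------------------
    for (int b = 0; b < Ms; ++b) {
      int r0 = (d.variant == 0) ? d.srec_start[b] : 0;
      int nr = (d.variant == 0) ? d.srec_len[b] : d.n;
      // per-record mean and squared residual scaled by the theta factor
      std::vector<double> mu_r(nr), w_r(nr), u_r(nr);
      double sum_w = 0.0;
      for (int i = 0; i < nr; ++i) {
        int r = r0 + i, e = d.enc[r];
        double th = theta[e];
        mu_r[i] = th + off[r];
        u_r[i] = (d.variant == 2) ? 1.0 : th * (1.0 - th);
        double resid = d.y[r] - mu_r[i];
        w_r[i] = resid * resid / u_r[i];
        sum_w += w_r[i];
      }
      auto lf = [&](double ls) {
        double s2 = std::exp(ls);
        double res = -v1 * ls - v1 / s2          // precision prior, log scale
                     - 0.5 * nr * ls - 0.5 * sum_w / s2;
        for (int i = 0; i < nr; ++i) {
          double sd = std::sqrt(s2 * u_r[i]);
          res -= log_phi_diff(-mu_r[i] / sd, (1.0 - mu_r[i]) / sd);
        }
        return res;
      };
      sig2[b] = std::exp(slice1(std::log(sig2[b]), lf, 1.0, 12, "sigma2"));
    }

    // --- tau2 blocks | rest: slice on log(tau2); O(M) per eval ----------
    for (int b = 0; b < Ms; ++b) {
      int s_lo = (d.variant == 0) ? b : 0;
      int s_hi = (d.variant == 0) ? b + 1 : d.M;
      double sum_sq = 0.0;
      std::vector<int> ne_s; std::vector<double> g_s;
      for (int s = s_lo; s < s_hi; ++s) {
        int e0 = d.senc_start[s], ne = d.senc_len[s];
        for (int e = e0; e < e0 + ne; ++e) {
          double dlt = theta[e] - gamma[s];
          sum_sq += dlt * dlt;
        }
        ne_s.push_back(ne); g_s.push_back(gamma[s]);
      }
      auto lf = [&](double lt) {
        double t2 = std::exp(lt);
        double tsd = std::sqrt(t2);
        double res = -v2 * lt - v2 / t2
                     - 0.5 * sum_sq / t2;
        for (size_t k = 0; k < g_s.size(); ++k) {
          res += -0.5 * ne_s[k] * lt
                 - ne_s[k] * log_phi_diff(-g_s[k] / tsd,
                                          (1.0 - g_s[k]) / tsd);
        }
        return res;
      };
      tau2[b] = std::exp(slice1(std::log(tau2[b]), lf, 1.0, 12, "tau2"));
    }

    // --- beta0 | gamma, omega2: exact normal conditional ----------------
    {
      double prec = d.M / om2 + 1.0 / pB2;
      double sg = 0.0;
      for (int s = 0; s < d.M; ++s) sg += gamma[s];
      double mean = (sg / om2 + pb0 / pB2) / prec;
      b0 = R::rnorm(mean, std::sqrt(1.0 / prec));
    }

    // --- omega^-2 | gamma, beta0: exact gamma conditional ---------------
    {
      double ss = 0.0;
      for (int s = 0; s < d.M; ++s)
        ss += (gamma[s] - b0) * (gamma[s] - b0);
      double prec = R::rgamma(v3 + 0.5 * d.M, 1.0 / (v3 + 0.5 * ss));
      om2 = 1.0 / prec;
    }

    if (it >= n_warmup && (it - n_warmup) % thin == 0) {
      int c = 0;
      out(row, c++) = b0; out(row, c++) = b1; out(row, c++) = b2;
      for (int s = 0; s < d.M; ++s) out(row, c++) = gamma[s];
      for (int s = 0; s < Ms; ++s) out(row, c++) = sig2[s];
      for (int s = 0; s < Ms; ++s) out(row, c++) = tau2[s];
      out(row, c++) = om2;
      if (keep_theta)
        for (int e = 0; e < d.E; ++e) out(row, c++) = theta[e];
      ++row;
    }
  }
  return out;
}
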