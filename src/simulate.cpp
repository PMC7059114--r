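#include <Rcpp.h>
using namespace Rcpp;

// Hazard of a gamma renewal process with shape k and mean rate r
// (rate parameter beta = k * r so the mean ISI is 1/r). For k = 1 this is
// the constant Poisson hazard. The hazard is increasing and asymptotes to
// beta for k > 1.
static double gamma_hazard(double u, double shape, double rate_mean) {
  const double beta = shape * rate_mean;
  if (shape == 1.0) return rate_mean;
  if (u <= 0.0) return 0.0;
  const double scale = 1.0 / beta;
  if (u > 30.0 * shape / beta) return beta;  // deep tail: asymptote
  double ld = R::dgamma(u, shape, scale, 1);
  double ls = R::pgamma(u, shape, scale, 0, 1);  // upper tail, log
  double h = std::exp(ld - ls);
  if (!std::isfinite(h) || h > beta) h = beta;
  return h;
}

// index of first element >= x
static int lower_idx(const NumericVector& v, double x) {
  return (int)(std::lower_bound(v.begin(), v.end(), x) - v.begin());
}

// Exact (Ogata) thinning simulation of a point process whose conditional
// intensity is
//   lambda(t) = base_hazard(t - t_last) * prod(multiplicative kernels)
//               * exp(common(t)) + sum(additive kernels) * exp(common(t))
// with an absolute refractory period. Kernel list entries: times (sorted
// source spike times), type (0 = BOX gain, 1 = ALPHA multiplicative,
// 2 = additive Gaussian bump), gain, onset, par (BOX width / ALPHA tau /
// Gaussian SD). Uses R's RNG.
// [[Rcpp::export]]
NumericVector sim_thinning_cpp(double duration, double base_rate,
                               double refractory, double shape,
                               List kernels, double lambda_max,
                               double common_dt, NumericVector common_log) {
  const int nk = kernels.size();
  std::vector<NumericVector> ktimes(nk);
  std::vector<int> ktype(nk);
  std::vector<double> kgain(nk), konset(nk), kpar(nk), kspan(nk);
  for (int k = 0; k < nk; ++k) {
    List kk = kernels[k];
    ktimes[k] = as<NumericVector>(kk["times"]);
    ktype[k] = as<int>(kk["type"]);
    kgain[k] = as<double>(kk["gain"]);
    konset[k] = as<double>(kk["onset"]);
    kpar[k] = as<double>(kk["par"]);
    if (ktype[k] == 0) kspan[k] = konset[k] + kpar[k];
    else if (ktype[k] == 1) kspan[k] = konset[k] + 10.0 * kpar[k];
    else kspan[k] = konset[k] + 6.0 * kpar[k];
  }
  const bool has_common = common_log.size() > 0;
  std::vector<double> out;
  out.reserve((size_t)(duration * base_rate * 1.5) + 16);
  double t = 0.0, tl = 0.0;
  if (lambda_max <= 0.0) stop("lambda_max must be positive");
  while (true) {
    t += R::exp_rand() / lambda_max;
    if (t >= duration) break;
    const double u = t - tl;
    if (u < refractory) continue;
    double mult = 1.0, add = 0.0;
    for (int k = 0; k < nk; ++k) {
      const NumericVector& st = ktimes[k];
      if (st.size() == 0) continue;
      int i0 = lower_idx(st, t - kspan[k]);
      for (int i = i0; i < st.size() && st[i] < t; ++i) {
        const double lag = t - st[i];
        if (ktype[k] == 0) {                       // BOX gain
          if (lag >= konset[k] && lag < konset[k] + kpar[k]) mult *= kgain[k];
        } else if (ktype[k] == 1) {                // ALPHA multiplicative
          if (lag > konset[k]) {
            const double x = (lag - konset[k]) / kpar[k];
            const double g = x * std::exp(1.0 - x);  // peaks at 1
            mult *= 1.0 + (kgain[k] - 1.0) * g;
          }
        } else {                                   // additive Gaussian, area = gain spikes
          const double z = (lag - konset[k]) / kpar[k];
          add += kgain[k] / (kpar[k] * M_SQRT2 * std::sqrt(M_PI)) *
                 std::exp(-0.5 * z * z);
        }
      }
    }
    double com = 1.0;
    if (has_common) {
      int ci = (int) std::floor(t / common_dt);
      if (ci >= common_log.size()) ci = common_log.size() - 1;
      com = std::exp(common_log[ci]);
    }
    double lambda = (gamma_hazard(u, shape, base_rate) * mult + add) * com;
    if (lambda > lambda_max * (1.0 + 1e-9))
      stop("conditional intensity exceeded its stated bound (lambda_max)");
    if (unif_rand() * lambda_max < lambda) {
      out.push_back(t);
      tl = t;
    }
  }
  return wrap(out);
}
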