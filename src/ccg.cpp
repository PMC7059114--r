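#include <Rcpp.h>
using namespace Rcpp;

// Counts of target spikes per lag bin around each trigger spike.
// Bins are half-open [l, l + bin) lower edges spanning [-window, window).
// Triggers are assumed pre-filtered (edge triggers already dropped).
// [[Rcpp::export]]
NumericVector ccg_counts_cpp(NumericVector trigger, NumericVector target,
                             double bin_size, double window) {
  const int nbins = (int) std::lround(2.0 * window / bin_size);
  NumericVector counts(nbins);
  const int nt = trigger.size(), ns = target.size();
  int lo = 0;
  for (int i = 0; i < nt; ++i) {
    const double t = trigger[i];
    while (lo < ns && target[lo] < t - window) ++lo;
    for (int j = lo; j < ns && target[j] < t + window; ++j) {
      const double lag = target[j] - t;
      int idx = (int) std::floor((lag + window) / bin_size);
      if (idx >= 0 && idx < nbins) counts[idx] += 1.0;
    }
  }
  return counts;
}

// Reorder fixed-length segments of a spike train uniformly at random.
// Segment k covers [k*block, min((k+1)*block, duration)); the final partial
// segment participates carrying its own length. Within-segment relative
// times are preserved. Uses R's RNG (so set.seed() controls it).
// [[Rcpp::export]]
NumericVector block_shuffle_cpp(NumericVector times, double duration,
                                double block) {
  const int nblocks = (int) std::ceil(duration / block);
  // Fisher-Yates permutation of segment order via R's RNG
  IntegerVector perm(nblocks);
  for (int i = 0; i < nblocks; ++i) perm[i] = i;
  for (int i = nblocks - 1; i > 0; --i) {
    int j = (int) std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(perm[i], perm[j]);
  }
  NumericVector seglen(nblocks);
  for (int k = 0; k < nblocks; ++k) {
    double hi = std::min((k + 1.0) * block, duration);
    seglen[k] = hi - k * block;
  }
  // new start offset of each original segment after permutation
  NumericVector newstart(nblocks);
  double off = 0.0;
  for (int pos = 0; pos < nblocks; ++pos) {
    newstart[perm[pos]] = off;
    off += seglen[perm[pos]];
  }
  const int n = times.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    int k = (int) std::floor(times[i] / block);
    if (k >= nblocks) k = nblocks - 1;
    out[i] = newstart[k] + (times[i] - k * block);
  }
  std::sort(out.begin(), out.end());
  return out;
}

// Shuffle-null accumulation: n_shuffles block-shuffled trigger trains, CCG
// for each, per-bin mean of baseline-normalized shuffled CCGs and per-bin SD
// of the raw (count-per-trigger) shuffled CCGs. Baseline bins are indices
// (0-based) into the lag axis.
// [[Rcpp::export]]
List shuffle_null_cpp(NumericVector trigger, NumericVector target,
                      double duration, double block, int n_shuffles,
                      double bin_size, double window,
                      IntegerVector baseline_bins) {
  const int nbins = (int) std::lround(2.0 * window / bin_size);
  NumericVector sum_norm(nbins), sum_raw(nbins), sumsq_raw(nbins);
  int n_used = 0;
  for (int s = 0; s < n_shuffles; ++s) {
    NumericVector sh = block_shuffle_cpp(trigger, duration, block);
    // drop edge triggers
    std::vector<double> keep;
    keep.reserve(sh.size());
    for (int i = 0; i < sh.size(); ++i)
      if (sh[i] >= window && sh[i] <= duration - window) keep.push_back(sh[i]);
    if (keep.empty()) continue;
    NumericVector kv = wrap(keep);
    NumericVector counts = ccg_counts_cpp(kv, target, bin_size, window);
    const double ntrig = (double) kv.size();
    double base = 0.0;
    for (int b = 0; b < baseline_bins.size(); ++b)
      base += counts[baseline_bins[b]] / ntrig;
    base /= (double) baseline_bins.size();
    for (int b = 0; b < nbins; ++b) {
      const double raw = counts[b] / ntrig;           // mean count/bin/trigger
      sum_raw[b] += raw;
      sumsq_raw[b] += raw * raw;
      if (base > 0) sum_norm[b] += raw / base;
    }
    ++n_used;
  }
  NumericVector mean_norm(nbins), mean_raw(nbins), sd_raw(nbins);
  for (int b = 0; b < nbins; ++b) {
    if (n_used > 0) {
      mean_norm[b] = sum_norm[b] / n_used;
      mean_raw[b] = sum_raw[b] / n_used;
    }
    if (n_used > 1) {
      double v = (sumsq_raw[b] - sum_raw[b] * sum_raw[b] / n_used) / (n_used - 1);
      sd_raw[b] = v > 0 ? std::sqrt(v) : 0.0;
    }
  }
  return List::create(_["mean_norm"] = mean_norm, _["mean_raw"] = mean_raw,
                      _["sd_raw"] = sd_raw, _["n_used"] = n_used);
}
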