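// Univariate normal mixture machinery and the permutation hot path.
//
// The partition estimator (EM over K = 1..kmax, BIC selection, split/merge
// refinement gated by the bimodality index and variance/size outlier rules)
// and the closed-form log joint predictive of the conjugate normal-gamma
// product partition model live here because the permutation test re-estimates
// partitions ~n_perm times per gene.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

static const double LOG_2PI = 1.8378770664093454836;

struct NGPrior {
  double m0, s0, a0, b0, alpha;
};

struct MixFit {
  int K;
  std::vector<double> mean, var, w;
  std::vector<int> lab;  // 1-based hard labels, components ordered by mean
  double loglik;
  bool ok;
};

struct RefineCfg {
  int min_size;
  double merge_ratio, split_ratio;
  std::vector<double> bi_n, bi_cut;  // calibrated threshold table
};

// Bimodality-index threshold: linear interpolation in log(n), clamped.
static double bi_threshold(double n, const RefineCfg& cfg) {
  const std::vector<double>& xs = cfg.bi_n;
  const std::vector<double>& ys = cfg.bi_cut;
  if (xs.empty()) return 1.5;
  if (n <= xs.front()) return ys.front();
  if (n >= xs.back()) return ys.back();
  size_t i = 1;
  while (i < xs.size() && xs[i] < n) ++i;
  double lx0 = std::log(xs[i - 1]), lx1 = std::log(xs[i]);
  double t = (std::log(n) - lx0) / (lx1 - lx0);
  return ys[i - 1] + t * (ys[i] - ys[i - 1]);
}

static double vec_mean(const std::vector<double>& x) {
  double s = 0.0;
  for (double v : x) s += v;
  return s / x.size();
}

static double vec_var(const std::vector<double>& x) {  // MLE (divide by n)
  if (x.size() < 2) return 0.0;
  double m = vec_mean(x), s = 0.0;
  for (double v : x) s += (v - m) * (v - m);
  return s / x.size();
}

// One EM run from a given initialisation; unequal component variances.
static MixFit em_run(const std::vector<double>& x, int K,
                     std::vector<double> mean, std::vector<double> var,
                     std::vector<double> w, double vfloor,
                     int maxit, double tol) {
  int n = (int)x.size();
  MixFit fit;
  fit.K = K;
  fit.ok = false;
  std::vector<double> resp((size_t)n * K);
  std::vector<double> logw(K), lv(K);
  double ll_old = -std::numeric_limits<double>::infinity();
  for (int it = 0; it < maxit; ++it) {
    for (int k = 0; k < K; ++k) {
      if (var[k] < vfloor) var[k] = vfloor;
      logw[k] = std::log(std::max(w[k], 1e-300));
      lv[k] = std::log(var[k]);
    }
    double ll = 0.0;
    for (int i = 0; i < n; ++i) {
      double mx = -std::numeric_limits<double>::infinity();
      for (int k = 0; k < K; ++k) {
        double d = x[i] - mean[k];
        double lp = logw[k] - 0.5 * (LOG_2PI + lv[k] + d * d / var[k]);
        resp[(size_t)i * K + k] = lp;
        if (lp > mx) mx = lp;
      }
      double se = 0.0;
      for (int k = 0; k < K; ++k) se += std::exp(resp[(size_t)i * K + k] - mx);
      double lse = mx + std::log(se);
      ll += lse;
      for (int k = 0; k < K; ++k)
        resp[(size_t)i * K + k] = std::exp(resp[(size_t)i * K + k] - lse);
    }
    // M step
    bool empty = false;
    for (int k = 0; k < K; ++k) {
      double nk = 0.0, s1 = 0.0;
      for (int i = 0; i < n; ++i) {
        double r = resp[(size_t)i * K + k];
        nk += r;
        s1 += r * x[i];
      }
      if (nk < 1e-8) { empty = true; break; }
      double mk = s1 / nk, s2 = 0.0;
      for (int i = 0; i < n; ++i) {
        double d = x[i] - mk;
        s2 += resp[(size_t)i * K + k] * d * d;
      }
      mean[k] = mk;
      var[k] = std::max(s2 / nk, vfloor);
      w[k] = nk / n;
    }
    if (empty) return fit;
    if (std::abs(ll - ll_old) < tol * (std::abs(ll) + 1.0)) { ll_old = ll; break; }
    ll_old = ll;
  }
  // final log-likelihood and hard labels at converged parameters
  for (int k = 0; k < K; ++k) {
    logw[k] = std::log(std::max(w[k], 1e-300));
    lv[k] = std::log(var[k]);
  }
  double ll = 0.0;
  std::vector<int> lab(n);
  for (int i = 0; i < n; ++i) {
    double mx = -std::numeric_limits<double>::infinity(), best = 0;
    double se = 0.0;
    std::vector<double> lp(K);
    for (int k = 0; k < K; ++k) {
      double d = x[i] - mean[k];
      lp[k] = logw[k] - 0.5 * (LOG_2PI + lv[k] + d * d / var[k]);
      if (lp[k] > mx) { mx = lp[k]; best = k; }
    }
    for (int k = 0; k < K; ++k) se += std::exp(lp[k] - mx);
    ll += mx + std::log(se);
    lab[i] = (int)best;
  }
  // order components by mean, relabel 1..K; drop components with no hard members
  std::vector<int> ord(K);
  for (int k = 0; k < K; ++k) ord[k] = k;
  std::sort(ord.begin(), ord.end(),
            [&](int a, int b) { return mean[a] < mean[b]; });
  std::vector<int> rank(K);
  for (int k = 0; k < K; ++k) rank[ord[k]] = k;
  std::vector<int> cnt(K, 0);
  for (int i = 0; i < n; ++i) cnt[lab[i]]++;
  for (int k = 0; k < K; ++k)
    if (cnt[k] == 0) return fit;  // vacuous hard component: reject this fit
  fit.mean.resize(K);
  fit.var.resize(K);
  fit.w.resize(K);
  fit.lab.resize(n);
  for (int k = 0; k < K; ++k) {
    fit.mean[rank[k]] = mean[k];
    fit.var[rank[k]] = var[k];
    fit.w[rank[k]] = w[k];
  }
  for (int i = 0; i < n; ++i) fit.lab[i] = rank[lab[i]] + 1;
  fit.loglik = ll;
  fit.ok = true;
  return fit;
}

// Best EM fit at fixed K from deterministic initialisations:
// (a) equal-size contiguous blocks of the sorted data;
// (b) blocks cut at the K-1 largest gaps of the sorted data.
static MixFit em_best(const std::vector<double>& x, int K,
                      double vfloor, int maxit = 80, double tol = 1e-5) {
  int n = (int)x.size();
  MixFit best;
  best.ok = false;
  if (K == 1) {
    MixFit f;
    f.K = 1;
    f.mean = {vec_mean(x)};
    f.var = {std::max(vec_var(x), vfloor)};
    f.w = {1.0};
    f.lab.assign(n, 1);
    double ll = 0.0;
    for (double v : x) {
      double d = v - f.mean[0];
      ll += -0.5 * (LOG_2PI + std::log(f.var[0]) + d * d / f.var[0]);
    }
    f.loglik = ll;
    f.ok = true;
    return f;
  }
  std::vector<double> xs(x);
  std::sort(xs.begin(), xs.end());
  std::vector<std::vector<int>> cutsets;
  // (a) equal blocks
  {
    std::vector<int> cuts;
    for (int k = 1; k < K; ++k) cuts.push_back((int)std::floor((double)k * n / K));
    cutsets.push_back(cuts);
  }
  // (b) largest gaps
  {
    std::vector<std::pair<double, int>> gaps;
    for (int i = 0; i + 1 < n; ++i)
      gaps.push_back({xs[i + 1] - xs[i], i + 1});
    std::sort(gaps.begin(), gaps.end(),
              [](const std::pair<double, int>& a, const std::pair<double, int>& b) {
                return a.first > b.first;
              });
    std::vector<int> cuts;
    for (int g = 0; g < (int)gaps.size() && (int)cuts.size() < K - 1; ++g)
      cuts.push_back(gaps[g].second);
    if ((int)cuts.size() == K - 1) {
      std::sort(cuts.begin(), cuts.end());
      bool ok = true;
      int prev = 0;
      for (int c : cuts) {
        if (c <= prev) { ok = false; break; }
        prev = c;
      }
      if (ok && prev < n) cutsets.push_back(cuts);
    }
  }
  for (const std::vector<int>& cuts : cutsets) {
    std::vector<double> mean(K), var(K), w(K);
    int lo = 0;
    bool feasible = true;
    for (int k = 0; k < K; ++k) {
      int hi = (k == K - 1) ? n : cuts[k];
      if (hi <= lo) { feasible = false; break; }
      std::vector<double> blk(xs.begin() + lo, xs.begin() + hi);
      mean[k] = vec_mean(blk);
      var[k] = std::max(vec_var(blk), vfloor);
      w[k] = (double)blk.size() / n;
      lo = hi;
    }
    if (!feasible) continue;
    MixFit f = em_run(x, K, mean, var, w, vfloor, maxit, tol);
    if (f.ok && (!best.ok || f.loglik > best.loglik)) best = f;
  }
  return best;
}

static int n_distinct(const std::vector<double>& x) {
  std::vector<double> xs(x);
  std::sort(xs.begin(), xs.end());
  int d = 1;
  for (size_t i = 1; i < xs.size(); ++i)
    if (xs[i] != xs[i - 1]) ++d;
  return d;
}

static double var_floor(const std::vector<double>& x) {
  double v = vec_var(x);
  return std::max(1e-10, v * 1e-4);
}

// Memoizes the per-K EM fits of one value vector so the BIC selection and
// the split/merge refinement share them.
struct Estimator {
  const std::vector<double>& x;
  double vfloor;
  std::vector<MixFit> cache;
  std::vector<bool> done;
  explicit Estimator(const std::vector<double>& xv)
      : x(xv), vfloor(var_floor(xv)), cache(16), done(16, false) {}
  const MixFit& fit(int K) {
    if (K >= (int)cache.size()) {
      cache.resize(K + 1);
      done.resize(K + 1, false);
    }
    if (!done[K]) {
      cache[K] = em_best(x, K, vfloor);
      done[K] = true;
    }
    return cache[K];
  }
};

// BIC-optimal mixture, K = 1..kcap; lower BIC wins, ties to smaller K.
// The K search stops early once BIC has worsened on two consecutive K.
static MixFit bic_mixture(Estimator& est, int kmax, int min_size) {
  const std::vector<double>& x = est.x;
  int n = (int)x.size();
  int kcap = std::min(kmax, n_distinct(x));
  kcap = std::min(kcap, std::max(1, n / std::max(1, min_size)));
  MixFit best;
  best.ok = false;
  double best_bic = std::numeric_limits<double>::infinity();
  int worse = 0;
  double prev_bic = std::numeric_limits<double>::infinity();
  for (int K = 1; K <= kcap; ++K) {
    const MixFit& f = est.fit(K);
    if (!f.ok) continue;
    double npar = 3.0 * K - 1.0;
    double bic = -2.0 * f.loglik + npar * std::log((double)n);
    if (bic < best_bic - 1e-12) {
      best_bic = bic;
      best = f;
    }
    worse = (bic > prev_bic) ? worse + 1 : 0;
    prev_bic = bic;
    if (worse >= 2) break;
  }
  if (!best.ok) {  // degenerate data (e.g. all values identical)
    best.K = 1;
    best.mean = {vec_mean(x)};
    best.var = {est.vfloor};
    best.w = {1.0};
    best.lab.assign(n, 1);
    best.loglik = 0.0;
    best.ok = true;
  }
  return best;
}

struct CompStats {
  std::vector<int> size;
  std::vector<double> mean, sd, var;  // sample SD (n-1), MLE var
};

static CompStats comp_stats(const std::vector<double>& x,
                            const std::vector<int>& lab, int K) {
  CompStats cs;
  cs.size.assign(K, 0);
  cs.mean.assign(K, 0.0);
  cs.sd.assign(K, 0.0);
  cs.var.assign(K, 0.0);
  for (size_t i = 0; i < x.size(); ++i) {
    cs.size[lab[i] - 1]++;
    cs.mean[lab[i] - 1] += x[i];
  }
  for (int k = 0; k < K; ++k) cs.mean[k] /= std::max(1, cs.size[k]);
  std::vector<double> ss(K, 0.0);
  for (size_t i = 0; i < x.size(); ++i) {
    double d = x[i] - cs.mean[lab[i] - 1];
    ss[lab[i] - 1] += d * d;
  }
  for (int k = 0; k < K; ++k) {
    cs.var[k] = cs.size[k] > 0 ? ss[k] / cs.size[k] : 0.0;
    cs.sd[k] = cs.size[k] > 1 ? std::sqrt(ss[k] / (cs.size[k] - 1)) : 0.0;
  }
  return cs;
}

static double bi_value(int n1, int n2, double mu1, double mu2, double sigma) {
  double nn = (double)n1 + n2;
  return 2.0 * std::sqrt((double)n1 * n2 / (nn * nn)) *
         std::fabs(mu1 - mu2) / sigma;
}

// All adjacent (mean-ordered) component pairs exceed the BI cutoff;
// sigma is conservatively the maximum within-component SD.
static bool bi_pass(const CompStats& cs, double cut) {
  int K = (int)cs.size.size();
  double sigma = 0.0;
  for (int k = 0; k < K; ++k) sigma = std::max(sigma, cs.sd[k]);
  if (sigma <= 0.0) return true;  // zero spread within components: separation is real
  for (int k = 0; k + 1 < K; ++k)
    if (bi_value(cs.size[k], cs.size[k + 1], cs.mean[k], cs.mean[k + 1], sigma) < cut)
      return false;
  return true;
}

static bool var_ratio_exceeds(const CompStats& cs, double ratio) {
  int K = (int)cs.size.size();
  double vmax = 0.0, vmin = std::numeric_limits<double>::infinity();
  for (int k = 0; k < K; ++k) {
    vmax = std::max(vmax, cs.var[k]);
    vmin = std::min(vmin, cs.var[k]);
  }
  return vmax > ratio * std::max(vmin, 1e-300);
}

// Split/merge refinement, iterated to a fixed point.
static std::vector<int> refine(Estimator& est, std::vector<int> lab,
                               const RefineCfg& cfg) {
  const std::vector<double>& x = est.x;
  int n = (int)x.size();
  double cut = bi_threshold((double)n, cfg);
  for (int iter = 0; iter < 12; ++iter) {
    int K = 0;
    for (int l : lab) K = std::max(K, l);
    CompStats cs = comp_stats(x, lab, K);
    if (K == 1) {
      if (n >= 2 * cfg.min_size && n_distinct(x) >= 2) {
        const MixFit& f2 = est.fit(2);
        if (f2.ok) {
          CompStats c2 = comp_stats(x, f2.lab, 2);
          bool sizes_ok = c2.size[0] >= cfg.min_size && c2.size[1] >= cfg.min_size;
          bool vars_ok = !var_ratio_exceeds(c2, cfg.split_ratio);
          if (sizes_ok && vars_ok && bi_pass(c2, cut)) {
            lab = f2.lab;
            continue;
          }
        }
      }
      return lab;
    }
    bool too_small = false;
    for (int k = 0; k < K; ++k)
      if (cs.size[k] < cfg.min_size) too_small = true;
    bool forced = too_small || var_ratio_exceeds(cs, cfg.merge_ratio);
    if (!forced && bi_pass(cs, cut)) return lab;
    const MixFit& fm = est.fit(K - 1);
    if (!fm.ok) {  // fall back to a single component
      std::fill(lab.begin(), lab.end(), 1);
      continue;
    }
    lab = fm.lab;
  }
  return lab;
}

static std::vector<int> estimate_labels(const std::vector<double>& x,
                                        int kmax, const RefineCfg& cfg) {
  Estimator est(x);
  MixFit f = bic_mixture(est, kmax, cfg.min_size);
  return refine(est, f.lab, cfg);
}

// log joint predictive: log[ alpha^K prod_k Gamma(n_k) Gamma(a_k/2)
//   (b_k/2)^{-a_k/2} s_k^{-1/2} ] plus the exact normal-gamma marginal
// constant per component. Empty data contributes 0.
static double ljp(const std::vector<double>& x, const std::vector<int>& lab,
                  const NGPrior& pr) {
  if (x.empty()) return 0.0;
  int K = 0;
  for (int l : lab) K = std::max(K, l);
  std::vector<double> n(K, 0.0), s1(K, 0.0), s2(K, 0.0);
  for (size_t i = 0; i < x.size(); ++i) {
    int k = lab[i] - 1;
    n[k] += 1.0;
    s1[k] += x[i];
    s2[k] += x[i] * x[i];
  }
  double tot = K * std::log(pr.alpha);
  for (int k = 0; k < K; ++k) {
    double sk = pr.s0 + n[k];
    double mk = (pr.s0 * pr.m0 + s1[k]) / sk;
    double ak = pr.a0 + n[k];
    double bk = pr.b0 + s2[k] + pr.s0 * pr.m0 * pr.m0 - sk * mk * mk;
    if (bk <= 0) bk = 1e-300;
    tot += std::lgamma(n[k]) + std::lgamma(ak / 2.0) -
           (ak / 2.0) * std::log(bk / 2.0) - 0.5 * std::log(sk) -
           (n[k] / 2.0) * LOG_2PI + (pr.a0 / 2.0) * std::log(pr.b0 / 2.0) +
           0.5 * std::log(pr.s0) - std::lgamma(pr.a0 / 2.0);
  }
  return tot;
}

static double ljp_of(const std::vector<double>& x, int kmax,
                     const RefineCfg& cfg, const NGPrior& pr) {
  if (x.empty()) return 0.0;
  std::vector<int> lab = estimate_labels(x, kmax, cfg);
  return ljp(x, lab, pr);
}

static RefineCfg make_cfg(int min_size, double merge_ratio, double split_ratio,
                          NumericVector bi_n, NumericVector bi_cut) {
  RefineCfg cfg;
  cfg.min_size = min_size;
  cfg.merge_ratio = merge_ratio;
  cfg.split_ratio = split_ratio;
  cfg.bi_n = as<std::vector<double>>(bi_n);
  cfg.bi_cut = as<std::vector<double>>(bi_cut);
  return cfg;
}

static NGPrior make_prior(double m0, double s0, double a0, double b0,
                          double alpha) {
  NGPrior p;
  p.m0 = m0;
  p.s0 = s0;
  p.a0 = a0;
  p.b0 = b0;
  p.alpha = alpha;
  return p;
}

// [[Rcpp::export(name = ".em_fit_cpp")]]
List em_fit_cpp(NumericVector x, int K) {
  std::vector<double> xv = as<std::vector<double>>(x);
  MixFit f = em_best(xv, K, var_floor(xv));
  if (!f.ok) return List::create(_["ok"] = false);
  return List::create(_["ok"] = true, _["labels"] = wrap(f.lab),
                      _["mean"] = wrap(f.mean), _["var"] = wrap(f.var),
                      _["weight"] = wrap(f.w), _["loglik"] = f.loglik);
}

// [[Rcpp::export(name = ".bic_mixture_cpp")]]
List bic_mixture_cpp(NumericVector x, int kmax, int min_size) {
  std::vector<double> xv = as<std::vector<double>>(x);
  Estimator est(xv);
  MixFit f = bic_mixture(est, kmax, min_size);
  return List::create(_["labels"] = wrap(f.lab), _["K"] = f.K,
                      _["mean"] = wrap(f.mean), _["var"] = wrap(f.var),
                      _["weight"] = wrap(f.w), _["loglik"] = f.loglik);
}

// [[Rcpp::export(name = ".refine_cpp")]]
IntegerVector refine_cpp(NumericVector x, IntegerVector labels, int min_size,
                         double merge_ratio, double split_ratio,
                         NumericVector bi_n, NumericVector bi_cut) {
  RefineCfg cfg = make_cfg(min_size, merge_ratio, split_ratio, bi_n, bi_cut);
  std::vector<double> xv = as<std::vector<double>>(x);
  std::vector<int> lab = as<std::vector<int>>(labels);
  Estimator est(xv);
  return wrap(refine(est, lab, cfg));
}

// [[Rcpp::export(name = ".ljp_cpp")]]
double ljp_cpp(NumericVector x, IntegerVector labels, double m0, double s0,
               double a0, double b0, double alpha) {
  return ljp(as<std::vector<double>>(x), as<std::vector<int>>(labels),
             make_prior(m0, s0, a0, b0, alpha));
}

// Observed Bayes factor score with partition estimates for each condition
// and pooled. cond is 1/2 over the nonzero cells.
// [[Rcpp::export(name = ".score_gene_cpp")]]
List score_gene_cpp(NumericVector y, IntegerVector cond, int kmax,
                    int min_size, double merge_ratio, double split_ratio,
                    NumericVector bi_n, NumericVector bi_cut, double m0,
                    double s0, double a0, double b0, double alpha) {
  RefineCfg cfg = make_cfg(min_size, merge_ratio, split_ratio, bi_n, bi_cut);
  NGPrior pr = make_prior(m0, s0, a0, b0, alpha);
  std::vector<double> y1, y2, yp;
  for (int i = 0; i < y.size(); ++i) {
    yp.push_back(y[i]);
    if (cond[i] == 1) y1.push_back(y[i]);
    else y2.push_back(y[i]);
  }
  std::vector<int> l1 = y1.empty() ? std::vector<int>()
                                   : estimate_labels(y1, kmax, cfg);
  std::vector<int> l2 = y2.empty() ? std::vector<int>()
                                   : estimate_labels(y2, kmax, cfg);
  std::vector<int> lp = estimate_labels(yp, kmax, cfg);
  double s = ljp(y1, l1, pr) + ljp(y2, l2, pr) - ljp(yp, lp, pr);
  return List::create(_["score"] = s, _["labels1"] = wrap(l1),
                      _["labels2"] = wrap(l2), _["labels_pooled"] = wrap(lp));
}

// Fisher-Yates using R's RNG so results follow set.seed().
static void shuffle_r(std::vector<int>& idx) {
  for (int i = (int)idx.size() - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(idx[i], idx[j]);
  }
}

// Plain permutation null: condition labels are shuffled over all J cells
// (the zero pattern stays attached to each cell); within-condition
// partitions are re-estimated, the pooled term is label-free and passed in.
// [[Rcpp::export(name = ".perm_scores_cpp")]]
NumericVector perm_scores_cpp(NumericVector y_all, LogicalVector nonzero,
                              IntegerVector cond, int n_perm,
                              double pooled_ljp, int kmax, int min_size,
                              double merge_ratio, double split_ratio,
                              NumericVector bi_n, NumericVector bi_cut,
                              double m0, double s0, double a0, double b0,
                              double alpha) {
  RefineCfg cfg = make_cfg(min_size, merge_ratio, split_ratio, bi_n, bi_cut);
  NGPrior pr = make_prior(m0, s0, a0, b0, alpha);
  int J = y_all.size();
  std::vector<int> labels(J);
  for (int i = 0; i < J; ++i) labels[i] = cond[i];
  NumericVector out(n_perm);
  RNGScope scope;
  for (int p = 0; p < n_perm; ++p) {
    shuffle_r(labels);
    std::vector<double> y1, y2;
    for (int i = 0; i < J; ++i) {
      if (!nonzero[i]) continue;
      if (labels[i] == 1) y1.push_back(y_all[i]);
      else y2.push_back(y_all[i]);
    }
    out[p] = ljp_of(y1, kmax, cfg, pr) + ljp_of(y2, kmax, cfg, pr) - pooled_ljp;
  }
  return out;
}

// Residual-permutation null for covariate adjustment: conditions stay fixed,
// permuted values are fitted + shuffled residuals, so all three partitions
// (including pooled) are re-estimated each time.
// [[Rcpp::export(name = ".perm_scores_resid_cpp")]]
NumericVector perm_scores_resid_cpp(NumericVector fitted, NumericVector resid,
                                    IntegerVector cond, int n_perm, int kmax,
                                    int min_size, double merge_ratio,
                                    double split_ratio, NumericVector bi_n,
                                    NumericVector bi_cut, double m0, double s0,
                                    double a0, double b0, double alpha) {
  RefineCfg cfg = make_cfg(min_size, merge_ratio, split_ratio, bi_n, bi_cut);
  NGPrior pr = make_prior(m0, s0, a0, b0, alpha);
  int m = fitted.size();
  std::vector<int> idx(m);
  for (int i = 0; i < m; ++i) idx[i] = i;
  NumericVector out(n_perm);
  RNGScope scope;
  for (int p = 0; p < n_perm; ++p) {
    shuffle_r(idx);
    std::vector<double> y1, y2, yp(m);
    for (int i = 0; i < m; ++i) {
      double v = fitted[i] + resid[idx[i]];
      yp[i] = v;
      if (cond[i] == 1) y1.push_back(v);
      else y2.push_back(v);
    }
    out[p] = ljp_of(y1, kmax, cfg, pr) + ljp_of(y2, kmax, cfg, pr) -
             ljp_of(yp, kmax, cfg, pr);
  }
  return out;
}
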