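// SGD trainers for the two embedding models: a contrastive (margin-ranking,
// cosine) model over patient bags of variants, and a CBOW model with negative
// sampling over patient bags of mutated genes. Randomness comes from a local
// mt19937_64 with hand-rolled uniform draws so runs are reproducible for a
// given seed and independent of R's global RNG.

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double u01(std::mt19937_64 &rng) {
  return (rng() >> 11) * (1.0 / 9007199254740992.0); // 53-bit uniform in [0,1)
}

static inline int uint_below(std::mt19937_64 &rng, int n) {
  int k = (int)(u01(rng) * n);
  return k >= n ? n - 1 : k;
}

static inline double sigmoid(double x) {
  if (x > 16.0) return 1.0 - 1e-7;
  if (x < -16.0) return 1e-7;
  return 1.0 / (1.0 + std::exp(-x));
}

// mean of the rows of E indexed by bag (0-based) -> out
static void bag_mean(const NumericMatrix &E, const IntegerVector &bag,
                     std::vector<double> &out) {
  const int d = E.ncol();
  std::fill(out.begin(), out.end(), 0.0);
  if (bag.size() == 0) return;
  for (int t = 0; t < bag.size(); ++t) {
    const int row = bag[t];
    for (int j = 0; j < d; ++j) out[j] += E(row, j);
  }
  const double inv = 1.0 / bag.size();
  for (int j = 0; j < d; ++j) out[j] *= inv;
}

static inline double norm2(const std::vector<double> &v) {
  double s = 0.0;
  for (double x : v) s += x * x;
  return std::sqrt(s);
}

static inline double dot(const std::vector<double> &a, const std::vector<double> &b) {
  double s = 0.0;
  for (size_t j = 0; j < a.size(); ++j) s += a[j] * b[j];
  return s;
}

// clip a gradient vector to unit L2 norm; cosine gradients blow up as
// 1/(|a||b|) when bag means are near the origin (as at initialization)
static inline void clip_grad(std::vector<double> &g) {
  double s = 0.0;
  for (double x : g) s += x * x;
  s = std::sqrt(s);
  if (s > 1.0) for (double &x : g) x /= s;
}

// project one embedding row back onto the max-norm ball
static inline void cap_row(NumericMatrix &E, int row, double max_norm) {
  double s = 0.0;
  const int d = E.ncol();
  for (int j = 0; j < d; ++j) s += E(row, j) * E(row, j);
  s = std::sqrt(s);
  if (s > max_norm) {
    const double f = max_norm / s;
    for (int j = 0; j < d; ++j) E(row, j) *= f;
  }
}

// [[Rcpp::export]]
List cpp_train_contrastive(List bags, IntegerVector patient, int n_tokens,
                           int dim, int epochs, double lr, double margin,
                           int k_neg, double max_norm, double decay,
                           double init_scale, int seed) {
  const int n_var = bags.size();
  std::mt19937_64 rng((uint64_t)seed);

  NumericMatrix E(n_tokens, dim);
  const double a0 = init_scale;
  for (int i = 0; i < n_tokens; ++i)
    for (int j = 0; j < dim; ++j)
      E(i, j) = (2.0 * u01(rng) - 1.0) * a0;

  // group variants by patient
  int n_pat = 0;
  for (int v = 0; v < n_var; ++v) n_pat = std::max(n_pat, patient[v] + 1);
  std::vector<std::vector<int>> by_pat(n_pat);
  for (int v = 0; v < n_var; ++v) by_pat[patient[v]].push_back(v);

  // enumerate all ordered within-patient pairs once; shuffled per epoch so
  // no patient's updates dominate the final state
  std::vector<std::pair<int, int>> pairs;
  for (int p = 0; p < n_pat; ++p) {
    const std::vector<int> &vs = by_pat[p];
    if (vs.size() < 2) continue;
    for (size_t ia = 0; ia < vs.size(); ++ia)
      for (size_t ip = 0; ip < vs.size(); ++ip)
        if (ia != ip) pairs.push_back({vs[ia], vs[ip]});
  }

  std::vector<double> ea(dim), ep(dim), en(dim), grad_a(dim), tmp(dim);
  NumericVector loss_traj(epochs);
  const double eps = 1e-12;

  for (int epoch = 0; epoch < epochs; ++epoch) {
    const double lr_e = lr * (double)(epochs - epoch) / epochs;
    double loss_sum = 0.0;
    long loss_n = 0;
    for (int i = (int)pairs.size() - 1; i > 0; --i)
      std::swap(pairs[i], pairs[uint_below(rng, i + 1)]);
    for (size_t pi = 0; pi < pairs.size(); ++pi) {
      {
        {
          const int va = pairs[pi].first, vp = pairs[pi].second;
          const int p = patient[va];
          IntegerVector bag_a = bags[va], bag_p = bags[vp];
          if (bag_a.size() == 0 || bag_p.size() == 0) continue;
          bag_mean(E, bag_a, ea);
          bag_mean(E, bag_p, ep);
          const double na = norm2(ea), np = norm2(ep);
          if (na < eps || np < eps) continue;
          const double sap = dot(ea, ep) / (na * np);
          std::fill(grad_a.begin(), grad_a.end(), 0.0);
          bool any_violation = false;
          for (int k = 0; k < k_neg; ++k) {
            int vn = uint_below(rng, n_var);
            int tries = 0;
            while (patient[vn] == p && tries++ < 64) vn = uint_below(rng, n_var);
            if (patient[vn] == p) continue;
            IntegerVector bag_n = bags[vn];
            if (bag_n.size() == 0) continue;
            bag_mean(E, bag_n, en);
            const double nn = norm2(en);
            if (nn < eps) continue;
            const double san = dot(ea, en) / (na * nn);
            const double L = margin - sap + san;
            loss_sum += (L > 0.0 ? L : 0.0);
            ++loss_n;
            if (L <= 0.0) continue;
            any_violation = true;
            // dL/d ea = -(ep/(na*np) - sap*ea/na^2) + (en/(na*nn) - san*ea/na^2)
            for (int j = 0; j < dim; ++j) {
              grad_a[j] += -(ep[j] / (na * np) - sap * ea[j] / (na * na)) +
                            (en[j] / (na * nn) - san * ea[j] / (na * na));
            }
            // dL/d ep = -(ea/(na*np) - sap*ep/np^2); token update: -lr/|bag| * grad
            const double invp = lr_e / bag_p.size();
            for (int j = 0; j < dim; ++j)
              tmp[j] = -(ea[j] / (na * np) - sap * ep[j] / (np * np));
            clip_grad(tmp);
            for (int t = 0; t < bag_p.size(); ++t) {
              for (int j = 0; j < dim; ++j)
                E(bag_p[t], j) -= invp * tmp[j];
              cap_row(E, bag_p[t], max_norm);
            }
            // dL/d en = ea/(na*nn) - san*en/nn^2
            const double invn = lr_e / bag_n.size();
            for (int j = 0; j < dim; ++j)
              tmp[j] = ea[j] / (na * nn) - san * en[j] / (nn * nn);
            clip_grad(tmp);
            for (int t = 0; t < bag_n.size(); ++t) {
              for (int j = 0; j < dim; ++j)
                E(bag_n[t], j) -= invn * tmp[j];
              cap_row(E, bag_n[t], max_norm);
            }
          }
          if (any_violation) {
            clip_grad(grad_a);
            const double inva = lr_e / bag_a.size();
            for (int t = 0; t < bag_a.size(); ++t) {
              for (int j = 0; j < dim; ++j)
                E(bag_a[t], j) -= inva * grad_a[j];
              cap_row(E, bag_a[t], max_norm);
            }
          }
        }
      }
    }
    // weight decay: tokens with coherent gradients regain norm, tokens with
    // conflicting (noise) gradients shrink — cosine itself exerts no norm
    // pressure, so this is the only force damping uninformative tokens
    if (decay > 0.0) {
      const double f = 1.0 - decay;
      for (int i = 0; i < n_tokens; ++i)
        for (int j = 0; j < dim; ++j) E(i, j) *= f;
    }
    loss_traj[epoch] = loss_n > 0 ? loss_sum / loss_n : 0.0;
    if (!std::isfinite(loss_traj[epoch]))
      stop("non-finite training loss at epoch %d", epoch + 1);
  }
  return List::create(_["vectors"] = E, _["loss"] = loss_traj);
}

// [[Rcpp::export]]
NumericMatrix cpp_embed_bags(List bags, NumericMatrix E) {
  const int n = bags.size(), d = E.ncol();
  NumericMatrix out(n, d);
  std::vector<double> buf(d);
  for (int i = 0; i < n; ++i) {
    IntegerVector bag = bags[i];
    bag_mean(E, bag, buf);
    for (int j = 0; j < d; ++j) out(i, j) = buf[j];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_train_cbow(List bags, int n_genes, int dim, int epochs, double lr,
                    int k_neg, NumericVector neg_prob, int seed) {
  std::mt19937_64 rng((uint64_t)seed);
  NumericMatrix Win(n_genes, dim), Wout(n_genes, dim);
  const double a0 = 1.0 / dim;
  for (int i = 0; i < n_genes; ++i)
    for (int j = 0; j < dim; ++j)
      Win(i, j) = (2.0 * u01(rng) - 1.0) * a0;
  // Wout stays at zero (word2vec convention)

  std::vector<double> cum(n_genes);
  double acc = 0.0;
  for (int i = 0; i < n_genes; ++i) { acc += neg_prob[i]; cum[i] = acc; }
  for (int i = 0; i < n_genes; ++i) cum[i] /= acc;
  auto sample_neg = [&]() {
    const double u = u01(rng);
    int lo = 0, hi = n_genes - 1;
    while (lo < hi) {
      const int mid = (lo + hi) / 2;
      if (cum[mid] < u) lo = mid + 1; else hi = mid;
    }
    return lo;
  };

  std::vector<double> ctx(dim), gctx(dim);
  NumericVector obj_traj(epochs);

  for (int epoch = 0; epoch < epochs; ++epoch) {
    const double lr_e = lr * (double)(epochs - epoch) / epochs;
    double obj_sum = 0.0;
    long obj_n = 0;
    for (int b = 0; b < bags.size(); ++b) {
      IntegerVector bag = bags[b];
      const int m = bag.size();
      if (m < 2) continue;
      // shuffled target order (Fisher-Yates)
      std::vector<int> order(m);
      for (int i = 0; i < m; ++i) order[i] = i;
      for (int i = m - 1; i > 0; --i)
        std::swap(order[i], order[uint_below(rng, i + 1)]);
      for (int oi = 0; oi < m; ++oi) {
        const int target = bag[order[oi]];
        // context = mean of input vectors of the remaining genes
        std::fill(ctx.begin(), ctx.end(), 0.0);
        for (int i = 0; i < m; ++i) {
          if (i == order[oi]) continue;
          for (int j = 0; j < dim; ++j) ctx[j] += Win(bag[i], j);
        }
        for (int j = 0; j < dim; ++j) ctx[j] /= (m - 1);
        std::fill(gctx.begin(), gctx.end(), 0.0);
        for (int k = 0; k <= k_neg; ++k) {
          int w;
          double label;
          if (k == 0) { w = target; label = 1.0; }
          else {
            w = sample_neg();
            int tries = 0;
            while (w == target && tries++ < 16) w = sample_neg();
            if (w == target) continue;
            label = 0.0;
          }
          double x = 0.0;
          for (int j = 0; j < dim; ++j) x += ctx[j] * Wout(w, j);
          const double s = sigmoid(x);
          obj_sum += label > 0.5 ? std::log(s) : std::log(1.0 - s);
          const double g = (label - s) * lr_e;
          for (int j = 0; j < dim; ++j) {
            gctx[j] += (label - s) * Wout(w, j);
            Wout(w, j) += g * ctx[j];
          }
        }
        ++obj_n;
        const double inv = lr_e / (m - 1);
        for (int i = 0; i < m; ++i) {
          if (i == order[oi]) continue;
          for (int j = 0; j < dim; ++j) Win(bag[i], j) += inv * gctx[j];
        }
      }
    }
    obj_traj[epoch] = obj_n > 0 ? obj_sum / obj_n : 0.0;
    if (!std::isfinite(obj_traj[epoch]))
      stop("non-finite objective at epoch %d", epoch + 1);
  }
  return List::create(_["input"] = Win, _["output"] = Wout,
                      _["objective"] = obj_traj);
}
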