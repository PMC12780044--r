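#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

// Built-in potential families evaluated in compiled code so that shooting
// moves stay cheap. type 1: symmetric quartic double well in 1D,
// params = (h, a): U = h ((x/a)^2 - 1)^2. type 2: 2D quartic confinement
// plus a sum of anisotropic Gaussians,
// params = (c4x, c4y, y0, nG, then per Gaussian A, cx, cy, sx2, sy2).

static inline double pot_energy(int type, const double *p, const double *x) {
  if (type == 1) {
    double s = x[0] / p[1];
    double t = s * s - 1.0;
    return p[0] * t * t;
  }
  double xx = x[0], yy = x[1];
  double u = p[0] * xx * xx * xx * xx;
  double dy = yy - p[2];
  u += p[1] * dy * dy * dy * dy;
  int nG = (int)p[3];
  for (int g = 0; g < nG; ++g) {
    const double *q = p + 4 + 5 * g;
    double ex = (xx - q[1]) * (xx - q[1]) / q[3] + (yy - q[2]) * (yy - q[2]) / q[4];
    u += q[0] * std::exp(-ex);
  }
  return u;
}

static inline void pot_grad(int type, const double *p, const double *x, double *g) {
  if (type == 1) {
    double a2 = p[1] * p[1];
    g[0] = 4.0 * p[0] * x[0] * (x[0] * x[0] / a2 - 1.0) / a2;
    return;
  }
  double xx = x[0], yy = x[1];
  double dy = yy - p[2];
  g[0] = 4.0 * p[0] * xx * xx * xx;
  g[1] = 4.0 * p[1] * dy * dy * dy;
  int nG = (int)p[3];
  for (int gg = 0; gg < nG; ++gg) {
    const double *q = p + 4 + 5 * gg;
    double ex = (xx - q[1]) * (xx - q[1]) / q[3] + (yy - q[2]) * (yy - q[2]) / q[4];
    double e = q[0] * std::exp(-ex);
    g[0] += e * (-2.0 * (xx - q[1]) / q[3]);
    g[1] += e * (-2.0 * (yy - q[2]) / q[4]);
  }
}

// [[Rcpp::export]]
double cpp_pot_energy(int type, NumericVector params, NumericVector x) {
  return pot_energy(type, params.begin(), x.begin());
}

// [[Rcpp::export]]
NumericVector cpp_pot_grad(int type, NumericVector params, NumericVector x) {
  NumericVector g(x.size());
  pot_grad(type, params.begin(), x.begin(), g.begin());
  return g;
}

// State geometry rows: kind 1 = interval on coordinate (dim, lo, hi, -),
// kind 2 = ball (cx, cy, r, -). Returns 1-based state index or 0.
static inline int which_state(const NumericMatrix &st, const double *x) {
  for (int i = 0; i < st.nrow(); ++i) {
    if (st(i, 0) == 1.0) {
      int d = (int)st(i, 1) - 1;
      if (x[d] > st(i, 2) && x[d] < st(i, 3)) return i + 1;
    } else {
      double dx = x[0] - st(i, 1), dyv = x[1] - st(i, 2);
      if (dx * dx + dyv * dyv < st(i, 3) * st(i, 3)) return i + 1;
    }
  }
  return 0;
}

// Euler-Maruyama overdamped Langevin with unit friction: dx = -grad U dt +
// sqrt(2 dt / beta) xi. Uses R's RNG so set.seed() governs reproducibility.
// Stops at first entrance into any state row when stop_on_state is true.
// [[Rcpp::export]]
List cpp_overdamped(int type, NumericVector params, NumericVector x0,
                    double dt, double beta, int max_steps,
                    NumericMatrix states, bool stop_on_state,
                    int stride) {
  int dim = x0.size();
  double noise = (beta > 0) ? std::sqrt(2.0 * dt / beta) : 0.0;
  std::vector<double> frames;
  frames.reserve((size_t)std::min(max_steps / stride + 2, 1000000) * dim);
  double x[2] = {x0[0], dim > 1 ? x0[1] : 0.0};
  double g[2];
  for (int d = 0; d < dim; ++d) frames.push_back(x[d]);
  int entered = stop_on_state ? which_state(states, x) : 0;
  int step = 0;
  if (!(stop_on_state && entered > 0)) {
    for (step = 1; step <= max_steps; ++step) {
      pot_grad(type, params.begin(), x, g);
      for (int d = 0; d < dim; ++d)
        x[d] += -g[d] * dt + noise * norm_rand();
      if (step % stride == 0)
        for (int d = 0; d < dim; ++d) frames.push_back(x[d]);
      if (stop_on_state) {
        entered = which_state(states, x);
        if (entered > 0) {
          if (step % stride != 0)  // always keep the entering frame
            for (int d = 0; d < dim; ++d) frames.push_back(x[d]);
          break;
        }
      }
    }
  }
  int nf = frames.size() / dim;
  NumericMatrix out(nf, dim);
  for (int i = 0; i < nf; ++i)
    for (int d = 0; d < dim; ++d) out(i, d) = frames[(size_t)i * dim + d];
  int steps_done = std::min(step, max_steps);
  return List::create(_["frames"] = out,
                      _["entered_state"] = entered,
                      _["n_steps"] = steps_done,
                      _["resolved"] = (!stop_on_state) || entered > 0);
}

// Random walk on a finite chain with row-stochastic transition matrix P,
// stopping at first entrance into a site flagged in `absorbing`
// (0 = interior, 1/2/... = state id). Uses R's RNG.
// [[Rcpp::export]]
List cpp_discrete_walk(NumericMatrix P, int start, IntegerVector absorbing,
                       int max_steps) {
  int n = P.nrow();
  std::vector<int> sites;
  sites.push_back(start);
  int cur = start - 1;
  int entered = absorbing[cur];
  int step = 0;
  while (entered == 0 && step < max_steps) {
    double u = unif_rand(), acc = 0.0;
    int nxt = n - 1;
    for (int j = 0; j < n; ++j) {
      acc += P(cur, j);
      if (u <= acc) { nxt = j; break; }
    }
    cur = nxt;
    sites.push_back(cur + 1);
    entered = absorbing[cur];
    ++step;
  }
  return List::create(_["sites"] = wrap(sites),
                      _["entered_state"] = entered,
                      _["resolved"] = entered > 0);
}

struct EnumCtx {
  const NumericMatrix *P;
  const IntegerVector *absorbing;
  const NumericVector *hB;  // P(reach B before A | site), 0/1 on states
  int max_len;
  double prune;
  std::vector<int> cur;
  std::vector<std::string> keys;
  std::vector<double> probs;
  std::vector<int> lens;
  double truncated;
};

static void enum_dfs(EnumCtx &ctx, int site, double w, int depth) {
  // site is 0-based current site (interior); w includes all hop factors so far
  int n = ctx.P->nrow();
  if (depth >= ctx.max_len) { ctx.truncated += w * (*ctx.hB)[site]; return; }
  if (w < ctx.prune) { ctx.truncated += w * (*ctx.hB)[site]; return; }
  for (int j = 0; j < n; ++j) {
    double pj = (*ctx.P)(site, j);
    if (pj <= 0) continue;
    int ab = (*ctx.absorbing)[j];
    double wj = w * pj;
    if (ab == 1) continue;  // fell back into A: not a transition path
    ctx.cur.push_back(j + 1);
    if (ab == 2) {
      std::string key;
      for (size_t i = 0; i < ctx.cur.size(); ++i) {
        if (i) key += "-";
        key += std::to_string(ctx.cur[i]);
      }
      ctx.keys.push_back(key);
      ctx.probs.push_back(wj);
      ctx.lens.push_back((int)ctx.cur.size());
    } else {
      enum_dfs(ctx, j, wj, depth + 1);
    }
    ctx.cur.pop_back();
  }
}

// Exact enumeration of first-entrance A -> B transition paths of a finite
// Markov chain, weighted by pi(x0) * prod P(hops). hB is the exact committor
// to B used to account for the truncated mass exactly.
// [[Rcpp::export]]
List cpp_enumerate_paths(NumericMatrix P, IntegerVector absorbing,
                         NumericVector pi_stat, NumericVector hB,
                         int max_len, double prune) {
  EnumCtx ctx;
  ctx.P = &P; ctx.absorbing = &absorbing; ctx.hB = &hB;
  ctx.max_len = max_len; ctx.prune = prune; ctx.truncated = 0.0;
  int n = P.nrow();
  for (int a = 0; a < n; ++a) {
    if (absorbing[a] != 1) continue;
    ctx.cur.clear();
    ctx.cur.push_back(a + 1);
    // first hop must leave A (first-entrance: only endpoints inside states)
    for (int j = 0; j < n; ++j) {
      double pj = P(a, j);
      if (pj <= 0 || absorbing[j] == 1) continue;
      double w = pi_stat[a] * pj;
      ctx.cur.push_back(j + 1);
      if (absorbing[j] == 2) {
        std::string key = std::to_string(a + 1) + "-" + std::to_string(j + 1);
        ctx.keys.push_back(key);
        ctx.probs.push_back(w);
        ctx.lens.push_back(2);
      } else {
        enum_dfs(ctx, j, w, 2);
      }
      ctx.cur.pop_back();
    }
  }
  return List::create(_["key"] = wrap(ctx.keys),
                      _["weight"] = wrap(ctx.probs),
                      _["length"] = wrap(ctx.lens),
                      _["truncated_weight"] = ctx.truncated);
}

// k-th nearest neighbour radius and mean of a feature matrix over the k
// nearest data points, per query point. Brute force with partial selection.
// [[Rcpp::export]]
List cpp_knn_mean(NumericMatrix coords, NumericMatrix feats,
                  NumericMatrix query, int k) {
  int n = coords.nrow(), d = coords.ncol(), m = query.nrow();
  int p = feats.ncol();
  NumericVector radius(m);
  NumericMatrix means(m, p);
  std::vector<std::pair<double, int> > dist(n);
  for (int q = 0; q < m; ++q) {
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < d; ++j) {
        double t = coords(i, j) - query(q, j);
        s += t * t;
      }
      dist[i] = std::make_pair(s, i);
    }
    std::nth_element(dist.begin(), dist.begin() + (k - 1), dist.end());
    radius[q] = std::sqrt(dist[k - 1].first);
    for (int j = 0; j < p; ++j) {
      double acc = 0.0;
      for (int i = 0; i < k; ++i) acc += feats(dist[i].second, j);
      means(q, j) = acc / k;
    }
  }
  return List::create(_["radius"] = radius, _["mean"] = means);
}
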