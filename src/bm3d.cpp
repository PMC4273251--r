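#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <limits>
#include <vector>

using namespace Rcpp;

// Orthonormal Haar step over a contiguous segment of length s (s even):
// averages land in [0, s/2), details in [s/2, s).
static void haar_step(std::vector<double> &buf, const double *x, double *out,
                      int s, int stride) {
  const double r = M_SQRT1_2;
  int h = s / 2;
  for (int k = 0; k < h; ++k) {
    double a = x[(2 * k) * stride];
    double b = x[(2 * k + 1) * stride];
    buf[k] = (a + b) * r;
    buf[h + k] = (a - b) * r;
  }
  for (int k = 0; k < s; ++k) out[k * stride] = buf[k];
}

static void haar_step_inv(std::vector<double> &buf, const double *x,
                          double *out, int s, int stride) {
  const double r = M_SQRT1_2;
  int h = s / 2;
  for (int k = 0; k < h; ++k) {
    double a = x[k * stride];
    double d = x[(h + k) * stride];
    buf[2 * k] = (a + d) * r;
    buf[2 * k + 1] = (a - d) * r;
  }
  for (int k = 0; k < s; ++k) out[k * stride] = buf[k];
}

// Full-depth non-standard (Mallat) 2D Haar on a b x b column-major block.
static void haar2d_fwd(double *blk, int b) {
  std::vector<double> buf(b);
  for (int s = b; s >= 2; s /= 2) {
    for (int i = 0; i < s; ++i)  // rows
      haar_step(buf, blk + i, blk + i, s, b);
    for (int j = 0; j < s; ++j)  // columns
      haar_step(buf, blk + j * b, blk + j * b, s, 1);
  }
}

static void haar2d_inv(double *blk, int b) {
  std::vector<double> buf(b);
  for (int s = 2; s <= b; s *= 2) {
    for (int j = 0; j < s; ++j)
      haar_step_inv(buf, blk + j * b, blk + j * b, s, 1);
    for (int i = 0; i < s; ++i)
      haar_step_inv(buf, blk + i, blk + i, s, b);
  }
}

// Full-depth 1D Haar along the stack axis of a b*b x K array (layer-major).
static void haar1d_fwd(double *stack, int n_pix, int K) {
  if (K < 2) return;
  std::vector<double> buf(K);
  for (int p = 0; p < n_pix; ++p)
    for (int s = K; s >= 2; s /= 2)
      haar_step(buf, stack + p, stack + p, s, n_pix);
}

static void haar1d_inv(double *stack, int n_pix, int K) {
  if (K < 2) return;
  std::vector<double> buf(K);
  for (int p = 0; p < n_pix; ++p)
    for (int s = 2; s <= K; s *= 2)
      haar_step_inv(buf, stack + p, stack + p, s, n_pix);
}

// [[Rcpp::export]]
NumericMatrix cpp_haar2d_ns_fwd(NumericMatrix block) {
  int b = block.nrow();
  NumericMatrix out = clone(block);
  haar2d_fwd(out.begin(), b);
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_haar2d_ns_inv(NumericMatrix coeff) {
  int b = coeff.nrow();
  NumericMatrix out = clone(coeff);
  haar2d_inv(out.begin(), b);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_haar1d_stack_fwd(NumericVector stack, int n_pix, int K) {
  NumericVector out = clone(stack);
  haar1d_fwd(out.begin(), n_pix, K);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_haar1d_stack_inv(NumericVector coeff, int n_pix, int K) {
  NumericVector out = clone(coeff);
  haar1d_inv(out.begin(), n_pix, K);
  return out;
}

struct Cand {
  double d;
  int r, c;
  bool operator<(const Cand &o) const {
    if (d != o.d) return d < o.d;
    if (r != o.r) return r < o.r;
    return c < o.c;
  }
};

// Step lattice covering [0, n - b], always including the last position.
static std::vector<int> lattice(int n, int b, int step) {
  std::vector<int> v;
  for (int p = 0; p + b <= n; p += step) v.push_back(p);
  if (v.empty() || v.back() != n - b) v.push_back(n - b);
  return v;
}

static double block_dist(const double *img, int H, int r1, int c1, int r2,
                         int c2, int b) {
  double s = 0.0;
  for (int j = 0; j < b; ++j) {
    const double *p1 = img + (c1 + j) * H + r1;
    const double *p2 = img + (c2 + j) * H + r2;
    for (int i = 0; i < b; ++i) {
      double d = p1[i] - p2[i];
      s += d * d;
    }
  }
  return s / (double)(b * b);
}

// Match within the search window; returns coords of the group (ref first),
// size truncated to the largest power of two <= max_group.
static void match_ref(const double *img, int H, int r0, int c0, int b,
                      int radius, int max_group, double th,
                      const std::vector<int> &rs, const std::vector<int> &cs,
                      std::vector<Cand> &out) {
  out.clear();
  std::vector<Cand> cand;
  for (int r : rs) {
    if (std::abs(r - r0) > radius) continue;
    for (int c : cs) {
      if (std::abs(c - c0) > radius) continue;
      if (r == r0 && c == c0) continue;
      double d = block_dist(img, H, r0, c0, r, c, b);
      if (d <= th) cand.push_back({d, r, c});
    }
  }
  std::sort(cand.begin(), cand.end());
  int total = (int)cand.size() + 1;
  int n = 1;
  while (2 * n <= std::min(max_group, total)) n *= 2;
  out.push_back({0.0, r0, c0});
  for (int k = 0; k < n - 1; ++k) out.push_back(cand[k]);
}

// [[Rcpp::export]]
List cpp_find_matches(NumericMatrix img, int r0, int c0, int bsize, int step,
                      int radius, int max_group, double th) {
  int H = img.nrow(), W = img.ncol();
  std::vector<int> rs = lattice(H, bsize, step), cs = lattice(W, bsize, step);
  std::vector<Cand> grp;
  match_ref(img.begin(), H, r0, c0, bsize, radius, max_group, th, rs, cs, grp);
  int n = (int)grp.size();
  IntegerMatrix coords(n, 2);
  NumericVector dist(n);
  for (int k = 0; k < n; ++k) {
    coords(k, 0) = grp[k].r;
    coords(k, 1) = grp[k].c;
    dist[k] = grp[k].d;
  }
  return List::create(_["coords"] = coords, _["dist"] = dist);
}

static void extract_stack(const double *img, int H,
                          const std::vector<Cand> &grp, int b,
                          std::vector<double> &stack) {
  int n_pix = b * b;
  for (size_t k = 0; k < grp.size(); ++k) {
    double *dst = stack.data() + k * n_pix;
    for (int j = 0; j < b; ++j) {
      const double *src = img + (grp[k].c + j) * H + grp[k].r;
      for (int i = 0; i < b; ++i) dst[j * b + i] = src[i];
    }
  }
}

// Per-subband Bayes (or fixed lambda*sigma) hard thresholding in place.
// labels: 1-based subband ids over the b*b*K coefficients; protected_id kept.
static int hard_threshold(double *coef, int n_coef, const int *labels,
                          int n_sub, int protected_id, double sigma,
                          bool bayes, double lambda) {
  std::vector<double> th(n_sub + 1, lambda * sigma);
  if (bayes) {
    std::vector<double> ss(n_sub + 1, 0.0);
    std::vector<int> cnt(n_sub + 1, 0);
    for (int i = 0; i < n_coef; ++i) {
      ss[labels[i]] += coef[i] * coef[i];
      cnt[labels[i]] += 1;
    }
    for (int s = 1; s <= n_sub; ++s) {
      double ms = cnt[s] > 0 ? ss[s] / cnt[s] : 0.0;
      double sy2 = ms - sigma * sigma;
      th[s] = sy2 > 0 ? sigma * sigma / std::sqrt(sy2)
                      : std::numeric_limits<double>::infinity();
    }
  }
  // retained counts positions surviving the rule (protected subband always
  // survives), not the number of numerically non-zero values
  int retained = 0;
  for (int i = 0; i < n_coef; ++i) {
    if (labels[i] != protected_id && std::fabs(coef[i]) < th[labels[i]])
      coef[i] = 0.0;
    else
      ++retained;
  }
  return retained;
}

static void aggregate_group(double *num, double *den, int H,
                            const std::vector<Cand> &grp, int b,
                            const std::vector<double> &stack, double w) {
  int n_pix = b * b;
  for (size_t k = 0; k < grp.size(); ++k) {
    const double *src = stack.data() + k * n_pix;
    for (int j = 0; j < b; ++j) {
      double *pn = num + (grp[k].c + j) * H + grp[k].r;
      double *pd = den + (grp[k].c + j) * H + grp[k].r;
      for (int i = 0; i < b; ++i) {
        pn[i] += w * src[j * b + i];
        pd[i] += w;
      }
    }
  }
}

static NumericMatrix finish(const NumericMatrix &img,
                            const std::vector<double> &num,
                            const std::vector<double> &den) {
  int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      int p = j * H + i;
      out(i, j) = den[p] > 0 ? num[p] / den[p] : img(i, j);
    }
  return out;
}

// labels_by_logk[[j]]: subband labels for group size K = 2^(j-1);
// n_sub_by_logk / protected_by_logk parallel that indexing.
// [[Rcpp::export]]
NumericMatrix cpp_bm3d_level1(NumericMatrix img, double sigma, int bsize,
                              int step, int radius, int max_group,
                              double th_match, bool bayes, double lambda,
                              List labels_by_logk, IntegerVector n_sub_by_logk,
                              IntegerVector protected_by_logk) {
  int H = img.nrow(), W = img.ncol();
  std::vector<int> rs = lattice(H, bsize, step), cs = lattice(W, bsize, step);
  std::vector<double> num(H * W, 0.0), den(H * W, 0.0);
  std::vector<double> stack(bsize * bsize * max_group);
  std::vector<Cand> grp;
  int n_pix = bsize * bsize;
  std::vector<const int *> lab(labels_by_logk.size());
  for (int j = 0; j < labels_by_logk.size(); ++j)
    lab[j] = INTEGER(labels_by_logk[j]);

  for (int r0 : rs) {
    for (int c0 : cs) {
      match_ref(img.begin(), H, r0, c0, bsize, radius, max_group, th_match,
                rs, cs, grp);
      int K = (int)grp.size();
      extract_stack(img.begin(), H, grp, bsize, stack);
      for (int k = 0; k < K; ++k) haar2d_fwd(stack.data() + k * n_pix, bsize);
      haar1d_fwd(stack.data(), n_pix, K);
      int logk = 0;
      for (int t = K; t > 1; t /= 2) ++logk;
      int retained =
          hard_threshold(stack.data(), n_pix * K, lab[logk],
                         n_sub_by_logk[logk], protected_by_logk[logk], sigma,
                         bayes, lambda);
      haar1d_inv(stack.data(), n_pix, K);
      for (int k = 0; k < K; ++k) haar2d_inv(stack.data() + k * n_pix, bsize);
      double w = 1.0 / std::max(retained, 1);
      aggregate_group(num.data(), den.data(), H, grp, bsize, stack, w);
    }
  }
  return finish(img, num, den);
}

// Level 2: matching on the pilot (basic estimate), empirical Wiener filtering
// of the noisy stack with the pilot stack, aggregation by Wiener energy.
// [[Rcpp::export]]
NumericMatrix cpp_bm3d_level2(NumericMatrix img, NumericMatrix pilot,
                              double sigma, int bsize, int step, int radius,
                              int max_group, double th_match, bool bayes_wiener,
                              double sigma_pilot, List labels_by_logk,
                              IntegerVector n_sub_by_logk,
                              IntegerVector protected_by_logk) {
  int H = img.nrow(), W = img.ncol();
  std::vector<int> rs = lattice(H, bsize, step), cs = lattice(W, bsize, step);
  std::vector<double> num(H * W, 0.0), den(H * W, 0.0);
  std::vector<double> stack(bsize * bsize * max_group);
  std::vector<double> pstack(bsize * bsize * max_group);
  std::vector<Cand> grp;
  int n_pix = bsize * bsize;
  double s2 = sigma * sigma;
  std::vector<const int *> lab(labels_by_logk.size());
  for (int j = 0; j < labels_by_logk.size(); ++j)
    lab[j] = INTEGER(labels_by_logk[j]);

  for (int r0 : rs) {
    for (int c0 : cs) {
      match_ref(pilot.begin(), H, r0, c0, bsize, radius, max_group, th_match,
                rs, cs, grp);
      int K = (int)grp.size();
      extract_stack(img.begin(), H, grp, bsize, stack);
      extract_stack(pilot.begin(), H, grp, bsize, pstack);
      for (int k = 0; k < K; ++k) {
        haar2d_fwd(stack.data() + k * n_pix, bsize);
        haar2d_fwd(pstack.data() + k * n_pix, bsize);
      }
      haar1d_fwd(stack.data(), n_pix, K);
      haar1d_fwd(pstack.data(), n_pix, K);
      if (bayes_wiener) {
        int logk = 0;
        for (int t = K; t > 1; t /= 2) ++logk;
        hard_threshold(pstack.data(), n_pix * K, lab[logk],
                       n_sub_by_logk[logk], protected_by_logk[logk],
                       sigma_pilot, true, 0.0);
      }
      double energy = 0.0;
      for (int i = 0; i < n_pix * K; ++i) {
        double p2 = pstack[i] * pstack[i];
        double wsh = (p2 + s2) > 0 ? p2 / (p2 + s2) : 0.0;
        stack[i] *= wsh;
        energy += wsh * wsh;
      }
      haar1d_inv(stack.data(), n_pix, K);
      for (int k = 0; k < K; ++k) haar2d_inv(stack.data() + k * n_pix, bsize);
      double w = 1.0 / std::max(energy, 1e-12);
      aggregate_group(num.data(), den.data(), H, grp, bsize, stack, w);
    }
  }
  return finish(img, num, den);
}
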