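// Core numerics: incremental nearest-neighbor retrieval and the per-grid-point
// balance loop. Dimensions are restricted to 1 and 2, so all small-matrix
// algebra (2x2 determinants, inverses) is written out explicitly.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <memory>
#include <numeric>
#include <queue>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// kd-tree over the (rescaled) sample, supporting best-first incremental
// neighbor retrieval: neighbors come off the stream in nondecreasing
// distance, ties broken by ascending sample index.
// ---------------------------------------------------------------------------

struct KdNode {
  double lo[2], hi[2];          // bounding box
  int left = -1, right = -1;    // children; -1 on both => leaf
  int begin = 0, end = 0;       // leaf: range in perm
};

struct NNIndex {
  int d = 0, M = 0;
  std::vector<double> pts;      // M*d, row-major
  std::vector<int> perm;
  std::vector<KdNode> nodes;
  int root = -1;

  double coord(int i, int a) const { return pts[(size_t)i * d + a]; }

  int build(int b, int e) {
    KdNode nd;
    for (int a = 0; a < d; ++a) { nd.lo[a] = R_PosInf; nd.hi[a] = R_NegInf; }
    for (int t = b; t < e; ++t)
      for (int a = 0; a < d; ++a) {
        double v = coord(perm[t], a);
        if (v < nd.lo[a]) nd.lo[a] = v;
        if (v > nd.hi[a]) nd.hi[a] = v;
      }
    int id = (int)nodes.size();
    nodes.push_back(nd);
    if (e - b <= 8) {
      nodes[id].begin = b; nodes[id].end = e;
      return id;
    }
    int axis = 0;
    if (d == 2 && (nd.hi[1] - nd.lo[1]) > (nd.hi[0] - nd.lo[0])) axis = 1;
    int mid = (b + e) / 2;
    std::nth_element(perm.begin() + b, perm.begin() + mid, perm.begin() + e,
                     [&](int u, int v) {
                       double cu = coord(u, axis), cv = coord(v, axis);
                       return cu < cv || (cu == cv && u < v);
                     });
    int L = build(b, mid);
    int R = build(mid, e);
    nodes[id].left = L;
    nodes[id].right = R;
    return id;
  }
};

using IndexPtr = std::shared_ptr<NNIndex>;

// Queue entries are either tree nodes (kind 0, keyed by the minimum distance
// from the probe to the bounding box) or points (kind 1, actual distance).
// A node's key is a lower bound on every point inside it, so popping nodes
// before equal-distance points preserves the ascending-index tie order.
struct QEntry { double d2; int kind; int id; };
struct QCmp {
  bool operator()(const QEntry& a, const QEntry& b) const {
    if (a.d2 != b.d2) return a.d2 > b.d2;      // min-heap on distance
    if (a.kind != b.kind) return a.kind > b.kind;  // nodes first
    return a.id > b.id;                        // ascending index
  }
};

struct NNStream {
  IndexPtr idx;
  double probe[2] = {0, 0};
  std::priority_queue<QEntry, std::vector<QEntry>, QCmp> q;

  void open(const IndexPtr& index, const double* pr) {
    idx = index;
    for (int a = 0; a < idx->d; ++a) probe[a] = pr[a];
    q = std::priority_queue<QEntry, std::vector<QEntry>, QCmp>();
    q.push({ndist2(idx->nodes[idx->root]), 0, idx->root});
  }
  double pdist2(int i) const {
    double s = 0;
    for (int a = 0; a < idx->d; ++a) {
      double t = idx->coord(i, a) - probe[a];
      s += t * t;
    }
    return s;
  }
  double ndist2(const KdNode& nd) const {
    double s = 0;
    for (int a = 0; a < idx->d; ++a) {
      double t = 0;
      if (probe[a] < nd.lo[a]) t = nd.lo[a] - probe[a];
      else if (probe[a] > nd.hi[a]) t = probe[a] - nd.hi[a];
      s += t * t;
    }
    return s;
  }
  bool next(int& out_i, double& out_d2) {
    while (!q.empty()) {
      QEntry e = q.top();
      q.pop();
      if (e.kind == 1) { out_i = e.id; out_d2 = e.d2; return true; }
      const KdNode& nd = idx->nodes[e.id];
      if (nd.left < 0) {
        for (int t = nd.begin; t < nd.end; ++t) {
          int p = idx->perm[t];
          q.push({pdist2(p), 1, p});
        }
      } else {
        q.push({ndist2(idx->nodes[nd.left]), 0, nd.left});
        q.push({ndist2(idx->nodes[nd.right]), 0, nd.right});
      }
    }
    return false;
  }
};

static IndexPtr make_index(const NumericMatrix& pts) {
  int M = pts.nrow(), d = pts.ncol();
  if (M < 1) stop("empty point set");
  if (d < 1 || d > 2) stop("only dimensions 1 and 2 are supported");
  for (int i = 0; i < M; ++i)
    for (int a = 0; a < d; ++a)
      if (!std::isfinite(pts(i, a))) stop("non-finite coordinate in point set");
  IndexPtr idx = std::make_shared<NNIndex>();
  idx->d = d;
  idx->M = M;
  idx->pts.resize((size_t)M * d);
  for (int i = 0; i < M; ++i)
    for (int a = 0; a < d; ++a) idx->pts[(size_t)i * d + a] = pts(i, a);
  idx->perm.resize(M);
  std::iota(idx->perm.begin(), idx->perm.end(), 0);
  idx->root = idx->build(0, M);
  return idx;
}

// [[Rcpp::export]]
SEXP cpp_nn_build(NumericMatrix pts) {
  IndexPtr idx = make_index(pts);
  XPtr<IndexPtr> xp(new IndexPtr(idx), true);
  return xp;
}

// [[Rcpp::export]]
SEXP cpp_nn_open(SEXP xp_, NumericVector probe) {
  XPtr<IndexPtr> xp(xp_);
  IndexPtr idx = *xp;
  if ((int)probe.size() != idx->d) stop("probe dimension does not match index");
  double pr[2] = {probe[0], idx->d == 2 ? probe[1] : 0.0};
  NNStream* s = new NNStream();
  s->open(idx, pr);
  XPtr<NNStream> sp(s, true);
  return sp;
}

// [[Rcpp::export]]
List cpp_nn_next(SEXP sp_, int n) {
  XPtr<NNStream> sp(sp_);
  std::vector<int> ids;
  std::vector<double> ds;
  ids.reserve(n > 0 ? n : 0);
  int i;
  double d2;
  for (int t = 0; t < n; ++t) {
    if (!sp->next(i, d2)) break;
    ids.push_back(i + 1);          // 1-based for R
    ds.push_back(std::sqrt(d2));
  }
  return List::create(_["index"] = wrap(ids), _["distance"] = wrap(ds));
}

// ---------------------------------------------------------------------------
// Balance loop: per grid point, consume neighbors while V_k * k < C2,
// maintaining running mean / scatter (Welford, rank-1 updates).
// ---------------------------------------------------------------------------

// n is the count AFTER including p; S holds the scatter (sum of cross
// products of deviations): S = {sxx} for d=1, {sxx, sxy, syy} for d=2.
static inline void welford_update(int d, int n, const double* p, double* mean,
                                  double* S) {
  double d0 = p[0] - mean[0];
  if (d == 1) {
    mean[0] += d0 / n;
    S[0] += d0 * (p[0] - mean[0]);
  } else {
    double d1 = p[1] - mean[1];
    mean[0] += d0 / n;
    mean[1] += d1 / n;
    double e0 = p[0] - mean[0], e1 = p[1] - mean[1];
    S[0] += d0 * e0;
    S[1] += d0 * e1;
    S[2] += d1 * e1;
  }
}

// [[Rcpp::export]]
List cpp_bade_grid(NumericMatrix pts, List axes, double C2, int k_min,
                   double jitter) {
  IndexPtr idx = make_index(pts);
  int d = idx->d, M = idx->M;
  if ((int)axes.size() != d) stop("grid dimension does not match point set");
  NumericVector ax1 = axes[0];
  int n1 = ax1.size(), n2 = 1;
  NumericVector ax2;
  if (d == 2) { ax2 = as<NumericVector>(axes[1]); n2 = ax2.size(); }
  int G = n1 * n2;
  if (k_min < 1) stop("k_min must be at least 1");

  IntegerVector kout(G);
  NumericVector ke(G), V(G), raw(G);
  NumericMatrix mu(G, d), cov(G, d == 1 ? 1 : 3);
  NNStream s;

  for (int i2 = 0; i2 < n2; ++i2) {
    for (int i1 = 0; i1 < n1; ++i1) {
      int g = i1 + n1 * i2;
      double probe[2] = {ax1[i1], d == 2 ? ax2[i2] : 0.0};
      s.open(idx, probe);
      double mean[2] = {0, 0}, S[3] = {0, 0, 0};
      int n = 0, pi;
      double pd2, Vk = 0.0;
      while (s.next(pi, pd2)) {
        const double* p = &idx->pts[(size_t)pi * d];
        ++n;
        welford_update(d, n, p, mean, S);
        if (n >= k_min) {
          double det;
          if (d == 1) det = S[0] / n;
          else {
            double a = S[0] / n, b = S[1] / n, c = S[2] / n;
            det = a * c - b * b;
          }
          Vk = det > 0 ? std::sqrt(det) : 0.0;
          if (Vk * n >= C2) break;
        }
        if (n >= M) break;
      }
      if (!(Vk > 0))
        stop("degenerate sample: local covariance singular even at k = M");

      double cxx = S[0] / n, cxy = 0, cyy = 0;
      if (d == 2) { cxy = S[1] / n; cyy = S[2] / n; }

      double q;
      if (d == 1) {
        double var = cxx;
        if (var <= 0 || !std::isfinite(var)) var += jitter;
        double dev = probe[0] - mean[0];
        q = dev * dev / var;
      } else {
        double a = cxx, b = cxy, c = cyy;
        double dt = a * c - b * b;
        if (dt <= 0 || !std::isfinite(dt)) {
          a += jitter;
          c += jitter;
          dt = a * c - b * b;
        }
        double dx = probe[0] - mean[0], dy = probe[1] - mean[1];
        q = (c * dx * dx - 2 * b * dx * dy + a * dy * dy) / dt;
      }
      double kev = n * std::exp(-0.5 * q);
      kout[g] = n;
      ke[g] = kev;
      V[g] = Vk;
      raw[g] = kev / ((double)M * Vk);
      mu(g, 0) = mean[0];
      if (d == 2) mu(g, 1) = mean[1];
      cov(g, 0) = cxx;
      if (d == 2) { cov(g, 1) = cxy; cov(g, 2) = cyy; }
      if ((g & 255) == 0) Rcpp::checkUserInterrupt();
    }
  }
  return List::create(_["k"] = kout, _["ke"] = ke, _["V"] = V, _["raw"] = raw,
                      _["mu"] = mu, _["cov"] = cov);
}

// ---------------------------------------------------------------------------
// Covariance smoothing: Gaussian-weighted averages of precision matrices and
// effective-k values over the grid, truncated at a Mahalanobis cutoff.
// Each source point j scatters into the axis-aligned bounding box of its
// cutoff ellipse, keeping the O(G^2) constant small.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_smooth_field(List axes, NumericMatrix cov, NumericVector ke,
                      double cutoff, double jitter) {
  int d = cov.ncol() == 1 ? 1 : 2;
  NumericVector ax1 = axes[0];
  int n1 = ax1.size(), n2 = 1;
  NumericVector ax2;
  if (d == 2) { ax2 = as<NumericVector>(axes[1]); n2 = ax2.size(); }
  int G = n1 * n2;
  if (cov.nrow() != G || ke.size() != G)
    stop("field size does not match grid");
  double a0 = ax1[0], dx1 = n1 > 1 ? ax1[1] - ax1[0] : 1.0;
  double b0 = 0, dx2 = 1.0;
  if (d == 2) { b0 = ax2[0]; dx2 = n2 > 1 ? ax2[1] - ax2[0] : 1.0; }

  std::vector<double> pn((size_t)G * (d == 1 ? 1 : 3), 0.0), den(G, 0.0),
      kn(G, 0.0);
  double c2 = cutoff * cutoff;

  for (int j2 = 0; j2 < n2; ++j2) {
    for (int j1 = 0; j1 < n1; ++j1) {
      int j = j1 + n1 * j2;
      double xj = ax1[j1], yj = d == 2 ? ax2[j2] : 0.0;
      double A = cov(j, 0), B = 0, C = 0, det, p00, p01 = 0, p11 = 0, pref;
      if (d == 1) {
        if (A <= 0 || !std::isfinite(A)) A += jitter;
        det = A;
        p00 = 1.0 / A;
      } else {
        B = cov(j, 1);
        C = cov(j, 2);
        det = A * C - B * B;
        if (det <= 0 || !std::isfinite(det)) {
          A += jitter;
          C += jitter;
          det = A * C - B * B;
        }
        p00 = C / det;
        p01 = -B / det;
        p11 = A / det;
      }
      pref = 1.0 / std::sqrt(det);

      double hw1 = cutoff * std::sqrt(A);
      int lo1 = std::max(0, (int)std::ceil((xj - hw1 - a0) / dx1 - 1e-9));
      int hi1 = std::min(n1 - 1, (int)std::floor((xj + hw1 - a0) / dx1 + 1e-9));
      int lo2 = 0, hi2 = 0;
      if (d == 2) {
        double hw2 = cutoff * std::sqrt(C);
        lo2 = std::max(0, (int)std::ceil((yj - hw2 - b0) / dx2 - 1e-9));
        hi2 = std::min(n2 - 1, (int)std::floor((yj + hw2 - b0) / dx2 + 1e-9));
      }
      for (int i2 = lo2; i2 <= hi2; ++i2) {
        for (int i1 = lo1; i1 <= hi1; ++i1) {
          int i = i1 + n1 * i2;
          double ddx = ax1[i1] - xj, ddy = d == 2 ? ax2[i2] - yj : 0.0;
          double q = d == 1
                         ? p00 * ddx * ddx
                         : p00 * ddx * ddx + 2 * p01 * ddx * ddy + p11 * ddy * ddy;
          if (q > c2) continue;
          double w = pref * std::exp(-0.5 * q);
          den[i] += w;
          kn[i] += w * ke[j];
          if (d == 1) pn[i] += w * p00;
          else {
            pn[(size_t)i * 3] += w * p00;
            pn[(size_t)i * 3 + 1] += w * p01;
            pn[(size_t)i * 3 + 2] += w * p11;
          }
        }
      }
      if ((j & 255) == 0) Rcpp::checkUserInterrupt();
    }
  }

  NumericVector keh(G), val(G);
  NumericMatrix prec(G, d == 1 ? 1 : 3);
  for (int i = 0; i < G; ++i) {
    double w = den[i];       // > 0: the self term always survives the cutoff
    double kh = kn[i] / w;
    keh[i] = kh;
    if (d == 1) {
      double p = pn[i] / w;
      prec(i, 0) = p;
      val[i] = kh * std::sqrt(p);
    } else {
      double p00 = pn[(size_t)i * 3] / w, p01 = pn[(size_t)i * 3 + 1] / w,
             p11 = pn[(size_t)i * 3 + 2] / w;
      prec(i, 0) = p00;
      prec(i, 1) = p01;
      prec(i, 2) = p11;
      double pd = p00 * p11 - p01 * p01;
      val[i] = kh * std::sqrt(pd > 0 ? pd : 0.0);
    }
  }
  return List::create(_["ke"] = keh, _["prec"] = prec, _["value"] = val);
}
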