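// Resampling and clustering engine for channel x time statistic maps.
//
// Layout convention throughout: a map is a length-P vector with the channel
// index varying fastest, i.e. point (c, t) lives at p = c + t * nchan, which is
// exactly the column-major storage of an nchan x ntime R matrix.
//
// Spatiotemporal connectivity: (c, t) ~ (c, t +/- 1) and (c, t) ~ (c', t) for
// c' a graph neighbour of c.  No diagonal channel-and-time moves.

#include <RcppArmadillo.h>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-mode SplitMix64: one independent substream per (seed, iteration,
// salt) triple, so resampled iterations are reproducible in any order.
// ---------------------------------------------------------------------------

static inline uint64_t mix64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Stream {
  uint64_t s;
  Stream(int seed, int iteration, int salt) {
    uint64_t a = mix64((uint64_t)(uint32_t)seed + 0x9E3779B97F4A7C15ULL);
    a = mix64(a ^ ((uint64_t)(uint32_t)iteration * 0xBF58476D1CE4E5B9ULL));
    a = mix64(a ^ ((uint64_t)(uint32_t)salt * 0x94D049BB133111EBULL));
    s = a;
  }
  inline uint64_t next() { s += 0x9E3779B97F4A7C15ULL; return mix64(s); }
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  inline int ri(int n) { return (int)(unif() * n); }  // 0 .. n-1
};

// Fisher-Yates permutation of 0..n-1
static void draw_perm(Stream& st, int n, std::vector<int>& out) {
  out.resize(n);
  for (int i = 0; i < n; ++i) out[i] = i;
  for (int i = n - 1; i > 0; --i) {
    int j = st.ri(i + 1);
    std::swap(out[i], out[j]);
  }
}

static int n_distinct(const int* idx, int n, std::vector<char>& mark, int range) {
  std::fill(mark.begin(), mark.begin() + range, 0);
  int d = 0;
  for (int i = 0; i < n; ++i) if (!mark[idx[i]]) { mark[idx[i]] = 1; ++d; }
  return d;
}

// schemes: 0 = permutation, 1 = percentile bootstrap (pooled), 2 = bootstrap-t
// (within-condition).  Pooled schemes index trials 0..n1+n2-1; bootstrap-t
// indexes each condition's own trials.  Returns false if min_unique cannot be
// satisfied within 100 redraws.
static bool draw_iteration(int seed, int iteration, int scheme, int n1, int n2,
                           int min_unique, std::vector<int>& i1,
                           std::vector<int>& i2, std::vector<int>& buf,
                           std::vector<char>& mark) {
  const int N = n1 + n2;
  Stream st(seed, iteration, scheme);
  i1.resize(n1); i2.resize(n2);
  for (int attempt = 0; attempt < 100; ++attempt) {
    if (scheme == 0) {
      draw_perm(st, N, buf);
      std::copy(buf.begin(), buf.begin() + n1, i1.begin());
      std::copy(buf.begin() + n1, buf.end(), i2.begin());
      return true;  // always n1 (resp. n2) distinct trials
    } else if (scheme == 1) {
      for (int i = 0; i < n1; ++i) i1[i] = st.ri(N);
      for (int i = 0; i < n2; ++i) i2[i] = st.ri(N);
      if (min_unique <= 0) return true;
      if (n_distinct(i1.data(), n1, mark, N) >= min_unique &&
          n_distinct(i2.data(), n2, mark, N) >= min_unique) return true;
    } else {
      for (int i = 0; i < n1; ++i) i1[i] = st.ri(n1);
      for (int i = 0; i < n2; ++i) i2[i] = st.ri(n2);
      if (min_unique <= 0) return true;
      if (n_distinct(i1.data(), n1, mark, n1) >= min_unique &&
          n_distinct(i2.data(), n2, mark, n2) >= min_unique) return true;
    }
  }
  return false;
}

// [[Rcpp::export]]
List cpp_resample_indices(int seed, int iteration, int scheme, int n1, int n2,
                          int min_unique) {
  std::vector<int> i1, i2, buf;
  std::vector<char> mark((size_t)(n1 + n2));
  if (!draw_iteration(seed, iteration, scheme, n1, n2, min_unique, i1, i2, buf, mark))
    stop("resampling error: could not satisfy min_unique = %d for scheme %d",
         min_unique, scheme);
  IntegerVector o1(n1), o2(n2);
  for (int i = 0; i < n1; ++i) o1[i] = i1[i] + 1;
  for (int i = 0; i < n2; ++i) o2[i] = i2[i] + 1;
  return List::create(_["idx1"] = o1, _["idx2"] = o2);
}

// [[Rcpp::export]]
IntegerVector cpp_permute(int seed, int iteration, int n) {
  Stream st(seed, iteration, 99);  // salt distinct from the three schemes
  std::vector<int> buf;
  draw_perm(st, n, buf);
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = buf[i] + 1;
  return out;
}

// ---------------------------------------------------------------------------
// Channel graph (CSR over symmetric neighbour lists)
// ---------------------------------------------------------------------------

struct ChanGraph {
  int nchan;
  std::vector<int> off, nbr;
};

static ChanGraph make_graph(const IntegerMatrix& edges, int nchan) {
  ChanGraph g;
  g.nchan = nchan;
  std::vector<int> deg(nchan, 0);
  const int E = edges.nrow();
  for (int e = 0; e < E; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    if (a < 0 || b < 0 || a >= nchan || b >= nchan)
      stop("adjacency edge index out of range");
    ++deg[a]; ++deg[b];
  }
  g.off.assign(nchan + 1, 0);
  for (int c = 0; c < nchan; ++c) g.off[c + 1] = g.off[c] + deg[c];
  g.nbr.assign(g.off[nchan], 0);
  std::vector<int> pos(g.off.begin(), g.off.end() - 1);
  for (int e = 0; e < E; ++e) {
    int a = edges(e, 0) - 1, b = edges(e, 1) - 1;
    g.nbr[pos[a]++] = b;
    g.nbr[pos[b]++] = a;
  }
  return g;
}

// ---------------------------------------------------------------------------
// Union-find connected components of {x > thr}
// ---------------------------------------------------------------------------

static inline int uf_find(std::vector<int>& parent, int p) {
  while (parent[p] != p) {
    parent[p] = parent[parent[p]];
    p = parent[p];
  }
  return p;
}

static inline void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[rb] = ra;
}

// parent[p] == -1 marks subthreshold points.
static void supra_components(const double* x, int nchan, int ntime, double thr,
                             const ChanGraph& g, std::vector<int>& parent) {
  const int P = nchan * ntime;
  parent.assign(P, -1);
  for (int p = 0; p < P; ++p) if (x[p] > thr) parent[p] = p;
  for (int t = 0; t < ntime; ++t) {
    const int base = t * nchan;
    for (int c = 0; c < nchan; ++c) {
      const int p = base + c;
      if (parent[p] < 0) continue;
      if (t > 0 && parent[p - nchan] >= 0) uf_union(parent, p, p - nchan);
      for (int k = g.off[c]; k < g.off[c + 1]; ++k) {
        const int c2 = g.nbr[k];
        if (c2 < c) {  // visit each spatial edge once per time slice
          const int q = base + c2;
          if (parent[q] >= 0) uf_union(parent, p, q);
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_label_clusters(NumericMatrix x, double thr, IntegerMatrix edges) {
  const int nchan = x.nrow(), ntime = x.ncol(), P = nchan * ntime;
  ChanGraph g = make_graph(edges, nchan);
  std::vector<int> parent;
  supra_components(REAL(x), nchan, ntime, thr, g, parent);
  // labels numbered by first-encountered point in channel-major (channel
  // outer, time inner) raster order, so labelling is deterministic
  IntegerMatrix labels(nchan, ntime);
  std::vector<int> rootlab(P, 0);
  int nl = 0;
  for (int c = 0; c < nchan; ++c) {
    for (int t = 0; t < ntime; ++t) {
      const int p = c + t * nchan;
      if (parent[p] < 0) continue;
      const int r = uf_find(parent, p);
      if (rootlab[r] == 0) rootlab[r] = ++nl;
      labels(c, t) = rootlab[r];
    }
  }
  return List::create(_["labels"] = labels, _["n_clusters"] = nl);
}

// [[Rcpp::export]]
List cpp_cluster_stats(NumericMatrix x, IntegerMatrix labels, int n_clusters) {
  const int nchan = x.nrow(), ntime = x.ncol();
  NumericVector height(n_clusters, R_NegInf), mass(n_clusters, 0.0);
  IntegerVector extent(n_clusters, 0), peak(n_clusters, 0);
  // raster order (channel outer, time inner); first strict max wins ties
  for (int c = 0; c < nchan; ++c) {
    for (int t = 0; t < ntime; ++t) {
      const int lab = labels(c, t);
      if (lab == 0) continue;
      const double v = x(c, t);
      const int i = lab - 1;
      mass[i] += v;
      extent[i] += 1;
      if (v > height[i]) { height[i] = v; peak[i] = c + t * nchan + 1; }
    }
  }
  return List::create(_["height"] = height, _["extent"] = extent,
                      _["mass"] = mass, _["peak"] = peak);
}

// Max height/extent/mass over components of {x > thr}; zeros when none.
static void cluster_maxima(const double* x, int nchan, int ntime, double thr,
                           const ChanGraph& g, std::vector<int>& parent,
                           std::vector<double>& massbuf,
                           std::vector<double>& hgtbuf,
                           std::vector<int>& extbuf, double& out_h,
                           double& out_e, double& out_m) {
  const int P = nchan * ntime;
  supra_components(x, nchan, ntime, thr, g, parent);
  for (int p = 0; p < P; ++p)
    if (parent[p] >= 0) { massbuf[p] = 0.0; hgtbuf[p] = 0.0; extbuf[p] = 0; }
  out_h = out_e = out_m = 0.0;
  for (int p = 0; p < P; ++p) {
    if (parent[p] < 0) continue;
    const int r = uf_find(parent, p);
    massbuf[r] += x[p];
    extbuf[r] += 1;
    if (x[p] > hgtbuf[r]) hgtbuf[r] = x[p];
  }
  for (int p = 0; p < P; ++p) {
    if (parent[p] != p) continue;  // roots only
    if (hgtbuf[p] > out_h) out_h = hgtbuf[p];
    if (extbuf[p] > out_e) out_e = extbuf[p];
    if (massbuf[p] > out_m) out_m = massbuf[p];
  }
}

// ---------------------------------------------------------------------------
// TFCE: single descending sweep over the dh grid with an incremental
// union-find.  Each component root carries an accumulator per parameter set;
// when components merge, the absorbed members record an offset so their final
// value is acc[root] - base[member].  Member lists are merged small-to-large.
// ---------------------------------------------------------------------------

struct TfceWS {
  int P = 0, K = 0;
  std::vector<int> parent, sz, order, mnext, mfirst, mlast, rnext, rprev;
  std::vector<char> active;
  std::vector<double> acc, base, out;  // K x P, column-major in p
  int rhead = -1;

  void ensure(int P_, int K_) {
    if (P_ == P && K_ == K) return;
    P = P_; K = K_;
    parent.resize(P); sz.resize(P); order.resize(P);
    mnext.resize(P); mfirst.resize(P); mlast.resize(P);
    rnext.resize(P); rprev.resize(P);
    active.resize(P);
    acc.resize((size_t)P * K); base.resize((size_t)P * K);
    out.resize((size_t)P * K);
  }
};

static void tfce_core(const double* x, int nchan, int ntime, const ChanGraph& g,
                      const std::vector<double>& Ev,
                      const std::vector<double>& Hv, double dh, double h0,
                      TfceWS& ws) {
  const int P = nchan * ntime;
  const int K = (int)Ev.size();
  if (K > 16) stop("at most 16 TFCE parameter sets per sweep");
  ws.ensure(P, K);
  std::fill(ws.out.begin(), ws.out.end(), 0.0);
  std::fill(ws.active.begin(), ws.active.end(), 0);
  ws.rhead = -1;

  // candidate points, descending value
  int n = 0;
  double vmax = h0;
  for (int p = 0; p < P; ++p) {
    if (x[p] > h0) {
      ws.order[n++] = p;
      if (x[p] > vmax) vmax = x[p];
    }
  }
  if (n == 0) return;
  std::sort(ws.order.begin(), ws.order.begin() + n,
            [&](int a, int b) { return x[a] > x[b]; });
  const int L = (int)std::floor((vmax - h0) / dh + 1e-6);
  if (L < 1) return;
  const double vtol = 1e-6 * dh;

  int ptr = 0;
  std::vector<int>& parent = ws.parent;

  // fold the smaller component into the larger, recording per-member offsets
  auto merge = [&](int a, int b) {
    int ra = uf_find(parent, a), rb = uf_find(parent, b);
    if (ra == rb) return;
    if (ws.sz[ra] < ws.sz[rb]) std::swap(ra, rb);
    for (int m = ws.mfirst[rb]; m >= 0; m = ws.mnext[m]) {
      for (int k = 0; k < K; ++k) {
        const size_t kp = (size_t)k * P;
        ws.base[kp + m] = ws.acc[kp + ra] - (ws.acc[kp + rb] - ws.base[kp + m]);
      }
    }
    ws.mnext[ws.mlast[ra]] = ws.mfirst[rb];
    ws.mlast[ra] = ws.mlast[rb];
    ws.sz[ra] += ws.sz[rb];
    parent[rb] = ra;
    // drop rb from the live-roots list
    if (ws.rprev[rb] >= 0) ws.rnext[ws.rprev[rb]] = ws.rnext[rb];
    else ws.rhead = ws.rnext[rb];
    if (ws.rnext[rb] >= 0) ws.rprev[ws.rnext[rb]] = ws.rprev[rb];
  };

  for (int j = L; j >= 1; --j) {
    const double h = h0 + j * dh;
    // activate points with value >= h and union with active neighbours
    while (ptr < n && x[ws.order[ptr]] >= h - vtol) {
      const int p = ws.order[ptr++];
      parent[p] = p; ws.sz[p] = 1;
      ws.mfirst[p] = ws.mlast[p] = p; ws.mnext[p] = -1;
      for (int k = 0; k < K; ++k) {
        ws.acc[(size_t)k * P + p] = 0.0;
        ws.base[(size_t)k * P + p] = 0.0;
      }
      ws.active[p] = 1;
      ws.rnext[p] = ws.rhead; ws.rprev[p] = -1;
      if (ws.rhead >= 0) ws.rprev[ws.rhead] = p;
      ws.rhead = p;
      const int c = p % nchan, t = p / nchan;
      if (t > 0 && ws.active[p - nchan]) merge(p, p - nchan);
      if (t + 1 < ntime && ws.active[p + nchan]) merge(p, p + nchan);
      for (int k2 = g.off[c]; k2 < g.off[c + 1]; ++k2) {
        const int q = g.nbr[k2] + t * nchan;
        if (ws.active[q]) merge(p, q);
      }
    }
    // accumulate extent(h)^E * h^H * dh on every live component
    double hk[16];
    for (int k = 0; k < K; ++k) {
      const double H = Hv[k];
      hk[k] = (H == 0.0 ? 1.0 : (H == 1.0 ? h : (H == 2.0 ? h * h
                : std::pow(h, H)))) * dh;
    }
    for (int r = ws.rhead; r >= 0; r = ws.rnext[r]) {
      const double s = (double)ws.sz[r];
      for (int k = 0; k < K; ++k) {
        const double E = Ev[k];
        const double se = (E == 0.5 ? std::sqrt(s) : (E == 1.0 ? s
                           : (E == 0.0 ? 1.0 : std::pow(s, E))));
        ws.acc[(size_t)k * P + r] += se * hk[k];
      }
    }
  }
  for (int i = 0; i < n; ++i) {
    const int p = ws.order[i];
    if (!ws.active[p]) continue;
    const int r = uf_find(parent, p);
    for (int k = 0; k < K; ++k) {
      const size_t kp = (size_t)k * P;
      ws.out[kp + p] = ws.acc[kp + r] - ws.base[kp + p];
    }
  }
}

// [[Rcpp::export]]
List cpp_tfce(NumericMatrix x, IntegerMatrix edges, NumericVector E,
              NumericVector H, double dh, double h0) {
  const int nchan = x.nrow(), ntime = x.ncol(), P = nchan * ntime;
  ChanGraph g = make_graph(edges, nchan);
  std::vector<double> Ev(E.begin(), E.end()), Hv(H.begin(), H.end());
  TfceWS ws;
  tfce_core(REAL(x), nchan, ntime, g, Ev, Hv, dh, h0, ws);
  List out(Ev.size());
  for (int k = 0; k < (int)Ev.size(); ++k) {
    NumericMatrix m(nchan, ntime);
    std::copy(ws.out.begin() + (size_t)k * P, ws.out.begin() + (size_t)(k + 1) * P,
              REAL(m));
    out[k] = m;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Null-distribution engine: per-iteration maxima of the chosen statistics.
//
// Group sums and sums of squares for all B iterations are obtained as two to
// four BLAS gemms against 0/1 (permutation) or count (bootstrap) assignment
// matrices, then each column's pooled-variance t^2 map is reduced to its
// cluster / TFCE / pointwise maxima.
// ---------------------------------------------------------------------------

static inline double t2_point(double s1, double q1, double s2, double q2,
                              int n1, int n2, double inv_df, double inv12,
                              double cap2) {
  const double m1 = s1 / n1, m2 = s2 / n2;
  const double md = m1 - m2;
  double ss1 = q1 - s1 * m1;  // within-group sums of squares
  double ss2 = q2 - s2 * m2;
  if (ss1 < 0) ss1 = 0;
  if (ss2 < 0) ss2 = 0;
  const double den = (ss1 + ss2) * inv_df * inv12;
  if (den <= 0) return (md == 0) ? 0.0 : cap2;
  return md * md / den;
}

// [[Rcpp::export]]
List cpp_null_maxima(const arma::mat& XA, const arma::mat& XB, int scheme,
                     int B, int seed, int min_unique, NumericVector form_thr,
                     bool want_cluster, NumericVector tfce_E,
                     NumericVector tfce_H, double dh, double h0,
                     IntegerMatrix edges, int nchan, int ntime, double t_cap) {
  const int P = XA.n_rows;
  const int n1 = XA.n_cols, n2 = XB.n_cols, N = n1 + n2;
  if ((int)XB.n_rows != P) stop("group shapes differ");
  if (P != nchan * ntime) stop("map size does not match nchan * ntime");
  const int df = n1 + n2 - 2;
  const double inv_df = 1.0 / df, inv12 = 1.0 / n1 + 1.0 / n2;
  const double cap2 = t_cap * t_cap;
  const int F = form_thr.size();
  const int K = tfce_E.size();

  ChanGraph g = make_graph(edges, nchan);
  std::vector<int> i1, i2, buf;
  std::vector<char> mark(N);

  arma::mat S1(P, B), S2(P, B), Q1(P, B), Q2(P, B);
  if (scheme == 2) {
    // bootstrap-t: mean-centre each condition, resample within condition
    arma::mat XAc = XA; XAc.each_col() -= arma::mean(XA, 1);
    arma::mat XBc = XB; XBc.each_col() -= arma::mean(XB, 1);
    arma::mat C1(n1, B, arma::fill::zeros), C2(n2, B, arma::fill::zeros);
    for (int b = 0; b < B; ++b) {
      if (!draw_iteration(seed, b + 1, scheme, n1, n2, min_unique, i1, i2, buf, mark))
        stop("resampling error: could not satisfy min_unique = %d for bootstrap-t",
             min_unique);
      for (int i = 0; i < n1; ++i) C1(i1[i], b) += 1.0;
      for (int i = 0; i < n2; ++i) C2(i2[i], b) += 1.0;
    }
    const arma::mat XAc2 = arma::square(XAc), XBc2 = arma::square(XBc);
    S1 = XAc * C1; Q1 = XAc2 * C1;
    S2 = XBc * C2; Q2 = XBc2 * C2;
  } else {
    arma::mat X = arma::join_rows(XA, XB);
    const arma::mat X2 = arma::square(X);
    if (scheme == 0) {
      // permutation partitions the pool: group 2 sums are complements
      arma::mat C1(N, B, arma::fill::zeros);
      for (int b = 0; b < B; ++b) {
        draw_iteration(seed, b + 1, scheme, n1, n2, min_unique, i1, i2, buf, mark);
        for (int i = 0; i < n1; ++i) C1(i1[i], b) += 1.0;
      }
      const arma::vec tot = arma::sum(X, 1), tot2 = arma::sum(X2, 1);
      S1 = X * C1; Q1 = X2 * C1;
      S2 = -S1; S2.each_col() += tot;
      Q2 = -Q1; Q2.each_col() += tot2;
    } else {
      arma::mat C1(N, B, arma::fill::zeros), C2(N, B, arma::fill::zeros);
      for (int b = 0; b < B; ++b) {
        if (!draw_iteration(seed, b + 1, scheme, n1, n2, min_unique, i1, i2, buf, mark))
          stop("resampling error: could not satisfy min_unique = %d for percentile bootstrap",
               min_unique);
        for (int i = 0; i < n1; ++i) C1(i1[i], b) += 1.0;
        for (int i = 0; i < n2; ++i) C2(i2[i], b) += 1.0;
      }
      S1 = X * C1; Q1 = X2 * C1;
      S2 = X * C2; Q2 = X2 * C2;
    }
  }

  NumericMatrix max_h(B, want_cluster ? F : 0), max_e(B, want_cluster ? F : 0),
      max_m(B, want_cluster ? F : 0), max_tfce(B, K);
  NumericVector max_t2(B);

  std::vector<double> t2(P), massbuf(P), hgtbuf(P);
  std::vector<int> extbuf(P), parent;
  std::vector<double> Ev(tfce_E.begin(), tfce_E.end()),
      Hv(tfce_H.begin(), tfce_H.end());
  TfceWS ws;

  for (int b = 0; b < B; ++b) {
    double mt = 0.0;
    const double *s1 = S1.colptr(b), *q1 = Q1.colptr(b), *s2 = S2.colptr(b),
                 *q2 = Q2.colptr(b);
    for (int p = 0; p < P; ++p) {
      const double v = t2_point(s1[p], q1[p], s2[p], q2[p], n1, n2, inv_df,
                                inv12, cap2);
      t2[p] = v;
      if (v > mt) mt = v;
    }
    max_t2[b] = mt;
    if (want_cluster) {
      for (int f = 0; f < F; ++f) {
        double mh, me, mm;
        cluster_maxima(t2.data(), nchan, ntime, form_thr[f], g, parent, massbuf,
                       hgtbuf, extbuf, mh, me, mm);
        max_h(b, f) = mh; max_e(b, f) = me; max_m(b, f) = mm;
      }
    }
    if (K > 0) {
      tfce_core(t2.data(), nchan, ntime, g, Ev, Hv, dh, h0, ws);
      for (int k = 0; k < K; ++k) {
        const double* o = ws.out.data() + (size_t)k * P;
        double m = 0.0;
        for (int p = 0; p < P; ++p) if (o[p] > m) m = o[p];
        max_tfce(b, k) = m;
      }
    }
    if ((b & 63) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["height"] = max_h, _["extent"] = max_e,
                      _["mass"] = max_m, _["tfce"] = max_tfce,
                      _["max_t2"] = max_t2);
}

// Pooled-variance t^2 map for one observed split (vector form, channel-fastest)
// [[Rcpp::export]]
NumericVector cpp_t2_map(const arma::mat& XA, const arma::mat& XB, double t_cap) {
  const int P = XA.n_rows, n1 = XA.n_cols, n2 = XB.n_cols;
  if ((int)XB.n_rows != P) stop("group shapes differ");
  if (n1 < 2 || n2 < 2) stop("each group needs at least 2 trials");
  const double inv_df = 1.0 / (n1 + n2 - 2), inv12 = 1.0 / n1 + 1.0 / n2;
  const double cap2 = t_cap * t_cap;
  NumericVector out(P);
  for (int p = 0; p < P; ++p) {
    double s1 = 0, q1 = 0, s2 = 0, q2 = 0;
    for (int i = 0; i < n1; ++i) { const double v = XA(p, i); s1 += v; q1 += v * v; }
    for (int i = 0; i < n2; ++i) { const double v = XB(p, i); s2 += v; q2 += v * v; }
    out[p] = t2_point(s1, q1, s2, q2, n1, n2, inv_df, inv12, cap2);
  }
  return out;
}
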