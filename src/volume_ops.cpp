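// Low-level volumetric primitives: 3D connected components, affinity-graph
// watershed (zwatershed-style), seeded voxel watershed, and a separable
// squared Euclidean distance transform. All arrays use R's (z, y, x) dim
// convention, column-major, so linear index = z + Z*y + Z*Y*x (0-based).
// Determinism: every tie is broken by raster (linear-index) order.

#include <Rcpp.h>
#include <map>
#include <queue>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

static inline int idx3(int z, int y, int x, int Z, int Y) {
  return z + Z * (y + Y * x);
}

struct DSU {
  std::vector<int> p;
  DSU(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int a) { while (p[a] != a) { p[a] = p[p[a]]; a = p[a]; } return a; }
  void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[std::max(a,b)] = std::min(a,b); }
};

// 6-connected components of a boolean mask; labels 1..k in raster order of
// each component's first voxel, 0 elsewhere.
// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dims) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const int n = Z * Y * X;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int z = v % Z, y = (v / Z) % Y, x = v / (Z * Y);
      const int dz[6] = {-1, 1, 0, 0, 0, 0};
      const int dy[6] = {0, 0, -1, 1, 0, 0};
      const int dx[6] = {0, 0, 0, 0, -1, 1};
      for (int k = 0; k < 6; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X) continue;
        int u = idx3(zz, yy, xx, Z, Y);
        if (mask[u] && lab[u] == 0) { lab[u] = next; stack.push_back(u); }
      }
    }
  }
  return lab;
}

// Components of the affinity graph restricted to edges with value >= thresh.
// aff is a (3, Z, Y, X)-shaped vector flattened R-style with channel fastest?
// No: we pass the three channels as separate vectors to keep the layout simple.
// Channel c at voxel v encodes the edge (v, v - e_c). Only voxels incident to
// at least one retained edge are labeled; the rest stay 0.
// [[Rcpp::export(name = ".cc_from_affinity")]]
IntegerVector cc_from_affinity(NumericVector az, NumericVector ay, NumericVector ax,
                               IntegerVector dims, double thresh) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const int n = Z * Y * X;
  DSU dsu(n);
  std::vector<char> touched(n, 0);
  for (int x = 0; x < X; ++x)
    for (int y = 0; y < Y; ++y)
      for (int z = 0; z < Z; ++z) {
        int v = idx3(z, y, x, Z, Y);
        if (z > 0 && az[v] >= thresh) { dsu.unite(v, idx3(z-1,y,x,Z,Y)); touched[v] = touched[idx3(z-1,y,x,Z,Y)] = 1; }
        if (y > 0 && ay[v] >= thresh) { dsu.unite(v, idx3(z,y-1,x,Z,Y)); touched[v] = touched[idx3(z,y-1,x,Z,Y)] = 1; }
        if (x > 0 && ax[v] >= thresh) { dsu.unite(v, idx3(z,y,x-1,Z,Y)); touched[v] = touched[idx3(z,y,x-1,Z,Y)] = 1; }
      }
  IntegerVector lab(n, 0);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    if (!touched[i]) continue;
    int r = dsu.find(i);
    if (remap[r] == 0) remap[r] = ++next;
    lab[i] = remap[r];
  }
  return lab;
}

struct EdgeEvent {
  double aff;
  int edge;   // global edge id, used for deterministic tie-breaks
};
struct EdgeCmp {
  bool operator()(const EdgeEvent& a, const EdgeEvent& b) const {
    if (a.aff != b.aff) return a.aff < b.aff;       // max-heap on affinity
    return a.edge > b.edge;                          // then min on edge id
  }
};

// zwatershed-style decoding of a 3-channel nearest-neighbour affinity map.
// Seeds: components over edges >= t_high. Growth: edges in decreasing
// affinity down to t_low. Fragments < min_size merge into the neighbour with
// the strongest connecting edge (ties: smaller label), or background if
// isolated. Finally fragment pairs with boundary mean affinity >=
// merge_threshold are merged greedily in decreasing order of that mean.
// [[Rcpp::export(name = ".zwatershed_cpp")]]
IntegerVector zwatershed_cpp(NumericVector az, NumericVector ay, NumericVector ax,
                             IntegerVector dims, double t_high, double t_low,
                             int min_size, double merge_threshold) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const int n = Z * Y * X;

  // edge tables: edge id = channel * n + voxel (voxel is the +side)
  auto edge_aff = [&](int e) -> double {
    int c = e / n, v = e % n;
    return c == 0 ? az[v] : (c == 1 ? ay[v] : ax[v]);
  };
  auto edge_ok = [&](int e) -> bool {
    int c = e / n, v = e % n;
    int z = v % Z, y = (v / Z) % Y, x = v / (Z * Y);
    return (c == 0 && z > 0) || (c == 1 && y > 0) || (c == 2 && x > 0);
  };
  auto edge_ends = [&](int e, int& u, int& v) {
    int c = e / n; v = e % n;
    int z = v % Z, y = (v / Z) % Y, x = v / (Z * Y);
    u = (c == 0) ? idx3(z-1,y,x,Z,Y) : (c == 1 ? idx3(z,y-1,x,Z,Y) : idx3(z,y,x-1,Z,Y));
  };

  // 1) seeds
  IntegerVector lab = cc_from_affinity(az, ay, ax, dims, t_high);
  std::vector<int> L(lab.begin(), lab.end());

  // 2) grow over edges >= t_low, decreasing affinity
  std::priority_queue<EdgeEvent, std::vector<EdgeEvent>, EdgeCmp> pq;
  auto push_edges_of = [&](int v) {
    int z = v % Z, y = (v / Z) % Y, x = v / (Z * Y);
    // edges where v is the +side
    for (int c = 0; c < 3; ++c) {
      int e = c * n + v;
      if (edge_ok(e) && edge_aff(e) >= t_low) pq.push({edge_aff(e), e});
    }
    // edges where v is the -side
    if (z + 1 < Z) { int e = 0 * n + idx3(z+1,y,x,Z,Y); if (edge_aff(e) >= t_low) pq.push({edge_aff(e), e}); }
    if (y + 1 < Y) { int e = 1 * n + idx3(z,y+1,x,Z,Y); if (edge_aff(e) >= t_low) pq.push({edge_aff(e), e}); }
    if (x + 1 < X) { int e = 2 * n + idx3(z,y,x+1,Z,Y); if (edge_aff(e) >= t_low) pq.push({edge_aff(e), e}); }
  };
  for (int v = 0; v < n; ++v) if (L[v] != 0) push_edges_of(v);
  while (!pq.empty()) {
    EdgeEvent ev = pq.top(); pq.pop();
    int u, v; edge_ends(ev.edge, u, v);
    int lu = L[u], lv = L[v];
    if ((lu != 0) == (lv != 0)) continue;   // both labeled or both empty
    int w = (lu == 0) ? u : v;
    L[w] = lu + lv;                          // the nonzero one
    push_edges_of(w);
  }

  // helper: relabel to consecutive ids by first-voxel raster order
  auto canonicalize = [&]() {
    std::vector<int> remap;
    remap.assign(n + 1, 0);
    int next = 0;
    for (int v = 0; v < n; ++v) {
      if (L[v] == 0) continue;
      if (remap[L[v]] == 0) remap[L[v]] = ++next;
    }
    for (int v = 0; v < n; ++v) L[v] = remap[L[v]];
    return next;
  };
  int k = canonicalize();
  if (k == 0) return IntegerVector(n, 0);

  // 3) size filter: merge fragments < min_size into strongest-edge neighbour
  {
    bool changed = true;
    while (changed) {
      changed = false;
      std::vector<int> size(k + 1, 0);
      for (int v = 0; v < n; ++v) if (L[v]) size[L[v]]++;
      // strongest connecting edge per (small fragment -> neighbour)
      std::vector<double> best(k + 1, -1.0);
      std::vector<int> bestnb(k + 1, 0);
      for (int e = 0; e < 3 * n; ++e) {
        if (!edge_ok(e)) continue;
        int u, v; edge_ends(e, u, v);
        int lu = L[u], lv = L[v];
        if (lu == 0 || lv == 0 || lu == lv) continue;
        double a = edge_aff(e);
        if (size[lu] < min_size) {
          if (a > best[lu] || (a == best[lu] && lv < bestnb[lu])) { best[lu] = a; bestnb[lu] = lv; }
        }
        if (size[lv] < min_size) {
          if (a > best[lv] || (a == best[lv] && lu < bestnb[lv])) { best[lv] = a; bestnb[lv] = lu; }
        }
      }
      // union-find so that mutually-pointing small fragments merge cleanly
      DSU dsu(k + 1);
      std::vector<char> dropf(k + 1, 0);
      for (int f = 1; f <= k; ++f) {
        if (size[f] >= min_size) continue;
        if (best[f] > 0.0) { dsu.unite(f, bestnb[f]); changed = true; }
        else { dropf[f] = 1; changed = true; }   // isolated -> background
      }
      if (changed) {
        for (int v = 0; v < n; ++v) {
          if (!L[v]) continue;
          L[v] = dropf[L[v]] ? 0 : dsu.find(L[v]);
        }
        k = canonicalize();
        if (k == 0) return IntegerVector(n, 0);
      }
    }
  }

  // 4) greedy agglomeration on boundary mean affinity. Each pass computes
  // the region-pair boundary means once, sorts pairs by decreasing mean and
  // merges through a union-find; passes repeat until stable. Deterministic:
  // ties sort by the (smaller, larger) label pair.
  {
    bool merged = true;
    while (merged) {
      merged = false;
      std::map<std::pair<int,int>, std::pair<double,int>> stats;  // (sum, count)
      for (int e = 0; e < 3 * n; ++e) {
        if (!edge_ok(e)) continue;
        int u, v; edge_ends(e, u, v);
        int lu = L[u], lv = L[v];
        if (lu == 0 || lv == 0 || lu == lv) continue;
        auto key = std::make_pair(std::min(lu, lv), std::max(lu, lv));
        auto& s = stats[key];
        s.first += edge_aff(e); s.second += 1;
      }
      struct PairMean { double mean; int a, b; };
      std::vector<PairMean> pm;
      pm.reserve(stats.size());
      for (auto& kv : stats) {
        double m = kv.second.first / kv.second.second;
        if (m >= merge_threshold)
          pm.push_back({m, kv.first.first, kv.first.second});
      }
      if (!pm.empty()) {
        std::sort(pm.begin(), pm.end(), [](const PairMean& x, const PairMean& y) {
          if (x.mean != y.mean) return x.mean > y.mean;
          if (x.a != y.a) return x.a < y.a;
          return x.b < y.b;
        });
        DSU dsu(k + 1);
        for (auto& p : pm) dsu.unite(p.a, p.b);
        for (int v = 0; v < n; ++v) if (L[v]) L[v] = dsu.find(L[v]);
        merged = true;
        k = canonicalize();
      }
    }
    canonicalize();
  }

  return IntegerVector(L.begin(), L.end());
}

struct VoxEvent {
  double h;
  int vox;
};
struct VoxCmp {
  bool operator()(const VoxEvent& a, const VoxEvent& b) const {
    if (a.h != b.h) return a.h > b.h;   // min-heap on height
    return a.vox > b.vox;               // then min on voxel index
  }
};

// Seeded watershed on a height map, restricted to mask. Markers are grown in
// increasing height; ties broken by raster order. Unreached mask voxels keep 0.
// [[Rcpp::export(name = ".seeded_watershed_cpp")]]
IntegerVector seeded_watershed_cpp(NumericVector height, IntegerVector markers,
                                   LogicalVector mask, IntegerVector dims) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const int n = Z * Y * X;
  std::vector<int> L(markers.begin(), markers.end());
  std::priority_queue<VoxEvent, std::vector<VoxEvent>, VoxCmp> pq;
  std::vector<char> inq(n, 0);
  const int dz[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, -1, 1};
  auto push_nbrs = [&](int v) {
    int z = v % Z, y = (v / Z) % Y, x = v / (Z * Y);
    for (int kk = 0; kk < 6; ++kk) {
      int zz = z + dz[kk], yy = y + dy[kk], xx = x + dx[kk];
      if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X) continue;
      int u = idx3(zz, yy, xx, Z, Y);
      if (mask[u] && L[u] == 0 && !inq[u]) { pq.push({height[u], u}); inq[u] = 1; }
    }
  };
  for (int v = 0; v < n; ++v) if (L[v] != 0 && mask[v]) push_nbrs(v);
  while (!pq.empty()) {
    VoxEvent ev = pq.top(); pq.pop();
    int v = ev.vox;
    if (L[v] != 0) continue;
    // claim by the labeled neighbour reached first; deterministic: smallest label
    int z = v % Z, y = (v / Z) % Y, x = v / (Z * Y);
    int claim = 0;
    for (int kk = 0; kk < 6; ++kk) {
      int zz = z + dz[kk], yy = y + dy[kk], xx = x + dx[kk];
      if (zz < 0 || zz >= Z || yy < 0 || yy >= Y || xx < 0 || xx >= X) continue;
      int u = idx3(zz, yy, xx, Z, Y);
      if (L[u] != 0 && (claim == 0 || L[u] < claim)) claim = L[u];
    }
    if (claim == 0) continue;
    L[v] = claim;
    push_nbrs(v);
  }
  return IntegerVector(L.begin(), L.end());
}

// Separable squared EDT (Felzenszwalb & Huttenlocher) with anisotropic
// spacing. Input: mask (1 = foreground). Output: squared Euclidean distance
// from each voxel to the nearest background voxel (in spacing units);
// foreground with no background anywhere gets a large finite value.
static void edt1d(std::vector<double>& f, std::vector<double>& d, double w2) {
  const int m = (int)f.size();
  std::vector<int> v(m);
  std::vector<double> zz(m + 1);
  int kk = 0;
  v[0] = 0; zz[0] = -std::numeric_limits<double>::infinity();
  zz[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < m; ++q) {
    double s;
    while (true) {
      int p = v[kk];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= zz[kk]) { --kk; } else break;
    }
    ++kk; v[kk] = q; zz[kk] = s; zz[kk + 1] = std::numeric_limits<double>::infinity();
  }
  kk = 0;
  for (int q = 0; q < m; ++q) {
    while (zz[kk + 1] < q) ++kk;
    int p = v[kk];
    d[q] = w2 * (q - p) * (q - p) + f[p];
  }
}

// [[Rcpp::export(name = ".edt_sq_3d")]]
NumericVector edt_sq_3d(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int Z = dims[0], Y = dims[1], X = dims[2];
  const int n = Z * Y * X;
  const double BIG = 1e12;
  NumericVector D(n);
  for (int i = 0; i < n; ++i) D[i] = mask[i] ? BIG : 0.0;
  // pass along z, then y, then x
  std::vector<double> f, d;
  // z
  f.resize(Z); d.resize(Z);
  double w2 = spacing[0] * spacing[0];
  for (int x = 0; x < X; ++x) for (int y = 0; y < Y; ++y) {
    for (int z = 0; z < Z; ++z) f[z] = D[idx3(z,y,x,Z,Y)];
    edt1d(f, d, w2);
    for (int z = 0; z < Z; ++z) D[idx3(z,y,x,Z,Y)] = std::min(d[z], BIG);
  }
  // y
  f.resize(Y); d.resize(Y);
  w2 = spacing[1] * spacing[1];
  for (int x = 0; x < X; ++x) for (int z = 0; z < Z; ++z) {
    for (int y = 0; y < Y; ++y) f[y] = D[idx3(z,y,x,Z,Y)];
    edt1d(f, d, w2);
    for (int y = 0; y < Y; ++y) D[idx3(z,y,x,Z,Y)] = std::min(d[y], BIG);
  }
  // x
  f.resize(X); d.resize(X);
  w2 = spacing[2] * spacing[2];
  for (int y = 0; y < Y; ++y) for (int z = 0; z < Z; ++z) {
    for (int x = 0; x < X; ++x) f[x] = D[idx3(z,y,x,Z,Y)];
    edt1d(f, d, w2);
    for (int x = 0; x < X; ++x) D[idx3(z,y,x,Z,Y)] = std::min(d[x], BIG);
  }
  return D;
}

// 1x3x3 convolution (xy only, zero padding) on a column-major (Z,H,W,C)
// array; the z axis is untouched. W layout matches an R array of dim
// (3, 3, Cin, Cout); out[v, co] = sum_{dy,dx,ci} X[., y+dy, x+dx, ci] * W.
// [[Rcpp::export(name = ".conv3x3_fwd_cpp")]]
NumericVector conv3x3_fwd_cpp(NumericVector X, IntegerVector dims,
                              NumericVector W, NumericVector b, int Cout) {
  const int Z = dims[0], H = dims[1], Wd = dims[2], Cin = dims[3];
  const int plane = Z * H;
  const int vol = plane * Wd;
  NumericVector Y((R_xlen_t)vol * Cout);
  for (int co = 0; co < Cout; ++co) {
    double* y = &Y[(R_xlen_t)vol * co];
    for (int v = 0; v < vol; ++v) y[v] = b[co];
    for (int ci = 0; ci < Cin; ++ci) {
      const double* x0 = &X[(R_xlen_t)vol * ci];
      for (int j = 0; j < 3; ++j) {        // dx = j - 1
        int dx = j - 1;
        for (int i = 0; i < 3; ++i) {      // dy = i - 1
          int dy = i - 1;
          double w = W[i + 3 * (j + 3 * (ci + Cin * co))];
          if (w == 0.0) continue;
          int ylo = std::max(0, -dy), yhi = std::min(H, H - dy);
          int xlo = std::max(0, -dx), xhi = std::min(Wd, Wd - dx);
          for (int xx = xlo; xx < xhi; ++xx) {
            const double* src = x0 + (R_xlen_t)plane * (xx + dx) + Z * dy;
            double* dst = y + (R_xlen_t)plane * xx;
            for (int yy = ylo; yy < yhi; ++yy)
              for (int zz = 0; zz < Z; ++zz)
                dst[zz + Z * yy] += w * src[zz + Z * yy];
          }
        }
      }
    }
  }
  return Y;
}

// [[Rcpp::export(name = ".conv3x3_bwd_cpp")]]
List conv3x3_bwd_cpp(NumericVector dY, NumericVector X, IntegerVector dims,
                     NumericVector W, int Cout) {
  const int Z = dims[0], H = dims[1], Wd = dims[2], Cin = dims[3];
  const int plane = Z * H;
  const int vol = plane * Wd;
  NumericVector dX((R_xlen_t)vol * Cin);
  NumericVector dW(9 * (R_xlen_t)Cin * Cout);
  NumericVector db(Cout);
  for (int co = 0; co < Cout; ++co) {
    const double* dy0 = &dY[(R_xlen_t)vol * co];
    double s = 0;
    for (int v = 0; v < vol; ++v) s += dy0[v];
    db[co] = s;
    for (int ci = 0; ci < Cin; ++ci) {
      const double* x0 = &X[(R_xlen_t)vol * ci];
      double* dx0 = &dX[(R_xlen_t)vol * ci];
      for (int j = 0; j < 3; ++j) {
        int dx = j - 1;
        for (int i = 0; i < 3; ++i) {
          int dy = i - 1;
          double w = W[i + 3 * (j + 3 * (ci + Cin * co))];
          double grad = 0;
          int ylo = std::max(0, -dy), yhi = std::min(H, H - dy);
          int xlo = std::max(0, -dx), xhi = std::min(Wd, Wd - dx);
          for (int xx = xlo; xx < xhi; ++xx) {
            const double* src = x0 + (R_xlen_t)plane * (xx + dx) + Z * dy;
            double* dsrc = dx0 + (R_xlen_t)plane * (xx + dx) + Z * dy;
            const double* dyp = dy0 + (R_xlen_t)plane * xx;
            for (int yy = ylo; yy < yhi; ++yy)
              for (int zz = 0; zz < Z; ++zz) {
                int k = zz + Z * yy;
                grad += src[k] * dyp[k];
                dsrc[k] += w * dyp[k];
              }
          }
          dW[i + 3 * (j + 3 * (ci + Cin * co))] = grad;
        }
      }
    }
  }
  return List::create(_["dX"] = dX, _["dW"] = dW, _["db"] = db);
}
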