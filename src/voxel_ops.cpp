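#include <Rcpp.h>
#include <queue>
#include <vector>
#include <map>
#include <cmath>
#include <climits>
#include <limits>
using namespace Rcpp;

// Voxel grids are R arrays in column-major order: idx = x + nx*(y + ny*z),
// 0-based here. Lexicographic order on (x,y,z) is used for all tie-breaks.

static inline void idx2xyz(int idx, const int *d, int &x, int &y, int &z) {
  x = idx % d[0];
  y = (idx / d[0]) % d[1];
  z = idx / (d[0] * d[1]);
}

static inline int xyz2idx(int x, int y, int z, const int *d) {
  return x + d[0] * (y + d[1] * z);
}

// lexicographic (x,y,z) comparison of two linear indices
static inline bool lex_less(int a, int b, const int *d) {
  int ax, ay, az, bx, by, bz;
  idx2xyz(a, d, ax, ay, az);
  idx2xyz(b, d, bx, by, bz);
  if (ax != bx) return ax < bx;
  if (ay != by) return ay < by;
  return az < bz;
}

struct NbOffsets {
  int n;
  int dx[26], dy[26], dz[26];
  NbOffsets(int connectivity) {
    n = 0;
    for (int cz = -1; cz <= 1; cz++)
      for (int cy = -1; cy <= 1; cy++)
        for (int cx = -1; cx <= 1; cx++) {
          if (cx == 0 && cy == 0 && cz == 0) continue;
          int s = std::abs(cx) + std::abs(cy) + std::abs(cz);
          if (connectivity == 6 && s > 1) continue;
          if (connectivity == 18 && s > 2) continue;
          dx[n] = cx; dy[n] = cy; dz[n] = cz; n++;
        }
  }
};

// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerVector cc_label_cpp(LogicalVector mask, IntegerVector dims,
                           int connectivity) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const int n = d[0] * d[1] * d[2];
  NbOffsets nb(connectivity);
  IntegerVector labels(n, 0);
  int cur = 0;
  std::vector<int> stack;
  for (int i = 0; i < n; i++) {
    if (!mask[i] || labels[i] != 0) continue;
    cur++;
    labels[i] = cur;
    stack.push_back(i);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int x, y, z; idx2xyz(v, d, x, y, z);
      for (int k = 0; k < nb.n; k++) {
        int xx = x + nb.dx[k], yy = y + nb.dy[k], zz = z + nb.dz[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= d[0] || yy >= d[1] || zz >= d[2])
          continue;
        int u = xyz2idx(xx, yy, zz, d);
        if (mask[u] && labels[u] == 0) { labels[u] = cur; stack.push_back(u); }
      }
    }
  }
  return labels;
}

// 1D squared distance transform (Felzenszwalb & Huttenlocher), grid step w
static void dt1d(const double *f, double *out, int n, double w) {
  std::vector<int> v(n);
  std::vector<double> zbd(n + 1);
  int k = 0;
  v[0] = 0;
  zbd[0] = -std::numeric_limits<double>::infinity();
  zbd[1] = std::numeric_limits<double>::infinity();
  const double w2 = w * w;
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s > zbd[k]) break;
      k--;
    }
    k++;
    v[k] = q;
    zbd[k] = s;
    zbd[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (zbd[k + 1] < q) k++;
    double dq = w * (q - v[k]);
    out[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (mm) from each foreground voxel to the nearest
// background voxel centre; 0 on background.
// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const int n = d[0] * d[1] * d[2];
  const double INF = 1e30;
  std::vector<double> g(n);
  for (int i = 0; i < n; i++) g[i] = mask[i] ? INF : 0.0;

  // pass along x
  {
    std::vector<double> f(d[0]), o(d[0]);
    for (int z = 0; z < d[2]; z++)
      for (int y = 0; y < d[1]; y++) {
        for (int x = 0; x < d[0]; x++) f[x] = g[xyz2idx(x, y, z, d)];
        dt1d(f.data(), o.data(), d[0], spacing[0]);
        for (int x = 0; x < d[0]; x++) g[xyz2idx(x, y, z, d)] = o[x];
      }
  }
  // pass along y
  {
    std::vector<double> f(d[1]), o(d[1]);
    for (int z = 0; z < d[2]; z++)
      for (int x = 0; x < d[0]; x++) {
        for (int y = 0; y < d[1]; y++) f[y] = g[xyz2idx(x, y, z, d)];
        dt1d(f.data(), o.data(), d[1], spacing[1]);
        for (int y = 0; y < d[1]; y++) g[xyz2idx(x, y, z, d)] = o[y];
      }
  }
  // pass along z
  {
    std::vector<double> f(d[2]), o(d[2]);
    for (int y = 0; y < d[1]; y++)
      for (int x = 0; x < d[0]; x++) {
        for (int z = 0; z < d[2]; z++) f[z] = g[xyz2idx(x, y, z, d)];
        dt1d(f.data(), o.data(), d[2], spacing[2]);
        for (int z = 0; z < d[2]; z++) g[xyz2idx(x, y, z, d)] = o[z];
      }
  }
  NumericVector out(n);
  for (int i = 0; i < n; i++) out[i] = std::sqrt(g[i]);
  return out;
}

// Dijkstra within the mask, 26-neighbour steps weighted by physical step
// length. Returns distance in mm; -1 outside the mask or unreachable.
// [[Rcpp::export(name = ".geodesic_cpp")]]
NumericVector geodesic_cpp(LogicalVector mask, IntegerVector dims,
                           NumericVector spacing, int root0) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const int n = d[0] * d[1] * d[2];
  NbOffsets nb(26);
  double step[26];
  for (int k = 0; k < nb.n; k++)
    step[k] = std::sqrt(nb.dx[k] * nb.dx[k] * spacing[0] * spacing[0] +
                        nb.dy[k] * nb.dy[k] * spacing[1] * spacing[1] +
                        nb.dz[k] * nb.dz[k] * spacing[2] * spacing[2]);
  std::vector<double> dist(n, -1.0);
  typedef std::pair<double, int> P;
  std::priority_queue<P, std::vector<P>, std::greater<P> > pq;
  if (!mask[root0]) stop("root voxel is not inside the mask");
  dist[root0] = 0.0;
  pq.push(P(0.0, root0));
  while (!pq.empty()) {
    P top = pq.top(); pq.pop();
    int v = top.second;
    if (top.first > dist[v] + 1e-12) continue;
    int x, y, z; idx2xyz(v, d, x, y, z);
    for (int k = 0; k < nb.n; k++) {
      int xx = x + nb.dx[k], yy = y + nb.dy[k], zz = z + nb.dz[k];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= d[0] || yy >= d[1] || zz >= d[2])
        continue;
      int u = xyz2idx(xx, yy, zz, d);
      if (!mask[u]) continue;
      double nd = top.first + step[k];
      if (dist[u] < 0 || nd < dist[u] - 1e-12) {
        dist[u] = nd;
        pq.push(P(nd, u));
      }
    }
  }
  return wrap(dist);
}

// Truncated Dijkstra ball around v; returns true if some voxel within
// geodesic radius 'rad' has strictly larger gdist (or equal gdist but
// lexicographically smaller coordinates) — i.e. v is NOT the farthest
// point of its own neighbourhood and must be suppressed.
static bool suppressed_by_ball(int v, const LogicalVector &mask, const int *d,
                               const double *step, const NbOffsets &nb,
                               const NumericVector &gdist, double rad) {
  typedef std::pair<double, int> P;
  std::priority_queue<P, std::vector<P>, std::greater<P> > pq;
  std::map<int, double> dist;
  dist[v] = 0.0;
  pq.push(P(0.0, v));
  const double dv = gdist[v];
  while (!pq.empty()) {
    P top = pq.top(); pq.pop();
    int u = top.second;
    std::map<int, double>::iterator it = dist.find(u);
    if (it != dist.end() && top.first > it->second + 1e-12) continue;
    if (u != v) {
      if (gdist[u] > dv + 1e-9) return true;
      if (std::fabs(gdist[u] - dv) <= 1e-9 && lex_less(u, v, d)) return true;
    }
    int x, y, z; idx2xyz(u, d, x, y, z);
    for (int k = 0; k < nb.n; k++) {
      int xx = x + nb.dx[k], yy = y + nb.dy[k], zz = z + nb.dz[k];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= d[0] || yy >= d[1] || zz >= d[2])
        continue;
      int w = xyz2idx(xx, yy, zz, d);
      if (!mask[w]) continue;
      double ndw = top.first + step[k];
      if (ndw > rad) continue;
      std::map<int, double>::iterator jt = dist.find(w);
      if (jt == dist.end() || ndw < jt->second - 1e-12) {
        dist[w] = ndw;
        pq.push(P(ndw, w));
      }
    }
  }
  return false;
}

// Tip detection: local maxima of geodesic distance from the root that are
// the farthest voxel within their own geodesic ball of radius min_sep_mm.
// Voxels with gdist <= root_excl_mm (the root's own blob) are excluded.
// [[Rcpp::export(name = ".detect_endpoints_cpp")]]
IntegerVector detect_endpoints_cpp(LogicalVector mask, IntegerVector dims,
                                   NumericVector spacing, NumericVector gdist,
                                   double min_sep_mm, double root_excl_mm) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const int n = d[0] * d[1] * d[2];
  NbOffsets nb(26);
  double step[26];
  for (int k = 0; k < nb.n; k++)
    step[k] = std::sqrt(nb.dx[k] * nb.dx[k] * spacing[0] * spacing[0] +
                        nb.dy[k] * nb.dy[k] * spacing[1] * spacing[1] +
                        nb.dz[k] * nb.dz[k] * spacing[2] * spacing[2]);
  std::vector<int> out;
  for (int v = 0; v < n; v++) {
    if (!mask[v] || gdist[v] < 0) continue;
    if (gdist[v] <= root_excl_mm) continue;
    // cheap pre-filter: 26-neighbour local maximum
    int x, y, z; idx2xyz(v, d, x, y, z);
    bool ismax = true;
    for (int k = 0; k < nb.n && ismax; k++) {
      int xx = x + nb.dx[k], yy = y + nb.dy[k], zz = z + nb.dz[k];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= d[0] || yy >= d[1] || zz >= d[2])
        continue;
      int u = xyz2idx(xx, yy, zz, d);
      if (mask[u] && gdist[u] > gdist[v] + 1e-9) ismax = false;
    }
    if (!ismax) continue;
    if (!suppressed_by_ball(v, mask, d, step, nb, gdist, min_sep_mm))
      out.push_back(v);
  }
  return wrap(out);
}

// A present voxel is "simple" (removal preserves digital topology for
// 26-connected foreground / 6-connected background) when (a) its present
// 26-neighbours form exactly one 26-connected component within the 3x3x3
// neighbourhood, and (b) the background cells of its 18-neighbourhood that
// are 6-adjacent to it form exactly one 6-connected component within that
// neighbourhood (Malandain-Bertrand characterization). Condition (a) stops
// disconnections; (b) stops tunnels from opening through junctions.
static bool simple_point(const std::vector<char> &present, int v, const int *d) {
  int x, y, z; idx2xyz(v, d, x, y, z);
  // collect present neighbours as offsets in {-1,0,1}^3 \ {0}
  bool nbf[27];
  int cnt = 0;
  for (int cz = -1; cz <= 1; cz++)
    for (int cy = -1; cy <= 1; cy++)
      for (int cx = -1; cx <= 1; cx++) {
        int code = (cx + 1) + 3 * (cy + 1) + 9 * (cz + 1);
        nbf[code] = false;
        if (cx == 0 && cy == 0 && cz == 0) continue;
        int xx = x + cx, yy = y + cy, zz = z + cz;
        if (xx < 0 || yy < 0 || zz < 0 || xx >= d[0] || yy >= d[1] || zz >= d[2])
          continue;
        if (present[xyz2idx(xx, yy, zz, d)]) { nbf[code] = true; cnt++; }
      }
  if (cnt == 0) return false;
  // (a) foreground: flood fill over neighbour offsets (26-adjacency)
  int start = -1;
  for (int c = 0; c < 27; c++) if (nbf[c]) { start = c; break; }
  bool seen[27] = {false};
  std::vector<int> stack;
  stack.push_back(start);
  seen[start] = true;
  int reached = 1;
  while (!stack.empty()) {
    int c = stack.back(); stack.pop_back();
    int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
    for (int dz2 = -1; dz2 <= 1; dz2++)
      for (int dy2 = -1; dy2 <= 1; dy2++)
        for (int dx2 = -1; dx2 <= 1; dx2++) {
          int ex = cx + dx2, ey = cy + dy2, ez = cz + dz2;
          if (ex < -1 || ex > 1 || ey < -1 || ey > 1 || ez < -1 || ez > 1)
            continue;
          int e = (ex + 1) + 3 * (ey + 1) + 9 * (ez + 1);
          if (nbf[e] && !seen[e]) { seen[e] = true; reached++; stack.push_back(e); }
        }
  }
  if (reached != cnt) return false;
  // (b) background: 6-connectivity among the 18-neighbourhood background
  // cells (out-of-grid counts as background), seeded from the 6-adjacent
  // ones; every 6-adjacent background cell must be reachable
  bool bg18[27];
  int bgAdj = 0;
  for (int c = 0; c < 27; c++) {
    bg18[c] = false;
    int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
    int s = std::abs(cx) + std::abs(cy) + std::abs(cz);
    if (s == 0 || s == 3) continue;        // centre and corners excluded
    if (!nbf[c]) { bg18[c] = true; if (s == 1) bgAdj++; }
  }
  if (bgAdj == 0) return false;            // interior voxel: not simple
  int bstart = -1;
  for (int c = 0; c < 27; c++) {
    int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
    if (bg18[c] && std::abs(cx) + std::abs(cy) + std::abs(cz) == 1) {
      bstart = c; break;
    }
  }
  bool bseen[27] = {false};
  stack.clear();
  stack.push_back(bstart);
  bseen[bstart] = true;
  int breachedAdj = 1;
  while (!stack.empty()) {
    int c = stack.back(); stack.pop_back();
    int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
    const int f6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
    for (int k = 0; k < 6; k++) {
      int ex = cx + f6[k][0], ey = cy + f6[k][1], ez = cz + f6[k][2];
      if (ex < -1 || ex > 1 || ey < -1 || ey > 1 || ez < -1 || ez > 1)
        continue;
      int e = (ex + 1) + 3 * (ey + 1) + 9 * (ez + 1);
      if (bg18[e] && !bseen[e]) {
        bseen[e] = true;
        if (std::abs(ex) + std::abs(ey) + std::abs(ez) == 1) breachedAdj++;
        stack.push_back(e);
      }
    }
  }
  return breachedAdj == bgAdj;
}

// Erosion skeletonization: peel removable voxels in increasing priority
// (distance-transform value), lexicographic tie-break; protected endpoint
// voxels are never removed. Returns the surviving voxel set.
// [[Rcpp::export(name = ".skeletonize_cpp")]]
LogicalVector skeletonize_cpp(LogicalVector mask, IntegerVector dims,
                              NumericVector priority, IntegerVector endpoints0) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const int n = d[0] * d[1] * d[2];
  NbOffsets nb(26);
  std::vector<char> present(n, 0), protect(n, 0);
  for (int i = 0; i < n; i++) present[i] = mask[i] ? 1 : 0;
  for (int k = 0; k < endpoints0.size(); k++) protect[endpoints0[k]] = 1;

  // order keys: (priority, x, y, z) ascending
  struct QE { double p; int x, y, z, idx; };
  struct Cmp {
    bool operator()(const QE &a, const QE &b) const {
      if (a.p != b.p) return a.p > b.p;
      if (a.x != b.x) return a.x > b.x;
      if (a.y != b.y) return a.y > b.y;
      return a.z > b.z;
    }
  };
  std::priority_queue<QE, std::vector<QE>, Cmp> pq;
  for (int i = 0; i < n; i++) {
    if (!present[i] || protect[i]) continue;
    QE e; e.p = priority[i]; idx2xyz(i, d, e.x, e.y, e.z); e.idx = i;
    pq.push(e);
  }
  while (!pq.empty()) {
    QE e = pq.top(); pq.pop();
    int v = e.idx;
    if (!present[v] || protect[v]) continue;
    if (!simple_point(present, v, d)) continue;
    present[v] = 0;
    int x, y, z; idx2xyz(v, d, x, y, z);
    for (int k = 0; k < nb.n; k++) {
      int xx = x + nb.dx[k], yy = y + nb.dy[k], zz = z + nb.dz[k];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= d[0] || yy >= d[1] || zz >= d[2])
        continue;
      int u = xyz2idx(xx, yy, zz, d);
      if (present[u] && !protect[u]) {
        QE f; f.p = priority[u]; f.x = xx; f.y = yy; f.z = zz; f.idx = u;
        pq.push(f);
      }
    }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; i++) out[i] = present[i] != 0;
  return out;
}

// Count present 26-neighbours of every voxel of a voxel set.
// [[Rcpp::export(name = ".count_neighbors_cpp")]]
IntegerVector count_neighbors_cpp(LogicalVector mask, IntegerVector dims) {
  const int d[3] = {dims[0], dims[1], dims[2]};
  const int n = d[0] * d[1] * d[2];
  NbOffsets nb(26);
  IntegerVector out(n, 0);
  for (int v = 0; v < n; v++) {
    if (!mask[v]) continue;
    int x, y, z; idx2xyz(v, d, x, y, z);
    int c = 0;
    for (int k = 0; k < nb.n; k++) {
      int xx = x + nb.dx[k], yy = y + nb.dy[k], zz = z + nb.dz[k];
      if (xx < 0 || yy < 0 || zz < 0 || xx >= d[0] || yy >= d[1] || zz >= d[2])
        continue;
      if (mask[xyz2idx(xx, yy, zz, d)]) c++;
    }
    out[v] = c;
  }
  return out;
}

// Nearest centreline voxel (physical Euclidean distance) for every mask
// voxel; ties go to the lower segment id, then lower skeleton row index.
// maskVox, skelVox: 0-based voxel coordinates (n x 3, m x 3).
// [[Rcpp::export(name = ".assign_nearest_cpp")]]
List assign_nearest_cpp(IntegerMatrix maskVox, IntegerMatrix skelVox,
                        IntegerVector skelSeg, NumericVector spacing) {
  const int n = maskVox.nrow(), m = skelVox.nrow();
  IntegerVector seg(n);
  NumericVector dmm(n);
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  std::vector<double> px(m), py(m), pz(m);
  for (int j = 0; j < m; j++) {
    px[j] = skelVox(j, 0) * sx;
    py[j] = skelVox(j, 1) * sy;
    pz[j] = skelVox(j, 2) * sz;
  }
  for (int i = 0; i < n; i++) {
    double qx = maskVox(i, 0) * sx, qy = maskVox(i, 1) * sy,
           qz = maskVox(i, 2) * sz;
    double best = std::numeric_limits<double>::infinity();
    int bseg = INT_MAX;
    for (int j = 0; j < m; j++) {
      double ddx = qx - px[j], ddy = qy - py[j], ddz = qz - pz[j];
      double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (d2 < best - 1e-12 ||
          (std::fabs(d2 - best) <= 1e-12 && skelSeg[j] < bseg)) {
        best = d2;
        bseg = skelSeg[j];
      }
    }
    seg[i] = bseg;
    dmm[i] = std::sqrt(best);
  }
  return List::create(_["segment"] = seg, _["dist_mm"] = dmm);
}
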