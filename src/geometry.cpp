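#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Linear index convention matches R arrays: idx = i + nx*(j + ny*k), zero-based.

// [[Rcpp::export]]
IntegerVector cc_label_26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int current = 0;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++current;
    stack.clear();
    stack.push_back(s);
    lab[s] = current;
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int k = (int)(v / ((R_xlen_t)nx * ny));
      int rem = (int)(v - (R_xlen_t)k * nx * ny);
      int j = rem / nx, i = rem % nx;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            R_xlen_t w = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (mask[w] && lab[w] == 0) {
              lab[w] = current;
              stack.push_back(w);
            }
          }
    }
  }
  return lab;
}

// Even-odd point-in-polygon test on a grid of pixel centers (one polygon).
// [[Rcpp::export]]
LogicalMatrix pip_grid(NumericVector px, NumericVector py,
                       NumericVector xc, NumericVector yc) {
  const int ne = px.size();
  const int nx = xc.size(), ny = yc.size();
  LogicalMatrix out(nx, ny);
  for (int j = 0; j < ny; ++j) {
    double y = yc[j];
    for (int i = 0; i < nx; ++i) {
      double x = xc[i];
      bool inside = false;
      for (int e = 0; e < ne; ++e) {
        int f = (e + 1) % ne;
        double y1 = py[e], y2 = py[f];
        if ((y1 > y) != (y2 > y)) {
          double xint = px[e] + (y - y1) / (y2 - y1) * (px[f] - px[e]);
          if (x < xint) inside = !inside;
        }
      }
      out(i, j) = inside;
    }
  }
  return out;
}

// Morphological erosion by an arbitrary offset set (voxels outside the array
// count as background).
// [[Rcpp::export]]
LogicalVector erode_offsets(LogicalVector mask, IntegerVector dims,
                            IntegerMatrix offsets) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int no = offsets.nrow();
  LogicalVector out(n, false);
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s]) continue;
    int k = (int)(s / ((R_xlen_t)nx * ny));
    int rem = (int)(s - (R_xlen_t)k * nx * ny);
    int j = rem / nx, i = rem % nx;
    bool keep = true;
    for (int o = 0; o < no && keep; ++o) {
      int ii = i + offsets(o, 0), jj = j + offsets(o, 1), kk = k + offsets(o, 2);
      if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz) {
        keep = false;
      } else if (!mask[ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk)]) {
        keep = false;
      }
    }
    if (keep) out[s] = true;
  }
  return out;
}

// Marching tetrahedra on a scalar grid (values at voxel centers, treated as
// grid nodes). Cells are split into the six Kuhn tetrahedra sharing the main
// diagonal, which makes face diagonals agree between neighbouring cells and
// the extracted surface watertight. Triangles are oriented outward
// (inside = value >= iso).
struct MTState {
  std::unordered_map<long long, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

static int mt_edge_vertex(MTState &st, long long gA, long long gB,
                          double vA, double vB,
                          const double pA[3], const double pB[3], double iso) {
  long long a = gA, b = gB;
  const double *qa = pA, *qb = pB;
  double va = vA, vb = vB;
  if (a > b) {
    std::swap(a, b);
    std::swap(va, vb);
    const double *t = qa; qa = qb; qb = t;
  }
  long long key = a * 2000000011LL + b;
  auto it = st.edge_vertex.find(key);
  if (it != st.edge_vertex.end()) return it->second;
  double t = (iso - va) / (vb - va);
  if (t < 1e-6) t = 1e-6;
  if (t > 1.0 - 1e-6) t = 1.0 - 1e-6;
  st.vx.push_back(qa[0] + t * (qb[0] - qa[0]));
  st.vy.push_back(qa[1] + t * (qb[1] - qa[1]));
  st.vz.push_back(qa[2] + t * (qb[2] - qa[2]));
  int id = (int)st.vx.size() - 1;
  st.edge_vertex[key] = id;
  return id;
}

static void mt_emit(MTState &st, int a, int b, int c,
                    const double inC[3], const double outC[3]) {
  // orient so the normal points from inside toward outside
  double ux = st.vx[b] - st.vx[a], uy = st.vy[b] - st.vy[a], uz = st.vz[b] - st.vz[a];
  double wx = st.vx[c] - st.vx[a], wy = st.vy[c] - st.vy[a], wz = st.vz[c] - st.vz[a];
  double nxv = uy * wz - uz * wy, nyv = uz * wx - ux * wz, nzv = ux * wy - uy * wx;
  double dx = outC[0] - inC[0], dy = outC[1] - inC[1], dz = outC[2] - inC[2];
  if (nxv * dx + nyv * dy + nzv * dz < 0) std::swap(b, c);
  st.f0.push_back(a); st.f1.push_back(b); st.f2.push_back(c);
}

// [[Rcpp::export]]
List marching_tetra(NumericVector vol, IntegerVector dims, double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};
  MTState st;
  double P[8][3];
  double V[8];
  long long G[8];
  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + (c & 1), cj = j + ((c >> 1) & 1), ck = k + ((c >> 2) & 1);
          G[c] = ci + (long long)nx * (cj + (long long)ny * ck);
          V[c] = vol[G[c]];
          P[c][0] = ci; P[c][1] = cj; P[c][2] = ck;
          if (V[c] >= iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        for (int t = 0; t < 6; ++t) {
          int id[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int in_idx[4], out_idx[4], nin = 0, nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (V[id[c]] >= iso) in_idx[nin++] = id[c];
            else out_idx[nout++] = id[c];
          }
          if (nin == 0 || nin == 4) continue;
          double inC[3] = {0, 0, 0}, outC[3] = {0, 0, 0};
          for (int c = 0; c < nin; ++c)
            for (int d = 0; d < 3; ++d) inC[d] += P[in_idx[c]][d] / nin;
          for (int c = 0; c < nout; ++c)
            for (int d = 0; d < 3; ++d) outC[d] += P[out_idx[c]][d] / nout;
          if (nin == 1) {
            int A = in_idx[0];
            int e0 = mt_edge_vertex(st, G[A], G[out_idx[0]], V[A], V[out_idx[0]], P[A], P[out_idx[0]], iso);
            int e1 = mt_edge_vertex(st, G[A], G[out_idx[1]], V[A], V[out_idx[1]], P[A], P[out_idx[1]], iso);
            int e2 = mt_edge_vertex(st, G[A], G[out_idx[2]], V[A], V[out_idx[2]], P[A], P[out_idx[2]], iso);
            mt_emit(st, e0, e1, e2, inC, outC);
          } else if (nin == 3) {
            int A = out_idx[0];
            int e0 = mt_edge_vertex(st, G[A], G[in_idx[0]], V[A], V[in_idx[0]], P[A], P[in_idx[0]], iso);
            int e1 = mt_edge_vertex(st, G[A], G[in_idx[1]], V[A], V[in_idx[1]], P[A], P[in_idx[1]], iso);
            int e2 = mt_edge_vertex(st, G[A], G[in_idx[2]], V[A], V[in_idx[2]], P[A], P[in_idx[2]], iso);
            mt_emit(st, e0, e1, e2, inC, outC);
          } else { // 2 in / 2 out -> quad
            int A = in_idx[0], B = in_idx[1], C = out_idx[0], D = out_idx[1];
            int eAC = mt_edge_vertex(st, G[A], G[C], V[A], V[C], P[A], P[C], iso);
            int eAD = mt_edge_vertex(st, G[A], G[D], V[A], V[D], P[A], P[D], iso);
            int eBD = mt_edge_vertex(st, G[B], G[D], V[B], V[D], P[B], P[D], iso);
            int eBC = mt_edge_vertex(st, G[B], G[C], V[B], V[C], P[B], P[C], iso);
            mt_emit(st, eAC, eAD, eBD, inC, outC);
            mt_emit(st, eAC, eBD, eBC, inC, outC);
          }
        }
      }
  int nv = (int)st.vx.size(), nf = (int)st.f0.size();
  NumericMatrix verts(nv, 3);
  IntegerMatrix faces(nf, 3);
  for (int v = 0; v < nv; ++v) {
    verts(v, 0) = st.vx[v]; verts(v, 1) = st.vy[v]; verts(v, 2) = st.vz[v];
  }
  for (int f = 0; f < nf; ++f) {
    faces(f, 0) = st.f0[f] + 1; faces(f, 1) = st.f1[f] + 1; faces(f, 2) = st.f2[f] + 1;
  }
  return List::create(Named("vertices") = verts, Named("faces") = faces);
}

// Uniform-grid nearest neighbour: buckets the reference cloud into a 3D grid
// and searches expanding cell shells. Exact (search stops only once the best
// distance is provably smaller than any unvisited shell).
// [[Rcpp::export]]
List nn_grid(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  if (nr == 0) stop("empty reference cloud");
  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int r = 0; r < nr; ++r)
    for (int d = 0; d < 3; ++d) {
      if (ref(r, d) < lo[d]) lo[d] = ref(r, d);
      if (ref(r, d) > hi[d]) hi[d] = ref(r, d);
    }
  double vol = 1.0;
  for (int d = 0; d < 3; ++d) vol *= std::max(hi[d] - lo[d], 1e-9);
  double h = std::cbrt(vol / nr) * 2.0;
  if (!(h > 0)) h = 1.0;
  int ng[3];
  for (int d = 0; d < 3; ++d)
    ng[d] = std::max(1, (int)((hi[d] - lo[d]) / h) + 1);
  auto cell_of = [&](double x, int d) {
    int c = (int)((x - lo[d]) / h);
    if (c < 0) c = 0;
    if (c >= ng[d]) c = ng[d] - 1;
    return c;
  };
  std::vector<std::vector<int>> buckets((size_t)ng[0] * ng[1] * ng[2]);
  for (int r = 0; r < nr; ++r) {
    int cx = cell_of(ref(r, 0), 0), cy = cell_of(ref(r, 1), 1),
        cz = cell_of(ref(r, 2), 2);
    buckets[cx + (size_t)ng[0] * (cy + (size_t)ng[1] * cz)].push_back(r);
  }
  int max_shell = ng[0] + ng[1] + ng[2];
  for (int q = 0; q < nq; ++q) {
    double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    int cx = cell_of(qx, 0), cy = cell_of(qy, 1), cz = cell_of(qz, 2);
    double best = R_PosInf;
    int besti = 0;
    for (int shell = 0; shell <= max_shell; ++shell) {
      if (best < R_PosInf) {
        double safe = (shell - 1) * h;   // closest possible point in this shell
        if (safe > 0 && best <= safe * safe) break;
      }
      for (int dz = -shell; dz <= shell; ++dz)
        for (int dy = -shell; dy <= shell; ++dy)
          for (int dx = -shell; dx <= shell; ++dx) {
            if (std::max(std::abs(dx), std::max(std::abs(dy), std::abs(dz))) != shell)
              continue;                   // only the shell surface
            int ix = cx + dx, iy = cy + dy, iz = cz + dz;
            if (ix < 0 || iy < 0 || iz < 0 || ix >= ng[0] || iy >= ng[1] ||
                iz >= ng[2])
              continue;
            const std::vector<int> &b =
              buckets[ix + (size_t)ng[0] * (iy + (size_t)ng[1] * iz)];
            for (int r : b) {
              double ddx = ref(r, 0) - qx, ddy = ref(r, 1) - qy,
                     ddz = ref(r, 2) - qz;
              double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
              if (d2 < best) { best = d2; besti = r; }
            }
          }
    }
    idx[q] = besti + 1;
    dist[q] = std::sqrt(best);
  }
  return List::create(Named("idx") = idx, Named("dist") = dist);
}

// Brute-force nearest neighbour (small point sets; ICP subsamples first).
// [[Rcpp::export]]
List nn_bruteforce(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  IntegerVector idx(nq);
  NumericVector dist(nq);
  for (int q = 0; q < nq; ++q) {
    double best = R_PosInf;
    int besti = 0;
    double qx = query(q, 0), qy = query(q, 1), qz = query(q, 2);
    for (int r = 0; r < nr; ++r) {
      double dx = ref(r, 0) - qx, dy = ref(r, 1) - qy, dz = ref(r, 2) - qz;
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; besti = r; }
    }
    idx[q] = besti + 1;
    dist[q] = std::sqrt(best);
  }
  return List::create(Named("idx") = idx, Named("dist") = dist);
}
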