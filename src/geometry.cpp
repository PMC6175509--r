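// Geometry kernels: uniform-grid nearest-neighbour search, tangent-plane
// signed distance fields, marching-tetrahedra isosurfacing, point-to-mesh
// distance, polygon rasterisation, vertex welding and mesh connectivity.
// All coordinates are in mm; vertex/face indices crossing the R boundary
// are 1-based.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <cstdint>
#include <functional>
#include <map>
#include <unordered_map>
#include <vector>

using namespace Rcpp;

namespace {

struct PointGrid {
  const double *px, *py, *pz;
  int n;
  double h, ox, oy, oz;
  int nx, ny, nz;
  std::vector<int> cell_start;   // size ncell+1
  std::vector<int> entries;      // point indices sorted by cell

  int clampi(int v, int hi) const { return v < 0 ? 0 : (v >= hi ? hi - 1 : v); }
  int cx(double x) const { return clampi((int)std::floor((x - ox) / h), nx); }
  int cy(double y) const { return clampi((int)std::floor((y - oy) / h), ny); }
  int cz(double z) const { return clampi((int)std::floor((z - oz) / h), nz); }
  int cid(int i, int j, int k) const { return i + nx * (j + ny * k); }

  void build(const NumericMatrix &P, double cell) {
    n = P.nrow();
    px = &P(0, 0); py = &P(0, 1); pz = &P(0, 2);
    double xmin = px[0], xmax = px[0], ymin = py[0], ymax = py[0],
           zmin = pz[0], zmax = pz[0];
    for (int i = 1; i < n; ++i) {
      xmin = std::min(xmin, px[i]); xmax = std::max(xmax, px[i]);
      ymin = std::min(ymin, py[i]); ymax = std::max(ymax, py[i]);
      zmin = std::min(zmin, pz[i]); zmax = std::max(zmax, pz[i]);
    }
    h = cell;
    if (h <= 0) {
      double vol = std::max(1e-12, (xmax - xmin) * (ymax - ymin) * (zmax - zmin));
      h = std::cbrt(vol / std::max(1, n)) * 2.0;
      if (h <= 0 || !std::isfinite(h)) h = 1.0;
    }
    ox = xmin - 0.5 * h; oy = ymin - 0.5 * h; oz = zmin - 0.5 * h;
    nx = std::max(1, (int)std::floor((xmax - ox) / h) + 1);
    ny = std::max(1, (int)std::floor((ymax - oy) / h) + 1);
    nz = std::max(1, (int)std::floor((zmax - oz) / h) + 1);
    // keep the table bounded for tiny h
    while ((double)nx * ny * nz > 4e6 && h < 1e12) {
      h *= 2.0;
      nx = std::max(1, (int)std::floor((xmax - ox) / h) + 1);
      ny = std::max(1, (int)std::floor((ymax - oy) / h) + 1);
      nz = std::max(1, (int)std::floor((zmax - oz) / h) + 1);
    }
    int ncell = nx * ny * nz;
    std::vector<int> count(ncell + 1, 0);
    std::vector<int> cells(n);
    for (int i = 0; i < n; ++i) {
      cells[i] = cid(cx(px[i]), cy(py[i]), cz(pz[i]));
      count[cells[i] + 1]++;
    }
    for (int c = 0; c < ncell; ++c) count[c + 1] += count[c];
    cell_start = count;
    entries.resize(n);
    std::vector<int> cursor(cell_start.begin(), cell_start.end() - 1);
    for (int i = 0; i < n; ++i) entries[cursor[cells[i]]++] = i;
  }

  // k nearest neighbours of (qx,qy,qz); fills idx/d2 (sized k), returns count
  int knn(double qx, double qy, double qz, int k,
          std::vector<int> &idx, std::vector<double> &d2) const {
    int found = 0;
    double worst = R_PosInf;
    int ci = cx(qx), cj = cy(qy), ck = cz(qz);
    int maxring = std::max(nx, std::max(ny, nz));
    for (int r = 0; r <= maxring; ++r) {
      double lb = (double)(r - 1) * h;  // rings >= r are at least this far
      if (found >= k && lb > 0 && worst <= lb * lb) break;
      int i0 = std::max(0, ci - r), i1 = std::min(nx - 1, ci + r);
      int j0 = std::max(0, cj - r), j1 = std::min(ny - 1, cj + r);
      int k0 = std::max(0, ck - r), k1 = std::min(nz - 1, ck + r);
      for (int kk = k0; kk <= k1; ++kk)
        for (int jj = j0; jj <= j1; ++jj)
          for (int ii = i0; ii <= i1; ++ii) {
            int cheb = std::max(std::abs(ii - ci),
                       std::max(std::abs(jj - cj), std::abs(kk - ck)));
            if (cheb != r) continue;  // only the new shell
            int c = cid(ii, jj, kk);
            for (int e = cell_start[c]; e < cell_start[c + 1]; ++e) {
              int p = entries[e];
              double dx = px[p] - qx, dy = py[p] - qy, dz = pz[p] - qz;
              double dd = dx * dx + dy * dy + dz * dz;
              if (found < k) {
                idx[found] = p; d2[found] = dd; ++found;
                if (found == k) {
                  worst = 0;
                  for (int t = 0; t < k; ++t) worst = std::max(worst, d2[t]);
                }
              } else if (dd < worst) {
                int wi = 0;
                for (int t = 1; t < k; ++t) if (d2[t] > d2[wi]) wi = t;
                idx[wi] = p; d2[wi] = dd;
                worst = 0;
                for (int t = 0; t < k; ++t) worst = std::max(worst, d2[t]);
              }
            }
          }
    }
    return found;
  }
};

inline double dot3(const double *a, const double *b) {
  return a[0] * b[0] + a[1] * b[1] + a[2] * b[2];
}

// Closest distance (squared) from point p to triangle (a,b,c); Ericson.
double point_tri_d2(const double *p, const double *a, const double *b,
                    const double *c) {
  double ab[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double ac[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double ap[3] = {p[0] - a[0], p[1] - a[1], p[2] - a[2]};
  double d1 = dot3(ab, ap), d2 = dot3(ac, ap);
  if (d1 <= 0 && d2 <= 0) return dot3(ap, ap);
  double bp[3] = {p[0] - b[0], p[1] - b[1], p[2] - b[2]};
  double d3 = dot3(ab, bp), d4 = dot3(ac, bp);
  if (d3 >= 0 && d4 <= d3) return dot3(bp, bp);
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0 && d1 >= 0 && d3 <= 0) {
    double v = d1 / (d1 - d3);
    double q[3] = {a[0] + v * ab[0] - p[0], a[1] + v * ab[1] - p[1],
                   a[2] + v * ab[2] - p[2]};
    return dot3(q, q);
  }
  double cp[3] = {p[0] - c[0], p[1] - c[1], p[2] - c[2]};
  double d5 = dot3(ab, cp), d6 = dot3(ac, cp);
  if (d6 >= 0 && d5 <= d6) return dot3(cp, cp);
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0 && d2 >= 0 && d6 <= 0) {
    double w = d2 / (d2 - d6);
    double q[3] = {a[0] + w * ac[0] - p[0], a[1] + w * ac[1] - p[1],
                   a[2] + w * ac[2] - p[2]};
    return dot3(q, q);
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    double q[3] = {b[0] + w * (c[0] - b[0]) - p[0],
                   b[1] + w * (c[1] - b[1]) - p[1],
                   b[2] + w * (c[2] - b[2]) - p[2]};
    return dot3(q, q);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  double q[3] = {a[0] + ab[0] * v + ac[0] * w - p[0],
                 a[1] + ab[1] * v + ac[1] * w - p[1],
                 a[2] + ab[2] * v + ac[2] * w - p[2]};
  return dot3(q, q);
}

}  // namespace

// [[Rcpp::export]]
List cpp_knn(NumericMatrix P, NumericMatrix Q, int k) {
  if (P.nrow() < 1) stop("empty point set");
  if (k < 1 || k > P.nrow()) stop("k must be in [1, nrow(P)]");
  PointGrid g;
  g.build(P, -1.0);
  int nq = Q.nrow();
  IntegerMatrix idx(nq, k);
  NumericMatrix dist(nq, k);
  std::vector<int> ii(k);
  std::vector<double> dd(k);
  for (int q = 0; q < nq; ++q) {
    g.knn(Q(q, 0), Q(q, 1), Q(q, 2), k, ii, dd);
    // sort ascending by distance for reproducibility
    std::vector<int> ord(k);
    for (int t = 0; t < k; ++t) ord[t] = t;
    std::sort(ord.begin(), ord.end(), [&](int a, int b) {
      if (dd[a] != dd[b]) return dd[a] < dd[b];
      return ii[a] < ii[b];
    });
    for (int t = 0; t < k; ++t) {
      idx(q, t) = ii[ord[t]] + 1;
      dist(q, t) = std::sqrt(dd[ord[t]]);
    }
  }
  return List::create(_["index"] = idx, _["distance"] = dist);
}

// Signed distance at each query as inverse-distance-weighted mean of the
// tangent-plane distances of the k nearest oriented points.  With band > 0
// a fast two-pass scheme is used: the 1-NN tangent-plane distance supplies
// value and sign everywhere, and the full k-NN estimate is recomputed only
// where |value| <= band (the zone containing the zero crossing).
// [[Rcpp::export]]
NumericVector cpp_plane_sdf(NumericMatrix P, NumericMatrix N, NumericMatrix Q,
                            int k, double band = 0.0) {
  if (k < 1 || k > P.nrow()) stop("k must be in [1, nrow(P)]");
  PointGrid g;
  g.build(P, -1.0);
  int nq = Q.nrow();
  NumericVector out(nq);
  std::vector<int> ii(k);
  std::vector<double> dd(k);
  // Mean of two first-order estimators whose curvature biases cancel:
  // (a) weighted mean of tangent-plane distances (zero set biased outward
  // on convex surfaces), (b) distance to the plane through the weighted
  // neighbour centroid with the averaged normal (biased inward).
  auto eval_k = [&](double qx, double qy, double qz, int kk) {
    g.knn(qx, qy, qz, kk, ii, dd);
    double sw = 0, sv = 0;
    double cx = 0, cy = 0, cz = 0, nxs = 0, nys = 0, nzs = 0;
    for (int t = 0; t < kk; ++t) {
      int p = ii[t];
      double d = std::sqrt(dd[t]);
      double w = 1.0 / (d + 1e-9);
      double pd = (qx - P(p, 0)) * N(p, 0) + (qy - P(p, 1)) * N(p, 1) +
                  (qz - P(p, 2)) * N(p, 2);
      sw += w;
      sv += w * pd;
      cx += w * P(p, 0); cy += w * P(p, 1); cz += w * P(p, 2);
      nxs += w * N(p, 0); nys += w * N(p, 1); nzs += w * N(p, 2);
    }
    double tangent = sv / sw;
    double nn = std::sqrt(nxs * nxs + nys * nys + nzs * nzs);
    if (nn < 1e-9 * sw) return tangent;
    double centroid = ((qx - cx / sw) * nxs + (qy - cy / sw) * nys +
                       (qz - cz / sw) * nzs) / nn;
    return 0.5 * (tangent + centroid);
  };
  for (int q = 0; q < nq; ++q) {
    double qx = Q(q, 0), qy = Q(q, 1), qz = Q(q, 2);
    if (band > 0) {
      double v1 = eval_k(qx, qy, qz, 1);
      out[q] = (std::abs(v1) <= band) ? eval_k(qx, qy, qz, k) : v1;
    } else {
      out[q] = eval_k(qx, qy, qz, k);
    }
  }
  return out;
}

// For each query, the number of points of P within `radius` (Euclidean).
// [[Rcpp::export]]
IntegerVector cpp_radius_count(NumericMatrix P, NumericMatrix Q, double radius) {
  int nq = Q.nrow();
  IntegerVector out(nq);
  if (P.nrow() == 0) return out;
  PointGrid g;
  g.build(P, radius);
  double r2 = radius * radius;
  for (int q = 0; q < nq; ++q) {
    double qx = Q(q, 0), qy = Q(q, 1), qz = Q(q, 2);
    int i0 = g.clampi((int)std::floor((qx - radius - g.ox) / g.h), g.nx);
    int i1 = g.clampi((int)std::floor((qx + radius - g.ox) / g.h), g.nx);
    int j0 = g.clampi((int)std::floor((qy - radius - g.oy) / g.h), g.ny);
    int j1 = g.clampi((int)std::floor((qy + radius - g.oy) / g.h), g.ny);
    int k0 = g.clampi((int)std::floor((qz - radius - g.oz) / g.h), g.nz);
    int k1 = g.clampi((int)std::floor((qz + radius - g.oz) / g.h), g.nz);
    int cnt = 0;
    for (int kk = k0; kk <= k1; ++kk)
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii) {
          int c = g.cid(ii, jj, kk);
          for (int e = g.cell_start[c]; e < g.cell_start[c + 1]; ++e) {
            int p = g.entries[e];
            double dx = g.px[p] - qx, dy = g.py[p] - qy, dz = g.pz[p] - qz;
            if (dx * dx + dy * dy + dz * dz <= r2) ++cnt;
          }
        }
    out[q] = cnt;
  }
  return out;
}

// Marching tetrahedra over a scalar field sampled on a regular node grid
// (Freudenthal 6-tet cube subdivision; iso-level 0; inside = negative).
// Triangles are oriented with normals pointing toward positive field values.
// [[Rcpp::export]]
List cpp_marching_tets(NumericVector vals, IntegerVector dims,
                       NumericVector origin, NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  if ((double)nx * ny * nz != (double)vals.size())
    stop("field length does not match dims");
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];

  auto gid = [&](int i, int j, int k) -> int64_t {
    return (int64_t)i + (int64_t)nx * ((int64_t)j + (int64_t)ny * k);
  };
  auto val = [&](int64_t g) {
    double v = vals[g];
    if (v == 0.0) v = 1e-12;  // nudge so crossings never sit on nodes
    return v;
  };

  // permutation paths of the Freudenthal subdivision
  static const int perms[6][3] = {{0, 1, 2}, {0, 2, 1}, {1, 0, 2},
                                  {1, 2, 0}, {2, 0, 1}, {2, 1, 0}};

  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> V;  // xyz triples
  std::vector<int> F;     // 0-based triples

  auto edge_vert = [&](int64_t ga, int64_t gb, double va, double vb,
                       const double *pa, const double *pb) -> int {
    int64_t lo = std::min(ga, gb), hi = std::max(ga, gb);
    uint64_t key = (uint64_t)lo * (uint64_t)(nx * (int64_t)ny * nz) + (uint64_t)hi;
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double t = va / (va - vb);
    if (!std::isfinite(t)) t = 0.5;
    t = std::min(1.0, std::max(0.0, t));
    int id = (int)(V.size() / 3);
    V.push_back(pa[0] + t * (pb[0] - pa[0]));
    V.push_back(pa[1] + t * (pb[1] - pa[1]));
    V.push_back(pa[2] + t * (pb[2] - pa[2]));
    edge_vertex.emplace(key, id);
    return id;
  };

  auto emit = [&](int a, int b, int c, const double g[3]) {
    // orient the triangle so its normal points along +gradient (outside)
    const double *A = &V[3 * a], *B = &V[3 * b], *C = &V[3 * c];
    double u[3] = {B[0] - A[0], B[1] - A[1], B[2] - A[2]};
    double w[3] = {C[0] - A[0], C[1] - A[1], C[2] - A[2]};
    double nrm[3] = {u[1] * w[2] - u[2] * w[1], u[2] * w[0] - u[0] * w[2],
                     u[0] * w[1] - u[1] * w[0]};
    if (nrm[0] * g[0] + nrm[1] * g[1] + nrm[2] * g[2] < 0) std::swap(b, c);
    F.push_back(a); F.push_back(b); F.push_back(c);
  };

  int corner[4][3];
  int64_t gids[4];
  double pos[4][3], vv[4];

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        // quick reject: all 8 corners same sign
        bool has_neg = false, has_pos = false;
        for (int c = 0; c < 8; ++c) {
          double v = val(gid(i + (c & 1), j + ((c >> 1) & 1), k + ((c >> 2) & 1)));
          (v < 0 ? has_neg : has_pos) = true;
        }
        if (!has_neg || !has_pos) continue;
        for (int t = 0; t < 6; ++t) {
          corner[0][0] = 0; corner[0][1] = 0; corner[0][2] = 0;
          for (int s = 0; s < 3; ++s) {
            corner[s + 1][0] = corner[s][0];
            corner[s + 1][1] = corner[s][1];
            corner[s + 1][2] = corner[s][2];
            corner[s + 1][perms[t][s]] += 1;
          }
          for (int c = 0; c < 4; ++c) {
            int ci = i + corner[c][0], cj = j + corner[c][1], ck = k + corner[c][2];
            gids[c] = gid(ci, cj, ck);
            vv[c] = val(gids[c]);
            pos[c][0] = ox + hx * ci;
            pos[c][1] = oy + hy * cj;
            pos[c][2] = oz + hz * ck;
          }
          int neg[4], posn[4], nn = 0, np = 0;
          for (int c = 0; c < 4; ++c) (vv[c] < 0 ? neg[nn++] : posn[np++]) = c;
          if (nn == 0 || nn == 4) continue;
          // per-tet linear gradient (Cramer)
          double M[3][3], dv[3], grad[3] = {0, 0, 0};
          for (int r = 0; r < 3; ++r) {
            for (int c2 = 0; c2 < 3; ++c2) M[r][c2] = pos[r + 1][c2] - pos[0][c2];
            dv[r] = vv[r + 1] - vv[0];
          }
          double det =
              M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
              M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
              M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
          if (std::abs(det) > 1e-300) {
            double inv[3][3];
            inv[0][0] = (M[1][1] * M[2][2] - M[1][2] * M[2][1]) / det;
            inv[1][0] = -(M[1][0] * M[2][2] - M[1][2] * M[2][0]) / det;
            inv[2][0] = (M[1][0] * M[2][1] - M[1][1] * M[2][0]) / det;
            inv[0][1] = -(M[0][1] * M[2][2] - M[0][2] * M[2][1]) / det;
            inv[1][1] = (M[0][0] * M[2][2] - M[0][2] * M[2][0]) / det;
            inv[2][1] = -(M[0][0] * M[2][1] - M[0][1] * M[2][0]) / det;
            inv[0][2] = (M[0][1] * M[1][2] - M[0][2] * M[1][1]) / det;
            inv[1][2] = -(M[0][0] * M[1][2] - M[0][2] * M[1][0]) / det;
            inv[2][2] = (M[0][0] * M[1][1] - M[0][1] * M[1][0]) / det;
            for (int r = 0; r < 3; ++r)
              grad[r] = inv[r][0] * dv[0] + inv[r][1] * dv[1] + inv[r][2] * dv[2];
          }
          if (nn == 1 || nn == 3) {
            int a = (nn == 1) ? neg[0] : posn[0];
            int o[3];
            int m = 0;
            for (int c = 0; c < 4; ++c) if (c != a) o[m++] = c;
            int e0 = edge_vert(gids[a], gids[o[0]], vv[a], vv[o[0]], pos[a], pos[o[0]]);
            int e1 = edge_vert(gids[a], gids[o[1]], vv[a], vv[o[1]], pos[a], pos[o[1]]);
            int e2 = edge_vert(gids[a], gids[o[2]], vv[a], vv[o[2]], pos[a], pos[o[2]]);
            emit(e0, e1, e2, grad);
          } else {  // 2 vs 2
            int a = neg[0], b = neg[1], c = posn[0], d = posn[1];
            int eac = edge_vert(gids[a], gids[c], vv[a], vv[c], pos[a], pos[c]);
            int ead = edge_vert(gids[a], gids[d], vv[a], vv[d], pos[a], pos[d]);
            int ebc = edge_vert(gids[b], gids[c], vv[b], vv[c], pos[b], pos[c]);
            int ebd = edge_vert(gids[b], gids[d], vv[b], vv[d], pos[b], pos[d]);
            emit(eac, ead, ebd, grad);
            emit(eac, ebd, ebc, grad);
          }
        }
      }

  int nV = (int)(V.size() / 3), nF = (int)(F.size() / 3);
  NumericMatrix Vm(nV, 3);
  IntegerMatrix Fm(nF, 3);
  for (int v = 0; v < nV; ++v)
    for (int c = 0; c < 3; ++c) Vm(v, c) = V[3 * v + c];
  for (int f = 0; f < nF; ++f)
    for (int c = 0; c < 3; ++c) Fm(f, c) = F[3 * f + c] + 1;
  return List::create(_["vertices"] = Vm, _["faces"] = Fm);
}

// Unsigned Euclidean distance from each query point to a triangle mesh.
// The nearest mesh VERTEX (found on a uniform point grid) bounds the answer
// from above; since the nearest triangle has a vertex within that bound
// plus the longest edge length, it suffices to test the faces incident to
// the vertices inside that radius.
// [[Rcpp::export]]
NumericVector cpp_point_mesh_distance(NumericMatrix Q, NumericMatrix V,
                                      IntegerMatrix Fc) {
  int nq = Q.nrow(), nf = Fc.nrow(), nv = V.nrow();
  if (nf == 0) stop("mesh has no faces");
  NumericVector out(nq);

  // incident-face lists (CSR)
  std::vector<int> deg(nv + 1, 0);
  for (int f = 0; f < nf; ++f)
    for (int c = 0; c < 3; ++c) deg[Fc(f, c)]++;
  for (int v = 0; v < nv; ++v) deg[v + 1] += deg[v];
  std::vector<int> inc(3 * nf);
  std::vector<int> cursor(deg.begin(), deg.end() - 1);
  for (int f = 0; f < nf; ++f)
    for (int c = 0; c < 3; ++c) inc[cursor[Fc(f, c) - 1]++] = f;

  double emax2 = 0;
  for (int f = 0; f < nf; ++f)
    for (int c = 0; c < 3; ++c) {
      int a = Fc(f, c) - 1, b = Fc(f, (c + 1) % 3) - 1;
      double dx = V(a, 0) - V(b, 0), dy = V(a, 1) - V(b, 1),
             dz = V(a, 2) - V(b, 2);
      emax2 = std::max(emax2, dx * dx + dy * dy + dz * dz);
    }
  double emax = std::sqrt(emax2);

  PointGrid g;
  g.build(V, -1.0);
  std::vector<int> i1(1);
  std::vector<double> d1(1);
  std::vector<int> stamp(nf, -1);
  for (int q = 0; q < nq; ++q) {
    double qx = Q(q, 0), qy = Q(q, 1), qz = Q(q, 2);
    double p[3] = {qx, qy, qz};
    g.knn(qx, qy, qz, 1, i1, d1);
    // the closest-point direction is perpendicular to the nearest triangle,
    // so that triangle has a vertex within sqrt(d^2 + emax^2) of the query
    double r2 = d1[0] + emax2 + 1e-12;
    double radius = std::sqrt(r2);
    double best2 = d1[0];
    int i0 = g.clampi((int)std::floor((qx - radius - g.ox) / g.h), g.nx);
    int i1b = g.clampi((int)std::floor((qx + radius - g.ox) / g.h), g.nx);
    int j0 = g.clampi((int)std::floor((qy - radius - g.oy) / g.h), g.ny);
    int j1 = g.clampi((int)std::floor((qy + radius - g.oy) / g.h), g.ny);
    int k0 = g.clampi((int)std::floor((qz - radius - g.oz) / g.h), g.nz);
    int k1 = g.clampi((int)std::floor((qz + radius - g.oz) / g.h), g.nz);
    for (int kk = k0; kk <= k1; ++kk)
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1b; ++ii) {
          // skip cells entirely outside the candidate ball
          double cx0 = g.ox + ii * g.h, cy0 = g.oy + jj * g.h,
                 cz0 = g.oz + kk * g.h;
          double ddx = std::max(std::max(cx0 - qx, qx - (cx0 + g.h)), 0.0);
          double ddy = std::max(std::max(cy0 - qy, qy - (cy0 + g.h)), 0.0);
          double ddz = std::max(std::max(cz0 - qz, qz - (cz0 + g.h)), 0.0);
          if (ddx * ddx + ddy * ddy + ddz * ddz > r2) continue;
          int c = g.cid(ii, jj, kk);
          for (int e = g.cell_start[c]; e < g.cell_start[c + 1]; ++e) {
            int v = g.entries[e];
            double dx = g.px[v] - qx, dy = g.py[v] - qy, dz = g.pz[v] - qz;
            if (dx * dx + dy * dy + dz * dz > r2) continue;
            for (int t = deg[v]; t < deg[v + 1]; ++t) {
              int f = inc[t];
              if (stamp[f] == q) continue;
              stamp[f] = q;
              int a = Fc(f, 0) - 1, b = Fc(f, 1) - 1, cc = Fc(f, 2) - 1;
              double A[3] = {V(a, 0), V(a, 1), V(a, 2)};
              double B[3] = {V(b, 0), V(b, 1), V(b, 2)};
              double C[3] = {V(cc, 0), V(cc, 1), V(cc, 2)};
              best2 = std::min(best2, point_tri_d2(p, A, B, C));
            }
          }
        }
    out[q] = std::sqrt(best2);
  }
  return out;
}

// Even-odd point-in-polygon over a grid of centres; points on an edge count
// as inside.  Returns an nx-by-ny logical matrix.
// [[Rcpp::export]]
LogicalMatrix cpp_pip_grid(NumericMatrix poly, NumericVector xs,
                           NumericVector ys) {
  int np = poly.nrow(), nx = xs.size(), ny = ys.size();
  if (np < 3) stop("polygon needs at least 3 points");
  LogicalMatrix out(nx, ny);
  const double eps = 1e-7;
  for (int j = 0; j < ny; ++j) {
    double py = ys[j];
    for (int i = 0; i < nx; ++i) {
      double px = xs[i];
      bool inside = false, onedge = false;
      for (int e = 0; e < np; ++e) {
        double x1 = poly(e, 0), y1 = poly(e, 1);
        int e2 = (e + 1) % np;
        double x2 = poly(e2, 0), y2 = poly(e2, 1);
        double dx = x2 - x1, dy = y2 - y1;
        double len2 = dx * dx + dy * dy;
        if (len2 > 0) {
          double t = ((px - x1) * dx + (py - y1) * dy) / len2;
          t = std::min(1.0, std::max(0.0, t));
          double ddx = px - (x1 + t * dx), ddy = py - (y1 + t * dy);
          if (ddx * ddx + ddy * ddy <= eps * eps) { onedge = true; break; }
        }
        if ((y1 > py) != (y2 > py)) {
          double xint = x1 + (py - y1) * dx / dy;
          if (px < xint) inside = !inside;
        }
      }
      out(i, j) = onedge || inside;
    }
  }
  return out;
}

// Group vertices whose coordinates agree after rounding to `tol`; returns
// 1-based group ids in first-occurrence order.
// [[Rcpp::export]]
IntegerVector cpp_weld_groups(NumericMatrix V, double tol) {
  int n = V.nrow();
  IntegerVector grp(n);
  std::map<std::array<int64_t, 3>, int> seen;
  int next = 0;
  for (int i = 0; i < n; ++i) {
    std::array<int64_t, 3> key;
    for (int c = 0; c < 3; ++c) key[c] = (int64_t)std::llround(V(i, c) / tol);
    auto it = seen.find(key);
    if (it == seen.end()) { seen.emplace(key, next); grp[i] = ++next; }
    else grp[i] = it->second + 1;
  }
  return grp;
}

// Counts of incident faces per unique undirected edge.
// [[Rcpp::export]]
IntegerVector cpp_edge_counts(IntegerMatrix Fc) {
  std::unordered_map<uint64_t, int> cnt;
  int nf = Fc.nrow();
  cnt.reserve(nf * 2);
  for (int f = 0; f < nf; ++f)
    for (int e = 0; e < 3; ++e) {
      int a = Fc(f, e), b = Fc(f, (e + 1) % 3);
      uint64_t lo = std::min(a, b), hi = std::max(a, b);
      cnt[(lo << 32) | hi]++;
    }
  IntegerVector out(cnt.size());
  int i = 0;
  for (auto &kv : cnt) out[i++] = kv.second;
  return out;
}

// Connected components over shared vertices; returns a 1-based component id
// per face, numbered in order of first appearance.
// [[Rcpp::export]]
IntegerVector cpp_face_components(IntegerMatrix Fc, int n_vertices) {
  std::vector<int> parent(n_vertices);
  for (int i = 0; i < n_vertices; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  int nf = Fc.nrow();
  for (int f = 0; f < nf; ++f) {
    int a = find(Fc(f, 0) - 1), b = find(Fc(f, 1) - 1), c = find(Fc(f, 2) - 1);
    parent[b] = a;
    parent[find(c)] = find(a);
  }
  IntegerVector out(nf);
  std::unordered_map<int, int> label;
  int next = 0;
  for (int f = 0; f < nf; ++f) {
    int r = find(Fc(f, 0) - 1);
    auto it = label.find(r);
    if (it == label.end()) { label.emplace(r, next); out[f] = ++next; }
    else out[f] = it->second + 1;
  }
  return out;
}
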