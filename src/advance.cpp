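// Inner mechanical loop of the vertex model: forces from the tissue
// energy (area elasticity, perimeter contractility, per-edge line
// tension), additive motile forces, forward-Euler updates with fixed
// vertices masked, endo-BC corridor projection, and trigger detection
// (short edges -> T1, small triangles -> T2, non-finite positions).
// Topology never changes here; junctional rearrangements are applied by
// the R layer between chunks.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// status codes returned to R
// 0 = completed, 1 = short edge (T1 trigger), 2 = small triangle (T2
// trigger), 3 = non-finite position (instability)

// [[Rcpp::export]]
List vm_advance_cpp(NumericMatrix pos_in,
                    LogicalVector fixed,
                    IntegerVector cellptr,   // 0-based CSR offsets, length nc+1
                    IntegerVector ring,      // 0-based vertex ids
                    IntegerVector typecode,  // 0 central,1 peripheral,2 tip,3 stalk,4 lumen
                    NumericVector A0,
                    NumericVector Kt,        // per type (length 5)
                    NumericVector Gt,
                    IntegerVector ev1,       // undirected edges, 0-based
                    IntegerVector ev2,
                    NumericVector elam,      // per-edge line tension
                    LogicalVector e_exempt,  // exempt from the T1 trigger
                    LogicalVector c_exempt,  // exempt from the T2 trigger
                    NumericMatrix addF,      // additive (motile) force per vertex
                    NumericMatrix corridors, // rows: ax ay ux uy halfwidth
                    LogicalVector proj_ok,   // vertices subject to corridors
                    double dt, int nsteps,
                    double t1_thresh, double t2_thresh) {
  NumericMatrix pos = clone(pos_in);
  const int nv = pos.nrow();
  const int nc = cellptr.size() - 1;
  const int ne = ev1.size();
  const int nbc = corridors.nrow();
  std::vector<double> fx(nv), fy(nv), A(nc), P(nc);

  int status = 0, steps = 0, info = -1;
  for (int s = 0; s < nsteps; ++s) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    // areas and perimeters
    for (int c = 0; c < nc; ++c) {
      double a = 0.0, p = 0.0;
      for (int k = cellptr[c]; k < cellptr[c + 1]; ++k) {
        int i = ring[k];
        int j = ring[(k + 1 < cellptr[c + 1]) ? k + 1 : cellptr[c]];
        a += pos(i, 0) * pos(j, 1) - pos(j, 0) * pos(i, 1);
        double dx = pos(j, 0) - pos(i, 0), dy = pos(j, 1) - pos(i, 1);
        p += std::sqrt(dx * dx + dy * dy);
      }
      A[c] = 0.5 * a;
      P[c] = p;
    }
    // cell terms
    for (int c = 0; c < nc; ++c) {
      const double ka = -Kt[typecode[c]] * (A[c] - A0[c]);
      const double gp = -Gt[typecode[c]] * P[c];
      const int b = cellptr[c], e = cellptr[c + 1], m = e - b;
      for (int k = 0; k < m; ++k) {
        int v = ring[b + k];
        int vn = ring[b + (k + 1) % m];
        int vp = ring[b + (k + m - 1) % m];
        // dA/dv = 0.5 (y_next - y_prev, x_prev - x_next)
        fx[v] += ka * 0.5 * (pos(vn, 1) - pos(vp, 1));
        fy[v] += ka * 0.5 * (pos(vp, 0) - pos(vn, 0));
        double d1x = pos(v, 0) - pos(vp, 0), d1y = pos(v, 1) - pos(vp, 1);
        double d2x = pos(v, 0) - pos(vn, 0), d2y = pos(v, 1) - pos(vn, 1);
        double l1 = std::sqrt(d1x * d1x + d1y * d1y);
        double l2 = std::sqrt(d2x * d2x + d2y * d2y);
        if (l1 > 0) { fx[v] += gp * d1x / l1; fy[v] += gp * d1y / l1; }
        if (l2 > 0) { fx[v] += gp * d2x / l2; fy[v] += gp * d2y / l2; }
      }
    }
    // edge tension
    for (int e = 0; e < ne; ++e) {
      int a = ev1[e], b = ev2[e];
      double dx = pos(a, 0) - pos(b, 0), dy = pos(a, 1) - pos(b, 1);
      double L = std::sqrt(dx * dx + dy * dy);
      if (L > 0) {
        double f = -elam[e] / L;
        fx[a] += f * dx; fy[a] += f * dy;
        fx[b] -= f * dx; fy[b] -= f * dy;
      }
    }
    // Euler update with additive forces, fixed mask
    for (int v = 0; v < nv; ++v) {
      if (fixed[v]) continue;
      pos(v, 0) += dt * (fx[v] + addF(v, 0));
      pos(v, 1) += dt * (fy[v] + addF(v, 1));
    }
    // minimum-edge-length clamp: edges exempted from T1 handling (fixed
    // anchors, cooled-down sites) must not shrink into coincident
    // vertex clusters
    const double lmin = 0.5 * t1_thresh;
    if (lmin > 0) {
      for (int e = 0; e < ne; ++e) {
        int a = ev1[e], b = ev2[e];
        if (fixed[a] && fixed[b]) continue;
        double dx = pos(b, 0) - pos(a, 0), dy = pos(b, 1) - pos(a, 1);
        double L = std::sqrt(dx * dx + dy * dy);
        if (L >= lmin) continue;
        double ux = (L > 1e-12) ? dx / L : 1.0;
        double uy = (L > 1e-12) ? dy / L : 0.0;
        double grow = lmin - L;
        if (fixed[a]) {
          pos(b, 0) += grow * ux; pos(b, 1) += grow * uy;
        } else if (fixed[b]) {
          pos(a, 0) -= grow * ux; pos(a, 1) -= grow * uy;
        } else {
          pos(a, 0) -= 0.5 * grow * ux; pos(a, 1) -= 0.5 * grow * uy;
          pos(b, 0) += 0.5 * grow * ux; pos(b, 1) += 0.5 * grow * uy;
        }
      }
    }
    // corridor projection (epithelial-only vertices)
    for (int b = 0; b < nbc; ++b) {
      double ax = corridors(b, 0), ay = corridors(b, 1);
      double ux = corridors(b, 2), uy = corridors(b, 3), hw = corridors(b, 4);
      double nx = -uy, ny = ux;
      for (int v = 0; v < nv; ++v) {
        if (!proj_ok[v]) continue;
        double rx = pos(v, 0) - ax, ry = pos(v, 1) - ay;
        double t = rx * ux + ry * uy;
        if (t <= 0) continue;
        double sside = rx * nx + ry * ny;
        if (std::fabs(sside) >= hw) continue;
        double side = (sside >= 0) ? 1.0 : -1.0;
        pos(v, 0) += (side * hw - sside) * nx;
        pos(v, 1) += (side * hw - sside) * ny;
      }
    }
    ++steps;
    // triggers on the updated state
    bool bad = false;
    for (int v = 0; v < nv && !bad; ++v)
      if (!std::isfinite(pos(v, 0)) || !std::isfinite(pos(v, 1))) bad = true;
    if (bad) { status = 3; break; }
    // degenerate cells take priority: a cell can only invert by first
    // shrinking through the removal threshold
    int hit = -1;
    for (int c = 0; c < nc; ++c) {
      if (typecode[c] == 4 || c_exempt[c]) continue;
      double a = 0.0;
      for (int k = cellptr[c]; k < cellptr[c + 1]; ++k) {
        int i = ring[k];
        int j = ring[(k + 1 < cellptr[c + 1]) ? k + 1 : cellptr[c]];
        a += pos(i, 0) * pos(j, 1) - pos(j, 0) * pos(i, 1);
      }
      if (0.5 * a < t2_thresh) { hit = c; break; }
    }
    if (hit >= 0) { status = 2; info = hit; break; }
    for (int e = 0; e < ne; ++e) {
      if (e_exempt[e]) continue;
      double dx = pos(ev1[e], 0) - pos(ev2[e], 0);
      double dy = pos(ev1[e], 1) - pos(ev2[e], 1);
      if (dx * dx + dy * dy < t1_thresh * t1_thresh) { hit = e; break; }
    }
    if (hit >= 0) { status = 1; info = hit; break; }
  }
  return List::create(_["pos"] = pos, _["status"] = status,
                      _["steps"] = steps, _["info"] = info + 1);
}

// Jacobi-preconditioned conjugate gradient for the VEGF steady state on
// the free (non-Dirichlet) cells. The system is symmetric positive
// definite (graph Laplacian plus positive degradation diagonal).
// [[Rcpp::export]]
NumericVector vegf_cg_cpp(IntegerVector ia, IntegerVector ib,  // 0-based pairs
                          NumericVector w, NumericVector diag,
                          NumericVector b, double tol = 1e-10,
                          int maxit = 1000) {
  const int n = b.size(), m = ia.size();
  std::vector<double> x(n, 0.0), r(n), z(n), p(n), Ap(n);
  for (int i = 0; i < n; ++i) r[i] = b[i];
  double bnorm = 0.0;
  for (int i = 0; i < n; ++i) bnorm += b[i] * b[i];
  if (bnorm == 0.0) return NumericVector(n);
  double rz = 0.0;
  for (int i = 0; i < n; ++i) { z[i] = r[i] / diag[i]; p[i] = z[i]; rz += r[i] * z[i]; }
  for (int it = 0; it < maxit; ++it) {
    for (int i = 0; i < n; ++i) Ap[i] = diag[i] * p[i];
    for (int k = 0; k < m; ++k) {
      Ap[ia[k]] -= w[k] * p[ib[k]];
      Ap[ib[k]] -= w[k] * p[ia[k]];
    }
    double pAp = 0.0;
    for (int i = 0; i < n; ++i) pAp += p[i] * Ap[i];
    if (pAp <= 0) break;
    double alpha = rz / pAp;
    double rnorm = 0.0;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * Ap[i];
      rnorm += r[i] * r[i];
    }
    if (rnorm <= tol * tol * bnorm) break;
    double rz_new = 0.0;
    for (int i = 0; i < n; ++i) { z[i] = r[i] / diag[i]; rz_new += r[i] * z[i]; }
    double beta = rz_new / rz;
    rz = rz_new;
    for (int i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
  }
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = x[i] > 0 ? x[i] : 0.0;
  return out;
}

// Areas, perimeters and area centroids of all cells in one pass.
// [[Rcpp::export]]
List cell_geom_cpp(NumericMatrix pos, IntegerVector cellptr,
                   IntegerVector ring) {
  const int nc = cellptr.size() - 1;
  NumericVector A(nc), P(nc), cx(nc), cy(nc);
  for (int c = 0; c < nc; ++c) {
    double a = 0.0, p = 0.0, sx = 0.0, sy = 0.0;
    for (int k = cellptr[c]; k < cellptr[c + 1]; ++k) {
      int i = ring[k];
      int j = ring[(k + 1 < cellptr[c + 1]) ? k + 1 : cellptr[c]];
      double cr = pos(i, 0) * pos(j, 1) - pos(j, 0) * pos(i, 1);
      a += cr;
      sx += (pos(i, 0) + pos(j, 0)) * cr;
      sy += (pos(i, 1) + pos(j, 1)) * cr;
      double dx = pos(j, 0) - pos(i, 0), dy = pos(j, 1) - pos(i, 1);
      p += std::sqrt(dx * dx + dy * dy);
    }
    A[c] = 0.5 * a;
    P[c] = p;
    cx[c] = sx / (3.0 * a);
    cy[c] = sy / (3.0 * a);
  }
  return List::create(_["area"] = A, _["perimeter"] = P,
                      _["cx"] = cx, _["cy"] = cy);
}

// Which cells (1-based) contain vertex v (1-based)?
// [[Rcpp::export]]
IntegerVector cells_containing_cpp(List rings, int v) {
  std::vector<int> out;
  const int nc = rings.size();
  for (int i = 0; i < nc; ++i) {
    IntegerVector r = rings[i];
    for (int k = 0; k < r.size(); ++k)
      if (r[k] == v) { out.push_back(i + 1); break; }
  }
  return wrap(out);
}

// Simple-polygon test: no repeated vertices, no crossing of
// non-adjacent edges (1-based vertex ids into pos).
// [[Rcpp::export]]
bool ring_simple_cpp(NumericMatrix pos, IntegerVector ring) {
  const int n = ring.size();
  if (n < 3) return false;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (ring[i] == ring[j]) return false;
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) { x[i] = pos(ring[i] - 1, 0); y[i] = pos(ring[i] - 1, 1); }
  for (int i = 0; i < n - 1; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 1; j < n; ++j) {
      if (j == i || std::abs(i - j) == 1 || (i == 0 && j == n - 1)) continue;
      int j2 = (j + 1) % n;
      double d1 = (x[i2] - x[i]) * (y[j] - y[i]) - (y[i2] - y[i]) * (x[j] - x[i]);
      double d2 = (x[i2] - x[i]) * (y[j2] - y[i]) - (y[i2] - y[i]) * (x[j2] - x[i]);
      double d3 = (x[j2] - x[j]) * (y[i] - y[j]) - (y[j2] - y[j]) * (x[i] - x[j]);
      double d4 = (x[j2] - x[j]) * (y[i2] - y[j]) - (y[j2] - y[j]) * (x[i2] - x[j]);
      if (d1 * d2 < 0 && d3 * d4 < 0) return false;
    }
  }
  return true;
}
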