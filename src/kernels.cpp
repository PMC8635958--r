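#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// Build interior-node adjacency from a triangle list.  Nodes are 1-based on
// the R side; node indices 1..n_mem are membrane (Dirichlet) nodes, the rest
// are free lamellipodial nodes.
static void build_adjacency(const IntegerMatrix &tri, int n_nodes,
                            std::vector<std::vector<int>> &adj) {
  adj.assign(n_nodes, std::vector<int>());
  int nt = tri.nrow();
  for (int t = 0; t < nt; ++t) {
    int a = tri(t, 0) - 1, b = tri(t, 1) - 1, c = tri(t, 2) - 1;
    adj[a].push_back(b); adj[a].push_back(c);
    adj[b].push_back(a); adj[b].push_back(c);
    adj[c].push_back(a); adj[c].push_back(b);
  }
  for (int i = 0; i < n_nodes; ++i) {
    std::sort(adj[i].begin(), adj[i].end());
    adj[i].erase(std::unique(adj[i].begin(), adj[i].end()), adj[i].end());
  }
}

// Zero-rest-length spring equilibrium of the lamellipodial network: each free
// node sits at the arithmetic mean of its Delaunay neighbours with the
// membrane ring as Dirichlet boundary.  Solved (both coordinates at once) by
// Jacobi-preconditioned conjugate gradients on the interior graph Laplacian
// (SPD for a connected network), warm-started from the current positions.
// `tol` bounds the infinity norm of the residual sum_j (X_j - X_i).
// [[Rcpp::export]]
NumericMatrix relax_interior_cpp(IntegerMatrix tri, NumericMatrix pos,
                                 int n_mem, double tol, int maxit) {
  int n = pos.nrow();
  int nf = n - n_mem;                    // free nodes: indices n_mem..n-1
  NumericMatrix out = clone(pos);
  if (nf <= 0) return out;

  std::vector<std::vector<int>> adj;
  build_adjacency(tri, n, adj);
  // flat CSR over the free nodes
  std::vector<int> ptr(nf + 1, 0), nbr;   // free-free edges, local indices
  std::vector<double> deg(nf), bx(nf, 0.0), by(nf, 0.0);
  for (int i = 0; i < nf; ++i) {
    const std::vector<int> &a = adj[n_mem + i];
    if (a.empty())
      stop("interior node %d has no Delaunay neighbours (disconnected)",
           n_mem + i + 1);
    deg[i] = (double)a.size();
    for (int j : a) {
      if (j < n_mem) { bx[i] += pos(j, 0); by[i] += pos(j, 1); }
      else nbr.push_back(j - n_mem);
    }
    ptr[i + 1] = (int)nbr.size();
  }

  std::vector<double> x(2 * nf), r(2 * nf), z(2 * nf), p(2 * nf), Ap(2 * nf);
  for (int i = 0; i < nf; ++i) {
    x[i] = pos(n_mem + i, 0);
    x[nf + i] = pos(n_mem + i, 1);
  }
  auto applyA = [&](const std::vector<double> &v, std::vector<double> &Av) {
    for (int i = 0; i < nf; ++i) {
      double sx = deg[i] * v[i], sy = deg[i] * v[nf + i];
      for (int k = ptr[i]; k < ptr[i + 1]; ++k) {
        sx -= v[nbr[k]];
        sy -= v[nf + nbr[k]];
      }
      Av[i] = sx; Av[nf + i] = sy;
    }
  };
  applyA(x, Ap);
  double rz = 0.0, rinf = 0.0;
  for (int i = 0; i < nf; ++i) {
    r[i] = bx[i] - Ap[i];
    r[nf + i] = by[i] - Ap[nf + i];
  }
  for (int i = 0; i < 2 * nf; ++i) {
    z[i] = r[i] / deg[i % nf];
    p[i] = z[i];
    rz += r[i] * z[i];
    rinf = std::max(rinf, std::fabs(r[i]));
  }
  for (int it = 0; it < maxit && rinf > tol; ++it) {
    applyA(p, Ap);
    double pAp = 0.0;
    for (int i = 0; i < 2 * nf; ++i) pAp += p[i] * Ap[i];
    if (pAp <= 0) break;
    double alpha = rz / pAp, rz_new = 0.0;
    rinf = 0.0;
    for (int i = 0; i < 2 * nf; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * Ap[i];
      z[i] = r[i] / deg[i % nf];
      rz_new += r[i] * z[i];
      rinf = std::max(rinf, std::fabs(r[i]));
    }
    double beta = rz_new / rz;
    for (int i = 0; i < 2 * nf; ++i) p[i] = z[i] + beta * p[i];
    rz = rz_new;
  }
  for (int i = 0; i < nf; ++i) {
    out(n_mem + i, 0) = x[i];
    out(n_mem + i, 1) = x[nf + i];
  }
  return out;
}

// Assemble the linearly implicit membrane matrix M = mu I + C + dt K over
// interleaved coordinates (x1,y1,x2,y2,...): C the edge dashpot damping,
// K the spring stiffness (tension term clamped at >= 0 transversally).
// [[Rcpp::export]]
NumericMatrix membrane_matrix_cpp(NumericMatrix u, NumericVector len,
                                  NumericVector tension, double k,
                                  double eta, double dt, double mu) {
  int n = u.nrow();
  NumericMatrix M(2 * n, 2 * n);
  for (int i = 0; i < 2 * n; ++i) M(i, i) = mu;
  for (int i = 0; i < n; ++i) {
    int j = (i + 1) % n;
    double ux = u(i, 0), uy = u(i, 1);
    double t_perp = tension[i] / len[i];
    if (t_perp < 0) t_perp = 0;
    double blk[2][2];
    blk[0][0] = eta * ux * ux + dt * (k * ux * ux + t_perp * (1 - ux * ux));
    blk[0][1] = eta * ux * uy + dt * (k * ux * uy - t_perp * ux * uy);
    blk[1][0] = blk[0][1];
    blk[1][1] = eta * uy * uy + dt * (k * uy * uy + t_perp * (1 - uy * uy));
    for (int a = 0; a < 2; ++a)
      for (int b = 0; b < 2; ++b) {
        M(2 * i + a, 2 * i + b) += blk[a][b];
        M(2 * j + a, 2 * j + b) += blk[a][b];
        M(2 * i + a, 2 * j + b) -= blk[a][b];
        M(2 * j + a, 2 * i + b) -= blk[a][b];
      }
  }
  return M;
}

// Accumulate `values` into `n` bins by 1-based `idx` (sum per bin).
// [[Rcpp::export]]
NumericVector accumulate_by_index_cpp(int n, IntegerVector idx,
                                      NumericVector values) {
  NumericVector out(n);
  for (int k = 0; k < idx.size(); ++k) out[idx[k] - 1] += values[k];
  return out;
}

// Corner angles (rad) of each triangle, in the order the vertices appear in
// the triangle row.  Angles of a non-degenerate triangle sum to pi.
// [[Rcpp::export]]
NumericMatrix tri_angles_cpp(IntegerMatrix tri, NumericMatrix pos) {
  int nt = tri.nrow();
  NumericMatrix ang(nt, 3);
  for (int t = 0; t < nt; ++t) {
    double px[3], py[3];
    for (int c = 0; c < 3; ++c) {
      px[c] = pos(tri(t, c) - 1, 0);
      py[c] = pos(tri(t, c) - 1, 1);
    }
    for (int c = 0; c < 3; ++c) {
      int u = (c + 1) % 3, v = (c + 2) % 3;
      double ax = px[u] - px[c], ay = py[u] - py[c];
      double bx = px[v] - px[c], by = py[v] - py[c];
      double dot = ax * bx + ay * by;
      double crs = std::fabs(ax * by - ay * bx);
      ang(t, c) = std::atan2(crs, dot);
    }
  }
  return ang;
}

// Ray-crossing point-in-polygon test for a batch of query points.
// Points on the boundary may land on either side; callers treat the test as
// open-region membership.
// [[Rcpp::export]]
LogicalVector points_in_polygon_cpp(NumericVector px, NumericVector py,
                                    NumericVector vx, NumericVector vy) {
  int np = px.size(), nv = vx.size();
  LogicalVector inside(np);
  for (int q = 0; q < np; ++q) {
    bool in = false;
    double x = px[q], y = py[q];
    for (int i = 0, j = nv - 1; i < nv; j = i++) {
      if (((vy[i] > y) != (vy[j] > y)) &&
          (x < (vx[j] - vx[i]) * (y - vy[i]) / (vy[j] - vy[i]) + vx[i]))
        in = !in;
    }
    inside[q] = in;
  }
  return inside;
}

static inline double orient(double ax, double ay, double bx, double by,
                            double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

static bool seg_intersect(double p1x, double p1y, double p2x, double p2y,
                          double q1x, double q1y, double q2x, double q2y) {
  double d1 = orient(q1x, q1y, q2x, q2y, p1x, p1y);
  double d2 = orient(q1x, q1y, q2x, q2y, p2x, p2y);
  double d3 = orient(p1x, p1y, p2x, p2y, q1x, q1y);
  double d4 = orient(p1x, p1y, p2x, p2y, q2x, q2y);
  return ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
         ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0));
}

// Simple-polygon check: no two non-adjacent edges properly intersect.
// [[Rcpp::export]]
bool polygon_is_simple_cpp(NumericVector vx, NumericVector vy) {
  int n = vx.size();
  for (int i = 0; i < n; ++i) {
    int i2 = (i + 1) % n;
    for (int j = i + 2; j < n; ++j) {
      int j2 = (j + 1) % n;
      if (i == j2 % n || i2 == j) continue;   // adjacent edges share a vertex
      if (i == 0 && j2 == 0) continue;        // first and last edge are adjacent
      if (seg_intersect(vx[i], vy[i], vx[i2], vy[i2],
                        vx[j], vy[j], vx[j2], vy[j2]))
        return false;
    }
  }
  return true;
}
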