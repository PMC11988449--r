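#include <Rcpp.h>
#include <queue>
#include <cmath>
using namespace Rcpp;

// Overdamped Langevin (Euler-Maruyama) on a sum-of-inverted-Gaussians
// potential with quadratic confinement:
//   U(x) = 0.5 * kconf * |x|^2 - sum_j A_j exp(-|x - c_j|^2 / (2 w_j^2))
// Noise is drawn from R's RNG so set.seed() upstream gives bit-exact replay.
// [[Rcpp::export]]
NumericMatrix bd_integrate(NumericMatrix centers, NumericVector depths,
                           NumericVector widths, double kconf,
                           NumericVector x0, int n_steps, double dt,
                           double kT) {
  const int dim = x0.size();
  const int nw = centers.nrow();
  NumericMatrix out(n_steps + 1, dim);
  std::vector<double> x(dim);
  for (int d = 0; d < dim; ++d) {
    x[d] = x0[d];
    out(0, d) = x[d];
  }
  const double noise_sd = std::sqrt(2.0 * kT * dt);
  std::vector<double> f(dim);
  for (int t = 1; t <= n_steps; ++t) {
    for (int d = 0; d < dim; ++d) f[d] = -kconf * x[d];
    for (int j = 0; j < nw; ++j) {
      double r2 = 0.0;
      for (int d = 0; d < dim; ++d) {
        const double dx = x[d] - centers(j, d);
        r2 += dx * dx;
      }
      const double w2 = widths[j] * widths[j];
      const double g = depths[j] * std::exp(-r2 / (2.0 * w2)) / w2;
      for (int d = 0; d < dim; ++d) f[d] -= g * (x[d] - centers(j, d));
    }
    NumericVector eta = rnorm(dim, 0.0, noise_sd);
    for (int d = 0; d < dim; ++d) {
      if (!std::isfinite(f[d]))
        stop("non-finite force at step %d, coordinate %d (x = %f)", t, d + 1,
             x[d]);
      x[d] += f[d] * dt + eta[d];
      out(t, d) = x[d];
    }
  }
  return out;
}

// Sample a discrete-time Markov chain with transition matrix T (row
// stochastic) from state s0 (0-based), using R's RNG.
// [[Rcpp::export]]
IntegerVector sample_markov_chain(NumericMatrix T, int n_steps, int s0) {
  const int n = T.nrow();
  IntegerVector out(n_steps + 1);
  int s = s0;
  out[0] = s;
  for (int t = 1; t <= n_steps; ++t) {
    const double u = unif_rand();
    double acc = 0.0;
    int nxt = n - 1;
    for (int j = 0; j < n; ++j) {
      acc += T(s, j);
      if (u < acc) { nxt = j; break; }
    }
    s = nxt;
    out[t] = s;
  }
  return out;
}

// Clearance field: for every voxel centre v, min over atoms of
// (|v - centre_i| - radius_i). Negative inside an atom. Voxel index runs
// x fastest, then y, then z (R array order).
// [[Rcpp::export]]
NumericVector grid_clearance_cpp(NumericMatrix atoms, NumericVector radii,
                                 NumericVector origin, IntegerVector dims,
                                 double spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int natom = atoms.nrow();
  NumericVector out((R_xlen_t)nx * ny * nz);
  R_xlen_t v = 0;
  for (int k = 0; k < nz; ++k) {
    const double z = origin[2] + k * spacing;
    for (int j = 0; j < ny; ++j) {
      const double y = origin[1] + j * spacing;
      for (int i = 0; i < nx; ++i, ++v) {
        const double x = origin[0] + i * spacing;
        double best = R_PosInf;
        for (int a = 0; a < natom; ++a) {
          const double dx = x - atoms(a, 0);
          const double dy = y - atoms(a, 1);
          const double dz = z - atoms(a, 2);
          const double c =
              std::sqrt(dx * dx + dy * dy + dz * dz) - radii[a];
          if (c < best) best = c;
        }
        out[v] = best;
      }
    }
  }
  return out;
}

// Breadth-first flood fill over the 6-connected voxel graph restricted to
// clearance >= thr. Seeds are 0-based voxel indices. Returns a logical
// reachability mask.
// [[Rcpp::export]]
LogicalVector grid_flood_cpp(NumericVector clearance, IntegerVector dims,
                             double thr, IntegerVector seeds) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector seen(n, false);
  std::queue<R_xlen_t> q;
  for (int s = 0; s < seeds.size(); ++s) {
    const R_xlen_t v = seeds[s];
    if (v >= 0 && v < n && clearance[v] >= thr && !seen[v]) {
      seen[v] = true;
      q.push(v);
    }
  }
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  while (!q.empty()) {
    const R_xlen_t v = q.front();
    q.pop();
    const int i = v % nx, j = (v / nx) % ny, k = v / sz;
    const R_xlen_t nb[6] = {v - sx, v + sx, v - sy, v + sy, v - sz, v + sz};
    const bool ok[6] = {i > 0, i < nx - 1, j > 0, j < ny - 1, k > 0,
                        k < nz - 1};
    for (int m = 0; m < 6; ++m) {
      if (ok[m] && !seen[nb[m]] && clearance[nb[m]] >= thr) {
        seen[nb[m]] = true;
        q.push(nb[m]);
      }
    }
  }
  return seen;
}

// BFS shortest path (in voxel steps) from start to the nearest target voxel,
// restricted to clearance >= thr. Returns the 0-based voxel path, or an
// empty vector if no target is reachable.
// [[Rcpp::export]]
IntegerVector grid_bfs_path_cpp(NumericVector clearance, IntegerVector dims,
                                double thr, int start,
                                LogicalVector is_target) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (start < 0 || start >= n || clearance[start] < thr)
    return IntegerVector(0);
  std::vector<R_xlen_t> parent(n, -2); // -2 unseen, -1 root
  std::queue<R_xlen_t> q;
  parent[start] = -1;
  q.push(start);
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  R_xlen_t hit = -1;
  if (is_target[start]) hit = start;
  while (hit < 0 && !q.empty()) {
    const R_xlen_t v = q.front();
    q.pop();
    const int i = v % nx, j = (v / nx) % ny, k = v / sz;
    const R_xlen_t nb[6] = {v - sx, v + sx, v - sy, v + sy, v - sz, v + sz};
    const bool ok[6] = {i > 0, i < nx - 1, j > 0, j < ny - 1, k > 0,
                        k < nz - 1};
    for (int m = 0; m < 6 && hit < 0; ++m) {
      if (ok[m] && parent[nb[m]] == -2 && clearance[nb[m]] >= thr) {
        parent[nb[m]] = v;
        if (is_target[nb[m]]) hit = nb[m];
        q.push(nb[m]);
      }
    }
  }
  if (hit < 0) return IntegerVector(0);
  std::vector<int> path;
  for (R_xlen_t v = hit; v != -1; v = parent[v]) path.push_back((int)v);
  std::reverse(path.begin(), path.end());
  return wrap(path);
}
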