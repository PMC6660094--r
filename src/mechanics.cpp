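// Center-based mechanics: pairwise Hookean repulsion/adhesion between cell
// spheres, overdamped explicit-Euler relaxation, and uniform-grid neighbor
// search.  Forces are expressed in units of the damping coefficient eta, so
// stiffnesses have units 1/h and dt * k is the dimensionless relaxation
// factor per sub-step.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Grid {
  double cell;
  double x0, y0, z0;
  int64_t nx, ny;
  std::unordered_map<int64_t, std::vector<int> > bins;

  Grid(const NumericMatrix& pos, double cell_size) : cell(cell_size) {
    const int n = pos.nrow();
    x0 = y0 = z0 = R_PosInf;
    for (int i = 0; i < n; ++i) {
      if (pos(i, 0) < x0) x0 = pos(i, 0);
      if (pos(i, 1) < y0) y0 = pos(i, 1);
      if (pos(i, 2) < z0) z0 = pos(i, 2);
    }
    double xmax = R_NegInf, ymax = R_NegInf;
    for (int i = 0; i < n; ++i) {
      if (pos(i, 0) > xmax) xmax = pos(i, 0);
      if (pos(i, 1) > ymax) ymax = pos(i, 1);
    }
    nx = (int64_t)std::floor((xmax - x0) / cell) + 3;
    ny = (int64_t)std::floor((ymax - y0) / cell) + 3;
    bins.reserve((size_t)(2 * n));
    for (int i = 0; i < n; ++i) bins[key_of(pos, i)].push_back(i);
  }

  int64_t key(int64_t ix, int64_t iy, int64_t iz) const {
    return ix + nx * (iy + ny * iz);
  }

  int64_t key_of(const NumericMatrix& pos, int i) const {
    int64_t ix = (int64_t)std::floor((pos(i, 0) - x0) / cell);
    int64_t iy = (int64_t)std::floor((pos(i, 1) - y0) / cell);
    int64_t iz = (int64_t)std::floor((pos(i, 2) - z0) / cell);
    return key(ix, iy, iz);
  }

  // visit all unordered pairs (i < j) whose centers are within `cell` of
  // each other (plus grid slack); callback receives (i, j, dist2)
  template <class F>
  void for_pairs(const NumericMatrix& pos, F fun) const {
    const double cut2 = cell * cell;
    for (const auto& kv : bins) {
      const std::vector<int>& a = kv.second;
      // decode bin coords back from the key
      int64_t k = kv.first;
      int64_t ix = k % nx, rest = k / nx;
      int64_t iy = rest % ny, iz = rest / ny;
      // within-bin pairs
      for (size_t p = 0; p < a.size(); ++p)
        for (size_t q = p + 1; q < a.size(); ++q)
          maybe_call(pos, a[p], a[q], cut2, fun);
      // half of the 26 neighbor bins to avoid double counting
      static const int off[13][3] = {
        {1,0,0},{0,1,0},{0,0,1},{1,1,0},{1,-1,0},{1,0,1},{1,0,-1},
        {0,1,1},{0,1,-1},{1,1,1},{1,1,-1},{1,-1,1},{1,-1,-1}};
      for (int o = 0; o < 13; ++o) {
        auto it = bins.find(key(ix + off[o][0], iy + off[o][1], iz + off[o][2]));
        if (it == bins.end()) continue;
        for (int i : a)
          for (int j : it->second)
            maybe_call(pos, i, j, cut2, fun);
      }
    }
  }

  template <class F>
  static void maybe_call(const NumericMatrix& pos, int i, int j,
                         double cut2, F fun) {
    const double dx = pos(i, 0) - pos(j, 0);
    const double dy = pos(i, 1) - pos(j, 1);
    const double dz = pos(i, 2) - pos(j, 2);
    const double d2 = dx * dx + dy * dy + dz * dz;
    if (d2 < cut2) fun(i, j, d2);
  }
};

// accumulate spring forces (units of eta) into fx/fy/fz; returns number of
// coincident-center pairs resolved with a random direction
int accumulate_forces(const NumericMatrix& pos, const NumericVector& radius,
                      double rmax, double k_rep, double k_adh,
                      std::vector<double>& fx, std::vector<double>& fy,
                      std::vector<double>& fz) {
  const double cutoff = 2.25 * rmax;
  int n_coincident = 0;
  Grid grid(pos, cutoff);
  grid.for_pairs(pos, [&](int i, int j, double d2) {
    const double d = std::sqrt(d2);
    const double rsum = radius[i] + radius[j];
    double mag = 0.0;              // signed magnitude along (Xi - Xj)/d
    if (d < rsum) {
      mag = k_rep * (rsum - d);    // repulsive, pushes i away from j
    } else if (d > 2.0 * rmax && d < 2.25 * rmax) {
      mag = k_adh * (2.0 * rmax - d);  // negative: attractive
    } else {
      return;
    }
    double ux, uy, uz;
    if (d < 1e-12) {
      // coincident centers: direction undefined, draw a random unit vector
      // from R's RNG stream so the resolution is seed-reproducible
      ++n_coincident;
      double gx = R::norm_rand(), gy = R::norm_rand(), gz = R::norm_rand();
      double g = std::sqrt(gx * gx + gy * gy + gz * gz);
      if (g < 1e-12) { gx = 1.0; gy = gz = 0.0; g = 1.0; }
      ux = gx / g; uy = gy / g; uz = gz / g;
      mag = k_rep * rsum;
    } else {
      ux = (pos(i, 0) - pos(j, 0)) / d;
      uy = (pos(i, 1) - pos(j, 1)) / d;
      uz = (pos(i, 2) - pos(j, 2)) / d;
    }
    fx[i] += mag * ux; fy[i] += mag * uy; fz[i] += mag * uz;
    fx[j] -= mag * ux; fy[j] -= mag * uy; fz[j] -= mag * uz;
  });
  return n_coincident;
}

}  // namespace

// [[Rcpp::export(name = ".osim_net_forces")]]
NumericMatrix osim_net_forces(NumericMatrix pos, NumericVector radius,
                              double rmax, double k_rep, double k_adh) {
  const int n = pos.nrow();
  std::vector<double> fx(n, 0.0), fy(n, 0.0), fz(n, 0.0);
  RNGScope scope;
  accumulate_forces(pos, radius, rmax, k_rep, k_adh, fx, fy, fz);
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = fx[i]; out(i, 1) = fy[i]; out(i, 2) = fz[i];
  }
  return out;
}

// [[Rcpp::export(name = ".osim_relax")]]
List osim_relax(NumericMatrix pos, NumericVector radius, double rmax,
                double k_rep, double k_adh, double dt, double tol,
                int max_substeps) {
  const int n = pos.nrow();
  NumericMatrix x = clone(pos);
  RNGScope scope;
  int substeps = 0, n_coincident = 0;
  bool converged = false;
  std::vector<double> fx(n), fy(n), fz(n);
  while (substeps < max_substeps) {
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    std::fill(fz.begin(), fz.end(), 0.0);
    n_coincident += accumulate_forces(x, radius, rmax, k_rep, k_adh, fx, fy, fz);
    double maxdisp2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const double ddx = dt * fx[i], ddy = dt * fy[i], ddz = dt * fz[i];
      x(i, 0) += ddx; x(i, 1) += ddy; x(i, 2) += ddz;
      const double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (d2 > maxdisp2) maxdisp2 = d2;
    }
    ++substeps;
    if (std::sqrt(maxdisp2) < tol) { converged = true; break; }
  }
  return List::create(_["positions"] = x, _["substeps"] = substeps,
                      _["converged"] = converged,
                      _["n_coincident"] = n_coincident);
}

// [[Rcpp::export(name = ".osim_count_neighbors")]]
IntegerVector osim_count_neighbors(NumericMatrix pos, double cutoff) {
  const int n = pos.nrow();
  IntegerVector counts(n);
  if (n == 0) return counts;
  Grid grid(pos, cutoff);
  grid.for_pairs(pos, [&](int i, int j, double) {
    // strict inequality: a neighbor at exactly `cutoff` is not counted;
    // Grid::maybe_call already tests d2 < cutoff^2
    ++counts[i];
    ++counts[j];
  });
  return counts;
}

// [[Rcpp::export(name = ".osim_pairs_within")]]
IntegerMatrix osim_pairs_within(NumericMatrix pos, double cutoff) {
  const int n = pos.nrow();
  std::vector<int> ii, jj;
  if (n > 1) {
    Grid grid(pos, cutoff);
    grid.for_pairs(pos, [&](int i, int j, double) {
      ii.push_back(i < j ? i : j);
      jj.push_back(i < j ? j : i);
    });
  }
  IntegerMatrix out(ii.size(), 2);
  for (size_t k = 0; k < ii.size(); ++k) {
    out(k, 0) = ii[k] + 1;  // 1-based for R
    out(k, 1) = jj[k] + 1;
  }
  return out;
}

// [[Rcpp::export(name = ".osim_count_neighbors_vec")]]
IntegerVector osim_count_neighbors_vec(NumericMatrix pos,
                                       NumericVector cutoffs) {
  const int n = pos.nrow();
  IntegerVector counts(n);
  if (n < 2) return counts;
  double cmax = 0.0;
  for (int i = 0; i < n; ++i) if (cutoffs[i] > cmax) cmax = cutoffs[i];
  Grid grid(pos, cmax);
  grid.for_pairs(pos, [&](int i, int j, double d2) {
    if (d2 < cutoffs[i] * cutoffs[i]) ++counts[i];
    if (d2 < cutoffs[j] * cutoffs[j]) ++counts[j];
  });
  return counts;
}
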