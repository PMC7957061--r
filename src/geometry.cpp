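// Voxel coverage: fraction of target-segment surface voxels with an
// astrocyte voxel within a contact distance along face-connected paths
// through the ECS. Distances are anisotropic (per-axis pitch); the distance
// field is computed by chamfer-style relaxation sweeps restricted to the
// ECS mask, iterated to convergence (the contact budget bounds the needed
// path length, so a handful of sweeps suffice).

#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// [[Rcpp::export]]
double coverage_cpp(IntegerVector labels, IntegerVector dim,
                    NumericVector pitch, int target_id, int astro_id,
                    int ecs_id, double contact_nm) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const long N = (long)nx * ny * nz;
  const int* lab = labels.begin();
  const double px = pitch[0], py = pitch[1], pz = pitch[2];
  const double INF = std::numeric_limits<double>::infinity();
  auto at = [&](int i, int j, int k) -> long {
    return i + (long)nx * (j + (long)ny * k);
  };

  // d = 0 for ECS voxels face-adjacent to astrocyte
  std::vector<double> d(N, INF);
  bool any_astro = false;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long v = at(i, j, k);
        if (lab[v] != ecs_id) continue;
        bool adj =
          (i > 0 && lab[at(i - 1, j, k)] == astro_id) ||
          (i < nx - 1 && lab[at(i + 1, j, k)] == astro_id) ||
          (j > 0 && lab[at(i, j - 1, k)] == astro_id) ||
          (j < ny - 1 && lab[at(i, j + 1, k)] == astro_id) ||
          (k > 0 && lab[at(i, j, k - 1)] == astro_id) ||
          (k < nz - 1 && lab[at(i, j, k + 1)] == astro_id);
        if (adj) { d[v] = 0.0; any_astro = true; }
      }

  int max_sweeps = (int)(contact_nm / std::min(px, std::min(py, pz))) + 2;
  for (int sweep = 0; sweep < max_sweeps && any_astro; ++sweep) {
    bool changed = false;
    // forward pass
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          long v = at(i, j, k);
          if (lab[v] != ecs_id || d[v] == 0.0) continue;
          double best = d[v];
          if (i > 0 && d[at(i - 1, j, k)] + px < best) best = d[at(i - 1, j, k)] + px;
          if (j > 0 && d[at(i, j - 1, k)] + py < best) best = d[at(i, j - 1, k)] + py;
          if (k > 0 && d[at(i, j, k - 1)] + pz < best) best = d[at(i, j, k - 1)] + pz;
          if (best < d[v]) { d[v] = best; changed = true; }
        }
    // backward pass
    for (int k = nz - 1; k >= 0; --k)
      for (int j = ny - 1; j >= 0; --j)
        for (int i = nx - 1; i >= 0; --i) {
          long v = at(i, j, k);
          if (lab[v] != ecs_id || d[v] == 0.0) continue;
          double best = d[v];
          if (i < nx - 1 && d[at(i + 1, j, k)] + px < best) best = d[at(i + 1, j, k)] + px;
          if (j < ny - 1 && d[at(i, j + 1, k)] + py < best) best = d[at(i, j + 1, k)] + py;
          if (k < nz - 1 && d[at(i, j, k + 1)] + pz < best) best = d[at(i, j, k + 1)] + pz;
          if (best < d[v]) { d[v] = best; changed = true; }
        }
    if (!changed) break;
  }

  long n_surf = 0, n_cov = 0;
  const double steps[3] = {px, py, pz};
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long v = at(i, j, k);
        if (lab[v] != target_id) continue;
        long nb[6];
        int nax[6];
        int nn = 0;
        if (i > 0)      { nb[nn] = at(i - 1, j, k); nax[nn++] = 0; }
        if (i < nx - 1) { nb[nn] = at(i + 1, j, k); nax[nn++] = 0; }
        if (j > 0)      { nb[nn] = at(i, j - 1, k); nax[nn++] = 1; }
        if (j < ny - 1) { nb[nn] = at(i, j + 1, k); nax[nn++] = 1; }
        if (k > 0)      { nb[nn] = at(i, j, k - 1); nax[nn++] = 2; }
        if (k < nz - 1) { nb[nn] = at(i, j, k + 1); nax[nn++] = 2; }
        bool surf = false, cov = false;
        for (int t = 0; t < nn; ++t) {
          int nl = lab[nb[t]];
          if (nl != target_id) surf = true;
          if (nl == astro_id) cov = true;
          else if (nl == ecs_id &&
                   steps[nax[t]] + d[nb[t]] <= contact_nm) cov = true;
        }
        if (surf) { ++n_surf; if (cov) ++n_cov; }
      }
  if (n_surf == 0) return 0.0;
  return (double)n_cov / (double)n_surf;
}

// Exposed-face count and anisotropic area of the voxel set labelled `id`;
// sample-boundary faces are not counted.
// [[Rcpp::export]]
List surface_cpp(IntegerVector labels, IntegerVector dim, NumericVector pitch,
                 int id) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int* lab = labels.begin();
  const double ax = pitch[1] * pitch[2], ay = pitch[0] * pitch[2],
               az = pitch[0] * pitch[1];
  auto at = [&](int i, int j, int k) -> long {
    return i + (long)nx * (j + (long)ny * k);
  };
  double area = 0.0;
  long faces = 0, nvox = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        if (lab[at(i, j, k)] != id) continue;
        ++nvox;
        if (i > 0 && lab[at(i - 1, j, k)] != id) { area += ax; ++faces; }
        if (i < nx - 1 && lab[at(i + 1, j, k)] != id) { area += ax; ++faces; }
        if (j > 0 && lab[at(i, j - 1, k)] != id) { area += ay; ++faces; }
        if (j < ny - 1 && lab[at(i, j + 1, k)] != id) { area += ay; ++faces; }
        if (k > 0 && lab[at(i, j, k - 1)] != id) { area += az; ++faces; }
        if (k < nz - 1 && lab[at(i, j, k + 1)] != id) { area += az; ++faces; }
      }
  return List::create(_["n_faces"] = (double)faces, _["area_nm2"] = area,
                      _["n_voxels"] = (double)nvox);
}
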