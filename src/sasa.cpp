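#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley test-point SASA.
//
// xyz: n x 3 atom coordinates (Angstrom)
// rad: n extended radii (vdW + probe)
// pts: m x 3 unit-sphere test directions (deterministic golden spiral,
//      generated in R so the point rule is shared with the pure-R oracle)
//
// A test point on atom i's extended sphere is accessible when it lies
// outside every other atom's extended sphere.  SASA_i = 4 pi r_i^2 *
// (accessible / m).  Neighbour search is the plain O(n^2) scan; inputs
// here are single chains or small complexes, not whole crystals.
// [[Rcpp::export]]
NumericVector sasa_kernel(NumericMatrix xyz, NumericVector rad,
                          NumericMatrix pts) {
  const int n = xyz.nrow(), m = pts.nrow();
  NumericVector out(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    const double ri = rad[i];
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = xi - xyz(j, 0);
      const double dy = yi - xyz(j, 1);
      const double dz = zi - xyz(j, 2);
      const double rr = ri + rad[j];
      if (dx * dx + dy * dy + dz * dz < rr * rr) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < m; ++k) {
      const double px = xi + ri * pts(k, 0);
      const double py = yi + ri * pts(k, 1);
      const double pz = zi + ri * pts(k, 2);
      bool accessible = true;
      for (size_t q = 0; q < nb.size(); ++q) {
        const int j = nb[q];
        const double dx = px - xyz(j, 0);
        const double dy = py - xyz(j, 1);
        const double dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz <= rad[j] * rad[j]) {
          accessible = false;
          break;
        }
      }
      if (accessible) ++acc;
    }
    out[i] = 4.0 * M_PI * ri * ri * static_cast<double>(acc) /
             static_cast<double>(m);
  }
  return out;
}
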