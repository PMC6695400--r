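#include <Rcpp.h>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area.
// xyz: n x 3 atom centres (angstrom); radii: per-atom van der Waals radii;
// probe: solvent probe radius; pts: m x 3 unit-sphere test points shared by
// all atoms (deterministic Fibonacci lattice, optionally re-oriented by the
// caller). Returns per-atom accessible area in angstrom^2.
// [[Rcpp::export(name = ".sasa_cpp")]]
NumericVector sasa_cpp(NumericMatrix xyz, NumericVector radii, double probe,
                       NumericMatrix pts) {
  const int n = xyz.nrow();
  const int m = pts.nrow();
  NumericVector area(n);
  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radii[i] + probe;

  std::vector<int> nb;
  nb.reserve(64);
  for (int i = 0; i < n; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    const double Ri = R[i];
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi,
                   dz = xyz(j, 2) - zi;
      const double lim = Ri + R[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nb.push_back(j);
    }
    int acc = 0;
    for (int p = 0; p < m; ++p) {
      const double qx = xi + Ri * pts(p, 0);
      const double qy = yi + Ri * pts(p, 1);
      const double qz = zi + Ri * pts(p, 2);
      bool free_pt = true;
      for (size_t k = 0; k < nb.size(); ++k) {
        const int j = nb[k];
        const double dx = qx - xyz(j, 0), dy = qy - xyz(j, 1),
                     dz = qz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < R[j] * R[j]) {
          free_pt = false;
          break;
        }
      }
      if (free_pt) ++acc;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * ((double)acc / (double)m);
  }
  return area;
}
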