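#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shrake-Rupley point-sampling SASA. `pts` holds unit-sphere directions
// (n_points x 3); per-atom area = exposed-point fraction times the expanded
// sphere area 4*pi*(r_vdw + probe)^2. Neighbor lists are built with a plain
// O(n^2) sweep, which is ample at the structure sizes this package handles.

// [[Rcpp::export(name = ".sasa_kernel")]]
NumericVector sasa_kernel(NumericMatrix xyz, NumericVector radii,
                          double probe, NumericMatrix pts) {
  const int n = xyz.nrow();
  const int m = pts.nrow();
  NumericVector area(n);
  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radii[i] + probe;

  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi,
                   dz = xyz(j, 2) - zi;
      const double s = R[i] + R[j];
      if (dx * dx + dy * dy + dz * dz < s * s) nb.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < m; ++k) {
      const double px = xi + R[i] * pts(k, 0);
      const double py = yi + R[i] * pts(k, 1);
      const double pz = zi + R[i] * pts(k, 2);
      bool buried = false;
      for (size_t t = 0; t < nb.size(); ++t) {
        const int j = nb[t];
        const double dx = px - xyz(j, 0), dy = py - xyz(j, 1),
                     dz = pz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < R[j] * R[j]) {
          buried = true;
          break;
        }
      }
      if (!buried) ++exposed;
    }
    area[i] = 4.0 * M_PI * R[i] * R[i] * exposed / static_cast<double>(m);
  }
  return area;
}
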