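#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Alpha-sphere enumeration: every 4-atom subset whose circumsphere has a
// radius inside [rmin, rmax] and contains no other heavy atom strictly
// inside (distance < radius - tol). In general position this is exactly
// the set of Delaunay-tetrahedron circumspheres in the radius window, so
// candidates are pruned to locally close quadruples: all four atoms must
// be pairwise within 2*rmax of each other.

static inline double dist2(const double* x, const double* y,
                           const double* z, int i, int j) {
  double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
  return dx * dx + dy * dy + dz * dz;
}

// [[Rcpp::export(name = "cpp_alpha_spheres")]]
List cpp_alpha_spheres(NumericMatrix xyz, double rmin, double rmax,
                       double tol) {
  const int n = xyz.nrow();
  std::vector<double> X(n), Y(n), Z(n), S(n);
  for (int i = 0; i < n; ++i) {
    X[i] = xyz(i, 0); Y[i] = xyz(i, 1); Z[i] = xyz(i, 2);
    S[i] = X[i] * X[i] + Y[i] * Y[i] + Z[i] * Z[i];
  }
  const double* x = X.data();
  const double* y = Y.data();
  const double* z = Z.data();
  const double dmax2 = 4.0 * rmax * rmax;
  const double rmin2 = rmin * rmin, rmax2 = rmax * rmax;

  // neighbour lists (j > i within 2*rmax)
  std::vector< std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (dist2(x, y, z, i, j) <= dmax2) nb[i].push_back(j);

  std::vector<double> cx, cy, cz, rr;
  std::vector<int> A1, A2, A3, A4;

  for (int i = 0; i < n; ++i) {
    const std::vector<int>& ni = nb[i];
    const int m = (int) ni.size();
    for (int a = 0; a < m; ++a) {
      const int j = ni[a];
      for (int b = a + 1; b < m; ++b) {
        const int k = ni[b];
        if (dist2(x, y, z, j, k) > dmax2) continue;
        for (int c = b + 1; c < m; ++c) {
          const int l = ni[c];
          if (dist2(x, y, z, j, l) > dmax2) continue;
          if (dist2(x, y, z, k, l) > dmax2) continue;
          // circumcenter: 2 (p_q - p_i) . c = |p_q|^2 - |p_i|^2, q = j,k,l
          const double a11 = 2.0 * (x[j] - x[i]), a12 = 2.0 * (y[j] - y[i]),
                       a13 = 2.0 * (z[j] - z[i]);
          const double a21 = 2.0 * (x[k] - x[i]), a22 = 2.0 * (y[k] - y[i]),
                       a23 = 2.0 * (z[k] - z[i]);
          const double a31 = 2.0 * (x[l] - x[i]), a32 = 2.0 * (y[l] - y[i]),
                       a33 = 2.0 * (z[l] - z[i]);
          const double b1 = S[j] - S[i], b2 = S[k] - S[i], b3 = S[l] - S[i];
          const double det = a11 * (a22 * a33 - a23 * a32)
                           - a12 * (a21 * a33 - a23 * a31)
                           + a13 * (a21 * a32 - a22 * a31);
          if (std::fabs(det) < 1e-9) continue;  // (near-)coplanar quadruple
          const double ccx = (b1 * (a22 * a33 - a23 * a32)
                            - a12 * (b2 * a33 - a23 * b3)
                            + a13 * (b2 * a32 - a22 * b3)) / det;
          const double ccy = (a11 * (b2 * a33 - a23 * b3)
                            - b1 * (a21 * a33 - a23 * a31)
                            + a13 * (a21 * b3 - b2 * a31)) / det;
          const double ccz = (a11 * (a22 * b3 - b2 * a32)
                            - a12 * (a21 * b3 - b2 * a31)
                            + b1 * (a21 * a32 - a22 * a31)) / det;
          const double dx = ccx - x[i], dy = ccy - y[i], dz = ccz - z[i];
          const double r2 = dx * dx + dy * dy + dz * dz;
          if (r2 < rmin2 || r2 > rmax2) continue;
          const double r = std::sqrt(r2);
          const double rin = r - tol;
          const double rin2 = rin > 0 ? rin * rin : 0.0;
          // emptiness against all other atoms
          bool empty = true;
          for (int q = 0; q < n; ++q) {
            if (q == i || q == j || q == k || q == l) continue;
            const double qx = ccx - x[q], qy = ccy - y[q], qz = ccz - z[q];
            if (qx * qx + qy * qy + qz * qz < rin2) { empty = false; break; }
          }
          if (!empty) continue;
          cx.push_back(ccx); cy.push_back(ccy); cz.push_back(ccz);
          rr.push_back(r);
          A1.push_back(i + 1); A2.push_back(j + 1);
          A3.push_back(k + 1); A4.push_back(l + 1);
        }
      }
    }
  }
  return List::create(
    _["x"] = wrap(cx), _["y"] = wrap(cy), _["z"] = wrap(cz),
    _["radius"] = wrap(rr),
    _["a1"] = wrap(A1), _["a2"] = wrap(A2),
    _["a3"] = wrap(A3), _["a4"] = wrap(A4));
}
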