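// Pair searching under orthorhombic periodic boundary conditions.
// pbc_z = false gives slab (xy-only) imaging. Minimum-image convention:
// each displacement component is wrapped into (-L/2, L/2] for periodic axes.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double wrap(double d, double L) {
  if (L <= 0.0) return d;
  d -= L * std::round(d / L);
  return d;
}

// All unordered pairs (i < j) within `cutoff`; returns displacement r_j - r_i
// (minimum image) and distance.
//' @noRd
// [[Rcpp::export(name = ".pairs_within_cpp")]]
List pairs_within_cpp(NumericMatrix pos, NumericVector box, bool pbc_z,
                      double cutoff) {
  int n = pos.nrow();
  double c2 = cutoff * cutoff;
  std::vector<int> I, J;
  std::vector<double> DX, DY, DZ, D;
  for (int i = 0; i < n; ++i) {
    double xi = pos(i,0), yi = pos(i,1), zi = pos(i,2);
    for (int j = i + 1; j < n; ++j) {
      double dx = wrap(pos(j,0) - xi, box[0]);
      double dy = wrap(pos(j,1) - yi, box[1]);
      double dz = pos(j,2) - zi;
      if (pbc_z) dz = wrap(dz, box[2]);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 <= c2) {
        I.push_back(i + 1); J.push_back(j + 1);
        DX.push_back(dx); DY.push_back(dy); DZ.push_back(dz);
        D.push_back(std::sqrt(d2));
      }
    }
  }
  return List::create(_["i"] = wrap(I), _["j"] = wrap(J),
                      _["dx"] = wrap(DX), _["dy"] = wrap(DY),
                      _["dz"] = wrap(DZ), _["d"] = wrap(D));
}

// Ordered cross-set pairs within `cutoff` between rows of A and rows of B.
//' @noRd
// [[Rcpp::export(name = ".cross_pairs_within_cpp")]]
List cross_pairs_within_cpp(NumericMatrix A, NumericMatrix B,
                            NumericVector box, bool pbc_z, double cutoff) {
  int na = A.nrow(), nb = B.nrow();
  double c2 = cutoff * cutoff;
  std::vector<int> I, J;
  std::vector<double> DX, DY, DZ, D;
  for (int i = 0; i < na; ++i) {
    double xi = A(i,0), yi = A(i,1), zi = A(i,2);
    for (int j = 0; j < nb; ++j) {
      double dx = wrap(B(j,0) - xi, box[0]);
      double dy = wrap(B(j,1) - yi, box[1]);
      double dz = B(j,2) - zi;
      if (pbc_z) dz = wrap(dz, box[2]);
      double d2 = dx*dx + dy*dy + dz*dz;
      if (d2 <= c2) {
        I.push_back(i + 1); J.push_back(j + 1);
        DX.push_back(dx); DY.push_back(dy); DZ.push_back(dz);
        D.push_back(std::sqrt(d2));
      }
    }
  }
  return List::create(_["i"] = wrap(I), _["j"] = wrap(J),
                      _["dx"] = wrap(DX), _["dy"] = wrap(DY),
                      _["dz"] = wrap(DZ), _["d"] = wrap(D));
}

// Random sequential insertion of points with a hard minimum-distance
// constraint under PBC; uses the R RNG (set.seed reproducible).
//' @noRd
// [[Rcpp::export(name = ".rsa_insert_cpp")]]
NumericMatrix rsa_insert_cpp(int n, NumericVector box, bool pbc_z,
                             double min_dist, NumericVector zrange,
                             int max_tries) {
  NumericMatrix out(n, 3);
  double m2 = min_dist * min_dist;
  double z0 = zrange[0], z1 = zrange[1];
  for (int k = 0; k < n; ++k) {
    bool placed = false;
    for (int t = 0; t < max_tries; ++t) {
      double x = R::runif(0.0, box[0]);
      double y = R::runif(0.0, box[1]);
      double z = R::runif(z0, z1);
      bool ok = true;
      for (int j = 0; j < k; ++j) {
        double dx = wrap(out(j,0) - x, box[0]);
        double dy = wrap(out(j,1) - y, box[1]);
        double dz = out(j,2) - z;
        if (pbc_z) dz = wrap(dz, box[2]);
        if (dx*dx + dy*dy + dz*dz < m2) { ok = false; break; }
      }
      if (ok) {
        out(k,0) = x; out(k,1) = y; out(k,2) = z;
        placed = true;
        break;
      }
    }
    if (!placed)
      stop("density infeasible: random sequential insertion failed after %d "
           "attempts at point %d of %d", max_tries, k + 1, n);
  }
  return out;
}
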