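#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Intermolecular pair kernels used by the single-trajectory interaction
// energies.  Indices arrive 1-based from R.  Units: Angstrom, kcal/mol, e.

static inline double dist3(const NumericMatrix &xyz, int i, int j) {
  double dx = xyz(i, 0) - xyz(j, 0);
  double dy = xyz(i, 1) - xyz(j, 1);
  double dz = xyz(i, 2) - xyz(j, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// [[Rcpp::export]]
double pairCoulombCpp(NumericMatrix xyz, NumericVector q,
                      IntegerVector ia, IntegerVector ib,
                      double cutoff, double dielectric, double ke) {
  double e = 0.0;
  for (int a = 0; a < ia.size(); ++a) {
    int i = ia[a] - 1;
    for (int b = 0; b < ib.size(); ++b) {
      int j = ib[b] - 1;
      double r = dist3(xyz, i, j);
      if (r < 1e-6)
        stop("singular geometry: atoms %d and %d coincide", i + 1, j + 1);
      if (r <= cutoff) e += ke * q[i] * q[j] / (dielectric * r);
    }
  }
  return e;
}

// [[Rcpp::export]]
double pairLJCpp(NumericMatrix xyz, NumericVector rminHalf,
                 NumericVector epsilon, IntegerVector ia, IntegerVector ib,
                 double cutoff) {
  double e = 0.0;
  for (int a = 0; a < ia.size(); ++a) {
    int i = ia[a] - 1;
    for (int b = 0; b < ib.size(); ++b) {
      int j = ib[b] - 1;
      double r = dist3(xyz, i, j);
      if (r < 1e-6)
        stop("singular geometry: atoms %d and %d coincide", i + 1, j + 1);
      if (r > cutoff) continue;
      double eps = std::sqrt(epsilon[i] * epsilon[j]);
      if (eps == 0.0) continue;
      double rmin = rminHalf[i] + rminHalf[j];
      double s6 = std::pow(rmin / r, 6.0);
      e += eps * (s6 * s6 - 2.0 * s6);
    }
  }
  return e;
}

// Effective Born radii by HCT pairwise descreening (the igb=1 analogue).
// rho: intrinsic radii; screen: screening factors; offset subtracted from
// every intrinsic radius before integration.  Returns -1 for a radius that
// comes out non-positive so the R wrapper can name the atom.
// [[Rcpp::export]]
NumericVector hctRadiiCpp(NumericMatrix xyz, NumericVector rho,
                          NumericVector screen, double offset) {
  int n = xyz.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double ri = rho[i] - offset;
    double I = 0.0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double sr = screen[j] * (rho[j] - offset);
      double r = dist3(xyz, i, j);
      double U = r + sr;
      if (ri >= U) continue;                       // fully outside
      double L = std::fabs(r - sr);
      if (ri > L) L = ri;
      double invL = 1.0 / L, invU = 1.0 / U;
      double term = 0.5 * ((invL - invU)
                    + 0.25 * r * (invU * invU - invL * invL)
                    + 0.5 / r * std::log(L / U)
                    + 0.25 * sr * sr / r * (invL * invL - invU * invU));
      if (ri < sr - r) term += (1.0 / ri - invL);  // atom engulfed by j
      I += term;
    }
    double inv = 1.0 / ri - I;
    out[i] = (inv > 0.0) ? 1.0 / inv : -1.0;
  }
  return out;
}

// GB polar solvation energy with the canonical smooth pair function
// f_GB = sqrt(r^2 + Ri*Rj*exp(-r^2/(4*Ri*Rj))); self terms use f_GB = Ri.
// [[Rcpp::export]]
double gbPairSumCpp(NumericMatrix xyz, NumericVector q, NumericVector reff,
                    double epsIn, double epsOut, double ke) {
  int n = xyz.nrow();
  double pref = -0.5 * ke * (1.0 / epsIn - 1.0 / epsOut);
  double s = 0.0;
  for (int i = 0; i < n; ++i) {
    s += q[i] * q[i] / reff[i];
    for (int j = i + 1; j < n; ++j) {
      double r = dist3(xyz, i, j);
      double rr = reff[i] * reff[j];
      double fgb = std::sqrt(r * r + rr * std::exp(-r * r / (4.0 * rr)));
      s += 2.0 * q[i] * q[j] / fgb;
    }
  }
  return pref * s;
}

// Shrake-Rupley SASA.  radii are vdW radii; each atom is sampled on a
// deterministic golden-spiral sphere of radius radii[i] + probe and a point
// is accessible when outside every neighbour's expanded sphere.
// [[Rcpp::export]]
NumericVector sasaCpp(NumericMatrix xyz, NumericVector radii, double probe,
                      int npoints) {
  int n = xyz.nrow();
  NumericVector area(n);
  std::vector<double> px(npoints), py(npoints), pz(npoints);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < npoints; ++k) {
    double z = 1.0 - 2.0 * (k + 0.5) / npoints;
    double rxy = std::sqrt(std::max(0.0, 1.0 - z * z));
    double th = golden * k;
    px[k] = rxy * std::cos(th);
    py[k] = rxy * std::sin(th);
    pz[k] = z;
  }
  for (int i = 0; i < n; ++i) {
    double ri = radii[i] + probe;
    // neighbour prefilter
    std::vector<int> nb;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double rj = radii[j] + probe;
      if (dist3(xyz, i, j) < ri + rj) nb.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < npoints; ++k) {
      double x = xyz(i, 0) + ri * px[k];
      double y = xyz(i, 1) + ri * py[k];
      double z = xyz(i, 2) + ri * pz[k];
      bool free = true;
      for (size_t m = 0; m < nb.size(); ++m) {
        int j = nb[m];
        double rj = radii[j] + probe;
        double dx = x - xyz(j, 0), dy = y - xyz(j, 1), dz = z - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < rj * rj) { free = false; break; }
      }
      if (free) ++acc;
    }
    area[i] = 4.0 * M_PI * ri * ri * (double)acc / (double)npoints;
  }
  return area;
}
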