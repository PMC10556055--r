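#include <Rcpp.h>
using namespace Rcpp;

// Coulomb prefactor, kJ mol^-1 nm e^-2
static const double F_COUL = 138.935458;

// LJ + Coulomb over inter-model bead pairs; B shifted by dx along +x.
// Coordinates in Angstrom; Coulomb term uses r in nm.
static void pair_energy(const NumericMatrix &A, const NumericMatrix &B,
                        const NumericVector &qA, const NumericVector &qB,
                        double dx, double sigma, double eps, double epsr,
                        double cutoff, double &elj, double &ecoul) {
  elj = 0.0;
  ecoul = 0.0;
  const double cut2 = cutoff * cutoff;
  const double sig2 = sigma * sigma;
  for (int i = 0; i < A.nrow(); ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < B.nrow(); ++j) {
      const double ddx = B(j, 0) + dx - ax;
      const double ddy = B(j, 1) - ay;
      const double ddz = B(j, 2) - az;
      const double r2 = ddx * ddx + ddy * ddy + ddz * ddz;
      if (r2 > cut2) continue;
      if (r2 < 0.01)
        stop("bead overlap: inter-bead distance below 0.1 angstrom");
      const double sr2 = sig2 / r2;
      const double sr6 = sr2 * sr2 * sr2;
      elj += 4.0 * eps * (sr6 * sr6 - sr6);
      const double qq = qA[i] * qB[j];
      if (qq != 0.0) ecoul += F_COUL * qq / (epsr * std::sqrt(r2) * 0.1);
    }
  }
}

// minimal surface separation min_ij (|a_i - (b_j + dx)| - ra_i - rb_j)
static double min_sep(const NumericMatrix &A, const NumericMatrix &B,
                      const NumericVector &rA, const NumericVector &rB,
                      double dx) {
  double best = R_PosInf;
  for (int i = 0; i < A.nrow(); ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2);
    for (int j = 0; j < B.nrow(); ++j) {
      const double ddx = B(j, 0) + dx - ax;
      const double ddy = B(j, 1) - ay;
      const double ddz = B(j, 2) - az;
      const double s =
          std::sqrt(ddx * ddx + ddy * ddy + ddz * ddz) - rA[i] - rB[j];
      if (s < best) best = s;
    }
  }
  return best;
}

// Bisect the x-offset of B until min surface separation equals `gap`.
// min_sep is 1-Lipschitz in dx, so an interval of width `tol` brackets the
// separation to within tol; the separated endpoint is returned.
static double contact_offset(const NumericMatrix &A, const NumericMatrix &B,
                             const NumericVector &rA, const NumericVector &rB,
                             double gap, double tol, int maxit) {
  double lo = 0.0;
  double hi_bound = 0.0;
  double mA = 0.0, mB = 0.0, rAmax = 0.0, rBmax = 0.0;
  for (int i = 0; i < A.nrow(); ++i) {
    const double n = std::sqrt(A(i, 0) * A(i, 0) + A(i, 1) * A(i, 1));
    if (n > mA) mA = n;
    if (rA[i] > rAmax) rAmax = rA[i];
  }
  for (int j = 0; j < B.nrow(); ++j) {
    const double n = std::sqrt(B(j, 0) * B(j, 0) + B(j, 1) * B(j, 1));
    if (n > mB) mB = n;
    if (rB[j] > rBmax) rBmax = rB[j];
  }
  hi_bound = mA + mB + rAmax + rBmax + gap + 1.0;
  if (min_sep(A, B, rA, rB, lo) - gap >= 0.0)
    stop("contact placement: models already separated beyond the gap at zero offset");
  double hi = hi_bound;
  if (min_sep(A, B, rA, rB, hi) - gap < 0.0)
    stop("contact placement: could not bracket the contact distance");
  int it = 0;
  while (hi - lo > tol) {
    if (++it > maxit) stop("contact placement: bisection did not converge");
    const double mid = 0.5 * (lo + hi);
    if (min_sep(A, B, rA, rB, mid) - gap < 0.0)
      lo = mid;
    else
      hi = mid;
  }
  return hi;
}

// [[Rcpp::export]]
NumericVector cpp_pair_energy(NumericMatrix A, NumericMatrix B,
                              NumericVector qA, NumericVector qB, double sigma,
                              double eps, double epsr, double cutoff) {
  double elj, ecoul;
  pair_energy(A, B, qA, qB, 0.0, sigma, eps, epsr, cutoff, elj, ecoul);
  return NumericVector::create(elj, ecoul);
}

// [[Rcpp::export]]
double cpp_min_surface_sep(NumericMatrix A, NumericMatrix B, NumericVector rA,
                           NumericVector rB) {
  return min_sep(A, B, rA, rB, 0.0);
}

// [[Rcpp::export]]
double cpp_contact_offset(NumericMatrix A, NumericMatrix B, NumericVector rA,
                          NumericVector rB, double gap, double tol, int maxit) {
  return contact_offset(A, B, rA, rB, gap, tol, maxit);
}

static NumericMatrix rotate_z(const NumericMatrix &X, double theta_deg) {
  const double th = theta_deg * M_PI / 180.0;
  const double c = std::cos(th), s = std::sin(th);
  NumericMatrix out(X.nrow(), 3);
  for (int i = 0; i < X.nrow(); ++i) {
    out(i, 0) = c * X(i, 0) - s * X(i, 1);
    out(i, 1) = s * X(i, 0) + c * X(i, 1);
    out(i, 2) = X(i, 2);
  }
  return out;
}

// Full rotational landscape: for each (theta1, theta2) rotate each monomer
// about its own axis (the z-axis; models are pre-centred), bring B into
// contact along +x by bisection, then evaluate the pair energy.
// Returns a (n1*n2) x 5 matrix: theta1, theta2, center_distance, E_LJ, E_Coul.
// [[Rcpp::export]]
NumericMatrix cpp_landscape(NumericMatrix A, NumericMatrix B, NumericVector qA,
                            NumericVector qB, NumericVector rA,
                            NumericVector rB, NumericVector thetas1,
                            NumericVector thetas2, double gap, double sigma,
                            double eps, double epsr, double cutoff, double tol,
                            int maxit) {
  const int n1 = thetas1.size(), n2 = thetas2.size();
  std::vector<NumericMatrix> rotA(n1), rotB(n2);
  for (int i = 0; i < n1; ++i) rotA[i] = rotate_z(A, thetas1[i]);
  for (int j = 0; j < n2; ++j) rotB[j] = rotate_z(B, thetas2[j]);
  NumericMatrix out(n1 * n2, 5);
  int row = 0;
  for (int i = 0; i < n1; ++i) {
    Rcpp::checkUserInterrupt();
    for (int j = 0; j < n2; ++j) {
      double d, elj, ecoul;
      try {
        d = contact_offset(rotA[i], rotB[j], rA, rB, gap, tol, maxit);
        pair_energy(rotA[i], rotB[j], qA, qB, d, sigma, eps, epsr, cutoff, elj,
                    ecoul);
      } catch (std::exception &e) {
        stop("landscape cell (theta1=%.1f, theta2=%.1f): %s", thetas1[i],
             thetas2[j], e.what());
      }
      out(row, 0) = thetas1[i];
      out(row, 1) = thetas2[j];
      out(row, 2) = d;
      out(row, 3) = elj;
      out(row, 4) = ecoul;
      ++row;
    }
  }
  return out;
}
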