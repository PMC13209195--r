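#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double GAUSS_P2 = 2.7 * 2.7;
static const double PI3 = M_PI * M_PI * M_PI;

// First-order Gaussian overlap volume between two atom sets at fixed pose.
// [[Rcpp::export]]
double overlap_volume_cpp(NumericMatrix A, NumericVector aA,
                          NumericMatrix B, NumericVector aB) {
  const int nA = A.nrow(), nB = B.nrow();
  double total = 0.0;
  for (int i = 0; i < nA; ++i) {
    const double ax = A(i, 0), ay = A(i, 1), az = A(i, 2), ai = aA[i];
    for (int j = 0; j < nB; ++j) {
      const double dx = ax - B(j, 0), dy = ay - B(j, 1), dz = az - B(j, 2);
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double s = ai + aB[j];
      total += GAUSS_P2 * std::sqrt(PI3 / (s * s * s)) *
        std::exp(-ai * aB[j] * d2 / s);
    }
  }
  return total;
}

static void rotvec_to_mat(const double *r, double R[3][3]) {
  const double theta = std::sqrt(r[0] * r[0] + r[1] * r[1] + r[2] * r[2]);
  if (theta < 1e-12) {
    for (int i = 0; i < 3; ++i)
      for (int j = 0; j < 3; ++j) R[i][j] = (i == j) ? 1.0 : 0.0;
    return;
  }
  const double kx = r[0] / theta, ky = r[1] / theta, kz = r[2] / theta;
  const double c = std::cos(theta), s = std::sin(theta), v = 1.0 - c;
  R[0][0] = c + kx * kx * v;      R[0][1] = kx * ky * v - kz * s; R[0][2] = kx * kz * v + ky * s;
  R[1][0] = ky * kx * v + kz * s; R[1][1] = c + ky * ky * v;      R[1][2] = ky * kz * v - kx * s;
  R[2][0] = kz * kx * v - ky * s; R[2][1] = kz * ky * v + kx * s; R[2][2] = c + kz * kz * v;
}

// Negative overlap of A0 (centred, fixed) with B0 rotated by
// rotvec(par[0:2]) %*% R0 and translated by par[3:5].
// [[Rcpp::export]]
double overlap_objective_cpp(NumericVector par, NumericMatrix A0,
                             NumericVector aA, NumericMatrix B0,
                             NumericVector aB, NumericMatrix R0) {
  double Rv[3][3];
  const double pr[3] = {par[0], par[1], par[2]};
  rotvec_to_mat(pr, Rv);
  // R = Rv %*% R0
  double R[3][3];
  for (int i = 0; i < 3; ++i)
    for (int j = 0; j < 3; ++j) {
      R[i][j] = 0.0;
      for (int k = 0; k < 3; ++k) R[i][j] += Rv[i][k] * R0(k, j);
    }
  const int nA = A0.nrow(), nB = B0.nrow();
  const double tx = par[3], ty = par[4], tz = par[5];
  double total = 0.0;
  std::vector<double> bx(nB), by(nB), bz(nB);
  for (int j = 0; j < nB; ++j) {
    const double x = B0(j, 0), y = B0(j, 1), z = B0(j, 2);
    bx[j] = R[0][0] * x + R[0][1] * y + R[0][2] * z + tx;
    by[j] = R[1][0] * x + R[1][1] * y + R[1][2] * z + ty;
    bz[j] = R[2][0] * x + R[2][1] * y + R[2][2] * z + tz;
  }
  for (int i = 0; i < nA; ++i) {
    const double ax = A0(i, 0), ay = A0(i, 1), az = A0(i, 2), ai = aA[i];
    for (int j = 0; j < nB; ++j) {
      const double dx = ax - bx[j], dy = ay - by[j], dz = az - bz[j];
      const double d2 = dx * dx + dy * dy + dz * dz;
      const double s = ai + aB[j];
      total += GAUSS_P2 * std::sqrt(PI3 / (s * s * s)) *
        std::exp(-ai * aB[j] * d2 / s);
    }
  }
  return -total;
}

// Central-difference gradient of overlap_objective_cpp, computed in C++
// so the optimizer makes two R-level calls per iteration instead of 13.
// [[Rcpp::export]]
NumericVector overlap_gradient_cpp(NumericVector par, NumericMatrix A0,
                                   NumericVector aA, NumericMatrix B0,
                                   NumericVector aB, NumericMatrix R0) {
  const double h = 1e-4;
  NumericVector g(6);
  NumericVector p = clone(par);
  for (int k = 0; k < 6; ++k) {
    const double orig = p[k];
    p[k] = orig + h;
    const double fp = overlap_objective_cpp(p, A0, aA, B0, aB, R0);
    p[k] = orig - h;
    const double fm = overlap_objective_cpp(p, A0, aA, B0, aB, R0);
    p[k] = orig;
    g[k] = (fp - fm) / (2.0 * h);
  }
  return g;
}
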