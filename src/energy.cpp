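#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Far-field screened-Coulomb (Yukawa) interaction between two uniformly
// charged rod segments of reduced length 1/M (rod length a = 1), each
// carrying a charge Z/M.  In the far field a segment acts as a line charge
// whose angular structure enters through the kernel
//   S(x) = sinh(x)/x,  x = kappa* (v . rhat) / (2 M),
// so the reduced segment-segment energy, in units of Z^2 l_B / a, is
//   u_ij = (1/M^2) S(x_i) S(x_j) exp(-kappa* r) / r .
// All lengths are reduced by the rod length a.

// sinh(x)/x; Taylor series on |x| < 2 (absolute truncation error < 1e-12)
static inline double sinhc(double x) {
  double x2 = x * x;
  if (x2 < 4.0)
    return 1.0 + x2 * (1.0 / 6.0 + x2 * (1.0 / 120.0 + x2 * (1.0 / 5040.0 +
           x2 * (1.0 / 362880.0 + x2 * (1.0 / 39916800.0 +
           x2 * (1.0 / 6227020800.0 + x2 * (1.0 / 1307674368000.0)))))));
  return std::sinh(x) / x;
}

static inline double seg_pair(double dx, double dy, double dz,
                              const double *vi, const double *vj,
                              double kappa, double half_seg) {
  double r2 = dx * dx + dy * dy + dz * dz;
  double r = std::sqrt(r2);
  double ci = (vi[0] * dx + vi[1] * dy + vi[2] * dz) / r;
  double cj = (vj[0] * dx + vj[1] * dy + vj[2] * dz) / r;
  return sinhc(kappa * half_seg * ci) * sinhc(kappa * half_seg * cj) *
         std::exp(-kappa * r) / r;
}

// [[Rcpp::export]]
double cpp_segment_energy(NumericVector rij, NumericVector vi,
                          NumericVector vj, double kappa, int M) {
  double r = std::sqrt(rij[0] * rij[0] + rij[1] * rij[1] + rij[2] * rij[2]);
  if (r <= 0.0) stop("segment separation must be positive");
  double vv_i[3] = {vi[0], vi[1], vi[2]};
  double vv_j[3] = {vj[0], vj[1], vj[2]};
  return seg_pair(rij[0], rij[1], rij[2], vv_i, vv_j, kappa, 0.5 / M) /
         (double)(M * M);
}

// Energy between two rods discretised as M collinear segments with centres
// at offsets ((k - (M+1)/2)/M) v, k = 1..M (spacing 1/M, symmetric about
// the rod centre).  Self-energies are never included (p != q by contract).
static double rod_pair(const double *pp, const double *vp,
                       const double *pq, const double *vq,
                       double kappa, int M, const double *off) {
  double e = 0.0;
  double half_seg = 0.5 / M;
  for (int k = 0; k < M; ++k) {
    double ax = pp[0] + off[k] * vp[0];
    double ay = pp[1] + off[k] * vp[1];
    double az = pp[2] + off[k] * vp[2];
    for (int l = 0; l < M; ++l) {
      double dx = pq[0] + off[l] * vq[0] - ax;
      double dy = pq[1] + off[l] * vq[1] - ay;
      double dz = pq[2] + off[l] * vq[2] - az;
      e += seg_pair(dx, dy, dz, vp, vq, kappa, half_seg);
    }
  }
  return e / (double)(M * M);
}

static void seg_offsets(int M, std::vector<double> &off) {
  off.resize(M);
  for (int k = 1; k <= M; ++k) off[k - 1] = (k - 0.5 * (M + 1)) / M;
}

// [[Rcpp::export]]
double cpp_rod_pair_energy(NumericVector pos_p, NumericVector v_p,
                           NumericVector pos_q, NumericVector v_q,
                           double kappa, int M) {
  std::vector<double> off;
  seg_offsets(M, off);
  double pp[3] = {pos_p[0], pos_p[1], pos_p[2]};
  double vp[3] = {v_p[0], v_p[1], v_p[2]};
  double pq[3] = {pos_q[0], pos_q[1], pos_q[2]};
  double vq[3] = {v_q[0], v_q[1], v_q[2]};
  return rod_pair(pp, vp, pq, vq, kappa, M, off.data());
}

// Pairwise energies of one central rod with every other rod in a cluster.
// Returns a vector of length N with entry `center` set to 0.
// [[Rcpp::export]]
NumericVector cpp_central_energies(NumericMatrix pos, NumericMatrix orient,
                                   int center, double kappa, int M) {
  int n = pos.nrow();
  std::vector<double> off;
  seg_offsets(M, off);
  NumericVector out(n);
  double pc[3] = {pos(center, 0), pos(center, 1), pos(center, 2)};
  double vc[3] = {orient(center, 0), orient(center, 1), orient(center, 2)};
  for (int j = 0; j < n; ++j) {
    if (j == center) continue;
    double pj[3] = {pos(j, 0), pos(j, 1), pos(j, 2)};
    double vj[3] = {orient(j, 0), orient(j, 1), orient(j, 2)};
    out[j] = rod_pair(pc, vc, pj, vj, kappa, M, off.data());
  }
  return out;
}
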