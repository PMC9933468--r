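#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Periodic NVT Monte Carlo for segmented charged rods.
//
// The box is cuboid and may be smaller than twice the interaction cutoff:
// rod-rod energies are summed over all periodic images whose
// center-to-center distance lies inside the cutoff (including a rod's own
// images), so small commensurate supercells remain exact.

// sinh(x)/x; Taylor series on |x| < 2 (absolute truncation error < 1e-12)
static inline double sinhc(double x) {
  double x2 = x * x;
  if (x2 < 4.0)
    return 1.0 + x2 * (1.0 / 6.0 + x2 * (1.0 / 120.0 + x2 * (1.0 / 5040.0 +
           x2 * (1.0 / 362880.0 + x2 * (1.0 / 39916800.0 +
           x2 * (1.0 / 6227020800.0 + x2 * (1.0 / 1307674368000.0)))))));
  return std::sinh(x) / x;
}

struct Pot {
  double kappa;
  int M;
  double rcut;
  std::vector<double> off;  // segment centre offsets along the axis
  double half_seg;
  double inv_M2;
};

static void pot_init(Pot &P, double kappa, int M, double rcut) {
  P.kappa = kappa;
  P.M = M;
  P.rcut = rcut;
  P.off.resize(M);
  for (int k = 1; k <= M; ++k) P.off[k - 1] = (k - 0.5 * (M + 1)) / M;
  P.half_seg = 0.5 / M;
  P.inv_M2 = 1.0 / ((double)M * (double)M);
}

// rod-rod energy for a given center displacement d (q relative to p)
static double rod_pair_d(const double *d, const double *vp, const double *vq,
                         const Pot &P) {
  double e = 0.0;
  for (int k = 0; k < P.M; ++k) {
    double ax = P.off[k] * vp[0], ay = P.off[k] * vp[1], az = P.off[k] * vp[2];
    for (int l = 0; l < P.M; ++l) {
      double dx = d[0] + P.off[l] * vq[0] - ax;
      double dy = d[1] + P.off[l] * vq[1] - ay;
      double dz = d[2] + P.off[l] * vq[2] - az;
      double r = std::sqrt(dx * dx + dy * dy + dz * dz);
      double ci = (vp[0] * dx + vp[1] * dy + vp[2] * dz) / r;
      double cj = (vq[0] * dx + vq[1] * dy + vq[2] * dz) / r;
      e += sinhc(P.kappa * P.half_seg * ci) * sinhc(P.kappa * P.half_seg * cj) *
           std::exp(-P.kappa * r) / r;
    }
  }
  return e * P.inv_M2;
}

struct State {
  int n;
  std::vector<double> px, py, pz, vx, vy, vz;
  double L[3];
};

static inline double wrap1(double x, double L) {
  x -= L * std::floor(x / L);
  if (x >= L) x -= L;
  return x;
}

// energy of rod i with rod j summed over periodic images within the cutoff;
// if i == j, images n = 0 is skipped and the sum is halved (each physical
// self-image pair is enumerated twice as +n and -n)
static double pair_images(const State &S, int i, int j, const Pot &P) {
  double d0[3] = {S.px[j] - S.px[i], S.py[j] - S.py[i], S.pz[j] - S.pz[i]};
  int nim[3];
  for (int d = 0; d < 3; ++d) {
    d0[d] -= S.L[d] * std::round(d0[d] / S.L[d]);
    // nearest-image |d0| <= L/2, so shifts beyond rcut/L + 1/2 are outside
    nim[d] = (int)std::floor(P.rcut / S.L[d] + 0.5 + 1e-12);
    if (nim[d] > 8) nim[d] = 8;
  }
  const double vp[3] = {S.vx[i], S.vy[i], S.vz[i]};
  const double vq[3] = {S.vx[j], S.vy[j], S.vz[j]};
  double rc2 = P.rcut * P.rcut;
  double e = 0.0;
  for (int nx = -nim[0]; nx <= nim[0]; ++nx)
    for (int ny = -nim[1]; ny <= nim[1]; ++ny)
      for (int nz = -nim[2]; nz <= nim[2]; ++nz) {
        if (i == j && nx == 0 && ny == 0 && nz == 0) continue;
        double d[3] = {d0[0] + nx * S.L[0], d0[1] + ny * S.L[1],
                       d0[2] + nz * S.L[2]};
        double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
        if (r2 > rc2) continue;
        e += rod_pair_d(d, vp, vq, P);
      }
  return (i == j) ? 0.5 * e : e;
}

// interaction energy of rod i with the rest of the system (incl. own images)
static double rod_energy(const State &S, int i, const Pot &P) {
  double e = 0.0;
  for (int j = 0; j < S.n; ++j)
    e += (j == i) ? pair_images(S, i, i, P) : pair_images(S, i, j, P);
  return e;
}

static double total_energy(const State &S, const Pot &P) {
  double e = 0.0;
  for (int i = 0; i < S.n; ++i) {
    for (int j = i + 1; j < S.n; ++j) e += pair_images(S, i, j, P);
    e += pair_images(S, i, i, P);
  }
  return e;
}

// pair-energy cache: umat[i*n+j] (j != i) holds the image-summed pair
// energy, umat[i*n+i] the rod's self-image energy
static void fill_row(const State &S, int i, const Pot &P, double *row) {
  for (int j = 0; j < S.n; ++j)
    row[j] = (j == i) ? pair_images(S, i, i, P) : pair_images(S, i, j, P);
}

static void fill_matrix(const State &S, const Pot &P,
                        std::vector<double> &umat, double &U) {
  int n = S.n;
  umat.assign((size_t)n * n, 0.0);
  U = 0.0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double e = pair_images(S, i, j, P);
      umat[(size_t)i * n + j] = e;
      umat[(size_t)j * n + i] = e;
      U += e;
    }
    double s = pair_images(S, i, i, P);
    umat[(size_t)i * n + i] = s;
    U += s;
  }
}

static void state_from_R(State &S, const NumericMatrix &pos,
                         const NumericMatrix &ori, const NumericVector &box) {
  S.n = pos.nrow();
  S.px.resize(S.n); S.py.resize(S.n); S.pz.resize(S.n);
  S.vx.resize(S.n); S.vy.resize(S.n); S.vz.resize(S.n);
  for (int i = 0; i < S.n; ++i) {
    S.px[i] = pos(i, 0); S.py[i] = pos(i, 1); S.pz[i] = pos(i, 2);
    S.vx[i] = ori(i, 0); S.vy[i] = ori(i, 1); S.vz[i] = ori(i, 2);
  }
  for (int d = 0; d < 3; ++d) S.L[d] = box[d];
}

// [[Rcpp::export]]
double cpp_rod_energy_pbc(NumericMatrix pos, NumericMatrix orient,
                          NumericVector box, int i, double kappa, int M,
                          double rcut) {
  Pot P; pot_init(P, kappa, M, rcut);
  State S; state_from_R(S, pos, orient, box);
  return rod_energy(S, i, P);
}

// [[Rcpp::export]]
double cpp_total_energy_pbc(NumericMatrix pos, NumericMatrix orient,
                            NumericVector box, double kappa, int M,
                            double rcut) {
  Pot P; pot_init(P, kappa, M, rcut);
  State S; state_from_R(S, pos, orient, box);
  return total_energy(S, P);
}

static void rand_axis(double *u) {
  double x, y, z, s2;
  do {
    x = 2.0 * unif_rand() - 1.0;
    y = 2.0 * unif_rand() - 1.0;
    z = 2.0 * unif_rand() - 1.0;
    s2 = x * x + y * y + z * z;
  } while (s2 > 1.0 || s2 < 1e-12);
  double s = std::sqrt(s2);
  u[0] = x / s; u[1] = y / s; u[2] = z / s;
}

static void rotate_vec(double *v, const double *u, double th) {
  double c = std::cos(th), s = std::sin(th);
  double dot = u[0] * v[0] + u[1] * v[1] + u[2] * v[2];
  double cr[3] = {u[1] * v[2] - u[2] * v[1], u[2] * v[0] - u[0] * v[2],
                  u[0] * v[1] - u[1] * v[0]};
  double w[3];
  for (int d = 0; d < 3; ++d)
    w[d] = v[d] * c + cr[d] * s + u[d] * dot * (1.0 - c);
  double nn = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  v[0] = w[0] / nn; v[1] = w[1] / nn; v[2] = w[2] / nn;
}

static bool accept_move(double du, double temp) {
  if (temp <= 0.0) return du < 0.0;
  if (du <= 0.0) return true;
  return unif_rand() < std::exp(-du / temp);
}

// One NVT Monte Carlo run.  A "step" is either n single-rod trials or 9
// isochoric box-dimension trials (every box_every-th step when enabled).
// Step sizes adapt multiplicatively toward an acceptance in [acc_lo,
// acc_hi] during the first tune_steps steps of each block of block_steps
// steps, with an adjustment every tune_every steps, and are frozen for the
// remainder of the block.
// [[Rcpp::export]]
List cpp_run_mc(NumericMatrix pos, NumericMatrix orient, NumericVector box,
                double kappa, int M, double rcut, double temperature,
                int n_steps, LogicalVector kinds_enabled, bool box_moves,
                int box_every, double delta_t, double delta_r,
                int tune_steps, int tune_every, int block_steps,
                double acc_lo, double acc_hi, int sample_every,
                int snapshot_every, int recompute_every, bool debug_check) {
  Pot P; pot_init(P, kappa, M, rcut);
  State S; state_from_R(S, pos, orient, box);
  RNGScope scope;

  bool en_t = kinds_enabled[0], en_r = kinds_enabled[1], en_c = kinds_enabled[2];
  int nkind = (en_t ? 1 : 0) + (en_r ? 1 : 0) + (en_c ? 1 : 0);
  if (nkind == 0) stop("no move kind enabled");
  // independent step sizes for the combined move
  double dt = delta_t, dr = delta_r, dct = delta_t, dcr = delta_r;

  std::vector<double> umat, umat_new;
  double U;
  fill_matrix(S, P, umat, U);
  std::vector<double> row(S.n);
  long att[4] = {0, 0, 0, 0}, acc[4] = {0, 0, 0, 0};   // t, r, c, box
  long watt[4] = {0, 0, 0, 0}, wacc[4] = {0, 0, 0, 0}; // tuning window

  int nsamp = n_steps / sample_every + 2;
  NumericVector tr_step(nsamp), tr_u(nsamp), tr_Lx(nsamp), tr_Ly(nsamp),
      tr_Lz(nsamp), tr_at(nsamp), tr_ar(nsamp), tr_ac(nsamp), tr_ab(nsamp);
  NumericMatrix tr_Q(nsamp, 6);
  int isamp = 0;
  List snaps;

  for (int step = 1; step <= n_steps; ++step) {
    bool box_step = box_moves && box_every > 0 && (step % box_every == 0);
    if (box_step) {
      for (int t = 0; t < 9; ++t) {
        ++att[3]; ++watt[3];
        int d1 = (int)(unif_rand() * 3.0); if (d1 > 2) d1 = 2;
        int pick = (int)(unif_rand() * 2.0); if (pick > 1) pick = 1;
        int d2 = (d1 + 1 + pick) % 3;
        double f = 1.0 + 0.005 * (2.0 * unif_rand() - 1.0);
        State Snew = S;
        Snew.L[d1] *= f; Snew.L[d2] /= f;
        double f1 = f, f2 = 1.0 / f;
        for (int i = 0; i < S.n; ++i) {
          double c[3] = {Snew.px[i], Snew.py[i], Snew.pz[i]};
          c[d1] *= f1; c[d2] *= f2;
          Snew.px[i] = c[0]; Snew.py[i] = c[1]; Snew.pz[i] = c[2];
        }
        double Unew;
        fill_matrix(Snew, P, umat_new, Unew);
        if (accept_move(Unew - U, temperature)) {
          S = Snew; U = Unew;
          umat.swap(umat_new);
          ++acc[3]; ++wacc[3];
        }
      }
    } else {
      for (int t = 0; t < S.n; ++t) {
        int kind;
        do { kind = (int)(unif_rand() * 3.0); if (kind > 2) kind = 2; }
        while (!((kind == 0 && en_t) || (kind == 1 && en_r) || (kind == 2 && en_c)));
        ++att[kind]; ++watt[kind];
        int i = (int)(unif_rand() * S.n); if (i >= S.n) i = S.n - 1;
        double op[3] = {S.px[i], S.py[i], S.pz[i]};
        double ov[3] = {S.vx[i], S.vy[i], S.vz[i]};
        double mt = (kind == 0) ? dt : dct;
        double mr = (kind == 1) ? dr : dcr;
        if (kind == 0 || kind == 2) {
          S.px[i] = wrap1(S.px[i] + mt * (2.0 * unif_rand() - 1.0), S.L[0]);
          S.py[i] = wrap1(S.py[i] + mt * (2.0 * unif_rand() - 1.0), S.L[1]);
          S.pz[i] = wrap1(S.pz[i] + mt * (2.0 * unif_rand() - 1.0), S.L[2]);
        }
        if (kind == 1 || kind == 2) {
          double axis[3]; rand_axis(axis);
          double v[3] = {S.vx[i], S.vy[i], S.vz[i]};
          rotate_vec(v, axis, mr * unif_rand());
          S.vx[i] = v[0]; S.vy[i] = v[1]; S.vz[i] = v[2];
        }
        fill_row(S, i, P, row.data());
        double du = 0.0;
        const double *orow = umat.data() + (size_t)i * S.n;
        for (int j = 0; j < S.n; ++j) du += row[j] - orow[j];
        if (accept_move(du, temperature)) {
          U += du;
          for (int j = 0; j < S.n; ++j) {
            umat[(size_t)i * S.n + j] = row[j];
            umat[(size_t)j * S.n + i] = row[j];
          }
          ++acc[kind]; ++wacc[kind];
          if (debug_check) {
            double Ufull = total_energy(S, P);
            if (std::fabs(Ufull - U) > 1e-8 * (std::fabs(Ufull) + 1.0))
              stop("local energy update drifted from full recompute");
            U = Ufull;
          }
        } else {
          S.px[i] = op[0]; S.py[i] = op[1]; S.pz[i] = op[2];
          S.vx[i] = ov[0]; S.vy[i] = ov[1]; S.vz[i] = ov[2];
        }
      }
    }

    // adaptive step sizes inside the tuning stage of each block
    int in_block = (block_steps > 0) ? ((step - 1) % block_steps) + 1 : step;
    if (in_block <= tune_steps && (in_block % tune_every) == 0) {
      double dmax = 0.5 * std::min(S.L[0], std::min(S.L[1], S.L[2]));
      double *tgt_t[3] = {&dt, NULL, &dct};
      double *tgt_r[3] = {NULL, &dr, &dcr};
      for (int k = 0; k < 3; ++k) {
        if (watt[k] == 0) continue;
        double rate = (double)wacc[k] / (double)watt[k];
        double fac = (rate > acc_hi) ? 1.25 : (rate < acc_lo ? 0.8 : 1.0);
        if (fac != 1.0) {
          if (tgt_t[k]) { *tgt_t[k] = std::min(std::max(*tgt_t[k] * fac, 1e-7), dmax); }
          if (tgt_r[k]) { *tgt_r[k] = std::min(std::max(*tgt_r[k] * fac, 1e-7), M_PI); }
        }
        watt[k] = wacc[k] = 0;
      }
    }
    if (in_block == 1) { for (int k = 0; k < 4; ++k) { watt[k] = wacc[k] = 0; } }

    if (recompute_every > 0 && (step % recompute_every) == 0)
      fill_matrix(S, P, umat, U);

    if ((step % sample_every) == 0 || step == n_steps) {
      tr_step[isamp] = step;
      tr_u[isamp] = U / S.n;
      tr_Lx[isamp] = S.L[0]; tr_Ly[isamp] = S.L[1]; tr_Lz[isamp] = S.L[2];
      tr_at[isamp] = att[0] ? (double)acc[0] / att[0] : NA_REAL;
      tr_ar[isamp] = att[1] ? (double)acc[1] / att[1] : NA_REAL;
      tr_ac[isamp] = att[2] ? (double)acc[2] / att[2] : NA_REAL;
      tr_ab[isamp] = att[3] ? (double)acc[3] / att[3] : NA_REAL;
      // second-moment tensor of orientations (order parameters in R)
      double q[6] = {0, 0, 0, 0, 0, 0};
      for (int i = 0; i < S.n; ++i) {
        q[0] += S.vx[i] * S.vx[i]; q[1] += S.vy[i] * S.vy[i];
        q[2] += S.vz[i] * S.vz[i]; q[3] += S.vx[i] * S.vy[i];
        q[4] += S.vx[i] * S.vz[i]; q[5] += S.vy[i] * S.vz[i];
      }
      for (int d = 0; d < 6; ++d) tr_Q(isamp, d) = q[d] / S.n;
      ++isamp;
    }
    if (snapshot_every > 0 && (step % snapshot_every) == 0) {
      NumericMatrix sp(S.n, 3), so(S.n, 3);
      for (int i = 0; i < S.n; ++i) {
        sp(i, 0) = S.px[i]; sp(i, 1) = S.py[i]; sp(i, 2) = S.pz[i];
        so(i, 0) = S.vx[i]; so(i, 1) = S.vy[i]; so(i, 2) = S.vz[i];
      }
      snaps.push_back(List::create(_["step"] = step, _["positions"] = sp,
                                   _["orientations"] = so,
                                   _["box"] = NumericVector::create(
                                       S.L[0], S.L[1], S.L[2])));
    }
  }

  NumericMatrix fp(S.n, 3), fo(S.n, 3);
  for (int i = 0; i < S.n; ++i) {
    fp(i, 0) = S.px[i]; fp(i, 1) = S.py[i]; fp(i, 2) = S.pz[i];
    fo(i, 0) = S.vx[i]; fo(i, 1) = S.vy[i]; fo(i, 2) = S.vz[i];
  }
  Range rr(0, isamp - 1);
  return List::create(
      _["positions"] = fp, _["orientations"] = fo,
      _["box"] = NumericVector::create(S.L[0], S.L[1], S.L[2]),
      _["u_final"] = U / S.n,
      _["step"] = tr_step[rr], _["u"] = tr_u[rr],
      _["Lx"] = tr_Lx[rr], _["Ly"] = tr_Ly[rr], _["Lz"] = tr_Lz[rr],
      _["acc_translate"] = tr_at[rr], _["acc_rotate"] = tr_ar[rr],
      _["acc_combined"] = tr_ac[rr], _["acc_box"] = tr_ab[rr],
      _["Qmom"] = tr_Q(rr, _),
      _["snapshots"] = snaps,
      _["delta_final"] = NumericVector::create(dt, dr, dct, dcr));
}
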