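// Rigid-body Brownian dynamics inner loop. The R level prepares all
// geometry (fibril charge/repulsion/reference sites, glycan body-frame
// sites) and seeds R's RNG per trajectory; this kernel draws its normal
// deviates from R's stream (3 translation, then 3 rotation per step) so a
// trajectory is exactly reproducible from its substream seed.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const double SOFTCORE_D0 = 3.5;   // pair contact distance, A
static const double SOFTCORE_EPS = 0.3;  // kcal/mol (must match R level)

static inline void rot_apply(const double R[9], const double* x, double* y) {
  // R column-major 3x3, y = R x
  y[0] = R[0] * x[0] + R[3] * x[1] + R[6] * x[2];
  y[1] = R[1] * x[0] + R[4] * x[1] + R[7] * x[2];
  y[2] = R[2] * x[0] + R[5] * x[1] + R[8] * x[2];
}

static void rot_compose_axis_angle(double R[9], const double w[3]) {
  // R <- Rot(w) * R, |w| = angle, axis w/|w| (Rodrigues)
  double th = std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
  if (th < 1e-14) return;
  double u0 = w[0] / th, u1 = w[1] / th, u2 = w[2] / th;
  double c = std::cos(th), s = std::sin(th), cc = 1.0 - c;
  double Q[9];
  Q[0] = c + u0 * u0 * cc;      Q[3] = u0 * u1 * cc - u2 * s; Q[6] = u0 * u2 * cc + u1 * s;
  Q[1] = u1 * u0 * cc + u2 * s; Q[4] = c + u1 * u1 * cc;      Q[7] = u1 * u2 * cc - u0 * s;
  Q[2] = u2 * u0 * cc - u1 * s; Q[5] = u2 * u1 * cc + u0 * s; Q[8] = c + u2 * u2 * cc;
  double Rn[9];
  for (int j = 0; j < 3; ++j)        // column j of new R
    for (int i = 0; i < 3; ++i)
      Rn[i + 3 * j] = Q[i] * R[3 * j] + Q[i + 3] * R[1 + 3 * j] +
                      Q[i + 6] * R[2 + 3 * j];
  std::copy(Rn, Rn + 9, R);
}

static void orthonormalize(double R[9]) {
  // Gram-Schmidt on the three columns
  double n0 = std::sqrt(R[0] * R[0] + R[1] * R[1] + R[2] * R[2]);
  for (int i = 0; i < 3; ++i) R[i] /= n0;
  double d = R[0] * R[3] + R[1] * R[4] + R[2] * R[5];
  for (int i = 0; i < 3; ++i) R[3 + i] -= d * R[i];
  double n1 = std::sqrt(R[3] * R[3] + R[4] * R[4] + R[5] * R[5]);
  for (int i = 0; i < 3; ++i) R[3 + i] /= n1;
  R[6] = R[1] * R[5] - R[2] * R[4];
  R[7] = R[2] * R[3] - R[0] * R[5];
  R[8] = R[0] * R[4] - R[1] * R[3];
}

// [[Rcpp::export(name = ".bd_run_cpp")]]
List bd_run_cpp(NumericMatrix fib_charge_pos, NumericVector fib_charge_q,
                NumericMatrix fib_rep_pos,
                NumericMatrix fib_ref_pos, IntegerVector fib_ref_res,
                NumericMatrix gly_charge_local, NumericVector gly_charge_q,
                NumericMatrix gly_ref_local,
                NumericMatrix R0, NumericVector t0,
                double kappa, double coul_pref,
                double Dt, double Dr, double kBT,
                double dt_far, double dt_near, double near_shell,
                double reaction_distance, int reaction_min_contacts,
                double q_radius, NumericVector fib_center,
                double max_steps_d, int record_stride) {
  const int nfc = fib_charge_pos.nrow(), nrp = fib_rep_pos.nrow();
  const int nfr = fib_ref_pos.nrow(), ngc = gly_charge_local.nrow();
  const int ngr = gly_ref_local.nrow();
  const double rd2 = reaction_distance * reaction_distance;
  const double shell2 = near_shell * near_shell;
  const double q2 = q_radius * q_radius;

  double R[9];
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i) R[i + 3 * j] = R0(i, j);
  double t[3] = { t0[0], t0[1], t0[2] };

  // residue-indexed contact counter (residues pooled across layers)
  std::vector<int> res_ids;
  std::vector<int> res_index(nfr);
  for (int i = 0; i < nfr; ++i) {
    int r = fib_ref_res[i];
    int idx = -1;
    for (size_t k = 0; k < res_ids.size(); ++k)
      if (res_ids[k] == r) { idx = (int)k; break; }
    if (idx < 0) { res_ids.push_back(r); idx = (int)res_ids.size() - 1; }
    res_index[i] = idx;
  }
  std::vector<int> res_count(res_ids.size());

  std::vector<double> gw(3 * ngc), rw(3 * ngr);
  std::vector<double> rec_t, rec_u;

  int status = 2;              // 0 reacted, 1 escaped, 2 max_steps
  int site = NA_INTEGER;
  long long step = 0;
  const long long max_steps = (long long)max_steps_d;
  GetRNGstate();

  while (step < max_steps) {
    // world-frame glycan reference atoms; reaction + proximity test
    double mind2 = R_PosInf;
    std::fill(res_count.begin(), res_count.end(), 0);
    int total = 0;
    for (int j = 0; j < ngr; ++j) {
      double xl[3] = { gly_ref_local(j, 0), gly_ref_local(j, 1),
                       gly_ref_local(j, 2) };
      double* w = &rw[3 * j];
      rot_apply(R, xl, w);
      w[0] += t[0]; w[1] += t[1]; w[2] += t[2];
    }
    for (int i = 0; i < nfr; ++i) {
      const double fx = fib_ref_pos(i, 0), fy = fib_ref_pos(i, 1),
                   fz = fib_ref_pos(i, 2);
      for (int j = 0; j < ngr; ++j) {
        const double* w = &rw[3 * j];
        double d2 = (w[0] - fx) * (w[0] - fx) + (w[1] - fy) * (w[1] - fy) +
                    (w[2] - fz) * (w[2] - fz);
        if (d2 < mind2) mind2 = d2;
        if (d2 <= rd2) { ++res_count[res_index[i]]; ++total; }
      }
    }
    if (total >= reaction_min_contacts && ngr > 0 && nfr > 0) {
      int best = -1, bestn = -1;
      for (size_t k = 0; k < res_ids.size(); ++k) {
        if (res_count[k] > bestn ||
            (res_count[k] == bestn && best >= 0 && res_ids[k] < res_ids[best])) {
          if (res_count[k] > 0) { bestn = res_count[k]; best = (int)k; }
        }
      }
      status = 0;
      site = (best >= 0) ? res_ids[best] : NA_INTEGER;
      break;
    }

    const double dt = (mind2 <= shell2) ? dt_near : dt_far;

    // world-frame glycan charges; force and torque
    double F[3] = { 0, 0, 0 }, T[3] = { 0, 0, 0 };
    for (int j = 0; j < ngc; ++j) {
      double xl[3] = { gly_charge_local(j, 0), gly_charge_local(j, 1),
                       gly_charge_local(j, 2) };
      double* w = &gw[3 * j];
      rot_apply(R, xl, w);
      w[0] += t[0]; w[1] += t[1]; w[2] += t[2];
      double fj[3] = { 0, 0, 0 };
      const double qj = gly_charge_q[j];
      for (int i = 0; i < nfc; ++i) {
        double dx = w[0] - fib_charge_pos(i, 0);
        double dy = w[1] - fib_charge_pos(i, 1);
        double dz = w[2] - fib_charge_pos(i, 2);
        double r2 = dx * dx + dy * dy + dz * dz;
        double r = std::sqrt(r2);
        double A = coul_pref * fib_charge_q[i] * qj;
        double fmag = A * std::exp(-kappa * r) * (kappa * r + 1.0) / (r2 * r);
        fj[0] += fmag * dx; fj[1] += fmag * dy; fj[2] += fmag * dz;
      }
      for (int i = 0; i < nrp; ++i) {
        double dx = w[0] - fib_rep_pos(i, 0);
        double dy = w[1] - fib_rep_pos(i, 1);
        double dz = w[2] - fib_rep_pos(i, 2);
        double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        if (r > 3.0 * SOFTCORE_D0) continue;
        if (r < 0.5) r = 0.5;
        double smag = 12.0 * SOFTCORE_EPS *
          std::pow(SOFTCORE_D0 / r, 12.0) / (r * r);
        fj[0] += smag * dx; fj[1] += smag * dy; fj[2] += smag * dz;
      }
      F[0] += fj[0]; F[1] += fj[1]; F[2] += fj[2];
      double ax = w[0] - t[0], ay = w[1] - t[1], az = w[2] - t[2];
      T[0] += ay * fj[2] - az * fj[1];
      T[1] += az * fj[0] - ax * fj[2];
      T[2] += ax * fj[1] - ay * fj[0];
    }
    if (!R_finite(F[0]) || !R_finite(F[1]) || !R_finite(F[2])) {
      PutRNGstate();
      stop("non-finite force encountered at step %lld", step);
    }

    // Ermak-McCammon update: drift + diffusion, then rotation
    const double ct = Dt / kBT * dt, st = std::sqrt(2.0 * Dt * dt);
    const double cr = Dr / kBT * dt, sr = std::sqrt(2.0 * Dr * dt);
    double xi[3] = { norm_rand(), norm_rand(), norm_rand() };
    t[0] += ct * F[0] + st * xi[0];
    t[1] += ct * F[1] + st * xi[1];
    t[2] += ct * F[2] + st * xi[2];
    double w[3] = { cr * T[0] + sr * norm_rand(),
                    cr * T[1] + sr * norm_rand(),
                    cr * T[2] + sr * norm_rand() };
    rot_compose_axis_angle(R, w);
    step += 1;
    if (step % 1000 == 0) orthonormalize(R);

    if (record_stride > 0 && step % record_stride == 0) {
      rec_t.push_back(t[0]); rec_t.push_back(t[1]); rec_t.push_back(t[2]);
      // orientation tracker: body z axis in world frame (third column of R)
      rec_u.push_back(R[6]); rec_u.push_back(R[7]); rec_u.push_back(R[8]);
    }

    double ex = t[0] - fib_center[0], ey = t[1] - fib_center[1],
           ez = t[2] - fib_center[2];
    if (ex * ex + ey * ey + ez * ez >= q2) { status = 1; break; }
  }
  PutRNGstate();

  NumericMatrix Rout(3, 3);
  for (int j = 0; j < 3; ++j)
    for (int i = 0; i < 3; ++i) Rout(i, j) = R[i + 3 * j];
  List out = List::create(
    _["status"] = status, _["site"] = site, _["n_steps"] = (double)step,
    _["R"] = Rout, _["t"] = NumericVector::create(t[0], t[1], t[2]));
  if (record_stride > 0) {
    int nr = (int)(rec_t.size() / 3);
    NumericMatrix P(nr, 3), U(nr, 3);
    for (int i = 0; i < nr; ++i)
      for (int j = 0; j < 3; ++j) {
        P(i, j) = rec_t[3 * i + j];
        U(i, j) = rec_u[3 * i + j];
      }
    out["positions"] = P;
    out["orientations"] = U;
  }
  return out;
}
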