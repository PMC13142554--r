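#include <Rcpp.h>
using namespace Rcpp;

// Cell-centered 5-point stencils on a rectangular grid with zero-flux
// (Neumann) boundaries implemented by mirrored ghost cells: the ghost
// beyond a boundary cell equals the boundary cell itself, so the flux
// across every domain face vanishes and all discrete sums telescope.

static inline int mir(int i, int n) {
  if (i < 0) return 0;
  if (i >= n) return n - 1;
  return i;
}

// [[Rcpp::export]]
NumericMatrix cpp_laplacian(const NumericMatrix& f, double h) {
  const int nr = f.nrow(), nc = f.ncol();
  NumericMatrix out(nr, nc);
  const double ih2 = 1.0 / (h * h);
  for (int j = 0; j < nc; ++j) {
    const int jm = mir(j - 1, nc), jp = mir(j + 1, nc);
    for (int i = 0; i < nr; ++i) {
      const int im = mir(i - 1, nr), ip = mir(i + 1, nr);
      out(i, j) = (f(im, j) + f(ip, j) + f(i, jm) + f(i, jp) - 4.0 * f(i, j)) * ih2;
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_grad_dot(const NumericMatrix& f, const NumericMatrix& g, double h) {
  const int nr = f.nrow(), nc = f.ncol();
  NumericMatrix out(nr, nc);
  const double i2h = 1.0 / (2.0 * h);
  for (int j = 0; j < nc; ++j) {
    const int jm = mir(j - 1, nc), jp = mir(j + 1, nc);
    for (int i = 0; i < nr; ++i) {
      const int im = mir(i - 1, nr), ip = mir(i + 1, nr);
      const double fx = (f(i, jp) - f(i, jm)) * i2h;
      const double fy = (f(ip, j) - f(im, j)) * i2h;
      const double gx = (g(i, jp) - g(i, jm)) * i2h;
      const double gy = (g(ip, j) - g(im, j)) * i2h;
      out(i, j) = fx * gx + fy * gy;
    }
  }
  return out;
}

// Face density: arithmetic mean (upwind = 0) or donor cell against the
// transport direction b grad v (upwind = 1; cells drift up-gradient, so the
// donor is the low-v side).
static inline double face_w(double uc, double unb, double vc, double vnb, int upwind) {
  if (!upwind) return 0.5 * (uc + unb);
  return (vnb > vc) ? uc : unb;
}

// Conservative chemotaxis divergence div(u grad v): each interior face
// carries flux w_face * (v_nb - v_c) / h; boundary faces carry none, so the
// global sum telescopes to zero.
// [[Rcpp::export]]
NumericMatrix cpp_chemotaxis_div(const NumericMatrix& u, const NumericMatrix& v,
                                 double h, int upwind = 0) {
  const int nr = u.nrow(), nc = u.ncol();
  NumericMatrix out(nr, nc);
  const double ih2 = 1.0 / (h * h);
  for (int j = 0; j < nc - 1; ++j) {   // faces between columns j, j+1
    for (int i = 0; i < nr; ++i) {
      const double fl = face_w(u(i, j), u(i, j + 1), v(i, j), v(i, j + 1), upwind) *
                        (v(i, j + 1) - v(i, j)) * ih2;
      out(i, j)     += fl;
      out(i, j + 1) -= fl;
    }
  }
  for (int j = 0; j < nc; ++j) {       // faces between rows i, i+1
    for (int i = 0; i < nr - 1; ++i) {
      const double fl = face_w(u(i, j), u(i + 1, j), v(i, j), v(i + 1, j), upwind) *
                        (v(i + 1, j) - v(i, j)) * ih2;
      out(i, j)     += fl;
      out(i + 1, j) -= fl;
    }
  }
  return out;
}

struct KsPar {
  double a, b, c, e, du, dv, gamma, h;
  int upwind;
};

// Fused single-pass right-hand side. The chemotaxis term is accumulated
// per cell from its four face fluxes with mirrored indices, which drops
// boundary faces automatically (v_ghost == v_cell) and agrees with the
// face-loop form of cpp_chemotaxis_div to round-off.
static void ks_rhs_into(const NumericMatrix& U, const NumericMatrix& V,
                        const KsPar& p, NumericMatrix& OU, NumericMatrix& OV) {
  const int nr = U.nrow(), nc = U.ncol();
  const double ih2 = 1.0 / (p.h * p.h);
  const double *u = U.begin(), *v = V.begin();
  double *ou = OU.begin(), *ov = OV.begin();
  for (int j = 0; j < nc; ++j) {
    const int jm = mir(j - 1, nc), jp = mir(j + 1, nc);
    const double *uc = u + (size_t)j * nr, *ul = u + (size_t)jm * nr,
                 *ur = u + (size_t)jp * nr;
    const double *vc = v + (size_t)j * nr, *vl = v + (size_t)jm * nr,
                 *vr = v + (size_t)jp * nr;
    double *po = ou + (size_t)j * nr, *pv = ov + (size_t)j * nr;
    for (int i = 0; i < nr; ++i) {
      const int im = (i > 0) ? i - 1 : 0, ip = (i < nr - 1) ? i + 1 : nr - 1;
      const double uij = uc[i], vij = vc[i];
      const double uim = uc[im], uip = uc[ip], vim = vc[im], vip = vc[ip];
      const double lapu = (uim + uip + ul[i] + ur[i] - 4.0 * uij) * ih2;
      const double lapv = (vim + vip + vl[i] + vr[i] - 4.0 * vij) * ih2;
      const double chem =
        (face_w(uij, ul[i], vij, vl[i], p.upwind) * (vl[i] - vij) +
         face_w(uij, ur[i], vij, vr[i], p.upwind) * (vr[i] - vij) +
         face_w(uij, uim, vij, vim, p.upwind) * (vim - vij) +
         face_w(uij, uip, vij, vip, p.upwind) * (vip - vij)) * ih2;
      const double fu = p.a * uij * (1.0 - uij) * (uij - p.gamma);
      po[i] = fu - p.b * chem + p.du * lapu;
      pv[i] = p.c * uij - p.e * vij + p.dv * lapv;
    }
  }
}

// [[Rcpp::export]]
List cpp_ks_rhs(const NumericMatrix& u, const NumericMatrix& v,
                double a, double b, double c, double e,
                double du, double dv, double gamma, double h,
                int upwind = 0) {
  KsPar p = {a, b, c, e, du, dv, gamma, h, upwind};
  NumericMatrix ou(u.nrow(), u.ncol()), ov(u.nrow(), u.ncol());
  ks_rhs_into(u, v, p, ou, ov);
  return List::create(_["du_dt"] = ou, _["dv_dt"] = ov);
}

// Classical RK4 integrator for the full PDE system.
//
// snap_steps: sorted 0-based step indices (0 = initial state) at which the
//   full (u, v) fields are stored.
// trace_rows/trace_cols: 0-based probe positions; every trace_every steps
//   the values of u, lap(u), grad(u).grad(v), v, lap(v) at each probe are
//   recorded.
// Returns diagnostics per step, snapshots, traces and a blow-up flag.
// [[Rcpp::export]]
List cpp_ks_simulate(const NumericMatrix& u0, const NumericMatrix& v0,
                     double a, double b, double c, double e,
                     double du, double dv, double gamma, double h,
                     double dt, int nsteps,
                     const IntegerVector& snap_steps,
                     const IntegerVector& trace_rows,
                     const IntegerVector& trace_cols,
                     int trace_every, double blowup, int upwind = 0) {
  KsPar p = {a, b, c, e, du, dv, gamma, h, upwind};
  const int nr = u0.nrow(), nc = u0.ncol(), n = nr * nc;
  NumericMatrix u = clone(u0), v = clone(v0);
  NumericMatrix k1u(nr, nc), k1v(nr, nc), k2u(nr, nc), k2v(nr, nc),
                k3u(nr, nc), k3v(nr, nc), k4u(nr, nc), k4v(nr, nc),
                tu(nr, nc), tv(nr, nc);

  const int ndiag = nsteps + 1;
  NumericVector d_t(ndiag), d_mu(ndiag), d_mv(ndiag),
                d_minu(ndiag), d_maxu(ndiag), d_minv(ndiag);
  List snaps_u(snap_steps.size()), snaps_v(snap_steps.size());
  int snap_i = 0;

  const int ntr = trace_rows.size();
  int ntrec = (trace_every > 0 && ntr > 0) ? nsteps / trace_every + 1 : 0;
  NumericVector tr_t(std::max(ntrec, 0));
  NumericMatrix tr_u(std::max(ntrec, 1), ntr), tr_lu(std::max(ntrec, 1), ntr),
                tr_gd(std::max(ntrec, 1), ntr), tr_v(std::max(ntrec, 1), ntr),
                tr_lv(std::max(ntrec, 1), ntr);
  int tr_i = 0;

  bool blew = false;
  int blow_step = -1;

  for (int step = 0; step <= nsteps; ++step) {
    double su = 0, sv = 0, mnu = u[0], mxu = u[0], mnv = v[0];
    for (int k = 0; k < n; ++k) {
      su += u[k]; sv += v[k];
      if (u[k] < mnu) mnu = u[k];
      if (u[k] > mxu) mxu = u[k];
      if (v[k] < mnv) mnv = v[k];
    }
    d_t[step] = step * dt;
    d_mu[step] = su / n; d_mv[step] = sv / n;
    d_minu[step] = mnu; d_maxu[step] = mxu; d_minv[step] = mnv;

    if (snap_i < snap_steps.size() && snap_steps[snap_i] == step) {
      snaps_u[snap_i] = clone(u);
      snaps_v[snap_i] = clone(v);
      ++snap_i;
    }
    if (ntrec > 0 && step % trace_every == 0 && tr_i < ntrec) {
      const double ih2 = 1.0 / (h * h), i2h = 1.0 / (2.0 * h);
      tr_t[tr_i] = step * dt;
      for (int q = 0; q < ntr; ++q) {
        const int i = trace_rows[q], j = trace_cols[q];
        const int im = mir(i - 1, nr), ip = mir(i + 1, nr);
        const int jm = mir(j - 1, nc), jp = mir(j + 1, nc);
        tr_u(tr_i, q) = u(i, j);
        tr_v(tr_i, q) = v(i, j);
        tr_lu(tr_i, q) = (u(im, j) + u(ip, j) + u(i, jm) + u(i, jp) - 4.0 * u(i, j)) * ih2;
        tr_lv(tr_i, q) = (v(im, j) + v(ip, j) + v(i, jm) + v(i, jp) - 4.0 * v(i, j)) * ih2;
        const double ux = (u(i, jp) - u(i, jm)) * i2h, uy = (u(ip, j) - u(im, j)) * i2h;
        const double vx = (v(i, jp) - v(i, jm)) * i2h, vy = (v(ip, j) - v(im, j)) * i2h;
        tr_gd(tr_i, q) = ux * vx + uy * vy;
      }
      ++tr_i;
    }

    if (std::abs(mxu) > blowup || std::abs(mnu) > blowup || !std::isfinite(su)) {
      blew = true; blow_step = step;
      break;
    }
    if (step == nsteps) break;

    // classical RK4 step
    ks_rhs_into(u, v, p, k1u, k1v);
    for (int k = 0; k < n; ++k) { tu[k] = u[k] + 0.5 * dt * k1u[k]; tv[k] = v[k] + 0.5 * dt * k1v[k]; }
    ks_rhs_into(tu, tv, p, k2u, k2v);
    for (int k = 0; k < n; ++k) { tu[k] = u[k] + 0.5 * dt * k2u[k]; tv[k] = v[k] + 0.5 * dt * k2v[k]; }
    ks_rhs_into(tu, tv, p, k3u, k3v);
    for (int k = 0; k < n; ++k) { tu[k] = u[k] + dt * k3u[k]; tv[k] = v[k] + dt * k3v[k]; }
    ks_rhs_into(tu, tv, p, k4u, k4v);
    const double w = dt / 6.0;
    for (int k = 0; k < n; ++k) {
      u[k] += w * (k1u[k] + 2.0 * k2u[k] + 2.0 * k3u[k] + k4u[k]);
      v[k] += w * (k1v[k] + 2.0 * k2v[k] + 2.0 * k3v[k] + k4v[k]);
    }
  }

  int used = blew ? blow_step + 1 : ndiag;
  DataFrame diag = DataFrame::create(
    _["t"] = head(d_t, used), _["mean_u"] = head(d_mu, used),
    _["mean_v"] = head(d_mv, used), _["min_u"] = head(d_minu, used),
    _["max_u"] = head(d_maxu, used), _["min_v"] = head(d_minv, used));

  return List::create(
    _["diag"] = diag,
    _["snaps_u"] = snaps_u, _["snaps_v"] = snaps_v,
    _["n_snaps"] = snap_i,
    _["trace_t"] = head(tr_t, tr_i),
    _["trace_u"] = tr_u, _["trace_lap_u"] = tr_lu, _["trace_grad_uv"] = tr_gd,
    _["trace_v"] = tr_v, _["trace_lap_v"] = tr_lv, _["n_trace"] = tr_i,
    _["blowup"] = blew, _["blow_step"] = blow_step,
    _["u_final"] = u, _["v_final"] = v);
}
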