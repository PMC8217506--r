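// Explicit central-difference dynamics for hexahedral tissue meshes with
// embedded vessel truss elements. One-point integrated trilinear hexes with
// Flanagan-Belytschko viscous hourglass control; Ogden hyperelasticity on
// isochoric principal stretches + volumetric penalty K(J-1); Prony-series
// deviatoric viscoelasticity via the recursive exponential update; beam
// nodes slaved to their host hex through trilinear shape functions with
// force distribution by the transposed weights; rigid flat-tipped
// cylindrical impactor by nodal penalty contact. All quantities SI.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const double SG[8][3] = {
  {-1, -1, -1}, {1, -1, -1}, {1, 1, -1}, {-1, 1, -1},
  {-1, -1, 1},  {1, -1, 1},  {1, 1, 1},  {-1, 1, 1}
};

// hourglass base vectors for the corner ordering above
static const double HG[4][8] = {
  { 1, -1,  1, -1,  1, -1,  1, -1},   // xi*eta
  { 1,  1, -1, -1, -1, -1,  1,  1},   // eta*zeta
  { 1, -1, -1,  1, -1,  1,  1, -1},   // xi*zeta
  {-1,  1, -1,  1,  1, -1,  1, -1}    // xi*eta*zeta
};

static inline void shape_fun(const double xi[3], double N[8]) {
  for (int a = 0; a < 8; ++a) {
    N[a] = 0.125 * (1 + SG[a][0] * xi[0]) * (1 + SG[a][1] * xi[1]) *
           (1 + SG[a][2] * xi[2]);
  }
}

static inline void shape_grad(const double xi[3], double d[8][3]) {
  for (int a = 0; a < 8; ++a) {
    d[a][0] = 0.125 * SG[a][0] * (1 + SG[a][1] * xi[1]) * (1 + SG[a][2] * xi[2]);
    d[a][1] = 0.125 * (1 + SG[a][0] * xi[0]) * SG[a][1] * (1 + SG[a][2] * xi[2]);
    d[a][2] = 0.125 * (1 + SG[a][0] * xi[0]) * (1 + SG[a][1] * xi[1]) * SG[a][2];
  }
}

// ---------------------------------------------------------------------------
// Inverse isoparametric point location with Newton iteration.
// nodes: n x 3, elems: E x 8 (1-based), pts: m x 3.
// Returns elem id (1-based, 0 = not found), natural coords, residual.
// [[Rcpp::export]]
List cpp_locate_points(const arma::mat& nodes, const arma::imat& elems,
                       const arma::mat& pts, double tol = 1e-10,
                       int max_iter = 50) {
  const int E = elems.n_rows, m = pts.n_rows;
  // element AABBs and a uniform binning grid
  arma::mat lo(E, 3), hi(E, 3);
  for (int e = 0; e < E; ++e) {
    arma::rowvec l(3), h(3);
    l.fill(arma::datum::inf); h.fill(-arma::datum::inf);
    for (int a = 0; a < 8; ++a) {
      const arma::rowvec x = nodes.row(elems(e, a) - 1);
      l = arma::min(l, x); h = arma::max(h, x);
    }
    lo.row(e) = l; hi.row(e) = h;
  }
  arma::rowvec glo = arma::min(lo, 0), ghi = arma::max(hi, 0);
  arma::rowvec ext = ghi - glo;
  double cell = arma::mean(arma::mean(hi - lo));
  if (!(cell > 0)) cell = 1.0;
  int nb[3];
  for (int k = 0; k < 3; ++k) {
    nb[k] = std::max(1, (int)std::floor(ext(k) / cell));
    nb[k] = std::min(nb[k], 64);
  }
  auto bin_of = [&](double v, int k) {
    int b = (int)std::floor((v - glo(k)) / (ext(k) > 0 ? ext(k) : 1.0) * nb[k]);
    return std::min(std::max(b, 0), nb[k] - 1);
  };
  std::vector<std::vector<int>> grid(nb[0] * nb[1] * nb[2]);
  double pad = 1e-9 * (arma::norm(ext) + 1.0);
  for (int e = 0; e < E; ++e) {
    int b0[3], b1[3];
    for (int k = 0; k < 3; ++k) {
      b0[k] = bin_of(lo(e, k) - pad, k);
      b1[k] = bin_of(hi(e, k) + pad, k);
    }
    for (int i = b0[0]; i <= b1[0]; ++i)
      for (int j = b0[1]; j <= b1[1]; ++j)
        for (int k2 = b0[2]; k2 <= b1[2]; ++k2)
          grid[i + nb[0] * (j + nb[1] * k2)].push_back(e);
  }

  IntegerVector out_elem(m);
  arma::mat out_xi(m, 3, arma::fill::zeros);
  NumericVector out_res(m);
  double scale = arma::norm(ext) + 1.0;

  for (int p = 0; p < m; ++p) {
    const arma::rowvec pt = pts.row(p);
    int cidx = bin_of(pt(0), 0) +
      nb[0] * (bin_of(pt(1), 1) + nb[1] * bin_of(pt(2), 2));
    std::vector<int> cand = grid[cidx];
    std::sort(cand.begin(), cand.end());
    out_elem[p] = 0;
    for (int e : cand) {
      bool inbox = true;
      for (int k = 0; k < 3; ++k) {
        if (pt(k) < lo(e, k) - pad || pt(k) > hi(e, k) + pad) {
          inbox = false; break;
        }
      }
      if (!inbox) continue;
      arma::mat X(3, 8);
      for (int a = 0; a < 8; ++a) {
        X.col(a) = nodes.row(elems(e, a) - 1).t();
      }
      double xi[3] = {0, 0, 0};
      double res = arma::datum::inf;
      bool conv = false;
      int polish = 0;  // extra Newton steps after meeting the tolerance
      for (int it = 0; it < max_iter; ++it) {
        double N[8];
        shape_fun(xi, N);
        arma::vec3 r = -pt.t();
        for (int a = 0; a < 8; ++a) r += N[a] * X.col(a);
        res = arma::norm(r);
        if (res < tol * scale) {
          conv = true;
          if (++polish > 2) break;
        }
        double d[8][3];
        shape_grad(xi, d);
        arma::mat33 Jm(arma::fill::zeros);
        for (int a = 0; a < 8; ++a)
          for (int i = 0; i < 3; ++i)
            for (int jj = 0; jj < 3; ++jj)
              Jm(i, jj) += X(i, a) * d[a][jj];
        arma::vec3 dxi;
        if (!arma::solve(dxi, Jm, r)) break;
        for (int k = 0; k < 3; ++k) xi[k] -= dxi(k);
        // keep the iterate from wandering far outside the element
        for (int k = 0; k < 3; ++k)
          xi[k] = std::min(std::max(xi[k], -3.0), 3.0);
      }
      if (conv &&
          std::max({std::fabs(xi[0]), std::fabs(xi[1]), std::fabs(xi[2])}) <=
            1.0 + 1e-8) {
        out_elem[p] = e + 1;
        for (int k = 0; k < 3; ++k)
          out_xi(p, k) = std::min(std::max(xi[k], -1.0), 1.0);
        out_res[p] = res;
        break;  // candidates sorted: lowest element id wins ties
      }
    }
  }
  return List::create(_["elem"] = out_elem, _["xi"] = out_xi,
                      _["residual"] = out_res);
}

// ---------------------------------------------------------------------------
// Batch symmetric 3x3 eigendecomposition. tensors: n x 6 Voigt
// (xx,yy,zz,xy,yz,xz). Values sorted descending; vectors as n x 9
// (v1, v2, v3 stacked column-major).
// [[Rcpp::export]]
List cpp_eig_batch(const arma::mat& tensors) {
  const int n = tensors.n_rows;
  arma::mat values(n, 3), vectors(n, 9);
  arma::mat33 A;
  arma::vec eval;
  arma::mat evec;
  for (int i = 0; i < n; ++i) {
    A(0, 0) = tensors(i, 0); A(1, 1) = tensors(i, 1); A(2, 2) = tensors(i, 2);
    A(0, 1) = A(1, 0) = tensors(i, 3);
    A(1, 2) = A(2, 1) = tensors(i, 4);
    A(0, 2) = A(2, 0) = tensors(i, 5);
    arma::eig_sym(eval, evec, A);  // ascending
    for (int k = 0; k < 3; ++k) {
      values(i, k) = eval(2 - k);
      for (int c = 0; c < 3; ++c) vectors(i, 3 * k + c) = evec(c, 2 - k);
    }
  }
  return List::create(_["values"] = values, _["vectors"] = vectors);
}

// ---------------------------------------------------------------------------
// helpers for the solver

struct Contact {
  bool on = false;
  double cx = 0, cy = 0, R = 0, z0 = 0, v = 0, depth = 0, dwell = 0;
  bool retract = false;
  double k = 0, fillet = 0, xi = 0.2;
  double face_vz(double t) const {
    double t1 = depth / v;
    if (t <= t1) return -v;
    if (t <= t1 + dwell) return 0.0;
    return retract ? v : 0.0;
  }
  double face_z(double t) const {
    double t1 = depth / v;
    if (t <= t1) return z0 - v * t;
    if (t <= t1 + dwell) return z0 - depth;
    if (!retract) return z0 - depth;
    double z = z0 - depth + v * (t - t1 - dwell);
    return std::min(z, z0 + 1.0);  // fully withdrawn
  }
  // tip surface height above the flat face: 0 in the interior, a quarter
  // torus of radius `fillet` at the rim (flat punches have finite edge
  // radii; this also spreads the edge shear over the rim width)
  double rim_lift(double r) const {
    if (fillet <= 0 || r <= R - fillet) return 0.0;
    double s = r - (R - fillet);
    if (s >= fillet) return fillet;  // unreachable: r <= R
    return fillet - std::sqrt(fillet * fillet - s * s);
  }
};

// [[Rcpp::export]]
List cpp_run_solver(const arma::mat& X0, const arma::imat& hex,
                    const arma::vec& og_mu, const arma::vec& og_alpha,
                    const arma::vec& pr_G, const arma::vec& pr_tau,
                    double rho, double Kbulk,
                    const arma::imat& beam_conn, const arma::vec& beam_area,
                    double beam_E, double beam_rho,
                    const arma::ivec& bn_elem, const arma::mat& bn_xi,
                    const arma::ivec& fixed_idx,
                    const arma::ivec& presc_idx, const arma::vec& presc_times,
                    const arma::cube& presc_pos,
                    List contact_cfg,
                    double dt, double t_end, double out_int,
                    double hg_coef, double hg_stiff, double damp,
                    bool record_energy,
                    const arma::mat& v_init,
                    double bulk_q1, double bulk_q2) {
  const int n = X0.n_rows, E = hex.n_rows;
  const int B = beam_conn.n_rows, nbn = bn_elem.n_elem;
  const int nog = og_mu.n_elem, npr = pr_G.n_elem;

  Contact ct;
  ct.on = as<bool>(contact_cfg["on"]);
  if (ct.on) {
    ct.fillet = as<double>(contact_cfg["fillet"]);
    ct.cx = as<double>(contact_cfg["cx"]);
    ct.cy = as<double>(contact_cfg["cy"]);
    ct.R = as<double>(contact_cfg["R"]);
    ct.z0 = as<double>(contact_cfg["z0"]);
    ct.v = as<double>(contact_cfg["v"]);
    ct.depth = as<double>(contact_cfg["depth"]);
    ct.dwell = as<double>(contact_cfg["dwell"]);
    ct.retract = as<bool>(contact_cfg["retract"]);
    ct.k = as<double>(contact_cfg["k"]);
    ct.xi = as<double>(contact_cfg["xi"]);
  }

  // --- precompute element reference data -------------------------------
  arma::cube gradN0(8, 3, E);     // dN/dX at centroid
  arma::vec V0(E);
  arma::mat gamma(4 * E, 8);      // FB hourglass vectors
  arma::vec m(n, arma::fill::zeros);
  {
    double d0[8][3];
    double xi0[3] = {0, 0, 0};
    shape_grad(xi0, d0);
    for (int e = 0; e < E; ++e) {
      arma::mat X(3, 8);
      for (int a = 0; a < 8; ++a) X.col(a) = X0.row(hex(e, a) - 1).t();
      arma::mat33 J(arma::fill::zeros);
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int jj = 0; jj < 3; ++jj)
            J(i, jj) += X(i, a) * d0[a][jj];
      double dJ = arma::det(J);
      if (dJ <= 0) stop("element %d has non-positive reference Jacobian", e + 1);
      V0(e) = 8.0 * dJ;
      arma::mat33 Jinv = arma::inv(J);
      for (int a = 0; a < 8; ++a) {
        arma::rowvec3 dref;
        for (int k = 0; k < 3; ++k) dref(k) = d0[a][k];
        arma::rowvec3 g = dref * Jinv;
        for (int k = 0; k < 3; ++k) gradN0(a, k, e) = g(k);
        m(hex(e, a) - 1) += rho * V0(e) / 8.0;
      }
      // gamma_i = h_i - (sum_b h_ib X_b) . gradN
      for (int i4 = 0; i4 < 4; ++i4) {
        arma::vec3 hx(arma::fill::zeros);
        for (int b = 0; b < 8; ++b) hx += HG[i4][b] * X.col(b);
        for (int a = 0; a < 8; ++a) {
          double dot = 0;
          for (int k = 0; k < 3; ++k) dot += hx(k) * gradN0(a, k, e);
          gamma(4 * e + i4, a) = HG[i4][a] - dot;
        }
      }
    }
  }

  // --- beam reference data ---------------------------------------------
  arma::mat bnW(nbn, 8);          // trilinear weights of each beam node
  arma::mat bnX0(nbn, 3);
  for (int b = 0; b < nbn; ++b) {
    double xi[3] = {bn_xi(b, 0), bn_xi(b, 1), bn_xi(b, 2)};
    double N[8];
    shape_fun(xi, N);
    arma::rowvec3 x(arma::fill::zeros);
    for (int a = 0; a < 8; ++a) {
      bnW(b, a) = N[a];
      x += N[a] * X0.row(hex(bn_elem(b) - 1, a) - 1);
    }
    bnX0.row(b) = x;
  }
  arma::vec L0(B);
  for (int e = 0; e < B; ++e) {
    L0(e) = arma::norm(bnX0.row(beam_conn(e, 1) - 1) -
                       bnX0.row(beam_conn(e, 0) - 1));
    if (L0(e) <= 0) stop("beam element %d has zero reference length", e + 1);
    // lump beam mass onto host nodes through the coupling weights
    for (int end = 0; end < 2; ++end) {
      int bn = beam_conn(e, end) - 1;
      double mb = beam_rho * beam_area(e) * L0(e) / 2.0;
      for (int a = 0; a < 8; ++a)
        m(hex(bn_elem(bn) - 1, a) - 1) += bnW(bn, a) * mb;
    }
  }

  // --- state ------------------------------------------------------------
  arma::mat x = X0, v(n, 3, arma::fill::zeros), f(n, 3, arma::fill::zeros);
  arma::mat fint(n, 3, arma::fill::zeros);
  if (v_init.n_rows == (arma::uword)n) v = v_init;
  arma::cube H(E, 6, npr, arma::fill::zeros);  // visco internal variables
  arma::mat Edev_prev(E, 6, arma::fill::zeros);
  arma::mat cur_stress(E, 6, arma::fill::zeros);
  arma::mat cur_strain(E, 6, arma::fill::zeros);
  arma::vec cur_bstress(B, arma::fill::zeros);
  arma::mat cur_bdir(B, 3, arma::fill::zeros);
  arma::mat bx(nbn, 3);           // current beam node positions

  std::vector<bool> is_fixed(n, false), is_presc(n, false);
  for (arma::uword i = 0; i < fixed_idx.n_elem; ++i)
    is_fixed[fixed_idx(i) - 1] = true;
  for (arma::uword i = 0; i < presc_idx.n_elem; ++i)
    is_presc[presc_idx(i) - 1] = true;

  const int nf = (int)std::llround(t_end / out_int) + 1;
  arma::cube out_pos(nf, n, 3), out_stress(nf, E, 6), out_strain(nf, E, 6);
  arma::mat out_bstress(nf, B), out_energy(nf, 3, arma::fill::zeros);
  arma::cube out_bdir(nf, B, 3);
  arma::vec out_times(nf);

  double Eint = 0, Wext = 0;
  const double mu_inst = arma::dot(og_mu, og_alpha) / 2.0 +
    arma::accu(pr_G);
  const double sound = std::sqrt((Kbulk + 4.0 / 3.0 * mu_inst) / rho);

  // reference beam directions for frame 0
  for (int e = 0; e < B; ++e) {
    arma::rowvec3 d = bnX0.row(beam_conn(e, 1) - 1) -
                      bnX0.row(beam_conn(e, 0) - 1);
    cur_bdir.row(e) = d / arma::norm(d);
  }

  int frame = 0;
  auto record = [&](double t) {
    out_times(frame) = t;
    for (int i = 0; i < n; ++i)
      for (int k = 0; k < 3; ++k) out_pos(frame, i, k) = x(i, k);
    for (int e = 0; e < E; ++e)
      for (int k = 0; k < 6; ++k) {
        out_stress(frame, e, k) = cur_stress(e, k);
        out_strain(frame, e, k) = cur_strain(e, k);
      }
    for (int e = 0; e < B; ++e) {
      out_bstress(frame, e) = cur_bstress(e);
      for (int k = 0; k < 3; ++k) out_bdir(frame, e, k) = cur_bdir(e, k);
    }
    if (record_energy) {
      double ke = 0;
      for (int i = 0; i < n; ++i) ke += 0.5 * m(i) * arma::dot(v.row(i), v.row(i));
      out_energy(frame, 0) = ke;
      out_energy(frame, 1) = Eint;
      out_energy(frame, 2) = Wext;
    }
    ++frame;
  };
  record(0.0);

  arma::vec eval;
  arma::mat evec;
  arma::mat33 Fdef, Cm, Sm, Pm, sig;

  int pseg = 0;  // current prescribed-waypoint interval
  const int np = presc_idx.n_elem;
  const int nw = presc_times.n_elem;

  // adaptive stepping: the base dt shrinks with the running minimum
  // Jacobian ratio, tracking the compression stiffening of the volumetric
  // response; steps land exactly on the output times
  double t = 0.0, dt_prev = dt, Jmin_prev = 1.0;
  long total_steps = 0;
  for (int k = 1; k < nf; ++k) {
   double t_target = k * out_int;
   while (t < t_target - 1e-12 * out_int) {
    // the volumetric push-back K(J-1)J C^-1 stiffens like 1/lambda_min^2
    // in the squashed direction, so the stable step shrinks with the
    // smallest eigenvalue of C (= lambda_min^2)
    double jf = std::max(Jmin_prev, 0.02);
    double dtn = dt * std::min(1.0, jf);
    if (t + dtn > t_target) dtn = t_target - t;
    double t_new = t + dtn;
    if (++total_steps > 50000000L) stop("step budget exhausted");
    double Jmin_cur = 1.0;
    f.zeros();

    // ---- hex internal forces ----
    for (int e = 0; e < E; ++e) {
      arma::mat X(3, 8);
      for (int a = 0; a < 8; ++a) X.col(a) = x.row(hex(e, a) - 1).t();
      Fdef.zeros();
      for (int a = 0; a < 8; ++a)
        for (int i = 0; i < 3; ++i)
          for (int jj = 0; jj < 3; ++jj)
            Fdef(i, jj) += X(i, a) * gradN0(a, jj, e);
      double J = arma::det(Fdef);
      if (!(J > 0)) {
        stop("element %d inverted at t = %g ms", e + 1, t_new * 1e3);
      }

      Cm = Fdef.t() * Fdef;
      arma::eig_sym(eval, evec, Cm);
      if (eval(0) < Jmin_cur) Jmin_cur = eval(0);
      arma::vec3 lam = arma::sqrt(eval);
      double Jm13 = std::pow(J, -1.0 / 3.0);
      arma::vec3 lb = lam * Jm13;
      arma::vec3 tdev(arma::fill::zeros);
      for (int p = 0; p < nog; ++p) {
        arma::vec3 pw;
        for (int k = 0; k < 3; ++k) pw(k) = std::pow(lb(k), og_alpha(p));
        double mn = (pw(0) + pw(1) + pw(2)) / 3.0;
        for (int k = 0; k < 3; ++k) tdev(k) += og_mu(p) * (pw(k) - mn);
      }
      // shock bulk viscosity (linear + quadratic in the volumetric strain
      // rate, compression only); the rate comes from the smooth velocity
      // gradient tr(Fdot F^-1), not a per-step difference of J
      double qbv = 0;
      if (bulk_q1 > 0 || bulk_q2 > 0) {
        arma::mat33 Vg(arma::fill::zeros);
        for (int a = 0; a < 8; ++a) {
          const arma::rowvec3 va = v.row(hex(e, a) - 1);
          for (int i = 0; i < 3; ++i)
            for (int jj = 0; jj < 3; ++jj)
              Vg(i, jj) += va(i) * gradN0(a, jj, e);
        }
        double epsv = arma::trace(Vg * arma::inv(Fdef));
        if (epsv < 0) {
          double Le = std::cbrt(V0(e));
          qbv = rho * Le * (bulk_q2 * bulk_q2 * Le * epsv * epsv +
                            bulk_q1 * sound * (-epsv));
        }
      }
      // S in the C-eigenbasis: deviatoric Ogden + volumetric penalty
      Sm.zeros();
      for (int k = 0; k < 3; ++k) {
        double sk = tdev(k) / eval(k) +
                    (Kbulk * (J - 1.0) - qbv) * J / eval(k);
        Sm += sk * (evec.col(k) * evec.col(k).t());
      }
      // Prony overstress on deviatoric Green-Lagrange strain increment
      double Ev[6];
      Ev[0] = 0.5 * (Cm(0, 0) - 1); Ev[1] = 0.5 * (Cm(1, 1) - 1);
      Ev[2] = 0.5 * (Cm(2, 2) - 1);
      Ev[3] = 0.5 * Cm(0, 1); Ev[4] = 0.5 * Cm(1, 2); Ev[5] = 0.5 * Cm(0, 2);
      double trE3 = (Ev[0] + Ev[1] + Ev[2]) / 3.0;
      double Edev[6] = {Ev[0] - trE3, Ev[1] - trE3, Ev[2] - trE3,
                        Ev[3], Ev[4], Ev[5]};
      for (int p = 0; p < npr; ++p) {
        double ef = std::exp(-dtn / pr_tau(p));
        double cf = pr_G(p) * (pr_tau(p) / dtn) * (1 - ef);
        for (int k = 0; k < 6; ++k) {
          H(e, k, p) = ef * H(e, k, p) + cf * (Edev[k] - Edev_prev(e, k));
        }
      }
      for (int k = 0; k < 6; ++k) Edev_prev(e, k) = Edev[k];
      arma::mat33 Sv(arma::fill::zeros);
      for (int p = 0; p < npr; ++p) {
        Sv(0, 0) += H(e, 0, p); Sv(1, 1) += H(e, 1, p); Sv(2, 2) += H(e, 2, p);
        Sv(0, 1) += H(e, 3, p); Sv(1, 2) += H(e, 4, p); Sv(0, 2) += H(e, 5, p);
      }
      Sv(1, 0) = Sv(0, 1); Sv(2, 1) = Sv(1, 2); Sv(2, 0) = Sv(0, 2);
      Sm += Sv;

      Pm = Fdef * Sm;
      for (int a = 0; a < 8; ++a) {
        int ia = hex(e, a) - 1;
        for (int i = 0; i < 3; ++i) {
          double fi = 0;
          for (int jj = 0; jj < 3; ++jj) fi += Pm(i, jj) * gradN0(a, jj, e);
          f(ia, i) -= V0(e) * fi;
        }
      }
      // hourglass resistance: viscous part on the modal velocity plus a
      // small stiffness part on the modal displacement (the stiffness term
      // gives the zero-energy modes a restoring force so patch tests and
      // quasi-static settles converge; gamma annihilates every affine
      // field, rotations included)
      if (hg_coef > 0 || hg_stiff > 0) {
        double q = hg_coef * rho * sound * std::pow(V0(e), 2.0 / 3.0) / 4.0;
        double kq = hg_stiff * mu_inst * std::cbrt(V0(e));
        for (int i4 = 0; i4 < 4; ++i4) {
          arma::rowvec3 g(arma::fill::zeros), gu(arma::fill::zeros);
          for (int a = 0; a < 8; ++a) {
            int ia = hex(e, a) - 1;
            g += gamma(4 * e + i4, a) * v.row(ia);
            gu += gamma(4 * e + i4, a) * (x.row(ia) - X0.row(ia));
          }
          for (int a = 0; a < 8; ++a) {
            int ia = hex(e, a) - 1;
            for (int k = 0; k < 3; ++k)
              f(ia, k) -= gamma(4 * e + i4, a) * (q * g(k) + kq * gu(k));
          }
        }
      }
      // Cauchy stress and strain for output
      sig = (Fdef * Sm * Fdef.t()) / J;
      cur_stress(e, 0) = sig(0, 0); cur_stress(e, 1) = sig(1, 1);
      cur_stress(e, 2) = sig(2, 2); cur_stress(e, 3) = sig(0, 1);
      cur_stress(e, 4) = sig(1, 2); cur_stress(e, 5) = sig(0, 2);
      for (int k = 0; k < 6; ++k) cur_strain(e, k) = Ev[k];
    }

    // ---- beam (truss) internal forces, slaved kinematics ----
    if (B > 0) {
      for (int b = 0; b < nbn; ++b) {
        arma::rowvec3 xb(arma::fill::zeros);
        for (int a = 0; a < 8; ++a)
          xb += bnW(b, a) * x.row(hex(bn_elem(b) - 1, a) - 1);
        bx.row(b) = xb;
      }
      for (int e = 0; e < B; ++e) {
        int na = beam_conn(e, 0) - 1, nbE = beam_conn(e, 1) - 1;
        arma::rowvec3 d = bx.row(nbE) - bx.row(na);
        double l = arma::norm(d);
        if (l <= 0) stop("beam element %d collapsed", e + 1);
        d /= l;
        double strain = l / L0(e) - 1.0;
        double sb = beam_E * strain;
        cur_bstress(e) = sb;
        cur_bdir.row(e) = d;
        double N = sb * beam_area(e);
        // tension pulls the two beam nodes together; distribute through the
        // transposed coupling weights (action-reaction with the host)
        for (int a = 0; a < 8; ++a) {
          int ha = hex(bn_elem(na) - 1, a) - 1;
          int hb = hex(bn_elem(nbE) - 1, a) - 1;
          for (int k = 0; k < 3; ++k) {
            f(ha, k) += bnW(na, a) * N * d(k);
            f(hb, k) -= bnW(nbE, a) * N * d(k);
          }
        }
      }
    }

    // material internal forces assembled so far (hex + hourglass + beams);
    // contact and damping are external inputs for the energy ledger
    if (record_energy) fint = f;

    // ---- impactor contact (penalty) ----
    if (ct.on) {
      double zf = ct.face_z(t_new);
      double vzf = ct.face_vz(t_new);
      for (int i = 0; i < n; ++i) {
        double dx0 = x(i, 0) - ct.cx, dy0 = x(i, 1) - ct.cy;
        double r2 = dx0 * dx0 + dy0 * dy0;
        if (r2 <= ct.R * ct.R) {
          double zc = zf + ct.rim_lift(std::sqrt(r2));
          if (x(i, 2) > zc) {
            // penalty spring + viscous damping, no adhesion: the punch can
            // only push, and damping must not turn the force tensile
            double fz = -ct.k * (x(i, 2) - zc) -
              2.0 * ct.xi * std::sqrt(ct.k * m(i)) * (v(i, 2) - vzf);
            if (fz < 0) f(i, 2) += fz;
          }
        }
      }
    }

    // ---- damping ----
    if (damp > 0) {
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 3; ++k) f(i, k) -= damp * m(i) * v(i, k);
    }

    // ---- integrate ----
    double dEint = 0, dWext = 0;
    // prescribed waypoint interval for t_new
    while (pseg < nw - 2 && presc_times(pseg + 1) < t_new) ++pseg;
    for (int i = 0; i < n; ++i) {
      if (is_fixed[i] || is_presc[i]) {
        if (is_fixed[i]) v.row(i).zeros();
        continue;
      }
      for (int kc = 0; kc < 3; ++kc) {
        v(i, kc) += 0.5 * (dt_prev + dtn) * f(i, kc) / m(i);
        double du = dtn * v(i, kc);
        x(i, kc) += du;
        if (record_energy) {
          dEint -= fint(i, kc) * du;
          dWext += (f(i, kc) - fint(i, kc)) * du;  // contact + damping input
        }
      }
    }
    if (np > 0) {
      double t0 = presc_times(pseg), t1 = presc_times(pseg + 1);
      double w = (t1 > t0) ? (t_new - t0) / (t1 - t0) : 0.0;
      w = std::min(std::max(w, 0.0), 1.0);
      for (int ip = 0; ip < np; ++ip) {
        int i = presc_idx(ip) - 1;
        for (int kc = 0; kc < 3; ++kc) {
          double xt = (1 - w) * presc_pos(pseg, ip, kc) +
                      w * presc_pos(pseg + 1, ip, kc);
          double du = xt - x(i, kc);
          double vnew = du / dtn;
          if (record_energy) {
            // constraint reaction drives the node: its work is external
            double react = m(i) * (vnew - v(i, kc)) / dtn - f(i, kc);
            dEint -= fint(i, kc) * du;
            dWext += (react + f(i, kc) - fint(i, kc)) * du;
          }
          v(i, kc) = vnew;
          x(i, kc) = xt;
        }
      }
    }
    Eint += dEint;
    Wext += dWext;

    t = t_new;
    dt_prev = dtn;
    Jmin_prev = Jmin_cur;
   }
   if (!x.is_finite()) stop("solver diverged at t = %g ms", t * 1e3);
   record(t);
   if (k % 16 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["times"] = out_times, _["pos"] = out_pos,
                      _["stress"] = out_stress, _["strain"] = out_strain,
                      _["beam_stress"] = out_bstress,
                      _["beam_dir"] = out_bdir,
                      _["energy"] = out_energy);
}
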