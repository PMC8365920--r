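// Planar kinematic-tree rigid-body dynamics with sphere-ground contact and
// Hill-type muscle-tendon actuators.  The same generic core simulates the
// 7-segment walker and the small oracle systems used in the tests (pendulum,
// double pendulum, ballistic flight).
//
// Conventions:
//   * generalized coordinates q = (x, y, phi_base, theta_1, ..., theta_{nb-1})
//     where body 0 is the floating base and theta_i is the revolute joint
//     angle of body i relative to its parent;
//   * world y is up, ground is the half-plane y <= 0;
//   * muscle path model is affine: L_m = L0_m - sum_j r_{mj} (theta_j - theta0_j),
//     so a positive moment arm r_{mj} produces a positive generalized force
//     r_{mj} * F_m on joint j.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

namespace {

struct Tree {
  int nb = 0;              // number of bodies
  int njoint = 0;          // nb - 1 revolute joints
  int ndof = 0;            // 3 + njoint
  bool base_fixed = false;
  arma::ivec parent;       // parent body index, -1 for base
  arma::mat jpos;          // nb x 2, joint position in parent frame
  arma::mat com;           // nb x 2, COM in body frame (origin at own joint)
  arma::vec mass;
  arma::vec inertia;       // about COM
  double g = 9.80665;

  // contact spheres
  arma::ivec cbody;        // attached body
  arma::mat cpos;          // ncon x 2 local position of centre
  arma::vec crad;
  double ck = 1.2e6, cexp = 1.5, cb = 1.0, mu = 0.8, vsm = 0.05;

  // joint limits: njoint x 4 (lo, hi, k, c); k == 0 disables
  arma::mat jlim;

  // muscles
  int nm = 0;
  arma::vec fmax, lopt, vmax, lslack, tact, tdeact, fvp, L0;
  arma::mat marm;          // nm x njoint moment arms
  arma::vec qneu;          // njoint neutral joint angles
};

Tree parse_tree(const List& p) {
  Tree t;
  t.parent = as<arma::ivec>(p["parent"]);
  t.nb = t.parent.n_elem;
  t.njoint = t.nb - 1;
  t.ndof = 3 + t.njoint;
  t.base_fixed = as<bool>(p["base_fixed"]);
  t.jpos = as<arma::mat>(p["jpos"]);
  t.com = as<arma::mat>(p["com"]);
  t.mass = as<arma::vec>(p["mass"]);
  t.inertia = as<arma::vec>(p["inertia"]);
  t.g = as<double>(p["gravity"]);
  if (p.containsElementNamed("contact_body")) {
    t.cbody = as<arma::ivec>(p["contact_body"]);
    t.cpos = as<arma::mat>(p["contact_pos"]);
    t.crad = as<arma::vec>(p["contact_radius"]);
    t.ck = as<double>(p["contact_stiffness"]);
    t.cexp = as<double>(p["contact_exponent"]);
    t.cb = as<double>(p["contact_damping"]);
    t.mu = as<double>(p["friction_mu"]);
    t.vsm = as<double>(p["friction_vsmooth"]);
  }
  if (p.containsElementNamed("joint_limits")) {
    t.jlim = as<arma::mat>(p["joint_limits"]);
  } else {
    t.jlim = arma::zeros<arma::mat>(t.njoint, 4);
  }
  if (p.containsElementNamed("mus_fmax")) {
    t.fmax = as<arma::vec>(p["mus_fmax"]);
    t.lopt = as<arma::vec>(p["mus_lopt"]);
    t.vmax = as<arma::vec>(p["mus_vmax"]);
    t.lslack = as<arma::vec>(p["mus_lslack"]);
    t.tact = as<arma::vec>(p["mus_tact"]);
    t.tdeact = as<arma::vec>(p["mus_tdeact"]);
    t.fvp = as<arma::vec>(p["mus_fvplateau"]);
    t.L0 = as<arma::vec>(p["mus_L0"]);
    t.marm = as<arma::mat>(p["mus_moment_arm"]);
    t.qneu = as<arma::vec>(p["q_neutral"]);
    t.nm = t.fmax.n_elem;
  }
  for (int i = 1; i < t.nb; ++i)
    if (t.parent(i) >= i) stop("bodies must be topologically ordered");
  return t;
}

inline arma::vec2 rot90(const arma::vec2& v) { return arma::vec2({-v(1), v(0)}); }

struct Kin {
  arma::vec phi, omega;          // nb
  arma::mat pref, vref;          // nb x 2 (body joint/reference point)
  arma::mat pcom, vcom;          // nb x 2
  // angular ancestor dof lists per body (dof indices >= 2)
  std::vector<std::vector<int>> adofs;
};

Kin kinematics(const Tree& t, const arma::vec& q, const arma::vec& qd) {
  Kin k;
  k.phi.set_size(t.nb); k.omega.set_size(t.nb);
  k.pref.set_size(t.nb, 2); k.vref.set_size(t.nb, 2);
  k.pcom.set_size(t.nb, 2); k.vcom.set_size(t.nb, 2);
  k.adofs.resize(t.nb);
  for (int i = 0; i < t.nb; ++i) {
    if (i == 0) {
      k.phi(0) = q(2); k.omega(0) = qd(2);
      k.pref.row(0) = arma::rowvec({q(0), q(1)});
      k.vref.row(0) = arma::rowvec({qd(0), qd(1)});
      k.adofs[0] = {2};
    } else {
      int p = t.parent(i);
      double cp = std::cos(k.phi(p)), sp = std::sin(k.phi(p));
      arma::vec2 jp = t.jpos.row(i).t();
      arma::vec2 off = {cp * jp(0) - sp * jp(1), sp * jp(0) + cp * jp(1)};
      k.pref.row(i) = k.pref.row(p) + off.t();
      k.vref.row(i) = k.vref.row(p) + (k.omega(p) * rot90(off)).t();
      k.phi(i) = k.phi(p) + q(3 + i - 1);
      k.omega(i) = k.omega(p) + qd(3 + i - 1);
      k.adofs[i] = k.adofs[p];
      k.adofs[i].push_back(3 + i - 1);
    }
    double c = std::cos(k.phi(i)), s = std::sin(k.phi(i));
    arma::vec2 cm = t.com.row(i).t();
    arma::vec2 coff = {c * cm(0) - s * cm(1), s * cm(0) + c * cm(1)};
    k.pcom.row(i) = k.pref.row(i) + coff.t();
    k.vcom.row(i) = k.vref.row(i) + (k.omega(i) * rot90(coff)).t();
  }
  return k;
}

// position and velocity of the origin point of angular dof d
inline arma::vec2 dof_origin(const Kin& k, int d) {
  int body = (d == 2) ? 0 : d - 2;  // dof 3+j-1 belongs to body j => body = d-2
  return k.pref.row(body).t();
}
inline arma::vec2 dof_origin_vel(const Kin& k, int d) {
  int body = (d == 2) ? 0 : d - 2;
  return k.vref.row(body).t();
}

// Jacobian of a world point p rigidly attached to `body`, as 2 x ndof
arma::mat point_jacobian(const Tree& t, const Kin& k, int body, const arma::vec2& p) {
  arma::mat J = arma::zeros<arma::mat>(2, t.ndof);
  J(0, 0) = 1.0; J(1, 1) = 1.0;
  for (int d : k.adofs[body]) {
    arma::vec2 r = p - dof_origin(k, d);
    arma::vec2 col = rot90(r);
    J(0, d) = col(0); J(1, d) = col(1);
  }
  return J;
}

arma::mat mass_matrix(const Tree& t, const Kin& k) {
  arma::mat M = arma::zeros<arma::mat>(t.ndof, t.ndof);
  for (int i = 0; i < t.nb; ++i) {
    arma::mat Jv = point_jacobian(t, k, i, k.pcom.row(i).t());
    M += t.mass(i) * (Jv.t() * Jv);
    arma::rowvec Jw = arma::zeros<arma::rowvec>(t.ndof);
    for (int d : k.adofs[i]) Jw(d) = 1.0;
    M += t.inertia(i) * (Jw.t() * Jw);
  }
  return M;
}

// gravity + velocity-product generalized forces
arma::vec bias_forces(const Tree& t, const Kin& k, const arma::vec& qd) {
  arma::vec Q = arma::zeros<arma::vec>(t.ndof);
  arma::vec2 grav = {0.0, -t.g};
  for (int i = 0; i < t.nb; ++i) {
    arma::mat Jv = point_jacobian(t, k, i, k.pcom.row(i).t());
    // velocity-product acceleration of the COM (planar, no gyroscopic term)
    arma::vec2 avp = arma::zeros<arma::vec>(2);
    for (int d : k.adofs[i]) {
      arma::vec2 dv = k.vcom.row(i).t() - dof_origin_vel(k, d);
      avp += qd(d) * rot90(dv);
    }
    Q += t.mass(i) * (Jv.t() * (grav - avp));
  }
  return Q;
}

// contact forces: each row (fx, fy, penetration); force acts at the lowest
// point of the sphere
arma::mat contact_forces(const Tree& t, const Kin& k) {
  int nc = t.cbody.n_elem;
  arma::mat F = arma::zeros<arma::mat>(nc, 3);
  for (int c = 0; c < nc; ++c) {
    int b = t.cbody(c);
    double co = std::cos(k.phi(b)), si = std::sin(k.phi(b));
    arma::vec2 lp = t.cpos.row(c).t();
    arma::vec2 ctr = k.pref.row(b).t() +
      arma::vec2({co * lp(0) - si * lp(1), si * lp(0) + co * lp(1)});
    double pen = t.crad(c) - ctr(1);
    if (pen <= 0.0) continue;
    arma::vec2 vc = k.vref.row(b).t() + k.omega(b) * rot90(ctr - k.pref.row(b).t());
    double pendot = -vc(1);
    double N = t.ck * std::pow(pen, t.cexp) * (1.0 + t.cb * pendot);
    if (N < 0.0) N = 0.0;
    double Ft = -t.mu * N * std::tanh(vc(0) / t.vsm);
    F(c, 0) = Ft; F(c, 1) = N; F(c, 2) = pen;
  }
  return F;
}

arma::vec joint_limit_torques(const Tree& t, const arma::vec& q, const arma::vec& qd) {
  arma::vec tau = arma::zeros<arma::vec>(t.njoint);
  for (int j = 0; j < t.njoint; ++j) {
    double lo = t.jlim(j, 0), hi = t.jlim(j, 1), kk = t.jlim(j, 2), cc = t.jlim(j, 3);
    if (kk <= 0.0) continue;
    double th = q(3 + j), w = qd(3 + j);
    if (th > hi) tau(j) = -kk * (th - hi) - cc * w;
    else if (th < lo) tau(j) = -kk * (th - lo) - cc * w;
  }
  return tau;
}

// --- Hill muscle scalar curves (must match the R reference implementation) ---
const double FL_WIDTH = 0.30;       // Gaussian width of active force-length
const double FV_CURV = 0.25;        // concentric curvature constant
const double FP_SCALE = 1.00;       // passive force reaches 1 at l = 1 + FP_SCALE

inline double fl_active(double l) {
  double z = (l - 1.0) / FL_WIDTH;
  return std::exp(-z * z);
}
inline double fv_curve(double v, double plateau) {
  if (v <= -1.0) return 0.0;
  if (v < 0.0) return (1.0 + v) / (1.0 - v / FV_CURV);
  double slope0 = (1.0 + 1.0 / FV_CURV);          // concentric slope at v = 0
  double ke = (plateau - 1.0) / slope0;           // C1 continuity at v = 0
  return plateau - (plateau - 1.0) / (1.0 + v / ke);
}
inline double fp_curve(double l) {
  if (l <= 1.0) return 0.0;
  double z = (l - 1.0) / FP_SCALE;
  return z * z;
}

struct MuscleEval {
  arma::vec L, V, lce, vce, force;
  arma::ivec degenerate;
};

MuscleEval muscle_eval(const Tree& t, const arma::vec& q, const arma::vec& qd,
                       const arma::vec& act) {
  MuscleEval m;
  m.L.set_size(t.nm); m.V.set_size(t.nm); m.lce.set_size(t.nm);
  m.vce.set_size(t.nm); m.force.set_size(t.nm);
  m.degenerate.zeros(t.nm);
  for (int i = 0; i < t.nm; ++i) {
    double L = t.L0(i), V = 0.0;
    for (int j = 0; j < t.njoint; ++j) {
      L -= t.marm(i, j) * (q(3 + j) - t.qneu(j));
      V -= t.marm(i, j) * qd(3 + j);
    }
    m.L(i) = L; m.V(i) = V;
    double lce = (L - t.lslack(i)) / t.lopt(i);     // rigid tendon
    double vce = (V / t.lopt(i)) / t.vmax(i);
    m.lce(i) = lce; m.vce(i) = vce;
    if (lce <= 0.0) {                               // degenerate geometry
      m.degenerate(i) = 1;
      m.force(i) = 0.0;
      continue;
    }
    double f = t.fmax(i) *
      (act(i) * fl_active(lce) * fv_curve(vce, t.fvp(i)) + fp_curve(lce));
    m.force(i) = f > 0.0 ? f : 0.0;
  }
  return m;
}

inline double act_step_exact(double a, double u, double dt, double ta, double td) {
  double tau = (u >= a) ? ta : td;
  return u + (a - u) * std::exp(-dt / tau);
}

arma::vec solve_fd(const Tree& t, const arma::mat& M, const arma::vec& Q) {
  arma::vec qdd = arma::zeros<arma::vec>(t.ndof);
  if (t.base_fixed) {
    if (t.njoint > 0) {
      arma::uvec idx = arma::regspace<arma::uvec>(3, t.ndof - 1);
      arma::vec sub = arma::solve(M.submat(idx, idx), Q.elem(idx),
                                  arma::solve_opts::likely_sympd);
      qdd.elem(idx) = sub;
    }
  } else {
    qdd = arma::solve(M, Q, arma::solve_opts::likely_sympd);
  }
  return qdd;
}

arma::vec assemble_forces(const Tree& t, const Kin& k, const arma::vec& q,
                          const arma::vec& qd, const arma::vec& tau_joint,
                          const arma::mat& extF) {
  arma::vec Q = bias_forces(t, k, qd);
  // external point forces: rows (body, px_local, py_local, fx, fy)
  for (arma::uword r = 0; r < extF.n_rows; ++r) {
    int b = (int)extF(r, 0);
    double co = std::cos(k.phi(b)), si = std::sin(k.phi(b));
    arma::vec2 lp = {extF(r, 1), extF(r, 2)};
    arma::vec2 p = k.pref.row(b).t() +
      arma::vec2({co * lp(0) - si * lp(1), si * lp(0) + co * lp(1)});
    arma::mat J = point_jacobian(t, k, b, p);
    Q += J.t() * arma::vec2({extF(r, 3), extF(r, 4)});
  }
  for (int j = 0; j < t.njoint; ++j) Q(3 + j) += tau_joint(j);
  return Q;
}

arma::vec contact_generalized(const Tree& t, const Kin& k, const arma::mat& CF) {
  arma::vec Q = arma::zeros<arma::vec>(t.ndof);
  for (arma::uword c = 0; c < CF.n_rows; ++c) {
    if (CF(c, 2) <= 0.0) continue;
    int b = t.cbody(c);
    double co = std::cos(k.phi(b)), si = std::sin(k.phi(b));
    arma::vec2 lp = t.cpos.row(c).t();
    arma::vec2 ctr = k.pref.row(b).t() +
      arma::vec2({co * lp(0) - si * lp(1), si * lp(0) + co * lp(1)});
    arma::vec2 cp = {ctr(0), ctr(1) - t.crad(c)};   // lowest point
    arma::mat J = point_jacobian(t, k, b, cp);
    Q += J.t() * arma::vec2({CF(c, 0), CF(c, 1)});
  }
  return Q;
}

}  // namespace

// [[Rcpp::export(name = ".pt_mass_matrix")]]
arma::mat pt_mass_matrix(const arma::vec& q, const List& params) {
  Tree t = parse_tree(params);
  arma::vec qd = arma::zeros<arma::vec>(t.ndof);
  Kin k = kinematics(t, q, qd);
  return mass_matrix(t, k);
}

// [[Rcpp::export(name = ".pt_bias_forces")]]
arma::vec pt_bias_forces(const arma::vec& q, const arma::vec& qd, const List& params) {
  Tree t = parse_tree(params);
  Kin k = kinematics(t, q, qd);
  return bias_forces(t, k, qd);
}

// [[Rcpp::export(name = ".pt_forward_dynamics")]]
arma::vec pt_forward_dynamics(const arma::vec& q, const arma::vec& qd,
                              const arma::vec& tau_joint, const arma::mat& ext_forces,
                              const List& params, bool with_contact = false,
                              bool with_limits = false) {
  Tree t = parse_tree(params);
  Kin k = kinematics(t, q, qd);
  arma::mat M = mass_matrix(t, k);
  arma::vec tau = tau_joint;
  if (with_limits) tau += joint_limit_torques(t, q, qd);
  arma::vec Q = assemble_forces(t, k, q, qd, tau, ext_forces);
  if (with_contact && t.cbody.n_elem > 0) {
    Q += contact_generalized(t, k, contact_forces(t, k));
  }
  return solve_fd(t, M, Q);
}

// [[Rcpp::export(name = ".pt_contact_forces")]]
arma::mat pt_contact_forces(const arma::vec& q, const arma::vec& qd, const List& params) {
  Tree t = parse_tree(params);
  Kin k = kinematics(t, q, qd);
  if (t.cbody.n_elem == 0) return arma::mat(0, 3);
  return contact_forces(t, k);
}

// [[Rcpp::export(name = ".pt_muscle_geometry")]]
List pt_muscle_geometry(const arma::vec& q, const arma::vec& qd, const List& params) {
  Tree t = parse_tree(params);
  arma::vec act = arma::zeros<arma::vec>(t.nm);
  MuscleEval m = muscle_eval(t, q, qd, act);
  return List::create(_["length"] = m.L, _["velocity"] = m.V,
                      _["lce_norm"] = m.lce, _["vce_norm"] = m.vce);
}

// [[Rcpp::export(name = ".pt_kinematics")]]
List pt_kinematics(const arma::vec& q, const arma::vec& qd, const List& params) {
  Tree t = parse_tree(params);
  Kin k = kinematics(t, q, qd);
  return List::create(_["phi"] = k.phi, _["omega"] = k.omega,
                      _["p_ref"] = k.pref, _["v_ref"] = k.vref,
                      _["p_com"] = k.pcom, _["v_com"] = k.vcom);
}

// [[Rcpp::export(name = ".pt_energy")]]
List pt_energy(const arma::vec& q, const arma::vec& qd, const List& params) {
  Tree t = parse_tree(params);
  Kin k = kinematics(t, q, qd);
  double T = 0.0, V = 0.0;
  for (int i = 0; i < t.nb; ++i) {
    T += 0.5 * t.mass(i) * arma::dot(k.vcom.row(i), k.vcom.row(i));
    T += 0.5 * t.inertia(i) * k.omega(i) * k.omega(i);
    V += t.mass(i) * t.g * k.pcom(i, 1);
  }
  return List::create(_["kinetic"] = T, _["potential"] = V, _["total"] = T + V);
}

// Advance the full neuromusculoskeletal state by one control step using
// semi-implicit Euler sub-stepping.  Excitations are held constant over the
// control step; activation dynamics use the exact exponential update.
// [[Rcpp::export(name = ".pt_step")]]
List pt_step(const List& state, const List& params, const arma::vec& excitation,
             double dt, int substeps) {
  Tree t = parse_tree(params);
  arma::vec q = as<arma::vec>(state["q"]);
  arma::vec qd = as<arma::vec>(state["qd"]);
  arma::vec act = as<arma::vec>(state["act"]);
  double time = as<double>(state["time"]);
  if ((int)excitation.n_elem != t.nm) stop("excitation length != number of muscles");
  if (!excitation.is_finite()) {
    for (arma::uword i = 0; i < excitation.n_elem; ++i)
      if (!std::isfinite(excitation(i)))
        stop("non-finite excitation at index %d", (int)(i + 1));
  }
  arma::vec u = arma::clamp(excitation, 0.0, 1.0);
  double h = dt / substeps;

  for (int s = 0; s < substeps; ++s) {
    // activation dynamics (exact first-order update over the substep)
    for (int i = 0; i < t.nm; ++i)
      act(i) = act_step_exact(act(i), u(i), h, t.tact(i), t.tdeact(i));
    Kin k = kinematics(t, q, qd);
    MuscleEval m = muscle_eval(t, q, qd, act);
    arma::vec tau = joint_limit_torques(t, q, qd);
    for (int i = 0; i < t.nm; ++i)
      for (int j = 0; j < t.njoint; ++j)
        tau(j) += m.force(i) * t.marm(i, j);
    arma::mat M = mass_matrix(t, k);
    arma::vec Q = assemble_forces(t, k, q, qd, tau, arma::mat(0, 5));
    if (t.cbody.n_elem > 0) Q += contact_generalized(t, k, contact_forces(t, k));
    arma::vec qdd = solve_fd(t, M, Q);
    if (t.base_fixed) { qd(0) = qd(1) = qd(2) = 0.0; }
    qd += h * qdd;
    q += h * qd;
    if (!q.is_finite() || !qd.is_finite())
      stop("non-finite state after sub-step at t=%.4f; increase substeps or "
           "check model parameters", time + (s + 1) * h);
  }
  time += dt;

  // evaluate muscles and contact at the post-step state for observation
  Kin k = kinematics(t, q, qd);
  MuscleEval m = muscle_eval(t, q, qd, act);
  arma::mat CF = (t.cbody.n_elem > 0) ? contact_forces(t, k) : arma::mat(0, 3);

  return List::create(
    _["q"] = q, _["qd"] = qd, _["act"] = act, _["time"] = time,
    _["mus_force"] = m.force, _["mus_length"] = m.L, _["mus_velocity"] = m.V,
    _["mus_lce_norm"] = m.lce, _["mus_vce_norm"] = m.vce,
    _["mus_degenerate"] = m.degenerate,
    _["contact"] = CF,
    _["excitation_clamped"] = any(excitation > 1.0) || any(excitation < 0.0));
}
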