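// Explicit overdamped bead-spring pulling simulation of one Talin chain.
//
// Beads: [substrate]? - integrin bead - (N rod beads) - actin bead - [network]?
// Chain segments: integrin linker, N rod subdomains, actin linker. The two
// linkers use folded-subdomain parameters and never unfold. The optional
// compliance variant adds a substrate bead (fixed) and an actin-network bead
// (driven at v_retro), each connected by a zero-rest-length spring of
// stiffness k3; otherwise the integrin bead end is fixed and the actin bead
// driven. Unfolding/unbinding are Monte Carlo events driven by accumulated
// hazard against Exp(1) thresholds, with rates from the local segment
// tension (Bell's law; optional two-state catch-slip unbinding).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double inv_langevin(double x) {
  // Pade seed, then two Newton corrections on coth(y) - 1/y = x
  double y = x * (3.0 - x * x) / (1.0 - x * x);
  for (int it = 0; it < 3; ++it) {
    double L, Lp;
    if (y < 1e-4) { L = y / 3.0; Lp = 1.0 / 3.0; }
    else {
      double c = 1.0 / std::tanh(y);
      L = c - 1.0 / y;
      Lp = 1.0 - c * c + 1.0 / (y * y);
    }
    y -= (L - x) / Lp;
    if (y < 0) y = 0;
  }
  return y;
}

// [[Rcpp::export]]
List run_pulling_cpp(int n_total, double theta0_deg, double v_retro,
                     double k_f, double l_f0, double kuhn_b, double n_res,
                     double kT,
                     NumericVector unfold_k0, NumericVector unfold_dx,
                     LogicalVector unfoldable,
                     int unbind_model, NumericVector unbind_par,
                     double zeta, double dt, int stride, double max_time,
                     double compliance_k3, bool has_compliance) {
  const int N = n_total;
  const int n_chain = N + 3;              // beads: integrin anchor .. actin
  const int nb = n_chain + (has_compliance ? 2 : 0);
  const double l_contour = kuhn_b * n_res;
  const double th = theta0_deg * M_PI / 180.0;
  const double ux = std::cos(th), uy = std::sin(th);

  // bead layout: [0..n_chain-1] chain; then substrate, network if compliant
  std::vector<double> x(nb), y(nb), fx(nb), fy(nb);
  for (int b = 0; b < n_chain; ++b) {
    x[b] = b * l_f0 * ux;
    y[b] = b * l_f0 * uy;
  }
  int sub_bead = -1, net_bead = -1, fixed_bead, driven_bead;
  if (has_compliance) {
    sub_bead = n_chain; net_bead = n_chain + 1;
    x[sub_bead] = x[0]; y[sub_bead] = y[0];
    x[net_bead] = x[n_chain - 1]; y[net_bead] = y[n_chain - 1];
    fixed_bead = sub_bead; driven_bead = net_bead;
  } else {
    fixed_bead = 0; driven_bead = n_chain - 1;
  }

  // chain segments s = 0..N+1 between beads s and s+1; rod segment s
  // (1..N) maps to subdomain s-1
  const int n_seg = N + 1 + 1;
  std::vector<int> unfolded(n_seg, 0);
  std::vector<double> seg_F(n_seg, 0.0);
  double comp_F_net = 0.0, comp_cos_net = 1.0;

  // hazards
  std::vector<double> Hu(n_seg, 0.0), Eu(n_seg, 0.0);
  for (int s = 1; s <= N; ++s)
    if (unfoldable[s - 1]) Eu[s] = R::exp_rand();
  double Hb = 0.0, Eb = R::exp_rand();

  std::vector<double> ev_t, ev_F;
  std::vector<int> ev_type; // segment index 1..N for unfolds, 0 for unbind

  const double k3 = compliance_k3 / 1e3; // pN/um -> pN/nm
  double work = 0.0;
  double t = 0.0;
  bool bound = true, censored = false;
  long nstep = 0;
  const long max_steps = (long)std::ceil(max_time / dt);
  const double max_disp = 1.0; // nm per step instability guard
  const double mob = dt / zeta;

  while (bound) {
    // forces
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    for (int s = 0; s < n_seg; ++s) {
      int i = s, j = s + 1;
      double dx_ = x[j] - x[i], dy_ = y[j] - y[i];
      double d = std::sqrt(dx_ * dx_ + dy_ * dy_);
      double famp;
      if (unfolded[s]) {
        double xi = d / l_contour;
        if (xi > 0.999) xi = 0.999;
        famp = (kT / kuhn_b) * inv_langevin(xi);
      } else {
        famp = k_f * (d - l_f0);
        if (famp < 0) famp = 0; // tensile only
      }
      seg_F[s] = famp;
      if (d > 1e-12) {
        double fxu = famp * dx_ / d, fyu = famp * dy_ / d;
        fx[i] += fxu; fy[i] += fyu;
        fx[j] -= fxu; fy[j] -= fyu;
      }
    }
    if (has_compliance) {
      // zero-rest-length springs substrate<->integrin, actin<->network
      double dx_ = x[0] - x[sub_bead], dy_ = y[0] - y[sub_bead];
      fx[0] -= k3 * dx_; fy[0] -= k3 * dy_;
      fx[sub_bead] += k3 * dx_; fy[sub_bead] += k3 * dy_;
      double dx2 = x[net_bead] - x[n_chain - 1],
             dy2 = y[net_bead] - y[n_chain - 1];
      fx[n_chain - 1] += k3 * dx2; fy[n_chain - 1] += k3 * dy2;
      fx[net_bead] -= k3 * dx2; fy[net_bead] -= k3 * dy2;
      double dn = std::sqrt(dx2 * dx2 + dy2 * dy2);
      comp_F_net = k3 * dn;
      comp_cos_net = dn > 1e-12 ? dx2 / dn : 1.0;
    }

    // work injected by the flow through the spring on the driven bead
    if (has_compliance) {
      work += comp_F_net * comp_cos_net * v_retro * dt;
    } else {
      int s = n_seg - 1;
      double dx_ = x[n_chain - 1] - x[n_chain - 2],
             dy_ = y[n_chain - 1] - y[n_chain - 2];
      double d = std::sqrt(dx_ * dx_ + dy_ * dy_);
      if (d > 1e-12) work += seg_F[s] * (dx_ / d) * v_retro * dt;
    }

    // positions
    for (int b = 0; b < nb; ++b) {
      if (b == fixed_bead) continue;
      if (b == driven_bead) { x[b] += v_retro * dt; continue; }
      double ddx = mob * fx[b], ddy = mob * fy[b];
      if (std::fabs(ddx) > max_disp || std::fabs(ddy) > max_disp)
        stop("pulling simulation unstable: bead %d moved %.3g nm in one step "
             "at t = %.4g s; reduce dt or increase zeta", b,
             std::sqrt(ddx * ddx + ddy * ddy), t);
      x[b] += ddx; y[b] += ddy;
    }
    t += dt;
    ++nstep;

    // hazard accumulation / events every `stride` steps
    if (nstep % stride == 0) {
      double span = stride * dt;
      for (int s = 1; s <= N; ++s) {
        if (unfolded[s] || !unfoldable[s - 1]) continue;
        double e = seg_F[s] * unfold_dx[s - 1] / kT;
        if (e > 700) e = 700;
        Hu[s] += unfold_k0[s - 1] * std::exp(e) * span;
        if (Hu[s] >= Eu[s]) {
          unfolded[s] = 1;
          ev_t.push_back(t); ev_type.push_back(s); ev_F.push_back(seg_F[s]);
        }
      }
      double Fb = seg_F[0]; // integrin linker tension
      double kb;
      if (unbind_model == 0) {
        double e = Fb * unbind_par[1] / kT;
        if (e > 700) e = 700;
        kb = unbind_par[0] * std::exp(e);
      } else {
        double k10 = unbind_par[0] * std::exp(std::min(Fb * unbind_par[4] / kT, 700.0));
        double k12 = unbind_par[1] * std::exp(std::min(Fb * unbind_par[6] / kT, 700.0));
        double k21 = unbind_par[2] * std::exp(std::min(Fb * unbind_par[7] / kT, 700.0));
        double k20 = unbind_par[3] * std::exp(std::min(Fb * unbind_par[5] / kT, 700.0));
        kb = (k21 * k10 + k12 * k20) / (k12 + k21);
      }
      Hb += kb * span;
      if (Hb >= Eb) {
        bound = false;
        ev_t.push_back(t); ev_type.push_back(0); ev_F.push_back(Fb);
      }
    }
    if (bound && nstep >= max_steps) { censored = true; break; }
  }

  int n_unf = 0;
  for (int s = 1; s <= N; ++s) n_unf += unfolded[s];

  return List::create(
    _["unbind_time"] = censored ? NA_REAL : t,
    _["work"] = work,
    _["n_unfolds"] = n_unf,
    _["censored"] = censored,
    _["events"] = DataFrame::create(_["time"] = wrap(ev_t),
                                    _["type"] = wrap(ev_type),
                                    _["tension"] = wrap(ev_F)),
    _["final_positions"] = DataFrame::create(
        _["x"] = NumericVector(x.begin(), x.end()),
        _["y"] = NumericVector(y.begin(), y.end())));
}
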