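// Fixed-step RK4 integration of the gated RNN and tangent-space (Benettin/QR)
// Lyapunov machinery.  The dynamics are
//   hdot = sigma_z(z) * (-h + J_h (phi(h) * sigma_r(r))) + I_h
//   tau_z zdot = -z + J_z phi(h) + I_z
//   tau_r rdot = -r + J_r phi(h) + I_r
// with phi(x) = tanh(g_h x + beta_h) and sigma_a(x) = 1/(1+exp(-a x + beta)).
// alpha = +Inf is the Heaviside gate (value 1/(1+exp(beta)) exactly at 0).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct GateSpec {
  double alpha, beta;
  bool pinned;
  double pin_value;
};

vec gate_val(const vec& x, const GateSpec& g) {
  if (g.pinned) return vec(x.n_elem, fill::value(g.pin_value));
  if (std::isinf(g.alpha)) {
    vec out(x.n_elem);
    const double at0 = 1.0 / (1.0 + std::exp(g.beta));
    for (uword i = 0; i < x.n_elem; ++i)
      out[i] = x[i] > 0 ? 1.0 : (x[i] < 0 ? 0.0 : at0);
    return out;
  }
  return 1.0 / (1.0 + exp(-g.alpha * x + g.beta));
}

vec gate_deriv(const vec& x, const GateSpec& g) {
  if (g.pinned || std::isinf(g.alpha)) return vec(x.n_elem, fill::zeros);
  vec s = 1.0 / (1.0 + exp(-g.alpha * x + g.beta));
  return g.alpha * s % (1.0 - s);
}

struct Net {
  const mat &Jh, &Jz, &Jr;
  double g_h, beta_h, tau_z, tau_r;
  GateSpec gz, gr;

  vec phi(const vec& h, const vec& Ib) const { return tanh(g_h * h + beta_h + Ib); }
  vec phip(const vec& h, const vec& Ib) const {
    vec t = tanh(g_h * h + beta_h + Ib);
    return g_h * (1.0 - t % t);
  }
};

// static input protocols: column k of ivecs applies to target[k]
// (0 = h, 1 = z, 2 = r additive; 3 = quenched bias inside the activation)
// while t_on[k] <= t < t_off[k]
struct Inputs {
  const mat& ivecs;
  const ivec& target;
  const vec& t_on, &t_off;

  void at(double t, vec& Ih, vec& Iz, vec& Ir, vec& Ib) const {
    Ih.zeros(); Iz.zeros(); Ir.zeros(); Ib.zeros();
    for (uword k = 0; k < target.n_elem; ++k) {
      if (t >= t_on[k] && t < t_off[k]) {
        if (target[k] == 0) Ih += ivecs.col(k);
        else if (target[k] == 1) Iz += ivecs.col(k);
        else if (target[k] == 2) Ir += ivecs.col(k);
        else Ib += ivecs.col(k);
      }
    }
  }
};

struct State { vec h, z, r; };

State vecfield(const Net& net, const State& s, const vec& Ih, const vec& Iz,
            const vec& Ir, const vec& Ib) {
  vec ph = net.phi(s.h, Ib);
  vec sr = gate_val(s.r, net.gr);
  vec sz = gate_val(s.z, net.gz);
  State d;
  d.h = sz % (-s.h + net.Jh * (ph % sr)) + Ih;
  d.z = (-s.z + net.Jz * ph + Iz) / net.tau_z;
  d.r = (-s.r + net.Jr * ph + Ir) / net.tau_r;
  return d;
}

// one RK4 step; inputs treated as piecewise-constant, evaluated at stage times
void rk4_step(const Net& net, State& s, double t, double dt, const Inputs& in,
              vec& Ih, vec& Iz, vec& Ir, vec& Ib) {
  in.at(t, Ih, Iz, Ir, Ib);
  State k1 = vecfield(net, s, Ih, Iz, Ir, Ib);
  State s2 = {s.h + 0.5 * dt * k1.h, s.z + 0.5 * dt * k1.z, s.r + 0.5 * dt * k1.r};
  in.at(t + 0.5 * dt, Ih, Iz, Ir, Ib);
  State k2 = vecfield(net, s2, Ih, Iz, Ir, Ib);
  State s3 = {s.h + 0.5 * dt * k2.h, s.z + 0.5 * dt * k2.z, s.r + 0.5 * dt * k2.r};
  State k3 = vecfield(net, s3, Ih, Iz, Ir, Ib);
  State s4 = {s.h + dt * k3.h, s.z + dt * k3.z, s.r + dt * k3.r};
  in.at(t + dt, Ih, Iz, Ir, Ib);
  State k4 = vecfield(net, s4, Ih, Iz, Ir, Ib);
  s.h += dt / 6.0 * (k1.h + 2 * k2.h + 2 * k3.h + k4.h);
  s.z += dt / 6.0 * (k1.z + 2 * k2.z + 2 * k3.z + k4.z);
  s.r += dt / 6.0 * (k1.r + 2 * k2.r + 2 * k3.r + k4.r);
}

Net make_net(const mat& Jh, const mat& Jz, const mat& Jr,
             const Rcpp::List& par) {
  GateSpec gz = {Rcpp::as<double>(par["alpha_z"]), Rcpp::as<double>(par["beta_z"]),
                 Rcpp::as<bool>(par["pin_z"]), Rcpp::as<double>(par["pin_z_value"])};
  GateSpec gr = {Rcpp::as<double>(par["alpha_r"]), Rcpp::as<double>(par["beta_r"]),
                 Rcpp::as<bool>(par["pin_r"]), Rcpp::as<double>(par["pin_r_value"])};
  return Net{Jh, Jz, Jr,
             Rcpp::as<double>(par["g_h"]), Rcpp::as<double>(par["beta_h"]),
             Rcpp::as<double>(par["tau_z"]), Rcpp::as<double>(par["tau_r"]),
             gz, gr};
}

void check_finite(const State& s, double t) {
  if (!s.h.is_finite() || !s.z.is_finite() || !s.r.is_finite() ||
      abs(s.h).max() > 1e8)
    Rcpp::stop("non-finite state encountered at t = %f", t);
}

} // namespace

// [[Rcpp::export]]
Rcpp::List simulate_cpp(const arma::mat& Jh, const arma::mat& Jz,
                        const arma::mat& Jr, const Rcpp::List& par,
                        const arma::vec& h0, const arma::vec& z0,
                        const arma::vec& r0, double dt, int n_steps,
                        int record_every, const arma::mat& ivecs,
                        const arma::ivec& target, const arma::vec& t_on,
                        const arma::vec& t_off) {
  Net net = make_net(Jh, Jz, Jr, par);
  Inputs in{ivecs, target, t_on, t_off};
  State s = {h0, z0, r0};
  const uword N = h0.n_elem;
  vec Ih(N), Iz(N), Ir(N), Ib(N);

  int n_rec = n_steps / record_every + 1;
  mat H(n_rec, N), Z(n_rec, N), R(n_rec, N);
  vec times(n_rec);
  H.row(0) = s.h.t(); Z.row(0) = s.z.t(); R.row(0) = s.r.t();
  times[0] = 0.0;

  int rec = 1;
  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;
    rk4_step(net, s, t, dt, in, Ih, Iz, Ir, Ib);
    check_finite(s, t + dt);
    if ((step + 1) % record_every == 0) {
      H.row(rec) = s.h.t(); Z.row(rec) = s.z.t(); R.row(rec) = s.r.t();
      times[rec] = (step + 1) * dt;
      ++rec;
    }
    if (step % 2000 == 0) Rcpp::checkUserInterrupt();
  }
  return Rcpp::List::create(
      Rcpp::Named("times") = times.head(rec),
      Rcpp::Named("h") = H.head_rows(rec), Rcpp::Named("z") = Z.head_rows(rec),
      Rcpp::Named("r") = R.head_rows(rec));
}

namespace {

// tangent blocks evolved alongside the state; columns are tangent vectors
struct Tangent { mat h, z, r; };

Tangent tangent_field(const Net& net, const State& s, const Tangent& v,
                      const vec& Ib) {
  vec ph = net.phi(s.h, Ib), php = net.phip(s.h, Ib);
  vec sr = gate_val(s.r, net.gr), srp = gate_deriv(s.r, net.gr);
  vec sz = gate_val(s.z, net.gz), szp = gate_deriv(s.z, net.gz);
  vec Dvec = szp % (-s.h + net.Jh * (ph % sr)); // zero at fixed points
  mat mixed = v.h.each_col() % (php % sr);
  mixed += v.r.each_col() % (ph % srp);
  mat dh = net.Jh * mixed;
  dh -= v.h;
  dh.each_col() %= sz;
  dh += v.z.each_col() % Dvec;
  mat vhp = v.h.each_col() % php;
  Tangent d;
  d.h = dh;
  d.z = (net.Jz * vhp - v.z) / net.tau_z;
  d.r = (net.Jr * vhp - v.r) / net.tau_r;
  return d;
}

} // namespace

// Benettin/QR Lyapunov spectrum: evolve k tangent vectors with the
// instantaneous Jacobian along the trajectory, reorthonormalize every
// reorth_interval, and average log|diag R| after the transient.  Also
// accumulates the time-averaged Jacobian trace (sum-rule diagnostic).
// [[Rcpp::export]]
Rcpp::List lyapunov_cpp(const arma::mat& Jh, const arma::mat& Jz,
                        const arma::mat& Jr, const Rcpp::List& par,
                        const arma::vec& h0, const arma::vec& z0,
                        const arma::vec& r0, int k, double dt,
                        double t_total, double t_transient,
                        double reorth_interval, const arma::mat& ivecs,
                        const arma::ivec& target, const arma::vec& t_on,
                        const arma::vec& t_off, const arma::mat& V0) {
  Net net = make_net(Jh, Jz, Jr, par);
  Inputs in{ivecs, target, t_on, t_off};
  State s = {h0, z0, r0};
  const uword N = h0.n_elem;
  vec Ih(N), Iz(N), Ir(N);

  vec Ib(N);
  mat Qq, Rr;
  if (!qr_econ(Qq, Rr, V0)) Rcpp::stop("QR factorization failed");
  Tangent v = {Qq.rows(0, N - 1), Qq.rows(N, 2 * N - 1), Qq.rows(2 * N, 3 * N - 1)};

  int steps_per_reorth = std::max(1, (int) std::round(reorth_interval / dt));
  int n_steps = (int) std::round(t_total / dt);
  vec logsum(k, fill::zeros);
  double t_accum = 0.0, trace_accum = 0.0;
  int trace_count = 0;

  for (int step = 0; step < n_steps; ++step) {
    double t = step * dt;
    // augmented RK4: tangent derivative uses the Jacobian at stage states
    in.at(t, Ih, Iz, Ir, Ib);
    State k1 = vecfield(net, s, Ih, Iz, Ir, Ib);
    Tangent m1 = tangent_field(net, s, v, Ib);
    State s2 = {s.h + 0.5 * dt * k1.h, s.z + 0.5 * dt * k1.z, s.r + 0.5 * dt * k1.r};
    Tangent v2 = {v.h + 0.5 * dt * m1.h, v.z + 0.5 * dt * m1.z, v.r + 0.5 * dt * m1.r};
    in.at(t + 0.5 * dt, Ih, Iz, Ir, Ib);
    State k2 = vecfield(net, s2, Ih, Iz, Ir, Ib);
    Tangent m2 = tangent_field(net, s2, v2, Ib);
    State s3 = {s.h + 0.5 * dt * k2.h, s.z + 0.5 * dt * k2.z, s.r + 0.5 * dt * k2.r};
    Tangent v3 = {v.h + 0.5 * dt * m2.h, v.z + 0.5 * dt * m2.z, v.r + 0.5 * dt * m2.r};
    State k3 = vecfield(net, s3, Ih, Iz, Ir, Ib);
    Tangent m3 = tangent_field(net, s3, v3, Ib);
    State s4 = {s.h + dt * k3.h, s.z + dt * k3.z, s.r + dt * k3.r};
    Tangent v4 = {v.h + dt * m3.h, v.z + dt * m3.z, v.r + dt * m3.r};
    in.at(t + dt, Ih, Iz, Ir, Ib);
    State k4 = vecfield(net, s4, Ih, Iz, Ir, Ib);
    Tangent m4 = tangent_field(net, s4, v4, Ib);

    s.h += dt / 6.0 * (k1.h + 2 * k2.h + 2 * k3.h + k4.h);
    s.z += dt / 6.0 * (k1.z + 2 * k2.z + 2 * k3.z + k4.z);
    s.r += dt / 6.0 * (k1.r + 2 * k2.r + 2 * k3.r + k4.r);
    v.h += dt / 6.0 * (m1.h + 2 * m2.h + 2 * m3.h + m4.h);
    v.z += dt / 6.0 * (m1.z + 2 * m2.z + 2 * m3.z + m4.z);
    v.r += dt / 6.0 * (m1.r + 2 * m2.r + 2 * m3.r + m4.r);
    check_finite(s, t + dt);

    if ((step + 1) % steps_per_reorth == 0) {
      mat V = join_cols(v.h, v.z, v.r);
      if (!qr_econ(Qq, Rr, V))
        Rcpp::stop("QR reorthonormalization failed (rank loss) at t = %f", t + dt);
      vec dg = abs(Rr.diag());
      if (dg.min() <= 0)
        Rcpp::stop("degenerate tangent basis at t = %f", t + dt);
      if (t + dt > t_transient) {
        logsum += log(dg);
        t_accum += steps_per_reorth * dt;
      }
      v.h = Qq.rows(0, N - 1);
      v.z = Qq.rows(N, 2 * N - 1);
      v.r = Qq.rows(2 * N, 3 * N - 1);
    }
    if (t + dt > t_transient) {
      // instantaneous Jacobian trace
      in.at(t + dt, Ih, Iz, Ir, Ib);
      vec ph = net.phi(s.h, Ib), php = net.phip(s.h, Ib);
      vec sr = gate_val(s.r, net.gr);
      vec sz = gate_val(s.z, net.gz), szp = gate_deriv(s.z, net.gz);
      double tr = accu(sz % (-1.0 + Jh.diag() % php % sr)) +
                  accu(szp % (-s.h + net.Jh * (ph % sr))) -
                  N / net.tau_z - N / net.tau_r;
      trace_accum += tr;
      ++trace_count;
    }
    if (step % 500 == 0) Rcpp::checkUserInterrupt();
  }

  vec expo = sort(logsum / t_accum, "descend");
  return Rcpp::List::create(
      Rcpp::Named("exponents") = expo,
      Rcpp::Named("t_averaged") = t_accum,
      Rcpp::Named("mean_trace") = trace_count ? trace_accum / trace_count : NA_REAL,
      Rcpp::Named("final_h") = s.h, Rcpp::Named("final_z") = s.z,
      Rcpp::Named("final_r") = s.r);
}
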