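// Population mean-field model: Wilson-Cowan rate dynamics through the
// Siegert transfer function, exact population calcium ODE, and the
// structural-plasticity connectivity flow with rectified-Gaussian
// (spiking-noise-corrected) element creation/deletion rates.
//
// State vector y (two plastic excitatory ensembles E1, E2 + static I):
//   (phi_E1, phi_E2, C11, C12, C21, C22, r_E1, r_E2, r_I)

#include <Rcpp.h>
#include <cmath>
#include "siegert.h"

using namespace Rcpp;

namespace {

// mean of a rectified Gaussian: E[max(X,0)], X ~ N(mu, sigma^2)
inline double rect_gauss(double mu, double sigma) {
  if (sigma <= 0.0) return mu > 0.0 ? mu : 0.0;
  double z = mu / sigma;
  return 0.5 * mu * (1.0 + std::erf(z * M_SQRT1_2)) +
         sigma * std::exp(-0.5 * z * z) / 2.50662827463100050242;
}

struct MFParams {
  double n1, n2, ni;
  double tau_m, t_ref, v_th, v_r, J, g, nu_ext;
  double nu, beta_a, beta_d, tau_ca, eta, tau_rate, eps;
  double sig_a, sig_d;  // element-rate noise, frozen at the set-point
};

// connectivity drift dC[4] given calcium state; C ordered C11,C12,C21,C22
void conn_flow(const MFParams &p, const double *phi, const double *C,
               double *dC) {
  double N[2] = {p.n1, p.n2};
  double rd_p[2], rd_m[2], ra_p[2], ra_m[2];
  for (int y = 0; y < 2; ++y) {
    double ud = (p.nu - phi[y]) / p.beta_d;
    double ua = (p.nu - phi[y]) / p.beta_a;
    rd_p[y] = rect_gauss(ud, p.sig_d);
    rd_m[y] = rect_gauss(-ud, p.sig_d);
    ra_p[y] = rect_gauss(ua, p.sig_a);
    ra_m[y] = rect_gauss(-ua, p.sig_a);
  }
  double kin[2], kout[2];
  for (int y = 0; y < 2; ++y) {
    kin[y]  = C[2 * y] * N[0] + C[2 * y + 1] * N[1];
    kout[y] = C[y] * N[0] + C[2 + y] * N[1];
  }
  // deletions free the bonded counterpart, which re-enters the pairing pool
  double rdc_p[2], rac_p[2];
  for (int y = 0; y < 2; ++y) {
    double acc = 0.0;
    for (int z = 0; z < 2; ++z)
      if (kout[z] > 0.0) acc += C[2 * y + z] * N[z] * ra_m[z] / kout[z];
    rdc_p[y] = rd_p[y] + acc;
    acc = 0.0;
    for (int z = 0; z < 2; ++z)
      if (kin[z] > 0.0) acc += C[2 * z + y] * N[z] * rd_m[z] / kin[z];
    rac_p[y] = ra_p[y] + acc;
  }
  double tot_a = N[0] * rac_p[0] + N[1] * rac_p[1];
  double tot_d = N[0] * rdc_p[0] + N[1] * rdc_p[1];
  double rho = tot_a > tot_d ? tot_a : tot_d;
  for (int y = 0; y < 2; ++y) {
    for (int z = 0; z < 2; ++z) {
      double create = rho > 0.0 ? rdc_p[y] * rac_p[z] / rho : 0.0;
      double del = 0.0;
      if (kin[y] > 0.0) del += rd_m[y] / kin[y];
      if (kout[z] > 0.0) del += ra_m[z] / kout[z];
      dC[2 * y + z] = create - C[2 * y + z] * del;
    }
  }
}

void moments(const MFParams &p, const double *C, const double *r,
             double m1, double m2, double *mu, double *sig) {
  double tJ = p.tau_m * p.J;
  double tJ2 = p.tau_m * p.J * p.J;
  double inh_mu = p.g * tJ * p.eps * p.ni * r[2];
  double inh_var = p.g * p.g * tJ2 * p.eps * p.ni * r[2];
  double rec1 = C[0] * p.n1 * r[0] + C[1] * p.n2 * r[1];
  double rec2 = C[2] * p.n1 * r[0] + C[3] * p.n2 * r[1];
  double reci = p.eps * (p.n1 * r[0] + p.n2 * r[1]);
  mu[0] = tJ * rec1 - inh_mu + tJ * p.nu_ext * m1;
  mu[1] = tJ * rec2 - inh_mu + tJ * p.nu_ext * m2;
  mu[2] = tJ * reci - inh_mu + tJ * p.nu_ext;
  sig[0] = std::sqrt(tJ2 * rec1 + inh_var + tJ2 * p.nu_ext * m1);
  sig[1] = std::sqrt(tJ2 * rec2 + inh_var + tJ2 * p.nu_ext * m2);
  sig[2] = std::sqrt(tJ2 * reci + inh_var + tJ2 * p.nu_ext);
}

}  // namespace

// [[Rcpp::export]]
List sim_meanfield_cpp(List model, NumericMatrix episodes, NumericVector y0,
                       double dt_s, double record_every_s) {
  MFParams p;
  p.n1 = as<double>(model["n_e1"]);
  p.n2 = as<double>(model["n_e2"]);
  p.ni = as<double>(model["n_i"]);
  p.tau_m = as<double>(model["tau_m_s"]);
  p.t_ref = as<double>(model["t_ref_s"]);
  p.v_th = as<double>(model["v_th_mv"]);
  p.v_r = as<double>(model["v_r_mv"]);
  p.J = as<double>(model["j_mv"]);
  p.g = as<double>(model["g"]);
  p.nu_ext = as<double>(model["nu_ext_hz"]);
  p.nu = as<double>(model["nu_target_hz"]);
  p.beta_a = as<double>(model["beta_a"]);
  p.beta_d = as<double>(model["beta_d"]);
  p.tau_ca = as<double>(model["tau_ca_s"]);
  p.eta = as<double>(model["eta"]);
  p.tau_rate = as<double>(model["tau_rate_s"]);
  p.eps = as<double>(model["eps"]);
  double sig_ca = p.eta * std::sqrt(p.nu / (2.0 * p.tau_ca));
  p.sig_a = sig_ca / p.beta_a;
  p.sig_d = sig_ca / p.beta_d;

  double phi[2] = {y0[0], y0[1]};
  double C[4] = {y0[2], y0[3], y0[4], y0[5]};
  double r[3] = {y0[6], y0[7], y0[8]};
  double r_del[3] = {r[0], r[1], r[2]};  // one-step (== synaptic delay) buffer

  double total_s = 0.0;
  for (int e = 0; e < episodes.nrow(); ++e) total_s += episodes(e, 0);
  int n_rec = (int)std::floor(total_s / record_every_s) + 1;
  NumericVector rec_t(n_rec);
  NumericMatrix rec_y(n_rec, 9);
  int rec_steps = (int)std::llround(record_every_s / dt_s);
  bool runaway = false;
  double mu[3], sig[3], dC[4];

  long step = 0;
  int irec = 0;
  auto record = [&](double t) {
    if (irec >= n_rec) return;
    rec_t[irec] = t;
    rec_y(irec, 0) = phi[0]; rec_y(irec, 1) = phi[1];
    for (int k = 0; k < 4; ++k) rec_y(irec, 2 + k) = C[k];
    for (int k = 0; k < 3; ++k) rec_y(irec, 6 + k) = r[k];
    ++irec;
  };
  record(0.0);

  for (int e = 0; e < episodes.nrow(); ++e) {
    long nstep = (long)std::llround(episodes(e, 0) / dt_s);
    double m1 = episodes(e, 1), m2 = episodes(e, 2);
    for (long k = 0; k < nstep; ++k) {
      moments(p, C, r_del, m1, m2, mu, sig);
      double f[3];
      for (int y = 0; y < 3; ++y)
        f[y] = en_siegert(mu[y], sig[y], p.tau_m, p.t_ref, p.v_th, p.v_r);
      for (int y = 0; y < 3; ++y) r_del[y] = r[y];
      for (int y = 0; y < 3; ++y) {
        r[y] += dt_s * (f[y] - r[y]) / p.tau_rate;
        if (r[y] < 0.0) r[y] = 0.0;
        if (r[y] > 10.0 / p.t_ref) runaway = true;
      }
      for (int y = 0; y < 2; ++y)
        phi[y] += dt_s * (r[y] - phi[y]) / p.tau_ca;
      conn_flow(p, phi, C, dC);
      for (int k2 = 0; k2 < 4; ++k2) {
        C[k2] += dt_s * dC[k2];
        if (C[k2] < 0.0) C[k2] = 0.0;
      }
      ++step;
      if (step % rec_steps == 0) record(step * dt_s);
    }
  }

  return List::create(_["time_s"] = rec_t[Range(0, irec - 1)],
                      _["y"] = rec_y(Range(0, irec - 1), _),
                      _["runaway"] = runaway);
}

// [[Rcpp::export]]
NumericVector conn_flow_cpp(List model, NumericVector phi, NumericVector C) {
  MFParams p;
  p.n1 = as<double>(model["n_e1"]);
  p.n2 = as<double>(model["n_e2"]);
  p.nu = as<double>(model["nu_target_hz"]);
  p.beta_a = as<double>(model["beta_a"]);
  p.beta_d = as<double>(model["beta_d"]);
  p.tau_ca = as<double>(model["tau_ca_s"]);
  p.eta = as<double>(model["eta"]);
  double sig_ca = p.eta * std::sqrt(p.nu / (2.0 * p.tau_ca));
  p.sig_a = sig_ca / p.beta_a;
  p.sig_d = sig_ca / p.beta_d;
  double ph[2] = {phi[0], phi[1]};
  double Cv[4] = {C[0], C[1], C[2], C[3]};
  double dC[4];
  conn_flow(p, ph, Cv, dC);
  return NumericVector::create(dC[0], dC[1], dC[2], dC[3]);
}
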