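// Compiled soma simulation loops.
//
// Per-step arithmetic deliberately mirrors the R reference steppers
// (lif_step, adex_step, hh_step) operation for operation, so the two paths
// agree to floating-point rounding; the loops here exist only to make long
// fine-dt fidelity runs cheap.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static inline double vtrap(double x, double y) {
  if (std::fabs(x / y) < 1e-6) return y * (1.0 + x / (2.0 * y));
  return x / (1.0 - std::exp(-x / y));
}

// [[Rcpp::export]]
List soma_sim_cpp(std::string kind, NumericMatrix current, double dt,
                  List params, bool return_v) {
  const int n_steps = current.nrow();
  const int n_units = current.ncol();
  std::vector<std::vector<double>> spikes(n_units);
  NumericMatrix vtrace;
  if (return_v) vtrace = NumericMatrix(n_steps, n_units);

  if (kind == "lif") {
    const double tau_m = params["tau_m"], v_rest = params["v_rest"],
                 Rm = params["R"], theta_base = params["theta_base"],
                 a = params["a"], tau_th = params["tau_th"],
                 r_spike = params["r_spike"], v_reset = params["v_reset"];
    const double em = std::exp(-dt / tau_m), eth = std::exp(-dt / tau_th);
    std::vector<double> v(n_units, v_rest), theta(n_units, theta_base),
        r(n_units, r_spike);
    for (int k = 0; k < n_steps; ++k) {
      for (int u = 0; u < n_units; ++u) {
        double rr = std::min(r[u] + dt, r_spike);
        double th = theta_base + (theta[u] - theta_base) * eth;
        double gate = (rr > 0.0) ? 1.0 : 0.0;
        double vv = v_rest + (v[u] - v_rest) * em +
                    gate * (dt / tau_m) * Rm * current(k, u);
        if (!std::isfinite(vv))
          stop("soma_sim: non-finite LIF state at step %d", k + 1);
        if (vv > th) {
          spikes[u].push_back((k + 1) * dt);
          vv = v_reset;
          th += a;
          rr = -r_spike;
        }
        v[u] = vv; theta[u] = th; r[u] = rr;
        if (return_v) vtrace(k, u) = vv;
      }
    }
  } else if (kind == "adex") {
    const double C = params["C"], g_L = params["g_L"], E_L = params["E_L"],
                 V_T = params["V_T"], delta_T = params["delta_T"],
                 tau_w = params["tau_w"], a_w = params["a_w"],
                 b_w = params["b_w"], v_reset = params["v_reset"],
                 v_cut = params["v_cut"];
    std::vector<double> v(n_units, E_L), w(n_units, 0.0);
    for (int k = 0; k < n_steps; ++k) {
      for (int u = 0; u < n_units; ++u) {
        double ex = std::exp(std::min((v[u] - V_T) / delta_T, 20.0));
        double dv = (g_L * (E_L - v[u]) + g_L * delta_T * ex - w[u] +
                     current(k, u)) / C;
        double dw = (a_w * (v[u] - E_L) - w[u]) / tau_w;
        double vv = v[u] + dt * dv;
        double ww = w[u] + dt * dw;
        if (!std::isfinite(vv) || !std::isfinite(ww))
          stop("soma_sim: non-finite AdEx state at step %d", k + 1);
        if (vv > v_cut) {
          spikes[u].push_back((k + 1) * dt);
          vv = v_reset;
          ww += b_w;
        }
        v[u] = vv; w[u] = ww;
        if (return_v) vtrace(k, u) = vv;
      }
    }
  } else if (kind == "hh") {
    const double C = params["C"], g_Na = params["g_Na"], g_K = params["g_K"],
                 g_L = params["g_L"], E_Na = params["E_Na"],
                 E_K = params["E_K"], E_L = params["E_L"];
    const double v0 = -65.0;
    double am0 = 0.1 * vtrap(v0 + 40.0, 10.0), bm0 = 4.0 * std::exp(-(v0 + 65.0) / 18.0);
    double ah0 = 0.07 * std::exp(-(v0 + 65.0) / 20.0),
           bh0 = 1.0 / (1.0 + std::exp(-(v0 + 35.0) / 10.0));
    double an0 = 0.01 * vtrap(v0 + 55.0, 10.0),
           bn0 = 0.125 * std::exp(-(v0 + 65.0) / 80.0);
    std::vector<double> v(n_units, v0), m(n_units, am0 / (am0 + bm0)),
        h(n_units, ah0 / (ah0 + bh0)), n(n_units, an0 / (an0 + bn0));
    for (int k = 0; k < n_steps; ++k) {
      for (int u = 0; u < n_units; ++u) {
        double vv = v[u];
        double am = 0.1 * vtrap(vv + 40.0, 10.0),
               bm = 4.0 * std::exp(-(vv + 65.0) / 18.0),
               ah = 0.07 * std::exp(-(vv + 65.0) / 20.0),
               bh = 1.0 / (1.0 + std::exp(-(vv + 35.0) / 10.0)),
               an = 0.01 * vtrap(vv + 55.0, 10.0),
               bn = 0.125 * std::exp(-(vv + 65.0) / 80.0);
        double tm = 1.0 / (am + bm), th = 1.0 / (ah + bh), tn = 1.0 / (an + bn);
        double mm = am * tm + (m[u] - am * tm) * std::exp(-dt / tm);
        double hh = ah * th + (h[u] - ah * th) * std::exp(-dt / th);
        double nn = an * tn + (n[u] - an * tn) * std::exp(-dt / tn);
        double i_ion = g_Na * mm * mm * mm * hh * (vv - E_Na) +
                       g_K * nn * nn * nn * nn * (vv - E_K) +
                       g_L * (vv - E_L);
        double vnew = vv + dt * (current(k, u) - i_ion) / C;
        if (!std::isfinite(vnew))
          stop("soma_sim: non-finite HH state at step %d", k + 1);
        if (vnew > 0.0 && vv <= 0.0) spikes[u].push_back((k + 1) * dt);
        v[u] = vnew; m[u] = mm; h[u] = hh; n[u] = nn;
        if (return_v) vtrace(k, u) = vnew;
      }
    }
  } else {
    stop("soma_sim: unknown soma kind '%s'", kind.c_str());
  }

  List sp(n_units);
  for (int u = 0; u < n_units; ++u) sp[u] = NumericVector(spikes[u].begin(), spikes[u].end());
  if (return_v) return List::create(_["spikes"] = sp, _["v"] = vtrace);
  return List::create(_["spikes"] = sp);
}
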