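// Performant executable instantiation of the mutual-inhibition cartpole
// architecture: LIF pools, traced synapses with per-connection delays,
// three-factor STDP, grid-cell-like encoder, saturable-trace decoder.
//
// Semantics mirror the generic R graph executor on this blueprint exactly:
// per step, the encoder emits this step's input spikes; every synapse group
// runs next, reading pool spikes from the previous step (one-step latency on
// back edges) and input spikes from the current step; pools then integrate
// this step's summed currents and emit spikes; the integrator reads the
// excitatory pools' fresh spikes. Synaptic propagation is event-driven
// (spikes are scheduled into per-delay rings), and eligibility traces use
// the identity x_pre(j,i; t) = u_j(t - d_ji) for the per-pre-unit trace u,
// so the per-step cost is O(units + spike events * degree), not O(weights).

#include <Rcpp.h>
#include <cmath>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// splitmix64: small, fast, deterministic across platforms.
struct SplitMix64 {
  uint64_t s;
  explicit SplitMix64(uint64_t seed) : s(seed) {}
  uint64_t next() {
    uint64_t z = (s += 0x9e3779b97f4a7c15ULL);
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
};

struct LifPool {
  int n;
  double tau_m, v_rest, Rm, theta_base, a, tau_th, r_spike, v_reset;
  double em, eth;  // exp(-dt/tau_m), exp(-dt/tau_th)
  std::vector<double> v, theta, r, S_prev, S_new, I_total;
  std::vector<int> spiking_prev;  // indices with S_prev == 1
};

struct SynGroup {
  std::string name;
  int pre_pool;   // -1 = encoder input
  int post_pool;
  int n_pre, n_post;
  double tau_s, decay_s, sign;
  bool plastic;
  int channel;  // 0 none, 1 motor A, 2 motor B
  double eta, alpha, beta, gamma, delta, w_min, w_max;
  double decay_pre, decay_post;
  std::vector<double> W;     // dense n_pre x n_post, column-major (R layout)
  std::vector<uint8_t> mask;
  std::vector<int> D;        // delays in steps
  int L;                     // ring length, > max delay
  // adjacency (rebuilt on structural change)
  std::vector<int> pre_ptr, pre_conn;    // by presynaptic unit -> dense idx
  std::vector<int> post_ptr, post_conn;  // by postsynaptic unit -> dense idx
  // event rings and state
  std::vector<std::vector<int>> pending;  // dense idx scheduled per slot
  std::vector<int> arrivals_now;
  std::vector<double> c_post;   // summed current per postsynaptic unit
  std::vector<double> u;        // per-pre eligibility trace (undelayed)
  std::vector<double> u_ring;   // L x n_pre history of u
  std::vector<double> p;        // per-post eligibility trace
};

struct Spiker {
  int dims, n_units;
  double rate_max;
  std::vector<double> lo, hi, sigma;
};

struct Engine {
  double dt;
  long long step = 0;
  SplitMix64 rng;
  Spiker spiker;
  int n_in;
  std::vector<LifPool> pools;
  std::vector<SynGroup> groups;
  std::vector<std::vector<int>> groups_into;  // per pool, group indices
  // integrator
  double tau_out, gain, decay_out;
  std::vector<double> y;
  std::vector<int> integ_pools;
  std::vector<double> probs;  // encoder probabilities for current hold
  explicit Engine(uint64_t seed) : rng(seed) {}
};

static void rebuild_adjacency(SynGroup& g) {
  g.pre_ptr.assign(g.n_pre + 1, 0);
  g.post_ptr.assign(g.n_post + 1, 0);
  int nnz = 0;
  for (int idx = 0; idx < g.n_pre * g.n_post; ++idx) {
    if (g.mask[idx]) {
      ++nnz;
      ++g.pre_ptr[idx % g.n_pre + 1];
      ++g.post_ptr[idx / g.n_pre + 1];
    }
  }
  for (int j = 0; j < g.n_pre; ++j) g.pre_ptr[j + 1] += g.pre_ptr[j];
  for (int i = 0; i < g.n_post; ++i) g.post_ptr[i + 1] += g.post_ptr[i];
  g.pre_conn.assign(nnz, 0);
  g.post_conn.assign(nnz, 0);
  std::vector<int> cp(g.pre_ptr.begin(), g.pre_ptr.end() - 1);
  std::vector<int> ci(g.post_ptr.begin(), g.post_ptr.end() - 1);
  for (int idx = 0; idx < g.n_pre * g.n_post; ++idx) {
    if (g.mask[idx]) {
      g.pre_conn[cp[idx % g.n_pre]++] = idx;
      g.post_conn[ci[idx / g.n_pre]++] = idx;
    }
  }
}

static inline void clip_w(SynGroup& g, int idx) {
  double lo = (g.sign > 0) ? g.w_min : -g.w_max;
  double hi = (g.sign > 0) ? g.w_max : -g.w_min;
  if (g.W[idx] < lo) g.W[idx] = lo;
  if (g.W[idx] > hi) g.W[idx] = hi;
}

// [[Rcpp::export]]
SEXP engine_create(List cfg) {
  uint64_t seed = (uint64_t)(double)cfg["seed"];
  Engine* E = new Engine(seed);
  E->dt = cfg["dt"];

  List sp = cfg["spiker"];
  E->spiker.dims = sp["dims"];
  E->spiker.n_units = sp["n_units"];
  E->spiker.rate_max = sp["rate_max"];
  E->spiker.lo = as<std::vector<double>>(sp["lo"]);
  E->spiker.hi = as<std::vector<double>>(sp["hi"]);
  E->spiker.sigma = as<std::vector<double>>(sp["sigma"]);
  E->n_in = E->spiker.dims * E->spiker.n_units;
  E->probs.assign(E->n_in, 0.0);

  List pools = cfg["pools"];
  for (int k = 0; k < pools.size(); ++k) {
    List pl = pools[k];
    LifPool P;
    P.n = pl["n"];
    P.tau_m = pl["tau_m"]; P.v_rest = pl["v_rest"]; P.Rm = pl["R"];
    P.theta_base = pl["theta_base"]; P.a = pl["a"]; P.tau_th = pl["tau_th"];
    P.r_spike = pl["r_spike"]; P.v_reset = pl["v_reset"];
    P.em = std::exp(-E->dt / P.tau_m);
    P.eth = std::exp(-E->dt / P.tau_th);
    P.v.assign(P.n, P.v_rest);
    P.theta.assign(P.n, P.theta_base);
    P.r.assign(P.n, P.r_spike);
    P.S_prev.assign(P.n, 0.0);
    P.S_new.assign(P.n, 0.0);
    P.I_total.assign(P.n, 0.0);
    E->pools.push_back(std::move(P));
  }
  E->groups_into.assign(E->pools.size(), {});

  List groups = cfg["groups"];
  for (int k = 0; k < groups.size(); ++k) {
    List gl = groups[k];
    SynGroup g;
    g.name = as<std::string>(gl["name"]);
    g.pre_pool = gl["pre"];
    g.post_pool = gl["post"];
    NumericMatrix W = gl["W"];
    IntegerMatrix Dm = gl["D"];
    NumericMatrix Mm = gl["mask"];
    g.n_pre = W.nrow(); g.n_post = W.ncol();
    g.W.assign(W.begin(), W.end());
    g.D.assign(Dm.begin(), Dm.end());
    g.mask.resize(g.n_pre * g.n_post);
    for (int idx = 0; idx < g.n_pre * g.n_post; ++idx)
      g.mask[idx] = Mm[idx] != 0 ? 1 : 0;
    g.tau_s = gl["tau_s"];
    g.decay_s = std::exp(-E->dt / g.tau_s);
    g.sign = gl["sign"];
    g.plastic = gl["plastic"];
    g.channel = gl["channel"];
    if (g.plastic) {
      g.eta = gl["eta"]; g.alpha = gl["alpha"]; g.beta = gl["beta"];
      g.gamma = gl["gamma"]; g.delta = gl["delta"];
      g.w_min = gl["w_min"]; g.w_max = gl["w_max"];
      double tau_pre = gl["tau_pre"], tau_post = gl["tau_post"];
      g.decay_pre = std::exp(-E->dt / tau_pre);
      g.decay_post = std::exp(-E->dt / tau_post);
    } else {
      g.eta = 0; g.alpha = 0; g.beta = 0; g.gamma = 0; g.delta = 0;
      g.w_min = 0; g.w_max = 0; g.decay_pre = 1; g.decay_post = 1;
    }
    int dmax = 1;
    for (int d : g.D) {
      if (d < 1) stop("engine: delays must be >= 1 step");
      if (d > dmax) dmax = d;
    }
    g.L = dmax + 1;
    g.pending.assign(g.L, {});
    g.c_post.assign(g.n_post, 0.0);
    g.u.assign(g.n_pre, 0.0);
    g.u_ring.assign((size_t)g.L * g.n_pre, 0.0);
    g.p.assign(g.n_post, 0.0);
    rebuild_adjacency(g);
    int expect_pre = g.pre_pool < 0 ? E->n_in : E->pools[g.pre_pool].n;
    if (g.n_pre != expect_pre || g.n_post != E->pools[g.post_pool].n)
      stop("engine: group '%s' has inconsistent shapes", g.name.c_str());
    E->groups.push_back(std::move(g));
    E->groups_into[(int)gl["post"]].push_back(k);
  }

  List integ = cfg["integrator"];
  E->tau_out = integ["tau_out"];
  E->gain = integ["gain"];
  E->decay_out = std::exp(-E->dt / E->tau_out);
  E->integ_pools = as<std::vector<int>>(integ["pools"]);
  E->y.assign(E->integ_pools.size(), 0.0);

  XPtr<Engine> ptr(E, true);
  return ptr;
}

static void set_probs(Engine* E, const std::vector<double>& obs) {
  const Spiker& s = E->spiker;
  for (int d = 0; d < s.dims; ++d) {
    double lo = s.lo[d], hi = s.hi[d], sg = s.sigma[d];
    double v = obs[d];
    if (v < lo) v = lo;
    if (v > hi) v = hi;
    for (int u = 0; u < s.n_units; ++u) {
      double c = lo + u * (hi - lo) / (s.n_units - 1);
      double dd = v - c;
      E->probs[d * s.n_units + u] =
          s.rate_max * std::exp(-dd * dd / (2.0 * sg * sg));
    }
  }
}

static void engine_step(Engine* E, const double* input_spikes, double mA,
                        double mB, bool plastic_on) {
  const long long s = E->step;
  const double dt = E->dt;
  // --- synapse phase ----------------------------------------------------
  for (auto& g : E->groups) {
    const double* pre = (g.pre_pool < 0)
                            ? input_spikes
                            : E->pools[g.pre_pool].S_prev.data();
    // schedule this step's presynaptic spikes
    for (int j = 0; j < g.n_pre; ++j) {
      if (pre[j] > 0.5) {
        for (int k = g.pre_ptr[j]; k < g.pre_ptr[j + 1]; ++k) {
          int idx = g.pre_conn[k];
          g.pending[(s + g.D[idx]) % g.L].push_back(idx);
        }
      }
    }
    // decay summed currents, process arrivals due now
    for (int i = 0; i < g.n_post; ++i) g.c_post[i] *= g.decay_s;
    int slot = (int)(s % g.L);
    g.arrivals_now.clear();
    for (int idx : g.pending[slot]) {
      if (!g.mask[idx]) continue;  // pruned while in flight
      g.c_post[idx / g.n_pre] += g.W[idx];
      g.arrivals_now.push_back(idx);
    }
    g.pending[slot].clear();
    // plasticity traces + three-factor update
    if (g.plastic) {
      double* urow = &g.u_ring[(size_t)slot * g.n_pre];
      for (int j = 0; j < g.n_pre; ++j) {
        g.u[j] = g.u[j] * g.decay_pre + pre[j];
        urow[j] = g.u[j];
      }
      const std::vector<double>& post_prev = E->pools[g.post_pool].S_prev;
      for (int i = 0; i < g.n_post; ++i)
        g.p[i] = g.p[i] * g.decay_post + post_prev[i];
      double m = (g.channel == 1) ? mA : (g.channel == 2 ? mB : 0.0);
      if (plastic_on && m != 0.0) {
        const double f = g.eta * m * dt;
        // post-spike term: S_post * (alpha + beta * x_pre)
        for (int i : E->pools[g.post_pool].spiking_prev) {
          for (int k = g.post_ptr[i]; k < g.post_ptr[i + 1]; ++k) {
            int idx = g.post_conn[k];
            int j = idx % g.n_pre;
            long long back = s - g.D[idx];
            double xpre =
                (back < 0) ? 0.0
                           : g.u_ring[(size_t)(back % g.L) * g.n_pre + j];
            g.W[idx] += f * (g.alpha + g.beta * xpre);
            clip_w(g, idx);
          }
        }
        // delayed pre-spike term: S_pre(t - d) * (gamma + delta * x_post)
        for (int idx : g.arrivals_now) {
          g.W[idx] += f * (g.gamma + g.delta * g.p[idx / g.n_pre]);
          clip_w(g, idx);
        }
      }
    }
  }
  // --- pool phase -------------------------------------------------------
  for (size_t pi = 0; pi < E->pools.size(); ++pi) {
    LifPool& P = E->pools[pi];
    std::fill(P.I_total.begin(), P.I_total.end(), 0.0);
    for (int gi : E->groups_into[pi]) {
      const SynGroup& g = E->groups[gi];
      for (int i = 0; i < P.n; ++i) P.I_total[i] += g.c_post[i];
    }
    for (int i = 0; i < P.n; ++i) {
      double rr = std::min(P.r[i] + dt, P.r_spike);
      double th = P.theta_base + (P.theta[i] - P.theta_base) * P.eth;
      double gate = (rr > 0.0) ? 1.0 : 0.0;
      double vv = P.v_rest + (P.v[i] - P.v_rest) * P.em +
                  gate * (dt / P.tau_m) * P.Rm * P.I_total[i];
      if (!std::isfinite(vv))
        stop("engine: non-finite membrane potential (pool %d, step %lld)",
             (int)pi, s);
      double S = 0.0;
      if (vv > th) {
        S = 1.0;
        vv = P.v_reset;
        th += P.a;
        rr = -P.r_spike;
      }
      P.v[i] = vv; P.theta[i] = th; P.r[i] = rr; P.S_new[i] = S;
    }
  }
  // --- integrator -------------------------------------------------------
  for (size_t k = 0; k < E->y.size(); ++k) {
    const LifPool& P = E->pools[E->integ_pools[k]];
    double count = 0.0;
    for (int i = 0; i < P.n; ++i) count += P.S_new[i];
    double yy = E->y[k] * E->decay_out;
    yy += (1.0 - yy) * (1.0 - std::exp(-E->gain * count));
    if (yy < 0.0) yy = 0.0;
    if (yy > 1.0) yy = 1.0;
    E->y[k] = yy;
  }
  // --- commit spikes ----------------------------------------------------
  for (auto& P : E->pools) {
    P.S_prev.swap(P.S_new);
    P.spiking_prev.clear();
    for (int i = 0; i < P.n; ++i)
      if (P.S_prev[i] > 0.5) P.spiking_prev.push_back(i);
  }
  E->step = s + 1;
}

// Run one interaction: hold an observation (or an injected spike raster) for
// n_steps network steps under per-step modulation, then read the greedy
// action. mod_a / mod_b are length-1 or length-n_steps vectors of the third
// factor delivered to motor channels A and B.
static List run_interaction(Engine* E, const NumericMatrix* inj,
                            int n_steps, NumericVector mod_a,
                            NumericVector mod_b, bool plastic_on,
                            bool record) {
  std::vector<double> input(E->n_in, 0.0);
  NumericMatrix rec_in;
  std::vector<NumericMatrix> rec_pool;
  NumericMatrix rec_y;
  if (record) {
    rec_in = NumericMatrix(E->n_in, n_steps);
    for (auto& P : E->pools) rec_pool.push_back(NumericMatrix(P.n, n_steps));
    rec_y = NumericMatrix(E->y.size(), n_steps);
  }
  std::vector<double> counts(E->pools.size(), 0.0);
  for (int k = 0; k < n_steps; ++k) {
    if (inj) {
      for (int j = 0; j < E->n_in; ++j) input[j] = (*inj)(j, k);
    } else {
      for (int j = 0; j < E->n_in; ++j)
        input[j] = (E->rng.unif() < E->probs[j]) ? 1.0 : 0.0;
    }
    double mA = mod_a.size() == 1 ? mod_a[0] : mod_a[k];
    double mB = mod_b.size() == 1 ? mod_b[0] : mod_b[k];
    engine_step(E, input.data(), mA, mB, plastic_on);
    for (size_t pi = 0; pi < E->pools.size(); ++pi) {
      const LifPool& P = E->pools[pi];
      for (int i : P.spiking_prev) counts[pi] += 1.0;
      if (record)
        for (int i = 0; i < P.n; ++i) rec_pool[pi](i, k) = P.S_prev[i];
    }
    if (record) {
      for (int j = 0; j < E->n_in; ++j) rec_in(j, k) = input[j];
      for (size_t t = 0; t < E->y.size(); ++t) rec_y(t, k) = E->y[t];
    }
  }
  // greedy action, ties toward the lowest index
  int action = 0;
  double best = E->y[0];
  for (size_t t = 1; t < E->y.size(); ++t) {
    if (E->y[t] > best) { best = E->y[t]; action = (int)t; }
  }
  List out = List::create(
      _["action"] = action, _["y"] = NumericVector(E->y.begin(), E->y.end()),
      _["counts"] = NumericVector(counts.begin(), counts.end()),
      _["step"] = (double)E->step);
  if (record) {
    List rp(rec_pool.size());
    for (size_t i = 0; i < rec_pool.size(); ++i) rp[i] = rec_pool[i];
    out["input_spikes"] = rec_in;
    out["pool_spikes"] = rp;
    out["y_trace"] = rec_y;
  }
  return out;
}

// [[Rcpp::export]]
List engine_interaction(SEXP eptr, NumericVector obs, int n_steps,
                        NumericVector mod_a, NumericVector mod_b,
                        bool plastic_on, bool record = false) {
  XPtr<Engine> E(eptr);
  std::vector<double> o(obs.begin(), obs.end());
  if ((int)o.size() != E->spiker.dims)
    stop("engine: observation has length %d, expected %d", (int)o.size(),
         E->spiker.dims);
  for (double v : o)
    if (!std::isfinite(v)) stop("engine: non-finite observation");
  set_probs(E, o);
  return run_interaction(E, nullptr, n_steps, mod_a, mod_b, plastic_on,
                         record);
}

// [[Rcpp::export]]
List engine_interaction_spikes(SEXP eptr, NumericMatrix input_spikes,
                               NumericVector mod_a, NumericVector mod_b,
                               bool plastic_on, bool record = false) {
  XPtr<Engine> E(eptr);
  if (input_spikes.nrow() != E->n_in)
    stop("engine: injected raster has %d rows, expected %d",
         input_spikes.nrow(), E->n_in);
  return run_interaction(E, &input_spikes, input_spikes.ncol(), mod_a, mod_b,
                         plastic_on, record);
}

// [[Rcpp::export]]
List engine_get_group(SEXP eptr, int gi) {
  XPtr<Engine> E(eptr);
  SynGroup& g = E->groups.at(gi);
  NumericMatrix W(g.n_pre, g.n_post), M(g.n_pre, g.n_post);
  IntegerMatrix D(g.n_pre, g.n_post);
  for (int idx = 0; idx < g.n_pre * g.n_post; ++idx) {
    W[idx] = g.W[idx];
    M[idx] = g.mask[idx];
    D[idx] = g.D[idx];
  }
  return List::create(_["name"] = g.name, _["W"] = W, _["mask"] = M,
                      _["D"] = D, _["plastic"] = g.plastic,
                      _["channel"] = g.channel, _["sign"] = g.sign);
}

// [[Rcpp::export]]
void engine_set_group(SEXP eptr, int gi, NumericMatrix W, NumericMatrix mask,
                      IntegerMatrix D) {
  XPtr<Engine> E(eptr);
  SynGroup& g = E->groups.at(gi);
  if (W.nrow() != g.n_pre || W.ncol() != g.n_post)
    stop("engine_set_group: shape mismatch");
  for (int idx = 0; idx < g.n_pre * g.n_post; ++idx) {
    g.W[idx] = W[idx];
    g.mask[idx] = mask[idx] != 0 ? 1 : 0;
    if (D[idx] < 1 || D[idx] > g.L - 1)
      stop("engine_set_group: delay outside the group's ring");
    g.D[idx] = D[idx];
  }
  rebuild_adjacency(g);
}

// [[Rcpp::export]]
int engine_n_groups(SEXP eptr) {
  XPtr<Engine> E(eptr);
  return (int)E->groups.size();
}

// [[Rcpp::export]]
List engine_pool_state(SEXP eptr) {
  XPtr<Engine> E(eptr);
  List out(E->pools.size());
  for (size_t k = 0; k < E->pools.size(); ++k) {
    const LifPool& P = E->pools[k];
    out[k] = List::create(
        _["v"] = NumericVector(P.v.begin(), P.v.end()),
        _["theta"] = NumericVector(P.theta.begin(), P.theta.end()),
        _["r"] = NumericVector(P.r.begin(), P.r.end()),
        _["S"] = NumericVector(P.S_prev.begin(), P.S_prev.end()));
  }
  return out;
}

// [[Rcpp::export]]
NumericVector engine_traces(SEXP eptr) {
  XPtr<Engine> E(eptr);
  return NumericVector(E->y.begin(), E->y.end());
}

// [[Rcpp::export]]
void engine_reset_integrator(SEXP eptr) {
  XPtr<Engine> E(eptr);
  std::fill(E->y.begin(), E->y.end(), 0.0);
}

// [[Rcpp::export]]
void engine_set_rng(SEXP eptr, double seed) {
  XPtr<Engine> E(eptr);
  E->rng = SplitMix64((uint64_t)seed);
}

// [[Rcpp::export]]
double engine_step_count(SEXP eptr) {
  XPtr<Engine> E(eptr);
  return (double)E->step;
}
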