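# The mutual-inhibition cartpole architecture as a blueprint.
#
# Two motor populations ("a" drives pushes to the left, "b" to the right),
# each 256 excitatory + 64 inhibitory LIF units, architecturally biased to
# mutually inhibit each other: each side's excitatory pool drives the other
# side's inhibitory pool, which in turn inhibits that side's excitatory
# pool. A topological spiker encodes the four cartpole observations onto
# line segments; a two-trace saturable integrator reads out the excitatory
# populations and a greedy policy picks the action. Excitatory synapses onto
# the motor populations (input and recurrent) are plastic under the
# three-factor rule and receive the per-motor third factor; the inhibitory
# loop is fixed.
#
# The numeric constants below are the package's recorded working set for
# this task (weight scales, densities, gains, learning constants); all are
# overridable.

#' Blueprint of the mutual-inhibition cartpole model
#'
#' @param n_exc,n_inh Excitatory/inhibitory units per side.
#' @param n_per_dim Encoder units per observation dimension.
#' @param obs_ranges 2 x 4 matrix of encoding ranges for
#'   (x, x_dot, phi, phi_dot); defaults span the termination bounds, with
#'   velocities clipped to +/- 3.
#' @param sigma_frac,rate_max Encoder tuning width (fraction of range) and
#'   peak spike probability per ms.
#' @param w_in,w_rec,w_ei,w_ie Weight scales: input -> excitatory,
#'   excitatory recurrent, excitatory -> (opposite) inhibitory, inhibitory ->
#'   excitatory.
#' @param density_in,density_rec,density_ei,density_ie Connection densities.
#' @param tau_s Synaptic time constant (ms).
#' @param d_max Maximum synaptic delay (ms).
#' @param eta Plasticity learning rate.
#' @param alpha,beta,gamma,delta Quadruplet STDP scaling constants.
#' @param tau_pre,tau_post Eligibility-trace time constants (ms).
#' @param w_clip_in,w_clip_rec Weight magnitude ceilings for the plastic
#'   groups.
#' @param w_floor_in Weight magnitude floor for the plastic input groups
#'   (keeps punished synapses from vanishing entirely, so a suppressed motor
#'   stays recoverable).
#' @param prune_eps,growth_prob,growth_w Structural plasticity constants
#'   (see [structural_update()]); `growth_prob` is per ms-step.
#' @param rec_plastic If `TRUE` the recurrent excitatory groups learn too;
#'   by default only the input -> motor synapses are plastic (the recurrent
#'   contribution to the third-factor update is not state-specific and tends
#'   to destabilize training).
#' @param tau_out,gain Integrator trace constant (ms) and spike-count gain.
#' @param lif Named list overriding [lif_params()] defaults for all pools.
#' @return A [blueprint()] for [build_model()] or [cartpole_agent()].
#' @export
cartpole_blueprint <- function(n_exc = 256, n_inh = 64, n_per_dim = 32,
                               obs_ranges = rbind(c(-2.4, -3, -0.2095, -3),
                                                  c(2.4, 3, 0.2095, 3)),
                               sigma_frac = 0.1, rate_max = 0.5,
                               w_in = 2.2, w_rec = 0.4, w_ei = 1.2,
                               w_ie = 4,
                               density_in = 0.3, density_rec = 0.1,
                               density_ei = 0.3, density_ie = 0.3,
                               tau_s = 5, d_max = 10,
                               eta = 0.05, alpha = -0.1, beta = 1,
                               gamma = 1, delta = -0.1,
                               tau_pre = 200, tau_post = 200,
                               w_clip_in = 3, w_clip_rec = 1,
                               w_floor_in = 0,
                               prune_eps = 0, growth_prob = 0,
                               growth_w = 0.5,
                               rec_plastic = FALSE,
                               tau_out = 25, gain = 0.02,
                               lif = list()) {
  soma <- utils::modifyList(
    list(tau_m = 20, v_rest = -65, R = 1, theta_base = -50, a = 2,
         tau_th = 50, r_spike = 5, v_reset = -65), lif)
  pool <- function(id, n) bp_node(id, "lif_pool", c(list(n = n), soma))
  plas_in <- list(eta = eta, alpha = alpha, beta = beta, gamma = gamma,
                  delta = delta, tau_pre = tau_pre, tau_post = tau_post,
                  w_min = w_floor_in, w_max = w_clip_in, prune_eps = prune_eps,
                  growth_prob = growth_prob, growth_w = growth_w)
  plas_rec <- utils::modifyList(plas_in, list(w_min = 0, w_max = w_clip_rec))
  syn <- function(id, n_pre, n_post, density, w_max, sign = 1,
                  plasticity = NULL, self_conn = FALSE) {
    bp_node(id, "synapse",
            list(n_pre = n_pre, n_post = n_post, tau_s = tau_s,
                 density = density, w_max = w_max, w_min = 0, sign = sign,
                 d_max = d_max, self_connections = self_conn,
                 plasticity = plasticity))
  }
  n_in <- 4 * n_per_dim
  nodes <- list(
    bp_node("spiker", "spiker",
            list(n_units = n_per_dim,
                 ranges = list(lo = obs_ranges[1, ], hi = obs_ranges[2, ]),
                 topology = "line", sigma_frac = sigma_frac,
                 rate_max = rate_max)),
    pool("exc_a", n_exc), pool("exc_b", n_exc),
    pool("inh_a", n_inh), pool("inh_b", n_inh),
    syn("syn_in_a", n_in, n_exc, density_in, w_in, plasticity = plas_in),
    syn("syn_in_b", n_in, n_exc, density_in, w_in, plasticity = plas_in),
    syn("syn_rec_a", n_exc, n_exc, density_rec, w_rec,
        plasticity = if (rec_plastic) plas_rec),
    syn("syn_rec_b", n_exc, n_exc, density_rec, w_rec,
        plasticity = if (rec_plastic) plas_rec),
    syn("syn_ei_ab", n_exc, n_inh, density_ei, w_ei),
    syn("syn_ei_ba", n_exc, n_inh, density_ei, w_ei),
    syn("syn_ie_a", n_inh, n_exc, density_ie, w_ie, sign = -1),
    syn("syn_ie_b", n_inh, n_exc, density_ie, w_ie, sign = -1),
    bp_node("out", "integrator", list(k = 2, tau_out = tau_out, gain = gain))
  )
  edges <- list(
    bp_edge("spiker", "out", "syn_in_a", "pre"),
    bp_edge("spiker", "out", "syn_in_b", "pre"),
    bp_edge("syn_in_a", "I_out", "exc_a", "I_in"),
    bp_edge("syn_in_b", "I_out", "exc_b", "I_in"),
    bp_edge("exc_a", "out", "syn_in_a", "post"),
    bp_edge("exc_b", "out", "syn_in_b", "post"),
    bp_edge("exc_a", "out", "syn_rec_a", "pre"),
    bp_edge("exc_a", "out", "syn_rec_a", "post"),
    bp_edge("syn_rec_a", "I_out", "exc_a", "I_in"),
    bp_edge("exc_b", "out", "syn_rec_b", "pre"),
    bp_edge("exc_b", "out", "syn_rec_b", "post"),
    bp_edge("syn_rec_b", "I_out", "exc_b", "I_in"),
    bp_edge("exc_a", "out", "syn_ei_ab", "pre"),
    bp_edge("syn_ei_ab", "I_out", "inh_b", "I_in"),
    bp_edge("exc_b", "out", "syn_ei_ba", "pre"),
    bp_edge("syn_ei_ba", "I_out", "inh_a", "I_in"),
    bp_edge("inh_a", "out", "syn_ie_a", "pre"),
    bp_edge("syn_ie_a", "I_out", "exc_a", "I_in"),
    bp_edge("inh_b", "out", "syn_ie_b", "pre"),
    bp_edge("syn_ie_b", "I_out", "exc_b", "I_in"),
    bp_edge("exc_a", "out", "out", "pool_0"),
    bp_edge("exc_b", "out", "out", "pool_1")
  )
  blueprint(nodes, edges,
            metadata = list(description = "mutual-inhibition cartpole model"))
}
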