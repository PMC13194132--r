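# Three-factor quadruplet STDP with eligibility traces and structural
# plasticity.
#
# The weight update for connection (j, i) (pre j, post i) is
#
#   dw_ji/dt = eta * M3rd * ( S_post_i * [alpha + beta * x_pre_ji]
#                           + S_pre_j(t - d_ji) * [gamma + delta * x_post_ji] )
#
# where x_pre is the eligibility trace of delayed presynaptic spikes, x_post
# the trace of postsynaptic spikes, and M3rd a modulatory third factor that
# gates all learning (M3rd == 0 freezes the weights exactly). Applied as
# forward-Euler per-step increments (* dt), then clipped to the magnitude
# bounds with the population sign preserved.

#' Plasticity parameters
#'
#' @param eta Learning rate (`>= 0`).
#' @param alpha,gamma Constant (trace-free) scaling of the post- and
#'   (delayed) pre-spike terms.
#' @param beta,delta Trace-weighted scaling of the post- and pre-spike terms.
#'   The defaults (`alpha = -0.1`, `beta = 1`, `gamma = 1`, `delta = -0.1`)
#'   potentiate pre-before-post pairings at the post-spike term with a mild
#'   constant depression offset. Scalars broadcast per connection; matrices
#'   of per-connection constants are accepted anywhere a scalar is.
#' @param tau_pre,tau_post Eligibility-trace time constants (ms).
#' @param w_min,w_max Weight magnitude bounds (`0 <= w_min <= w_max`).
#' @param prune_eps Magnitude below which an existing connection is deleted
#'   by [structural_update()] (0 disables pruning).
#' @param growth_prob Per-call probability that an absent connection is added
#'   by [structural_update()] (0 disables growth).
#' @param growth_w Magnitude assigned to newly grown connections.
#' @param sign Population sign of the weights (`+1` or `-1`).
#' @return An object of class `plasticity_params`.
#' @export
plasticity_params <- function(eta = 0.05, alpha = -0.1, beta = 1,
                              gamma = 1, delta = -0.1,
                              tau_pre = 20, tau_post = 20,
                              w_min = 0, w_max = 1,
                              prune_eps = 0, growth_prob = 0,
                              growth_w = 0.05, sign = 1) {
  stopifnot(eta >= 0, tau_pre > 0, tau_post > 0, prune_eps >= 0,
            w_min >= 0, w_min <= w_max, growth_prob >= 0, growth_prob <= 1,
            sign %in% c(-1, 1))
  structure(list(eta = eta, alpha = alpha, beta = beta, gamma = gamma,
                 delta = delta, tau_pre = tau_pre, tau_post = tau_post,
                 w_min = w_min, w_max = w_max, prune_eps = prune_eps,
                 growth_prob = growth_prob, growth_w = growth_w, sign = sign),
            class = "plasticity_params")
}

#' Initialize eligibility traces
#'
#' @param n_pre,n_post Pool sizes.
#' @return A list with zero matrices `x_pre` and `x_post` (pre x post).
#' @export
traces_init <- function(n_pre, n_post) {
  list(x_pre = matrix(0, n_pre, n_post), x_post = matrix(0, n_pre, n_post))
}

# Accept a per-pre vector (broadcast across posts) or a pre x post matrix of
# delayed presynaptic arrivals.
.as_arrival_matrix <- function(pre, n_pre, n_post) {
  if (is.matrix(pre)) {
    stopifnot(nrow(pre) == n_pre, ncol(pre) == n_post)
    pre
  } else {
    stopifnot(length(pre) == n_pre)
    matrix(pre, n_pre, n_post)
  }
}

#' Update eligibility traces by one step
#'
#' Each trace decays by `exp(-dt/tau)` and is incremented by 1 on its
#' triggering spike: the pre trace on the delayed presynaptic spike arriving
#' this step, the post trace on the postsynaptic spike.
#'
#' @param traces A list from [traces_init()].
#' @param pre_spikes_delayed Delayed presynaptic arrivals: 0/1 pre x post
#'   matrix (per-connection delays) or a per-pre vector (uniform delay).
#' @param post_spikes 0/1 vector of postsynaptic spikes.
#' @param params A [plasticity_params()] object.
#' @param dt Step size (ms).
#' @return Updated traces.
#' @export
update_traces <- function(traces, pre_spikes_delayed, post_spikes, params, dt) {
  n_pre <- nrow(traces$x_pre)
  n_post <- ncol(traces$x_pre)
  A <- .as_arrival_matrix(pre_spikes_delayed, n_pre, n_post)
  stopifnot(length(post_spikes) == n_post)
  traces$x_pre <- traces$x_pre * exp(-dt / params$tau_pre) + A
  traces$x_post <- traces$x_post * exp(-dt / params$tau_post) +
    matrix(post_spikes, n_pre, n_post, byrow = TRUE)
  traces
}

# Clip weights to the signed interval implied by the magnitude bounds:
# [w_min, w_max] for excitatory groups, [-w_max, -w_min] for inhibitory
# ones. Depression can therefore drive a weight to its floor but never
# across zero (Dale-like sign preservation).
clip_weights <- function(W, mask, params) {
  if (params$sign > 0) {
    lo <- params$w_min
    hi <- params$w_max
  } else {
    lo <- -params$w_max
    hi <- -params$w_min
  }
  pmin(pmax(W, lo), hi) * mask
}

#' Apply the three-factor STDP update to a weight matrix
#'
#' Computes the per-connection increment described above for one step and
#' clips the result to the magnitude bounds. Only masked (existing)
#' connections are updated. `m3rd = 0` returns `W` unchanged exactly.
#'
#' @param W Weight matrix (pre x post).
#' @param mask 0/1 connectivity matrix.
#' @param traces Eligibility traces, already advanced to this step with
#'   [update_traces()].
#' @param pre_spikes_delayed Delayed presynaptic arrivals (matrix or vector,
#'   as in [update_traces()]).
#' @param post_spikes 0/1 postsynaptic spike vector.
#' @param m3rd Scalar third factor for this step.
#' @param params A [plasticity_params()] object.
#' @param dt Step size (ms).
#' @return The updated weight matrix.
#' @export
stdp_update <- function(W, mask, traces, pre_spikes_delayed, post_spikes,
                        m3rd, params, dt) {
  if (m3rd == 0) return(W)
  n_pre <- nrow(W)
  n_post <- ncol(W)
  A <- .as_arrival_matrix(pre_spikes_delayed, n_pre, n_post)
  Sp <- matrix(post_spikes, n_pre, n_post, byrow = TRUE)
  dW <- params$eta * m3rd * dt *
    (Sp * (params$alpha + params$beta * traces$x_pre) +
       A * (params$gamma + params$delta * traces$x_post))
  if (any(!is.finite(dW))) {
    bad <- which(!is.finite(dW), arr.ind = TRUE)[1, ]
    stop("stdp_update: non-finite weight increment at connection (",
         bad[1], ", ", bad[2], ")", call. = FALSE)
  }
  clip_weights(W + dW * mask, mask, params)
}

#' Structural plasticity: prune weak connections, grow absent ones
#'
#' Existing connections with `|w| < prune_eps` are removed from the mask and
#' zeroed. Absent connections are added independently with probability
#' `growth_prob`, at magnitude `growth_w` with the population's sign.
#' Deterministic under `seed`.
#'
#' @param W Weight matrix (pre x post).
#' @param mask 0/1 connectivity matrix.
#' @param params A [plasticity_params()] object.
#' @param seed Integer seed for the growth draws.
#' @param allowed Optional 0/1 matrix of connections that may ever exist
#'   (e.g. to keep a recurrent pool's diagonal empty); defaults to all.
#' @return A list with the updated `W` and `mask`.
#' @export
structural_update <- function(W, mask, params, seed = 1, allowed = NULL) {
  if (is.null(allowed)) allowed <- matrix(1, nrow(W), ncol(W))
  if (params$prune_eps > 0) {
    drop <- mask == 1 & abs(W) < params$prune_eps
    mask[drop] <- 0
    W[drop] <- 0
  }
  if (params$growth_prob > 0) {
    grow <- with_seed(seed, {
      matrix(runif(length(W)) < params$growth_prob, nrow(W), ncol(W))
    })
    grow <- grow & mask == 0 & allowed == 1
    mask[grow] <- 1
    W[grow] <- params$sign * params$growth_w
  }
  list(W = W, mask = mask)
}
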