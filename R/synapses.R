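# Traced-current synapses with per-connection integer-step delays.
#
# Connection matrices are oriented pre x post: entry [j, i] is the connection
# from presynaptic unit j to postsynaptic unit i. The per-connection current
# obeys tau_s * dI/dt = -I, incremented by w_ji when the presynaptic spike
# emitted d_ji earlier arrives; the drive onto postsynaptic unit i is the
# column sum over j. Excitatory groups carry nonnegative weights, inhibitory
# groups nonpositive ones (sign is a population property and is preserved).

#' Synapse group parameters
#'
#' @param n_pre,n_post Pool sizes.
#' @param tau_s Synaptic time constant (ms).
#' @param density Initial connection probability in `[0, 1]`.
#' @param w_max Maximum weight magnitude (weights are initialized uniformly in
#'   `[0, w_max]` and signed by `sign`).
#' @param w_min Minimum weight magnitude (default 0).
#' @param sign `+1` for an excitatory population, `-1` for inhibitory.
#' @param d_max Maximum connection delay (ms); per-connection delays are drawn
#'   as integer multiples of `dt`, uniform on `[dt, d_max]`.
#' @param self_connections Allow the diagonal when the group is square (a
#'   recurrent pool onto itself); default `FALSE`.
#' @return An object of class `synapse_params`.
#' @export
synapse_params <- function(n_pre, n_post, tau_s = 5, density = 0.1,
                           w_max = 1, w_min = 0, sign = 1, d_max = 10,
                           self_connections = FALSE) {
  stopifnot(n_pre >= 1, n_post >= 1, tau_s > 0,
            density >= 0, density <= 1,
            w_min >= 0, w_min <= w_max, sign %in% c(-1, 1), d_max > 0)
  structure(list(n_pre = n_pre, n_post = n_post, tau_s = tau_s,
                 density = density, w_max = w_max, w_min = w_min,
                 sign = sign, d_max = d_max,
                 self_connections = self_connections),
            class = "synapse_params")
}

#' Sparse uniform weight initialization
#'
#' Each potential connection is present independently with probability
#' `density`; present weights are drawn `Uniform(0, w_max)` and signed by
#' `sign`. Self-connections are excluded for square groups unless requested.
#'
#' @param n_pre,n_post Pool sizes.
#' @param density Connection probability in `[0, 1]`.
#' @param w_max Maximum weight magnitude.
#' @param sign `+1` or `-1`.
#' @param seed Integer seed; initialization is reproducible.
#' @param self_connections Allow diagonal connections when `n_pre == n_post`.
#' @return A list with `W` (pre x post weight matrix) and `mask` (0/1 matrix).
#' @export
init_weights <- function(n_pre, n_post, density, w_max, sign = 1, seed = 1,
                         self_connections = FALSE) {
  if (density < 0 || density > 1) {
    stop("init_weights: density must be in [0, 1]", call. = FALSE)
  }
  with_seed(seed, {
    mask <- matrix(as.numeric(runif(n_pre * n_post) < density), n_pre, n_post)
    if (n_pre == n_post && !self_connections) diag(mask) <- 0
    W <- mask * matrix(runif(n_pre * n_post, 0, w_max), n_pre, n_post) * sign
    list(W = W, mask = mask)
  })
}

#' Per-connection integer-step delays
#'
#' @param n_pre,n_post Pool sizes.
#' @param d_max Maximum delay (ms).
#' @param dt Step size (ms).
#' @param seed Integer seed.
#' @return Integer matrix (pre x post) of delays in steps, uniform on
#'   `1..d_max/dt`.
#' @export
init_delays <- function(n_pre, n_post, d_max, dt, seed = 1) {
  steps <- max(1L, as.integer(round(d_max / dt)))
  with_seed(seed, {
    matrix(sample.int(steps, n_pre * n_post, replace = TRUE), n_pre, n_post)
  })
}

#' Initialize synapse-group state
#'
#' @param params A [synapse_params()] object.
#' @param dt Step size (ms).
#' @param seed Integer seed used for both weights and delays.
#' @return An object of class `synapse_state` holding the weight matrix `W`,
#'   `mask`, delay matrix `D` (steps), per-connection currents `I`, and the
#'   circular presynaptic spike history.
#' @export
synapse_init <- function(params, dt, seed = 1) {
  wm <- init_weights(params$n_pre, params$n_post, params$density,
                     params$w_max, params$sign, seed,
                     params$self_connections)
  D <- init_delays(params$n_pre, params$n_post, params$d_max, dt,
                   derive_seed(seed, "delays"))
  L <- max(D) + 1L
  structure(list(W = wm$W, mask = wm$mask, D = D,
                 I = matrix(0, params$n_pre, params$n_post),
                 history = matrix(0, params$n_pre, L),
                 step = 0L, dt = dt),
            class = "synapse_state")
}

# Delayed-arrival indicator matrix: A[j, i] = 1 iff presynaptic unit j spiked
# D[j, i] steps before the current one. Reads the circular history; the
# current step's spikes must already be pushed.
synapse_arrivals <- function(state) {
  L <- ncol(state$history)
  n_pre <- nrow(state$D)
  slot <- ((state$step - state$D) %% L) + 1L
  idx <- cbind(rep.int(seq_len(n_pre), ncol(state$D)), as.vector(slot))
  matrix(state$history[idx], n_pre, ncol(state$D))
}

#' Advance a synapse group by one step
#'
#' Pushes the current presynaptic spike vector into the delay history, decays
#' every per-connection current by `exp(-dt/tau_s)`, and increments connection
#' `(j, i)` by `w_ji` when the spike emitted by `j` exactly `d_ji` steps ago
#' arrives. Delays are at least one step, so a spike never arrives on the step
#' it is pushed.
#'
#' @param state A `synapse_state` from [synapse_init()].
#' @param presyn_spikes 0/1 vector of presynaptic spikes for this step.
#' @param params The group's [synapse_params()].
#' @param dt Step size (ms); must equal the `dt` the state was built with.
#' @return The updated state, with `$current` the per-postsynaptic-unit summed
#'   current and `$arrivals` the 0/1 pre x post delayed-arrival matrix (used
#'   by the plasticity rule).
#' @export
synapse_step <- function(state, presyn_spikes, params, dt) {
  stopifnot(length(presyn_spikes) == params$n_pre,
            all(presyn_spikes %in% c(0, 1)),
            isTRUE(all.equal(dt, state$dt)))
  L <- ncol(state$history)
  state$step <- state$step + 1L
  state$history[, (state$step %% L) + 1L] <- presyn_spikes
  A <- synapse_arrivals(state)
  state$I <- state$I * exp(-dt / params$tau_s) + state$W * A
  state$current <- colSums(state$I)
  state$arrivals <- A
  state
}
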