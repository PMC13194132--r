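# I/O boundary: the topological spiker (value -> spike distribution) and the
# saturable-trace integrator with a greedy action policy.

#' Topological spiker configuration
#'
#' A grid-cell-like population encoder: each input dimension is covered by
#' `n_units` units with Gaussian tuning curves centered on an even grid over
#' the dimension's range. Unit `i` fires a Bernoulli spike per ms with
#' probability `rate_max * exp(-dist(value, center_i)^2 / (2 sigma^2))`,
#' where `dist` respects the dimension's topology: values are clipped to the
#' range for `"line"` segments, and distances wrap around for `"circle"`
#' dimensions (the borders are glued, so `lo` and `hi` are the same point).
#'
#' @param ranges Numeric 2-row matrix (or 2-vector for one dimension): per
#'   dimension `lo` and `hi`, `lo < hi`.
#' @param n_units Units per input dimension.
#' @param topology Character vector, `"line"` or `"circle"` per dimension
#'   (recycled).
#' @param sigma_frac Tuning width as a fraction of each dimension's range.
#' @param rate_max Peak spike probability per ms, in `[0, 1]` (0 silences
#'   the encoder).
#' @return An object of class `spiker_config`.
#' @export
spiker_config <- function(ranges, n_units = 32, topology = "line",
                          sigma_frac = 0.1, rate_max = 0.5) {
  if (!is.matrix(ranges)) ranges <- matrix(ranges, nrow = 2)
  stopifnot(nrow(ranges) == 2, all(ranges[1, ] < ranges[2, ]),
            n_units >= 2, sigma_frac > 0, rate_max >= 0, rate_max <= 1)
  d <- ncol(ranges)
  topology <- rep_len(match.arg(topology, c("line", "circle"), several.ok = TRUE),
                      d)
  centers <- lapply(seq_len(d), function(k) {
    lo <- ranges[1, k]; hi <- ranges[2, k]
    if (topology[k] == "circle") {
      lo + (seq_len(n_units) - 1) / n_units * (hi - lo)
    } else {
      seq(lo, hi, length.out = n_units)
    }
  })
  structure(list(ranges = ranges, n_units = n_units, topology = topology,
                 sigma = sigma_frac * (ranges[2, ] - ranges[1, ]),
                 rate_max = rate_max, centers = centers, dims = d),
            class = "spiker_config")
}

#' Per-unit firing probabilities for an observation
#'
#' The deterministic part of [encode()]: the Bernoulli probability of each
#' unit for the given value, concatenated across dimensions.
#'
#' @param value Numeric vector, one scalar per configured dimension.
#' @param config A [spiker_config()].
#' @return Numeric vector of length `dims * n_units`.
#' @export
encode_probs <- function(value, config) {
  if (any(!is.finite(value))) stop("encode: non-finite observation", call. = FALSE)
  stopifnot(length(value) == config$dims)
  unlist(lapply(seq_len(config$dims), function(k) {
    lo <- config$ranges[1, k]; hi <- config$ranges[2, k]
    v <- value[k]
    ctr <- config$centers[[k]]
    if (config$topology[k] == "circle") {
      span <- hi - lo
      d <- abs(((v - ctr) %% span))
      d <- pmin(d, span - d)
    } else {
      v <- min(max(v, lo), hi)
      d <- abs(v - ctr)
    }
    config$rate_max * exp(-d^2 / (2 * config$sigma[k]^2))
  }))
}

#' Encode an observation as a spike vector
#'
#' Draws one Bernoulli spike per unit per call (one call per simulated ms;
#' encoding noise is refreshed every ms even while an observation is held).
#'
#' @inheritParams encode_probs
#' @param seed Optional integer seed for a reproducible draw; if `NULL` the
#'   current RNG state is used.
#' @return 0/1 spike vector of length `dims * n_units`.
#' @export
encode <- function(value, config, seed = NULL) {
  p <- encode_probs(value, config)
  draw <- function() as.numeric(runif(length(p)) < p)
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Saturable trace integrator
#'
#' The output decoder: `k` traces in `[0, 1]`, each fed exclusively by one
#' population's spikes. Per step each trace decays by `exp(-dt/tau_out)` and
#' is then incremented by `(1 - y) * (1 - exp(-gain * count))`, a saturating
#' jump that is monotone in the spike count and can never push the trace
#' above 1.
#'
#' @param k Number of traces (one per action).
#' @param tau_out Trace time constant (ms).
#' @param gain Gain constant `c` of the saturating increment.
#' @return An object of class `integrator_state` with `$y = 0` vector.
#' @export
integrator_state <- function(k = 2, tau_out = 25, gain = 0.3) {
  stopifnot(k >= 1, tau_out > 0, gain > 0)
  structure(list(y = numeric(k), k = k, tau_out = tau_out, gain = gain),
            class = "integrator_state")
}

#' Advance the integrator by one step
#'
#' @param state An [integrator_state()].
#' @param pool_spikes Nonnegative spike counts, one per trace.
#' @param dt Step size (ms).
#' @return Updated state.
#' @export
integrate_traces <- function(state, pool_spikes, dt) {
  stopifnot(length(pool_spikes) == state$k, all(pool_spikes >= 0))
  y <- state$y * exp(-dt / state$tau_out)
  y <- y + (1 - y) * (1 - exp(-state$gain * pool_spikes))
  state$y <- pmin(pmax(y, 0), 1)
  state
}

#' Greedy action from the integrator traces
#'
#' Argmax over traces at the moment of the interaction step; ties break
#' deterministically toward the lowest index.
#'
#' @param state An [integrator_state()] (or a bare numeric vector of traces).
#' @return 0-based action index (0 selects the first trace).
#' @export
select_action <- function(state) {
  y <- if (inherits(state, "integrator_state")) state$y else state
  stopifnot(length(y) >= 2)
  which.max(y) - 1L
}
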