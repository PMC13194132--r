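# Soma models.
#
# All somas are integrated with a mixture of forward Euler (driving terms) and
# exponential Euler (linear leak/decay terms), on a fixed step dt in ms.
# Potentials are in mV, time constants in ms; input currents are in the
# model-specific units implied by each soma's input scaling.

#' Leaky integrate-and-fire parameters
#'
#' LIF soma with a refractory period and an adaptive (spike-incremented)
#' threshold. Subthreshold dynamics are
#' \deqn{\tau_m \dot v = -(v - v_{rest}) + R \sum I}{tau_m v' = -(v - v_rest) + R*I}
#' while the neuron is non-refractory; during the refractory window the input
#' term is gated off and only the leak acts. The threshold decays toward
#' `theta_base` with time constant `tau_th` and jumps by `a` on each spike.
#' A spike (`v > theta`, tested after the integration update) resets `v` to
#' `v_reset` and starts a refractory window of `r_spike` ms.
#'
#' @param tau_m Membrane time constant (ms).
#' @param v_rest Resting potential (mV).
#' @param R Membrane resistance (input scaling, dimensionless here).
#' @param theta_base Base firing threshold (mV); must exceed `v_rest`.
#' @param a Threshold increment per spike (mV, `>= 0`).
#' @param tau_th Threshold decay time constant (ms).
#' @param r_spike Refractory duration (ms).
#' @param v_reset Post-spike reset potential (mV); defaults to `v_rest`.
#' @return An object of class `lif_params`.
#' @export
lif_params <- function(tau_m = 20, v_rest = -65, R = 1, theta_base = -50,
                       a = 2, tau_th = 50, r_spike = 5, v_reset = v_rest) {
  stopifnot(tau_m > 0, tau_th > 0, r_spike > 0, theta_base > v_rest, a >= 0)
  structure(list(tau_m = tau_m, v_rest = v_rest, R = R,
                 theta_base = theta_base, a = a, tau_th = tau_th,
                 r_spike = r_spike, v_reset = v_reset),
            class = "lif_params")
}

#' Initial LIF state for a pool of `n` units
#'
#' Units start at rest, threshold at base, non-refractory.
#'
#' @param n Number of units.
#' @param params A [lif_params()] object.
#' @return An object of class `lif_state` with fields `v`, `theta`, `r`, `S`.
#' @export
lif_init <- function(n, params) {
  structure(list(v = rep(params$v_rest, n),
                 theta = rep(params$theta_base, n),
                 r = rep(params$r_spike, n),
                 S = numeric(n)),
            class = "lif_state")
}

#' Advance a LIF pool by one step
#'
#' Order of operations within a step: the refractory clock advances; the
#' threshold decays toward base (exponential Euler); the potential integrates
#' the leak (exponential Euler) plus, for non-refractory units (`r > 0`), the
#' forward-Euler input term `(dt/tau_m) * R * I`; the spike test `v > theta`
#' is evaluated after the update; spiking units are reset and their threshold
#' incremented.
#'
#' @param state A `lif_state`.
#' @param input_current Per-unit summed input current.
#' @param params A [lif_params()] object.
#' @param dt Step size (ms).
#' @return Updated `lif_state`; `$S` flags this step's spikes.
#' @export
lif_step <- function(state, input_current, params, dt) {
  stopifnot(dt > 0, length(input_current) == length(state$v))
  p <- params
  r <- pmin(state$r + dt, p$r_spike)
  theta <- p$theta_base + (state$theta - p$theta_base) * exp(-dt / p$tau_th)
  gate <- as.numeric(r > 0)
  v <- p$v_rest + (state$v - p$v_rest) * exp(-dt / p$tau_m) +
    gate * (dt / p$tau_m) * p$R * input_current
  if (any(!is.finite(v))) {
    stop("lif_step: non-finite membrane potential (unit ",
         which(!is.finite(v))[1], ")", call. = FALSE)
  }
  S <- as.numeric(v > theta)
  fired <- S == 1
  v[fired] <- p$v_reset
  theta <- theta + p$a * S
  r[fired] <- -p$r_spike
  structure(list(v = v, theta = theta, r = r, S = S), class = "lif_state")
}

#' Adaptive exponential integrate-and-fire parameters
#'
#' Two-variable AdEx soma: membrane potential with an exponential
#' spike-initiation term, plus an adaptation current `w` with subthreshold
#' coupling `a_w` and spike-triggered increment `b_w`. Defaults are the
#' standard regular-spiking parameter set (capacitance in pF, conductances in
#' nS, currents in pA, potentials in mV, time in ms).
#'
#' @param C Membrane capacitance (pF).
#' @param g_L Leak conductance (nS).
#' @param E_L Leak reversal / rest potential (mV).
#' @param V_T Exponential threshold (mV).
#' @param delta_T Slope factor (mV).
#' @param tau_w Adaptation time constant (ms).
#' @param a_w Subthreshold adaptation coupling (nS).
#' @param b_w Spike-triggered adaptation increment (pA).
#' @param v_reset Post-spike reset potential (mV).
#' @param v_cut Numerical spike cutoff (mV); the exponential argument is also
#'   clamped so the update never overflows.
#' @return An object of class `adex_params`.
#' @export
adex_params <- function(C = 281, g_L = 30, E_L = -70.6, V_T = -50.4,
                        delta_T = 2, tau_w = 144, a_w = 4, b_w = 80.5,
                        v_reset = -70.6, v_cut = V_T + 5 * delta_T) {
  stopifnot(C > 0, g_L > 0, delta_T > 0, tau_w > 0)
  structure(list(C = C, g_L = g_L, E_L = E_L, V_T = V_T, delta_T = delta_T,
                 tau_w = tau_w, a_w = a_w, b_w = b_w, v_reset = v_reset,
                 v_cut = v_cut),
            class = "adex_params")
}

#' @rdname adex_params
#' @param n Number of units.
#' @param params An `adex_params` object.
#' @export
adex_init <- function(n, params) {
  structure(list(v = rep(params$E_L, n), w = numeric(n), S = numeric(n)),
            class = "adex_state")
}

#' Advance an AdEx pool by one step
#'
#' Forward-Euler update of both variables with the exponential term clamped
#' (argument capped at 20) for numerical safety; spike when `v` exceeds
#' `v_cut`, then reset and adaptation jump `w <- w + b_w`.
#'
#' @inheritParams lif_step
#' @param state An `adex_state`.
#' @param params An [adex_params()] object.
#' @return Updated `adex_state`.
#' @export
adex_step <- function(state, input_current, params, dt) {
  stopifnot(dt > 0, length(input_current) == length(state$v))
  p <- params
  ex <- exp(pmin((state$v - p$V_T) / p$delta_T, 20))
  dv <- (p$g_L * (p$E_L - state$v) + p$g_L * p$delta_T * ex -
           state$w + input_current) / p$C
  dw <- (p$a_w * (state$v - p$E_L) - state$w) / p$tau_w
  v <- state$v + dt * dv
  w <- state$w + dt * dw
  if (any(!is.finite(v)) || any(!is.finite(w))) {
    stop("adex_step: non-finite state", call. = FALSE)
  }
  S <- as.numeric(v > p$v_cut)
  fired <- S == 1
  v[fired] <- p$v_reset
  w[fired] <- w[fired] + p$b_w
  structure(list(v = v, w = w, S = S), class = "adex_state")
}

#' Hodgkin-Huxley parameters (classic squid-axon set)
#'
#' Four-variable conductance-based soma (`v`, gating `m`, `h`, `n`) with the
#' standard alpha/beta rate functions. Conductances in mS/cm^2, capacitance in
#' uF/cm^2, currents in uA/cm^2, potentials in mV, time in ms. Gating
#' variables use exponential Euler (and therefore remain in `[0, 1]` by
#' construction); the potential uses forward Euler. A spike is an upward
#' crossing of 0 mV.
#'
#' @param C Membrane capacitance (uF/cm^2).
#' @param g_Na,g_K,g_L Maximal conductances (mS/cm^2).
#' @param E_Na,E_K,E_L Reversal potentials (mV).
#' @return An object of class `hh_params`.
#' @export
hh_params <- function(C = 1, g_Na = 120, g_K = 36, g_L = 0.3,
                      E_Na = 50, E_K = -77, E_L = -54.387) {
  structure(list(C = C, g_Na = g_Na, g_K = g_K, g_L = g_L,
                 E_Na = E_Na, E_K = E_K, E_L = E_L),
            class = "hh_params")
}

# x / (1 - exp(-x / y)), with the removable singularity at x = 0 filled in.
.hh_vtrap <- function(x, y) {
  out <- x / (1 - exp(-x / y))
  small <- abs(x / y) < 1e-6
  out[small] <- y * (1 + x[small] / (2 * y))
  out
}

.hh_rates <- function(v) {
  list(
    am = 0.1 * .hh_vtrap(v + 40, 10),
    bm = 4 * exp(-(v + 65) / 18),
    ah = 0.07 * exp(-(v + 65) / 20),
    bh = 1 / (1 + exp(-(v + 35) / 10)),
    an = 0.01 * .hh_vtrap(v + 55, 10),
    bn = 0.125 * exp(-(v + 65) / 80)
  )
}

#' @rdname hh_params
#' @param n Number of units.
#' @param params An `hh_params` object.
#' @param v0 Initial potential (mV); gating variables start at their
#'   steady-state values for `v0`.
#' @export
hh_init <- function(n, params, v0 = -65) {
  r <- .hh_rates(v0)
  structure(list(v = rep(v0, n),
                 m = rep(r$am / (r$am + r$bm), n),
                 h = rep(r$ah / (r$ah + r$bh), n),
                 n = rep(r$an / (r$an + r$bn), n),
                 S = numeric(n)),
            class = "hh_state")
}

#' Advance a Hodgkin-Huxley pool by one step
#'
#' @inheritParams lif_step
#' @param state An `hh_state`.
#' @param params An [hh_params()] object.
#' @return Updated `hh_state`; `$S` flags upward 0 mV crossings this step.
#' @export
hh_step <- function(state, input_current, params, dt) {
  stopifnot(dt > 0, length(input_current) == length(state$v))
  p <- params
  v <- state$v
  r <- .hh_rates(v)
  upd <- function(g, a, b) {
    tau <- 1 / (a + b)
    inf <- a * tau
    inf + (g - inf) * exp(-dt / tau)
  }
  m <- upd(state$m, r$am, r$bm)
  h <- upd(state$h, r$ah, r$bh)
  nn <- upd(state$n, r$an, r$bn)
  i_ion <- p$g_Na * m^3 * h * (v - p$E_Na) + p$g_K * nn^4 * (v - p$E_K) +
    p$g_L * (v - p$E_L)
  v_new <- v + dt * (input_current - i_ion) / p$C
  if (any(!is.finite(v_new))) {
    stop("hh_step: non-finite membrane potential", call. = FALSE)
  }
  S <- as.numeric(v_new > 0 & v <= 0)
  structure(list(v = v_new, m = m, h = h, n = nn, S = S), class = "hh_state")
}

#' Simulate a soma under a prescribed current
#'
#' Runs one of the soma models for `nrow(current)` steps (or `length(current)`
#' for a single unit) under a per-step injected current and returns spike
#' times. The loop runs in compiled code; `lif_step()`, `adex_step()` and
#' `hh_step()` implement the identical per-step arithmetic in R.
#'
#' @param kind One of `"lif"`, `"adex"`, `"hh"`.
#' @param current Numeric vector (single unit) or matrix (steps x units) of
#'   input current per step.
#' @param dt Step size (ms). The fidelity protocol of [fidelity_report()] uses
#'   0.1 ms for LIF/AdEx and 0.05 ms for HH.
#' @param params Soma parameter object matching `kind`; defaults to the
#'   model's default parameters.
#' @param return_v If `TRUE`, also return the membrane-potential trace.
#' @return A list with `spikes` (list of per-unit spike-time vectors, ms,
#'   spike time = end of the step on which the spike was registered) and,
#'   optionally, `v` (steps x units matrix).
#' @export
simulate_soma <- function(kind = c("lif", "adex", "hh"), current, dt,
                          params = NULL, return_v = FALSE) {
  kind <- match.arg(kind)
  if (is.null(params)) {
    params <- switch(kind, lif = lif_params(), adex = adex_params(),
                     hh = hh_params())
  }
  if (is.vector(current)) current <- matrix(current, ncol = 1)
  out <- soma_sim_cpp(kind, current, dt, unclass(params), return_v)
  out$spikes <- lapply(out$spikes, function(s) s)  # already times in ms
  out
}
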