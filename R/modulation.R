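# The sparse-reward third factor.
#
# Training delivers a single reward event per episode: R_step is -1 when the
# pole fell or the cart left the track within the last interaction window,
# and 0 otherwise (including truncation at the episode cap). The modulatory
# third factor is
#
#   M3rd(t) = (N_ema / N_max) * R_step * exp(-tau_R * (t - t_step))   if R_step != 0
#           = lambda                                                  otherwise
#
# where N_ema is an exponential moving average of episode lengths, N_max the
# episode cap, and lambda a small background constant that lets the network
# self-organize between reward events.

#' Modulation state
#'
#' @param N_max Episode cap of the environment (steps).
#' @param lambda Background modulation constant (small, `>= 0`).
#' @param xi Opposite-motor gain: on failure the suppressed motor receives
#'   `M3rd` and the other motor `-xi * M3rd` (a small positive signal that
#'   promotes synaptic growth on the alternative action).
#' @param tau_R Decay constant of the reward modulation (1/ms).
#' @param ema EMA coefficient for the episode-length average.
#' @return An object of class `modulation_state` with fields `N_ema`
#'   (initialized to the first observed episode length), `t_step`, `R_step`,
#'   and `n_episodes`.
#' @export
modulation_state <- function(N_max = 500, lambda = 1e-4, xi = 0.5,
                             tau_R = 0.02, ema = 0.1) {
  stopifnot(N_max >= 1, lambda >= 0, xi >= 0, tau_R >= 0,
            ema > 0, ema <= 1)
  structure(list(N_max = N_max, lambda = lambda, xi = xi, tau_R = tau_R,
                 ema = ema, N_ema = 0, t_step = 0, R_step = 0,
                 n_episodes = 0L),
            class = "modulation_state")
}

#' Terminal reward of an interaction window
#'
#' `-1` if the pole fell or the cart went out of bounds during the window,
#' `0` otherwise; truncation at the episode cap is not a failure and yields
#' `0`.
#'
#' @param flags A `cartpole_state` (or any list with logical `pole_fell` and
#'   `oob`).
#' @return `-1` or `0`.
#' @export
compute_rstep <- function(flags) {
  if (isTRUE(flags$pole_fell) || isTRUE(flags$oob)) -1 else 0
}

#' Evaluate the modulatory third factor
#'
#' @param mod A [modulation_state()] whose `R_step` and `t_step` describe the
#'   last interaction step.
#' @param t Simulated time (ms).
#' @return `(N_ema/N_max) * R_step * exp(-tau_R (t - t_step))` when
#'   `R_step != 0`; `lambda` exactly otherwise.
#' @export
compute_m3rd <- function(mod, t) {
  if (mod$R_step != 0) {
    (mod$N_ema / mod$N_max) * mod$R_step * exp(-mod$tau_R * (t - mod$t_step))
  } else {
    mod$lambda
  }
}

#' Per-motor delivery of the third factor
#'
#' The third factor is delivered independently to each motor population. On a
#' failure event the motor whose action is being suppressed (the action
#' chosen most recently before termination) receives `m3rd`; the other motor
#' receives `-xi * m3rd`. During non-reward steps both motors receive the
#' background `lambda`.
#'
#' @param m3rd Scalar third factor from [compute_m3rd()].
#' @param chosen_action 0-based index of the action to suppress.
#' @param mod A [modulation_state()].
#' @return Named numeric vector `c(motor_0, motor_1)`.
#' @export
deliver_modulation <- function(m3rd, chosen_action, mod) {
  stopifnot(chosen_action %in% c(0, 1))
  if (mod$R_step == 0) {
    out <- c(mod$lambda, mod$lambda)
  } else {
    out <- c(0, 0)
    out[chosen_action + 1] <- m3rd
    out[2 - chosen_action] <- -mod$xi * m3rd
  }
  names(out) <- c("motor_0", "motor_1")
  out
}

#' Fold an episode length into the episode-length EMA
#'
#' The first observed episode initializes `N_ema` directly; afterwards
#' `N_ema <- (1 - ema) * N_ema + ema * length`. The average is a convex
#' combination of observed lengths and therefore bounded by their range (and
#' by `[0, N_max]`).
#'
#' @param mod A [modulation_state()].
#' @param episode_length Episode length in environment steps.
#' @return The updated `modulation_state`.
#' @export
update_nema <- function(mod, episode_length) {
  stopifnot(episode_length >= 0, episode_length <= mod$N_max)
  if (mod$n_episodes == 0L) {
    mod$N_ema <- episode_length
  } else {
    mod$N_ema <- (1 - mod$ema) * mod$N_ema + mod$ema * episode_length
  }
  mod$n_episodes <- mod$n_episodes + 1L
  mod
}
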