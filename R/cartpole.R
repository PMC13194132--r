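# Self-contained cartpole environment.
#
# The classic pole-balancing task: a cart on a frictionless track with a
# rigid pole hinged on top; the agent pushes the cart left or right with a
# fixed force and must keep the pole within the angle limit and the cart
# within the track bounds. Dynamics follow the community-standard
# parameterization and are integrated by semi-implicit Euler (velocities
# first, then positions) at the environment step.

#' Cartpole parameters
#'
#' @param version `"v1"` (episode cap 500 steps) or `"v0"` (200 steps).
#' @param gravity Gravitational acceleration (m/s^2).
#' @param m_cart,m_pole Cart and pole masses (kg).
#' @param half_length Half the pole length (m).
#' @param force Magnitude of the applied force (N).
#' @param tau Environment step (s).
#' @param angle_limit Failure threshold on `|phi|` (rad).
#' @param x_limit Failure threshold on `|x|` (m).
#' @param N_max Episode cap; defaults from `version`.
#' @return An object of class `cartpole_params`.
#' @export
cartpole_params <- function(version = c("v1", "v0"), gravity = 9.8,
                            m_cart = 1.0, m_pole = 0.1, half_length = 0.5,
                            force = 10.0, tau = 0.02,
                            angle_limit = 12 * pi / 180, x_limit = 2.4,
                            N_max = NULL) {
  version <- match.arg(version)
  if (is.null(N_max)) N_max <- if (version == "v0") 200L else 500L
  stopifnot(gravity > 0, m_cart > 0, m_pole > 0, half_length > 0,
            force > 0, tau > 0, angle_limit > 0, x_limit > 0, N_max >= 1)
  structure(list(version = version, gravity = gravity, m_cart = m_cart,
                 m_pole = m_pole, half_length = half_length, force = force,
                 tau = tau, angle_limit = angle_limit, x_limit = x_limit,
                 N_max = as.integer(N_max)),
            class = "cartpole_params")
}

#' Reset the cartpole environment
#'
#' All four state variables are drawn `Uniform(-0.05, 0.05)`; flags clear.
#'
#' @param params A [cartpole_params()] object.
#' @param seed Optional integer seed for a reproducible reset.
#' @return An object of class `cartpole_state` with fields `x`, `x_dot`,
#'   `phi`, `phi_dot`, `step_count`, and flags `pole_fell`, `oob`,
#'   `truncated`, `done`.
#' @export
env_reset <- function(params, seed = NULL) {
  draw <- function() runif(4, -0.05, 0.05)
  s <- if (is.null(seed)) draw() else with_seed(seed, draw())
  structure(list(x = s[1], x_dot = s[2], phi = s[3], phi_dot = s[4],
                 step_count = 0L, pole_fell = FALSE, oob = FALSE,
                 truncated = FALSE, done = FALSE),
            class = "cartpole_state")
}

#' Observation vector of a cartpole state
#'
#' @param state A `cartpole_state`.
#' @return Numeric `c(x, x_dot, phi, phi_dot)`.
#' @export
env_observation <- function(state) {
  c(state$x, state$x_dot, state$phi, state$phi_dot)
}

#' Step the cartpole environment
#'
#' Applies the force for `action` (0 pushes left, 1 pushes right), integrates
#' the cart-pole equations of motion by semi-implicit Euler, advances the
#' step counter, and sets the termination flags: `pole_fell` when
#' `|phi| > angle_limit`, `oob` when `|x| > x_limit`, `truncated` when the
#' episode cap `N_max` is reached without failure.
#'
#' @param state A live (`!done`) `cartpole_state`.
#' @param action 0 (left) or 1 (right).
#' @param params A [cartpole_params()] object.
#' @return The updated `cartpole_state`.
#' @export
env_step <- function(state, action, params) {
  if (state$done) stop("env_step: episode already terminated", call. = FALSE)
  stopifnot(action %in% c(0, 1))
  p <- params
  f <- if (action == 1) p$force else -p$force
  total <- p$m_cart + p$m_pole
  pml <- p$m_pole * p$half_length
  sin_p <- sin(state$phi)
  cos_p <- cos(state$phi)
  temp <- (f + pml * state$phi_dot^2 * sin_p) / total
  phi_acc <- (p$gravity * sin_p - cos_p * temp) /
    (p$half_length * (4 / 3 - p$m_pole * cos_p^2 / total))
  x_acc <- temp - pml * phi_acc * cos_p / total
  state$x_dot <- state$x_dot + p$tau * x_acc
  state$x <- state$x + p$tau * state$x_dot
  state$phi_dot <- state$phi_dot + p$tau * phi_acc
  state$phi <- state$phi + p$tau * state$phi_dot
  state$step_count <- state$step_count + 1L
  state$pole_fell <- abs(state$phi) > p$angle_limit
  state$oob <- abs(state$x) > p$x_limit
  state$truncated <- !state$pole_fell && !state$oob &&
    state$step_count >= p$N_max
  state$done <- state$pole_fell || state$oob || state$truncated
  state
}
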