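# Online training loop: 50 ms interaction steps, sparse terminal reward,
# per-motor modulation delivery, the post-episode extra step, and frozen
# evaluation.
#
# During an episode the network runs with both motors at the background
# factor lambda (plasticity self-organizes without a reward). When an
# episode ends in failure (pole fell or cart out of bounds), one extra
# interaction is run on the final observation while the decaying third
# factor is delivered: the motor of the action chosen most recently before
# termination receives the (negative) M3rd, the other motor -xi * M3rd.
# Truncation at the episode cap is not a failure and triggers no extra step.
# The episode-length EMA is updated once per episode, after the extra step.

#' Run one cartpole episode
#'
#' @param agent A [cartpole_agent()].
#' @param env_params A [cartpole_params()] object.
#' @param env_seed Integer seed for the environment reset.
#' @param train If `TRUE`, plasticity runs (background `lambda` within the
#'   episode, decaying terminal modulation on failure, structural update at
#'   episode end); if `FALSE` the network is frozen (all updates disabled).
#' @param interaction_ms Hold duration per environment step (ms); must be a
#'   multiple of the agent's `dt`.
#' @param policy Optional function `(observation) -> action` bypassing the
#'   network entirely (the network is neither run nor updated); used for
#'   decoupled baselines.
#' @return A list: `agent` (updated), `length` (episode length in
#'   environment steps), `failed` (logical), `actions` (integer vector).
#' @export
run_episode <- function(agent, env_params = cartpole_params("v1"),
                        env_seed = NULL, train = TRUE, interaction_ms = 50,
                        policy = NULL) {
  n_ms <- as.integer(round(interaction_ms / agent$dt))
  stopifnot(isTRUE(all.equal(n_ms * agent$dt, interaction_ms)), n_ms >= 1)
  env <- env_reset(env_params, env_seed)
  use_net <- is.null(policy)
  if (use_net) engine_reset_integrator(agent$ptr)
  mod <- agent$mod
  lam <- if (train) mod$lambda else 0
  actions <- integer()
  repeat {
    obs <- env_observation(env)
    act <- if (use_net) {
      engine_interaction(agent$ptr, obs, n_ms, lam, lam,
                         plastic_on = train)$action
    } else {
      policy(obs)
    }
    actions <- c(actions, act)
    env <- env_step(env, act, env_params)
    if (env$done) break
  }
  mod$R_step <- compute_rstep(env)
  if (use_net && train && mod$R_step != 0 && mod$N_ema > 0) {
    tt <- (seq_len(n_ms) - 1) * agent$dt
    m <- (mod$N_ema / mod$N_max) * mod$R_step * exp(-mod$tau_R * tt)
    suppress <- actions[length(actions)]
    mod_a <- if (suppress == 0) m else -mod$xi * m
    mod_b <- if (suppress == 1) m else -mod$xi * m
    engine_interaction(agent$ptr, env_observation(env), n_ms,
                       mod_a, mod_b, plastic_on = TRUE)
  }
  mod <- update_nema(mod, env$step_count)
  agent$mod <- mod
  if (use_net && train) {
    agent <- agent_structural_update(
      agent, n_steps = (env$step_count + 1) * n_ms,
      seed = derive_seed(agent$seed, sprintf("structural%d",
                                             agent$episodes_trained)))
    agent$episodes_trained <- agent$episodes_trained + 1L
  }
  list(agent = agent, length = env$step_count,
       failed = mod$R_step != 0, actions = actions)
}

#' Train a cartpole agent online
#'
#' Runs `episodes` training episodes with the sparse terminal reward.
#'
#' @param agent A [cartpole_agent()].
#' @param episodes Number of training episodes.
#' @param seed Integer seed; episode `k` resets the environment with the
#'   stream `derive_seed(seed, k)`.
#' @param env_params A [cartpole_params()]; its `N_max` should match the
#'   agent's modulation state.
#' @param interaction_ms Hold duration (ms).
#' @param stop_at Optional early-stop rule: stop once an episode reaches
#'   `stop_at` steps.
#' @param verbose Print a line every 25 episodes.
#' @return An object of class `cartpole_training`: list with the updated
#'   `agent` and `log`, a tibble (episode, length, failed, n_ema).
#' @export
train_cartpole <- function(agent, episodes = 300, seed = 1,
                           env_params = cartpole_params("v1"),
                           interaction_ms = 50, stop_at = NULL,
                           verbose = FALSE) {
  agent$mod$N_max <- env_params$N_max
  log <- vector("list", episodes)
  done <- 0L
  for (k in seq_len(episodes)) {
    res <- run_episode(agent, env_params, env_seed = derive_seed(seed, k),
                       train = TRUE, interaction_ms = interaction_ms)
    agent <- res$agent
    log[[k]] <- tibble::tibble(episode = k, length = res$length,
                               failed = res$failed, n_ema = agent$mod$N_ema)
    done <- k
    if (verbose && k %% 25 == 0) {
      recent <- mean(vapply(log[max(1, k - 24):k], `[[`, 0, "length"))
      message(sprintf("episode %d: mean length (last 25) = %.1f, N_ema = %.1f",
                      k, recent, agent$mod$N_ema))
    }
    if (!is.null(stop_at) && res$length >= stop_at) break
  }
  structure(list(agent = agent, log = do.call(rbind, log[seq_len(done)])),
            class = "cartpole_training")
}

#' Train a cartpole agent until it solves the task
#'
#' The full training protocol with early stopping and candidate restarts.
#' Weight initialization is the only difference between two agents, and a
#' sizable fraction of initializations never stabilizes within the episode
#' budget, so the protocol trains candidate agents (seeds derived from
#' `seed`) sequentially, each for at most `max_episodes` episodes, stopping
#' as soon as an episode reaches the cap. A stopped candidate is validated
#' with a short frozen evaluation; a candidate whose validation mean falls
#' short resumes training until its budget is spent, and the first candidate
#' to pass is returned.
#'
#' @param seed Integer seed for the whole protocol.
#' @param bp Blueprint for the agents.
#' @param max_episodes Training-episode budget per candidate.
#' @param candidates Maximum number of candidate initializations.
#' @param validate_episodes,validate_mean Frozen-validation length and the
#'   mean episode length required to accept a stopped candidate.
#' @param env_params A [cartpole_params()] object.
#' @param mod_template A [modulation_state()] with the training constants.
#' @param verbose Print per-candidate progress.
#' @return A list: `agent` (the accepted, or last, candidate), `solved`
#'   (logical), `candidate` (index), `episodes` (episodes the accepted
#'   candidate trained), `log` (its episode log).
#' @export
solve_cartpole <- function(seed = 1, bp = cartpole_blueprint(),
                           max_episodes = 300, candidates = 6,
                           validate_episodes = 5, validate_mean = 300,
                           env_params = cartpole_params("v1"),
                           mod_template = modulation_state(),
                           verbose = FALSE) {
  last <- NULL
  for (ci in seq_len(candidates)) {
    aseed <- derive_seed(seed, sprintf("candidate%d", ci))
    agent <- cartpole_agent(bp, seed = aseed, mod = mod_template)
    log <- NULL
    budget <- max_episodes
    block <- 0L
    while (budget > 0) {
      fit <- train_cartpole(agent, episodes = budget,
                            seed = derive_seed(aseed, sprintf("train%d", block)),
                            env_params = env_params,
                            stop_at = env_params$N_max)
      agent <- fit$agent
      log <- rbind(log, fit$log)
      budget <- budget - nrow(fit$log)
      block <- block + 1L
      hit_cap <- fit$log$length[nrow(fit$log)] >= env_params$N_max
      if (!hit_cap) break
      val <- evaluate_frozen(agent, episodes = validate_episodes,
                             seed = derive_seed(aseed, "validate"),
                             env_params = env_params)
      if (verbose) {
        message(sprintf("candidate %d: cap reached after %d episodes; ",
                        ci, nrow(log)),
                sprintf("validation mean %.0f", mean(val$length)))
      }
      if (mean(val$length) >= validate_mean) {
        return(list(agent = agent, solved = TRUE, candidate = ci,
                    episodes = nrow(log), log = log))
      }
    }
    if (verbose) {
      message(sprintf("candidate %d did not stabilize in %d episodes",
                      ci, max_episodes))
    }
    last <- list(agent = agent, solved = FALSE, candidate = ci,
                 episodes = nrow(log), log = log)
  }
  last
}

#' Evaluate a frozen agent
#'
#' Runs test episodes with every plasticity update disabled (third factor
#' forced to zero, structural updates off): the weights are bit-identical
#' before and after, which is asserted. The engine's encoder stream is
#' reseeded from `seed`, so frozen evaluation is a pure function of
#' (weights, seed).
#'
#' @param agent A [cartpole_agent()].
#' @param episodes Number of test episodes.
#' @param seed Integer seed.
#' @param env_params A [cartpole_params()].
#' @param interaction_ms Hold duration (ms).
#' @return A tibble (episode, length, failed) with the updated agent in
#'   attribute `"agent"`.
#' @export
evaluate_frozen <- function(agent, episodes = 50, seed = 1,
                            env_params = cartpole_params("v1"),
                            interaction_ms = 50) {
  hash_before <- agent_weight_hash(agent)
  engine_set_rng(agent$ptr, derive_seed(seed, "eval-rng"))
  log <- vector("list", episodes)
  for (k in seq_len(episodes)) {
    res <- run_episode(agent, env_params,
                       env_seed = derive_seed(seed, paste0("eval", k)),
                       train = FALSE, interaction_ms = interaction_ms)
    agent <- res$agent
    log[[k]] <- tibble::tibble(episode = k, length = res$length,
                               failed = res$failed)
  }
  if (!identical(agent_weight_hash(agent), hash_before)) {
    stop("evaluate_frozen: weights changed during frozen evaluation",
         call. = FALSE)
  }
  out <- do.call(rbind, log)
  attr(out, "agent") <- agent
  out
}

#' @export
print.cartpole_training <- function(x, ...) {
  n <- nrow(x$log)
  cat("<cartpole_training> ", n, " episodes\n", sep = "")
  last <- x$log$length[max(1, n - 9):n]
  cat("  mean length (last 10): ", round(mean(last), 1),
      "; best: ", max(x$log$length), "\n", sep = "")
  invisible(x)
}

#' Tidy a training run
#'
#' @param x A `cartpole_training`.
#' @param ... Unused.
#' @return The per-episode log tibble.
#' @method tidy cartpole_training
#' @export
tidy.cartpole_training <- function(x, ...) x$log

#' @rdname tidy.cartpole_training
#' @method glance cartpole_training
#' @export
glance.cartpole_training <- function(x, ...) {
  n <- nrow(x$log)
  tibble::tibble(
    episodes = n,
    mean_length = mean(x$log$length),
    mean_length_last10 = mean(x$log$length[max(1, n - 9):n]),
    best_length = max(x$log$length),
    first_max = if (any(x$log$length >= x$agent$mod$N_max)) {
      min(x$log$episode[x$log$length >= x$agent$mod$N_max])
    } else NA_integer_,
    n_ema = x$agent$mod$N_ema
  )
}

#' @rdname tidy.cartpole_training
#' @param object A `cartpole_training`.
#' @method autoplot cartpole_training
#' @export
autoplot.cartpole_training <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$episode,
                                           y = .data$length)) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(ggplot2::aes(color = .data$failed), size = 0.8) +
    ggplot2::labs(x = "episode", y = "episode length (env steps)",
                  title = "Cartpole training trajectory")
}
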