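# Cartpole agent: the performant executable instantiation of the
# mutual-inhibition blueprint.
#
# The agent wraps a compiled engine whose step semantics match the generic
# graph executor on the same blueprint (same execution order, one-step
# latency on back edges, identical soma/synapse/trace arithmetic); weights
# and delays are initialized in R from the same per-node seeded streams that
# build_model() uses, so the two instantiations share their initial state
# exactly.

#' Build a cartpole agent from a blueprint
#'
#' @param bp A [cartpole_blueprint()] (or a structurally compatible
#'   blueprint: one spiker, LIF pools, synapse groups, one 2-trace
#'   integrator).
#' @param dt Network integration step (ms).
#' @param seed Integer seed: per-node streams for weights/delays and the
#'   engine's encoder stream derive from it.
#' @param mod A [modulation_state()] carrying the training constants
#'   (lambda, xi, tau_R, EMA coefficient, N_max).
#' @return An object of class `cartpole_agent`. The compiled network state
#'   lives behind an external pointer: functions that advance the agent
#'   return the updated object, which must be kept.
#' @export
cartpole_agent <- function(bp = cartpole_blueprint(), dt = 1, seed = 1,
                           mod = modulation_state()) {
  validate_blueprint(bp)
  ids <- vapply(bp$nodes, `[[`, "", "id")
  kinds <- vapply(bp$nodes, `[[`, "", "kind")
  nodes <- stats::setNames(bp$nodes, ids)
  spiker_id <- ids[kinds == "spiker"]
  integ_id <- ids[kinds == "integrator"]
  pool_ids <- sort(ids[kinds == "lif_pool"])
  syn_ids <- sort(ids[kinds == "synapse"])
  stopifnot(length(spiker_id) == 1, length(integ_id) == 1,
            length(pool_ids) >= 2, length(syn_ids) >= 1)
  scfg <- .spiker_cfg(nodes[[spiker_id]]$params)

  edge_match <- function(f) Filter(f, bp$edges)
  pre_of <- function(sid) {
    e <- edge_match(function(e) e$to == sid && e$to_port == "pre")
    stopifnot(length(e) == 1)
    e[[1]]$from
  }
  post_of <- function(sid) {
    e <- edge_match(function(e) e$from == sid && e$from_port == "I_out")
    stopifnot(length(e) == 1)
    e[[1]]$to
  }
  integ_pool <- function(port) {
    e <- edge_match(function(e) e$to == integ_id && e$to_port == port)
    stopifnot(length(e) == 1)
    match(e[[1]]$from, pool_ids) - 1L
  }
  integ_pools <- c(integ_pool("pool_0"), integ_pool("pool_1"))

  pools_cfg <- lapply(pool_ids, function(pid) {
    p <- .soma_params_from("lif_pool", nodes[[pid]]$params)
    c(list(n = nodes[[pid]]$params$n), unclass(p))
  })

  groups_meta <- list()
  groups_cfg <- lapply(seq_along(syn_ids), function(k) {
    sid <- syn_ids[k]
    params <- nodes[[sid]]$params
    sp <- .synapse_params_from(params)
    st <- synapse_init(sp, dt, derive_seed(seed, sid))
    pre <- pre_of(sid)
    post <- post_of(sid)
    pre_idx <- if (pre == spiker_id) -1L else match(pre, pool_ids) - 1L
    post_idx <- match(post, pool_ids) - 1L
    plastic <- !is.null(params$plasticity)
    channel <- 0L
    if (plastic) {
      channel <- if (post_idx == integ_pools[1]) 1L
                 else if (post_idx == integ_pools[2]) 2L else 0L
    }
    plas <- if (plastic) .plasticity_params_from(params$plasticity, sp$sign)
    groups_meta[[sid]] <<- list(
      index = k - 1L, plastic = plastic, channel = channel,
      plasticity = plas, sign = sp$sign,
      allowed = if (sp$n_pre == sp$n_post && !sp$self_connections) {
        1 - diag(sp$n_pre)
      } else NULL)
    cfgg <- list(name = sid, pre = pre_idx, post = post_idx,
                 W = st$W, mask = st$mask, D = st$D, tau_s = sp$tau_s,
                 sign = sp$sign, plastic = plastic, channel = channel)
    if (plastic) {
      cfgg <- c(cfgg, plas[c("eta", "alpha", "beta", "gamma", "delta",
                             "tau_pre", "tau_post", "w_min", "w_max")])
    }
    cfgg
  })

  inode <- nodes[[integ_id]]$params
  cfg <- list(
    dt = dt, seed = derive_seed(seed, "engine"),
    spiker = list(dims = scfg$dims, n_units = scfg$n_units,
                  rate_max = scfg$rate_max,
                  lo = scfg$ranges[1, ], hi = scfg$ranges[2, ],
                  sigma = scfg$sigma),
    pools = pools_cfg,
    groups = groups_cfg,
    integrator = list(tau_out = inode$tau_out %||% 25,
                      gain = inode$gain %||% 0.3,
                      pools = integ_pools)
  )
  structure(list(blueprint = bp, dt = dt, seed = seed,
                 ptr = engine_create(cfg), cfg = cfg,
                 spiker = scfg, mod = mod,
                 pool_ids = pool_ids, syn_ids = syn_ids,
                 groups_meta = groups_meta,
                 episodes_trained = 0L),
            class = "cartpole_agent")
}

#' Weight matrices of an agent
#'
#' @param agent A [cartpole_agent()].
#' @return Named list (by synapse node id) of lists `W`, `mask`, `D`.
#' @export
agent_weights <- function(agent) {
  out <- lapply(seq_along(agent$syn_ids) - 1L,
                function(g) engine_get_group(agent$ptr, g))
  stats::setNames(out, agent$syn_ids)
}

# Stable digest of all weights (sum-free: serializes the numbers).
agent_weight_hash <- function(agent) {
  w <- agent_weights(agent)
  paste(vapply(w, function(g) {
    paste0(format(sum(g$W * (seq_along(g$W) %% 97)), digits = 17), ":",
           sum(g$mask))
  }, ""), collapse = "|")
}

# Apply structural plasticity to every plastic group (called once per
# training episode; the per-step growth probability is compounded over the
# episode's network steps). New connections draw a delay uniform over the
# group's existing delay range.
agent_structural_update <- function(agent, n_steps, seed) {
  for (sid in agent$syn_ids) {
    meta <- agent$groups_meta[[sid]]
    if (!meta$plastic) next
    pp <- meta$plasticity
    if (pp$prune_eps <= 0 && pp$growth_prob <= 0) next
    g <- engine_get_group(agent$ptr, meta$index)
    p_eff <- 1 - (1 - pp$growth_prob)^n_steps
    pp_eff <- pp
    pp_eff$growth_prob <- p_eff
    res <- structural_update(g$W, g$mask, pp_eff,
                             seed = derive_seed(seed, sid),
                             allowed = meta$allowed)
    new <- res$mask == 1 & g$mask == 0
    if (any(new)) {
      dmax <- max(g$D)
      g$D[new] <- with_seed(derive_seed(seed, paste0(sid, ":d")),
                            sample.int(dmax, sum(new), replace = TRUE))
    }
    engine_set_group(agent$ptr, meta$index, res$W, res$mask, g$D)
  }
  agent
}

#' Snapshot an agent's learned parameters
#'
#' Captures weights, masks, delays, the modulation state and the episode
#' counter (dynamic neural state is transient and not captured).
#'
#' @param agent A [cartpole_agent()].
#' @return A plain list snapshot, serializable with [saveRDS()] or JSON.
#' @export
agent_snapshot <- function(agent) {
  list(weights = agent_weights(agent), mod = unclass(agent$mod),
       episodes_trained = agent$episodes_trained, seed = agent$seed)
}

#' Restore a snapshot into a freshly built agent
#'
#' @param agent A [cartpole_agent()] built from the same blueprint.
#' @param snapshot A list from [agent_snapshot()].
#' @return The agent with weights, modulation state and episode counter
#'   restored.
#' @export
agent_restore <- function(agent, snapshot) {
  for (sid in names(snapshot$weights)) {
    g <- snapshot$weights[[sid]]
    engine_set_group(agent$ptr, agent$groups_meta[[sid]]$index,
                     g$W, g$mask, g$D)
  }
  agent$mod <- structure(snapshot$mod, class = "modulation_state")
  agent$episodes_trained <- snapshot$episodes_trained
  agent
}

#' @export
print.cartpole_agent <- function(x, ...) {
  cat("<cartpole_agent>\n")
  cat("  pools:", paste(x$pool_ids, collapse = ", "), "\n")
  cat("  synapse groups:", length(x$syn_ids), "\n")
  cat("  episodes trained:", x$episodes_trained,
      " N_ema:", round(x$mod$N_ema, 1), "\n")
  invisible(x)
}

#' @method glance cartpole_agent
#' @export
glance.cartpole_agent <- function(x, ...) {
  w <- agent_weights(x)
  tibble::tibble(
    episodes_trained = x$episodes_trained,
    n_ema = x$mod$N_ema,
    n_groups = length(x$syn_ids),
    n_connections = sum(vapply(w, function(g) sum(g$mask), 0)),
    mean_abs_weight = mean(unlist(lapply(w, function(g) abs(g$W[g$mask == 1]))))
  )
}
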