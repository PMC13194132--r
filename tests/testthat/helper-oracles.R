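# Independent oracles and small fixtures used across the suite.

# ---- spike-distance oracles -------------------------------------------
# Naive pointwise profile evaluators, independent of the package's exact
# segment integration: every quantity is recomputed per time point by direct
# search over the (auxiliary-augmented) spike lists. Evaluating at segment
# midpoints and weighting by exact segment lengths integrates the
# piecewise-constant ISI profile and the piecewise-linear SPIKE profile
# exactly.

aug_times <- function(st) {
  t <- st$times
  if (!length(t) || t[1] > 0) t <- c(0, t)
  if (t[length(t)] < st$duration) t <- c(t, st$duration)
  t
}

profile_points <- function(a, b) {
  ev <- sort(unique(c(aug_times(a), aug_times(b))))
  left <- ev[-length(ev)]; right <- ev[-1]
  keep <- right > left
  list(mid = (left + right)[keep] / 2, len = (right - left)[keep])
}

oracle_isi_profile_at <- function(t, ta, tb) {
  isi_at <- function(t, tt) {
    i <- max(which(tt <= t))
    if (i >= length(tt)) i <- length(tt) - 1
    tt[i + 1] - tt[i]
  }
  ia <- isi_at(t, ta); ib <- isi_at(t, tb)
  abs(ia - ib) / max(ia, ib)
}

oracle_isi_distance <- function(a, b) {
  ta <- aug_times(a); tb <- aug_times(b)
  p <- profile_points(a, b)
  vals <- vapply(p$mid, oracle_isi_profile_at, 0, ta = ta, tb = tb)
  sum(vals * p$len) / a$duration
}

oracle_spike_profile_at <- function(t, ta, tb) {
  side <- function(t, tt, other) {
    i <- max(which(tt <= t))
    if (i >= length(tt)) i <- length(tt) - 1
    tP <- tt[i]; tF <- tt[i + 1]
    dP <- min(abs(tP - other)); dF <- min(abs(tF - other))
    xisi <- tF - tP
    S <- (dP * (tF - t) + dF * (t - tP)) / xisi
    c(S = S, xisi = xisi)
  }
  sa <- side(t, ta, tb); sb <- side(t, tb, ta)
  (sa["S"] * sb["xisi"] + sb["S"] * sa["xisi"]) /
    (2 * ((sa["xisi"] + sb["xisi"]) / 2)^2)
}

oracle_spike_distance <- function(a, b) {
  ta <- aug_times(a); tb <- aug_times(b)
  p <- profile_points(a, b)
  vals <- vapply(p$mid, function(t) {
    unname(oracle_spike_profile_at(t, ta, tb))
  }, 0)
  sum(vals * p$len) / a$duration
}

# ---- scalar three-factor STDP replay ----------------------------------
# Per-connection scalar reimplementation of the full synapse + trace +
# weight-update pipeline over a recorded spike sequence. `pre_raster` and
# `post_raster` are (units x steps) 0/1 matrices of the streams the group
# consumed; `m3rd` is the per-step third factor.
scalar_stdp_replay <- function(W0, mask, D, pre_raster, post_raster, m3rd,
                               params, dt) {
  n_steps <- ncol(pre_raster)
  W <- W0
  dec_pre <- exp(-dt / params$tau_pre)
  dec_post <- exp(-dt / params$tau_post)
  lo <- if (params$sign > 0) params$w_min else -params$w_max
  hi <- if (params$sign > 0) params$w_max else -params$w_min
  for (j in seq_len(nrow(W0))) {
    for (i in seq_len(ncol(W0))) {
      if (mask[j, i] == 0) next
      w <- W0[j, i]; xpre <- 0; xpost <- 0
      d <- D[j, i]
      for (t in seq_len(n_steps)) {
        arr <- if (t - d >= 1) pre_raster[j, t - d] else 0
        xpre <- xpre * dec_pre + arr
        xpost <- xpost * dec_post + post_raster[i, t]
        m <- m3rd[t]
        if (m != 0) {
          w <- w + params$eta * m * dt *
            (post_raster[i, t] * (params$alpha + params$beta * xpre) +
               arr * (params$gamma + params$delta * xpost))
          w <- min(max(w, lo), hi)
        }
      }
      W[j, i] <- w
    }
  }
  W
}

# ---- scalar cartpole physics ------------------------------------------
# Independent transcription of the cart-pole equations of motion with
# semi-implicit Euler, operating on bare numbers.
oracle_cartpole_step <- function(x, x_dot, phi, phi_dot, force,
                                 g = 9.8, mc = 1.0, mp = 0.1, l = 0.5,
                                 tau = 0.02) {
  total <- mc + mp
  temp <- (force + mp * l * phi_dot^2 * sin(phi)) / total
  phi_acc <- (g * sin(phi) - cos(phi) * temp) /
    (l * (4 / 3 - mp * cos(phi)^2 / total))
  x_acc <- temp - mp * l * phi_acc * cos(phi) / total
  x_dot2 <- x_dot + tau * x_acc
  x2 <- x + tau * x_dot2
  phi_dot2 <- phi_dot + tau * phi_acc
  phi2 <- phi + tau * phi_dot2
  c(x = x2, x_dot = x_dot2, phi = phi2, phi_dot = phi_dot2)
}

# Total mechanical energy of the cart-pole (rod pole of length 2*l pivoted
# at the cart, uniform density: I_com = mp * l^2 / 3).
cartpole_energy <- function(s, g = 9.8, mc = 1.0, mp = 0.1, l = 0.5) {
  ke_cart <- 0.5 * mc * s$x_dot^2
  vx <- s$x_dot + l * s$phi_dot * cos(s$phi)
  vy <- -l * s$phi_dot * sin(s$phi)
  ke_pole <- 0.5 * mp * (vx^2 + vy^2) + 0.5 * (mp * l^2 / 3) * s$phi_dot^2
  pe <- mp * g * l * cos(s$phi)
  ke_cart + ke_pole + pe
}

# ---- small blueprints --------------------------------------------------

tiny_cartpole_bp <- function(...) {
  cartpole_blueprint(n_exc = 8, n_inh = 4, n_per_dim = 4, ...)
}

# Twin of a spiker-driven blueprint with the spiker replaced by a raw input
# node, so the identical spike raster can be injected into the generic
# executor and the compiled engine.
input_twin_bp <- function(bp) {
  nodes <- lapply(bp$nodes, function(nd) {
    if (nd$kind == "spiker") {
      cfg <- snnkit:::.spiker_cfg(nd$params)
      bp_node(nd$id, "input", list(n = cfg$dims * cfg$n_units))
    } else {
      nd
    }
  })
  blueprint(nodes, bp$edges, bp$metadata)
}

# Minimal two-node model: external input -> synapse -> LIF pool.
two_node_bp <- function(n_in = 3, n_out = 2, w_max = 20, density = 1,
                        tau_s = 5, d_max = 3, plasticity = NULL) {
  blueprint(
    nodes = list(
      bp_node("in", "input", list(n = n_in)),
      bp_node("syn", "synapse",
              list(n_pre = n_in, n_post = n_out, tau_s = tau_s,
                   density = density, w_max = w_max, w_min = 0, sign = 1,
                   d_max = d_max, self_connections = TRUE,
                   plasticity = plasticity)),
      bp_node("pool", "lif_pool", list(n = n_out))
    ),
    edges = c(list(
      bp_edge("in", "out", "syn", "pre"),
      bp_edge("syn", "I_out", "pool", "I_in")),
      if (!is.null(plasticity)) list(bp_edge("pool", "out", "syn", "post"))
    )
  )
}

random_train <- function(n, duration, seed) {
  make_fixture("poisson_train", list(rate = n / duration, duration = duration),
               seed = seed)
}
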