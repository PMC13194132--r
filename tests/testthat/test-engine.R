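# The compiled agent engine against the generic executor and the scalar
# plasticity oracle, on an identical injected spike raster.

make_pair <- function(seed = 3, ...) {
  bp <- tiny_cartpole_bp(...)
  agent <- cartpole_agent(bp, dt = 1, seed = seed)
  model <- build_model(input_twin_bp(bp), dt = 1, seed = seed)
  list(agent = agent, model = model)
}

n_in_of <- function(agent) agent$spiker$dims * agent$spiker$n_units

test_that("engine and generic executor share their initial weights", {
  pr <- make_pair(seed = 11)
  w <- agent_weights(pr$agent)
  for (sid in names(w)) {
    expect_identical(w[[sid]]$W, pr$model$comps[[sid]]$syn$W)
    expect_identical(w[[sid]]$D, pr$model$comps[[sid]]$syn$D)
  }
})

test_that("frozen dynamics match the generic executor step for step", {
  pr <- make_pair(seed = 3, w_in = 6)
  n_in <- n_in_of(pr$agent)
  raster <- make_fixture("random_raster",
                         list(n_units = n_in, n_steps = 200, p = 0.25),
                         seed = 5)
  eng <- snnkit:::engine_interaction_spikes(pr$agent$ptr, raster, 0, 0,
                                            plastic_on = FALSE, record = TRUE)
  ex <- run_model(pr$model, 200, function(k) list(spiker = raster[, k + 1]),
                  record = c("exc_a", "exc_b", "inh_a", "inh_b"))
  for (pi in seq_along(pr$agent$pool_ids)) {
    pid <- pr$agent$pool_ids[pi]
    expect_identical(t(eng$pool_spikes[[pi]]), unname(ex$recorded[[pid]]),
                     info = pid)
  }
  expect_gt(sum(eng$pool_spikes[[1]]), 0)  # the comparison sees real spikes
  expect_equal(eng$y, unname(ex$model$outs$out$y), tolerance = 1e-9)
})

test_that("plastic dynamics and weights match the generic executor", {
  pr <- make_pair(seed = 9, w_in = 6, rec_plastic = TRUE, w_clip_in = 50,
                  w_clip_rec = 50, eta = 0.05)
  n_in <- n_in_of(pr$agent)
  raster <- make_fixture("random_raster",
                         list(n_units = n_in, n_steps = 150, p = 0.3),
                         seed = 6)
  m_a <- 0.02  # motor-A channel modulation, constant over the window
  m_b <- -0.015
  eng <- snnkit:::engine_interaction_spikes(pr$agent$ptr, raster, m_a, m_b,
                                            plastic_on = TRUE, record = TRUE)
  modmap <- list(syn_in_a = m_a, syn_rec_a = m_a,
                 syn_in_b = m_b, syn_rec_b = m_b)
  ex <- run_model(pr$model, 150, function(k) list(spiker = raster[, k + 1]),
                  modulation = modmap,
                  record = c("exc_a", "exc_b"))
  for (pi in 1:2) {
    pid <- pr$agent$pool_ids[pi]
    expect_identical(t(eng$pool_spikes[[pi]]), unname(ex$recorded[[pid]]),
                     info = pid)
  }
  w_eng <- agent_weights(pr$agent)
  for (sid in c("syn_in_a", "syn_in_b", "syn_rec_a", "syn_rec_b")) {
    expect_lt(max(abs(w_eng[[sid]]$W - ex$model$comps[[sid]]$syn$W)), 1e-9)
  }
  # weights actually moved
  expect_gt(max(abs(w_eng$syn_in_a$W - make_pair(seed = 9, w_in = 6,
    rec_plastic = TRUE, w_clip_in = 50, w_clip_rec = 50,
    eta = 0.05)$model$comps$syn_in_a$syn$W)), 0)
})

test_that("engine plasticity replays through the scalar oracle", {
  pr <- make_pair(seed = 21, w_in = 6, w_clip_in = 50, eta = 0.05)
  agent <- pr$agent
  n_in <- n_in_of(agent)
  w0 <- agent_weights(agent)
  raster <- make_fixture("random_raster",
                         list(n_units = n_in, n_steps = 120, p = 0.3),
                         seed = 7)
  m_a <- rep(c(1e-3, -0.3), each = 60)
  m_b <- rep(1e-3, 120)
  eng <- snnkit:::engine_interaction_spikes(agent$ptr, raster, m_a, m_b,
                                            plastic_on = TRUE, record = TRUE)
  w1 <- agent_weights(agent)
  # replay: group pre stream is the injected raster; its post stream is the
  # post pool's spikes lagged one step (back-edge latency)
  lag <- function(S) cbind(0, S[, -ncol(S), drop = FALSE])
  for (sid in c("syn_in_a", "syn_in_b")) {
    meta <- agent$groups_meta[[sid]]
    post_pool <- if (meta$channel == 1) 1 else 2
    post <- lag(eng$pool_spikes[[post_pool]])
    m <- if (meta$channel == 1) m_a else m_b
    W_oracle <- scalar_stdp_replay(w0[[sid]]$W, w0[[sid]]$mask, w0[[sid]]$D,
                                   raster, post, m, meta$plasticity, dt = 1)
    expect_lt(max(abs(w1[[sid]]$W - W_oracle)), 1e-9)
  }
})

test_that("engine runs are deterministic and seed-sensitive", {
  run_once <- function(seed) {
    a <- cartpole_agent(tiny_cartpole_bp(), seed = seed)
    fit <- train_cartpole(a, episodes = 3, seed = 1,
                          env_params = cartpole_params(N_max = 50))
    list(log = fit$log$length, w = agent_weights(fit$agent)$syn_in_a$W)
  }
  r1 <- run_once(5)
  r2 <- run_once(5)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$w, r2$w)
  r3 <- run_once(6)
  expect_false(identical(r1$w, r3$w))
})
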