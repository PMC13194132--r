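# Three-factor STDP: trace dynamics, gating, hand-evaluated updates, the
# scalar replay oracle, bounds, sign preservation, structural updates.

test_that("traces decay exponentially and superpose", {
  p <- plasticity_params(tau_pre = 20, tau_post = 30)
  tr <- traces_init(1, 1)
  # single pre spike at step 1
  tr <- update_traces(tr, 1, 0, p, dt = 1)
  vals <- numeric(20)
  vals[1] <- tr$x_pre[1, 1]
  for (k in 2:20) {
    tr <- update_traces(tr, 0, 0, p, dt = 1)
    vals[k] <- tr$x_pre[1, 1]
  }
  expect_equal(vals, exp(-(0:19) / 20), tolerance = 1e-12)
  # a second spike delta = 5 later lands on the decayed first one
  tr2 <- traces_init(1, 1)
  tr2 <- update_traces(tr2, 1, 0, p, dt = 1)
  for (k in 1:4) tr2 <- update_traces(tr2, 0, 0, p, dt = 1)
  tr2 <- update_traces(tr2, 1, 0, p, dt = 1)
  expect_equal(tr2$x_pre[1, 1], 1 + exp(-5 / 20), tolerance = 1e-12)
  # post trace uses its own constant
  tr3 <- traces_init(1, 1)
  tr3 <- update_traces(tr3, 0, 1, p, dt = 1)
  tr3 <- update_traces(tr3, 0, 0, p, dt = 1)
  expect_equal(tr3$x_post[1, 1], exp(-1 / 30), tolerance = 1e-12)
})

test_that("M3rd = 0 and spike-free steps leave weights exactly unchanged", {
  p <- plasticity_params(eta = 0.5)
  W <- matrix(runif(12), 3, 4)
  mask <- matrix(1, 3, 4)
  tr <- traces_init(3, 4)
  tr$x_pre[] <- 0.5
  tr$x_post[] <- 0.3
  expect_identical(stdp_update(W, mask, tr, rep(1, 3), rep(1, 4), 0, p, 1), W)
  expect_equal(stdp_update(W, mask, tr, rep(0, 3), rep(0, 4), 0.7, p, 1), W,
               tolerance = 1e-15)
})

test_that("a coincident pre/post pair matches the hand-evaluated formula", {
  p <- plasticity_params(eta = 0.2, alpha = -0.1, beta = 1, gamma = 1,
                         delta = -0.1, w_min = 0, w_max = 10)
  W <- matrix(2, 1, 1)
  mask <- matrix(1, 1, 1)
  tr <- traces_init(1, 1)
  tr <- update_traces(tr, 1, 1, p, dt = 1)  # both traces now 1
  W2 <- stdp_update(W, mask, tr, 1, 1, m3rd = -0.5, p, dt = 1)
  dw_hand <- 0.2 * (-0.5) * (1 * (-0.1 + 1 * 1) + 1 * (1 + (-0.1) * 1)) * 1
  expect_equal(W2[1, 1], 2 + dw_hand, tolerance = 1e-12)
})

test_that("vectorized update equals the per-connection scalar replay", {
  # random 10-unit networks, 1000 steps, modulation switching sign
  for (net in 1:3) {
    n <- 10
    p <- plasticity_params(eta = 0.05, tau_pre = 15, tau_post = 25,
                           w_min = 0, w_max = 50)
    init <- init_weights(n, n, density = 0.6, w_max = 1, seed = 100 + net,
                         self_connections = TRUE)
    D <- init_delays(n, n, d_max = 5, dt = 1, seed = 200 + net)
    pre <- make_fixture("random_raster",
                        list(n_units = n, n_steps = 1000, p = 0.08),
                        seed = 300 + net)
    post <- make_fixture("random_raster",
                         list(n_units = n, n_steps = 1000, p = 0.08),
                         seed = 400 + net)
    m3rd <- rep(c(1e-3, -0.4, 0, 0.2), length.out = 1000)

    # vectorized path: per-connection arrival matrix from the delay table
    W <- init$W
    tr <- traces_init(n, n)
    for (t in 1:1000) {
      arr <- matrix(0, n, n)
      for (d in unique(as.vector(D))) {
        if (t - d >= 1) arr[D == d] <- pre[, t - d][row(D)[D == d]]
      }
      tr <- update_traces(tr, arr, post[, t], p, dt = 1)
      W <- stdp_update(W, init$mask, tr, arr, post[, t], m3rd[t], p, dt = 1)
    }
    W_oracle <- scalar_stdp_replay(init$W, init$mask, D, pre, post, m3rd, p,
                                   dt = 1)
    expect_lt(max(abs(W - W_oracle)), 1e-6)
  }
})

test_that("weights stay inside bounds and never change sign", {
  p_exc <- plasticity_params(eta = 5, w_min = 0, w_max = 1, sign = 1)
  p_inh <- plasticity_params(eta = 5, w_min = 0, w_max = 1, sign = -1)
  for (rep in 1:5) {
    initE <- init_weights(6, 6, 0.7, 1, sign = 1, seed = rep,
                          self_connections = TRUE)
    initI <- init_weights(6, 6, 0.7, 1, sign = -1, seed = rep,
                          self_connections = TRUE)
    WE <- initE$W; WI <- initI$W
    trE <- traces_init(6, 6); trI <- traces_init(6, 6)
    for (t in 1:100) {
      pre <- as.numeric(runif(6) < 0.3)
      post <- as.numeric(runif(6) < 0.3)
      m <- runif(1, -1, 1)
      trE <- update_traces(trE, pre, post, p_exc, 1)
      trI <- update_traces(trI, pre, post, p_inh, 1)
      WE <- stdp_update(WE, initE$mask, trE, pre, post, m, p_exc, 1)
      WI <- stdp_update(WI, initI$mask, trI, pre, post, m, p_inh, 1)
      expect_true(all(WE >= 0 & WE <= 1))
      expect_true(all(WI <= 0 & WI >= -1))
    }
  }
})

test_that("structural update prunes, grows, and respects determinism", {
  p_id <- plasticity_params(prune_eps = 0, growth_prob = 0)
  W <- matrix(c(0.001, 0.5, 0, 0), 2, 2)
  mask <- matrix(c(1, 1, 0, 0), 2, 2)
  expect_identical(structural_update(W, mask, p_id, seed = 1),
                   list(W = W, mask = mask))

  p_prune <- plasticity_params(prune_eps = 0.01, growth_prob = 0)
  res <- structural_update(W, mask, p_prune, seed = 1)
  expect_equal(res$mask, matrix(c(0, 1, 0, 0), 2, 2))
  expect_equal(res$W[1, 1], 0)

  # all weights below threshold -> empty mask
  res2 <- structural_update(matrix(1e-4, 3, 3), matrix(1, 3, 3),
                            plasticity_params(prune_eps = 0.01), seed = 1)
  expect_equal(sum(res2$mask), 0)

  # growth on an empty 100x100 mask: count within 3 binomial sigmas
  p_grow <- plasticity_params(growth_prob = 0.01, growth_w = 0.2)
  res3 <- structural_update(matrix(0, 100, 100), matrix(0, 100, 100),
                            p_grow, seed = 7)
  n_new <- sum(res3$mask)
  expect_lt(abs(n_new - 100), 3 * sqrt(1e4 * 0.01 * 0.99))
  expect_true(all(res3$W[res3$mask == 1] == 0.2))
  expect_identical(res3, structural_update(matrix(0, 100, 100),
                                           matrix(0, 100, 100), p_grow,
                                           seed = 7))
  # disallowed entries never grow
  allowed <- matrix(1, 50, 50); allowed[1, ] <- 0
  res4 <- structural_update(matrix(0, 50, 50), matrix(0, 50, 50),
                            plasticity_params(growth_prob = 0.5),
                            seed = 3, allowed = allowed)
  expect_true(all(res4$mask[1, ] == 0))
})
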