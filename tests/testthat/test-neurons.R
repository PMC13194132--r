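# Soma models: fixed points, closed-form subthreshold dynamics, refractory
# and threshold-adaptation contracts, fine-dt reference agreement, and
# R-vs-compiled stepper equivalence.

run_lif <- function(n_steps, I, params = lif_params(), dt = 1, n = 1) {
  st <- lif_init(n, params)
  v <- matrix(NA_real_, n_steps, n)
  S <- matrix(NA_real_, n_steps, n)
  for (k in seq_len(n_steps)) {
    st <- lif_step(st, rep(I, length.out = n), params, dt)
    v[k, ] <- st$v
    S[k, ] <- st$S
  }
  list(v = v, S = S, state = st)
}

test_that("rest is a fixed point of the LIF", {
  out <- run_lif(50, I = 0)
  expect_true(all(out$v == lif_params()$v_rest))
  expect_true(all(out$S == 0))
})

test_that("subthreshold LIF tracks the closed-form exponential", {
  p <- lif_params(a = 0)  # no adaptation
  I0 <- 10  # v_inf = -55, below threshold
  out <- run_lif(200, I = I0, params = p, dt = 1)
  t <- 1:200
  closed <- p$v_rest + p$R * I0 * (1 - exp(-t / p$tau_m))
  # forward-Euler input term biases the discrete fixed point by O(dt/tau)
  expect_lt(max(abs(out$v[, 1] - closed)), p$R * I0 * 0.03)
  # halving dt shrinks the endpoint error (first-order input term)
  err_at <- function(dt) {
    n <- round(100 / dt)
    o <- run_lif(n, I = I0, params = p, dt = dt)
    abs(o$v[n, 1] - (p$v_rest + p$R * I0 * (1 - exp(-100 / p$tau_m))))
  }
  e1 <- err_at(1); e05 <- err_at(0.5); e025 <- err_at(0.25)
  expect_lt(e05, e1)
  expect_lt(e025, e05)
})

test_that("disabling adaptation pins the threshold at base", {
  p <- lif_params(a = 0)
  st <- lif_init(1, p)
  for (k in 1:100) {
    st <- lif_step(st, 30, p, 1)
    expect_equal(st$theta, p$theta_base)
  }
})

test_that("threshold stays >= base, decays monotonically between spikes", {
  p <- lif_params()
  st <- lif_init(3, p)
  drive <- make_fixture("ou_trace",
                        list(n_steps = 400, mean = 20, sigma = 8, dt = 1),
                        seed = 4)
  th_prev <- st$theta
  for (k in 1:400) {
    st <- lif_step(st, rep(drive[k], 3), p, 1)
    expect_true(all(st$theta >= p$theta_base - 1e-12))
    no_spike <- st$S == 0
    expect_true(all(st$theta[no_spike] <= th_prev[no_spike] + 1e-12))
    th_prev <- st$theta
  }
})

test_that("input is gated off for r_spike ms after a spike", {
  p <- lif_params(a = 0)
  # drive to a spike, then compare with-input vs zero-input trajectories
  st <- lif_init(1, p)
  repeat {
    st <- lif_step(st, 40, p, 1)
    if (st$S == 1) break
  }
  st_a <- st; st_b <- st
  for (k in seq_len(p$r_spike)) {  # refractory window at dt = 1
    st_a <- lif_step(st_a, 40, p, 1)
    st_b <- lif_step(st_b, 0, p, 1)
    expect_identical(st_a$v, st_b$v)
  }
  # once the window closes the input matters again
  st_a <- lif_step(st_a, 40, p, 1)
  st_b <- lif_step(st_b, 0, p, 1)
  expect_gt(st_a$v, st_b$v)
})

test_that("no two spikes of one unit are closer than r_spike", {
  p <- lif_params()
  drive <- make_fixture("ou_trace",
                        list(n_steps = 2000, mean = 25, sigma = 10, dt = 1),
                        seed = 9)
  out <- simulate_soma("lif", drive, 1, params = p)
  times <- out$spikes[[1]]
  expect_gt(length(times), 10)
  expect_true(all(diff(times) > p$r_spike))
})

test_that("AdEx: silent from rest, spike count matches a 10x-finer reference", {
  p <- adex_params()
  quiet <- simulate_soma("adex", rep(0, 1e4), 0.1, params = p)
  expect_length(quiet$spikes[[1]], 0)

  step_current <- rep(800, 1e4)  # suprathreshold step, 1 s at 0.1 ms
  coarse <- simulate_soma("adex", step_current, 0.1, params = p)
  fine <- simulate_soma("adex", rep(step_current, each = 10), 0.01, params = p)
  expect_lte(abs(length(coarse$spikes[[1]]) - length(fine$spikes[[1]])), 1)
})

test_that("HH: resting equilibrium, periodic ISIs near fine-dt reference, gating bounds", {
  p <- hh_params()
  # long zero-current integration settles to an equilibrium
  out <- simulate_soma("hh", rep(0, 2e4), 0.05, params = p, return_v = TRUE)
  expect_length(out$spikes[[1]], 0)
  v_tail <- tail(out$v[, 1], 2000)
  expect_lt(diff(range(v_tail)), 1e-3)

  # sustained suprathreshold current: tonic spiking, ISI within 5% of the
  # 10x-finer reference
  drive <- rep(10, 2e4)
  coarse <- simulate_soma("hh", drive, 0.05, params = p)
  fine <- simulate_soma("hh", rep(drive, each = 10), 0.005, params = p)
  isi_c <- median(diff(coarse$spikes[[1]]))
  isi_f <- median(diff(fine$spikes[[1]]))
  expect_lt(abs(isi_c - isi_f) / isi_f, 0.05)

  # gating variables remain in [0, 1] under OU drive
  st <- hh_init(2, p)
  ou <- make_fixture("ou_trace",
                     list(n_steps = 2e4, mean = 2, sigma = 3, dt = 0.05),
                     seed = 11)
  for (k in seq(1, 2e4, by = 1)) {
    st <- hh_step(st, rep(ou[k], 2), p, 0.05)
    if (k %% 500 == 0) {
      expect_true(all(st$m >= 0 & st$m <= 1))
      expect_true(all(st$h >= 0 & st$h <= 1))
      expect_true(all(st$n >= 0 & st$n <= 1))
    }
  }
})

test_that("compiled simulation loops agree with the R steppers", {
  drive <- make_fixture("ou_trace",
                        list(n_steps = 2000, mean = 20, sigma = 8, dt = 1),
                        seed = 5)
  for (kind in c("lif", "adex", "hh")) {
    dt <- if (kind == "hh") 0.05 else 1
    cur <- if (kind == "adex") drive * 30 else if (kind == "hh") drive / 4 else drive
    params <- switch(kind, lif = lif_params(), adex = adex_params(),
                     hh = hh_params())
    cpp <- simulate_soma(kind, cur, dt, params = params, return_v = TRUE)
    st <- switch(kind, lif = lif_init(1, params), adex = adex_init(1, params),
                 hh = hh_init(1, params))
    stepper <- switch(kind, lif = lif_step, adex = adex_step, hh = hh_step)
    v_r <- numeric(length(cur))
    spikes_r <- numeric(0)
    for (k in seq_along(cur)) {
      st <- stepper(st, cur[k], params, dt)
      v_r[k] <- st$v
      if (st$S == 1) spikes_r <- c(spikes_r, (k) * dt)
    }
    expect_lt(max(abs(v_r - cpp$v[, 1])), 1e-9)
    expect_equal(spikes_r, cpp$spikes[[1]], tolerance = 1e-12)
  }
})

test_that("non-finite states raise a numerical-instability error", {
  p <- lif_params()
  st <- lif_init(1, p)
  expect_error(lif_step(st, Inf, p, 1), "non-finite")
})
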