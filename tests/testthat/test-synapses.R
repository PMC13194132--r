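# Traced synapses: analytic pulse response, superposition, delay recovery,
# sparse uniform initialization statistics.

test_that("silent input yields identically zero current", {
  p <- synapse_params(4, 3, density = 1, w_max = 2)
  st <- synapse_init(p, dt = 1, seed = 2)
  for (k in 1:30) {
    st <- synapse_step(st, rep(0, 4), p, 1)
    expect_true(all(st$current == 0))
  }
})

test_that("a single spike produces the closed-form delayed pulse", {
  p <- synapse_params(1, 1, tau_s = 5, density = 1, w_max = 1,
                      self_connections = TRUE)
  st <- synapse_init(p, dt = 1, seed = 3)
  st$W[1, 1] <- 0.7
  st$mask[1, 1] <- 1
  d <- st$D[1, 1]
  n_steps <- 40
  cur <- numeric(n_steps)
  for (k in seq_len(n_steps)) {
    st <- synapse_step(st, as.numeric(k == 1), p, 1)
    cur[k] <- st$current
  }
  expected <- numeric(n_steps)
  arrive <- 1 + d
  expected[arrive:n_steps] <- 0.7 * exp(-(seq(arrive, n_steps) - arrive) / 5)
  expect_equal(cur, expected, tolerance = 1e-12)
})

test_that("zero weights give zero output regardless of spiking", {
  p <- synapse_params(5, 5, density = 1, w_max = 0, self_connections = TRUE)
  st <- synapse_init(p, dt = 1, seed = 1)
  raster <- make_fixture("random_raster",
                         list(n_units = 5, n_steps = 50, p = 0.4), seed = 8)
  for (k in 1:50) {
    st <- synapse_step(st, raster[, k], p, 1)
    expect_true(all(st$current == 0))
  }
})

test_that("summed currents obey superposition over spike trains", {
  p <- synapse_params(6, 4, tau_s = 4, density = 0.8, w_max = 1.5)
  r1 <- make_fixture("random_raster", list(n_units = 6, n_steps = 80, p = 0.2),
                     seed = 21)
  r2 <- make_fixture("random_raster", list(n_units = 6, n_steps = 80, p = 0.2),
                     seed = 22)
  # trains must be disjoint for their sum to stay binary
  r2[r1 == 1] <- 0
  run <- function(raster) {
    st <- synapse_init(p, dt = 1, seed = 7)
    out <- matrix(0, 80, 4)
    for (k in 1:80) {
      st <- synapse_step(st, raster[, k], p, 1)
      out[k, ] <- st$current
    }
    out
  }
  expect_equal(run(r1) + run(r2), run(r1 + r2), tolerance = 1e-10)
})

test_that("arrival times recover every connection delay exactly", {
  p <- synapse_params(5, 6, density = 1, w_max = 1, d_max = 8)
  st0 <- synapse_init(p, dt = 1, seed = 13)
  raster <- make_fixture("random_raster",
                         list(n_units = 5, n_steps = 60, p = 0.15), seed = 14)
  st <- st0
  arr <- array(0, dim = c(5, 6, 60))
  for (k in 1:60) {
    st <- synapse_step(st, raster[, k], p, 1)
    arr[, , k] <- st$arrivals
  }
  for (j in 1:5) {
    for (i in 1:6) {
      d <- st0$D[j, i]
      spikes <- which(raster[j, ] == 1)
      expected_arrivals <- spikes + d
      expected_arrivals <- expected_arrivals[expected_arrivals <= 60]
      expect_identical(which(arr[j, i, ] == 1), as.integer(expected_arrivals))
    }
  }
})

test_that("sparse uniform initialization matches its stated law", {
  expect_error(init_weights(4, 4, density = 1.2, w_max = 1), "density")

  empty <- init_weights(10, 10, density = 0, w_max = 1, seed = 1)
  expect_equal(sum(empty$mask), 0)

  full0 <- init_weights(10, 10, density = 1, w_max = 0, seed = 1,
                        self_connections = TRUE)
  expect_equal(sum(full0$mask), 100)
  expect_true(all(full0$W == 0))

  # realized connection count within 3 binomial sigmas
  w <- init_weights(256, 256, density = 0.1, w_max = 1, seed = 42)
  n_possible <- 256 * 256 - 256  # diagonal excluded
  expect_lt(abs(sum(w$mask) - 0.1 * n_possible),
            3 * sqrt(n_possible * 0.1 * 0.9))
  expect_true(all(diag(w$mask) == 0))
  # present weights uniform on (0, w_max), signed
  vals <- w$W[w$mask == 1]
  expect_true(all(vals >= 0 & vals <= 1))
  expect_lt(abs(mean(vals) - 0.5), 3 * sqrt(1 / 12 / length(vals)))

  neg <- init_weights(20, 20, density = 0.5, w_max = 2, sign = -1, seed = 5)
  expect_true(all(neg$W[neg$mask == 1] <= 0))

  # reproducibility
  expect_identical(init_weights(30, 30, 0.2, 1, seed = 9),
                   init_weights(30, 30, 0.2, 1, seed = 9))
})

test_that("delays are integer steps within [1, d_max/dt], seeded", {
  D <- init_delays(50, 50, d_max = 10, dt = 1, seed = 3)
  expect_true(all(D >= 1 & D <= 10))
  expect_true(all(D == round(D)))
  expect_identical(D, init_delays(50, 50, d_max = 10, dt = 1, seed = 3))
})
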