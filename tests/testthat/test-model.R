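# Model assembly and stepping: determinism, clock accounting, component
# isolation, execution order, and the end-to-end blueprint examples.

test_that("an empty blueprint builds a model that steps as a no-op", {
  m <- build_model(blueprint(), dt = 0.5, seed = 1)
  m <- step_model(m)
  m <- step_model(m)
  expect_identical(m$clock$step_index, 2L)
  expect_length(m$outputs, 0)
})

test_that("the clock is exact integer accounting: t == n * dt", {
  m <- build_model(two_node_bp(), dt = 0.1, seed = 1)
  for (k in 1:1000) m <- step_model(m, list(`in` = c(0, 0, 0)))
  expect_identical(m$clock$step_index, 1000L)
  expect_identical(model_time(m), 1000L * 0.1)  # never accumulated
})

test_that("a LIF pool with zero input stays silent", {
  bp <- blueprint(list(bp_node("p", "lif_pool", list(n = 5))))
  m <- build_model(bp, dt = 1, seed = 1)
  for (k in 1:100) {
    m <- step_model(m, list(`p:I_in` = rep(0, 5)))
    expect_true(all(m$outs$p$out == 0))
  }
})

test_that("two builds with identical arguments are bit-identical; seeds differ", {
  bp <- two_node_bp(density = 0.5)
  m1 <- build_model(bp, dt = 1, seed = 7)
  m2 <- build_model(bp, dt = 1, seed = 7)
  expect_identical(m1$comps$syn$syn$W, m2$comps$syn$syn$W)
  m3 <- build_model(bp, dt = 1, seed = 8)
  expect_false(identical(m1$comps$syn$syn$W, m3$comps$syn$syn$W))
  # same shapes and node set either way
  expect_identical(dim(m1$comps$syn$syn$W), dim(m3$comps$syn$syn$W))
  expect_identical(names(m1$comps), names(m3$comps))
})

test_that("identical runs produce identical spike rasters over 1000 steps", {
  bp <- two_node_bp(n_in = 4, n_out = 3, w_max = 30, d_max = 4)
  raster <- make_fixture("random_raster",
                         list(n_units = 4, n_steps = 1000, p = 0.3), seed = 6)
  run <- function() {
    m <- build_model(bp, dt = 1, seed = 3)
    run_model(m, 1000, function(k) list(`in` = raster[, k + 1]),
              record = "pool")$recorded$pool
  }
  r1 <- run()
  expect_gt(sum(r1), 0)  # the drive actually spikes the pool
  expect_identical(r1, run())
})

test_that("unknown precision and missing inputs are errors", {
  expect_error(build_model(two_node_bp(), precision = "float16"),
               "precision")
  m <- build_model(two_node_bp(), seed = 1)
  expect_error(step_model(m), "external input")
  expect_error(step_model(m, list(`in` = c(1, 0))), "length")
})

test_that("disconnected components are isolated from parameter mutation", {
  bp <- blueprint(list(bp_node("p1", "lif_pool", list(n = 2)),
                       bp_node("p2", "lif_pool", list(n = 2))))
  drive <- function(m) {
    for (k in 1:50) {
      m <- step_model(m, list(`p1:I_in` = c(20, 20), `p2:I_in` = c(18, 18)))
    }
    m
  }
  m_a <- build_model(bp, dt = 1, seed = 2)
  m_b <- build_model(bp, dt = 1, seed = 2)
  # crank p1's membrane resistance in one copy only
  m_b$comps$p1$params$R <- 3
  m_a <- drive(m_a); m_b <- drive(m_b)
  expect_identical(m_a$comps$p2$soma, m_b$comps$p2$soma)
  expect_false(identical(m_a$comps$p1$soma$v, m_b$comps$p1$soma$v))
})

test_that("execution order is topological with synapses first inside cycles", {
  bp <- tiny_cartpole_bp()
  ord <- execution_order(bp)
  expect_identical(ord[1], "spiker")
  expect_identical(ord[length(ord)], "out")
  syn_pos <- match(c("syn_ie_a", "syn_rec_a", "syn_ei_ab"), ord)
  pool_pos <- match(c("exc_a", "exc_b", "inh_a", "inh_b"), ord)
  expect_true(all(syn_pos < min(pool_pos)))
  # deterministic
  expect_identical(ord, execution_order(bp))
})

test_that("the full-size mutual-inhibition blueprint builds at paper scale", {
  bp <- cartpole_blueprint()
  ids <- vapply(bp$nodes, `[[`, "", "id")
  n_of <- function(id) bp$nodes[[match(id, ids)]]$params$n
  expect_identical(n_of("exc_a"), 256)
  expect_identical(n_of("inh_b"), 64)
  m <- build_model(bp, dt = 1, seed = 1)
  expect_length(m$order, length(bp$nodes))
})

test_that("held input drives the integrator iff motor spikes occur", {
  bp <- tiny_cartpole_bp(w_in = 6, rate_max = 0.8)  # strong drive
  m <- build_model(bp, dt = 1, seed = 4)
  out <- run_model(m, 50, list(spiker = c(0, 0, 0.05, 0)),
                   record = c("exc_a", "exc_b"))
  n_spikes <- sum(out$recorded$exc_a) + sum(out$recorded$exc_b)
  y <- out$model$outs$out$y
  expect_gt(n_spikes, 0)
  expect_true(any(y > 0))

  # encoder silenced: no spikes can ever reach the integrator
  bp0 <- tiny_cartpole_bp(rate_max = 0)
  m0 <- build_model(bp0, dt = 1, seed = 4)
  out0 <- run_model(m0, 50, list(spiker = c(0, 0, 0.05, 0)),
                    record = c("exc_a", "exc_b"))
  expect_identical(sum(out0$recorded$exc_a) + sum(out0$recorded$exc_b), 0)
  expect_true(all(out0$model$outs$out$y == 0))
})

test_that("raster export is tidy (unit, time_ms)", {
  mat <- rbind(c(0, 1, 0), c(1, 0, 0))  # steps x units
  tb <- raster_tibble(mat, dt = 2)
  expect_identical(names(tb), c("unit", "time_ms"))
  expect_identical(tb$unit, c(1L, 2L))
  expect_identical(tb$time_ms, c(4, 2))
})
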