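# Seeded synthetic fixture generators used by the test suite and the CLI.

#' Generate a synthetic fixture
#'
#' Deterministic generators for the artifacts the test-suite and the fidelity
#' harness consume:
#'
#' * `"ou_trace"`: an Ornstein-Uhlenbeck current trace; `params` are passed
#'   to [ou_params()] plus `n_steps`.
#' * `"poisson_train"`: a homogeneous Poisson spike train; `params` needs
#'   `rate` (spikes/ms) and `duration` (ms).
#' * `"periodic_train"`: a perfectly regular train; `params` needs `period`
#'   (ms), `duration` (ms) and optionally `phase` (first spike time,
#'   default `period`).
#' * `"random_raster"`: an i.i.d. Bernoulli spike raster; `params` needs
#'   `n_units`, `n_steps` and `p`.
#'
#' @param kind One of `"ou_trace"`, `"poisson_train"`, `"periodic_train"`,
#'   `"random_raster"`.
#' @param params Named list of generator parameters (see above).
#' @param seed Integer seed; identical arguments give identical artifacts.
#' @return The generated artifact: a numeric vector, a [spike_train()], or a
#'   0/1 matrix (units x steps).
#' @export
make_fixture <- function(kind = c("ou_trace", "poisson_train",
                                  "periodic_train", "random_raster"),
                         params = list(), seed = 1) {
  kind <- match.arg(kind)
  switch(kind,
    ou_trace = {
      n_steps <- params$n_steps %||% 1000L
      op <- ou_params(mean = params$mean %||% 0,
                      sigma = params$sigma %||% 1,
                      tau_ou = params$tau_ou %||% 5,
                      dt = params$dt %||% 0.1)
      ou_current(op, n_steps, seed = seed)
    },
    poisson_train = {
      rate <- params$rate
      duration <- params$duration
      stopifnot(rate > 0, duration > 0)
      times <- with_seed(seed, {
        # Draw exponential gaps until the duration is exceeded.
        n_guess <- ceiling(rate * duration + 6 * sqrt(rate * duration)) + 10
        gaps <- stats::rexp(n_guess, rate)
        t <- cumsum(gaps)
        while (sum(gaps) <= duration) {
          gaps <- c(gaps, stats::rexp(n_guess, rate))
          t <- cumsum(gaps)
        }
        t[t < duration]
      })
      spike_train(times, duration)
    },
    periodic_train = {
      period <- params$period
      duration <- params$duration
      phase <- params$phase %||% period
      stopifnot(period > 0, duration > 0, phase > 0)
      spike_train(seq(phase, duration - 1e-9, by = period), duration)
    },
    random_raster = {
      n_units <- params$n_units
      n_steps <- params$n_steps
      p <- params$p
      stopifnot(n_units >= 1, n_steps >= 1, p >= 0, p <= 1)
      with_seed(seed, {
        matrix(as.numeric(runif(n_units * n_steps) < p), n_units, n_steps)
      })
    }
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x
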