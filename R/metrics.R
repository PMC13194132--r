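# Spike-train dissimilarity metrics (ISI-distance and SPIKE-distance),
# shuffle surrogates, and the Ornstein-Uhlenbeck drive generator.
#
# Both distances follow the standard parameter-free definitions of Kreuz and
# colleagues, with edge intervals handled by auxiliary spikes at 0 and T (the
# common convention). Profiles are integrated exactly over the segments
# between consecutive event times: the ISI profile is piecewise constant and
# the SPIKE profile piecewise linear, so segment-wise closed-form integration
# is exact.

#' Construct a spike train
#'
#' @param times Spike times (ms), strictly increasing, within `[0, duration]`.
#' @param duration Recording duration T (ms).
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, duration) {
  times <- as.numeric(times)
  stopifnot(duration > 0)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("spike_train: times must be strictly increasing", call. = FALSE)
  }
  if (length(times) && (times[1] < 0 || times[length(times)] > duration)) {
    stop("spike_train: times must lie in [0, duration]", call. = FALSE)
  }
  structure(list(times = times, duration = duration), class = "spike_train")
}

# Augment a train with auxiliary spikes at 0 and T.
.aug <- function(st) {
  t <- st$times
  if (!length(t) || t[1] > 0) t <- c(0, t)
  if (t[length(t)] < st$duration) t <- c(t, st$duration)
  t
}

.check_pair <- function(a, b) {
  stopifnot(inherits(a, "spike_train"), inherits(b, "spike_train"))
  if (!isTRUE(all.equal(a$duration, b$duration))) {
    stop("spike trains must share a duration", call. = FALSE)
  }
  if (length(a$times) < 2 || length(b$times) < 2) {
    stop("distance undefined for trains with fewer than 2 spikes",
         call. = FALSE)
  }
}

# For each segment midpoint, the index of the enclosing interval of `aug`.
.interval_of <- function(mids, aug) {
  pmin(pmax(findInterval(mids, aug), 1L), length(aug) - 1L)
}

#' ISI-distance between two spike trains
#'
#' Time average of the instantaneous normalized ISI-ratio profile
#' `|isi_a - isi_b| / max(isi_a, isi_b)`, integrated exactly over the
#' piecewise-constant segments between spikes of either train.
#'
#' @param a,b [spike_train()] objects with at least 2 spikes each and equal
#'   duration.
#' @return A scalar in `[0, 1]`.
#' @export
isi_distance <- function(a, b) {
  .check_pair(a, b)
  ta <- .aug(a); tb <- .aug(b)
  ev <- sort(unique(c(ta, tb)))
  left <- ev[-length(ev)]
  right <- ev[-1]
  len <- right - left
  keep <- len > 0
  mids <- (left + right)[keep] / 2
  ia <- .interval_of(mids, ta)
  ib <- .interval_of(mids, tb)
  isa <- diff(ta)[ia]
  isb <- diff(tb)[ib]
  prof <- abs(isa - isb) / pmax(isa, isb)
  sum(prof * len[keep]) / a$duration
}

# Distance from each element of x to the nearest element of y (both sorted).
.nearest_dist <- function(x, y) {
  i <- findInterval(x, y)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(y))
  pmin(abs(x - y[lo]), abs(x - y[hi]))
}

#' SPIKE-distance between two spike trains
#'
#' Time average of the SPIKE-distance profile: for each train the distances
#' from the preceding and following spike to the nearest spike of the other
#' train are interpolated linearly across the local interspike interval, the
#' two curves are averaged with local-ISI weights and normalized by the
#' squared mean local ISI. The profile is piecewise linear between events and
#' is integrated exactly (trapezoid per segment).
#'
#' @inheritParams isi_distance
#' @return A nonnegative scalar (empirically `<= 1`).
#' @export
spike_distance <- function(a, b) {
  .check_pair(a, b)
  ta <- .aug(a); tb <- .aug(b)
  ev <- sort(unique(c(ta, tb)))
  left <- ev[-length(ev)]
  right <- ev[-1]
  len <- right - left
  keep <- len > 0
  left <- left[keep]; right <- right[keep]; len <- len[keep]
  mids <- (left + right) / 2
  ia <- .interval_of(mids, ta)
  ib <- .interval_of(mids, tb)
  # Per-segment constants for train a: preceding/following spike and their
  # distances to the nearest spike of b (and vice versa).
  da <- .nearest_dist(ta, tb)
  db <- .nearest_dist(tb, ta)
  tPa <- ta[ia]; tFa <- ta[ia + 1L]; dPa <- da[ia]; dFa <- da[ia + 1L]
  tPb <- tb[ib]; tFb <- tb[ib + 1L]; dPb <- db[ib]; dFb <- db[ib + 1L]
  xa <- tFa - tPa
  xb <- tFb - tPb
  s_at <- function(t) {
    Sa <- (dPa * (tFa - t) + dFa * (t - tPa)) / xa
    Sb <- (dPb * (tFb - t) + dFb * (t - tPb)) / xb
    (Sa * xb + Sb * xa) / (2 * ((xa + xb) / 2)^2)
  }
  sum((s_at(left) + s_at(right)) / 2 * len) / a$duration
}

#' ISI-shuffled surrogate of a spike train
#'
#' Permutes the inter-spike intervals (including the leading interval from 0
#' to the first spike) and rebuilds the train by cumulative summation. Spike
#' count, total duration, and the multiset of ISIs are preserved; a perfectly
#' periodic train maps to itself.
#'
#' @param a A [spike_train()].
#' @param seed Integer seed.
#' @return A [spike_train()] surrogate.
#' @export
shuffle_surrogate <- function(a, seed = 1) {
  stopifnot(inherits(a, "spike_train"))
  isi <- diff(c(0, a$times))
  perm <- with_seed(seed, sample.int(length(isi)))
  spike_train(cumsum(isi[perm]), a$duration)
}

#' Ornstein-Uhlenbeck parameters
#'
#' @param mean Long-run mean of the drive.
#' @param sigma Noise amplitude (`>= 0`).
#' @param tau_ou Correlation time (ms).
#' @param dt Sampling step (ms).
#' @return An object of class `ou_params`.
#' @export
ou_params <- function(mean = 0, sigma = 1, tau_ou = 5, dt = 0.1) {
  stopifnot(tau_ou > 0, sigma >= 0, dt > 0)
  structure(list(mean = mean, sigma = sigma, tau_ou = tau_ou, dt = dt),
            class = "ou_params")
}

#' Generate an Ornstein-Uhlenbeck-like current trace
#'
#' Euler-Maruyama recursion
#' `x[k+1] = x[k] + (mean - x[k]) dt/tau_ou + sigma sqrt(dt) xi[k]` with
#' standard-normal innovations. The first returned sample is `x0`. For small
#' `dt` the stationary variance approaches `sigma^2 tau_ou / 2`.
#'
#' @param params An [ou_params()] object.
#' @param n_steps Number of samples to return.
#' @param seed Integer seed.
#' @param x0 Initial value; defaults to `mean`.
#' @return Numeric vector of length `n_steps`.
#' @export
ou_current <- function(params, n_steps, seed = 1, x0 = params$mean) {
  stopifnot(n_steps >= 1)
  p <- params
  phi <- 1 - p$dt / p$tau_ou
  if (n_steps == 1) return(x0)
  eps <- with_seed(seed, rnorm(n_steps - 1, 0, p$sigma * sqrt(p$dt)))
  dev <- stats::filter(eps, phi, method = "recursive",
                       init = x0 - p$mean)
  c(x0, p$mean + as.numeric(dev))
}
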