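# Spike-timing fidelity harness.
#
# For each soma model, the neuron is driven by a seeded Ornstein-Uhlenbeck
# current for 1 s at the step size of record, and again at a 10x-finer step
# under the identical drive (zero-order hold of each coarse sample across the
# fine substeps). The ISI- and SPIKE-distances between the two runs measure
# how much spike timing the coarse integration loses; the same distances
# against an ISI-shuffled surrogate of the reference train provide the null
# scale.

# Drive constants per soma, chosen so each model fires in the 10-50 Hz range
# under its default parameters (recorded here; overridable via `ou`).
.fidelity_ou_defaults <- function(soma, dt) {
  switch(soma,
    lif = ou_params(mean = 17, sigma = 8, tau_ou = 5, dt = dt),
    adex = ou_params(mean = 550, sigma = 250, tau_ou = 5, dt = dt),
    hh = ou_params(mean = 2, sigma = 3, tau_ou = 5, dt = dt)
  )
}

.fidelity_dt_default <- function(soma) if (soma == "hh") 0.05 else 0.1

#' Single-soma fidelity comparison across step sizes
#'
#' Runs `n_trials` seeded 1-s simulations of one soma model at `dt_record`
#' and at `dt_record / refine` under identical OU drive, and returns the
#' per-trial ISI- and SPIKE-distances of the record run against the fine
#' reference and against an ISI-shuffled surrogate of the reference.
#'
#' @param soma One of `"lif"`, `"adex"`, `"hh"`.
#' @param dt_record Step size of record (ms); defaults to 0.1 ms (0.05 ms for
#'   HH).
#' @param n_trials Number of independent trials.
#' @param duration Trial duration (ms).
#' @param seed Integer seed; trial `k` uses the stream
#'   `derive_seed(seed, paste(soma, k))`.
#' @param refine Reference refinement factor (reference runs at
#'   `dt_record / refine`).
#' @param ou Optional [ou_params()] overriding the per-soma drive defaults
#'   (its `dt` is forced to `dt_record`).
#' @param params Optional soma parameter object.
#' @return A tibble with one row per trial: spike counts of both runs and
#'   `isi_d`, `spike_d`, `isi_d_shuffled`, `spike_d_shuffled`.
#' @export
fidelity_report <- function(soma = c("lif", "adex", "hh"), dt_record = NULL,
                            n_trials = 100, duration = 1000, seed = 1,
                            refine = 10, ou = NULL, params = NULL) {
  soma <- match.arg(soma)
  if (is.null(dt_record)) dt_record <- .fidelity_dt_default(soma)
  if (is.null(ou)) ou <- .fidelity_ou_defaults(soma, dt_record)
  ou$dt <- dt_record
  n_steps <- as.integer(round(duration / dt_record))
  rows <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    s <- derive_seed(seed, paste(soma, k))
    drive <- ou_current(ou, n_steps, seed = s)
    fine <- rep(drive, each = refine)
    rec <- simulate_soma(soma, drive, dt_record, params = params)
    ref <- simulate_soma(soma, fine, dt_record / refine, params = params)
    tr_rec <- spike_train(rec$spikes[[1]], duration)
    tr_ref <- spike_train(ref$spikes[[1]], duration)
    if (length(tr_rec$times) < 2 || length(tr_ref$times) < 2) {
      rows[[k]] <- tibble::tibble(trial = k,
                                  n_spikes_record = length(tr_rec$times),
                                  n_spikes_ref = length(tr_ref$times),
                                  isi_d = NA_real_, spike_d = NA_real_,
                                  isi_d_shuffled = NA_real_,
                                  spike_d_shuffled = NA_real_)
      next
    }
    shuf <- shuffle_surrogate(tr_ref, seed = derive_seed(s, "shuffle"))
    rows[[k]] <- tibble::tibble(
      trial = k,
      n_spikes_record = length(tr_rec$times),
      n_spikes_ref = length(tr_ref$times),
      isi_d = isi_distance(tr_rec, tr_ref),
      spike_d = spike_distance(tr_rec, tr_ref),
      isi_d_shuffled = isi_distance(tr_rec, shuf),
      spike_d_shuffled = spike_distance(tr_rec, shuf)
    )
  }
  out <- do.call(rbind, rows)
  attr(out, "soma") <- soma
  attr(out, "dt_record") <- dt_record
  class(out) <- c("fidelity_report", class(out))
  out
}

#' Summarize a fidelity report
#'
#' @param x A [fidelity_report()] tibble.
#' @param ... Unused.
#' @return One-row tibble with median distances and the fraction of trials
#'   whose record-vs-reference distances fall strictly below the shuffled
#'   baselines.
#' @method glance fidelity_report
#' @export
glance.fidelity_report <- function(x, ...) {
  ok <- stats::complete.cases(x[, c("isi_d", "spike_d",
                                    "isi_d_shuffled", "spike_d_shuffled")])
  xx <- x[ok, ]
  tibble::tibble(
    soma = attr(x, "soma"),
    dt_record = attr(x, "dt_record"),
    n_trials = nrow(x),
    n_valid = nrow(xx),
    median_isi_d = stats::median(xx$isi_d),
    median_spike_d = stats::median(xx$spike_d),
    frac_isi_below_shuffle = mean(xx$isi_d < xx$isi_d_shuffled),
    frac_spike_below_shuffle = mean(xx$spike_d < xx$spike_d_shuffled)
  )
}

#' @rdname glance.fidelity_report
#' @param object A `fidelity_report`.
#' @method autoplot fidelity_report
#' @export
autoplot.fidelity_report <- function(object, ...) {
  df <- tibble::tibble(
    statistic = rep(c("ISI-distance", "SPIKE-distance"), each = 2 * nrow(object)),
    comparison = rep(rep(c("vs reference", "vs shuffled"), each = nrow(object)), 2),
    value = c(object$isi_d, object$isi_d_shuffled,
              object$spike_d, object$spike_d_shuffled)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$comparison, y = .data$value)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~.data$statistic, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "distance",
                  title = paste0("Spike-train fidelity (",
                                 attr(object, "soma"), ")"))
}

#' @importFrom rlang .data
NULL
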