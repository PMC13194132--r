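# Component registry for the graph executor.
#
# Each registered kind declares its ports, how to initialize its state from
# blueprint parameters, and a one-step update. Components are self-contained:
# a component's state is touched only by its own step function.

#' Registered component kinds
#'
#' @return Character vector of the component kinds a blueprint may use.
#' @export
component_kinds <- function() {
  c("input", "spiker", "lif_pool", "adex_pool", "hh_pool", "synapse",
    "integrator")
}

#' Ports of a component kind
#'
#' @param kind A registered kind.
#' @param params The node's parameter list.
#' @return List with character vectors `in_` and `out`.
#' @export
component_ports <- function(kind, params = list()) {
  switch(kind,
    input = list(in_ = character(), out = "out"),
    spiker = list(in_ = "value", out = "out"),
    lif_pool = ,
    adex_pool = ,
    hh_pool = list(in_ = "I_in", out = "out"),
    synapse = list(in_ = c("pre", "post"), out = "I_out"),
    integrator = list(
      in_ = paste0("pool_", seq_len(params$k %||% 2) - 1), out = "y"),
    stop("unknown component kind '", kind, "'", call. = FALSE)
  )
}

# Declared length of a port (NA = unconstrained).
.port_len <- function(kind, params, port, direction) {
  n <- params$n %||% NA
  switch(kind,
    input = as.numeric(params$n),
    spiker = if (direction == "in") length(.spiker_cfg(params)$sigma)
             else .spiker_cfg(params)$dims * .spiker_cfg(params)$n_units,
    lif_pool = ,
    adex_pool = ,
    hh_pool = as.numeric(n),
    synapse = if (direction == "in" && port == "pre") as.numeric(params$n_pre)
              else as.numeric(params$n_post),
    integrator = if (direction == "in") NA_real_ else as.numeric(params$k %||% 2)
  )
}

.spiker_cfg <- function(params) {
  ranges <- params$ranges
  if (is.list(ranges)) ranges <- rbind(ranges$lo, ranges$hi)
  if (!is.matrix(ranges)) ranges <- matrix(ranges, nrow = 2)
  spiker_config(ranges,
                n_units = params$n_units %||% 32,
                topology = params$topology %||% "line",
                sigma_frac = params$sigma_frac %||% 0.1,
                rate_max = params$rate_max %||% 0.5)
}

.soma_params_from <- function(kind, params) {
  known <- switch(kind,
    lif_pool = names(formals(lif_params)),
    adex_pool = names(formals(adex_params)),
    hh_pool = names(formals(hh_params)))
  do.call(switch(kind, lif_pool = lif_params, adex_pool = adex_params,
                 hh_pool = hh_params),
          params[intersect(names(params), known)])
}

.synapse_params_from <- function(params) {
  known <- names(formals(synapse_params))
  do.call(synapse_params, params[intersect(names(params), known)])
}

.plasticity_params_from <- function(plas, sign) {
  known <- names(formals(plasticity_params))
  plas <- plas[intersect(names(plas), known)]
  plas$sign <- sign
  do.call(plasticity_params, plas)
}

# -- init ---------------------------------------------------------------

component_init <- function(node, dt, seed) {
  stream <- derive_seed(seed, node$id)
  base <- list(id = node$id, kind = node$kind, stream = stream)
  st <- switch(node$kind,
    input = list(n = node$params$n),
    spiker = list(config = .spiker_cfg(node$params)),
    lif_pool = {
      p <- .soma_params_from("lif_pool", node$params)
      list(params = p, soma = lif_init(node$params$n, p))
    },
    adex_pool = {
      p <- .soma_params_from("adex_pool", node$params)
      list(params = p, soma = adex_init(node$params$n, p))
    },
    hh_pool = {
      p <- .soma_params_from("hh_pool", node$params)
      list(params = p, soma = hh_init(node$params$n, p))
    },
    synapse = {
      p <- .synapse_params_from(node$params)
      st <- synapse_init(p, dt, stream)
      plas <- NULL
      traces <- NULL
      if (!is.null(node$params$plasticity)) {
        plas <- .plasticity_params_from(node$params$plasticity, p$sign)
        traces <- traces_init(p$n_pre, p$n_post)
      }
      list(params = p, syn = st, plasticity = plas, traces = traces)
    },
    integrator = {
      list(state = integrator_state(node$params$k %||% 2,
                                    node$params$tau_out %||% 25,
                                    node$params$gain %||% 0.3))
    }
  )
  c(base, st)
}

# Zero-valued initial output for each out port.
component_zero_output <- function(node) {
  ports <- component_ports(node$kind, node$params)
  out <- lapply(ports$out, function(p) {
    len <- .port_len(node$kind, node$params, p, "out")
    numeric(if (is.na(len)) 0 else len)
  })
  names(out) <- ports$out
  out
}

# -- step ---------------------------------------------------------------

# inputs: named list port -> numeric vector. Returns list(comp, out).
component_step <- function(comp, node, inputs, clock, modulation = 0) {
  switch(comp$kind,
    input = {
      x <- inputs$out
      if (is.null(x)) {
        stop("input node '", comp$id, "' requires an external input",
             call. = FALSE)
      }
      if (length(x) != comp$n) {
        stop("input '", comp$id, "': expected length ", comp$n, ", got ",
             length(x), call. = FALSE)
      }
      list(comp = comp, out = list(out = as.numeric(x)))
    },
    spiker = {
      v <- inputs$value
      if (is.null(v)) {
        stop("spiker '", comp$id, "' requires a value input", call. = FALSE)
      }
      s <- encode(v, comp$config,
                  seed = derive_seed(comp$stream, clock$step_index))
      list(comp = comp, out = list(out = s))
    },
    lif_pool = {
      comp$soma <- lif_step(comp$soma, inputs$I_in, comp$params, clock$dt)
      list(comp = comp, out = list(out = comp$soma$S))
    },
    adex_pool = {
      comp$soma <- adex_step(comp$soma, inputs$I_in, comp$params, clock$dt)
      list(comp = comp, out = list(out = comp$soma$S))
    },
    hh_pool = {
      comp$soma <- hh_step(comp$soma, inputs$I_in, comp$params, clock$dt)
      list(comp = comp, out = list(out = comp$soma$S))
    },
    synapse = {
      comp$syn <- synapse_step(comp$syn, inputs$pre, comp$params, clock$dt)
      if (!is.null(comp$plasticity)) {
        post <- inputs$post
        if (is.null(post)) {
          stop("plastic synapse '", comp$id,
               "' requires a 'post' connection", call. = FALSE)
        }
        comp$traces <- update_traces(comp$traces, comp$syn$arrivals, post,
                                     comp$plasticity, clock$dt)
        if (modulation != 0) {
          comp$syn$W <- stdp_update(comp$syn$W, comp$syn$mask, comp$traces,
                                    comp$syn$arrivals, post, modulation,
                                    comp$plasticity, clock$dt)
        }
      }
      list(comp = comp, out = list(I_out = comp$syn$current))
    },
    integrator = {
      counts <- vapply(paste0("pool_", seq_len(comp$state$k) - 1),
                       function(p) sum(inputs[[p]] %||% 0), 0)
      comp$state <- integrate_traces(comp$state, counts, clock$dt)
      list(comp = comp, out = list(y = comp$state$y))
    }
  )
}
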