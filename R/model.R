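# Model assembly and deterministic stepping.
#
# A model instance is an ordered collection of stateful components plus a
# simulation clock. The execution order is fixed at build time: topological
# order over the blueprint graph, with cycles broken by one-step delayed
# edges — within a strongly connected component, synapse components (which
# already buffer their presynaptic input by at least one step) run first,
# remaining ties break lexicographically on node id, and any edge from a
# later-scheduled to an earlier-scheduled component is read with one step of
# latency (the standard synchronous-update convention). Time is derived from
# an integer step counter, never accumulated in floating point.

#' Deterministic execution order of a blueprint
#'
#' @param bp A [blueprint()].
#' @return Character vector of node ids in execution order.
#' @export
execution_order <- function(bp) {
  ids <- vapply(bp$nodes, `[[`, "", "id")
  kinds <- stats::setNames(vapply(bp$nodes, `[[`, "", "kind"), ids)
  if (!length(ids)) return(character())
  if (length(bp$edges)) {
    el <- do.call(rbind, lapply(bp$edges, function(e) c(e$from, e$to)))
    g <- igraph::graph_from_data_frame(
      data.frame(from = el[, 1], to = el[, 2]),
      directed = TRUE, vertices = data.frame(name = ids))
    memb <- igraph::components(g, mode = "strong")$membership[ids]
  } else {
    memb <- stats::setNames(seq_along(ids), ids)
  }
  sccs <- split(ids, memb)
  # Condensation DAG with deterministic Kahn ordering: among ready SCCs pick
  # the one whose smallest node id sorts first.
  scc_ids <- names(sccs)
  reps <- vapply(sccs, function(s) min(s), "")
  succ <- stats::setNames(vector("list", length(scc_ids)), scc_ids)
  indeg <- stats::setNames(integer(length(scc_ids)), scc_ids)
  for (e in bp$edges) {
    a <- as.character(memb[[e$from]]); b <- as.character(memb[[e$to]])
    if (a != b && !(b %in% succ[[a]])) {
      succ[[a]] <- c(succ[[a]], b)
      indeg[[b]] <- indeg[[b]] + 1L
    }
  }
  order_scc <- character()
  ready <- scc_ids[indeg == 0L]
  while (length(ready)) {
    nxt <- ready[order(reps[ready])][1]
    ready <- setdiff(ready, nxt)
    order_scc <- c(order_scc, nxt)
    for (b in succ[[nxt]]) {
      indeg[[b]] <- indeg[[b]] - 1L
      if (indeg[[b]] == 0L) ready <- c(ready, b)
    }
  }
  unlist(lapply(order_scc, function(s) {
    members <- sccs[[s]]
    syn <- sort(members[kinds[members] == "synapse"])
    c(syn, sort(setdiff(members, syn)))
  }), use.names = FALSE)
}

#' Build an executable model from a blueprint
#'
#' Initializes every component's state (membrane potentials at rest, weights
#' drawn from the sparse uniform initializer) using per-component random
#' streams derived from `(seed, node id)`, so two builds with identical
#' arguments are bit-identical and topology does not depend on build order.
#'
#' @param bp A [blueprint()].
#' @param dt Integration step (ms), fixed for the lifetime of the model.
#' @param seed Integer global seed.
#' @param precision Floating-point width of the instance. R computes in
#'   64-bit floats; `"float64"` is the only supported width.
#' @return An object of class `snn_model`.
#' @export
build_model <- function(bp, dt = 1, seed = 1, precision = "float64") {
  validate_blueprint(bp)
  if (!identical(precision, "float64")) {
    stop("build_model: unsupported precision '", precision,
         "' (supported: 'float64')", call. = FALSE)
  }
  stopifnot(dt > 0)
  ids <- vapply(bp$nodes, `[[`, "", "id")
  comps <- list()
  outs <- list()
  for (nd in bp$nodes) {
    comps[[nd$id]] <- component_init(nd, dt, seed)
    outs[[nd$id]] <- component_zero_output(nd)
  }
  nodes_by_id <- stats::setNames(bp$nodes, ids)
  sinks <- setdiff(ids, vapply(bp$edges, `[[`, "", "from"))
  structure(list(blueprint = bp, nodes = nodes_by_id,
                 order = execution_order(bp),
                 comps = comps, outs = outs, sinks = sinks,
                 clock = list(step_index = 0L, dt = dt, t = 0),
                 seed = seed, precision = precision,
                 outputs = NULL),
            class = "snn_model")
}

#' Current simulated time of a model (ms)
#'
#' Always exactly `step_index * dt`.
#'
#' @param model An `snn_model`.
#' @return Time in ms.
#' @export
model_time <- function(model) model$clock$step_index * model$clock$dt

#' Advance a model by one step
#'
#' Every component is updated exactly once, in the fixed execution order.
#' A component reads each input port from the value its upstream neighbor
#' produced this step if the neighbor has already run, and from the previous
#' step otherwise (one-step latency on back edges). Unconnected input ports
#' read from `external_inputs`, keyed `"node:port"` (or just `"node"` when
#' unambiguous).
#'
#' @param model An `snn_model` from [build_model()].
#' @param external_inputs Named list of arrays for source ports.
#' @param modulation Named numeric list: third-factor value per plastic
#'   synapse node for this step (default 0 everywhere, i.e. frozen weights).
#' @return The updated model; `model$outputs` holds the sink-port values of
#'   this step.
#' @export
step_model <- function(model, external_inputs = list(), modulation = list()) {
  clock <- model$clock
  edges <- model$blueprint$edges
  for (id in model$order) {
    node <- model$nodes[[id]]
    ports <- component_ports(node$kind, node$params)
    ins <- list()
    for (p in ports$in_) {
      vals <- NULL
      for (e in edges) {
        if (e$to == id && e$to_port == p) {
          v <- model$outs[[e$from]][[e$from_port]]
          vals <- if (is.null(vals)) v else vals + v
        }
      }
      if (is.null(vals)) {
        key <- paste0(id, ":", p)
        vals <- external_inputs[[key]] %||% external_inputs[[id]]
      }
      if (!is.null(vals)) {
        want <- .port_len(node$kind, node$params, p, "in")
        if (!is.na(want) && length(vals) != want) {
          stop("step_model: port '", id, ":", p, "' expects length ", want,
               ", got ", length(vals), call. = FALSE)
        }
      }
      ins[[p]] <- vals
    }
    if (node$kind == "input") {
      ins$out <- external_inputs[[id]] %||% external_inputs[[paste0(id, ":out")]]
    }
    res <- component_step(model$comps[[id]], node, ins, clock,
                          modulation = modulation[[id]] %||% 0)
    model$comps[[id]] <- res$comp
    model$outs[[id]] <- res$out
  }
  model$clock$step_index <- clock$step_index + 1L
  model$clock$t <- model$clock$step_index * clock$dt
  model$outputs <- lapply(stats::setNames(model$sinks, model$sinks),
                          function(s) model$outs[[s]])
  model
}

#' Run a model for several steps
#'
#' @param model An `snn_model`.
#' @param n_steps Number of steps.
#' @param external_inputs Fixed external inputs applied every step, or a
#'   function `(step_index) -> named list`.
#' @param modulation As in [step_model()].
#' @param record Optional character vector of node ids whose `out` port
#'   should be recorded.
#' @return List with the final `model` and, if requested, `recorded`: a named
#'   list of (steps x units) matrices.
#' @export
run_model <- function(model, n_steps, external_inputs = list(),
                      modulation = list(), record = NULL) {
  rec <- NULL
  if (!is.null(record)) {
    rec <- lapply(stats::setNames(record, record), function(id) NULL)
  }
  for (k in seq_len(n_steps)) {
    ext <- if (is.function(external_inputs)) {
      external_inputs(model$clock$step_index)
    } else {
      external_inputs
    }
    model <- step_model(model, ext, modulation)
    if (!is.null(record)) {
      for (id in record) {
        rec[[id]] <- rbind(rec[[id]], model$outs[[id]][[1]])
      }
    }
  }
  list(model = model, recorded = rec)
}

#' Spike raster as a tidy table
#'
#' @param mat A (steps x units) 0/1 matrix as recorded by [run_model()].
#' @param dt Step size (ms).
#' @return Tibble with columns `unit`, `time_ms`.
#' @export
raster_tibble <- function(mat, dt = 1) {
  idx <- which(mat != 0, arr.ind = TRUE)
  tibble::tibble(unit = as.integer(idx[, 2]),
                 time_ms = as.numeric(idx[, 1]) * dt)[order(idx[, 2], idx[, 1]), ]
}
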