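# Blueprints: declarative, serializable descriptions of a model's component
# graph, kept separate from the executable model instance built from them.
#
# A blueprint is a list of typed nodes (id, kind, parameter map) and directed
# port-to-port edges, plus free-form string metadata. The serialized form is
# canonical JSON (schema version string, sorted keys, nodes sorted by id,
# edges sorted lexicographically), so serialize(deserialize(x)) is the
# identity on canonical text.

BLUEPRINT_VERSION <- "1"

#' Construct a blueprint node
#'
#' @param id Unique node identifier (character).
#' @param kind Registered component kind (see [component_kinds()]).
#' @param params Named list of component parameters.
#' @return A node description list.
#' @export
bp_node <- function(id, kind, params = list()) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(kind), length(kind) == 1L)
  # NULL entries mean "absent" and must not survive serialization
  params <- params[!vapply(params, is.null, TRUE)]
  list(id = id, kind = kind, params = params)
}

#' Construct a blueprint edge
#'
#' @param from,to Node ids.
#' @param from_port,to_port Port names on the source and target components.
#' @return An edge description list.
#' @export
bp_edge <- function(from, from_port, to, to_port) {
  list(from = from, from_port = from_port, to = to, to_port = to_port)
}

#' Construct a blueprint
#'
#' @param nodes List of [bp_node()] descriptions.
#' @param edges List of [bp_edge()] descriptions.
#' @param metadata Named list of free-form string metadata (description,
#'   seed provenance, ...).
#' @return An object of class `blueprint`, validated.
#' @export
blueprint <- function(nodes = list(), edges = list(), metadata = list()) {
  bp <- structure(list(version = BLUEPRINT_VERSION, nodes = nodes,
                       edges = edges, metadata = metadata),
                  class = "blueprint")
  validate_blueprint(bp)
  bp
}

#' Validate a blueprint
#'
#' Checks id uniqueness, registered kinds, and that every edge references
#' existing nodes and ports with compatible shapes.
#'
#' @param bp A [blueprint()].
#' @return The blueprint, invisibly; errors describe every offending edge.
#' @export
validate_blueprint <- function(bp) {
  ids <- vapply(bp$nodes, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop("blueprint: duplicate node ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  for (nd in bp$nodes) {
    if (!nd$kind %in% component_kinds()) {
      stop("blueprint: unknown component kind '", nd$kind, "' at node '",
           nd$id, "'", call. = FALSE)
    }
  }
  bad <- character()
  for (e in bp$edges) {
    if (!e$from %in% ids || !e$to %in% ids) {
      bad <- c(bad, sprintf("%s:%s -> %s:%s (dangling node)",
                            e$from, e$from_port, e$to, e$to_port))
      next
    }
    kf <- bp$nodes[[match(e$from, ids)]]
    kt <- bp$nodes[[match(e$to, ids)]]
    if (!e$from_port %in% component_ports(kf$kind, kf$params)$out) {
      bad <- c(bad, sprintf("%s:%s -> %s:%s (no such output port)",
                            e$from, e$from_port, e$to, e$to_port))
    }
    if (!e$to_port %in% component_ports(kt$kind, kt$params)$in_) {
      bad <- c(bad, sprintf("%s:%s -> %s:%s (no such input port)",
                            e$from, e$from_port, e$to, e$to_port))
    }
  }
  if (length(bad)) {
    stop("blueprint: invalid edges:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  }
  invisible(bp)
}

# Recursively sort list names for the canonical form.
.canon <- function(x) {
  if (is.list(x)) {
    if (!is.null(names(x)) && length(x)) x <- x[order(names(x))]
    lapply(x, .canon)
  } else {
    x
  }
}

#' Serialize a blueprint to canonical JSON text
#'
#' @param bp A [blueprint()].
#' @return A single character string of pretty-printed canonical JSON.
#' @export
serialize_blueprint <- function(bp) {
  validate_blueprint(bp)
  ids <- vapply(bp$nodes, `[[`, "", "id")
  nodes <- lapply(bp$nodes[order(ids)], function(nd) {
    list(id = nd$id, kind = nd$kind, params = .canon(nd$params))
  })
  ekey <- vapply(bp$edges, function(e) {
    paste(e$from, e$from_port, e$to, e$to_port, sep = "\r")
  }, "")
  edges <- bp$edges[order(ekey)]
  obj <- list(version = bp$version,
              metadata = .canon(bp$metadata),
              nodes = nodes,
              edges = edges)
  paste0(jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, digits = NA),
         "\n")
}

#' Deserialize a blueprint from JSON text
#'
#' Unknown fields are an error, not silently ignored; a schema version other
#' than the supported one is an explicit version error.
#'
#' @param text JSON text (or a length-one path read with [readLines()] by the
#'   caller).
#' @return A validated [blueprint()].
#' @export
deserialize_blueprint <- function(text) {
  obj <- tryCatch(
    jsonlite::fromJSON(text, simplifyVector = FALSE),
    error = function(e) stop("blueprint parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  extra <- setdiff(names(obj), c("version", "metadata", "nodes", "edges"))
  if (length(extra)) {
    stop("blueprint: unknown top-level field(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  if (!identical(obj$version, BLUEPRINT_VERSION)) {
    stop("blueprint: unsupported schema version '", obj$version,
         "' (supported: '", BLUEPRINT_VERSION, "')", call. = FALSE)
  }
  nodes <- lapply(obj$nodes, function(nd) {
    extra <- setdiff(names(nd), c("id", "kind", "params"))
    if (length(extra)) {
      stop("blueprint: unknown node field(s) at '", nd$id %||% "?", "': ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    bp_node(nd$id, nd$kind, .simplify_params(nd$params %||% list()))
  })
  edges <- lapply(obj$edges, function(e) {
    extra <- setdiff(names(e), c("from", "from_port", "to", "to_port"))
    if (length(extra)) {
      stop("blueprint: unknown edge field(s): ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    bp_edge(e$from, e$from_port, e$to, e$to_port)
  })
  blueprint(nodes, edges, lapply(obj$metadata %||% list(), identity))
}

# fromJSON(simplifyVector = FALSE) leaves every vector as a list; collapse
# unnamed lists of scalars back to atomic vectors, recurse into named lists.
.simplify_params <- function(p) {
  lapply(p, function(v) {
    if (is.list(v)) {
      if (is.null(names(v)) &&
          all(vapply(v, function(x) is.atomic(x) && length(x) == 1L, TRUE))) {
        unlist(v)
      } else {
        .simplify_params(v)
      }
    } else {
      v
    }
  })
}

#' Write / read a blueprint file
#'
#' @param bp A [blueprint()].
#' @param path File path.
#' @return `write_blueprint` returns `path` invisibly; `read_blueprint`
#'   returns the [blueprint()].
#' @export
write_blueprint <- function(bp, path) {
  writeLines(sub("\n$", "", serialize_blueprint(bp)), path)
  invisible(path)
}

#' @rdname write_blueprint
#' @export
read_blueprint <- function(path) {
  deserialize_blueprint(paste(readLines(path, warn = FALSE), collapse = "\n"))
}
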