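## Declarative dataflow graphs: typed nodes, DAG validation, nested groups,
## externalized properties, a YAML workflow format and a builder that
## compiles a graph against an operator registry into a live pipeline.

NODE_CATEGORIES <- c("source", "combinator", "transform", "condition",
                     "sink", "property", "nested")

category_arity <- function(category) {
  switch(category,
    source = c(0L, 0L),
    transform = ,
    condition = ,
    sink = ,
    property = c(1L, 1L),
    combinator = ,
    nested = c(0L, .Machine$integer.max),
    stop("unknown category: ", category))
}

#' Construct a dataflow node
#'
#' @param id Unique node id.
#' @param category One of `source`, `combinator`, `transform`, `condition`,
#'   `sink`, `property`, `nested` (input arity is fixed by the category:
#'   sources take 0 inputs, transforms/conditions/sinks/properties exactly 1,
#'   combinators and nested groups 0..N).
#' @param operator Registered operator name.
#' @param params Named list of operator parameters.
#' @param properties Names of parameters exposed for property binding.
#' @return A list of class `stream_node`.
#' @export
stream_node <- function(id, category, operator, params = list(),
                        properties = character(0)) {
  stopifnot(is.character(id), length(id) == 1L)
  structure(list(id = id, category = category, operator = operator,
                 params = params, properties = properties),
            class = "stream_node")
}

#' Construct a dataflow graph
#'
#' @param nodes List of [stream_node()]s.
#' @param edges List of `list(from =, to =, slot =)` entries; `slot` is the
#'   0-based input position on the target (edge order defines slot order for
#'   multi-input combinators when `slot` is omitted).
#' @param groups Named list mapping each nested node's id to its inner
#'   `dataflow_graph`. Inner graphs use `input` placeholder sources (one per
#'   external input, with a 0-based `index` param) and exactly one `output`
#'   sink marking the group's result.
#' @return A list of class `dataflow_graph`.
#' @export
dataflow_graph <- function(nodes, edges = list(), groups = list()) {
  edges <- lapply(edges, function(e) {
    if (is.null(e$slot)) e$slot <- NA_integer_
    e
  })
  # default slots: position among the target's inbound edges, in edge order
  counts <- new.env(parent = emptyenv())
  edges <- lapply(edges, function(e) {
    if (is.na(e$slot)) {
      k <- counts[[e$to]] %||% 0L
      e$slot <- k
      counts[[e$to]] <- k + 1L
    } else {
      counts[[e$to]] <- max(counts[[e$to]] %||% 0L, e$slot + 1L)
    }
    e
  })
  structure(list(nodes = nodes, edges = edges, groups = groups),
            class = "dataflow_graph")
}

graph_node_ids <- function(graph)
  vapply(graph$nodes, `[[`, character(1), "id")

graph_node <- function(graph, id) {
  for (n in graph$nodes) if (n$id == id) return(n)
  NULL
}

inbound_edges <- function(graph, id) {
  es <- Filter(function(e) e$to == id, graph$edges)
  es[order(vapply(es, `[[`, numeric(1), "slot"))]
}

#' Validate a dataflow graph
#'
#' Checks the structural invariants — unique known-category nodes, edges
#' between existing nodes, per-category input arity, acyclicity (a data
#' stream cannot loop back on itself), property targets, nested-group
#' placeholder/output structure, and (when a registry is supplied) operator
#' existence. Returns diagnostics naming the offending node and rule; an
#' empty character vector means the graph is valid.
#'
#' @param graph A [dataflow_graph()].
#' @param registry Optional operator registry for operator checks.
#' @return Character vector of diagnostics (empty iff valid).
#' @export
validate_graph <- function(graph, registry = NULL) {
  diags <- character(0)
  ids <- graph_node_ids(graph)
  if (anyDuplicated(ids)) {
    diags <- c(diags, paste0("duplicate: node id '",
                             ids[duplicated(ids)][1], "' is not unique"))
  }
  for (n in graph$nodes) {
    if (!(n$category %in% NODE_CATEGORIES)) {
      diags <- c(diags, paste0("category: node '", n$id,
                               "' has unknown category '", n$category, "'"))
    }
    if (!is.null(registry) && !(n$category %in% c("nested", "property")) &&
        is.null(registry$ops[[n$operator]])) {
      diags <- c(diags, paste0("operator: node '", n$id,
                               "' uses unregistered operator '",
                               n$operator, "'"))
    }
  }
  for (e in graph$edges) {
    if (!(e$from %in% ids)) {
      diags <- c(diags, paste0("edge: unknown source node '", e$from, "'"))
    }
    if (!(e$to %in% ids)) {
      diags <- c(diags, paste0("edge: unknown target node '", e$to, "'"))
    }
  }
  for (n in graph$nodes) {
    if (!(n$category %in% NODE_CATEGORIES)) next
    k <- length(inbound_edges(graph, n$id))
    lim <- category_arity(n$category)
    if (k < lim[1] || k > lim[2]) {
      diags <- c(diags, paste0("arity: node '", n$id, "' (", n$category,
                               ") has ", k, " inputs, expects ",
                               if (lim[1] == lim[2]) lim[1]
                               else paste0(lim[1], "..N")))
    }
    slots <- vapply(inbound_edges(graph, n$id), `[[`, numeric(1), "slot")
    if (anyDuplicated(slots)) {
      diags <- c(diags, paste0("slot: node '", n$id,
                               "' has duplicate input slots"))
    }
  }
  # acyclicity (Kahn)
  if (all(c(vapply(graph$edges, `[[`, character(1), "from"),
            vapply(graph$edges, `[[`, character(1), "to")) %in% ids)) {
    indeg <- stats::setNames(integer(length(ids)), ids)
    for (e in graph$edges) indeg[e$to] <- indeg[e$to] + 1L
    queue <- names(indeg)[indeg == 0L]
    seen <- 0L
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]; seen <- seen + 1L
      for (e in graph$edges) {
        if (e$from == v) {
          indeg[e$to] <- indeg[e$to] - 1L
          if (indeg[e$to] == 0L) queue <- c(queue, e$to)
        }
      }
    }
    if (seen < length(ids)) {
      diags <- c(diags, paste0("cycle: involving node(s) ",
                               paste(names(indeg)[indeg > 0L],
                                     collapse = ", ")))
    }
  }
  for (n in graph$nodes) {
    if (n$category == "property") {
      tgt <- n$params$target
      if (is.null(tgt) || !(tgt %in% ids)) {
        diags <- c(diags, paste0("property: node '", n$id,
                                 "' targets unknown node '",
                                 tgt %||% "<missing>", "'"))
      }
      if (is.null(n$params$property)) {
        diags <- c(diags, paste0("property: node '", n$id,
                                 "' does not name a target property"))
      }
    }
    if (n$category == "nested") {
      g2 <- graph$groups[[n$id]]
      if (is.null(g2)) {
        diags <- c(diags, paste0("group: nested node '", n$id,
                                 "' has no inner graph"))
        next
      }
      n_in <- length(inbound_edges(graph, n$id))
      inner_inputs <- Filter(function(m) m$operator == "input", g2$nodes)
      inner_outputs <- Filter(function(m) m$operator == "output", g2$nodes)
      if (length(inner_inputs) != n_in) {
        diags <- c(diags, paste0("group: nested node '", n$id, "' has ",
                                 n_in, " external inputs but ",
                                 length(inner_inputs),
                                 " input placeholders"))
      }
      if (length(inner_outputs) != 1L) {
        diags <- c(diags, paste0("group: nested node '", n$id,
                                 "' must have exactly one output sink"))
      }
      diags <- c(diags, validate_graph(g2, registry))
    }
  }
  diags
}

## ---- operator registry --------------------------------------------------

#' Operator registry
#'
#' A name-to-factory table. Each factory is called as
#' `factory(penv, inputs, ctx)` where `penv` is the node's parameter
#' environment (mutated at runtime by bound properties, so factories that
#' support binding read it per element), `inputs` the list of input
#' observables in slot order, and `ctx` the build context (`scheduler`,
#' `fixtures`, `out_dir`, `logs`, `node_id`, `inputs` for group
#' placeholders). Factories return the node's output observable.
#'
#' @param registry A registry created by `operator_registry()`.
#' @param name Operator name.
#' @param category Node category the operator belongs to.
#' @param factory Factory function (see above).
#' @return `operator_registry()` returns an empty registry;
#'   [default_registry()] one with the built-in operators.
#' @export
operator_registry <- function() {
  r <- new.env(parent = emptyenv())
  r$ops <- list()
  class(r) <- "operator_registry"
  r
}

#' @rdname operator_registry
#' @export
register_operator <- function(registry, name, category, factory) {
  stopifnot(category %in% NODE_CATEGORIES || category == "nested")
  registry$ops[[name]] <- list(category = category, factory = factory)
  invisible(registry)
}

resolve_function <- function(name) {
  if (is.function(name)) return(name)
  for (env in list(globalenv(), asNamespace("rivulet"), baseenv())) {
    if (exists(name, envir = env, mode = "function")) {
      return(get(name, envir = env, mode = "function"))
    }
  }
  stop("cannot resolve function '", name, "'")
}

#' @rdname operator_registry
#' @export
default_registry <- function() {
  r <- operator_registry()
  reg <- function(name, category, factory)
    register_operator(r, name, category, factory)

  ## sources
  reg("marble", "source", function(p, ins, ctx)
    marble_source(ctx$scheduler, p$text, tick = p$tick %||% 1,
                  values = as.list(p$values %||% list()),
                  hot = p$hot %||% TRUE))
  reg("events", "source", function(p, ins, ctx)
    events_stream(ctx$scheduler, times = unlist(p$times),
                  complete_at = p$complete_at))
  reg("timer", "source", function(p, ins, ctx)
    timer_stream(ctx$scheduler, p$delay))
  reg("fixture", "source", function(p, ins, ctx) {
    s <- ctx$fixtures[[p$name]]
    if (is.null(s)) stop("unknown fixture '", p$name, "'")
    s
  })
  reg("input", "source", function(p, ins, ctx) {
    idx <- (p$index %||% 0) + 1
    s <- ctx$inputs[[idx]]
    if (is.null(s)) stop("group input placeholder ", idx, " not bound")
    s
  })

  ## transforms
  reg("map", "transform", function(p, ins, ctx) {
    fn <- resolve_function(p$fn)
    rx_map(ins[[1]], fn)
  })
  reg("rescale", "transform", function(p, ins, ctx)
    rx_map(ins[[1]], function(x)
      rescale(x, p$min %||% 0, p$max %||% 1,
              p$range_min %||% 0, p$range_max %||% 1)))
  reg("grayscale", "transform", function(p, ins, ctx)
    rx_map(ins[[1]], grayscale))
  reg("track_largest", "transform", function(p, ins, ctx)
    track_largest(ins[[1]], lo = p$lo %||% 128, hi = p$hi %||% 255,
                  invert = p$invert %||% FALSE, penv = p))

  ## conditions
  reg("filter", "condition", function(p, ins, ctx) {
    fn <- resolve_function(p$fn)
    rx_filter(ins[[1]], fn)
  })
  reg("above", "condition", function(p, ins, ctx)
    rx_filter(ins[[1]], function(x) x >= p$threshold))
  reg("in_range", "condition", function(p, ins, ctx)
    rx_filter(ins[[1]], function(x) x >= (p$lo %||% -Inf) &&
                x <= (p$hi %||% Inf)))

  ## sinks
  reg("log", "sink", function(p, ins, ctx) {
    id <- ctx$node_id
    ctx$logs[[id]] <- list()
    rx_sink(ins[[1]], function(v) {
      ctx$logs[[id]][[length(ctx$logs[[id]]) + 1L]] <-
        list(time = ctx$scheduler$clock, value = v)
    })
  })
  reg("csv", "sink", function(p, ins, ctx) {
    id <- ctx$node_id
    ctx$logs[[id]] <- list()
    collected <- rx_sink(ins[[1]], function(v) {
      ctx$logs[[id]][[length(ctx$logs[[id]]) + 1L]] <-
        list(time = ctx$scheduler$clock, value = v)
    })
    path <- if (!is.null(ctx$out_dir))
      file.path(ctx$out_dir, p$path) else p$path
    new_observable(ctx$scheduler, function(obs, sub) {
      up <- subscribe(collected,
        on_next = obs$on_next,
        on_completed = function() {
          write_notification_csv(ctx$logs[[id]], path)
          obs$on_completed()
        },
        on_error = obs$on_error)
      add_teardown(sub, function() dispose(up))
    })
  })
  reg("frame_writer", "sink", function(p, ins, ctx) {
    path <- if (!is.null(ctx$out_dir))
      file.path(ctx$out_dir, p$path) else p$path
    frame_writer(ins[[1]], path)
  })
  reg("raw_binary", "sink", function(p, ins, ctx) {
    path <- if (!is.null(ctx$out_dir))
      file.path(ctx$out_dir, p$path) else p$path
    raw_binary_sink(ins[[1]], path)
  })
  reg("output", "sink", function(p, ins, ctx) ins[[1]])

  ## combinators
  reg("sample", "combinator", function(p, ins, ctx)
    rx_sample(ins[[1]], ins[[2]]))
  reg("merge", "combinator", function(p, ins, ctx) rx_merge(ins))
  reg("take", "combinator", function(p, ins, ctx) rx_take(ins[[1]], p$n))
  reg("timestamp", "combinator", function(p, ins, ctx)
    rx_timestamp(ins[[1]]))
  reg("moving_average", "combinator", function(p, ins, ctx)
    moving_average(ins[[1]], p$k))
  reg("window_count", "combinator", function(p, ins, ctx)
    window_count(ins[[1]], p$count, p$skip %||% p$count))
  reg("window_time", "combinator", function(p, ins, ctx)
    window_time(ins[[1]], p$duration))
  reg("window_trigger", "combinator", function(p, ins, ctx)
    window_trigger(ins[[1]], ins[[2]]))
  r
}

write_notification_csv <- function(entries, path) {
  repr <- function(v) {
    if (is.list(v)) paste(deparse(unclass(v), control = NULL), collapse = "")
    else paste(format(v), collapse = ";")
  }
  df <- data.frame(
    tick = vapply(entries, `[[`, numeric(1), "time"),
    payload = vapply(entries, function(e) repr(e$value), character(1)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

## ---- builder ------------------------------------------------------------

# Per-call frames: factories and inner-blueprint closures may evaluate their
# arguments lazily (first property read can happen ticks after the build
# loop finished), so each instantiation gets its own frame rather than the
# builder's loop frame.
call_factory <- function(factory, penv, ins, ctx) {
  force(penv); force(ins); force(ctx)
  factory(penv, ins, ctx)
}

make_select_many_node <- function(wins, g2, scheduler, registry, fixtures,
                                  out_dir) {
  rx_share(select_many(wins, inner = function(w) {
    p <- build_graph(g2, scheduler, registry, fixtures, out_dir,
                     inputs = list(w))
    p$output
  }))
}

topo_order <- function(graph) {
  ids <- graph_node_ids(graph)
  indeg <- stats::setNames(integer(length(ids)), ids)
  for (e in graph$edges) indeg[e$to] <- indeg[e$to] + 1L
  order <- character(0)
  queue <- ids[indeg[ids] == 0L]  # preserves node declaration order
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    order <- c(order, v)
    for (e in graph$edges) {
      if (e$from == v) {
        indeg[e$to] <- indeg[e$to] - 1L
        if (indeg[e$to] == 0L) queue <- c(queue, e$to)
      }
    }
  }
  order
}

#' Compile a dataflow graph into a live pipeline
#'
#' Validates, instantiates nodes in topological order against the operator
#' registry, wires property nodes into their target's parameter environment
#' (updates become visible before any later-tick element), instantiates
#' nested nodes as encapsulated sub-pipelines (`group`) or per-window
#' dataflows (`select_many`), multicasts every node output (one upstream
#' run per node however many taps attach), and subscribes the sinks so the
#' pipeline runs as the scheduler advances.
#'
#' @param graph A valid [dataflow_graph()].
#' @param scheduler A [virtual_scheduler()].
#' @param registry Operator registry (defaults to [default_registry()]).
#' @param fixtures Named list of fixture observables for `fixture` sources.
#' @param out_dir Directory prefixed to sink file paths.
#' @param inputs Input observables for group placeholders (internal).
#' @return A list of class `dataflow_pipeline` with `taps` (named list of
#'   per-node output observables), `output` (the tap of the terminal
#'   node), `logs` (environment of `log`/`csv` sink collections), `graph`,
#'   `scheduler`.
#' @export
build_graph <- function(graph, scheduler, registry = default_registry(),
                        fixtures = list(), out_dir = NULL, inputs = list()) {
  diags <- validate_graph(graph, registry)
  if (length(diags)) {
    stop("invalid graph:\n", paste0("  - ", diags, collapse = "\n"))
  }
  logs <- new.env(parent = emptyenv())
  penvs <- list()
  for (n in graph$nodes) {
    penvs[[n$id]] <- list2env(as.list(n$params), parent = emptyenv())
  }
  taps <- list()
  subs <- list()
  order <- topo_order(graph)
  for (id in order) {
    n <- graph_node(graph, id)
    ins <- lapply(inbound_edges(graph, id),
                  function(e) taps[[e$from]])
    ctx <- list(scheduler = scheduler, fixtures = fixtures,
                out_dir = out_dir, logs = logs, node_id = id,
                inputs = inputs)
    if (n$category == "property") {
      # the property stream writes into the target's parameter environment
      src <- ins[[1]]
      tgt_env <- penvs[[n$params$target]]
      field <- n$params$property
      subs[[length(subs) + 1L]] <- bind_property(src, tgt_env, field)
      taps[[id]] <- src
    } else if (n$category == "nested") {
      g2 <- graph$groups[[id]]
      op <- n$operator
      if (op == "select_many") {
        taps[[id]] <- make_select_many_node(ins[[1]], g2, scheduler,
                                            registry, fixtures, out_dir)
      } else if (op == "group") {
        p <- build_graph(g2, scheduler, registry, fixtures, out_dir,
                         inputs = ins)
        taps[[id]] <- p$output
      } else {
        stop("build: nested node '", id, "' has unknown operator '", op, "'")
      }
    } else {
      entry <- registry$ops[[n$operator]]
      if (is.null(entry)) {
        stop("build: node '", id, "' uses unregistered operator '",
             n$operator, "'")
      }
      out <- call_factory(entry$factory, penvs[[id]], ins, ctx)
      if (!inherits(out, "observable")) {
        stop("build: operator '", n$operator, "' of node '", id,
             "' did not return an observable")
      }
      taps[[id]] <- rx_share(out)
    }
  }
  # activate sinks and terminal nodes
  outbound <- vapply(graph$edges, `[[`, character(1), "from")
  terminal <- setdiff(order, outbound)
  for (id in order) {
    n <- graph_node(graph, id)
    if (n$category == "sink" || id %in% terminal) {
      if (n$category == "property") next
      subs[[length(subs) + 1L]] <- subscribe(taps[[id]])
    }
  }
  output_id <- if (length(terminal)) terminal[length(terminal)] else
    order[length(order)]
  structure(list(taps = taps, output = taps[[output_id]], logs = logs,
                 graph = graph, scheduler = scheduler,
                 subscriptions = subs),
            class = "dataflow_pipeline")
}

## ---- workflow files -----------------------------------------------------

node_to_list <- function(n) {
  list(id = n$id, category = n$category, operator = n$operator,
       params = n$params, properties = as.list(n$properties))
}

graph_to_list <- function(g) {
  list(nodes = lapply(g$nodes, node_to_list),
       edges = lapply(g$edges, function(e)
         list(from = e$from, to = e$to, slot = e$slot)),
       groups = lapply(g$groups, graph_to_list))
}

list_to_node <- function(x, where) {
  for (f in c("id", "category", "operator")) {
    if (is.null(x[[f]])) stop("workflow parse error at ", where,
                              ": missing field '", f, "'")
  }
  if (!(x$category %in% NODE_CATEGORIES)) {
    stop("workflow parse error at ", where, ": unknown category '",
         x$category, "'")
  }
  stream_node(x$id, x$category, x$operator,
              params = as.list(x$params %||% list()),
              properties = as.character(unlist(x$properties %||%
                                                 character(0))))
}

list_to_graph <- function(x, where = "workflow") {
  nodes <- lapply(seq_along(x$nodes %||% list()), function(i)
    list_to_node(x$nodes[[i]], paste0(where, " node ", i)))
  edges <- lapply(seq_along(x$edges %||% list()), function(i) {
    e <- x$edges[[i]]
    if (is.null(e$from) || is.null(e$to)) {
      stop("workflow parse error at ", where, " edge ", i,
           ": missing from/to")
    }
    list(from = e$from, to = e$to, slot = e$slot %||% NA_integer_)
  })
  groups <- lapply(x$groups %||% list(), list_to_graph, where = where)
  names(groups) <- names(x$groups %||% list())
  dataflow_graph(nodes, edges, groups)
}

#' Save / load a workflow file
#'
#' Workflows are stored as YAML with top-level keys `nodes`, `edges` and
#' `groups` (see `inst/extdata/workflow-schema.json` for the schema; this
#' text format is an original design for this package).
#' `load_workflow(save_workflow(g))` is structurally identical to `g`.
#'
#' @param graph A [dataflow_graph()].
#' @param path File path.
#' @return `load_workflow()` returns a `dataflow_graph`.
#' @export
save_workflow <- function(graph, path) {
  yaml::write_yaml(graph_to_list(graph), path, precision = 12L)
  invisible(path)
}

#' @rdname save_workflow
#' @export
load_workflow <- function(path) {
  x <- tryCatch(suppressWarnings(yaml::read_yaml(path)), error = function(e)
    stop("workflow parse error: ", conditionMessage(e)))
  list_to_graph(x)
}

canonical_params <- function(p) {
  p <- lapply(p, function(v) {
    if (is.integer(v)) as.double(v)
    else if (is.list(v)) canonical_params(v)
    else v
  })
  if (is.null(names(p))) p else p[order(names(p))]
}

#' Structural graph equality
#'
#' Compares node lists, edge lists and nested groups field by field, with
#' numeric parameters compared on value (so a YAML round trip that turns
#' integers into doubles still compares equal).
#'
#' @param a,b [dataflow_graph()]s.
#' @return `TRUE` or `FALSE`.
#' @export
graph_equal <- function(a, b) {
  if (length(a$nodes) != length(b$nodes) ||
      length(a$edges) != length(b$edges) ||
      length(a$groups) != length(b$groups)) return(FALSE)
  for (i in seq_along(a$nodes)) {
    x <- a$nodes[[i]]; y <- b$nodes[[i]]
    if (!identical(x$id, y$id) || !identical(x$category, y$category) ||
        !identical(x$operator, y$operator)) return(FALSE)
    if (!isTRUE(all.equal(canonical_params(x$params),
                          canonical_params(y$params)))) return(FALSE)
    if (!identical(as.character(x$properties),
                   as.character(y$properties))) return(FALSE)
  }
  for (i in seq_along(a$edges)) {
    x <- a$edges[[i]]; y <- b$edges[[i]]
    if (!identical(x$from, y$from) || !identical(x$to, y$to) ||
        !isTRUE(all.equal(as.numeric(x$slot), as.numeric(y$slot))))
      return(FALSE)
  }
  if (!identical(sort(names(a$groups)), sort(names(b$groups))))
    return(FALSE)
  for (nm in names(a$groups)) {
    if (!graph_equal(a$groups[[nm]], b$groups[[nm]])) return(FALSE)
  }
  TRUE
}
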