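## Single- and multi-stream operators. Every operator subscribes to its
## source(s) with the contract-enforcing observer from subscribe(), forwards
## downstream through the observer it was handed, and registers upstream
## teardown so disposing the outer subscription releases the whole chain.
## Operators never change notification times: delivery is synchronous within
## the scheduled action that produced the source event.

#' Transform each element (map)
#'
#' One output value per input value, same times and order; terminals are
#' forwarded. `fn` raising converts the stream to an error.
#'
#' @param src An `observable`.
#' @param fn Unary function applied to each payload.
#' @return An `observable`.
#' @export
rx_map <- function(src, fn) {
  new_observable(src$scheduler, function(obs, sub) {
    up <- subscribe(src,
      on_next = function(value) {
        out <- tryCatch(list(v = fn(value)), error = function(e)
          structure(list(msg = conditionMessage(e)), class = "rx_fail"))
        if (inherits(out, "rx_fail")) obs$on_error(out$msg)
        else obs$on_next(out$v)
      },
      on_completed = obs$on_completed,
      on_error = obs$on_error)
    add_teardown(sub, function() dispose(up))
  })
}

#' Linear rescaling transform
#'
#' Maps `x` from `[min, max]` to `[range_min, range_max]`:
#' `(x - min) / (max - min) * (range_max - range_min) + range_min`.
#' The canonical user-defined scripting transform for calibrating raw sensor
#' values into meaningful units.
#'
#' @param x Numeric value(s).
#' @param min,max Input range.
#' @param range_min,range_max Output range.
#' @export
rescale <- function(x, min = 0, max = 1, range_min = 0, range_max = 1) {
  (x - min) / (max - min) * (range_max - range_min) + range_min
}

#' Drop elements failing a predicate (filter)
#'
#' @param src An `observable`.
#' @param pred Predicate on payloads; `TRUE` forwards at the original time.
#' @return An `observable`.
#' @export
rx_filter <- function(src, pred) {
  new_observable(src$scheduler, function(obs, sub) {
    up <- subscribe(src,
      on_next = function(value) {
        keep <- tryCatch(list(v = isTRUE(pred(value))), error = function(e)
          structure(list(msg = conditionMessage(e)), class = "rx_fail"))
        if (inherits(keep, "rx_fail")) obs$on_error(keep$msg)
        else if (keep$v) obs$on_next(value)
      },
      on_completed = obs$on_completed,
      on_error = obs$on_error)
    add_teardown(sub, function() dispose(up))
  })
}

#' Side effects without changing the stream (sink)
#'
#' The output is identical to the input in payloads, times and terminal;
#' `effect` runs once per value, before forwarding.
#'
#' @param src An `observable`.
#' @param effect Unary side-effecting function.
#' @return An `observable`.
#' @export
rx_sink <- function(src, effect) {
  new_observable(src$scheduler, function(obs, sub) {
    up <- subscribe(src,
      on_next = function(value) {
        res <- tryCatch({ effect(value); NULL }, error = function(e)
          conditionMessage(e))
        if (!is.null(res)) obs$on_error(res) else obs$on_next(value)
      },
      on_completed = obs$on_completed,
      on_error = obs$on_error)
    add_teardown(sub, function() dispose(up))
  })
}

#' Sample the latest value on a trigger
#'
#' At each trigger value, emits the most recent payload of `src` (repeating
#' an unchanged latest value on rapid triggers); nothing is emitted before
#' `src` produces its first value. The output completes when `src` completes;
#' an error on either input propagates.
#'
#' @param src Data stream.
#' @param trigger Trigger stream (same scheduler).
#' @return An `observable`.
#' @export
rx_sample <- function(src, trigger) {
  stopifnot(identical(src$scheduler, trigger$scheduler))
  new_observable(src$scheduler, function(obs, sub) {
    st <- new.env(parent = emptyenv())
    st$has <- FALSE
    st$latest <- NULL
    up1 <- subscribe(src,
      on_next = function(value) { st$has <- TRUE; st$latest <- value },
      on_completed = obs$on_completed,
      on_error = obs$on_error)
    up2 <- subscribe(trigger,
      on_next = function(value) if (st$has) obs$on_next(st$latest),
      on_completed = function() NULL,  # sampling just stops
      on_error = obs$on_error)
    add_teardown(sub, function() { dispose(up1); dispose(up2) })
  })
}

#' Truncate to the first n elements (take)
#'
#' Forwards the first `n` values and completes at the n-th element's tick
#' (same-tick completion — the state-exit semantics used by reactive state
#' machines). If the source ends earlier, its terminal is forwarded.
#'
#' @param src An `observable`.
#' @param n Positive integer.
#' @return An `observable`.
#' @export
rx_take <- function(src, n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != floor(n)) {
    stop("take: n must be a positive integer, got ", deparse(n))
  }
  new_observable(src$scheduler, function(obs, sub) {
    st <- new.env(parent = emptyenv())
    st$seen <- 0L
    up <- subscribe(src,
      on_next = function(value) {
        if (st$seen >= n) return(invisible(NULL))
        st$seen <- st$seen + 1L
        obs$on_next(value)
        if (st$seen >= n) obs$on_completed()
      },
      on_completed = obs$on_completed,
      on_error = obs$on_error)
    add_teardown(sub, function() dispose(up))
  })
}

#' Restart a stream blueprint when it completes (repeat)
#'
#' `factory()` must build a fresh observable per iteration. When iteration k
#' completes, iteration k+1 is subscribed at the same tick (via a same-tick
#' scheduler action, so delivery order stays deterministic). Errors are not
#' restarted. A blueprint that completes at its own subscription tick twice
#' in a row trips a "zero-time loop" error, guarding against infinite loops
#' that would freeze virtual time.
#'
#' @param factory Zero-argument function returning a fresh `observable`.
#' @return An `observable`.
#' @export
rx_repeat <- function(factory) {
  first <- factory()
  stopifnot(inherits(first, "observable"))
  sched <- first$scheduler
  new_observable(sched, function(obs, sub) {
    st <- new.env(parent = emptyenv())
    st$zero_runs <- 0L
    st$inner <- NULL
    start <- function(inst) {
      started_at <- sched$clock
      st$inner <- subscribe(inst,
        on_next = obs$on_next,
        on_completed = function() {
          if (sched$clock <= started_at) {
            st$zero_runs <- st$zero_runs + 1L
            if (st$zero_runs >= 2L) {
              obs$on_error("zero-time loop: blueprint completed twice without consuming ticks")
              return(invisible(NULL))
            }
          } else st$zero_runs <- 0L
          schedule_action(sched, sched$clock, function() {
            if (!sub$disposed) start(factory())
          })
        },
        on_error = obs$on_error)
    }
    add_teardown(sub, function() if (!is.null(st$inner)) dispose(st$inner))
    start(first)
  })
}

#' Merge several streams by time (merge)
#'
#' Interleaves all values in time order; simultaneous values across sources
#' fire in source subscription order. Completes when all sources complete;
#' the first error wins. An empty source list completes immediately.
#'
#' @param sources List of `observable`s on one scheduler.
#' @return An `observable`.
#' @export
rx_merge <- function(sources) {
  if (length(sources) == 0L) {
    stop("merge: need a scheduler; pass at least one source or use stream_of")
  }
  sched <- sources[[1]]$scheduler
  new_observable(sched, function(obs, sub) {
    st <- new.env(parent = emptyenv())
    st$remaining <- length(sources)
    ups <- vector("list", length(sources))
    for (i in seq_along(sources)) {
      ups[[i]] <- subscribe(sources[[i]],
        on_next = obs$on_next,
        on_completed = function() {
          st$remaining <- st$remaining - 1L
          if (st$remaining == 0L) obs$on_completed()
        },
        on_error = obs$on_error)
    }
    add_teardown(sub, function() for (u in ups) dispose(u))
  })
}

#' Attach the scheduler clock to each element (timestamp)
#'
#' Wraps each payload as a `timestamped` list with fields `value` and `time`
#' (the shared virtual clock at emission); timing is unchanged.
#'
#' @param src An `observable`.
#' @return An `observable` of `timestamped` values.
#' @export
rx_timestamp <- function(src) {
  sched <- src$scheduler
  rx_map(src, function(value)
    structure(list(value = value, time = sched$clock),
              class = "timestamped"))
}

#' Share one upstream subscription among many subscribers
#'
#' Multicasts `src` through a subject, subscribing upstream once on the first
#' subscriber. Used by the graph builder so that node taps and sinks observe
#' a single run of each node rather than re-triggering upstream side effects.
#'
#' @param src An `observable`.
#' @return An `observable`.
#' @export
rx_share <- function(src) {
  sched <- src$scheduler
  st <- new.env(parent = emptyenv())
  st$subj <- subject(sched)
  st$up <- NULL
  new_observable(sched, function(obs, sub) {
    st$subj$subscribe_impl(obs, sub)
    if (is.null(st$up)) {
      st$up <- subscribe(src,
        on_next = function(value) subject_next(st$subj, value),
        on_completed = function() subject_complete(st$subj),
        on_error = function(message) subject_error(st$subj, message))
    }
    invisible(NULL)
  })
}

## ---- externalized properties --------------------------------------------

#' Externalized node properties
#'
#' A property binding is a mutable cell holding the current value of a node
#' parameter. `bind_property()` subscribes a stream to the cell: each value
#' updates the cell before any element at a later tick is processed by the
#' node reading it (same-tick updates follow the scheduler's simultaneity
#' order; two updates at one tick resolve last-writer-wins).
#'
#' @param default Value used before the first update.
#' @param name Optional property name (for diagnostics).
#' @return `property_binding()`: an environment of class `property_binding`
#'   with field `value`.
#' @export
property_binding <- function(default, name = NULL) {
  b <- new.env(parent = emptyenv())
  b$value <- default
  b$name <- name
  class(b) <- "property_binding"
  b
}

#' @rdname property_binding
#' @param prop_stream Stream of property values.
#' @param binding A `property_binding` (or any environment) to update.
#' @param field Field name written on each update.
#' @return The subscription handle.
#' @export
bind_property <- function(prop_stream, binding, field = "value") {
  stopifnot(is.environment(binding))
  subscribe(prop_stream,
            on_next = function(value) assign(field, value, envir = binding))
}
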