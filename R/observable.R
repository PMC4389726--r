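## Push-based observable sequences over a virtual-time scheduler.
##
## The delivery contract is the usual one for observable sequences: zero or
## more NEXT notifications in non-decreasing time order, followed by at most
## one terminal (COMPLETED or ERROR); nothing is delivered after a terminal or
## after the subscription is disposed. The contract is enforced centrally by
## the safe observer that wraps every subscription, so individual operators
## only need to be correct in the common path.

#' Construct a notification
#'
#' A notification is one event on a stream: a value (`next`), a normal end
#' (`completed`) or an abnormal end (`error`), stamped with a virtual time.
#'
#' @param time Virtual time in ticks (non-negative).
#' @param value Payload (present only for `next`).
#' @param message Error text (present only for `error`).
#' @return A list of class `notification` with fields `time`, `kind`, and
#'   `value` or `message`.
#' @export
notify_next <- function(time, value) {
  structure(list(time = time, kind = "next", value = value),
            class = "notification")
}

#' @rdname notify_next
#' @export
notify_complete <- function(time) {
  structure(list(time = time, kind = "completed"), class = "notification")
}

#' @rdname notify_next
#' @export
notify_error <- function(time, message = "error") {
  structure(list(time = time, kind = "error", message = message),
            class = "notification")
}

#' @export
format.notification <- function(x, ...) {
  switch(x$kind,
    "next" = sprintf("next(%s)@%g", paste(format(x$value), collapse = ","), x$time),
    completed = sprintf("completed@%g", x$time),
    error = sprintf("error(%s)@%g", x$message, x$time))
}

#' @export
print.notification <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Build an observer
#'
#' @param on_next Called with each payload.
#' @param on_completed Called once on normal termination.
#' @param on_error Called once with an error message on abnormal termination.
#' @return A list of class `stream_observer`.
#' @export
observer <- function(on_next = function(value) NULL,
                     on_completed = function() NULL,
                     on_error = function(message) NULL) {
  structure(list(on_next = on_next, on_completed = on_completed,
                 on_error = on_error),
            class = "stream_observer")
}

#' Create an observable from a subscribe implementation
#'
#' `subscribe_impl(obs, sub)` receives a contract-enforcing observer `obs`
#' (fields `on_next`, `on_completed`, `on_error`) and the subscription handle
#' `sub`, and should register any upstream teardown with [add_teardown()].
#'
#' @param scheduler The [virtual_scheduler()] the stream runs on.
#' @param subscribe_impl Function of `(obs, sub)` performing the wiring.
#' @return A list of class `observable`.
#' @export
new_observable <- function(scheduler, subscribe_impl) {
  structure(list(scheduler = scheduler, subscribe_impl = subscribe_impl),
            class = "observable")
}

#' Subscribe to an observable
#'
#' Attaches an observer and returns a disposable handle. Delivery respects the
#' stream grammar `next* (completed | error)?`; an observer callback that
#' raises converts the subscription to `error` and releases upstream
#' resources. Disposing the handle stops all further delivery.
#'
#' @param stream An `observable`.
#' @param on_next,on_completed,on_error Callbacks (see [observer()]).
#' @param obs Alternatively, a ready-made [observer()].
#' @return A subscription handle (environment of class `subscription`).
#' @export
subscribe <- function(stream, on_next = NULL, on_completed = NULL,
                      on_error = NULL, obs = NULL) {
  stopifnot(inherits(stream, "observable"))
  if (is.null(obs)) {
    obs <- observer(on_next %||% function(value) NULL,
                    on_completed %||% function() NULL,
                    on_error %||% function(message) NULL)
  }
  sub <- new.env(parent = emptyenv())
  sub$disposed <- FALSE
  sub$terminated <- FALSE
  sub$teardowns <- list()
  class(sub) <- "subscription"

  finish <- function() {
    sub$terminated <- TRUE
    dispose(sub)
  }
  safe <- list(
    on_next = function(value) {
      if (sub$disposed || sub$terminated) return(invisible(NULL))
      tryCatch(obs$on_next(value), error = function(e) {
        if (!sub$terminated) {
          sub$terminated <- TRUE
          obs$on_error(conditionMessage(e))
          dispose(sub)
        }
      })
      invisible(NULL)
    },
    on_completed = function() {
      if (sub$disposed || sub$terminated) return(invisible(NULL))
      sub$terminated <- TRUE
      obs$on_completed()
      dispose(sub)
      invisible(NULL)
    },
    on_error = function(message) {
      if (sub$disposed || sub$terminated) return(invisible(NULL))
      sub$terminated <- TRUE
      obs$on_error(message)
      dispose(sub)
      invisible(NULL)
    }
  )
  stream$subscribe_impl(safe, sub)
  sub
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Register a teardown on a subscription
#' @param sub A subscription handle.
#' @param fn Zero-argument function run at disposal.
#' @export
add_teardown <- function(sub, fn) {
  if (sub$disposed) { fn(); return(invisible(sub)) }
  sub$teardowns[[length(sub$teardowns) + 1L]] <- fn
  invisible(sub)
}

#' Dispose a subscription
#'
#' Stops delivery and releases upstream resources (idempotent).
#' @param sub A subscription handle.
#' @export
dispose <- function(sub) {
  if (sub$disposed) return(invisible(sub))
  sub$disposed <- TRUE
  for (fn in sub$teardowns) fn()
  sub$teardowns <- list()
  invisible(sub)
}

## ---- subjects (hot multicast) ------------------------------------------

#' A subject: a hot, multicast observable that is pushed by its owner
#'
#' Subjects broadcast each pushed notification to all currently attached
#' subscribers; late subscribers miss earlier values, and a subscriber
#' arriving after termination receives only the terminal notification.
#'
#' @param scheduler The [virtual_scheduler()] the subject runs on.
#' @return An environment of class `c("subject", "observable")`.
#' @export
subject <- function(scheduler) {
  s <- new.env(parent = emptyenv())
  s$scheduler <- scheduler
  s$subscribers <- list()
  s$done <- FALSE
  s$err <- NULL
  s$key_counter <- 0L
  s$subscribe_impl <- function(obs, sub) {
    if (s$done) {
      if (is.null(s$err)) obs$on_completed() else obs$on_error(s$err)
      return(invisible(NULL))
    }
    s$key_counter <- s$key_counter + 1L
    key <- as.character(s$key_counter)
    s$subscribers[[key]] <- obs
    add_teardown(sub, function() s$subscribers[[key]] <- NULL)
    invisible(NULL)
  }
  class(s) <- c("subject", "observable")
  s
}

#' Push into a subject
#' @param s A [subject()].
#' @param value Payload to broadcast.
#' @param message Error text for [subject_error()].
#' @export
subject_next <- function(s, value) {
  if (s$done) return(invisible(NULL))
  for (obs in as.list(s$subscribers)) obs$on_next(value)
  invisible(NULL)
}

#' @rdname subject_next
#' @export
subject_complete <- function(s) {
  if (s$done) return(invisible(NULL))
  s$done <- TRUE
  for (obs in as.list(s$subscribers)) obs$on_completed()
  invisible(NULL)
}

#' @rdname subject_next
#' @export
subject_error <- function(s, message = "error") {
  if (s$done) return(invisible(NULL))
  s$done <- TRUE
  s$err <- message
  for (obs in as.list(s$subscribers)) obs$on_error(message)
  invisible(NULL)
}

## ---- cold and hot scripted sources -------------------------------------

#' Cold scripted stream
#'
#' Replays a list of [notify_next()]-style notifications for every
#' subscription, with times taken relative to the subscription tick. If the
#' script carries no terminal notification the stream simply never ends.
#'
#' @param scheduler A [virtual_scheduler()].
#' @param notifications List of `notification` objects with non-decreasing
#'   times.
#' @return An `observable`.
#' @export
cold_stream <- function(scheduler, notifications) {
  prio <- next_source_priority(scheduler)
  new_observable(scheduler, function(obs, sub) {
    base <- scheduler$clock
    deliver <- function(i) {
      if (i > length(notifications)) return(invisible(NULL))
      n <- notifications[[i]]
      schedule_action(scheduler, base + n$time, function() {
        if (sub$disposed) return(invisible(NULL))
        switch(n$kind,
          "next" = { obs$on_next(n$value); deliver(i + 1L) },
          completed = obs$on_completed(),
          error = obs$on_error(n$message %||% "error"))
      }, priority = prio)
    }
    if (length(notifications) == 0L) {
      schedule_action(scheduler, base, function() {
        if (!sub$disposed) obs$on_completed()
      }, priority = prio)
    } else {
      deliver(1L)
    }
    invisible(NULL)
  })
}

#' Hot scripted stream
#'
#' Schedules the scripted notifications at absolute virtual times as the
#' stream's single broadcast run; all current subscribers observe each event,
#' and subscribers attached after an event miss it.
#'
#' @inheritParams cold_stream
#' @return A [subject()] fed by the script.
#' @export
hot_stream <- function(scheduler, notifications) {
  s <- subject(scheduler)
  prio <- next_source_priority(scheduler)
  deliver <- function(i) {
    if (i > length(notifications)) return(invisible(NULL))
    n <- notifications[[i]]
    schedule_action(scheduler, n$time, function() {
      switch(n$kind,
        "next" = { subject_next(s, n$value); deliver(i + 1L) },
        completed = subject_complete(s),
        error = subject_error(s, n$message %||% "error"))
    }, priority = prio)
  }
  deliver(1L)
  s
}

#' Convenience scripted sources
#'
#' `stream_of()` builds a cold stream of values at given ticks;
#' `events_stream()` builds a hot stream of values at absolute ticks (the
#' usual shape for scripted keys, triggers and task events; it does not
#' terminate unless `complete_at` is given, so that pipelines driven by it
#' park quietly when the script runs out). `timer_stream()` is a cold
#' one-shot: it emits `value` `delay` ticks after subscription, then
#' completes.
#'
#' @param scheduler A [virtual_scheduler()].
#' @param values Payloads (recycled against `times`).
#' @param times Ticks.
#' @param complete Whether the cold stream completes after the last value.
#' @param complete_at Optional absolute completion tick for `events_stream`.
#' @param delay Ticks until the timer fires.
#' @param value Payload for the timer tick.
#' @return An `observable` (hot for `events_stream`).
#' @export
stream_of <- function(scheduler, values, times = seq_along(values) - 1,
                      complete = TRUE) {
  stopifnot(length(times) == length(values))
  ns <- mapply(function(v, t) notify_next(t, v), values, times,
               SIMPLIFY = FALSE)
  if (complete) {
    end <- if (length(times)) max(times) else 0
    ns <- c(ns, list(notify_complete(end)))
  }
  cold_stream(scheduler, ns)
}

#' @rdname stream_of
#' @export
events_stream <- function(scheduler, times, values = as.list(times),
                          complete_at = NULL) {
  stopifnot(length(times) == length(values))
  o <- order(times)
  ns <- mapply(function(v, t) notify_next(t, v), values[o], times[o],
               SIMPLIFY = FALSE)
  if (!is.null(complete_at)) ns <- c(ns, list(notify_complete(complete_at)))
  hot_stream(scheduler, ns)
}

#' @rdname stream_of
#' @export
timer_stream <- function(scheduler, delay, value = "tick") {
  cold_stream(scheduler, list(notify_next(delay, value),
                              notify_complete(delay)))
}

## ---- recording ----------------------------------------------------------

#' Record a stream's notifications
#'
#' Subscribes immediately and logs every notification with the scheduler
#' clock at delivery. Use [recorded_log()] to extract the log as a list of
#' `notification` objects after driving the scheduler.
#'
#' @param stream An `observable`.
#' @return A recorder (environment) with fields `log` and `subscription`.
#' @export
record <- function(stream) {
  rec <- new.env(parent = emptyenv())
  rec$log <- list()
  sched <- stream$scheduler
  push <- function(n) rec$log[[length(rec$log) + 1L]] <- n
  rec$subscription <- subscribe(stream,
    on_next = function(value) push(notify_next(sched$clock, value)),
    on_completed = function() push(notify_complete(sched$clock)),
    on_error = function(message) push(notify_error(sched$clock, message)))
  class(rec) <- "stream_recorder"
  rec
}

#' @rdname record
#' @param rec A recorder from [record()].
#' @export
recorded_log <- function(rec) rec$log

#' Compare two notification logs
#'
#' Notification-by-notification equality on `(time, kind, payload/message)`.
#' @param a,b Lists of `notification` objects.
#' @return `TRUE` or `FALSE`.
#' @export
logs_equal <- function(a, b) {
  if (length(a) != length(b)) return(FALSE)
  for (i in seq_along(a)) {
    x <- a[[i]]; y <- b[[i]]
    if (!isTRUE(all.equal(x$time, y$time)) || x$kind != y$kind) return(FALSE)
    if (x$kind == "next" && !identical(x$value, y$value)) return(FALSE)
    if (x$kind == "error" &&
        !identical(x$message %||% "error", y$message %||% "error")) return(FALSE)
  }
  TRUE
}
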