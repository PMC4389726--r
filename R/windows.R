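## Stream slicing into windows, each window itself an observable, plus the
## SelectMany pattern: instantiate a fresh inner dataflow per window and merge
## every instance's output by time.

new_window <- function(scheduler, id) {
  w <- subject(scheduler)
  w$window_id <- id
  w
}

#' Windows by element count
#'
#' A new window opens at source elements `0, skip, 2*skip, ...`; each window
#' closes after `count` elements or at source completion (trailing partial
#' windows are emitted, so concatenating windows with `skip == count`
#' reproduces the source exactly). Windows overlap when `skip < count`.
#' Each emitted payload is itself an observable (a hot window stream) with a
#' `window_id` field; the window is emitted downstream before its first
#' element is pushed, so per-window consumers never miss elements.
#'
#' @param src An `observable`.
#' @param count Window length in elements (`>= 1`).
#' @param skip Elements between window openings (`>= 1`).
#' @return An `observable` of window observables.
#' @export
window_count <- function(src, count, skip = count) {
  stopifnot(count >= 1, skip >= 1, count == floor(count), skip == floor(skip))
  sched <- src$scheduler
  new_observable(sched, function(obs, sub) {
    st <- new.env(parent = emptyenv())
    st$seen <- 0L       # source elements so far
    st$opened <- 0L     # windows opened so far
    st$open <- list()   # list of list(w = subject, n = fill count)
    up <- subscribe(src,
      on_next = function(value) {
        if (st$seen %% skip == 0) {
          w <- new_window(sched, st$opened)
          st$opened <- st$opened + 1L
          st$open[[length(st$open) + 1L]] <- list2env(
            list(w = w, n = 0L), parent = emptyenv())
          obs$on_next(w)
        }
        st$seen <- st$seen + 1L
        keep <- logical(length(st$open))
        for (i in seq_along(st$open)) {
          slot <- st$open[[i]]
          subject_next(slot$w, value)
          slot$n <- slot$n + 1L
          if (slot$n >= count) subject_complete(slot$w) else keep[i] <- TRUE
        }
        st$open <- st$open[keep]
      },
      on_completed = function() {
        for (slot in st$open) subject_complete(slot$w)
        st$open <- list()
        obs$on_completed()
      },
      on_error = function(message) {
        for (slot in st$open) subject_error(slot$w, message)
        st$open <- list()
        obs$on_error(message)
      })
    add_teardown(sub, function() dispose(up))
  })
}

#' Windows by fixed time intervals
#'
#' Virtual time is split into half-open intervals `[k*duration,
#' (k+1)*duration)`; each element joins the interval active at its arrival
#' tick (an element exactly on a boundary belongs to the later window).
#' Element-free intervals still yield (empty) windows, so window indices
#' track wall time up to source completion.
#'
#' @param src An `observable`.
#' @param duration Interval length in ticks (`> 0`).
#' @return An `observable` of window observables.
#' @export
window_time <- function(src, duration) {
  stopifnot(duration > 0)
  sched <- src$scheduler
  new_observable(sched, function(obs, sub) {
    st <- new.env(parent = emptyenv())
    st$cur_k <- 0L
    st$w <- new_window(sched, 0L)
    obs$on_next(st$w)
    roll_to <- function(k) {
      while (st$cur_k < k) {
        subject_complete(st$w)
        st$cur_k <- st$cur_k + 1L
        st$w <- new_window(sched, st$cur_k)
        obs$on_next(st$w)
      }
    }
    up <- subscribe(src,
      on_next = function(value) {
        roll_to(floor(sched$clock / duration))
        subject_next(st$w, value)
      },
      on_completed = function() {
        roll_to(floor(sched$clock / duration))
        subject_complete(st$w)
        obs$on_completed()
      },
      on_error = function(message) {
        subject_error(st$w, message)
        obs$on_error(message)
      })
    add_teardown(sub, function() dispose(up))
  })
}

#' Windows delimited by an external trigger
#'
#' The first window opens at subscription; each boundary value closes the
#' current window and opens the next (a boundary with no intervening elements
#' yields an empty window). Source completion closes the last window.
#'
#' @param src Data stream.
#' @param boundary Trigger stream on the same scheduler.
#' @return An `observable` of window observables.
#' @export
window_trigger <- function(src, boundary) {
  stopifnot(identical(src$scheduler, boundary$scheduler))
  sched <- src$scheduler
  new_observable(sched, function(obs, sub) {
    st <- new.env(parent = emptyenv())
    st$k <- 0L
    st$w <- new_window(sched, 0L)
    obs$on_next(st$w)
    up1 <- subscribe(src,
      on_next = function(value) subject_next(st$w, value),
      on_completed = function() {
        subject_complete(st$w)
        obs$on_completed()
      },
      on_error = function(message) {
        subject_error(st$w, message)
        obs$on_error(message)
      })
    up2 <- subscribe(boundary,
      on_next = function(value) {
        subject_complete(st$w)
        st$k <- st$k + 1L
        st$w <- new_window(sched, st$k)
        obs$on_next(st$w)
      },
      on_completed = function() NULL,
      on_error = function(message) {
        subject_error(st$w, message)
        obs$on_error(message)
      })
    add_teardown(sub, function() { dispose(up1); dispose(up2) })
  })
}

#' Process each window with a fresh inner dataflow (SelectMany)
#'
#' For every window, `inner` is called with the window observable and must
#' return an observable — a brand-new, state-isolated instance of the
#' encapsulated dataflow. All instances' outputs are merged by time
#' (same-tick outputs from overlapping windows fire lowest `window_id`
#' first, since inners are subscribed in window-open order). The result
#' completes once the outer stream and every inner instance complete.
#'
#' @param windows An observable of windows ([window_count()] and friends).
#' @param inner Blueprint: function of one window observable returning an
#'   observable.
#' @return An `observable` of merged inner outputs.
#' @export
select_many <- function(windows, inner) {
  sched <- windows$scheduler
  new_observable(sched, function(obs, sub) {
    st <- new.env(parent = emptyenv())
    st$active <- 0L
    st$outer_done <- FALSE
    st$inner_subs <- list()
    check_done <- function() {
      if (st$outer_done && st$active == 0L) obs$on_completed()
    }
    up <- subscribe(windows,
      on_next = function(w) {
        inst <- tryCatch(inner(w), error = function(e)
          structure(list(msg = conditionMessage(e)), class = "rx_fail"))
        if (inherits(inst, "rx_fail")) { obs$on_error(inst$msg); return(invisible(NULL)) }
        if (!inherits(inst, "observable")) {
          obs$on_error("select_many: inner blueprint did not return an observable")
          return(invisible(NULL))
        }
        st$active <- st$active + 1L
        isub <- subscribe(inst,
          on_next = obs$on_next,
          on_completed = function() {
            st$active <- st$active - 1L
            check_done()
          },
          on_error = obs$on_error)
        st$inner_subs[[length(st$inner_subs) + 1L]] <- isub
      },
      on_completed = function() {
        st$outer_done <- TRUE
        check_done()
      },
      on_error = obs$on_error)
    add_teardown(sub, function() {
      dispose(up)
      for (s in st$inner_subs) dispose(s)
    })
  })
}

#' Collect a stream and emit an aggregate at completion
#'
#' Accumulates every payload; at completion applies `fn` to the list of
#' values and, unless it returns `NULL`, emits the result before completing.
#' The natural inner dataflow for per-window summaries.
#'
#' @param src An `observable`.
#' @param fn Function of the collected value list; `NULL` suppresses output.
#' @return An `observable`.
#' @export
collect_stream <- function(src, fn) {
  new_observable(src$scheduler, function(obs, sub) {
    st <- new.env(parent = emptyenv())
    st$values <- list()
    up <- subscribe(src,
      on_next = function(value)
        st$values[[length(st$values) + 1L]] <- value,
      on_completed = function() {
        out <- tryCatch(list(v = fn(st$values)), error = function(e)
          structure(list(msg = conditionMessage(e)), class = "rx_fail"))
        if (inherits(out, "rx_fail")) { obs$on_error(out$msg); return(invisible(NULL)) }
        if (!is.null(out$v)) obs$on_next(out$v)
        obs$on_completed()
      },
      on_error = obs$on_error)
    add_teardown(sub, function() dispose(up))
  })
}

#' Moving average via sliding count windows
#'
#' The windowed construction of a running mean: sliding windows of `k`
#' elements (skip 1) are opened over the source and each complete window's
#' mean is emitted at the tick its last element arrives — i.e. the output is
#' time-shifted by the `k - 1` "future" samples each window waits for.
#' Trailing partial windows are dropped, so the output has
#' `max(0, n - k + 1)` elements for an `n`-element source.
#'
#' @param src An `observable` of numbers.
#' @param k Window length (`>= 1`).
#' @return An `observable` of numbers.
#' @export
moving_average <- function(src, k) {
  stopifnot(k >= 1, k == floor(k))
  select_many(window_count(src, count = k, skip = 1),
              inner = function(w) collect_stream(w, function(values) {
                if (length(values) == k) mean(unlist(values)) else NULL
              }))
}
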