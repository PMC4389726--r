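#' Marble-diagram scripts
#'
#' Marble diagrams encode a stream timeline as a string, one character per
#' tick:
#'
#' * `-` — one tick of silence
#' * `|` — normal completion
#' * `#` — error
#' * `(` ... `)` — a group of simultaneous notifications, all stamped with the
#'   tick of the opening parenthesis; the characters of the group still
#'   consume string positions, so time keeps counting through them
#' * any other character — a value notification, whose payload is looked up in
#'   `values` (falling back to the character itself)
#'
#' `marble()` bundles the script with its tick size and value map;
#' [parse_marble()] turns it into a notification list.
#'
#' @param text Marble string.
#' @param tick Ticks per character.
#' @param values Named list mapping symbols to payloads.
#' @return `marble()`: a list of class `marble`.
#' @examples
#' parse_marble("a-b|")        # a@0, b@2, completed@3
#' parse_marble("(ab)-c|")     # a@0, b@0, c@5, completed@6
#' @export
marble <- function(text, tick = 1, values = list()) {
  stopifnot(is.character(text), length(text) == 1L, tick > 0)
  structure(list(text = text, tick = tick, values = values),
            class = "marble")
}

#' Parse a marble script into notifications
#'
#' @param script A [marble()] or a bare string (tick 1, empty value map).
#' @param tick,values Used when `script` is a bare string.
#' @return List of `notification` objects in time order.
#' @export
parse_marble <- function(script, tick = 1, values = list()) {
  if (is.character(script)) script <- marble(script, tick, values)
  stopifnot(inherits(script, "marble"))
  chars <- strsplit(script$text, "", fixed = TRUE)[[1]]
  out <- list()
  terminal_seen <- FALSE
  group_start <- NA_real_
  in_group <- FALSE
  lookup <- function(sym) {
    if (!is.null(script$values[[sym]])) script$values[[sym]] else sym
  }
  for (i in seq_along(chars)) {
    ch <- chars[i]
    t <- (i - 1) * script$tick
    at <- if (in_group) group_start else t
    if (ch == "-") next
    if (ch == "(") {
      if (in_group) stop("marble parse error: nested '(' at position ", i)
      in_group <- TRUE
      group_start <- t
      next
    }
    if (ch == ")") {
      if (!in_group) stop("marble parse error: unmatched ')' at position ", i)
      in_group <- FALSE
      next
    }
    if (terminal_seen) {
      stop("marble parse error: symbol '", ch, "' after terminal at position ", i)
    }
    if (ch == "|") {
      out[[length(out) + 1L]] <- notify_complete(at)
      terminal_seen <- TRUE
    } else if (ch == "#") {
      out[[length(out) + 1L]] <- notify_error(at, "error")
      terminal_seen <- TRUE
    } else {
      out[[length(out) + 1L]] <- notify_next(at, lookup(ch))
    }
  }
  if (in_group) stop("marble parse error: unbalanced '(' in \"", script$text, "\"")
  out
}

#' Scripted source from a marble diagram
#'
#' @param scheduler A [virtual_scheduler()].
#' @param script A [marble()] or string.
#' @param tick,values Passed to [parse_marble()] for bare strings.
#' @param hot Hot (broadcast at absolute times, the default — matches how
#'   device sources behave) or cold (replay per subscription).
#' @return An `observable`.
#' @export
marble_source <- function(scheduler, script, tick = 1, values = list(),
                          hot = TRUE) {
  ns <- parse_marble(script, tick = tick, values = values)
  if (hot) hot_stream(scheduler, ns) else cold_stream(scheduler, ns)
}

#' Run a marble test
#'
#' Creates one hot source per input script on a fresh scheduler, applies
#' `pipeline` (a function taking the input observables as separate arguments
#' and returning an observable), records the output, advances virtual time
#' past the last scripted event, and compares the recorded log
#' notification-by-notification against the expected script.
#'
#' @param inputs List of [marble()]s / strings (may be empty for
#'   source-less pipelines).
#' @param pipeline Function of the input observables returning an observable.
#' @param expected Expected output as a [marble()] or string.
#' @param tick,values Defaults for bare-string scripts.
#' @return A list of class `marble_report` with fields `pass`, `actual`,
#'   `expected` and `mismatches` (character).
#' @export
run_marble_test <- function(inputs, pipeline, expected, tick = 1,
                            values = list()) {
  sched <- virtual_scheduler()
  srcs <- lapply(inputs, function(s)
    marble_source(sched, s, tick = tick, values = values, hot = TRUE))
  out <- do.call(pipeline, srcs)
  stopifnot(inherits(out, "observable"))
  rec <- record(out)
  exp_ns <- parse_marble(expected, tick = tick, values = values)
  horizon <- max(c(0, vapply(exp_ns, `[[`, numeric(1), "time"),
                   unlist(lapply(srcs, function(s) 0))))
  in_ns <- unlist(lapply(inputs, function(s)
    vapply(parse_marble(s, tick = tick, values = values), `[[`,
           numeric(1), "time")))
  horizon <- max(c(horizon, in_ns, 0)) + tick
  run_until_idle(sched)
  advance_to(sched, max(horizon, sched$clock))
  act <- recorded_log(rec)
  mism <- character(0)
  n <- max(length(act), length(exp_ns))
  for (i in seq_len(n)) {
    a <- if (i <= length(act)) format(act[[i]]) else "<none>"
    e <- if (i <= length(exp_ns)) format(exp_ns[[i]]) else "<none>"
    ok <- i <= length(act) && i <= length(exp_ns) &&
      logs_equal(act[i], exp_ns[i])
    if (!ok) mism <- c(mism, sprintf("[%d] expected %s, got %s", i, e, a))
  }
  structure(list(pass = length(mism) == 0L, actual = act,
                 expected = exp_ns, mismatches = mism),
            class = "marble_report")
}

#' @export
print.marble_report <- function(x, ...) {
  cat(if (x$pass) "PASS" else "FAIL", "\n")
  if (!x$pass) cat(paste0("  ", x$mismatches, collapse = "\n"), "\n")
  invisible(x)
}
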