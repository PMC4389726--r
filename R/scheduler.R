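#' Deterministic virtual-time scheduler
#'
#' All stream delivery in rivulet is driven by a virtual clock measured in
#' integer (or fractional) "ticks". Actions queued on the scheduler execute in
#' `(time, priority, sequence)` order: `time` is the requested tick, `priority`
#' is a per-source rank assigned when a source is created (so simultaneous
#' events from different sources fire in source-creation order, which equals
#' subscription order in every pipeline built by this package), and `sequence`
#' is assignment order, giving a deterministic tie-break for everything else.
#' The clock never decreases.
#'
#' @return An environment of class `virtual_scheduler`.
#' @examples
#' sched <- virtual_scheduler()
#' log <- c()
#' schedule_action(sched, 5, function() log <<- c(log, "b"))
#' schedule_action(sched, 3, function() log <<- c(log, "a"))
#' advance_to(sched, 10)
#' log  # "a" then "b": time order wins over queueing order
#' @export
virtual_scheduler <- function() {
  sched <- new.env(parent = emptyenv())
  sched$clock <- 0
  sched$seq <- 0L
  sched$times <- numeric(0)
  sched$prios <- numeric(0)
  sched$seqs <- integer(0)
  sched$actions <- list()
  sched$source_count <- 0L
  class(sched) <- "virtual_scheduler"
  sched
}

#' Current virtual time
#' @param sched A [virtual_scheduler()].
#' @return The scheduler clock in ticks.
#' @export
now <- function(sched) sched$clock

#' Assign a source priority rank
#'
#' Each event source takes a rank at creation; simultaneous notifications from
#' different sources are delivered in rank order. Internal bookkeeping actions
#' use `Inf` and therefore run after any same-tick source event.
#' @keywords internal
next_source_priority <- function(sched) {
  sched$source_count <- sched$source_count + 1L
  sched$source_count
}

#' Queue an action at a virtual time
#'
#' @param sched A [virtual_scheduler()].
#' @param time Tick at which to run; must be `>= now(sched)`.
#' @param action A zero-argument function.
#' @param priority Delivery rank for same-tick ordering; sources pass their
#'   creation rank, internal actions default to `Inf`.
#' @return The action's sequence number, invisibly.
#' @export
schedule_action <- function(sched, time, action, priority = Inf) {
  if (time < sched$clock) {
    stop("cannot schedule an action in the past (time ", time,
         " < clock ", sched$clock, ")")
  }
  sched$seq <- sched$seq + 1L
  sched$times <- c(sched$times, time)
  sched$prios <- c(sched$prios, priority)
  sched$seqs <- c(sched$seqs, sched$seq)
  sched$actions[[length(sched$actions) + 1L]] <- action
  invisible(sched$seq)
}

pop_due <- function(sched, horizon) {
  due <- which(sched$times <= horizon)
  if (length(due) == 0L) return(NULL)
  i <- due[order(sched$times[due], sched$prios[due], sched$seqs[due])[1L]]
  entry <- list(time = sched$times[i], action = sched$actions[[i]])
  sched$times <- sched$times[-i]
  sched$prios <- sched$prios[-i]
  sched$seqs <- sched$seqs[-i]
  sched$actions[[i]] <- NULL
  entry
}

#' Advance the virtual clock
#'
#' Executes every queued action with `time <= t` in `(time, priority, seq)`
#' order (actions may queue further actions, which are honoured if they fall
#' inside the horizon), then sets the clock to `t`.
#'
#' @param sched A [virtual_scheduler()].
#' @param t Target tick; moving backwards is a contract violation.
#' @export
advance_to <- function(sched, t) {
  if (t < sched$clock) {
    stop("virtual clock cannot move backwards (clock ", sched$clock,
         ", requested ", t, ")")
  }
  repeat {
    entry <- pop_due(sched, t)
    if (is.null(entry)) break
    if (entry$time > sched$clock) sched$clock <- entry$time
    entry$action()
  }
  sched$clock <- t
  invisible(sched)
}

#' @rdname advance_to
#' @param dt Ticks to advance by.
#' @export
advance_by <- function(sched, dt) advance_to(sched, sched$clock + dt)

#' Run until the action queue drains
#'
#' Repeatedly executes the earliest pending action until nothing is queued.
#' Suitable for pipelines whose sources are finite scripts; indefinitely
#' self-rescheduling pipelines should be driven with [advance_to()] instead.
#'
#' @param sched A [virtual_scheduler()].
#' @param max_actions Safety bound on executed actions; exceeding it is an
#'   error (it almost always indicates an unintended self-perpetuating loop).
#' @export
run_until_idle <- function(sched, max_actions = 1e6) {
  n <- 0L
  repeat {
    entry <- pop_due(sched, Inf)
    if (is.null(entry)) break
    if (entry$time > sched$clock) sched$clock <- entry$time
    entry$action()
    n <- n + 1L
    if (n > max_actions) stop("run_until_idle exceeded ", max_actions, " actions")
  }
  invisible(sched)
}
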