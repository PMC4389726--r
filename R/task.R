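## Reactive task control: state machines assembled from the take/repeat/
## window primitives, a reaction-time trial machine, and multi-site foraging
## with a coincidence-detector reward rule.

#' Specify one state of a reactive state machine
#'
#' A state is an encapsulated dataflow that activates when it receives an
#' input event: its entry actions fire at the activation tick, and the first
#' element (or completion) of its exit stream — the exit trigger is always
#' truncated with take(1) — hands control to the next state.
#'
#' @param name State name.
#' @param exit_trigger Zero-argument factory returning a fresh observable
#'   whose first element exits the state (e.g. a [timer_stream()] blueprint
#'   or a hot key stream).
#' @param entry_actions List of zero-argument functions run at activation.
#' @return A list of class `state_spec`.
#' @export
state_spec <- function(name, exit_trigger, entry_actions = list()) {
  stopifnot(is.character(name), is.function(exit_trigger))
  structure(list(name = name, exit_trigger = exit_trigger,
                 entry_actions = entry_actions),
            class = "state_spec")
}

#' Chain states into a runnable blueprint
#'
#' Returns a blueprint (zero-argument factory, suitable for [rx_repeat()])
#' producing an observable that, when subscribed, activates the states in
#' order: each state's take(1)-truncated exit stream feeds the next state's
#' activation at the exit tick. The stream emits one transition record
#' `(state, time)` per activation and completes when the last state exits.
#' An exit stream that completes without producing an element also advances
#' the machine (timers emit-then-complete, so both conventions chain).
#'
#' @param states Non-empty list of [state_spec()]s.
#' @param scheduler The [virtual_scheduler()] the machine runs on.
#' @return A blueprint function.
#' @export
chain_states <- function(states, scheduler) {
  if (length(states) == 0L) stop("chain_states: empty state list")
  stopifnot(all(vapply(states, inherits, logical(1), "state_spec")))
  function() {
    new_observable(scheduler, function(obs, sub) {
      st <- new.env(parent = emptyenv())
      st$exit_sub <- NULL
      activate <- function(k) {
        if (sub$disposed) return(invisible(NULL))
        if (k > length(states)) { obs$on_completed(); return(invisible(NULL)) }
        spec <- states[[k]]
        obs$on_next(list(state = spec$name, time = scheduler$clock))
        for (act in spec$entry_actions) act()
        exit_stream <- rx_take(spec$exit_trigger(), 1)
        st$exit_sub <- subscribe(exit_stream,
          on_next = function(value) NULL,
          on_completed = function() activate(k + 1L),
          on_error = obs$on_error)
      }
      add_teardown(sub, function()
        if (!is.null(st$exit_sub)) dispose(st$exit_sub))
      activate(1L)
    })
  }
}

#' Reaction-time trial machine
#'
#' The two-state Ready/Go cycle: Ready arms a timer of `timer_delay` ticks;
#' when it fires the machine enters Go and the stimulus turns on; the first
#' key event after stimulus onset closes the trial with
#' `rt = key time - stimulus time`, and the machine returns to Ready for the
#' next trial, indefinitely. Keys during Ready are ignored (the Go state
#' only starts listening at stimulus onset). Drive the scheduler with
#' [advance_to()] or feed a finite, non-terminating key script: when the
#' script runs out the machine parks in Go with nothing scheduled.
#'
#' @param scheduler A [virtual_scheduler()].
#' @param timer_delay Ticks from Ready entry to stimulus onset.
#' @param key_stream Hot observable of key presses.
#' @return An `observable` of `trial_record` lists
#'   `(trial, stimulus_time, response_time, rt)`.
#' @export
reaction_time_task <- function(scheduler, timer_delay, key_stream) {
  stopifnot(timer_delay > 0)
  trial_env <- new.env(parent = emptyenv())
  trial_env$stim <- NA_real_
  states <- list(
    state_spec("ready", exit_trigger = function()
      timer_stream(scheduler, timer_delay)),
    state_spec("go",
      exit_trigger = function() key_stream,
      entry_actions = list(function() trial_env$stim <- scheduler$clock)))
  transitions <- rx_repeat(chain_states(states, scheduler))
  st <- new.env(parent = emptyenv())
  st$trial <- 0L
  new_observable(scheduler, function(obs, sub) {
    up <- subscribe(transitions,
      on_next = function(tr) {
        if (tr$state == "ready" && !is.na(trial_env$stim)) {
          st$trial <- st$trial + 1L
          obs$on_next(structure(list(trial = st$trial,
                                     stimulus_time = trial_env$stim,
                                     response_time = tr$time,
                                     rt = tr$time - trial_env$stim),
                                class = "trial_record"))
          trial_env$stim <- NA_real_
        }
      },
      on_completed = obs$on_completed,
      on_error = obs$on_error)
    add_teardown(sub, function() dispose(up))
  })
}

#' Single-site foraging with a coincidence detector
#'
#' Each availability event (A) arms the site until `min(next A, A + w)`:
#' re-arming by a new A replaces the pending availability (a single-item
#' site — the previous item "rots" when replaced or when `w` ticks elapse).
#' The first sample event (S) while armed delivers a reward and disarms;
#' samples while unarmed do nothing. A sample exactly at `A + w` still
#' collects (closed window); a sample at the tick of a replacing A collects
#' the new item (A streams are subscribed first, so same-tick A precedes S).
#'
#' @param avail Hot observable of availability events (payloads ignored).
#' @param sample Hot observable of sampling events.
#' @param w Availability window in ticks (`> 0`).
#' @param site_id Index stamped on reward events.
#' @return An `observable` of `reward_event` lists
#'   `(site_id, time, availability_time)`. Completes when both inputs
#'   complete.
#' @export
foraging_site <- function(avail, sample, w, site_id = 0L) {
  if (!(is.numeric(w) && length(w) == 1L && w > 0)) {
    stop("foraging_site: availability window w must be > 0")
  }
  stopifnot(identical(avail$scheduler, sample$scheduler))
  sched <- avail$scheduler
  new_observable(sched, function(obs, sub) {
    st <- new.env(parent = emptyenv())
    st$armed <- FALSE
    st$avail_time <- NA_real_
    st$remaining <- 2L
    done <- function() {
      st$remaining <- st$remaining - 1L
      if (st$remaining == 0L) obs$on_completed()
    }
    up1 <- subscribe(avail,
      on_next = function(value) {
        st$armed <- TRUE
        st$avail_time <- sched$clock
      },
      on_completed = done,
      on_error = obs$on_error)
    up2 <- subscribe(sample,
      on_next = function(value) {
        if (st$armed && sched$clock <= st$avail_time + w) {
          obs$on_next(structure(list(site_id = site_id, time = sched$clock,
                                     availability_time = st$avail_time),
                                class = "reward_event"))
          st$armed <- FALSE
        } else if (st$armed) {
          st$armed <- FALSE  # rotted: window elapsed before this sample
        }
      },
      on_completed = done,
      on_error = obs$on_error)
    add_teardown(sub, function() { dispose(up1); dispose(up2) })
  })
}

#' Multi-site foraging by dataflow replication
#'
#' One independent [foraging_site()] per site, merged into a single reward
#' stream; simultaneous rewards at different sites are ordered by site
#' index. Adding a site never changes another site's rewards.
#'
#' @param sites List of per-site specs `list(avail =, sample =, w =)`.
#' @return An `observable` of `reward_event`s.
#' @export
foraging_multisite <- function(sites) {
  stopifnot(length(sites) >= 1L)
  streams <- lapply(seq_along(sites), function(i) {
    s <- sites[[i]]
    foraging_site(s$avail, s$sample, s$w, site_id = i - 1L)
  })
  rx_merge(streams)
}

#' State-space growth: product machine vs replicated dataflow
#'
#' For `n_sites` independent sites of `states_per_site` states each, a
#' single classical finite-state machine must enumerate every combination —
#' `states_per_site ^ n_sites` states — whereas the dataflow description
#' grows linearly: `n_sites * nodes_per_site` nodes.
#'
#' @param n_sites Number of independent sites.
#' @param states_per_site States per site.
#' @param nodes_per_site Dataflow nodes needed per site (default 4: the
#'   availability source, sampling source, coincidence detector and reward
#'   sink).
#' @return Named numeric vector `c(product_states, dataflow_nodes)`.
#' @export
fsm_explosion_count <- function(n_sites, states_per_site, nodes_per_site = 4) {
  stopifnot(n_sites >= 1, states_per_site >= 1)
  c(product_states = states_per_site^n_sites,
    dataflow_nodes = n_sites * nodes_per_site)
}

#' Reward events to a data frame / CSV
#'
#' @param events List of `reward_event`s.
#' @param path Optional CSV path.
#' @return Data frame with `site_id`, `time`, `availability_time`.
#' @export
reward_events_df <- function(events, path = NULL) {
  df <- data.frame(
    site_id = vapply(events, `[[`, numeric(1), "site_id"),
    time = vapply(events, `[[`, numeric(1), "time"),
    availability_time = vapply(events, `[[`, numeric(1), "availability_time"))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Trial records to a data frame / CSV
#'
#' @param trials List of `trial_record`s.
#' @param path Optional CSV path.
#' @return Data frame with `trial`, `stimulus_time`, `response_time`, `rt`.
#' @export
trial_records_df <- function(trials, path = NULL) {
  df <- data.frame(
    trial = vapply(trials, `[[`, numeric(1), "trial"),
    stimulus_time = vapply(trials, `[[`, numeric(1), "stimulus_time"),
    response_time = vapply(trials, `[[`, numeric(1), "response_time"),
    rt = vapply(trials, `[[`, numeric(1), "rt"))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
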