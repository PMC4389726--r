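# Conveniences for driving the engine in tests.

# Run a pipeline over scripted hot sources and return the recorded output
# log as plain entries (time, kind, value/message). `build` receives the
# source observables (created in script order, which fixes the simultaneity
# rank) and returns the observable under test.
run_pipeline <- function(scripts, build, horizon = NULL) {
  sched <- virtual_scheduler()
  srcs <- lapply(scripts, function(ns)
    hot_stream(sched, script_to_notifications(ns)))
  out <- do.call(build, c(srcs, list(sched = sched)))
  rec <- record(out)
  run_until_idle(sched)
  if (!is.null(horizon) && horizon > sched$clock) advance_to(sched, horizon)
  lapply(recorded_log(rec), unclass)
}

# normalize an oracle script/log for comparison: drop src/pos bookkeeping
norm_log <- function(ns) {
  lapply(ns, function(e) {
    out <- list(time = e$time, kind = e$kind)
    if (e$kind == "next") out$value <- e$value
    if (e$kind == "error") out$message <- e$message %||% "error"
    out
  })
}

expect_log_equal <- function(actual, expected, info = NULL) {
  a <- norm_log(actual)
  b <- norm_log(expected)
  expect_equal(a, b, info = info)
}

# Collect the contents of a stream of windows: one entry per window with its
# payload vector (NULL when empty), in window-id order.
collect_windows <- function(windows_obs, sched, horizon = NULL) {
  acc <- new.env(parent = emptyenv())
  acc$wins <- list()
  subscribe(windows_obs, on_next = function(w) {
    id <- w$window_id + 1L
    acc$wins[[id]] <- list(values = NULL)
    local({
      wid <- id
      subscribe(w, on_next = function(v) {
        acc$wins[[wid]]$values <- c(acc$wins[[wid]]$values, v)
      })
    })
  })
  run_until_idle(sched)
  if (!is.null(horizon) && horizon > sched$clock) advance_to(sched, horizon)
  lapply(acc$wins, function(w) w$values)
}

# values-only view of a log
log_values <- function(log) {
  lapply(Filter(function(e) e$kind == "next", log), `[[`, "value")
}

# Run every combinator against the replay oracle on n_cases random script
# pairs; returns a character vector naming any disagreements (empty = pass).
check_operators_against_oracle <- function(n_cases, seed = 20240601,
                                           with_error = FALSE,
                                           events_range = 0:12) {
  set.seed(seed)
  fails <- character(0)
  note <- function(tag, i) fails <<- c(fails, paste0(tag, "#", i))
  for (i in seq_len(n_cases)) {
    s1 <- random_script(n_events = sample(events_range, 1),
                        with_error = with_error)
    s2 <- random_script(n_events = sample(events_range, 1),
                        with_error = with_error)
    k <- sample(1:5, 1)
    fn <- function(x) x * 10 + 1
    pred <- function(x) x %% 2 == 0

    if (!isTRUE(all.equal(
      norm_log(run_pipeline(list(s1), function(s, sched) rx_map(s, fn))),
      norm_log(oracle_map(s1, fn))))) note("map", i)

    if (!isTRUE(all.equal(
      norm_log(run_pipeline(list(s1), function(s, sched) rx_filter(s, pred))),
      norm_log(oracle_filter(s1, pred))))) note("filter", i)

    if (!isTRUE(all.equal(
      norm_log(run_pipeline(list(s1), function(s, sched)
        rx_sink(s, function(v) NULL))),
      norm_log(oracle_map(s1, identity))))) note("sink", i)

    if (!isTRUE(all.equal(
      norm_log(run_pipeline(list(s1), function(s, sched) rx_take(s, k))),
      norm_log(oracle_take(s1, k))))) note("take", i)

    if (!isTRUE(all.equal(
      norm_log(run_pipeline(list(s1, s2), function(a, b, sched)
        rx_merge(list(a, b)))),
      norm_log(oracle_merge(list(s1, s2)))))) note("merge", i)

    if (!isTRUE(all.equal(
      norm_log(run_pipeline(list(s1, s2), function(s, t, sched)
        rx_sample(s, t))),
      norm_log(oracle_sample(s1, s2))))) note("sample", i)

    if (!isTRUE(all.equal(
      norm_log(run_pipeline(list(s1), function(s, sched) rx_timestamp(s))),
      norm_log(oracle_timestamp(s1))))) note("timestamp", i)
  }
  fails
}

# moving average of a numeric vector through the windowed engine path
run_ma <- function(x, k) {
  sched <- virtual_scheduler()
  src <- events_stream(sched, times = seq_along(x) - 1, values = as.list(x),
                       complete_at = length(x) - 1)
  collect_values(moving_average(src, k), sched)
}

collect_values <- function(obs, sched, horizon = NULL) {
  got <- new.env(parent = emptyenv())
  got$x <- list()
  subscribe(obs, on_next = function(v) got$x[[length(got$x) + 1L]] <- v)
  run_until_idle(sched)
  if (!is.null(horizon) && horizon > sched$clock) advance_to(sched, horizon)
  got$x
}
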