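test_that("chained states log transitions at exit ticks", {
  sched <- virtual_scheduler()
  keys <- events_stream(sched, c(7, 20))
  machine <- chain_states(list(
    state_spec("ready", function() timer_stream(sched, 4)),
    state_spec("go", function() keys)), sched)
  log <- collect_values(machine(), sched, horizon = 30)
  expect_equal(vapply(log, `[[`, character(1), "state"), c("ready", "go"))
  expect_equal(vapply(log, `[[`, numeric(1), "time"), c(0, 4))
})

test_that("entry actions fire at the activation tick", {
  sched <- virtual_scheduler()
  fired <- c()
  machine <- chain_states(list(
    state_spec("a", function() timer_stream(sched, 3),
               entry_actions = list(function() fired <<- c(fired, now(sched)))),
    state_spec("b", function() timer_stream(sched, 2),
               entry_actions = list(function() fired <<- c(fired, now(sched))))),
    sched)
  collect_values(machine(), sched)
  expect_equal(fired, c(0, 3))
  expect_error(chain_states(list(), sched), "empty")
})

test_that("N one-tick states under repeat cycle their names exactly", {
  sched <- virtual_scheduler()
  n <- 4
  states <- lapply(seq_len(n), function(i)
    state_spec(paste0("s", i), function() timer_stream(sched, 1)))
  machine <- rx_take(rx_repeat(chain_states(states, sched)), 2 * n)
  log <- collect_values(machine, sched)
  expect_equal(vapply(log, `[[`, character(1), "state"),
               rep(paste0("s", 1:n), 2))
  expect_equal(vapply(log, `[[`, numeric(1), "time"), 0:(2 * n - 1))
})

test_that("a one-state machine with immediate exit trips the loop guard", {
  sched <- virtual_scheduler()
  machine <- chain_states(list(
    state_spec("flash", function()
      cold_stream(sched, list(notify_next(0, "x"), notify_complete(0))))),
    sched)
  errs <- c()
  subscribe(rx_repeat(machine), on_error = function(m) errs <<- c(errs, m))
  run_until_idle(sched)
  expect_match(errs, "zero-time loop")
})

test_that("repeated chains match an explicit FSM interpreter on scripted runs", {
  set.seed(51)
  for (rep_i in 1:5) {
    delay <- sample(3:8, 1)
    keys <- sort(sample(seq(delay + 1, 400), 25))
    horizon <- 400
    sched <- virtual_scheduler()
    key_src <- events_stream(sched, keys)
    machine <- rx_repeat(chain_states(list(
      state_spec("ready", function() timer_stream(sched, delay)),
      state_spec("go", function() key_src)), sched))
    log <- collect_values(machine, sched, horizon = horizon)
    want <- oracle_fsm(list(
      list(name = "ready", kind = "timer", delay = delay),
      list(name = "go", kind = "events", times = keys)), horizon)
    got <- lapply(log, function(e) list(state = e$state, time = e$time))
    expect_equal(got[seq_along(want)], want)
  }
})

test_that("reaction times equal the scripted key latencies", {
  sched <- virtual_scheduler()
  keys <- events_stream(sched, c(8, 16, 24))  # stimulus at 5, 13, 21
  trials <- reaction_time_task(sched, 5, keys)
  got <- collect_values(trials, sched, horizon = 100)
  df <- trial_records_df(got)
  expect_equal(df$trial, 1:3)
  expect_equal(df$stimulus_time, c(5, 13, 21))
  expect_equal(df$rt, c(3, 3, 3))
})

test_that("without a key press the machine waits in Go with no trial", {
  sched <- virtual_scheduler()
  keys <- events_stream(sched, numeric(0))
  trials <- reaction_time_task(sched, 5, keys)
  got <- collect_values(trials, sched, horizon = 200)
  expect_equal(length(got), 0L)
})

test_that("random scripted latencies are recovered exactly", {
  set.seed(52)
  delay <- 10
  lat <- sample(2:30, 40, replace = TRUE)
  key_times <- cumsum(delay + lat)
  sched <- virtual_scheduler()
  trials <- reaction_time_task(sched, delay,
                               events_stream(sched, key_times))
  got <- collect_values(trials, sched, horizon = max(key_times) + 1)
  expect_equal(vapply(got, `[[`, numeric(1), "rt"), lat)
})

test_that("keys during Ready are ignored", {
  sched <- virtual_scheduler()
  # key at tick 2 lands mid-Ready (stimulus at 5); first counted key is at 9
  keys <- events_stream(sched, c(2, 9))
  trials <- reaction_time_task(sched, 5, keys)
  got <- collect_values(trials, sched, horizon = 50)
  expect_equal(length(got), 1L)
  expect_equal(got[[1]]$rt, 4)
})

test_that("the coincidence rule rewards timely samples only", {
  sched <- virtual_scheduler()
  A <- events_stream(sched, c(10, 30))
  S <- events_stream(sched, c(12, 36))
  got <- collect_values(foraging_site(A, S, w = 5), sched, horizon = 50)
  df <- reward_events_df(got)
  expect_equal(nrow(df), 1L)               # S@36 is 6 ticks late: rotted
  expect_equal(df$time, 12)
  expect_equal(df$availability_time, 10)
  expect_error(foraging_site(A, S, w = 0), "w must be")
})

test_that("a sample exactly at the window edge still collects", {
  sched <- virtual_scheduler()
  A <- events_stream(sched, 10)
  S <- events_stream(sched, 15)
  got <- collect_values(foraging_site(A, S, w = 5), sched, horizon = 20)
  expect_equal(length(got), 1L)
})

test_that("re-arming replaces the pending availability (no queueing)", {
  sched <- virtual_scheduler()
  A <- events_stream(sched, c(10, 12))
  S <- events_stream(sched, c(13, 14))
  got <- collect_values(foraging_site(A, S, w = 10), sched, horizon = 30)
  # one item only: S@13 collects the item armed at 12; S@14 finds nothing
  expect_equal(length(got), 1L)
  expect_equal(got[[1]]$availability_time, 12)
})

test_that("every reward satisfies the availability-window invariant", {
  set.seed(53)
  A_t <- gen_event_schedule(5000, rate_per_tick = 0.02, seed = 531)
  S_t <- gen_event_schedule(5000, rate_per_tick = 0.05, seed = 532)
  w <- 15
  sched <- virtual_scheduler()
  A <- events_stream(sched, A_t)
  S <- events_stream(sched, S_t)
  got <- collect_values(foraging_site(A, S, w = w), sched, horizon = 5001)
  df <- reward_events_df(got)
  expect_true(all(df$availability_time <= df$time))
  expect_true(all(df$time <= df$availability_time + w))
  # at most one reward per availability event
  expect_lte(max(table(df$availability_time)), 1L)
})

test_that("foraging rewards equal the event-sweep oracle", {
  for (seed in c(54, 55)) {
    A_t <- gen_event_schedule(4000, rate_per_tick = 0.015, seed = seed)
    S_t <- gen_event_schedule(4000, rate_per_tick = 0.04, seed = seed + 100)
    w <- 20
    sched <- virtual_scheduler()
    got <- collect_values(
      foraging_site(events_stream(sched, A_t), events_stream(sched, S_t), w),
      sched, horizon = 4001)
    df <- reward_events_df(got)
    want <- oracle_foraging(A_t, S_t, w)
    expect_equal(df$time, vapply(want, `[[`, numeric(1), "time"))
    expect_equal(df$availability_time,
                 vapply(want, `[[`, numeric(1), "availability_time"))
  }
})

test_that("multi-site foraging replicates sites independently", {
  mk <- function(sched, with_site1) {
    A0 <- events_stream(sched, c(5, 40, 80))
    S0 <- events_stream(sched, c(8, 49, 83))
    sites <- list(list(avail = A0, sample = S0, w = 10))
    if (with_site1) {
      sites[[2]] <- list(avail = events_stream(sched, c(6, 41)),
                         sample = events_stream(sched, c(7, 60)), w = 10)
    }
    sites
  }
  sched1 <- virtual_scheduler()
  solo <- reward_events_df(collect_values(
    foraging_multisite(mk(sched1, FALSE)), sched1, horizon = 100))
  sched2 <- virtual_scheduler()
  both <- reward_events_df(collect_values(
    foraging_multisite(mk(sched2, TRUE)), sched2, horizon = 100))
  site0 <- both[both$site_id == 0, c("time", "availability_time")]
  rownames(site0) <- NULL
  expect_equal(site0, solo[, c("time", "availability_time")])
  expect_gt(nrow(both[both$site_id == 1, ]), 0)
})

test_that("simultaneous rewards at two sites are ordered by site index", {
  sched <- virtual_scheduler()
  sites <- list(
    list(avail = events_stream(sched, 5),
         sample = events_stream(sched, 8), w = 10),
    list(avail = events_stream(sched, 5),
         sample = events_stream(sched, 8), w = 10))
  got <- collect_values(foraging_multisite(sites), sched, horizon = 20)
  expect_equal(vapply(got, `[[`, numeric(1), "site_id"), c(0, 1))
  expect_equal(vapply(got, `[[`, numeric(1), "time"), c(8, 8))
})

test_that("state-space counts: exponential product machine, linear dataflow", {
  expect_equal(unname(fsm_explosion_count(1, 2)), c(2, 4))
  expect_equal(unname(fsm_explosion_count(2, 2)[1]), 4)
  expect_equal(unname(fsm_explosion_count(5, 3)), c(243, 20))
})

test_that("empirical reward probability matches the arming-rule closed form", {
  lam_S <- 0.04
  w <- 20
  A_t <- gen_event_schedule(2e5, rate_per_tick = 0.005, seed = 56)
  S_t <- gen_event_schedule(2e5, rate_per_tick = lam_S, seed = 57)
  rewards <- oracle_check <- NULL
  sched <- virtual_scheduler()
  got <- collect_values(
    foraging_site(events_stream(sched, A_t), events_stream(sched, S_t), w),
    sched, horizon = 2e5 + 1)
  n_rewarded <- length(got)
  # per-availability success probability: the site stays armed for
  # L = min(gap - 1, w) + 1 ticks (a sample on the next A's tick belongs to
  # the new item); samples are per-tick Bernoulli(lam_S)
  gaps <- diff(c(A_t, 2e5))
  L <- pmin(gaps - 1, w) + 1
  p <- 1 - (1 - lam_S)^L
  se <- sqrt(sum(p * (1 - p)))
  expect_lt(abs(n_rewarded - sum(p)), 3 * se)
  # and the engine agrees with the event-sweep oracle exactly
  expect_equal(length(oracle_foraging(A_t, S_t, w)), n_rewarded)
})
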