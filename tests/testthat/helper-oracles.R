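# Independent brute-force oracles. These materialize whole scripts into
# plain lists and apply each operator's declarative definition directly —
# no scheduler, no subscriptions — so they share no code path with the
# engine they check.

# A script here is a list of entries list(time=, kind=, value=/message=),
# i.e. the same shape as package notifications, built by hand.

ev_next <- function(time, value) list(time = time, kind = "next", value = value)
ev_done <- function(time) list(time = time, kind = "completed")
ev_err <- function(time, message = "error") {
  list(time = time, kind = "error", message = message)
}

script_values <- function(ns) {
  ns[vapply(ns, function(n) n$kind == "next", logical(1))]
}

script_terminal <- function(ns) {
  term <- ns[vapply(ns, function(n) n$kind != "next", logical(1))]
  if (length(term)) term[[1]] else NULL
}

# Merge several scripts into one global delivery order: (time, source index,
# within-source position) — the engine's cross-stream simultaneity rule.
global_order <- function(scripts) {
  entries <- list()
  for (si in seq_along(scripts)) {
    ns <- scripts[[si]]
    for (k in seq_along(ns)) {
      e <- ns[[k]]
      e$src <- si
      e$pos <- k
      entries[[length(entries) + 1L]] <- e
    }
  }
  if (!length(entries)) return(list())
  o <- order(vapply(entries, `[[`, numeric(1), "time"),
             vapply(entries, `[[`, numeric(1), "src"),
             vapply(entries, `[[`, numeric(1), "pos"))
  entries[o]
}

oracle_map <- function(ns, fn) {
  out <- list()
  for (n in ns) {
    if (n$kind == "next") out[[length(out) + 1L]] <- ev_next(n$time, fn(n$value))
    else { out[[length(out) + 1L]] <- n; break }
  }
  out
}

oracle_filter <- function(ns, pred) {
  out <- list()
  for (n in ns) {
    if (n$kind == "next") {
      if (isTRUE(pred(n$value))) out[[length(out) + 1L]] <- n
    } else { out[[length(out) + 1L]] <- n; break }
  }
  out
}

oracle_take <- function(ns, k) {
  out <- list()
  seen <- 0L
  for (n in ns) {
    if (n$kind == "next") {
      if (seen < k) {
        seen <- seen + 1L
        out[[length(out) + 1L]] <- n
        if (seen == k) {
          out[[length(out) + 1L]] <- ev_done(n$time)
          return(out)
        }
      }
    } else { out[[length(out) + 1L]] <- n; break }
  }
  out
}

oracle_merge <- function(scripts) {
  out <- list()
  remaining <- length(scripts)
  for (e in global_order(scripts)) {
    if (e$kind == "next") {
      out[[length(out) + 1L]] <- ev_next(e$time, e$value)
    } else if (e$kind == "completed") {
      remaining <- remaining - 1L
      if (remaining == 0L) {
        out[[length(out) + 1L]] <- ev_done(e$time)
        break
      }
    } else {
      out[[length(out) + 1L]] <- e[c("time", "kind", "message")]
      break
    }
  }
  out
}

oracle_sample <- function(src, trig) {
  out <- list()
  latest <- NULL
  has <- FALSE
  for (e in global_order(list(src, trig))) {
    if (e$src == 1) {
      if (e$kind == "next") { latest <- e$value; has <- TRUE }
      else if (e$kind == "completed") {
        out[[length(out) + 1L]] <- ev_done(e$time); break
      } else {
        out[[length(out) + 1L]] <- e[c("time", "kind", "message")]; break
      }
    } else {
      if (e$kind == "next") {
        if (has) out[[length(out) + 1L]] <- ev_next(e$time, latest)
      } else if (e$kind == "error") {
        out[[length(out) + 1L]] <- e[c("time", "kind", "message")]; break
      }
      # trigger completion: sampling just stops
    }
  }
  out
}

oracle_timestamp <- function(ns) {
  oracle_map(ns, identity) -> out
  lapply(out, function(n) {
    if (n$kind == "next") {
      ev_next(n$time, structure(list(value = n$value, time = n$time),
                                class = "timestamped"))
    } else n
  })
}

# windows: list of value-vectors per window (payloads only)
oracle_window_count <- function(values, count, skip) {
  n <- length(values)
  starts <- seq(1, n, by = skip)
  lapply(starts, function(s) values[s:min(s + count - 1, n)])
}

oracle_window_time <- function(ns, duration) {
  vals <- script_values(ns)
  term <- script_terminal(ns)
  end_t <- if (!is.null(term)) term$time else
    if (length(vals)) max(vapply(vals, `[[`, numeric(1), "time")) else 0
  n_win <- floor(end_t / duration) + 1
  wins <- rep(list(list()), n_win)
  for (v in vals) {
    k <- floor(v$time / duration) + 1
    wins[[k]][[length(wins[[k]]) + 1L]] <- v$value
  }
  lapply(wins, function(w) unlist(w) %||% NULL)
}

oracle_window_trigger <- function(src, boundaries) {
  vals <- script_values(src)
  bt <- sort(vapply(script_values(boundaries), `[[`, numeric(1), "time"))
  wins <- rep(list(c()), length(bt) + 1)
  for (v in vals) {
    # simultaneity rule: ties across streams follow source creation order;
    # tests create the data source first, so an element at a boundary tick
    # is delivered first and joins the closing window
    k <- sum(bt < v$time) + 1
    wins[[k]] <- c(wins[[k]], v$value)
  }
  wins
}

oracle_moving_average <- function(x, k) {
  if (length(x) < k) return(numeric(0))
  as.numeric(stats::filter(x, rep(1 / k, k), sides = 1))[k:length(x)]
}

# union-find connected components (8-connectivity) — an algorithm distinct
# from the package's BFS flood fill
oracle_largest_component <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  parent <- seq_len(nr * nc)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  for (r in seq_len(nr)) for (cc in seq_len(nc)) {
    if (!mask[r, cc]) next
    i <- (cc - 1) * nr + r
    for (d in list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1))) {
      r2 <- r + d[1]; c2 <- cc + d[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (mask[r2, c2]) union(i, (c2 - 1) * nr + r2)
    }
  }
  idx <- which(mask)
  roots <- vapply(idx, function(i) as.integer(find(i)), integer(1))
  tab <- table(roots)
  best_size <- max(tab)
  # tie-break: component whose first pixel in (row, col) scan order is first
  cand <- as.integer(names(tab)[tab == best_size])
  if (length(cand) > 1L) {
    rows <- ((idx - 1L) %% nr) + 1L
    cols <- ((idx - 1L) %/% nr) + 1L
    scan <- order(rows, cols)
    first_scan <- vapply(cand, function(rt)
      min(which(roots[scan] == rt)), numeric(1))
    best_root <- cand[which.min(first_scan)]
  } else best_root <- cand
  out <- matrix(FALSE, nr, nc)
  out[idx[roots == best_root]] <- TRUE
  out
}

# direct-form difference equation, one sample at a time
oracle_biquad <- function(x, b, a) {
  y <- numeric(length(x))
  x1 <- x2 <- y1 <- y2 <- 0
  for (i in seq_along(x)) {
    y[i] <- b[1] * x[i] + b[2] * x1 + b[3] * x2 - a[2] * y1 - a[3] * y2
    x2 <- x1; x1 <- x[i]; y2 <- y1; y1 <- y[i]
  }
  y
}

# explicit-FSM interpreter for a cyclic state machine driven by scripted
# events: states is a list of list(name=, kind="timer"/"events", delay=/times=)
oracle_fsm <- function(states, horizon) {
  log <- list()
  clock <- 0
  k <- 1L
  while (clock <= horizon) {
    spec <- states[[k]]
    log[[length(log) + 1L]] <- list(state = spec$name, time = clock)
    if (spec$kind == "timer") {
      exit_t <- clock + spec$delay
    } else {
      future <- spec$times[spec$times > clock]
      if (!length(future)) break  # parked: no more events
      exit_t <- future[1]
    }
    if (exit_t > horizon) break
    clock <- exit_t
    k <- if (k == length(states)) 1L else k + 1L
  }
  log
}

# stateful sweep over merged availability/sample events (single site)
oracle_foraging <- function(avail_times, sample_times, w) {
  events <- rbind(
    data.frame(time = avail_times,
               kind = "A", ord = seq_along(avail_times)),
    data.frame(time = sample_times,
               kind = "S", ord = seq_along(sample_times)))
  # same-tick rule: A before S (availability sources are subscribed first)
  events <- events[order(events$time, events$kind), ]
  armed <- FALSE
  armed_at <- NA_real_
  rewards <- list()
  for (i in seq_len(nrow(events))) {
    e <- events[i, ]
    if (e$kind == "A") {
      armed <- TRUE
      armed_at <- e$time
    } else if (armed) {
      if (e$time <= armed_at + w) {
        rewards[[length(rewards) + 1L]] <-
          list(time = e$time, availability_time = armed_at)
      }
      armed <- FALSE
    }
  }
  rewards
}

# ---- random script generation -------------------------------------------

random_script <- function(n_events = NULL, max_time = 40, with_error = FALSE,
                          payload_pool = 1:9) {
  if (is.null(n_events)) n_events <- sample(0:12, 1)
  times <- sort(sample(0:max_time, n_events, replace = TRUE))
  ns <- lapply(seq_len(n_events), function(i)
    ev_next(times[i], sample(payload_pool, 1)))
  end_t <- if (n_events) max(times) + sample(0:3, 1) else sample(0:5, 1)
  term <- if (with_error && stats::runif(1) < 0.3) ev_err(end_t) else ev_done(end_t)
  c(ns, list(term))
}

script_to_notifications <- function(ns) {
  lapply(ns, function(e) {
    switch(e$kind,
      "next" = notify_next(e$time, e$value),
      completed = notify_complete(e$time),
      error = notify_error(e$time, e$message))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
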