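## Buffered time-series operators: streaming band-pass filtering with state
## carried across buffer boundaries, threshold spike detection with trough
## alignment and a refractory rule, spike-triggered multichannel window
## extraction, and flat int16 binary I/O. All operators are chunking
## invariant: the same samples split into different buffer sizes yield the
## same results.

#' Construct a sample buffer
#'
#' @param data Channels x samples numeric matrix.
#' @param start_index Absolute (0-based) sample index of the first column.
#' @param rate Sampling rate in samples/second (`> 0`).
#' @return A list of class `sample_buffer`.
#' @export
sample_buffer <- function(data, start_index = 0, rate = 30000) {
  stopifnot(is.matrix(data), rate > 0, start_index >= 0)
  structure(list(data = data, start_index = start_index, rate = rate),
            class = "sample_buffer")
}

#' Design a 2nd-order band-pass biquad
#'
#' Bilinear-transform Butterworth band-pass with the stated corner
#' frequencies (one pole pair; numerator/denominator of length 3). Requires
#' `0 < low_hz < high_hz < rate/2`.
#'
#' @param low_hz,high_hz Corner frequencies in Hz.
#' @param rate Sampling rate in samples/second.
#' @return List with numeric `b` and `a` (both length 3, `a[1] == 1`).
#' @export
design_bandpass <- function(low_hz, high_hz, rate) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < rate / 2)) {
    stop("design_bandpass: need 0 < low_hz < high_hz < rate/2")
  }
  ba <- signal::butter(1, c(low_hz, high_hz) / (rate / 2), type = "pass")
  b <- as.numeric(ba$b); a <- as.numeric(ba$a)
  b <- b / a[1]; a <- a / a[1]
  list(b = b, a = a)
}

# One causal biquad step over a sample block with explicit state
# (per-channel last two inputs and outputs), exactly equal to the direct
# difference equation y[n] = b0 x[n] + b1 x[n-1] + b2 x[n-2]
#                           - a1 y[n-1] - a2 y[n-2].
biquad_block <- function(x, b, a, state) {
  v <- stats::filter(c(state$x2, state$x1, x), b, method = "convolution",
                     sides = 1)[-(1:2)]
  y <- as.numeric(stats::filter(v, c(-a[2], -a[3]), method = "recursive",
                                init = c(state$y1, state$y2)))
  n <- length(x)
  state2 <- list(x1 = x[n], x2 = if (n >= 2) x[n - 1] else state$x1,
                 y1 = y[n], y2 = if (n >= 2) y[n - 1] else state$y1)
  list(y = y, state = state2)
}

#' Streaming band-pass filter
#'
#' Applies the causal biquad of [design_bandpass()] per channel, carrying
#' filter state across buffer boundaries, so output buffers align 1:1 with
#' input buffers and the result is independent of how the stream is chunked.
#'
#' @param src An `observable` of [sample_buffer()]s.
#' @param low_hz,high_hz Corner frequencies in Hz.
#' @return An `observable` of filtered [sample_buffer()]s.
#' @export
bandpass <- function(src, low_hz, high_hz) {
  new_observable(src$scheduler, function(obs, sub) {
    st <- new.env(parent = emptyenv())
    st$coef <- NULL
    st$chan_state <- NULL
    up <- subscribe(src,
      on_next = function(buf) {
        if (is.null(st$coef)) {
          co <- tryCatch(list(v = design_bandpass(low_hz, high_hz, buf$rate)),
                         error = function(e)
                           structure(list(msg = conditionMessage(e)),
                                     class = "rx_fail"))
          if (inherits(co, "rx_fail")) { obs$on_error(co$msg); return(invisible(NULL)) }
          st$coef <- co$v
          st$chan_state <- rep(list(list(x1 = 0, x2 = 0, y1 = 0, y2 = 0)),
                               nrow(buf$data))
        }
        out <- buf$data
        for (ch in seq_len(nrow(buf$data))) {
          r <- biquad_block(buf$data[ch, ], st$coef$b, st$coef$a,
                            st$chan_state[[ch]])
          out[ch, ] <- r$y
          st$chan_state[[ch]] <- r$state
        }
        obs$on_next(sample_buffer(out, buf$start_index, buf$rate))
      },
      on_completed = obs$on_completed,
      on_error = obs$on_error)
    add_teardown(sub, function() dispose(up))
  })
}

#' Threshold spike detection with trough alignment
#'
#' For a negative threshold, a candidate fires when the monitored channel
#' crosses below `threshold`; the event's `sample_index` is the absolute
#' index of the signal minimum within the `refractory` samples following the
#' crossing (trough alignment keeps spike-triggered averages sharp), and
#' later crossings within `refractory` samples of that trough are
#' suppressed. A positive threshold applies the mirrored rule (peak
#' alignment). Detection state is carried across buffers; crossings whose
#' alignment span is not yet available are deferred to the next buffer, so
#' results are chunking invariant. At stream completion pending crossings
#' are finalized over the available samples.
#'
#' @param src An `observable` of [sample_buffer()]s.
#' @param channel 1-based channel to monitor.
#' @param threshold Signed amplitude.
#' @param refractory Minimum samples between consecutive event troughs.
#' @return An `observable` of `spike_event` lists `(channel, sample_index,
#'   threshold, time_s)` with 0-based `sample_index`.
#' @export
detect_spikes <- function(src, channel, threshold, refractory) {
  stopifnot(refractory >= 1)
  sgn <- if (threshold < 0) -1 else 1
  new_observable(src$scheduler, function(obs, sub) {
    st <- new.env(parent = emptyenv())
    st$x <- numeric(0)       # unprocessed samples (monitored channel)
    st$x0 <- NA_real_        # absolute 0-based index of st$x[1]
    st$last_trough <- -Inf
    st$rate <- NULL
    emit <- function(idx) {
      obs$on_next(structure(list(channel = channel, sample_index = idx,
                                 threshold = threshold,
                                 time_s = idx / st$rate),
                            class = "spike_event"))
    }
    process <- function(final) {
      x <- st$x * sgn  # work on the "positive-crossing" mirror
      thr <- threshold * sgn
      n <- length(x)
      if (n < 2) return(invisible(NULL))
      i <- 2L
      consumed <- 1L  # samples before this local index are fully processed
      while (i <= n) {
        if (x[i] > thr && x[i - 1] <= thr) {
          abs_i <- st$x0 + (i - 1L)
          if (abs_i <= st$last_trough + refractory) { i <- i + 1L; next }
          span_end <- i + refractory
          if (span_end > n && !final) {
            consumed <- i - 1L  # keep from the pre-crossing sample
            break
          }
          span_end <- min(span_end, n)
          rel <- which.max(x[i:span_end])  # mirror of the trough
          trough_abs <- st$x0 + (i - 1L) + (rel - 1L)
          st$last_trough <- trough_abs
          emit(trough_abs)
          i <- i + rel  # continue after the trough; suppression guards the rest
          consumed <- min(i - 1L, n - 1L)
        } else {
          consumed <- i - 1L
          i <- i + 1L
        }
      }
      if (!final && consumed >= 1L) {
        st$x <- st$x[(consumed):n]  # retain one processed sample for crossing
        st$x0 <- st$x0 + (consumed - 1L)
      }
      invisible(NULL)
    }
    up <- subscribe(src,
      on_next = function(buf) {
        if (is.null(st$rate)) st$rate <- buf$rate
        seg <- buf$data[channel, ]
        if (length(st$x) == 0L) {
          st$x <- seg
          st$x0 <- buf$start_index
        } else {
          st$x <- c(st$x, seg)
        }
        process(final = FALSE)
      },
      on_completed = function() {
        process(final = TRUE)
        obs$on_completed()
      },
      on_error = obs$on_error)
    add_teardown(sub, function() dispose(up))
  })
}

#' Spike-triggered multichannel window extraction
#'
#' For each spike event with full context available, emits the all-channel
#' slice `[sample_index - pre, sample_index + post]` (a `triggered_window`
#' whose column `pre + 1` is the event sample). Events whose window would
#' run off the start of the recording, or whose trailing context never
#' arrives before the data stream completes, are dropped and counted; the
#' drop count is available on the returned observable as `$dropped$count`.
#'
#' @param src An `observable` of [sample_buffer()]s.
#' @param events An `observable` of `spike_event`s (same scheduler).
#' @param pre,post Samples of context before/after the event sample.
#' @return An `observable` of `triggered_window` lists `(data, event)`.
#' @export
extract_triggered <- function(src, events, pre, post) {
  stopifnot(pre >= 0, post >= 0)
  sched <- src$scheduler
  dropped <- new.env(parent = emptyenv())
  dropped$count <- 0L
  out <- new_observable(sched, function(obs, sub) {
    st <- new.env(parent = emptyenv())
    st$hist <- NULL          # channels x kept-samples
    st$h0 <- 0               # absolute index of hist col 1 (0-based)
    st$end <- 0              # absolute index one past the last sample
    st$pending <- list()
    st$src_done <- FALSE
    st$ev_done <- FALSE
    st$max_buf <- 0L
    serve <- function(ev) {
      s <- ev$sample_index
      if (s - pre < 0 || s - pre < st$h0) {
        dropped$count <- dropped$count + 1L
        return(TRUE)
      }
      if (s + post >= st$end) {
        if (st$src_done) { dropped$count <- dropped$count + 1L; return(TRUE) }
        return(FALSE)
      }
      cols <- (s - pre - st$h0 + 1):(s + post - st$h0 + 1)
      obs$on_next(structure(list(data = st$hist[, cols, drop = FALSE],
                                 event = ev),
                            class = "triggered_window"))
      TRUE
    }
    flush_pending <- function() {
      st$pending <- Filter(function(ev) !serve(ev), st$pending)
      if (st$ev_done && st$src_done && length(st$pending)) {
        dropped$count <- dropped$count + length(st$pending)
        st$pending <- list()
      }
      maybe_done()
    }
    maybe_done <- function() {
      if (st$ev_done && length(st$pending) == 0L) obs$on_completed()
    }
    trim <- function() {
      # keep the lookback window plus a couple of buffers of slack: events
      # produced downstream of the same source (e.g. a spike detector) may
      # reference troughs up to a buffer behind the newest samples
      need <- st$end - (pre + post + 1 + 2 * st$max_buf)
      if (length(st$pending)) {
        need <- min(need,
                    min(vapply(st$pending, function(e) e$sample_index,
                               numeric(1))) - pre)
      }
      if (need > st$h0) {
        drop_cols <- need - st$h0
        st$hist <- st$hist[, -(1:drop_cols), drop = FALSE]
        st$h0 <- need
      }
    }
    up1 <- subscribe(src,
      on_next = function(buf) {
        if (is.null(st$hist)) {
          st$hist <- buf$data
          st$h0 <- buf$start_index
        } else {
          st$hist <- cbind(st$hist, buf$data)
        }
        st$max_buf <- max(st$max_buf, ncol(buf$data))
        st$end <- st$h0 + ncol(st$hist)
        flush_pending()
        trim()
      },
      on_completed = function() {
        st$src_done <- TRUE
        flush_pending()
      },
      on_error = obs$on_error)
    up2 <- subscribe(events,
      on_next = function(ev) {
        if (!serve(ev)) st$pending[[length(st$pending) + 1L]] <- ev
      },
      on_completed = function() {
        st$ev_done <- TRUE
        flush_pending()
      },
      on_error = obs$on_error)
    add_teardown(sub, function() { dispose(up1); dispose(up2) })
  })
  out$dropped <- dropped
  out
}

## ---- raw int16 binary ---------------------------------------------------

#' Flat int16 binary I/O
#'
#' The common raw extracellular format: little-endian int16, sample-major
#' interleaved (`c0 s0, c1 s0, ..., c0 s1, ...`). Values are clipped to the
#' int16 range on write; `read_raw_int16(write_raw_int16(x))` is the
#' identity for int16-valued input. A file whose length is not a multiple of
#' `2 * channels` is a format error.
#'
#' @param x Channels x samples numeric matrix.
#' @param path File path.
#' @param channels Channel count for reading.
#' @return `read_raw_int16()` returns a channels x samples integer matrix.
#' @export
write_raw_int16 <- function(x, path) {
  stopifnot(is.matrix(x))
  v <- as.integer(pmin(pmax(round(as.numeric(x)), -32768), 32767))
  con <- file(path, "wb"); on.exit(close(con))
  # column-major matrix layout == sample-major interleaving
  writeBin(v, con, size = 2L, endian = "little")
  invisible(path)
}

#' @rdname write_raw_int16
#' @export
read_raw_int16 <- function(path, channels) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz %% (2L * channels) != 0L) {
    stop("read_raw_int16: file length ", sz,
         " is not a multiple of 2 * channels (", channels, ")")
  }
  con <- file(path, "rb"); on.exit(close(con))
  v <- readBin(con, "integer", n = sz / 2L, size = 2L, signed = TRUE,
               endian = "little")
  matrix(v, nrow = channels)
}

#' Raw binary stream source and sink
#'
#' `raw_binary_sink()` appends every buffer of a stream to a flat int16 file
#' (forwarding buffers unchanged); `raw_binary_source()` replays a file as a
#' cold stream of [sample_buffer()]s, one buffer per tick.
#'
#' @param src An `observable` of [sample_buffer()]s.
#' @param path File path.
#' @param scheduler A [virtual_scheduler()].
#' @param channels,rate Layout of the stored data.
#' @param buffer_size Samples per emitted buffer.
#' @return `raw_binary_sink()`: pass-through observable;
#'   `raw_binary_source()`: a cold `observable`.
#' @export
raw_binary_sink <- function(src, path) {
  new_observable(src$scheduler, function(obs, sub) {
    st <- new.env(parent = emptyenv())
    st$con <- NULL
    close_con <- function() {
      if (!is.null(st$con)) { close(st$con); st$con <- NULL }
    }
    up <- subscribe(src,
      on_next = function(buf) {
        if (is.null(st$con)) st$con <- file(path, "wb")
        v <- as.integer(pmin(pmax(round(as.numeric(buf$data)), -32768), 32767))
        writeBin(v, st$con, size = 2L, endian = "little")
        obs$on_next(buf)
      },
      on_completed = function() { close_con(); obs$on_completed() },
      on_error = function(message) { close_con(); obs$on_error(message) })
    add_teardown(sub, close_con)
    add_teardown(sub, function() dispose(up))
  })
}

#' @rdname raw_binary_sink
#' @export
raw_binary_source <- function(scheduler, path, channels, rate,
                              buffer_size = 1024) {
  data <- read_raw_int16(path, channels)
  n <- ncol(data)
  starts <- seq(1L, n, by = buffer_size)
  ns <- vector("list", length(starts) + 1L)
  for (i in seq_along(starts)) {
    s <- starts[i]
    e <- min(s + buffer_size - 1L, n)
    ns[[i]] <- notify_next(i - 1L, sample_buffer(
      data[, s:e, drop = FALSE] * 1.0, start_index = s - 1L, rate = rate))
  }
  ns[[length(starts) + 1L]] <- notify_complete(length(starts) - 1L)
  cold_stream(scheduler, ns)
}

#' Spike events to a data frame / CSV
#'
#' @param events List of `spike_event`s.
#' @param path Optional CSV path; written when given.
#' @return Data frame with `channel`, `sample_index`, `time_s`.
#' @export
spike_events_df <- function(events, path = NULL) {
  df <- data.frame(
    channel = vapply(events, `[[`, numeric(1), "channel"),
    sample_index = vapply(events, `[[`, numeric(1), "sample_index"),
    time_s = vapply(events, `[[`, numeric(1), "time_s"))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
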