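## Seeded synthetic fixtures: every stream the operator packs consume can be
## generated deterministically in code, so the package builds and tests with
## no external data. All generators restore the caller's RNG state.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Generate a synthetic tracking video
#'
#' Renders `n_frames` grayscale frames (8-bit, `size x size`) of either a
#' bright disc moving along a smooth Lissajous-style path (`mode = "dot"`) or
#' a bright bar rotating about the frame center (`mode = "bar"`), over an
#' i.i.d. Gaussian noise background, together with the ground-truth path.
#' Pixel coordinates are 0-based with the origin at the top-left, `x` along
#' columns and `y` along rows (down).
#'
#' @param n_frames Number of frames.
#' @param size Frame side length in pixels.
#' @param radius Disc radius (`dot` mode), pixels.
#' @param half_length,half_width Bar half-dimensions (`bar` mode), pixels.
#' @param noise_sd Background noise standard deviation (intensity units).
#' @param foreground,background Intensities of object and background.
#' @param mode `"dot"` or `"bar"`.
#' @param seed RNG seed; the same config yields byte-identical output.
#' @return A list with `frames` (list of integer matrices) and `truth`
#'   (data.frame with `frame`, `cx`, `cy`, and for bars `angle_deg`).
#' @export
gen_dot_video <- function(n_frames = 100, size = 64, radius = 6,
                          half_length = 20, half_width = 3,
                          noise_sd = 5, foreground = 255, background = 20,
                          mode = c("dot", "bar"), seed = 1) {
  mode <- match.arg(mode)
  with_seed(seed, {
    xs <- matrix(rep(0:(size - 1), each = size), nrow = size)   # col index = x
    ys <- matrix(rep(0:(size - 1), times = size), nrow = size)  # row index = y
    frames <- vector("list", n_frames)
    t <- seq_len(n_frames)
    if (mode == "dot") {
      margin <- radius + 4
      cx <- (size - 1) / 2 + (size / 2 - margin) * sin(2 * pi * t / 97)
      cy <- (size - 1) / 2 + (size / 2 - margin) * cos(2 * pi * t / 61)
      truth <- data.frame(frame = t - 1L, cx = cx, cy = cy)
    } else {
      cx <- rep((size - 1) / 2, n_frames)
      cy <- rep((size - 1) / 2, n_frames)
      angle <- ((t - 1) * 1.7) %% 180
      angle_sym <- ifelse(angle > 90, angle - 180, angle)  # (-90, 90]
      truth <- data.frame(frame = t - 1L, cx = cx, cy = cy,
                          angle_deg = angle_sym)
    }
    for (i in t) {
      noise <- matrix(stats::rnorm(size * size, background, noise_sd),
                      nrow = size)
      if (mode == "dot") {
        mask <- (xs - cx[i])^2 + (ys - cy[i])^2 <= radius^2
      } else {
        th <- angle[i] * pi / 180
        u <- (xs - cx[i]) * cos(th) + (ys - cy[i]) * sin(th)
        v <- -(xs - cx[i]) * sin(th) + (ys - cy[i]) * cos(th)
        mask <- abs(u) <= half_length & abs(v) <= half_width
      }
      px <- noise
      px[mask] <- foreground
      frames[[i]] <- matrix(as.integer(pmin(pmax(round(px), 0), 255)),
                            nrow = size)
    }
    list(frames = frames, truth = truth)
  })
}

#' Biphasic spike template
#'
#' Negative trough followed by a smaller positive rebound; the trough sits at
#' (1-based) sample `trough_at`.
#'
#' @param length_samples Template length.
#' @param amplitude Trough depth (positive number; the trough is `-amplitude`).
#' @param trough_at Trough position within the template.
#' @return Numeric vector.
#' @export
spike_template <- function(length_samples = 30, amplitude = 1,
                           trough_at = 10) {
  t <- seq_len(length_samples)
  w <- -amplitude * exp(-((t - trough_at)^2) / 4) +
    0.45 * amplitude * exp(-((t - trough_at - 9)^2) / 18)
  w
}

#' Generate a multichannel signal with injected spikes
#'
#' Gaussian noise on every channel plus a biphasic template added at the
#' given (or Poisson-drawn) trough times on one channel, scaled down on the
#' others to mimic spatial decay across a probe.
#'
#' @param n_samples Total samples.
#' @param n_channels Channels (rows).
#' @param rate Sampling rate in samples/second.
#' @param channel 1-based channel carrying the full-amplitude spikes.
#' @param spike_times Integer vector of 0-based trough sample indices, or
#'   `NULL` to draw them with exponential gaps of mean `1/spike_rate_hz`
#'   (enforcing `min_gap` samples between troughs).
#' @param spike_rate_hz Mean spike rate when drawing times.
#' @param min_gap Minimum samples between drawn troughs.
#' @param amplitude Trough depth; `amplitude / noise_sd` is the trough SNR.
#' @param noise_sd Noise standard deviation.
#' @param neighbor_scale Template scale on the other channels.
#' @param seed RNG seed.
#' @return A list with `data` (channels x samples matrix), `spike_times`
#'   (0-based trough indices), `template`, `rate`, `channel`.
#' @export
gen_spike_signal <- function(n_samples = 30000, n_channels = 4, rate = 30000,
                             channel = 1, spike_times = NULL,
                             spike_rate_hz = 10, min_gap = 90,
                             amplitude = 8, noise_sd = 1,
                             neighbor_scale = 0.3, seed = 1) {
  with_seed(seed, {
    tpl <- spike_template(amplitude = amplitude)
    trough_at <- if (amplitude > 0) which.min(tpl) else 10L
    # noise field first, so the background is identical whatever the
    # injection schedule or amplitude
    data <- matrix(stats::rnorm(n_channels * n_samples, 0, noise_sd),
                   nrow = n_channels)
    if (is.null(spike_times)) {
      times <- integer(0)
      t <- 100
      while (TRUE) {
        gap <- max(min_gap, round(stats::rexp(1, spike_rate_hz) * rate))
        t <- t + gap
        if (t > n_samples - length(tpl)) break
        times <- c(times, t)
      }
      spike_times <- times
    }
    for (s in spike_times) {
      i0 <- s - trough_at + 1L + 1L  # 0-based trough -> 1-based window start
      idx <- i0:(i0 + length(tpl) - 1L)
      keep <- idx >= 1 & idx <= n_samples
      for (ch in seq_len(n_channels)) {
        scale <- if (ch == channel) 1 else neighbor_scale
        data[ch, idx[keep]] <- data[ch, idx[keep]] + scale * tpl[keep]
      }
    }
    list(data = data, spike_times = as.integer(spike_times), template = tpl,
         rate = rate, channel = channel)
  })
}

#' Generate a scripted or Poisson event schedule
#'
#' Event times on the virtual clock, either an explicit list or a discrete
#' Poisson process (independent per-tick Bernoulli events with probability
#' `rate_per_tick`, i.e. geometric gaps). Used for keys, triggers and
#' foraging availability/sampling streams.
#'
#' @param duration Ticks covered (events fall in `[0, duration)`).
#' @param rate_per_tick Per-tick event probability for the Poisson mode.
#' @param times Explicit 0-based event ticks (overrides the Poisson draw).
#' @param seed RNG seed.
#' @return Sorted numeric vector of event ticks.
#' @export
gen_event_schedule <- function(duration, rate_per_tick = NULL, times = NULL,
                               seed = 1) {
  if (!is.null(times)) return(sort(as.numeric(times)))
  stopifnot(!is.null(rate_per_tick), rate_per_tick >= 0, rate_per_tick <= 1)
  if (rate_per_tick == 0) return(numeric(0))
  with_seed(seed, {
    # geometric gaps <=> per-tick Bernoulli(rate_per_tick)
    ts <- numeric(0)
    t <- -1
    while (TRUE) {
      gap <- stats::rgeom(1, rate_per_tick) + 1
      t <- t + gap
      if (t >= duration) break
      ts <- c(ts, t)
    }
    ts
  })
}

#' Stream wrappers for fixture payloads
#'
#' `frames_stream()` emits [new_frame()] payloads at `interval`-tick spacing;
#' `buffers_stream()` chops a channels x samples matrix into contiguous
#' [sample_buffer()]s emitted one per tick. Both are hot sources that
#' complete after the last payload.
#'
#' @param scheduler A [virtual_scheduler()].
#' @param frames List of pixel matrices.
#' @param interval Ticks between frames.
#' @param data Channels x samples matrix.
#' @param rate Sampling rate stored on each buffer.
#' @param buffer_size Samples per emitted buffer.
#' @return A hot `observable`.
#' @export
frames_stream <- function(scheduler, frames, interval = 1) {
  ns <- vector("list", length(frames) + 1L)
  for (i in seq_along(frames)) {
    ns[[i]] <- notify_next((i - 1L) * interval,
                           new_frame(frames[[i]], time = (i - 1L) * interval,
                                     index = i - 1L))
  }
  end <- if (length(frames)) (length(frames) - 1L) * interval else 0
  ns[[length(frames) + 1L]] <- notify_complete(end)
  hot_stream(scheduler, ns)
}

#' @rdname frames_stream
#' @export
buffers_stream <- function(scheduler, data, rate, buffer_size = 1024) {
  n <- ncol(data)
  starts <- seq(1L, n, by = buffer_size)
  ns <- vector("list", length(starts) + 1L)
  for (i in seq_along(starts)) {
    s <- starts[i]
    e <- min(s + buffer_size - 1L, n)
    ns[[i]] <- notify_next(i - 1L,
                           sample_buffer(data[, s:e, drop = FALSE],
                                         start_index = s - 1L, rate = rate))
  }
  ns[[length(starts) + 1L]] <- notify_complete(length(starts) - 1L)
  hot_stream(scheduler, ns)
}
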