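## Image-stream operators for behavior tracking: threshold segmentation,
## connected components, image-moment blob measures, region-of-interest
## crossing events, and a bit-exact raw frame container.
##
## Conventions: frames are row x col 8-bit intensity matrices, origin at the
## top-left; pixel coordinates are 0-based with x along columns and y along
## rows (downwards). Orientation is reported in degrees in (-90, 90],
## measured from the +x axis towards +y (down).

#' Construct a frame
#'
#' @param pixels Integer matrix (grayscale) or rows x cols x 3 array (RGB),
#'   values 0-255.
#' @param time Virtual timestamp in ticks.
#' @param index Frame ordinal.
#' @return A list of class `frame`.
#' @export
new_frame <- function(pixels, time = 0, index = 0L) {
  structure(list(pixels = pixels, time = time, index = index),
            class = "frame")
}

frame_pixels <- function(x) if (inherits(x, "frame")) x$pixels else x

#' Convert an RGB frame to grayscale
#'
#' Per-pixel luma `round(0.299 R + 0.587 G + 0.114 B)`, clipped to 0-255.
#' Input must be 3-channel; a gray RGB image (all channels equal) maps to
#' exactly its channel values.
#'
#' @param x A `frame` holding a rows x cols x 3 array, or such an array.
#' @return Same container type with a 2-D integer pixel matrix.
#' @export
grayscale <- function(x) {
  px <- frame_pixels(x)
  if (length(dim(px)) != 3L || dim(px)[3] != 3L) {
    stop("grayscale: input must have exactly 3 channels")
  }
  g <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  g <- matrix(as.integer(pmin(pmax(round(g), 0), 255)), nrow = dim(px)[1])
  if (inherits(x, "frame")) new_frame(g, x$time, x$index) else g
}

#' Intensity-range threshold
#'
#' Binary mask where `lo <= pixel <= hi`, optionally inverted (use
#' `invert = TRUE` to select dark objects).
#'
#' @param x A `frame` or pixel matrix.
#' @param lo,hi Inclusive intensity bounds.
#' @param invert Flip the mask.
#' @return Logical matrix of the frame's dimensions.
#' @export
threshold_range <- function(x, lo = 0, hi = 255, invert = FALSE) {
  px <- frame_pixels(x)
  m <- px >= lo & px <= hi
  if (invert) m <- !m
  m
}

#' Largest connected component of a binary mask
#'
#' 8-connectivity; among equally large components the one whose first pixel
#' comes earliest in (row, col) scan order wins. Returns `NULL` for an empty
#' mask.
#'
#' @param mask Logical matrix.
#' @return Logical matrix selecting the largest component, or `NULL`.
#' @export
largest_component <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  if (length(idx) == 0L) return(NULL)
  labels <- integer(nr * nc)
  # visit seeds in (row, col) scan order so label ids order components by
  # their first pixel; idx (column-major) must be reordered
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  scan <- idx[order(rows, cols)]
  n_labels <- 0L
  sizes <- integer(0)
  for (seed in scan) {
    if (labels[seed] != 0L) next
    n_labels <- n_labels + 1L
    stack <- seed
    labels[seed] <- n_labels
    count <- 0L
    while (length(stack) > 0L) {
      p <- stack[length(stack)]
      stack <- stack[-length(stack)]
      count <- count + 1L
      r <- ((p - 1L) %% nr) + 1L
      cc <- ((p - 1L) %/% nr) + 1L
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0L && dc == 0L) next
        r2 <- r + dr; c2 <- cc + dc
        if (r2 < 1L || r2 > nr || c2 < 1L || c2 > nc) next
        q <- (c2 - 1L) * nr + r2
        if (mask[q] && labels[q] == 0L) {
          labels[q] <- n_labels
          stack <- c(stack, q)
        }
      }
    }
    sizes[n_labels] <- count
  }
  best <- which.max(sizes)  # first maximum = earliest first pixel
  matrix(labels == best, nrow = nr)
}

#' Image-moment measures of a blob
#'
#' From raw and central moments of the component mask: centroid
#' `(M10/M00, M01/M00)`, orientation
#' `0.5 * atan2(2 mu11', mu20' - mu02')` in degrees, and major axis
#' `4 * sqrt(lambda1)` with `lambda1` the larger eigenvalue of the
#' normalized second-moment matrix — the ellipse-model axis length.
#'
#' @param mask Logical matrix (a single component, non-empty).
#' @return A list of class `blob_measure` with `centroid_x`, `centroid_y`,
#'   `area`, `orientation` (degrees, (-90, 90]), `major_axis` (pixels).
#' @export
blob_measure <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop("blob_measure: empty component")
  x <- idx[, "col"] - 1
  y <- idx[, "row"] - 1
  m00 <- length(x)
  cx <- mean(x); cy <- mean(y)
  mu20 <- mean((x - cx)^2)
  mu02 <- mean((y - cy)^2)
  mu11 <- mean((x - cx) * (y - cy))
  theta <- 0.5 * atan2(2 * mu11, mu20 - mu02) * 180 / pi
  if (theta <= -90) theta <- theta + 180
  lam1 <- ((mu20 + mu02) + sqrt((mu20 - mu02)^2 + 4 * mu11^2)) / 2
  structure(list(centroid_x = cx, centroid_y = cy, area = m00,
                 orientation = theta, major_axis = 4 * sqrt(lam1)),
            class = "blob_measure")
}

#' Track the largest object in a frame stream
#'
#' The standard segmentation chain: threshold to a binary mask, keep the
#' largest 8-connected component, and measure it. Frames with an empty mask
#' are skipped. Threshold bounds are property-bindable via `penv` (fields
#' `lo` and `hi`), mirroring an externalized Threshold property.
#'
#' @param frames An `observable` of `frame`s.
#' @param lo,hi Intensity bounds of the object.
#' @param invert `TRUE` to track dark objects.
#' @param penv Optional environment with fields `lo`/`hi` consulted per
#'   frame (overrides the defaults when bound).
#' @return An `observable` of `blob_measure` values (with `time` and `index`
#'   fields carried over from the frame).
#' @export
track_largest <- function(frames, lo = 128, hi = 255, invert = FALSE,
                          penv = NULL) {
  if (is.null(penv)) {
    penv <- new.env(parent = emptyenv())
  }
  if (is.null(penv$lo)) penv$lo <- lo
  if (is.null(penv$hi)) penv$hi <- hi
  new_observable(frames$scheduler, function(obs, sub) {
    up <- subscribe(frames,
      on_next = function(fr) {
        mask <- threshold_range(fr, penv$lo, penv$hi, invert)
        comp <- largest_component(mask)
        if (is.null(comp)) return(invisible(NULL))
        m <- blob_measure(comp)
        m$time <- fr$time
        m$index <- fr$index
        obs$on_next(m)
      },
      on_completed = obs$on_completed,
      on_error = obs$on_error)
    add_teardown(sub, function() dispose(up))
  })
}

#' Region-of-interest crossing events
#'
#' Tracks whether the centroid lies inside the half-open rectangle
#' `[x0, x1) x [y0, y1)` and emits an event on each transition: `enter` on
#' outside-to-inside, `exit` on inside-to-outside, with `level` the digital
#' output state after the event (1 iff inside). Initial state is outside;
#' enter/exit strictly alternate.
#'
#' @param centroids An `observable` of `blob_measure`s (or any list with
#'   `centroid_x`/`centroid_y`).
#' @param roi Numeric `c(x0, y0, x1, y1)`.
#' @return An `observable` of lists `(kind, time, level)`.
#' @export
roi_monitor <- function(centroids, roi) {
  stopifnot(length(roi) == 4)
  sched <- centroids$scheduler
  new_observable(sched, function(obs, sub) {
    st <- new.env(parent = emptyenv())
    st$inside <- FALSE
    up <- subscribe(centroids,
      on_next = function(m) {
        inside <- m$centroid_x >= roi[1] && m$centroid_x < roi[3] &&
          m$centroid_y >= roi[2] && m$centroid_y < roi[4]
        if (inside != st$inside) {
          st$inside <- inside
          obs$on_next(list(kind = if (inside) "enter" else "exit",
                           time = sched$clock,
                           level = as.integer(inside)))
        }
      },
      on_completed = obs$on_completed,
      on_error = obs$on_error)
    add_teardown(sub, function() dispose(up))
  })
}

## ---- raw frame container ------------------------------------------------

#' Raw frame container
#'
#' A bit-exact storage format for 8-bit frame sequences: one JSON header line
#' `{"rows": r, "cols": c, "dtype": "u8", "count": n}` terminated by a
#' newline, followed by the concatenated row-major frame bytes.
#' `write_frames()`/`read_frames()` invert each other exactly.
#'
#' @param frames List of integer pixel matrices (equal dimensions).
#' @param path File path.
#' @return `read_frames()` returns the list of integer matrices.
#' @export
write_frames <- function(frames, path) {
  stopifnot(length(frames) >= 0)
  if (length(frames) == 0L) {
    header <- jsonlite::toJSON(list(rows = 0L, cols = 0L, dtype = "u8",
                                    count = 0L), auto_unbox = TRUE)
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(charToRaw(paste0(header, "\n")), con)
    return(invisible(path))
  }
  d <- dim(frames[[1]])
  for (f in frames) {
    if (!identical(dim(f), d)) stop("write_frames: frame dimensions changed mid-sequence")
  }
  header <- jsonlite::toJSON(list(rows = d[1], cols = d[2], dtype = "u8",
                                  count = length(frames)), auto_unbox = TRUE)
  con <- file(path, "wb"); on.exit(close(con))
  writeBin(charToRaw(paste0(header, "\n")), con)
  for (f in frames) {
    # row-major byte order
    writeBin(as.raw(as.integer(t(f))), con)
  }
  invisible(path)
}

#' @rdname write_frames
#' @export
read_frames <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  header_bytes <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1L)
    if (length(b) == 0L) stop("read_frames: truncated header")
    if (b == charToRaw("\n")) break
    header_bytes <- c(header_bytes, b)
  }
  h <- jsonlite::fromJSON(rawToChar(header_bytes))
  if (!identical(h$dtype, "u8")) stop("read_frames: unsupported dtype ", h$dtype)
  n_px <- h$rows * h$cols
  frames <- vector("list", h$count)
  for (i in seq_len(h$count)) {
    bytes <- readBin(con, "raw", n_px)
    if (length(bytes) != n_px) stop("read_frames: truncated frame ", i)
    frames[[i]] <- matrix(as.integer(bytes), nrow = h$rows, byrow = TRUE)
  }
  frames
}

#' Frame-writing sink
#'
#' Buffers every frame of the stream and writes the raw container at
#' completion (one file per stream — nest it inside [select_many()] over
#' [window_trigger()] windows to split a recording into one file per
#' trigger). Forwards frames unchanged. A dimension change mid-stream is an
#' error.
#'
#' @param frames An `observable` of `frame`s.
#' @param path Output file path.
#' @return An `observable` (the input, passed through).
#' @export
frame_writer <- function(frames, path) {
  new_observable(frames$scheduler, function(obs, sub) {
    st <- new.env(parent = emptyenv())
    st$buf <- list()
    st$dim <- NULL
    up <- subscribe(frames,
      on_next = function(fr) {
        px <- frame_pixels(fr)
        if (is.null(st$dim)) st$dim <- dim(px)
        if (!identical(dim(px), st$dim)) {
          obs$on_error("frame_writer: frame dimensions changed mid-stream")
          return(invisible(NULL))
        }
        st$buf[[length(st$buf) + 1L]] <- px
        obs$on_next(fr)
      },
      on_completed = function() {
        write_frames(st$buf, path)
        obs$on_completed()
      },
      on_error = obs$on_error)
    add_teardown(sub, function() dispose(up))
  })
}
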