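#' Binary stimulus frame
#'
#' An N-by-N matrix of 0/1 pixels with a role label.  All model inputs are
#' binary: 1 marks pixels that optimally drive the feature channel, 0 the
#' opposite.
#'
#' @param pixels numeric matrix with values in `{0, 1}`.
#' @param label role tag, e.g. `"figure-input"`, `"pattern-mask"`.
#' @return An object of class `binary_frame` (the matrix, with attributes).
#' @export
binary_frame <- function(pixels, label = "frame") {
  stopifnot(is.matrix(pixels), nrow(pixels) == ncol(pixels))
  if (!all(pixels %in% c(0, 1)))
    stop("frame pixels must be strictly binary (0 or 1)")
  storage.mode(pixels) <- "double"
  structure(pixels, label = label, class = c("binary_frame", "matrix", "array"))
}

#' @export
print.binary_frame <- function(x, ...) {
  cat(sprintf("binary frame '%s': %dx%d, %d active pixels\n",
              attr(x, "label"), nrow(x), ncol(x), sum(x)))
  invisible(x)
}

#' Figure-ground texture pair
#'
#' The figure-ground stimulus is a pair of complementary binary textures: the
#' first channel's input is all zeros except a centred `fig_size` x
#' `fig_size` square of ones (the figure); the second channel's input is its
#' binary complement (the ground).  Together they tile the grid.
#'
#' The figure occupies rows and columns `[N/2 - fig_size/2, N/2 + fig_size/2)`
#' in 0-based half-open indexing, so both `N` and `fig_size` must be even for
#' the square to centre exactly.
#'
#' @param N grid side (default 64).
#' @param fig_size side of the central square (default 16).
#' @return A list with `feat1` (figure input) and `feat2` (its complement),
#'   both [binary_frame()]s.
#' @examples
#' fg <- make_fg_texture(64, 16)
#' sum(fg$feat1)  # 256
#' @export
make_fg_texture <- function(N = 64, fig_size = 16) {
  stopifnot(N > 0, fig_size > 0)
  if (fig_size >= N) stop("fig_size must be smaller than N")
  if (N %% 2L != 0L || fig_size %% 2L != 0L)
    stop("N and fig_size must both be even so the figure centres exactly")
  f <- matrix(0, N, N)
  idx <- (N / 2 - fig_size / 2 + 1):(N / 2 + fig_size / 2)
  f[idx, idx] <- 1
  list(feat1 = binary_frame(f, "figure-input"),
       feat2 = binary_frame(1 - f, "complement"))
}

#' Random binary pattern mask
#'
#' I.i.d. Bernoulli(`p`) pixels; reproducible under `seed`.  The RNG state of
#' the session is left untouched.
#'
#' @param N grid side.
#' @param p probability that a pixel is 1 (default 0.5, an unbiased random
#'   binary texture).
#' @param seed optional integer seed for reproducibility.
#' @return A [binary_frame()] labelled `"pattern-mask"`.
#' @export
make_pattern_mask <- function(N = 64, p = 0.5, seed = NULL) {
  stopifnot(p >= 0, p <= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  binary_frame(matrix(stats::rbinom(N * N, 1L, p), N, N), "pattern-mask")
}

#' Uniform (homogeneous) mask
#'
#' All pixels 1: a large homogeneous surface presented to both channels.
#'
#' @param N grid side.
#' @return A [binary_frame()] labelled `"uniform-mask"`.
#' @export
make_uniform_mask <- function(N = 64) {
  binary_frame(matrix(1, N, N), "uniform-mask")
}

#' Metacontrast target/mask pair
#'
#' The target is the central square; the metacontrast mask is its spatial
#' complement, so mask and target share the same feature preference but have
#' disjoint supports (the mask never overlaps the target region).
#'
#' @inheritParams make_fg_texture
#' @return A list with `target` and `mask` [binary_frame()]s.
#' @export
make_metacontrast_pair <- function(N = 64, fig_size = 16) {
  fg <- make_fg_texture(N, fig_size)
  list(target = binary_frame(unclass(fg$feat1), "target"),
       mask = binary_frame(unclass(fg$feat2), "metacontrast-mask"))
}

#' Stimulus event
#'
#' One timed presentation of a binary frame to one channel.
#'
#' @param channel 1-based channel index.
#' @param frame a [binary_frame()] (or plain binary matrix).
#' @param onset_ms onset time (ms), non-negative.
#' @param duration_ms presentation duration (ms), non-negative; `Inf` keeps
#'   the frame on until the end of the simulation.
#' @param weight input weight; the current delivered to a layer-1 neuron is
#'   `weight * pixel`.  Negative weights hyperpolarize (used by the rebound
#'   variant of the OFF channel).
#' @return A list of class `stim_event`.
#' @export
stim_event <- function(channel, frame, onset_ms, duration_ms, weight = 1) {
  stopifnot(channel >= 1, onset_ms >= 0, duration_ms >= 0)
  if (!inherits(frame, "binary_frame")) frame <- binary_frame(frame)
  structure(list(channel = as.integer(channel), frame = frame,
                 onset_ms = onset_ms, duration_ms = duration_ms,
                 weight = weight),
            class = "stim_event")
}

#' Build a time-resolved stimulus schedule
#'
#' Collects timed frame presentations into a schedule the network integrator
#' consumes.  Event times are rounded down to the containing Euler step.
#' Overlapping events on one channel combine by pixel-wise OR of the weighted
#' frames (pixelwise max over positive-weight events plus pixelwise min over
#' negative-weight events), so doubly covered pixels are not driven twice.
#'
#' @param events a list of [stim_event()]s.
#' @param n_channels number of feature channels (default 2).
#' @param duration_ms total scheduled time (ms); defaults to the latest
#'   finite event offset.
#' @param dt Euler step used to discretize event times (ms).
#' @return An object of class `stimulus_schedule`.
#' @examples
#' fg <- make_fg_texture(16, 4)
#' sch <- build_schedule(list(
#'   stim_event(1, fg$feat1, 0, 50),
#'   stim_event(2, fg$feat2, 0, 50)), duration_ms = 100)
#' sch
#' @export
build_schedule <- function(events, n_channels = 2, duration_ms = NULL, dt = 0.2) {
  stopifnot(is.list(events), dt > 0)
  for (e in events) {
    if (!inherits(e, "stim_event")) stop("all events must be stim_event objects")
    if (e$channel > n_channels) stop("event channel exceeds n_channels")
  }
  ends <- vapply(events, function(e) e$onset_ms + e$duration_ms, numeric(1))
  if (is.null(duration_ms))
    duration_ms <- if (length(ends) && any(is.finite(ends))) max(ends[is.finite(ends)]) else 0
  structure(list(events = events, n_channels = as.integer(n_channels),
                 duration_ms = duration_ms, dt = dt),
            class = "stimulus_schedule")
}

#' @export
print.stimulus_schedule <- function(x, ...) {
  cat(sprintf("stimulus schedule: %d events, %d channels, %g ms at dt = %g ms\n",
              length(x$events), x$n_channels, x$duration_ms, x$dt))
  for (e in x$events)
    cat(sprintf("  ch %d: '%s' on [%g, %g) ms, weight %g\n", e$channel,
                attr(e$frame, "label"), e$onset_ms, e$onset_ms + e$duration_ms,
                e$weight))
  invisible(x)
}

#' Materialize the drive of one channel at a given time
#'
#' Returns the current field a layer-1 channel receives at time `t_ms`,
#' combining all active events as the schedule semantics specify.  Mainly a
#' testing and inspection helper; the compiled integrator applies the same
#' rule internally.
#'
#' @param schedule a [build_schedule()] result.
#' @param channel channel index.
#' @param t_ms time (ms).
#' @return A numeric matrix of per-pixel input currents.
#' @export
schedule_drive <- function(schedule, channel, t_ms) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  k <- floor(t_ms / schedule$dt)
  pos <- NULL
  neg <- NULL
  for (e in schedule$events) {
    if (e$channel != channel) next
    on <- floor(e$onset_ms / schedule$dt)
    off <- if (is.finite(e$duration_ms))
      floor((e$onset_ms + e$duration_ms) / schedule$dt) else Inf
    if (k < on || k >= off) next
    f <- unclass(e$frame)
    attr(f, "label") <- NULL
    wf <- e$weight * f
    if (e$weight >= 0) pos <- if (is.null(pos)) wf else pmax(pos, wf)
    else neg <- if (is.null(neg)) wf else pmin(neg, wf)
  }
  if (is.null(pos) && is.null(neg)) {
    N <- if (length(schedule$events)) nrow(schedule$events[[1]]$frame) else 1
    return(matrix(0, N, N))
  }
  if (is.null(pos)) return(neg)
  if (is.null(neg)) return(pos)
  pos + neg
}

#' Export a frame as plain text
#'
#' Writes a binary frame either as CSV (0/1 integers, no header) or as an
#' ASCII PGM image, chosen by the file extension.
#'
#' @param frame a [binary_frame()].
#' @param path output path ending in `.csv` or `.pgm`.
#' @return The path, invisibly.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "binary_frame"))
  ext <- tolower(tools::file_ext(path))
  m <- unclass(frame)
  if (ext == "csv") {
    utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  } else if (ext == "pgm") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", paste(ncol(m), nrow(m)), "1"), con)
    writeLines(apply(m, 1, paste, collapse = " "), con)
  } else stop("unsupported frame format: ", ext)
  invisible(path)
}

#' Serialize a schedule to YAML or JSON
#'
#' Frames are stored run-length free as lists of active pixel indices
#' (column-major, 1-based), which keeps text files small for sparse frames.
#'
#' @param schedule a [build_schedule()] result.
#' @param path output path ending in `.yaml`, `.yml` or `.json`.
#' @return The path, invisibly.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "stimulus_schedule"))
  x <- list(n_channels = schedule$n_channels, duration_ms = schedule$duration_ms,
            dt = schedule$dt,
            events = lapply(schedule$events, function(e) list(
              channel = e$channel, label = attr(e$frame, "label"),
              N = nrow(e$frame), active = which(unclass(e$frame) == 1),
              onset_ms = e$onset_ms, duration_ms = e$duration_ms,
              weight = e$weight)))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(x, path)
  else if (ext == "json") jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  else stop("unsupported schedule format: ", ext)
  invisible(path)
}

#' Read back a serialized schedule
#'
#' @param path a file written by [write_schedule()].
#' @return A `stimulus_schedule`.
#' @export
read_schedule <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = FALSE)
  else stop("unsupported schedule format: ", ext)
  num <- function(z) if (is.null(z)) Inf else as.numeric(z)
  events <- lapply(x$events, function(e) {
    n <- as.integer(e$N)
    m <- matrix(0, n, n)
    m[unlist(e$active)] <- 1
    dur <- num(e$duration_ms[[1]])
    stim_event(as.integer(e$channel), binary_frame(m, as.character(e$label)),
               as.numeric(e$onset_ms), if (is.finite(dur)) dur else Inf,
               as.numeric(e$weight))
  })
  build_schedule(events, n_channels = as.integer(x$n_channels),
                 duration_ms = num(x$duration_ms), dt = as.numeric(x$dt))
}
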