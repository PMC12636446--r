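# Behavioral staging: from a centroid track to a developmental timeline
# (hatch, three lethargus-midpoint stage transitions, collection age).

#' Read a locomotion track from delimited text
#'
#' Expects columns `frame`, `time_s`, `x`, `y` (header required); extra
#' columns are ignored.
#'
#' @param path file path.
#' @param frame_rate frames per second (used when the file has no uniform
#'   time step to infer it from).
#' @param individual_id id to attach; defaults to the file name.
#' @return object of class `locomotion_track`.
#' @export
read_track <- function(path, frame_rate = NULL,
                       individual_id = tools::file_path_sans_ext(basename(path))) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  need <- c("frame", "time_s", "x", "y")
  if (!all(need %in% names(df))) {
    stop("track file must have columns frame, time_s, x, y", call. = FALSE)
  }
  if (is.unsorted(df$time_s, strictly = TRUE)) {
    stop("track time must be strictly increasing", call. = FALSE)
  }
  if (is.null(frame_rate)) {
    dt <- stats::median(diff(df$time_s))
    frame_rate <- 1 / dt
  }
  structure(
    list(frames = df[need], frame_rate = frame_rate,
         individual_id = individual_id, arena_diameter = NA_real_),
    class = "locomotion_track"
  )
}

#' Write a locomotion track as delimited text
#'
#' @param track a `locomotion_track`.
#' @param path output path.
#' @export
write_track <- function(track, path) {
  utils::write.table(track$frames, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.locomotion_track <- function(x, ...) {
  cat(sprintf(
    "<locomotion_track> %s: %d frames @ %.3g fps (%.1f min)\n",
    x$individual_id, nrow(x$frames), x$frame_rate,
    utils::tail(x$frames$time_s, 1) / 60
  ))
  invisible(x)
}

# Split a track into contiguous segments; gaps wider than `max_gap_s` are
# never bridged by speed computation.
track_segments <- function(track, max_gap_s = 2) {
  dt <- diff(track$frames$time_s)
  breaks <- which(dt > max_gap_s)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, nrow(track$frames))
  cbind(start = starts, end = ends)
}

#' Compute windowed centroid speed
#'
#' Speed at time `t` is the Euclidean displacement over the trailing
#' `timescale_s` seconds divided by `timescale_s`. Frame gaps wider than 2 s
#' split the series; no window spans a split.
#'
#' @param track a `locomotion_track`.
#' @param timescale_s displacement window in seconds.
#' @return object of class `speed_series` with fields `time_s`, `speed`.
#' @export
compute_speed <- function(track, timescale_s = 10) {
  stopifnot_scalar_number(timescale_s, "timescale_s", positive = TRUE)
  w <- round(timescale_s * track$frame_rate)
  segs <- track_segments(track)
  if (all(segs[, "end"] - segs[, "start"] + 1 < w + 1)) {
    stop("track shorter than one speed window", call. = FALSE)
  }
  tt <- track$frames$time_s
  xx <- track$frames$x
  yy <- track$frames$y
  out_t <- numeric(0)
  out_s <- numeric(0)
  for (k in seq_len(nrow(segs))) {
    i0 <- segs[k, "start"]; i1 <- segs[k, "end"]
    n <- i1 - i0 + 1
    if (n < w + 1) next
    idx <- (i0 + w):i1
    d <- sqrt((xx[idx] - xx[idx - w])^2 + (yy[idx] - yy[idx - w])^2)
    out_t <- c(out_t, tt[idx])
    out_s <- c(out_s, d / timescale_s)
  }
  structure(
    list(time_s = out_t, speed = out_s, frame_rate = track$frame_rate,
         smoothing_window = 1L, individual_id = track$individual_id),
    class = "speed_series"
  )
}

#' Smooth a speed series with a centered moving average
#'
#' Window is forced odd; edges use shrinking (truncated) windows so the
#' series length is preserved.
#'
#' @param series a `speed_series`.
#' @param window_frames moving-average window in frames.
#' @return smoothed `speed_series`.
#' @export
smooth_speed <- function(series, window_frames = 225) {
  if (!is.numeric(window_frames) || window_frames <= 0) {
    stop("`window_frames` must be positive", call. = FALSE)
  }
  w <- as.integer(window_frames)
  if (w %% 2L == 0L) w <- w + 1L
  n <- length(series$speed)
  if (n <= w) stop("series not longer than the smoothing window", call. = FALSE)
  h <- (w - 1L) %/% 2L
  cs <- cumsum(c(0, series$speed))
  idx <- seq_len(n)
  lo <- pmax(1L, idx - h)
  hi <- pmin(n, idx + h)
  series$speed <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  series$smoothing_window <- w
  series
}

# Scale-free activity threshold: a fraction of the track's typical active
# smoothed speed (75th percentile sits inside the active regime for any
# track that is mostly active).
speed_threshold <- function(smoothed, frac = 0.1) {
  active_level <- stats::quantile(smoothed$speed, 0.75, names = FALSE)
  frac * active_level
}

#' Detect hatch time from the onset of sustained activity
#'
#' Hatching is called at the first time the smoothed speed exceeds the
#' activity threshold and stays above it for at least `persistence_min`
#' minutes. A track already active at its first observable sample reports
#' hatch at 0.
#'
#' @param track a `locomotion_track`.
#' @param activity_threshold absolute speed threshold; `NULL` uses
#'   `threshold_frac` of the track's active speed level.
#' @param threshold_frac fraction used for the scale-free default threshold.
#' @param persistence_min minimum sustained suprathreshold run, minutes.
#' @param timescale_s,window_frames speed-computation parameters.
#' @return hatch time in minutes since recording start.
#' @export
detect_hatch <- function(track, activity_threshold = NULL, threshold_frac = 0.1,
                         persistence_min = 2, timescale_s = 10, window_frames = 225) {
  sm <- smooth_speed(compute_speed(track, timescale_s), window_frames)
  thr <- if (is.null(activity_threshold)) speed_threshold(sm, threshold_frac) else activity_threshold
  if (thr <= 0 || all(sm$speed <= thr)) stop("no hatch detected", call. = FALSE)
  above <- sm$speed > thr
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  need <- persistence_min * 60 * track$frame_rate
  ok <- which(r$values & r$lengths >= need)
  if (!length(ok)) stop("no hatch detected", call. = FALSE)
  first <- starts[ok[1]]
  if (first == 1L) return(0)
  sm$time_s[first] / 60
}

#' Detect quiescence bouts in a smoothed speed series
#'
#' Maximal sub-threshold runs; runs separated by less than `merge_gap_min`
#' are merged, and merged runs shorter than `min_duration_min` are
#' discarded.
#'
#' @param series a smoothed `speed_series`.
#' @param threshold absolute speed threshold; `NULL` uses `threshold_frac`
#'   of the active speed level.
#' @param threshold_frac fraction for the scale-free default.
#' @param min_duration_min minimum bout duration, minutes.
#' @param merge_gap_min gaps shorter than this (minutes) are bridged.
#' @return data.frame with `start_min`, `end_min`, `midpoint_min`,
#'   `duration_min`, sorted by start (possibly zero rows).
#' @export
detect_quiescence_bouts <- function(series, threshold = NULL, threshold_frac = 0.1,
                                    min_duration_min = 10, merge_gap_min = 5) {
  thr <- if (is.null(threshold)) speed_threshold(series, threshold_frac) else threshold
  below <- series$speed < thr
  empty <- data.frame(start_min = numeric(0), end_min = numeric(0),
                      midpoint_min = numeric(0), duration_min = numeric(0))
  if (!any(below)) return(empty)
  r <- rle(below)
  ends_i <- cumsum(r$lengths)
  starts_i <- ends_i - r$lengths + 1L
  runs <- which(r$values)
  start <- series$time_s[starts_i[runs]] / 60
  end <- series$time_s[ends_i[runs]] / 60
  # merge runs separated by short gaps
  if (length(start) > 1) {
    keep_start <- start[1]
    merged_s <- numeric(0); merged_e <- numeric(0)
    cur_e <- end[1]
    for (i in seq_along(start)[-1]) {
      if (start[i] - cur_e < merge_gap_min) {
        cur_e <- end[i]
      } else {
        merged_s <- c(merged_s, keep_start); merged_e <- c(merged_e, cur_e)
        keep_start <- start[i]; cur_e <- end[i]
      }
    }
    merged_s <- c(merged_s, keep_start); merged_e <- c(merged_e, cur_e)
    start <- merged_s; end <- merged_e
  }
  dur <- end - start
  keep <- dur >= min_duration_min
  data.frame(
    start_min = start[keep], end_min = end[keep],
    midpoint_min = (start[keep] + end[keep]) / 2, duration_min = dur[keep]
  )
}

#' Developmental timeline of one individual
#'
#' @param hatch_min hatch time, minutes since recording start.
#' @param transitions length-3 increasing vector: lethargus midpoints at the
#'   L1/L2, L2/L3 and L3/L4 boundaries (minutes).
#' @param collection_min collection time, minutes.
#' @param individual_id id string.
#' @param partial logical; allow fewer than 3 transitions (padded with NA).
#' @return object of class `developmental_timeline` with derived
#'   `age_since_hatch` and `age_since_L4` at collection.
#' @export
developmental_timeline <- function(hatch_min, transitions, collection_min,
                                   individual_id = NA_character_, partial = FALSE) {
  if (!partial) {
    if (length(transitions) != 3L) stop("need exactly 3 transitions", call. = FALSE)
    ord <- c(hatch_min, transitions, collection_min)
    if (any(diff(ord) < 0) || any(diff(c(hatch_min, transitions)) <= 0)) {
      stop("timeline must satisfy hatch < t1 < t2 < t3 <= collection", call. = FALSE)
    }
  } else {
    transitions <- c(transitions, rep(NA_real_, max(0, 3 - length(transitions))))[1:3]
  }
  structure(
    list(
      individual_id = individual_id,
      hatch_min = hatch_min,
      transitions = as.numeric(transitions),
      collection_min = collection_min,
      age_since_hatch = collection_min - hatch_min,
      age_since_L4 = collection_min - transitions[3]
    ),
    class = "developmental_timeline"
  )
}

#' @export
print.developmental_timeline <- function(x, ...) {
  cat(sprintf(
    "<developmental_timeline> %s hatch=%.1f t=[%s] collect=%.1f (L4 age %.1f min)\n",
    x$individual_id, x$hatch_min,
    paste(sprintf("%.1f", x$transitions), collapse = ", "),
    x$collection_min, x$age_since_L4
  ))
  invisible(x)
}

#' Call stage transitions from detected quiescence bouts
#'
#' The three stage transitions are the midpoints of the three
#' highest-scoring post-hatch bouts (score = duration; ties broken by
#' earlier start), reported in temporal order.
#'
#' @param bouts data.frame from [detect_quiescence_bouts()].
#' @param hatch_time hatch time, minutes.
#' @param collection_min collection time, minutes (defaults to the last bout
#'   end if missing; normally pass the track end).
#' @param partial allow incomplete timelines.
#' @param individual_id id for error messages and the returned timeline.
#' @return a [developmental_timeline()].
#' @export
call_transitions <- function(bouts, hatch_time, collection_min,
                             partial = FALSE, individual_id = NA_character_) {
  post <- bouts[bouts$midpoint_min > hatch_time, , drop = FALSE]
  if (nrow(post) < 3 && !partial) {
    stop(sprintf(
      "staging error for '%s': %d qualifying bout(s), need 3",
      individual_id, nrow(post)
    ), call. = FALSE)
  }
  ord <- order(-post$duration_min, post$start_min)
  chosen <- post[ord[seq_len(min(3L, nrow(post)))], , drop = FALSE]
  transitions <- sort(chosen$midpoint_min)
  developmental_timeline(hatch_time, transitions, collection_min,
                         individual_id = individual_id, partial = partial)
}

#' Stage a track end to end
#'
#' Convenience wrapper: speed, smoothing, hatch detection, bout detection,
#' transition calling; collection time is the last frame.
#'
#' @param track a `locomotion_track`.
#' @param threshold_frac fraction of the active speed level used as the
#'   quiescence/activity threshold.
#' @param timescale_s,window_frames speed parameters.
#' @param min_duration_min,merge_gap_min bout-detection parameters.
#' @param partial allow incomplete timelines.
#' @return a [developmental_timeline()].
#' @export
stage_track <- function(track, threshold_frac = 0.1, timescale_s = 10,
                        window_frames = 225, min_duration_min = 10,
                        merge_gap_min = 5, partial = FALSE) {
  sm <- smooth_speed(compute_speed(track, timescale_s), window_frames)
  thr <- speed_threshold(sm, threshold_frac)
  hatch <- detect_hatch(track, activity_threshold = thr,
                        timescale_s = timescale_s, window_frames = window_frames)
  bouts <- detect_quiescence_bouts(sm, threshold = thr,
                                   min_duration_min = min_duration_min,
                                   merge_gap_min = merge_gap_min)
  call_transitions(bouts, hatch,
                   collection_min = utils::tail(track$frames$time_s, 1) / 60,
                   partial = partial, individual_id = track$individual_id)
}

#' Collect timelines into the standard staging table
#'
#' @param timelines list of [developmental_timeline()] objects.
#' @return data.frame with columns individual_id, hatch_min, t1, t2, t3,
#'   collection_min, age_since_hatch, age_since_L4.
#' @export
timelines_table <- function(timelines) {
  do.call(rbind, lapply(timelines, function(tl) {
    data.frame(
      individual_id = tl$individual_id,
      hatch_min = tl$hatch_min,
      t1 = tl$transitions[1], t2 = tl$transitions[2], t3 = tl$transitions[3],
      collection_min = tl$collection_min,
      age_since_hatch = tl$age_since_hatch,
      age_since_L4 = tl$age_since_L4,
      stringsAsFactors = FALSE
    )
  }))
}

#' Per-bin roaming fraction
#'
#' Classifies each frame as roaming (windowed speed above `speed_frac` of
#' the active level and smoothed turning rate below `turn_threshold`) and
#' reports the roaming fraction per `bin_min`-minute bin. The two-threshold
#' rule is an approximation of published roaming/dwelling classifiers.
#'
#' @param track a `locomotion_track`.
#' @param bin_min bin width, minutes.
#' @param speed_frac fraction of the active speed level for the roaming
#'   speed criterion.
#' @param turn_threshold max smoothed turning rate (rad/s) for roaming.
#' @param timescale_s,window_frames speed parameters.
#' @return data.frame with `bin_start_min`, `bin_end_min`, `fraction_roaming`,
#'   `n_frames`.
#' @export
roaming_fraction <- function(track, bin_min = 3, speed_frac = 0.5,
                             turn_threshold = 0.3, timescale_s = 10,
                             window_frames = 225) {
  sm <- smooth_speed(compute_speed(track, timescale_s), window_frames)
  thr <- speed_threshold(sm, 0.75) / 0.75 * speed_frac  # speed_frac of active level
  # turning rate from successive displacement headings, smoothed like speed
  seg <- track$frames
  dx <- diff(seg$x); dy <- diff(seg$y)
  heading <- atan2(dy, dx)
  dturn <- abs(atan2(sin(diff(heading)), cos(diff(heading)))) * track$frame_rate
  dturn <- c(dturn[1], dturn, dturn[length(dturn)])  # pad to frame count
  turn_at <- stats::approx(seg$time_s, dturn, xout = sm$time_s, rule = 2)$y
  w <- sm$smoothing_window
  cs <- cumsum(c(0, turn_at))
  n <- length(turn_at); h <- (w - 1L) %/% 2L
  idx <- seq_len(n)
  lo <- pmax(1L, idx - h); hi <- pmin(n, idx + h)
  turn_sm <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  roaming <- sm$speed > thr & turn_sm < turn_threshold
  bin <- floor(sm$time_s / 60 / bin_min)
  agg <- tapply(roaming, bin, mean)
  cnt <- tapply(roaming, bin, length)
  b <- as.numeric(names(agg))
  data.frame(
    bin_start_min = b * bin_min, bin_end_min = (b + 1) * bin_min,
    fraction_roaming = as.numeric(agg), n_frames = as.integer(cnt)
  )
}
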