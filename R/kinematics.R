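#' Compute per-frame swimming speed
#'
#' Speed at frame `j` is the Euclidean displacement between consecutive
#' samples `j-1` and `j` divided by the frame interval, assigned to the
#' later sample (frame `j` covers `((j-1)/fps, j/fps]`). Speed is
#' undefined (invalid) across tracking gaps: a frame is valid only when
#' both of its endpoint samples are present.
#'
#' @param traj A [trajectory()].
#' @param smooth_window_s Optional boxcar smoothing window in seconds
#'   (default 0 = no smoothing). When positive, valid speeds are replaced
#'   by a centred running mean over `round(smooth_window_s * fps)` frames
#'   (forced odd); frames whose window touches a gap stay unsmoothed.
#' @return A `speed_series` with elements `speed`, `valid`, `fps`.
#' @export
compute_speed <- function(traj, smooth_window_s = 0) {
  stopifnot(inherits(traj, "trajectory"))
  n <- length(traj$x)
  if (n < 2L || sum(traj$present) < 2L) {
    warning("trajectory has fewer than 2 valid samples; empty speed series",
            call. = FALSE)
    return(new_speed_series(traj$subject_id, numeric(0), logical(0),
                            traj$fps, traj$stage))
  }
  dx <- diff(traj$x); dy <- diff(traj$y)
  valid <- traj$present[-n] & traj$present[-1L]
  speed <- sqrt(dx * dx + dy * dy) * traj$fps
  speed[!valid] <- NA_real_
  if (smooth_window_s > 0) {
    w <- max(1L, round(smooth_window_s * traj$fps))
    if (w %% 2L == 0L) w <- w + 1L
    if (w > 1L) {
      sm <- stats::filter(speed, rep(1 / w, w), sides = 2)
      keep <- !is.na(sm)
      speed[keep] <- as.numeric(sm[keep])
    }
  }
  new_speed_series(traj$subject_id, speed, valid, traj$fps, traj$stage)
}

#' Detect rest bouts by threshold and minimum duration
#'
#' A rest bout is a maximal run of frames with speed strictly below
#' `threshold` lasting at least `min_duration_s` (inclusive: "1 min or
#' longer" under the 60 s default). Runs interrupted by tracking gaps are
#' split -- gap frames belong to no bout.
#'
#' @param speed A `speed_series` from [compute_speed()].
#' @param threshold Speed threshold in mm/s; defaults to
#'   [stage_threshold()] for the series' stage (12 mm/s juvenile,
#'   40 mm/s adult).
#' @param min_duration_s Minimum bout duration in seconds (default 60).
#' @return A `rest_bouts` data frame with columns `start_s`, `stop_s`,
#'   `duration_s` (possibly zero rows).
#' @export
detect_rest_bouts <- function(speed, threshold = NULL, min_duration_s = 60) {
  stopifnot(inherits(speed, "speed_series"), min_duration_s > 0)
  if (is.null(threshold)) threshold <- stage_threshold(speed$stage)
  stopifnot(threshold > 0)
  fps <- speed$fps
  # 0 = active, 1 = sub-threshold, 2 = gap
  code <- integer(length(speed$speed))
  code[speed$valid & speed$speed < threshold] <- 1L
  code[!speed$valid] <- 2L
  r <- rle(code)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  min_frames <- ceiling(min_duration_s * fps - 1e-9)
  keep <- r$values == 1L & r$lengths >= min_frames
  a <- starts[keep]; b <- ends[keep]
  start_s <- (a - 1L) / fps
  stop_s <- b / fps
  new_rest_bouts(speed$subject_id, start_s, stop_s, threshold, min_duration_s)
}

new_rest_bouts <- function(subject_id, start_s, stop_s, threshold = NA,
                           min_duration_s = 60) {
  structure(data.frame(start_s = as.numeric(start_s),
                       stop_s = as.numeric(stop_s),
                       duration_s = as.numeric(stop_s) - as.numeric(start_s)),
            subject_id = subject_id, threshold = threshold,
            min_duration_s = min_duration_s,
            class = c("rest_bouts", "data.frame"))
}

#' Derive rest bouts from scored active-swimming events
#'
#' Complements the active-swimming intervals of a manually scored ethogram
#' within the recording span; complement gaps of at least `min_duration_s`
#' (inclusive, matching [detect_rest_bouts()]) become rest bouts.
#'
#' @param events An [ethogram_events()].
#' @param recording_span Numeric `c(start_s, stop_s)` of the recording.
#' @param min_duration_s Minimum bout duration in seconds (default 60).
#' @return A `rest_bouts` data frame.
#' @export
ethogram_to_rest <- function(events, recording_span, min_duration_s = 60) {
  stopifnot(inherits(events, "ethogram_events"),
            length(recording_span) == 2L,
            recording_span[2] > recording_span[1], min_duration_s > 0)
  lo <- recording_span[1]; hi <- recording_span[2]
  s <- events$start_s; e <- events$stop_s
  if (length(s) && (any(s < lo - 1e-9) || any(e > hi + 1e-9)))
    warning("ethogram intervals extend outside the recording span; clipped",
            call. = FALSE)
  s <- pmax(s, lo); e <- pmin(e, hi)
  keep <- e > s
  s <- s[keep]; e <- e[keep]
  # complement within [lo, hi]
  gap_start <- c(lo, e)
  gap_stop <- c(s, hi)
  len <- gap_stop - gap_start
  tol <- 1e-9 * max(1, min_duration_s)
  sel <- len >= min_duration_s - tol
  new_rest_bouts(events$subject_id, gap_start[sel], gap_stop[sel],
                 threshold = NA, min_duration_s = min_duration_s)
}

#' @export
print.rest_bouts <- function(x, ...) {
  cat(sprintf("Rest bouts for '%s': %d bout(s), %.1f min total (threshold %s mm/s, >= %g s)\n",
              attr(x, "subject_id"), nrow(x), sum(x$duration_s) / 60,
              format(attr(x, "threshold")), attr(x, "min_duration_s")))
  if (nrow(x)) print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("...\n")
  invisible(x)
}

#' Exact time accounting of a speed series
#'
#' Partitions every frame of a speed series into four exclusive
#' categories: rest (inside a detected rest bout), active
#' (supra-threshold), sub-minimum inactivity (sub-threshold runs shorter
#' than the bout rule), and gap (speed undefined). Frame counts sum to the
#' total number of frames exactly.
#'
#' @inheritParams detect_rest_bouts
#' @return A list with integer `frames` (named: rest, active, sub_minimum,
#'   gap, total) and the corresponding `seconds`.
#' @export
time_accounting <- function(speed, threshold = NULL, min_duration_s = 60) {
  stopifnot(inherits(speed, "speed_series"))
  if (is.null(threshold)) threshold <- stage_threshold(speed$stage)
  code <- integer(length(speed$speed))
  code[speed$valid & speed$speed < threshold] <- 1L
  code[!speed$valid] <- 2L
  r <- rle(code)
  min_frames <- ceiling(min_duration_s * speed$fps - 1e-9)
  is_rest <- r$values == 1L & r$lengths >= min_frames
  is_sub <- r$values == 1L & r$lengths < min_frames
  frames <- c(rest = sum(r$lengths[is_rest]),
              active = sum(r$lengths[r$values == 0L]),
              sub_minimum = sum(r$lengths[is_sub]),
              gap = sum(r$lengths[r$values == 2L]),
              total = length(code))
  list(frames = frames, seconds = frames / speed$fps)
}
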