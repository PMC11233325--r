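#' Construct a trajectory
#'
#' A trajectory is one subject's positional time series on a uniform frame
#' grid: sample `i` (0-based) sits at `t = i / fps` seconds from recording
#' start, with coordinates in millimetres. Lost-tracking samples are kept on
#' the grid but flagged absent in `present`; speeds across them are
#' undefined rather than interpolated.
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param x,y Coordinates in mm (NA allowed where `present` is FALSE).
#' @param fps Frames per second (>= 1).
#' @param stage `"juvenile"` or `"adult"`; selects the default analysis
#'   speed threshold (12 and 40 mm/s respectively).
#' @param present Logical mask of valid samples; defaults to non-NA x and y.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(subject_id, x, y, fps, stage = c("juvenile", "adult"),
                       present = NULL) {
  stage <- match.arg(stage)
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 1L, is.numeric(fps), length(fps) == 1L, fps >= 1)
  if (is.null(present)) present <- !is.na(x) & !is.na(y)
  stopifnot(is.logical(present), length(present) == length(x))
  if (any(!is.finite(x[present])) || any(!is.finite(y[present])))
    stop("x, y must be finite where present", call. = FALSE)
  structure(list(subject_id = as.character(subject_id)[1L],
                 x = as.numeric(x), y = as.numeric(y),
                 fps = as.numeric(fps), stage = stage,
                 present = present),
            class = "trajectory")
}

# sample times (seconds), derived on demand so trajectories stay compact;
# single definition so every pathway produces bit-identical time values
traj_times <- function(traj) (seq_along(traj$x) - 1) / traj$fps

#' @export
print.trajectory <- function(x, ...) {
  n <- length(x$x)
  cat(sprintf("Trajectory '%s' (%s): %d samples at %g fps (%.2f h), %d missing\n",
              x$subject_id, x$stage, n, x$fps,
              (n - 1) / x$fps / 3600, sum(!x$present)))
  invisible(x)
}

#' Duration of a trajectory in seconds
#' @param traj A [trajectory()].
#' @return Seconds spanned by the sample grid.
#' @export
traj_duration <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  (length(traj$x) - 1) / traj$fps
}

#' Construct an ethogram event series
#'
#' Manually scored state events for one subject: a list of
#' `(start_s, stop_s)` intervals during which the behaviour (typically
#' active swimming) was on. Intervals are normalized on construction:
#' sorted, zero/negative-length records rejected, and touching or
#' overlapping intervals merged.
#'
#' @param subject_id Subject identifier.
#' @param start_s,stop_s Interval endpoints in seconds from recording start.
#' @param behavior Behaviour label (default `"active_swimming"`).
#' @return An object of class `ethogram_events` with normalized intervals;
#'   the number of rejected records is stored in attribute `n_rejected`.
#' @export
ethogram_events <- function(subject_id, start_s, stop_s,
                            behavior = "active_swimming") {
  stopifnot(is.numeric(start_s), is.numeric(stop_s),
            length(start_s) == length(stop_s))
  bad <- !is.finite(start_s) | !is.finite(stop_s) | stop_s <= start_s
  n_rejected <- sum(bad)
  if (n_rejected > 0)
    warning(sprintf("ethogram '%s': rejected %d record(s) with stop <= start",
                    as.character(subject_id)[1L], n_rejected), call. = FALSE)
  ivl <- normalize_intervals(start_s[!bad], stop_s[!bad])
  structure(list(subject_id = as.character(subject_id)[1L],
                 behavior = as.character(behavior)[1L],
                 start_s = ivl$start_s, stop_s = ivl$stop_s),
            class = "ethogram_events", n_rejected = n_rejected)
}

# sort and merge touching/overlapping intervals
normalize_intervals <- function(start_s, stop_s) {
  if (length(start_s) == 0L)
    return(list(start_s = numeric(0), stop_s = numeric(0)))
  o <- order(start_s, stop_s)
  start_s <- start_s[o]; stop_s <- stop_s[o]
  ms <- numeric(length(start_s)); me <- numeric(length(start_s))
  k <- 1L; ms[1L] <- start_s[1L]; me[1L] <- stop_s[1L]
  for (i in seq_along(start_s)[-1L]) {
    if (start_s[i] <= me[k]) {
      me[k] <- max(me[k], stop_s[i])
    } else {
      k <- k + 1L; ms[k] <- start_s[i]; me[k] <- stop_s[i]
    }
  }
  list(start_s = ms[seq_len(k)], stop_s = me[seq_len(k)])
}

#' @export
print.ethogram_events <- function(x, ...) {
  cat(sprintf("Ethogram '%s': %d '%s' interval(s), %.1f s total\n",
              x$subject_id, length(x$start_s), x$behavior,
              sum(x$stop_s - x$start_s)))
  invisible(x)
}

# internal speed-series constructor; speed[j] covers ((j-1)/fps, j/fps]
new_speed_series <- function(subject_id, speed, valid, fps, stage = "juvenile") {
  structure(list(subject_id = subject_id, speed = speed, valid = valid,
                 fps = fps, stage = stage),
            class = "speed_series")
}

#' @export
print.speed_series <- function(x, ...) {
  cat(sprintf("Speed series '%s': %d frames at %g fps, %d undefined (gaps)\n",
              x$subject_id, length(x$speed), x$fps, sum(!x$valid)))
  invisible(x)
}

#' Default analysis speed threshold for a life stage
#'
#' Sub-threshold swimming counts as inactivity; thresholds are 12 mm/s for
#' juveniles and 40 mm/s (4 cm/s) for adults, determined empirically in
#' this assay lineage to separate passive drift from active swimming.
#'
#' @param stage `"juvenile"` or `"adult"`.
#' @return Threshold in mm/s.
#' @export
stage_threshold <- function(stage = c("juvenile", "adult")) {
  stage <- match.arg(stage)
  c(juvenile = 12, adult = 40)[[stage]]
}
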