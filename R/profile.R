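#' Construct an hourly zeitgeber profile
#'
#' An hourly profile holds 24 zeitgeber-hour bins (bin `k` covers
#' `[ZT k, ZT k+1)`) of locomotion (mm per hour), time spent active
#' (minutes per hour) and rest (minutes per hour), for one subject or
#' group, averaged across recording days for multi-day recordings.
#' Normally produced by [bin_hourly()]; the constructor is exported for
#' building analytic profiles directly.
#'
#' @param locomotion Numeric length-24 vector, mm per hour, in ZT order
#'   (bin 1 = ZT0); NA where unmeasured.
#' @param active_min,rest_min Optional length-24 vectors of minutes per
#'   hour.
#' @param schedule The [light_schedule()] the profile is referenced to.
#' @param subject_id Subject or group identifier.
#' @param n_days Number of recording days averaged per bin.
#' @return An object of class `hourly_profile` (a data frame with columns
#'   `zt`, `locomotion`, `active_min`, `rest_min`).
#' @export
hourly_profile <- function(locomotion = rep(NA_real_, 24),
                           active_min = rep(NA_real_, 24),
                           rest_min = rep(NA_real_, 24),
                           schedule = light_schedule(),
                           subject_id = "subject", n_days = 1) {
  stopifnot(length(locomotion) == 24L, length(active_min) == 24L,
            length(rest_min) == 24L, inherits(schedule, "light_schedule"))
  if (any(rest_min < -1e-9 | rest_min > 60 + 1e-9, na.rm = TRUE))
    stop("rest_min must lie in [0, 60] minutes per hour", call. = FALSE)
  if (any(locomotion < 0, na.rm = TRUE))
    stop("locomotion must be non-negative", call. = FALSE)
  structure(data.frame(zt = 0:23, locomotion = as.numeric(locomotion),
                       active_min = as.numeric(active_min),
                       rest_min = as.numeric(rest_min)),
            schedule = schedule, subject_id = as.character(subject_id)[1L],
            n_days = n_days,
            class = c("hourly_profile", "data.frame"))
}

#' @export
print.hourly_profile <- function(x, ...) {
  cat(sprintf("Hourly profile '%s' (%g day(s) averaged)\n",
              attr(x, "subject_id"), max(attr(x, "n_days"))))
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Bin locomotion and rest into zeitgeber-hour profiles
#'
#' Builds the 24-bin hourly profile of a recording: locomotion per ZT hour
#' is the sum of frame displacements whose later sample falls in that hour
#' (gap frames excluded); active minutes count supra-threshold frames;
#' rest minutes are the overlap of rest bouts with the hour (bouts
#' spanning bin edges are split pro rata). Multi-day recordings are
#' averaged per ZT hour across days. Only whole recorded hours are used;
#' a trailing partial hour is dropped, and ZT bins never covered are NA.
#'
#' For ethogram events, locomotion is unavailable (NA); active minutes
#' come from the scored intervals and rest minutes from
#' [ethogram_to_rest()].
#'
#' @param x A [trajectory()] or [ethogram_events()].
#' @param schedule A [light_schedule()].
#' @param ... Method arguments.
#' @return An [hourly_profile()].
#' @export
bin_hourly <- function(x, schedule = light_schedule(), ...) {
  UseMethod("bin_hourly")
}

#' @rdname bin_hourly
#' @param bouts Optional `rest_bouts` (from [detect_rest_bouts()]) used to
#'   fill `rest_min`; if `NULL`, rest minutes are NA.
#' @param threshold Speed threshold for the active-minutes column;
#'   defaults to [stage_threshold()] of the trajectory's stage.
#' @param speed Optional precomputed `speed_series` (recomputed from the
#'   trajectory if omitted).
#' @export
bin_hourly.trajectory <- function(x, schedule = light_schedule(),
                                  bouts = NULL, threshold = NULL,
                                  speed = NULL, ...) {
  fps <- x$fps
  fph <- round(3600 * fps)
  if (abs(3600 * fps - fph) > 1e-6)
    stop("fps must divide the hour into an integer number of frames",
         call. = FALSE)
  N <- length(x$x) - 1L
  H <- N %/% fph
  if (H < 1L) stop("recording shorter than 1 h cannot be binned", call. = FALSE)
  if (is.null(speed)) speed <- compute_speed(x)
  if (is.null(threshold)) threshold <- stage_threshold(x$stage)
  used <- seq_len(H * fph)
  hour <- rep.int(seq_len(H) - 1L, rep.int(fph, H))
  sp <- speed$speed[used]
  ok <- speed$valid[used]
  dist <- sp / fps
  dist[!ok] <- 0
  loco_h <- as.vector(rowsum(dist, hour, reorder = TRUE))
  act_h <- as.vector(rowsum(as.numeric(ok & sp >= threshold), hour,
                            reorder = TRUE)) / fps / 60
  rest_h <- if (is.null(bouts)) rep(NA_real_, H) else
    bout_overlap_minutes(bouts, H)
  fold_days(loco_h, act_h, rest_h, schedule, x$subject_id)
}

#' @rdname bin_hourly
#' @param recording_span Numeric `c(start_s, stop_s)` of the scored
#'   recording (required for ethogram events).
#' @param min_duration_s Minimum rest-bout duration in seconds.
#' @export
bin_hourly.ethogram_events <- function(x, schedule = light_schedule(),
                                       recording_span, min_duration_s = 60,
                                       ...) {
  stopifnot(length(recording_span) == 2L,
            recording_span[1] == 0) # profiles are referenced to recording start
  H <- floor((recording_span[2] - recording_span[1]) / 3600 + 1e-9)
  if (H < 1L) stop("recording shorter than 1 h cannot be binned", call. = FALSE)
  act_h <- interval_overlap_minutes(x$start_s, x$stop_s, H)
  bouts <- ethogram_to_rest(x, recording_span, min_duration_s)
  rest_h <- bout_overlap_minutes(bouts, H)
  fold_days(rep(NA_real_, H), act_h, rest_h, schedule, x$subject_id)
}

# minutes of overlap of (start_s, stop_s) intervals with each recording
# hour [3600 h, 3600 (h+1)), h = 0..H-1
interval_overlap_minutes <- function(start_s, stop_s, H) {
  out <- numeric(H)
  for (i in seq_along(start_s)) {
    h0 <- max(0L, floor(start_s[i] / 3600))
    h1 <- min(H - 1L, floor((stop_s[i] - 1e-12) / 3600))
    if (h1 < h0) next
    for (h in h0:h1) {
      ov <- min(stop_s[i], 3600 * (h + 1)) - max(start_s[i], 3600 * h)
      if (ov > 0) out[h + 1L] <- out[h + 1L] + ov / 60
    }
  }
  out
}

bout_overlap_minutes <- function(bouts, H) {
  interval_overlap_minutes(bouts$start_s, bouts$stop_s, H)
}

# average recording hours into ZT bins across days
fold_days <- function(loco_h, act_h, rest_h, schedule, subject_id) {
  H <- length(loco_h)
  zt <- (schedule$recording_start_zt + seq_len(H) - 1L) %% 24L
  f <- factor(zt, levels = 0:23)
  cnt <- as.integer(table(f))
  avg <- function(v) {
    s <- tapply(v, f, function(z) if (all(is.na(z))) NA_real_ else sum(z))
    out <- as.numeric(s) / cnt
    out[cnt == 0L] <- NA_real_
    out
  }
  hourly_profile(locomotion = avg(loco_h), active_min = avg(act_h),
                 rest_min = avg(rest_h), schedule = schedule,
                 subject_id = subject_id, n_days = max(cnt))
}

#' Mean hourly activity in the light and dark phases
#'
#' `D` is the mean of the light-phase bins and `N` the mean of the
#' dark-phase bins of an hourly profile (14 and 10 bins under the default
#' 14:10 schedule). NA bins propagate: partial days are rejected rather
#' than guessed.
#'
#' @param profile An [hourly_profile()].
#' @param measure Which profile column to average: `"locomotion"` (mm/h),
#'   `"active_min"` or `"rest_min"` (min/h).
#' @param schedule Optional [light_schedule()] override; defaults to the
#'   schedule stored in the profile.
#' @return Named numeric `c(D = , N = )`.
#' @export
day_night_means <- function(profile, measure = c("locomotion", "active_min",
                                                 "rest_min"),
                            schedule = NULL) {
  stopifnot(inherits(profile, "hourly_profile"))
  measure <- match.arg(measure)
  if (is.null(schedule)) schedule <- attr(profile, "schedule")
  light <- in_light(schedule, profile$zt)
  v <- profile[[measure]]
  c(D = mean(v[light]), N = mean(v[!light]))
}

#' Average hourly profiles across subjects
#'
#' Per-bin arithmetic mean across subjects sharing one binning, as used
#' for group recordings where individual identity cannot be maintained:
#' the group's average locomotion stands in for the individual traces.
#'
#' @param profiles List of [hourly_profile()] with identical bin structure.
#' @param group_id Identifier for the averaged profile.
#' @return An [hourly_profile()] with attribute `n_subjects`.
#' @export
group_average <- function(profiles, group_id = "group") {
  stopifnot(is.list(profiles), length(profiles) >= 1L)
  lapply(profiles, function(p) stopifnot(inherits(p, "hourly_profile")))
  sched <- attr(profiles[[1L]], "schedule")
  for (p in profiles[-1L]) {
    s2 <- attr(p, "schedule")
    if (!identical(unclass(sched), unclass(s2)))
      stop("profiles have mismatched schedules", call. = FALSE)
  }
  m <- function(col) rowMeans(vapply(profiles, function(p) p[[col]],
                                     numeric(24)))
  out <- hourly_profile(locomotion = m("locomotion"),
                        active_min = m("active_min"),
                        rest_min = m("rest_min"),
                        schedule = sched, subject_id = group_id,
                        n_days = max(vapply(profiles, function(p)
                          max(attr(p, "n_days")), 0)))
  attr(out, "n_subjects") <- length(profiles)
  out
}

#' Plot a 24 h hourly profile
#'
#' Draws the profile against zeitgeber time with the dark period shaded,
#' in the style of standard actogram-adjacent locomotion figures.
#'
#' @param x An [hourly_profile()].
#' @param measure Profile column to draw.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.hourly_profile <- function(x, measure = c("locomotion", "active_min",
                                               "rest_min"), ...) {
  measure <- match.arg(measure)
  sched <- attr(x, "schedule")
  v <- x[[measure]]
  ylab <- switch(measure, locomotion = "locomotion (mm/h)",
                 active_min = "active (min/h)", rest_min = "rest (min/h)")
  graphics::plot(x$zt + 0.5, v, type = "n", xlab = "zeitgeber time (h)",
                 ylab = ylab, xlim = c(0, 24), xaxs = "i",
                 main = attr(x, "subject_id"), ...)
  usr <- graphics::par("usr")
  graphics::rect(sched$lights_on_h, usr[3], 24, usr[4],
                 col = grDevices::grey(0.9), border = NA)
  graphics::lines(x$zt + 0.5, v, type = "b", pch = 16)
  graphics::box()
  invisible(x)
}
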