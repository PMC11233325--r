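#' Define a light:dark schedule
#'
#' A light schedule fixes the photoperiod geometry used everywhere else in
#' the package: zeitgeber time (ZT) 0 is lights-on, lights stay on for
#' `lights_on_h` hours and off for the remaining `lights_off_h` hours, and
#' the cycle repeats with a 24 h period. `recording_start_zt` records the
#' zeitgeber hour at which the recording (time 0 of every trajectory or
#' ethogram) begins.
#'
#' The defaults describe a 14 h:10 h light:dark cycle with recording
#' starting at ZT1, the standard design for fish activity assays of this
#' kind.
#'
#' @param lights_on_h Hours of light per cycle (lights on at ZT0).
#' @param lights_off_h Hours of dark per cycle. Must satisfy
#'   `lights_on_h + lights_off_h == 24`.
#' @param recording_start_zt Zeitgeber hour at which recording starts.
#'   Must be a whole hour in `[0, 24)` so hourly bins align with ZT hours.
#' @return An object of class `light_schedule`.
#' @examples
#' sched <- light_schedule()
#' zt_hour(sched, 0)        # recording starts at ZT1
#' in_light(sched, 13)      # ZT13 is still light under 14:10
#' @export
light_schedule <- function(lights_on_h = 14, lights_off_h = 10,
                           recording_start_zt = 1) {
  stopifnot(is.numeric(lights_on_h), is.numeric(lights_off_h),
            length(lights_on_h) == 1L, length(lights_off_h) == 1L,
            lights_on_h > 0, lights_off_h > 0)
  if (abs(lights_on_h + lights_off_h - 24) > 1e-9)
    stop("lights_on_h + lights_off_h must equal 24 hours", call. = FALSE)
  if (!is.numeric(recording_start_zt) || length(recording_start_zt) != 1L ||
      recording_start_zt < 0 || recording_start_zt >= 24)
    stop("recording_start_zt must lie in [0, 24)", call. = FALSE)
  if (abs(recording_start_zt - round(recording_start_zt)) > 1e-9)
    stop("recording_start_zt must be a whole hour so bins align with ZT hours",
         call. = FALSE)
  structure(list(lights_on_h = lights_on_h,
                 lights_off_h = lights_off_h,
                 recording_start_zt = as.integer(round(recording_start_zt))),
            class = "light_schedule")
}

#' @export
print.light_schedule <- function(x, ...) {
  cat(sprintf("Light schedule: %g h light : %g h dark, recording starts at ZT%g\n",
              x$lights_on_h, x$lights_off_h, x$recording_start_zt))
  invisible(x)
}

#' Map recording time to zeitgeber time
#'
#' @param schedule A [light_schedule()].
#' @param t_s Seconds from recording start.
#' @return Zeitgeber hour in `[0, 24)` (continuous).
#' @export
zt_hour <- function(schedule, t_s) {
  stopifnot(inherits(schedule, "light_schedule"))
  (schedule$recording_start_zt + t_s / 3600) %% 24
}

#' Is a zeitgeber hour in the light phase?
#'
#' @param schedule A [light_schedule()].
#' @param zt Zeitgeber hour(s), any real value (reduced mod 24).
#' @return Logical; `TRUE` where lights are on (`ZT mod 24 < lights_on_h`).
#' @export
in_light <- function(schedule, zt) {
  stopifnot(inherits(schedule, "light_schedule"))
  (zt %% 24) < schedule$lights_on_h
}

#' Light transition times within a recording
#'
#' Returns the times (seconds from recording start) at which lights switch
#' on or off during `[0, duration_s]`, together with the transition type.
#' Used by the simulator (hazards switch at transitions, crepuscular speed
#' boost in the post-transition window) and by plotting.
#'
#' @param schedule A [light_schedule()].
#' @param duration_s Recording duration in seconds.
#' @return A data frame with columns `t_s` and `type` ("on" or "off").
#' @export
light_transitions <- function(schedule, duration_s) {
  stopifnot(inherits(schedule, "light_schedule"), duration_s > 0)
  start_zt <- schedule$recording_start_zt
  # transitions occur at ZT 0 (on) and ZT lights_on_h (off), every 24 h
  n_cycles <- ceiling(duration_s / 86400) + 1
  zt_on  <- 24 * seq(0, n_cycles) # absolute ZT hours of lights-on events
  zt_off <- schedule$lights_on_h + 24 * seq(-1, n_cycles)
  t_on  <- (zt_on - start_zt) * 3600
  t_off <- (zt_off - start_zt) * 3600
  out <- rbind(data.frame(t_s = t_on, type = "on"),
               data.frame(t_s = t_off, type = "off"))
  out <- out[out$t_s > 0 & out$t_s < duration_s, , drop = FALSE]
  out <- out[order(out$t_s), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Zeitgeber hour index (integer 0..23) of recording hour h (0-based).
zt_of_hour <- function(schedule, h) {
  (schedule$recording_start_zt + h) %% 24L
}
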