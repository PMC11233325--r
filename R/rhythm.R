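#' Analyse the rest-activity rhythm of one subject
#'
#' The central analysis of the package: from a positional trajectory (or a
#' manually scored ethogram) it computes per-frame speed, detects rest
#' bouts by the threshold-and-minimum-duration rule, bins locomotion,
#' activity and rest into zeitgeber-hour profiles, and derives the
#' day/night means `D` and `N`, the diurnality index
#' `A_R = (D - N)/(D + N)` and the crepuscularity index `C_R = C/NC - 1`.
#'
#' For trajectories the indices are computed on locomotion (mm/h); for
#' ethograms, where distances are unobservable, on time spent active
#' (min/h). The fitted object carries the full profile, the bout table
#' and an exact time accounting, and supports `print`, `summary`, `coef`
#' and `plot`.
#'
#' @param x A [trajectory()] or [ethogram_events()].
#' @param schedule A [light_schedule()].
#' @param ... Method arguments.
#' @return An object of class `rhythm_fit`.
#' @examples
#' sim <- simulate_trajectory(sim_params(seed = 42, fps = 5, duration_h = 24))
#' fit <- rhythm_analysis(sim$trajectories[[1]])
#' coef(fit)["A_R"]
#' @export
rhythm_analysis <- function(x, schedule = light_schedule(), ...) {
  UseMethod("rhythm_analysis")
}

#' @rdname rhythm_analysis
#' @param threshold Speed threshold (mm/s); default from the stage.
#' @param min_duration_s Minimum rest-bout duration (s).
#' @param window_h Crepuscular window (h), 1 or 2.
#' @param smooth_window_s Optional boxcar speed smoothing (s), 0 = none.
#' @export
rhythm_analysis.trajectory <- function(x, schedule = light_schedule(),
                                       threshold = NULL, min_duration_s = 60,
                                       window_h = 1, smooth_window_s = 0,
                                       ...) {
  if (is.null(threshold)) threshold <- stage_threshold(x$stage)
  speed <- compute_speed(x, smooth_window_s = smooth_window_s)
  bouts <- detect_rest_bouts(speed, threshold, min_duration_s)
  profile <- bin_hourly(x, schedule, bouts = bouts, threshold = threshold,
                        speed = speed)
  acct <- time_accounting(speed, threshold, min_duration_s)
  new_rhythm_fit(x$subject_id, profile, bouts, schedule,
                 measure = "locomotion", window_h = window_h,
                 params = list(threshold = threshold,
                               min_duration_s = min_duration_s,
                               window_h = window_h,
                               smooth_window_s = smooth_window_s,
                               stage = x$stage),
                 accounting = acct)
}

#' @rdname rhythm_analysis
#' @param recording_span Numeric `c(start_s, stop_s)` of the scored
#'   recording.
#' @export
rhythm_analysis.ethogram_events <- function(x, schedule = light_schedule(),
                                            recording_span,
                                            min_duration_s = 60,
                                            window_h = 1, ...) {
  bouts <- ethogram_to_rest(x, recording_span, min_duration_s)
  profile <- bin_hourly(x, schedule, recording_span = recording_span,
                        min_duration_s = min_duration_s)
  new_rhythm_fit(x$subject_id, profile, bouts, schedule,
                 measure = "active_min", window_h = window_h,
                 params = list(threshold = NA_real_,
                               min_duration_s = min_duration_s,
                               window_h = window_h, stage = NA_character_),
                 accounting = NULL)
}

new_rhythm_fit <- function(subject_id, profile, bouts, schedule, measure,
                           window_h, params, accounting) {
  dn <- day_night_means(profile, measure = measure)
  AR <- diurnality_index(dn[["D"]], dn[["N"]])
  cr <- crepuscularity_index(profile, window_h = window_h, measure = measure)
  indices <- c(D = dn[["D"]], N = dn[["N"]], A_R = AR,
               C = cr$C, NC = cr$NC, C_R = cr$C_R)
  structure(list(subject_id = subject_id, profile = profile, bouts = bouts,
                 indices = indices, measure = measure, schedule = schedule,
                 params = params, accounting = accounting),
            class = "rhythm_fit")
}

#' @export
print.rhythm_fit <- function(x, ...) {
  unit <- if (x$measure == "locomotion") "mm/h" else "min/h"
  cat(sprintf("Rest-activity rhythm analysis for '%s' (%s-based)\n",
              x$subject_id, x$measure))
  cat(sprintf("  D = %.4g %s, N = %.4g %s, A_R = %s\n",
              x$indices[["D"]], unit, x$indices[["N"]], unit,
              format(x$indices[["A_R"]], digits = 4)))
  cat(sprintf("  C = %.4g, NC = %.4g, C_R = %s\n",
              x$indices[["C"]], x$indices[["NC"]],
              format(x$indices[["C_R"]], digits = 4)))
  cat(sprintf("  %d rest bout(s), %.1f min total rest\n",
              nrow(x$bouts), sum(x$bouts$duration_s) / 60))
  invisible(x)
}

#' @export
summary.rhythm_fit <- function(object, ...) {
  print(object)
  cat("\nHourly profile:\n")
  print(object$profile)
  if (!is.null(object$accounting)) {
    cat("\nTime accounting (s):\n")
    print(round(object$accounting$seconds, 1))
  }
  invisible(object)
}

#' Indices of a fitted rhythm analysis
#'
#' @param object A `rhythm_fit`.
#' @param ... Ignored.
#' @return Named vector `D`, `N`, `A_R`, `C`, `NC`, `C_R`.
#' @export
coef.rhythm_fit <- function(object, ...) object$indices

#' Plot a fitted rhythm analysis
#'
#' Draws the 24 h profile of the fitted measure (locomotion for
#' trajectory fits, active minutes for ethogram fits) against zeitgeber
#' time with the dark phase shaded.
#'
#' @param x A `rhythm_fit`.
#' @param measure Profile column; defaults to the fitted measure.
#' @param ... Passed on to [plot.hourly_profile()].
#' @export
plot.rhythm_fit <- function(x, measure = NULL, ...) {
  if (is.null(measure)) measure <- x$measure
  plot(x$profile, measure = measure, ...)
  invisible(x)
}
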