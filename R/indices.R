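#' Diurnality index (activity change ratio)
#'
#' The activity change ratio `A_R = (D - N) / (D + N)`, where `D` and `N`
#' are mean hourly activity during the light and dark phases. +1 indicates
#' total diurnality, -1 total nocturnality, 0 no day/night preference.
#' A motionless subject (`D + N = 0`) has no diurnality: the index is NA
#' (flagged missing), never silently 0.
#'
#' @param D,N Mean hourly activity in light and dark phases (same units,
#'   non-negative).
#' @return `A_R` in `[-1, 1]`, or NA when undefined.
#' @examples
#' diurnality_index(10, 0)  #  1, fully diurnal
#' diurnality_index(0, 10)  # -1, fully nocturnal
#' diurnality_index(3, 1)   #  0.5
#' @export
diurnality_index <- function(D, N) {
  if (is.na(D) || is.na(N)) return(NA_real_)
  if (D < 0 || N < 0) stop("D and N must be non-negative", call. = FALSE)
  if (D + N == 0) return(NA_real_)
  (D - N) / (D + N)
}

#' Crepuscularity index
#'
#' Quantifies elevated activity around light transitions:
#' `C_R = C / NC - 1`, where `C` is the mean activity of the
#' `window_h`-hour bins immediately following lights-on (dawn) and
#' lights-off (dusk), and `NC` the mean of all remaining bins. 0 means no
#' change after light transitions; 1 means a 100% increase. Undefined
#' (NA) when `NC = 0`.
#'
#' @param profile An [hourly_profile()].
#' @param window_h Post-transition window in hours, 1 (default) or 2.
#' @param measure Profile column to use.
#' @param schedule Optional [light_schedule()] override.
#' @return A list with `C`, `NC` and `C_R`.
#' @examples
#' p <- hourly_profile(locomotion = rep(10, 24))
#' p$locomotion[p$zt %in% c(0, 14)] <- 20   # doubled dawn and dusk bins
#' crepuscularity_index(p)$C_R              # 1: 100% increase at transitions
#' @export
crepuscularity_index <- function(profile, window_h = 1,
                                 measure = c("locomotion", "active_min",
                                             "rest_min"),
                                 schedule = NULL) {
  stopifnot(inherits(profile, "hourly_profile"))
  measure <- match.arg(measure)
  if (!window_h %in% c(1, 2))
    stop("window_h must be 1 or 2", call. = FALSE)
  if (is.null(schedule)) schedule <- attr(profile, "schedule")
  L <- schedule$lights_on_h
  if (window_h > min(L, schedule$lights_off_h))
    stop("post-transition window overlaps the next transition", call. = FALSE)
  zt <- profile$zt
  crep <- (zt < window_h) | (zt >= L & zt < L + window_h)
  v <- profile[[measure]]
  C <- mean(v[crep]); NC <- mean(v[!crep])
  C_R <- if (is.na(NC) || is.na(C)) NA_real_
         else if (NC == 0) NA_real_
         else C / NC - 1
  list(C = C, NC = NC, C_R = C_R)
}
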