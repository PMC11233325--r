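# Shared fixtures and independent oracles for the test suite.

# Plain-loop rest-bout oracle: scans a logical rest vector (NA = tracking
# gap) frame by frame and enumerates maximal rest runs meeting the
# duration rule. Independent of the rle-based detector.
oracle_bouts <- function(rest, fps, min_duration_s) {
  n <- length(rest)
  starts <- integer(0); ends <- integer(0)
  s <- NA_integer_
  for (j in seq_len(n)) {
    r <- isTRUE(rest[j])
    if (r && is.na(s)) s <- j
    if (!is.na(s) && (!r || j == n)) {
      e <- if (r) j else j - 1L
      if ((e - s + 1L) / fps >= min_duration_s - 1e-9) {
        starts <- c(starts, s); ends <- c(ends, e)
      }
      s <- NA_integer_
    }
  }
  data.frame(start_s = (starts - 1L) / fps, stop_s = ends / fps)
}

# speed series with sub-threshold frames where rest is TRUE, supra where
# FALSE, gaps where NA
speed_from_rest <- function(rest, fps = 1, thr = 12, subject = "t") {
  sp <- rep(2 * thr, length(rest))
  sp[which(rest)] <- 0.5 * thr
  sp[is.na(rest)] <- NA_real_
  zeitact:::new_speed_series(subject, sp, !is.na(rest), fps)
}

# straight-line trajectory moving dist_per_frame mm every frame
line_trajectory <- function(n_frames, dist_per_frame, fps = 1,
                            stage = "juvenile", subject = "line") {
  trajectory(subject, x = (0:n_frames) * dist_per_frame,
             y = rep(0, n_frames + 1), fps = fps, stage = stage)
}

# profile with given locomotion vector (ZT order) under the default 14:10
loco_profile <- function(loco, schedule = light_schedule()) {
  hourly_profile(locomotion = loco, schedule = schedule)
}

# parameter set with closed-form expected_AR exactly 0.5 (light:dark
# expected hourly distances 3:1, rest jitter included); verified against
# brute-force averaging of 200 simulated subject-days before freezing
recovery_params <- function(seed, n_subjects, fps = 15) {
  sim_params(seed = seed, stage = "juvenile", duration_h = 24, fps = fps,
             n_subjects = n_subjects,
             phase_params = list(
               light = list(mean_active_speed = 50, rest_rate = 1 / 120,
                            wake_rate = 1 / 120),
               dark = list(mean_active_speed = 20.5, rest_rate = 1 / 60,
                           wake_rate = 1 / 120)),
             arena_width_mm = 60, arena_height_mm = 60)
}

# phase-homogeneous null: identical light and dark parameters, no
# crepuscular boost
null_params <- function(seed, n_subjects, fps = 15, duration_h = 24) {
  ph <- list(mean_active_speed = 40, rest_rate = 1 / 150, wake_rate = 1 / 100)
  sim_params(seed = seed, stage = "juvenile", duration_h = duration_h,
             fps = fps, n_subjects = n_subjects,
             phase_params = list(light = ph, dark = ph),
             arena_width_mm = 200, arena_height_mm = 200)
}

# per-subject day/night locomotion means from a simulation result
dn_table <- function(sim) {
  t(vapply(sim$trajectories, function(tr) {
    day_night_means(bin_hourly(tr, sim$schedule, bouts = NULL))
  }, c(D = 0, N = 0)))
}
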