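#' Simulation parameters for the two-state locomotor model
#'
#' The simulator represents a fish as a two-state semi-Markov process
#' alternating between "active" swimming and "rest". Dwell times are
#' exponential with phase-dependent hazards (`rest_rate` is the
#' active-to-rest hazard, `wake_rate` the rest-to-active hazard), switching
#' instantaneously at light transitions. While active, per-frame
#' displacement magnitudes are drawn uniformly on
#' `[threshold, 2 * mean_active_speed - threshold]`, so the mean speed
#' equals the phase mean while every active frame stays strictly above the
#' analysis threshold; headings are isotropic with reflection-free
#' rejection at the arena walls. While resting, the fish drifts with a
#' fixed jitter of 25% of the threshold (unambiguously sub-threshold).
#' During the first hour after each light transition, active speeds are
#' multiplied by `crepuscular_multiplier`.
#'
#' Stage defaults emulate the standard recording setups: juveniles in
#' 6-well plate wells (35 x 35 mm) with a 12 mm/s threshold, adults in
#' small tanks (500 x 300 mm side view) with a 40 mm/s threshold. Default
#' phase parameters give a moderately diurnal juvenile and an arrhythmic
#' adult.
#'
#' @param seed Integer RNG seed (mandatory; the simulation is fully
#'   deterministic given the parameters).
#' @param stage `"juvenile"` or `"adult"`.
#' @param duration_h Recording length in hours (default 24; multi-day
#'   recordings allowed).
#' @param fps Frames per second (default 15).
#' @param n_subjects Number of independently simulated subjects.
#' @param phase_params List with elements `light` and `dark`, each a list
#'   of `mean_active_speed` (mm/s, must exceed the stage threshold),
#'   `rest_rate` (1/s) and `wake_rate` (1/s). Defaults depend on `stage`.
#' @param crepuscular_multiplier Speed multiplier (>= 1) applied to active
#'   swimming in the first hour after each light transition.
#' @param arena_width_mm,arena_height_mm Arena dimensions (defaults by
#'   stage).
#' @param threshold Analysis speed threshold in mm/s; defaults to
#'   [stage_threshold()] for `stage`. The simulator uses it only to anchor
#'   the active/rest speed distributions.
#' @return An object of class `sim_params`.
#' @seealso [simulate_trajectory()], [ground_truth()], [species_presets()]
#' @export
sim_params <- function(seed,
                       stage = c("juvenile", "adult"),
                       duration_h = 24,
                       fps = 15,
                       n_subjects = 1,
                       phase_params = NULL,
                       crepuscular_multiplier = 1,
                       arena_width_mm = NULL,
                       arena_height_mm = NULL,
                       threshold = NULL) {
  stage <- match.arg(stage)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed is mandatory and must be a single integer", call. = FALSE)
  if (is.null(threshold)) threshold <- stage_threshold(stage)
  if (is.null(arena_width_mm))
    arena_width_mm <- if (stage == "juvenile") 35 else 500
  if (is.null(arena_height_mm))
    arena_height_mm <- if (stage == "juvenile") 35 else 300
  if (is.null(phase_params)) {
    phase_params <- if (stage == "juvenile") {
      list(light = list(mean_active_speed = 45, rest_rate = 1 / 300, wake_rate = 1 / 60),
           dark  = list(mean_active_speed = 25, rest_rate = 1 / 100, wake_rate = 1 / 100))
    } else {
      list(light = list(mean_active_speed = 120, rest_rate = 1 / 180, wake_rate = 1 / 90),
           dark  = list(mean_active_speed = 120, rest_rate = 1 / 180, wake_rate = 1 / 90))
    }
  }
  stopifnot(is.list(phase_params), all(c("light", "dark") %in% names(phase_params)))
  for (ph in c("light", "dark")) {
    p <- phase_params[[ph]]
    if (!all(c("mean_active_speed", "rest_rate", "wake_rate") %in% names(p)))
      stop("phase_params$", ph,
           " needs mean_active_speed, rest_rate, wake_rate", call. = FALSE)
    if (p$mean_active_speed <= threshold)
      stop("mean_active_speed (", ph, ") must exceed the speed threshold (",
           threshold, " mm/s)", call. = FALSE)
    if (p$rest_rate <= 0 || p$wake_rate <= 0)
      stop("rest_rate and wake_rate must be strictly positive", call. = FALSE)
  }
  stopifnot(duration_h > 0, fps >= 1, n_subjects >= 1,
            crepuscular_multiplier >= 1,
            arena_width_mm > 0, arena_height_mm > 0, threshold > 0)
  # largest possible per-frame step must fit in the arena so an admissible
  # heading always exists
  # from any point a heading at 45 degrees into the far-corner quadrant
  # stays inside when the step is at most half the smaller dimension
  vmax <- max(vapply(phase_params, function(p) p$mean_active_speed, 0))
  max_step <- crepuscular_multiplier * (2 * vmax - threshold) / fps
  if (max_step > min(arena_width_mm, arena_height_mm) / 2)
    stop(sprintf(paste0("arena too small for one displacement step: max step ",
                        "%.1f mm exceeds half the min arena dimension (%.1f mm)"),
                 max_step, min(arena_width_mm, arena_height_mm) / 2),
         call. = FALSE)
  structure(list(seed = as.integer(seed), stage = stage,
                 duration_h = duration_h, fps = fps,
                 n_subjects = as.integer(n_subjects),
                 phase_params = phase_params,
                 crepuscular_multiplier = crepuscular_multiplier,
                 arena_width_mm = arena_width_mm,
                 arena_height_mm = arena_height_mm,
                 threshold = threshold),
            class = "sim_params")
}

#' @export
print.sim_params <- function(x, ...) {
  cat(sprintf("Simulation parameters (%s): %g h at %g fps, %d subject(s), seed %d\n",
              x$stage, x$duration_h, x$fps, x$n_subjects, x$seed))
  for (ph in c("light", "dark")) {
    p <- x$phase_params[[ph]]
    cat(sprintf("  %-5s v_active = %g mm/s, rest hazard = %.4g /s, wake hazard = %.4g /s\n",
                ph, p$mean_active_speed, p$rest_rate, p$wake_rate))
  }
  if (x$crepuscular_multiplier != 1)
    cat(sprintf("  crepuscular multiplier %g in the post-transition hour\n",
                x$crepuscular_multiplier))
  invisible(x)
}

#' Closed-form ground truth for a simulation
#'
#' For each phase the stationary rest fraction of the two-state process is
#' `rest_rate / (rest_rate + wake_rate)`. The expected locomotion per hour
#' combines active swimming and the sub-threshold rest drift:
#' `3600 * ((1 - rho) * v * kappa + rho * 0.25 * threshold)` mm/h, where
#' `kappa` averages the crepuscular speed multiplier over the phase's hours
#' (one post-transition hour per phase). The expected activity change
#' ratio follows as `(D - N) / (D + N)`.
#'
#' @param params A [sim_params()].
#' @param schedule A [light_schedule()].
#' @return A list with `expected_D`, `expected_N` (mm/h), `expected_AR`,
#'   and `expected_rest_fraction` (named vector, light/dark).
#' @export
ground_truth <- function(params, schedule = light_schedule()) {
  stopifnot(inherits(params, "sim_params"), inherits(schedule, "light_schedule"))
  jit <- 0.25 * params$threshold
  m <- params$crepuscular_multiplier
  hours <- c(light = schedule$lights_on_h, dark = schedule$lights_off_h)
  out <- vapply(c("light", "dark"), function(ph) {
    p <- params$phase_params[[ph]]
    rho <- p$rest_rate / (p$rest_rate + p$wake_rate)
    w <- min(1, hours[[ph]]) # boosted post-transition window inside the phase
    kappa <- ((hours[[ph]] - w) + w * m) / hours[[ph]]
    c(rho = rho,
      mmh = 3600 * ((1 - rho) * p$mean_active_speed * kappa + rho * jit))
  }, c(rho = 0, mmh = 0))
  D <- out["mmh", "light"]; N <- out["mmh", "dark"]
  list(expected_D = unname(D), expected_N = unname(N),
       expected_AR = if (D + N > 0) unname((D - N) / (D + N)) else NA_real_,
       expected_rest_fraction = c(light = unname(out["rho", "light"]),
                                  dark = unname(out["rho", "dark"])))
}

# Event-driven state sequence for one subject over [0, duration_s].
# Returns the initial state (TRUE = rest) and the vector of switch times.
# Hazards switch at light transitions; dwell times in progress are redrawn
# there (memoryless, so equivalent to continuing with the new hazard).
sim_states <- function(params, schedule, duration_s) {
  trans <- light_transitions(schedule, duration_s)$t_s
  boundaries <- c(trans, duration_s)
  phase0 <- in_light(schedule, zt_hour(schedule, 0))
  p_light <- params$phase_params$light
  p_dark <- params$phase_params$dark
  rho0 <- with(if (phase0) p_light else p_dark, rest_rate / (rest_rate + wake_rate))
  rest <- stats::runif(1) < rho0
  init <- rest
  t <- 0
  bi <- 1L
  phase_light <- phase0
  switches <- numeric(0)
  n_sw <- 0L
  # grow in chunks to avoid quadratic appends
  cap <- 256L
  switches <- numeric(cap)
  while (t < duration_s) {
    p <- if (phase_light) p_light else p_dark
    rate <- if (rest) p$wake_rate else p$rest_rate
    nb <- boundaries[bi]
    dwell <- stats::rexp(1, rate)
    if (t + dwell >= nb) {
      t <- nb
      if (bi <= length(trans)) phase_light <- !phase_light
      bi <- bi + 1L
    } else {
      t <- t + dwell
      rest <- !rest
      n_sw <- n_sw + 1L
      if (n_sw > cap) {
        cap <- cap * 2L
        switches <- c(switches, numeric(cap / 2L))
      }
      switches[n_sw] <- t
    }
  }
  list(init_rest = init, switches = switches[seq_len(n_sw)])
}

# Per-displacement-frame quantities for one subject. Displacement frame j
# (j = 1..N) covers ((j-1)/fps, j/fps] and is attributed to its later
# sample time t_j = j/fps.
sim_frames <- function(params, schedule, duration_s, states) {
  fps <- params$fps
  N <- as.integer(round(duration_s * fps))
  tj <- seq_len(N) / fps
  # state at the later sample
  rest <- xor(states$init_rest,
              findInterval(tj, states$switches) %% 2L == 1L)
  zt <- (schedule$recording_start_zt + tj / 3600) %% 24
  light <- zt < schedule$lights_on_h
  L <- schedule$lights_on_h
  crep <- zt < 1 | (zt >= L & zt < L + 1)
  list(N = N, rest = rest, light = light, crep = crep)
}

sim_speeds <- function(params, fr) {
  thr <- params$threshold
  vl <- params$phase_params$light$mean_active_speed
  vd <- params$phase_params$dark$mean_active_speed
  v <- vd + (vl - vd) * fr$light
  u <- stats::runif(fr$N)
  speed <- (thr + u * (2 * (v - thr))) *
    (1 + (params$crepuscular_multiplier - 1) * fr$crep)
  speed[fr$rest] <- 0.25 * thr
  speed
}

#' Simulate trajectories with known ground truth
#'
#' Runs the two-state semi-Markov locomotor model (see [sim_params()]) for
#' each subject and returns positional trajectories on the frame grid,
#' together with the closed-form [ground_truth()]. Fully deterministic
#' given the seed: each subject gets a sub-seed drawn from the master seed,
#' so [simulate_ethogram()] with the same parameters reproduces exactly the
#' same state sequences.
#'
#' @param params A [sim_params()].
#' @param schedule A [light_schedule()].
#' @return A list with `trajectories` (list of [trajectory()], one per
#'   subject), `ground_truth`, `params` and `schedule`.
#' @examples
#' sim <- simulate_trajectory(sim_params(seed = 1, duration_h = 2, fps = 5))
#' sim$ground_truth$expected_AR
#' @export
simulate_trajectory <- function(params, schedule = light_schedule()) {
  stopifnot(inherits(params, "sim_params"), inherits(schedule, "light_schedule"))
  duration_s <- params$duration_h * 3600
  set.seed(params$seed)
  subseeds <- sample.int(.Machine$integer.max, params$n_subjects)
  trajs <- vector("list", params$n_subjects)
  for (k in seq_len(params$n_subjects)) {
    set.seed(subseeds[k])
    states <- sim_states(params, schedule, duration_s)
    fr <- sim_frames(params, schedule, duration_s, states)
    speed <- sim_speeds(params, fr)
    x0 <- stats::runif(1, 0, params$arena_width_mm)
    y0 <- stats::runif(1, 0, params$arena_height_mm)
    pos <- bounded_walk_cpp(x0, y0, speed / params$fps,
                            params$arena_width_mm, params$arena_height_mm)
    trajs[[k]] <- trajectory(sprintf("s%02d", k), pos[, 1], pos[, 2],
                             fps = params$fps, stage = params$stage)
  }
  names(trajs) <- vapply(trajs, function(tr) tr$subject_id, "")
  list(trajectories = trajs,
       ground_truth = ground_truth(params, schedule),
       params = params, schedule = schedule)
}

#' Simulate manually scored ethogram events
#'
#' Emits the active-swimming state sequence of the same semi-Markov process
#' as [simulate_trajectory()] directly as `(start, stop)` intervals, at
#' frame resolution. With identical parameters (including seed) the
#' intervals coincide exactly with the frames in which the simulated
#' trajectory is in the active state; the crepuscular multiplier changes
#' speeds, not states, so it leaves the intervals untouched.
#'
#' @inheritParams simulate_trajectory
#' @return A list of [ethogram_events()], one per subject.
#' @export
simulate_ethogram <- function(params, schedule = light_schedule()) {
  stopifnot(inherits(params, "sim_params"), inherits(schedule, "light_schedule"))
  duration_s <- params$duration_h * 3600
  set.seed(params$seed)
  subseeds <- sample.int(.Machine$integer.max, params$n_subjects)
  out <- vector("list", params$n_subjects)
  for (k in seq_len(params$n_subjects)) {
    set.seed(subseeds[k])
    states <- sim_states(params, schedule, duration_s)
    fr <- sim_frames(params, schedule, duration_s, states)
    r <- rle(!fr$rest)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    act <- which(r$values)
    out[[k]] <- ethogram_events(sprintf("s%02d", k),
                                start_s = (starts[act] - 1L) / params$fps,
                                stop_s = ends[act] / params$fps)
  }
  names(out) <- vapply(out, function(e) e$subject_id, "")
  out
}

#' Illustrative species-like simulation presets
#'
#' Named parameter sets spanning the activity phenotypes seen in cichlid
#' assays: diurnal, nocturnal, crepuscular-nocturnal and arrhythmic.
#' The presets are illustrative only -- no published per-species activity
#' parameters exist to calibrate them against.
#'
#' @param stage `"juvenile"` or `"adult"`.
#' @param seed Master seed passed to each preset.
#' @param n_subjects Subjects per preset.
#' @param ... Further arguments passed to [sim_params()] (e.g. `fps`,
#'   `duration_h`).
#' @return Named list of [sim_params()].
#' @export
species_presets <- function(stage = c("juvenile", "adult"), seed = 1,
                            n_subjects = 6, ...) {
  stage <- match.arg(stage)
  thr <- stage_threshold(stage)
  s <- if (stage == "juvenile") 1 else 3 # adult speeds roughly 3x juvenile
  mk <- function(vl, vd, rl, wl, rd, wd, crep = 1, offset = 0) {
    sim_params(seed = seed + offset, stage = stage, n_subjects = n_subjects,
               phase_params = list(
                 light = list(mean_active_speed = vl * s, rest_rate = rl, wake_rate = wl),
                 dark  = list(mean_active_speed = vd * s, rest_rate = rd, wake_rate = wd)),
               crepuscular_multiplier = crep, ...)
  }
  list(
    diurnal_strong  = mk(55, 20, 1/400, 1/60, 1/60, 1/120, offset = 0),
    diurnal_mild    = mk(45, 30, 1/300, 1/80, 1/120, 1/100, offset = 1),
    diurnal_active  = mk(70, 30, 1/500, 1/50, 1/90, 1/110, offset = 2),
    nocturnal       = mk(25, 55, 1/80, 1/120, 1/400, 1/60, crep = 1.5, offset = 3),
    nocturnal_crep  = mk(20, 45, 1/70, 1/140, 1/350, 1/60, crep = 2, offset = 4),
    arrhythmic      = mk(40, 40, 1/150, 1/90, 1/150, 1/90, offset = 5)
  )
}
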