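#' Default pipeline configuration
#'
#' Returns the full set of recognised configuration keys with their
#' defaults. A user config (list or YAML file) overrides any subset;
#' `seed` has no default and must be supplied.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    mode = "individual",        # individual | group | ethogram
    stage = "juvenile",
    seed = NULL,                # mandatory
    n_days = 1,
    fps = 15,
    n_subjects = 6,
    schedule = list(lights_on_h = 14, lights_off_h = 10,
                    recording_start_zt = 1),
    threshold = NULL,           # resolved from stage unless overridden
    min_duration_s = 60,
    window_h = 1,
    smooth_window_s = 0,
    group_size = 5,
    species_presets = FALSE,    # simulate the bundled multi-species set
    phase_params = NULL,        # passed to sim_params() when simulating
    crepuscular_multiplier = 1,
    arena_width_mm = NULL,      # default arena resolved from stage
    arena_height_mm = NULL,
    write_positions = FALSE,    # positional CSVs are large; off by default
    plots = FALSE,
    input = list(positions = NULL, ethogram = NULL)
  )
}

read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(default_config(), config)
  if (is.null(cfg$seed)) stop("config error: seed is mandatory", call. = FALSE)
  cfg
}

#' Run the end-to-end rest-activity pipeline
#'
#' Orchestrates one reproducible analysis run from a single declarative
#' config: simulate (or ingest) recordings, detect rest bouts, build
#' hourly profiles, compute diurnality and crepuscularity indices,
#' average within groups if requested, and run the statistical battery
#' when several species are present. All outputs (delimited tables, a
#' ground-truth sidecar for simulated data, the echoed config, a log) are
#' written atomically to `out_dir`. Deterministic given config + seed.
#'
#' @param config Path to a YAML config file, or a named list overriding
#'   [default_config()].
#' @param out_dir Output directory (created if missing). `NULL` runs
#'   in-memory only.
#' @param seed Optional seed override.
#' @return Invisibly, a list with `fits`, `profiles`, `indices`, `bouts`,
#'   `stats`, `ground_truth` and `config`.
#' @examples
#' \donttest{
#' res <- run_pipeline(list(seed = 1, fps = 1, n_subjects = 2,
#'                          arena_width_mm = 200, arena_height_mm = 200),
#'                     out_dir = tempfile())
#' res$indices
#' }
#' @export
run_pipeline <- function(config, out_dir = NULL, seed = NULL) {
  cfg <- read_run_config(config)
  if (!is.null(seed)) cfg$seed <- seed
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message("[zeitact] ", line)
    log_lines <<- c(log_lines, line)
  }
  stage_ctx <- function(stage_name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage_name,
                   conditionMessage(e)), call. = FALSE))
  }
  schedule <- stage_ctx("config", do.call(light_schedule, cfg$schedule))
  say("mode=%s stage=%s seed=%d days=%g fps=%g", cfg$mode, cfg$stage,
      as.integer(cfg$seed), cfg$n_days, cfg$fps)

  gt <- NULL
  species_of <- NULL
  sim_csv <- list()

  if (cfg$mode == "ethogram") {
    span <- c(0, cfg$n_days * 24 * 3600)
    events <- stage_ctx("acquire", {
      if (!is.null(cfg$input$ethogram)) {
        ev <- read_ethogram(cfg$input$ethogram)
        # span from the data when ingesting: last scored stop, whole hours
        span <- c(0, max(vapply(ev, function(e) max(e$stop_s, 0), 0)))
        span[2] <- floor(span[2] / 3600) * 3600
        ev
      } else {
        p <- build_sim_params(cfg)
        sim_csv$ethogram <- simulate_ethogram(p, schedule)
        sim_csv$ethogram
      }
    })
    say("acquired %d ethogram subject(s), span %g h", length(events),
        diff(span) / 3600)
    fits <- stage_ctx("analyze", lapply(events, function(ev)
      rhythm_analysis(ev, schedule, recording_span = span,
                      min_duration_s = cfg$min_duration_s,
                      window_h = cfg$window_h)))
  } else {
    trajs <- stage_ctx("acquire", {
      if (!is.null(cfg$input$positions)) {
        read_positions(cfg$input$positions, stage = cfg$stage)
      } else if (isTRUE(cfg$species_presets)) {
        pargs <- list(cfg$stage, seed = cfg$seed,
                      n_subjects = cfg$n_subjects, fps = cfg$fps,
                      duration_h = 24 * cfg$n_days)
        if (!is.null(cfg$arena_width_mm)) {
          pargs$arena_width_mm <- cfg$arena_width_mm
          pargs$arena_height_mm <- cfg$arena_height_mm
        }
        presets <- do.call(species_presets, pargs)
        all_tr <- list()
        species_of <- character(0)
        for (sp in names(presets)) {
          sim <- simulate_trajectory(presets[[sp]], schedule)
          tr <- sim$trajectories
          names(tr) <- paste0(sp, "_", names(tr))
          for (k in seq_along(tr)) tr[[k]]$subject_id <- names(tr)[k]
          species_of <- c(species_of,
                           stats::setNames(rep(sp, length(tr)), names(tr)))
          all_tr <- c(all_tr, tr)
        }
        all_tr
      } else {
        p <- build_sim_params(cfg)
        sim <- simulate_trajectory(p, schedule)
        gt <- sim$ground_truth
        sim$trajectories
      }
    })
    say("acquired %d trajectory subject(s)", length(trajs))
    fits <- stage_ctx("analyze", lapply(trajs, function(tr)
      rhythm_analysis(tr, schedule, threshold = cfg$threshold,
                      min_duration_s = cfg$min_duration_s,
                      window_h = cfg$window_h,
                      smooth_window_s = cfg$smooth_window_s)))
    if (isTRUE(cfg$write_positions)) sim_csv$positions <- trajs
  }

  profiles_tab <- do.call(rbind, lapply(fits, function(f)
    cbind(subject = f$subject_id, as.data.frame(f$profile))))
  rownames(profiles_tab) <- NULL
  indices_tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(subject = f$subject_id, t(f$indices),
               total_rest_min = sum(f$bouts$duration_s) / 60,
               n_rest_bouts = nrow(f$bouts))
  }))
  rownames(indices_tab) <- NULL
  if (!is.null(species_of))
    indices_tab$species <- unname(species_of[indices_tab$subject])
  bouts_tab <- do.call(rbind, lapply(fits, function(f)
    if (nrow(f$bouts)) cbind(subject = f$subject_id, as.data.frame(f$bouts))
    else NULL))
  if (!is.null(bouts_tab)) rownames(bouts_tab) <- NULL
  say("profiles: %d rows; indices: %d subjects; %d rest bouts",
      nrow(profiles_tab), nrow(indices_tab),
      if (is.null(bouts_tab)) 0L else nrow(bouts_tab))

  group_tab <- NULL
  if (cfg$mode == "group") {
    group_tab <- stage_ctx("group", {
      ids <- names(fits)
      grp <- ceiling(seq_along(fits) / cfg$group_size)
      do.call(rbind, lapply(split(seq_along(fits), grp), function(ix) {
        gp <- group_average(lapply(fits[ix], function(f) f$profile),
                            group_id = sprintf("group%02d", grp[ix[1]]))
        dn <- day_night_means(gp)
        cr <- crepuscularity_index(gp, window_h = cfg$window_h)
        data.frame(group = attr(gp, "subject_id"), n = length(ix),
                   D = dn[["D"]], N = dn[["N"]],
                   A_R = diurnality_index(dn[["D"]], dn[["N"]]),
                   C = cr$C, NC = cr$NC, C_R = cr$C_R)
      }))
    })
    say("group mode: %d group(s) of up to %d subjects", nrow(group_tab),
        cfg$group_size)
  }

  stats_tab <- NULL
  if (!is.null(species_of) && length(unique(species_of)) >= 2L) {
    stats_tab <- stage_ctx("stats", {
      sp <- indices_tab$species
      rbind(species_anova(indices_tab$D + indices_tab$N, sp),
            day_night_rm_anova(indices_tab$D, indices_tab$N, sp))
    })
    n_und <- sum(is.na(indices_tab$A_R))
    if (n_und > 0)
      say("stats: %d subject(s) with undefined indices excluded", n_und)
    say("stats: %d result rows", nrow(stats_tab))
  }

  out <- list(fits = fits, profiles = profiles_tab, indices = indices_tab,
              bouts = bouts_tab, groups = group_tab, stats = stats_tab,
              ground_truth = gt, config = cfg)

  if (!is.null(out_dir)) {
    stage_ctx("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      atomic_write <- function(writer, obj, file) {
        if (is.null(obj)) return(invisible(NULL))
        tmp <- file.path(out_dir, paste0(file, ".tmp"))
        writer(obj, tmp)
        file.rename(tmp, file.path(out_dir, file))
      }
      wcsv <- function(obj, f) utils::write.csv(obj, f, row.names = FALSE)
      atomic_write(wcsv, profiles_tab, "profiles.csv")
      atomic_write(wcsv, indices_tab, "indices.csv")
      atomic_write(wcsv, bouts_tab, "rest_bouts.csv")
      atomic_write(wcsv, group_tab, "groups.csv")
      atomic_write(wcsv, stats_tab, "stats.csv")
      if (!is.null(gt))
        atomic_write(function(o, f) jsonlite::write_json(o, f,
                       auto_unbox = TRUE, digits = NA), gt,
                     "ground_truth.json")
      if (!is.null(sim_csv$positions))
        atomic_write(write_positions, sim_csv$positions, "positions.csv")
      if (!is.null(sim_csv$ethogram))
        atomic_write(write_ethogram, sim_csv$ethogram, "ethogram.csv")
      atomic_write(function(o, f) yaml::write_yaml(o, f), cfg,
                   "config_echo.yaml")
      if (isTRUE(cfg$plots)) {
        grDevices::pdf(file.path(out_dir, "profiles.pdf"), width = 7,
                       height = 4)
        for (f in fits) plot(f)
        grDevices::dev.off()
      }
      atomic_write(function(o, f) writeLines(o, f), log_lines, "log.txt")
    })
    say("outputs written to %s", out_dir)
  }
  invisible(out)
}

build_sim_params <- function(cfg) {
  args <- list(seed = cfg$seed, stage = cfg$stage,
               duration_h = 24 * cfg$n_days, fps = cfg$fps,
               n_subjects = cfg$n_subjects,
               crepuscular_multiplier = cfg$crepuscular_multiplier)
  if (!is.null(cfg$phase_params)) args$phase_params <- cfg$phase_params
  if (!is.null(cfg$threshold)) args$threshold <- cfg$threshold
  if (!is.null(cfg$arena_width_mm)) args$arena_width_mm <- cfg$arena_width_mm
  if (!is.null(cfg$arena_height_mm)) args$arena_height_mm <- cfg$arena_height_mm
  do.call(sim_params, args)
}
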