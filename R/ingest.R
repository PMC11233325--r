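#' Read positional tracking exports
#'
#' Parses a delimited table of tracked positions into one [trajectory()]
#' per subject. The expected layout (the convention written by
#' [write_positions()] and typical of re-exported tracker data) is a header
#' with columns `time_s`, `subject`, `x`, `y`; the delimiter is
#' auto-detected among comma, semicolon and tab. Coordinates are converted
#' to mm via `scale`. Samples missing from the file, or with NA
#' coordinates (lost tracking), are flagged in the presence mask and never
#' interpolated.
#'
#' Row accounting (rows read, kept, flagged as gaps) is reported via
#' [message()] per subject.
#'
#' @param path Path to the delimited file.
#' @param stage `"juvenile"` or `"adult"` (stored on each trajectory and
#'   used for default thresholds downstream).
#' @param scale mm per coordinate unit (default 1 = already mm).
#' @param fps Frames per second of the recording; if `NULL`, inferred from
#'   the median time step.
#' @return A named list of [trajectory()] objects.
#' @export
read_positions <- function(path, stage = c("juvenile", "adult"), scale = 1,
                           fps = NULL) {
  stage <- match.arg(stage)
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  df <- read_delimited(path, required = c("time_s", "subject", "x", "y"))
  df$time_s <- as.numeric(df$time_s)
  df$x <- as.numeric(df$x)
  df$y <- as.numeric(df$y)
  out <- lapply(split(df, df$subject), function(d) {
    if (is.unsorted(d$time_s, strictly = TRUE))
      stop(sprintf("subject '%s': time_s is not strictly increasing",
                   d$subject[1L]), call. = FALSE)
    this_fps <- fps
    if (is.null(this_fps)) {
      if (nrow(d) < 2L)
        stop(sprintf("subject '%s': cannot infer fps from a single sample",
                     d$subject[1L]), call. = FALSE)
      this_fps <- 1 / stats::median(diff(d$time_s))
      if (abs(this_fps - round(this_fps)) < 1e-6)
        this_fps <- round(this_fps)
    }
    idx <- round(d$time_s * this_fps)
    if (any(abs(d$time_s - idx / this_fps) > 0.25 / this_fps))
      stop(sprintf("subject '%s': time_s does not lie on a uniform %g fps grid",
                   d$subject[1L], this_fps), call. = FALSE)
    n <- max(idx) + 1L
    x <- rep(NA_real_, n); y <- rep(NA_real_, n)
    x[idx + 1L] <- d$x * scale
    y[idx + 1L] <- d$y * scale
    tr <- trajectory(d$subject[1L], x, y, fps = this_fps, stage = stage)
    message(sprintf("read_positions: subject '%s': %d rows read, %d grid samples, %d gap(s)",
                    tr$subject_id, nrow(d), n, sum(!tr$present)))
    tr
  })
  out
}

#' Write trajectories as a positional CSV
#'
#' Inverse of [read_positions()]: one row per grid sample per subject with
#' columns `time_s`, `subject`, `x`, `y`; absent samples are written with
#' empty coordinates.
#'
#' @param trajs A [trajectory()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_positions <- function(trajs, path) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  rows <- lapply(trajs, function(tr) {
    data.frame(time_s = traj_times(tr), subject = tr$subject_id,
               x = ifelse(tr$present, tr$x, NA_real_),
               y = ifelse(tr$present, tr$y, NA_real_))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a manually scored ethogram export
#'
#' Parses an aggregated-events style table (columns `subject`, `behavior`,
#' `start_s`, `stop_s`; delimiter auto-detected) into one
#' [ethogram_events()] per subject, with intervals sorted and
#' merged-if-touching. Records with `stop_s <= start_s` are rejected with
#' a warning; row accounting is reported via [message()].
#'
#' @param path Path to the delimited file.
#' @param behavior If non-`NULL`, keep only rows with this behaviour label.
#' @return A named list of [ethogram_events()].
#' @export
read_ethogram <- function(path, behavior = NULL) {
  df <- read_delimited(path, required = c("subject", "behavior", "start_s", "stop_s"))
  if (!is.null(behavior)) df <- df[df$behavior == behavior, , drop = FALSE]
  if (nrow(df) == 0L) return(structure(list(), names = character(0)))
  out <- lapply(split(df, df$subject), function(d) {
    ev <- ethogram_events(d$subject[1L], as.numeric(d$start_s),
                          as.numeric(d$stop_s), behavior = d$behavior[1L])
    message(sprintf("read_ethogram: subject '%s': %d rows read = %d kept + %d rejected",
                    ev$subject_id, nrow(d), nrow(d) - attr(ev, "n_rejected"),
                    attr(ev, "n_rejected")))
    ev
  })
  out
}

#' Write ethogram events as a CSV
#'
#' @param events An [ethogram_events()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ethogram <- function(events, path) {
  if (inherits(events, "ethogram_events")) events <- list(events)
  rows <- lapply(events, function(ev) {
    if (length(ev$start_s) == 0L) return(NULL)
    data.frame(subject = ev$subject_id, behavior = ev$behavior,
               start_s = ev$start_s, stop_s = ev$stop_s)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = character(0), behavior = character(0),
               start_s = numeric(0), stop_s = numeric(0))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Delimiter-sniffing reader for the package's CSV dialects. Errors name
# the offending header when required columns are absent.
read_delimited <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- c(",", ";", "\t")[which.max(vapply(c(",", ";", "\t"), function(s)
    lengths(regmatches(header, gregexpr(s, header, fixed = TRUE))), 0L))]
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(sprintf("unknown column layout in '%s': header is [%s]; missing [%s]",
                 path, paste(names(df), collapse = ", "),
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  df$subject <- as.character(df$subject)
  df
}
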