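#' Sidak multiple-comparisons adjustment
#'
#' Adjusts raw post hoc p-values for a family of `m` comparisons:
#' `p_adj = 1 - (1 - p)^m`.
#'
#' @param p Raw p-value(s).
#' @param m Family size (defaults to `length(p)`).
#' @return Adjusted p-value(s).
#' @export
sidak_adjust <- function(p, m = length(p)) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE), m >= 1)
  1 - (1 - p)^m
}

stat_row <- function(test_name, term, statistic, df1, df2 = NA_real_,
                     p = NA_real_, adjusted_p = NA_real_) {
  data.frame(test_name = test_name, term = term, statistic = statistic,
             df1 = df1, df2 = df2, p = p, adjusted_p = adjusted_p,
             stringsAsFactors = FALSE)
}

#' One-way ANOVA across species
#'
#' Fixed-effects one-way ANOVA of a per-subject scalar (e.g. total
#' locomotion or total rest over 24 h) on species, as used to test for
#' cross-species variation.
#'
#' @param values Numeric per-subject measurements.
#' @param species Species label per subject.
#' @return A one-row data frame: `test_name`, `term`, `statistic` (F),
#'   `df1`, `df2`, `p`.
#' @export
species_anova <- function(values, species) {
  species <- factor(species)
  ok <- !is.na(values) & !is.na(species)
  values <- values[ok]; species <- droplevels(species[ok])
  if (nlevels(species) < 2L)
    stop("need at least 2 groups", call. = FALSE)
  n_per <- table(species)
  if (any(n_per < 2L))
    stop("each group needs at least 2 subjects (got n = 1 for: ",
         paste(names(n_per)[n_per < 2], collapse = ", "), ")", call. = FALSE)
  fit <- stats::aov(values ~ species)
  s <- summary(fit)[[1L]]
  stat_row("one_way_anova", "species", s[["F value"]][1L],
           s[["Df"]][1L], s[["Df"]][2L], s[["Pr(>F)"]][1L])
}

#' Two-way repeated-measures (split-plot) ANOVA for day/night by species
#'
#' Mixed between-within ANOVA with species as the between-subject factor
#' and time of day (day vs night) as the two-level within-subject factor,
#' subjects nested in species. Sphericity is trivially satisfied with two
#' within-factor levels. Per-species day-vs-night post hoc contrasts are
#' paired t tests with Sidak adjustment (family size = number of species).
#'
#' @param day_vals,night_vals Paired per-subject scalars (e.g. mean hourly
#'   locomotion in light and dark phase). Subjects with a missing member
#'   of the pair are dropped with a reported count.
#' @param species Species label per subject.
#' @return A data frame with main-effect, interaction and post hoc rows.
#' @export
day_night_rm_anova <- function(day_vals, night_vals, species) {
  stopifnot(length(day_vals) == length(night_vals),
            length(species) == length(day_vals))
  species <- factor(species)
  ok <- !is.na(day_vals) & !is.na(night_vals) & !is.na(species)
  if (any(!ok))
    message(sprintf("day_night_rm_anova: dropped %d subject(s) with incomplete pairs",
                    sum(!ok)))
  day_vals <- day_vals[ok]; night_vals <- night_vals[ok]
  species <- droplevels(species[ok])
  n <- length(day_vals)
  if (nlevels(species) < 2L) stop("need at least 2 species", call. = FALSE)
  dat <- data.frame(
    value = c(day_vals, night_vals),
    time = factor(rep(c("day", "night"), each = n), levels = c("day", "night")),
    species = rep(species, 2L),
    subject = factor(rep(seq_len(n), 2L)))
  fit <- stats::aov(value ~ species * time + Error(subject), data = dat)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1L]]
  within <- s[["Error: Within"]][[1L]]
  rn_b <- trimws(rownames(between)); rn_w <- trimws(rownames(within))
  grab <- function(tab, rn, term, stratum_res) {
    i <- match(term, rn)
    stat_row("rm_anova", term, tab[["F value"]][i], tab[["Df"]][i],
             stratum_res, tab[["Pr(>F)"]][i])
  }
  res_b <- between[["Df"]][match("Residuals", rn_b)]
  res_w <- within[["Df"]][match("Residuals", rn_w)]
  out <- rbind(grab(between, rn_b, "species", res_b),
               grab(within, rn_w, "time", res_w),
               grab(within, rn_w, "species:time", res_w))
  # Sidak-adjusted per-species paired contrasts
  m <- nlevels(species)
  ph <- lapply(levels(species), function(sp) {
    i <- species == sp
    tt <- stats::t.test(day_vals[i], night_vals[i], paired = TRUE)
    stat_row("paired_t", paste0("day_vs_night:", sp),
             unname(tt$statistic), unname(tt$parameter), NA_real_,
             tt$p.value, sidak_adjust(tt$p.value, m))
  })
  rbind(out, do.call(rbind, ph))
}

#' Cross-stage least-squares correlation of species means
#'
#' Ordinary least-squares regression of adult species means on juvenile
#' species means, used to test whether a trait (total locomotion, total
#' rest) is conserved across life stages.
#'
#' @param juvenile_means,adult_means Per-species scalars (>= 3 species).
#' @return A one-row data frame with `statistic` = r-squared and `p` for
#'   slope != 0; the slope and intercept are attached as attributes
#'   `slope` and `intercept`.
#' @export
stage_correlation <- function(juvenile_means, adult_means) {
  stopifnot(length(juvenile_means) == length(adult_means))
  ok <- !is.na(juvenile_means) & !is.na(adult_means)
  x <- juvenile_means[ok]; y <- adult_means[ok]
  if (length(x) < 3L) stop("need at least 3 species", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance in juvenile means", call. = FALSE)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  out <- stat_row("ols_regression", "juvenile_vs_adult", s$r.squared,
                  1, s$df[2L], s$coefficients["x", "Pr(>|t|)"])
  attr(out, "slope") <- unname(stats::coef(fit)[2L])
  attr(out, "intercept") <- unname(stats::coef(fit)[1L])
  out
}

#' Paired day/night t test
#'
#' Two-sided paired t test of per-subject day vs night values
#' (df = n - 1).
#'
#' @param day_vals,night_vals Paired per-subject scalars.
#' @return A one-row data frame with `statistic` (t), `df1` (df), `p`.
#' @export
paired_day_night_test <- function(day_vals, night_vals) {
  stopifnot(length(day_vals) == length(night_vals))
  ok <- !is.na(day_vals) & !is.na(night_vals)
  d <- day_vals[ok] - night_vals[ok]
  if (length(d) < 2L) stop("need at least 2 complete pairs", call. = FALSE)
  if (stats::sd(d) == 0) {
    # identical day and night values carry no evidence of a difference;
    # a constant non-zero difference leaves t undefined
    if (all(d == 0))
      return(stat_row("paired_t", "day_vs_night", 0, length(d) - 1L,
                      NA_real_, 1))
    stop("zero variance in day-night differences; paired t undefined",
         call. = FALSE)
  }
  tt <- stats::t.test(day_vals[ok], night_vals[ok], paired = TRUE)
  stat_row("paired_t", "day_vs_night", unname(tt$statistic),
           unname(tt$parameter), NA_real_, tt$p.value)
}
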