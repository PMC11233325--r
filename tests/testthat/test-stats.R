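# Hand-coded sums-of-squares oracles, independent of stats::aov / t.test.

oracle_oneway_F <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); n <- length(values)
  gm <- mean(values)
  ss_b <- sum(tapply(values, groups, function(v) length(v) * (mean(v) - gm)^2))
  ss_w <- sum(unlist(tapply(values, groups, function(v) (v - mean(v))^2)))
  Fv <- (ss_b / (k - 1)) / (ss_w / (n - k))
  list(F = Fv, df1 = k - 1, df2 = n - k,
       p = stats::pf(Fv, k - 1, n - k, lower.tail = FALSE))
}

oracle_paired_t <- function(day, night) {
  d <- day - night
  n <- length(d)
  tv <- mean(d) / (stats::sd(d) / sqrt(n))
  list(t = tv, df = n - 1, p = 2 * stats::pt(-abs(tv), n - 1))
}

# balanced split-plot ANOVA: k species, n subjects each, 2 within levels
oracle_splitplot <- function(day, night, species) {
  species <- factor(species)
  k <- nlevels(species); n_per <- length(day) / k; N <- length(day)
  y <- c(day, night)
  gm <- mean(y)
  subj_mean <- (day + night) / 2
  sp_mean <- tapply(y, rep(species, 2), mean)
  t_mean <- c(mean(day), mean(night))
  cell <- rbind(tapply(day, species, mean), tapply(night, species, mean))
  ss_between_subj <- 2 * sum((subj_mean - gm)^2)
  ss_species <- 2 * n_per * sum((sp_mean - gm)^2)
  ss_err_b <- ss_between_subj - ss_species
  ss_total <- sum((y - gm)^2)
  ss_within <- ss_total - ss_between_subj
  ss_time <- N * sum((t_mean - gm)^2)
  # cell[t, g] - species mean[g] - time mean[t] + grand mean
  dev <- sweep(sweep(cell, 2, as.numeric(sp_mean)), 1, t_mean) + gm
  ss_int <- n_per * sum(dev^2)
  ss_err_w <- ss_within - ss_time - ss_int
  df_eb <- N - k; df_ew <- N - k
  list(F_species = (ss_species / (k - 1)) / (ss_err_b / df_eb),
       F_time = ss_time / (ss_err_w / df_ew),
       F_int = (ss_int / (k - 1)) / (ss_err_w / df_ew),
       df_eb = df_eb, df_ew = df_ew, k = k)
}

test_that("one-way ANOVA: identical groups give F = 0, p = 1", {
  r <- species_anova(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
})

test_that("one-way ANOVA matches the hand-computed oracle exactly", {
  vals <- c(4, 6, 5, 10, 12, 11, 1, 2, 3)
  grp <- rep(c("a", "b", "c"), each = 3)
  r <- species_anova(vals, grp)
  o <- oracle_oneway_F(vals, grp)
  expect_equal(r$statistic, o$F, tolerance = 1e-12)
  expect_equal(r$df1, o$df1)
  expect_equal(r$df2, o$df2)
  expect_equal(r$p, o$p, tolerance = 1e-12)
})

test_that("one-way ANOVA agrees with the oracle on 100 random datasets", {
  set.seed(101)
  for (i in 1:100) {
    k <- sample(2:5, 1)
    n <- sample(3:8, 1)
    vals <- rnorm(k * n, mean = rep(runif(k, 0, 3), each = n))
    grp <- rep(letters[1:k], each = n)
    r <- species_anova(vals, grp)
    o <- oracle_oneway_F(vals, grp)
    expect_equal(r$statistic, o$F, tolerance = 1e-8)
    expect_equal(r$p, o$p, tolerance = 1e-8)
  }
})

test_that("one-way ANOVA p-values are uniform under label permutation", {
  set.seed(77)
  vals <- rnorm(18)
  ps <- replicate(500, {
    grp <- sample(rep(c("a", "b", "c"), each = 6))
    species_anova(vals, grp)$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ANOVA input validation rejects degenerate designs", {
  expect_error(species_anova(1:5, rep("a", 5)), "at least 2 groups")
  expect_error(species_anova(c(1, 2, 3), c("a", "a", "b")), "n = 1")
})

test_that("split-plot ANOVA matches hand-computed sums of squares", {
  set.seed(55)
  for (i in 1:40) {
    k <- sample(2:4, 1); n <- sample(3:8, 1)
    base <- rep(rnorm(k, sd = 2), each = n)
    day <- base + rnorm(k * n)
    night <- base + rep(rnorm(k, sd = 1), each = n) + rnorm(k * n)
    sp <- rep(letters[1:k], each = n)
    r <- day_night_rm_anova(day, night, sp)
    o <- oracle_splitplot(day, night, sp)
    expect_equal(r$statistic[r$term == "species"], o$F_species,
                 tolerance = 1e-8)
    expect_equal(r$statistic[r$term == "time"], o$F_time, tolerance = 1e-8)
    expect_equal(r$statistic[r$term == "species:time"], o$F_int,
                 tolerance = 1e-8)
    expect_equal(r$df2[r$term == "species"], o$df_eb)
    expect_equal(r$df2[r$term == "time"], o$df_ew)
  }
})

test_that("time effect is exactly zero when day/night differences cancel", {
  day <- c(10, 12, 14, 20, 22, 24)
  night <- day + c(1, -1, 1, -1, 1, -1)  # mean difference zero
  r <- day_night_rm_anova(day, night, rep(c("a", "b"), each = 3))
  expect_equal(r$statistic[r$term == "time"], 0, tolerance = 1e-12)
})

test_that("post hoc contrasts are Sidak-adjusted paired t tests per species", {
  set.seed(12)
  day <- rnorm(12, 10); night <- rnorm(12, 8)
  sp <- rep(c("a", "b", "c"), each = 4)
  r <- day_night_rm_anova(day, night, sp)
  ph <- r[grepl("day_vs_night:", r$term), ]
  expect_equal(nrow(ph), 3)
  for (s in c("a", "b", "c")) {
    i <- sp == s
    o <- oracle_paired_t(day[i], night[i])
    row <- ph[ph$term == paste0("day_vs_night:", s), ]
    expect_equal(row$statistic, o$t, tolerance = 1e-8)
    expect_equal(row$p, o$p, tolerance = 1e-8)
    expect_equal(row$adjusted_p, 1 - (1 - o$p)^3, tolerance = 1e-8)
    expect_gte(row$adjusted_p, row$p)
  }
})

test_that("incomplete pairs are dropped with a reported count", {
  expect_message(
    day_night_rm_anova(c(1, 2, NA, 4, 5, 6, 7, 8), c(8:5, NA, 3:1),
                       rep(c("a", "b"), each = 4)),
    "dropped 2 subject")
})

test_that("Sidak adjustment matches its closed form", {
  expect_equal(sidak_adjust(0.01, 6), 1 - 0.99^6)
  expect_equal(sidak_adjust(0.01, 6), 0.0585, tolerance = 1e-3)
  p <- c(0.01, 0.2, 0.5)
  expect_equal(sidak_adjust(p), 1 - (1 - p)^3)
  expect_true(all(sidak_adjust(p) >= p))
})

test_that("stage correlation recovers exact and random-data r-squared", {
  juv <- c(1, 2, 3, 4, 5, 6)
  r <- suppressWarnings(stage_correlation(juv, 3 * juv)) # exact fit warns
  expect_equal(r$statistic, 1)
  r2 <- suppressWarnings(stage_correlation(juv, 10 - 2 * juv))
  expect_equal(r2$statistic, 1)
  expect_lt(attr(r2, "slope"), 0)
  set.seed(21)
  for (i in 1:100) {
    x <- rnorm(6); y <- 0.5 * x + rnorm(6, sd = 0.5)
    r3 <- stage_correlation(x, y)
    expect_equal(r3$statistic, stats::cor(x, y)^2, tolerance = 1e-8)
    tv <- stats::cor(x, y) * sqrt(4 / (1 - stats::cor(x, y)^2))
    expect_equal(r3$p, 2 * stats::pt(-abs(tv), 4), tolerance = 1e-8)
  }
  expect_error(stage_correlation(1:2, 1:2), "at least 3")
  expect_error(stage_correlation(rep(1, 4), 1:4), "zero variance")
})

test_that("paired day/night test matches the textbook formula", {
  day <- c(320, 290, 410, 380, 295, 365)
  night <- c(250, 270, 300, 320, 210, 301)
  r <- paired_day_night_test(day, night)
  o <- oracle_paired_t(day, night)
  expect_equal(r$statistic, o$t, tolerance = 1e-12)
  expect_equal(r$df1, 5)
  expect_equal(r$p, o$p, tolerance = 1e-12)
  set.seed(3)
  for (i in 1:100) {
    a <- rnorm(8); b <- rnorm(8)
    r <- paired_day_night_test(a, b)
    o <- oracle_paired_t(a, b)
    expect_equal(r$statistic, o$t, tolerance = 1e-8)
    expect_equal(r$p, o$p, tolerance = 1e-8)
  }
})

test_that("degenerate paired differences are handled as specified", {
  # identical day and night values: no evidence of difference
  r <- paired_day_night_test(c(5, 7, 9), c(5, 7, 9))
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  # constant non-zero difference: t undefined
  expect_error(paired_day_night_test(c(5, 7, 9), c(4, 6, 8)),
               "zero variance")
  expect_error(paired_day_night_test(5, 4), "at least 2")
})
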