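test_that("a constant-speed subject has equal bins summing to total path length", {
  tr <- line_trajectory(24 * 3600, dist_per_frame = 20, fps = 1)
  pr <- bin_hourly(tr, bouts = NULL)
  expect_false(anyNA(pr$locomotion))
  expect_equal(pr$locomotion, rep(20 * 3600, 24))
  expect_equal(sum(pr$locomotion), 20 * 24 * 3600, tolerance = 1e-6)
  expect_equal(pr$active_min, rep(60, 24))   # 20 mm/s is supra-threshold
})

test_that("bin sum equals total path length on simulated data (gap frames excluded)", {
  p <- sim_params(seed = 19, duration_h = 24, fps = 2, n_subjects = 1,
                  arena_width_mm = 200, arena_height_mm = 200)
  tr <- simulate_trajectory(p)$trajectories[[1]]
  # inject gaps
  drop <- seq(1000, 40000, by = 997)
  tr$x[drop] <- NA; tr$y[drop] <- NA; tr$present[drop] <- FALSE
  sp <- compute_speed(tr)
  pr <- bin_hourly(tr, bouts = NULL)
  total <- sum(sp$speed[sp$valid]) / tr$fps
  expect_equal(sum(pr$locomotion), total, tolerance = 1e-9)
})

test_that("recording starting at ZT1 fills bins in zeitgeber order", {
  # 2 h recording: first hour -> ZT1, second -> ZT2; other bins NA
  tr <- line_trajectory(2 * 3600, dist_per_frame = 1, fps = 1)
  pr <- bin_hourly(tr, bouts = NULL)
  expect_equal(which(!is.na(pr$locomotion)) - 1L, c(1L, 2L))
  s0 <- light_schedule(recording_start_zt = 0)
  pr0 <- bin_hourly(tr, s0, bouts = NULL)
  expect_equal(which(!is.na(pr0$locomotion)) - 1L, c(0L, 1L))
})

test_that("rest bouts split pro rata across bin edges", {
  # 90 min bout starting exactly at the second recorded hour boundary
  rest <- c(rep(FALSE, 3600), rep(TRUE, 5400), rep(FALSE, 24 * 3600 - 9000))
  sp <- speed_from_rest(rest, 1)
  bouts <- detect_rest_bouts(sp, 12, 60)
  expect_equal(bouts$duration_s, 5400)
  tr <- line_trajectory(24 * 3600, 1, fps = 1)
  pr <- bin_hourly(tr, bouts = bouts)
  # recording hour 1 (ZT2) fully rest, hour 2 (ZT3) half
  expect_equal(pr$rest_min[pr$zt == 2], 60)
  expect_equal(pr$rest_min[pr$zt == 3], 30)
  expect_equal(sum(pr$rest_min), 90)
})

test_that("recordings shorter than an hour cannot be binned", {
  tr <- line_trajectory(1800, 1, fps = 1)
  expect_error(bin_hourly(tr, bouts = NULL), "shorter than 1 h")
})

test_that("multi-day profiles equal the mean of single-day binnings", {
  p <- sim_params(seed = 23, duration_h = 72, fps = 1, n_subjects = 1,
                  arena_width_mm = 200, arena_height_mm = 200)
  tr <- simulate_trajectory(p)$trajectories[[1]]
  pr <- bin_hourly(tr, bouts = NULL)
  expect_equal(max(attr(pr, "n_days")), 3)
  # recompute each day independently
  per_day <- lapply(0:2, function(d) {
    i0 <- d * 86400 + 1L
    day_tr <- trajectory(tr$subject_id, tr$x[i0:(i0 + 86400)],
                         tr$y[i0:(i0 + 86400)], fps = 1)
    # shift the schedule so each daily slice keeps its true ZT alignment
    bin_hourly(day_tr, light_schedule(recording_start_zt =
                                        (1 + 24 * d) %% 24), bouts = NULL)
  })
  manual <- rowMeans(vapply(per_day, function(x) x$locomotion, numeric(24)))
  expect_equal(pr$locomotion, manual, tolerance = 1e-9)
})

test_that("day/night means match a brute-force phase average", {
  set.seed(5)
  for (i in 1:20) {
    v <- runif(24, 0, 100)
    pr <- loco_profile(v)
    dn <- day_night_means(pr)
    sched <- light_schedule()
    manual_D <- mean(v[in_light(sched, 0:23)])
    manual_N <- mean(v[!in_light(sched, 0:23)])
    expect_equal(dn[["D"]], manual_D)
    expect_equal(dn[["N"]], manual_N)
  }
  # schedule-driven phase counts, not hard-coded 14/10
  s <- light_schedule(12, 12)
  v <- c(rep(2, 12), rep(8, 12))
  dn <- day_night_means(hourly_profile(locomotion = v, schedule = s))
  expect_equal(unname(dn), c(2, 8))
})

test_that("group averaging is the per-bin mean with identity for one profile", {
  a <- loco_profile(1:24); b <- loco_profile(rep(10, 24))
  expect_equal(group_average(list(a))$locomotion, a$locomotion)
  expect_equal(group_average(list(a, b))$locomotion, (c(1:24) + 10) / 2)
  set.seed(9)
  ps <- lapply(1:6, function(i) loco_profile(runif(24)))
  ga <- group_average(ps, "g1")
  manual <- rowMeans(vapply(ps, function(p) p$locomotion, numeric(24)))
  expect_equal(ga$locomotion, manual)
  expect_equal(attr(ga, "n_subjects"), 6)
  # mismatched schedules refuse to average
  other <- hourly_profile(locomotion = rep(1, 24),
                          schedule = light_schedule(12, 12))
  expect_error(group_average(list(a, other)), "mismatched")
})

test_that("diurnality index hits its boundary and worked values", {
  expect_equal(diurnality_index(10, 0), 1)
  expect_equal(diurnality_index(0, 10), -1)
  expect_equal(diurnality_index(3, 1), 0.5)
  expect_equal(diurnality_index(5, 5), 0)
  expect_true(is.na(diurnality_index(0, 0)))
  expect_error(diurnality_index(-1, 2), "non-negative")
})

test_that("crepuscularity index reproduces its worked cases", {
  flat <- loco_profile(rep(7, 24))
  expect_equal(crepuscularity_index(flat)$C_R, 0)
  doubled <- rep(7, 24); doubled[c(0, 14) + 1] <- 14
  expect_equal(crepuscularity_index(loco_profile(doubled))$C_R, 1)
  zeroed <- rep(7, 24); zeroed[c(0, 14) + 1] <- 0
  expect_equal(crepuscularity_index(loco_profile(zeroed))$C_R, -1)
  # 2 h window takes two bins after each transition
  w2 <- rep(3, 24); w2[c(0, 1, 14, 15) + 1] <- 9
  expect_equal(crepuscularity_index(loco_profile(w2), window_h = 2)$C_R, 2)
  # all-zero profile has undefined crepuscularity
  expect_true(is.na(crepuscularity_index(loco_profile(rep(0, 24)))$C_R))
  expect_error(crepuscularity_index(flat, window_h = 3), "must be 1 or 2")
  narrow <- hourly_profile(locomotion = rep(1, 24),
                           schedule = light_schedule(23, 1))
  expect_error(crepuscularity_index(narrow, window_h = 2), "overlaps")
})

test_that("indices are antisymmetric, scale invariant and bounded", {
  set.seed(31)
  for (i in 1:50) {
    v <- runif(24, 0, 50)
    pr <- loco_profile(v)
    dn <- day_night_means(pr)
    ar <- diurnality_index(dn[["D"]], dn[["N"]])
    expect_gte(ar, -1); expect_lte(ar, 1)
    # antisymmetry
    expect_equal(diurnality_index(dn[["N"]], dn[["D"]]), -ar)
    # scale invariance
    k <- runif(1, 0.1, 9)
    dnk <- day_night_means(loco_profile(k * v))
    expect_equal(diurnality_index(dnk[["D"]], dnk[["N"]]), ar,
                 tolerance = 1e-12)
    cr <- crepuscularity_index(pr)$C_R
    expect_gte(cr, -1)
    expect_equal(crepuscularity_index(loco_profile(k * v))$C_R, cr,
                 tolerance = 1e-12)
  }
})

test_that("profile validation rejects impossible rest minutes", {
  expect_error(hourly_profile(rest_min = c(rep(10, 23), 61)), "\\[0, 60\\]")
  expect_error(hourly_profile(locomotion = c(rep(1, 23), -2)), "non-negative")
})
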