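test_that("speed_profile: constants, closed-form minimum-jerk peak, errors", {
  n <- 101
  t <- (seq_len(n) - 1) / 50
  uniform <- kinematic_stream(t, cbind(10 * t, 0, 0), identity_quat(n))
  raw <- speed_profile(uniform, smooth = FALSE)
  smooth <- speed_profile(uniform)
  expect_equal(raw$speed, rep(10, n - 1), tolerance = 1e-9)
  expect_equal(smooth$speed, rep(10, n - 1), tolerance = 1e-6)
  expect_length(raw$speed, n - 1L)

  still <- kinematic_stream(t, matrix(0, n, 3), identity_quat(n))
  expect_equal(speed_profile(still)$speed, rep(0, n - 1))

  mj <- min_jerk_stream(100, 2, rate_hz = 100, lead_s = 1, trail_s = 1)
  peak <- max(speed_profile(mj)$speed)
  expect_lt(abs(peak - 1.875 * 100 / 2) / (1.875 * 100 / 2), 0.02)

  one <- kinematic_stream(0, matrix(0, 1, 3), identity_quat(1))
  expect_error(speed_profile(one), "at least 2 samples")
})

test_that("count_speed_peaks matches the constructive oracle", {
  expect_equal(count_speed_peaks(rep(5, 100)), 0L)
  expect_error(count_speed_peaks(numeric()), "non-empty")

  two <- speed_profile(multi_submovement_stream(2))
  three <- speed_profile(multi_submovement_stream(3))
  expect_equal(count_speed_peaks(two), 2L)
  expect_equal(count_speed_peaks(three), 3L)
  # brute-force local-maximum oracle on the raw (unfiltered) profile,
  # where the stationary gaps are exactly flat; grid-aligned onsets put
  # the apex exactly between two equal samples, so offset the gaps
  two_raw <- speed_profile(multi_submovement_stream(2, gap_s = 2.13),
                           smooth = FALSE)
  expect_equal(length(brute_local_maxima(two_raw$speed)), 2L)

  # one submovement gives one peak for any prominence below the peak speed
  mj <- speed_profile(min_jerk_stream(100, 2, lead_s = 1, trail_s = 1))
  for (prom in c(1, 10, 50, 90)) {
    cfg <- opi_config(peak_min_prominence_mm_s = prom)
    expect_equal(count_speed_peaks(mj, cfg), 1L)
  }
})

test_that("linear_path_length: Pythagorean example, helix oracle, properties", {
  s <- kinematic_stream(c(0, 1, 2),
                        rbind(c(0, 0, 0), c(3, 4, 0), c(3, 4, 12)),
                        identity_quat(3))
  expect_equal(linear_path_length(s), 17)

  still <- kinematic_stream(0:9, matrix(1, 10, 3), identity_quat(10))
  expect_equal(linear_path_length(still), 0)

  # helix arc length: r = 10, pitch term b = 2, 3 turns
  u <- seq(0, 6 * pi, length.out = 1000)
  helix <- kinematic_stream(u, cbind(10 * cos(u), 10 * sin(u), 2 * u),
                            identity_quat(1000))
  analytic <- 6 * pi * sqrt(10^2 + 2^2)
  expect_lt(abs(linear_path_length(helix) - analytic) / analytic, 0.005)

  # invariance under rigid motion; refinement never shortens the path
  set.seed(1)
  pts <- matrix(rnorm(30), 10, 3)
  base <- kinematic_stream(1:10, pts, identity_quat(10))
  R <- random_rotation_matrix()
  moved <- kinematic_stream(1:10, sweep(pts %*% t(R), 2, c(5, -3, 2), `+`),
                            identity_quat(10))
  expect_equal(linear_path_length(moved), linear_path_length(base),
               tolerance = 1e-9)

  jit <- matrix(0, 19, 3)
  jit[seq(1, 19, 2), ] <- pts
  jit[seq(2, 18, 2), ] <- (pts[-10, ] + pts[-1, ]) / 2 +
    matrix(rnorm(27, sd = 0.1), 9, 3)
  refined <- kinematic_stream(seq(1, 10, 0.5), jit, identity_quat(19))
  expect_gte(linear_path_length(refined), linear_path_length(base))
})

test_that("angular_path_length: geodesic additivity and sign invariance", {
  n <- 91
  still <- kinematic_stream(1:10, matrix(0, 10, 3), identity_quat(10))
  expect_equal(angular_path_length(still), 0)

  # rotation about z from 0 to pi/2 in 90 equal steps
  ang <- seq(0, pi / 2, length.out = n)
  quat <- cbind(cos(ang / 2), 0, 0, sin(ang / 2))
  s <- kinematic_stream(seq_len(n), matrix(0, n, 3), quat)
  expect_equal(angular_path_length(s), pi / 2, tolerance = 1e-9)

  # flipping the sign of any subset of quaternions changes nothing
  set.seed(8)
  walk <- matrix(rnorm(4 * 50), 50, 4)
  walk <- walk / sqrt(rowSums(walk^2))
  sw <- kinematic_stream(1:50, matrix(0, 50, 3), walk)
  flip <- sample(c(-1, 1), 50, replace = TRUE)
  swf <- kinematic_stream(1:50, matrix(0, 50, 3), walk * flip)
  expect_equal(angular_path_length(swf), angular_path_length(sw),
               tolerance = 1e-12)

  bad <- s; bad$quat[3, ] <- bad$quat[3, ] * 1.5
  expect_error(angular_path_length(bad), "non-unit")
})

test_that("idle_time matches the brute-force segment scan", {
  cfg <- opi_config(idle_speed_threshold_mm_s = 1, idle_min_dwell_s = 0.5)
  # always moving
  expect_equal(idle_time(rep(20, 100), t = (0:100) / 50, config = cfg), 0)

  # 10 s stationary block inside a 60 s moving stream
  rate <- 50
  t <- (0:(60 * rate)) / rate
  speed <- rep(20, length(t) - 1)
  block <- t[-length(t)] >= 25 & t[-length(t)] < 35
  speed[block] <- 0.1
  got <- idle_time(speed, t = t, config = cfg)
  want <- brute_idle_time(speed, diff(t), 1, 0.5)
  expect_equal(got, want)
  expect_lt(abs(got - 10), 1 / rate + 1e-9)

  # a 0.1 s dip is filtered out by the minimum dwell
  speed2 <- rep(20, length(t) - 1)
  speed2[1000:1004] <- 0.1 # 5 samples = 0.1 s
  expect_equal(idle_time(speed2, t = t, config = cfg), 0)
})

test_that("energy_proportion: interval sums, clipping and errors", {
  expect_equal(energy_proportion(event_stream(), 40), 0)
  ev <- event_stream(c(5, 15), c("energy_on", "energy_off"))
  expect_equal(energy_proportion(ev, 40), 0.25)
  bursts <- event_stream(c(1, 3, 10, 12, 20, 22),
                         rep(c("energy_on", "energy_off"), 3))
  expect_equal(energy_proportion(bursts, 30), 0.2)
  expect_equal(energy_proportion(bursts, 3), 1) # clipped
  expect_error(energy_proportion(bursts, 0), "active_time_s")
  expect_error(event_stream(c(1, 2), c("energy_off", "energy_on")),
               "alternate")
  expect_error(event_stream(1, "energy_on"), "unmatched")
})

test_that("clutch_count filters by kind", {
  expect_equal(clutch_count(event_stream()), 0L)
  ev <- event_stream(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                     c("clutch", "energy_on", "clutch", "energy_off", "clutch",
                       "energy_on", "clutch", "energy_off", "clutch"))
  expect_equal(clutch_count(ev), 5L)
})

test_that("extract_opis is internally consistent and orders skill", {
  n <- 501
  t <- (seq_len(n) - 1) / 50
  still <- kinematic_stream(t, matrix(0, n, 3), identity_quat(n))
  v <- extract_opis(still, event_stream())
  expect_equal(v$speed_peaks, 0L)
  expect_equal(v$angular_path_length_rad, 0)
  expect_equal(v$linear_path_length_mm, 0)
  expect_equal(v$idle_time_s, 10, tolerance = 0.05)
  expect_equal(v$energy_proportion, 0)
  expect_equal(v$clutch_count, 0L)

  # paired simulation: novice at least as high on peaks, path, idle
  for (seed in c(4, 9)) {
    e <- extract_opis(simulate_trajectory(expert_profile(), 60, seed = seed),
                      simulate_events(expert_profile(), 60, seed = seed))
    nv <- extract_opis(simulate_trajectory(novice_profile(), 60, seed = seed),
                       simulate_events(novice_profile(), 60, seed = seed))
    expect_gte(nv$speed_peaks, e$speed_peaks)
    expect_gte(nv$linear_path_length_mm, e$linear_path_length_mm)
    expect_gte(nv$idle_time_s, e$idle_time_s)
  }
})

test_that("energy_proportion stays in [0, 1] across random event streams", {
  set.seed(13)
  for (i in 1:25) {
    p <- skill_profile(energy_duty = runif(1), clutch_rate_per_min = runif(1, 0, 10))
    ev <- simulate_events(p, runif(1, 5, 60), seed = i + 100)
    ep <- energy_proportion(ev, runif(1, 0.5, 60))
    expect_gte(ep, 0); expect_lte(ep, 1)
  }
})
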