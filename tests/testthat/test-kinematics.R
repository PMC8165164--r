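test_that("the initial trim removes exactly the first seconds and keeps absolute time", {
  n <- 300  # 10 s at 30 fps
  traj <- make_traj(rep(1, n), rep(1, n), rep(2, n), rep(2, n), fps = 30)
  tr <- trim_initial(traj, 2)
  expect_identical(length(tr), 240L)
  expect_equal(min(tr$time), 2)
  expect_identical(trim_initial(traj, 0)$frames, traj$frames)
  expect_error(trim_initial(traj, 11), class = "empty_trajectory")
  expect_error(trim_initial(traj, -1), class = "config_error")
})

test_that("likelihood filtering interpolates short gaps linearly and keeps long gaps missing", {
  n <- 30
  hx <- seq(0, 2, length.out = n); hy <- hx
  lik <- rep(0.99, n)
  lik[15] <- 0.1                      # one-frame dropout
  traj <- make_traj(hx, hy, hx, hy, lik = lik, fps = 30)
  traj$x[15, ] <- 99; traj$y[15, ] <- -99
  filt <- filter_low_likelihood(traj, threshold = 0.6, max_gap = 0.5)
  # midpoint of the neighbours on a straight line
  expect_equal(unname(filt$x[15, "head"]), (hx[14] + hx[16]) / 2)
  expect_equal(unname(filt$y[15, "head"]), (hy[14] + hy[16]) / 2)

  # threshold 0 never marks anything
  expect_identical(filter_low_likelihood(traj, threshold = 0)$x, traj$x)

  # a gap longer than max_gap stays missing
  lik2 <- rep(0.99, n); lik2[10:28] <- 0.1
  traj2 <- make_traj(hx, hy, hx, hy, lik = lik2, fps = 30)
  filt2 <- filter_low_likelihood(traj2, threshold = 0.6, max_gap = 0.1)
  expect_true(all(is.na(filt2$x[12:26, "head"])))

  lik3 <- rep(0.2, n)
  traj3 <- make_traj(hx, hy, hx, hy, lik = lik3, fps = 30)
  expect_error(filter_low_likelihood(traj3, threshold = 0.6),
               class = "empty_trajectory")
})

test_that("local linear smoothing preserves constants and straight lines exactly", {
  const <- rep(3.7, 100)
  expect_equal(loess_smooth(const, span = 0.2), const, tolerance = 1e-10)
  line <- 0.5 + 0.25 * seq_len(100)
  expect_equal(loess_smooth(line, span = 0.2), line, tolerance = 1e-8)
  expect_error(loess_smooth(line, span = 0.001), class = "parameter_error")
  expect_error(loess_smooth(line, span = 1.5), class = "parameter_error")
})

test_that("smoothing reduces the error of a jittered signal", {
  set.seed(7)
  t <- seq(0, 10, by = 1 / 30)
  truth <- sin(2 * pi * t / 5)
  noisy <- truth + rnorm(length(t), 0, 0.3)
  sm <- loess_smooth(noisy, span = 0.05, time = t)
  rmse <- function(a, b) sqrt(mean((a - b)^2))
  expect_lt(rmse(sm, truth), 0.5 * rmse(noisy, truth))
})

test_that("the orientation index hits its geometric anchor cases", {
  expect_equal(orientation_index(c(0, 0), c(1, 0), c(2, 0)), 1)
  expect_equal(orientation_index(c(0, 0), c(1, 0), c(0, 5)), 0)
  expect_equal(orientation_index(c(0, 0), c(1, 0), c(-3, 0)), -1)
  # degenerate zero-length vectors give NA, not an error
  expect_true(is.na(orientation_index(c(0, 0), c(0, 0), c(1, 1))))
  expect_true(is.na(orientation_index(c(1, 1), c(2, 2), c(1, 1))))
})

test_that("the index-to-degrees mapping is the sign-preserving arcsine", {
  expect_equal(index_to_degrees(0), 0)
  expect_equal(index_to_degrees(1), 90)
  expect_equal(index_to_degrees(-1), -90)
  expect_equal(index_to_degrees(0.5), asin(0.5) * 180 / pi)
  expect_equal(index_to_degrees(-0.2), -index_to_degrees(0.2))
  expect_error(index_to_degrees(1.01), class = "domain_error")
})

test_that("feeding detection respects the zone and debounces short crossings", {
  geom <- arena_geometry()
  feeder <- geom$feeder_center
  n <- 60
  # head parked at the feeder: all frames are feeding
  at <- make_traj(rep(feeder[1], n), rep(feeder[2], n),
                  rep(feeder[1] - 3, n), rep(feeder[2], n), fps = 30)
  expect_true(all(detect_feeding(at, geom)))
  # head far away: none
  far <- make_traj(rep(5, n), rep(5, n), rep(6, n), rep(5, n), fps = 30)
  expect_false(any(detect_feeding(far, geom)))
  # a 3-frame blip (0.1 s) is removed at the default 0.3 s debounce
  hx <- rep(5, n); hy <- rep(5, n)
  hx[30:32] <- feeder[1]; hy[30:32] <- feeder[2]
  blip <- make_traj(hx, hy, hx - 1, hy, fps = 30)
  expect_false(any(detect_feeding(blip, geom)))
  expect_true(any(detect_feeding(blip, geom, min_bout = 0.05)))
  # pixel input must be calibrated first
  px <- make_traj(hx, hy, hx, hy, fps = 30, units = "px")
  expect_error(detect_feeding(px, geom), class = "config_error")
})

test_that("the activity rate is the log mean non-feeding speed", {
  fps <- 30
  n <- 61
  v <- 4  # cm/s along x
  traj <- make_traj((0:60) * v / fps, rep(0, n),
                    (0:60) * v / fps, rep(0.1, n), fps = fps)
  mask <- rep(FALSE, n)
  expect_equal(activity_rate(traj, mask), log(v))
  # uniform rescaling of space shifts the log rate by log(scale)
  traj2 <- traj; traj2$x <- traj$x * 3; traj2$y <- traj$y * 3
  expect_equal(activity_rate(traj2, mask), log(v) + log(3))
  # a stationary bird hits the floor, not -Inf
  still <- make_traj(rep(1, n), rep(1, n), rep(1, n), rep(1, n), fps = fps)
  expect_equal(activity_rate(still, mask), log(1e-3))
  expect_warning(r <- activity_rate(traj, rep(TRUE, n)), "non-feeding")
  expect_true(is.na(r))
})

test_that("latency to feed matches the first debounced zone entry or censors", {
  geom <- arena_geometry()
  feeder <- geom$feeder_center
  fps <- 30
  n <- 300
  hx <- rep(5, n); hy <- rep(5, n)
  enter <- 151  # first feeding frame, time (151 - 1) / 30 = 5 s
  hx[enter:n] <- feeder[1]; hy[enter:n] <- feeder[2]
  traj <- make_traj(hx, hy, hx - 2, hy, fps = fps)
  lat <- latency_to_feed(traj, geom)
  expect_false(lat$censored)
  expect_equal(lat$latency_s, (enter - 1) / fps)

  never <- make_traj(rep(5, n), rep(5, n), rep(6, n), rep(5, n), fps = fps)
  lat2 <- latency_to_feed(never, geom)
  expect_true(lat2$censored)
  expect_equal(lat2$latency_s, max(never$time) + 1 / fps)
})

test_that("the full preprocessing chain recovers the simulator's ground truth", {
  cfg <- sim_config(n_birds = 4, conditions = "Wall", n_sessions = 1,
                    session_length = 180, tracker_noise_sd = 0,
                    dropout_prob = 0,
                    approach_speed_mean = c(Wall = 6),
                    orientation_bias = c(Wall = 0.5),
                    latency_mean = matrix(15, 1, 1, dimnames = list("Wall", NULL)),
                    seed = 2024)
  ori <- numeric(4)
  for (b in 1:4) {
    sim <- simulate_session(cfg, b, "Wall", 1)
    st <- session_stats(sim$trajectory, cfg$arena)
    expect_false(st$censored)
    expect_lt(abs(st$latency_s - sim$events$latency_s), 0.5)
    # feeding frames agree with the generator's ground-truth mask
    truth <- sim$events$feeding_mask[sim$trajectory$time >= 2]
    expect_gt(mean(st$feeding_mask == truth), 0.93)
    # orientation is defined over the post-approach segment
    post <- st$orientation$time_s > sim$events$latency_s + 5
    ori[b] <- mean(st$orientation$value[post], na.rm = TRUE)
  }
  # the per-session OU average fluctuates; the bias is recovered on average
  expect_lt(abs(mean(ori) - 0.5), 0.05)
})
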