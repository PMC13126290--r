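make_traj <- function(t, x, y, id = "a1") {
  structure(data.frame(t_s = t, x_mm = x, y_mm = y),
            class = c("trajectory", "data.frame"), animal_id = id)
}

test_that("uniform linear motion gives a constant speed series", {
  t <- seq(0, 10, by = 0.1)
  tr <- make_traj(t, 5 * t, rep(0, length(t)))
  sp <- trajectory_speeds(tr)
  expect_equal(sp$speed, rep(5, length(t) - 1), tolerance = 1e-9)

  still <- make_traj(t, rep(3, length(t)), rep(4, length(t)))
  expect_true(all(trajectory_speeds(still)$speed == 1e-3))  # floored
  expect_error(trajectory_speeds(make_traj(c(0, 1, 1), 1:3, 1:3)),
               "duplicate")
})

test_that("circular motion recovers r*omega at fine sampling", {
  r <- 10; omega <- 0.5
  t <- seq(0, 20, by = 0.01)
  tr <- make_traj(t, r * cos(omega * t), r * sin(omega * t))
  sp <- trajectory_speeds(tr)
  expect_lt(max(abs(sp$speed - r * omega)) / (r * omega), 0.01)
})

test_that("tracking gaps break the differencing instead of creating teleports", {
  t <- c(seq(0, 5, by = 0.1), seq(10, 15, by = 0.1))
  x <- c(seq(0, 5, by = 0.1), seq(100, 105, by = 0.1))
  tr <- make_traj(t, x, rep(0, length(t)))
  sp <- trajectory_speeds(tr)
  expect_lt(max(sp$speed), 2)  # the 95 mm jump is not turned into a speed
})

test_that("window speeds equal configured means for noise-free generators", {
  t <- seq(0, 120, by = 0.05)
  tr <- make_traj(t, 5 * t, rep(0, length(t)))
  ws <- window_speeds(tr)
  expect_equal(ws$startle_speed, 5, tolerance = 1e-9)
  expect_equal(ws$cruising_speed, 5, tolerance = 1e-9)

  trajs <- simulate_trajectories(swim_sim_params(speed_cv = 0), seed = 1)
  ws2 <- window_speeds(trajs[[1]])
  expect_equal(ws2$startle_speed, 20, tolerance = 1e-9)
  expect_equal(ws2$cruising_speed, 5, tolerance = 1e-9)
  expect_equal(ws2$activity_class, "active")
})

test_that("noisy generator recovers the startle/cruise ratio within 5%", {
  p <- swim_sim_params(n_animals = 12)
  ratios <- sapply(1:5, function(s) {
    trajs <- simulate_trajectories(p, seed = s)
    ws <- do.call(rbind, lapply(trajs, window_speeds))
    mean(ws$startle_speed / ws$cruising_speed)
  })
  # lognormal frame noise biases both window geometric means by the same
  # factor, so the ratio is recovered cleanly
  expect_lt(abs(mean(ratios) - 20 / 5) / (20 / 5), 0.05)
})

test_that("activity classes capture still, active, and half-active animals", {
  stills <- simulate_trajectories(swim_sim_params(still_fraction = 1),
                                  seed = 2)
  cls <- vapply(stills, function(tr) classify_activity(tr)$activity_class, "")
  expect_true(all(cls == "still"))

  movers <- simulate_trajectories(swim_sim_params(still_fraction = 0),
                                  seed = 3)
  expect_true(all(vapply(movers, function(tr)
    classify_activity(tr)$activity_class, "") == "active"))

  # active exactly during the first half of the session
  t <- seq(0, 120, by = 0.1)
  x <- ifelse(t <= 60, 5 * t, 5 * 60)
  half <- make_traj(t, x, rep(0, length(t)))
  act <- classify_activity(half)
  expect_equal(act$activity_class, "half_active")
  expect_true(act$first_half_active)
})

test_that("geometric means obey AM-GM and metrics are rigid-motion invariant", {
  trajs <- simulate_trajectories(swim_sim_params(), seed = 4)
  for (tr in trajs[1:3]) {
    sp <- trajectory_speeds(tr)
    expect_lte(exp(mean(log(sp$speed))), mean(sp$speed) + 1e-12)
    # rotate by 40 degrees and translate
    th <- 40 * pi / 180
    tr2 <- make_traj(tr$t_s,
                     cos(th) * tr$x_mm - sin(th) * tr$y_mm + 12,
                     sin(th) * tr$x_mm + cos(th) * tr$y_mm - 7)
    expect_equal(window_speeds(tr2)$startle_speed,
                 window_speeds(tr)$startle_speed, tolerance = 1e-9)
    expect_equal(window_speeds(tr2)$cruising_speed,
                 window_speeds(tr)$cruising_speed, tolerance = 1e-9)
  }
})

test_that("raising speeds never lowers the activity class", {
  t <- seq(0, 120, by = 0.1)
  x <- ifelse(t <= 50, 3 * t, 3 * 50)
  tr <- make_traj(t, x, rep(0, length(t)))
  lvl <- c(still = 1, half_active = 2, active = 3)
  a <- lvl[[classify_activity(tr)$activity_class]]
  tr_fast <- make_traj(t, 3 * x, rep(0, length(t)))
  b <- lvl[[classify_activity(tr_fast)$activity_class]]
  expect_gte(b, a)
})

test_that("repetition trends are flat for stationary behavior and catch habituation", {
  p <- swim_sim_params(n_animals = 12)
  mk_summaries <- function(decay) {
    do.call(rbind, lapply(1:7, function(rep) {
      trajs <- simulate_trajectories(p, seed = 50 + rep)
      ws <- do.call(rbind, lapply(trajs, window_speeds))
      ws$startle_speed <- ws$startle_speed * decay^(rep - 1)
      ws$cruising_speed <- ws$cruising_speed * decay^(rep - 1)
      ws$repetition <- rep
      ws
    }))
  }
  flat <- repetition_trend(mk_summaries(1))
  expect_gt(min(flat$p_value), 0.05)
  expect_lt(max(abs(flat$slope)), 0.05)

  hab <- repetition_trend(mk_summaries(0.9))
  expect_true(all(hab$slope < 0))
  expect_lt(max(hab$p_value), 0.05)

  # permuting repetition labels destroys the injected trend
  s <- mk_summaries(0.9)
  set.seed(1)
  s$repetition <- sample(s$repetition)
  perm <- repetition_trend(s)
  expect_gt(min(perm$p_value), 0.05)
  expect_error(repetition_trend(s[s$repetition == 1, ]), "at least 2")
})

test_that("trajectory CSV round trip preserves tracks", {
  trajs <- simulate_trajectories(swim_sim_params(n_animals = 3), seed = 5)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(trajs, f)
  back <- read_trajectories(f)
  expect_equal(length(back), 3L)
  expect_equal(back[[1]]$x_mm, trajs[[1]]$x_mm, tolerance = 1e-9)
})

test_that("still animals are fully reproducible and flagged in truth metadata", {
  a <- simulate_trajectories(swim_sim_params(still_fraction = 0.5), seed = 6)
  b <- simulate_trajectories(swim_sim_params(still_fraction = 0.5), seed = 6)
  expect_identical(lapply(a, as.data.frame), lapply(b, as.data.frame))
  stills <- vapply(a, attr, logical(1), "truth_still")
  modes <- vapply(a, function(tr) tr$truth_mode[1], "")
  expect_equal(unname(stills), unname(modes == "still"))
})

test_that("group speed comparison works on the log2 scale", {
  p <- swim_sim_params(n_animals = 10)
  mk <- function(seed, group, factor = 1) {
    trajs <- simulate_trajectories(p, seed = seed)
    ws <- do.call(rbind, lapply(trajs, window_speeds))
    ws$startle_speed <- ws$startle_speed * factor
    ws$group <- group
    ws
  }
  s <- rbind(mk(1, "diploid"), mk(2, "triploid", factor = 1.5))
  res <- compare_speed_groups(s, "startle")
  expect_lt(abs(res$ratio - 1.5), 0.15)
  expect_lt(res$p_value, 0.01)
  same <- rbind(mk(3, "diploid"), mk(3, "triploid"))
  expect_gt(compare_speed_groups(same, "cruising")$p_value, 0.99)
})
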