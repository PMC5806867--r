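test_that("mBruce walk of 10.5 min splits into 3 full stages and 1.5 min extra", {
  p <- mbruce()
  sp <- split_walk_time(p, 10.5)
  expect_identical(sp$completed_stages, 3L)
  expect_equal(sp$partial_stage_time, 1.5)
  expect_equal(walked_distance(p, 10.5), 505)
  # partial-stage distance: (50/3) * 1.5 min * 4 km/h = 100 m
  expect_equal(walked_distance(p, 10.5) - walked_distance(p, 9), 100)
  expect_equal(round(average_velocity(505, 10.5), 3), 2.886)
  expect_equal(six_minute_velocity(505), 5.05)
})

test_that("the 6MWT-equivalent velocity exceeds the treadmill average velocity", {
  out <- treadmill_outcome(mbruce(), 10.5)
  expect_gt(out$six_minute_equivalent_velocity, out$average_velocity)
  expect_equal(out$met, 5.95)  # tabulated device score for this walk time
})

test_that("stage splitting handles boundaries, rest and full protocol", {
  p <- mbruce()
  expect_equal(unname(unlist(split_walk_time(p, 0))), c(0, 0))
  # exact stage boundary belongs to the completed stage
  sp <- split_walk_time(p, 6)
  expect_identical(sp$completed_stages, 2L)
  expect_equal(sp$partial_stage_time, 0)
  expect_equal(walked_distance(p, 6), (50 / 3) * 3 * (2.7 + 2.7))
  sp <- split_walk_time(p, 12)  # exhausts the 4-stage preset
  expect_identical(sp$completed_stages, 4L)
  expect_equal(sp$partial_stage_time, 0)
  expect_error(split_walk_time(p, -1), "walk_time")
  expect_error(split_walk_time(p, 12.1), "walk_time")
})

test_that("walk time is exactly reconstructible and distance is monotone", {
  p <- mbruce()
  times <- seq(0, 12, by = 0.125)
  ends <- cumsum(p$stage_durations)
  recon <- vapply(times, function(t) {
    sp <- split_walk_time(p, t)
    s <- sp$completed_stages
    (if (s > 0) ends[s] else 0) + sp$partial_stage_time
  }, numeric(1))
  expect_equal(recon, times)
  d <- vapply(times, function(t) walked_distance(p, t), numeric(1))
  expect_true(all(diff(d) >= 0))
  # slope within a stage is (50/3) * stage velocity [m/min]
  expect_equal((d[times == 2] - d[times == 1]) / 1, (50 / 3) * 2.7)
  expect_equal((d[times == 11] - d[times == 10]) / 1, (50 / 3) * 4.0)
})

test_that("average velocity over a single-stage protocol equals the belt velocity", {
  p <- treadmill_protocol("one-stage", 10, 3.3)
  for (t in c(0.5, 2, 7.25, 10))
    expect_equal(average_velocity(walked_distance(p, t), t), 3.3)
  expect_equal(average_velocity(0, 6), 0)
  expect_equal(average_velocity(270, 6), 2.7)
  expect_error(average_velocity(100, 0), "walk_time")
  expect_error(six_minute_velocity(-5), "non-negative")
})

test_that("heart-rate limit follows the age-predicted maximum and target fraction", {
  expect_equal(predicted_hr_limit(40), 180)
  expect_equal(predicted_hr_limit(40, 0.75), 135)
  expect_equal(predicted_hr_limit(1e-9), 208, tolerance = 1e-6)
  expect_error(predicted_hr_limit(40, 1.2), "fraction")
  expect_error(predicted_hr_limit(40, 0), "fraction")
  expect_error(predicted_hr_limit(-3), "age")
})

test_that("protocol construction validates stage tables", {
  expect_error(treadmill_protocol("bad", c(3, 3), 2.7), "equal length")
  expect_error(treadmill_protocol("bad", c(3, 0), c(2.7, 4)), "positive")
  expect_error(treadmill_protocol("bad", c(3, 3), c(2.7, -1)), "non-negative")
  expect_true(all(mbruce()$stage_durations == 3))
})
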