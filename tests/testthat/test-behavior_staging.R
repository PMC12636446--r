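# Staging pipeline: speed computation, smoothing, hatch detection, bout
# detection, transition calling and roaming fractions.

test_that("compute_speed matches closed forms", {
  n <- 200
  # stationary
  still <- make_track(rep(1, n), rep(2, n))
  expect_true(all(compute_speed(still)$speed == 0))
  # straight line at v = 0.3 units/s
  tt <- (seq_len(n) - 1) / 3
  line <- make_track(0.3 * tt, rep(0, n))
  expect_equal(compute_speed(line)$speed, rep(0.3, n - 30), tolerance = 1e-12)
  # circle radius R, period T: windowed speed = chord(10 s) / 10
  R <- 2; T <- 120
  tt <- (seq_len(1200) - 1) / 3
  circ <- make_track(R * cos(2 * pi * tt / T), R * sin(2 * pi * tt / T))
  chord <- 2 * R * sin(pi * 10 / T)
  expect_equal(compute_speed(circ)$speed, rep(chord / 10, 1200 - 30), tolerance = 1e-9)
})

test_that("compute_speed refuses short tracks and never spans gaps", {
  short <- make_track(rep(0, 10), rep(0, 10))
  expect_error(compute_speed(short), "shorter than one speed window")
  # a >2 s gap splits the series: speed resumes only 30 frames into part 2
  tt <- c((0:299) / 3, (0:299) / 3 + 110)
  tr <- make_track(seq_along(tt) * 0.1, rep(0, length(tt)))
  tr$frames$time_s <- tt
  sp <- compute_speed(tr)
  expect_equal(length(sp$speed), 2 * (300 - 30))
  expect_false(any(sp$time_s > 100 & sp$time_s < 110 + 10))
})

test_that("smooth_speed is the centered shrinking-window mean", {
  const <- make_speed_series(rep(2.5, 400))
  expect_equal(smooth_speed(const, 25)$speed, rep(2.5, 400))
  # unit impulse -> plateau of height 1/window over window frames
  imp <- make_speed_series(c(rep(0, 200), 1, rep(0, 200)))
  sm <- smooth_speed(imp, 25)
  expect_equal(sum(sm$speed > 1 / 25 - 1e-12), 25)
  expect_equal(max(sm$speed), 1 / 25)
  # white noise: output variance ~ input variance / window
  set.seed(42)
  noise <- make_speed_series(abs(rnorm(20000)))
  smn <- smooth_speed(noise, 101)
  ratio <- stats::var(smn$speed[200:19800]) / stats::var(noise$speed)
  expect_lt(abs(ratio - 1 / 101) / (1 / 101), 0.25)
  expect_error(smooth_speed(const, 0), "positive")
})

test_that("hatch detection finds the activity onset", {
  cfg <- behavior_sim_config(
    stage_durations = c(90, 70, 70, 120), bout_durations = c(20, 20, 20),
    hatch_delay = 60, jitter_sd = 0
  )
  sim <- gen_locomotion_track(cfg, individual_seed = 13, collection_age_L4 = 30)
  expect_lt(abs(detect_hatch(sim$track) - 60), 2)
  # all-quiet track: no hatch
  still <- make_track(rep(0, 2000), rep(0, 2000))
  expect_error(detect_hatch(still), "no hatch")
  # active from frame 0: hatch = 0
  set.seed(1)
  tt <- cumsum(runif(5000, 0.05, 0.15))
  active <- make_track(cumsum(rnorm(5000, 0, 0.05)), cumsum(rnorm(5000, 0, 0.05)))
  expect_equal(detect_hatch(active), 0)
})

test_that("bout detection finds planted bouts and applies the merge rule", {
  sim <- short_track()
  sm <- smooth_speed(compute_speed(sim$track))
  bouts <- detect_quiescence_bouts(sm)
  post <- bouts[bouts$midpoint_min > sim$truth$hatch_min, ]
  expect_equal(nrow(post), 3)
  expect_lt(max(abs(post$midpoint_min - sim$truth$transitions_min)), 2)

  # constant high speed: no bouts
  high <- make_speed_series(rep(1, 600), frame_rate = 1 / 60)
  expect_equal(nrow(detect_quiescence_bouts(high, threshold = 0.1)), 0)

  # two sub-threshold runs separated by < merge_gap merge into one bout
  sp <- rep(1, 120)
  sp[31:40] <- 0.01   # minutes 30-39
  sp[44:55] <- 0.01   # minutes 43-54, gap 4 min < 5
  ser <- make_speed_series(sp, frame_rate = 1 / 60)
  merged <- detect_quiescence_bouts(ser, threshold = 0.1, min_duration_min = 10,
                                    merge_gap_min = 5)
  expect_equal(nrow(merged), 1)
  expect_equal(merged$start_min, 30)
  expect_gte(merged$end_min, 54)
})

test_that("transition calling ranks bouts by duration and enforces order", {
  bouts <- data.frame(
    start_min = c(100, 300, 500, 700), end_min = c(130, 330, 512, 730),
    midpoint_min = c(115, 315, 506, 715), duration_min = c(30, 30, 12, 30)
  )
  tl <- call_transitions(bouts, hatch_time = 50, collection_min = 800, individual_id = "w1")
  expect_equal(tl$transitions, c(115, 315, 715))  # 12-min bout excluded by ranking
  expect_equal(tl$age_since_L4, 800 - 715)
  expect_equal(tl$age_since_hatch, 800 - 50)
  expect_error(call_transitions(bouts[1:2, ], 50, 800, individual_id = "w2"),
               "staging error for 'w2'")
  partial <- call_transitions(bouts[1:2, ], 50, 800, partial = TRUE)
  expect_true(is.na(partial$transitions[3]))
})

test_that("staging recovers planted timelines; ages satisfy the exact identity", {
  sim <- short_track()
  tl <- stage_track(sim$track)
  expect_lt(max(abs(tl$transitions - sim$truth$transitions_min)), 2)
  expect_lt(abs(tl$hatch_min - sim$truth$hatch_min), 2)
  expect_equal(tl$age_since_L4 + tl$transitions[3] - tl$hatch_min, tl$age_since_hatch)
})

test_that("bout detection is invariant to rotation, translation and time shift", {
  sim <- short_track()
  tl0 <- stage_track(sim$track)
  th <- 0.7
  rot <- sim$track
  rot$frames$x <- cos(th) * sim$track$frames$x - sin(th) * sim$track$frames$y + 3
  rot$frames$y <- sin(th) * sim$track$frames$x + cos(th) * sim$track$frames$y - 1
  tl1 <- stage_track(rot)
  expect_equal(tl1$transitions, tl0$transitions, tolerance = 1e-8)
  shifted <- sim$track
  shifted$frames$time_s <- shifted$frames$time_s + 600
  tl2 <- stage_track(shifted)
  expect_equal(tl2$transitions, tl0$transitions + 10, tolerance = 1e-8)
})

test_that("roaming fraction hits its limits", {
  sim <- short_track()
  rf <- roaming_fraction(sim$track)
  truth <- sim$truth
  # bins fully inside a quiescence bout: fraction ~0
  in_bout <- rf$bin_start_min >= truth$bout_intervals[1, "start"] + 2 &
    rf$bin_end_min <= truth$bout_intervals[1, "end"] - 2
  expect_lt(max(rf$fraction_roaming[in_bout]), 0.1)
  # bins well inside an active stage: fraction near 1 (default sim roams)
  act <- rf$bin_start_min >= truth$hatch_min + 10 &
    rf$bin_end_min <= truth$bout_intervals[1, "start"] - 10
  expect_gt(mean(rf$fraction_roaming[act]), 0.8)
  expect_true(all(rf$fraction_roaming >= 0 & rf$fraction_roaming <= 1))
})

test_that("track text round-trips through write_track/read_track", {
  sim <- short_track()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_track(sim$track, f)
  back <- read_track(f)
  expect_equal(back$frames$x, sim$track$frames$x, tolerance = 1e-6)
  expect_equal(back$frame_rate, sim$track$frame_rate, tolerance = 1e-6)
})
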