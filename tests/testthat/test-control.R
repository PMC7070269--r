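test_that("the therapy profile table holds all 21 settings", {
  m <- therapy_profiles()
  expect_equal(dim(m), c(7L, 3L))
  expect_equal(unname(m[1, ]), c(1, 2, 4))
  expect_equal(unname(m[2, ]), c(1, 3, 5))
  expect_equal(unname(m[3, ]), c(1, 4, 5))
  expect_equal(unname(m[4, ]), c(2, 4, 5))
  expect_equal(unname(m[5, ]), c(3, 4, 5))
  expect_equal(unname(m[6, ]), c(0, 2, 5))
  expect_equal(unname(m[7, ]), c(0, 1, 4))
  # settings never decrease with intensity
  for (p in 1:7) expect_true(all(diff(m[p, ]) >= 0))
})

test_that("profile lookup matches the table and rejects bad ids", {
  expect_equal(profile_lookup(2, 0), 1)
  expect_equal(profile_lookup(2, "light"), 3)
  expect_equal(profile_lookup(2, 2), 5)
  expect_equal(profile_lookup(6, "sedentary"), 0)
  expect_error(profile_lookup(8, 0), "1..7")
  expect_error(profile_lookup(0, 0), "1..7")
})

test_that("bolus volumes reproduce the pulse-dose table exactly", {
  printed <- rbind(c(12, 9, 7.2), c(24, 18, 14.4), c(36, 27, 21.6),
                   c(48, 36, 28.8), c(60, 45, 36.0))
  bpms <- c(15, 20, 25)
  for (s in 1:5) for (b in 1:3) {
    expect_equal(bolus_volume(s, bpms[b]), printed[s, b], tolerance = 1e-12)
  }
  expect_equal(bolus_volume(1, 15), 12)      # 12 mL per setting at 15 bpm
  expect_equal(bolus_volume(5, 15) * 15, 900)  # 900 mL/min at the top setting
  expect_equal(bolus_volume(0, 20), 0)
  expect_error(bolus_volume(1, 0), "bpm")
  expect_error(bolus_volume(6, 15), "setting")
  # strictly decreasing in bpm, non-decreasing in setting
  expect_true(all(diff(bolus_volume(3, c(10, 15, 20, 25, 30))) < 0))
  expect_true(all(diff(bolus_volume(0:5, 15)) >= 0))
})

test_that("the FSM moves one level per window toward the observation", {
  p2 <- therapy_profile(2)
  st <- fsm_state(0)
  same <- fsm_step(st, 0, p2)
  expect_equal(same$state$current, 0L)
  expect_equal(same$setting, 1)

  up1 <- fsm_step(fsm_state(0), 2, p2)
  expect_equal(up1$state$current, 1L)
  expect_equal(up1$setting, 3)
  up2 <- fsm_step(up1$state, 2, p2)
  expect_equal(up2$state$current, 2L)
  expect_equal(up2$setting, 5)
})

test_that("the FSM never jumps two levels and converges within two steps", {
  p <- therapy_profile(1)
  set.seed(50)
  st <- fsm_state(0)
  prev <- st$current
  for (obs in sample(0:2, 2000, replace = TRUE)) {
    out <- fsm_step(st, obs, p)
    st <- out$state
    expect_lte(abs(st$current - prev), 1)
    prev <- st$current
  }
  for (start in 0:2) for (target in 0:2) {
    st <- fsm_state(start)
    for (k in 1:2) st <- fsm_step(st, target, p)$state
    expect_equal(st$current, target)
  }
})

test_that("debounce delays reaction until observations persist", {
  p <- therapy_profile(2)
  st <- fsm_state(0, debounce = 2)
  one <- fsm_step(st, 2, p)
  expect_equal(one$state$current, 0L)        # single observation ignored
  two <- fsm_step(one$state, 2, p)
  expect_equal(two$state$current, 1L)        # second consecutive one reacts
  # a dissenting observation resets the streak
  st <- fsm_state(0, debounce = 2)
  st <- fsm_step(st, 2, p)$state
  st <- fsm_step(st, 0, p)$state
  st <- fsm_step(st, 2, p)$state
  expect_equal(st$current, 0L)
})

test_that("closed-loop runs count adjustments and latency correctly", {
  allsed <- run_closed_loop(rep(0, 20), 2)
  expect_equal(unique(allsed$timeline$setting), 1)
  expect_equal(allsed$adjustments, 0)

  updown <- run_closed_loop(c(rep(0, 10), rep(1, 10), rep(0, 10)), 2)
  expect_equal(updown$timeline$setting[c(5, 15, 25)], c(1, 3, 1))
  expect_equal(updown$adjustments, 2)

  ramp <- run_closed_loop(c(rep(0, 10), rep(2, 10)), 1)
  # the setting passes through the light level (2) before reaching 4
  expect_equal(ramp$timeline$setting[11:12], c(2, 4))
  expect_equal(ramp$latency$latency[1], 2)
  expect_equal(ramp$latency$to[1], 2)

  # adjustment count agrees with an independent diff oracle
  set.seed(51)
  stream <- sample(0:2, 500, replace = TRUE)
  tl <- run_closed_loop(stream, 3)
  expect_equal(tl$adjustments, sum(diff(c(1, tl$timeline$setting)) != 0))
  expect_error(run_closed_loop(integer(0), 2), "empty")
})

test_that("adherence percentages reproduce the printed statistic", {
  expect_equal(adherence_rate(17, 96), 17.7)
  expect_equal(adherence_rate(96, 96), 100.0)
  expect_equal(adherence_rate(0, 96), 0.0)
  expect_error(adherence_rate(1, 0), "positive")
  expect_error(adherence_rate(10, 5), "between")
})

test_that("SpO2 summaries compute CTxx and desaturation events", {
  flat <- spo2_summary(rep(95, 120))
  expect_equal(unname(flat$ct), c(0, 0))
  expect_equal(flat$events, 0)

  half <- spo2_summary(c(rep(88, 60), rep(92, 60)))
  expect_equal(unname(half$ct["ct90"]), 50.0)
  expect_equal(unname(half$ct["ct85"]), 0.0)

  set.seed(52)
  v <- runif(500, 80, 100)
  r <- spo2_summary(v)
  expect_equal(unname(r$ct["ct90"]), 100 * sum(v < 90) / 500)
  expect_equal(unname(r$ct["ct85"]), 100 * sum(v < 85) / 500)
  expect_lte(r$ct["ct85"], r$ct["ct90"])
  expect_equal(r$min, min(v))

  # a 12 s dip is one event; a 5 s dip alone is none
  dip <- c(rep(95, 30), rep(88, 12), rep(95, 30))
  expect_equal(spo2_summary(dip)$events, 1)
  blip <- c(rep(95, 30), rep(88, 5), rep(95, 30))
  expect_equal(spo2_summary(blip)$events, 0)
  # two dips separated by a 5 s recovery merge into one event
  merged <- c(rep(95, 20), rep(88, 8), rep(95, 5), rep(88, 8), rep(95, 20))
  expect_equal(spo2_summary(merged)$events, 1)
  # separated by 30 s they stay two events
  two <- c(rep(95, 20), rep(88, 12), rep(95, 30), rep(88, 12), rep(95, 20))
  expect_equal(spo2_summary(two)$events, 2)

  expect_error(spo2_summary(numeric(0)), "empty")
  expect_error(spo2_summary(c(50, 120)), "0, 100")
})
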