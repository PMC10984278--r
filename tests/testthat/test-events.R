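# Event detection, synchronicity, bout classification, event position.

test_that("threshold rule: 0.049 L never fires, 0.06 L spans the series", {
  t <- (0:99) / 150
  none <- detect_extension_events(rep(0.049, 100), t)
  expect_equal(nrow(none), 0)
  all_on <- detect_extension_events(rep(0.06, 100), t)
  expect_equal(nrow(all_on), 1)
  expect_equal(all_on$onset, 0)
  expect_equal(all_on$offset, 100 / 150)
  expect_equal(all_on$t_max, 0)   # earliest argmax on ties
})

test_that("a trapezoid crossing 0.05 L at 1.00 and 1.40 s gives that event", {
  fs <- 150
  t <- (0:(3 * fs - 1)) / fs
  # rise at 0.5 L/s from t=0.9 (crosses 0.05 at 1.00), apex 0.15 at 1.2,
  # fall at -0.5 L/s (crosses 0.05 at 1.40)
  e <- pmax(0, pmin(0.5 * (t - 0.9), 0.15 - 0.5 * (t - 1.2)))
  ev <- detect_extension_events(e, t)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset, 1.00, tolerance = 1 / fs)
  expect_equal(ev$offset, 1.40, tolerance = 1.5 / fs)
  expect_equal(ev$offset - ev$onset, 0.40, tolerance = 2 / fs)
})

test_that("detector equals the exhaustive-scan oracle on random series", {
  set.seed(31)
  fs <- 150
  for (rep in 1:50) {
    n <- sample(30:200, 1)
    t <- (0:(n - 1)) / fs
    e <- pmax(0, 0.05 + cumsum(rnorm(n, 0, 0.01)))
    got <- detect_extension_events(e, t)
    want <- oracle_detect_events(e, t)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got) > 0) {
      expect_equal(got$onset, want$onset)
      expect_equal(got$offset, want$offset)
      expect_equal(got$t_max, want$t_max)
      # events are disjoint and ordered
      if (nrow(got) > 1)
        expect_true(all(got$onset[-1] >= got$offset[-nrow(got)]))
    }
  }
})

test_that("lowering the threshold never loses above-threshold samples", {
  set.seed(32)
  t <- (0:199) / 150
  e <- pmax(0, 0.05 + cumsum(rnorm(200, 0, 0.008)))
  covered <- function(th) {
    ev <- detect_extension_events(e, t, threshold = th)
    sum(vapply(seq_len(nrow(ev)), function(i)
      ev$offset_idx[i] - ev$onset_idx[i], numeric(1)))
  }
  ths <- c(0.08, 0.06, 0.05, 0.03)
  expect_true(all(diff(vapply(ths, covered, numeric(1))) >= 0))
})

test_that("synchronicity follows the 50%-of-shorter-event overlap rule", {
  mk <- function(side, on, off)
    data.frame(side = side, onset = on, offset = off, t_max = (on + off) / 2,
               peak_extension = 0.1, onset_idx = 1L, offset_idx = 2L)
  # identical intervals: synchronous
  s1 <- label_synchronicity(mk("left", 0, 1), mk("right", 0, 1))
  expect_equal(s1$left$synchronicity, "synchronous")
  expect_equal(s1$right$synchronicity, "synchronous")
  # disjoint: both asynchronous
  s2 <- label_synchronicity(mk("left", 0, 1), mk("right", 2, 3))
  expect_equal(s2$left$synchronicity, "asynchronous")
  expect_equal(s2$right$synchronicity, "asynchronous")
  # 0.4 s overlap = 40% of the shorter event: asynchronous
  s3 <- label_synchronicity(mk("left", 0, 1), mk("right", 0.6, 1.6))
  expect_equal(s3$left$synchronicity, "asynchronous")
  # 0.6 s overlap = 60%: synchronous
  s4 <- label_synchronicity(mk("left", 0, 1), mk("right", 0.4, 1.4))
  expect_equal(s4$left$synchronicity, "synchronous")
  # within-side overlap is an input error
  bad <- rbind(mk("left", 0, 1), mk("left", 0.5, 2))
  expect_error(label_synchronicity(bad, mk("right", 0, 1)), "overlap")
})

test_that("synchronicity labels agree with the interval oracle and are symmetric", {
  set.seed(33)
  mk1 <- function(side, on, off)
    data.frame(side = side, onset = on, offset = off, t_max = (on + off) / 2,
               peak_extension = 0.1, onset_idx = 1L, offset_idx = 2L)
  for (rep in 1:50) {
    l_on <- runif(1, 0, 3); l_off <- l_on + runif(1, 0.1, 1.5)
    r_on <- runif(1, 0, 3); r_off <- r_on + runif(1, 0.1, 1.5)
    got <- label_synchronicity(mk1("left", l_on, l_off),
                               mk1("right", r_on, r_off))
    want <- oracle_pair_synchronous(l_on, l_off, r_on, r_off)
    expect_equal(got$left$synchronicity == "synchronous", want)
    expect_equal(got$right$synchronicity == "synchronous", want)
    # swapping sides preserves the labels
    swapped <- label_synchronicity(mk1("left", r_on, r_off),
                                   mk1("right", l_on, l_off))
    expect_equal(swapped$left$synchronicity, got$right$synchronicity)
  }
})

test_that("greedy pairing uses each event at most once, by largest overlap", {
  mk <- function(side, on, off)
    data.frame(side = side, onset = on, offset = off, t_max = (on + off) / 2,
               peak_extension = 0.1, onset_idx = 1L, offset_idx = 2L)
  left <- rbind(mk("left", 0, 1), mk("left", 1.2, 2.2))
  right <- mk("right", 0.9, 1.9)   # overlaps both; more with the second
  s <- label_synchronicity(left, right)
  expect_equal(s$left$synchronicity, c("asynchronous", "synchronous"))
  expect_equal(nrow(s$pairs), 1)
  expect_equal(s$pairs$li, 2)
})

test_that("bout classification recovers the three behavior modes", {
  meta <- test_meta()
  for (beh in c("karman_gait", "braking", "still")) {
    tr <- simulate_trial(default_synth_config(beh, meta, seed = 101))
    res <- analyze_trial(tr$pose, NULL, meta)
    want <- if (beh == "still") "other" else beh
    expect_equal(res$bout$label, want)
    if (beh == "karman_gait")
      expect_true(all(res$bout$criteria_flags[paste0("kg", 1:5)]))
    if (beh == "braking")
      expect_true(all(res$bout$criteria_flags[paste0("br", 1:4)]))
  }
  expect_error(classify_bout(list(), numeric(0), numeric(0), 21.7),
               "1 s")
})

test_that("event positions map to suction zone, wake, and outside", {
  ev <- stub_event(t_max = 0.1)
  mk <- function(x, y) flat_track(60, override_x = list(midline_1 = x),
                                  override_y = list(midline_1 = y))
  expect_equal(event_position(ev, mk(10, 1))$zone, "suction_zone")
  expect_equal(event_position(ev, mk(18, -2))$zone, "wake")
  expect_equal(event_position(ev, mk(-5, 0))$zone, "outside")
  expect_error(event_position(stub_event(t_max = 99), mk(10, 1)), "t_max")
})
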