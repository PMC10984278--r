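# EMG filtering, two-pass spike detection, burst grouping.

make_rec <- function(values, rate = 5000) {
  n <- length(values)
  ch <- matrix(0, n, 4, dimnames = list(NULL, emg_channels()))
  ch[, "L_abductor"] <- values
  emg_recording(ch, emg_rate = rate)
}

test_that("bandpass filter kills DC, passes midband, crushes the low stopband", {
  rate <- 5000
  t <- seq(0, 2 - 1 / rate, by = 1 / rate)
  flt <- function(v) {
    rec <- bandpass_filter(make_rec(v, rate), band = c(100, 2250))
    rec$channels[, "L_abductor"]
  }
  expect_lt(abs(mean(flt(rep(1.7, length(t))))), 1e-6)
  mid <- flt(sin(2 * pi * 500 * t))
  expect_lt(abs(max(abs(mid[2000:8000])) - 1), 0.05)
  # 25 Hz = low edge / 4: >= 40 dB down for a 10th-order design
  lowf <- flt(sin(2 * pi * 25 * t))
  expect_lt(max(abs(lowf[2000:8000])), 10^(-40 / 20))
  suppressWarnings(
    expect_error(bandpass_filter(make_rec(rnorm(100), 1000),
                                 band = c(500, 600)), "infeasible"))
  expect_warning(bandpass_filter(make_rec(rnorm(1000), 1000),
                                 band = c(100, 3000)), "clamped")
})

test_that("filtering is linear", {
  set.seed(41)
  rate <- 5000
  x <- rnorm(4000); y <- rnorm(4000)
  flt <- function(v) {
    rec <- bandpass_filter(make_rec(v, rate), band = c(100, 2250))
    rec$channels[, "L_abductor"]
  }
  lhs <- flt(2.5 * x - 1.3 * y)
  rhs <- 2.5 * flt(x) - 1.3 * flt(y)
  expect_lt(max(abs(lhs - rhs)) / max(abs(lhs)), 1e-9)
})

# plant clean biphasic spikes on a near-zero baseline
plant_spikes <- function(times_s, amps, rate = 5000, dur = 1,
                         noise_sd = 1e-6) {
  set.seed(43)
  v <- rnorm(rate * dur, 0, noise_sd)
  ns <- round(0.002 * rate)
  wave <- sin(2 * pi * seq(0, ns - 1) / ns)
  for (k in seq_along(times_s)) {
    i0 <- round(times_s[k] * rate) + 1
    v[i0:(i0 + ns - 1)] <- v[i0:(i0 + ns - 1)] + amps[k] * wave
  }
  make_rec(v, rate)
}

test_that("two-pass rule keeps spikes at >= 25% of the mean spike amplitude", {
  # amplitudes {1.0, 1.0, 0.2}: mean ~0.733, threshold ~0.183, all retained
  rec <- plant_spikes(c(0.2, 0.5, 0.8), c(1.0, 1.0, 0.2))
  sp <- detect_spikes(rec, "L_abductor", noise_k = 5)
  expect_equal(nrow(sp), 3)
  expect_equal(mean(sp$amplitude), 0.733, tolerance = 0.05)
  # {1.0, 1.0, 0.02}: pass 1 excludes 0.02, so mean is 1.0 and two remain
  rec2 <- plant_spikes(c(0.2, 0.5, 0.8), c(1.0, 1.0, 0.02), noise_sd = 0.002)
  sp2 <- detect_spikes(rec2, "L_abductor", noise_k = 5)
  expect_equal(nrow(sp2), 2)
  # peak lands within the 2 ms biphasic waveform
  expect_lt(max(abs(sp2$time - c(0.2, 0.5))), 0.003)
})

test_that("pure noise yields no spikes and a flat channel yields none", {
  set.seed(44)
  rec <- make_rec(rnorm(10000), 5000)
  filtered <- bandpass_filter(rec, band = c(100, 2250))
  sp <- detect_spikes(filtered, "L_abductor")
  expect_equal(nrow(sp), 0)
  expect_equal(nrow(detect_spikes(make_rec(rep(0, 1000)), "L_abductor")), 0)
})

test_that("spike times are invariant under positive rescaling", {
  rec <- plant_spikes(c(0.1, 0.4, 0.7), c(1, 0.8, 0.5), noise_sd = 0.01)
  sp1 <- detect_spikes(rec, "L_abductor")
  rec2 <- rec; rec2$channels <- rec2$channels * 37.5
  sp2 <- detect_spikes(rec2, "L_abductor")
  expect_equal(sp1$time, sp2$time)
  expect_equal(sp2$amplitude, 37.5 * sp1$amplitude, tolerance = 1e-12)
})

test_that("raising the relative threshold never adds spikes", {
  rec <- plant_spikes(seq(0.1, 0.9, by = 0.1),
                      c(1, 0.8, 0.6, 0.5, 0.4, 0.3, 0.25, 0.2, 0.15),
                      noise_sd = 0.005)
  counts <- vapply(c(0.1, 0.25, 0.5, 0.8),
                   function(th) nrow(detect_spikes(rec, "L_abductor",
                                                   rel_threshold = th)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("burst grouping matches the gap-scan oracle", {
  expect_equal(nrow(group_bursts(data.frame(time = numeric(),
                                            amplitude = numeric()))), 0)
  sp <- data.frame(time = c(1.00, 1.02, 1.04), amplitude = rep(1, 3))
  b <- group_bursts(sp, max_gap = 0.05)
  expect_equal(nrow(b), 1)
  expect_equal(c(b$onset, b$offset), c(1.00, 1.04))
  sp2 <- data.frame(time = c(1.00, 1.02, 1.20), amplitude = rep(1, 3))
  b2 <- group_bursts(sp2, max_gap = 0.05)
  expect_equal(nrow(b2), 2)
  expect_error(group_bursts(data.frame(time = c(2, 1), amplitude = c(1, 1))),
               "sorted")
  set.seed(45)
  for (rep in 1:30) {
    times <- sort(runif(sample(1:25, 1), 0, 2))
    got <- group_bursts(data.frame(time = times, amplitude = 1),
                        max_gap = 0.05)
    want <- oracle_group_bursts(times, max_gap = 0.05)
    expect_equal(got$onset, want$onset)
    expect_equal(got$offset, want$offset)
    expect_equal(got$n_spikes, want$n_spikes)
  }
})

test_that("planted bursts are recovered with exact recall/precision and 20 ms timing", {
  meta <- test_meta()
  cfg <- default_synth_config("karman_gait", meta, seed = 301)
  trial <- simulate_trial(cfg)
  got <- detect_bursts(trial$emg, band = c(100, 2250))
  truth <- trial$truth$bursts
  expect_equal(nrow(got), nrow(truth))
  for (k in seq_len(nrow(truth))) {
    g <- got[got$channel == truth$channel[k], , drop = FALSE]
    ov <- interval_ov <- pmax(0, pmin(g$offset, truth$offset[k]) -
                                pmax(g$onset, truth$onset[k]))
    j <- which.max(ov)
    expect_gt(ov[j], 0)
    expect_lt(abs(g$onset[j] - truth$onset[k]), 0.02)
    expect_lt(abs(g$offset[j] - truth$offset[k]), 0.02)
  }
})
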