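# Boundary conventions under test: "at least" thresholds (80%, 90%, 100 ms,
# 50 ms, 6 ms) are inclusive; "more than"/"less than" thresholds (1 deg run
# gate, 10 deg plausibility, 1.5 deg break distance, 1/15 deg amplitude) are
# strict.

cfg <- qc_config()                      # 500 Hz, 2 ms samples

flat_trial <- function(x0 = 0, y0 = 0, n = 475) {
  make_trial(rep(x0, n), rep(y0, n))    # -250 .. 698 ms, constant gaze
}

test_that("run gate: median pre-onset SD over 1 degree excludes the run", {
  # pooled radial SD sqrt(var(x) + var(y)): alternate +/- d about the mean
  # in x only gives SD d * sqrt(n/(n-1)) ~ d
  sd_trial <- function(d) {
    x <- c(rep(c(-d, d), length.out = 125), rep(0, 350))
    make_trial(x, rep(0, 475))
  }
  noisy <- lapply(1:5, function(i) sd_trial(2))
  expect_false(run_acceptable(noisy, cfg)$acceptable)
  quiet <- lapply(1:5, function(i) sd_trial(0.1))
  expect_true(run_acceptable(quiet, cfg)$acceptable)

  # median decides: 3 quiet trials against 2 noisy ones
  mixed <- c(lapply(1:3, function(i) sd_trial(0.2)),
             lapply(1:2, function(i) sd_trial(3)))
  r <- run_acceptable(mixed, cfg)
  expect_true(r$acceptable)
  expect_lt(r$median_sd, 0.3)

  # boundary: median SD exactly at the limit is kept (exclusion is "> 1")
  exact <- lapply(1:3, function(i) {
    tr <- flat_trial()
    pre <- which(tr$samples$t_ms < 0)
    n <- length(pre)                   # odd: pad alternating +/-1 with one 0
    tr$samples$x_deg[pre] <- c(rep(c(-1, 1), (n - 1) / 2), 0)
    tr                                 # mean 0, sample variance (n-1)/(n-1)=1
  })
  r2 <- run_acceptable(exact, cfg)
  expect_equal(r2$median_sd, 1, tolerance = 1e-10)
  expect_true(r2$acceptable)
})

test_that("trial gate: 80% acceptable is inclusive; >10 degrees and missing
           samples are unacceptable", {
  tr <- flat_trial()
  expect_true(trial_acceptable(tr, cfg))

  in_stim <- which(tr$samples$t_ms >= 0 & tr$samples$t_ms < 649)
  n <- length(in_stim)

  # exactly 80% acceptable -> acceptable
  k_bad <- round(0.2 * n)
  tr80 <- tr
  tr80$samples$x_deg[in_stim[seq_len(k_bad)]] <- NA
  expect_equal(1 - k_bad / n, 0.8, tolerance = 1e-9)
  expect_true(trial_acceptable(tr80, cfg))

  # one more bad sample -> unacceptable
  tr79 <- tr80
  tr79$samples$x_deg[in_stim[k_bad + 1]] <- NA
  expect_false(trial_acceptable(tr79, cfg))

  # implausible positions count as bad; exactly 10 degrees is still plausible
  tr10 <- tr
  tr10$samples$x_deg[in_stim] <- 10
  expect_true(trial_acceptable(tr10, cfg))
  tr11 <- tr
  tr11$samples$x_deg[in_stim[seq_len(k_bad + 1)]] <- 10.01
  expect_false(trial_acceptable(tr11, cfg))
})

test_that("drift correction is the median of per-trial pre-onset medians", {
  run <- lapply(1:5, function(i) flat_trial(0.5, 0.3))
  fix <- drift_correct(run, cfg)
  expect_equal(c(fix$x, fix$y), c(0.5, 0.3))

  # one outlier trial cannot move the median
  run2 <- c(lapply(1:4, function(i) flat_trial(0, 0)),
            list(flat_trial(5, 5)))
  fix2 <- drift_correct(run2, cfg)
  expect_equal(c(fix2$x, fix2$y), c(0, 0))

  # the 90% pre-onset gate is inclusive, and no qualifying trial errors
  tr <- flat_trial()
  pre <- which(tr$samples$t_ms < 0)
  tr$samples$x_deg[pre[seq_len(round(0.1 * length(pre)))]] <- NA
  expect_equal(drift_correct(list(tr), cfg)$n_trials, 1)
  tr$samples$x_deg[pre] <- NA
  expect_error(drift_correct(list(tr), cfg), "drift correction failed")
})

test_that("blink detection: pupil zero for at least 100 ms inside the
           stimulus window", {
  blink_trial <- function(from, len_ms) {
    tr <- flat_trial()
    z <- tr$samples$t_ms >= from & tr$samples$t_ms < from + len_ms
    tr$samples$pupil[z] <- 0
    tr
  }
  expect_equal(nrow(detect_blinks(blink_trial(200, 150), cfg)), 1)
  expect_equal(nrow(detect_blinks(blink_trial(200, 50), cfg)), 0)
  # boundary: exactly 100 ms counts
  expect_equal(nrow(detect_blinks(blink_trial(200, 100), cfg)), 1)

  # two separated zero-runs are two blinks
  tr <- flat_trial()
  z1 <- tr$samples$t_ms >= 100 & tr$samples$t_ms < 220
  z2 <- tr$samples$t_ms >= 400 & tr$samples$t_ms < 520
  tr$samples$pupil[z1 | z2] <- 0
  expect_equal(nrow(detect_blinks(tr, cfg)), 2)
})

test_that("saccade detection recovers injected events and applies the
           amplitude filters", {
  des <- small_design()
  inject <- function(amp, dur = 30) {
    sched <- data.frame(trial = 1, t_ms = 250, amplitude_deg = amp,
                        angle_deg = 0, duration_ms = dur)
    gen_gaze(des, gaze_preset(noise_sd = 0.05, saccades = sched),
             seed = 90 + round(amp * 10))$trials[[1]]
  }
  ev <- detect_saccades(inject(3), cfg)
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$amplitude_deg - 3) / 3, 0.10)

  # microsaccades (<= 1 deg) and huge jumps (>= 15 deg) are filtered out
  expect_equal(nrow(detect_saccades(inject(0.5), cfg)), 0)
  expect_equal(nrow(detect_saccades(inject(20), cfg)), 0)
})

test_that("saccade recovery rate and false alarms meet detector targets", {
  des <- list(trials = data.frame(idx = 1:100))   # gaze only needs the rows
  set.seed(33)
  amps <- runif(100, 2, 10)
  sched <- data.frame(trial = 1:100, t_ms = runif(100, 50, 500),
                      amplitude_deg = amps,
                      angle_deg = runif(100, 0, 360), duration_ms = 30)
  g <- gen_gaze(des, gaze_preset(noise_sd = 0.1, saccades = sched),
                seed = 34)
  hits <- vapply(seq_len(100), function(i) {
    ev <- detect_saccades(g$trials[[i]], cfg)
    nrow(ev) >= 1 && any(abs(ev$amplitude_deg - amps[i]) / amps[i] < 0.25)
  }, logical(1))
  expect_gte(mean(hits), 0.95)

  pure <- gen_gaze(des, gaze_preset(noise_sd = 0.1), seed = 35)
  fa <- sum(vapply(pure$trials, function(tr) nrow(detect_saccades(tr, cfg)),
                   integer(1)))
  expect_lte(fa, 1)
})

test_that("fixation breaks: sustained deviation, blinks, and vertical
           saccades each trigger a break", {
  excursion_trial <- function(dist, len_ms) {
    tr <- flat_trial()
    w <- tr$samples$t_ms >= 300 & tr$samples$t_ms < 300 + len_ms
    tr$samples$x_deg[w] <- tr$samples$x_deg[w] + dist
    tr
  }
  no_sacc <- data.frame(vertical_deg = numeric(0))

  b <- detect_fixation_break(excursion_trial(2, 120), saccades = no_sacc,
                             cfg = cfg)
  expect_true(b$broken)
  expect_equal(b$reason, "position")

  # below 100 ms is not sustained; exactly 100 ms is
  expect_false(detect_fixation_break(excursion_trial(2, 60),
                                     saccades = no_sacc, cfg = cfg)$broken)
  expect_true(detect_fixation_break(excursion_trial(2, 100),
                                    saccades = no_sacc, cfg = cfg)$broken)

  # 1.5 degrees is "more than": an excursion exactly at 1.5 does not break
  expect_false(detect_fixation_break(excursion_trial(1.5, 200),
                                     saccades = no_sacc, cfg = cfg)$broken)

  # vertical saccade component over 1.5 degrees
  sacc <- data.frame(onset_ms = 100, offset_ms = 130, amplitude_deg = 2,
                     vertical_deg = 1.8, peak_velocity = 200)
  b2 <- detect_fixation_break(flat_trial(), saccades = sacc, cfg = cfg)
  expect_true(b2$broken)
  expect_equal(b2$reason, "saccade")

  sacc$vertical_deg <- 1.4
  expect_false(detect_fixation_break(flat_trial(), saccades = sacc,
                                     cfg = cfg)$broken)
})

test_that("direct word fixation needs 50 ms cumulative time in the box", {
  bbox <- c(-1.5, 1.5, 1.0, 2.0)       # top word
  frame <- c(0, 183)
  in_box <- function(ms_total, split = 1) {
    tr <- flat_trial()
    per_visit <- ms_total / split
    for (v in seq_len(split)) {
      w <- tr$samples$t_ms >= (v - 1) * 90 &
        tr$samples$t_ms < (v - 1) * 90 + per_visit
      tr$samples$y_deg[w] <- 1.5
    }
    tr
  }
  expect_true(word_fixated(in_box(183), bbox, frame, cfg))
  expect_false(word_fixated(in_box(20), bbox, frame, cfg))
  # cumulative rule: two 30 ms visits count
  expect_true(word_fixated(in_box(60, split = 2), bbox, frame, cfg))
  # boundary: exactly 50 ms counts
  expect_true(word_fixated(in_box(50), bbox, frame, cfg))
})

test_that("supra-threshold runs must last at least 6 ms (3 samples at
           500 Hz)", {
  # deterministic baseline jitter with period 6 (a,a,a,-a,-a,-a) has
  # 5-sample central-difference velocities in {0, +/-4a}, hence a known
  # median-based SD of 4a (in step units) and ellipse radius 16a; with
  # a = 0.1125 the radius (1.5B) sits between the edge and peak velocities
  # of a one-sample position step (velocities B, 2B, 2B, B with B = 1.2),
  # whose 2-sample (4 ms) supra run is rejected, while a two-sample
  # staircase (velocities B, 3B, 4B, 3B, B) yields a 3-sample (6 ms) supra
  # run and is detected
  a <- 0.1125
  B <- 1.2
  base <- rep(c(a, a, a, -a, -a, -a), length.out = 475)
  step1 <- base
  step1[321:475] <- step1[321:475] + B
  two_step <- base
  two_step[321] <- two_step[321] + B
  two_step[322:475] <- two_step[322:475] + 2 * B
  expect_equal(nrow(detect_saccades(make_trial(step1, rep(0, 475)), cfg)), 0)
  ev <- detect_saccades(make_trial(two_step, rep(0, 475)), cfg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$amplitude_deg, 2 * B, tolerance = 0.3)
})

test_that("decisions are unchanged across sample rates on noise-free
           inputs", {
  for (rate in c(250, 500, 1000)) {
    cfg_r <- qc_config(sample_rate_hz = rate)
    per <- 1000 / rate
    n <- length(seq(-250, 698, by = per))
    tr <- make_trial(rep(0, n), rep(0, n), period = per)
    expect_true(trial_acceptable(tr, cfg_r))
    expect_equal(nrow(detect_blinks(tr, cfg_r)), 0)
    # injected 120 ms 2-degree excursion breaks fixation at every rate
    w <- tr$samples$t_ms >= 300 & tr$samples$t_ms < 420
    tr2 <- tr
    tr2$samples$x_deg[w] <- 2
    expect_true(detect_fixation_break(
      tr2, saccades = data.frame(vertical_deg = numeric(0)),
      cfg = cfg_r)$broken)
  }
})

test_that("qc_summary aggregates cleanly and flags injected breaks", {
  des <- small_design()
  clean <- gen_gaze(des, gaze_preset(noise_sd = 0.05), seed = 51)
  qc <- qc_summary(list(clean$trials), cfg)
  expect_true(qc$run_acceptable)
  expect_equal(qc$break_rate, 0)
  expect_equal(qc$vertical_saccade_rate, 0)

  exc <- data.frame(trial = 1:3, t_ms = 300, duration_ms = 150,
                    distance_deg = 2.5)
  dirty <- gen_gaze(des, gaze_preset(noise_sd = 0.05, excursions = exc),
                    seed = 52)
  qc2 <- qc_summary(list(dirty$trials), cfg)
  expect_gte(qc2$break_rate, 3 / 16 - 1e-9)

  expect_equal(nrow(qc_summary(list(), cfg)), 0)
})
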