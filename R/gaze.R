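#' @name gaze_qc
#' @title Eye-tracking quality control and event detection
#'
#' @description
#' The pipeline runs in a fixed order: (1) a run-level gate — a whole run is
#' excluded if the across-trial median SD of gaze positions in the 250 ms
#' before stimulus onset exceeds 1 degree; (2) a trial-level gate — a trial
#' is analyzable if at least 80\% of samples during the stimulus window are
#' acceptable (present and within 10 degrees of the fixation mark); (3) drift
#' correction — the corrected fixation position is the across-trial median of
#' per-trial median pre-onset positions, over trials with at least 90\%
#' acceptable pre-onset samples; (4) event detection — blinks (pupil 0 for at
#' least 100 ms), saccades (2-D velocity outside an ellipse of radii 4x the
#' median-based SD for at least 6 ms, amplitude between 1 and 15 degrees),
#' and fixation breaks (deviation > 1.5 degrees sustained for at least
#' 100 ms, any blink, or any saccade with vertical extent > 1.5 degrees).
NULL

#' QC configuration
#'
#' All thresholds as used in the analysis; durations in ms, distances in
#' degrees of visual angle.
#'
#' @param run_sd_limit run gate on the median pre-onset gaze SD (degrees).
#' @param pre_window_ms pre-onset window length.
#' @param trial_accept_frac minimum acceptable-sample fraction per trial.
#' @param max_plausible_deg samples farther than this from the fixation mark
#'   are implausible (calibration failure) and count as unacceptable.
#' @param drift_frac minimum acceptable pre-onset fraction for a trial to
#'   contribute to drift correction.
#' @param break_dist_deg,break_min_ms fixation-break distance and duration.
#' @param blink_min_ms minimum blink duration.
#' @param vel_lambda velocity threshold multiplier on the median-based SD.
#' @param sacc_min_ms minimum supra-threshold duration for a saccade.
#' @param sacc_amp_min_deg,sacc_amp_max_deg amplitude filter (strict bounds).
#' @param sacc_merge_ms supra-threshold runs separated by less than this are
#'   merged into one saccade.
#' @param word_fix_min_ms minimum cumulative in-bounding-box time to count a
#'   word as directly fixated.
#' @param sample_rate_hz gaze sample rate.
#' @export
qc_config <- function(run_sd_limit = 1.0, pre_window_ms = 250,
                      trial_accept_frac = 0.80, max_plausible_deg = 10,
                      drift_frac = 0.90, break_dist_deg = 1.5,
                      break_min_ms = 100, blink_min_ms = 100, vel_lambda = 4,
                      sacc_min_ms = 6, sacc_amp_min_deg = 1,
                      sacc_amp_max_deg = 15, sacc_merge_ms = 4,
                      word_fix_min_ms = 50, sample_rate_hz = 500) {
  cfg <- as.list(environment())
  if (any(unlist(cfg) <= 0)) stop("all QC parameters must be positive")
  if (trial_accept_frac > 1 || drift_frac > 1) stop("fractions must be <= 1")
  structure(cfg, class = "qc_config")
}

#' Construct one trial's gaze record
#'
#' @param samples data.frame with columns \code{t_ms}, \code{x_deg},
#'   \code{y_deg}, \code{pupil}; time is relative to stimulus onset at 0 and
#'   must be strictly increasing. Missing samples carry NA positions.
#' @param stim_onset_ms,stim_offset_ms stimulus window (defaults 0 and 649).
#' @param trial trial identifier.
#' @export
trial_gaze <- function(samples, stim_onset_ms = 0, stim_offset_ms = 649,
                       trial = 1L) {
  stopifnot(all(c("t_ms", "x_deg", "y_deg", "pupil") %in% names(samples)))
  if (is.unsorted(samples$t_ms, strictly = TRUE)) {
    stop("sample times must be strictly increasing")
  }
  structure(list(samples = samples, stim_onset_ms = stim_onset_ms,
                 stim_offset_ms = stim_offset_ms, trial = trial),
            class = "trial_gaze")
}

sample_period_ms <- function(cfg) 1000 / cfg$sample_rate_hz

# threshold in ms -> minimum run length in samples, rounding toward inclusion
min_samples <- function(ms, cfg) ceiling(ms / sample_period_ms(cfg) - 1e-9)

sample_ok <- function(s, cfg) {
  !is.na(s$x_deg) & !is.na(s$y_deg) &
    sqrt(s$x_deg^2 + s$y_deg^2) <= cfg$max_plausible_deg
}

pre_window <- function(trial, cfg) {
  s <- trial$samples
  s[s$t_ms >= trial$stim_onset_ms - cfg$pre_window_ms &
      s$t_ms < trial$stim_onset_ms, , drop = FALSE]
}

stim_window <- function(trial) {
  s <- trial$samples
  s[s$t_ms >= trial$stim_onset_ms & s$t_ms < trial$stim_offset_ms, ,
    drop = FALSE]
}

# pooled 2-D radial SD: sqrt(var(x) + var(y)) on present samples
gaze_sd2 <- function(s) {
  ok <- !is.na(s$x_deg) & !is.na(s$y_deg)
  if (sum(ok) < 2) return(NA_real_)
  sqrt(stats::var(s$x_deg[ok]) + stats::var(s$y_deg[ok]))
}

#' Run-level acceptability gate
#'
#' A run is excluded if the across-trial median of the pre-onset 2-D gaze SD
#' exceeds \code{run_sd_limit} (pooled radial SD, sqrt(var(x) + var(y))).
#'
#' @param run a list of \code{\link{trial_gaze}} objects.
#' @param cfg a \code{\link{qc_config}}.
#' @return list(acceptable, median_sd, trial_sds).
#' @export
run_acceptable <- function(run, cfg = qc_config()) {
  sds <- vapply(run, function(tr) gaze_sd2(pre_window(tr, cfg)), numeric(1))
  if (all(is.na(sds))) stop("no pre-onset data in any trial")
  med <- stats::median(sds, na.rm = TRUE)
  list(acceptable = med <= cfg$run_sd_limit, median_sd = med, trial_sds = sds)
}

#' Trial-level acceptability gate
#'
#' Acceptable iff at least \code{trial_accept_frac} of samples during the
#' stimulus window are present and within \code{max_plausible_deg} of the
#' fixation mark (the 80\% bound is inclusive).
#'
#' @param trial a \code{trial_gaze}.
#' @param cfg a \code{\link{qc_config}}.
#' @export
trial_acceptable <- function(trial, cfg = qc_config()) {
  s <- stim_window(trial)
  if (nrow(s) == 0) stop("empty stimulus window")
  mean(sample_ok(s, cfg)) >= cfg$trial_accept_frac
}

#' Drift correction: corrected fixation position for a run
#'
#' Per qualifying trial (>= 90\% acceptable pre-onset samples), the median
#' (x, y) over the pre-onset window; the corrected fixation position is the
#' coordinate-wise across-trial median of those medians.
#'
#' @inheritParams run_acceptable
#' @return list(x, y, n_trials).
#' @export
drift_correct <- function(run, cfg = qc_config()) {
  meds <- lapply(run, function(tr) {
    s <- pre_window(tr, cfg)
    if (nrow(s) == 0) return(NULL)
    ok <- sample_ok(s, cfg)
    if (mean(ok) < cfg$drift_frac) return(NULL)
    c(stats::median(s$x_deg[ok]), stats::median(s$y_deg[ok]))
  })
  meds <- do.call(rbind, meds)
  if (is.null(meds) || nrow(meds) == 0) {
    stop("drift correction failed: no trial has >= 90% acceptable ",
         "pre-onset samples")
  }
  list(x = stats::median(meds[, 1]), y = stats::median(meds[, 2]),
       n_trials = nrow(meds))
}

# maximal runs of TRUE in a logical vector -> start/end indices
true_runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & !is.na(r$values)
  data.frame(start = starts[keep], end = ends[keep])
}

#' Detect blinks in one trial
#'
#' Maximal runs of pupil = 0 lasting at least \code{blink_min_ms}, clipped to
#' the stimulus window.
#'
#' @inheritParams trial_acceptable
#' @return data.frame(onset_ms, offset_ms, duration_ms); zero rows if none.
#' @export
detect_blinks <- function(trial, cfg = qc_config()) {
  s <- trial$samples
  zero <- !is.na(s$pupil) & s$pupil == 0
  runs <- true_runs(zero)
  per <- sample_period_ms(cfg)
  out <- lapply(seq_len(nrow(runs)), function(i) {
    t0 <- max(s$t_ms[runs$start[i]], trial$stim_onset_ms)
    t1 <- min(s$t_ms[runs$end[i]] + per, trial$stim_offset_ms)
    if (t1 <= t0) return(NULL)
    n_in <- sum(s$t_ms >= t0 & s$t_ms < t1 & zero)
    if (n_in < min_samples(cfg$blink_min_ms, cfg)) return(NULL)
    data.frame(onset_ms = t0, offset_ms = t1, duration_ms = n_in * per)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      duration_ms = numeric(0))
  }
  out
}

# 5-sample moving-window central-difference velocity (deg/s)
ek_velocity <- function(p, dt_s) {
  n <- length(p)
  v <- rep(NA_real_, n)
  if (n >= 5) {
    i <- 3:(n - 2)
    v[i] <- (p[i + 2] + p[i + 1] - p[i - 1] - p[i - 2]) / (6 * dt_s)
  }
  v
}

# median-based SD: sqrt(median(v^2) - median(v)^2), floored
median_sd <- function(v, eps = 1e-6) {
  v <- v[!is.na(v)]
  sqrt(max(stats::median(v^2) - stats::median(v)^2, eps^2))
}

#' Detect saccades in one trial
#'
#' Velocity-threshold detection: 2-D gaze velocities (5-sample moving-window
#' central difference) are compared against an ellipse with radii
#' \code{vel_lambda} times the horizontal and vertical median-based SDs,
#' computed over the interval from 250 ms before stimulus onset to stimulus
#' offset. Candidate events are maximal supra-threshold runs lasting at least
#' \code{sacc_min_ms} (runs separated by less than \code{sacc_merge_ms} are
#' merged); events are kept iff their 2-D amplitude is strictly between
#' \code{sacc_amp_min_deg} and \code{sacc_amp_max_deg}.
#'
#' @inheritParams trial_acceptable
#' @return data.frame(onset_ms, offset_ms, amplitude_deg, vertical_deg,
#'   peak_velocity); attribute \code{"flagged"} is TRUE when the velocity
#'   variance was degenerate and no detection was attempted.
#' @export
detect_saccades <- function(trial, cfg = qc_config()) {
  s <- trial$samples
  win <- s$t_ms >= trial$stim_onset_ms - cfg$pre_window_ms &
    s$t_ms < trial$stim_offset_ms
  s <- s[win, , drop = FALSE]
  empty <- data.frame(onset_ms = numeric(0), offset_ms = numeric(0),
                      amplitude_deg = numeric(0), vertical_deg = numeric(0),
                      peak_velocity = numeric(0))
  if (nrow(s) < 5) stop("need at least 5 samples for velocity estimation")
  dt_s <- sample_period_ms(cfg) / 1000
  vx <- ek_velocity(s$x_deg, dt_s)
  vy <- ek_velocity(s$y_deg, dt_s)
  rx <- cfg$vel_lambda * median_sd(vx)
  ry <- cfg$vel_lambda * median_sd(vy)
  if (rx <= cfg$vel_lambda * 1e-6 && ry <= cfg$vel_lambda * 1e-6) {
    attr(empty, "flagged") <- TRUE
    return(empty)
  }
  crit <- (vx / rx)^2 + (vy / ry)^2 > 1
  crit[is.na(crit)] <- FALSE
  runs <- true_runs(crit)
  if (nrow(runs) > 1) {
    # merge runs separated by < sacc_merge_ms
    per <- sample_period_ms(cfg)
    merged <- runs[1, , drop = FALSE]
    for (i in 2:nrow(runs)) {
      gap <- (runs$start[i] - merged$end[nrow(merged)] - 1) * per
      if (gap < cfg$sacc_merge_ms) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
    runs <- merged
  }
  per <- sample_period_ms(cfg)
  out <- lapply(seq_len(nrow(runs)), function(i) {
    i0 <- runs$start[i]; i1 <- runs$end[i]
    if (i1 - i0 + 1 < min_samples(cfg$sacc_min_ms, cfg)) return(NULL)
    amp <- sqrt((s$x_deg[i1] - s$x_deg[i0])^2 + (s$y_deg[i1] - s$y_deg[i0])^2)
    if (!(amp > cfg$sacc_amp_min_deg && amp < cfg$sacc_amp_max_deg)) {
      return(NULL)
    }
    data.frame(onset_ms = s$t_ms[i0], offset_ms = s$t_ms[i1] + per,
               amplitude_deg = amp,
               vertical_deg = abs(s$y_deg[i1] - s$y_deg[i0]),
               peak_velocity = max(sqrt(vx[i0:i1]^2 + vy[i0:i1]^2),
                                   na.rm = TRUE))
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- empty
  attr(out, "flagged") <- FALSE
  out
}

#' Detect a fixation break in one trial
#'
#' A trial is a fixation break if (a) gaze deviates more than
#' \code{break_dist_deg} from the corrected fixation position for at least
#' \code{break_min_ms} during the stimulus window, (b) a blink occurred, or
#' (c) a saccade's vertical extent exceeds \code{break_dist_deg}.
#'
#' @inheritParams trial_acceptable
#' @param fix_pos list(x, y): the corrected fixation position (from
#'   \code{\link{drift_correct}}), or c(0, 0) when correction failed.
#' @param saccades,blinks optional precomputed event tables; computed from
#'   the trial when NULL.
#' @return list(broken, reason) with reason one of "position", "blink",
#'   "saccade" or NA.
#' @export
detect_fixation_break <- function(trial, fix_pos = list(x = 0, y = 0),
                                  saccades = NULL, blinks = NULL,
                                  cfg = qc_config()) {
  if (is.null(blinks)) blinks <- detect_blinks(trial, cfg)
  if (nrow(blinks) > 0) return(list(broken = TRUE, reason = "blink"))
  if (is.null(saccades)) saccades <- detect_saccades(trial, cfg)
  if (nrow(saccades) > 0 &&
      any(saccades$vertical_deg > cfg$break_dist_deg)) {
    return(list(broken = TRUE, reason = "saccade"))
  }
  s <- stim_window(trial)
  d <- sqrt((s$x_deg - fix_pos$x)^2 + (s$y_deg - fix_pos$y)^2)
  far <- !is.na(d) & d > cfg$break_dist_deg
  runs <- true_runs(far)
  if (nrow(runs) > 0 &&
      any(runs$end - runs$start + 1 >= min_samples(cfg$break_min_ms, cfg))) {
    return(list(broken = TRUE, reason = "position"))
  }
  list(broken = FALSE, reason = NA_character_)
}

#' Was a word fixated directly?
#'
#' TRUE iff the cumulative time with gaze inside the word's bounding box
#' during the word's frame is at least \code{word_fix_min_ms} (visits
#' accumulate).
#'
#' @inheritParams trial_acceptable
#' @param word_bbox numeric vector (xmin, xmax, ymin, ymax) in degrees.
#' @param frame_interval numeric (t0, t1) ms: the frame during which the word
#'   was on screen.
#' @export
word_fixated <- function(trial, word_bbox, frame_interval, cfg = qc_config()) {
  s <- trial$samples
  s <- s[s$t_ms >= frame_interval[1] & s$t_ms < frame_interval[2], ,
         drop = FALSE]
  inside <- !is.na(s$x_deg) & !is.na(s$y_deg) &
    s$x_deg >= word_bbox[1] & s$x_deg <= word_bbox[2] &
    s$y_deg >= word_bbox[3] & s$y_deg <= word_bbox[4]
  sum(inside) >= min_samples(cfg$word_fix_min_ms, cfg)
}

#' QC summary over runs
#'
#' Applies the full pipeline in its fixed order (run gate, trial gate, drift
#' correction, event detection) and tabulates rates per run.
#'
#' @param runs a list of runs, each a list of \code{trial_gaze} objects.
#' @param cfg a \code{\link{qc_config}}.
#' @return data.frame with one row per run: run acceptability, acceptable
#'   trial fraction, fixation-break rate, vertical-saccade rate, and whether
#'   drift correction succeeded.
#' @export
qc_summary <- function(runs, cfg = qc_config()) {
  if (length(runs) == 0) {
    return(data.frame(run = integer(0), run_acceptable = logical(0),
                      trial_accept_frac = numeric(0), break_rate = numeric(0),
                      vertical_saccade_rate = numeric(0),
                      drift_corrected = logical(0)))
  }
  rows <- lapply(seq_along(runs), function(ri) {
    run <- runs[[ri]]
    ra <- run_acceptable(run, cfg)$acceptable
    if (!ra) {
      return(data.frame(run = ri, run_acceptable = FALSE,
                        trial_accept_frac = NA_real_, break_rate = NA_real_,
                        vertical_saccade_rate = NA_real_,
                        drift_corrected = NA))
    }
    ok <- vapply(run, trial_acceptable, logical(1), cfg = cfg)
    fix <- tryCatch(drift_correct(run, cfg), error = function(e) NULL)
    corrected <- !is.null(fix)
    if (!corrected) fix <- list(x = 0, y = 0)
    kept <- run[ok]
    brk <- vs <- logical(length(kept))
    for (i in seq_along(kept)) {
      sac <- detect_saccades(kept[[i]], cfg)
      b <- detect_fixation_break(kept[[i]], fix, saccades = sac, cfg = cfg)
      brk[i] <- b$broken
      vs[i] <- nrow(sac) > 0 && any(sac$vertical_deg > cfg$break_dist_deg)
    }
    data.frame(run = ri, run_acceptable = TRUE,
               trial_accept_frac = mean(ok),
               break_rate = if (length(kept)) mean(brk) else NA_real_,
               vertical_saccade_rate = if (length(kept)) mean(vs) else NA_real_,
               drift_corrected = corrected)
  })
  do.call(rbind, rows)
}
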