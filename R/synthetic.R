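#' @name synthetic_data
#' @title Synthetic single-trial data with known ground truth
#'
#' @description
#' Generators for every input the analysis pipeline consumes: single-trial
#' BOLD betas with the full mixed-model decomposition (subject random
#' intercepts and slopes, stimulus-item effects, residual noise), behavioral
#' responses with condition-dependent accuracy and lognormal response times,
#' and gaze traces with injected blinks, saccades and fixation excursions
#' recorded in a ground-truth table for detector scoring. Everything is
#' deterministic under its seed.
NULL

#' Beta-generator presets for text-selective ROIs
#'
#' Named presets for the three left-hemisphere text-selective regions. The
#' number-of-words slope and the sequential-vs-simultaneous (suppression)
#' difference are the empirical single-trial mixed-model estimates for each
#' region; the variance components (subject slope SD 0.05, item SD 0.05,
#' residual SD 0.4 percent signal change) are defaults chosen to reproduce
#' standard errors of realistic magnitude and are configurable.
#'
#' @param roi one of "pots_words", "mots_words", "mfus_words", or "custom".
#' @param n_subjects number of simulated subjects.
#' @param intercept baseline (zero-word) response, percent signal change.
#' @param slope number-of-words fixed-effect slope (psc per word); defaults
#'   to the preset ROI's estimate.
#' @param suppression 2seq minus 2sim difference (psc).
#' @param freq_effect_seq,freq_effect_sim low-minus-high frequency-pair
#'   difference in the sequential and simultaneous conditions (psc).
#' @param subject_int_sd,subject_slope_sd,item_sd,resid_sd variance
#'   components (SDs, psc).
#' @param suppression_subject_sd SD of the subject-level suppression effect
#'   (the generative counterpart of the condition-by-subject random slope;
#'   0.05 psc matches the across-subject spread implied by the empirical
#'   suppression standard errors).
#' @param trials_per_condition trials per condition per subject.
#' @return list of class \code{beta_preset}.
#' @export
beta_preset <- function(roi = c("pots_words", "mots_words", "mfus_words",
                                "custom"),
                        n_subjects = 20, intercept = 0.1, slope = NULL,
                        suppression = NULL, freq_effect_seq = 0.05,
                        freq_effect_sim = 0.01, subject_int_sd = 0.1,
                        subject_slope_sd = 0.05, item_sd = 0.05,
                        resid_sd = 0.4, suppression_subject_sd = 0.05,
                        trials_per_condition = 128) {
  roi <- match.arg(roi)
  defaults <- list(
    pots_words = list(slope = 0.116, suppression = 0.014),
    mots_words = list(slope = 0.100, suppression = -0.005),
    mfus_words = list(slope = 0.109, suppression = 0.008),
    custom = list(slope = 0.1, suppression = 0)
  )[[roi]]
  if (is.null(slope)) slope <- defaults$slope
  if (is.null(suppression)) suppression <- defaults$suppression
  sds <- c(subject_int_sd, subject_slope_sd, item_sd, resid_sd)
  if (any(sds < 0)) stop("variance-component SDs must be non-negative")
  structure(list(roi = roi, n_subjects = n_subjects, intercept = intercept,
                 slope = slope, suppression = suppression,
                 freq_effect_seq = freq_effect_seq,
                 freq_effect_sim = freq_effect_sim,
                 subject_int_sd = subject_int_sd,
                 subject_slope_sd = subject_slope_sd, item_sd = item_sd,
                 resid_sd = resid_sd,
                 suppression_subject_sd = suppression_subject_sd,
                 trials_per_condition = trials_per_condition),
            class = "beta_preset")
}

# frequency bin of a trial: LOW/HIGH when all legible words fall on one side
# of the lexicon's median Zipf frequency, NA otherwise
trial_freq_bin <- function(design, lexicon) {
  tr <- design$trials
  med <- stats::median(lexicon$zipf)
  z1 <- lexicon$zipf[match(tr$word1_id, lexicon$word_id)]
  z2 <- lexicon$zipf[match(tr$word2_id, lexicon$word_id)]
  bin1 <- ifelse(is.na(z1), NA, ifelse(z1 < med, "LOW", "HIGH"))
  bin2 <- ifelse(is.na(z2), NA, ifelse(z2 < med, "LOW", "HIGH"))
  out <- rep(NA_character_, nrow(tr))
  one <- tr$condition == "ONE"
  out[one] <- bin1[one]
  two <- tr$condition %in% c("TWO_SEQ", "TWO_SIM")
  same <- two & !is.na(bin1) & !is.na(bin2) & bin1 == bin2
  out[same] <- bin1[same]
  out
}

#' Generate synthetic single-trial betas
#'
#' Each beta is intercept + subject intercept + item effect +
#' (slope + subject slope) x W + condition terms + frequency term +
#' residual, where W is the number of words (TWO_SIM also has W = 2 but
#' receives the suppression offset), items are shared across subjects via
#' the design's stimulus ids, and the frequency term is +/- half the
#' condition's frequency effect for LOW/HIGH pairs.
#'
#' @param preset a \code{\link{beta_preset}}.
#' @param design a \code{session_design} shared by all subjects.
#' @param lexicon the lexicon (for stimulus ids and frequency bins).
#' @param seed integer seed.
#' @return data.frame: subject, roi, trial, condition, W, freq_bin, stim_id,
#'   beta. Attribute \code{"truth"} carries the generating parameters.
#' @export
gen_betas <- function(preset, design, lexicon, seed = 1) {
  tr <- design$trials
  n_tr <- nrow(tr)
  stim_id <- code_stimulus_ids(design, lexicon, seed = seed)
  freq_bin <- trial_freq_bin(design, lexicon)
  W <- as.numeric(n_words_for(tr$condition))
  is_sim <- tr$condition == "TWO_SIM"
  freq_term <- ifelse(is.na(freq_bin) | W < 2, 0,
                      ifelse(freq_bin == "LOW", 0.5, -0.5) *
                        ifelse(is_sim, preset$freq_effect_sim,
                               preset$freq_effect_seq))

  rng <- local_rng(seed)
  on.exit(rng())
  items <- unique(stim_id)
  item_eff <- stats::setNames(stats::rnorm(length(items), 0, preset$item_sd),
                              items)
  rows <- vector("list", preset$n_subjects)
  for (s in seq_len(preset$n_subjects)) {
    b0 <- stats::rnorm(1, 0, preset$subject_int_sd)
    b1 <- stats::rnorm(1, 0, preset$subject_slope_sd)
    b2 <- stats::rnorm(1, 0, preset$suppression_subject_sd)
    mu <- preset$intercept + b0 + item_eff[stim_id] +
      (preset$slope + b1) * W -
      (preset$suppression + b2) * is_sim + freq_term
    rows[[s]] <- data.frame(
      subject = sprintf("s%02d", s), roi = preset$roi,
      trial = seq_len(n_tr), condition = tr$condition, W = W,
      freq_bin = freq_bin, stim_id = stim_id,
      beta = mu + stats::rnorm(n_tr, 0, preset$resid_sd),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- preset
  out
}

#' Behavior-generator preset
#'
#' @param accuracy named per-condition probabilities of a correct report.
#' @param rt_meanlog,rt_sdlog lognormal RT parameters per condition (RT in ms
#'   from the critical-frame onset; stored internally relative to
#'   final-frame offset).
#' @param miss_one_prob probability of reporting "1" (vs "0") on an incorrect
#'   two-word simultaneous trial.
#' @param no_response_rate probability of failing to respond in time.
#' @export
behavior_preset <- function(accuracy = c(ZERO = 0.95, ONE = 0.89,
                                         TWO_SEQ = 0.91, TWO_SIM = 0.86),
                            rt_meanlog = log(c(ZERO = 850, ONE = 1000,
                                               TWO_SEQ = 950,
                                               TWO_SIM = 1050)),
                            rt_sdlog = 0.25, miss_one_prob = 0.94,
                            no_response_rate = 0.013) {
  if (any(accuracy < 0 | accuracy > 1)) stop("accuracies must lie in [0, 1]")
  structure(list(accuracy = accuracy, rt_meanlog = rt_meanlog,
                 rt_sdlog = rt_sdlog, miss_one_prob = miss_one_prob,
                 no_response_rate = no_response_rate),
            class = "behavior_preset")
}

#' Generate synthetic behavioral responses
#'
#' Per-trial responses and response times under the preset's
#' condition-dependent accuracy. Errors on two-word simultaneous trials
#' report "1" with probability \code{miss_one_prob} (a missed second word),
#' otherwise "0"; errors elsewhere report an adjacent count. If
#' \code{model_linked} is given, simultaneous-trial accuracy is scaled by
#' how far the model lets the second word rise toward its threshold, so
#' TWO_SIM accuracy never exceeds TWO_SEQ accuracy when word 2 is left
#' unfinished.
#'
#' @param preset a \code{\link{behavior_preset}}.
#' @param design a \code{session_design}.
#' @param seed integer seed.
#' @param model_linked optional list(params = accumulator_params, model =
#'   "SERIAL" or "PARALLEL_LIMITED").
#' @param subject subject label.
#' @return responses data.frame: subject, trial, response, resp_ms (ms from
#'   final-frame offset).
#' @export
gen_behavior <- function(preset, design, seed = 1, model_linked = NULL,
                         subject = "s01") {
  tr <- design$trials
  n <- nrow(tr)
  acc <- preset$accuracy[tr$condition]
  if (!is.null(model_linked)) {
    fn <- switch(toupper(model_linked$model),
                 SERIAL = simulate_serial,
                 PARALLEL_LIMITED = simulate_parallel_limited,
                 stop("model_linked$model must be SERIAL or PARALLEL_LIMITED"))
    completion <- mean(vapply(c("LOW", "HIGH"), function(fb) {
      p <- fn(model_linked$params, "TWO_SIM", fb)
      th <- threshold_for(model_linked$params, fb)
      a2 <- p$word_areas[2]
      full <- th^2 / (2 * model_linked$params$slope)
      min(1, a2 / full)
    }, numeric(1)))
    sim <- tr$condition == "TWO_SIM"
    acc[sim] <- preset$accuracy[["TWO_SEQ"]] * (0.5 + 0.5 * completion)
  }
  rng <- local_rng(seed)
  on.exit(rng())
  nw <- as.integer(n_words_for(tr$condition))
  correct <- stats::runif(n) < acc
  response <- integer(n)
  response[correct] <- nw[correct]
  wrong <- which(!correct)
  for (i in wrong) {
    if (tr$condition[i] == "TWO_SIM") {
      response[i] <- if (stats::runif(1) < preset$miss_one_prob) 1L else 0L
    } else {
      opts <- intersect(c(nw[i] - 1L, nw[i] + 1L), 0:2)
      response[i] <- if (length(opts) == 1) opts else sample(opts, 1)
    }
  }
  rt_frame2 <- stats::rlnorm(n, preset$rt_meanlog[tr$condition],
                             preset$rt_sdlog)
  # convert from frame-2 onset to final-frame-offset reference
  resp_ms <- pmax(rt_frame2 - (STIM_MS - frame_onset_ms(2)), 1)
  none <- stats::runif(n) < preset$no_response_rate
  data.frame(subject = subject, trial = seq_len(n),
             response = ifelse(none, NA_integer_, response),
             resp_ms = ifelse(none, NA_real_, resp_ms),
             stringsAsFactors = FALSE)
}

#' Gaze-generator preset
#'
#' @param noise_sd per-axis fixation noise SD in degrees (white noise).
#' @param drift constant (x, y) offset of true fixation from the mark.
#' @param sample_rate_hz sample rate.
#' @param noisy_run if TRUE, noise_sd is inflated to \code{noisy_sd} so the
#'   run fails the 1-degree median-SD gate by construction.
#' @param noisy_sd the inflated SD for noisy runs.
#' @param saccades,blinks,excursions optional event schedules: data.frames
#'   with a \code{trial} column plus, respectively, (t_ms, amplitude_deg,
#'   angle_deg, duration_ms), (t_ms, duration_ms), and (t_ms, duration_ms,
#'   distance_deg).
#' @export
gaze_preset <- function(noise_sd = 0.05, drift = c(0, 0),
                        sample_rate_hz = 500, noisy_run = FALSE,
                        noisy_sd = 2, saccades = NULL, blinks = NULL,
                        excursions = NULL) {
  structure(list(noise_sd = if (noisy_run) noisy_sd else noise_sd,
                 drift = drift, sample_rate_hz = sample_rate_hz,
                 noisy_run = noisy_run, saccades = saccades, blinks = blinks,
                 excursions = excursions),
            class = "gaze_preset")
}

raised_cosine_step <- function(t, t0, duration, amplitude) {
  u <- (t - t0) / duration
  ifelse(u <= 0, 0, ifelse(u >= 1, amplitude,
                           amplitude * (1 - cos(pi * u)) / 2))
}

#' Generate synthetic gaze traces with ground-truth events
#'
#' One \code{\link{trial_gaze}} per design trial: Gaussian fixation noise
#' around the (possibly drifted) fixation position from 300 ms before
#' stimulus onset to 50 ms after offset, with scheduled saccades (smooth
#' raised-cosine displacement profiles), blinks (pupil 0, positions missing)
#' and fixation excursions injected and recorded in a truth table.
#'
#' @param design a \code{session_design} (or any object whose \code{trials}
#'   has one row per trial).
#' @param preset a \code{\link{gaze_preset}}.
#' @param seed integer seed.
#' @return list(trials = list of \code{trial_gaze}, truth = list of the
#'   injected event schedules).
#' @export
gen_gaze <- function(design, preset = gaze_preset(), seed = 1) {
  n_tr <- nrow(design$trials)
  per <- 1000 / preset$sample_rate_hz
  t_grid <- seq(-300, STIM_MS + 50, by = per)
  check_sched <- function(sc, what) {
    if (is.null(sc)) return(invisible())
    if (any(sc$trial < 1 | sc$trial > n_tr) ||
        any(sc$t_ms < min(t_grid) | sc$t_ms + sc$duration_ms > max(t_grid))) {
      stop(what, " schedule outside trial bounds")
    }
  }
  check_sched(preset$saccades, "saccade")
  check_sched(preset$blinks, "blink")
  check_sched(preset$excursions, "excursion")

  rng <- local_rng(seed)
  on.exit(rng())
  trials <- vector("list", n_tr)
  for (k in seq_len(n_tr)) {
    x <- preset$drift[1] + stats::rnorm(length(t_grid), 0, preset$noise_sd)
    y <- preset$drift[2] + stats::rnorm(length(t_grid), 0, preset$noise_sd)
    pupil <- rep(1000, length(t_grid))
    sc <- preset$saccades
    if (!is.null(sc)) {
      for (i in which(sc$trial == k)) {
        dx <- cos(sc$angle_deg[i] * pi / 180) * sc$amplitude_deg[i]
        dy <- sin(sc$angle_deg[i] * pi / 180) * sc$amplitude_deg[i]
        x <- x + raised_cosine_step(t_grid, sc$t_ms[i], sc$duration_ms[i], dx)
        y <- y + raised_cosine_step(t_grid, sc$t_ms[i], sc$duration_ms[i], dy)
      }
    }
    ex <- preset$excursions
    if (!is.null(ex)) {
      for (i in which(ex$trial == k)) {
        inwin <- t_grid >= ex$t_ms[i] & t_grid < ex$t_ms[i] + ex$duration_ms[i]
        x[inwin] <- x[inwin] + ex$distance_deg[i]
      }
    }
    bl <- preset$blinks
    if (!is.null(bl)) {
      for (i in which(bl$trial == k)) {
        inwin <- t_grid >= bl$t_ms[i] & t_grid < bl$t_ms[i] + bl$duration_ms[i]
        pupil[inwin] <- 0
        x[inwin] <- NA_real_
        y[inwin] <- NA_real_
      }
    }
    trials[[k]] <- trial_gaze(
      data.frame(t_ms = t_grid, x_deg = x, y_deg = y, pupil = pupil),
      stim_onset_ms = 0, stim_offset_ms = STIM_MS, trial = k)
  }
  list(trials = trials,
       truth = list(saccades = preset$saccades, blinks = preset$blinks,
                    excursions = preset$excursions))
}
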