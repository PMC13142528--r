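#' @name accumulator
#' @title Evidence-accumulation models of multi-word processing
#'
#' @description
#' A word's neuronal activation rises linearly over time (slope \code{slope}
#' evidence/ms) until it reaches a recognition threshold, or until the next
#' stimulus frame interrupts processing. Low-frequency words carry a higher
#' threshold than high-frequency words, so they are processed longer and
#' accumulate more total activation — the lexical frequency effect. The
#' predicted BOLD response for a trial is the integral (area) of activation
#' over time summed across the words processed on that trial. Four model
#' variants differ only in how two simultaneously presented words share the
#' processing window: strictly serial, limited-capacity parallel (slope
#' divided by an interference factor), unlimited-capacity parallel, and a
#' hybrid parallel-then-serial scheme.
NULL

#' Accumulator model parameters
#'
#' @param slope evidence accumulated per ms (> 0).
#' @param theta_low recognition threshold for low-frequency words (evidence
#'   units); must be >= \code{theta_high}.
#' @param theta_high recognition threshold for high-frequency words.
#' @param kappa interference factor (>= 1) dividing the slope on simultaneous
#'   trials in the limited-capacity parallel model. The default,
#'   (slope x window / theta_high)^2 = 5.43, keeps the reduced slope below
#'   even the high-frequency threshold within the window (so the
#'   simultaneous lexical frequency effect is exactly zero) while making the
#'   simultaneous totals match the sequential high-frequency total — the two
#'   signature patterns of this model.
#' @param window_ms per-frame processing window; defaults to the stimulus
#'   onset asynchrony, 183 ms frame + 50 ms ISI = 233 ms, because the next
#'   frame (or the frame-3 post-mask) interrupts processing.
#' @param reset_on_threshold if TRUE (default) activation returns to 0 once
#'   the threshold is reached, so a fully processed word contributes area
#'   theta^2 / (2 slope); if FALSE activation plateaus at threshold until the
#'   window ends.
#' @return a list of class \code{accumulator_params}.
#' @export
accumulator_params <- function(slope = 0.01, theta_low = 1.6, theta_high = 1.0,
                               kappa = 5.43, window_ms = 233,
                               reset_on_threshold = TRUE) {
  if (slope <= 0) stop("slope must be positive")
  if (theta_high <= 0 || theta_low < theta_high) {
    stop("need theta_low >= theta_high > 0")
  }
  if (kappa < 1) stop("kappa must be >= 1")
  if (window_ms <= 0) stop("window_ms must be positive")
  structure(list(slope = slope, theta_low = theta_low, theta_high = theta_high,
                 kappa = kappa, window_ms = window_ms,
                 reset_on_threshold = reset_on_threshold),
            class = "accumulator_params")
}

threshold_for <- function(params, freq_bin) {
  switch(toupper(freq_bin), LOW = params$theta_low, HIGH = params$theta_high,
         stop("freq_bin must be LOW or HIGH"))
}

#' Accumulate evidence for one word over a processing interval
#'
#' Linear rise at \code{slope} from \code{t_start}; if the threshold is
#' reached before \code{t_end}, activation either resets to 0 (default) or
#' plateaus at the threshold. Returns the activation trace (piecewise linear,
#' with every breakpoint on the grid so trapezoid integration of the trace is
#' exact) and the closed-form area under it.
#'
#' @param slope evidence per ms (> 0).
#' @param threshold evidence threshold (> 0).
#' @param t_start,t_end interval bounds in ms (\code{t_end >= t_start}).
#' @param reset_on_threshold see \code{\link{accumulator_params}}.
#' @param dt trace grid step in ms.
#' @return list of class \code{activation_trace}: \code{trace} (data.frame
#'   \code{t}, \code{activation}), \code{area}, \code{threshold_crossed},
#'   \code{crossing_time_ms}.
#' @examples
#' accumulate(0.01, 1, 0, 233)$area   # crossing at 100 ms, area 50
#' @export
accumulate <- function(slope, threshold, t_start, t_end,
                       reset_on_threshold = TRUE, dt = 0.1) {
  if (slope <= 0 || threshold <= 0) stop("slope and threshold must be positive")
  if (t_end < t_start) stop("t_end must be >= t_start")
  T_ <- t_end - t_start
  t_cross <- threshold / slope
  crossed <- t_cross <= T_

  if (T_ == 0) {
    area <- 0
  } else if (!crossed) {
    area <- slope * T_^2 / 2
  } else if (reset_on_threshold) {
    area <- threshold^2 / (2 * slope)
  } else {
    area <- threshold^2 / (2 * slope) + threshold * (T_ - t_cross)
  }

  grid <- unique(sort(c(seq(t_start, t_end, by = dt), t_end,
                        if (crossed) t_start + t_cross)))
  act <- pmin(slope * (grid - t_start), threshold)
  if (crossed && reset_on_threshold) {
    act[grid > t_start + t_cross] <- 0
    # duplicate the crossing point so the drop to 0 is a zero-width segment
    # and trapezoid integration of the trace stays exact
    ci <- which(grid == t_start + t_cross)
    grid <- append(grid, grid[ci], after = ci)
    act <- append(act, 0, after = ci)
  }
  structure(list(trace = data.frame(t = grid, activation = act),
                 area = area, threshold_crossed = crossed,
                 crossing_time_ms = if (crossed) t_start + t_cross else NA_real_),
            class = "activation_trace")
}

new_prediction <- function(word_areas, condition, freq_bin, model) {
  structure(list(word_areas = word_areas, total_area = sum(word_areas),
                 condition = condition, freq_bin = freq_bin,
                 model = model),
            class = "trial_prediction")
}

#' @export
print.trial_prediction <- function(x, ...) {
  cat(sprintf("%s | %s, %s: total area %.3f (words: %s)\n", x$model,
              x$condition, x$freq_bin, x$total_area,
              paste(sprintf("%.3f", x$word_areas), collapse = ", ")))
  invisible(x)
}

check_condition <- function(condition) {
  condition <- toupper(condition)
  if (!condition %in% CONDITIONS) stop("unknown condition: ", condition)
  condition
}

#' Serial model trial prediction
#'
#' One word is processed at a time. On sequential trials each word gets its
#' own full frame window. On simultaneous trials the second word begins only
#' when the first reaches threshold, and is truncated at the window end; if
#' the first word never finishes, the second is never processed.
#'
#' @param params \code{\link{accumulator_params}}.
#' @param condition one of ZERO, ONE, TWO_SEQ, TWO_SIM.
#' @param freq_bin "LOW" or "HIGH" (both words of a pair share a bin).
#' @return a \code{trial_prediction}.
#' @export
simulate_serial <- function(params, condition, freq_bin = "HIGH") {
  condition <- check_condition(condition)
  th <- threshold_for(params, freq_bin)
  W <- params$window_ms
  s <- params$slope
  r <- params$reset_on_threshold
  one <- function() accumulate(s, th, 0, W, r)
  areas <- switch(condition,
    ZERO = numeric(0),
    ONE = one()$area,
    TWO_SEQ = c(one()$area, one()$area),
    TWO_SIM = {
      a1 <- one()
      a2 <- if (a1$threshold_crossed) {
        accumulate(s, th, a1$crossing_time_ms, W, r)$area
      } else 0
      c(a1$area, a2)
    })
  new_prediction(areas, condition, freq_bin, "SERIAL")
}

#' Limited-capacity parallel model trial prediction
#'
#' Sequential trials are identical to the serial model. On simultaneous
#' trials both words accumulate for the full window but at slope
#' \code{slope / kappa}: mutual interference slows evidence accumulation. If
#' the reduced slope cannot reach either threshold within the window, the
#' areas are threshold-independent and the lexical frequency effect is
#' exactly zero.
#'
#' @inheritParams simulate_serial
#' @export
simulate_parallel_limited <- function(params, condition, freq_bin = "HIGH") {
  condition <- check_condition(condition)
  if (condition != "TWO_SIM") {
    p <- simulate_serial(params, condition, freq_bin)
    p$model <- "PARALLEL_LIMITED"
    return(p)
  }
  th <- threshold_for(params, freq_bin)
  a <- accumulate(params$slope / params$kappa, th, 0, params$window_ms,
                  params$reset_on_threshold)$area
  new_prediction(c(a, a), condition, freq_bin, "PARALLEL_LIMITED")
}

#' Unlimited-capacity parallel model trial prediction
#'
#' Two simultaneous words are processed exactly as two sequential words: same
#' slope, same thresholds, a full window each. Predicts identical BOLD
#' responses and frequency effects in both presentation conditions (the
#' pattern the data reject).
#'
#' @inheritParams simulate_serial
#' @export
simulate_parallel_unlimited <- function(params, condition, freq_bin = "HIGH") {
  condition <- check_condition(condition)
  if (condition != "TWO_SIM") {
    p <- simulate_serial(params, condition, freq_bin)
    p$model <- "PARALLEL_UNLIMITED"
    return(p)
  }
  th <- threshold_for(params, freq_bin)
  a <- accumulate(params$slope, th, 0, params$window_ms,
                  params$reset_on_threshold)$area
  new_prediction(c(a, a), condition, freq_bin, "PARALLEL_UNLIMITED")
}

#' Hybrid parallel-then-serial model trial prediction
#'
#' Sublexical evidence for both words rises in parallel to a sublexical level
#' h = threshold / 2; lexical completion is serial. While word A completes,
#' word B's activation returns to baseline but its sublexical evidence is
#' retained, so B later resumes at h and completes — the characteristic
#' jagged trace. Each word's area under activation is h^2/(2s) +
#' (theta^2 - h^2)/(2s) = theta^2/(2s), exactly the area of a fully processed
#' sequential word, so the two word areas are equal and the simultaneous
#' total equals the sequential total. By default processing is not
#' interrupted by the post-mask (both words reach threshold); with
#' \code{interrupt = TRUE} word B's completion is truncated at the window
#' end.
#'
#' @inheritParams simulate_serial
#' @param interrupt if TRUE, the frame window truncates word B's completion.
#' @export
simulate_hybrid <- function(params, condition, freq_bin = "HIGH",
                            interrupt = FALSE) {
  condition <- check_condition(condition)
  if (condition != "TWO_SIM") {
    p <- simulate_serial(params, condition, freq_bin)
    p$model <- "HYBRID"
    return(p)
  }
  th <- threshold_for(params, freq_bin)
  s <- params$slope
  h <- th / 2
  # word A: continuous rise 0 -> theta (sublexical then lexical)
  area_a <- th^2 / (2 * s)
  # word B: rise 0 -> h, activation silent while A completes, then h -> theta
  rise1 <- h^2 / (2 * s)
  if (!interrupt) {
    area_b <- rise1 + (th^2 - h^2) / (2 * s)
  } else {
    W <- params$window_ms
    t_a_done <- th / s                       # A completes (A started at 0)
    avail <- max(0, W - t_a_done)            # time left for B's completion
    gained <- min(th - h, s * avail)
    dur <- gained / s
    area_b <- if (t_a_done > W) {
      # A itself truncated; B never resumes
      s * min(h / s, W)^2 / 2                # only the initial sublexical rise
    } else {
      rise1 + (h + h + gained) / 2 * dur
    }
    if (t_a_done > W) area_a <- s * W^2 / 2
  }
  new_prediction(c(area_a, area_b), condition, freq_bin, "HYBRID")
}

MODEL_KINDS <- c(SERIAL = "simulate_serial",
                 PARALLEL_LIMITED = "simulate_parallel_limited",
                 PARALLEL_UNLIMITED = "simulate_parallel_unlimited",
                 HYBRID = "simulate_hybrid")

#' Predicted BOLD table over conditions and frequency bins
#'
#' Evaluates one model over the full condition-by-frequency grid and returns
#' the per-word and total activation areas (arbitrary units) that stand in
#' for predicted BOLD responses.
#'
#' @param model_kind one of "SERIAL", "PARALLEL_LIMITED",
#'   "PARALLEL_UNLIMITED", "HYBRID" (case-insensitive).
#' @param params \code{\link{accumulator_params}}.
#' @return data.frame with columns model, condition, freq_bin, word1_area,
#'   word2_area, total_area.
#' @examples
#' predict_bold_table("SERIAL", accumulator_params())
#' @export
predict_bold_table <- function(model_kind, params = accumulator_params()) {
  model_kind <- toupper(model_kind)
  if (!model_kind %in% names(MODEL_KINDS)) {
    stop("unknown model kind: ", model_kind)
  }
  fn <- get(MODEL_KINDS[[model_kind]], mode = "function")
  grid <- expand.grid(condition = CONDITIONS, freq_bin = c("LOW", "HIGH"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- fn(params, grid$condition[i], grid$freq_bin[i])
    wa <- c(p$word_areas, rep(NA_real_, 2 - length(p$word_areas)))
    data.frame(model = model_kind, condition = p$condition,
               freq_bin = p$freq_bin, word1_area = wa[1], word2_area = wa[2],
               total_area = p$total_area, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Lexical frequency effect predicted for one condition
#'
#' Total activation area for a low-frequency pair minus a high-frequency pair.
#'
#' @inheritParams predict_bold_table
#' @param condition trial condition (typically TWO_SEQ or TWO_SIM).
#' @export
frequency_effect <- function(model_kind, params = accumulator_params(),
                             condition = "TWO_SIM") {
  tab <- predict_bold_table(model_kind, params)
  tab <- tab[tab$condition == check_condition(condition), ]
  tab$total_area[tab$freq_bin == "LOW"] - tab$total_area[tab$freq_bin == "HIGH"]
}
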