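#' @name power
#' @title Simulation-based power analysis for the simultaneous-suppression
#'   contrast
#'
#' @description
#' The pre-data power analysis assumes single-word responses of mean 0.32
#' percent signal change with SD 0.2, a two-word sequential mean elevated by
#' a suppression effect delta over the two-word simultaneous mean, and a
#' two-sided paired t test at alpha = 0.05. \code{simulate_power} estimates
#' power by Monte Carlo over a grid of sample sizes; \code{power_closed_form}
#' is the exact noncentral-t benchmark.
NULL

#' Power-analysis configuration
#'
#' @param suppression_delta the assumed 2seq minus 2sim mean difference in
#'   percent signal change. The effect size behind the original sample-size
#'   choice is not published, so this is a required input.
#' @param mean_1w single-word mean response (psc); the simultaneous mean.
#' @param sd per-condition SD across subjects (psc).
#' @param n_grid subject counts to evaluate.
#' @param alpha two-sided test level.
#' @param target_power power target for the minimal-n rule.
#' @param reps Monte-Carlo replicates per n (>= 100).
#' @param seed integer seed.
#' @export
power_config <- function(suppression_delta, mean_1w = 0.32, sd = 0.2,
                         n_grid = 5:40, alpha = 0.05, target_power = 0.90,
                         reps = 5000, seed = 1) {
  if (sd <= 0) stop("sd must be positive")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (reps < 100) stop("need at least 100 replicates")
  if (length(n_grid) == 0) stop("empty n grid")
  if (any(n_grid < 2)) stop("paired t test needs n >= 2")
  structure(list(suppression_delta = suppression_delta, mean_1w = mean_1w,
                 sd = sd, n_grid = sort(unique(n_grid)), alpha = alpha,
                 target_power = target_power, reps = reps, seed = seed),
            class = "power_config")
}

#' Monte-Carlo power for the paired suppression contrast
#'
#' For each n, draws per-subject responses in the sequential
#' (mean_1w + delta) and simultaneous (mean_1w) conditions, runs a two-sided
#' paired t test at alpha, and reports the rejection fraction with a 95\%
#' Monte-Carlo CI. The minimal n is the smallest n whose
#' monotone-smoothed power (running maximum over n) reaches the target.
#'
#' @param cfg a \code{\link{power_config}}.
#' @return object of class \code{power_result}: data.frame (n, power, ci_lo,
#'   ci_hi) plus \code{minimal_n}.
#' @export
simulate_power <- function(cfg) {
  rng <- local_rng(cfg$seed)
  on.exit(rng())
  tab <- lapply(cfg$n_grid, function(n) {
    # paired differences: delta + noise with SD sd*sqrt(2)
    d <- matrix(stats::rnorm(n * cfg$reps, cfg$suppression_delta,
                             cfg$sd * sqrt(2)), nrow = n)
    m <- colMeans(d)
    s <- sqrt(colSums((d - rep(m, each = n))^2) / (n - 1))
    tstat <- m / (s / sqrt(n))
    rej <- mean(abs(tstat) > stats::qt(1 - cfg$alpha / 2, n - 1))
    se <- sqrt(rej * (1 - rej) / cfg$reps)
    data.frame(n = n, power = rej, ci_lo = max(0, rej - 1.96 * se),
               ci_hi = min(1, rej + 1.96 * se))
  })
  tab <- do.call(rbind, tab)
  smoothed <- cummax(tab$power)
  hit <- which(smoothed >= cfg$target_power)
  minimal_n <- if (length(hit)) tab$n[hit[1]] else NA_integer_
  structure(list(table = tab, minimal_n = minimal_n, config = cfg),
            class = "power_result")
}

#' @export
print.power_result <- function(x, ...) {
  cat(sprintf("Paired-t power, delta = %.3f psc, sd = %.2f, alpha = %.2f\n",
              x$config$suppression_delta, x$config$sd, x$config$alpha))
  print(x$table, digits = 3, row.names = FALSE)
  cat("minimal n for", x$config$target_power, "power:", x$minimal_n, "\n")
  invisible(x)
}

#' Exact paired-t power (noncentral t)
#'
#' @param d standardized effect size (mean difference / SD of differences).
#' @param n number of pairs (>= 2); vectorized.
#' @param alpha two-sided level.
#' @export
power_closed_form <- function(d, n, alpha = 0.05) {
  if (any(n < 2)) stop("paired t test needs n >= 2")
  ncp <- d * sqrt(n)
  tcrit <- stats::qt(1 - alpha / 2, n - 1)
  stats::pt(-tcrit, n - 1, ncp) + stats::pt(tcrit, n - 1, ncp,
                                            lower.tail = FALSE)
}

#' Minimal n reaching a power target, closed form
#'
#' @inheritParams power_closed_form
#' @param target power target.
#' @param n_max search cap.
#' @export
minimal_n_closed_form <- function(d, alpha = 0.05, target = 0.90,
                                  n_max = 10000) {
  for (n in 2:n_max) {
    if (power_closed_form(d, n, alpha) >= target) return(n)
  }
  NA_integer_
}
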