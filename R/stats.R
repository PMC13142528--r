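#' @name stats_module
#' @title Single-trial behavioral and BOLD statistics
#'
#' @description
#' Mixed-effects analyses of single-trial data: accuracy and critical-frame
#' response times, linear and generalized linear mixed models with subject
#' random slopes and stimulus-item random intercepts, planned pairwise
#' contrasts as Wald F tests with denominator degrees of freedom equal to
#' n_observations - n_fixed_effects, Benjamini-Hochberg FDR correction across
#' regions, and a BIC-based Bayes factor approximation.
NULL

RESPONSE_PERIOD_MS <- 3651   # response window after final-frame offset

#' Code each trial's stimulus as a single item string
#'
#' Two-word trials are coded as the concatenation of the two words (frame
#' order for sequential trials, top-then-bottom for simultaneous trials);
#' one-word trials as the word itself; zero-word trials as a randomly
#' selected frame-1/2 false-font filler's source word suffixed \code{"_ff"}.
#'
#' @param design a \code{session_design}.
#' @param lexicon the lexicon data.frame (tokens looked up by word_id).
#' @param seed seed for the zero-word filler selection.
#' @return character vector of stimulus ids, one per trial.
#' @export
code_stimulus_ids <- function(design, lexicon, seed = 1) {
  tr <- design$trials
  tok <- function(id) {
    t <- lexicon$token[match(id, lexicon$word_id)]
    if (any(is.na(t))) stop("word id not found in lexicon")
    t
  }
  rng <- local_rng(seed)
  on.exit(rng())
  vapply(seq_len(nrow(tr)), function(i) {
    r <- tr[i, ]
    switch(r$condition,
      ZERO = {
        # fillers are stored in slot order; the first four sit in frames 1-2
        f <- strsplit(r$filler_ids, ";")[[1]]
        pick <- sample(f[seq_len(min(4, length(f)))], 1)
        paste0(tok(as.integer(pick)), "_ff")
      },
      ONE = tok(r$word1_id),
      TWO_SEQ = {
        first <- if (r$word1_frame <= r$word2_frame) r$word1_id else r$word2_id
        second <- if (r$word1_frame <= r$word2_frame) r$word2_id else r$word1_id
        paste0(tok(first), tok(second))
      },
      TWO_SIM = {
        top <- if (r$word1_loc == "TOP") r$word1_id else r$word2_id
        bot <- if (r$word1_loc == "TOP") r$word2_id else r$word1_id
        paste0(tok(top), tok(bot))
      })
  }, character(1))
}

n_words_for <- function(condition) {
  c(ZERO = 0L, ONE = 1L, TWO_SEQ = 2L, TWO_SIM = 2L)[condition]
}

#' Score responses against the design
#'
#' A response is correct iff the reported word count equals the true count
#' and the button press fell within the 3.651 s response period after the
#' final-frame offset. Late or absent responses are flagged as no-response
#' and excluded from accuracy.
#'
#' @param responses data.frame with columns \code{trial}, \code{response}
#'   (0, 1, 2, or NA for none) and \code{resp_ms} (button time in ms from
#'   final-frame offset); optionally \code{subject}.
#' @param design a \code{session_design}.
#' @return a behavioral-record data.frame: trial, condition, n_words,
#'   response, resp_ms, no_response, correct (NA when no response).
#' @export
compute_accuracy <- function(responses, design) {
  tr <- design$trials
  idx <- match(responses$trial, seq_len(nrow(tr)))
  if (any(is.na(idx))) stop("response refers to unknown trial")
  resp <- responses$response
  bad <- !is.na(resp) & !resp %in% 0:2
  if (any(bad)) stop("responses must be 0, 1, 2 or NA")
  cond <- tr$condition[idx]
  nw <- n_words_for(cond)
  no_resp <- is.na(resp) | is.na(responses$resp_ms) |
    responses$resp_ms > RESPONSE_PERIOD_MS
  out <- data.frame(trial = responses$trial, condition = cond,
                    n_words = as.integer(nw), response = resp,
                    resp_ms = responses$resp_ms, no_response = no_resp,
                    correct = ifelse(no_resp, NA, resp == nw),
                    stringsAsFactors = FALSE)
  if ("subject" %in% names(responses)) out$subject <- responses$subject
  out
}

#' Response times from the critical frame
#'
#' The critical frame — the frame that disambiguates the correct count — is
#' frame 2 for all trials except two-word simultaneous trials with both words
#' in frame 1. For an unbiased comparison, trials with two words in frame 1
#' and one-word trials with the word in frame 1 are excluded; all analyzed
#' RTs are measured from frame-2 onset and only correct responses are kept.
#'
#' @param records output of \code{\link{compute_accuracy}}.
#' @param design a \code{session_design}.
#' @return the records with added columns \code{rt_ms} (from frame-2 onset)
#'   and \code{rt_excluded}, filtered to correct, responded trials.
#' @export
rt_from_critical_frame <- function(records, design) {
  tr <- design$trials
  idx <- match(records$trial, seq_len(nrow(tr)))
  w1f <- tr$word1_frame[idx]
  excl <- (tr$condition[idx] == "TWO_SIM" & !is.na(w1f) & w1f == 1) |
    (tr$condition[idx] == "ONE" & !is.na(w1f) & w1f == 1)
  records$rt_excluded <- excl
  # resp_ms runs from final-frame offset (649 ms); frame-2 onset is 233 ms
  records$rt_ms <- records$resp_ms + (STIM_MS - frame_onset_ms(2))
  records[!records$rt_excluded & !records$no_response &
            records$correct %in% TRUE, , drop = FALSE]
}

#' Fit a linear or generalized linear mixed model
#'
#' A thin, convention-fixing front end to \code{lme4}: Gaussian models are
#' fit by maximum likelihood (so BIC comparisons are coherent), binomial
#' models by Laplace-approximation \code{glmer}. If the requested random
#' structure fails to converge, it is reduced along a fixed ladder — full
#' random slopes, then diagonal covariance (\code{||}), then random
#' intercepts only — and the reduction is recorded. The returned fit carries
#' the degrees-of-freedom convention used for all F tests: DF =
#' n_observations - n_fixed_effects.
#'
#' @param formula an lme4 model formula, e.g.
#'   \code{beta ~ W + (W | subject) + (1 | stim_id)}.
#' @param data model data.
#' @param family "gaussian" or "binomial".
#' @return object of class \code{mw_fit}: the lme4 model plus coefficient
#'   table (estimate, SE, Wald 95\% CI), \code{df}, \code{converged},
#'   \code{reduction}.
#' @export
fit_mixed <- function(formula, data, family = "gaussian") {
  gvars <- unlist(lapply(lme4::findbars(formula), function(b) all.vars(b[[3]])))
  for (g in unique(gvars)) {
    if (!g %in% names(data)) stop("grouping variable not in data: ", g)
    if (g == "subject" && length(unique(data[[g]])) < 2) {
      stop("need at least 2 subjects")
    }
  }

  ladder <- list(full = formula,
                 diagonal = diagonalize_bars(formula),
                 intercepts = intercepts_only(formula))
  fit <- NULL
  reduction <- NA_character_
  for (step in names(ladder)) {
    f <- ladder[[step]]
    res <- try_fit(f, data, family)
    if (!is.null(res)) {
      fit <- res
      reduction <- step
      break
    }
  }
  if (is.null(fit)) stop("mixed model failed to converge at every ladder step")

  n_obs <- stats::nobs(fit)
  b <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(diag(V))
  df <- n_obs - length(b)
  tcrit <- stats::qt(0.975, df)
  coefs <- data.frame(term = names(b), estimate = unname(b), se = se,
                      ci_lo = unname(b) - tcrit * se,
                      ci_hi = unname(b) + tcrit * se,
                      stringsAsFactors = FALSE)
  rownames(coefs) <- NULL
  structure(list(model = fit, formula = ladder[[reduction]],
                 family = family, n_obs = n_obs, n_fixed = length(b),
                 df = df, coefficients = coefs,
                 vcov = V, converged = TRUE,
                 reduction = reduction,
                 singular = lme4::isSingular(fit)),
            class = "mw_fit")
}

try_fit <- function(formula, data, family) {
  ok <- TRUE
  fit <- withCallingHandlers(
    tryCatch({
      if (identical(family, "gaussian")) {
        lme4::lmer(formula, data = data, REML = FALSE)
      } else {
        lme4::glmer(formula, data = data, family = stats::binomial())
      }
    }, error = function(e) NULL),
    warning = function(w) {
      if (grepl("converge", conditionMessage(w), ignore.case = TRUE)) {
        ok <<- FALSE
      }
      invokeRestart("muffleWarning")
    })
  if (is.null(fit) || !ok) NULL else fit
}

# (x | g) -> (x || g)
diagonalize_bars <- function(formula) {
  f <- deparse1(formula)
  stats::as.formula(gsub("\\|(?!\\|)", "||", f, perl = TRUE),
                    env = environment(formula))
}

# every (x | g) -> (1 | g)
intercepts_only <- function(formula) {
  bars <- lme4::findbars(formula)
  f <- deparse1(formula)
  for (b in bars) {
    g <- deparse1(b[[3]])
    f <- gsub(paste0("\\(\\s*[^|()]*\\|+\\s*", g, "\\s*\\)"),
              paste0("(1 | ", g, ")"), f)
  }
  stats::as.formula(f, env = environment(formula))
}

#' @export
print.mw_fit <- function(x, ...) {
  cat(sprintf("Mixed model (%s, %s): %d obs, %d fixed effects, DF = %d\n",
              x$family, x$reduction, x$n_obs, x$n_fixed, x$df))
  print(x$coefficients, digits = 4)
  invisible(x)
}

#' @export
coef.mw_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate, object$coefficients$term)
}

#' Wald F test for a fixed-effect term
#'
#' Joint test that all coefficients belonging to \code{term} are zero, with
#' denominator DF = n_obs - n_fixed.
#'
#' @param fit an \code{mw_fit}.
#' @param term name of a fixed-effect term (matched against coefficient
#'   names).
#' @export
fixed_effect_F <- function(fit, term) {
  asgn <- attr(stats::model.matrix(fit$model), "assign")
  labs <- attr(stats::terms(fit$model), "term.labels")
  k <- match(term, labs)
  if (is.na(k)) stop("term not found: ", term)
  idx <- which(asgn == k)
  L <- matrix(0, length(idx), fit$n_fixed)
  L[cbind(seq_along(idx), idx)] <- 1
  pairwise_contrast(fit, L)
}

#' Planned contrast on a fitted mixed model
#'
#' Linear-hypothesis Wald F test \code{L beta = 0} with the package's DF
#' convention (denominator DF = n_obs - n_fixed). A single contrast vector
#' gives a 1-DF test with estimate, SE and 95\% CI; a matrix gives a joint
#' test.
#'
#' @param fit an \code{mw_fit}.
#' @param contrast numeric vector (length = number of fixed effects) or
#'   matrix with one contrast per row.
#' @return list(estimate, se, ci_lo, ci_hi, F, df1, df2, p) — the first four
#'   are NA for joint (multi-row) contrasts.
#' @export
pairwise_contrast <- function(fit, contrast) {
  L <- if (is.matrix(contrast)) contrast else matrix(contrast, nrow = 1)
  if (ncol(L) != fit$n_fixed) {
    stop("contrast length ", ncol(L), " does not match ", fit$n_fixed,
         " fixed effects")
  }
  if (all(L == 0)) stop("degenerate all-zero contrast")
  b <- coef(fit)
  est <- drop(L %*% b)
  M <- L %*% fit$vcov %*% t(L)
  q <- nrow(L)
  Fstat <- drop(t(est) %*% solve(M, est)) / q
  p <- stats::pf(Fstat, q, fit$df, lower.tail = FALSE)
  if (q == 1) {
    se <- sqrt(drop(M))
    tcrit <- stats::qt(0.975, fit$df)
    list(estimate = est, se = se, ci_lo = est - tcrit * se,
         ci_hi = est + tcrit * se, F = Fstat, df1 = 1, df2 = fit$df, p = p)
  } else {
    list(estimate = NA_real_, se = NA_real_, ci_lo = NA_real_,
         ci_hi = NA_real_, F = Fstat, df1 = q, df2 = fit$df, p = p)
  }
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values and the rejection set at level \code{q}.
#'
#' @param pvals numeric p-values in [0, 1].
#' @param q false discovery rate (default 0.05).
#' @return list(adjusted, rejected).
#' @export
fdr_adjust <- function(pvals, q = 0.05) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, rejected = adj <= q)
}

#' BIC-approximate Bayes factor
#'
#' BF10 ~ exp((BIC_null - BIC_alt) / 2). This is a coarse approximation
#' (unit-information prior); it is not expected to match Bayes factors
#' computed by dedicated toolboxes on trial-averaged data.
#'
#' @param fit_alt,fit_null \code{mw_fit} objects on the same data, null
#'   nested in the alternative.
#' @export
bayes_factor_bic <- function(fit_alt, fit_null) {
  if (fit_alt$n_obs != fit_null$n_obs) {
    stop("models must be fit to the same observations")
  }
  alt_terms <- fit_alt$coefficients$term
  null_terms <- fit_null$coefficients$term
  if (!all(null_terms %in% alt_terms)) {
    warning("null fixed effects are not a subset of the alternative's; ",
            "models may not be nested")
  }
  exp((stats::BIC(fit_null$model) - stats::BIC(fit_alt$model)) / 2)
}

#' Canonical analysis model formulas
#'
#' The single-trial model family used throughout: accuracy and RT models
#' over presentation condition, BOLD models over the number of words (W) and
#' over condition, region-interaction variants, and the lexical-frequency
#' models (which drop the item random effect because items are confounded
#' with frequency bin).
#'
#' @return a named list of formulas with a \code{family} attribute per entry.
#' @export
analysis_formulas <- function() {
  f <- list(
    accuracy      = correct ~ condition + (condition | subject) + (1 | stim_id),
    rt            = rt_ms ~ condition + (condition | subject) + (1 | stim_id),
    number_of_words = beta ~ W + (W | subject) + (1 | stim_id),
    suppression   = beta ~ condition + (condition | subject) + (1 | stim_id),
    words_by_region = beta ~ W * region + (W * region | subject) + (1 | stim_id),
    suppression_by_region =
      beta ~ condition * region + (condition * region | subject) + (1 | stim_id),
    freq_bold     = beta ~ condition * region * freq_bin +
      (condition * region * freq_bin | subject),
    freq_accuracy = correct ~ condition * freq_bin +
      (condition * freq_bin | subject),
    freq_rt       = rt_ms ~ condition * freq_bin +
      (condition * freq_bin | subject)
  )
  attr(f$accuracy, "family") <- "binomial"
  attr(f$freq_accuracy, "family") <- "binomial"
  f
}
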