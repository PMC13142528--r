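#' Generate a synthetic five-letter word lexicon
#'
#' Creates a lexicon of unique five-letter tokens with lexical frequencies on
#' the Zipf scale (log10 frequency per million words + 3) and orthographic
#' neighborhood sizes. The Zipf values are drawn by stratified sampling from a
#' piecewise-linear quantile map anchored at (0, \code{zipf_min}),
#' (0.5, \code{zipf_median}) and (1, \code{zipf_max}), so the empirical range
#' stays within bounds and the empirical median lands on the target up to
#' O(1/n) stratification error.
#'
#' @param n number of words (default 768).
#' @param zipf_min,zipf_max bounds of the Zipf frequency range.
#' @param zipf_median target median Zipf frequency.
#' @param word_length token length in letters.
#' @param neighborhood_lambda Poisson mean for orthographic neighborhood size.
#' @param seed integer seed; the lexicon is fully deterministic given the seed.
#' @return a data.frame with columns \code{word_id}, \code{token}, \code{zipf},
#'   \code{log_freq} (log10 frequency per million) and \code{neighborhood}.
#' @examples
#' lex <- gen_lexicon(n = 32, seed = 1)
#' range(lex$zipf)
#' @export
gen_lexicon <- function(n = 768, zipf_min = 2.2, zipf_max = 6.1,
                        zipf_median = 4.1, word_length = 5,
                        neighborhood_lambda = 1.5, seed = 1) {
  if (n < 2) stop("lexicon needs at least 2 words")
  if (!(zipf_min < zipf_median && zipf_median < zipf_max)) {
    stop("infeasible Zipf constraints: need zipf_min < zipf_median < zipf_max")
  }
  rng <- local_rng(seed)
  on.exit(rng())

  if (n == 2) {
    zipf <- c(zipf_min, zipf_max)
  } else {
    # one uniform draw per stratum, mapped through the anchored quantile curve
    u <- (seq_len(n) - stats::runif(n)) / n
    zipf <- ifelse(u <= 0.5,
                   zipf_min + (zipf_median - zipf_min) * (u / 0.5),
                   zipf_median + (zipf_max - zipf_median) * ((u - 0.5) / 0.5))
    zipf <- sample(zipf)  # decouple frequency from word_id order
  }

  tokens <- character(0)
  while (length(tokens) < n) {
    need <- n - length(tokens)
    cand <- vapply(seq_len(need), function(i) {
      paste(sample(letters, word_length, replace = TRUE), collapse = "")
    }, character(1))
    tokens <- unique(c(tokens, cand))
  }

  data.frame(
    word_id = seq_len(n),
    token = tokens[seq_len(n)],
    zipf = zipf,
    log_freq = zipf - 3,
    neighborhood = stats::rpois(n, neighborhood_lambda),
    stringsAsFactors = FALSE
  )
}

# Seeded RNG scope: sets the seed, returns a restore function.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }
}
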