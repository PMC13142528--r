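#' @name design
#' @title Trial-design generation for the four-condition word-counting task
#'
#' @description
#' Each trial presents three successive frames (183 ms each, 50 ms ISI) with
#' two character strings per frame, one above and one below fixation. Most
#' strings are illegible false-font fillers; the four conditions differ in how
#' many legible words appear and when: \code{ZERO} (no words), \code{ONE} (one
#' word in frame 1 or 2, top or bottom), \code{TWO_SEQ} (one word per frame at
#' opposite locations in frames 1 and 2) and \code{TWO_SIM} (two words in the
#' same frame, top and bottom). Frame 3 is always a false-font post-mask.
NULL

CONDITIONS <- c("ZERO", "ONE", "TWO_SEQ", "TWO_SIM")
FRAME_MS <- 183
ISI_MS <- 50
ITI_MS <- 3651
SOA_MS <- FRAME_MS + ISI_MS                    # 233 ms between frame onsets
STIM_MS <- 3 * FRAME_MS + 2 * ISI_MS           # 649 ms of stimulus presentation

#' Onset time of a stimulus frame, in ms from trial onset
#' @param frame frame number (1, 2 or 3).
#' @export
frame_onset_ms <- function(frame) (frame - 1) * SOA_MS

#' Design configuration
#'
#' @param n_runs number of runs (default 8).
#' @param trials_per_run trials per run (default 64; runs last about five
#'   minutes at the default trial timing).
#' @param block_size trials per block; a blank follows every block.
#' @param blank_choices_s possible blank durations in seconds.
#' @param n_lists number of balanced word lists.
#' @param seed integer seed for trial-order randomization.
#' @return a list of class \code{design_config}.
#' @export
design_config <- function(n_runs = 8, trials_per_run = 64, block_size = 5,
                          blank_choices_s = c(4, 6, 8), n_lists = 6, seed = 1) {
  total <- n_runs * trials_per_run
  if (total %% 4 != 0) stop("total trials must be divisible by 4 conditions")
  nper <- total / 4
  if (nper %% 4 != 0) {
    stop("trials per condition must be divisible by 4 for exact frame x ",
         "location counterbalancing of one-word trials")
  }
  structure(list(n_runs = n_runs, trials_per_run = trials_per_run,
                 block_size = block_size, blank_choices_s = blank_choices_s,
                 n_lists = n_lists, seed = seed,
                 frame_ms = FRAME_MS, isi_ms = ISI_MS, iti_ms = ITI_MS),
            class = "design_config")
}

#' Balance word lists across condition groups
#'
#' Partitions a lexicon into condition groups so that group means of log
#' lexical frequency and orthographic neighborhood size are matched, and does
#' so \code{n_lists} times with different random starts to produce distinct
#' balanced lists. Both covariates are standardized before balancing; the
#' assignment starts from a seeded random partition and hill-climbs pairwise
#' swaps between groups until the largest pairwise gap in group means (on the
#' standardized scales) is below \code{tolerance}.
#'
#' @param lexicon a lexicon data.frame from \code{\link{gen_lexicon}}.
#' @param n_lists number of distinct balanced lists to produce.
#' @param n_condition_groups number of condition groups.
#' @param group_sizes optional integer vector of group sizes summing to the
#'   (possibly trimmed) lexicon size; equal split by default.
#' @param tolerance maximum allowed pairwise gap between group means on the
#'   standardized covariate scales (default 0.05).
#' @param max_iter hill-climbing iteration cap per list.
#' @param seed integer seed.
#' @return a data.frame with columns \code{list_id}, \code{word_id},
#'   \code{group}; attribute \code{"balance"} holds the achieved gap per list.
#' @export
balance_word_lists <- function(lexicon, n_lists = 6, n_condition_groups = 4,
                               group_sizes = NULL, tolerance = 0.05,
                               max_iter = 20000, seed = 1) {
  n <- nrow(lexicon)
  if (is.null(group_sizes)) {
    if (n < n_condition_groups) stop("lexicon too small for requested groups")
    keep <- n - (n %% n_condition_groups)   # trim rule: drop trailing words
    lexicon <- lexicon[seq_len(keep), , drop = FALSE]
    n <- keep
    group_sizes <- rep(n / n_condition_groups, n_condition_groups)
  } else {
    if (length(group_sizes) != n_condition_groups ||
        sum(group_sizes) != n) {
      stop("group_sizes must have one entry per group and sum to lexicon size")
    }
  }
  std <- function(v) if (stats::sd(v) > 0) (v - mean(v)) / stats::sd(v) else v * 0
  covars <- cbind(log_freq = std(lexicon$log_freq),
                  nbhd = std(lexicon$neighborhood))

  rng <- local_rng(seed)
  on.exit(rng())

  max_gap <- function(assign) {
    gaps <- apply(covars, 2, function(v) {
      m <- tapply(v, assign, mean)
      max(m) - min(m)
    })
    max(gaps)
  }

  out <- vector("list", n_lists)
  achieved <- numeric(n_lists)
  for (l in seq_len(n_lists)) {
    assign <- sample(rep.int(seq_len(n_condition_groups), group_sizes))
    gap <- max_gap(assign)
    it <- 0
    while (gap >= tolerance && it < max_iter) {
      it <- it + 1
      i <- sample.int(n, 1)
      j <- sample.int(n, 1)
      if (assign[i] == assign[j]) next
      cand <- assign
      cand[c(i, j)] <- cand[c(j, i)]
      g2 <- max_gap(cand)
      if (g2 < gap) {
        assign <- cand
        gap <- g2
      }
    }
    if (gap >= tolerance) {
      stop(sprintf("list %d: balance tolerance %.3f not reached (gap %.3f)",
                   l, tolerance, gap))
    }
    out[[l]] <- data.frame(list_id = l, word_id = lexicon$word_id,
                           group = assign)
    achieved[l] <- gap
  }
  res <- do.call(rbind, out)
  attr(res, "balance") <- achieved
  res
}

#' Generate a full session design
#'
#' Produces the complete randomized trial sequence for one participant:
#' exactly one quarter of trials per condition, exact counterbalancing of
#' frame (1 vs 2) and location (top vs bottom) within the conditions where
#' those vary, a blank of 4/6/8 s after every block of five trials, and every
#' legible word used at most once. Legible words are drawn from each
#' condition's balanced group; false-font filler slots are filled by words not
#' used legibly in the session (with reuse, since the session has more string
#' slots than the lexicon has words).
#'
#' @param config a \code{\link{design_config}}.
#' @param lexicon the lexicon data.frame.
#' @param word_lists output of \code{\link{balance_word_lists}} (or NULL to
#'   balance internally with groups sized to condition needs).
#' @param list_id which balanced list to use.
#' @param seed integer seed; overrides \code{config$seed} when given.
#' @return an object of class \code{session_design}: a list with elements
#'   \code{trials} (data.frame), \code{config}, and \code{word_list_id}.
#' @examples
#' lex <- gen_lexicon(n = 96, seed = 1)
#' cfg <- design_config(n_runs = 1, trials_per_run = 16)
#' des <- generate_session(cfg, lex, seed = 2)
#' table(des$trials$condition)
#' @export
generate_session <- function(config, lexicon, word_lists = NULL, list_id = 1,
                             seed = NULL) {
  if (is.null(seed)) seed <- config$seed
  total <- config$n_runs * config$trials_per_run
  nper <- total / 4

  rng <- local_rng(seed)
  on.exit(rng())

  need <- c(ZERO = nper, ONE = nper, TWO_SEQ = 2 * nper, TWO_SIM = 2 * nper)
  if (is.null(word_lists)) {
    sizes <- round(nrow(lexicon) * need / sum(need))
    sizes[length(sizes)] <- nrow(lexicon) - sum(sizes[-length(sizes)])
    word_lists <- balance_word_lists(lexicon, n_lists = 1,
                                     n_condition_groups = 4,
                                     group_sizes = as.integer(sizes),
                                     seed = seed + 7L)
    list_id <- 1
  }
  wl <- word_lists[word_lists$list_id == list_id, , drop = FALSE]
  if (nrow(wl) == 0) stop("word list ", list_id, " not found")
  groups <- split(wl$word_id, wl$group)
  for (k in 2:4) {
    if (length(groups[[k]]) < need[k]) {
      stop(sprintf("group %d has %d words but %d legible slots are needed",
                   k, length(groups[[k]]), need[k]))
    }
  }

  draw <- function(pool, k) sample(pool, k)
  one_words <- draw(groups[[2]], nper)
  seq_words <- matrix(draw(groups[[3]], 2 * nper), ncol = 2)
  sim_words <- matrix(draw(groups[[4]], 2 * nper), ncol = 2)

  # ONE: frame x location fully crossed; TWO_SEQ: first-word location
  # counterbalanced (word 1 frame 1, word 2 frame 2 at the opposite
  # location); TWO_SIM: frame counterbalanced, word 1 top and word 2 bottom
  cells <- expand.grid(frame = 1:2, loc = c("TOP", "BOTTOM"),
                       stringsAsFactors = FALSE)
  cell_idx <- rep(seq_len(4), each = nper / 4)
  loc1 <- rep(c("TOP", "BOTTOM"), each = nper / 2)
  frame_sim <- rep(1:2, each = nper / 2)
  trials <- data.frame(
    condition = rep(CONDITIONS, each = nper),
    word1_id = c(rep(NA_integer_, nper), one_words,
                 seq_words[, 1], sim_words[, 1]),
    word1_frame = c(rep(NA_integer_, nper), cells$frame[cell_idx],
                    rep(1L, nper), frame_sim),
    word1_loc = c(rep(NA_character_, nper), cells$loc[cell_idx],
                  loc1, rep("TOP", nper)),
    word2_id = c(rep(NA_integer_, 2 * nper), seq_words[, 2], sim_words[, 2]),
    word2_frame = c(rep(NA_integer_, 2 * nper), rep(2L, nper), frame_sim),
    word2_loc = c(rep(NA_character_, 2 * nper),
                  ifelse(loc1 == "TOP", "BOTTOM", "TOP"),
                  rep("BOTTOM", nper)),
    stringsAsFactors = FALSE)
  trials <- trials[sample.int(total), , drop = FALSE]
  rownames(trials) <- NULL
  trials$run <- rep(seq_len(config$n_runs), each = config$trials_per_run)
  trials$trial <- rep(seq_len(config$trials_per_run), config$n_runs)

  # false-font fillers: words never shown legibly this session, reuse allowed
  used <- stats::na.omit(c(trials$word1_id, trials$word2_id))
  unused <- setdiff(lexicon$word_id, used)
  if (length(unused) == 0) stop("no unused words left for fillers")
  n_fill <- 6 - (!is.na(trials$word1_id)) - (!is.na(trials$word2_id))
  trials$filler_ids <- vapply(n_fill, function(k) {
    paste(sample(unused, k, replace = TRUE), collapse = ";")
  }, character(1))

  # blank after every block of block_size trials (including the last block)
  blk <- config$block_size
  trials$blank_after_s <- NA_real_
  is_block_end <- trials$trial %% blk == 0
  trials$blank_after_s[is_block_end] <-
    sample(config$blank_choices_s, sum(is_block_end), replace = TRUE)

  trials <- trials[, c("run", "trial", "condition",
                       "word1_id", "word1_frame", "word1_loc",
                       "word2_id", "word2_frame", "word2_loc",
                       "filler_ids", "blank_after_s")]
  structure(list(trials = trials, config = config, word_list_id = list_id),
            class = "session_design")
}

#' @export
print.session_design <- function(x, ...) {
  cat("Session design:", nrow(x$trials), "trials in", x$config$n_runs,
      "runs\n")
  print(table(x$trials$condition))
  invisible(x)
}

#' Validate a session design
#'
#' Checks every design invariant and returns a report: condition counts,
#' frame/location counterbalancing counts, number of character-string slots
#' per trial, legible word reuse, and blank-block placement. A clean design
#' yields zero violations.
#'
#' @param design a \code{session_design}.
#' @return an object of class \code{design_report} with elements
#'   \code{violations} (character vector) and \code{counts} (list).
#' @export
validate_design <- function(design) {
  tr <- design$trials
  cfg <- design$config
  total <- cfg$n_runs * cfg$trials_per_run
  v <- character(0)

  cc <- table(factor(tr$condition, levels = CONDITIONS))
  if (nrow(tr) != total) v <- c(v, "total trial count")
  if (any(cc != total / 4)) v <- c(v, "condition counts")

  n_words <- (!is.na(tr$word1_id)) + (!is.na(tr$word2_id))
  n_fill <- vapply(strsplit(tr$filler_ids, ";"), length, integer(1))
  if (any(n_words + n_fill != 6)) v <- c(v, "six character strings per trial")

  one <- tr[tr$condition == "ONE", ]
  if (any(is.na(one$word1_id))) v <- c(v, "one-word trial without a word")
  f1 <- sum(one$word1_frame == 1, na.rm = TRUE)
  f2 <- sum(one$word1_frame == 2, na.rm = TRUE)
  top <- sum(one$word1_loc == "TOP", na.rm = TRUE)
  bot <- sum(one$word1_loc == "BOTTOM", na.rm = TRUE)
  if (f1 != f2) v <- c(v, "one-word frame counterbalancing")
  if (top != bot) v <- c(v, "one-word location counterbalancing")

  sim <- tr[tr$condition == "TWO_SIM", ]
  sf <- table(factor(sim$word1_frame, levels = 1:2))
  if (sf[1] != sf[2]) v <- c(v, "two-word simultaneous frame counterbalancing")
  if (any(sim$word1_frame != sim$word2_frame, na.rm = TRUE)) {
    v <- c(v, "simultaneous words must share a frame")
  }

  sq <- tr[tr$condition == "TWO_SEQ", ]
  sl <- table(factor(sq$word1_loc, levels = c("TOP", "BOTTOM")))
  if (sl[1] != sl[2]) v <- c(v, "two-word sequential location counterbalancing")
  if (any(sq$word1_frame == sq$word2_frame, na.rm = TRUE) ||
      any(sq$word1_loc == sq$word2_loc, na.rm = TRUE)) {
    v <- c(v, "sequential words must be in different frames and locations")
  }

  legible <- stats::na.omit(c(tr$word1_id, tr$word2_id))
  if (anyDuplicated(legible)) v <- c(v, "word reuse")

  ends <- tr$trial %% cfg$block_size == 0
  if (any(is.na(tr$blank_after_s[ends]))) v <- c(v, "missing block blank")
  if (any(!is.na(tr$blank_after_s[!ends]))) v <- c(v, "blank outside block end")

  structure(list(
    violations = v,
    counts = list(condition = cc,
                  one_frame = c(frame1 = f1, frame2 = f2),
                  one_loc = c(top = top, bottom = bot),
                  sim_frame = sf, seq_first_loc = sl)
  ), class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  if (length(x$violations) == 0) {
    cat("Design report: no violations\n")
  } else {
    cat("Design report:", length(x$violations), "violation(s):\n")
    cat(paste0(" - ", x$violations, collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Write / read a session design as TSV
#' @param design a \code{session_design}.
#' @param path file path.
#' @export
write_design <- function(design, path) {
  utils::write.table(design$trials, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_design
#' @param config a \code{design_config} to attach to the read design.
#' @export
read_design <- function(path, config = design_config()) {
  tr <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                          na.strings = "")
  tr$word1_loc <- as.character(tr$word1_loc)
  tr$word2_loc <- as.character(tr$word2_loc)
  tr$filler_ids <- as.character(tr$filler_ids)
  structure(list(trials = tr, config = config, word_list_id = NA),
            class = "session_design")
}
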