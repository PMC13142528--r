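# Shared fixtures, built in code at test time.

small_lexicon <- function(n = 96, seed = 1) gen_lexicon(n = n, seed = seed)

small_design <- function(n_runs = 1, trials_per_run = 16, seed = 3,
                         lexicon = small_lexicon()) {
  generate_session(design_config(n_runs = n_runs,
                                 trials_per_run = trials_per_run),
                   lexicon, seed = seed)
}

# a hand-built trial with fully controlled samples (500 Hz by default)
make_trial <- function(x, y, pupil = NULL, t0 = -250, period = 2,
                       onset = 0, offset = 649, trial = 1L) {
  n <- length(x)
  if (is.null(pupil)) pupil <- rep(1000, n)
  trial_gaze(data.frame(t_ms = seq(t0, by = period, length.out = n),
                        x_deg = x, y_deg = y, pupil = pupil),
             stim_onset_ms = onset, stim_offset_ms = offset, trial = trial)
}

# independent trapezoid integration oracle for activation traces
trapezoid <- function(t, a) sum(diff(t) * (a[-1] + a[-length(a)]) / 2)

# independent brute-force Benjamini-Hochberg step-up: find the largest k with
# p_(k) <= k q / m, reject those; adjusted p by direct step-up minimization
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(ranked[i:m] * m / (i:m))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
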