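# Shared fixtures, built in code.

# A small planted penetration with one unit per call site's needs.
tiny_truth <- function(n = c(superficial = 2, granular = 2, deep = 2), ...) {
  ground_truth(n_units = n, ...)
}

# Per-condition counts drawn directly as Poisson rates (fast path for
# calibration loops): a bo_counts-shaped object.
poisson_counts <- function(rates, n_trials = 10, window = c(50, 500)) {
  w <- diff(window) / 1000
  counts <- lapply(rates, function(r) stats::rpois(n_trials, r * w))
  structure(list(counts = counts, pretrial = stats::rpois(n_trials, 2 * 0.4),
                 n = rep(n_trials, 4), window = window, unit_id = "sim"),
            class = "bo_counts")
}

# Deterministic response-function population: a step divergence at
# `onset` ms on a [-100, 500] ms grid.
step_population <- function(n_units = 20, onset = 80, depth = 0.4,
                            jitter_sd = 0) {
  t <- seq(-100, 500)
  base <- ifelse(t >= 50, 1, 0)
  P <- t(vapply(seq_len(n_units), function(i)
    base * (1 + depth * (t >= onset)) + stats::rnorm(length(t), 0, jitter_sd),
    numeric(length(t))))
  N <- t(vapply(seq_len(n_units), function(i)
    base * (1 - depth * (t >= onset)) + stats::rnorm(length(t), 0, jitter_sd),
    numeric(length(t))))
  list(P = P, N = N, t = t)
}
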