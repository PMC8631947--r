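#' Postsynaptic smoothing kernel
#'
#' \deqn{K(t) = (1 - e^{-t/\tau_g})\, e^{-t/\tau_d}, \quad t \ge 0}
#' with growth constant `tau_g` (1 ms) and decay constant `tau_d`
#' (20 ms); zero for `t < 0` and deliberately unnormalized. Its maximum
#' sits at `tau_g * log((tau_g + tau_d)/tau_g)` (~3.045 ms for 1, 20).
#'
#' @param t time, ms (vectorized)
#' @param tau_g,tau_d growth and decay constants, ms, `> 0`
#' @return kernel values
#' @export
psp_kernel <- function(t, tau_g = 1, tau_d = 20) {
  stop_if_not(tau_g > 0 && tau_d > 0, "tau_g and tau_d must be > 0")
  ifelse(t < 0, 0, (1 - exp(-t / tau_g)) * exp(-t / tau_d))
}

# Kernel-smoothed trace of one spike train evaluated on a ms grid.
# Spike times are rounded to 0.1 ms before the (analytic) convolution.
spike_trace <- function(spike_t, t_grid, tau_g = 1, tau_d = 20) {
  if (length(spike_t) == 0) return(numeric(length(t_grid)))
  ts <- round(spike_t * 10) / 10
  ts <- ts[ts <= max(t_grid)]
  if (length(ts) == 0) return(numeric(length(t_grid)))
  colSums(psp_kernel(outer(ts, t_grid, function(s, g) g - s), tau_g, tau_d))
}

# Mean kernel trace over the trials of given ids.
mean_trace <- function(spikes_t, spikes_trial, trial_ids, t_grid,
                       tau_g = 1, tau_d = 20) {
  acc <- numeric(length(t_grid))
  for (id in trial_ids)
    acc <- acc + spike_trace(spikes_t[spikes_trial == id], t_grid, tau_g, tau_d)
  acc / length(trial_ids)
}

#' Normalized preferred / non-preferred response functions for one unit
#'
#' Each trial's spike train is convolved with the postsynaptic kernel,
#' traces are averaged per condition and then across the two contrast
#' polarities, giving one function for the preferred and one for the
#' non-preferred conditions. Both are normalized by the unit's average
#' response across all four conditions in the \[50, 500\] ms window, so
#' the mean of `(pref + nonpref)/2` over that window is 1.
#'
#' @param spikes spike table (`unit_id`, `trial_id`, `t`)
#' @param trials trial table (`trial_id`, `condition_id`)
#' @param unit_id unit to analyse
#' @param pref_conds the preferred condition pair: `c(1, 3)` or `c(2, 4)`
#'   for border ownership (sign of the BOI); `c(1, 2)` or `c(3, 4)` for
#'   contrast polarity
#' @param t_grid output grid, ms (1 ms steps)
#' @param norm_window normalization window, ms
#' @param tau_g,tau_d kernel constants, ms
#' @return list of class `response_function`: `t`, `pref`, `nonpref`,
#'   `norm` (the normalization constant, must be `> 0`)
#' @export
unit_response_function <- function(spikes, trials, unit_id, pref_conds = c(1, 3),
                                   t_grid = seq(-100, 500),
                                   norm_window = c(50, 500),
                                   tau_g = 1, tau_d = 20) {
  stop_if_not(length(pref_conds) == 2, "pref_conds must name two conditions")
  nonpref_conds <- setdiff(1:4, pref_conds)
  sp <- spikes[spikes$unit_id == unit_id, , drop = FALSE]
  cond_mean <- lapply(1:4, function(cond)
    mean_trace(sp$t, sp$trial_id, trials$trial_id[trials$condition_id == cond],
               t_grid, tau_g, tau_d))
  pref <- (cond_mean[[pref_conds[1]]] + cond_mean[[pref_conds[2]]]) / 2
  nonpref <- (cond_mean[[nonpref_conds[1]]] + cond_mean[[nonpref_conds[2]]]) / 2
  win <- t_grid >= norm_window[1] & t_grid <= norm_window[2]
  norm <- mean((pref[win] + nonpref[win]) / 2)
  stop_if_not(norm > 0, "normalization constant <= 0: unit cannot be normalized")
  structure(list(t = t_grid, pref = pref / norm, nonpref = nonpref / norm,
                 norm = norm, unit_id = unit_id),
            class = "response_function")
}

# Stack response functions into population matrices (units x time).
stack_population <- function(rfs) {
  P <- do.call(rbind, lapply(rfs, `[[`, "pref"))
  N <- do.call(rbind, lapply(rfs, `[[`, "nonpref"))
  list(P = P, N = N, t = rfs[[1]]$t)
}

#' Population divergence latency (paired sign-rank)
#'
#' The first time at which the preferred and non-preferred functions
#' differ (Wilcoxon signed rank across units, p < 0.05) at every
#' millisecond of a 20 ms run.
#'
#' @param P,N unit x time matrices of normalized pref / non-pref functions
#' @param t time grid, ms (1 ms steps)
#' @param alpha per-ms significance level
#' @param persist_ms required run length, ms
#' @param search latency search window, ms
#' @return latency in ms, or `NA` if no qualifying run
#' @export
divergence_latency <- function(P, N, t, alpha = 0.05, persist_ms = 20,
                               search = c(0, 500)) {
  stop_if_not(nrow(P) >= 2, "need >= 2 units")
  idx <- which(t >= search[1] & t <= search[2])
  pv <- vapply(idx, function(i) {
    d <- P[, i] - N[, i]
    if (all(d == 0)) return(1)
    suppressWarnings(stats::wilcox.test(d)$p.value)
  }, numeric(1))
  hit <- first_sustained(-pv, -alpha + 1e-15, persist_ms)
  if (is.na(hit)) NA_real_ else t[idx[hit]]
}

#' Border-ownership index function of a population
#'
#' `B(t)` is the difference between the population-mean preferred and
#' non-preferred functions divided by their sum; the denominator is
#' floored at `eps` (flagged) to keep early, near-zero times defined.
#'
#' @param P,N unit x time matrices
#' @param eps denominator floor
#' @return list of class `boi_function`: `B`, `floored` (logical per
#'   sample), the mean curves
#' @export
boi_function <- function(P, N, eps = 1e-6) {
  stop_if_not(nrow(P) >= 1, "empty population")
  mp <- colMeans(P); mn <- colMeans(N)
  den <- mp + mn
  floored <- den < eps
  structure(list(B = (mp - mn) / pmax(den, eps), floored = floored,
                 pref = mp, nonpref = mn),
            class = "boi_function")
}

#' Earliest sustained threshold crossing
#'
#' The earliest time `t` with `f >= threshold` throughout
#' `[t, t + persist_ms)`; `NA` when no such time exists in the search
#' window.
#'
#' @param f function values on `t`
#' @param t time grid, ms (1 ms steps)
#' @param threshold crossing level
#' @param persist_ms persistence requirement, ms
#' @param search search window, ms
#' @return latency in ms or `NA`
#' @export
threshold_latency <- function(f, t, threshold, persist_ms = 20,
                              search = c(0, 500)) {
  idx <- which(t >= search[1] & t <= search[2])
  x <- f[idx]
  x[is.na(x)] <- -Inf
  hit <- first_sustained(x, threshold, persist_ms)
  if (is.na(hit)) NA_real_ else t[idx[hit]]
}

#' Threshold latency of a population's BOI function
#'
#' Convenience composition of [boi_function()] and
#' [threshold_latency()].
#'
#' @param P,N unit x time matrices
#' @param t time grid, ms
#' @param threshold crossing level
#' @param persist_ms,search latency parameters
#' @param eps denominator floor
#' @return latency in ms or `NA`
#' @export
population_latency <- function(P, N, t, threshold, persist_ms = 20,
                               search = c(0, 500), eps = 1e-6) {
  threshold_latency(boi_function(P, N, eps)$B, t, threshold, persist_ms, search)
}

# Per-shuffle "highest threshold with a defined latency": rows of B get a
# rolling minimum over the persistence window, then a row maximum.
shuffle_maxmin <- function(Bm, t, persist_ms, search) {
  idx <- which(t >= search[1] & t <= search[2])
  sub <- Bm[, idx, drop = FALSE]
  sub[is.na(sub)] <- -Inf
  apply(roll_min_rows(sub, persist_ms), 1, max)
}

# Smallest multiple of `step` at which fewer than `rate` of the shuffles
# keep a defined latency.
threshold_from_maxmin <- function(M, step = 0.001, rate = 0.01) {
  n <- length(M)
  k_allowed <- ceiling(rate * n) - 1          # max #shuffles allowed >= thr
  crit <- sort(M, decreasing = TRUE)[k_allowed + 1]
  floor(crit / step) * step + step            # strictly above crit
}

#' Shuffle-calibrated latency threshold
#'
#' For each compartment the preferred / non-preferred labels of every
#' unit are shuffled (independent fair coin per unit, respecting the
#' contrast-polarity pairing), the population `B(t)` is recomputed, and
#' the lowest threshold (grid 0.001) at which fewer than 1% of shuffles
#' keep a defined latency (20 ms persistence) is found. The highest
#' value across compartments is returned, so every compartment is timed
#' with the same threshold.
#'
#' @param pops named list of compartments, each a list with matrices `P`
#'   and `N` (units x time)
#' @param t time grid, ms
#' @param n_shuffles shuffles per compartment
#' @param step threshold grid
#' @param persist_ms persistence, ms
#' @param search latency search window, ms
#' @param seed integer seed
#' @return list: `threshold` (max across compartments),
#'   `per_compartment` named vector
#' @export
shuffle_threshold <- function(pops, t, n_shuffles = 1000, step = 0.001,
                              persist_ms = 20, search = c(0, 500), seed = 1) {
  stop_if_not(length(pops) >= 1, "no compartments")
  # every compartment uses the same shuffle stream, so identical
  # populations yield identical thresholds
  per <- vapply(pops, function(pop) with_seed(seed, {
    P <- pop$P; N <- pop$N
    n <- nrow(P)
    if (all(P == 0) && all(N == 0)) stop("degenerate population: all-zero functions",
                                         call. = FALSE)
    S <- matrix(stats::rbinom(n_shuffles * n, 1, 0.5), n_shuffles, n)
    MP <- (S %*% P + (1 - S) %*% N) / n
    MN <- (S %*% N + (1 - S) %*% P) / n
    Bm <- (MP - MN) / pmax(MP + MN, 1e-6)
    threshold_from_maxmin(shuffle_maxmin(Bm, t, persist_ms, search), step)
  }), numeric(1))
  list(threshold = max(per), per_compartment = per)
}

# Bootstrap replicate latencies for a (P, N) population: units are
# resampled with replacement; the full pipeline (mean functions -> B(t)
# -> threshold latency) is recomputed per replicate. Vectorized through
# a multinomial weight matrix.
boot_latency_replicates <- function(P, N, t, threshold, n_boot = 2000,
                                    persist_ms = 20, search = c(0, 500),
                                    seed = 1) {
  n <- nrow(P)
  with_seed(seed, {
    W <- stats::rmultinom(n_boot, n, rep(1, n)) # n x n_boot
    MP <- t(W) %*% P / n
    MN <- t(W) %*% N / n
    Bm <- (MP - MN) / pmax(MP + MN, 1e-6)
    replicate_latencies(Bm, t, threshold, persist_ms, search)
  })
}

replicate_latencies <- function(Bm, t, threshold, persist_ms, search) {
  idx <- which(t >= search[1] & t <= search[2])
  sub <- Bm[, idx, drop = FALSE]
  sub[is.na(sub)] <- -Inf
  rm_ <- roll_min_rows(sub, persist_ms)
  hit <- apply(rm_ >= threshold, 1, function(r) {
    w <- which(r); if (length(w)) w[1] else NA_integer_
  })
  t[idx[hit]]
}

# Jackknife latencies (leave-one-unit-out) for the BCa acceleration.
jackknife_latencies <- function(P, N, t, threshold, persist_ms, search) {
  n <- nrow(P)
  SP <- colSums(P); SN <- colSums(N)
  MP <- (matrix(SP, n, ncol(P), byrow = TRUE) - P) / (n - 1)
  MN <- (matrix(SN, n, ncol(N), byrow = TRUE) - N) / (n - 1)
  Bm <- (MP - MN) / pmax(MP + MN, 1e-6)
  replicate_latencies(Bm, t, threshold, persist_ms, search)
}

# Bias-corrected and accelerated percentile interval from replicate and
# jackknife values; NA replicates are assumed already dropped.
bca_interval <- function(theta_boot, theta_hat, theta_jack, conf = 0.95) {
  b <- length(theta_boot)
  if (b == 0 || length(unique(theta_boot)) == 1) {
    ci <- rep(if (b) theta_boot[1] else theta_hat, 2)
    return(ci)
  }
  p0 <- (sum(theta_boot < theta_hat) + 0.5 * sum(theta_boot == theta_hat)) / b
  p0 <- min(max(p0, 1 / (2 * b)), 1 - 1 / (2 * b))
  z0 <- stats::qnorm(p0)
  tj <- theta_jack[!is.na(theta_jack)]
  if (length(tj) >= 3 && stats::sd(tj) > 0) {
    d <- mean(tj) - tj
    a <- sum(d^3) / (6 * sum(d^2)^1.5)
  } else a <- 0
  alpha <- (1 - conf) / 2
  zl <- stats::qnorm(alpha); zu <- stats::qnorm(1 - alpha)
  adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  unname(stats::quantile(theta_boot, c(adj(zl), adj(zu)), type = 6,
                         na.rm = TRUE))
}

#' BCa bootstrap confidence interval for a population latency
#'
#' Units are resampled with replacement and the full latency pipeline
#' is recomputed per replicate; the 95% interval uses the
#' bias-corrected and accelerated percentile method. Replicates with an
#' undefined latency are dropped and their fraction reported; above 50%
#' undefined the interval is declared undefined.
#'
#' @param P,N unit x time matrices
#' @param t time grid, ms
#' @param threshold latency threshold (from [shuffle_threshold()])
#' @param n_boot bootstrap replicates
#' @param persist_ms,search latency parameters
#' @param conf confidence level
#' @param seed integer seed
#' @return list of class `latency_estimate`: `latency`, `ci95`,
#'   `frac_undefined`, `replicates`, `threshold`, `method`
#' @export
bootstrap_latency_ci <- function(P, N, t, threshold, n_boot = 2000,
                                 persist_ms = 20, search = c(0, 500),
                                 conf = 0.95, seed = 1) {
  theta_hat <- population_latency(P, N, t, threshold, persist_ms, search)
  stop_if_not(!is.na(theta_hat), "observed latency undefined")
  reps <- boot_latency_replicates(P, N, t, threshold, n_boot, persist_ms,
                                  search, seed)
  frac_na <- mean(is.na(reps))
  ok <- reps[!is.na(reps)]
  if (nrow(P) < 2) {
    warning("single-unit population: degenerate resampling, CI = point estimate")
    ci <- c(theta_hat, theta_hat)
  } else if (frac_na > 0.5) {
    warning(sprintf("%.0f%% of bootstrap replicates undefined: CI undefined",
                    100 * frac_na))
    ci <- c(NA_real_, NA_real_)
  } else {
    jack <- jackknife_latencies(P, N, t, threshold, persist_ms, search)
    ci <- bca_interval(ok, theta_hat, jack, conf)
  }
  structure(list(latency = theta_hat, ci95 = ci, frac_undefined = frac_na,
                 replicates = reps, threshold = threshold,
                 persistence_ms = persist_ms, method = "boi_threshold"),
            class = "latency_estimate")
}

#' @export
print.latency_estimate <- function(x, ...) {
  cat(sprintf("<latency_estimate> %s ms, 95%% CI [%s, %s] (%s, threshold %.3g)\n",
              format(x$latency), format(x$ci95[1]), format(x$ci95[2]),
              x$method, x$threshold))
  invisible(x)
}

#' One-sided bootstrap comparison of two population latencies
#'
#' Tests whether population A's latency is shorter than population B's:
#' p is the fraction of bootstrap sample pairs on which
#' `latency_B - latency_A <= 0`. Pairs with an undefined member are
#' dropped (fraction reported).
#'
#' @param pop_a,pop_b lists with `P`, `N` matrices (population A is the
#'   putatively earlier one)
#' @param t time grid, ms
#' @param threshold shared latency threshold
#' @param n_boot bootstrap replicates
#' @param persist_ms,search latency parameters
#' @param seed integer seed
#' @return list: `p`, `latency_a`, `latency_b`, `frac_dropped`
#' @export
compare_latencies <- function(pop_a, pop_b, t, threshold, n_boot = 2000,
                              persist_ms = 20, search = c(0, 500), seed = 1) {
  la <- population_latency(pop_a$P, pop_a$N, t, threshold, persist_ms, search)
  lb <- population_latency(pop_b$P, pop_b$N, t, threshold, persist_ms, search)
  stop_if_not(!is.na(la) && !is.na(lb), "both observed latencies must be defined")
  ra <- boot_latency_replicates(pop_a$P, pop_a$N, t, threshold, n_boot,
                                persist_ms, search, derive_seed(seed, 1L))
  rb <- boot_latency_replicates(pop_b$P, pop_b$N, t, threshold, n_boot,
                                persist_ms, search, derive_seed(seed, 2L))
  ok <- !is.na(ra) & !is.na(rb)
  stop_if_not(any(ok), "all bootstrap pairs undefined")
  list(p = mean((rb[ok] - ra[ok]) <= 0), latency_a = la, latency_b = lb,
       frac_dropped = mean(!ok))
}

#' Border-ownership reliability function of one unit
#'
#' For each position of a 100 ms sliding window, `n_sets` sets of four
#' spike trains are drawn (one uniformly random trial per condition,
#' with replacement across sets). A set votes with the unit
#' (`A(j) = 1`) when the sign of `(C1 + C3) - (C2 + C4)` matches the
#' unit's across-trial preferred side `S = sgn[(R1 + R3) - (R2 + R4)]`
#' (rates from \[50, 500\] ms), and against it (`B(j) = 1`) when it
#' matches `-S`. `BOR = sum(A) / (sum(A) + sum(B))`. Window positions
#' are indexed by the window's right edge; positions with fewer than 10
#' spikes across conditions, or with no non-tied set, are undefined.
#'
#' @param spikes,trials,unit_id as in [bo_counts()]
#' @param window_ms sliding window length, ms
#' @param step_ms window step, ms
#' @param n_sets number of resampled trial sets
#' @param min_spikes minimum total spikes in a window
#' @param t_range right-edge range, ms
#' @param seed integer seed
#' @return list of class `bor_function`: `t` (right edges), `bor`
#'   (values in \[0,1\] or `NA`), `S`, `n_sets`; `NULL` with a warning
#'   when `S = 0`
#' @export
bor_function <- function(spikes, trials, unit_id, window_ms = 100, step_ms = 1,
                         n_sets = 10000, min_spikes = 10,
                         t_range = c(0, 500), seed = 1) {
  cnt <- bo_counts(spikes, trials, unit_id)
  r <- vapply(cnt$counts, mean, numeric(1))
  S <- sign((r[1] + r[3]) - (r[2] + r[4]))
  if (S == 0) {
    warning("unit ", unit_id, ": tied across-trial preference (S = 0), skipped")
    return(NULL)
  }
  sp <- spikes[spikes$unit_id == unit_id, , drop = FALSE]
  edges <- seq(t_range[1], t_range[2], by = step_ms)
  trial_counts <- function(cond) {
    ids <- trials$trial_id[trials$condition_id == cond]
    m <- vapply(ids, function(id) {
      ts <- sort(sp$t[sp$trial_id == id])
      findInterval(edges - 1e-9, ts) - findInterval(edges - window_ms - 1e-9, ts)
    }, numeric(length(edges)))
    t(m)                                      # trials x edges
  }
  TC <- lapply(1:4, trial_counts)
  total <- Reduce(`+`, lapply(TC, colSums))
  with_seed(seed, {
    idx <- lapply(TC, function(m) sample.int(nrow(m), n_sets, replace = TRUE))
    nA <- numeric(length(edges)); nB <- numeric(length(edges))
    chunk <- 100
    for (a in seq(1, length(edges), by = chunk)) {
      b <- min(a + chunk - 1, length(edges))
      D <- TC[[1]][idx[[1]], a:b, drop = FALSE] +
        TC[[3]][idx[[3]], a:b, drop = FALSE] -
        TC[[2]][idx[[2]], a:b, drop = FALSE] -
        TC[[4]][idx[[4]], a:b, drop = FALSE]
      sg <- sign(D)
      nA[a:b] <- colSums(sg == S)
      nB[a:b] <- colSums(sg == -S)
    }
    bor <- nA / (nA + nB)
    bor[(nA + nB) == 0] <- NA
    bor[total < min_spikes] <- NA
    structure(list(t = edges, bor = bor, S = S, n_sets = n_sets,
                   window_ms = window_ms, unit_id = unit_id),
              class = "bor_function")
  })
}

#' Population latency of mean border-ownership reliability
#'
#' Unit BOR functions are averaged per time point (undefined values
#' dropped), and the same shuffle-calibrated threshold machinery as for
#' the BOI functions is applied: the per-unit null flips BOR to
#' `1 - BOR` with probability one half (equivalent to swapping the
#' preferred side), and the threshold is the lowest grid value at which
#' fewer than 1% of shuffled mean functions keep a defined latency.
#'
#' @param bor_mat unit x time matrix of BOR values (may contain `NA`)
#' @param t right-edge time grid, ms
#' @param n_shuffles shuffles for the threshold
#' @param step threshold grid
#' @param persist_ms,search latency parameters
#' @param n_boot bootstrap replicates for the CI (0 to skip)
#' @param seed integer seed
#' @return a `latency_estimate` with extra fields `mean_bor` and
#'   `threshold`
#' @export
bor_population_latency <- function(bor_mat, t, n_shuffles = 1000, step = 0.001,
                                   persist_ms = 20, search = c(0, 500),
                                   n_boot = 2000, seed = 1) {
  nunit <- nrow(bor_mat)
  stop_if_not(nunit >= 2, "need >= 2 units")
  mean_na <- function(M) colSums(ifelse(is.na(M), 0, M)) /
    pmax(colSums(!is.na(M)), 1)
  defined <- colSums(!is.na(bor_mat)) > 0
  thr <- with_seed(derive_seed(seed, 1L), {
    S <- matrix(stats::rbinom(n_shuffles * nunit, 1, 0.5), n_shuffles, nunit)
    ok <- !is.na(bor_mat)
    V <- ifelse(ok, bor_mat, 0)
    Vf <- ifelse(ok, 1 - bor_mat, 0)
    cnt <- colSums(ok)
    Bm <- (S %*% V + (1 - S) %*% Vf) / matrix(pmax(cnt, 1), n_shuffles,
                                              ncol(bor_mat), byrow = TRUE)
    Bm[, cnt == 0] <- NA
    threshold_from_maxmin(shuffle_maxmin(Bm, t, persist_ms, search), step)
  })
  curve <- mean_na(bor_mat)
  curve[!defined] <- NA
  lat <- threshold_latency(curve, t, thr, persist_ms, search)
  reps <- with_seed(derive_seed(seed, 2L), {
    if (n_boot > 0) {
      W <- matrix(sample.int(nunit, n_boot * nunit, replace = TRUE), n_boot)
      vapply(seq_len(n_boot), function(b) {
        cm <- mean_na(bor_mat[W[b, ], , drop = FALSE])
        cm[colSums(!is.na(bor_mat[W[b, ], , drop = FALSE])) == 0] <- NA
        threshold_latency(cm, t, thr, persist_ms, search)
      }, numeric(1))
    } else numeric(0)
  })
  ok <- reps[!is.na(reps)]
  ci <- if (is.na(lat) || length(ok) == 0 || mean(is.na(reps)) > 0.5)
    c(NA_real_, NA_real_)
  else {
    jack <- vapply(seq_len(nunit), function(i) {
      cm <- mean_na(bor_mat[-i, , drop = FALSE])
      cm[colSums(!is.na(bor_mat[-i, , drop = FALSE])) == 0] <- NA
      threshold_latency(cm, t, thr, persist_ms, search)
    }, numeric(1))
    bca_interval(ok, lat, jack)
  }
  structure(list(latency = lat, ci95 = ci,
                 frac_undefined = if (length(reps)) mean(is.na(reps)) else NA,
                 replicates = reps, threshold = thr, persistence_ms = persist_ms,
                 mean_bor = curve, method = "bor_threshold"),
            class = "latency_estimate")
}

#' Contrast-polarity preferred pair for one unit
#'
#' The condition pair (\{1,2\} or \{3,4\}) with the higher mean evoked
#' rate; feeding it to [unit_response_function()] as `pref_conds`
#' yields the contrast-polarity analogue of the border-ownership
#' response functions, and the same latency machinery applies.
#'
#' @param counts a [bo_counts()] object
#' @return `c(1, 2)` or `c(3, 4)`
#' @export
cp_pref_conds <- function(counts) {
  r <- vapply(counts$counts, mean, numeric(1))
  if ((r[1] + r[2]) >= (r[3] + r[4])) c(1, 2) else c(3, 4)
}

#' Ring-response latency per compartment
#'
#' Unit responses to small flashed rings in the receptive field,
#' normalized to peak 1 per unit, are averaged per compartment. The
#' latency threshold is a third of the way from baseline to peak,
#' `B* + (1 - B*)/3`, using the highest pre-stimulus baseline `B*`
#' across compartments so all compartments are timed against the same
#' level.
#'
#' @param pops named list of unit x time matrices of (unnormalized)
#'   kernel-smoothed ring responses
#' @param t time grid, ms (must extend before 0 for the baseline)
#' @param baseline_window window for the baseline, ms
#' @param persist_ms,search latency parameters
#' @param n_boot bootstrap replicates for CIs (0 to skip)
#' @param seed integer seed
#' @return list of class `ring_latency`: per-compartment `latency`,
#'   `ci95`, plus `threshold`, `baselines`, `curves`
#' @export
ring_latency <- function(pops, t, baseline_window = c(-100, 0),
                         persist_ms = 20, search = c(0, 500),
                         n_boot = 2000, seed = 1) {
  norm_rows <- function(M) {
    pk <- apply(M, 1, max)
    stop_if_not(all(pk > 0), "flat unit function: peak is zero")
    M / pk
  }
  pops <- lapply(pops, norm_rows)
  bsel <- t >= baseline_window[1] & t < baseline_window[2]
  curves <- lapply(pops, colMeans)
  baselines <- vapply(curves, function(f) mean(f[bsel]), numeric(1))
  bstar <- max(baselines)
  thr <- bstar + (1 - bstar) / 3
  res <- lapply(names(pops), function(nm) {
    f <- curves[[nm]]
    if (max(f) - baselines[nm] < 1e-9)
      return(list(latency = NA_real_, ci95 = c(NA_real_, NA_real_),
                  replicates = numeric(0)))
    lat <- threshold_latency(f, t, thr, persist_ms, search)
    M <- pops[[nm]]
    reps <- with_seed(derive_seed(seed, match(nm, names(pops))), {
      if (n_boot > 0) {
        W <- stats::rmultinom(n_boot, nrow(M), rep(1, nrow(M)))
        Bm <- t(W) %*% M / nrow(M)
        replicate_latencies(Bm, t, thr, persist_ms, search)
      } else numeric(0)
    })
    ok <- reps[!is.na(reps)]
    ci <- if (is.na(lat) || length(ok) == 0) c(NA_real_, NA_real_)
    else {
      n <- nrow(M)
      SP <- colSums(M)
      MJ <- (matrix(SP, n, ncol(M), byrow = TRUE) - M) / (n - 1)
      jack <- replicate_latencies(MJ, t, thr, persist_ms, search)
      bca_interval(ok, lat, jack)
    }
    list(latency = lat, ci95 = ci, replicates = reps)
  })
  names(res) <- names(pops)
  structure(list(compartments = res, threshold = thr, baselines = baselines,
                 curves = curves, t = t),
            class = "ring_latency")
}

#' @export
print.ring_latency <- function(x, ...) {
  cat(sprintf("<ring_latency> threshold %.3f\n", x$threshold))
  for (nm in names(x$compartments))
    cat(sprintf("  %-12s %s ms\n", nm, format(x$compartments[[nm]]$latency)))
  invisible(x)
}

#' One-sided comparison of two bootstrap replicate sets
#'
#' Shared helper for latency estimates that already carry replicates
#' (e.g. [bor_population_latency()], [ring_latency()] compartments):
#' p is the fraction of pairs with `latency_B - latency_A <= 0`.
#'
#' @param reps_a,reps_b replicate latency vectors (A putatively earlier)
#' @return list: `p`, `frac_dropped`
#' @export
compare_replicates <- function(reps_a, reps_b) {
  n <- min(length(reps_a), length(reps_b))
  ra <- reps_a[seq_len(n)]; rb <- reps_b[seq_len(n)]
  ok <- !is.na(ra) & !is.na(rb)
  stop_if_not(any(ok), "all bootstrap pairs undefined")
  list(p = mean((rb[ok] - ra[ok]) <= 0), frac_dropped = mean(!ok))
}

#' Sample-size subsampling control for latency differences
#'
#' Repeatedly subsamples every compartment to a common unit count
#' (without replacement) and recomputes the threshold latency, to check
#' that latency differences are not explained by unequal sample sizes.
#'
#' @param pops named list of `list(P, N)` populations
#' @param target_n common subsample size (at most the smallest
#'   compartment)
#' @param n_repeats subsampling repeats
#' @param threshold latency threshold
#' @param t time grid, ms
#' @param persist_ms,search latency parameters
#' @param seed integer seed
#' @return matrix `n_repeats` x compartments of latencies (`NA` when
#'   undefined)
#' @export
subsample_latency <- function(pops, target_n, n_repeats = 100, threshold, t,
                              persist_ms = 20, search = c(0, 500), seed = 1) {
  for (nm in names(pops))
    stop_if_not(target_n <= nrow(pops[[nm]]$P),
                paste0("target_n exceeds compartment size: ", nm))
  with_seed(seed, {
    out <- sapply(names(pops), function(nm) {
      P <- pops[[nm]]$P; N <- pops[[nm]]$N
      vapply(seq_len(n_repeats), function(r) {
        i <- sample.int(nrow(P), target_n)
        population_latency(P[i, , drop = FALSE], N[i, , drop = FALSE],
                           t, threshold, persist_ms, search)
      }, numeric(1))
    })
    matrix(out, nrow = n_repeats, dimnames = list(NULL, names(pops)))
  })
}
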