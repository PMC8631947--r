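test_that("postsynaptic kernel closed form: boundaries and analytic argmax", {
  expect_equal(psp_kernel(0), 0)
  expect_lt(psp_kernel(1e4), 1e-12)
  expect_equal(psp_kernel(-5), 0)
  t_star <- 1 * log((1 + 20) / 1)
  num <- stats::optimize(psp_kernel, c(0, 50), maximum = TRUE)$maximum
  expect_lt(abs(t_star - num), 0.01)
  expect_error(psp_kernel(1, tau_g = 0), "tau_g")
})

test_that("response functions are symmetric, normalized and scale invariant", {
  trials <- data.frame(trial_id = 1:8, condition_id = rep(1:4, each = 2))
  tt <- seq(60, 480, by = 7)
  spikes <- do.call(rbind, lapply(1:8, function(id)
    data.frame(unit_id = "u", trial_id = id, t = tt)))
  rf <- unit_response_function(spikes, trials, "u")
  # identical trains in all conditions -> identical functions
  expect_equal(rf$pref, rf$nonpref)
  win <- rf$t >= 50 & rf$t <= 500
  expect_equal(mean((rf$pref[win] + rf$nonpref[win]) / 2), 1, tolerance = 1e-9)
  # doubling every spike leaves the normalized functions unchanged
  rf2 <- unit_response_function(rbind(spikes, spikes), trials, "u")
  expect_equal(rf2$pref, rf$pref, tolerance = 1e-9)
  # no spikes: normalization impossible
  empty <- spikes[0, ]
  expect_error(unit_response_function(empty, trials, "u"), "normaliz")
})

test_that("divergence latency obeys the persistence rule", {
  pop <- step_population(30, onset = 80, jitter_sd = 0.01)
  expect_equal(divergence_latency(pop$P, pop$N, pop$t), 80, tolerance = 1)
  # no divergence -> undefined
  same <- step_population(30, onset = 80, depth = 0)
  expect_true(is.na(divergence_latency(same$P, same$N, same$t)))
  # a 10 ms transient does not qualify
  trans <- step_population(30, onset = 80, jitter_sd = 0.01)
  mask <- pop$t >= 90
  trans$P[, mask] <- trans$N[, mask] <- 1
  expect_true(is.na(divergence_latency(trans$P, trans$N, trans$t)))
})

test_that("B(t) arithmetic, bounds and exchange antisymmetry", {
  t <- seq(-100, 500)
  N <- matrix(rep(1, length(t)), 1)
  B <- boi_function(3 * N, N)
  expect_true(all(abs(B$B - 0.5) < 1e-12))
  expect_true(all(boi_function(N, N)$B == 0))
  set.seed(1)
  P <- matrix(runif(10 * length(t)), 10)
  Q <- matrix(runif(10 * length(t)), 10)
  expect_true(all(abs(boi_function(P, Q)$B) <= 1))
  expect_equal(boi_function(Q, P)$B, -boi_function(P, Q)$B)
})

test_that("threshold latency: crossing, persistence and monotonicity", {
  t <- 0:500
  f <- ifelse(t >= 80, 0.5, 0)
  expect_equal(threshold_latency(f, t, 0.2), 80)
  expect_true(is.na(threshold_latency(f, t, 0.7)))
  blip <- ifelse(t >= 60 & t < 70, 0.5, ifelse(t >= 120, 0.5, 0))
  expect_equal(threshold_latency(blip, t, 0.2), 120)
  # raising the threshold never decreases a defined latency
  g <- pmin(1, pmax(0, (t - 100) / 200)) # ramp
  l1 <- threshold_latency(g, t, 0.2); l2 <- threshold_latency(g, t, 0.6)
  expect_gte(l2, l1)
})

test_that("shuffle threshold is symmetric and self-consistent under the null", {
  set.seed(2)
  pop <- step_population(40, onset = 75, depth = 0.3, jitter_sd = 0.05)
  st <- shuffle_threshold(list(a = pop, b = pop), pop$t, n_shuffles = 400,
                          seed = 3)
  expect_equal(st$per_compartment[["a"]], st$per_compartment[["b"]])
  # under a null population the returned threshold keeps < 1% of fresh
  # shuffles with a defined latency
  null <- step_population(40, onset = 75, depth = 0, jitter_sd = 0.05)
  stn <- shuffle_threshold(list(x = null), null$t, n_shuffles = 500, seed = 4)
  n <- nrow(null$P)
  with(null, {
    S <- matrix(stats::rbinom(300 * n, 1, 0.5), 300, n)
    MP <- (S %*% P + (1 - S) %*% N) / n
    MN <- (S %*% N + (1 - S) %*% P) / n
    Bm <- (MP - MN) / pmax(MP + MN, 1e-6)
    lat <- laminarbo:::replicate_latencies(Bm, t, stn$threshold, 20, c(0, 500))
    expect_lt(mean(!is.na(lat)), 0.03)
  })
  expect_error(shuffle_threshold(list(z = list(P = matrix(0, 3, 601),
                                               N = matrix(0, 3, 601))),
                                 pop$t, 100, seed = 1), "degenerate")
})

test_that("BCa machinery agrees with the reference implementation on a smooth statistic", {
  skip_if_not_installed("boot")
  set.seed(5)
  x <- rnorm(40, 10, 2)
  bo <- boot::boot(x, function(d, i) mean(d[i]), R = 2000)
  ref <- boot::boot.ci(bo, type = "bca")$bca[4:5]
  jack <- vapply(seq_along(x), function(i) mean(x[-i]), numeric(1))
  mine <- laminarbo:::bca_interval(as.numeric(bo$t), mean(x), jack)
  expect_equal(mine, ref, tolerance = 0.05)
})

test_that("latency CIs cover a constructed truth and degenerate cases warn", {
  pop <- step_population(60, onset = 90, depth = 0.4, jitter_sd = 0.02)
  ci <- bootstrap_latency_ci(pop$P, pop$N, pop$t, threshold = 0.2,
                             n_boot = 300, seed = 6)
  expect_equal(ci$latency, 90, tolerance = 1)
  expect_lt(ci$ci95[2] - ci$ci95[1], 2)
  expect_gte(ci$latency, ci$ci95[1])
  expect_lte(ci$latency, ci$ci95[2])
  one <- step_population(1, onset = 90, depth = 0.4)
  expect_warning(ci1 <- bootstrap_latency_ci(one$P, one$N, one$t, 0.2,
                                             n_boot = 50, seed = 7),
                 "single-unit")
  expect_equal(ci1$ci95, c(90, 90))
})

test_that("identical populations compare at p near one half", {
  # per-unit onset spread so bootstrap latencies actually vary
  set.seed(8)
  t <- seq(-100, 500)
  onsets <- rnorm(50, 85, 15)
  base <- ifelse(t >= 50, 1, 0)
  P <- t(vapply(onsets, function(o) base * (1 + 0.4 * (t >= o)),
                numeric(length(t))))
  N <- t(vapply(onsets, function(o) base * (1 - 0.4 * (t >= o)),
                numeric(length(t))))
  pop <- list(P = P, N = N, t = t)
  cmp <- compare_latencies(pop, pop, t, threshold = 0.2, n_boot = 400, seed = 9)
  expect_gt(cmp$p, 0.3); expect_lt(cmp$p, 0.8)
})

test_that("BOR is 1 for strictly ordered counts and undefined under 10 spikes", {
  trials <- data.frame(trial_id = 1:8, condition_id = rep(1:4, 2))
  dense <- seq(10, 490, by = 4)     # 120 spikes in pref conditions
  sparse <- seq(20, 480, by = 40)   # 12 in non-pref
  spikes <- rbind(
    do.call(rbind, lapply(which(trials$condition_id %in% c(1, 3)), function(id)
      data.frame(unit_id = "u", trial_id = id, t = dense))),
    do.call(rbind, lapply(which(trials$condition_id %in% c(2, 4)), function(id)
      data.frame(unit_id = "u", trial_id = id, t = sparse))))
  bf <- bor_function(spikes, trials, "u", n_sets = 200, seed = 10)
  expect_equal(bf$S, 1)
  defined <- !is.na(bf$bor)
  expect_true(any(defined))
  expect_true(all(bf$bor[defined] == 1))
  # windows before spikes accumulate: fewer than 10 total spikes -> NA
  expect_true(all(is.na(bf$bor[bf$t < 10])))
})

test_that("BOR is near one half for side-symmetric rates and invariant to relabelling", {
  # many trials so the trial-sampling noise in S and the window counts
  # averages out
  gt <- ground_truth(n_units = c(deep = 1), m = 0, cp_modulation = 0, seed = 11)
  s <- sim_bo_session(gt, 60, seed = 12)
  bf <- bor_function(s$spikes, s$trials, "u01", n_sets = 4000, seed = 13)
  late <- bf$bor[bf$t >= 200 & !is.na(bf$bor)]
  expect_lt(abs(mean(late) - 0.5), 0.05)
  # relabel trials within conditions: same distribution of counts
  tr2 <- s$trials
  for (cond in 1:4) {
    ids <- tr2$trial_id[tr2$condition_id == cond]
    tr2$trial_id[tr2$condition_id == cond] <- sample(ids)
  }
  bf2 <- bor_function(s$spikes, tr2, "u01", n_sets = 4000, seed = 13)
  expect_equal(bf2$S, bf$S)
  # zero-preference unit: S = 0 is skipped with a diagnostic
  trials0 <- data.frame(trial_id = 1:4, condition_id = 1:4)
  sp0 <- do.call(rbind, lapply(1:4, function(id)
    data.frame(unit_id = "u", trial_id = id, t = seq(60, 480, by = 10))))
  expect_warning(out <- bor_function(sp0, trials0, "u", n_sets = 100, seed = 1),
                 "S = 0")
  expect_null(out)
})

test_that("population BOR latency finds a constructed onset at the window edge", {
  t <- 0:500
  mk_unit <- function() {
    b <- ifelse(t >= 100, 1, 0.5) + stats::rnorm(length(t), 0, 0.01)
    b[t < 30] <- NA
    pmin(pmax(b, 0), 1)
  }
  set.seed(14)
  bm <- t(replicate(30, mk_unit()))
  est <- bor_population_latency(bm, t, n_shuffles = 400, n_boot = 200, seed = 15)
  expect_equal(est$latency, 100, tolerance = 2)
  # null populations keep no defined latency
  set.seed(16)
  bm0 <- t(replicate(30, pmin(pmax(0.5 + rnorm(length(t), 0, 0.02), 0), 1)))
  est0 <- bor_population_latency(bm0, t, n_shuffles = 400, n_boot = 0, seed = 17)
  expect_true(is.na(est0$latency))
})

test_that("contrast-polarity machinery reuses the response-function pipeline", {
  gt <- ground_truth(n_units = c(deep = 25), m = 0, cp_modulation = 0.3, seed = 18)
  s <- sim_bo_session(gt, 10, seed = 19)
  rfs <- lapply(gt$units$unit_id, function(uid) {
    cnt <- bo_counts(s$spikes, s$trials, uid)
    unit_response_function(s$spikes, s$trials, uid, cp_pref_conds(cnt))
  })
  pop <- laminarbo:::stack_population(rfs)
  Bcp <- boi_function(pop$P, pop$N)
  plateau <- mean(Bcp$B[rfs[[1]]$t >= 200 & rfs[[1]]$t <= 500])
  # planted cp 0.3 attenuated by the unmodulated baseline: 0.3 * 50/52
  expect_lt(abs(plateau - 0.3), 0.05)
  # polarity-symmetric generator stays flat near zero
  gt0 <- ground_truth(n_units = c(deep = 25), m = 0, cp_modulation = 0, seed = 20)
  s0 <- sim_bo_session(gt0, 10, seed = 21)
  rfs0 <- lapply(gt0$units$unit_id, function(uid)
    unit_response_function(s0$spikes, s0$trials, uid, c(1, 2)))
  pop0 <- laminarbo:::stack_population(rfs0)
  B0 <- boi_function(pop0$P, pop0$N)
  expect_lt(abs(mean(B0$B[rfs0[[1]]$t >= 200 & rfs0[[1]]$t <= 500])), 0.05)
})

test_that("ring latency: instant step, identical populations, flat errors", {
  t <- seq(-200, 400)
  step <- matrix(rep(ifelse(t >= 50, 1, 0), 10), 10, byrow = TRUE)
  rl <- ring_latency(list(a = step, b = step), t, n_boot = 50, seed = 22)
  expect_equal(rl$threshold, 1 / 3, tolerance = 1e-9)
  expect_equal(rl$compartments$a$latency, 50)
  cmp <- compare_replicates(rl$compartments$a$replicates,
                            rl$compartments$b$replicates)
  expect_equal(cmp$p, 1)   # all differences are exactly zero
  flat <- matrix(1, 5, length(t))
  expect_true(is.na(ring_latency(list(f = flat), t, n_boot = 0,
                                 seed = 1)$compartments$f$latency))
})

test_that("subsampling at full size reproduces the point estimate", {
  pop <- step_population(20, onset = 85, depth = 0.4, jitter_sd = 0.03)
  full <- population_latency(pop$P, pop$N, pop$t, 0.2)
  ss <- subsample_latency(list(a = pop), target_n = 20, n_repeats = 3,
                          threshold = 0.2, t = pop$t, seed = 23)
  expect_true(all(ss[, "a"] == full))
  expect_error(subsample_latency(list(a = pop), target_n = 21, n_repeats = 1,
                                 threshold = 0.2, t = pop$t), "exceeds")
})
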