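test_that("orientation selectivity combines the rank test with the z criterion", {
  set.seed(1)
  os <- sim_orientation_session(preferred = 45, kappa = 2, n_trials = 8, seed = 2)
  a <- analyze_orientation_session(os$trials, os$spikes)
  expect_true(a$selectivity$selective)
  expect_lt(abs(wrap180(a$preferred - 45)), 10)
  # identical counts: no rejection
  cnt <- data.frame(orientation = rep(seq(0, 165, by = 15), each = 4), count = 5)
  sel <- orientation_selectivity(cnt, baseline_counts = rpois(40, 3))
  expect_false(sel$selective)
  # zero baseline SD excludes the unit
  expect_warning(z0 <- orientation_selectivity(
    data.frame(orientation = rep(c(0, 90), each = 5), count = rpois(10, 8)),
    baseline_counts = rep(2, 10)), "zero baseline SD")
  expect_false(z0$selective)
  expect_error(orientation_selectivity(
    data.frame(orientation = 0, count = 1), 1:5), ">= 2 orientations")
})

test_that("doubled-angle preferred orientation: point mass, symmetry, equivariance", {
  oris <- seq(0, 165, by = 15)
  r <- rep(0, 12); r[oris == 30] <- 5
  expect_equal(preferred_orientation(r, oris)$preferred, 30)
  u <- preferred_orientation(rep(3, 12), oris)
  expect_true(is.na(u$preferred))
  expect_equal(u$magnitude, 0)
  expect_error(preferred_orientation(rep(0, 12), oris), "all rates zero")
  # adding 90 deg to every orientation rotates the preference by 90 (mod 180)
  set.seed(3)
  w <- rgamma(12, 2)
  p1 <- preferred_orientation(w, oris)$preferred
  p2 <- preferred_orientation(w, oris + 90)$preferred
  expect_equal(wrap180(p2 - (p1 + 90)), 0, tolerance = 1e-9)
  # magnitude never exceeds the total rate
  expect_lte(preferred_orientation(w, oris)$magnitude, sum(w))
})

test_that("planted von Mises preference is recovered within 5 degrees", {
  err <- vapply(1:6, function(sd) {
    os <- sim_orientation_session(preferred = 45, kappa = 1.5, n_trials = 10,
                                  seed = sd)
    a <- analyze_orientation_session(os$trials, os$spikes)
    abs(wrap180(a$preferred - 45))
  }, numeric(1))
  expect_lt(mean(err), 5)
})

test_that("aggregate orientation: alignment, cancellation and the unit floor", {
  aligned <- data.frame(preferred = rep(37, 6), magnitude = rgamma(6, 3) + .5)
  ag <- aggregate_orientation(aligned, n_randomizations = 1000, seed = 4)
  expect_equal(ag$angle, 37, tolerance = 1e-6)
  expect_lte(ag$p, 0.005)
  # orthogonal-preferring subgroups cancel in doubled space
  ortho <- data.frame(preferred = rep(c(10, 100), each = 4), magnitude = 1)
  ag2 <- aggregate_orientation(ortho, n_randomizations = 500, seed = 5)
  expect_lt(ag2$magnitude, 1e-9)
  expect_gt(ag2$p, 0.9)
  expect_warning(out <- aggregate_orientation(aligned[1:3, ], 100, seed = 6),
                 "fewer than 4")
  expect_null(out)
})

test_that("BO-selective circular mean handles single, paired and cancelling cases", {
  expect_equal(bo_circular_mean(60, 0.5, TRUE)$mean_orientation, 60)
  two <- bo_circular_mean(c(80, 100), c(0.4, 0.4), c(TRUE, TRUE))
  expect_equal(two$mean_orientation, 90)
  cancel <- bo_circular_mean(c(0, 90), c(0.4, 0.4), c(TRUE, TRUE))
  expect_true(is.na(cancel$mean_orientation))
  none <- bo_circular_mean(c(0, 90), c(0.4, 0.4), c(FALSE, FALSE))
  expect_true(is.na(none$mean_orientation))
  expect_equal(none$n_significant, 0L)
})

test_that("identity-line distance: exact arithmetic, symmetry and periodicity", {
  d <- function(a, b) abs(wrap180(a - b)) / sqrt(2)
  expect_equal(d(5, 5), 0)
  expect_equal(d(0, 90), 90 / sqrt(2))
  expect_equal(d(10, 170), 20 / sqrt(2))
  set.seed(7)
  x <- runif(20, 0, 180); y <- runif(20, 0, 180)
  expect_equal(d(x, y), d(y, x))
  expect_equal(d(x + 180, y), d(x, y))
  idt <- identity_distance_test(x, x, n_shuffles = 400, seed = 8)
  expect_equal(idt$mean_distance, 0)
  expect_lte(idt$p, 0.01)
  expect_error(identity_distance_test(1:3, 1:3), ">= 5")
})

test_that("preferred-side span measures the smallest containing arc", {
  expect_equal(preferred_side_span(c(0, 90)),
               list(span = 90, contiguous = TRUE))
  expect_equal(preferred_side_span(c(0, 60, 120)),
               list(span = 120, contiguous = TRUE))
  sp <- preferred_side_span(c(0, 180))
  expect_equal(sp$span, 180)
  expect_false(sp$contiguous)
  expect_equal(preferred_side_span(c(350, 10))$span, 20)
  expect_error(preferred_side_span(90), ">= 2")
})

test_that("selectivity contingency table reproduces the printed worked example", {
  ori <- rep(c(FALSE, TRUE), c(125, 285))
  bo <- rep(c(FALSE, TRUE, FALSE, TRUE), c(79, 46, 133, 152))
  tb <- bo_orientation_table(ori, bo)
  expect_equal(unclass(tb$table)[1:4], c(79, 133, 46, 152),
               ignore_attr = TRUE)
  expect_lt(abs(tb$chisq - 9.51), 0.01)
  expect_lt(tb$p, 0.05)
  # perfectly associated flags: p at floor
  assoc <- bo_orientation_table(rep(c(FALSE, TRUE), each = 30),
                                rep(c(FALSE, TRUE), each = 30))
  expect_lt(assoc$p, 1e-10)
  # sparse table triggers the exact-test fallback
  expect_warning(sm <- bo_orientation_table(rep(c(FALSE, TRUE), c(4, 26)),
                                            rep(c(TRUE, FALSE), c(6, 24))),
                 "expected cell")
  expect_false(is.na(sm$fisher_p))
})
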