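test_that("BOI arithmetic matches its definition", {
  expect_equal(compute_boi(10, 5, 10, 5), 1 / 3)
  expect_equal(compute_boi(7, 7, 7, 7), 0)
  expect_equal(compute_boi(8, 0, 8, 0), 1)
  expect_error(compute_boi(0, 0, 0, 0), "all rates zero")
})

test_that("BOI is antisymmetric under side swap and scale invariant", {
  set.seed(1)
  for (i in 1:25) {
    r <- runif(4, 0, 50)
    expect_equal(compute_boi(r[2], r[1], r[4], r[3]),
                 -compute_boi(r[1], r[2], r[3], r[4]))
    c <- runif(1, 0.1, 10)
    expect_equal(compute_boi(c * r[1], c * r[2], c * r[3], c * r[4]),
                 compute_boi(r[1], r[2], r[3], r[4]))
  }
})

test_that("inclusion criteria flag low rates, few trials and bad geometry", {
  geom <- bo_geometry(90, edge_az = 5, edge_el = 5)
  crf <- data.frame(az = 5 + 1.5 * cos(seq(0, 2 * pi, length.out = 40)),
                    el = 5 + 1.5 * sin(seq(0, 2 * pi, length.out = 40)))
  mk <- function(rate, n) {
    w <- 0.45
    structure(list(counts = lapply(1:4, function(i) rep(round(rate * w), n)),
                   pretrial = rep(0L, n), n = rep(n, 4),
                   window = c(50, 500), unit_id = "u"),
              class = "bo_counts")
  }
  ok <- bo_inclusion(mk(20, 8), geom, crf)
  expect_true(ok$included)
  # criterion 1: max rate 0.5 sp/s
  low <- bo_inclusion(mk(0.5, 8), geom, crf)
  expect_false(low$rate_ok)
  # criterion 3: five trials in a condition
  few <- mk(20, 8); few$counts[[2]] <- few$counts[[2]][1:5]; few$n[2] <- 5L
  expect_false(bo_inclusion(few, geom, crf)$trials_ok)
  # criterion 4: central edge wholly outside the contour
  far <- data.frame(az = 30 + cos(seq(0, 2 * pi, length.out = 40)),
                    el = 30 + sin(seq(0, 2 * pi, length.out = 40)))
  expect_false(bo_inclusion(mk(20, 8), geom, far)$edge_in_crf)
  # criterion 5: contour reaching within 1 dva of a non-central edge
  big <- data.frame(az = 5 + 8 * cos(seq(0, 2 * pi, length.out = 80)),
                    el = 5 + 8 * sin(seq(0, 2 * pi, length.out = 80)))
  expect_false(bo_inclusion(mk(20, 8), geom, big)$clearance_ok)
  # no contour: geometric criteria undeterminable
  nc <- bo_inclusion(mk(20, 8), geom, NULL)
  expect_true(is.na(nc$edge_in_crf))
  expect_false(nc$included)
  expect_match(nc$exclusion_reason, "undeterminable")
})

test_that("permutation p is 1 for constant counts and small for a planted effect", {
  const <- structure(list(counts = lapply(1:4, function(i) rep(3L, 8)),
                          pretrial = rep(0L, 8), n = rep(8L, 4),
                          window = c(50, 500), unit_id = "u"),
                     class = "bo_counts")
  expect_equal(boi_permutation_test(const, 500, seed = 1)$p, 1)
  set.seed(2)
  hits <- vapply(1:10, function(i) {
    cnt <- poisson_counts(c(40, 10, 40, 10), n_trials = 10)
    boi_permutation_test(cnt, 1000, seed = i)$p
  }, numeric(1))
  expect_gte(mean(hits < 0.01), 0.95)
  expect_error(boi_permutation_test(const, 50), "n_shuffles")
})

test_that("permutation p is invariant to relabelling trials within a condition", {
  set.seed(3)
  cnt <- poisson_counts(c(30, 15, 25, 20), n_trials = 8)
  perm <- cnt
  perm$counts <- lapply(cnt$counts, function(x) x[c(3, 1, 2, 8, 7, 6, 4, 5)])
  expect_equal(boi_permutation_test(cnt, 2000, seed = 4)$p,
               boi_permutation_test(perm, 2000, seed = 4)$p)
})

test_that("type-I error of the permutation test is near nominal (small run)", {
  set.seed(5)
  p <- vapply(1:300, function(i) {
    cnt <- poisson_counts(rep(25, 4), n_trials = 8)
    boi_permutation_test(cnt, 500, seed = i)$p
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.02)
  expect_lt(mean(p < 0.05), 0.09)
})

test_that("preferred side follows the geometry convention and its antisymmetry", {
  geom <- bo_geometry(90, side_13 = 180)   # vertical edge, squares left/right
  expect_equal(preferred_side(0.4, geom), 180)
  expect_equal(preferred_side(-0.4, geom), 0)
  geoms <- bo_geometry(90, side_13 = 0)    # labels' sides negated
  expect_equal(preferred_side(0.4, geoms), 0)
  expect_warning(out <- preferred_side(0, geom), "tie")
  expect_true(is.na(out))
  # generator-planted side recovered through the analysis chain
  gt <- ground_truth(n_units = c(deep = 12), columnar_side = 270,
                     edge_orientation = 0, columnar_coherence = 1, seed = 6)
  s <- sim_bo_session(gt, 10, seed = 7)
  res <- analyze_bo_session(s, n_shuffles = 500, seed = 8)
  sig <- res[res$significant, ]
  expect_gte(mean(sig$side == 270), 0.95)
})

test_that("clustering proportion matches the exact enumeration null for 4 units", {
  d <- data.frame(penetration_id = "p1", unit_id = paste0("u", 1:4),
                  edge_orientation = 90, edge_az = 0, edge_el = 0,
                  boi = c(.4, .3, .5, .2), significant = TRUE, side = 180)
  cl <- bo_clustering(d, n_randomizations = 4000, seed = 9)
  expect_equal(cl$per_penetration$proportion, 1)
  # exact null: P(all four coins agree) = 2 * 0.5^4 = 0.125
  expect_lt(abs(cl$p - 0.125), 0.02)
})

test_that("clustering keeps one dataset per unit and the largest geometry subgroup", {
  # units 1-4: two positions at orientation 0 (higher |BOI| at az 0, all
  # side 90) and a selective orientation-90 dataset; unit 5 only at 90.
  d <- data.frame(
    penetration_id = "p1",
    unit_id = c(rep(paste0("u", 1:4), each = 3), "u5"),
    edge_orientation = c(rep(c(0, 0, 90), 4), 90),
    edge_az = c(rep(c(0, 2, 0), 4), 0),
    edge_el = 0,
    boi = c(rep(c(.9, .3, .5), 4), .8),
    significant = TRUE,
    side = c(rep(c(90, 270, 0), 4), 0))
  cl <- bo_clustering(d, n_randomizations = 500, min_units = 4, seed = 10)
  # the (orientation 0, az 0) subgroup keeps the highest-|BOI| dataset of
  # units 1-4; orientation 90 also has 5 rows but per-unit selection keeps
  # geometry (90, az 0) at size 5... the retained subgroup is the largest:
  expect_equal(cl$per_penetration$n_units, 5)
  expect_equal(cl$per_penetration$proportion, 1)
  # removing unit 5 leaves two equal-size subgroups; the lower orientation
  # wins the tie and carries side 90 for all four units
  cl2 <- bo_clustering(d[d$unit_id != "u5", ], n_randomizations = 500,
                       min_units = 4, seed = 10)
  expect_equal(cl2$per_penetration$n_units, 4)
  expect_equal(cl2$per_penetration$proportion, 1)
})

test_that("full columnar coherence yields P_pref = 1 through the pipeline", {
  gt <- ground_truth(n_units = c(deep = 8), columnar_coherence = 1, seed = 11)
  s <- sim_bo_session(gt, 10, seed = 12)
  res <- analyze_bo_session(s, n_shuffles = 500, seed = 13)
  d <- data.frame(penetration_id = "p1", unit_id = res$unit_id,
                  edge_orientation = 90, edge_az = 5, edge_el = 5,
                  boi = res$boi, significant = res$significant, side = res$side)
  cl <- bo_clustering(d, n_randomizations = 500, seed = 14)
  expect_equal(cl$P_pref, 1)
  # no qualifying penetration -> NA result with warning
  d0 <- d; d0$significant <- FALSE
  expect_warning(cl0 <- bo_clustering(d0, 100, seed = 1), "no penetration")
  expect_true(is.na(cl0$P_pref))
})
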