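#' Orientation selectivity of one unit
#'
#' A Kruskal--Wallis test on evoked spike counts (window \[30, 200\] ms)
#' grouped by orientation, combined with a z-score criterion: the rate
#' at the best orientation, z-scored against the pre-trial baseline
#' distribution, must reach 3. A unit is orientation-selective when
#' p < 0.05 and z_peak >= 3.
#'
#' @param counts data.frame with `orientation` (deg) and `count`
#'   (evoked spikes per trial)
#' @param baseline_counts per-trial baseline counts in a window of the
#'   same length as the evoked one
#' @return list: `kw_p`, `z_peak`, `selective`, `mean_rates` (named by
#'   orientation, in counts per trial); `z_peak` is `NA` (unit
#'   excluded) when the baseline SD is zero
#' @export
orientation_selectivity <- function(counts, baseline_counts) {
  stop_if_not(length(unique(counts$orientation)) >= 2,
              "need >= 2 orientations")
  kw <- stats::kruskal.test(counts$count, factor(counts$orientation))
  mu <- tapply(counts$count, counts$orientation, mean)
  sdb <- stats::sd(baseline_counts)
  if (is.na(sdb) || sdb == 0) {
    warning("zero baseline SD: z undefined, unit excluded")
    return(list(kw_p = kw$p.value, z_peak = NA_real_, selective = FALSE,
                mean_rates = mu))
  }
  z <- (max(mu) - mean(baseline_counts)) / sdb
  list(kw_p = kw$p.value, z_peak = z,
       selective = kw$p.value < 0.05 && z >= 3, mean_rates = mu)
}

# Doubled-angle resultant of non-negative weights at orientations (deg).
doubled_resultant <- function(weights, orientations_deg) {
  v <- sum(weights * exp(2i * orientations_deg * pi / 180))
  list(magnitude = Mod(v), angle_doubled = (Arg(v) * 180 / pi) %% 360)
}

#' Preferred orientation from mean rates (doubled-angle resultant)
#'
#' Each orientation `j` contributes a vector with direction `2j`
#' (orientation has period 180 deg) and length equal to its mean rate;
#' the preferred orientation is the resultant's direction divided by 2.
#'
#' @param mean_rates non-negative rates, one per orientation
#' @param orientations orientations in degrees
#' @return list: `preferred` (deg in \[0,180), `NA` when the resultant
#'   magnitude is 0), `magnitude`
#' @export
preferred_orientation <- function(mean_rates, orientations) {
  stop_if_not(all(mean_rates >= 0), "rates must be >= 0")
  stop_if_not(any(mean_rates > 0), "all rates zero: preferred undefined")
  r <- doubled_resultant(mean_rates, orientations)
  if (r$magnitude < 1e-9 * sum(mean_rates))
    return(list(preferred = NA_real_, magnitude = 0))
  list(preferred = (r$angle_doubled / 2) %% 180, magnitude = r$magnitude)
}

#' Aggregate preferred orientation of a penetration
#'
#' The resultant of the orientation-selective units' resultant vectors
#' (in the doubled-angle space); significance from a null in which each
#' unit's direction is randomized uniformly on the doubled circle while
#' magnitudes are kept.
#'
#' @param unit_resultants data.frame with `preferred` (deg) and
#'   `magnitude` per orientation-selective unit
#' @param n_randomizations null draws
#' @param min_units minimum selective units to evaluate
#' @param seed integer seed
#' @return list of class `aggregate_orientation`: `angle` (deg in
#'   \[0,180)), `magnitude`, `p`, `p_add_one`; `NULL` when fewer than
#'   `min_units` units
#' @export
aggregate_orientation <- function(unit_resultants, n_randomizations = 2000,
                                  min_units = 4, seed = 1) {
  n <- nrow(unit_resultants)
  if (n < min_units) {
    warning("fewer than ", min_units, " orientation-selective units: not evaluated")
    return(NULL)
  }
  mags <- unit_resultants$magnitude
  obs <- doubled_resultant(mags, unit_resultants$preferred)
  null_mag <- with_seed(seed, {
    vapply(seq_len(n_randomizations), function(i) {
      Mod(sum(mags * exp(1i * stats::runif(n, 0, 2 * pi))))
    }, numeric(1))
  })
  k <- sum(null_mag >= obs$magnitude - 1e-12)
  structure(list(angle = (obs$angle_doubled / 2) %% 180,
                 magnitude = obs$magnitude,
                 p = k / n_randomizations,
                 p_add_one = (k + 1) / (n_randomizations + 1),
                 n_units = n),
            class = "aggregate_orientation")
}

#' Circular mean of border-ownership-selective orientations
#'
#' The |BOI|-weighted doubled-angle resultant over the orientations at
#' which a unit's border-ownership selectivity is significant; its
#' direction divided by 2. Undefined when no orientation is significant
#' or when the weighted vectors cancel (e.g. equal |BOI| at orthogonal
#' orientations).
#'
#' @param orientations tested orientations, deg
#' @param abs_boi `|BOI|` per orientation
#' @param significant logical flags (Bonferroni-corrected) per orientation
#' @return list: `mean_orientation` (deg in \[0,180) or `NA`),
#'   `magnitude`, `n_significant`
#' @export
bo_circular_mean <- function(orientations, abs_boi, significant) {
  k <- which(significant)
  if (length(k) == 0)
    return(list(mean_orientation = NA_real_, magnitude = 0, n_significant = 0L))
  r <- doubled_resultant(abs_boi[k], orientations[k])
  if (r$magnitude < 1e-9 * sum(abs_boi[k]))
    return(list(mean_orientation = NA_real_, magnitude = 0,
                n_significant = length(k)))
  list(mean_orientation = (r$angle_doubled / 2) %% 180,
       magnitude = r$magnitude, n_significant = length(k))
}

#' Identity-line distance between orientation preference and
#' border-ownership orientations
#'
#' For each unit, the perpendicular distance from the point
#' `(preferred orientation, circular mean of BO-selective orientations)`
#' to the nearest periodic identity line:
#' `d = |wrap180(x - y)| / sqrt(2)` with the difference wrapped into
#' `(-90, 90]`. The observed mean is compared against a null formed by
#' shuffling the pairing; p is the fraction of null means at most as
#' large as the observed one.
#'
#' @param x,y paired angles, deg (pairs with an undefined member are
#'   dropped)
#' @param n_shuffles pairing shuffles
#' @param min_pairs minimum retained pairs
#' @param seed integer seed
#' @return list: `mean_distance` (deg), `distances`, `p`, `p_add_one`,
#'   `n_pairs`
#' @export
identity_distance_test <- function(x, y, n_shuffles = 2000, min_pairs = 5,
                                   seed = 1) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  stop_if_not(length(x) >= min_pairs,
              paste0("need >= ", min_pairs, " defined pairs"))
  dist1 <- function(a, b) abs(wrap180(a - b)) / sqrt(2)
  d <- dist1(x, y)
  obs <- mean(d)
  null_means <- with_seed(seed, vapply(seq_len(n_shuffles), function(i)
    mean(dist1(x, sample(y))), numeric(1)))
  k <- sum(null_means <= obs + 1e-12)
  list(mean_distance = obs, distances = d, p = k / n_shuffles,
       p_add_one = (k + 1) / (n_shuffles + 1), n_pairs = length(x))
}

#' Span of preferred sides of border ownership
#'
#' The arc length of the smallest circular arc (period 360 deg, sides
#' are true directions in stimulus space) containing all preferred-side
#' directions of a unit. Spatially contiguous preferred sides give a
#' span below 180 deg.
#'
#' @param sides preferred ownership directions, deg (>= 2)
#' @return list: `span` (deg), `contiguous`
#' @export
preferred_side_span <- function(sides) {
  stop_if_not(length(sides) >= 2, "need >= 2 sides")
  a <- sort(wrap360(sides))
  gaps <- diff(c(a, a[1] + 360))
  span <- 360 - max(gaps)
  list(span = span, contiguous = span < 180)
}

#' Association between orientation and border-ownership selectivity
#'
#' Cross-tabulates the two per-unit selectivity flags and tests
#' independence with an (uncorrected) chi-square test; when an expected
#' cell drops below 5 a warning is raised and Fisher's exact p is
#' reported alongside.
#'
#' @param orientation_selective,bo_selective logical vectors per unit
#' @return list: `table` (2x2, rows orientation -/+, cols BO -/+),
#'   `chisq`, `p`, `fisher_p` (`NA` unless warranted)
#' @export
bo_orientation_table <- function(orientation_selective, bo_selective) {
  stop_if_not(length(orientation_selective) == length(bo_selective),
              "flag vectors differ in length")
  tab <- table(factor(orientation_selective, c(FALSE, TRUE), c("-", "+")),
               factor(bo_selective, c(FALSE, TRUE), c("-", "+")))
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  fisher_p <- NA_real_
  if (any(ct$expected < 5)) {
    warning("expected cell count < 5: exact test reported alongside")
    fisher_p <- stats::fisher.test(tab)$p.value
  }
  list(table = tab, chisq = unname(ct$statistic), p = ct$p.value,
       fisher_p = fisher_p)
}
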