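#' Per-condition spike counts for one border-ownership dataset
#'
#' Collects, for one unit under one stimulus geometry, the trial spike
#' counts per condition in the evoked window (default \[50, 500\] ms)
#' and the pre-trial baseline counts (\[-400, 0) ms fixation window)
#' used by the inclusion criteria.
#'
#' @param spikes spike table (`unit_id`, `trial_id`, `t`)
#' @param trials trial table (`trial_id`, `condition_id`)
#' @param unit_id unit to extract
#' @param window evoked count window, ms
#' @return list of class `bo_counts`: `counts` (list of 4 integer
#'   vectors), `pretrial` (per-trial baseline counts), `n` (trials per
#'   condition), `window`
#' @export
bo_counts <- function(spikes, trials, unit_id, window = c(50, 500)) {
  sp <- spikes[spikes$unit_id == unit_id, , drop = FALSE]
  per_trial <- function(a, b) {
    k <- sp$t >= a & sp$t < b
    cnt <- table(factor(sp$trial_id[k], levels = trials$trial_id))
    as.integer(cnt)
  }
  ev <- per_trial(window[1], window[2])
  pre <- per_trial(-400, 0)
  counts <- lapply(1:4, function(cond) ev[trials$condition_id == cond])
  structure(list(counts = counts, pretrial = pre,
                 n = vapply(counts, length, integer(1)),
                 window = window, unit_id = unit_id),
            class = "bo_counts")
}

#' Border-ownership inclusion criteria
#'
#' Five criteria gate a dataset into the selectivity analysis:
#' (1) average rate >= 1 sp/s in at least one condition; (2) the evoked
#' count differs from the pre-trial baseline for at least one condition
#' (two-sided rank-sum, Bonferroni over the four conditions; baseline
#' counts are rescaled to the evoked window length); (3) at least six
#' trials per condition; (4) the central edge intersects the cRF
#' contour; (5) every point of the cRF contour is at least 1 dva from
#' every non-central square edge. Criteria 4--5 need a contour: without
#' one the dataset is excluded with a reason.
#'
#' @param counts a [bo_counts()] object
#' @param geometry a [bo_geometry()]
#' @param rf_contour_poly data.frame (`az`, `el`) of the cRF contour, or `NULL`
#' @param min_rate,min_trials,clearance_dva criterion parameters
#' @return list with per-criterion logical flags and `included`
#' @export
bo_inclusion <- function(counts, geometry, rf_contour_poly,
                         min_rate = 1, min_trials = 6, clearance_dva = 1) {
  w <- diff(counts$window) / 1000
  rates <- vapply(counts$counts, mean, numeric(1)) / w
  c1 <- any(rates >= min_rate)
  pre_scaled <- counts$pretrial * diff(counts$window) / 400
  p2 <- vapply(1:4, function(i) {
    x <- counts$counts[[i]]
    if (length(x) == 0 || (stats::sd(c(x, pre_scaled)) == 0)) return(1)
    suppressWarnings(stats::wilcox.test(x, pre_scaled)$p.value)
  }, numeric(1))
  c2 <- min(p2 * 4) < 0.05
  c3 <- all(counts$n >= min_trials)
  if (is.null(rf_contour_poly)) {
    c4 <- NA; c5 <- NA
  } else {
    c4 <- segment_intersects_polygon(geometry$edge, rf_contour_poly)
    noncentral <- noncentral_edges(geometry)
    dmin <- min(vapply(noncentral, function(seg)
      min(point_segment_dist(rf_contour_poly$az, rf_contour_poly$el,
                             seg[1, ], seg[2, ])), numeric(1)))
    c5 <- dmin >= clearance_dva
  }
  included <- isTRUE(c1) && isTRUE(c2) && isTRUE(c3) && isTRUE(c4) && isTRUE(c5)
  reason <- if (is.na(c4)) "cRF contour unavailable: criteria 4-5 undeterminable"
  else NULL
  list(rate_ok = c1, evoked_ok = c2, trials_ok = c3,
       edge_in_crf = c4, clearance_ok = c5, included = included,
       exclusion_reason = reason)
}

# Non-central edges of both candidate squares: each square contributes its
# three sides that are not the shared central edge.
noncentral_edges <- function(geometry) {
  per_square <- function(sq) {
    list(rbind(sq[2, ], sq[3, ]), rbind(sq[3, ], sq[4, ]),
         rbind(sq[4, ], sq[1, ]))
  }
  c(per_square(geometry$square_13), per_square(geometry$square_24))
}

# --- small computational-geometry helpers ---------------------------------

point_in_polygon <- function(px, py, poly) {
  x <- poly$az; y <- poly$el
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  inside <- rep(FALSE, length(px))
  for (k in seq_len(n)) {
    xi <- x[k]; yi <- y[k]; xj <- x[j[k]]; yj <- y[j[k]]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi + 1e-300) + xi)
    inside <- xor(inside, cross)
  }
  inside
}

# Does segment (2x2 matrix, rows = endpoints) intersect the polygon region?
segment_intersects_polygon <- function(seg, poly) {
  tt <- seq(0, 1, length.out = 64)
  px <- seg[1, 1] + tt * (seg[2, 1] - seg[1, 1])
  py <- seg[1, 2] + tt * (seg[2, 2] - seg[1, 2])
  any(point_in_polygon(px, py, poly))
}

# Distance from points (px, py) to segment a-b.
point_segment_dist <- function(px, py, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  L2 <- vx^2 + vy^2
  tt <- if (L2 == 0) rep(0, length(px))
  else pmin(1, pmax(0, ((px - a[1]) * vx + (py - a[2]) * vy) / L2))
  sqrt((px - (a[1] + tt * vx))^2 + (py - (a[2] + tt * vy))^2)
}

#' Border-ownership index
#'
#' \deqn{BOI = \frac{(R_1 + R_3) - (R_2 + R_4)}{R_1 + R_3 + R_2 + R_4}}
#' where `R_i` is the average spike rate in the evoked window for
#' condition `i`. Positive values prefer the side owning in conditions
#' 1 and 3.
#'
#' @param r1,r2,r3,r4 average spike rates (sp/s), all `>= 0`, not all zero
#' @return the index, in \[-1, 1\]
#' @export
compute_boi <- function(r1, r2, r3, r4) {
  tot <- r1 + r2 + r3 + r4
  stop_if_not(all(tot > 0), "BOI undefined: all rates zero")
  ((r1 + r3) - (r2 + r4)) / tot
}

boi_from_counts <- function(counts) {
  r <- vapply(counts$counts, mean, numeric(1))
  compute_boi(r[1], r[2], r[3], r[4])
}

#' Permutation test for border-ownership selectivity
#'
#' Builds the null by shuffling the side labels independently within
#' each contrast pair (\{1,2\} and \{3,4\}), recomputing `|BOI|` each
#' time. The p value is the plain fraction of shuffles with
#' `|BOI_shuffled| >= |BOI|`; an add-one-corrected value
#' `(k+1)/(n+1)` is reported alongside.
#'
#' @param counts a [bo_counts()] object with at least one spike
#' @param n_shuffles number of label shuffles (>= 100)
#' @param seed integer seed
#' @return list: `boi`, `p`, `p_add_one`, `n_shuffles`
#' @export
boi_permutation_test <- function(counts, n_shuffles = 10000, seed = 1) {
  stop_if_not(n_shuffles >= 100, "n_shuffles must be >= 100")
  stop_if_not(sum(unlist(counts$counts)) > 0, "no spikes in evoked window")
  x12 <- c(counts$counts[[1]], counts$counts[[2]])
  x34 <- c(counts$counts[[3]], counts$counts[[4]])
  n1 <- counts$n[1]; n3 <- counts$n[3]
  obs <- abs(boi_from_counts(counts))
  shuffle_pair_sums <- function(pool, nsel) {
    np <- length(pool)
    keys <- stats::runif(np * n_shuffles)
    ord <- order(rep(seq_len(n_shuffles), each = np), keys, method = "radix")
    sel <- matrix(pool[((ord - 1) %% np) + 1], np, n_shuffles)
    s1 <- colSums(sel[seq_len(nsel), , drop = FALSE])
    list(first = s1, rest = sum(pool) - s1)
  }
  sh <- with_seed(seed, {
    a <- shuffle_pair_sums(x12, n1)
    b <- shuffle_pair_sums(x34, n3)
    list(a = a, b = b)
  })
  r1 <- sh$a$first / n1; r2 <- sh$a$rest / counts$n[2]
  r3 <- sh$b$first / n3; r4 <- sh$b$rest / counts$n[4]
  boi_null <- abs(((r1 + r3) - (r2 + r4)) / (r1 + r2 + r3 + r4))
  k <- sum(boi_null >= obs - 1e-12)
  list(boi = boi_from_counts(counts), p = k / n_shuffles,
       p_add_one = (k + 1) / (n_shuffles + 1), n_shuffles = n_shuffles)
}

#' Preferred side of border ownership
#'
#' The direction, perpendicular to the central edge, pointing from the
#' edge toward the square of the configuration evoking the higher rate.
#'
#' @param boi signed border-ownership index, non-zero
#' @param geometry a [bo_geometry()]
#' @return direction in degrees, or `NA` with a warning when `boi == 0`
#' @export
preferred_side <- function(boi, geometry) {
  if (boi == 0) {
    warning("boi = 0: preferred side undefined (tie)")
    return(NA_real_)
  }
  if (boi > 0) geometry$side_13 else geometry$side_24
}

#' Columnar clustering of the preferred side of border ownership
#'
#' For each penetration: per unit and edge orientation the selective
#' dataset with the highest `|BOI|` is kept (ties: lower orientation,
#' then lower azimuth/elevation), then the largest subgroup sharing the
#' same edge orientation and position is retained, so each unit
#' contributes at most one dataset. The proportion of units sharing the
#' most common preferred side is computed per penetration; `P_pref` is
#' the mean across penetrations, compared against a null in which each
#' unit's side is an independent fair coin.
#'
#' @param datasets data.frame with columns `penetration_id`, `unit_id`,
#'   `edge_orientation`, `edge_az`, `edge_el`, `boi` (signed),
#'   `significant` (logical), `side` (deg)
#' @param n_randomizations null draws
#' @param min_units minimum selective units per penetration
#' @param seed integer seed
#' @return list of class `bo_clustering`: `per_penetration` data.frame,
#'   `P_pref`, `p`, `p_add_one`, `n_randomizations`; empty penetration
#'   set gives `NA` results with a warning
#' @export
bo_clustering <- function(datasets, n_randomizations = 2000, min_units = 4,
                          seed = 1) {
  sel <- datasets[datasets$significant, , drop = FALSE]
  pens <- split(sel, sel$penetration_id)
  rows <- lapply(pens, function(d) {
    # per unit x orientation keep highest |BOI| (deterministic tie-break)
    d <- d[order(d$unit_id, d$edge_orientation, -abs(d$boi), d$edge_az,
                 d$edge_el), , drop = FALSE]
    d <- d[!duplicated(d[, c("unit_id", "edge_orientation")]), , drop = FALSE]
    grp <- interaction(d$edge_orientation, d$edge_az, d$edge_el, drop = TRUE)
    sizes <- table(grp)
    best <- names(sizes)[order(-as.integer(sizes), names(sizes))][1]
    d <- d[grp == best, , drop = FALSE]
    d <- d[!duplicated(d$unit_id), , drop = FALSE]
    if (nrow(d) < min_units) return(NULL)
    prop <- max(table(d$side)) / nrow(d)
    data.frame(penetration_id = d$penetration_id[1], n_units = nrow(d),
               proportion = prop, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(rows) || nrow(rows) == 0) {
    warning("no penetration with >= ", min_units, " selective units")
    return(structure(list(per_penetration = NULL, P_pref = NA_real_,
                          p = NA_real_, p_add_one = NA_real_,
                          n_randomizations = n_randomizations),
                     class = "bo_clustering"))
  }
  obs <- mean(rows$proportion)
  null_mean <- with_seed(seed, {
    acc <- numeric(n_randomizations)
    for (i in seq_len(nrow(rows))) {
      nk <- rows$n_units[i]
      heads <- stats::rbinom(n_randomizations, nk, 0.5)
      acc <- acc + pmax(heads, nk - heads) / nk
    }
    acc / nrow(rows)
  })
  k <- sum(null_mean >= obs - 1e-12)
  structure(list(per_penetration = rows, P_pref = obs,
                 p = k / n_randomizations,
                 p_add_one = (k + 1) / (n_randomizations + 1),
                 n_randomizations = n_randomizations),
            class = "bo_clustering")
}

#' @export
print.bo_clustering <- function(x, ...) {
  cat(sprintf("<bo_clustering> %d penetrations, P_pref = %.3f, p = %.4g\n",
              if (is.null(x$per_penetration)) 0 else nrow(x$per_penetration),
              x$P_pref, x$p))
  invisible(x)
}
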