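#' Border-ownership selectivity for every unit of a session
#'
#' Runs the per-unit chain — evoked/pre-trial counts, BOI, label
#' permutation test, preferred side — over all units of a session's
#' (single) stimulus geometry. Inclusion criteria 1--3 are evaluated
#' from the counts; the geometric criteria (4--5) are applied when a
#' cRF contour is supplied and recorded as `NA` otherwise.
#'
#' @param session a `bo_session`
#' @param n_shuffles permutation count
#' @param rf_contour_poly optional cRF contour polygon (`az`, `el`)
#' @param alpha significance level (Bonferroni across a unit's datasets
#'   is the caller's concern when several geometries exist; a session
#'   carries one)
#' @param seed integer seed
#' @return data.frame, one row per unit: `unit_id`, `boi`, `p`,
#'   `significant`, `side`, `included`, inclusion flags, `n_min`
#'   (smallest per-condition trial count)
#' @export
analyze_bo_session <- function(session, n_shuffles = 10000,
                               rf_contour_poly = NULL, alpha = 0.05, seed = 1) {
  geom <- attr(session, "geometry")
  if (is.null(geom)) {
    d <- session$manifest$datasets[[1]]
    geom <- bo_geometry(d$edge_orientation, d$edge_az, d$edge_el,
                        d$square_size, side_13 = d$side_13)
  }
  rows <- lapply(seq_len(nrow(session$units)), function(i) {
    uid <- session$units$unit_id[i]
    cnt <- bo_counts(session$spikes, session$trials, uid)
    inc <- bo_inclusion(cnt, geom, rf_contour_poly)
    if (sum(unlist(cnt$counts)) == 0)
      return(data.frame(unit_id = uid, boi = NA_real_, p = NA_real_,
                        significant = FALSE, side = NA_real_,
                        included = FALSE, rate_ok = inc$rate_ok,
                        trials_ok = inc$trials_ok, n_min = min(cnt$n),
                        stringsAsFactors = FALSE))
    pt <- boi_permutation_test(cnt, n_shuffles, derive_seed(seed, i))
    sig <- isTRUE(inc$rate_ok) && isTRUE(inc$evoked_ok) && isTRUE(inc$trials_ok) &&
      !isFALSE(inc$edge_in_crf) && !isFALSE(inc$clearance_ok) && pt$p < alpha
    side <- if (pt$boi == 0) NA_real_ else preferred_side(pt$boi, geom)
    data.frame(unit_id = uid, boi = pt$boi, p = pt$p, significant = sig,
               side = side, included = inc$included, rate_ok = inc$rate_ok,
               trials_ok = inc$trials_ok, n_min = min(cnt$n),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-compartment preferred/non-preferred population matrices
#'
#' Builds, for the border-ownership-selective units of a session, the
#' unit x time matrices of normalized preferred and non-preferred
#' response functions, grouped by laminar compartment. The preferred
#' pair is taken from the sign of each unit's empirical BOI.
#'
#' @param session a `bo_session`
#' @param results output of [analyze_bo_session()]
#' @param compartments named character vector `unit_id -> compartment`
#' @param t_grid time grid, ms
#' @return list: `pops` (named list of `list(P, N)`), `t`, `units`
#'   (unit ids per compartment)
#' @export
bo_populations <- function(session, results, compartments,
                           t_grid = seq(-100, 500)) {
  sel <- results[results$significant & !is.na(results$boi) & results$boi != 0, ,
                 drop = FALSE]
  comps <- split(sel$unit_id, compartments[sel$unit_id])
  pops <- lapply(comps, function(uids) {
    rfs <- lapply(uids, function(uid) {
      pref <- if (results$boi[results$unit_id == uid] > 0) c(1, 3) else c(2, 4)
      unit_response_function(session$spikes, session$trials, uid, pref, t_grid)
    })
    stack_population(rfs)
  })
  list(pops = pops, t = t_grid, units = comps)
}

#' Kernel-smoothed ring-response populations per compartment
#'
#' Mean kernel traces per unit for a single-condition ring session,
#' grouped by compartment, as input to [ring_latency()].
#'
#' @param ring list with `trials` and `spikes` (e.g. [sim_ring_session()])
#' @param compartments named character vector `unit_id -> compartment`
#' @param t_grid time grid, ms (extend before 0 for baselines)
#' @return named list of unit x time matrices
#' @export
ring_populations <- function(ring, compartments, t_grid = seq(-200, 400)) {
  uids <- unique(ring$spikes$unit_id)
  comps <- split(uids, compartments[uids])
  lapply(comps, function(ids) {
    do.call(rbind, lapply(ids, function(uid) {
      sp <- ring$spikes[ring$spikes$unit_id == uid, , drop = FALSE]
      mean_trace(sp$t, sp$trial_id, ring$trials$trial_id, t_grid)
    }))
  })
}

#' Orientation tuning analysis of one unit's orientation session
#'
#' Counts evoked spikes per trial in the \[30, 200\] ms window and
#' baseline spikes in an equal-length pre-trial window, then applies
#' the Kruskal--Wallis + z-score selectivity criterion and the
#' doubled-angle preferred-orientation estimate.
#'
#' @param trials data.frame with `trial_id`, `orientation`
#' @param spikes data.frame with `trial_id`, `t`
#' @param window evoked window, ms
#' @return list: `selectivity` (see [orientation_selectivity()]),
#'   `preferred`, `magnitude`, `mean_rates` (sp/s by orientation)
#' @export
analyze_orientation_session <- function(trials, spikes, window = c(30, 200)) {
  wlen <- diff(window)
  count_window <- function(a, b) {
    k <- spikes$t >= a & spikes$t < b
    as.integer(table(factor(spikes$trial_id[k], levels = trials$trial_id)))
  }
  ev <- count_window(window[1], window[2])
  base <- count_window(-wlen, 0)
  sel <- orientation_selectivity(
    data.frame(orientation = trials$orientation, count = ev), base)
  rates <- sel$mean_rates / (wlen / 1000)
  po <- preferred_orientation(as.numeric(sel$mean_rates),
                              as.numeric(names(sel$mean_rates)))
  list(selectivity = sel, preferred = po$preferred, magnitude = po$magnitude,
       mean_rates = rates)
}
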