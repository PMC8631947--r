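#' Ground truth for a synthetic penetration
#'
#' Builds the planted parameter set for one synthetic laminar penetration.
#' Units are inhomogeneous-Poisson spikers whose rate is
#' \deqn{r(t) = b + A\,g(t-\ell_{cRF})\,[1 \pm m\,h(t-\ell_{BO})]\,[1 \pm c\,h(t-\ell_{cRF})]}
#' where `g`, `h` are logistic onset ramps (10 ms 10--90% rise), the `m`
#' term's sign follows whether the trial's owning side matches the unit's
#' preferred side, and the `c` term's sign follows contrast polarity.
#' Compartment defaults mirror the laminar timing structure the analysis
#' is designed to detect: the classical-receptive-field response starts
#' earliest in the granular layer, while border-ownership modulation
#' starts earliest in the deep layer.
#'
#' @param n_units named integer vector: units per compartment
#'   (`superficial`, `granular`, `deep`)
#' @param granular_band depth (mm) of the granular compartment, `c(top, bottom)`
#' @param baseline_rate spontaneous rate, sp/s
#' @param evoked_amplitude evoked rate amplitude, sp/s
#' @param crf_latency named vector, onset of the evoked response per
#'   compartment (ms)
#' @param bo_latency named vector, onset of border-ownership modulation
#'   per compartment (ms); must be `>= crf_latency`
#' @param m planted border-ownership modulation depth in `[0, 1)`; the
#'   sustained border-ownership index approaches
#'   `m * evoked / (baseline + evoked)`
#' @param cp_modulation planted contrast-polarity modulation depth in `[0, 1)`
#' @param columnar_coherence probability that a unit adopts the
#'   penetration's common preferred side
#' @param columnar_side penetration-level preferred ownership direction (deg)
#' @param edge_orientation central-edge orientation (deg)
#' @param preferred_orientation penetration-level preferred edge
#'   orientation (deg); per-unit preferences get circular jitter
#' @param orientation_jitter SD (deg) of that jitter
#' @param kappa von Mises concentration of orientation tuning (doubled angle)
#' @param rf_center,rf_sigma receptive-field centre (dva) and size (dva)
#' @param probe_span_mm depth of the deepest contact below the most
#'   superficial one (32 contacts at 100 um)
#' @param seed integer; the unit-parameter draw is a pure function of it
#' @return a list of class `bo_ground_truth` with `$units` (per-unit
#'   parameter data.frame) and `$penetration` (shared parameters)
#' @export
ground_truth <- function(n_units = c(superficial = 20, granular = 25, deep = 30),
                         granular_band = c(1.0, 1.4),
                         baseline_rate = 2, evoked_amplitude = 50,
                         crf_latency = c(superficial = 51, granular = 48, deep = 50),
                         bo_latency = c(superficial = 100, granular = 95, deep = 75),
                         m = 0.4, cp_modulation = 0.2,
                         columnar_coherence = 1.0, columnar_side = 180,
                         edge_orientation = 90,
                         preferred_orientation = 45, orientation_jitter = 10,
                         kappa = 1.5,
                         rf_center = c(5, 5), rf_sigma = 1.5,
                         probe_span_mm = 3.1, seed = 1) {
  stop_if_not(m >= 0 && m < 1, "m must be in [0, 1)")
  stop_if_not(cp_modulation >= 0 && cp_modulation < 1,
              "cp_modulation must be in [0, 1)")
  stop_if_not(granular_band[1] < granular_band[2],
              "granular_band: top must be above bottom")
  stop_if_not(all(bo_latency[names(crf_latency)] >= crf_latency),
              "bo_latency must be >= crf_latency in every compartment")
  comps <- rep(names(n_units), n_units)
  n <- length(comps)
  with_seed(seed, {
    # Units are planted at least half a contact pitch (0.05 mm) away from
    # the band boundaries -- closer than that, assignment is unresolvable
    # at the probe's 100 um pitch -- and no deeper than the 2 mm
    # white-matter guard used by the laminar analyses.
    depth <- vapply(comps, function(cc) switch(cc,
      superficial = stats::runif(1, 0.15, granular_band[1] - 0.05),
      granular    = stats::runif(1, granular_band[1] + 0.05, granular_band[2] - 0.05),
      deep        = stats::runif(1, granular_band[2] + 0.05,
                                 min(granular_band[2] + 0.8, 1.95))),
      numeric(1))
    same_side <- stats::runif(n) < columnar_coherence
    pref_side <- ifelse(same_side, columnar_side, wrap360(columnar_side + 180))
    pref_pol <- sample(c("pair12", "pair34"), n, replace = TRUE)
    pref_ori <- (preferred_orientation +
                   stats::rnorm(n, 0, orientation_jitter)) %% 180
    units <- data.frame(
      unit_id = sprintf("u%02d", seq_len(n)),
      compartment = comps,
      depth = depth,
      baseline_rate = baseline_rate,
      evoked_amplitude = evoked_amplitude,
      crf_latency = unname(crf_latency[comps]),
      bo_latency = unname(bo_latency[comps]),
      m = m,
      cp_modulation = cp_modulation,
      preferred_side = pref_side,
      preferred_polarity = pref_pol,
      preferred_orientation = pref_ori,
      kappa = kappa,
      stringsAsFactors = FALSE)
  })
  structure(list(
    units = units,
    penetration = list(granular_band = granular_band,
                       columnar_side = columnar_side,
                       edge_orientation = edge_orientation,
                       rf_center = rf_center, rf_sigma = rf_sigma,
                       probe_span_mm = probe_span_mm,
                       columnar_coherence = columnar_coherence,
                       seed = seed)),
    class = "bo_ground_truth")
}

# Logistic onset ramp, 10 ms 10-90% rise, value ~0.1 at u = 0.
onset_ramp <- function(u, rise_ms = 10) {
  stats::plogis((u - rise_ms / 2) * (2 * log(9) / rise_ms))
}

# Instantaneous rate (sp/s) for one unit under one condition, on a ms grid.
unit_rate <- function(t, u, sign_bo, sign_cp, stim_dur = 500) {
  g <- onset_ramp(t - u$crf_latency) *
    (1 - onset_ramp(t - (stim_dur + u$crf_latency)))
  h_bo <- onset_ramp(t - u$bo_latency)
  h_cp <- onset_ramp(t - u$crf_latency)
  r <- u$baseline_rate + u$evoked_amplitude * g *
    (1 + sign_bo * u$m * h_bo) * (1 + sign_cp * u$cp_modulation * h_cp)
  if (any(r < 0)) stop("negative instantaneous rate under planted modulation",
                       call. = FALSE)
  r
}

#' Simulate a four-condition border-ownership session
#'
#' Generates spike trains for every unit of a planted [ground_truth()]
#' under the four-condition design: two owning sides x two contrast
#' polarities, conditions numbered so \{1,3\} share the owning side and
#' \{1,2\} share the local edge. Spiking is an inhomogeneous Poisson
#' process on a 1 ms rate grid, spike times jittered uniformly within
#' bins and rounded to 0.1 ms.
#'
#' @param truth a `bo_ground_truth`
#' @param n_trials_per_condition trials per condition (the emulated
#'   design collected 8--10)
#' @param seed integer seed; same seed gives an identical session
#' @return a `bo_session` with the `bo_ground_truth` attached as
#'   attribute `"truth"` and the stimulus geometry in
#'   `manifest$datasets[[1]]`
#' @export
sim_bo_session <- function(truth, n_trials_per_condition = 8, seed = 1) {
  stop_if_not(n_trials_per_condition >= 1, "n_trials_per_condition must be >= 1")
  pen <- truth$penetration
  geom <- bo_geometry(pen$edge_orientation,
                      edge_az = pen$rf_center[1], edge_el = pen$rf_center[2],
                      square_size = 16)
  nt <- 4 * n_trials_per_condition
  trials <- data.frame(trial_id = seq_len(nt),
                       condition_id = rep(1:4, each = n_trials_per_condition),
                       edge_orientation = pen$edge_orientation,
                       edge_az = pen$rf_center[1], edge_el = pen$rf_center[2],
                       onset_time = 0)
  tgrid <- seq(-400, 599) # 1 ms bin left edges
  units <- truth$units
  spk <- with_seed(seed, {
    out <- vector("list", nrow(units) * 4)
    k <- 0
    for (i in seq_len(nrow(units))) {
      u <- units[i, ]
      for (cond in 1:4) {
        s_bo <- if (condition_side(geom, cond) == u$preferred_side) 1 else -1
        pol <- if (cond <= 2) "pair12" else "pair34"
        s_cp <- if (pol == u$preferred_polarity) 1 else -1
        rate <- unit_rate(tgrid + 0.5, u, s_bo, s_cp)
        ids <- trials$trial_id[trials$condition_id == cond]
        counts <- stats::rpois(length(tgrid) * length(ids),
                               rep(rate, length(ids)) / 1000)
        nz <- which(counts > 0)
        if (length(nz)) {
          reps <- counts[nz]
          bin <- rep(tgrid[(nz - 1) %% length(tgrid) + 1], reps)
          tid <- rep(ids[(nz - 1) %/% length(tgrid) + 1], reps)
          tt <- round((bin + stats::runif(length(bin))) * 10) / 10
          k <- k + 1
          out[[k]] <- data.frame(unit_id = u$unit_id, trial_id = tid, t = tt,
                                 stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, out[seq_len(k)])
  })
  if (is.null(spk)) spk <- data.frame(unit_id = character(), trial_id = integer(),
                                      t = numeric())
  spk <- spk[order(spk$unit_id, spk$trial_id, spk$t), , drop = FALSE]
  rownames(spk) <- NULL
  unit_meta <- synth_unit_meta(units, pitch_mm = 0.1, n_contacts = 32,
                               seed = derive_seed(seed, 7L))
  manifest <- list(penetration_id = sprintf("synthP%03d", seed %% 1000L),
                   animal_id = "synthA", n_contacts = 32L,
                   contact_pitch_um = 100,
                   datasets = list(list(square_size = geom$square_size,
                                        edge_orientation = pen$edge_orientation,
                                        edge_az = pen$rf_center[1],
                                        edge_el = pen$rf_center[2],
                                        side_13 = geom$side_13)),
                   rf_grid = list(extent = 25, spacing = 1,
                                  origin = c(7.5, 7.5)),
                   seed = seed)
  s <- bo_session(manifest, trials, spk, unit_meta)
  attr(s, "truth") <- truth
  attr(s, "geometry") <- geom
  s
}

# Per-unit waveform-amplitude metadata from planted depths: amplitudes fall
# off as a Gaussian of depth distance around the unit, sampled at the five
# contacts centred on the largest one.
synth_unit_meta <- function(units, pitch_mm = 0.1, n_contacts = 32, seed = NULL,
                            amp_sigma_mm = 0.08, amp_jitter = 0.05) {
  contact_depth <- (n_contacts - seq_len(n_contacts)) * pitch_mm
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(units)), function(i) {
      d <- units$depth[i]
      peak <- which.min(abs(contact_depth - d))
      idx <- peak + (-2:2)
      ok <- idx >= 1 & idx <= n_contacts
      amps <- numeric(5)
      amps[ok] <- 100 * exp(-(contact_depth[idx[ok]] - d)^2 / (2 * amp_sigma_mm^2)) *
        pmax(0, 1 + stats::rnorm(sum(ok), 0, amp_jitter))
      data.frame(unit_id = units$unit_id[i], isolation = "single",
                 peak_contact = peak,
                 amp1 = amps[1], amp2 = amps[2], amp3 = amps[3],
                 amp4 = amps[4], amp5 = amps[5], stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate a laminar LFP block from a planted current-source-density map
#'
#' The planted CSD is a sum of Gaussian-in-depth, Gaussian-in-time
#' dipole components: an early sink centred in the granular band, a
#' deeper source followed by a later deep sink, and a superficial
#' source. The potential is obtained by solving the discrete Poisson
#' problem \eqn{\phi'' = -C} over depth with zero potential at both end
#' contacts, so the second-spatial-difference CSD estimator is its exact
#' inverse on interior contacts. Additive 1/f Gaussian noise emulates
#' background LFP.
#'
#' @param granular_band `c(top, bottom)` in mm; must lie within the probe
#' @param n_contacts,pitch_mm probe geometry
#' @param fs sampling rate, Hz
#' @param t_range time range of the trial-aligned average, ms
#' @param amplitude overall CSD scale (arbitrary units); `0` gives pure noise
#' @param noise_sd SD of the additive 1/f noise, mV
#' @param n_trials nominal trial count stored in the block
#' @param seed integer seed
#' @return an LFP block (list with `sampling_rate`, `data` time x contact
#'   ordered superficial to deep, `n_trials`, `t0`) with the planted
#'   contact-resolution CSD attached as attribute `"planted_csd"`
#' @export
sim_lfp_session <- function(granular_band = c(1.0, 1.4), n_contacts = 32,
                            pitch_mm = 0.1, fs = 1000, t_range = c(-100, 300),
                            amplitude = 1, noise_sd = 0.001,
                            n_trials = 50, seed = 1) {
  span <- (n_contacts - 1) * pitch_mm
  stop_if_not(granular_band[1] >= 0 && granular_band[2] <= span,
              "granular_band outside probe span")
  depth <- (seq_len(n_contacts) - 1) * pitch_mm   # superficial -> deep
  tms <- seq(t_range[1], t_range[2] - 1000 / fs, by = 1000 / fs)
  gauss <- function(x, mu, sd) exp(-(x - mu)^2 / (2 * sd^2))
  half_w <- diff(granular_band) / 2
  comps <- list(
    # leading granular sink (sink-positive)
    list(z = mean(granular_band), sz = half_w / sqrt(2 * log(2)),
         t = 60, st = 12, a = 2.0),
    # deep source then later deep sink
    list(z = granular_band[2] + 0.25, sz = 0.12, t = 75, st = 14, a = -1.2),
    list(z = granular_band[2] + 0.55, sz = 0.12, t = 120, st = 20, a = 0.8),
    # superficial return source
    list(z = granular_band[1] - 0.30, sz = 0.15, t = 70, st = 15, a = -0.8))
  csd <- matrix(0, length(tms), n_contacts)
  for (cp in comps)
    csd <- csd + amplitude * cp$a * outer(gauss(tms, cp$t, cp$st),
                                          gauss(depth, cp$z, cp$sz))
  # phi'' = -csd, phi = 0 at both end contacts (discrete, h = pitch)
  phi <- matrix(0, length(tms), n_contacts)
  ni <- n_contacts - 2
  A <- diag(-2, ni)
  A[cbind(seq_len(ni - 1), 2:ni)] <- 1
  A[cbind(2:ni, seq_len(ni - 1))] <- 1
  phi[, 2:(n_contacts - 1)] <-
    t(solve(A, t(-csd[, 2:(n_contacts - 1), drop = FALSE]) * pitch_mm^2))
  noise <- with_seed(seed, {
    if (noise_sd > 0) one_over_f_noise(length(tms), n_contacts, noise_sd)
    else matrix(0, length(tms), n_contacts)
  })
  out <- list(sampling_rate = fs, data = phi + noise, n_trials = n_trials,
              t0 = t_range[1])
  attr(out, "planted_csd") <- list(depth = depth, time = tms, values = csd)
  attr(out, "granular_band") <- granular_band
  out
}

# Columns of temporally-correlated (1/f amplitude spectrum) Gaussian noise,
# scaled to per-column SD `sd`.
one_over_f_noise <- function(n, ncol, sd) {
  m <- 2^ceiling(log2(n) + 1)
  f <- c(1, seq_len(m - 1))
  out <- vapply(seq_len(ncol), function(j) {
    spec <- (stats::rnorm(m) + 1i * stats::rnorm(m)) / sqrt(f)
    x <- Re(stats::fft(spec, inverse = TRUE))[seq_len(n)]
    x / stats::sd(x) * sd
  }, numeric(n))
  out
}

#' Simulate a reverse-correlation receptive-field mapping stream
#'
#' Probe stimuli appear every 50--60 ms at uniformly random grid
#' positions. Evoked spikes are Poisson with per-event mean
#' `gain * exp(-||pos - center||^2 / (2 sigma^2))`, placed inside the
#' 30--100 ms post-event count window, on top of a homogeneous
#' background that supplies the pre-event baseline counts.
#'
#' @param rf_center,rf_sigma planted Gaussian receptive field (dva)
#' @param grid list with `extent` (dva), `spacing` (dva) and `origin`
#'   (grid centre, dva)
#' @param n_events number of probe events (the default emulates a few
#'   minutes of mapping at 50--60 ms spacing)
#' @param gain mean evoked spikes per event at the RF centre (0 = no RF)
#' @param background_rate homogeneous background rate, sp/s
#' @param seed integer seed
#' @return list with `events` (data.frame `event_id`, `onset`, `az`,
#'   `el`) and `spike_times` (numeric, same clock as `onset`)
#' @export
sim_rf_events <- function(rf_center = c(5, 5), rf_sigma = 1.5,
                          grid = list(extent = 25, spacing = 1,
                                      origin = c(7.5, 7.5)),
                          n_events = 10000, gain = 12, background_rate = 30,
                          seed = 1) {
  stop_if_not(n_events >= 1, "n_events must be >= 1")
  half <- (grid$extent - grid$spacing) / 2
  az_vals <- grid$origin[1] + seq(-half, half, by = grid$spacing)
  el_vals <- grid$origin[2] + seq(-half, half, by = grid$spacing)
  with_seed(seed, {
    isi <- sample(c(50, 60), n_events, replace = TRUE)
    onset <- 400 + cumsum(isi) - isi[1]
    az <- sample(az_vals, n_events, replace = TRUE)
    el <- sample(el_vals, n_events, replace = TRUE)
    d2 <- (az - rf_center[1])^2 + (el - rf_center[2])^2
    mu <- gain * exp(-d2 / (2 * rf_sigma^2))
    n_ev <- stats::rpois(n_events, mu)
    ev_spk <- rep(onset, n_ev) + stats::runif(sum(n_ev), 35, 95)
    t_end <- onset[n_events] + 300
    bg_spk <- stats::runif(stats::rpois(1, background_rate * t_end / 1000),
                           0, t_end)
    list(events = data.frame(event_id = seq_len(n_events), onset = onset,
                             az = az, el = el),
         spike_times = sort(c(ev_spk, bg_spk)))
  })
}

#' Simulate an orientation-tuning session
#'
#' Trial rates follow a von Mises profile in the doubled angle,
#' `rate(theta) = baseline + gain * exp(kappa * (cos(2(theta - preferred)) - 1))`,
#' so `kappa = 0` gives an untuned unit with the same mean rate. Spikes
#' are homogeneous Poisson within the pre-trial (baseline) and evoked
#' segments.
#'
#' @param preferred preferred orientation, deg
#' @param kappa von Mises concentration (doubled angle), `>= 0`
#' @param n_orientations number of equally spaced orientations in \[0,180)
#' @param n_trials trials per orientation x polarity cell
#' @param baseline_rate,gain sp/s
#' @param seed integer seed
#' @return list with `trials` (data.frame `trial_id`, `orientation`,
#'   `polarity`) and `spikes` (data.frame `trial_id`, `t` ms, epoch
#'   \[-400, 400\])
#' @export
sim_orientation_session <- function(preferred = 45, kappa = 1.5,
                                    n_orientations = 12, n_trials = 10,
                                    baseline_rate = 5, gain = 30, seed = 1) {
  stop_if_not(kappa >= 0, "kappa must be >= 0")
  stop_if_not(n_trials >= 1, "n_trials must be >= 1")
  oris <- seq(0, 180 - 180 / n_orientations, by = 180 / n_orientations)
  trials <- expand.grid(orientation = oris, polarity = c(1, 2),
                        rep = seq_len(n_trials))
  trials <- data.frame(trial_id = seq_len(nrow(trials)),
                       orientation = trials$orientation,
                       polarity = trials$polarity)
  rate_of <- function(th) baseline_rate + gain *
    exp(kappa * (cos(2 * (th - preferred) * pi / 180) - 1))
  with_seed(seed, {
    spk <- lapply(seq_len(nrow(trials)), function(i) {
      r_ev <- rate_of(trials$orientation[i])
      # homogeneous segments: [-400,30) baseline, [30,230) evoked, [230,400) baseline
      seg <- function(a, b, r) {
        n <- stats::rpois(1, r * (b - a) / 1000)
        stats::runif(n, a, b)
      }
      tt <- c(seg(-400, 30, baseline_rate), seg(30, 230, r_ev),
              seg(230, 400, baseline_rate))
      if (length(tt) == 0) return(NULL)
      data.frame(trial_id = trials$trial_id[i], t = round(sort(tt) * 10) / 10)
    })
    spk <- do.call(rbind, spk)
    if (is.null(spk)) spk <- data.frame(trial_id = integer(), t = numeric())
    list(trials = trials, spikes = spk)
  })
}

#' Simulate responses to small flashed rings in the receptive field
#'
#' Rings (the stimuli also used for the CSD maps) evoke a brief
#' transient whose onset latency is the unit's classical-receptive-field
#' latency: earliest in the granular compartment under the default
#' ground truth. One condition, homogeneous trials.
#'
#' @param truth a `bo_ground_truth`
#' @param n_trials trials per unit
#' @param transient_ms duration of the evoked transient, ms
#' @param seed integer seed
#' @return list with `trials` and `spikes` data.frames (epoch \[-200, 400\] ms)
#' @export
sim_ring_session <- function(truth, n_trials = 30, transient_ms = 60, seed = 1) {
  units <- truth$units
  trials <- data.frame(trial_id = seq_len(n_trials), condition_id = 1L)
  tgrid <- seq(-200, 399)
  with_seed(seed, {
    out <- vector("list", nrow(units))
    for (i in seq_len(nrow(units))) {
      u <- units[i, ]
      env <- onset_ramp(tgrid + 0.5 - u$crf_latency) *
        (1 - onset_ramp(tgrid + 0.5 - u$crf_latency - transient_ms))
      rate <- u$baseline_rate + u$evoked_amplitude * env
      counts <- stats::rpois(length(tgrid) * n_trials,
                             rep(rate, n_trials) / 1000)
      nz <- which(counts > 0)
      if (length(nz)) {
        reps <- counts[nz]
        bin <- rep(tgrid[(nz - 1) %% length(tgrid) + 1], reps)
        tid <- rep(((nz - 1) %/% length(tgrid)) + 1, reps)
        tt <- round((bin + stats::runif(length(bin))) * 10) / 10
        out[[i]] <- data.frame(unit_id = u$unit_id, trial_id = tid, t = tt,
                               stringsAsFactors = FALSE)
      }
    }
    spk <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    if (is.null(spk)) spk <- data.frame(unit_id = character(),
                                        trial_id = integer(), t = numeric())
    list(trials = trials, spikes = spk)
  })
}
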