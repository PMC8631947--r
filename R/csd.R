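#' Current-source-density map from trial-averaged laminar LFP
#'
#' The trial-averaged LFP is band-pass filtered (zero-phase 2nd-order
#' Butterworth applied forward and backward, default 3.3--88 Hz) and the
#' CSD is computed as the negative discrete second spatial difference of
#' the potential, so current sinks are positive:
#' \deqn{CSD(z,t) = -[\phi(z+h) - 2\phi(z) + \phi(z-h)] / h^2.}
#' Edge contacts are dropped rather than extrapolated, and the depth
#' axis is interpolated to 10 um by cubic splines.
#'
#' @param lfp LFP block: list with `sampling_rate` (Hz), `data` (time x
#'   contact matrix, columns ordered superficial to deep), `t0` (ms)
#' @param pitch_mm contact pitch, mm
#' @param band band-pass corner frequencies in Hz, or `NULL` to skip
#'   filtering
#' @param interp_res_mm depth resolution of the interpolated map, mm
#' @return an object of class `csd_map`: `depth` (mm, interior
#'   contacts), `depth_interp`, `time` (ms), `values` and
#'   `values_interp` (time x depth, sink-positive)
#' @export
compute_csd <- function(lfp, pitch_mm = 0.1, band = c(3.3, 88),
                        interp_res_mm = 0.01) {
  phi <- lfp$data
  stop_if_not(ncol(phi) >= 3, "need >= 3 contacts for a second difference")
  fs <- lfp$sampling_rate
  if (!is.null(band)) phi <- apply(phi, 2, bandpass_zero_phase, fs = fs,
                                   band = band)
  n <- ncol(phi)
  csd <- -(phi[, 3:n, drop = FALSE] - 2 * phi[, 2:(n - 1), drop = FALSE] +
             phi[, 1:(n - 2), drop = FALSE]) / pitch_mm^2
  depth <- (seq_len(n) - 1) * pitch_mm
  depth_in <- depth[2:(n - 1)]
  depth_interp <- seq(depth_in[1], depth_in[length(depth_in)],
                      by = interp_res_mm)
  vi <- t(apply(csd, 1, function(row)
    stats::spline(depth_in, row, xout = depth_interp)$y))
  tms <- lfp$t0 + (seq_len(nrow(phi)) - 1) * 1000 / fs
  structure(list(depth = depth_in, depth_interp = depth_interp, time = tms,
                 values = csd, values_interp = vi, pitch_mm = pitch_mm,
                 band = band),
            class = "csd_map")
}

# Zero-phase 2nd-order Butterworth band-pass with reflected padding.
bandpass_zero_phase <- function(x, fs, band) {
  ny <- fs / 2
  bf <- signal::butter(2, c(band[1] / ny, band[2] / ny), type = "pass")
  npad <- min(length(x) - 1, 3 * ceiling(fs / band[1]))
  xp <- c(2 * x[1] - rev(x[2:(npad + 1)]), x,
          2 * x[length(x)] - rev(x[(length(x) - npad):(length(x) - 1)]))
  y <- signal::filtfilt(bf, xp)
  y[(npad + 1):(npad + length(x))]
}

#' @export
print.csd_map <- function(x, ...) {
  cat(sprintf("<csd_map> %d depths x %d samples, peak sink %.3g\n",
              length(x$depth), length(x$time), max(x$values)))
  invisible(x)
}

#' Identify the granular band from a CSD map
#'
#' Within the search window, depth clusters whose peak sink exceeds 50%
#' of the global sink maximum are treated as candidate sinks; the one
#' with the earliest threshold crossing is taken as the granular (input
#' layer) sink. The band is the contiguous depth range around the sink
#' centre where, at the sink's peak time, the CSD exceeds 50% of that
#' sink's peak. A map whose peak sink does not rise sufficiently above
#' the pre-stimulus noise floor is flagged uninterpretable and the
#' penetration is excluded from laminar analyses. The automatic call can
#' be overridden with an explicit band.
#'
#' @param csd a `csd_map`
#' @param search_window time window for the leading sink, ms
#' @param snr_min minimum ratio of peak sink to pre-stimulus CSD SD
#' @param override optional `c(top, bottom)` mm, bypassing detection
#' @return list of class `granular_band`: `top`, `bottom`, `center`
#'   (mm), `peak_sink_latency` (ms), `interpretable`
#' @export
identify_granular <- function(csd, search_window = c(0, 100), snr_min = 8,
                              override = NULL) {
  if (!is.null(override)) {
    stop_if_not(override[1] < override[2], "override: top must be above bottom")
    return(structure(list(top = override[1], bottom = override[2],
                          center = mean(override), peak_sink_latency = NA_real_,
                          interpretable = TRUE, source = "override"),
                     class = "granular_band"))
  }
  v <- csd$values_interp
  tsel <- csd$time >= search_window[1] & csd$time <= search_window[2]
  w <- v[tsel, , drop = FALSE]
  tw <- csd$time[tsel]
  pre <- v[csd$time < 0, , drop = FALSE]
  noise <- if (nrow(pre) >= 10) stats::sd(pre) else stats::mad(v)
  gmax <- max(w)
  if (!is.finite(gmax) || gmax <= 0 || (noise > 0 && gmax / noise < snr_min))
    return(structure(list(top = NA_real_, bottom = NA_real_, center = NA_real_,
                          peak_sink_latency = NA_real_, interpretable = FALSE,
                          source = "auto"),
                     class = "granular_band"))
  thr <- 0.5 * gmax
  depth_peak <- apply(w, 2, max)              # per-depth peak within window
  supra <- depth_peak >= thr
  runs <- rle(supra)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  clusters <- cbind(starts[runs$values], ends[runs$values])
  # earliest threshold crossing per cluster
  lat <- apply(clusters, 1, function(cl) {
    sub <- w[, cl[1]:cl[2], drop = FALSE]
    hit <- which(apply(sub >= thr, 1, any))
    if (length(hit)) tw[hit[1]] else Inf
  })
  cl <- clusters[which.min(lat), ]
  sub <- w[, cl[1]:cl[2], drop = FALSE]
  pk <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  peak_time <- tw[pk[1]]
  # band: contiguous >= 50% of the sink's peak on the depth profile
  # averaged over +/-10 ms around the peak time (robust to sample noise)
  tsel2 <- abs(csd$time - peak_time) <= 10
  prof <- colMeans(v[tsel2, , drop = FALSE])
  center_idx <- cl[1] + which.max(prof[cl[1]:cl[2]]) - 1
  ok <- prof >= 0.5 * prof[center_idx]
  i <- center_idx
  lo <- i; while (lo > 1 && ok[lo - 1]) lo <- lo - 1
  hi <- i; while (hi < length(ok) && ok[hi + 1]) hi <- hi + 1
  structure(list(top = csd$depth_interp[lo], bottom = csd$depth_interp[hi],
                 center = csd$depth_interp[i], peak_sink_latency = peak_time,
                 interpretable = TRUE, source = "auto"),
            class = "granular_band")
}

#' @export
print.granular_band <- function(x, ...) {
  if (x$interpretable)
    cat(sprintf("<granular_band> [%.2f, %.2f] mm, center %.2f mm, sink latency %s ms\n",
                x$top, x$bottom, x$center, format(x$peak_sink_latency)))
  else cat("<granular_band> uninterpretable CSD\n")
  invisible(x)
}

#' Assign units to laminar compartments
#'
#' Each unit's depth is the average of the five contact depths around
#' its peak contact, weighted by the peak-to-trough waveform amplitude
#' on those contacts (the unit sits where its waveform is largest).
#' Compartments follow the granular band: above the top is superficial,
#' within \[top, bottom\] granular, below the bottom deep. Units deeper
#' than 2 mm below the most superficial contact with multiunit activity
#' are excluded (white-matter guard), as are units with all-zero
#' amplitudes.
#'
#' @param units data.frame with `unit_id`, `peak_contact`, `amp1`..`amp5`
#' @param band an interpretable `granular_band`
#' @param topmost_active_contact index of the most superficial contact
#'   with multiunit activity (higher index = more superficial)
#' @param n_contacts,pitch_mm probe geometry
#' @param max_depth_below_top exclusion depth, mm
#' @return data.frame: `unit_id`, `depth` (mm), `depth_rel_granular_center`,
#'   `compartment` in superficial/granular/deep/excluded
#' @export
assign_layers <- function(units, band, topmost_active_contact,
                          n_contacts = 32, pitch_mm = 0.1,
                          max_depth_below_top = 2.0) {
  stop_if_not(isTRUE(band$interpretable), "granular band not interpretable")
  contact_depth <- (n_contacts - seq_len(n_contacts)) * pitch_mm
  top_active_depth <- contact_depth[topmost_active_contact]
  amps <- as.matrix(units[, paste0("amp", 1:5)])
  res <- lapply(seq_len(nrow(units)), function(i) {
    idx <- units$peak_contact[i] + (-2:2)
    ok <- idx >= 1 & idx <= n_contacts
    a <- amps[i, ok]
    d <- contact_depth[idx[ok]]
    if (sum(a) == 0) {
      warning("unit ", units$unit_id[i], ": all amplitudes zero, excluded")
      return(data.frame(unit_id = units$unit_id[i], depth = NA_real_,
                        depth_rel_granular_center = NA_real_,
                        compartment = "excluded", stringsAsFactors = FALSE))
    }
    depth <- sum(a * d) / sum(a)
    comp <- if (depth - top_active_depth > max_depth_below_top) "excluded"
    else if (depth < band$top) "superficial"
    else if (depth <= band$bottom) "granular"
    else "deep"
    data.frame(unit_id = units$unit_id[i], depth = depth,
               depth_rel_granular_center = depth - band$center,
               compartment = comp, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
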