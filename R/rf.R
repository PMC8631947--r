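#' Reverse-correlation receptive-field z-map
#'
#' For each grid position, spikes are counted in a window (default
#' \[30, 100\] ms) after each probe event at that position, and in a
#' same-length window immediately preceding each of those events. The
#' z-score is the mean evoked count minus the mean preceding count,
#' divided by the SD of the preceding counts. Positions whose baseline
#' SD is zero get `NA` (undefined), and a map with no defined position
#' is flagged empty.
#'
#' @param events data.frame with `onset` (ms), `az`, `el` (dva)
#' @param spike_times numeric vector of spike times on the same clock
#' @param count_window response window relative to event onset, ms
#' @return an object of class `rf_map`: grid axes, `z` matrix
#'   (az x el), per-position event counts, and an `empty` flag
#' @export
rf_zmap <- function(events, spike_times, count_window = c(30, 100)) {
  stop_if_not(nrow(events) >= 1, "no events")
  w <- diff(count_window)
  stop_if_not(w > 0, "count_window must have positive length")
  spike_times <- sort(spike_times)
  count_in <- function(a, b)
    findInterval(b, spike_times) - findInterval(a, spike_times)
  evoked <- count_in(events$onset + count_window[1],
                     events$onset + count_window[2])
  before <- count_in(events$onset - w, events$onset)
  az_vals <- sort(unique(events$az))
  el_vals <- sort(unique(events$el))
  key <- interaction(factor(events$az, az_vals), factor(events$el, el_vals),
                     drop = FALSE)
  mean_by <- function(x) tapply(x, key, mean)
  sd_by <- function(x) tapply(x, key, stats::sd)
  n_ev <- matrix(as.vector(tapply(evoked, key, length)),
                 length(az_vals), length(el_vals))
  mu_e <- matrix(as.vector(mean_by(evoked)), length(az_vals), length(el_vals))
  mu_b <- matrix(as.vector(mean_by(before)), length(az_vals), length(el_vals))
  sd_b <- matrix(as.vector(sd_by(before)), length(az_vals), length(el_vals))
  z <- (mu_e - mu_b) / sd_b
  z[!is.finite(z)] <- NA
  structure(list(az = az_vals, el = el_vals, z = z, n_events = n_ev,
                 empty = all(is.na(z)), contours = NULL, center = NULL),
            class = "rf_map")
}

#' @export
print.rf_map <- function(x, ...) {
  cat(sprintf("<rf_map> %d x %d grid, max z = %.2f%s\n",
              length(x$az), length(x$el),
              suppressWarnings(max(x$z, na.rm = TRUE)),
              if (is.null(x$center)) ""
              else sprintf(", center (%.2f, %.2f) dva", x$center[1], x$center[2])))
  invisible(x)
}

# Gaussian blur with NA-aware normalization; sigma in grid steps.
gauss_smooth2d <- function(z, sigma = 1) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  w <- !is.na(z)
  z0 <- ifelse(w, z, 0)
  conv1 <- function(m, along) {
    if (along == 2) m <- t(m)
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in (-r):r) {
      idx <- pmin(pmax(seq_len(n) + j, 1L), n)   # replicate edges
      out <- out + k[j + r + 1] * m[idx, , drop = FALSE]
    }
    if (along == 2) t(out) else out
  }
  num <- conv1(conv1(z0, 1), 2)
  den <- conv1(conv1(w * 1, 1), 2)
  out <- num / den
  out[den == 0] <- NA
  out
}

#' Smooth a receptive-field map and extract the cRF contour
#'
#' The z-map is smoothed with a Gaussian filter (default sigma of one
#' grid step) and closed contours are traced at the stated level
#' (default z = 3) by marching squares. Each contour is returned with
#' its polygon area centroid; the largest-area contour defines "the"
#' cRF and its centroid the map's `center`. An empty contour set is a
#' valid outcome, not an error.
#'
#' @param map an `rf_map`
#' @param sigma Gaussian smoothing SD in grid steps
#' @param level contour level on the smoothed z-map
#' @return the map with `z_smooth`, `contours` (list of data.frames with
#'   `az`, `el`, attribute `centroid`/`area`) and `center` filled in
#' @export
rf_contour <- function(map, sigma = 1, level = 3) {
  stop_if_not(!map$empty, "map has no defined z values")
  zs <- gauss_smooth2d(map$z, sigma)
  zfill <- zs
  zfill[is.na(zfill)] <- min(zfill, na.rm = TRUE)
  cl <- grDevices::contourLines(map$az, map$el, zfill, levels = level)
  contours <- lapply(cl, function(cc) {
    poly <- data.frame(az = cc$x, el = cc$y)
    ar <- polygon_area(poly$az, poly$el)
    attr(poly, "area") <- abs(ar)
    attr(poly, "centroid") <- polygon_centroid(poly$az, poly$el)
    poly
  })
  map$z_smooth <- zs
  map$contours <- contours
  map$level <- level
  if (length(contours)) {
    areas <- vapply(contours, function(p) attr(p, "area"), numeric(1))
    map$center <- attr(contours[[which.max(areas)]], "centroid")
  } else map$center <- NULL
  map
}

# Signed polygon area (shoelace); vertices need not repeat the first point.
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  sum(x[j] * y - x * y[j]) / 2
}

polygon_centroid <- function(x, y) {
  a <- polygon_area(x, y)
  if (abs(a) < 1e-12) return(c(mean(x), mean(y)))
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  cross <- x[j] * y - x * y[j]
  cx <- sum((x[j] + x) * cross) / (6 * a)
  cy <- sum((y[j] + y) * cross) / (6 * a)
  c(cx, cy)
}

#' Probe orthogonality metric D
#'
#' Fits a least-squares line through receptive-field centres stacked by
#' depth (within a 2 mm span starting at the most superficial centre)
#' and reports `D`, the displacement of the line's endpoints in the
#' azimuth x elevation plane per mm of depth. A perfectly orthogonal
#' penetration has vertically stacked receptive fields and `D = 0`.
#'
#' @param centers data.frame with `depth` (mm), `az`, `el` (dva)
#' @param span depth span used for the fit, mm
#' @return list of class `probe_orthogonality` with `D` (dva/mm), the
#'   fitted slopes and the centres used
#' @export
probe_orthogonality <- function(centers, span = 2.0) {
  keep <- centers$depth <= min(centers$depth) + span + 1e-9
  cc <- centers[keep, , drop = FALSE]
  stop_if_not(nrow(cc) >= 3, "insufficient data: need >= 3 centers within span")
  fa <- stats::lm(az ~ depth, data = cc)
  fe <- stats::lm(el ~ depth, data = cc)
  sa <- unname(stats::coef(fa)[2]); se <- unname(stats::coef(fe)[2])
  structure(list(D = sqrt(sa^2 + se^2), slope_az = sa, slope_el = se,
                 depth_span = span, n_centers = nrow(cc), centers = cc),
            class = "probe_orthogonality")
}

#' @export
print.probe_orthogonality <- function(x, ...) {
  cat(sprintf("<probe_orthogonality> D = %.3f dva/mm over %g mm (%d centers)\n",
              x$D, x$depth_span, x$n_centers))
  invisible(x)
}
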