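#' Session data model for laminar border-ownership recordings
#'
#' A session bundles everything recorded during one probe penetration:
#' the manifest (probe geometry, stimulus geometry, receptive-field grid),
#' the trial table, the spike table, per-unit metadata and, optionally,
#' trial-aligned laminar LFP. All times are milliseconds relative to
#' stimulus onset, angles are degrees, depths are millimetres increasing
#' downward from the most superficial contact.
#'
#' @param manifest list with at least `penetration_id`, `animal_id`,
#'   `n_contacts`, `contact_pitch_um`; optionally `datasets` (stimulus
#'   geometries), `rf_grid` and `seed`.
#' @param trials data.frame with columns `trial_id`, `condition_id` (1..4,
#'   odd/even encodes the owning side, the pairs \{1,2\} and \{3,4\} share
#'   the local edge), `edge_orientation` (deg), `edge_az`, `edge_el` (dva),
#'   `onset_time` (ms).
#' @param spikes data.frame with columns `unit_id`, `trial_id`, `t` (ms
#'   relative to stimulus onset).
#' @param units data.frame with columns `unit_id`, `isolation`
#'   (`"single"`/`"multi"`), `peak_contact`, and `amp1`..`amp5`, the
#'   peak-to-trough waveform amplitudes on the five contacts centred on
#'   `peak_contact` (edge contacts padded with 0).
#' @param lfp optional list with `sampling_rate` (Hz), `data` (time x
#'   contact matrix, mV, columns ordered superficial to deep), `n_trials`,
#'   `t0` (time of first sample, ms).
#' @return an object of class `bo_session`
#' @export
bo_session <- function(manifest, trials, spikes, units, lfp = NULL) {
  s <- structure(list(manifest = manifest, trials = trials, spikes = spikes,
                      units = units, lfp = lfp),
                 class = "bo_session")
  validate_session(s)
  s
}

#' Validate a session against the data-model invariants
#'
#' Checks field presence, value ranges (epoch bounds, condition ids,
#' positive pitch) and referential integrity (every spike's `trial_id`
#' exists, every spiking `unit_id` has metadata). Errors name the
#' offending field or ids.
#'
#' @param s a `bo_session`
#' @return the session, invisibly
#' @export
validate_session <- function(s) {
  m <- s$manifest
  for (f in c("penetration_id", "animal_id", "n_contacts", "contact_pitch_um"))
    stop_if_not(!is.null(m[[f]]), paste0("manifest field missing: ", f))
  stop_if_not(m$n_contacts >= 2, "manifest field n_contacts: must be >= 2")
  stop_if_not(m$contact_pitch_um > 0, "manifest field contact_pitch_um: must be > 0")
  if (!is.null(m$rf_grid))
    stop_if_not(m$rf_grid$spacing > 0, "manifest field rf_grid$spacing: must be > 0")
  if (!is.null(m$datasets)) for (d in m$datasets) {
    if (!is.null(d$square_size))
      stop_if_not(d$square_size >= 12 && d$square_size <= 20,
                  "manifest field datasets$square_size: outside [12, 20] dva")
  }
  tr <- s$trials
  stop_if_not(all(tr$condition_id %in% 1:4),
              "trials field condition_id: values outside {1,2,3,4}")
  stop_if_not(!anyDuplicated(tr$trial_id), "trials field trial_id: duplicates")
  sp <- s$spikes
  if (nrow(sp)) {
    stop_if_not(all(is.finite(sp$t)), "spikes field t: non-finite values")
    stop_if_not(all(sp$t >= -400 & sp$t <= 1500),
                "spikes field t: outside recorded epoch [-400, 1500] ms")
    bad <- setdiff(unique(sp$trial_id), tr$trial_id)
    stop_if_not(length(bad) == 0,
                paste0("spikes field trial_id: dangling references: ",
                       paste(utils::head(bad, 5), collapse = ", ")))
    badu <- setdiff(unique(sp$unit_id), s$units$unit_id)
    stop_if_not(length(badu) == 0,
                paste0("spikes field unit_id: no metadata for: ",
                       paste(utils::head(badu, 5), collapse = ", ")))
  }
  un <- s$units
  if (nrow(un)) {
    amps <- as.matrix(un[, paste0("amp", 1:5)])
    stop_if_not(all(amps >= 0), "units field amp1..amp5: negative amplitude")
  }
  if (!is.null(s$lfp)) {
    stop_if_not(s$lfp$sampling_rate > 0, "lfp field sampling_rate: must be > 0")
    stop_if_not(ncol(s$lfp$data) == m$n_contacts,
                "lfp field data: contact count differs from manifest n_contacts")
  }
  invisible(s)
}

#' @export
print.bo_session <- function(x, ...) {
  cat("<bo_session>", x$manifest$penetration_id,
      sprintf("(%s)\n", x$manifest$animal_id))
  cat(sprintf("  %d contacts @ %g um | %d trials | %d units | %d spikes | LFP: %s\n",
              x$manifest$n_contacts, x$manifest$contact_pitch_um,
              nrow(x$trials), nrow(x$units), nrow(x$spikes),
              if (is.null(x$lfp)) "absent" else "present"))
  invisible(x)
}

#' Write a session to a directory
#'
#' One JSON manifest plus delimited text tables (`trials.csv`,
#' `spikes.csv`, `units.csv`) and, when present, the trial-averaged LFP
#' matrix as `lfp.csv` with its metadata in the manifest.
#'
#' @param s a `bo_session`
#' @param dir output directory (created if needed)
#' @return `dir`, invisibly
#' @export
save_session <- function(s, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stop_if_not(dir.exists(dir), paste0("cannot create directory: ", dir))
  man <- s$manifest
  man$schema_version <- 1L
  if (!is.null(s$lfp))
    man$lfp_meta <- list(sampling_rate = s$lfp$sampling_rate,
                         n_trials = s$lfp$n_trials, t0 = s$lfp$t0)
  jsonlite::write_json(man, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(s$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(s$spikes, file.path(dir, "spikes.csv"), row.names = FALSE)
  utils::write.csv(s$units, file.path(dir, "units.csv"), row.names = FALSE)
  if (!is.null(s$lfp))
    utils::write.table(s$lfp$data, file.path(dir, "lfp.csv"), sep = ",",
                       row.names = FALSE, col.names = FALSE)
  invisible(dir)
}

#' Load a session from a directory written by [save_session()]
#'
#' @param dir session directory
#' @return a validated `bo_session`
#' @export
load_session <- function(dir) {
  mf <- file.path(dir, "manifest.json")
  stop_if_not(file.exists(mf), paste0("missing file: ", mf))
  man <- jsonlite::read_json(mf, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  read1 <- function(name, required = TRUE) {
    p <- file.path(dir, name)
    if (!file.exists(p)) {
      if (required) stop("missing file: ", p, call. = FALSE)
      return(NULL)
    }
    utils::read.csv(p, stringsAsFactors = FALSE)
  }
  trials <- read1("trials.csv")
  spikes <- read1("spikes.csv")
  units <- read1("units.csv")
  lfp <- NULL
  if (!is.null(man$lfp_meta)) {
    p <- file.path(dir, "lfp.csv")
    stop_if_not(file.exists(p), paste0("missing file: ", p))
    dat <- as.matrix(utils::read.table(p, sep = ","))
    dimnames(dat) <- NULL
    lfp <- list(sampling_rate = man$lfp_meta$sampling_rate, data = dat,
                n_trials = man$lfp_meta$n_trials, t0 = man$lfp_meta$t0)
  }
  man$lfp_meta <- NULL
  man$schema_version <- NULL
  bo_session(man, trials, spikes, units, lfp)
}

#' Serialize a stage result to JSON
#'
#' Results are written with a schema version; `NA` values (e.g. an
#' undefined latency) become explicit JSON nulls and survive a round
#' trip as `NA`.
#'
#' @param results a (possibly nested) list of stage outputs
#' @param path output file path
#' @return `path`, invisibly
#' @export
save_results <- function(results, path) {
  dir <- dirname(path)
  stop_if_not(dir.exists(dir) || dir.create(dir, recursive = TRUE),
              paste0("unwritable path: ", path))
  payload <- list(schema_version = 1L, results = results)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a result file written by [save_results()]
#' @param path file path
#' @return the deserialized results list
#' @export
load_results <- function(path) {
  stop_if_not(file.exists(path), paste0("missing file: ", path))
  jsonlite::read_json(path, simplifyVector = TRUE,
                      simplifyDataFrame = FALSE)$results
}

#' Border-ownership stimulus geometry
#'
#' Describes one four-condition stimulus set: a square abutting a central
#' edge through the receptive field. Conditions \{1,3\} place the owning
#' square on one side of the edge, \{2,4\} on the other; \{1,2\} share one
#' contrast polarity, \{3,4\} the reversed one. "Side" is the outward
#' normal direction from the central edge toward the owning square's
#' centre, in screen coordinates.
#'
#' @param edge_orientation orientation of the central edge, deg in \[0,180)
#' @param edge_az,edge_el centre of the central edge, dva
#' @param square_size side length of the square, dva (12..20 in the
#'   emulated design)
#' @param side_13 direction (deg) toward the square owning the edge in
#'   conditions 1 and 3; defaults to `edge_orientation + 90`
#' @return a list of class `bo_geometry` with the central edge segment,
#'   both candidate square polygons and the side directions
#' @export
bo_geometry <- function(edge_orientation, edge_az = 0, edge_el = 0,
                        square_size = 16,
                        side_13 = wrap360(edge_orientation + 90)) {
  stop_if_not(square_size > 0, "square_size must be > 0")
  th <- edge_orientation * pi / 180
  ex <- cos(th); ey <- sin(th)          # unit vector along the edge
  half <- square_size / 2
  edge <- rbind(c(edge_az - half * ex, edge_el - half * ey),
                c(edge_az + half * ex, edge_el + half * ey))
  square_at <- function(dir_deg) {
    phi <- dir_deg * pi / 180
    cx <- edge_az + half * cos(phi); cy <- edge_el + half * sin(phi)
    # square with one side along the central edge
    rbind(edge[1, ], edge[2, ],
          edge[2, ] + square_size * c(cos(phi), sin(phi)),
          edge[1, ] + square_size * c(cos(phi), sin(phi)))
  }
  side_24 <- wrap360(side_13 + 180)
  structure(list(edge_orientation = edge_orientation,
                 edge_az = edge_az, edge_el = edge_el,
                 square_size = square_size,
                 edge = edge,
                 side_13 = side_13, side_24 = side_24,
                 square_13 = square_at(side_13),
                 square_24 = square_at(side_24)),
            class = "bo_geometry")
}

# Owning-side direction for a condition id under a geometry.
condition_side <- function(geometry, condition_id) {
  ifelse(condition_id %% 2 == 1, geometry$side_13, geometry$side_24)
}
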