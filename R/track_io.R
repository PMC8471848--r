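#' Construct a track set
#'
#' A `track_set` is the internal container for single-particle tracking data:
#' a long-format spot table (one row per detected cell position) plus the
#' nominal frame interval and spatial units. It is the common currency between
#' the trajectory simulator, the tracking-export reader and the motility
#' statistics.
#'
#' @param spots data.frame with columns `track_id`, `x`, `y`, `t` and
#'   optionally `z` (missing `z` is set to 0 and the set flagged planar).
#'   Coordinates are micrometres, `t` is hours.
#' @param frame_interval nominal time between frames, hours.
#' @param spatial_units unit label for coordinates (informational).
#' @param validate run [validate_tracks()] on the result.
#' @return object of class `track_set`: the spot data.frame (sorted by
#'   `track_id`, then `t`) with attributes `frame_interval`, `spatial_units`
#'   and `planar`.
#' @export
track_set <- function(spots, frame_interval = 1, spatial_units = "micron",
                      validate = TRUE) {
  stopifnot(is.data.frame(spots))
  required <- c("track_id", "x", "y", "t")
  missing_cols <- setdiff(required, names(spots))
  if (length(missing_cols) > 0) {
    stop("spot table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  planar <- !("z" %in% names(spots))
  if (planar) spots$z <- rep(0, nrow(spots))
  spots <- spots[, c("track_id", "x", "y", "z", "t")]
  spots <- spots[order(spots$track_id, spots$t), , drop = FALSE]
  rownames(spots) <- NULL
  structure(spots,
            frame_interval = frame_interval,
            spatial_units = spatial_units,
            planar = planar,
            class = c("track_set", "data.frame"))
}

#' Validate a track set
#'
#' Checks the track-set invariants: finite coordinates, strictly increasing
#' timestamps within each track, and no duplicated (track, t) pairs.
#'
#' @param ts a [track_set()].
#' @return `ts`, invisibly, if valid; otherwise an error naming the offending
#'   track.
#' @export
validate_tracks <- function(ts) {
  stopifnot(inherits(ts, "track_set"))
  num <- as.data.frame(ts)[, c("x", "y", "z", "t")]
  if (!all(vapply(num, is.numeric, logical(1)))) {
    stop("track coordinates and timestamps must be numeric")
  }
  if (!all(is.finite(as.matrix(num)))) {
    stop("track set contains non-finite coordinates or timestamps")
  }
  for (id in unique(ts$track_id)) {
    tt <- ts$t[ts$track_id == id]
    if (any(diff(tt) <= 0)) {
      stop("track ", id, ": timestamps must be strictly increasing ",
           "(duplicate or non-monotone t)")
    }
  }
  invisible(ts)
}

#' Number of tracks in a track set
#' @param ts a [track_set()].
#' @return integer count of distinct track ids.
#' @export
n_tracks <- function(ts) length(unique(ts$track_id))

#' Split a track set into per-track spot tables
#' @param ts a [track_set()].
#' @return named list of data.frames, one per track, sorted by time.
#' @export
track_list <- function(ts) {
  split(as.data.frame(ts), ts$track_id)
}

# Column dialects accepted by read_tracks(). The uppercase one is the header
# used by common Fiji/TrackMate spot exports.
.track_dialects <- list(
  minimal = c(track_id = "track_id", x = "x", y = "y", z = "z", t = "t"),
  trackmate = c(track_id = "TRACK_ID", x = "POSITION_X", y = "POSITION_Y",
                z = "POSITION_Z", t = "POSITION_T")
)

#' Read a single-particle tracking export
#'
#' Reads a CSV table of tracked spots into a [track_set()]. Two header
#' dialects are auto-detected: the package's minimal header
#' (`track_id,x,y,z,t`) and the uppercase export header used by common
#' tracking tools (`TRACK_ID, POSITION_X, POSITION_Y, POSITION_Z,
#' POSITION_T`). The `z` column is optional; when absent, z is set to 0 and
#' the set is flagged planar. Non-spot metadata rows (as emitted below the
#' header by some exporters) are dropped when they fail numeric parsing of
#' the coordinate columns.
#'
#' @param path CSV file path.
#' @param dialect `"auto"` (default), `"minimal"` or `"trackmate"`.
#' @param frame_interval nominal frame interval, hours.
#' @param time_scale multiply the time column by this factor to obtain hours
#'   (e.g. `1/3600` for seconds).
#' @param space_scale multiply coordinates by this factor to obtain
#'   micrometres.
#' @return a validated [track_set()].
#' @export
read_tracks <- function(path, dialect = c("auto", "minimal", "trackmate"),
                        frame_interval = 1, time_scale = 1, space_scale = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("track file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  header <- names(raw)
  pick <- function(d) all(.track_dialects[[d]][c("track_id", "x", "y", "t")] %in% header)
  if (dialect == "auto") {
    dialect <- if (pick("minimal")) "minimal"
    else if (pick("trackmate")) "trackmate"
    else {
      # name the first missing required column of the closer dialect
      miss <- setdiff(.track_dialects$minimal[c("track_id", "x", "y", "t")], header)
      stop("unrecognised track table header; missing required column(s): ",
           paste(miss, collapse = ", "))
    }
  }
  cols <- .track_dialects[[dialect]]
  miss <- setdiff(cols[c("track_id", "x", "y", "t")], header)
  if (length(miss) > 0) {
    stop("track table is missing required column(s): ",
         paste(miss, collapse = ", "))
  }
  has_z <- cols[["z"]] %in% header
  spots <- data.frame(
    track_id = raw[[cols[["track_id"]]]],
    x = suppressWarnings(as.numeric(raw[[cols[["x"]]]])) * space_scale,
    y = suppressWarnings(as.numeric(raw[[cols[["y"]]]])) * space_scale,
    t = suppressWarnings(as.numeric(raw[[cols[["t"]]]])) * time_scale,
    stringsAsFactors = FALSE
  )
  if (has_z) {
    spots$z <- suppressWarnings(as.numeric(raw[[cols[["z"]]]])) * space_scale
  }
  # drop exporter metadata rows (units/sub-header lines parse to NA)
  bad <- is.na(spots$x) & is.na(spots$y) & is.na(spots$t)
  spots <- spots[!bad, , drop = FALSE]
  if (nrow(spots) > 0 && anyNA(spots[, c("x", "y", "t")])) {
    stop("track table contains non-numeric coordinate or time entries")
  }
  ts <- track_set(spots, frame_interval = frame_interval)
  validate_tracks(ts)
  ts
}

#' Write a track set to CSV
#'
#' Writes the minimal dialect (`track_id,x,y,z,t`) with a deterministic row
#' order (track id, then time), so identical track sets always produce
#' byte-identical files.
#'
#' @param ts a [track_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(ts, path) {
  stopifnot(inherits(ts, "track_set"))
  df <- as.data.frame(ts)
  df <- df[order(df$track_id, df$t), c("track_id", "x", "y", "z", "t")]
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Flag tracks unusable for speed and MSD statistics
#'
#' Tracks with a single spot carry no displacement information; tracks with
#' fewer than 3 spots are excluded from ensemble statistics.
#'
#' @param ts a [track_set()].
#' @return data.frame with `track_id`, `n_spots`, `usable_speed` (>= 2 spots)
#'   and `usable_ensemble` (>= 3 spots).
#' @export
track_qc <- function(ts) {
  n <- table(ts$track_id)
  data.frame(track_id = names(n),
             n_spots = as.integer(n),
             usable_speed = as.integer(n) >= 2,
             usable_ensemble = as.integer(n) >= 3,
             row.names = NULL, stringsAsFactors = FALSE)
}
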