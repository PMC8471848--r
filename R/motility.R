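#' Resample a track onto a uniform time grid
#'
#' Spots are binned to the nominal interval grid (anchored at the track's
#' first timestamp) by nearest timestamp; when several spots fall into one
#' bin the one closest to the grid time wins. Gaps longer than one interval
#' split the track into segments, so displacement statistics never bridge a
#' missing frame.
#'
#' @param spots data.frame for a single track (`x`, `y`, `z`, `t`).
#' @param interval grid spacing, hours.
#' @return data.frame with columns `x`, `y`, `z`, `t` (grid times), `step`
#'   (grid index) and `segment` (consecutive runs of present grid points).
#' @export
resample_track <- function(spots, interval = 1) {
  stopifnot(interval > 0)
  spots <- spots[order(spots$t), , drop = FALSE]
  idx <- round((spots$t - spots$t[1]) / interval)
  off <- abs(spots$t - spots$t[1] - idx * interval)
  keep <- !duplicated(idx[order(idx, off)])
  ord <- order(idx, off)
  spots <- spots[ord, , drop = FALSE][keep, , drop = FALSE]
  idx <- idx[ord][keep]
  segment <- cumsum(c(1, diff(idx) > 1))
  data.frame(x = spots$x, y = spots$y, z = spots$z,
             t = spots$t[1] + idx * interval,
             step = idx, segment = segment)
}

#' Per-track average migration speed
#'
#' Average speed is the mean of the absolute planar net displacement per
#' time interval: each interval's displacement magnitude
#' `sqrt(dx^2 + dy^2)` (micrometres per interval), averaged over intervals.
#' Net displacement per interval — not path length — so a cell that zig-zags
#' within an interval is credited only with where it ended up.
#'
#' @param spots data.frame for a single track (`x`, `y`, `z`, `t`), or a
#'   single-track [track_set()].
#' @param interval time interval, hours (default 1 h).
#' @return object of class `speed_series`: list with `magnitudes` (per
#'   interval, micrometres), `speed` (mean, micrometres/h), `n_intervals`,
#'   and `usable` (FALSE for single-spot tracks, where speed is `NA`).
#' @export
average_speed <- function(spots, interval = 1) {
  spots <- as.data.frame(spots)
  if (nrow(spots) < 2) {
    return(structure(list(magnitudes = numeric(0), speed = NA_real_,
                          n_intervals = 0L, usable = FALSE),
                     class = "speed_series"))
  }
  rs <- resample_track(spots, interval)
  mags <- numeric(0)
  for (seg in split(rs, rs$segment)) {
    if (nrow(seg) < 2) next
    consec <- diff(seg$step) == 1
    dx <- diff(seg$x)[consec]
    dy <- diff(seg$y)[consec]
    mags <- c(mags, sqrt(dx^2 + dy^2))
  }
  if (length(mags) == 0) {
    return(structure(list(magnitudes = numeric(0), speed = NA_real_,
                          n_intervals = 0L, usable = FALSE),
                     class = "speed_series"))
  }
  structure(list(magnitudes = mags, speed = mean(mags) / interval,
                 n_intervals = length(mags), usable = TRUE),
            class = "speed_series")
}

#' Average speed for every track in a set
#'
#' @param ts a [track_set()].
#' @param interval time interval, hours.
#' @return data.frame with `track_id`, `speed` (micrometres/h; `NA` for
#'   single-spot tracks), `n_intervals` and `usable`.
#' @export
track_speeds <- function(ts, interval = 1) {
  tl <- track_list(ts)
  res <- lapply(tl, average_speed, interval = interval)
  data.frame(track_id = names(tl),
             speed = vapply(res, function(r) r$speed, numeric(1)),
             n_intervals = vapply(res, function(r) r$n_intervals, integer(1)),
             usable = vapply(res, function(r) r$usable, logical(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Time-averaged mean squared displacement of a single track
#'
#' For a track of N steps (N + 1 positions at uniform spacing), the MSD at
#' lag n is the average over all overlapping windows:
#' \deqn{MSD(n) = \frac{1}{N-n+1} \sum_{i=0}^{N-n}
#'   [(x_{i+n}-x_i)^2 + (y_{i+n}-y_i)^2]}
#' Planar (x, y) coordinates only, matching speed; an optional 3D variant
#' adds the z term.
#'
#' @param spots data.frame for a single track, positions at uniform time
#'   spacing (`x`, `y`, and `z` if `use_z`), or a single-track
#'   [track_set()].
#' @param n_max largest lag to compute (default: N, the full range).
#' @param use_z include the z displacement (off by default).
#' @param tol relative tolerance on time-spacing uniformity.
#' @return object of class `msd_curve`: data.frame with `lag` (steps), `msd`
#'   (square micrometres) and `n_windows` (= N - n + 1 contributing
#'   intervals).
#' @export
msd <- function(spots, n_max = NULL, use_z = FALSE, tol = 1e-8) {
  spots <- as.data.frame(spots)
  if (nrow(spots) < 2) stop("MSD needs a track with at least one step")
  spots <- spots[order(spots$t), , drop = FALSE]
  dts <- diff(spots$t)
  if (diff(range(dts)) > tol * max(abs(dts))) {
    stop("MSD requires uniform time spacing; resample the track first")
  }
  N <- nrow(spots) - 1L
  if (is.null(n_max)) n_max <- N
  n_max <- min(n_max, N)
  lags <- seq_len(n_max)
  vals <- vapply(lags, function(n) {
    i <- seq_len(N - n + 1L)
    d2 <- (spots$x[i + n] - spots$x[i])^2 + (spots$y[i + n] - spots$y[i])^2
    if (use_z) d2 <- d2 + (spots$z[i + n] - spots$z[i])^2
    mean(d2)
  }, numeric(1))
  structure(data.frame(lag = lags, msd = vals, n_windows = N - lags + 1L),
            class = c("msd_curve", "data.frame"))
}

#' Ensemble (cell-averaged) MSD curve
#'
#' Per-lag mean and standard error of the per-track time-averaged MSD
#' curves, over the tracks long enough to possess that lag. Tracks with
#' fewer than 3 spots are excluded and counted in the QC attribute. Lags
#' where fewer than `min_frac` of the usable tracks contribute are reported
#' but flagged, so plots can cap the noisy tail.
#'
#' @param ts a [track_set()].
#' @param n_max largest lag (default: longest track).
#' @param use_z include z displacements.
#' @param min_frac contribution fraction below which a lag is flagged
#'   (default 0.5).
#' @return data.frame with `lag`, `msd_mean`, `sem`, `n_tracks` and
#'   `well_sampled`; attributes `qc` (excluded-track count) and `max_lag`
#'   (largest well-sampled lag).
#' @export
ensemble_msd <- function(ts, n_max = NULL, use_z = FALSE, min_frac = 0.5) {
  qc <- track_qc(ts)
  usable <- qc$track_id[qc$usable_ensemble]
  if (length(usable) == 0) stop("no track with >= 3 spots; ensemble MSD undefined")
  tl <- track_list(ts)[as.character(usable)]
  curves <- lapply(tl, msd, n_max = n_max, use_z = use_z)
  all_lags <- sort(unique(unlist(lapply(curves, function(cv) cv$lag))))
  per_lag <- lapply(all_lags, function(n) {
    v <- unlist(lapply(curves, function(cv) cv$msd[cv$lag == n]))
    c(mean = mean(v),
      sem = if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0,
      n = length(v))
  })
  m <- do.call(rbind, per_lag)
  out <- data.frame(lag = all_lags, msd_mean = m[, "mean"], sem = m[, "sem"],
                    n_tracks = as.integer(m[, "n"]))
  out$well_sampled <- out$n_tracks >= min_frac * length(usable)
  attr(out, "qc") <- list(n_excluded = sum(!qc$usable_ensemble),
                          n_used = length(usable))
  attr(out, "max_lag") <- max(out$lag[out$well_sampled])
  out
}

#' Log-log slope of an MSD curve
#'
#' Diagnostic of the motility regime: slope 1 for uncorrelated (diffusive)
#' motion, 2 for ballistic (straight-line) motion. Fit by ordinary least
#' squares of log(MSD) on log(lag) over the well-sampled lags.
#'
#' @param curve data.frame with `lag` and either `msd` or `msd_mean`.
#' @param lags subset of lags to fit (default: all positive-MSD rows).
#' @return slope (dimensionless).
#' @export
msd_loglog_slope <- function(curve, lags = NULL) {
  y <- if ("msd_mean" %in% names(curve)) curve$msd_mean else curve$msd
  keep <- y > 0
  if (!is.null(lags)) keep <- keep & curve$lag %in% lags
  if (sum(keep) < 2) stop("need at least two positive-MSD lags to fit a slope")
  unname(stats::coef(stats::lm(log(y[keep]) ~ log(curve$lag[keep])))[2])
}
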