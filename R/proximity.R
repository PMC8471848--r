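#' Nearest tumor-cell distance for each query cell
#'
#' Pairs every query cell (typically the macrophages) with its nearest
#' tumor cell by 3D Euclidean distance, using positions at the beginning of
#' imaging (immediately after gelation). Ties are broken by the lowest
#' tumor-cell id.
#'
#' @param cells data.frame with `x`, `y`, `z` and an id column (`cell_id` or
#'   `id`).
#' @param tumors data.frame of tumor-cell positions, same columns.
#' @return data.frame with `id`, `nearest_tumor_id` and `distance`
#'   (micrometres), one row per query cell, in input order.
#' @export
pair_distances <- function(cells, tumors) {
  get_id <- function(df) {
    if ("cell_id" %in% names(df)) df$cell_id
    else if ("id" %in% names(df)) df$id
    else seq_len(nrow(df))
  }
  if (nrow(tumors) == 0) stop("no tumor cells: paired distance undefined")
  zc <- if ("z" %in% names(cells)) cells$z else 0
  zt <- if ("z" %in% names(tumors)) tumors$z else 0
  tid <- get_id(tumors)
  ord <- order(tid)  # lowest-id-first so which.min breaks ties by tumor id
  tx <- tumors$x[ord]; ty <- tumors$y[ord]
  tz <- (if (length(zt) == 1) rep(zt, nrow(tumors)) else zt)[ord]
  tid <- tid[ord]
  d2 <- outer(cells$x, tx, "-")^2 + outer(cells$y, ty, "-")^2 +
    outer(if (length(zc) == 1) rep(zc, nrow(cells)) else zc, tz, "-")^2
  j <- apply(d2, 1, which.min)
  data.frame(id = get_id(cells),
             nearest_tumor_id = tid[j],
             distance = sqrt(d2[cbind(seq_len(nrow(cells)), j)]))
}

#' Assign close / far / middle proximity regimes
#'
#' Ranks macrophages by their initial distance to the nearest tumor cell
#' (ascending) and labels the `k` closest as the close group and the `k`
#' farthest as the far group; everything in between is retained as
#' `middle` (for speed-versus-distance scatter plots). Distance ties are
#' broken deterministically by macrophage id.
#'
#' @param records data.frame from [pair_distances()] (columns `id`,
#'   `distance`; extra columns such as `speed` are carried through).
#' @param k group size (default 15, the top-15 convention).
#' @return `records` with an added `regime` factor (close/middle/far),
#'   rows sorted by ascending distance.
#' @export
close_far_groups <- function(records, k = 15) {
  n <- nrow(records)
  if (n < 2 * k) {
    stop("need at least 2k = ", 2 * k, " records for disjoint close/far ",
         "groups (got ", n, "); use a smaller k")
  }
  ord <- order(records$distance, records$id)
  out <- records[ord, , drop = FALSE]
  out$regime <- "middle"
  out$regime[seq_len(k)] <- "close"
  out$regime[seq(n - k + 1, n)] <- "far"
  rownames(out) <- NULL
  out
}

#' One-tailed Welch comparison of close versus far speeds
#'
#' Tests whether tumor-proximal macrophages move faster than distal ones:
#' one-sided Welch (unequal-variance) t-test with alternative
#' mean(close) > mean(far) by default. When both groups have zero variance
#' and equal means the test is degenerate and reported as t = 0, p = 0.5
#' with a flag.
#'
#' @param close,far numeric vectors of average speeds (micrometres/h).
#' @param alternative direction of the alternative hypothesis
#'   (`"greater"`: close > far).
#' @return list with `mean_close`, `mean_far`, `t`, `df`, `p`,
#'   `alternative` and `degenerate`.
#' @export
compare_speeds <- function(close, far, alternative = "greater") {
  close <- close[!is.na(close)]; far <- far[!is.na(far)]
  if (length(close) < 2 || length(far) < 2) {
    stop("both groups need at least 2 members with defined speeds")
  }
  degenerate <- stats::var(close) == 0 && stats::var(far) == 0
  if (degenerate) {
    delta <- mean(close) - mean(far)
    t_stat <- if (delta == 0) 0 else sign(delta) * Inf
    p <- if (delta == 0) 0.5
    else if ((alternative == "greater") == (delta > 0)) 0 else 1
    return(list(mean_close = mean(close), mean_far = mean(far),
                t = t_stat, df = NA_real_, p = p,
                alternative = alternative, degenerate = TRUE))
  }
  tt <- stats::t.test(close, far, alternative = alternative,
                      var.equal = FALSE)
  list(mean_close = mean(close), mean_far = mean(far),
       t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, alternative = alternative, degenerate = FALSE)
}

#' Full proximity-motility analysis of a simulated or measured experiment
#'
#' Convenience wrapper: computes macrophage speeds from tracks, pairs each
#' macrophage with its nearest tumor cell at t0, forms the close/far
#' groups, and runs the one-tailed comparison.
#'
#' @param tracks a [track_set()] of all cells.
#' @param population data.frame of seeded positions and types
#'   (`cell_id`, `type`, `x`, `y`, `z`).
#' @param k close/far group size.
#' @param interval speed interval, hours.
#' @param alternative test direction (see [compare_speeds()]).
#' @return list with `records` (per-macrophage proximity + speed table with
#'   regimes) and `test` (the [compare_speeds()] result).
#' @export
proximity_analysis <- function(tracks, population, k = 15, interval = 1,
                               alternative = "greater") {
  mac <- population[population$type == "macrophage", , drop = FALSE]
  tum <- population[population$type == "tumor", , drop = FALSE]
  pr <- pair_distances(mac, tum)
  sp <- track_speeds(tracks, interval = interval)
  pr$speed <- sp$speed[match(pr$id, sp$track_id)]
  rec <- close_far_groups(pr, k = k)
  test <- compare_speeds(rec$speed[rec$regime == "close"],
                         rec$speed[rec$regime == "far"],
                         alternative = alternative)
  list(records = rec, test = test)
}
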