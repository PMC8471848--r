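#' Configuration for the synthetic tri-culture generator
#'
#' Bundles every tunable of the synthetic tumor-microenvironment generator:
#' domain geometry, seeding composition, persistent-random-walk motility,
#' proximity modulation, parametric cell shapes and secretion-plate
#' parameters. Defaults emulate the 3D melanoma tri-culture the package
#' quantifies: macrophage/fibroblast/tumor seeding densities 2400/600/200
#' K cells/mL (a 12:3:1 ratio, 75% macrophages), a 100 micrometre
#' tumor-proximity radius, 1 h frame interval, and a 40% single-cell
#' secretor fraction.
#'
#' @param domain_size c(Lx, Ly, Lz) in micrometres.
#' @param seeding_densities cells/mL per type, named
#'   (macrophage/fibroblast/tumor); only the ratio matters for composition.
#' @param n_total total number of seeded cells (allocated to types in
#'   proportion to `seeding_densities`).
#' @param dt frame interval, hours.
#' @param n_steps number of movement steps per trajectory.
#' @param base_speed_far,base_speed_close mean macrophage speed
#'   (micrometres/h) for cells starting farther/nearer than
#'   `proximity_radius` from the nearest tumor cell.
#' @param speed_cv coefficient of variation of the per-step step length
#'   (0 = deterministic step length).
#' @param proximity_radius distance (micrometres) below which a macrophage
#'   counts as tumor-proximal.
#' @param persistence directional persistence in [0, 1): mean resultant
#'   length of the turning-angle distribution (0 = uncorrelated headings,
#'   -> 1 = ballistic).
#' @param jitter_sd per-step positional jitter (micrometres) of the
#'   quasi-static fibroblasts and tumor cells.
#' @param shape_params list controlling [render_masks()]: `n` (named counts
#'   per morphology: disk, spindle, star), `disk_radius`, `spindle_axes`
#'   (semi-axes, px), `star_arms`, `star_outer`, `star_inner` (px),
#'   `image_size` (px), `margin` (px).
#' @param secretion_params list controlling [simulate_secretion_plate()]:
#'   `n_analytes`, `log_mean`, `log_sd`, `group_effect` (fold change planted
#'   in group 2), `affected_frac` (fraction of analytes carrying the
#'   effect), `lod` (pg/mL), `n_samples` (named per-group sample counts).
#' @param single_cell_params list controlling
#'   [simulate_single_cell_secretion()]: `n_cells`, `n_analytes`,
#'   `threshold`, `n_clusters`, `background_logsd`, `signal_logmean`,
#'   `signal_logsd`.
#' @param secretor_fraction probability in [0, 1] that a single cell is an
#'   active secretor.
#' @param seed integer seed; every generator draw flows from it.
#' @return object of class `sim_config` (validated list).
#' @export
sim_config <- function(domain_size = c(1000, 1000, 300),
                       seeding_densities = c(macrophage = 2400,
                                             fibroblast = 600,
                                             tumor = 200),
                       n_total = 320,
                       dt = 1,
                       n_steps = 12,
                       base_speed_far = 6,
                       base_speed_close = 12,
                       speed_cv = 0.2,
                       proximity_radius = 100,
                       persistence = 0.6,
                       jitter_sd = 0.3,
                       shape_params = list(
                         n = c(disk = 4, spindle = 4, star = 4),
                         disk_radius = 40,
                         spindle_axes = c(18, 55),
                         star_arms = 5, star_outer = 70, star_inner = 28,
                         image_size = 900, margin = 10),
                       secretion_params = list(
                         n_analytes = 12, log_mean = log(100), log_sd = 0.6,
                         group_effect = 2, affected_frac = 0.5, lod = 40,
                         n_samples = c(control = 10, treated = 10)),
                       single_cell_params = list(
                         n_cells = 500, n_analytes = 8, threshold = 50,
                         n_clusters = 3, background_logsd = 0.5,
                         signal_logmean_shift = 1.5, signal_logsd = 0.6),
                       secretor_fraction = 0.4,
                       seed = 1L) {
  cfg <- list(domain_size = domain_size,
              seeding_densities = seeding_densities,
              n_total = n_total, dt = dt, n_steps = n_steps,
              base_speed_far = base_speed_far,
              base_speed_close = base_speed_close,
              speed_cv = speed_cv,
              proximity_radius = proximity_radius,
              persistence = persistence, jitter_sd = jitter_sd,
              shape_params = shape_params,
              secretion_params = secretion_params,
              single_cell_params = single_cell_params,
              secretor_fraction = secretor_fraction,
              seed = as.integer(seed))
  if (any(domain_size <= 0)) stop("domain_size must be positive")
  if (dt <= 0) stop("dt must be positive")
  if (n_steps < 1) stop("n_steps must be >= 1")
  if (base_speed_far < 0 || base_speed_close < 0) stop("speeds must be >= 0")
  if (persistence < 0 || persistence >= 1) stop("persistence must lie in [0, 1)")
  if (proximity_radius <= 0) stop("proximity_radius must be > 0")
  if (secretor_fraction < 0 || secretor_fraction > 1) {
    stop("secretor_fraction must lie in [0, 1]")
  }
  if (any(seeding_densities < 0) || sum(seeding_densities) <= 0) {
    stop("seeding_densities must be non-negative with a positive total")
  }
  structure(cfg, class = "sim_config")
}

#' Allocate cell counts from seeding densities
#'
#' Splits a total cell count across types in proportion to seeding densities
#' (largest-remainder rounding, so counts always sum to the total).
#'
#' @param densities named non-negative densities (cells/mL).
#' @param n_total total cell count to allocate.
#' @return named integer vector of counts summing to `n_total`.
#' @export
population_counts <- function(densities, n_total) {
  if (n_total < 1) stop("n_total must be at least 1")
  frac <- densities / sum(densities)
  raw <- frac * n_total
  base <- floor(raw)
  rem <- n_total - sum(base)
  if (rem > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(densities))
}

#' Seed a synthetic cell population
#'
#' Places cells of each type uniformly at random in the 3D culture domain,
#' with per-type counts proportional to the configured seeding densities.
#'
#' @param config a [sim_config()].
#' @return object of class `cell_population`: data.frame with `cell_id`,
#'   `type` and `x`, `y`, `z` (micrometres).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  counts <- population_counts(config$seeding_densities, config$n_total)
  if (sum(counts) == 0) stop("population is empty")
  set.seed(config$seed)
  n <- sum(counts)
  pop <- data.frame(
    cell_id = seq_len(n),
    type = rep(names(counts), counts),
    x = stats::runif(n, 0, config$domain_size[1]),
    y = stats::runif(n, 0, config$domain_size[2]),
    z = stats::runif(n, 0, config$domain_size[3]),
    stringsAsFactors = FALSE
  )
  structure(pop, class = c("cell_population", "data.frame"))
}

# reflect positions into [0, L]
reflect_into <- function(x, L) {
  x <- x %% (2 * L)
  ifelse(x > L, 2 * L - x, x)
}

#' Simulate tri-culture trajectories
#'
#' Macrophages follow a planar persistent random walk: each step's heading
#' is the previous heading plus a wrapped-normal turning angle whose mean
#' resultant length is the `persistence` parameter, and the step length is
#' `speed * dt` with coefficient of variation `speed_cv` (truncated at 0).
#' The mean speed is `base_speed_close` for macrophages whose *initial* 3D
#' distance to the nearest tumor cell is at most `proximity_radius`, and
#' `base_speed_far` otherwise — proximity is assigned once, at seeding, so
#' the ground-truth regime is static. Fibroblasts and tumor cells are
#' quasi-static (isotropic planar jitter of sd `jitter_sd` per step).
#' Boundaries are reflecting; z is held fixed (speed and MSD are planar
#' statistics).
#'
#' @param population a [simulate_population()] result.
#' @param config a [sim_config()].
#' @return list with `tracks` (a [track_set()], all cells) and `truth`
#'   (data.frame: `cell_id`, `type`, `regime` (close/far/static),
#'   `dist_tumor` (initial 3D distance, micrometres), `true_speed`
#'   (configured mean speed, micrometres/h)).
#' @export
simulate_trajectories <- function(population, config) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(population) == 0) stop("population is empty")
  if (config$dt <= 0) stop("dt must be positive")
  tumors <- population[population$type == "tumor", , drop = FALSE]
  modulated <- config$base_speed_close != config$base_speed_far
  if (modulated && nrow(tumors) == 0) {
    stop("proximity modulation requires at least one tumor cell")
  }
  set.seed(config$seed + 1L)
  dt <- config$dt
  n_steps <- config$n_steps
  sigma_turn <- if (config$persistence <= 0) Inf else
    sqrt(-2 * log(config$persistence))

  dist_tumor <- rep(NA_real_, nrow(population))
  if (nrow(tumors) > 0) {
    pr <- pair_distances(population, tumors)
    dist_tumor <- pr$distance[match(population$cell_id, pr$id)]
  }

  spots <- vector("list", nrow(population))
  truth <- vector("list", nrow(population))
  for (i in seq_len(nrow(population))) {
    cell <- population[i, ]
    x <- numeric(n_steps + 1); y <- numeric(n_steps + 1)
    x[1] <- cell$x; y[1] <- cell$y
    if (cell$type == "macrophage") {
      close <- !is.na(dist_tumor[i]) && dist_tumor[i] <= config$proximity_radius
      speed <- if (close) config$base_speed_close else config$base_speed_far
      regime <- if (close) "close" else "far"
      heading <- stats::runif(1, 0, 2 * pi)
      for (s in seq_len(n_steps)) {
        heading <- if (is.finite(sigma_turn)) {
          heading + stats::rnorm(1, 0, sigma_turn)
        } else stats::runif(1, 0, 2 * pi)
        len <- speed * dt *
          max(0, stats::rnorm(1, 1, config$speed_cv))
        x[s + 1] <- x[s] + len * cos(heading)
        y[s + 1] <- y[s] + len * sin(heading)
      }
    } else {
      speed <- 0
      regime <- "static"
      if (config$jitter_sd > 0) {
        x <- x[1] + cumsum(c(0, stats::rnorm(n_steps, 0, config$jitter_sd)))
        y <- y[1] + cumsum(c(0, stats::rnorm(n_steps, 0, config$jitter_sd)))
      } else {
        x[] <- x[1]; y[] <- y[1]
      }
    }
    x <- reflect_into(x, config$domain_size[1])
    y <- reflect_into(y, config$domain_size[2])
    spots[[i]] <- data.frame(track_id = cell$cell_id, x = x, y = y,
                             z = cell$z, t = (0:n_steps) * dt)
    truth[[i]] <- data.frame(cell_id = cell$cell_id, type = cell$type,
                             regime = regime, dist_tumor = dist_tumor[i],
                             true_speed = speed, stringsAsFactors = FALSE)
  }
  list(tracks = track_set(do.call(rbind, spots), frame_interval = dt),
       truth = do.call(rbind, truth))
}

# ---- parametric shapes ---------------------------------------------------

# Continuous polygon (n x 2 matrix, closed implicitly) for each morphology,
# centered at the origin. The analytic ground truth is computed from these
# polygons.
shape_polygon <- function(type, params, n_circle = 256) {
  switch(type,
    disk = {
      th <- seq(0, 2 * pi, length.out = n_circle + 1)[-1]
      cbind(params$disk_radius * cos(th), params$disk_radius * sin(th))
    },
    spindle = {
      th <- seq(0, 2 * pi, length.out = n_circle + 1)[-1]
      cbind(params$spindle_axes[1] * cos(th), params$spindle_axes[2] * sin(th))
    },
    rect = {
      w <- params$rect_dims[1]; l <- params$rect_dims[2]
      cbind(c(-w, w, w, -w) / 2, c(-l, -l, l, l) / 2)
    },
    star = {
      k <- params$star_arms
      th <- seq(0, 2 * pi, length.out = 2 * k + 1)[-(2 * k + 1)]
      r <- rep(c(params$star_outer, params$star_inner), k)
      cbind(r * cos(th), r * sin(th))
    },
    stop("unknown shape type: ", type)
  )
}

polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

polygon_perimeter <- function(p) {
  d <- rbind(diff(p), p[1, ] - p[nrow(p), ])
  sum(sqrt(rowSums(d^2)))
}

# Analytic shape record from the continuous polygon: area, perimeter, convex
# perimeter (Euclidean hull), min-area rotated bounding box, and the three
# indices.
polygon_truth <- function(p) {
  area <- polygon_area(p)
  per <- polygon_perimeter(p)
  hull <- p[grDevices::chull(p), , drop = FALSE]
  cper <- polygon_perimeter(hull)
  bb <- min_area_rect(p)
  data.frame(area = area, perimeter = per, convex_perimeter = cper,
             bbox_width = bb[1], bbox_length = bb[2],
             compactness = 4 * pi * area / per^2,
             circularity = 4 * pi * area / cper^2,
             elongation = bb[1] / bb[2])
}

rotate_polygon <- function(p, angle) {
  rot <- cbind(c(cos(angle), sin(angle)), c(-sin(angle), cos(angle)))
  p %*% rot
}

# Even-odd point-in-polygon test, vectorized over query points.
points_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross & !is.na(cross))
    j <- i
  }
  inside
}

#' Render a synthetic label image of parametric cell shapes
#'
#' Draws non-overlapping disks (round cells), ellipses (spindle cells) and
#' k-armed stars (stellate cells) as filled polygons on a pixel grid, at
#' random positions and orientations, and records the analytic shape truth
#' (area, perimeter, convex perimeter, rotated bounding box and the three
#' indices) of each continuous polygon. The analytic indices are exact for
#' the continuous shape; the rasterized measurement carries a discretization
#' tolerance of about 3% at linear sizes of 30 px and above.
#'
#' @param config a [sim_config()] (uses `shape_params` and `seed`).
#' @param max_retries placement attempts per shape before giving up.
#' @return list with `mask` (a [labeled_mask()]) and `truth` (data.frame:
#'   `label`, `type`, the analytic geometry columns of the polygon truth).
#' @export
render_masks <- function(config, max_retries = 200) {
  stopifnot(inherits(config, "sim_config"))
  sp <- config$shape_params
  set.seed(config$seed + 2L)
  size <- sp$image_size
  margin <- if (is.null(sp$margin)) 10 else sp$margin
  img <- matrix(0L, size, size)
  placed <- list()  # center + radius for overlap rejection
  truth <- list()
  label <- 0L
  for (type in names(sp$n)) {
    for (rep_i in seq_len(sp$n[[type]])) {
      poly0 <- shape_polygon(type, sp)
      rad <- max(sqrt(rowSums(poly0^2)))
      ok <- FALSE
      for (try_i in seq_len(max_retries)) {
        cx <- stats::runif(1, margin + rad, size - margin - rad)
        cy <- stats::runif(1, margin + rad, size - margin - rad)
        clear <- TRUE
        for (pl in placed) {
          if (sqrt((cx - pl[1])^2 + (cy - pl[2])^2) < rad + pl[3] + 3) {
            clear <- FALSE; break
          }
        }
        if (clear) { ok <- TRUE; break }
      }
      if (!ok) {
        stop("could not place all shapes without overlap; ",
             "reduce counts or sizes")
      }
      angle <- stats::runif(1, 0, 2 * pi)
      poly <- rotate_polygon(poly0, angle)
      poly[, 1] <- poly[, 1] + cx
      poly[, 2] <- poly[, 2] + cy
      label <- label + 1L
      rr <- max(1, floor(cx - rad - 2)):min(size, ceiling(cx + rad + 2))
      cc <- max(1, floor(cy - rad - 2)):min(size, ceiling(cy + rad + 2))
      grid <- expand.grid(r = rr, c = cc)
      if (type == "disk") {
        hit <- (grid$r - cx)^2 + (grid$c - cy)^2 <= sp$disk_radius^2
      } else {
        hit <- points_in_polygon(grid$r, grid$c, poly)
      }
      img[cbind(grid$r[hit], grid$c[hit])] <- label
      placed[[label]] <- c(cx, cy, rad)
      tr <- polygon_truth(poly)
      if (type == "disk") {
        # exact closed forms beat the 256-gon approximation
        r0 <- sp$disk_radius
        tr$area <- pi * r0^2; tr$perimeter <- 2 * pi * r0
        tr$convex_perimeter <- 2 * pi * r0
        tr$bbox_width <- 2 * r0; tr$bbox_length <- 2 * r0
        tr$compactness <- 1; tr$circularity <- 1; tr$elongation <- 1
      }
      truth[[label]] <- cbind(data.frame(label = label, type = type,
                                         stringsAsFactors = FALSE), tr)
    }
  }
  list(mask = labeled_mask(img), truth = do.call(rbind, truth))
}

#' Simulate a multiplex secretion plate with below-range censoring
#'
#' Concentrations are log-normal per analyte; a planted fold-change
#' (`group_effect`) is applied to the first `affected_frac` of analytes in
#' every non-reference group. Values below the analyte's limit of detection
#' are censored: the concentration is masked (NA) and flagged below-range,
#' as in a real plate export.
#'
#' @param config a [sim_config()] (uses `secretion_params` and `seed`).
#' @return list with `table` (a [secretion_table()]) and `truth`
#'   (list: `group` per sample, `log_mean` matrix groups x analytes,
#'   `censored` flag matrix).
#' @export
simulate_secretion_plate <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  pp <- config$secretion_params
  if (pp$n_analytes < 1) stop("need at least one analyte")
  if (sum(pp$n_samples) < 2) stop("need at least two samples")
  set.seed(config$seed + 3L)
  analytes <- sprintf("A%02d", seq_len(pp$n_analytes))
  groups <- rep(names(pp$n_samples), pp$n_samples)
  n <- length(groups)
  affected <- seq_len(round(pp$affected_frac * pp$n_analytes))
  log_mu <- matrix(pp$log_mean, nrow = length(pp$n_samples),
                   ncol = pp$n_analytes,
                   dimnames = list(names(pp$n_samples), analytes))
  if (length(pp$n_samples) > 1 && length(affected) > 0) {
    log_mu[-1, affected] <- log_mu[-1, affected] + log(pp$group_effect)
  }
  conc <- matrix(NA_real_, n, pp$n_analytes,
                 dimnames = list(sprintf("S%02d", seq_len(n)), analytes))
  for (i in seq_len(n)) {
    conc[i, ] <- exp(stats::rnorm(pp$n_analytes,
                                  log_mu[groups[i], ], pp$log_sd))
  }
  lod <- rep(pp$lod, length.out = pp$n_analytes)
  censored <- sweep(conc, 2, lod, "<")
  if (any(colSums(!censored) == 0)) {
    warning("analyte(s) entirely below the limit of detection: ",
            paste(analytes[colSums(!censored) == 0], collapse = ", "))
  }
  obs <- conc
  obs[censored] <- NA_real_
  tab <- secretion_table(obs, censored = censored,
                         sample_groups = groups)
  list(table = tab,
       truth = list(group = groups, log_mean = log_mu, lod = lod,
                    censored = censored, true_conc = conc))
}

#' Simulate a single-cell secretion matrix with planted secretors
#'
#' Each cell is an active secretor with probability `secretor_fraction`.
#' Non-secretors draw every analyte from background noise strictly below
#' the positivity threshold. Secretors are assigned one of `n_clusters`
#' planted profiles (a contiguous block of analytes) and draw those
#' analytes from a signal distribution above threshold (the first profile
#' analyte is guaranteed above threshold, so every planted secretor is
#' detectable).
#'
#' @param config a [sim_config()] (uses `single_cell_params`,
#'   `secretor_fraction`, `seed`).
#' @return list with `matrix` (cells x analytes), `thresholds` (named
#'   per-analyte positivity thresholds) and `truth` (data.frame: `cell_id`,
#'   `secretor`, `cluster`).
#' @export
simulate_single_cell_secretion <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sc <- config$single_cell_params
  set.seed(config$seed + 4L)
  n <- sc$n_cells; k <- sc$n_analytes
  analytes <- sprintf("P%02d", seq_len(k))
  thr <- rep(sc$threshold, length.out = k)
  names(thr) <- analytes
  secretor <- stats::runif(n) < config$secretor_fraction
  cluster <- ifelse(secretor,
                    sample.int(sc$n_clusters, n, replace = TRUE), NA)
  # cluster c secretes a block of ceil(k / n_clusters) analytes
  block <- ceiling(k / sc$n_clusters)
  mat <- matrix(NA_real_, n, k, dimnames = list(sprintf("C%04d", seq_len(n)),
                                                analytes))
  for (i in seq_len(n)) {
    bg <- exp(stats::rnorm(k, log(thr) - 3, sc$background_logsd))
    bg <- pmin(bg, thr * 0.99)  # background is below threshold by definition
    mat[i, ] <- bg
    if (secretor[i]) {
      first <- (cluster[i] - 1) * block + 1
      cols <- first:min(first + block - 1, k)
      sig <- exp(stats::rnorm(length(cols),
                              log(thr[cols]) + sc$signal_logmean_shift,
                              sc$signal_logsd))
      mat[i, cols] <- sig
      if (all(mat[i, cols] <= thr[cols])) {
        mat[i, cols[1]] <- thr[cols[1]] * 1.5  # detectability guarantee
      }
    }
  }
  list(matrix = mat, thresholds = thr,
       truth = data.frame(cell_id = rownames(mat), secretor = secretor,
                          cluster = cluster, stringsAsFactors = FALSE))
}
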