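test_that("seeding densities 2400/600/200 give the 12:3:1, 75%-macrophage composition", {
  counts <- population_counts(c(macrophage = 2400, fibroblast = 600,
                                tumor = 200), 320)
  expect_equal(unname(counts), c(240L, 60L, 20L))
  expect_equal(unname(counts / 20), c(12, 3, 1))
  expect_equal(unname(counts[["macrophage"]] / sum(counts)), 0.75)

  cfg <- sim_config()
  pop <- simulate_population(cfg)
  expect_equal(sum(pop$type == "macrophage") / nrow(pop), 0.75)
})

test_that("single-type populations land inside the domain and seeds reproduce", {
  cfg <- sim_config(seeding_densities = c(macrophage = 1), n_total = 5,
                    domain_size = c(100, 50, 20))
  pop <- simulate_population(cfg)
  expect_equal(nrow(pop), 5)
  expect_true(all(pop$type == "macrophage"))
  expect_true(all(pop$x >= 0 & pop$x <= 100))
  expect_true(all(pop$y >= 0 & pop$y <= 50))
  expect_true(all(pop$z >= 0 & pop$z <= 20))
  expect_identical(pop, simulate_population(cfg))

  expect_error(sim_config(seeding_densities = c(macrophage = 0)), "positive")
  expect_error(sim_config(persistence = 1), "persistence")
})

test_that("zero-speed, zero-jitter trajectories are stationary", {
  cfg <- sim_config(base_speed_close = 0, base_speed_far = 0,
                    jitter_sd = 0, n_total = 32, n_steps = 5)
  pop <- simulate_population(cfg)
  tr <- simulate_trajectories(pop, cfg)
  sp <- track_speeds(tr$tracks)
  expect_true(all(sp$speed == 0))
  expect_equal(n_tracks(tr$tracks), nrow(pop))
})

test_that("ballistic limit: persistence near 1, no step noise, speed exact", {
  cfg <- sim_config(persistence = 1 - 1e-12, speed_cv = 0, jitter_sd = 0,
                    base_speed_close = 12, base_speed_far = 6,
                    n_total = 48, n_steps = 20,
                    domain_size = c(1e6, 1e6, 300))
  pop <- simulate_population(cfg)
  tr <- simulate_trajectories(pop, cfg)
  sp <- track_speeds(tr$tracks)
  mac <- merge(tr$truth[tr$truth$type == "macrophage", ], sp,
               by.x = "cell_id", by.y = "track_id")
  expect_equal(mac$speed, mac$true_speed, tolerance = 1e-9)
  # straight lines: per-track MSD follows the ballistic square law exactly
  one <- track_list(tr$tracks)[[as.character(mac$cell_id[1])]]
  curve <- msd(one)
  expect_equal(curve$msd, (mac$true_speed[1] * cfg$dt * curve$lag)^2,
               tolerance = 1e-6)
})

test_that("proximity-modulated speeds are recovered within 10% per regime", {
  cfg <- sim_config(n_total = 134, n_steps = 48, base_speed_close = 12,
                    base_speed_far = 6, seed = 11)
  pop <- simulate_population(cfg)
  tr <- simulate_trajectories(pop, cfg)
  sp <- track_speeds(tr$tracks)
  truth <- tr$truth
  truth$speed <- sp$speed[match(truth$cell_id, sp$track_id)]
  est <- tapply(truth$speed[truth$type == "macrophage"],
                truth$regime[truth$type == "macrophage"], mean)
  expect_lt(abs(est[["close"]] / 12 - 1), 0.10)
  expect_lt(abs(est[["far"]] / 6 - 1), 0.10)
  expect_error(simulate_trajectories(pop, sim_config(dt = 0)), "dt")
})

test_that("every simulated entity has exactly one ground-truth record", {
  cfg <- sim_config(n_total = 32, n_steps = 4)
  pop <- simulate_population(cfg)
  tr <- simulate_trajectories(pop, cfg)
  expect_setequal(unique(tr$tracks$track_id), pop$cell_id)
  expect_equal(sort(tr$truth$cell_id), sort(pop$cell_id))
  rm_ <- render_masks(cfg)
  expect_setequal(sort(unique(as.vector(rm_$mask[rm_$mask > 0]))),
                  rm_$truth$label)
})

test_that("rendered shapes carry correct analytic ground truth", {
  cfg <- sim_config(shape_params = list(n = c(disk = 1), disk_radius = 50,
                                        image_size = 200, margin = 5))
  rm_ <- render_masks(cfg)
  expect_equal(max(rm_$mask), 1)
  expect_equal(rm_$truth$compactness, 1)
  expect_equal(rm_$truth$area, pi * 50^2)

  rect <- tmequant:::polygon_truth(
    tmequant:::shape_polygon("rect", list(rect_dims = c(40, 80))))
  expect_equal(rect$elongation, 0.5)
  expect_equal(rect$area, 3200)

  star <- tmequant:::polygon_truth(
    tmequant:::shape_polygon("star", list(star_arms = 5, star_outer = 70,
                                          star_inner = 28)))
  expect_gt(star$circularity, star$compactness)

  tiny <- sim_config(shape_params = list(n = c(disk = 50), disk_radius = 40,
                                         image_size = 150, margin = 2))
  expect_error(render_masks(tiny), "overlap")
})

test_that("secretion plates honour their planted structure and censoring", {
  # zero log-sd, single group: all entries of an analyte identical
  cfg0 <- sim_config(secretion_params = list(
    n_analytes = 3, log_mean = log(50), log_sd = 0, group_effect = 1,
    affected_frac = 0, lod = 0, n_samples = c(only = 6)))
  pl0 <- simulate_secretion_plate(cfg0)
  expect_true(all(apply(pl0$table$conc, 2, function(v) diff(range(v)) == 0)))
  # lod 0: censoring mask all-false
  expect_false(any(pl0$table$censored))

  # planted 2x effect, small sd: ln-scale group means within 10%
  pl <- simulate_secretion_plate(block_plate_config(seed = 3, log_sd = 0.1))
  lnc <- log(pl$table$conc)
  for (j in 1:6) {
    for (g in c("control", "treated")) {
      est <- mean(lnc[pl$truth$group == g, j])
      expect_lt(abs(est / pl$truth$log_mean[g, j] - 1), 0.10)
    }
  }

  # every censored entry is strictly below its analyte's LOD
  cfg_c <- sim_config(seed = 5)
  plc <- simulate_secretion_plate(cfg_c)
  expect_gt(sum(plc$table$censored), 0)
  below <- plc$truth$true_conc[plc$table$censored]
  lods <- matrix(plc$truth$lod, nrow(plc$table$conc),
                 ncol(plc$table$conc), byrow = TRUE)[plc$table$censored]
  expect_true(all(below < lods))
})

test_that("planted secretor fractions are recovered at the extremes and in between", {
  base <- list(n_cells = 200, n_analytes = 8, threshold = 50,
               n_clusters = 3, background_logsd = 0.5,
               signal_logmean_shift = 1.5, signal_logsd = 0.6)
  for (f in c(0, 1)) {
    sc <- simulate_single_cell_secretion(
      sim_config(secretor_fraction = f, single_cell_params = base))
    cls <- classify_secretors(sc$matrix, sc$thresholds)
    expect_equal(cls$fraction, f)
  }
  big <- base; big$n_cells <- 1000
  sc <- simulate_single_cell_secretion(
    sim_config(secretor_fraction = 0.4, single_cell_params = big, seed = 9))
  cls <- classify_secretors(sc$matrix, sc$thresholds)
  expect_lt(abs(cls$fraction - 0.4), 0.04)
  # classification agrees with the planted flags exactly
  expect_equal(cls$secretor, sc$truth$secretor)
})

test_that("identical config and seed give bit-identical generator output", {
  cfg <- sim_config(seed = 42, n_total = 48, n_steps = 6)
  a <- simulate_trajectories(simulate_population(cfg), cfg)
  b <- simulate_trajectories(simulate_population(cfg), cfg)
  expect_identical(a, b)
  expect_identical(simulate_secretion_plate(cfg), simulate_secretion_plate(cfg))
  expect_identical(simulate_single_cell_secretion(cfg),
                   simulate_single_cell_secretion(cfg))
  expect_identical(render_masks(cfg)$mask, render_masks(cfg)$mask)
})
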