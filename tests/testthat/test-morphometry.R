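render_disk <- function(r, pad = 10) {
  n <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  idx <- expand.grid(i = 1:n, j = 1:n)
  matrix(as.integer((idx$i - c0)^2 + (idx$j - c0)^2 <= r^2), n, n)
}

test_that("segmentation: blank image, separated objects, self-consistency", {
  expect_warning(m0 <- segment_projection(matrix(0, 20, 20)), "empty")
  expect_equal(max(m0), 0)

  img <- matrix(0, 120, 120)
  img[20:40, 20:40] <- 1
  img[80:100, 80:100] <- 1
  img <- img + 0.01  # non-constant background
  m2 <- segment_projection(img, min_area = 10)
  expect_equal(max(m2), 2)

  # re-threshold the rendering of known shapes: same objects, >= 99% pixels
  cfg <- sim_config(seed = 8)
  rm_ <- render_masks(cfg)
  reseg <- segment_projection((unclass(rm_$mask) > 0) * 1.0, min_area = 10)
  expect_equal(max(reseg), max(rm_$mask))
  agree <- mean((unclass(reseg) > 0) == (unclass(rm_$mask) > 0))
  expect_gte(agree, 0.99)
})

test_that("8-connectivity keeps diagonal protrusions attached", {
  img <- matrix(0, 30, 30)
  img[10:15, 10:15] <- 1
  img[16, 16] <- 1; img[17, 17] <- 1  # diagonal chain off the corner
  lab <- tmequant:::label_components8(img)
  expect_equal(max(lab), 1)
})

test_that("disk indices are 1 within discretization tolerance (3%, 2% elongation)", {
  for (r in c(30, 50)) {
    si <- shape_indices(labeled_mask(render_disk(r)))
    expect_equal(si$compactness, 1, tolerance = 0.03)
    expect_equal(si$circularity, 1, tolerance = 0.03)
    expect_equal(si$elongation, 1, tolerance = 0.02)
    expect_false(si$touches_border)
  }
})

test_that("rectangle: elongation exactly 0.5, compactness pi/4 within 3%", {
  img <- matrix(0L, 200, 200)
  img[50:89, 40:119] <- 1L
  si <- shape_indices(labeled_mask(img))
  expect_equal(si$elongation, 0.5)
  expect_equal(si$bbox_width, 40)
  expect_equal(si$bbox_length, 80)
  expect_equal(si$compactness, pi / 4, tolerance = 0.03)
  # convexity: same digital metric for both boundaries, so equality holds
  expect_equal(si$circularity, si$compactness)
})

test_that("star fixtures: circularity exceeds compactness, both near analytic", {
  cfg <- sim_config(seed = 21, shape_params = list(
    n = c(star = 3), star_arms = 5, star_outer = 70, star_inner = 28,
    image_size = 500, margin = 10))
  rm_ <- render_masks(cfg)
  si <- shape_indices(rm_$mask)
  m <- merge(si, rm_$truth, by = "label", suffixes = c("", "_true"))
  expect_true(all(m$circularity > m$compactness))
  expect_true(all(abs(m$compactness / m$compactness_true - 1) < 0.05))
  expect_true(all(abs(m$circularity / m$circularity_true - 1) < 0.05))
  expect_true(all(m$convex_perimeter <= m$perimeter))
})

test_that("indices are scale-invariant within tolerance at 2x resolution", {
  s1 <- shape_indices(labeled_mask(render_disk(30)))
  s2 <- shape_indices(labeled_mask(render_disk(60)))
  expect_equal(s2$compactness, s1$compactness, tolerance = 0.03)
  expect_equal(s2$circularity, s1$circularity, tolerance = 0.03)
  expect_equal(s2$elongation, s1$elongation, tolerance = 0.02)
})

test_that("elongation is rotation-invariant within 3% for a rectangle", {
  base <- tmequant:::shape_polygon("rect", list(rect_dims = c(40, 80)))
  for (ang in c(0, 0.3, 0.7, 1.1)) {
    poly <- tmequant:::rotate_polygon(base, ang)
    poly[, 1] <- poly[, 1] + 100; poly[, 2] <- poly[, 2] + 100
    grid <- expand.grid(r = 1:200, c = 1:200)
    hit <- tmequant:::points_in_polygon(grid$r, grid$c, poly)
    img <- matrix(0L, 200, 200)
    img[cbind(grid$r[hit], grid$c[hit])] <- 1L
    si <- shape_indices(labeled_mask(img))
    expect_equal(si$elongation, 0.5, tolerance = 0.03)
  }
})

test_that("adding protrusions to a disk strictly decreases compactness", {
  disk <- render_disk(30)
  si0 <- shape_indices(labeled_mask(disk))
  spiky <- disk
  c0 <- 41
  spiky[c0 + (-1:1), (c0 + 29):(c0 + 39)] <- 1L  # one thin arm
  si1 <- shape_indices(labeled_mask(spiky))
  expect_lt(si1$compactness, si0$compactness)
})

test_that("compactness binning returns complementary percentages", {
  expect_equal(bin_compactness(c(0.9, 0.95, 0.99))$percent, c(0, 100))
  b <- bin_compactness(c(0.5, 0.9))
  expect_equal(b$percent, c(50, 50))
  expect_equal(sum(b$percent), 100)
  # ground-truth analytic indices bin exactly by construction
  cfg <- sim_config(seed = 13)
  tr <- render_masks(cfg)$truth
  b2 <- bin_compactness(tr)
  expect_equal(b2$n[b2$bin == "high"], sum(tr$compactness >= 0.8))

  # a border-touching object is flagged truncated
  img <- matrix(0L, 50, 50); img[1:10, 20:30] <- 1L
  expect_true(shape_indices(labeled_mask(img))$touches_border)
})

test_that("mask TIFF I/O round-trips 16-bit labels", {
  cfg <- sim_config(seed = 2, shape_params = list(
    n = c(disk = 2), disk_radius = 20, image_size = 150, margin = 5))
  rm_ <- render_masks(cfg)
  f <- tempfile(fileext = ".tif")
  write_mask(rm_$mask, f)
  back <- read_mask(f)
  expect_equal(unclass(back), unclass(rm_$mask), ignore_attr = TRUE)
})
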