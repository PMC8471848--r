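make_plate <- function(conc, censored = NULL) {
  secretion_table(conc, censored = censored)
}

test_that("below-range imputation substitutes the analyte's uncensored minimum", {
  conc <- matrix(c(5, NA, 7), 3, 1, dimnames = list(NULL, "A"))
  cen <- matrix(c(FALSE, TRUE, FALSE), 3, 1)
  imp <- impute_oor(make_plate(conc, cen))
  expect_equal(unname(imp$conc[, 1]), c(5, 5, 7))

  # no censored entries: unchanged
  full <- make_plate(matrix(1:6, 2, 3))
  expect_equal(impute_oor(full)$conc, full$conc)

  # exhaustive check on a random censored plate
  set.seed(12)
  x <- matrix(exp(rnorm(200, log(50), 1)), 20, 10)
  cen <- x < 20
  obs <- x; obs[cen] <- NA
  imp2 <- impute_oor(make_plate(obs, cen))
  for (j in 1:10) {
    mins <- min(x[!cen[, j], j])
    expect_true(all(imp2$conc[cen[, j], j] == mins))
    expect_equal(unname(imp2$conc[!cen[, j], j]), x[!cen[, j], j])
  }
  # idempotence
  expect_equal(impute_oor(imp2)$conc, imp2$conc)

  # fully censored analyte is left censored and flagged
  allc <- make_plate(matrix(NA_real_, 3, 1, dimnames = list(NULL, "Z")),
                     matrix(TRUE, 3, 1))
  expect_warning(impz <- impute_oor(allc), "Z")
  expect_true(all(is.na(impz$conc)))
})

test_that("ln and z-score transforms match their closed forms", {
  tab <- make_plate(matrix(c(1, exp(1), exp(2)), 3, 1))
  expect_equal(unname(transform_secretion(tab, "ln")$conc[, 1]), c(0, 1, 2))

  tab2 <- make_plate(matrix(c(1, 2, 3), 3, 1))
  expect_equal(unname(transform_secretion(tab2, "zscore")$conc[, 1]),
               c(-1, 0, 1))

  set.seed(3)
  big <- make_plate(matrix(exp(rnorm(300)), 20, 15))
  z <- transform_secretion(big, "zscore")
  expect_lt(max(abs(colMeans(z$conc))), 1e-12)
  expect_lt(max(abs(apply(z$conc, 2, sd) - 1)), 1e-12)
  # re-standardizing a z table reproduces it
  expect_lt(max(abs(transform_secretion(z, "zscore")$conc - z$conc)), 1e-12)

  withzero <- make_plate(matrix(c(0, 1, 2), 3, 1))
  expect_error(transform_secretion(withzero, "ln"), "pseudo_floor")
  expect_equal(unname(transform_secretion(withzero, "ln",
                                          pseudo_floor = 1)$conc[, 1]),
               c(0, 0, log(2)))
})

test_that("sample correlation matrix matches the textbook formula", {
  set.seed(5)
  x <- matrix(rnorm(60), 6, 10)
  x[2, ] <- x[1, ]                       # duplicated sample
  x[3, ] <- -(x[1, ] - mean(x[1, ]))     # centered negation
  x2 <- x - min(x) + 1
  cc <- correlation_matrix(make_plate(x2))
  expect_equal(cc, t(cc))
  expect_true(all(diag(cc) == 1))
  expect_equal(cc[1, 2], 1)
  expect_equal(cc[1, 3], -1)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      expect_equal(cc[i, j], pearson_textbook(x2[i, ], x2[j, ]),
                   tolerance = 1e-12)
    }
  }
  # zero-variance sample is reported missing, with a flag
  x2[4, ] <- 3
  cc2 <- correlation_matrix(make_plate(x2))
  expect_true(all(is.na(cc2[4, ])))
  expect_equal(attr(cc2, "flagged"), rownames(cc2)[4])
})

test_that("hierarchical clustering merges nearest profiles first and is stable", {
  x <- rbind(a = c(0, 0), b = c(0, 0), c = c(50, 50), d = c(80, -20))
  cl <- cluster_profiles(x)
  first <- cl$row_hclust$merge[1, ]
  expect_setequal(-first, c(1, 2))  # the identical pair merges first

  pts <- matrix(c(0, 1, 10), 3, 1)
  rownames(pts) <- c("p0", "p1", "p10")
  colnames(pts) <- "v"
  cl1 <- suppressWarnings(cluster_profiles(cbind(pts, pts)))
  expect_setequal(-cl1$row_hclust$merge[1, ], c(1, 2))

  # deterministic leaf order across runs
  set.seed(8)
  y <- matrix(rnorm(80), 10, 8)
  o1 <- cluster_profiles(y)$row_order
  o2 <- cluster_profiles(y)$row_order
  expect_identical(o1, o2)
})

test_that("planted two-group plates are recovered by dendrogram cut and PCA", {
  pl <- simulate_secretion_plate(block_plate_config(seed = 2))
  z <- transform_secretion(impute_oor(pl$table), "zscore")
  cl <- cluster_profiles(z, k = 2)
  agreement <- table(cl$row_clusters, pl$truth$group)
  expect_equal(sum(apply(agreement, 1, max)), nrow(z$conc))  # exact blocks

  pca <- pca_scores(z, 2)
  sil <- cluster::silhouette(as.integer(factor(pl$truth$group)),
                             dist(pca$scores[, 1, drop = FALSE]))
  expect_gt(mean(sil[, "sil_width"]), 0.5)
})

test_that("PCA scores: 1D data on PC1, orthonormal loadings, truncation warning", {
  line <- outer(1:6, c(1, 2, 3))  # samples on a line in analyte space
  expect_warning(pca <- pca_scores(make_plate(line), 2), "rank")
  expect_equal(pca$explained[1], 1)
  set.seed(10)
  x <- matrix(rnorm(80), 8, 10)
  p <- pca_scores(make_plate(x - min(x)), 5)
  gram <- t(p$loadings) %*% p$loadings
  expect_lt(max(abs(gram - diag(5))), 1e-10)
  expect_true(all(diff(p$explained) <= 1e-12))
  expect_lte(sum(p$explained), 1)
  expect_warning(pca_scores(make_plate(line), 5), "rank")
})

test_that("secretor classification counts analytes above threshold", {
  m <- matrix(0, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  thr <- c(a = 1, b = 1, c = 1)
  cls <- classify_secretors(m, thr)
  expect_equal(cls$fraction, 0)

  m2 <- matrix(5, 4, 3, dimnames = list(NULL, c("a", "b", "c")))
  cls2 <- classify_secretors(m2, thr)
  expect_equal(cls2$fraction, 1)
  expect_true(all(cls2$polyfunctionality == 3))
  expect_equal(cls2$polyfunctional_fraction, 1)

  # invariant to analyte column order
  set.seed(4)
  m3 <- matrix(runif(60, 0, 2), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  r1 <- classify_secretors(m3, thr)
  r2 <- classify_secretors(m3[, c(3, 1, 2)], thr)
  expect_equal(r1$secretor, r2$secretor)
  expect_equal(r1$polyfunctionality, r2$polyfunctionality)

  expect_error(classify_secretors(m3, c(a = 1, b = 1)), "c")
})

test_that("plate CSV round-trips concentrations and OOR markers", {
  cfg <- sim_config(seed = 31)
  pl <- simulate_secretion_plate(cfg)
  f <- tempfile(fileext = ".csv")
  write_secretion_csv(pl$table, f)
  expect_true(any(grepl("OOR<", readLines(f))))
  back <- read_secretion_csv(f)
  expect_equal(back$censored, pl$table$censored)
  expect_equal(back$conc, pl$table$conc, tolerance = 1e-9)
})
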