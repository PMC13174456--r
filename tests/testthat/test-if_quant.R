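test_that("ITGB4 mean intensity is the ROI mean and the compartment is enforced", {
  img <- matrix(100, 20, 20)
  roi <- matrix(TRUE, 20, 20)
  reg <- annotated_region(img, roi, "basal-epidermis")
  expect_equal(itgb4_mean_intensity(reg), 100)

  half <- matrix(c(rep(0, 200), rep(200, 200)), 20, 20)
  expect_equal(itgb4_mean_intensity(annotated_region(half, roi, "basal-epidermis")),
               100)
  wrong <- annotated_region(img, roi, "papillary-dermis")
  expect_error(itgb4_mean_intensity(wrong), "basal-epidermis")
  expect_error(annotated_region(img, roi & FALSE, "epidermis"), "empty ROI")

  ph <- render_if_phantom("itgb4", list(mean = 120, sd = 5), seed = 3)
  m <- itgb4_mean_intensity(annotated_region(ph$image, ph$roi, "basal-epidermis"))
  expect_lt(abs(m - 120), 3 * 5 / sqrt(ph$truth$n_px))
})

test_that("Ki67 indices normalize counts and degrade gracefully", {
  k <- ki67_indices(12L, 1000)
  expect_equal(k$cells_per_length, 0.012)
  expect_true(is.na(k$cells_per_ridge))
  k2 <- ki67_indices(12L, 1000, in_ridge = 6L, ridge_count = 3L)
  expect_equal(k2$cells_per_ridge, 2)
  # coordinate input counts rows; logical in_ridge sums
  cells <- data.frame(r = 1:9, c = 1:9)
  k3 <- ki67_indices(cells, 900, in_ridge = rep(c(TRUE, FALSE, FALSE), 3),
                     ridge_count = 3L)
  expect_equal(k3$n_cells, 9)
  expect_equal(k3$cells_per_ridge, 1)
  expect_error(ki67_indices(-1, 100), "non-negative")
})

test_that("CD31 segmentation separates, merges and drops objects correctly", {
  img <- matrix(10, 80, 120)
  img[20:30, 20:40] <- 200
  img[50:60, 70:95] <- 200
  roi <- matrix(TRUE, 80, 120)
  reg <- annotated_region(img, roi, "papillary-dermis")
  expect_equal(segment_cd31(reg)$n_objects, 2)
  expect_equal(segment_cd31(reg, threshold = 100)$n_objects, 2)
  # a 1-px bright bridge merges the two under 8-connectivity
  img2 <- img
  steps <- cbind(round(seq(25, 55, length.out = 40)),
                 round(seq(40, 70, length.out = 40)))
  img2[steps] <- 200
  expect_equal(segment_cd31(annotated_region(img2, roi, "papillary-dermis"),
                            threshold = 100)$n_objects, 1)
  blank <- annotated_region(matrix(10, 40, 40), matrix(TRUE, 40, 40),
                            "papillary-dermis")
  expect_equal(segment_cd31(blank, threshold = 100)$n_objects, 0)
  expect_error(segment_cd31(annotated_region(img, roi, "epidermis")),
               "papillary-dermis")
})

test_that("vessel features match analytic geometry of known shapes", {
  # filled axis-aligned 20x10 ellipse
  img <- matrix(5, 60, 60)
  for (r in 1:60) for (c in 1:60) {
    if (((r - 30) / 5)^2 + ((c - 30) / 10)^2 <= 1) img[r, c] <- 200
  }
  vf <- vessel_features(segment_cd31(
    annotated_region(img, matrix(TRUE, 60, 60), "papillary-dermis"),
    threshold = 100), img)
  expect_equal(vf$aspect_ratio, 2, tolerance = 0.1)
  expect_equal(vf$minor_axis, 10, tolerance = 0.1 * 10)
  expect_gte(vf$solidity, 0.95)
  expect_equal(vf$mean_intensity, 200)
  expect_equal(vf$sum_intensity, 200 * vf$area)

  # filled square: inertia ellipse is a circle
  sq <- matrix(5, 40, 40); sq[10:29, 10:29] <- 200
  vsq <- vessel_features(segment_cd31(
    annotated_region(sq, matrix(TRUE, 40, 40), "papillary-dermis"),
    threshold = 100), sq)
  expect_lt(vsq$eccentricity, 0.1)
  expect_gte(vsq$solidity, 0.99)

  # C-shaped arc is far from convex
  arc <- matrix(5, 60, 60)
  for (r in 1:60) for (c in 1:60) {
    rad <- sqrt((r - 30)^2 + (c - 30)^2)
    ang <- atan2(r - 30, c - 30)
    if (rad >= 15 && rad <= 22 && abs(ang) > pi / 3) arc[r, c] <- 200
  }
  varc <- vessel_features(segment_cd31(
    annotated_region(arc, matrix(TRUE, 60, 60), "papillary-dermis"),
    threshold = 100), arc)
  expect_lt(varc$solidity, 0.6)

  # degenerate 1-px object
  one <- matrix(5, 20, 20); one[10, 10] <- 200
  v1 <- vessel_features(segment_cd31(
    annotated_region(one, matrix(TRUE, 20, 20), "papillary-dermis"),
    threshold = 100, min_object_px = 1), one)
  expect_equal(v1$major_axis, 1)
  expect_equal(v1$solidity, 1)
})

test_that("intensity scaling moves intensity features and leaves geometry alone", {
  ph <- render_if_phantom("cd31", list(n_objects = 6), seed = 8)
  reg <- annotated_region(ph$image, ph$roi, "papillary-dermis")
  seg <- segment_cd31(reg, threshold = 100)
  a <- vessel_features(seg, ph$image)
  b <- vessel_features(seg, ph$image * 3)
  expect_equal(b$mean_intensity, 3 * a$mean_intensity)
  expect_equal(b$sum_intensity, 3 * a$sum_intensity)
  expect_equal(b$median_intensity, 3 * a$median_intensity)
  expect_identical(a[c("area", "eccentricity", "solidity", "major_axis")],
                   b[c("area", "eccentricity", "solidity", "major_axis")])
})

test_that("section summary averages regions and is permutation-invariant", {
  ph <- render_if_phantom("cd31", seed = 5)
  reg <- annotated_region(ph$image, ph$roi, "papillary-dermis")
  vf <- vessel_features(segment_cd31(reg), ph$image)
  expect_equal(nrow(vf), 10)
  expect_gte(mean(vf$solidity), 0.95) # filled convex ellipses

  # identical regions: summary equals single-region stats
  s1 <- summarize_cd31(list(vf), sum(ph$roi))
  s5 <- summarize_cd31(rep(list(vf), 5), rep(sum(ph$roi), 5))
  expect_equal(s5$solidity_mean, s1$solidity_mean)
  expect_equal(s5$area_median, s1$area_median)

  # stated area-fraction example via heterogeneous regions
  regs <- lapply(c(0.1, 0.2, 0.3, 0.2, 0.2), function(f) {
    tibble::tibble(area = f * 100, eccentricity = 0.5, solidity = 1,
                   perimeter = 10, major_axis = 5, minor_axis = 4,
                   aspect_ratio = 1.2, sum_intensity = 10,
                   mean_intensity = 1, median_intensity = 1)
  })
  s <- summarize_cd31(regs, rep(100, 5))
  expect_equal(s$cd31_area_fraction, 0.2)

  # permutation invariance over region order
  perm <- summarize_cd31(regs[c(3, 1, 5, 2, 4)], rep(100, 5))
  expect_equal(s, perm)
})
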