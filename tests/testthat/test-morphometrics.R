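test_that("aggregate statistics match a brute-force reference", {
  withr::with_seed(7, {
    for (i in 1:5) {
      x <- rnorm(sample(10:200, 1))
      got <- as.numeric(agg_stats(x, "v"))
      expect_equal(got, unname(brute_stats(x)), tolerance = 1e-12)
    }
  })
  # stated order-statistics example
  s <- agg_stats(c(10, 10, 20, 20), "t")
  expect_equal(s$t_median, 15)
  expect_equal(s$t_iqr, 10)
  expect_equal(s$t_range, 10)
  expect_true(all(is.na(agg_stats(numeric(0), "e"))))
})

test_that("thickness profile doubles the nearest-boundary distance", {
  # 21-px tall band with the midline centred: thickness ~ 20 everywhere
  band <- matrix(FALSE, 41, 120); band[10:30, 10:110] <- TRUE
  eb <- boundary_index(band, "epidermis")
  midline <- cbind(rep(20, 81), 20:100)
  tp <- thickness_profile(midline, eb)
  expect_true(all(abs(tp - 20) <= 2))
  # a midline pixel right next to the boundary has thickness 2
  expect_equal(thickness_profile(cbind(11, 50), eb), 2)
})

test_that("annulus thickness profile is constant up to discretization", {
  dims <- c(121, 121)
  rad <- sqrt(outer((1:121 - 61)^2, rep(1, 121)) +
                outer(rep(1, 121), (1:121 - 61)^2))
  ring <- rad >= 35 & rad <= 55
  eb <- boundary_index(ring, "epidermis")
  mid <- which(abs(rad - 45) < 0.5 & ring, arr.ind = TRUE)
  tp <- thickness_profile(mid, eb)
  expect_lt(stats::sd(tp) / mean(tp), 0.10)
  expect_true(all(tp > 0))
})

test_that("ridge metrics recover the generating geometry", {
  # protrusion of 50 px with the junction on the midline: length ~ 50 + T/2.
  # Measured on the generating mask itself to isolate the metric from
  # segmentation-boundary trimming.
  ph <- small_phantom(seed = 31, n_ridges = 4, ridge_length = 50,
                      ridge_base_width = 24, ridge_end_width = 24,
                      undulation_amplitude = 0.01, width = 700)
  tb <- boundary_index(ph$truth$tissue_mask, "tissue")
  g <- analyze_component(ph$truth$epidermis_mask, tb)
  eb <- boundary_index(ph$truth$epidermis_mask, "epidermis")
  rm_ <- ridge_metrics(g, eb)
  expect_equal(nrow(rm_), 4)
  expected <- 50 + ph$truth$spec$band_thickness / 2
  # thinning retracts the skeleton endpoint slightly beyond the half-width
  # compensated by the tip-to-boundary term: ~10% systematic shortfall
  expect_true(all(abs(rm_$length - expected) / expected < 0.15))
  expect_true(all(rm_$base_thickness > 0 & rm_$end_thickness > 0))
  expect_true(all(rm_$dilation_factor > 0))
})

test_that("dilation factor tracks the generated taper ratio", {
  # with band thickness equal to the base width, end/base thickness recovers
  # the drawn width ratio
  mk <- function(end_w) {
    ph <- render_he_phantom(skin_phantom_spec(
      band_thickness = 30, n_ridges = 4, ridge_length = 70,
      ridge_base_width = 30, ridge_end_width = end_w, width = 750, seed = 17))
    g <- analyze_component(ph$truth$epidermis_mask,
                           boundary_index(ph$truth$tissue_mask, "tissue"))
    eb <- boundary_index(ph$truth$epidermis_mask, "epidermis")
    stats::median(ridge_metrics(g, eb)$dilation_factor)
  }
  expect_lt(abs(mk(30) - 1), 0.2)      # equal widths -> ~1
  expect_lt(abs(mk(15) - 0.5), 0.2)    # tip half as wide -> ~0.5
})

test_that("slice records satisfy the exact arithmetic invariants", {
  ph <- small_phantom(seed = 4, width = 700)
  an <- analyze_phantom(ph)
  rec <- slice_features(list(an$graph), an$epidermis, "acc1", 2L)
  expect_equal(rec$ridge_density,
               rec$ridge_count / rec$epidermal_length_px)
  expect_equal(rec$thickness_iqr, rec$thickness_p75 - rec$thickness_p25)
  expect_equal(rec$area_per_length,
               sum(an$graph$component_mask) / rec$epidermal_length_px)
  expect_equal(rec$ID, "acc1")

  # flat band (no ridges): ridge aggregates missing, density 0
  ph0 <- small_phantom(seed = 5, n_ridges = 0, width = 700)
  an0 <- analyze_phantom(ph0)
  rec0 <- slice_features(list(an0$graph), an0$epidermis, "acc0")
  expect_equal(rec0$ridge_count, 0)
  expect_equal(rec0$ridge_density, 0)
  expect_true(is.na(rec0$ridge_length_median))

  # rejected-only slices emit no record
  short <- line_mask(100)
  g <- analyze_component(short, boundary_index(short, "tissue"))
  expect_message(out <- slice_features(list(g), NULL, "accX"), "no accepted")
  expect_null(out)
})

test_that("scaling a phantom doubles lengths and halves density", {
  base <- skin_phantom_spec(n_ridges = 3, ridge_length = 40,
                            ridge_base_width = 16, ridge_end_width = 14,
                            band_thickness = 24, width = 640, seed = 9)
  dbl <- skin_phantom_spec(n_ridges = 3, ridge_length = 80,
                           ridge_base_width = 32, ridge_end_width = 28,
                           band_thickness = 48, width = 1280,
                           ridge_spacing = 2 * base$ridge_spacing,
                           undulation_amplitude = 12,
                           undulation_period = 600, seed = 9)
  r1 <- {
    an <- analyze_phantom(render_he_phantom(base))
    slice_features(list(an$graph), an$epidermis, "a")
  }
  r2 <- {
    an <- analyze_phantom(render_he_phantom(dbl))
    slice_features(list(an$graph), an$epidermis, "b")
  }
  expect_equal(r2$ridge_length_median / r1$ridge_length_median, 2,
               tolerance = 0.15)
  expect_equal(r2$base_thickness_median / r1$base_thickness_median, 2,
               tolerance = 0.15)
  expect_equal(r2$ridge_density / r1$ridge_density, 0.5, tolerance = 0.15)
  # dilation factor is scale-invariant
  expect_equal(r2$dilation_factor_median, r1$dilation_factor_median,
               tolerance = 0.2)
})

test_that("age-trend fits recover exact lines and flag degenerate input", {
  d <- tibble::tibble(age = seq(20, 80, length.out = 30))
  d$y <- 2 * d$age + 1
  tr <- suppressWarnings(fit_age_trend(d, "y")) # exact fit: lm warns
  expect_equal(tr$slope, 2, tolerance = 1e-10)
  expect_equal(tr$r_squared, 1, tolerance = 1e-10)
  expect_lt(tr$p_value, 1e-20)
  expect_equal(tidy(tr)$estimate, c(1, 2), tolerance = 1e-8)
  band <- augment_trend(tr)
  expect_true(all(band$.lower <= band$.fitted & band$.fitted <= band$.upper))

  const <- tibble::tibble(age = c(20, 40, 60), y = c(5, 5, 5))
  tc <- fit_age_trend(const, "y")
  expect_equal(tc$slope, 0)
  expect_equal(tc$p_value, 1)
  expect_equal(tc$degenerate, "constant_feature")

  two <- tibble::tibble(age = c(20, 60), y = c(1, 3))
  t2 <- fit_age_trend(two, "y")
  expect_true(is.na(t2$p_value))
  expect_equal(t2$degenerate, "zero_residual_df")
  expect_equal(t2$slope, 0.05)
})
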