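#' Specification of a synthetic H&E skin phantom
#'
#' Describes an epidermis band of controllable thickness with downward
#' trapezoidal rete-ridge protrusions (rounded tips) over a pale dermis, with
#' sinusoidal surface undulation and nuclear dots, rendered in H&E-like stain
#' colors by optical-density composition. The seed fully determines the
#' output. Defaults are the package's reference phantom: a 40 px band with 6
#' ridges of length 80 px, base width 24 px and end width 20 px.
#'
#' Geometry note: the skeleton junction of a ridge sits at band mid-depth, so
#' the measured base thickness (twice the junction-to-boundary distance)
#' tracks the local band thickness, while the measured end thickness tracks
#' the drawn end width; the per-ridge truth records these analytic
#' expectations (`expected_*` columns).
#'
#' @param band_thickness epidermis band thickness (px).
#' @param n_ridges number of rete ridges.
#' @param ridge_length ridge protrusion length below the band (px).
#' @param ridge_base_width,ridge_end_width trapezoid widths (px).
#' @param ridge_spacing center-to-center spacing; default `3.5 *
#'   ridge_base_width` (well-separated).
#' @param undulation_amplitude,undulation_period surface sinusoid (px).
#' @param nucleus_spacing,nucleus_radius nuclear dot packing (px).
#' @param od stain load (hematoxylin/eosin concentration) of each tissue
#'   class.
#' @param stains 2x3 unit OD stain matrix (rows: hematoxylin, eosin).
#' @param noise_sd Gaussian intensity noise, default 0.008.
#' @param width optional image width; computed from the ridge layout when
#'   `NULL`.
#' @param seed RNG seed.
#' @return `skin_phantom_spec` list.
#' @export
skin_phantom_spec <- function(band_thickness = 40, n_ridges = 6,
                              ridge_length = 80, ridge_base_width = 24,
                              ridge_end_width = 20, ridge_spacing = NULL,
                              undulation_amplitude = 6,
                              undulation_period = 300,
                              nucleus_spacing = 5, nucleus_radius = 2.2,
                              od = list(epidermis_h = 0.6, epidermis_e = 0.5,
                                        nucleus_h = 1.8, nucleus_e = 0.1,
                                        dermis_h = 0.05, dermis_e = 1.0),
                              stains = he_reference_stains(),
                              noise_sd = 0.008, width = NULL, seed = 1) {
  if (is.null(ridge_spacing)) ridge_spacing <- 3.5 * ridge_base_width
  top_margin <- 20 + undulation_amplitude
  side_margin <- 20
  taper <- band_thickness
  span_needed <- if (n_ridges > 0) n_ridges * ridge_spacing else 0
  width_auto <- ceiling(2 * (side_margin + taper + ridge_base_width) +
                          max(span_needed, 600))
  if (is.null(width)) width <- width_auto
  height <- ceiling(top_margin + undulation_amplitude + band_thickness +
                      ridge_length + 50)
  spec <- list(band_thickness = band_thickness, n_ridges = n_ridges,
               ridge_length = ridge_length,
               ridge_base_width = ridge_base_width,
               ridge_end_width = ridge_end_width,
               ridge_spacing = ridge_spacing,
               undulation_amplitude = undulation_amplitude,
               undulation_period = undulation_period,
               nucleus_spacing = nucleus_spacing,
               nucleus_radius = nucleus_radius,
               od = od, stains = stains, noise_sd = noise_sd,
               width = width, height = height,
               top_margin = top_margin, side_margin = side_margin,
               taper = taper, seed = seed)
  viol <- character(0)
  geom <- c(band_thickness = band_thickness, ridge_length = ridge_length,
            ridge_base_width = ridge_base_width,
            ridge_end_width = ridge_end_width, nucleus_radius = nucleus_radius)
  viol <- c(viol, names(geom)[geom <= 0])
  if (ridge_end_width > ridge_base_width) {
    viol <- c(viol, "ridge_end_width > ridge_base_width")
  }
  if (n_ridges > 0 && ridge_spacing < ridge_base_width + 2) {
    viol <- c(viol, "ridge_spacing too small for ridge_base_width")
  }
  usable <- width - 2 * (side_margin + taper + ridge_base_width)
  if (n_ridges > 0 && span_needed > usable + ridge_spacing) {
    viol <- c(viol, "ridges do not fit within image width")
  }
  if (length(viol)) {
    stop("invalid phantom spec: ", paste(viol, collapse = "; "))
  }
  structure(spec, class = "skin_phantom_spec")
}

draw_disk <- function(mask, r0, c0, radius, value = TRUE) {
  rr <- max(1, floor(r0 - radius)):min(nrow(mask), ceiling(r0 + radius))
  cc <- max(1, floor(c0 - radius)):min(ncol(mask), ceiling(c0 + radius))
  sub <- outer(rr - r0, cc - c0, function(a, b) a^2 + b^2) <= radius^2
  mask[rr, cc][sub] <- value
  mask
}

#' Render the H&E skin phantom and its ground truth
#'
#' Builds the epidermis band with its ridge protrusions over a dermis block,
#' places nuclear dots inside the epidermis, composes the RGB image in
#' optical-density space (`I = exp(-OD . stain_mix)`) and adds Gaussian
#' intensity noise. The truth is consistent with the rendered image by
#' construction.
#'
#' @param spec a [skin_phantom_spec()].
#' @return list with `image` (H x W x 3 in `[0,1]`) and `truth`: epidermis /
#'   dermis / tissue masks, per-column midline row, per-ridge records (with
#'   `expected_length`, `expected_base_thickness`, `expected_end_thickness`),
#'   nucleus coordinates, the stain matrix and the spec.
#' @export
render_he_phantom <- function(spec) {
  stopifnot(inherits(spec, "skin_phantom_spec"))
  H <- spec$height; W <- spec$width; T <- spec$band_thickness
  cols <- seq_len(W)
  surface <- spec$top_margin +
    spec$undulation_amplitude * sin(2 * pi * cols / spec$undulation_period)
  x0 <- spec$side_margin + 1
  x1 <- W - spec$side_margin
  mid <- surface + T / 2
  half <- rep(T / 2, W)
  half[cols < x0 | cols > x1] <- 0
  tl <- cols >= x0 & cols < x0 + spec$taper
  half[tl] <- (T / 2) * (cols[tl] - x0 + 1) / spec$taper
  tr <- cols <= x1 & cols > x1 - spec$taper
  half[tr] <- pmin(half[tr], (T / 2) * (x1 - cols[tr] + 1) / spec$taper)
  rowm <- matrix(seq_len(H), H, W)
  midm <- matrix(mid, H, W, byrow = TRUE)
  halfm <- matrix(half, H, W, byrow = TRUE)
  band <- abs(rowm - midm) <= halfm & halfm > 0
  band_bottom <- mid + half
  # ridge protrusions
  epid <- band
  ridges <- NULL
  if (spec$n_ridges > 0) {
    inner0 <- x0 + spec$taper + spec$ridge_base_width
    inner1 <- x1 - spec$taper - spec$ridge_base_width
    centers <- inner0 + (inner1 - inner0) / 2 +
      (seq_len(spec$n_ridges) - (spec$n_ridges + 1) / 2) * spec$ridge_spacing
    L <- spec$ridge_length
    wb <- spec$ridge_base_width / 2
    we <- spec$ridge_end_width / 2
    recs <- lapply(seq_along(centers), function(i) {
      xc <- centers[i]
      b0 <- band_bottom[round(xc)]
      straight <- L - we
      for (d in 0:ceiling(straight)) {
        hw <- wb - (wb - we) * min(1, d / max(straight, 1))
        r <- round(b0 + d - 1)
        if (r >= 1 && r <= H) {
          c_lo <- max(1, ceiling(xc - hw)); c_hi <- min(W, floor(xc + hw))
          if (c_lo <= c_hi) epid[r, c_lo:c_hi] <<- TRUE
        }
      }
      epid <<- draw_disk(epid, b0 + straight - 1, xc, we)
      tibble::tibble(
        ridge_id = i, center_col = xc, base_row = b0,
        tip_row = b0 + L - 1,
        length = L, base_width = spec$ridge_base_width,
        end_width = spec$ridge_end_width,
        expected_length = L + T / 2,
        expected_base_thickness = T,
        expected_end_thickness = spec$ridge_end_width,
        expected_dilation = spec$ridge_end_width / T
      )
    })
    ridges <- dplyr::bind_rows(recs)
  } else {
    ridges <- tibble::tibble(ridge_id = integer(), center_col = numeric(),
                             base_row = numeric(), tip_row = numeric(),
                             length = numeric(), base_width = numeric(),
                             end_width = numeric(), expected_length = numeric(),
                             expected_base_thickness = numeric(),
                             expected_end_thickness = numeric(),
                             expected_dilation = numeric())
  }
  # dermis fills from the tissue top (band bottom where the band exists,
  # otherwise the surface) down to the image bottom
  dermis_top <- ifelse(half > 0, band_bottom, mid)
  dermis <- rowm > matrix(dermis_top, H, W, byrow = TRUE)
  dermis <- dermis & !epid
  tissue <- epid | dermis
  # nuclei on a jittered grid inside the epidermis
  nuclei <- withr::with_seed(spec$seed, {
    gr <- expand.grid(
      r = seq(2, H - 1, by = spec$nucleus_spacing),
      c = seq(2, W - 1, by = spec$nucleus_spacing))
    gr$r <- gr$r + stats::runif(nrow(gr), -1.5, 1.5)
    gr$c <- gr$c + stats::runif(nrow(gr), -1.5, 1.5)
    rr <- pmin(pmax(round(gr$r), 1), H)
    cc <- pmin(pmax(round(gr$c), 1), W)
    gr[epid[cbind(rr, cc)], ]
  })
  nucmask <- matrix(FALSE, H, W)
  for (i in seq_len(nrow(nuclei))) {
    nucmask <- draw_disk(nucmask, nuclei$r[i], nuclei$c[i],
                         spec$nucleus_radius)
  }
  nucmask <- nucmask & epid
  od <- spec$od
  ch <- matrix(0, H, W); ce <- matrix(0, H, W)
  ch[dermis] <- od$dermis_h; ce[dermis] <- od$dermis_e
  ch[epid] <- od$epidermis_h; ce[epid] <- od$epidermis_e
  ch[nucmask] <- od$nucleus_h; ce[nucmask] <- od$nucleus_e
  ch <- gaussian_blur(ch, 0.7); ce <- gaussian_blur(ce, 0.7)
  S <- spec$stains
  img <- array(0, c(H, W, 3))
  for (k in 1:3) img[, , k] <- exp(-(ch * S[1, k] + ce * S[2, k]))
  img <- img + withr::with_seed(spec$seed + 1L,
                                array(stats::rnorm(H * W * 3, 0, spec$noise_sd),
                                      c(H, W, 3)))
  img <- clip01(img)
  list(image = img,
       truth = list(epidermis_mask = epid, dermis_mask = dermis,
                    tissue_mask = tissue, midline_row = mid,
                    ridges = ridges, nuclei = nuclei,
                    stains = S, spec = spec))
}

#' Render a synthetic immunofluorescence phantom
#'
#' Single-channel phantoms with known ground truth: `itgb4` draws a bright
#' basal band of stated mean intensity; `ki67` places a stated number of
#' bright nuclei at recorded coordinates within an epidermal band; `cd31`
#' scatters non-overlapping filled ellipses of stated geometry and intensity.
#' Background noise is added everywhere.
#'
#' @param kind `"itgb4"`, `"ki67"` or `"cd31"`.
#' @param params named list of overrides (see Details in the source; all
#'   geometric/intensity parameters have stated defaults).
#' @param seed RNG seed.
#' @return list with `image`, `roi` (logical mask) and `truth`.
#' @export
render_if_phantom <- function(kind = c("itgb4", "ki67", "cd31"),
                              params = list(), seed = 1) {
  kind <- match.arg(kind)
  withr::with_seed(seed, switch(
    kind,
    itgb4 = {
      p <- utils::modifyList(list(height = 200, width = 600, band_rows = 60:110,
                                  mean = 120, sd = 5, background = 20,
                                  bg_noise = 3), params)
      img <- matrix(p$background + stats::rnorm(p$height * p$width, 0, p$bg_noise),
                    p$height, p$width)
      roi <- matrix(FALSE, p$height, p$width)
      roi[p$band_rows, ] <- TRUE
      img[roi] <- stats::rnorm(sum(roi), p$mean, p$sd)
      list(image = img, roi = roi,
           truth = list(mean = p$mean, sd = p$sd, n_px = sum(roi)))
    },
    ki67 = {
      p <- utils::modifyList(list(height = 200, width = 1000, band_rows = 60:110,
                                  n_cells = 12, n_in_ridge = 6,
                                  epidermal_length_px = 1000, ridge_count = 3,
                                  radius = 3, intensity = 200, background = 10,
                                  bg_noise = 3), params)
      img <- matrix(p$background + stats::rnorm(p$height * p$width, 0, p$bg_noise),
                    p$height, p$width)
      roi <- matrix(FALSE, p$height, p$width)
      roi[p$band_rows, ] <- TRUE
      cells <- tibble::tibble(
        r = stats::runif(p$n_cells, min(p$band_rows) + 5, max(p$band_rows) - 5),
        c = stats::runif(p$n_cells, 10, p$width - 10),
        in_ridge = seq_len(p$n_cells) <= p$n_in_ridge)
      for (i in seq_len(nrow(cells))) {
        img <- draw_disk(img, cells$r[i], cells$c[i], p$radius, p$intensity)
      }
      list(image = img, roi = roi,
           truth = list(cells = cells, n_cells = p$n_cells,
                        n_in_ridge = p$n_in_ridge,
                        epidermal_length_px = p$epidermal_length_px,
                        ridge_count = p$ridge_count))
    },
    cd31 = {
      p <- utils::modifyList(list(height = 400, width = 400, n_objects = 10,
                                  major = c(8, 16), minor = c(4, 9),
                                  intensity = 200, background = 10,
                                  bg_noise = 3, margin = 25), params)
      img <- matrix(p$background + stats::rnorm(p$height * p$width, 0, p$bg_noise),
                    p$height, p$width)
      roi <- matrix(TRUE, p$height, p$width)
      objs <- list(); tries <- 0
      min_sep <- 2 * (max(p$major) + 4)
      while (length(objs) < p$n_objects) {
        tries <- tries + 1
        if (tries > 5000) stop("render_if_phantom: cannot pack ", p$n_objects,
                               " non-overlapping objects (packing capacity)")
        a <- stats::runif(1, p$major[1], p$major[2])
        b <- stats::runif(1, p$minor[1], min(a, p$minor[2]))
        r0 <- stats::runif(1, p$margin, p$height - p$margin)
        c0 <- stats::runif(1, p$margin, p$width - p$margin)
        ok <- all(vapply(objs, function(o) {
          sqrt((o$r - r0)^2 + (o$c - c0)^2) >= min_sep
        }, logical(1)))
        if (ok) objs[[length(objs) + 1]] <-
            list(r = r0, c = c0, a = a, b = b,
                 theta = stats::runif(1, 0, pi))
      }
      truth <- dplyr::bind_rows(lapply(seq_along(objs), function(i) {
        o <- objs[[i]]
        tibble::tibble(object_id = i, r = o$r, c = o$c, major = 2 * o$a,
                       minor = 2 * o$b, theta = o$theta,
                       aspect_ratio = o$a / o$b)
      }))
      for (o in objs) {
        rr <- max(1, floor(o$r - o$a)):min(p$height, ceiling(o$r + o$a))
        cc <- max(1, floor(o$c - o$a)):min(p$width, ceiling(o$c + o$a))
        dr <- outer(rr - o$r, rep(1, length(cc)))
        dc <- outer(rep(1, length(rr)), cc - o$c)
        u <- (dr * cos(o$theta) + dc * sin(o$theta)) / o$a
        v <- (-dr * sin(o$theta) + dc * cos(o$theta)) / o$b
        sel <- u^2 + v^2 <= 1
        img[rr, cc][sel] <- p$intensity
      }
      list(image = img, roi = roi,
           truth = list(objects = truth, intensity = p$intensity))
    }))
}

#' Default feature generator for synthetic age-linear tables
#'
#' Sixteen slice-aggregated features: eight age-informative ("planted")
#' features whose slopes mirror the directions seen in aging skin (rete-ridge
#' end/base geometry, ridge length, ITGB4 intensity and Ki67 density
#' decreasing; dilation factor and CD31 solidity increasing), and eight
#' age-independent nuisance features. Planted slopes give per-feature age
#' correlations around `r = 0.72-0.74` at the default noise.
#'
#' @return tibble: feature, intercept, slope (units/year), noise_sd, planted.
#' @export
default_feature_spec <- function() {
  tibble::tribble(
    ~feature,                 ~intercept, ~slope,    ~noise_sd, ~planted,
    "end_thickness_p75",      70,         -0.45,     7,         TRUE,
    "end_thickness_sd",       18,         -0.12,     2,         TRUE,
    "end_thickness_range",    55,         -0.35,     6,         TRUE,
    "ridge_length_median",    150,        -0.9,      14,        TRUE,
    "base_thickness_median",  60,         -0.30,     5,         TRUE,
    "itgb4_mean",             160,        -1.0,      16,        TRUE,
    "ki67_per_length",        0.030,      -2.5e-4,   4e-3,      TRUE,
    "dilation_factor_median", 0.55,       3.0e-3,    0.05,      TRUE,
    "thickness_mean",         90,         0,         8,         FALSE,
    "thickness_iqr",          20,         0,         3,         FALSE,
    "ridge_density",          0.006,      0,         1e-3,      FALSE,
    "area_per_length",        35,         0,         5,         FALSE,
    "cd31_solidity_mean",     0.80,       8.0e-4,    0.04,      FALSE,
    "cd31_minor_axis_median", 12,         -0.02,     2,         FALSE,
    "cd31_perimeter_mean",    40,         0,         6,         FALSE,
    "cd31_eccentricity_mean", 0.70,       0,         0.05,      FALSE
  )
}

#' Simulate a per-sample feature table with linear age trends
#'
#' Ages are uniform over `age_range`; each feature is
#' `intercept + slope * age + N(0, noise_sd)`.
#'
#' @param n_samples number of samples (>= 10).
#' @param age_range numeric length 2, default 20-80 years.
#' @param feature_spec a [default_feature_spec()]-shaped tibble.
#' @param seed RNG seed.
#' @return tibble with `ID`, `Age` and one column per feature; the generating
#'   spec is attached as attribute `"truth"`.
#' @export
simulate_feature_table <- function(n_samples = 60, age_range = c(20, 80),
                                   feature_spec = default_feature_spec(),
                                   seed = 1) {
  stopifnot(n_samples >= 10)
  withr::with_seed(seed, {
    ages <- stats::runif(n_samples, age_range[1], age_range[2])
    out <- tibble::tibble(ID = sprintf("S%03d", seq_len(n_samples)),
                          Age = ages)
    for (i in seq_len(nrow(feature_spec))) {
      fs <- feature_spec[i, ]
      out[[fs$feature]] <- fs$intercept + fs$slope * ages +
        stats::rnorm(n_samples, 0, fs$noise_sd)
    }
    attr(out, "truth") <- feature_spec
    out
  })
}

#' Simulate xenograft feature tables with a planted rejuvenation shift
#'
#' Each donor contributes slices under three conditions: `Pre` features drawn
#' at the donor's age, `Young`/`Old` features drawn at the donor's age minus
#' the planted shift (grafting rejuvenates the tissue by `shift_*` years
#' regardless of host age, as observed experimentally).
#'
#' @param n_donors number of donors.
#' @param donor_age_range ages of the (elderly) donors; the default keeps the
#'   rejuvenated state inside the trained age support so the planted shift is
#'   identifiable by a bounded-range learner.
#' @param shift_young,shift_old planted rejuvenation (years), default 15.
#' @param n_slices replicate slices per (donor, condition).
#' @param feature_spec generator spec shared with
#'   [simulate_feature_table()].
#' @param seed RNG seed.
#' @return tibble with `Sample`, `Condition`, `ID` (Sample_Condition key),
#'   `true_effective_age` and the feature columns.
#' @export
simulate_xenograft_table <- function(n_donors = 5,
                                     donor_age_range = c(62, 75),
                                     shift_young = 15, shift_old = 15,
                                     n_slices = 3,
                                     feature_spec = default_feature_spec(),
                                     seed = 1) {
  withr::with_seed(seed, {
    donors <- sprintf("D%02d", seq_len(n_donors))
    ages <- stats::runif(n_donors, donor_age_range[1], donor_age_range[2])
    rows <- list()
    for (d in seq_len(n_donors)) {
      for (cond in c("Pre", "Young", "Old")) {
        eff <- ages[d] - switch(cond, Pre = 0, Young = shift_young,
                                Old = shift_old)
        for (s in seq_len(n_slices)) {
          row <- tibble::tibble(Sample = donors[d], Condition = cond,
                                ID = paste(donors[d], cond, sep = "_"),
                                true_effective_age = eff)
          for (i in seq_len(nrow(feature_spec))) {
            fs <- feature_spec[i, ]
            row[[fs$feature]] <- fs$intercept + fs$slope * eff +
              stats::rnorm(1, 0, fs$noise_sd)
          }
          rows[[length(rows) + 1]] <- row
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}
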