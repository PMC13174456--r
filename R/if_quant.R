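#' Annotated immunofluorescence region
#'
#' Bundles a single-channel intensity raster with its region-of-interest mask
#' and compartment label. The compartment gates which quantifications accept
#' the region: ITGB4 mean intensity requires `basal-epidermis`, CD31 vessel
#' segmentation requires `papillary-dermis`.
#'
#' @param image numeric matrix (raw intensities, any scale).
#' @param roi_mask logical matrix, same shape, non-empty.
#' @param compartment `"basal-epidermis"`, `"epidermis"` or
#'   `"papillary-dermis"`.
#' @param sample_id sample identifier.
#' @param region_index region number (1..5 for the CD31 protocol).
#' @return `annotated_region` object.
#' @export
annotated_region <- function(image, roi_mask,
                             compartment = c("basal-epidermis", "epidermis",
                                             "papillary-dermis"),
                             sample_id = NA_character_, region_index = 1L) {
  compartment <- match.arg(compartment)
  stopifnot(is.matrix(image), identical(dim(image), dim(roi_mask)))
  if (!any(roi_mask)) stop("annotated_region: empty ROI")
  structure(list(image = image, roi_mask = roi_mask > 0,
                 compartment = compartment, sample_id = sample_id,
                 region_index = as.integer(region_index)),
            class = "annotated_region")
}

#' Mean ITGB4 fluorescence intensity in the basal epidermis
#'
#' Arithmetic mean of the raw pixel intensities inside the ROI.
#'
#' @param region an [annotated_region()] with compartment `basal-epidermis`.
#' @return scalar mean intensity.
#' @export
itgb4_mean_intensity <- function(region) {
  stopifnot(inherits(region, "annotated_region"))
  if (region$compartment != "basal-epidermis") {
    stop("itgb4_mean_intensity expects a basal-epidermis region, got ",
         region$compartment)
  }
  mean(region$image[region$roi_mask])
}

#' Ki67 proliferation indices
#'
#' Normalizes the Ki67-positive cell count to the epidermal length
#' (cells/px), and the count of cells lying within rete ridges to the ridge
#' count (cells/ridge). The per-ridge index is undefined (NA) when the slice
#' has no ridges; the per-length index is still emitted.
#'
#' @param positive_cells either an integer count or a data frame/matrix of
#'   cell coordinates (one row per positive cell).
#' @param epidermal_length_px epidermal (midline) length in pixels, > 0.
#' @param in_ridge logical vector (one per cell) or an integer count of cells
#'   inside rete ridges; default 0.
#' @param ridge_count number of validated rete ridges, >= 0.
#' @return tibble with `cells_per_length`, `cells_per_ridge`, counts.
#' @export
ki67_indices <- function(positive_cells, epidermal_length_px,
                         in_ridge = 0L, ridge_count = 0L) {
  n <- if (is.numeric(positive_cells) && length(positive_cells) == 1L) {
    as.integer(positive_cells)
  } else {
    nrow(positive_cells)
  }
  n_ridge <- if (is.logical(in_ridge)) sum(in_ridge) else as.integer(in_ridge)
  if (n < 0 || n_ridge < 0 || ridge_count < 0) {
    stop("ki67_indices: counts must be non-negative")
  }
  stopifnot(epidermal_length_px > 0)
  tibble::tibble(
    n_cells = n, n_cells_in_ridges = n_ridge, ridge_count = ridge_count,
    cells_per_length = n / epidermal_length_px,
    cells_per_ridge = if (ridge_count > 0) n_ridge / ridge_count else NA_real_
  )
}

#' Segment CD31-positive microvessel objects
#'
#' Intensity-thresholds the CD31 channel inside the ROI (Otsu within the ROI
#' by default, or a user threshold), labels 8-connected components, and drops
#' objects below `min_object_px` (anti-speckle guard).
#'
#' @param region an [annotated_region()] with compartment `papillary-dermis`.
#' @param threshold numeric intensity cutoff, or `"otsu"`.
#' @param min_object_px minimum object area kept, default 5.
#' @return list with `labels` (integer matrix), `threshold` (resolved value),
#'   `n_objects`.
#' @export
segment_cd31 <- function(region, threshold = "otsu", min_object_px = 5) {
  stopifnot(inherits(region, "annotated_region"))
  if (region$compartment != "papillary-dermis") {
    stop("segment_cd31 expects a papillary-dermis region, got ",
         region$compartment)
  }
  vals <- region$image[region$roi_mask]
  thr <- if (identical(threshold, "otsu")) {
    t0 <- suppressWarnings(otsu_threshold(vals, range = range(vals)))
    if (is.na(t0)) Inf else t0
  } else {
    as.numeric(threshold)
  }
  binary <- (region$image >= thr) & region$roi_mask
  binary <- drop_small_components(binary, min_object_px)
  labels <- label_components(binary)
  list(labels = labels, threshold = thr, n_objects = max(labels))
}

# Convex-hull pixel area by rasterizing the hull of the pixel centres
# (half-plane containment test); >= the object pixel count for convex shapes,
# so solidity stays in (0, 1].
convex_area_px <- function(px) {
  if (nrow(px) <= 2L) return(nrow(px))
  if (length(unique(px[, 1])) == 1L || length(unique(px[, 2])) == 1L) {
    return(nrow(px)) # collinear pixel run
  }
  h <- grDevices::chull(px[, 2], px[, 1])
  hx <- px[h, 2]; hy <- px[h, 1] # counter/clockwise ring
  rr <- seq(min(px[, 1]), max(px[, 1]))
  cc <- seq(min(px[, 2]), max(px[, 2]))
  grid <- expand.grid(r = rr, c = cc)
  inside <- rep(TRUE, nrow(grid))
  n <- length(h)
  # orientation of the ring
  area2 <- sum(hx * hy[c(2:n, 1)] - hx[c(2:n, 1)] * hy)
  sgn <- if (area2 >= 0) 1 else -1
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    cr <- (hx[j] - hx[i]) * (grid$r - hy[i]) - (hy[j] - hy[i]) * (grid$c - hx[i])
    inside <- inside & (sgn * cr >= -1e-9)
  }
  sum(inside)
}

#' Per-object vessel morphometrics
#'
#' Geometry from the object pixel sets: area, perimeter, inertia-ellipse
#' major/minor axes and eccentricity (via [EBImage::computeFeatures.moment()]
#' and [EBImage::computeFeatures.shape()]), aspect ratio (major/minor), and
#' solidity as object area over rasterized convex-hull area. Intensity
#' features (sum, mean, median) come from the raw raster. Degenerate 1-2 px
#' objects get unit axes and solidity 1.
#'
#' @param objects a [segment_cd31()] result (or an integer label matrix).
#' @param image raw intensity matrix.
#' @return tibble, one row per object.
#' @export
vessel_features <- function(objects, image) {
  labels <- if (is.list(objects)) objects$labels else objects
  n <- max(labels)
  if (n == 0L) {
    return(tibble::tibble(
      object_id = integer(), area = numeric(), eccentricity = numeric(),
      solidity = numeric(), perimeter = numeric(), major_axis = numeric(),
      minor_axis = numeric(), aspect_ratio = numeric(),
      sum_intensity = numeric(), mean_intensity = numeric(),
      median_intensity = numeric()))
  }
  fm <- EBImage::computeFeatures.moment(labels)
  fs <- EBImage::computeFeatures.shape(labels)
  px_all <- which(labels > 0, arr.ind = TRUE)
  ids <- labels[labels > 0]
  vals <- image[labels > 0]
  rows <- lapply(seq_len(n), function(i) {
    px <- px_all[ids == i, , drop = FALSE]
    area <- nrow(px)
    v <- vals[ids == i]
    if (area <= 2L) {
      major <- minor <- 1; ecc <- 0; sol <- 1
      perim <- fs[i, "s.perimeter"]
    } else {
      major <- fm[i, "m.majoraxis"]
      ecc <- min(fm[i, "m.eccentricity"], 1 - 1e-12)
      minor <- major * sqrt(1 - ecc^2)
      if (minor < 1) { minor <- 1; major <- max(major, 1) }
      perim <- fs[i, "s.perimeter"]
      sol <- min(1, area / convex_area_px(px))
    }
    tibble::tibble(
      object_id = i, area = area, eccentricity = ecc, solidity = sol,
      perimeter = perim, major_axis = major, minor_axis = minor,
      aspect_ratio = major / minor,
      sum_intensity = sum(v), mean_intensity = mean(v),
      median_intensity = stats::median(v))
  })
  dplyr::bind_rows(rows)
}

#' Section-level CD31 summary across annotated regions
#'
#' For each region, computes the [agg_stats()] distribution summary of every
#' vessel property plus the CD31-positive area fraction of the ROI, then
#' averages the per-region statistics across the (typically five) regions of
#' a sample. Set `pool = TRUE` to instead pool all objects before computing
#' statistics.
#'
#' @param objects_by_region list of [vessel_features()] tibbles, one per
#'   region.
#' @param roi_areas numeric ROI pixel areas, one per region.
#' @param pool pool objects across regions instead of averaging per-region
#'   statistics (default `FALSE`).
#' @return one-row tibble of `property_stat` columns plus
#'   `cd31_area_fraction` and `n_regions`.
#' @export
summarize_cd31 <- function(objects_by_region, roi_areas, pool = FALSE) {
  stopifnot(length(objects_by_region) >= 1L,
            length(roi_areas) == length(objects_by_region))
  props <- c("area", "eccentricity", "solidity", "perimeter", "major_axis",
             "minor_axis", "aspect_ratio", "sum_intensity", "mean_intensity",
             "median_intensity")
  fracs <- vapply(seq_along(objects_by_region), function(i) {
    sum(objects_by_region[[i]]$area) / roi_areas[i]
  }, numeric(1))
  if (pool) {
    all_obj <- dplyr::bind_rows(objects_by_region)
    out <- dplyr::bind_cols(lapply(props, function(p) agg_stats(all_obj[[p]], p)))
  } else {
    per_region <- lapply(objects_by_region, function(obj) {
      dplyr::bind_cols(lapply(props, function(p) agg_stats(obj[[p]], p)))
    })
    stacked <- dplyr::bind_rows(per_region)
    out <- tibble::as_tibble(as.list(colMeans(stacked, na.rm = TRUE)))
  }
  dplyr::bind_cols(out,
                   tibble::tibble(cd31_area_fraction = mean(fracs),
                                  n_regions = length(roi_areas)))
}
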