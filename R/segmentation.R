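#' Color-filter configuration for epidermis segmentation
#'
#' Thresholds are expressed in 8-bit channel encodings: CIELAB with
#' `L in [0,255]` (`L* * 255/100`) and `A`/`B` offset by 128; HSV with hue on
#' `[0, hue_max]` (default 0-179) and `S`,`V` on `[0,255]`. A pixel matching
#' *any* rule is excluded from the keep-mask:
#' `L < L_low`; `L > L_high` (site-dependent); `L < 100 & A < 150`;
#' `H < H_max`; `S < S_min`; `R = G = B` (gray rule).
#'
#' @param site one of `"abdomen"` (`L_high = 140`), `"graft"` (160),
#'   `"buttock"` (200). Slices marked as xenografts use the graft threshold
#'   regardless of donor site.
#' @param smoothing_sigma Gaussian sigma applied per RGB channel before
#'   conversion, default 2.
#' @param L_low,L_high,LA_L,LA_A,H_max,S_min,hue_max threshold overrides.
#' @param gray_rule exclude exactly gray pixels (`R = G = B`), default `TRUE`.
#' @return list of resolved thresholds (class `color_filter_config`).
#' @export
color_filter_config <- function(site = c("buttock", "abdomen", "graft"),
                                smoothing_sigma = 2,
                                L_low = 50, L_high = NULL,
                                LA_L = 100, LA_A = 150,
                                H_max = 110, S_min = 40,
                                hue_max = 179, gray_rule = TRUE) {
  site <- match.arg(site)
  if (is.null(L_high)) {
    L_high <- c(abdomen = 140, graft = 160, buttock = 200)[[site]]
  }
  structure(list(site = site, smoothing_sigma = smoothing_sigma,
                 L_low = L_low, L_high = L_high, LA_L = LA_L, LA_A = LA_A,
                 H_max = H_max, S_min = S_min, hue_max = hue_max,
                 gray_rule = gray_rule),
            class = "color_filter_config")
}

#' Smooth an H&E crop and apply the color keep-filter
#'
#' Gaussian-smooths each RGB channel, converts to 8-bit LAB and HSV encodings,
#' and excludes every pixel matching any configured rule (background, gray
#' artifacts, out-of-gamut hues). The returned keep-mask marks pixels eligible
#' for stain fitting and nuclear-density masking.
#'
#' @param image RGB array (H x W x 3) in `[0,1]`.
#' @param cfg a [color_filter_config()].
#' @return logical keep-mask matrix.
#' @export
smooth_and_filter <- function(image, cfg = color_filter_config()) {
  stopifnot(inherits(cfg, "color_filter_config"),
            length(dim(image)) == 3L, dim(image)[3] == 3L)
  sm <- blur_rgb(image, cfg$smoothing_sigma)
  lab <- rgb_to_lab8(sm)
  hsv <- rgb_to_hsv8(sm, hue_max = cfg$hue_max)
  r8 <- as_uint8(sm[, , 1]); g8 <- as_uint8(sm[, , 2]); b8 <- as_uint8(sm[, , 3])
  excl <- (lab$L < cfg$L_low) |
    (lab$L > cfg$L_high) |
    (lab$L < cfg$LA_L & lab$A < cfg$LA_A) |
    (hsv$H < cfg$H_max) |
    (hsv$S < cfg$S_min)
  if (isTRUE(cfg$gray_rule)) excl <- excl | (r8 == g8 & g8 == b8)
  !excl
}

# Canonical H&E optical-density vectors (hematoxylin, eosin), unit norm.
he_reference_stains <- function() {
  m <- rbind(h = c(0.65, 0.70, 0.29), e = c(0.07, 0.99, 0.11))
  m / sqrt(rowSums(m^2))
}

rgb_to_od <- function(image, background = 1) {
  eps <- 1 / 256
  -log((image + eps) / (background + eps))
}

#' Fit a two-stain optical-density model (PCA/Macenko-style)
#'
#' Converts kept pixels to optical density, finds the dominant 2-D PCA plane
#' of the OD cloud, and takes the extreme projection-angle percentiles as the
#' two stain directions. Vectors are unit-norm, componentwise non-negative,
#' and ordered so the first is the hematoxylin-like vector (largest red-OD
#' component, i.e. the bluest stain).
#'
#' @param image RGB array in `[0,1]`.
#' @param keep logical keep-mask from [smooth_and_filter()].
#' @param background per-channel background intensity, default 1.
#' @param transparency_floor pixels with max OD below this are ignored when
#'   fitting (default 0.15).
#' @param angle_percentiles extreme-angle percentiles, default `c(0.01, 0.99)`.
#' @param min_pixels minimum usable pixels, default 1000.
#' @param fallback if `TRUE`, degenerate fits fall back to canonical published
#'   H&E vectors with a warning instead of erroring.
#' @return `stain_model`: list with `od_matrix` (2 x 3, rows = stains) and
#'   `background`.
#' @export
fit_stain_model <- function(image, keep, background = 1,
                            transparency_floor = 0.15,
                            angle_percentiles = c(0.01, 0.99),
                            min_pixels = 1000, fallback = FALSE) {
  od <- matrix(rgb_to_od(image, background), ncol = 3L)
  use <- as.vector(keep) & apply(od, 1L, max) > transparency_floor
  fall <- function(msg) {
    if (fallback) {
      warning("fit_stain_model: ", msg, "; falling back to reference H&E vectors")
      return(structure(list(od_matrix = he_reference_stains(),
                            background = background, fallback = TRUE),
                       class = "stain_model"))
    }
    stop("fit_stain_model: ", msg)
  }
  if (sum(use) < min_pixels) {
    return(fall(sprintf("too few usable pixels (%d < %d)", sum(use), min_pixels)))
  }
  od <- od[use, , drop = FALSE]
  pc <- stats::prcomp(od, center = TRUE, scale. = FALSE)
  if (pc$sdev[2] < 0.02 * pc$sdev[1] || pc$sdev[2] < 1e-8) {
    return(fall("degenerate (single-stain) OD cloud"))
  }
  basis <- pc$rotation[, 1:2, drop = FALSE]
  # orient plane axes positively so angles are well-behaved
  for (j in 1:2) if (sum(basis[, j]) < 0) basis[, j] <- -basis[, j]
  proj <- od %*% basis
  phi <- atan2(proj[, 2], proj[, 1])
  qs <- stats::quantile(phi, angle_percentiles, names = FALSE)
  vecs <- t(vapply(qs, function(a) {
    v <- basis[, 1] * cos(a) + basis[, 2] * sin(a)
    v <- pmax(v, 0)
    v / sqrt(sum(v^2))
  }, numeric(3)))
  # hematoxylin-like (bluest) first: largest red-channel OD
  if (vecs[1, 1] < vecs[2, 1]) vecs <- vecs[2:1, , drop = FALSE]
  rownames(vecs) <- c("h", "e")
  structure(list(od_matrix = vecs, background = background, fallback = FALSE),
            class = "stain_model")
}

#' @export
print.stain_model <- function(x, ...) {
  cat("<stain_model>\n")
  print(round(x$od_matrix, 3))
  invisible(x)
}

# Least-squares stain concentrations: OD = C %*% S  =>  C = OD S' (S S')^-1
stain_concentrations <- function(od, stains) {
  S <- stains$od_matrix
  od %*% t(S) %*% solve(S %*% t(S))
}

#' Nuclear-density mask from the hematoxylin channel
#'
#' Unmixes the optical-density image into stain concentrations, isolates the
#' hematoxylin (nuclear) channel, zeroes values below `od_floor`, Gaussian
#' filters the channel (density smoothing) and Otsu-thresholds it into a
#' binary nuclear-density mask. The result is always a subset of the
#' keep-mask.
#'
#' @param image RGB array in `[0,1]`.
#' @param keep logical keep-mask.
#' @param stains a [fit_stain_model()] result.
#' @param od_floor nuclear-channel floor, default 0.2.
#' @param sigma Gaussian sigma of the density filter, default 2.
#' @return logical matrix.
#' @export
nuclear_density_mask <- function(image, keep, stains, od_floor = 0.2,
                                 sigma = 2) {
  stopifnot(inherits(stains, "stain_model"))
  od <- matrix(rgb_to_od(image, stains$background), ncol = 3L)
  conc <- stain_concentrations(od, stains)
  nuc <- matrix(pmax(conc[, 1], 0), nrow(keep), ncol(keep))
  nuc[!keep] <- 0
  nuc[nuc < od_floor] <- 0
  if (all(nuc == 0)) {
    warning("nuclear_density_mask: no hematoxylin signal above floor")
    return(keep & FALSE)
  }
  dens <- gaussian_blur(nuc, sigma)
  th <- suppressWarnings(otsu_threshold(dens, range = c(0, max(dens))))
  if (is.na(th)) return(keep & FALSE)
  (dens > th) & keep
}

#' Morphological refinement into the epidermis mask
#'
#' Applies the refinement chain: binary opening (3x3), small-object removal,
#' opening with 4 iterations, a 10x10 uniform (box-mean) filter, and a strict
#' local-mean `> 0.5` threshold; surviving pixels are labelled (8-connectivity)
#' as epidermal components ("trees").
#'
#' @param nuclear logical matrix from [nuclear_density_mask()].
#' @param min_object_px small-object removal size, default 64.
#' @param open_iterations iterations of the second opening pass, default 4.
#' @param uniform_size box filter size, default 10.
#' @return `epidermis_mask`: list with `mask`, `labels`, `areas`, `provenance`.
#' @export
refine_epidermis <- function(nuclear, min_object_px = 64,
                             open_iterations = 4, uniform_size = 10) {
  m <- binary_open(nuclear, 1L)
  m <- drop_small_components(m, min_object_px)
  m <- binary_open(m, open_iterations)
  dens <- box_mean(m * 1, uniform_size)
  mask <- dens > 0.5
  labels <- label_components(mask)
  structure(list(mask = mask, labels = labels,
                 areas = component_areas(labels),
                 provenance = list(min_object_px = min_object_px,
                                   open_iterations = open_iterations,
                                   uniform_size = uniform_size)),
            class = "epidermis_mask")
}

#' Segment the epidermis of one slice crop
#'
#' Convenience chain: [smooth_and_filter()], [fit_stain_model()],
#' [nuclear_density_mask()], [refine_epidermis()].
#'
#' @param image RGB array in `[0,1]`.
#' @param cfg a [color_filter_config()].
#' @param stain_fallback passed to [fit_stain_model()] as `fallback`.
#' @param ... passed to [refine_epidermis()].
#' @return an `epidermis_mask` with the keep-mask and stain model attached.
#' @export
segment_epidermis <- function(image, cfg = color_filter_config(),
                              stain_fallback = TRUE, ...) {
  keep <- smooth_and_filter(image, cfg)
  stains <- fit_stain_model(image, keep, fallback = stain_fallback)
  nuc <- nuclear_density_mask(image, keep, stains)
  em <- refine_epidermis(nuc, ...)
  em$keep <- keep
  em$stains <- stains
  em$provenance$filter <- unclass(cfg)
  em
}
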