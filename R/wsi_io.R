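#' Load an RGB image as a (possibly one-level) pyramid
#'
#' Reads a pyramidal TIFF (e.g. an SVS-style multi-resolution series), a flat
#' TIFF, or a PNG. Flat images are treated as single-level pyramids so that the
#' downstream pipeline is agnostic to whether a slide scanner produced the
#' file. Levels are ordered by decreasing resolution and per-level downsample
#' factors are computed relative to level 0.
#'
#' @param path path to an RGB TIFF/SVS or PNG file.
#' @return A `pyramid_image`: list with `levels` (arrays H x W x 3 in `[0,1]`),
#'   `factors` (numeric, level-0-relative downsample factors) and `path`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".png")
#' png::writePNG(array(runif(64 * 64 * 3), c(64, 64, 3)), f)
#' pyr <- load_pyramid(f)
#' pyr$factors
load_pyramid <- function(path) {
  if (!file.exists(path)) stop("cannot read image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  levels <- if (ext %in% c("png")) {
    list(png::readPNG(path))
  } else {
    lv <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(lv)) list(lv) else lv
  }
  levels <- lapply(levels, function(x) {
    if (is.matrix(x)) {
      stop("format error: expected an RGB image with 3 channels, got 1 channel")
    }
    nch <- dim(x)[3]
    if (nch != 3L) {
      stop("format error: expected an RGB image with 3 channels, got ",
           nch, " channels")
    }
    x
  })
  ord <- order(vapply(levels, function(x) dim(x)[1], numeric(1)),
               decreasing = TRUE)
  levels <- levels[ord]
  d0 <- dim(levels[[1]])
  factors <- vapply(levels, function(x) {
    mean(c(d0[1] / dim(x)[1], d0[2] / dim(x)[2]))
  }, numeric(1))
  structure(list(levels = levels, factors = factors, path = path),
            class = "pyramid_image")
}

#' @export
print.pyramid_image <- function(x, ...) {
  dims <- vapply(x$levels, function(l) paste(dim(l)[1:2], collapse = "x"), "")
  cat("<pyramid_image> ", length(x$levels), " level(s): ",
      paste(sprintf("%s (%.3gx)", dims, x$factors), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Working-resolution raster at a target downsample factor
#'
#' Returns the raster whose effective downsample factor (relative to level 0)
#' equals `target_factor`. If a pyramid level with exactly that factor exists
#' it is returned verbatim; otherwise the closest larger level (largest factor
#' strictly below the target) is resampled down with bilinear interpolation.
#'
#' @param pyr a [load_pyramid()] result.
#' @param target_factor desired downsample factor (>= 1), default 16.
#' @return RGB array at the working resolution.
#' @export
working_image <- function(pyr, target_factor = 16) {
  stopifnot(inherits(pyr, "pyramid_image"), target_factor >= 1)
  hit <- which(abs(pyr$factors - target_factor) < 1e-6)
  if (length(hit) > 0) return(pyr$levels[[hit[1]]])
  cand <- which(pyr$factors < target_factor)
  src <- cand[which.max(pyr$factors[cand])]
  lvl <- pyr$levels[[src]]
  ratio <- target_factor / pyr$factors[src]
  nr <- max(1L, round(dim(lvl)[1] / ratio))
  nc <- max(1L, round(dim(lvl)[2] / ratio))
  out <- EBImage::resize(lvl, w = nr, h = nc)
  array(clip01(out), c(nr, nc, 3L))
}

#' Detect tissue on a working-resolution raster
#'
#' Converts the raster to HSV, Otsu-thresholds the hue channel and the
#' per-pixel channel minimum, combines the two masks by logical conjunction,
#' then dilates (3x3 box, 2 iterations), fills holes, and removes connected
#' components smaller than `min_component_px`. The hue polarity (which side of
#' the hue threshold is tissue) is chosen as the side that overlaps the
#' low-brightness, i.e. non-white, pixels more, and is recorded in the result.
#'
#' @param working RGB array in `[0,1]`.
#' @param min_component_px minimum component area kept, default 50000.
#' @return A `tissue_mask`: list with `mask` (logical matrix), `working_factor`
#'   (filled in by [run_pipeline()]; `NA` here) and `provenance`.
#' @export
detect_tissue <- function(working, min_component_px = 50000) {
  stopifnot(length(dim(working)) == 3L, dim(working)[3] == 3L)
  d <- dim(working)
  hsv <- grDevices::rgb2hsv(t(matrix(working, ncol = 3L)), maxColorValue = 1)
  hue <- matrix(hsv[1, ], d[1], d[2])
  minch <- pmin(working[, , 1], working[, , 2], working[, , 3])
  th_h <- suppressWarnings(otsu_threshold(hue, range = c(0, 1)))
  th_m <- suppressWarnings(otsu_threshold(minch, range = c(0, 1)))
  empty <- function(why) {
    warning("detect_tissue: ", why, "; returning empty mask")
    structure(list(mask = matrix(FALSE, d[1], d[2]), working_factor = NA_real_,
                   provenance = list(reason = why)),
              class = "tissue_mask")
  }
  if (is.na(th_h) || is.na(th_m)) return(empty("Otsu threshold undefined"))
  dark <- minch < th_m
  side_hi <- hue > th_h
  overlap <- function(side) if (!any(side)) -1 else mean(dark[side])
  hue_polarity <- if (overlap(side_hi) >= overlap(!side_hi)) "high" else "low"
  hue_mask <- if (hue_polarity == "high") side_hi else !side_hi
  mask <- hue_mask & dark
  m <- mask * 1
  for (i in 1:2) m <- EBImage::dilate(m, brush3())
  mask <- fill_holes(m > 0)
  mask <- drop_small_components(mask, min_component_px)
  structure(list(
    mask = mask, working_factor = NA_real_,
    provenance = list(hue_polarity = hue_polarity, hue_threshold = th_h,
                      min_threshold = th_m, min_component_px = min_component_px)
  ), class = "tissue_mask")
}

#' Extract per-slice high-resolution crops
#'
#' Labels the tissue mask with 8-connectivity and extracts one `slice_region`
#' per connected component: the component's half-open bounding box at working
#' resolution, the same box mapped (and clamped) to the finest high-fidelity
#' level (level 1, or level 0 for flat images), the RGB crop at that level and
#' the component mask resampled (order 0) to the crop size.
#'
#' @param pyr a [load_pyramid()] result.
#' @param tissue a [detect_tissue()] result (mask at working resolution).
#' @return list of `slice_region` objects ordered by label index.
#' @export
extract_slices <- function(pyr, tissue) {
  stopifnot(inherits(pyr, "pyramid_image"), inherits(tissue, "tissue_mask"))
  lab <- label_components(tissue$mask)
  n <- max(lab)
  if (n == 0L) return(list())
  lvl_idx <- min(2L, length(pyr$levels))
  lvl <- pyr$levels[[lvl_idx]]
  dw <- dim(tissue$mask); dl <- dim(lvl)[1:2]
  sc <- dl / dw
  lapply(seq_len(n), function(i) {
    px <- which(lab == i, arr.ind = TRUE)
    # half-open [r0, r1) x [c0, c1) in 0-based working coordinates
    r0 <- min(px[, 1]) - 1L; r1 <- max(px[, 1])
    c0 <- min(px[, 2]) - 1L; c1 <- max(px[, 2])
    R0 <- max(0L, floor(r0 * sc[1])); R1 <- min(dl[1], ceiling(r1 * sc[1]))
    C0 <- max(0L, floor(c0 * sc[2])); C1 <- min(dl[2], ceiling(c1 * sc[2]))
    crop <- lvl[(R0 + 1):R1, (C0 + 1):C1, , drop = FALSE]
    cmask <- (lab == i)[(r0 + 1):r1, (c0 + 1):c1, drop = FALSE]
    mk <- EBImage::resize(cmask * 1, w = R1 - R0, h = C1 - C0,
                          filter = "none") > 0.5
    structure(list(
      slice_id = i,
      bbox_downsampled = c(r0, c0, r1, c1),
      bbox_level1 = c(R0, C0, R1, C1),
      level_index = lvl_idx - 1L,
      image = crop,
      mask = mk,
      area_downsampled = nrow(px)
    ), class = "slice_region")
  })
}

#' @export
print.slice_region <- function(x, ...) {
  cat("<slice_region> id ", x$slice_id, ", crop ",
      paste(dim(x$image)[1:2], collapse = "x"),
      " at level ", x$level_index, "\n", sep = "")
  invisible(x)
}
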