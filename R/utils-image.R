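#' @useDynLib dermatomics, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import rlang
NULL

clip01 <- function(x) pmin(pmax(x, 0), 1)

as_uint8 <- function(x) round(clip01(x) * 255)

#' Otsu threshold with a constant-image guard
#'
#' Wraps [EBImage::otsu()]; a (near-)constant input has no Otsu threshold, in
#' which case `NA` is returned with a warning instead of an error so that
#' callers can degrade to an empty mask.
#'
#' @param x numeric matrix.
#' @param range numeric length-2, the value range used for binning.
#' @return scalar threshold, or `NA_real_` for constant input.
#' @keywords internal
otsu_threshold <- function(x, range = c(0, 1)) {
  v <- x[is.finite(x)]
  if (length(v) == 0L || diff(range(v)) < 1e-10) {
    warning("constant-valued input: Otsu threshold undefined, returning NA")
    return(NA_real_)
  }
  EBImage::otsu(matrix(v, nrow = 1L), range = range)
}

#' 8-connected component labelling
#'
#' @param mask logical or 0/1 matrix.
#' @return integer matrix of labels (0 = background), labelled in raster-scan
#'   order of first occurrence.
#' @keywords internal
label_components <- function(mask) {
  storage.mode(mask) <- "integer"
  .label8(mask)
}

component_areas <- function(labels) {
  n <- max(labels)
  if (n == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = n)
}

drop_small_components <- function(mask, min_px) {
  lab <- label_components(mask)
  areas <- component_areas(lab)
  if (length(areas) == 0L) return(mask & FALSE)
  keep <- which(areas >= min_px)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Box-mean (uniform) filter via summed-area tables
#'
#' Supports even window sizes (a `k = 10` window spans rows
#' `r - floor((k-1)/2) .. r + ceiling((k-1)/2)`); out-of-image pixels count as
#' zero, matching zero-padded uniform filtering.
#'
#' @keywords internal
box_mean <- function(m, k) {
  lo <- floor((k - 1) / 2)
  hi <- k - 1 - lo
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + k, nc + k)
  pad[(lo + 1):(lo + nr), (lo + 1):(lo + nc)] <- m
  sat <- apply(apply(pad, 2L, cumsum), 1L, cumsum) # sat[c, r] after second apply
  sat <- t(sat)
  sat <- rbind(0, cbind(0, sat))
  r1 <- (1:nr); r2 <- r1 + k
  c1 <- (1:nc); c2 <- c1 + k
  out <- sat[r2, c2, drop = FALSE] - sat[r1, c2, drop = FALSE] -
    sat[r2, c1, drop = FALSE] + sat[r1, c1, drop = FALSE]
  out / (k * k)
}

# Sum of the 8 neighbours of every pixel (zero padding outside the image).
neighbor_sum8 <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(0, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  out <- matrix(0, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    out <- out + pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
  }
  out
}

# Mask pixels 8-adjacent to background *within the image*; pixels on the image
# edge are only boundary if an in-image neighbour is background, so a mask
# flush to the frame does not acquire a spurious rim.
mask_boundary <- function(mask) {
  m <- mask * 1
  nr <- nrow(m); nc <- ncol(m)
  pad <- matrix(1, nr + 2, nc + 2) # outside counts as foreground
  pad[2:(nr + 1), 2:(nc + 1)] <- m
  minn <- matrix(1, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    minn <- pmin(minn, pad[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)])
  }
  mask & (minn == 0)
}

brush3 <- function() EBImage::makeBrush(3, shape = "box")

binary_open <- function(mask, iterations = 1L) {
  m <- mask * 1
  for (i in seq_len(iterations)) m <- EBImage::erode(m, brush3())
  for (i in seq_len(iterations)) m <- EBImage::dilate(m, brush3())
  m > 0
}

fill_holes <- function(mask) EBImage::fillHull(mask * 1) > 0

#' Distance-to-set map
#'
#' Exact Euclidean distance from every pixel to the nearest pixel of `set_mask`
#' (0 on the set itself), computed with [EBImage::distmap()].
#'
#' @keywords internal
dist_to_set <- function(set_mask) {
  if (!any(set_mask)) {
    return(matrix(Inf, nrow(set_mask), ncol(set_mask)))
  }
  EBImage::distmap(1 - (set_mask * 1))
}

# Convert an RGB array (H x W x 3, values in [0,1]) to 8-bit-encoded CIELAB
# channels: L in [0,255] (L* * 255/100), A/B offset by 128.
rgb_to_lab8 <- function(img) {
  d <- dim(img)
  px <- matrix(img, ncol = 3L)
  lab <- grDevices::convertColor(px, from = "sRGB", to = "Lab")
  list(
    L = matrix(lab[, 1] * 255 / 100, d[1], d[2]),
    A = matrix(lab[, 2] + 128, d[1], d[2]),
    B = matrix(lab[, 3] + 128, d[1], d[2])
  )
}

# HSV channels with 8-bit OpenCV-style encoding: H in [0, hue_max] (default
# 179), S and V in [0,255].
rgb_to_hsv8 <- function(img, hue_max = 179) {
  d <- dim(img)
  px <- t(matrix(img, ncol = 3L))
  hsv <- grDevices::rgb2hsv(px, maxColorValue = 1)
  list(
    H = matrix(hsv[1, ] * hue_max, d[1], d[2]),
    S = matrix(hsv[2, ] * 255, d[1], d[2]),
    V = matrix(hsv[3, ] * 255, d[1], d[2])
  )
}

gaussian_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  EBImage::gblur(m, sigma = sigma)
}

blur_rgb <- function(img, sigma) {
  if (sigma <= 0) return(img)
  out <- img
  for (ch in 1:3) out[, , ch] <- gaussian_blur(img[, , ch], sigma)
  out
}
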