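#' Distribution summary used for every per-slice aggregate
#'
#' Mean, standard deviation, median, IQR (p75 - p25), percentiles 5/25/75/95
#' and range (max - min), with linear interpolation between order statistics
#' (quantile type 7). `NA`s are returned for empty input.
#'
#' @param x numeric vector.
#' @param prefix column-name prefix.
#' @return one-row tibble with columns `<prefix>_<stat>`.
#' @export
agg_stats <- function(x, prefix) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) {
    v <- rep(NA_real_, 9)
  } else {
    q <- stats::quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95),
                         names = FALSE, type = 7)
    v <- c(mean(x), stats::sd(x), q[3], q[4] - q[2], q[1], q[2], q[4], q[5],
           max(x) - min(x))
  }
  names(v) <- paste0(prefix, "_",
                     c("mean", "sd", "median", "iqr", "p5", "p25", "p75",
                       "p95", "range"))
  tibble::as_tibble(as.list(v))
}

#' Epidermal thickness profile along the midline
#'
#' For every midline pixel, the Euclidean distance to the nearest epidermal
#' boundary pixel, doubled (the midline runs along the band centre, so twice
#' the half-width estimates the local thickness).
#'
#' @param midline coordinate matrix (row, col) of midline pixels.
#' @param epidermal_boundary a [boundary_index()] of the epidermal component.
#' @return numeric vector of thicknesses (px), one per midline pixel.
#' @export
thickness_profile <- function(midline, epidermal_boundary) {
  if (nrow(midline) == 0L) return(numeric(0))
  2 * boundary_distance(epidermal_boundary, midline[, 1], midline[, 2])
}

#' Rete-ridge metrics for the valid ridges of a component
#'
#' Ridge length is the branch length plus the base-to-midline distance plus
#' the tip-to-boundary distance. Base and end thickness are twice the
#' base/tip distance to the external epidermal boundary; the dilation factor
#' is end over base thickness.
#'
#' @param g a classified `epidermis_graph` (see [classify_and_validate()]).
#' @param epidermal_boundary a [boundary_index()] of the component
#'   (epidermis scope).
#' @return tibble with ridge_id, length, base_thickness, end_thickness,
#'   dilation_factor.
#' @export
ridge_metrics <- function(g, epidermal_boundary) {
  rv <- g$ridges[g$ridges$valid, , drop = FALSE]
  if (nrow(rv) == 0L) {
    return(tibble::tibble(ridge_id = integer(), length = numeric(),
                          base_thickness = numeric(), end_thickness = numeric(),
                          dilation_factor = numeric()))
  }
  mid <- g$midline$pixels
  mid_map <- dist_to_set(coords_to_mask(mid, dim(epidermal_boundary$distmap)))
  d_base_mid <- lookup_map(mid_map, rv$base_r, rv$base_c)
  d_base_b <- boundary_distance(epidermal_boundary, rv$base_r, rv$base_c)
  d_tip_b <- boundary_distance(epidermal_boundary, rv$tip_r, rv$tip_c)
  tibble::tibble(
    ridge_id = seq_len(nrow(rv)),
    length = rv$length + d_base_mid + d_tip_b,
    base_thickness = 2 * d_base_b,
    end_thickness = 2 * d_tip_b,
    dilation_factor = (2 * d_tip_b) / (2 * d_base_b)
  )
}

coords_to_mask <- function(px, dims) {
  m <- matrix(FALSE, dims[1], dims[2])
  if (nrow(px) > 0) m[cbind(px[, 1], px[, 2])] <- TRUE
  m
}

lookup_map <- function(map, r, c) {
  rr <- pmin(pmax(round(r), 1), nrow(map))
  cc <- pmin(pmax(round(c), 1), ncol(map))
  map[cbind(rr, cc)]
}

#' Per-slice morphometric feature record
#'
#' Pools the accepted components of a slice into one feature row: total
#' epidermal (midline) length, validated ridge count and density
#' (count / length), epidermis area per length, and the full
#' [agg_stats()] summary of the thickness profile and of each ridge metric.
#' Slices with no ridges carry missing ridge aggregates (not zeros) and a
#' density of 0; slices with no accepted component yield no record.
#'
#' @param graphs list of classified `epidermis_graph` objects (one per
#'   component of the slice).
#' @param epidermis an `epidermis_mask` for the slice (area source).
#' @param accession_id sample/accession identifier.
#' @param slice_id integer slice index.
#' @return one-row tibble, or `NULL` when no component was accepted.
#' @export
slice_features <- function(graphs, epidermis, accession_id, slice_id = 1L) {
  acc <- Filter(function(g) isTRUE(g$accepted), graphs)
  if (length(acc) == 0L) {
    message("slice ", accession_id, "/", slice_id,
            ": no accepted epidermal component, no record emitted")
    return(NULL)
  }
  thick <- numeric(0)
  ridges <- list()
  mid_len <- 0L
  area <- 0
  for (g in acc) {
    eb <- boundary_index(g$component_mask, scope = "epidermis")
    thick <- c(thick, thickness_profile(g$midline$pixels, eb))
    ridges[[length(ridges) + 1L]] <- ridge_metrics(g, eb)
    mid_len <- mid_len + g$midline$length_px
    area <- area + sum(g$component_mask)
  }
  rg <- dplyr::bind_rows(ridges)
  n_ridges <- nrow(rg)
  base <- tibble::tibble(
    ID = accession_id,
    slice_id = as.integer(slice_id),
    epidermal_length_px = as.numeric(mid_len),
    ridge_count = n_ridges,
    ridge_density = n_ridges / mid_len,
    area_per_length = area / mid_len
  )
  dplyr::bind_cols(
    base,
    agg_stats(thick, "thickness"),
    agg_stats(rg$length, "ridge_length"),
    agg_stats(rg$base_thickness, "base_thickness"),
    agg_stats(rg$end_thickness, "end_thickness"),
    agg_stats(rg$dilation_factor, "dilation_factor")
  )
}

#' Ordinary least-squares age trend of one feature
#'
#' Fits `feature ~ age` by OLS and tests the slope with a Wald test (the
#' regression t-test); the 95% confidence band for the mean response is
#' available through [augment_trend()] / `autoplot()`. Degenerate inputs are
#' flagged rather than erroring: a constant feature gives slope 0 and p = 1;
#' a saturated fit (zero residual degrees of freedom) gives an undefined p.
#'
#' @param records data frame of per-slice records with an age column.
#' @param feature_name feature column to model.
#' @param age_col age column, default `"age"`.
#' @return an `age_trend` object; see [tidy.age_trend()], [glance.age_trend()].
#' @export
fit_age_trend <- function(records, feature_name, age_col = "age") {
  stopifnot(feature_name %in% names(records), age_col %in% names(records))
  df <- tibble::tibble(age = records[[age_col]], y = records[[feature_name]])
  df <- df[stats::complete.cases(df), ]
  if (length(unique(df$age)) < 2L) {
    stop("fit_age_trend: need at least 2 distinct ages")
  }
  degenerate <- NA_character_
  if (stats::sd(df$y) < 1e-12) {
    degenerate <- "constant_feature"
    fit <- NULL
    est <- c(intercept = mean(df$y), slope = 0)
    p <- 1; r2 <- 0; se <- c(NA_real_, NA_real_)
  } else {
    fit <- stats::lm(y ~ age, data = df)
    sm <- summary(fit)
    est <- c(intercept = unname(stats::coef(fit)[1]),
             slope = unname(stats::coef(fit)[2]))
    se <- sm$coefficients[, "Std. Error"]
    r2 <- sm$r.squared
    if (fit$df.residual == 0L) {
      degenerate <- "zero_residual_df"
      p <- NA_real_
    } else {
      p <- sm$coefficients["age", "Pr(>|t|)"]
    }
  }
  structure(list(feature = feature_name, fit = fit, data = df,
                 intercept = est[["intercept"]], slope = est[["slope"]],
                 se = unname(se), r_squared = r2, p_value = p,
                 n = nrow(df), degenerate = degenerate),
            class = "age_trend")
}

#' @export
print.age_trend <- function(x, ...) {
  cat(sprintf("<age_trend> %s ~ age: slope %.4g (p = %.3g, R^2 = %.3f, n = %d)%s\n",
              x$feature, x$slope, x$p_value, x$r_squared, x$n,
              if (!is.na(x$degenerate)) paste0(" [", x$degenerate, "]") else ""))
  invisible(x)
}

#' @rdname fit_age_trend
#' @param x,object an `age_trend`.
#' @param ... ignored.
#' @method tidy age_trend
#' @export
tidy.age_trend <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", "age"),
    estimate = c(x$intercept, x$slope),
    std.error = x$se,
    p.value = c(NA_real_, x$p_value)
  )
}

#' @rdname fit_age_trend
#' @method glance age_trend
#' @export
glance.age_trend <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, p.value = x$p_value, nobs = x$n,
                 degenerate = x$degenerate)
}

#' Fitted trend with a 95% confidence band for the mean response
#' @param x an `age_trend`.
#' @param newages optional ages at which to evaluate the band.
#' @return tibble with age, .fitted, .lower, .upper.
#' @export
augment_trend <- function(x, newages = NULL) {
  stopifnot(inherits(x, "age_trend"))
  ages <- if (is.null(newages)) sort(unique(x$data$age)) else newages
  if (is.null(x$fit)) {
    return(tibble::tibble(age = ages, .fitted = x$intercept,
                          .lower = NA_real_, .upper = NA_real_))
  }
  pr <- stats::predict(x$fit, newdata = data.frame(age = ages),
                       interval = "confidence", level = 0.95)
  tibble::tibble(age = ages, .fitted = pr[, "fit"],
                 .lower = pr[, "lwr"], .upper = pr[, "upr"])
}
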