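#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_ribbon
#'   geom_col geom_raster labs coord_fixed scale_fill_identity theme_minimal
NULL

#' Age-trend scatter with fitted line and 95% confidence band
#'
#' @param object an `age_trend` from [fit_age_trend()].
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.age_trend <- function(object, ...) {
  band <- augment_trend(object)
  ggplot(object$data, aes(x = .data$age, y = .data$y)) +
    geom_ribbon(data = band,
                aes(x = .data$age, ymin = .data$.lower, ymax = .data$.upper),
                inherit.aes = FALSE, alpha = 0.2) +
    geom_line(data = band, aes(x = .data$age, y = .data$.fitted),
              inherit.aes = FALSE, color = "steelblue") +
    geom_point(alpha = 0.7) +
    labs(x = "age (years)", y = object$feature,
         title = sprintf("%s ~ age (slope %.3g, p = %.2g, R² = %.2f)",
                         object$feature, object$slope, object$p_value,
                         object$r_squared)) +
    theme_minimal()
}

#' Feature-importance bars of a trained skin-age model
#'
#' @param object a `skin_age_model`.
#' @param top_n number of features shown, default 15.
#' @param ... ignored.
#' @return a ggplot.
#' @export
autoplot.skin_age_model <- function(object, top_n = 15, ...) {
  imp <- utils::head(object$importance, top_n)
  imp$feature <- factor(imp$feature, levels = rev(imp$feature))
  ggplot(imp, aes(x = .data$importance, y = .data$feature)) +
    geom_col(fill = "steelblue") +
    labs(x = "mean decrease in impurity (normalized)", y = NULL,
         title = sprintf("%s model: CV MAE %.2f y, R² %.3f",
                         object$type, object$cv_mae, object$cv_r2)) +
    theme_minimal()
}

#' QC overlay of a classified epidermis graph
#'
#' Renders the component mask in gray with the midline in blue, valid rete
#' ridges in green and rejected ridges in red (pixel-level overlay).
#'
#' @param g a classified `epidermis_graph` with `component_mask`.
#' @return a ggplot.
#' @export
plot_graph_overlay <- function(g) {
  stopifnot(inherits(g, "epidermis_graph"), !is.null(g$component_mask))
  px <- which(g$component_mask, arr.ind = TRUE)
  df <- tibble::tibble(row = px[, 1], col = px[, 2], color = "grey80")
  mp <- g$midline$pixels
  if (nrow(mp)) {
    df <- dplyr::bind_rows(df, tibble::tibble(row = mp[, 1], col = mp[, 2],
                                              color = "steelblue"))
  }
  if (!is.null(g$ridges) && nrow(g$ridges) && !is.null(g$maps)) {
    for (i in seq_len(nrow(g$ridges))) {
      bp <- g$maps$branch_pixels[[g$ridges$branch_id[i]]]
      clr <- if (g$ridges$valid[i]) "forestgreen" else "firebrick"
      df <- dplyr::bind_rows(df, tibble::tibble(row = bp[, 1], col = bp[, 2],
                                                color = clr))
    }
  }
  ggplot(df, aes(x = .data$col, y = -.data$row, fill = .data$color)) +
    geom_raster() +
    scale_fill_identity() +
    coord_fixed() +
    labs(x = NULL, y = NULL) +
    theme_minimal()
}

#' @export
generics::tidy

#' @export
generics::glance
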