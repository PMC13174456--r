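#' Random-Forest age-model configuration
#'
#' Defaults mirror the modeling protocol: 500 trees, 5-fold shuffled
#' cross-validation with a fixed seed of 42, top-8 feature selection and a
#' degree-2, no-bias polynomial expansion for the reduced model.
#'
#' @param n_trees,cv_folds,shuffle,seed,top_k,poly_degree,include_bias see
#'   defaults.
#' @return `model_config` list.
#' @export
model_config <- function(n_trees = 500, cv_folds = 5, shuffle = TRUE,
                         seed = 42, top_k = 8, poly_degree = 2,
                         include_bias = FALSE) {
  stopifnot(n_trees > 0, cv_folds > 1, top_k >= 1, poly_degree == 2,
            !include_bias)
  structure(list(n_trees = n_trees, cv_folds = cv_folds, shuffle = shuffle,
                 seed = seed, top_k = top_k, poly_degree = poly_degree,
                 include_bias = include_bias),
            class = "model_config")
}

#' Deterministic k-fold assignment
#'
#' Fold membership depends only on `(n, k, seed)`: rows are permuted under the
#' seed (when `shuffle`) and split into `k` nearly equal contiguous chunks;
#' the folds partition `1:n` exactly.
#'
#' @param n number of rows.
#' @param k number of folds.
#' @param seed RNG seed.
#' @param shuffle permute before splitting, default `TRUE`.
#' @return list of `k` integer index vectors (test folds).
#' @export
kfold_indices <- function(n, k, seed = 42, shuffle = TRUE) {
  stopifnot(n >= k)
  idx <- if (shuffle) withr::with_seed(seed, sample.int(n)) else seq_len(n)
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  split(idx, rep(seq_len(k), sizes))
}

#' Assemble the modeling feature table
#'
#' Inner-joins the H&E morphometrics, ITGB4, and Ki67 tables on the common
#' accession `ID`, then attaches the target age from the metadata table.
#' Xenograft keys concatenate the donor sample number with the graft
#' condition (e.g. `"S3_Young"`) before this join. Duplicate keys error with
#' the offenders listed; keys absent from the metadata are dropped with a
#' warning.
#'
#' @param he_csv,itgb4_csv,ki67_csv data frames (or CSV paths) sharing
#'   `id_col`.
#' @param metadata_csv data frame (or CSV path) with `id_col` and `age_col`.
#' @param id_col key column, default `"ID"`.
#' @param age_col age column in the metadata, default `"Age"`.
#' @return tibble: one row per ID with all predictors and `Age`.
#' @export
assemble_features <- function(he_csv, itgb4_csv, ki67_csv, metadata_csv,
                              id_col = "ID", age_col = "Age") {
  read1 <- function(x) {
    if (is.character(x)) x <- utils::read.csv(x, check.names = FALSE)
    tibble::as_tibble(x)
  }
  tabs <- lapply(list(he_csv, itgb4_csv, ki67_csv), read1)
  meta <- read1(metadata_csv)
  for (i in seq_along(tabs)) {
    t <- tabs[[i]]
    if (!id_col %in% names(t)) stop("assemble_features: missing key column ", id_col)
    dup <- unique(t[[id_col]][duplicated(t[[id_col]])])
    if (length(dup)) {
      stop("assemble_features: duplicate keys in input ", i, ": ",
           paste(utils::head(dup, 10), collapse = ", "))
    }
  }
  joined <- Reduce(function(a, b) dplyr::inner_join(a, b, by = id_col), tabs)
  missing_meta <- setdiff(joined[[id_col]], meta[[id_col]])
  if (length(missing_meta)) {
    warning("assemble_features: dropping keys absent from metadata: ",
            paste(utils::head(missing_meta, 10), collapse = ", "))
  }
  out <- dplyr::inner_join(joined,
                           dplyr::select(meta, dplyr::all_of(c(id_col, age_col))),
                           by = id_col)
  dplyr::rename(out, Age = dplyr::all_of(age_col), ID = dplyr::all_of(id_col))
}

predictor_columns <- function(table, predictors = NULL) {
  if (!is.null(predictors)) return(predictors)
  cand <- setdiff(names(table), c("ID", "Age", "Sample", "Condition",
                                  "slice_id"))
  cand[vapply(table[cand], is.numeric, logical(1))]
}

rf_metrics <- function(obs, pred) {
  mae <- mean(abs(obs - pred))
  r2 <- 1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
  c(mae = mae, r2 = r2)
}

fit_forest_cv <- function(x, y, cfg) {
  folds <- kfold_indices(nrow(x), cfg$cv_folds, seed = cfg$seed,
                         shuffle = cfg$shuffle)
  # all features are candidates at every split (regression-forest default of
  # the reference implementation this protocol mirrors)
  cv <- purrr::map_dfr(seq_along(folds), function(f) {
    test <- folds[[f]]
    rf <- withr::with_seed(cfg$seed + f, randomForest::randomForest(
      x = x[-test, , drop = FALSE], y = y[-test], ntree = cfg$n_trees,
      mtry = ncol(x)))
    m <- rf_metrics(y[test], stats::predict(rf, x[test, , drop = FALSE]))
    tibble::tibble(fold = f, n_test = length(test), mae = m["mae"],
                   r2 = m["r2"])
  })
  forest <- withr::with_seed(cfg$seed, randomForest::randomForest(
    x = x, y = y, ntree = cfg$n_trees, mtry = ncol(x)))
  imp <- randomForest::importance(forest, type = 2)[, 1]
  imp <- imp / sum(imp)
  importance <- tibble::tibble(feature = names(imp), importance = unname(imp),
                               input_order = match(names(imp), colnames(x)))
  importance <- dplyr::arrange(importance, dplyr::desc(.data$importance),
                               .data$input_order)
  list(forest = forest, cv = cv, importance = importance)
}

#' Train the full-feature Random Forest age model
#'
#' Cross-validates MAE and R-squared over the configured folds (R-squared per
#' fold, averaged), then refits the forest on all rows and extracts the mean
#' decrease in impurity importance ranking (normalized to sum 1). Rows with
#' any missing predictor are excluded.
#'
#' @param table feature table from [assemble_features()] (or any tibble with
#'   an `Age` column).
#' @param cfg a [model_config()].
#' @param predictors optional explicit predictor list; defaults to every
#'   numeric column except `ID`/`Age` bookkeeping columns.
#' @return a `skin_age_model`.
#' @export
train_full <- function(table, cfg = model_config(), predictors = NULL) {
  preds <- predictor_columns(table, predictors)
  bad <- preds[!vapply(table[preds], is.numeric, logical(1))]
  if (length(bad)) stop("train_full: non-numeric predictors: ",
                        paste(bad, collapse = ", "))
  keep <- stats::complete.cases(table[c(preds, "Age")])
  tab <- table[keep, , drop = FALSE]
  if (nrow(tab) < cfg$cv_folds) stop("train_full: fewer complete rows than folds")
  x <- as.matrix(tab[preds])
  y <- tab$Age
  if (stats::sd(y) < 1e-12) warning("train_full: constant target (degenerate)")
  fit <- fit_forest_cv(x, y, cfg)
  structure(list(
    forest = fit$forest, predictors = preds, importance = fit$importance,
    cv = fit$cv, cv_mae = mean(fit$cv$mae), cv_r2 = mean(fit$cv$r2),
    config = cfg, type = "full", expansion = NULL, n = nrow(tab)
  ), class = "skin_age_model")
}

#' Degree-2 polynomial expansion without bias
#'
#' Expands `k` features into `k` linear + `k` squared + `k(k-1)/2` pairwise
#' product columns (`2k + k(k-1)/2` total; 44 for `k = 8`). Naming is
#' deterministic: squares are `"f^2"`, products `"fA*fB"` with A before B in
#' input column order. Forests are scale-invariant, so no centering or
#' scaling is applied.
#'
#' @param table data frame containing the features (other columns pass
#'   through).
#' @param features character vector of feature columns to expand.
#' @param degree polynomial degree (2 supported).
#' @param include_bias must be `FALSE` (no intercept column).
#' @return tibble: pass-through columns plus the expanded predictors.
#' @export
polynomial_expand <- function(table, features, degree = 2,
                              include_bias = FALSE) {
  stopifnot(degree == 2, !include_bias, all(features %in% names(table)))
  k <- length(features)
  out <- tibble::as_tibble(table[setdiff(names(table), features)])
  lin <- tibble::as_tibble(table[features])
  sq <- purrr::map_dfc(features, function(f) {
    tibble::tibble(!!paste0(f, "^2") := table[[f]]^2)
  })
  pairs <- if (k >= 2) {
    combs <- utils::combn(seq_len(k), 2)
    purrr::map_dfc(seq_len(ncol(combs)), function(j) {
      a <- features[combs[1, j]]; b <- features[combs[2, j]]
      tibble::tibble(!!paste0(a, "*", b) := table[[a]] * table[[b]])
    })
  } else NULL
  dplyr::bind_cols(out, lin, sq, pairs)
}

expansion_names <- function(features) {
  k <- length(features)
  sq <- paste0(features, "^2")
  pr <- if (k >= 2) {
    combs <- utils::combn(seq_len(k), 2)
    vapply(seq_len(ncol(combs)), function(j) {
      paste0(features[combs[1, j]], "*", features[combs[2, j]])
    }, character(1))
  } else character(0)
  c(features, sq, pr)
}

#' Train the reduced-polynomial Random Forest age model
#'
#' Ranks the full model's predictors by impurity importance (ties broken by
#' input column order), keeps the top `cfg$top_k` (all, with a warning, when
#' fewer exist), applies the degree-2 no-bias polynomial expansion, and
#' retrains/cross-validates with the same fold seed as the full model.
#'
#' @param table the same feature table used for [train_full()].
#' @param full_model the trained full model.
#' @param cfg a [model_config()].
#' @return a `skin_age_model` with `type = "reduced"` and the expansion
#'   schema recorded.
#' @export
train_reduced <- function(table, full_model, cfg = model_config()) {
  stopifnot(inherits(full_model, "skin_age_model"))
  imp <- full_model$importance
  k <- min(cfg$top_k, nrow(imp))
  if (k < cfg$top_k) {
    warning("train_reduced: only ", k, " predictors available; using all")
  }
  top <- imp$feature[seq_len(k)]
  keep <- stats::complete.cases(table[c(full_model$predictors, "Age")])
  tab <- table[keep, , drop = FALSE]
  ex <- polynomial_expand(tab[c("Age", top)], top, degree = cfg$poly_degree,
                          include_bias = cfg$include_bias)
  preds <- expansion_names(top)
  fit <- fit_forest_cv(as.matrix(ex[preds]), ex$Age, cfg)
  structure(list(
    forest = fit$forest, predictors = preds, importance = fit$importance,
    cv = fit$cv, cv_mae = mean(fit$cv$mae), cv_r2 = mean(fit$cv$r2),
    config = cfg, type = "reduced", top_features = top,
    expansion = list(features = top, degree = cfg$poly_degree),
    n = nrow(ex)
  ), class = "skin_age_model")
}

#' @export
print.skin_age_model <- function(x, ...) {
  cat(sprintf(
    "<skin_age_model> %s: %d predictors, n = %d, CV MAE %.2f y, CV R^2 %.3f\n",
    x$type, length(x$predictors), x$n, x$cv_mae, x$cv_r2))
  invisible(x)
}

#' Predict skin age for new feature rows
#'
#' For a reduced model the stored expansion schema is applied first (in the
#' training column order). Missing predictor columns raise an error naming
#' them.
#'
#' @param object a `skin_age_model`.
#' @param newdata data frame of predictor columns (pre-expansion features for
#'   a reduced model).
#' @param ... ignored.
#' @return numeric predicted ages.
#' @export
predict.skin_age_model <- function(object, newdata, ...) {
  if (!is.null(object$expansion)) {
    need <- object$expansion$features
    miss <- setdiff(need, names(newdata))
    if (length(miss)) stop("predict: missing feature columns: ",
                           paste(miss, collapse = ", "))
    newdata <- polynomial_expand(newdata[need], need)
  }
  miss <- setdiff(object$predictors, names(newdata))
  if (length(miss)) stop("predict: missing predictor columns: ",
                         paste(miss, collapse = ", "))
  as.numeric(stats::predict(object$forest,
                            as.matrix(newdata[object$predictors])))
}

#' @rdname train_full
#' @param x,object a `skin_age_model`.
#' @param ... ignored.
#' @method tidy skin_age_model
#' @export
tidy.skin_age_model <- function(x, ...) x$importance

#' @rdname train_full
#' @method glance skin_age_model
#' @export
glance.skin_age_model <- function(x, ...) {
  tibble::tibble(type = x$type, n = x$n, n_predictors = length(x$predictors),
                 cv_mae = x$cv_mae, cv_r2 = x$cv_r2,
                 n_trees = x$config$n_trees, cv_folds = x$config$cv_folds)
}

#' Predicted-age xenograft deltas
#'
#' Predicts an age for every graft slice, averages predictions within each
#' (Sample, Condition) pair, pivots to one row per donor with `Pre`, `Young`,
#' `Old` columns, and reports the within-donor deltas:
#' `delta_pre_young = Pre - Young` (predicted-age drop after grafting into a
#' young host), `delta_pre_old = Pre - Old`, and
#' `delta_young_old = Young - Old`. Donors missing a condition get missing
#' deltas.
#'
#' @param model a trained `skin_age_model`.
#' @param graft_table feature table with `Sample` and `Condition`
#'   (`"Pre"`/`"Young"`/`"Old"`) columns plus the model's features.
#' @return tibble: one row per donor with condition means and deltas.
#' @export
predict_and_delta <- function(model, graft_table) {
  stopifnot(all(c("Sample", "Condition") %in% names(graft_table)))
  pred <- predict(model, graft_table)
  means <- graft_table |>
    dplyr::mutate(.pred = pred) |>
    dplyr::group_by(.data$Sample, .data$Condition) |>
    dplyr::summarise(mean_pred = mean(.data$.pred), .groups = "drop")
  wide <- tidyr::pivot_wider(means, names_from = "Condition",
                             values_from = "mean_pred")
  for (cond in c("Pre", "Young", "Old")) {
    if (!cond %in% names(wide)) wide[[cond]] <- NA_real_
  }
  dplyr::mutate(
    wide,
    delta_pre_young = .data$Pre - .data$Young,
    delta_pre_old = .data$Pre - .data$Old,
    delta_young_old = .data$Young - .data$Old
  )
}
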