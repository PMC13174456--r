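#' Reproducible pipeline configuration
#'
#' Mirrors every module default in one place; the resolved configuration is
#' serialized verbatim next to the outputs of every run.
#'
#' @param site donor site for the color filter.
#' @param target_factor working-resolution downsample factor.
#' @param min_component_px tissue-component size cutoff at working
#'   resolution.
#' @param min_path_px midline rejection threshold (px).
#' @param boundary_scope ridge-validation boundary: `"tissue"` (directional
#'   filter against the outer surface; default) or `"epidermis"`.
#' @param px_per_mm optional pixels-per-mm for unit conversion in reports.
#' @param seed seed recorded in the manifest.
#' @param ... overrides forwarded to [color_filter_config()].
#' @return `pipeline_config` list.
#' @export
pipeline_config <- function(site = "buttock", target_factor = 16,
                            min_component_px = 50000, min_path_px = 500,
                            boundary_scope = c("tissue", "epidermis"),
                            px_per_mm = NULL, seed = 1, ...) {
  structure(list(site = site, target_factor = target_factor,
                 min_component_px = min_component_px,
                 min_path_px = min_path_px,
                 boundary_scope = match.arg(boundary_scope),
                 px_per_mm = px_per_mm, seed = seed,
                 filter = color_filter_config(site = site, ...)),
            class = "pipeline_config")
}

#' Run the slice -> segment -> graph -> features pipeline
#'
#' For each input image: build the pyramid, derive the working-resolution
#' raster, detect tissue, extract slices, segment the epidermis per slice,
#' analyze every epidermal component as a skeleton graph, and aggregate the
#' accepted components into per-slice feature records. Stage errors are
#' recorded per slice and the run continues; the manifest logs component
#' accept/reject decisions (rejections are auditable, not silent).
#'
#' @param inputs character vector of image paths, or a (named) list of RGB
#'   arrays.
#' @param config a [pipeline_config()].
#' @param out_dir optional output directory: writes `features.csv`,
#'   `manifest.csv` and `config.json`.
#' @return list with `features` (tibble, one row per accepted slice),
#'   `manifest` (tibble, one row per slice with status) and `config`.
#' @export
run_pipeline <- function(inputs, config = pipeline_config(), out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(inputs)) {
    nm <- ifelse(nzchar(names(inputs) %||% ""), names(inputs),
                 tools::file_path_sans_ext(basename(inputs)))
    inputs <- stats::setNames(as.list(inputs), nm)
  }
  if (is.null(names(inputs)) || any(!nzchar(names(inputs)))) {
    names(inputs) <- sprintf("img%02d", seq_along(inputs))
  }
  features <- list(); manifest <- list()
  for (nm in names(inputs)) {
    res <- tryCatch({
      src <- inputs[[nm]]
      pyr <- if (is.character(src)) load_pyramid(src) else {
        structure(list(levels = list(src), factors = 1, path = nm),
                  class = "pyramid_image")
      }
      wk <- working_image(pyr, config$target_factor)
      tis <- detect_tissue(wk, config$min_component_px)
      slices <- extract_slices(pyr, tis)
      list(slices = slices, error = NULL)
    }, error = function(e) list(slices = list(), error = conditionMessage(e)))
    if (!is.null(res$error)) {
      manifest[[length(manifest) + 1]] <- tibble::tibble(
        input = nm, slice_id = NA_integer_, status = "error",
        detail = res$error)
      next
    }
    if (length(res$slices) == 0L) {
      manifest[[length(manifest) + 1]] <- tibble::tibble(
        input = nm, slice_id = NA_integer_, status = "no_tissue",
        detail = "no tissue components detected")
      next
    }
    for (sl in res$slices) {
      out <- tryCatch({
        em <- segment_epidermis(sl$image, config$filter)
        tb <- boundary_index(
          if (config$boundary_scope == "tissue") sl$mask else em$mask,
          scope = "tissue")
        ncomp <- max(em$labels)
        graphs <- lapply(seq_len(ncomp), function(i) {
          analyze_component(em$labels == i, tb,
                            min_path_px = config$min_path_px)
        })
        graphs <- Filter(Negate(is.null), graphs)
        rec <- slice_features(graphs, em, accession_id = nm,
                              slice_id = sl$slice_id)
        n_acc <- sum(vapply(graphs, function(g) isTRUE(g$accepted), logical(1)))
        list(rec = rec, n_comp = length(graphs), n_acc = n_acc, error = NULL)
      }, error = function(e) list(rec = NULL, n_comp = NA, n_acc = NA,
                                  error = conditionMessage(e)))
      status <- if (!is.null(out$error)) "error"
        else if (is.null(out$rec)) "no_accepted_component" else "ok"
      manifest[[length(manifest) + 1]] <- tibble::tibble(
        input = nm, slice_id = sl$slice_id, status = status,
        detail = out$error %||%
          sprintf("%d/%d components accepted", out$n_acc, out$n_comp))
      if (!is.null(out$rec)) features[[length(features) + 1]] <- out$rec
    }
  }
  features <- dplyr::bind_rows(features)
  manifest <- dplyr::bind_rows(manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(features, file.path(out_dir, "features.csv"),
                     row.names = FALSE)
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    cfg <- config
    cfg$filter <- unclass(cfg$filter)
    jsonlite::write_json(unclass(cfg), file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(features = features, manifest = manifest, config = config)
}
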