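# Top-level pipelines tying the stages together: simulate, coloc, zymo,
# cohort. Each run echoes its configuration into the report so every
# number it writes is recomputable from inputs + config + seed.

#' Build a run configuration
#'
#' @param pipeline one of `"simulate"`, `"coloc"`, `"zymo"`, `"cohort"`.
#' @param ... pipeline options, see [run_pipeline()].
#' @param out_dir output directory (created if missing).
#' @param seed integer seed for any simulated input.
#' @return list of class `RunConfig`.
#' @export
run_config <- function(pipeline = c("coloc", "zymo", "cohort", "simulate"),
                       ..., out_dir = ".", seed = 1) {
  pipeline <- match.arg(pipeline)
  structure(list(pipeline = pipeline, out_dir = out_dir,
                 seed = as.integer(seed), options = list(...)),
            class = "RunConfig")
}

#' Run a configured pipeline
#'
#' * `simulate`: options `what` (`"coloc"` or `"scene"`) plus the matching
#'   spec arguments; writes the stack (and for scenes the cell labels and
#'   ground truth).
#' * `coloc`: options `input` (TIFF path) or `stack`, `channels` (length
#'   2), optional `mask_path`/`mask`, `ratio`, `threshold`; writes an
#'   ICQ/p-value report, the colocalized-pixel mask and ICA plot CSVs.
#' * `zymo`: options `input`/`stack`, `mode`, `digestion_channel`,
#'   `actin_channel`, `cortactin_channel`, `cells` (label TIFF path) or
#'   `cell_labels`; writes per-spot and per-cell CSVs and the index JSON.
#' * `cohort`: options `input` (cohort CSV) or `cohort`, `stratify`;
#'   writes the contingency CSV and association-test JSON.
#'
#' @param config a [run_config()].
#' @return list of class `Report`: `config`, `results`, `version`,
#'   `timestamp`. Also written as `report.json` in `out_dir` (the
#'   timestamp is the only field that differs between identical runs).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  o <- config$options
  results <- switch(config$pipeline,
    simulate = pipeline_simulate(o, config),
    coloc = pipeline_coloc(o, config),
    zymo = pipeline_zymo(o, config),
    cohort = pipeline_cohort(o, config))
  report <- structure(
    list(config = c(list(pipeline = config$pipeline, seed = config$seed),
                    serializable_options(o)),
         results = results,
         version = as.character(utils::packageVersion("invadoquant")),
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "Report")
  jsonlite::write_json(unclass(report),
                       file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  report
}

# drop non-scalar objects (in-memory stacks etc.) from the config echo
serializable_options <- function(o) {
  Filter(function(x) is.atomic(x) && length(x) <= 16, o)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

pipeline_simulate <- function(o, config) {
  what <- o$what %||% "coloc"
  if (what == "coloc") {
    spec <- coloc_spec(width = o$width %||% 256, height = o$height %||% 256,
                       n_planes = o$n_planes %||% 10, w = o$w %||% 0.5,
                       noise_sd = o$noise_sd %||% 200, seed = config$seed)
    out <- gen_coloc_stack(spec)
    write_stack(out$stack, file.path(config$out_dir, "coloc_stack.tif"))
    list(kind = "coloc", true_w = out$truth$true_w,
         files = "coloc_stack.tif")
  } else {
    spec <- scene_spec(n_cells = o$n_cells %||% 20,
                       spots_per_cell_mean = o$spots_per_cell_mean %||% 2,
                       mode = o$mode %||% "gain", snr = o$snr %||% 5,
                       seed = config$seed)
    sc <- gen_digestion_scene(spec)
    write_stack(sc$stack, file.path(config$out_dir, "scene.tif"))
    write_labels(sc$cell_labels, file.path(config$out_dir, "scene_cells.tif"))
    write_scene_truth(sc, spec, file.path(config$out_dir, "scene"))
    list(kind = "scene", true_index = sc$truth$index,
         n_true_spots = nrow(sc$truth$spots))
  }
}

pipeline_coloc <- function(o, config) {
  stack <- o$stack %||% read_stack(o$input)
  ch <- o$channels %||% c(1, 2)
  a <- get_channel(stack, ch[[1]], drop = FALSE)
  b <- get_channel(stack, ch[[2]], drop = FALSE)
  mask <- o$mask %||% (if (!is.null(o$mask_path)) {
    read_labels(o$mask_path) > 0
  } else NULL)
  if (!is.null(mask) && length(dim(mask)) == 2L && length(dim(a)) == 3L) {
    mask <- array(rep(mask, each = dim(a)[1]), dim(a))  # apply per plane
  }
  res <- compute_icq(compute_pdm(a, b, mask))
  cm <- coloc_mask(a, b, coloc_params(ratio = o$ratio %||% 97,
                                      threshold_a = o$threshold %||% 50,
                                      threshold_b = o$threshold %||% 50))
  ica <- ica_plot_data(a, b, mask)
  utils::write.csv(ica$channel_a,
                   file.path(config$out_dir, "ica_channel_a.csv"),
                   row.names = FALSE)
  utils::write.csv(ica$channel_b,
                   file.path(config$out_dir, "ica_channel_b.csv"),
                   row.names = FALSE)
  mask_img <- array(cm$mask * 65535, c(dim(a)[1], 1, dim(a)[2], dim(a)[3]))
  write_stack(ImageStack(mask_img, pixel_size_xy = stack$pixel_size_xy,
                         step_z = stack$step_z,
                         channel_names = "colocalized"),
              file.path(config$out_dir, "colocalized_mask.tif"), bits = 16L)
  list(icq = res$icq, p_value = res$p_value, n_pixels = res$n_pixels,
       n_positive_pdm = res$n_positive_pdm,
       n_colocalized = cm$n_colocalized)
}

pipeline_zymo <- function(o, config) {
  stack <- o$stack %||% read_stack(o$input)
  labels <- o$cell_labels %||% read_labels(o$cells)
  dig <- get_channel(stack, o$digestion_channel %||% "digestion")
  act <- get_channel(stack, o$actin_channel %||% "actin")
  cor <- get_channel(stack, o$cortactin_channel %||% "cortactin")
  ss <- detect_digestion(dig, mode = o$mode %||% "gain",
                         pixel_size = stack$pixel_size_xy,
                         params = o$params %||% zymo_params())
  ss <- assign_spots(ss, labels)
  ss <- classify_active(ss, act, cor)
  cells <- quantify_cells(ss, labels)
  idx <- invadopodia_index(cells)
  utils::write.csv(ss$spots, file.path(config$out_dir, "spots.csv"),
                   row.names = FALSE)
  utils::write.csv(cells, file.path(config$out_dir, "cells.csv"),
                   row.names = FALSE)
  jsonlite::write_json(unclass(idx), file.path(config$out_dir, "index.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(n_spots = nrow(ss$spots), index = idx$index,
       pct_positive = idx$pct_positive,
       mean_spots_per_positive_cell = idx$mean_spots_per_positive_cell,
       n_cells_analyzed = idx$n_cells_analyzed)
}

pipeline_cohort <- function(o, config) {
  cohort <- o$cohort %||% read_cohort(o$input)
  strat <- o$stratify %||% "grade"
  tab <- contingency(cohort, strat)
  utils::write.csv(tab, file.path(config$out_dir, "contingency.csv"),
                   row.names = FALSE)
  at <- association_tests(cohort$marker_fraction, cohort[[strat]])
  jsonlite::write_json(at, file.path(config$out_dir, "tests.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(stratifier = strat, n_patients = nrow(cohort),
       test = at$method, statistic = at$statistic, p_value = at$p_value,
       table = tab)
}
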