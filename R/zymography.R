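# Quantification of focal proteolysis in in situ zymography images.
#
# Both acquisition dialects reduce to bright-spot detection on a
# "digestion signal": in gain mode (dequenched substrate) the signal is the
# image minus a coarse Gaussian background estimate; in loss mode (labeled
# gelatin) the signal is the background plateau minus the image, clamped at
# zero, so holes become peaks. Spots are connected components above a
# robust threshold that survive a physical size filter bracketing
# invadopodial morphology (~1 um x 3-5 um).

#' Parameters for digestion-spot detection
#'
#' @param threshold_k spot threshold in robust noise units: pixels with
#'   smoothed signal above `median + k * MAD` are candidate spot pixels.
#' @param method `"mad"` (default) or `"otsu"` for Otsu's threshold on the
#'   smoothed signal.
#' @param min_diameter smallest acceptable spot, um: components smaller
#'   than the equivalent circle are discarded.
#' @param max_length longest acceptable major-axis extent, um.
#' @param smooth_sigma pre-threshold Gaussian smoothing, pixels.
#' @param bg_sigma gain-mode background blur scale, um.
#' @return parameter list of class `ZymoParams`.
#' @export
zymo_params <- function(threshold_k = 3, method = c("mad", "otsu"),
                        min_diameter = 0.5, max_length = 8,
                        smooth_sigma = 1, bg_sigma = 20) {
  method <- match.arg(method)
  if (threshold_k <= 0) stop("`threshold_k` must be > 0")
  if (min_diameter <= 0 || max_length <= 0) stop("size filters must be > 0")
  structure(list(threshold_k = threshold_k, method = method,
                 min_diameter = min_diameter, max_length = max_length,
                 smooth_sigma = smooth_sigma, bg_sigma = bg_sigma),
            class = "ZymoParams")
}

# Coarse gain-mode background: blur at bg_sigma um on an 8x down-sampled
# copy (the structures of interest are 1-5 um, two orders below the blur).
estimate_background <- function(img, pixel_size, bg_sigma_um) {
  f <- 8L
  small <- EBImage::resize(img, w = max(2L, nrow(img) %/% f),
                           h = max(2L, ncol(img) %/% f))
  sig <- max(1, bg_sigma_um / (pixel_size * f))
  # a blur scale beyond what the field of view supports degrades gracefully
  # to the coarsest kernel that still fits
  sig <- min(sig, (min(dim(small)) - 1) / 7)
  bg <- EBImage::gblur(small, sigma = sig)
  EBImage::resize(bg, w = nrow(img), h = ncol(img))
}

# Loss-mode background plateau: median of the brightest quartile.
background_plateau <- function(img) {
  stats::median(img[img >= stats::quantile(img, 0.75)])
}

#' Detect focal proteolysis spots
#'
#' @param image single-channel matrix (y, x) or an [ImageStack] whose
#'   digestion channel is taken via `channel`.
#' @param mode `"gain"` or `"loss"` (see the file-level notes).
#' @param pixel_size um/pixel; taken from the stack when `image` is an
#'   [ImageStack].
#' @param params a [zymo_params()].
#' @param channel digestion channel index/name for stack input.
#' @return An object of class `spot_set`: list with
#'   * `spots` — data.frame: `spot_id`, `y`, `x` (signal-weighted centroid,
#'     1-based pixels), `area_px`, `area_um2`, `pixel_density` (integrated
#'     digestion signal), `cell_id` (`NA` until [assign_spots()]),
#'     `active` (`NA` until [classify_active()]);
#'   * `labels` — integer matrix labelling each spot's pixels;
#'   * `signal` — the digestion-signal image the densities integrate;
#'   * `pixel_size`, `mode`, `params`.
#' @examples
#' sc <- gen_digestion_scene(scene_spec(n_cells = 4, seed = 1))
#' ss <- detect_digestion(sc$stack, mode = "gain")
#' nrow(ss$spots)
#' @export
detect_digestion <- function(image, mode = c("gain", "loss"),
                             pixel_size = NULL, params = zymo_params(),
                             channel = "digestion") {
  mode <- match.arg(mode)
  if (inherits(image, "ImageStack")) {
    pixel_size <- image$pixel_size_xy
    img <- get_channel(image, channel)
    if (length(dim(img)) == 3L) {
      stop("pass one z plane at a time (use get_channel and subset)")
    }
  } else {
    img <- image
  }
  if (is.null(pixel_size)) {
    stop("`pixel_size` is required for the physical size filter")
  }
  if (!is.matrix(img)) stop("`image` must be a 2-d matrix")

  signal <- if (mode == "gain") {
    img - estimate_background(img, pixel_size, params$bg_sigma)
  } else {
    pmax(background_plateau(img) - img, 0)
  }
  if (!is.matrix(signal)) signal <- matrix(signal, nrow(img), ncol(img))

  sm <- EBImage::gblur(signal, sigma = params$smooth_sigma)
  thr <- if (params$method == "otsu") {
    rng <- range(sm)
    if (diff(rng) <= 0) Inf
    else EBImage::otsu(EBImage::Image((sm - rng[1]) / diff(rng)),
                       range = c(0, 1)) * diff(rng) + rng[1]
  } else {
    stats::median(sm) + params$threshold_k * stats::mad(sm)
  }
  bw <- sm > thr
  labels <- EBImage::bwlabel(EBImage::Image(bw * 1))
  lab_m <- matrix(as.integer(EBImage::imageData(labels)), nrow(img))

  n_obj <- max(lab_m)
  spots <- NULL
  if (n_obj > 0) {
    min_area_px <- pi * (params$min_diameter / 2)^2 / pixel_size^2
    # EBImage moments give the major-axis extent for the length filter
    mom <- EBImage::computeFeatures.moment(labels)
    if (is.null(dim(mom))) {
      mom <- matrix(mom, nrow = 1, dimnames = list(NULL, names(mom)))
    }
    areas <- tabulate(lab_m, n_obj)
    maj_um <- mom[, "m.majoraxis"] * pixel_size
    keep <- which(areas >= min_area_px & maj_um <= params$max_length)
    # vectorized per-component sums: one pass over the labelled pixels
    pos <- which(lab_m > 0L)
    grp <- factor(lab_m[pos], levels = seq_len(n_obj))
    sig_pos <- pmax(signal, 0)
    w <- sig_pos[pos]
    yy <- (pos - 1L) %% nrow(img) + 1L
    xx <- (pos - 1L) %/% nrow(img) + 1L
    dens <- as.vector(rowsum(w, grp))
    wy <- as.vector(rowsum(yy * w, grp))
    wx <- as.vector(rowsum(xx * w, grp))
    uy <- as.vector(rowsum(as.numeric(yy), grp))
    ux <- as.vector(rowsum(as.numeric(xx), grp))
    cy <- ifelse(dens > 0, wy / dens, uy / areas)
    cx <- ifelse(dens > 0, wx / dens, ux / areas)
    if (length(keep)) {
      spots <- data.frame(
        spot_id = seq_along(keep), y = cy[keep], x = cx[keep],
        area_px = areas[keep], area_um2 = areas[keep] * pixel_size^2,
        pixel_density = dens[keep], cell_id = NA_integer_, active = NA)
    }
    relab <- integer(n_obj)
    relab[keep] <- seq_along(keep)
    lab_m <- matrix(ifelse(lab_m > 0, relab[pmax(lab_m, 1L)], 0L), nrow(img))
  }
  if (is.null(spots)) spots <- data.frame(
    spot_id = integer(), y = numeric(), x = numeric(), area_px = numeric(),
    area_um2 = numeric(), pixel_density = numeric(), cell_id = integer(),
    active = logical())
  structure(list(spots = spots, labels = lab_m, signal = signal,
                 pixel_size = pixel_size, mode = mode, params = params),
            class = "spot_set")
}

#' @export
print.spot_set <- function(x, ...) {
  cat(sprintf("spot_set: %d spot(s), %s mode, %.3g um/px\n",
              nrow(x$spots), x$mode, x$pixel_size))
  invisible(x)
}

#' Assign detected spots to cells
#'
#' A spot belongs to the cell whose mask contains its centroid; failing
#' that, to the nearest cell centroid within `max_distance`; otherwise it
#' stays unassigned (`NA`) but is retained.
#'
#' @param spot_set a `spot_set` from [detect_digestion()].
#' @param cell_labels integer label matrix in the same frame.
#' @param max_distance centroid fallback radius, um.
#' @return the `spot_set` with `spots$cell_id` filled in.
#' @export
assign_spots <- function(spot_set, cell_labels, max_distance = 10) {
  stopifnot(inherits(spot_set, "spot_set"))
  if (!identical(dim(cell_labels), dim(spot_set$signal))) {
    stop("`cell_labels` must match the image frame")
  }
  sp <- spot_set$spots
  if (nrow(sp) == 0) return(spot_set)
  cent <- cell_centroids(cell_labels)
  px <- spot_set$pixel_size
  for (i in seq_len(nrow(sp))) {
    ry <- min(max(round(sp$y[i]), 1L), nrow(cell_labels))
    rx <- min(max(round(sp$x[i]), 1L), ncol(cell_labels))
    lab <- cell_labels[ry, rx]
    if (lab > 0) { sp$cell_id[i] <- lab; next }
    if (nrow(cent) == 0) next
    d_um <- sqrt((cent$y - sp$y[i])^2 + (cent$x - sp$x[i])^2) * px
    j <- which.min(d_um)
    if (d_um[j] <= max_distance) sp$cell_id[i] <- cent$cell_id[j]
  }
  spot_set$spots <- sp
  spot_set
}

cell_centroids <- function(cell_labels) {
  ids <- sort(unique(cell_labels[cell_labels > 0]))
  if (length(ids) == 0) {
    return(data.frame(cell_id = integer(), y = numeric(), x = numeric()))
  }
  do.call(rbind, lapply(ids, function(id) {
    idx <- which(cell_labels == id)
    data.frame(cell_id = id,
               y = mean((idx - 1L) %% nrow(cell_labels) + 1L),
               x = mean((idx - 1L) %/% nrow(cell_labels) + 1L))
  }))
}

#' Flag spots as proteolytically active (actin/cortactin co-positive)
#'
#' A spot is active iff the mean intensity of BOTH marker channels over the
#' spot footprint reaches its threshold. Default thresholds are estimated
#' per channel as `median + k * MAD` of the whole marker image — the same
#' robust convention as spot detection.
#'
#' @param spot_set a `spot_set`.
#' @param actin,cortactin marker-channel matrices co-registered with the
#'   digestion image; passing `NULL` for either is a configuration error.
#' @param thresholds optional length-2 numeric, explicit marker thresholds.
#' @param k robust threshold multiplier when `thresholds` is `NULL`. The
#'   default 2 reflects that the decision is on a footprint MEAN: even a
#'   bright marker blob averages well below its peak over the footprint, so
#'   the bar sits lower than the per-pixel detection threshold.
#' @return the `spot_set` with `spots$active` filled in.
#' @export
classify_active <- function(spot_set, actin, cortactin, thresholds = NULL,
                            k = 2) {
  stopifnot(inherits(spot_set, "spot_set"))
  if (is.null(actin) || is.null(cortactin)) {
    stop("both marker channels are required to resolve active flags")
  }
  if (!identical(dim(actin), dim(spot_set$signal)) ||
      !identical(dim(cortactin), dim(spot_set$signal))) {
    stop("marker channels must match the image frame")
  }
  if (is.null(thresholds)) {
    thresholds <- c(
      stats::median(actin) + k * stats::mad(actin),
      stats::median(cortactin) + k * stats::mad(cortactin))
  }
  sp <- spot_set$spots
  if (nrow(sp)) {
    pos <- which(spot_set$labels > 0L)
    grp <- factor(spot_set$labels[pos], levels = sp$spot_id)
    n_px <- as.vector(table(grp))
    mean_a <- as.vector(rowsum(actin[pos], grp)) / n_px
    mean_c <- as.vector(rowsum(cortactin[pos], grp)) / n_px
    sp$active <- mean_a >= thresholds[1] & mean_c >= thresholds[2]
  }
  spot_set$spots <- sp
  spot_set
}

#' Per-cell digestion accounting
#'
#' Splits each cell's digestion signal into focal (sum of its spots'
#' pixel densities) and pericellular (signal under the dilated cell
#' footprint, excluding all spot pixels) components. A cell is
#' invadopodia-positive iff it has at least one ACTIVE spot.
#'
#' @param spot_set a `spot_set` with assignments (and active flags, unless
#'   `require_active = FALSE`).
#' @param cell_labels integer cell label matrix.
#' @param dilate_um pericellular margin around the cell mask, um.
#' @param require_active if `TRUE` (default) unresolved active flags are an
#'   error, since positivity is defined on active spots.
#' @return `data.frame`, one row per cell: `cell_id`, `n_spots`,
#'   `n_active_spots`, `focal_density`, `pericellular_density`,
#'   `is_positive`.
#' @export
quantify_cells <- function(spot_set, cell_labels, dilate_um = 2,
                           require_active = TRUE) {
  stopifnot(inherits(spot_set, "spot_set"))
  sp <- spot_set$spots
  if (require_active && nrow(sp) > 0 && anyNA(sp$active)) {
    stop("active flags unresolved: run classify_active() first")
  }
  ids <- sort(unique(cell_labels[cell_labels > 0]))
  r_px <- max(1L, round(dilate_um / spot_set$pixel_size))
  foot <- if (length(ids)) {
    dil <- EBImage::dilate(EBImage::Image(cell_labels),
                           EBImage::makeBrush(2L * r_px + 1L, "disc"))
    dil <- matrix(as.integer(EBImage::imageData(dil)), nrow(cell_labels))
    # dilation may only claim background: a cell's own mask keeps its label
    ifelse(cell_labels > 0L, cell_labels, dil)
  } else cell_labels
  spot_px <- spot_set$labels > 0
  sig <- pmax(spot_set$signal, 0)
  out <- lapply(ids, function(id) {
    mine <- sp[!is.na(sp$cell_id) & sp$cell_id == id, , drop = FALSE]
    n_act <- if (nrow(mine)) sum(mine$active %in% TRUE) else 0L
    peri <- sum(sig[foot == id & !spot_px])
    data.frame(cell_id = id, n_spots = nrow(mine),
               n_active_spots = n_act,
               focal_density = sum(mine$pixel_density),
               pericellular_density = peri,
               is_positive = n_act >= 1L)
  })
  if (length(out)) do.call(rbind, out) else data.frame(
    cell_id = integer(), n_spots = integer(), n_active_spots = integer(),
    focal_density = numeric(), pericellular_density = numeric(),
    is_positive = logical())
}

#' Invadopodia Index
#'
#' `index = pct_positive * mean_spots_per_positive_cell`, where
#' `pct_positive` is the percentage of analysed cells with at least one
#' active spot and the mean counts active spots over positive cells only
#' (set `average_over = "all"` to average over every analysed cell
#' instead; both conventions are reported in the result).
#'
#' @param cells per-cell table from [quantify_cells()].
#' @param average_over `"positive"` (default) or `"all"`.
#' @return An object of class `IndexResult`: list with `pct_positive`,
#'   `mean_spots_per_positive_cell`, `index`, `n_cells_analyzed`,
#'   `average_over` and `mean_spots_all_cells`.
#' @examples
#' cells <- data.frame(cell_id = 1:4, n_spots = c(2, 0, 3, 0),
#'                     n_active_spots = c(2, 0, 3, 0),
#'                     focal_density = 0, pericellular_density = 0,
#'                     is_positive = c(TRUE, FALSE, TRUE, FALSE))
#' invadopodia_index(cells)$index  # 50 * 2.5 = 125
#' @export
invadopodia_index <- function(cells, average_over = c("positive", "all")) {
  average_over <- match.arg(average_over)
  if (nrow(cells) == 0) stop("no cells to analyse")
  n <- nrow(cells)
  pos <- cells$is_positive
  pct <- 100 * sum(pos) / n
  mean_pos <- if (any(pos)) mean(cells$n_active_spots[pos]) else 0
  mean_all <- mean(cells$n_active_spots)
  m <- if (average_over == "positive") mean_pos else mean_all
  structure(list(pct_positive = pct, mean_spots_per_positive_cell = mean_pos,
                 mean_spots_all_cells = mean_all, index = pct * m,
                 n_cells_analyzed = n, average_over = average_over),
            class = "IndexResult")
}

#' @export
print.IndexResult <- function(x, ...) {
  cat(sprintf(
    "Invadopodia Index = %.2f  (%.1f%% positive cells x %.2f active spots/%s cell; n = %d)\n",
    x$index, x$pct_positive,
    if (x$average_over == "positive") x$mean_spots_per_positive_cell
    else x$mean_spots_all_cells,
    x$average_over, x$n_cells_analyzed))
  invisible(x)
}

#' Fallback cell segmentation (threshold + watershed)
#'
#' Convenience only — cell masks should normally come from a dedicated
#' segmentation or the scene generator. Thresholds a cell-body channel at
#' Otsu, fills holes, and splits touching cells by watershed on the
#' distance map.
#'
#' @param img cell-body channel matrix.
#' @param min_area_px discard objects smaller than this.
#' @return integer label matrix.
#' @export
segment_cells <- function(img, min_area_px = 100) {
  rng <- range(img)
  if (diff(rng) <= 0) return(matrix(0L, nrow(img), ncol(img)))
  norm <- (img - rng[1]) / diff(rng)
  bw <- norm > EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  bw <- EBImage::fillHull(EBImage::Image(bw * 1))
  dm <- EBImage::distmap(bw)
  ws <- EBImage::watershed(dm)
  lab <- matrix(as.integer(EBImage::imageData(ws)), nrow(img))
  counts <- table(lab[lab > 0])
  drop <- as.integer(names(counts)[counts < min_area_px])
  lab[lab %in% drop] <- 0L
  relab <- match(lab, sort(unique(lab[lab > 0])))
  matrix(ifelse(is.na(relab), 0L, relab), nrow(img))
}
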