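# Synthetic in situ zymography scenes with full ground truth.
#
# Cells are disks laid out on a jittered grid (one tile per cell, so cells
# never overlap and adding cells never perturbs earlier ones — every cell
# draws from its own PRNG stream derived from the scene seed). Proteolytic
# spots are anisotropic Gaussians truncated at 2 sigma whose footprint spans
# spot_diameter x spot_length, the elongated profile invadopodia show in
# sagittal sections; they are placed fully inside their cell with a minimum
# centre separation so detection failures reflect the detector, not merged
# truth. Two dialects:
#   gain — dequenched-substrate imaging: bright spots on a dark background;
#   loss — labeled-gelatin imaging: dark holes in a bright background.
# A scene carries three channels (digestion, actin, cortactin). Active
# spots are rendered at full amplitude in BOTH marker channels; inactive
# spots have at least one marker at 20% amplitude, below the 50% marker
# threshold that defines actin/cortactin co-positivity.

#' Specification for a synthetic digestion scene
#'
#' @param n_cells number of cells (0 gives a blank background).
#' @param spots_per_cell_mean Poisson mean of spots per cell.
#' @param spot_diameter spot minor-axis extent, um.
#' @param spot_length length-2 range of the major-axis extent, um.
#' @param mode `"gain"` (bright spots, dark background) or `"loss"`
#'   (dark holes, bright background).
#' @param pixel_size lateral calibration, um/pixel.
#' @param snr spot peak amplitude divided by the read-noise sd.
#' @param p_active probability a spot is actin/cortactin co-positive.
#' @param cell_radius cell disk radius, um.
#' @param noise_sd Gaussian read noise, intensity units.
#' @param seed integer seed.
#' @return validated list of class `SceneSpec`.
#' @export
scene_spec <- function(n_cells = 20, spots_per_cell_mean = 2,
                       spot_diameter = 1.0, spot_length = c(3, 5),
                       mode = c("gain", "loss"), pixel_size = 0.1,
                       snr = 5, p_active = 0.8, cell_radius = 10,
                       noise_sd = 400, seed = 1) {
  mode <- match.arg(mode)
  if (n_cells < 0) stop("`n_cells` must be >= 0")
  if (spots_per_cell_mean < 0) stop("`spots_per_cell_mean` must be >= 0")
  if (spot_diameter <= 0 || any(spot_length <= 0)) {
    stop("spot dimensions must be > 0")
  }
  if (length(spot_length) != 2L || spot_length[1] > spot_length[2]) {
    stop("`spot_length` must be an increasing length-2 range")
  }
  if (snr <= 0) stop("`snr` must be > 0")
  if (p_active < 0 || p_active > 1) stop("`p_active` must be in [0, 1]")
  if (pixel_size <= 0) stop("`pixel_size` must be > 0")
  if (spot_diameter < 2 * pixel_size) {
    stop("`pixel_size` too coarse: spot diameter must span >= 2 pixels")
  }
  if (cell_radius <= spot_length[2] / 2) {
    stop("spots would not fit inside a cell: need cell_radius > max length/2")
  }
  structure(list(n_cells = as.integer(n_cells),
                 spots_per_cell_mean = spots_per_cell_mean,
                 spot_diameter = spot_diameter, spot_length = spot_length,
                 mode = mode, pixel_size = pixel_size, snr = snr,
                 p_active = p_active, cell_radius = cell_radius,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "SceneSpec")
}

# background conventions (intensity units, 16-bit range)
.BG_GAIN <- 2000
.BG_LOSS <- 20000
.BG_MARKER <- 1000
.CELL_TILE_UM <- 26       # grid spacing per cell
.CENTER_JITTER_UM <- 2
.SPOT_SEP_MARGIN_UM <- 0.6
.INACTIVE_MARKER_FRAC <- 0.2

# Add a truncated anisotropic Gaussian to `img` in place (returns img).
# Returns list(img, area_px, integrated) for ground truth bookkeeping.
render_spot <- function(img, cy, cx, sig_maj, sig_min, theta, amplitude) {
  ny <- nrow(img); nx <- ncol(img)
  ext <- ceiling(2 * sig_maj) + 1L
  ys <- max(1L, floor(cy - ext)):min(ny, ceiling(cy + ext))
  xs <- max(1L, floor(cx - ext)):min(nx, ceiling(cx + ext))
  dy <- outer(ys - cy, rep(1, length(xs)))
  dx <- outer(rep(1, length(ys)), xs - cx)
  u <- cos(theta) * dx + sin(theta) * dy   # along major axis
  v <- -sin(theta) * dx + cos(theta) * dy
  r2 <- (u / sig_maj)^2 + (v / sig_min)^2  # elliptical radius^2 in sigma units
  g <- amplitude * exp(-r2 / 2)
  g[r2 > 4] <- 0                           # truncate at 2 sigma
  img[ys, xs] <- img[ys, xs] + g
  list(img = img, area_px = sum(g > 0), integrated = sum(g))
}

#' Generate a zymography scene with ground truth
#'
#' @param spec a [scene_spec()].
#' @return list with:
#'   * `stack` — [ImageStack], 1 plane, channels
#'     `digestion`, `actin`, `cortactin`;
#'   * `cell_labels` — integer label matrix of cell disks (0 = background);
#'   * `truth` — list with `spots` (data.frame: `spot_id`, `cell_id`, `y`,
#'     `x` in 1-based pixels, `length_um`, `diameter_um`, `theta`,
#'     `area_px`, `integrated`, `active`), `cells` (data.frame: `cell_id`,
#'     `y`, `x`, `radius_um`) and `index` (the implied Invadopodia Index,
#'     see [invadopodia_index()]).
#' @examples
#' sc <- gen_digestion_scene(scene_spec(n_cells = 4, seed = 2))
#' nrow(sc$truth$spots)
#' @export
gen_digestion_scene <- function(spec) {
  stopifnot(inherits(spec, "SceneSpec"))
  px <- spec$pixel_size
  tile <- round(.CELL_TILE_UM / px)
  n_cols <- max(1L, ceiling(sqrt(spec$n_cells)))
  n_rows <- max(1L, ceiling(spec$n_cells / n_cols))
  ny <- n_rows * tile; nx <- n_cols * tile

  digestion_sig <- matrix(0, ny, nx)   # noiseless proteolysis signal
  actin_sig <- matrix(0, ny, nx)
  cortactin_sig <- matrix(0, ny, nx)
  labels <- matrix(0L, ny, nx)
  amplitude <- spec$snr * spec$noise_sd

  cells <- list(); spots <- list(); sid <- 0L

  for (ci in seq_len(spec$n_cells)) {
    set.seed((spec$seed * 1009L + ci) %% .Machine$integer.max)
    row <- (ci - 1L) %/% n_cols; col <- (ci - 1L) %% n_cols
    jit <- .CENTER_JITTER_UM / px
    cy <- row * tile + tile / 2 + stats::runif(1, -jit, jit)
    cx <- col * tile + tile / 2 + stats::runif(1, -jit, jit)
    r_um <- spec$cell_radius * stats::runif(1, 0.85, 1)
    r_px <- r_um / px
    ys <- max(1L, floor(cy - r_px)):min(ny, ceiling(cy + r_px))
    xs <- max(1L, floor(cx - r_px)):min(nx, ceiling(cx + r_px))
    d2 <- outer((ys - cy)^2, rep(1, length(xs))) +
      outer(rep(1, length(ys)), (xs - cx)^2)
    sub <- labels[ys, xs]
    sub[d2 <= r_px^2] <- ci
    labels[ys, xs] <- sub
    cells[[ci]] <- data.frame(cell_id = ci, y = cy, x = cx, radius_um = r_um)

    n_spots <- stats::rpois(1, spec$spots_per_cell_mean)
    placed <- matrix(numeric(0), 0, 3)   # y, x, half-length (um)
    for (si in seq_len(n_spots)) {
      len <- stats::runif(1, spec$spot_length[1], spec$spot_length[2])
      theta <- stats::runif(1, 0, pi)
      # keep the whole 2-sigma footprint inside the cell disk
      r_place <- (r_um - len / 2) / px
      # spots must not overlap regardless of orientation: centres at least
      # the sum of half-lengths apart (plus a margin), so ground truth is
      # resolvable and benchmark misses indict the detector
      for (try in 1:400) {
        ang <- stats::runif(1, 0, 2 * pi)
        rad <- sqrt(stats::runif(1)) * max(r_place, 1)
        sy <- cy + rad * sin(ang); sx <- cx + rad * cos(ang)
        sep <- (placed[, 3] + len / 2 + .SPOT_SEP_MARGIN_UM) / px
        if (nrow(placed) == 0 ||
            all((placed[, 1] - sy)^2 + (placed[, 2] - sx)^2 >= sep^2) ||
            try == 400L) break
      }
      placed <- rbind(placed, c(sy, sx, len / 2))
      sig_maj <- len / 4 / px            # 2-sigma truncation spans `len`
      sig_min <- spec$spot_diameter / 4 / px
      rs <- render_spot(digestion_sig, sy, sx, sig_maj, sig_min, theta,
                        amplitude)
      digestion_sig <- rs$img
      active <- stats::runif(1) < spec$p_active
      if (active) {
        fa <- 1; fc <- 1
      } else {
        # at least one marker below the 50%-amplitude co-positivity bar
        miss <- sample(c("actin", "cortactin", "both"), 1)
        fa <- if (miss %in% c("actin", "both")) .INACTIVE_MARKER_FRAC else 1
        fc <- if (miss %in% c("cortactin", "both")) .INACTIVE_MARKER_FRAC else 1
      }
      actin_sig <- render_spot(actin_sig, sy, sx, sig_maj, sig_min, theta,
                               fa * amplitude)$img
      cortactin_sig <- render_spot(cortactin_sig, sy, sx, sig_maj, sig_min,
                                   theta, fc * amplitude)$img
      sid <- sid + 1L
      spots[[sid]] <- data.frame(
        spot_id = sid, cell_id = ci, y = sy, x = sx, length_um = len,
        diameter_um = spec$spot_diameter, theta = theta,
        area_px = rs$area_px, integrated = rs$integrated, active = active)
    }
  }

  spots_df <- if (sid > 0) do.call(rbind, spots) else data.frame(
    spot_id = integer(), cell_id = integer(), y = numeric(), x = numeric(),
    length_um = numeric(), diameter_um = numeric(), theta = numeric(),
    area_px = numeric(), integrated = numeric(), active = logical())
  cells_df <- if (spec$n_cells > 0) do.call(rbind, cells) else data.frame(
    cell_id = integer(), y = numeric(), x = numeric(), radius_um = numeric())

  set.seed((spec$seed * 1009L) %% .Machine$integer.max)  # noise stream
  noise <- function() matrix(stats::rnorm(ny * nx, sd = spec$noise_sd), ny, nx)
  digestion <- if (spec$mode == "gain") {
    .BG_GAIN + digestion_sig + noise()
  } else {
    .BG_LOSS - digestion_sig + noise()
  }
  actin <- .BG_MARKER + actin_sig + noise()
  cortactin <- .BG_MARKER + cortactin_sig + noise()

  arr <- array(0, c(1L, 3L, ny, nx))
  arr[1, 1, , ] <- pmax(digestion, 0)    # detector floor
  arr[1, 2, , ] <- pmax(actin, 0)
  arr[1, 3, , ] <- pmax(cortactin, 0)
  stack <- ImageStack(arr, pixel_size_xy = px,
                      channel_names = c("digestion", "actin", "cortactin"))
  truth_index <- true_scene_index(spots_df, spec$n_cells)
  list(stack = stack, cell_labels = labels,
       truth = list(spots = spots_df, cells = cells_df, index = truth_index,
                    mode = spec$mode, amplitude = amplitude))
}

# Invadopodia Index implied by ground truth: % of cells with >= 1 active
# spot times the mean number of active spots per positive cell.
true_scene_index <- function(spots_df, n_cells) {
  if (n_cells == 0) {
    return(list(pct_positive = NA_real_, mean_spots_per_positive_cell = 0,
                index = NA_real_, n_cells = 0L))
  }
  act <- spots_df[spots_df$active, , drop = FALSE]
  per_cell <- table(factor(act$cell_id, levels = seq_len(n_cells)))
  pos <- sum(per_cell > 0)
  pct <- 100 * pos / n_cells
  mean_spots <- if (pos > 0) mean(per_cell[per_cell > 0]) else 0
  list(pct_positive = pct, mean_spots_per_positive_cell = mean_spots,
       index = pct * mean_spots, n_cells = as.integer(n_cells))
}

#' Write a scene's ground truth to plain-text files
#'
#' Spots go to `<prefix>_spots.csv` (one row per spot), cells to
#' `<prefix>_cells.csv`, and the spec echo plus implied index to
#' `<prefix>_scene.json`.
#'
#' @param scene output of [gen_digestion_scene()].
#' @param spec the [scene_spec()] that produced it.
#' @param prefix output path prefix.
#' @return character vector of the files written, invisibly.
#' @export
write_scene_truth <- function(scene, spec, prefix) {
  fs <- paste0(prefix, c("_spots.csv", "_cells.csv", "_scene.json"))
  utils::write.csv(scene$truth$spots, fs[1], row.names = FALSE)
  utils::write.csv(scene$truth$cells, fs[2], row.names = FALSE)
  jsonlite::write_json(
    list(spec = unclass(spec), index = scene$truth$index),
    fs[3], auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(fs)
}
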