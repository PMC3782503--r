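# Synthetic two-channel stacks with tunable channel co-dependence.
#
# Both channels are mixtures of a shared smooth field S and private fields
# U_a, U_b plus Gaussian read noise:
#   A = w*S + (1-w)*U_a + eps_a,   B = w*S + (1-w)*U_b + eps_b.
# All fields are low-pass-filtered white noise (Gaussian blur, sigma = 3 px)
# renormalised to a common intensity scale, so the images carry realistic
# spatial correlation instead of per-pixel speckle. For unit-variance fields
# the channel correlation is rho = w^2 / (w^2 + (1-w)^2 + v) with
# v = (noise_sd/field_sd)^2, and the expected ICQ is asin(rho)/pi; w = 0.8
# with the defaults lands in the 0.35-0.40 regime typical of strongly
# co-dependent invadopodial markers.

#' Specification for a synthetic colocalization stack
#'
#' @param width,height plane size in pixels (>= 1).
#' @param n_planes number of z sections.
#' @param w dependence weight in `[0, 1]`: 0 = independent channels,
#'   1 = both channels share the same underlying field.
#' @param noise_sd per-pixel Gaussian read noise, intensity units.
#' @param seed integer seed; every field derives its own stream from it.
#' @return validated list of class `ColocSpec`.
#' @seealso [gen_coloc_stack()]
#' @export
coloc_spec <- function(width = 256, height = 256, n_planes = 10,
                       w = 0.5, noise_sd = 200, seed = 1) {
  if (width < 1 || height < 1 || n_planes < 1) stop("all dims must be >= 1")
  if (w < 0 || w > 1) stop("`w` must be in [0, 1]")
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  structure(list(width = as.integer(width), height = as.integer(height),
                 n_planes = as.integer(n_planes), w = w,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ColocSpec")
}

# intensity convention for generated fields
.FIELD_MEAN <- 10000
.FIELD_SD <- 1500
.FIELD_BLUR_SIGMA <- 3

# Smooth unit-scale random field: blurred white noise per z plane,
# renormalised to mean .FIELD_MEAN, sd .FIELD_SD over the whole volume.
# Own PRNG stream so sibling fields never share draws.
smooth_field <- function(height, width, n_planes, seed) {
  set.seed(seed)
  vol <- array(0, c(n_planes, height, width))
  for (z in seq_len(n_planes)) {
    wn <- matrix(stats::rnorm(height * width), height, width)
    vol[z, , ] <- EBImage::gblur(wn, sigma = .FIELD_BLUR_SIGMA)
  }
  .FIELD_MEAN + .FIELD_SD * (vol - mean(vol)) / stats::sd(vol)
}

#' Generate a two-channel stack with known channel co-dependence
#'
#' See the file-level model above. Intensities are continuous doubles, so
#' no pixel ever coincides exactly with a channel mean and the ICQ sign
#' rule is unambiguous. Identical specs (including the seed) reproduce the
#' stack bit for bit.
#'
#' @param spec a [coloc_spec()].
#' @return list with `stack` (an [ImageStack], channels `"a"`, `"b"`) and
#'   `truth` (list with `true_w` and the noise level).
#' @examples
#' out <- gen_coloc_stack(coloc_spec(64, 64, 2, w = 1, noise_sd = 0, seed = 3))
#' identical(out$stack$data[, 1, , ], out$stack$data[, 2, , ])  # TRUE
#' @export
gen_coloc_stack <- function(spec) {
  stopifnot(inherits(spec, "ColocSpec"))
  h <- spec$height; wd <- spec$width; nz <- spec$n_planes
  base <- spec$seed * 101L
  S  <- smooth_field(h, wd, nz, seed = base + 1L)
  Ua <- smooth_field(h, wd, nz, seed = base + 2L)
  Ub <- smooth_field(h, wd, nz, seed = base + 3L)
  a <- spec$w * S + (1 - spec$w) * Ua
  b <- spec$w * S + (1 - spec$w) * Ub
  if (spec$noise_sd > 0) {
    set.seed(base + 4L)
    a <- a + stats::rnorm(length(a), sd = spec$noise_sd)
    b <- b + stats::rnorm(length(b), sd = spec$noise_sd)
  }
  arr <- array(0, c(nz, 2L, h, wd))
  arr[, 1L, , ] <- a
  arr[, 2L, , ] <- b
  stack <- ImageStack(arr, pixel_size_xy = 0.1, step_z = 0.45,
                      channel_names = c("a", "b"))
  list(stack = stack,
       truth = list(true_w = spec$w, noise_sd = spec$noise_sd,
                    field_sd = .FIELD_SD))
}
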