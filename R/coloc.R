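#' Per-pixel product of the differences from the mean (PDM)
#'
#' For two co-registered channels A and B the PDM at pixel i is
#' \deqn{PDM_i = (A_i - \bar A)(B_i - \bar B),}
#' with the channel means taken over the analysis mask. PDM is positive
#' where the two intensities deviate from their means in the same
#' direction (co-varying staining) and negative where they deviate in
#' opposite directions; its mean over the mask is exactly the population
#' covariance of the two channels.
#'
#' @param a,b numeric arrays of identical shape (plane, stack, or any
#'   dimensionality) — intensities of the two channels.
#' @param mask optional logical array of the same shape selecting the
#'   analysis region (e.g. one cell). Default: all pixels.
#' @return An object of class `PDMField`: list with `values` (signed PDM,
#'   same order as `which(mask)`), `mask_index` (linear pixel indices),
#'   `mean_a`, `mean_b`, and `n` (pixel count).
#' @examples
#' compute_pdm(c(1, 2, 3), c(1, 2, 3))$values   # 1 0 1
#' compute_pdm(c(1, 2, 3), c(3, 2, 1))$values   # -1 0 -1
#' @seealso [compute_icq()], [ica_plot_data()]
#' @export
compute_pdm <- function(a, b, mask = NULL) {
  a <- as.numeric_keepdim(a); b <- as.numeric_keepdim(b)
  if (!identical(dim1(a), dim1(b))) stop("`a` and `b` must have the same shape")
  if (is.null(mask)) {
    idx <- seq_along(a)
  } else {
    if (!identical(dim1(mask), dim1(a))) stop("`mask` shape must match the channels")
    idx <- which(as.logical(mask))
  }
  n <- length(idx)
  if (n < 2L) stop("analysis mask must contain at least 2 pixels")
  av <- a[idx]; bv <- b[idx]
  ma <- mean(av); mb <- mean(bv)
  structure(
    list(values = (av - ma) * (bv - mb), mask_index = idx,
         mean_a = ma, mean_b = mb, n = n),
    class = "PDMField"
  )
}

as.numeric_keepdim <- function(x) {
  if (!is.numeric(x)) stop("channel data must be numeric")
  x
}
dim1 <- function(x) if (is.null(dim(x))) length(x) else dim(x)

#' Li's intensity correlation quotient (ICQ)
#'
#' The ICQ is the fraction of analysed pixels with a positive PDM, minus
#' 0.5. Random (independent) staining gives ICQ near 0; co-dependent
#' distributions give positive values up to the bound +0.5; mutually
#' exclusive staining gives negative values down to -0.5. Pixels with PDM
#' exactly 0 count as non-positive, so a continuous-valued image paired
#' with itself attains exactly +0.5.
#'
#' Significance is the exact two-sided sign test of the positive-PDM count
#' against Binomial(n, 1/2); see [icq_significance()].
#'
#' @param pdm a `PDMField` from [compute_pdm()].
#' @return An object of class `ICQResult`: list with `icq` (in
#'   `[-0.5, 0.5]`), `n_pixels`, `n_positive_pdm` and `p_value`.
#' @examples
#' x <- runif(1000)
#' compute_icq(compute_pdm(x, x))$icq       # 0.5
#' compute_icq(compute_pdm(x, 1 - x))$icq   # -0.5
#' @export
compute_icq <- function(pdm) {
  stopifnot(inherits(pdm, "PDMField"))
  n <- pdm$n
  if (n < 2L) stop("need at least 2 pixels")
  npos <- sum(pdm$values > 0)
  structure(
    list(icq = npos / n - 0.5, n_pixels = n, n_positive_pdm = npos,
         p_value = icq_significance(npos, n)),
    class = "ICQResult"
  )
}

#' @export
print.ICQResult <- function(x, ...) {
  cat(sprintf("ICQ = %.4f  (n = %d pixels, %d with PDM > 0), p = %.3g\n",
              x$icq, x$n_pixels, x$n_positive_pdm, x$p_value))
  invisible(x)
}

#' Sign-test significance for an ICQ
#'
#' Exact two-sided sign test: under the null of independent channels the
#' positive-PDM count is Binomial(n, 1/2); the p-value is the doubled
#' smaller tail, clamped at 1,
#' \eqn{p = \min(1,\; 2\min(P(X \le k), P(X \ge k)))}.
#' Computed from the binomial CDF directly, so it is exact at any n.
#'
#' @param n_positive number of pixels with positive PDM.
#' @param n total analysed pixels (>= 1).
#' @return two-sided p-value in `[0, 1]`.
#' @examples
#' icq_significance(100, 100)  # 2 * 0.5^100
#' icq_significance(50, 100)   # 1
#' @export
icq_significance <- function(n_positive, n) {
  if (length(n) != 1L || n < 1) stop("`n` must be a positive count")
  if (n_positive < 0 || n_positive > n) stop("`n_positive` must be in [0, n]")
  lo <- stats::pbinom(n_positive, n, 0.5)
  hi <- stats::pbinom(n_positive - 1, n, 0.5, lower.tail = FALSE)
  min(1, 2 * min(lo, hi))
}

#' ICQ of two channels in one call
#'
#' Convenience wrapper: [compute_pdm()] then [compute_icq()]. For an
#' [ImageStack], pass channel indices or names; the analysis region
#' defaults to the whole volume (pass `mask` for per-cell/ROI ICQ).
#'
#' @param x an [ImageStack], or a numeric array (channel A).
#' @param channels length-2 channel indices/names when `x` is a stack.
#' @param b channel B array when `x` is an array.
#' @param mask optional logical array, analysis region.
#' @return An `ICQResult`.
#' @export
icq <- function(x, channels = c(1, 2), b = NULL, mask = NULL) {
  if (inherits(x, "ImageStack")) {
    a <- get_channel(x, channels[[1L]], drop = FALSE)
    b <- get_channel(x, channels[[2L]], drop = FALSE)
  } else {
    a <- x
    if (is.null(b)) stop("supply `b` when `x` is a plain array")
  }
  compute_icq(compute_pdm(a, b, mask = mask))
}

#' Threshold/ratio colocalization mask
#'
#' Reimplementation of the classic two-channel colocalization rule used to
#' produce "colocalized points" images: a pixel is colocalized iff both
#' channels reach their intensity thresholds and the two intensities agree
#' to within a ratio, taken symmetrically as
#' `100 * min(a, b) / max(a, b) >= ratio` (the ratio test is skipped when
#' both intensities are 0). Defaults are ratio 97 and threshold 50 on both
#' channels, the settings used for invadopodia marker stacks.
#'
#' @param a,b numeric arrays of identical shape.
#' @param params a [coloc_params()] list, or `NULL` for the defaults.
#' @return list with `mask` (logical array, same shape as the input) and
#'   `n_colocalized` (pixel count).
#' @examples
#' coloc_mask(c(100, 100), c(100, 50))$mask  # TRUE FALSE
#' @export
coloc_mask <- function(a, b, params = coloc_params()) {
  if (!identical(dim1(a), dim1(b))) stop("`a` and `b` must have the same shape")
  p <- params
  hi <- pmax(a, b)
  lo <- pmin(a, b)
  ratio_ok <- hi == 0 | 100 * lo >= p$ratio * hi
  m <- a >= p$threshold_a & b >= p$threshold_b & ratio_ok
  if (!is.null(dim(a))) dim(m) <- dim(a)
  list(mask = m, n_colocalized = sum(m))
}

#' Parameters for the threshold/ratio colocalization rule
#'
#' @param ratio percent agreement required between the two intensities,
#'   in `[0, 100]`.
#' @param threshold_a,threshold_b minimum intensity per channel.
#' @return validated parameter list of class `ColocParams`.
#' @export
coloc_params <- function(ratio = 97, threshold_a = 50, threshold_b = 50) {
  if (ratio < 0 || ratio > 100) stop("`ratio` must be in [0, 100]")
  if (threshold_a < 0 || threshold_b < 0) stop("thresholds must be >= 0")
  structure(list(ratio = ratio, threshold_a = threshold_a,
                 threshold_b = threshold_b),
            class = "ColocParams")
}

#' Intensity correlation analysis (ICA) plot data
#'
#' For each channel, pairs each pixel's intensity (normalized to 1 by the
#' per-channel maximum over the mask) with the pixel's PDM. Co-dependent
#' channels give the characteristic positively skewed "hour-glass"
#' scatter; independent channels scatter symmetrically about PDM = 0.
#'
#' @inheritParams compute_pdm
#' @return list of two data frames `channel_a` and `channel_b`, each with
#'   columns `intensity` (in `[0, 1]`) and `pdm`.
#' @export
ica_plot_data <- function(a, b, mask = NULL) {
  pdm <- compute_pdm(a, b, mask)
  av <- a[pdm$mask_index]; bv <- b[pdm$mask_index]
  ma <- max(av); mb <- max(bv)
  if (ma <= 0 || mb <= 0) stop("a channel is all zero over the mask")
  list(
    channel_a = data.frame(intensity = av / ma, pdm = pdm$values),
    channel_b = data.frame(intensity = bv / mb, pdm = pdm$values)
  )
}

#' Scatter the ICA distributions of two channels
#'
#' Base-graphics rendering of [ica_plot_data()]: PDM on the x axis,
#' normalized intensity on the y axis, one panel per channel.
#'
#' @inheritParams compute_pdm
#' @param names length-2 channel labels for the panel titles.
#' @return the plot data, invisibly.
#' @export
plot_ica <- function(a, b, mask = NULL, names = c("channel A", "channel B")) {
  pd <- ica_plot_data(a, b, mask)
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (i in 1:2) {
    df <- pd[[i]]
    graphics::plot(df$pdm, df$intensity, pch = ".", col = "#00000040",
                   xlab = "PDM", ylab = "normalized intensity",
                   main = names[i])
    graphics::abline(v = 0, lty = 2)
  }
  invisible(pd)
}
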