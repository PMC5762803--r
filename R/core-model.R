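#' Working points (analyzer offsets) for an acquisition
#'
#' @param thetas ordered analyzer offsets in microradians (2 or 3 for the
#'   closed-form retrievals); must be pairwise distinct and finite.
#' @return object of class `working_points`.
#' @export
working_points <- function(thetas) {
  thetas <- as.numeric(thetas)
  if (!all(is.finite(thetas))) stop("working-point angles must be finite")
  if (anyDuplicated(thetas)) stop("working-point angles must be pairwise distinct")
  structure(list(thetas = thetas), class = "working_points")
}

#' Per-pixel intensity triple
#'
#' Intensities measured at the working points, normalized so that the
#' object-free background at offset theta equals the rocking-curve value
#' `R(theta)` (one shared normalization against the peak-position flat, not
#' per-angle flats — per-angle division would silently cancel the `R(theta_i)`
#' factors the inversion relies on).
#'
#' @param intensities positive intensities `I(theta_i)`.
#' @param thetas the matching analyzer offsets (microradians), or a
#'   [working_points()].
#' @return object of class `pixel_triple`.
#' @export
pixel_triple <- function(intensities, thetas) {
  if (inherits(thetas, "working_points")) thetas <- thetas$thetas
  wp <- working_points(thetas)
  intensities <- as.numeric(intensities)
  if (length(intensities) != length(wp$thetas))
    stop("intensities and thetas must have the same length")
  structure(list(intensities = intensities, thetas = wp$thetas),
            class = "pixel_triple")
}

#' Closed-form forward model of analyzer-based image formation
#'
#' The intensity behind the analyzer at offset `theta` is the convolution of
#' the Gaussian rocking curve with the Gaussian scattering density, scaled by
#' the apparent absorption:
#' \deqn{I(\theta) = I_R \sqrt{\sigma^2 / (\sigma_S^2 + \sigma^2)}
#'   \exp\!\left(-\frac{(\theta + \Delta\theta_R)^2}
#'   {2(\sigma_S^2 + \sigma^2)}\right)}
#' It reduces to \eqn{I_R R(\theta + \Delta\theta_R)} for `sigma_s = 0`; the
#' prefactor is the extinction loss (scattered photons rejected by the
#' analyzer).
#'
#' @param i_r apparent absorption (transmission).
#' @param dtheta_r refraction angle, microradians (signed).
#' @param sigma_s scattering width (standard deviation), microradians, `>= 0`.
#' @param theta analyzer offset, microradians.
#' @param rc a [rocking_curve()].
#' @return intensity (vectorized over any argument).
#' @export
forward_intensity <- function(i_r, dtheta_r, sigma_s, theta, rc) {
  stopifnot(inherits(rc, "rocking_curve"))
  if (any(sigma_s < 0)) stop("`sigma_s` must be >= 0")
  s2 <- sigma_s^2 + rc$sigma^2
  i_r * sqrt(rc$sigma^2 / s2) * exp(-(theta + dtheta_r)^2 / (2 * s2))
}

# Shared vectorized three-image solver. I1..I3 and th (length 3) per the
# log-ratio linear system; returns dtheta, sig2 and a validity mask.
# Degeneracy: |denominator| < eps * max(|terms|) -> invalid (masked).
.three_image_solve <- function(I1, I2, I3, th, sigma, eps = 1e-12) {
  ok <- is.finite(I1) & is.finite(I2) & is.finite(I3) &
    I1 > 0 & I2 > 0 & I3 > 0
  L1 <- ifelse(ok, log(I1 / I2), NA_real_)
  L3 <- ifelse(ok, log(I3 / I2), NA_real_)
  t1 <- L1 * (th[2] - th[3])
  t3 <- L3 * (th[2] - th[1])
  den <- 2 * (t1 - t3)
  degen <- !is.finite(den) | abs(den) < eps * pmax(abs(2 * t1), abs(2 * t3),
                                                   .Machine$double.xmin)
  ok <- ok & !degen
  dtheta <- (L3 * (th[2]^2 - th[1]^2) - L1 * (th[2]^2 - th[3]^2)) / den
  sig2 <- (th[2] - th[1]) * (th[2] - th[3]) * (th[1] - th[3]) / den - sigma^2
  dtheta[!ok] <- NA_real_
  sig2[!ok] <- NA_real_
  list(dtheta = dtheta, sig2 = sig2, ok = ok)
}

.as_triple <- function(triple) {
  stopifnot(inherits(triple, "pixel_triple"))
  if (length(triple$intensities) != 3L)
    stop("three-image retrieval needs exactly 3 intensities")
  triple
}

#' Three-image refraction retrieval
#'
#' Exact algebraic inverse of [forward_intensity()] for the refraction angle,
#' from the log-ratios of the three images. Degenerate denominators and
#' non-positive intensities yield `NA` (an invalid-pixel signal, not an
#' error, so image pipelines keep running).
#'
#' @param triple a [pixel_triple()] with 3 intensities.
#' @return refraction angle in microradians, or `NA` if invalid.
#' @export
retrieve_refraction <- function(triple) {
  triple <- .as_triple(triple)
  I <- triple$intensities
  # sigma does not enter the refraction formula; pass 0
  .three_image_solve(I[1], I[2], I[3], triple$thetas, 0)$dtheta
}

#' Three-image scattering-variance retrieval
#'
#' Exact algebraic inverse of [forward_intensity()] for the scattering
#' variance \eqn{\sigma_S^2}. On noisy pixels the computed variance can be
#' negative; it is reported as computed (clamping happens only in the
#' displayable standard-deviation map of [retrieve_parametric_images()]),
#' so ROI averages stay unbiased.
#'
#' @inheritParams retrieve_refraction
#' @param rc a [rocking_curve()].
#' @return scattering variance in microradians squared (signed), or `NA`.
#' @export
retrieve_scatter_variance <- function(triple, rc) {
  triple <- .as_triple(triple)
  stopifnot(inherits(rc, "rocking_curve"))
  I <- triple$intensities
  .three_image_solve(I[1], I[2], I[3], triple$thetas, rc$sigma)$sig2
}

#' Three-image apparent-absorption retrieval
#'
#' Given the refraction angle and scattering variance, inverts the forward
#' model for `I_R` using (arbitrarily) one of the three images; on noiseless
#' data the result is independent of which image is used.
#'
#' @inheritParams retrieve_scatter_variance
#' @param dtheta_r refraction angle (microradians).
#' @param scatter_var scattering variance (microradians squared); must
#'   satisfy `scatter_var + rc$sigma^2 > 0`.
#' @param which index (1, 2 or 3) of the image to invert.
#' @return apparent absorption (transmission), or `NA` if invalid.
#' @export
retrieve_apparent_absorption <- function(triple, dtheta_r, scatter_var, rc,
                                         which = 2L) {
  triple <- .as_triple(triple)
  stopifnot(inherits(rc, "rocking_curve"), which %in% 1:3)
  s2 <- scatter_var + rc$sigma^2
  if (!is.finite(s2) || s2 <= 0) return(NA_real_)
  I <- triple$intensities[which]
  th <- triple$thetas[which]
  if (!is.finite(I) || I <= 0 || !is.finite(dtheta_r)) return(NA_real_)
  I * sqrt(s2) / rc$sigma * exp((th + dtheta_r)^2 / (2 * s2))
}

#' Two-image refraction retrieval (no scattering)
#'
#' Valid when the pixel has no scattering (`sigma_s = 0`); with scattering
#' present the result is biased by the factor
#' \eqn{\sigma^2/(\sigma^2+\sigma_S^2)}.
#'
#' @param intensities two positive intensities.
#' @param thetas the two distinct analyzer offsets, microradians.
#' @param rc a [rocking_curve()].
#' @return refraction angle, microradians.
#' @export
retrieve_two_image_refraction <- function(intensities, thetas, rc) {
  stopifnot(inherits(rc, "rocking_curve"), length(intensities) == 2L,
            length(thetas) == 2L)
  if (thetas[1] == thetas[2]) stop("the two angles must be distinct")
  if (any(!is.finite(intensities) | intensities <= 0)) return(NA_real_)
  rc$sigma^2 / (thetas[2] - thetas[1]) * log(intensities[1] / intensities[2]) -
    (thetas[2] + thetas[1]) / 2
}

#' Two-image apparent absorption (no scattering)
#'
#' @param intensity measured intensity at `theta`.
#' @param theta analyzer offset, microradians.
#' @param dtheta_r refraction angle, microradians.
#' @param rc a [rocking_curve()].
#' @return apparent absorption. Equals the three-image formula with
#'   `scatter_var = 0`.
#' @export
retrieve_two_image_absorption_noscatter <- function(intensity, theta,
                                                    dtheta_r, rc) {
  stopifnot(inherits(rc, "rocking_curve"))
  if (!is.finite(intensity) || intensity <= 0) return(NA_real_)
  intensity * exp((theta + dtheta_r)^2 / (2 * rc$sigma^2))
}

#' Two-image scattering variance (no refraction)
#'
#' Requires `|theta1| != |theta2|`: at symmetric angles both the numerator
#' and the log-ratio vanish and the formula is degenerate.
#'
#' @inheritParams retrieve_two_image_refraction
#' @return scattering variance, microradians squared, or `NA` if degenerate.
#' @export
retrieve_two_image_scatter_norefraction <- function(intensities, thetas, rc) {
  stopifnot(inherits(rc, "rocking_curve"), length(intensities) == 2L,
            length(thetas) == 2L)
  if (abs(thetas[1]) == abs(thetas[2]))
    stop("degenerate: need |theta1| != |theta2|")
  if (any(!is.finite(intensities) | intensities <= 0)) return(NA_real_)
  L <- log(intensities[1] / intensities[2])
  if (L == 0) return(NA_real_)
  (thetas[2]^2 - thetas[1]^2) / (2 * L) - rc$sigma^2
}

#' Two-image apparent absorption (no refraction)
#'
#' @inheritParams retrieve_two_image_absorption_noscatter
#' @param scatter_var scattering variance, microradians squared.
#' @return apparent absorption. Equals the three-image formula with
#'   `dtheta_r = 0`.
#' @export
retrieve_two_image_absorption_norefraction <- function(intensity, theta,
                                                       scatter_var, rc) {
  stopifnot(inherits(rc, "rocking_curve"))
  s2 <- scatter_var + rc$sigma^2
  if (!is.finite(intensity) || intensity <= 0 || s2 <= 0) return(NA_real_)
  intensity * sqrt(s2) / rc$sigma * exp(theta^2 / (2 * s2))
}

#' Per-pixel parametric-image retrieval from a three-image stack
#'
#' Applies the three closed-form inversions pixel-wise to three co-registered
#' images, producing the apparent-absorption, refraction and
#' scattering-variance maps plus a validity mask. Pixels with non-positive
#' intensity or a degenerate denominator are masked (`NA` in the maps), not
#' propagated as errors. The scattering standard-deviation map clamps
#' negative variances to 0; such pixels are flagged in `clamped` but remain
#' valid (the signed variance map is untouched, keeping ROI averages
#' unbiased). Apparent absorption above 1 is physically impossible for a
#' passive sample but is *not* clipped; the fraction of such pixels is
#' returned as `frac_ir_gt1`.
#'
#' @param stack either an `image_stack` (see [simulate_working_point_set()])
#'   or a list of three numeric matrices.
#' @param thetas the three analyzer offsets (ignored if `stack` carries its
#'   own); microradians.
#' @param rc a [rocking_curve()].
#' @param which_absorption image index used in the absorption inversion.
#' @param pixel_pitch pixel pitch in micrometres (metadata).
#' @return object of class `parametric_images`: matrices `i_r`, `dtheta_r`,
#'   `sigma_s2`, `sigma_s`, logical `mask` (TRUE = valid) and `clamped`,
#'   plus `pixel_pitch` and `frac_ir_gt1`.
#' @export
retrieve_parametric_images <- function(stack, thetas = NULL, rc,
                                       which_absorption = 2L,
                                       pixel_pitch = NA_real_) {
  if (inherits(stack, "image_stack")) {
    imgs <- stack$images
    if (is.null(thetas)) thetas <- stack$thetas
    if (is.na(pixel_pitch) && !is.null(stack$pixel_pitch))
      pixel_pitch <- stack$pixel_pitch
  } else imgs <- stack
  if (length(imgs) != 3L) stop("need exactly three images")
  dims <- lapply(imgs, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("images must share one shape")
  thetas <- working_points(thetas)$thetas
  if (length(thetas) != 3L) stop("need exactly three angles")
  stopifnot(inherits(rc, "rocking_curve"))

  I1 <- imgs[[1]]; I2 <- imgs[[2]]; I3 <- imgs[[3]]
  sol <- .three_image_solve(I1, I2, I3, thetas, rc$sigma)
  s2 <- sol$sig2 + rc$sigma^2
  Ii <- imgs[[which_absorption]]
  ok <- sol$ok & is.finite(s2) & s2 > 0
  i_r <- rep(NA_real_, length(Ii))
  idx <- which(ok)
  i_r[idx] <- Ii[idx] * sqrt(s2[idx]) / rc$sigma *
    exp((thetas[which_absorption] + sol$dtheta[idx])^2 / (2 * s2[idx]))
  dtheta <- sol$dtheta; dtheta[!ok] <- NA_real_
  sig2 <- sol$sig2; sig2[!ok] <- NA_real_
  clamped <- ok & sig2 < 0
  sigma_s <- sqrt(pmax(sig2, 0))
  dim(i_r) <- dim(dtheta) <- dim(sig2) <- dim(sigma_s) <- dim(ok) <-
    dim(clamped) <- dim(I1)
  structure(list(i_r = i_r, dtheta_r = dtheta, sigma_s2 = sig2,
                 sigma_s = sigma_s, mask = ok, clamped = clamped,
                 pixel_pitch = pixel_pitch,
                 frac_ir_gt1 = mean(i_r[ok] > 1)),
            class = "parametric_images")
}

#' @export
print.parametric_images <- function(x, ...) {
  d <- dim(x$i_r)
  cat(sprintf("parametric images %d x %d (pitch %s um): %.1f%% valid, %.1f%% I_R > 1, %.1f%% variance clamped\n",
              d[1], d[2], format(x$pixel_pitch), 100 * mean(x$mask),
              100 * x$frac_ir_gt1, 100 * mean(x$clamped)))
  invisible(x)
}
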