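#' Gaussian rocking-curve model of the analyzer crystal
#'
#' The analyzer transmission versus angular offset from the Bragg peak is
#' modelled as a unit-peak Gaussian, \eqn{R(\theta) = \exp(-\theta^2 /
#' (2\sigma^2))}. All working angles in the package are offsets from the peak
#' in microradians; the Bragg angle itself never enters the retrieval and is
#' kept only as metadata.
#'
#' @param sigma angular width (standard deviation) of the rocking curve, in
#'   microradians. Must be positive. For a Si(111) analyzer at 17 keV a
#'   typical value is 8.6.
#' @param bragg_offset reference (Bragg) angle, microradians. Default 0;
#'   informational only.
#' @return an object of class `rocking_curve` with fields `sigma`,
#'   `bragg_offset` and `peak_transmission` (fixed at 1).
#' @examples
#' rc <- rocking_curve(8.6)
#' rc_transmission(0, rc)      # 1 at the peak
#' rc_transmission(8.6, rc)    # exp(-1/2) at one sigma
#' @export
rocking_curve <- function(sigma, bragg_offset = 0) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, is.finite(sigma))
  if (sigma <= 0) stop("rocking curve width `sigma` must be > 0")
  structure(
    list(sigma = as.numeric(sigma), bragg_offset = as.numeric(bragg_offset),
         peak_transmission = 1),
    class = "rocking_curve"
  )
}

#' @export
print.rocking_curve <- function(x, ...) {
  cat(sprintf("Gaussian rocking curve: sigma = %.4g urad (FWHM %.4g urad)\n",
              x$sigma, x$sigma * 2 * sqrt(2 * log(2))))
  invisible(x)
}

#' Analyzer transmission at an angular offset
#'
#' @param theta angular offset from the rocking-curve peak, microradians.
#'   Vectorized.
#' @param rc a [rocking_curve()].
#' @return transmission in `(0, 1]`; even in `theta`, equal to 1 at 0.
#' @export
rc_transmission <- function(theta, rc) {
  stopifnot(inherits(rc, "rocking_curve"))
  if (!all(is.finite(theta))) stop("`theta` must be finite")
  exp(-theta^2 / (2 * rc$sigma^2))
}

#' Working-point angle on the ideal Gaussian rocking curve
#'
#' Cardinal acquisition points are conventionally the two 50% half-slopes and
#' the peak. For a unit-peak Gaussian the offset where the transmission drops
#' to `fraction` is \eqn{\theta = \mp\sigma\sqrt{-2\ln f}} (negative on the
#' low-angle side).
#'
#' @param rc a [rocking_curve()].
#' @param fraction transmission fraction in `(0, 1]`.
#' @param side `"low"`, `"high"` or `"peak"`. `"peak"` ignores `fraction`'s
#'   side and returns 0 only when `fraction == 1`.
#' @return offset angle in microradians.
#' @examples
#' working_point_angle(rocking_curve(8.6), 0.5, "low")   # -10.1257
#' @export
working_point_angle <- function(rc, fraction, side = c("low", "high", "peak")) {
  stopifnot(inherits(rc, "rocking_curve"))
  side <- match.arg(side)
  if (!is.numeric(fraction) || length(fraction) != 1L || !is.finite(fraction) ||
      fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]")
  mag <- rc$sigma * sqrt(-2 * log(fraction))
  switch(side, low = -mag, high = mag, peak = 0)
}

#' Working-point angle interpolated on measured rocking-curve samples
#'
#' Locates the analyzer offset where the *measured* curve crosses
#' `fraction` of its peak sample, by linear interpolation between the two
#' bracketing samples, scanning outward from the peak (robust to side-lobe
#' noise). This supplies the actual, off-nominal working angles to the
#' retrieval (e.g. a 49%/55% pair instead of nominal half-slopes).
#'
#' @param angles,intensities rocking-curve samples (microradians, counts or
#'   normalized); need not be sorted.
#' @param fraction fraction of the peak sample intensity, in `(0, 1]`.
#' @param side `"low"` or `"high"` of the peak, or `"peak"`.
#' @return interpolated offset angle in microradians.
#' @export
working_point_from_samples <- function(angles, intensities, fraction,
                                       side = c("low", "high", "peak")) {
  side <- match.arg(side)
  stopifnot(length(angles) == length(intensities), length(angles) >= 2)
  o <- order(angles)
  a <- as.numeric(angles[o]); y <- as.numeric(intensities[o])
  ipk <- which.max(y)
  if (side == "peak") return(a[ipk])
  target <- fraction * y[ipk]
  if (fraction > 1 || fraction <= 0) stop("`fraction` must be in (0, 1]")
  idx <- if (side == "low") seq(ipk, 1L) else seq(ipk, length(a))
  for (k in seq_len(length(idx) - 1L)) {
    i1 <- idx[k]; i2 <- idx[k + 1L]
    lo <- min(y[i1], y[i2]); hi <- max(y[i1], y[i2])
    if (target <= hi && target >= lo) {
      if (y[i2] == y[i1]) return((a[i1] + a[i2]) / 2)
      return(a[i1] + (target - y[i1]) * (a[i2] - a[i1]) / (y[i2] - y[i1]))
    }
  }
  stop(sprintf("fraction %.3g of peak not bracketed on the %s side", fraction,
               side))
}

#' Read rocking-curve samples from delimited text
#'
#' Two whitespace- or comma-delimited columns (angle in microradians,
#' intensity); lines starting with `#` are comments.
#'
#' @param path file path.
#' @return data.frame with columns `angle` and `intensity`.
#' @export
read_rc_samples <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ln <- readLines(path, warn = FALSE)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(gsub(",", " ", ln, fixed = TRUE))
  ln <- ln[nzchar(ln)]
  if (!length(ln)) stop("no data rows in ", path)
  v <- scan(text = ln, what = numeric(), quiet = TRUE)
  if (length(v) %% 2L != 0L) stop("expected two numeric columns in ", path)
  d <- data.frame(angle = v[c(TRUE, FALSE)], intensity = v[c(FALSE, TRUE)])
  if (any(d$intensity < 0)) stop("negative intensities in RC samples")
  d
}
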