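#' Monte Carlo simulation configuration
#'
#' @param photons_per_pixel photons aimed at each detector pixel. The budget
#'   is per pixel so image noise is predictable; default 1e4.
#' @param pixel_pitch detector pixel pitch, micrometres (default 14, the
#'   planar-phantom detector).
#' @param intrinsic_resolution sub-pixel sampling of photon positions,
#'   micrometres (default 1).
#' @param psf_fwhm Gaussian source/detector PSF FWHM in micrometres applied
#'   as a positional jitter before binning; 0 (default) disables it.
#' @param seed master RNG seed; per-angle substreams are derived from it so
#'   adding working points never perturbs earlier images.
#' @param rc a [rocking_curve()].
#' @return object of class `sim_config`.
#' @export
sim_config <- function(photons_per_pixel = 1e4, pixel_pitch = 14,
                       intrinsic_resolution = 1, psf_fwhm = 0, seed = 1L,
                       rc = rocking_curve(8.6)) {
  stopifnot(photons_per_pixel > 0, pixel_pitch >= intrinsic_resolution,
            intrinsic_resolution > 0, psf_fwhm >= 0,
            inherits(rc, "rocking_curve"))
  structure(list(photons_per_pixel = as.integer(photons_per_pixel),
                 pixel_pitch = pixel_pitch,
                 intrinsic_resolution = intrinsic_resolution,
                 psf_fwhm = psf_fwhm, seed = as.integer(seed), rc = rc),
            class = "sim_config")
}

# Pixel grid of a phantom at a given pitch: row centers (mm, descending,
# physical y up) and column centers (mm, ascending).
.pixel_grid <- function(ph, pixel_pitch_um) {
  p <- pixel_pitch_um / 1000
  nx <- max(1L, floor(diff(ph$fov_x) / p))
  ny <- max(1L, floor(diff(ph$fov_y) / p))
  list(
    x = ph$fov_x[1] + (seq_len(nx) - 0.5) * p,
    y = ph$fov_y[2] - (seq_len(ny) - 0.5) * p,
    pitch_mm = p, nx = nx, ny = ny
  )
}

# Per-pixel foil maps: scattering width (urad) and foil transmission.
# Overlapping foils combine: variances add, transmissions multiply.
.foil_maps <- function(ph, grid) {
  s2 <- matrix(0, grid$ny, grid$nx)
  tr <- matrix(1, grid$ny, grid$nx)
  for (e in ph$elements) {
    if (e$kind != "foil") next
    cols <- which(grid$x >= e$x_range[1] & grid$x < e$x_range[2])
    rows <- which(grid$y >= e$y_range[1] & grid$y < e$y_range[2])
    if (length(cols) && length(rows)) {
      s2[rows, cols] <- s2[rows, cols] + e$sigma_s^2
      tr[rows, cols] <- tr[rows, cols] * e$transmission
    }
  }
  list(sigma_s = sqrt(s2), trans = tr)
}

.derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1009 + 97 * k) %% 2147483647)
}

#' Simulate one analyzer-based image of a phantom
#'
#' Per photon: (1) uniform transverse position on the intrinsic sub-grid of
#' its pixel; (2) Gaussian scattering draw with the local foil width; (3)
#' Bernoulli absorption in foil material and along the rod chord; (4)
#' deterministic two-interface refraction from the rod geometry; (5)
#' Bernoulli analyzer acceptance with probability
#' `R(theta + dtheta_R + dtheta_S)`; (6) optional Gaussian PSF jitter; (7)
#' binning. The returned image is normalized by the peak-flat level (the
#' photon budget), so an object-free pixel has expectation `R(theta)`; raw
#' accepted counts are attached. Bit-identical for identical seed and
#' configuration.
#'
#' @param ph a [phantom()].
#' @param cfg a [sim_config()].
#' @param theta analyzer offset, microradians.
#' @param angle_index integer used to derive the per-angle RNG substream.
#' @return object of class `sim_image`: `image` (normalized matrix),
#'   `counts`, `theta`, `norm` (expected background counts), and the grid.
#' @export
simulate_image <- function(ph, cfg, theta, angle_index = 0L) {
  stopifnot(inherits(ph, "phantom"), inherits(cfg, "sim_config"),
            is.finite(theta))
  if (cfg$photons_per_pixel <= 0) stop("photon budget must be positive")
  grid <- .pixel_grid(ph, cfg$pixel_pitch)
  fm <- .foil_maps(ph, grid)
  cyl <- Filter(function(e) e$kind == "cylinder", ph$elements)
  radius <- vapply(cyl, `[[`, numeric(1), "radius")
  center <- vapply(cyl, `[[`, numeric(1), "center_y")
  mu <- vapply(cyl, `[[`, numeric(1), "mu")
  delta <- vapply(cyl, `[[`, numeric(1), "delta")
  cap <- cfg$rc$sigma * sqrt(2 * log(1e12))
  psf_sigma_mm <- cfg$psf_fwhm / (2 * sqrt(2 * log(2))) / 1000

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(.derive_seed(cfg$seed, angle_index))
  res <- simulate_image_cpp(fm$sigma_s, fm$trans, grid$y, grid$pitch_mm,
                            cfg$intrinsic_resolution / 1000,
                            cfg$photons_per_pixel, theta, cfg$rc$sigma,
                            radius, center, mu, delta, cap, psf_sigma_mm)
  # shared peak-flat normalization: object-free expectation is R(theta),
  # never 1 (per-angle flats would cancel the factors the inversion needs)
  norm <- cfg$photons_per_pixel
  structure(list(image = res$counts / norm, counts = res$counts,
                 theta = theta, norm = norm, x = grid$x, y = grid$y,
                 pixel_pitch = cfg$pixel_pitch), class = "sim_image")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Simulate a set of images at several working points
#'
#' Repeated [simulate_image()] with an independent RNG substream per angle
#' index (derived from the master seed), so extending the angle list never
#' changes the earlier images.
#'
#' @param ph a [phantom()].
#' @param cfg a [sim_config()].
#' @param thetas analyzer offsets, microradians (a numeric vector or
#'   [working_points()]).
#' @return object of class `image_stack`: `images` (list of normalized
#'   matrices), `counts`, `thetas`, `norms`, grid coordinates `x`, `y` and
#'   `pixel_pitch`.
#' @export
simulate_working_point_set <- function(ph, cfg, thetas) {
  if (inherits(thetas, "working_points")) thetas <- thetas$thetas
  thetas <- working_points(thetas)$thetas
  sims <- lapply(seq_along(thetas), function(i)
    simulate_image(ph, cfg, thetas[i], angle_index = i))
  structure(list(images = lapply(sims, `[[`, "image"),
                 counts = lapply(sims, `[[`, "counts"),
                 thetas = thetas,
                 norms = vapply(sims, `[[`, numeric(1), "norm"),
                 x = sims[[1]]$x, y = sims[[1]]$y,
                 pixel_pitch = cfg$pixel_pitch), class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$images[[1]])
  cat(sprintf("image stack: %d angle(s) [%s] urad, %d x %d px @ %g um\n",
              length(x$thetas), paste(signif(x$thetas, 4), collapse = ", "),
              d[1], d[2], x$pixel_pitch))
  invisible(x)
}

#' Chord length of a ray through a horizontal rod
#'
#' @param y height of the ray relative to the rod axis, mm.
#' @param radius rod radius, mm.
#' @return `2 * sqrt(radius^2 - y^2)` inside, 0 outside (vectorized).
#' @export
cylinder_path_length <- function(y, radius) {
  stopifnot(radius > 0)
  ifelse(abs(y) < radius, 2 * sqrt(pmax(radius^2 - y^2, 0)), 0)
}

#' Small-angle two-interface refraction by a horizontal rod
#'
#' Geometrical-optics deflection of a ray entering and leaving the cylinder,
#' `2 * delta * y / sqrt(radius^2 - y^2)` (radians), returned in
#' microradians. Antisymmetric in `y`; positive (away from the axis) for
#' `y > 0`; diverges toward the edge, so [simulate_image()] caps it where the
#' analyzer acceptance is below 1e-12. Rays outside the rod return 0;
#' exactly grazing rays (`|y| == radius`) are an error.
#'
#' @param y ray height relative to the rod axis, mm.
#' @param radius rod radius, mm.
#' @param delta refractive-index decrement.
#' @return deflection in microradians (vectorized over `y`).
#' @export
cylinder_deflection <- function(y, radius, delta) {
  stopifnot(radius > 0, delta >= 0)
  if (any(abs(y) == radius)) stop("deflection undefined exactly at the rod edge")
  ifelse(abs(y) < radius, 2 * delta * y / sqrt(pmax(radius^2 - y^2, 0)) * 1e6,
         0)
}
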