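#' Phantom elements
#'
#' A phantom is a list of geometric elements in a rectangular field of view.
#' The coordinate convention: the beam travels along z, images are (y, x)
#' matrices with physical y in mm increasing upward and mapped to rows top to
#' bottom (row 1 = largest y), x in mm increasing to the right along columns.
#'
#' `cylinder_element()` is a horizontal rod (axis along x) providing
#' absorption (`mu`, linear attenuation per mm of chord length) and
#' refraction (`delta`, refractive-index decrement; two-interface small-angle
#' deflection `2*delta*y/sqrt(R^2-y^2)`, positive away from the axis for
#' `y > 0`).
#'
#' `scatter_foil_element()` is an axis-aligned rectangle acting as a pure
#' Gaussian scatterer of width `sigma_s` (microradians) as seen through its
#' full thickness; `transmission < 1` adds plain (non-refracting) absorption,
#' used by the paper-stairway factory.
#'
#' @param radius rod radius, mm.
#' @param center_y rod axis height, mm.
#' @param mu linear attenuation, 1/mm.
#' @param delta refractive-index decrement.
#' @name phantom-elements
NULL

#' @rdname phantom-elements
#' @export
cylinder_element <- function(radius, center_y = 0, mu = 0, delta = 0) {
  stopifnot(radius > 0, mu >= 0, delta >= 0)
  structure(list(kind = "cylinder", radius = radius, center_y = center_y,
                 mu = mu, delta = delta), class = "phantom_element")
}

#' @rdname phantom-elements
#' @param x_range,y_range foil extents, mm (length-2 vectors).
#' @param sigma_s Gaussian scattering width of the foil, microradians.
#' @param transmission foil transmission in `(0, 1]` (default 1: pure
#'   scatterer).
#' @export
scatter_foil_element <- function(x_range, y_range, sigma_s, transmission = 1) {
  stopifnot(length(x_range) == 2L, length(y_range) == 2L,
            diff(x_range) > 0, diff(y_range) > 0, sigma_s >= 0,
            transmission > 0, transmission <= 1)
  structure(list(kind = "foil", x_range = as.numeric(x_range),
                 y_range = as.numeric(y_range), sigma_s = sigma_s,
                 transmission = transmission), class = "phantom_element")
}

#' Assemble a phantom
#'
#' @param elements list of phantom elements.
#' @param fov_x,fov_y field of view, mm (length-2; should be slightly larger
#'   than the object).
#' @return object of class `phantom`.
#' @export
phantom <- function(elements, fov_x, fov_y) {
  stopifnot(length(fov_x) == 2L, length(fov_y) == 2L, diff(fov_x) > 0,
            diff(fov_y) > 0)
  stopifnot(all(vapply(elements, inherits, logical(1), "phantom_element")))
  structure(list(elements = elements, fov_x = as.numeric(fov_x),
                 fov_y = as.numeric(fov_y)), class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  kinds <- vapply(x$elements, `[[`, character(1), "kind")
  cat(sprintf("phantom: %d cylinder(s), %d foil(s), FOV [%g, %g] x [%g, %g] mm\n",
              sum(kinds == "cylinder"), sum(kinds == "foil"),
              x$fov_x[1], x$fov_x[2], x$fov_y[1], x$fov_y[2]))
  invisible(x)
}

# Tabulated PMMA constants at 17 keV (density 1.19 g/cm^3): linear
# attenuation and refractive-index decrement from standard optical-constant
# tables. Overridable in every factory.
#' @export
PMMA_MU_17KEV <- 0.0786   # 1/mm
#' @export
PMMA_DELTA_17KEV <- 9.2e-7

#' The simulated rod + 12-foil validation phantom
#'
#' A horizontal PMMA rod (diameter 3.6 mm) crossed by 12 adjacent vertical
#' scatter foils, each 2.3 mm wide and 7.2 mm high, with scattering widths
#' 0, 0.86, 1.71, 2.57, 3.43, 4.28, 6.42, 8.57, 10.71, 12.85, 17.13 and
#' 21.41 microradians (i.e. 0 to 50 microradians FWHM) — spanning widths well
#' below, comparable to and well above the 8.6 microradian rocking-curve
#' width. Foils are pure scatterers; the rod carries all absorption and
#' refraction.
#'
#' @param mu,delta rod material constants (defaults: tabulated PMMA at
#'   17 keV).
#' @param rod_diameter mm.
#' @param foil_width,foil_height mm.
#' @param margin extra field of view around the object, mm.
#' @return a [phantom()].
#' @export
make_simulated_phantom <- function(mu = PMMA_MU_17KEV,
                                   delta = PMMA_DELTA_17KEV,
                                   rod_diameter = 3.6, foil_width = 2.3,
                                   foil_height = 7.2, margin = 0.5) {
  sig <- c(0, 0.86, 1.71, 2.57, 3.43, 4.28, 6.42, 8.57, 10.71, 12.85,
           17.13, 21.41)
  foils <- lapply(seq_along(sig), function(i)
    scatter_foil_element(x_range = c((i - 1), i) * foil_width,
                         y_range = c(-1, 1) * foil_height / 2,
                         sigma_s = sig[i]))
  rod <- cylinder_element(radius = rod_diameter / 2, center_y = 0,
                          mu = mu, delta = delta)
  phantom(c(list(rod), foils),
          fov_x = c(-margin, length(sig) * foil_width + margin),
          fov_y = c(-1, 1) * (foil_height / 2 + margin))
}

#' The experimental-style paper-stairway phantom
#'
#' Up to `n_layers_max` steps of stacked paper layers; step `n` scatters with
#' width `sigma_one_layer * sqrt(n)` (scattering widths add in quadrature
#' with layer count) and transmits `(1 - absorption_per_layer)^n`. Strips at
#' both sides are left blank for normalization. Optionally a PMMA rod
#' (diameter 5 mm) is superimposed as in the experimental phantom.
#'
#' @param n_layers_max number of steps (default 6).
#' @param sigma_one_layer scattering width of a single 100 um paper layer,
#'   microradians.
#' @param absorption_per_layer fractional absorption of one layer.
#' @param step_width,step_height step extents, mm.
#' @param blank_width blank normalization strip width on each side, mm.
#' @param rod logical: superimpose the 5 mm rod.
#' @param mu,delta rod constants (defaults: PMMA at 17 keV).
#' @return a [phantom()].
#' @export
make_paper_stairway_phantom <- function(n_layers_max = 6L,
                                        sigma_one_layer = 4.3,
                                        absorption_per_layer = 0.027,
                                        step_width = 2.3, step_height = 7.2,
                                        blank_width = 1.5, rod = FALSE,
                                        mu = PMMA_MU_17KEV,
                                        delta = PMMA_DELTA_17KEV) {
  stopifnot(n_layers_max >= 1L, sigma_one_layer >= 0,
            absorption_per_layer >= 0, absorption_per_layer < 1)
  steps <- lapply(seq_len(n_layers_max), function(n)
    scatter_foil_element(
      x_range = blank_width + c(n - 1, n) * step_width,
      y_range = c(-1, 1) * step_height / 2,
      sigma_s = sigma_one_layer * sqrt(n),
      transmission = (1 - absorption_per_layer)^n))
  els <- steps
  if (rod) els <- c(list(cylinder_element(2.5, 0, mu, delta)), els)
  phantom(els,
          fov_x = c(0, 2 * blank_width + n_layers_max * step_width),
          fov_y = c(-1, 1) * (step_height / 2 + 0.4))
}

#' Serialize / deserialize phantoms as structured text (JSON)
#'
#' @param ph a [phantom()].
#' @param path file path.
#' @return `read_phantom` returns a [phantom()]; `write_phantom` returns
#'   `path` invisibly.
#' @export
write_phantom <- function(ph, path) {
  stopifnot(inherits(ph, "phantom"))
  obj <- list(fov_x = ph$fov_x, fov_y = ph$fov_y,
              elements = lapply(ph$elements, unclass))
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x))
  els <- lapply(obj$elements, function(e) {
    if (unlist(e$kind) == "cylinder")
      cylinder_element(num(e$radius), num(e$center_y), num(e$mu),
                       num(e$delta))
    else
      scatter_foil_element(num(e$x_range), num(e$y_range), num(e$sigma_s),
                           num(e$transmission))
  })
  phantom(els, num(obj$fov_x), num(obj$fov_y))
}
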