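#' Offset ("dark") and slope ("flat") correction
#'
#' Normalizes a raw image as `(raw - dark) / (flat_peak - dark)`, where
#' `flat_peak` is the object-free image acquired at the rocking-curve *peak*
#' position. Dividing every working-point image by this one peak flat leaves
#' the background at offset theta equal to `R(theta)` — the normalization
#' contract the closed-form inversion relies on. Dividing each image by its
#' own per-angle flat would silently cancel those factors; that mode exists
#' behind `per_angle = TRUE` for raw-data exploration and warns loudly.
#'
#' @param raw raw image matrix.
#' @param dark dark (offset) image, same shape.
#' @param flat flat (slope reference) image, same shape; the peak-position
#'   flat unless `per_angle = TRUE`.
#' @param per_angle set `TRUE` only if `flat` was acquired at the same
#'   analyzer offset as `raw`; breaks the retrieval normalization contract.
#' @return normalized matrix; pixels with non-positive `flat - dark` are
#'   `NA` (masked).
#' @export
correct_image <- function(raw, dark, flat, per_angle = FALSE) {
  stopifnot(is.matrix(raw), identical(dim(raw), dim(dark)),
            identical(dim(raw), dim(flat)))
  if (per_angle)
    warning("per-angle flat normalization cancels the R(theta_i) factors; ",
            "the three-image inversion is NOT valid on such images")
  den <- flat - dark
  out <- (raw - dark) / den
  out[!is.finite(out) | den <= 0] <- NA_real_
  out
}

#' Rectangular region of interest
#'
#' Rows and columns are 1-based inclusive index ranges (R convention).
#'
#' @param rows,cols length-2 integer vectors `c(first, last)`.
#' @return object of class `region_spec`.
#' @export
region_spec <- function(rows, cols) {
  stopifnot(length(rows) == 2L, length(cols) == 2L,
            rows[1] >= 1, cols[1] >= 1, rows[2] >= rows[1],
            cols[2] >= cols[1])
  structure(list(rows = as.integer(rows), cols = as.integer(cols)),
            class = "region_spec")
}

#' ROI statistics
#'
#' Mean, standard deviation, standard error of the mean and count over a
#' rectangular region (or logical mask), ignoring masked (`NA`) pixels.
#'
#' @param image numeric matrix.
#' @param region a [region_spec()], or a logical matrix the same shape as
#'   `image`.
#' @return named list `mean`, `sd`, `sem`, `n`.
#' @export
roi_stats <- function(image, region) {
  if (inherits(region, "region_spec")) {
    if (region$rows[2] > nrow(image) || region$cols[2] > ncol(image))
      stop("region exceeds image bounds")
    v <- image[region$rows[1]:region$rows[2], region$cols[1]:region$cols[2]]
  } else if (is.logical(region)) {
    stopifnot(identical(dim(region), dim(image)))
    v <- image[region]
  } else stop("`region` must be a region_spec or a logical mask")
  v <- v[is.finite(v)]
  n <- length(v)
  if (n == 0L) return(list(mean = NA_real_, sd = NA_real_, sem = NA_real_,
                           n = 0L))
  s <- if (n > 1L) stats::sd(v) else 0
  list(mean = mean(v), sd = s, sem = s / sqrt(n), n = n)
}
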