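# Levenberg-Marquardt fit of A*exp(-(x-c)^2/(2 s^2)), vectorized over many
# curves sharing one abscissa. stats::nls cannot be used: it aborts on
# zero-residual (noiseless) input, which must converge to machine precision
# here. Normal equations are 3x3 per curve and solved in closed form.

# Y: P x N matrix (one curve per row), x: length-N abscissa.
# Returns list of length-P vectors: amplitude, center, sigma, rss, converged,
# and (if se = TRUE) standard errors from the Gauss-Newton approximation.
.gauss_lm <- function(x, Y, weights = NULL, max_iter = 200L, tol = 1e-13,
                      se = FALSE) {
  Y <- rbind(Y)
  P <- nrow(Y); N <- ncol(Y)
  stopifnot(length(x) == N, N >= 4L)
  W <- if (is.null(weights)) matrix(1, P, N) else rbind(weights)

  # moment initialization (intensity-weighted mean / std)
  Yp <- pmax(Y, 0)
  sw <- rowSums(Yp) + 1e-300
  c0 <- as.numeric(Yp %*% x) / sw
  D0 <- sweep(outer(rep(1, P), x), 1L, c0)
  s0 <- sqrt(pmax(rowSums(Yp * D0^2) / sw, 1e-12))
  A0 <- apply(Y, 1L, max)

  A <- A0; cc <- c0; s <- pmax(s0, 1e-6)
  lambda <- rep(1e-3, P)
  conv <- rep(FALSE, P)

  model <- function(A, cc, s) {
    D <- sweep(outer(rep(1, length(cc)), x), 1, cc) # x - c, P x N
    E <- exp(-D^2 / (2 * s^2))
    list(D = D, E = E, M = A * E)
  }
  rss_of <- function(A, cc, s) {
    m <- model(A, cc, s)
    rowSums(W * (Y - m$M)^2)
  }
  rss <- rss_of(A, cc, s)

  for (it in seq_len(max_iter)) {
    m <- model(A, cc, s)
    Rz <- Y - m$M
    # Jacobian columns: dM/dA = E ; dM/dc = M * D / s^2 ; dM/ds = M * D^2 / s^3
    J1 <- m$E
    J2 <- m$M * m$D / s^2
    J3 <- m$M * m$D^2 / s^3
    g1 <- rowSums(W * J1 * Rz); g2 <- rowSums(W * J2 * Rz)
    g3 <- rowSums(W * J3 * Rz)
    a11 <- rowSums(W * J1 * J1); a12 <- rowSums(W * J1 * J2)
    a13 <- rowSums(W * J1 * J3); a22 <- rowSums(W * J2 * J2)
    a23 <- rowSums(W * J2 * J3); a33 <- rowSums(W * J3 * J3)
    d11 <- a11 * (1 + lambda); d22 <- a22 * (1 + lambda)
    d33 <- a33 * (1 + lambda)
    # closed-form 3x3 solve (symmetric)
    det <- d11 * (d22 * d33 - a23^2) - a12 * (a12 * d33 - a23 * a13) +
      a13 * (a12 * a23 - d22 * a13)
    det[det == 0 | !is.finite(det)] <- NA
    dA <- (g1 * (d22 * d33 - a23^2) + g2 * (a13 * a23 - a12 * d33) +
             g3 * (a12 * a23 - a13 * d22)) / det
    dc <- (g1 * (a23 * a13 - a12 * d33) + g2 * (d11 * d33 - a13^2) +
             g3 * (a12 * a13 - d11 * a23)) / det
    ds <- (g1 * (a12 * a23 - d22 * a13) + g2 * (a13 * a12 - d11 * a23) +
             g3 * (d11 * d22 - a12^2)) / det
    bad <- !is.finite(dA) | !is.finite(dc) | !is.finite(ds)
    dA[bad] <- 0; dc[bad] <- 0; ds[bad] <- 0
    A_n <- A + dA; c_n <- cc + dc; s_n <- pmax(s + ds, 1e-9)
    rss_n <- rss_of(A_n, c_n, s_n)
    better <- is.finite(rss_n) & (rss_n <= rss)
    A[better] <- A_n[better]; cc[better] <- c_n[better]
    s[better] <- s_n[better]
    lambda <- ifelse(better, pmax(lambda / 5, 1e-12), pmin(lambda * 10, 1e8))
    step <- pmax(abs(dA) / pmax(abs(A), 1e-12),
                 abs(dc) / pmax(abs(cc), 1),
                 abs(ds) / pmax(abs(s), 1e-12))
    improved <- (rss - pmin(rss_n, rss)) <= tol * pmax(rss, 1e-300)
    rss <- pmin(rss, rss_n, na.rm = TRUE)
    conv <- conv | (better & step < 1e-10) | (improved & rss < 1e-24)
    if (all(conv | bad)) break
  }

  out <- list(amplitude = A, center = cc, sigma = abs(s), rss = rss,
              converged = conv | rss <= 1e-20)
  if (se) {
    m <- model(A, cc, s)
    J1 <- m$E; J2 <- m$M * m$D / s^2; J3 <- m$M * m$D^2 / s^3
    a11 <- rowSums(W * J1^2); a12 <- rowSums(W * J1 * J2)
    a13 <- rowSums(W * J1 * J3); a22 <- rowSums(W * J2^2)
    a23 <- rowSums(W * J2 * J3); a33 <- rowSums(W * J3^2)
    det <- a11 * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
      a13 * (a12 * a23 - a22 * a13)
    det[det <= 0 | !is.finite(det)] <- NA
    s2 <- rss / pmax(N - 3, 1)
    out$se_amplitude <- sqrt(pmax(s2 * (a22 * a33 - a23^2) / det, 0))
    out$se_center <- sqrt(pmax(s2 * (a11 * a33 - a13^2) / det, 0))
    out$se_sigma <- sqrt(pmax(s2 * (a11 * a22 - a12^2) / det, 0))
  }
  out
}

#' Fit a Gaussian to rocking-curve samples
#'
#' Nonlinear least squares of \eqn{A \exp(-(\theta - c)^2 / (2 s^2))},
#' initialized from intensity-weighted moments. Converges to machine
#' precision on exact Gaussian input. Used both for the analyzer rocking
#' curve and for local (object-modulated) curves, whose fitted width is
#' \eqn{\sigma_m} with \eqn{\sigma_m^2 = \sigma^2 + \sigma_S^2}.
#'
#' @param angles sample angles, microradians.
#' @param intensities sample intensities (counts or normalized), `>= 0`.
#' @param weighted if `TRUE`, weight residuals by intensity (counting
#'   statistics); default unweighted.
#' @return object of class `rc_fit`: `amplitude`, `center`, `sigma`,
#'   `residual_norm`, standard errors `se_*`, and `converged`.
#' @examples
#' th <- seq(-30, 30, length.out = 21)
#' f <- fit_gaussian(th, exp(-th^2 / (2 * 8.6^2)))
#' f$sigma   # 8.6
#' @export
fit_gaussian <- function(angles, intensities, weighted = FALSE) {
  stopifnot(length(angles) == length(intensities))
  keep <- is.finite(angles) & is.finite(intensities)
  a <- as.numeric(angles[keep]); y <- as.numeric(intensities[keep])
  if (length(unique(a)) < 4L) stop("need >= 4 distinct angles for a 3-parameter fit")
  if (any(y < 0)) stop("intensities must be >= 0")
  w <- if (weighted) pmax(y, max(y) * 1e-6) else NULL
  ft <- .gauss_lm(a, matrix(y, nrow = 1), weights = if (is.null(w)) NULL else
    matrix(w, nrow = 1), se = TRUE)
  if (!ft$converged[1] || !is.finite(ft$rss[1]))
    stop(sprintf(paste0("Gaussian fit did not converge (rss=%.3g, A=%.3g, ",
                        "c=%.3g, s=%.3g)"),
                 ft$rss[1], ft$amplitude[1], ft$center[1], ft$sigma[1]))
  peak_at_edge <- which.max(y) %in% c(1L, length(y))
  structure(list(amplitude = ft$amplitude[1], center = ft$center[1],
                 sigma = ft$sigma[1], residual_norm = sqrt(ft$rss[1]),
                 se_amplitude = ft$se_amplitude[1],
                 se_center = ft$se_center[1], se_sigma = ft$se_sigma[1],
                 peak_at_edge = peak_at_edge, converged = TRUE),
            class = "rc_fit")
}

#' @export
print.rc_fit <- function(x, ...) {
  cat(sprintf("Gaussian fit: A = %.6g, center = %.6g urad, sigma = %.6g urad (rss^1/2 = %.3g)\n",
              x$amplitude, x$center, x$sigma, x$residual_norm))
  if (isTRUE(x$peak_at_edge)) cat("warning: peak lies at an extreme sample\n")
  invisible(x)
}
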