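# Independent oracles and fixture builders shared across tests.

# Numerical convolution of the Gaussian rocking curve with the Gaussian
# scattering density -- the quadrature oracle for the closed-form forward
# model. Shares no code with forward_intensity().
quad_forward <- function(i_r, dtheta_r, sigma_s, theta, rc) {
  if (sigma_s == 0)
    return(i_r * rc_transmission(theta + dtheta_r, rc))
  f <- function(dts)
    rc_transmission(theta + dtheta_r + dts, rc) * dnorm(dts, 0, sigma_s)
  i_r * integrate(f, -Inf, Inf, rel.tol = 1e-12, abs.tol = 0)$value
}

# Random parameter tuples + triads for property sweeps. Triads are distinct
# (pairwise separation >= 0.5 urad) offsets within +/- 3 sigma.
rand_cases <- function(n, rc, seed = 42) {
  set.seed(seed)
  draw_triad <- function() {
    repeat {
      th <- sort(runif(3, -3 * rc$sigma, 3 * rc$sigma))
      if (min(diff(th)) >= 0.5) return(th)
    }
  }
  list(i_r = runif(n, 1e-3, 1),
       dtheta_r = runif(n, -30, 30),
       sigma_s2 = runif(n, 0, 900),
       triads = t(vapply(seq_len(n), function(i) draw_triad(), numeric(3))))
}

# Noiseless closed-form image stack: every pixel shares (i_r, dtheta_r,
# sigma_s), evaluated at each working point.
closed_form_stack <- function(i_r, dtheta_r, sigma_s, thetas, rc,
                              dims = c(3, 4)) {
  lapply(thetas, function(t)
    matrix(forward_intensity(i_r, dtheta_r, sigma_s, t, rc), dims[1],
           dims[2]))
}

rc86 <- rocking_curve(8.6)
half_slope <- function(rc = rc86) c(working_point_angle(rc, 0.5, "low"), 0,
                                    working_point_angle(rc, 0.5, "high"))
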