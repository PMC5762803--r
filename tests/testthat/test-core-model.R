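test_that("forward model matches its special cases and the quadrature oracle", {
  rc <- rc86
  expect_identical(forward_intensity(1, 0, 0, 0, rc), 1)
  # equal-width convolution at the peak loses 1/sqrt(2) to extinction
  expect_equal(forward_intensity(1, 0, 8.6, 0, rc), 1 / sqrt(2),
               tolerance = 1e-12)
  # sigma_s = 0 degenerates to I_R * R(theta + dtheta)
  expect_equal(forward_intensity(0.8, 3, 0, 5, rc),
               0.8 * rc_transmission(8, rc))
  # strictly decreasing in sigma_s at theta = -dtheta_r (extinction)
  v <- forward_intensity(1, 5, seq(0, 20, by = 2), -5, rc)
  expect_true(all(diff(v) < 0))
  # quadrature oracle, spec example
  expect_equal(forward_intensity(0.79, 5, 6.42, 10.1257, rc),
               quad_forward(0.79, 5, 6.42, 10.1257, rc), tolerance = 1e-8)
  expect_error(forward_intensity(1, 0, -1, 0, rc), ">= 0")
})

test_that("three-image inversion is the exact algebraic inverse", {
  rc <- rc86
  triad <- half_slope()
  # symmetric triad, no refraction
  tr0 <- pixel_triple(forward_intensity(1, 0, 6.42, triad, rc), triad)
  expect_equal(retrieve_refraction(tr0), 0, tolerance = 1e-9)
  expect_equal(retrieve_scatter_variance(tr0, rc), 41.2164,
               tolerance = 1e-6)
  # refraction round-trip
  tr5 <- pixel_triple(forward_intensity(1, 5, 6.42, triad, rc), triad)
  expect_equal(retrieve_refraction(tr5), 5, tolerance = 1e-9)
  # asymmetric triad
  tha <- c(-10.1257, 0, 4.3)
  tra <- pixel_triple(forward_intensity(1, -3, 6.42, tha, rc), tha)
  expect_equal(retrieve_refraction(tra), -3, tolerance = 1e-9)
  # zero and largest-foil scattering widths
  trz <- pixel_triple(forward_intensity(1, 2, 0, triad, rc), triad)
  expect_equal(retrieve_scatter_variance(trz, rc), 0, tolerance = 1e-9)
  trl <- pixel_triple(forward_intensity(1, 0, 21.41, triad, rc), triad)
  expect_equal(retrieve_scatter_variance(trl, rc), 458.3881,
               tolerance = 1e-6)
})

test_that("absorption retrieval is index-invariant and exact", {
  rc <- rc86
  triad <- half_slope()
  # object-free pixel
  bg <- pixel_triple(rc_transmission(triad, rc), triad)
  for (i in 1:3)
    expect_equal(retrieve_apparent_absorption(bg, 0, 0, rc, i), 1,
                 tolerance = 1e-12)
  # round-trip, all three indices agree
  tr <- pixel_triple(forward_intensity(0.79, 5, 6.42, triad, rc), triad)
  dt <- retrieve_refraction(tr)
  s2 <- retrieve_scatter_variance(tr, rc)
  ir <- vapply(1:3, function(i)
    retrieve_apparent_absorption(tr, dt, s2, rc, i), numeric(1))
  expect_equal(ir, rep(0.79, 3), tolerance = 1e-9)
  expect_lt(max(abs(ir - ir[1])) / ir[1], 1e-9)
  # scatter_var <= -sigma^2 is invalid, not an exception
  expect_true(is.na(retrieve_apparent_absorption(tr, 0, -rc$sigma^2 - 1, rc)))
})

test_that("exact-inversion property holds over a random sweep", {
  rc <- rc86
  cs <- rand_cases(300, rc, seed = 7)
  for (k in seq_len(300)) {
    th <- cs$triads[k, ]
    I <- forward_intensity(cs$i_r[k], cs$dtheta_r[k], sqrt(cs$sigma_s2[k]),
                           th, rc)
    tr <- pixel_triple(I, th)
    dt <- retrieve_refraction(tr)
    s2 <- retrieve_scatter_variance(tr, rc)
    ir <- retrieve_apparent_absorption(tr, dt, s2, rc, 1L)
    expect_equal(dt, cs$dtheta_r[k], tolerance = 1e-8)
    expect_equal(s2, cs$sigma_s2[k], tolerance = max(1e-8, 1e-8 * cs$sigma_s2[k]))
    expect_equal(ir, cs$i_r[k], tolerance = 1e-8)
  }
})

test_that("local angular profile has additive variance and extinction amplitude", {
  rc <- rc86
  th <- seq(-35, 35, length.out = 41)
  for (ss in c(3.43, 8.57, 17.13)) {
    y <- forward_intensity(0.7, -2, ss, th, rc)
    f <- fit_gaussian(th, y)
    expect_equal(f$sigma^2, rc$sigma^2 + ss^2, tolerance = 1e-6)
    expect_equal(f$amplitude, 0.7 * sqrt(rc$sigma^2 / (rc$sigma^2 + ss^2)),
                 tolerance = 1e-8)
    expect_equal(-f$center, -2, tolerance = 1e-8)
  }
})

test_that("invalid pixels signal NA, not exceptions", {
  rc <- rc86
  triad <- half_slope()
  expect_true(is.na(retrieve_refraction(pixel_triple(c(0.5, 0, 0.5), triad))))
  expect_true(is.na(retrieve_refraction(pixel_triple(c(0.5, -1, 0.5), triad))))
  # degenerate denominator: intensities equal at all three angles
  expect_true(is.na(retrieve_scatter_variance(
    pixel_triple(c(0.4, 0.4, 0.4), triad), rc)))
  expect_error(pixel_triple(c(1, 1), c(0, 0)), "distinct")
})

test_that("two-image formulas coincide with their stated assumptions", {
  rc <- rc86
  pair <- c(-10.1257, 10.1257)
  # refraction round-trip without scattering
  I <- forward_intensity(1, 2.5, 0, pair, rc)
  expect_equal(retrieve_two_image_refraction(I, pair, rc), 2.5,
               tolerance = 1e-9)
  # equal intensities at symmetric angles -> 0
  expect_equal(retrieve_two_image_refraction(c(0.37, 0.37), pair, rc), 0)
  expect_error(retrieve_two_image_refraction(c(1, 1), c(3, 3), rc),
               "distinct")
  # with true scattering present the formula is biased by sigma^2/sigma_m^2
  Is <- forward_intensity(1, 2.5, 6.42, pair, rc)
  biased <- retrieve_two_image_refraction(Is, pair, rc)
  expect_gt(abs(biased - 2.5), 1e-3)
  expect_equal(biased, 2.5 * rc$sigma^2 / (rc$sigma^2 + 6.42^2),
               tolerance = 1e-9)

  # absorption without scattering
  expect_equal(retrieve_two_image_absorption_noscatter(
    rc_transmission(10.1257, rc), 10.1257, 0, rc), 1, tolerance = 1e-12)
  I3 <- forward_intensity(0.66, 3, 0, 10.1257, rc)
  expect_equal(retrieve_two_image_absorption_noscatter(I3, 10.1257, 3, rc),
               0.66, tolerance = 1e-9)
  # degenerates to the three-image formula at scatter_var = 0
  tr <- pixel_triple(forward_intensity(0.66, 3, 0, half_slope(), rc),
                     half_slope())
  expect_equal(retrieve_two_image_absorption_noscatter(I3, 10.1257, 3, rc),
               retrieve_apparent_absorption(tr, 3, 0, rc, 3L),
               tolerance = 1e-9)

  # scattering without refraction
  pair2 <- c(0, 10.1257)
  I4 <- forward_intensity(1, 0, 8.57, pair2, rc)
  expect_equal(retrieve_two_image_scatter_norefraction(I4, pair2, rc),
               73.4449, tolerance = 1e-6)
  I5 <- forward_intensity(1, 0, 0, pair2, rc)
  expect_equal(retrieve_two_image_scatter_norefraction(I5, pair2, rc), 0,
               tolerance = 1e-9)
  expect_error(retrieve_two_image_scatter_norefraction(
    c(0.5, 0.5), c(-7, 7), rc), "degenerate")

  # absorption without refraction
  expect_equal(retrieve_two_image_absorption_norefraction(1, 0, 0, rc), 1)
  I6 <- forward_intensity(0.9, 0, 4.28, 10.1257, rc)
  expect_equal(retrieve_two_image_absorption_norefraction(
    I6, 10.1257, 4.28^2, rc), 0.9, tolerance = 1e-9)
  tr2 <- pixel_triple(forward_intensity(0.9, 0, 4.28, half_slope(), rc),
                      half_slope())
  expect_equal(retrieve_two_image_absorption_norefraction(
    I6, 10.1257, 4.28^2, rc),
    retrieve_apparent_absorption(tr2, 0, 4.28^2, rc, 3L), tolerance = 1e-9)
})

test_that("per-pixel retrieval maps, mask and round-trip consistency", {
  rc <- rc86
  triad <- half_slope()
  # object-free stack
  bg <- lapply(triad, function(t) matrix(rc_transmission(t, rc), 5, 6))
  pm <- retrieve_parametric_images(bg, triad, rc)
  expect_true(all(pm$mask))
  expect_equal(pm$i_r, matrix(1, 5, 6), tolerance = 1e-10)
  expect_equal(pm$dtheta_r, matrix(0, 5, 6), tolerance = 1e-8)
  expect_equal(pm$sigma_s2, matrix(0, 5, 6), tolerance = 1e-8)

  # heterogeneous pixels, one dead pixel: masked, no NaN propagation
  imgs <- closed_form_stack(0.79, 5, 6.42, triad, rc, dims = c(3, 4))
  imgs[[2]][2, 2] <- 0
  pm2 <- retrieve_parametric_images(imgs, triad, rc)
  expect_false(pm2$mask[2, 2])
  expect_true(is.na(pm2$i_r[2, 2]))
  expect_true(all(pm2$mask[-5]))
  expect_equal(pm2$dtheta_r[1, 1], 5, tolerance = 1e-9)
  # valid pixels reproduce the inputs through the forward model
  for (i in 1:3)
    expect_equal(forward_intensity(pm2$i_r[1, 1], pm2$dtheta_r[1, 1],
                                   sqrt(pm2$sigma_s2[1, 1]), triad[i], rc),
                 imgs[[i]][1, 1], tolerance = 1e-9)

  expect_error(retrieve_parametric_images(
    list(matrix(1, 2, 2), matrix(1, 2, 2), matrix(1, 3, 2)), triad, rc),
    "shape")
  expect_error(retrieve_parametric_images(bg[1:2], triad[1:2], rc),
               "three")
})

test_that("triad invariance: alternate working points retrieve identically", {
  rc <- rc86
  fracs <- list(c(0.22, 1, 0.95), c(0.95, 1, 0.61), c(0.33, 1, 0.22),
                c(0.5, 1, 0.5))
  for (fr in fracs) {
    triad <- c(working_point_angle(rc, fr[1], "low"), 0,
               working_point_angle(rc, fr[3], "high"))
    tr <- pixel_triple(forward_intensity(0.79, 5, 6.42, triad, rc), triad)
    expect_equal(retrieve_refraction(tr), 5, tolerance = 1e-8)
    expect_equal(retrieve_scatter_variance(tr, rc), 6.42^2,
                 tolerance = 1e-6)
    dt <- retrieve_refraction(tr)
    s2 <- retrieve_scatter_variance(tr, rc)
    expect_equal(retrieve_apparent_absorption(tr, dt, s2, rc, 2L), 0.79,
                 tolerance = 1e-8)
  }
})

test_that("negative noisy variances are retained signed but clamped in sigma_s", {
  rc <- rc86
  triad <- half_slope()
  # craft a pixel whose inversion yields a negative variance
  I <- forward_intensity(1, 0, 0, triad, rc)
  I[2] <- I[2] * 1.02 # peak bumped up -> narrower-than-sigma local curve
  imgs <- lapply(seq_along(triad), function(i) matrix(I[i], 2, 2))
  pm <- retrieve_parametric_images(imgs, triad, rc)
  expect_true(all(pm$sigma_s2 < 0))
  expect_true(all(pm$sigma_s == 0))
  expect_true(all(pm$clamped))
  expect_true(all(pm$mask))
})
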