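test_that("surface detection finds the keratin top and flags dark images", {
  ph <- render_phantom(clean_params(seed = 2), boundary_model(40))
  surf <- detect_surface(ph$section)
  # surface (top of the keratin band) sits at z = 0 within one pixel
  expect_true(all(surf$depth_um <= ph$section$px_axial))

  dark <- cross_section(matrix(1, 70, 70), matrix(1, 70, 70), 0.625, 1)
  expect_error(detect_surface(dark), "detection error")
})

test_that("surface never lies below the traced interface on phantoms", {
  m <- boundary_model(40, sine_amplitude = 8, sine_period = 60)
  ph <- render_phantom(small_params(seed = 8), m)
  surf <- detect_surface(ph$section)
  tr <- measure_ecti(ph$section)
  s <- approx(surf$x_um, surf$depth_um, xout = tr$points$x_um)$y
  expect_true(all(s < tr$points$z_um))
})

test_that("thickness sampling uses the four interior positions exactly", {
  # linear wedge: boundary from 80 to 120 um across the width, surface at 0
  width <- 320
  xs <- seq(0, width, by = 0.625)
  surf <- structure(list(depth_um = rep(0, length(xs)), x_um = xs,
                         level = 10), class = "surface_line")
  tr <- structure(list(points = data.frame(
    x_um = xs, z_um = 80 + 40 * xs / width)), class = "boundary_trace")
  th <- epithelial_thickness(surf, tr, n_sites = 4)
  expect_equal(th$positions_um / width, c(1, 3, 5, 7) / 8)
  expect_equal(th$thickness_um, c(85, 95, 105, 115))
  expect_equal(th$mean_um, 100)

  # surface identical to the boundary: no epithelium left
  surf2 <- structure(list(depth_um = tr$points$z_um, x_um = xs, level = 10),
                     class = "surface_line")
  expect_error(epithelial_thickness(surf2, tr), "geometry error")
})

test_that("constant-thickness phantoms are recovered within 2 um", {
  ph <- render_phantom(phantom_params(rng_seed = 13), boundary_model(100))
  tr <- measure_ecti(ph$section)
  surf <- detect_surface(ph$section)
  th <- epithelial_thickness(surf, tr)
  expect_equal(length(th$thickness_um), 4L)
  expect_lt(abs(th$mean_um - 100), 2)
})

test_that("thickness is invariant under lateral mirroring", {
  m <- boundary_model(40, sine_amplitude = 10, sine_period = 50)
  ph <- render_phantom(small_params(seed = 17), m)
  sec <- ph$section
  mir <- cross_section(sec$channel_af[, ncol(sec$channel_af):1],
                       sec$channel_shg[, ncol(sec$channel_shg):1],
                       sec$px_lateral, sec$px_axial)
  th <- epithelial_thickness(detect_surface(sec), measure_ecti(sec))
  thm <- epithelial_thickness(detect_surface(mir), measure_ecti(mir))
  expect_equal(thm$mean_um, th$mean_um, tolerance = 0.02)
})

test_that("nuclear density recovers the generator truth", {
  # blank bright field: zero density
  blank <- matrix(200, 160, 160)
  nd0 <- nuclear_density(blank, 0.625)
  expect_equal(nd0$density_per_100um2, 0)

  # 100x100 um field at 0.12 nuclei/100 um^2, normal-size nuclei:
  # counts match the realized truth within +-1 in >= 90% of seeds
  hits <- vapply(1:20, function(s) {
    ef <- render_enface(0.12, c(8, 10), fov = 100,
                        params = small_params(seed = 100 + s))
    nd <- nuclear_density(ef$raster, 0.625, scale_range = c(6, 12))
    abs(nd$count - ef$truth$count) <= 1
  }, logical(1))
  expect_gte(mean(hits), 0.9)

  expect_error(nuclear_density(blank, 0.625, scale_range = c(0.5, 1)),
               "parameter error")
})

test_that("density estimation is invariant to global intensity scaling", {
  ef <- render_enface(0.12, c(8, 10), fov = 100,
                      params = small_params(seed = 55))
  a <- nuclear_density(ef$raster, 0.625, scale_range = c(6, 12))
  b <- nuclear_density(ef$raster * 3.7, 0.625, scale_range = c(6, 12))
  expect_equal(a$count, b$count)
})
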