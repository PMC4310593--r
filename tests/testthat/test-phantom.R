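test_that("noiseless SHG channel is exactly zero above the true boundary", {
  m <- boundary_model(40, sine_amplitude = 8, sine_period = 30)
  ph <- render_phantom(clean_params(seed = 2), m)
  z <- (seq_len(nrow(ph$section$channel_shg)) - 1) * ph$section$px_axial
  above <- outer(z, ph$truth$true_depth_um, "<")
  expect_true(all(ph$section$channel_shg[above] == 0))
  # and nonzero essentially everywhere below (base intensity, no texture)
  expect_true(all(ph$section$channel_shg[!above] > 0))
})

test_that("rendering is bit-identical under a fixed seed", {
  m <- boundary_model(40, sine_amplitude = 6, sine_period = 40)
  a <- render_phantom(small_params(seed = 9), m)
  b <- render_phantom(small_params(seed = 9), m)
  expect_identical(a$section, b$section)
  c <- render_phantom(small_params(seed = 10), m)
  expect_false(identical(a$section$channel_shg, c$section$channel_shg))
})

test_that("phantom geometry errors are raised", {
  expect_error(render_phantom(small_params(), boundary_model(100)),
               "deeper than")
  expect_error(render_phantom(small_params(), boundary_model(5)),
               "keratin")
  expect_error(render_phantom(phantom_params(fov_width = 30, fov_depth = 30,
                                             rng_seed = 1),
                              boundary_model(15)),
               "64 x 64")
  expect_error(phantom_params(fov_width = 100.3), "integers")
  expect_error(phantom_params(intensity_keratin = 300), "0, 255")
})

test_that("ground truth carries the analytic linearity of the model", {
  m <- boundary_model(40, sine_amplitude = 10, sine_period = 40)
  ph <- render_phantom(small_params(seed = 4), m)
  x <- ph$truth$x_um
  expect_equal(ph$truth$true_delta_linearity,
               true_delta_linearity(m, 80, xlim = range(x)),
               tolerance = 1e-10)
  expect_true(all(ph$truth$true_thickness_profile_um > 0))
})

test_that("en-face generator places nuclei at the requested density", {
  # density 0: uniform background, empty center list
  ef0 <- render_enface(0, c(8, 10), fov = 100,
                       params = clean_params(seed = 1))
  expect_equal(ef0$truth$count, 0L)
  expect_equal(length(unique(as.vector(ef0$raster))), 1L)

  # 0.12 per 100 um^2 on 100x100 um: mean realized count ~ Poisson(12)
  counts <- vapply(1:60, function(s) {
    render_enface(0.12, c(8, 10), fov = 100,
                  params = small_params(seed = s))$truth$count
  }, numeric(1))
  expect_lt(abs(mean(counts) - 12), 3 * sqrt(12 / 60))

  # hard core: no two nuclei overlap
  ef <- render_enface(0.25, c(8, 10), fov = 100,
                      params = small_params(seed = 3))
  ctr <- ef$truth$centers
  if (nrow(ctr) > 1) {
    d <- as.matrix(dist(ctr[, c("x_um", "y_um")]))
    rr <- outer(ctr$radius_um, ctr$radius_um, "+")
    diag(d) <- Inf
    expect_true(all(d >= rr - 1e-9))
  }
})

test_that("infeasible hard-core packing is rejected", {
  # 0.25 nuclei/100 um^2 with 16-18 um diameters: disk area fraction ~ 0.57
  expect_error(render_enface(0.25, c(16, 18), fov = 100,
                             params = small_params(seed = 1)),
               "packing error")
})
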