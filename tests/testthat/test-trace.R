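test_that("arc length sums Euclidean segments in physical units", {
  expect_equal(arc_length(rbind(c(0, 0), c(3, 4))), 5)
  # 8 pixel steps at 0.625 um/px lateral
  expect_equal(arc_length(cbind(c(0, 8) * 0.625, c(0, 0))), 5)
  semi <- semicircle_points(R = 50, n = 1e4)
  expect_equal(arc_length(semi), pi * 50, tolerance = 0.005)
  expect_error(arc_length(rbind(c(0, 0))), "degenerate trace")
})

test_that("deviation from linearity matches closed forms", {
  flat <- cbind(seq(0, 100, 5), rep(12, 21))
  m <- delta_linearity(flat)
  expect_equal(m$delta_L_norm, 0)
  expect_equal(m$l_um, m$L_um)

  semi <- delta_linearity(semicircle_points(R = 50, n = 2e4))
  expect_equal(semi$delta_L_norm, pi / 2 - 1, tolerance = 1e-4)

  expect_error(delta_linearity(rbind(c(1, 1), c(1, 1))),
               "degenerate geometry")
})

test_that("the statistic is translation invariant", {
  set.seed(11)
  pts <- cbind(seq(0, 80, 0.5), 40 + cumsum(rnorm(161, 0, 0.3)))
  a <- delta_linearity(pts)
  b <- delta_linearity(sweep(pts, 2, c(-37.2, 1051), "+"))
  expect_equal(a$delta_L_norm, b$delta_L_norm, tolerance = 1e-12)
  expect_equal(a$l_um, b$l_um, tolerance = 1e-12)
  expect_equal(a$L_um, b$L_um, tolerance = 1e-12)
})

test_that("minimal-cost path cost equals an independent relaxation oracle", {
  for (s in 1:100) {
    set.seed(s)
    cost <- matrix(runif(64, 0.05, 1), 8, 8)
    start <- c(sample(8, 1), 1L); end <- c(sample(8, 1), 8L)
    got <- ectishape:::dijkstra_grid(cost, start, end)
    want <- relax_grid_cost(cost, start, end)
    expect_equal(got$cost, want, tolerance = 1e-9)
  }
})

test_that("path cost never exceeds the monotone-path optimum", {
  for (s in 1:20) {
    set.seed(1000 + s)
    cost <- matrix(runif(100, 0.05, 1), 10, 10)
    got <- ectishape:::dijkstra_grid(cost, c(3, 1), c(7, 10))$cost
    mono <- monotone_path_cost(cost, c(3, 1), c(7, 10))
    expect_lte(got, mono + 1e-9)
  }
})

test_that("a continuous horizontal edge is traced as a flat line", {
  step <- matrix(0, 80, 100); step[41:80, ] <- 150
  em <- detect_edges(step, sigma = 2)
  tr <- trace_boundary(em, px_lateral = 0.625, px_axial = 1)
  expect_equal(nrow(tr$points), 100)
  expect_lt(tr$delta_L_norm, 1e-6)
  expect_lt(diff(range(tr$points$z_um)), 0.5)
})

test_that("the traced boundary of a sine phantom stays within 2 um RMS", {
  m <- boundary_model(100, sine_amplitude = 20, sine_period = 80)
  ph <- render_phantom(phantom_params(rng_seed = 21), m)
  tr <- measure_ecti(ph$section)
  zt <- approx(ph$truth$x_um, ph$truth$true_depth_um,
               xout = tr$points$x_um)$y
  expect_lt(sqrt(mean((tr$points$z_um - zt)^2)), 2)
  expect_equal(tr$delta_L_norm, ph$truth$true_delta_linearity,
               tolerance = 0.05)
})

test_that("measured linearity deviation never decreases along a bump ladder", {
  vals <- vapply(c(0, 8, 16, 24, 32), function(amp) {
    m <- if (amp == 0) boundary_model(40) else
      boundary_model(40, bumps = data.frame(center = 40, amplitude = amp,
                                            width = 8))
    ph <- render_phantom(clean_params(seed = 31), m)
    measure_ecti(ph$section)$delta_L_norm
  }, numeric(1))
  expect_true(all(diff(vals) >= -1e-6))
})

test_that("traces recover the quadrature oracle across analytic models", {
  # subset of the validity-domain grid; the full sweep runs in acceptance
  ms <- oracle_model_grid()[c(1, 4, 8, 11, 13, 16, 18, 20)]
  for (i in seq_along(ms)) {
    truth <- true_delta_linearity(ms[[i]], 320, xlim = c(0, 319.375))
    med <- median(vapply(1:3, function(r) {
      ph <- render_phantom(phantom_params(rng_seed = 400 + 10 * i + r),
                           ms[[i]])
      measure_ecti(ph$section)$delta_L_norm
    }, numeric(1)))
    expect_true(abs(med - truth) <= max(0.05 * truth, 0.01),
                info = sprintf("model %d: truth %.4f measured %.4f",
                               i, truth, med))
  }
})
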