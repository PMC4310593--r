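test_that("thresholding separates a two-valued image and rejects constants", {
  img <- matrix(0, 70, 70); img[30:70, ] <- 200
  sec <- cross_section(img, img, 0.625, 1)
  mask <- threshold_shg(sec)
  expect_identical(unclass(mask)[, 1], img[, 1] == 200)
  expect_true(attr(mask, "level") > 0 && attr(mask, "level") < 200)

  zero <- cross_section(img, matrix(0, 70, 70), 0.625, 1)
  expect_error(threshold_shg(zero), "degenerate histogram")
  # manual level still works on a constant image
  expect_true(all(!threshold_shg(zero, "manual", manual_level = 10)))
})

test_that("mask topmost row tracks the true boundary on a noiseless phantom", {
  ph <- render_phantom(clean_params(seed = 3), boundary_model(40))
  mask <- threshold_shg(ph$section)
  top <- apply(mask, 2, function(col) which(col)[1])
  true_row <- ph$truth$true_depth_um / ph$section$px_axial + 1
  expect_true(all(abs(top - true_row) <= 1))
})

test_that("edge detection finds a step and returns nothing on constants", {
  em0 <- detect_edges(matrix(5, 60, 60))
  expect_false(any(em0$edges))

  step <- matrix(0, 80, 80); step[41:80, ] <- 150
  em <- detect_edges(step, sigma = 2)
  hit <- apply(em$edges, 2, function(col) which(col))
  expect_true(all(lengths(hit) >= 1))
  rows <- unlist(hit)
  expect_true(all(abs(rows - 40.5) <= 1.5))   # within 1 px of the step
  expect_true(all(em$gradient >= 0))

  expect_error(detect_edges(step, sigma = 0), "sigma")
  expect_error(detect_edges(step, low = 0.9, high = 0.5), "low")
})

test_that("edges lie near the true boundary across phantom columns", {
  m <- boundary_model(40, sine_amplitude = 8, sine_period = 60)
  ph <- render_phantom(small_params(seed = 6), m)
  em <- detect_edges(ph$section$channel_shg)
  true_row <- ph$truth$true_depth_um / ph$section$px_axial + 1
  ok <- vapply(seq_len(ncol(em$edges)), function(j) {
    rows <- which(em$edges[, j])
    length(rows) > 0 && min(abs(rows - true_row[j])) <= 2
  }, logical(1))
  expect_gte(mean(ok), 0.95)
})

test_that("topmost candidates report gaps and reject speckle", {
  mask <- matrix(FALSE, 100, 40)
  mask[80, ] <- TRUE
  expect_equal(topmost_candidates(mask), rep(80L, 40))

  hole <- mask; hole[80, 10:12] <- FALSE
  cand <- topmost_candidates(hole)
  expect_true(all(is.na(cand[10:12])))
  expect_equal(cand[c(9, 13)], c(80L, 80L))

  speck <- mask; speck[5, 20] <- TRUE     # isolated spot far above the line
  cand <- topmost_candidates(speck)
  expect_true(is.na(cand[20]))
  expect_equal(cand[21], 80L)

  sparse <- matrix(FALSE, 100, 40); sparse[50, 1:10] <- TRUE
  expect_error(topmost_candidates(sparse), "extraction failure")
  expect_error(topmost_candidates(matrix(FALSE, 10, 10)), "empty mask")
})
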