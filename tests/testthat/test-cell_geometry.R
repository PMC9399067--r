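test_that("equivalent sphere radius follows (abc)^(1/3)", {
  expect_equal(equivalent_sphere_radius(4, 4, 4), 4)
  expect_equal(equivalent_sphere_radius(8, 2, 4), 4)
  expect_equal(equivalent_sphere_radius(5, 3, 2), 30^(1 / 3),
               tolerance = 1e-9)
  expect_error(equivalent_sphere_radius(-1, 2, 3), "positive")
})

test_that("attached geometry preserves volume, a/b ratio and height rules", {
  g <- build_attached_geometry(4, 4, 4, cytoplasm_scale = 2.5,
                               floating_volume = 4 / 3 * pi * 8^3)
  expect_equal(cell_volume(g), 2144.7, tolerance = 0.01)
  expect_equal(g$a_cyt / g$b_cyt, g$a / g$b, tolerance = 1e-9)

  g2 <- build_attached_geometry(5, 3.2, 3, cytoplasm_scale = 2.2,
                                floating_volume = 2000)
  expect_equal(g2$a_cyt / g2$b_cyt, g2$a / g2$b, tolerance = 1e-7)
  expect_equal(cell_volume(g2), 2000, tolerance = 1e-9)

  expect_error(build_attached_geometry(4, 4, 6, floating_volume = 2000),
               "must be one of 3, 4, 5")
  expect_error(build_attached_geometry(4, 4, 4, floating_volume = 100),
               "exceed the nucleus volume")
  # wildly displaced nucleus cannot stay inside the cell
  expect_error(attached_cell_geometry(4, 4, 2, 10, 10, 3,
                                      nucleus_offset = -2.5),
               "protrude")
})

test_that("membrane shell volume follows the thin-shell limit", {
  g <- floating_cell_geometry(8.7, 4)
  ratio <- membrane_shell_volume(g) / cell_volume(g)
  expect_equal(ratio, 3 * 0.0075 / 8.7, tolerance = 2e-3)
})

test_that("Hough transform recovers a single circle and rejects blanks", {
  # dark ring of radius 20 px on a bright field, 0.4 um/px
  n <- 128
  img <- matrix(0.9, n, n)
  d <- sqrt(outer((seq_len(n) - 64)^2, (seq_len(n) - 64)^2, `+`))
  img[abs(d - 20) <= 1.2] <- 0.2
  det <- detect_circle_radii(img, c(6, 10), 0.4)
  expect_identical(nrow(det$detections), 1L)
  expect_equal(det$radii_um, 8.0, tolerance = 0.4 / 8)

  expect_warning(out <- detect_circle_radii(matrix(0.5, 64, 64),
                                            c(2, 6), 0.4), "constant|no circles")
  expect_length(out$radii_um, 0)

  # intensity scaling leaves detections unchanged
  det2 <- detect_circle_radii(img * 7 + 0.3, c(6, 10), 0.4)
  expect_equal(det2$radii_um, det$radii_um)
})

test_that("Hough transform sizes a dense synthetic field of cells", {
  gen <- gen_brightfield(n_circles = 100, radius_range_um = c(6, 11),
                         pixel_size_um = 0.4, seed = 42)
  det <- detect_circle_radii(gen$image, c(5, 12), 0.4)
  expect_gte(nrow(det$detections), 95)
  m <- match_detections(as.matrix(det$detections[, c("x", "y")]),
                        as.matrix(gen$truth[, c("cx", "cy")]),
                        max_dist = 8)
  ok <- !is.na(m)
  expect_gte(sum(ok), 95)
  err_px <- abs(det$detections$radius_px[ok] - gen$truth$radius_px[m[ok]])
  expect_lte(max(err_px), 1)
  expect_true(all(c("min", "mean", "max", "n") %in% names(det$summary)))
})
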