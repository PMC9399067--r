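test_that("generators are bit-reproducible under a fixed seed", {
  expect_identical(gen_clonogenic(c(1, 2), 0.3, seed = 5)$data,
                   gen_clonogenic(c(1, 2), 0.3, seed = 5)$data)
  expect_false(identical(gen_clonogenic(c(1, 2), 0.3, seed = 5)$data,
                         gen_clonogenic(c(1, 2), 0.3, seed = 6)$data))
  expect_identical(gen_excretion(seed = 3)$data, gen_excretion(seed = 3)$data)
  g1 <- gen_foci_images(n_nuclei = 3, nuclei_per_image = 3, seed = 11)
  g2 <- gen_foci_images(n_nuclei = 3, nuclei_per_image = 3, seed = 11)
  expect_identical(g1$stacks[[1]]$damage, g2$stacks[[1]]$damage)
})

test_that("clonogenic generator matches its analytic mean", {
  g <- gen_clonogenic(3.70, alpha = 0.16, n_experiments = 1,
                      n_replicates = 10000, seed = 8)
  counts <- g$data$colonies[g$data$dose_gy == 3.70]
  expect_equal(mean(counts), 450 * 0.5 * exp(-0.16 * 3.70),
               tolerance = 0.02)
  # alpha = 0 reduces to the untreated distribution
  g0 <- gen_clonogenic(2, alpha = 0, n_experiments = 1,
                       n_replicates = 2000, seed = 9)
  m <- tapply(g0$data$colonies, g0$data$dose_gy, mean)
  expect_equal(unname(m[["2"]]), unname(m[["0"]]), tolerance = 0.05)
})

test_that("excretion generator reproduces the assay design", {
  g <- gen_excretion(seed = 2)
  expect_setequal(unique(g$data$time_h), c(0, 4, 24, 48, 120))
  expect_identical(max(g$data$experiment), 2L)
  expect_identical(max(g$data$replicate), 3L)
  # zero noise lies exactly on the generating model
  g0 <- gen_excretion(cv = 0, seed = 2)
  expect_equal(g0$data$retained_fraction,
               retained_fraction(clearance_model(0.41, 2.3),
                                 g0$data$time_h),
               tolerance = 1e-12)
})

test_that("focus-count distribution matches the requested moments", {
  set.seed(1)
  x <- celldosim:::.sample_foci_counts(1e4, 18.1, 7.4, "nbinom")
  expect_equal(mean(x), 18.1, tolerance = 0.05)
  expect_equal(sd(x), 7.4, tolerance = 0.05)
  y <- celldosim:::.sample_foci_counts(1e4, 18.1, 7.4, "poisson")
  expect_equal(sd(y), sqrt(18.1), tolerance = 0.05)
})

test_that("zero-foci scenario leaves a pure background damage channel", {
  g <- gen_foci_images(n_nuclei = 4, nuclei_per_image = 4, mean_foci = 0,
                       seed = 3)
  pr <- max_project(g$stacks[[1]])
  rois <- segment_nuclei(pr$nuclear)
  expect_true(all(count_foci(rois, pr$damage)$foci_count == 0))
  expect_true(all(g$truth$n_foci == 0))
})

test_that("brightfield generator round-trips through circle detection", {
  g <- gen_brightfield(n_circles = 20, noise_sd = 0, seed = 13)
  det <- detect_circle_radii(g$image, c(5, 12), 0.4)
  expect_identical(nrow(det$detections), 20L)
  m <- match_detections(as.matrix(det$detections[, c("x", "y")]),
                        as.matrix(g$truth[, c("cx", "cy")]), max_dist = 8)
  expect_true(all(!is.na(m)))
  expect_lte(max(abs(det$detections$radius_px - g$truth$radius_px[m])), 1)
})

test_that("generators write metadata sidecars alongside their data", {
  g <- gen_excretion(seed = 12)
  path <- tempfile(fileext = ".csv")
  write_synthetic_csv(g, path)
  expect_true(file.exists(path))
  meta <- jsonlite::read_json(paste0(path, ".json"))
  expect_identical(meta$seed, 12L)
  expect_equal(meta$plateau_fraction, 0.41)
  unlink(c(path, paste0(path, ".json")))
})
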