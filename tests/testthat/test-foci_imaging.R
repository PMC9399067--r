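# hand-built circular nucleus ROI for threshold tests
manual_roi <- function(n = 121, r = 45) {
  cen <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - cen)^2, (seq_len(n) - cen)^2, `+`))
  lab <- matrix(0L, n, n)
  lab[d <= r] <- 1L
  structure(list(labels = lab,
                 stats = data.frame(roi = 1L, area_px = sum(lab),
                                    cx = cen, cy = cen)),
            class = "nucleus_rois")
}

gaussian_spot <- function(img, cx, cy, amp, sigma) {
  xs <- seq_len(nrow(img)); ys <- seq_len(ncol(img))
  img + amp * exp(-outer((xs - cx)^2, (ys - cy)^2, `+`) / (2 * sigma^2))
}

test_that("maximum projection is the per-pixel envelope", {
  m1 <- matrix(runif(64), 8, 8)
  st <- image_stack(array(m1, c(8, 8, 1)), array(m1, c(8, 8, 1)), 0.1)
  expect_identical(max_project(st)$nuclear, m1)

  a <- matrix(0, 8, 8); a[2, 2] <- 1
  b <- matrix(0, 8, 8); b[6, 7] <- 0.8
  st2 <- image_stack(array(c(a, b), c(8, 8, 2)),
                     array(c(a, b), c(8, 8, 2)), 0.1)
  expect_identical(max_project(st2)$damage, pmax(a, b))

  # generator stacks: projection equals the analytic envelope (plane 2)
  g <- gen_foci_images(n_nuclei = 4, nuclei_per_image = 4, mean_foci = 5,
                       seed = 2)
  pr <- max_project(g$stacks[[1]])
  expect_equal(pr$damage, g$stacks[[1]]$damage[, , 2], tolerance = 1e-12)
})

test_that("nucleus segmentation recovers synthetic ellipses", {
  g <- gen_foci_images(n_nuclei = 30, nuclei_per_image = 30, mean_foci = 0,
                       seed = 7)
  pr <- max_project(g$stacks[[1]])
  rois <- segment_nuclei(pr$nuclear)
  expect_identical(nrow(rois$stats), 30L)
  # per-nucleus IoU against the ground-truth masks
  truth <- g$masks[[1]]
  ious <- vapply(seq_len(30), function(j) {
    tr <- truth == j
    cx <- mean(which(tr, arr.ind = TRUE)[, 1])
    cy <- mean(which(tr, arr.ind = TRUE)[, 2])
    dd <- (rois$stats$cx - cx)^2 + (rois$stats$cy - cy)^2
    id <- rois$stats$roi[which.min(dd)]
    dt <- rois$labels == id
    sum(dt & tr) / sum(dt | tr)
  }, 0)
  expect_true(all(ious >= 0.8))
})

test_that("blank images and touching nuclei are handled", {
  expect_warning(r0 <- segment_nuclei(matrix(0.2, 64, 64)), "no nuclei|constant")
  expect_identical(nrow(r0$stats), 0L)

  # two ellipses with centres 1.2 minor-axes apart: split by watershed
  n <- 221
  img <- matrix(0.1, n, n)
  mk <- function(cx, cy, a, b) {
    dx <- outer(seq_len(n) - cx, rep(1, n))
    dy <- outer(rep(1, n), seq_len(n) - cy)
    (dx / a)^2 + (dy / b)^2 <= 1
  }
  bmin <- 30
  img[mk(110 - 0.6 * bmin, 110, 40, bmin)] <- 0.9
  img[mk(110 + 0.6 * bmin, 110, 40, bmin)] <- 0.9
  rois <- segment_nuclei(img, watershed_tolerance = 1)
  expect_identical(nrow(rois$stats), 2L)
})

test_that("per-nucleus adaptive threshold counts foci correctly", {
  set.seed(5)
  rois <- manual_roi()
  # uniform signal: nothing exceeds mean + k SD
  flat <- matrix(0.4, 121, 121)
  expect_identical(count_foci(rois, flat)$foci_count, 0L)

  # 12 well-separated Gaussian foci at SNR 5
  bg_sd <- 0.05
  dmg <- matrix(rnorm(121^2, 0.2, bg_sd), 121, 121)
  th <- seq(0, 2 * pi, length.out = 13)[1:12]
  for (k in seq_len(12))
    dmg <- gaussian_spot(dmg, 61 + 30 * cos(th[k]), 61 + 30 * sin(th[k]),
                         5 * bg_sd, 3)
  n12 <- count_foci(rois, dmg)$foci_count
  expect_gte(n12, 11)
  expect_lte(n12, 13)

  # affine intensity invariance
  expect_identical(count_foci(rois, dmg * 11 + 3)$foci_count, n12)

  # adding a focus in an empty spot never decreases the count
  dmg2 <- gaussian_spot(dmg, 61, 61, 5 * bg_sd, 3)
  expect_gte(count_foci(rois, dmg2)$foci_count, n12)
})

test_that("end-to-end foci recovery tracks the generated mean", {
  means <- c(4, 10, 20)
  detected <- vapply(means, function(mu) {
    g <- gen_foci_images(n_nuclei = 25, nuclei_per_image = 25,
                         mean_foci = mu, sd_foci = sqrt(mu),
                         seed = 100 + mu)
    pr <- max_project(g$stacks[[1]])
    rois <- segment_nuclei(pr$nuclear)
    mean(count_foci(rois, pr$damage)$foci_count)
  }, 0)
  slope <- coef(lm(detected ~ 0 + means))[[1]]
  expect_gte(slope, 0.85)
  expect_lte(slope, 1.1)
})

test_that("time-course summaries compute SEM and fold change", {
  df <- data.frame(
    condition = rep(c("treated", "untreated"), each = 6),
    timepoint_h = rep(c(0, 0, 0, 16, 16, 16), 2),
    foci_count = c(8, 10, 12, 18, 20, 22, 4, 5, 6, 5, 5, 5))
  tc <- focus_timecourse(df)
  tr0 <- tc[tc$condition == "treated" & tc$timepoint_h == 0, ]
  expect_equal(tr0$mean_foci, 10)
  expect_equal(tr0$sem, sd(c(8, 10, 12)) / sqrt(3))
  expect_equal(tr0$fold_change_vs_untreated, 2)

  single <- focus_timecourse(df[df$condition == "treated", ])
  expect_false("fold_change_vs_untreated" %in% names(single))
})

test_that("image stacks survive a TIFF round trip", {
  g <- gen_foci_images(n_nuclei = 2, nuclei_per_image = 2, mean_foci = 3,
                       seed = 9)
  path <- tempfile(fileext = ".tif")
  write_image_stack(g$stacks[[1]], path)
  back <- read_image_stack(path, g$stacks[[1]]$pixel_size_um)
  expect_equal(dim(back$nuclear), dim(g$stacks[[1]]$nuclear))
  expect_lt(max(abs(back$damage - pmin(g$stacks[[1]]$damage, 1))),
            2 / 65535)
  unlink(path)
})
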