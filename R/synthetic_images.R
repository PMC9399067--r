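# ---------------------------------------------------------------------------
# Synthetic microscopy generators: two-channel z-stacks of elliptical
# nuclei carrying Gaussian damage foci (for the foci pipeline), and
# brightfield fields of circular cells (for Hough sizing). Ground truth
# (masks, counts, radii) is returned alongside the images.
# ---------------------------------------------------------------------------

# per-nucleus focus counts: negative binomial matched to (mean, sd) when
# overdispersed, Poisson otherwise
.sample_foci_counts <- function(n, mean_foci, sd_foci, distribution) {
  if (mean_foci == 0) return(integer(n))
  if (distribution == "poisson" || sd_foci^2 <= mean_foci)
    return(stats::rpois(n, mean_foci))
  size <- mean_foci^2 / (sd_foci^2 - mean_foci)
  stats::rnbinom(n, size = size, mu = mean_foci)
}

# add a Gaussian spot in place, clipped to the image
.add_gaussian <- function(img, cx, cy, amp, sigma) {
  r <- ceiling(4 * sigma)
  xs <- max(1, round(cx) - r):min(nrow(img), round(cx) + r)
  ys <- max(1, round(cy) - r):min(ncol(img), round(cy) + r)
  dx <- xs - cx
  dy <- ys - cy
  img[xs, ys] <- img[xs, ys] +
    amp * exp(-outer(dx^2, dy^2, `+`) / (2 * sigma^2))
  img
}

# logical mask of a rotated ellipse, as index pairs
.ellipse_indices <- function(nr, nc, cx, cy, a, b, theta) {
  r <- ceiling(max(a, b))
  xs <- max(1, round(cx) - r):min(nr, round(cx) + r)
  ys <- max(1, round(cy) - r):min(nc, round(cy) + r)
  dx <- outer(xs - cx, rep(1, length(ys)))
  dy <- outer(rep(1, length(xs)), ys - cy)
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u^2 + v^2 <= 1
  cbind(rep(xs, times = length(ys))[inside],
        rep(ys, each = length(xs))[inside])
}

# grid-with-jitter placement of n objects of radius `rad` px
.grid_positions <- function(n, rad, jitter, step_pad = 10) {
  side <- ceiling(sqrt(n))
  step <- 2 * rad + step_pad + 2 * jitter
  margin <- rad + jitter + 5
  extent <- ceiling(2 * margin + (side - 1) * step)
  base <- margin + (seq_len(side) - 1) * step
  pos <- expand.grid(x = base, y = base)[seq_len(n), ]
  pos$x <- pos$x + stats::runif(n, -jitter, jitter)
  pos$y <- pos$y + stats::runif(n, -jitter, jitter)
  list(positions = pos, extent = extent)
}

#' Simulate two-channel z-stacks of nuclei with damage foci
#'
#' Generates elliptical nuclei on a grid (with jitter) across as many
#' images as needed. Per-nucleus focus counts are drawn from a negative
#' binomial matched to the requested mean and SD (overdispersed, as
#' observed for damage foci) or from a Poisson; each focus is an additive
#' Gaussian spot of amplitude `snr` times the in-nucleus background SD.
#' Z-stacks are built by scaling a single noisy master plane with
#' per-plane weights (max 1), so the analytic envelope of the stack is
#' exactly the master image.
#'
#' @param n_nuclei Total number of nuclei to generate.
#' @param mean_foci,sd_foci Target mean and SD of the per-nucleus focus
#'   count (defaults 18.1 and 7.4).
#' @param distribution `"nbinom"` (default) or `"poisson"` (ignores
#'   `sd_foci`).
#' @param snr Focus amplitude in units of the in-nucleus background SD
#'   (default 5).
#' @param pixel_size_um Pixel size (default 0.1 um/px).
#' @param nuclei_per_image Nuclei per generated image (default 25).
#' @param n_z Number of z-planes (default 3).
#' @param axis_a_um,axis_b_um Ranges of the nucleus semi-axes in um.
#' @param focus_sigma_um Gaussian focus SD (default 0.3 um).
#' @param min_focus_sep_um Minimum distance between focus centres
#'   (default 1.5 um; relaxed progressively if a nucleus is too crowded).
#' @param seed Integer seed.
#' @return List with `stacks` (list of [image_stack()]), `masks` (list of
#'   ground-truth label matrices), `truth` (`data.frame` per nucleus:
#'   image, nucleus, centre, axes, angle, `n_foci`) and `params`.
#' @export
gen_foci_images <- function(n_nuclei = 108, mean_foci = 18.1,
                            sd_foci = 7.4,
                            distribution = c("nbinom", "poisson"),
                            snr = 5, pixel_size_um = 0.1,
                            nuclei_per_image = 25, n_z = 3,
                            axis_a_um = c(4, 6), axis_b_um = c(3, 5),
                            focus_sigma_um = 0.3,
                            min_focus_sep_um = 1.5, seed = 1L) {
  distribution <- match.arg(distribution)
  stopifnot(n_nuclei >= 1, mean_foci >= 0, snr > 0)
  bg_in <- 0.20; bg_in_sd <- 0.05
  bg_out <- 0.05; bg_out_sd <- 0.02
  nuc_fg <- 0.85; nuc_fg_sd <- 0.05; nuc_bg <- 0.10; nuc_bg_sd <- 0.03
  sigma_px <- focus_sigma_um / pixel_size_um
  sep_px <- min_focus_sep_um / pixel_size_um
  amp <- snr * bg_in_sd
  zw <- if (n_z == 1L) 1 else {
    w <- 0.6 + 0.4 * exp(-((seq_len(n_z) - (n_z + 1) / 2)^2) / 2)
    w / max(w)
  }
  n_images <- ceiling(n_nuclei / nuclei_per_image)
  with_seed(seed, {
    counts <- .sample_foci_counts(n_nuclei, mean_foci, sd_foci,
                                  distribution)
    stacks <- list(); masks <- list(); truth <- list()
    done <- 0L
    for (im in seq_len(n_images)) {
      n_here <- min(nuclei_per_image, n_nuclei - done)
      max_a_px <- max(axis_a_um) / pixel_size_um
      gp <- .grid_positions(n_here, max_a_px, jitter = 8)
      npx <- gp$extent
      nuclear <- matrix(nuc_bg + stats::rnorm(npx * npx, 0, nuc_bg_sd),
                        npx, npx)
      damage <- matrix(bg_out + stats::rnorm(npx * npx, 0, bg_out_sd),
                       npx, npx)
      lab <- matrix(0L, npx, npx)
      for (j in seq_len(n_here)) {
        ai <- stats::runif(1, axis_a_um[1], axis_a_um[2]) / pixel_size_um
        bi <- stats::runif(1, axis_b_um[1], axis_b_um[2]) / pixel_size_um
        th <- stats::runif(1, 0, pi)
        cx <- gp$positions$x[j]; cy <- gp$positions$y[j]
        idx <- .ellipse_indices(npx, npx, cx, cy, ai, bi, th)
        lab[idx] <- j
        nuclear[idx] <- nuc_fg + stats::rnorm(nrow(idx), 0, nuc_fg_sd)
        damage[idx] <- bg_in + stats::rnorm(nrow(idx), 0, bg_in_sd)
        nf <- counts[done + j]
        if (nf > 0) {
          centres <- matrix(NA_real_, 0, 2)
          sep <- sep_px
          tries <- 0L
          while (nrow(centres) < nf) {
            u <- stats::runif(1); v <- stats::runif(1, 0, 2 * pi)
            rr <- 0.75 * sqrt(u)
            px <- cx + rr * ai * cos(v) * cos(th) -
              rr * bi * sin(v) * sin(th)
            py <- cy + rr * ai * cos(v) * sin(th) +
              rr * bi * sin(v) * cos(th)
            ok <- !nrow(centres) ||
              all((centres[, 1] - px)^2 + (centres[, 2] - py)^2 >= sep^2)
            if (ok) centres <- rbind(centres, c(px, py))
            tries <- tries + 1L
            if (tries > 300L) { sep <- sep * 0.7; tries <- 0L }
          }
          for (f in seq_len(nf))
            damage <- .add_gaussian(damage, centres[f, 1], centres[f, 2],
                                    amp, sigma_px)
        }
        truth[[length(truth) + 1L]] <- data.frame(
          image = im, nucleus = j, cx = cx, cy = cy, a_px = ai,
          b_px = bi, theta = th, n_foci = nf)
      }
      # intensities are non-negative so that per-plane scaling with
      # weights <= 1 makes the master image the exact stack envelope
      nuclear <- pmax(nuclear, 0)
      damage <- pmax(damage, 0)
      nuc_stack <- array(0, c(npx, npx, n_z))
      dam_stack <- array(0, c(npx, npx, n_z))
      for (k in seq_len(n_z)) {
        nuc_stack[, , k] <- nuclear * zw[k]
        dam_stack[, , k] <- damage * zw[k]
      }
      stacks[[im]] <- image_stack(nuc_stack, dam_stack, pixel_size_um)
      masks[[im]] <- lab
      done <- done + n_here
    }
    list(stacks = stacks, masks = masks,
         truth = do.call(rbind, truth),
         params = list(generator = "gen_foci_images", seed = seed,
                       n_nuclei = n_nuclei, mean_foci = mean_foci,
                       sd_foci = sd_foci, distribution = distribution,
                       snr = snr, pixel_size_um = pixel_size_um,
                       n_z = n_z, focus_sigma_um = focus_sigma_um,
                       min_focus_sep_um = min_focus_sep_um))
  })
}

#' Simulate a brightfield image of floating (circular) cells
#'
#' Dark disks on a bright background, placed on a jittered grid, with
#' Gaussian pixel noise; the ground-truth centres and radii are returned
#' for round-trip tests of the Hough sizing.
#'
#' @param n_circles Number of cells (default 100).
#' @param radius_range_um Radii drawn uniformly from this range
#'   (default 6-11 um).
#' @param pixel_size_um Pixel size (default 0.4 um/px).
#' @param noise_sd Gaussian noise SD (default 0.01).
#' @param seed Integer seed.
#' @return List with `image` (matrix), `truth` (`data.frame`: `cx`, `cy`,
#'   `radius_px`, `radius_um`) and `params`.
#' @export
gen_brightfield <- function(n_circles = 100, radius_range_um = c(6, 11),
                            pixel_size_um = 0.4, noise_sd = 0.01,
                            seed = 1L) {
  stopifnot(n_circles >= 1, all(radius_range_um > 0))
  rmax_px <- max(radius_range_um) / pixel_size_um
  with_seed(seed, {
    gp <- .grid_positions(n_circles, rmax_px, jitter = 5, step_pad = 14)
    npx <- gp$extent
    img <- matrix(0.9, npx, npx)
    radii <- stats::runif(n_circles, radius_range_um[1],
                          radius_range_um[2]) / pixel_size_um
    xs <- matrix(seq_len(npx), npx, npx)
    ys <- t(xs)
    for (j in seq_len(n_circles)) {
      d2 <- (xs - gp$positions$x[j])^2 + (ys - gp$positions$y[j])^2
      img[d2 <= radii[j]^2] <- 0.35
    }
    img <- img + matrix(stats::rnorm(npx * npx, 0, noise_sd), npx, npx)
    list(image = img,
         truth = data.frame(cx = gp$positions$x, cy = gp$positions$y,
                            radius_px = radii,
                            radius_um = radii * pixel_size_um),
         params = list(generator = "gen_brightfield", seed = seed,
                       n_circles = n_circles,
                       radius_range_um = radius_range_um,
                       pixel_size_um = pixel_size_um,
                       noise_sd = noise_sd))
  })
}

#' Write synthetic image data with ground truth and metadata
#'
#' Writes each stack as a multi-page TIFF plus a ground-truth CSV and a
#' JSON metadata sidecar into a directory.
#'
#' @param x Result of [gen_foci_images()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_synthetic_images <- function(x, dir) {
  stopifnot(is.list(x), !is.null(x$stacks))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (i in seq_along(x$stacks))
    write_image_stack(x$stacks[[i]],
                      file.path(dir, sprintf("stack_%03d.tif", i)))
  utils::write.csv(x$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  jsonlite::write_json(x$params, file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
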